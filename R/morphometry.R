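#' Area of a simple polygon (shoelace formula)
#'
#' Returns the absolute enclosed area, so the result is invariant to vertex
#' orientation, cyclic rotation of the vertex order, and rigid motion. The
#' polygon is implicitly closed (an explicitly repeated first vertex is
#' tolerated and dropped).
#'
#' @param vertices Two-column numeric matrix (or data.frame) of x/y
#'   coordinates in um.
#' @param check If `TRUE` (default), verify that at least 3 distinct
#'   vertices remain and that the polygon does not self-intersect
#'   (O(n^2) segment test). Generated star-shaped contours are simple by
#'   construction; bulk callers may pass `FALSE`.
#' @return Area in um^2.
#' @export
#' @examples
#' polygon_area(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)))  # unit square -> 1
polygon_area <- function(vertices, check = TRUE) {
  v <- as.matrix(vertices)
  if (!is.numeric(v) || ncol(v) != 2L) stop("vertices must be an n x 2 numeric matrix")
  n <- nrow(v)
  if (n >= 2L && all(v[1L, ] == v[n, ])) { v <- v[-n, , drop = FALSE]; n <- n - 1L }
  if (check) {
    if (nrow(unique(v)) < 3L) stop("polygon needs at least 3 distinct vertices")
    if (polygon_self_intersects(v)) stop("polygon is self-intersecting")
  } else if (n < 3L) stop("polygon needs at least 3 vertices")
  x <- v[, 1L]; y <- v[, 2L]
  xn <- c(x[-1L], x[1L]); yn <- c(y[-1L], y[1L])
  abs(sum(x * yn - xn * y)) / 2
}

# TRUE if any two non-adjacent edges of the closed polygon properly
# intersect or overlap; vectorized over all edge pairs
polygon_self_intersects <- function(v) {
  n <- nrow(v)
  if (n < 4L) return(FALSE)
  a <- v; b <- v[c(2:n, 1L), , drop = FALSE]
  idx <- which(outer(seq_len(n), seq_len(n), function(i, j)
    j > i + 1L & !(i == 1L & j == n)), arr.ind = TRUE)
  i <- idx[, 1L]; j <- idx[, 2L]
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  d1 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], a[j, 1], a[j, 2])
  d2 <- cross(a[i, 1], a[i, 2], b[i, 1], b[i, 2], b[j, 1], b[j, 2])
  d3 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], a[i, 1], a[i, 2])
  d4 <- cross(a[j, 1], a[j, 2], b[j, 1], b[j, 2], b[i, 1], b[i, 2])
  any(((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
      ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

#' Morphometric indices from the three cross-sectional areas
#'
#' Given the inner area of the external elastic lamina (`a_eel`), the inner
#' area of the internal elastic lamina (`a_iel`) and the lumen area
#' (`a_lumen`), computes:
#' \deqn{MA = A_{EEL} - A_{IEL}, \quad IA = A_{IEL} - A_{lumen}}
#' and thicknesses as differences of equivalent-circle radii
#' \eqn{r(A) = \sqrt{A/\pi}}:
#' \deqn{MT = r(A_{EEL}) - r(A_{IEL})}
#' \deqn{IT = r(A_{EEL}) - r(A_{lumen}) \ \mathrm{(printed\ mode)}
#'   \quad\textrm{or}\quad r(A_{IEL}) - r(A_{lumen}) \ \mathrm{(anatomical)}}
#' \deqn{HRIA = IA/(IA+MA), \quad HRIT = IT/(IT+MT)}
#'
#' The default `"printed"` mode keeps fidelity to the source study's
#' printed IT formula, which measures from the EEL (and therefore includes
#' the media); `"anatomical"` measures the intima proper, from the IEL.
#' Ratios are returned as fractions in `[0, 1]`; multiply by 100 to report
#' percent. Degenerate denominators (an uninjured vessel with `IA = IT =
#' 0`, or a fully collapsed annulus) yield a ratio of 0, not an error.
#'
#' @param a_eel,a_iel,a_lumen Areas in um^2 (vectorized; must satisfy
#'   `a_eel >= a_iel >= a_lumen >= 0` up to a 1e-9 relative tolerance).
#' @param mode `"printed"` (default) or `"anatomical"`.
#' @param labels Optional slice labels used in error messages.
#' @return `data.frame` with columns `a_eel`, `a_iel`, `a_lumen`, `MA`,
#'   `IA`, `MT`, `IT`, `HRIA`, `HRIT`.
#' @export
#' @examples
#' compute_indices(9 * pi, 4 * pi, pi)  # concentric circles, radii 3, 2, 1
compute_indices <- function(a_eel, a_iel, a_lumen,
                            mode = c("printed", "anatomical"),
                            labels = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(a_eel) == length(a_iel), length(a_iel) == length(a_lumen))
  tol <- 1e-9 * pmax(a_eel, 1)
  bad <- which(a_lumen < -tol | a_iel < a_lumen - tol | a_eel < a_iel - tol)
  if (length(bad)) {
    who <- if (is.null(labels)) paste("slice", bad) else labels[bad]
    stop("contour nesting violated (need a_eel >= a_iel >= a_lumen >= 0) for: ",
         paste(utils::head(who, 5L), collapse = ", "))
  }
  ma <- pmax(a_eel - a_iel, 0)
  ia <- pmax(a_iel - a_lumen, 0)
  r <- function(a) sqrt(pmax(a, 0) / pi)
  mt <- pmax(r(a_eel) - r(a_iel), 0)
  it <- pmax(switch(mode,
                    printed    = r(a_eel) - r(a_lumen),
                    anatomical = r(a_iel) - r(a_lumen)), 0)
  safe_ratio <- function(num, den) ifelse(den > 0, num / den, 0)
  data.frame(a_eel = a_eel, a_iel = a_iel, a_lumen = a_lumen,
             MA = ma, IA = ia, MT = mt, IT = it,
             HRIA = safe_ratio(ia, ia + ma),
             HRIT = safe_ratio(it, it + mt))
}

#' Per-slice morphometry for a cohort or section list
#'
#' Measures the three ring areas of every section with the shoelace
#' formula and derives the six indices via [compute_indices()].
#'
#' @param x A `vessel_cohort`, a list of section records, or a long
#'   contour table (see [as_contour_table()]).
#' @param mode Thickness mode, see [compute_indices()].
#' @param check Validate polygon simplicity per slice (slow; default
#'   `FALSE` for generated cohorts, which are simple by construction).
#' @return `data.table` with `group`, `animal`, `slice` and the index
#'   columns.
#' @export
compute_morphometry <- function(x, mode = c("printed", "anatomical"),
                                check = FALSE) {
  mode <- match.arg(mode)
  sections <- if (inherits(x, "vessel_cohort")) x$sections
              else if (is.data.frame(x)) contour_table_to_sections(x)
              else x
  area3 <- vapply(sections, function(s) c(
    polygon_area(s$contours$eel, check = check),
    polygon_area(s$contours$iel, check = check),
    polygon_area(s$contours$lumen, check = check)), numeric(3L))
  meta <- data.table::data.table(
    group = vapply(sections, `[[`, "", "group"),
    animal = vapply(sections, function(s) as.integer(s$animal), 1L),
    slice = vapply(sections, function(s) as.integer(s$slice), 1L))
  idx <- compute_indices(area3[1L, ], area3[2L, ], area3[3L, ], mode = mode,
                         labels = sprintf("%s/animal %d/slice %d",
                                          meta$group, meta$animal, meta$slice))
  cbind(meta, data.table::as.data.table(idx))
}

#' Aggregate slice-level morphometry to animals and groups
#'
#' Animal value = mean of its slices (slices are repeated measurements of
#' one vessel, not independent replicates); group value = mean +/- sample
#' SD (n-1 denominator) over animals, with n = number of animals.
#'
#' @param records Slice-level table from [compute_morphometry()], or any
#'   table with `group`, `animal` and numeric index columns.
#' @param indices Index columns to aggregate (default the six indices).
#' @return List with `animal` (per-animal means) and `group` (long table:
#'   `group`, `index`, `mean`, `sd`, `n`) `data.table`s.
#' @export
summarize_morphometry <- function(records,
                                  indices = c("MA", "IA", "MT", "IT",
                                              "HRIA", "HRIT")) {
  dt <- data.table::as.data.table(records)
  miss <- setdiff(c("group", "animal", indices), names(dt))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  if (!nrow(dt)) stop("no records to summarize")
  animal <- dt[, lapply(.SD, mean), by = c("group", "animal"),
               .SDcols = indices]
  long <- data.table::melt(animal, id.vars = c("group", "animal"),
                           variable.name = "index", value.name = "value",
                           variable.factor = FALSE)
  grp <- long[, list(mean = mean(value),
                     sd = stats::sd(value),
                     n = .N), by = c("group", "index")]
  list(animal = animal, group = grp)
}
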