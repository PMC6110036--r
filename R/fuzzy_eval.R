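#' Construct a groups-by-criteria evaluation matrix
#'
#' The single-factor fuzzy comprehensive evaluation operates on a
#' judgement set of groups (rows) scored on an evaluation-factor set of
#' criteria (columns), each criterion marked as `cost` (lower is better;
#' hyperplasia ratios are cost criteria) or `benefit`, with nonnegative
#' weights that are normalized to sum to 1.
#'
#' @param values Numeric matrix or data.frame, groups x criteria.
#' @param groups Row (group) labels; defaults to rownames.
#' @param criteria Column (criterion) labels; defaults to colnames.
#' @param directions Per-criterion `"cost"` or `"benefit"` (recycled if
#'   length 1). Default `"cost"`.
#' @param weights Per-criterion nonnegative weights; default equal.
#' @return Object of class `eval_matrix`.
#' @export
#' @examples
#' eval_matrix(rbind(model = c(53, 40), treated = c(24, 20)),
#'             criteria = c("HRIA", "HRIT"))
eval_matrix <- function(values, groups = rownames(values),
                        criteria = colnames(values),
                        directions = "cost", weights = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (nrow(m) < 2L) stop("need at least 2 groups")
  if (ncol(m) < 1L) stop("need at least 1 criterion")
  if (anyNA(m) || any(!is.finite(m))) stop("values must be finite, no missing")
  groups <- groups %||% paste0("group", seq_len(nrow(m)))
  criteria <- criteria %||% paste0("criterion", seq_len(ncol(m)))
  stopifnot(length(groups) == nrow(m), length(criteria) == ncol(m))
  if (length(directions) == 1L) directions <- rep(directions, ncol(m))
  if (!all(directions %in% c("cost", "benefit")))
    stop("directions must be 'cost' or 'benefit'")
  stopifnot(length(directions) == ncol(m))
  weights <- weights %||% rep(1 / ncol(m), ncol(m))
  if (length(weights) != ncol(m) || any(weights < 0) || sum(weights) <= 0)
    stop("weights must be nonnegative and not all zero")
  weights <- weights / sum(weights)
  dimnames(m) <- list(groups, criteria)
  structure(list(values = m, groups = as.character(groups),
                 criteria = as.character(criteria),
                 directions = directions, weights = weights),
            class = "eval_matrix")
}

#' Normalize the columns of an evaluation matrix
#'
#' Schemes:
#' \describe{
#'   \item{`"vector"`}{Each column divided by its Euclidean norm (the
#'     classic TOPSIS normalization). Directions are unchanged.}
#'   \item{`"minmax"`}{Direction-aware affine rescaling: the best value of
#'     each column (minimum for cost, maximum for benefit) maps to 1 and
#'     the worst to 0, so all columns become benefit-oriented. Constant
#'     columns map to 0 with a warning.}
#'   \item{`"none"`}{Pass-through.}
#' }
#'
#' @param matrix An [eval_matrix()].
#' @param scheme `"vector"`, `"minmax"` or `"none"`.
#' @return An `eval_matrix` with normalized values (and, for `"minmax"`,
#'   all directions set to `"benefit"`).
#' @export
topsis_normalize <- function(matrix, scheme = c("vector", "minmax", "none")) {
  stopifnot(inherits(matrix, "eval_matrix"))
  scheme <- match.arg(scheme)
  m <- matrix$values
  if (scheme == "vector") {
    norms <- sqrt(colSums(m^2))
    if (any(norms == 0)) stop("zero-norm column under vector normalization: ",
                              paste(matrix$criteria[norms == 0], collapse = ", "))
    matrix$values <- sweep(m, 2L, norms, "/")
  } else if (scheme == "minmax") {
    out <- m
    for (j in seq_len(ncol(m))) {
      rng <- range(m[, j])
      if (rng[1] == rng[2]) {
        warning("constant criterion '", matrix$criteria[j],
                "' maps to 0 under minmax normalization")
        out[, j] <- 0
      } else if (matrix$directions[j] == "cost") {
        out[, j] <- (rng[2] - m[, j]) / (rng[2] - rng[1])
      } else {
        out[, j] <- (m[, j] - rng[1]) / (rng[2] - rng[1])
      }
    }
    matrix$values <- out
    matrix$directions <- rep("benefit", ncol(m))
  }
  matrix
}

#' Ideal and anti-ideal criterion vectors
#'
#' Per criterion, the ideal value is the best across groups in the
#' criterion's direction (the minimum for cost criteria such as HRIA and
#' HRIT, the maximum for benefit criteria); the anti-ideal is the worst.
#'
#' @param values Numeric groups x criteria matrix (typically normalized
#'   and weighted).
#' @param directions Per-criterion `"cost"`/`"benefit"`.
#' @return List with numeric vectors `ideal` and `anti_ideal`.
#' @export
#' @examples
#' ideal_points(cbind(c(0.2, 0.5, 0.9)), "cost")
ideal_points <- function(values, directions) {
  m <- as.matrix(values)
  if (length(directions) == 1L) directions <- rep(directions, ncol(m))
  stopifnot(length(directions) == ncol(m),
            all(directions %in% c("cost", "benefit")))
  lo <- apply(m, 2L, min); hi <- apply(m, 2L, max)
  cost <- directions == "cost"
  list(ideal = ifelse(cost, lo, hi), anti_ideal = ifelse(cost, hi, lo))
}

#' Closeness grade from the two ideal-point distances
#'
#' The closeness grade (closeness coefficient) of a group with distance
#' `d_plus` to the ideal point and `d_minus` to the anti-ideal point is
#' \deqn{C = \frac{D^-}{D^+ + D^-} \in [0, 1].}
#' A group at the ideal gets 1; a group at the anti-ideal gets 0. This
#' identity holds regardless of the normalization that produced the
#' distances. The degenerate case `d_plus = d_minus = 0` (single-point
#' matrix) is defined as 1 with a warning.
#'
#' @param d_plus,d_minus Nonnegative distances (vectorized).
#' @return Closeness C in `[0, 1]`.
#' @export
#' @examples
#' closeness(0.045, 0.465)  # 0.912 to 3 decimal places
closeness <- function(d_plus, d_minus) {
  stopifnot(length(d_plus) == length(d_minus))
  if (any(d_plus < 0 | d_minus < 0)) stop("distances must be nonnegative")
  tot <- d_plus + d_minus
  out <- ifelse(tot > 0, d_minus / tot, 1)
  if (any(tot == 0)) warning("both distances zero; closeness defined as 1")
  out
}

#' Dense rank in descending order
#'
#' Rank 1 goes to the largest value; tied values share a rank and the next
#' distinct value gets the next consecutive integer.
#'
#' @param x Numeric vector.
#' @return Integer ranks.
#' @export
#' @examples
#' dense_rank_desc(c(1, 0.9, 0.3, 0.3, 0))  # 1 2 3 3 4
dense_rank_desc <- function(x) {
  match(-x, sort(unique(-x)))
}

#' TOPSIS efficacy evaluation of an evaluation matrix
#'
#' Full single-factor fuzzy comprehensive evaluation: normalize, apply
#' criterion weights, locate the ideal and anti-ideal points, measure
#' Euclidean distances \eqn{D^+} and \eqn{D^-} of every group to them,
#' compute the closeness grade \eqn{C = D^-/(D^+ + D^-)} and assign dense
#' ranks in descending C. Ranks are computed on unrounded C; `closeness_3dp`
#' is provided for comparison against published tables. Output rows keep
#' the input group order.
#'
#' @param matrix An [eval_matrix()].
#' @param scheme Normalization scheme, see [topsis_normalize()]. Default
#'   `"vector"`.
#' @return `data.frame` with `group`, `d_plus`, `d_minus`, `closeness`,
#'   `closeness_3dp`, `rank`.
#' @export
#' @examples
#' m <- eval_matrix(rbind(a = c(1, 1), b = c(2, 2), c = c(3, 3)),
#'                  criteria = c("HRIA", "HRIT"))
#' topsis_evaluate(m)  # closeness 1, 0.5, 0
topsis_evaluate <- function(matrix, scheme = c("vector", "minmax", "none")) {
  stopifnot(inherits(matrix, "eval_matrix"))
  scheme <- match.arg(scheme)
  nm <- topsis_normalize(matrix, scheme)
  w <- sweep(nm$values, 2L, nm$weights, "*")
  pts <- ideal_points(w, nm$directions)
  d_plus <- sqrt(rowSums(sweep(w, 2L, pts$ideal, "-")^2))
  d_minus <- sqrt(rowSums(sweep(w, 2L, pts$anti_ideal, "-")^2))
  cc <- closeness(d_plus, d_minus)
  data.frame(group = matrix$groups, d_plus = d_plus, d_minus = d_minus,
             closeness = cc, closeness_3dp = round(cc, 3L),
             rank = dense_rank_desc(cc), row.names = NULL)
}

#' Published nine-group efficacy evaluation (reference worked example)
#'
#' The ideal-point distance pairs (D+, D-), closeness grades and dense
#' ranks published for the nine-group rat balloon-injury efficacy
#' evaluation that this package's synthetic generator emulates (judgement
#' set: model, atorvastatin, single herbs, five herb ratios; evaluation
#' factors: HRIA %, HRIT %). Used as the package's acceptance surface:
#' `closeness(d_plus, d_minus)` must reproduce `c_published` to 3 decimal
#' places, and dense-ranking the closeness values must reproduce
#' `rank_published`, including its 7/7/8 tie.
#'
#' @return `data.frame` with columns `group`, `d_plus`, `d_minus`,
#'   `c_published`, `rank_published`.
#' @export
#' @examples
#' ref <- efficacy_reference()
#' all(round(closeness(ref$d_plus, ref$d_minus), 3) == ref$c_published)
efficacy_reference <- function() {
  path <- system.file("extdata", "efficacy_reference.csv",
                      package = "vesselmorph", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
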