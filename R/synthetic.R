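#' Specification of one experimental group for the synthetic cohort
#'
#' Describes the mean cross-sectional geometry of a vessel and the mean
#' relative protein-expression levels for one group of animals. The geometry
#' is a three-ring model: a (possibly eccentric) lumen, the internal elastic
#' lamina (IEL) at `lumen + intima thickness`, and the external elastic
#' lamina (EEL) at `lumen + intima + media thickness`. All lengths are in
#' micrometres.
#'
#' @param label Group label (unique within a cohort).
#' @param n_animals Number of animals (>= 1).
#' @param lumen_radius_mean Mean lumen radius, um (> 0).
#' @param intima_thickness_mean Mean intimal thickness, um (>= 0; an
#'   uninjured vessel has a single-cell intima, modelled as 0).
#' @param media_thickness_mean Mean medial thickness, um (> 0).
#' @param eccentricity Lumen-centre offset as a fraction of the intimal
#'   annulus width, in `[0, 1)`. 0 gives concentric stenosis, larger values
#'   eccentric stenosis.
#' @param cv Coefficient of variation of the lognormal biological noise
#'   applied to the geometric parameters (>= 0, dimensionless).
#' @param expression_effects Named numeric vector: mean relative expression
#'   level per protein (1 = reference/normal level).
#'
#' @return An object of class `group_spec`.
#' @export
#' @examples
#' group_spec("model", 8, lumen_radius_mean = 250,
#'            intima_thickness_mean = 120, media_thickness_mean = 80,
#'            eccentricity = 0.5)
group_spec <- function(label, n_animals = 8,
                       lumen_radius_mean = 300,
                       intima_thickness_mean = 0,
                       media_thickness_mean = 80,
                       eccentricity = 0,
                       cv = 0.1,
                       expression_effects = c(pcna = 1, sma_actin = 1)) {
  stopifnot(is.character(label), length(label) == 1L, nzchar(label))
  n_animals <- as.integer(n_animals)
  if (is.na(n_animals) || n_animals < 1L) stop("n_animals must be >= 1")
  if (!is.numeric(lumen_radius_mean) || lumen_radius_mean <= 0)
    stop("lumen_radius_mean must be > 0")
  if (!is.numeric(intima_thickness_mean) || intima_thickness_mean < 0)
    stop("intima_thickness_mean must be >= 0")
  if (!is.numeric(media_thickness_mean) || media_thickness_mean <= 0)
    stop("media_thickness_mean must be > 0")
  if (!is.numeric(eccentricity) || eccentricity < 0 || eccentricity >= 1)
    stop("eccentricity must be in [0, 1)")
  if (!is.numeric(cv) || cv < 0) stop("cv must be >= 0")
  if (length(expression_effects) &&
      (is.null(names(expression_effects)) || any(!nzchar(names(expression_effects)))))
    stop("expression_effects must be a named numeric vector")
  structure(
    list(label = label, n_animals = n_animals,
         lumen_radius_mean = lumen_radius_mean,
         intima_thickness_mean = intima_thickness_mean,
         media_thickness_mean = media_thickness_mean,
         eccentricity = eccentricity, cv = cv,
         expression_effects = expression_effects),
    class = "group_spec")
}

#' Cohort configuration for the synthetic study
#'
#' Bundles the per-group specifications with the sampling design: number of
#' cross-sections ("slices") measured per vessel and number of microscope
#' fields measured per slice for immunohistochemistry.
#'
#' @param groups List of [group_spec()] objects with unique labels.
#' @param slices_per_vessel Slices cut per vessel (default 8).
#' @param fields_per_slice IHC fields measured per slice (default 3).
#' @param seed Integer root seed for all randomness.
#' @param n_vertices Vertices per contour polygon (default 128; the area
#'   error of a regular 128-gon relative to its circumscribing circle is
#'   below 0.05%).
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(groups, slices_per_vessel = 8L,
                          fields_per_slice = 3L, seed = 1L,
                          n_vertices = 128L) {
  if (!length(groups) || !all(vapply(groups, inherits, TRUE, "group_spec")))
    stop("groups must be a non-empty list of group_spec objects")
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("duplicate group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  slices_per_vessel <- as.integer(slices_per_vessel)
  fields_per_slice <- as.integer(fields_per_slice)
  n_vertices <- as.integer(n_vertices)
  stopifnot(slices_per_vessel >= 1L, fields_per_slice >= 1L, n_vertices >= 8L)
  structure(
    list(groups = stats::setNames(groups, labels),
         slices_per_vessel = slices_per_vessel,
         fields_per_slice = fields_per_slice,
         seed = as.integer(seed), n_vertices = n_vertices),
    class = "cohort_config")
}

#' Default nine-group balloon-injury cohort
#'
#' Emulates the design of the rat study the package models: a normal
#' (sham) group, an untreated balloon-injury model group, single-herb
#' Astragalus and Angelica groups, five Astragalus-Angelica ratio groups
#' (1:2, 1:5, 1:1, 5:1, 2:1) and an atorvastatin positive-control group,
#' with 8 animals per group, 8 slices per vessel and 3 IHC fields per
#' slice.
#'
#' Geometric defaults (um): media thickness 80 in every group (medial
#' indices do not separate groups); lumen radius 350 in the normal group,
#' 250 in the model group (stenosis), 300 under treatment; intimal
#' thickness 0 (normal), 130 (model), and strictly ordered over treatments
#' from 21 (ratio 1:1, strongest effect) to 88 (ratio 2:1, weakest). The
#' thickness grid is spaced so that group-mean HRIA steps by ~0.04 per
#' rank over an 0.18-0.55 span (model ~0.55, best treatment ~0.18), which
#' at cv = 0.1 and n = 8 keeps adjacent groups >= ~2.5 SE apart so the
#' configured order is recoverable (see the methods vignette for the
#' variance budget). The configured efficacy order (by increasing intimal
#' thickness) is `aa-1:1 < atorvastatin < aa-1:2 < aa-1:5 < angelica <
#' aa-5:1 < astragalus < aa-2:1 < model`.
#'
#' Expression defaults emulate a proliferation marker (`pcna`, raised ~2x
#' in the model group) and a contractile-phenotype marker (`sma_actin`,
#' halved in the model group), with treatment groups interpolated toward
#' normal in proportion to their intimal effect.
#'
#' @param n_animals Animals per group (default 8).
#' @param cv Biological coefficient of variation (default 0.1).
#' @param seed Root seed.
#' @return A [cohort_config()] object.
#' @export
#' @examples
#' cfg <- default_cohort_config(seed = 42)
#' names(cfg$groups)
default_cohort_config <- function(n_animals = 8L, cv = 0.1, seed = 1L) {
  intima <- c(
    "normal" = 0, "model" = 130, "astragalus" = 74, "angelica" = 51,
    "aa-1:2" = 34, "aa-1:5" = 42, "aa-1:1" = 21, "aa-5:1" = 62,
    "aa-2:1" = 88, "atorvastatin" = 27)
  lumen <- c(
    "normal" = 350, "model" = 250, "astragalus" = 300, "angelica" = 300,
    "aa-1:2" = 300, "aa-1:5" = 300, "aa-1:1" = 300, "aa-5:1" = 300,
    "aa-2:1" = 300, "atorvastatin" = 300)
  ecc <- c(
    "normal" = 0, "model" = 0.5, "astragalus" = 0.3, "angelica" = 0.3,
    "aa-1:2" = 0.3, "aa-1:5" = 0.3, "aa-1:1" = 0.3, "aa-5:1" = 0.3,
    "aa-2:1" = 0.3, "atorvastatin" = 0.3)
  # expression interpolated between normal (1x) and model level by the
  # severity of the residual intimal response
  severity <- intima / intima[["model"]]
  groups <- lapply(names(intima), function(g) {
    group_spec(
      label = g, n_animals = n_animals,
      lumen_radius_mean = lumen[[g]],
      intima_thickness_mean = intima[[g]],
      media_thickness_mean = 80,
      eccentricity = ecc[[g]], cv = cv,
      expression_effects = c(
        pcna = 1 + 1.0 * severity[[g]],       # model ~2x normal
        sma_actin = 1 - 0.5 * severity[[g]])) # model ~0.5x normal
  })
  cohort_config(groups, slices_per_vessel = 8L, fields_per_slice = 3L,
                seed = seed)
}

#' Generate one synthetic vessel cross-section
#'
#' Draws section-level geometry (lumen radius, intimal and medial
#' thickness) as lognormal perturbations of the group means at the group's
#' `cv`, then builds three nested star-shaped polygons with small
#' vertex-level multiplicative jitter (at `cv / 5`; full-strength vertex
#' noise would destroy ring nesting for thin intimas). The lumen centre is
#' offset from the vessel axis by `eccentricity * intimal thickness`.
#' Nesting is enforced by truncating offending vertex radii at a small
#' positive floor; the return value records whether any truncation fired.
#'
#' Uses the current R random-number state; seed upstream (e.g. via
#' [generate_cohort()] or `set.seed()`).
#'
#' @param spec A [group_spec()].
#' @param n_vertices Vertices per ring polygon (default 128).
#' @return An object of class `contour_set`: list with `eel`, `iel`,
#'   `lumen` (each an `n_vertices x 2` matrix of x/y in um, implicitly
#'   closed), and `floor_applied` (logical).
#' @export
#' @examples
#' set.seed(1)
#' cs <- generate_section(group_spec("model", intima_thickness_mean = 120,
#'                                   lumen_radius_mean = 250))
#' polygon_area(cs$lumen) < polygon_area(cs$iel)
generate_section <- function(spec, n_vertices = 128L) {
  stopifnot(inherits(spec, "group_spec"))
  n <- as.integer(n_vertices)
  theta <- 2 * pi * (seq_len(n) - 1L) / n
  floor_um <- 0.5  # minimal physical gap between adjacent rings, um

  r_l <- spec$lumen_radius_mean * lognormal_multiplier(1L, spec$cv)
  t_i <- if (spec$intima_thickness_mean > 0)
    spec$intima_thickness_mean * lognormal_multiplier(1L, spec$cv) else 0
  t_m <- spec$media_thickness_mean * lognormal_multiplier(1L, spec$cv)
  t_m <- max(t_m, floor_um)

  cv_v <- spec$cv / 5
  eel_r <- (r_l + t_i + t_m) * lognormal_multiplier(n, cv_v)
  iel_r <- (r_l + t_i) * lognormal_multiplier(n, cv_v)

  floored <- FALSE
  # media: IEL strictly inside EEL
  bad <- iel_r > eel_r - floor_um
  if (any(bad)) { iel_r[bad] <- eel_r[bad] - floor_um; floored <- TRUE }
  if (t_i == 0) {
    # no hyperplasia: the lumen boundary is the IEL itself
    lum_r <- iel_r
    offset <- 0
  } else {
    # intima: lumen (offset centre) strictly inside IEL
    lum_r <- r_l * lognormal_multiplier(n, cv_v)
    offset <- spec$eccentricity * t_i
    cap <- min(iel_r) - offset - floor_um
    bad <- lum_r > cap
    if (any(bad)) { lum_r[bad] <- cap; floored <- TRUE }
  }

  ring <- function(r, cx = 0) cbind(x = cx + r * cos(theta), y = r * sin(theta))
  structure(
    list(eel = ring(eel_r), iel = ring(iel_r), lumen = ring(lum_r, offset),
         floor_applied = floored),
    class = "contour_set")
}

#' Generate a full synthetic cohort of vessel cross-sections
#'
#' For every animal, a lognormal animal-level random effect (at the group
#' `cv`) scales the three geometric means; individual slices then vary
#' around the animal's geometry at `cv / 2`. Output is deterministic for a
#' fixed config and seed.
#'
#' @param config A [cohort_config()].
#' @return An object of class `vessel_cohort`: list with `sections` (list
#'   of records: `group`, `animal`, `slice`, `contours` ([generate_section()]
#'   output)), `truth` (per-group generating parameters, the recovery-test
#'   sidecar) and `config`.
#' @export
#' @examples
#' cfg <- default_cohort_config(n_animals = 2, seed = 7)
#' coh <- generate_cohort(cfg)
#' length(coh$sections)  # 10 groups x 2 animals x 8 slices
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sections <- vector("list",
    sum(vapply(config$groups, `[[`, 1L, "n_animals")) * config$slices_per_vessel)
  k <- 0L
  for (spec in config$groups) {
    for (animal in seq_len(spec$n_animals)) {
      mult <- lognormal_multiplier(3L, spec$cv)
      aspec <- spec
      aspec$lumen_radius_mean <- spec$lumen_radius_mean * mult[1]
      aspec$intima_thickness_mean <- spec$intima_thickness_mean * mult[2]
      aspec$media_thickness_mean <- spec$media_thickness_mean * mult[3]
      aspec$cv <- spec$cv / 2
      for (slice in seq_len(config$slices_per_vessel)) {
        k <- k + 1L
        sections[[k]] <- list(
          group = spec$label, animal = animal, slice = slice,
          contours = generate_section(aspec, config$n_vertices))
      }
    }
  }
  truth <- lapply(config$groups, function(s)
    s[c("n_animals", "lumen_radius_mean", "intima_thickness_mean",
        "media_thickness_mean", "eccentricity", "cv", "expression_effects")])
  structure(list(sections = sections, truth = truth, config = config),
            class = "vessel_cohort")
}

#' Flatten a cohort's contours to a long vertex table
#'
#' @param cohort A [generate_cohort()] result.
#' @return A `data.table` with columns `group`, `animal`, `slice`, `ring`
#'   (`EEL`, `IEL`, `LUMEN`), `vertex_index`, `x_um`, `y_um`.
#' @export
as_contour_table <- function(cohort) {
  stopifnot(inherits(cohort, "vessel_cohort"))
  rings <- c(eel = "EEL", iel = "IEL", lumen = "LUMEN")
  out <- lapply(cohort$sections, function(s) {
    data.table::rbindlist(lapply(names(rings), function(r) {
      m <- s$contours[[r]]
      data.table::data.table(
        group = s$group, animal = s$animal, slice = s$slice,
        ring = rings[[r]], vertex_index = seq_len(nrow(m)),
        x_um = m[, 1], y_um = m[, 2])
    }))
  })
  data.table::rbindlist(out)
}

#' Rebuild a section list from a long vertex table
#'
#' Inverse of [as_contour_table()]; accepts any table with the same
#' columns (e.g. read from CSV with [data.table::fread()]).
#'
#' @param tab Long contour table.
#' @return List of section records as in a `vessel_cohort`.
#' @export
contour_table_to_sections <- function(tab) {
  tab <- data.table::as.data.table(tab)
  need <- c("group", "animal", "slice", "ring", "vertex_index", "x_um", "y_um")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("contour table lacks columns: ",
                         paste(miss, collapse = ", "))
  keys <- unique(tab[, c("group", "animal", "slice")])
  lapply(seq_len(nrow(keys)), function(i) {
    sub <- tab[keys[i], on = c("group", "animal", "slice")]
    get_ring <- function(r) {
      m <- sub[sub$ring == r, ][order(vertex_index)]
      if (!nrow(m)) stop("missing ring ", r, " for slice ",
                         paste(unlist(keys[i]), collapse = "/"))
      cbind(x = m$x_um, y = m$y_um)
    }
    list(group = keys$group[i], animal = keys$animal[i],
         slice = keys$slice[i],
         contours = structure(list(eel = get_ring("EEL"),
                                   iel = get_ring("IEL"),
                                   lumen = get_ring("LUMEN"),
                                   floor_applied = NA),
                              class = "contour_set"))
  })
}

#' Generate synthetic densitometry (IHC and Western blot) tables
#'
#' Per animal and protein: one Western-blot record, with beta-actin
#' reference IOD drawn lognormally around 10000 and target IOD equal to
#' `effect x reference x lognormal(cv)`; and `fields_per_slice` IHC field
#' IODs per slice around `effect x 1000`, with an animal-level lognormal
#' effect (at `cv`) shared across that animal's measurements. All IODs are
#' strictly positive by construction.
#'
#' @param config A [cohort_config()].
#' @param proteins Protein labels to simulate; default all labels present
#'   in the groups' `expression_effects`. Unknown labels are an error.
#' @return `data.table` with columns `protein`, `group`, `animal`, `kind`
#'   (`IHC`/`WB`), `slice`, `field_or_band`, `iod`, `reference_iod` (NA for
#'   IHC rows).
#' @export
generate_densitometry <- function(config, proteins = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  known <- unique(unlist(lapply(config$groups,
                                function(s) names(s$expression_effects))))
  proteins <- proteins %||% known
  unknown <- setdiff(proteins, known)
  if (length(unknown))
    stop("unknown protein label(s): ", paste(unknown, collapse = ", "))
  set.seed(config$seed + 1000L)  # densitometry substream
  out <- list()
  for (spec in config$groups) {
    miss <- setdiff(proteins, names(spec$expression_effects))
    if (length(miss))
      stop("group '", spec$label, "' lacks expression_effects for: ",
           paste(miss, collapse = ", "))
    for (animal in seq_len(spec$n_animals)) {
      for (p in proteins) {
        eff <- spec$expression_effects[[p]] * lognormal_multiplier(1L, spec$cv)
        ref <- 10000 * lognormal_multiplier(1L, spec$cv)
        wb <- data.table::data.table(
          protein = p, group = spec$label, animal = animal, kind = "WB",
          slice = NA_integer_, field_or_band = 1L,
          iod = eff * ref * lognormal_multiplier(1L, spec$cv),
          reference_iod = ref)
        nf <- config$fields_per_slice
        ihc <- data.table::data.table(
          protein = p, group = spec$label, animal = animal, kind = "IHC",
          slice = rep(seq_len(config$slices_per_vessel), each = nf),
          field_or_band = rep(seq_len(nf), config$slices_per_vessel),
          iod = 1000 * eff *
            lognormal_multiplier(nf * config$slices_per_vessel, spec$cv),
          reference_iod = NA_real_)
        out[[length(out) + 1L]] <- rbind(wb, ihc)
      }
    }
  }
  data.table::rbindlist(out)
}

#' Write a cohort to disk as plain-text artifacts
#'
#' Writes `contours.csv` (long vertex table) and `truth.json` (the
#' generating parameters per group).
#'
#' @param cohort A `vessel_cohort`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "vessel_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  contours <- file.path(dir, "contours.csv")
  truth <- file.path(dir, "truth.json")
  data.table::fwrite(as_contour_table(cohort), contours)
  jsonlite::write_json(cohort$truth, truth, auto_unbox = TRUE, digits = NA)
  invisible(c(contours = contours, truth = truth))
}
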