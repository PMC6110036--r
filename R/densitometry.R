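#' Immunohistochemistry expression intensity for one record
#'
#' The expression intensity of a stained field set is the mean of its
#' integrated optical density (IOD) values.
#'
#' @param iod_values Positive IOD values for the fields of one slice (or
#'   any pooled set of fields).
#' @return Mean IOD, dimensionless.
#' @export
#' @examples
#' ihc_expression(c(10, 20, 30))  # 20
ihc_expression <- function(iod_values) {
  if (!length(iod_values)) stop("empty IOD field list")
  if (any(!is.finite(iod_values) | iod_values <= 0))
    stop("IOD values must be positive and finite")
  mean(iod_values)
}

#' Western-blot relative expression for one band
#'
#' Relative expression is the ratio of the target-band IOD to the
#' beta-actin (loading-control) band IOD of the same lane, which makes the
#' measure invariant to common exposure rescaling.
#'
#' @param target_iod Target band IOD (> 0).
#' @param reference_iod Beta-actin band IOD (> 0).
#' @return Relative expression, dimensionless.
#' @export
#' @examples
#' wb_relative_expression(50, 100)  # 0.5
wb_relative_expression <- function(target_iod, reference_iod) {
  if (any(!is.finite(reference_iod) | reference_iod <= 0))
    stop("reference IOD must be positive")
  if (any(!is.finite(target_iod) | target_iod <= 0))
    stop("target IOD must be positive")
  target_iod / reference_iod
}

#' Animal- and group-level expression summaries from a densitometry table
#'
#' For `WB` rows the animal value is the band's relative expression
#' (target / beta-actin). For `IHC` rows the animal value is the mean over
#' its slice-level means (each slice's value being the mean of its field
#' IODs), mirroring the slice-then-animal aggregation of the morphometry
#' module. Group values are mean +/- sample SD over animals. No hypothesis
#' testing happens here; feed the `animal` table to the group-stats
#' module.
#'
#' @param records Table as produced by [generate_densitometry()] (columns
#'   `protein`, `group`, `animal`, `kind`, `slice`, `field_or_band`,
#'   `iod`, `reference_iod`).
#' @return List with `animal` (`protein`, `kind`, `group`, `animal`,
#'   `value`) and `group` (`protein`, `kind`, `group`, `mean`, `sd`, `n`)
#'   `data.table`s.
#' @export
summarize_densitometry <- function(records) {
  dt <- data.table::as.data.table(records)
  need <- c("protein", "group", "animal", "kind", "iod")
  miss <- setdiff(need, names(dt))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  wb <- dt[dt$kind == "WB", ]
  ihc <- dt[dt$kind == "IHC", ]
  parts <- list()
  if (nrow(wb)) {
    parts$wb <- wb[, list(value = wb_relative_expression(iod, reference_iod)),
                   by = c("protein", "kind", "group", "animal")]
  }
  if (nrow(ihc)) {
    per_slice <- ihc[, list(value = ihc_expression(iod)),
                     by = c("protein", "kind", "group", "animal", "slice")]
    parts$ihc <- per_slice[, list(value = mean(value)),
                           by = c("protein", "kind", "group", "animal")]
  }
  animal <- data.table::rbindlist(parts)
  if (!nrow(animal)) stop("no WB or IHC records found")
  grp <- animal[, list(mean = mean(value), sd = stats::sd(value), n = .N),
                by = c("protein", "kind", "group")]
  list(animal = animal, group = grp)
}
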