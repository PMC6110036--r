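#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA on animal-level values, computed
#' directly from sums of squares (equivalent to
#' `stats::oneway.test(..., var.equal = TRUE)` but cheap enough for
#' simulation loops).
#'
#' @param values Numeric vector of observations, or a named list of
#'   per-group numeric vectors (in which case `groups` is ignored).
#' @param groups Group label per observation.
#' @return List with `f`, `p_value`, `df_between`, `df_within`,
#'   `ms_within`, `n_total` and `flag` (`"ok"`, or `"zero-within-variance"`
#'   when groups separate perfectly so F diverges, or `"degenerate"` when
#'   every value in every group is identical and F is undefined).
#' @export
#' @examples
#' one_way_anova(list(a = c(1, 2, 3), b = c(4, 5, 6)))
one_way_anova <- function(values, groups = NULL) {
  if (is.list(values)) {
    groups <- rep(names(values) %||% seq_along(values),
                  lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  stopifnot(length(values) == length(groups))
  ok <- is.finite(values)
  values <- values[ok]; groups <- as.character(groups)[ok]
  ns <- table(groups)
  if (length(ns) < 2L) stop("need at least 2 groups")
  if (any(ns < 2L)) stop("each group needs at least 2 values")
  n <- length(values); k <- length(ns)
  gm <- tapply(values, groups, mean)
  ssb <- sum(ns * (gm[names(ns)] - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1L; df2 <- n - k
  msb <- ssb / df1; msw <- ssw / df2
  if (ssw == 0 && ssb == 0) {
    return(list(f = NaN, p_value = NaN, df_between = df1, df_within = df2,
                ms_within = 0, n_total = n, flag = "degenerate"))
  }
  if (ssw == 0) {
    return(list(f = Inf, p_value = 0, df_between = df1, df_within = df2,
                ms_within = 0, n_total = n, flag = "zero-within-variance"))
  }
  f <- msb / msw
  list(f = f, p_value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df_between = df1, df_within = df2, ms_within = msw, n_total = n,
       flag = "ok")
}

#' Significance tier of a p value
#'
#' Maps a p value to the two-tier star convention used in the study's
#' figures: `"ns"`, `"p<0.05"` or `"p<0.01"`.
#'
#' @param p Numeric p values.
#' @return Character vector of tiers.
#' @export
p_tier <- function(p) {
  ifelse(p < 0.01, "p<0.01", ifelse(p < 0.05, "p<0.05", "ns"))
}

#' Pairwise comparisons of every group against a reference group
#'
#' Two-sided post-hoc comparisons versus a designated reference group
#' (normal, model or positive control), with the two-tier significance
#' convention. Methods:
#' \describe{
#'   \item{`"lsd"`}{Fisher's least significant difference: t statistics on
#'     the pooled within-group variance from the omnibus ANOVA, df = N - k.
#'     Default; reproduces the classic SPSS-style star pattern.}
#'   \item{`"welch"`}{Pairwise Welch t tests (no pooling).}
#' }
#' No multiplicity correction is applied across factors or proteins,
#' matching the source study's reporting convention.
#'
#' @param values Numeric vector of animal-level values, or named list of
#'   per-group vectors.
#' @param groups Group label per observation (ignored for list input).
#' @param reference Label of the reference group.
#' @param method `"lsd"` (default) or `"welch"`.
#' @return `data.frame` with `group`, `reference`, `estimate` (group mean
#'   minus reference mean), `p_value`, `tier` — one row per non-reference
#'   group.
#' @export
pairwise_vs_reference <- function(values, groups = NULL, reference,
                                  method = c("lsd", "welch")) {
  method <- match.arg(method)
  if (is.list(values)) {
    groups <- rep(names(values) %||% seq_along(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  groups <- as.character(groups)
  if (!reference %in% groups)
    stop("reference group '", reference, "' not present in data")
  labs <- setdiff(unique(groups), reference)
  ref_v <- values[groups == reference]
  if (method == "lsd") {
    aov <- one_way_anova(values, groups)
    if (aov$flag == "degenerate")
      stop("all values identical; comparisons undefined")
  }
  rows <- lapply(labs, function(g) {
    gv <- values[groups == g]
    est <- mean(gv) - mean(ref_v)
    if (method == "lsd") {
      if (aov$ms_within == 0) {
        p <- if (est == 0) 1 else 0
      } else {
        se <- sqrt(aov$ms_within * (1 / length(gv) + 1 / length(ref_v)))
        p <- 2 * stats::pt(abs(est / se), aov$df_within, lower.tail = FALSE)
      }
    } else {
      p <- stats::t.test(gv, ref_v)$p.value
    }
    data.frame(group = g, reference = reference, estimate = est,
               p_value = p, tier = p_tier(p))
  })
  do.call(rbind, rows)
}

#' Comparisons of one factor against several reference groups
#'
#' Convenience wrapper running [pairwise_vs_reference()] once per
#' reference (the study compares each group against the normal, model and
#' atorvastatin groups).
#'
#' @inheritParams pairwise_vs_reference
#' @param references Character vector of reference labels.
#' @return Row-bound `data.frame` of all comparisons.
#' @export
compare_vs_references <- function(values, groups = NULL,
                                  references = c("normal", "model",
                                                 "atorvastatin"),
                                  method = c("lsd", "welch")) {
  method <- match.arg(method)
  do.call(rbind, lapply(references, function(r)
    pairwise_vs_reference(values, groups, reference = r, method = method)))
}
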