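#' Two-factor interaction model for knockdown / drug viability
#'
#' Models viability from a 2x2 factorial design (e.g. siRNA x drug, or
#' NAC x drug) as
#' `w = w0 + dw_a * [a on] + dw_b * [b on] + dw_inter * [both on]`,
#' i.e. a saturated two-factor linear model under treatment coding with
#' the both-off cell as reference, so each printed delta reads directly as
#' a departure from baseline. Normal-theory p-values and 95% confidence
#' intervals come from the fitted linear model. An optional time-point
#' column can be pooled (default, as when 24 h and 48 h experiments are
#' collected) or included as a blocking covariate.
#'
#' @param table data.frame with columns `replicate`, `factor_a`,
#'   `factor_b` (each `"off"`/`"on"`), `viability_ratio`, and optionally
#'   `timepoint_h`.
#' @param pool_timepoints if `FALSE` and `timepoint_h` is present, adjust
#'   for time point as an additive block.
#' @return List of class `factorial_fit`: `w0`, `d_a`, `d_b`, `d_inter`,
#'   `se`, `ci` (rows = terms), `p`, `cell_means`, `n_per_cell`, `model`.
#' @export
factorial_interaction_lm <- function(table, pool_timepoints = TRUE) {
  need <- c("replicate", "factor_a", "factor_b", "viability_ratio")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("factorial table missing column(s): ", paste(miss, collapse = ", "))
  fa <- factor(table$factor_a, levels = c("off", "on"))
  fb <- factor(table$factor_b, levels = c("off", "on"))
  if (any(is.na(fa)) || any(is.na(fb)))
    stop("factor_a/factor_b must be 'off' or 'on'")
  cells <- table(fa, fb)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)[1, ]
    stop(sprintf("missing design cell: factor_a=%s, factor_b=%s",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  if (any(cells < 2)) stop("every design cell needs >= 2 replicates")

  dat <- data.frame(w = table$viability_ratio, fa = fa, fb = fb)
  use_block <- !pool_timepoints && "timepoint_h" %in% names(table)
  if (use_block) dat$tp <- factor(table$timepoint_h)
  fit <- if (use_block) stats::lm(w ~ tp + fa * fb, data = dat)
         else stats::lm(w ~ fa * fb, data = dat)
  cf <- suppressWarnings(summary(fit))$coefficients
  terms <- c("(Intercept)", "faon", "fbon", "faon:fbon")
  ci <- suppressWarnings(stats::confint(fit))[terms, , drop = FALSE]
  est <- cf[terms, "Estimate"]
  cm <- tapply(dat$w, list(dat$fa, dat$fb), mean)
  structure(list(
    w0 = unname(est[1]), d_a = unname(est[2]), d_b = unname(est[3]),
    d_inter = unname(est[4]),
    se = stats::setNames(cf[terms, "Std. Error"],
                         c("w0", "d_a", "d_b", "d_inter")),
    ci = ci, p = stats::setNames(cf[terms, "Pr(>|t|)"],
                                 c("w0", "d_a", "d_b", "d_inter")),
    cell_means = cm, n_per_cell = cells, model = fit),
    class = "factorial_fit")
}

#' Nonparametric comparison of normalized response ratios
#'
#' Mann-Whitney (two-sample Wilcoxon rank-sum) test on normalized
#' phenotype ratios (`Y_treated / Y_control`). The exact distribution is
#' used for tie-free samples with combined n <= 20; otherwise the normal
#' approximation with tie correction and continuity correction. If every
#' value across both groups is tied the comparison is vacuous: p = 1 with
#' a flag.
#'
#' @param group_a,group_b numeric ratio vectors, each of length >= 3.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `U` (rank-sum statistic for `group_a`), `p`,
#'   `exact` and `flag`.
#' @export
ratio_comparison <- function(group_a, group_b,
                             alternative = c("two.sided", "less",
                                             "greater")) {
  alternative <- match.arg(alternative)
  stopifnot(all(is.finite(group_a)), all(is.finite(group_b)))
  if (length(group_a) < 3 || length(group_b) < 3)
    stop("each group needs n >= 3")
  all_vals <- c(group_a, group_b)
  if (length(unique(all_vals)) == 1)
    return(list(U = length(group_a) * length(group_b) / 2, p = 1,
                exact = FALSE, flag = "all_tied"))
  exact <- length(all_vals) <= 20 && !any(duplicated(all_vals))
  ht <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = alternative,
                       exact = exact, correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact,
       flag = NULL)
}
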