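#' DNA-content histograms from per-nucleus intensities
#'
#' Integrated DNA-stain (e.g. Hoechst) intensity per nucleus is binned to
#' `n_bins` equal-width intensity levels. Bin edges are shared across all
#' doses of a culture (the per-culture intensity range) so histograms at
#' different doses are directly comparable; `range_policy = "global"`
#' shares edges across every culture instead, and `"group"` uses each
#' (culture, dose) group's own range.
#'
#' @param table data.frame with columns `culture_id, dose_uM, well_id,
#'   integrated_intensity` (positive finite intensities).
#' @param n_bins number of intensity levels (default 100).
#' @param range_policy `"culture"` (default), `"global"` or `"group"`.
#' @return A list of `dna_histogram` objects (one per culture x dose),
#'   each with `culture_id`, `dose_uM`, `breaks` (`n_bins + 1` edges) and
#'   `counts` (`n_bins` integers summing to the group's nucleus count).
#' @export
bin_intensities <- function(table, n_bins = 100,
                            range_policy = c("culture", "global", "group")) {
  range_policy <- match.arg(range_policy)
  check_nucleus_table(table)
  split_key <- interaction(table$culture_id, table$dose_uM, drop = TRUE)
  groups <- split(table, split_key)
  global_rng <- range(table$integrated_intensity)
  out <- lapply(groups, function(g) {
    rng <- switch(range_policy,
      global = global_rng,
      culture = range(table$integrated_intensity[
        table$culture_id == g$culture_id[1]]),
      group = range(g$integrated_intensity))
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)   # all-equal degenerate
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    idx <- findInterval(g$integrated_intensity, breaks,
                        rightmost.closed = TRUE, all.inside = TRUE)
    counts <- tabulate(idx, nbins = n_bins)
    structure(list(culture_id = g$culture_id[1], dose_uM = g$dose_uM[1],
                   breaks = breaks, counts = counts),
              class = "dna_histogram")
  })
  names(out) <- names(groups)
  out
}

check_nucleus_table <- function(table) {
  need <- c("culture_id", "dose_uM", "well_id", "integrated_intensity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("nucleus table missing column(s): ", paste(miss, collapse = ", "))
  v <- table$integrated_intensity
  if (any(!is.finite(v) | v <= 0))
    stop("integrated intensities must be positive and finite")
  invisible(table)
}

#' Gate nuclei into G1 / S / G2M by DNA content
#'
#' Assigns each nucleus to a cell-cycle phase by its integrated DNA-stain
#' intensity relative to the G1 peak: cells in G2/M carry twice the G1 DNA
#' content and S-phase cells lie in between. With `gates = "auto"` the G1
#' mode `m` is located as the peak of a 100-bin histogram and the default
#' gates are G1 = [0.75m, 1.3m), S = [1.3m, 1.7m), G2M = [1.7m, 2.5m] —
#' a stated stand-in for manually placed gates, which remain the primary
#' path via an explicit `gates` list. Fractions are normalized over gated
#' nuclei; out-of-gate nuclei are counted and excluded.
#'
#' @param intensities positive numeric vector of integrated intensities.
#' @param gates `"auto"` or a list with numeric `G1`, `S`, `G2M` intervals
#'   `c(lo, hi)`, non-overlapping and ordered.
#' @param n_bins histogram bins used for auto peak finding.
#' @return List of class `phase_fractions`: `f_G1`, `f_S`, `f_G2M`
#'   (summing to 1), `gates`, `n_total`, `n_outside`.
#' @export
gate_phases <- function(intensities, gates = "auto", n_bins = 100) {
  if (any(!is.finite(intensities) | intensities <= 0))
    stop("intensities must be positive and finite")
  if (length(intensities) < 50)
    stop("need at least 50 nuclei for phase gating")
  if (identical(gates, "auto")) gates <- auto_gates(intensities, n_bins)
  check_gates(gates)
  in_g1 <- intensities >= gates$G1[1] & intensities < gates$G1[2]
  in_s <- intensities >= gates$S[1] & intensities < gates$S[2]
  in_g2 <- intensities >= gates$G2M[1] & intensities <= gates$G2M[2]
  n_gated <- sum(in_g1) + sum(in_s) + sum(in_g2)
  if (n_gated == 0) stop("no nuclei fall inside the gates")
  structure(list(f_G1 = sum(in_g1) / n_gated, f_S = sum(in_s) / n_gated,
                 f_G2M = sum(in_g2) / n_gated, gates = gates,
                 n_total = length(intensities),
                 n_outside = length(intensities) - n_gated),
            class = "phase_fractions")
}

check_gates <- function(gates) {
  if (!is.list(gates) || !all(c("G1", "S", "G2M") %in% names(gates)))
    stop("gates must be a list with G1, S and G2M intervals")
  g <- rbind(gates$G1, gates$S, gates$G2M)
  if (any(g[, 2] <= g[, 1])) stop("each gate must have lo < hi")
  if (g[1, 2] > g[2, 1] || g[2, 2] > g[3, 1])
    stop("gates must be ordered G1 < S < G2M and non-overlapping")
  invisible(gates)
}

## locate the G1 mode as the tallest histogram bin; error if a second,
## well-separated local maximum comes within 10% of the peak height
auto_gates <- function(intensities, n_bins = 100, min_sep_bins = 10) {
  rng <- range(intensities)
  if (diff(rng) == 0) {
    m <- rng[1]
  } else {
    breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
    idx <- findInterval(intensities, breaks, rightmost.closed = TRUE,
                        all.inside = TRUE)
    counts <- tabulate(idx, nbins = n_bins)
    mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
    is_peak <- vapply(seq_along(counts), function(i) {
      lo <- max(1, i - 2); hi <- min(n_bins, i + 2)
      counts[i] == max(counts[lo:hi]) && counts[i] > 0
    }, logical(1))
    peaks <- which(is_peak)
    top <- peaks[which.max(counts[peaks])]
    rival <- peaks[abs(peaks - top) >= min_sep_bins]
    if (length(rival) && max(counts[rival]) >= 0.9 * counts[top])
      stop("ambiguous G1 peak (two comparable modes); supply manual gates")
    m <- mids[top]
  }
  list(G1 = c(0.75 * m, 1.3 * m), S = c(1.3 * m, 1.7 * m),
       G2M = c(1.7 * m, 2.5 * m))
}

#' Phase fractions for every culture and dose
#'
#' Convenience wrapper applying [gate_phases()] across a nucleus table.
#' With `gates = "auto"` the gates are placed once per culture, from its
#' lowest-dose (most control-like) sample, and then applied to every dose
#' of that culture so the fractions are comparable along the dose axis.
#'
#' @inheritParams bin_intensities
#' @inheritParams gate_phases
#' @return data.frame with columns `culture_id, dose_uM, f_G1, f_S, f_G2M,
#'   n_total, n_outside`.
#' @export
phase_fraction_table <- function(table, gates = "auto") {
  check_nucleus_table(table)
  out <- list()
  for (cid in unique(table$culture_id)) {
    sub <- table[table$culture_id == cid, ]
    g <- gates
    if (identical(gates, "auto")) {
      ref <- sub$integrated_intensity[sub$dose_uM == min(sub$dose_uM)]
      g <- auto_gates(ref)
    }
    for (d in sort(unique(sub$dose_uM))) {
      pf <- gate_phases(sub$integrated_intensity[sub$dose_uM == d], g)
      out[[length(out) + 1]] <- data.frame(
        culture_id = cid, dose_uM = d, f_G1 = pf$f_G1, f_S = pf$f_S,
        f_G2M = pf$f_G2M, n_total = pf$n_total, n_outside = pf$n_outside)
    }
  }
  do.call(rbind, out)
}

#' Per-culture regression of phase fraction on log dose
#'
#' Ordinary least squares of a phase fraction on log10(dose in uM); the
#' slope is the change in fraction per tenfold dose increase. Zero doses
#' have no log and are excluded with a warning.
#'
#' @param fractions data.frame as from [phase_fraction_table()] for one
#'   culture.
#' @param phase `"G1"`, `"S"` or `"G2M"`.
#' @return List of class `phase_slope_fit`: `slope`, `intercept`,
#'   `r_squared`, `n`, `phase`, `culture_id`.
#' @export
phase_dose_regression <- function(fractions, phase = c("G1", "S", "G2M")) {
  phase <- match.arg(phase)
  col <- paste0("f_", phase)
  stopifnot(col %in% names(fractions), "dose_uM" %in% names(fractions))
  if (any(fractions$dose_uM <= 0)) {
    warning("excluding zero/negative doses from log-dose regression")
    fractions <- fractions[fractions$dose_uM > 0, ]
  }
  if (length(unique(fractions$dose_uM)) < 3)
    stop("need at least 3 distinct positive doses")
  x <- log10(fractions$dose_uM)
  y <- fractions[[col]]
  fit <- stats::lm(y ~ x)
  structure(list(
    culture_id = if ("culture_id" %in% names(fractions))
      fractions$culture_id[1] else NA_character_,
    phase = phase, slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = suppressWarnings(summary(fit))$r.squared,
    n = nrow(fractions)),
    class = "phase_slope_fit")
}

#' Exact sign test
#'
#' Exact binomial tail probabilities for `k` successes in `n` trials with
#' success probability one half. The two-sided p-value is twice the
#' smaller tail, capped at 1.
#'
#' @param k number of successes (e.g. cultures with a negative slope).
#' @param n number of trials.
#' @param alternative `"greater"`, `"less"` or `"two.sided"`.
#' @return The p-value.
#' @examples
#' sign_test(13, 14, "greater")   # 9.155e-04
#' @export
sign_test <- function(k, n, alternative = c("greater", "less",
                                            "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(n >= 1, k >= 0, k <= n, k == round(k), n == round(n))
  upper <- stats::pbinom(k - 1, n, 0.5, lower.tail = FALSE)  # P(K >= k)
  lower <- stats::pbinom(k, n, 0.5)                          # P(K <= k)
  switch(alternative,
         greater = upper,
         less = lower,
         two.sided = min(1, 2 * min(upper, lower)))
}

#' Common-slope linear mixed-effects dose response
#'
#' Models a phase fraction across cultures as
#' `y_ij = c_fixed + b_fixed * x_ij + c_j + b_j * x_ij + e_ij`, where
#' `x = log10(dose uM)`, the fixed terms capture the effect common to all
#' cultures and the random intercept `c_j` and random slope `b_j`
#' (independent, one pair per culture) absorb culture-specific departures.
#' Fitted by maximum likelihood with [lme4::lmer()]; the common slope is
#' reported with a Wald standard error, 95% confidence interval and
#' normal-reference p-value (a t reference with `n_cultures - 2` degrees
#' of freedom is available). A singular fit (zero random-effect variance)
#' falls back to pooled ordinary least squares with a flag.
#'
#' @param fractions data.frame with `culture_id, dose_uM` and phase
#'   fraction columns, across >= 3 cultures with >= 3 doses each.
#' @param phase `"G1"`, `"S"` or `"G2M"`.
#' @param df_method `"normal"` (default) or `"t"`.
#' @return List of class `mixed_model_fit`: `phase`, `fixed_intercept`,
#'   `fixed_slope`, `se`, `ci` (95%), `p`, `varcomp` (random intercept /
#'   slope / residual variances), `ranef` (per-culture random effects),
#'   `method` (`"lmm"` or `"pooled_ols"`), `logLik`.
#' @export
lmm_fixed_slope <- function(fractions, phase = c("G1", "S", "G2M"),
                            df_method = c("normal", "t")) {
  phase <- match.arg(phase)
  df_method <- match.arg(df_method)
  col <- paste0("f_", phase)
  stopifnot(all(c("culture_id", "dose_uM", col) %in% names(fractions)))
  fractions <- fractions[fractions$dose_uM > 0, ]
  cultures <- unique(fractions$culture_id)
  if (length(cultures) < 3)
    stop("need >= 3 cultures for the mixed model, got ", length(cultures))
  per_doses <- tapply(fractions$dose_uM, fractions$culture_id,
                      function(d) length(unique(d)))
  if (any(per_doses < 3)) stop("every culture needs >= 3 positive doses")

  dat <- data.frame(y = fractions[[col]], x = log10(fractions$dose_uM),
                    culture = factor(fractions$culture_id))
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(y ~ x + (1 | culture) + (0 + x | culture), data = dat,
               REML = FALSE)))
  singular <- lme4::isSingular(fit, tol = 1e-6)

  if (singular) {
    ols <- stats::lm(y ~ x, data = dat)
    est <- unname(stats::coef(ols)[2])
    se <- summary(ols)$coefficients["x", "Std. Error"]
    ll <- as.numeric(stats::logLik(ols))
    method <- "pooled_ols"
    vc <- c(intercept = 0, slope = 0,
            residual = sum(stats::resid(ols)^2) / nrow(dat))
    re <- NULL
    intercept <- unname(stats::coef(ols)[1])
  } else {
    est <- unname(lme4::fixef(fit)["x"])
    se <- sqrt(as.matrix(stats::vcov(fit))["x", "x"])
    ll <- as.numeric(stats::logLik(fit))
    method <- "lmm"
    vcdf <- as.data.frame(lme4::VarCorr(fit))
    vc <- c(intercept = vcdf$vcov[vcdf$grp == "culture" &
                                  !is.na(vcdf$var1) & vcdf$var1 ==
                                  "(Intercept)"][1],
            slope = vcdf$vcov[vcdf$var1 == "x" & !is.na(vcdf$var1)][1],
            residual = vcdf$vcov[vcdf$grp == "Residual"][1])
    re <- lme4::ranef(fit)
    intercept <- unname(lme4::fixef(fit)["(Intercept)"])
  }
  crit <- if (df_method == "normal") stats::qnorm(0.975)
          else stats::qt(0.975, df = length(cultures) - 2)
  z <- est / se
  p <- if (df_method == "normal") 2 * stats::pnorm(-abs(z))
       else 2 * stats::pt(-abs(z), df = length(cultures) - 2)
  p <- max(p, .Machine$double.xmin)  # keep p in (0, 1]
  structure(list(phase = phase, fixed_intercept = intercept,
                 fixed_slope = est, se = se,
                 ci = c(est - crit * se, est + crit * se), p = p,
                 varcomp = vc, ranef = re, method = method, logLik = ll,
                 n_cultures = length(cultures)),
            class = "mixed_model_fit")
}
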