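#' Bliss interaction score
#'
#' Under Bliss independence two non-interacting drugs leave a surviving
#' fraction equal to the product of their single-drug surviving fractions.
#' The interaction score is the departure from that product,
#' `IS = w_ab - w_a * w_b`, where each `w` is a control-normalized
#' viability ratio. Values significantly below zero indicate potentiation.
#'
#' @param w_ab combination viability ratio.
#' @param w_a,w_b single-drug viability ratios at the component doses.
#' @return `w_ab - w_a * w_b` (vectorized).
#' @export
interaction_score <- function(w_ab, w_a, w_b) {
  for (v in list(w_ab, w_a, w_b))
    if (any(!is.finite(v)) || any(v < 0))
      stop("viability ratios must be finite and >= 0")
  w_ab - w_a * w_b
}

#' Per-culture interaction scores over a fixed-ratio dose series
#'
#' For every anchor dose of the design, the combination viability is
#' compared with the Bliss product of the single-drug viabilities at the
#' matching component doses. Singles can be taken from measured wells at
#' matching doses (`"measured"`) or evaluated from fitted curves
#' (`"fitted"`), which also covers misaligned single-dose series.
#'
#' @param ratios normalized well table for one culture, as returned by
#'   [normalize_viability()] (must contain column `W`).
#' @param design a [combination_design()].
#' @param single_source `"measured"` or `"fitted"`.
#' @param fit_a,fit_b `ll4_fit` objects for the single drugs, required when
#'   `single_source = "fitted"`.
#' @param dose_tol relative tolerance used to match measured single doses.
#' @return A list of class `is_result` with the per-dose table (`entries`),
#'   `mean_IS`, the culture and pair identifiers, and a `reason` code when
#'   no dose was resolvable.
#' @export
interaction_score_screen <- function(ratios, design,
                                     single_source = c("measured", "fitted"),
                                     fit_a = NULL, fit_b = NULL,
                                     dose_tol = 1e-6) {
  single_source <- match.arg(single_source)
  stopifnot(inherits(design, "combination_design"), "W" %in% names(ratios))
  culture <- unique(ratios$culture_id)
  if (length(culture) != 1)
    stop("interaction_score_screen expects wells of exactly one culture")
  a <- design$compound_a; b <- design$compound_b
  if (single_source == "fitted" &&
      (!inherits(fit_a, "ll4_fit") || !inherits(fit_b, "ll4_fit")))
    stop("single_source = 'fitted' needs fit_a and fit_b")

  is_combo <- ratios$compound_a == a & ratios$compound_b == b &
    !ratios$is_control
  is_single_a <- ratios$compound_a == a & ratios$compound_b == "" &
    !ratios$is_control
  is_single_b <- ratios$compound_a == b & ratios$compound_b == "" &
    !ratios$is_control

  match_mean <- function(sel, dose_col, target) {
    d <- ratios[[dose_col]][sel]
    hit <- abs(d - target) <= dose_tol * target
    if (!any(hit)) return(NA_real_)
    mean(ratios$W[sel][hit])
  }

  entries <- lapply(design$anchor_doses, function(da) {
    db <- design$ratio * da
    hit_ab <- is_combo & abs(ratios$dose_a_uM - da) <= dose_tol * da
    if (!any(hit_ab)) return(NULL)
    w_ab <- mean(ratios$W[hit_ab])
    if (single_source == "measured") {
      w_a <- match_mean(is_single_a, "dose_a_uM", da)
      w_b <- match_mean(is_single_b, "dose_a_uM", db)
    } else {
      w_a <- ll4_predict(fit_a, da)
      w_b <- ll4_predict(fit_b, db)
    }
    if (is.na(w_a) || is.na(w_b)) return(NULL)
    data.frame(dose_a_uM = da, dose_b_uM = db, w_ab = w_ab,
               w_a = w_a, w_b = w_b, IS = w_ab - w_a * w_b)
  })
  entries <- do.call(rbind, entries)

  structure(list(
    culture_id = culture, pair = pair_label(design),
    entries = if (is.null(entries))
      data.frame(dose_a_uM = numeric(), dose_b_uM = numeric(),
                 w_ab = numeric(), w_a = numeric(), w_b = numeric(),
                 IS = numeric())
      else entries,
    mean_IS = if (is.null(entries)) NA_real_ else mean(entries$IS),
    reason = if (is.null(entries)) "no_resolvable_dose" else NA_character_),
    class = "is_result")
}

#' Permutation test for a factorial interaction score
#'
#' Tests the interaction score computed from a small factorial plate with
#' replicate wells of the four conditions control / drug a / drug b /
#' combination. Well values are first normalized by the observed
#' control-well mean (making the test invariant to a common scaling of
#' all values); treatment labels are then shuffled across all wells of
#' the plate and `IS = m_ab - m_a * m_b` recomputed at each shuffle,
#' giving the null distribution of the score under no functional
#' interaction. The empirical p-value uses the add-one rule
#' `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param values numeric well values (raw signals or ratios).
#' @param condition factor/character parallel to `values`, with levels
#'   `"control"`, `"a"`, `"b"`, `"ab"`.
#' @param n_perm number of label permutations (default 10000).
#' @param seed integer seed; the test is deterministic given the seed.
#' @param alternative `"less"` (potentiation, default) or `"two.sided"`.
#' @return List with `observed_IS`, `p`, `n_perm`, `seed`, `alternative`.
#' @export
permutation_test_is <- function(values, condition, n_perm = 10000,
                                seed = 1L,
                                alternative = c("less", "two.sided")) {
  alternative <- match.arg(alternative)
  stopifnot(length(values) == length(condition), all(is.finite(values)))
  condition <- as.character(condition)
  lev <- c("control", "a", "b", "ab")
  missing_lev <- setdiff(lev, unique(condition))
  if (length(missing_lev))
    stop("missing condition(s): ", paste(missing_lev, collapse = ", "))
  if (any(table(condition) < 2))
    stop("need at least 2 replicate wells per condition")
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value")

  # canonical well order (condition blocks, values sorted within) so the
  # result is invariant to how replicates happen to be labelled
  ord <- order(match(condition, lev), values)
  values <- values[ord]
  condition <- condition[ord]
  idx <- lapply(lev, function(l) which(condition == l))
  ctl_mean <- mean(values[idx[[1]]])
  if (ctl_mean == 0) stop("control mean is zero")
  w <- values / ctl_mean
  stat <- function(v) {
    m <- vapply(idx, function(i) mean(v[i]), numeric(1))
    m[4] - m[2] * m[3]
  }
  obs <- stat(w)
  n <- length(values)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) stat(w[sample.int(n)]),
           numeric(1))
  })
  extreme <- switch(alternative,
    less = sum(perm <= obs),
    two.sided = sum(abs(perm) >= abs(obs)))
  list(observed_IS = obs, p = (1 + extreme) / (1 + n_perm),
       n_perm = n_perm, seed = seed, alternative = alternative)
}

#' Expected fixed-ratio combination curve under no synergy
#'
#' Along the fixed dose ray of a design, the Bliss-independent expectation
#' for the combination viability at anchor dose `d_a` is the product of
#' the single-drug curves at the component doses,
#' `W_a(d_a) * W_b(ratio * d_a)`.
#'
#' @param fit_a,fit_b converged `ll4_fit` objects for the single drugs.
#' @param design a [combination_design()].
#' @return An object of class `bliss_curve` that can be evaluated with
#'   [predict()] at anchor doses and used as the combination curve in
#'   [combination_index()].
#' @export
expected_combination_curve <- function(fit_a, fit_b, design) {
  stopifnot(inherits(fit_a, "ll4_fit"), inherits(fit_b, "ll4_fit"),
            inherits(design, "combination_design"))
  if (!fit_a$converged || !fit_b$converged)
    stop("expected combination curve needs converged single-drug fits")
  structure(list(fit_a = fit_a, fit_b = fit_b, ratio = design$ratio),
            class = "bliss_curve")
}

#' @export
viability_at.bliss_curve <- function(object, d) {
  ll4_predict(object$fit_a, d) * ll4_predict(object$fit_b, object$ratio * d)
}

#' @export
predict.bliss_curve <- function(object, d, ...) viability_at(object, d)

## invert the (strictly decreasing) product curve by root-finding on
## log10 anchor dose
#' @export
dose_for.bliss_curve <- function(object, y) {
  stopifnot(all(y > 0), all(y < 1))
  lo_w <- object$fit_a$L * object$fit_b$L
  hi_w <- object$fit_a$U * object$fit_b$U
  vapply(y, function(yy) {
    w <- 1 - yy
    if (w <= lo_w || w >= hi_w) return(NA_real_)
    span_lo <- log10(min(object$fit_a$e, object$fit_b$e / object$ratio)) - 8
    span_hi <- log10(max(object$fit_a$e, object$fit_b$e / object$ratio)) + 8
    f <- function(t) viability_at(object, 10^t) - w
    r <- stats::uniroot(f, c(span_lo, span_hi), tol = 1e-12)
    10^r$root
  }, numeric(1))
}

#' Fixed-ratio Chou-Talalay combination index
#'
#' At effect level `y` (inhibition fraction), the combination index is
#' `CI_y = X_a/x_a + X_b/x_b`: `X_a` and `X_b = ratio * X_a` are the
#' component doses at which the combination reaches effect `y`, and `x_a`,
#' `x_b` are the single-drug doses achieving the same effect alone.
#' `CI < 1` is consistent with synergy (a reporting annotation, not a
#' test). The index is averaged over an effect band, by default 21 evenly
#' spaced levels spanning 40-60% inhibition.
#'
#' A single-drug term whose effect level is unattainable (the drug alone
#' never reaches `y`) contributes 0 to `CI_y` — the limit of an inert
#' constituent — and the level is flagged partially defined; in
#' `strict = TRUE` mode such levels are undefined instead. Levels where the
#' combination itself cannot reach `y` are always undefined.
#'
#' @param fit_a,fit_b converged `ll4_fit`s for the single drugs.
#' @param fit_ab combination response indexed by the anchor-component dose:
#'   either a converged `ll4_fit` of combination viability versus anchor
#'   dose, or a [expected_combination_curve()] object.
#' @param design a [combination_design()].
#' @param band effect band `[y_lo, y_hi]`, inside (0, 1).
#' @param n_grid number of evenly spaced levels in the band.
#' @param strict logical; treat unattainable single-drug terms as
#'   undefined rather than zero.
#' @return A list of class `ci_result` with the per-level table
#'   (`entries`), `mean_CI` over defined levels, `n_defined_levels`, the
#'   band and a `reason` code when no level is defined.
#' @export
combination_index <- function(fit_a, fit_b, fit_ab, design,
                              band = c(0.4, 0.6), n_grid = 21,
                              strict = FALSE) {
  stopifnot(inherits(fit_a, "ll4_fit"), inherits(fit_b, "ll4_fit"),
            inherits(design, "combination_design"))
  if (!(band[1] > 0 && band[2] < 1 && band[1] < band[2]))
    stop("band must lie inside (0, 1)")
  if (!fit_a$converged || !fit_b$converged)
    stop("combination_index needs converged single-drug fits")
  if (inherits(fit_ab, "ll4_fit") && !fit_ab$converged)
    stop("combination_index needs a converged combination fit")

  y <- seq(band[1], band[2], length.out = n_grid)
  X_a <- dose_for(fit_ab, y)
  X_b <- design$ratio * X_a
  x_a <- ll4_inverse(fit_a, y)
  x_b <- ll4_inverse(fit_b, y)

  term_a <- ifelse(is.na(x_a), if (strict) NA_real_ else 0, X_a / x_a)
  term_b <- ifelse(is.na(x_b), if (strict) NA_real_ else 0, X_b / x_b)
  ci <- term_a + term_b
  defined <- !is.na(X_a) & !is.na(ci)
  ci[!defined] <- NA_real_
  partial <- defined & (is.na(x_a) | is.na(x_b))

  entries <- data.frame(y = y, X_a_uM = X_a, X_b_uM = X_b,
                        x_a_uM = x_a, x_b_uM = x_b, CI = ci,
                        defined = defined, partial = partial)
  structure(list(
    pair = pair_label(design), entries = entries,
    mean_CI = if (any(defined)) mean(ci[defined]) else NA_real_,
    band = band, n_defined_levels = sum(defined),
    reason = if (any(defined)) NA_character_ else "no_defined_level"),
    class = "ci_result")
}

#' Cohort-level synergy statistics
#'
#' Two-sided one-sample Wilcoxon signed-rank tests of whether the median
#' per-culture interaction score differs from 0 and the median combination
#' index differs from 1. Zero differences are dropped; the exact
#' distribution is used for up to 25 non-zero differences and the normal
#' approximation with continuity correction above that.
#'
#' @param mean_is numeric per-culture mean interaction scores (may contain
#'   `NA`).
#' @param mean_ci numeric per-culture mean combination indices (may contain
#'   `NA`).
#' @param pair pair identifier carried into the result.
#' @param min_n minimum number of cultures with defined values.
#' @return List of class `cohort_synergy_stats`.
#' @export
cohort_synergy_stats <- function(mean_is, mean_ci, pair = "", min_n = 6) {
  is_ok <- mean_is[is.finite(mean_is)]
  ci_ok <- mean_ci[is.finite(mean_ci)]
  if (length(is_ok) < min_n || length(ci_ok) < min_n)
    stop("need at least ", min_n, " cultures with defined IS and CI")
  w_is <- wilcoxon_signed(is_ok, mu = 0)
  w_ci <- wilcoxon_signed(ci_ok, mu = 1)
  structure(list(
    pair = pair, n_cultures = length(is_ok),
    median_IS = stats::median(is_ok), wilcoxon_p_IS = w_is$p,
    median_CI = stats::median(ci_ok), wilcoxon_p_CI = w_ci$p,
    flags = c(w_is$flag, w_ci$flag)),
    class = "cohort_synergy_stats")
}

## one-sample Wilcoxon signed rank vs mu; exact for n <= 25, else normal
## approximation with continuity correction
wilcoxon_signed <- function(x, mu) {
  d <- x - mu
  d <- d[d != 0]
  if (!length(d)) return(list(p = 1, flag = "all_differences_zero"))
  exact <- length(d) <= 25 && !any(duplicated(abs(d)))
  p <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, exact = exact, correct = TRUE)$p.value)
  list(p = p, flag = NULL)
}
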