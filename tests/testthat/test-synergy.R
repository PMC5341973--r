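test_that("interaction score is the departure from the Bliss product", {
  expect_equal(interaction_score(0.5, 1.0, 1.0), -0.5)
  expect_equal(interaction_score(0.48, 0.8, 0.6), 0)
  expect_equal(interaction_score(0.3, 0.8, 0.6), -0.18)
  expect_error(interaction_score(-0.1, 1, 1), "finite")
})

make_pair_culture <- function(fa, fb, des, excess = 0, combo_w = NULL) {
  # one culture's normalized wells: singles at the component doses plus
  # combination wells on the fixed ray
  da <- des$anchor_doses
  db <- des$ratio * da
  w_ab <- if (is.null(combo_w))
    ll4_predict(fa, da) * ll4_predict(fb, db) - excess else combo_w
  data.frame(
    culture_id = "GC01", plate_id = "P1",
    well_id = paste0("w", seq_len(3 * length(da))),
    compound_a = c(rep("A", length(da)), rep("B", length(da)),
                   rep("A", length(da))),
    dose_a_uM = c(da, db, da),
    compound_b = c(rep("", 2 * length(da)), rep("B", length(da))),
    dose_b_uM = c(rep(0, 2 * length(da)), db),
    replicate = 1L, raw_signal = 1, is_control = FALSE,
    W = c(ll4_predict(fa, da), ll4_predict(fb, db), w_ab),
    stringsAsFactors = FALSE)
}

test_that("screen IS is zero on Bliss-multiplicative data and tracks a planted excess", {
  fa <- ll4(1, 0.1, 10, 1.5); fb <- ll4(1, 0.2, 4, 2)
  des <- combination_design("A", "B", 0.35, 10 * 3^seq(-5, 5))

  null_tab <- make_pair_culture(fa, fb, des)
  r0 <- interaction_score_screen(null_tab, des)
  expect_equal(nrow(r0$entries), 11)
  expect_lt(max(abs(r0$entries$IS)), 1e-12)

  shifted <- make_pair_culture(fa, fb, des, excess = 0.1)
  r1 <- interaction_score_screen(shifted, des)
  expect_equal(r1$mean_IS, -0.1, tolerance = 1e-12)

  # fitted singles reproduce the direct formula on the fitted curves
  r2 <- interaction_score_screen(shifted, des, single_source = "fitted",
                                 fit_a = fa, fit_b = fb)
  manual <- shifted$W[23:33] -
    ll4_predict(fa, des$anchor_doses) *
    ll4_predict(fb, des$ratio * des$anchor_doses)
  expect_equal(r2$entries$IS, manual)
})

test_that("unmatchable singles produce an empty result with a reason", {
  fa <- ll4(1, 0.1, 10, 1.5); fb <- ll4(1, 0.2, 4, 2)
  des <- combination_design("A", "B", 0.35, 10 * 3^seq(-5, 5))
  tab <- make_pair_culture(fa, fb, des)
  tab <- tab[tab$compound_b == "B", ]       # drop all single wells
  r <- interaction_score_screen(tab, des)
  expect_equal(nrow(r$entries), 0)
  expect_equal(r$reason, "no_resolvable_dose")
  expect_true(is.na(r$mean_IS))
})

test_that("permutation test detects potentiation and is invariant", {
  cond <- factorial_conditions(3)
  set.seed(10)
  v <- c(rnorm(3, 1, 0.02), rnorm(3, 0.8, 0.02), rnorm(3, 0.6, 0.02),
         rnorm(3, 0.48 - 0.4, 0.02))  # w_ab 0.4 below the Bliss product
  p <- permutation_test_is(v, cond, n_perm = 2000, seed = 5)
  expect_lte(p$p, 0.05)

  # identical wells carry no signal
  expect_equal(permutation_test_is(rep(0.7, 12), cond, n_perm = 200,
                                   seed = 1)$p, 1)

  # invariant to common scaling and to relabeling replicates
  p_scaled <- permutation_test_is(v * 1234, cond, n_perm = 2000, seed = 5)
  expect_identical(p$p, p_scaled$p)
  shuffle <- c(3, 1, 2, 6, 4, 5, 9, 8, 7, 12, 10, 11)
  p_relab <- permutation_test_is(v[shuffle], cond[shuffle], n_perm = 2000,
                                 seed = 5)
  expect_identical(p$p, p_relab$p)

  expect_error(permutation_test_is(v[1:9], cond[1:9], seed = 1),
               "missing condition")
})

test_that("expected combination curve is the Bliss product along the ray", {
  fa <- ll4(1, 0, 10, 2)
  des <- combination_design("A", "B", 2, c(1, 2, 4, 8))

  inert <- ll4(1 + 1e-9, 1, 1, 1)  # flat at 1: inert partner
  bc <- expected_combination_curve(fa, inert, des)
  d <- c(0.5, 2, 10, 40)
  expect_equal(predict(bc, d), ll4_predict(fa, d), tolerance = 1e-8)

  fb <- ll4(1, 0, 20, 2)
  bc2 <- expected_combination_curve(fa, fb, des)
  expect_equal(predict(bc2, 10), 0.5 * 0.5)  # both at midpoint
  # closed form: W(d) = 1/(1+(d/10)^2)^2 crosses 0.5 at 10*sqrt(sqrt(2)-1)
  d_half <- 10 * sqrt(sqrt(2) - 1)
  expect_equal(predict(bc2, d_half), 0.5, tolerance = 1e-12)

  bad <- fit_ll4(c(1, 3, 9, 27, 81), rep(1, 5))
  expect_error(expected_combination_curve(fa, bad, des), "converged")
})

test_that("sham self-combination gives CI = 1 across the band", {
  f <- ll4(1, 0.12, 8, 1.7)
  des <- combination_design("A", "Asham", 1, c(1, 2, 4, 8, 16))
  # combining a drug with itself at 1:1: response at anchor d is the
  # single curve at total dose 2d, i.e. an LL4 with midpoint e/2
  f_ab <- ll4(f$U, f$L, f$e / 2, f$h)
  ci <- combination_index(f, f, f_ab, des)
  expect_equal(ci$n_defined_levels, 21)
  expect_lt(max(abs(ci$entries$CI - 1)), 1e-6)
  expect_equal(ci$mean_CI, 1, tolerance = 1e-6)
})

test_that("an inert partner contributes zero and flags partial levels", {
  fa <- ll4(1, 0, 10, 2)
  inert <- ll4(1 + 1e-9, 1, 1, 1)
  des <- combination_design("A", "B", 0.5, c(1, 2, 4, 8))
  ci <- combination_index(fa, inert, fa, des)  # combo curve = A's curve
  expect_true(all(ci$entries$partial))
  expect_equal(ci$mean_CI, 1, tolerance = 1e-9)
  # strict mode refuses those levels instead
  ci_strict <- combination_index(fa, inert, fa, des, strict = TRUE)
  expect_equal(ci_strict$n_defined_levels, 0)
  expect_equal(ci_strict$reason, "no_defined_level")
})

test_that("CI on a Bliss-product combination matches the closed form and bisection", {
  fa <- ll4(1, 0, 10, 2); fb <- ll4(1, 0, 20, 2)
  des <- combination_design("A", "B", 2, c(1, 2, 4, 8, 16))
  bc <- expected_combination_curve(fa, fb, des)
  ci <- combination_index(fa, fb, bc, des)
  at_half <- ci$entries[abs(ci$entries$y - 0.5) < 1e-12, ]
  # X_a = 10*sqrt(sqrt(2)-1), x_a = 10, x_b = 20, X_b = 2 X_a
  expect_equal(at_half$CI, 2 * sqrt(sqrt(2) - 1), tolerance = 1e-6)

  # brute-force: bisect each of the three raw curves independently
  for (y in c(0.45, 0.5, 0.55)) {
    Xa <- bisect_root(function(d) predict(bc, d) - (1 - y), 1e-4, 1e4)
    xa <- bisect_root(function(d) ll4_predict(fa, d) - (1 - y), 1e-4, 1e4)
    xb <- bisect_root(function(d) ll4_predict(fb, d) - (1 - y), 1e-4, 1e4)
    brute <- Xa / xa + 2 * Xa / xb
    got <- ci$entries$CI[abs(ci$entries$y - y) < 1e-9]
    expect_equal(got, brute, tolerance = 1e-6)
  }
})

test_that("mean CI is stable under grid refinement", {
  fa <- ll4(1, 0.05, 10, 1.4); fb <- ll4(1, 0.1, 5, 2.1)
  des <- combination_design("A", "B", 0.5, c(1, 2, 4, 8))
  bc <- expected_combination_curve(fa, fb, des)
  ci21 <- combination_index(fa, fb, bc, des, n_grid = 21)
  ci42 <- combination_index(fa, fb, bc, des, n_grid = 42)
  expect_lt(abs(ci21$mean_CI - ci42$mean_CI), 1e-3)
})

test_that("cohort Wilcoxon statistics behave at the extremes and null", {
  is_null <- rnorm(41, 0, 0.01)
  all_one <- rep(1, 41)
  st <- cohort_synergy_stats(is_null, all_one, pair = "x")
  expect_equal(st$wilcoxon_p_CI, 1)
  expect_true("all_differences_zero" %in% st$flags)

  st2 <- cohort_synergy_stats(is_null, rep(0.5, 41))
  expect_lt(st2$wilcoxon_p_CI, 1e-6)
  expect_equal(st2$median_CI, 0.5)

  expect_error(cohort_synergy_stats(rnorm(4), rnorm(4)), "at least 6")

  # symmetric-around-1 CI gives uniform p over seeds
  ps <- vapply(1:200, function(s) {
    set.seed(s)
    cohort_synergy_stats(rnorm(41, 0, 0.1), 1 + rnorm(41, 0, 0.1))$wilcoxon_p_CI
  }, numeric(1))
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})
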