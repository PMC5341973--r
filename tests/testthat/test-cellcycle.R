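nucleus_table <- function(intensities, dose = 1, culture = "GC01") {
  data.frame(culture_id = culture, dose_uM = dose,
             well_id = "w1", integrated_intensity = intensities)
}

test_that("binning honours the contract and conserves counts", {
  set.seed(21)
  tab <- rbind(nucleus_table(runif(2000, 500, 2500), dose = 1),
               nucleus_table(runif(1500, 500, 2500), dose = 10))
  hists <- bin_intensities(tab)
  expect_length(hists, 2)
  for (h in hists) {
    expect_length(h$counts, 100)
    expect_length(h$breaks, 101)
  }
  expect_equal(sum(hists[[1]]$counts), 2000)
  expect_equal(sum(hists[[2]]$counts), 1500)
  # per-culture policy: both doses share the same edges
  expect_equal(hists[[1]]$breaks, hists[[2]]$breaks)

  # all-equal intensities land in a single bin
  h1 <- bin_intensities(nucleus_table(rep(1000, 77)))[[1]]
  expect_equal(sum(h1$counts > 0), 1)
  expect_equal(sum(h1$counts), 77)

  expect_error(bin_intensities(nucleus_table(c(1, -2, 3))), "positive")
})

test_that("uniform intensities fill bins evenly (multinomial bound)", {
  set.seed(22)
  tab <- nucleus_table(runif(1e5, 0, 100))
  h <- bin_intensities(tab, range_policy = "group")[[1]]
  sd_bin <- sqrt(1e5 * 0.01 * 0.99)
  expect_true(all(abs(h$counts - 1000) <= 5 * sd_bin))
})

test_that("auto gating separates a G1/G2M mixture", {
  set.seed(23)
  n <- 1e4
  x <- c(rnorm(n / 2, 1000, 50), rnorm(n / 2, 2000, 100))
  pf <- gate_phases(x)
  expect_equal(pf$f_G1, 0.5, tolerance = 0.03)
  expect_equal(pf$f_G2M, 0.5, tolerance = 0.03)
  expect_lte(pf$f_S, 0.05)
  expect_equal(pf$f_G1 + pf$f_S + pf$f_G2M, 1, tolerance = 1e-9)
})

test_that("degenerate and ambiguous gating inputs behave as specified", {
  # all nuclei exactly at the mode
  pf <- gate_phases(rep(1000, 60))
  expect_equal(pf$f_G1, 1)

  # two equal modes: ambiguous peak must be refused
  set.seed(24)
  x <- c(rnorm(5000, 1000, 50), rnorm(5000, 2000, 50))
  expect_error(gate_phases(x), "ambiguous")

  expect_error(gate_phases(rep(1000, 10)), "50 nuclei")
  bad_gates <- list(G1 = c(900, 1400), S = c(1300, 1700),
                    G2M = c(1700, 2500))
  expect_error(gate_phases(rep(1000, 60), bad_gates), "non-overlapping")
})

test_that("gating is equivariant under a common intensity rescaling", {
  set.seed(25)
  x <- c(rnorm(3000, 1000, 50), runif(1000, 1150, 1850),
         rnorm(2000, 2000, 100))
  g <- list(G1 = c(750, 1300), S = c(1300, 1700), G2M = c(1700, 2500))
  pf1 <- gate_phases(x, g)
  g2 <- lapply(g, function(v) v * 3.7)
  pf2 <- gate_phases(x * 3.7, g2)
  expect_equal(pf1$f_G1, pf2$f_G1)
  expect_equal(pf1$f_S, pf2$f_S)
  expect_equal(pf1$f_G2M, pf2$f_G2M)
})

test_that("phase fractions regress on log dose as specified", {
  doses <- c(1, 3, 10, 30, 100)
  const <- data.frame(culture_id = "GC01", dose_uM = doses, f_G1 = 0.5,
                      f_S = 0.3, f_G2M = 0.2)
  expect_equal(phase_dose_regression(const, "G1")$slope, 0)

  lin <- const
  lin$f_G1 <- 0.6 - 0.05 * log10(doses)
  fit <- phase_dose_regression(lin, "G1")
  expect_equal(fit$slope, -0.05, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)

  withz <- rbind(lin, data.frame(culture_id = "GC01", dose_uM = 0,
                                 f_G1 = 0.7, f_S = 0.2, f_G2M = 0.1))
  expect_warning(phase_dose_regression(withz, "G1"), "zero")
  expect_error(phase_dose_regression(lin[1:2, ], "G1"), "3 distinct")
})

test_that("noisy slope recovery stays within tolerance", {
  doses <- c(1, 4, 16, 63, 250, 1000)   # three decades of dose
  hits <- vapply(1:100, function(s) {
    set.seed(s)
    df <- data.frame(culture_id = "GC01", dose_uM = doses,
                     f_G1 = 0.6 - 0.05 * log10(doses) + rnorm(6, 0, 0.02),
                     f_S = 0.2, f_G2M = 0.2)
    abs(phase_dose_regression(df, "G1")$slope + 0.05) <= 0.02
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("sign test reproduces exact binomial tails", {
  expect_equal(sign_test(14, 14, "greater"), 0.5^14)
  expect_equal(sign_test(13, 14, "greater"), 15 / 16384)
  expect_equal(sign_test(7, 14, "greater"), 9908 / 16384)
  # symmetry of the two-sided test
  for (k in 0:10)
    expect_equal(sign_test(k, 10, "two.sided"),
                 sign_test(10 - k, 10, "two.sided"))
  expect_equal(sign_test(5, 10, "two.sided"), 1)
  expect_error(sign_test(11, 10), "k <= n")
})

lmm_sim <- function(seed, n_cultures = 14, slope = -0.04, slope_sd = 0,
                    int_sd = 0, resid_sd = 0.02,
                    doses = c(1, 2.5, 6, 16, 40, 100)) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(n_cultures), function(j) {
    b <- slope + rnorm(1, 0, slope_sd)
    a <- 0.55 + rnorm(1, 0, int_sd)
    data.frame(culture_id = sprintf("GC%02d", j), dose_uM = doses,
               f_G1 = a + b * log10(doses) + rnorm(length(doses), 0,
                                                   resid_sd),
               f_S = 0.2, f_G2M = 0.2)
  }))
}

test_that("mixed model collapses to pooled OLS when variance is absent", {
  df <- lmm_sim(31)
  m <- lmm_fixed_slope(df, "G1")
  pooled <- stats::lm(f_G1 ~ log10(dose_uM), data = df)
  expect_equal(m$fixed_slope, unname(coef(pooled)[2]), tolerance = 1e-3)
  expect_lte(max(m$varcomp[c("intercept", "slope")]), 1e-4)
})

test_that("mixed model rejects too-small designs and nests pooled OLS", {
  df1 <- lmm_sim(32, n_cultures = 1)
  expect_error(lmm_fixed_slope(df1, "G1"), ">= 3 cultures")

  df <- lmm_sim(33, slope_sd = 0.015, int_sd = 0.03)
  m <- lmm_fixed_slope(df, "G1")
  pooled <- stats::lm(f_G1 ~ log10(dose_uM), data = df)
  expect_gte(m$logLik, as.numeric(stats::logLik(pooled)) - 1e-6)
  expect_true(is.finite(m$p) && m$p > 0 && m$p <= 1)
})
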