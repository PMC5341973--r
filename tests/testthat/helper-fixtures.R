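# shared fixtures and independent oracles used across test files

# minimal well table: two treated wells + one control on a single plate
tiny_wells <- function() {
  data.frame(
    culture_id = "GC01", plate_id = "P1",
    well_id = c("w1", "w2", "w3"),
    compound_a = c("drugA", "drugA", ""),
    dose_a_uM = c(1, 10, 0),
    compound_b = "", dose_b_uM = 0,
    replicate = 1L,
    raw_signal = c(4500, 2000, 9000),
    is_control = c(FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
}

# hand-rolled bisection root finder, independent of stats::uniroot, used
# as the brute-force oracle for dose inversion
bisect_root <- function(f, lo, hi, iter = 200) {
  flo <- f(lo)
  if (flo * f(hi) > 0) stop("root not bracketed")
  for (i in seq_len(iter)) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (flo * fm <= 0) hi <- mid else { lo <- mid; flo <- fm }
  }
  (lo + hi) / 2
}

# random plausible single-drug LL4 parameter draws for property loops
random_ll4 <- function() {
  ll4(U = 1, L = runif(1, 0, 0.3), e = exp(runif(1, log(0.5), log(50))),
      h = runif(1, 0.8, 3))
}

# a factorial plate layout used by the permutation-test checks
factorial_conditions <- function(n_rep = 3)
  rep(c("control", "a", "b", "ab"), each = n_rep)
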