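#' Configuration for the synthetic screen generator
#'
#' Defaults emulate the structure of a 41-culture patient-derived glioma
#' screen: each drug in an 11-point 3-fold dilution series, combinations
#' diluted at a fixed dose ratio derived from the working doses 20 uM
#' pterostilbene, 7 uM sertraline and 10 uM gefitinib (ratios 7/20 and
#' 10/20), triplicate wells, DMSO control wells on every plate, and
#' multiplicative log-normal measurement noise.
#'
#' @param n_cultures number of cultures (default 41).
#' @param n_doses points per dilution series (default 11).
#' @param dilution_factor fold-change between adjacent doses (default 3).
#' @param top_dose_multiple top anchor dose as a multiple of the working
#'   dose (default 4, centering typical midpoints inside the series).
#' @param pairs named list of combination specs, each a list with
#'   `compound_a`, `compound_b` and working doses `wd_a`, `wd_b` in uM;
#'   the design ratio is `wd_b / wd_a`.
#' @param replicates wells per (treatment, dose).
#' @param controls_per_plate DMSO vehicle wells per plate.
#' @param cv multiplicative log-normal noise coefficient of variation;
#'   `0` gives noiseless signals.
#' @param plate_scale,plate_scale_cv mean raw-fluorescence scale of a
#'   fully viable well and its between-plate log-normal CV.
#' @param sigma planted synergy strength (scalar, >= -1): `sigma = 0`
#'   makes every combination response exactly the Bliss product of the
#'   true single-drug curves.
#' @param sigma_sd between-culture SD of the planted synergy strength.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(n_cultures = 41, n_doses = 11,
                              dilution_factor = 3, top_dose_multiple = 4,
                              pairs = default_pairs(), replicates = 3,
                              controls_per_plate = 16, cv = 0.05,
                              plate_scale = 10000, plate_scale_cv = 0.1,
                              sigma = 0, sigma_sd = 0) {
  stopifnot(n_cultures >= 1, n_doses >= 4, dilution_factor > 1,
            replicates >= 1, controls_per_plate >= 1, cv >= 0,
            plate_scale > 0, sigma >= -1, sigma_sd >= 0)
  structure(list(n_cultures = n_cultures, n_doses = n_doses,
                 dilution_factor = dilution_factor,
                 top_dose_multiple = top_dose_multiple, pairs = pairs,
                 replicates = replicates,
                 controls_per_plate = controls_per_plate, cv = cv,
                 plate_scale = plate_scale, plate_scale_cv = plate_scale_cv,
                 sigma = sigma, sigma_sd = sigma_sd),
            class = "simulation_config")
}

#' @rdname simulation_config
#' @export
default_pairs <- function() {
  list(
    PS = list(compound_a = "pterostilbene", compound_b = "sertraline",
              wd_a = 20, wd_b = 7),
    PG = list(compound_a = "pterostilbene", compound_b = "gefitinib",
              wd_a = 20, wd_b = 10))
}

## dilution series for a compound: top = multiple x working dose, then
## n_doses points descending by the dilution factor, returned increasing
dose_series <- function(wd, config) {
  top <- config$top_dose_multiple * wd
  sort(top / config$dilution_factor^(seq_len(config$n_doses) - 1))
}

#' Simulate a drug-combination screen with known ground truth
#'
#' Draws per-culture four-parameter log-logistic single-drug curves
#' (`U = 1`, `L ~ U(0.05, 0.25)`, midpoint log-normal around half the
#' working dose, slope `h ~ U(1, 2.5)`), plants synergy through a
#' multiplicative Bliss-excess kernel tied to the anchor drug's occupancy,
#' \deqn{W_{ab}(d) = W_a(d)\,W_b(\rho d)\,(1 - \sigma s(d)),\quad
#'   s(d) = \frac{(d/e_a)^{h_a}}{1 + (d/e_a)^{h_a}},}
#' and emits raw signals `plate_scale x true viability x log-normal
#' noise`, plus control wells, one plate per culture. `sigma = 0` gives
#' exact Bliss-null combinations. Subtype / age / sex / survival
#' annotations are drawn from simple categorical and normal models. The
#' output is byte-identical for identical (config, seed).
#'
#' @param config a [simulation_config()].
#' @param seed integer seed.
#' @return List with `dataset` (a [screen_dataset()] with designs and
#'   annotations) and `truth` (class `cohort_ground_truth`: per-culture
#'   curve parameters, planted `sigma`, and `ci_true`, the per-culture
#'   mean combination index over the 40-60% band computed by numerical
#'   inversion of the true combination curves).
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(seed, simulate_cohort_impl(config, seed))
}

simulate_cohort_impl <- function(config, seed) {
  cids <- sprintf("GC%02d", seq_len(config$n_cultures))
  compounds <- unique(unlist(lapply(config$pairs, function(p)
    c(p$compound_a, p$compound_b))))
  wd <- stats::setNames(numeric(length(compounds)), compounds)
  for (p in config$pairs) {
    wd[p$compound_a] <- p$wd_a
    wd[p$compound_b] <- p$wd_b
  }

  # per-culture true single-drug curves: drug sensitivity is modeled as a
  # shared per-culture scale (cultures are globally more or less
  # sensitive) with smaller compound-specific departures, so the fixed
  # dose ratio chosen from the working doses stays roughly matched to the
  # per-culture potencies, as the design intends
  curves <- list()
  for (cid in cids) {
    sens <- stats::rnorm(1, 0, 0.3)          # shared log-potency scale
    h_base <- stats::runif(1, 0.9, 1.4)      # near-hyperbolic steepness
    for (cp in compounds) {
      curves[[paste(cid, cp, sep = "|")]] <- ll4(
        U = 1,
        L = stats::runif(1, 0.05, 0.25),
        e = wd[cp] * 0.5 * exp(sens + stats::rnorm(1, 0, 0.15)),
        h = max(h_base + stats::runif(1, -0.15, 0.15), 0.7))
    }
  }
  sigma <- pmin(pmax(config$sigma + config$sigma_sd * stats::rnorm(
    config$n_cultures), -1), 1)
  names(sigma) <- cids

  designs <- lapply(config$pairs, function(p) combination_design(
    p$compound_a, p$compound_b, ratio = p$wd_b / p$wd_a,
    anchor_doses = dose_series(p$wd_a, config)))
  names(designs) <- vapply(designs, pair_label, character(1))

  kern <- function(d, fa) (d / fa$e)^fa$h / (1 + (d / fa$e)^fa$h)
  combo_viab <- function(cid, des, d) {
    fa <- curves[[paste(cid, des$compound_a, sep = "|")]]
    fb <- curves[[paste(cid, des$compound_b, sep = "|")]]
    ll4_predict(fa, d) * ll4_predict(fb, des$ratio * d) *
      (1 - sigma[cid] * kern(d, fa))
  }

  noise <- function(n) {
    if (config$cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + config$cv^2))
    exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
  }
  plate_noise <- function() {
    if (config$plate_scale_cv == 0) return(1)
    sdlog <- sqrt(log(1 + config$plate_scale_cv^2))
    exp(stats::rnorm(1, -sdlog^2 / 2, sdlog))
  }

  rows <- vector("list", config$n_cultures)
  for (ci in seq_along(cids)) {
    cid <- cids[ci]
    scale <- config$plate_scale * plate_noise()
    wlist <- list()
    add <- function(compound_a, dose_a, compound_b, dose_b, viab,
                    is_control, nrep) {
      data.frame(
        culture_id = cid, plate_id = paste0("P_", cid),
        compound_a = compound_a, dose_a_uM = dose_a,
        compound_b = compound_b, dose_b_uM = dose_b,
        replicate = seq_len(nrep),
        raw_signal = scale * viab * noise(nrep),
        is_control = is_control)
    }
    wlist[[1]] <- add("", 0, "", 0, 1, TRUE, config$controls_per_plate)
    k <- 2
    for (cp in compounds) {
      fa <- curves[[paste(cid, cp, sep = "|")]]
      for (d in dose_series(wd[cp], config)) {
        wlist[[k]] <- add(cp, d, "", 0, ll4_predict(fa, d), FALSE,
                          config$replicates)
        k <- k + 1
      }
    }
    for (des in designs) {
      for (d in des$anchor_doses) {
        v <- combo_viab(cid, des, d)
        if (v < -0.05)
          stop("config drives combination viability below the clipping ",
               "threshold for culture ", cid)
        wlist[[k]] <- add(des$compound_a, d, des$compound_b,
                          des$ratio * d, max(v, 0), FALSE,
                          config$replicates)
        k <- k + 1
      }
    }
    plate <- do.call(rbind, wlist)
    plate$well_id <- sprintf("w%04d", seq_len(nrow(plate)))
    rows[[ci]] <- plate
  }
  wells <- do.call(rbind, rows)
  wells <- wells[, c("culture_id", "plate_id", "well_id", "compound_a",
                     "dose_a_uM", "compound_b", "dose_b_uM", "replicate",
                     "raw_signal", "is_control")]
  rownames(wells) <- NULL

  cultures <- data.frame(
    culture_id = cids,
    subtype = sample(c("CL", "MS", "NL", "PN"), config$n_cultures,
                     replace = TRUE, prob = c(0.3, 0.3, 0.1, 0.3)),
    age = pmin(pmax(round(stats::rnorm(config$n_cultures, 65.5, 10)), 18),
               90),
    sex = sample(c("M", "F"), config$n_cultures, replace = TRUE,
                 prob = c(25, 16) / 41),
    survival_days = round(stats::rlnorm(config$n_cultures, log(450), 0.5)),
    stringsAsFactors = FALSE)

  # true mean CI over the 40-60% band by numerical inversion of the true
  # combination curve (closed-form single-drug inverses)
  y_grid <- seq(0.4, 0.6, length.out = 21)
  ci_true <- matrix(NA_real_, config$n_cultures, length(designs),
                    dimnames = list(cids, names(designs)))
  for (cid in cids) for (pn in names(designs)) {
    des <- designs[[pn]]
    fa <- curves[[paste(cid, des$compound_a, sep = "|")]]
    fb <- curves[[paste(cid, des$compound_b, sep = "|")]]
    ci_vals <- vapply(y_grid, function(yy) {
      w <- 1 - yy
      f <- function(t) combo_viab(cid, des, 10^t) - w
      lo <- log10(min(fa$e, fb$e / des$ratio)) - 8
      hi <- log10(max(fa$e, fb$e / des$ratio)) + 8
      if (f(lo) <= 0 || f(hi) >= 0) return(NA_real_)
      Xa <- 10^stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
      xa <- ll4_inverse(fa, yy); xb <- ll4_inverse(fb, yy)
      (if (is.na(xa)) 0 else Xa / xa) +
        (if (is.na(xb)) 0 else des$ratio * Xa / xb)
    }, numeric(1))
    if (any(!is.na(ci_vals))) ci_true[cid, pn] <- mean(ci_vals,
                                                       na.rm = TRUE)
  }

  truth <- structure(list(
    curves = curves, sigma = sigma, ci_true = ci_true,
    cultures = cultures, designs = designs, config = config, seed = seed),
    class = "cohort_ground_truth")
  list(dataset = screen_dataset(wells, cultures = cultures,
                                designs = designs),
       truth = truth)
}

#' Simulate molecular profiles with a planted synergy signal
#'
#' Builds expression and copy-number matrices (cultures x features) and a
#' binary missense-mutation table carrying a known linear signal for the
#' per-culture synergy level. `n_causal` independent standard-normal
#' expression features each contribute `effect_size` to the molecular
#' synergy score, and the returned `response` is
#' `sum(effect_size * x_causal) + Normal(0, noise_sd)` — a centered
#' combination-index surrogate (the association tests in this package are
#' shift-invariant, and an affine map puts it on the CI scale). The
#' copy-number matrix carries one contiguous simulated segment (emulating
#' a focal-deletion signal) whose shared per-culture value tracks the
#' causal transcript signal with extra noise, the way a dosage-driving
#' deletion acts through expression; the segment therefore predicts the
#' response, but less well than the transcripts themselves. All remaining
#' features are independent standard normal noise.
#' The planted mutation flag marks the `n_mutants`
#' cultures ranking highest on a noisy copy of the response, so carriers
#' are enriched for synergy; the other listed genes get independent
#' low-frequency flags.
#'
#' @param truth a `cohort_ground_truth` from [simulate_cohort()] (used
#'   for the culture identifiers).
#' @param n_features features per matrix (default 500).
#' @param n_causal causal features (default 5), `<= n_features`.
#' @param effect_size per-feature coefficient in the response (default 1,
#'   i.e. a planted standardized effect of 1 per causal feature).
#' @param noise_sd residual SD of the response (default 0.1).
#' @param cn_noise_sd extra noise between the causal transcript signal
#'   and the copy-number segment value.
#' @param n_mutants carriers of the planted mutation flag (default 8).
#' @param mutation_genes gene names for the mutation table; the first is
#'   the planted flag.
#' @param mutation_noise SD of the latent used to pick carriers.
#' @param seed integer seed.
#' @return List of class `molecular_profiles`: `expression`,
#'   `copynumber` (cultures x features), `mutations` (data.frame),
#'   `response`, `causal_expression`, `causal_copynumber` (feature
#'   names), `planted_gene`, `seed`.
#' @export
simulate_molecular <- function(truth, n_features = 500, n_causal = 5,
                               effect_size = 1, noise_sd = 0.1,
                               cn_noise_sd = 0.5, n_mutants = 8,
                               mutation_genes = c("EGFR", "NF1", "PDGFRA",
                                                  "PIK3CA", "PIK3R1",
                                                  "PTEN", "RB1", "RYR2",
                                                  "TP53", "TTN"),
                               mutation_noise = 1, seed = 1L) {
  stopifnot(inherits(truth, "cohort_ground_truth"),
            n_causal <= n_features)
  cids <- names(truth$sigma)
  n <- length(cids)
  if (abs(effect_size) + noise_sd == 0)
    stop("degenerate effect: the planted response has zero variance")
  with_seed(seed, {
    feat_names <- sprintf("GENE%04d", seq_len(n_features))
    expr <- matrix(stats::rnorm(n * n_features), n, n_features,
                   dimnames = list(cids, feat_names))
    causal_e <- sample(n_features, n_causal)

    signal <- drop(expr[, causal_e, drop = FALSE] %*%
                     rep(effect_size, n_causal))
    response <- signal + stats::rnorm(n, 0, noise_sd)
    names(response) <- cids

    # focal segment: dosage tracks the causal transcript signal
    cn <- matrix(stats::rnorm(n * n_features), n, n_features,
                 dimnames = list(cids,
                                 sprintf("SEGGENE%04d", seq_len(n_features))))
    seg_start <- sample(n_features - n_causal + 1, 1)
    causal_c <- seg_start:(seg_start + n_causal - 1)
    seg_value <- as.numeric(scale(signal)) + stats::rnorm(n, 0, cn_noise_sd)
    for (j in causal_c)
      cn[, j] <- seg_value + stats::rnorm(n, 0, 0.25)

    latent <- as.numeric(scale(response)) + stats::rnorm(n, 0,
                                                         mutation_noise)
    planted <- as.integer(rank(-latent, ties.method = "first") <= n_mutants)
    muts <- data.frame(culture_id = cids)
    muts[[mutation_genes[1]]] <- planted
    for (g in mutation_genes[-1])
      muts[[g]] <- stats::rbinom(n, 1, 0.15)

    structure(list(expression = expr, copynumber = cn, mutations = muts,
                   response = response,
                   causal_expression = feat_names[causal_e],
                   causal_copynumber = colnames(cn)[causal_c],
                   planted_gene = mutation_genes[1], seed = seed),
              class = "molecular_profiles")
  })
}

#' Logistic dose interpolation of cell-cycle phase weights
#'
#' Interpolates phase-weight triples (G1, S, G2M) between a low-dose and a
#' high-dose composition along a logistic curve in log10 dose.
#'
#' @param doses positive doses (uM).
#' @param start,end weight triples at the low- and high-dose ends; each
#'   must sum to 1.
#' @param steepness logistic steepness on the rescaled log-dose axis.
#' @return Matrix `length(doses) x 3` with columns G1, S, G2M, rows
#'   summing to 1.
#' @export
default_phase_weights <- function(doses, start = c(0.60, 0.25, 0.15),
                                  end = c(0.35, 0.40, 0.25),
                                  steepness = 6) {
  stopifnot(all(doses > 0), abs(sum(start) - 1) < 1e-8,
            abs(sum(end) - 1) < 1e-8)
  t <- (log10(doses) - min(log10(doses))) /
    max(diff(range(log10(doses))), .Machine$double.eps)
  s <- stats::plogis(steepness * (t - 0.5))
  w <- outer(1 - s, start) + outer(s, end)
  colnames(w) <- c("G1", "S", "G2M")
  w
}

#' Simulate per-nucleus DNA-content intensities
#'
#' Draws nuclei for one culture at each dose from a three-component
#' DNA-content mixture: G1 ~ Normal(mu, cv_g1 * mu), G2/M ~ Normal(2 mu,
#' cv_g2 * 2 mu) (doubled DNA content) and S uniform on (1.15 mu,
#' 1.85 mu). Per-dose phase counts are multinomial in the supplied
#' weights.
#'
#' @param doses positive doses (uM).
#' @param weights matrix `length(doses) x 3` of G1/S/G2M weights, rows
#'   summing to 1 (see [default_phase_weights()]).
#' @param g1_mean G1 mode of integrated intensity (arbitrary units).
#' @param cv_g1,cv_g2 coefficients of variation of the G1 and G2/M peaks.
#' @param n_nuclei nuclei per dose; `0` returns an empty table.
#' @param culture_id culture label for the output rows.
#' @param seed integer seed.
#' @return data.frame with columns `culture_id, dose_uM, well_id,
#'   integrated_intensity`.
#' @export
simulate_dna_content <- function(doses, weights = default_phase_weights(doses),
                                 g1_mean = 1000, cv_g1 = 0.05,
                                 cv_g2 = 0.05, n_nuclei = 5000,
                                 culture_id = "SIM01", seed = 1L) {
  weights <- as.matrix(weights)
  stopifnot(nrow(weights) == length(doses), ncol(weights) == 3)
  if (any(weights < 0)) stop("phase weights must be non-negative")
  if (any(abs(rowSums(weights) - 1) > 1e-8))
    stop("phase weights must sum to 1 at every dose")
  empty <- data.frame(culture_id = character(), dose_uM = numeric(),
                      well_id = character(),
                      integrated_intensity = numeric())
  if (n_nuclei == 0) return(empty)
  with_seed(seed, {
    rows <- lapply(seq_along(doses), function(i) {
      counts <- as.vector(stats::rmultinom(1, n_nuclei, weights[i, ]))
      g1 <- stats::rnorm(counts[1], g1_mean, cv_g1 * g1_mean)
      s <- stats::runif(counts[2], 1.15 * g1_mean, 1.85 * g1_mean)
      g2 <- stats::rnorm(counts[3], 2 * g1_mean, cv_g2 * 2 * g1_mean)
      intens <- pmax(c(g1, s, g2), g1_mean * 0.05)  # keep intensities > 0
      data.frame(culture_id = culture_id, dose_uM = doses[i],
                 well_id = sprintf("%s_d%02d", culture_id, i),
                 integrated_intensity = intens)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a cohort of DNA-content dose series
#'
#' Independent cultures, each with its own G1 intensity location (15%
#' log-normal spread) and slightly jittered phase-weight endpoints around
#' the [default_phase_weights()] shift from a G1-rich to an S/G2M-enriched
#' composition.
#'
#' @param n_cultures number of cultures (default 14).
#' @param doses shared dose series (uM).
#' @param n_nuclei nuclei per (culture, dose).
#' @param endpoint_jitter_sd SD of the jitter on weight endpoints.
#' @param seed integer seed.
#' @return One combined nucleus table (see [simulate_dna_content()]).
#' @export
simulate_cellcycle_cohort <- function(n_cultures = 14,
                                      doses = c(2.5, 5, 10, 20, 40, 80),
                                      n_nuclei = 4000,
                                      endpoint_jitter_sd = 0.03,
                                      seed = 1L) {
  with_seed(seed, {
    tabs <- lapply(seq_len(n_cultures), function(j) {
      mu <- 1000 * exp(stats::rnorm(1, 0, 0.15))
      jitter_w <- function(w) {
        w <- pmax(w + stats::rnorm(3, 0, endpoint_jitter_sd), 0.02)
        w / sum(w)
      }
      wts <- default_phase_weights(doses,
                                   start = jitter_w(c(0.60, 0.25, 0.15)),
                                   end = jitter_w(c(0.35, 0.40, 0.25)))
      simulate_dna_content(doses, wts, g1_mean = mu, n_nuclei = n_nuclei,
                           culture_id = sprintf("GC%02d", j),
                           seed = child_seed(seed, j))
    })
    do.call(rbind, tabs)
  })
}

#' Simulate a 2x2 factorial viability table
#'
#' Cell means follow the factorial model of
#' [factorial_interaction_lm()] with iid Gaussian noise.
#'
#' @param w0 baseline viability (both factors off).
#' @param d_a,d_b,d_inter planted main effects and interaction.
#' @param noise_sd residual SD.
#' @param n_per_cell replicates per design cell (>= 2).
#' @param seed integer seed.
#' @return data.frame with columns `replicate, factor_a, factor_b,
#'   viability_ratio`.
#' @export
simulate_factorial <- function(w0 = 1, d_a = -0.1, d_b = -0.2,
                               d_inter = 0, noise_sd = 0.02,
                               n_per_cell = 5, seed = 1L) {
  stopifnot(n_per_cell >= 2, noise_sd >= 0)
  cells <- expand.grid(factor_a = c("off", "on"),
                       factor_b = c("off", "on"),
                       stringsAsFactors = FALSE)
  cells$mean <- w0 + d_a * (cells$factor_a == "on") +
    d_b * (cells$factor_b == "on") +
    d_inter * (cells$factor_a == "on" & cells$factor_b == "on")
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(cells)), function(i) data.frame(
      replicate = seq_len(n_per_cell),
      factor_a = cells$factor_a[i], factor_b = cells$factor_b[i],
      viability_ratio = cells$mean[i] + stats::rnorm(n_per_cell, 0,
                                                     noise_sd)))
    do.call(rbind, rows)
  })
}
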