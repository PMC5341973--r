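#' End-to-end screen analysis
#'
#' Runs the full combination-screen pipeline: viability normalization
#' against vehicle controls, per-culture four-parameter log-logistic fits
#' of the single-drug and fixed-ratio combination series (on replicate-
#' mean ratios), per-culture Bliss interaction scores and combination
#' indices over the effect band, and cohort-level Wilcoxon statistics per
#' pair. The result is a pure function of (inputs, config, seed).
#'
#' @param config a list (or path to a YAML file) with entries:
#'   \describe{
#'     \item{simulate}{a [simulation_config()] (a synthetic cohort is
#'       generated), or}
#'     \item{screen_file / cultures_file}{paths read via [read_screen()],
#'       plus `designs` (named list of [combination_design()]s);}
#'     \item{pairs}{pair labels to score (default: all designs);}
#'     \item{control_scope}{`"plate"` (default) or `"culture"`;}
#'     \item{single_source}{`"measured"` (default) or `"fitted"`;}
#'     \item{band, n_grid}{combination-index band (default `c(0.4, 0.6)`)
#'       and grid size (21);}
#'     \item{fix_upper}{fix the LL4 upper asymptote at 1 (default FALSE);}
#'     \item{per_replicate}{fit per replicate instead of replicate means
#'       (default FALSE).}
#'   }
#' @param seed integer seed (used by the simulator; recorded in the
#'   report).
#' @return List of class `screen_report`: `per_culture` (data.frame with
#'   `culture_id, pair, mean_IS, mean_CI, n_defined_levels, flags`),
#'   `cohort` (one row per pair), `fits`, `truth` (when simulated),
#'   `config`, `seed`.
#' @export
run_screen_analysis <- function(config, seed = 1L) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(list(control_scope = "plate",
                                single_source = "measured",
                                band = c(0.4, 0.6), n_grid = 21,
                                fix_upper = FALSE, per_replicate = FALSE,
                                min_cohort_n = 6),
                           config)
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    sim_cfg <- if (inherits(cfg$simulate, "simulation_config")) cfg$simulate
               else do.call(simulation_config, cfg$simulate)
    sim <- simulate_cohort(sim_cfg, seed = seed)
    dataset <- sim$dataset
    truth <- sim$truth
  } else if (!is.null(cfg$screen_file)) {
    dataset <- read_screen(cfg$screen_file, cultures = cfg$cultures_file,
                           designs = cfg$designs)
  } else stop("config must provide either 'simulate' or 'screen_file'")
  if (is.null(dataset$designs) || !length(dataset$designs))
    stop("no combination designs available")

  pairs <- if (is.null(cfg$pairs)) names(dataset$designs) else cfg$pairs
  unknown <- setdiff(pairs, names(dataset$designs))
  if (length(unknown))
    stop("unknown compound pair(s): ", paste(unknown, collapse = ", "))

  wtab <- normalize_viability(dataset, control_scope = cfg$control_scope)
  cultures <- unique(wtab$culture_id[!wtab$is_control])

  fits <- list()
  rows <- list()
  for (pn in pairs) {
    des <- dataset$designs[[pn]]
    for (cid in cultures) {
      res <- tryCatch(
        score_culture_pair(wtab[wtab$culture_id == cid, ], des, cfg, fits,
                           cid),
        error = function(e)
          stop(sprintf("stage 'score' failed for culture %s, pair %s: %s",
                       cid, pn, conditionMessage(e)), call. = FALSE))
      fits <- res$fits
      rows[[length(rows) + 1]] <- data.frame(
        culture_id = cid, pair = pn, mean_IS = res$mean_IS,
        mean_CI = res$mean_CI, n_defined_levels = res$n_defined_levels,
        flags = res$flags, stringsAsFactors = FALSE)
    }
  }
  per_culture <- do.call(rbind, rows)

  cohort <- do.call(rbind, lapply(pairs, function(pn) {
    sub <- per_culture[per_culture$pair == pn, ]
    st <- cohort_synergy_stats(sub$mean_IS, sub$mean_CI, pair = pn,
                               min_n = cfg$min_cohort_n)
    data.frame(pair = pn, n_cultures = st$n_cultures,
               median_IS = st$median_IS, wilcoxon_p_IS = st$wilcoxon_p_IS,
               median_CI = st$median_CI, wilcoxon_p_CI = st$wilcoxon_p_CI,
               stringsAsFactors = FALSE)
  }))

  structure(list(per_culture = per_culture, cohort = cohort, fits = fits,
                 truth = truth, config = cfg, seed = seed),
            class = "screen_report")
}

## fit singles + combination for one (culture, pair) and score IS and CI;
## memoizes single-drug fits across pairs sharing a compound
score_culture_pair <- function(wsub, des, cfg, fits, cid) {
  mean_ratios <- function(sel, dose_col) {
    d <- wsub[[dose_col]][sel]
    w <- wsub$W[sel]
    if (cfg$per_replicate) return(list(d = d, w = w))
    agg <- tapply(w, d, mean)
    list(d = as.numeric(names(agg)), w = as.numeric(agg))
  }
  get_single_fit <- function(compound) {
    key <- paste(cid, compound, sep = "|")
    if (!is.null(fits[[key]])) return(fits[[key]])
    sel <- wsub$compound_a == compound & wsub$compound_b == "" &
      !wsub$is_control
    mr <- mean_ratios(sel, "dose_a_uM")
    fits[[key]] <<- fit_ll4(mr$d, mr$w, fix_upper = cfg$fix_upper)
    fits[[key]]
  }
  fit_a <- get_single_fit(des$compound_a)
  fit_b <- get_single_fit(des$compound_b)
  sel_ab <- wsub$compound_a == des$compound_a &
    wsub$compound_b == des$compound_b & !wsub$is_control
  mr_ab <- mean_ratios(sel_ab, "dose_a_uM")
  fit_ab <- fit_ll4(mr_ab$d, mr_ab$w, fix_upper = cfg$fix_upper)
  fits[[paste(cid, pair_label(des), sep = "|")]] <- fit_ab

  flags <- character()
  isr <- interaction_score_screen(wsub, des, single_source =
                                    cfg$single_source,
                                  fit_a = fit_a, fit_b = fit_b)
  mean_is <- isr$mean_IS
  if (!is.na(isr$reason)) flags <- c(flags, isr$reason)

  flat <- any(c("flat" %in% fit_a$flags, "flat" %in% fit_b$flags,
                "flat" %in% fit_ab$flags))
  if (flat || !fit_a$converged || !fit_b$converged || !fit_ab$converged) {
    mean_ci <- NA_real_
    n_def <- 0L
    flags <- c(flags, if (flat) "flat_fit" else "nonconverged_fit")
  } else {
    cir <- combination_index(fit_a, fit_b, fit_ab, des, band = cfg$band,
                             n_grid = cfg$n_grid)
    mean_ci <- cir$mean_CI
    n_def <- cir$n_defined_levels
    if (!is.na(cir$reason)) flags <- c(flags, cir$reason)
  }
  list(fits = fits, mean_IS = mean_is, mean_CI = mean_ci,
       n_defined_levels = n_def,
       flags = paste(flags, collapse = ";"))
}

#' @export
print.screen_report <- function(x, ...) {
  cat("Combination screen report:",
      length(unique(x$per_culture$culture_id)), "cultures,",
      length(unique(x$per_culture$pair)), "pair(s)\n\n")
  print(x$cohort, row.names = FALSE)
  invisible(x)
}

#' Write the per-culture synergy report
#'
#' @param report a `screen_report`.
#' @param path output TSV path.
#' @export
write_synergy_report <- function(report, path) {
  stopifnot(inherits(report, "screen_report"))
  utils::write.table(report$per_culture, path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
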