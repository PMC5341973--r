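#' Four-parameter log-logistic dose-response objects
#'
#' The package models control-normalized viability as a decreasing sigmoid
#' of dose,
#' \deqn{W(d) = L + \frac{U - L}{1 + (d/e)^h},}
#' with upper asymptote `U` (viability at zero dose), lower asymptote `L`,
#' midpoint dose `e` (in uM) and slope `h > 0`. This is the standard
#' four-parameter log-logistic used by common dose-response software,
#' parameterized so that the inverse has a closed form.
#'
#' @param U,L upper and lower asymptote (dimensionless viability ratios),
#'   `L < U`.
#' @param e midpoint dose in uM, strictly positive.
#' @param h slope parameter, strictly positive for decreasing viability.
#' @return An object of class `ll4_fit`.
#' @examples
#' f <- ll4(U = 1, L = 0.1, e = 5, h = 2)
#' ll4_predict(f, c(0, 5, 10))
#' @export
ll4 <- function(U, L, e, h) {
  new_ll4(U, L, e, h, rss = 0, n_points = 0L, converged = TRUE)
}

new_ll4 <- function(U, L, e, h, rss = NA_real_, n_points = NA_integer_,
                    converged = FALSE, flags = character()) {
  stopifnot(is.numeric(U), is.numeric(L), is.numeric(e), is.numeric(h))
  if (!("flat" %in% flags)) {
    if (!is.finite(e) || e <= 0) stop("midpoint dose 'e' must be > 0")
    if (!is.finite(h) || h <= 0) stop("slope 'h' must be > 0")
    if (L >= U) stop("lower asymptote must lie below the upper asymptote")
  }
  structure(
    list(U = U, L = L, e = e, h = h, rss = rss,
         n_points = as.integer(n_points), converged = isTRUE(converged),
         flags = flags),
    class = "ll4_fit"
  )
}

#' @export
print.ll4_fit <- function(x, ...) {
  cat(sprintf(
    "LL4 fit: U = %.4g, L = %.4g, e = %.4g uM, h = %.4g (rss %.4g, %s)\n",
    x$U, x$L, x$e, x$h, x$rss,
    if (x$converged) "converged" else paste0("NOT converged",
      if (length(x$flags)) paste0(": ", paste(x$flags, collapse = ","))
      else "")))
  invisible(x)
}

#' Evaluate a log-logistic fit at given doses
#'
#' @param fit an [ll4()] / [fit_ll4()] object.
#' @param d dose(s) in uM, non-negative.
#' @return Predicted viability ratio(s); `W(0) = U` and the curve is
#'   monotone non-increasing in dose.
#' @export
ll4_predict <- function(fit, d) {
  stopifnot(inherits(fit, "ll4_fit"))
  if (any(!is.finite(d)) || any(d < 0)) stop("doses must be finite and >= 0")
  fit$L + (fit$U - fit$L) / (1 + (d / fit$e)^fit$h)
}

#' Invert a log-logistic fit at an effect level
#'
#' Effect is expressed as an inhibition fraction `y = 1 - W`. The single-drug
#' dose achieving effect `y` exists only when the target viability `1 - y`
#' lies strictly between the asymptotes; otherwise the level is
#' unattainable and `NA` is returned.
#'
#' @param fit an `ll4_fit` object.
#' @param y effect level(s) in (0, 1), as inhibition fractions.
#' @return Dose(s) in uM, or `NA_real_` where the effect level is
#'   unattainable for this curve.
#' @export
ll4_inverse <- function(fit, y) {
  stopifnot(inherits(fit, "ll4_fit"))
  if (any(!is.finite(y)) || any(y <= 0) || any(y >= 1))
    stop("effect level y must lie strictly inside (0, 1)")
  w <- 1 - y
  out <- rep(NA_real_, length(y))
  ok <- w > fit$L & w < fit$U
  out[ok] <- fit$e * ((fit$U - w[ok]) / (w[ok] - fit$L))^(1 / fit$h)
  out
}

## internal generics so the combination-index code can treat a fitted LL4
## curve and a derived Bliss-product curve uniformly
viability_at <- function(object, d) UseMethod("viability_at")
dose_for <- function(object, y) UseMethod("dose_for")

#' @export
viability_at.ll4_fit <- function(object, d) ll4_predict(object, d)
#' @export
dose_for.ll4_fit <- function(object, y) ll4_inverse(object, y)

#' Fit a four-parameter log-logistic curve
#'
#' Bounded nonlinear least squares with five deterministic data-driven
#' starts (`U` from the largest ratio, `L` from the smallest, midpoint
#' candidates at the dose nearest half-range and at the geometric mean
#' dose, slopes 0.5/1/2); the start reaching the lowest residual sum of
#' squares wins and ties are broken toward the smaller slope. Default
#' bounds are `L` in [0, 1], `U` in [0.5, 1.5], `e` within a tenfold
#' extension of the tested dose range and `h` in (0, 10].
#'
#' @param doses dose series in uM; at least 4 distinct positive doses.
#'   Zero doses are allowed and constrain the upper asymptote.
#' @param ratios viability ratios, same length as `doses`.
#' @param fix_upper logical; fix `U = 1` (ratios are control-normalized).
#' @param h_max upper bound for the slope parameter.
#' @return An `ll4_fit` with `rss`, `n_points`, a `converged` flag and
#'   `flags` recording active bounds or degeneracy (`"flat"` when all
#'   ratios are identical; such fits must not be used for synergy scoring).
#' @export
fit_ll4 <- function(doses, ratios, fix_upper = FALSE, h_max = 10) {
  stopifnot(length(doses) == length(ratios))
  if (any(!is.finite(doses)) || any(doses < 0))
    stop("doses must be finite and >= 0")
  if (any(!is.finite(ratios))) stop("ratios must be finite")
  pos <- unique(doses[doses > 0])
  if (length(pos) < 4)
    stop("need at least 4 distinct positive doses, got ", length(pos))

  if (diff(range(ratios)) < 1e-10) {
    return(new_ll4(U = mean(ratios), L = mean(ratios), e = median(pos),
                   h = 1, rss = sum((ratios - mean(ratios))^2),
                   n_points = length(ratios), converged = FALSE,
                   flags = "flat"))
  }

  dmin <- min(pos); dmax <- max(pos)
  lb_e <- log10(dmin / 10); ub_e <- log10(dmax * 10)
  lb_h <- log10(1e-2); ub_h <- log10(h_max)
  U0 <- min(max(max(ratios), 0.5), 1.5)
  L0 <- min(max(min(ratios), 0), 1)
  if (L0 >= U0) L0 <- max(U0 - 0.05, 0)

  # midpoint heuristics: dose whose mean ratio is nearest half-range, and
  # the geometric mean of the tested doses
  mid_target <- (U0 + L0) / 2
  mr <- vapply(pos, function(d) mean(ratios[doses == d]), numeric(1))
  e_half <- pos[which.min(abs(mr - mid_target))]
  e_geo <- exp(mean(log(pos)))
  starts <- list(c(e_half, 0.5), c(e_half, 1), c(e_half, 2),
                 c(e_geo, 1), c(e_geo, 2))

  obj <- if (fix_upper) {
    function(p) {
      w <- p[1] + (1 - p[1]) / (1 + (doses / 10^p[2])^(10^p[3]))
      sum((ratios - w)^2)
    }
  } else {
    function(p) {
      w <- p[2] + (p[1] - p[2]) / (1 + (doses / 10^p[3])^(10^p[4]))
      sum((ratios - w)^2)
    }
  }

  best <- NULL
  for (s in starts) {
    par0 <- if (fix_upper) c(L0, log10(s[1]), log10(s[2]))
            else c(U0, L0, log10(s[1]), log10(s[2]))
    lo <- if (fix_upper) c(0, lb_e, lb_h) else c(0.5, 0, lb_e, lb_h)
    hi <- if (fix_upper) c(1, ub_e, ub_h) else c(1.5, 1, ub_e, ub_h)
    par0 <- pmin(pmax(par0, lo), hi)
    res <- tryCatch(
      stats::optim(par0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                   control = list(maxit = 500, factr = 1e3)),
      error = function(e) NULL)
    if (is.null(res)) next
    res$start_h <- s[2]
    if (is.null(best) || res$value < best$value - 1e-12 ||
        (abs(res$value - best$value) <= 1e-12 && s[2] < best$start_h))
      best <- res
  }
  if (is.null(best)) stop("all optimizer starts failed")

  # L-BFGS-B occasionally reports an abnormal line-search exit at the
  # optimum; polish from the best point and accept if no real progress
  if (best$convergence != 0) {
    lo <- if (fix_upper) c(0, lb_e, lb_h) else c(0.5, 0, lb_e, lb_h)
    hi <- if (fix_upper) c(1, ub_e, ub_h) else c(1.5, 1, ub_e, ub_h)
    polish <- tryCatch(
      stats::optim(best$par, obj, method = "L-BFGS-B", lower = lo,
                   upper = hi, control = list(maxit = 500, factr = 1e7)),
      error = function(e) NULL)
    if (!is.null(polish)) {
      improved <- best$value - polish$value
      if (polish$value <= best$value) {
        polish$start_h <- best$start_h
        best <- polish
      }
      if (best$convergence != 0 && improved < 1e-10) best$convergence <- 0
    }
  }

  p <- best$par
  if (fix_upper) {
    U <- 1; L <- p[1]; e <- 10^p[2]; h <- 10^p[3]
  } else {
    U <- p[1]; L <- p[2]; e <- 10^p[3]; h <- 10^p[4]
  }
  flags <- character()
  tol_b <- 1e-6
  if (!fix_upper && (abs(U - 0.5) < tol_b || abs(U - 1.5) < tol_b))
    flags <- c(flags, "U_at_bound")
  if (abs(L) < 0 + tol_b || abs(L - 1) < tol_b) flags <- c(flags, "L_at_bound")
  if (abs(log10(e) - lb_e) < tol_b || abs(log10(e) - ub_e) < tol_b)
    flags <- c(flags, "e_at_bound")
  if (abs(log10(h) - ub_h) < tol_b) flags <- c(flags, "h_at_bound")
  conv <- best$convergence == 0
  if (L >= U - 1e-8) {           # pathological: no decreasing signal left
    L <- min(L, U - 1e-8)
    flags <- c(flags, "collapsed_range")
    conv <- FALSE
  }
  new_ll4(U, L, e, h, rss = best$value, n_points = length(ratios),
          converged = conv, flags = flags)
}

#' Write a table of LL4 fits
#'
#' @param fits named list of `ll4_fit` objects; names of the form
#'   `"culture|treatment"` or a data.frame-compatible naming handled by the
#'   caller.
#' @param culture_id,treatment character vectors parallel to `fits`.
#' @param path output TSV path.
#' @return The data.frame written, invisibly.
#' @export
write_fit_table <- function(fits, culture_id, treatment, path) {
  stopifnot(length(fits) == length(culture_id),
            length(fits) == length(treatment))
  df <- data.frame(
    culture_id = culture_id, treatment = treatment,
    U = vapply(fits, `[[`, numeric(1), "U"),
    L = vapply(fits, `[[`, numeric(1), "L"),
    e_uM = vapply(fits, `[[`, numeric(1), "e"),
    h = vapply(fits, `[[`, numeric(1), "h"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    n_points = vapply(fits, `[[`, integer(1), "n_points"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    flags = vapply(fits, function(f) paste(f$flags, collapse = ";"),
                   character(1)),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
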