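#' Elastic-net regression of synergy on molecular features
#'
#' Fits the penalized least-squares objective
#' \deqn{\frac{1}{2N}\sum_i (y_i - \beta_0 - x_i'\beta)^2 +
#'   \lambda \sum_j \Big(\frac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|\Big)}
#' by cyclic coordinate descent on columns standardized to mean 0 and
#' (1/N) unit variance, with an unpenalized intercept. Convergence is
#' declared when the largest coefficient change in a full sweep falls
#' below `tol`. Coefficients are returned on the original feature scale.
#'
#' @param X numeric matrix, N cultures x p features (e.g. log2 expression
#'   or log2 copy number). No missing values.
#' @param y numeric response of length N (per-culture combination index).
#' @param lambda penalty strength, >= 0.
#' @param alpha lasso/ridge mixing parameter in [0, 1]; default 0.9.
#' @param tol convergence tolerance on coefficient changes.
#' @param max_sweeps cap on coordinate-descent sweeps.
#' @return An object of class `enet_fit` with `beta0`, named `beta`,
#'   `lambda`, `alpha`, `n_iter` and `converged`.
#' @seealso [loocv_tune()] for lambda selection, [enet_lambda_max()].
#' @export
elastic_net_fit <- function(X, y, lambda, alpha = 0.9, tol = 1e-7,
                            max_sweeps = 100000L) {
  prep <- enet_prepare(X, y, alpha)
  if (!is.finite(lambda) || lambda < 0) stop("lambda must be >= 0")
  res <- .cd_enet_path(prep$Xs, prep$yc, lambda, alpha, tol,
                       as.integer(max_sweeps))
  beta_std <- drop(res$beta)
  beta <- enet_original_scale(beta_std, prep)
  structure(list(beta0 = beta$beta0, beta = beta$beta, lambda = lambda,
                 alpha = alpha, n_iter = res$sweeps[1],
                 converged = res$converged[1] == 1L,
                 obj_trace = res$obj_trace),  # per-sweep objective values
            class = "enet_fit")
}

#' @export
predict.enet_fit <- function(object, newdata, ...) {
  drop(object$beta0 + as.matrix(newdata) %*% object$beta)
}

## standardize columns (mean 0, 1/N-variance 1) and center y; zero-variance
## columns are dropped from the solve and forced to zero with a warning
enet_prepare <- function(X, y, alpha) {
  X <- as.matrix(X)
  if (!is.numeric(X) || any(!is.finite(X))) stop("X must be finite numeric")
  if (any(!is.finite(y))) stop("y must be finite")
  N <- nrow(X)
  if (length(y) != N) stop("length(y) must equal nrow(X)")
  if (N < 5) stop("need at least 5 cultures")
  if (!is.finite(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2, mu)^2))
  zero_var <- sdv == 0
  if (any(zero_var))
    warning(sum(zero_var), " zero-variance feature(s); coefficients set to 0")
  keep <- which(!zero_var)
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  list(Xs = Xs, yc = y - mean(y), ybar = mean(y), mu = mu, sd = sdv,
       keep = keep, p = ncol(X),
       names = if (is.null(colnames(X))) paste0("f", seq_len(ncol(X)))
               else colnames(X))
}

enet_original_scale <- function(beta_std, prep) {
  beta <- numeric(prep$p)
  beta[prep$keep] <- beta_std / prep$sd[prep$keep]
  names(beta) <- prep$names
  list(beta0 = prep$ybar - sum(beta * prep$mu), beta = beta)
}

#' Smallest penalty with an all-zero solution
#'
#' `lambda_max = max_j |<x_j_std, y - ybar>| / (N * alpha)`; at or above
#' this penalty every coefficient is zero and the intercept equals the
#' response mean.
#'
#' @inheritParams elastic_net_fit
#' @export
enet_lambda_max <- function(X, y, alpha = 0.9) {
  prep <- enet_prepare(X, y, alpha)
  max(abs(crossprod(prep$Xs, prep$yc))) / (nrow(prep$Xs) * max(alpha, 1e-3))
}

#' Elastic-net objective value
#'
#' The penalized objective as minimized by [elastic_net_fit()], evaluated
#' for given coefficients on the scale of the supplied `X`.
#'
#' @inheritParams elastic_net_fit
#' @param beta0,beta intercept and coefficient vector.
#' @export
enet_objective <- function(X, y, beta0, beta, lambda, alpha = 0.9) {
  r <- y - beta0 - drop(as.matrix(X) %*% beta)
  sum(r^2) / (2 * length(y)) +
    lambda * sum((1 - alpha) / 2 * beta^2 + alpha * abs(beta))
}

#' Leave-one-out tuning of the elastic-net penalty
#'
#' For each lambda on a descending grid, N leave-one-out refits produce N
#' held-out predictions; the selected lambda maximizes the Pearson
#' correlation between observed and left-out predicted values (ties broken
#' toward the larger penalty). Feature selection frequency is the fraction
#' of the N leave-one-out fits, at the selected lambda, in which the
#' feature has a nonzero coefficient.
#'
#' @inheritParams elastic_net_fit
#' @param lambda_grid descending penalty grid; default 100 log-spaced
#'   values from `lambda_max` down to `lambda_max * 1e-3`.
#' @param nlambda,lambda_min_ratio grid size and range used when
#'   `lambda_grid` is `NULL`.
#' @param seed stored with the result (the procedure itself is
#'   deterministic).
#' @return An object of class `enet_cv`: `lambda_path`, `pearson_r_path`,
#'   `best_lambda`, `pearson_r`, `predicted` (left-out predictions at the
#'   best lambda), `selection_frequency` (named, per feature), `fits`
#'   (coefficient matrix at best lambda, features x folds) and `seed`.
#' @export
loocv_tune <- function(X, y, lambda_grid = NULL, alpha = 0.9,
                       nlambda = 100, lambda_min_ratio = 1e-3,
                       tol = 1e-7, max_sweeps = 100000L, seed = NULL) {
  X <- as.matrix(X)
  N <- nrow(X)
  if (stats::sd(y) == 0)
    stop("constant response: correlation is undefined")
  if (is.null(lambda_grid)) {
    lmax <- enet_lambda_max(X, y, alpha)
    lambda_grid <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                           length.out = nlambda))
  }
  if (!length(lambda_grid)) stop("empty lambda grid")
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)

  preds <- matrix(NA_real_, N, length(lambda_grid))
  beta_by_fold <- vector("list", N)
  for (i in seq_len(N)) {
    prep <- enet_prepare(X[-i, , drop = FALSE], y[-i], alpha)
    res <- .cd_enet_path(prep$Xs, prep$yc, lambda_grid, alpha, tol,
                         as.integer(max_sweeps))
    bmat <- matrix(0, prep$p, length(lambda_grid))
    bmat[prep$keep, ] <- res$beta / prep$sd[prep$keep]
    b0 <- prep$ybar - drop(crossprod(bmat, prep$mu))
    preds[i, ] <- b0 + drop(X[i, ] %*% bmat)
    beta_by_fold[[i]] <- bmat
  }

  r_path <- apply(preds, 2, function(p)
    if (stats::sd(p) == 0) -Inf else stats::cor(y, p))
  best_idx <- which(r_path == max(r_path))[1]  # grid descends: first = largest
  best_lambda <- lambda_grid[best_idx]
  sel_mat <- matrix(vapply(beta_by_fold, function(b) b[, best_idx] != 0,
                           logical(ncol(X))), nrow = ncol(X))
  sel <- rowMeans(sel_mat)
  names(sel) <- if (is.null(colnames(X))) paste0("f", seq_len(ncol(X)))
                else colnames(X)
  structure(list(lambda_path = lambda_grid, pearson_r_path = r_path,
                 best_lambda = best_lambda, pearson_r = r_path[best_idx],
                 predicted = preds[, best_idx],
                 selection_frequency = sel,
                 fits = vapply(beta_by_fold, function(b) b[, best_idx],
                               numeric(ncol(X))),
                 seed = seed),
            class = "enet_cv")
}

#' Association of combination index with group labels
#'
#' Three tests used for clinical / mutation predictors of synergy:
#' a Welch two-sample t-test on a binary flag, a one-way ANOVA across three
#' or more subtype groups, and a singleton z-test for a group of size one
#' (e.g. a single mutant culture): `z = (x_1 - mean(ref)) / sd(ref)` with a
#' two-sided normal p-value.
#'
#' @param ci per-culture combination index values.
#' @param groups parallel vector of labels or binary flags.
#' @param test `"t"`, `"z"` or `"anova"`.
#' @return List with `statistic`, `p`, `test` and group sizes.
#' @export
group_association <- function(ci, groups, test = c("t", "z", "anova")) {
  test <- match.arg(test)
  ok <- is.finite(ci) & !is.na(groups)
  ci <- ci[ok]; groups <- as.character(groups[ok])
  tab <- table(groups)
  if (test == "t") {
    if (length(tab) != 2 || any(tab < 2))
      stop("t test needs exactly 2 groups with n >= 2 each")
    if (stats::sd(ci) == 0)          # identical groups: no difference
      return(list(statistic = 0, p = 1, test = "t", n = as.vector(tab)))
    ht <- stats::t.test(ci ~ groups)
    list(statistic = unname(ht$statistic), p = ht$p.value, test = "t",
         n = as.vector(tab))
  } else if (test == "z") {
    if (sum(tab == 1) != 1 || length(tab) != 2)
      stop("z test needs one singleton group and one reference group")
    singleton <- names(tab)[tab == 1]
    x1 <- ci[groups == singleton]
    ref <- ci[groups != singleton]
    if (length(ref) < 2) stop("z test reference group needs n >= 2")
    z <- (x1 - mean(ref)) / stats::sd(ref)
    list(statistic = z, p = 2 * stats::pnorm(-abs(z)), test = "z",
         n = as.vector(tab))
  } else {
    if (length(tab) < 3 || any(tab < 2))
      stop("anova needs >= 3 groups with n >= 2 each")
    fit <- stats::aov(ci ~ factor(groups))
    s <- summary(fit)[[1]]
    list(statistic = s[["F value"]][1], p = s[["Pr(>F)"]][1],
         test = "anova", n = as.vector(tab))
  }
}

#' Correlation of combination index with a clinical covariate
#'
#' Pearson correlation with the usual t-approximation p-value; pairs with
#' a missing covariate are dropped and counted.
#'
#' @param ci per-culture combination index values.
#' @param covariate numeric covariate (e.g. age in years or survival in
#'   days), same length.
#' @return List with `r`, `p`, `n`, `n_dropped`.
#' @export
clinical_correlation <- function(ci, covariate) {
  stopifnot(length(ci) == length(covariate))
  ok <- is.finite(ci) & is.finite(covariate)
  if (sum(ok) < 5) stop("need at least 5 complete pairs")
  if (stats::sd(ci[ok]) == 0 || stats::sd(covariate[ok]) == 0)
    stop("zero variance in ci or covariate")
  ht <- stats::cor.test(ci[ok], covariate[ok], method = "pearson")
  list(r = unname(ht$estimate), p = ht$p.value, n = sum(ok),
       n_dropped = sum(!ok))
}

#' Read / write feature matrices and mutation tables
#'
#' Feature matrices are TSV with a `feature_id` first column and one
#' column per culture, holding log2 values (genes x cultures on disk; use
#' `t()` for the cultures x features orientation the models expect).
#' Mutation tables are TSV with `culture_id` rows and 0/1 gene columns.
#'
#' @param path TSV file path.
#' @return `read_feature_matrix` returns a numeric matrix with feature
#'   rownames and culture colnames; `read_mutation_table` a data.frame
#'   with `culture_id` plus 0/1 columns.
#' @export
read_feature_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "feature_id") stop("first column must be feature_id")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$feature_id
  storage.mode(m) <- "double"
  m
}

#' @rdname read_feature_matrix
#' @param m matrix features x cultures.
#' @export
write_feature_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_feature_matrix
#' @export
read_mutation_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "culture_id") stop("first column must be culture_id")
  df
}
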