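#' Mixed SCAD + ridge penalty specification
#'
#' The penalty applied to a coefficient vector is
#' \deqn{P(\beta) = \sum_j p_{SCAD}(|\beta_j|; \lambda_1, a) +
#'   (\lambda_2/2)\beta_j^2,\qquad \lambda_1 = \alpha\lambda,\
#'   \lambda_2 = (1-\alpha)\lambda,}
#' where `alpha` sets the SCAD share (0.1 in the analysis this package
#' supports: mostly ridge with mild sparsity) and `a` is the SCAD shape
#' parameter (canonical default 3.7). `df_max` caps the number of nonzero
#' coefficients along the regularization path (28 in the reference analysis).
#'
#' @param lambda overall regularization strength, >= 0.
#' @param alpha SCAD share in \[0, 1\].
#' @param a SCAD shape, > 2.
#' @param df_max maximum active-set size, >= 1.
#' @return a `penalty_spec` list.
#' @export
penalty_spec <- function(lambda = 1, alpha = 0.1, a = 3.7, df_max = 28) {
  stopifnot(lambda >= 0, alpha >= 0, alpha <= 1, a > 2, df_max >= 1)
  structure(list(lambda = lambda, alpha = alpha, a = a,
                 df_max = as.integer(df_max)),
            class = "penalty_spec")
}

scad_pen_scalar <- function(t, lam1, a) {
  ifelse(t <= lam1, lam1 * t,
         ifelse(t <= a * lam1,
                (2 * a * lam1 * t - t^2 - lam1^2) / (2 * (a - 1)),
                lam1^2 * (a + 1) / 2))
}

#' Mixed penalty value
#'
#' @param beta coefficient vector.
#' @param spec a [penalty_spec()].
#' @return scalar penalty value.
#' @export
penalty_value <- function(beta, spec) {
  lam1 <- spec$alpha * spec$lambda
  lam2 <- (1 - spec$alpha) * spec$lambda
  sum(scad_pen_scalar(abs(beta), lam1, spec$a) + lam2 / 2 * beta^2)
}

#' Proximal operator of the mixed SCAD + ridge penalty (unit weight)
#'
#' Closed-form solution of
#' `argmin_b 0.5 (b - z)^2 + p_SCAD(|b|; lam1, a) + (lam2/2) b^2`
#' in its three zones: soft-thresholding near zero, a linearly interpolated
#' middle zone, and no SCAD shrinkage (ridge only) beyond `a * lam1 * (1 + lam2)`.
#' Vectorized over `z`.
#'
#' @param z numeric vector.
#' @param spec a [penalty_spec()].
#' @return the minimizing coefficients, same length as `z`.
#' @export
prox_coord <- function(z, spec) {
  lam1 <- spec$alpha * spec$lambda
  lam2 <- (1 - spec$alpha) * spec$lambda
  a <- spec$a
  az <- abs(z); s <- sign(z)
  out <- z / (1 + lam2)                                   # zone C
  zoneA <- az <= lam1 * (2 + lam2)
  zoneB <- !zoneA & az <= a * lam1 * (1 + lam2)
  out[zoneA] <- s[zoneA] * pmax(az[zoneA] - lam1, 0) / (1 + lam2)
  out[zoneB] <- s[zoneB] * ((a - 1) * az[zoneB] - a * lam1) /
    ((a - 1) * (1 + lam2) - 1)
  out
}

check_standardized <- function(X, tol = 1e-4) {
  n <- nrow(X)
  ctr <- colMeans(X)
  scl <- sqrt(colSums(sweep(X, 2, ctr)^2) / n)
  if (max(abs(ctr)) > tol || max(abs(scl - 1)) > tol) {
    stop("X must be column-standardized (mean 0, sd 1 with the 1/n convention); ",
         "use scad_ridge() for automatic standardization")
  }
  invisible(TRUE)
}

#' Fit a SCAD + ridge (or lasso) penalized logistic regression
#'
#' Minimizes the mean logistic log-loss plus [penalty_value()] by IRLS
#' majorization (fixed curvature bound 1/4) with cyclic coordinate descent;
#' each scalar subproblem is solved exactly, so the penalized objective is
#' non-increasing across outer iterations even though the SCAD penalty is
#' nonconvex. The intercept is never penalized.
#'
#' @param X column-standardized predictor matrix (mean 0, sd 1, 1/n
#'   convention); see [scad_ridge()] for the standardizing front end.
#' @param y binary 0/1 outcome with both classes present.
#' @param spec a [penalty_spec()].
#' @param penalty `"scad_ridge"` or `"lasso"` (plain L1 at `lambda`).
#' @param init optional list with `intercept` and `beta` warm start.
#' @param tol convergence tolerance on the largest coordinate update.
#' @param max_iter outer iteration cap.
#' @param trace_objective record the objective at every outer iteration.
#' @return a `scad_ridge_fit` list: intercept, beta, active_set, df, n_iter,
#'   converged, objective (and `objective_trace` when requested).
#' @export
scad_ridge_fit <- function(X, y, spec, penalty = c("scad_ridge", "lasso"),
                           init = NULL, tol = 1e-8, max_iter = 500L,
                           trace_objective = FALSE) {
  penalty <- match.arg(penalty)
  if (!is_binary01(y)) stop("y must be binary 0/1 with both classes present")
  check_standardized(X)
  ptype <- if (penalty == "lasso") 1L else 0L
  lam1 <- if (ptype == 1L) spec$lambda else spec$alpha * spec$lambda
  lam2 <- if (ptype == 1L) 0 else (1 - spec$alpha) * spec$lambda
  b0 <- init$intercept %||% qlogis(mean(y))
  beta0 <- init$beta %||% numeric(ncol(X))
  f <- cpp_scad_fit(X, as.numeric(y), lam1, lam2, spec$a, ptype,
                    b0, beta0, tol, as.integer(max_iter), trace_objective)
  beta <- as.numeric(f$beta)
  names(beta) <- colnames(X)
  structure(list(intercept = f$intercept, beta = beta,
                 active_set = which(beta != 0), df = f$df,
                 n_iter = f$n_iter, converged = f$converged,
                 objective = f$objective,
                 objective_trace = if (trace_objective) as.numeric(f$objective_trace),
                 spec = spec, penalty = penalty),
            class = "scad_ridge_fit")
}

#' Largest useful lambda for a path
#'
#' `lambda_max = max_j |x_j' (y - mean(y))| / (n * max(alpha, 0.001))`, the
#' smallest lambda at which the active set is empty.
#'
#' @param X standardized predictors; @param y binary outcome.
#' @param alpha SCAD share (use 1 for lasso).
#' @return scalar lambda.
#' @export
lambda_max <- function(X, y, alpha) {
  max(abs(crossprod(X, y - mean(y)))) / (nrow(X) * max(alpha, 0.001))
}

#' Warm-started regularization path
#'
#' Fits a log-spaced descending lambda sequence starting at [lambda_max()],
#' warm-starting each fit from its predecessor; the path stops at the first
#' lambda whose active set exceeds `df_max` (that fit is discarded).
#'
#' @inheritParams scad_ridge_fit
#' @param spec_template a [penalty_spec()]; its `lambda` is ignored.
#' @param n_lambda grid length (default 100).
#' @param lambda_min_ratio smallest lambda as a fraction of `lambda_max`.
#' @param lambdas optional explicit descending grid (overrides the above).
#' @return a `scad_ridge_path` list: lambdas (kept), betas (p x kept),
#'   intercepts, df, converged, objective, truncated_at (0 when never
#'   truncated).
#' @export
fit_path <- function(X, y, spec_template = penalty_spec(),
                     penalty = c("scad_ridge", "lasso"),
                     n_lambda = 100L, lambda_min_ratio = 0.01,
                     lambdas = NULL, tol = 1e-7, max_iter = 200L) {
  penalty <- match.arg(penalty)
  if (!is_binary01(y)) stop("y must be binary 0/1 with both classes present")
  check_standardized(X)
  ptype <- if (penalty == "lasso") 1L else 0L
  alpha <- if (ptype == 1L) 1 else spec_template$alpha
  if (is.null(lambdas)) {
    lmax <- lambda_max(X, y, alpha)
    lambdas <- exp(seq(log(lmax), log(lmax * lambda_min_ratio),
                       length.out = n_lambda))
  }
  stopifnot(all(diff(lambdas) < 0))
  res <- cpp_scad_path(X, as.numeric(y), lambdas, alpha, spec_template$a,
                       ptype, spec_template$df_max, tol, as.integer(max_iter))
  kept <- res$kept
  betas <- res$betas[, seq_len(kept), drop = FALSE]
  rownames(betas) <- colnames(X)
  structure(list(lambdas = lambdas[seq_len(kept)], betas = betas,
                 intercepts = res$intercepts[seq_len(kept)],
                 df = res$df[seq_len(kept)],
                 converged = res$converged[seq_len(kept)],
                 objective = res$objective[seq_len(kept)],
                 truncated_at = res$truncated_at,
                 spec = spec_template, penalty = penalty),
            class = "scad_ridge_path")
}

binomial_deviance <- function(y, prob) {
  eps <- 1e-12
  prob <- pmin(pmax(prob, eps), 1 - eps)
  -2 * mean(y * log(prob) + (1 - y) * log(1 - prob))
}

#' Select lambda by stratified k-fold cross-validation
#'
#' A common descending grid is built on the full data; per fold, the path is
#' refitted on the training part and out-of-fold predictions are scored with
#' the binomial deviance (default) or AUC. Lambdas not reachable in every
#' fold (df_max truncation) are dropped. Ties break toward the larger lambda.
#'
#' @inheritParams fit_path
#' @param k number of folds (default 5).
#' @param criterion `"deviance"` (minimized) or `"auc"` (maximized).
#' @param seed integer seed controlling the fold assignment.
#' @return list with `lambda` (the selected value), `cv_curve` (data.frame
#'   lambda, mean criterion, n_folds) and the full-data `path`.
#' @export
cv_select_lambda <- function(X, y, spec_template = penalty_spec(),
                             penalty = c("scad_ridge", "lasso"), k = 5L,
                             criterion = c("deviance", "auc"), seed = 1L,
                             n_lambda = 100L, lambda_min_ratio = 0.01,
                             tol = 1e-7, max_iter = 200L) {
  penalty <- match.arg(penalty)
  criterion <- match.arg(criterion)
  if (length(y) < 2 * k) stop("need n >= 2k for ", k, "-fold CV")
  path <- fit_path(X, y, spec_template, penalty, n_lambda = n_lambda,
                   lambda_min_ratio = lambda_min_ratio, tol = tol,
                   max_iter = max_iter)
  lambdas <- path$lambdas
  folds <- with_seed(seed, stratified_folds(y, k))
  score <- matrix(NA_real_, k, length(lambdas))
  for (f in seq_len(k)) {
    tr <- folds != f; te <- !tr
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      stop("a class is absent from fold ", f, "; reduce k or rebalance")
    }
    # restandardize within the training part of the fold; map the test part
    # with the training parameters (no leakage)
    std <- standardize_columns(X[tr, , drop = FALSE])
    Xtr <- std$x
    Xte <- sweep(sweep(X[te, , drop = FALSE], 2, std$center), 2, std$scale, "/")
    pf <- fit_path(Xtr, y[tr], spec_template, penalty, lambdas = lambdas,
                   tol = tol, max_iter = max_iter)
    nl <- length(pf$lambdas)
    if (nl == 0) next
    eta <- sweep(Xte %*% pf$betas, 2, pf$intercepts, "+")
    prob <- plogis(eta)
    for (l in seq_len(nl)) {
      score[f, l] <- if (criterion == "deviance") {
        binomial_deviance(y[te], prob[, l])
      } else {
        score_auc(prob[, l], y[te])
      }
    }
  }
  ok <- colSums(!is.na(score)) == k
  if (!any(ok)) stop("no lambda reachable in every fold")
  mean_score <- colMeans(score)
  cand <- which(ok)
  best <- if (criterion == "deviance") {
    cand[which.min(mean_score[cand])]
  } else {
    cand[which.max(mean_score[cand])]
  }
  list(lambda = lambdas[best], index = best,
       cv_curve = data.frame(lambda = lambdas, score = mean_score,
                             n_folds = colSums(!is.na(score))),
       path = path)
}

#' Standardizing front end for the penalized logistic solver
#'
#' Standardizes the predictors (1/n convention), fits on the standardized
#' scale and stores the standardization so that [predict.scad_ridge_fit()]
#' accepts new data on the original scale. Coefficients are reported on both
#' scales.
#'
#' @param X predictor matrix on the original (NPX) scale.
#' @param y binary outcome.
#' @inheritParams scad_ridge_fit
#' @return a `scad_ridge_fit` with `center`, `scale` and `beta_original`.
#' @export
scad_ridge <- function(X, y, spec = penalty_spec(),
                       penalty = c("scad_ridge", "lasso"), ...) {
  std <- standardize_columns(X)
  fit <- scad_ridge_fit(std$x, y, spec, penalty = penalty, ...)
  fit$center <- std$center
  fit$scale <- std$scale
  fit$beta_original <- fit$beta / std$scale
  fit$intercept_original <- fit$intercept - sum(fit$beta * std$center / std$scale)
  fit
}

#' Predict class-1 probabilities
#'
#' @param object a fit from [scad_ridge()] (original-scale input) or
#'   [scad_ridge_fit()] (standardized input).
#' @param newdata predictor matrix.
#' @param ... unused.
#' @return vector of probabilities in (0, 1).
#' @export
predict.scad_ridge_fit <- function(object, newdata, ...) {
  if (ncol(newdata) != length(object$beta)) {
    stop("newdata has ", ncol(newdata), " columns; fit expects ",
         length(object$beta))
  }
  if (!is.null(object$center)) {
    newdata <- sweep(sweep(newdata, 2, object$center), 2, object$scale, "/")
  }
  as.numeric(plogis(object$intercept + newdata %*% object$beta))
}

#' @export
print.scad_ridge_fit <- function(x, ...) {
  cat(sprintf("%s logistic fit: lambda=%.4g alpha=%.2f df=%d %s (iter %d)\n",
              x$penalty, x$spec$lambda, x$spec$alpha, x$df,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' KKT residual of a penalized logistic fit
#'
#' First-order stationarity measure: for active coefficients the absolute
#' gradient of the smooth part plus the penalty subgradient; for zero
#' coefficients the overshoot of the gradient beyond the threshold
#' `lambda_1`. The maximum over coordinates should be ~0 at convergence.
#'
#' @param fit a `scad_ridge_fit` on standardized data.
#' @param X,y the (standardized) training data.
#' @return the maximum absolute KKT violation.
#' @export
kkt_residual <- function(fit, X, y) {
  spec <- fit$spec
  lam1 <- if (fit$penalty == "lasso") spec$lambda else spec$alpha * spec$lambda
  lam2 <- if (fit$penalty == "lasso") 0 else (1 - spec$alpha) * spec$lambda
  a <- spec$a
  p <- plogis(fit$intercept + as.numeric(X %*% fit$beta))
  g <- -crossprod(X, y - p) / nrow(X)
  scad_deriv <- function(t) {
    ifelse(t <= lam1, lam1,
           ifelse(t <= a * lam1, pmax(a * lam1 - t, 0) / (a - 1), 0))
  }
  viol <- numeric(length(fit$beta))
  nz <- fit$beta != 0
  d1 <- if (fit$penalty == "lasso") lam1 else scad_deriv(abs(fit$beta[nz]))
  viol[nz] <- abs(g[nz] + d1 * sign(fit$beta[nz]) + lam2 * fit$beta[nz])
  viol[!nz] <- pmax(abs(g[!nz]) - lam1, 0)
  max(c(abs(mean(y - p)), viol))
}

#' Serialize a fit to JSON
#'
#' @param fit a `scad_ridge_fit`.
#' @param path output path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- fit[c("intercept", "beta", "active_set", "df", "n_iter",
               "converged", "objective", "penalty")]
  obj$spec <- unclass(fit$spec)
  obj$center <- fit$center; obj$scale <- fit$scale
  obj$beta_original <- fit$beta_original
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
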