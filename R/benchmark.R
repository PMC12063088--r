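#' Classifier family adapters
#'
#' Every family exposes the same contract: `fit(X, y)` on original-scale
#' predictors with binary 0/1 labels, and `predict_proba(model, X)` returning
#' a ranking score (probability or decision value — AUC only needs ranks).
#' Hyperparameters are tuned inside the training data.
#'
#' Families:
#' \describe{
#'   \item{scad_ridge_plr}{this package's SCAD+ridge penalized logistic
#'     regression; lambda tuned by inner CV.}
#'   \item{lasso_plr}{the same solver with a plain L1 penalty.}
#'   \item{random_forest}{compact in-package CART forest (bootstrap + mtry,
#'     Gini splits); mtry tuned by inner CV.}
#'   \item{svm_radial}{regularized radial-kernel classifier implemented as a
#'     least-squares SVM (kernel ridge on +/-1 labels); gamma and cost tuned
#'     by inner CV on AUC. Used because no SVM package is available in the
#'     offline runtime; decision values serve as ranking scores.}
#' }
#'
#' @param family one of `"scad_ridge_plr"`, `"lasso_plr"`,
#'   `"random_forest"`, `"svm_radial"`.
#' @param spec_template [penalty_spec()] for the PLR families.
#' @param inner_k inner CV folds used for tuning.
#' @param ntree forest size for `random_forest`.
#' @return a list with elements `name`, `fit`, `predict_proba`.
#' @export
model_family <- function(family = c("scad_ridge_plr", "lasso_plr",
                                    "random_forest", "svm_radial"),
                         spec_template = penalty_spec(), inner_k = 3L,
                         ntree = 100L) {
  family <- match.arg(family)
  if (family %in% c("scad_ridge_plr", "lasso_plr")) {
    pen <- if (family == "lasso_plr") "lasso" else "scad_ridge"
    list(
      name = family,
      fit = function(X, y, seed = 1L) {
        sel <- cv_select_lambda(standardize_columns(X)$x, y, spec_template,
                                penalty = pen, k = inner_k, seed = seed,
                                n_lambda = 30L, lambda_min_ratio = 0.05)
        spec <- spec_template; spec$lambda <- sel$lambda
        scad_ridge(X, y, spec, penalty = pen)
      },
      predict_proba = function(model, X) predict(model, X))
  } else if (family == "random_forest") {
    list(
      name = family,
      fit = function(X, y, seed = 1L) {
        p <- ncol(X)
        grid <- unique(pmax(1L, c(floor(sqrt(p)), floor(p / 3))))
        mtry <- if (length(grid) > 1) {
          with_seed(seed, tune_by_cv(X, y, grid, inner_k, function(m, tr, te) {
            fr <- cpp_rf_fit(X[tr, , drop = FALSE], y[tr], as.integer(ntree / 2),
                             m, 5L)
            score_auc(cpp_rf_predict(fr, X[te, , drop = FALSE]), y[te])
          }))
        } else grid[1]
        with_seed(derive_seed(seed, 1L),
                  list(forest = cpp_rf_fit(X, y, ntree, mtry, 5L), mtry = mtry))
      },
      predict_proba = function(model, X) as.numeric(cpp_rf_predict(model$forest, X)))
  } else {
    list(
      name = family,
      fit = function(X, y, seed = 1L) {
        std <- standardize_columns(X)
        gammas <- c(0.5, 1, 2) / ncol(X)
        costs <- c(1, 10)
        grid <- expand.grid(gamma = gammas, cost = costs)
        best <- with_seed(seed, tune_by_cv(std$x, y, seq_len(nrow(grid)),
                                           inner_k, function(gi, tr, te) {
          m <- lssvm_fit(std$x[tr, , drop = FALSE], y[tr],
                         grid$gamma[gi], grid$cost[gi])
          score_auc(lssvm_decision(m, std$x[te, , drop = FALSE]), y[te])
        }))
        m <- lssvm_fit(std$x, y, grid$gamma[best], grid$cost[best])
        m$center <- std$center; m$scale <- std$scale
        m
      },
      predict_proba = function(model, X) {
        Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
        lssvm_decision(model, Xs)
      })
  }
}

# Generic small-grid tuner: stratified inner_k-fold CV, mean AUC, first
# argmax wins. `eval_fun(par, train_idx, test_idx)` returns an AUC.
tune_by_cv <- function(X, y, grid, inner_k, eval_fun) {
  folds <- stratified_folds(y, inner_k)
  scores <- vapply(grid, function(par) {
    mean(vapply(seq_len(inner_k), function(f) {
      eval_fun(par, which(folds != f), which(folds == f))
    }, numeric(1)))
  }, numeric(1))
  grid[which.max(scores)]
}

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  exp(-gamma * (outer(an, bn, "+") - 2 * tcrossprod(A, B)))
}

# Least-squares SVM: solve [0 1'; 1 K + I/C] [b; alpha] = [0; yp] with
# yp = 2y - 1; decision f(x) = sum_i alpha_i K(x, x_i) + b.
lssvm_fit <- function(X, y, gamma, cost) {
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  A <- rbind(c(0, rep(1, n)), cbind(1, K + diag(n) / cost))
  sol <- solve(A, c(0, 2 * y - 1))
  list(alpha = sol[-1], b = sol[1], Xtrain = X, gamma = gamma, cost = cost)
}

lssvm_decision <- function(model, X) {
  as.numeric(rbf_kernel(X, model$Xtrain, model$gamma) %*% model$alpha + model$b)
}

#' Down-sample groups of a pair to equal size
#'
#' Uniform random subsample of the larger group(s) down to the smallest
#' group's size; composite group names are pooled before down-sampling (e.g.
#' `COLONIC_IBD` pools UC and colonic CD against ileal CD).
#'
#' @param groups group label per sample.
#' @param pair length-2 character vector of group names.
#' @param seed integer seed (deterministic selection).
#' @return list with `idx` (selected sample indices) and `y` (binary labels,
#'   first pair member = 1).
#' @export
downsample_groups <- function(groups, pair, seed = 1L) {
  ia <- group_index(groups, pair[1])
  ib <- group_index(groups, pair[2])
  if (!length(ia) || !length(ib)) {
    stop("empty group in pair ", pair[1], " vs ", pair[2])
  }
  m <- min(length(ia), length(ib))
  with_seed(seed, {
    ia <- sort(ia[sample.int(length(ia), m)])
    ib <- sort(ib[sample.int(length(ib), m)])
  })
  list(idx = c(ia, ib), y = rep(c(1, 0), each = m))
}

#' Repeated down-sampled cross-validated AUC for one pair and family
#'
#' Per repeat: a fresh balanced down-sample, a stratified k-fold split; per
#' fold, the family is tuned and fitted on the training folds only (no
#' leakage: standardization and hyperparameter search happen inside
#' `family$fit`) and scored on the held-out fold with the rank-based AUC.
#'
#' @param ds an [npx_dataset()] (or a plain numeric matrix).
#' @param groups group label per sample.
#' @param pair length-2 character vector (composites allowed).
#' @param family a [model_family()].
#' @param k outer folds (default 5).
#' @param repeats down-sample/CV repeats (default 20).
#' @param seed master seed.
#' @return a `benchmark_result` list: pair, family, `aucs` data.frame
#'   (repeat, fold, auc) and `median_auc`.
#' @export
repeated_cv_auc <- function(ds, groups, pair, family, k = 5L, repeats = 20L,
                            seed = 1L) {
  X <- if (inherits(ds, "npx_dataset")) ds$values else ds
  if (inherits(ds, "npx_dataset")) groups <- groups[sample_ids(ds)]
  rows <- list()
  for (r in seq_len(repeats)) {
    dsmp <- downsample_groups(groups, pair, seed = derive_seed(seed, r))
    Xr <- X[dsmp$idx, , drop = FALSE]
    yr <- dsmp$y
    if (min(table(yr)) < k) stop("need >= k samples per group after down-sampling")
    folds <- with_seed(derive_seed(seed, 10000L + r), stratified_folds(yr, k))
    for (f in seq_len(k)) {
      tr <- folds != f
      if (length(unique(yr[!tr])) < 2) stop("single-class fold")
      model <- family$fit(Xr[tr, , drop = FALSE], yr[tr],
                          seed = derive_seed(seed, 100L * r + f))
      sc <- family$predict_proba(model, Xr[!tr, , drop = FALSE])
      rows[[length(rows) + 1]] <- data.frame(rep = r, fold = f,
                                             auc = score_auc(sc, yr[!tr]))
    }
  }
  aucs <- do.call(rbind, rows)
  structure(list(pair = paste(pair[1], "vs", pair[2]), family = family$name,
                 aucs = aucs, median_auc = median(aucs$auc)),
            class = "benchmark_result")
}

#' Full pair x family benchmark grid
#'
#' @inheritParams repeated_cv_auc
#' @param pairs list of group pairs.
#' @param families list of [model_family()] adapters.
#' @return data.frame: pair, family, median_auc (one row per cell), with the
#'   per-fold AUC tables in the `"details"` attribute.
#' @export
compare_all <- function(ds, groups, pairs, families, k = 5L, repeats = 20L,
                        seed = 1L) {
  cells <- list()
  details <- list()
  for (pair in pairs) {
    for (fam in families) {
      res <- repeated_cv_auc(ds, groups, pair, fam, k = k, repeats = repeats,
                             seed = seed)
      cells[[length(cells) + 1]] <- data.frame(
        pair = res$pair, family = res$family, median_auc = res$median_auc,
        stringsAsFactors = FALSE)
      details[[paste(res$pair, res$family, sep = " | ")]] <- res$aucs
    }
  }
  out <- do.call(rbind, cells)
  attr(out, "details") <- details
  out
}
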