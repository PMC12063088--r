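test_that("penalty_value limits: zero beta, zero lambda, pure ridge", {
  b <- c(0.5, -1, 2)
  expect_equal(penalty_value(numeric(3), penalty_spec(lambda = 1)), 0)
  expect_equal(penalty_value(b, penalty_spec(lambda = 0)), 0)
  lam <- 0.7
  expect_equal(penalty_value(b, penalty_spec(lambda = lam, alpha = 0)),
               lam / 2 * sum(b^2))
  expect_error(penalty_spec(a = 2), "a")
  expect_error(penalty_spec(alpha = 1.5))
})

test_that("prox_coord reproduces the zone formulas and the grid oracle", {
  sp <- function(lambda, alpha = 1, a = 3.7) penalty_spec(lambda, alpha, a)
  expect_equal(prox_coord(c(-1.3, 0.2, 2), penalty_spec(0)), c(-1.3, 0.2, 2))
  expect_equal(prox_coord(0.1, sp(0.2)), 0)
  expect_equal(prox_coord(0.5, sp(0.2)), (2.7 * 0.5 - 0.74) / 1.7,
               tolerance = 1e-12)
  expect_equal(prox_coord(2.0, sp(0.2)), 2.0)
  set.seed(5)
  for (i in 1:200) {
    z <- runif(1, -2, 2)
    spec <- penalty_spec(lambda = runif(1, 0.01, 1), alpha = runif(1),
                         a = runif(1, 2.1, 5))
    lam1 <- spec$alpha * spec$lambda
    lam2 <- (1 - spec$alpha) * spec$lambda
    expect_lt(abs(prox_coord(z, spec) -
                    prox_grid_oracle(z, lam1, lam2, spec$a)), 1e-3)
  }
})

test_that("huge lambda gives the null model; inputs are validated", {
  fx <- logistic_fixture(seed = 6, n = 150, p = 6)
  f <- scad_ridge_fit(fx$Xs, fx$y, penalty_spec(lambda = 50))
  expect_equal(f$beta, setNames(numeric(6), colnames(fx$Xs)))
  expect_equal(f$intercept, qlogis(mean(fx$y)), tolerance = 1e-7)
  expect_error(scad_ridge_fit(fx$X, fx$y, penalty_spec(1)), "standardized")
  expect_error(scad_ridge_fit(fx$Xs, rep(1, 150), penalty_spec(1)), "binary")
})

test_that("perfect separation at vanishing lambda is flagged", {
  set.seed(7)
  x <- matrix(rnorm(80), 80, 1, dimnames = list(NULL, "V1"))
  xs <- npxspectrum:::standardize_columns(x)$x
  y <- as.numeric(xs > 0)
  f <- scad_ridge_fit(xs, y, penalty_spec(lambda = 1e-10), max_iter = 200)
  expect_false(f$converged)
})

test_that("solver matches glm, BFGS-ridge and glmnet-lasso oracles", {
  fx <- logistic_fixture(seed = 8, n = 500, p = 5,
                         beta = c(1, -0.8, 0.5, 0, 0))
  f <- scad_ridge_fit(fx$Xs, fx$y, penalty_spec(lambda = 1e-8), tol = 1e-10,
                      max_iter = 5000)
  g <- glm(fx$y ~ fx$Xs, family = binomial)
  expect_lt(max(abs(c(f$intercept, f$beta) - coef(g))), 1e-3)

  lam <- 0.5
  f2 <- scad_ridge_fit(fx$Xs, fx$y, penalty_spec(lambda = lam, alpha = 0),
                       tol = 1e-10, max_iter = 5000)
  obj <- function(par) {
    eta <- par[1] + fx$Xs %*% par[-1]
    mean(log1p(exp(-(2 * fx$y - 1) * eta))) + lam / 2 * sum(par[-1]^2)
  }
  o <- optim(rep(0, 6), obj, method = "BFGS",
             control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(c(f2$intercept, f2$beta) - o$par)), 1e-4)

  skip_if_not_installed("glmnet")
  lamL <- 0.05
  f3 <- scad_ridge_fit(fx$Xs, fx$y, penalty_spec(lambda = lamL, alpha = 1),
                       penalty = "lasso", tol = 1e-12, max_iter = 5000)
  gn <- glmnet::glmnet(fx$Xs, fx$y, family = "binomial", lambda = lamL,
                       standardize = FALSE, thresh = 1e-12)
  expect_lt(max(abs(c(f3$intercept, f3$beta) - as.numeric(coef(gn)))), 1e-3)
  # SCAD with alpha = 1 and enormous shape parameter behaves like the lasso
  f4 <- scad_ridge_fit(fx$Xs, fx$y, penalty_spec(lambda = lamL, alpha = 1,
                                                 a = 1e6),
                       tol = 1e-12, max_iter = 5000)
  expect_lt(max(abs(f4$beta - f3$beta)), 1e-3)
})

test_that("the path starts empty, warm-starts, and honors df_max", {
  fx <- logistic_fixture(seed = 9, n = 200, p = 12,
                         beta = c(2, -1.5, rep(0, 10)))
  path <- fit_path(fx$Xs, fx$y, penalty_spec(df_max = 28), n_lambda = 40)
  expect_equal(path$df[1], 0L)
  expect_true(all(diff(path$lambdas) < 0))

  capped <- fit_path(fx$Xs, fx$y, penalty_spec(df_max = 1), n_lambda = 40)
  expect_true(all(capped$df <= 1))
  expect_gt(capped$truncated_at, 0)

  # df roughly monotone along the path (rare nonconvexity dips tolerated)
  viol <- 0; tot <- 0
  for (s in 1:10) {
    fxs <- logistic_fixture(seed = 100 + s, n = 150, p = 10)
    pth <- fit_path(fxs$Xs, fxs$y, penalty_spec(), n_lambda = 30)
    d <- diff(pth$df)
    viol <- viol + sum(d < 0); tot <- tot + length(d)
  }
  expect_lte(viol / tot, 0.05)
})

test_that("cross-validated lambda selection is deterministic and sensible", {
  fx <- logistic_fixture(seed = 10, n = 200, p = 8,
                         beta = c(2, rep(0, 7)))
  s1 <- cv_select_lambda(fx$Xs, fx$y, seed = 42, n_lambda = 30)
  s2 <- cv_select_lambda(fx$Xs, fx$y, seed = 42, n_lambda = 30)
  expect_identical(s1$lambda, s2$lambda)
  expect_error(cv_select_lambda(fx$Xs[1:8, ], fx$y[1:8], k = 5), "n >= 2k")

  # the strong predictor is selected
  hits <- 0
  for (s in 1:10) {
    fxs <- logistic_fixture(seed = 200 + s, n = 150, p = 8,
                            beta = c(2, rep(0, 7)))
    sel <- cv_select_lambda(fxs$Xs, fxs$y, seed = s, n_lambda = 30)
    if (sel$path$betas["V1", sel$index] != 0) hits <- hits + 1
  }
  expect_gte(hits, 9)

  # pure noise: selection stays close to the null end of the path
  small <- 0
  for (s in 1:10) {
    fxs <- logistic_fixture(seed = 300 + s, n = 150, p = 8, beta = rep(0, 8))
    sel <- cv_select_lambda(fxs$Xs, fxs$y, seed = s, n_lambda = 30)
    if (sum(sel$path$betas[, sel$index] != 0) <= 3) small <- small + 1
  }
  expect_gte(small, 8)
})

test_that("prediction probabilities behave and standardization round-trips", {
  fx <- logistic_fixture(seed = 11, n = 120, p = 4)
  null_fit <- structure(list(intercept = 0, beta = rep(0, 4), spec = penalty_spec(1),
                             penalty = "scad_ridge"),
                        class = "scad_ridge_fit")
  expect_equal(predict(null_fit, fx$Xs), rep(0.5, 120))
  expect_error(predict(null_fit, fx$Xs[, 1:2]), "columns")

  fit <- scad_ridge(fx$X, fx$y, penalty_spec(lambda = 0.05))
  pr <- predict(fit, fx$X)
  expect_true(all(pr > 0 & pr < 1))
  # mean point maps to sigmoid of the standardized-scale intercept
  expect_equal(predict(fit, matrix(fit$center, 1)), plogis(fit$intercept),
               tolerance = 1e-12, ignore_attr = TRUE)
  # monotone in a single positive-coefficient predictor
  one <- scad_ridge(fx$X[, 1, drop = FALSE],
                    as.numeric(runif(120) < plogis(fx$X[, 1])),
                    penalty_spec(lambda = 0.05))
  grid <- matrix(seq(-2, 2, length.out = 9), 9, 1)
  if (one$beta[1] > 0) expect_true(all(diff(predict(one, grid)) > 0))

  # scale equivariance: rescaling a column leaves the standardized fit alone
  X2 <- fx$X; X2[, 2] <- X2[, 2] * 100
  fit2 <- scad_ridge(X2, fx$y, penalty_spec(lambda = 0.05))
  expect_equal(fit2$beta, fit$beta, tolerance = 1e-9)
  expect_equal(fit2$beta_original[2], fit$beta_original[2] / 100,
               tolerance = 1e-9)
})

test_that("fits serialize to JSON and back", {
  fx <- logistic_fixture(seed = 12, n = 80, p = 3)
  fit <- scad_ridge(fx$X, fx$y, penalty_spec(lambda = 0.1))
  dir <- withr_local_tempdir()
  p <- file.path(dir, "fit.json")
  write_fit_json(fit, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_equal(back$intercept, fit$intercept, tolerance = 1e-12)
  expect_equal(unname(back$beta), unname(fit$beta), tolerance = 1e-12)
  expect_equal(back$spec$lambda, 0.1)
})
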