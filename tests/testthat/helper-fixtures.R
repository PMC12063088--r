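# Shared fixture builders. Everything is generated in code; no stored data.

# A small two-group cohort with a clean planted continuum signal.
two_group_cohort <- function(seed = 1, n = 100, n_proteins = 20, n_signal = 5,
                             effect = 1, sd = 1) {
  cfg <- synthetic_config(
    group_sizes = c(UC = n, CD_L1 = n),
    group_positions = c(UC = 0, CD_L1 = 1),
    n_proteins = n_proteins, n_signal = min(n_signal, n_proteins),
    effect_scale = effect,
    ibd_shift = 0, n_ibd_proteins = 0, n_batches = 1, batch_sd = 0,
    residual_sd = sd, lod_quantile = 0, qc_fail_rate = 0,
    covariate_effects = c(age = 0, sex = 0, duration = 0), seed = seed)
  generate_cohort(cfg)
}

# Three groups on the latent continuum (UC-like, mid, CD-like).
continuum_cohort <- function(seed = 1, n = 150, positions = c(UC = 0,
                                                             CD_L2 = 0.5,
                                                             CD_L1 = 1),
                             n_proteins = 86, n_signal = 20, effect = 0.8,
                             sd = 1) {
  cfg <- synthetic_config(
    group_sizes = setNames(rep(n, length(positions)), names(positions)),
    group_positions = positions,
    n_proteins = n_proteins, n_signal = min(n_signal, n_proteins),
    effect_scale = effect,
    ibd_shift = 0, n_ibd_proteins = 0, n_batches = 1, batch_sd = 0,
    residual_sd = sd, lod_quantile = 0, qc_fail_rate = 0,
    covariate_effects = c(age = 0, sex = 0, duration = 0), seed = seed)
  generate_cohort(cfg)
}

# Plain design matrix + labels for solver tests.
logistic_fixture <- function(seed = 1, n = 200, p = 10,
                             beta = c(1.5, -1, rep(0, p - 2))) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("V", seq_len(p))))
  y <- rbinom(n, 1, plogis(X %*% beta))
  list(X = X, Xs = npxspectrum:::standardize_columns(X)$x, y = y)
}

# Independent brute-force BH step-up (loop form, no vectorized shortcuts).
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    vals <- numeric(0)
    for (j in i:m) vals <- c(vals, p[o[j]] * m / j)
    q[o[i]] <- min(1, min(vals))
  }
  q
}

# Independent brute-force AUC: all pairs, half credit for ties.
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# 1-D grid oracle for the scalar prox problem.
prox_grid_oracle <- function(z, lam1, lam2, a, step = 1e-4) {
  grid <- seq(-3 * abs(z), 3 * abs(z), by = step)
  pen <- ifelse(abs(grid) <= lam1, lam1 * abs(grid),
                ifelse(abs(grid) <= a * lam1,
                       (2 * a * lam1 * abs(grid) - grid^2 - lam1^2) /
                         (2 * (a - 1)),
                       lam1^2 * (a + 1) / 2))
  h <- 0.5 * (grid - z)^2 + pen + lam2 / 2 * grid^2
  grid[which.min(h)]
}

# Temp dir scoped to the calling test.
withr_local_tempdir <- function(env = parent.frame()) {
  d <- tempfile("npxtest")
  dir.create(d)
  withr::defer(unlink(d, recursive = TRUE), envir = env)
  d
}
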