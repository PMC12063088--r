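`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library calls do not perturb user-level
#' reproducibility.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic derivation of a stream of sub-seeds from one master seed,
# kept strictly below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647L)
}

# Column standardization with the 1/n variance convention used throughout the
# model-fitting code. Returns the matrix plus center/scale attributes.
standardize_columns <- function(X) {
  n <- nrow(X)
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  scl <- sqrt(colSums(Xc^2) / n)
  if (any(scl <= 0)) {
    stop("constant predictor column(s): ",
         paste(colnames(X)[scl <= 0], collapse = ", "))
  }
  Xs <- sweep(Xc, 2, scl, "/")
  list(x = Xs, center = ctr, scale = scl)
}

# Stratified k-fold assignment: within each class, samples are permuted and
# dealt round-robin, so every fold contains both classes whenever n_class >= k.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

is_binary01 <- function(y) {
  is.numeric(y) && all(y %in% c(0, 1)) && length(unique(y)) == 2L
}
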