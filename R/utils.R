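## Internal helpers: seed streams, symmetry checks, edge indexing.

# Deterministic child seed derived from a master seed and an integer offset.
# Kept strictly below 2^31 so it is always a valid R integer seed.
childSeed <- function(seed, offset) {
  as.integer(((as.double(seed) %% 2147483629) * 7919 + offset * 104729) %% 2147483629)
}

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# RNG stream afterwards so library calls never perturb user code.
withSeed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Relative asymmetry |W - W'| / max(|W|); 0 for all-zero matrices.
relAsymmetry <- function(W) {
  scale <- max(abs(W))
  if (scale == 0) return(0)
  max(abs(W - t(W))) / scale
}

# Upper-triangle (i < j) index pairs in lexicographic order by (i, j).
upperPairs <- function(n) {
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

# Gaussian-copula latent correlation that yields a target Spearman rho
# for continuous marginals: rho_z = 2 * sin(pi * rho_s / 6).
copulaLatentRho <- function(rho_s) 2 * sin(pi * rho_s / 6)

# Normal scores of a vector: qnorm of mid-ranks, ties broken by average.
normalScores <- function(x) {
  n <- length(x)
  qnorm((rank(x, ties.method = "average") - 0.5) / n)
}

stopIfNot <- function(cond, ...) if (!cond) stop(..., call. = FALSE)
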