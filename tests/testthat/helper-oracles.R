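# Independent brute-force oracles and random fixtures. These deliberately
# use naive enumeration (triple loops, Floyd-Warshall, path counting,
# permutation search) so they share no code path with the package
# implementations they check.

randomWeightedGraph <- function(n, p = 0.4, seed = 1, weighted = TRUE) {
  set.seed(seed)
  W <- matrix(0, n, n)
  ut <- which(upper.tri(W))
  on <- ut[runif(length(ut)) < p]
  W[on] <- if (weighted) runif(length(on), 0.1, 2) else 1
  W <- W + t(W)
  WeightedConnectome(W, "COMMIT", sprintf("fix-%d", seed))
}

ringLattice <- function(n, k = 4, rewireP = 0, seed = 1) {
  set.seed(seed)
  W <- matrix(0, n, n)
  for (d in seq_len(k / 2))
    for (i in seq_len(n)) {
      j <- ((i - 1 + d) %% n) + 1
      W[i, j] <- W[j, i] <- 1
    }
  if (rewireP > 0) {
    ut <- which(upper.tri(W) & W != 0)
    for (e in ut[runif(length(ut)) < rewireP]) {
      i <- row(W)[e]
      cand <- which(W[i, ] == 0 & seq_len(n) != i)
      if (length(cand)) {
        j <- cand[sample.int(length(cand), 1)]
        W[e] <- 0; W[col(W)[e], i] <- 0
        W[i, j] <- W[j, i] <- 1
      }
    }
  }
  WeightedConnectome(W, "COMMIT", "ring")
}

# Onnela clustering by explicit triple enumeration
oracleClustering <- function(W) {
  mx <- max(W)
  n <- nrow(W)
  out <- numeric(n)
  if (mx == 0) return(out)
  Wn <- W / mx
  for (i in seq_len(n)) {
    nb <- which(W[i, ] != 0)
    k <- length(nb)
    if (k < 2) next
    s <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      j <- nb[a]; h <- nb[b]
      if (j != h)
        s <- s + (Wn[i, j] * Wn[i, h] * Wn[j, h])^(1/3)
    }
    out[i] <- s / (k * (k - 1))
  }
  out
}

# all-pairs shortest paths by Floyd-Warshall on a length matrix
oracleFloyd <- function(L) {
  n <- nrow(L)
  D <- L
  diag(D) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

oracleCharPath <- function(L) {
  D <- oracleFloyd(L)
  off <- D[row(D) != col(D)]
  mean(off[is.finite(off)])
}

# shortest-path betweenness by exhaustive path counting on the distance
# matrix: sigma via dynamic programming in order of distance, pair
# dependencies accumulated explicitly (unordered source/target pairs)
oracleBetweenness <- function(L, tol = 1e-9) {
  n <- nrow(L)
  D <- oracleFloyd(L)
  sigma <- matrix(0, n, n)   # number of shortest s->t paths
  for (s in seq_len(n)) {
    ord <- order(D[s, ])
    sigma[s, s] <- 1
    for (v in ord) {
      if (v == s || !is.finite(D[s, v])) next
      pred <- which(is.finite(L[, v]) & L[, v] > 0 | (L[, v] == 0 & seq_len(n) != v))
      pred <- pred[abs(D[s, pred] + L[pred, v] - D[s, v]) <= tol * (1 + abs(D[s, v]))]
      sigma[s, v] <- sum(sigma[s, pred])
    }
  }
  bc <- numeric(n)
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s >= t || !is.finite(D[s, t])) next
    for (v in seq_len(n)) {
      if (v == s || v == t) next
      if (abs(D[s, v] + D[v, t] - D[s, t]) <= tol * (1 + abs(D[s, t])) &&
          sigma[s, t] > 0)
        bc[v] <- bc[v] + sigma[s, v] * sigma[v, t] / sigma[s, t]
    }
  }
  bc
}

# independent per-k rich-club recomputation (set-based, no matrix slicing)
oracleRichClub <- function(W, weighted) {
  deg <- colSums(W != 0)
  allW <- sort(W[upper.tri(W) & W != 0], decreasing = TRUE)
  ks <- seq_len(max(max(deg) - 1, 1))
  vapply(ks, function(k) {
    nodes <- which(deg > k)
    if (length(nodes) < 2) return(NaN)
    tot <- 0; ek <- 0
    for (a in seq_along(nodes)) for (b in seq_along(nodes)) {
      if (a < b && W[nodes[a], nodes[b]] != 0) {
        ek <- ek + 1
        tot <- tot + W[nodes[a], nodes[b]]
      }
    }
    if (weighted) {
      if (ek == 0) return(NaN)
      tot / sum(allW[seq_len(ek)])
    } else {
      2 * ek / (length(nodes) * (length(nodes) - 1))
    }
  }, numeric(1))
}

# Spearman via explicit rank-then-Pearson
oracleSpearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..n (n small)
allPerms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- allPerms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# brute-force optimal strength-matching energy over all weight placements
oracleAnnealOptimum <- function(edges0, weights, target) {
  n <- length(target)
  m <- nrow(edges0)
  perms <- allPerms(m)
  best <- Inf
  for (r in seq_len(nrow(perms))) {
    w <- weights[perms[r, ]]
    s <- numeric(n)
    for (e in seq_len(m)) {
      s[edges0[e, 1] + 1] <- s[edges0[e, 1] + 1] + w[e]
      s[edges0[e, 2] + 1] <- s[edges0[e, 2] + 1] + w[e]
    }
    best <- min(best, sum((s - target)^2))
  }
  best
}

skewness <- function(x) mean((x - mean(x))^3) / sd(x)^3

# mirror of the centrality panel's strictly-positive length convention
epsLengths <- function(L) {
  pos <- L[is.finite(L) & L > 0]
  eps <- if (length(pos)) max(min(pos) * 1e-6, 1e-5) else 1
  L[L <= 0 & is.finite(L)] <- eps
  diag(L) <- 0
  L
}

# toy parcellation spanning all eight modules
toyParcellation <- function(n = 16, seed = 1) {
  set.seed(seed)
  Parcellation(sprintf("n%02d", seq_len(n)),
               rep(moduleLevels(), length.out = n),
               runif(n, 800, 1200),
               matrix(runif(n * 3, 0, 150), n, 3))
}

toyStreamlineRow <- function(i, j, len = 10, wc = 1, ws = 1, r1 = 1,
                             fa = 0.4, rd = 0.6, icvf = 0.5) {
  data.frame(node_i = i, node_j = j, length_mm = len, w_commit = wc,
             w_sift2 = ws, med_R1 = r1, med_FA = fa, med_RD = rd,
             med_ICVF = icvf, stringsAsFactors = FALSE)
}
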