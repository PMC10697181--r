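# Weighted graph measures, null normalization, hubness and rich club.

test_that("Onnela clustering matches closed forms and the triple-loop oracle", {
  tri <- WeightedConnectome(matrix(1, 3, 3) - diag(3), "COMMIT")
  expect_equal(unname(weightedClustering(tri)), rep(1, 3))
  P <- matrix(0, 4, 4)
  P[1, 2] <- P[2, 3] <- P[3, 4] <- 1
  P <- P + t(P)
  expect_equal(unname(weightedClustering(WeightedConnectome(P, "COMMIT"))),
               rep(0, 4))
  for (seed in 1:8) {
    g <- randomWeightedGraph(12, 0.5, seed)
    expect_equal(unname(weightedClustering(g)),
                 oracleClustering(connMatrix(g)), tolerance = 1e-12)
  }
})

test_that("the -log transform and path length match closed forms and Floyd-Warshall", {
  g <- randomWeightedGraph(6, 0.8, seed = 2)
  L <- weightToLength(g)
  W <- connMatrix(g)
  expect_equal(L[which.max(W)], 0)   # max-weight edge has length 0
  expect_true(all(L[W > 0] >= 0))
  # two-node network at half the normalizing weight: path length ln 2
  two <- WeightedConnectome(matrix(c(0, 0.5, 0.5, 0), 2), "COMMIT")
  expect_equal(as.numeric(charPathLength(two, wmax = 1)), log(2))
  # negative lengths are refused
  expect_error(weightToLength(two, wmax = 0.1), "negative")
  # Floyd-Warshall oracle agreement on random graphs
  for (seed in 3:8) {
    g <- randomWeightedGraph(10, 0.55, seed)
    if (any(!is.finite(oracleFloyd(weightToLength(g))[1, ]))) next
    expect_equal(as.numeric(charPathLength(g)),
                 oracleCharPath(weightToLength(g)), tolerance = 1e-10)
  }
})

test_that("betweenness and closeness match the path-counting oracle", {
  # star K1,4: center betweenness = (n-1)(n-2)/2 = 6 unnormalized
  S <- matrix(0, 5, 5); S[1, 2:5] <- 1; S <- S + t(S)
  pan <- centralityPanel(WeightedConnectome(S, "COMMIT"))
  expect_equal(pan$betweenness[1], 6)
  expect_equal(pan$betweenness[-1], rep(0, 4))
  # uniform ring: all nodes identical on every metric
  ring <- ringLattice(12, 2)
  panR <- centralityPanel(ring)
  for (col in c("strength", "betweenness", "closeness", "eigenvector",
                "clustering"))
    expect_equal(diff(range(panR[[col]])), 0, tolerance = 1e-9)
  # random connected graphs against the exhaustive oracle
  for (seed in 1:6) {
    g <- randomWeightedGraph(10, 0.6, seed + 40)
    L <- weightToLength(g)
    if (any(!is.finite(oracleFloyd(L)))) next
    pan <- centralityPanel(g)
    Lo <- epsLengths(L)
    expect_equal(pan$betweenness, oracleBetweenness(Lo), tolerance = 1e-6)
  }
})

test_that("hubness scores implement the top/bottom 20 percent rule", {
  # star center is top on all four centralities and bottom on clustering
  S <- matrix(0, 5, 5); S[1, 2:5] <- 1; S <- S + t(S)
  hub <- hubnessScores(centralityPanel(WeightedConnectome(S, "COMMIT")))
  expect_gte(hub$score[1], 4)
  expect_true(all(hub$score %in% 0:5))
  # symmetric ring: ties broken by node index, exactly ceiling(0.2 N) nodes
  # receive each point
  ring <- ringLattice(10, 2)
  hubR <- hubnessScores(centralityPanel(ring))
  m <- ceiling(0.2 * 10)
  expect_equal(hubR$score[seq_len(m)], rep(5L, m))
  expect_equal(hubR$score[-seq_len(m)], rep(0L, 10 - m))
  # bounds on random graphs
  for (seed in 1:10) {
    g <- randomWeightedGraph(15, 0.5, seed + 60)
    sc <- hubnessScores(centralityPanel(g))$score
    expect_true(all(sc >= 0 & sc <= 5))
  }
})

test_that("hubness distance is the Euclidean nodewise score distance", {
  a <- c(3, 2, 0, 5); b <- c(1, 2, 4, 0)
  D <- hubnessDistance(list(A = a, B = b))
  expect_equal(D["A", "B"], sqrt(4 + 0 + 16 + 25))
  expect_equal(D["A", "A"], 0)
  expect_equal(hubnessDistance(list(X = a, Y = a))["X", "Y"], 0)
  expect_equal(hubnessDistance(list(X = a, Y = c(3, 2, 0, 4)))["X", "Y"], 1)
  expect_error(hubnessDistance(list(X = a, Y = c(1, 2))), "node count")
})

test_that("rich-club curves match closed forms and the per-k oracle", {
  # uniform-weight complete graph: phi_w = 1 at all valid k
  K6 <- WeightedConnectome(matrix(1, 6, 6) - diag(6), "COMMIT")
  rcw <- richClubWeighted(K6)
  expect_true(all(rcw$phi[!is.nan(rcw$phi)] == 1))
  # K4 minus one edge at k = 1: degrees {3,2,2,3} -> whole graph, phi = 5/6
  K4m <- matrix(1, 4, 4) - diag(4)
  K4m[2, 3] <- K4m[3, 2] <- 0
  rb <- richClubBinary(WeightedConnectome(K4m, "binary"))
  expect_equal(rb$phi[rb$k == 1], 5 / 6)
  # random weighted graphs against the independent oracle
  for (seed in 1:6) {
    g <- randomWeightedGraph(15, 0.45, seed + 80)
    expect_equal(richClubWeighted(g)$phi,
                 oracleRichClub(connMatrix(g), TRUE), tolerance = 1e-12)
    expect_equal(richClubBinary(g)$phi,
                 oracleRichClub(connMatrix(g), FALSE), tolerance = 1e-12)
  }
})

test_that("degenerate null ensembles normalize S and phi_norm to exactly 1", {
  g <- randomWeightedGraph(20, 0.4, seed = 14)
  copies <- new("NullEnsemble", kind = "weighted-degree-strength",
                surrogates = rep(list(g), 8), seed = 0, swaps = 0,
                annealTrace = list())
  sw <- smallWorldness(g, nulls = copies)
  expect_equal(sw$S, 1)
  expect_equal(sw$Cnorm, 1)
  expect_equal(sw$Lnorm, 1)
  rc <- normalizeRichClub(richClubWeighted(g), copies)
  expect_equal(rc$phiNorm[!is.nan(rc$phiNorm)],
               rep(1, sum(!is.nan(rc$phiNorm))))
  expect_null(attr(rc, "detected"))
})

test_that("a rewired ring lattice is small-world against annealed nulls", {
  net <- ringLattice(60, 6, rewireP = 0.05, seed = 15)
  # continuous weight jitter keeps the -log length transform non-degenerate
  set.seed(15)
  W <- connMatrix(net)
  jit <- matrix(runif(60 * 60, 0.75, 1.25), 60, 60)
  jit[lower.tri(jit)] <- t(jit)[lower.tri(jit)]
  net <- WeightedConnectome(W * jit, "COMMIT")
  sw <- smallWorldness(net, nNulls = 8, seed = 16,
                       params = list(totalSwaps = 5e3))
  expect_gt(sw$S, 1)
})

test_that("all measures are equivariant under node relabeling", {
  g <- randomWeightedGraph(14, 0.5, seed = 17)
  set.seed(18)
  perm <- sample(14)
  W <- connMatrix(g)
  gp <- WeightedConnectome(W[perm, perm], "COMMIT",
                           nodeIds = nodeIds(g)[perm])
  expect_equal(unname(weightedClustering(gp)),
               unname(weightedClustering(g))[perm])
  expect_equal(as.numeric(charPathLength(gp)), as.numeric(charPathLength(g)))
  expect_equal(richClubWeighted(gp)$phi, richClubWeighted(g)$phi)
  panP <- centralityPanel(gp); pan <- centralityPanel(g)
  expect_equal(panP$strength, pan$strength[perm])
  expect_equal(panP$betweenness, pan$betweenness[perm], tolerance = 1e-9)
})

test_that("equal weights reduce weighted measures to their binary forms", {
  for (seed in 1:5) {
    gb <- randomWeightedGraph(12, 0.5, seed + 90, weighted = FALSE)
    A <- connMatrix(gb)
    gw <- WeightedConnectome(A * 0.37, "COMMIT")
    expect_equal(unname(weightedClustering(gw)),
                 unname(weightedClustering(gb)), tolerance = 1e-12)
    # with a flat weight multiset the ranked-weight denominator equals the
    # subgraph weight sum, so phi_w is identically 1 where defined
    pw <- richClubWeighted(gw)$phi
    expect_equal(pw[!is.nan(pw)], rep(1, sum(!is.nan(pw))))
    expect_equal(rowSums(connMatrix(gw)), 0.37 * rowSums(A))
  }
})
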