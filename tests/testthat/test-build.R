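# Construction of the eight weighted networks, filtering and consensus.

test_that("COMMIT streamline filter applies the machine-precision threshold", {
  parc <- toyParcellation()
  df <- rbind(toyStreamlineRow("n01", "n02", wc = 0.5),
              toyStreamlineRow("n01", "n02", wc = 1e-13),
              toyStreamlineRow("n01", "n03", wc = 0.2))
  st <- StreamlineTable(df, parc)
  filt <- commitFilter(st)
  expect_equal(nrow(filt), 2L)
  expect_equal(attr(filt, "removed"), 1L)
  # all passing -> unchanged
  ok <- commitFilter(StreamlineTable(df[c(1, 3), ], parc))
  expect_equal(nrow(ok), 2L)
  expect_warning(commitFilter(StreamlineTable(df[2, , drop = FALSE], parc)),
                 "every streamline")
})

test_that("NoS, LoS, SIFT2 and tractometry aggregate per node pair", {
  parc <- toyParcellation()
  df <- rbind(toyStreamlineRow("n01", "n02", len = 10, ws = 0.2, r1 = 0.6),
              toyStreamlineRow("n01", "n02", len = 20, ws = 0.3, r1 = 0.8),
              toyStreamlineRow("n01", "n02", len = 30, ws = 0.1, r1 = 0.7))
  st <- StreamlineTable(df, parc)
  nl <- buildNosLos(st, parc)
  expect_equal(connMatrix(nl$NoS)[1, 2], 3)
  expect_equal(connMatrix(nl$LoS)[1, 2], 20)
  expect_equal(connMatrix(nl$NoS)[1, 3], 0)   # empty pair
  expect_equal(connMatrix(buildSift2(st, parc))[1, 2], 0.6)
  expect_equal(connMatrix(buildTractometry(st, parc, "R1"))[1, 2], 0.7)
  expect_error(buildTractometry(st, parc, "QQ"), "unknown tractometry")

  # order invariance: shuffled rows give identical networks
  set.seed(3)
  big <- do.call(rbind, lapply(1:60, function(k)
    toyStreamlineRow(sprintf("n%02d", sample(16, 1)),
                     sprintf("n%02d", sample(16, 1)),
                     len = runif(1, 5, 90), wc = runif(1),
                     ws = runif(1), r1 = runif(1, 0.8, 1.2))))
  big <- big[big$node_i != big$node_j, ]
  st1 <- StreamlineTable(big, parc)
  st2 <- StreamlineTable(big[sample(nrow(big)), ], parc)
  expect_equal(connMatrix(buildSift2(st1, parc)),
               connMatrix(buildSift2(st2, parc)))
  expect_equal(connMatrix(buildCommit(st1, parc)),
               connMatrix(buildCommit(st2, parc)))

  # aggregation oracle: brute-force group-by on the raw data.frame, with
  # keys canonicalized to unordered node pairs
  ii <- match(big$node_i, nodeIds(parc))
  jj <- match(big$node_j, nodeIds(parc))
  key <- paste(pmin(ii, jj), pmax(ii, jj))
  sums <- tapply(big$w_sift2, key, sum)
  S <- connMatrix(buildSift2(st1, parc))
  for (k in names(sums)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    expect_equal(S[ij[1], ij[2]], unname(sums[[k]]))
  }
  means <- tapply(big$med_R1, key, mean)
  R <- connMatrix(buildTractometry(st1, parc, "R1"))
  for (k in names(means)) {
    ij <- as.integer(strsplit(k, " ")[[1]])
    expect_equal(R[ij[1], ij[2]], unname(means[[k]]))
  }
})

test_that("COMMIT edge weight is the length-weighted streamline-weight sum", {
  parc <- toyParcellation()
  # single streamline: alpha = x * l / l = x
  one <- StreamlineTable(toyStreamlineRow("n01", "n02", len = 37, wc = 1), parc)
  expect_equal(connMatrix(buildCommit(one, parc))[1, 2], 1)
  # hand evaluation: x = (2, 4), l = (10, 20) -> (20 + 80) / 15
  two <- StreamlineTable(rbind(toyStreamlineRow("n01", "n02", len = 10, wc = 2),
                               toyStreamlineRow("n01", "n02", len = 20, wc = 4)),
                         parc)
  expect_equal(connMatrix(buildCommit(two, parc))[1, 2], 100 / 15)
  # equal lengths: reduces to the plain weight sum
  eq <- StreamlineTable(rbind(toyStreamlineRow("n01", "n02", len = 25, wc = 2),
                              toyStreamlineRow("n01", "n02", len = 25, wc = 4)),
                        parc)
  expect_equal(connMatrix(buildCommit(eq, parc))[1, 2], 6)
})

test_that("volume normalization divides by the mean endpoint volume", {
  parc <- Parcellation(c("a", "b"), c("VIS", "VIS"), c(2, 2), matrix(0, 2, 3))
  net <- WeightedConnectome(matrix(c(0, 4, 4, 0), 2), "NoS")
  expect_equal(connMatrix(volumeNormalize(net, parc))[1, 2], 2)
  unit <- Parcellation(c("a", "b"), c("VIS", "VIS"), c(1, 1), matrix(0, 2, 3))
  expect_equal(connMatrix(volumeNormalize(net, unit)), connMatrix(net))
  # homogeneity: doubling all volumes halves all weights
  dbl <- Parcellation(c("a", "b"), c("VIS", "VIS"), c(4, 4), matrix(0, 2, 3))
  expect_equal(connMatrix(volumeNormalize(net, dbl)),
               connMatrix(volumeNormalize(net, parc)) / 2)
})

test_that("FC construction is Fisher-Z Pearson with boundary clipping", {
  set.seed(5)
  X <- matrix(rnorm(5 * 200), 5, 200)
  fc <- buildFc(X)
  r <- cor(t(X))
  expect_equal(connMatrix(fc)[1, 2], atanh(r[1, 2]))
  expect_equal(atanh(0.5), 0.5493061, tolerance = 1e-7)
  # an exact copy row yields a large finite Z, never Inf
  X2 <- rbind(X, X[1, ])
  fc2 <- buildFc(X2)
  expect_true(is.finite(connMatrix(fc2)[1, 6]))
  expect_gt(connMatrix(fc2)[1, 6], 10)
  # constant row names the node
  X3 <- X; X3[2, ] <- 1
  expect_error(buildFc(X3), "2")
})

test_that("consensus mask retains edges present in at least the threshold fraction", {
  parc <- toyParcellation(4)
  mk <- function(edges) {
    W <- matrix(0, 4, 4)
    for (e in edges) W[e[1], e[2]] <- W[e[2], e[1]] <- 1
    WeightedConnectome(W, "COMMIT", paste0("s", length(edges)))
  }
  # edge (1,2) in 2 of 4 subjects -> retained at 0.5; edge (1,3) in 1 of 4 -> dropped
  subs <- list(mk(list(c(1, 2), c(1, 3))), mk(list(c(1, 2))),
               mk(list(c(2, 3))), mk(list(c(3, 4))))
  ens <- SubjectEnsemble(subs, parc, "COMMIT")
  M <- connMatrix(consensusMask(ens, 0.5))
  expect_equal(M[1, 2], 1)
  expect_equal(M[1, 3], 0)
  # fraction 1 is the intersection
  Mall <- connMatrix(consensusMask(ens, 1))
  expect_equal(sum(Mall), 0)
  # single subject: mask equals its own binary map
  ens1 <- SubjectEnsemble(subs[1], parc, "COMMIT")
  expect_equal(connMatrix(consensusMask(ens1, 0.5)),
               (connMatrix(subs[[1]]) != 0) * 1)
})

test_that("edge-level COMMIT filter enforces uniform binary maps and group averaging excludes zeros", {
  parc <- toyParcellation(4)
  mkW <- function(v12, v13, name, sid) {
    W <- matrix(0, 4, 4)
    W[1, 2] <- W[2, 1] <- v12
    W[1, 3] <- W[3, 1] <- v13
    WeightedConnectome(W, name, sid)
  }
  commitE <- SubjectEnsemble(list(mkW(0.5, 0, "COMMIT", "s1"),
                                  mkW(0.4, 0.2, "COMMIT", "s2")), parc)
  faE <- SubjectEnsemble(list(mkW(0.3, 0.9, "FA", "s1"),
                              mkW(0.2, 0.8, "FA", "s2")), parc)
  filt <- applyCommitEdgeFilter(list(COMMIT = commitE, FA = faE), commitE)
  # edge (1,3) had COMMIT 0 in s1 -> zeroed in FA for s1 only
  expect_equal(connMatrix(subjects(filt$FA)[[1]])[1, 3], 0)
  expect_equal(connMatrix(subjects(filt$FA)[[2]])[1, 3], 0.8)
  # binary maps now identical across weightings within subject
  for (s in 1:2)
    expect_equal(connMatrix(subjects(filt$FA)[[s]]) != 0,
                 connMatrix(subjects(filt$COMMIT)[[s]]) != 0)

  # group average excludes zero-valued edges: {2, 0, 4} -> 3
  g3 <- SubjectEnsemble(list(mkW(2, 1, "NoS", "s1"), mkW(0, 1, "NoS", "s2"),
                             mkW(4, 1, "NoS", "s3")), parc)
  mask <- consensusMask(g3, 0.5)
  avg <- groupAverage(g3, mask)
  expect_equal(connMatrix(avg)[1, 2], 3)
  # single subject mean is the identity
  g1 <- SubjectEnsemble(list(mkW(5, 0, "NoS", "s1")), parc)
  expect_equal(connMatrix(groupAverage(g1, consensusMask(g1)))[1, 2], 5)
})

test_that("full cohort filtering yields identical binary maps across all weightings", {
  cfg <- generatorConfig(nNodes = 40, nSubjects = 4, seed = 99)
  co <- generateCohort(cfg)
  ref <- lapply(subjects(co$ensembles$COMMIT),
                function(s) connMatrix(s) != 0)
  for (w in c("NoS", "LoS", "SIFT2", "R1", "FA", "RD", "ICVF")) {
    maps <- lapply(subjects(co$ensembles[[w]]), function(s) connMatrix(s) != 0)
    for (s in seq_along(maps)) expect_identical(maps[[s]], ref[[s]])
  }
})
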