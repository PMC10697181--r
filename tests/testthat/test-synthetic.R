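# The cohort generator: determinism, topology properties, marginal shapes,
# coupling recovery and the FC simulator.

test_that("parcellation generation is feasible, positive and deterministic", {
  cfg <- generatorConfig(nNodes = 16, nModules = 8, seed = 1)
  p <- generateParcellation(cfg)
  expect_equal(as.integer(table(modules(p))), rep(2L, 8))
  p2 <- generateParcellation(cfg)
  expect_identical(nodeCoords(p), nodeCoords(p2))
  expect_error(generatorConfig(nNodes = 10, nModules = 8, seed = 1),
               "nNodes")
  # property sweep: volumes strictly positive, coords inside the cube
  set.seed(2)
  for (k in 1:100) {
    cfgk <- generatorConfig(nNodes = sample(16:60, 1), seed = sample(1e6, 1))
    pk <- generateParcellation(cfgk)
    expect_true(all(volumes(pk) > 0))
    expect_true(all(nodeCoords(pk) >= 0 & nodeCoords(pk) <= 150))
  }
})

test_that("binary topology hits the target density and respects modular bias", {
  # lambda = 0, beta = 0: Erdos-Renyi with realized density near target
  cfg <- generatorConfig(nNodes = 200, distanceDecay = 0, modularBias = 0,
                         targetDensity = 0.3, seed = 3)
  parc <- generateParcellation(cfg)
  net <- generateBinaryTopology(parc, cfg)
  A <- connMatrix(net)
  dens <- mean(A[upper.tri(A)])
  expect_lt(abs(dens - 0.3), 0.02)
  # strong modular bias: within-module density exceeds between-module
  cfgB <- generatorConfig(nNodes = 80, modularBias = 6, targetDensity = 0.2,
                          seed = 4)
  parcB <- generateParcellation(cfgB)
  netB <- generateBinaryTopology(parcB, cfgB)
  AB <- connMatrix(netB)
  same <- outer(modules(parcB), modules(parcB), `==`)
  ut <- upper.tri(AB)
  expect_gt(mean(AB[ut & same]), mean(AB[ut & !same]))
  # connectedness over seeds (MST repair)
  for (s in 1:20) {
    cfgS <- generatorConfig(nNodes = 40, targetDensity = 0.08, seed = s)
    pS <- generateParcellation(cfgS)
    nS <- generateBinaryTopology(pS, cfgS)
    g <- igraph::graph_from_adjacency_matrix(connMatrix(nS), "undirected")
    expect_true(igraph::is_connected(g))
  }
  expect_error(generateBinaryTopology(
    parc, generatorConfig(nNodes = 200, targetDensity = 0.005, seed = 1)),
    "floor")
})

test_that("streamline tables carry the configured false-positive fraction", {
  cfg <- generatorConfig(nNodes = 90, commitZeroFraction = 0.3, seed = 5)
  parc <- generateParcellation(cfg)
  st <- generateStreamlineTable(generateBinaryTopology(parc, cfg), parc, cfg)
  frac <- mean(streamlines(st)$w_commit < 1e-12)
  expect_gt(nrow(st), 10000)
  expect_lt(abs(frac - 0.3), 0.02)
  # heavy fraction: commit filter removes nearly everything
  cfg9 <- generatorConfig(nNodes = 90, commitZeroFraction = 0.9, seed = 6)
  parc9 <- generateParcellation(cfg9)
  st9 <- generateStreamlineTable(generateBinaryTopology(parc9, cfg9), parc9,
                                 cfg9)
  filt <- commitFilter(st9)
  expect_gte(attr(filt, "removed") / nrow(st9), 0.85)
  # determinism
  stA <- generateStreamlineTable(generateBinaryTopology(parc, cfg), parc, cfg)
  expect_identical(streamlines(stA), streamlines(st))
})

test_that("edge distributions are heavy-tailed for streamline weights and near normal for tractometry", {
  cfg <- generatorConfig(seed = 7)
  co <- generateCohort(cfg)
  for (w in c("NoS", "SIFT2", "COMMIT")) {
    ev <- edgeVectorize(co$group[[w]], co$mask)
    expect_gt(skewness(ev$value[ev$value != 0]), 1)
  }
  for (w in c("R1", "FA", "RD", "ICVF")) {
    ev <- edgeVectorize(co$group[[w]], co$mask)
    expect_lt(abs(skewness(ev$value[ev$value != 0])), 0.5)
  }
})

test_that("configured couplings are recovered at five thousand edges", {
  # 170 nodes yields >= 5,000 edges in a single generator draw
  cfg <- generatorConfig(nNodes = 170, targetDensity = 0.36, seed = 8)
  parc <- generateParcellation(cfg)
  st <- generateStreamlineTable(generateBinaryTopology(parc, cfg), parc, cfg)
  ep <- attr(st, "edgeProfile")
  expect_gte(nrow(ep), 5000)
  got <- c(NoS = spearmanRho(ep$nStreamlines, ep$distance),
           SIFT2 = spearmanRho(ep$sift2, ep$distance),
           COMMIT = spearmanRho(ep$alpha, ep$distance),
           R1 = spearmanRho(ep$R1, ep$distance),
           FA = spearmanRho(ep$FA, ep$distance),
           RD = spearmanRho(ep$RD, ep$distance),
           ICVF = spearmanRho(ep$ICVF, ep$distance))
  for (w in names(got)) {
    expect_equal(sign(got[[w]]), sign(cfg$rhoLen[[w]]))
    expect_lt(abs(got[[w]] - cfg$rhoLen[[w]]), 0.05)
  }
  # tercile-wise myelin coupling on normal-score residuals
  ns <- function(x) qnorm((rank(x) - 0.5) / length(x))
  for (t in c(1, 3)) {
    i <- ep$tercile == t
    rc <- residualizeOnLength(ns(ep$alpha[i]), ns(ep$distance[i]))
    rr <- residualizeOnLength(ns(ep$R1[i]), ns(ep$distance[i]))
    target <- if (t == 1) cfg$rhoMyelinShort else cfg$rhoMyelinLong
    expect_lt(abs(spearmanRho(rc, rr) - target), 0.05)
  }
})

test_that("subject noise drives inter-subject dispersion monotonically", {
  # zero noise and dropout: all subjects identical
  cfg0 <- generatorConfig(nNodes = 40, nSubjects = 3, subjectNoiseSd = 0,
                          dropout = 0, seed = 9)
  co0 <- generateCohort(cfg0)
  subs <- subjects(co0$ensembles$COMMIT)
  expect_equal(connMatrix(subs[[1]]), connMatrix(subs[[2]]))
  expect_equal(connMatrix(subs[[1]]), connMatrix(subs[[3]]))
  # inter-subject CQD increases with subjectNoiseSd
  med <- vapply(c(0.1, 0.2, 0.4), function(s) {
    cfgS <- generatorConfig(nNodes = 40, nSubjects = 6, subjectNoiseSd = s,
                            dropout = 0, seed = 10)
    coS <- generateCohort(cfgS)
    median(interSubjectCqd(coS$ensembles$COMMIT, coS$mask)$value, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(med) > 0))
  # single subject: consensus mask is its own binary map
  cfg1 <- generatorConfig(nNodes = 30, nSubjects = 1, seed = 11)
  co1 <- generateCohort(cfg1)
  expect_equal(connMatrix(co1$mask),
               (connMatrix(subjects(co1$ensembles$COMMIT)[[1]]) != 0) * 1)
})

test_that("the FC simulator couples to SC and is seed-reproducible", {
  cfg <- generatorConfig(nNodes = 40, nSubjects = 2, seed = 12,
                         fcCoupling = 0.9, fcT = 600)
  co <- generateCohort(cfg)
  sc <- edgeVectorize(co$group$COMMIT, co$mask)
  fc <- edgeVectorize(subjects(co$ensembles$FC)[[1]], co$mask)
  ok <- sc$value != 0
  expect_gt(spearmanRho(fc$value[ok], sc$value[ok]), 0.5)
  # uncoupled FC is pure noise at the 1/sqrt(T) scale
  cfg0 <- generatorConfig(nNodes = 20, nSubjects = 1, seed = 13,
                          fcCoupling = 0, fcT = 10000)
  fc0 <- generateFc(co$group$COMMIT, cfg0)
  r0 <- tanh(connMatrix(subjects(fc0)[[1]]))
  expect_lt(mean(abs(r0[upper.tri(r0)])), 0.03)
  # identical seed, identical FC
  fcA <- generateFc(co$group$COMMIT, cfg, seed = 55)
  fcB <- generateFc(co$group$COMMIT, cfg, seed = 55)
  expect_equal(connMatrix(subjects(fcA)[[1]]), connMatrix(subjects(fcB)[[1]]))
})
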