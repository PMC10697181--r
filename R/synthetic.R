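## Synthetic multi-subject cohorts with the statistical structure the
## downstream analyses assume: distance-dependent, modular binary topology;
## heavy-tailed streamline-specific edge weights; near-normal tractometry
## weights; configurable weight-length, weight-myelin and weight-function
## couplings; per-subject dropout and multiplicative weight noise.
##
## Spearman coupling targets are imposed through a Gaussian copula: a latent
## correlation rho_z = 2*sin(pi*rho_s/6) between normal scores yields the
## requested Spearman rho_s after any monotone marginal transform, so the
## configured couplings are recovered (up to sampling error) by measurement
## on the generated cohort.

#' Configuration for the synthetic cohort generator
#'
#' All downstream draws are pure functions of this configuration and its
#' mandatory seed.
#'
#' @param nNodes number of nodes (default 90).
#' @param nModules number of modules (default 8, the canonical set).
#' @param nSubjects cohort size (default 10).
#' @param targetDensity expected binary edge density in (0, 1] (default 0.35).
#' @param distanceDecay exponential connection-probability decay per mm
#'   (default 0.01).
#' @param modularBias within-module connection-probability multiplier
#'   (probability scales with 1 + modularBias; default 1).
#' @param countDispersion log-normal sigma of per-edge streamline counts
#'   (default 1).
#' @param commitZeroFraction fraction of streamlines that are COMMIT false
#'   positives (weight below 1e-12), in [0, 1) (default 0.3).
#' @param rhoLen named vector of target Spearman(edge weight, edge length)
#'   per weighting; defaults follow the empirical sign pattern (negative
#'   for NoS/SIFT2/COMMIT/RD, positive for R1/FA/ICVF).
#' @param rhoMyelinShort target Spearman of length-residualized COMMIT vs
#'   R1 on shortest-tercile edges (negative; default -0.55).
#' @param rhoMyelinLong same on longest-tercile edges (reversed sign;
#'   default +0.25); middle tercile is uncoupled.
#' @param fcCoupling SC-FC coupling strength in [0, 1) (default 0.6).
#' @param fcT functional time-series length (default 400).
#' @param subjectNoiseSd sd of per-subject log-normal multiplicative weight
#'   noise (default 0.2).
#' @param dropout per-subject edge dropout probability (default 0.05).
#' @param seed mandatory integer master seed.
#'
#' @return A validated list of class \code{"GeneratorConfig"}.
#' @export
generatorConfig <- function(nNodes = 90, nModules = 8, nSubjects = 10,
                            targetDensity = 0.35, distanceDecay = 0.01,
                            modularBias = 1, countDispersion = 1,
                            commitZeroFraction = 0.3,
                            rhoLen = c(NoS = -0.5, SIFT2 = -0.4,
                                       COMMIT = -0.6, R1 = 0.35, FA = 0.3,
                                       RD = -0.3, ICVF = 0.3),
                            rhoMyelinShort = -0.55, rhoMyelinLong = 0.25,
                            fcCoupling = 0.6, fcT = 400,
                            subjectNoiseSd = 0.2, dropout = 0.05, seed) {
  if (missing(seed)) stop("a master seed is mandatory")
  stopIfNot(nNodes >= 2 * nModules, "nNodes must be >= 2 * nModules")
  stopIfNot(targetDensity > 0 && targetDensity <= 1,
            "targetDensity must be in (0, 1]")
  stopIfNot(distanceDecay >= 0, "distanceDecay must be >= 0")
  stopIfNot(modularBias >= 0, "modularBias must be >= 0")
  stopIfNot(countDispersion > 0, "countDispersion must be > 0")
  stopIfNot(commitZeroFraction >= 0 && commitZeroFraction < 1,
            "commitZeroFraction must be in [0, 1)")
  stopIfNot(fcCoupling >= 0 && fcCoupling < 1, "fcCoupling must be in [0, 1)")
  stopIfNot(fcT >= 3, "fcT must be >= 3")
  stopIfNot(subjectNoiseSd >= 0, "subjectNoiseSd must be >= 0")
  stopIfNot(dropout >= 0 && dropout < 1, "dropout must be in [0, 1)")
  stopIfNot(all(abs(rhoLen) < 1) && all(names(rhoLen) %in% weightLevels()),
            "rhoLen must be named by weightings with values in (-1, 1)")
  structure(list(nNodes = nNodes, nModules = nModules, nSubjects = nSubjects,
                 targetDensity = targetDensity, distanceDecay = distanceDecay,
                 modularBias = modularBias, countDispersion = countDispersion,
                 commitZeroFraction = commitZeroFraction, rhoLen = rhoLen,
                 rhoMyelinShort = rhoMyelinShort,
                 rhoMyelinLong = rhoMyelinLong, fcCoupling = fcCoupling,
                 fcT = fcT, subjectNoiseSd = subjectNoiseSd,
                 dropout = dropout, seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# marginal scales of the synthetic weightings (units arbitrary but chosen
# to resemble typical magnitudes: tiny heavy-tailed streamline weights,
# near-unity tractometry values)
.marginals <- list(
  commit = c(meanlog = log(1e-3), sdlog = 1.5),
  sift2  = c(meanlog = log(0.5),  sdlog = 1.2),
  count  = c(meanlog = log(12)),           # sdlog from countDispersion
  R1   = c(mean = 1.00, sd = 0.05),
  FA   = c(mean = 0.45, sd = 0.08),
  RD   = c(mean = 0.60, sd = 0.10),
  ICVF = c(mean = 0.55, sd = 0.10),
  streamlineMetricNoise = 0.2   # per-streamline metric noise, x marginal sd
)

#' Generate a synthetic parcellation
#'
#' Nodes are placed in a 150 mm cube, clustered by module (uniform module
#' centers plus isotropic Gaussian scatter, sd 12 mm); volumes are
#' log-normal around 1,000 mm^3 (sdlog 0.15); module sizes are as equal as
#' possible.
#'
#' @param cfg a \code{GeneratorConfig}.
#' @return A [Parcellation-class]; deterministic given \code{cfg$seed}.
#' @export
generateParcellation <- function(cfg) {
  n <- cfg$nNodes; m <- cfg$nModules
  sizes <- rep(n %/% m, m) + c(rep(1, n %% m), rep(0, m - n %% m))
  if (any(sizes < 2)) stop("infeasible module sizes: need >= 2 nodes per module")
  mods <- rep(moduleLevels()[seq_len(m)], sizes)
  withSeed(childSeed(cfg$seed, 1), {
    centers <- matrix(runif(m * 3, 15, 135), m, 3)
    coords <- centers[rep(seq_len(m), sizes), , drop = FALSE] +
      matrix(rnorm(n * 3, sd = 12), n, 3)
    coords <- pmin(pmax(coords, 0), 150)
    vols <- rlnorm(n, log(1000), 0.15)
    Parcellation(sprintf("n%03d", seq_len(n)), mods, vols, coords,
                 labels = sprintf("%s_%02d", mods, sequence(sizes)))
  })
}

#' Generate a distance-dependent modular binary topology
#'
#' Edge probability is proportional to
#' \eqn{\exp(-\lambda d_{ij}) (1 + \beta \cdot 1[same\ module])}, rescaled
#' so the expected density matches \code{targetDensity}; the graph is then
#' forced connected by adding the Euclidean minimum-spanning-tree edges.
#'
#' @param parc a [Parcellation-class].
#' @param cfg a \code{GeneratorConfig}.
#' @return A binary, connected [WeightedConnectome-class].
#' @export
generateBinaryTopology <- function(parc, cfg) {
  n <- nNodes(parc)
  nPairs <- n * (n - 1) / 2
  if (cfg$targetDensity < (n - 1) / nPairs)
    stop("targetDensity below the connectivity floor (n-1 edges)")
  D <- as.matrix(dist(nodeCoords(parc)))
  sameMod <- outer(modules(parc), modules(parc), `==`)
  S <- exp(-cfg$distanceDecay * D) * (1 + cfg$modularBias * sameMod)
  ut <- upper.tri(S)
  p <- S * (cfg$targetDensity * nPairs / sum(S[ut]))
  p[p > 1] <- 1
  A <- withSeed(childSeed(cfg$seed, 2), {
    a <- matrix(0, n, n)
    a[ut] <- rbinom(nPairs, 1, p[ut])
    a + t(a)
  })
  # connectivity repair: union with the Euclidean MST
  gD <- igraph::graph_from_adjacency_matrix(D, mode = "undirected",
                                            weighted = TRUE)
  mst <- igraph::as_adjacency_matrix(igraph::mst(gD), sparse = FALSE)
  A <- pmax(A, (mst != 0) * 1)
  diag(A) <- 0
  WeightedConnectome(A, "binary", "group", nodeIds(parc))
}

# internal: standardize to zero mean / unit (population-style) variance
.std <- function(x) {
  x <- x - mean(x)
  x / sqrt(mean(x^2))
}

# internal: orthogonalize x against the columns of basis, then standardize
.orth <- function(x, basis) {
  for (k in seq_len(ncol(basis))) {
    b <- basis[, k]
    x <- x - b * sum(x * b) / sum(b * b)
  }
  .std(x)
}

# internal: latent copula draw with target Spearman rho against z (normal
# scores of the conditioning variable). The noise component is
# orthogonalized against z so the empirical latent correlation equals the
# target exactly (the empirical-enforcement device of mvrnorm-style
# simulators); the target Spearman is then recovered up to the small
# rank-transform wrinkle rather than up to sampling noise.
.copulaDraw <- function(z, rho_s) {
  rz <- copulaLatentRho(rho_s)
  zs <- .std(z)
  e <- .orth(rnorm(length(z)), cbind(zs))
  rz * zs + sqrt(1 - rz^2) * e
}

#' Generate a synthetic streamline table
#'
#' For each edge of the binary topology: a log-normal streamline count
#' (decreasing with distance via the configured NoS coupling), streamline
#' lengths jittered around the Euclidean node distance (truncated-normal
#' 5\% jitter), COMMIT and SIFT2 per-streamline weights whose edge-level
#' aggregates follow heavy-tailed log-normal marginals coupled to edge
#' length, a configured fraction of near-zero COMMIT "false positive"
#' streamlines, and near-normal per-streamline tractometry medians. The
#' COMMIT-R1 coupling is imposed on the residual (length-independent)
#' component, negative on shortest-tercile edges and reversed on the
#' longest tercile.
#'
#' @param adj binary connected [WeightedConnectome-class].
#' @param parc the [Parcellation-class].
#' @param cfg a \code{GeneratorConfig}.
#' @param seed seed for this table (default derived from \code{cfg$seed}).
#' @return A [StreamlineTable-class]; attribute \code{edgeProfile} holds the
#'   per-edge latent targets (used by the cohort generator).
#' @export
generateStreamlineTable <- function(adj, parc, cfg,
                                    seed = childSeed(cfg$seed, 3)) {
  A <- connMatrix(adj)
  D <- as.matrix(dist(nodeCoords(parc)))
  pairs <- upperPairs(nrow(A))
  pairs <- pairs[A[pairs] != 0, , drop = FALSE]
  nE <- nrow(pairs)
  d <- D[pairs]
  ids <- nodeIds(parc)
  rl <- cfg$rhoLen
  withSeed(seed, {
    zd <- normalScores(d)
    # streamline counts (NoS target)
    zN <- .copulaDraw(zd, rl[["NoS"]])
    Ntot <- pmax(1L, as.integer(round(qlnorm(pnorm(zN),
                                             .marginals$count[["meanlog"]],
                                             cfg$countDispersion))))
    # edge-level weight targets
    zc <- .copulaDraw(zd, rl[["COMMIT"]])
    alpha <- qlnorm(pnorm(zc), .marginals$commit[["meanlog"]],
                    .marginals$commit[["sdlog"]])
    zs <- .copulaDraw(zd, rl[["SIFT2"]])
    sift <- qlnorm(pnorm(zs), .marginals$sift2[["meanlog"]],
                   .marginals$sift2[["sdlog"]])
    # tractometry edge values; R1 couples to the length-independent COMMIT
    # component, tercile-dependently (negative on short edges, reversed on
    # long edges, uncoupled in the middle). Within each tercile the
    # residual coupling is enforced empirically.
    zs <- .std(zd)
    rzC <- copulaLatentRho(rl[["COMMIT"]])
    eps_c <- (zc - rzC * zs) / sqrt(1 - rzC^2)
    terc <- cut(rank(d, ties.method = "first"),
                breaks = quantile(rank(d, ties.method = "first"),
                                  c(0, 1/3, 2/3, 1)),
                include.lowest = TRUE, labels = FALSE)
    gTarget <- c(copulaLatentRho(cfg$rhoMyelinShort), 0,
                 copulaLatentRho(cfg$rhoMyelinLong))
    resid_r1 <- numeric(nE)
    for (t in 1:3) {
      i <- which(terc == t)
      ec <- .orth(eps_c[i], cbind(zs[i]))
      eta <- .orth(rnorm(length(i)), cbind(ec, zs[i]))
      g <- gTarget[t]
      resid_r1[i] <- g * ec + sqrt(1 - g^2) * eta
    }
    b1 <- copulaLatentRho(rl[["R1"]])
    zr1 <- b1 * zs + sqrt(1 - b1^2) * resid_r1
    mkMetric <- function(z, nm) .marginals[[nm]][["mean"]] +
      .marginals[[nm]][["sd"]] * z
    r1 <- mkMetric(zr1, "R1")
    fa <- mkMetric(.copulaDraw(zd, rl[["FA"]]), "FA")
    rd <- mkMetric(.copulaDraw(zd, rl[["RD"]]), "RD")
    icvf <- mkMetric(.copulaDraw(zd, rl[["ICVF"]]), "ICVF")
    # false-positive streamline counts (at least one true streamline/edge)
    Nfp <- rbinom(nE, Ntot, cfg$commitZeroFraction)
    Nfp <- pmin(Nfp, Ntot - 1L)
    rows <- Ntot
    edgeIdx <- rep.int(seq_len(nE), rows)
    isFp <- unlist(lapply(seq_len(nE), function(e)
      c(rep(FALSE, Ntot[e] - Nfp[e]), rep(TRUE, Nfp[e]))), use.names = FALSE)
    nRows <- length(edgeIdx)
    # lengths: d * (1 + eps), eps ~ N(0, 0.05^2) truncated so lengths > 0
    eps <- rnorm(nRows, sd = 0.05)
    while (any(eps <= -1)) eps[eps <= -1] <- rnorm(sum(eps <= -1), sd = 0.05)
    len <- d[edgeIdx] * (1 + eps)
    # COMMIT weights: gamma shares of the edge target alpha so that the
    # length-weighted sum over true streamlines reproduces alpha exactly
    u <- rgamma(nRows, shape = 1.2, rate = 1)
    wc <- numeric(nRows)
    real <- !isFp
    # per-edge normalization sum(u*l) over true rows
    sul <- tapply(u[real] * len[real], edgeIdx[real], sum)
    lbar <- tapply(len[real], edgeIdx[real], mean)
    scale <- alpha * lbar / sul           # ordered by edge index
    wc[real] <- u[real] * scale[edgeIdx[real]]
    wc[isFp] <- runif(sum(isFp), 0, 1e-13)
    # SIFT2 weights: gamma shares of the edge target over all rows
    v <- rgamma(nRows, shape = 1.2, rate = 1)
    sv <- tapply(v, edgeIdx, sum)
    ws <- sift[edgeIdx] * v / sv[edgeIdx]
    # per-streamline metric medians: edge value + small streamline noise
    mnoise <- function(edgeVal, nm) edgeVal[edgeIdx] +
      rnorm(nRows, sd = .marginals$streamlineMetricNoise * .marginals[[nm]][["sd"]])
    df <- data.frame(
      node_i = ids[pairs[edgeIdx, 1]], node_j = ids[pairs[edgeIdx, 2]],
      length_mm = len, w_commit = wc, w_sift2 = ws,
      med_R1 = mnoise(r1, "R1"), med_FA = mnoise(fa, "FA"),
      med_RD = mnoise(rd, "RD"), med_ICVF = pmax(mnoise(icvf, "ICVF"), 0.01),
      stringsAsFactors = FALSE)
    out <- StreamlineTable(df, parc)
    attr(out, "edgeProfile") <- data.frame(
      i = pairs[, 1], j = pairs[, 2], distance = d, nStreamlines = Ntot,
      alpha = alpha, sift2 = sift, R1 = r1, FA = fa, RD = rd, ICVF = icvf,
      tercile = terc)
    out
  })
}

# internal: apply per-subject dropout and weight noise to the base table
.subjectTable <- function(base, parc, cfg, subjectSeed) {
  df <- streamlines(base)
  key <- paste(df$node_i, df$node_j)
  edges <- unique(key)
  withSeed(subjectSeed, {
    keepEdge <- runif(length(edges)) >= cfg$dropout
    fC <- exp(rnorm(length(edges), sd = cfg$subjectNoiseSd))
    fS <- exp(rnorm(length(edges), sd = cfg$subjectNoiseSd))
    fL <- exp(rnorm(length(edges), sd = 0.25 * cfg$subjectNoiseSd))
    mN <- matrix(rnorm(length(edges) * 4), ncol = 4)  # tractometry noise
    idx <- match(key, edges)
    keep <- keepEdge[idx]
    df <- df[keep, , drop = FALSE]
    idx <- idx[keep]
    df$w_commit <- df$w_commit * fC[idx]
    df$w_sift2 <- df$w_sift2 * fS[idx]
    df$length_mm <- df$length_mm * fL[idx]
    nsd <- 0.3 * cfg$subjectNoiseSd
    df$med_R1 <- df$med_R1 + mN[idx, 1] * nsd * .marginals$R1[["sd"]]
    df$med_FA <- df$med_FA + mN[idx, 2] * nsd * .marginals$FA[["sd"]]
    df$med_RD <- df$med_RD + mN[idx, 3] * nsd * .marginals$RD[["sd"]]
    df$med_ICVF <- pmax(df$med_ICVF + mN[idx, 4] * nsd * .marginals$ICVF[["sd"]],
                        0.01)
    new("StreamlineTable", streamlines = df)
  })
}

#' Generate a full synthetic cohort
#'
#' One group topology; per subject, independent edge dropout and
#' multiplicative weight noise applied to a shared base streamline table;
#' all eight structural weightings built per subject ([buildAllWeights()]),
#' edge-level COMMIT filtering and 50\% consensus masking applied, group
#' networks averaged excluding zeros, and per-subject FC simulated from the
#' group COMMIT network ([generateFc()]).
#'
#' @param cfg a \code{GeneratorConfig}.
#' @param consensus consensus fraction (default 0.5).
#' @param commitThreshold streamline/edge COMMIT threshold (default 1e-12).
#' @return List of class \code{"SyntheticCohort"}: \code{parcellation},
#'   \code{baseTable}, \code{tables} (per subject), \code{ensembles}
#'   (named [SubjectEnsemble-class] for the 8 SC weightings + FC),
#'   \code{mask} (consensus), \code{group} (named group-level
#'   [WeightedConnectome-class]), \code{config}.
#' @export
generateCohort <- function(cfg, consensus = 0.5, commitThreshold = 1e-12) {
  parc <- generateParcellation(cfg)
  adj <- generateBinaryTopology(parc, cfg)
  base <- generateStreamlineTable(adj, parc, cfg)
  scNames <- c("NoS", "LoS", "SIFT2", "COMMIT", "R1", "FA", "RD", "ICVF")
  tables <- vector("list", cfg$nSubjects)
  nets <- vector("list", cfg$nSubjects)
  for (s in seq_len(cfg$nSubjects)) {
    sid <- sprintf("sub-%02d", s)
    tables[[s]] <- .subjectTable(base, parc, cfg, childSeed(cfg$seed, 1000 + s))
    nets[[s]] <- buildAllWeights(tables[[s]], parc, sid, commitThreshold)
  }
  names(tables) <- sprintf("sub-%02d", seq_len(cfg$nSubjects))
  ensembles <- lapply(scNames, function(w)
    SubjectEnsemble(lapply(nets, `[[`, w), parc, w))
  names(ensembles) <- scNames
  ensembles <- applyCommitEdgeFilter(ensembles, ensembles$COMMIT,
                                     commitThreshold)
  mask <- consensusMask(ensembles$COMMIT, consensus)
  group <- lapply(ensembles, groupAverage, mask = mask)
  fcEns <- generateFc(group$COMMIT, cfg, parc = parc)
  fullMask <- WeightedConnectome(1 - diag(nNodes(parc)), "binary", "group",
                                 nodeIds(parc))
  group$FC <- groupAverage(fcEns, fullMask)
  ensembles$FC <- fcEns
  structure(list(parcellation = parc, baseTable = base, tables = tables,
                 ensembles = ensembles, mask = mask, group = group,
                 config = cfg),
            class = "SyntheticCohort")
}

#' Simulate per-subject functional connectivity from a structural network
#'
#' Per subject, \code{fcT} samples are drawn from
#' \eqn{N(0, \Sigma)} with \eqn{\Sigma = I + c\, s\, A}, where \eqn{A}
#' carries rank-transformed SC weights on the SC edges, \eqn{c} is
#' \code{fcCoupling} and \eqn{s} scales \eqn{A} so \eqn{\Sigma} stays
#' positive definite (nearest-PD repair is applied if needed). FC is the
#' Fisher-Z Pearson correlation of the samples ([buildFc()]).
#'
#' @param groupSc nonnegative group-level [WeightedConnectome-class].
#' @param cfg a \code{GeneratorConfig}.
#' @param seed master seed (default derived from \code{cfg$seed}).
#' @param parc optional [Parcellation-class] for the resulting ensemble; a
#'   minimal placeholder is synthesized when omitted.
#' @return A [SubjectEnsemble-class] of FC networks.
#' @export
generateFc <- function(groupSc, cfg, seed = childSeed(cfg$seed, 4),
                       parc = NULL) {
  W <- connMatrix(groupSc)
  if (any(W < 0)) stop("generateFc expects a nonnegative structural network")
  n <- nrow(W)
  ut <- upper.tri(W)
  A <- matrix(0, n, n)
  nz <- which(ut & W != 0)
  if (length(nz)) A[nz] <- rank(W[nz]) / length(nz)
  A <- A + t(A)
  Sigma <- diag(n)
  if (cfg$fcCoupling > 0 && length(nz)) {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    s <- 0.9 / abs(min(ev))
    Sigma <- diag(n) + cfg$fcCoupling * s * A
    if (min(eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
      rep <- try(Matrix::nearPD(Sigma, corr = TRUE), silent = TRUE)
      if (inherits(rep, "try-error")) stop("positive-definite repair failed")
      Sigma <- as.matrix(rep$mat)
    }
  }
  L <- chol(Sigma)
  subs <- lapply(seq_len(cfg$nSubjects), function(sbj) {
    X <- withSeed(childSeed(seed, sbj), {
      matrix(rnorm(cfg$fcT * n), cfg$fcT, n) %*% L
    })
    buildFc(t(X), sprintf("sub-%02d", sbj), nodeIds = nodeIds(groupSc))
  })
  if (is.null(parc))
    parc <- Parcellation(nodeIds(groupSc), rep(moduleLevels()[1], n),
                         rep(1000, n), matrix(0, n, 3))
  SubjectEnsemble(subs, parc, "FC")
}
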