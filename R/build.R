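## Construction of the eight weighted structural networks and FC from
## streamline-level data, plus the filtering/consensus post-processing.
##
## Streamline-specific weightings: NoS (streamline count), LoS (mean
## streamline length), SIFT2 (sum of SIFT2 streamline weights), COMMIT
## (length-weighted sum of COMMIT streamline weights,
## alpha_ij = sum_k x_ijk * l_k / Lbar_ij). Tractometry weightings (R1, FA,
## RD, ICVF) average the per-streamline metric medians across streamlines.
## NoS/SIFT2/COMMIT are normalized by node volume.

# internal: aggregate a per-streamline quantity into an N x N matrix
.aggregateEdges <- function(table, parc, values, fun) {
  df <- streamlines(table)
  n <- nNodes(parc)
  W <- matrix(0, n, n)
  if (nrow(df)) {
    ii <- match(df$node_i, nodeIds(parc))
    jj <- match(df$node_j, nodeIds(parc))
    key <- (ii - 1) * n + jj    # unique per canonical (i < j) pair
    agg <- tapply(values, key, fun)
    k <- as.integer(names(agg))
    i <- (k - 1L) %/% n + 1L
    j <- (k - 1L) %% n + 1L
    W[cbind(i, j)] <- as.numeric(agg)
    W <- W + t(W)
  }
  W
}

#' Remove streamlines with near-zero COMMIT weights
#'
#' Streamlines whose COMMIT weight falls below machine-precision zero
#' (default 1e-12) are treated as tractography false positives and dropped.
#'
#' @param table a [StreamlineTable-class].
#' @param threshold COMMIT weight threshold (default \code{1e-12}).
#' @return The filtered [StreamlineTable-class], with attributes
#'   \code{retained} and \code{removed} recording row counts.
#' @export
#' @examples
#' # see buildCommit() for a full construction example
commitFilter <- function(table, threshold = 1e-12) {
  df <- streamlines(table)
  keep <- df$w_commit >= threshold
  out <- new("StreamlineTable", streamlines = df[keep, , drop = FALSE])
  if (!any(keep) && nrow(df) > 0)
    warning("COMMIT filter removed every streamline")
  attr(out, "retained") <- sum(keep)
  attr(out, "removed") <- sum(!keep)
  out
}

#' Build NoS and LoS networks
#'
#' NoS is the per-pair streamline count; LoS is the per-pair mean
#' streamline length (mm). Node pairs without streamlines are 0.
#'
#' @param table a [StreamlineTable-class].
#' @param parc the [Parcellation-class].
#' @param subjectId subject tag for the outputs.
#' @return Named list with [WeightedConnectome-class] elements \code{NoS}
#'   and \code{LoS}.
#' @export
buildNosLos <- function(table, parc, subjectId = "group") {
  df <- streamlines(table)
  nos <- .aggregateEdges(table, parc, rep(1, nrow(df)), sum)
  los <- .aggregateEdges(table, parc, df$length_mm, mean)
  list(NoS = WeightedConnectome(nos, "NoS", subjectId, nodeIds(parc)),
       LoS = WeightedConnectome(los, "LoS", subjectId, nodeIds(parc)))
}

#' Build the SIFT2-weighted network
#'
#' Edge weight is the sum of SIFT2 streamline weights per node pair.
#'
#' @inheritParams buildNosLos
#' @return A [WeightedConnectome-class] ("SIFT2").
#' @export
buildSift2 <- function(table, parc, subjectId = "group") {
  df <- streamlines(table)
  W <- .aggregateEdges(table, parc, df$w_sift2, sum)
  WeightedConnectome(W, "SIFT2", subjectId, nodeIds(parc))
}

#' Build the COMMIT-weighted network
#'
#' Edge weight is the length-weighted sum of COMMIT streamline weights,
#' \deqn{\alpha_{ij} = \sum_{k=1}^{N_{ij}} x_{ijk} \, l_k / \bar L_{ij},}
#' where \eqn{x_{ijk}} is the COMMIT weight of streamline k, \eqn{l_k} its
#' length and \eqn{\bar L_{ij}} the mean streamline length of the pair.
#' Interpretable as total intra-axonal cross-sectional area.
#'
#' @inheritParams buildNosLos
#' @return A [WeightedConnectome-class] ("COMMIT").
#' @export
#' @examples
#' p <- Parcellation(c("A", "B"), c("VIS", "VIS"), c(1000, 1000),
#'                   matrix(rnorm(6), 2))
#' df <- data.frame(node_i = "A", node_j = "B", length_mm = c(10, 20),
#'                  w_commit = c(2, 4), w_sift2 = 0, med_R1 = 1, med_FA = 0.4,
#'                  med_RD = 0.6, med_ICVF = 0.5)
#' st <- StreamlineTable(df, p)
#' connMatrix(buildCommit(st, p))[1, 2]  # (2*10 + 4*20) / 15 = 100/15
buildCommit <- function(table, parc, subjectId = "group") {
  df <- streamlines(table)
  if (nrow(df) && any(df$length_mm <= 0))
    stop("nonpositive streamline length encountered in COMMIT aggregation")
  num <- .aggregateEdges(table, parc, df$w_commit * df$length_mm, sum)
  lbar <- .aggregateEdges(table, parc, df$length_mm, mean)
  W <- num
  nz <- lbar > 0
  W[nz] <- num[nz] / lbar[nz]
  WeightedConnectome(W, "COMMIT", subjectId, nodeIds(parc))
}

#' Build a tractometry-weighted network
#'
#' Edge weight is the mean across streamlines of the per-streamline metric
#' median (median-along-streamline, mean-across-streamlines).
#'
#' @inheritParams buildNosLos
#' @param metric one of \code{"R1"}, \code{"FA"}, \code{"RD"}, \code{"ICVF"}.
#' @return A [WeightedConnectome-class] tagged with \code{metric}.
#' @export
buildTractometry <- function(table, parc, metric, subjectId = "group") {
  if (!metric %in% names(.metric_cols))
    stop("unknown tractometry metric '", metric, "'; expected one of ",
         paste(names(.metric_cols), collapse = ", "))
  df <- streamlines(table)
  col <- .metric_cols[[metric]]
  W <- .aggregateEdges(table, parc, df[[col]], mean)
  WeightedConnectome(W, metric, subjectId, nodeIds(parc))
}

#' Normalize edge weights by node volume
#'
#' Divides each edge weight by the mean volume of its two endpoints:
#' \eqn{W'_{ij} = 2 W_{ij} / (v_i + v_j)}. Symmetric in the endpoints and
#' the identity when all volumes are 1.
#'
#' @param net a [WeightedConnectome-class].
#' @param parc the [Parcellation-class] carrying node volumes (mm^3).
#' @return The volume-normalized [WeightedConnectome-class].
#' @export
volumeNormalize <- function(net, parc) {
  v <- volumes(parc)
  if (any(v <= 0)) stop("node volumes must be strictly positive")
  W <- connMatrix(net)
  denom <- outer(v, v, `+`) / 2
  W <- W / denom
  diag(W) <- 0
  WeightedConnectome(W, weightName(net), subjectId(net), nodeIds(net))
}

#' Build a functional connectivity network from node time series
#'
#' Pairwise Pearson correlation of node time series, Fisher Z-transformed
#' (\code{atanh}), with r clipped to |r| <= 1 - 1e-15 so edge weights stay
#' finite. Diagonal is 0.
#'
#' @param timeSeries numeric nodes x T matrix of node-averaged time series.
#' @param subjectId subject tag.
#' @param nodeIds optional node identifiers (default: rownames).
#' @return A [WeightedConnectome-class] ("FC").
#' @export
buildFc <- function(timeSeries, subjectId = "group", nodeIds = NULL) {
  X <- as.matrix(timeSeries)
  if (ncol(X) < 3L) stop("need at least 3 time points")
  sds <- apply(X, 1, sd)
  if (any(sds == 0))
    stop("constant time series at node(s): ",
         paste(head(which(sds == 0)), collapse = ", "))
  r <- cor(t(X))
  clip <- 1 - 1e-15
  r[r > clip] <- clip
  r[r < -clip] <- -clip
  Z <- atanh(r)
  diag(Z) <- 0
  Z <- (Z + t(Z)) / 2
  if (is.null(nodeIds)) nodeIds <- rownames(X)
  WeightedConnectome(Z, "FC", subjectId, nodeIds = nodeIds)
}

#' Group-consensus edge mask
#'
#' An edge is retained iff it is nonzero in at least \code{fraction} of the
#' subjects (ties at exactly the threshold are retained).
#'
#' @param ensemble a [SubjectEnsemble-class].
#' @param fraction consensus fraction in (0, 1]; default 0.5.
#' @return A binary [WeightedConnectome-class] mask.
#' @export
consensusMask <- function(ensemble, fraction = 0.5) {
  mats <- lapply(subjects(ensemble), connMatrix)
  cnt <- Reduce(`+`, lapply(mats, function(W) (W != 0) * 1))
  M <- (cnt >= fraction * length(mats)) * 1
  diag(M) <- 0
  WeightedConnectome(M, "binary", "group", nodeIds(subjects(ensemble)[[1]]))
}

#' Zero edges with sub-threshold COMMIT weight in every weighting
#'
#' Within each subject, any edge whose COMMIT weight is below the threshold
#' is set to 0 in all weighted networks, enforcing a uniform binary
#' connectivity map across weightings within subject.
#'
#' @param ensembles named list of [SubjectEnsemble-class] (one per weighting).
#' @param commitEnsemble the COMMIT [SubjectEnsemble-class]; subject order
#'   must match every ensemble in \code{ensembles}.
#' @param threshold edge-level COMMIT threshold (default \code{1e-12}).
#' @return The filtered named list of ensembles.
#' @export
applyCommitEdgeFilter <- function(ensembles, commitEnsemble,
                                  threshold = 1e-12) {
  ns <- nSubjects(commitEnsemble)
  commitSubs <- subjects(commitEnsemble)
  lapply(ensembles, function(ens) {
    if (nSubjects(ens) != ns)
      stop("subject count mismatch between '", weightName(ens),
           "' ensemble and COMMIT ensemble")
    subs <- mapply(function(s, cs) {
      if (subjectId(s) != subjectId(cs))
        stop("subject order mismatch: ", subjectId(s), " vs ", subjectId(cs))
      W <- connMatrix(s)
      W[connMatrix(cs) < threshold] <- 0
      WeightedConnectome(W, weightName(s), subjectId(s), nodeIds(s))
    }, subjects(ens), commitSubs, SIMPLIFY = FALSE)
    SubjectEnsemble(subs, parcellation(ens), weightName(ens))
  })
}

#' Group-average network under a consensus mask
#'
#' For each masked edge, the mean across subjects with a nonzero value at
#' that edge; edges outside the mask, and masked edges that are zero in
#' every subject, are 0.
#'
#' @param ensemble a [SubjectEnsemble-class].
#' @param mask binary [WeightedConnectome-class] from [consensusMask()].
#' @return A group-level [WeightedConnectome-class]; the attribute
#'   \code{allZeroMaskedEdges} counts masked edges with no nonzero subject.
#' @export
groupAverage <- function(ensemble, mask) {
  mats <- lapply(subjects(ensemble), connMatrix)
  M <- connMatrix(mask)
  tot <- Reduce(`+`, mats)
  cnt <- Reduce(`+`, lapply(mats, function(W) (W != 0) * 1))
  W <- matrix(0, nrow(M), ncol(M))
  nz <- cnt > 0 & M != 0
  W[nz] <- tot[nz] / cnt[nz]
  out <- WeightedConnectome(W, weightName(ensemble), "group",
                            nodeIds(subjects(ensemble)[[1]]))
  attr(out, "allZeroMaskedEdges") <- sum(M[upper.tri(M)] != 0 & cnt[upper.tri(cnt)] == 0)
  out
}

#' Build all structural weightings for one subject
#'
#' Runs the full single-subject construction: NoS/LoS/SIFT2 from the
#' streamline-filtered table, then COMMIT and the four tractometry
#' weightings from the COMMIT-filtered table (streamlines with COMMIT
#' weight below \code{threshold} dropped), and finally node-volume
#' normalization of NoS, SIFT2 and COMMIT.
#'
#' @param table a [StreamlineTable-class] (streamline-filtered).
#' @param parc the [Parcellation-class].
#' @param subjectId subject tag.
#' @param threshold streamline-level COMMIT threshold.
#' @return Named list of eight [WeightedConnectome-class] objects
#'   (NoS, LoS, SIFT2, COMMIT, R1, FA, RD, ICVF).
#' @export
buildAllWeights <- function(table, parc, subjectId = "group",
                            threshold = 1e-12) {
  noslos <- buildNosLos(table, parc, subjectId)
  sift2 <- buildSift2(table, parc, subjectId)
  filt <- commitFilter(table, threshold)
  commit <- buildCommit(filt, parc, subjectId)
  tracto <- lapply(names(.metric_cols), function(m)
    buildTractometry(filt, parc, m, subjectId))
  names(tracto) <- names(.metric_cols)
  out <- c(list(NoS = volumeNormalize(noslos$NoS, parc),
                LoS = noslos$LoS,
                SIFT2 = volumeNormalize(sift2, parc),
                COMMIT = volumeNormalize(commit, parc)),
           tracto)
  out
}
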