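## Weighted graph measures and their null-normalized summaries:
## Onnela clustering, -log weight-to-length transform and characteristic
## path length, small-worldness, centrality panel and hubness scores,
## and raw/normalized rich-club curves.

# internal: igraph object weighted by -log lengths (positive edges only)
.lengthGraph <- function(net, wmax = NULL) {
  L <- weightToLength(net, wmax)
  n <- nrow(L)
  idx <- which(is.finite(L) & upper.tri(L), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(idx)) {
    g <- igraph::add_edges(g, t(idx))
    igraph::E(g)$weight <- L[idx]
  }
  g
}

#' Onnela weighted clustering coefficient
#'
#' Per-node geometric-mean triangle intensity on weights max-normalized to
#' [0, 1]: with \eqn{\hat W = W / \max W} and \eqn{A = \hat W^{1/3}}
#' (elementwise), \eqn{C_i = (A^3)_{ii} / (k_i (k_i - 1))} where \eqn{k_i}
#' is the binary degree. Nodes with \eqn{k_i < 2} have \eqn{C_i = 0}.
#' Reduces to the binary triangle fraction for 0/1 weights.
#'
#' @param net a [WeightedConnectome-class] with nonnegative weights.
#' @return Named numeric vector of per-node clustering coefficients.
#' @export
weightedClustering <- function(net) {
  W <- connMatrix(net)
  mx <- max(W)
  k <- rowSums(W != 0)
  out <- numeric(nrow(W))
  if (mx > 0) {
    A <- (W / mx)^(1/3)
    tri <- diag(A %*% A %*% A)
    ok <- k >= 2
    out[ok] <- tri[ok] / (k[ok] * (k[ok] - 1))
  }
  names(out) <- rownames(W)
  out
}

#' Weight-to-length transform
#'
#' \eqn{L_{ij} = -\log(W_{ij} / w_{max})} with weights max-normalized so
#' every length is nonnegative (the strongest edge has length 0); absent
#' edges have infinite length.
#'
#' @param net a [WeightedConnectome-class].
#' @param wmax normalizing weight; defaults to the network maximum.
#' @return Numeric matrix of edge lengths (Inf for absent edges, 0 diagonal).
#' @export
weightToLength <- function(net, wmax = NULL) {
  W <- connMatrix(net)
  if (is.null(wmax)) wmax <- max(W)
  if (wmax <= 0) stop("network has no positive weights")
  if (max(W) > wmax * (1 + 1e-12))
    stop("weights exceed the normalizing maximum; lengths would be negative")
  L <- matrix(Inf, nrow(W), ncol(W), dimnames = dimnames(W))
  nz <- W > 0
  L[nz] <- -log(W[nz] / wmax)
  diag(L) <- 0
  L
}

#' Characteristic path length
#'
#' Mean shortest-path distance on the \eqn{-\log} length graph over all
#' reachable ordered node pairs (self-pairs excluded). Disconnected
#' networks are computed on reachable pairs and flagged via the
#' \code{disconnected} attribute.
#'
#' @param net a [WeightedConnectome-class].
#' @param wmax normalizing weight for [weightToLength()].
#' @return Scalar characteristic path length with attribute
#'   \code{disconnected} (logical).
#' @export
charPathLength <- function(net, wmax = NULL) {
  g <- .lengthGraph(net, wmax)
  D <- igraph::distances(g, algorithm = "dijkstra")
  off <- D[row(D) != col(D)]
  reach <- is.finite(off)
  if (!any(reach)) stop("network is fully disconnected; path length undefined")
  out <- mean(off[reach])
  attr(out, "disconnected") <- any(!reach)
  out
}

#' Null-normalized small-worldness
#'
#' \eqn{S = (C / C_{null}) / (L / L_{null})}: per-node clustering is
#' normalized by the null-ensemble mean for that node and then averaged
#' across nodes; characteristic path length is normalized by the null mean.
#' Nulls are degree- and strength-preserving surrogates (see
#' [generateNullEnsemble()]); \eqn{S > 1} indicates small-world topology.
#'
#' @param net a connected [WeightedConnectome-class].
#' @param nNulls number of surrogate networks (default 50).
#' @param seed integer seed for surrogate generation.
#' @param nulls optional pre-built [NullEnsemble-class]; overrides
#'   \code{nNulls}/\code{seed}.
#' @param params surrogate parameters passed to [generateNullEnsemble()].
#' @return List of class \code{"SmallWorldReport"}: \code{S}, \code{Cnorm},
#'   \code{Lnorm}, raw \code{C} (per node) and \code{L}, \code{nNulls},
#'   \code{seed}, \code{excludedNodes}.
#' @export
smallWorldness <- function(net, nNulls = 50, seed = NULL, nulls = NULL,
                           params = list()) {
  if (is.null(nulls)) {
    if (is.null(seed)) stop("provide either a seed or a pre-built null ensemble")
    nulls <- generateNullEnsemble(net, nNulls, "weighted-degree-strength",
                                  params, seed)
  }
  surro <- surrogates(nulls)
  cObs <- weightedClustering(net)
  lObs <- as.numeric(charPathLength(net))
  cNull <- rowMeans(vapply(surro, weightedClustering, numeric(length(cObs))))
  lNull <- mean(vapply(surro, function(s) as.numeric(charPathLength(s)),
                       numeric(1)))
  usable <- cNull > 0
  if (!any(usable)) stop("all nodes have zero null-mean clustering")
  Cnorm <- mean(cObs[usable] / cNull[usable])
  Lnorm <- lObs / lNull
  structure(list(S = Cnorm / Lnorm, Cnorm = Cnorm, Lnorm = Lnorm,
                 C = cObs, L = lObs, nNulls = length(surro),
                 seed = nulls@seed, excludedNodes = sum(!usable)),
            class = "SmallWorldReport")
}

#' @export
print.SmallWorldReport <- function(x, ...) {
  cat(sprintf("Small-worldness S = %.3f (C/Cnull = %.3f, L/Lnull = %.3f, %d nulls)\n",
              x$S, x$Cnorm, x$Lnorm, x$nNulls))
  invisible(x)
}

# internal: eigenvector centrality by power iteration on the weight matrix
.powerEigen <- function(W, tol = 1e-10, maxIter = 10000L) {
  n <- nrow(W)
  v <- rep(1 / sqrt(n), n)
  # shift guarantees convergence for bipartite-like spectra
  shift <- max(rowSums(W)) * 1e-3 + 1e-12
  for (it in seq_len(maxIter)) {
    vn <- as.numeric(W %*% v) + shift * v
    nv <- sqrt(sum(vn^2))
    if (nv == 0) stop("eigenvector centrality undefined: zero iterate")
    vn <- vn / nv
    if (max(abs(vn - v)) < tol) return(abs(vn))
    v <- vn
  }
  stop("eigenvector centrality did not converge in ", maxIter, " iterations")
}

#' Nodewise centrality panel
#'
#' Computes, per node: strength (row sum of weights), betweenness and
#' closeness on the \eqn{-\log} length graph, eigenvector centrality of the
#' weight matrix (power iteration, tolerance 1e-10), and the Onnela
#' clustering coefficient.
#'
#' @param net a connected, nonnegative [WeightedConnectome-class].
#' @return A data.frame of class \code{"HubnessTable"} with columns
#'   \code{node}, \code{strength}, \code{betweenness}, \code{closeness},
#'   \code{eigenvector}, \code{clustering} (and \code{score = NA} until
#'   [hubnessScores()] is applied).
#' @export
centralityPanel <- function(net) {
  W <- connMatrix(net)
  g <- .lengthGraph(net)
  # strictly positive lengths required by igraph's shortest-path routines;
  # zero-length (max-weight) edges are nudged by an eps far below the
  # graph's own length scale but far above double rounding, so geodesic
  # counting stays numerically well-posed
  wts <- igraph::E(g)$weight
  minPos <- suppressWarnings(min(wts[wts > 0]))
  eps <- if (is.finite(minPos)) max(minPos * 1e-6, 1e-5) else 1
  wts[wts <= 0] <- eps
  btw <- igraph::betweenness(g, weights = wts, directed = FALSE)
  cls <- igraph::closeness(g, weights = wts, mode = "all")
  out <- data.frame(node = rownames(W) %||% as.character(seq_len(nrow(W))),
                    strength = rowSums(W),
                    betweenness = as.numeric(btw),
                    closeness = as.numeric(cls),
                    eigenvector = .powerEigen(W),
                    clustering = as.numeric(weightedClustering(net)),
                    score = NA_integer_,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("HubnessTable", "data.frame")
  out
}

#' Composite hubness scores (0-5)
#'
#' +1 point for membership in the top \eqn{\lceil 0.2N \rceil} nodes by
#' strength, betweenness, closeness and eigenvector centrality, and +1 for
#' the bottom \eqn{\lceil 0.2N \rceil} by clustering coefficient. Rank ties
#' are broken deterministically by node index.
#'
#' @param panel a \code{HubnessTable} from [centralityPanel()].
#' @return The table with the \code{score} column filled (integers 0-5).
#' @export
hubnessScores <- function(panel) {
  n <- nrow(panel)
  m <- ceiling(0.2 * n)
  topSet <- function(x) head(order(-x, seq_along(x)), m)
  botSet <- function(x) head(order(x, seq_along(x)), m)
  score <- integer(n)
  for (col in c("strength", "betweenness", "closeness", "eigenvector"))
    score[topSet(panel[[col]])] <- score[topSet(panel[[col]])] + 1L
  score[botSet(panel$clustering)] <- score[botSet(panel$clustering)] + 1L
  panel$score <- score
  panel
}

#' Euclidean distance between hubness vectors
#'
#' \eqn{D_{ab} = \sqrt{\sum_{nodes} (score_a - score_b)^2}} for every pair
#' of weightings.
#'
#' @param tables named list of \code{HubnessTable}s (scores filled) or of
#'   numeric score vectors, all on the same node set.
#' @return Symmetric numeric matrix of pairwise distances.
#' @export
hubnessDistance <- function(tables) {
  vecs <- lapply(tables, function(t) {
    if (is.data.frame(t)) {
      if (anyNA(t$score)) stop("hubness scores not filled; run hubnessScores()")
      setNames(as.numeric(t$score), t$node)
    } else as.numeric(t)
  })
  lens <- lengths(vecs)
  if (length(unique(lens)) != 1L) stop("hubness vectors differ in node count")
  nm <- names(vecs)
  nodeRef <- names(vecs[[1]])
  if (!is.null(nodeRef)) {
    for (v in vecs) if (!is.null(names(v)) && !identical(names(v), nodeRef))
      stop("hubness vectors are on different node sets")
  }
  D <- matrix(0, length(vecs), length(vecs), dimnames = list(nm, nm))
  for (a in seq_along(vecs)) for (b in seq_along(vecs))
    D[a, b] <- sqrt(sum((vecs[[a]] - vecs[[b]])^2))
  D
}

#' Raw rich-club curves
#'
#' For each degree level \eqn{k} from 1 to (max degree - 1), the subnetwork
#' of nodes with binary degree \eqn{> k} is extracted. The binary
#' coefficient is the subnetwork density
#' \eqn{\phi(k) = 2 E_{>k} / (N_{>k} (N_{>k} - 1))}; the weighted
#' coefficient divides the total weight inside the subnetwork by the sum of
#' the \eqn{E_{>k}} largest edge weights anywhere in the network. Levels
#' with fewer than 2 qualifying nodes are \code{NaN}.
#'
#' @param net a [WeightedConnectome-class].
#' @return A data.frame of class \code{"RichClubCurve"} with columns
#'   \code{k} and \code{phi}; attribute \code{weighted} records the
#'   variant.
#' @export
richClubWeighted <- function(net) .richClub(net, weighted = TRUE)

#' @rdname richClubWeighted
#' @export
richClubBinary <- function(net) .richClub(net, weighted = FALSE)

.richClub <- function(net, weighted) {
  W <- connMatrix(net)
  A <- (W != 0) * 1
  deg <- rowSums(A)
  kmax <- max(deg)
  ut <- upper.tri(W)
  wSorted <- sort(W[ut & W != 0], decreasing = TRUE)
  ks <- seq_len(max(kmax - 1, 1))
  phi <- rep(NaN, length(ks))
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    sel <- deg > k
    nk <- sum(sel)
    if (nk < 2) next
    sub <- W[sel, sel, drop = FALSE]
    ek <- sum(sub[upper.tri(sub)] != 0)
    if (weighted) {
      if (ek == 0) next
      phi[idx] <- sum(sub[upper.tri(sub)]) / sum(wSorted[seq_len(ek)])
    } else {
      phi[idx] <- 2 * ek / (nk * (nk - 1))
    }
  }
  out <- data.frame(k = ks, phi = phi)
  attr(out, "weighted") <- weighted
  class(out) <- c("RichClubCurve", "data.frame")
  out
}

#' Null-normalized rich-club curve
#'
#' \eqn{\phi_{norm}(k) = \phi(k) / \langle \phi_{null}(k) \rangle}, the raw
#' curve divided by the null-ensemble mean at each k. A rich club is
#' detected over the maximal contiguous k ranges with
#' \eqn{\phi_{norm} > 1}.
#'
#' @param raw a \code{RichClubCurve} from [richClubWeighted()] or
#'   [richClubBinary()].
#' @param nulls a [NullEnsemble-class] of matching kind (weighted curves
#'   need degree- and strength-preserving nulls).
#' @return A data.frame of class \code{"RichClubCurve"} with columns
#'   \code{k}, \code{phi}, \code{phiNull}, \code{phiNorm}; attribute
#'   \code{detected} lists the contiguous detection ranges (two-column
#'   matrix of k bounds).
#' @export
normalizeRichClub <- function(raw, nulls) {
  weighted <- attr(raw, "weighted")
  if (weighted && nulls@kind != "weighted-degree-strength")
    stop("weighted rich-club curves require weighted-degree-strength nulls")
  fn <- if (weighted) richClubWeighted else richClubBinary
  nullPhi <- vapply(surrogates(nulls), function(s) {
    cv <- fn(s)
    if (nrow(cv) != nrow(raw))
      stop("null surrogate has a different degree range than the observed network")
    cv$phi
  }, numeric(nrow(raw)))
  nullMean <- rowMeans(matrix(nullPhi, nrow = nrow(raw)), na.rm = FALSE)
  phiNorm <- raw$phi / nullMean
  phiNorm[!is.na(nullMean) & nullMean == 0] <- NaN
  out <- data.frame(k = raw$k, phi = raw$phi, phiNull = nullMean,
                    phiNorm = phiNorm)
  det <- which(!is.na(phiNorm) & phiNorm > 1)
  ranges <- NULL
  if (length(det)) {
    brk <- c(0, which(diff(det) > 1), length(det))
    ranges <- t(vapply(seq_len(length(brk) - 1), function(b)
      c(out$k[det[brk[b] + 1]], out$k[det[brk[b + 1]]]), numeric(2)))
    colnames(ranges) <- c("kmin", "kmax")
  }
  attr(out, "weighted") <- weighted
  attr(out, "detected") <- ranges
  class(out) <- c("RichClubCurve", "data.frame")
  out
}
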