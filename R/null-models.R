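## Degree-preserving (Maslov-Sneppen) and degree- and strength-preserving
## (rewire-then-anneal) surrogate networks used to normalize topology.

# internal: 0-based canonical edge list of the binary map
.edgeList0 <- function(W) {
  idx <- which(W != 0 & upper.tri(W), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  cbind(as.integer(idx[, 1] - 1L), as.integer(idx[, 2] - 1L))
}

.matrixFromEdges0 <- function(edges, weights, n) {
  W <- matrix(0, n, n)
  W[cbind(edges[, 1] + 1L, edges[, 2] + 1L)] <- weights
  W[cbind(edges[, 2] + 1L, edges[, 1] + 1L)] <- weights
  W
}

#' Degree-preserving rewiring (double-edge swaps)
#'
#' Repeated Maslov-Sneppen double-edge swaps: two edges (a-b), (c-d) are
#' replaced by (a-d), (c-b), rejecting proposals that would create
#' self-loops or multi-edges. The degree sequence is preserved exactly.
#'
#' @param net a [WeightedConnectome-class]; its binary map is rewired.
#' @param swapsPerEdge attempted swaps per edge (default 100, so the total
#'   attempt budget is \code{100 * |E|}).
#' @param seed integer seed.
#' @param attempts optional explicit total attempt budget, overriding
#'   \code{swapsPerEdge}.
#' @return A binary [WeightedConnectome-class] with attributes
#'   \code{attempted} and \code{accepted} (swap counts). Graphs admitting
#'   no valid swap are returned unchanged with a warning.
#' @export
rewireDegreePreserving <- function(net, swapsPerEdge = 100, seed,
                                   attempts = NULL) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  W <- connMatrix(net)
  edges <- .edgeList0(W)
  if (nrow(edges) < 2L) stop("need at least 2 edges to rewire")
  if (is.null(attempts)) attempts <- swapsPerEdge * nrow(edges)
  res <- withSeed(seed, .rewire_ms_cpp(edges, nrow(W), as.double(attempts)))
  if (res$accepted == 0)
    warning("no admissible swap was accepted; graph returned unchanged")
  out <- WeightedConnectome(.matrixFromEdges0(res$edges, 1, nrow(W)),
                            "binary", subjectId(net), nodeIds(net))
  attr(out, "attempted") <- attempts
  attr(out, "accepted") <- res$accepted
  out
}

#' Place a weight multiset to approximate a strength sequence
#'
#' Assigns a fixed multiset of edge weights to a fixed binary topology so
#' that node strengths approach a target sequence, by simulated annealing
#' over weight swaps between edge pairs. Energy is
#' \eqn{E = \sum_i (s_i - s_i^{target})^2}; moves are accepted when they
#' lower E, or with probability \eqn{\exp(-\Delta E / T)} otherwise, with
#' geometric cooling per sweep (one sweep = |E| proposals). The best state
#' seen is returned; the weight multiset is untouched.
#'
#' @param topology binary [WeightedConnectome-class] defining the edges.
#' @param weights numeric multiset, one weight per edge of the topology.
#' @param targetStrengths numeric target strength per node.
#' @param anneal list of schedule parameters: \code{t0frac} (initial
#'   temperature as a fraction of initial energy, default 0.05),
#'   \code{cooling} (geometric factor per sweep, default 0.996),
#'   \code{maxSweeps} (default 2e4), \code{stagnation} (early stop after
#'   this many sweeps without improvement, default 400). The defaults
#'   favour placement quality over speed; pass a smaller \code{maxSweeps}
#'   for large surrogate ensembles.
#' @param seed integer seed.
#' @param initPermute randomly permute the weights before annealing
#'   (default TRUE; FALSE keeps the given edge-to-weight assignment).
#' @return A [WeightedConnectome-class] with attributes \code{energy}
#'   (best E), \code{trace} (best E per sweep) and \code{sweeps}.
#' @export
matchStrengthSequence <- function(topology, weights, targetStrengths,
                                  anneal = list(), seed, initPermute = TRUE) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  a <- modifyList(list(t0frac = 0.05, cooling = 0.996, maxSweeps = 20000L,
                       stagnation = 400L), anneal)
  W <- connMatrix(topology)
  edges <- .edgeList0(W)
  if (length(weights) != nrow(edges))
    stop("weight multiset size (", length(weights),
         ") != edge count of topology (", nrow(edges), ")")
  if (length(targetStrengths) != nrow(W))
    stop("target strength length != node count")
  res <- withSeed(seed, {
    w0 <- if (initPermute) sample(weights) else weights
    .anneal_strength_cpp(edges, as.double(w0), as.double(targetStrengths),
                         a$t0frac, a$cooling, as.integer(a$maxSweeps),
                         as.integer(a$stagnation))
  })
  out <- WeightedConnectome(.matrixFromEdges0(edges, res$weights, nrow(W)),
                            weightName(topology), subjectId(topology),
                            nodeIds(topology))
  attr(out, "energy") <- res$energy
  attr(out, "trace") <- res$trace
  attr(out, "sweeps") <- res$sweeps
  out
}

#' Generate an ensemble of surrogate networks
#'
#' \code{kind = "binary-degree"}: Maslov-Sneppen rewired surrogates with
#' the exact degree sequence (default budget 100 attempted swaps per edge).
#' \code{kind = "weighted-degree-strength"}: the binary topology is rewired
#' (default budget 1e6 attempted swaps per surrogate), then the original
#' weight multiset is re-placed by simulated annealing to approximate the
#' original strength sequence. Surrogates are independent, with child seeds
#' derived deterministically from \code{seed}.
#'
#' @param net the observed [WeightedConnectome-class].
#' @param nNulls number of surrogates.
#' @param kind \code{"weighted-degree-strength"} or \code{"binary-degree"}.
#' @param params list overriding defaults: \code{swapsPerEdge} (binary),
#'   \code{totalSwaps} (weighted rewiring budget), \code{anneal} (schedule
#'   list as in [matchStrengthSequence()]).
#' @param seed integer master seed.
#' @return A [NullEnsemble-class].
#' @export
generateNullEnsemble <- function(net, nNulls = 50,
                                 kind = c("weighted-degree-strength",
                                          "binary-degree"),
                                 params = list(), seed) {
  if (missing(seed)) stop("a seed is required for reproducibility")
  kind <- match.arg(kind)
  W <- connMatrix(net)
  edges <- .edgeList0(W)
  nEdges <- nrow(edges)
  p <- modifyList(list(swapsPerEdge = 100, totalSwaps = 1e6, anneal = list()),
                  params)
  weights <- W[cbind(edges[, 1] + 1L, edges[, 2] + 1L)]
  target <- rowSums(W)
  surro <- vector("list", nNulls)
  traces <- vector("list", nNulls)
  swaps <- if (kind == "binary-degree") p$swapsPerEdge * nEdges else p$totalSwaps
  for (k in seq_len(nNulls)) {
    sk <- childSeed(seed, k)
    if (kind == "binary-degree") {
      surro[[k]] <- rewireDegreePreserving(net, seed = sk, attempts = swaps)
      traces[[k]] <- numeric(0)
    } else {
      topo <- rewireDegreePreserving(net, seed = sk, attempts = swaps)
      s <- matchStrengthSequence(topo, weights, target, anneal = p$anneal,
                                 seed = childSeed(seed, 100000 + k))
      surro[[k]] <- WeightedConnectome(connMatrix(s), weightName(net),
                                       subjectId(net), nodeIds(net))
      attr(surro[[k]], "energy") <- attr(s, "energy")
      traces[[k]] <- attr(s, "trace")
    }
  }
  new("NullEnsemble", kind = kind, surrogates = surro, seed = as.numeric(seed),
      swaps = as.numeric(swaps), annealTrace = traces)
}
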