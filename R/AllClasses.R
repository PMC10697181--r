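#' @import methods
#' @importFrom stats quantile cor sd rnorm runif rlnorm rgamma rbinom median
#'   complete.cases lm.fit ks.test qnorm pnorm qlnorm setNames
#' @importFrom utils head tail
#' @useDynLib wbnet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Canonical label sets shared across the package ---------------------------

#' Canonical resting-state module labels
#'
#' The eight module labels used throughout: subcortex plus the seven
#' canonical cortical resting-state networks.
#'
#' @return Character vector of the eight module labels.
#' @export
#' @examples moduleLevels()
moduleLevels <- function() {
  c("SUB", "VIS", "SMN", "DAN", "SVAN", "LIMB", "CONT", "DMN")
}

#' Recognized network weightings
#'
#' The eight structural weightings (streamline-specific: NoS, LoS, SIFT2,
#' COMMIT; tractometry: R1, FA, RD, ICVF) plus functional connectivity
#' ("FC") and the unweighted map ("binary").
#'
#' @return Character vector of weight names.
#' @export
#' @examples weightLevels()
weightLevels <- function() {
  c("NoS", "LoS", "SIFT2", "COMMIT", "R1", "FA", "RD", "ICVF", "FC", "binary")
}

## Parcellation --------------------------------------------------------------

#' Parcellation of the brain into network nodes
#'
#' Holds the node set shared by all networks of a cohort: unique node
#' identifiers, human-readable labels, module assignment (one of
#' \code{moduleLevels()}), node volumes in mm^3 and 3-D centroid
#' coordinates in mm.
#'
#' @slot nodeIds character, unique node identifiers (defines node order).
#' @slot labels character, one label per node.
#' @slot module factor with levels \code{moduleLevels()}.
#' @slot volume numeric, strictly positive node volumes (mm^3).
#' @slot coords numeric matrix, nodes x 3 (mm).
#'
#' @seealso [Parcellation()], [readParcellation()]
#' @export
setClass("Parcellation",
  representation(
    nodeIds = "character",
    labels  = "character",
    module  = "factor",
    volume  = "numeric",
    coords  = "matrix"
  )
)

setValidity("Parcellation", function(object) {
  n <- length(object@nodeIds)
  msg <- character()
  if (n < 2L) msg <- c(msg, "parcellation must have at least 2 nodes")
  if (anyDuplicated(object@nodeIds)) msg <- c(msg, "node_ids must be unique")
  if (length(object@labels) != n) msg <- c(msg, "labels length != node count")
  if (length(object@module) != n) msg <- c(msg, "module length != node count")
  if (!identical(levels(object@module), moduleLevels()))
    msg <- c(msg, "module levels must be exactly the canonical level set")
  if (anyNA(object@module)) msg <- c(msg, "module labels outside the declared level set")
  if (length(object@volume) != n) msg <- c(msg, "volume length != node count")
  if (!all(is.finite(object@volume)) || any(object@volume <= 0))
    msg <- c(msg, "volumes must be finite and strictly positive")
  if (!is.numeric(object@coords) || !identical(dim(object@coords), c(n, 3L)))
    msg <- c(msg, "coords must be a numeric nodes x 3 matrix")
  if (length(msg)) msg else TRUE
})

#' Construct a Parcellation
#'
#' @param nodeIds character vector of unique node identifiers.
#' @param module character or factor of module assignments; values must be
#'   drawn from \code{moduleLevels()}.
#' @param volume positive node volumes (mm^3).
#' @param coords numeric nodes x 3 matrix of centroid coordinates (mm).
#' @param labels optional node labels; defaults to \code{nodeIds}.
#'
#' @return A [Parcellation-class] object.
#' @export
#' @examples
#' p <- Parcellation(c("A", "B"), c("VIS", "SMN"), c(900, 1100),
#'                   matrix(0, 2, 3))
#' nNodes(p)
Parcellation <- function(nodeIds, module, volume, coords, labels = nodeIds) {
  module <- factor(as.character(module), levels = moduleLevels())
  coords <- as.matrix(coords)
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  new("Parcellation", nodeIds = as.character(nodeIds),
      labels = as.character(labels), module = module,
      volume = as.numeric(volume), coords = coords)
}

## StreamlineTable -----------------------------------------------------------

#' Table of per-streamline records
#'
#' One row per tractography streamline: canonicalized endpoints
#' (node_i < node_j in parcellation order), length in mm, per-streamline
#' COMMIT and SIFT2 weights, and per-streamline medians of the tractometry
#' metrics (R1, FA, RD, ICVF).
#'
#' @slot streamlines data.frame with columns \code{node_i}, \code{node_j},
#'   \code{length_mm}, \code{w_commit}, \code{w_sift2}, \code{med_R1},
#'   \code{med_FA}, \code{med_RD}, \code{med_ICVF}.
#'
#' @seealso [StreamlineTable()], [commitFilter()]
#' @export
setClass("StreamlineTable", representation(streamlines = "data.frame"))

.streamline_cols <- c("node_i", "node_j", "length_mm", "w_commit", "w_sift2",
                      "med_R1", "med_FA", "med_RD", "med_ICVF")
.metric_cols <- c(R1 = "med_R1", FA = "med_FA", RD = "med_RD", ICVF = "med_ICVF")

setValidity("StreamlineTable", function(object) {
  df <- object@streamlines
  msg <- character()
  missing_cols <- setdiff(.streamline_cols, names(df))
  if (length(missing_cols))
    return(sprintf("missing required column(s): %s",
                   paste(missing_cols, collapse = ", ")))
  if (nrow(df)) {
    if (any(df$node_i == df$node_j)) msg <- c(msg, "self-pairs are not allowed")
    if (!all(is.finite(df$length_mm)) || any(df$length_mm <= 0))
      msg <- c(msg, "streamline lengths must be finite and positive")
    if (any(df$w_commit < 0) || any(df$w_sift2 < 0))
      msg <- c(msg, "streamline weights must be nonnegative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a StreamlineTable
#'
#' Endpoints are canonicalized so that \code{node_i < node_j} in
#' parcellation order; rows whose endpoints are absent from the
#' parcellation are rejected (pass \code{dropUnknown = TRUE} to emulate
#' tractogram-level streamline filtering and silently drop them).
#'
#' @param df data.frame with the columns documented in
#'   [StreamlineTable-class].
#' @param parcellation a [Parcellation-class]; endpoints are validated and
#'   canonicalized against its node order.
#' @param dropUnknown drop rows with endpoints outside the parcellation
#'   instead of erroring.
#'
#' @return A [StreamlineTable-class] object.
#' @export
StreamlineTable <- function(df, parcellation, dropUnknown = FALSE) {
  df <- as.data.frame(df)
  missing_cols <- setdiff(.streamline_cols, names(df))
  if (length(missing_cols))
    stop("streamline table missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  ids <- nodeIds(parcellation)
  ii <- match(as.character(df$node_i), ids)
  jj <- match(as.character(df$node_j), ids)
  unknown <- is.na(ii) | is.na(jj)
  if (any(unknown)) {
    if (dropUnknown) {
      df <- df[!unknown, , drop = FALSE]
      ii <- ii[!unknown]; jj <- jj[!unknown]
    } else {
      stop(sum(unknown), " streamline(s) have endpoints absent from the parcellation")
    }
  }
  swap <- ii > jj
  df$node_i <- ifelse(swap, ids[jj], ids[ii])
  df$node_j <- ifelse(swap, ids[ii], ids[jj])
  rownames(df) <- NULL
  new("StreamlineTable", streamlines = df[, .streamline_cols, drop = FALSE])
}

## WeightedConnectome --------------------------------------------------------

#' A single weighted connectome
#'
#' Symmetric node x node matrix with zero diagonal, tagged with the
#' weighting scheme and subject identifier. Structural weightings are
#' nonnegative; FC entries (Fisher-Z correlations) may be negative.
#'
#' @slot matrix symmetric numeric matrix, zero diagonal, node ids as dimnames.
#' @slot weightName one of \code{weightLevels()}.
#' @slot subjectId subject identifier, or \code{"group"}.
#'
#' @seealso [WeightedConnectome()], [connMatrix()], [readMatrix()]
#' @export
setClass("WeightedConnectome",
  representation(matrix = "matrix", weightName = "character",
                 subjectId = "character"))

setValidity("WeightedConnectome", function(object) {
  W <- object@matrix
  msg <- character()
  if (!is.numeric(W) || nrow(W) != ncol(W)) msg <- c(msg, "matrix must be square numeric")
  if (!all(is.finite(W))) msg <- c(msg, "matrix entries must be finite")
  else {
    if (!isTRUE(all.equal(W, t(W), tolerance = 1e-12, check.attributes = FALSE)))
      msg <- c(msg, "matrix must be exactly symmetric")
    if (any(diag(W) != 0)) msg <- c(msg, "diagonal must be zero")
    if (object@weightName != "FC" && any(W < 0))
      msg <- c(msg, "structural weights must be nonnegative")
  }
  if (length(object@weightName) != 1L || !object@weightName %in% weightLevels())
    msg <- c(msg, sprintf("weightName must be one of: %s",
                          paste(weightLevels(), collapse = ", ")))
  if (length(object@subjectId) != 1L) msg <- c(msg, "subjectId must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a WeightedConnectome
#'
#' @param W square numeric matrix (symmetric, zero diagonal).
#' @param weightName one of \code{weightLevels()}.
#' @param subjectId subject identifier (default \code{"group"}).
#' @param nodeIds optional node identifiers used as dimnames.
#'
#' @return A [WeightedConnectome-class] object.
#' @export
#' @examples
#' W <- matrix(c(0, 1, 1, 0), 2, 2)
#' wc <- WeightedConnectome(W, "NoS", "sub-01")
WeightedConnectome <- function(W, weightName, subjectId = "group",
                               nodeIds = NULL) {
  W <- as.matrix(W)
  if (is.null(nodeIds)) {
    nodeIds <- rownames(W)
    if (is.null(nodeIds)) nodeIds <- sprintf("n%03d", seq_len(nrow(W)))
  }
  dimnames(W) <- list(nodeIds, nodeIds)
  new("WeightedConnectome", matrix = W, weightName = weightName,
      subjectId = as.character(subjectId))
}

## SubjectEnsemble -----------------------------------------------------------

#' Per-subject connectomes on one parcellation
#'
#' An ordered collection of same-weighting connectomes from different
#' subjects, sharing a single parcellation. Supports consensus masking and
#' group averaging.
#'
#' @slot parcellation the shared [Parcellation-class].
#' @slot weightName shared weighting of all members.
#' @slot subjects list of [WeightedConnectome-class].
#'
#' @seealso [SubjectEnsemble()], [consensusMask()], [groupAverage()]
#' @export
setClass("SubjectEnsemble",
  representation(parcellation = "Parcellation", weightName = "character",
                 subjects = "list"))

setValidity("SubjectEnsemble", function(object) {
  msg <- character()
  n <- length(object@parcellation@nodeIds)
  if (length(object@subjects) < 1L) msg <- c(msg, "ensemble needs >= 1 subject")
  for (s in object@subjects) {
    if (!is(s, "WeightedConnectome")) { msg <- c(msg, "subjects must be WeightedConnectome"); break }
    if (nrow(s@matrix) != n) { msg <- c(msg, "subject matrix shape != parcellation"); break }
    if (s@weightName != object@weightName) { msg <- c(msg, "mixed weightName in ensemble"); break }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SubjectEnsemble
#'
#' @param subjects list of [WeightedConnectome-class] sharing one weighting.
#' @param parcellation the shared [Parcellation-class].
#' @param weightName weighting; defaults to the first subject's.
#'
#' @return A [SubjectEnsemble-class] object.
#' @export
SubjectEnsemble <- function(subjects, parcellation,
                            weightName = subjects[[1]]@weightName) {
  new("SubjectEnsemble", parcellation = parcellation,
      weightName = weightName, subjects = subjects)
}

## NullEnsemble --------------------------------------------------------------

#' Ensemble of rewired surrogate networks
#'
#' Degree-preserving (binary) or degree- and strength-preserving (weighted)
#' surrogates of one observed network, with generation provenance.
#'
#' @slot kind \code{"binary-degree"} or \code{"weighted-degree-strength"}.
#' @slot surrogates list of [WeightedConnectome-class].
#' @slot seed master seed used for the ensemble.
#' @slot swaps integer, attempted swaps per surrogate.
#' @slot annealTrace list of numeric best-energy traces (weighted kind only).
#'
#' @seealso [generateNullEnsemble()]
#' @export
setClass("NullEnsemble",
  representation(kind = "character", surrogates = "list", seed = "numeric",
                 swaps = "numeric", annealTrace = "list"))

setValidity("NullEnsemble", function(object) {
  if (!object@kind %in% c("binary-degree", "weighted-degree-strength"))
    return("kind must be 'binary-degree' or 'weighted-degree-strength'")
  if (!length(object@surrogates)) return("ensemble is empty")
  TRUE
})

## Generics and accessors ----------------------------------------------------

#' @rdname Parcellation-class
#' @param object,x object to query.
#' @export
setGeneric("nNodes", function(object) standardGeneric("nNodes"))
#' @rdname Parcellation-class
#' @export
setMethod("nNodes", "Parcellation", function(object) length(object@nodeIds))
#' @rdname WeightedConnectome-class
#' @param object object to query.
#' @export
setMethod("nNodes", "WeightedConnectome", function(object) nrow(object@matrix))

#' @rdname Parcellation-class
#' @export
setGeneric("nodeIds", function(object) standardGeneric("nodeIds"))
#' @rdname Parcellation-class
#' @export
setMethod("nodeIds", "Parcellation", function(object) object@nodeIds)
#' @rdname WeightedConnectome-class
#' @export
setMethod("nodeIds", "WeightedConnectome", function(object) rownames(object@matrix))

#' @rdname Parcellation-class
#' @export
setGeneric("modules", function(object) standardGeneric("modules"))
#' @rdname Parcellation-class
#' @export
setMethod("modules", "Parcellation", function(object) object@module)

#' @rdname Parcellation-class
#' @export
setGeneric("volumes", function(object) standardGeneric("volumes"))
#' @rdname Parcellation-class
#' @export
setMethod("volumes", "Parcellation", function(object) object@volume)

#' @rdname Parcellation-class
#' @export
setGeneric("nodeCoords", function(object) standardGeneric("nodeCoords"))
#' @rdname Parcellation-class
#' @export
setMethod("nodeCoords", "Parcellation", function(object) object@coords)

#' @rdname WeightedConnectome-class
#' @export
setGeneric("connMatrix", function(object) standardGeneric("connMatrix"))
#' @rdname WeightedConnectome-class
#' @export
setMethod("connMatrix", "WeightedConnectome", function(object) object@matrix)

#' @rdname WeightedConnectome-class
#' @export
setGeneric("weightName", function(object) standardGeneric("weightName"))
#' @rdname WeightedConnectome-class
#' @export
setMethod("weightName", "WeightedConnectome", function(object) object@weightName)
#' @rdname SubjectEnsemble-class
#' @export
setMethod("weightName", "SubjectEnsemble", function(object) object@weightName)

#' @rdname WeightedConnectome-class
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname WeightedConnectome-class
#' @export
setMethod("subjectId", "WeightedConnectome", function(object) object@subjectId)

#' @rdname SubjectEnsemble-class
#' @param object object to query.
#' @export
setGeneric("subjects", function(object) standardGeneric("subjects"))
#' @rdname SubjectEnsemble-class
#' @export
setMethod("subjects", "SubjectEnsemble", function(object) object@subjects)

#' @rdname SubjectEnsemble-class
#' @export
setGeneric("nSubjects", function(object) standardGeneric("nSubjects"))
#' @rdname SubjectEnsemble-class
#' @export
setMethod("nSubjects", "SubjectEnsemble", function(object) length(object@subjects))

#' @rdname SubjectEnsemble-class
#' @export
setGeneric("parcellation", function(object) standardGeneric("parcellation"))
#' @rdname SubjectEnsemble-class
#' @export
setMethod("parcellation", "SubjectEnsemble", function(object) object@parcellation)

#' @rdname StreamlineTable-class
#' @param object object to query.
#' @export
setGeneric("streamlines", function(object) standardGeneric("streamlines"))
#' @rdname StreamlineTable-class
#' @export
setMethod("streamlines", "StreamlineTable", function(object) object@streamlines)

#' @rdname NullEnsemble-class
#' @param object object to query.
#' @export
setGeneric("surrogates", function(object) standardGeneric("surrogates"))
#' @rdname NullEnsemble-class
#' @export
setMethod("surrogates", "NullEnsemble", function(object) object@surrogates)

#' @rdname StreamlineTable-class
#' @param x a StreamlineTable.
#' @export
setMethod("nrow", "StreamlineTable", function(x) base::nrow(x@streamlines))

## show methods --------------------------------------------------------------

setMethod("show", "Parcellation", function(object) {
  cat(sprintf("Parcellation: %d nodes, %d modules represented\n",
              nNodes(object), nlevels(droplevels(object@module))))
  tab <- table(object@module)
  cat("  modules:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "StreamlineTable", function(object) {
  df <- object@streamlines
  cat(sprintf("StreamlineTable: %d streamlines, %d node pairs\n",
              base::nrow(df),
              if (base::nrow(df)) base::nrow(unique(df[, c("node_i", "node_j")])) else 0L))
})

setMethod("show", "WeightedConnectome", function(object) {
  W <- object@matrix
  ut <- W[upper.tri(W)]
  cat(sprintf("WeightedConnectome '%s' [%s]: %d nodes, %d edges, density %.3f\n",
              object@weightName, object@subjectId, nrow(W), sum(ut != 0),
              mean(ut != 0)))
})

setMethod("show", "SubjectEnsemble", function(object) {
  cat(sprintf("SubjectEnsemble '%s': %d subjects x %d nodes\n",
              object@weightName, nSubjects(object), nNodes(object@parcellation)))
})

setMethod("show", "NullEnsemble", function(object) {
  cat(sprintf("NullEnsemble (%s): %d surrogates, %g attempted swaps each\n",
              object@kind, length(object@surrogates), object@swaps))
})
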