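## Delimited-text readers/writers and edge vectorization.
##
## File contracts:
##  - connectome matrix: CSV, header row + first column of node ids,
##    "." decimal, UTF-8; values round-trip at >= 12 significant digits.
##  - streamline table: TSV, columns node_i, node_j, length_mm, w_commit,
##    w_sift2, med_R1, med_FA, med_RD, med_ICVF.
##  - parcellation: TSV, columns node_id, label, module, volume_mm3, x, y, z,
##    plus a JSON sidecar (<path>.json) recording the module level set.

#' Read a connectome matrix from CSV
#'
#' Reads a square numeric CSV with a header row and a leading node-id
#' column. Inputs whose relative asymmetry is below 1e-10 are symmetrized
#' as (W + t(W))/2; larger asymmetries are rejected.
#'
#' @param path CSV file path.
#' @param expectedNodes optional node count to enforce.
#' @param weightName weighting tag for the result (default "binary" if the
#'   matrix is 0/1, else "NoS").
#' @param subjectId subject tag for the result.
#'
#' @return A [WeightedConnectome-class].
#' @export
readMatrix <- function(path, expectedNodes = NULL, weightName = NULL,
                       subjectId = "group") {
  dt <- data.table::fread(path, header = TRUE, sep = ",", data.table = FALSE)
  if (ncol(dt) < 2L) stop("matrix file has no value columns: ", path)
  ids <- as.character(dt[[1]])
  W <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(W) <- "double"
  if (nrow(W) != ncol(W))
    stop("non-square matrix (", nrow(W), " x ", ncol(W), ") in ", path)
  if (!identical(ids, colnames(W)))
    stop("row and column node ids disagree in ", path)
  if (!is.null(expectedNodes) && nrow(W) != expectedNodes)
    stop("expected ", expectedNodes, " nodes, found ", nrow(W))
  if (anyNA(W) || !all(is.finite(W)))
    stop("matrix contains NaN/Inf entries: ", path)
  if (relAsymmetry(W) > 1e-10)
    stop("matrix asymmetry exceeds 1e-10 relative tolerance: ", path)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  if (is.null(weightName))
    weightName <- if (all(W %in% c(0, 1))) "binary" else "NoS"
  WeightedConnectome(W, weightName, subjectId, nodeIds = ids)
}

#' Write a connectome matrix to CSV
#'
#' @param net a [WeightedConnectome-class].
#' @param path destination CSV path.
#' @return The path, invisibly.
#' @export
writeMatrix <- function(net, path) {
  W <- connMatrix(net)
  df <- data.frame(node_id = rownames(W), W, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = ",")
  invisible(path)
}

#' Read / write a streamline table (TSV)
#'
#' One streamline per row; see [StreamlineTable-class] for the column
#' contract. Reading validates endpoints against the parcellation and
#' canonicalizes them to \code{node_i < node_j}.
#'
#' @param path TSV path.
#' @param parcellation a [Parcellation-class] for endpoint validation.
#' @param dropUnknown drop rows with endpoints outside the parcellation.
#' @return [StreamlineTable-class] (read) or the path (write).
#' @export
readStreamlines <- function(path, parcellation, dropUnknown = FALSE) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = c("node_i", "node_j")))
  missing_cols <- setdiff(.streamline_cols, names(df))
  if (length(missing_cols))
    stop("streamline file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  StreamlineTable(df, parcellation, dropUnknown = dropUnknown)
}

#' @rdname readStreamlines
#' @param table a [StreamlineTable-class] to write.
#' @export
writeStreamlines <- function(table, path) {
  data.table::fwrite(streamlines(table), path, sep = "\t")
  invisible(path)
}

#' Read / write a parcellation (TSV + JSON sidecar)
#'
#' The TSV holds node_id, label, module, volume_mm3, x, y, z; the JSON
#' sidecar (\code{<path>.json}) records the module level set so that the
#' categorical coding survives round trips.
#'
#' @param path TSV path.
#' @return [Parcellation-class] (read) or the path (write).
#' @export
readParcellation <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = c("node_id", "label", "module")))
  req <- c("node_id", "label", "module", "volume_mm3", "x", "y", "z")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols))
    stop("parcellation file missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  sidecar <- paste0(path, ".json")
  lv <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE)$module_levels
  else moduleLevels()
  if (!identical(sort(lv), sort(moduleLevels())))
    stop("sidecar module levels differ from the canonical level set")
  bad <- setdiff(unique(df$module), moduleLevels())
  if (length(bad))
    stop("unknown module label(s): ", paste(bad, collapse = ", "))
  Parcellation(df$node_id, df$module, df$volume_mm3,
               as.matrix(df[, c("x", "y", "z")]), labels = df$label)
}

#' @rdname readParcellation
#' @param parc a [Parcellation-class] to write.
#' @export
writeParcellation <- function(parc, path) {
  df <- data.frame(node_id = nodeIds(parc), label = parc@labels,
                   module = as.character(modules(parc)),
                   volume_mm3 = volumes(parc), nodeCoords(parc),
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path, sep = "\t")
  jsonlite::write_json(list(module_levels = moduleLevels()),
                       paste0(path, ".json"), auto_unbox = FALSE)
  invisible(path)
}

#' Vectorize the upper triangle of a connectome
#'
#' Returns the i < j edge values in deterministic lexicographic order by
#' (i, j), optionally restricted to the nonzero entries of a mask.
#'
#' @param net a [WeightedConnectome-class].
#' @param mask optional same-shape [WeightedConnectome-class]; only edges
#'   with nonzero mask entries are kept.
#' @return A data.frame of class \code{"EdgeVector"} with columns \code{i},
#'   \code{j} (1-based node indices), \code{node_i}, \code{node_j},
#'   \code{value}, and attributes \code{weightName}, \code{subjectId}.
#' @export
#' @examples
#' wc <- WeightedConnectome(matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3), "NoS")
#' edgeVectorize(wc)$value
edgeVectorize <- function(net, mask = NULL) {
  W <- connMatrix(net)
  n <- nrow(W)
  pairs <- upperPairs(n)
  keep <- rep(TRUE, nrow(pairs))
  if (!is.null(mask)) {
    M <- connMatrix(mask)
    if (!identical(dim(M), dim(W)))
      stop("mask shape ", nrow(M), "x", ncol(M),
           " does not match matrix shape ", n, "x", n)
    keep <- M[pairs] != 0
  }
  pairs <- pairs[keep, , drop = FALSE]
  ids <- rownames(W)
  out <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    node_i = ids[pairs[, 1]], node_j = ids[pairs[, 2]],
                    value = W[pairs], stringsAsFactors = FALSE)
  attr(out, "weightName") <- weightName(net)
  attr(out, "subjectId") <- subjectId(net)
  attr(out, "nNodes") <- n
  class(out) <- c("EdgeVector", "data.frame")
  out
}

#' Rebuild a connectome from an edge vector
#'
#' Inverse of [edgeVectorize()]: entries absent from the edge vector are 0.
#'
#' @param ev an \code{EdgeVector} from [edgeVectorize()].
#' @param nNodes node count (default: recorded in the edge vector).
#' @param nodeIds optional node identifiers.
#' @return A [WeightedConnectome-class].
#' @export
edgeDevectorize <- function(ev, nNodes = attr(ev, "nNodes"), nodeIds = NULL) {
  W <- matrix(0, nNodes, nNodes)
  W[cbind(ev$i, ev$j)] <- ev$value
  W <- W + t(W)
  WeightedConnectome(W, attr(ev, "weightName") %||% "NoS",
                     attr(ev, "subjectId") %||% "group", nodeIds = nodeIds)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
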