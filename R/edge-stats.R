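## Edge-weight variability (quartile coefficient of dispersion), module
## summaries, edge-length binning, residualized correlations and
## permutation testing.

#' Quartile coefficient of dispersion
#'
#' \eqn{CQD = (Q_3 - Q_1) / (Q_3 + Q_1)}, a robust relative-variability
#' measure suited to heavy-tailed edge-weight distributions. Quartiles use
#' linear interpolation between order statistics (quantile type 7). For
#' nonnegative data, CQD lies in [0, 1] and is invariant to positive
#' rescaling.
#'
#' @param values numeric vector, length >= 2.
#' @return The CQD, or \code{NaN} (with a warning) when \eqn{Q_3 + Q_1 = 0}.
#' @export
#' @examples
#' cqd(1:8)  # (6.25 - 2.75) / 9
cqd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2L) return(NA_real_)
  q <- quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  denom <- q[2] + q[1]
  if (denom == 0) {
    warning("CQD undefined: Q1 + Q3 = 0")
    return(NaN)
  }
  (q[2] - q[1]) / denom
}

#' Intra- and inter-subject edge-weight variability
#'
#' \code{intraSubjectCqd} computes, per subject, the CQD across that
#' subject's nonzero masked edge weights. \code{interSubjectCqd} computes,
#' per masked edge, the CQD across subjects (zero values excluded from the
#' sample; edges with fewer than 2 usable values are \code{NA}).
#' \code{nodeMeanInterCqd} averages the inter-subject edge CQD over the
#' edges incident to each node.
#'
#' @param ensemble a [SubjectEnsemble-class].
#' @param mask binary [WeightedConnectome-class] restricting the edge set.
#' @return \code{intraSubjectCqd}: named numeric, one value per subject.
#'   \code{interSubjectCqd}: an \code{EdgeVector} data.frame of per-edge CQD.
#'   \code{nodeMeanInterCqd}: named numeric, one value per node.
#' @export
intraSubjectCqd <- function(ensemble, mask) {
  M <- connMatrix(mask)
  ut <- upper.tri(M)
  out <- vapply(subjects(ensemble), function(s) {
    w <- connMatrix(s)[ut & M != 0]
    cqd(w[w != 0])
  }, numeric(1))
  names(out) <- vapply(subjects(ensemble), subjectId, character(1))
  out
}

#' @rdname intraSubjectCqd
#' @export
interSubjectCqd <- function(ensemble, mask) {
  ev <- edgeVectorize(subjects(ensemble)[[1]], mask)
  vals <- vapply(subjects(ensemble), function(s)
    connMatrix(s)[cbind(ev$i, ev$j)], numeric(nrow(ev)))
  vals <- matrix(vals, nrow = nrow(ev))
  ev$value <- apply(vals, 1, function(w) {
    w <- w[w != 0]
    if (length(w) < 2L) NA_real_ else cqd(w)
  })
  attr(ev, "weightName") <- weightName(ensemble)
  attr(ev, "subjectId") <- "inter-subject-CQD"
  ev
}

#' @rdname intraSubjectCqd
#' @export
nodeMeanInterCqd <- function(ensemble, mask) {
  ev <- interSubjectCqd(ensemble, mask)
  n <- nNodes(parcellation(ensemble))
  out <- vapply(seq_len(n), function(v) {
    x <- ev$value[ev$i == v | ev$j == v]
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  }, numeric(1))
  names(out) <- nodeIds(parcellation(ensemble))
  out
}

#' Edge-length bin scheme: five linear bins plus a wide tail bin
#'
#' Splits the observed length range into six bins: bins 1-5 of equal width
#' \eqn{w = (max - min)/8} and a final bin of width \eqn{3w} absorbing the
#' long tail. Values on a boundary fall in the lower bin; the global
#' maximum falls in bin 6.
#'
#' @param lengths numeric edge lengths (mm); needs >= 6 distinct values.
#' @return List of class \code{"BinScheme"}: \code{edges} (7 breakpoints),
#'   \code{w} (base width), \code{rule} (\code{"5xw + 1x3w"}).
#' @export
makeBins <- function(lengths) {
  lengths <- lengths[is.finite(lengths)]
  if (length(unique(lengths)) < 6L)
    stop("need at least 6 distinct edge lengths to build the bin scheme")
  lo <- min(lengths); hi <- max(lengths)
  if (hi == lo) stop("all edge lengths equal; bin width undefined")
  w <- (hi - lo) / 8
  edges <- c(lo + (0:5) * w, hi)
  structure(list(edges = edges, w = w, rule = "5xw + 1x3w"),
            class = "BinScheme")
}

#' Assign lengths to bins
#'
#' @param lengths numeric lengths.
#' @param bins a \code{BinScheme} from [makeBins()].
#' @return Integer bin index in 1..6 (\code{NA} outside the scheme's range).
#' @export
binAssign <- function(lengths, bins) {
  lo <- bins$edges[1]; w <- bins$w
  idx <- ceiling((lengths - lo) / w)
  idx[lengths == lo] <- 1L
  idx[idx >= 6L] <- 6L
  idx[lengths < lo | lengths > bins$edges[7]] <- NA_integer_
  as.integer(idx)
}

#' Per-bin edge statistics across edge-length bins
#'
#' Computes a statistic within each edge-length bin: either the CQD of
#' \code{values}, or the Spearman correlation of \code{values} with
#' \code{other}. With \code{proportion = TRUE} the per-bin values are
#' divided by the within-network maximum over bins.
#'
#' @param values numeric edge values.
#' @param lengths numeric edge lengths aligned with \code{values}.
#' @param bins a \code{BinScheme}; default built from \code{lengths}.
#' @param stat \code{"cqd"} or \code{"spearman"}.
#' @param other second vector for \code{stat = "spearman"}.
#' @param proportion divide per-bin statistics by their maximum over bins.
#' @return data.frame with columns \code{bin}, \code{n}, \code{stat}.
#' @export
binnedStatistic <- function(values, lengths, bins = makeBins(lengths),
                            stat = c("cqd", "spearman"), other = NULL,
                            proportion = FALSE) {
  stat <- match.arg(stat)
  if (stat == "spearman" && is.null(other))
    stop("stat = 'spearman' requires 'other'")
  idx <- binAssign(lengths, bins)
  out <- data.frame(bin = 1:6, n = 0L, stat = NA_real_)
  for (b in 1:6) {
    sel <- which(idx == b)
    out$n[b] <- length(sel)
    if (length(sel) >= 3L) {
      out$stat[b] <- if (stat == "cqd") cqd(values[sel])
                     else spearmanRho(values[sel], other[sel])
    }
  }
  if (proportion) {
    m <- max(out$stat, na.rm = TRUE)
    if (is.finite(m) && m != 0) out$stat <- out$stat / m
  }
  out
}

#' Group edges by module membership
#'
#' Classifies each nonzero masked edge under two schemes: (1) within- vs
#' between-module; (2) unimodal (both endpoints in VIS or SMN), transmodal
#' (both endpoints in DAN, SVAN, CONT or DMN), or between (all remaining
#' edges, including any touching SUB or LIMB). Each edge belongs to exactly
#' one group per scheme.
#'
#' @param net a [WeightedConnectome-class].
#' @param parc the [Parcellation-class] with module assignments.
#' @param mask optional binary mask.
#' @return List with \code{edges} (data.frame: value, scheme labels) and
#'   \code{summary} (median and quartiles per group per scheme).
#' @export
moduleEdgeSummary <- function(net, parc, mask = NULL) {
  ev <- edgeVectorize(net, mask)
  ev <- ev[ev$value != 0, , drop = FALSE]
  mod <- as.character(modules(parc))
  mi <- mod[ev$i]; mj <- mod[ev$j]
  withinBetween <- ifelse(mi == mj, "within", "between")
  uni <- c("VIS", "SMN"); trans <- c("DAN", "SVAN", "CONT", "DMN")
  zone <- rep("between", nrow(ev))
  zone[mi %in% uni & mj %in% uni] <- "unimodal"
  zone[mi %in% trans & mj %in% trans] <- "transmodal"
  edges <- data.frame(value = ev$value, module_i = mi, module_j = mj,
                      within_between = withinBetween, zone = zone,
                      stringsAsFactors = FALSE)
  summarize <- function(split) {
    do.call(rbind, lapply(names(split), function(g) {
      v <- split[[g]]
      data.frame(group = g, n = length(v),
                 q1 = if (length(v)) quantile(v, 0.25, names = FALSE) else NA_real_,
                 median = if (length(v)) median(v) else NA_real_,
                 q3 = if (length(v)) quantile(v, 0.75, names = FALSE) else NA_real_)
    }))
  }
  if (length(unique(mod)) < 2L)
    warning("single-module parcellation: 'between' groups are empty")
  list(edges = edges,
       summary = list(
         within_between = summarize(split(edges$value, edges$within_between)),
         zone = summarize(split(edges$value, edges$zone))))
}

#' Residualize edge values on edge length
#'
#' Ordinary least-squares fit \code{value ~ length}; returns the residuals.
#' By OLS orthogonality the residuals have zero sample correlation with the
#' lengths (to numerical tolerance).
#'
#' @param values numeric edge values (or an \code{EdgeVector}).
#' @param lengths numeric edge lengths aligned with \code{values}.
#' @return Numeric residual vector (same order as input).
#' @export
residualizeOnLength <- function(values, lengths) {
  if (inherits(values, "EdgeVector")) values <- values$value
  if (inherits(lengths, "EdgeVector")) lengths <- lengths$value
  if (length(values) != length(lengths)) stop("values/lengths length mismatch")
  if (length(values) < 3L) stop("need at least 3 edges to residualize")
  if (sd(lengths) == 0) stop("degenerate regression: constant edge lengths")
  fit <- lm.fit(cbind(1, lengths), values)
  as.numeric(fit$residuals)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties; \code{NA} values are
#' pairwise-deleted.
#'
#' @param x,y aligned numeric vectors (>= 3 complete pairs).
#' @return Spearman's rho, or \code{NaN} (flagged with a warning) when a
#'   vector is constant.
#' @export
spearmanRho <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) return(NA_real_)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("Spearman undefined for constant vector")
    return(NaN)
  }
  cor(x, y, method = "spearman")
}

#' One-sided permutation test for an edgewise Spearman correlation
#'
#' The observed statistic is \code{spearmanRho(x, y)}. The null sample is
#' the statistic under \code{nPerm} independent uniform permutations of
#' \code{y}; the one-sided p value counts null draws at least as extreme as
#' the observation in the observed direction,
#' \eqn{p = (1 + \#\{extreme\}) / (nPerm + 1)}.
#'
#' @param x,y aligned numeric vectors.
#' @param nPerm number of permutations (default 10000; < 100 warns).
#' @param seed integer seed; the result is a pure function of the inputs
#'   and the seed.
#' @param direction \code{"auto"} (default) takes the one-sided direction
#'   from the sign of the observed statistic, as in exploratory reporting;
#'   \code{"greater"}/\code{"less"} fix the tested tail, the calibrated
#'   choice when the alternative is known a priori (under the null the
#'   sign-chosen p value is uniform on (0, 1/2), the fixed-tail p value on
#'   (0, 1)).
#' @return List of class \code{"PermutationResult"}: \code{observed},
#'   \code{null} (numeric, length \code{nPerm}), \code{p}, \code{direction}
#'   (+1/-1), \code{nPerm}, \code{seed}.
#' @export
permutationPvalue <- function(x, y, nPerm = 10000, seed,
                              direction = c("auto", "greater", "less")) {
  direction <- match.arg(direction)
  if (missing(seed)) stop("a seed is required for reproducibility")
  if (nPerm < 100) warning("nPerm < 100 gives a very coarse p value")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  observed <- spearmanRho(x, y)
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  # Pearson on ranks; means/sds of the rank vectors are permutation-invariant
  rx <- rx - mean(rx); ry <- ry - mean(ry)
  denom <- sqrt(sum(rx^2) * sum(ry^2))
  nullRho <- withSeed(seed, {
    vapply(seq_len(nPerm), function(k)
      sum(rx * ry[sample.int(n)]) / denom, numeric(1))
  })
  dir <- switch(direction,
                auto = if (observed >= 0) 1 else -1,
                greater = 1, less = -1)
  extreme <- if (dir > 0) sum(nullRho >= observed) else sum(nullRho <= observed)
  p <- (1 + extreme) / (nPerm + 1)
  structure(list(observed = observed, null = nullRho, p = p,
                 direction = dir, nPerm = nPerm, seed = seed),
            class = "PermutationResult")
}

#' @export
print.PermutationResult <- function(x, ...) {
  cat(sprintf("Permutation test: rho = %.4f, one-sided p = %.4g (%d permutations, seed %d)\n",
              x$observed, x$p, x$nPerm, as.integer(x$seed)))
  invisible(x)
}
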