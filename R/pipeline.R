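## End-to-end orchestration: simulate -> build -> stats -> nulls/topology,
## with JSON config validation, per-stage logging, hash-based stage
## skipping and a reproducibility manifest.

.presets <- list(
  desk = list(nNodes = 90, nSubjects = 10, nNullsSmallWorld = 20,
              nNullsRichClub = 50, nPerm = 1000, totalSwaps = 2e4,
              swapsPerEdge = 20,
              topologyWeights = c("COMMIT", "NoS", "R1")),
  paper = list(nNodes = 414, nSubjects = 50, nNullsSmallWorld = 50,
               nNullsRichClub = 1000, nPerm = 10000, totalSwaps = 1e6,
               swapsPerEdge = 100,
               topologyWeights = c("NoS", "SIFT2", "COMMIT", "R1", "FA",
                                   "RD", "ICVF"))
)

.configDefaults <- function(preset = "desk") {
  p <- .presets[[preset]]
  list(preset = preset, seed = 1L,
       stages = c("simulate", "build", "stats", "topology"),
       nNodes = p$nNodes, nSubjects = p$nSubjects,
       consensus = 0.5, commitThreshold = 1e-12, bins = 6L,
       nPerm = p$nPerm, nNullsSmallWorld = p$nNullsSmallWorld,
       nNullsRichClub = p$nNullsRichClub, totalSwaps = p$totalSwaps,
       swapsPerEdge = p$swapsPerEdge, topologyWeights = p$topologyWeights,
       generator = list())
}

#' Validate a pipeline configuration
#'
#' Reads a JSON configuration (or takes a list), fills preset defaults
#' (\code{"desk"} scales everything down; \code{"paper"} pins the
#' full-scale constants: 50\% consensus, 1e-12 COMMIT threshold, 6 bins,
#' 50/1,000 nulls, 1e6 rewires), rejects unknown keys and range
#' violations.
#'
#' @param config path to a JSON file, or a named list (possibly empty).
#' @param preset \code{"desk"} or \code{"paper"}; a \code{preset} entry in
#'   the config takes precedence.
#' @return A validated list of class \code{"RunConfig"}.
#' @export
validateConfig <- function(config = list(), preset = "desk") {
  if (is.character(config)) {
    config <- if (file.exists(config) && file.size(config) > 0)
      jsonlite::read_json(config, simplifyVector = TRUE) else list()
  }
  if (!is.null(config$preset)) preset <- config$preset
  if (!preset %in% names(.presets)) stop("unknown preset '", preset, "'")
  def <- .configDefaults(preset)
  unknown <- setdiff(names(config), c(names(def), "preset"))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg <- modifyList(def, config)
  cfg$preset <- preset
  rangeCheck <- function(key, ok) if (!ok)
    stop("configuration value out of range for '", key, "'")
  rangeCheck("consensus", cfg$consensus > 0 && cfg$consensus <= 1)
  rangeCheck("commitThreshold", cfg$commitThreshold >= 0)
  rangeCheck("bins", cfg$bins == 6L)
  rangeCheck("nPerm", cfg$nPerm >= 1)
  rangeCheck("nNodes", cfg$nNodes >= 16)
  rangeCheck("nSubjects", cfg$nSubjects >= 1)
  if (preset == "paper") {
    cfg$consensus <- 0.5
    cfg$commitThreshold <- 1e-12
    cfg$nNullsSmallWorld <- 50L
    cfg$nNullsRichClub <- 1000L
    cfg$totalSwaps <- 1e6
    cfg$swapsPerEdge <- 100
  }
  structure(cfg, class = c("RunConfig", "list"))
}

.log <- function(stage, ...) {
  kv <- c(...)
  message(sprintf("[%s] stage=%s %s", format(Sys.time(), "%H:%M:%S"), stage,
                  paste(names(kv), unname(kv), sep = "=", collapse = " ")))
}

.hashFiles <- function(paths) {
  paths <- paths[file.exists(paths)]
  as.list(tools::md5sum(paths))
}

.stageUnchanged <- function(manifest, stage, inputHash, cfgHash) {
  old <- manifest$stages[[stage]]
  !is.null(old) && identical(old$inputs, inputHash) &&
    identical(old$config, cfgHash) &&
    all(file.exists(unlist(old$outputs %||% character())))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in dependency order under one master seed,
#' writing all artifacts beneath \code{out}: \code{simulate} (parcellation,
#' per-subject streamline TSVs and FC matrices), \code{build} (per-subject
#' and group CSV matrices per weighting, consensus mask, build report),
#' \code{stats} (per-subject correlations, CQD tables, binned statistics,
#' permutation p values), \code{topology} (null-normalized small-world
#' reports, rich-club curves, hubness tables and distances). Stages whose
#' inputs and configuration are unchanged since the previous run are
#' skipped; a manifest JSON records config and file hashes and all seeds.
#'
#' @param config a \code{RunConfig} from [validateConfig()] (or a list/path
#'   accepted by it).
#' @param out output directory.
#' @return The manifest, invisibly (also written to
#'   \code{<out>/manifest.json}).
#' @export
runPipeline <- function(config = list(), out) {
  cfg <- if (inherits(config, "RunConfig")) config else validateConfig(config)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(cfg), file.path(out, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifestPath <- file.path(out, "manifest.json")
  manifest <- if (file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = FALSE)
    else list(stages = list())
  manifest$config <- unclass(cfg)
  cfgHash <- function(keys) digestConfig(cfg[keys])
  scNames <- c("NoS", "LoS", "SIFT2", "COMMIT", "R1", "FA", "RD", "ICVF")

  cohort <- NULL
  needCohort <- function() {
    if (is.null(cohort)) {
      gen <- do.call(generatorConfig,
                     modifyList(list(nNodes = cfg$nNodes,
                                     nSubjects = cfg$nSubjects,
                                     seed = cfg$seed), cfg$generator))
      cohort <<- generateCohort(gen, consensus = cfg$consensus,
                                commitThreshold = cfg$commitThreshold)
    }
    cohort
  }

  ## ---- simulate ----
  if ("simulate" %in% cfg$stages) {
    stage <- "simulate"
    h <- cfgHash(c("seed", "nNodes", "nSubjects", "generator",
                   "consensus", "commitThreshold"))
    if (.stageUnchanged(manifest, stage, list(), h)) {
      .log(stage, skipped = "inputs-unchanged")
    } else {
      co <- needCohort()
      simDir <- file.path(out, "simulate")
      dir.create(simDir, showWarnings = FALSE)
      writeParcellation(co$parcellation, file.path(simDir, "parcellation.tsv"))
      outs <- c(file.path(simDir, "parcellation.tsv"))
      for (s in names(co$tables)) {
        p <- file.path(simDir, sprintf("streamlines_%s.tsv", s))
        writeStreamlines(co$tables[[s]], p)
        outs <- c(outs, p)
      }
      for (fc in subjects(co$ensembles$FC)) {
        p <- file.path(simDir, sprintf("fc_%s.csv", subjectId(fc)))
        writeMatrix(fc, p)
        outs <- c(outs, p)
      }
      .log(stage, subjects = cfg$nSubjects,
           streamlines = nrow(co$baseTable), seed = cfg$seed)
      manifest$stages[[stage]] <- list(inputs = list(), config = h,
                                       outputs = as.list(outs),
                                       hashes = .hashFiles(outs))
    }
  }

  ## ---- build ----
  if ("build" %in% cfg$stages) {
    stage <- "build"
    simDir <- file.path(out, "simulate")
    inFiles <- list.files(simDir, pattern = "^(streamlines_|parcellation)",
                          full.names = TRUE)
    inHash <- .hashFiles(inFiles)
    h <- cfgHash(c("consensus", "commitThreshold"))
    if (.stageUnchanged(manifest, stage, inHash, h)) {
      .log(stage, skipped = "inputs-unchanged")
    } else {
      parc <- readParcellation(file.path(simDir, "parcellation.tsv"))
      stFiles <- sort(list.files(simDir, pattern = "^streamlines_",
                                 full.names = TRUE))
      subjectsIds <- sub("^streamlines_(.*)\\.tsv$", "\\1", basename(stFiles))
      removedTotal <- 0L; keptTotal <- 0L
      nets <- list()
      for (k in seq_along(stFiles)) {
        tab <- readStreamlines(stFiles[k], parc)
        filt <- commitFilter(tab, cfg$commitThreshold)
        removedTotal <- removedTotal + attr(filt, "removed")
        keptTotal <- keptTotal + attr(filt, "retained")
        nets[[k]] <- buildAllWeights(tab, parc, subjectsIds[k],
                                     cfg$commitThreshold)
      }
      ensembles <- lapply(scNames, function(w)
        SubjectEnsemble(lapply(nets, `[[`, w), parc, w))
      names(ensembles) <- scNames
      ensembles <- applyCommitEdgeFilter(ensembles, ensembles$COMMIT,
                                         cfg$commitThreshold)
      mask <- consensusMask(ensembles$COMMIT, cfg$consensus)
      buildDir <- file.path(out, "build")
      dir.create(buildDir, showWarnings = FALSE)
      outs <- character()
      for (w in scNames) {
        g <- groupAverage(ensembles[[w]], mask)
        p <- file.path(buildDir, sprintf("group_%s.csv", w))
        writeMatrix(g, p); outs <- c(outs, p)
        for (s in subjects(ensembles[[w]])) {
          ps <- file.path(buildDir, sprintf("%s_%s.csv", w, subjectId(s)))
          writeMatrix(s, ps); outs <- c(outs, ps)
        }
      }
      pm <- file.path(buildDir, "consensus_mask.csv")
      writeMatrix(mask, pm); outs <- c(outs, pm)
      report <- list(streamlinesRemoved = removedTotal,
                     streamlinesRetained = keptTotal,
                     consensusEdges = sum(connMatrix(mask)) / 2)
      pr <- file.path(buildDir, "build_report.json")
      jsonlite::write_json(report, pr, auto_unbox = TRUE, digits = NA)
      outs <- c(outs, pr)
      .log(stage, removed = removedTotal, retained = keptTotal,
           consensus_edges = report$consensusEdges)
      manifest$stages[[stage]] <- list(inputs = inHash, config = h,
                                       outputs = as.list(outs),
                                       hashes = .hashFiles(outs))
    }
  }

  ## ---- stats ----
  if ("stats" %in% cfg$stages) {
    stage <- "stats"
    buildDir <- file.path(out, "build")
    simDir <- file.path(out, "simulate")
    inFiles <- c(list.files(buildDir, pattern = "\\.csv$", full.names = TRUE),
                 list.files(simDir, pattern = "^fc_", full.names = TRUE))
    inHash <- .hashFiles(inFiles)
    h <- cfgHash(c("nPerm", "seed", "bins"))
    if (.stageUnchanged(manifest, stage, inHash, h)) {
      .log(stage, skipped = "inputs-unchanged")
    } else {
      statsDir <- file.path(out, "stats")
      dir.create(statsDir, showWarnings = FALSE)
      mask <- readMatrix(file.path(buildDir, "consensus_mask.csv"))
      groups <- lapply(scNames, function(w)
        readMatrix(file.path(buildDir, sprintf("group_%s.csv", w)),
                   weightName = w))
      names(groups) <- scNames
      fcFiles <- sort(list.files(simDir, pattern = "^fc_", full.names = TRUE))
      fcs <- lapply(fcFiles, readMatrix, weightName = "FC")
      fcGroupM <- Reduce(`+`, lapply(fcs, connMatrix)) / length(fcs)
      fcGroup <- WeightedConnectome(fcGroupM, "FC", "group",
                                    nodeIds(groups$COMMIT))
      lenEv <- edgeVectorize(groups$LoS, mask)
      res <- do.call(rbind, lapply(scNames, function(w) {
        ev <- edgeVectorize(groups[[w]], mask)
        fcv <- edgeVectorize(fcGroup, mask)
        ok <- ev$value != 0
        rr <- residualizeOnLength(ev$value[ok], lenEv$value[ok])
        rf <- residualizeOnLength(fcv$value[ok], lenEv$value[ok])
        pt <- permutationPvalue(rr, rf, nPerm = cfg$nPerm,
                                seed = childSeed(cfg$seed, 7000 + match(w, scNames)))
        data.frame(weight = w,
                   rho_len = spearmanRho(ev$value[ok], lenEv$value[ok]),
                   rho_fc_resid = pt$observed, p_perm = pt$p)
      }))
      data.table::fwrite(res, file.path(statsDir, "group_correlations.csv"))
      cqdTab <- do.call(rbind, lapply(scNames, function(w) {
        g <- readMatrix(file.path(buildDir, sprintf("group_%s.csv", w)),
                        weightName = w)
        ev <- edgeVectorize(g, mask)
        data.frame(weight = w, group_cqd = cqd(ev$value[ev$value != 0]))
      }))
      data.table::fwrite(cqdTab, file.path(statsDir, "group_cqd.csv"))
      outs <- file.path(statsDir, c("group_correlations.csv", "group_cqd.csv"))
      .log(stage, weights = length(scNames), nperm = cfg$nPerm)
      manifest$stages[[stage]] <- list(inputs = inHash, config = h,
                                       outputs = as.list(outs),
                                       hashes = .hashFiles(outs))
    }
  }

  ## ---- topology (includes null generation) ----
  if (any(c("topology", "nulls") %in% cfg$stages)) {
    stage <- "topology"
    buildDir <- file.path(out, "build")
    inFiles <- file.path(buildDir, sprintf("group_%s.csv", cfg$topologyWeights))
    inHash <- .hashFiles(inFiles)
    h <- cfgHash(c("seed", "nNullsSmallWorld", "nNullsRichClub",
                   "totalSwaps", "topologyWeights"))
    if (.stageUnchanged(manifest, stage, inHash, h)) {
      .log(stage, skipped = "inputs-unchanged")
    } else {
      topoDir <- file.path(out, "topology")
      dir.create(topoDir, showWarnings = FALSE)
      outs <- character()
      hubTabs <- list()
      for (w in cfg$topologyWeights) {
        g <- readMatrix(file.path(buildDir, sprintf("group_%s.csv", w)),
                        weightName = w)
        nullsSW <- generateNullEnsemble(
          g, cfg$nNullsSmallWorld, "weighted-degree-strength",
          params = list(totalSwaps = cfg$totalSwaps),
          seed = childSeed(cfg$seed, 8000 + match(w, weightLevels())))
        sw <- smallWorldness(g, nulls = nullsSW)
        pj <- file.path(topoDir, sprintf("smallworld_%s.json", w))
        jsonlite::write_json(list(S = sw$S, Cnorm = sw$Cnorm, Lnorm = sw$Lnorm,
                                  nNulls = sw$nNulls),
                             pj, auto_unbox = TRUE, digits = NA)
        nullsRC <- generateNullEnsemble(
          g, cfg$nNullsRichClub, "weighted-degree-strength",
          params = list(totalSwaps = cfg$totalSwaps),
          seed = childSeed(cfg$seed, 9000 + match(w, weightLevels())))
        rc <- normalizeRichClub(richClubWeighted(g), nullsRC)
        pc <- file.path(topoDir, sprintf("richclub_%s.csv", w))
        data.table::fwrite(as.data.frame(rc), pc)
        hub <- hubnessScores(centralityPanel(g))
        ph <- file.path(topoDir, sprintf("hubness_%s.csv", w))
        data.table::fwrite(hub, ph)
        hubTabs[[w]] <- hub
        outs <- c(outs, pj, pc, ph)
        .log(stage, weight = w, S = sprintf("%.3f", sw$S))
      }
      if (length(hubTabs) > 1) {
        pd <- file.path(topoDir, "hubness_distance.csv")
        D <- hubnessDistance(hubTabs)
        data.table::fwrite(data.frame(weight = rownames(D), D), pd)
        outs <- c(outs, pd)
      }
      manifest$stages[[stage]] <- list(inputs = inHash, config = h,
                                       outputs = as.list(outs),
                                       hashes = .hashFiles(outs))
    }
  }

  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

# stable hash of a configuration subset (serialize to canonical JSON)
digestConfig <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
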