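## End-to-end orchestration: simulate/read -> preprocess -> correlate ->
## network -> communities -> traits, with reproducible artifacts.

#' Run configuration for the end-to-end pipeline
#'
#' Validates and assembles the knobs of a single-state pipeline run.
#' Exactly one input source is used: a [SimulationConfig-class]
#' (`simConfig`) or a fixture directory with `abundance.csv` /
#' `traits.csv` (`inputDir`).
#'
#' @param simConfig a [SimulationConfig-class], or NULL when reading
#'   files.
#' @param inputDir fixture directory readable by [readFixture()], or
#'   NULL when simulating.
#' @param state seed state to analyse.
#' @param qTarget edge FDR level, in (0, 1).
#' @param rThreshold `"auto"` (robustness scan, fallback 0.5 when the
#'   scan warns) or a fixed value in (0, 1).
#' @param walkSteps random-walk length for community detection.
#' @param minCommunitySize communities must exceed this size to be
#'   tested.
#' @param seed integer RNG seed for the run.
#' @param outDir output directory, or NULL to skip writing artifacts.
#' @return validated configuration list (class `"seasonetRunConfig"`).
#' @export
runConfig <- function(simConfig = simulationConfig(),
                      inputDir = NULL,
                      state = "dehydrated",
                      qTarget = 0.05,
                      rThreshold = "auto",
                      walkSteps = 4,
                      minCommunitySize = 9,
                      seed = 1,
                      outDir = NULL) {
  if (is.null(simConfig) && is.null(inputDir))
    stop("invalid 'input': provide simConfig or inputDir")
  state <- match.arg(state, .SEED_STATES)
  if (!is.numeric(qTarget) || qTarget <= 0 || qTarget >= 1)
    stop("invalid 'qTarget': must lie in (0, 1)")
  if (!identical(rThreshold, "auto")) {
    if (!is.numeric(rThreshold) || rThreshold <= 0 || rThreshold >= 1)
      stop("invalid 'rThreshold': must be 'auto' or a value in (0, 1)")
  }
  if (walkSteps < 1) stop("invalid 'walkSteps': must be >= 1")
  if (minCommunitySize < 0) stop("invalid 'minCommunitySize'")
  structure(list(simConfig = simConfig, inputDir = inputDir,
                 state = state, qTarget = qTarget,
                 rThreshold = rThreshold, walkSteps = walkSteps,
                 minCommunitySize = minCommunitySize,
                 seed = as.integer(seed), outDir = outDir),
            class = "seasonetRunConfig")
}

#' Validate input fixture files
#'
#' Schema check of the abundance / trait CSVs: required columns,
#' duplicated samples or metabolites, value ranges. Returns an itemized
#' character vector of problems (empty when the files are well formed).
#'
#' @param abundancePath path to a wide abundance CSV (month, state,
#'   replicate + one column per metabolite).
#' @param traitsPath optional path to a long trait CSV (month, trait,
#'   replicate, successes, n).
#' @return character vector of error messages, empty if valid.
#' @export
validateInputs <- function(abundancePath, traitsPath = NULL) {
  errs <- character()
  if (!file.exists(abundancePath)) {
    return(paste0("abundance file not found: ", abundancePath))
  }
  ab <- read.csv(abundancePath, check.names = FALSE)
  idx <- c("month", "state", "replicate")
  miss <- setdiff(idx, colnames(ab))
  if (length(miss))
    errs <- c(errs, paste0("abundance: missing index column(s): ",
                           paste(miss, collapse = ", ")))
  mets <- setdiff(colnames(ab), idx)
  if (!length(mets))
    errs <- c(errs, "abundance: no metabolite columns")
  if (anyDuplicated(colnames(ab)))
    errs <- c(errs, paste0("abundance: duplicated column(s): ",
                           paste(unique(colnames(ab)[duplicated(colnames(ab))]),
                                 collapse = ", ")))
  if (!length(miss)) {
    badM <- setdiff(unique(ab$month), monthCycle())
    if (length(badM))
      errs <- c(errs, paste0("abundance: unknown month label(s): ",
                             paste(badM, collapse = ", ")))
    badS <- setdiff(unique(ab$state), .SEED_STATES)
    if (length(badS))
      errs <- c(errs, paste0("abundance: unknown state(s): ",
                             paste(badS, collapse = ", ")))
    key <- paste(ab$month, ab$state, ab$replicate)
    if (anyDuplicated(key))
      errs <- c(errs, "abundance: duplicated (month, state, replicate) rows")
  }
  for (j in mets) {
    v <- suppressWarnings(as.numeric(ab[[j]]))
    if (any(is.na(v) & !is.na(ab[[j]]) & ab[[j]] != "NA"))
      errs <- c(errs, paste0("abundance: non-numeric values in '", j, "'"))
    else if (any(v < 0, na.rm = TRUE))
      errs <- c(errs, paste0("abundance: negative values in '", j, "'"))
  }
  if (!is.null(traitsPath)) {
    if (!file.exists(traitsPath)) {
      errs <- c(errs, paste0("trait file not found: ", traitsPath))
    } else {
      tr <- read.csv(traitsPath)
      need <- c("month", "trait", "replicate", "successes", "n")
      missT <- setdiff(need, colnames(tr))
      if (length(missT)) {
        errs <- c(errs, paste0("traits: missing column(s): ",
                               paste(missT, collapse = ", ")))
      } else {
        if (!all(tr$trait %in% c("germination", "survival")))
          errs <- c(errs, "traits: trait must be germination or survival")
        bad <- tr$successes < 0 | tr$successes > tr$n
        if (any(bad, na.rm = TRUE))
          errs <- c(errs,
                    "traits: successes outside [0, n] (percentage > 100?)")
        if (anyDuplicated(tr[, c("month", "trait", "replicate")]))
          errs <- c(errs, "traits: duplicated (month, trait, replicate) rows")
      }
    }
  }
  errs
}

#' Run the pipeline for all three seed states
#'
#' Convenience loop over the dry, germinated and dehydrated networks: the
#' same configuration is run once per state (artifacts, when written, go
#' to per-state subdirectories of `outDir`).
#'
#' @param config a configuration from [runConfig()].
#' @return named list of per-state run reports.
#' @export
runPipelineAllStates <- function(config) {
  if (!inherits(config, "seasonetRunConfig"))
    config <- do.call(runConfig, config)
  out <- lapply(.SEED_STATES, function(st) {
    cfg <- config
    cfg$state <- st
    if (!is.null(cfg$outDir)) cfg$outDir <- file.path(cfg$outDir, st)
    runPipeline(cfg)
  })
  names(out) <- .SEED_STATES
  out
}

#' Run the full pipeline for one seed state
#'
#' Executes preprocessing, normality screening, correlation, network
#' construction (with robustness-based or fixed r threshold), walktrap
#' community detection, community-significance testing and trait
#' subgraph extraction. When `outDir` is set, all artifacts are written
#' (`abundance.csv`/`traits.csv`/`truth.json` for simulated inputs,
#' `correlations.csv`, `normality.json`, `scan.csv`, `network.graphml`,
#' `network.sif` + attribute tables, `communities.csv`,
#' `community_tests.json`, `subgraph_<trait>.graphml`,
#' `sign_summary.csv`, `report.json`). Identical configuration and seed
#' give byte-identical artifacts.
#'
#' @param config a configuration from [runConfig()].
#' @return the run report (named list), invisibly also written as JSON.
#' @examples
#' \donttest{
#' rep <- runPipeline(runConfig(simulationConfig(rngSeed = 1), seed = 1))
#' rep$network$nNodes   # 69 metabolites + 2 traits = 71
#' }
#' @export
runPipeline <- function(config) {
  if (!inherits(config, "seasonetRunConfig"))
    config <- do.call(runConfig, config)
  outDir <- config$outDir
  if (!is.null(outDir))
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name) if (is.null(outDir)) NULL
                         else file.path(outDir, name)
  warnings <- character()
  noteWarning <- function(w) {
    warnings <<- c(warnings, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  set.seed(config$seed)
  stage <- "input"
  report <- list(package = "seasonet",
                 version = as.character(utils::packageVersion("seasonet")),
                 config = list(state = config$state,
                               qTarget = config$qTarget,
                               rThreshold = config$rThreshold,
                               walkSteps = config$walkSteps,
                               minCommunitySize = config$minCommunitySize,
                               seed = config$seed,
                               simulated = is.null(config$inputDir)))
  runStage <- function(name, expr) {
    stage <<- name
    tryCatch(withCallingHandlers(expr, warning = noteWarning),
             error = function(e) {
               if (!is.null(outDir))
                 writeLines(paste0("FAILED at stage: ", name, "\n",
                                   conditionMessage(e)),
                            file.path(outDir, "FAILED"))
               stop("pipeline stage '", name, "' failed: ",
                    conditionMessage(e), call. = FALSE)
             })
  }

  dataset <- runStage("input", {
    if (!is.null(config$inputDir)) {
      errs <- validateInputs(file.path(config$inputDir, "abundance.csv"),
                             file.path(config$inputDir, "traits.csv"))
      if (length(errs))
        stop("invalid inputs:\n  ", paste(errs, collapse = "\n  "))
      readFixture(config$inputDir)
    } else {
      sim <- simulateDataset(config$simConfig)
      if (!is.null(outDir)) writeFixture(sim, outDir)
      sim
    }
  })
  report$input <- list(
    nMetabolites = nrow(dataset$abundance),
    nSamples = ncol(dataset$abundance),
    hasTraits = !is.null(dataset$traits))

  prep <- runStage("preprocessing", {
    prepareAnalysisMatrix(dataset$abundance, dataset$traits,
                          state = config$state)
  })
  report$preprocessing <- list(
    nVariables = ncol(prep$matrix),
    nMonths = nrow(prep$matrix))

  screen <- runStage("normality", {
    sc <- normalityScreen(prep$matrix)
    if (!is.null(outDir))
      write_json(list(violationFraction = sc$violationFraction,
                      recommended = sc$recommended,
                      table = sc$table),
                 emit("normality.json"), auto_unbox = TRUE, digits = NA,
                 dataframe = "columns")
    sc
  })
  report$normality <- list(
    violationFraction = screen$violationFraction,
    recommended = screen$recommended)

  stats <- runStage("correlation", {
    cs <- correlationMatrix(prep$matrix, method = "spearman",
                            nodeKind = prep$nodeKind,
                            compoundClass = prep$compoundClass)
    if (!is.null(outDir)) writeCorrelations(cs, emit("correlations.csv"))
    cs
  })
  report$correlation <- list(
    method = stats@method, pMethod = stats@pMethod,
    nPairs = sum(!is.na(stats@pval[upper.tri(stats@pval)])))

  netStage <- runStage("network", {
    scanInfo <- NULL
    if (identical(config$rThreshold, "auto")) {
      scanWarned <- FALSE
      scan <- withCallingHandlers(
        robustnessScan(stats),
        warning = function(w) {
          scanWarned <<- TRUE
          noteWarning(w)
        })
      chosenR <- if (scanWarned) 0.5 else scan$chosenR
      if (!is.null(outDir))
        write.csv(scan$properties, emit("scan.csv"), row.names = FALSE)
      scanInfo <- list(chosenR = chosenR, scanChosenR = scan$chosenR,
                       usedFallback = scanWarned)
    } else {
      chosenR <- config$rThreshold
    }
    nw <- buildNetwork(stats, rThresh = chosenR,
                       qTarget = config$qTarget)
    if (!is.null(outDir)) {
      writeGraphML(nw, emit("network.graphml"))
      writeSIF(nw, emit("network.sif"))
    }
    list(net = nw, scanInfo = scanInfo)
  })
  net <- netStage$net
  if (!is.null(netStage$scanInfo)) report$network_scan <- netStage$scanInfo
  report$network <- list(
    nNodes = nrow(net@nodes), nEdges = nrow(net@edges),
    chosenR = net@thresholds$r, pThreshold = net@thresholds$p,
    nPositive = sum(net@edges$sign > 0),
    nNegative = sum(net@edges$sign < 0))

  partition <- runStage("communities", {
    cp <- walktrapCommunities(net, steps = config$walkSteps)
    if (!is.null(outDir)) {
      memb <- communityMembership(cp)
      write.csv(data.frame(node = names(memb), community = memb,
                           row.names = NULL),
                emit("communities.csv"), row.names = FALSE)
    }
    cp
  })
  tests <- runStage("community_tests", {
    ct <- communitySignificance(net, communityMembership(partition),
                                minSize = config$minCommunitySize)
    if (!is.null(outDir))
      write_json(ct, emit("community_tests.json"), dataframe = "rows",
                 auto_unbox = TRUE, digits = NA)
    ct
  })
  report$communities <- list(
    nCommunities = length(unique(communityMembership(partition))),
    modularity = max(modularityTrace(partition)),
    sizes = as.integer(communitySizes(partition)),
    nTested = sum(tests$tested),
    nSignificant = sum(tests$tested & !is.na(tests$pValue) &
                         tests$pValue < 0.05))

  traitNames <- intersect(c("germination", "survival"), net@nodes$name)
  traitReports <- runStage("traits", {
    out <- list()
    signRows <- list()
    for (tr in traitNames) {
      sub <- traitSubgraph(net, tr)
      if (!is.null(outDir))
        writeGraphML(sub, emit(paste0("subgraph_", tr, ".graphml")))
      ss <- signSummary(sub)
      if (nrow(ss)) signRows[[tr]] <- cbind(trait = tr, ss)
      out[[tr]] <- list(degree = unname(nodeDegree(net)[tr]),
                        nPositive = sum(ss$nPositive),
                        nNegative = sum(ss$nNegative))
    }
    if (!is.null(outDir)) {
      allSigns <- if (length(signRows)) do.call(rbind, signRows)
                  else data.frame(trait = character(), class = character(),
                                  nPositive = integer(),
                                  nNegative = integer())
      write.csv(allSigns, emit("sign_summary.csv"), row.names = FALSE)
    }
    out
  })
  report$traits <- traitReports
  report$warnings <- unique(warnings)

  if (!is.null(outDir))
    write_json(report, emit("report.json"), auto_unbox = TRUE,
               digits = NA, pretty = TRUE)
  report
}
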