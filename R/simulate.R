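## Synthetic seasonal metabolome + trait generator with planted structure.

#' Simulation configuration
#'
#' Parameters of the synthetic seasonal seed-metabolome generator. The
#' defaults emulate the original study design: a 12-month series (June
#' through May), four replicates per month and seed state, 69 metabolites
#' (so metabolites + 2 traits = 71 network nodes) organised in four
#' correlated blocks. The first block carries a strong
#' summer-accumulation shift and is coupled positively to germination
#' and negatively to survival (the reported trait-association pattern);
#' the remaining blocks are weakly seasonal with alternating sign.
#' Survival percentage follows a sinusoid from 0% in July to 100% in
#' January, sampled as Binomial counts of 50 seeds per replicate;
#' germination stays near 90% with a November dip to 76.5%.
#'
#' @slot nMonths number of consecutive months starting at June.
#' @slot nReplicates replicates per month per seed state.
#' @slot nMetabolites number of metabolites.
#' @slot blockSizes integer block sizes summing to nMetabolites.
#' @slot blockLoadings per-block latent-factor loading in [0, 1].
#' @slot seasonalAmplitude per-block summer/winter mean shift (signed;
#'   positive = summer-accumulating).
#' @slot traitCouplings 2 x nBlocks matrix (rows germination, survival) of
#'   signed couplings of each trait to the block factors.
#' @slot noiseSd residual measurement noise SD (> 0).
#' @slot replicateSd SD of the replicate-level jitter around the
#'   month-level block factor (the within-month replicate correlation of
#'   the planted signal is a free design knob).
#' @slot survivalPhase month of the survival peak.
#' @slot germinationBase,germinationDipMonth,germinationDip germination
#'   percentage baseline, dip month, dip percentage.
#' @slot couplingScale named numeric (germination, survival): logit-scale
#'   units of trait shift per unit block score. Germination's near-flat
#'   baseline needs only a small gain for couplings to dominate its
#'   ranking; survival's strong seasonal sinusoid requires a larger gain
#'   for couplings to stay visible next to it.
#' @slot stateAttenuation named multiplier of the seasonal + factor signal
#'   per seed state (dry seeds show attenuated seasonal structure).
#' @slot traitN seeds per trait replicate.
#' @slot rngSeed integer seed; identical seeds give bit-identical output.
#' @export
setClass("SimulationConfig",
         representation(nMonths = "integer", nReplicates = "integer",
                        nMetabolites = "integer", blockSizes = "integer",
                        blockLoadings = "numeric",
                        seasonalAmplitude = "numeric",
                        traitCouplings = "matrix", noiseSd = "numeric",
                        replicateSd = "numeric",
                        survivalPhase = "character",
                        germinationBase = "numeric",
                        germinationDipMonth = "character",
                        germinationDip = "numeric",
                        couplingScale = "numeric",
                        stateAttenuation = "numeric",
                        traitN = "integer", rngSeed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk <- function(cond, field, what)
    if (!cond) msg <<- c(msg, paste0("invalid '", field, "': ", what))
  chk(object@nMonths >= 4 && object@nMonths <= 12, "nMonths",
      "must be in [4, 12]")
  chk(object@nReplicates >= 1, "nReplicates", "must be >= 1")
  chk(object@nMetabolites >= 2, "nMetabolites", "must be >= 2")
  chk(sum(object@blockSizes) == object@nMetabolites, "blockSizes",
      "must sum to nMetabolites")
  chk(all(object@blockSizes >= 1), "blockSizes", "must be positive")
  nb <- length(object@blockSizes)
  chk(length(object@blockLoadings) == nb &&
        all(object@blockLoadings >= 0 & object@blockLoadings <= 1),
      "blockLoadings", "must be one value in [0, 1] per block")
  chk(length(object@seasonalAmplitude) == nb, "seasonalAmplitude",
      "must have one value per block")
  chk(is.numeric(object@traitCouplings) &&
        nrow(object@traitCouplings) == 2 &&
        ncol(object@traitCouplings) == nb,
      "traitCouplings", "must be a 2 x nBlocks numeric matrix")
  chk(object@noiseSd > 0, "noiseSd", "must be > 0")
  chk(object@replicateSd >= 0, "replicateSd", "must be >= 0")
  chk(object@survivalPhase %in% monthCycle(), "survivalPhase",
      "must be a month abbreviation")
  chk(object@germinationDipMonth %in% monthCycle(), "germinationDipMonth",
      "must be a month abbreviation")
  chk(object@germinationBase >= 0 && object@germinationBase <= 100,
      "germinationBase", "must be a percentage")
  chk(object@germinationDip >= 0 && object@germinationDip <= 100,
      "germinationDip", "must be a percentage")
  chk(length(object@couplingScale) == 2 &&
        all(object@couplingScale >= 0) &&
        all(c("germination", "survival") %in% names(object@couplingScale)),
      "couplingScale",
      "must be nonnegative and named (germination, survival)")
  chk(all(.SEED_STATES %in% names(object@stateAttenuation)),
      "stateAttenuation", "must name all three seed states")
  chk(object@traitN >= 1, "traitN", "must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname SimulationConfig-class
#' @param nMonths,nReplicates,nMetabolites,blockSizes,blockLoadings see slots
#' @param seasonalAmplitude,traitCouplings,noiseSd,survivalPhase see slots
#' @param germinationBase,germinationDipMonth,germinationDip see slots
#' @param couplingScale,stateAttenuation,traitN,rngSeed see slots
#' @return a validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(rngSeed = 7)
#' cfg
#' @export
simulationConfig <- function(nMonths = 12,
                             nReplicates = 4,
                             nMetabolites = 69,
                             blockSizes = c(18L, 17L, 17L, 17L),
                             blockLoadings = rep(0.9, length(blockSizes)),
                             seasonalAmplitude =
                               c(0.6, 0.15 * (-1)^seq_len(length(blockSizes) - 1)),
                             traitCouplings = NULL,
                             noiseSd = 0.2,
                             replicateSd = 0.5,
                             survivalPhase = "Jan",
                             germinationBase = 90,
                             germinationDipMonth = "Nov",
                             germinationDip = 76.5,
                             couplingScale = c(germination = 1,
                                               survival = 5),
                             stateAttenuation = c(dry = 0.25,
                                                  germinated = 1,
                                                  dehydrated = 1),
                             traitN = 50,
                             rngSeed = 1) {
  nb <- length(blockSizes)
  if (is.null(traitCouplings)) {
    # the paper's pattern: germination positive and survival negative to
    # the same (strongly seasonal, summer-accumulating) compounds
    traitCouplings <- rbind(
      germination = c(0.8, rep(0, nb - 1)),
      survival = c(-0.8, rep(0, nb - 1)))
  }
  if (is.null(rownames(traitCouplings)))
    rownames(traitCouplings) <- c("germination", "survival")
  cfg <- new("SimulationConfig",
             nMonths = as.integer(nMonths),
             nReplicates = as.integer(nReplicates),
             nMetabolites = as.integer(nMetabolites),
             blockSizes = as.integer(blockSizes),
             blockLoadings = as.numeric(blockLoadings),
             seasonalAmplitude = as.numeric(seasonalAmplitude),
             traitCouplings = traitCouplings,
             noiseSd = as.numeric(noiseSd),
             replicateSd = as.numeric(replicateSd),
             survivalPhase = as.character(survivalPhase),
             germinationBase = as.numeric(germinationBase),
             germinationDipMonth = as.character(germinationDipMonth),
             germinationDip = as.numeric(germinationDip),
             couplingScale = couplingScale,
             stateAttenuation = stateAttenuation,
             traitN = as.integer(traitN),
             rngSeed = as.integer(rngSeed))
  validObject(cfg)
  cfg
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nMonths, "months x",
      object@nReplicates, "replicates,", object@nMetabolites,
      "metabolites in", length(object@blockSizes), "blocks\n")
  cat("  loadings:", paste(object@blockLoadings, collapse = ", "),
      " amplitudes:", paste(object@seasonalAmplitude, collapse = ", "), "\n")
  cat("  noise SD:", object@noiseSd, " seed:", object@rngSeed, "\n")
})

.simMonths <- function(cfg) monthCycle()[seq_len(cfg@nMonths)]

.blockOf <- function(cfg) rep(seq_along(cfg@blockSizes), cfg@blockSizes)

#' Simulate a seasonal metabolome + trait dataset with known ground truth
#'
#' Generates relative metabolite abundances for the three seed states and
#' the two physiological trait series. Each metabolite j in block b, month
#' m, replicate k (state st) is
#' \deqn{y = baseline_j + att_{st} (A_b s(m) + L_b f_b(m,k)) + \epsilon,}
#' where s(m) is +1 in summer, -1 in winter and 0 in shoulder months and
#' \eqn{\epsilon \sim N(0, noiseSd^2)}. The block factor
#' \eqn{f_b(m,k) = g_b(m) + u_{b}(m,k)} combines a month-level Gaussian
#' factor \eqn{g_b} -- orthogonalized across blocks and against the
#' seasonal contrast so that distinct blocks remain statistically
#' distinguishable over a 12-month design -- with replicate-level jitter
#' \eqn{u \sim N(0, replicateSd^2)}. Survival
#' percentage follows a sinusoid peaking (100%) at `survivalPhase` and
#' troughing (0%) six months away; germination stays near its baseline
#' with one dip month. Both traits are shifted on the logit scale by the
#' planted couplings to the block scores and sampled as Binomial counts
#' of `traitN` seeds per replicate.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `abundance` ([AbundanceTable-class], all
#'   three states), `traits` ([TraitSeries-class]) and `truth` (list:
#'   `blockAssignment`, `traitSigns`, `seasonalMeans`).
#' @examples
#' sim <- simulateDataset(simulationConfig(rngSeed = 1))
#' sim$abundance
#' round(traitMonthlyPercent(sim$traits), 1)
#' @export
simulateDataset <- function(config) {
  validObject(config)
  .simulateCore(config, null = FALSE)
}

#' @rdname simulateDataset
#' @details `simulateNullDataset()` forces all loadings and seasonal
#'   amplitudes to zero: metabolites are mutually independent Gaussian
#'   noise around their baselines, the reference input for false-discovery
#'   calibration of the downstream edge selection.
#' @return `simulateNullDataset()`: an [AbundanceTable-class] only.
#' @export
simulateNullDataset <- function(config) {
  validObject(config)
  .simulateCore(config, null = TRUE)$abundance
}

.simulateCore <- function(cfg, null = FALSE) {
  set.seed(cfg@rngSeed)
  months <- .simMonths(cfg)
  nM <- cfg@nMonths; nR <- cfg@nReplicates; nMet <- cfg@nMetabolites
  nb <- length(cfg@blockSizes)
  block <- .blockOf(cfg)
  loadings <- if (null) rep(0, nb) else cfg@blockLoadings
  amp <- if (null) rep(0, nb) else cfg@seasonalAmplitude
  metNames <- sprintf("met%02d", seq_len(nMet))
  classes <- rep_len(.COMPOUND_CLASSES, nMet)

  baseline <- runif(nMet, 3, 8)
  s <- seasonSign(months)                        # length nM
  phase <- match(cfg@survivalPhase, monthCycle())
  idx <- match(months, monthCycle())
  p0 <- (1 + cos(2 * pi * (idx - phase) / 12)) / 2
  eps <- 1e-3
  survBase <- qlogis(pmin(pmax(p0, eps), 1 - eps))
  # month-level block factors, orthogonalized against each other and
  # against the fixed seasonal structures (summer/winter contrast and the
  # survival sinusoid) so distinct blocks stay statistically
  # distinguishable at the design size (12 monthly values) and trait
  # couplings are not confounded by chance factor/season alignment
  g <- matrix(rnorm(nM * nb), nM, nb)
  fixedCols <- cbind(rep(1, nM),
                     if (sd(s) > 0) s else NULL,
                     if (sd(survBase) > 0) survBase else NULL)
  basis <- cbind(fixedCols, g)
  Q <- qr.Q(qr(basis))
  gcols <- (ncol(basis) - nb + 1):ncol(basis)
  g <- Q[, gcols, drop = FALSE]
  g <- sweep(g, 2, apply(g, 2, sd), `/`)         # unit SD per factor
  # replicate-level jitter around the month-level factor
  f <- array(rep(g, each = nR), dim = c(nR, nM, nb))
  f <- aperm(f, c(2, 1, 3)) +
    array(rnorm(nM * nR * nb, 0, cfg@replicateSd), dim = c(nM, nR, nb))

  sampleRows <- expand.grid(replicate = seq_len(nR), month = months,
                            state = .SEED_STATES, stringsAsFactors = FALSE,
                            KEEP.OUT.ATTRS = FALSE)
  sampleRows <- sampleRows[, c("month", "state", "replicate")]
  values <- matrix(NA_real_, nrow(sampleRows), nMet,
                   dimnames = list(NULL, metNames))
  for (i in seq_len(nrow(sampleRows))) {
    m <- match(sampleRows$month[i], months)
    k <- sampleRows$replicate[i]
    att <- cfg@stateAttenuation[[sampleRows$state[i]]]
    signal <- att * (amp[block] * s[m] + loadings[block] * f[m, k, block])
    values[i, ] <- baseline + signal + rnorm(nMet, 0, cfg@noiseSd)
  }
  values[values < 0] <- 0       # relative abundances are nonnegative

  abundance <- AbundanceTable(values, sampleRows,
                              data.frame(compound_class = classes))

  # block monthly scores seen by the traits (unattenuated, month level)
  z <- sweep(g, 2, loadings, `*`) + outer(s, amp)      # nM x nb

  # traits
  g0 <- rep(cfg@germinationBase, nM)
  dipIdx <- match(cfg@germinationDipMonth, months)
  if (!is.na(dipIdx)) g0[dipIdx] <- cfg@germinationDip
  couple <- z %*% t(cfg@traitCouplings)                        # nM x 2
  couple <- sweep(couple, 2,
                  cfg@couplingScale[colnames(couple)], `*`)
  pG <- plogis(qlogis(pmin(pmax(g0 / 100, eps), 1 - eps)) +
                 couple[, "germination"])
  pS <- plogis(survBase + couple[, "survival"])

  tn <- cfg@traitN
  counts <- rbind(
    data.frame(month = rep(months, each = nR), trait = "germination",
               replicate = rep(seq_len(nR), nM),
               successes = rbinom(nM * nR, tn, rep(pG, each = nR)), n = tn),
    data.frame(month = rep(months, each = nR), trait = "survival",
               replicate = rep(seq_len(nR), nM),
               successes = rbinom(nM * nR, tn, rep(pS, each = nR)), n = tn))
  traits <- TraitSeries(counts)

  seasonalMeans <- outer(s, amp)
  dimnames(seasonalMeans) <- list(months, paste0("block", seq_len(nb)))
  truth <- list(
    blockAssignment = setNames(block, metNames),
    traitSigns = sign(cfg@traitCouplings) *
      (abs(cfg@traitCouplings) > 0),
    seasonalMeans = seasonalMeans)

  list(abundance = abundance, traits = traits, truth = truth)
}

#' Write / read a simulated dataset as plain-text fixture files
#'
#' `writeFixture()` writes `abundance.csv` (wide: month, state, replicate
#' plus one column per metabolite), `metabolites.csv` (name,
#' compound_class), `traits.csv` (long counts) and, when ground truth is
#' present, `truth.json`. Numeric values are written with 17 significant
#' digits so the round-trip through `readFixture()` is lossless.
#'
#' @param dataset list with `abundance` ([AbundanceTable-class]) and
#'   optionally `traits` / `truth` as returned by [simulateDataset()].
#' @param dir output directory (created if needed).
#' @return `writeFixture()`: invisibly, the paths written.
#'   `readFixture()`: list with `abundance`, `traits` (NULL if absent) and
#'   `truth` (NULL if absent).
#' @export
writeFixture <- function(dataset, dir) {
  if (is(dataset, "AbundanceTable")) dataset <- list(abundance = dataset)
  ab <- dataset$abundance
  if (is.null(ab) || ncol(ab) == 0L || nrow(ab) == 0L)
    stop("empty dataset: nothing to write")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  v <- abundanceValues(ab)
  sd <- sampleData(ab)
  wide <- data.frame(month = as.character(sd$month), state = sd$state,
                     replicate = sd$replicate)
  for (j in colnames(v)) wide[[j]] <- sprintf("%.17g", v[, j])
  p <- file.path(dir, "abundance.csv")
  write.csv(wide, p, row.names = FALSE, quote = FALSE)
  paths <- c(paths, p)

  metTab <- data.frame(name = rownames(ab),
                       compound_class = metaboliteClass(ab))
  p <- file.path(dir, "metabolites.csv")
  write.csv(metTab, p, row.names = FALSE)
  paths <- c(paths, p)

  if (!is.null(dataset$traits)) {
    d <- dataset$traits@counts
    d$month <- as.character(d$month)
    p <- file.path(dir, "traits.csv")
    write.csv(d, p, row.names = FALSE, quote = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(dataset$truth)) {
    p <- file.path(dir, "truth.json")
    tr <- dataset$truth
    tr$blockAssignment <- as.list(tr$blockAssignment)  # keep names in JSON
    write_json(tr, p, auto_unbox = TRUE, digits = NA,
               matrix = "rowmajor", pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' @rdname writeFixture
#' @export
readFixture <- function(dir) {
  abPath <- file.path(dir, "abundance.csv")
  if (!file.exists(abPath)) stop("no abundance.csv under ", dir)
  wide <- read.csv(abPath, check.names = FALSE,
                   colClasses = "character")
  idx <- c("month", "state", "replicate")
  metNames <- setdiff(colnames(wide), idx)
  v <- vapply(metNames, function(j) as.numeric(wide[[j]]),
              numeric(nrow(wide)))
  if (!is.matrix(v)) v <- matrix(v, nrow = nrow(wide),
                                 dimnames = list(NULL, metNames))
  metaPath <- file.path(dir, "metabolites.csv")
  metaboliteData <- if (file.exists(metaPath)) {
    mt <- read.csv(metaPath)
    data.frame(compound_class = mt$compound_class[match(metNames, mt$name)])
  } else NULL
  abundance <- AbundanceTable(
    v, data.frame(month = wide$month, state = wide$state,
                  replicate = as.integer(wide$replicate)),
    metaboliteData)

  traits <- NULL
  trPath <- file.path(dir, "traits.csv")
  if (file.exists(trPath)) {
    d <- read.csv(trPath)
    traits <- TraitSeries(d[, c("month", "trait", "replicate",
                                "successes", "n")])
  }
  truth <- NULL
  tuPath <- file.path(dir, "truth.json")
  if (file.exists(tuPath)) {
    raw <- read_json(tuPath, simplifyVector = TRUE)
    ba <- unlist(raw$blockAssignment)
    storage.mode(ba) <- "integer"
    truth <- list(blockAssignment = ba,
                  traitSigns = raw$traitSigns,
                  seasonalMeans = raw$seasonalMeans)
  }
  list(abundance = abundance, traits = traits, truth = truth)
}
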