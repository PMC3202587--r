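#' Construct a gene panel for simulation
#'
#' @param gene_id gene labels (unique).
#' @param role per-gene role: "target", "control", "psi_numerator" or
#'   "psi_denominator".
#' @param true_efficiency per-cycle amplification factor (> 1, typically
#'   1.85-2.15).
#' @param baseline_level mean log2 abundance (Ca units) in the control
#'   condition.
#' @return a validated [GenePanel-class].
#' @export
genePanel <- function(gene_id, role = "target", true_efficiency = 2,
                      baseline_level = -12) {
  out <- as(DataFrame(gene_id = as.character(gene_id),
                      role = rep_len(role, length(gene_id)),
                      true_efficiency = rep_len(true_efficiency,
                                                length(gene_id)),
                      baseline_level = rep_len(baseline_level,
                                               length(gene_id))),
            "GenePanel")
  validObject(out)
  out
}

#' Construct a generative scenario configuration
#'
#' @param name scenario label.
#' @param genes a [GenePanel-class].
#' @param nColonies number of coral colonies.
#' @param treatments treatment labels; the first is the reference
#'   (control) level.
#' @param timepoints optional sampling-point labels (factorial designs).
#' @param sites optional field-site labels; when given, each colony is
#'   sampled once at its site and \code{siteAssignment} places colonies.
#' @param siteAssignment per-colony site label (length \code{nColonies});
#'   required when \code{sites} is non-empty.
#' @param tanksPerTreatment replicate tanks per treatment (0 = none).
#' @param replicates fragments per colony per design cell: a single count
#'   or an inclusive range \code{c(lo, hi)} sampled uniformly.
#' @param missingArms data.frame (colony, treatment) of deliberately
#'   absent arms.
#' @param effects data.frame (gene_id, cell, effect) of true log2 effects;
#'   anything not listed is 0. Cells are treatment labels, or
#'   "treatment:timepoint" in factorial designs, or site labels in field
#'   designs.
#' @param variance named numeric overriding any of colony_sd, tank_sd,
#'   residual_sd, loading_sd (Ca/log2 units) and technical_sd (CP units).
#'   Defaults: colony 0.5, tank 0, residual 0.5, loading 1.0,
#'   technical 0.2.
#' @param sharedColony draw one colony effect shared across genes instead
#'   of independent per-gene colony effects; default FALSE.
#' @param seed integer seed stored with the scenario.
#' @return a validated [ScenarioConfig-class].
#' @seealso [presetScenario()] for the ready-made experimental designs,
#'   [simulateExperiment()].
#' @export
scenarioConfig <- function(name, genes, nColonies,
                           treatments = c("control", "stress"),
                           timepoints = character(),
                           sites = character(),
                           siteAssignment = character(),
                           tanksPerTreatment = 0L,
                           replicates = 1L,
                           missingArms = NULL,
                           effects = NULL,
                           variance = numeric(),
                           sharedColony = FALSE,
                           seed = 1L) {
  defVar <- c(colony_sd = 0.5, tank_sd = 0, residual_sd = 0.5,
              loading_sd = 1.0, technical_sd = 0.2)
  if (length(variance) > 0L) {
    bad <- setdiff(names(variance), names(defVar))
    if (length(bad) > 0L)
      stop("unknown variance component(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    defVar[names(variance)] <- variance
  }
  if (length(replicates) == 1L) replicates <- c(replicates, replicates)
  if (is.null(missingArms))
    missingArms <- DataFrame(colony = character(),
                             treatment = character())
  else missingArms <- DataFrame(colony = as.character(missingArms$colony),
                                treatment =
                                  as.character(missingArms$treatment))
  if (is.null(effects))
    effects <- DataFrame(gene_id = character(), cell = character(),
                         effect = numeric())
  else effects <- DataFrame(gene_id = as.character(effects$gene_id),
                            cell = as.character(effects$cell),
                            effect = as.numeric(effects$effect))
  if (length(sites) > 0L && length(siteAssignment) != nColonies)
    stop("'siteAssignment' must give one site per colony", call. = FALSE)
  cellBy <- if (length(sites) > 0L) "site"
            else if (length(timepoints) > 0L) c("treatment", "timepoint")
            else "treatment"
  out <- new("ScenarioConfig", name = as.character(name), genes = genes,
             nColonies = as.integer(nColonies),
             treatments = as.character(treatments),
             timepoints = as.character(timepoints),
             sites = as.character(sites),
             tanksPerTreatment = as.integer(tanksPerTreatment),
             replicates = as.integer(replicates),
             missingArms = as(missingArms, "DFrame"),
             effects = as(effects, "DFrame"), cellBy = cellBy,
             variance = defVar, sharedColony = isTRUE(sharedColony),
             seed = as.integer(seed))
  if (length(sites) > 0L)
    metadata(out@missingArms)$siteAssignment <-
      as.character(siteAssignment)
  validObject(out)
  out
}

siteAssignmentOf <- function(config) {
  metadata(config@missingArms)$siteAssignment
}

#' Ready-made experimental scenario presets
#'
#' Fully populated [ScenarioConfig-class] objects emulating the study
#' designs the pipeline targets, with true log2 effects set to the
#' headline fold changes of each experiment:
#' \describe{
#'   \item{exp1}{five colonies halved into paired control / heat-light
#'     stress fragments; 13-gene panel (8 targets + 5 candidate controls).
#'     Stress effects: Hsp16 +log2(800), chromoprotein +1 (2-fold up),
#'     actin -2 (4-fold down), C3 -log2(6) (6-fold down).}
#'   \item{exp2}{paired colonies (default 8, parameterizable) in a
#'     treatment x sampling-point factorial (stress / recovery). Heat
#'     effects at the stress point: Hsp16 +log2(700), actin -2,
#'     Hsp60 +2, Hsp90 +log2(6); at the recovery point only Hsp16 remains
#'     up, +3 (8-fold).}
#'   \item{exp4}{five colonies with three replicate tanks per treatment
#'     and 1-3 fragments per colony per treatment; the fifth colony has
#'     only control fragments (its treatment arm is missing). Two-gene
#'     PSI panel; heat shifts the index by +3 log2 units
#'     (Hsp16 +2, actin -1).}
#'   \item{field}{two field sites, nine inshore and seven offshore
#'     colonies sampled once each; the warmer inshore site shifts the
#'     index by +2 log2 units (on Hsp16).}
#' }
#'
#' @param name one of "exp1", "exp2", "exp4", "field".
#' @param nColonies override the default colony count (reported sample
#'   sizes for the stress-recovery design vary between 8 colonies and
#'   12-15 pairs, so exp2 leaves it as a parameter; default 8).
#' @param seed seed stored in the config; default 1.
#' @param nullEffects if TRUE, all fixed effects are set to 0 (null
#'   scenario for error-control simulations).
#' @return a [ScenarioConfig-class].
#' @export
presetScenario <- function(name = c("exp1", "exp2", "exp4", "field"),
                           nColonies = NULL, seed = 1L,
                           nullEffects = FALSE) {
  name <- match.arg(name)
  controls <- genePanel(c("RPL11", "EIF3H", "ND5", "G3PDH", "GSP2"),
                        role = "control",
                        true_efficiency = c(1.93, 1.97, 2.05, 1.90, 2.01),
                        baseline_level = c(-12, -12.5, -13.5, -11.5, -13))
  psiPair <- genePanel(c("Hsp16", "Actin"),
                       role = c("psi_numerator", "psi_denominator"),
                       true_efficiency = c(1.95, 2.02),
                       baseline_level = c(-19, -9))
  cfg <- switch(name,
    exp1 = {
      targets <- genePanel(c("ADK", "C3", "Clect", "Chrom", "Spon2",
                             "Ubl3"),
                           true_efficiency = c(2.00, 1.88, 2.10, 1.92,
                                               2.06, 1.96),
                           baseline_level = c(-12.5, -13, -14, -11,
                                              -13.5, -12))
      eff <- data.frame(
        gene_id = c("Hsp16", "Chrom", "Actin", "C3"),
        cell = "stress",
        effect = c(log2(800), 1, -2, -log2(6)))
      scenarioConfig("exp1", rbind(psiPair, targets, controls),
                     nColonies = if (is.null(nColonies)) 5L
                                 else nColonies,
                     treatments = c("control", "stress"),
                     effects = eff, seed = seed)
    },
    exp2 = {
      targets <- genePanel(c("ADK", "C3", "Chrom", "Ubl3", "Hsp60",
                             "Hsp90"),
                           true_efficiency = c(2.00, 1.88, 1.92, 1.96,
                                               2.04, 1.91),
                           baseline_level = c(-12.5, -13, -11, -12,
                                              -12.8, -10.5))
      eff <- data.frame(
        gene_id = c("Hsp16", "Actin", "Hsp60", "Hsp90", "Hsp16"),
        cell = c(rep("heat:stress", 4L), "heat:recovery"),
        effect = c(log2(700), -2, 2, log2(6), 3))
      scenarioConfig("exp2", rbind(psiPair, targets, controls),
                     nColonies = if (is.null(nColonies)) 8L
                                 else nColonies,
                     treatments = c("control", "heat"),
                     timepoints = c("stress", "recovery"),
                     effects = eff, seed = seed)
    },
    exp4 = {
      n <- if (is.null(nColonies)) 5L else as.integer(nColonies)
      eff <- data.frame(gene_id = c("Hsp16", "Actin"), cell = "heat",
                        effect = c(2, -1))
      scenarioConfig("exp4", psiPair, nColonies = n,
                     treatments = c("control", "heat"),
                     tanksPerTreatment = 3L, replicates = c(1L, 3L),
                     missingArms = data.frame(
                       colony = sprintf("colony%02d", n),
                       treatment = "heat"),
                     effects = eff,
                     variance = c(tank_sd = 0.3), seed = seed)
    },
    field = {
      n <- if (is.null(nColonies)) 16L else as.integer(nColonies)
      nIn <- ceiling(n * 9 / 16)
      eff <- data.frame(gene_id = "Hsp16", cell = "inshore", effect = 2)
      scenarioConfig("field", psiPair, nColonies = n,
                     treatments = "ambient",
                     sites = c("offshore", "inshore"),
                     siteAssignment = rep(c("inshore", "offshore"),
                                          c(nIn, n - nIn)),
                     effects = eff, seed = seed)
    })
  if (isTRUE(nullEffects)) cfg@effects$effect <- 0
  validObject(cfg)
  cfg
}

#' Simulate an amplification-efficiency dilution series
#'
#' Generates (input amount, CP) pairs for a primer pair with true
#' per-cycle amplification factor \code{trueE}: each \code{foldStep}-fold
#' decrease in input raises the expected CP by log(foldStep) / log(trueE)
#' cycles, plus Gaussian CP noise.
#'
#' @param trueE true amplification factor (> 1).
#' @param cpAtMax expected CP at the highest input amount, cycles.
#' @param nPoints number of dilution points (>= 3); the default 7 spans
#'   two orders of magnitude of 2-fold dilutions.
#' @param foldStep dilution factor between consecutive points (> 1).
#' @param noiseSd Gaussian CP noise sd, cycles; 0 gives an exact series.
#' @param seed seed, required when \code{noiseSd > 0}.
#' @param maxAmount highest input amount (arbitrary units), default 5.
#' @param geneId label for the series.
#' @return a [DilutionSeries-class].
#' @examples
#' simulateDilutionSeries(2, cpAtMax = 15, nPoints = 7)  # CP 15..21
#' @export
simulateDilutionSeries <- function(trueE, cpAtMax = 15, nPoints = 7,
                                   foldStep = 2, noiseSd = 0,
                                   seed = NULL, maxAmount = 5,
                                   geneId = "gene") {
  stopifnotScalarNumeric(trueE, "trueE")
  if (trueE <= 1) stop("'trueE' must be > 1", call. = FALSE)
  if (nPoints < 3L) stop("'nPoints' must be >= 3", call. = FALSE)
  if (foldStep <= 1) stop("'foldStep' must be > 1", call. = FALSE)
  if (maxAmount <= 0) stop("'maxAmount' must be > 0", call. = FALSE)
  k <- seq_len(nPoints) - 1L
  amount <- maxAmount / foldStep^k
  cp <- cpAtMax + k * log(foldStep) / log(trueE)
  if (noiseSd > 0) {
    if (is.null(seed))
      stop("a 'seed' is required when noiseSd > 0", call. = FALSE)
    cp <- cp + withSeed(seed, stats::rnorm(nPoints, 0, noiseSd))
  }
  dilutionSeries(amount, cp, geneId = geneId)
}

#' Simulate dilution series for every gene of a scenario
#'
#' One series per panel gene, at the gene's true efficiency, with
#' independent per-gene seeds derived from \code{seed}.
#'
#' @param config a [ScenarioConfig-class].
#' @param noiseSd CP noise sd per point; default 0.15.
#' @param seed master seed; defaults to the config seed.
#' @param ... passed to [simulateDilutionSeries()].
#' @return named list of [DilutionSeries-class] objects.
#' @export
simulateDilutionSeriesSet <- function(config, noiseSd = 0.15,
                                      seed = config@seed, ...) {
  genes <- config@genes
  seeds <- deriveSeeds(seed, nrow(genes))
  out <- lapply(seq_len(nrow(genes)), function(i)
    simulateDilutionSeries(genes$true_efficiency[i], noiseSd = noiseSd,
                           seed = seeds[i], geneId = genes$gene_id[i],
                           ...))
  stats::setNames(out, genes$gene_id)
}

# design cell label of a sample under the config's cellBy columns
cellLabel <- function(config, meta) {
  labs <- lapply(config@cellBy, function(col) as.character(meta[[col]]))
  do.call(paste, c(labs, sep = ":"))
}

buildSampleFrame <- function(config, repSeed) {
  cols <- sprintf("colony%02d", seq_len(config@nColonies))
  if (length(config@sites) > 0L) {
    meta <- DataFrame(colony = cols, treatment = config@treatments[1L],
                      timepoint = NA_character_,
                      tank = NA_character_,
                      site = siteAssignmentOf(config))
  } else {
    tps <- if (length(config@timepoints) > 0L) config@timepoints
           else NA_character_
    grid <- expand.grid(colony = cols, treatment = config@treatments,
                        timepoint = tps, stringsAsFactors = FALSE)
    drop <- paste(grid$colony, grid$treatment) %in%
      paste(config@missingArms$colony, config@missingArms$treatment)
    grid <- grid[!drop, , drop = FALSE]
    nrep <- withSeed(repSeed, {
      lo <- config@replicates[1L]; hi <- config@replicates[2L]
      if (lo == hi) rep(lo, nrow(grid))
      else sample(seq.int(lo, hi), nrow(grid), replace = TRUE)
    })
    grid <- grid[rep(seq_len(nrow(grid)), nrep), , drop = FALSE]
    repIdx <- stats::ave(seq_len(nrow(grid)),
                         paste(grid$colony, grid$treatment,
                               grid$timepoint),
                         FUN = seq_along)
    tank <- if (config@tanksPerTreatment > 0L)
      paste0(grid$treatment, "_tank",
             ((repIdx - 1L) %% config@tanksPerTreatment) + 1L)
    else NA_character_
    meta <- DataFrame(colony = grid$colony, treatment = grid$treatment,
                      timepoint = grid$timepoint, tank = tank,
                      site = NA_character_)
  }
  meta$sample_id <- sprintf("s%03d", seq_len(nrow(meta)))
  rownames(meta) <- meta$sample_id
  meta[, c("sample_id", "colony", "treatment", "timepoint", "tank",
           "site")]
}

#' Simulate a full qPCR experiment
#'
#' Draws an experiment from the generative model the downstream analysis
#' assumes. For sample s and gene g the true log2 abundance is
#' \deqn{a(s,g) = baseline_g + colony(s,g) + tank(s,g) + effect(g,
#' cell(s)) + residual(s,g)} with Gaussian random effects and residuals on
#' the log2 (Ca) scale. A per-sample template-loading factor L(s) (shared
#' by all genes of the sample) is added, and each technical run emits
#' \deqn{CP(s,g,run) = -(a(s,g) + L(s)) / log2(E_g) + technical\ noise}
#' with Gaussian noise on the CP scale. Colony effects are drawn
#' independently per gene unless \code{sharedColony} is set in the
#' config. Everything drawn is recorded in the returned
#' [SimulationTruth-class]; identical config and seed reproduce the CP
#' table bit for bit.
#'
#' @param config a [ScenarioConfig-class].
#' @param seed overrides the config seed.
#' @param nRuns technical duplicates per (sample, gene); default 2,
#'   emulating assaying each cDNA sample in duplicate runs.
#' @return a list with elements \code{cp} ([CpTable-class]),
#'   \code{metadata} (sample DataFrame) and \code{truth}
#'   ([SimulationTruth-class]).
#' @export
simulateExperiment <- function(config, seed = config@seed, nRuns = 2L) {
  validObject(config)
  seeds <- deriveSeeds(seed, 6L)
  meta <- buildSampleFrame(config, seeds[1L])
  genes <- config@genes
  nG <- nrow(genes); nS <- nrow(meta)
  v <- config@variance
  gid <- genes$gene_id

  colNames <- sprintf("colony%02d", seq_len(config@nColonies))
  colonyEff <- withSeed(seeds[2L], {
    if (config@sharedColony)
      matrix(stats::rnorm(config@nColonies, 0, v["colony_sd"]),
             nrow = config@nColonies, ncol = nG,
             dimnames = list(colNames, gid))
    else
      matrix(stats::rnorm(config@nColonies * nG, 0, v["colony_sd"]),
             nrow = config@nColonies, ncol = nG,
             dimnames = list(colNames, gid))
  })
  tanks <- unique(meta$tank[!is.na(meta$tank)])
  tankEff <- withSeed(seeds[3L],
    matrix(stats::rnorm(length(tanks) * nG, 0, v["tank_sd"]),
           nrow = length(tanks), ncol = nG,
           dimnames = list(tanks, gid)))
  loading <- withSeed(seeds[4L],
    stats::setNames(stats::rnorm(nS, 0, v["loading_sd"]),
                    meta$sample_id))
  resid <- withSeed(seeds[5L],
    matrix(stats::rnorm(nS * nG, 0, v["residual_sd"]), nrow = nS,
           dimnames = list(meta$sample_id, gid)))

  cells <- cellLabel(config, meta)
  fixedEff <- matrix(0, nrow = nS, ncol = nG,
                     dimnames = list(meta$sample_id, gid))
  if (nrow(config@effects) > 0L) {
    effKey <- paste(config@effects$gene_id, config@effects$cell,
                    sep = "\r")
    effSum <- tapply(config@effects$effect, effKey, sum)
    keyAll <- paste(rep(gid, each = nS), rep(cells, times = nG),
                    sep = "\r")
    hit <- match(keyAll, names(effSum))
    fixedEff[] <- ifelse(is.na(hit), 0, as.numeric(effSum[hit]))
  }

  abundance <- matrix(rep(genes$baseline_level, each = nS), nrow = nS,
                      dimnames = list(meta$sample_id, gid)) +
    colonyEff[meta$colony, , drop = FALSE] + fixedEff + resid
  if (length(tanks) > 0L) {
    hasTank <- !is.na(meta$tank)
    abundance[hasTank, ] <- abundance[hasTank, , drop = FALSE] +
      tankEff[meta$tank[hasTank], , drop = FALSE]
  }

  logE <- log2(genes$true_efficiency)
  cpExp <- sweep(-(abundance + loading), 2L, logE, "/")
  techNoise <- withSeed(seeds[6L],
    array(stats::rnorm(nS * nG * nRuns, 0, v["technical_sd"]),
          dim = c(nS, nG, nRuns)))
  rows <- expand.grid(sample_id = meta$sample_id, gene_id = gid,
                      run_id = as.character(seq_len(nRuns)),
                      stringsAsFactors = FALSE)
  rows$cp <- as.vector(
    array(cpExp, dim = c(nS, nG, nRuns)) + techNoise)
  cp <- cpTable(rows)

  truth <- new("SimulationTruth", abundance = abundance,
               loading = loading, colonyEffects = colonyEff,
               tankEffects = tankEff,
               effects = config@effects, config = config)
  list(cp = cp, metadata = meta, truth = truth)
}
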