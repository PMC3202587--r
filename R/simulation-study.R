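#' One simulated replicate of the full analysis pipeline
#'
#' Simulates an experiment from \code{config}, estimates per-gene
#' amplification efficiencies from simulated dilution series, aggregates
#' duplicates to raw Ca, normalizes against the control genes, and runs
#' the gene-wise model screen with BH correction. This is the unit of the
#' parameter-recovery and error-control simulation studies.
#'
#' @param config a [ScenarioConfig-class].
#' @param seed replicate seed.
#' @param controls control genes for normalization; default the three most
#'   stable candidates of the reference panel
#'   (\code{c("RPL11", "EIF3H", "ND5")}).
#' @param design list with \code{fixed} and \code{random} (see
#'   [designFor()]); defaults to the design matching the scenario name.
#' @param dilutionNoiseSd CP noise on the calibration series; default
#'   0.15.
#' @param ... passed to [fitGeneModels()].
#' @return an [EffectTable-class] for the screened panel.
#' @export
screenOnce <- function(config, seed = config@seed,
                       controls = c("RPL11", "EIF3H", "ND5"),
                       design = NULL, dilutionNoiseSd = 0.15, ...) {
  if (is.null(design)) design <- designFor(config@name)
  seeds <- deriveSeeds(seed, 2L)
  sim <- simulateExperiment(config, seed = seeds[1L])
  eff <- efficiencyTable(lapply(
    simulateDilutionSeriesSet(config, noiseSd = dilutionNoiseSd,
                              seed = seeds[2L]),
    estimateEfficiency))
  raw <- suppressWarnings(
    aggregateDuplicates(sim$cp, eff, metadata = sim$metadata))
  norm <- if (length(controls) >= 1L) normalizeCa(raw, controls) else raw
  suppressWarnings(
    fitGeneModels(norm, fixed = design$fixed, random = design$random,
                  seed = seed, ...))
}

#' Replicated parameter-recovery / error-control screen
#'
#' Runs [screenOnce()] for \code{nReps} independently seeded replicates of
#' a preset scenario and stacks the per-replicate effect tables, tagging
#' each with its replicate index. Summarize with [summarizeRecovery()] or
#' use directly for empirical error-rate estimation.
#'
#' @param preset preset name passed to [presetScenario()].
#' @param nReps number of replicates.
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param nullEffects simulate under the global null (all effects 0).
#' @param ... passed to [screenOnce()].
#' @return a \code{DataFrame} of stacked effect rows with a \code{rep}
#'   column.
#' @export
replicateScreen <- function(preset, nReps, seed = 1L,
                            nullEffects = FALSE, ...) {
  seeds <- deriveSeeds(seed, nReps)
  parts <- lapply(seq_len(nReps), function(i) {
    cfg <- presetScenario(preset, seed = seeds[i],
                          nullEffects = nullEffects)
    et <- screenOnce(cfg, seed = seeds[i], ...)
    df <- as(et, "DFrame")
    df$rep <- i
    df
  })
  do.call(rbind, parts)
}

#' Summarize effect recovery across replicates
#'
#' For a (gene, term) of interest, reports the Monte-Carlo mean of the
#' log2 estimate B, its Monte-Carlo standard error, the geometric-mean
#' fold 2^mean(B), and the configured truth if supplied.
#'
#' @param screens stacked replicate table from [replicateScreen()].
#' @param gene gene id.
#' @param term fixed-effect term name.
#' @return a one-row data.frame with \code{meanB}, \code{mcse},
#'   \code{fold} (= 2^|meanB|), \code{direction} and \code{n} replicates.
#' @export
summarizeRecovery <- function(screens, gene, term) {
  i <- screens$gene_id == gene & screens$term == term
  if (!any(i))
    stop(sprintf("no rows for gene '%s', term '%s'", gene, term),
         call. = FALSE)
  B <- screens$B[i]
  data.frame(gene_id = gene, term = term, meanB = mean(B),
             mcse = stats::sd(B) / sqrt(length(B)),
             fold = 2^abs(mean(B)),
             direction = if (mean(B) >= 0) "up" else "down",
             n = length(B))
}

#' Empirical discovery rate under replicated screening
#'
#' Fraction of replicates in which any gene passes the BH-adjusted
#' threshold for the given term. Under a global-null simulation every
#' discovery is false, so this is the empirical familywise false-discovery
#' rate of the screen.
#'
#' @param screens stacked replicate table from [replicateScreen()].
#' @param alpha FDR level; default 0.05.
#' @param term restrict to one fixed-effect term; default all terms.
#' @return proportion of replicates with at least one discovery.
#' @export
discoveryRate <- function(screens, alpha = 0.05, term = NULL) {
  df <- as.data.frame(screens[, c("rep", "term", "p_adj")])
  if (!is.null(term)) df <- df[df$term %in% term, , drop = FALSE]
  hit <- tapply(df$p_adj <= alpha, df$rep, any, na.rm = TRUE)
  mean(hit)
}
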