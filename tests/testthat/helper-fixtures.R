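# Shared fixture builders; everything is generated in code.

# genes x samples CaExperiment from a plain matrix
makeCaExp <- function(m, meta = NULL, normalized = FALSE,
                      controls = character()) {
  if (is.null(rownames(m)))
    rownames(m) <- paste0("g", seq_len(nrow(m)))
  if (is.null(colnames(m)))
    colnames(m) <- paste0("s", seq_len(ncol(m)))
  caExperiment(m, colData = meta, normalized = normalized,
               controlGenes = controls)
}

# a preset with every variance component set to zero (deterministic)
zeroNoiseConfig <- function(name = "exp1", ...) {
  cfg <- presetScenario(name, ...)
  cfg@variance[] <- 0
  cfg
}

# quantify a simulated experiment with the true efficiencies (no
# calibration noise)
quantifyTrue <- function(sim, config, ...) {
  effs <- stats::setNames(config@genes$true_efficiency,
                          config@genes$gene_id)
  suppressWarnings(
    aggregateDuplicates(sim$cp, effs, metadata = sim$metadata, ...))
}

# paired-colony fixture: one control + one treated observation per colony
pairedData <- function(b, nColony = 5, sd = 0.3, seed = 1) {
  set.seed(seed)
  colony <- rep(sprintf("c%d", seq_len(nColony)), each = 2)
  treatment <- rep(c("control", "stress"), nColony)
  ce <- rnorm(nColony, 0, 0.5)
  data.frame(
    ca = ce[as.integer(factor(colony))] +
      ifelse(treatment == "stress", b, 0) + rnorm(2 * nColony, 0, sd),
    colony = colony, treatment = treatment)
}
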