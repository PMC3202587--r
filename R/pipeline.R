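#' Model design for a named experimental layout
#'
#' Maps the study designs to their model formulas: "exp1" is a paired
#' treatment contrast with colony as a random factor; "exp2" a treatment x
#' sampling-point factorial (coded so the treatment contrast is estimated
#' separately at each timepoint) with colony random; "exp4" adds tank as a
#' second random factor; "field" is a plain two-site linear model.
#'
#' @param name one of "exp1", "exp2", "exp4", "field".
#' @return list with elements \code{fixed} (one-sided formula) and
#'   \code{random} (character vector).
#' @export
designFor <- function(name = c("exp1", "exp2", "exp4", "field")) {
  name <- match.arg(name)
  switch(name,
         exp1 = list(fixed = ~ treatment, random = "colony"),
         exp2 = list(fixed = ~ timepoint + timepoint:treatment,
                     random = "colony"),
         exp4 = list(fixed = ~ treatment, random = c("colony", "tank")),
         field = list(fixed = ~ site, random = character()))
}

#' Assemble and validate a pipeline configuration
#'
#' @param cp a [CpTable-class] or path to a CP CSV.
#' @param dilutions named list of [DilutionSeries-class], an
#'   [EfficiencyTable-class], or path to a dilution-series CSV.
#' @param metadata sample metadata (DataFrame/data.frame with
#'   \code{sample_id}) or path to a metadata CSV.
#' @param controls control gene ids used for normalization.
#' @param design design name (see [designFor()]) or a list with
#'   \code{fixed} and \code{random}.
#' @param psiPair numerator and denominator genes of the stress index;
#'   default \code{c("Hsp16", "Actin")}.
#' @param pcaGenes optional genes for the PCA marker screen (run on the
#'   normalized matrix when >= 2 are present).
#' @param alpha FDR level for the discovery report, in (0, 1);
#'   default 0.05.
#' @param seed seed for any stochastic inference; default 1.
#' @param qcRange accepted efficiency range.
#' @param discordanceLimit duplicate-run CP discordance limit, cycles.
#' @return a validated \code{RunConfig} list.
#' @export
runConfig <- function(cp, dilutions, metadata = NULL,
                      controls = character(), design = "exp1",
                      psiPair = c("Hsp16", "Actin"),
                      pcaGenes = NULL, alpha = 0.05, seed = 1L,
                      qcRange = c(1.85, 2.15), discordanceLimit = 1.5) {
  for (p in Filter(is.character, list(cp, dilutions, metadata)))
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  if (!(is.numeric(alpha) && length(alpha) == 1L && alpha > 0 &&
        alpha < 1))
    stop("'alpha' must lie in (0, 1)", call. = FALSE)
  if (length(qcRange) != 2L || qcRange[1L] >= qcRange[2L])
    stop("'qcRange' must be an increasing pair", call. = FALSE)
  if (length(psiPair) != 2L)
    stop("'psiPair' must name exactly two genes", call. = FALSE)
  design <- if (is.character(design)) designFor(design) else design
  structure(list(cp = cp, dilutions = dilutions, metadata = metadata,
                 controls = as.character(controls), design = design,
                 psiPair = psiPair, pcaGenes = pcaGenes, alpha = alpha,
                 seed = as.integer(seed), qcRange = qcRange,
                 discordanceLimit = discordanceLimit),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Executes, in order: efficiency estimation, duplicate aggregation to raw
#' Ca, the stress index on raw Ca, reference-gene stability ranking (when
#' >= 3 controls are configured), control-gene normalization, the
#' gene-wise mixed-model screen with BH correction, the stress-index group
#' comparison, and (optionally) the PCA marker screen. Any stage error
#' aborts with the stage name and cause. With \code{outDir} set, all
#' result tables are written as CSV together with a run log recording the
#' seed and QC flags; identical config and seed reproduce identical
#' outputs.
#'
#' @param config a \code{RunConfig} from [runConfig()].
#' @param outDir optional output directory.
#' @param quiet suppress the stage log on the console.
#' @return a list with elements \code{efficiencies}, \code{raw},
#'   \code{psi}, \code{stability}, \code{normalized}, \code{effects},
#'   \code{psiEffect}, \code{pca} (NULL when not run) and \code{log}.
#' @export
runPipeline <- function(config, outDir = NULL, quiet = FALSE) {
  if (!inherits(config, "RunConfig"))
    stop("'config' must come from runConfig()", call. = FALSE)
  logLines <- character()
  note <- function(...) {
    line <- sprintf(...)
    logLines <<- c(logLines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }
  note("pipeline seed: %d", config$seed)

  eff <- stage("efficiency", {
    d <- config$dilutions
    if (is.character(d)) d <- readDilutionSeries(d)
    if (methods::is(d, "EfficiencyTable")) d
    else efficiencyTable(lapply(d, estimateEfficiency,
                                qcRange = config$qcRange))
  })
  if (any(!eff$qc_pass))
    note("efficiency QC flag: %s",
         paste(eff$gene_id[!eff$qc_pass], collapse = ", "))

  cp <- stage("read-cp",
              if (is.character(config$cp)) readCpTable(config$cp)
              else config$cp)
  meta <- stage("read-metadata", {
    m <- config$metadata
    if (is.character(m)) readMetadata(m) else m
  })
  badCtl <- setdiff(config$controls, unique(cp$gene_id))
  if (length(badCtl) > 0L)
    stop("configuration error: control gene(s) absent from CP table: ",
         paste(badCtl, collapse = ", "), call. = FALSE)

  raw <- stage("quantify",
               aggregateDuplicates(cp, eff,
                                   discordanceLimit =
                                     config$discordanceLimit,
                                   metadata = meta))
  nDisc <- sum(SummarizedExperiment::assays(raw)[["discordant"]])
  note("quantified %d genes x %d samples; %d discordant duplicate cell(s)",
       nrow(raw), ncol(raw), nDisc)

  psi <- stage("psi", computePsi(raw, config$psiPair[1L],
                                 config$psiPair[2L]))
  stab <- if (length(config$controls) >= 3L)
    stage("stability", genormRank(raw, config$controls))
  else NULL
  if (!is.null(stab))
    note("stability ranking (least->most stable): %s",
         paste(exclusionOrder(stab), collapse = ", "))

  norm <- if (length(config$controls) >= 1L)
    stage("normalize", normalizeCa(raw, config$controls))
  else raw

  effects <- stage("diffexpr",
                   fitGeneModels(norm, fixed = config$design$fixed,
                                 random = config$design$random,
                                 seed = config$seed))
  nSig <- sum(effects$p_adj <= config$alpha, na.rm = TRUE)
  note("gene-wise screen: %d effect(s) at FDR %.2f", nSig, config$alpha)

  psiEffect <- stage("psi-compare",
                     comparePsi(psi, fixed = config$design$fixed,
                                random = config$design$random,
                                seed = config$seed))
  pca <- NULL
  if (!is.null(config$pcaGenes) && length(config$pcaGenes) >= 2L)
    pca <- stage("pca", pcaMarkers(norm, genes = config$pcaGenes))

  out <- list(efficiencies = eff, raw = raw, psi = psi,
              stability = stab, normalized = norm, effects = effects,
              psiEffect = psiEffect, pca = pca, log = logLines)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(eff),
                     file.path(outDir, "efficiencies.csv"),
                     row.names = FALSE)
    writeCaMatrix(raw, file.path(outDir, "ca_raw.csv"))
    writeCaMatrix(norm, file.path(outDir, "ca_normalized.csv"))
    utils::write.csv(as.data.frame(psi), file.path(outDir, "psi.csv"),
                     row.names = FALSE)
    if (!is.null(stab))
      utils::write.csv(data.frame(gene_id = exclusionOrder(stab),
                                  M = stabilityM(stab)[
                                    exclusionOrder(stab)]),
                       file.path(outDir, "stability.csv"),
                       row.names = FALSE)
    utils::write.csv(as.data.frame(effects),
                     file.path(outDir, "effects.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(psiEffect),
                     file.path(outDir, "psi_effect.csv"),
                     row.names = FALSE)
    writeLines(logLines, file.path(outDir, "run_log.txt"))
  }
  out
}
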