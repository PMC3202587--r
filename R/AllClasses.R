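#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Raw crossing-point observations
#'
#' A \code{CpTable} holds raw qPCR crossing-point (CP) observations, one row
#' per (sample, gene, technical run). CP is the cycle at which amplification
#' fluorescence crosses the detection threshold; lower CP means more
#' template. Columns are \code{sample_id}, \code{gene_id}, \code{run_id}
#' and \code{cp}.
#'
#' @slot .Data inherited \code{DFrame} representation.
#' @seealso [cpTable()], [readCpTable()], [aggregateDuplicates()]
#' @exportClass CpTable
setClass("CpTable", contains = "DFrame")

setValidity("CpTable", function(object) {
  req <- c("sample_id", "gene_id", "run_id", "cp")
  miss <- setdiff(req, colnames(object))
  if (length(miss) > 0L)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  cp <- object$cp
  if (!is.numeric(cp))
    return("'cp' must be numeric")
  if (nrow(object) > 0L && (any(!is.finite(cp)) || any(cp <= 0)))
    return("'cp' values must be finite and > 0")
  key <- paste(object$sample_id, object$gene_id, object$run_id, sep = "\r")
  if (anyDuplicated(key))
    return("duplicate (sample_id, gene_id, run_id) keys")
  TRUE
})

#' Amplification-efficiency dilution series
#'
#' CP observations from a serial dilution of template for one primer pair,
#' used to estimate the per-cycle amplification factor E. Columns are
#' \code{amount} (template input, strictly positive, arbitrary mass or
#' relative units) and \code{cp}.
#'
#' @slot geneId gene identifier for the assayed primer pair.
#' @seealso [dilutionSeries()], [estimateEfficiency()],
#'   [simulateDilutionSeries()]
#' @exportClass DilutionSeries
setClass("DilutionSeries", contains = "DFrame",
         representation(geneId = "character"))

setValidity("DilutionSeries", function(object) {
  if (!all(c("amount", "cp") %in% colnames(object)))
    return("columns 'amount' and 'cp' are required")
  if (nrow(object) < 3L)
    return("a dilution series needs at least 3 points")
  if (any(!is.finite(object$amount)) || any(object$amount <= 0))
    return("'amount' values must be finite and > 0")
  if (length(unique(object$amount)) < 2L)
    return("at least two distinct input amounts are required")
  if (length(object@geneId) != 1L)
    return("'geneId' must be a single string")
  TRUE
})

#' Per-gene amplification-efficiency estimates
#'
#' One row per gene with the dilution-regression slope (CP per log2 input),
#' the amplification factor \code{efficiency} = 2^(-1/slope), the regression
#' \code{r_squared}, and \code{qc_pass} indicating whether the efficiency
#' lies within the accepted assay range.
#'
#' @seealso [estimateEfficiency()], [efficiencyTable()]
#' @exportClass EfficiencyTable
setClass("EfficiencyTable", contains = "DFrame")

setValidity("EfficiencyTable", function(object) {
  req <- c("gene_id", "slope", "efficiency", "r_squared", "qc_pass")
  miss <- setdiff(req, colnames(object))
  if (length(miss) > 0L)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$gene_id))
    return("duplicate gene_id entries")
  if (nrow(object) > 0L && any(object$efficiency <= 1, na.rm = TRUE))
    return("efficiencies must be > 1")
  TRUE
})

#' Samples-by-genes matrix of log2 abundances (Ca values)
#'
#' A \code{CaExperiment} extends \code{SummarizedExperiment}: the "ca" assay
#' holds Ca values (genes as rows, samples as columns) where
#' Ca = -CP * log2(E) is a log2-scale relative abundance; differences in Ca
#' are log2 fold changes. \code{colData} carries sample metadata (colony,
#' treatment, timepoint, tank, site as available) and \code{metadata()}
#' records whether the matrix is control-gene normalized and against which
#' control genes. Cells with no usable observations are explicit \code{NA},
#' never silently dropped. A "discordant" assay flags duplicate runs that
#' disagreed by more than the discordance limit.
#'
#' @seealso [aggregateDuplicates()], [normalizeCa()], [isNormalized()]
#' @exportClass CaExperiment
setClass("CaExperiment", contains = "SummarizedExperiment")

setValidity("CaExperiment", function(object) {
  if (!"ca" %in% SummarizedExperiment::assayNames(object))
    return("assay 'ca' is required")
  md <- metadata(object)
  if (!is.logical(md$normalized) || length(md$normalized) != 1L)
    return("metadata 'normalized' must be a single logical")
  if (isTRUE(md$normalized) && length(md$control_genes) < 1L)
    return("a normalized CaExperiment must record its control genes")
  TRUE
})

#' geNorm reference-gene stability ranking
#'
#' Result of iterative geNorm exclusion over candidate reference genes: each
#' gene's stability value M (mean pairwise standard deviation of per-sample
#' log2 ratios with the other candidates, evaluated at the step where the
#' gene was excluded; lower M is more stable), the exclusion order from
#' least to most stable, and the per-step M recomputations.
#'
#' @slot M named numeric, each gene's M at its exclusion step (the two
#'   survivors share the final two-gene value).
#' @slot exclusionOrder character, genes from least to most stable.
#' @slot steps list of named numeric vectors, M over the candidate set at
#'   each exclusion step.
#' @seealso [genormRank()], [genormM()]
#' @exportClass StabilityRanking
setClass("StabilityRanking",
         representation(M = "numeric", exclusionOrder = "character",
                        steps = "list"))

setValidity("StabilityRanking", function(object) {
  if (any(object@M < 0)) return("M values must be >= 0")
  if (!setequal(names(object@M), object@exclusionOrder))
    return("M names and exclusionOrder must contain the same genes")
  TRUE
})

#' Residual control-gene variation report
#'
#' Per control gene, the fold by which it is regulated across experimental
#' conditions (2^|range of condition means| of its all-controls-normalized
#' Ca) and the fold by which it fluctuates within a condition
#' (2^(multiplier * pooled residual sd)).
#'
#' @seealso [controlVariation()]
#' @exportClass ControlVariationReport
setClass("ControlVariationReport", contains = "DFrame")

setValidity("ControlVariationReport", function(object) {
  req <- c("gene_id", "between_condition_fold", "within_condition_fold")
  miss <- setdiff(req, colnames(object))
  if (length(miss) > 0L)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(object) > 0L &&
      (any(object$between_condition_fold < 1 - 1e-12) ||
       any(object$within_condition_fold < 1 - 1e-12)))
    return("fold values must be >= 1")
  TRUE
})

#' Fixed-effect estimates from gene-wise models
#'
#' One row per (gene, fixed-effect term): the log2 effect size \code{B},
#' \code{fold} = 2^|B| with \code{direction} ("up"/"down"/"none"),
#' confidence bounds on the log2 scale, the nominal p-value and the
#' Benjamini-Hochberg adjusted p-value.
#'
#' @seealso [fitGeneModel()], [fitGeneModels()], [comparePsi()]
#' @exportClass EffectTable
setClass("EffectTable", contains = "DFrame")

setValidity("EffectTable", function(object) {
  req <- c("gene_id", "term", "B", "fold", "direction", "ci_low", "ci_high",
           "p")
  miss <- setdiff(req, colnames(object))
  if (length(miss) > 0L)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (nrow(object) == 0L) return(TRUE)
  if (any(abs(object$fold - 2^abs(object$B)) > 1e-8 * (1 + object$fold)))
    return("fold must equal 2^|B|")
  p <- object$p[!is.na(object$p)]
  if (any(p < 0 | p > 1)) return("p-values must lie in [0, 1]")
  TRUE
})

#' Per-sample Porites Stress Index values
#'
#' The two-gene stress index D = Ca(numerator) - Ca(denominator) computed on
#' NON-normalized Ca values (per-sample template-loading factors cancel in
#' the difference, so no control genes are needed). Negative at baseline;
#' rises toward or above zero under acute heat-light stress when the
#' numerator (Hsp16 by default) is induced and the denominator (actin) is
#' repressed. Sample metadata columns are carried through.
#'
#' @seealso [computePsi()], [comparePsi()]
#' @exportClass PsiResult
setClass("PsiResult", contains = "DFrame")

setValidity("PsiResult", function(object) {
  if (!all(c("sample_id", "psi") %in% colnames(object)))
    return("columns 'sample_id' and 'psi' are required")
  if (anyDuplicated(object$sample_id))
    return("duplicate sample_id entries")
  TRUE
})

#' Principal-components marker screen
#'
#' PCA of the normalized Ca matrix (samples as observations, genes as
#' variables; centered, optionally scaled), with per-component variance
#' fractions, unit-norm gene loadings, sample scores, and the suggested
#' two-gene assay: the pair of genes with the extreme positive and negative
#' loadings on PC1.
#'
#' @slot varianceFraction numeric, fraction of variance per component
#'   (sums to 1).
#' @slot loadings genes x components matrix of unit-norm loadings.
#' @slot scores samples x components score matrix.
#' @slot markers character(2): the extreme positive- and negative-loading
#'   genes on PC1, in that order.
#' @slot markerLoadings numeric(2): their PC1 loadings.
#' @slot scaled logical, whether variables were scaled to unit variance.
#' @seealso [pcaMarkers()]
#' @exportClass PcaResult
setClass("PcaResult",
         representation(varianceFraction = "numeric", loadings = "matrix",
                        scores = "matrix", markers = "character",
                        markerLoadings = "numeric", scaled = "logical"))

setValidity("PcaResult", function(object) {
  if (abs(sum(object@varianceFraction) - 1) > 1e-8)
    return("variance fractions must sum to 1")
  nrm <- sqrt(colSums(object@loadings^2))
  if (any(abs(nrm - 1) > 1e-8))
    return("loadings must have unit norm per component")
  if (length(object@markers) != 2L)
    return("exactly two marker genes are selected")
  TRUE
})

#' Gene panel for synthetic experiments
#'
#' One row per simulated gene: \code{gene_id}, \code{role} (one of
#' "target", "control", "psi_numerator", "psi_denominator"),
#' \code{true_efficiency} (per-cycle amplification factor, > 1) and
#' \code{baseline_level} (mean log2 abundance in the control condition, Ca
#' units).
#'
#' @seealso [genePanel()], [scenarioConfig()]
#' @exportClass GenePanel
setClass("GenePanel", contains = "DFrame")

setValidity("GenePanel", function(object) {
  req <- c("gene_id", "role", "true_efficiency", "baseline_level")
  miss <- setdiff(req, colnames(object))
  if (length(miss) > 0L)
    return(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(object$gene_id))
    return("gene_id must be unique within a panel")
  ok <- c("target", "control", "psi_numerator", "psi_denominator")
  if (!all(object$role %in% ok))
    return(paste0("role must be one of: ", paste(ok, collapse = ", ")))
  if (any(object$true_efficiency <= 1))
    return("true_efficiency must be > 1")
  TRUE
})

#' Generative scenario configuration
#'
#' Full description of a synthetic qPCR experiment: the gene panel, the
#' paired-colony design (colonies, treatments, optional timepoints, optional
#' replicate tanks), the per-(gene, design-cell) log2 fixed effects, and the
#' variance components. All standard deviations are on the log2 (Ca) scale
#' except \code{technical_sd}, which is Gaussian noise on the CP scale.
#'
#' @slot name scenario label.
#' @slot genes [GenePanel-class] of simulated genes.
#' @slot nColonies number of coral colonies.
#' @slot treatments treatment labels (first label is the reference level).
#' @slot timepoints sampling-point labels, or character(0) for single-time
#'   designs.
#' @slot sites field-site labels, or character(0) for lab designs.
#' @slot tanksPerTreatment replicate tanks per treatment (0 = no tank
#'   structure).
#' @slot replicates integer(2) inclusive range of fragments per colony per
#'   design cell.
#' @slot missingArms DataFrame (colony, treatment) of deliberately absent
#'   colony-by-treatment arms (unbalanced designs).
#' @slot effects DataFrame (gene_id, cell, effect) of true log2 effects;
#'   unlisted combinations default to 0. Cells are labels over the columns
#'   in \code{cellBy}, joined with ":".
#' @slot cellBy metadata columns whose combination defines a design cell.
#' @slot variance named numeric: colony_sd, tank_sd, residual_sd,
#'   loading_sd (all Ca units) and technical_sd (CP units).
#' @slot sharedColony if TRUE colony effects are shared across genes;
#'   default FALSE draws them independently per gene, matching gene-wise
#'   model fitting.
#' @slot seed integer seed; every stochastic operation is explicitly seeded.
#' @seealso [scenarioConfig()], [presetScenario()], [simulateExperiment()]
#' @exportClass ScenarioConfig
setClass("ScenarioConfig",
         representation(name = "character", genes = "GenePanel",
                        nColonies = "integer", treatments = "character",
                        timepoints = "character", sites = "character",
                        tanksPerTreatment = "integer",
                        replicates = "integer", missingArms = "DFrame",
                        effects = "DFrame", cellBy = "character",
                        variance = "numeric", sharedColony = "logical",
                        seed = "integer"))

setValidity("ScenarioConfig", function(object) {
  v <- object@variance
  req <- c("colony_sd", "tank_sd", "residual_sd", "loading_sd",
           "technical_sd")
  miss <- setdiff(req, names(v))
  if (length(miss) > 0L)
    return(paste0("missing variance component(s): ",
                  paste(miss, collapse = ", ")))
  if (any(v < 0)) return("all variance components must be >= 0")
  if (object@nColonies < 1L) return("nColonies must be >= 1")
  if (length(object@treatments) < 1L)
    return("at least one treatment label is required")
  if (length(object@replicates) != 2L ||
      object@replicates[1L] < 1L ||
      object@replicates[2L] < object@replicates[1L])
    return("replicates must be an increasing integer range >= 1")
  bad <- setdiff(object@effects$gene_id, object@genes$gene_id)
  if (length(bad) > 0L)
    return(paste0("effects reference unknown gene(s): ",
                  paste(bad, collapse = ", ")))
  TRUE
})

#' Ground truth of a simulated experiment
#'
#' Everything the generator drew, stored exactly: the noiseless per-sample,
#' per-gene log2 abundances, the per-sample template-loading factors, the
#' realized colony and tank random effects, and the true effect map. With
#' all noise components at zero the emitted CP table round-trips through
#' [cpToCa()] to \code{abundance + loading} exactly.
#'
#' @slot abundance samples x genes matrix of true log2 abundances a(s, g)
#'   (before the loading factor).
#' @slot loading named numeric of per-sample loading factors L(s).
#' @slot colonyEffects realized colony random effects (colony x gene
#'   matrix, or colony vector when shared across genes).
#' @slot tankEffects realized tank random effects (tank x gene matrix; empty
#'   when the design has no tanks).
#' @slot effects DataFrame of the true (gene, cell) log2 effects in force.
#' @slot config the [ScenarioConfig-class] that generated the data.
#' @seealso [simulateExperiment()]
#' @exportClass SimulationTruth
setClass("SimulationTruth",
         representation(abundance = "matrix", loading = "numeric",
                        colonyEffects = "matrix", tankEffects = "matrix",
                        effects = "DFrame", config = "ScenarioConfig"))
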