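#' Construct a CpTable from raw CP observations
#'
#' @param x a data.frame (or DataFrame) with columns \code{sample_id},
#'   \code{gene_id}, \code{run_id} and \code{cp}.
#' @return a validated [CpTable-class].
#' @examples
#' cpTable(data.frame(sample_id = "s1", gene_id = "Actin",
#'                    run_id = 1:2, cp = c(20.1, 20.3)))
#' @export
cpTable <- function(x) {
  df <- DataFrame(sample_id = as.character(x$sample_id),
                  gene_id = as.character(x$gene_id),
                  run_id = as.character(x$run_id),
                  cp = as.numeric(x$cp))
  out <- as(df, "CpTable")
  validObject(out)
  out
}

#' Construct a dilution series
#'
#' @param amount template input amounts (strictly positive).
#' @param cp observed CP values.
#' @param geneId gene / primer-pair identifier.
#' @return a validated [DilutionSeries-class].
#' @examples
#' dilutionSeries(amount = 5 / 2^(0:6), cp = 15:21, geneId = "Actin")
#' @export
dilutionSeries <- function(amount, cp, geneId = "gene") {
  if (length(amount) != length(cp))
    stop("'amount' and 'cp' must have the same length", call. = FALSE)
  if (length(amount) < 3L)
    stop("a dilution series needs at least 3 points", call. = FALSE)
  if (any(!is.finite(amount)) || any(amount <= 0))
    stop("input amounts must be finite and > 0", call. = FALSE)
  out <- as(DataFrame(amount = as.numeric(amount), cp = as.numeric(cp)),
            "DilutionSeries")
  out@geneId <- as.character(geneId)
  validObject(out)
  out
}

#' Assemble an efficiency table from per-gene estimates
#'
#' @param ... one or more single-row [EfficiencyTable-class] objects, as
#'   returned by [estimateEfficiency()], or a single list of them.
#' @return an [EfficiencyTable-class] with one row per gene.
#' @export
efficiencyTable <- function(...) {
  parts <- list(...)
  if (length(parts) == 1L && is.list(parts[[1L]]) &&
      !methods::is(parts[[1L]], "DataFrame"))
    parts <- parts[[1L]]
  col <- function(nm, fun) unlist(lapply(parts, function(p) fun(p[[nm]])),
                                  use.names = FALSE)
  df <- DataFrame(gene_id = col("gene_id", as.character),
                  slope = col("slope", as.numeric),
                  efficiency = col("efficiency", as.numeric),
                  r_squared = col("r_squared", as.numeric),
                  n_points = col("n_points", as.integer),
                  qc_pass = col("qc_pass", as.logical))
  out <- as(df, "EfficiencyTable")
  validObject(out)
  out
}

#' Construct a CaExperiment
#'
#' @param ca genes x samples numeric matrix of Ca values (dimnames
#'   required).
#' @param colData sample metadata (rows match columns of \code{ca}).
#' @param normalized whether the values are control-gene normalized.
#' @param controlGenes control genes used, if normalized.
#' @param discordant optional logical genes x samples matrix flagging
#'   duplicate runs that disagreed beyond the discordance limit.
#' @param efficiencies optional [EfficiencyTable-class] recorded in rowData.
#' @return a validated [CaExperiment-class].
#' @export
caExperiment <- function(ca, colData = NULL, normalized = FALSE,
                         controlGenes = character(), discordant = NULL,
                         efficiencies = NULL) {
  ca <- as.matrix(ca)
  if (is.null(rownames(ca)) || is.null(colnames(ca)))
    stop("'ca' must have gene rownames and sample colnames", call. = FALSE)
  assays <- list(ca = ca)
  if (!is.null(discordant)) assays$discordant <- discordant
  if (is.null(colData))
    colData <- DataFrame(row.names = colnames(ca))
  else {
    colData <- DataFrame(colData)
    rownames(colData) <- colnames(ca)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = assays, colData = colData)
  if (!is.null(efficiencies)) {
    idx <- match(rownames(ca), efficiencies$gene_id)
    SummarizedExperiment::rowData(se)$efficiency <-
      efficiencies$efficiency[idx]
    SummarizedExperiment::rowData(se)$qc_pass <- efficiencies$qc_pass[idx]
  }
  out <- as(se, "CaExperiment")
  metadata(out)$normalized <- isTRUE(normalized)
  metadata(out)$control_genes <- as.character(controlGenes)
  validObject(out)
  out
}

#' @describeIn caExperiment extract the Ca value matrix (genes x samples).
#' @param x a \code{CaExperiment}.
#' @param ... unused.
#' @aliases caValues
#' @export
setMethod("caValues", "CaExperiment", function(x, ...)
  SummarizedExperiment::assay(x, "ca"))

#' Accessors for CaExperiment
#'
#' \code{isNormalized} reports whether the Ca values have been normalized
#' against control genes; \code{controlGenes} returns the control genes
#' used (empty for a raw matrix).
#'
#' @param x a [CaExperiment-class].
#' @name CaExperiment-accessors
#' @aliases isNormalized controlGenes
NULL

#' @rdname CaExperiment-accessors
#' @export
setMethod("isNormalized", "CaExperiment", function(x)
  isTRUE(metadata(x)$normalized))

#' @rdname CaExperiment-accessors
#' @export
setMethod("controlGenes", "CaExperiment", function(x)
  as.character(metadata(x)$control_genes))

#' Accessors for StabilityRanking
#'
#' \code{stabilityM} returns each candidate's geNorm stability value M at
#' the step where it was excluded (lower is more stable);
#' \code{exclusionOrder} returns the candidates from least to most stable.
#'
#' @param x a [StabilityRanking-class].
#' @name StabilityRanking-accessors
#' @aliases stabilityM exclusionOrder
NULL

#' @rdname StabilityRanking-accessors
#' @export
setMethod("stabilityM", "StabilityRanking", function(x) x@M)

#' @rdname StabilityRanking-accessors
#' @export
setMethod("exclusionOrder", "StabilityRanking", function(x)
  x@exclusionOrder)

#' Accessors for PcaResult
#'
#' \code{varianceFraction} gives the fraction of variance explained per
#' component; \code{pcaLoadings} the unit-norm gene loadings;
#' \code{markerPair} the suggested two-gene assay (extreme positive and
#' negative PC1 loadings), with the loadings as an attribute.
#'
#' @param x a [PcaResult-class].
#' @name PcaResult-accessors
#' @aliases varianceFraction pcaLoadings markerPair
NULL

#' @rdname PcaResult-accessors
#' @export
setMethod("varianceFraction", "PcaResult", function(x) x@varianceFraction)

#' @rdname PcaResult-accessors
#' @export
setMethod("pcaLoadings", "PcaResult", function(x) x@loadings)

#' @rdname PcaResult-accessors
#' @export
setMethod("markerPair", "PcaResult", function(x)
  structure(x@markers, loadings = x@markerLoadings))

#' Accessors for SimulationTruth
#'
#' \code{trueAbundance} returns the noiseless samples x genes log2
#' abundance matrix (before loading factors); \code{loadingFactors} the
#' realized per-sample template-loading factors; \code{trueEffects} the
#' (gene, cell) log2 effect map in force.
#'
#' @param x a [SimulationTruth-class].
#' @name SimulationTruth-accessors
#' @aliases trueAbundance loadingFactors trueEffects
NULL

#' @rdname SimulationTruth-accessors
#' @export
setMethod("trueAbundance", "SimulationTruth", function(x) x@abundance)

#' @rdname SimulationTruth-accessors
#' @export
setMethod("loadingFactors", "SimulationTruth", function(x) x@loading)

#' @rdname SimulationTruth-accessors
#' @export
setMethod("trueEffects", "SimulationTruth", function(x) x@effects)

setMethod("show", "CaExperiment", function(object) {
  cat(sprintf("CaExperiment: %d genes x %d samples (%s)\n",
              nrow(object), ncol(object),
              if (isNormalized(object)) "normalized" else "raw"))
  if (isNormalized(object))
    cat("control genes:", paste(controlGenes(object), collapse = ", "),
        "\n")
  callNextMethod()
})

setMethod("show", "StabilityRanking", function(object) {
  cat("geNorm stability ranking (least to most stable):\n")
  m <- object@M[object@exclusionOrder]
  print(round(m, 4))
  invisible(object)
})

setMethod("show", "PcaResult", function(object) {
  k <- min(3L, length(object@varianceFraction))
  cat(sprintf("PCA marker screen: %d genes, %d samples\n",
              nrow(object@loadings), nrow(object@scores)))
  cat("variance explained:",
      paste0(sprintf("PC%d %.1f%%", seq_len(k),
                     100 * object@varianceFraction[seq_len(k)]),
             collapse = ", "), "\n")
  cat(sprintf("suggested pair: %s (%.3f) / %s (%.3f)\n",
              object@markers[1L], object@markerLoadings[1L],
              object@markers[2L], object@markerLoadings[2L]))
  invisible(object)
})

setMethod("show", "ScenarioConfig", function(object) {
  cat(sprintf("ScenarioConfig '%s': %d genes, %d colonies\n",
              object@name, nrow(object@genes), object@nColonies))
  cat("treatments:", paste(object@treatments, collapse = ", "), "\n")
  if (length(object@timepoints) > 0L)
    cat("timepoints:", paste(object@timepoints, collapse = ", "), "\n")
  if (length(object@sites) > 0L)
    cat("sites:", paste(object@sites, collapse = ", "), "\n")
  if (object@tanksPerTreatment > 0L)
    cat("tanks per treatment:", object@tanksPerTreatment, "\n")
  cat("variance:", paste(sprintf("%s=%.2f", names(object@variance),
                                 object@variance), collapse = ", "), "\n")
  nz <- object@effects[object@effects$effect != 0, , drop = FALSE]
  if (nrow(nz) > 0L) {
    cat("non-zero effects (log2):\n")
    for (i in seq_len(nrow(nz)))
      cat(sprintf("  %s @ %s: %+0.3f\n", nz$gene_id[i], nz$cell[i],
                  nz$effect[i]))
  }
  invisible(object)
})
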