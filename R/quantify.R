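#' Estimate amplification efficiency from a dilution series
#'
#' Regresses CP on log2(input amount) by ordinary least squares and derives
#' the per-cycle amplification factor E = 2^(-1/slope). A perfect assay
#' doubles the template every cycle: CP drops by one per doubling of input,
#' the slope is -1 and E = 2. Assays whose E falls outside \code{qcRange}
#' are flagged (\code{qc_pass = FALSE}) but still quantified; downstream
#' steps warn rather than refuse, since a flagged primer pair may still be
#' informative while it awaits redesign.
#'
#' @param series a [DilutionSeries-class], or a data.frame with columns
#'   \code{amount} and \code{cp}.
#' @param qcRange accepted efficiency range, default \code{c(1.85, 2.15)}.
#' @return a single-row [EfficiencyTable-class] with the slope (CP per log2
#'   input), efficiency, regression r-squared, number of points and QC
#'   flag.
#' @examples
#' s <- dilutionSeries(amount = 5 / 2^(0:6), cp = 15:21, geneId = "g")
#' estimateEfficiency(s)
#' @export
estimateEfficiency <- function(series, qcRange = c(1.85, 2.15)) {
  if (is.data.frame(series)) {
    gid <- if (!is.null(series$gene_id)) as.character(series$gene_id[1L])
           else "gene"
    series <- dilutionSeries(series$amount, series$cp, geneId = gid)
  }
  if (!methods::is(series, "DilutionSeries"))
    stop("'series' must be a DilutionSeries or data.frame", call. = FALSE)
  if (length(qcRange) != 2L || qcRange[1L] >= qcRange[2L])
    stop("'qcRange' must be an increasing pair", call. = FALSE)
  if (length(unique(series$amount)) < 3L)
    stop("at least 3 distinct input amounts are required", call. = FALSE)
  fit <- stats::lm(cp ~ log2(amount), data = as.data.frame(series))
  slope <- unname(stats::coef(fit)[2L])
  if (!is.finite(slope) || slope >= 0)
    stop(sprintf("non-amplifying series for gene '%s': CP does not ",
                 series@geneId),
         "decrease with input amount (slope >= 0)", call. = FALSE)
  E <- 2^(-1 / slope)
  ssTot <- sum((series$cp - mean(series$cp))^2)
  r2 <- if (ssTot > 0) 1 - sum(stats::residuals(fit)^2) / ssTot else 1
  out <- as(DataFrame(gene_id = series@geneId, slope = slope,
                      efficiency = E, r_squared = r2,
                      n_points = nrow(series),
                      qc_pass = E >= qcRange[1L] & E <= qcRange[2L]),
            "EfficiencyTable")
  validObject(out)
  out
}

#' Convert a crossing point to a log2 abundance (Ca)
#'
#' Applies the efficiency-calibrated transform Ca = -CP * log2(E), turning
#' a crossing point into a value proportional (on the log2 scale) to the
#' absolute template amount. Differences in Ca between samples or genes are
#' log2 fold changes.
#'
#' @param cp crossing point(s), cycles.
#' @param E per-cycle amplification factor(s), > 1; recycled against
#'   \code{cp}.
#' @return numeric Ca value(s).
#' @examples
#' cpToCa(20, 2)    # -20
#' cpToCa(20, 1.9)  # -18.52
#' @export
cpToCa <- function(cp, E) {
  if (!is.numeric(cp) || any(!is.finite(cp)))
    stop("'cp' must be finite numeric", call. = FALSE)
  if (!is.numeric(E) || any(!is.finite(E)) || any(E <= 1))
    stop("'E' must be finite and > 1", call. = FALSE)
  -cp * log2(E)
}

#' Average technical duplicates into a raw Ca matrix
#'
#' Converts every CP observation to the Ca scale with its gene-specific
#' efficiency and averages replicate runs per (sample, gene) cell
#' arithmetically on the Ca scale (downstream models are linear in Ca).
#' Duplicate runs whose CP values differ by more than
#' \code{discordanceLimit} cycles are flagged in the "discordant" assay and
#' warned about, but kept. Cells with no observations are explicit
#' \code{NA}.
#'
#' @param table a [CpTable-class].
#' @param efficiencies an [EfficiencyTable-class] (or a named numeric
#'   vector of per-gene E values) covering every gene in \code{table}.
#' @param discordanceLimit maximum tolerated CP spread between runs of one
#'   cell, cycles; default 1.5.
#' @param metadata optional sample metadata (data.frame or DataFrame with a
#'   \code{sample_id} column) attached as colData.
#' @return a raw (non-normalized) [CaExperiment-class].
#' @export
aggregateDuplicates <- function(table, efficiencies,
                                discordanceLimit = 1.5, metadata = NULL) {
  if (!methods::is(table, "CpTable")) table <- cpTable(table)
  if (methods::is(efficiencies, "EfficiencyTable")) {
    eff <- stats::setNames(efficiencies$efficiency, efficiencies$gene_id)
    qc <- efficiencies
  } else {
    eff <- efficiencies
    qc <- NULL
  }
  stopifnotScalarNumeric(discordanceLimit, "discordanceLimit")
  genes <- sort(unique(table$gene_id))
  missing_eff <- setdiff(genes, names(eff))
  if (length(missing_eff) > 0L)
    stop("no efficiency provided for gene(s): ",
         paste(missing_eff, collapse = ", "), call. = FALSE)
  if (!is.null(qc) && any(!qc$qc_pass))
    warning("efficiency QC failed for gene(s): ",
            paste(qc$gene_id[!qc$qc_pass], collapse = ", "),
            "; values computed anyway", call. = FALSE)
  samples <- unique(table$sample_id)
  ca <- matrix(NA_real_, nrow = length(genes), ncol = length(samples),
               dimnames = list(genes, samples))
  disc <- matrix(FALSE, nrow = length(genes), ncol = length(samples),
                 dimnames = list(genes, samples))
  caObs <- cpToCa(table$cp, eff[table$gene_id])
  grp <- paste(table$gene_id, table$sample_id, sep = "\r")
  means <- tapply(caObs, grp, mean)
  spread <- tapply(table$cp, grp, function(x) diff(range(x)))
  key <- strsplit(names(means), "\r", fixed = TRUE)
  gi <- vapply(key, `[`, "", 1L)
  si <- vapply(key, `[`, "", 2L)
  ca[cbind(gi, si)] <- as.numeric(means)
  disc[cbind(gi, si)] <- as.numeric(spread) > discordanceLimit
  if (any(disc))
    warning(sum(disc), " (sample, gene) cell(s) had duplicate runs more ",
            "than ", discordanceLimit, " cycles apart (kept, flagged)",
            call. = FALSE)
  colData <- NULL
  if (!is.null(metadata)) {
    metadata <- DataFrame(metadata)
    idx <- match(samples, metadata$sample_id)
    if (anyNA(idx))
      stop("metadata missing sample(s): ",
           paste(samples[is.na(idx)], collapse = ", "), call. = FALSE)
    colData <- metadata[idx, , drop = FALSE]
  }
  caExperiment(ca, colData = colData, normalized = FALSE,
               discordant = disc, efficiencies = qc)
}

#' Normalize Ca values against internal control genes
#'
#' Subtracts, per sample, the arithmetic mean of the control genes' Ca
#' values from every target gene's Ca. On the log2 scale this is identical
#' to dividing each gene's relative amount by the geometric mean of the
#' control genes' amounts, and it cancels per-sample template-loading
#' differences. Samples missing some (but not all) control genes are
#' normalized against the mean of the available ones, with a warning;
#' samples missing every control gene are an error.
#'
#' @param raw a raw [CaExperiment-class].
#' @param controlGenes character vector of control gene ids (>= 1),
#'   all present in \code{raw}.
#' @param keepControls if TRUE, control genes are themselves normalized
#'   against the control mean and kept in the output (useful for stability
#'   diagnostics); if FALSE (default) control genes are dropped from the
#'   normalized matrix.
#' @return a normalized [CaExperiment-class].
#' @export
normalizeCa <- function(raw, controlGenes, keepControls = FALSE) {
  if (!methods::is(raw, "CaExperiment"))
    stop("'raw' must be a CaExperiment", call. = FALSE)
  if (isNormalized(raw))
    stop("'raw' is already normalized", call. = FALSE)
  controlGenes <- as.character(controlGenes)
  if (length(controlGenes) < 1L)
    stop("at least one control gene is required", call. = FALSE)
  ca <- caValues(raw)
  absent <- setdiff(controlGenes, rownames(ca))
  if (length(absent) > 0L)
    stop("control gene(s) not in matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  ctrl <- ca[controlGenes, , drop = FALSE]
  nAvail <- colSums(!is.na(ctrl))
  if (any(nAvail == 0L))
    stop("sample(s) missing ALL control genes: ",
         paste(colnames(ca)[nAvail == 0L], collapse = ", "),
         call. = FALSE)
  if (any(nAvail < length(controlGenes)))
    warning("sample(s) missing some control genes; normalized against ",
            "the mean of the available ones: ",
            paste(colnames(ca)[nAvail < length(controlGenes)],
                  collapse = ", "), call. = FALSE)
  ctrlMean <- colMeans(ctrl, na.rm = TRUE)
  keep <- if (keepControls) rownames(ca)
          else setdiff(rownames(ca), controlGenes)
  norm <- sweep(ca[keep, , drop = FALSE], 2L, ctrlMean, "-")
  disc <- SummarizedExperiment::assays(raw)[["discordant"]]
  if (!is.null(disc)) disc <- disc[keep, , drop = FALSE]
  out <- caExperiment(norm, colData = SummarizedExperiment::colData(raw),
                      normalized = TRUE, controlGenes = controlGenes,
                      discordant = disc)
  SummarizedExperiment::rowData(out) <-
    SummarizedExperiment::rowData(raw)[keep, , drop = FALSE]
  out
}
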