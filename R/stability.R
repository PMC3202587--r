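#' Pairwise variation between two candidate reference genes
#'
#' The geNorm pairwise variation V for genes a and b is the sample standard
#' deviation (n - 1 denominator), across samples, of the per-sample log2
#' expression ratio Ca_a - Ca_b. Two genes that track each other perfectly
#' (constant ratio) have V = 0; per-sample loading factors cancel in the
#' difference and cannot inflate V.
#'
#' @param ca a raw [CaExperiment-class] or a genes x samples numeric
#'   matrix of Ca values.
#' @param geneA,geneB gene ids, both present in at least 3 common samples.
#' @return the pairwise variation V (log2 units).
#' @export
pairwiseVariation <- function(ca, geneA, geneB) {
  m <- if (methods::is(ca, "CaExperiment")) caValues(ca) else as.matrix(ca)
  for (g in c(geneA, geneB))
    if (!g %in% rownames(m))
      stop("gene not in matrix: ", g, call. = FALSE)
  d <- m[geneA, ] - m[geneB, ]
  d <- d[!is.na(d)]
  if (length(d) < 3L)
    stop(sprintf("genes '%s' and '%s' share fewer than 3 samples",
                 geneA, geneB), call. = FALSE)
  stats::sd(d)
}

#' geNorm stability value M for candidate reference genes
#'
#' M(g) is the arithmetic mean of the pairwise variations of g with every
#' other candidate. Lower M means the gene's log ratio with the rest of the
#' panel is more constant across samples, i.e. the gene is a more stable
#' normalizer.
#'
#' @param ca a raw [CaExperiment-class] or genes x samples matrix.
#' @param candidates character vector of >= 3 candidate gene ids.
#' @return named numeric vector of M values, one per candidate.
#' @export
genormM <- function(ca, candidates) {
  m <- if (methods::is(ca, "CaExperiment")) caValues(ca) else as.matrix(ca)
  candidates <- as.character(candidates)
  if (length(candidates) < 3L)
    stop("at least 3 candidate genes are required", call. = FALSE)
  absent <- setdiff(candidates, rownames(m))
  if (length(absent) > 0L)
    stop("candidate gene(s) not in matrix: ",
         paste(absent, collapse = ", "), call. = FALSE)
  n <- length(candidates)
  V <- matrix(0, n, n, dimnames = list(candidates, candidates))
  for (i in seq_len(n - 1L))
    for (j in seq.int(i + 1L, n)) {
      v <- pairwiseVariation(m, candidates[i], candidates[j])
      V[i, j] <- V[j, i] <- v
    }
  rowSums(V) / (n - 1L)
}

#' Iterative geNorm ranking of candidate reference genes
#'
#' Computes M over the current candidate set, excludes the gene with the
#' highest M (least stable), and repeats until two genes remain. Ties in
#' the maximum M are broken deterministically by lexicographic gene id.
#' Each gene's reported M is its value at the step where it was excluded;
#' the two survivors share the final two-gene M (pairwise variation is
#' symmetric for two genes).
#'
#' @inheritParams genormM
#' @return a [StabilityRanking-class].
#' @export
genormRank <- function(ca, candidates) {
  m <- if (methods::is(ca, "CaExperiment")) caValues(ca) else as.matrix(ca)
  candidates <- as.character(candidates)
  if (length(candidates) < 3L)
    stop("at least 3 candidate genes are required", call. = FALSE)
  current <- candidates
  M <- numeric(0)
  order <- character(0)
  steps <- list()
  while (length(current) > 2L) {
    Mi <- genormM(m, current)
    steps[[length(steps) + 1L]] <- Mi
    worstM <- max(Mi)
    worst <- sort(names(Mi)[Mi >= worstM - 1e-12])[1L]
    M[worst] <- Mi[[worst]]
    order <- c(order, worst)
    current <- setdiff(current, worst)
  }
  # final pair: both genes share the symmetric two-gene variation
  vFinal <- pairwiseVariation(m, current[1L], current[2L])
  survivors <- sort(current)
  steps[[length(steps) + 1L]] <- stats::setNames(rep(vFinal, 2L),
                                                 survivors)
  M[survivors] <- vFinal
  order <- c(order, survivors)
  out <- new("StabilityRanking", M = M, exclusionOrder = order,
             steps = steps)
  validObject(out)
  out
}

#' Residual variation of control genes across and within conditions
#'
#' Diagnoses how imperfect the chosen control genes are: after normalizing
#' the control genes against the mean of all of them, fits a
#' condition-means model per gene and reports (i) the fold by which the
#' gene is regulated across conditions, 2^(max condition mean - min
#' condition mean), and (ii) the fold by which it fluctuates within a
#' condition, 2^(sdMultiplier * pooled residual sd).
#'
#' @param ca a [CaExperiment-class] normalized against ALL candidate
#'   control genes with \code{keepControls = TRUE}, or a genes x samples
#'   matrix of such values.
#' @param condition per-sample condition labels (>= 2 conditions, >= 2
#'   samples each); if \code{ca} is a CaExperiment this may name a colData
#'   column.
#' @param genes genes to report; defaults to all rows of \code{ca}.
#' @param sdMultiplier multiplier k in 2^(k * sd) for the within-condition
#'   fold; default 1.
#' @return a [ControlVariationReport-class].
#' @export
controlVariation <- function(ca, condition, genes = NULL,
                             sdMultiplier = 1) {
  if (methods::is(ca, "CaExperiment")) {
    if (is.character(condition) && length(condition) == 1L &&
        condition %in% colnames(SummarizedExperiment::colData(ca)))
      condition <- SummarizedExperiment::colData(ca)[[condition]]
    m <- caValues(ca)
  } else m <- as.matrix(ca)
  condition <- factor(condition)
  if (length(condition) != ncol(m))
    stop("'condition' must have one label per sample", call. = FALSE)
  if (nlevels(condition) < 2L)
    stop("at least 2 conditions are required", call. = FALSE)
  if (any(table(condition) < 2L))
    stop("every condition needs at least 2 samples", call. = FALSE)
  if (is.null(genes)) genes <- rownames(m)
  stopifnotScalarNumeric(sdMultiplier, "sdMultiplier")
  rows <- lapply(genes, function(g) {
    y <- m[g, ]
    mu <- tapply(y, condition, mean, na.rm = TRUE)
    resid <- y - mu[condition]
    n <- sum(!is.na(resid))
    df <- n - nlevels(condition)
    pooledSd <- if (df > 0) sqrt(sum(resid^2, na.rm = TRUE) / df) else 0
    DataFrame(gene_id = g,
              between_condition_fold = 2^(max(mu) - min(mu)),
              within_condition_fold = 2^(sdMultiplier * pooledSd))
  })
  out <- as(do.call(rbind, rows), "ControlVariationReport")
  validObject(out)
  out
}
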