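#' Compute the two-gene Porites Stress Index
#'
#' D(s) = Ca(s, numerator) - Ca(s, denominator), evaluated on NON-normalized
#' Ca values. Because both genes are amplified from the same cDNA sample,
#' the per-sample template-loading factor cancels in the difference and no
#' internal control genes are needed. With the default pair (numerator
#' Hsp16, a strongly stress-induced small heat-shock protein; denominator
#' actin, stress-repressed), D is negative in unstressed corals and rises
#' toward or above zero under acute heat-light stress.
#'
#' @param rawCa a raw (non-normalized) [CaExperiment-class].
#' @param numerator,denominator gene ids of the index pair.
#' @return a [PsiResult-class]; samples missing either gene are omitted
#'   with a warning. Sample metadata columns are carried through.
#' @export
computePsi <- function(rawCa, numerator = "Hsp16",
                       denominator = "Actin") {
  if (!methods::is(rawCa, "CaExperiment"))
    stop("'rawCa' must be a CaExperiment", call. = FALSE)
  if (isNormalized(rawCa))
    stop("the stress index is defined on non-normalized Ca values",
         call. = FALSE)
  m <- caValues(rawCa)
  for (g in c(numerator, denominator))
    if (!g %in% rownames(m))
      stop("gene not in matrix: ", g, call. = FALSE)
  d <- m[numerator, ] - m[denominator, ]
  drop <- is.na(d)
  if (any(drop))
    warning(sum(drop), " sample(s) missing ", numerator, " or ",
            denominator, " omitted from the index", call. = FALSE)
  cd <- SummarizedExperiment::colData(rawCa)[!drop, , drop = FALSE]
  out <- DataFrame(sample_id = colnames(m)[!drop], psi = unname(d[!drop]))
  extra <- setdiff(colnames(cd), colnames(out))
  if (length(extra) > 0L) out <- cbind(out, cd[, extra, drop = FALSE])
  metadata(out)$numerator <- numerator
  metadata(out)$denominator <- denominator
  out <- as(out, "PsiResult")
  validObject(out)
  out
}

#' Compare the stress index between groups
#'
#' Fits the same model machinery as [fitGeneModel()] with the per-sample
#' index D as the response: a colony-random mixed model for paired designs,
#' colony and tank random intercepts for replicated tank designs, or a
#' plain two-group linear model for field-site comparisons (empty
#' \code{random}).
#'
#' @param psi a [PsiResult-class].
#' @param fixed one-sided formula of fixed factors (e.g.
#'   \code{~ treatment} or \code{~ site}).
#' @param random character vector of random-intercept columns; may be
#'   empty.
#' @param ... passed to [fitGeneModel()] (method, seed, level, ...).
#' @return an [EffectTable-class] (gene_id "PSI").
#' @export
comparePsi <- function(psi, fixed, random = character(), ...) {
  if (!methods::is(psi, "PsiResult"))
    stop("'psi' must be a PsiResult", call. = FALSE)
  d <- as.data.frame(psi)
  d$ca <- d$psi
  fitGeneModel(d, fixed = fixed, random = random, geneId = "PSI", ...)
}

#' PCA-based stress-marker selection
#'
#' Principal components analysis of the normalized Ca matrix (samples as
#' observations, genes as variables; centered, unscaled by default since
#' all genes already share the log2 scale). Returns per-component variance
#' fractions, unit-norm gene loadings and sample scores, and suggests a
#' two-gene assay: the pair of genes with the extreme positive and extreme
#' negative loadings on PC1. Principal-component signs are arbitrary; each
#' component is oriented so its largest-magnitude loading is positive,
#' making the reported loadings deterministic, and the selected pair is
#' invariant to sign flips in any case.
#'
#' @param normCa a [CaExperiment-class] (typically normalized) or a genes
#'   x samples matrix, restricted to the genes under consideration.
#' @param genes optional subset of genes to analyze.
#' @param scale scale variables to unit variance; default FALSE.
#' @return a [PcaResult-class].
#' @export
pcaMarkers <- function(normCa, genes = NULL, scale = FALSE) {
  m <- if (methods::is(normCa, "CaExperiment")) caValues(normCa)
       else as.matrix(normCa)
  if (!is.null(genes)) {
    absent <- setdiff(genes, rownames(m))
    if (length(absent) > 0L)
      stop("gene(s) not in matrix: ", paste(absent, collapse = ", "),
           call. = FALSE)
    m <- m[genes, , drop = FALSE]
  }
  if (nrow(m) < 2L || ncol(m) < 3L)
    stop("PCA needs at least 2 genes and 3 samples", call. = FALSE)
  x <- t(m)
  if (anyNA(x)) {
    keep <- stats::complete.cases(x)
    warning(sum(!keep), " sample(s) with missing values dropped from PCA",
            call. = FALSE)
    x <- x[keep, , drop = FALSE]
  }
  if (all(abs(sweep(x, 2L, colMeans(x), "-")) < 1e-12))
    stop("constant matrix: no variance to decompose", call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = scale)
  # orient each component so its largest-magnitude loading is positive
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rotation <- sweep(pc$rotation, 2L, flip, "*")
  scores <- sweep(pc$x, 2L, flip, "*")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  l1 <- rotation[, 1L]
  markers <- c(names(l1)[which.max(l1)], names(l1)[which.min(l1)])
  out <- new("PcaResult", varianceFraction = vf, loadings = rotation,
             scores = scores, markers = markers,
             markerLoadings = unname(c(max(l1), min(l1))),
             scaled = isTRUE(scale))
  validObject(out)
  out
}
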