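#' Read a CP table from CSV
#'
#' Expects comma-separated UTF-8 text with a header row and columns
#' \code{sample_id}, \code{gene_id}, \code{run_id}, \code{cp}. Rows whose
#' \code{cp} is missing or non-numeric are skipped with a warning that
#' reports their line numbers; duplicate (sample, gene, run) keys are an
#' error.
#'
#' @param path path to the CSV file.
#' @return a [CpTable-class].
#' @export
readCpTable <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  req <- c("sample_id", "gene_id", "run_id", "cp")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("CP table schema error, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  cp <- suppressWarnings(as.numeric(df$cp))
  bad <- is.na(cp) | !is.finite(cp) | cp <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing/invalid cp skipped (lines ",
            paste(utils::head(which(bad) + 1L, 10L), collapse = ", "),
            if (sum(bad) > 10L) ", ..." else "", ")", call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    cp <- cp[!bad]
  }
  df$cp <- cp
  cpTable(df)
}

#' Write a CP table to CSV
#'
#' @param x a [CpTable-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCpTable <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read dilution series from CSV
#'
#' Expects columns \code{gene_id}, \code{amount}, \code{cp}; returns one
#' [DilutionSeries-class] per gene.
#'
#' @param path path to the CSV file.
#' @return named list of [DilutionSeries-class] objects.
#' @export
readDilutionSeries <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "amount", "cp")
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("dilution series schema error, missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  parts <- split(df, df$gene_id)
  lapply(parts, function(p)
    dilutionSeries(p$amount, p$cp, geneId = p$gene_id[1L]))
}

#' Write dilution series to CSV
#'
#' @param series a [DilutionSeries-class] or a list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDilutionSeries <- function(series, path) {
  if (methods::is(series, "DilutionSeries")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s)
    data.frame(gene_id = s@geneId, amount = s$amount, cp = s$cp)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' Requires a \code{sample_id} column; other columns (colony, treatment,
#' timepoint, tank, site) are carried through as-is.
#'
#' @param path path to the CSV file.
#' @return a \code{DataFrame} keyed by sample_id.
#' @export
readMetadata <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(df))
    stop("metadata schema error, missing column: sample_id",
         call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata", call. = FALSE)
  out <- DataFrame(df)
  rownames(out) <- df$sample_id
  out
}

#' Write a Ca matrix to CSV
#'
#' Samples as rows, genes as columns. The first line is a comment header
#' recording the normalized flag and control genes, so the file
#' round-trips through [readCaMatrix()] without losing that state.
#'
#' @param ca a [CaExperiment-class].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCaMatrix <- function(ca, path) {
  if (!methods::is(ca, "CaExperiment"))
    stop("'ca' must be a CaExperiment", call. = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# normalized: %s; controls: %s",
                     isNormalized(ca),
                     paste(controlGenes(ca), collapse = ";")), con)
  m <- t(caValues(ca))
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a Ca matrix written by [writeCaMatrix()]
#'
#' @param path path to the CSV file.
#' @return a [CaExperiment-class].
#' @export
readCaMatrix <- function(path) {
  first <- readLines(path, n = 1L)
  normalized <- FALSE
  controls <- character()
  skip <- 0L
  if (startsWith(first, "#")) {
    skip <- 1L
    normalized <- grepl("normalized: TRUE", first, fixed = TRUE)
    ctl <- sub(".*controls: *", "", first)
    if (nzchar(ctl))
      controls <- strsplit(ctl, ";", fixed = TRUE)[[1L]]
  }
  df <- utils::read.csv(path, skip = skip, check.names = FALSE,
                        stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1L, drop = FALSE]))
  colnames(m) <- df$sample_id
  caExperiment(m, normalized = normalized, controlGenes = controls)
}
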