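#' Gene-wise mixed-model differential expression
#'
#' Fits a linear mixed model to one gene's (normalized) Ca values with the
#' requested fixed factors and random intercepts, and returns every
#' non-intercept fixed-effect estimate as a log2 effect size B with fold
#' change 2^|B|, a confidence interval, and a p-value.
#'
#' Inference methods:
#' \describe{
#'   \item{\code{"auto"} (default)}{balanced paired two-level designs with
#'     a single random factor and one observation per (group, level) cell
#'     use the exact paired-difference t-test, whose point estimate equals
#'     the REML mixed-model fixed effect; every other design falls through
#'     to \code{"satterthwaite"}.}
#'   \item{\code{"satterthwaite"}}{REML fit via \pkg{lmerTest} with
#'     Satterthwaite denominator degrees of freedom; Wald t intervals.}
#'   \item{\code{"pb"}}{seeded parametric-bootstrap likelihood-ratio test:
#'     each fixed term is dropped in turn, \code{nsim} response vectors are
#'     simulated from the reduced fit, and the p-value is the bootstrap
#'     tail probability of the observed LRT statistic. Point estimates and
#'     intervals come from the REML fit.}
#' }
#' Responses with zero residual variance (noise-free fixtures) would
#' degenerate any mixed-model fit; they short-circuit to exact arithmetic:
#' B is recovered by least squares with the grouping factors as fixed
#' blocks, the interval collapses to the point and p is reported as 0.
#' Singular (boundary) variance-component fits are flagged, not errors.
#'
#' @param data a data.frame with the response column \code{ca} plus the
#'   design columns.
#' @param fixed one-sided formula of fixed factors, e.g. \code{~ treatment}
#'   or \code{~ timepoint + timepoint:treatment} (the latter estimates the
#'   treatment contrast separately at each timepoint).
#' @param random character vector of random-intercept grouping columns
#'   (e.g. \code{"colony"}, or \code{c("colony", "tank")}); may be empty,
#'   in which case an ordinary linear model is fitted.
#' @param method inference method, see Details.
#' @param nsim parametric-bootstrap draws (method "pb"), default 1000.
#' @param seed seed for the parametric bootstrap; required for "pb".
#' @param level confidence level, default 0.95.
#' @param geneId label carried into the result.
#' @return an [EffectTable-class], one row per fixed-effect coefficient.
#' @seealso [fitGeneModels()] for the whole-panel screen with FDR control,
#'   [comparePsi()] for the same machinery on the stress index.
#' @export
fitGeneModel <- function(data, fixed, random = "colony",
                         method = c("auto", "satterthwaite", "pb"),
                         nsim = 1000, seed = NULL, level = 0.95,
                         geneId = "gene") {
  method <- match.arg(method)
  data <- as.data.frame(data)
  if (!"ca" %in% names(data))
    stop("'data' must contain a response column 'ca'", call. = FALSE)
  fvars <- all.vars(fixed)
  missing_cols <- setdiff(c(fvars, random), names(data))
  if (length(missing_cols) > 0L)
    stop("design column(s) not in data: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  data <- data[!is.na(data$ca), , drop = FALSE]
  for (v in c(fvars, random)) data[[v]] <- factor(data[[v]])
  for (v in fvars)
    if (nlevels(data[[v]]) < 2L)
      stop(sprintf("fixed factor '%s' has a single observed level", v),
           call. = FALSE)

  # zero-residual-variance short circuit: exact arithmetic
  blockForm <- stats::reformulate(c(random, attr(stats::terms(fixed),
                                                 "term.labels")),
                                  response = "ca")
  ols <- stats::lm(blockForm, data = data)
  if (stats::sigma(ols) < 1e-8) {
    cf <- stats::coef(ols)
    keep <- fixedCoefNames(fixed, data)
    cf <- cf[names(cf) %in% keep]
    return(effectRows(geneId, names(cf), unname(cf), unname(cf),
                      unname(cf), rep(0, length(cf)),
                      method = "exact-zero-variance", flag = "exact"))
  }

  if (method == "auto") {
    if (isBalancedPaired(data, fixed, random))
      return(exactPairedFit(data, fixed, random, level, geneId))
    method <- "satterthwaite"
  }
  if (length(random) == 0L)
    return(fixedOnlyFit(data, fixed, level, geneId))
  if (method == "satterthwaite")
    return(satterthwaiteFit(data, fixed, random, level, geneId))
  pbFit(data, fixed, random, nsim, seed, level, geneId)
}

#' Fit the gene-wise model across a whole panel
#'
#' Runs [fitGeneModel()] for every gene of a (normalized)
#' [CaExperiment-class] and applies Benjamini-Hochberg FDR adjustment
#' across genes, separately per fixed-effect term (the correction spans
#' the gene panel of one experiment, not the terms of one gene).
#'
#' @param ca a [CaExperiment-class]; design columns are taken from
#'   colData.
#' @param genes genes to fit; default all rows.
#' @inheritParams fitGeneModel
#' @param ... passed on to [fitGeneModel()].
#' @return an [EffectTable-class] with the FDR-adjusted column
#'   \code{p_adj} filled in.
#' @export
fitGeneModels <- function(ca, fixed, random = "colony", genes = NULL,
                          ...) {
  if (!methods::is(ca, "CaExperiment"))
    stop("'ca' must be a CaExperiment", call. = FALSE)
  m <- caValues(ca)
  cd <- as.data.frame(SummarizedExperiment::colData(ca))
  if (is.null(genes)) genes <- rownames(m)
  res <- lapply(genes, function(g) {
    d <- cbind(ca = m[g, ], cd)
    fitGeneModel(d, fixed = fixed, random = random, geneId = g, ...)
  })
  out <- do.call(rbind, lapply(res, function(x) as(x, "DFrame")))
  for (tm in unique(out$term)) {
    i <- out$term == tm
    out$p_adj[i] <- adjustFdr(out$p[i])
  }
  out <- as(out, "EffectTable")
  validObject(out)
  out
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values with monotonicity enforcement, controlling the
#' expected false-discovery proportion when discoveries are declared at
#' \code{p_adj <= alpha}.
#'
#' @param pvals numeric vector of nominal p-values in [0, 1]; NA entries
#'   are passed through.
#' @return adjusted p-values, same length and order as the input.
#' @examples
#' adjustFdr(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjustFdr <- function(pvals) {
  if (!is.numeric(pvals))
    stop("'pvals' must be numeric", call. = FALSE)
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(pvals, method = "BH")
}

#' Fold change of a log2 effect size
#'
#' @param B log2 effect size(s).
#' @return a data.frame with \code{B}, \code{fold} = 2^|B| and
#'   \code{direction} ("up" for B > 0, "down" for B < 0, "none" at 0), so
#'   that B = -2 reads as "4-fold down".
#' @examples
#' foldChange(c(9.644, -2, 0))
#' @export
foldChange <- function(B) {
  if (!is.numeric(B) || any(!is.finite(B)))
    stop("'B' must be finite numeric", call. = FALSE)
  data.frame(B = B, fold = 2^abs(B),
             direction = ifelse(B > 0, "up", ifelse(B < 0, "down",
                                                    "none")))
}

## ---- internal fitting helpers ------------------------------------------

# coefficient names the fixed part of the design generates (no intercept)
fixedCoefNames <- function(fixed, data) {
  mm <- stats::model.matrix(fixed, data = data)
  setdiff(colnames(mm), "(Intercept)")
}

effectRows <- function(geneId, term, B, ciLow, ciHigh, p,
                       method, flag = "") {
  fc <- foldChange(B)
  out <- as(DataFrame(gene_id = geneId, term = term, B = B,
                      fold = fc$fold, direction = fc$direction,
                      ci_low = ciLow, ci_high = ciHigh, p = p,
                      p_adj = NA_real_, method = method, flag = flag),
            "EffectTable")
  validObject(out)
  out
}

# TRUE when the design is a two-level single-fixed-factor paired layout:
# one random grouping factor, every group observed exactly once per level
isBalancedPaired <- function(data, fixed, random) {
  if (length(random) != 1L) return(FALSE)
  tl <- attr(stats::terms(fixed), "term.labels")
  if (length(tl) != 1L || grepl(":", tl, fixed = TRUE)) return(FALSE)
  f <- data[[tl]]
  if (nlevels(f) != 2L) return(FALSE)
  tab <- table(data[[random]], f)
  all(tab == 1L)
}

# exact paired-difference t-test; point estimate identical to the REML
# mixed-model treatment effect on this layout
exactPairedFit <- function(data, fixed, random, level, geneId) {
  tl <- attr(stats::terms(fixed), "term.labels")
  f <- data[[tl]]
  g <- data[[random]]
  lev <- levels(f)
  y1 <- data$ca[f == lev[1L]][order(g[f == lev[1L]])]
  y2 <- data$ca[f == lev[2L]][order(g[f == lev[2L]])]
  d <- y2 - y1
  n <- length(d)
  B <- mean(d)
  se <- stats::sd(d) / sqrt(n)
  tstat <- B / se
  df <- n - 1L
  p <- 2 * stats::pt(-abs(tstat), df)
  q <- stats::qt(1 - (1 - level) / 2, df)
  effectRows(geneId, paste0(tl, lev[2L]), B, B - q * se, B + q * se, p,
             method = "exact-paired")
}

lmerQuiet <- function(formula, data, useLmerTest = TRUE) {
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  fitfun <- if (useLmerTest) lmerTest::lmer else lme4::lmer
  withCallingHandlers(
    suppressMessages(fitfun(formula, data = data, REML = TRUE,
                            control = ctrl)),
    warning = function(w) {
      if (grepl("boundary|singular|converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
}

mixedFormula <- function(fixed, random) {
  rhs <- c(attr(stats::terms(fixed), "term.labels"),
           paste0("(1 | ", random, ")"))
  stats::reformulate(rhs, response = "ca")
}

satterthwaiteFit <- function(data, fixed, random, level, geneId) {
  fit <- lmerQuiet(mixedFormula(fixed, random), data)
  sm <- stats::coef(summary(fit))
  keep <- rownames(sm) != "(Intercept)"
  sm <- sm[keep, , drop = FALSE]
  q <- stats::qt(1 - (1 - level) / 2, sm[, "df"])
  flag <- if (lme4::isSingular(fit)) "boundary" else ""
  effectRows(geneId, rownames(sm), sm[, "Estimate"],
             sm[, "Estimate"] - q * sm[, "Std. Error"],
             sm[, "Estimate"] + q * sm[, "Std. Error"],
             sm[, "Pr(>|t|)"], method = "satterthwaite", flag = flag)
}

# ordinary linear model when the design has no random factors (field data)
fixedOnlyFit <- function(data, fixed, level, geneId) {
  fit <- stats::lm(stats::update(fixed, ca ~ .), data = data)
  sm <- stats::coef(summary(fit))
  keep <- rownames(sm) != "(Intercept)"
  sm <- sm[keep, , drop = FALSE]
  q <- stats::qt(1 - (1 - level) / 2, stats::df.residual(fit))
  effectRows(geneId, rownames(sm), sm[, "Estimate"],
             sm[, "Estimate"] - q * sm[, "Std. Error"],
             sm[, "Estimate"] + q * sm[, "Std. Error"],
             sm[, "Pr(>|t|)"], method = "lm")
}

# seeded parametric-bootstrap likelihood-ratio test, term by term
pbFit <- function(data, fixed, random, nsim, seed, level, geneId) {
  if (is.null(seed))
    stop("method 'pb' requires an explicit 'seed'", call. = FALSE)
  full <- lmerQuiet(mixedFormula(fixed, random), data,
                    useLmerTest = FALSE)
  est <- satterthwaiteFit(data, fixed, random, level, geneId)
  terms <- attr(stats::terms(fixed), "term.labels")
  seeds <- deriveSeeds(seed, length(terms))
  pByTerm <- stats::setNames(rep(NA_real_, length(terms)), terms)
  for (k in seq_along(terms)) {
    remaining <- terms[-k]
    rhs <- c(if (length(remaining) > 0L) remaining else "1",
             paste0("(1 | ", random, ")"))
    reduced <- lmerQuiet(stats::reformulate(rhs, response = "ca"), data,
                         useLmerTest = FALSE)
    mlLik <- function(fit)
      stats::logLik(withCallingHandlers(
        suppressMessages(lme4::refitML(fit)),
        warning = function(w) {
          if (grepl("boundary|singular|converge", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }))
    obs <- as.numeric(2 * (mlLik(full) - mlLik(reduced)))
    sims <- withSeed(seeds[k], {
      ysim <- stats::simulate(reduced, nsim = nsim)
      vapply(ysim, function(y) {
        d2 <- data
        d2$ca <- y
        f2 <- tryCatch(lmerQuiet(mixedFormula(fixed, random), d2,
                                 useLmerTest = FALSE),
                       error = function(e) NULL)
        r2 <- tryCatch(lmerQuiet(stats::reformulate(rhs,
                                                    response = "ca"),
                                 d2, useLmerTest = FALSE),
                       error = function(e) NULL)
        if (is.null(f2) || is.null(r2)) return(NA_real_)
        as.numeric(2 * (mlLik(f2) - mlLik(r2)))
      }, numeric(1))
    })
    sims <- sims[is.finite(sims)]
    pByTerm[k] <- (1 + sum(sims >= obs - 1e-10)) / (1 + length(sims))
  }
  # map term-level bootstrap p-values onto the term's coefficients
  assign_ <- attr(stats::model.matrix(fixed, data = data), "assign")
  coefTerm <- terms[assign_[assign_ > 0L]]
  df <- as(est, "DFrame")
  df$p <- unname(pByTerm[coefTerm])
  df$method <- "pb-lrt"
  out <- as(df, "EffectTable")
  validObject(out)
  out
}
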