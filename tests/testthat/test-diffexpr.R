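test_that("BH adjustment matches hand-derived step-up values", {
  # m = 4, sorted p * m / rank = (.04, .04, .04, .04)
  expect_equal(adjustFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjustFdr(0.03), 0.03)              # single p unchanged
  expect_equal(adjustFdr(rep(0.2, 5)), rep(0.2, 5)) # m/m factor
  # step-up with monotonicity enforcement, worked by hand:
  # sorted (.005,.01,.2,.9) * 4/rank = (.02,.02,.2667,.9)
  expect_equal(adjustFdr(c(0.9, 0.005, 0.2, 0.01)),
               c(0.9, 0.02, 4 * 0.2 / 3, 0.02))
  expect_error(adjustFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(adjustFdr(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("BH adjustment is order-preserving and idempotent", {
  set.seed(21)
  p <- runif(30)
  a <- adjustFdr(p)
  expect_true(all(a >= p))
  expect_true(all(diff(a[order(p)]) >= 0))  # ranking preserved
  # fixed points of the step-up procedure (constant sequences) are
  # unchanged by re-adjustment
  expect_equal(adjustFdr(rep(0.04, 4)), rep(0.04, 4))
  expect_equal(adjustFdr(rep(0.2, 7)), rep(0.2, 7))
})

test_that("fold changes report magnitude and direction", {
  fc <- foldChange(c(0, -2, 9.644))
  expect_equal(fc$fold, c(1, 4, 2^9.644))
  expect_equal(fc$fold[3], 800, tolerance = 1e-3)
  expect_identical(fc$direction, c("none", "down", "up"))
  expect_error(foldChange(Inf), "finite")
})

test_that("zero-residual-variance data short-circuits to exact arithmetic", {
  colony <- rep(paste0("c", 1:4), each = 2)
  treatment <- rep(c("control", "stress"), 4)
  ce <- c(0.3, -0.1, 0.5, 0)
  d <- data.frame(ca = ce[as.integer(factor(colony))] +
                    ifelse(treatment == "stress", 2.5, 0),
                  colony = colony, treatment = treatment)
  fit <- fitGeneModel(d, ~ treatment, "colony")
  expect_equal(fit$B, 2.5, tolerance = 1e-10)
  expect_equal(fit$p, 0)
  expect_identical(fit$method, "exact-zero-variance")
  expect_equal(fit$ci_low, fit$ci_high)
})

test_that("the REML mixed-model paired estimate equals the paired-difference mean", {
  for (seed in 1:4) {
    d <- pairedData(b = 1.7, nColony = 6, sd = 0.4, seed = seed)
    oracle <- mean(d$ca[d$treatment == "stress"] -
                   d$ca[d$treatment == "control"])
    sat <- fitGeneModel(d, ~ treatment, "colony",
                        method = "satterthwaite")
    expect_equal(sat$B, oracle, tolerance = 1e-8)
    # the fast exact-paired path gives the same estimate and exact df
    ex <- fitGeneModel(d, ~ treatment, "colony", method = "auto")
    expect_identical(ex$method, "exact-paired")
    expect_equal(ex$B, oracle, tolerance = 1e-12)
    t0 <- t.test(d$ca[d$treatment == "stress"][order(
                   d$colony[d$treatment == "stress"])],
                 d$ca[d$treatment == "control"][order(
                   d$colony[d$treatment == "control"])],
                 paired = TRUE)
    expect_equal(ex$p, t0$p.value, tolerance = 1e-10)
  }
})

test_that("treatment contrasts are translation-invariant", {
  d <- pairedData(b = 0.8, nColony = 5, sd = 0.3, seed = 9)
  d2 <- d
  d2$ca <- d2$ca + 100
  for (m in c("auto", "satterthwaite")) {
    f1 <- fitGeneModel(d, ~ treatment, "colony", method = m)
    f2 <- fitGeneModel(d2, ~ treatment, "colony", method = m)
    expect_equal(f1$B, f2$B, tolerance = 1e-6)
  }
})

test_that("degenerate designs raise informative errors", {
  d <- pairedData(b = 1, seed = 2)
  d1 <- d[d$treatment == "control", ]
  expect_error(fitGeneModel(d1, ~ treatment, "colony"),
               "single observed level")
  expect_error(fitGeneModel(d[, -1], ~ treatment, "colony"),
               "response column")
  expect_error(fitGeneModel(d, ~ treatment + site, "colony"), "site")
})

test_that("unbalanced designs with a missing arm still fit", {
  set.seed(31)
  cfg <- presetScenario("exp4", seed = 31)
  sim <- simulateExperiment(cfg)
  raw <- quantifyTrue(sim, cfg)
  d <- data.frame(ca = caValues(raw)["Hsp16", ],
                  as.data.frame(SummarizedExperiment::colData(raw)))
  fit <- suppressWarnings(
    fitGeneModel(d, ~ treatment, c("colony", "tank")))
  expect_equal(nrow(fit), 1L)
  expect_true(is.finite(fit$B) && is.finite(fit$p))
})

test_that("the parametric bootstrap is seeded and reproducible", {
  d <- pairedData(b = 2.2, nColony = 6, sd = 0.4, seed = 5)
  expect_error(fitGeneModel(d, ~ treatment, "colony", method = "pb"),
               "seed")
  f1 <- fitGeneModel(d, ~ treatment, "colony", method = "pb",
                     nsim = 99, seed = 77)
  f2 <- fitGeneModel(d, ~ treatment, "colony", method = "pb",
                     nsim = 99, seed = 77)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$method, "pb-lrt")
  # a 2.2-log2 effect at residual sd 0.4 is decisively significant
  expect_lt(f1$p, 0.05)
  # the REML point estimate is unchanged by the inference method
  sat <- fitGeneModel(d, ~ treatment, "colony",
                      method = "satterthwaite")
  expect_equal(f1$B, sat$B, tolerance = 1e-6)
})

test_that("panel-wide screening adjusts FDR across genes per term", {
  set.seed(41)
  m <- matrix(rnorm(40, -2, 0.5), 4, 10,
              dimnames = list(paste0("g", 1:4),
                              sprintf("s%02d", 1:10)))
  meta <- data.frame(sample_id = colnames(m),
                     colony = rep(paste0("c", 1:5), each = 2),
                     treatment = rep(c("control", "stress"), 5))
  m["g1", meta$treatment == "stress"] <-
    m["g1", meta$treatment == "stress"] + 4
  ca <- makeCaExp(m, meta = meta, normalized = TRUE, controls = "x")
  et <- fitGeneModels(ca, ~ treatment, "colony")
  expect_equal(nrow(et), 4L)
  expect_equal(et$p_adj, adjustFdr(et$p))
  expect_true(all(et$p_adj >= et$p))
  expect_lt(et$p_adj[et$gene_id == "g1"], 0.05)
})
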