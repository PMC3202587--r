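test_that("dilution simulation produces the exact noise-free ladder", {
  s <- simulateDilutionSeries(2, cpAtMax = 15, nPoints = 7,
                              foldStep = 2, noiseSd = 0)
  expect_equal(s$cp, 15:21)            # one cycle per doubling
  expect_equal(s$amount, 5 / 2^(0:6))
  # noise-free round trip at a non-ideal efficiency
  s2 <- simulateDilutionSeries(1.9, noiseSd = 0)
  expect_equal(estimateEfficiency(s2)$efficiency, 1.9,
               tolerance = 1e-10)
  # a fold step of 4 costs log(4)/log(E) cycles per step
  s3 <- simulateDilutionSeries(2, cpAtMax = 10, nPoints = 4,
                               foldStep = 4, noiseSd = 0)
  expect_equal(diff(s3$cp), rep(2, 3))
})

test_that("dilution simulation validates its arguments", {
  expect_error(simulateDilutionSeries(1, noiseSd = 0), "> 1")
  expect_error(simulateDilutionSeries(2, nPoints = 2), ">= 3")
  expect_error(simulateDilutionSeries(2, foldStep = 1), "> 1")
  expect_error(simulateDilutionSeries(2, maxAmount = -1), "> 0")
  expect_error(simulateDilutionSeries(2, noiseSd = 0.1), "seed")
})

test_that("noisy efficiency recovery is unbiased over many seeds", {
  Es <- vapply(1:500, function(i)
    estimateEfficiency(simulateDilutionSeries(
      2, noiseSd = 0.15, seed = i))$efficiency, numeric(1))
  mcse <- sd(Es) / sqrt(length(Es))
  expect_lt(abs(mean(Es) - 2), 3 * mcse + 1e-3)
})

test_that("identical config and seed give bit-identical CP tables", {
  cfg <- presetScenario("exp1", seed = 5)
  s1 <- simulateExperiment(cfg)
  s2 <- simulateExperiment(cfg)
  expect_identical(s1$cp$cp, s2$cp$cp)
  expect_identical(as.data.frame(s1$metadata),
                   as.data.frame(s2$metadata))
  s3 <- simulateExperiment(cfg, seed = 6)
  expect_false(identical(s1$cp$cp, s3$cp$cp))
})

test_that("the degenerate zero-noise, zero-effect model is constant", {
  cfg <- zeroNoiseConfig("exp1", nullEffects = TRUE)
  sim <- simulateExperiment(cfg)
  raw <- quantifyTrue(sim, cfg)
  norm <- normalizeCa(raw, c("RPL11", "EIF3H", "ND5"))
  m <- caValues(norm)
  expect_true(all(abs(m - m[, 1]) < 1e-10))   # identical across samples
  psi <- computePsi(raw)
  expect_true(all(abs(psi$psi - psi$psi[1]) < 1e-10))
})

test_that("loading factors cancel in normalized Ca and in the index", {
  cfg <- zeroNoiseConfig("exp1", nullEffects = TRUE)
  cfg@variance["loading_sd"] <- 1.5
  sim <- simulateExperiment(cfg)
  raw <- quantifyTrue(sim, cfg)
  expect_gt(sd(caValues(raw)["ADK", ]), 0.1)  # raw Ca varies
  norm <- normalizeCa(raw, c("RPL11", "EIF3H", "ND5"))
  m <- caValues(norm)
  expect_true(all(abs(m - m[, 1]) < 1e-10))   # normalized does not
  psi <- computePsi(raw)
  expect_true(all(abs(psi$psi - psi$psi[1]) < 1e-10))
})

test_that("zero-noise CP tables round-trip to abundance + loading", {
  cfg <- zeroNoiseConfig("exp1")
  cfg@variance["loading_sd"] <- 1
  sim <- simulateExperiment(cfg)
  raw <- quantifyTrue(sim, cfg)
  want <- t(trueAbundance(sim$truth)) +
    rep(loadingFactors(sim$truth), each = nrow(raw))
  expect_equal(caValues(raw), want[rownames(raw), ],
               tolerance = 1e-12)
})

test_that("colony effects are per-gene unless the shared switch is on", {
  cfg <- presetScenario("exp1", seed = 3)
  s <- simulateExperiment(cfg)
  ce <- s$truth@colonyEffects
  expect_false(isTRUE(all.equal(ce[, 1], ce[, 2])))
  cfg@sharedColony <- TRUE
  s2 <- simulateExperiment(cfg)
  ce2 <- s2$truth@colonyEffects
  expect_equal(ce2[, 1], ce2[, 2])
})

test_that("preset exp1 encodes the headline stress effects", {
  cfg <- presetScenario("exp1")
  eff <- as.data.frame(cfg@effects)
  get <- function(g) eff$effect[eff$gene_id == g & eff$cell == "stress"]
  expect_equal(get("Hsp16"), log2(800))
  expect_equal(get("Hsp16"), 9.64, tolerance = 1e-3)
  expect_equal(get("Actin"), -2)        # 4-fold down
  expect_equal(get("C3"), -log2(6))     # 6-fold down
  expect_equal(get("Chrom"), 1)         # 2-fold up
  expect_equal(cfg@nColonies, 5L)
  expect_equal(nrow(cfg@genes), 13L)    # 8 targets + 5 control candidates
  expect_equal(sum(cfg@genes$role == "control"), 5L)
})

test_that("preset exp2 is a paired factorial with stress and recovery effects", {
  cfg <- presetScenario("exp2")
  expect_equal(cfg@nColonies, 8L)       # parameterizable sample size
  expect_equal(presetScenario("exp2", nColonies = 12)@nColonies, 12L)
  eff <- as.data.frame(cfg@effects)
  get <- function(g, cell)
    sum(eff$effect[eff$gene_id == g & eff$cell == cell])
  expect_equal(get("Hsp16", "heat:stress"), log2(700))
  expect_equal(get("Hsp16", "heat:recovery"), 3)   # 8-fold
  expect_equal(get("Hsp60", "heat:stress"), 2)     # 4-fold
  expect_equal(get("Hsp90", "heat:stress"), log2(6))
  sim <- simulateExperiment(cfg)
  tab <- table(sim$metadata$treatment, sim$metadata$timepoint)
  expect_true(all(tab == 8))            # one fragment per colony per cell
})

test_that("preset exp4 is unbalanced with a colony missing its heat arm", {
  cfg <- presetScenario("exp4", seed = 2)
  sim <- simulateExperiment(cfg)
  meta <- as.data.frame(sim$metadata)
  tab <- table(meta$colony, meta$treatment)
  expect_equal(tab["colony05", "heat"], 0L)    # missing treatment arm
  expect_gt(tab["colony05", "control"], 0L)
  expect_true(all(tab[paste0("colony0", 1:4), ] >= 1 &
                  tab[paste0("colony0", 1:4), ] <= 3))
  expect_equal(length(unique(meta$tank)), 6L)  # 3 tanks per treatment
})

test_that("the field preset samples nine inshore and seven offshore colonies", {
  cfg <- presetScenario("field")
  sim <- simulateExperiment(cfg)
  expect_equal(as.vector(table(sim$metadata$site)[c("inshore",
                                                    "offshore")]),
               c(9L, 7L))
  eff <- as.data.frame(cfg@effects)
  expect_equal(eff$effect[eff$gene_id == "Hsp16" &
                          eff$cell == "inshore"], 2)
  expect_error(presetScenario("exp9"), "arg")
})

test_that("null scenarios zero every fixed effect", {
  cfg <- presetScenario("exp1", nullEffects = TRUE)
  expect_true(all(cfg@effects$effect == 0))
})

test_that("scenario validation catches inconsistent configurations", {
  gp <- genePanel(c("a", "b"))
  expect_error(scenarioConfig("x", gp, nColonies = 2,
                              effects = data.frame(gene_id = "zz",
                                                   cell = "stress",
                                                   effect = 1)),
               "unknown gene")
  expect_error(scenarioConfig("x", gp, nColonies = 2,
                              variance = c(bogus_sd = 1)),
               "unknown variance")
  expect_error(genePanel(c("a", "a")), "unique")
  expect_error(genePanel("a", true_efficiency = 0.9), "> 1")
})
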