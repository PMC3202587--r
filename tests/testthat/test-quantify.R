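test_that("efficiency estimation reproduces closed-form values", {
  # perfect doubling: CP drops one cycle per doubling of input
  s <- dilutionSeries(amount = 5 / 2^(0:6), cp = 15:21, geneId = "g")
  e <- estimateEfficiency(s)
  expect_equal(e$slope, -1)
  expect_equal(e$efficiency, 2)
  expect_equal(e$r_squared, 1)
  expect_true(e$qc_pass)

  # constructed slope of -1.1 gives E = 2^(1/1.1)
  amt <- 5 / 2^(0:6)
  s2 <- dilutionSeries(amt, cp = 10 - 1.1 * log2(amt), geneId = "g")
  e2 <- estimateEfficiency(s2)
  expect_equal(e2$efficiency, 2^(1 / 1.1), tolerance = 1e-10)
  expect_equal(e2$efficiency, 1.878, tolerance = 1e-3)
  expect_true(e2$qc_pass)

  # an efficiency outside the accepted range is flagged, not rejected
  s3 <- dilutionSeries(amt, cp = 10 - 1.5 * log2(amt), geneId = "g")
  expect_false(estimateEfficiency(s3)$qc_pass)
})

test_that("efficiency estimation rejects degenerate series", {
  amt <- 5 / 2^(0:4)
  # CP increasing with input amount cannot come from amplification
  expect_error(estimateEfficiency(dilutionSeries(amt, cp = 19:15)),
               "non-amplifying")
  expect_error(dilutionSeries(c(5, 5, 5), c(15, 15, 15)),
               "distinct")
  expect_error(estimateEfficiency(
    dilutionSeries(c(5, 5, 2.5, 2.5), c(15, 15.1, 16, 16.1))),
    "3 distinct")
})

test_that("efficiency is invariant to rescaling all input amounts", {
  amt <- 5 / 1.7^(0:5)
  cp <- 12 - 1.05 * log2(amt)
  e1 <- estimateEfficiency(dilutionSeries(amt, cp))
  e2 <- estimateEfficiency(dilutionSeries(amt * 137.5, cp))
  expect_equal(e1$slope, e2$slope, tolerance = 1e-10)
  expect_equal(e1$efficiency, e2$efficiency, tolerance = 1e-10)
})

test_that("cpToCa applies Ca = -CP * log2(E)", {
  expect_identical(cpToCa(20, 2), -20)
  expect_equal(cpToCa(20, 1.9), -18.520, tolerance = 1e-4)
  expect_identical(cpToCa(0, 1.9), 0)
  expect_error(cpToCa(20, 1), "> 1")
  expect_error(cpToCa(20, 0.9), "> 1")
  expect_error(cpToCa(NA_real_, 2), "finite")

  # strictly decreasing in cp, and in E for fixed cp > 0
  cps <- seq(5, 35, by = 5)
  expect_true(all(diff(cpToCa(cps, 1.95)) < 0))
  Es <- seq(1.5, 2.15, by = 0.05)
  expect_true(all(diff(cpToCa(20, Es)) < 0))
})

test_that("duplicate runs average on the Ca scale with discordance flags", {
  cp <- cpTable(data.frame(
    sample_id = c("s1", "s1", "s2", "s3", "s3"),
    gene_id = "g1",
    run_id = c(1, 2, 1, 1, 2),
    cp = c(20, 21, 18, 10, 12)))
  expect_warning(
    ca <- aggregateDuplicates(cp, c(g1 = 2), discordanceLimit = 1.5),
    "1.5 cycles")
  m <- caValues(ca)
  expect_equal(m["g1", "s1"], -20.5)       # mean of -20 and -21
  expect_equal(m["g1", "s2"], -18)         # single run, its own Ca
  disc <- SummarizedExperiment::assays(ca)[["discordant"]]
  expect_false(disc["g1", "s1"])           # 1 cycle apart: within limit
  expect_true(disc["g1", "s3"])            # 2 cycles apart: flagged, kept
  expect_equal(m["g1", "s3"], -11)
})

test_that("aggregation demands an efficiency per gene and keeps gaps", {
  cp <- cpTable(data.frame(sample_id = c("s1", "s1"),
                           gene_id = c("g1", "g2"), run_id = 1,
                           cp = c(20, 22)))
  expect_error(aggregateDuplicates(cp, c(g1 = 2)), "g2")
  cp2 <- cpTable(data.frame(sample_id = c("s1", "s1", "s2"),
                            gene_id = c("g1", "g2", "g1"), run_id = 1,
                            cp = c(20, 22, 19)))
  m <- caValues(aggregateDuplicates(cp2, c(g1 = 2, g2 = 2)))
  expect_true(is.na(m["g2", "s2"]))        # explicit missing cell
})

test_that("control-gene normalization subtracts the per-sample control mean", {
  m <- rbind(t = c(-5, -7), c1 = c(-10, -9), c2 = c(-12, -11),
             c3 = c(-14, -13))
  norm <- normalizeCa(makeCaExp(m), c("c1", "c2", "c3"))
  expect_equal(unname(caValues(norm)["t", ]), c(7, 4))
  expect_true(isNormalized(norm))
  expect_identical(controlGenes(norm), c("c1", "c2", "c3"))
})

test_that("normalization cancels per-sample loading shifts", {
  set.seed(42)
  m <- matrix(rnorm(24, -12), 6, 4,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:4)))
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 3
  n1 <- caValues(normalizeCa(makeCaExp(m), c("g1", "g2")))
  n2 <- caValues(normalizeCa(makeCaExp(shifted), c("g1", "g2")))
  expect_equal(n1[, 2], n2[, 2], tolerance = 1e-12)
})

test_that("normalization equals the exponentiate-geomean-relog oracle", {
  # the log2-scale arithmetic-mean subtraction is mathematically the
  # geometric-mean normalization of the absolute amounts
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(rnorm(40, -12, 3), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:5)))
    ctl <- c("g1", "g4", "g7")
    got <- caValues(normalizeCa(makeCaExp(m), ctl))
    q <- 2^m
    geo <- apply(q[ctl, ], 2, function(x) exp(mean(log(x))))
    want <- log2(sweep(q[setdiff(rownames(m), ctl), ], 2, geo, "/"))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("normalized control genes average exactly zero per sample", {
  set.seed(8)
  m <- matrix(rnorm(30, -12), 5, 6,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
  ctl <- c("g2", "g3", "g5")
  kept <- normalizeCa(makeCaExp(m), ctl, keepControls = TRUE)
  ctlMeans <- colMeans(caValues(kept)[ctl, ])
  expect_equal(unname(ctlMeans), rep(0, 6), tolerance = 1e-12)
})

test_that("normalization errors and warnings follow the missing-data policy", {
  m <- rbind(t = c(-5, -6), c1 = c(-10, NA), c2 = c(-12, NA))
  expect_error(normalizeCa(makeCaExp(m), c("c1", "c2")), "ALL control")
  m2 <- rbind(t = c(-5, -6), c1 = c(-10, -9), c2 = c(-12, NA))
  expect_warning(norm <- normalizeCa(makeCaExp(m2), c("c1", "c2")),
                 "some control")
  expect_equal(unname(caValues(norm)["t", 2]), -6 - (-9))
  expect_error(normalizeCa(makeCaExp(m2), character()), "at least one")
  expect_error(normalizeCa(makeCaExp(m2), "nope"), "not in matrix")
})
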