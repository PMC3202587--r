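# brute-force geNorm oracle: explicit double loop over pairs and samples
bruteM <- function(m, cands) {
  M <- numeric(0)
  for (g in cands) {
    vs <- numeric(0)
    for (k in cands) {
      if (k == g) next
      ratios <- numeric(0)
      for (s in seq_len(ncol(m)))
        ratios <- c(ratios, m[g, s] - m[k, s])
      vs <- c(vs, stats::sd(ratios))
    }
    M[g] <- mean(vs)
  }
  M
}

caFixture3 <- function() {
  m <- rbind(g1 = c(0, 1, 2, 3),
             g2 = c(0, 1, 2, 3) + 1,
             g3 = c(0, 2, 1, 3))
  colnames(m) <- paste0("s", 1:4)
  m
}

test_that("pairwise variation is the sd of the per-sample log ratio", {
  m <- caFixture3()
  expect_equal(pairwiseVariation(m, "g1", "g2"), 0)
  expect_equal(pairwiseVariation(m, "g1", "g3"), sd(c(0, -1, 1, 0)))
  expect_equal(pairwiseVariation(m, "g1", "g3"), 0.8165,
               tolerance = 1e-4)
  # per-sample loading constants cancel
  load <- c(2, -1, 0.5, 4)
  m2 <- sweep(m, 2, load, "+")
  expect_equal(pairwiseVariation(m2, "g1", "g3"),
               pairwiseVariation(m, "g1", "g3"), tolerance = 1e-12)
  expect_error(pairwiseVariation(m[, 1:2], "g1", "g3"), "fewer than 3")
  expect_error(pairwiseVariation(m, "g1", "gX"), "not in matrix")
})

test_that("genormM matches the hand-computed 3-gene example", {
  M <- genormM(caFixture3(), c("g1", "g2", "g3"))
  v <- sd(c(0, -1, 1, 0))
  expect_equal(unname(M), c(v / 2, v / 2, v), tolerance = 1e-12)
  expect_equal(unname(M), c(0.408, 0.408, 0.8165), tolerance = 1e-3)
  # all pairwise constant offsets: perfectly stable panel
  m0 <- rbind(a = 1:5, b = 1:5 + 2, c = 1:5 - 1)
  colnames(m0) <- paste0("s", 1:5)
  expect_equal(unname(genormM(m0, c("a", "b", "c"))), c(0, 0, 0))
  # permuting candidate order leaves values unchanged
  M2 <- genormM(caFixture3(), c("g3", "g1", "g2"))
  expect_equal(M[sort(names(M))], M2[sort(names(M2))])
})

test_that("genormM agrees with the brute-force double-loop oracle", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rnorm(80, -12, 2), 10, 8,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
    cands <- sample(rownames(m), 6)
    expect_equal(genormM(m, cands), bruteM(m, cands),
                 tolerance = 1e-10)
  }
})

test_that("M is invariant to per-sample loading constants", {
  set.seed(12)
  m <- matrix(rnorm(50, -12), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  m2 <- sweep(m, 2, rnorm(10, 0, 5), "+")
  expect_equal(genormM(m, rownames(m)), genormM(m2, rownames(m2)),
               tolerance = 1e-10)
})

test_that("iterative ranking excludes the least stable gene first", {
  r <- genormRank(caFixture3(), c("g1", "g2", "g3"))
  expect_identical(exclusionOrder(r)[1], "g3")
  expect_setequal(names(stabilityM(r)), c("g1", "g2", "g3"))
  # survivors share the symmetric two-gene value
  expect_equal(stabilityM(r)[["g1"]], stabilityM(r)[["g2"]])
  expect_equal(stabilityM(r)[["g1"]], 0)
})

test_that("ranking ties break deterministically by gene id", {
  # two interchangeable noisy genes against one stable pair
  m <- rbind(a = c(0, 0, 0, 0), b = c(0, 0, 0, 0),
             zb = c(0, 1, -1, 0), za = c(0, -1, 1, 0))
  colnames(m) <- paste0("s", 1:4)
  r <- genormRank(m, rownames(m))
  # za and zb have identical M at every step; lexicographic order decides
  expect_identical(exclusionOrder(r)[1:2], c("za", "zb"))
})

test_that("an independently noisy gene is excluded first almost always", {
  set.seed(13)
  hits <- 0L
  for (i in 1:200) {
    m <- matrix(rnorm(40, 0, 0.3), 5, 8,
                dimnames = list(c("a", "b", "c", "d", "noisy"),
                                paste0("s", 1:8)))
    m["noisy", ] <- rnorm(8, 0, 1.5)
    r <- genormRank(m, rownames(m))
    if (exclusionOrder(r)[1] == "noisy") hits <- hits + 1L
  }
  expect_gte(hits / 200, 0.95)
})

test_that("control variation reports between/within condition folds", {
  cond <- rep(c("A", "B"), each = 4)
  # zero noise, zero effect: both folds exactly 1
  m0 <- matrix(-12, 2, 8, dimnames = list(c("g1", "g2"),
                                          paste0("s", 1:8)))
  r0 <- controlVariation(m0, cond)
  expect_equal(r0$between_condition_fold, c(1, 1))
  expect_equal(r0$within_condition_fold, c(1, 1))

  # configured condition shift of 0.3 log2 units, no residual noise
  m1 <- m0
  m1["g1", cond == "B"] <- -12 + 0.3
  r1 <- controlVariation(m1, cond)
  expect_equal(r1$between_condition_fold[1], 2^0.3, tolerance = 1e-12)
  expect_equal(r1$between_condition_fold[1], 1.231, tolerance = 1e-3)

  # symmetric +w/-w residuals: condition means stay 0 and the pooled
  # residual sd is w * sqrt(8 / 6); choose w so it equals 0.9
  w <- 0.9 * sqrt(6 / 8)
  m2 <- m0
  m2["g2", ] <- -12 + rep(c(w, -w), 4)
  pooled <- sqrt(sum((m2["g2", ] + 12)^2) / (8 - 2))
  expect_equal(pooled, 0.9, tolerance = 1e-12)
  r2 <- controlVariation(m2, cond)
  expect_equal(r2$within_condition_fold[2], 2^pooled, tolerance = 1e-10)
  # and 2^0.9 is about the 1.87-fold fluctuation scale
  expect_equal(2^0.9, 1.866, tolerance = 1e-3)

  # sd multiplier is configurable
  r3 <- controlVariation(m2, cond, sdMultiplier = 2)
  expect_equal(r3$within_condition_fold[2], (2^pooled)^2,
               tolerance = 1e-8)

  expect_error(controlVariation(m0, rep("A", 8)), "2 conditions")
  expect_error(controlVariation(m0[, 1:3], c("A", "A", "B")),
               "at least 2 samples")
})
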