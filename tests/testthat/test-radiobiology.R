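make_records <- function(doses, colonies, plated = 1000, rep_id = "s1") {
  data.frame(cell_line = "L", condition = "c", replicate = rep_id,
             dose_gy = doses, cells_plated = plated, colonies = colonies)
}

test_that("survival fractions normalize to per-stratum plating efficiency", {
  rec <- make_records(c(0, 4), c(200, 50))
  sf <- survivalFraction(rec)
  expect_equal(sf$pe, c(0.2, 0.2))
  expect_equal(sf$sf[sf$dose_gy == 0], 1)
  expect_equal(sf$sf[sf$dose_gy == 4], 0.25)

  expect_error(survivalFraction(make_records(c(2, 4), c(100, 50))),
               "NoControlDose")
  expect_error(survivalFraction(make_records(c(0, 4), c(0, 10))),
               "ZeroControlColonies")

  # random counts match hand computation; SF(0) = 1 in every stratum
  set.seed(12)
  rec <- do.call(rbind, lapply(c("s1", "s2"), function(s)
    make_records(c(0, 2, 4, 6), rbinom(4, 1000, c(0.3, 0.2, 0.1, 0.04)),
                 rep_id = s)))
  sf <- survivalFraction(rec)
  for (s in c("s1", "s2")) {
    g <- rec[rec$replicate == s, ]
    pe <- g$colonies[g$dose_gy == 0] / 1000
    expect_equal(sf$sf[sf$replicate == s], (g$colonies / 1000) / pe)
  }
  expect_true(all(sf$sf[sf$dose_gy == 0] == 1))
})

test_that("LQ fit inverts noiseless survival exactly and flags bad input", {
  doses <- c(0, 2, 4, 6)
  sf <- data.frame(stratum = "s1", dose_gy = doses,
                   sf = exp(-(0.2 * doses + 0.05 * doses^2)))
  fit <- fitLQ(sf)
  expect_equal(fit@alpha, 0.2, tolerance = 1e-10)
  expect_equal(fit@beta, 0.05, tolerance = 1e-10)
  expect_equal(predictSF(fit, doses), sf$sf, tolerance = 1e-10)

  flat <- data.frame(stratum = "s1", dose_gy = doses, sf = 1)
  fit0 <- fitLQ(flat)
  expect_equal(fit0@alpha, 0, tolerance = 1e-12)
  expect_equal(fit0@beta, 0, tolerance = 1e-12)

  expect_error(fitLQ(sf[sf$dose_gy < 4, ]), "TooFewDoses")
  bad <- sf; bad$sf[2] <- 0
  expect_error(fitLQ(bad), "NonPositiveSF")
})

test_that("LQ fit is invariant to scaling colony counts within a stratum", {
  set.seed(33)
  rec <- make_records(c(0, 2, 4, 6), c(400, 250, 120, 40), plated = 2000)
  f1 <- fitLQ(survivalFraction(rec))
  rec2 <- rec; rec2$colonies <- rec2$colonies * 2  # e.g. double plating yield
  f2 <- fitLQ(survivalFraction(rec2))
  expect_equal(f1@alpha, f2@alpha, tolerance = 1e-12)
  expect_equal(f1@beta, f2@beta, tolerance = 1e-12)
})

test_that("LQ recovery within 15% on binomial colony data at the assay design", {
  spec <- synthSpec()
  clono <- genClonogenic(spec)
  fit <- fitLQ(survivalFraction(clono))
  expect_lt(abs(fit@alpha - spec@clonogenic$alpha) / spec@clonogenic$alpha,
            0.15)
  expect_lt(abs(fit@beta - spec@clonogenic$beta) / spec@clonogenic$beta, 0.15)
})

test_that("exact Mann-Whitney p equals wilcox.test enumeration on tie-free data", {
  set.seed(8)
  for (rep in 1:12) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    x <- rnorm(n1); y <- rnorm(n2, 0.5)
    got <- mannWhitneyTest(x, y)
    ref <- wilcox.test(x, y, exact = TRUE, correct = FALSE)
    expect_equal(got$U, unname(ref$statistic))
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
    expect_identical(got$method, "exact enumeration")
  }
  # fully tied data: identical groups are indistinguishable, p = 1
  tied <- mannWhitneyTest(rep(1, 4), rep(1, 5))
  expect_equal(tied$p, 1)
  # documented small example: complete separation of 3 vs 3
  sep <- mannWhitneyTest(c(0.5, 0.6, 0.55), c(1.0, 1.1, 0.95))
  expect_equal(sep$U, 0)
  expect_equal(sep$p, 2 / choose(6, 3))  # 2 of 20 assignments as extreme
})

test_that("large samples fall back to the tie-corrected normal approximation", {
  set.seed(9)
  x <- rnorm(15); y <- rnorm(12, 0.8)
  got <- mannWhitneyTest(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_identical(got$method, "normal approximation")
  expect_equal(got$p, ref$p.value, tolerance = 1e-9)
})

test_that("enhancement ratios divide matched survival fractions", {
  doses <- c(0, 2, 4, 6)
  mk <- function(sfs) data.frame(replicate = rep(c("r1", "r2"), each = 4),
                                 dose_gy = rep(doses, 2), sf = sfs)
  ctrl <- mk(rep(exp(-(0.2 * doses + 0.05 * doses^2)), 2))
  trt <- mk(rep(exp(-(0.35 * doses + 0.05 * doses^2)), 2))
  er <- enhancementRatio(trt, ctrl)
  expect_true(all(er$ratio < 1))  # radiosensitization
  expect_equal(er$ratio[er$dose_gy == 2][1], exp(-0.3), tolerance = 1e-12)

  # treated identical to control: all ratios 1 and p = 1 by symmetry
  er1 <- enhancementRatio(ctrl, ctrl)
  expect_true(all(er1$ratio == 1))
  expect_equal(compareEnhancement(er1, er1)$p, 1)

  missing <- ctrl[ctrl$dose_gy != 4, ]
  expect_error(enhancementRatio(trt, missing), "DoseMismatch")
})

test_that("foci counts normalize by nuclear area with per-condition summary", {
  out <- fociPerNucleus(10, 100)
  expect_equal(out$values, 0.1)
  z <- fociPerNucleus(c(0, 0, 0), c(50, 60, 70))
  expect_equal(z$values, c(0, 0, 0))
  set.seed(14)
  n <- 12
  cts <- rpois(n, 8); areas <- runif(n, 50, 150)
  cond <- rep(c("gln+", "gln-"), each = 6)
  out <- fociPerNucleus(cts, areas, cond)
  expect_equal(out$values, cts / areas)
  expect_equal(out$summary$mean[out$summary$condition == "gln-"],
               mean((cts / areas)[cond == "gln-"]))
  expect_error(fociPerNucleus(c(1, 2), c(1, 0)), "ZeroArea")
  expect_error(fociPerNucleus(c(1, 2), c(1, 2, 3)), "LengthMismatch")
})
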