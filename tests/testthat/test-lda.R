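test_that("hemiellipsoid tumor volume follows (L*W*H)/2", {
  expect_equal(tumorVolume(10, 10, 10), 500)
  expect_equal(tumorVolume(5, 0, 7), 0)
  expect_error(tumorVolume(-1, 2, 3), "NegativeDimension")
  set.seed(3)
  d <- runif(3, 1, 20)
  expect_equal(tumorVolume(d[1], d[2], d[3]), prod(d) / 2)
})

test_that("single-dose LDA reproduces the analytic closed form", {
  tab <- data.frame(dose_cells = 1000, n_tested = 6, n_positive = 3)
  fit <- fitLDA(tab)
  expect_equal(fit@frequency, -log(1 - 0.5) / 1000, tolerance = 1e-8)
  expect_equal(fit@frequency, 6.931e-4, tolerance = 1e-4)
  expect_equal(fit@status, "ok")
  expect_true(fit@lower < fit@frequency && fit@frequency < fit@upper)
})

test_that("multi-dose MLE agrees with brute-force grid search", {
  tab <- data.frame(dose_cells = c(100, 1000, 10000), n_tested = 6,
                    n_positive = c(0, 3, 6))
  fit <- fitLDA(tab)
  # independent two-stage grid oracle over log(f)
  ll_of <- function(f) {
    pneg <- exp(-f * tab$dose_cells)
    sum((tab$n_tested - tab$n_positive) * (-f * tab$dose_cells) +
        tab$n_positive * log1p(-pneg + (tab$n_positive == 0)))
  }
  grid <- exp(seq(log(1e-6), log(1e-1), length.out = 10001))
  f1 <- grid[which.max(vapply(grid, ll_of, numeric(1)))]
  fine <- exp(seq(log(f1) - 0.01, log(f1) + 0.01, length.out = 10001))
  f_grid <- fine[which.max(vapply(fine, ll_of, numeric(1)))]
  expect_lt(abs(fit@frequency - f_grid) / f_grid, 1e-4)
  expect_gte(fit@logLik, ll_of(f_grid) - 1e-8)

  fmt <- ldaFrequency(fit)
  expect_equal(fmt$oneIn, ceiling(1 / fit@frequency))
  expect_equal(fmt$percent, 100 * fit@frequency)
})

test_that("degenerate take tables yield one-sided likelihood bounds", {
  neg <- data.frame(dose_cells = c(100, 1000), n_tested = 6, n_positive = 0)
  fn <- fitLDA(neg)
  expect_identical(fn@status, "all_negative")
  expect_true(is.na(fn@frequency))
  expect_equal(fn@lower, 0)
  # upper bound where the log-likelihood drops qchisq(.95,1)/2 below 0
  expect_equal(-fn@upper * sum(neg$n_tested * neg$dose_cells),
               -qchisq(0.95, 1) / 2, tolerance = 1e-6)

  pos <- data.frame(dose_cells = c(1000, 10000), n_tested = 6,
                    n_positive = 6)
  fp <- fitLDA(pos)
  expect_identical(fp@status, "all_positive")
  expect_true(is.na(fp@frequency))
  expect_equal(fp@upper, 1)
  expect_gt(fp@lower, 0)
})

test_that("group comparison LRT is zero for identical tables, positive otherwise", {
  tab <- data.frame(dose_cells = c(100, 1000, 10000), n_tested = 6,
                    n_positive = c(1, 3, 6))
  same <- compareLDA(tab, tab)
  expect_equal(same$statistic, 0, tolerance = 1e-8)
  expect_equal(same$p, 1, tolerance = 1e-6)

  tab2 <- data.frame(dose_cells = c(100, 1000, 10000), n_tested = 6,
                     n_positive = c(0, 1, 3))
  diff <- compareLDA(tab, tab2)
  expect_gte(diff$statistic, 0)
  expect_lt(diff$p, 1)

  # a degenerate group enters via its boundary likelihood
  degen <- data.frame(dose_cells = 100, n_tested = 6, n_positive = 0)
  res <- compareLDA(tab, degen)
  expect_gte(res$statistic, 0)
  # malformed tables propagate their errors
  bad <- data.frame(dose_cells = 100, n_tested = 6, n_positive = 7)
  expect_error(compareLDA(tab, bad), "n_positive")
})

test_that("well-separated frequencies are detected in most seeded simulations", {
  # f = 1/100 vs 1/10000, 6 implants per dose: power check over 60 runs
  hits <- 0
  for (s in 1:60) {
    spec <- synthSpec(seed = 5000L + s,
                      lda = list(frequencies = c(hi = 1e-2, lo = 1e-4),
                                 doses = c(100, 1000, 10000), nTested = 6L))
    tab <- genLda(spec)
    a <- tab[tab$group == "hi", ]
    b <- tab[tab$group == "lo", ]
    ok <- tryCatch(compareLDA(a, b)$p < 0.05, error = function(e) NA)
    if (isTRUE(ok)) hits <- hits + 1
  }
  expect_gte(hits / 60, 0.9)
})

test_that("tumor take analysis thresholds, censors and matches hand log-rank", {
  days <- c(7, 14, 21)
  mk <- function(animal, group, v) data.frame(
    animal = animal, group = group, day = days,
    length_mm = (2 * v)^(1/3), width_mm = (2 * v)^(1/3),
    height_mm = (2 * v)^(1/3))
  # group A: takes at day 14 and 21; group B: one take at 21, one censored
  g <- rbind(mk("a1", "A", c(20, 150, 400)), mk("a2", "A", c(10, 50, 120)),
             mk("b1", "B", c(5, 20, 110)), mk("b2", "B", c(1, 2, 4)))
  res <- tumorTakeAnalysis(g, threshold = 100)
  takes <- res$takes[order(res$takes$animal), ]
  expect_equal(takes$time, c(14, 21, 21, 21))
  expect_equal(takes$event, c(1L, 1L, 1L, 0L))

  hand <- logrank_bruteforce(takes$time, takes$event, takes$group)
  expect_equal(res$chisq, hand, tolerance = 1e-9)

  # identical groups: statistic 0, p = 1
  g2 <- rbind(mk("a1", "A", c(20, 150, 400)), mk("a2", "A", c(5, 20, 110)),
              mk("b1", "B", c(20, 150, 400)), mk("b2", "B", c(5, 20, 110)))
  res2 <- tumorTakeAnalysis(g2, threshold = 100)
  expect_equal(res2$chisq, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-9)

  expect_error(tumorTakeAnalysis(g[g$group == "A", ]), "EmptyGroup")
})

test_that("KM estimate matches the hand product-limit computation", {
  time <- c(5, 8, 8, 12, 20, 25)
  event <- c(1, 1, 0, 1, 1, 0)
  g <- data.frame(animal = paste0("m", 1:6),
                  group = rep(c("A", "B"), 3), day = time,
                  volume_mm3 = ifelse(event == 1, 200, 50))
  res <- tumorTakeAnalysis(g, threshold = 100)
  km <- survival::survfit(survival::Surv(time, event) ~ 1,
                          data = res$takes)
  hand <- km_bruteforce(res$takes$time, res$takes$event)
  got <- summary(km, times = hand$time)
  expect_equal(got$surv, hand$surv, tolerance = 1e-12)
})
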