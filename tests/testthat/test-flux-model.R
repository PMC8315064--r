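test_that("flux sets enforce nonnegativity and the VGLS >= VGDH constraint", {
  fs <- fluxSet(25, 15, 20, 12, 60)
  expect_equal(vGluOut(fs), 10)
  expect_equal(vOaaOut(fs), 15)
  expect_equal(glsTcaRatio(fs), 1.25)
  expect_error(fluxSet(10, 15, 20, 12, 60), "InfeasibleFluxes")
  expect_error(fluxSet(-1, 0, 1, 1, 1), "nonnegative")
})

test_that("reaction wiring balances every pool for random feasible fluxes", {
  set.seed(31)
  for (rep in 1:20) {
    v <- runif(5, 0, 50)
    v[1] <- v[2] + runif(1, 0, 20)  # VGLS >= VGDH
    fs <- fluxSet(v[1], v[2], v[3], v[4], v[5])
    bal <- glnflux:::.pool_balance(fs)
    expect_equal(bal$inflow, bal$outflow, tolerance = 1e-12)
  }
})

test_that("driving function interpolates, extrapolates constantly, forces t=0", {
  tc <- MIDTimeCourse("GLN", c(10, 30),
                      list(MID(c(0.5, 0, 0, 0, 0, 0.5), 5),
                           MID(c(0.1, 0, 0, 0, 0, 0.9), 5)))
  drv <- drivingFunction(tc)
  expect_equal(drv@times[1], 0)
  expect_equal(midAt(drv, 0)[1, ], c(1, 0, 0, 0, 0, 0))     # forced M0 start
  expect_equal(midAt(drv, 20)[1, 6], 0.7)                   # linear midpoint
  expect_equal(midAt(drv, 500)[1, ], midAt(drv, 30)[1, ])   # constant tail
  expect_equal(rowSums(midAt(drv, c(0, 5, 17, 200))), rep(1, 4))
})

test_that("zero fluxes freeze all pools unlabeled", {
  model <- quick_model()
  sim <- simulateLabeling(model, fluxSet(0, 0, 0, 0, 0), c(0, 10, 30, 90))
  for (p in c("GLU", "AKG", "SUC", "MAL", "OAA", "CIT", "HCO3"))
    for (m in sim[[p]]@mids)
      expect_equal(fractions(m)[1], 1, tolerance = 1e-8)
})

test_that("citrate M+6 appears only through IDH exchange with bicarbonate", {
  model <- quick_model()
  sim0 <- simulateLabeling(model, fluxSet(25, 15, 20, 0, 60), c(0, 10, 30, 90))
  m6 <- vapply(sim0$CIT@mids, function(m) fractions(m)[7], numeric(1))
  expect_true(all(m6 <= 1e-9))
  simr <- simulateLabeling(model, fluxSet(25, 15, 20, 12, 60), c(10, 30, 90))
  m6r <- vapply(simr$CIT@mids, function(m) fractions(m)[7], numeric(1))
  expect_true(all(m6r > 1e-6))
})

test_that("first-turn labeling gives M5 glutamate and M4 malate/citrate", {
  model <- quick_model()
  sim <- simulateLabeling(model, fluxSet(25, 15, 20, 0, 60), c(0, 10, 30, 90))
  last <- function(p) fractions(sim[[p]]@mids[[4]])
  glu <- last("GLU"); mal <- last("MAL"); cit <- last("CIT")
  expect_equal(unname(which.max(glu[-1])), 5)  # M+5 dominates labeled glutamate
  expect_equal(unname(which.max(mal[-1])), 4)  # M+4 dominates labeled malate
  expect_equal(unname(which.max(cit[-1])), 4)  # M+4 dominates labeled citrate
})

test_that("MID validity and the enrichment bound hold along trajectories", {
  model <- quick_model()
  sim <- simulateLabeling(model, fluxSet(25, 15, 20, 12, 60),
                          seq(0, 90, by = 5))
  drv_enr_max <- max(vapply(seq(0, 90, by = 5), function(t)
    sum((0:5) * midAt(model@driving, t)[1, ]) / 5, numeric(1)))
  for (p in c("GLU", "AKG", "SUC", "MAL", "OAA", "CIT", "HCO3")) {
    for (m in sim[[p]]@mids) {
      expect_true(all(fractions(m) >= 0))
      expect_equal(sum(fractions(m)), 1, tolerance = 1e-6)
      expect_lte(fractionalEnrichment(m), 1)
      # no pool can exceed the driving enrichment (HCO3 only dilutes here)
      expect_lte(fractionalEnrichment(m), drv_enr_max + 1e-6)
    }
  }
})

test_that("aspartate mirrors oxaloacetate", {
  model <- quick_model()
  sim <- simulateLabeling(model, fluxSet(25, 15, 20, 12, 60), c(10, 90))
  expect_equal(lapply(sim$ASP@mids, fractions),
               lapply(sim$OAA@mids, fractions))
})

test_that("glutamate approaches the driving enrichment exponentially when
           downstream fluxes vanish", {
  spec <- quick_spec()
  # constant fully-labeled driving from t = 0
  drv <- new("DrivingFunction", times = c(0, 90),
             fractions = matrix(c(0, 0, 0, 0, 0, 0, 1, 1, 0, 0, 0, 0),
                                nrow = 2)[, c(1, 3, 4, 5, 6, 2)])
  drv@fractions <- matrix(rep(c(0, 0, 0, 0, 0, 1), each = 2), nrow = 2)
  model <- buildFluxModel(spec@concentrations, drv)
  vgls <- 20
  sim <- simulateLabeling(model, fluxSet(vgls, 0, 0, 0, 0), c(0, 10, 30, 90))
  enr <- vapply(sim$GLU@mids, fractionalEnrichment, numeric(1))
  # closed form: single pool fed at VGLS, m5(t) = 1 - exp(-VGLS t / C)
  expected <- 1 - exp(-vgls * c(0, 10, 30, 90) / spec@concentrations["GLU"])
  expect_equal(enr, unname(expected), tolerance = 1e-6)
})

test_that("jointly halving concentrations and fluxes leaves labeling unchanged", {
  spec <- quick_spec()
  drv <- synthDrivingTimecourse(spec)
  m1 <- buildFluxModel(spec@concentrations, drv)
  m2 <- buildFluxModel(spec@concentrations / 2, drv)
  f1 <- fluxSet(25, 15, 20, 12, 60)
  f2 <- fluxSet(12.5, 7.5, 10, 6, 30)
  s1 <- simulateLabeling(m1, f1, c(10, 30, 90))
  s2 <- simulateLabeling(m2, f2, c(10, 30, 90))
  for (p in c("GLU", "MAL", "CIT", "HCO3"))
    expect_equal(lapply(s1[[p]]@mids, fractions),
                 lapply(s2[[p]]@mids, fractions), tolerance = 1e-6)
})

test_that("steady-state concentrations average over time points", {
  tab <- data.frame(metabolite = rep(c("GLU", "AKG"), each = 4),
                    time_min = rep(c(0, 10, 30, 90), 2),
                    concentration_um = c(10, 20, 30, 40, 5, 5, 5, 5))
  out <- steadyStateConcentrations(tab)
  expect_equal(out[["GLU"]], 25)
  expect_equal(out[["AKG"]], 5)
  expect_error(steadyStateConcentrations(tab[, 1:2]), "MissingPool")
  set.seed(41)
  tab$concentration_um <- runif(8, 1, 100)
  out <- steadyStateConcentrations(tab)
  expect_equal(out[["GLU"]], mean(tab$concentration_um[1:4]))
})

test_that("replicate fits average arithmetically, ratios as mean of ratios", {
  f <- fluxSet(2, 1, 1, 0.5, 3)
  est <- averageReplicateFits(list(f, f, f))
  expect_equal(fluxes(est@meanFluxes), fluxes(f))
  expect_equal(est@meanGlsTcaRatio, 2)

  fs <- list(fluxSet(1, 0.5, 1, 0, 1), fluxSet(2, 1, 2, 0, 1),
             fluxSet(3, 1.5, 3, 0, 1))
  est <- averageReplicateFits(fs)
  expect_equal(unname(fluxes(est@meanFluxes)["VTCA"]), 2)
  expect_equal(est@meanGlsTcaRatio, 1)  # each replicate ratio is 1
  # brute-force mean over random triples
  set.seed(17)
  fs <- lapply(1:3, function(i) {
    v <- runif(5, 1, 10); v[1] <- v[2] + 1
    fluxSet(v[1], v[2], v[3], v[4], v[5])
  })
  est <- averageReplicateFits(fs)
  expect_equal(fluxes(est@meanFluxes),
               rowMeans(vapply(fs, fluxes, numeric(5))))
  expect_error(averageReplicateFits(list()), "EmptyInput")
})

test_that("model construction rejects missing pools and infeasible fits", {
  spec <- quick_spec()
  drv <- synthDrivingTimecourse(spec)
  expect_error(buildFluxModel(spec@concentrations[-2], drv),
               "MissingPoolConcentration")
  model <- buildFluxModel(spec@concentrations, drv)
  sim <- simulateLabeling(model, spec@fluxes, c(0, 10, 30))
  expect_error(
    fitFluxes(model, list(GLU = sim$GLU)), "two target pools")
  short <- MIDTimeCourse("GLU", 10, list(MID(c(1, 0, 0, 0, 0, 0), 5)))
  expect_error(fitFluxes(model, list(GLU = short, MAL = short)),
               "TooFewTimePoints")
})
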