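#' Construct a FluxSet
#'
#' @param VGLS,VGDH,VTCA,VIDHr,VCO2dil nonnegative fluxes, uM/min per 5e5
#'   cells; \code{VGLS >= VGDH} is required (glutaminase output cannot be
#'   less than the glutamate drawn into oxidation).
#' @return a \linkS4class{FluxSet}.
#' @export
fluxSet <- function(VGLS, VGDH, VTCA, VIDHr, VCO2dil) {
  new("FluxSet", VGLS = as.numeric(VGLS), VGDH = as.numeric(VGDH),
      VTCA = as.numeric(VTCA), VIDHr = as.numeric(VIDHr),
      VCO2dil = as.numeric(VCO2dil))
}

#' @rdname FluxSet
#' @export
setMethod("fluxes", "FluxSet", function(x)
  c(VGLS = x@VGLS, VGDH = x@VGDH, VTCA = x@VTCA, VIDHr = x@VIDHr,
    VCO2dil = x@VCO2dil))

#' @rdname vGluOut
#' @export
setMethod("vGluOut", "FluxSet", function(x) x@VGLS - x@VGDH)

#' @rdname vGluOut
#' @export
setMethod("vOaaOut", "FluxSet", function(x) x@VGDH)

#' @rdname vGluOut
#' @export
setMethod("glsTcaRatio", "FluxSet", function(x) {
  if (x@VTCA == 0) stop("ZeroDenominator: VTCA is 0")
  x@VGLS / x@VTCA
})

setMethod("show", "FluxSet", function(object) {
  cat("FluxSet (uM/min per 5e5 cells):\n")
  print(round(fluxes(object), 4))
  cat(sprintf("derived: VGLUout = %.4f, VOAAout = %.4f, GLS/TCA = %.4f\n",
              vGluOut(object), vOaaOut(object),
              if (object@VTCA > 0) glsTcaRatio(object) else NA_real_))
  invisible(object)
})

#' Build a driving function from a glutamine MID time course
#'
#' Piecewise-linear interpolation of the measured GLN MID with constant
#' extrapolation beyond the last measured time. If the course does not
#' include t = 0 an unlabeled (M+0 = 1) point is prepended, reflecting that
#' labeling starts at tracer addition.
#'
#' @param timecourse a \linkS4class{MIDTimeCourse} for glutamine (5 carbons).
#' @return a \linkS4class{DrivingFunction}.
#' @export
drivingFunction <- function(timecourse) {
  stopifnot(is(timecourse, "MIDTimeCourse"))
  if (nCarbons(timecourse@mids[[1]]) != 5L)
    stop("InvalidDrivingFunction: glutamine has 5 carbons")
  tt <- timecourse@times
  m <- do.call(rbind, lapply(timecourse@mids, fractions))
  if (tt[1] > 0) {
    tt <- c(0, tt)
    m <- rbind(c(1, 0, 0, 0, 0, 0), m)
  }
  new("DrivingFunction", times = tt, fractions = m)
}

#' @rdname midAt
#' @export
setMethod("midAt", "DrivingFunction", function(x, t) {
  tt <- x@times
  t <- pmin(pmax(t, tt[1]), tt[length(tt)])  # constant extrapolation
  out <- vapply(seq_len(ncol(x@fractions)), function(j)
    stats::approx(tt, x@fractions[, j], xout = t, rule = 2)$y,
    numeric(length(t)))
  out <- matrix(out, nrow = length(t))
  out[out < 0] <- 0
  out / rowSums(out)
})

#' Build the one-compartment glutamine tracer model
#'
#' Wires the reaction network over fixed pools: GLN -> GLU at VGLS; GLU ->
#' AKG at VGDH; glutamate sink at VGLS - VGDH; AKG -> SUC (+CO2) at
#' VTCA + VGDH; SUC -> MAL and MAL -> OAA at VTCA + VGDH; OAA sink at VGDH;
#' OAA + acetyl-CoA -> CIT at VTCA; CIT -> AKG (+CO2) at VTCA + VIDHr;
#' AKG + HCO3 -> CIT at VIDHr; unlabeled HCO3 inflow VCO2dil with balancing
#' efflux. Per-pool inflow equals outflow identically for any feasible
#' \linkS4class{FluxSet}; this balance is asserted at build time.
#'
#' @param concentrations named numeric, positive, for pools GLU, AKG, SUC,
#'   MAL, OAA, CIT, HCO3 (uM per 5e5 cells), e.g. from
#'   \code{\link{steadyStateConcentrations}}.
#' @param drivingTimecourse \linkS4class{MIDTimeCourse} of measured GLN
#'   labeling (the driving function), or a ready \linkS4class{DrivingFunction}.
#' @param config list; \code{accoa}: acetyl-CoA MID fractions (default
#'   unlabeled \code{c(1, 0, 0)} — no significant enrichment reaches
#'   glycolytic intermediates), \code{VX}: optional glutamate/AKG exchange
#'   flux (default 0).
#' @return a \linkS4class{FluxModel}.
#' @export
buildFluxModel <- function(concentrations, drivingTimecourse,
                           config = list()) {
  drv <- if (is(drivingTimecourse, "DrivingFunction")) drivingTimecourse
         else drivingFunction(drivingTimecourse)
  cfg <- list(accoa = c(1, 0, 0), VX = 0)
  cfg[names(config)] <- config
  if (abs(sum(cfg$accoa) - 1) > 1e-6 || any(cfg$accoa < 0))
    stop("config$accoa must be a valid 2-carbon MID fraction vector")
  model <- new("FluxModel", concentrations = concentrations, driving = drv,
               config = cfg)
  ## assert per-pool mass balance on a handful of feasible flux sets
  for (fs in list(fluxSet(1, 1, 1, 1, 1), fluxSet(3, 1, 2, 0.5, 4),
                  fluxSet(2, 0, 5, 0, 0))) {
    bal <- .pool_balance(fs, cfg$VX)
    if (any(abs(bal$inflow - bal$outflow) > 1e-12))
      stop("internal error: reaction wiring violates mass balance")
  }
  model
}

## Per-pool total inflow/outflow implied by the wiring, for balance checks.
.pool_balance <- function(fs, VX = 0) {
  v <- fluxes(fs)
  vAS <- v["VTCA"] + v["VGDH"]   # AKG->SUC->MAL->OAA segment
  vCA <- v["VTCA"] + v["VIDHr"]  # CIT->AKG
  inflow <- c(GLU = unname(v["VGLS"] + VX),
              AKG = unname(v["VGDH"] + vCA + VX),
              SUC = unname(vAS), MAL = unname(vAS), OAA = unname(vAS),
              CIT = unname(v["VTCA"] + v["VIDHr"]),
              HCO3 = unname(vAS + vCA + v["VCO2dil"]))
  outflow <- c(GLU = unname(v["VGDH"] + (v["VGLS"] - v["VGDH"]) + VX),
               AKG = unname(vAS + v["VIDHr"] + VX),
               SUC = unname(vAS), MAL = unname(vAS),
               OAA = unname(v["VTCA"] + v["VGDH"]),
               CIT = unname(vCA),
               HCO3 = unname(v["VIDHr"] +
                             (vAS + vCA + v["VCO2dil"] - v["VIDHr"])))
  list(inflow = inflow, outflow = outflow)
}

## state layout: 36 entries, MID fraction blocks in .model_pools order
.state_index <- local({
  len <- .pool_carbons + 1L
  ends <- cumsum(len)
  starts <- ends - len + 1L
  lapply(stats::setNames(seq_along(.model_pools), .model_pools),
         function(i) starts[i]:ends[i])
})

.initial_state <- function() {
  y <- numeric(sum(.pool_carbons + 1L))
  for (p in .model_pools) y[.state_index[[p]][1]] <- 1
  y
}

## derivative of the isotopologue-balance system; driving evaluated at t
.flux_rhs <- function(t, y, parms) {
  ix <- .state_index
  glu <- y[ix$GLU]; akg <- y[ix$AKG]; suc <- y[ix$SUC]
  mal <- y[ix$MAL]; oaa <- y[ix$OAA]; cit <- y[ix$CIT]; hco3 <- y[ix$HCO3]
  v <- parms$v; C <- parms$C; VX <- parms$VX
  vAS <- v[["VTCA"]] + v[["VGDH"]]
  vCA <- v[["VTCA"]] + v[["VIDHr"]]

  gln <- parms$driving(t)                       # length-6 MID
  dc_akg <- .decarb_frac(akg)                   # AKG -> SUC + CO2
  dc_cit <- .decarb_frac(cit)                   # CIT -> AKG + CO2
  cit_syn <- .conv_frac(oaa, parms$accoa)       # OAA + AcCoA -> CIT
  cit_idh <- .conv_frac(akg, hco3)              # AKG + HCO3 -> CIT

  dglu <- (v[["VGLS"]] * (gln - glu) + VX * (akg - glu)) / C[["GLU"]]
  dakg <- (v[["VGDH"]] * glu + vCA * dc_cit$fractions + VX * glu -
           (vAS + v[["VIDHr"]] + VX) * akg) / C[["AKG"]]
  dsuc <- vAS * (dc_akg$fractions - suc) / C[["SUC"]]
  dmal <- vAS * (suc - mal) / C[["MAL"]]
  doaa <- vAS * (mal - oaa) / C[["OAA"]]
  dcit <- (v[["VTCA"]] * cit_syn + v[["VIDHr"]] * cit_idh -
           vCA * cit) / C[["CIT"]]
  co2_in <- c(vAS * (1 - dc_akg$co2) + vCA * (1 - dc_cit$co2) + v[["VCO2dil"]],
              vAS * dc_akg$co2 + vCA * dc_cit$co2)
  dhco3 <- (co2_in - (vAS + vCA + v[["VCO2dil"]]) * hco3) / C[["HCO3"]]

  list(c(dglu, dakg, dsuc, dmal, doaa, dcit, dhco3))
}

#' Simulate isotope labeling under the model
#'
#' Integrates the isotopologue-balance ODEs \eqn{dm_i/dt = (1/C_i)
#' [\sum v_{in} m_{delivered} - \sum v_{out} m_i]} with all internal pools
#' initialized unlabeled (M+0 = 1) at t = 0, condensation handled by MID
#' convolution and decarboxylation by the exchangeable-positions carbon-loss
#' model (released CO2 label feeds the HCO3 pool). Aspartate is reported as a
#' mirror of oxaloacetate. Uses a stiff-capable adaptive integrator (lsoda)
#' at rtol 1e-8 / atol 1e-10.
#'
#' @param model a \linkS4class{FluxModel}.
#' @param fluxes a \linkS4class{FluxSet}.
#' @param times numeric vector of output times (min), nonnegative.
#' @param replicateId identifier attached to the returned time courses.
#' @param rtol,atol integrator tolerances; the defaults are used for all
#'   reported results (looser values are appropriate only for optimizer
#'   search phases).
#' @return named list of \linkS4class{MIDTimeCourse} for GLU, AKG, SUC, MAL,
#'   OAA, ASP (= OAA), CIT and HCO3.
#' @export
simulateLabeling <- function(model, fluxes, times, replicateId = "sim",
                             rtol = 1e-8, atol = 1e-10) {
  stopifnot(is(model, "FluxModel"), is(fluxes, "FluxSet"))
  times <- sort(unique(as.numeric(times)))
  if (any(times < 0)) stop("times must be nonnegative")
  tgrid <- if (times[1] > 0) c(0, times) else times
  drv_t <- model@driving@times
  drv_m <- model@driving@fractions
  nt <- length(drv_t)
  driving <- function(t) {
    if (t <= drv_t[1]) return(drv_m[1, ])
    if (t >= drv_t[nt]) return(drv_m[nt, ])
    k <- findInterval(t, drv_t)
    w <- (t - drv_t[k]) / (drv_t[k + 1L] - drv_t[k])
    (1 - w) * drv_m[k, ] + w * drv_m[k + 1L, ]
  }
  parms <- list(v = as.list(fluxes(fluxes)),
                C = as.list(model@concentrations[.model_pools]),
                VX = model@config$VX,
                accoa = model@config$accoa,
                driving = driving)
  sol <- deSolve::ode(y = .initial_state(), times = tgrid, func = .flux_rhs,
                      parms = parms, method = "lsoda",
                      rtol = rtol, atol = atol)
  if (any(!is.finite(sol)))
    stop("SolverFailure: non-finite state in labeling simulation")
  sol <- sol[match(times, tgrid), -1, drop = FALSE]
  out <- lapply(stats::setNames(.model_pools, .model_pools), function(p) {
    idx <- .state_index[[p]]
    mids <- lapply(seq_along(times), function(k) {
      f <- unname(sol[k, idx])
      f[f < 0] <- 0
      new("MID", nCarbons = .pool_carbons[[p]], fractions = f / sum(f))
    })
    MIDTimeCourse(p, times, mids, replicateId)
  })
  asp <- out$OAA
  asp@metabolite <- "ASP"
  out$ASP <- asp
  out[c("GLU", "AKG", "SUC", "MAL", "OAA", "ASP", "CIT", "HCO3")]
}

#' Steady-state pool concentrations from a time-course table
#'
#' Averages measured concentrations over all time points per pool; the
#' averages are then held constant in the kinetic model to respect metabolic
#' steady state.
#'
#' @param concTable data.frame with columns \code{metabolite},
#'   \code{time_min}, \code{concentration_um} (optionally \code{replicate},
#'   averaged over as well).
#' @return named numeric vector of mean concentrations.
#' @export
steadyStateConcentrations <- function(concTable) {
  need <- c("metabolite", "time_min", "concentration_um")
  miss <- setdiff(need, names(concTable))
  if (length(miss))
    stop("MissingPool: concentration table lacks columns ",
         paste(miss, collapse = ", "))
  if (nrow(concTable) == 0) stop("MissingPool: empty concentration table")
  c(tapply(concTable$concentration_um, concTable$metabolite, mean))
}
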