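#' @import methods
NULL

## Internal tolerance for MID normalization. Input tables may be off by up to
## .mid_input_tol (renormalized silently); internally MIDs are kept normalized
## to .mid_tol.
.mid_tol <- 1e-9
.mid_input_tol <- 1e-3

#' Mass-isotopologue distribution (MID)
#'
#' An \code{MID} stores the fractions of a metabolite's molecules carrying
#' 0..n heavy (13C) carbons, ordered M+0 first. Fractions are nonnegative and
#' sum to one. Use \code{\link{MID}} to construct one from raw fractions.
#'
#' @slot nCarbons integer, number of carbon atoms (>= 1).
#' @slot fractions numeric vector of length \code{nCarbons + 1}; fraction of
#'   molecules with mass shift M+0 ... M+n.
#' @export
setClass("MID",
  representation(nCarbons = "integer", fractions = "numeric"),
  validity = function(object) {
    n <- object@nCarbons
    f <- object@fractions
    if (length(n) != 1L || is.na(n) || n < 1L)
      return("nCarbons must be a single integer >= 1")
    if (length(f) != n + 1L)
      return(sprintf("fractions must have length nCarbons + 1 = %d", n + 1L))
    if (any(!is.finite(f)))
      return("fractions must be finite")
    if (any(f < -1e-9))
      return("NegativeFraction: fractions must be nonnegative")
    if (abs(sum(f) - 1) > 1e-6)
      return("fractions must sum to 1")
    TRUE
  }
)

#' Mass-isotopologue time course
#'
#' One metabolite's MID measured (or simulated) at several time points within
#' a single replicate. Times are minutes from tracer addition and strictly
#' increasing; all MIDs share the metabolite's carbon count.
#'
#' @slot metabolite character, pool identifier (e.g. "GLU", "MAL").
#' @slot times numeric, strictly increasing, minutes, first time >= 0.
#' @slot mids list of \linkS4class{MID}, one per time point.
#' @slot replicateId character replicate/experiment identifier.
#' @export
setClass("MIDTimeCourse",
  representation(metabolite = "character", times = "numeric",
                 mids = "list", replicateId = "character"),
  validity = function(object) {
    t <- object@times
    m <- object@mids
    if (length(t) < 1L) return("at least one time point required")
    if (any(!is.finite(t)) || t[1] < 0) return("times must be finite and start at >= 0")
    if (length(t) > 1L && any(diff(t) <= 0)) return("times must be strictly increasing")
    if (length(m) != length(t)) return("one MID per time point required")
    if (!all(vapply(m, is, logical(1), "MID"))) return("mids must be MID objects")
    nc <- vapply(m, nCarbons, integer(1))
    if (length(unique(nc)) != 1L) return("all MIDs must share nCarbons")
    TRUE
  }
)

#' Flux parameter set of the one-compartment glutamine tracer model
#'
#' The five free fluxes of the model, all in uM/min per 5e5 cells:
#' \describe{
#'   \item{VGLS}{glutaminase flux, GLN -> GLU.}
#'   \item{VGDH}{glutamate oxidation into alpha-ketoglutarate (glutamine
#'     oxidation entry into the TCA cycle); must not exceed VGLS.}
#'   \item{VTCA}{net TCA cycle flux (citrate synthase).}
#'   \item{VIDHr}{reversible isocitrate-dehydrogenase exchange,
#'     AKG + CO2 <-> CIT.}
#'   \item{VCO2dil}{unlabeled bicarbonate inflow diluting the CO2/HCO3 pool.}
#' }
#' Derived quantities are available via \code{\link{vGluOut}},
#' \code{\link{vOaaOut}} and \code{\link{glsTcaRatio}}.
#'
#' @export
setClass("FluxSet",
  representation(VGLS = "numeric", VGDH = "numeric", VTCA = "numeric",
                 VIDHr = "numeric", VCO2dil = "numeric"),
  validity = function(object) {
    v <- c(object@VGLS, object@VGDH, object@VTCA, object@VIDHr, object@VCO2dil)
    if (length(v) != 5L || any(!is.finite(v)))
      return("all five fluxes must be single finite numbers")
    if (any(v < 0)) return("fluxes must be nonnegative")
    if (object@VGLS < object@VGDH - 1e-9)
      return("InfeasibleFluxes: VGLS must be >= VGDH")
    TRUE
  }
)

#' Driving function: measured glutamine labeling forced on the model
#'
#' Piecewise-linear interpolation of a measured GLN MID time course,
#' constant-extrapolated beyond the last time point, evaluable at any t >= 0.
#'
#' @slot times numeric, strictly increasing time grid (min), starting at 0.
#' @slot fractions matrix, one row per time, one column per mass shift.
#' @export
setClass("DrivingFunction",
  representation(times = "numeric", fractions = "matrix"),
  validity = function(object) {
    if (length(object@times) != nrow(object@fractions))
      return("one fraction row per time required")
    if (object@times[1] != 0) return("driving function grid must start at t = 0")
    if (any(diff(object@times) <= 0)) return("times must be strictly increasing")
    if (any(object@fractions < -1e-9)) return("driving fractions must be nonnegative")
    s <- rowSums(object@fractions)
    if (any(abs(s - 1) > 1e-6)) return("driving MIDs must sum to 1")
    TRUE
  }
)

#' One-compartment glutamine tracer flux model
#'
#' Wired reaction network over fixed intracellular pools, driven by the
#' measured glutamine MID time course. Pools (carbons): GLU(5), AKG(5),
#' SUC(4, succinate+fumarate lumped), MAL(4), OAA(4, aspartate mirror),
#' CIT(6), HCO3(1). Acetyl-CoA is an external 2-carbon pool, unlabeled by
#' default. Concentrations are uM per 5e5 cells and held constant (metabolic
#' steady state).
#'
#' @slot concentrations named numeric, positive, one entry per internal pool.
#' @slot driving \linkS4class{DrivingFunction} for GLN.
#' @slot config list: \code{accoa} (MID fractions of acetyl-CoA, default
#'   unlabeled), \code{VX} (optional GLU<->AKG exchange flux, default 0).
#' @export
setClass("FluxModel",
  representation(concentrations = "numeric", driving = "DrivingFunction",
                 config = "list"),
  validity = function(object) {
    need <- .model_pools
    miss <- setdiff(need, names(object@concentrations))
    if (length(miss))
      return(paste0("MissingPoolConcentration: ", paste(miss, collapse = ", ")))
    if (any(object@concentrations[need] <= 0))
      return("pool concentrations must be positive")
    if (ncol(object@driving@fractions) != 6L)
      return("InvalidDrivingFunction: GLN driving must be a 5-carbon MID course")
    TRUE
  }
)

#' Flux estimation result across replicates
#'
#' Per-replicate fitted \linkS4class{FluxSet}s plus their arithmetic mean.
#' The mean GLS/TCA ratio is the mean of per-replicate ratios (not the ratio
#' of means).
#'
#' @slot fits list of \linkS4class{FluxSet}, one per replicate.
#' @slot meanFluxes \linkS4class{FluxSet}, arithmetic mean per flux.
#' @slot meanGlsTcaRatio numeric, mean of per-replicate VGLS/VTCA.
#' @slot objectives numeric, weighted-SSE objective per replicate.
#' @slot diagnostics list (nStarts, converged flags, seed).
#' @export
setClass("FluxEstimate",
  representation(fits = "list", meanFluxes = "FluxSet",
                 meanGlsTcaRatio = "numeric", objectives = "numeric",
                 diagnostics = "list"),
  validity = function(object) {
    if (length(object@fits) < 1L) return("EmptyInput: need at least one fit")
    if (!all(vapply(object@fits, is, logical(1), "FluxSet")))
      return("fits must be FluxSet objects")
    TRUE
  }
)

#' Linear-quadratic survival fit
#'
#' Parameters of the radiobiological dose response
#' \eqn{SF(D) = \exp(-(\alpha D + \beta D^2))}, fitted by least squares on
#' \eqn{\ln SF} with the zero-dose point anchored at SF = 1 in every stratum.
#' Alpha and beta are reported as positive radiosensitivity parameters; on
#' the equivalent printed convention \eqn{S(D)/S(0) = \exp(aD + bD^2)} the
#' regression coefficients are \eqn{a = -\alpha}, \eqn{b = -\beta}.
#'
#' @slot alpha numeric, Gy^-1.
#' @slot beta numeric, Gy^-2.
#' @slot se named numeric, standard errors of (alpha, beta).
#' @slot nPoints integer, number of ln SF points used.
#' @slot stratumIntercepts named numeric, per-stratum intercepts (zero under
#'   the default anchored fit).
#' @export
setClass("LQFit",
  representation(alpha = "numeric", beta = "numeric", se = "numeric",
                 nPoints = "integer", stratumIntercepts = "numeric"),
  validity = function(object) {
    if (!is.finite(object@alpha) || !is.finite(object@beta))
      return("alpha and beta must be finite")
    TRUE
  }
)

#' Limiting-dilution (single-hit Poisson) fit
#'
#' Tumor-initiating cell frequency under P(no take | dose d) = exp(-f d),
#' estimated by complementary log-log binomial regression with offset
#' log(dose); 95% CI from the profile likelihood. Degenerate tables (all
#' implants negative or all positive) carry a one-sided bound and
#' \code{status} records which.
#'
#' @slot frequency numeric, cells^-1 (NA for degenerate tables).
#' @slot lower,upper numeric, 95% CI bounds on the frequency.
#' @slot logLik numeric, maximized log-likelihood.
#' @slot deviance numeric, residual deviance against the saturated model.
#' @slot dfResidual integer, residual degrees of freedom.
#' @slot status character: "ok", "all_negative" or "all_positive".
#' @export
setClass("LDAFit",
  representation(frequency = "numeric", lower = "numeric", upper = "numeric",
                 logLik = "numeric", deviance = "numeric",
                 dfResidual = "integer", status = "character"),
  validity = function(object) {
    if (object@status == "ok") {
      f <- object@frequency
      if (!is.finite(f) || f <= 0 || f > 1)
        return("frequency must be in (0, 1]")
      if (is.finite(object@lower) && is.finite(object@upper) &&
          object@lower > object@upper)
        return("CI bounds must be ordered")
    }
    TRUE
  }
)

#' Ground-truth specification for the synthetic-data generators
#'
#' Bundles every parameter the generators need: the true fluxes and pool
#' concentrations of the tracer model, the sampling grid and measurement
#' noise, the clonogenic design (true alpha/beta/plating efficiency), the
#' limiting-dilution design (true frequency per group), and the tumor growth
#' law. A fixed \code{seed} makes every generator fully deterministic;
#' substreams derived from it let each generator be re-run independently.
#'
#' @slot seed integer master seed.
#' @slot fluxes true \linkS4class{FluxSet}.
#' @slot concentrations named numeric, true pool concentrations (uM/5e5 cells).
#' @slot times numeric sampling grid, minutes.
#' @slot midNoiseSd numeric, sd of truncated Gaussian noise on MID fractions.
#' @slot nReplicates integer, number of tracing replicates.
#' @slot drivingTau numeric, time constant (min) of intracellular GLN
#'   labeling rise; \code{drivingPlateau} its asymptotic M+5 fraction.
#' @slot drivingPlateau numeric in (0, 1].
#' @slot clonogenic list: alpha, beta, pe, cellsPlated, doses, nStrata.
#' @slot lda list: frequencies (named numeric per group), doses, nTested.
#' @slot growth list: v0, rate (day^-1), lagSd, days, cvNoise.
#' @export
setClass("SynthSpec",
  representation(seed = "integer", fluxes = "FluxSet",
                 concentrations = "numeric", times = "numeric",
                 midNoiseSd = "numeric", nReplicates = "integer",
                 drivingTau = "numeric", drivingPlateau = "numeric",
                 clonogenic = "list", lda = "list", growth = "list"),
  validity = function(object) {
    if (object@midNoiseSd < 0) return("noise sd must be >= 0")
    if (object@nReplicates < 1L) return("need >= 1 replicate")
    if (any(object@times < 0) || any(diff(object@times) <= 0))
      return("times must be increasing and nonnegative")
    if (object@times[1] != 0) return("time grid must include t = 0")
    TRUE
  }
)

.model_pools <- c("GLU", "AKG", "SUC", "MAL", "OAA", "CIT", "HCO3")
.pool_carbons <- c(GLU = 5L, AKG = 5L, SUC = 4L, MAL = 4L, OAA = 4L,
                   CIT = 6L, HCO3 = 1L)
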