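## Run expr with a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

## (log VGLS, logit VGDH/VGLS, log VTCA, log VIDHr, log VCO2dil) <-> FluxSet.
## The ratio parameterization keeps VGLS >= VGDH by construction inside the
## box-constrained Levenberg-Marquardt refinement.
.theta_to_fluxset <- function(theta) {
  vgls <- exp(theta[1])
  fluxSet(VGLS = vgls, VGDH = vgls * stats::plogis(theta[2]),
          VTCA = exp(theta[3]), VIDHr = exp(theta[4]),
          VCO2dil = exp(theta[5]))
}

.fluxset_to_theta <- function(fs) {
  v <- fluxes(fs)
  r <- min(max(v["VGDH"] / max(v["VGLS"], 1e-12), 1e-5), 1 - 1e-5)
  unname(c(log(v["VGLS"]), stats::qlogis(r), log(v["VTCA"]),
           log(v["VIDHr"]), log(v["VCO2dil"])))
}

#' Fit the five model fluxes to observed labeling time courses
#'
#' Minimizes the weighted sum of squared differences between simulated and
#' observed MID fractions (or fractional enrichments, per
#' \code{fitConfig$objective}) over the supplied target pools, with pool
#' concentrations held fixed at their steady-state values. Optimization runs
#' in a transformed space (log fluxes; logit of VGDH/VGLS, so the
#' glutaminase flux always covers the oxidation flux) with seeded log-uniform
#' multi-starts inside the flux bounds: all starts are screened on the
#' objective, the best few refined by box-constrained Levenberg-Marquardt at
#' a relaxed integrator tolerance (basin finding), and the incumbent is
#' polished at full precision (rtol 1e-8 / atol 1e-10).
#'
#' @param model a \linkS4class{FluxModel} (its driving function should come
#'   from the same replicate as \code{observed}).
#' @param observed named list of \linkS4class{MIDTimeCourse}; names among
#'   GLU, AKG, SUC, MAL, OAA, ASP, CIT. At least two pools, each with at
#'   least three time points.
#' @param fitConfig list of options: \code{sigma} (measurement sd on
#'   fractions, default 0.02; scalar or named per pool), \code{objective}
#'   ("mid", the default, or "enrichment"), \code{nStarts} (default 20),
#'   \code{nRefine} (starts refined by Levenberg-Marquardt, default 10),
#'   \code{bounds} (default \code{c(1e-4, 1e3)} uM/min), \code{seed}
#'   (default 20210626), \code{maxiter} (default 200, polish stage).
#' @return list with \code{fluxes} (\linkS4class{FluxSet}), \code{objective}
#'   (weighted SSE at the optimum), \code{converged}, \code{nStarts},
#'   \code{seed}.
#' @export
fitFluxes <- function(model, observed, fitConfig = list()) {
  stopifnot(is(model, "FluxModel"), is.list(observed))
  cfg <- list(sigma = 0.02, objective = "mid", nStarts = 20L, nRefine = 10L,
              bounds = c(1e-4, 1e3), seed = 20210626L, maxiter = 200L)
  cfg[names(fitConfig)] <- fitConfig
  if (length(observed) < 2L)
    stop("need observations for at least two target pools")
  if (is.null(names(observed)) || any(names(observed) == ""))
    stop("observed must be a named list of MIDTimeCourse")
  for (tc in observed) {
    stopifnot(is(tc, "MIDTimeCourse"))
    if (length(tc@times) < 3L)
      stop("TooFewTimePoints: each fitted pool needs >= 3 time points")
  }

  pools <- names(observed)
  times_union <- sort(unique(unlist(lapply(observed, function(tc) tc@times))))
  obs_frac <- lapply(observed, function(tc)
    do.call(rbind, lapply(tc@mids, fractions)))
  obs_tidx <- lapply(observed, function(tc) match(tc@times, times_union))
  sig <- vapply(pools, function(p) {
    if (length(cfg$sigma) > 1L && !is.null(names(cfg$sigma)))
      unname(cfg$sigma[[p]]) else cfg$sigma[[1]]
  }, numeric(1))

  resid_fn <- function(theta, rtol = 1e-8, atol = 1e-10) {
    fs <- .theta_to_fluxset(theta)
    sim <- simulateLabeling(model, fs, times_union, rtol = rtol, atol = atol)
    unlist(lapply(seq_along(pools), function(i) {
      p <- pools[i]
      sm <- do.call(rbind, lapply(sim[[p]]@mids, fractions))
      if (cfg$objective == "enrichment") {
        se <- vapply(sim[[p]]@mids, fractionalEnrichment, numeric(1))
        oe <- apply(obs_frac[[i]], 1, function(f)
          sum((seq_along(f) - 1L) * f) / (length(f) - 1L))
        (se[obs_tidx[[i]]] - oe) / sig[i]
      } else {
        (sm[obs_tidx[[i]], , drop = FALSE] - obs_frac[[i]]) / sig[i]
      }
    }), use.names = FALSE)
  }

  lb <- log(cfg$bounds[1]); ub <- log(cfg$bounds[2])
  lower <- c(lb, -12, lb, lb, lb)
  upper <- c(ub, 12, ub, ub, ub)
  starts <- .with_seed(cfg$seed, {
    m <- matrix(stats::runif(5L * cfg$nStarts), ncol = 5L)
    t(apply(m, 1, function(u) c(lb + u[1] * (ub - lb),
                                stats::qlogis(0.05 + 0.9 * u[2]),
                                lb + u[3] * (ub - lb),
                                lb + u[4] * (ub - lb),
                                lb + u[5] * (ub - lb))))
  })

  ## stage 1: screen all starts on the objective at search tolerance
  coarse <- function(th) resid_fn(th, rtol = 1e-6, atol = 1e-8)
  sse <- apply(starts, 1, function(th)
    tryCatch(sum(coarse(th)^2), error = function(e) Inf))
  if (all(!is.finite(sse)))
    stop("AllStartsFailed: no start produced a finite objective")
  keep <- order(sse)[seq_len(min(cfg$nRefine, sum(is.finite(sse))))]

  ## stage 2: Levenberg-Marquardt from the best starts, still at search
  ## tolerance (basin finding, not final precision)
  best <- NULL
  for (k in keep) {
    ## truncated on purpose: suppress the iteration-limit notice
    fit <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = starts[k, ], lower = lower, upper = upper,
                           fn = coarse,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 60L, ftol = 1e-10, ptol = 1e-10))),
      error = function(e) NULL)
    if (is.null(fit)) next
    obj <- sum(fit$fvec^2)
    if (is.null(best) || obj < best$objective)
      best <- list(theta = fit$par, objective = obj)
  }
  if (is.null(best)) stop("AllStartsFailed: no refinement converged")

  ## stage 3: polish the incumbent at full integrator precision, with one
  ## restart (escapes occasional stalls of the damping schedule)
  converged <- FALSE
  best$objective <- sum(resid_fn(best$theta)^2)
  for (round in 1:2) {
    polish <- tryCatch(
      minpack.lm::nls.lm(par = best$theta, lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = cfg$maxiter, ftol = 1e-12,
                           ptol = 1e-12)),
      error = function(e) NULL)
    if (!is.null(polish) && sum(polish$fvec^2) <= best$objective) {
      best <- list(theta = polish$par, objective = sum(polish$fvec^2))
      converged <- polish$info %in% 1:4
    }
  }

  list(fluxes = .theta_to_fluxset(best$theta), objective = best$objective,
       converged = converged, nStarts = cfg$nStarts, seed = cfg$seed)
}

#' Average per-replicate flux fits
#'
#' Replicate time courses are modeled separately; the final fluxes are the
#' arithmetic mean of the per-replicate fits, and the mean GLS/TCA ratio is
#' the mean of per-replicate ratios.
#'
#' @param fits list of \linkS4class{FluxSet}, or of \code{\link{fitFluxes}}
#'   results (their \code{fluxes} elements are extracted).
#' @return a \linkS4class{FluxEstimate}.
#' @export
averageReplicateFits <- function(fits) {
  if (length(fits) == 0L) stop("EmptyInput: no fits to average")
  objectives <- rep(NA_real_, length(fits))
  sets <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (is(f, "FluxSet")) return(f)
    if (is.list(f) && is(f$fluxes, "FluxSet")) {
      objectives[i] <<- f$objective
      return(f$fluxes)
    }
    stop("fits must be FluxSet objects or fitFluxes results")
  })
  vm <- rowMeans(vapply(sets, fluxes, numeric(5)))
  mean_set <- fluxSet(vm["VGLS"], min(vm["VGDH"], vm["VGLS"]), vm["VTCA"],
                      vm["VIDHr"], vm["VCO2dil"])
  new("FluxEstimate", fits = sets, meanFluxes = mean_set,
      meanGlsTcaRatio = mean(vapply(sets, glsTcaRatio, numeric(1))),
      objectives = objectives,
      diagnostics = list(nReplicates = length(sets)))
}

setMethod("show", "FluxEstimate", function(object) {
  cat(sprintf("FluxEstimate over %d replicate fit(s)\n", length(object@fits)))
  cat("mean fluxes (uM/min per 5e5 cells):\n")
  print(round(fluxes(object@meanFluxes), 4))
  cat(sprintf("mean GLS/TCA ratio: %.4f\n", object@meanGlsTcaRatio))
  invisible(object)
})
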