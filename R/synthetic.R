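#' Construct a synthetic-data specification
#'
#' Bundles the ground truth for every generator. Defaults emulate the study
#' conditions of the assays the pipeline analyzes: a 0/10/30/90 min tracing
#' grid with three independent replicates and 2% measurement scatter on MID
#' fractions; clonogenic plates of 1000 cells at 0/2/4/6 Gy in three strata
#' with alpha = 0.3 Gy^-1, beta = 0.03 Gy^-2, plating efficiency 0.2;
#' limiting-dilution injections of 100/1000/10000 cells into 6 mice per dose;
#' and weekly caliper measurements over 140 days with a 100 mm^3 take
#' threshold. True fluxes and pool sizes are plausible values for glutamine-
#' avid cancer cells producing clearly evolving labeling on this grid (the
#' study's own fitted values are not printed in the text).
#'
#' @param seed integer master seed; every generator derives its own
#'   substream from it, so outputs are byte-identical across runs.
#' @param fluxes true \linkS4class{FluxSet}.
#' @param concentrations named numeric pool concentrations (uM/5e5 cells).
#' @param times sampling grid in minutes (must include 0).
#' @param midNoiseSd truncated-Gaussian sd added to MID fractions.
#' @param nReplicates number of tracing replicates.
#' @param drivingTau,drivingPlateau time constant (min) and asymptote of the
#'   intracellular glutamine M+5 rise after medium change to
#'   [U-13C5]-glutamine.
#' @param clonogenic,lda,growth lists overriding individual defaults (see
#'   \linkS4class{SynthSpec}).
#' @return a \linkS4class{SynthSpec}.
#' @export
synthSpec <- function(seed = 20210626L,
                      fluxes = fluxSet(VGLS = 25, VGDH = 15, VTCA = 15,
                                       VIDHr = 20, VCO2dil = 25),
                      concentrations = c(GLU = 300, AKG = 25, SUC = 50,
                                         MAL = 60, OAA = 25, CIT = 50,
                                         HCO3 = 800),
                      times = c(0, 10, 30, 90),
                      midNoiseSd = 0.02,
                      nReplicates = 3L,
                      drivingTau = 5,
                      drivingPlateau = 0.98,
                      clonogenic = list(),
                      lda = list(),
                      growth = list()) {
  clo <- list(alpha = 0.3, beta = 0.03, pe = 0.2, cellsPlated = 1000L,
              doses = c(0, 2, 4, 6), nStrata = 3L)
  clo[names(clonogenic)] <- clonogenic
  ld <- list(frequencies = c(control = 1e-3, starved = 1e-4),
             doses = c(100, 1000, 10000), nTested = 6L)
  ld[names(lda)] <- lda
  gr <- list(takeProb = c(control = 0.8, starved = 0.2), rate = 0.08,
             lagMean = 30, lagSd = 12, days = seq(7, 140, by = 7),
             cvNoise = 0.1, nPerGroup = 8L)
  gr[names(growth)] <- growth
  new("SynthSpec", seed = as.integer(seed), fluxes = fluxes,
      concentrations = concentrations, times = as.numeric(times),
      midNoiseSd = midNoiseSd, nReplicates = as.integer(nReplicates),
      drivingTau = drivingTau, drivingPlateau = drivingPlateau,
      clonogenic = clo, lda = ld, growth = gr)
}

## deterministic substream offsets per generator
.substream <- c(mids = 101L, clonogenic = 211L, lda = 307L, growth = 401L)

#' True glutamine driving time course of a synthetic spec
#'
#' Intracellular glutamine labeling after the medium swap is modeled as a
#' single-exponential rise of the M+5 fraction,
#' \eqn{m_5(t) = plateau (1 - e^{-t/\tau})}, the remainder staying M+0.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param replicateId identifier for the returned course.
#' @return a \linkS4class{MIDTimeCourse} for GLN.
#' @export
synthDrivingTimecourse <- function(spec, replicateId = "truth") {
  m5 <- spec@drivingPlateau * (1 - exp(-spec@times / spec@drivingTau))
  mids <- lapply(m5, function(x) MID(c(1 - x, 0, 0, 0, 0, x), 5))
  MIDTimeCourse("GLN", spec@times, mids, replicateId)
}

## add truncated Gaussian noise to a fraction vector and renormalize
.noisy_fractions <- function(f, sd) {
  if (sd == 0) return(f)
  g <- pmax(f + stats::rnorm(length(f), 0, sd), 0)
  if (sum(g) <= 0) g <- f
  g / sum(g)
}

#' Generate synthetic isotopologue time courses and concentrations
#'
#' Simulates labeling at the spec's true fluxes (driving built from the true
#' glutamine course sampled on the same grid), then adds truncated Gaussian
#' noise to every fraction and renormalizes, independently per replicate.
#' Measured metabolites are those the model is fitted to plus the driving:
#' GLN, GLU, MAL, ASP, CIT. Concentration measurements get multiplicative
#' noise of the same relative magnitude.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return list with \code{mids} (long data.frame: replicate, metabolite,
#'   time_min, mass_shift, fraction), \code{concentrations} (metabolite,
#'   time_min, concentration_um), and \code{truth} (the noise-free simulated
#'   time courses and the spec's fluxes).
#' @export
genMidTimecourses <- function(spec) {
  drv <- synthDrivingTimecourse(spec)
  model <- buildFluxModel(spec@concentrations, drv)
  sim <- simulateLabeling(model, spec@fluxes, spec@times)
  courses <- c(list(GLN = drv), sim[c("GLU", "MAL", "ASP", "CIT")])

  mids <- .with_seed(spec@seed + .substream[["mids"]], {
    do.call(rbind, lapply(seq_len(spec@nReplicates), function(r) {
      do.call(rbind, lapply(names(courses), function(met) {
        tc <- courses[[met]]
        do.call(rbind, lapply(seq_along(tc@times), function(k) {
          f <- .noisy_fractions(fractions(tc@mids[[k]]), spec@midNoiseSd)
          data.frame(replicate = paste0("r", r), metabolite = met,
                     time_min = tc@times[k],
                     mass_shift = seq_along(f) - 1L, fraction = f)
        }))
      }))
    }))
  })
  conc <- .with_seed(spec@seed + .substream[["mids"]] + 1L, {
    do.call(rbind, lapply(names(spec@concentrations), function(met) {
      mult <- if (spec@midNoiseSd == 0) rep(1, length(spec@times))
              else pmax(stats::rnorm(length(spec@times), 1, spec@midNoiseSd),
                        0.01)
      data.frame(metabolite = met, time_min = spec@times,
                 concentration_um = spec@concentrations[[met]] * mult)
    }))
  })
  rownames(mids) <- rownames(conc) <- NULL
  list(mids = mids, concentrations = conc,
       truth = list(courses = courses, fluxes = spec@fluxes,
                    concentrations = spec@concentrations))
}

#' Generate synthetic clonogenic colony counts
#'
#' Colonies per plate are Binomial(cells_plated, PE * SF(D)) with the
#' linear-quadratic SF(D) = exp(-(alpha D + beta D^2)), independently per
#' stratum and dose.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return data.frame with the clonogenic CSV columns (cell_line, condition,
#'   replicate, dose_gy, cells_plated, colonies).
#' @export
genClonogenic <- function(spec) {
  p <- spec@clonogenic
  sf <- exp(-(p$alpha * p$doses + p$beta * p$doses^2))
  prob <- p$pe * sf
  if (any(prob > 1))
    stop("InvalidSurvivalProbability: PE * SF exceeds 1")
  .with_seed(spec@seed + .substream[["clonogenic"]], {
    out <- expand.grid(replicate = paste0("s", seq_len(p$nStrata)),
                       dose_gy = p$doses, stringsAsFactors = FALSE)
    out <- out[order(out$replicate, out$dose_gy), ]
    out$cell_line <- "synthetic"
    out$condition <- "control"
    out$cells_plated <- p$cellsPlated
    out$colonies <- stats::rbinom(nrow(out), p$cellsPlated,
                                  prob[match(out$dose_gy, p$doses)])
    rownames(out) <- NULL
    out[, c("cell_line", "condition", "replicate", "dose_gy",
            "cells_plated", "colonies")]
  })
}

#' Generate a synthetic limiting-dilution take table
#'
#' Tumor takes are Binomial(n_tested, 1 - exp(-f * dose)) under the
#' single-hit Poisson model, per group and injected dose.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @return data.frame with columns group, dose_cells, n_tested, n_positive.
#' @export
genLda <- function(spec) {
  p <- spec@lda
  if (any(p$frequencies < 0 | p$frequencies > 1))
    stop("frequencies must be in [0, 1]")
  .with_seed(spec@seed + .substream[["lda"]], {
    out <- do.call(rbind, lapply(names(p$frequencies), function(g) {
      f <- p$frequencies[[g]]
      data.frame(group = g, dose_cells = p$doses, n_tested = p$nTested,
                 n_positive = stats::rbinom(length(p$doses), p$nTested,
                                            1 - exp(-f * p$doses)))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Generate synthetic tumor-growth caliper curves
#'
#' Each animal either takes (with its group's take probability) and then
#' grows exponentially — crossing the take threshold at a lagged,
#' animal-specific day — or never exceeds background. Caliper dimensions are
#' reported so the volume formula V = (L W H)/2 reproduces the simulated
#' volume up to multiplicative measurement noise.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param threshold take threshold used to place the crossing day (mm^3).
#' @return data.frame with columns animal, group, day, length_mm, width_mm,
#'   height_mm.
#' @export
genTumorGrowth <- function(spec, threshold = 100) {
  p <- spec@growth
  .with_seed(spec@seed + .substream[["growth"]], {
    out <- do.call(rbind, lapply(names(p$takeProb), function(g) {
      do.call(rbind, lapply(seq_len(p$nPerGroup), function(a) {
        takes <- stats::runif(1) < p$takeProb[[g]]
        cross <- max(1, stats::rnorm(1, p$lagMean, p$lagSd))
        v <- if (takes) threshold * exp(p$rate * (p$days - cross))
             else stats::runif(length(p$days), 0, threshold / 4)
        v <- pmax(v * stats::rnorm(length(p$days), 1, p$cvNoise), 0)
        s <- (2 * v)^(1 / 3)  # report cubic-equivalent caliper dimensions
        data.frame(animal = sprintf("%s_%02d", g, a), group = g,
                   day = p$days, length_mm = s, width_mm = s, height_mm = s)
      }))
    }))
    rownames(out) <- NULL
    out
  })
}

#' Write every synthetic table plus a ground-truth manifest
#'
#' Writes mids.csv, concentrations.csv, clonogenic.csv, lda.csv, growth.csv
#' and manifest.json (the spec's ground-truth parameters) into \code{dir}.
#' Outputs are byte-identical for a fixed spec.
#'
#' @param spec a \linkS4class{SynthSpec}.
#' @param dir output directory, created if missing.
#' @return invisibly, the named vector of file paths.
#' @export
writeSyntheticData <- function(spec, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tc <- genMidTimecourses(spec)
  tabs <- list(mids = tc$mids, concentrations = tc$concentrations,
               clonogenic = genClonogenic(spec), lda = genLda(spec),
               growth = genTumorGrowth(spec))
  paths <- vapply(names(tabs), function(nm) {
    fp <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tabs[[nm]], fp, row.names = FALSE, quote = FALSE)
    fp
  }, character(1))
  manifest <- list(seed = spec@seed,
                   fluxes = as.list(fluxes(spec@fluxes)),
                   concentrations = as.list(spec@concentrations),
                   times = spec@times, midNoiseSd = spec@midNoiseSd,
                   nReplicates = spec@nReplicates,
                   drivingTau = spec@drivingTau,
                   drivingPlateau = spec@drivingPlateau,
                   clonogenic = spec@clonogenic,
                   lda = lapply(spec@lda, function(x)
                     if (is.numeric(x) && !is.null(names(x))) as.list(x) else x),
                   growth = lapply(spec@growth, function(x)
                     if (is.numeric(x) && !is.null(names(x)) &&
                         length(names(x)) == length(x)) as.list(x) else x))
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, manifest = mp))
}
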