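#' Construct and validate a mass-isotopologue distribution
#'
#' Validates a raw fraction vector for a metabolite with \code{nCarbons}
#' carbon atoms. Entries must be nonnegative (within numerical jitter of
#' -1e-9, which is clamped to zero) and sum to one; sums deviating by at most
#' 1e-3 — typical after integrating noisy peaks — are renormalized, larger
#' deviations are an error.
#'
#' @param rawFractions numeric vector of length \code{nCarbons + 1}, ordered
#'   M+0 first.
#' @param nCarbons integer >= 1.
#' @return an \linkS4class{MID}.
#' @examples
#' MID(c(1, 0, 0, 0, 0, 0), 5)            # unlabeled glutamate
#' MID(c(0.5, 0, 0, 0, 0, 0.5), 5)        # M0/M5 mixture
#' @export
MID <- function(rawFractions, nCarbons) {
  nCarbons <- as.integer(nCarbons)
  if (length(nCarbons) != 1L || is.na(nCarbons) || nCarbons < 1L)
    stop("SingularCorrection: nCarbons must be a single integer >= 1")
  f <- as.numeric(rawFractions)
  if (length(f) != nCarbons + 1L)
    stop(sprintf("fractions must have length nCarbons + 1 = %d, got %d",
                 nCarbons + 1L, length(f)))
  if (any(!is.finite(f))) stop("fractions must be finite")
  if (any(f < -1e-9))
    stop("NegativeFraction: MID fractions must be nonnegative")
  f[f < 0] <- 0
  s <- sum(f)
  if (abs(s - 1) > .mid_input_tol)
    stop(sprintf("NotNormalized: MID fractions sum to %.6f (|sum - 1| > %g)",
                 s, .mid_input_tol))
  new("MID", nCarbons = nCarbons, fractions = f / s)
}

#' @rdname MID
#' @export
setMethod("nCarbons", "MID", function(x) x@nCarbons)

#' @rdname MID
#' @export
setMethod("fractions", "MID", function(x) x@fractions)

setMethod("show", "MID", function(object) {
  f <- object@fractions
  lab <- paste0("M+", seq_along(f) - 1L)
  cat(sprintf("MID on %d carbons (enrichment %.4f)\n", object@nCarbons,
              fractionalEnrichment(object)))
  print(stats::setNames(round(f, 4), lab))
  invisible(object)
})

#' @rdname fractionalEnrichment
#' @export
setMethod("fractionalEnrichment", "MID", function(x) {
  n <- x@nCarbons
  sum((0:n) * x@fractions) / n
})

#' Construct a MID time course
#'
#' @param metabolite pool identifier.
#' @param times numeric, minutes, strictly increasing, first >= 0.
#' @param mids list of \linkS4class{MID}, one per time.
#' @param replicateId replicate identifier.
#' @return a \linkS4class{MIDTimeCourse}.
#' @export
MIDTimeCourse <- function(metabolite, times, mids, replicateId = "r1") {
  new("MIDTimeCourse", metabolite = as.character(metabolite),
      times = as.numeric(times), mids = mids,
      replicateId = as.character(replicateId))
}

setMethod("show", "MIDTimeCourse", function(object) {
  cat(sprintf("MIDTimeCourse: %s (%d carbons), replicate %s\n",
              object@metabolite, nCarbons(object@mids[[1]]),
              object@replicateId))
  m <- do.call(rbind, lapply(object@mids, fractions))
  dimnames(m) <- list(paste0("t=", object@times),
                      paste0("M+", 0:(ncol(m) - 1L)))
  print(round(m, 4))
  invisible(object)
})

## Forward natural-abundance contamination matrix: column i (tracer-labeled
## M+i molecules) spreads to rows j >= i as extra 13C arises at natural
## abundance p among the n - i non-tracer carbons.
.na_matrix <- function(nCarbons, p) {
  n <- as.integer(nCarbons)
  if (n < 1L) stop("SingularCorrection: nCarbons must be >= 1")
  C <- matrix(0, n + 1L, n + 1L)
  for (i in 0:n) {
    j <- i:n
    C[j + 1L, i + 1L] <- stats::dbinom(j - i, size = n - i, prob = p)
  }
  C
}

#' Natural-abundance contamination and correction of MIDs
#'
#' \code{applyNaturalAbundance} is the forward model: it contaminates a
#' tracer-only MID with 13C arising at natural abundance \code{p} in the
#' non-tracer carbons (binomial, 13C only; H/N/O isotopes ignored).
#' \code{correctNaturalAbundance} inverts it: it solves the triangular system
#' \eqn{C x = raw}, clamps small negative solutions to zero and renormalizes.
#' With \code{p = 0} both are the identity.
#'
#' @param mid an \linkS4class{MID} (raw, as measured, for correction).
#' @param p natural 13C abundance; default 0.0107.
#' @return an \linkS4class{MID}.
#' @examples
#' raw <- applyNaturalAbundance(MID(c(1, 0, 0, 0, 0, 0), 5))
#' fractions(correctNaturalAbundance(raw))[1] # 1 again
#' @export
correctNaturalAbundance <- function(mid, p = 0.0107) {
  stopifnot(is(mid, "MID"))
  if (p == 0) return(mid)
  C <- .na_matrix(nCarbons(mid), p)
  x <- solve(C, fractions(mid))
  x[x < 0] <- 0
  s <- sum(x)
  if (s <= 0) stop("correction annihilated the distribution")
  new("MID", nCarbons = nCarbons(mid), fractions = x / s)
}

#' @rdname correctNaturalAbundance
#' @export
applyNaturalAbundance <- function(mid, p = 0.0107) {
  stopifnot(is(mid, "MID"))
  if (p == 0) return(mid)
  C <- .na_matrix(nCarbons(mid), p)
  new("MID", nCarbons = nCarbons(mid),
      fractions = as.numeric(C %*% fractions(mid)))
}

## bare-vector convolution kernel shared by convolveMids and the ODE core
.conv_frac <- function(fa, fb) {
  na <- length(fa); nb <- length(fb)
  out <- numeric(na + nb - 1L)
  for (k in seq_len(nb)) {
    idx <- k:(k + na - 1L)
    out[idx] <- out[idx] + fb[k] * fa
  }
  out
}

#' Condensation convolution of two MIDs
#'
#' The MID of a condensation product (e.g. citrate from oxaloacetate +
#' acetyl-CoA) is the discrete convolution of the substrate MIDs: the product
#' carries i + j labels whenever the substrates carry i and j.
#'
#' @param a,b \linkS4class{MID} objects.
#' @return an \linkS4class{MID} on \code{nCarbons(a) + nCarbons(b)} carbons.
#' @export
convolveMids <- function(a, b) {
  stopifnot(is(a, "MID"), is(b, "MID"))
  new("MID", nCarbons = nCarbons(a) + nCarbons(b),
      fractions = .conv_frac(fractions(a), fractions(b)))
}

## bare-vector decarboxylation kernel; returns list(fractions, co2)
.decarb_frac <- function(f) {
  n <- length(f) - 1L
  j <- 0:(n - 1L)
  g <- f[j + 2L] * (j + 1L) / n + f[j + 1L] * (n - j) / n
  list(fractions = g, co2 = sum((0:n) * f) / n)
}

#' Decarboxylation of a MID
#'
#' Removes one carbon under the exchangeable-positions (hypergeometric)
#' model: a molecule carrying i of n labels loses a labeled carbon with
#' probability i/n. Returns the product MID on n - 1 carbons together with
#' the fraction of released CO2 that is labeled. Expected labeled carbons are
#' conserved: \eqn{\sum_i i f_i = \sum_j j g_j + co2}.
#'
#' @param mid an \linkS4class{MID} with at least 2 carbons.
#' @return list with elements \code{mid} (the product \linkS4class{MID}) and
#'   \code{labeledCO2} (numeric in [0, 1]).
#' @examples
#' d <- decarboxylateMid(MID(c(0, 0, 0, 0, 0, 1), 5)) # M5 -> M4, CO2 labeled
#' d$labeledCO2 # 1
#' @export
decarboxylateMid <- function(mid) {
  stopifnot(is(mid, "MID"))
  n <- nCarbons(mid)
  if (n < 2L) stop("TooFewCarbons: decarboxylation needs >= 2 carbons")
  d <- .decarb_frac(fractions(mid))
  list(mid = new("MID", nCarbons = n - 1L, fractions = d$fractions),
       labeledCO2 = d$co2)
}

#' Ratio of two intracellular pool concentrations
#'
#' Simple concentration ratio, e.g. the alpha-ketoglutarate/succinate ratio
#' used as an index of alpha-KG diversion away from oxidation.
#'
#' @param conc named numeric vector of pool concentrations (uM/5e5 cells).
#' @param num,den metabolite names.
#' @return numeric ratio.
#' @export
metaboliteRatio <- function(conc, num, den) {
  miss <- setdiff(c(num, den), names(conc))
  if (length(miss))
    stop("MissingMetabolite: ", paste(miss, collapse = ", "))
  if (conc[[den]] == 0) stop("ZeroDenominator: ", den)
  unname(conc[[num]] / conc[[den]])
}
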