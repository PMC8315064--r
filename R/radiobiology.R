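#' Survival fractions from clonogenic colony counts
#'
#' Each stratum (independent experiment/replicate within a cell line and
#' condition) is normalized to its own unirradiated control: plating
#' efficiency PE = colonies/cells_plated at 0 Gy, and SF(d) =
#' (colonies/cells_plated)/PE, so SF(0) = 1 by construction.
#'
#' @param records data.frame with columns \code{cell_line}, \code{condition},
#'   \code{replicate}, \code{dose_gy}, \code{cells_plated}, \code{colonies}.
#' @return data.frame with columns \code{cell_line}, \code{condition},
#'   \code{replicate}, \code{stratum}, \code{dose_gy}, \code{pe}, \code{sf}.
#' @export
survivalFraction <- function(records) {
  need <- c("cell_line", "condition", "replicate", "dose_gy",
            "cells_plated", "colonies")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(records$colonies > records$cells_plated))
    stop("colonies cannot exceed cells plated")
  if (any(records$dose_gy < 0)) stop("doses must be nonnegative")
  records$stratum <- interaction(records$cell_line, records$condition,
                                 records$replicate, drop = TRUE)
  out <- lapply(split(records, records$stratum), function(g) {
    ctrl <- g[g$dose_gy == 0, , drop = FALSE]
    if (nrow(ctrl) == 0)
      stop("NoControlDose: stratum ", g$stratum[1], " has no 0 Gy row")
    if (sum(ctrl$colonies) == 0)
      stop("ZeroControlColonies: stratum ", g$stratum[1])
    pe <- sum(ctrl$colonies) / sum(ctrl$cells_plated)
    data.frame(cell_line = g$cell_line, condition = g$condition,
               replicate = g$replicate, stratum = as.character(g$stratum),
               dose_gy = g$dose_gy, pe = pe,
               sf = (g$colonies / g$cells_plated) / pe)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Fit the linear-quadratic survival model
#'
#' Least-squares fit of \eqn{\ln SF = a D + b D^2} on the pooled,
#' per-stratum-normalized survival fractions, with the intercept fixed at
#' zero so SF(0) = 1 in every stratum ("stratified" regression: each
#' experiment is anchored to its own control and a common alpha/beta is
#' estimated across strata). Returned \code{alpha = -a} and \code{beta = -b}
#' are the positive radiosensitivity parameters of
#' \eqn{SF(D) = \exp(-(\alpha D + \beta D^2))}. Optionally estimates
#' per-stratum intercepts instead of anchoring them, or weights the ln SF
#' points by the Poisson delta-method variance 1/colonies.
#'
#' @param sfTable data.frame as returned by \code{\link{survivalFraction}}
#'   (needs \code{stratum}, \code{dose_gy}, \code{sf}; \code{colonies} only
#'   for Poisson weighting).
#' @param stratumIntercepts logical; if TRUE estimate a free intercept per
#'   stratum instead of fixing them at zero.
#' @param weighting "none" (default) or "poisson" (weights = colonies).
#' @return an \linkS4class{LQFit}.
#' @examples
#' d <- expand.grid(stratum = "s1", dose_gy = c(0, 2, 4, 6))
#' d$sf <- exp(-(0.2 * d$dose_gy + 0.05 * d$dose_gy^2))
#' fitLQ(d)
#' @export
fitLQ <- function(sfTable, stratumIntercepts = FALSE,
                  weighting = c("none", "poisson")) {
  weighting <- match.arg(weighting)
  need <- c("stratum", "dose_gy", "sf")
  miss <- setdiff(need, names(sfTable))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (length(unique(sfTable$dose_gy)) < 3L)
    stop("TooFewDoses: need >= 3 distinct doses to fit alpha and beta")
  if (any(sfTable$sf <= 0))
    stop("NonPositiveSF: log survival undefined at SF <= 0")
  d <- data.frame(y = log(sfTable$sf), D = sfTable$dose_gy,
                  stratum = factor(sfTable$stratum))
  w <- if (weighting == "poisson") {
    if (!"colonies" %in% names(sfTable))
      stop("Poisson weighting needs a colonies column")
    sfTable$colonies
  } else rep(1, nrow(d))
  fit <- if (stratumIntercepts && nlevels(d$stratum) >= 1L)
    stats::lm(y ~ 0 + stratum + D + I(D^2), data = d, weights = w)
  else
    stats::lm(y ~ 0 + D + I(D^2), data = d, weights = w)
  cf <- stats::coef(fit)
  ## vcov warns on exactly noiseless data; the point estimates are still exact
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  ic <- cf[grep("^stratum", names(cf))]
  names(ic) <- sub("^stratum", "", names(ic))
  if (!length(ic)) ic <- stats::setNames(rep(0, nlevels(d$stratum)),
                                         levels(d$stratum))
  new("LQFit", alpha = unname(-cf["D"]), beta = unname(-cf["I(D^2)"]),
      se = c(alpha = unname(se["D"]), beta = unname(se["I(D^2)"])),
      nPoints = nrow(d), stratumIntercepts = ic)
}

setMethod("show", "LQFit", function(object) {
  cat(sprintf(
    "Linear-quadratic fit: alpha = %.4f Gy^-1 (se %.4f), beta = %.4f Gy^-2 (se %.4f), n = %d\n",
    object@alpha, object@se["alpha"], object@beta, object@se["beta"],
    object@nPoints))
  invisible(object)
})

#' Predicted survival fraction under a fitted LQ model
#'
#' @param fit an \linkS4class{LQFit}.
#' @param dose numeric vector of doses (Gy).
#' @return numeric survival fractions.
#' @export
predictSF <- function(fit, dose) {
  stopifnot(is(fit, "LQFit"))
  exp(-(fit@alpha * dose + fit@beta * dose^2))
}

#' Mann-Whitney (Wilcoxon rank-sum) test with exact small-sample enumeration
#'
#' Two-sided test of a location difference between two samples. When both
#' group sizes are at most \code{exactMax} the p-value is computed by full
#' enumeration of all group assignments of the pooled values (which handles
#' ties exactly); otherwise a normal approximation with mid-ranks, tie
#' correction and continuity correction is used. The two-sided exact p-value
#' is the permutation probability of a U statistic at least as far from its
#' null mean as the observed one.
#'
#' @param x,y numeric samples.
#' @param exactMax largest per-group size for exact enumeration (default 8).
#' @return list with \code{U} (statistic for \code{x}), \code{p},
#'   \code{method}.
#' @export
mannWhitneyTest <- function(x, y, exactMax = 8L) {
  x <- as.numeric(x); y <- as.numeric(y)
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups must be non-empty")
  pooled <- c(x, y)
  r <- rank(pooled)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 <= exactMax && n2 <= exactMax) {
    idx <- utils::combn(n1 + n2, n1)
    Us <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
    p <- mean(abs(Us - mu) >= abs(U_obs - mu) - 1e-12)
    return(list(U = U_obs, p = p, method = "exact enumeration"))
  }
  ties <- table(r)
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  z <- (abs(U_obs - mu) - 0.5) / sqrt(sigma2)
  z <- max(z, 0)
  list(U = U_obs, p = min(1, 2 * stats::pnorm(z, lower.tail = FALSE)),
       method = "normal approximation")
}

#' Radiation enhancement/diminishment ratios
#'
#' For each dose and replicate, the ratio of the treated survival fraction to
#' the control survival fraction at the same dose. Ratios below 1 indicate
#' radiosensitization (enhancement), above 1 diminishment. Two groups of
#' ratios (e.g. tumor vs benign cultures) are compared with
#' \code{\link{compareEnhancement}}.
#'
#' @param treatedSf,controlSf data.frames as from
#'   \code{\link{survivalFraction}}, with matching (replicate, dose) grids.
#' @param dropZeroDose drop the trivially-1 ratios at 0 Gy (default TRUE).
#' @return data.frame with columns \code{replicate}, \code{dose_gy},
#'   \code{ratio}.
#' @export
enhancementRatio <- function(treatedSf, controlSf, dropZeroDose = TRUE) {
  key <- function(d) paste(d$replicate, d$dose_gy, sep = "@")
  kt <- key(treatedSf); kc <- key(controlSf)
  if (length(kt) != length(kc) || !setequal(kt, kc) ||
      anyDuplicated(kt) || anyDuplicated(kc))
    stop("DoseMismatch: treated and control (replicate, dose) grids differ")
  m <- match(kt, kc)
  if (any(controlSf$sf[m] <= 0)) stop("control SF must be positive")
  out <- data.frame(replicate = treatedSf$replicate,
                    dose_gy = treatedSf$dose_gy,
                    ratio = treatedSf$sf / controlSf$sf[m])
  if (dropZeroDose) out <- out[out$dose_gy > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @rdname enhancementRatio
#' @param ratiosA,ratiosB numeric vectors of ratios, or data.frames from
#'   \code{enhancementRatio} (their \code{ratio} columns are used).
#' @param exactMax passed to \code{\link{mannWhitneyTest}}.
#' @export
compareEnhancement <- function(ratiosA, ratiosB, exactMax = 8L) {
  pick <- function(r) if (is.data.frame(r)) r$ratio else as.numeric(r)
  mannWhitneyTest(pick(ratiosA), pick(ratiosB), exactMax = exactMax)
}

#' Foci counts normalized to nucleus size
#'
#' Elementwise foci count per unit nuclear area (e.g. residual gammaH2A.X
#' foci), with an optional per-condition mean +/- sd summary.
#'
#' @param fociCounts nonnegative numeric vector.
#' @param nucleusAreas positive numeric vector, same length.
#' @param condition optional grouping vector for the summary.
#' @return list with \code{values} (counts/area) and \code{summary}
#'   (data.frame of condition, n, mean, sd).
#' @export
fociPerNucleus <- function(fociCounts, nucleusAreas, condition = NULL) {
  if (length(fociCounts) != length(nucleusAreas))
    stop("LengthMismatch: counts and areas differ in length")
  if (any(nucleusAreas <= 0)) stop("ZeroArea: nucleus areas must be positive")
  if (any(fociCounts < 0)) stop("foci counts must be nonnegative")
  v <- fociCounts / nucleusAreas
  grp <- if (is.null(condition)) rep("all", length(v)) else as.character(condition)
  sm <- do.call(rbind, lapply(split(v, grp), function(g)
    data.frame(n = length(g), mean = mean(g), sd = stats::sd(g))))
  sm <- data.frame(condition = rownames(sm), sm, row.names = NULL)
  list(values = v, summary = sm)
}
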