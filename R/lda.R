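#' Hemiellipsoid tumor volume
#'
#' V = (L * W * H) / 2 from caliper length, width and height in mm.
#'
#' @param L,W,H nonnegative dimensions (mm); vectors recycle as usual.
#' @return volume(s) in mm^3.
#' @export
tumorVolume <- function(L, W, H) {
  if (any(c(L, W, H) < 0)) stop("NegativeDimension: dimensions must be >= 0")
  (L * W * H) / 2
}

## single-hit Poisson log-likelihood for an LDA table at log-frequency b
.lda_loglik <- function(b, dose, tested, positive) {
  f <- exp(b)
  pneg <- exp(-f * dose)
  neg <- tested - positive
  pos <- positive > 0
  sum(neg * (-f * dose)) + sum(positive[pos] * log1p(-pneg[pos]))
}

#' Fit the single-hit Poisson limiting-dilution model
#'
#' Estimates the tumor-initiating cell frequency f under
#' P(no tumor | dose d) = exp(-f d): binomial regression of the response on
#' log(dose) through a complementary log-log link (the standard extreme
#' limiting dilution formulation), maximized directly on the bounded
#' log-frequency scale so the estimate stays in (0, 1] even on nearly
#' separated tables. The 95% CI comes from the profile likelihood (Wald
#' interval from the observed information as fallback); goodness of fit is
#' the residual deviance against the saturated model. Degenerate tables
#' follow the usual convention: all-negative tables report only a finite
#' upper bound, all-positive tables only a lower bound.
#'
#' @param table data.frame with columns \code{dose_cells} (cells injected
#'   per implant), \code{n_tested}, \code{n_positive} (implants forming a
#'   tumor); or \code{dose}, \code{tested}, \code{positive}.
#' @param conf confidence level, default 0.95.
#' @return an \linkS4class{LDAFit}.
#' @examples
#' t1 <- data.frame(dose_cells = c(100, 1000, 10000), n_tested = 6,
#'                  n_positive = c(0, 3, 6))
#' fitLDA(t1)
#' @export
fitLDA <- function(table, conf = 0.95) {
  tab <- .as_lda_table(table)
  dose <- tab$dose; tested <- tab$tested; positive <- tab$positive
  qcrit <- stats::qchisq(conf, df = 1)
  ll <- function(b) .lda_loglik(b, dose, tested, positive)

  if (sum(positive) == 0L) {
    ## likelihood maximal at f -> 0; one-sided upper profile bound
    up <- stats::uniroot(function(b) ll(b) + qcrit / 2,
                         lower = log(1e-16), upper = 0, tol = 1e-12)$root
    return(new("LDAFit", frequency = NA_real_, lower = 0, upper = exp(up),
               logLik = 0, deviance = 0, dfResidual = length(dose) - 1L,
               status = "all_negative"))
  }
  if (sum(positive) == sum(tested)) {
    ## likelihood increasing in f; one-sided lower bound, cap at f = 1
    llmax <- ll(0)
    lo <- stats::uniroot(function(b) ll(b) - (llmax - qcrit / 2),
                         lower = log(1e-16), upper = 0, tol = 1e-12)$root
    return(new("LDAFit", frequency = NA_real_, lower = exp(lo), upper = 1,
               logLik = llmax, deviance = 0,
               dfResidual = length(dose) - 1L, status = "all_positive"))
  }

  ## MLE of the complementary log-log intercept (log frequency), maximized
  ## directly on b in [log 1e-16, 0] so f <= 1 by construction; equals the
  ## cloglog-GLM-with-offset estimate on regular tables but stays finite on
  ## nearly separated ones
  opt <- stats::optimize(ll, c(log(1e-16), 0), maximum = TRUE,
                         tol = .Machine$double.eps^0.5)
  b_hat <- opt$maximum
  llmax <- opt$objective
  if (ll(0) > llmax) { b_hat <- 0; llmax <- ll(0) }
  target <- llmax - qcrit / 2
  lo <- tryCatch(
    stats::uniroot(function(b) ll(b) - target, lower = b_hat - 40,
                   upper = b_hat, tol = 1e-12)$root,
    error = function(e) NA_real_)
  hi <- tryCatch(
    stats::uniroot(function(b) ll(b) - target, lower = b_hat,
                   upper = min(b_hat + 40, log(1)), tol = 1e-12)$root,
    error = function(e) NA_real_)
  if (is.na(lo) || is.na(hi)) {  # Wald fallback on the log-frequency scale
    h <- 1e-5
    d2 <- (ll(b_hat + h) - 2 * llmax + ll(b_hat - h)) / h^2
    se <- if (is.finite(d2) && d2 < 0) 1 / sqrt(-d2) else Inf
    z <- stats::qnorm(1 - (1 - conf) / 2)
    if (is.na(lo)) lo <- b_hat - z * se
    if (is.na(hi)) hi <- min(b_hat + z * se, 0)
  }
  ## residual deviance against the saturated model (binomial constants cancel)
  p_hat <- positive / tested
  ll_sat <- sum(ifelse(positive > 0, positive * log(p_hat), 0) +
                ifelse(positive < tested,
                       (tested - positive) * log(1 - p_hat), 0))
  new("LDAFit", frequency = exp(b_hat), lower = exp(lo),
      upper = min(exp(hi), 1), logLik = llmax,
      deviance = 2 * (ll_sat - llmax),
      dfResidual = length(dose) - 1L, status = "ok")
}

.as_lda_table <- function(table) {
  nm <- names(table)
  pick <- function(a, b) if (a %in% nm) table[[a]] else table[[b]]
  dose <- pick("dose_cells", "dose")
  tested <- pick("n_tested", "tested")
  positive <- pick("n_positive", "positive")
  if (is.null(dose) || is.null(tested) || is.null(positive))
    stop("LDA table needs dose_cells, n_tested, n_positive columns")
  if (any(dose <= 0)) stop("doses must be positive")
  if (any(positive < 0 | positive > tested))
    stop("need 0 <= n_positive <= n_tested")
  list(dose = as.numeric(dose), tested = as.integer(tested),
       positive = as.integer(positive))
}

setMethod("show", "LDAFit", function(object) {
  if (object@status == "ok") {
    cat(sprintf(
      "Tumor-initiating cell frequency: 1 in %.0f (%.4g%%)\n95%% CI: 1 in %.0f - 1 in %.0f\n",
      1 / object@frequency, 100 * object@frequency,
      1 / object@upper, 1 / object@lower))
  } else {
    cat(sprintf("Degenerate table (%s); 95%% bound on frequency: [%.3g, %.3g]\n",
                object@status, object@lower, object@upper))
  }
  cat(sprintf("deviance %.3f on %d df\n", object@deviance, object@dfResidual))
  invisible(object)
})

#' Frequency of tumor-initiating cells in the three reporting formats
#'
#' @param fit an \linkS4class{LDAFit}.
#' @return list with \code{frequency}, \code{oneIn} ("1 in N"),
#'   \code{percent}.
#' @export
ldaFrequency <- function(fit) {
  stopifnot(is(fit, "LDAFit"))
  f <- fit@frequency
  list(frequency = f, oneIn = if (is.na(f)) NA_real_ else ceiling(1 / f),
       percent = 100 * f)
}

#' Likelihood-ratio comparison of two limiting-dilution groups
#'
#' Tests a shared tumor-initiating cell frequency against group-specific
#' frequencies (1 df chi-square), the standard limiting-dilution group
#' difference test. Degenerate groups (all negative or all positive) enter
#' through their boundary-maximized likelihood, so the test remains defined;
#' the pooled table must be non-degenerate.
#'
#' @param tableA,tableB LDA tables as in \code{\link{fitLDA}}.
#' @return list with \code{statistic}, \code{df}, \code{p}, and the two
#'   \linkS4class{LDAFit}s.
#' @export
compareLDA <- function(tableA, tableB) {
  fa <- fitLDA(tableA)
  fb <- fitLDA(tableB)
  ta <- .as_lda_table(tableA); tb <- .as_lda_table(tableB)
  pooled <- data.frame(dose_cells = c(ta$dose, tb$dose),
                       n_tested = c(ta$tested, tb$tested),
                       n_positive = c(ta$positive, tb$positive))
  f0 <- fitLDA(pooled)
  if (f0@status != "ok")
    stop("pooled table is degenerate; no shared frequency is estimable")
  stat <- max(0, 2 * (fa@logLik + fb@logLik - f0@logLik))
  list(statistic = stat, df = 1L,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       fitA = fa, fitB = fb)
}

#' Tumor-take analysis: threshold crossing, Kaplan-Meier and log-rank
#'
#' An implant is scored as a tumor at the first measurement day its volume
#' reaches \code{threshold} (no interpolation between the weekly caliper
#' measurements); animals never reaching it are censored at their last
#' observation. Take-time distributions per group are estimated by the
#' product-limit (Kaplan-Meier) method and compared by the (Mantel-Cox)
#' log-rank test (k-group form for more than two groups).
#'
#' @param growth data.frame with columns \code{animal}, \code{group},
#'   \code{day} and either \code{volume_mm3} or the caliper columns
#'   \code{length_mm}, \code{width_mm}, \code{height_mm} (converted with
#'   \code{\link{tumorVolume}}).
#' @param threshold take threshold in mm^3, default 100.
#' @return list with \code{takes} (per-animal time/event/group table),
#'   \code{km} (a \code{survival::survfit} object), \code{chisq}, \code{df},
#'   \code{p}.
#' @export
tumorTakeAnalysis <- function(growth, threshold = 100) {
  need <- c("animal", "group", "day")
  miss <- setdiff(need, names(growth))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"volume_mm3" %in% names(growth)) {
    cal <- c("length_mm", "width_mm", "height_mm")
    if (!all(cal %in% names(growth)))
      stop("need volume_mm3 or caliper columns ", paste(cal, collapse = ", "))
    growth$volume_mm3 <- tumorVolume(growth$length_mm, growth$width_mm,
                                     growth$height_mm)
  }
  takes <- do.call(rbind, lapply(split(growth, growth$animal), function(g) {
    g <- g[order(g$day), , drop = FALSE]
    hit <- which(g$volume_mm3 >= threshold)
    data.frame(animal = g$animal[1], group = g$group[1],
               time = if (length(hit)) g$day[hit[1]] else max(g$day),
               event = as.integer(length(hit) > 0))
  }))
  rownames(takes) <- NULL
  groups <- unique(takes$group)
  if (length(groups) < 2L) stop("EmptyGroup: need >= 2 groups to compare")
  if (any(table(takes$group) == 0L)) stop("EmptyGroup")
  km <- survival::survfit(survival::Surv(time, event) ~ group, data = takes)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group, data = takes)
  df <- length(groups) - 1L
  list(takes = takes, km = km, chisq = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}
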