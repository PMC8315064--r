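# Shared fixtures built in code.

# a random valid MID on n carbons
random_mid <- function(n) {
  f <- runif(n + 1)
  MID(f / sum(f), n)
}

# brute-force condensation: enumerate all isotopologue pairs
conv_bruteforce <- function(fa, fb) {
  out <- numeric(length(fa) + length(fb) - 1L)
  for (i in seq_along(fa)) for (j in seq_along(fb))
    out[i + j - 1L] <- out[i + j - 1L] + fa[i] * fb[j]
  out
}

# a small model with fast pools for quick ODE-based tests
quick_spec <- function(...) synthSpec(...)

quick_model <- function(spec = quick_spec()) {
  buildFluxModel(spec@concentrations, synthDrivingTimecourse(spec))
}

# hand computation of the two-group log-rank chi-square statistic
logrank_bruteforce <- function(time, event, group) {
  g <- unique(group)
  stopifnot(length(g) == 2L)
  tab <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in tab) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g[1])
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# product-limit estimate by hand for one group
km_bruteforce <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (k in seq_along(tt)) {
    n <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / n)
    out[k] <- s
  }
  data.frame(time = tt, surv = out)
}
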