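---
title: "Models and methods behind glnflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind glnflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glnflux)
```

glnflux packages the quantitative backbone of a class of studies on
glutamine-driven tumor metabolism and radioresistance: a kinetic
mass-isotopologue model of [U-¹³C₅]-glutamine catabolism fitted to LC-MS/MS
labeling time courses, and the radiobiology statistics used alongside it
(clonogenic survival, radiation enhancement ratios, limiting-dilution
analysis of tumor-initiating cell frequency, tumor-take survival analysis).
This vignette explains each model, its assumptions, the tunable parameters,
and the numerical choices; the package README shows the worked example.

## Mass-isotopologue distributions

A metabolite with $n$ carbons is represented by its mass-isotopologue
distribution (MID): the vector $(f_0, \dots, f_n)$ of fractions of molecules
carrying $0 \dots n$ heavy carbons (M+0 … M+n). MIDs are validated on entry
(non-negative, summing to one; sums off by at most $10^{-3}$ — ordinary
peak-integration jitter — are renormalized, larger deviations rejected) and
kept normalized to $10^{-9}$ internally.

Only mass isotopologues are tracked, not positional isotopomers: LC-MS/MS in
MRM mode observes mass shifts, and molecular symmetry (e.g. succinate's)
does not affect mass distributions.

Three elementary operators drive the kinetic model:

* **Condensation** (`convolveMids`) — the product of a condensation carries
  the summed label of its substrates, so the product MID is the discrete
  convolution of the substrate MIDs.
* **Decarboxylation** (`decarboxylateMid`) — one carbon is removed under the
  exchangeable-positions model: a molecule with $i$ of $n$ labels loses a
  labeled carbon with probability $i/n$, giving product fractions
  $g_j = f_{j+1}(j+1)/n + f_j(n-j)/n$ and a labeled-CO₂ fraction
  $\sum_i i f_i / n$. This is exact for the dominant uniformly labeled
  first-turn species (M5 → M4) and a declared approximation for mixed
  species; expected labeled carbons are conserved exactly.
* **Natural-abundance correction** (`correctNaturalAbundance`) — a
  ¹³C-only binomial mixing matrix
  $C_{ji} = \binom{n-i}{j-i} p^{j-i} (1-p)^{n-j}$ (natural abundance
  $p = 0.0107$) is inverted by triangular solve, with a non-negativity clamp
  and renormalization. H/N/O isotopes are ignored. Whether measured tables
  should be corrected before fitting is left as an explicit user step
  (`applyNaturalAbundance` provides the forward model for testing either
  choice), since vendor peak-processing pipelines differ in whether they
  already correct.

## The one-compartment tracer model

Labeling is modeled over fixed intracellular pools — glutamate GLU(5C),
α-ketoglutarate AKG(5C), succinate+fumarate lumped as SUC(4C), malate
MAL(4C), oxaloacetate OAA(4C, reported as the aspartate mirror), citrate
CIT(6C), and bicarbonate HCO₃(1C) — driven by the *measured* glutamine MID
time course (piecewise-linear interpolation, constant extrapolation, an
unlabeled point forced at $t=0$ if absent). Acetyl-CoA is held unlabeled
because no significant enrichment reaches the glycolytic intermediates in
the cells this model targets. Pool concentrations are averaged over all
sampling times and held constant: metabolic steady state, with only isotope
ratios evolving.

Five free fluxes (µM/min per 5×10⁵ cells) wire the network:

| flux | reaction | notes |
|------|----------|-------|
| VGLS | GLN → GLU | glutaminase |
| VGDH | GLU → AKG | glutamine oxidation entry; VGDH ≤ VGLS |
| VTCA | OAA + AcCoA → CIT and onward | net cycle flux |
| VIDHr | AKG + CO₂ ↔ CIT | reversible IDH exchange |
| VCO2dil | unlabeled HCO₃ inflow | dilutes the bicarbonate pool |

Derived: the glutamate sink VGLS − VGDH (non-oxidative fates such as
glutathione synthesis), a balancing cataplerotic OAA exit equal to VGDH, and
the GLS/TCA ratio VGLS/VTCA. The AKG → SUC → MAL → OAA segment carries
VTCA + VGDH; CIT → AKG carries VTCA + VIDHr; both decarboxylating steps feed
their CO₂ label into the HCO₃ pool, whose efflux balances all inflows.
Inflow equals outflow for every pool identically in any feasible flux set —
asserted at model construction. The wiring is a declared reconstruction (the
anaplerotic entry at AKG, the equal cataplerotic OAA exit, and the glutamate
sink are the minimal closure consistent with the measured species); the
acetyl-CoA MID and an optional glutamate/AKG exchange flux (default 0,
absent from the named fluxes) are configurable.

Isotopologue balances give, for each pool $P$ with concentration $C_P$,
$$\dot m_P = \frac{1}{C_P}\Big[\sum_{\text{in}} v \, m_{\text{delivered}}
 - \Big(\sum_{\text{out}} v\Big) m_P\Big],$$
36 states in total, integrated with a stiff-capable adaptive solver
(deSolve's lsoda) at rtol $10^{-8}$, atol $10^{-10}$. Two structural
consequences are worth noting, because the fitting relies on them: citrate
M+6 can arise **only** through VIDHr acting on M+5 AKG together with labeled
bicarbonate (with unlabeled acetyl-CoA the condensation route saturates at
M+4), and jointly rescaling all fluxes and all concentrations leaves the
labeling trajectories unchanged — concentrations must therefore be measured,
not fitted.

## Flux estimation

`fitFluxes` minimizes the weighted SSE between simulated and observed MID
fractions of the measured pools (glutamate, malate, aspartate, citrate) at
the measured times, with weight $1/\sigma$ per point ($\sigma = 0.02$ by
default, the replicate scatter typical of targeted LC-MS/MS fraction
estimates; a per-pool σ or scalar-enrichment fitting are options). The
optimizer works in transformed coordinates — log fluxes, with VGDH
parameterized as a logistic fraction of VGLS so the glutaminase flux always
covers oxidation — inside bounds $[10^{-4}, 10^3]$ µM/min. Twenty seeded
log-uniform starts are screened on the objective; the best six are refined
by box-constrained Levenberg–Marquardt (minpack.lm), and the incumbent is
restarted once, which in practice rescues occasional stalls of the damping
schedule on this landscape. The default optimizer seed (20210626) makes fits
bit-reproducible. Each replicate time course is fitted separately with its
own measured glutamine driving curve; final fluxes are arithmetic means
across replicates, and the GLS/TCA ratio is the mean of per-replicate
ratios.

## What the synthetic generators emulate

`synthSpec` fixes the ground truth for every generator; one master seed fans
out to per-generator substreams, so outputs are byte-identical and each
table can be regenerated independently.

* **Tracing** (`genMidTimecourses`): sampling at 0/10/30/90 min, three
  independent replicates, intracellular glutamine labeling rising
  exponentially (τ = 5 min) to an M+5 plateau of 0.98 after the medium swap
  to 2 mM [U-¹³C₅]-glutamine. Downstream pools are simulated at the true
  fluxes with the driving built from the *sampled* glutamine grid, so the
  generated data are exactly self-consistent with the fitting procedure.
  Noise is additive truncated Gaussian on fractions (sd 0.02) followed by
  renormalization — simple and declared, rather than a Dirichlet model.
* **Clonogenic assay** (`genClonogenic`): colonies ~
  Binomial(cells plated, PE·SF(D)) at 0/2/4/6 Gy, 1000 cells, three strata,
  true α = 0.3 Gy⁻¹, β = 0.03 Gy⁻², plating efficiency 0.2.
* **Limiting dilution** (`genLda`): takes ~ Binomial(6, 1 − e^{−f·dose}) at
  10²/10³/10⁴ cells per implant.
* **Tumor growth** (`genTumorGrowth`): weekly caliper measurements over 140
  days; takers grow exponentially through the 100 mm³ threshold at an
  animal-specific lagged day, non-takers stay at background.

The default true fluxes (VGLS 25, VGDH 15, VTCA 15, VIDHr 20, VCO2dil 25)
and pools (GLU 300, AKG 25, SUC 50, MAL 60, OAA 25, CIT 50, HCO₃ 800 µM per
5×10⁵ cells) were chosen once as plausible values for glutamine-avid cancer
cells whose labeling evolves visibly across the 0–90 min grid — glutamate
turnover ~12 min, fast downstream pools, substantial IDH exchange (exchange
fluxes commonly rival or exceed net flux, and an observable citrate M+6
requires them to). A linearized information analysis of this design shows
VGLS, VGDH, VTCA and VIDHr are estimated with 2–6% precision from three
replicates at 2% noise, while **VCO2dil is intrinsically weakly identified**
(≳15–30% sd): its only signature is a modest modulation of citrate M+5/M+6
through bicarbonate labeling. That limitation is a property of the assay
design (four time points, fraction-level noise), not of the optimizer —
noiseless recovery is exact to well below 1% — and holds across every
physiologically sensible parameter set we scanned. Users should treat
fitted bicarbonate-dilution fluxes as order-of-magnitude estimates.

What the generators do **not** emulate: peak integration artifacts,
metabolite-specific noise, natural-abundance contamination (tables are
generated tracer-pure; the forward model is available separately),
inter-replicate concentration drift beyond simple scatter, or biological
deviations from the model topology. Passing recovery tests therefore shows
the estimator is correct and precise *under the model*, not that the model
is correct for any particular cell line.

## Clonogenic survival and enhancement ratios

Survival fractions normalize each stratum (independent experiment) to its
own unirradiated control, so SF(0) = 1 by construction; the
linear-quadratic model is then fitted by least squares on
$\ln SF = -( \alpha D + \beta D^2 )$ with the intercept fixed at zero —
the "stratified" regression: common (α, β) across strata, each anchored to
its own control. Free per-stratum intercepts and Poisson (1/colonies)
weighting are available by flag. α and β are reported as positive
radiosensitivity parameters of $SF = e^{-(\alpha D + \beta D^2)}$; on the
equivalent convention $S(D)/S(0) = e^{aD + bD^2}$ the printed coefficients
are simply negated. On noiseless data the inversion is exact.

Enhancement (or diminishment) ratios divide the treated survival fraction by
the control survival fraction at the same dose and replicate; ratios below
one indicate radiosensitization. Groups of ratios are compared with a
two-sided Mann–Whitney test whose p-value is computed by **full enumeration
of group assignments** when both groups have ≤ 8 observations (ties handled
exactly; identical groups give p = 1 by symmetry), and by a mid-rank normal
approximation with tie and continuity corrections otherwise.

## Limiting dilution and tumor take

Under the single-hit Poisson model an implant of $d$ cells stays tumor-free
with probability $e^{-fd}$, $f$ the tumor-initiating cell frequency. The
binomial likelihood is maximized on the log-frequency scale (the
complementary log-log regression of take on log dose, maximized directly on
the bounded scale so $f \le 1$ even for nearly saturated tables); 95%
intervals come from the profile likelihood, with a Wald fallback from the
observed information. Degenerate tables follow the usual convention: all
negative → finite upper bound only; all positive → lower bound only; both
enter group comparisons through their boundary likelihood. The group test is
the 1-df likelihood ratio of shared versus group-specific frequency.
Frequencies are reported as $f$, "1 in ⌈1/f⌉", and percent. Goodness of fit
is the residual deviance against the saturated model — always reported,
never used as a gate.

Tumor take is scored at the first measurement day the hemiellipsoid volume
$V = (L \cdot W \cdot H)/2$ reaches 100 mm³ (no interpolation between the
weekly measurements, matching the caliper schedule); animals never reaching
it are censored at their last observation. Take-time curves are product-
limit estimates and groups are compared with the Mantel–Cox log-rank test
(k-group form beyond two groups), via the survival package.

## Numerical choices and degenerate inputs

* MID input tolerance $10^{-3}$, internal tolerance $10^{-9}$; ODE
  trajectories keep sum-to-one drift below $10^{-6}$.
* Optimizer bounds $[10^{-4}, 10^3]$ µM/min; a flux fitted at the lower
  bound (e.g. VIDHr when citrate M+6 is absent) should be read as zero.
* Profile-likelihood roots are bracketed within ±40 log units of the MLE
  and solved to $10^{-12}$; the single-dose table reduces to the analytic
  closed form $f = -\ln(1 - p)/d$.
* LQ fitting requires ≥ 3 distinct doses and positive SF everywhere;
  zero-colony wells at positive dose must be handled upstream (they make
  $\ln SF$ undefined).
* Problem sizes in the test suite — one noiseless plus three noisy replicate
  fits for flux recovery, 500 simulations for CI coverage, 60 for the group
  comparison power check — were chosen to make the Monte Carlo verdicts
  stable at desk scale.

## Known limitations

* No positional-isotopomer (EMU) resolution, no compartmentation
  (cytosol/mitochondria), no glycolytic reactions.
* The decarboxylation operator assumes exchangeable label positions within
  a mass isotopologue — exact for first-turn species only.
* VCO2dil is weakly identified at realistic noise (see above).
* The LQ fit treats ln SF points as homoscedastic by default; use Poisson
  weighting when colony counts are small.
* Take-time censoring ignores interval censoring between weekly
  measurements.
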