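# glnflux

Kinetic flux analysis of [U-¹³C₅]-glutamine tracing experiments, plus the
radiobiology statistics that accompany studies of glutamine-driven tumor
metabolism and radioresistance.

Cancer cells that resist ionizing radiation often rewire glutamine
catabolism: glutaminase (GLS) converts glutamine to glutamate, which either
enters the TCA cycle through α-ketoglutarate or is diverted to non-oxidative
fates such as glutathione synthesis. Quantifying that split requires fitting
a kinetic model to mass-isotopologue time courses, and assessing its
consequences requires clonogenic survival fits, radiation enhancement
ratios, and in vivo limiting-dilution estimates of tumor-initiating cell
frequency. glnflux implements all of these as one tested pipeline, with
seeded synthetic-data generators so every stage runs without laboratory
inputs.

## The models

**Tracer kinetics.** Mass-isotopologue distributions (MIDs) of glutamate,
α-ketoglutarate, succinate/fumarate, malate, oxaloacetate (aspartate
mirror), citrate and bicarbonate evolve over fixed pool concentrations
(metabolic steady state), driven by the measured glutamine MID time course:

    dm_P/dt = (1/C_P) [ Σ v_in · m_delivered − (Σ v_out) · m_P ]

with condensation as MID convolution and decarboxylation feeding labeled CO₂
into the bicarbonate pool. Five fluxes are estimated (µM/min per 5×10⁵
cells): VGLS (glutaminase), VGDH (glutamine oxidation entry), VTCA (net
cycle flux), VIDHr (reversible IDH exchange — the only route to M+6
citrate from [U-¹³C₅]-glutamine when acetyl-CoA is unlabeled) and VCO2dil
(unlabeled bicarbonate inflow). Fitting is multi-start, box-constrained
Levenberg–Marquardt on weighted MID residuals; replicates are fitted
separately and averaged.

**Radiobiology.** Clonogenic survival is normalized per stratum and fitted
to the linear-quadratic model SF(D) = exp(−(αD + βD²)) by stratified
regression through the origin of ln SF. Enhancement ratios
SF_treated/SF_control at matched doses are compared with an exact
(full-enumeration) Mann–Whitney test for small samples. Limiting-dilution
tables are fitted under the single-hit Poisson model P(no take) =
exp(−f·dose) with profile-likelihood intervals and a likelihood-ratio group
test; tumor take (volume (L·W·H)/2 ≥ 100 mm³) is analyzed with
Kaplan–Meier curves and the Mantel–Cox log-rank test.

## Worked example

Everything below is computed from synthetic data with published-style
designs; `synthSpec()` carries the ground truth and one master seed.

```r
library(glnflux)
spec <- synthSpec()                      # seed 20210626, 3 replicates, 2% noise

## 13C5-glutamine tracing -> flux estimation
dat <- genMidTimecourses(spec)           # long MID table + concentrations
est <- estimateFluxes(dat$mids, dat$concentrations)
est
#> FluxEstimate over 3 replicate fit(s)
#> mean fluxes (uM/min per 5e5 cells):
#>    VGLS    VGDH    VTCA   VIDHr VCO2dil
#> 25.3956 14.7121 13.9294 17.5280 28.3082
#> mean GLS/TCA ratio: 1.8334
```

The generating truth was VGLS 25, VGDH 15, VTCA 15, VIDHr 20, VCO2dil 25:
the glutaminase and oxidation fluxes come back within ~2%, the net cycle
flux within ~7%, while the IDH exchange and bicarbonate dilution fluxes —
identified only through the small citrate M+5/M+6 fractions — carry
~12–13% error at this noise level. The methods vignette quantifies these
information limits. The derived GLS/TCA ratio is the mean of per-replicate
VGLS/VTCA.

```r
## clonogenic survival -> linear-quadratic parameters
lq <- fitLQ(survivalFraction(genClonogenic(spec)))
lq
#> Linear-quadratic fit: alpha = 0.2969 Gy^-1 (se 0.0609),
#>                       beta  = 0.0343 Gy^-2 (se 0.0115), n = 12
```

True values were α = 0.3 Gy⁻¹ and β = 0.03 Gy⁻²: binomial colony noise at
1000 cells/plate across three strata leaves both within 15%.

```r
## limiting dilution -> tumor-initiating cell frequency
lda <- genLda(spec)
fitLDA(lda[lda$group == "control", ])
#> Tumor-initiating cell frequency: 1 in 2340 (0.04273%)
#> 95% CI: 1 in 863 - 1 in 6553
#> deviance 0.687 on 2 df

compareLDA(lda[lda$group == "control", ], lda[lda$group == "starved", ])$p
#> [1] 0.01734

## tumor take at the 100 mm3 threshold
take <- tumorTakeAnalysis(genTumorGrowth(spec))
c(chisq = take$chisq, p = take$p)
#>     chisq         p
#> 11.862000  0.000573
```

The control group was generated at f = 10⁻³ (1 in 1000; the 95% CI covers
it), the starved group at 10⁻⁴; the likelihood-ratio test separates them at
p ≈ 0.017, and the log-rank test separates the take-time curves of the two
growth groups.

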