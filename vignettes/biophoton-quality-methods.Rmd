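---
title: "Methods: delayed-luminescence analysis and quality screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: delayed-luminescence analysis and quality screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biophotonQC)
```

## The measurement and the model

Living leaf tissue emits ultra-weak light in two regimes. *Spontaneous
photon emission* (SPE) is the steady-state glow of metabolic redox
chemistry, tens to hundreds of photon counts per second on a
photomultiplier. *Delayed luminescence* (DL) is the relaxation that
follows a light stimulus: after illumination ends, the emission decays
over minutes back toward the spontaneous baseline. Both regimes are
recorded as photon counts in fixed 1-second bins; `photon_trace` is the
container for such a run (DL, SPE, or an instrument background run).

The DL decay is modelled with the hyperbolic-cosecant (Gu) law

$$I(t) = A \,\mathrm{csch}^2\!\left(\frac{t}{B} + C\right),$$

where $A$ (counts/s scale) sets the intensity, $B$ (seconds) is a
characteristic time of the relaxation, and $C$ (dimensionless) is a phase
factor fixing the state at $t = 0$. The model requires $B, C > 0$; at
$C \le 0$ it diverges at the time origin, so such parameters are rejected
as a domain error. Three macroscopic quantities summarise a fitted curve:

* the initial intensity $I_0 = A\,\mathrm{csch}^2 C$,
* the decay time $T$, defined by $I(T) = I_0/m$ and available in closed
  form as $T = B\,(\operatorname{asinh}(\sqrt{m}\,\sinh C) - C)$,
* the window-mean intensity
  $I_W = \frac{AB}{W}\left[\coth C - \coth\!\left(\frac{W}{B}+C\right)\right]$
  over the measurement window $[0, W]$.

The decay factor $m$ conventionally lies in $[2,4]$; the package default is
$m = 3$, and the default window is $W = 300$ s, matching a five-minute
decay acquisition. The closed forms are unit-tested against a root-finder
and adaptive quadrature. SPE is summarised as the background-corrected
count rate $\mathrm{CPS} = N - n$, with $N$ the mean sample bin rate and
$n$ the mean rate of a dark background run of the same bin width. A
negative CPS (possible on pure noise) is flagged, never clamped.

Intensity-type quantities ($I_0$, $I_W$, CPS) scale with the amount and
geometry of tissue in the beam, so they are homogenised by multiplying by
leaf thickness (mm) and dividing by leaf mass (g); the shape quantities
($A$, $B$, $C$, $T$) are never normalised. Units for the normalisation are
fixed as mm and g for reproducibility.

## Fitting: bin integration and two-stage weighting

Counts are integrals of the intensity over bins, not point samples, so the
fitter compares observed bin rates with the *exact* integral of the model
over each bin, using the antiderivative $-AB\coth(t/B + C)$. This matters
early in the decay, where the curve falls appreciably within a single
1-second bin; midpoint evaluation would bias $C$ and hence $I_0$.

Estimation is least squares on the background-subtracted bin rates, with
parameters optimised on the log scale (which enforces positivity without
constrained optimisation) by Levenberg–Marquardt. Starting values come
from the data: the first-bin rate approximates $I_0$, the time for the
rate to fall to one third of the first bin approximates $B$, and a small
grid of phase factors ($C_0 \in \{0.3, 0.6, 1.0, 1.6\}$) provides
multi-start robustness; the best converged start is kept, and a fit that
never converges is returned flagged, with derived parameters withheld.

The default `weighting = "poisson"` is a two-stage generalised least
squares: an unweighted pilot fit supplies per-bin variances (model mean
plus background — the Poisson counting variance), and the final fit holds
those weights *fixed*. Letting the weights track the parameters during
optimisation (i.e. minimising Pearson's chi-square) systematically pulls
the amplitude down at low counts — in our simulations the median bias on
$A$ reached tens of percent on faint traces — whereas the frozen-weight
scheme keeps the median bias of all three parameters below 5% at the
study's intensity scales (this is verified by the parameter-recovery test
over 200 Poisson-simulated traces). `weighting = "uniform"` gives plain
least squares.

Background handling is explicit and switchable: the DL fitter subtracts
the rate estimated from the sample's own background run (pass
`background_rate = 0` to fit raw counts). Each of a sample's replicate
decay runs is fitted independently; downstream stages use the
across-replicate mean parameter set, with standard deviations retained
(`fit_dl_replicates()`).

## What the synthetic-data module emulates

`sim_config()` + `simulate_study()` + `simulate_assay_tables()` generate a
complete five-arm stress study (control, three salinity levels, drought;
six replicate runs per group) with the acquisition protocol used
throughout: a 300-s DL decay window in 1-s bins, three DL replicates per
sample, 600 one-second SPE bins, and a 600-s dark background run. Every
bin count is Poisson with mean equal to the exact model integral over the
bin plus the dark-count rate. Each trace draws from its own random stream
derived from `(seed, sample_id, run)` through an avalanche hash, so
generation order is irrelevant and a fixed seed reproduces every byte.

The decay-count magnitudes are the package's own defaults (control
$A = 2000$, $B = 15$ s, $C = 0.8$, SPE 120 counts/s over a 30 counts/s
dark rate), chosen so that stimulated emission is far brighter than the
spontaneous baseline, decays essentially to baseline within the window,
and single-run fits are stable — values typical of leaf tissue on a
cooled-PMT system. Stress acts by multiplying $A$ (and the SPE rate),
which halves the fitted $I_0$ at the severe-stress multiplier 0.5 while
leaving $B$, $C$ — and therefore $T$ — untouched: an intensity
("density") effect rather than a kinetic ("composition") effect. Group
multipliers for the quality endpoints follow the same pattern: contents of
the five marker compounds fall under stress (indirubin to 0.018% under
high salinity, below the 0.02% pharmacopoeial standard), pigments fall,
relative conductivity rises to 2.4–3× control, the ROS production rate
roughly doubles, and MIC shifts one or two steps up the two-fold dilution
ladder. Within-group variability is lognormal (8% CV on the photon
amplitudes, 5% on assay values), plus Poisson counting noise, plus
mass/thickness variation entering through the geometry normalisation.

What the generator does *not* emulate: PMT afterpulsing and dead time,
shutter and LED spectral dynamics, wavelength-resolved emission,
temperature drift, instrument ageing, or biological structure beyond the
group-level multipliers (no leaf-age or diurnal covariates, no
between-day batch effects). Passing tests therefore demonstrate that the
estimators recover what this statistical structure plants — they cannot
certify behaviour on real instrument quirks.

## Screening, tests and the correlation network

Seven candidate parameters per sample ($A$, $B$, $C$, $I_0$, $I_W$, $T$,
CPS, with the three intensity measures normalised) are screened for
control-vs-stressed discrimination by L1-penalised logistic regression
over a log-spaced penalty path with 10-fold cross-validation on binomial
deviance. The response is binary membership (control vs any stressed arm)
— a choice the package fixes because a deviance-based CV curve needs a
likelihood, and stress-arm identity is better examined afterwards by PCA
and per-arm tests. Folds are stratified by class and seed-controlled.
Features are standardised internally; coefficients are reported on both
scales. Selections are reported at both $\lambda_{\min}$ and
$\lambda_{1\text{-SE}}$ (the largest penalty within one standard error of
the CV minimum). Two properties are worth knowing: at the top of the path
all coefficients are zero, and under a pure-noise response the 1-SE rule
still admits a feature in roughly 10–20% of runs — the familiar
false-selection rate of the rule, which our null-simulation test measures
rather than wishes away.

Group differences use the two-tailed unpaired Student's t-test with
pooled variance (Welch available via `var_equal = FALSE`); the degenerate
all-constant case follows the convention $t = 0, P = 1$ for equal means.
Raw $P$ values are compared against the 0.05 threshold by default —
Benjamini–Hochberg is deliberately not applied anywhere, matching the
single-endpoint-at-a-time reporting style of stress-physiology studies;
users can adjust externally if they screen many endpoints.

Associations between photon parameters and quality endpoints use
Spearman's rank correlation (average ranks for ties). For $n \le 9$ the
two-sided $P$ is exact, by enumeration of all $n!$ rank permutations; for
larger $n$ the $t$-approximation on $n-2$ degrees of freedom is used. The
exact path is unit-tested against `stats::cor.test`'s exact null
distribution at $n = 5$. The network keeps an edge wherever $P \le 0.05$,
carrying $\rho$, $P$ and $\operatorname{sign}(\rho)$ (solid/dotted and
line-width conventions in figures); constant vectors — e.g. a per-group
consensus MIC in a null study — are skipped with a warning rather than
producing undefined correlations.

MIC calling uses the 80%-of-growth-control endpoint on
sterility-corrected OD600: the call is the lowest ladder concentration
whose corrected OD falls below 0.8 × the corrected growth control. This
threshold reading is monotone under OD perturbations (raising a well's OD
can only raise the call), which the literal "closest-OD-to-endpoint"
reading is not; the latter remains available via `rule = "closest"`.
Uninhibited plates are censored `> top`; fully inhibited plates are
flagged `<= bottom`. Replicate consensus is the mode, with ties resolved
toward the *higher* concentration — the conservative call for an
inhibitory endpoint.

Quality classification applies the pharmacopoeial indirubin marker rule:
a group passes when its content is at least 0.02% w/w, with the boundary
value passing (a ≥ rule, so a content exactly at standard is not failed).

## Numerical choices and degenerate inputs

* Bins are half-open $[k, k+1)$ s with $t = 0$ the first detection
  instant after illumination ends.
* All-zero DL traces, empty traces, wrong-kind traces and sub-10-bin
  traces are rejected with specific errors; non-converged fits withhold
  derived parameters rather than returning garbage.
* Negative pigment concentrations (possible under odd absorbance
  combinations) are reported with a warning, never truncated.
* The REC denominator requires $E_3 > E_1$; REC lies in $[0,1]$ whenever
  $E_1 \le E_2 \le E_3$ but is not clamped outside that ordering.
* ROS slopes are ordinary least squares with intercept, so constant
  fluorescence offsets in either tube cancel exactly.
* `glmnet` needs two or more columns; a univariate screen is padded with
  an all-zero column that can never enter the model.

## Validation problem sizes

The shipped test-and-acceptance suite exercises: analytic identities on a
48-point parameter grid (to $10^{-9}$ for the decay-time relation,
$10^{-6}$ against quadrature for $I_W$); parameter recovery on 200
Poisson-simulated decay traces (median relative bias of $A$, $B$, $C$
below 5%, planted $I_0$ halving recovered within $\pm 0.05$); LASSO
planted-signal selection over 100 seeds and t-test size over 500 seeds at
$n = 6$ per group; and full correlation-network sign recovery over 200
seeds. These sizes were chosen to keep Monte-Carlo error well below the
margins being tested while remaining friendly to a laptop.

## Known limitations

Only the csch² decay law is implemented — no multi-exponential or
power-law alternatives, and no model-selection between decay families.
The exact Spearman path enumerates $n!$ permutations and is therefore
capped at $n \le 9$. The pipeline's LASSO stage requires at least three
samples per class for cross-validation folds to retain two classes in
every training split. Consensus MICs attached per sample are constant
within a group, which ties their ranks in the network stage; with few
groups this discretisation weakens the attainable correlation strength.
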