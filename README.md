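# biophotonQC

Quality assessment of medicinal plant leaves from their ultra-weak photon
emission.

Herbal raw material such as *Isatidis Folium* (the dried leaf of *Isatis
indigotica*) is quality-controlled by marker-compound content and
antibacterial potency — assays that are slow, destructive, and blind
during cultivation. Leaves, however, emit measurable ultra-weak light:
a steady spontaneous emission (SPE) of tens to hundreds of photon counts
per second, and, after a light stimulus, a delayed luminescence (DL)
that decays over minutes. Both change with the physiological state of the
tissue, so photon parameters measured on *fresh* leaves can act as
non-destructive proxies for the eventual herbal quality. This package
implements the full analysis chain for that idea, aimed at researchers in
biophotonics and medicinal-plant quality control.

## The model at the core

The DL decay is fitted with the hyperbolic-cosecant (Gu) law

```
I(t) = A · csch²(t/B + C)
```

with intensity scale `A` (counts/s), characteristic time `B` (s) and phase
factor `C`. From a fit, three macroscopic parameters follow:

```
I0 = A · csch²(C)                               initial intensity
T  = B · (asinh(√m · sinh C) − C)               time at which I(T) = I0/m   (m = 3)
Iw = (A·B/W) · [coth C − coth(W/B + C)]         mean intensity over [0, W]  (W = 300 s)
```

SPE is summarised as the background-corrected rate `CPS = N − n`. The
intensity measures `I0`, `Iw`, `CPS` are normalised by leaf geometry
(× thickness / mass). Downstream, the package screens the seven candidate
parameters (`A`, `B`, `C`, `I0`, `Iw`, `T`, `CPS`) with cross-validated
LASSO, stratifies groups by PCA, tests group differences (pooled t-test),
calls MICs from broth-microdilution plates (80%-of-control endpoint on a
two-fold ladder), computes physiological indices (pigment contents,
relative electrical conductivity, ROS production rate), and links photon
parameters to quality endpoints in a Spearman correlation network. A
synthetic-data module simulates Poisson photon-counting studies with
planted group effects so every stage is testable without instrument data.

## Worked example

Simulate one decay run of a control leaf, fit it, and derive the
macroscopic parameters:

```r
library(biophotonQC)

tr <- simulate_dl_trace(A = 2000, B = 15, C = 0.8, background_rate = 30,
                        seed = 42, sample_id = "leaf_01")
fit <- fit_gu_model(tr, background_rate = 30)
fit
#> Gu model fit (poisson weights, 1 replicate)
#>   A = 2277.12  B = 14.9104 s  C = 0.845291   (residual norm 17.16)

derive_dl_parameters(fit, m = 3, W = 300)
#> Derived DL parameters (m = 3, W = 300 s)
#>   I0 (initial intensity): 2525 counts/s
#>   T  (decay time):        6.37 s
#>   Iw (window mean):       51.18 counts/s
```

The fitted initial intensity (2525 counts/s) recovers the generating
truth `2000·csch²(0.8) ≈ 2536` to about half a percent; `T ≈ 6.4 s` says
the emission needs ~6 seconds to fall to a third of its initial value.
Spontaneous emission and its geometry-normalised rate:

```r
spe <- simulate_spe_trace(120, 30, seed = 43, sample_id = "leaf_01")
bg  <- simulate_spe_trace(0, 30, seed = 44, run_kind = "background")
k <- compute_cps(spe, bg)
k
#> SPE summary: N = 150.8, n = 29.61, CPS = 121.2 counts/s
normalize_intensity(k$CPS, mass_g = 0.5, thickness_mm = 0.4)
#> [1] 96.964
```

An MIC call from a microdilution plate row (threshold = 80% of the growth
control, so wells at 1024–128 µg/mL count as inhibited and 128 is the
lowest of them):

```r
p <- mic_plate(dilution_ladder(1024, 8),
               c(0.05, 0.06, 0.07, 0.10, 0.60, 0.65, 0.70, 0.72),
               od_positive = 0.70, od_negative = 0)
call_mic(p)$label
#> [1] "128"
```

`run_pipeline(sim_config(), seed = 1)` runs the whole chain — simulation,
replicate fitting, normalisation, physiology, MIC consensus, LASSO screen,
t-tests, network, quality flags — and returns all stage outputs plus a
manifest; with `out_dir =` it also writes CSV/GraphML/JSON outputs whose
hashes are deterministic under the seed. A thin command-line wrapper is
included at `inst/scripts/run_pipeline.R`.

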