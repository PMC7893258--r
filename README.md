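# whalebc

Lipid-store body condition of free-ranging whales from two independent,
non-invasive channels: **tissue body density (TBD)** estimated from
biologging-tag glide kinematics via a Bayesian hydrodynamic model, and a
**length-standardized surface area index (LSSAI)** from overhead
photogrammetry outlines — fused in a hierarchical latent-variable model of
the underlying tissue body density (uTBD) with life-history covariates.

Body lipid (~920 kg m⁻³) is much less dense than lean tissue, so whales with
larger lipid stores have lower tissue density and look wider from above for
a given length. The package is for marine-mammal ecologists working with
suction-cup tag records (depth, pitch, dorsoventral acceleration, optionally
propeller speed), CTD seawater-density profiles, and UAV outline
measurements.

## The models

**Glide hydrodynamics.** During a stroke-free glide the along-path
acceleration is drag plus tissue buoyancy plus air buoyancy:

```
a = -1/2 (C_D A / m) ρ_sw v²
    + (ρ_sw / ρ_tissue(d) - 1) g sin p
    + (V_air / m) g sin p (ρ_sw - ρ_air (1 + 0.1 d)) / (1 + 0.1 d)

ρ_tissue(d) = ρ_tissue(0) / (1 - r (1 + 0.1 d) · 101325)
```

with pitch `p` positive ascending, `(1 + 0.1 d)` the absolute pressure in
atmospheres at depth `d` (m), and tissue compressibility fixed at
`r = 0.38e-9` Pa⁻¹. The unknowns — ρ_tissue(0), the combined drag term
`C_D·A/m`, and the per-mass diving air volume `V_air/m` — are estimated by
Gibbs sampling from 5-s glide segments (acceleration = OLS slope of speed on
time), with individual/global parameter sharing compared by DIC.

**LSSAI.** The body outline is 21 boundary widths at 20 equal-length
sections; each section's length-standardized trapezoid area is
`PA = (B/L + b/L)(h/L)/2` and `LSSAI = Σ_{i=7..17} PA_i` (the mid-body,
30–85% of body length). Pixels cancel, so no camera calibration is needed.

**Fusion.** Per whale, a latent `uTBD_j ~ Gamma(mean exp(X_j β), shape k)`
is observed through `TBD_j ~ N(uTBD_j, sd_j)` (sd supplied per observation
from the glide fit) and `LSSAI_j ~ N(α + γ uTBD_j, σ_L)`; covariates are
location, feeding-season day, sex, and pregnant/lactating/immature flags.
Effects are reported in kg m⁻³ at reference covariates; missing channels are
predicted from the posterior.

A declared affine calibration converts density to an approximate lipid
fraction, anchored on two published density↔lipid pairs.

## Worked example

```r
library(whalebc)

## 1. Tag record -> glide observations
sim <- simulateTimeseries(n_dives = 3, glide_s = 10, dive_depth = 90,
                          pitch_deg = 50, speed = 1.6, seed = 42)
windows <- detectGlides(sim$series)
windows
#> # A tibble: 9 × 5
#>   start   end start_time end_time duration
#> 1   159   208       31.6     41.4      9.8
#> 2   526   576      105      115       10
#> ...
ctd <- simulateCtd(surface_density = 1023.3, gradient = 0.02, max_depth = 200)
glides <- segmentGlides(windows, sim$series, ctd)   # 12 five-second glides

## 2. Bayesian tissue-density estimation (synthetic truth: 1036 kg m^-3,
##    drag 12e-6 m^2 kg^-1, air 37.3 ml kg^-1, noise sd 0.01 m s^-2)
truth <- hydroParams(tissue_density = 1036, drag_term = 12e-6,
                     air_per_mass = 3.73e-5)
gl <- simulateGlides(truth, n_glides = 200, noise_sd = 0.01, seed = 1)
fit <- fitHydroModel(gl, modelStructure("global", "global", "global"),
                     mcmc = mcmcConfig(iterations = 6000, seed = 2))
fit$summaries
#> # A tibble: 4 × 7
#>   parameter      mean       sd      ci_lo     ci_hi   ess  rhat
#> 1 drag_u      12.7    0.558      11.6       13.8    1996.  1.00
#> 2 rho0      1036.     0.228    1035.      1036.      767.  1.00
#> 3 sigma        0.0110 0.000554    0.00997    0.0121 1800.  1.00
#> 4 vair_u      35.8    1.18       33.5       38.2     816.  1.01
```

`rho0` is the tissue density (posterior mean 1036.0 kg m⁻³, truth recovered
within ~0.2), `drag_u` and `vair_u` are the drag term and air volume in 1e-6
units (m² kg⁻¹ and m³ kg⁻¹ ≈ ml kg⁻¹), `sigma` the acceleration error
(m s⁻²). Every fit reports 95% credible intervals, effective sample sizes
and R-hat; non-convergence is flagged, never silent.

```r
## 3. Cross-validate the two channels on the published 21-whale table
ct <- correlateChannels(crossvalRecords())
sprintf("r = %.2f, p = %.4f, n = %d", ct$r, ct$p, ct$n)
#> "r = -0.48, p = 0.0267, n = 21"

## 4. Density -> approximate lipid-store fraction
lipidFraction(1036.5)
#> 0.365  (36.5% body lipid)
```

Fatter whales (higher LSSAI) have lower tissue density — the negative
correlation above is the cross-validation of the two methods.

For population-level inference, `simulatePopulation()` +
`fitUtbd()` estimate covariate effects on the latent density, and
`runPipeline()` orchestrates the full chain (glides → density → LSSAI →
fusion → lipid) reproducibly from one seed. See the methods vignette
(`vignettes/whalebc-methods.Rmd`) for the models, priors, detection
thresholds and design decisions.

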