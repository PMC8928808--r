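# curvlamina

Analysis of curvature-driven nuclear lamina dilution and nuclear envelope
rupture.

The nuclear lamina — juxtaposed meshworks of lamin-A and lamin-B
intermediate filaments lining the inner nuclear membrane — protects the
genome mechanically. Lamin-B filaments are stiff on the micron scale and
membrane-anchored: where the nuclear envelope acquires high positive
Gaussian curvature (nuclear poles, constricting pores, micropipette tips),
filament attachment becomes energetically costly and the local lamin-B
density drops, favouring envelope rupture. Lamin-A behaves instead as a
viscous layer that only flows, and hence dilutes, above a critical strain
rate. `curvlamina` implements the quantitative pipeline built on those two
ideas, for cell biophysicists analysing nuclear contours, intensity line
scans, pore-migration cohorts and micropipette aspiration traces.

## The model

A single lamin-B filament (in-situ length `L_fil`, persistence length
`ℓ_p`) is either attached to or detached from the membrane. With the
detached state as reference (`E_det = 0`), the attached-state energy at
membrane curvature `1/R` is

```
E_att = −E + a/R + (k/2)(1/R)²,        k = ℓ_p · L_fil   [kBT·µm²]
```

where `E` is the flat-membrane binding energy, `a/R` the curvature-induced
loss of contact area, and the last term the bending cost of conforming the
stiff filament to the membrane. Boltzmann statistics give the detachment
probability

```
P_det(1/R) = 1 / (1 + exp(E − a/R − (k/2)(1/R)²))      (energies in kBT)
```

which rises sigmoidally with curvature. Measured responses (lamin-B/A pole
ratios, % ruptured nuclei vs pore curvature) are fitted with
`y = B / (1 + exp(ε − α·x))`. With the measured filament geometry
(`ℓ_p = 0.5 µm`, `L_fil = 0.38 µm`), `k = 0.19 kBT·µm²` — small enough
that the bending term barely moves the fitted curves.

Around the model sit the measurement operations: osculating-circle
curvature on nuclear contours (2 µm arc window), min–max-normalised
intensity profiles with 1 µm pole means, the dilution measure
`φ = inside/tip − 1`, multi-site rupture independence (`P(N≥k) = p₁ᵏ`),
curvature-regime enrichment, and the critical-rate hinge fit
`φ = c · max(0, rate − r_crit)`.

## Worked example

Simulate a pore-migration study at the standard conditions (six pore
diameters 2.25–8 µm, 500 cells each), refit the rupture sigmoid, and
estimate the lamin-A critical rate from aspiration traces:

```r
library(curvlamina)

params <- filament_params(binding_energy_E = 4, contact_coeff_a = 8)
detach_probability(pore_curvature(c(8, 5, 3, 2.25)), params)
#> [1] 0.1198277 0.3132863 0.7982763 0.9603106

cfg    <- generator_config(seed = 42)
cohort <- simulate_migration_cohort(cfg)
per_pore <- dplyr::summarise(
  dplyr::group_by(cohort, pore_diameter_um),
  curvature    = pore_curvature(pore_diameter_um[1]),
  pct_ruptured = 100 * mean(n_sites >= 1),
  n            = dplyr::n(), .groups = "drop")
per_pore
#>   pore_diameter_um curvature pct_ruptured     n
#> 1             2.25     0.889         97.6   500
#> 2             3        0.667         80.8   500
#> 3             4        0.5           52.4   500
#> 4             5        0.4           32.8   500
#> 5             6        0.333         18     500
#> 6             8        0.25          12.4   500

fit_sigmoid(per_pore$curvature, per_pore$pct_ruptured, n_trials = per_pore$n)
#> Sigmoidal curvature response y = B / (1 + exp(eps - alpha x))  [full fit]
#>   B = 100.596   eps = 4.17094 kBT   alpha = 8.45541 kBT um
#>   residual norm = 0.0238 over 6 points

tr   <- simulate_aspiration(cfg, rates = seq(0.05, 0.6, length.out = 30))
phi  <- aspiration_phi(tr, at_time = 60)
phiA <- subset(phi, channel == "laminA")
estimate_critical_rate(phiA$rate_um_s, phiA$phi, "laminA")
#> Hinge fit (laminA): phi = 0.7717 * max(0, rate - 0.168 um/s)
#>   residual norm = 0.467 over 30 points
```

Rupture frequency rises from ~12% in 8 µm pores to ~98% in 2.25 µm pores;
the refit recovers the generating parameters (B = 102, ε = 4, α = 8)
within sampling error, and the hinge fit recovers the configured critical
extension rate of 0.2 µm/s from noisy traces. The full chain (simulate →
measure → fit → rupture-stats → report) is also available through
`run_pipeline()` and the `inst/scripts/lamina-pipeline.R` command-line
wrapper.

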