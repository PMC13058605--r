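# sonognp

Quantitative analysis of ultrasound-mediated gold nanoparticle (GNP) uptake
and intracellular dispersion in cultured cells.

Low-frequency ultrasound transiently permeabilises the plasma membrane
(sonoporation) and changes both how many nanoparticles a cell takes up and
how they are distributed in the cytoplasm. Studies of this effect combine
four measurement modalities, each with its own quantitative post-processing:

* **label-free reflectance confocal imaging** of intracellular GNP clusters,
  segmented by K-means intensity clustering combined with thresholding and
  summarised by equivalent circular diameters;
* **ICP-AES elemental analysis**, converting a measured gold mass
  concentration into a per-cell particle count;
* **nanoparticle tracking analysis (NTA)**, summarised by a log-normal
  diameter distribution;
* **optical diffraction tomography (ODT)**, yielding refractive-index
  volumes from which the membrane surface-area-to-volume ratio is used as a
  morphological indicator of sonoporation.

`sonognp` implements this full analysis chain for R, together with seeded
synthetic-data generators that emulate each instrument's output, so every
stage is testable end to end without raw instrument data.

## The models at the core

**Mass-to-particle conversion.** With gold molar mass `M_Au` (g/mol),
`N_Au` atoms per particle, `N_C` cells, Avogadro's number `N_A` and an
effective sample volume `V` (L), a measured concentration `C_m` (mg/L)
converts to particles per cell as

    N_np = (C_m · 1e-3 · V · N_A) / (M_Au · N_Au · N_C)

reported on the ×10⁴ scale. With the defaults (50 nm gold particles,
`N_Au = 3 849 991`, `N_C = 10⁶`, `V = 0.010` L) the slope is 0.7941 ×10⁴
particles per cell per mg/L.

**First-order absorption kinetics.** Uptake over time follows the
saturating model

    Y(t) = A_max · (1 − e^(−k t))

with the asymptote `A_max` fixed to the last observed uptake (the "maximum
uptake capacity") and the series anchored at the origin, so the absorption
rate constant `k` is the sole free parameter. For a three-timepoint series
this gives four points and three degrees of freedom; `fit_first_order()`
reports `k`, its standard error (linearised Jacobian), centred R², and t/F
tests of the rate constant and the model.

**Cluster sizing.** Segmented components of pixel area `A_px` at pixel
size `p` are reported as equivalent circular diameters
`d = 2·sqrt(A_px/π)·p`; group summaries pool cluster sizes across images,
and size-versus-exposure trends are assessed by linear (Pearson) and
quadratic least-squares regression.

**Log-normal sizing.** Diameter histograms (NTA or cluster tables) are fit
with `amplitude · dlnorm(x; µ, σ)` by damped least squares
(Levenberg–Marquardt); the modal diameter is `exp(µ − σ²)`.

**Morphometry.** Binary cell masks are measured by voxel-count volume and
a triangulated 0.5 iso-surface area (tetrahedral decomposition with linear
edge interpolation); RI tomograms are classified into membrane
(1.33–1.34), nucleus (1.35–1.36) and lipid (>1.37) bands first.

## Worked example

Fit the uptake kinetics of a group exposed to ultrasound for 20 minutes,
from its mean gold concentrations at 3, 6 and 27 h of particle treatment:

```r
library(sonognp)

concentration_to_particles(c(0.25, 0.91))   # x10^4 particles per cell
#> [1] 0.1985310 0.7226528                   # prints as 0.20 and 0.72

s <- uptake_series(c(3, 6, 27), c(0.91, 1.38, 2.31), group_min = 20)
fit_first_order(s, a_max = 2.31)
#> First-order absorption fit (fixed asymptote)
#>   A_max = 2.31 (fixed), k = 0.1581 1/h (SE 0.00507), df = 3
#>   R^2 = 0.9987, p(model) = 2.07e-05, p(k) = 7.23e-05
```

The 0 h means 0.25 and 0.91 mg/L convert to 0.20 and 0.72 ×10⁴ particles
per cell — a 3.64-fold uptake enhancement immediately after a 20-minute
exposure — and the fitted rate constant 0.158 1/h describes how the
exposed group saturates toward its maximum uptake capacity.

A full synthetic study (4 exposure groups × 3 timepoints × 3 replicates)
runs through every stage in one call:

```r
rep <- run_pipeline(study_config(master_seed = 1))
rep$kinetic_fits
#>   group_min a_max     k    se_k df r_squared  p_model      p_k
#> 1         0  1.95 0.147 0.00761  3     0.997 7.96e-05 0.000305
#> 2         5  1.86 0.128 0.00801  3     0.996 1.28e-04 0.000533
#> 3        10  2.23 0.121 0.00666  3     0.997 8.57e-05 0.000365
#> 4        20  2.13 0.174 0.01377  3     0.992 2.96e-04 0.001065
```

`verify_paper_examples()` re-evaluates the bundled reference tables (the
12 conversion cells, the percent reductions in cluster size, both
regression R² values, the 20-minute kinetic fit and the fold change) and
reports a pass flag per check.

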