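---
title: "Methods: quantifying ultrasound-mediated nanoparticle uptake and dispersion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying ultrasound-mediated nanoparticle uptake and dispersion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sonognp)
```

This vignette describes the models and procedures `sonognp` implements,
the assumptions behind them, the defaults and why they were chosen, and
what the synthetic-data generators do and do not emulate.

# The study design being analysed

The package targets a common experimental design for ultrasound-assisted
nanoparticle delivery: adherent cells are incubated with ~50 nm gold
nanoparticles for 3 h, exposed to low-frequency ultrasound for 0, 5, 10 or
20 minutes, and assayed 0, 3 or 24 h after irradiation. On the kinetic
clock that starts at particle administration, the three assay times read
t = 3, 6 and 27 h. Four modalities feed the analysis: reflectance confocal
images of label-free intracellular clusters, ICP-AES gold concentrations,
NTA diameter distributions, and ODT refractive-index volumes.

# Mass-to-particle conversion

ICP-AES reports a gold mass concentration in the diluted digest. The
conversion to particles per cell,

$$N_{np} = \frac{C_m \cdot 10^{-3} \cdot V \cdot N_A}{M_{Au} \cdot N_{Au} \cdot N_C},$$

is exactly linear in $C_m$. The effective sample volume $V = 0.010$ L
encodes the dilution bookkeeping: a 2 mL digest diluted to 10 mL gives a
dilution factor of 5, and multiplying the diluted concentration by 10 mL
recovers the same gold mass as multiplying the adjusted concentration by
2 mL — `adjust_dilution()` and the `V_sample` constant are two views of the
same accounting. With the default constants (gold molar mass 196.966657
g/mol, 3 849 991 atoms in a 50 nm particle, $10^6$ cells) the slope is
0.794124 ×10⁴ particles per cell per mg/L. Against the bundled reference
table, 11 of the 12 converted cells agree with the tabulated values within
one unit of the printed last digit; the residual cell is consistent with
the measured concentrations having been rounded to two decimals before
tabulation, which is also why printed-precision comparison (not raw
difference) is the meaningful check.

# Fixed-asymptote first-order kinetics

Uptake is modelled as $Y(t) = A_{max}(1 - e^{-kt})$ with two constraints
that reflect how such series are constructed:

* the series is anchored at the origin — no intracellular particles at
  the moment of administration — so $(0, 0)$ enters the fit as a data
  point;
* $A_{max}$ is pinned to the observed uptake at the last time point (the
  "maximum uptake capacity") rather than estimated.

This leaves $k \ge 0$ as the sole free parameter: a three-timepoint group
series gives four points, one parameter and df = 3 by the convention
df = n − 1 used throughout. The model then slightly under-predicts the
last observation by construction (the curve reaches $A_{max}$ only
asymptotically); that is a property of the estimator as defined, not a
defect, and it is why the exact-recovery test supplies the true asymptote.

Numerics: the 1-D sum of squares is minimised by a bracketed line search.
The SSE profile flattens once $e^{-kt}$ underflows at all positive times,
so a plain golden-section search over a wide interval can stall on the
plateau; the implementation therefore brackets the minimum on a combined
linear and logarithmic grid in $[0, k_{upper}]$ ($k_{upper} = 50$/h by
default) before refining, and checks the $k = 0$ boundary explicitly.

Inference: $SE(k)$ comes from the linearised Jacobian
$\partial Y/\partial k = A_{max} t e^{-kt}$ at the optimum with residual
variance $SSE/df$; $p_k$ is a two-sided t test of $k = 0$; the model
p-value is an F test against the constant-mean model with $(1, df)$
degrees of freedom; R² is centred on the mean of all fitted observations,
origin included — with df = n − 1 this is the only centring convention
consistent with the stated degrees of freedom. The exact construction of
separate model and rate p-values in reference reports is not documented;
the F/t pair above is this package's own, standard, choice.

A practical note on the fitting level: when the fit is run on group means
of a three-timepoint design, the origin anchor is error-free, so only two
effective residual degrees of freedom inform the variance estimate while
the df = 3 convention divides by three. Confidence intervals built from
means-level fits of tiny designs are therefore anti-conservative; the
parameter-recovery simulations in the test suite fit at replicate level
(nine noisy observations, df = 9), where the normal-approximation
interval $k \pm 1.96\,SE(k)$ attains close to nominal coverage. Both
levels are available — pass the replicate series or the aggregated means
to `fit_first_order()`.

# Label-free cluster segmentation and sizing

Reflectance images are min-max normalised (a constant frame maps to
zeros), then segmented by K-means clustering of pixel intensities combined
with intensity thresholding. Choices the method description leaves open,
fixed here as defaults:

* `k_clusters = 3` — background, diffuse cellular reflectance, bright
  particle signal; configurable.
* Combination rule: foreground is the *intersection* of the brightest
  K-means class with the pixels above the `threshold_quantile = 0.95`
  intensity quantile — the conservative reading of "clustering combined
  with thresholding".
* Connectivity 8; components under `min_cluster_pixels = 4` are removed
  as single-pixel noise.
* K-means determinism: ten seeded random restarts, best inertia. Because
  the bright population can be a tiny fraction of pixels, every random
  start may land in the background mass and the bright tail gets absorbed
  into the top background cluster; one additional deterministic start —
  spread quantile centres with the image maximum pinned as a centre — is
  always evaluated and wins whenever its inertia is lower. The result
  remains deterministic for a fixed seed.
* Feature space is intensity only; texture features are out of scope.

Cluster "size" is the equivalent circular diameter
$d = 2\sqrt{A_{px}/\pi}\,p$ — the standard measure consistent with sizes
spanning the sub-resolution to multi-micrometre range. Group summaries
pool cluster sizes across a group's images rather than averaging
per-image means; the pooled standard deviation is what makes the large
dispersion of cluster sizes visible in a `mean ± SD` summary. Trends
versus exposure time are assessed on individual sizes (Pearson r, linear)
and on group means (linear and quadratic least squares with the model
F-test); a saturated fit reports R² = 1 with an undefined p-value.

# Log-normal size fitting

Size histograms use right-open fixed-width bins covering the data range
(default widths: 5 nm for NTA-scale data, 0.1 µm for cluster tables —
instrument bin widths are rarely reported, so both are configurable).
`fit_lognormal()` fits `amplitude · dlnorm(x; µ, σ)` at the bin centres by
Levenberg–Marquardt damped least squares, unweighted, with deterministic
starting values from the histogram-weighted log-moments. At least three
occupied bins are required to identify three parameters. The modal
diameter is $e^{\mu - \sigma^2}$; the fitted distribution's mean
$e^{\mu + \sigma^2/2}$ and SD summarise cluster populations. Fitting the
binned histogram (rather than maximum likelihood on raw diameters)
mirrors how sizing instruments report distributions.

# Voxel morphometry and the sonoporation indicator

ODT refractive-index volumes are classified into compartments by RI band:
membrane 1.33–1.34, nucleus 1.35–1.36, lipid droplets above 1.37, with the
remainder of the cell support labelled cytoplasm (support floor 1.33 by
default, so the membrane band lies inside the support). Values between
bands — e.g. RI 1.345 — deliberately fall to the cytoplasm remainder.

For a binary cell mask, volume is the voxel count times voxel volume, and
surface area is measured on a triangulated 0.5 iso-surface: each boundary
cube is decomposed into the six tetrahedra sharing its main diagonal, the
iso-surface within a tetrahedron is one or two triangles with vertices
linearly interpolated along edges, and triangle areas are summed. The
tetrahedral scheme implements the iso-surface-triangulation contract
without large case tables and is exactly vectorisable. Binary masks are
pre-smoothed with a one-voxel Gaussian so edge interpolation is sub-voxel;
digitized spheres of radius 5–15 µm at 0.25 µm voxels then measure within
3% of $4\pi r^2$, whereas counting exposed voxel faces overestimates a
sphere's area by roughly 50% — the face count is kept only as a negative
control (`method = "voxel-faces"`). The measured area-to-volume ratio is
rotation invariant within 2% and increases monotonically with the
generator's membrane-roughness amplitude, the two properties the
sonoporation indicator relies on.

Whether "membrane area" means the outer cell surface or the area of the
RI-band membrane shell is ambiguous in typical method descriptions; the
package measures the outer iso-surface of the mask (the shell variant can
be obtained by meshing the membrane-band mask from `classify_ri()`).
Absolute A/V values of real cells are not reproduced here — the study
level analysis is population-relative (percent increase over control,
ANOVA with Tukey HSD per timepoint).

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
validated:

* **Particle diameters** are i.i.d. log-normal; defaults
  (`log_mu = log(57)`, `log_sigma = 0.35`) place the mode near 57 nm, the
  modal diameter typical of nominally 50–55 nm colloidal gold measured by
  NTA.
* **Reflectance scenes** place clusters uniformly in a cytoplasmic
  annulus, render each as a filled disk of its true equivalent diameter
  (making recovery well-defined), convolve with a Gaussian PSF
  (σ = 0.085 µm, matching ~200 nm lateral resolution), and add clipped
  Gaussian noise. The default frame is 1024 × 1024 px at 0.2 µm/px; the
  test suite uses 512 × 512 and smaller frames with the same pixel size
  to keep runtimes in seconds. Default cluster-diameter parameters
  (`log_mu = log(0.45)`, `log_sigma = 0.75` µm) give a population mean ±
  SD of 0.60 ± 0.52 µm, matching the unexposed-group summary in the
  bundled reference table. Overlapping disks are allowed and flagged
  `merged` in the ground truth; count-recovery tests compare against the
  union of overlapping disks, since a segmenter sees one blob. Because
  clusters below the minimum-pixel filter are undetectable by
  construction, count-recovery checks use scenes with resolvable
  diameters (median 1 µm); the bit depth and noise law of real
  reflectance channels are not published, so additive clipped Gaussian
  noise is a modelling choice, not an instrument fact.
* **Uptake series** evaluate the first-order model exactly and add
  Gaussian replicate noise (default SD 0.15 mg/L, the scale of the
  replicate SDs in the reference table). Default per-group asymptotes and
  rate constants are the values `fit_first_order()` recovers from the
  bundled table, so a default `study_config()` emulates the measured
  behaviour of the four exposure groups.
* **Cell masks** digitize a radially perturbed sphere
  $r(\theta,\varphi) = R + a\,s(\theta,\varphi)$ where $s$ is a
  band-limited sum of random-direction sinusoids on the unit sphere,
  normalised to $[-1, 1]$ — smooth, seedable, and with a monotone effect
  of amplitude $a$ on surface area. It emulates membrane corrugation
  only; it does not model pores, blebs or tomographic reconstruction
  artefacts.

What passing tests show, and do not show: the suites demonstrate that the
estimators recover the generators' ground truth under these idealised
conditions (disk-shaped clusters, Gaussian noise, spherical cells). Real
images add out-of-focus haze, intracellular reflectance texture and
anisotropic PSFs; real tomograms add reconstruction artefacts. Results on
real data depend on how far those effects depart from the emulation.

Problem sizes used by the test and acceptance suites — 512² count-recovery
scenes, $10^5$-draw histograms, 200 kinetic simulations, 1000 ANOVA null
replicates, spheres up to radius 15 µm at 0.25 µm voxels — were chosen as
the smallest scales at which the law-of-large-numbers checks are stable.

# Orchestration and determinism

`study_config()` + `run_pipeline()` execute the stages in dependency
order and optionally write all tables as TSV at six significant digits
(stable diffs) plus a YAML config snapshot. Every stochastic stage draws
from a per-item seed derived from the master seed, so reruns from the
same configuration are identical; generation and analysis never share an
RNG stream, and all seeded helpers restore the caller's RNG state. The
command-line surface is deliberately thin: the exported functions are the
interface, and `scripts/acceptance.R` shows the scripted usage pattern.

`verify_paper_examples()` re-evaluates the bundled reference tables
(conversions at printed precision, percent reductions, both regression
R² values, the 20-minute kinetic fit, the fold change) and reports one
pass flag per check; corrupting a reference constant fails exactly the
corresponding row.

# Known limitations

* The segmentation operates on 2-D projections; axial blur can make
  membrane-proximal particles appear nuclear, and no 3-D or
  colocalisation correction is attempted.
* Sub-resolution clusters below the minimum-pixel filter are invisible;
  reported cluster counts and means are conditional on detectability.
* The fixed-asymptote convention biases $k$ upward when true uptake is
  far from saturation at the last time point; with slow kinetics, prefer
  longer series or replicate-level fits.
* RI band limits are configurable but device- and cell-line dependent;
  the defaults suit adherent epithelial cells imaged by holotomography.
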