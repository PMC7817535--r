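---
title: "Autocorrelation-competition-error models for forest genetics trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autocorrelation-competition-error models for forest genetics trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Forest genetics trials estimate how much of the variation in tree traits —
height (H, m), diameter at breast height (DBH, cm), stem volume (V, m³),
Dothistroma needle-blight infection (D38, % needle loss), and stress-wave
velocity (A, km/s, a wood-stiffness surrogate) — is additive-genetic, and
hence heritable. The standard individual-tree mixed model

$$ y = Xb + Zu + e $$

treats residual environmental variation as independent noise. Real trials
violate that twice over:

* **Site effects** (fertility, moisture, micro-topography) are *positively*
  autocorrelated: neighbouring trees share conditions.
* **Competition** is *negatively* autocorrelated: a large tree's neighbours
  tend to be small, because they compete for the same light and water.

A generic autoregressive residual cannot tell these apart — they partially
cancel — so models that include only an AR1 term confound them, and models
with neither inflate the residual and bias heritability downward. The ACE
(autocorrelation-competition-error) approach fits an explicit competition
covariate (the negative component), a separable AR1×AR1 correlated residual
(the positive component), and an independent "units" (nugget) error.

`aceforest` implements this workflow end to end *on simulated data with
known truth*: trial simulation → canopy height model (CHM) processing →
competition indices → REML model fitting → model comparison. Because no
field dataset ships with the package, every claim the test suite makes is a
claim about parameter recovery and qualitative behaviour, not a reproduction
of any particular trial's estimates.

## The four model families

All models share the fixed effects: overall mean and a control-vs-non-control
factor. Writing $\sigma^2_A$ for additive variance with pedigree
relationship matrix $A$:

| family | random terms | residual |
|--------|--------------|----------|
| B | pedigree + replicate + iblock:rep | iid $\sigma^2_e$ |
| BA | pedigree | $\sigma^2_\xi\, \mathrm{AR1}(\rho_r)\!\otimes\!\mathrm{AR1}(\rho_c) + \sigma^2_\eta I$ |
| BC | B + competition covariate | iid $\sigma^2_e$ |
| BAC | BA + competition covariate | as BA |

The spatial residual correlation between grid cells is
$\rho_r^{|\Delta \mathrm{row}|}\rho_c^{|\Delta \mathrm{col}|}$, with
distances in *grid steps*, not metres. Replicate and incomplete-block terms
are dropped from the AR1 models: the autoregressive field absorbs them, and
they were reported non-significant once an AR1 term was present. Missing
trees (mortality, thinning) keep their grid cells; their phenotypes are
simply absent from the response while the AR1 index set still refers to the
complete rectangular grid.

Narrow-sense heritability is $h^2 = \sigma^2_A / (\sigma^2_A + \sigma^2_E)$
where $\sigma^2_E$ is the iid residual for B/BC and the **units** component
$\sigma^2_\eta$ for BA/BAC — the spatially correlated $\sigma^2_\xi$ and the
design variances are excluded from the denominator. Standard errors use the
delta method on the variance-parameter covariance (2 × the inverse Hessian
of −2LL at the optimum).

### The competition covariate: fixed or random?

The source field convention is ambiguous: competition is described as a
*covariate* but tabulated among *random* terms. `fit_ace()` fits it as a
fixed regression on the standardized index by default — identifiable,
matches the covariate language, and makes the regression coefficient
directly interpretable as trait units per SD of competition — and offers
`competition = "random"` (a one-column random regression with its own
variance) for the other reading. With the fixed default, BC/BAC differ from
B/BA in their fixed effects, so their REML log-likelihoods are only
heuristically comparable; `likelihood_ratio()` warns rather than refuses,
because ranking such fits by LL is exactly what practitioners do with
ASReml, and the ranking question ("does a competition term help?") is
qualitative.

### Boundary likelihood-ratio tests

Testing a variance component against zero puts the null on the boundary of
the parameter space, so the usual $\chi^2_q$ reference is conservative in
the wrong direction. The package uses the equal-weight mixture
$p = \tfrac12 P(\chi^2_q \ge D) + \tfrac12 P(\chi^2_{q-1} \ge D)$ with
$\chi^2_0$ a point mass at zero. `q` defaults to the number of
variance/correlation parameters present in the test model and absent from
the base (residual and units aliased): a BA-vs-B comparison has
$q = 3$ ($\sigma^2_\xi, \rho_r, \rho_c$). The default is deliberately
simple; the exact distribution for several boundary parameters plus
correlations is not tractable, and the mixture errs conservative.

### Information criteria

`information_criteria()` implements AIC $= -2LL + 2t$ and, as the default
BIC, the *printed* field convention $-2LL + 2t\log\nu$ ($t$ = number of
variance parameters, $\nu = n - p$); `bic_convention = "standard"` gives the
textbook $-2LL + t\log\nu$. Reports rank by LL, which is how the model
families are compared in practice.

## What the simulator states about the world

`trial_design_params()` defaults describe a concrete 2.76 ha progeny trial:
75 blocks (25 replicates × 3 incomplete blocks), each a 6×6 grid of
single-tree plots at 3.2 m spacing (19.2 m block edge), 96 open-pollinated
families of which 6 controls appear in every block while the other 90 are
partitioned across the incomplete blocks of each replicate; a 50 m buffer
stand thinned to 786 stems/ha surrounds the trial. The replicates are laid
out 5 × 5 with the three incomplete blocks of a replicate side by side,
giving a 30 × 90 tree grid.

`sim_params()` defaults state the generative world used throughout the
acceptance suite: trait mean 9 m (height at age ~7 for radiata pine),
control offset +0.5 m, $\sigma^2_A = 1$, $\sigma^2_\xi = 1$,
$\rho_r = \rho_c = 0.6$, $\sigma^2_\eta = 1$, competition coefficient
$\beta_c = -0.3$ per SD of index, 10 % mortality. Replicate and
incomplete-block variances default to 0.2 and 0.1 — plausible for a uniform
site — but are set to zero in the recovery experiments, whose stated world
lists only the genetic, spatial, and competition components. Open-pollinated
half-sib families are the default pedigree, the common case in radiata
breeding programs; full-sib crosses are supported but not asserted.

Competition enters the simulation by a **single-pass mechanism**: every
tree draws a lognormal baseline size (CV 20 %), each trial tree's CIA index
is computed from its neighbours' baselines within the 8.273 m radius (the
radius at which a 3.2 m grid holds 20 expected neighbours), the index is
standardized over live trial trees, and the trait is penalised by
$\beta_c$ × the standardized index. This avoids iterating a growth model
the analysis never requires, at the cost of making competition exogenous to
the trait — adequate for testing *recovery* of a competition coefficient,
silent about feedback dynamics.

The synthetic CHM is composed directly as the per-cell maximum of
generalized-cone crown surfaces (exponent 1.5, crown radius 0.24 × height
clamped to [0.6, 2.4] m) over live trial and buffer trees, plus Gaussian
sensor noise (SD 3 cm) and random single-cell dropouts ("pits"). **Not**
emulated: point-cloud geometry, occlusion, off-nadir distortion, terrain
(the gully-driven site effects of real trials enter only through the AR1
field), crown asymmetry, and species mixtures. A green segmentation test
therefore establishes that the watershed pipeline recovers *these* idealised
crowns, and the ≥95 % detection property mirrors what the reference
operator-calibrated method claims on real stands — it does not validate the
simulator against LiDAR.

## CHM processing choices

* **Pit closing**: grayscale morphological closing with an odd square
  kernel (default 3) — extensive, plateau-preserving.
* **Segmentation**: marker-controlled watershed (priority-flood, FIFO
  tie-break for determinism) on the Gaussian-smoothed CHM; markers are
  local maxima above 2 m by default, or known stem positions. The
  operator-calibration step of the reference method is replaced by a
  config scalar `sigma` (default 1.5 cells) plus `calibrate_sigma()`,
  which maximises one-to-one stem matches.
* **Crown rule**: within each growing space, the crown is the 4-connected
  component containing the apex of cells ≥ max(1 m, 0.3 × apex height).
  The delineation rule of the reference method is unpublished; this one is
  simple, configurable, and reduces to crown = growing space for gap-free
  segments.
* **CS_C**: the source field table garbles the row defining the "closed"
  crown surface area; here CS_C is the surface area of the
  Gaussian-smoothed crown surface (same sigma as segmentation),
  distinguishing it from CS_T on raw heights. Surface areas use per-cell
  slope factors $\sqrt{1 + |\nabla h|^2}$ with gradients restricted to
  crown cells, so a flat 16 m² crown has CS_T exactly 16 m².
* **Matching**: detected apices to planted stems by optimal assignment
  (Hungarian algorithm) on squared distance, pairs beyond 1.6 m (half the
  spacing) unassigned.

## Competition index conventions

The three Hegyi-type formulations (CIA = size ratio / distance,
CIB = ratio / distance², CIC = ratio² / distance) are crossed with nine
crown metrics and two neighbourhoods (fixed 8.273 m radius N_A; shared
watershed boundary N_B, 4-connected by default) for 54 configurations.
Dead trees are excluded from neighbour sums — their gaps genuinely lower
competition. Buffer trees compete but are never standardization or model
rows. Empty neighbourhoods yield CI = 0 (flagged) so design matrices stay
complete. In simulation mode distances are stem-to-stem; in CHM mode they
are apex-to-apex; the pipeline records which.

## Numerical choices

REML is maximised over log-variances and scaled atanh-correlations
(|ρ| ≤ 0.999) by BFGS from a moment-based start (half-sib ANOVA for
$\sigma^2_A$; neighbour correlation of the centred response for the spatial
split) followed by a Nelder-Mead polish, optionally from additional spread
starts (`n_starts`, default 3; deterministic, so identical data and options
reproduce fits bit-for-bit). Non-positive-definite proposals return a large
penalty rather than an exception. Convergence tolerance is 1e-8 on −2LL.
Hessians are central differences on the natural scale; components estimated
at the zero boundary get `NA` standard errors rather than a fabricated
number. The AR1×AR1 field is simulated *exactly* via the Kronecker-factored
Cholesky, never by approximate sequential sweeps.

Degenerate inputs fail loudly: duplicate coordinates (zero distances) are an
error in neighbourhood construction, constant vectors cannot be
standardized, heights at or below breast height (1.4 m) are outside the
V182 volume equation's domain, and non-topologically-ordered pedigrees are
rejected by the tabular relationship-matrix recursion.

## Scaling of the test suite

The recovery, ranking, and type-I experiments in the acceptance tests run
20 (or 10) independent 12-block trials (4 replicates × 3 incomplete
blocks, ≈390 phenotyped trees) rather than the full 75-block design,
purely for compute budget: a single dense-REML fit costs $O(n^3)$ per
likelihood evaluation. At this scale REML exhibits the textbook
small-sample partition bias between the nugget and the correlated
residual — the suite reports it rather than hiding it — and the bias
shrinks steadily as blocks are added; at full size the same pipeline runs
unchanged, only slower.

## Known limitations

* The raster I/O is the plain-text ESRI ASCII grid, not GeoTIFF (no raster
  library in the supported dependency set); crown polygons export as convex
  hulls.
* No BLUP breeding-value ranking, multi-trait models, or genomic
  relationship matrices.
* D38 is simulated as a spatially correlated trait only — there is no
  epidemic process model.
* Absolute REML log-likelihoods are implementation-specific (constant
  conventions differ between mixed-model software); only differences are
  meaningful.
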