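---
title: "Models, calibration and design choices in firecarb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, calibration and design choices in firecarb}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`firecarb` estimates annual wildfire occurrence probabilities and
fire-related biomass loss on forest-inventory plots from seasonal climate,
and converts them into CO₂ emission estimates under combustion scenarios.
This vignette records the models, their assumptions, and the design
decisions a maintainer would want to understand — especially where the
design was genuinely open. It states no empirical result that the package's
tests or acceptance script do not themselves compute.

## 1. Climate covariates

Six covariates drive both regressions: fire-season (July–October) and
spring (February–April) means of monthly precipitation, monthly maximum
temperature, and monthly potential evapotranspiration. ET uses the
modified Hargreaves form

$$ET = 0.0135\,(\bar T + 17.78)\; R_a \; \frac{238.80}{595.5 - 0.55\,\bar T}$$

in mm/day, with $\bar T$ the mean of the monthly maximum and minimum
temperature and $R_a$ incident radiation in MJ m⁻² day⁻¹. The divisor is
the latent heat of vaporization in cal/g, so the 238.80 constant is the
MJ-to-mm conversion; ET is clamped at zero for very cold months, and a
mean temperature above $595.5/0.55$ °C (non-physical) is an error.

*Solar model.* $R_a$ is the standard extraterrestrial closed form from
latitude and the month's midpoint day (the 15th), times a transmittance of
$0.75 + 2\times10^{-5}\,\mathrm{elevation(m)}$ capped at 1, times a
slope/aspect tilt factor. The tilt factor is the solar-noon incidence
ratio; it is exactly 1 on flat ground, and equatorward slopes receive at
least as much as poleward slopes in winter. This is deliberately the
simplest model satisfying those contracts — terrain shading, diffuse/direct
splitting and hourly integration are out of scope.

*Monthly totals.* Seasonal ET averages monthly totals (daily ET × days in
month) by default, because the emulated inventory's reported seasonal ET
magnitudes (≈ 405 mm fire season, 220 mm spring) are only reachable on a
monthly-total reading; `et_monthly_total = FALSE` switches to daily means.
Note a deliberate asymmetry: the synthetic generator draws the `ET`/`ETs`
*columns* from the calibrated copula (to honour those magnitudes), while
`seasonal_aggregate()` recomputes ET from the monthly normals. The two do
not agree in magnitude, because no transmittance below 1 produces
405 mm/month from the Hargreaves form; the generator's columns are the
covariates the regressions consume, and recomputation from monthly data is
the path real-data users take.

## 2. Spatial weights and Moran's I

Weights are $w_{ij} = 1/d_{ij}^2$ for great-circle distances below 660 km,
symmetric, with no self-neighbours. Distances use the haversine formula on
a 6371 km sphere — reproducible, and stable at short range. Spatial lags
are row-standardized weighted neighbour means by default (the construction
consistent with "average distance to neighbours within the cutoff");
`row_standardize = FALSE` gives the raw weighted sum. Isolated units get
lag 0 with a warning.

Moran's I uses the raw weights; inference is by two-sided permutation
(default 999 permutations, $p = (1 + \#\{|I^*| \ge |I_{obs}|\})/(n_{perm}+1)$)
because the normal approximation's validity under heavy-tailed
inverse-squared weights is doubtful. P-values are seed-reproducible and
invariant to affine rescaling of the data.

## 3. The SAR model and its estimation

Both regressions share the form

$$y = \alpha + \rho\,\mathrm{lag}(y) + \sum_k \beta_k\,(X_k - \rho\,\mathrm{lag}(X_k)) + \sum_j \delta_j Z_j + \varepsilon,$$

with 18 climate terms (6 mains, 6 quadratics, 6 interactions) and
untransformed attributes $Z$ (ownership; plus stand age and biomass for
mortality). Quadratics and interactions are computed on the original
covariates and lagged *as whole columns* — the product is lagged, not the
factors. At fixed $\rho$ the model is linear, so estimation profiles
$\rho$ over a grid ($[-1.5, 1.5]$ in steps of 0.01, then golden-section
refinement) with an exact least-squares inner solve.

*Criterion (an open design point resolved during implementation).* The
obvious profile criterion — the raw error sum of squares — is
**inconsistent** for $\rho$ here: with the simultaneous error process
$u = \rho\,\mathrm{lag}(u) + \varepsilon$, the lagged error is correlated
with $\varepsilon$ ($\mathrm{tr}(L(I-\rho L)^{-1}) > 0$ for any weights
with $\mathrm{tr}(L)=0$), and in simulations the SSE minimiser converged
to roughly $2\rho$ regardless of geometry. The default criterion is
therefore the concentrated Gaussian likelihood,
$\tfrac n2\log(\mathrm{SSE}/n) - \sum_i \log|1-\rho\lambda_i|$, where
$\lambda_i$ are the lag operator's eigenvalues (real, since the
row-standardized operator is similar to a symmetric matrix). This is the
classic eigenvalue method for spatial error models; parameter-recovery
simulations in the test suite confirm it is approximately unbiased.
`sar_method = "ls"` retains the raw SSE profile for comparison. The grid
extends beyond $|\rho|=1$ because published fits report $\rho$ above 1;
the likelihood diverges at reciprocal eigenvalues, so such candidates are
never selected spuriously.

*Degenerate fits.* If the model fits perfectly, $\rho$ is unidentified
(the transform $(I-\rho L)$ applies to an exactly-zero residual); the
smallest $|\rho|$ with zero error is reported.

*Standard errors* are conditional on the profiled $\rho$ (OLS formulas at
the optimum) and labelled as such — how the source tables' SEs accounted
for $\rho$ estimation is unknown.

*RMSE* is the df-adjusted residual standard error
$\sqrt{\mathrm{SSE}/(n-p)}$ with $p$ counting all estimated parameters
including $\rho$. In-sample $\sqrt{\mathrm{SSE}/n}$ can never decrease
when a term is removed, which would make the backward-elimination rule
("remove the interaction whose removal most reduces RMSE, stop when none
does") vacuous; the df-adjusted reading is also consistent with RMSE
described as the standard deviation of the residuals. Elimination only
ever considers interaction terms; mains and quadratics stay.

*Prediction* is plug-in: $\hat\eta = \alpha + \rho\,\mathrm{lag}_{obs}(y)
+ \sum\beta(X-\rho\,\mathrm{lag}(X)) + \sum\delta Z$, clipped to $[0,1]$
for probabilities (the linear SAR can leave the unit interval; the raw
predictor is also returned). Solving the simultaneous system
$(I-\rho W)^{-1}$ is not attempted because the published fire-risk
$\rho = 1.331$ makes it ill-posed under row-standardized weights. The
observed response lag must be supplied; in the bundled pipeline the
mortality lag at unburned plots uses the observed mortality field with
zeros off burned plots — the only field observable there.

*Unit scaling.* The published coefficient magnitudes imply covariate
scalings that differ between the two tables (the ET² coefficients differ
by ~10¹¹) and are not recoverable from the text; `unit_scaling` in the
configuration applies per-covariate multiplicative factors before the
coefficients, and the packaged tables are otherwise used verbatim.

## 4. Carbon accounting

Burned area $A=\sum a\,p_i$ with $a = 2428.1$ ha (6000 acres — the
emulated inventory's sampling intensity; configurable). Combusted biomass
is $\sum a\,p_i m_i (Bb_i f_b + Bo_i f_o)$ and CO₂ is
$0.5\cdot(44/12)$ times that (half of dry biomass is carbon; 44/12 is the
CO₂:C mass ratio — the rounded-integer ratio, which reproduces the
published ledger where exact molar masses do not). The pre-combustion
mortality biomass (no $f$ factors) is also reported, because the published
ledger's "biomass loss" column varies with the combustion rates and is
therefore the combusted quantity. Two published catastrophic-combustion
rows fail the $C = \tfrac{11}{6}B$ identity as printed and are flagged
inconsistent in the packaged table; they are excluded from reproduction
checks. The 12-scenario grid crosses probability sources (historical
county means; model predictions at county×ecoregion units; model
predictions at plots) with four combustion levels (fb/fo = 0.05/0.5,
0.3/0.8, 0.46/0.92, 0.8/1.0).

*Annualization.* The fire models are fitted on window incidence (default
15 years); predicted probabilities are divided by `window_years` where an
annual probability is needed. Mortality fractions are per-event and are
not annualized.

## 5. The synthetic landscape

The generator emulates the statistical structure the analysis assumes —
not any real geography. Construction:

- **Locations**: one plot placed uniformly at random inside each cell of a
  regular grid over a ~1000 × 1000 km box. A fully uniform point process
  was rejected: its near-duplicate pairs dominate raw $1/d^2$ weights and
  reduce Moran's I to the noise of a few closest pairs, and the emulated
  inventory is itself a quasi-systematic sample (~one plot per 2428 ha).
- **Latent fields**: one unit-variance Gaussian random field per variable
  (exponential covariance, 150 km range, simulated on a 40×40 grid and
  bilinearly interpolated, then re-standardized) plus a 30 % white-noise
  nugget.
- **Copula**: each targeted pairwise correlation is inverted through the
  two marginal transforms by quadrature and root-finding, the resulting
  latent matrix is completed to positive semidefinite holding targeted
  entries fixed (untargeted pairs are free to move off zero — pinning them
  at zero is infeasible given a 0.95 temperature correlation next to
  opposing age/ownership correlations), and the latent field matrix is
  empirically whitened before mixing so the realized latent correlation is
  exact by construction. Without whitening, the fields' finite-domain
  correlation noise (~±0.05 even at n = 50,000) leaks into every pair.
- **Marginals**: normals for climate (precipitation clamped at 0),
  lognormal biomass, gamma stand age, thresholded latents for ownership
  (25 %) and fire (7 %). Binary fields threshold at the *empirical*
  quantile, so the realized incidence is calibrated to the target up to
  1/n — a fixed Gaussian threshold would leave the incidence with an SD of
  2–3 percentage points at any n, because the latent field's domain
  average does not vanish.
- **Mortality**: on burned plots, a zero-inflated Beta (zero mass 0.45,
  Beta parameters moment-matched to mean 0.23, SD 0.36), independent
  across plots.
- **Monthly back-fill**: fire-season and spring months carry their
  seasonal values exactly (re-aggregation reproduces `PPT`, `TEMP`,
  `PPTs`, `TEMPs`); other months are a 50/50 blend; minimum temperature is
  maximum minus an 11 °C diurnal range.

What a green test does **not** establish: the generator has no
remeasurement panel, no fire perimeters, no real orography or coastline
effects, fire is uncorrelated with climate by default (only the quoted
pairs are targeted), and mortality is spatially unstructured given burn
status. Model-fit quality on this landscape says nothing about fit quality
on real inventory data; what the tests establish is that the machinery —
weights, Moran inference, profiled estimation, accounting arithmetic —
computes the right quantities.

*SAR recovery experiments* use $|\rho| < 1$ (the generative fixed-point
solve requires a contraction; the published fire-risk $\rho = 1.331$
regime is exercised only through the plug-in predictor), iid N(0,1)
covariates drawn from an RNG stream independent of the coordinate jitter
(spatially smooth covariates absorb part of the error field and bias
$\hat\rho$ down; sharing one stream makes the covariates deterministic
siblings of the locations), and a 150 km cutoff so the lag operator is
local enough to identify $\rho$ well.

## 6. Numerical choices

- Haversine on a 6371 km sphere everywhere; degenerate (duplicate)
  coordinates are an error, not an infinite weight.
- $\rho$ grid $[-1.5, 1.5]$ step 0.01; golden-section refinement to 1e-10
  within the bracketing cells; boundary solutions warn.
- Permutation p-values use the +1 convention (never zero).
- The fixed-point generative solve iterates to 1e-10 (max 10,000 sweeps).
- Zero-inflated-Beta moment matching fails loudly when the requested SD is
  infeasible for the zero mass.
- Configuration hashes use FNV-1a over a canonical serialization; two
  configurations hash equal iff all fields agree (up to 15 significant
  digits).

## 7. Known limitations

- Standard errors ignore $\rho$'s sampling variability.
- The published coefficient tables cannot be re-estimated here (their
  inputs are a full national inventory); they are transcription-audited
  and exercised arithmetically.
- The plug-in predictor with published coefficients inherits the unknown
  covariate scaling (see §3); predictions on synthetic units with those
  coefficients are structurally correct but not calibrated probabilities.
- Emissions cover live-biomass combustion only: no soil, litter, deadwood,
  smoldering chemistry, or salvage accounting.
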