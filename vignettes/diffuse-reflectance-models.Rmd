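---
title: "Analytical models of diffuse reflectance in homogeneous tissue: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytical models of diffuse reflectance in homogeneous tissue: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Visible-range (450--650 nm) diffuse reflectance spectra of tissue carry
information about oxygen saturation (StO~2~), blood content and
microstructural scattering. Extracting those parameters from a measured
spectrum requires a forward model mapping optical properties to
reflectance that is cheap enough to sit inside a nonlinear least-squares
loop. This package implements and compares three such analytical models
for a homogeneous, semi-infinite medium, benchmarked against an in-package
Monte Carlo photon-transport reference:

* **Modified Beer--Lambert (`mbl`)** --- attenuation affine in the optical
  coefficients: $A(\lambda) = M_1\mu_a + M_2\mu_s' + M_3$,
  $R = \exp(-A/100)$. The classical unit-path-length model is the special
  case $M_1 = M_2 = L$, $M_3 = 0$.
* **Jacques (1999) (`jacques`)** --- a single effective photon path length
  built from diffusion quantities: $N' = \mu_s'/\mu_a$,
  $\delta = 1/\sqrt{3\mu_a(\mu_a+\mu_s')}$,
  $A = M_1 + M_2\,N'^{1/M_3}$, $R = \exp(-A\,\delta\,\mu_a)$.
* **Simplified Yudovsky (2009) (`yudovsky`)** --- a semi-empirical
  Kubelka--Munk-type curve in the reduced albedo
  $w' = \mu_s'/(\mu_a+\mu_s')$ alone:
  $R = M_1 + M_2 e^{M_3 w'^{M_4}} + M_5 (1.02-w')^{-M_6}$.

All three consume only $\mu_a(\lambda)$ and $\mu_s'(\lambda)$; the medium's
refractive index enters through the fitted coefficients $M_i$
("hyperparameters"), one set per model per index.

Two printed forms of these equations are typographically ambiguous; the
parses adopted here were fixed by sanity limits *before* any calibration
was run. The Yudovsky tail is read as $M_5(1.02-w')^{-M_6}$ (the
alternative divides by zero at the tabulated $M_6 = 1.02$); with the
published coefficients this gives $R(w'{=}0) \approx 0.0005$ and
$R(w'{=}1) \approx 0.845$, exactly the behavior a reflectance curve must
have. The Jacques exponent is read as $N'^{1/M_3}$ (the alternative
$e^{M_3\ln N'}$ explodes for typical $N' \sim 10$--$100$).

# Optical property models

**Tissue.** Absorption is a blood/background mixture,
$\mu_a = f_{blood}\,\mu_{a,blood} + (1-f_{blood})\,\mu_{a,back}$, with
$\mu_{a,blood} = c_{HbT}\ln(10)/64500 \cdot
[\mathrm{StO_2}\,\varepsilon_{HbO_2} + (1-\mathrm{StO_2})\,\varepsilon_{Hb}]$
($c_{HbT} = 150$ g L^-1^) and the background power law
$\mu_{a,back} = 7.84\times10^{8}\,\lambda^{-3.255}$ cm^-1^. Reduced
scattering follows the Mie power law
$\mu_s' = a\,(\lambda/500)^{-b}$ with $a \in [8, 70]$ cm^-1^ and
$b \in [0.1, 3.3]$; $f_{blood} \in [0.002, 0.07]$, StO~2~ $\in [0,1]$,
anisotropy $g \in [0.7, 0.9]$. All coefficients are held in cm^-1^
throughout. The bundled hemoglobin extinction table is an approximate
transcription of the standard compiled literature curves at 5 nm spacing;
because the Monte Carlo reference and the analytical models consume the
*same* table, every comparative quantity in this package (NRMSE, APE,
model orderings) is insensitive to transcription error --- only the
absolute realism of individual spectra depends on it. Lookups interpolate
linearly and refuse to extrapolate.

**Phantoms.** Gelatin phantoms replace hemoglobin with stable dyes (acid
red 1 and 14 mimicking oxy-/deoxyhemoglobin, crystal violet as a third
chromophore):
$\mu_a = 8\times10^{-6} c_{tot}\ln(10)\,[AR1\,\varepsilon_{AR1,eff} +
AR14\,\varepsilon_{AR14,eff} + CV\,\varepsilon_{CV,eff}] + \mu_{a,gelatin}$,
the two-dye design being the $CV = 0$ special case. The *effective*
extinction curves already include the impact-equalisation factors (53 for
AR14, 12 for CV). Scattering comes from intralipid via the affine
calibration $a = 6.66\,(I/I_0) + 2.55$ cm^-1^ ($I_0 = 1\%$ v/v) with a
fixed Mie exponent $b = 0.98$. The measured effective dye curves are
published only as figures, so the package generates synthetic ones: sums
of Gaussian peaks with the red-dye maxima near 505/515 nm (about 45 nm
below the corresponding hemoglobin features, as for the real dyes), the
crystal violet maximum near 590 nm, and a systematic +5 nm "gelatin
shift". Parameter-recovery conclusions depend on the peaks being distinct
and correctly scaled, not on their exact shapes; this is asserted in the
tests. The gelatin background is a weak smooth stand-in
($0.2\,(\lambda/500)^{-2}$ cm^-1^), of the right order for a
dye-free matrix.

# The Monte Carlo reference

`simulate_single()` / `simulate_spectrum()` implement standard
layered-medium (MCML-convention) photon-packet transport in a homogeneous
slab: pencil beam at normal incidence with specular deduction
$R_{sp} = ((n_{in}-n_{out})/(n_{in}+n_{out}))^2$, step length
$-\ln(\xi)/\mu_t$, implicit absorption weighting $W\mu_a/\mu_t$,
Henyey--Greenstein deflection sampling (isotropic special case at
$g = 0$), exact unpolarized Fresnel reflection at both faces, and Russian
roulette (threshold $10^{-4}$, survival 0.1 --- the MCML defaults). The
semi-infinite medium is approximated by a 3 cm slab (valid above 1 cm;
verified by a thickness-invariance test). Since `mu_s` (not `mu_s'`) is
the transport input, spectra convert via $\mu_s = \mu_s'/(1-g)$ with one
anisotropy per spectrum.

Two tally-level design choices (documented also in the kernel source):

* **Partial transmission at boundaries.** Instead of the stochastic
  reflect-or-escape draw, the escaping fraction $W(1-R_F)$ is tallied and
  the packet continues with $W R_F$. Identical expectation, substantially
  lower variance. The test suite's *independent oracle* (a naive
  loop-per-photon R implementation) deliberately uses the stochastic
  decision, so agreement between the two is a meaningful cross-check.
* **Exact energy bookkeeping.** Roulette weight adjustments are
  credited/debited against the absorbed tally, so
  $R_{sp} + R_d + T + A = 1$ holds to float rounding on *every* run, not
  just in expectation.

RNG streams (xoshiro256** seeded by splitmix64) derive deterministically
from `(seed, wavelength index, photon index)`: spectra are bit-reproducible
independent of evaluation order.

The kernel was validated against the exact Chandrasekhar H-function value
for a matched isotropic semi-infinite medium (albedo 0.9: MC 0.4159 vs
exact 0.4158), against energy conservation in the zero-absorption
mismatched case, and against the independent naive oracle at
mismatched-boundary parameter sets; these checks live in the test suite.

# Calibration and inversion

`fit_hyperparameters()` fits one coefficient set per (model, index) by
minimizing the stacked squared residuals between model forward spectra
(from ground-truth optical properties) and the reference spectra over all
dataset entries, restricted to 450--600 nm --- the window in which the
Yudovsky model is known to be reliable; quantitative reflectance
fractions, unweighted. The optimizer is Levenberg--Marquardt
(`minpack.lm::nls.lm`, tolerances $10^{-10}$), warm-started from the
published coefficients where they exist (Yudovsky, Jacques) and from the
unit vector for the modified Beer--Lambert, unbounded. Fits are
deterministic given `(dataset, init)`; non-convergence is flagged on the
result, not thrown. Because the Yudovsky model's last two coefficients can
trade off against the first four with near-identical fit quality on small
datasets, `freeze_m6 = TRUE` optionally pins $M_6$ at its universal
tabulated value 1.02 and fits the remaining five.

`invert_tissue()` recovers $(\mathrm{StO_2}, f_{blood}, a, b)$ from a
single spectrum by bound-constrained least squares within the sampling
box; `invert_phantom()` recovers dye fractions (stick-breaking
parameterization keeps them on the simplex), $c_{tot}$ and intralipid
concentration, with bounds $c_{tot} \in [0.5, 40]$ and
$I \in [0.5, 8]\%$ --- generous margins around the design levels (1--20
and 1--6%), since no explicit phantom-fit bounds are prescribed.
Anisotropy and refractive index are never fitted. Initialization is at the
midpoint of each bound interval; an optional seeded Latin-hypercube
multi-start (`n_starts > 1`) guards against local minima and keeps the
best-residual solution. In relative mode both reference and model spectra
are mean-normalized (window 450--575 nm for phantoms --- the region where
the forward models remain reliable for those media --- or the fit window
itself for MC data) before residuals are taken.

# Evaluation

`nrmse()` is RMS error over the window normalized by the reference RMS;
`ape()` is $|e-g|/|g| \times 100$; medians and IQRs use the standard
linear-interpolation quantile. Forward-model correlation pools every
(modelled, reference) wavelength pair across all spectra of a dataset into
one Pearson $r$ with a two-sided no-correlation test --- pooling is the
only reading that yields a single $r$ per model and index.
APE is undefined at zero ground truth; design entries whose true value of
a parameter is zero (e.g. $AR14 = 0$ rows) are excluded from that
parameter's APE summary but still enter the recovered-vs-truth
correlation.

# Study conditions and problem sizes

The reference design simulates 100 spectra per refractive index
(1.33, 1.35, 1.44) at $10^5$ photon packets per wavelength. This package's
default analyses and the acceptance script run a desk-scale version ---
20 spectra per index on the 450--650 nm, 5 nm grid (41 wavelengths) ---
chosen so that a full two-index study completes on a single CPU core in
minutes while keeping the Monte Carlo noise floor below or near the
model-fit signals being measured. The photon budget is allocated where
precision matters: $4\times10^4$ packets per wavelength for the
inversion-facing dataset (median parameter-recovery errors of the good
models are MC-noise limited, scaling as $1/\sqrt{N}$; relative SE
$\approx 0.5\%$) and $10^4$ for the forward-fidelity datasets (NRMSE
means tolerate a $\approx 1\%$ floor). The wavelength sampling density is not
prescribed by the study design; 5 nm resolves the 542/577 nm oxyhemoglobin
doublet while keeping the transport budget modest. Where an acceptance
check targets a small reference NRMSE established at $10^5$ photons, the
desk-scale check widens its band in quadrature with the dataset's own
measured noise floor (computed from the per-wavelength MC standard
errors), since at reduced scale the observed NRMSE is
$\sqrt{\text{model}^2 + \text{noise}^2}$.

The synthetic phantom study defaults to the fast analytical engine for its
pseudo-measurements (the slab MC is available via `engine = "mc"`), at
refractive index 1.35 with measurement artefacts of plausible
spectrophotometer scale: 1% multiplicative noise, 0.02 baseline offset,
3 nm crystal-violet peak jitter. These magnitudes are package choices ---
the study does not quantify its measurement noise --- and are configurable.

# Numerical choices and degenerate inputs

* Quantitative model outputs are clipped below at 0 (the Yudovsky curve is
  slightly negative near $w' = 0$ with published coefficients).
* The Jacques model is undefined at $\mu_a = 0$ and raises a
  `division_by_zero` error rather than returning infinities; tissue
  absorption is strictly positive by construction (background power law),
  so this only bites contrived inputs.
* A medium with $\mu_a = \mu_s = 0$ is rejected as degenerate.
* Extinction lookups are interpolation-only; a grid outside table coverage
  is an error, never an extrapolation.
* The c_tot--intralipid degeneracy is real physics, not an optimizer
  artifact: near-identical phantom spectra arise from different
  (concentration, scattering) pairs, so those two parameters recover far
  worse than the dye fractions under any measurement noise. A dedicated
  test pins $c_{tot}$ 50% off and shows the spectrum is still reproduced.

# What the synthetic data do and do not show

The generators emulate the *statistical structure* of the study: uniform
parameter draws within physiological bounds, the 70-phantom design matrix,
dye-peak geometry and spectrophotometer-scale artefacts. They do not
emulate gelatin chemistry, spatial inhomogeneity, instrument line-shape,
or the unpublished measured dye curves; phantom-side results therefore
validate the *procedure* (forward fidelity ordering, relative-mode
robustness, the concentration/scattering degeneracy) rather than
reproducing the original study's phantom tables numerically.

# Known limitations

* The Monte Carlo engine and the published Yudovsky curve at $n = 1.44$
  agree to about 2--3% across the reduced-albedo range; the original
  study's GPU engine evidently tracked that curve to ~1%. The residual is
  an engine-convention difference (normalization/specular handling in the
  reference engine is not fully specified) that propagates into the
  literature-coefficient forward-fidelity number; refit-based quantities
  are unaffected.
* An unbounded modified Beer--Lambert refit on this package's MC data
  fits considerably better (NRMSE ~0.16) than the reference study reports
  (~0.63), because the optimum takes $M_2 < 0$ --- reflectance increasing
  with scattering, which is physically right but outside the
  Beer--Lambert attenuation interpretation. The package follows the
  stated procedure (unbounded nonlinear least squares); the inversion-side
  conclusion (MBL recovers parameters an order of magnitude worse than
  the other two models) is reproduced either way.
* Single-layer media only; no water/melanin/fat chromophores; no NIR.
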