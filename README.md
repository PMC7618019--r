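# drspectra

Forward and inverse modelling of visible-range (450–650 nm) diffuse
reflectance spectra of homogeneous, semi-infinite turbid media — tissue
and gelatin optical phantoms — with a Monte Carlo photon-transport
reference simulator and a full evaluation harness.

## Who this is for

Biomedical-optics researchers who need to extract tissue oxygen
saturation (StO₂), blood volume fraction and Mie scattering parameters
from diffuse reflectance spectra (e.g. hyperspectral imaging pixels), and
want to know **which analytical reflectance model to trust**. The package
implements three standard single-layer models and benchmarks them, forward
and inverse, against its own gold-standard Monte Carlo simulations and
against synthetic dye/intralipid phantom measurements.

## The models

All three map per-wavelength absorption `μa(λ)` and reduced scattering
`μs′(λ)` (cm⁻¹) to diffuse reflectance `R(λ)`, with per-refractive-index
coefficients `M` fitted against reference spectra:

| id | model | form |
|----|-------|------|
| `mbl` | modified Beer–Lambert | `A = M₁μa + M₂μs′ + M₃`, `R = exp(−A/100)` |
| `jacques` | Jacques (1999) | `N′ = μs′/μa`, `δ = 1/√(3μa(μa+μs′))`, `A = M₁ + M₂N′^(1/M₃)`, `R = exp(−A·δ·μa)` |
| `yudovsky` | simplified Yudovsky (2009) | `w′ = μs′/(μa+μs′)`, `R = M₁ + M₂·exp(M₃w′^M₄) + M₅(1.02−w′)^(−M₆)` |

Tissue absorption is the hemoglobin mixture
`μa = f_blood·μa,blood(StO₂) + (1−f_blood)·7.84×10⁸λ^−3.255`; scattering
is the Mie power law `μs′ = a(λ/500)^−b`. Phantom absorption combines
three synthetic dyes over a gelatin background; phantom scattering follows
the intralipid calibration `a = 6.66(I/I₀) + 2.55` cm⁻¹ with `b = 0.98`.

The Monte Carlo reference (`simulate_spectrum()`) is an MCML-convention
photon-packet transport kernel (Rcpp) for a 3 cm slab: Henyey–Greenstein
scattering, Fresnel boundaries, Russian roulette, exact per-run energy
bookkeeping, and counter-seeded RNG streams for bit-reproducible spectra.

## Worked example

Simulate one tissue spectrum by Monte Carlo, then recover its parameters
with the Yudovsky inverse model:

```r
library(drspectra)

grid  <- wavelength_grid()                      # 450-650 nm, 5 nm steps
truth <- tissue_params(sto2 = 0.62, f_blood = 0.025, a = 28, b = 1.4,
                       g = 0.8, n = 1.44)
props <- tissue_optical_properties(truth, grid)
ref   <- simulate_spectrum(props, g = truth$g,
                           mc_config(n_photons = 1e4, n_inside = 1.44, seed = 7))

hp  <- reference_hyperparameters("yudovsky", 1.44, "refit")
fit <- invert_tissue(ref, "yudovsky", hp)
fit$recovered[c("sto2", "f_blood", "a", "b")]
```

```
$sto2
[1] 0.6328265

$f_blood
[1] 0.02255693

$a
[1] 25.24777

$b
[1] 1.439776
```

StO₂ comes back at 0.633 against a truth of 0.62 (2% error), the
scattering exponent within 3%, blood fraction and Mie amplitude within
about 10% — the residual error is dominated by the 10⁴-photon Monte Carlo
noise of the reference spectrum (and shrinks with `n_photons`). `nrmse()`, `ape()` and `regression_summary()` quantify this over
whole datasets; `run_mc_study()` and `run_phantom_study()` run the full
comparative pipelines (see `analysis/01_mc_model_comparison.R` and
`analysis/02_phantom_study.R`, which write their tables under `results/`).

On desk-scale Monte Carlo datasets (20 spectra per index) the package
reproduces the qualitative study findings: the Yudovsky model fits the MC
reference best (mean refit NRMSE ≈ 0.014 at n = 1.33), Jacques follows
closely (≈ 0.03, four-fold better than its published coefficients at
≈ 0.13), and the modified Beer–Lambert recovers StO₂ with a median error
more than an order of magnitude above the other two (≈ 57% vs ≈ 2% for
Yudovsky at n = 1.44).

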