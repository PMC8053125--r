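---
title: "Models and methods: aptamer-ligand binding kinetics with aptkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: aptamer-ligand binding kinetics with aptkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptkin)
```

## The scientific problem

RNA aptamers selected in vitro against a fluorescent small molecule can
have near-identical equilibrium dissociation constants and yet differ
completely in their ability to act as riboswitches in vivo. The
discriminating quantity is kinetic: the mechanism and rates by which the
ligand-bound complex forms, and in particular how reversible the final
binding step is. `aptkin` implements the complete analysis chain used to
establish this for ciprofloxacin-binding aptamers, where the ligand's
intrinsic fluorescence is quenched on binding and serves as the reporter in
three complementary experiments:

1. **Stopped-flow kinetics** — time courses of the emission after rapid
   mixing of RNA with ligand, one trace series per RNA at several ligand
   concentrations, analysed by pseudo-first-order fitting and by global
   mass-action model fitting with AIC/BIC discrimination.
2. **TCSPC lifetime measurements** — photon-count decay histograms of free
   and bound ligand, analysed by Poisson-weighted multi-exponential
   fitting; the sub-nanosecond quench lifetime reports on the bound state.
3. **Equilibrium titrations** — emission versus RNA (or Mg²⁺)
   concentration at a fixed 50 nM probe, analysed with the modified Hill
   equation.

Because the corresponding instrument datasets are not publicly deposited,
the package carries a first-class synthetic-data module that emulates the
statistical structure of all three experiments; every fitter is validated
by parameter recovery against the generating truth.

## Binding schemes and their ODEs

A mechanism is a `reaction_scheme`: species with roles (receptor, ligand,
intermediate complex, final complex, inactive receptor) and elementary
mass-action reactions. Five canonical mechanisms ship as presets:

| id | scheme | interpretation |
|----|--------|----------------|
| model1 | R + L ⇌ B | one-step reversible binding |
| model2 | Rin ⇌ Ract; Ract + L ⇌ B | conformational selection |
| model3 | R + L → I → B | two irreversible steps |
| model4 | R + L ⇌ I ⇌ B | induced fit, fully reversible |
| model5 | R + L ⇌ I → B | induced fit with irreversible locking |

The differential equations are derived mechanically from the scheme by the
law of mass action with unit stoichiometry: every elementary step
contributes ±k·∏(reactant concentrations) to each participant. No
cooperativity or higher stoichiometry is assumed. Units are fixed
package-wide — μM and seconds, bimolecular rates in μM⁻¹s⁻¹ — so fitted
values are directly comparable with published rate tables without
conversion.

In model2 the preformation rates would collide with the binding-step
rates under the conventional k₁/k₋₁ naming; the package namespaces them
(`k_pre`, `k_unpre`, `k_on`, `k_off`) and `paper_rate_labels()` maps them
back to k₁…k₋₂ in reports. For model2 the receptor pool is initialized at
the preformation equilibrium (`k_pre/(k_pre + k_unpre)` active), reflecting
RNA folded and equilibrated in buffer before mixing.

Integration uses `deSolve::lsoda` driving a compiled generic mass-action
right-hand side, with relative tolerance 1e-8 and absolute tolerance 1e-10
μM. The systems are only mildly stiff (unimolecular rates spanning ~0.06
to ~23 s⁻¹ on top of fast bimolecular association), but the stiff-capable
solver keeps the tolerance budget uniform across schemes. Ligand depletion
is always explicit: the free-ligand pool is a dynamic species, never
clamped. Negative concentrations from round-off are clamped at zero
(silently below 1e-9 μM in magnitude, with a warning up to 1e-6 μM, a hard
error beyond).

Two independent oracles guard the integrator: the closed-form
pseudo-first-order solution of model1
(`closed_form_model1_pfo`, B(t) = B_eq(1 − e^(−k_obs t)) with
k_obs = k₁L₀ + k₋₁), and conservation of the total ligand and receptor
pools, which must hold to < 1e-6 μM along every trajectory. Note that the
closed form itself carries an O(R₀/L₀) ligand-depletion error, so the
achievable agreement with the full simulation is set by the excess ratio,
not by the integrator tolerance; the tests assert exactly this scaling.

## The fluorescence observable and preprocessing

The measured emission is carried by free ligand (response 1) plus
partially quenched contributions from the complexes:

signal(t) = baseline + ([L] + Σ response_s · [complex_s]) / L₀.

The experiments do not constrain how strongly the intermediate complex
fluoresces, so by default both complexes are treated as fully quenched
(response 0); responses can be freed as bounded fit parameters
(`fit_responses = TRUE`), which is deliberately off by default to avoid
over-parametrization. One consequence worth knowing: under the default
observable, model3's second rate k₂ is structurally unidentifiable — the
signal then depends only on free ligand, whose decay is governed by k₁
alone. Distinguishing the two irreversible steps requires an intermediate
with a distinct response.

Measured (and generated) traces pass through one normalization contract,
shared verbatim by data preprocessing and model prediction so that the two
are always on the same scale: average the raw shots pointwise, subtract
the plateau (mean of the final 5% of points), and rescale so signal(0) = 1.
The contract is affine-invariant (a·x + b maps to the same trace), and a
trace whose last decile still drifts by more than 2% of the amplitude is
flagged `plateau-not-reached`. Anchoring at the noisy first point leaves a
small correlated scale error of order σ/√(shots) per trace; this is why
the package's parameter-recovery checks are phrased directly in terms of
recovery error rather than solely in i.i.d. standard-error units.

## Pseudo-first-order analysis

Under ligand excess each trace is approximately mono-exponential.
`fit_monoexponential` fits offset + amplitude·e^(−k_obs·t) with the
initial rate guess ln 2 / t_half; `kon_regression` then regresses k_obs on
ligand concentration, reporting the slope as the apparent association rate
k_on and the intercept as the apparent off-rate. Saturation at high ligand
excess (k_obs plateauing, as expected when a conformational step becomes
rate-limiting) is detected as a high-concentration point falling below the
regression line with a studentized residual beyond −3; such points are
excluded from the slope with a logged note. The exclusion is one-sided and
restricted to concentrations above the median because, on low-noise data,
the dominant residual structure is ligand-depletion curvature at the *low*
end, which must not be discarded.

At the reference design's 2 equivalents of ligand the depletion bias is
substantial (the fitted k_obs falls below k₁L₀ + k₋₁ by ~15–20%), which is
the reason global ODE fitting — with explicit depletion — is the primary
analysis and the k_on regression a cross-check.

## Global fitting and model discrimination

`global_fit` minimizes the summed squared residuals over all traces of a
concentration series simultaneously, rates shared across traces.
Numerical choices:

* **Parametrization.** Rates are optimized as log₁₀(k), which enforces
  positivity and makes the default bounds [1e-3, 1e3] (in each rate's
  natural unit) symmetric in the search space.
* **Multi-start.** Two-step models have genuine local minima under noise,
  so the Levenberg–Marquardt optimizer is launched from 20 starts drawn
  log-uniformly within the bounds from a recorded seed (the first start is
  the bounds' geometric midpoint); the best converged start wins. Failed
  starts are recorded in the result's convergence table; a fit where *no*
  start converges is an error carrying that table.
* **Standard errors** come from the linearized covariance at the optimum,
  RSS/(n−p)·(JᵀJ)⁻¹, with the Jacobian in natural (linear) parameters.
  Parameters that end on a bound are flagged, not silently reported.
* **Dead time** defaults to 0 (none is published for the reference data)
  but can be set to truncate the first d seconds of every trace.

Model comparison uses the least-squares information criteria
AIC = n·ln(RSS/n) + 2p and BIC = n·ln(RSS/n) + p·ln n, where p counts free
rates plus free observable parameters; additive constants cancel in the
ΔAIC/ΔBIC values, which are reported relative to the best model of the
comparison. The small-sample AICc is available behind a flag. Two models
within ΔAIC < 2 are reported as indistinguishable rather than ranked —
this matters in practice, because the fully reversible model4 nests
model5 (k₋₂ → 0) and on irreversible-locking data the two fit equally
well, with the simpler model winning on BIC.

The implied equilibrium constant of a fitted mechanism is available as
`apparent_kd`: k₋₁/k₁ for one-step binding, (k₋₁/k₁)·(k₋₂/(k₂+k₋₂)) for
the reversible two-step scheme, and 0 for mechanisms with an irreversible
final step. model2 is rejected there because its apparent K_D also depends
on the inactive fraction, which is not a function of the binding-step
rates alone.

## TCSPC decay fitting

`fit_decay` models channel counts as bg + Σ aᵢ·e^(−t/τᵢ), minimizing the
Poisson-weighted chi-square Σ(obs − model)²/max(obs, 1); the max(obs, 1)
floor keeps empty channels usable, at the cost of deflating the reduced χ²
when a large fraction of channels is nearly empty (choose the channel
range to match the decay, as one would on the instrument). Amplitudes are
constrained non-negative and reported as percentages of their sum;
lifetimes are bounded to [0.05, 50] ns because sub-channel lifetimes are
not resolvable without a measured instrument response. Components are
returned sorted by ascending lifetime, so the quench lifetime τ_q of a
bound-state decay is always the first row. By default the decay is
tail-fitted from the peak channel (no IRF is published for the reference
setup); optional Gaussian-IRF reconvolution (default FWHM 0.5 ns, the
pulsed-LED regime) is available. Near-degenerate lifetime pairs (within
1%) are flagged as unresolvable.

`select_n_components` fits n = 1, 2, 3 sequentially and accepts the larger
model only when the reduced χ² improves by more than 5% *and* every new
component is significant (amplitude > 3× its SE), returning the decision
trail. The amplitude-weighted average lifetime ⟨τ⟩ = Σ(Aᵢ/100)·τᵢ
summarizes a fit; on the free-ligand biexponential composition it
evaluates to 1.9 ns.

## Equilibrium titrations

The modified Hill equation y = B_max·xʰ/(K_Dʰ + xʰ) is fitted by
unweighted least squares with initial guesses B_max = max response, K_D =
concentration at half-max, h = 1. The canonical response is the quench
fraction (F₀ − F)/F₀, which rises with binding and follows the printed
functional form directly; raw F/F₀ can be fitted via
`response_is_quench = FALSE`. Ligand depletion is ignored exactly as the
Hill form does — at a 50 nM probe against K_D ≈ 13 nM this biases K_D
upward slightly, which is a property of the assay's standard analysis, not
of the implementation. K_D and h are optimized on a log scale (positivity);
a flat response is returned as a diagnosed `no-binding` failure rather
than a degenerate fit, mirroring the behaviour of cation-starved aptamers.
`kd_vs_mg_profile` assembles per-Mg²⁺ fits into the familiar K_D-vs-Mg²⁺
profile, flagging non-binding levels. The Hill slope of the Mg²⁺
dependence is used descriptively (apparent cooperativity of folding), not
as a physical multi-site binding model.

## What the synthetic data do and do not emulate

`gen_stopped_flow` simulates the scheme per ligand concentration, applies
the observable, adds per-shot Gaussian noise *on the normalized scale*
(i.e. as a fraction of the quench amplitude — the natural scale after
detector gain adjustment; raw-scale noise would grow ~5× across the
concentration series), averages the shots and runs the preprocessing
contract. `gen_tcspc` Poisson-samples expected counts; `gen_titration`
adds Gaussian noise to exact Hill responses. All generators require an
explicit seed and are bit-reproducible given it.

Defaults encode the reference experiment: RNA 2 μM; ligand 4, 8, 12, 16,
20 μM; 25 shots averaged per concentration (within the reported 20–30);
per-shot σ = 0.01 (a stand-in — the instrument's true noise is
unpublished); TCSPC histograms of 1024 × 25 ps channels; titrations of 12
log-spaced points over 1–500 nM at a 50 nM probe. Traces are sampled on a
logarithmic time base (t = 0 anchor, then 0.3 ms to 2 s, 400 points): the
fastest association phase at 10 equivalents has a ~5 ms time constant
while the slowest fitted back-rate (0.06 s⁻¹) only leaves a measurable
signature over seconds, and a log base resolves both. Named presets
(`kinetic_presets()`, `decay_preset()`) carry the published rate and
lifetime tables verbatim so that tests and scripts reference presets, not
retyped numbers.

Not emulated: mixing artifacts and dead-time distortion, photobleaching,
detector pile-up, RF pickup, and any heteroscedasticity beyond the
Poisson/Gaussian models above. Passing recovery tests on these synthetics
therefore validates the estimators under the assumed noise structure; they
cannot certify robustness to instrument systematics.

## Problem sizes and reproducibility

The shipped tests and the acceptance script run the full pipeline at the
reference design (five concentrations × 400 points, 1e6-count histograms,
12-point titrations), with 8–20 optimizer starts per global fit; a
complete run takes well under a minute per global fit on a single core.
`scripts/acceptance.R --seed S --out results.json` regenerates every
synthetic dataset and recomputes the seven headline recovery quantities
from scratch; all randomness derives from the given seed.

## Known limitations

* Standard errors of global stopped-flow fits assume i.i.d. residuals;
  the normalization anchor induces weak correlation, making them somewhat
  optimistic. Replicated-seed calibration (as done for the Hill fitter in
  the tests) is the honest way to assess them.
* The observable model ties all traces of a series to a single response
  set; per-trace responses or baselines are not fitted.
* No stochastic (Gillespie) simulation, diffusion-limited kinetics, or
  temperature dependence; no global (linked) lifetime analysis across
  histograms; no exact-depletion binding isotherm by default (a quadratic
  alternative is deliberately out of the default path).

## A worked example

```{r example, eval = FALSE}
library(aptkin)

# generate a synthetic series for the locking mechanism and refit it
ser <- gen_stopped_flow("RS-model5",
                        noise = noise_spec("gaussian", sigma = 0.005,
                                           seed = 11))
fits <- lapply(paste0("model", c(1, 4, 5)), function(m)
  global_fit(scheme_preset(m), ser,
             options = global_fit_options(n_starts = 10, seed = 12)))
compare_models(fits)

# pseudo-first-order cross-check
kon_regression(ser)

# lifetime analysis of the bound state
h <- gen_tcspc("CFX@A", noise = noise_spec("poisson", total_counts = 1e6,
                                           seed = 13))
fit_decay(h, n_components = 3)
```
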