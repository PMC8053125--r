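# aptkin

Kinetic and equilibrium analysis of aptamer–ligand binding from
fluorescence data.

`aptkin` is for RNA scientists who characterize small-molecule binding
aptamers and riboswitches with the ligand's own fluorescence as the
reporter. Aptamers with indistinguishable equilibrium constants can differ
decisively in their binding *kinetics* — in particular in how reversible
the final, conformational step of binding is — and that difference is what
separates a mere binder from a working riboswitch. The package implements
the three analyses that establish this, end to end:

* **Stopped-flow kinetics.** Binding mechanisms are declared as
  mass-action reaction schemes (five canonical mechanisms built in, from
  one-step binding `R + L ⇌ B` through conformational selection and
  induced fit to irreversible locking `R + L ⇌ I → B`). Their ODE systems
  are derived mechanically and fitted **globally** — all ligand
  concentrations of a series simultaneously, rate constants shared — by
  multi-start Levenberg–Marquardt. Mechanisms are discriminated with
  ΔAIC/ΔBIC (`AIC = n ln(RSS/n) + 2p`, `BIC = n ln(RSS/n) + p ln n`).
  Pseudo-first-order analysis (mono-exponential `k_obs` per trace, slope
  of `k_obs` vs ligand = apparent `k_on`) is included as the classical
  cross-check.
* **TCSPC fluorescence decays.** Poisson-weighted multi-exponential
  fitting of photon-count histograms, `χ² = Σ (obs − model)²/max(obs, 1)`,
  with component-count selection and amplitude-weighted average lifetimes
  `⟨τ⟩ = Σ (Aᵢ/100) τᵢ`. The sub-ns quench lifetime of the bound ligand is
  always the first reported component.
* **Equilibrium titrations.** Modified-Hill fits
  `y = B_max xʰ/(K_Dʰ + xʰ)` for apparent `K_D`, and Hill analysis of
  Mg²⁺-dependence profiles of the binding-competent fraction.

Since the corresponding instrument datasets are not publicly deposited,
the package ships a first-class synthetic-data module
(`gen_stopped_flow`, `gen_tcspc`, `gen_titration`) that reproduces the
statistical structure of each experiment under the published parameter
sets (available as named presets), so every estimator is validated by
parameter recovery. See the vignette
(`vignettes/aptamer-binding-kinetics.Rmd`) for models, assumptions and
numerical choices.

## Worked example

Generate a stopped-flow series for the irreversible-locking mechanism
(rates of the optimized riboswitch preset: k₁ = 7.62 μM⁻¹s⁻¹,
k₋₁ = 2.9 s⁻¹, k₂ = 23 s⁻¹), refit three candidate mechanisms, and compare:

```r
library(aptkin)

ser <- gen_stopped_flow("RS-model5",
                        noise = noise_spec("gaussian", sigma = 0.005,
                                           seed = 11))
fits <- lapply(paste0("model", c(1, 4, 5)), function(m)
  global_fit(scheme_preset(m), ser,
             options = global_fit_options(n_starts = 10, seed = 12)))
fits[[3]]
#> <global_fit_result> scheme model5 on 'RS-model5'
#>   k1 = 7.618±0.002
#>   k-1 = 2.89±0.02
#>   k2 = 22.7±0.2
#>   RSS = 0.0025704, RMSD = 0.0011337 (n = 2000, p = 3)

compare_models(fits)
#>  scheme n_parameters         rss        rmsd       aic       bic delta_aic delta_bic
#>  model1            2 0.095453930 0.006908471 -19896.03 -19884.83      7227      7222
#>  model4            4 0.002570799 0.001133755 -27120.88 -27098.48         2         8
#>  model5            3 0.002570441 0.001133676 -27123.16 -27106.36         0         0
```

The generating rates are recovered within their uncertainties; the
one-step model is decisively rejected, and the fully reversible two-step
model4 — which contains the generating model5 as its k₋₂ → 0 limit — fits
equally well but is penalized for its extra parameter, so model5 wins both
criteria. (Models within ΔAIC < 2 are reported as indistinguishable rather
than ranked.)

Lifetime analysis of a bound-state decay histogram (generating
composition 0.64 ns/77%, 2.48 ns/14%, 6.5 ns/9%):

```r
h <- gen_tcspc("CFX@A", noise = noise_spec("poisson", total_counts = 1e6,
                                           seed = 13))
fit_decay(h, n_components = 3)
#> <decay_fit> 3 component(s), reduced chi2 = 1.004
#>   tau = 0.638±0.006 ns (76.4±0.2 %)
#>   tau = 2.3±0.1 ns (14.1±0.7 %)
#>   tau = 6.34±0.07 ns (9.6±0.7 %)
```

Equilibrium titration (truth: K_D = 13 nM, h = 1):

```r
cur <- gen_titration(list(K_D = 13, h = 1, B_max = 1),
                     noise = noise_spec("gaussian", sigma = 0.01, seed = 14))
fit_hill(cur)
#> <hill_fit> K_D = 12.6±0.4 nM, h = 0.97±0.02, B_max = 1.005±0.008
```

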