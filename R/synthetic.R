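# Synthetic-data generators for all three experiment types, plus the named
# rate/lifetime presets used throughout tests and examples.

#' Noise specification for the generators
#'
#' @param kind `"gaussian"` (stopped-flow, titration) or `"poisson"`
#'   (TCSPC).
#' @param sigma Per-shot / per-point Gaussian standard deviation (normalized
#'   signal units).
#' @param total_counts Target total photon counts for Poisson histograms.
#' @param seed Mandatory integer seed; every generated dataset records it.
#'   There is no global random state: generation is deterministic given the
#'   spec and seed.
#' @return A `noise_spec` object.
#' @export
noise_spec <- function(kind = c("gaussian", "poisson"), sigma = 0.01,
                       total_counts = 1e6, seed) {
  kind <- match.arg(kind)
  if (missing(seed)) stop("noise_spec: a seed is mandatory")
  stopifnot(sigma >= 0, total_counts >= 1)
  structure(list(kind = kind, sigma = sigma, total_counts = total_counts,
                 seed = as.integer(seed)), class = "noise_spec")
}

#' Named kinetic parameter presets
#'
#' Rate-constant sets for the three aptamer candidates (A, preRS, RS) under
#' the one-step scheme and the best-supported two-step schemes, as
#' determined by global stopped-flow analysis. Units: k1 in uM^-1 s^-1, all
#' others s^-1. The one-step RS off-rate is below the resolvable level
#' (< 1e-6 s^-1) and is stored as 1e-7.
#'
#' @param name Preset name, e.g. `"A-model4"`, `"RS-model5"`; see
#'   `names(kinetic_presets())`.
#' @return `preset_rates()`: list with `scheme` (a [reaction_scheme()]) and
#'   `rates` (named numeric). `kinetic_presets()`: the full preset list.
#' @export
kinetic_presets <- function() {
  list(
    "A-model1"     = list(scheme = "model1",
                          rates = c(k1 = 7.78, k_m1 = 0.33)),
    "preRS-model1" = list(scheme = "model1",
                          rates = c(k1 = 3.61, k_m1 = 0.09)),
    "RS-model1"    = list(scheme = "model1",
                          rates = c(k1 = 5.21, k_m1 = 1e-7)),
    "A-model4"     = list(scheme = "model4",
                          rates = c(k1 = 10, k_m1 = 1.6, k2 = 4, k_m2 = 2.3)),
    "A-model5"     = list(scheme = "model5",
                          rates = c(k1 = 10, k_m1 = 0.8, k2 = 6)),
    "preRS-model4" = list(scheme = "model4",
                          rates = c(k1 = 4.33, k_m1 = 5.7, k2 = 13.2,
                                    k_m2 = 0.06)),
    "preRS-model5" = list(scheme = "model5",
                          rates = c(k1 = 4.31, k_m1 = 5.4, k2 = 12.1)),
    "RS-model4"    = list(scheme = "model4",
                          rates = c(k1 = 7.6, k_m1 = 3.1, k2 = 23,
                                    k_m2 = 0.27)),
    "RS-model5"    = list(scheme = "model5",
                          rates = c(k1 = 7.62, k_m1 = 2.9, k2 = 23)))
}

#' @rdname kinetic_presets
#' @export
preset_rates <- function(name) {
  presets <- kinetic_presets()
  if (!name %in% names(presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  list(scheme = scheme_preset(p$scheme), rates = p$rates)
}

#' Named fluorescence-lifetime presets
#'
#' Multi-exponential decay compositions of the free ligand and the three
#' ligand-aptamer complexes (lifetimes in ns, amplitudes in percent), plus
#' the mono-exponential cation-free ligand decay.
#'
#' @param name One of `"CFX"`, `"CFX@A"`, `"CFX@preRS"`, `"CFX@RS"`,
#'   `"CFX-cation-free"`.
#' @return Data frame with columns `tau_ns`, `amplitude_pct`.
#' @export
decay_preset <- function(name) {
  presets <- list(
    "CFX"             = data.frame(tau_ns = c(1.28, 2.92),
                                   amplitude_pct = c(65, 35)),
    "CFX@A"           = data.frame(tau_ns = c(0.64, 2.48, 6.5),
                                   amplitude_pct = c(77, 14, 9)),
    "CFX@preRS"       = data.frame(tau_ns = c(0.43, 2.22, 6.3),
                                   amplitude_pct = c(53, 37, 10)),
    "CFX@RS"          = data.frame(tau_ns = c(0.49, 1.90, 8.3),
                                   amplitude_pct = c(58, 36, 6)),
    "CFX-cation-free" = data.frame(tau_ns = 1.3, amplitude_pct = 100))
  if (!name %in% names(presets))
    stop("unknown decay preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  presets[[name]]
}

#' Experiment designs
#'
#' `stopped_flow_design()` defaults reproduce the reference experiment:
#' RNA at 2 uM mixed with ligand at 4, 8, 12, 16 and 20 uM (2-10
#' equivalents), 25 shots averaged per concentration, sampled on a
#' logarithmic time base (plus the t = 0 anchor) out to 2 s so that both
#' the millisecond association phase and the slow second-step relaxation
#' are resolved.
#'
#' @param receptor_conc_uM RNA concentration (uM).
#' @param ligand_concs_uM Ligand concentrations (uM).
#' @param duration_s Trace duration (s).
#' @param n_points Points per trace.
#' @param shots_per_concentration Raw shots averaged per concentration.
#' @param t_first_s First non-zero sample time of the log grid (s).
#' @return A design list; `$time_grid` carries the sampling grid.
#' @export
stopped_flow_design <- function(receptor_conc_uM = 2,
                                ligand_concs_uM = c(4, 8, 12, 16, 20),
                                duration_s = 2, n_points = 400L,
                                shots_per_concentration = 25L,
                                t_first_s = 3e-4) {
  grid <- c(0, exp(seq(log(t_first_s), log(duration_s),
                       length.out = n_points - 1L)))
  list(receptor_conc_uM = receptor_conc_uM,
       ligand_concs_uM = ligand_concs_uM, duration_s = duration_s,
       n_points = as.integer(n_points),
       shots_per_concentration = as.integer(shots_per_concentration),
       time_grid = grid)
}

#' @rdname stopped_flow_design
#' @param n_channels,channel_width_ns,background TCSPC histogram geometry
#'   and flat background (counts/channel).
#' @export
tcspc_design <- function(n_channels = 1024L, channel_width_ns = 0.025,
                         background = 0) {
  list(n_channels = as.integer(n_channels),
       channel_width_ns = channel_width_ns, background = background)
}

#' @rdname stopped_flow_design
#' @param titrant_grid Titrant concentrations; default 12 log-spaced points
#'   over 1-500 nM (RNA titration at a 50 nM probe).
#' @param probe_conc_nM Fixed probe concentration.
#' @param titrant_unit,titrant Axis metadata.
#' @export
titration_design <- function(titrant_grid = exp(seq(log(1), log(500),
                                                    length.out = 12L)),
                             probe_conc_nM = 50, titrant_unit = "nM",
                             titrant = "RNA") {
  list(titrant_grid = titrant_grid, probe_conc_nM = probe_conc_nM,
       titrant_unit = titrant_unit, titrant = titrant)
}

#' Generate a synthetic stopped-flow concentration series
#'
#' For each ligand concentration the scheme is integrated, the fluorescence
#' observable applied, per-shot Gaussian noise added, shots averaged and the
#' result passed through the [preprocess()] contract -- exactly the path a
#' measured series takes. Deterministic given the seed.
#'
#' @param scheme A [reaction_scheme()], or a preset name like `"A-model4"`
#'   (in which case `rates` may be omitted).
#' @param rates Named rates.
#' @param design A [stopped_flow_design()].
#' @param observable An [observable_map()]; default: both complexes fully
#'   quenched.
#' @param noise A Gaussian [noise_spec()]; `sigma` is the per-shot noise as
#'   a fraction of the trace's quench amplitude (i.e. in normalized signal
#'   units, where every preprocessed trace decays from 1 to 0), so a
#'   25-shot average carries residual noise of about `sigma / 5`.
#' @param label Series label; defaults to the preset name when one is used.
#' @return A [trace_series()].
#' @export
gen_stopped_flow <- function(scheme, rates = NULL,
                             design = stopped_flow_design(),
                             observable = observable_map(),
                             noise = noise_spec("gaussian", sigma = 0.01,
                                                seed = 1),
                             label = NULL) {
  if (is.character(scheme)) {
    p <- preset_rates(scheme)
    if (is.null(label)) label <- scheme
    if (is.null(rates)) rates <- p$rates
    scheme <- p$scheme
  }
  if (is.null(label)) label <- scheme$id
  stopifnot(noise$kind == "gaussian")
  set.seed(noise$seed)
  grid <- design$time_grid
  traces <- lapply(design$ligand_concs_uM, function(L0) {
    clean <- predict_signal_raw(scheme, rates, observable, grid, L0,
                                design$receptor_conc_uM)
    # express per-shot noise on the normalized scale (fraction of the
    # quench amplitude), so the noise level is comparable across ligand
    # concentrations, as it is for the detector after gain adjustment
    clean <- as.numeric(normalize_signal(clean))
    shots <- matrix(rnorm(length(grid) * design$shots_per_concentration,
                          mean = clean, sd = noise$sigma),
                    nrow = length(grid))
    suppressWarnings(
      preprocess(shots, grid, ligand_conc_uM = L0,
                 receptor_conc_uM = design$receptor_conc_uM))
  })
  trace_series(traces, label = label)
}

# Un-normalized observable signal (the "instrument" output before the
# preprocessing contract); shared by gen_stopped_flow and predict_signal.
predict_signal_raw <- function(scheme, rates, observable, time_s,
                               ligand_conc_uM, receptor_conc_uM) {
  resp <- resolve_responses(observable, scheme)
  y0 <- initial_state(scheme, rates, R0 = receptor_conc_uM,
                      L0 = ligand_conc_uM)
  traj <- simulate_scheme(scheme, rates, y0, time_s)
  lig <- species_of_role(scheme, "ligand")
  raw <- traj$conc[, lig]
  for (s in names(resp)) raw <- raw + resp[[s]] * traj$conc[, s]
  observable$baseline + raw / ligand_conc_uM
}

#' Generate a synthetic TCSPC decay histogram
#'
#' Expected channel counts follow the multi-exponential model (optionally
#' convolved with a Gaussian IRF), scaled so the expected total equals
#' `noise$total_counts`, then Poisson-sampled per channel. Deterministic
#' given the seed.
#'
#' @param components Data frame with `tau_ns` and `amplitude_pct` (e.g.
#'   from [decay_preset()]), or a preset name.
#' @param design A [tcspc_design()].
#' @param noise A Poisson [noise_spec()].
#' @param irf_fwhm_ns Optional Gaussian IRF width; `NULL` (default) for an
#'   ideal delta excitation (tail-fit regime).
#' @return A [decay_histogram()].
#' @export
gen_tcspc <- function(components, design = tcspc_design(),
                      noise = noise_spec("poisson", total_counts = 1e6,
                                         seed = 1),
                      irf_fwhm_ns = NULL) {
  if (is.character(components)) components <- decay_preset(components)
  stopifnot(noise$kind == "poisson",
            all(c("tau_ns", "amplitude_pct") %in% names(components)))
  if (any(components$tau_ns < 0.05 | components$tau_ns > 50))
    stop("lifetimes must lie within [0.05, 50] ns")
  t <- (seq_len(design$n_channels) - 1L) * design$channel_width_ns
  f <- components$amplitude_pct / sum(components$amplitude_pct)
  shape <- numeric(length(t))
  for (i in seq_along(f)) shape <- shape + f[i] * exp(-t / components$tau_ns[i])
  irf <- NULL
  if (!is.null(irf_fwhm_ns)) {
    irf <- gaussian_irf(t, irf_fwhm_ns)
    shape <- convolve_irf(shape, irf)
  }
  bg_total <- design$background * design$n_channels
  scale <- max(noise$total_counts - bg_total, 0) / sum(shape)
  expected <- design$background + scale * shape
  set.seed(noise$seed)
  counts <- rpois(length(expected), expected)
  decay_histogram(t, counts, background = design$background, irf = irf)
}

#' Generate a synthetic equilibrium titration curve
#'
#' [hill_model()] responses plus i.i.d. Gaussian noise. Deterministic given
#' the seed. Warns when the generating K_D falls outside the titrant grid.
#'
#' @param true_fit List with `K_D`, `h`, `B_max` (generating truth).
#' @param design A [titration_design()].
#' @param noise A Gaussian [noise_spec()].
#' @return A [titration_curve()].
#' @export
gen_titration <- function(true_fit, design = titration_design(),
                          noise = noise_spec("gaussian", sigma = 0.01,
                                             seed = 1)) {
  stopifnot(noise$kind == "gaussian",
            all(c("K_D", "h", "B_max") %in% names(true_fit)))
  x <- design$titrant_grid
  if (true_fit$K_D < min(x) || true_fit$K_D > max(x))
    warning("generating K_D lies outside the titrant grid; the fit will ",
            "extrapolate")
  y <- hill_model(x, true_fit$K_D, true_fit$h, true_fit$B_max)
  set.seed(noise$seed)
  titration_curve(x, y + rnorm(length(x), sd = noise$sigma),
                  probe_conc_nM = design$probe_conc_nM,
                  titrant_unit = design$titrant_unit,
                  titrant = design$titrant)
}

#' Time to reach the binding plateau
#'
#' Utility on generated or measured traces: the earliest time from which
#' the signal stays within `frac` of its total amplitude from the plateau.
#' Used to compare equilibration times across candidates.
#'
#' @param trace A [stopped_flow_trace()] (normalized: 1 at t = 0, 0 at the
#'   plateau).
#' @param frac Closeness criterion as a fraction of the amplitude. The 2%
#'   default reflects what is resolvable by eye on a plotted trace;
#'   mechanisms with a reversible second step have a shallow slow tail
#'   that dominates much tighter criteria without being visible.
#' @return Time (s).
#' @export
equilibration_time <- function(trace, frac = 0.02) {
  s <- trace$signal
  within <- abs(s) <= frac
  # earliest index from which the trace never leaves the band again
  stay <- rev(cumprod(rev(within))) > 0
  if (!any(stay)) return(NA_real_)
  trace$time_s[which(stay)[1]]
}
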