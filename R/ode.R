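# ODE construction and integration for mass-action schemes.
# Units package-wide: concentrations uM, time s, bimolecular rates uM^-1 s^-1.

# Expand reversible reactions into elementary irreversible steps with
# resolved rate values. Errors if any rate symbol is missing from `rates`.
elementary_steps <- function(scheme, rates) {
  syms <- rate_symbols(scheme)
  missing <- setdiff(syms, names(rates))
  if (length(missing))
    stop("missing rate value for symbol(s): ", paste(missing, collapse = ", "),
         " (scheme '", scheme$id, "')")
  bad <- syms[!is.finite(unlist(rates[syms])) | unlist(rates[syms]) < 0]
  if (length(bad))
    stop("rate constants must be finite and >= 0; offending symbol(s): ",
         paste(bad, collapse = ", "))
  steps <- list()
  for (r in scheme$reactions) {
    steps[[length(steps) + 1L]] <-
      list(reactants = r$reactants, products = r$products, k = rates[[r$forward]])
    if (!is.null(r$reverse))
      steps[[length(steps) + 1L]] <-
        list(reactants = r$products, products = r$reactants, k = rates[[r$reverse]])
  }
  steps
}

#' Build the mass-action ODE right-hand side of a scheme
#'
#' Derives the system of ordinary differential equations mechanically from
#' the scheme by the law of mass action with unit stoichiometry: each
#' elementary step contributes +/- k * prod(reactant concentrations) to the
#' derivative of every participating species.
#'
#' @param scheme A [reaction_scheme()].
#' @param rates Named numeric vector or list, one non-negative value per
#'   rate symbol of the scheme (s^-1 for unimolecular, uM^-1 s^-1 for
#'   bimolecular steps).
#' @return A function `(t, state)` returning the named vector of
#'   time-derivatives (uM/s); `state` is a named concentration vector.
#' @examples
#' f <- build_ode(scheme_preset("model1"), c(k1 = 1, k_m1 = 0))
#' f(0, c(R = 1, L = 1, B = 0))  # dB/dt = 1
#' @export
build_ode <- function(scheme, rates) {
  steps <- elementary_steps(scheme, as.list(rates))
  nm <- species_names(scheme)
  function(t, state) {
    y <- state[nm]
    d <- setNames(numeric(length(nm)), nm)
    for (s in steps) {
      v <- s$k * prod(y[s$reactants])
      d[s$reactants] <- d[s$reactants] - v
      d[s$products] <- d[s$products] + v
    }
    d
  }
}

# Encode a scheme + rates as the fixed-length parameter vector understood by
# the compiled RHS (see src/mass_action.c).
.PMAX <- 256L

encode_scheme <- function(scheme, rates) {
  steps <- elementary_steps(scheme, as.list(rates))
  nm <- species_names(scheme)
  enc <- c(length(nm), length(steps))
  for (s in steps) {
    ri <- match(s$reactants, nm) - 1L
    pi <- match(s$products, nm) - 1L
    enc <- c(enc,
             length(ri), ri[1], if (length(ri) == 2) ri[2] else -1,
             length(pi), pi[1], if (length(pi) == 2) pi[2] else -1,
             s$k)
  }
  if (length(enc) > .PMAX) stop("scheme too large for the compiled backend")
  c(enc, numeric(.PMAX - length(enc)))
}

# Clamp small negative concentrations produced by integrator round-off.
# Silent below 1e-9 uM in magnitude, warning up to 1e-6, hard error beyond.
clamp_negatives <- function(conc, context = "simulate") {
  mn <- min(conc)
  if (mn >= 0) return(conc)
  if (mn < -1e-6)
    stop(context, ": negative concentration ", format(mn),
         " uM exceeds round-off tolerance; integration is unreliable")
  if (mn < -1e-9)
    warning(context, ": clamped negative concentrations down to ",
            format(mn), " uM (integrator round-off)")
  pmax(conc, 0)
}

#' Simulate the concentration time course of a scheme
#'
#' Integrates the mass-action ODE system with a stiff-capable solver
#' (`deSolve::lsoda` driving a compiled right-hand side). Default
#' tolerances (rtol 1e-8, atol 1e-10 uM) resolve the mildly stiff rate
#' ranges typical of two-step binding (unimolecular rates from ~0.06 to
#' ~23 s^-1 on top of fast bimolecular association).
#'
#' @param scheme A [reaction_scheme()].
#' @param rates Named rates as in [build_ode()].
#' @param initial Named non-negative concentrations (uM); species omitted
#'   from the vector start at 0.
#' @param time_grid Strictly increasing time points (s) starting at 0.
#' @param rtol,atol Integrator tolerances.
#' @return A `trajectory` object: list with `time`, `conc` (matrix, one
#'   column per species, uM), `scheme_id`, `rates`, `initial`.
#' @export
simulate_scheme <- function(scheme, rates, initial, time_grid,
                            rtol = 1e-8, atol = 1e-10) {
  nm <- species_names(scheme)
  stopifnot(is.numeric(time_grid), length(time_grid) >= 2L)
  if (time_grid[1] != 0) stop("time_grid must start at 0")
  if (any(diff(time_grid) <= 0)) stop("time_grid must be strictly increasing")
  y0 <- setNames(numeric(length(nm)), nm)
  extra <- setdiff(names(initial), nm)
  if (length(extra)) stop("initial state names unknown to scheme: ",
                          paste(extra, collapse = ", "))
  y0[names(initial)] <- as.numeric(initial)
  if (any(y0 < 0)) stop("initial concentrations must be non-negative")
  rates <- unlist(as.list(rates))
  enc <- encode_scheme(scheme, rates)
  sol <- tryCatch(
    deSolve::lsoda(y = y0, times = time_grid, func = "ma_derivs",
                   parms = enc, dllname = "aptkin", initfunc = "ma_init",
                   rtol = rtol, atol = atol),
    error = function(e) stop("integration failed for scheme '", scheme$id,
                             "' (rates: ",
                             paste(names(rates), signif(rates, 3),
                                   sep = "=", collapse = ", "),
                             "): ", conditionMessage(e), call. = FALSE))
  if (nrow(sol) < length(time_grid))
    stop("integration of scheme '", scheme$id, "' stopped at t = ",
         signif(sol[nrow(sol), 1], 4), " s (step ", nrow(sol), " of ",
         length(time_grid), ")")
  conc <- clamp_negatives(unname(sol[, -1, drop = FALSE]),
                          context = paste0("simulate(", scheme$id, ")"))
  dimnames(conc) <- list(NULL, nm)
  structure(list(time = time_grid, conc = conc, scheme_id = scheme$id,
                 rates = rates, initial = y0, scheme = scheme),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat("<trajectory> scheme ", x$scheme_id, ", ", length(x$time),
      " time points over [0, ", signif(max(x$time), 4), "] s, species: ",
      paste(colnames(x$conc), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Conserved totals along a trajectory
#'
#' Total ligand (free + every ligand-containing complex) and total receptor
#' (free active + inactive + every complex) at each time point; both must be
#' constant for a valid mass-action simulation.
#'
#' @param traj A [simulate_scheme()] result.
#' @return Data frame with columns `time`, `ligand_total`, `receptor_total`.
#' @export
conserved_totals <- function(traj) {
  sch <- traj$scheme
  complexes <- species_of_role(sch, c("intermediate-complex", "final-complex"))
  lig <- species_of_role(sch, "ligand")
  rec <- species_of_role(sch, c("receptor", "inactive-receptor"))
  data.frame(
    time = traj$time,
    ligand_total = rowSums(traj$conc[, c(lig, complexes), drop = FALSE]),
    receptor_total = rowSums(traj$conc[, c(rec, complexes), drop = FALSE]))
}

#' Pseudo-first-order closed form for the one-step scheme
#'
#' Under ligand excess the one-step reversible scheme R + L <-> B relaxes
#' mono-exponentially:
#' \deqn{B(t) = B_{eq} (1 - e^{-k_{obs} t}),\quad
#'       k_{obs} = k_1 L_0 + k_{-1},\quad
#'       B_{eq} = R_0 L_0 / (L_0 + k_{-1}/k_1).}
#' Serves as an independent oracle for [simulate_scheme()] on `model1`.
#'
#' @param k1 Association rate (uM^-1 s^-1), must be > 0.
#' @param k_minus1 Dissociation rate (s^-1), >= 0.
#' @param L0 Initial free ligand (uM); must be at least 2x `R0`
#'   (pseudo-first-order requires excess), with a warning below 5x.
#' @param R0 Initial receptor (uM).
#' @param time_grid Time points (s).
#' @return List with `time`, `bound` (B(t), uM), `k_obs` and `B_eq`.
#' @export
closed_form_model1_pfo <- function(k1, k_minus1, L0, R0, time_grid) {
  if (!is.numeric(k1) || k1 <= 0) stop("k1 must be > 0")
  if (k_minus1 < 0) stop("k_minus1 must be >= 0")
  if (L0 < 2 * R0)
    stop("pseudo-first-order closed form requires L0 >= 2*R0")
  if (L0 < 5 * R0)
    warning("L0 < 5*R0: pseudo-first-order approximation is marginal")
  k_obs <- k1 * L0 + k_minus1
  B_eq <- R0 * L0 / (L0 + k_minus1 / k1)
  list(time = time_grid, bound = B_eq * (1 - exp(-k_obs * time_grid)),
       k_obs = k_obs, B_eq = B_eq)
}

#' Overall equilibrium dissociation constant implied by fitted rates
#'
#' Standard equilibrium algebra on the scheme: for the one-step scheme
#' K_D = k-1/k1; for the reversible two-step scheme the bound pool is
#' I + B, giving K_D = (k-1/k1) * (k-2 / (k2 + k-2)). Schemes whose final
#' step is irreversible (model3, model5) have no finite equilibrium and
#' return 0.
#'
#' @param scheme A preset [reaction_scheme()] (`model1`, `model3`, `model4`
#'   or `model5`). `model2` is rejected: its apparent K_D additionally
#'   depends on the inactive-receptor fraction, which is not a property of
#'   the rates alone in the same reduced form.
#' @param rates Named rates as in [build_ode()].
#' @return Apparent K_D in uM.
#' @export
apparent_kd <- function(scheme, rates) {
  rates <- as.list(rates)
  switch(scheme$id,
    model1 = rates$k_m1 / rates$k1,
    model3 = 0,
    model5 = 0,
    model4 = (rates$k_m1 / rates$k1) * (rates$k_m2 / (rates$k2 + rates$k_m2)),
    model2 = stop("apparent_kd is unsupported for model2: the overall K_D ",
                  "depends on the inactive/active preformation fraction, ",
                  "not only on the binding-step rates"),
    stop("apparent_kd supports the preset schemes model1/model3/model4/model5"))
}

#' Initial concentration state for a binding experiment
#'
#' Places `R0` on the receptor and `L0` on the ligand, complexes at 0. For
#' the conformational-selection scheme (`model2`) the receptor pool is
#' pre-equilibrated between inactive and active forms according to
#' k_pre/k_unpre, reflecting RNA folded and equilibrated in buffer before
#' mixing.
#'
#' @param scheme A [reaction_scheme()].
#' @param rates Named rates (needed only for schemes with an
#'   inactive-receptor species).
#' @param R0,L0 Total receptor and ligand concentrations (uM).
#' @return Named concentration vector over the scheme's species.
#' @export
initial_state <- function(scheme, rates, R0, L0) {
  nm <- species_names(scheme)
  y0 <- setNames(numeric(length(nm)), nm)
  y0[species_of_role(scheme, "ligand")] <- L0
  rec <- species_of_role(scheme, "receptor")
  inact <- species_of_role(scheme, "inactive-receptor")
  if (length(inact)) {
    rates <- as.list(rates)
    # locate the unimolecular preformation reaction inactive -> active
    pre <- Filter(function(r) length(r$reactants) == 1 && r$reactants %in% inact,
                  scheme$reactions)
    if (length(pre) != 1L)
      stop("cannot locate the preformation reaction for scheme '", scheme$id, "'")
    kf <- rates[[pre[[1]]$forward]]
    kr <- if (is.null(pre[[1]]$reverse)) 0 else rates[[pre[[1]]$reverse]]
    f_act <- if (kf + kr > 0) kf / (kf + kr) else 0
    y0[rec] <- R0 * f_act
    y0[inact] <- R0 * (1 - f_act)
  } else {
    y0[rec] <- R0
  }
  y0
}

#' Export a trajectory as CSV
#'
#' Columns `time_s` then one column per species (uM).
#'
#' @param traj A [simulate_scheme()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(time_s = traj$time, traj$conc, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
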