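# Stopped-flow fluorescence-quench analysis: preprocessing, pseudo-first-
# order k_obs/k_on analysis, global mass-action fitting, AIC/BIC comparison.

#' A preprocessed stopped-flow trace
#'
#' @param time_s Strictly increasing time grid (s), starting >= 0.
#' @param signal Normalized fluorescence (dimensionless, finite).
#' @param ligand_conc_uM Ligand concentration of the shot series (> 0).
#' @param receptor_conc_uM Receptor (RNA) concentration.
#' @param n_averaged Number of raw shots averaged into this trace.
#' @param flags Character vector of quality flags (e.g.
#'   `"plateau-not-reached"`).
#' @return A `stopped_flow_trace` object.
#' @export
stopped_flow_trace <- function(time_s, signal, ligand_conc_uM,
                               receptor_conc_uM, n_averaged = 1L,
                               flags = character()) {
  stopifnot(is.numeric(time_s), is.numeric(signal),
            length(time_s) == length(signal), length(time_s) >= 3L)
  if (any(diff(time_s) <= 0)) stop("time grid must be strictly increasing")
  if (time_s[1] < 0) stop("time grid must start at >= 0")
  if (!all(is.finite(signal))) stop("signal must be finite")
  if (!is.numeric(ligand_conc_uM) || ligand_conc_uM <= 0)
    stop("ligand_conc_uM must be > 0")
  structure(list(time_s = time_s, signal = signal,
                 ligand_conc_uM = ligand_conc_uM,
                 receptor_conc_uM = receptor_conc_uM,
                 n_averaged = as.integer(n_averaged), flags = flags),
            class = "stopped_flow_trace")
}

#' A concentration series of stopped-flow traces
#'
#' @param traces List of [stopped_flow_trace()] objects sharing the same
#'   receptor concentration, at >= 2 distinct ligand concentrations.
#' @param label Candidate name (free text).
#' @return A `trace_series` object.
#' @export
trace_series <- function(traces, label = "user") {
  stopifnot(is.list(traces), length(traces) >= 2L)
  lc <- vapply(traces, function(tr) tr$ligand_conc_uM, numeric(1))
  rc <- vapply(traces, function(tr) tr$receptor_conc_uM, numeric(1))
  if (length(unique(lc)) < 2L)
    stop("a trace series needs >= 2 distinct ligand concentrations")
  if (length(unique(rc)) != 1L)
    stop("all traces of a series must share the receptor concentration")
  structure(list(traces = traces, label = label,
                 receptor_conc_uM = rc[1]), class = "trace_series")
}

#' @export
print.trace_series <- function(x, ...) {
  lc <- vapply(x$traces, function(tr) tr$ligand_conc_uM, numeric(1))
  cat("<trace_series '", x$label, "'> RNA ", x$receptor_conc_uM,
      " uM; ligand ", paste(lc, collapse = ", "), " uM\n", sep = "")
  invisible(x)
}

#' Fluorescence observable map
#'
#' The measured emission is carried by the free ligand (response fixed at 1)
#' plus partially quenched contributions from the ligand-containing
#' complexes. By default both complexes are treated as fully quenched
#' (response 0); responses can be freed as fit parameters in [global_fit()].
#'
#' @param responses Named numeric vector in \[0, 1\]: response factor per
#'   ligand-containing complex species. `NULL` means 0 for every complex of
#'   the scheme at hand.
#' @param baseline Additive signal offset (removed again by the
#'   normalization contract; kept for generality).
#' @return An `observable_map` object.
#' @export
observable_map <- function(responses = NULL, baseline = 0) {
  if (!is.null(responses)) {
    stopifnot(is.numeric(responses), !is.null(names(responses)))
    if (any(responses < 0 | responses > 1))
      stop("complex response factors must lie in [0, 1]")
  }
  structure(list(responses = responses, baseline = baseline),
            class = "observable_map")
}

resolve_responses <- function(observable, scheme) {
  complexes <- species_of_role(scheme, c("intermediate-complex", "final-complex"))
  resp <- setNames(numeric(length(complexes)), complexes)
  if (!is.null(observable$responses)) {
    unknown <- setdiff(names(observable$responses), complexes)
    if (length(unknown))
      stop("response factors for species not in scheme: ",
           paste(unknown, collapse = ", "))
    resp[names(observable$responses)] <- observable$responses
  }
  resp
}

# Normalization contract shared by data preprocessing and model prediction:
# subtract the plateau (mean of the final `tail_frac` of points), then scale
# so the first point equals 1. Affine-invariant: a*x + b (a > 0) maps to the
# same output as x. Degenerate (flat) input is returned unchanged with an
# attribute so callers can flag it.
normalize_signal <- function(signal, tail_frac = 0.05) {
  n <- length(signal)
  k <- max(1L, ceiling(tail_frac * n))
  b <- mean(signal[(n - k + 1L):n])
  s <- signal - b
  if (abs(s[1]) < 1e-12 * max(abs(signal), 1)) {
    attr(signal, "degenerate_normalization") <- TRUE
    return(signal)
  }
  s / s[1]
}

#' Average, baseline-correct and normalize raw stopped-flow shots
#'
#' Pointwise mean of the raw shots, followed by the normalization contract:
#' the baseline (mean of the final 5% of points, i.e. the plateau) is
#' subtracted and the trace rescaled so signal(0) = 1 and the plateau is 0.
#' If the last decile of the averaged trace still drifts (fitted slope times
#' trace duration exceeding `slope_tol` in normalized units) the trace is
#' flagged `"plateau-not-reached"` with a warning.
#'
#' @param raw Numeric vector (one shot) or matrix with one column per shot
#'   on a common time grid.
#' @param time_s Common time grid (s).
#' @param ligand_conc_uM,receptor_conc_uM Metadata for the resulting trace.
#' @param tail_frac Fraction of trailing points defining the baseline.
#' @param slope_tol Plateau drift threshold (normalized units per trace).
#' @return A [stopped_flow_trace()].
#' @export
preprocess <- function(raw, time_s, ligand_conc_uM, receptor_conc_uM,
                       tail_frac = 0.05, slope_tol = 0.02) {
  if (is.vector(raw)) raw <- matrix(raw, ncol = 1L)
  stopifnot(is.matrix(raw), nrow(raw) == length(time_s))
  avg <- rowMeans(raw)
  norm <- normalize_signal(avg, tail_frac = tail_frac)
  flags <- character()
  if (isTRUE(attr(norm, "degenerate_normalization"))) {
    flags <- "degenerate-normalization"
    warning("preprocess: flat trace, normalization skipped")
  } else {
    n <- length(norm)
    idx <- seq.int(max(1L, floor(0.9 * n)), n)
    sl <- coef(lm(norm[idx] ~ time_s[idx]))[2]
    drift <- abs(sl) * (max(time_s) - min(time_s))
    if (is.finite(drift) && drift > slope_tol) {
      flags <- "plateau-not-reached"
      warning("preprocess: plateau not reached (last-decile drift ",
              signif(drift, 3), " normalized units)")
    }
  }
  stopped_flow_trace(time_s, as.numeric(norm), ligand_conc_uM,
                     receptor_conc_uM, n_averaged = ncol(raw), flags = flags)
}

# Linearized standard errors at a least-squares optimum:
# cov = RSS/(n-p) * (J'J)^-1 with J the numeric Jacobian of the residuals.
lin_se <- function(resfun, par, rel_step = 1e-5) {
  r0 <- resfun(par)
  n <- length(r0); p <- length(par)
  J <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    h <- max(abs(par[j]) * rel_step, 1e-10)
    up <- par; up[j] <- up[j] + h
    dn <- par; dn[j] <- dn[j] - h
    J[, j] <- (resfun(up) - resfun(dn)) / (2 * h)
  }
  rss <- sum(r0^2)
  dof <- max(n - p, 1L)
  cov <- tryCatch(solve(crossprod(J)) * rss / dof,
                  error = function(e) NULL)
  if (is.null(cov)) {
    return(list(se = setNames(rep(NA_real_, p), names(par)), cov = NULL,
                rss = rss, singular = TRUE))
  }
  list(se = setNames(sqrt(pmax(diag(cov), 0)), names(par)), cov = cov,
       rss = rss, singular = FALSE)
}

#' Mono-exponential fit of a stopped-flow transient
#'
#' Least-squares fit of `offset + amplitude * exp(-k_obs * t)`; under
#' pseudo-first-order conditions k_obs estimates the observed association
#' rate at that ligand concentration. The initial rate guess is
#' `ln 2 / t_half` where `t_half` is the time at half-decay.
#'
#' @param trace A preprocessed [stopped_flow_trace()].
#' @return A `mono_exp_fit`: `k_obs` (s^-1), `amplitude`, `offset`, `rss`,
#'   standard errors, `converged`, and a `diagnostic` message on failure.
#' @export
fit_monoexponential <- function(trace) {
  t <- trace$time_s; y <- trace$signal
  n <- length(y)
  off0 <- mean(y[max(1L, floor(0.95 * n)):n])
  amp0 <- y[1] - off0
  fail <- function(msg) structure(
    list(k_obs = NA_real_, amplitude = NA_real_, offset = NA_real_,
         rss = NA_real_, se = NULL, converged = FALSE, diagnostic = msg,
         ligand_conc_uM = trace$ligand_conc_uM), class = "mono_exp_fit")
  if (!is.finite(amp0) || amp0 <= 0)
    return(fail("trace does not decay (non-positive initial amplitude)"))
  half <- off0 + amp0 / 2
  idx <- which(y <= half)
  idx <- idx[idx > 1L]
  if (!length(idx))
    return(fail("trace never reaches half-decay"))
  t_half <- t[idx[1]]
  if (t_half <= 0) t_half <- t[2]
  k0 <- log(2) / t_half
  resfun <- function(p) p[3] + p[2] * exp(-p[1] * t) - y
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(k_obs = k0, amplitude = amp0, offset = off0),
                       lower = c(1e-8, -Inf, -Inf), fn = resfun,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4))
    return(fail(paste("mono-exponential fit failed to converge:",
                      if (is.null(fit)) "optimizer error" else fit$message)))
  p <- coef(fit)
  se <- lin_se(resfun, p)
  structure(list(k_obs = unname(p[1]), amplitude = unname(p[2]),
                 offset = unname(p[3]), rss = sum(resfun(p)^2), se = se$se,
                 converged = TRUE, diagnostic = NULL,
                 ligand_conc_uM = trace$ligand_conc_uM),
            class = "mono_exp_fit")
}

#' Pseudo-first-order k_on analysis of a concentration series
#'
#' Fits every trace mono-exponentially and regresses k_obs on ligand
#' concentration by ordinary least squares. The slope is the apparent
#' bimolecular association rate k_on (uM^-1 s^-1) and the intercept the
#' apparent off-rate (s^-1). High-concentration points that fall below the
#' line with a studentized residual beyond -3 (the saturation regime, where
#' k_obs plateaus at large ligand excess) are excluded from the slope with
#' a note.
#'
#' @param series A [trace_series()] with >= 3 concentrations yielding
#'   successful mono-exponential fits.
#' @return A `pfo_result`: per-concentration table (`conc_uM`, `k_obs`,
#'   `se`, `excluded`), `k_on`, `intercept`, their standard errors, the
#'   underlying fits and any exclusion note.
#' @export
kon_regression <- function(series) {
  fits <- lapply(series$traces, fit_monoexponential)
  ok <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
  if (sum(ok) < 3L)
    stop("kon_regression needs >= 3 concentrations with successful ",
         "mono-exponential fits (got ", sum(ok), ")")
  conc <- vapply(fits[ok], function(f) f$ligand_conc_uM, numeric(1))
  kobs <- vapply(fits[ok], function(f) f$k_obs, numeric(1))
  kse <- vapply(fits[ok], function(f) unname(f$se["k_obs"]), numeric(1))
  tab <- data.frame(conc_uM = conc, k_obs = kobs, se = kse, excluded = FALSE)
  fit0 <- lm(k_obs ~ conc_uM, data = tab)
  note <- NULL
  rs <- tryCatch(rstudent(fit0), error = function(e) rep(0, nrow(tab)))
  # a dominant outlier can drive the leave-one-out variance to zero and
  # rstudent to NaN/Inf; treat it as infinitely discrepant with the sign of
  # its raw residual
  raw <- stats::residuals(fit0)
  bad <- !is.finite(rs)
  rs[bad] <- ifelse(raw[bad] == 0, 0, sign(raw[bad]) * Inf)
  # saturation pulls k_obs below the line at the high-concentration end
  out <- rs < -3 & tab$conc_uM > stats::median(tab$conc_uM)
  if (any(out) && sum(!out) >= 3L) {
    tab$excluded[out] <- TRUE
    note <- paste0("excluded ", sum(out), " saturating point(s) at ",
                   paste(tab$conc_uM[out], collapse = ", "),
                   " uM (studentized residual > 3)")
    message("kon_regression: ", note)
    fit0 <- lm(k_obs ~ conc_uM, data = tab[!tab$excluded, ])
  }
  cf <- summary(fit0)$coefficients
  structure(list(table = tab, k_on = unname(cf["conc_uM", 1]),
                 intercept = unname(cf["(Intercept)", 1]),
                 k_on_se = unname(cf["conc_uM", 2]),
                 intercept_se = unname(cf["(Intercept)", 2]),
                 fits = fits, note = note, label = series$label),
            class = "pfo_result")
}

#' @export
print.pfo_result <- function(x, ...) {
  cat("<pfo_result '", x$label, "'> k_on = ", signif(x$k_on, 4),
      " +/- ", signif(x$k_on_se, 2), " uM^-1 s^-1; intercept = ",
      signif(x$intercept, 3), " s^-1\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Model signal on a trace's time grid
#'
#' Simulates the scheme from the trace's concentrations, forms the
#' fluorescence observable
#' `baseline + ([L] + sum(response_s * [complex_s])) / L0`
#' and passes it through the same normalization contract as [preprocess()],
#' so that model and preprocessed data live on the same scale.
#'
#' @param scheme A [reaction_scheme()].
#' @param rates Named rates.
#' @param observable An [observable_map()].
#' @param time_s Time grid of the trace (s); may start after 0 (dead time),
#'   integration always starts at the mixing instant t = 0.
#' @param ligand_conc_uM,receptor_conc_uM Mixing concentrations (uM).
#' @param rtol,atol Integrator tolerances, forwarded to [simulate_scheme()].
#' @return Numeric vector of the normalized model signal.
#' @export
predict_signal <- function(scheme, rates, observable, time_s,
                           ligand_conc_uM, receptor_conc_uM,
                           rtol = 1e-8, atol = 1e-10) {
  resp <- resolve_responses(observable, scheme)
  y0 <- initial_state(scheme, rates, R0 = receptor_conc_uM,
                      L0 = ligand_conc_uM)
  grid <- time_s
  prepended <- FALSE
  if (grid[1] > 0) {
    grid <- c(0, grid)
    prepended <- TRUE
  }
  traj <- simulate_scheme(scheme, rates, y0, grid, rtol = rtol, atol = atol)
  lig <- species_of_role(scheme, "ligand")
  raw <- traj$conc[, lig]
  for (s in names(resp)) raw <- raw + resp[[s]] * traj$conc[, s]
  raw <- observable$baseline + raw / ligand_conc_uM
  if (prepended) raw <- raw[-1]
  out <- normalize_signal(raw)
  as.numeric(out)
}

#' Options for [global_fit()]
#'
#' @param n_starts Number of multi-start optimizations (starting rates drawn
#'   log-uniformly within the bounds; the first start is the bounds'
#'   geometric midpoint).
#' @param seed Seed for the multi-start draw (recorded in the result).
#' @param lower,upper Bounds on every rate constant in its natural unit.
#' @param fit_responses If `TRUE`, the complex response factors are freed as
#'   fit parameters in \[0, 1\]; default fixed at the [observable_map()]
#'   values.
#' @param dead_time Instrument dead time (s): the first `dead_time` seconds
#'   of every trace are discarded before fitting.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param rtol,atol ODE tolerances used during fitting.
#' @return Options list.
#' @export
global_fit_options <- function(n_starts = 20L, seed = 1L, lower = 1e-3,
                               upper = 1e3, fit_responses = FALSE,
                               dead_time = 0, maxiter = 200L,
                               rtol = 1e-8, atol = 1e-10) {
  list(n_starts = as.integer(n_starts), seed = as.integer(seed),
       lower = lower, upper = upper, fit_responses = fit_responses,
       dead_time = dead_time, maxiter = as.integer(maxiter),
       rtol = rtol, atol = atol)
}

#' Global fit of a binding scheme to a stopped-flow concentration series
#'
#' Minimizes the summed squared residuals over all traces of the series
#' simultaneously, with rate constants shared across traces. Rates are
#' optimized on a log10 scale (enforcing positivity) by
#' Levenberg-Marquardt from multiple log-uniform random starts; the best
#' converged start is kept. Standard errors come from the linearized
#' covariance at the optimum, `RSS/(n-p) * (J'J)^-1`, with the Jacobian
#' taken in the natural (linear) parameters.
#'
#' @param scheme A [reaction_scheme()].
#' @param series A preprocessed [trace_series()].
#' @param observable An [observable_map()]; its responses are fixed unless
#'   `options$fit_responses`.
#' @param options See [global_fit_options()].
#' @return A `global_fit_result`: fitted `rates` with `se`, `responses`,
#'   `rss`, `rmsd` (= sqrt(RSS/n)), `n_points`, `n_parameters`, per-start
#'   `convergence` table, `seed`, `at_bound` flags and the options echo.
#' @export
global_fit <- function(scheme, series, observable = observable_map(),
                       options = global_fit_options()) {
  syms <- rate_symbols(scheme)
  nr <- length(syms)
  complexes <- species_of_role(scheme, c("intermediate-complex", "final-complex"))
  fixed_resp <- resolve_responses(observable, scheme)

  traces <- series$traces
  if (options$dead_time > 0) {
    traces <- lapply(traces, function(tr) {
      keep <- tr$time_s >= options$dead_time
      stopped_flow_trace(tr$time_s[keep], tr$signal[keep], tr$ligand_conc_uM,
                         tr$receptor_conc_uM, tr$n_averaged, tr$flags)
    })
  }
  n_points <- sum(vapply(traces, function(tr) length(tr$signal), numeric(1)))

  p_resp <- if (options$fit_responses) length(complexes) else 0L
  n_par <- nr + p_resp
  lo <- c(rep(log10(options$lower), nr), rep(0, p_resp))
  hi <- c(rep(log10(options$upper), nr), rep(1, p_resp))
  par_names <- c(syms, if (p_resp) paste0("resp_", complexes))

  residuals_for <- function(rates, resp) {
    obs <- observable_map(responses = resp, baseline = observable$baseline)
    unlist(lapply(traces, function(tr) {
      pred <- tryCatch(
        predict_signal(scheme, rates, obs, tr$time_s, tr$ligand_conc_uM,
                       tr$receptor_conc_uM, rtol = options$rtol,
                       atol = options$atol),
        error = function(e) NULL)
      if (is.null(pred)) return(rep(1e4, length(tr$signal)))
      pred - tr$signal
    }))
  }
  theta_resid <- function(theta) {
    rates <- setNames(10^theta[seq_len(nr)], syms)
    resp <- if (p_resp) setNames(theta[nr + seq_len(p_resp)], complexes)
            else fixed_resp
    residuals_for(rates, resp)
  }

  set.seed(options$seed)
  starts <- matrix(runif(options$n_starts * n_par, lo, hi),
                   nrow = options$n_starts, byrow = TRUE)
  starts[1, ] <- (lo + hi) / 2
  if (options$n_starts >= 2L) {
    # informed start from the pseudo-first-order analysis: bimolecular
    # steps near the k_obs-vs-concentration slope, their reverse near the
    # intercept magnitude, conformational steps at 1 s^-1
    guess <- tryCatch({
      pf <- suppressWarnings(suppressMessages(kon_regression(series)))
      g <- setNames(rep(1, nr), syms)
      for (r in scheme$reactions) {
        if (length(r$reactants) == 2L) {
          g[r$forward] <- pf$k_on
          if (!is.null(r$reverse)) g[r$reverse] <- abs(pf$intercept)
        }
      }
      pmin(pmax(g, options$lower * 1.01), options$upper * 0.99)
    }, error = function(e) NULL)
    if (!is.null(guess))
      starts[2, seq_len(nr)] <- log10(guess)
  }

  runs <- vector("list", options$n_starts)
  for (i in seq_len(options$n_starts)) {
    runs[[i]] <- tryCatch({
      f <- minpack.lm::nls.lm(
        par = setNames(starts[i, ], par_names), lower = lo, upper = hi,
        fn = theta_resid,
        control = minpack.lm::nls.lm.control(maxiter = options$maxiter))
      list(par = coef(f), rss = f$deviance, info = f$info,
           message = f$message, niter = f$niter)
    }, error = function(e) list(par = rep(NA_real_, n_par), rss = Inf,
                                info = -1L, message = conditionMessage(e),
                                niter = NA_integer_))
  }
  conv <- data.frame(
    start = seq_along(runs),
    rss = vapply(runs, function(r) r$rss, numeric(1)),
    info = vapply(runs, function(r) r$info, numeric(1)),
    message = vapply(runs, function(r) r$message, character(1)))
  ok <- conv$info %in% 1:4 & is.finite(conv$rss)
  if (!any(ok))
    stop("global_fit: no multi-start converged for scheme '", scheme$id,
         "'; per-start diagnostics:\n",
         paste(utils::capture.output(print(conv)), collapse = "\n"))
  best <- runs[[which.min(ifelse(ok, conv$rss, Inf))]]
  theta <- best$par
  rates_hat <- setNames(10^theta[seq_len(nr)], syms)
  resp_hat <- if (p_resp) setNames(theta[nr + seq_len(p_resp)], complexes)
              else fixed_resp

  at_bound <- par_names[theta <= lo + 1e-6 | theta >= hi - 1e-6]
  if (length(at_bound))
    warning("global_fit(", scheme$id, "): parameter(s) at bound: ",
            paste(at_bound, collapse = ", "))

  # SE in natural parameter space (rates; responses when freed)
  nat_par <- c(rates_hat, if (p_resp) resp_hat)
  nat_resid <- function(p) {
    residuals_for(setNames(p[seq_len(nr)], syms),
                  if (p_resp) setNames(p[nr + seq_len(p_resp)], complexes)
                  else fixed_resp)
  }
  seinfo <- lin_se(nat_resid, nat_par)
  rss <- best$rss
  structure(list(
    scheme_id = scheme$id, scheme = scheme,
    rates = rates_hat, se = seinfo$se[seq_len(nr)],
    responses = resp_hat,
    response_se = if (p_resp) seinfo$se[nr + seq_len(p_resp)] else NULL,
    rss = rss, rmsd = sqrt(rss / n_points), n_points = n_points,
    n_parameters = n_par,
    convergence = conv, seed = options$seed, at_bound = at_bound,
    singular_covariance = seinfo$singular,
    label = series$label, options = options),
    class = "global_fit_result")
}

#' @export
print.global_fit_result <- function(x, ...) {
  lab <- paper_rate_labels(x$scheme)
  cat("<global_fit_result> scheme ", x$scheme_id, " on '", x$label, "'\n",
      sep = "")
  for (s in names(x$rates))
    cat("  ", lab[[s]], " = ", format_pm(x$rates[[s]], x$se[[s]]), "\n",
        sep = "")
  cat("  RSS = ", signif(x$rss, 5), ", RMSD = ", signif(x$rmsd, 5),
      " (n = ", x$n_points, ", p = ", x$n_parameters, ")\n", sep = "")
  if (length(x$at_bound))
    cat("  at bound: ", paste(x$at_bound, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' AIC/BIC comparison of global fits on a common dataset
#'
#' Least-squares information criteria:
#' `AIC = n ln(RSS/n) + 2p` and `BIC = n ln(RSS/n) + p ln(n)`, with `p`
#' counting free rate constants plus free observable parameters (constant
#' terms cancel in the Delta values). Delta values are reported relative to
#' the minimum across the supplied fits. Models whose Delta-AIC falls below
#' 2 are reported as statistically indistinguishable rather than ranked.
#'
#' @param fits List of [global_fit()] results on the identical dataset
#'   (equal `n_points`).
#' @param aicc If `TRUE`, the small-sample corrected AICc
#'   (`AIC + 2p(p+1)/(n-p-1)`) replaces AIC.
#' @return A `model_comparison` data frame with columns `scheme`,
#'   `n_parameters`, `rss`, `rmsd`, `aic`, `bic`, `delta_aic`, `delta_bic`;
#'   attribute `indistinguishable` lists the scheme ids within Delta-AIC
#'   < 2 of the best.
#' @export
compare_models <- function(fits, aicc = FALSE) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  n <- vapply(fits, function(f) f$n_points, numeric(1))
  if (length(unique(n)) != 1L)
    stop("compare_models: fits were made on datasets of different size (n = ",
         paste(unique(n), collapse = ", "), ")")
  n <- n[1]
  p <- vapply(fits, function(f) f$n_parameters, numeric(1))
  rss <- vapply(fits, function(f) f$rss, numeric(1))
  aic <- n * log(rss / n) + 2 * p
  if (aicc) aic <- aic + 2 * p * (p + 1) / (n - p - 1)
  bic <- n * log(rss / n) + p * log(n)
  tab <- data.frame(
    scheme = vapply(fits, function(f) f$scheme_id, character(1)),
    n_parameters = p, rss = rss,
    rmsd = vapply(fits, function(f) f$rmsd, numeric(1)),
    aic = aic, bic = bic,
    delta_aic = aic - min(aic), delta_bic = bic - min(bic))
  attr(tab, "indistinguishable") <- tab$scheme[tab$delta_aic < 2]
  attr(tab, "n_points") <- n
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.model_comparison <- function(x, ...) {
  df <- as.data.frame(x)
  df$delta_aic <- round(df$delta_aic)
  df$delta_bic <- round(df$delta_bic)
  print(df, row.names = FALSE)
  ind <- attr(x, "indistinguishable")
  if (length(ind) > 1L)
    cat("models indistinguishable by AIC (Delta < 2): ",
        paste(ind, collapse = ", "), "\n", sep = "")
  invisible(x)
}
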