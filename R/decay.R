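# Multi-exponential fitting of TCSPC photon-count histograms.
#
# The fit model is counts(t) = bg + sum_i a_i * exp(-t / tau_i), optionally
# convolved with a Gaussian instrument response, minimizing the
# Poisson-weighted chi-square  sum (obs - model)^2 / max(obs, 1).

#' A TCSPC decay histogram
#'
#' @param channel_time_ns Uniform channel-time grid (ns).
#' @param counts Non-negative integer photon counts per channel.
#' @param background Known background counts per channel (used as a fixed
#'   offset unless the background is fitted).
#' @param irf Optional normalized instrument response on the same grid.
#' @return A `decay_histogram` object.
#' @export
decay_histogram <- function(channel_time_ns, counts, background = 0,
                            irf = NULL) {
  stopifnot(is.numeric(channel_time_ns), is.numeric(counts),
            length(channel_time_ns) == length(counts),
            length(channel_time_ns) >= 8L)
  dt <- diff(channel_time_ns)
  if (any(dt <= 0) || diff(range(dt)) > 1e-6 * mean(dt))
    stop("channel grid must be uniform and increasing")
  if (any(counts < 0)) stop("counts must be >= 0")
  if (any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be integers")
  if (!is.null(irf)) {
    stopifnot(length(irf) == length(counts), all(irf >= 0))
    irf <- irf / sum(irf)
  }
  structure(list(channel_time_ns = channel_time_ns,
                 counts = as.numeric(round(counts)),
                 background = background, irf = irf,
                 channel_width_ns = mean(dt)),
            class = "decay_histogram")
}

# Gaussian IRF kernel on the channel grid (area 1), used for reconvolution.
gaussian_irf <- function(channel_time_ns, fwhm_ns = 0.5,
                         center_ns = min(channel_time_ns) + 2 * fwhm_ns) {
  s <- fwhm_ns / (2 * sqrt(2 * log(2)))
  k <- exp(-0.5 * ((channel_time_ns - center_ns) / s)^2)
  k / sum(k)
}

# Discrete causal convolution of a model decay with a normalized IRF.
convolve_irf <- function(model, irf) {
  n <- length(model)
  out <- stats::convolve(c(model, numeric(n)), rev(c(irf, numeric(n))),
                         type = "open")
  out[seq_len(n)]
}

decay_model_counts <- function(t, tau, a, bg, irf = NULL) {
  m <- rep(bg, length(t))
  base <- numeric(length(t))
  for (i in seq_along(tau)) base <- base + a[i] * exp(-(t - t[1]) / tau[i])
  if (!is.null(irf)) base <- convolve_irf(base, irf)
  m + base
}

#' Fit a multi-exponential decay to a TCSPC histogram
#'
#' Levenberg-Marquardt minimization of the Poisson-weighted chi-square
#' `sum (obs - model)^2 / max(obs, 1)` (the `max(obs, 1)` floor keeps empty
#' channels usable). By default the decay is tail-fitted from the peak
#' channel onward; with `use_irf = TRUE` the model is reconvolved with the
#' histogram's IRF (or a Gaussian of `irf_fwhm_ns` when none is stored) and
#' the full histogram is fitted. Amplitudes are constrained non-negative,
#' lifetimes to \[0.05, 50\] ns; components are returned sorted by
#' ascending lifetime with amplitudes as percent of the total.
#'
#' @param hist A [decay_histogram()]. Total counts below 1e4 trigger a
#'   warning (lifetime precision degrades).
#' @param n_components Number of exponential components (1-3).
#' @param use_irf Reconvolution flag (default tail fitting).
#' @param fit_background If `TRUE` the flat background is a fit parameter;
#'   otherwise it is fixed at `hist$background`.
#' @param irf_fwhm_ns Gaussian IRF width used when `use_irf = TRUE` and the
#'   histogram carries no measured IRF.
#' @return A `decay_fit`: data frame `components` (`tau_ns`, `tau_se`,
#'   `amplitude_pct`, `amplitude_se`), `background`, `reduced_chi2`,
#'   `n_channels`, `fit_window_ns`, `flags`.
#' @export
fit_decay <- function(hist, n_components = 2L, use_irf = FALSE,
                      fit_background = FALSE, irf_fwhm_ns = 0.5) {
  stopifnot(inherits(hist, "decay_histogram"))
  n_components <- as.integer(n_components)
  if (n_components < 1L || n_components > 3L)
    stop("n_components must be 1, 2 or 3")
  if (sum(hist$counts) < 1e4)
    warning("total counts below 1e4; lifetime estimates will be imprecise")

  irf <- NULL
  if (use_irf) {
    irf <- if (!is.null(hist$irf)) hist$irf
           else gaussian_irf(hist$channel_time_ns, irf_fwhm_ns)
    i0 <- 1L
  } else {
    i0 <- which.max(hist$counts)  # tail fit from the peak channel
  }
  t <- hist$channel_time_ns[i0:length(hist$counts)]
  y <- hist$counts[i0:length(hist$counts)]
  w <- 1 / sqrt(pmax(y, 1))
  bg_fixed <- hist$background

  nc <- n_components
  # initial guesses: lifetimes log-spaced over the observed decay range,
  # amplitudes an equal split of the peak excess
  span <- max(t) - min(t)
  tau0 <- exp(seq(log(max(0.1, span / 200)), log(max(0.5, span / 3)),
                  length.out = nc))
  tau0 <- pmin(pmax(tau0, 0.06), 49)
  a0 <- rep(max(y[1] - bg_fixed, 1) / nc, nc)
  par0 <- c(log10(tau0), a0, if (fit_background) max(bg_fixed, 1))
  lo <- c(rep(log10(0.05), nc), rep(0, nc), if (fit_background) 0)
  hi <- c(rep(log10(50), nc), rep(Inf, nc), if (fit_background) Inf)
  par_names <- c(paste0("ltau", seq_len(nc)), paste0("a", seq_len(nc)),
                 if (fit_background) "bg")

  resfun <- function(p) {
    tau <- 10^p[seq_len(nc)]
    a <- p[nc + seq_len(nc)]
    bg <- if (fit_background) p[2 * nc + 1] else bg_fixed
    w * (decay_model_counts(t, tau, a, bg, irf) - y)
  }
  fit <- minpack.lm::nls.lm(
    par = setNames(par0, par_names), lower = lo, upper = hi, fn = resfun,
    control = minpack.lm::nls.lm.control(maxiter = 500))
  p <- coef(fit)
  tau <- unname(10^p[seq_len(nc)])
  a <- unname(p[nc + seq_len(nc)])
  bg <- if (fit_background) unname(p[2 * nc + 1]) else bg_fixed

  flags <- character()
  if (nc > 1L) {
    st <- sort(tau)
    if (any(diff(st) / st[-1] < 0.01))
      flags <- c(flags, "degenerate-lifetimes")
  }

  # covariance in natural parameters (tau, a, [bg]) for reporting
  nat_res <- function(q) {
    tt <- q[seq_len(nc)]; aa <- q[nc + seq_len(nc)]
    bb <- if (fit_background) q[2 * nc + 1] else bg_fixed
    w * (decay_model_counts(t, tt, aa, bb, irf) - y)
  }
  seinfo <- lin_se(nat_res, c(tau, a, if (fit_background) bg))
  tau_se <- seinfo$se[seq_len(nc)]
  a_se <- seinfo$se[nc + seq_len(nc)]

  # percent amplitudes with delta-method SEs (full covariance of the a's)
  tot <- sum(a)
  pct <- if (tot > 0) 100 * a / tot else rep(NA_real_, nc)
  pct_se <- rep(NA_real_, nc)
  if (!seinfo$singular && tot > 0) {
    cov_a <- seinfo$cov[nc + seq_len(nc), nc + seq_len(nc), drop = FALSE]
    for (i in seq_len(nc)) {
      g <- -100 * a / tot^2
      g[i] <- g[i] + 100 / tot
      pct_se[i] <- sqrt(max(drop(crossprod(g, cov_a %*% g)), 0))
    }
  }
  if (any(!is.na(a_se) & a <= 3 * a_se))
    flags <- c(flags, "weak-component")

  ord <- order(tau)
  comp <- data.frame(tau_ns = tau[ord], tau_se = unname(tau_se[ord]),
                     amplitude_pct = pct[ord], amplitude_se = pct_se[ord])
  chi2 <- fit$deviance
  dof <- length(y) - length(p)
  structure(list(components = comp, background = bg,
                 reduced_chi2 = chi2 / dof, chi2 = chi2,
                 n_channels = length(y), dof = dof,
                 fit_window_ns = range(t), use_irf = use_irf,
                 converged = fit$info %in% 1:4, flags = flags),
            class = "decay_fit")
}

#' @export
print.decay_fit <- function(x, ...) {
  cat("<decay_fit> ", nrow(x$components), " component(s), reduced chi2 = ",
      signif(x$reduced_chi2, 4), "\n", sep = "")
  for (i in seq_len(nrow(x$components))) {
    c_i <- x$components[i, ]
    cat("  tau = ", format_pm(c_i$tau_ns, c_i$tau_se), " ns (",
        format_pm(c_i$amplitude_pct, c_i$amplitude_se), " %)\n", sep = "")
  }
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "),
                           "\n", sep = "")
  invisible(x)
}

#' Choose the number of decay components
#'
#' Fits 1, 2 and 3 components sequentially and accepts the larger model
#' when its reduced chi-square improves by more than 5% and every new
#' component is significant (amplitude exceeding 3x its standard error).
#'
#' @param hist A [decay_histogram()].
#' @param max_components Upper bound on the component count (<= 3).
#' @param ... Passed to [fit_decay()].
#' @return The accepted `decay_fit`, with attribute `decision_trail`: a
#'   data frame of n, reduced chi2 and the accept/reject decision.
#' @export
select_n_components <- function(hist, max_components = 3L, ...) {
  fits <- list()
  trail <- data.frame(n = integer(), reduced_chi2 = numeric(),
                      accepted = logical(), reason = character())
  chosen <- 1L
  for (n in seq_len(max_components)) {
    fits[[n]] <- fit_decay(hist, n_components = n, ...)
    if (n == 1L) {
      trail <- rbind(trail, data.frame(n = 1L,
        reduced_chi2 = fits[[1]]$reduced_chi2, accepted = TRUE,
        reason = "baseline"))
      next
    }
    impr <- 1 - fits[[n]]$reduced_chi2 / fits[[chosen]]$reduced_chi2
    sig <- !("weak-component" %in% fits[[n]]$flags)
    accept <- is.finite(impr) && impr > 0.05 && sig
    trail <- rbind(trail, data.frame(n = n,
      reduced_chi2 = fits[[n]]$reduced_chi2, accepted = accept,
      reason = if (accept) sprintf("chi2 improved %.1f%%, components significant",
                                   100 * impr)
               else if (!sig) "new component not significant (A < 3 SE)"
               else sprintf("chi2 improvement %.1f%% below 5%%", 100 * impr)))
    if (accept) chosen <- n else break
  }
  out <- fits[[chosen]]
  attr(out, "decision_trail") <- trail
  out
}

#' Amplitude-weighted average fluorescence lifetime
#'
#' `<tau> = sum (A_i / 100) * tau_i` over the fitted components.
#'
#' @param fit A `decay_fit`, or a data frame with columns `tau_ns` and
#'   `amplitude_pct`.
#' @return Average lifetime in ns.
#' @export
average_lifetime <- function(fit) {
  comp <- if (inherits(fit, "decay_fit")) fit$components else fit
  stopifnot(all(c("tau_ns", "amplitude_pct") %in% names(comp)))
  sum(comp$amplitude_pct / 100 * comp$tau_ns)
}
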