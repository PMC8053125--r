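# Equilibrium titration analysis: modified-Hill fitting of fluorescence
# quench curves and Mg2+-dependence profiling.

#' An equilibrium titration curve
#'
#' @param titrant_conc Strictly increasing titrant concentrations (nM for
#'   RNA titrations, mM for Mg2+ profiles; record the unit in
#'   `titrant_unit`).
#' @param response Measured response per concentration. The canonical
#'   response is the quench fraction (F0 - F)/F0, which rises with binding
#'   and follows the modified Hill form directly; raw F/F0 can be fitted via
#'   `fit_hill(..., response_is_quench = FALSE)`.
#' @param probe_conc_nM Fixed fluorophore (ligand) concentration.
#' @param titrant_unit Axis unit label (`"nM"`, `"uM"`, `"mM"`).
#' @param titrant Free-text titrant identity (e.g. `"RNA"`, `"Mg2+"`).
#' @return A `titration_curve` object.
#' @export
titration_curve <- function(titrant_conc, response, probe_conc_nM = 50,
                            titrant_unit = "nM", titrant = "RNA") {
  stopifnot(is.numeric(titrant_conc), is.numeric(response),
            length(titrant_conc) == length(response))
  if (any(titrant_conc < 0)) stop("titrant concentrations must be >= 0")
  if (any(diff(titrant_conc) <= 0))
    stop("titrant concentrations must be strictly increasing")
  if (!all(is.finite(response))) stop("responses must be finite")
  structure(list(titrant_conc = titrant_conc, response = response,
                 probe_conc_nM = probe_conc_nM, titrant_unit = titrant_unit,
                 titrant = titrant), class = "titration_curve")
}

#' Modified Hill binding isotherm
#'
#' \deqn{y(x) = B_{max} \frac{x^h}{K_D^h + x^h}}
#'
#' @param x Titrant concentration(s), >= 0.
#' @param K_D Half-saturation constant (> 0), in the unit of `x`.
#' @param h Hill slope.
#' @param B_max Maximum binding response.
#' @return Response value(s).
#' @examples
#' hill_model(13, K_D = 13, h = 1, B_max = 1)  # half-saturation: 0.5
#' @export
hill_model <- function(x, K_D, h, B_max) {
  if (any(x < 0)) stop("titrant concentration must be >= 0")
  if (K_D <= 0) stop("K_D must be > 0")
  xh <- x^h
  B_max * xh / (K_D^h + xh)
}

#' Fit the modified Hill equation to a titration curve
#'
#' Unweighted least squares with initial guesses B_max = max response,
#' K_D = concentration at half-maximal response, h = 1; standard errors
#' from the linearized covariance at the optimum.
#'
#' @param curve A [titration_curve()] (>= 5 points recommended, spanning
#'   both sides of the half-saturation region; a warning is issued
#'   otherwise).
#' @param fix_h Optional fixed Hill slope (e.g. 1); default all three
#'   parameters float.
#' @param response_is_quench If `FALSE` the stored response is taken as raw
#'   F/F0 (decreasing with binding) and `1 - hill_model` is fitted instead.
#' @return A `hill_fit`: `K_D`, `h`, `B_max`, standard errors, `rss`,
#'   `converged`, `flags` (e.g. `"no-binding"`, `"half-max-not-bracketed"`).
#' @export
fit_hill <- function(curve, fix_h = NULL, response_is_quench = TRUE) {
  x <- curve$titrant_conc
  y <- if (response_is_quench) curve$response else 1 - curve$response
  flags <- character()
  fail <- function(msg, flag) structure(
    list(K_D = NA_real_, h = NA_real_, B_max = NA_real_,
         se = c(K_D = NA_real_, h = NA_real_, B_max = NA_real_),
         rss = NA_real_, converged = FALSE, flags = flag, diagnostic = msg,
         titrant_unit = curve$titrant_unit), class = "hill_fit")
  if (length(x) < 5L)
    warning("fewer than 5 titration points; Hill fit will be poorly ",
            "constrained")
  ymax <- max(y)
  if (ymax <= 0 || diff(range(y)) < 1e-12)
    return(fail("no response above zero: no binding detected", "no-binding"))
  half <- ymax / 2
  above <- y >= half
  if (!any(above) || all(above[x > 0])) {
    flags <- c(flags, "half-max-not-bracketed")
  }
  kd0 <- tryCatch(approx(y, x, xout = half, ties = mean)$y,
                  error = function(e) NA_real_)
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- exp(mean(log(pmax(x, min(x[x > 0])))))
  # monotonicity check beyond noise: response should not fall substantially
  # after its peak
  peak <- which.max(y)
  if (peak < length(y) && min(y[peak:length(y)]) < ymax - 3 * sd_est(y))
    warning("fit_hill: response is non-monotone beyond the noise level")

  free_h <- is.null(fix_h)
  par0 <- c(lK = log(kd0), lh = log(if (free_h) 1 else fix_h), B = ymax)
  resfun <- function(p) {
    hh <- if (free_h) exp(p[["lh"]]) else fix_h
    hill_model(x, exp(p[["lK"]]), hh, p[["B"]]) - y
  }
  use <- if (free_h) c("lK", "lh", "B") else c("lK", "B")
  resfun_use <- function(p) {
    full <- par0; full[use] <- p
    resfun(full)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0[use], fn = resfun_use,
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit) || !(fit$info %in% 1:4))
    return(fail("Hill fit failed to converge", "fit-failure"))
  p <- par0; p[use] <- coef(fit)
  K_D <- exp(p[["lK"]]); h <- exp(p[["lh"]]); B_max <- p[["B"]]
  # natural-parameter SEs
  nat <- c(K_D = K_D, h = h, B_max = B_max)
  nat_res <- function(q) hill_model(x, q[1], if (free_h) q[2] else fix_h,
                                    q[3]) - y
  seinfo <- lin_se(nat_res, nat)
  se <- seinfo$se
  names(se) <- c("K_D", "h", "B_max")
  if (!free_h) se["h"] <- 0
  if ("half-max-not-bracketed" %in% flags) flags <- c(flags, "wide-se")
  structure(list(K_D = K_D, h = h, B_max = B_max, se = se,
                 rss = seinfo$rss, converged = TRUE, flags = flags,
                 diagnostic = NULL, titrant_unit = curve$titrant_unit),
            class = "hill_fit")
}

# robust-ish noise scale from first differences
sd_est <- function(y) {
  if (length(y) < 3L) return(0)
  sd(diff(y)) / sqrt(2)
}

#' @export
print.hill_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hill_fit> FAILED: ", x$diagnostic, "\n", sep = "")
    return(invisible(x))
  }
  cat("<hill_fit> K_D = ", format_pm(x$K_D, x$se[["K_D"]]), " ",
      x$titrant_unit, ", h = ", format_pm(x$h, x$se[["h"]]),
      ", B_max = ", format_pm(x$B_max, x$se[["B_max"]]), "\n", sep = "")
  if (length(x$flags)) cat("  flags: ", paste(x$flags, collapse = ", "),
                           "\n", sep = "")
  invisible(x)
}

#' Apparent K_D as a function of Mg2+ concentration
#'
#' Collects per-Mg2+ Hill fits into a profile table, flagging levels where
#' no binding was detected.
#'
#' @param fits List of `list(mg_mM = <numeric>, fit = <hill_fit>)` entries
#'   (>= 1).
#' @return Data frame with columns `mg_mM`, `K_D`, `se`, `h`, `binding`.
#' @export
kd_vs_mg_profile <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1L)
  rows <- lapply(fits, function(e) {
    f <- e$fit
    data.frame(mg_mM = e$mg_mM,
               K_D = if (f$converged) f$K_D else NA_real_,
               se = if (f$converged) unname(f$se[["K_D"]]) else NA_real_,
               h = if (f$converged) f$h else NA_real_,
               binding = isTRUE(f$converged))
  })
  out <- do.call(rbind, rows)
  out[order(out$mg_mM), , drop = FALSE]
}
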