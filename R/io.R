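# CSV interchange (comma-separated, dot decimal, UTF-8, '#' metadata
# headers) and report rendering.

parse_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (ln in meta_lines) {
    body <- sub("^#\\s*", "", ln)
    if (!grepl("=", body, fixed = TRUE)) next
    key <- trimws(sub("=.*$", "", body))
    val <- trimws(sub("^[^=]*=", "", body))
    kv[[key]] <- val
  }
  kv
}

check_numeric_column <- function(raw, col, path) {
  if (any(grepl("^\\s*-?[0-9]+,[0-9]+\\s*$", raw))) # comma decimals
    stop("file '", path, "', column '", col,
         "': comma decimal separators are not accepted; use '.'")
  x <- suppressWarnings(as.numeric(raw))
  bad <- which(!is.finite(x) & nzchar(trimws(raw)))
  if (length(bad))
    stop("file '", path, "', column '", col, "': malformed value '",
         raw[bad[1]], "' in data row ", bad[1])
  x
}

read_body <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  data_lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(data_lines) < 2L) stop("file '", path, "' contains no data rows")
  header <- strsplit(data_lines[1], ",", fixed = TRUE)[[1]]
  cells <- strsplit(data_lines[-1], ",", fixed = TRUE)
  if (any(lengths(cells) != length(header)))
    stop("file '", path, "': data row ",
         which(lengths(cells) != length(header))[1],
         " has the wrong number of fields")
  cols <- lapply(seq_along(header), function(j)
    vapply(cells, `[[`, character(1), j))
  names(cols) <- trimws(header)
  list(meta = parse_meta(lines), cols = cols)
}

meta_num <- function(meta, key, path) {
  if (is.null(meta[[key]]))
    stop("file '", path, "' is missing the required '# ", key,
         "=' header (units are load-bearing)")
  as.numeric(meta[[key]])
}

#' Read a measurement CSV
#'
#' Dispatches on the column header: `time_s,signal` loads a stopped-flow
#' trace (required metadata headers `# receptor_uM=`, `# ligand_uM=`),
#' `time_ns,counts` a TCSPC histogram, `titrant_conc,response` a titration
#' curve (required `# titrant_unit=`, `# probe_nM=`). Malformed rows, comma
#' decimal separators and non-monotone time axes are hard errors naming the
#' offending line.
#'
#' @param path CSV file path.
#' @return A [stopped_flow_trace()], [decay_histogram()] or
#'   [titration_curve()].
#' @export
read_trace_csv <- function(path) {
  b <- read_body(path)
  cn <- names(b$cols)
  num <- function(col) check_numeric_column(b$cols[[col]], col, path)
  if (all(c("time_s", "signal") %in% cn)) {
    lig <- meta_num(b$meta, "ligand_uM", path)
    rec <- meta_num(b$meta, "receptor_uM", path)
    t <- num("time_s")
    mono_check(t, path)
    return(stopped_flow_trace(
      t, num("signal"), ligand_conc_uM = lig, receptor_conc_uM = rec,
      n_averaged = if (!is.null(b$meta$n_averaged))
        as.integer(b$meta$n_averaged) else 1L))
  }
  if (all(c("time_ns", "counts") %in% cn)) {
    t <- num("time_ns")
    mono_check(t, path)
    irf <- if ("irf_counts" %in% cn) num("irf_counts")
    return(decay_histogram(t, num("counts"),
                           background = if (!is.null(b$meta$background))
                             as.numeric(b$meta$background) else 0,
                           irf = irf))
  }
  if (all(c("titrant_conc", "response") %in% cn)) {
    if (is.null(b$meta$titrant_unit))
      stop("file '", path, "' is missing the required '# titrant_unit=' ",
           "header (units are load-bearing)")
    probe <- meta_num(b$meta, "probe_nM", path)
    x <- num("titrant_conc")
    mono_check(x, path, axis = "titrant_conc")
    return(titration_curve(
      x, num("response"), probe_conc_nM = probe,
      titrant_unit = b$meta$titrant_unit,
      titrant = if (!is.null(b$meta$titrant)) b$meta$titrant else "RNA"))
  }
  stop("file '", path, "': unrecognized column header (",
       paste(cn, collapse = ","), ")")
}

mono_check <- function(x, path, axis = "time") {
  bad <- which(diff(x) <= 0)
  if (length(bad))
    stop("file '", path, "': non-monotone ", axis, " column at data row ",
         bad[1] + 1L)
}

#' Write a measurement object as CSV
#'
#' The inverse of [read_trace_csv()]: metadata as `#` header lines, then
#' the data columns. Round-trips losslessly up to numeric formatting.
#'
#' @param x A [stopped_flow_trace()], [decay_histogram()] or
#'   [titration_curve()].
#' @param path Output file path.
#' @param label Optional series/candidate label stored in the header.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(x, path, label = NULL) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  wline <- function(...) writeLines(paste0(...), con)
  fmt <- function(v) format(v, digits = 15, trim = TRUE, scientific = FALSE)
  if (inherits(x, "stopped_flow_trace")) {
    wline("# type=stopped_flow")
    wline("# receptor_uM=", x$receptor_conc_uM)
    wline("# ligand_uM=", x$ligand_conc_uM)
    wline("# n_averaged=", x$n_averaged)
    if (!is.null(label)) wline("# label=", label)
    wline("time_s,signal")
    writeLines(paste(fmt(x$time_s), fmt(x$signal), sep = ","), con)
  } else if (inherits(x, "decay_histogram")) {
    wline("# type=tcspc")
    wline("# background=", x$background)
    if (is.null(x$irf)) {
      wline("time_ns,counts")
      writeLines(paste(fmt(x$channel_time_ns), fmt(x$counts), sep = ","), con)
    } else {
      wline("time_ns,counts,irf_counts")
      writeLines(paste(fmt(x$channel_time_ns), fmt(x$counts), fmt(x$irf),
                       sep = ","), con)
    }
  } else if (inherits(x, "titration_curve")) {
    wline("# type=titration")
    wline("# titrant_unit=", x$titrant_unit)
    wline("# titrant=", x$titrant)
    wline("# probe_nM=", x$probe_conc_nM)
    wline("titrant_conc,response")
    writeLines(paste(fmt(x$titrant_conc), fmt(x$response), sep = ","), con)
  } else stop("write_trace_csv: unsupported object of class ",
              paste(class(x), collapse = "/"))
  invisible(path)
}

#' Read or write a whole stopped-flow series (one CSV per trace)
#'
#' @param series A [trace_series()].
#' @param dir Directory holding/receiving the per-trace CSVs.
#' @return `write_series_csv()`: the file paths, invisibly.
#'   `read_series_csv()`: a [trace_series()].
#' @export
write_series_csv <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(series$traces, function(tr) {
    p <- file.path(dir, sprintf("trace_L%g.csv", tr$ligand_conc_uM))
    write_trace_csv(tr, p, label = series$label)
    p
  }, character(1))
  invisible(paths)
}

#' @rdname write_series_csv
#' @param label Label for the loaded series.
#' @export
read_series_csv <- function(dir, label = basename(dir)) {
  paths <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(paths)) stop("no CSV files found in '", dir, "'")
  traces <- lapply(paths, read_trace_csv)
  lc <- vapply(traces, function(tr) tr$ligand_conc_uM, numeric(1))
  trace_series(traces[order(lc)], label = label)
}

#' Format a value with its standard error
#'
#' Reproduces the conventional table style "7.78±0.09": the error is
#' rounded to one significant digit and the value to the same decimal
#' place.
#'
#' @param value,se Numerics. A missing/zero `se` yields the bare value.
#' @return Character scalar.
#' @export
format_pm <- function(value, se) {
  if (is.na(value)) return("NA")
  if (is.null(se) || length(se) == 0 || is.na(se) || se <= 0)
    return(format(signif(value, 3), trim = TRUE))
  se_r <- signif(se, 1)
  digits <- max(0L, -floor(log10(se_r)))
  sprintf("%.*f±%.*f", digits, round(value, digits), digits, se_r)
}

#' Render analysis results as report tables
#'
#' Collects fit results into the standard table layouts: a rate-constant /
#' model-comparison table (value±SE per rate, RMSD, integer-rounded
#' Delta-AIC/Delta-BIC), a lifetime table (tau±SE with amplitude percent in
#' parentheses, reduced chi2) and a k_obs/k_on table. The bundle is also
#' serializable to JSON so every displayed number traces back to a
#' machine-readable record.
#'
#' @param global_fits Optional named list of [global_fit()] results (names
#'   = row labels); supply together with `comparison` for Delta columns.
#' @param comparison Optional [compare_models()] table.
#' @param decay_fits Optional named list of `decay_fit` objects.
#' @param pfo Optional named list of `pfo_result` objects.
#' @return A `report_bundle` with data-frame entries `rates`, `decays`,
#'   `kobs` (those supplied) and a `provenance` block.
#' @export
render_report <- function(global_fits = NULL, comparison = NULL,
                          decay_fits = NULL, pfo = NULL) {
  out <- list()
  if (!is.null(global_fits) && length(global_fits)) {
    rows <- lapply(seq_along(global_fits), function(i) {
      f <- global_fits[[i]]
      lab <- paper_rate_labels(f$scheme)
      vals <- setNames(
        vapply(names(f$rates),
               function(s) format_pm(f$rates[[s]], f$se[[s]]), character(1)),
        lab[names(f$rates)])
      row <- data.frame(dataset = names(global_fits)[i] %||% f$label,
                        scheme = f$scheme_id, t(vals),
                        RMSD = signif(f$rmsd, 5), check.names = FALSE)
      if (!is.null(comparison)) {
        m <- match(f$scheme_id, comparison$scheme)
        if (!is.na(m)) {
          row$dAIC <- round(comparison$delta_aic[m])
          row$dBIC <- round(comparison$delta_bic[m])
        }
      }
      row
    })
    all_cols <- unique(unlist(lapply(rows, names)))
    rows <- lapply(rows, function(r) {
      r[setdiff(all_cols, names(r))] <- "-"
      r[all_cols]
    })
    out$rates <- do.call(rbind, rows)
  }
  if (!is.null(decay_fits) && length(decay_fits)) {
    out$decays <- do.call(rbind, lapply(seq_along(decay_fits), function(i) {
      f <- decay_fits[[i]]
      comp <- f$components
      cells <- vapply(seq_len(nrow(comp)), function(j)
        paste0(format_pm(comp$tau_ns[j], comp$tau_se[j]), " (",
               format_pm(comp$amplitude_pct[j], comp$amplitude_se[j]), ")"),
        character(1))
      data.frame(sample = names(decay_fits)[i],
                 t(setNames(cells, paste0("tau", seq_along(cells)))),
                 chi2 = round(f$reduced_chi2, 3), check.names = FALSE)
    }))
  }
  if (!is.null(pfo) && length(pfo)) {
    out$kobs <- do.call(rbind, lapply(seq_along(pfo), function(i) {
      p <- pfo[[i]]
      data.frame(series = names(pfo)[i],
                 k_on = format_pm(p$k_on, p$k_on_se),
                 intercept = format_pm(p$intercept, p$intercept_se),
                 n_points = sum(!p$table$excluded))
    }))
  }
  out$provenance <- list(
    package = "aptkin",
    version = as.character(utils::packageVersion("aptkin")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = if (!is.null(global_fits))
      vapply(global_fits, function(f) f$seed, numeric(1)))
  structure(out, class = "report_bundle")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.report_bundle <- function(x, ...) {
  for (nm in setdiff(names(x), "provenance")) {
    cat("== ", nm, " ==\n", sep = "")
    print(x[[nm]], row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Serialize a report bundle (or any fit result) to JSON
#'
#' @param x A `report_bundle`, `global_fit_result`, `decay_fit`,
#'   `hill_fit` or [compare_models()] table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  obj <- if (inherits(x, "global_fit_result")) {
    list(scheme = x$scheme_id, label = x$label,
         rates = as.list(x$rates), rate_se = as.list(x$se),
         responses = as.list(x$responses), rss = x$rss, rmsd = x$rmsd,
         n_points = x$n_points, n_parameters = x$n_parameters,
         seed = x$seed, at_bound = x$at_bound,
         options = x$options[c("n_starts", "lower", "upper",
                               "fit_responses", "dead_time")])
  } else if (inherits(x, "report_bundle") || is.list(x)) {
    unclass(x)
  } else stop("unsupported object")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
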