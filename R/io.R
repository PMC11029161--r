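KNOWN_ANALYTES <- c("ABZSO", "ABZSO2", "ABZSO2NH2", "total")
KNOWN_MATRICES <- c("plasma", "liver", "kidney", "skin", "muscle")

normalize_analyte <- function(x) {
  y <- toupper(gsub("[-_ ]", "", x))
  y[y == "TOTAL"] <- "total"
  y
}

#' Read a censored concentration table into a study bundle
#'
#' Parses the shared CSV dialect — comma-separated, UTF-8, header
#' `analyte,matrix,time_h,conc,n,sd`, with `ND` (case-insensitive)
#' marking non-detected values — and assembles one [conc_series] per
#' analyte/matrix pair. Standard deviations are carried as metadata
#' only; fits never weight by them.
#'
#' @param path CSV file path.
#' @param lods Data frame `matrix, analyte, lod` supplying detection
#'   limits; defaults to [donkey_lods].
#' @param dose Administered dose, mg/kg.
#' @param schedule Free-text dosing schedule for the bundle metadata.
#' @param verbose Log row counts per series.
#' @return An object of class `study_bundle`: `plasma` (named list of
#'   series), `tissues` (tissue -> named list of series), `dose`,
#'   `schedule`, `metadata`.
#' @export
read_concentration_csv <- function(path, lods = donkey_lods(),
                                   dose = NA_real_, schedule = "",
                                   verbose = FALSE) {
  if (!file.exists(path)) stop_pkd("validation", "file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character", strip.white = TRUE)
  need <- c("analyte", "matrix", "time_h", "conc")
  if (!all(need %in% names(raw)))
    stop_pkd("validation", "missing column(s): %s",
             paste(setdiff(need, names(raw)), collapse = ", "))
  if (nrow(raw) == 0) {
    warning("empty concentration table: ", path)
    return(study_bundle(list(), list(), dose, schedule,
                        metadata = list(source = path)))
  }
  line_no <- seq_len(nrow(raw)) + 1L  # header is line 1

  analyte <- normalize_analyte(raw$analyte)
  matrix <- tolower(raw$matrix)
  bad <- which(!(analyte %in% KNOWN_ANALYTES) | !(matrix %in% KNOWN_MATRICES))
  if (length(bad))
    stop_pkd("validation", "unknown analyte/matrix at line(s) %s",
             paste(line_no[bad], collapse = ", "))

  parse_num <- function(x, col) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) & nzchar(x))
    if (length(bad))
      stop_pkd("validation", "malformed %s value '%s' at line %d",
               col, x[bad[1]], line_no[bad[1]])
    out
  }
  time_h <- parse_num(raw$time_h, "time_h")
  is_nd <- toupper(raw$conc) == "ND"
  conc <- rep(NA_real_, nrow(raw))
  conc[!is_nd] <- parse_num(raw$conc[!is_nd], "conc")
  n <- if ("n" %in% names(raw)) suppressWarnings(as.integer(raw$n)) else NA
  sd <- if ("sd" %in% names(raw)) suppressWarnings(as.numeric(raw$sd)) else NA

  key <- paste(analyte, matrix, sep = "|")
  plasma <- list(); tissues <- list()
  for (k in unique(key)) {
    idx <- which(key == k)
    a <- analyte[idx[1]]; m <- matrix[idx[1]]
    if (any(diff(time_h[idx]) <= 0))
      stop_pkd("validation",
               "times not strictly increasing for %s in %s (ordering error)", a, m)
    lod <- lods$lod[lods$matrix == m &
                      lods$analyte == (if (a == "total") "ABZSO" else a)]
    s <- conc_series(a, m, time_h[idx], conc[idx], is_nd[idx],
                     lod = if (length(lod)) max(lod) else NA_real_,
                     n_animals = n[idx][1], sd = sd[idx])
    if (verbose)
      message(sprintf("read %s in %s: %d rows, %d censored",
                      a, m, length(idx), sum(is_nd[idx])))
    if (m == "plasma") plasma[[a]] <- s
    else tissues[[m]][[a]] <- s
  }
  study_bundle(plasma, tissues, dose, schedule, metadata = list(source = path))
}

#' Construct a study bundle
#'
#' Container tying together the plasma series, the tissue residue
#' series, the dose and the dosing schedule of one study.
#'
#' @param plasma Named list of plasma [conc_series] (by analyte).
#' @param tissues Named list (by tissue) of named lists of
#'   [conc_series].
#' @param dose Dose, mg/kg body weight.
#' @param schedule Free-text description of the dosing schedule.
#' @param metadata Free-form provenance list.
#' @return An object of class `study_bundle`.
#' @export
study_bundle <- function(plasma = list(), tissues = list(), dose = NA_real_,
                         schedule = "", metadata = list()) {
  if (!is.na(dose) && dose <= 0) stop_pkd("validation", "dose must be positive")
  structure(list(plasma = plasma, tissues = tissues, dose = dose,
                 schedule = schedule, metadata = metadata),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("Study bundle")
  if (!is.na(x$dose)) cat(sprintf(" (dose %g mg/kg%s)", x$dose,
                                  if (nzchar(x$schedule)) paste0("; ", x$schedule) else ""))
  cat("\n")
  if (length(x$plasma))
    cat("  plasma:", paste(names(x$plasma), collapse = ", "), "\n")
  for (tis in names(x$tissues))
    cat(sprintf("  %s: %s\n", tis, paste(names(x$tissues[[tis]]), collapse = ", ")))
  invisible(x)
}

#' Write series or bundles back to the shared CSV dialect
#'
#' Inverse of [read_concentration_csv]: censored entries are written as
#' `ND`, values and ordering are preserved, so read-write round trips
#' are value-identical.
#'
#' @param x A `study_bundle`, a [conc_series], or a list of series.
#' @param path Output CSV path.
#' @export
write_concentration_csv <- function(x, path) {
  series <- if (inherits(x, "conc_series")) list(x)
  else if (inherits(x, "study_bundle"))
    c(x$plasma, unlist(unname(x$tissues), recursive = FALSE))
  else x
  rows <- do.call(rbind, lapply(series, function(s) {
    df <- as.data.frame(s)
    df$conc <- ifelse(df$censored, "ND",
                      vapply(df$conc, format, "", digits = 15))
    df$sd <- ifelse(is.na(df$sd), "", vapply(df$sd, format, "", digits = 15))
    df[, c("analyte", "matrix", "time_h", "conc", "n", "sd")]
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' @param mrl An [mrl_spec] (limits and marker definition).
#' @param percentile,confidence Tolerance-bound settings for the
#'   withdrawal times.
#' @param weighting Objective weighting for the plasma fits (see
#'   [fit_one_compartment]).
#' @param printed_constants Use 0.693 in place of `ln 2` for half-lives.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(mrl = mrl_spec(), percentile = 0.95,
                            confidence = 0.95,
                            weighting = c("1/C^2", "1/C", "none"),
                            printed_constants = FALSE) {
  stopifnot(inherits(mrl, "mrl_spec"))
  structure(list(mrl = mrl, percentile = percentile, confidence = confidence,
                 weighting = match.arg(weighting),
                 printed_constants = printed_constants),
            class = "pipeline_config")
}

# series holding the marker residue quantity for one tissue
marker_series <- function(tissue_series, marker) {
  if (marker == "total") {
    if (!is.null(tissue_series[["total"]])) return(tissue_series[["total"]])
    comp <- tissue_series[setdiff(names(tissue_series), "total")]
    return(total_residue(comp))
  }
  tissue_series[[marker]]
}

#' Run the full analysis pipeline on a study bundle
#'
#' Fits the one-compartment absorption model to every plasma analyte
#' with enough quantified points, fits log-linear depletion to the
#' configured marker residue in every tissue, computes withdrawal times
#' for the tissues carrying an MRL, and cross-checks any transcribed
#' total columns against recomputed sums. The default path contains no
#' randomness; identical inputs give byte-identical reports.
#'
#' @param bundle A `study_bundle`.
#' @param config A [pipeline_config].
#' @return A report list (class `pkd_report`) with elements
#'   `schema_version`, `dose`, `pk` (per analyte), `tissues` (per
#'   tissue depletion summaries), `wdt` (per tissue + `overall_days`),
#'   and `flags` (total-column discrepancies).
#' @examples
#' rep <- run_pipeline(donkey_study())
#' rep$wdt$overall_days
#' @export
run_pipeline <- function(bundle, config = pipeline_config()) {
  stopifnot(inherits(bundle, "study_bundle"), inherits(config, "pipeline_config"))
  report <- list(schema_version = "1.0", dose = bundle$dose,
                 marker = config$mrl$marker,
                 pk = list(), tissues = list(), wdt = list(), flags = list())

  for (a in names(bundle$plasma)) {
    s <- bundle$plasma[[a]]
    if (n_quantified(s) < 4) next
    fit <- fit_one_compartment(s, dose = bundle$dose, weighting = config$weighting)
    d <- derive_parameters(fit$params, config$printed_constants)
    report$pk[[a]] <- list(
      m = fit$params$M, ka = fit$params$Ka, ke = fit$params$Ke,
      t_half_ka_h = d$t_half_ka_h, t_half_ke_h = d$t_half_ke_h,
      t_max_h = d$t_max_h, c_max = d$c_max, auc = d$auc,
      vd_over_f = d$vd_over_f, cl_b = d$cl_b,
      rss = fit$residual_sum_squares, n_points = fit$n_points,
      converged = fit$converged,
      note = if (a != "ABZSO") "apparent, parent-dose-referenced" else NULL)
  }

  fits <- list()
  for (tis in names(bundle$tissues)) {
    ts <- bundle$tissues[[tis]]
    ms <- tryCatch(marker_series(ts, config$mrl$marker), pkd_error = function(e) NULL)
    usable <- !is.null(ms) && n_quantified(ms) >= 3
    if (!usable) {
      if (tis %in% names(config$mrl$limits))
        stop_pkd("insufficient_data",
                 "marker '%s' has too few quantified points in %s",
                 config$mrl$marker, tis)
      report$tissues[[tis]] <- list(note = sprintf(
        "marker '%s' not quantifiable; tissue skipped", config$mrl$marker))
      next
    }
    fit <- fit_depletion(ms, select = TRUE)
    fits[[tis]] <- fit
    report$tissues[[tis]] <- list(
      k = fit$k,
      t_half_h = depletion_half_life(fit, config$printed_constants),
      intercept_ln = fit$intercept_ln, residual_sd = fit$residual_sd,
      n_points = fit$n_points, t_mean = fit$t_mean, s_xx = fit$s_xx)
    if (!is.null(ts[["total"]]) && length(ts) > 1) {
      fl <- check_total_consistency(ts[setdiff(names(ts), "total")], ts[["total"]])
      if (nrow(fl)) report$flags[[tis]] <- fl
    }
  }

  if (length(fits)) {
    lims <- config$mrl$limits[intersect(names(config$mrl$limits), names(fits))]
    wr <- wdt_report(fits, mrl_spec(lims, config$mrl$marker),
                     config$percentile, config$confidence)
    report$wdt <- c(
      lapply(wr$results, function(r) list(
        crossing_time_h = r$crossing_time_h, wdt_days = r$wdt_days,
        mrl = r$mrl, k = r$fit$k, t_half_h = r$fit$t_half,
        residual_sd = r$fit$residual_sd, n_points = r$fit$n_points)),
      list(overall_days = wr$overall_wdt_days,
           percentile = config$percentile, confidence = config$confidence))
  }
  class(report) <- "pkd_report"
  report
}

#' @export
print.pkd_report <- function(x, ...) {
  cat("Analysis report (schema", x$schema_version, ")\n")
  for (a in names(x$pk))
    cat(sprintf("  PK %-7s Ke %.4g /h, AUC %.4g, Cmax %.3g at %.3g h\n",
                a, x$pk[[a]]$ke, x$pk[[a]]$auc, x$pk[[a]]$c_max,
                x$pk[[a]]$t_max_h))
  for (tis in names(x$tissues)) {
    b <- x$tissues[[tis]]
    if (!is.null(b$k))
      cat(sprintf("  depletion %-7s k %.4g /h, t1/2 %.3g h\n", tis, b$k, b$t_half_h))
  }
  if (!is.null(x$wdt$overall_days))
    cat(sprintf("  overall WDT: %d day(s)\n", x$wdt$overall_days))
  if (length(x$flags))
    cat("  flagged total-column discrepancies in:",
        paste(names(x$flags), collapse = ", "), "\n")
  invisible(x)
}

#' Write a pipeline report as JSON
#'
#' @param report A `pkd_report` from [run_pipeline].
#' @param path Output path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Flat CSV mirrors of a pipeline report
#'
#' Writes `pk.csv`, `depletion.csv` and `wdt.csv` under `dir`, one row
#' per analyte or tissue.
#'
#' @param report A `pkd_report`.
#' @param dir Output directory (created if needed).
#' @export
write_report_csv <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  row_bind <- function(lst, idcol) {
    keep <- Filter(function(b) is.null(b$note) || !is.null(b$k) || !is.null(b$m), lst)
    if (!length(keep)) return(invisible(NULL))
    df <- do.call(rbind, lapply(names(keep), function(nm) {
      b <- keep[[nm]]
      b <- b[vapply(b, function(v) is.numeric(v) || is.logical(v), TRUE)]
      cbind(data.frame(id = nm), as.data.frame(b))
    }))
    names(df)[1] <- idcol
    df
  }
  pk <- row_bind(report$pk, "analyte")
  if (!is.null(pk)) utils::write.csv(pk, file.path(dir, "pk.csv"), row.names = FALSE)
  dep <- row_bind(report$tissues, "tissue")
  if (!is.null(dep)) utils::write.csv(dep, file.path(dir, "depletion.csv"), row.names = FALSE)
  w <- report$wdt[setdiff(names(report$wdt), c("overall_days", "percentile", "confidence"))]
  wd <- row_bind(w, "tissue")
  if (!is.null(wd)) utils::write.csv(wd, file.path(dir, "wdt.csv"), row.names = FALSE)
  invisible(dir)
}
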