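#' Concentration-time series with below-detection censoring
#'
#' A `conc_series` holds one analyte's concentration-time course in one
#' matrix (plasma or an edible tissue). Observations below the limit of
#' detection (LOD) are carried as censored markers, never as imputed
#' numbers: `conc` is `NA` wherever `censored` is `TRUE`.
#'
#' @param analyte One of `"ABZSO"`, `"ABZSO2"`, `"ABZSO2NH2"` (albendazole
#'   sulphoxide, its sulfone, its 2-aminosulfone) or `"total"` for the
#'   three-analyte residue sum.
#' @param matrix One of `"plasma"`, `"liver"`, `"kidney"`, `"skin"`,
#'   `"muscle"`.
#' @param times Sampling times in hours, strictly increasing, all >= 0.
#' @param values Numeric concentrations (ug/mL for plasma, ug/g for
#'   tissue); `NA` marks a censored (non-detected) observation.
#' @param censored Optional logical vector; defaults to `is.na(values)`.
#' @param lod Detection limit applying to the censored entries; must be
#'   positive when any entry is censored.
#' @param n_animals Animals contributing to each mean (informational).
#' @param sd Optional per-time standard deviations (metadata only; fits do
#'   not weight by them).
#' @return An object of class `conc_series`.
#' @examples
#' s <- conc_series("ABZSO", "plasma", times = c(1, 2, 4, 8),
#'                  values = c(0.47, 0.55, 0.78, 0.47), lod = 0.01)
#' s
#' @export
conc_series <- function(analyte, matrix, times, values, censored = NULL,
                        lod = NA_real_, n_animals = NA_integer_, sd = NULL) {
  analyte <- match.arg(analyte, c("ABZSO", "ABZSO2", "ABZSO2NH2", "total"))
  matrix <- match.arg(matrix, c("plasma", "liver", "kidney", "skin", "muscle"))
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (is.null(censored)) censored <- is.na(values)
  censored <- as.logical(censored)
  if (length(values) != length(times) || length(censored) != length(times))
    stop_pkd("validation", "times, values and censored must have equal length")
  if (any(times < 0) || any(diff(times) <= 0))
    stop_pkd("validation", "times must be nonnegative and strictly increasing")
  values[censored] <- NA_real_
  if (any(!censored & (is.na(values) | values <= 0)))
    stop_pkd("validation", "quantified values must be positive numbers")
  if (any(censored) && (is.na(lod) || lod <= 0))
    stop_pkd("validation", "lod must be positive when any entry is censored")
  structure(
    list(analyte = analyte, matrix = matrix, times = times, values = values,
         censored = censored, lod = as.numeric(lod),
         n_animals = n_animals,
         sd = if (is.null(sd)) rep(NA_real_, length(times)) else as.numeric(sd)),
    class = "conc_series"
  )
}

#' @export
print.conc_series <- function(x, ...) {
  unit <- if (x$matrix == "plasma") "ug/mL" else "ug/g"
  cat(sprintf("Concentration series: %s in %s (%d time points, %d censored)\n",
              x$analyte, x$matrix, length(x$times), sum(x$censored)))
  if (!is.na(x$lod)) cat(sprintf("  LOD: %g %s\n", x$lod, unit))
  df <- as.data.frame(x)
  df$conc <- ifelse(df$censored, "ND", format(df$conc))
  print(df[, c("time_h", "conc")], row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.conc_series <- function(x, ...) {
  data.frame(analyte = x$analyte, matrix = x$matrix, time_h = x$times,
             conc = x$values, censored = x$censored,
             n = x$n_animals, sd = x$sd, stringsAsFactors = FALSE)
}

#' @export
length.conc_series <- function(x) length(x$times)

# number of quantified (non-censored) observations
n_quantified <- function(series) sum(!series$censored)

# subset a conc_series by index, preserving structure
subset_series <- function(series, idx) {
  conc_series(series$analyte, series$matrix, series$times[idx],
              series$values[idx], series$censored[idx], series$lod,
              series$n_animals, series$sd[idx])
}

#' Extract the depletion phase of a tissue residue series
#'
#' Returns the sub-series from the time of the maximum quantified
#' concentration onward (inclusive), with censored points removed. Tissue
#' residues typically peak at the first or second post-dose sampling time;
#' everything from the peak on is modelled as mono-exponential decay.
#'
#' @param series A [conc_series].
#' @return A [conc_series] containing only quantified, post-peak points.
#' @export
select_depletion_phase <- function(series) {
  stopifnot(inherits(series, "conc_series"))
  q <- which(!series$censored)
  if (length(q) == 0)
    stop_pkd("insufficient_data", "no quantified points in series")
  i_max <- q[which.max(series$values[q])]
  keep <- q[q >= i_max]
  if (length(keep) < 3)
    stop_pkd("insufficient_data",
             "need >= 3 quantified points at or after the maximum, got %d",
             length(keep))
  subset_series(series, keep)
}

#' Sum analyte series into a total-residue series
#'
#' Regulatory marker-residue limits for albendazole apply to the sum of
#' ABZSO, ABZSO2 and ABZSO2NH2. Censored components contribute zero to the
#' sum; a time point is censored in the total only when every component is
#' censored there.
#'
#' @param series_list List of [conc_series] sharing one tissue and one
#'   time grid.
#' @return A [conc_series] with `analyte = "total"`.
#' @export
total_residue <- function(series_list) {
  stopifnot(length(series_list) >= 1,
            all(vapply(series_list, inherits, TRUE, "conc_series")))
  tmpl <- series_list[[1]]
  for (s in series_list) {
    if (s$matrix != tmpl$matrix)
      stop_pkd("alignment", "series are from different matrices (%s vs %s)",
               s$matrix, tmpl$matrix)
    if (length(s$times) != length(tmpl$times) ||
        any(s$times != tmpl$times))
      stop_pkd("alignment", "series do not share a common time grid")
  }
  vals <- sapply(series_list, function(s) ifelse(s$censored, 0, s$values))
  if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1)
  cen <- sapply(series_list, function(s) s$censored)
  if (is.null(dim(cen))) cen <- matrix(cen, nrow = 1)
  all_cen <- apply(cen, 1, all)
  total <- rowSums(vals)
  total[all_cen] <- NA_real_
  lods <- vapply(series_list, function(s) s$lod, 0)
  conc_series("total", tmpl$matrix, tmpl$times, total, all_cen,
              lod = if (any(all_cen)) max(lods, na.rm = TRUE) else tmpl$lod,
              n_animals = tmpl$n_animals)
}

#' Check printed total columns against recomputed sums
#'
#' Compares a transcribed "total concentration" column with the sum of its
#' component series and flags discrepancies larger than `tol` rather than
#' silently reconciling them (printed tables occasionally disagree with
#' their own components).
#'
#' @param components List of analyte [conc_series] for one tissue.
#' @param printed_total The transcribed total [conc_series].
#' @param tol Largest acceptable absolute discrepancy, ug/g.
#' @return Data frame of flagged time points (zero rows when consistent),
#'   with columns `time_h`, `printed`, `computed`, `diff`.
#' @export
check_total_consistency <- function(components, printed_total, tol = 0.02) {
  comp <- total_residue(components)
  both <- !comp$censored & !printed_total$censored
  d <- abs(comp$values - printed_total$values)
  flag <- both & !is.na(d) & d > tol + 1e-9
  mism <- (comp$censored != printed_total$censored)
  out <- data.frame(
    time_h = comp$times[flag | mism],
    printed = printed_total$values[flag | mism],
    computed = comp$values[flag | mism],
    diff = (printed_total$values - comp$values)[flag | mism]
  )
  out[order(out$time_h), , drop = FALSE]
}
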