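#' One-sided normal tolerance factor for a regression prediction
#'
#' Exact (Owen) construction of the one-sided tolerance bound on a
#' normal-theory regression: at a prediction point with leverage
#' `d = 1/n + (t - t_mean)^2 / s_xx`, the factor is
#' \deqn{K = \sqrt{d}\; t'_{n-2, z_p/\sqrt{d}}(\gamma)}{K = sqrt(d) * q}
#' where `q` is the `confidence`-quantile of the noncentral t
#' distribution with `n - 2` degrees of freedom and noncentrality
#' `qnorm(percentile)/sqrt(d)`. The upper tolerance limit on the fitted
#' line is then `yhat + K * residual_sd`; with confidence `gamma` it
#' exceeds the `percentile` quantile of the response distribution at
#' that point.
#'
#' @param n Number of observations in the regression (>= 3).
#' @param percentile Quantile of the residue distribution to bound
#'   (default 0.95).
#' @param confidence Confidence level of the bound (default 0.95).
#' @param d Leverage of the prediction point; > 0.
#' @return The multiplier K (dimensionless).
#' @examples
#' tolerance_factor(n = 10, d = 0.1)
#' @export
tolerance_factor <- function(n, percentile = 0.95, confidence = 0.95, d) {
  if (n < 3) stop_pkd("domain", "n must be >= 3")
  if (percentile <= 0 || percentile >= 1 || confidence <= 0 || confidence >= 1)
    stop_pkd("domain", "percentile and confidence must lie in (0, 1)")
  if (any(d <= 0)) stop_pkd("domain", "leverage d must be positive")
  sqrt(d) * stats::qt(confidence, df = n - 2,
                      ncp = stats::qnorm(percentile) / sqrt(d))
}

#' Maximum residue limit specification
#'
#' Tissue-to-limit map plus the definition of the marker residue the
#' limits apply to. Defaults are the Chinese national limits for
#' albendazole marker residues (GB 31650-2019): muscle and fat
#' 100 ug/kg (0.1 ug/g), liver and kidney 5000 ug/kg (5 ug/g). Skin has
#' no limit and is deliberately absent: it is reported descriptively,
#' never used for the withdrawal decision.
#'
#' @param limits Named numeric vector, tissue -> MRL in ug/g.
#' @param marker `"total"` for the three-analyte sum (ABZSO + ABZSO2 +
#'   ABZSO2NH2) or a single analyte name.
#' @return An object of class `mrl_spec`.
#' @export
mrl_spec <- function(limits = c(muscle = 0.1, fat = 0.1, liver = 5, kidney = 5),
                     marker = "total") {
  if (length(limits) && (is.null(names(limits)) || any(!nzchar(names(limits)))))
    stop_pkd("config", "limits must be a named vector")
  if (any(limits <= 0)) stop_pkd("config", "all MRLs must be positive")
  marker <- match.arg(marker, c("total", "ABZSO", "ABZSO2", "ABZSO2NH2"))
  structure(list(limits = limits, marker = marker), class = "mrl_spec")
}

#' @export
print.mrl_spec <- function(x, ...) {
  cat(sprintf("MRL specification (marker: %s)\n", x$marker))
  for (tis in names(x$limits))
    cat(sprintf("  %-8s %g ug/g\n", tis, x$limits[[tis]]))
  invisible(x)
}

# upper one-sided tolerance limit on the ln scale at times tt
upper_tolerance_limit <- function(fit, tt, percentile, confidence) {
  d <- 1 / fit$n_points + (tt - fit$t_mean)^2 / fit$s_xx
  K <- if (fit$residual_sd > 0)
    tolerance_factor(fit$n_points, percentile, confidence, d)
  else 0
  fit$intercept_ln + fit$slope * tt + K * fit$residual_sd
}

#' Withdrawal time from a depletion fit and a residue limit
#'
#' Finds the earliest time at which the upper one-sided
#' `percentile`/`confidence` tolerance limit on the log-linear depletion
#' regression falls to the natural log of the MRL, and rounds it up to
#' whole days. This is the standard regulatory construction used by
#' withdrawal-period calculators: the animal's residues are below the
#' limit, for the stated share of the population, with the stated
#' confidence, from the crossing time on.
#'
#' With `residual_sd = 0` the bound coincides with the regression line
#' and the crossing is the analytic `ln(C0/MRL)/k`. Otherwise the
#' crossing is located by a grid scan plus bisection to 0.01 h; the
#' bound is eventually strictly decreasing because `k > 0` dominates the
#' leverage growth (when it does not, no crossing exists within the
#' horizon and a `no_crossing` error is raised).
#'
#' @param fit A [depletion_fit] with `k > 0`.
#' @param mrl Maximum residue limit, ug/g.
#' @param percentile,confidence Tolerance-bound settings (default 95/95).
#' @param horizon_h Search horizon, h.
#' @param tol_h Bisection tolerance, h.
#' @return An object of class `withdrawal_result`: `tissue`,
#'   `crossing_time_h`, `wdt_days` (ceiling of `crossing_time_h / 24`),
#'   `mrl`, `percentile`, `confidence`, `fit`.
#' @examples
#' fit <- fit_depletion(donkey_residues("liver")$total, select = TRUE)
#' withdrawal_time(fit, mrl = 5)
#' @export
withdrawal_time <- function(fit, mrl, percentile = 0.95, confidence = 0.95,
                            horizon_h = 10000, tol_h = 0.01) {
  stopifnot(inherits(fit, "depletion_fit"))
  if (fit$k <= 0) stop_pkd("domain", "fit shows no depletion (k <= 0)")
  if (mrl <= 0) stop_pkd("domain", "mrl must be positive")
  target <- log(mrl)
  if (fit$residual_sd == 0) {
    crossing <- max(0, (fit$intercept_ln - target) / fit$k)
  } else {
    ub <- function(tt) upper_tolerance_limit(fit, tt, percentile, confidence)
    if (ub(0) <= target) {
      crossing <- 0
    } else {
      grid <- seq(0, horizon_h, by = max(tol_h * 100, 1))
      below <- which(ub(grid) <= target)
      if (length(below) == 0)
        stop_pkd("no_crossing",
                 "tolerance bound stays above ln(MRL) up to %g h", horizon_h)
      hi <- grid[below[1]]; lo <- if (below[1] == 1) 0 else grid[below[1] - 1]
      while (hi - lo > tol_h) {
        mid <- (lo + hi) / 2
        if (ub(mid) <= target) hi <- mid else lo <- mid
      }
      crossing <- hi
    }
  }
  structure(list(
    tissue = fit$tissue,
    crossing_time_h = crossing,
    wdt_days = as.integer(ceiling(crossing / 24)),
    mrl = mrl,
    percentile = percentile,
    confidence = confidence,
    fit = fit
  ), class = "withdrawal_result")
}

#' @export
print.withdrawal_result <- function(x, ...) {
  cat(sprintf(
    "Withdrawal time, %s (MRL %g ug/g, %g/%g tolerance): bound crosses at %.2f h -> %d day(s)\n",
    x$tissue, x$mrl, 100 * x$percentile, 100 * x$confidence,
    x$crossing_time_h, x$wdt_days))
  invisible(x)
}

#' Withdrawal-time report over all tissues
#'
#' Applies [withdrawal_time] to every tissue carrying a limit in the
#' [mrl_spec]; the overall withdrawal time is the maximum over those
#' tissues. Fitted tissues without a limit (skin) are reported
#' descriptively with `NA` results.
#'
#' @param tissue_fits Named list of [depletion_fit]s, one per tissue.
#' @param spec An [mrl_spec].
#' @param percentile,confidence Tolerance-bound settings.
#' @return An object of class `wdt_report`: list with `results` (one
#'   [withdrawal_result] or descriptive stub per fitted tissue) and
#'   `overall_wdt_days`.
#' @export
wdt_report <- function(tissue_fits, spec, percentile = 0.95, confidence = 0.95) {
  stopifnot(inherits(spec, "mrl_spec"))
  if (length(spec$limits) == 0)
    return(structure(list(results = list(), overall_wdt_days = NA_integer_,
                          marker = spec$marker), class = "wdt_report"))
  missing_fit <- setdiff(names(spec$limits), names(tissue_fits))
  if (length(missing_fit))
    stop_pkd("config", "no depletion fit supplied for limited tissue(s): %s",
             paste(missing_fit, collapse = ", "))
  results <- list()
  for (tis in names(tissue_fits)) {
    if (tis %in% names(spec$limits)) {
      results[[tis]] <- withdrawal_time(tissue_fits[[tis]], spec$limits[[tis]],
                                        percentile, confidence)
    } else {
      results[[tis]] <- structure(list(
        tissue = tis, crossing_time_h = NA_real_, wdt_days = NA_integer_,
        mrl = NA_real_, percentile = percentile, confidence = confidence,
        fit = tissue_fits[[tis]], note = "no MRL; reported descriptively"
      ), class = "withdrawal_result")
    }
  }
  wdt <- vapply(results, function(r) r$wdt_days, 1L)
  structure(list(
    results = results,
    overall_wdt_days = if (all(is.na(wdt))) NA_integer_
                       else as.integer(max(wdt, na.rm = TRUE)),
    marker = spec$marker
  ), class = "wdt_report")
}

#' @export
print.wdt_report <- function(x, ...) {
  cat(sprintf("Withdrawal-time report (marker: %s)\n", x$marker))
  for (r in x$results) {
    if (is.na(r$wdt_days))
      cat(sprintf("  %-8s no MRL; t1/2 = %.1f h (descriptive)\n",
                  r$tissue, r$fit$t_half))
    else
      cat(sprintf("  %-8s MRL %g ug/g: crossing %.2f h, WDT %d day(s)\n",
                  r$tissue, r$mrl, r$crossing_time_h, r$wdt_days))
  }
  cat(sprintf("  overall WDT: %s day(s)\n", x$overall_wdt_days))
  invisible(x)
}
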