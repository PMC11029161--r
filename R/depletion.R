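#' Fit first-order depletion to a tissue residue series
#'
#' Tissue residues after the last dose are modelled as mono-exponential
#' decay, `C(t) = C0 exp(-k t)`, fitted as an ordinary least-squares
#' regression of `ln C` on time via [stats::lm]. The fit stores the
#' design summaries (`t_mean`, `s_xx`) and the residual standard
#' deviation (n - 2 denominator) needed by the withdrawal-time tolerance
#' bound.
#'
#' The series should already be a selected depletion phase (see
#' [select_depletion_phase]); if it still contains censored points or a
#' rising prefix, pass `select = TRUE`.
#'
#' @param series A [conc_series] with >= 3 quantified points.
#' @param select Apply [select_depletion_phase] first.
#' @return An object of class `depletion_fit`: `tissue`, `analyte`,
#'   `intercept_ln` (ln C0), `slope` (= -k, signed), `k`, `t_half`
#'   (ln 2 / k), `residual_sd`, `n_points`, `t_mean`, `s_xx`, plus the
#'   points used and the underlying `lm` object. Methods: `print`,
#'   `coef`, `predict`, `residuals`, `summary`, `plot`.
#' @examples
#' liv <- donkey_residues("liver")$total
#' fit_depletion(liv, select = TRUE)
#' @export
fit_depletion <- function(series, select = FALSE) {
  stopifnot(inherits(series, "conc_series"))
  if (select) series <- select_depletion_phase(series)
  if (any(series$censored))
    stop_pkd("validation",
             "series still contains censored points; use select = TRUE")
  t <- series$times; y <- series$values
  if (length(t) < 3)
    stop_pkd("insufficient_data", "need >= 3 points, got %d", length(t))
  if (any(y <= 0)) stop_pkd("domain", "nonpositive concentration in series")
  if (stats::var(t) == 0) stop_pkd("singular_design", "zero time variance")
  fit <- stats::lm(log(y) ~ t)
  b <- unname(stats::coef(fit))
  structure(list(
    tissue = series$matrix,
    analyte = series$analyte,
    intercept_ln = b[1],
    slope = b[2],
    k = -b[2],
    t_half = log(2) / -b[2],
    # suppressed: lm warns on exact (zero-residual) fits, a legitimate input here
    residual_sd = suppressWarnings(summary(fit)$sigma),
    n_points = length(t),
    t_mean = mean(t),
    s_xx = sum((t - mean(t))^2),
    times = t, observed = y, lm = fit
  ), class = "depletion_fit")
}

#' Elimination half-life from a depletion fit
#'
#' @param fit A [depletion_fit] (or any list with element `k`).
#' @param printed_constants Use 0.693 in place of `ln 2`.
#' @return Half-life in hours.
#' @export
depletion_half_life <- function(fit, printed_constants = FALSE) {
  k <- if (is.list(fit)) fit$k else fit
  if (!is.finite(k) || k <= 0)
    stop_pkd("domain", "no depletion: k must be positive, got %g", k)
  (if (printed_constants) 0.693 else log(2)) / k
}

#' @export
print.depletion_fit <- function(x, ...) {
  cat(sprintf("Log-linear depletion fit: %s in %s\n", x$analyte, x$tissue))
  cat(sprintf("  C0 = %.3f ug/g, k = %.5f /h, t1/2 = %.1f h (%.2f d)\n",
              exp(x$intercept_ln), x$k, x$t_half, x$t_half / 24))
  cat(sprintf("  n = %d points (%g-%g h), residual SD (ln scale) = %.4f\n",
              x$n_points, min(x$times), max(x$times), x$residual_sd))
  invisible(x)
}

#' @export
coef.depletion_fit <- function(object, ...) {
  c(intercept_ln = object$intercept_ln, slope = object$slope)
}

#' Predicted residue concentration from a depletion fit
#'
#' @param object A [depletion_fit].
#' @param newdata Times in hours (vector or data frame with `time_h`);
#'   defaults to the fitted times.
#' @param log Return on the natural-log scale.
#' @param ... Unused.
#' @return Predicted concentrations, ug/g (or ln ug/g).
#' @export
predict.depletion_fit <- function(object, newdata = NULL, log = FALSE, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.data.frame(newdata)) newdata$time_h
       else as.numeric(newdata)
  eta <- object$intercept_ln + object$slope * t
  if (log) eta else exp(eta)
}

#' @export
residuals.depletion_fit <- function(object, ...) {
  log(object$observed) - predict(object, log = TRUE)
}

#' @export
summary.depletion_fit <- function(object, ...) {
  print(object)
  invisible(summary(object$lm))
}

#' @export
plot.depletion_fit <- function(x, ...) {
  graphics::plot(x$times, log(x$observed), xlab = "Time (h)",
                 ylab = "ln concentration (ln ug/g)",
                 main = sprintf("%s depletion, %s", x$tissue, x$analyte), ...)
  graphics::abline(x$intercept_ln, x$slope)
  invisible(x)
}
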