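#' Primary parameters of the one-compartment absorption model
#'
#' The model for plasma concentration after extravascular dosing is the
#' Bateman curve \deqn{C(t) = M (e^{-K_e t} - e^{-K_a t})}{C(t) = M (exp(-Ke t) - exp(-Ka t))}
#' where `M` is the zero-time intercept of the back-extrapolated
#' elimination phase, `Ka` the first-order absorption rate constant and
#' `Ke` the first-order elimination rate constant. The form is undefined
#' when `Ka == Ke`; that degenerate case is rejected rather than replaced
#' by its `t exp(-kt)` limit.
#'
#' @param M Zero-time intercept, ug/mL; > 0.
#' @param Ka Absorption rate constant, 1/h; > 0.
#' @param Ke Elimination rate constant, 1/h; > 0.
#' @param dose Administered dose, mg/kg body weight (used only by
#'   [derive_parameters] for Vd/F and clearance).
#' @return An object of class `pk_params`.
#' @examples
#' p <- pk_params(M = 0.73, Ka = 1.04, Ke = 0.054, dose = 7.5)
#' predict_concentration(p, c(1, 3, 24))
#' @export
pk_params <- function(M, Ka, Ke, dose = NA_real_) {
  if (!is.finite(M) || M <= 0) stop_pkd("domain", "M must be positive")
  if (!is.finite(Ka) || Ka <= 0) stop_pkd("domain", "Ka must be positive")
  if (!is.finite(Ke) || Ke <= 0) stop_pkd("domain", "Ke must be positive")
  check_not_degenerate(Ka, Ke)
  structure(list(M = M, Ka = Ka, Ke = Ke, dose = dose), class = "pk_params")
}

check_not_degenerate <- function(Ka, Ke) {
  if (abs(Ka - Ke) / Ke < 1e-8)
    stop_pkd("degenerate_model",
             "Ka and Ke coincide (|Ka-Ke|/Ke < 1e-8); the two-exponential model is undefined")
  invisible(TRUE)
}

#' @export
print.pk_params <- function(x, ...) {
  cat(sprintf("One-compartment absorption model: M = %.4g ug/mL, Ka = %.4g /h, Ke = %.4g /h",
              x$M, x$Ka, x$Ke))
  if (!is.na(x$dose)) cat(sprintf(", dose = %g mg/kg", x$dose))
  cat("\n")
  invisible(x)
}

#' Model plasma concentration at given times
#'
#' Evaluates the Bateman curve `M (exp(-Ke t) - exp(-Ka t))`. The curve is
#' zero at `t = 0`, positive for all `t > 0` when `Ka > Ke`, and decays to
#' zero as `t` grows.
#'
#' @param params A [pk_params] object.
#' @param t Time(s) in hours, >= 0.
#' @return Concentration(s), ug/mL.
#' @export
predict_concentration <- function(params, t) {
  stopifnot(inherits(params, "pk_params"))
  if (any(t < 0)) stop_pkd("domain", "t must be nonnegative")
  check_not_degenerate(params$Ka, params$Ke)
  params$M * (exp(-params$Ke * t) - exp(-params$Ka * t))
}

#' Secondary pharmacokinetic parameters in closed form
#'
#' From the primary triple (M, Ka, Ke) and the dose, computes:
#' absorption and elimination half-lives `ln 2 / Ka` and `ln 2 / Ke`;
#' the stationary point of the curve, `t_max = ln(Ka/Ke) / (Ka - Ke)`,
#' and `c_max = C(t_max)`; the area under the curve to infinity,
#' `AUC = M (1/Ke - 1/Ka)`; the apparent distribution volume
#' `Vd/F = dose / (AUC * Ke)`; and total body clearance
#' `CLb = (Vd/F) * Ke`.
#'
#' Units: with the dose in mg/kg and AUC in ug/mL * h (= mg/L * h), the
#' mg/ug and mL/L factors cancel, so `dose / (AUC * Ke)` is directly in
#' L/kg and CLb in L/h/kg — no explicit conversion factor is needed.
#'
#' @param params A [pk_params] with `dose` set (required for `vd_over_f`
#'   and `cl_b`; they are `NA` otherwise).
#' @param printed_constants If `TRUE`, half-lives use the rounded constant
#'   0.693 instead of `ln 2`, matching hand calculations in older reports.
#'   The difference is below a tenth of a percent.
#' @return An object of class `derived_pk`: a list with elements
#'   `t_half_ka_h`, `t_half_ke_h`, `t_max_h`, `c_max`, `auc`, `vd_over_f`,
#'   `cl_b`.
#' @examples
#' derive_parameters(pk_params(0.73, 1.04, 0.054, dose = 7.5))
#' @export
derive_parameters <- function(params, printed_constants = FALSE) {
  stopifnot(inherits(params, "pk_params"))
  check_not_degenerate(params$Ka, params$Ke)
  ln2 <- if (printed_constants) 0.693 else log(2)
  M <- params$M; Ka <- params$Ka; Ke <- params$Ke
  t_max <- log(Ka / Ke) / (Ka - Ke)
  auc <- M * (1 / Ke - 1 / Ka)
  vd <- if (is.na(params$dose)) NA_real_ else params$dose / (auc * Ke)
  structure(list(
    t_half_ka_h = ln2 / Ka,
    t_half_ke_h = ln2 / Ke,
    t_max_h = t_max,
    c_max = predict_concentration(params, t_max),
    auc = auc,
    vd_over_f = vd,
    cl_b = vd * Ke
  ), class = "derived_pk")
}

#' @export
print.derived_pk <- function(x, ...) {
  cat("Derived PK parameters:\n")
  cat(sprintf("  t1/2 (absorption)  %8.3f h\n", x$t_half_ka_h))
  cat(sprintf("  t1/2 (elimination) %8.3f h\n", x$t_half_ke_h))
  cat(sprintf("  Tmax               %8.3f h\n", x$t_max_h))
  cat(sprintf("  Cmax               %8.3f ug/mL\n", x$c_max))
  cat(sprintf("  AUC(0-inf)         %8.3f ug/mL*h\n", x$auc))
  if (!is.na(x$vd_over_f)) {
    cat(sprintf("  Vd/F               %8.3f L/kg\n", x$vd_over_f))
    cat(sprintf("  CLb                %8.3f L/h/kg\n", x$cl_b))
  }
  invisible(x)
}

#' Trapezoidal AUC as an independent numerical check
#'
#' Integrates [predict_concentration] on `[0, t_end]` by the trapezoid
#' rule. Serves as an oracle for the closed-form `M (1/Ke - 1/Ka)`.
#'
#' @param params A [pk_params].
#' @param t_end Upper limit, h; must be far enough out that the tail is
#'   negligible (`C(t_end) < 1e-6 * M`) unless `check_tail = FALSE`.
#' @param step Grid step, h.
#' @param check_tail Enforce the tail condition.
#' @return AUC in ug/mL * h.
#' @export
auc_numeric <- function(params, t_end, step = 0.01, check_tail = TRUE) {
  stopifnot(inherits(params, "pk_params"))
  if (t_end < 0 || step <= 0) stop_pkd("domain", "t_end >= 0 and step > 0 required")
  if (t_end == 0) return(0)
  if (check_tail && predict_concentration(params, t_end) >= 1e-6 * params$M)
    stop_pkd("domain",
             "t_end = %g truncates the tail: C(t_end) >= 1e-6 * M", t_end)
  grid <- seq(0, t_end, by = step)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  y <- predict_concentration(params, grid)
  sum(diff(grid) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Curve-stripping (feathering) initial estimates
#'
#' Classical two-stage initializer for the Bateman fit. The terminal
#' phase — all quantified points at or after twice the time of the
#' observed maximum (at least 3) — gives `Ke` and `ln M` by log-linear
#' regression; the absorption constant comes from regressing the log of
#' the residuals (back-extrapolated elimination line minus observation)
#' over the pre-peak points.
#'
#' @param series A plasma [conc_series].
#' @param dose Dose carried into the returned parameters, mg/kg.
#' @return A [pk_params] suitable as a starting point for
#'   [fit_one_compartment].
#' @export
strip_initial_estimates <- function(series, dose = NA_real_) {
  stopifnot(inherits(series, "conc_series"))
  q <- which(!series$censored)
  t <- series$times[q]; y <- series$values[q]
  if (length(t) < 5)
    stop_pkd("insufficient_data",
             "curve stripping needs >= 5 quantified points, got %d", length(t))
  i_max <- which.max(y)
  t_peak <- t[i_max]
  if (i_max < 3)
    stop_pkd("insufficient_data",
             "need >= 2 quantified points before the observed peak")
  term <- which(t >= 2 * t_peak)
  if (length(term) < 3) term <- utils::tail(seq_along(t), 3)
  if (length(unique(t[term])) < 2)
    stop_pkd("insufficient_data", "terminal phase has no time spread")
  fe <- stats::lm.fit(cbind(1, t[term]), log(y[term]))
  Ke <- -fe$coefficients[2]
  M <- exp(fe$coefficients[1])
  if (!is.finite(Ke) || Ke <= 0)
    stop_pkd("stripping_failed", "terminal phase shows no decay")
  pre <- seq_len(i_max - 1)
  resid <- M * exp(-Ke * t[pre]) - y[pre]
  ok <- which(resid > 0)
  if (length(ok) < 2)
    stop_pkd("stripping_failed",
             "back-extrapolated line does not exceed the pre-peak observations")
  fa <- stats::lm.fit(cbind(1, t[pre][ok]), log(resid[ok]))
  Ka <- -fa$coefficients[2]
  if (!is.finite(Ka) || Ka <= Ke)
    stop_pkd("stripping_failed", "absorption phase regression failed")
  pk_params(unname(M), unname(Ka), unname(Ke), dose)
}

#' Fit the one-compartment absorption model to plasma data
#'
#' Minimizes the weighted residual sum of squares between quantified
#' observations and the Bateman curve over (M, Ka, Ke), with positivity
#' enforced by optimizing on the log scale. Censored (non-detected)
#' points are excluded from the objective, never imputed.
#'
#' The default objective weights each squared residual by `1/C^2`
#' (relative least squares): plasma concentrations span more than an
#' order of magnitude, and proportional-error weighting keeps the
#' terminal phase — which carries all the information about `Ke` — from
#' being swamped by the peak. Unweighted (`"none"`) and `1/C` weighting
#' are selectable; weights use the observed concentrations, so the
#' objective is an ordinary fixed-weights least squares.
#'
#' Optimization runs Nelder-Mead followed by a BFGS polish, each capped
#' at 500 iterations with relative objective tolerance 1e-12; the fit is
#' deterministic for identical inputs.
#'
#' @param series A plasma [conc_series] with >= 4 quantified points.
#' @param init Optional [pk_params] starting values; defaults to
#'   [strip_initial_estimates], falling back to `Ka = 10 Ke` from the
#'   terminal regression when stripping fails (a message is emitted).
#' @param dose Dose in mg/kg, attached to the fitted parameters.
#' @param weighting `"1/C^2"` (default), `"1/C"`, or `"none"`.
#' @return An object of class `pk_fit` with components `params`
#'   ([pk_params]), `derived` ([derive_parameters] output),
#'   `residual_sum_squares` (value of the weighted objective), `n_points`,
#'   `converged`, `iterations`, plus the data used. Standard methods
#'   (`print`, `summary`, `coef`, `predict`, `residuals`, `fitted`,
#'   `plot`, `simulate`) apply.
#' @examples
#' fit <- fit_one_compartment(donkey_plasma()$ABZSO, dose = 7.5)
#' coef(fit)
#' summary(fit)
#' @export
fit_one_compartment <- function(series, init = NULL, dose = NA_real_,
                                weighting = c("1/C^2", "1/C", "none")) {
  stopifnot(inherits(series, "conc_series"))
  weighting <- match.arg(weighting)
  q <- which(!series$censored)
  if (length(q) == 0)
    stop_pkd("insufficient_data", "all points are censored")
  if (length(q) < 4)
    stop_pkd("insufficient_data",
             "need >= 4 quantified points to fit 3 parameters, got %d",
             length(q))
  t <- series$times[q]; y <- series$values[q]
  w <- switch(weighting, "1/C^2" = 1 / y^2, "1/C" = 1 / y, "none" = rep(1, length(y)))

  if (is.null(init)) {
    init <- tryCatch(strip_initial_estimates(series, dose),
      pkd_stripping_failed = function(e) {
        message("curve stripping failed (", conditionMessage(e),
                "); using Ka = 10*Ke heuristic")
        terminal_heuristic_init(t, y, dose)
      },
      pkd_insufficient_data = function(e) terminal_heuristic_init(t, y, dose))
  }
  stopifnot(inherits(init, "pk_params"))

  obj <- function(lp) {
    p <- exp(lp)
    if (abs(p[2] - p[3]) / p[3] < 1e-8) return(1e12)
    sum(w * (y - p[1] * (exp(-p[3] * t) - exp(-p[2] * t)))^2)
  }
  lp0 <- log(c(init$M, init$Ka, init$Ke))
  o1 <- stats::optim(lp0, obj, method = "Nelder-Mead",
                     control = list(maxit = 500, reltol = 1e-12))
  o2 <- stats::optim(o1$par, obj, method = "BFGS",
                     control = list(maxit = 500, reltol = 1e-12))
  p <- exp(o2$par)
  params <- pk_params(p[1], p[2], p[3], dose)
  structure(list(
    params = params,
    derived = derive_parameters(params),
    residual_sum_squares = o2$value,
    n_points = length(q),
    converged = (o1$convergence == 0 || o2$convergence == 0),
    iterations = unname(o1$counts[1] + o2$counts[1]),
    weighting = weighting,
    series = series,
    times = t, observed = y, weights = w
  ), class = "pk_fit")
}

# crude initializer when feathering is impossible: Ke and M from the
# terminal half of the data, Ka set an order of magnitude above Ke
terminal_heuristic_init <- function(t, y, dose) {
  n <- length(t)
  term <- seq.int(max(1, n - max(3, floor(n / 2)) + 1), n)
  fe <- stats::lm.fit(cbind(1, t[term]), log(y[term]))
  Ke <- max(-fe$coefficients[2], 1e-4)
  pk_params(unname(exp(fe$coefficients[1])), 10 * Ke, unname(Ke), dose)
}

#' @export
print.pk_fit <- function(x, ...) {
  cat(sprintf("One-compartment absorption fit: %s in %s\n",
              x$series$analyte, x$series$matrix))
  print(x$params)
  cat(sprintf("  %d quantified points, weighting %s, objective %.4g, %s\n",
              x$n_points, x$weighting, x$residual_sum_squares,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' @export
coef.pk_fit <- function(object, ...) {
  with(object$params, c(M = M, Ka = Ka, Ke = Ke))
}

#' @export
predict.pk_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$times
       else if (is.data.frame(newdata)) newdata$time_h
       else as.numeric(newdata)
  predict_concentration(object$params, t)
}

#' @export
fitted.pk_fit <- function(object, ...) predict_concentration(object$params, object$times)

#' @export
residuals.pk_fit <- function(object, ...) object$observed - fitted(object)

#' @export
summary.pk_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.pk_fit")
}

#' @export
print.summary.pk_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  d <- f$derived
  print(d)
  if (!is.na(f$params$dose) && f$series$analyte != "ABZSO")
    cat("  (Vd/F and CLb are apparent, parent-dose-referenced values)\n")
  invisible(x)
}

#' @export
plot.pk_fit <- function(x, n_grid = 200, ...) {
  tg <- seq(0, max(x$times) * 1.05, length.out = n_grid)
  graphics::plot(x$times, x$observed, xlab = "Time (h)",
                 ylab = "Concentration (ug/mL)",
                 main = sprintf("%s in %s", x$series$analyte, x$series$matrix),
                 ...)
  graphics::lines(tg, predict_concentration(x$params, tg))
  invisible(x)
}

#' @export
simulate.pk_fit <- function(object, nsim = 1, seed = NULL, noise_cv = 0.15,
                            n_animals = 5, ...) {
  cfg <- sim_config(pk_truth = object$params,
                    sample_times_plasma = object$series$times,
                    n_animals = n_animals, noise_cv = noise_cv,
                    seed = if (is.null(seed)) 1L else seed)
  lapply(seq_len(nsim), function(i) {
    cfg$seed <- cfg$seed + i - 1L
    simulate_plasma(cfg, analyte = object$series$analyte)
  })
}
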