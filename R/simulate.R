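# run expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for the synthetic-data generator
#'
#' Defines the ground truth and error structure that the simulated
#' datasets follow: a Bateman plasma curve at the scale of the donkey
#' ABZSO study, mono-exponential tissue depletion with tissue-specific
#' rate constants at the scale of the printed residue tables,
#' multiplicative lognormal inter-animal error, and censoring at the
#' assay detection limits.
#'
#' Defaults: plasma truth (M = 0.73 ug/mL, Ka = 1.04 /h, Ke = 0.054 /h,
#' dose 7.5 mg/kg); tissue truth (C0 in ug/g, k in 1/h) liver (8.0,
#' 0.0225), kidney (5.5, 0.0233), skin (4.0, 0.0135), muscle (5.4,
#' 0.0302), i.e. the total-residue scales of the study tissues; the 14
#' plasma and 11 tissue sampling times of the study; 5 animals per time
#' point; 15% coefficient of variation; the assay LODs per
#' [donkey_lods].
#'
#' @param pk_truth A [pk_params] ground truth for plasma.
#' @param tissue_truth Named list, tissue -> c(C0, k).
#' @param sample_times_plasma,sample_times_tissue Sampling grids, h.
#' @param n_animals Animals per time point.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   lognormal error (>= 0).
#' @param lods Data frame with columns `matrix`, `analyte`, `lod` (see
#'   [donkey_lods]).
#' @param peak_time_h If > 0, tissue curves get a first-order uptake
#'   prefix peaking near this time, so the first samples sit below C0
#'   (exercises [select_depletion_phase]).
#' @param seed Integer seed; every simulation drawn from this config is
#'   reproducible from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(pk_truth = pk_params(0.73, 1.04, 0.054, dose = 7.5),
                       tissue_truth = list(
                         liver = c(C0 = 8.0, k = 0.0225),
                         kidney = c(C0 = 5.5, k = 0.0233),
                         skin = c(C0 = 4.0, k = 0.0135),
                         muscle = c(C0 = 5.4, k = 0.0302)),
                       sample_times_plasma = c(0.25, 0.5, 1, 2, 4, 6, 8, 10,
                                               12, 24, 36, 48, 60, 72),
                       sample_times_tissue = c(4, 8, 12, 24, 48, 72, 96, 120,
                                               144, 168, 240),
                       n_animals = 5, noise_cv = 0.15,
                       lods = donkey_lods(), peak_time_h = 0, seed = 1L) {
  stopifnot(inherits(pk_truth, "pk_params"))
  if (noise_cv < 0) stop_pkd("config", "noise_cv must be >= 0")
  if (n_animals < 1) stop_pkd("config", "n_animals must be >= 1")
  for (tt in tissue_truth)
    if (any(tt <= 0)) stop_pkd("config", "tissue truth parameters must be positive")
  structure(list(pk_truth = pk_truth, tissue_truth = tissue_truth,
                 sample_times_plasma = sample_times_plasma,
                 sample_times_tissue = sample_times_tissue,
                 n_animals = n_animals, noise_cv = noise_cv, lods = lods,
                 peak_time_h = peak_time_h, seed = as.integer(seed)),
            class = "sim_config")
}

lookup_lod <- function(config, analyte, matrix) {
  l <- config$lods
  a <- if (analyte == "total") "ABZSO" else analyte
  hit <- l$lod[l$matrix == matrix & l$analyte == a]
  if (length(hit) == 0) 0 else hit[1]
}

# multiplicative lognormal noise factors, mean-preserving:
# eps ~ N(-s2/2, s2) with s2 = ln(1 + cv^2), so E[exp(eps)] = 1
noise_factors <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, mean = -s2 / 2, sd = sqrt(s2)))
}

# censor a per-animal matrix (animals x times) at lod, then average the
# quantified animals per time; a time is ND only when all animals are ND
mean_with_censoring <- function(vals, lod) {
  cen <- vals < lod
  vals[cen] <- NA_real_
  m <- colMeans(vals, na.rm = TRUE)
  all_cen <- apply(cen, 2, all)
  m[all_cen] <- NA_real_
  list(mean = m, censored = all_cen, n_quant = colSums(!cen))
}

#' Simulate a plasma concentration study
#'
#' Draws per-animal concentrations `C(t) * exp(eps)` around the Bateman
#' truth, with `eps ~ N(-sigma^2/2, sigma^2)`, `sigma^2 = ln(1 +
#' noise_cv^2)` — so the noise is mean-preserving on the arithmetic
#' scale. Values below the LOD become censored markers; the mean series
#' averages quantified animals only and is censored where every animal
#' is below the LOD, matching how such studies tabulate "ND".
#'
#' @param config A [sim_config].
#' @param analyte Analyte label for the output series.
#' @return List with `per_animal` (data frame: animal, time_h, conc,
#'   censored), `mean` (a [conc_series]), and `config`.
#' @examples
#' sim <- simulate_plasma(sim_config(seed = 7))
#' sim$mean
#' @export
simulate_plasma <- function(config, analyte = "ABZSO") {
  stopifnot(inherits(config, "sim_config"))
  tt <- config$sample_times_plasma
  lod <- lookup_lod(config, analyte, "plasma")
  truth <- predict_concentration(config$pk_truth, tt)
  with_seed(config$seed, {
    vals <- matrix(rep(truth, each = config$n_animals) *
                     noise_factors(config$n_animals * length(tt), config$noise_cv),
                   nrow = config$n_animals)
    agg <- mean_with_censoring(vals, lod)
    per_animal <- data.frame(
      animal = rep(seq_len(config$n_animals), times = length(tt)),
      time_h = rep(tt, each = config$n_animals),
      conc = as.vector(ifelse(vals < lod, NA_real_, vals)),
      censored = as.vector(vals < lod))
    list(per_animal = per_animal,
         mean = conc_series(analyte, "plasma", tt, agg$mean, agg$censored,
                            lod = lod, n_animals = config$n_animals),
         config = config)
  })
}

#' Simulate tissue residue depletion studies
#'
#' Mono-exponential decay `C0 exp(-k t)` per tissue with the same
#' mean-preserving lognormal error and LOD censoring as
#' [simulate_plasma]. With `peak_time_h > 0` the curve is multiplied by
#' a first-order uptake term `1 - exp(-3 t / peak_time_h)` so early
#' samples rise toward a peak before depleting.
#'
#' @param config A [sim_config].
#' @param analyte Analyte label for the output series (default
#'   `"total"`).
#' @return Named list of [conc_series], one mean series per tissue in
#'   `config$tissue_truth`.
#' @export
simulate_tissue <- function(config, analyte = "total") {
  stopifnot(inherits(config, "sim_config"))
  tt <- config$sample_times_tissue
  with_seed(config$seed, {
    out <- list()
    for (tis in names(config$tissue_truth)) {
      th <- config$tissue_truth[[tis]]
      truth <- th[["C0"]] * exp(-th[["k"]] * tt)
      if (config$peak_time_h > 0)
        truth <- truth * (1 - exp(-3 * tt / config$peak_time_h))
      lod <- lookup_lod(config, analyte, tis)
      vals <- matrix(rep(truth, each = config$n_animals) *
                       noise_factors(config$n_animals * length(tt), config$noise_cv),
                     nrow = config$n_animals)
      agg <- mean_with_censoring(vals, lod)
      out[[tis]] <- conc_series(analyte, tis, tt, agg$mean, agg$censored,
                                lod = lod, n_animals = config$n_animals)
    }
    out
  })
}

#' Parameter-recovery experiment
#'
#' Runs simulate -> fit -> derive over seeded replicates and summarizes
#' how well the analysis pipeline recovers the generating parameters.
#' Plasma mode refits the Bateman model to each simulated mean curve and
#' reports bias and median absolute relative error for M, Ka, Ke and
#' AUC. Tissue mode refits the log-linear depletion per tissue (and,
#' when `mrl` is given, computes the per-replicate withdrawal time).
#' Replicates whose fit fails are counted, never fatal.
#'
#' @param config A [sim_config]; replicate r uses seed `seed + r - 1`.
#' @param n_reps Number of replicates (>= 1).
#' @param what `"plasma"` or `"tissue"`.
#' @param mrl Optional named vector tissue -> MRL for withdrawal-time
#'   recovery in tissue mode.
#' @return An object of class `recovery_report`: `summary` (data frame
#'   per parameter: truth, mean_rel_error, median_abs_rel_error),
#'   `n_reps`, `n_failed`, `estimates` (per-replicate draws), and in
#'   tissue mode with `mrl` a `wdt_days` table per tissue.
#' @export
recovery_experiment <- function(config, n_reps, what = c("plasma", "tissue"),
                                mrl = NULL) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  what <- match.arg(what)
  n_failed <- 0L
  if (what == "plasma") {
    truth <- c(M = config$pk_truth$M, Ka = config$pk_truth$Ka,
               Ke = config$pk_truth$Ke,
               auc = derive_parameters(config$pk_truth)$auc)
    est <- matrix(NA_real_, n_reps, 4, dimnames = list(NULL, names(truth)))
    for (r in seq_len(n_reps)) {
      cfg <- config; cfg$seed <- config$seed + r - 1L
      sim <- simulate_plasma(cfg)
      fit <- tryCatch(fit_one_compartment(sim$mean, dose = config$pk_truth$dose),
                      pkd_error = function(e) NULL)
      if (is.null(fit) || !fit$converged) { n_failed <- n_failed + 1L; next }
      est[r, ] <- c(coef(fit), fit$derived$auc)
    }
    rel <- sweep(sweep(est, 2, truth), 2, truth, "/")
    summ <- data.frame(
      parameter = names(truth), truth = unname(truth),
      mean_rel_error = colMeans(rel, na.rm = TRUE),
      median_abs_rel_error = apply(abs(rel), 2, stats::median, na.rm = TRUE),
      row.names = NULL)
    wdt <- NULL
  } else {
    tissues <- names(config$tissue_truth)
    truth <- vapply(config$tissue_truth, function(x) x[["k"]], 0)
    est <- matrix(NA_real_, n_reps, length(tissues),
                  dimnames = list(NULL, tissues))
    wdt <- matrix(NA_integer_, n_reps, length(tissues),
                  dimnames = list(NULL, tissues))
    for (r in seq_len(n_reps)) {
      cfg <- config; cfg$seed <- config$seed + r - 1L
      sims <- simulate_tissue(cfg)
      for (tis in tissues) {
        fit <- tryCatch(fit_depletion(sims[[tis]], select = TRUE),
                        pkd_error = function(e) NULL)
        if (is.null(fit)) { n_failed <- n_failed + 1L; next }
        est[r, tis] <- fit$k
        if (!is.null(mrl) && tis %in% names(mrl)) {
          res <- tryCatch(withdrawal_time(fit, mrl[[tis]]),
                          pkd_error = function(e) NULL)
          if (!is.null(res)) wdt[r, tis] <- res$wdt_days
        }
      }
    }
    rel <- sweep(sweep(est, 2, truth), 2, truth, "/")
    summ <- data.frame(
      parameter = paste0("k_", tissues), truth = unname(truth),
      mean_rel_error = colMeans(rel, na.rm = TRUE),
      median_abs_rel_error = apply(abs(rel), 2, stats::median, na.rm = TRUE),
      row.names = NULL)
  }
  structure(list(summary = summ, n_reps = n_reps, n_failed = n_failed,
                 estimates = est, wdt_days = wdt, what = what),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat(sprintf("Parameter recovery (%s), %d replicates, %d failed fits\n",
              x$what, x$n_reps, x$n_failed))
  print(x$summary, digits = 3, row.names = FALSE)
  if (!is.null(x$wdt_days)) {
    cat("Withdrawal-time (days) distribution per tissue:\n")
    for (tis in colnames(x$wdt_days)) {
      tab <- table(x$wdt_days[, tis])
      if (length(tab))
        cat(sprintf("  %-8s %s\n", tis,
                    paste(sprintf("%sd:%d", names(tab), tab), collapse = "  ")))
    }
  }
  invisible(x)
}
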