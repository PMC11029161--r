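test_that("tolerance factor matches an external noncentral-t computation", {
  # frozen from scipy.stats.nct.ppf(0.95, 8, qnorm(0.95)/sqrt(0.1)) * sqrt(0.1)
  expect_equal(tolerance_factor(n = 10, d = 0.1), 3.0117120228, tolerance = 1e-8)
  # symmetric null case: median-of-median bound collapses toward zero
  expect_lt(abs(tolerance_factor(n = 200, percentile = 0.5, confidence = 0.5,
                                 d = 0.05)), 0.01)
  expect_error(tolerance_factor(2, d = 0.1), class = "pkd_domain")
  expect_error(tolerance_factor(10, percentile = 1, d = 0.1), class = "pkd_domain")
  expect_error(tolerance_factor(10, d = 0), class = "pkd_domain")
})

test_that("tolerance factor increases with percentile and confidence", {
  for (d in c(0.05, 0.1, 0.5)) {
    ks <- sapply(c(0.8, 0.9, 0.95, 0.99), function(g)
      tolerance_factor(10, 0.95, g, d))
    expect_true(all(diff(ks) > 0))
    kp <- sapply(c(0.5, 0.75, 0.9, 0.95, 0.99), function(p)
      tolerance_factor(10, p, 0.95, d))
    expect_true(all(diff(kp) > 0))
    expect_gt(tolerance_factor(10, 0.95, 0.95, d), 0)  # bound above mean line
  }
})

test_that("the factor delivers its nominal confidence (Monte-Carlo check)", {
  # ybar ~ N(mu, d s2), s^2 ~ s2 chi2_df/df: the bound ybar + K s should
  # exceed mu + z_p * s with probability = confidence
  set.seed(77)
  n <- 10; d <- 0.1; df <- n - 2
  K <- tolerance_factor(n, 0.95, 0.95, d)
  m <- 40000
  yhat <- rnorm(m, 0, sqrt(d))
  s <- sqrt(rchisq(m, df) / df)
  cover <- mean(yhat + K * s >= qnorm(0.95))
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
})

test_that("zero-scatter withdrawal reduces to the analytic line crossing", {
  t <- c(4, 24, 48, 96, 168)
  fit <- depletion_from_points(t, 8 * exp(-0.02 * t))
  res <- withdrawal_time(fit, mrl = 5)
  # exact crossing 23.50 h, located to the 0.01 h bisection tolerance
  expect_lt(abs(res$crossing_time_h - log(8 / 5) / 0.02), 0.011)
  expect_identical(res$wdt_days, 1L)
})

test_that("liver total residues against the 5 ug/g limit give a 3-day withdrawal", {
  fit <- fit_depletion(donkey_residues("liver")$total, select = TRUE)
  res <- withdrawal_time(fit, mrl = 5)
  expect_identical(res$wdt_days, 3L)
  expect_gt(res$crossing_time_h, 48)
  expect_lte(res$crossing_time_h, 72)
})

test_that("crossing time is monotone in MRL, scatter, percentile and confidence", {
  liver <- fit_depletion(donkey_residues("liver")$total, select = TRUE)
  r1 <- withdrawal_time(liver, 5); r2 <- withdrawal_time(liver, 10)
  expect_lt(r2$crossing_time_h, r1$crossing_time_h)

  set.seed(99)
  for (i in 1:10) {
    t <- sort(sample(4:240, 8))
    k <- runif(1, 0.01, 0.05)
    C0 <- runif(1, 4, 10)
    y <- C0 * exp(-k * t) * exp(rnorm(8, 0, 0.25))
    fit <- depletion_from_points(t, y)
    mrl <- runif(1, 0.2, 2)
    base <- withdrawal_time(fit, mrl)$crossing_time_h
    # inflate the scatter, keep the line
    fat <- fit; fat$residual_sd <- fit$residual_sd * 2 + 0.1
    class(fat) <- "depletion_fit"
    expect_gte(withdrawal_time(fat, mrl)$crossing_time_h, base - 0.011)
    expect_gte(withdrawal_time(fit, mrl, percentile = 0.99)$crossing_time_h,
               base - 0.011)
    expect_gte(withdrawal_time(fit, mrl, confidence = 0.99)$crossing_time_h,
               base - 0.011)
    expect_lte(withdrawal_time(fit, mrl * 2)$crossing_time_h, base + 0.011)
  }
})

test_that("as scatter vanishes the tolerance crossing approaches the line crossing", {
  t <- c(4, 24, 48, 96, 168)
  base <- depletion_from_points(t, 8 * exp(-0.025 * t))
  analytic <- log(8 / 0.5) / 0.025
  for (s in c(0.2, 0.05, 0.01, 0.001)) {
    fit <- base; fit$residual_sd <- s; class(fit) <- "depletion_fit"
    res <- withdrawal_time(fit, 0.5)
    expect_gt(res$crossing_time_h, analytic - 0.011)
  }
  fit <- base; fit$residual_sd <- 1e-4
  expect_equal(withdrawal_time(fit, 0.5)$crossing_time_h, analytic,
               tolerance = 0.01)
})

test_that("95/95 bound covers the true 95th percentile at the crossing time", {
  set.seed(2024)
  tt <- c(4, 8, 12, 24, 48, 72, 96, 120, 144, 168)
  C0 <- 8; k <- 0.0225; sig <- 0.3; mrl <- 5
  hits <- 0; n_ok <- 0
  for (i in 1:500) {
    y <- C0 * exp(-k * tt) * exp(rnorm(10, 0, sig))
    fit <- depletion_from_points(tt, y)
    res <- tryCatch(withdrawal_time(fit, mrl), pkd_error = function(e) NULL)
    if (is.null(res)) next
    n_ok <- n_ok + 1
    # at the crossing the bound equals ln(mrl); compare with the true
    # 95th percentile of ln-residue at that same time
    true95 <- log(C0) - k * res$crossing_time_h + qnorm(0.95) * sig
    if (log(mrl) >= true95 - 1e-9) hits <- hits + 1
  }
  expect_gt(n_ok, 450)
  expect_gte(hits / n_ok, 0.90)
})

test_that("muscle withdrawal sits at or beyond the data's own 0.1 ug/g crossing", {
  fit <- fit_depletion(donkey_residues("muscle")$total, select = TRUE)
  res <- withdrawal_time(fit, mrl = 0.1)
  # printed series crosses 0.1 between 96 and 120 h; the tolerance bound
  # can only push the crossing later
  expect_gt(res$crossing_time_h, 96)
})

test_that("no-crossing and domain failures are reported as such", {
  t <- c(4, 24, 48, 96, 168)
  # scatter so large relative to the slope that the bound never comes down
  fit <- depletion_from_points(t, 50 * exp(-0.0005 * t))
  fit$residual_sd <- 2
  expect_error(withdrawal_time(fit, 0.001, horizon_h = 2000),
               class = "pkd_no_crossing")
  good <- depletion_from_points(t, 8 * exp(-0.02 * t))
  expect_error(withdrawal_time(good, -5), class = "pkd_domain")
})

test_that("report aggregates tissues and treats unlimited tissues descriptively", {
  fits <- lapply(c(liver = "liver", kidney = "kidney", muscle = "muscle",
                   skin = "skin"),
                 function(tis) fit_depletion(donkey_residues(tis)$total,
                                             select = TRUE))
  spec <- mrl_spec(limits = c(muscle = 0.1, liver = 5, kidney = 5))
  rep <- wdt_report(fits, spec)
  per <- vapply(rep$results[c("muscle", "liver", "kidney")],
                function(r) r$wdt_days, 1L)
  expect_identical(rep$overall_wdt_days, max(per))
  expect_true(is.na(rep$results$skin$wdt_days))       # no MRL for skin

  empty <- wdt_report(fits, mrl_spec(limits = numeric(0)))
  expect_identical(empty$results, list())

  expect_error(wdt_report(fits["liver"], spec), class = "pkd_config")
})
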