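# shared helpers: independent oracles kept deliberately simple-minded

# noise-free Bateman series sampled at the plasma study times
bateman_series <- function(params, times = c(0.25, 0.5, 1, 2, 4, 6, 8, 10,
                                             12, 24, 36, 48, 60)) {
  vals <- params$M * (exp(-params$Ke * times) - exp(-params$Ka * times))
  conc_series("ABZSO", "plasma", times, vals, lod = 1e-9)
}

# closed-form simple linear regression via explicit normal equations
ols_oracle <- function(t, lny) {
  n <- length(t)
  sx <- sum(t); sy <- sum(lny); sxx <- sum(t * t); sxy <- sum(t * lny)
  b <- (n * sxy - sx * sy) / (n * sxx - sx * sx)
  a <- (sy - b * sx) / n
  res <- lny - (a + b * t)
  list(intercept = a, slope = b,
       sigma = sqrt(sum(res^2) / (n - 2)),
       t_mean = sx / n, s_xx = sxx - sx^2 / n)
}

# a depletion_fit built from raw (t, y) pairs, through the package path
depletion_from_points <- function(t, y, tissue = "liver") {
  fit_depletion(conc_series("total", tissue, t, y, lod = 1e-9))
}

reference_abzso <- function() pk_params(0.73, 1.04, 0.054, dose = 7.5)
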