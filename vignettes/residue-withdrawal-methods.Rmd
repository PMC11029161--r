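---
title: "Methods: one-compartment kinetics, residue depletion and withdrawal times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: one-compartment kinetics, residue depletion and withdrawal times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pkdeplete)
```

This vignette documents the models the package fits, the statistical
construction behind its withdrawal-time estimates, the design choices that
were genuinely open, and what the bundled simulations do and do not
demonstrate. The running example is the bundled donkey study of albendazole
sulphoxide (ABZSO) given intramuscularly at 7.5 mg/kg: single dose for the
plasma kinetics, three daily doses for the tissue residues.

## The plasma model

After extravascular dosing, plasma concentration is modelled by the
one-compartment open model with first-order absorption and elimination (the
Bateman curve):

$$C(t) = M\left(e^{-K_e t} - e^{-K_a t}\right)$$

with $M$ the zero-time intercept of the back-extrapolated elimination phase
(µg/mL), $K_a$ the absorption and $K_e$ the elimination rate constant
(1/h). The model assumes a single well-mixed compartment, first-order
transfer in and out, and $K_a \neq K_e$; the coincident-rate limit
$M K t e^{-Kt}$ is deliberately not substituted — inputs within a relative
$10^{-8}$ of degeneracy are rejected so that every downstream closed form
(AUC, $T_{max}$) is well defined.

All secondary parameters follow in closed form: half-lives $\ln 2 / K_a$
and $\ln 2 / K_e$; the stationary point
$T_{max} = \ln(K_a/K_e)/(K_a - K_e)$ with $C_{max} = C(T_{max})$; exposure
$AUC_{0\to\infty} = M(1/K_e - 1/K_a)$; the apparent distribution volume
$V_d/F = X_0 / (AUC \cdot K_e)$ for dose $X_0$; and clearance
$CL_b = (V_d/F)\,K_e$. With the dose in mg/kg and AUC in µg/mL·h
(numerically equal to mg/L·h), the mass and volume prefixes cancel and
$V_d/F$ comes out directly in L/kg — no conversion constant appears in the
code, and `cl_b * auc = dose` holds to round-off as a unit sanity check.

Half-lives use $\ln 2$. Older desk calculations print the rounded constant
0.693; a `printed_constants` switch reproduces that convention exactly, and
the difference (about 0.02%) is far below every tolerance used here.

## Fitting: objective, weighting, initial values

The fit minimizes a weighted sum of squared residuals over quantified
points only; non-detected (ND) observations are excluded, never imputed,
because in the plasma tables censoring occurs only at the leading and
trailing ends where imputation would bias $K_e$.

Weighting was a genuinely open choice and the default is **relative least
squares** ($1/C^2$ weights on the observed concentrations). The
concentrations span more than an order of magnitude, and an unweighted
objective lets the absorption peak dominate: on the bundled ABZSO mean
curve, unweighted least squares converges to $K_e = 0.097$/h, nearly twice
the study's reported 0.054/h, whereas the $1/C^2$ objective recovers
0.0528/h and an AUC within 5% of the reported 12.81 µg/mL·h. Proportional
error is also the standard assumption for chromatographic concentration
assays. Unweighted and $1/C$ objectives remain selectable
(`weighting = "none"`, `"1/C"`), and at zero residuals all three coincide,
which the noise-free recovery tests exploit.

Positivity of $(M, K_a, K_e)$ is enforced by optimizing on the log scale.
Starting values come from classical curve stripping (feathering): a
log-linear regression of the terminal points — all quantified points at or
after twice the time of the observed peak, minimum three — yields $K_e$ and
$\ln M$; regressing the log of the back-extrapolated-minus-observed
residuals over pre-peak points yields $K_a$. When stripping fails (no
positive residuals before the peak), a $K_a = 10 K_e$ heuristic from the
terminal regression is used and a message is emitted. Optimization runs
Nelder–Mead then a BFGS polish, each capped at 500 iterations with relative
objective tolerance $10^{-12}$; the procedure is deterministic, and
restarting from a fitted optimum never worsens the objective.

A note on what "agreement with the study" can mean: the study reports
*means of five per-animal fits*, while only the mean concentration curve is
printed. A fit to the mean curve is not the mean of fits, so the package's
tests expect tight agreement only for the closed-form secondary parameters
computed *from* the reported primary triple, and loose (25%) agreement for
refits of the printed mean curves.

## Tissue depletion

Post-peak residues in each edible tissue are modelled as first-order decay,
$C(t) = C_0 e^{-kt}$, fitted by ordinary least squares of $\ln C$ on time
(`stats::lm`). The depletion phase starts at the observed maximum
(inclusive); tissues in this design peak at the first or second sampling
time and no uptake model is attempted. The fit retains the design summaries
needed later: $\bar t$, $S_{xx} = \sum (t_i - \bar t)^2$, and the residual
standard deviation with the $n-2$ denominator.

The regulatory marker for albendazole is the *sum* of ABZSO, its sulfone
and its 2-aminosulfone. Sums treat ND components as zero — this reproduces
the printed total columns exactly wherever a component is ND — and a time
point is censored in the total only when every component is. Printed total
columns are kept as transcribed and *cross-checked*, not recomputed: the
kidney table's totals at 4 h and 8 h disagree with their own components by
0.16 and 0.03 µg/g, and the package flags (threshold 0.02 µg/g) rather than
reconciles such rows.

## Withdrawal time

The withdrawal time (WDT) answers: from what time on are residues below the
maximum residue limit (MRL) for the stated share of the population, with
the stated confidence? Following the standard approach of regulatory
withdrawal-period calculators, the package places a one-sided upper
tolerance limit on the log-linear depletion regression. At prediction time
$t$ with leverage $d = 1/n + (t - \bar t)^2 / S_{xx}$, the exact (Owen)
construction gives

$$U(t) = \hat a + \hat b\,t + K(t)\,s, \qquad
  K(t) = \sqrt{d}\; t'_{n-2,\; z_p/\sqrt d}(\gamma),$$

where $t'_{\nu,\delta}(\gamma)$ is the $\gamma$-quantile of the noncentral
$t$ distribution (via `stats::qt(ncp = )`), $z_p$ the standard-normal
quantile of the bounded percentile $p$ (default 0.95) and $\gamma$ the
confidence (default 0.95). The WDT is the earliest $t$ with
$U(t) \le \ln(\text{MRL})$, found by a coarse scan plus bisection to
0.01 h, then rounded **up** to whole days. With zero residual scatter the
bound collapses onto the regression line and the crossing is the analytic
$\ln(C_0/\text{MRL})/k$. The bound is eventually decreasing whenever
$k > s\,t_{\gamma,n-2}/\sqrt{S_{xx}}$; otherwise no crossing exists within
the 10 000 h search horizon and an explicit no-crossing error is raised —
a flat, noisy series should not silently yield a withdrawal time.

Two documented deviations from per-animal regulatory practice are forced
by the available data. First, each printed per-time *mean* enters the
regression as a single observation (individual animals are not published),
so $n$ in the tolerance factor is the number of mean points — the bound is
therefore a tolerance limit on mean curves, not on individual animals, and
is anti-conservative in that respect. Second, the MRL map follows the
Chinese national limits (liver and kidney 5 µg/g, muscle and fat 0.1 µg/g);
skin, the commercially decisive donkey tissue, carries no limit and is
reported descriptively only. On the bundled data the liver total-residue
series against its 5 µg/g limit crosses at 70.4 h → 3 days, matching the
study's reported withdrawal time; the muscle series against 0.1 µg/g
crosses much later (≈179 h → 8 days), so the *overall* maximum across
limited tissues exceeds the study's headline figure — the package reports
both rather than choosing.

## Synthetic data and what it shows

The generator emulates the study's statistical structure: Bateman plasma
curves and mono-exponential tissue decay at the scale of the study's
parameters, sampled at the study's 14 plasma and 11 tissue time points,
5 animals per point, multiplicative lognormal inter-animal error, and
censoring at the assay LODs (0.01 µg/mL plasma, 0.02–0.05 µg/g tissue). The
error is mean-preserving: $\varepsilon \sim N(-\sigma^2/2, \sigma^2)$ with
$\sigma^2 = \ln(1 + \text{CV}^2)$, so $E[e^{\varepsilon}] = 1$ and the
expected simulated concentration equals the model value. The default CV of
15% was chosen once to match the magnitude of the printed per-time SDs
relative to their means (roughly 10–30%) and is not a fitted quantity —
the study publishes no inter-animal variance structure beyond those SDs.
Lognormal multiplicative error was preferred over additive error because
additive noise at this scale produces negative concentrations at late
times. A per-time mean is marked ND only when *all* simulated animals fall
below the LOD, matching how such studies tabulate means. All draws are
reproducible from the configuration seed, and the caller's RNG stream is
left untouched.

What passing recovery tests demonstrate: the estimator chain (censor →
average → strip → fit → derive; or censor → phase-select → regress →
tolerance bound) recovers its own generating parameters under the stated
error model — e.g. median $|{\Delta K_e}/K_e|$ ≈ 1% over 200 replicates at
the default settings, tissue half-life orderings preserved in ≥ 95% of
replicates, and 95/95 bound coverage ≈ 96% over 500 simulated studies.
What they do not show: robustness to model misspecification (biphasic
depletion, correlated residuals, assay drift), per-animal heterogeneity in
rate constants, or anything about matrices and species beyond the fixture
scales.

## Numerical choices, in one place

- Degeneracy guard: $|K_a - K_e|/K_e < 10^{-8}$ → error, everywhere.
- PK objective: fixed observed-concentration weights; log-parameterized;
  Nelder–Mead (≤ 500 iterations) then BFGS (≤ 500), reltol $10^{-12}$.
- Depletion: OLS on $\ln C$, residual SD with $n-2$ denominator.
- Tolerance bound: exact noncentral-$t$ quantile, no Satterthwaite or
  large-$n$ approximation; bisection tolerance 0.01 h; horizon 10 000 h.
- Rounding: WDT is always the ceiling in whole days; an exact multiple of
  24 h stays at its day, anything beyond rounds up.
- Problem sizes in the test suite: 100 seeded parameter draws for the
  AUC closed-form/trapezoid cross-check (relative $10^{-4}$), 200
  replicates for plasma recovery and tissue orderings, 500 simulated
  studies for bound coverage, 40 000 draws for the tolerance-factor
  Monte-Carlo check — sizes chosen so each property estimate is stable to
  well within its asserted margin.

## Known limitations

- Means-as-observations (above) understates between-animal variance in the
  tolerance bound; with per-animal residue data the same code applies
  unchanged with one row per animal and time.
- The metabolite's $V_d/F$ and $CL_b$ are *apparent, parent-dose-referenced*
  quantities: a metabolite has no dose of its own, so these reproduce the
  study's convention and are labelled as such in reports.
- Closed-form reproduction of every published secondary parameter from the
  published primary triple is not exactly possible: quantities the study
  derived from separately averaged per-animal values (notably the
  metabolite clearance) differ by a few percent from the closed forms on
  the mean triple. The tests document the one case outside 2% instead of
  relaxing the check.
- No nonparametric (NCA) analysis, multi-compartment models, covariate
  models or safe-concentration derivation; percentile and confidence are
  exposed so other jurisdictions' settings (e.g. 99/95) can be requested,
  but no jurisdiction-specific presets are shipped.
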