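---
title: "Methods: simulation-based evaluation of darunavir limited sampling strategies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation-based evaluation of darunavir limited sampling strategies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drvoss)
```

## The model

drvoss implements a fixed-parameter population pharmacokinetic analysis of
ritonavir- or cobicistat-boosted darunavir. The structural model is a
one-compartment model with first-order absorption and first-order
elimination, evaluated directly at steady state for repeated oral dosing of
dose $D$ every $\tau$ hours:

$$
C(t) = \frac{D\,k_a}{V\,(k_a - k_e)}\left[
  \frac{e^{-k_e t'}}{1-e^{-k_e\tau}} -
  \frac{e^{-k_a t'}}{1-e^{-k_a\tau}}\right],
\qquad k_e = \mathrm{CL}/V,\quad t' = t \bmod \tau .
$$

All disposition parameters are apparent oral parameters (CL/F, V/F):
bioavailability is not separately identifiable and is absorbed into them.
When $|k_a-k_e| < 10^{-8}\,\mathrm{h^{-1}}$ the analytic equal-rates limit
is substituted; the two branches agree to well beyond six significant
digits at the switch point.

Individual parameters combine proportional covariate effects with
log-normal inter-individual variability (IIV):

$$
\mathrm{CL}_i = \mathrm{CL}_{pop}(1+\theta_{sex}\,\mathrm{female}_i)
 (1+\theta_{CYP3A5}\,\mathrm{cyp}_i)\,e^{\eta_{1i}},\quad
V_i = V_{pop}(1+\theta_{SLCO3A1}\,\mathrm{slc}_i)\,e^{\eta_{2i}},\quad
k_{a,i} = k_{a,pop}\,e^{\eta_{3i}},
$$

with independent $\eta_{ki} \sim N(0, \omega_k^2)$ (no correlations are
part of the model). Residual error is combined exponential plus additive:
an observed concentration is $y = C\,e^{\varepsilon_1} + \varepsilon_2$
with $\varepsilon_1\sim N(0,\sigma_{exp}^2)$,
$\varepsilon_2\sim N(0,\sigma_{add}^2)$.

The default parameter set (`drv_parameters()`) is the published
learning-cohort estimate of the reduced model (the variant without the
alpha-1 acid glycoprotein covariate): CL/F 12.6 L/h, V/F 137 L,
$k_a$ 0.545 /h, $\theta_{sex} = -0.198$, $\theta_{CYP3A5} = -0.192$ (on
CL), $\theta_{SLCO3A1} = 0.991$ (on V), $\omega$ = 0.238/0.353/0.575,
$\sigma_{exp}$ = 0.306, $\sigma_{add}$ = 0.611 mg/L. Any other set can be
supplied programmatically or loaded from YAML/JSON
(`read_parameters()`).

### Covariate coding assumptions

The source analyses report only the magnitudes of the covariate
coefficients, not the functional form or the genotype reference groups.
drvoss adopts proportional effects $TV\,(1+\theta\,x)$ with $x$ a 0/1
indicator — a value like $-0.198$ then reads naturally as $-19.8\%$ — and
codes `cyp3a5_flag = 1` for \*3/\*3 homozygotes (CYP3A5 non-expressers,
reference \*1 carriers) and `slco3a1_flag = 1` for rs8027174 T-allele
carriers (GT/TT, reference GG). Both codings are assumptions and both the
coefficients and the indicator assignments can be changed through the
parameter object and the covariate columns. Because the downstream
strategy metrics depend on the covariates only through the mild spread
they add to the typical values, switching to an exponential coding
$TV\,e^{\theta x}$ perturbs the strategy metrics by well under the
Monte-Carlo tolerance (the factor differs by at most
$e^{-0.198}/0.802 \approx 2\%$ per covariate).

## The synthetic population

No subject-level data are shipped or downloaded; every analysis runs on
virtual subjects from `sample_covariates()`. The generator reproduces the
learning cohort's frequencies: 33.1% women; CYP3A5 \*1/\*1 26.0%,
\*1/\*3 26.0%, \*3/\*3 45.7%, missing 2.4%; SLCO3A1 GG 82.7%, GT 14.2%,
missing 3.1%; race Caucasian 52.8% / African 43.3% / other 3.9%; regimens
600 mg q12h 7.9%, 800 mg q24h 91.3%, 1200 mg q24h 0.8%. Printed
percentages carry rounding (the CYP3A5 column sums to 100.1%), so each
categorical distribution is renormalized exactly at construction. Missing
genotypes are imputed with the most frequent observed genotype among
generated subjects of the same race, mirroring the handling used for the
sparse clinical cohort.

This frequency resampling is the main approximation relative to the
original analysis, which conditioned on the actual 127 covariate vectors:
passing tests therefore demonstrate reproduction of the published
strategy metrics under a covariate-exchangeable population, not on the
original subjects. The generator also does not emulate alpha-1 acid
glycoprotein (dropped from the validated model), adherence patterns, or
between-occasion variability (none is part of the model).

Sparse "therapeutic drug monitoring"-like datasets
(`sample_validation_like()`) place one sample per subject at a random
post-intake time. The sparse cohort reports only the median and range of
post-intake delays; a right-skewed truncated log-normal is used, with
$\mu = \log(\mathrm{median})$ and $\sigma$ solved from
$P(X \le \mathrm{max}) = 0.975$ before truncation: median 14.8 h on
[2, 31.5] for q24h and 13.7 h on [2, 25.8] for q12h. Delays beyond the
dosing interval (a delayed next intake) are evaluated on the periodic
steady-state profile. Simulated observations are floored at 0.001 mg/L —
below any plausible assay quantification limit for darunavir — rather
than redrawn, as the least distorting way to keep concentrations
physical; whether the original simulations floored or redrew negatives is
unstated.

Every generator is a pure function of its seed. In
`simulate_profiles()` the random-effect draws consume the RNG stream
before any residual-error draws (which use a derived sub-stream), so runs
that differ only in sampling times share identical parameter draws. This
pairs strategy comparisons (common random numbers), which
`compare_strategies(common_random = FALSE)` can disable.

## MAP estimation

Individual parameters are estimated as the empirical-Bayes mode: the
minimizer over $\eta$ of

$$
O(\eta) = \sum_i\left[\frac{(y_i - f_i(\eta))^2}{g_i(\eta)}
  + \ln g_i(\eta)\right] + \sum_k \frac{\eta_k^2}{\omega_k^2},
\qquad g_i = f_i^2\sigma_{exp}^2 + \sigma_{add}^2 .
$$

The likelihood uses the variance-linearized Gaussian approximation of the
combined error (the convention of mixed-effects estimation software); the
exact log-normal-plus-normal convolution has no closed form, and the
simulator deliberately uses the exact form while the estimator uses the
approximation, mirroring common practice. All three random effects are
estimated jointly even when only clearance feeds the AUC, because V and
$k_a$ shape the prediction at early sampling times; components with
$\omega_k = 0$ are fixed at zero. With no observations the prior mode
$\eta = 0$ is returned.

`map_estimate()` is the reference path: BFGS from $\eta = 0$, gradient
tolerance $10^{-6}$, a positive-definiteness check of the Hessian at the
solution, and a 5-point random multistart fallback otherwise (ties broken
by objective, then by $\lVert\eta\rVert$). `map_fit()` runs all
subject-replicate groups of a dataset simultaneously through a vectorized
damped Gauss-Newton solver (steps accepted per group only when the
objective decreases, so descent never relies on the Hessian approximation
being exact) and re-fits any group it cannot converge with the reference
path. The two paths agree to $10^{-6}$ in the objective on random sparse
datasets, and a dense two-stage grid search over $\pm4\omega$ (0.04-step
global pass, 0.01-step refinement) bounds the optimum independently of
either optimizer. AUC is derived as daily dose over the clearance
estimate, $\mathrm{AUC}_{24} = D \cdot (24/\tau) / \widehat{\mathrm{CL}}$.

## Strategy evaluation

`evaluate_strategy()` reproduces the Monte-Carlo protocol behind the
published strategy table: 127 synthetic subjects, 250 replicate profiles
each (fresh $\eta$ per replicate), observation at the strategy's times,
MAP estimation, and comparison of $\mathrm{AUC}_{OSS}$ with
$\mathrm{AUC}_{ref} = D_{daily}/\mathrm{CL}_{true}$ through
$\mathrm{PE} = (\mathrm{AUC}_{ref}-\mathrm{AUC}_{OSS})/\mathrm{AUC}_{ref}$,
$\mathrm{MPE} = 100\%\cdot\overline{\mathrm{PE}}$,
$\mathrm{RMSPE} = 100\%\cdot\sqrt{\overline{\mathrm{PE}^2}}$, Spearman's
$\rho$ (average ranks), and the proportion with
$|\mathrm{PE}| \le 0.15$ — inclusive, as the boundary convention is
unstated — overall and restricted to reference exposures in the
clinically typical 50-130 mg·h/L window. All replicates are pooled into
one metric vector. For q12h subjects the strategy times are hours after
the morning dose evaluated on the periodic q12h profile, since sampling
times are constrained to be identical across subjects; a pre-dose sample
(t = 0) is the steady-state trough.

A deliberate and load-bearing choice: by default the evaluated
observations are the model-predicted concentrations at the strategy times
*without* residual error (`observation_noise = FALSE`), while the
estimation step retains the full combined-error variance. The published
strategy metrics are only consistent with this protocol. Two independent
lines of evidence: (i) the linearized posterior standard deviation of
$\log \mathrm{CL}$ for the three-point design 1/4/19 h is 0.172 under the
shipped error magnitudes, so an RMSPE near 12% is unattainable when
measurement noise is added to three samples (simulated: ~17.5%, and the
bias flips sign); (ii) with noise-free observations every published row —
$\rho$, MPE including its sign, RMSPE, and the within-15% percentages —
is matched within the Monte-Carlo/covariate-resampling tolerance for all
eight strategies. With `observation_noise = TRUE` the package evaluates
the practically relevant variant in which assay noise degrades all
strategies (roughly five RMSPE points here).

## D-optimal design

`fo_fim()` assembles the first-order (FO) Fisher information matrix of a
design: the model is linearized in $\eta$ around zero, giving a marginal
normal approximation with mean $f(t;\theta)$ and covariance
$V = A\,\Omega\,A^{\top} + \mathrm{diag}(g)$, $A = \partial f/\partial\eta$.
The reduced (block-diagonal) FIM is used — the default of standard design
software: the fixed-effect block is $J^{\top}V^{-1}J$ and variance
parameters contribute
$\tfrac12\,\mathrm{tr}(V^{-1}\partial_i V\,V^{-1}\partial_j V)$.
Derivatives of $f$ are central finite differences, relative step
$10^{-4}$ (the model is analytic and well-scaled). The evaluation group
defaults to the rich-substudy design: 12 subjects, 800 mg q24h,
reference covariates, times in [0, 24] h. Covariate coefficients are not
design parameters: for a reference-covariate group their sensitivities
vanish identically. No prior information term is added to the FIM: the
criterion measures the design alone.

Which variance parameters the D-criterion spans is switchable
(`parameters`), and the default is `"fixed+iiv"` — the three structural
fixed effects plus the three IIV variances, excluding the residual
variances. The choice was settled empirically: including the residual
variances makes the criterion reward designs that duplicate
information-rich early samples and *reverses* the published comparison of
the two three-point candidates (1/4/19 h vs 0/1/4 h), whereas the default
reproduces its sign and magnitude (+0.11 vs the published +0.081).
Reassuringly, under any of these conventions a one- or two-point design
has a rank-deficient fixed-effect block (three structural parameters
cannot be identified from fewer points), which is reported as a
non-computable criterion — exactly the behaviour described for the
original design software.

`optimize_design()` maximizes $\ln\det$ FIM by adaptive random search
(3000 draws, shrinking perturbations), cyclic per-coordinate line search
on a 0.05 h grid, and an L-BFGS-B polish, with a 0.1 h minimum spacing to
avoid near-singular designs, and also reports the nearest-integer-hour
("near-optimal") variant. The continuous 3-point optimum under the
default convention is approximately {1.1, 6.9, 22.2} h; the criterion is
nearly flat in the last sample over roughly 16-24 h, consistent with the
published sensitivity analysis in which the last optimal sample moved
across that whole range, and with the published three-point choice lying
within the flat region rather than at the numerical argmax.
`sensitivity_analysis()` re-optimizes after perturbing each fixed effect
by ±30%; because the steady-state profile is periodic, a pre-dose trough
is the same design point as $t=\tau$, and the last-sample summary counts
it at $\tau$.

## Simulation-based diagnostics

`compute_npde()` implements normalized prediction distribution errors:
for each subject, K (default 1000) replicate observation vectors are
simulated from the full model; observed and simulated vectors are
decorrelated with the inverse Cholesky factor of the empirical simulation
covariance (for one observation per subject this is centering/scaling,
which leaves ranks unchanged); the prediction discrepancy is the
half-rank-tied fraction of simulations below the observation, clamped to
$[1/2K,\,1-1/2K]$ to keep the normal quantile finite. The test battery is
Wilcoxon signed-rank (mean 0), a $\chi^2$ variance test against 1, and
Shapiro-Wilk (on a seeded 5000-value subsample above the test's limit).
The global p is the Bonferroni bound 3·min(p); the Simes combination is
reported alongside because reference implementations differ in the
correction their global p uses — for the published component p-values
(0.1, 0.39, 0.01) both conventions give 0.03 while the source reports
0.04, so neither is asserted against that value.

`pc_vpc()` bins observations by time-after-dose quantiles (8 bins by
default — binning is genuinely hard for heterogeneous sparse designs, so
the count is an argument; bins under 3 observations merge leftward),
prediction-corrects each observation and simulation by the ratio of the
bin-median population prediction to its own population prediction, and
compares observed 5th/50th/95th percentiles with the 2.5-97.5% envelope
of the same percentiles across K simulated replicates.

`gof_table()` emits population predictions (η = 0), individual
predictions (η at the MAP estimate) and individually weighted residuals
$(y - \mathrm{IPRED})/\sqrt{g(\mathrm{IPRED})}$. Conditional weighted
residuals are deliberately not computed — they require a different
(FOCE-type) linearization, and simulation-based npde are the recommended
metric here. Note that MAP-based IWRES have standard deviation below one
by construction (the posthoc fit absorbs part of the noise; about 0.90 at
12 samples/subject): the unit-variance calibration property belongs to
residuals standardized at the true parameters, which the test suite
checks separately.

## Numerical choices and problem sizes

* Equal-rates absorption/elimination degeneracy: analytic limit below
  $10^{-8}$/h.
* MAP: gradient tolerance $10^{-6}$; batch solver capped at 100 damped
  Gauss-Newton iterations with per-row Levenberg damping; positivity of
  the observation floor 0.001 mg/L.
* FIM: finite differences at relative step $10^{-4}$; PSD verified to
  $-10^{-8}\cdot\mathrm{tr}$ on every evaluation; minimum time spacing
  0.1 h.
* Ties in Spearman's $\rho$ use average ranks; the within-±15% window is
  closed.
* The test suite sizes its Monte-Carlo checks so the full run stays in
  the minutes range on one core: the headline strategy table runs at the
  full 127 x 250 replicates; generator moment checks use $10^5$ draws;
  the npde calibration study uses 200 repetitions of 500 subjects at
  K = 300 (K = 1000 is the analysis default; the calibration of the test
  battery does not require it); VPC coverage uses $10^4$ subjects at
  K = 200.

## Known limitations

* The synthetic population resamples covariates independently by
  frequency; joint covariate structure (e.g. race-genotype dependence) in
  the original cohorts is not reproduced, and results are conditional on
  the published frequency table.
* The covariate functional form and genotype reference groups are
  assumptions (above), switchable but not verifiable from the published
  material.
* The FO linearization underlying both the FIM and the design criterion
  is known to be optimistic for large IIV; conclusions about design
  rankings are more trustworthy than absolute information values.
* Reproducing the exact published D-optimal time set is not possible:
  the published {1, 4, 19} h is not the argmax of any standard FO FIM
  convention examined, sitting instead on the flat shoulder of the
  criterion; the package reports its own optimum and the criterion
  difference between the published candidates.
* No dose-adjustment/TDM advice layer, no multi-compartment or
  transit-absorption structures, no time-varying covariates, and no
  estimation of the population parameters themselves (they are inputs).
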