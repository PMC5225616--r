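---
title: "Hybrid estimation of mean QALY throughout the remaining lifetime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid estimation of mean QALY throughout the remaining lifetime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The estimation problem

Quality-adjusted life years (QALY) weight each year of life by a
preference-based utility anchored at 0 (death) and 1 (perfect health), so one
year lived at utility 0.5 counts as half a QALY. Estimating the *mean QALY
throughout the remaining lifetime* of a population group from a survey cohort
linked to mortality records is hard for one structural reason: most
participants are still alive when follow-up ends, so the bulk of their
remaining lifetime must be extrapolated.

`qalyhybrid` implements a hybrid estimator that splits the problem at the
end-of-follow-up horizon \(L\):

1. **Within follow-up** \((0, L]\): nonparametric. With death times
   \(t_1 \le \dots \le t_l < L\) and the survey-weighted Kaplan–Meier curve
   \(\hat S_{KM}\), the quality-adjusted years are
   \[
     \sum_{j=1}^{l} \hat Q(t_j)\,\bigl(\hat S_{KM}(t_{j-1}) - \hat S_{KM}(t_j)\bigr)
     \;+\; \hat Q(L)\,\hat S_{KM}(t_l),
   \]
   with \(t_0 = 0\), \(\hat S_{KM}(0) = 1\). \(\hat Q(t_j)\) is the weighted
   mean QALY accumulated by participants dying at \(t_j\) and \(\hat Q(L)\)
   the weighted mean QALY of those alive at the end of follow-up.
2. **Beyond follow-up**: parametric tail. A Weibull survival model
   \(S_p(t) = \exp[-(t/\lambda)^\beta]\) is fitted to the same records by
   weighted maximum likelihood; its mean lifetime has the closed form
   \(\lambda\,\Gamma(1 + 1/\beta)\). The tail QALY is
   \[
     \hat q(L)\,\Bigl\{\lambda\,\Gamma(1 + 1/\beta)
       - \text{RMST}_{KM}(L)\Bigr\},
   \]
   where \(\hat q(L)\) is the mean utility of survivors at the horizon and
   \(\text{RMST}_{KM}(L)\) the restricted mean survival time (area under the
   Kaplan–Meier step function on \((0, L]\)). The parametric model supplies
   only *total* expected life-years; life-years inside the window always come
   from the nonparametric curve, because parametric fits tend to track the
   data well early in follow-up and badly near its end.

The total is the sum of the two parts (`total_qaly()`), and with utility
fixed at 1 the estimator collapses — exactly, by a telescoping identity — to
the Weibull estimate of remaining life expectancy.

### The constant-utility convention

Utility is measured once, at baseline. The package therefore values the
quality-adjusted time of a participant followed to time \(t\) as
\(\text{utility} \times t\): \(\hat Q(t_j)\) is the weighted mean of
\(u_i t_j\) over deaths at \(t_j\), and \(\hat Q(L) = L \,\hat q(L)\). This is
the only convention supportable from a single baseline measurement, and it is
the same convention the tail formula uses when it applies one scalar
\(\hat q(L)\) to every extrapolated year. Time-varying utilities are a
non-goal.

### Who counts as "alive at the end of follow-up"

Entry into the cohort is staggered while the mortality linkage ends on a
fixed calendar date, so per-participant follow-up times differ and almost no
record has `time` equal to the common horizon \(L\). The package defines the
survivors-at-horizon set as the administratively censored records
(`event == 0`): under registry-linkage censoring these are precisely the
participants known alive at the end of follow-up. Their weighted mean utility
is \(\hat q(L)\). If the cohort also contains loss to follow-up (the
generator can produce it), those records enter the same set; with utility
independent of censoring this leaves the estimator consistent, but heavy
informative loss to follow-up would bias \(\hat q(L)\) — a documented
limitation.

## Severity scoring and utility mapping

PHQ-9 totals (0–27, the sum of nine 0–3 item frequencies) are binned into the
standard bands: none/minimal 0–4, mild 5–9, moderate 10–14, moderately severe
15–19, severe 20–27. Because the severe band is rare in older populations,
analyses use the collapsed four-level form merging the top two bands
(`modsev_severe`, 15–27). Major depressive disorder (MDD) is a total of 10 or
higher. Records with any missing item have an undefined total and are
excluded from severity analyses with a logged count — no imputation, by
design.

Utilities come either from a precomputed `eq5d` column (the preferred path,
used by the generator) or from the four CDC Healthy Days responses plus age
via `map_to_eq5d()`. The built-in coefficient set is an explicit **stand-in**:
an additive decrement model with the qualitatively correct monotonicities,
clipped to `[0, 1]`. Published mapping algorithms of this kind permit states
valued below zero; users holding such a coefficient set supply it through
`mapping_coefficients()` with a lower `utility_floor`. The default floor of 0
matches the death anchor of the utility scale.

## The synthetic cohort generator

There is no public microdata deposit for cohorts of this kind, so the package
ships a generator (`generate_cohort()`) whose defaults emulate the published
structure of a U.S. survey cohort of adults 65+ with mortality linkage:

* **Prevalences** over the four collapsed categories: 0.821 / 0.138 / 0.032 /
  0.009.
* **Utility**: Beta-distributed within category (concentration 10, giving a
  within-category SD of roughly 0.10–0.15, typical of mapped EQ-5D scores in
  survey data), with means 0.875 / 0.680 / 0.482 / 0.353.
* **Mortality**: Weibull time to death per category. Scale and shape were
  calibrated jointly so that (a) the early mortality rate under the default
  censoring window matches 2.99 / 4.69 / 4.97 / 8.15 deaths per 100
  person-years, and (b) the mean remaining lifetime equals the published QALY
  gradient divided by the utility means (16.0 / 11.5 / 9.8 / 9.3 years). The
  mortality rates alone leave one degree of freedom per category; pinning the
  mean lifetime closes it and makes the generator's analytic truth match the
  published QALY values. The frozen solutions are scale 17.642 / 12.669 /
  10.898 / 9.979 years and shape 1.448 / 1.466 / 1.638 / 1.220 (shapes above
  1, i.e. rising hazard, as expected in an elderly cohort).
* **Censoring**: administrative only, uniform over 1.5–6.5 years of follow-up
  (three two-year survey waves with a common linkage end roughly half a year
  to six and a half years after entry; the exact wave structure is not
  published, so the window is a recorded assumption). A configurable
  exponential loss-to-follow-up rate exists for stress tests, default 0.
* **Weights**: lognormal (meanlog 0, sdlog 0.5), independent of outcomes by
  default so weighted and unweighted estimands coincide — a property the
  tests exploit. An `informative_weights` switch breaks this deliberately.
* **PHQ-9**: the total is uniform over the category's score range (the
  simplest distribution consistent with the binning) and the nine items are
  drawn uniformly at random among all compositions of the total with parts in
  {0,...,3}, via exact composition counts.

Utility and death time are conditionally independent given category, which
makes the group-level truth analytic:
`true_group_qaly(spec, c)` \(= u_c\,\lambda_c\,\Gamma(1+1/\beta_c)\). A
`utility_hazard_corr` switch couples them negatively (rank coupling through a
shared uniform) for robustness experiments; no analytic truth is claimed
there. What the generator does **not** emulate: the survey's multistage
design (strata/PSUs), nonresponse adjustment, item-level psychometrics, and
any realistic joint structure between Healthy Days responses and utility
beyond monotonicity. Passing recovery tests therefore demonstrate estimator
correctness under the stated sampling model, not robustness to design
features the generator omits.

## Group contrasts

QALY loss for an exposed severity group against a reference group is
`loss = QALY_ref − QALY_exposed` and
`percent_loss = 100 × loss / QALY_ref`, computed at full precision and
rounded for display only (one decimal year; whole percent). Groups differ
systematically in covariates such as age and sex, so `run_contrast()`
balances them with **stabilized inverse-probability weights**: a weighted
logistic model of exposure on age and sex (extensible) yields scores \(e_i\),
and the analysis weight multiplies the survey weight by \(\bar p/e_i\)
(exposed) or \((1-\bar p)/(1-e_i)\) (reference). Weighting was chosen over
matching or stratification because it composes exactly with the survey
weights already inside the weighted Kaplan–Meier and Weibull fits. Scores
within 1e-6 of 0 or 1 are trimmed with a logged count.

Standard errors use a nonparametric bootstrap over participants (default
B = 500 in the run configuration), re-running the entire pipeline —
propensity fit included — on each resample. A design-based (linearization)
variance is out of scope; the bootstrap is valid for this composite,
non-standard estimator and is documented as an implementation choice.

## Numerical choices

* Weibull likelihood maximized over \((\log\lambda, \log\beta)\) by BFGS with
  analytic gradients; start values \(\log\lambda\) = mean log death time,
  \(\beta = 1\); relative tolerance 1e-12 in `optim` with an explicit
  gradient-norm check backing the convergence flag. Weights are normalized to
  mean 1 inside the fit, making the MLE exactly invariant to weight
  rescaling. Fewer than two distinct event times is an error, surfaced as an
  `unestimable` flag (never a silent drop) when it occurs inside a contrast.
* Tied death times form a single product-limit step; records censored at an
  event time remain in the risk set at that time (standard convention).
* A negative tail — fitted parametric mean below the restricted mean — is
  arithmetically possible; it is reported with a warning, not floored, since
  flooring would bias group totals upward.
* Records with follow-up beyond the configured horizon are clamped to it with
  a warning.
* The default horizon is the maximum observed follow-up time of the group
  being estimated (contrasts share one horizon across both groups).
* All generation and bootstrap randomness is seeded and runs in a local RNG
  scope, so a fixed configuration is bit-reproducible and never perturbs the
  caller's random stream.

## Problem sizes in the test suite

The tests validate the estimator at sizes chosen to balance Monte-Carlo
resolution against a quick default run: exhaustive product-limit and
follow-up-QALY oracles on all event patterns of up to 8 records; Weibull
recovery at n = 5,000 with ~20% censoring (5% tolerance, comfortably above
the sampling spread); per-category end-to-end recovery on single-category
cohorts of n = 20,000 against the analytic truth at 3%; and a null contrast
(two categories with identical laws) at n = 6,000 with 200 bootstrap
replicates. The tail extrapolation for the healthiest category — a ~16-year
mean reconstructed from at most 6.5 years of follow-up — is the variance
bottleneck; its Monte-Carlo spread at n = 20,000 is of the same order as the
3% recovery margin, which is worth knowing before tightening either.

## Known limitations

* Baseline-only utility: within-person trajectories of health-related quality
  of life are invisible to the estimator.
* A single Weibull per group: no covariate-dependent survival, no competing
  risks. If the true tail is not Weibull, the extrapolated part inherits the
  misfit; the hybrid design limits the damage to the tail.
* The default Healthy Days mapping is a stand-in, not a published algorithm;
  analyses of real data should supply published coefficients.
* Percent loss compares two estimated totals; its bootstrap SE accounts for
  shared sampling variation, but small reference-group QALYs make it
  unstable.
* The generator's independence assumptions (weights and covariates
  independent of outcomes by default) are idealizations; the stress switches
  probe, but do not exhaust, realistic violations.
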