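---
title: "Models and methods for delay-discounting analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for delay-discounting analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discountr)
```

This vignette explains the models implemented in `discountr`, the
assumptions behind them, the tunable parameters and their defaults, and
the design decisions taken where the underlying methodology leaves room.
It states no empirical result that the package's test suite does not
itself compute.

## The task and its domain objects

One session of the task is a list of 140 binary offers: a fixed immediate
amount (20 €) against a delayed amount. The default grid crosses seven
delays (1, 2, 7, 14, 30, 90, 180 days) with 20 amounts uniformly spaced
from 20.5 € to 80 € per delay (`build_trial_set()`). A session's offers
plus the recorded choices form a `dd_dataset`, the unit of all fitting;
choices are stored as the strings `"immediate"`, `"delayed"` or
`"missing"` rather than 0/1 to avoid polarity mistakes. Responses that
timed out are represented as `"missing"` and excluded from every
likelihood and indifference-point computation — how such responses should
be treated is genuinely open, and exclusion is the least committal policy.
Files hold many subject-sessions keyed by `(subject_id, session)`; the
table dialect is comma-separated UTF-8 with a decimal point, for
interoperability, even though the amounts are euros.

Two session variants exist. The main analysis uses the fixed uniform grid
above. An adaptive variant first runs `adaptive_pretest()` — a per-delay
bisection staircase of 6 steps over the full amount range — and then
centers each delay's amounts on the predicted indifference amount
`20 · (1 + k0 · D)` (`subject_specific_trials()`). The staircase design
(bisection, 6 steps, bracket = amount range) is this package's choice; a
pretest of this kind is conventional but its exact schedule is rarely
reported. Delays whose staircase saturated (the responder accepted or
rejected every probe) are excluded from the provisional least-squares fit
of `1 / (1 + kD)`, because a saturated staircase only brackets the
indifference point from one side. The provisional rate is clamped to
[1e-5, 2], the same admissible range used everywhere else, and flagged
`converged = FALSE` at the bounds.

## The choice model

Subjective value of a delayed reward is hyperbolic, `SV = A / (1 + kD)`,
with the immediate option at face value; choice probabilities are softmax
with noise `temp` dividing SV. Units matter: SV is in euros, so `temp` is
in euros too — a `temp` of 2 means choice probabilities are driven by SV
differences on a ~2 € scale. There is no inverse-temperature
reparameterization in the public interface. Probabilities are clamped to
`[1e-12, 1 - 1e-12]` before logging so that near-deterministic choosers
(tiny `temp`) yield finite log-likelihoods during optimization; the clamp
is far below any probability the data could resolve.

Two value functions coexist by design: the normalized curve
`1 / (1 + kD)` drives only the pretest (where amounts are the quantity
being searched), while the amount-scaled `A / (1 + kD)` drives all
likelihoods.

## Maximum-likelihood fits

`fit_subject()` minimizes the negative log-likelihood over
`(log k, log temp)` — the log scale enforces positivity without a
constrained solver — using Nelder–Mead with relative tolerance 1e-8 and
at most 2000 iterations, restarted from the 3 × 3 grid
k ∈ {0.001, 0.01, 0.1} × temp ∈ {0.5, 2, 10} and keeping the best
restart. The objective clamps parameters to k ∈ [1e-5, 2],
temp ∈ [1e-3, 1e3]; the k range matches the support of the Bayesian prior
so that both estimation routes share one admissible region. Fits at a
bound (e.g. a subject who always chose the delayed option) are returned
and flagged `at_bound` rather than discarded — degenerate response
patterns are data, not errors. The test suite certifies the optimizer two
ways: against a 200 × 200 log-spaced grid search (the simplex optimum is
never worse), and by parameter recovery on simulated agents (correlation
of true and fitted log k at 140 trials per session).

## The hierarchical Bayesian model

`sample_posterior()` fits all subject-sessions jointly. Each dataset
belongs to one of four cells — patients with stimulation on, patients
off, controls session 1, controls session 2 — and its `(k, temp)` is
drawn from that cell's normal hyper-distribution, truncated to (0, ∞) at
the subject level. Priors: each cell's k-mean is uniform on
[0.00001, 2]; each temp-mean is normal with mean 20 and variance 1000,
truncated at 0 (essentially flat over the plausible range); the group
SDs, for which no convention exists, get uniform priors — [0.001, 2] for
k and [0.01, 100] for temp, wide enough to be uninformative at the scale
of the parameters.

Two modeling choices deserve comment:

* **Scale of the k hyper-distribution.** The default places the normal
  hyper-distribution on k itself (truncated at 0), which is the reading
  most consistent with a uniform prior on the k-mean's natural scale;
  log(k) is then only a display transform. The alternative — a normal on
  log k — is available via `mcmc$scale = "log"`, in which case draws of
  the implied k-mean `exp(μ + σ²/2)` are recorded under the same names so
  summaries and contrasts are scale-agnostic.
* **Retained draws.** "20000 retained samples" with two chains is read as
  20000 total (10000 per chain after thinning by 2);
  `mcmc$retained_per_chain = TRUE` switches to the per-chain reading.

The sampler is componentwise random-walk Metropolis within Gibbs, written
for this package so its behavior is fully specified: subject-level k and
temp are updated in two vectorized sweeps across all subjects with
log-scale Gaussian proposals (the Jacobian is included in the acceptance
ratio), then each cell's four hyper-parameters are updated in turn —
means with natural-scale proposals, SDs with log-scale proposals, and the
truncated-normal normalizing constants `P(X > 0)` enter the hyper-updates
explicitly. Proposal scales adapt every 50 iterations during burn-in only
(multiplied by 1.25 above 50% acceptance, by 0.8 below 20%), and are
frozen afterwards so the retained draws come from a fixed-kernel Markov
chain. Chains start from jittered maximum-likelihood fits when available
(`mcmc$init = "ml"`), with later chains jittered more strongly to give
genuinely dispersed starts; `"prior"` skips the ML stage. Datasets whose
records are all missing are admitted with an empty likelihood, which is
what makes prior-recovery validation runs possible; the sampler fits
whichever of the four cells are present in the data, so single-group
calibration studies work without placeholder groups.

Diagnostics (`convergence_report()`) are split R-hat — each chain halved,
the Gelman–Rubin ratio computed over the resulting sequences — and
effective sample sizes from `coda::effectiveSize()`, capped at the total
draw count; parameters at or above R-hat 1.05 are flagged. Comparisons
between cells (`compare_conditions()`) report the posterior of the
difference of hyper-means, its 95% central interval, P(A > B), and an
overlap coefficient computed as the mass of the pointwise minimum of the
two marginal histograms on a common 512-bin grid.

The sampler's validity is tested, not assumed: prior recovery with no
likelihood (posterior means of all four hyper-parameters against their
analytic prior means, at Monte-Carlo tolerances derived from the measured
effective sample size), 95%-interval coverage of a known group mean over
20 seeded replicates, agreement with an independent JAGS fit of the same
model on a common dataset, and split R-hat below 1.05 on the default
synthetic study.

## Model-free analysis

`indifference_points()` estimates, per delay, the delayed amount at which
the subject accepts with probability 0.5, by maximum-likelihood logistic
regression of acceptance on amount. With near-deterministic choices the
logistic separates perfectly; the estimator then falls back to the
midpoint between the largest rejected and the smallest accepted amount,
which keeps it defined for every dataset. Subjects who accept (reject)
everything at a delay are censored at the smallest (largest) offered
amount — censored points are kept at their boundary values rather than
dropped, because dropping them would silently change the delay spacing of
the curve. How per-delay subjective values should be derived from binary
choices is not standardized; the logistic/midpoint estimator is this
package's choice and is validated against deterministic agents, whose
indifference points are known exactly up to one amount-grid step.

`build_profile()` normalizes: `x = D / D_max`,
`y = 20 / indifference amount`, and prepends the anchor (0, 1) — a reward
now is worth its face value — which is standard AUC practice; the anchor
is switchable for sensitivity analyses. `auc()` is the plain trapezoid
sum `Σ (x₂ − x₁)(y₁ + y₂)/2`, giving values in (0, 1] with 1 = no
discounting. The tests verify the analytic trapezoid value for
deterministic hyperbolic agents within the tolerance implied by one
amount-grid step per indifference point, and monotonicity of AUC in k.

## The statistical battery

All tests are two-tailed. The independent t-test pools variances
(df = n₁ + n₂ − 2, so 9 patients vs 18 controls give df = 25, the
convention this design reports). The counterbalance-robust comparison
(`session_average_compare()`) averages each subject's two sessions with
an unweighted arithmetic mean before the between-group t-test; no further
transform is applied to the averaged AUC values. The Mann–Whitney U test
uses exact enumeration when both groups have at most 8 tie-free
observations and the tie-corrected normal approximation otherwise, and
reports U as the number of pairwise wins. The 2 × 2 chi-square is
Pearson's without continuity correction — the variant that reproduces the
published demographic statistics from their group counts. Test-retest
reliability is the Pearson correlation of a fitted parameter across
sessions with the p-value from the t transform `r√((n−2)/(1−r²))`, and
`abs_logk_difference()` compares |log k₁ − log k₂| between groups to
detect stimulation effects of inconsistent sign; when that comparison is
undefined (zero variance), the per-subject table is still returned and
the undefined test is reported as such. No multiple-testing correction is
applied anywhere, matching the analysis battery this package mirrors.

## The synthetic cohort

`simulate_cohort()` generates study-shaped data with known truth: 9
patients and 18 controls by default, each with two sessions of the same
140-trial list. Truth is generated on the log-k scale — a bivariate
normal across the two conditions with correlation ρ — because log-normal
rates guarantee positivity and match how discount rates are conventionally
reported; note this deliberately differs from the hierarchical model's
default natural-scale hyper-distribution, so the model is never fit to
data generated from exactly itself except in the dedicated calibration
tests. Defaults (log-k mean ln 0.01, SD 0.8; temp mean 2 €, SD 1,
truncated at 0.05; ρ = 0.7; no session effect) describe a moderately
discounting, highly retest-stable population; they are configuration, not
claims about any real group. `session_effect` shifts log k additively in
the DBS-off condition (patients) or session 2 (controls); patients
alternate on-first/off-first when counterbalancing is on. Missing
responses can be injected at a configurable rate (default 0) to exercise
the missing-data policy.

What the generator does *not* emulate: response times and deadline
pressure, within-session drift or fatigue, order effects beyond the
counterbalance flag, any dependence of temp on condition, and real
subjects' deviations from the hyperbolic/softmax form. Passing recovery
tests therefore show that the pipeline inverts its own generative model
at realistic sizes and noise — not that real data satisfy the model.

`recovery_experiment()` chains simulate → fit → AUC → group statistics
(optionally the hierarchical model) over seeded replicates and reports
log-k bias/RMSE and correlation, AUC-test rejection rates, and
hierarchical interval coverage. Under the default (null) specification the
rejection rate of the AUC group test estimates the pipeline's type-I
error; the suite checks it against binomial bounds at 100 replicates.

## Numerical choices and problem sizes

Degenerate inputs are handled deterministically: boundary fits flagged,
censored indifference points kept, zero-variance tests raised as errors
(or reported as conditions where a partial result is still useful),
probability and rate clamps as above. Validation runs use reduced but
stated sizes chosen to keep Monte-Carlo tolerances meaningful: sampler
calibration at 2 chains with burn-in 1000–2000 and 4000–40000 retained
draws depending on the check (shorter for likelihood-rich runs, longer
for the diffuse no-data run), 18 subjects × 140 trials per calibration
replicate, 20 replicates for interval coverage, 100 for type-I error, and
25–30 simulated agents for the optimizer certifications. The default
analysis schedule (burn-in 2000, thinning 2, 20000 retained) remains the
package default for real use.

## Known limitations

Only the hyperbolic discount function is implemented — no exponential or
quasi-hyperbolic variants, and no model comparison, because the pipeline
targets a design in which the hyperbolic model is the fixed analysis
choice. The Metropolis-within-Gibbs sampler is adequate for the 4-cell,
tens-of-subjects scale it is designed for; much larger hierarchies would
deserve gradient-based samplers. Standard errors for the ML fits are not
provided (the hierarchical posterior is the recommended uncertainty
quantification), and the demographic tests operate on counts or raw
vectors supplied by the user — the package does not manage demographic
data itself.
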