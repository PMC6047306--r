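---
title: "Bias and coverage under blinded sample size reassessment: methods"
author: "bssr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bias and coverage under blinded sample size reassessment: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bssr)
```

## The design and its estimators

We consider a two-arm parallel-group superiority trial on a normally
distributed endpoint with common unknown variance $\sigma^2$, testing
$H_0: \delta \le 0$ one-sided at level $\alpha$, where
$\delta = \mu_b - \mu_a$. A first stage of $n_1 \ge 2$ patients per group is
followed by a blinded interim analysis that computes the one-sample
("lumped") variance of all $2n_1$ observations about their pooled mean,

$$S_{1,OS}^2 = \frac{1}{2n_1-1}\Big[(ss_a + ss_b) +
  \tfrac{n_1}{2}\,\bar\Delta_1^2\Big],$$

where $ss_a, ss_b$ are the within-group sums of squares and $\bar\Delta_1$
the stage-1 mean difference. The identity above is exact and is both how
`blinded_variance()` computes the estimator from sufficient statistics and
the structural fact on which the whole bias theory rests: the blinded
statistic mixes the nuisance variance with the (squared) treatment effect,
which is why $S_{1,OS}^2$ is inflated by $\delta^2 n_1/(4n_1-2)$ away from
the null.

The second-stage size per group is a pre-specified function of this
statistic. Two power-targeting rules are built in, both clamped to
$[n_{2min}, n_{2max}]$:

* unadjusted: $n_{2u} = 2(z_{1-\alpha}+z_{1-\beta})^2 S_{1,OS}^2/\delta_0^2 - n_1 + 1$;
* adjusted: the same with $S_{1,OS}^2$ replaced by
  $S_{1,OS}^2 - \delta_0^2 n_1/(4n_1-2)$, removing the inflation the
  statistic would carry if the planning effect $\delta_0$ were true.

The rules are kept real-valued in all analytic work (the $+1$ belongs to the
analytic form and makes the closed-form variance-bias bound clean); a trial
that actually recruits patients rounds *up* (`realized_n2()`), since a
fractional patient cannot be recruited and rounding down would concede
power. The two case-study interim sizes (4.7 and 0.6 rounding to 5 and 1
recruited patients) fix this convention.

After the trial, the standard fixed-sample estimates are reported:
$\bar\Delta$ over all $n = n_1 + n_2$ per group, the pooled $S^2$ with
$2n-2$ degrees of freedom, the one-sided $1-\alpha$ bounds
$\bar\Delta \mp t_{2n-2,1-\alpha} S\sqrt{2/n}$, and the two-sided interval
formed as their intersection. The two-sided interval therefore has level
$1-2\alpha$ (95% at the default $\alpha = 0.025$); this is the standard
pairing and makes the two-sided non-coverage the exact sum of the two
disjoint one-sided non-coverage events, an identity the test suite asserts
per replicate.

## Exact bias theory

Because $(q, \bar\Delta_1)$ — the stage-1 pooled variance and mean
difference — are independent with known distributions
($q \sim \sigma^2\chi^2_{2n_1-2}/(2n_1-2)$,
$\bar\Delta_1 \sim N(\delta, 2\sigma^2/n_1)$), and the rule acts on
$S_{1,OS}^2$, which is a deterministic function of the pair, both final
estimators have exact double-integral bias representations. Writing
$r(q,y) = n_2(S_{1,OS}^2(q,y))/n_1$ for the relative second-stage size:

* **Mean.** $E(\bar\Delta) - \delta = E\big[t\,/\,(1 + r(q, \delta+t))\big]$
  with $t = \bar\Delta_1 - \delta$. `mean_bias_exact()` integrates the
  equivalent form folded over the sign of $t$, whose integrand contains the
  factor $r(q,\delta-t) - r(q,\delta+t)$: it vanishes identically at
  $\delta = 0$, so exact null unbiasedness holds to quadrature precision by
  construction, and for monotone rules the sign and antisymmetry properties
  are visible directly in the integrand.

* **Variance.** Conditioning on $(q, t)$ and integrating the second stage
  out via the two-sample pooling identity
  $SS = SS_1 + SS_2 + \tfrac{n_1 n_2}{n}(\bar X_1 - \bar X_2)^2$ gives the
  contribution

  $$\frac{(2n_1-2)(q-\sigma^2) +
    \frac{n_2}{n}\big(\frac{n_1 t^2}{2} - \sigma^2\big)}{2n-2}.$$

  This integrand was derived from first principles here and then validated
  empirically: with a real-valued rule bounded below by one patient the
  simulator is an exact model match (see below), and quadrature and
  simulation agree within Monte-Carlo error at $4\times10^6$ replicates;
  alternative bracketings of the second term fail that comparison by many
  standard errors. Two structural checks pin it further: it integrates to
  exactly zero for constant rules, and under the unadjusted rule at
  $\delta = 0$ it converges to the closed-form lower bound
  $-(2n_1-1)/((2n_1-3)v)$ as $\sigma^2 \to \infty$.

* **Worst case.** Among blinded rules confined to $[n_{2min}, n_{2max}]$,
  the bias of $\bar\Delta$ is maximized by the oracle rule that jumps
  between the extremes where the conditional mean
  $E(\bar\Delta_1 \mid S_{1,OS}^2)$ crosses $\delta$; the attained maximum
  is a leading cap factor times
  $E[(\bar\Delta_1-\delta)\,1\{E(\bar\Delta_1\mid S_{1,OS}^2) > \delta\}]$.
  `conditional_mean_delta1()` evaluates the conditional mean as a ratio of
  one-dimensional integrals over the support $(-b, b)$,
  $b = \sqrt{2 S_{1,OS}^2 (2n_1-1)/n_1}$; the integrand is rescaled by its
  grid maximum so the ratio survives far into the tails. For any rule that
  may use the *unblinded* interim data, the cap factor times
  $\sigma\sqrt{2/n_1}\,/\sqrt{2\pi}$ bounds the bias; the constant is the
  maximal mean of a half-truncated standard normal, i.e. the exact value
  behind the rounded "0.4" often quoted, and the test suite confirms the
  bound is attained by its realizing rule within Monte-Carlo error.

### Numerical choices

Nested adaptive quadrature (`stats::integrate`) with relative tolerance
$10^{-8}$; the outer $q$ domain is truncated at the $10^{-12}$ and
$1-10^{-12}$ chi-square quantiles, the inner $t$ domain at $\pm 10$ standard
deviations of the stage-1 mean difference. The reported `abs_error` is the
outer integrator's estimate. The sharp blinded bound's outer expectation is
Monte-Carlo ($10^6$ draws by default) because the density of $S_{1,OS}^2$
has no convenient closed form; the indicator is computed by evaluating the
conditional mean exactly on a 200-point grid spanning the sampled range and
interpolating, which is accurate because the function is smooth and the
crossing is simple. At $\delta = 0$ the conditional mean is identically
zero, the indicator event is empty, and the bound is exactly 0 — the
worst-case rule degenerates to a constant.

## The Monte-Carlo engine

`simulate_trials()` draws per-group *sufficient statistics* from their exact
sampling distributions (stage means normal, within-group sums of squares
$\sigma^2\chi^2_{n-1}$) instead of individual observations. This is an
equality in distribution, not an approximation; a raw-observation reference
path (`simulate_trials_raw()`) is retained and the suite compares the two by
Kolmogorov–Smirnov tests on $\bar\Delta$, $S^2$ and $S_{1,OS}^2$. Each
replicate applies the rule, rounds with `realized_n2()` (integer
recruitment), skips the second stage entirely when $n_2 = 0$ (legal when
$n_{2min} = 0$; estimation then falls back to stage-1 data with $2n_1-2$
degrees of freedom), and computes estimates and bounds exactly as the
single-trial functions do.

Two simulation conventions are worth stating. First, coverage events use
closed bounds (`lower <= delta`), a measure-zero choice fixed for
reproducibility. Second, `rounding = "none"` keeps the rule's real-valued
output and draws the second-stage sum of squares from a chi-square with
fractional degrees of freedom $\max(n_2-1, 0)$; for rules with values
outside $(0,1)$ this is the exact sampling model of the analytic integrals,
which is how the quadrature code is oracle-tested without the one-patient
discretization blurring the comparison. For the built-in rules the
ceiling perturbs $n_2$ by less than one patient, which shifts biases by a
few percent at case-study sample sizes; the suite's quadrature-versus-
simulation checks on rounded rules therefore carry a small explicit
rounding allowance on top of Monte-Carlo error.

Reproducibility is by explicit seeds: identical seed and configuration give
bit-identical output, and grid scans derive per-point seeds from the base
seed by a fixed linear-congruential step, so results do not depend on
evaluation order.

## Scenario scans

`evaluate_grid()` runs the engine over a $(\delta, \sigma)$ grid and records
the argmax of each objective with its standard error, an at-boundary flag
(the true supremum of the unadjusted rule's variance bias is at
$\sigma \to \infty$, so a boundary argmax means "unresolved by this box"; a
singleton grid dimension is never flagged), and a degeneracy flag when the
maximum is within noise of zero. `refine_maximum()` then halves the
neighborhood around the argmax each round, keeps the point count, clips to
the original box, and steps up the replicate schedule — a deliberately
simple coarse-to-fine procedure chosen for this package (documented as such,
with the monotonicity of the reported maximum asserted up to noise between
rounds). No smoothing is applied to reported maxima.

## What the generator emulates — and what it does not

The simulator *is* the data model of the theory: normal endpoints, common
variance, equal allocation, independent stages, a rule driven only by the
blinded lumped variance. Passing tests therefore demonstrate internal
correctness of the estimators, bounds and integrals under that model, not
robustness of blinded reassessment to non-normal endpoints, unequal
variances or allocation, dropout, or rules that peek at more than
$S_{1,OS}^2$ — all of which are outside scope, as are group-sequential
efficacy looks, bias-corrected estimators and the confidence-interval
constructions of flexible (combination-test) designs.

## Default problem sizes

Desk-scale defaults were chosen so the full suite runs in about a minute of
CPU: $10^4$–$10^5$ replicates for distributional and coverage tests, $10^5$
per grid point for coverage scans, $2\times10^5$ for oracle comparisons,
$10^6$ for headline bias numbers in the acceptance script (Monte-Carlo
standard errors of order $10^{-3}$ in outcome units and 0.03 units² for the
variance bias at $\sigma = 20$). Every stochastic assertion is stated with
its own Monte-Carlo standard error (typically a 3-SE band) rather than a
fixed tolerance.

## Known limitations

* The quadrature applies real-valued rules inside the integrand; exact
  agreement with integer recruitment is not expected (see the rounding
  allowance above).
* At very small first stages the closed-form variance-bias bound is a loose
  proxy for moderate $\sigma$: at $n_1 = 2$ the exact bias at
  $\sigma = 4$ has reached only about 84% of the asymptotic bound (exact
  quadrature $-0.161$, integer-recruitment simulation $-0.154$, bound
  $-0.191$), while for $n_1 \ge 5$ the $\sigma = 4$ value is within 1% of
  the bound. Summaries that quote the bound as "the" small-$n_1$ bias
  overstate it; the package reports the computed value.
* The worst-case blinded rule needs the true $(\delta, \sigma)$; it is a
  bound-generating oracle and is labelled as such, never a practicable
  design.
* With $n_{2min} = n_{2max}$ the design degenerates to a fixed design; the
  constructor rejects it, and bounds for nearly-equal caps scale with the
  leading cap factor, which the suite verifies exactly.
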