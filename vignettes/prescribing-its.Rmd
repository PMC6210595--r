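---
title: "Methods: segmented regression and variation analysis of practice prescribing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented regression and variation analysis of practice prescribing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a medicines regulator issues a direct healthcare professional
communication (DHPC) — a safety letter telling prescribers that a drug is
newly contraindicated or cautioned in some patients — two questions follow.
Did prescribing change, over and above the trend it was already on? And did
practices respond uniformly, or did some reduce prescribing while others
carried on?

`presvar` answers both at the level of general practices observed monthly.
The outcome is a *share*: the focal drug's prescriptions as a percentage of
all prescriptions in its drug class, which nets out growth of the class
itself. The motivating application is the September 2015 DHPC on mirabegron
(an overactive-bladder drug, BNF code `0704020AE`, class `070402`), observed
January 2014 to March 2017, but every code, month and threshold is a
parameter.

```{r, eval = FALSE}
library(presvar)

panel <- read_prescribing("prescribing.csv")      # practice x month counts
profiles <- read_profiles("characteristics.csv")  # one row per practice
kept <- apply_exclusions(panel, profiles, dhpc_month = 201509)
shares <- compute_share(kept$panel)
```

## Outcome construction and exclusions

`compute_share()` defines `share_pct = 100 * focal / class`. A month with no
class prescribing has an *undefined* share, not a zero: 0/0 carries no
information about the practice's preference within the class. Undefined rows
are dropped from model and variation computations and their count is logged
(attribute `n_undefined`, and `n_dropped_share` on the design).

`apply_exclusions()` removes atypical practices: fewer than 750 registered
patients, fewer than 500 or more than 5000 patients per full-time-equivalent
GP (strict inequalities; practices exactly at a boundary are retained;
a zero FTE count with a non-empty list is its own rule, since the ratio is
undefined), and practices with under 100 prescription items in any single
month of the 13 months either side of the communication (August 2014 to
October 2016 for a September 2015 DHPC). The item rule counts all items by
default because low overall volume, not low class volume, marks a practice
as contributing unreliable data; `items_basis = "class"` switches the basis.
The report names the first rule each excluded practice triggered, so every
practice is either retained or reported exactly once, and the filter is
idempotent.

## Between-practice variation

`scv_month()` implements the systematic component of variation on the x100
scale with a Poisson sampling correction. With observed focal counts
$O_i$ and expected counts $E_i = c_i \sum_j O_j / \sum_j c_j$ (class counts
$c_i$),

$$\mathrm{SCV} = \frac{100}{k} \sum_{i=1}^{k}
  \left[ \left( \frac{O_i - E_i}{E_i} \right)^2 - \frac{1}{E_i} \right].$$

The $1/E_i$ term subtracts the variation a Poisson sampling model would
produce by itself, so the statistic estimates *systematic* (practice-level)
variation. We adopted this estimator because the conventional interpretation
bands — low below 3, moderate 3–5.4, high 5.4–10, very high above 10 — sit
on this x100 scale. Practices are first trimmed to the month's 5th–95th
percentile band of shares (inclusive bounds, type-7 quantiles, fixed for
reproducibility); trimming on shares rather than raw counts keeps the
trimmed set size-independent. Sampling noise can push the raw value below
zero when there is essentially no systematic variation; the reported `scv`
is truncated at zero and the raw value is kept alongside.

`scv_window_compare()` compares the monthly SCVs of the six months strictly
before and strictly after the communication month (which belongs to neither
window) with a two-sided rank-sum test. Because the groups are small, the
p-value comes from the exact permutation distribution of the mid-rank sum,
computed by a counting recursion over half-integer ranks
(`exact_rank_sum_test()`); the two-sided value is the null probability of a
rank sum at least as far from its expectation as observed. `stats::wilcox.test`
is not used here because it abandons exactness under ties.

`standardized_ratios()` divides each practice's share by the pooled share of
the month; the class-weighted mean ratio is exactly 1 each month, which the
test suite asserts to 1e-12 as an algebraic canary.
`rolling_ratio_distribution()` tracks each practice's six-month rolling mean
share relative to its share in the reference month, summarised as deciles
and 1st–9th bottom/top percentiles; practices with a zero or undefined
reference share are excluded, since the ratio is then degenerate.

## The segmented mixed model

`build_design()` codes month $t$ relative to the month *before* the
communication ($t = 0$), so the intercept is the level of prescribing just
before the warning; `post` switches on in the month after it ($t \ge 2$) and
$s = (t - 2)\,\mathrm{post}$ counts post-warning months. The communication
month itself ($t = 1$) is a transition month — the letter arrives partway
through it — and is excluded from fitting by default
(`include_transition = TRUE` keeps it as a pre-period row; the anchor and
the post period are unaffected either way).

`fit_segmented()` estimates

$$y_{pt} = \beta_0 + \beta_1 t + \beta_2\,\mathrm{post}_t + \beta_3 s_t +
  \gamma_{m(t)} + b_{0p} + b_{1p} t + b_{2p}\,\mathrm{post}_t + b_{3p} s_t +
  \varepsilon_{pt},$$

with practice effects $b_p \sim N(0, G)$, $G$ unstructured over the
requested effects, calendar-month fixed effects $\gamma$ (11 dummies,
January reference), and within-practice errors either independent or with a
stationary AR(2) correlation. Estimation is REML by default; model
comparisons of random-effect structures refit with ML, the standard
division of labour. Rows are unweighted — each practice-month counts
equally — because the model is specified directly on the percentage.

Numerically, the no-AR case goes through `lme4::lmer` and the AR(2) case
through `nlme::lme` with `corARMA(p = 2)`; both estimate the same model, and
the package treats them as interchangeable engines behind one surface. Two
caveats are inherent to the AR implementation: consecutive design rows
within a practice are treated as consecutive months (so a gap, e.g. the
excluded transition month, is compressed), and the AR correlation applies to
the single residual variance. On failure the fit falls back along a
documented ladder — drop the AR terms, then the slope-change random effect —
recording each step; `strict = TRUE` turns any fallback or optimizer failure
into an error. `lme4`'s post-hoc gradient checks are recorded in
`$messages` but do not set `converged = FALSE` on their own, as they are
known to flag healthy large-n fits; the flag follows the optimizer's own
return status.

With no random effects and no AR terms the model degenerates to ordinary
least squares (via `stats::lm`), which the tests pin against a closed-form
solve to 1e-8.

`predict_counterfactual()` produces population-level (fixed-effects)
monthly predictions with all terms, and with the $\beta_2$ and $\beta_3$
contributions removed — the continuation of the pre-warning trend —
averaging calendar-month effects as observed.

## BLUPs, classification and predictors

Practice-specific effects are best linear unbiased predictors computed from
the estimated parameters: for practice $p$ with design blocks $X_p, Z_p$ and
$V_p = Z_p G Z_p' + \sigma^2 R_p$,

$$\hat b_p = G Z_p' V_p^{-1} (y_p - X_p \hat\beta), \qquad
  \mathrm{Var}(\hat b_p - b_p) = G - G Z_p' V_p^{-1} Z_p G.$$

The conditional (posterior) variance is the appropriate spread for
*predicting an individual practice's effect*; unconditional variances would
answer a different question. The implementation is cross-checked in the
tests against `lme4`'s conditional modes and `condVar` on the same fits.

`classify_practices()` labels a practice `decrease` when the 95% interval
$\hat b \pm 1.96\,\mathrm{SE}_{\mathrm{cond}}$ lies below zero, `increase`
when above, `no_change` otherwise, separately for the level-change and
slope-change effects. No multiplicity correction is applied across the
thousands of practice-level intervals — a deliberate mirror of common
practice in profiling analyses, and a documented caveat: the labels are
descriptive, not confirmatory. Because BLUPs shrink toward zero, the
false-positive rate under a true null is well below the nominal 5% (the
acceptance suite bounds it at 10% at 500 practices).

`fit_predictors()` models `decrease` versus everything else by
maximum-likelihood logistic regression with all characteristics entered
jointly. Continuous characteristics (including the deprivation decile) are
z-scored over the included practices so odds ratios are per SD; the
registrar indicator stays 0/1, because standardizing a dummy destroys its
interpretation — set `standardize_binary = TRUE` to override. Separation and
low event counts are flagged, practices with missing characteristics are
dropped from this model only, and the standardization constants are returned
so the standardized fit can be mapped back to the raw scale (asserted to
1e-6 in the tests).

## The synthetic generator

`simulate_panel()` draws data from exactly the model the estimator assumes,
plus the count layer the estimator ignores: latent percentage
$\mu_{pt}$ from the segmented mixed model (the communication month is
generated from the pre-period line, matching its exclusion as a transition
month), then `class_items ~ Poisson(lambda_p)` with $\lambda_p$ lognormal
with mean 76 (the observed scale of class prescribing, and per-practice
rather than constant so that binomial noise is heteroscedastic across
practices), and `focal_items ~ Binomial(class_items, mu/100)` with $\mu$
clamped to $[0, 100]$.

Default calibration choices, made once:

* Structural parameters default to the motivating study's estimates
  (level 8.30, trend 0.294 pp/month, level change -0.023, trend change
  -0.036).
* Random-effect SDs default to (1.5, 0.05, 0.15, 0.02) with a 0.8
  correlation between intercept and pre-period slope. The correlation
  encodes adoption-curve structure — early in the window the drug is new, so
  low-share practices are late adopters with flatter growth — and it is also
  what keeps the latent percentage physically plausible early in the window:
  the clamp rate under defaults is about 0.2%, and the generator logs it
  (`truth$clamp_rate`; the tests require < 1%).
* Seasonality defaults to a small sum-zero cosine (amplitude 0.3 pp); AR
  noise defaults to coefficients (0.3, 0.1) with innovation SD 0.5.
* `delta_level` / `delta_slope` shift a practice's level-change /
  slope-change effect by $\delta' z_p$ (standardized covariates, shift in
  percentage points), giving responder status a known, recoverable
  association with characteristics; the default is no association.

One seed drives everything through a fixed sub-seed ladder (stage `k`
reseeds with `seed * 10 + k`: profiles, practice effects, AR noise, counts),
so each stage is independently reproducible, distinct seeds never share a
stage stream, and fixtures written twice are byte-identical.

What the generator does *not* emulate: practice entry/exit and mergers,
within-month dispensing lags, spatial correlation between practices,
patient-level case mix, and any feedback from prescribing levels to
characteristics. Passing tests therefore demonstrate that the estimators
recover the truth *under the assumed model at the simulated scale*, not that
the model is right for any particular real extract.

## Parameter recovery and problem sizes

`recovery_study()` is the package's end-to-end check: it plants the default
structural parameters, with random-effect SDs (2.0, 0.05, 0.2, 0.02),
seasonal and AR terms off, simulates 10 independent replicates of 500
practices over the full 39-month window, runs share construction, design
building (transition month excluded) and the mixed fit with all four random
effects, and averages the estimates. Because the replicates are generated
without seasonality, the recovery fit sets `seasonality = FALSE` — it fits
the model that generated the data; estimating eleven month effects that are
truly zero is unbiased but adds collinearity with the step and trend terms
and roughly doubles the sampling error of the level-change estimate, which
would only blur what the check is measuring. The analysis default for real
data remains `seasonality = TRUE`.

At these sizes the dominant uncertainty is the level-change estimate
(per-replicate SD about 0.08 percentage points: an interior step is hard to
pin against binomial noise with ~76 class items per practice-month), which
is why it carries the widest recovery margin. Each replicate fits in a few
seconds; the whole study completes in a few minutes on one core.
`scripts/acceptance.R` re-runs exactly this study from a command-line seed
and writes the four mean estimates as JSON.

## Known limitations

* The linear-on-percentage model can predict outside $[0, 100]$ for extreme
  practices; the motivating analyses accept this, and so does the package.
* AR(2) estimation treats design rows as equally spaced even across the
  excluded transition month.
* The likelihood-ratio test for random effects uses a plain chi-square
  reference on the covariance-parameter difference, which is conservative
  for variances on the boundary; the 50:50 mixture refinement is documented
  in the literature but not the default here.
* Exact rank-sum inference is limited to groups of at most 12 (beyond that
  a tie-corrected normal approximation is used), which covers the intended
  six-month windows.
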