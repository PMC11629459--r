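---
title: "Models and methods behind discountr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind discountr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(discountr)
```

This vignette is the package's own account of its science: the choice model
and its assumptions, the design solver, the synthetic-cohort generator, the
preprocessing rules, the statistical machinery, and the numerical and design
choices made where the problem left them open. Everything quantitative
stated here is computed by the package's tests or examples; nothing is
asserted that the code does not check.

## The hyperboloid choice model

A trial offers a smaller-sooner amount $r_1$ and a larger-later amount $r_2$
at delay $D$ (days). Delayed outcomes are devalued by the modified
hyperboloid

$$V_{a2} = \frac{r_2}{1 + \kappa D^s}, \qquad V_{a1} = r_1,$$

with discount rate $\kappa$ and temporal scaling exponent $s$; at $s = 1$
this reduces to the single-parameter hyperbola. Values drive choice through
a sigmoid,

$$p(a_1) = \frac{1}{1 + e^{\beta (V_{a2} - V_{a1})}},$$

where $\beta$ is an inverse temperature: $\beta \to 0$ yields random
choice, large $\beta$ near-deterministic exploitation of the higher value.

**Assumptions.** One $(\kappa, s, \beta)$ triple per participant *and*
condition (reward, loss), stable across the session; choices conditionally
independent given the trial values; no reaction-time model (RTs enter only
quality control). Losses are represented by negating both option values and
reusing the same sigmoid — under this convention a steep loss discounter
devalues the delayed loss toward zero and therefore *prefers* the
larger-later loss, which is what the loss-condition "discounted choice"
(choosing the delayed loss) counts.

**Parameters and bounds.** $\kappa \in [0, 1000]$ day$^{-s}$ and
$\beta \in [0.01, 2]$ are the optimization constraints of the estimation
procedure; $s$ is constrained to $[0, 1]$, the range over which temporal
sensitivity runs from delay-insensitive to linear-in-delay and on which the
observed estimates lie. $\kappa = 0$ (no discounting) is admissible: the
analysis scale is $\log(\kappa + 10^{-4})$, whose offset exists precisely to
keep zero finite. The scale's attainable range is therefore
$[-9.2103, 6.9078]$, and these endpoints are what the acceptance script
recovers by fitting always-delayed and always-immediate responders.

## Maximum-likelihood fitting

The negative log-likelihood sums $-\log p(\text{observed choice})$ over
non-missing trials; missing trials are excluded, never imputed. Choice
probabilities are clipped to $[10^{-12}, 1 - 10^{-12}]$ inside the
likelihood so saturated sigmoids cannot produce infinite objective values;
the clipping constant is exposed in `fit_config()`.

The likelihood is multimodal in $(\kappa, s)$ — a shallow rate with strong
scaling and a steep rate with weak scaling can mimic each other on a finite
design — so optimization is multi-start: box-constrained L-BFGS-B from the
fixed $3^3$ grid
$\log\kappa \in \{-7, -3, 1\} \times s \in \{0.2, 0.5, 0.9\} \times \beta
\in \{0.1, 1.0, 1.9\}$. Two *boundary-profile* candidates are added, with
$\kappa$ pinned at each bound and $(s, \beta)$ re-optimized. The reason is
numerical: for extreme responders the likelihood is strictly monotone in
$\kappa$, so the MLE sits exactly on a bound, but a quasi-Newton iteration
approaching the bound along an asymptotically flat profile can stop short of
it; evaluating the bound profile directly guarantees the fitted
$\log\kappa$ reaches $-9.21$ or $6.91$ for such data. The lowest NLL wins;
exact ties break toward smaller $\kappa$, then smaller $s$. The procedure is
deterministic given the data and configuration. Tests verify that the fitted
NLL never exceeds the minimum over a $20^3$ grid of the bounded cube, and
that over 200 simulated participants the correlation between generating and
recovered $\log\kappa$ exceeds 0.85 at $\beta = 2$ (0.60 at $\beta = 0.5$ —
recovery degrades gracefully as choices become noisy).

## Design generation

`generate_design()` crosses delays $\{7, 30, 90, 180, 365, 1095\}$ days,
delayed amounts $\{5, 10, 20, 50\}$ GBP, four hypothetical parameter sets,
and target probabilities $\{0.5\}$ — 96 trials per condition, identical
magnitude structure in reward and loss. The longest delay defaults to 1095
days (three years) and, like the whole set, is configurable. The immediate amount solves the sigmoid
in closed form,
$r_1 = V_2 - \log(1/p - 1)/\beta$, clamped to $[0.02, 0.98] \cdot r_2$ and
rounded to £0.10. The hypothetical grid
($\kappa \in \{0.001, 0.01, 0.1, 1\}$, $s = 1$, $\beta = 1$) is a design
decision: no canonical grid exists for this task family,
and four log-spaced rates spanning shallow to steep discounting yield
informative trials across the plausible range while reproducing the
96-trial count. Unclamped trials reproduce their target probability to
$10^{-6}$ by construction (a round-trip the tests enforce); clamped trials —
about a quarter of the default design, where the hypothetical agent's
indifference point would fall outside $(0.02, 0.98) \cdot r_2$ — sit on the
clamp bound and are flagged in the design table. Randomization permutes each
condition, splits it into two 48-trial blocks, alternates conditions with a
random starting condition, and assigns the immediate option's screen side
uniformly; everything derives from one seed.

## The synthetic cohort

The generator exists so every downstream stage is testable without any
data download. Its defaults *are* the study conditions: $n = 341$,
gender-balanced, with the published covariate marginals and correlation
targets.

**Copula.** Covariates are drawn from a Gaussian copula: a latent
multivariate normal with the target correlation matrix (repaired to the
nearest positive semi-definite correlation matrix if needed), mapped through
each variable's marginal quantile function. Marginals: age truncated-normal
(43.48, 11.90) on [19, 65]; AUDIT rounded truncated-normal (11.76, 6.06) on
[0, 40]; BIS-15 rounded truncated-normal (30.65, 6.65) on [15, 60]; latent
$\log\kappa_R$ truncated-normal (−3.44, 3.40) and $\log\kappa_L$ (−5.99,
3.77) on the transform's range; weekly drinking gamma with mean 24.43 and
SD 18.48; education a discretized normal over ISCED 0–7 (mean 4.31, SD
1.57); income bands from discretized lognormals whose band-midpoint means
match £28,000 (individual) and £53,541 (household); subjective SES a
discretized normal on 1–10. Gender is assigned by latent rank, making the
split exactly balanced while preserving any configured gender correlations.
Nonzero correlation targets are the published pairwise values; pairs without
a published value default to zero, except AUDIT–weekly units (0.60), which
the marginal construction requires to be positive and which the two alcohol
measures' strong intercorrelation motivates. With $n = 5000$ every empirical
pairwise correlation lands within ±0.04 of its target (a fidelity test);
discretized marginals (income bands especially) attenuate Pearson
correlations slightly, which that band absorbs.

**Ground truth and choices.** True rates invert the analysis transform,
$\kappa = e^{\text{latent}} - 10^{-4}$ clipped to the bounds;
$s \sim U(0,1)$ and $\beta \sim U(0.5, 2)$ — the lower $\beta$ limit stays
above the fit bound 0.01 because near-random responders carry almost no
parameter information and the observed inverse temperatures center well
above it. With probability 0.297 an agent's loss-side rate is replaced by
$\kappa_L = 0$, reproducing the loss-condition nondiscounter subgroup.
Choices are Bernoulli draws from the model probabilities; RTs are lognormal
(median 1500 ms, $\sigma_{\log} = 0.4$) truncated at the 10-s response
window. Artifact injection (for QC testing) makes flagged agents
single-key responders (choices re-derived from option sides) or fast
responders (lognormal median 350 ms, mean below the 500-ms rule), and blanks
trials at a configurable missingness rate.

**What it does not emulate.** Real questionnaire response styles
(acquiescence, digit preferences), RTs that depend on value difference,
session-position effects, and any nonlinearity in the covariate
dependencies beyond the Gaussian copula. Item-level allocations are
arbitrary within the constraint that items sum correctly — analyses use
sums only. Passing tests on this cohort therefore validate the pipeline's
statistical behavior under the published moment structure, not the full
texture of real data.

## Preprocessing

Exclusion rules, applied strictly: completion below 80% of the 96 scheduled
trials in either condition; exactly one distinct key across all non-missing
trials of the session (the operationalization of stereotypical key pressing
— windowed run-length variants were rejected as unsupported); mean RT below
500 ms over the non-missing discounting trials of both conditions pooled.
Scores: AUDIT sum (items 1–8 scored 0–4, items 9–10 scored 0/2/4), BIS-15
sum after reverse-keying ($x \mapsto 5 - x$; the reverse-keyed set is
configurable, default $\{1, 4, 5, 6, 9, 11\}$, since the keying varies
across published versions of the short scale), DDQ weekly units as the sum of seven daily
averages, converted to grams of ethanol per day by $\times 8/7$ (one UK
unit = 8 g). Income bands code to midpoints, with the open-ended bands
top/bottom-coded to £250,000 and £5,000; ISCED education is treated as an
equal-interval score; caregiver education levels are averaged. Missing
entries propagate as `NA` and each analysis drops its own incomplete cases —
never listwise deletion across the whole table.

## Statistical suite

Correlations use Fisher's $z$: CI $\tanh(\operatorname{atanh} r \pm
z_{0.975}/\sqrt{n-3})$, $p$ from the $t$ transform. Regressions are OLS;
standardized weights are computed on the complete-case sample as
$b \cdot s_x / s_y$ (CIs scaled from the unstandardized ones). Squared
semipartials are R² differences against the model without that predictor.

**Alf–Graf intervals.** CIs for $\Delta R^2$ and $sr^2$ use the asymptotic
normal theory for dependent squared multiple correlations: with
$r_1 = \operatorname{cor}(y, \hat y_{\text{full}})$,
$r_2 = \operatorname{cor}(y, \hat y_{\text{reduced}})$ and
$r_3 = \operatorname{cor}(\hat y_{\text{full}}, \hat y_{\text{reduced}})$,
$\operatorname{var}(r_i^2) = 4 r_i^2 (1 - r_i^2)^2 / n$ and the
Pearson–Filon covariance of $r_1, r_2$ through $r_3$ give
$\operatorname{var}(r_1^2 - r_2^2)$. The $R^2$ CI uses the Olkin–Finn
variance with its degrees-of-freedom adjustment, truncated to $[0, 1]$. Near
the boundary $\Delta R^2 = 0$ the statistic's sampling distribution is
skewed while the interval is symmetric, so a significant block-$F$ can
coexist with a $\Delta R^2$ interval covering zero — the package reproduces
exactly this signature on cohorts generated at the published targets, and
tests verify the intervals against a 2000-resample bootstrap (endpoint
agreement < 0.02 away from the boundary) and 95% ± 2% coverage at
$n = 341$.

**Tests and decisions.** Independent-group comparisons use Welch's
unequal-variance $t$ (Welch is the safer default when group variances may differ); the nondiscounter-vs-discounter comparisons are
independent-samples tests (the groups are disjoint participants; a paired
reading is available behind the `paired` flag). The gender moderation model
uses an uncentered product with the 0/1 dummy. All tests are two-tailed at
$\alpha = 0.05$ with no multiplicity correction, matching the study design's
reporting conventions. Sample-size planning for a correlation
uses the Fisher-$z$ formula
$n = \lceil ((z_{1-\alpha/\text{sides}} + z_{\text{power}})/
\operatorname{atanh} r)^2 + 3 \rceil$; at $r = 0.14$, 80% power, this gives
315 one-sided and 399 two-sided.

**Confirmatory flow.** H1: AUDIT ~ log $\kappa_R$ (simple regression). H2:
the loss-side correlation gates its regression — no correlation below
$\alpha$, no regression. H3: log $\kappa_R$ ~ education + individual
income. H4: AUDIT ~ education + income. H5: hierarchical — education +
income first, log $\kappa_R$ added, block $F$ on the increment. The
exploratory suite adds the full correlation matrix, gender $t$-tests and
moderation, nondiscounter comparisons under the strict below-5% rule, the
age + education hierarchical model, the impulsivity model, and repeats of
H4/H5 with the model-free discounting indices.

## Calibration and problem sizes

The statistical suite's operating characteristics are verified on
covariate-level cohort tables (`cohort_truth_table()`), which carry the
generator's ground-truth $\log\kappa$ instead of re-fitted values: under
independence targets (200 cohorts, $n = 341$) each confirmatory test rejects
at most 7% of the time; at the published targets H1 is significant in at
least 14 of 20 cohorts, consistent with ~80% power for $r = 0.15$ at this
$n$. Fitting noise is exercised separately: parameter recovery over 200
agents, grid-oracle optimality over 20, and a pipeline-closure check that
fits an 80-agent cohort end-to-end and recovers the configured
discounting–alcohol association within its Fisher-$z$ sampling band. These
sizes keep the full test suite within a few minutes on one CPU while
leaving the acceptance quantities at full scale.

## Known limitations

The loss-condition value equation is a sign-convention choice with no
single standard in the task literature; alternative conventions (e.g., discounting
the *relief* of a delayed loss) would change the mapping between
$\kappa_L$ and choice frequencies. The Alf–Graf implementation is the
standard asymptotic variant; software that uses a different variance
expression may differ in the third decimal. The copula reproduces printed
moments, not the unpublished full covariance of the real data, so exact
replication of the study's Tables from simulated cohorts is out of scope by
design. Hierarchical/Bayesian group-level estimation, alternative
discounting functionals, and RT modeling are deliberate non-goals.
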