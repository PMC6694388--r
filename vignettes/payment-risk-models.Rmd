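---
title: "Modeling 30-day episode payments from claims: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling 30-day episode payments from claims: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(payrisk)
```

This vignette is the package's account of its statistical methods: the
models and procedures, the parameters that matter and their defaults, what
the synthetic claims generator does and does not emulate, the numerical
choices, and the design decisions taken where the methodology left room.

## The modeling problem

Condition-specific payment measures predict the total standardized payment
in the 30 days following an index admission for acute myocardial infarction
(AMI), heart failure (HF) or pneumonia (PN) in a fee-for-service population
aged 65 and over. Risk adjustment uses only what claims contain: diagnosis
codes from the index admission and from all claims in the 12 months before
it, plus age. The central question the package supports is how the
*construction of candidate risk variables* — grouped condition categories
(CCs) versus individual codes, present-on-admission (POA) logic versus a
complication-exclusion algorithm, pooled versus separated index/history
channels — changes model performance and downstream hospital profiling.

## Cohorts and outcome

`build_cohort()` applies the inclusion rules: age at least 65 at the index
admission, a full 12 months of continuous prior fee-for-service enrollment
(a strict `prior_ff_months >= 12`), and retention of 30-day decedents with
unprorated payments. The outcome is winsorized at the cohort's 99.5%
quantile, one-sided: payments are bounded below by zero and the cap exists
to blunt high-cost outliers. The quantile uses linear interpolation between
order statistics (`type = 7`), fixed and documented because the cap is
sensitive to the rule. Winsorization is applied per condition cohort, after
the inclusion filters; whether the original measures pooled conditions for
this step is not documented, so the choice is exposed as `winsor_q` plus the
per-cohort convention. One subtlety of the interpolated rule: capping is
exactly idempotent only when the quantile position $(n-1)q + 1$ lands on an
order statistic; off the grid, a recapped cap can drift within one
interpolation gap. The tests pin both facts.

## Covariate schemes

All schemes share the two age-band indicators (reference ≤ 74). Index
diagnoses pass an eligibility rule first:

* **POA rule** (all schemes except `cms_base`): principal diagnoses always
  count; secondary diagnoses count iff flagged `Y`, or flagged `missing`
  while the code is on the POA-exempt list. `N` means the condition arose
  during the stay and is excluded.
* **Complication-exclusion algorithm** (`cms_base`): an index secondary
  diagnosis whose CC is on the excludable list is dropped unless the same CC
  also arises from the 12-month history — the pre-POA proxy for "probably a
  complication".

Codes map to CCs through a crosswalk with a hierarchy: within a hierarchy
group, a present higher-ranked category suppresses the listed lower-ranked
ones, with presence judged before any suppression. The licensed v22
crosswalk and the real POA-exempt list are not redistributed; the package
ships a small synthetic stand-in (`toy_code_maps()`: 57 codes, 9 comorbidity
CCs, 3 hierarchy groups) and reads full tables in the same four-file CSV
format (`read_code_maps()`). The algorithms, not the tables, are the
substance here.

Channel semantics follow the footnote defining the pooled model: a pooled CC
indicator is set if the patient had the CC in the index admission, the
history, *or both*. Concretely `hcc_pooled` is the OR of the two
`hcc_separate` channel indicators after per-channel hierarchy resolution —
an exact identity the tests enforce on arbitrary bundles. (Applying the
hierarchy to the pooled code set instead would break the identity whenever a
higher CC in one channel met a lower CC in the other; the CMS-style
`cms_base`/`cms_poa` schemes do pool codes before the hierarchy, as the
grouped models did.) The variable construction that separates "principal
and secondary diagnoses from index and historical admissions" is
implemented as index-vs-history channel separation with principal/secondary
kept as provenance tags: the channel is the axis the incremental model
ladder actually varies, and the tags allow the finer split if a user wants
it.

Individual-code schemes bypass CC grouping entirely. A code is a candidate
iff strictly more than 0.5% of cohort admissions carry it (counted once per
admission, per channel when channels are separate).

## GLMs, selection, and comparison metrics

The family/link pairs are inverse Gaussian + log (AMI), Gamma + log (HF),
Gamma + identity (PN); other pairs are deliberately opt-in. Fitting is
IRLS (`stats::glm.fit`), with an internal step-halving IRLS fallback that
guards identity-link fits against non-positive means, initialized at the
least-squares solution clipped to positive fitted values. Duplicate or
collinear columns are an error, not a silent drop.

Dispersion is estimated by Pearson $\chi^2/(n-p)$ — the methodology is
silent here, and the Pearson estimator is the standard robust default. The
McFadden pseudo $R^2 = 1 - \ell_{model}/\ell_{null}$ evaluates both
log-likelihoods at the *full model's* dispersion so the ratio reflects
mean-structure improvement only; the likelihoods use Gamma with shape
$1/\phi$, scale $\phi\mu$ and inverse Gaussian with variance $\phi\mu^3$,
matching the GLM variance functions and the generator. Two caveats worth
stating: McFadden ratios of continuous log-densities depend on the outcome's
scale (only the model-minus-null log-likelihood difference is
unit-invariant, which the property tests check), and their magnitudes on
synthetic data are small — the toy catalogs carry far less case-mix signal
than hundreds of real diagnosis codes, so absolute pseudo-$R^2$ values here
are not comparable to published real-data values. The qualitative ordering
across schemes is what the synthetic studies reproduce.

Selection for the individual-code schemes mirrors the published constraint
pair: an L1 path for the matched family/link (glmnet's family-object
interface; a Gaussian working-response approximation is available as an
option), columns standardized internally for penalization and reported on
the original scale, over a 100-point log-spaced grid; the smallest penalty
whose active set holds at most 200 non-forced variables is chosen; the set
is refit unpenalized; and backward elimination drops the least significant
variable with two-sided Wald $p \ge .005$ and refits until every survivor
is significant. Backward iteration rather than a single pass is what the
end-state constraint ("all final variables significant") actually
guarantees, since refitting can resurrect a p-value. Age columns are
forced: unpenalized and exempt from pruning.

`cross_validate()` assigns admissions (not patients) to 5 folds — the
models operate on admissions, and fold assignment is configurable — and
repeats candidate construction, selection and training on each set of
training folds, scoring RMSE on the held-out fold. The pseudo $R^2$ is
computed from a separate full-cohort selection and fit, matching how the
two metrics are defined for the comparison tables. Calibration uses decile
predictive ratios (mean predicted over mean actual per decile of predicted
payment, stable tie order, near-equal bins), and `quintile_shift()`
cross-classifies admissions by predicted-payment quintile under two models.

## Hospital profiling

The hierarchical GLM $g(\mu_{ij}) = x_{ij}'\beta + \alpha_i$,
$\alpha_i \sim N(0, \tau^2)$ is estimated by alternating steps: given the
intercepts, a GLM step for $\beta$ with $\alpha$ as offset; given $\beta$,
each hospital's intercept is the ridge-shrunk weighted mean of its working
residuals, $\hat\alpha_i = m_i/(S_i + 1/\tau^2)$; and $\tau^2$ comes from a
method-of-moments step on the raw per-hospital estimates — their
precision-weighted dispersion minus its sampling expectation, truncated at
zero (a DerSimonian–Laird estimator on the working model). An earlier
EM-type update ($\tau^2 = \mathrm{mean}(\hat\alpha_i^2 + v_i)$) was
abandoned: it contracts only quadratically under strong shrinkage and
crawls near the $\tau = 0$ boundary, while the moment step converges in a
handful of outer iterations and collapses exactly to zero when the data
carry no between-hospital signal. A full integrated likelihood is out of
scope by design; the estimator is validated by parameter recovery and by
agreement with `lme4::glmer` in the test suite.

RSP is $(P_i/E_i) \times$ national mean, with $P_i$ summing
$g^{-1}(x'\beta + \alpha_i)$ over the hospital's cases and $E_i$ setting the
random effect to its prior mean zero (a population-average hospital with the
same case mix; `mean(alpha)` centering would be a configuration away). The
national mean is the observed mean winsorized payment over the whole
condition cohort, including sub-threshold hospitals' admissions; winsorized
rather than raw payments keep the reference on the same scale as the model.

Uncertainty comes from a cluster bootstrap: hospitals are resampled with
replacement (the hospital effect is the target of inference, so the cluster
is the resampling unit), the hierarchical model is refit per replicate, and
each sampled hospital's intercept is drawn from its conditional posterior
$N(\hat\alpha_i, v_i)$ before its RSP is computed. The posterior draw is
essential, not cosmetic: a hospital's own data are identical in every
replicate that samples it, so point-estimate RSPs would concentrate on a
possibly off-center value and produce degenerate intervals that miscategorize
most hospitals even when $\tau = 0$. Percentile CIs (2.5/97.5, inverse-ECDF
quantiles so that two replicates give the min/max) are used for determinism
and simplicity; BCa would complicate reproducibility for little gain at 2000
replicates. The production default is 2000 replicates; the packaged tests
run at 200 with the null-coverage property checked across seeds. Hospitals
with at least 25 cases are categorized by comparing the CI to the national
mean (`lower` / `no_different` / `higher`); `shift_table()` cross-classifies
two models' categories and reports the off-diagonal percentage.

## The synthetic claims generator

`generate_bundle()` draws linked admission, diagnosis and enrollment tables
from the same model family the estimators assume: payments from Gamma
(variance $\phi\mu^2$) or inverse Gaussian (variance $\phi\mu^3$) with mean
$g^{-1}(x'\beta + \alpha_h)$, diagnosis codes as independent per-channel
Bernoulli draws from a catalog whose prevalences straddle the 0.5% filter,
POA flags with per-code probabilities over Y/N/missing, hospital volumes
with ~20% of hospitals under the 25-case threshold (no volume distribution
is documented anywhere, so this is a choice made to exercise the
eligibility rule), an exact-count fraction of patients with under 12 months
of enrollment, a small under-65 fraction, and an independent death flag
that does not alter payment. Identity-link configurations whose worst-case
linear predictor (all negative effects active, a 6-sigma random intercept)
is non-positive are rejected at configuration time. Every table draws from
its own seed-derived substream, so extending one table never perturbs the
others, and the full ground truth (coefficients, hospital effects,
dispersions) is recorded for recovery tests.

Default study conditions: condition mix 0.18/0.35/0.47 (AMI/HF/PN, the
relative cohort sizes of the measures), mean payments in the $15–23k range,
Gamma dispersions near 0.5 (payment SD ≈ 75% of the mean, matching the
reported cohort moments), inverse-Gaussian dispersion 2.7e-5 (the value
implied by the reported AMI mean and SD), hospital random-intercept SD 0.08
on the log scale (~8% between-hospital spread, typical of payment
profiling) and $1300 on the pneumonia identity scale, 10% short enrollment,
8% 30-day death. One index admission per patient is generated; real cohorts
have ~1.16 admissions per patient, but with fold assignment and modeling
both at the admission level the simplification does not touch any tested
behavior.

What the generator does *not* emulate — and hence what passing tests do not
establish about real claims: correlated comorbidities (codes are
independent given the channel), coding intensity that varies by hospital,
payment tails beyond what the two-parameter families produce (dispersion is
the only tail knob), seasonal or policy variation (payments arrive already
standardized), and any real crosswalk semantics. Recovery and calibration
results on synthetic data validate the estimators under their assumed
model, not the measures' real-world performance.

## Problem sizes and numerics

The test suite runs recovery at $n = 20{,}000$ (coefficients within 3
reported SEs), selection recovery at $n = 50{,}000$ with 300 candidates
(at least 9 of 10 true codes), hierarchical recovery at 100 hospitals × 200
cases ($\hat\tau \in [0.15, 0.25]$ for truth 0.2, rank correlation of
intercepts > 0.9), null categorization at 100 hospitals with 200 bootstrap
replicates averaged over 5 seeds, and the scheme-ordering study at
$n = 8{,}000$ — sizes chosen so each property is sharply testable on a
single CPU. IRLS tolerance is 1e-9 on the relative step, 100 iterations;
the hierarchical loop stops when coefficients and intercepts move less than
1e-6 (relative) and $\tau$ less than 1e-4; glmnet paths stop early once the
active set exceeds the cap comfortably. Ties in quantile binning are broken
by stable input order; synthetic payments make exact ties essentially
impossible but integer fixtures do not.

## Known limitations

Selection inference is intentionally naive: reported SEs and p-values come
from the refit GLM and are not adjusted for the selection path. The
hierarchical estimator is a working-model approximation, adequate for
profiling but not a substitute for integrated-likelihood inference about
$\tau$. The CLI surface is the R API plus `run_pipeline()` over a YAML
config; there is no shell subcommand layer. And the toy crosswalk is a
stand-in: analyses of real claims must supply the licensed tables.
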