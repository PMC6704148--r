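---
title: "Cross-comparing multigene breast cancer signatures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-comparing multigene breast cancer signatures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigcordance)
library(dplyr)
```

## The problem

Multigene expression signatures divide early breast cancer either into
molecular subtypes (gene expression phenotypes such as luminal A/B,
HER2-enriched, basal-like) or into prognostic risk classes (low /
medium-intermediate / high). Many such classifiers exist, they are built
from different genes and different mathematics, and in routine practice a
patient is managed within a clinical stratum defined by
immunohistochemistry (ER, PR, HER2), nodal status and the adjuvant
treatment actually given. Two questions then matter: do different
signatures agree on individual patients within such strata, and does any of
them still carry prognostic information after accounting for the standard
clinicopathological covariates?

sigcordance implements that comparison as a reusable pipeline:

1. a seeded synthetic cohort generator with the statistical structure the
   downstream stages assume, so everything is testable without any data
   download;
2. a classification engine covering four mathematical families of
   signature model, driven entirely by external configuration files;
3. stratification into nine adjuvant clinical assessment groups;
4. pairwise exact-agreement statistics, agreement-chart geometry and
   consensus voting;
5. Kaplan-Meier / log-rank / Cox outcome analysis per signature class
   within each stratum.

## The synthetic cohort generator

Each patient carries a latent molecular subtype drawn from
`subtype_proportions` (defaults LumA .45, LumB .20, HER2E .12, Basal .12,
Normal .11 — approximations to the subtype mix of unselected early breast
cancer; published proportion figures for such cohorts are graphical, so
these are stated as approximations, not transcriptions). Subtypes activate
expression *axes* — blocks of genes for ER signalling, HER2, proliferation
and basal biology. A sample's expression is

    x_gs = baseline_g + axis_effect * activation(subtype_s, axis(g)) + N(0, noise_sd)

on the log2(FPKM + 0.1) scale. The 0.1 offset keeps zero-FPKM values
finite and is configurable. The gene baseline is a fixed deterministic
grid (2–10 log2 units), *not* drawn from the seed, so that
`expected_profiles()` — the noise-free subtype mean profiles — is a closed
form of the parameters; the zero-noise recovery tests and the
generator-aligned toy models both rely on that. HER2-enriched tumors also
activate the proliferation axis at half strength; every subtype therefore
has a distinct activation pattern, which makes zero-noise recovery exact.

Clinical fields are drawn consistently with the latent subtype:

* **ER IHC %** is drawn above the 10% positivity cutoff with a per-subtype
  probability (defaults .99/.99/.75/.05/.99 for LumA/LumB/HER2E/Basal/
  Normal). A flat "5% label noise on luminal = ER+" rule cannot reach the
  84.2% ER-positive marginal of a population-based series with this
  subtype mix (it caps near 73%), so the per-subtype probabilities are the
  primitive: basal-like keeps ~5% discordance, and the HER2-enriched value
  reflects the roughly 70/30 ER+/ER− split observed among HER2-positive
  tumors in registry data.
* **Age** is normal (mean 65, sd 12) truncated to 25–100 (median target
  65); **tumor size** log-normal with median 17 mm; **grade** 1/2/3 at
  15/47/36% with 2% missing; **nodal status** node-negative with
  probability .59, positive patients receiving 1 + Poisson(1.2) nodes.
* **Adjuvant treatment** is sampled conditional on marker group
  (ER+/HER2−/LN±, HER2+/ER±, TNBC) from registry-style percentages — e.g.
  endocrine-only 71% in ER+/HER2−/LN−, chemotherapy-only 70% in TNBC,
  anti-HER2 + chemotherapy 79% in HER2+/ER−. Treatment never depends on
  outcome (no confounding by indication), which keeps the survival
  recovery tests interpretable.
* **Overall survival** is exponential with hazard
  `baseline_hazard * exp(log_hazard_per_risk_unit * risk)`, administratively
  censored at `followup_years`. The latent risk is the standardized
  per-sample mean of the proliferation axis. Defaults: 0.03 events/year,
  log-HR 0.69 per risk unit (hazard ratio 2 — a conventional effect size),
  8-year horizon, giving roughly 20–25% events. No published per-subtype
  survival parameters exist for this structure; the hazard defaults are
  free parameters of the generator, chosen once as plausible for a
  contemporary cohort, and are not estimates of any real series.

What the generator deliberately does **not** emulate: read-level count
noise (the negative-binomial mean-variance structure of RNA-seq),
gene-gene correlation beyond the block structure, copy number, mutations,
competing risks, or outcome-dependent treatment. Passing tests therefore
demonstrate the correctness of the *statistical machinery* on data with
the assumed structure, not classifier performance on real tumors.

## Signature model families

Published signature coefficients are not reprinted anywhere in this
package; models are external YAML artifacts, and the bundled parameter
sets are self-consistent toys, clearly labelled non-clinical. The schema
covers:

* **`centroid_subtype`** — nearest-centroid calls: each sample is assigned
  the class whose centroid it correlates with most strongly. Spearman by
  default (robust to monotone distortions of a single sample's profile),
  overridable per model. Exact ties take the first class in declared
  order.
* **`ror`** — the risk-of-recurrence family:
  `score = intercept + a * sum_k(w_k r_k) + b * P + c * size_cm`, with
  `r_k` the per-class Pearson correlations, `P` the mean median-centered
  proliferation-module expression, and the size term in cm. Variants
  S/P/T/PT/Tot enable the terms; Tot is the PT form scored against
  lymph-node-specific cutpoints.
* **`linear_risk`** — recurrence-score style weighted module sums with
  optional clip-at-zero terms (`max(f_m - tau, 0)`) and an affine output
  rescale.
* **`correlation_risk`** — correlation to a single template profile,
  dichotomized at a threshold (good-prognosis class at or above it).
* **`module_subtype`** — a deterministic tree over ER/HER2/proliferation
  module means: HER2 first, then ER (split into low/high proliferation
  luminal classes), else basal-like.

Reference-set centering subtracts each gene's *median* over a declared
reference subset (median rather than mean for robustness);
`choose_reference_set()` draws an ER-stratified seeded subsample, with the
stratification fraction configurable because the composition of such
reference sets is conventionally described only as "similar" to the
training population.

Risk cutpoints are right-closed upward: a score exactly at a cutpoint
takes the higher class. The convention is arbitrary but must be fixed;
it is documented here and tested at the boundary. Any input needed by a
model that is missing yields an NA call — never silent imputation.

## Stratification

ER and PR positivity follow the Swedish IHC convention (≤10% staining is
negative, strictly >10% positive). The nine assessment groups are
TNBC±chemotherapy, HER2+/ER− and HER2+/ER+ with anti-HER2-based regimens,
and five ER+/HER2− strata split by nodal status and endocrine ±
chemotherapy, with one untreated LN− group. "Untreated" means all three
adjuvant flags are zero; any other combination — including mixed regimens
and records with missing markers or flags — falls to `NONE`, so the ten
labels always partition the cohort. Sub-micrometastasis handling is
exposed through the node-count threshold of `derive_markers()` (default:
≥1 positive node is node-positive).

## Agreement and consensus

Exact agreement is the raw diagonal percentage of the pairwise
contingency table; no chance correction is applied anywhere. Comparisons
are *pairwise-complete*: a sample missing either call is dropped from
that pair only, not from the whole panel — this changes denominators
relative to listwise deletion and is therefore stated explicitly. The
intermediate-omission variant drops any sample called intermediate by
either signature before counting; two-class signatures simply contribute
all their samples.

The agreement chart follows the Bangdiwala construction: for ordered
classes, rectangle k spans the cumulative marginal totals of the two
classifiers; a black square of side `count[k,k]` (exact agreement) sits
offset by the within-margin totals of the previous levels; a gray zone
spans the cells at most one level off; white is disagreement by more than
one level. Geometry is emitted in counts with origin bottom-left, so the
tests can assert coordinates exactly; rendering rescales.

Consensus voting calls a sample unanimous-low/high only when *every*
signature in the panel agrees; the panel is an argument because reasonable
panels differ. Unanimity is bounded above by every pairwise agreement (a
set-inclusion fact), which the tests assert on random tables.

## Survival analysis

Kaplan-Meier, log-rank and Cox fits delegate to the survival package;
ties use the Efron approximation (ties are certain in registry-scale data
with rounded follow-up). The Cox models use the signature class with the
low-risk class as reference, plus tumor size (mm), age (years), nodal
status (positive/negative) and grade; grade enters categorically with
grade 1 as reference rather than ordinally, because an ordinal coding
asserts equal spacing that nothing justifies. Covariates are
complete-case with the dropped count reported; covariates constant within
a stratum (nodal status in an LN-homogeneous group) are dropped
automatically. Classes smaller than 8% of the stratum's non-NA calls are
excluded from multivariable analysis — strictly smaller, so a class at
exactly 8% stays. Monotone-likelihood separation (e.g. one event total)
is flagged `converged = FALSE` rather than reported as a huge finite
hazard ratio. Groups enter outcome analysis only with at least 10 events
(configurable); published analyses of this kind exclude strata on
combined size/event/bias grounds without a stated numeric cutoff, so a
simple event floor is used and exposed.

## Numerical and testing choices

* All simulation randomness flows through a single integer seed per
  parameter set (`withr::with_seed`), so a cohort is a pure function of
  its parameters; pipeline outputs embed the seed and a config hash and
  re-running a config reproduces files byte for byte.
* Every scoring operation is tested against an independent naive
  re-implementation (explicit loops over the defining formulas) at
  tolerance 1e-10 or better; chart geometry against explicit cumulative
  sums at 1e-12.
* Calibration checks run at reduced replicate counts in the unit suite
  (200 null log-rank simulations, 15–30 Cox replicates) and at full scale
  in the acceptance script (1000 null simulations of n = 200; 100 Cox
  replicates at n = 2000; Kaplan-Meier versus the exponential closed form
  at n = 5000; 1000 random tables for the concordance oracles). These
  sizes keep the default check fast while the acceptance run exercises
  the stated operating characteristics.
* The end-to-end acceptance run uses the generator's default 3520-patient
  cohort with the generator-aligned toy panel.

## Limitations

The bundled models are toys: nothing here validates any published
signature's clinical coefficients, and agreement or hazard-ratio values
computed on synthetic cohorts characterize the pipeline, not commercial
assays. Overall survival is the only endpoint; there are no competing
risks and no time-varying effects. The generator's Gaussian log-scale
noise understates the heavy tails of real RNA-seq, so planted-subtype
recovery rates are optimistic relative to real cohorts.
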