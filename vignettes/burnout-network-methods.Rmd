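---
title: "Methods: inferring colleague networks from burnout surveys and modelling homophily"
author: "burnoutnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burnout network inference and ERGM homophily}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnoutnet)
```

## The scientific problem

Occupational burnout is usually measured by self-report scales, but staff
have incentives to conceal it, and burnout-adjacent characteristics —
demographics, work role, health status, lifestyle — are easier to observe.
The analysis chain implemented here asks whether those characteristics,
alone, carry a network-level burnout signal: respondents are embedded as
standardized feature vectors, a colleague network is inferred by linking
respondents with high cosine similarity, and an exponential random graph
model (ERGM) then tests whether sharing a burnout status makes an edge
more likely (homophily).

The motivating setting is a cross-sectional occupational-health survey of
a large airport company (5,794 valid respondents of 6,689 returned
questionnaires; 728 scored at high burnout risk). The raw microdata are
not public, so the package ships (i) the published group-level descriptive
statistics as a reference table, `cohort_reference()`, and (ii) a
synthetic cohort generator with the same structure, so that every stage is
runnable and testable.

## Burnout scoring (MBI-GS)

The Maslach Burnout Inventory – General Survey has 16 items on a 0–6
scale in three subscales. This package fixes the standard layout — five
emotional-exhaustion items, five cynicism items, six professional-efficacy
items — computes subscale means, and labels a respondent *high* burnout
when **two or more** subscale scores strictly exceed their critical
boundaries (`score_mbi()`). Two conventions were genuinely open and are
therefore configurable:

* **Efficacy reversal.** Professional efficacy is protective; by default
  the reversed score `6 − mean` is compared against the third boundary, so
  low efficacy counts toward burnout. The unreversed comparison is
  available (`efficacy_reversed = FALSE`).
* **Boundaries.** Critical boundaries are study-group calibrations and no
  public values exist for this cohort; the default `c(3, 3, 3)` is the
  scale midpoint and is shared with the synthetic item generator so that
  generation → scoring round-trips are self-consistent.

Ties are not exceedances (strict inequality), and scoring is monotone:
raising an exhaustion item can never flip a high label to low.

## Association screening

Each variable is tested against the burnout label with the tests
appropriate at cohort scale: the **uncorrected** Pearson chi-squared test
for categorical variables and the Wilcoxon rank-sum test (normal
approximation, midranks, tie-corrected variance, continuity correction)
for numeric ones. The uncorrected chi-squared convention is not arbitrary:
the recomputable two-digit p-values in the reference cohort's descriptive
table (high blood pressure 0.09, overweight 0.07, sex 0.11, smoking 0.08,
marital status 0.01) are reproduced without the Yates correction and not
with it (the high-blood-pressure cell computes to ≈0.11 corrected,
≈0.093 uncorrected). Expected counts below 5 warn rather than error —
the reference table itself reports tests on levels with expected counts
near 2. No multiple-testing correction is applied, matching the source
analysis; the screen (`screen_variables()`) selects variables at
`p < alpha` (default 0.05) grouped into the four categories.

An exact-enumeration Wilcoxon path (`exact = TRUE`) exists for tiny
untied samples and is used as a test oracle; the approximation is the
analysis path.

## Survey2Vector encoding and network inference

Respondent *i* becomes a vector $X_i \in [0,1]^n$:

* numeric variables are min–max scaled using the observed range
  ("standardizing" must land in $[0,1]$, which rules out z-scores);
* ordinal variables map their level index to equally spaced codes
  $0, 1/(L-1), \dots, 1$, preserving order;
* nominal and binary variables become one-hot indicators, under which
  cosine similarity reduces to shared-level matching — the natural
  homophily notion for unordered categories.

Constant columns are dropped with a warning (they carry no similarity
information); an all-constant selection is an error.

Similarity is the cosine
$S_{ij} = X_i \cdot X_j / (\lVert X_i\rVert\,\lVert X_j\rVert) \in [0,1]$,
and the network links $i$ and $j$ when $S_{ij} \ge t$ (ties at $t$
included). The reference analysis used $t = 0.7799$, chosen there to match
an average number of colleagues estimated by the company's HR director;
the estimation procedure itself was never specified, so this package
implements the intent as a deterministic quantile calibration:
`calibrate_threshold()` returns the largest $t$ whose thresholded network
reaches a target average degree — the off-diagonal similarity of rank
$\lceil N\bar d/2 \rceil$ — which is within one edge-quantum ($2/N$) of
the target when similarities are distinct. Whether all variables or only
screened ones feed the encoder is a configuration choice
(`feature_mode`), because the source description is ambiguous on this
point; the default uses the screened set. The full $N \times N$ matrix is
materialized densely; at $N \approx 5{,}800$ this is ~270 MB, fine on a
workstation, and no sparse path is provided.

## The ERGM

For a network $y$ with node attributes $X$ the model is
$P(Y = y \mid X) = \exp\left(\sum_a \theta_a g_a(y, X)\right) / \kappa$,
with the term set used throughout: `edges` (edge count),
`nodefactor("burnout")` (number of edge endpoints at the high level, the
degree main effect; base level low, configurable), and
`nodematch("burnout")` (number of edges whose endpoints share a status —
homophily). The change statistics for a dyad depend only on its endpoint
statuses: $(1, 0, 1)$, $(1, 1, 0)$, $(1, 2, 1)$ for low–low, low–high,
high–high.

**Exact fit.** All three terms are dyad-independent, so the likelihood
factorises over the $D = N(N-1)/2$ unordered dyads and the MLE is an
ordinary logistic likelihood. `fit_exact()` collapses the dyads into the
three attribute-pair patterns and runs Newton–Raphson on the collapsed
binomial likelihood to tolerance $10^{-12}$; the log-normalizer
$\log \kappa = \sum_{\text{dyads}} \log(1 + e^{\theta\cdot\delta})$ is
closed-form. Standard errors come from the inverse observed Fisher
information, p-values are two-sided normal (Wald), and
$\mathrm{AIC} = 2k - 2\ell$, $\mathrm{BIC} = k \ln D - 2\ell$. Using the
dyad count as the BIC sample size is deliberate: at $N = 5{,}794$ and
$k = 3$ it gives $\mathrm{BIC} - \mathrm{AIC} = 3(\ln D - 2) = 43.9$,
consistent with the published gap of 44 between the two reported criteria.
Separation (a pattern with all or no edges present) is reported as a
non-converged fit with a diagnostic naming the pattern, never silently.

**MCMC-MLE.** The source analysis names Markov-chain Monte Carlo maximum
likelihood, so the package provides it even though the exact fit already
maximises the true likelihood for these terms: a tie-flip Metropolis
sampler (`mh_sampler()`, implemented in C++ for throughput) proposes
toggling a uniformly random dyad and accepts with probability
$\min(1, e^{\theta\cdot\delta})$; `fit_mcmcmle()` runs the Geyer–Thompson
iteration initialised at the exact fit, maximising the importance-sampled
log-likelihood-ratio approximation at each step. Defaults: burn-in
$10D$ toggles, thinning interval $D$, 1,000 retained samples, update
tolerance $10^{-4}$, at most 20 iterations. The tolerance is below the
Monte-Carlo noise floor at the default sample size, so runs typically
stop at the iteration cap with a diagnostic noting that the final update
is within MCMC noise — an honest description of a sampler hovering at the
optimum. Effective-sample-size collapse or observed statistics outside
the sampled range are flagged as degeneracy, not returned as answers.

**Model comparison.** `compare_models()` reports AIC and BIC for the zero
model (edges only, the control) and the node-attribute model, selects the
lower, and flags ties and criteria disagreement rather than forcing a
choice.

## The synthetic cohort generator

`default_schema()` reproduces the reference cohort's variable structure:
age and weekly walking time as numeric variables plus 32 categorical
variables across the demographic, work-related, health, and lifestyle
categories, with marginal probabilities computed from the published
group-level counts (the group columns are self-consistent; the printed
overall column contains typos, e.g. a professional-grade row and a
self-rated-health row that disagree with the group sums, so group counts
are authoritative throughout). `generate_survey()` draws the burnout label
Bernoulli at the configured prevalence — default $728/5{,}794 \approx
0.126$ — then each variable from its marginal, tilted for high-burnout
respondents:

* categorical levels receive per-level **log-odds shifts**
  ($p^{\text{high}}_\ell \propto p_\ell e^{e_\ell}$), so zero effects give
  an exact null — convenient for calibration testing and composable with
  the logistic machinery elsewhere;
* numeric variables are drawn from a normal truncated to the schema range
  (bounded, unimodal, and simple — only medians and IQRs are published,
  so the family is our choice), with a location shift expressed as a
  fraction of the range.

`cohort_effect_sizes()` converts the published group distributions into
this parameterisation (log of the high/low probability ratio per level,
0.5-smoothed; median difference over range for numeric variables), giving
burnout contrasts of realistic magnitude. `generate_mbi_items()` draws
item responses whose subscale means sit `separation` (default 1.5) points
beyond the boundaries on the appropriate side, with between-respondent SD
0.7 and item SD 0.8; at these defaults scoring recovers the generating
label for ≳99% of respondents.

What the generator does **not** emulate: the joint dependence structure
among covariates (variables are conditionally independent given burnout
status), invalid-questionnaire behaviour (the reference study excluded
895 responses by unstated criteria), and any true underlying social
network. Consequently, passing tests demonstrate that the *machinery* is
correct and that the chain detects structure it generates — not that the
inferred network of any real cohort is accurate, a caveat the source
analysis itself makes.

## Numerical and testing choices

* Cosine similarities are clamped to $[0,1]$ and symmetrised against
  floating-point drift; a zero-norm feature vector is an error naming the
  respondent.
* Threshold calibration and thresholding use the $\ge$ rule everywhere,
  so ties at the threshold can only add edges.
* Newton fits flag non-convergence when coefficients exceed 15 in
  magnitude (empty/full patterns drive estimates to $\pm\infty$).
* Validation checks run at deliberately modest sizes chosen for a
  single-CPU workstation: the MCMC/exact consistency check uses a
  200-node network simulated at the reference coefficient values
  $(-4.65, -0.14, 0.09)$ with a 50/50 status composition — at the cohort
  prevalence the expected high–high edge count at those coefficients is
  ~2, which would risk separation, and the composition of a synthetic
  check network is free; parameter recovery uses 100 replicates at
  $N = 500$; the null-calibration check uses 1,000 synthetic null
  variables with all level probabilities ≥ 0.05, because levels at 0.3%
  prevalence (present in the realistic schema) would invalidate the
  chi-squared approximation itself at feasible sample sizes and the check
  targets the screen's calibration, not small-sample chi-squared
  behaviour.

## Limitations

The inferred network is a similarity graph, not an observed social
network; homophily estimated on it reflects the encoding and threshold as
much as any social process. Only dyad-independent ERGM terms are
supported (no triangles, no curved terms, no directed networks), missing
cells are rejected rather than imputed, and the exact reproduction of the
reference study's coefficient table is out of reach without its raw data
— the package instead reproduces every quantity that is recomputable from
published material and validates the estimators by simulation.
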