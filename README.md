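# burnoutnet

Occupational-burnout risk analysis via inferred colleague networks.

Burnout is routinely measured with self-report scales (the Maslach Burnout
Inventory – General Survey, MBI-GS), but employees tend to under-report
it. This package implements an alternative, network-based analysis chain
for workplace survey cohorts, aimed at occupational-health researchers and
biostatisticians:

1. **Score** burnout from 16 MBI-GS items: subscale means for emotional
   exhaustion, cynicism and (reversed) professional efficacy, with a
   respondent labelled high-risk when ≥ 2 subscale scores exceed their
   critical boundaries.
2. **Screen** survey variables (demographic, work-related, health,
   lifestyle) for association with burnout: uncorrected Pearson
   chi-squared tests for categorical variables, Wilcoxon rank-sum tests
   for numeric ones, with the standard cohort descriptive table as output.
3. **Infer** a colleague network (*Survey2Vector*): each respondent
   becomes a vector `X_i ∈ [0,1]^n` (min–max scaled numerics, equally
   spaced ordinal codes, one-hot nominals); respondents are linked when
   their cosine similarity

   `S_ij = (X_i · X_j) / (‖X_i‖ ‖X_j‖)`

   reaches a threshold `t` (fixed, e.g. the reference value `t = 0.7799`,
   or calibrated to a target average degree).
4. **Model** the network with an exponential random graph model,

   `P(Y = y | X) = exp( Σ_a θ_a g_a(y, X) ) / κ`,

   with terms `edges`, `nodefactor(burnout)` and `nodematch(burnout)`
   (homophily). All three terms are dyad-independent, so the MLE is
   computed exactly (collapsed-pattern Newton–Raphson); an MCMC
   maximum-likelihood path (tie-flip Metropolis + Geyer–Thompson) is
   provided and cross-checked against it. The edges-only "zero" model and
   the node-attribute model are compared by AIC/BIC
   (`BIC = k ln D − 2ℓ`, `D = N(N−1)/2` dyads).

Because the motivating airport-staff cohort (N = 5,794, 728 high-risk) is
not publicly available, the package ships the published group-level
descriptive statistics (`cohort_reference()`) and a synthetic cohort
generator (`default_schema()`, `generate_survey()`, `generate_mbi_items()`)
with the same structure, so the entire chain is runnable and testable.

## Worked example

```r
library(burnoutnet)

sch <- default_schema()
cfg <- simulation_config(1500, burnout_prevalence = 728 / 5794,
                         effect_sizes = cohort_effect_sizes(sch), seed = 1)
survey <- generate_survey(sch, cfg)

scr   <- screen_variables(survey, sch, alpha = 0.05)
feats <- encode_features(survey, sch, unlist(scr$selected))
sim   <- cosine_similarity_matrix(feats)
net   <- threshold_network(sim, 0.7799, status = survey$burnout)

fit0 <- fit_exact(net, ergm_spec("edges"))
fit1 <- fit_exact(net, ergm_spec())
print(fit1)
compare_models(fit0, fit1)
```

On the synthetic full-size cohort (N = 5,794 simulated with the
reference-cohort effect sizes, 1,500-respondent subcohort for the network
stage; see `analysis/`), this prints:

```
ERGM fit (exact_dyad): 1500 nodes, 1.12425e+06 dyads
                        Estimated value (Std. Error) Z-value p-Value
edges                                   -3.94 (0.03) -130.32  <1e-04
nodefactor.burnout.high                  0.02 (0.03)    0.69  0.4876
nodematch.burnout                        0.17 (0.03)    5.58  <1e-04
AIC: 237134   BIC: 237170   logLik: -118564.2
           model k    loglik      aic      bic
1           zero 1 -118607.7 237217.3 237229.2
2 node_attribute 3 -118564.2 237134.5 237170.3
selected: node_attribute (lower AIC and BIC)
```

Read: at this threshold the inferred network has density
`plogis(-3.94) ≈ 0.02`; the positive, strongly significant
`nodematch.burnout` coefficient (0.17, p < 1e-04) means two respondents
sharing a burnout status are more likely to be linked — burnout homophily
— and the node-attribute model beats the edges-only control on both
criteria.

## The analysis workflow

`analysis/` contains the numbered stage scripts, each a thin driver over
the package that prints what it found and writes its tables under
`results/`:

| script | what it does |
|---|---|
| `analysis/01_simulate.R` | simulate the full-size synthetic cohort + MBI items |
| `analysis/02_screen.R`   | descriptive table, association screen, reference p-values |
| `analysis/03_network.R`  | Survey2Vector encoding, cosine matrix, thresholding & calibration |
| `analysis/04_ergm.R`     | zero vs node-attribute ERGM, MCMC-MLE consistency, predictions |

`run_pipeline()` performs the same chain end-to-end from one seeded
config (YAML/JSON or list), stamping all artifacts with a config hash.

See `vignettes/burnout-network-methods.Rmd` for the model, the design
decisions (scoring boundaries, uncorrected chi-squared, threshold
calibration, BIC sample size) and the generator's scope.

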