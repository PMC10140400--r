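Package: burnoutnet
Title: Occupational-Burnout Risk Analysis via Inferred Colleague Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying occupational burnout in workplace cohorts
    from survey data alone: Maslach Burnout Inventory - General Survey
    (MBI-GS) scoring, chi-squared and Wilcoxon rank-sum association
    screening, inference of a colleague social network by thresholding
    cosine similarities between respondents' standardized feature vectors
    (Survey2Vector), and exponential random graph models (ERGM) with
    edges, nodefactor and nodematch terms fitted by exact dyad-independent
    maximum likelihood or Markov chain Monte Carlo maximum likelihood.
    Includes a synthetic survey generator emulating a large airport-staff
    occupational-health cohort so the full chain is testable without
    access to restricted survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
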