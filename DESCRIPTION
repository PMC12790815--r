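Package: ckgmed
Title: Causal Knowledge Graph Mediation Analysis for Adverse Drug Effect Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds drug-disease causal knowledge graphs (typed edges for
    disease progression, drug indications, side effects and the ICD-10 is_a
    hierarchy, with a marked causal relation subset and an empirical
    population probability measure), generates drug-mediation hypotheses from
    progression edges or cohort comorbidity statistics, filters hypotheses
    contradicted by graph knowledge or lacking cohort support, identifies
    adjustment sets by the backdoor and disjunctive cause criteria on the
    causal subgraph, shrinks them with cross-validated LASSO, and estimates
    the average causal mediation effect (natural indirect effect) of each
    drug by quasi-Bayesian simulation with heteroskedasticity-consistent
    standard errors and Benjamini-Hochberg correction. Includes a synthetic
    longitudinal cohort generator with planted mediation effects and
    ground-truth oracles so every stage is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    glmnet,
    sandwich,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
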