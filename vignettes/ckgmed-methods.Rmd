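---
title: "Methods: knowledge-graph-driven causal mediation analysis of drug effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: knowledge-graph-driven causal mediation analysis of drug effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ckgmed)
```

## The problem

Post-marketing drug surveillance asks whether a drug, prescribed for one
disease, contributes causally to the onset of another. In observational
cohort data this question is confounded twice over: the indication itself
progresses to downstream disease, and sicker patients both receive more
drugs and develop more conditions. `ckgmed` frames the question as a
*mediation* problem — does the drug mediate the association between its
indication and the downstream disease? — and automates three steps that are
usually manual: posing hypotheses consistent with background knowledge,
identifying adjustment sets from an explicit causal structure, and
estimating the mediated effect with multiplicity control.

## The causal knowledge graph

The background knowledge lives in a typed directed multigraph over disease
(ICD-10) and drug (RxNorm) nodes with four relations: `progression`
(disease leads to disease), `indication` (drug is prescribed for disease),
`side_effect` (drug is documented to cause disease) and `is_a` (ICD-10
hierarchy). Two relation types are read causally: progression edges, and
the *inverse* of indication edges — a diagnosis leads to a prescription.
These form the causal subgraph, which must be a DAG; `load_graph()`
validates acyclicity (of both the causal subgraph and the hierarchy),
endpoint kinds, and deduplicates triples.

A cohort turns the graph into a probability space. `assign_population()`
maps each disease node to the set of persons ever diagnosed with it *or
with any `is_a` descendant* — the subsumption constraint `f(child) ⊆
f(parent)` is enforced by construction — and each drug node to the persons
ever prescribed it. The measure is relative frequency. Lifetime
(ever/ever) record presence is used throughout, matching the binary
treatment/mediator/outcome encoding of the models; internal disease
identifiers are normalized (dots stripped, uppercased) so cohort dialects
compare equal, and the default hierarchy is code → 3-character category
unless a fuller `is_a` table is supplied.

## Hypothesis generation and filtering

Candidate triples (indication x, drug M, outcome y) come from two sources:

* **causal set** — the progression edges of the graph, each paired with
  every drug indicated for the source disease;
* **comorbidity set** — disease pairs significantly co-occurring in the
  cohort. For each co-occurring pair the relative risk is
  `RR = n_both * n_total / (n_a * n_b)`; enrichment is tested with a
  one-sided Fisher exact test on the person-level 2×2 table and corrected
  by Benjamini–Hochberg over all tested pairs in the run. Significant
  pairs are oriented by first-diagnosis dates; a strict majority is
  required and exact ties drop the pair. The exact test was chosen because
  it remains valid for the sparse pairs that dominate claim-style data;
  the orientation tie rule is ours, since "majority" alone does not
  resolve ties.

Two contradiction filters then remove triples the graph itself explains
without mediation: the drug indicated for *both* diseases (treatment
overlap), and both diseases listed as side effects of one drug (a shared
downstream effect). A support filter removes triples whose drug or
diseases never appear in the cohort or for which no person carries all
three components in valid temporal order. The filters commute, and the
contradiction predicates give identical answers when evaluated over the
package's sorted N-Triples export of the graph — the export exists so the
same filter can be run as a query against an external triple store.

## Temporal validity and encoding

For each hypothesis, `apply_temporal_validity()` builds the analysis table:
persons without follow-up are excluded; persons whose outcome preceded the
indication or the drug are excluded; persons whose drug use occurred *only
before* the indication diagnosis are excluded (operationalized as
`max(prescription dates) < min(indication dates)`; same-day events count
as valid order, because same-visit prescribing is routine). Survivors are
encoded as binary T (indication ever), M (drug ever), Y (outcome ever).
Persons with M = 1 but T = 0 are retained — the mediator model needs them.
Severity proxies (distinct 3-character diagnosis categories; distinct
drugs prescribed) are computed over the whole record; restricting them to
pre-treatment records is a defensible alternative we did not take, for
want of a principled per-hypothesis cut date.

## Adjustment sets

For each hypothesis the causal subgraph is augmented with the single edge
drug → outcome (the hypothesized effect); an augmentation that would close
a cycle marks the hypothesis untestable. Two criteria are implemented:

* **Backdoor.** Candidate sets are enumerated in increasing cardinality,
  then lexicographic order, over nodes that are neither descendants of the
  treatment, nor the outcome, nor the mediator drug; a set is accepted
  when it d-separates treatment and outcome in the graph with the
  treatment's outgoing edges removed. The first acceptable set is
  therefore a minimum-cardinality valid set, with ties broken by first
  encounter; enumeration stops after 1000 candidate sets. Because minimal
  d-separators lie within the ancestors of the treatment and outcome,
  enumeration is restricted to those ancestors — this does not change the
  chosen set but keeps the cap from binding on large graphs. The
  enumeration order is our own deterministic convention: "first
  encountered" is only reproducible relative to a stated order.
* **Disjunctive cause.** The union of the DAG parents of treatment and
  outcome, excluding treatment, outcome and mediator.

The backdoor pair is (indication, outcome) on the augmented graph, and the
mediator drug is never admitted into a set: sequential ignorability wants
pre-treatment covariates, and the drug is the exposure whose effect the
outcome model estimates. When a set contains a disease and one of its
`is_a` ancestors, the descendant is pruned (transitively, so a three-level
chain collapses to its root). `d_separated()` implements standard
d-separation by the moralized-ancestral-graph reduction and is validated
exhaustively against a path-enumeration oracle.

## LASSO covariate selection

Graph-derived adjustment sets can be large. `select_covariates()` fits an
L1-penalized regression of each target (indication; outcome) on the
candidate covariates — logistic loss for the binary targets here, although
the identity-link objective is used automatically for continuous ones —
choosing λ to minimize 10-fold cross-validated deviance with fold
assignment fixed by a seed. Covariates are standardized to unit variance
internally and reported on the original scale. The adjustment set used for
modeling is the union of the two selections. Demographics (sex, age,
ethnicity, BMI, plus lifestyle variables when present) and the severity
proxies are never penalized: they enter every model unconditionally. The
alternative — penalizing demographics alongside graph covariates — is
defensible; we kept them unconditional because they are the canonical
fixed confounder list for this design.

## The mediation estimator

With T the indication, M the drug and Y the outcome, the estimand is the
natural indirect effect `NIE = E[Y(0, M(1)) − Y(0, M(0))]`: the outcome
shift from moving the mediator between its treated and untreated
distributions with treatment at baseline. Estimation is regression-based:

1. mediator model `M ~ T + X` and outcome model `Y ~ T + M + X`, logistic
   links for binary responses, with a `T×M` interaction kept only when its
   HC3-robust Wald p-value is below 0.05;
2. coefficient covariances by the HC3 heteroskedasticity-consistent
   estimator (the "heteroskedasticity-consistent" family leaves the flavor
   open; HC3 is the conservative default for moderate samples);
3. 1000 quasi-Bayesian draws of both coefficient vectors from their
   asymptotic normal approximation; per draw and per observed covariate
   row, the mediator distribution under T = 0/1 and the potential-outcome
   expectations `E[Y(t, M(t'))]` are computed by **exact summation over
   the binary mediator** — the coefficient draw is the only stochastic
   element, which removes the Monte-Carlo noise that resampling mediator
   values would add;
4. ACME is reported at t = 0 and the average direct effect at t = 1, so
   the identity `total = ACME(0) + ADE(1)` holds exactly per draw;
5. the CI is the 2.5/97.5 percentile over draws; the p-value is the
   two-sided simulation tail probability `2·min(Pr(draws ≤ 0),
   Pr(draws ≥ 0))`, floored at 1/sims; the proportion mediated is the
   draw-median of ACME/total, robust to near-zero totals — it can be
   negative when direct and mediated effects oppose (suppression);
6. Benjamini–Hochberg over all testable hypotheses of a run; significant
   results are split into positive ACME (adverse-effect signal) and
   negative ACME (protective signal).

A continuous (Gaussian) mediator replaces the summation with the plug-in
mean, which is exact when the outcome model is linear in the mediator; a
continuous mediator with a binary outcome is refused rather than
approximated. Degenerate tables (constant T/M/Y), non-convergence and
separation mark the hypothesis untestable ("N/A") instead of erroring, so
one pathological hypothesis cannot stop a run. The p-value is taken from
the simulation distribution rather than a normal approximation; with the
1/sims floor this is slightly conservative near zero.

## The synthetic cohort generator

Real cohorts for this design are access-restricted, so the generator
defines the study conditions everything is tested under. Each hypothesis
block follows logistic structural equations

```
T ~ Bern(expit(-1.8 + 0.3·sex + 0.4·age_z + 0.3·bmi_z + 0.8·z))
M ~ Bern(expit(-2.2 + 2.0·T + 0.1·sex + 0.2·age_z + 0.1·bmi_z))
Y ~ Bern(expit(-2.5 + b·M + 0.3·T + 0.2·sex + 0.3·age_z + 0.2·bmi_z + 0.8·z))
```

with `b = 1.2` for planted adverse effects and `b = 0` for null blocks,
and `z` the count of two shared binary comorbidity-confounder diseases
(prevalence 0.3 each) that also appear in the companion graph as
progression parents of every indication and outcome — giving the backdoor
machinery genuine confounding structure to find. These defaults put the
indication prevalence near 0.15, prescription uptake near 0.45 among the
indicated, and the planted NIE near 0.07 on the probability scale: a
moderately strong ADR in a 10 000-person cohort, detectable but not
trivial. Dates are drawn uniformly in ordered windows (indication in the
first third of a 16-year study window, prescription after the indication,
outcome after both), so a generated cohort loses no one to the ordering
rules; decoy blocks exist for every filter (drug indicated for both
diseases; both diseases side effects of one extra drug; drug absent from
the cohort). The oracle `true_nie()` evaluates the NIE from the known
equations with an exact inner expectation, so its Monte-Carlo error comes
only from the confounder average.

A separate severity scenario plants the classic false-positive pattern: a
latent severity variable drives both prescription and outcome while the
drug is inert, and inflates the person's recorded comorbidity and
prescription counts. Adjusting for the two observable proxies shrinks the
spurious mediated effect by more than half in the packaged test — a
directional contrast, not a claim that proxies remove the bias entirely.

What the generator does *not* emulate: realistic ICD-10 epidemiology,
dose/duration effects, time-varying confounding, informative missingness,
or coding error. Passing the planted-truth tests therefore shows the
machinery is correct under its stated assumptions, not that those
assumptions hold in any particular cohort.

## Numerical choices and problem sizes

Fold assignment, coefficient draws and all generators are driven by
explicit seeds; identical seeds give byte-identical outputs, and the
pipeline derives per-hypothesis seeds from one master seed. The validation
suite runs at sizes chosen to make each check sharp but affordable:
d-separation against the path-enumeration oracle on 200 random DAGs of 4-8
nodes (every query triple); backdoor validity and minimality by full
subset enumeration on the same family; effect recovery at n = 5000 with
500-1000 draws; CI coverage and null calibration over 200 replicates;
global-null FDR over 50 replicates of 200 hypotheses at n = 250 with 100
draws (small n and draw counts only widen the null p-value granularity,
which is the conservative direction); and the end-to-end planted-truth run
at the generator's default 10 000 persons, 5 planted effects, 20 nulls and
6 filter decoys.

## Known limitations

* Identification rests on sequential ignorability; no sensitivity analysis
  for its violation is provided, and no front-door or instrumental-variable
  fallback exists when the backdoor search fails.
* The comorbidity orientation rule (majority of first-diagnosis dates) is
  a heuristic; reverse-causation pairs with close dates can survive it.
* Severity proxies are lifetime counts and treat all conditions equally;
  weighted indices would capture severity gradients better.
* The binary lifetime encoding ignores dose, duration and recurrence.
* With many hypotheses sharing one cohort, results are dependent across
  hypotheses; BH remains valid under the positive-dependence regimes
  typical here but is not guaranteed for arbitrary dependence.
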