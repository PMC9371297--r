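---
title: "Methods: network learning, inference and instantiation in negtetrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: network learning, inference and instantiation in negtetrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(negtetrad)
```

## The model

Every variable in the pipeline is binary with ordered levels
`("Low", "High")` — the published analysis reports only Low/High
probabilities, so multi-level support is deliberately out of scope. A
network is a DAG plus one conditional probability table (CPT) per node,
factorizing the joint as the product of `P(node | parents)`. Parent
configurations are enumerated lexicographically (first parent slowest,
Low before High), which makes CPT serialization bit-stable and gives
every table a canonical row order.

Topology labels follow the antecessor/node/predecessor reading of a
learned network: *top* variables have no parents, *bottom* variables no
children, everything else is an intermediate *node*. Isolated nodes are
classified top: antecessor status is defined by the absence of parents,
and that is the property an isolated node shares with the roots. The
bottom set is the object of interest — when it has exactly four members
the report flags it as the "Negative Tetrad" constellation; any other
size is reported as-is rather than forced to four.

## Parameter estimation

`fit_cpts()` estimates each CPT cell as `(n_jk + α) / (n_j + 2α)`.
Two settings matter:

* `alpha = 0` — maximum likelihood, the estimator implicit in the BIC
  score; an unobserved parent configuration falls back to (0.5, 0.5).
* `alpha = 1` (Laplace, the default) — used for every network that
  later answers inference queries. At n = 235 with several parents per
  node, zero cells are common under maximum likelihood, and a single
  zero cell can make an instantiation trace's conditional probabilities
  undefined. Smoothing keeps every CPT entry strictly inside (0, 1),
  which also yields the qualitative ceiling property discussed below.

The published analysis does not state its smoothing convention, so the
choice is exposed rather than hidden.

## Structure learning

The score is the natural-log BIC with "higher is better" sign, so the
search maximizes it; the score decomposes per family, and every edge
move is evaluated through the affected child's family delta only.
`tabu_search()` hill-climbs over add/delete/reverse moves that keep the
graph acyclic:

* at each iteration the best admissible move is applied *even if it
  worsens the score* — this is what lets Tabu escape local optima;
* the inverse of each applied move is forbidden for `tabu_length`
  iterations (default 10), with the standard aspiration exception for
  moves that would beat the incumbent best;
* equal-scoring moves are broken lexicographically by (child, parent,
  move type), and restart graphs are drawn from the configured seed, so
  a search is a pure function of (data, config);
* the run stops at `max_iterations` (default `10·|nodes|²`) or — since
  continuing a stagnated search only burns time — after
  `max(tabu_length, 10)` consecutive iterations without improving the
  incumbent, whichever comes first. The incumbent-best DAG across all
  iterations and restarts is returned.

`max_parents` is unlimited by default; it exists as a guard for very
small samples, where the `2^|parents|` configuration table outgrows the
data. No blacklist/whitelist constraints are implemented: the published
analysis does not report any.

## Exact inference

`posterior_marginal()` implements variable elimination: all CPTs are
converted to factors, evidence is sliced out, and the remaining
variables are summed out along a min-degree order with lexicographic
tie-break (determinism matters more than elimination-order optimality
at 18 nodes). Probabilities are carried in plain space — at these
network sizes the smallest intermediate values are far from underflow.
Evidence with probability zero raises an explicit inconsistent-evidence
error instead of returning NaN or a silent uniform: in practice this
only happens with unsmoothed CPTs, and the error says so.
`joint_enumeration()` provides the brute-force oracle (guarded to 20
nodes) against which elimination is tested.

A consequence worth stating: when every CPT entry is strictly interior,
every posterior is strictly interior too, so no instantiation sequence
can reach exactly 100% — the package reproduces the qualitative
impossibility of certainty, not as a special case but as arithmetic.

## Cross-validated validation

`cross_validate()` splits records into k = 10 deterministic folds
(sizes differing by at most one). Per fold the structure is re-learned
on the training split and CPTs refitted — honest cross-validation; a
`fixed_structure` switch learns the DAG once on all data and
cross-validates only the parameters, since the original report is
silent on which was done. Each held-out record is scored per node with
all its other variables as evidence; because the evidence covers the
whole Markov blanket, the posterior reduces to the node's own CPT row
times its children's rows, renormalized — an algebraic shortcut that is
exactly variable elimination and is tested against enumeration.

Predictions are pooled across folds (micro-average) before computing
metrics: with 235 records and skewed variables, per-fold metrics can
have empty cells, while pooled counts always sum to n. Sensitivity,
specificity and accuracy use the standard confusion-count formulas at a
fixed 0.5 threshold (no tuning); AUC is the rank-based concordant-pair
estimator with ties counted one half. The positive level defaults to
"High" and is exposed, because the published table's
sensitivity/specificity skew is consistent with the majority level
having been treated as positive — the package does not guess silently.

## The synthetic cohort

The study's raw data is not deposited, so the generator emulates it:

* **Structure.** The 18-factor ground-truth DAG encodes the published
  verbal description of the learned network — devaluation after error
  as the sole root feeding the frustration column, the worry branch of
  anxiety and the shame/future error factors; a controlled-motivation
  regulation triangle with external regulation feeding the anxiety
  branch; achievement burnout, concentration-disruption anxiety,
  amotivation and importance given to error as the four leaves. The
  full edge list was never printed, so this is a faithful-as-possible
  encoding, not a claimed reproduction.
* **Marginals.** Conditional probabilities are logistic in the number
  of High parents, `P(High | pa) = plogis(b0 + slope·n_high)`, with
  `slope = 2.2` (a strong, plausibly detectable dependence on the
  log-odds scale) and each node's intercept solved by `uniroot` so the
  *exact ancestral marginal* equals its target: the six published
  baselines (25% root, 67.23% worry, 29.33/37.89/19.28/23.04% for the
  four leaves) and design values in the 0.20–0.35 range elsewhere,
  matching the sample's reported low occurrence of negative states.
* **Items.** Each factor's Likert items are drawn from a normal with
  state-conditional means, rounded and clamped to the instrument's
  scale (17 frustration items on 1–7 split 4/4/4/5, 25 fear-of-error
  items on 1–5, 15 anxiety items on 1–4, 18 burnout items on 1–5, 12
  regulation items on 1–7). Means are separated by at least two
  standard deviations, so midpoint discretization recovers the latent
  state for the vast majority of records. The item-level distribution
  is entirely this package's choice — nothing item-level was published
  — and real questionnaire data (ordinal response styles, floor
  effects, reverse-coded items, missingness) is *not* emulated. Passing
  tests therefore demonstrate pipeline correctness, not that the
  pipeline would reproduce the published numbers on the real cohort.

Separate seeds drive state sampling and item noise, both derived from
the master seed by fixed offsets and logged in the run manifest.

## Preprocessing

Factor scores are plain item means (the original aggregation is
unstated; the mean is the convention for these instruments), and the
Low/High cut defaults to the scale midpoint `(min + max)/2` with ties
to Low — conservative for negatively-valenced variables. A median-split
is available by passing per-factor thresholds. Records with any missing
mapped item are dropped with a message; the original reports no
missing-data handling to mirror.

## Instantiation

`greedy_instantiation()` starts from the no-evidence posterior,
then repeatedly evaluates every remaining candidate instantiated to
High on top of the current evidence and accepts the best one if it
gains at least `min_gain` (default 0.001, i.e. 0.1 percentage point —
about where the published stepwise tables stop adding rows). Gains are
evaluated exactly, ties break by name, values are reported ×100. The
acceptance rule makes traces monotone by construction; whether the
original steps were chosen greedily or by theory-driven ordering is not
stated, so the per-step gains are recorded for audit. Candidates
default to all non-target variables and are always asserted High
(matching every Level row of the published tables); Low instantiation
exists behind a flag.

## Problem sizes and runtime choices

The shipped tests and the acceptance script use: 200 random networks of
up to 8 nodes for the elimination-vs-enumeration check; 20 replicates
of n = 5000 from a 5-node generator for structure recovery (skeleton
structural Hamming distance ≤ 2); n = 50 000 for parameter recovery
(max CPT error < 0.02); n = 2000 independent coins for the null AUC
calibration; and the full 18-node, n = 235 pipeline for the
study-scale, shape-level checks. These sizes give tight Monte-Carlo
bounds while keeping a complete run in the tens of seconds on one CPU.

## Known limitations

* Binary nodes only; no ordinal or Gaussian variables, no latent-class
  (EM) estimation, no dynamic networks.
* The BIC/Tabu search recovers skeletons reliably at n = 5000 in the
  recovery study, but at n = 235 the learned leaf set is sample-noise
  dependent — exactly why the pipeline reports the learned bottom set
  rather than asserting the ground truth's.
* Exact inference scales exponentially with treewidth; fine at 18
  sub-scales, not intended for hundreds of variables.
* The generator's calibration targets marginals, not the published
  conditional (step-gain) magnitudes, so instantiation traces match the
  published tables in format and mechanism, not in value.
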