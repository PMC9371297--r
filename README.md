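# negtetrad

Discrete Bayesian-network analysis of negatively-valenced psychological
variables in competitive sport — a reusable, tested R implementation of
the full questionnaire-to-network pipeline: Likert item simulation,
factor scoring and Low/High discretization, BIC-scored Tabu structure
search, conditional-probability estimation, exact inference, per-node
10-fold cross-validated classification, topology classification
(antecessor / node / predecessor), and greedy stepwise evidence
instantiation.

## The scientific problem

Sports psychologists measure athletes on batteries of Likert
questionnaires — psychological-need frustration, fear of error,
competitive anxiety, burnout, behavioural regulation — and want to know
not just which "negative" factors correlate, but which ones
probabilistically *precede* the others. A discrete Bayesian network
answers this: each sub-scale becomes a binary Low/High variable, a
directed acyclic graph G is learned from data by maximizing the
decomposable BIC score

    BIC(G) = Σ_v Σ_{j,k} n_jk ln(n_jk / n_j) − (r−1) q_v ln(N) / 2

(counts n_jk of child level k under parent configuration j; r = 2
levels; q_v = 2^|pa(v)| parent configurations) via Tabu search over edge
additions, deletions and reversals, and conditional probability tables
are estimated by (optionally Laplace-smoothed) counting. The network's
*bottom* variables — leaves that receive probabilistic influence but
pass none on — are the candidate "Negative Tetrad": the constellation of
achievement burnout, concentration-disruption anxiety, amotivation and
importance given to error. Greedy stepwise instantiation then asks how
far each leaf's posterior P(High) can be pushed by asserting other
variables High one at a time, the gain of each step identifying its
probabilistic drivers.

Because the original 235-sailor dataset is not public, the package ships
a calibrated synthetic-data generator: an 18-factor ground-truth network
whose structure encodes the published verbal description (devaluation of
sport after error as the sole antecessor, a regulation triangle, an
anxiety branch, the four tetrad leaves) and whose exact marginals are
solved to match the published baseline probabilities (e.g. 29.33% High
for concentration-disruption anxiety, 67.23% High for worry).

## Worked example

```r
library(negtetrad)

# a two-variable network: P(A=High)=0.3, P(B=High|A)=0.9/0.2
dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
bn <- new_discrete_bn(dag, list(
  A = new_cpt("A", character(0), c(0.7, 0.3)),
  B = new_cpt("B", "A", rbind(c(0.8, 0.2), c(0.1, 0.9)))))

p_high(posterior_marginal(bn, "B"))              # 0.41
p_high(posterior_marginal(bn, "A", c(B = "High")))  # 0.6585366

greedy_instantiation(bn, "B", candidates = "A")
#> Stepwise instantiation towards P(B = High)
#>  Step   Instantiated variable Level Value
#>     1 None (BN initial value)  High 41.00
#>     2                       A  High 90.00
#> stopped: exhausted
```

The 0.41 is the prior P(B = High) = 0.3·0.9 + 0.7·0.2; instantiating A
to High lifts it to the CPT row value 0.9, and the trace reports both on
the ×100 scale of the stepwise tables.

The full study-scale analysis (simulate 235 respondents, score and
discretize, learn, cross-validate, instantiate) is one call:

```r
res <- run_full_analysis(pipeline_config(out_dir = "results/run"))
res$report
#> Topology report
#>   top (antecessor): Burnout.PracDev, Error.Disturbance
#>   node:              ... (12 intermediate variables)
#>   bottom:            Anxiety.Concerns, Error.Important,
#>                      Frust.Competency, Reg.external
#>   bottom set of 4 -> Negative Tetrad
```

or, staged with inspectable intermediate tables under `results/`:

```sh
Rscript analysis/run_all.R
```

At n = 235 the learned leaves need not coincide with the ground truth's
(the generator's own bottom set is recovered as sample size grows); the
validation table quantifies per-node predictability — on the default
seed the median cross-validated AUC is 0.82.

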