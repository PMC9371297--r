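# Fixtures and independent oracles shared across the test files. The
# oracles deliberately avoid the code paths they check: cycle detection
# by explicit depth-first search, posteriors by filtering the enumerated
# joint, AUC by all-pairs counting, BIC by a non-decomposed evaluation.

LV <- c("Low", "High")

# A -> B chain with P(A=High) = 0.3, P(B=High | A) = 0.9 / 0.2.
chain_bn <- function() {
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  new_discrete_bn(dag, list(
    A = new_cpt("A", character(0), c(0.7, 0.3)),
    B = new_cpt("B", "A", rbind(c(0.8, 0.2), c(0.1, 0.9)))
  ))
}

# Random DAG edges over the given nodes: random topological order, each
# forward pair kept with probability p. Uses the ambient RNG stream.
random_edges <- function(nodes, p = 0.4) {
  k <- length(nodes)
  ord <- sample(nodes)
  edges <- NULL
  if (k >= 2) {
    for (j in 2:k) {
      for (i in 1:(j - 1)) {
        if (stats::runif(1) < p) edges <- rbind(edges, c(ord[i], ord[j]))
      }
    }
  }
  edges
}

# Random network with strictly interior CPT entries.
random_bn <- function(k, p = 0.4, node_names = LETTERS[seq_len(k)]) {
  dag <- validate_dag(node_names, random_edges(node_names, p))
  cpts <- lapply(node_names, function(v) {
    q <- 2^length(dag_parents_h(dag, v))
    ph <- stats::runif(q, 0.05, 0.95)
    new_cpt(v, dag_parents_h(dag, v), cbind(1 - ph, ph))
  })
  names(cpts) <- node_names
  new_discrete_bn(dag, cpts)
}

dag_parents_h <- function(dag, v) {
  sort(unname(dag$edges[dag$edges[, 2] == v, 1]))
}

# Five-node recovery network with strong, detectable dependencies:
# A -> B, A -> C, B -> D, C -> D, D -> E.
recovery_bn5 <- function() {
  dag <- validate_dag(c("A", "B", "C", "D", "E"),
                      rbind(c("A", "B"), c("A", "C"), c("B", "D"),
                            c("C", "D"), c("D", "E")))
  one_parent <- rbind(c(0.8, 0.2), c(0.2, 0.8))
  # D | B, C: P(High) = 0.15, 0.5, 0.5, 0.85 by number of High parents
  two_parent <- rbind(c(0.85, 0.15), c(0.5, 0.5), c(0.5, 0.5),
                      c(0.15, 0.85))
  new_discrete_bn(dag, list(
    A = new_cpt("A", character(0), c(0.6, 0.4)),
    B = new_cpt("B", "A", one_parent),
    C = new_cpt("C", "A", one_parent),
    D = new_cpt("D", c("B", "C"), two_parent),
    E = new_cpt("E", "D", one_parent)
  ))
}

# Oracle: depth-first-search cycle detection, independent of igraph.
dfs_has_cycle <- function(nodes, edges) {
  adj <- lapply(stats::setNames(nodes, nodes), function(v)
    edges[edges[, 1] == v, 2])
  state <- stats::setNames(rep(0L, length(nodes)), nodes) # 0 new, 1 open, 2 done
  visit <- function(v) {
    if (state[[v]] == 1L) return(TRUE)
    if (state[[v]] == 2L) return(FALSE)
    state[[v]] <<- 1L
    for (w in adj[[v]]) if (visit(w)) return(TRUE)
    state[[v]] <<- 2L
    FALSE
  }
  any(vapply(nodes, visit, logical(1)))
}

# Oracle: posterior from the enumerated joint by filtering and summing.
enum_posterior <- function(bn, target, evidence = character(0)) {
  joint <- joint_enumeration(bn)
  keep <- rep(TRUE, nrow(joint))
  for (v in names(evidence)) keep <- keep & joint[[v]] == evidence[[v]]
  sub <- joint[keep, ]
  ph <- sum(sub$prob[sub[[target]] == "High"]) / sum(sub$prob)
  c(Low = 1 - ph, High = ph)
}

# Oracle: max deviation from X _||_ Y | Z in the enumerated joint.
max_ci_violation <- function(joint, x, y, z) {
  configs <- unique(joint[, z, drop = FALSE])
  worst <- 0
  for (i in seq_len(max(1, nrow(configs)))) {
    keep <- rep(TRUE, nrow(joint))
    for (v in z) keep <- keep & joint[[v]] == configs[i, v]
    sub <- joint[keep, ]
    pz <- sum(sub$prob)
    if (pz < 1e-12) next
    for (xl in LV) for (yl in LV) {
      pxy <- sum(sub$prob[sub[[x]] == xl & sub[[y]] == yl]) / pz
      px <- sum(sub$prob[sub[[x]] == xl]) / pz
      py <- sum(sub$prob[sub[[y]] == yl]) / pz
      worst <- max(worst, abs(pxy - px * py))
    }
  }
  worst
}

# Oracle: AUC by brute-force concordant-pair counting, ties = 1/2.
brute_auc <- function(scores, labels, positive = "High") {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Oracle: non-decomposed BIC — maximum-likelihood joint log-likelihood
# of the data under the DAG factorization, evaluated record by record,
# minus the total penalty.
naive_bic <- function(data, dag) {
  n <- nrow(data)
  ll <- 0
  penalty <- 0
  for (v in dag$nodes) {
    pa <- dag_parents_h(dag, v)
    penalty <- penalty + 2^length(pa) * log(n) / 2
    for (r in seq_len(n)) {
      if (length(pa) == 0) {
        num <- sum(data[[v]] == data[[v]][r])
        den <- n
      } else {
        same_pa <- rep(TRUE, n)
        for (p in pa) same_pa <- same_pa & data[[p]] == data[[p]][r]
        num <- sum(same_pa & data[[v]] == data[[v]][r])
        den <- sum(same_pa)
      }
      ll <- ll + log(num / den)
    }
  }
  ll - penalty
}

# All 25 DAGs on three nodes, as edge matrices (including the empty one).
all_dags_3 <- function(nodes = c("A", "B", "C")) {
  pairs <- t(combn(nodes, 2))
  arcs <- rbind(pairs, pairs[, 2:1])
  out <- list()
  for (mask in 0:(2^nrow(arcs) - 1)) {
    sel <- arcs[bitwAnd(mask, 2^(seq_len(nrow(arcs)) - 1)) > 0, ,
                drop = FALSE]
    if (anyDuplicated(apply(sel, 1, function(e)
      paste(sort(e), collapse = "")))) next
    if (dfs_has_cycle(nodes, sel)) next
    out[[length(out) + 1]] <- sel
  }
  out
}

# Independent fair coins dataset.
coin_data <- function(n, k, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv())
  set.seed(seed)
  d <- as.data.frame(replicate(k, sample(LV, n, TRUE), simplify = FALSE),
                     col.names = paste0("V", seq_len(k)))
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  d
}
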