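#' Search configuration for Tabu structure learning
#'
#' @param tabu_length Number of iterations a reversed move stays
#'   forbidden (also the stagnation allowance before the search stops).
#' @param max_iterations Hard iteration cap; `NULL` defaults to
#'   `10 * n_nodes^2` at search time.
#' @param random_restarts Number of searches; the first starts from the
#'   empty graph, later ones from random seeded DAGs. Best result wins.
#' @param seed Integer seed controlling restart graphs.
#' @param max_parents Maximum in-degree; `Inf` (default) for unlimited.
#' @return Object of class `search_config`.
#' @export
search_config <- function(tabu_length = 10, max_iterations = NULL,
                          random_restarts = 1, seed = 1,
                          max_parents = Inf) {
  stopifnot(tabu_length >= 0, random_restarts >= 1,
            is.null(max_iterations) || max_iterations >= 1)
  structure(list(tabu_length = tabu_length,
                 max_iterations = max_iterations,
                 random_restarts = random_restarts,
                 seed = seed, max_parents = max_parents),
            class = "search_config")
}

# Convert a Low/High data.frame to an integer (1/2) matrix, validating.
discrete_matrix <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop("empty data")
  m <- vapply(data, function(col) {
    i <- match(col, BN_LEVELS)
    if (anyNA(i)) stop("non-binary values: data must be 'Low'/'High'")
    i
  }, integer(nrow(data)))
  if (is.vector(m)) m <- matrix(m, nrow = 1, dimnames = list(NULL,
                                                             names(data)))
  m
}

# Family BIC on the integer matrix: sum_jk n_jk ln(n_jk / n_j) minus
# (r-1) q ln(N) / 2 with r = 2 child levels and q = 2^|parents|.
bic_family_int <- function(m, child, parents) {
  n <- nrow(m)
  q <- 2L^length(parents)
  if (length(parents) == 0) {
    idx <- rep(1L, n)
  } else {
    idx <- 1L
    for (j in seq_along(parents)) {
      idx <- idx + (m[, parents[j]] - 1L) * 2L^(j - 1L)
    }
  }
  cell <- idx + (m[, child] - 1L) * q
  njk <- tabulate(cell, nbins = 2L * q)
  nj <- tabulate(idx, nbins = q)
  njrep <- rep(nj, 2L)
  pos <- njk > 0
  ll <- sum(njk[pos] * log(njk[pos] / njrep[pos]))
  ll - q * log(n) / 2
}

#' Decomposable family BIC score
#'
#' Natural-log BIC for one child given a parent set, with the
#' "higher is better" sign convention:
#' \deqn{\sum_{j,k} n_{jk} \ln(n_{jk}/n_j) - (r-1)\, q \ln(N) / 2}
#' where \eqn{r = 2} child levels, \eqn{q = 2^{|parents|}} parent
#' configurations, and \eqn{N} the number of records. Zero-count cells
#' contribute zero to the log-likelihood term.
#'
#' @param data Data frame of `"Low"`/`"High"` values.
#' @param child Child column name.
#' @param parents Character vector of parent column names (may be empty).
#' @return Numeric score.
#' @export
bic_family_score <- function(data, child, parents = character(0)) {
  data <- as.data.frame(data)
  stopifnot(child %in% names(data), all(parents %in% names(data)),
            !child %in% parents)
  bic_family_int(discrete_matrix(data), child, parents)
}

#' Network BIC score
#'
#' Sum of [bic_family_score()] over every node with its DAG parents.
#' Decomposability means an edge change alters the total only through
#' the affected child's family term.
#'
#' @param data Data frame of `"Low"`/`"High"` values.
#' @param dag A `bn_dag` whose nodes are the data columns.
#' @return Numeric score (higher is better).
#' @export
bic_score <- function(data, dag) {
  stopifnot(inherits(dag, "bn_dag"))
  data <- as.data.frame(data)
  if (!setequal(names(data), dag$nodes)) {
    stop("data columns must equal the DAG's nodes")
  }
  m <- discrete_matrix(data)
  sum(vapply(dag$nodes, function(v)
    bic_family_int(m, v, dag_parents(dag, v)), numeric(1)))
}

# Reachability matrix (TRUE if a directed path of length >= 1 exists)
# by repeated boolean squaring of the adjacency matrix.
reach_matrix <- function(adj) {
  r <- adj
  repeat {
    nxt <- r | (r %*% adj > 0)
    if (identical(nxt, r)) return(r)
    r <- nxt
  }
}

# Path u ~> v test via depth-first search on the adjacency matrix.
has_path <- function(adj, u, v) {
  stack <- which(adj[u, ])
  seen <- logical(nrow(adj))
  while (length(stack) > 0) {
    w <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (w == v) return(TRUE)
    if (seen[w]) next
    seen[w] <- TRUE
    stack <- c(stack, which(adj[w, ] & !seen))
  }
  FALSE
}

move_key <- function(type, u, v) paste(type, u, v, sep = "|")

# One tabu run from a starting adjacency matrix; returns list(adj, score,
# iterations). Family scores cached in `cache` across restarts.
tabu_run <- function(m, nodes, adj, config, cache) {
  nn <- length(nodes)
  fam <- function(child_i, parent_is) {
    key <- paste(child_i, paste(sort(parent_is), collapse = ","),
                 sep = ":")
    val <- cache[[key]]
    if (is.null(val)) {
      val <- bic_family_int(m, nodes[child_i],
                            nodes[sort(parent_is)])
      cache[[key]] <- val
    }
    val
  }
  fam_now <- vapply(seq_len(nn), function(v) fam(v, which(adj[, v])),
                    numeric(1))
  score <- sum(fam_now)
  best_adj <- adj
  best_score <- score
  tabu <- new.env(parent = emptyenv())
  max_iter <- if (is.null(config$max_iterations)) 10 * nn^2 else
    config$max_iterations
  stall_limit <- max(config$tabu_length, 10)
  stall <- 0
  iter <- 0
  while (iter < max_iter && stall <= stall_limit) {
    iter <- iter + 1
    reach <- reach_matrix(adj)
    indeg <- colSums(adj)
    moves <- list()
    for (u in seq_len(nn)) {
      for (v in seq_len(nn)) {
        if (u == v) next
        if (!adj[u, v] && !adj[v, u] && !reach[v, u] &&
              indeg[v] + 1 <= config$max_parents) {
          delta <- fam(v, c(which(adj[, v]), u)) - fam_now[v]
          moves[[length(moves) + 1]] <-
            list(type = "add", u = u, v = v, delta = delta)
        } else if (adj[u, v]) {
          delta <- fam(v, setdiff(which(adj[, v]), u)) - fam_now[v]
          moves[[length(moves) + 1]] <-
            list(type = "delete", u = u, v = v, delta = delta)
          adj2 <- adj
          adj2[u, v] <- FALSE
          if (!has_path(adj2, u, v) &&
                indeg[u] + 1 <= config$max_parents) {
            delta_r <- delta +
              fam(u, c(which(adj[, u]), v)) - fam_now[u]
            moves[[length(moves) + 1]] <-
              list(type = "reverse", u = u, v = v, delta = delta_r)
          }
        }
      }
    }
    if (length(moves) == 0) break
    # order: best delta first, ties by child, parent, move type
    childn <- vapply(moves, function(mv)
      nodes[if (mv$type == "reverse") mv$u else mv$v], character(1))
    parentn <- vapply(moves, function(mv)
      nodes[if (mv$type == "reverse") mv$v else mv$u], character(1))
    typev <- vapply(moves, function(mv) mv$type, character(1))
    deltav <- vapply(moves, function(mv) mv$delta, numeric(1))
    ord <- order(-deltav, childn, parentn, typev)
    chosen <- NULL
    for (i in ord) {
      mv <- moves[[i]]
      key <- move_key(mv$type, mv$u, mv$v)
      expiry <- tabu[[key]]
      is_tabu <- !is.null(expiry) && expiry >= iter
      aspirates <- score + mv$delta > best_score + 1e-12
      if (!is_tabu || aspirates) {
        chosen <- mv
        break
      }
    }
    if (is.null(chosen)) break
    # apply and mark the inverse move tabu
    u <- chosen$u
    v <- chosen$v
    inverse <- switch(chosen$type,
                      add = move_key("delete", u, v),
                      delete = move_key("add", u, v),
                      reverse = move_key("reverse", v, u))
    tabu[[inverse]] <- iter + config$tabu_length
    if (chosen$type == "add") {
      adj[u, v] <- TRUE
      fam_now[v] <- fam(v, which(adj[, v]))
    } else if (chosen$type == "delete") {
      adj[u, v] <- FALSE
      fam_now[v] <- fam(v, which(adj[, v]))
    } else {
      adj[u, v] <- FALSE
      adj[v, u] <- TRUE
      fam_now[v] <- fam(v, which(adj[, v]))
      fam_now[u] <- fam(u, which(adj[, u]))
    }
    score <- sum(fam_now)
    if (score > best_score + 1e-12) {
      best_score <- score
      best_adj <- adj
      stall <- 0
    } else {
      stall <- stall + 1
    }
  }
  list(adj = best_adj, score = best_score, iterations = iter)
}

# Random DAG for restarts: random topological order, each forward pair
# included independently.
random_adj <- function(nn, p = 0.25, max_parents = Inf) {
  ord <- sample.int(nn)
  adj <- matrix(FALSE, nn, nn)
  for (j in 2:nn) {
    for (i in 1:(j - 1)) {
      if (stats::runif(1) < p && sum(adj[, ord[j]]) + 1 <= max_parents) {
        adj[ord[i], ord[j]] <- TRUE
      }
    }
  }
  adj
}

#' Tabu structure search with the BIC score
#'
#' Hill-climbing over single-edge moves (add, delete, reverse) that keep
#' the graph acyclic and respect `max_parents`. At each iteration the
#' best non-tabu move is applied even when it worsens the score; the
#' inverse of each applied move is forbidden for `tabu_length`
#' iterations, and a tabu move is still admissible when it would beat the
#' best score seen (aspiration). The incumbent-best structure across all
#' iterations and restarts is returned. Equal-scoring moves are broken by
#' lexicographic (child, parent, move type) order, and restart graphs are
#' drawn from the configured seed, so the search is fully deterministic.
#'
#' @param data Data frame of `"Low"`/`"High"` values (>= 2 columns).
#' @param config A [search_config()].
#' @return Object of class `scored_structure`: list with `dag` (a
#'   `bn_dag`), `score` (its BIC on `data`) and `iterations_used`.
#' @export
tabu_search <- function(data, config = search_config()) {
  stopifnot(inherits(config, "search_config"))
  data <- as.data.frame(data)
  if (ncol(data) < 2) stop("need at least two variables")
  m <- discrete_matrix(data)
  nodes <- colnames(m)
  nn <- length(nodes)
  cache <- new.env(parent = emptyenv())
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)
  best <- NULL
  iters <- 0
  for (r in seq_len(config$random_restarts)) {
    start <- if (r == 1) matrix(FALSE, nn, nn) else
      random_adj(nn, max_parents = config$max_parents)
    run <- tabu_run(m, nodes, start, config, cache)
    iters <- iters + run$iterations
    if (is.null(best) || run$score > best$score + 1e-12) best <- run
  }
  edges <- which(best$adj, arr.ind = TRUE)
  dag <- validate_dag(nodes,
                      cbind(nodes[edges[, 1]], nodes[edges[, 2]]))
  structure(list(dag = dag, score = best$score,
                 iterations_used = iters),
            class = "scored_structure")
}

#' @export
print.scored_structure <- function(x, ...) {
  cat("Learned structure:", length(x$dag$nodes), "nodes,",
      nrow(x$dag$edges), "edges, BIC =", format(x$score), "\n")
  invisible(x)
}

#' Structural Hamming distance between two DAGs
#'
#' `type = "skeleton"` compares undirected adjacencies only (each edge
#' present in exactly one graph costs 1). `type = "directed"` counts
#' additions, deletions and orientation reversals, each at cost 1.
#'
#' @param dag1,dag2 `bn_dag` objects over the same node set.
#' @param type `"skeleton"` or `"directed"`.
#' @return Nonnegative integer distance.
#' @export
shd <- function(dag1, dag2, type = c("skeleton", "directed")) {
  type <- match.arg(type)
  stopifnot(setequal(dag1$nodes, dag2$nodes))
  e1 <- paste(dag1$edges[, 1], dag1$edges[, 2], sep = "->")
  e2 <- paste(dag2$edges[, 1], dag2$edges[, 2], sep = "->")
  if (type == "directed") {
    only1 <- setdiff(e1, e2)
    only2 <- setdiff(e2, e1)
    rev1 <- paste(dag1$edges[, 2], dag1$edges[, 1], sep = "->")
    reversed <- sum(rev1 %in% only2 & e1 %in% only1)
    return(length(only1) + length(only2) - reversed)
  }
  und <- function(edges) {
    if (nrow(edges) == 0) return(character(0))
    unique(apply(edges, 1, function(e) paste(sort(e), collapse = "~")))
  }
  u1 <- und(dag1$edges)
  u2 <- und(dag2$edges)
  length(setdiff(u1, u2)) + length(setdiff(u2, u1))
}
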