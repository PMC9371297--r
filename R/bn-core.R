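# All variables in this package are binary with a fixed, ordered level set.
# "Low" always comes first; probabilities are reported for "High".
BN_LEVELS <- c("Low", "High")

#' Level labels used by all network variables
#'
#' Every variable in a [discrete_bn] takes exactly two ordered levels,
#' `"Low"` then `"High"`. The ordering is load-bearing: conditional
#' probability tables, parent-configuration enumeration and serialization
#' all list `"Low"` first.
#'
#' @return Character vector `c("Low", "High")`.
#' @export
bn_levels <- function() BN_LEVELS

#' Validate and construct a directed acyclic graph
#'
#' Checks that every edge endpoint is a declared node, that there are no
#' self-loops, and that the directed graph is acyclic. Isolated nodes are
#' allowed.
#'
#' @param nodes Character vector of unique variable names.
#' @param edges Two-column character matrix or data frame (`from`, `to`),
#'   one directed edge per row. May have zero rows.
#' @return An object of class `bn_dag`: a list with elements `nodes`
#'   (character) and `edges` (two-column character matrix).
#' @examples
#' validate_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' @export
validate_dag <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) {
    stop("duplicate node names: ",
         paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  }
  if (is.null(edges) || NROW(edges) == 0) {
    edges <- matrix(character(0), ncol = 2)
  } else {
    edges <- as.matrix(edges)
    if (ncol(edges) != 2) stop("'edges' must have two columns (from, to)")
    storage.mode(edges) <- "character"
  }
  colnames(edges) <- c("from", "to")
  unknown <- setdiff(c(edges), nodes)
  if (length(unknown) > 0) {
    stop("edge endpoint(s) not declared as nodes: ",
         paste(unknown, collapse = ", "))
  }
  if (any(edges[, 1] == edges[, 2])) {
    bad <- edges[edges[, 1] == edges[, 2], 1]
    stop("self-loop on node(s): ", paste(unique(bad), collapse = ", "))
  }
  if (anyDuplicated(paste(edges[, 1], edges[, 2]))) {
    stop("duplicate edges in edge list")
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    cyc <- names(comp$membership)[comp$membership ==
                                    which.max(comp$csize)]
    stop("graph contains a directed cycle involving: ",
         paste(sort(cyc), collapse = " -> "))
  }
  structure(list(nodes = nodes, edges = edges), class = "bn_dag")
}

#' @export
print.bn_dag <- function(x, ...) {
  cat("DAG with", length(x$nodes), "nodes and", nrow(x$edges), "edges\n")
  invisible(x)
}

dag_parents <- function(dag, node) {
  sort(unname(dag$edges[dag$edges[, 2] == node, 1]))
}

dag_children <- function(dag, node) {
  sort(unname(dag$edges[dag$edges[, 1] == node, 2]))
}

#' Topological order of a DAG
#'
#' @param dag A `bn_dag`.
#' @return Character vector of node names, parents before children.
#' @export
topological_order <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  g <- dag_to_igraph(dag)
  as.character(igraph::topo_sort(g, mode = "out")$name)
}

dag_to_igraph <- function(dag) {
  igraph::graph_from_data_frame(
    as.data.frame(dag$edges, stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = dag$nodes, stringsAsFactors = FALSE)
  )
}

#' Classify nodes as top, node or bottom variables
#'
#' The taxonomy used to read the learned network: "top" variables
#' (antecessors) have no parents, "bottom" variables (predecessors in the
#' probabilistic-consequence sense; the leaves) have no children, and
#' "node" variables sit in between with both parents and children.
#' Isolated nodes, which have neither, are classified "top" since absence
#' of parents is what defines an antecessor.
#'
#' @param dag A `bn_dag`.
#' @return Named character vector mapping each node to `"top"`, `"node"`
#'   or `"bottom"`.
#' @export
classify_topology <- function(dag) {
  stopifnot(inherits(dag, "bn_dag"))
  indeg <- table(factor(dag$edges[, 2], levels = dag$nodes))
  outdeg <- table(factor(dag$edges[, 1], levels = dag$nodes))
  out <- ifelse(outdeg == 0 & indeg > 0, "bottom",
                ifelse(indeg == 0, "top", "node"))
  stats::setNames(as.character(out), dag$nodes)
}

#' Markov blanket of a node
#'
#' Parents, children and the children's other parents. Conditioning on the
#' blanket renders the node independent of every other variable.
#'
#' @param dag A `bn_dag`.
#' @param node Node name.
#' @return Character vector of blanket members (sorted), excluding `node`.
#' @export
markov_blanket <- function(dag, node) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!node %in% dag$nodes) stop("unknown node: ", node)
  pa <- dag_parents(dag, node)
  ch <- dag_children(dag, node)
  spouses <- unlist(lapply(ch, function(c) dag_parents(dag, c)))
  sort(setdiff(unique(c(pa, ch, spouses)), node))
}

# Enumerate all parent-level configurations in lexicographic order:
# first parent varies slowest, Low before High. Returns a data.frame
# with one column per parent; a zero-parent input gives a single empty row.
parent_configs <- function(parents) {
  if (length(parents) == 0) {
    return(structure(data.frame(row.names = "1"), names = character(0)))
  }
  grids <- rev(lapply(parents, function(p) BN_LEVELS))
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[, rev(seq_along(parents)), drop = FALSE]
  names(g) <- parents
  g
}

config_keys <- function(configs) {
  if (ncol(configs) == 0) return("")
  apply(configs, 1, function(r) paste(names(configs), r, sep = "=",
                                      collapse = ","))
}

#' Construct a conditional probability table
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (stored sorted).
#' @param prob Numeric matrix with one row per parent configuration (in
#'   the lexicographic order of [parent_configs()], i.e. first parent
#'   slowest, Low before High) and two columns `Low`, `High`; rows must
#'   sum to 1. A numeric vector of length 2 is accepted for a root node.
#' @return Object of class `bn_cpt`.
#' @export
new_cpt <- function(child, parents, prob) {
  parents <- sort(as.character(parents))
  if (is.vector(prob) && length(prob) == 2) prob <- matrix(prob, nrow = 1)
  prob <- as.matrix(prob)
  nconf <- 2L^length(parents)
  if (nrow(prob) != nconf || ncol(prob) != 2) {
    stop("CPT for ", child, " must be ", nconf, " x 2")
  }
  if (any(prob < 0 | prob > 1)) stop("CPT entries must lie in [0, 1]")
  if (any(abs(rowSums(prob) - 1) > 1e-12)) {
    stop("CPT rows for ", child, " must each sum to 1")
  }
  dimnames(prob) <- list(config_keys(parent_configs(parents)), BN_LEVELS)
  structure(list(child = child, parents = parents, prob = prob),
            class = "bn_cpt")
}

#' @export
print.bn_cpt <- function(x, ...) {
  cat("CPT for", x$child,
      if (length(x$parents)) paste("|", paste(x$parents, collapse = ", "))
      else "(root)", "\n")
  print(round(x$prob, 4))
  invisible(x)
}

#' Construct a discrete Bayesian network
#'
#' @param dag A `bn_dag`.
#' @param cpts Named list of `bn_cpt`, one per node; each CPT's parent set
#'   must equal the node's parents in `dag`.
#' @return Object of class `discrete_bn`.
#' @export
new_discrete_bn <- function(dag, cpts) {
  stopifnot(inherits(dag, "bn_dag"))
  if (!setequal(names(cpts), dag$nodes)) {
    stop("cpts must be keyed exactly by the DAG's nodes")
  }
  for (v in dag$nodes) {
    cpt <- cpts[[v]]
    if (!inherits(cpt, "bn_cpt") || cpt$child != v) {
      stop("cpts[['", v, "']] is not a CPT for ", v)
    }
    if (!identical(cpt$parents, dag_parents(dag, v))) {
      stop("CPT parents for ", v, " do not match the DAG")
    }
  }
  structure(list(dag = dag, cpts = cpts[dag$nodes]), class = "discrete_bn")
}

#' @export
print.discrete_bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$dag$nodes), "binary nodes,",
      nrow(x$dag$edges), "edges\n")
  invisible(x)
}

# Look up P(child = level | parent configuration), config given as a named
# character vector covering at least the CPT's parents.
cpt_prob <- function(cpt, level, config) {
  if (length(cpt$parents) == 0) return(cpt$prob[1, level])
  key <- paste(cpt$parents, config[cpt$parents], sep = "=", collapse = ",")
  cpt$prob[key, level]
}

#' Estimate conditional probability tables from discrete data
#'
#' Parametric learning: given a network structure and a table of Low/High
#' observations, each CPT entry is estimated as
#' \deqn{(n_{jk} + \alpha) / (n_j + 2\alpha)}
#' where \eqn{n_{jk}} counts records with the child at level \eqn{k} under
#' parent configuration \eqn{j}. With `alpha = 0` (maximum likelihood) an
#' unobserved parent configuration yields the uniform distribution
#' (0.5, 0.5).
#'
#' @param data Data frame of `"Low"`/`"High"` values, one column per node.
#' @param dag A `bn_dag` whose nodes are exactly the data columns.
#' @param alpha Nonnegative smoothing pseudo-count. Use `alpha = 1`
#'   (Laplace) for any network later used in inference to avoid
#'   zero-probability cells; `alpha = 0` matches the maximum-likelihood
#'   estimates implicit in the BIC score.
#' @return A `discrete_bn`.
#' @export
fit_cpts <- function(data, dag, alpha = 1) {
  stopifnot(inherits(dag, "bn_dag"), alpha >= 0)
  data <- as.data.frame(data)
  if (nrow(data) == 0) stop("cannot fit CPTs from empty data")
  if (!setequal(names(data), dag$nodes)) {
    stop("data columns must equal the DAG's nodes")
  }
  bad <- !vapply(data, function(col) all(col %in% BN_LEVELS), logical(1))
  if (any(bad)) {
    stop("non-Low/High values in column(s): ",
         paste(names(data)[bad], collapse = ", "))
  }
  cpts <- lapply(dag$nodes, function(v) {
    pa <- dag_parents(dag, v)
    child <- factor(data[[v]], levels = BN_LEVELS)
    if (length(pa) == 0) {
      counts <- matrix(table(child), nrow = 1)
    } else {
      key <- interaction(data[pa], sep = ",", lex.order = TRUE)
      configs <- parent_configs(pa)
      lv <- apply(configs, 1, paste, collapse = ",")
      key <- factor(as.character(key), levels = lv)
      counts <- t(table(child, key))
    }
    prob <- (counts + alpha) / (rowSums(counts) + 2 * alpha)
    empty <- rowSums(counts) + 2 * alpha == 0
    prob[empty, ] <- 0.5
    new_cpt(v, pa, prob)
  })
  names(cpts) <- dag$nodes
  new_discrete_bn(dag, cpts)
}

#' Serialize a network to JSON
#'
#' Writes `{nodes, edges, cpts}` with CPT rows in the package's
#' lexicographic parent-configuration order, so serialization is
#' bit-stable for a given network.
#'
#' @param bn A `discrete_bn`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
bn_to_json <- function(bn, path = NULL) {
  stopifnot(inherits(bn, "discrete_bn"))
  obj <- list(
    nodes = bn$dag$nodes,
    edges = apply(bn$dag$edges, 1, function(e)
      list(from = e[[1]], to = e[[2]])),
    cpts = lapply(bn$cpts, function(cpt) list(
      child = cpt$child,
      parents = cpt$parents,
      rows = rownames(cpt$prob),
      prob = lapply(seq_len(nrow(cpt$prob)), function(i)
        unname(cpt$prob[i, ]))
    ))
  )
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Deserialize a network from JSON
#'
#' @param json JSON string or path to a file written by [bn_to_json()].
#' @return A `discrete_bn`.
#' @export
bn_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  edges <- if (length(obj$edges) == 0) NULL else
    do.call(rbind, lapply(obj$edges, function(e) c(e$from, e$to)))
  dag <- validate_dag(unlist(obj$nodes), edges)
  cpts <- lapply(obj$cpts, function(c) {
    prob <- do.call(rbind, lapply(c$prob, unlist))
    new_cpt(c$child, unlist(c$parents), prob)
  })
  names(cpts) <- vapply(cpts, function(c) c$child, character(1))
  new_discrete_bn(dag, cpts)
}

#' Export a DAG as Graphviz DOT
#'
#' @param dag A `bn_dag`.
#' @param path Optional file path; when `NULL` the DOT source is returned.
#' @return Character vector of DOT lines, invisibly when written.
#' @export
dag_to_dot <- function(dag, path = NULL) {
  stopifnot(inherits(dag, "bn_dag"))
  lines <- c(
    "digraph bn {",
    paste0("  \"", dag$nodes, "\";"),
    if (nrow(dag$edges) > 0)
      paste0("  \"", dag$edges[, 1], "\" -> \"", dag$edges[, 2], "\";"),
    "}"
  )
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}
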