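# Internal factor representation for exact inference: a character vector
# of variable names plus a numeric vector of length 2^k holding the
# potential in column-major order (first variable fastest, Low = 1,
# High = 2). All variables are binary so strides are powers of two.

new_factor <- function(vars, vals) {
  list(vars = vars, vals = vals)
}

factor_strides <- function(k) {
  if (k == 0) return(integer(0))
  2L^(seq_len(k) - 1L)
}

# Vectorized lookup: idx is an n x k matrix of level indices (1/2) whose
# columns follow f$vars; returns the n potentials.
factor_lookup <- function(f, idx) {
  k <- length(f$vars)
  if (k == 0) return(rep(f$vals[1], nrow(idx)))
  lin <- 1L + as.vector((idx - 1L) %*% factor_strides(k))
  f$vals[lin]
}

factor_from_cpt <- function(cpt) {
  vars <- c(cpt$parents, cpt$child)
  k <- length(vars)
  grid <- as.matrix(expand.grid(rep(list(1:2), k)))
  np <- length(cpt$parents)
  if (np == 0) {
    vals <- cpt$prob[1, grid[, 1]]
  } else {
    keys <- apply(grid[, seq_len(np), drop = FALSE], 1, function(r)
      paste(cpt$parents, BN_LEVELS[r], sep = "=", collapse = ","))
    vals <- cpt$prob[cbind(keys, BN_LEVELS[grid[, k]])]
  }
  new_factor(vars, as.numeric(vals))
}

factor_product <- function(f, g) {
  vars <- union(f$vars, g$vars)
  k <- length(vars)
  if (k == 0) return(new_factor(character(0), f$vals[1] * g$vals[1]))
  grid <- as.matrix(expand.grid(rep(list(1:2), k)))
  colnames(grid) <- vars
  vals <- factor_lookup(f, grid[, f$vars, drop = FALSE]) *
    factor_lookup(g, grid[, g$vars, drop = FALSE])
  new_factor(vars, vals)
}

factor_sum_out <- function(f, var) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  k <- length(f$vars)
  arr <- array(f$vals, dim = rep(2L, k))
  if (k == 1) return(new_factor(character(0), sum(arr)))
  kept <- setdiff(seq_len(k), pos)
  out <- apply(arr, kept, sum)
  new_factor(f$vars[kept], as.numeric(out))
}

# Fix var to the given level label and drop it from the factor's scope.
factor_reduce <- function(f, var, level) {
  pos <- match(var, f$vars)
  if (is.na(pos)) return(f)
  k <- length(f$vars)
  lev <- match(level, BN_LEVELS)
  arr <- array(f$vals, dim = rep(2L, k))
  idx <- rep(list(quote(expr = )), k)
  idx[[pos]] <- lev
  out <- do.call(`[`, c(list(arr), idx, list(drop = FALSE)))
  new_factor(f$vars[-pos], as.numeric(out))
}

#' Enumerate the full joint distribution of a network
#'
#' Brute-force oracle: one probability per complete Low/High
#' configuration, computed as the product of CPT entries. Guarded to at
#' most 20 nodes (2^20 rows).
#'
#' @param bn A `discrete_bn`.
#' @return Data frame with one `"Low"`/`"High"` column per node (first
#'   node varying fastest) and a final numeric column `prob` summing to 1.
#' @export
joint_enumeration <- function(bn) {
  stopifnot(inherits(bn, "discrete_bn"))
  nodes <- bn$dag$nodes
  if (length(nodes) > 20) {
    stop("joint enumeration is guarded to networks of at most 20 nodes")
  }
  k <- length(nodes)
  grid <- as.matrix(expand.grid(rep(list(1:2), k)))
  colnames(grid) <- nodes
  prob <- rep(1, nrow(grid))
  for (v in nodes) {
    f <- factor_from_cpt(bn$cpts[[v]])
    prob <- prob * factor_lookup(f, grid[, f$vars, drop = FALSE])
  }
  out <- as.data.frame(matrix(BN_LEVELS[grid], nrow = nrow(grid)),
                       stringsAsFactors = FALSE)
  names(out) <- nodes
  out$prob <- prob
  out
}

# Marginal distribution over a subset of nodes, via enumeration of the
# sub-network induced by their ancestors. Returns a data.frame of level
# columns plus prob. Used by the synthetic-data calibration.
ancestral_marginal <- function(bn, vars) {
  anc <- vars
  repeat {
    more <- unique(unlist(lapply(anc, function(v)
      dag_parents(bn$dag, v))))
    grown <- union(anc, more)
    if (length(grown) == length(anc)) break
    anc <- grown
  }
  anc <- intersect(bn$dag$nodes, anc)
  sub_edges <- bn$dag$edges[bn$dag$edges[, 1] %in% anc &
                              bn$dag$edges[, 2] %in% anc, , drop = FALSE]
  sub <- new_discrete_bn(validate_dag(anc, sub_edges), bn$cpts[anc])
  joint <- joint_enumeration(sub)
  agg <- stats::aggregate(joint$prob,
                          by = joint[, vars, drop = FALSE],
                          FUN = sum)
  names(agg)[ncol(agg)] <- "prob"
  agg
}

validate_evidence <- function(bn, evidence) {
  if (length(evidence) == 0) return(invisible(NULL))
  evidence <- unlist(evidence)
  if (is.null(names(evidence)) || any(names(evidence) == "")) {
    stop("evidence must be a named vector/list of variable = level")
  }
  if (anyDuplicated(names(evidence))) {
    stop("duplicate evidence assertions for: ",
         paste(unique(names(evidence)[duplicated(names(evidence))]),
               collapse = ", "))
  }
  unknown <- setdiff(names(evidence), bn$dag$nodes)
  if (length(unknown) > 0) {
    stop("evidence on unknown variable(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!all(evidence %in% BN_LEVELS)) {
    stop("evidence levels must be 'Low' or 'High'")
  }
  invisible(NULL)
}

#' Exact posterior marginal by variable elimination
#'
#' Computes P(target | evidence) exactly, eliminating variables along a
#' min-degree order (ties broken lexicographically, so results and
#' runtimes are deterministic). Evidence asserted with probability zero
#' under the network raises an explicit inconsistent-evidence error
#' rather than returning NaN.
#'
#' @param bn A `discrete_bn`.
#' @param target Query variable name; must not appear in `evidence`.
#' @param evidence Named character vector or list mapping variable names
#'   to asserted levels (`"Low"`/`"High"`); may be empty.
#' @return Object of class `bn_posterior`: a named numeric vector of
#'   probabilities over `c("Low", "High")` with attribute `variable`.
#' @export
posterior_marginal <- function(bn, target, evidence = character(0)) {
  stopifnot(inherits(bn, "discrete_bn"))
  if (!target %in% bn$dag$nodes) stop("unknown target: ", target)
  validate_evidence(bn, evidence)
  evidence <- unlist(evidence)
  if (target %in% names(evidence)) {
    stop("target must not be part of the evidence")
  }
  factors <- lapply(bn$cpts, factor_from_cpt)
  for (v in names(evidence)) {
    factors <- lapply(factors, factor_reduce, var = v,
                      level = evidence[[v]])
  }
  to_elim <- setdiff(bn$dag$nodes, c(target, names(evidence)))
  while (length(to_elim) > 0) {
    # min-degree: eliminate the variable sharing factors with the fewest
    # other variables
    degree <- vapply(to_elim, function(v) {
      nb <- unique(unlist(lapply(factors, function(f)
        if (v %in% f$vars) f$vars else NULL)))
      length(setdiff(nb, v))
    }, numeric(1))
    v <- sort(to_elim[degree == min(degree)])[1]
    touches <- vapply(factors, function(f) v %in% f$vars, logical(1))
    prod_f <- Reduce(factor_product, factors[touches])
    factors <- c(factors[!touches], list(factor_sum_out(prod_f, v)))
    to_elim <- setdiff(to_elim, v)
  }
  final <- Reduce(factor_product, factors)
  stopifnot(identical(final$vars, target))
  total <- sum(final$vals)
  if (total <= 0) {
    stop("inconsistent evidence: asserted configuration has probability ",
         "zero under the network")
  }
  dist <- final$vals / total
  structure(stats::setNames(dist, BN_LEVELS),
            variable = target, class = "bn_posterior")
}

#' @export
print.bn_posterior <- function(x, ...) {
  cat("P(", attr(x, "variable"), ") = [Low ",
      sprintf("%.4f", x[["Low"]]), ", High ",
      sprintf("%.4f", x[["High"]]), "]\n", sep = "")
  invisible(x)
}

#' Probability of the High level from a posterior
#'
#' @param x A `bn_posterior`.
#' @return Numeric scalar P(variable = High).
#' @export
p_high <- function(x) unname(x[["High"]])
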