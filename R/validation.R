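#' Deterministic k-fold split
#'
#' Shuffles record indices with the given seed and deals them into `k`
#' disjoint folds whose sizes differ by at most one (the first `n %% k`
#' folds get the extra record).
#'
#' @param n Number of records.
#' @param k Number of folds, `2 <= k <= n`.
#' @param seed Integer RNG seed.
#' @return List of `k` integer vectors (1-based indices) partitioning
#'   `1:n`.
#' @export
kfold_split <- function(n, k, seed = 1) {
  stopifnot(k >= 2)
  if (k > n) stop("k must not exceed the number of records")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  idx <- sample.int(n)
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  split(idx, rep(seq_len(k), times = sizes))
}

#' Per-record posterior scores for one node given all others
#'
#' The per-node classifier: each held-out record's variables other than
#' `node` are asserted as evidence and the posterior P(node = High) is
#' computed. Because the full remainder of the record is observed, the
#' posterior depends only on the node's Markov blanket and reduces to
#' the product of the node's own CPT row and its children's CPT rows,
#' renormalized — mathematically identical to full variable elimination.
#'
#' @param bn A `discrete_bn`.
#' @param node Node to score.
#' @param records Data frame of `"Low"`/`"High"` values containing every
#'   network variable.
#' @return Numeric vector of P(node = High), one per record.
#' @export
predict_node_posteriors <- function(bn, node, records) {
  stopifnot(inherits(bn, "discrete_bn"))
  if (!node %in% bn$dag$nodes) stop("unknown node: ", node)
  records <- as.data.frame(records)
  absent <- setdiff(bn$dag$nodes, names(records))
  if (length(absent) > 0) {
    stop("records are missing variable(s): ",
         paste(absent, collapse = ", "))
  }
  n <- nrow(records)
  fams <- c(node, dag_children(bn$dag, node))
  w <- matrix(1, nrow = n, ncol = 2, dimnames = list(NULL, BN_LEVELS))
  for (level in BN_LEVELS) {
    rec <- records
    rec[[node]] <- level
    for (f in fams) {
      cpt <- bn$cpts[[f]]
      if (length(cpt$parents) == 0) {
        w[, level] <- w[, level] * cpt$prob[1, rec[[f]]]
      } else {
        keys <- do.call(paste, c(
          lapply(cpt$parents, function(pa) paste0(pa, "=", rec[[pa]])),
          sep = ","))
        w[, level] <- w[, level] * cpt$prob[cbind(keys, rec[[f]])]
      }
    }
  }
  tot <- rowSums(w)
  if (any(tot <= 0)) {
    stop("inconsistent evidence for some records: a CPT cell is zero; ",
         "refit with alpha >= 1")
  }
  unname(w[, "High"] / tot)
}

#' Confusion counts and threshold classification metrics
#'
#' Predicts the positive level when the score for that level is at or
#' above `threshold`, then computes
#' sensitivity = TP/(TP+FN), specificity = TN/(TN+FP) and
#' accuracy = (TN+TP)/(TN+TP+FN+FP). A zero denominator yields `NA` with
#' a warning.
#'
#' @param scores Numeric vector of P(High) per record.
#' @param labels Character vector of true `"Low"`/`"High"` labels.
#' @param threshold Decision threshold in (0, 1).
#' @param positive_level Level treated as positive (default `"High"`);
#'   the score for `"Low"` is `1 - scores`.
#' @return List with elements `counts` (named tp/tn/fp/fn),
#'   `accuracy`, `sensitivity`, `specificity`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5,
                                   positive_level = "High") {
  stopifnot(length(scores) == length(labels),
            threshold > 0, threshold < 1,
            positive_level %in% BN_LEVELS)
  if (length(scores) == 0) stop("empty input")
  pos_score <- if (positive_level == "High") scores else 1 - scores
  pred_pos <- pos_score >= threshold
  is_pos <- labels == positive_level
  tp <- sum(pred_pos & is_pos)
  tn <- sum(!pred_pos & !is_pos)
  fp <- sum(pred_pos & !is_pos)
  fn <- sum(!pred_pos & is_pos)
  ratio <- function(num, den, what) {
    if (den == 0) {
      warning(what, " undefined: zero denominator")
      return(NA_real_)
    }
    num / den
  }
  list(counts = c(tp = tp, tn = tn, fp = fp, fn = fn),
       accuracy = (tn + tp) / (tn + tp + fn + fp),
       sensitivity = ratio(tp, tp + fn, "sensitivity"),
       specificity = ratio(tn, tn + fp, "specificity"))
}

#' Area under the ROC curve
#'
#' Rank-based (concordant-pair) estimator: the probability that a
#' randomly chosen positive record is scored above a randomly chosen
#' negative one, with ties counted one half.
#'
#' @inheritParams classification_metrics
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels, positive_level = "High") {
  stopifnot(length(scores) == length(labels),
            positive_level %in% BN_LEVELS)
  pos_score <- if (positive_level == "High") scores else 1 - scores
  is_pos <- labels == positive_level
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC needs at least one positive and one negative label")
  }
  r <- rank(pos_score)
  (sum(r[is_pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Per-node 10-fold cross-validated classification metrics
#'
#' For each fold, the network structure is learned on the training split
#' (unless `fixed_structure`), CPTs are fitted with Laplace smoothing,
#' and each held-out record is scored per node given all its other
#' variables as evidence. Predictions are pooled over folds
#' (micro-average) before computing AUC, accuracy, sensitivity and
#' specificity per node.
#'
#' @param data Data frame of `"Low"`/`"High"` values.
#' @param search A [search_config()] for the per-fold structure search.
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold split.
#' @param positive_level Level treated as positive (default `"High"`).
#' @param threshold Decision threshold (default 0.5; not tuned).
#' @param alpha CPT smoothing (default 1; keeps posteriors well-defined).
#' @param fixed_structure When `TRUE`, learn the structure once on all
#'   data and cross-validate only the CPTs.
#' @return Data frame of class `validation_table` with columns
#'   `Variable`, `AUC`, `Accuracy`, `Sensitivity`, `Specificity`, and a
#'   `counts` attribute holding the pooled confusion counts per node.
#' @export
cross_validate <- function(data, search = search_config(), k = 10,
                           seed = 1, positive_level = "High",
                           threshold = 0.5, alpha = 1,
                           fixed_structure = FALSE) {
  data <- as.data.frame(data)
  if (k < 2) stop("k must be at least 2")
  n <- nrow(data)
  folds <- kfold_split(n, k, seed)
  nodes <- names(data)
  scores <- matrix(NA_real_, nrow = n, ncol = length(nodes),
                   dimnames = list(NULL, nodes))
  global_structure <- if (fixed_structure) tabu_search(data, search)
  for (fold in folds) {
    train <- data[-fold, , drop = FALSE]
    structure_fold <- if (fixed_structure) global_structure else
      tabu_search(train, search)
    bn <- fit_cpts(train, structure_fold$dag, alpha = alpha)
    test <- data[fold, , drop = FALSE]
    for (v in nodes) {
      scores[fold, v] <- predict_node_posteriors(bn, v, test)
    }
  }
  rows <- lapply(nodes, function(v) {
    met <- classification_metrics(scores[, v], data[[v]], threshold,
                                  positive_level)
    a <- tryCatch(auc(scores[, v], data[[v]], positive_level),
                  error = function(e) NA_real_)
    list(row = data.frame(Variable = v, AUC = a,
                          Accuracy = met$accuracy,
                          Sensitivity = met$sensitivity,
                          Specificity = met$specificity,
                          stringsAsFactors = FALSE),
         counts = met$counts)
  })
  out <- do.call(rbind, lapply(rows, `[[`, "row"))
  rownames(out) <- NULL
  attr(out, "counts") <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(attr(out, "counts")) <- nodes
  attr(out, "scores") <- scores
  class(out) <- c("validation_table", class(out))
  out
}

#' @export
print.validation_table <- function(x, digits = 2, ...) {
  y <- as.data.frame(x)
  y[-1] <- lapply(y[-1], round, digits = digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
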