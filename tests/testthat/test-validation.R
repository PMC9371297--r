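test_that("kfold_split builds a deterministic balanced partition", {
  f <- kfold_split(10, 10, seed = 1)
  expect_length(f, 10)
  expect_true(all(lengths(f) == 1))

  f235 <- kfold_split(235, 10, seed = 1)
  expect_setequal(lengths(f235), c(23, 24))
  expect_equal(sum(lengths(f235) == 24), 5)
  expect_setequal(unlist(f235), 1:235)

  expect_identical(kfold_split(50, 5, seed = 3), kfold_split(50, 5, seed = 3))
  expect_error(kfold_split(5, 10), "exceed")
  expect_error(kfold_split(5, 1))
})

test_that("predict_node_posteriors matches the enumeration oracle", {
  set.seed(91)
  bn <- random_bn(6, p = 0.45)
  records <- sample_bn(bn, 40, seed = 4)
  worst <- 0
  for (v in bn$dag$nodes) {
    fast <- predict_node_posteriors(bn, v, records)
    for (r in seq_len(10)) {
      ev <- unlist(records[r, setdiff(bn$dag$nodes, v)])
      oracle <- enum_posterior(bn, v, ev)
      worst <- max(worst, abs(fast[r] - oracle[["High"]]))
    }
  }
  expect_lt(worst, 1e-10)
})

test_that("degenerate classifiers score as expected", {
  # node B copies evidence variable A deterministically
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  bn <- new_discrete_bn(dag, list(
    A = new_cpt("A", character(0), c(0.5, 0.5)),
    B = new_cpt("B", "A", rbind(c(1, 0), c(0, 1)))
  ))
  rec <- data.frame(A = c("High", "Low"), B = c("High", "Low"))
  expect_equal(predict_node_posteriors(bn, "B", rec), c(1, 0))

  # node independent of all others always scores its marginal
  dag2 <- validate_dag(c("A", "B"))
  bn2 <- new_discrete_bn(dag2, list(
    A = new_cpt("A", character(0), c(0.35, 0.65)),
    B = new_cpt("B", character(0), c(0.5, 0.5))
  ))
  expect_equal(predict_node_posteriors(bn2, "A", rec), c(0.65, 0.65))
})

test_that("classification_metrics implements the quoted formulas", {
  m <- classification_metrics(c(1, 1, 0, 0), c("High", "High", "Low", "Low"))
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
  expect_equal(m$accuracy, 1)

  # constructed confusion: tp=8 fn=2 tn=6 fp=4
  scores <- c(rep(1, 8), rep(0, 2), rep(0, 6), rep(1, 4))
  labels <- c(rep("High", 10), rep("Low", 10))
  m2 <- classification_metrics(scores, labels)
  expect_equal(unname(m2$counts), c(8, 6, 4, 2))
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 0.6)
  expect_equal(m2$accuracy, 0.7)

  # swapping the positive level swaps sensitivity and specificity
  m3 <- classification_metrics(scores, labels, positive_level = "Low")
  expect_equal(m3$sensitivity, m2$specificity)
  expect_equal(m3$specificity, m2$sensitivity)

  # probability 0/1 scores at threshold .5 reduce to label comparison
  expect_equal(m2$accuracy,
               mean(ifelse(scores >= 0.5, "High", "Low") == labels))

  expect_warning(
    res <- classification_metrics(c(0, 0), c("Low", "Low")),
    "sensitivity undefined")
  expect_true(is.na(res$sensitivity))
  expect_error(classification_metrics(numeric(0), character(0)))
})

test_that("auc equals brute-force concordant-pair counting", {
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1),
                   c("High", "High", "Low", "Low")), 1)
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.2),
                   c("High", "High", "Low", "Low")), 0.75)
  set.seed(121)
  for (rep in 1:30) {
    n <- sample(6:40, 1)
    scores <- round(runif(n), sample(1:3, 1)) # induce ties
    labels <- sample(LV, n, TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc(scores, labels), brute_auc(scores, labels))
    # invariance under strictly monotone transforms
    expect_equal(auc(stats::plogis(5 * scores - 2), labels),
                 auc(scores, labels))
  }
  expect_error(auc(c(0.1, 0.2), c("High", "High")), "negative")
})

test_that("cross_validate pools predictions over a full partition", {
  bn <- recovery_bn5()
  d <- sample_bn(bn, 400, seed = 13)
  vt <- cross_validate(d, search_config(seed = 1), k = 5, seed = 2)
  expect_s3_class(vt, "validation_table")
  expect_equal(vt$Variable, names(d))
  expect_equal(dim(vt), c(5, 5))
  counts <- attr(vt, "counts")
  expect_true(all(rowSums(counts) == nrow(d)))
  expect_true(all(vt$AUC >= 0 & vt$AUC <= 1, na.rm = TRUE))
  # strong dependencies: informative nodes classify well
  expect_gt(median(vt$AUC), 0.8)

  # fixed-structure mode runs and yields the same table shape
  vt2 <- cross_validate(d, search_config(seed = 1), k = 5, seed = 2,
                        fixed_structure = TRUE)
  expect_equal(dim(vt2), c(5, 5))
  expect_error(cross_validate(d, k = 1), "at least 2")
})
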