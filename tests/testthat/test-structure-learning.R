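test_that("bic_family_score matches hand-derived closed forms", {
  d1 <- data.frame(A = c("High", "High", "Low", "Low"))
  expect_equal(bic_family_score(d1, "A"), 4 * log(0.5) - log(4) / 2,
               tolerance = 1e-12)

  d2 <- data.frame(
    A = rep(c("High", "Low"), each = 4),
    B = c("High", "High", "High", "Low", "High", "Low", "Low", "Low"))
  expect_equal(bic_family_score(d2, "B", "A"),
               6 * log(0.75) + 2 * log(0.25) - 2 * log(8) / 2,
               tolerance = 1e-12)

  # deterministic child: zero entropy, score is pure penalty
  d3 <- data.frame(A = rep(c("High", "Low"), 10))
  d3$B <- d3$A
  expect_equal(bic_family_score(d3, "B", "A"), -2 * log(20) / 2)
})

test_that("bic_score decomposes over families and ignores column order", {
  set.seed(51)
  for (rep in 1:5) {
    k <- sample(3:6, 1)
    bn <- random_bn(k, p = 0.5)
    d <- sample_bn(bn, 150, seed = rep)
    dag <- bn$dag
    total <- bic_score(d, dag)
    by_family <- sum(vapply(dag$nodes, function(v)
      bic_family_score(d, v, negtetrad:::dag_parents(dag, v)),
      numeric(1)))
    expect_equal(total, by_family, tolerance = 1e-12)
    expect_equal(bic_score(d[rev(names(d))], dag), total,
                 tolerance = 1e-12)

    # adding an edge changes the total by the child's family delta
    topo <- topological_order(dag)
    u <- topo[1]
    v <- topo[length(topo)]
    if (!any(dag$edges[, 1] == u & dag$edges[, 2] == v)) {
      dag2 <- validate_dag(dag$nodes, rbind(dag$edges, c(u, v)))
      delta <- bic_family_score(d, v, negtetrad:::dag_parents(dag2, v)) -
        bic_family_score(d, v, negtetrad:::dag_parents(dag, v))
      expect_equal(bic_score(d, dag2), total + delta, tolerance = 1e-10)
    }
  }
})

test_that("bic_score equals a naive non-decomposed evaluation", {
  set.seed(61)
  d <- sample_bn(random_bn(3, p = 0.6), 60, seed = 2)
  for (edges in list(NULL, rbind(c("A", "B")),
                     rbind(c("A", "B"), c("B", "C")),
                     rbind(c("A", "C"), c("B", "C")))) {
    dag <- validate_dag(c("A", "B", "C"), edges)
    expect_equal(bic_score(d, dag), naive_bic(d, dag),
                 tolerance = 1e-8)
  }
})

test_that("tabu_search separates signal from independence", {
  set.seed(71)
  d_ind <- coin_data(10000, 2, seed = 71)
  names(d_ind) <- c("A", "B")
  r <- tabu_search(d_ind, search_config(seed = 1))
  expect_equal(nrow(r$dag$edges), 0)
  # exhaustive check: the empty graph really is BIC-optimal here
  single <- bic_score(d_ind, validate_dag(c("A", "B"),
                                          rbind(c("A", "B"))))
  expect_gt(r$score, single)

  d_copy <- data.frame(A = sample(LV, 1000, TRUE))
  d_copy$B <- d_copy$A
  r2 <- tabu_search(d_copy, search_config(seed = 1))
  expect_equal(nrow(r2$dag$edges), 1)
})

test_that("tabu_search attains the exhaustive optimum on 3 nodes", {
  set.seed(81)
  for (rep in 1:5) {
    bn <- random_bn(3, p = 0.6, node_names = c("A", "B", "C"))
    d <- sample_bn(bn, 400, seed = rep)
    best <- max(vapply(all_dags_3(), function(e)
      bic_score(d, validate_dag(c("A", "B", "C"), e)), numeric(1)))
    r <- tabu_search(d, search_config(seed = rep))
    expect_gte(r$score + 1e-9, best)
    expect_equal(r$score, bic_score(d, r$dag), tolerance = 1e-10)
    empty_score <- bic_score(d, validate_dag(c("A", "B", "C")))
    expect_gte(r$score, empty_score)
  }
})

test_that("tabu_search is deterministic and honors max_parents", {
  d <- sample_bn(recovery_bn5(), 500, seed = 3)
  r1 <- tabu_search(d, search_config(seed = 9, random_restarts = 2))
  r2 <- tabu_search(d, search_config(seed = 9, random_restarts = 2))
  expect_identical(r1$dag$edges, r2$dag$edges)
  expect_identical(r1$score, r2$score)

  r3 <- tabu_search(d, search_config(seed = 9, max_parents = 1))
  indeg <- table(factor(r3$dag$edges[, 2], levels = r3$dag$nodes))
  expect_true(all(indeg <= 1))
  expect_error(tabu_search(d["A"], search_config()), "two variables")
  expect_error(tabu_search(data.frame(A = c("x", "y"), B = c("x", "y")),
                           search_config()), "non-binary")
})

test_that("shd counts skeleton and orientation differences", {
  d1 <- validate_dag(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
  d2 <- validate_dag(c("A", "B", "C"), rbind(c("B", "A"), c("B", "C")))
  expect_equal(shd(d1, d1), 0)
  expect_equal(shd(d1, d2, "skeleton"), 0)
  expect_equal(shd(d1, d2, "directed"), 1)
  d3 <- validate_dag(c("A", "B", "C"), rbind(c("A", "C")))
  expect_equal(shd(d1, d3, "skeleton"), 3)
})
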