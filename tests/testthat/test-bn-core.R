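test_that("validate_dag accepts DAGs and rejects cycles and bad endpoints", {
  d <- validate_dag(c("A", "B", "C"))
  expect_s3_class(d, "bn_dag")
  expect_equal(nrow(d$edges), 0)
  expect_setequal(topological_order(d), c("A", "B", "C"))

  expect_error(validate_dag(c("A", "B"),
                            rbind(c("A", "B"), c("B", "A"))), "cycle")
  expect_error(validate_dag(c("A", "B"), rbind(c("A", "Z"))),
               "not declared")
  expect_error(validate_dag(c("A"), rbind(c("A", "A"))), "self-loop")
  expect_error(validate_dag(c("A", "A")), "duplicate")
})

test_that("cycle detection agrees with a DFS oracle on random graphs", {
  set.seed(11)
  nodes <- paste0("N", 1:8)
  for (rep in 1:20) {
    edges <- random_edges(nodes, p = 0.35)
    if (is.null(edges)) next
    expect_false(dfs_has_cycle(nodes, edges))
    expect_s3_class(validate_dag(nodes, edges), "bn_dag")
    # one back-edge along the topological order forces a cycle
    d <- validate_dag(nodes, edges)
    ord <- topological_order(d)
    e <- edges[sample(nrow(edges), 1), ]
    back <- rbind(edges, c(e[2], e[1]))
    expect_true(dfs_has_cycle(nodes, back))
    expect_error(validate_dag(nodes, back))
  }
})

test_that("classify_topology follows the antecessor/node/predecessor rules", {
  chain <- validate_dag(c("A", "B", "C"),
                        rbind(c("A", "B"), c("B", "C")))
  expect_equal(classify_topology(chain),
               c(A = "top", B = "node", C = "bottom"))
  # isolated nodes count as antecessors
  lone <- validate_dag(c("A", "B", "C"))
  expect_equal(unname(classify_topology(lone)), rep("top", 3))
  # partition: every node gets exactly one label
  set.seed(4)
  for (rep in 1:10) {
    d <- validate_dag(paste0("N", 1:7),
                      random_edges(paste0("N", 1:7), 0.3))
    lab <- classify_topology(d)
    expect_setequal(names(lab), d$nodes)
    expect_true(all(lab %in% c("top", "node", "bottom")))
  }
})

test_that("markov_blanket includes spouses and matches the CI oracle", {
  chain <- validate_dag(c("A", "B", "C"),
                        rbind(c("A", "B"), c("B", "C")))
  expect_equal(markov_blanket(chain, "B"), c("A", "C"))
  vstruct <- validate_dag(c("A", "B", "C"),
                          rbind(c("A", "C"), c("B", "C")))
  expect_equal(markov_blanket(vstruct, "A"), c("B", "C"))
  expect_error(markov_blanket(chain, "Z"), "unknown")

  set.seed(21)
  for (rep in 1:5) {
    bn <- random_bn(7, p = 0.35)
    joint <- joint_enumeration(bn)
    for (x in bn$dag$nodes) {
      mb <- markov_blanket(bn$dag, x)
      # conditioned on its blanket, x is independent of every non-member
      for (y in setdiff(bn$dag$nodes, c(x, mb))) {
        expect_lt(max_ci_violation(joint, x, y, mb), 1e-9)
      }
      # moralized symmetry
      for (y in mb) expect_true(x %in% markov_blanket(bn$dag, y))
    }
  }
})

test_that("fit_cpts implements smoothed counting with uniform fallback", {
  dag <- validate_dag("A")
  d <- data.frame(A = c("High", "High", "High", "Low"))
  expect_equal(fit_cpts(d, dag, alpha = 0)$cpts$A$prob[1, "High"], 0.75)
  expect_equal(fit_cpts(d, dag, alpha = 1)$cpts$A$prob[1, "High"], 4 / 6)

  # unobserved parent configuration -> uniform under alpha = 0
  dag2 <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  d2 <- data.frame(A = c("Low", "Low"), B = c("Low", "High"))
  bn2 <- fit_cpts(d2, dag2, alpha = 0)
  expect_equal(unname(bn2$cpts$B$prob["A=High", ]), c(0.5, 0.5))

  expect_error(fit_cpts(d[0, , drop = FALSE], dag), "empty")
  expect_error(fit_cpts(data.frame(A = "Mid"), dag), "non-Low/High")
})

test_that("fitted CPT rows sum to one and deterministic data round-trips", {
  set.seed(31)
  for (alpha in c(0, 0.5, 1, 3)) {
    bn <- random_bn(5, p = 0.5)
    d <- sample_bn(bn, 300, seed = 7)
    fit <- fit_cpts(d, bn$dag, alpha = alpha)
    for (cpt in fit$cpts) {
      expect_true(all(abs(rowSums(cpt$prob) - 1) < 1e-12))
    }
  }
  # a deterministic CPT is reproduced exactly at alpha = 0
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  det <- new_discrete_bn(dag, list(
    A = new_cpt("A", character(0), c(0.5, 0.5)),
    B = new_cpt("B", "A", rbind(c(1, 0), c(0, 1)))
  ))
  d <- sample_bn(det, 200, seed = 9)
  refit <- fit_cpts(d, dag, alpha = 0)
  expect_equal(refit$cpts$B$prob, det$cpts$B$prob)
})

test_that("network JSON and DOT serialization round-trip", {
  set.seed(41)
  bn <- random_bn(5, p = 0.5)
  json <- bn_to_json(bn)
  back <- bn_from_json(json)
  expect_equal(back$dag$nodes, bn$dag$nodes)
  expect_equal(back$dag$edges, bn$dag$edges)
  for (v in bn$dag$nodes) {
    expect_equal(back$cpts[[v]]$prob, bn$cpts[[v]]$prob)
  }
  dot <- dag_to_dot(bn$dag)
  expect_equal(dot[1], "digraph bn {")
  expect_equal(sum(grepl("->", dot, fixed = TRUE)), nrow(bn$dag$edges))
})
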