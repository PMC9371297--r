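spec <- default_study_spec()

test_that("the study fixture has the published shape and topology", {
  expect_length(spec$bn$dag$nodes, 18)
  expect_equal(spec$n_default, 235)
  expect_equal(sum(vapply(spec$item_models, function(m) m$n_items,
                          numeric(1))), 17 + 25 + 15 + 18 + 12)
  topo <- classify_topology(spec$bn$dag)
  expect_equal(names(topo)[topo == "top"], "Error.Devaluation")
  expect_setequal(names(topo)[topo == "bottom"],
                  c("Reg.amotivation", "Error.Important",
                    "Burnout.Achievement", "Anxiety.Concentration"))
  # constructing the spec already ran validate_dag; CPT rows sum to 1
  for (cpt in spec$bn$cpts) {
    expect_true(all(abs(rowSums(cpt$prob) - 1) < 1e-12))
    expect_true(all(cpt$prob > 0 & cpt$prob < 1))
  }
})

test_that("fixture marginals are calibrated to the printed baselines", {
  targets <- c(Anxiety.Concentration = 0.2933,
               Burnout.Achievement = 0.3789,
               Error.Important = 0.1928,
               Reg.amotivation = 0.2304,
               Anxiety.Concerns = 0.6723,
               Error.Devaluation = 0.25)
  for (v in names(targets)) {
    marg <- negtetrad:::ancestral_marginal(spec$bn, v)
    got <- marg$prob[marg[[v]] == "High"]
    expect_equal(got, unname(targets[[v]]), tolerance = 1e-6)
  }
})

test_that("ancestral sampling is reproducible and respects the CPTs", {
  s1 <- sample_factor_states(spec, 100, seed = 5)
  s2 <- sample_factor_states(spec, 100, seed = 5)
  expect_identical(s1, s2)
  s3 <- sample_factor_states(spec, 100, seed = 6)
  expect_false(identical(s1, s3))
  expect_equal(nrow(sample_factor_states(spec)), 235)

  # deterministic CPTs force every record to the same configuration
  dag <- validate_dag(c("A", "B"), rbind(c("A", "B")))
  det <- new_discrete_bn(dag, list(
    A = new_cpt("A", character(0), c(0, 1)),
    B = new_cpt("B", "A", rbind(c(1, 0), c(0, 1)))
  ))
  d <- sample_bn(det, 50, seed = 1)
  expect_true(all(d$A == "High" & d$B == "High"))

  # root frequency within a 3-sigma binomial bound of its parameter
  dag1 <- validate_dag("R")
  bn1 <- new_discrete_bn(dag1, list(
    R = new_cpt("R", character(0), c(0.7, 0.3))))
  freq <- mean(sample_bn(bn1, 10000, seed = 2)$R == "High")
  expect_lt(abs(freq - 0.3), 0.014)
})

test_that("sampled High frequencies match the enumerated marginals", {
  states <- sample_factor_states(spec, 20000, seed = 33)
  for (v in spec$bn$dag$nodes) {
    marg <- negtetrad:::ancestral_marginal(spec$bn, v)
    truth <- marg$prob[marg[[v]] == "High"]
    expect_lt(abs(mean(states[[v]] == "High") - truth), 0.015)
  }
})

test_that("item responses stay in range and track the latent state", {
  states <- sample_factor_states(spec, 500, seed = 3)
  items <- sample_item_responses(states, spec, seed = 4)
  for (m in spec$item_models) {
    cols <- paste0(m$factor, "_", seq_len(m$n_items))
    vals <- unlist(items[cols])
    expect_true(all(vals >= m$scale_min & vals <= m$scale_max))
    expect_true(all(vals == as.integer(vals)))
  }
  # near-zero dispersion with mean_high at the ceiling pins responses
  tiny <- ground_truth_spec(
    chain_bn(),
    list(A = item_model("A", 3, 1, 5, 2, 5, 1e-9),
         B = item_model("B", 2, 1, 5, 2, 5, 1e-9)),
    n_default = 20)
  st <- sample_bn(tiny$bn, 200, seed = 8)
  it <- sample_item_responses(st, tiny, seed = 9)
  expect_true(all(it$A_1[st$A == "High"] == 5))
  expect_true(all(it$A_1[st$A == "Low"] == 2))

  # Monte-Carlo: High-state item mean approaches mean_high
  m <- spec$item_models$Anxiety.Somatic
  high_rows <- states$Anxiety.Somatic == "High"
  big_states <- data.frame(
    Anxiety.Somatic = rep("High", 10000), stringsAsFactors = FALSE)
  big_items <- sample_item_responses(big_states, spec, seed = 10)
  expect_lt(abs(mean(big_items$Anxiety.Somatic_1) - m$mean_high), 0.05)
})

test_that("well-separated item means let discretization recover the state", {
  states <- sample_factor_states(spec, 2000, seed = 11)
  items <- sample_item_responses(states, spec, seed = 12)
  prep <- prepare_factor_dataset(items, factor_mapping_from_spec(spec))
  agreement <- mean(as.matrix(prep$discrete) == as.matrix(states))
  expect_gt(agreement, 0.95)
})

test_that("item_model enforces its mean and scale invariants", {
  expect_error(item_model("X", 3, 1, 5, 4.5, 4.0, 1), "mean_low")
  expect_error(item_model("X", 3, 1, 5, 0.5, 4.0, 1), "mean_low")
  expect_error(item_model("X", 3, 5, 1, 2, 4, 1))
  expect_error(ground_truth_spec(chain_bn(),
                                 list(A = item_model("A", 2, 1, 5, 2, 4, 1)),
                                 10),
               "keyed")
})
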