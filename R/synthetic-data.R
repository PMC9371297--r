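#' Item-response model for one factor
#'
#' Describes how a factor's Likert items are generated conditional on the
#' latent Low/High state: each item response is drawn from a normal with
#' the state-conditional mean and common dispersion, rounded to the
#' nearest integer and clamped to the instrument's scale range.
#'
#' @param factor Factor (sub-scale) name.
#' @param n_items Number of items on the sub-scale.
#' @param scale_min,scale_max Integer response bounds (e.g. 1 and 7).
#' @param mean_low,mean_high State-conditional item means; must satisfy
#'   `scale_min <= mean_low < mean_high <= scale_max`.
#' @param sd Common item standard deviation, > 0.
#' @return Object of class `item_model`.
#' @export
item_model <- function(factor, n_items, scale_min, scale_max,
                       mean_low, mean_high, sd) {
  stopifnot(n_items >= 1, scale_min < scale_max, sd > 0)
  if (!(scale_min <= mean_low && mean_low < mean_high &&
          mean_high <= scale_max)) {
    stop("need scale_min <= mean_low < mean_high <= scale_max for ",
         factor)
  }
  structure(list(factor = factor, n_items = as.integer(n_items),
                 scale_min = as.integer(scale_min),
                 scale_max = as.integer(scale_max),
                 mean_low = mean_low, mean_high = mean_high, sd = sd),
            class = "item_model")
}

#' Ground-truth specification for simulating a questionnaire study
#'
#' @param bn A `discrete_bn` over the latent factor variables.
#' @param item_models Named list of [item_model()] objects, one per
#'   network node.
#' @param n_default Default respondent count for simulated samples.
#' @return Object of class `ground_truth_spec`.
#' @export
ground_truth_spec <- function(bn, item_models, n_default) {
  stopifnot(inherits(bn, "discrete_bn"), n_default > 0)
  if (!setequal(names(item_models), bn$dag$nodes)) {
    stop("item_models must be keyed exactly by the network's nodes")
  }
  structure(list(bn = bn, item_models = item_models[bn$dag$nodes],
                 n_default = as.integer(n_default)),
            class = "ground_truth_spec")
}

#' @export
print.ground_truth_spec <- function(x, ...) {
  cat("Ground-truth study spec:", length(x$bn$dag$nodes),
      "latent factors,",
      sum(vapply(x$item_models, function(m) m$n_items, numeric(1))),
      "items, default n =", x$n_default, "\n")
  invisible(x)
}

# Solve the CPT intercept so that the node's ancestral marginal P(High)
# equals `target`, with the conditional P(High | parents) logistic in the
# number of High parents: p = plogis(b0 + slope * n_high).
solve_intercept <- function(config_prob, n_high, slope, target) {
  stats::uniroot(function(b0)
    sum(config_prob * stats::plogis(b0 + slope * n_high)) - target,
    interval = c(-30, 30), tol = 1e-12)$root
}

# Edge list of the ground-truth factor network. The structure encodes the
# study's qualitative findings: devaluation of sport after error is the
# sole root; it feeds the frustration column, the worry branch of
# anxiety, and the shame/future error factors; the three controlled-
# motivation regulations form a triangle with external regulation feeding
# the anxiety branch; and the four "Negative Tetrad" variables
# (achievement burnout, concentration-disruption anxiety, amotivation,
# importance given to error) are the leaves.
study_edges <- function() {
  rbind(
    c("Error.Devaluation",   "Frust.Autonomy"),
    c("Error.Devaluation",   "Frust.Competency"),
    c("Error.Devaluation",   "Frust.Novelty"),
    c("Error.Devaluation",   "Error.Future"),
    c("Error.Devaluation",   "Error.Shame"),
    c("Error.Devaluation",   "Anxiety.Concerns"),
    c("Frust.Competency",    "Frust.Relation"),
    c("Frust.Novelty",       "Error.Important"),
    c("Frust.Competency",    "Error.Important"),
    c("Frust.Relation",      "Error.Important"),
    c("Error.Disturbance",   "Error.Important"),
    c("Error.Future",        "Error.Disturbance"),
    c("Frust.Autonomy",      "Burnout.Physical"),
    c("Frust.Autonomy",      "Reg.introjected"),
    c("Burnout.Physical",    "Burnout.Achievement"),
    c("Burnout.Physical",    "Burnout.PracDev"),
    c("Burnout.Physical",    "Anxiety.Concentration"),
    c("Burnout.PracDev",     "Burnout.Achievement"),
    c("Error.Shame",         "Burnout.Achievement"),
    c("Reg.introjected",     "Reg.external"),
    c("Reg.introjected",     "Reg.amotivation"),
    c("Reg.introjected",     "Anxiety.Concentration"),
    c("Reg.external",        "Reg.amotivation"),
    c("Reg.external",        "Anxiety.Somatic"),
    c("Anxiety.Concerns",    "Anxiety.Somatic"),
    c("Anxiety.Somatic",     "Anxiety.Concentration")
  )
}

# Target ancestral marginals P(High). Six are the study's printed
# baselines (the four tetrad variables' no-evidence values, worry anxiety
# at 67.23% High, and the root's 25% High); the rest are design choices
# representing the sample's generally low occurrence of negative states.
study_marginals <- function() {
  c(Frust.Autonomy        = 0.24,
    Frust.Competency      = 0.22,
    Frust.Relation        = 0.20,
    Frust.Novelty         = 0.26,
    Error.Devaluation     = 0.25,
    Error.Shame           = 0.30,
    Error.Future          = 0.28,
    Error.Important       = 0.1928,
    Error.Disturbance     = 0.26,
    Anxiety.Somatic       = 0.35,
    Anxiety.Concerns      = 0.6723,
    Anxiety.Concentration = 0.2933,
    Burnout.Physical      = 0.30,
    Burnout.Achievement   = 0.3789,
    Burnout.PracDev       = 0.22,
    Reg.introjected       = 0.35,
    Reg.external          = 0.30,
    Reg.amotivation       = 0.2304)
}

#' Default ground-truth specification emulating the sailing study
#'
#' Builds the 18-factor simulation blueprint: a ground-truth network over
#' the five instruments' sub-scales (psychological-need frustration, fear
#' of error, competitive anxiety, athlete burnout, behavioural
#' regulation), with devaluation-after-error as the sole antecessor and
#' the four Negative-Tetrad variables (achievement burnout,
#' concentration-disruption anxiety, amotivation, importance given to
#' error) as leaves. Conditional probabilities are logistic in the number
#' of High parents with slope `slope`, and each node's intercept is
#' solved so its exact ancestral marginal matches the calibrated target
#' (printed study baselines where available, plausible low-occurrence
#' values elsewhere). Item models follow the instruments' response
#' formats: 17 frustration items on 1-7 (sub-scale split 4/4/4/5), 25
#' fear-of-error items on 1-5, 15 anxiety items on 1-4, 18 burnout items
#' on 1-5, and the 12 controlled-motivation regulation items on 1-7.
#'
#' @param n_default Default respondent count (study size 235).
#' @param slope Log-odds increase in P(High) per High parent; controls
#'   dependence strength.
#' @return A `ground_truth_spec`.
#' @export
default_study_spec <- function(n_default = 235, slope = 2.2) {
  marg <- study_marginals()
  dag <- validate_dag(names(marg), study_edges())
  cpts <- list()
  for (v in topological_order(dag)) {
    pa <- dag_parents(dag, v)
    if (length(pa) == 0) {
      cpts[[v]] <- new_cpt(v, pa, c(1 - marg[[v]], marg[[v]]))
      next
    }
    # exact parent-configuration distribution from the part of the
    # network already built (all ancestors precede v topologically)
    built <- names(cpts)
    sub_dag <- validate_dag(
      built, dag$edges[dag$edges[, 1] %in% built &
                         dag$edges[, 2] %in% built, , drop = FALSE])
    pmarg <- ancestral_marginal(new_discrete_bn(sub_dag, cpts), sort(pa))
    configs <- parent_configs(sort(pa))
    key_m <- do.call(paste, c(pmarg[names(configs)], sep = ","))
    key_c <- do.call(paste, c(configs, sep = ","))
    config_prob <- pmarg$prob[match(key_c, key_m)]
    n_high <- rowSums(configs == "High")
    b0 <- solve_intercept(config_prob, n_high, slope, marg[[v]])
    p <- stats::plogis(b0 + slope * n_high)
    cpts[[v]] <- new_cpt(v, pa, cbind(1 - p, p))
  }
  bn <- new_discrete_bn(dag, cpts[dag$nodes])

  im <- function(factors, n_items, lo, hi, mlow, mhigh, sd) {
    lapply(factors, function(f)
      item_model(f, n_items, lo, hi, mlow, mhigh, sd))
  }
  item_models <- c(
    im(c("Frust.Autonomy", "Frust.Competency", "Frust.Relation"),
       4, 1, 7, 2.5, 5.5, 1.0),
    im("Frust.Novelty", 5, 1, 7, 2.5, 5.5, 1.0),
    im(c("Error.Devaluation", "Error.Shame", "Error.Future",
         "Error.Important", "Error.Disturbance"),
       5, 1, 5, 2.0, 4.0, 0.8),
    im(c("Anxiety.Somatic", "Anxiety.Concerns", "Anxiety.Concentration"),
       5, 1, 4, 1.8, 3.2, 0.6),
    im(c("Burnout.Physical", "Burnout.Achievement", "Burnout.PracDev"),
       6, 1, 5, 2.0, 4.0, 0.8),
    im(c("Reg.introjected", "Reg.external", "Reg.amotivation"),
       4, 1, 7, 2.5, 5.5, 1.0)
  )
  names(item_models) <- vapply(item_models, function(m) m$factor,
                               character(1))
  ground_truth_spec(bn, item_models, n_default)
}

#' Sample records from a discrete network by ancestral sampling
#'
#' Draws each record root-to-leaf in topological order from the
#' network's CPTs. Fully deterministic given the seed.
#'
#' @param bn A `discrete_bn`.
#' @param n Number of records.
#' @param seed Integer RNG seed.
#' @return Data frame of `"Low"`/`"High"` states, `n` rows, one column
#'   per node (in network node order).
#' @export
sample_bn <- function(bn, n, seed = 1) {
  stopifnot(inherits(bn, "discrete_bn"), n > 0)
  nodes <- bn$dag$nodes
  out <- matrix(NA_character_, nrow = n, ncol = length(nodes),
                dimnames = list(NULL, nodes))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (v in topological_order(bn$dag)) {
    cpt <- bn$cpts[[v]]
    if (length(cpt$parents) == 0) {
      p <- rep(cpt$prob[1, "High"], n)
    } else {
      keys <- do.call(paste, c(
        lapply(cpt$parents, function(pa)
          paste0(pa, "=", out[, pa])),
        sep = ","))
      p <- cpt$prob[keys, "High"]
    }
    out[, v] <- ifelse(stats::runif(n) < p, "High", "Low")
  }
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Sample latent factor states for a simulated study
#'
#' Ancestral sampling from the ground-truth network ([sample_bn()]).
#'
#' @param spec A `ground_truth_spec`.
#' @param n Number of respondents; defaults to `spec$n_default`.
#' @param seed Integer RNG seed.
#' @return Data frame of `"Low"`/`"High"` states, `n` rows, one column
#'   per factor.
#' @export
sample_factor_states <- function(spec, n = spec$n_default, seed = 1) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  sample_bn(spec$bn, n, seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate Likert item responses from latent factor states
#'
#' Each item response is drawn from a normal distribution with the
#' state-conditional mean (`mean_low` or `mean_high`) and dispersion
#' `sd`, rounded to the nearest integer and clamped to the item's scale
#' range, giving integer Likert responses.
#'
#' @param states Data frame of `"Low"`/`"High"` factor states (one row
#'   per respondent).
#' @param spec A `ground_truth_spec` providing the item models.
#' @param seed Integer RNG seed (independent of the state-sampling seed).
#' @return Data frame of integer item responses; columns named
#'   `<factor>_<i>`.
#' @export
sample_item_responses <- function(states, spec, seed = 1) {
  stopifnot(inherits(spec, "ground_truth_spec"))
  if (!all(names(states) %in% names(spec$item_models))) {
    stop("states contains factors without an item model")
  }
  n <- nrow(states)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cols <- list()
  for (f in names(states)) {
    m <- spec$item_models[[f]]
    mu <- ifelse(states[[f]] == "High", m$mean_high, m$mean_low)
    for (i in seq_len(m$n_items)) {
      x <- round(stats::rnorm(n, mean = mu, sd = m$sd))
      cols[[paste0(f, "_", i)]] <- as.integer(
        pmin(pmax(x, m$scale_min), m$scale_max))
    }
  }
  as.data.frame(cols, check.names = FALSE)
}
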