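#' Greedy stepwise evidence instantiation
#'
#' The study's signature procedure: starting from the target's
#' no-evidence posterior, repeatedly instantiate the single remaining
#' candidate variable (to `"High"` by default, matching the stepwise
#' tables' Level column) that most increases P(target = target_level),
#' and stop when no candidate gains at least `min_gain`, when candidates
#' are exhausted, or at `max_steps`. The first step records the baseline
#' ("None (BN initial value)"). Posterior values are reported multiplied
#' by 100. Ties are broken by variable name, so the trace is
#' deterministic and independent of candidate order.
#'
#' With every CPT entry strictly inside (0, 1) no evidence can drive the
#' posterior to exactly 100 — the trace's ceiling mirrors the
#' impossibility of certainty under a strictly positive network.
#'
#' @param bn A `discrete_bn`.
#' @param target Variable whose posterior is maximized.
#' @param target_level Level being maximized (default `"High"`).
#' @param candidates Variables eligible for instantiation; defaults to
#'   all non-target variables.
#' @param candidate_level Level candidates are asserted at (default
#'   `"High"`).
#' @param min_gain Minimum increase in P(target = target_level) required
#'   to accept a step (default 0.001, i.e. 0.1 percentage point).
#' @param max_steps Maximum number of instantiation steps.
#' @return Object of class `instantiation_trace`: list with `target`,
#'   `target_level`, `steps` (data frame with columns `step`, `variable`,
#'   `level`, `value` — `value` is P(target = target_level) x 100) and
#'   `stop_reason` (`"no_gain"`, `"exhausted"` or `"max_steps"`).
#' @export
greedy_instantiation <- function(bn, target, target_level = "High",
                                 candidates = NULL,
                                 candidate_level = "High",
                                 min_gain = 0.001,
                                 max_steps = Inf) {
  stopifnot(inherits(bn, "discrete_bn"), min_gain > 0,
            target_level %in% BN_LEVELS,
            candidate_level %in% BN_LEVELS)
  if (!target %in% bn$dag$nodes) stop("unknown target: ", target)
  if (is.null(candidates)) {
    candidates <- setdiff(bn$dag$nodes, target)
  }
  candidates <- sort(unique(as.character(candidates)))
  if (target %in% candidates) {
    stop("target must not be among the candidates")
  }
  unknown <- setdiff(candidates, bn$dag$nodes)
  if (length(unknown) > 0) {
    stop("unknown candidate(s): ", paste(unknown, collapse = ", "))
  }
  evidence <- character(0)
  current <- unname(
    posterior_marginal(bn, target, evidence)[[target_level]])
  steps <- data.frame(step = 1L, variable = "none",
                      level = candidate_level,
                      value = 100 * current,
                      stringsAsFactors = FALSE)
  remaining <- candidates
  stop_reason <- "exhausted"
  while (length(remaining) > 0) {
    if (nrow(steps) - 1L >= max_steps) {
      stop_reason <- "max_steps"
      break
    }
    gains <- vapply(remaining, function(v) {
      ev <- c(evidence, stats::setNames(candidate_level, v))
      post <- tryCatch(posterior_marginal(bn, target, ev),
                       error = function(e)
                         stop("inconsistent evidence when instantiating ",
                              v, ": ", conditionMessage(e)))
      unname(post[[target_level]]) - current
    }, numeric(1))
    best <- sort(remaining[gains == max(gains)])[1]
    if (gains[[best]] < min_gain) {
      stop_reason <- "no_gain"
      break
    }
    evidence <- c(evidence, stats::setNames(candidate_level, best))
    current <- current + gains[[best]]
    steps <- rbind(steps, data.frame(
      step = nrow(steps) + 1L, variable = best,
      level = candidate_level, value = 100 * current,
      stringsAsFactors = FALSE))
    remaining <- setdiff(remaining, best)
  }
  structure(list(target = target, target_level = target_level,
                 steps = steps, stop_reason = stop_reason),
            class = "instantiation_trace")
}

#' @export
print.instantiation_trace <- function(x, ...) {
  cat("Stepwise instantiation towards P(", x$target, " = ",
      x$target_level, ")\n", sep = "")
  tab <- x$steps
  tab$value <- sprintf("%.2f", tab$value)
  tab$variable[1] <- "None (BN initial value)"
  names(tab) <- c("Step", "Instantiated variable", "Level", "Value")
  print.data.frame(tab, row.names = FALSE)
  cat("stopped:", x$stop_reason, "\n")
  invisible(x)
}

#' Write an instantiation trace as CSV
#'
#' Columns `Step`, `Instantiated variable`, `Level`, `Value` — the
#' stepwise-table layout, values rounded to two decimals.
#'
#' @param trace An `instantiation_trace`.
#' @param path Output file path.
#' @return The written data frame, invisibly.
#' @export
trace_to_csv <- function(trace, path) {
  stopifnot(inherits(trace, "instantiation_trace"))
  tab <- trace$steps
  tab$variable[1] <- "None (BN initial value)"
  tab$value <- round(tab$value, 2)
  names(tab) <- c("Step", "Instantiated variable", "Level", "Value")
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Topology report with the bottom-set ("tetrad") flag
#'
#' Lists the network's top (antecessor), intermediate and bottom
#' (predecessor) variables and attaches the supplied instantiation
#' traces. The bottom set is flagged as a tetrad exactly when it has
#' four members — the constellation of negatively-valenced leaves the
#' analysis looks for. A warning is issued for traces whose target is
#' not a bottom variable.
#'
#' @param dag A `bn_dag`.
#' @param traces List of `instantiation_trace` objects (possibly empty).
#' @return Object of class `tetrad_report`: list with `top`, `node`,
#'   `bottom` (sorted name vectors), `is_tetrad` (logical), `traces`.
#' @export
tetrad_report <- function(dag, traces = list()) {
  stopifnot(inherits(dag, "bn_dag"))
  if (inherits(traces, "instantiation_trace")) traces <- list(traces)
  topo <- classify_topology(dag)
  bottom <- sort(names(topo)[topo == "bottom"])
  targets <- vapply(traces, function(t) t$target, character(1))
  stray <- setdiff(targets, bottom)
  if (length(stray) > 0) {
    warning("trace target(s) not in the bottom set: ",
            paste(stray, collapse = ", "))
  }
  structure(list(top = sort(names(topo)[topo == "top"]),
                 node = sort(names(topo)[topo == "node"]),
                 bottom = bottom,
                 is_tetrad = length(bottom) == 4,
                 traces = traces),
            class = "tetrad_report")
}

#' @export
print.tetrad_report <- function(x, ...) {
  cat("Topology report\n")
  cat("  top (antecessor):", paste(x$top, collapse = ", "), "\n")
  cat("  node:            ", paste(x$node, collapse = ", "), "\n")
  cat("  bottom:          ", paste(x$bottom, collapse = ", "), "\n")
  cat("  bottom set of", length(x$bottom),
      if (x$is_tetrad) "-> Negative Tetrad" else "(no tetrad flag)",
      "\n")
  for (t in x$traces) {
    cat("\n")
    print(t)
  }
  invisible(x)
}

#' Serialize a tetrad report to JSON
#'
#' @param report A `tetrad_report`.
#' @param path Optional output path; when `NULL` the JSON is returned.
#' @return JSON string, invisibly when written.
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "tetrad_report"))
  obj <- list(top = report$top, node = report$node,
              bottom = report$bottom, is_tetrad = report$is_tetrad,
              traces = lapply(report$traces, function(t)
                list(target = t$target, target_level = t$target_level,
                     stop_reason = t$stop_reason, steps = t$steps)))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Deserialize a tetrad report from JSON
#'
#' @param json JSON string or file path written by [report_to_json()].
#' @return A `tetrad_report` (traces restored as
#'   `instantiation_trace` objects).
#' @export
report_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json, simplifyDataFrame = TRUE)
  traces <- list()
  if (length(obj$traces) > 0) {
    tr <- obj$traces
    traces <- lapply(seq_len(nrow(tr)), function(i) {
      steps <- as.data.frame(tr$steps[[i]])
      steps$step <- as.integer(steps$step)
      structure(list(target = tr$target[i],
                     target_level = tr$target_level[i],
                     steps = steps,
                     stop_reason = tr$stop_reason[i]),
                class = "instantiation_trace")
    })
  }
  structure(list(top = as.character(obj$top),
                 node = as.character(obj$node),
                 bottom = as.character(obj$bottom),
                 is_tetrad = isTRUE(obj$is_tetrad),
                 traces = traces),
            class = "tetrad_report")
}
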