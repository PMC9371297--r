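#!/usr/bin/env Rscript
# Stage 1 — simulate a study-like questionnaire sample.
#
# The original 235-respondent sailing dataset is not public, so the
# analysis runs on a synthetic cohort: 18 Low/High latent factors drawn
# ancestrally from the calibrated ground-truth network, then Likert item
# responses per factor. Outputs: results/data/{states,items}.csv and the
# ground-truth network JSON.

suppressPackageStartupMessages(library(negtetrad))

master_seed <- 1L
n <- 235L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- default_study_spec(n_default = n)
cat("Ground-truth network:", length(spec$bn$dag$nodes), "factors,",
    nrow(spec$bn$dag$edges), "edges\n")
cat("Calibrated baseline P(High), percent:\n")
for (v in c("Error.Devaluation", "Anxiety.Concerns",
            "Anxiety.Concentration", "Burnout.Achievement",
            "Error.Important", "Reg.amotivation")) {
  m <- negtetrad:::ancestral_marginal(spec$bn, v)
  cat(sprintf("  %-22s %6.2f\n", v, 100 * m$prob[m[[v]] == "High"]))
}

states <- sample_factor_states(spec, n, seed = master_seed + 1L)
items <- sample_item_responses(states, spec, seed = master_seed + 2L)
cat("Simulated", nrow(states), "respondents,", ncol(items), "items\n")

write.csv(states, file.path(out, "states.csv"), row.names = FALSE)
write.csv(items, file.path(out, "items.csv"), row.names = FALSE)
bn_to_json(spec$bn, file.path(out, "ground_truth_network.json"))
mp <- factor_mapping_from_spec(spec)
write.csv(data.frame(item = names(mp$items), factor = unname(mp$items)),
          file.path(out, "item_mapping.csv"), row.names = FALSE)
write.csv(mp$bounds, file.path(out, "scale_bounds.csv"),
          row.names = FALSE)
cat("Wrote", out, "\n")
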