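#!/usr/bin/env Rscript
# Runs the whole analysis in order. Equivalent to
# run_full_analysis(pipeline_config()), but staged so each step's
# outputs can be inspected under results/.

for (script in c("analysis/01_simulate_study.R",
                 "analysis/02_preprocess.R",
                 "analysis/03_learn_network.R",
                 "analysis/04_validate.R",
                 "analysis/05_instantiate.R")) {
  cat("\n==>", script, "\n")
  source(script, echo = FALSE)
}
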