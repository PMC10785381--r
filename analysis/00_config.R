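# Shared settings for the analysis scripts. Every script can be re-run from
# a clean checkout; all randomness descends from this seed.

library(nnagp)

ANALYSIS_SEED <- 42L
DATA_DIR <- "results/simulated_data"
RESULTS_DIR <- "results"

analysis_config <- function() sim_config(seed = ANALYSIS_SEED)

dir.create(RESULTS_DIR, showWarnings = FALSE, recursive = TRUE)
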