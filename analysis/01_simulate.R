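#!/usr/bin/env Rscript
# Generate the synthetic semi-field experiment: ~70 inbred barley-like lines
# on 2 beds x 2 half-bed units x 150 rows (wet and dry half-rows, 1200
# above-ground records), minirhizotron images at 3 time points, and SNP
# genotypes with family structure. Writes the delimited-text data set that
# the remaining scripts consume, plus the generating truth.

source("analysis/00_config.R")

cfg <- analysis_config()
sim <- simulate_experiment(cfg)
paths <- write_simulation(sim, DATA_DIR, cfg)

cat("Simulated experiment (seed", cfg$seed, ")\n")
cat("  lines:           ", nrow(sim$geno$dosages), "\n")
cat("  SNPs:            ", ncol(sim$geno$dosages), "\n")
cat("  above-ground rec:", nrow(sim$above$records), "\n")
cat("  root images:     ", nrow(sim$roots$images), "\n")
cat("  GRM avg diagonal:", round(sim$grm$d_g, 3), "\n")
cat("files written under", DATA_DIR, "\n")
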