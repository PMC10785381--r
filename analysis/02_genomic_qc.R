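#!/usr/bin/env Rscript
# Genomic quality control and relationship matrix: read the dosage table,
# apply the missingness and MAF filters, impute the residual gaps, and build
# the VanRaden genomic relationship matrix. The average diagonal d(G) close
# to 2 reflects the (near-)fully inbred lines.

source("analysis/00_config.R")

geno_path <- file.path(DATA_DIR, "genotypes.tsv")
if (!file.exists(geno_path))
  stop("run analysis/01_simulate.R first (missing ", geno_path, ")")

geno <- read_genotypes(geno_path)
print(geno)

filtered <- filter_snps(geno, max_missing = 0.10, min_maf = 0.03)
cat("QC report:\n")
print(attr(filtered, "qc_report"), row.names = FALSE)

grm <- compute_grm(impute_missing(filtered))
print(grm)

write_grm(grm, file.path(RESULTS_DIR, "grm.tsv"))
write.table(attr(filtered, "qc_report"),
            file.path(RESULTS_DIR, "qc_report.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("wrote", file.path(RESULTS_DIR, "grm.tsv"), "\n")
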