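# nnagp — genomic prediction with nearest-neighbour spatial adjustment

`nnagp` is an R package and analysis workflow for genomic prediction of
above-ground and root traits in semi-field row experiments grown under a
water-availability gradient. It is aimed at quantitative geneticists and
plant breeders analysing long single-row layouts — e.g. rain-out-shelter
facilities where each sown row is split into a wet and a dry half and root
growth is imaged through minirhizotron tubes — but every component (the
spatial kernels, the REML engine, the cross-validation machinery) is generic.

## The models

Phenotypes are analysed with multi-kernel linear mixed models. For an
above-ground trait measured on half-rows,

```
y = Xb + Z_g g + Z_l l + Z_ng n_g + Z_nl n_l + Z_r r
      + Z_tg t_g + Z_tl t_l + Z_s1 s_1 + Z_s2 s_2 + e
```

with fixed unit-bed-treatment means `b`; additive genomic values
`g ~ N(0, G σ²_g)` with `G` the VanRaden genomic relationship matrix
`G = MM′ / 2Σp_j(1−p_j)`; non-additive line effects `l ~ N(0, I σ²_l)`;
genomic and non-genomic effects of the two flanking neighbour lines
(`n_g`, `n_l`); row effects `r`; genotype-by-treatment interactions `t_g`
(block-diagonal `G` per treatment) and `t_l`; one spatial effect per
treatment with covariance `S σ²_s`; and residual `e`. Root traits use the
same machinery with a bed-camera-time fixed factor, repeated tube records
across three imaging time points, and one spatial variance per time point.

The two spatial kernels are built from row-neighbourhood loading matrices
and trace-normalised, `S = XX′ / (tr(XX′)/n)`:

* `S_knn` — indicator loadings on the target row and its 5 left / 5 right
  neighbours, giving interior correlation exactly `(11 − d)/11` at a
  separation of `d` rows;
* `S_euc` — the same neighbourhood weighted by Euclidean distance,
  `w = 1 − d_ij/2.75 m`, which concentrates correlation on close neighbours.

Virtual rows pad each half-bed unit so every real row has a complete
neighbour window. Variance components are estimated by average-information
REML with EM fallback and variance flooring; genetic parameters
(`σ²_P`, `h²`, `H²`, GCV) and leave-one-line-out cross-validation statistics
(predictive ability, maximum potential PA `√(nh²/(1+(n−1)h²))`, accuracy,
dispersion slope `b_w,p`, bootstrap SEs, Hotelling–Williams tests) follow.

## Worked example

The `analysis/` scripts run the full pipeline on a synthetic experiment
(70 inbred lines, 2 beds × 2 half-bed units × 150 rows, 1200 half-row
records, 42 300 root images), in order:

```sh
Rscript analysis/01_simulate.R          # generate the experiment (seed 42)
Rscript analysis/02_genomic_qc.R        # SNP QC and the VanRaden GRM
Rscript analysis/03_spatial_structures.R
Rscript analysis/04_fit_above_ground.R  # AM1/AM2 REML fits + genetic params
Rscript analysis/05_fit_roots.R         # RM1/RM2 on TRL/SRL/DRL
Rscript analysis/06_cross_validation.R  # LOO-CV prediction report
```

`02_genomic_qc.R` prints, for the simulated genotypes,

```
<genotype_matrix> 70 lines x 3000 SNPs, 0.00% missing
      snp_maf     432     2568
<grm> 70 lines, d(G) = 1.854
```

— 432 SNPs fail the 3% MAF floor and the GRM average diagonal `d(G) ≈ 1.85`
reflects the near-fully-inbred lines. `06_cross_validation.R` ends with

```
 model    pa  pa_se max_pa   acc  b_wp b_wp_se n_lines n_obs
   AM1 0.311 0.0248  0.966 0.322 1.030  0.2038      70  1195
   AM2 0.312 0.0248  0.966 0.322 1.032  0.2037      70  1195
```

a predictive ability of ~0.31 (correlation between corrected phenotypes and
leave-one-line-out GEBVs), accuracy ~0.32 of the theoretical maximum, and a
dispersion slope `b_w,p ≈ 1.03` — no meaningful inflation of predicted
genetic effects. Each script writes its tables under `results/`.

Real data in the same delimited-text schemas (genotype dosage table,
half-row phenotype records, per-image root lengths) drop into the same
functions; see `?read_genotypes`, `?read_phenotypes`, `?read_root_images`.

## Package layout

* `R/` — layout & spatial structures, genomics/GRM, trait derivation and
  editing, the AI-REML engine, study-model assembly and genetic parameters,
  cross-validation statistics, the synthetic-data generator.
* `tests/testthat/` — unit, property and end-to-end acceptance tests.
* `vignettes/` — the methods vignette (modelling background and design
  choices).
* `analysis/` — the numbered workflow scripts above.
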