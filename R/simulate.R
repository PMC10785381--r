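#' Configuration for a synthetic semi-field experiment
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the study design the package targets: ~70 inbred spring-barley lines
#' genotyped at thousands of SNPs (MAF >= 3%), two beds of two half-bed units
#' with 150 rows each at 0.25 m spacing, a wet and a dry half per row
#' (~1200 half-row records), minirhizotron tubes in one unit per bed imaged
#' at three time points, and generating variance components of the magnitude
#' reported for grain yield (above-ground) and total root length (roots).
#'
#' @param seed integer seed; mandatory, drives every random draw through
#'   per-component substreams (so adding one model term never shifts the
#'   draws of another).
#' @param n_lines,n_snps population size and marker count.
#' @param maf_range range of simulated allele frequencies.
#' @param n_founders number of inbred founders whose biparental crosses the
#'   lines descend from; gives the relationship matrix the family structure
#'   of breeding material (needed to separate genomic from line variance).
#'   `NULL` simulates unrelated lines.
#' @param inbreeding probability that a line is fully homozygous at a SNP;
#'   the GRM average diagonal approaches `1 + inbreeding`.
#' @param geno_missing fraction of dosages set missing (for QC testing).
#' @param beds,units_per_bed,rows_per_unit,row_spacing layout geometry.
#' @param k,d_max spatial window parameters (rows per side; metres).
#' @param spatial_kind `"knn"` or `"euc"`: kernel used to draw the spatial
#'   fields.
#' @param vc_above named generating variances for the above-ground model
#'   (`g, l, ng, nl, r, tg, tl, s1, s2, e`).
#' @param mu_above fixed treatment means (named `wet`, `dry`).
#' @param vc_root named generating variances for the root model
#'   (`g, l, r, s1, s2, s3, e`).
#' @param mu_root fixed time-point means (length 3, trait units).
#' @param mr_unit unit index carrying minirhizotron tubes in each bed.
#' @param depth_grid image depths in cm (one image every 5 cm).
#' @param depth_mean,depth_sd Gaussian depth-profile location/spread per time
#'   point (cm); the profile deepens over time so the deep-window root
#'   fraction grows.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed,
                       n_lines = 70, n_snps = 3000,
                       maf_range = c(0.03, 0.5), n_founders = 8,
                       inbreeding = 0.86,
                       geno_missing = 0,
                       beds = 2, units_per_bed = 2, rows_per_unit = 150,
                       row_spacing = 0.25, k = 5, d_max = 2.75,
                       spatial_kind = c("knn", "euc"),
                       vc_above = c(g = 0.23, l = 0.11, ng = 0, nl = 0,
                                    r = 0.13, tg = 0.01, tl = 0.01,
                                    s1 = 0.12, s2 = 0.06, e = 0.48),
                       mu_above = c(wet = 7.20, dry = 6.91),
                       vc_root = c(g = 10.13, l = 0, r = 127.82,
                                   s1 = 61.89, s2 = 88.45, s3 = 232.72,
                                   e = 50),
                       mu_root = c(24, 34, 43),
                       mr_unit = 1,
                       depth_grid = seq(40, 270, by = 5),
                       depth_mean = c(80, 110, 140),
                       depth_sd = c(25, 30, 35)) {
  if (missing(seed)) stop("a seed is mandatory for reproducibility", call. = FALSE)
  if (any(vc_above < 0) || any(vc_root < 0))
    stop("generating variances must be non-negative", call. = FALSE)
  cfg <- list(seed = as.integer(seed), n_lines = n_lines, n_snps = n_snps,
              maf_range = maf_range, n_founders = n_founders,
              inbreeding = inbreeding,
              geno_missing = geno_missing,
              beds = beds, units_per_bed = units_per_bed,
              rows_per_unit = rows_per_unit, row_spacing = row_spacing,
              k = k, d_max = d_max,
              spatial_kind = match.arg(spatial_kind),
              vc_above = vc_above, mu_above = mu_above,
              vc_root = vc_root, mu_root = mu_root, mr_unit = mr_unit,
              depth_grid = depth_grid, depth_mean = depth_mean,
              depth_sd = depth_sd)
  class(cfg) <- "sim_config"
  cfg
}

## Named substream: a deterministic seed per generator component, so each
## component's draws are independent of which others are generated.
substream <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  set.seed((seed * 7919L + h) %% .Machine$integer.max)
}

## Draw N(0, K * s2) via the (pivoted, PSD-tolerant) Cholesky factor.
draw_mvn <- function(K, s2) {
  q <- nrow(K)
  if (s2 <= 0) return(stats::setNames(rep(0, q), rownames(K)))
  ch <- suppressWarnings(chol(K + diag(1e-10 * mean(diag(K)) + 1e-12, q),
                              pivot = TRUE))
  piv <- attr(ch, "pivot")
  x <- numeric(q)
  x[piv] <- as.numeric(t(ch) %*% stats::rnorm(q))
  stats::setNames(sqrt(s2) * x, rownames(K))
}

#' Simulate inbred-line SNP genotypes
#'
#' Draws per-SNP allele frequencies uniformly over `maf_range`. With
#' `n_founders` set (the default), inbred founders are drawn at those
#' frequencies and each line descends from a biparental founder cross,
#' inheriting either parent's allele per SNP — giving the sample the family
#' structure of breeding material, with related lines sharing long-run allele
#' states. At each SNP a line is fully homozygous with probability
#' `inbreeding` (dosage 0 or 2); with the complementary probability the
#' dosage is an outbred `Binomial(2, p)` draw, so the GRM average diagonal
#' approaches `1 + inbreeding`. `n_founders = NULL` gives unrelated lines.
#' Optional missing entries exercise the quality-control filters.
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] with attribute `truth` (the generating
#'   allele frequencies and the founder-pair family of each line).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  substream(config$seed, "genotypes")
  p <- stats::runif(config$n_snps, config$maf_range[1], config$maf_range[2])
  n <- config$n_lines
  P <- matrix(p, n, config$n_snps, byrow = TRUE)
  family <- NULL
  if (!is.null(config$n_founders)) {
    nf <- config$n_founders
    founders <- matrix(stats::rbinom(nf * config$n_snps, 1,
                                     matrix(p, nf, config$n_snps, byrow = TRUE)),
                       nf, config$n_snps)
    crosses <- utils::combn(nf, 2)
    family <- (seq_len(n) - 1L) %% ncol(crosses) + 1L
    pick <- matrix(stats::rbinom(n * config$n_snps, 1, 0.5), n)
    par1 <- founders[crosses[1, family], , drop = FALSE]
    par2 <- founders[crosses[2, family], , drop = FALSE]
    inherited <- 2 * (pick * par1 + (1 - pick) * par2)
  } else {
    inherited <- 2 * matrix(stats::rbinom(n * config$n_snps, 1, P), n)
  }
  hom <- matrix(stats::rbinom(n * config$n_snps, 1, config$inbreeding),
                n, config$n_snps)
  d <- hom * inherited +
    (1 - hom) * matrix(stats::rbinom(n * config$n_snps, 2, P), n)
  if (config$geno_missing > 0) {
    miss <- matrix(stats::runif(n * config$n_snps) < config$geno_missing,
                   n, config$n_snps)
    d[miss] <- NA
  }
  dimnames(d) <- list(sprintf("L%03d", seq_len(n)),
                      sprintf("snp%05d", seq_len(config$n_snps)))
  out <- genotype_matrix(d)
  attr(out, "truth") <- list(p = p, inbreeding = config$inbreeding,
                             family = family)
  out
}

## Layout with lines randomised within bed, under the config's substream.
sim_layout <- function(config) {
  lay <- build_layout(config$beds, config$units_per_bed, config$rows_per_unit,
                      config$row_spacing, k = config$k, d_max = config$d_max)
  substream(config$seed, "layout")
  assign_lines(lay, sprintf("L%03d", seq_len(config$n_lines)))
}

sim_spatial <- function(config, layout) {
  if (config$spatial_kind == "knn") build_s_knn(layout, k = config$k)
  else build_s_euc(layout, d_max = config$d_max)
}

#' Simulate above-ground half-row records
#'
#' Generates phenotypes from the above-ground model equation: treatment mean
#' plus additive genomic (`g`), line (`l`), left+right neighbour-line genomic
#' and non-genomic (`ng`, `nl`), row (`r`), genotype-by-treatment (`tg`,
#' `tl`), treatment-specific spatial (drawn with the configured
#' nearest-neighbour kernel) and residual effects, each from its normal
#' distribution at the configured variance. One record per real row and
#' treatment.
#'
#' @param config a [sim_config()].
#' @param geno a [genotype_matrix()] for the same lines (defaults to a fresh
#'   [simulate_genotypes()] draw).
#' @param layout optional pre-built layout with lines assigned.
#' @return list with `records` (data frame `bed`, `unit`, `row`, `treatment`,
#'   `line`, `y`), `truth` (generating effect vectors and variances),
#'   `geno`, `grm`, `layout` and `spatial`.
#' @export
simulate_above_ground <- function(config, geno = NULL, layout = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(geno)) geno <- simulate_genotypes(config)
  if (is.null(layout)) layout <- sim_layout(config)
  grm <- compute_grm(impute_missing(geno))
  spatial <- sim_spatial(config, layout)
  vc <- config$vc_above
  lines <- rownames(grm$G)
  rows <- real_rows(layout)
  n_rows <- nrow(rows)

  substream(config$seed, "above_g");  g <- draw_mvn(grm$G, vc["g"])
  substream(config$seed, "above_l")
  l <- stats::setNames(stats::rnorm(length(lines), 0, sqrt(vc["l"])), lines)
  substream(config$seed, "above_ng"); ng <- draw_mvn(grm$G, vc["ng"])
  substream(config$seed, "above_nl")
  nl <- stats::setNames(stats::rnorm(length(lines), 0, sqrt(vc["nl"])), lines)
  substream(config$seed, "above_r")
  r <- stats::setNames(stats::rnorm(n_rows, 0, sqrt(vc["r"])), rows$row_id)
  substream(config$seed, "above_tg")
  tg <- c(draw_mvn(grm$G, vc["tg"]), draw_mvn(grm$G, vc["tg"]))
  names(tg) <- c(paste(lines, "wet", sep = ":"), paste(lines, "dry", sep = ":"))
  substream(config$seed, "above_tl")
  tl <- stats::setNames(stats::rnorm(2 * length(lines), 0, sqrt(vc["tl"])),
                        names(tg))
  substream(config$seed, "above_s1"); s1 <- draw_mvn(spatial$S, vc["s1"])
  substream(config$seed, "above_s2"); s2 <- draw_mvn(spatial$S, vc["s2"])

  ## neighbour-line lookup along each unit
  key <- paste(layout$bed, layout$unit, layout$row)
  nb_line <- function(offset) layout$line[
    match(paste(rows$bed, rows$unit, rows$row + offset), key)]
  left <- nb_line(-1L); right <- nb_line(1L)
  nb_effect <- function(eff) {
    out <- numeric(n_rows)
    out[!is.na(left)] <- out[!is.na(left)] + eff[left[!is.na(left)]]
    out[!is.na(right)] <- out[!is.na(right)] + eff[right[!is.na(right)]]
    out
  }
  row_base <- g[rows$line] + l[rows$line] + nb_effect(ng) + nb_effect(nl) +
    r[rows$row_id]

  records <- do.call(rbind, lapply(c("wet", "dry"), function(tr) {
    data.frame(bed = rows$bed, unit = rows$unit, row = rows$row_id,
               treatment = tr, line = rows$line,
               y = config$mu_above[tr] + row_base +
                 tg[paste(rows$line, tr, sep = ":")] +
                 tl[paste(rows$line, tr, sep = ":")] +
                 (if (tr == "wet") s1 else s2)[rows$row_id])
  }))
  substream(config$seed, "above_e")
  records$y <- records$y + stats::rnorm(nrow(records), 0, sqrt(vc["e"]))
  rownames(records) <- NULL

  list(records = records,
       truth = list(vc = vc, g = g, l = l, ng = ng, nl = nl, r = r,
                    tg = tg, tl = tl, s1 = s1, s2 = s2, seed = config$seed),
       geno = geno, grm = grm, layout = layout, spatial = spatial)
}

#' Simulate minirhizotron root images
#'
#' Generates tube x time-point latent root lengths from the root model
#' equation (time-point mean + genomic + line + row + time-specific spatial +
#' residual effects) for the minirhizotron-equipped unit of each bed, then
#' allocates each latent total across a 5 cm depth grid with a scaled
#' Gaussian depth profile whose centre deepens across time points. Image
#' lengths sum exactly to the (non-negative part of the) latent total, so
#' [summarize_roots()] recovers it.
#'
#' @inheritParams simulate_above_ground
#' @return list with `images` (data frame `bed`, `row`, `time`, `depth`,
#'   `length`), `latent` (tube x time records with the latent trait `y` and
#'   line ids), `truth`, `geno`, `grm`, `layout` and `spatial`.
#' @export
simulate_root_images <- function(config, geno = NULL, layout = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(geno)) geno <- simulate_genotypes(config)
  if (is.null(layout)) layout <- sim_layout(config)
  grm <- compute_grm(impute_missing(geno))
  spatial <- sim_spatial(config, layout)
  vc <- config$vc_root
  lines <- rownames(grm$G)
  rows <- real_rows(layout)
  mr <- rows[rows$unit == config$mr_unit, , drop = FALSE]

  substream(config$seed, "root_g"); g <- draw_mvn(grm$G, vc["g"])
  substream(config$seed, "root_l")
  l <- stats::setNames(stats::rnorm(length(lines), 0, sqrt(vc["l"])), lines)
  substream(config$seed, "root_r")
  r <- stats::setNames(stats::rnorm(nrow(rows), 0, sqrt(vc["r"])), rows$row_id)
  s <- lapply(1:3, function(k) {
    substream(config$seed, paste0("root_s", k))
    draw_mvn(spatial$S, vc[paste0("s", k)])
  })

  latent <- do.call(rbind, lapply(1:3, function(k) {
    data.frame(bed = mr$bed, row = mr$row_id, time = k, line = mr$line,
               camera = mr$bed,
               y = config$mu_root[k] + g[mr$line] + l[mr$line] +
                 r[mr$row_id] + s[[k]][mr$row_id])
  }))
  substream(config$seed, "root_e")
  latent$y <- latent$y + stats::rnorm(nrow(latent), 0, sqrt(vc["e"]))
  rownames(latent) <- NULL

  depth <- config$depth_grid
  images <- do.call(rbind, lapply(seq_len(nrow(latent)), function(i) {
    k <- latent$time[i]
    w <- stats::dnorm(depth, config$depth_mean[k], config$depth_sd[k])
    w <- w / sum(w)
    data.frame(bed = latent$bed[i], row = latent$row[i], time = k,
               depth = depth, length = max(latent$y[i], 0) * w)
  }))
  rownames(images) <- NULL

  list(images = images, latent = latent,
       truth = list(vc = vc, g = g, l = l, r = r, s = s, seed = config$seed),
       geno = geno, grm = grm, layout = layout, spatial = spatial)
}

#' Simulate a complete synthetic experiment
#'
#' One call generating everything the analysis pipeline consumes: genotypes,
#' GRM, layout with line assignment, spatial structure, above-ground half-row
#' records and root images (sharing the same genotypes and layout), plus the
#' generating truth for parameter-recovery checks.
#'
#' @param config a [sim_config()].
#' @return list with `geno`, `grm`, `layout`, `spatial`, `above` (records +
#'   truth) and `roots` (images + latent + truth).
#' @export
simulate_experiment <- function(config) {
  geno <- simulate_genotypes(config)
  layout <- sim_layout(config)
  above <- simulate_above_ground(config, geno, layout)
  roots <- simulate_root_images(config, geno, layout)
  list(geno = geno, grm = above$grm, layout = layout,
       spatial = above$spatial, above = above, roots = roots)
}

#' Write a simulated experiment as delimited text
#'
#' Emits the same formats the readers consume: genotype dosages, above-ground
#' records, root images, plus the generating truth and a config snapshot.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory (created if needed).
#' @param config the [sim_config()] used.
#' @return invisibly, the written file paths.
#' @export
write_simulation <- function(sim, dir, config) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genotypes = file.path(dir, "genotypes.tsv"),
    above = file.path(dir, "above_ground.tsv"),
    images = file.path(dir, "root_images.tsv"),
    truth_above = file.path(dir, "truth_above_vc.tsv"),
    truth_root = file.path(dir, "truth_root_vc.tsv"),
    config = file.path(dir, "config.txt"))
  utils::write.table(sim$geno$dosages, paths["genotypes"], sep = "\t",
                     quote = FALSE, col.names = NA)
  utils::write.table(sim$above$records, paths["above"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$roots$images, paths["images"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  vc_df <- function(vc) data.frame(component = names(vc), variance = unname(vc))
  utils::write.table(vc_df(sim$above$truth$vc), paths["truth_above"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(vc_df(sim$roots$truth$vc), paths["truth_root"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(utils::capture.output(utils::str(config)), paths["config"])
  invisible(paths)
}
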