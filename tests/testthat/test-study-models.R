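test_that("the above-ground model carries all nine random components", {
  am <- shared_am()
  spec <- am$spec
  nms <- vapply(spec$terms, `[[`, "", "name")
  expect_equal(nms, c("g", "l", "ng", "nl", "r", "tg", "tl", "s1", "s2"))

  # neighbour loadings: two adjacent lines per interior observation, one at
  # unit edges
  lay <- am$sim$layout
  Zn <- nnagp:::neighbour_loadings(am$sim$records, lay,
                                   rownames(am$sim$grm$G))
  loads <- rowSums(Zn)
  rows <- am$sim$records$row
  edge <- lay$row[match(rows, lay$row_id)] %in%
    c(1, attr(lay, "rows_per_unit"))
  expect_true(all(loads[!edge] == 2))
  # unit-edge rows flank a virtual row on one side, but padding means the
  # virtual side simply contributes nothing
  expect_true(all(loads[edge] == 1))

  # treatment partition: wet observations load nothing on s2 and vice versa
  s1_map <- spec$terms[[8]]$factor
  s2_map <- spec$terms[[9]]$factor
  wet <- am$sim$records$treatment == "wet"
  expect_true(all(is.na(s2_map[wet])))
  expect_true(all(is.na(s1_map[!wet])))
  expect_true(all(!is.na(s1_map[wet])))

  # genomic-by-treatment kernel is block-diagonal over treatments
  K <- spec$terms[[6]]$K
  G <- am$sim$grm$G
  wet_lv <- paste(rownames(G), "wet", sep = ":")
  dry_lv <- paste(rownames(G), "dry", sep = ":")
  expect_equal(unname(K[wet_lv, wet_lv]), unname(G))
  expect_equal(unname(K[dry_lv, dry_lv]), unname(G))
  expect_true(all(K[wet_lv, dry_lv] == 0))
})

test_that("the root model has three time-point spatial terms and no neighbours", {
  cfg <- sim_config(seed = 12, n_lines = 30, n_snps = 500,
                    beds = 1, units_per_bed = 1, rows_per_unit = 40)
  sim <- simulate_root_images(cfg)
  tr <- summarize_roots(sim$images)
  lay <- sim$layout
  tr$line <- lay$line[match(tr$row, lay$row_id)]
  tr$camera <- tr$bed
  spec <- build_rm(tr, "trl", sim$grm, sim$spatial)
  nms <- vapply(spec$terms, `[[`, "", "name")
  expect_equal(nms, c("g", "l", "r", "s1", "s2", "s3"))
  expect_false(any(c("ng", "nl") %in% nms))
  # spatial variance tied to the record's time point
  for (k in 1:3) {
    map <- spec$terms[[3 + k]]$factor
    expect_true(all(is.na(map[tr$time != k])))
    expect_true(all(!is.na(map[tr$time == k])))
  }
  # repeated records of a tube share one row level
  expect_equal(length(unique(spec$terms[[3]]$factor)),
               length(unique(tr$row)))
  expect_error(build_rm(transform(tr, time = time + 3), "trl", sim$grm,
                        sim$spatial), "time point")
})

test_that("single-time-point data leaves the other spatial variances at the floor", {
  cfg <- sim_config(seed = 13, n_lines = 25, n_snps = 400,
                    beds = 1, units_per_bed = 1, rows_per_unit = 50)
  sim <- simulate_root_images(cfg)
  tr <- summarize_roots(sim$images)
  tr <- tr[tr$time == 1, ]
  lay <- sim$layout
  tr$line <- lay$line[match(tr$row, lay$row_id)]
  spec <- build_rm(tr, "trl", sim$grm, sim$spatial)
  fit <- suppressWarnings(reml_fit(spec, max_iter = 100))
  expect_true(fit$floored["s2"])
  expect_true(fit$floored["s3"])
})

test_that("phenotypic variance sums the reported components per context", {
  vc_tab <- reference_table("vc_above")
  vc <- reference_vc(vc_tab, "GY", "AM1")
  # hand sum, wet treatment, unscaled
  hand <- vc["g"] + vc["l"] + 2 * vc["ng"] + 2 * vc["nl"] + vc["r"] +
    vc["tg"] + vc["tl"] + vc["s1"] + vc["e"]
  expect_equal(phenotypic_variance(vc, "s1"), unname(hand), tolerance = 1e-12)
  expect_equal(phenotypic_variance(vc, "s1"), 1.09, tolerance = 1e-4)

  # all components zero except a unit residual
  vc0 <- c(g = 0, l = 0, ng = 0, nl = 0, r = 0, tg = 0, tl = 0,
           s1 = 0, s2 = 0, e = 1)
  expect_equal(phenotypic_variance(vc0, "s1"), 1)

  # scaling by d(G) adds (d-1) * (g + 2 ng + tg)
  d_g <- 1.856
  diff <- phenotypic_variance(vc, "s2", d_g = d_g, scale_by_avg_diag = TRUE) -
    phenotypic_variance(vc, "s2")
  expect_equal(diff, unname((d_g - 1) * (vc["g"] + 2 * vc["ng"] + vc["tg"])),
               tolerance = 1e-12)
  expect_error(phenotypic_variance(vc[-1], "s1"), "missing")
})

test_that("heritabilities and GCV reproduce the reported genetic parameters", {
  vc_tab <- reference_table("vc_above")
  means <- reference_table("trait_summary")
  for (i in seq_len(nrow(vc_tab))) {
    vc <- reference_vc(vc_tab, vc_tab$trait[i], vc_tab$model[i])
    mu <- means$mean[means$trait == vc_tab$trait[i]]
    gp <- heritabilities(vc, trait_mean = mu)
    avg <- gp[gp$context == "average", ]
    # printed parameters are rounded to two decimals
    expect_lt(abs(avg$h2 - vc_tab$h2[i]), 0.02)
    expect_lt(abs(avg$H2 - vc_tab$H2[i]), 0.02)
    expect_lt(abs(attr(gp, "gcv") - vc_tab$gcv[i]), 0.1)
  }
  expect_equal(gcv(0, 10), 0)
  expect_error(gcv(-1, 10), "non-negative")
  expect_error(gcv(1, 0), "positive")
})

test_that("root-model heritabilities per time point match the reported table", {
  vc_tab <- reference_table("vc_root")
  means <- reference_table("trait_summary")
  for (i in seq_len(nrow(vc_tab))) {
    vc <- reference_vc(vc_tab, vc_tab$trait[i], vc_tab$model[i])
    gp <- heritabilities(vc, model = "RM")
    for (k in 1:3) {
      expect_lt(abs(gp$h2[gp$context == paste0("s", k)] -
                      vc_tab[[paste0("h2_t", k)]][i]), 0.011)
      expect_lt(abs(gp$H2[gp$context == paste0("s", k)] -
                      vc_tab[[paste0("H2_t", k)]][i]), 0.011)
    }
    mu <- means$mean[means$trait == vc_tab$trait[i]]
    expect_lt(abs(gcv(unname(vc["g"]), mu) - vc_tab$gcv[i]), 0.1)
  }
})

test_that("fitted phenotypic variance is an exact bookkeeping identity", {
  am <- shared_am()
  fit <- am$fit
  for (ct in c("s1", "s2")) {
    manual <- sum(fit$vc[c("g", "l", "r", "tg", "tl", ct, "e")]) +
      2 * sum(fit$vc[c("ng", "nl")])
    expect_equal(phenotypic_variance(fit, ct), unname(manual),
                 tolerance = 1e-12)
  }
})

test_that("record order does not change the assembled model's fit", {
  am <- shared_am()
  set.seed(3)
  shuf <- am$sim$records[sample(nrow(am$sim$records)), ]
  spec2 <- build_am(shuf, "y", am$sim$grm, am$sim$spatial)
  fit2 <- suppressWarnings(reml_fit(spec2, max_iter = 150))
  expect_equal(fit2$vc, am$fit$vc, tolerance = 1e-6)
  expect_equal(fit2$blups$g, am$fit$blups$g, tolerance = 1e-6)
})

test_that("model builders validate their inputs", {
  am <- shared_am()
  rec <- am$sim$records
  bad <- transform(rec, treatment = "damp")
  expect_error(build_am(bad, "y", am$sim$grm, am$sim$spatial), "wet")
  bad2 <- rec; bad2$line[1] <- "UNKNOWN"
  expect_error(build_am(bad2, "y", am$sim$grm, am$sim$spatial),
               "absent from the relationship matrix")
  bad3 <- rec; bad3$row[1] <- "nowhere"
  expect_error(build_am(bad3, "y", am$sim$grm, am$sim$spatial),
               "absent from the layout")
})
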