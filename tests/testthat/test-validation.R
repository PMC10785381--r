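test_that("corrected phenotypes subtract the fitted fixed effects", {
  # single fixed level: y_c is the GLS-mean-centred phenotype
  set.seed(21)
  d <- data.frame(grp = rep(letters[1:5], each = 4), lvl = "one")
  d$y <- rnorm(5)[as.integer(factor(d$grp))] + rnorm(20) + 3
  spec <- model_spec(d, "y", fixed = "lvl",
                     terms = list(random_term("u", factor = d$grp)))
  fit <- reml_fit(spec)
  y_c <- corrected_phenotypes(fit)
  expect_equal(y_c, d$y - fit$beta[[1]])
  expect_lt(abs(mean(y_c)), 0.5)

  # two-level design: y_c equals y minus the level's BLUE
  d2 <- data.frame(grp = rep(letters[1:6], each = 4),
                   lvl = rep(c("A", "B"), 12))
  set.seed(22)
  d2$y <- rnorm(6)[as.integer(factor(d2$grp))] + rnorm(24) +
    ifelse(d2$lvl == "A", 1, -1)
  spec2 <- model_spec(d2, "y", fixed = "lvl",
                      terms = list(random_term("u", factor = d2$grp)))
  fit2 <- reml_fit(spec2)
  expect_equal(corrected_phenotypes(fit2),
               d2$y - fit2$beta[paste0("lvl", d2$lvl)],
               ignore_attr = TRUE)
})

test_that("leave-one-line-out predictions flow only through the kernel", {
  # a line genomically unrelated to every other gets GEBV 0 when left out
  set.seed(23)
  K <- diag(6) * 0.02 + 0.9
  K[6, ] <- K[, 6] <- 0; K[6, 6] <- 0.92
  dimnames(K) <- list(paste0("L", 1:6), paste0("L", 1:6))
  d <- data.frame(line = rep(paste0("L", 1:6), each = 5))
  d$y <- rnorm(6)[as.integer(factor(d$line))] + rnorm(30)
  spec <- model_spec(d, "y",
                     terms = list(random_term("g", factor = d$line, K = K)))
  fit <- suppressWarnings(reml_fit(spec, max_iter = 100))
  fit$vc[] <- c(g = 0.8, e = 1)     # fix components for the analytic check
  cv <- loo_cv(fit)
  expect_equal(cv$gebv_partial[cv$line == "L6"], 0, tolerance = 1e-10)

  # a clone pair: the left-out clone inherits (almost) its twin's BLUP
  K2 <- diag(5) * 0.05 + 0.05
  K2[1, 2] <- K2[2, 1] <- 0.999
  diag(K2)[1:2] <- 1
  K2[3, 3] <- K2[4, 4] <- K2[5, 5] <- 1
  dimnames(K2) <- list(paste0("L", 1:5), paste0("L", 1:5))
  d2 <- data.frame(line = rep(paste0("L", 1:5), each = 6))
  set.seed(24)
  d2$y <- rnorm(5, sd = 1.5)[as.integer(factor(d2$line))] + rnorm(30)
  spec2 <- model_spec(d2, "y",
                      terms = list(random_term("g", factor = d2$line,
                                               K = K2)))
  fit2 <- suppressWarnings(reml_fit(spec2, max_iter = 100))
  fit2$vc[] <- c(g = 1, e = 1)
  cv2 <- loo_cv(fit2)
  # oracle: solve the fold's mixed-model equations directly for line 1
  keep <- d2$line != "L1"
  Z <- outer(d2$line[keep], paste0("L", 1:5), "==") * 1
  V <- Z %*% K2 %*% t(Z) + diag(sum(keep))
  X <- matrix(1, sum(keep), 1)
  Vi <- solve(V)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d2$y[keep])
  Py <- Vi %*% (d2$y[keep] - X %*% b)
  u <- K2 %*% t(Z) %*% Py
  expect_equal(cv2$gebv_partial[cv2$line == "L1"], unname(u["L1", 1]),
               tolerance = 1e-8)
  # near-perfect correlation: the left-out clone tracks its twin's training
  # BLUP from the same fold
  expect_equal(cv2$gebv_partial[cv2$line == "L1"], unname(u["L2", 1]),
               tolerance = 0.01)
})

test_that("left-out records cannot influence their own prediction", {
  am <- shared_am()
  cv <- am$cv
  line1 <- cv$line[1]
  fit2 <- am$fit
  pert <- fit2$spec$data
  pert$y[pert$line == line1] <- pert$y[pert$line == line1] + 100
  fit2$spec <- model_spec(pert, "y", fixed = ".fixed", terms = am$spec$terms)
  cv2 <- loo_cv(fit2)
  expect_equal(cv2$gebv_partial[cv2$line == line1],
               cv$gebv_partial[cv$line == line1], tolerance = 1e-6)
  expect_false(isTRUE(all.equal(cv2$gebv_partial[cv2$line != line1],
                                cv$gebv_partial[cv$line != line1])))
})

test_that("predictive ability is the corrected-phenotype/GEBV correlation", {
  y_c <- c(1.2, -0.5, 0.3, 2.0)
  gebv <- c(L1 = 0.9, L2 = -0.6, L3 = 0.1, L4 = 1.4)
  lines <- paste0("L", 1:4)
  expect_equal(predictive_ability(y_c, gebv, lines),
               cor(y_c, unname(gebv)))
  expect_equal(predictive_ability(y_c, y_c), 1)
  expect_equal(predictive_ability(y_c, -y_c), -1)
  # observation vs line level differ once lines are replicated
  y2 <- c(y_c, y_c + 0.3)
  lines2 <- c(lines, lines)
  expect_equal(predictive_ability(y2, gebv, lines2, level = "line"),
               cor(tapply(y2, lines2, mean), unname(gebv[sort(lines)])))
  expect_error(predictive_ability(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(predictive_ability(1:2, 1:2), "at least 3")
})

test_that("maximum potential PA follows the replication formula", {
  expect_equal(max_potential_pa(0, 10), 0)
  expect_equal(max_potential_pa(1, 7), 1)
  h2 <- 0.22; n <- 15.9
  expect_equal(max_potential_pa(h2, n), sqrt(n * h2 / (1 + (n - 1) * h2)))
  expect_equal(max_potential_pa(h2, n), 0.904, tolerance = 1e-3)
  expect_error(max_potential_pa(1.2, 10), "h2")
  expect_error(max_potential_pa(0.5, 0.5), "n_reps")
})

test_that("the dispersion slope is the covariance ratio", {
  g <- rnorm(50)
  expect_equal(inflation_bwp(g, g), 1)
  expect_equal(inflation_bwp(g, g / 2), 2)
  set.seed(25)
  gw <- rnorm(80); gp <- 0.8 * gw + rnorm(80, sd = 0.3)
  expect_equal(inflation_bwp(gw, gp),
               unname(coef(lm(gw ~ gp))[2]), tolerance = 1e-10)
  expect_error(inflation_bwp(g, rep(1, 50)), "zero variance")
})

test_that("bootstrap standard errors behave like the sampling distribution", {
  expect_equal(bootstrap_se(rnorm(20), function(x) 42, B = 100, seed = 1)$se,
               0)
  set.seed(26)
  x <- rnorm(400, sd = 2)
  bs <- bootstrap_se(x, mean, B = 3000, seed = 7)
  expect_lt(abs(bs$se - sd(x) / sqrt(length(x))) / (sd(x) / sqrt(length(x))),
            0.1)
  expect_equal(bs$ci_halfwidth, 1.96 * bs$se)
  # deterministic given the seed, different across seeds
  bs2 <- bootstrap_se(x, mean, B = 3000, seed = 7)
  expect_identical(bs$se, bs2$se)
  bs3 <- bootstrap_se(x, mean, B = 3000, seed = 8)
  expect_false(identical(bs$se, bs3$se))
  expect_lt(abs(bs3$se - bs$se) / bs$se, 0.1)
  expect_error(bootstrap_se(x, mean, B = 1), "at least 2")
})

test_that("the Hotelling-Williams test compares dependent correlations", {
  expect_equal(hotelling_williams(0.4, 0.4, 0.3, 50)$t, 0)
  expect_equal(hotelling_williams(0.4, 0.4, 0.3, 50)$p_value, 1)

  # frozen value computed independently from the published formula
  hw <- hotelling_williams(0.5, 0.3, 0.4, 103)
  expect_equal(hw$t, 2.0968, tolerance = 1e-4)
  expect_equal(hw$df, 100)
  expect_equal(hw$p_value, 2 * pt(-abs(hw$t), 100))

  # p falls monotonically as the correlations separate
  ps <- sapply(seq(0, 0.3, by = 0.05),
               function(d) hotelling_williams(0.4 + d, 0.4 - d, 0.5, 80)$p_value)
  expect_true(all(diff(ps) < 1e-12))
  expect_error(hotelling_williams(0.5, 0.3, 0.4, 3), "exceed 3")
  expect_error(hotelling_williams(1, 0.3, 0.4, 30), "strictly within")
})

test_that("the assembled CV report is internally consistent", {
  am <- shared_am()
  hp <- heritabilities(am$fit, d_g = am$sim$grm$d_g, scale_by_avg_diag = TRUE)
  h2 <- hp$h2[hp$context == "average"]
  n_reps <- mean(table(am$sim$records$line))
  rep <- cv_report(am$fit, am$cv, h2 = h2, n_reps = n_reps, B = 500, seed = 3)
  expect_equal(rep$acc, rep$pa / rep$max_pa)
  expect_true(rep$pa > -1 && rep$pa < 1)
  expect_true(rep$max_pa >= 0 && rep$max_pa <= 1)
  expect_gt(rep$pa_se, 0)
  expect_equal(rep$n_lines, nrow(am$cv))
})
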