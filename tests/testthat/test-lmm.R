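library(lme4)

one_way <- function(ngrp, reps, seed, sd_u = 1.2, sd_e = 1) {
  set.seed(seed)
  d <- data.frame(grp = rep(sprintf("g%02d", seq_len(ngrp)), each = reps))
  d$y <- rnorm(ngrp, sd = sd_u)[as.integer(factor(d$grp))] +
    rnorm(nrow(d), sd = sd_e)
  d
}

test_that("balanced one-way estimates match the closed-form REML solution", {
  for (case in list(c(10, 5, 1), c(6, 4, 2), c(15, 3, 3))) {
    d <- one_way(case[1], case[2], case[3])
    spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
    fit <- reml_fit(spec)
    # oracle: mean-square equations for balanced data
    ybar <- tapply(d$y, d$grp, mean)
    mse <- sum((d$y - ybar[d$grp])^2) / (case[1] * (case[2] - 1))
    msb <- case[2] * var(ybar)
    expect_equal(unname(fit$vc["u"]), max((msb - mse) / case[2], 0),
                 tolerance = 1e-6)
    expect_equal(unname(fit$vc["e"]), mse, tolerance = 1e-6)
  }
})

test_that("identity-kernel fits agree with lme4 on unbalanced data", {
  d <- one_way(12, 6, 4)
  d <- d[-c(2, 3, 10, 30, 31, 32, 40), ]        # unbalance the groups
  spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
  fit <- reml_fit(spec)
  ref <- lmer(y ~ 1 + (1 | grp), d, REML = TRUE)
  vc <- as.data.frame(VarCorr(ref))$vcov
  expect_equal(unname(fit$vc[c("u", "e")]), vc, tolerance = 1e-5)
  expect_equal(fit$loglik, -0.5 * REMLcrit(ref), tolerance = 1e-6)
  expect_equal(unname(fit$beta), unname(fixef(ref)), tolerance = 1e-5)
  blup_ref <- ranef(ref)$grp[["(Intercept)"]]
  expect_equal(unname(fit$blups$u[rownames(ranef(ref)$grp)]), blup_ref,
               tolerance = 1e-4)
})

test_that("the iteration trace never decreases the restricted likelihood", {
  d <- one_way(8, 4, 5)
  spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
  fit <- reml_fit(spec)
  expect_true(all(diff(fit$trace$loglik) > -1e-8))

  am <- shared_am()
  expect_true(all(diff(am$fit$trace$loglik) > -1e-8))
  expect_true(am$fit$converged)
})

test_that("a constant response drives every component to the floor", {
  d <- data.frame(grp = rep(letters[1:4], each = 3), y = 5)
  spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
  fit <- suppressWarnings(reml_fit(spec, max_iter = 50))
  expect_lt(fit$vc["u"], 1e-6)
  expect_lt(fit$vc["e"], 1e-6)
})

test_that("simulated variance components are recovered within 3 SE", {
  set.seed(11)
  n <- 500; q <- 100
  grp <- sample(sprintf("g%03d", 1:q), n, replace = TRUE)
  u <- rnorm(q); names(u) <- sprintf("g%03d", 1:q)
  d <- data.frame(grp = grp, y = u[grp] + rnorm(n))
  spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
  fit <- reml_fit(spec)
  expect_lt(abs(fit$vc["u"] - 1), 3 * fit$se["u"])
  expect_lt(abs(fit$vc["e"] - 1), 3 * fit$se["e"])
})

test_that("supplied-kernel recovery works for genomic and spatial kernels", {
  cfg <- sim_config(seed = 31, n_lines = 60, n_snps = 1200,
                    beds = 1, units_per_bed = 2, rows_per_unit = 100,
                    spatial_kind = "euc",
                    vc_above = c(g = 1, l = 0, ng = 0, nl = 0, r = 0,
                                 tg = 0, tl = 0, s1 = 0.8, s2 = 0.8, e = 1))
  sim <- simulate_above_ground(cfg)
  d <- sim$records
  spec <- model_spec(d, "y", fixed = NULL, terms = list(
    random_term("g", factor = d$line, K = sim$grm$G),
    random_term("s1", factor = ifelse(d$treatment == "wet", d$row, NA),
                K = sim$spatial$S),
    random_term("s2", factor = ifelse(d$treatment == "dry", d$row, NA),
                K = sim$spatial$S)))
  fit <- reml_fit(spec)
  expect_true(fit$converged)
  for (cmp in c("g", "s1", "s2", "e")) {
    truth <- c(g = 1, s1 = 0.8, s2 = 0.8, e = 1)[cmp]
    expect_lt(abs(fit$vc[cmp] - truth), 3 * fit$se[cmp])
  }
})

test_that("BLUPs at fixed variances equal the closed-form shrinkage solution", {
  # two diagonal groups with a GLS intercept: the oracle is hand-derivable
  d <- data.frame(grp = c("a", "a", "a", "b", "b"),
                  y = c(3, 4, 5, -1, 1))
  vcs <- c(u = 2, e = 1)
  sol <- blup_solve(model_spec(d, "y",
                               terms = list(random_term("u", factor = d$grp))),
                    vcs)
  nb <- c(a = 3, b = 2); yb <- c(a = 4, b = 0)
  w <- nb / (vcs["e"] + nb * vcs["u"])
  mu <- sum(w * yb) / sum(w)
  u_oracle <- vcs["u"] * nb * (yb - mu) / (vcs["e"] + nb * vcs["u"])
  expect_equal(unname(sol$beta), unname(mu), tolerance = 1e-10)
  expect_equal(sol$blups$u, unname(u_oracle), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("kernel levels without observations are predicted through the kernel", {
  # identity kernel: unobserved level stays at 0
  K <- diag(3); dimnames(K) <- list(c("a", "b", "c"), c("a", "b", "c"))
  d <- data.frame(grp = c("a", "a", "b", "b"), y = c(2, 3, -1, 0))
  sol <- blup_solve(model_spec(d, "y",
                               terms = list(random_term("u", factor = d$grp,
                                                        K = K))),
                    c(u = 1, e = 1))
  expect_equal(unname(sol$blups$u["c"]), 0)

  # a perfect correlate of an observed level inherits its BLUP
  K2 <- matrix(c(1, 0, 1, 0, 1, 0, 1, 0, 1), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  sol2 <- blup_solve(model_spec(d, "y",
                                terms = list(random_term("u", factor = d$grp,
                                                         K = K2))),
                     c(u = 1, e = 1))
  expect_equal(unname(sol2$blups$u["c"]), unname(sol2$blups$u["a"]))
})

test_that("the restricted likelihood is maximised and matches brute force", {
  d <- one_way(6, 3, 8)
  spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
  fit <- reml_fit(spec)
  ll0 <- profile_loglik(spec, fit$vc)
  expect_equal(ll0, fit$loglik, tolerance = 1e-8)
  for (fac in c(0.8, 1.2)) {
    expect_lt(profile_loglik(spec, fit$vc * fac), ll0 + 1e-10)
    expect_lt(profile_loglik(spec, fit$vc * c(fac, 1)), ll0 + 1e-10)
  }

  # 3-observation toy against a direct determinant/quadratic-form evaluation
  d3 <- data.frame(grp = c("a", "a", "b"), y = c(1, 2, 4))
  spec3 <- model_spec(d3, "y",
                      terms = list(random_term("u", factor = d3$grp)))
  vcs <- c(u = 0.7, e = 1.3)
  Z <- cbind(a = c(1, 1, 0), b = c(0, 0, 1))
  V <- vcs["u"] * tcrossprod(Z) + vcs["e"] * diag(3)
  X <- matrix(1, 3, 1)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  ll_brute <- -0.5 * (determinant(V)$modulus +
                        determinant(t(X) %*% Vi %*% X)$modulus +
                        t(d3$y) %*% P %*% d3$y + (3 - 1) * log(2 * pi))
  expect_equal(profile_loglik(spec3, vcs), as.numeric(ll_brute),
               tolerance = 1e-10)
})

test_that("estimates are equivariant to scaling and observation order", {
  d <- one_way(10, 4, 9)
  spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
  fit <- reml_fit(spec)

  d2 <- transform(d, y = 10 * y)
  fit2 <- reml_fit(model_spec(d2, "y",
                              terms = list(random_term("u", factor = d2$grp))))
  expect_equal(unname(fit2$vc), unname(100 * fit$vc), tolerance = 1e-5)
  expect_equal(fit2$blups$u, 10 * fit$blups$u, tolerance = 1e-5)

  set.seed(1); perm <- sample(nrow(d))
  d3 <- d[perm, ]
  fit3 <- reml_fit(model_spec(d3, "y",
                              terms = list(random_term("u", factor = d3$grp))))
  expect_equal(fit3$vc, fit$vc, tolerance = 1e-8)
  expect_equal(fit3$blups$u, fit$blups$u, tolerance = 1e-8)
})

test_that("invalid specifications fail loudly", {
  d <- data.frame(grp = c("a", "b"), y = 1:2)
  K_bad <- matrix(c(1, 2, 0, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(random_term("u", factor = d$grp, K = K_bad), "symmetric")
  expect_error(random_term("u"), "exactly one")
  spec <- model_spec(d, "y", terms = list(random_term("u", factor = d$grp)))
  expect_error(blup_solve(spec, c(u = 1)), "every component")
  expect_error(blup_solve(spec, c(u = 1, e = 0)), "positive")
  dbig <- one_way(10, 5, 1)
  spec_big <- model_spec(dbig, "y",
                         terms = list(random_term("u", factor = dbig$grp)))
  expect_warning(fit1 <- reml_fit(spec_big, max_iter = 1), "did not converge")
  expect_false(fit1$converged)
})
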