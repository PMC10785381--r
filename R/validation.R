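#' Phenotypes corrected for fixed effects
#'
#' `y_c = y - X b`, using the fixed-effect estimates of a full-data fit: the
#' phenotype with the unit/bed/treatment (or bed/camera/time) means removed,
#' one value per observation.
#'
#' @param fit a [reml_fit()] result (carries its model specification).
#' @return numeric vector of corrected phenotypes.
#' @export
corrected_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "reml_fit"))
  des <- build_design(fit$spec)
  as.numeric(des$y - des$X %*% fit$beta[colnames(des$X)])
}

#' Leave-one-line-out cross-validated breeding values
#'
#' For each line in turn, removes all of the line's observations, re-solves
#' the mixed-model equations on the remaining data at the full-data variance
#' components (components are estimated once, never per fold), and predicts
#' the left-out line's additive genomic effect through the relationship
#' kernel. Whole-data genetic values come from the full fit, so the pair
#' (whole, partial) supports dispersion diagnostics.
#'
#' @param fit a converged [reml_fit()] of a model containing the genomic
#'   term.
#' @param term name of the genomic random term to cross-validate (default
#'   `"g"`).
#' @return An object of class `cv_report`: data frame with one row per
#'   observed line — `line`, `gebv_partial` (LOO prediction), `gebv_whole`
#'   (full-data BLUP) and `n_obs`.
#' @export
loo_cv <- function(fit, term = "g") {
  stopifnot(inherits(fit, "reml_fit"))
  spec <- fit$spec
  des <- build_design(spec)
  vnames <- fit$term_names
  sig <- as.numeric(fit$vc[vnames])
  m <- length(des$terms)
  tix <- match(term, vapply(des$terms, `[[`, "", "name"))
  if (is.na(tix)) stop("no random term named '", term, "'", call. = FALSE)
  tm <- des$terms[[tix]]
  if (is.null(tm$idx))
    stop("cross-validation requires a factor-coded genomic term", call. = FALSE)

  n <- des$n
  V <- diag(sig[m + 1], n)
  for (i in seq_len(m)) V <- V + sig[i] * des$terms[[i]]$Vi

  observed <- sort(unique(tm$idx[!is.na(tm$idx)]))
  out <- data.frame(line = tm$levels[observed],
                    gebv_partial = NA_real_,
                    gebv_whole = fit$blups[[term]][tm$levels[observed]],
                    n_obs = as.integer(table(factor(tm$idx, levels = observed))))
  K <- tm$K
  for (j in seq_along(observed)) {
    lev <- observed[j]
    keep <- which(is.na(tm$idx) | tm$idx != lev)
    if (!length(keep)) stop("a fold has no training data", call. = FALSE)
    ch <- chol(V[keep, keep])
    Xk <- des$X[keep, , drop = FALSE]
    yk <- des$y[keep]
    A <- forwardsolve(t(ch), cbind(yk, Xk))
    Ay <- A[, 1]; AX <- A[, -1, drop = FALSE]
    C <- crossprod(AX)
    beta <- tryCatch(solve(C, crossprod(AX, Ay)), error = function(e)
      stop("fixed-effect design became singular in a fold", call. = FALSE))
    r <- yk - Xk %*% beta
    Py <- backsolve(ch, forwardsolve(t(ch), r))
    agg <- rep(0, tm$q)
    obs <- which(!is.na(tm$idx[keep]))
    s <- tapply(Py[obs], tm$idx[keep][obs], sum)
    agg[as.integer(names(s))] <- s
    u <- sig[tix] * as.numeric(K %*% agg)
    out$gebv_partial[j] <- u[lev]
  }
  rownames(out) <- NULL
  class(out) <- c("cv_report", "data.frame")
  out
}

#' Predictive ability
#'
#' The correlation between fixed-effect-corrected phenotypes and genomic
#' estimated breeding values. By default computed at observation level (each
#' record paired with its line's GEBV); `level = "line"` correlates line
#' means of the corrected phenotypes with the GEBVs instead.
#'
#' @param y_c corrected phenotypes, one per observation.
#' @param gebv named vector of per-line GEBVs (or per-observation values when
#'   `line` is `NULL`).
#' @param line line id per observation; `NULL` when `y_c` and `gebv` are
#'   already aligned.
#' @param level `"observation"` (default) or `"line"`.
#' @return the predictive ability (Pearson correlation).
#' @export
predictive_ability <- function(y_c, gebv, line = NULL,
                               level = c("observation", "line")) {
  level <- match.arg(level)
  if (is.null(line)) {
    x <- y_c; g <- gebv
  } else if (level == "observation") {
    x <- y_c; g <- unname(gebv[line])
  } else {
    x <- tapply(y_c, line, mean)
    g <- unname(gebv[names(x)])
  }
  if (length(x) < 3) stop("need at least 3 values", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(g) == 0)
    stop("predictive ability undefined: zero variance", call. = FALSE)
  stats::cor(x, g)
}

#' Maximum potential predictive ability
#'
#' `sqrt(n h2 / (1 + (n - 1) h2))`: the upper bound on the correlation
#' between corrected phenotypes and true breeding values given the trait
#' heritability `h2` and the average number of replicates per line `n`.
#' Prediction accuracy is `ACC = PA / max_potential_pa(h2, n)`.
#'
#' @param h2 narrow-sense heritability in `[0, 1]`.
#' @param n_reps average number of records per line (>= 1).
#' @return the maximum potential predictive ability in `[0, 1]`.
#' @export
max_potential_pa <- function(h2, n_reps) {
  if (any(h2 < 0 | h2 > 1)) stop("h2 must be in [0, 1]", call. = FALSE)
  if (any(n_reps < 1)) stop("n_reps must be >= 1", call. = FALSE)
  sqrt(n_reps * h2 / (1 + (n_reps - 1) * h2))
}

#' Dispersion of cross-validated predictions
#'
#' The regression slope of whole-data genetic values on partial-data
#' (leave-one-out) predictions, `b = cov(g_w, g_p) / var(g_p)`. A value of 1
#' indicates no variance inflation; below 1 over-dispersion (inflated
#' predictions), above 1 under-dispersion.
#'
#' @param ghat_whole genetic values predicted with all phenotypes.
#' @param ghat_partial paired predictions with the line's phenotypes removed.
#' @return the regression coefficient.
#' @export
inflation_bwp <- function(ghat_whole, ghat_partial) {
  stopifnot(length(ghat_whole) == length(ghat_partial))
  v <- stats::var(ghat_partial)
  if (v == 0) stop("partial predictions have zero variance", call. = FALSE)
  stats::cov(ghat_whole, ghat_partial) / v
}

#' Non-parametric bootstrap standard error
#'
#' Ordinary bootstrap with replacement at full sample size: resamples the
#' rows (records) of `data` `B` times, evaluates `statistic` on each
#' resample, and reports the standard deviation of the replicates as the
#' standard error, plus the half-width of the normal 95% interval
#' (`1.96 * SE`). Deterministic for a given `seed`.
#'
#' @param data data frame or vector of records.
#' @param statistic function of one resampled `data` returning a scalar.
#' @param B number of bootstrap replicates (default 10000).
#' @param seed optional integer seed.
#' @return list with `estimate` (statistic on the original data), `se`,
#'   `ci_halfwidth` and `B`.
#' @export
bootstrap_se <- function(data, statistic, B = 10000, seed = NULL) {
  if (B < 2) stop("B must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- if (is.data.frame(data)) nrow(data) else length(data)
  take <- if (is.data.frame(data)) function(i) data[i, , drop = FALSE]
          else function(i) data[i]
  reps <- vapply(seq_len(B), function(b) {
    statistic(take(sample.int(n, n, replace = TRUE)))
  }, numeric(1))
  se <- stats::sd(reps)
  list(estimate = statistic(data), se = se, ci_halfwidth = 1.96 * se, B = B)
}

#' Hotelling-Williams test for two dependent correlations
#'
#' Williams' t test comparing two correlations `r12` and `r13` that share
#' variable 1 (e.g. the predictive abilities of two models against the same
#' corrected phenotypes), with `r23` the correlation between the competing
#' predictors and `n` the number of shared observations:
#' \deqn{t = (r_{12} - r_{13}) \sqrt{\frac{(n-1)(1+r_{23})}
#'   {2 \frac{n-1}{n-3} |R| + \bar r^2 (1-r_{23})^3}}}
#' with \eqn{|R| = 1 - r_{12}^2 - r_{13}^2 - r_{23}^2 + 2 r_{12} r_{13}
#' r_{23}}, \eqn{\bar r = (r_{12} + r_{13})/2} and `n - 3` degrees of
#' freedom; the p-value is two-sided.
#'
#' @param r12,r13 the two correlations being compared.
#' @param r23 correlation between the two competing variables.
#' @param n number of shared observations (> 3).
#' @return list with `t`, `df` and `p_value`.
#' @export
hotelling_williams <- function(r12, r13, r23, n) {
  if (n <= 3) stop("n must exceed 3", call. = FALSE)
  if (any(abs(c(r12, r13, r23)) >= 1))
    stop("correlations must lie strictly within (-1, 1)", call. = FALSE)
  detR <- 1 - r12^2 - r13^2 - r23^2 + 2 * r12 * r13 * r23
  rbar <- (r12 + r13) / 2
  t_stat <- (r12 - r13) *
    sqrt(((n - 1) * (1 + r23)) /
           (2 * ((n - 1) / (n - 3)) * detR + rbar^2 * (1 - r23)^3))
  df <- n - 3
  list(t = t_stat, df = df, p_value = 2 * stats::pt(-abs(t_stat), df))
}

#' Summarise a leave-one-line-out validation
#'
#' Convenience wrapper assembling the full prediction-quality report for a
#' fitted model: observation-level predictive ability of the LOO GEBVs
#' against corrected phenotypes, maximum potential predictive ability from
#' the supplied heritability and replication, prediction accuracy, the
#' dispersion slope `b_w,p`, and bootstrap standard errors for PA and
#' `b_w,p`.
#'
#' @param fit a converged [reml_fit()].
#' @param cv a [loo_cv()] report for the same fit.
#' @param h2 narrow-sense heritability used for the maximum potential PA.
#' @param n_reps average records per line.
#' @param line_col name of the line column in the model data.
#' @param B bootstrap replicates (default 10000).
#' @param seed bootstrap seed.
#' @return list with `pa`, `pa_se`, `max_pa`, `acc`, `b_wp`, `b_wp_se`,
#'   `n_lines`, `n_obs`.
#' @export
cv_report <- function(fit, cv, h2, n_reps, line_col = "line", B = 10000,
                      seed = NULL) {
  y_c <- corrected_phenotypes(fit)
  lines_obs <- as.character(fit$spec$data[[line_col]])
  gebv <- stats::setNames(cv$gebv_partial, cv$line)
  keep <- lines_obs %in% cv$line
  pa_data <- data.frame(y_c = y_c[keep], g = unname(gebv[lines_obs[keep]]))
  pa <- predictive_ability(pa_data$y_c, pa_data$g)
  pa_boot <- bootstrap_se(pa_data, function(d) stats::cor(d$y_c, d$g),
                          B = B, seed = seed)
  mp <- max_potential_pa(h2, n_reps)
  pair <- data.frame(w = cv$gebv_whole, p = cv$gebv_partial)
  bwp <- inflation_bwp(pair$w, pair$p)
  bwp_boot <- bootstrap_se(pair, function(d) inflation_bwp(d$w, d$p),
                           B = B, seed = if (is.null(seed)) NULL else seed + 1L)
  list(pa = pa, pa_se = pa_boot$se, max_pa = mp,
       acc = if (mp > 0) pa / mp else NA_real_,
       b_wp = bwp, b_wp_se = bwp_boot$se,
       n_lines = nrow(cv), n_obs = nrow(pa_data))
}
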