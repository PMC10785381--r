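#' Define a random term of a linear mixed model
#'
#' A random term contributes `Z u` to the model, with `u ~ N(0, K sigma^2)`.
#' The loading matrix can be given implicitly through a grouping factor (one
#' unit loading per observation; observations with `NA` load nothing) or
#' explicitly as a numeric matrix `Z` (e.g. two unit loadings on the flanking
#' neighbour lines). The covariance kernel `K` is a symmetric PSD matrix over
#' the effect levels (a genomic relationship matrix, a spatial correlation
#' structure, a block-diagonal kernel, ...) or `NULL` for the identity.
#'
#' @param name term label; also the variance-parameter id.
#' @param factor grouping values per observation (vector), or the name of a
#'   column of the model data.
#' @param Z explicit numeric loading matrix, observations x levels, with
#'   column names naming the levels. Exactly one of `factor`/`Z` must be set.
#' @param K covariance kernel with row/column names matching the levels, or
#'   `NULL` for identity covariance. Levels present in `K` but never observed
#'   are legal: their effects are predicted through the kernel.
#' @return an object of class `random_term`.
#' @export
random_term <- function(name, factor = NULL, Z = NULL, K = NULL) {
  if (is.null(factor) == is.null(Z))
    stop("give exactly one of `factor` or `Z`", call. = FALSE)
  if (!is.null(K)) {
    K <- as.matrix(K)
    if (is.null(rownames(K))) stop("K must have row/column names", call. = FALSE)
    if (max(abs(K - t(K))) > 1e-8 * max(1, max(abs(K))))
      stop("K must be symmetric", call. = FALSE)
    K <- (K + t(K)) / 2
  }
  if (!is.null(Z)) {
    Z <- as.matrix(Z)
    if (is.null(colnames(Z))) stop("Z must have column names", call. = FALSE)
  }
  structure(list(name = name, factor = factor, Z = Z, K = K),
            class = "random_term")
}

#' Specify a linear mixed model
#'
#' `y = X b + sum_i Z_i u_i + e`, with a single combined categorical fixed
#' factor (cell-means coding; rank deficiencies resolved by dropping dependent
#' columns in first-occurrence order), an ordered list of [random_term()]s and
#' an i.i.d. residual.
#'
#' @param data data frame of observations.
#' @param response name of the numeric response column.
#' @param fixed name of the fixed-factor column, or `NULL` for an intercept
#'   only.
#' @param terms list of [random_term()] objects.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(data, response, fixed = NULL, terms = list()) {
  stopifnot(is.data.frame(data), response %in% names(data))
  if (!is.null(fixed) && !fixed %in% names(data))
    stop("fixed factor column not found: ", fixed, call. = FALSE)
  if (!all(vapply(terms, inherits, TRUE, "random_term")))
    stop("`terms` must be a list of random_term objects", call. = FALSE)
  nm <- vapply(terms, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicated term names", call. = FALSE)
  structure(list(data = data, response = response, fixed = fixed,
                 terms = terms),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> response %s, %d observations\n", x$response,
              nrow(x$data)))
  cat(sprintf("  fixed: %s\n", if (is.null(x$fixed)) "(intercept)" else x$fixed))
  for (tm in x$terms)
    cat(sprintf("  random: %-6s kernel: %s\n", tm$name,
                if (is.null(tm$K)) "identity" else
                  sprintf("%dx%d supplied", nrow(tm$K), nrow(tm$K))))
  cat("  random: e      kernel: identity (residual)\n")
  invisible(x)
}

## ---- internal design assembly -------------------------------------------

## Full-rank fixed-effect design matrix (cell means for a factor), dropping
## linearly dependent columns in first-occurrence order.
fixed_design <- function(spec) {
  data <- spec$data
  if (is.null(spec$fixed)) {
    X <- matrix(1, nrow(data), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    f <- factor(data[[spec$fixed]])
    ## cell-means indicators built directly (works for any level count)
    X <- outer(as.integer(f), seq_along(levels(f)), `==`) * 1
    colnames(X) <- paste0(spec$fixed, levels(f))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

## Resolve one random term against the data: effect levels, observation
## mapping and the n x n unit-variance covariance contribution V_i = Z K Z'.
resolve_term <- function(term, data) {
  n <- nrow(data)
  if (!is.null(term$Z)) {
    Z <- term$Z
    if (nrow(Z) != n) stop("Z of term '", term$name, "' has wrong row count",
                           call. = FALSE)
    levels <- colnames(Z)
    if (!is.null(term$K)) {
      if (!all(levels %in% rownames(term$K)))
        stop("levels of term '", term$name, "' missing from its kernel",
             call. = FALSE)
      K <- term$K[levels, levels, drop = FALSE]
      Vi <- Z %*% K %*% t(Z)
    } else {
      K <- NULL
      Vi <- tcrossprod(Z)
    }
    list(name = term$name, levels = levels, q = length(levels), Z = Z,
         idx = NULL, K = K, Vi = Vi,
         all_levels = if (is.null(term$K)) levels else rownames(term$K))
  } else {
    vals <- term$factor
    if (length(vals) == 1 && is.character(vals) && vals %in% names(data))
      vals <- data[[vals]]
    vals <- as.character(vals)
    if (length(vals) != n)
      stop("grouping of term '", term$name, "' has wrong length", call. = FALSE)
    if (!is.null(term$K)) {
      levels <- rownames(term$K)
      bad <- setdiff(unique(vals[!is.na(vals)]), levels)
      if (length(bad))
        stop("term '", term$name, "': levels not in kernel: ",
             paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
      K <- term$K
    } else {
      levels <- sort(unique(vals[!is.na(vals)]))
      K <- NULL
    }
    idx <- match(vals, levels)
    Vi <- matrix(0, n, n)
    obs <- which(!is.na(idx))
    if (length(obs)) {
      if (is.null(K)) {
        Vi[obs, obs] <- (outer(idx[obs], idx[obs], "==")) * 1
      } else {
        Vi[obs, obs] <- K[idx[obs], idx[obs]]
      }
    }
    list(name = term$name, levels = levels, q = length(levels), Z = NULL,
         idx = idx, K = K, Vi = Vi, all_levels = levels)
  }
}

build_design <- function(spec) {
  y <- spec$data[[spec$response]]
  if (anyNA(y)) stop("response contains missing values; edit records first",
                     call. = FALSE)
  X <- fixed_design(spec)
  terms <- lapply(spec$terms, resolve_term, data = spec$data)
  list(y = as.numeric(y), X = X, terms = terms, n = length(y))
}

## P matrix pieces at variance parameters `sig` (component order: terms then
## residual). Returns Vinv, P, Py, REML log-likelihood.
reml_core <- function(des, sig) {
  n <- des$n
  m <- length(des$terms)
  V <- diag(sig[m + 1], n)
  for (i in seq_len(m)) V <- V + sig[i] * des$terms[[i]]$Vi
  ch <- tryCatch(chol(V), error = function(e)
    stop("covariance matrix not positive definite at current variance values",
         call. = FALSE))
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% des$X
  C <- crossprod(des$X, VinvX)
  cC <- chol(C)
  beta <- backsolve(cC, forwardsolve(t(cC), crossprod(VinvX, des$y)))
  Py <- Vinv %*% des$y - VinvX %*% beta
  P <- Vinv - VinvX %*% backsolve(cC, forwardsolve(t(cC), t(VinvX)))
  p <- ncol(des$X)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(cC))) +
                  sum(des$y * Py) + (n - p) * log(2 * pi))
  list(Vinv = Vinv, P = P, Py = as.numeric(Py), beta = as.numeric(beta),
       loglik = as.numeric(ll))
}

## Scores, AI matrix and EM ingredients at the current point.
reml_derivs <- function(des, core) {
  m <- length(des$terms)
  P <- core$P; Py <- core$Py
  n <- des$n
  tr <- qf <- numeric(m + 1)
  W <- matrix(0, n, m + 1)
  for (i in seq_len(m)) {
    Vi <- des$terms[[i]]$Vi
    tr[i] <- sum(P * Vi)
    w <- Vi %*% Py
    W[, i] <- w
    qf[i] <- sum(Py * w)
  }
  tr[m + 1] <- sum(diag(P))
  W[, m + 1] <- Py
  qf[m + 1] <- sum(Py * Py)
  score <- -0.5 * (tr - qf)
  AI <- 0.5 * crossprod(W, P %*% W)
  qlev <- c(vapply(des$terms, `[[`, 0L, "q"), n)
  list(score = score, AI = AI, tr = tr, qf = qf, q = qlev)
}

#' Fit a linear mixed model by AI-REML
#'
#' Maximises the restricted likelihood of a [model_spec()] by average
#' information updates, replaced by an EM-REML step whenever the AI proposal
#' leaves the parameter space. Variances are floored at
#' `floor_frac * var(y)`; a component wanting to fall below the floor is
#' held there (and reported at the floor) rather than dropped. Convergence is
#' declared when the largest relative variance change is below `tol_vc` or
#' the log-likelihood change is below `tol_ll`.
#'
#' @param spec a [model_spec()].
#' @param start optional named numeric vector of starting variances (term
#'   names plus `"e"`); the default splits `var(y)` equally over components.
#' @param max_iter maximum iterations (default 200).
#' @param tol_vc relative variance-change convergence tolerance (default 1e-8).
#' @param tol_ll log-likelihood-change tolerance (default 1e-9).
#' @param floor_frac variance floor as a fraction of `var(y)` (default 1e-8).
#' @param use_ai set `FALSE` to disable average-information updates and
#'   iterate pure EM-REML (slower, monotone; mainly for diagnostics).
#' @param verbose print the iteration trace.
#' @return An object of class `reml_fit`: variance components `vc`,
#'   asymptotic standard errors `se` (from the inverse AI matrix, including
#'   components held at the floor), fixed effects `beta`, BLUPs per term `blups`
#'   (levels never observed are predicted through the kernel), REML
#'   log-likelihood, `converged` flag, the iteration `trace`, and bookkeeping
#'   (`floored`, `ai`, `n`, term names).
#' @export
reml_fit <- function(spec, start = NULL, max_iter = 200, tol_vc = 1e-8,
                     tol_ll = 1e-9, floor_frac = 1e-8, use_ai = TRUE,
                     verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"))
  des <- build_design(spec)
  m <- length(des$terms)
  vnames <- c(vapply(des$terms, `[[`, "", "name"), "e")
  vy <- stats::var(des$y)
  if (vy == 0) vy <- 1e-8                      # constant response: degenerate
  floor_v <- floor_frac * vy
  sig <- if (is.null(start)) rep(vy / (m + 1), m + 1) else {
    if (!all(vnames %in% names(start)))
      stop("`start` must name every component: ",
           paste(vnames, collapse = ", "), call. = FALSE)
    pmax(as.numeric(start[vnames]), floor_v)
  }
  ## terms with no loaded observations are structurally unidentified:
  ## pinned to the floor, excluded from updates
  identifiable <- c(vapply(des$terms, function(tm) any(tm$Vi != 0), TRUE),
                    TRUE)
  sig[!identifiable] <- floor_v

  trace <- data.frame(iter = integer(), loglik = numeric(), step = character())
  vcs_trace <- matrix(NA_real_, 0, m + 1, dimnames = list(NULL, vnames))
  ll_prev <- -Inf
  converged <- FALSE
  core <- reml_core(des, sig)
  dv <- reml_derivs(des, core)

  for (it in seq_len(max_iter)) {
    step <- NULL
    free <- identifiable & !(sig <= floor_v & dv$score < 0)
    delta <- rep(0, m + 1)
    if (use_ai && any(free)) {
      AIf <- dv$AI[free, free, drop = FALSE]
      sol <- tryCatch(solve(AIf, dv$score[free]), error = function(e) NULL)
      if (!is.null(sol)) delta[free] <- sol
    }
    ## AI step with step-halving: accept the longest fraction of the AI
    ## direction that stays in bounds and does not lower the likelihood
    if (any(delta != 0)) {
      for (h in c(1, 0.5, 0.25, 0.1)) {
        cand <- pmax(sig + h * delta, floor_v)
        core_cand <- tryCatch(reml_core(des, cand), error = function(e) NULL)
        if (!is.null(core_cand) && core_cand$loglik >= core$loglik - 1e-10) {
          step <- if (h == 1) "AI" else sprintf("AI/%g", 1 / h)
          prop <- cand
          core_new <- core_cand
          break
        }
      }
    }
    if (is.null(step)) {                       # EM fallback, always monotone
      step <- "EM"
      prop <- pmax(sig + sig^2 * (dv$qf - dv$tr) / dv$q, floor_v)
      core_new <- reml_core(des, prop)
    }

    rel <- max(abs(prop - sig) / pmax(sig, floor_v))
    dll <- core_new$loglik - ll_prev
    trace <- rbind(trace, data.frame(iter = it, loglik = core_new$loglik,
                                     step = step))
    vcs_trace <- rbind(vcs_trace, prop)
    if (verbose)
      message(sprintf("iter %3d [%s] logL = %.6f  max rel dVC = %.2e",
                      it, step, core_new$loglik, rel))
    ll_prev_old <- ll_prev
    sig <- prop
    ll_prev <- core_new$loglik
    core <- core_new
    dv <- reml_derivs(des, core)
    if (rel < tol_vc || (it > 1 && abs(dll) < tol_ll)) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("REML did not converge in ", max_iter, " iterations", call. = FALSE)

  floored <- sig <= floor_v * (1 + 1e-6)
  se <- rep(NA_real_, m + 1)
  if (converged) {
    ## curvature-based SEs from the full AI matrix (also reported for
    ## components held at the floor); free-only block if the full AI is
    ## singular
    AIinv <- tryCatch(solve(dv$AI), error = function(e) NULL)
    if (!is.null(AIinv)) {
      se <- sqrt(pmax(diag(AIinv), 0))
    } else if (any(!floored)) {
      AIf <- dv$AI[!floored, !floored, drop = FALSE]
      AIinv <- tryCatch(solve(AIf), error = function(e) NULL)
      if (!is.null(AIinv)) se[!floored] <- sqrt(pmax(diag(AIinv), 0))
    }
  }
  names(sig) <- names(se) <- vnames
  blups <- term_blups(des, core, sig)
  beta <- core$beta
  names(beta) <- colnames(des$X)

  structure(list(vc = sig, se = se, beta = beta, blups = blups,
                 loglik = core$loglik, converged = converged,
                 trace = cbind(trace, as.data.frame(vcs_trace)),
                 floored = stats::setNames(floored, vnames),
                 ai = dv$AI, n = des$n, term_names = vnames,
                 floor = floor_v, spec = spec),
            class = "reml_fit")
}

#' @export
print.reml_fit <- function(x, ...) {
  cat(sprintf("<reml_fit> logL = %.4f, %s after %d iterations\n", x$loglik,
              if (x$converged) "converged" else "NOT converged",
              nrow(x$trace)))
  tab <- data.frame(component = x$term_names, estimate = signif(x$vc, 4),
                    se = signif(x$se, 3), at_floor = x$floored)
  print(tab, row.names = FALSE)
  invisible(x)
}

## BLUPs u_i = sigma_i^2 K Z' P y for every term, at all kernel levels.
term_blups <- function(des, core, sig) {
  out <- list()
  for (i in seq_along(des$terms)) {
    tm <- des$terms[[i]]
    if (!is.null(tm$Z)) {
      agg <- as.numeric(crossprod(tm$Z, core$Py))
      names(agg) <- tm$levels
    } else {
      agg <- rep(0, tm$q)
      names(agg) <- tm$levels
      obs <- !is.na(tm$idx)
      if (any(obs)) {
        s <- tapply(core$Py[obs], tm$idx[obs], sum)
        agg[as.integer(names(s))] <- s
      }
    }
    u <- if (is.null(tm$K)) sig[i] * agg else sig[i] * as.numeric(tm$K %*% agg)
    names(u) <- tm$levels
    out[[tm$name]] <- u
  }
  out
}

#' Solve the mixed-model equations at fixed variance components
#'
#' Computes generalised-least-squares fixed-effect estimates and BLUPs for a
#' [model_spec()] at supplied (not estimated) variance values — the
#' work-horse of cross-validation, where components are estimated once on the
#' full data and each fold only re-solves. Effect levels with no observations
#' are predicted through their covariance kernel (genomic prediction).
#'
#' @param spec a [model_spec()].
#' @param vcs named numeric vector of variances (term names plus `"e"`).
#' @return list with `beta`, `blups` (per term, all kernel levels),
#'   `loglik` (REML log-likelihood at `vcs`) and `fitted_fixed` (`X beta`).
#' @export
blup_solve <- function(spec, vcs) {
  stopifnot(inherits(spec, "model_spec"))
  des <- build_design(spec)
  vnames <- c(vapply(des$terms, `[[`, "", "name"), "e")
  if (!all(vnames %in% names(vcs)))
    stop("`vcs` must name every component: ", paste(vnames, collapse = ", "),
         call. = FALSE)
  sig <- as.numeric(vcs[vnames])
  if (any(sig < 0) || sig[length(sig)] <= 0)
    stop("variances must be non-negative with a positive residual",
         call. = FALSE)
  core <- reml_core(des, sig)
  beta <- core$beta
  names(beta) <- colnames(des$X)
  list(beta = beta,
       blups = term_blups(des, core, sig),
       loglik = core$loglik,
       fitted_fixed = as.numeric(des$X %*% core$beta))
}

#' REML log-likelihood at given variance components
#'
#' @inheritParams blup_solve
#' @return the restricted log-likelihood (including constants).
#' @export
profile_loglik <- function(spec, vcs) {
  blup_solve(spec, vcs)$loglik
}
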