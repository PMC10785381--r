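## Neighbour-line loading matrix: each observation loads the line sown in the
## immediately adjacent row on each side (coefficient 1 per flank; virtual or
## unassigned flanks load nothing).
neighbour_loadings <- function(data, layout, lines) {
  key <- paste(layout$bed, layout$unit, layout$row)
  left <- layout$line[match(paste(layout$bed, layout$unit, layout$row - 1L), key)]
  right <- layout$line[match(paste(layout$bed, layout$unit, layout$row + 1L), key)]
  names(left) <- names(right) <- layout$row_id
  Z <- matrix(0, nrow(data), length(lines),
              dimnames = list(NULL, lines))
  for (nb in list(left[data$row], right[data$row])) {
    sel <- which(!is.na(nb) & nb %in% lines)
    if (length(sel))
      Z[cbind(sel, match(nb[sel], lines))] <-
        Z[cbind(sel, match(nb[sel], lines))] + 1
  }
  Z
}

## Kernel for the genomic-by-treatment interaction: independent copies of G
## per context, levels "<line>:<context>".
block_kernel <- function(G, contexts) {
  lines <- rownames(G)
  q <- length(lines) * length(contexts)
  K <- matrix(0, q, q)
  nm <- unlist(lapply(contexts, function(ct) paste(lines, ct, sep = ":")))
  dimnames(K) <- list(nm, nm)
  for (i in seq_along(contexts)) {
    sel <- seq_along(lines) + (i - 1L) * length(lines)
    K[sel, sel] <- G
  }
  K
}

#' Assemble the above-ground trait model
#'
#' Builds the full half-row model for an above-ground trait: fixed combined
#' unit-bed-treatment factor and nine random components — additive genomic
#' line effects `g` (GRM kernel), non-additive line effects `l` (identity),
#' neighbour-line genomic and non-genomic effects `ng`/`nl` (each observation
#' loads the lines of its two flanking rows; edge rows load their single real
#' flank), row effects `r`, genomic-by-treatment `tg` (independent copy of
#' the GRM per treatment) and line-by-treatment `tl` interactions, and one
#' spatial effect per treatment (`s1` wet, `s2` dry) with the supplied
#' nearest-neighbour correlation kernel — plus the residual. Passing an
#' indicator-window structure ([build_s_knn()]) gives the M1 variant;
#' a distance-weighted structure ([build_s_euc()]) gives M2.
#'
#' @param data data frame of half-row records with columns `bed`, `unit`,
#'   `row` (row id matching the layout), `treatment` (`"wet"`/`"dry"`),
#'   `line`, and the trait column.
#' @param trait name of the response column.
#' @param grm a [compute_grm()] object covering all lines in `data`.
#' @param spatial a `spatial_structure` built on the experiment's layout
#'   (which also carries the line-to-row assignment used for the neighbour
#'   loadings).
#' @return a [model_spec()] with terms `g, l, ng, nl, r, tg, tl, s1, s2`.
#' @export
build_am <- function(data, trait, grm, spatial) {
  stopifnot(inherits(grm, "grm"), inherits(spatial, "spatial_structure"))
  req <- c("bed", "unit", "row", "treatment", "line", trait)
  if (!all(req %in% names(data)))
    stop("records need columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (!all(data$treatment %in% c("wet", "dry")))
    stop("treatment must be 'wet' or 'dry'", call. = FALSE)
  layout <- spatial$layout
  if (!all(data$row %in% layout$row_id[!layout$virtual]))
    stop("records reference rows absent from the layout", call. = FALSE)
  G <- grm$G
  if (!all(data$line %in% rownames(G)))
    stop("records contain lines absent from the relationship matrix",
         call. = FALSE)

  data$.fixed <- paste(data$unit, data$bed, data$treatment, sep = "_")
  Zn <- neighbour_loadings(data, layout, rownames(G))
  S <- spatial$S
  terms <- list(
    random_term("g", factor = data$line, K = G),
    random_term("l", factor = data$line),
    random_term("ng", Z = Zn, K = G),
    random_term("nl", Z = Zn),
    random_term("r", factor = data$row),
    random_term("tg", factor = paste(data$line, data$treatment, sep = ":"),
                K = block_kernel(G, c("wet", "dry"))),
    random_term("tl", factor = paste(data$line, data$treatment, sep = ":")),
    random_term("s1", factor = ifelse(data$treatment == "wet", data$row, NA),
                K = S),
    random_term("s2", factor = ifelse(data$treatment == "dry", data$row, NA),
                K = S))
  spec <- model_spec(data, trait, fixed = ".fixed", terms = terms)
  attr(spec, "study_model") <- "AM"
  spec
}

#' Assemble the root trait model
#'
#' Builds the repeated-records model for a minirhizotron root trait (TRL, SRL
#' or DRL over three imaging time points): fixed combined bed-camera-time
#' factor (collapsing to bed-time when no `camera` column is present), random
#' additive genomic `g` (GRM), line `l`, row/tube `r` effects shared across
#' time points, one spatial effect per time point (`s1`, `s2`, `s3`) with the
#' supplied nearest-neighbour kernel, and the residual. Neighbour-line terms
#' are deliberately absent from the root models.
#'
#' @param data data frame of tube x time-point records with columns `bed`,
#'   `row` (tube/row id matching the layout), `time` (1, 2 or 3), `line`,
#'   optionally `camera`, and the trait column.
#' @inheritParams build_am
#' @return a [model_spec()] with terms `g, l, r, s1, s2, s3`.
#' @export
build_rm <- function(data, trait, grm, spatial) {
  stopifnot(inherits(grm, "grm"), inherits(spatial, "spatial_structure"))
  req <- c("bed", "row", "time", "line", trait)
  if (!all(req %in% names(data)))
    stop("records need columns: ", paste(req, collapse = ", "), call. = FALSE)
  if (!all(data$time %in% 1:3))
    stop("time point must be 1, 2 or 3", call. = FALSE)
  G <- grm$G
  if (!all(data$line %in% rownames(G)))
    stop("records contain lines absent from the relationship matrix",
         call. = FALSE)
  data$.fixed <- if ("camera" %in% names(data))
    paste(data$bed, data$camera, data$time, sep = "_")
  else paste(data$bed, data$time, sep = "_")

  S <- spatial$S
  sp_term <- function(k) random_term(paste0("s", k),
    factor = ifelse(data$time == k, data$row, NA), K = S)
  terms <- list(
    random_term("g", factor = data$line, K = G),
    random_term("l", factor = data$line),
    random_term("r", factor = data$row),
    sp_term(1), sp_term(2), sp_term(3))
  spec <- model_spec(data, trait, fixed = ".fixed", terms = terms)
  attr(spec, "study_model") <- "RM"
  spec
}

vc_vector <- function(x) {
  if (inherits(x, "reml_fit")) x$vc
  else if (is.numeric(x) && !is.null(names(x))) x
  else stop("supply a reml_fit or a named numeric vector of variance components",
            call. = FALSE)
}

am_required <- c("g", "l", "ng", "nl", "r", "tg", "tl", "e")
rm_required <- c("g", "l", "r", "e")

#' Half-row phenotypic variance from variance components
#'
#' Sums the model's variance components into the phenotypic variance for one
#' context — a treatment (above-ground models, spatial components `s1` wet /
#' `s2` dry) or a time point (root models, `s1`-`s3`):
#' \deqn{\sigma^2_{P,i} = d \sigma^2_g + \sigma^2_l + 2 d \sigma^2_{ng} +
#'   2 \sigma^2_{nl} + \sigma^2_r + d \sigma^2_{tg} + \sigma^2_{tl} +
#'   \sigma^2_{s_i} + \sigma^2_e}
#' for the above-ground model and
#' \eqn{d \sigma^2_g + \sigma^2_l + \sigma^2_r + \sigma^2_{s_k} + \sigma^2_e}
#' for the root model, where `d = d(G)` (the GRM average diagonal) when
#' `scale_by_avg_diag = TRUE` and `d = 1` otherwise. The neighbour components
#' enter twice because every observation is flanked by two neighbour rows.
#'
#' @param fit a `reml_fit` or a named vector of variance components
#'   (`g, l, ng, nl, r, tg, tl, s1, s2, e` for AM; `g, l, r, s1, s2, s3, e`
#'   for RM).
#' @param context spatial context: `"s1"`, `"s2"` (or `"s3"` for root
#'   models).
#' @param model `"AM"` or `"RM"`; inferred from the component names when
#'   missing.
#' @param d_g GRM average diagonal `d(G)` (default 1, i.e. unscaled).
#' @param scale_by_avg_diag apply the `d(G)` factor to the genomic components.
#' @return the phenotypic variance (numeric scalar).
#' @export
phenotypic_variance <- function(fit, context, model = NULL, d_g = 1,
                                scale_by_avg_diag = FALSE) {
  vc <- vc_vector(fit)
  if (is.null(model))
    model <- if (all(am_required %in% names(vc))) "AM" else "RM"
  model <- match.arg(model, c("AM", "RM"))
  need <- c(if (model == "AM") am_required else rm_required, context)
  if (!all(need %in% names(vc)))
    stop("variance components missing: ",
         paste(setdiff(need, names(vc)), collapse = ", "), call. = FALSE)
  d <- if (scale_by_avg_diag) d_g else 1
  sp <- if (model == "AM") {
    d * vc["g"] + vc["l"] + 2 * d * vc["ng"] + 2 * vc["nl"] + vc["r"] +
      d * vc["tg"] + vc["tl"] + vc[context] + vc["e"]
  } else {
    d * vc["g"] + vc["l"] + vc["r"] + vc[context] + vc["e"]
  }
  if (sp <= 0) stop("phenotypic variance must be positive", call. = FALSE)
  unname(sp)
}

#' Heritabilities and genetic coefficient of variation
#'
#' Computes, per context (treatment for above-ground models, time point for
#' root models) and averaged over contexts, the narrow-sense heritability
#' `h^2 = d * sigma_g^2 / sigma_P^2`, the broad-sense heritability
#' `H^2 = (sigma_l^2 + d * sigma_g^2) / sigma_P^2`, and the genetic
#' coefficient of variation `GCV = 100 * sigma_g / mean`. Both heritability
#' scalings are available: `scale_by_avg_diag = TRUE` multiplies the genomic
#' components by the GRM average diagonal `d(G)` in numerator and phenotypic
#' variance; the default (`FALSE`) omits the factor, which reproduces
#' tabulated genetic-parameter summaries computed directly from variance
#' components.
#'
#' @inheritParams phenotypic_variance
#' @param trait_mean overall trait mean, used for the GCV (optional).
#' @return an object of class `genetic_params`: data frame with one row per
#'   context plus an `"average"` row, columns `sigma_p`, `h2`, `H2`, and a
#'   `gcv` attribute (percent, `NA` without `trait_mean`).
#' @export
heritabilities <- function(fit, model = NULL, d_g = 1, trait_mean = NULL,
                           scale_by_avg_diag = FALSE) {
  vc <- vc_vector(fit)
  if (is.null(model))
    model <- if (all(am_required %in% names(vc))) "AM" else "RM"
  model <- match.arg(model, c("AM", "RM"))
  contexts <- if (model == "AM") c("s1", "s2") else c("s1", "s2", "s3")
  contexts <- intersect(contexts, names(vc))
  d <- if (scale_by_avg_diag) d_g else 1
  rows <- lapply(contexts, function(ct) {
    sp <- phenotypic_variance(vc, ct, model, d_g, scale_by_avg_diag)
    data.frame(context = ct, sigma_p = sp,
               h2 = d * unname(vc["g"]) / sp,
               H2 = (unname(vc["l"]) + d * unname(vc["g"])) / sp)
  })
  tab <- do.call(rbind, rows)
  avg <- data.frame(context = "average", sigma_p = mean(tab$sigma_p),
                    h2 = mean(tab$h2), H2 = mean(tab$H2))
  out <- rbind(tab, avg)
  gcv <- if (is.null(trait_mean)) NA_real_
         else 100 * sqrt(unname(vc["g"])) / trait_mean
  structure(out, class = c("genetic_params", "data.frame"),
            gcv = gcv, model = model, d_g = d_g,
            scaled = scale_by_avg_diag)
}

#' @export
print.genetic_params <- function(x, ...) {
  cat(sprintf("<genetic_params> %s model, d(G) = %.3f (%s)\n",
              attr(x, "model"), attr(x, "d_g"),
              if (attr(x, "scaled")) "d(G)-scaled" else "unscaled"))
  print.data.frame(x, row.names = FALSE, digits = 4)
  if (is.finite(attr(x, "gcv")))
    cat(sprintf("GCV = %.2f%%\n", attr(x, "gcv")))
  invisible(x)
}

#' Genetic coefficient of variation
#'
#' `GCV = 100 * sqrt(sigma_g^2) / mean`: the additive genetic standard
#' deviation as a percentage of the trait mean.
#'
#' @param sigma_g2 additive genomic variance.
#' @param trait_mean overall trait mean (> 0).
#' @return GCV in percent.
#' @export
gcv <- function(sigma_g2, trait_mean) {
  if (any(sigma_g2 < 0)) stop("variance must be non-negative", call. = FALSE)
  if (any(trait_mean <= 0)) stop("trait mean must be positive", call. = FALSE)
  100 * sqrt(sigma_g2) / trait_mean
}
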