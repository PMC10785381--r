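#' Build a semi-field row layout
#'
#' Constructs the row geometry of a semi-field experiment: `beds` beds, each
#' divided into `units_per_bed` independent half-bed units of `rows_per_unit`
#' sown rows at `row_spacing` metres. Virtual (unsown) rows are appended at
#' both edges of every unit so that each real row has a complete spatial
#' neighbour window; the pad width is the largest window requirement among the
#' structures the layout is intended for: `max(k, ceiling(d_max / row_spacing))`.
#'
#' Real rows carry a line identifier (assign with [assign_lines()] or by
#' writing to the `line` column); virtual rows never do. Physical positions run
#' at `row_spacing` intervals within each unit, with virtual rows extending
#' beyond the unit edges. Units never share neighbours: all spatial windows are
#' confined to a single bed/unit block.
#'
#' @param beds number of beds.
#' @param units_per_bed number of half-bed units per bed.
#' @param rows_per_unit number of real (sown) rows per unit.
#' @param row_spacing distance between adjacent rows in metres.
#' @param k neighbour window half-width (rows per side) for the indicator
#'   structure, or `NULL` if no indicator structure will be built.
#' @param d_max maximum neighbour distance in metres for the
#'   distance-weighted structure, or `NULL` if none will be built.
#' @return An object of class `field_layout`: a data frame with one row per row site
#'   (real and virtual) and columns `bed`, `unit`, `row` (index within unit,
#'   virtual rows outside `1..rows_per_unit`), `position` (m), `virtual`,
#'   `line` (`NA` for virtual rows) and `row_id`; attributes record the
#'   geometry parameters and pad width.
#' @examples
#' lay <- build_layout(beds = 1, units_per_bed = 1, rows_per_unit = 10, k = 5)
#' nrow(lay)  # 10 real + 5 virtual per edge = 20
#' @export
build_layout <- function(beds = 2, units_per_bed = 2, rows_per_unit = 150,
                         row_spacing = 0.25, k = 5, d_max = NULL) {
  if (beds < 1 || units_per_bed < 1 || rows_per_unit < 1)
    stop("layout dimensions must be positive counts", call. = FALSE)
  if (row_spacing <= 0) stop("row_spacing must be > 0", call. = FALSE)
  if (is.null(k) && is.null(d_max))
    stop("at least one of `k` or `d_max` must be given to size the virtual padding",
         call. = FALSE)
  pad <- max(if (!is.null(k)) k else 0L,
             if (!is.null(d_max)) {
               if (d_max <= 0) stop("d_max must be > 0", call. = FALSE)
               ceiling(d_max / row_spacing)
             } else 0L)
  pad <- as.integer(pad)

  idx <- seq.int(1L - pad, rows_per_unit + pad)
  per_unit <- length(idx)
  grid <- expand.grid(row = idx, unit = seq_len(units_per_bed),
                      bed = seq_len(beds), KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, c("bed", "unit", "row")]
  grid$position <- (grid$row - 1L) * row_spacing
  grid$virtual <- grid$row < 1L | grid$row > rows_per_unit
  grid$line <- NA_character_
  grid$row_id <- sprintf("b%d_u%d_r%+04d", grid$bed, grid$unit, grid$row)

  structure(grid,
            class = c("field_layout", "data.frame"),
            beds = beds, units_per_bed = units_per_bed,
            rows_per_unit = rows_per_unit, row_spacing = row_spacing,
            pad = pad, rows_per_unit_padded = per_unit)
}

#' @export
print.field_layout <- function(x, ...) {
  cat(sprintf(
    "<layout> %d bed(s) x %d unit(s) x %d real rows (%.2f m spacing), pad %d virtual rows/edge\n",
    attr(x, "beds"), attr(x, "units_per_bed"), attr(x, "rows_per_unit"),
    attr(x, "row_spacing"), attr(x, "pad")))
  cat(sprintf("  %d row sites total, %d real\n", nrow(x), sum(!x$virtual)))
  invisible(x)
}

#' Assign lines to the real rows of a layout
#'
#' Randomises `lines` over the real rows, independently within each bed (every
#' line appears a near-equal number of times per bed). Uses the current RNG
#' state; set a seed for reproducibility.
#'
#' @param layout a [build_layout()] object.
#' @param lines character vector of line identifiers.
#' @return the layout with the `line` column filled for real rows.
#' @export
assign_lines <- function(layout, lines) {
  stopifnot(inherits(layout, "field_layout"))
  lines <- as.character(lines)
  for (b in seq_len(attr(layout, "beds"))) {
    sel <- which(!layout$virtual & layout$bed == b)
    reps <- ceiling(length(sel) / length(lines))
    pool <- rep(lines, reps)[seq_along(sel)]
    layout$line[sel] <- sample(pool)
  }
  layout
}

## Targets (real rows) of a layout, in layout order.
real_rows <- function(layout) layout[!layout$virtual, , drop = FALSE]

## Loading-matrix constructor shared by both structures: for each real target
## row, weights over all row sites (real + virtual) of the same bed/unit.
## weight_fn(d) maps non-negative inter-row distances (m) to loadings.
spatial_loadings <- function(layout, reach_rows, weight_fn) {
  pad <- attr(layout, "pad")
  if (pad < reach_rows)
    stop(sprintf("layout pad (%d) is smaller than the required neighbour window (%d rows); rebuild the layout",
                 pad, reach_rows), call. = FALSE)
  tgt <- which(!layout$virtual)
  X <- matrix(0, length(tgt), nrow(layout),
              dimnames = list(layout$row_id[tgt], layout$row_id))
  block <- interaction(layout$bed, layout$unit, drop = TRUE)
  for (bl in levels(block)) {
    cols <- which(block == bl)
    rows <- intersect(tgt, cols)
    if (!length(rows)) next
    d <- abs(outer(layout$position[rows], layout$position[cols], "-"))
    X[match(rows, tgt), cols] <- weight_fn(d)
  }
  X
}

new_spatial_structure <- function(kind, layout, X, param) {
  n <- nrow(X)
  G <- tcrossprod(X)
  cnorm <- sum(diag(G)) / n
  S <- G / cnorm
  structure(list(kind = kind, param = param, layout = layout,
                 loadings = X, S = S, norm_const = cnorm,
                 row_ids = rownames(X)),
            class = "spatial_structure")
}

#' Indicator-window spatial correlation structure
#'
#' Builds the nearest-neighbour spatial correlation matrix from an indicator
#' loading matrix: each real target row loads itself and its `k` left and `k`
#' right neighbour row sites (real or virtual) with weight 1, giving `2k + 1`
#' unit loadings per target. The correlation matrix is the Gram matrix of the
#' loadings scaled by its mean diagonal, `S = X X' / (tr(X X') / n)`, so every
#' target row has unit diagonal and rows `d <= 2k` apart within a unit share
#' `(2k + 1 - d)` window members, i.e. correlation `(2k + 1 - d)/(2k + 1)`.
#'
#' @param layout a [build_layout()] layout padded with at least `k` virtual
#'   rows per unit edge.
#' @param k neighbours per side (default 5, an 11-row window).
#' @return A `spatial_structure` with elements `S` (n x n correlation matrix
#'   over real rows), `loadings`, `norm_const`, `row_ids`, and the layout.
#' @seealso [build_s_euc()], [correlation_decay()]
#' @export
build_s_knn <- function(layout, k = 5) {
  stopifnot(inherits(layout, "field_layout"))
  if (k < 1) stop("k must be a positive number of neighbours", call. = FALSE)
  spacing <- attr(layout, "row_spacing")
  reach <- k * spacing
  X <- spatial_loadings(layout, k, function(d) (d <= reach + 1e-9) * 1)
  new_spatial_structure("knn", layout, X, list(k = k))
}

#' Distance-weighted spatial correlation structure
#'
#' Builds the Euclidean-distance nearest-neighbour correlation structure: the
#' loading of target row i on row site j is `1 - d_ij / d_max` for
#' `d_ij <= d_max` and 0 beyond, so closer neighbours receive relatively more
#' weight than under the indicator window of [build_s_knn()]. The correlation
#' matrix is again the trace-normalised Gram matrix of the loadings,
#' `S = X X' / (tr(X X') / n)`.
#'
#' The neighbour set is, by default, the same `window_k`-rows-per-side window
#' the indicator structure uses (5 left and 5 right), with the distance
#' weighting applied inside it; `d_max = 2.75` m — the distance spanned by 11
#' rows at 0.25 m spacing — fixes the weighting scale. This is what makes the
#' structure concentrate correlation on close neighbours relative to
#' [build_s_knn()]. Setting `window_k = NULL` switches to the pure distance
#' rule (every row within `d_max` per side contributes), which yields a
#' wider, flatter correlation profile.
#'
#' @param layout a padded [build_layout()] layout.
#' @param d_max distance-weighting scale and maximum neighbour distance in
#'   metres (default 2.75).
#' @param window_k neighbour rows per side (default 5); `NULL` for the pure
#'   distance rule.
#' @return A `spatial_structure`; see [build_s_knn()].
#' @export
build_s_euc <- function(layout, d_max = 2.75, window_k = 5) {
  stopifnot(inherits(layout, "field_layout"))
  if (d_max <= 0) stop("d_max must be > 0", call. = FALSE)
  spacing <- attr(layout, "row_spacing")
  reach_rows <- if (is.null(window_k)) ceiling(d_max / spacing) else
    min(window_k, ceiling(d_max / spacing))
  reach <- min(d_max, reach_rows * spacing)
  X <- spatial_loadings(layout, reach_rows, function(d) {
    w <- 1 - d / d_max
    w[d > reach + 1e-9] <- 0
    pmax(w, 0)
  })
  new_spatial_structure("euc", layout, X, list(d_max = d_max, window_k = window_k))
}

#' @export
print.spatial_structure <- function(x, ...) {
  cat(sprintf("<spatial_structure> kind = %s, %d target rows, trace norm = %.4f\n",
              x$kind, nrow(x$S), x$norm_const))
  invisible(x)
}

#' Mean between-neighbour correlation by inter-row distance
#'
#' Summarises a spatial structure as a decay curve: the mean correlation
#' `S[i, j]` over all pairs of real rows at each distinct within-unit
#' inter-row distance (pairs in different beds or units have zero correlation
#' and are excluded).
#'
#' @param structure a `spatial_structure`.
#' @param max_distance optional cap on the distance (m) reported.
#' @return data frame with `distance` (m), `rows_apart`, `mean_correlation`
#'   and `n_pairs`.
#' @export
correlation_decay <- function(structure, max_distance = NULL) {
  stopifnot(inherits(structure, "spatial_structure"))
  lay <- real_rows(structure$layout)
  spacing <- attr(structure$layout, "row_spacing")
  block <- interaction(lay$bed, lay$unit, drop = TRUE)
  same <- outer(block, block, "==")
  d <- abs(outer(lay$position, lay$position, "-"))
  keep <- same & upper.tri(d, diag = TRUE)
  dist <- round(d[keep] / spacing) * spacing
  corr <- structure$S[keep]
  if (!is.null(max_distance)) {
    sel <- dist <= max_distance + 1e-9
    dist <- dist[sel]; corr <- corr[sel]
  }
  agg <- aggregate(corr, by = list(distance = dist), FUN = mean)
  n <- aggregate(corr, by = list(distance = dist), FUN = length)
  data.frame(distance = agg$distance,
             rows_apart = as.integer(round(agg$distance / spacing)),
             mean_correlation = agg$x,
             n_pairs = n$x)
}

#' Export a spatial correlation matrix as delimited text
#'
#' @param structure a `spatial_structure`.
#' @param path output file; tab-separated with row/column headers of row ids.
#' @export
write_spatial_structure <- function(structure, path) {
  stopifnot(inherits(structure, "spatial_structure"))
  utils::write.table(structure$S, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}
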