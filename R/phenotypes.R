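#' Grain nitrogen removal from yield and protein content
#'
#' `GNR = GY * GPC / 6.25 * 10` in kg/ha, where 6.25 is the standard
#' nitrogen-to-protein conversion factor for cereals and the factor 10
#' converts t/ha x percent to kg/ha.
#'
#' @param gy grain yield in t/ha.
#' @param gpc grain protein content in percent.
#' @return grain nitrogen removal in kg/ha.
#' @examples
#' derive_gnr(7.07, 9.42)  # ~106.6 kg/ha
#' @export
derive_gnr <- function(gy, gpc) {
  if (any(gy < 0, na.rm = TRUE) || any(gpc < 0, na.rm = TRUE))
    stop("grain yield and protein content must be non-negative", call. = FALSE)
  gy * gpc / 6.25 * 10
}

#' Thousand kernel weight from a counted sample
#'
#' `TKW = sample_weight / seed_count * 1000` grams.
#'
#' @param sample_weight sample weight in grams.
#' @param seed_count number of seeds in the sample (> 0).
#' @return thousand kernel weight in grams.
#' @export
derive_tkw <- function(sample_weight, seed_count) {
  if (any(seed_count <= 0, na.rm = TRUE))
    stop("seed_count must be positive", call. = FALSE)
  if (any(sample_weight < 0, na.rm = TRUE))
    stop("sample_weight must be non-negative", call. = FALSE)
  sample_weight / seed_count * 1000
}

#' Summarise root images into tube x time-point root-length traits
#'
#' Aggregates per-image visible root length (cm) into three traits per
#' minirhizotron tube and time point: total root length (TRL, sum over all
#' images of the tube/time point), shallow root length (SRL, sum over images
#' in the shallow depth window) and deep root length (DRL, deep window).
#' Depth windows are half-open on the right for SRL and closed for DRL so the
#' shared 120 cm boundary is counted once, in DRL. Tube/time-point groups with
#' no images yield no record — absence of images is missing data, not zero
#' root length.
#'
#' @param images data frame with columns `bed`, `row` (tube id), `time`,
#'   `depth` (cm) and `length` (cm, non-negative).
#' @param shallow_window numeric length-2, shallow depth interval
#'   `[lo, hi)` in cm (default `c(100, 120)`).
#' @param deep_window numeric length-2, deep depth interval `[lo, hi]` in cm
#'   (default `c(120, 180)`).
#' @return data frame with one record per observed bed x tube x time point:
#'   `bed`, `row`, `time`, `trl`, `srl`, `drl`, `n_images`.
#' @examples
#' img <- data.frame(bed = 1, row = 1, time = 1,
#'                   depth = c(110, 130, 200), length = c(3, 4, 5))
#' summarize_roots(img)  # TRL 12, SRL 3, DRL 4
#' @export
summarize_roots <- function(images, shallow_window = c(100, 120),
                            deep_window = c(120, 180)) {
  req <- c("bed", "row", "time", "depth", "length")
  if (!all(req %in% names(images)))
    stop("images must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(images$length < 0, na.rm = TRUE))
    stop("visible root lengths must be non-negative", call. = FALSE)
  if (any(images$depth <= 0, na.rm = TRUE))
    stop("image depths must be positive", call. = FALSE)
  images <- images[!is.na(images$length), , drop = FALSE]
  if (!nrow(images))
    return(data.frame(bed = integer(), row = integer(), time = integer(),
                      trl = numeric(), srl = numeric(), drl = numeric(),
                      n_images = integer()))
  sh <- images$depth >= shallow_window[1] & images$depth < shallow_window[2]
  dp <- images$depth >= deep_window[1] & images$depth <= deep_window[2]
  key <- list(bed = images$bed, row = images$row, time = images$time)
  out <- aggregate(cbind(trl = images$length,
                         srl = images$length * sh,
                         drl = images$length * dp),
                   by = key, FUN = sum)
  n <- aggregate(list(n_images = images$length), by = key, FUN = length)
  out <- merge(out, n, by = c("bed", "row", "time"), sort = TRUE)
  out[order(out$bed, out$row, out$time), , drop = FALSE]
}

#' Edit trait records: outlier and ungenotyped-line removal
#'
#' Applies the study's data-editing rules to a trait table: per trait, values
#' farther than `sd_limit` standard deviations from the mean are set to
#' missing (mean and SD taken from the unedited column in a single pass), and
#' records of lines absent from `genotyped_lines` are dropped. A zero or
#' undefined SD disables outlier editing for that column. Editing may
#' optionally be performed within groups.
#'
#' @param records data frame of trait records with a `line` column.
#' @param traits character vector of numeric trait columns to edit.
#' @param sd_limit outlier threshold in SD units (default 3).
#' @param genotyped_lines optional character vector; records of other lines
#'   are removed.
#' @param group optional column name: outlier editing within each group level
#'   rather than globally (default global).
#' @return list with `records` (edited table, rows with all edited traits
#'   missing removed) and `report` (removal counts per rule and trait).
#' @export
edit_records <- function(records, traits, sd_limit = 3,
                         genotyped_lines = NULL, group = NULL) {
  stopifnot(is.data.frame(records), all(traits %in% names(records)))
  report <- list()
  n0 <- nrow(records)
  if (!is.null(genotyped_lines)) {
    keep <- records$line %in% genotyped_lines
    report$no_genotype <- sum(!keep)
    records <- records[keep, , drop = FALSE]
  }
  grp <- if (is.null(group)) rep(1L, nrow(records)) else records[[group]]
  for (tr in traits) {
    x <- records[[tr]]
    out <- rep(FALSE, length(x))
    for (g in unique(grp)) {
      sel <- which(grp == g & !is.na(x))
      if (length(sel) < 2) next
      m <- mean(x[sel]); s <- sd(x[sel])
      if (!is.finite(s) || s == 0) next
      out[sel] <- abs(x[sel] - m) > sd_limit * s
    }
    records[[tr]][out] <- NA
    report[[paste0("outlier_", tr)]] <- sum(out)
  }
  all_missing <- rowSums(!is.na(records[, traits, drop = FALSE])) == 0
  records <- records[!all_missing, , drop = FALSE]
  if (!nrow(records))
    stop("no records left after editing", call. = FALSE)
  report$rows_in <- n0
  report$rows_out <- nrow(records)
  list(records = records,
       report = data.frame(rule = names(report),
                           count = unlist(report, use.names = FALSE)))
}

#' Read an above-ground phenotype table
#'
#' Delimited text with named columns; requires `bed`, `unit`, `row`,
#' `treatment` and `line`, plus any trait columns. Missing values may be
#' empty or `NA`.
#'
#' @param path file path.
#' @param sep field separator (default tab).
#' @return data frame of records.
#' @export
read_phenotypes <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("bed", "unit", "row", "treatment", "line")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("phenotype table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}

#' Read a root-image table
#'
#' Delimited text with columns `bed`, `row` (tube), `time`, `depth` (cm) and
#' `length` (cm).
#'
#' @inheritParams read_phenotypes
#' @return data frame of image records.
#' @export
read_root_images <- function(path, sep = "\t") {
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  req <- c("bed", "row", "time", "depth", "length")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols))
    stop("root-image table lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  tab
}
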