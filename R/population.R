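# Population-level analysis: viability filtering, slice exclusion,
# proportional activation, amplitude distributions, and granule-cell-layer
# position statistics.
#
# Cell records are long-format data frames with one row per cell and
# condition: slice_id, roi_id, condition, responded (logical), and optionally
# peak_dff and position_pct. The saturating-disinhibition viability condition
# is labelled "PTX" by default.

check_cell_records <- function(cells, ptx_label) {
  need <- c("slice_id", "roi_id", "condition", "responded")
  miss <- setdiff(need, names(cells))
  if (length(miss))
    stop("cell records lack column(s): ", paste(miss, collapse = ", "))
  has_ptx <- tapply(cells$condition == ptx_label,
                    paste(cells$slice_id, cells$roi_id), any)
  if (!all(has_ptx))
    stop("every cell needs a '", ptx_label, "' condition entry")
  invisible(TRUE)
}

#' Viability filter
#'
#' Cells that are inactive in every non-viability condition and also inactive
#' under the saturating-disinhibition viability condition are considered
#' non-viable (deafferented or damaged) and removed.
#'
#' @param cells Long-format cell records (see module description).
#' @param ptx_label Condition label of the viability check. Default `"PTX"`.
#' @return List: `cells` (retained rows), `excluded` (removed rows), and
#'   `report` (per-slice counts of cells in, excluded, retained).
#' @export
viability_filter <- function(cells, ptx_label = "PTX") {
  check_cell_records(cells, ptx_label)
  key <- paste(cells$slice_id, cells$roi_id)
  any_resp <- tapply(cells$responded, key, any)
  dead <- names(any_resp)[!any_resp]
  out <- !(key %in% dead)
  per_slice <- function(k) {
    sl <- vapply(strsplit(k, " "), `[`, character(1), 1)
    table(sl)
  }
  all_cells <- unique(data.frame(key = key, slice = cells$slice_id))
  exc_cells <- all_cells[all_cells$key %in% dead, ]
  report <- merge(
    as.data.frame(table(all_cells$slice), responseName = "n_cells"),
    as.data.frame(table(factor(exc_cells$slice,
                               levels = unique(all_cells$slice))),
                  responseName = "n_excluded"),
    by = "Var1")
  names(report)[1] <- "slice_id"
  report$n_retained <- report$n_cells - report$n_excluded
  list(cells = cells[out, , drop = FALSE],
       excluded = cells[!out, , drop = FALSE],
       report = report)
}

#' Slice-level exclusion on the viability condition
#'
#' A slice is flagged damaged/deafferented and excluded when at least 70\% of
#' its ROIs fail to activate under the viability condition.
#'
#' @param cells Long-format cell records for one or more slices.
#' @param threshold Inactive fraction at or above which a slice is excluded.
#'   Default 0.70.
#' @param ptx_label Viability condition label.
#' @return Data frame per slice: `slice_id`, `n_rois`, `frac_inactive_ptx`,
#'   `excluded`.
#' @export
slice_exclusion <- function(cells, threshold = 0.70, ptx_label = "PTX") {
  ptx <- cells[cells$condition == ptx_label, , drop = FALSE]
  if (!nrow(ptx)) stop("no '", ptx_label, "' condition rows")
  agg <- aggregate(responded ~ slice_id, data = ptx,
                   FUN = function(x) c(n = length(x), inact = mean(!x)))
  out <- data.frame(slice_id = agg$slice_id,
                    n_rois = agg$responded[, "n"],
                    frac_inactive_ptx = agg$responded[, "inact"])
  out$excluded <- out$frac_inactive_ptx >= threshold
  out
}

#' Proportional activation per slice
#'
#' Percentage of viable cells in a slice responding under one condition.
#'
#' @param cells Long-format cell records, already viability-filtered.
#' @param condition Condition label to evaluate.
#' @return Data frame: `slice_id`, `n_viable`, `n_responding`, `pct_active`.
#'   Slices with zero viable cells are dropped with a warning.
#' @export
proportional_activation <- function(cells, condition) {
  sub <- cells[cells$condition == condition, , drop = FALSE]
  if (!nrow(sub)) stop("no rows for condition '", condition, "'")
  agg <- aggregate(responded ~ slice_id, data = sub,
                   FUN = function(x) c(n = length(x), k = sum(x)))
  out <- data.frame(slice_id = agg$slice_id,
                    n_viable = agg$responded[, "n"],
                    n_responding = agg$responded[, "k"])
  bad <- out$n_viable == 0
  if (any(bad)) {
    warning("slice(s) with zero viable cells skipped: ",
            paste(out$slice_id[bad], collapse = ", "))
    out <- out[!bad, , drop = FALSE]
  }
  out$pct_active <- 100 * out$n_responding / out$n_viable
  out
}

#' Amplitude summary for a set of events
#'
#' Median, interquartile range and empirical cumulative distribution of peak
#' amplitudes.
#'
#' @param amplitudes Numeric vector of peak dF/F0 values (\%).
#' @return List: `n`, `median`, `iqr` (25th/75th percentiles, midpoint
#'   interpolation), `ecdf` (data frame of sorted value, cumulative
#'   fraction).
#' @export
amplitude_summary <- function(amplitudes) {
  amplitudes <- amplitudes[is.finite(amplitudes)]
  if (!length(amplitudes)) stop("no amplitudes to summarize")
  q <- quantile(amplitudes, c(0.25, 0.75), names = FALSE)
  v <- sort(amplitudes)
  list(n = length(v), median = median(v), iqr = q,
       ecdf = data.frame(value = v, fraction = seq_along(v) / length(v)))
}

#' Compare position distributions of active vs all cells
#'
#' Two-sided two-sample Kolmogorov-Smirnov test on granule-cell-layer
#' positions (\% distance from the inner to the outer border).
#'
#' @param active_positions,all_positions Numeric vectors in [0, 100].
#' @return An `sg_test` with the KS `D` statistic and p value.
#' @export
compare_position_distributions <- function(active_positions, all_positions) {
  stopifnot(length(active_positions) > 0, length(all_positions) > 0)
  ks_two_sample(active_positions, all_positions)
}

#' Inner/outer granule-cell-layer contingency test
#'
#' Counts cells of two groups falling in the inner (< `boundary`) vs outer
#' half of the layer and tests association with Fisher's exact test.
#'
#' @param positions_a,positions_b Positions (\%) for the two groups.
#' @param boundary Inner/outer boundary (\%). Default 50.
#' @return List: `table` (2x2: rows = groups, cols = inner/outer) and
#'   `test` (an `sg_test` from [fisher_exact()]).
#' @export
inner_outer_contingency <- function(positions_a, positions_b, boundary = 50) {
  if (!length(positions_a) || !length(positions_b))
    stop("both groups must be non-empty")
  stopifnot(all(positions_a >= 0 & positions_a <= 100),
            all(positions_b >= 0 & positions_b <= 100))
  tab <- rbind(a = c(inner = sum(positions_a < boundary),
                     outer = sum(positions_a >= boundary)),
               b = c(inner = sum(positions_b < boundary),
                     outer = sum(positions_b >= boundary)))
  list(table = tab, test = fisher_exact(tab))
}
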