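# File formats and the end-to-end pipeline driver.
#
# Trace tables are CSV with a first column of frame times (seconds) and one
# column per ROI (header = ROI ID). Event tables are CSV with the exported
# event columns. Image mode reads a multi-frame grayscale TIFF plus an ROI
# label mask and averages each labelled region per frame.

#' Write a trace table
#'
#' @param traces List of `roi_trace` objects sharing one time grid.
#' @param path Output CSV path.
#' @export
write_trace_table <- function(traces, path) {
  stopifnot(length(traces) > 0)
  t0 <- traces[[1]]$t
  for (tr in traces)
    if (length(tr$t) != length(t0) || max(abs(tr$t - t0)) > 1e-9)
      stop("all traces must share one time grid")
  df <- data.frame(time_s = t0)
  for (tr in traces) df[[tr$roi_id]] <- tr$f_raw
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace table
#'
#' @param path CSV path (first column time in seconds, one column per ROI).
#' @param frame_rate Frame rate; inferred from the time column when `NULL`.
#' @param stimulus_times Stimulus schedule attached to every trace.
#' @return List of `roi_trace` objects.
#' @export
read_trace_table <- function(path, frame_rate = NULL, stimulus_times = numeric(0)) {
  df <- read.csv(path, check.names = FALSE)
  if (ncol(df) < 2) stop("trace table needs a time column and >= 1 ROI column")
  t <- df[[1]]
  if (length(t) < 2 || is.unsorted(t))
    stop("malformed trace table: time column must be increasing")
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6)
    stop("malformed trace table: non-uniform frame times")
  if (is.null(frame_rate)) frame_rate <- 1 / mean(dt)
  lapply(names(df)[-1], function(id)
    new_roi_trace(id, t, df[[id]], frame_rate, stimulus_times))
}

#' Write an event table
#'
#' Columns: `roi_id`, `peak_id`, `onset_time`, `max_dff`, `peak_time`,
#' `decay90_time`, `decay_fit_param`, `auc`, `evoking_stimulus_index`.
#'
#' @param events A `calcium_events` data frame.
#' @param path Output CSV path.
#' @export
write_event_table <- function(events, path) {
  out <- data.frame(roi_id = events$roi_id, peak_id = events$peak_id,
                    onset_time = events$onset_time,
                    max_dff = events$peak_dff,
                    peak_time = events$peak_time,
                    decay90_time = events$decay90_time,
                    decay_fit_param = events$decay_tau,
                    auc = events$auc,
                    evoking_stimulus_index = events$evoking_stimulus_index)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an event table
#'
#' @param path CSV path written by [write_event_table()].
#' @return A `calcium_events` data frame.
#' @export
read_event_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("roi_id", "peak_id", "onset_time", "max_dff", "peak_time",
            "decay90_time", "decay_fit_param", "auc",
            "evoking_stimulus_index")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed event table, missing column(s): ",
         paste(miss, collapse = ", "))
  out <- data.frame(roi_id = as.character(df$roi_id), peak_id = df$peak_id,
                    onset_time = df$onset_time, peak_time = df$peak_time,
                    peak_dff = df$max_dff, auc = df$auc,
                    decay90_time = df$decay90_time,
                    decay_tau = df$decay_fit_param,
                    evoking_stimulus_index = df$evoking_stimulus_index,
                    stringsAsFactors = FALSE)
  class(out) <- c("calcium_events", "data.frame")
  out
}

#' Extract ROI traces from a TIFF stack and label mask
#'
#' @param stack_path Multi-frame grayscale TIFF.
#' @param mask_path Single-frame TIFF whose pixel values label ROIs (0 =
#'   background); values are rounded to integers after rescaling.
#' @param frame_rate Acquisition rate (Hz).
#' @param stimulus_times Stimulus schedule attached to the traces.
#' @param scale Intensity scale factor applied to the stack (TIFF floats in
#'   [0,1] are multiplied by this). Default 1.
#' @return List of `roi_trace` objects, one per mask label.
#' @export
read_tiff_stack_with_rois <- function(stack_path, mask_path, frame_rate = 55,
                                      stimulus_times = numeric(0), scale = 1) {
  frames <- tiff::readTIFF(stack_path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  mask <- tiff::readTIFF(mask_path)
  if (length(dim(mask)) > 2) mask <- mask[, , 1]
  labels <- round(mask * 255)
  ids <- sort(setdiff(unique(as.vector(labels)), 0))
  if (!length(ids)) stop("ROI mask contains no labels")
  nt <- length(frames)
  t <- (seq_len(nt) - 1) / frame_rate
  lapply(ids, function(lab) {
    sel <- labels == lab
    f <- vapply(frames, function(fr) {
      m <- if (length(dim(fr)) > 2) fr[, , 1] else fr
      if (!all(dim(m) == dim(labels)))
        stop("stack frame and mask dimensions differ")
      mean(m[sel]) * scale
    }, numeric(1))
    new_roi_trace(sprintf("roi%03d", lab), t, f, frame_rate, stimulus_times)
  })
}

#' Write a synthetic image stack for a set of ROI traces
#'
#' Renders each ROI as a uniform disc whose intensity follows its trace, on a
#' constant background; writes the multi-frame stack and the matching label
#' mask. Intensities are scaled by `1/max` into [0, 1].
#'
#' @param traces List of `roi_trace` objects.
#' @param stack_path,mask_path Output TIFF paths.
#' @param dim_px Image side length. Default 64.
#' @param radius Disc radius in pixels. Default 5.
#' @param background Background intensity. Default 0.
#' @return The intensity scale used (multiply pixel values by it to recover
#'   trace units).
#' @export
write_synthetic_stack <- function(traces, stack_path, mask_path, dim_px = 64,
                                  radius = 5, background = 0) {
  n <- length(traces)
  stopifnot(n >= 1, n <= 9)
  nt <- length(traces[[1]]$t)
  centers <- cbind(x = dim_px * (seq_len(n)) / (n + 1), y = dim_px / 2)
  xs <- matrix(rep(seq_len(dim_px), dim_px), dim_px, byrow = TRUE)
  ys <- matrix(rep(seq_len(dim_px), dim_px), dim_px)
  mx <- max(vapply(traces, function(tr) max(tr$f_raw), numeric(1)),
            background)
  scale <- mx
  mask <- matrix(0, dim_px, dim_px)
  sels <- vector("list", n)
  for (i in seq_len(n)) {
    sel <- (xs - centers[i, "x"])^2 + (ys - centers[i, "y"])^2 <= radius^2
    sels[[i]] <- sel
    mask[sel] <- i / 255
  }
  frames <- lapply(seq_len(nt), function(k) {
    img <- matrix(background / scale, dim_px, dim_px)
    for (i in seq_len(n)) img[sels[[i]]] <- traces[[i]]$f_raw[k] / scale
    img
  })
  tiff::writeTIFF(frames, stack_path, bits.per.sample = 16)
  tiff::writeTIFF(mask, mask_path, bits.per.sample = 8)
  invisible(scale)
}

#' Run the full simulation-to-statistics pipeline
#'
#' Simulates one population per group, runs transient detection on every
#' trace, classifies stimulus responses, applies viability and slice
#' exclusion rules, computes proportional activation per slice and amplitude
#' summaries per group, and compares per-slice activation across groups.
#'
#' @param groups Named list of [group_profile] objects.
#' @param n_slices,n_cells_per_slice Cohort dimensions per group.
#' @param conditions Condition labels (stimulus intensities plus `"PTX"`).
#' @param acq An [acquisition_config].
#' @param params A [detection_params].
#' @param seed Master seed; per-group seeds are derived from it.
#' @param out_dir Optional directory for CSV/JSON artifacts.
#' @return An object of class `sparsegate_report` (list): per-slice
#'   activation, group summaries, test results, the resolved configuration
#'   and seed.
#' @export
run_pipeline <- function(groups = dgc_group_profiles(),
                         n_slices = 3, n_cells_per_slice = 15,
                         conditions = c("100uA", "400uA", "PTX"),
                         acq = acquisition_config(n_frames = 275,
                                                  stimulus_times = 2),
                         params = detection_params(),
                         seed = 1, out_dir = NULL) {
  stopifnot(length(groups) >= 1, !is.null(names(groups)))
  group_results <- list()
  counts <- list()
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    pop <- generate_population(g, n_slices, n_cells_per_slice,
                               conditions = conditions, acq = acq,
                               seed = seed + 1000L * gi, make_traces = TRUE)
    cells <- detect_population(pop, params)
    vf <- viability_filter(cells$records)
    se <- slice_exclusion(vf$cells)
    ok_slices <- se$slice_id[!se$excluded]
    kept <- vf$cells[vf$cells$slice_id %in% ok_slices, , drop = FALSE]
    act <- lapply(setdiff(conditions, "PTX"), function(cond)
      cbind(group = names(groups)[gi], condition = cond,
            proportional_activation(kept, cond)))
    act_ptx <- cbind(group = names(groups)[gi], condition = "PTX",
                     proportional_activation(kept, "PTX"))
    amp <- lapply(setdiff(conditions, "PTX"), function(cond) {
      a <- kept$peak_dff[kept$condition == cond & kept$responded]
      a <- a[is.finite(a)]
      if (length(a)) amplitude_summary(a) else NULL
    })
    names(amp) <- setdiff(conditions, "PTX")
    counts[[names(groups)[gi]]] <- list(
      cells_in = nrow(pop$cells),
      excluded_nonviable = nrow(vf$excluded) /
        max(1, length(unique(cells$records$condition))),
      slices_excluded = sum(se$excluded))
    group_results[[names(groups)[gi]]] <- list(
      activation = do.call(rbind, c(act, list(act_ptx))),
      amplitudes = amp, slice_exclusion = se,
      viability_report = vf$report)
  }
  act_all <- do.call(rbind, lapply(group_results, `[[`, "activation"))
  tests <- list()
  for (cond in setdiff(conditions, "PTX")) {
    sub <- act_all[act_all$condition == cond, ]
    if (length(unique(sub$group)) >= 2)
      tests[[paste0("activation_", cond)]] <-
        kruskal_wallis(log1p_transform(sub$pct_active), sub$group,
                       control = names(groups)[1])
  }
  report <- structure(list(
    activation = act_all, groups = group_results, tests = tests,
    filter_counts = counts,
    config = list(n_slices = n_slices, n_cells_per_slice = n_cells_per_slice,
                  conditions = conditions, acq = unclass(acq),
                  params = unclass(params), seed = seed)),
    class = "sparsegate_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(act_all, file.path(out_dir, "slice_activation.csv"),
              row.names = FALSE)
    jsonlite::write_json(report_to_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# detection + response classification over a synthetic population; returns
# long-format cell records with observed responded flags and peak amplitudes
detect_population <- function(pop, params = detection_params()) {
  stopifnot(inherits(pop, "synthetic_population"),
            !is.null(pop$traces))
  recs <- list()
  all_events <- list()
  for (id in names(pop$traces)) {
    tr <- pop$traces[[id]]
    ev <- detect_events(tr, params)
    evoked <- ev[!is.na(ev$evoking_stimulus_index), , drop = FALSE]
    recs[[id]] <- data.frame(
      slice_id = tr$slice_id, roi_id = tr$roi_id, condition = tr$condition,
      responded = nrow(evoked) > 0,
      peak_dff = if (nrow(evoked)) max(evoked$peak_dff) else NA_real_,
      stringsAsFactors = FALSE)
    if (nrow(ev)) all_events[[id]] <- ev
  }
  records <- do.call(rbind, recs)
  records <- merge(records, pop$cells, by = c("slice_id", "roi_id"),
                   sort = FALSE)
  rownames(records) <- NULL
  list(records = records,
       events = if (length(all_events)) do.call(rbind, all_events) else NULL)
}

report_to_json <- function(report) {
  list(activation = report$activation,
       tests = lapply(report$tests, function(x)
         list(method = x$method, statistic = x$statistic, df = x$df,
              p = x$p.value)),
       filter_counts = report$filter_counts,
       config = report$config)
}

#' @export
print.sparsegate_report <- function(x, ...) {
  cat("Pipeline report:", length(x$groups), "group(s), seed",
      x$config$seed, "\n")
  agg <- aggregate(pct_active ~ group + condition, data = x$activation, mean)
  print(agg)
  invisible(x)
}
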