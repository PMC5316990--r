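# Calcium-transient detection on ROI traces.
#
# The detector follows the two-threshold scheme used for somatic population
# imaging: dF/F0 conversion, Savitzky-Golay smoothing, first derivative,
# an initial derivative threshold estimated from the whole trace (robust
# MAD scale), sliding-window local maxima with their flanking derivative
# zero crossings, and an area-under-the-curve second threshold that
# discriminates genuine transients from noise excursions. Accepted events are
# characterized by onset, peak amplitude/time, AUC, 90%-decay time and a
# fitted exponential decay constant.

#' Detection parameters
#'
#' @param sg_window Savitzky-Golay window length in frames (odd). Default 11
#'   (~200 ms at 55 Hz).
#' @param sg_order Savitzky-Golay polynomial order. Default 3.
#' @param deriv_threshold_k Initial-threshold multiplier of the robust
#'   (MAD-based) noise scale of the derivative trace. Default 3.
#' @param auc_threshold_k Second-threshold multiplier: an event is kept iff
#'   its AUC is at least `auc_threshold_k * sigma_smooth * median event
#'   duration`, where `sigma_smooth` is the robust noise SD of the smoothed
#'   trace. Default 2.
#' @param min_event_separation Non-maximum-suppression window (s): derivative
#'   maxima closer than this are merged, keeping the larger. Default 0.15.
#' @param response_window Window (s) after each stimulus within which an
#'   event onset counts as a response. Default 0.5.
#' @param baseline_window Baseline used for F0: either `NULL` (all frames
#'   before the first stimulus, capped at 1 s) or a length-2 numeric giving a
#'   time range in seconds.
#' @param auc_on_smoothed Integrate the smoothed (default) or raw dF/F0 for
#'   the second threshold.
#' @return Object of class `detection_params`.
#' @export
detection_params <- function(sg_window = 11, sg_order = 3,
                             deriv_threshold_k = 3, auc_threshold_k = 2,
                             min_event_separation = 0.15,
                             response_window = 0.5,
                             baseline_window = NULL,
                             auc_on_smoothed = TRUE) {
  stopifnot(sg_window %% 2 == 1, sg_window > sg_order,
            deriv_threshold_k > 0, auc_threshold_k > 0,
            min_event_separation >= 0, response_window > 0)
  structure(list(sg_window = as.integer(sg_window),
                 sg_order = as.integer(sg_order),
                 deriv_threshold_k = deriv_threshold_k,
                 auc_threshold_k = auc_threshold_k,
                 min_event_separation = min_event_separation,
                 response_window = response_window,
                 baseline_window = baseline_window,
                 auc_on_smoothed = auc_on_smoothed),
            class = "detection_params")
}

#' Convert a raw trace to percent dF/F0
#'
#' F0 is the mean fluorescence over the baseline window; the default window
#' is all frames before the first stimulus, capped at 1 s (the whole trace
#' when there are no stimuli).
#'
#' @param trace A `roi_trace`.
#' @param baseline Optional length-2 time range (s) overriding the default.
#' @return Object of class `dff_trace`: `t`, `dff` (\%), `f0`, plus the
#'   originating ROI metadata.
#' @export
compute_dff <- function(trace, baseline = NULL) {
  stopifnot(inherits(trace, "roi_trace"))
  t <- trace$t
  if (is.null(baseline)) {
    end <- if (length(trace$stimulus_times))
      min(min(trace$stimulus_times), t[1] + 1) else t[1] + 1
    idx <- which(t < end)
  } else {
    idx <- which(t >= baseline[1] & t <= baseline[2])
    if (length(trace$stimulus_times) &&
        any(trace$stimulus_times >= baseline[1] &
            trace$stimulus_times <= baseline[2]))
      warning("baseline window overlaps a stimulus")
  }
  if (length(idx) < 5)
    stop("baseline window must contain at least 5 frames")
  f0 <- mean(trace$f_raw[idx])
  if (!is.finite(f0) || f0 <= 0)
    stop("non-positive baseline fluorescence F0")
  structure(list(roi_id = trace$roi_id, slice_id = trace$slice_id,
                 condition = trace$condition, t = t,
                 dff = 100 * (trace$f_raw - f0) / f0, f0 = f0,
                 frame_rate = trace$frame_rate,
                 stimulus_times = trace$stimulus_times),
            class = "dff_trace")
}

#' Savitzky-Golay smoothing of a dF/F0 trace
#'
#' Polynomial least-squares smoothing. The returned object carries the
#' smoothed series in `$dff` and keeps the unsmoothed input in `$dff_raw`
#' (peak amplitudes are measured on the raw series).
#'
#' @param dff A `dff_trace`.
#' @param params A [detection_params].
#' @return A `dff_trace` with smoothed `$dff` and the original in `$dff_raw`.
#' @export
sg_smooth <- function(dff, params = detection_params()) {
  stopifnot(inherits(dff, "dff_trace"))
  if (params$sg_window >= length(dff$dff))
    stop("sg_window must be shorter than the trace")
  out <- dff
  out$dff_raw <- dff$dff
  out$dff <- as.numeric(signal::sgolayfilt(dff$dff, p = params$sg_order,
                                           n = params$sg_window))
  out$sg_window <- params$sg_window
  out
}

#' First derivative of a (smoothed) trace
#'
#' Central differences on the uniform frame grid, one-sided at the ends.
#'
#' @param dff A `dff_trace` (typically smoothed).
#' @return List with `t` and `deriv` (\% dF/F0 per second).
#' @export
trace_derivative <- function(dff) {
  x <- dff$dff; t <- dff$t; n <- length(x)
  if (n < 3) stop("need at least 3 frames")
  dt <- t[2] - t[1]
  d <- c(x[2] - x[1], (x[3:n] - x[1:(n - 2)]) / 2, x[n] - x[n - 1]) / dt
  list(t = t, deriv = d)
}

# noise gain of the SG smoothing filter: sqrt(sum of squared central-row
# coefficients), evaluated by filtering a unit impulse
sg_noise_gain <- function(order, window) {
  m <- 10L * window
  x <- numeric(2L * m + 1L); x[m + 1L] <- 1
  sqrt(sum(signal::sgolayfilt(x, p = order, n = window)^2))
}

#' Initial derivative threshold from the entire trace
#'
#' The threshold is `deriv_threshold_k` times the robust noise scale of the
#' derivative series, scale = median absolute deviation x 1.4826 over the
#' whole trace (filter edge frames excluded when the series came from a
#' smoothed trace).
#'
#' @param deriv Output of [trace_derivative()] (or a bare numeric vector).
#' @param params A [detection_params].
#' @param edge Number of frames to drop at each end (filter edge guard);
#'   default one smoothing window.
#' @return Threshold in \% dF/F0 per second.
#' @export
estimate_initial_threshold <- function(deriv, params = detection_params(),
                                       edge = params$sg_window) {
  d <- if (is.list(deriv)) deriv$deriv else deriv
  if (length(d) < 20) stop("need at least 20 frames to estimate a threshold")
  core <- d[max(1L, edge + 1L):max(1L, length(d) - edge)]
  sc <- mad(core)  # 1.4826 * MAD
  if (sc == 0) {
    warning("zero-variance derivative; threshold is 0")
    return(0)
  }
  params$deriv_threshold_k * sc
}

#' Find candidate events on the derivative trace
#'
#' Local maxima of the derivative exceeding `threshold`, with non-maximum
#' suppression over `min_event_separation` (larger maximum wins), each
#' bracketed by its preceding and following derivative zero crossings. The
#' preceding zero crossing is the event onset. Maxima inside the filter edge
#' guard are ignored.
#'
#' @param deriv Output of [trace_derivative()].
#' @param threshold Derivative threshold (>= 0).
#' @param min_event_separation Merge window (s).
#' @param edge Edge guard in frames.
#' @return Data frame with `i_max`, `i_onset`, `i_zc2` (frame indices) and
#'   corresponding times; zero rows when nothing crosses threshold.
#' @export
find_candidate_events <- function(deriv, threshold,
                                  min_event_separation = 0.15, edge = 11L) {
  stopifnot(threshold >= 0)
  d <- deriv$deriv; t <- deriv$t; n <- length(d)
  empty <- data.frame(i_max = integer(), i_onset = integer(),
                      i_zc2 = integer(), t_max = numeric(),
                      t_onset = numeric(), t_zc2 = numeric())
  loc <- which(d > threshold &
                 d >= c(-Inf, d[-n]) & d > c(d[-1], Inf))
  loc <- loc[loc > edge & loc <= n - edge]
  if (!length(loc)) return(empty)
  # non-maximum suppression, larger derivative wins, earlier frame on ties
  ord <- loc[order(-d[loc], loc)]
  keep <- integer(0)
  for (i in ord)
    if (!length(keep) || all(abs(t[i] - t[keep]) >= min_event_separation))
      keep <- c(keep, i)
  keep <- sort(keep)
  onset <- vapply(keep, function(i) {
    pre <- which(d[seq_len(i)] <= 0)
    if (length(pre)) max(pre) else 1L
  }, integer(1))
  zc2 <- vapply(keep, function(i) {
    post <- which(d[i:n] <= 0)
    if (length(post)) i + min(post) - 1L else n
  }, integer(1))
  data.frame(i_max = keep, i_onset = onset, i_zc2 = zc2,
             t_max = t[keep], t_onset = t[onset], t_zc2 = t[zc2])
}

# event window bookkeeping shared by the AUC threshold and characterization:
# for each candidate, a baseline level (median of up to 1 s of pre-onset
# smoothed trace, floored at the global trace median), and an end frame
# (first return of the smoothed trace to that level after the rising phase,
# capped at the next candidate's onset).
event_windows <- function(cand, sm, t, edge) {
  n <- length(sm)
  core <- sm[min(edge + 1L, n):max(1L, n - edge)]
  gmed <- median(core)
  dt <- t[2] - t[1]
  base_win <- max(1L, round(1 / dt))
  k <- nrow(cand)
  lev <- numeric(k); iend <- integer(k)
  for (j in seq_len(k)) {
    on <- cand$i_onset[j]
    nxt <- if (j < k) cand$i_onset[j + 1L] - 1L else n
    lo <- max(1L, on - base_win)
    lev[j] <- max(median(sm[lo:on]), gmed)
    from <- min(cand$i_zc2[j], nxt)
    ret <- which(sm[from:nxt] <= lev[j])
    iend[j] <- if (length(ret)) from + min(ret) - 1L else nxt
  }
  cbind(cand, data.frame(level = lev, i_end = iend, t_end = t[iend]))
}

trapz <- function(t, y) sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)

#' Apply the area-under-the-curve second threshold
#'
#' For each candidate, the AUC is the trapezoidal integral of dF/F0 above the
#' event's baseline level, from onset until the trace first returns to that
#' level (or the next event/trace end). A candidate is accepted iff
#' `AUC >= auc_threshold_k * sigma * median(duration)` where `sigma` is the
#' robust noise SD of the smoothed trace (frame-to-frame noise of the raw
#' trace times the smoothing filter's noise gain) and the median is over the
#' trace's candidates.
#'
#' @param cand Candidates from [find_candidate_events()].
#' @param dff A smoothed `dff_trace` (from [sg_smooth()]).
#' @param params A [detection_params].
#' @return The accepted candidate rows with `auc`, `level`, `i_end` columns.
#' @export
apply_auc_threshold <- function(cand, dff, params = detection_params()) {
  stopifnot(inherits(dff, "dff_trace"))
  if (!nrow(cand)) {
    cand$auc <- numeric(0); cand$level <- numeric(0)
    cand$i_end <- integer(0); cand$t_end <- numeric(0)
    return(cand)
  }
  sm <- dff$dff
  raw <- if (is.null(dff$dff_raw)) dff$dff else dff$dff_raw
  t <- dff$t
  w <- event_windows(cand, sm, t, edge = params$sg_window)
  series <- if (params$auc_on_smoothed) sm else raw
  w$auc <- vapply(seq_len(nrow(w)), function(j) {
    seg <- w$i_onset[j]:w$i_end[j]
    trapz(t[seg], series[seg] - w$level[j])
  }, numeric(1))
  sigma <- 1.4826 * median(abs(diff(raw))) / sqrt(2) *
    sg_noise_gain(params$sg_order, params$sg_window)
  dur <- w$t_end - w$t_onset
  thr <- params$auc_threshold_k * sigma * median(dur)
  w[w$auc >= thr, , drop = FALSE]
}

#' Characterize one accepted event
#'
#' Peak amplitude is measured on the unsmoothed dF/F0 as the maximum of a
#' 3-frame boxcar within the event window (this suppresses the upward bias of
#' a single-frame maximum under noise while staying within one frame's kernel
#' change of the true peak on clean data). The 90\%-decay time is the first
#' (linearly interpolated) time after the peak at which the smoothed trace
#' falls to `level + 0.1 * (peak - level)`; the decay constant is a
#' least-squares exponential fit between peak and 90\% decay.
#'
#' @param dff A smoothed `dff_trace`.
#' @param event One accepted candidate row (from [apply_auc_threshold()]).
#' @param params A [detection_params].
#' @return One-row data frame: `onset_time`, `peak_time`, `peak_dff`, `auc`,
#'   `decay90_time`, `decay_tau` (NA when unresolved), `decay_resolved`.
#' @export
characterize_event <- function(dff, event, params = detection_params()) {
  stopifnot(inherits(dff, "dff_trace"), nrow(event) == 1)
  sm <- dff$dff
  raw <- if (is.null(dff$dff_raw)) dff$dff else dff$dff_raw
  t <- dff$t; n <- length(sm)
  seg <- event$i_onset:event$i_end
  box <- vapply(seg, function(i) {
    lo <- max(1L, i - 1L); hi <- min(n, i + 1L)
    mean(raw[lo:hi])
  }, numeric(1))
  ipk <- seg[which.max(box)]
  peak <- max(box)
  lev <- event$level
  target <- lev + 0.1 * (peak - lev)
  after <- which(sm <= target & seq_len(n) > ipk)
  if (length(after)) {
    i2 <- after[1]
    d90 <- if (i2 > 1 && sm[i2 - 1] > target)
      t[i2 - 1] + (sm[i2 - 1] - target) / (sm[i2 - 1] - sm[i2]) * (t[2] - t[1])
    else t[i2]
    resolved <- TRUE
  } else {
    d90 <- NA_real_; resolved <- FALSE
  }
  # exponential decay fit (log-linear least squares) from peak to 90% decay
  fit_end <- if (resolved) min(n, which(t >= d90)[1]) else event$i_end
  fseg <- ipk:fit_end
  y <- sm[fseg] - lev
  ok <- y > 0
  tau <- NA_real_
  if (sum(ok) >= 3) {
    co <- stats::coef(lm(log(y[ok]) ~ t[fseg][ok]))
    if (is.finite(co[2]) && co[2] < 0) tau <- -1 / co[2]
  }
  data.frame(onset_time = t[event$i_onset], peak_time = t[ipk],
             peak_dff = peak, auc = event$auc, decay90_time = d90,
             decay_tau = tau, decay_resolved = resolved)
}

#' Detect calcium transients in one ROI trace
#'
#' Deterministic composition of the pipeline stages: dF/F0, smoothing,
#' derivative, initial threshold, candidate search, AUC threshold, event
#' characterization. Events are sorted by onset and numbered ordinally.
#'
#' @param trace A `roi_trace`.
#' @param params A [detection_params].
#' @return Data frame of class `calcium_events`: `roi_id`, `peak_id`,
#'   `onset_time`, `peak_time`, `peak_dff`, `auc`, `decay90_time`,
#'   `decay_tau`, `decay_resolved`, `evoking_stimulus_index` (NA =
#'   spontaneous, filled by [classify_stimulus_responses()]).
#' @export
detect_events <- function(trace, params = detection_params()) {
  dff <- compute_dff(trace, baseline = params$baseline_window)
  smd <- sg_smooth(dff, params)
  dv <- trace_derivative(smd)
  thr <- estimate_initial_threshold(dv, params)
  cand <- find_candidate_events(dv, thr, params$min_event_separation,
                                edge = params$sg_window)
  acc <- apply_auc_threshold(cand, smd, params)
  if (!nrow(acc)) {
    out <- data.frame(roi_id = character(), peak_id = integer(),
                      onset_time = numeric(), peak_time = numeric(),
                      peak_dff = numeric(), auc = numeric(),
                      decay90_time = numeric(), decay_tau = numeric(),
                      decay_resolved = logical(),
                      evoking_stimulus_index = integer())
    class(out) <- c("calcium_events", "data.frame")
    return(out)
  }
  rows <- lapply(seq_len(nrow(acc)),
                 function(j) characterize_event(smd, acc[j, , drop = FALSE],
                                                params))
  out <- do.call(rbind, rows)
  out <- out[order(out$onset_time), , drop = FALSE]
  out <- cbind(data.frame(roi_id = trace$roi_id,
                          peak_id = seq_len(nrow(out))), out)
  if (length(trace$stimulus_times)) {
    # smoothing advances the apparent onset (derivative zero crossing) by up
    # to half a filter window; compensate before assigning stimuli
    lead <- (params$sg_window - 1) / 2 / trace$frame_rate
    shifted <- out
    shifted$onset_time <- out$onset_time + lead
    cls <- classify_stimulus_responses(shifted, trace$stimulus_times,
                                       params$response_window)
    out$evoking_stimulus_index <- cls$assignment
  } else {
    out$evoking_stimulus_index <- NA_integer_
  }
  rownames(out) <- NULL
  class(out) <- c("calcium_events", "data.frame")
  out
}

#' Assign events to stimuli
#'
#' An event responds to stimulus `j` iff its onset lies in
#' `(t_j, t_j + response_window]`; with overlapping windows the nearest
#' preceding stimulus wins. Events with no stimulus in range are spontaneous
#' (`NA` assignment).
#'
#' @param events A `calcium_events` data frame (or any frame with
#'   `onset_time`).
#' @param stimulus_times Sorted stimulus times (s).
#' @param response_window Window length (s).
#' @return List: `assignment` (integer stimulus index per event, `NA` =
#'   spontaneous) and `responded` (logical per stimulus).
#' @export
classify_stimulus_responses <- function(events, stimulus_times,
                                        response_window = 0.5) {
  stopifnot(!is.unsorted(stimulus_times), response_window > 0)
  onsets <- events$onset_time
  assignment <- rep(NA_integer_, length(onsets))
  for (k in seq_along(onsets)) {
    prev <- which(stimulus_times < onsets[k] &
                    onsets[k] <= stimulus_times + response_window)
    if (length(prev)) assignment[k] <- max(prev)  # nearest preceding stimulus
  }
  responded <- vapply(seq_along(stimulus_times),
                      function(j) any(assignment == j, na.rm = TRUE),
                      logical(1))
  list(assignment = assignment, responded = responded)
}
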