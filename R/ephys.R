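# Juxtacellular AP latency measurement and summary-statistic effect sizes.

#' Summary statistics triple
#'
#' A (mean, SEM, n) container for published group summaries used by the
#' effect-size helpers.
#'
#' @param mean Group mean.
#' @param sem Standard error of the mean (>= 0).
#' @param n Optional sample size (>= 2 when given).
#' @return Object of class `summary_stats`.
#' @export
summary_stats <- function(mean, sem, n = NULL) {
  stopifnot(sem >= 0, is.null(n) || n >= 2)
  structure(list(mean = mean, sem = sem, n = n), class = "summary_stats")
}

#' Detect action-potential latency in a juxtacellular trace
#'
#' After blanking the stimulus artifact window, the AP time is the first
#' sample at which the signal crosses `threshold_k` times the robust SD
#' (MAD-based) of the pre-stimulus signal; the latency is the time from
#' stimulus to that crossing in milliseconds.
#'
#' @param trace A `voltage_trace` (list with `t`, `v`, `stimulus_time`), as
#'   produced by [generate_juxtacellular()].
#' @param artifact_blank Blanking window after the stimulus (ms). Default 1.
#' @param threshold_k Threshold multiplier of the pre-stimulus robust SD.
#'   Default 5.
#' @return List: `detected` (logical), `latency` (ms, NA if none),
#'   `ap_time` (s), `threshold` used.
#' @export
detect_ap_latency <- function(trace, artifact_blank = 1, threshold_k = 5) {
  stopifnot(artifact_blank >= 0, threshold_k > 0)
  t <- trace$t; v <- trace$v; st <- trace$stimulus_time
  if (st < t[1] || st > t[length(t)]) stop("stimulus_time outside trace")
  pre <- v[t < st]
  if (length(pre) < 5) stop("too few pre-stimulus samples")
  thr <- threshold_k * mad(pre)
  search <- which(t > st + artifact_blank / 1000)
  cross <- search[v[search] > thr]
  if (!length(cross))
    return(list(detected = FALSE, latency = NA_real_, ap_time = NA_real_,
                threshold = thr))
  ap <- t[cross[1]]
  list(detected = TRUE, latency = 1000 * (ap - st), ap_time = ap,
       threshold = thr)
}

#' Percent change between two group means
#'
#' `100 * (ref - new) / ref`: positive values are reductions relative to the
#' reference.
#'
#' @param ref,new `summary_stats` objects (or bare numbers).
#' @param rounded Round half-up to an integer (the convention used when
#'   percentages are reported alongside published values). Default `FALSE`.
#' @return Signed percent change.
#' @export
percent_change <- function(ref, new, rounded = FALSE) {
  r <- if (inherits(ref, "summary_stats")) ref$mean else ref
  x <- if (inherits(new, "summary_stats")) new$mean else new
  if (r == 0) stop("reference mean must be non-zero")
  pc <- 100 * (r - x) / r
  if (rounded) floor(pc + 0.5) else pc
}

#' Fold change between two group means
#'
#' @param base,new `summary_stats` objects (or bare numbers); `base` mean
#'   must be positive.
#' @return `new / base`.
#' @export
fold_change <- function(base, new) {
  b <- if (inherits(base, "summary_stats")) base$mean else base
  x <- if (inherits(new, "summary_stats")) new$mean else new
  if (b <= 0) stop("base mean must be positive")
  x / b
}

#' Welch t statistic from summary statistics
#'
#' `t = |mean_a - mean_b| / sqrt(sem_a^2 + sem_b^2)`; the Welch-Satterthwaite
#' degrees of freedom are reported when both sample sizes are available,
#' otherwise omitted.
#'
#' @param a,b `summary_stats` objects with positive SEMs.
#' @return List: `statistic`, `df` (NA when either n is missing).
#' @export
welch_t_from_summary <- function(a, b) {
  stopifnot(inherits(a, "summary_stats"), inherits(b, "summary_stats"))
  if (a$sem <= 0 || b$sem <= 0) stop("both SEMs must be positive")
  va <- a$sem^2; vb <- b$sem^2
  t <- abs(a$mean - b$mean) / sqrt(va + vb)
  df <- if (!is.null(a$n) && !is.null(b$n))
    (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1)) else NA_real_
  list(statistic = t, df = df)
}
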