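# Synthetic data generation: fluorescence traces with stimulus-locked calcium
# transients, population datasets across slices/conditions, and juxtacellular
# voltage traces. Every generator returns its ground truth so detection and
# population statistics can be validated end to end.

#' Acquisition configuration for synthetic recordings
#'
#' Describes one imaging recording: frame rate, duration, stimulus schedule,
#' baseline fluorescence, and noise/drift levels.
#'
#' @param frame_rate Imaging frame rate in Hz. Default 55, the swept-field
#'   confocal rate used for somatic population imaging.
#' @param n_frames Number of frames in the recording.
#' @param stimulus_times Stimulus onset times in seconds. All must fall within
#'   the recording.
#' @param baseline_f0 Baseline fluorescence in arbitrary camera units.
#' @param noise_sd Additive Gaussian noise SD, as a fraction of `baseline_f0`.
#'   Default 0.01 (1\% of F0).
#' @param drift_rate Linear bleach/drift, as a fraction of `baseline_f0` per
#'   second (negative = bleaching). Default 0.
#' @return An object of class `acquisition_config`.
#' @export
acquisition_config <- function(frame_rate = 55, n_frames = 550,
                               stimulus_times = 2, baseline_f0 = 100,
                               noise_sd = 0.01, drift_rate = 0) {
  stopifnot(frame_rate > 0, n_frames >= 2, noise_sd >= 0, baseline_f0 > 0)
  dur <- n_frames / frame_rate
  if (length(stimulus_times) &&
      (any(stimulus_times < 0) || any(stimulus_times >= dur)))
    stop("all stimulus_times must lie within [0, n_frames/frame_rate)")
  structure(list(frame_rate = frame_rate, n_frames = as.integer(n_frames),
                 stimulus_times = as.numeric(stimulus_times),
                 baseline_f0 = baseline_f0, noise_sd = noise_sd,
                 drift_rate = drift_rate),
            class = "acquisition_config")
}

#' Generative parameters for one experimental group
#'
#' Bundles the per-group quantities that drive the simulator: activation
#' probability per stimulus intensity, transient amplitude distribution
#' (log-normal, parameterized by its median), transient kinetics, and the
#' action-potential latency distribution seen in juxtacellular recordings.
#'
#' @param name Group label.
#' @param p_active Named numeric vector of activation probabilities, one per
#'   stimulus intensity label (e.g. `c("100uA" = 0.04, "400uA" = 0.21)`).
#' @param amplitude_median Median transient amplitude in \% dF/F0. Either a
#'   single value or a named vector parallel to `p_active`.
#' @param amplitude_dispersion Log-scale SD of the log-normal amplitude
#'   distribution. Default 0.4.
#' @param tau_rise,tau_decay Transient rise and decay time constants (s).
#'   Must satisfy `tau_decay > tau_rise > 0`.
#' @param latency_mean,latency_sd AP latency distribution (ms) after a
#'   stimulus; the transient onset is delayed by a latency draw.
#' @param p_active_ptx Activation probability under saturating GABA-A
#'   blockade (picrotoxin viability condition); should be >= 0.9.
#' @return An object of class `group_profile`.
#' @export
group_profile <- function(name, p_active, amplitude_median,
                          amplitude_dispersion = 0.4,
                          tau_rise = 0.02, tau_decay = 0.5,
                          latency_mean = 7.28, latency_sd = 2.0,
                          p_active_ptx = 0.95) {
  stopifnot(all(p_active >= 0 & p_active <= 1),
            p_active_ptx >= 0 && p_active_ptx <= 1,
            all(amplitude_median > 0),
            amplitude_dispersion >= 0,
            tau_rise > 0, tau_decay > tau_rise,
            latency_mean > 0, latency_sd >= 0)
  if (is.null(names(p_active)))
    names(p_active) <- paste0("stim", seq_along(p_active))
  if (length(amplitude_median) > 1 && is.null(names(amplitude_median)))
    names(amplitude_median) <- names(p_active)
  structure(list(name = name, p_active = p_active,
                 amplitude_median = amplitude_median,
                 amplitude_dispersion = amplitude_dispersion,
                 tau_rise = tau_rise, tau_decay = tau_decay,
                 latency_mean = latency_mean, latency_sd = latency_sd,
                 p_active_ptx = p_active_ptx),
            class = "group_profile")
}

#' Study group profiles
#'
#' The five experimental groups of the epileptogenesis time course (naive
#' controls and four post-status-epilepticus time points), parameterized with
#' the published proportional-activation percentages at 100/400 uA perforant
#' path stimulation, the published median transient amplitudes, and the
#' published mean AP latencies. Latency SDs are reconstructed from the printed
#' SEM and cell counts. The >6 month group, for which no latency was reported,
#' reuses the 2-3 month value.
#'
#' @return Named list of [group_profile] objects.
#' @export
dgc_group_profiles <- function() {
  list(
    control = group_profile("control",
      p_active = c("100uA" = 0.04, "400uA" = 0.21),
      amplitude_median = c("100uA" = 5.2, "400uA" = 6.6),
      latency_mean = 7.28, latency_sd = 0.50 * sqrt(16)),
    se_3_7d = group_profile("se_3_7d",
      p_active = c("100uA" = 0.57, "400uA" = 0.82),
      amplitude_median = c("100uA" = 9.8, "400uA" = 13.6),
      latency_mean = 5.82, latency_sd = 0.23 * sqrt(23)),
    se_14d = group_profile("se_14d",
      p_active = c("100uA" = 0.13, "400uA" = 0.43),
      amplitude_median = c("100uA" = 6.43, "400uA" = 10.4),
      latency_mean = 6.94, latency_sd = 0.52 * sqrt(15)),
    se_2_3mo = group_profile("se_2_3mo",
      p_active = c("100uA" = 0.54, "400uA" = 0.81),
      amplitude_median = c("100uA" = 12.33, "400uA" = 12.68),
      latency_mean = 5.65, latency_sd = 0.35 * sqrt(17)),
    se_6mo = group_profile("se_6mo",
      p_active = c("100uA" = 0.54, "400uA" = 0.91),
      amplitude_median = c("100uA" = 10.1, "400uA" = 19.7),
      latency_mean = 5.65, latency_sd = 0.35 * sqrt(17))
  )
}

#' Calcium transient kernel
#'
#' Difference-of-exponentials waveform normalized so its continuous-time
#' maximum equals `amplitude`: zero before `onset`, fast rise with time
#' constant `tau_rise`, mono-exponential decay with `tau_decay`.
#'
#' @param t Time grid (s).
#' @param amplitude Peak amplitude, \% dF/F0.
#' @param tau_rise,tau_decay Time constants (s), `tau_decay > tau_rise > 0`.
#' @param onset Event onset time (s). Default 0.
#' @return Numeric vector of \% dF/F0 values over `t`.
#' @export
transient_kernel <- function(t, amplitude, tau_rise, tau_decay, onset = 0) {
  if (!(tau_rise > 0 && tau_decay > tau_rise))
    stop("time constants must satisfy tau_decay > tau_rise > 0")
  t_peak <- log(tau_decay / tau_rise) * tau_rise * tau_decay /
    (tau_decay - tau_rise)
  h_max <- exp(-t_peak / tau_decay) - exp(-t_peak / tau_rise)
  u <- t - onset
  out <- numeric(length(t))
  pos <- u > 0
  out[pos] <- amplitude * (exp(-u[pos] / tau_decay) - exp(-u[pos] / tau_rise)) / h_max
  out
}

#' Peak time of the transient kernel
#'
#' @param tau_rise,tau_decay Time constants (s).
#' @return Time from onset to the kernel maximum (s).
#' @export
transient_peak_time <- function(tau_rise, tau_decay) {
  log(tau_decay / tau_rise) * tau_rise * tau_decay / (tau_decay - tau_rise)
}

new_roi_trace <- function(roi_id, t, f_raw, frame_rate, stimulus_times,
                          slice_id = NA_character_, condition = NA_character_) {
  structure(list(roi_id = roi_id, slice_id = slice_id, condition = condition,
                 t = t, f_raw = f_raw, frame_rate = frame_rate,
                 stimulus_times = stimulus_times),
            class = "roi_trace")
}

#' @export
print.roi_trace <- function(x, ...) {
  cat(sprintf("ROI trace '%s': %d frames at %.1f Hz, %d stimuli\n",
              x$roi_id, length(x$t), x$frame_rate, length(x$stimulus_times)))
  invisible(x)
}

#' Generate one synthetic ROI fluorescence trace
#'
#' Builds a raw fluorescence trace as
#' `F(t) = F0 * (1 + drift*t) * (1 + sum(kernels)/100) + noise`, with one
#' transient kernel per responding stimulus. Transient amplitudes are drawn
#' log-normal around the profile's median; onsets are the stimulus time plus a
#' latency draw.
#'
#' @param profile A [group_profile].
#' @param acq An [acquisition_config].
#' @param respond Logical vector, one flag per stimulus in
#'   `acq$stimulus_times`: does this cell respond to that stimulus?
#' @param intensity Stimulus intensity label used to select the amplitude
#'   median (when `profile$amplitude_median` is named). Default: first entry.
#' @param roi_id ROI label for the trace.
#' @param seed Optional integer seed for reproducibility.
#' @return List with elements `trace` (a `roi_trace`) and `ground_truth`
#'   (data frame of true onsets/amplitudes, one row per responding stimulus).
#' @export
generate_trace <- function(profile, acq, respond,
                           intensity = NULL, roi_id = "roi1", seed = NULL) {
  stopifnot(inherits(profile, "group_profile"),
            inherits(acq, "acquisition_config"))
  if (length(respond) != length(acq$stimulus_times))
    stop("`respond` must have one flag per stimulus")
  if (!is.null(seed)) set.seed(seed)
  amed <- amplitude_median_for(profile, intensity)
  t <- (seq_len(acq$n_frames) - 1L) / acq$frame_rate
  dff_true <- numeric(acq$n_frames)
  gt <- list()
  for (j in which(as.logical(respond))) {
    amp <- rlnorm(1, meanlog = log(amed), sdlog = profile$amplitude_dispersion)
    lat_s <- max(0, rnorm(1, profile$latency_mean, profile$latency_sd)) / 1000
    onset <- acq$stimulus_times[j] + lat_s
    dff_true <- dff_true +
      transient_kernel(t, amp, profile$tau_rise, profile$tau_decay, onset)
    gt[[length(gt) + 1L]] <- data.frame(
      roi_id = roi_id, true_onset = onset, true_amplitude = amp,
      evoking_stimulus_index = j, stringsAsFactors = FALSE)
  }
  f <- acq$baseline_f0 * (1 + acq$drift_rate * t) * (1 + dff_true / 100) +
    rnorm(acq$n_frames, 0, acq$noise_sd * acq$baseline_f0)
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(roi_id = character(), true_onset = numeric(),
               true_amplitude = numeric(), evoking_stimulus_index = integer(),
               stringsAsFactors = FALSE)
  list(trace = new_roi_trace(roi_id, t, f, acq$frame_rate, acq$stimulus_times),
       ground_truth = gt)
}

amplitude_median_for <- function(profile, intensity) {
  am <- profile$amplitude_median
  if (length(am) == 1L) return(unname(am))
  if (is.null(intensity)) return(unname(am[1L]))
  if (!intensity %in% names(am)) return(unname(am[1L]))
  unname(am[intensity])
}

#' Generate a synthetic multi-slice population dataset
#'
#' Simulates `n_slices` slices of `n_cells_per_slice` cells each, recorded
#' under each requested condition. A condition is either a stimulus intensity
#' label present in `profile$p_active` (cells respond Bernoulli with that
#' probability) or `"PTX"` (saturating disinhibition viability check; cells
#' respond with `profile$p_active_ptx`). Cells keep consistent ROI IDs across
#' conditions and carry a granule-cell-layer position drawn uniform on
#' [0, 100]\% (inner to outer border).
#'
#' @param profile A [group_profile].
#' @param n_slices,n_cells_per_slice Cohort dimensions.
#' @param conditions Character vector of condition labels.
#' @param acq An [acquisition_config] used when traces are synthesized.
#' @param seed Integer seed.
#' @param make_traces If `TRUE`, synthesize a fluorescence trace per cell and
#'   condition (slower); if `FALSE`, only responding flags and metadata.
#' @return An object of class `synthetic_population`: list with `cells`
#'   (metadata), `responses` (long table of true responding flags),
#'   `traces` (named list or `NULL`), `ground_truth`, `profile`, `acq`,
#'   `seed`.
#' @export
generate_population <- function(profile, n_slices, n_cells_per_slice,
                                conditions = c("100uA", "400uA", "PTX"),
                                acq = acquisition_config(), seed = 1,
                                make_traces = FALSE) {
  stopifnot(inherits(profile, "group_profile"))
  known <- c(names(profile$p_active), "PTX")
  bad <- setdiff(conditions, known)
  if (length(bad))
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  set.seed(seed)
  n_cells <- n_slices * n_cells_per_slice
  cells <- data.frame(
    slice_id = rep(sprintf("slice%02d", seq_len(n_slices)),
                   each = n_cells_per_slice),
    roi_id = sprintf("roi%04d", seq_len(n_cells)),
    position_pct = runif(n_cells, 0, 100),
    stringsAsFactors = FALSE)
  resp <- list(); traces <- if (make_traces) list() else NULL
  gt <- list()
  for (cond in conditions) {
    p <- if (cond == "PTX") profile$p_active_ptx else profile$p_active[[cond]]
    flags <- rbinom(n_cells, 1, p) == 1
    resp[[cond]] <- data.frame(
      slice_id = cells$slice_id, roi_id = cells$roi_id, condition = cond,
      responded = flags, stringsAsFactors = FALSE)
    if (make_traces) {
      for (i in seq_len(n_cells)) {
        id <- paste(cells$roi_id[i], cond, sep = ".")
        # PTX viability runs use saturating tetanic stimulation: amplitudes
        # follow the strongest intensity's median
        amp_int <- if (cond == "PTX")
          names(profile$amplitude_median)[which.max(profile$amplitude_median)]
        else cond
        one <- generate_trace(profile, acq,
                              respond = rep(flags[i], length(acq$stimulus_times)),
                              intensity = amp_int,
                              roi_id = cells$roi_id[i])
        one$trace$slice_id <- cells$slice_id[i]
        one$trace$condition <- cond
        traces[[id]] <- one$trace
        if (nrow(one$ground_truth)) {
          one$ground_truth$condition <- cond
          one$ground_truth$slice_id <- cells$slice_id[i]
          gt[[length(gt) + 1L]] <- one$ground_truth
        }
      }
    }
  }
  gt <- if (length(gt)) do.call(rbind, gt) else
    data.frame(roi_id = character(), true_onset = numeric(),
               true_amplitude = numeric(), evoking_stimulus_index = integer(),
               condition = character(), slice_id = character(),
               stringsAsFactors = FALSE)
  structure(list(cells = cells, responses = do.call(rbind, resp),
                 traces = traces, ground_truth = gt,
                 profile = profile, acq = acq, seed = seed),
            class = "synthetic_population")
}

#' @export
print.synthetic_population <- function(x, ...) {
  cat(sprintf("Synthetic population '%s': %d cells x %d condition(s)%s\n",
              x$profile$name, nrow(x$cells),
              length(unique(x$responses$condition)),
              if (is.null(x$traces)) " (flags only)" else " with traces"))
  invisible(x)
}

#' Generate synthetic juxtacellular voltage traces
#'
#' Each trace holds a stimulus artifact at `stimulus_time` and one stereotyped
#' action-potential waveform starting at `stimulus_time + latency`, with the
#' latency drawn from a normal distribution. The AP waveform is a fast
#' difference of exponentials that is exactly zero before its onset, so the
#' ground-truth latency is the first departure of the spike from baseline.
#'
#' @param latency_mean,latency_sd Latency distribution (ms); draws are
#'   truncated below at 0.1 ms.
#' @param n_traces Number of traces.
#' @param sampling_rate Hz. Default 20000 (loose-patch acquisition rate).
#' @param duration Trace duration (s). Default 0.05.
#' @param stimulus_time Stimulus (artifact) time (s). Default 0.01.
#' @param ap_amplitude AP waveform peak, arbitrary units. Default 1.
#' @param noise_sd Baseline noise SD in the same units. Default 0.02.
#' @param seed Integer seed.
#' @return List with `traces` (list of `voltage_trace` objects: `t`, `v`,
#'   `stimulus_time`, `sampling_rate`) and `latencies` (true latencies, ms).
#' @export
generate_juxtacellular <- function(latency_mean, latency_sd, n_traces,
                                   sampling_rate = 20000, duration = 0.05,
                                   stimulus_time = 0.01, ap_amplitude = 1,
                                   noise_sd = 0.02, seed = 1) {
  stopifnot(latency_mean > 0, latency_sd >= 0, n_traces >= 0)
  set.seed(seed)
  t <- seq(0, duration, by = 1 / sampling_rate)
  if (n_traces == 0)
    return(list(traces = list(), latencies = numeric(0)))
  lat <- pmax(0.1, rnorm(n_traces, latency_mean, latency_sd))
  traces <- vector("list", n_traces)
  for (i in seq_len(n_traces)) {
    v <- rnorm(length(t), 0, noise_sd)
    # biphasic stimulus artifact, 0.4 ms
    au <- t - stimulus_time
    art <- au >= 0 & au < 4e-4
    v[art] <- v[art] + 5 * ap_amplitude * sin(2 * pi * au[art] / 4e-4)
    # AP waveform: zero before onset, ~0.1 ms rise
    on <- stimulus_time + lat[i] / 1000
    u <- t - on
    tp <- transient_peak_time(1e-4, 5e-4)
    hm <- exp(-tp / 5e-4) - exp(-tp / 1e-4)
    pos <- u > 0
    v[pos] <- v[pos] + ap_amplitude * (exp(-u[pos] / 5e-4) - exp(-u[pos] / 1e-4)) / hm
    traces[[i]] <- structure(list(t = t, v = v, stimulus_time = stimulus_time,
                                  sampling_rate = sampling_rate),
                             class = "voltage_trace")
  }
  list(traces = traces, latencies = lat)
}
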