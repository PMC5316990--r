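params_def <- detection_params()

test_that("dF/F0 conversion is exact on constructed traces", {
  t <- (0:299) / 55
  tr <- sparsegate:::new_roi_trace("r", t, rep(100, 300), 55, numeric(0))
  expect_equal(compute_dff(tr)$dff, rep(0, 300))
  f <- rep(100, 300); f[150] <- 110
  tr2 <- sparsegate:::new_roi_trace("r", t, f, 55, numeric(0))
  d2 <- compute_dff(tr2, baseline = c(0, 1))
  expect_equal(d2$dff[150], 10)
  expect_equal(d2$f0, 100)
  # generator round trip at 5.2% amplitude, zero noise
  g <- clean_transient_trace(amplitude = 5.2)
  expect_equal(max(compute_dff(g)$dff), 5.2, tolerance = 0.01)
})

test_that("dF/F0 conversion validates its baseline", {
  t <- (0:99) / 55
  tr <- sparsegate:::new_roi_trace("r", t, rep(0, 100), 55, numeric(0))
  expect_error(compute_dff(tr), "non-positive")
  tr2 <- sparsegate:::new_roi_trace("r", t, rep(100, 100), 55, 0.5)
  expect_warning(compute_dff(tr2, baseline = c(0, 1)), "overlaps a stimulus")
  expect_error(compute_dff(tr2, baseline = c(0, 0.05)), "at least 5 frames")
})

test_that("smoothing reproduces low-order polynomials and reduces noise", {
  t <- (0:299) / 55
  mk <- function(y) {
    tr <- sparsegate:::new_roi_trace("r", t, 100 + y, 55, numeric(0))
    compute_dff(tr, baseline = c(0, 1))
  }
  ramp <- mk(seq(0, 10, length.out = 300))
  sm <- sg_smooth(ramp, params_def)
  interior <- 20:280
  expect_equal(sm$dff[interior], ramp$dff[interior], tolerance = 1e-8)
  const <- mk(rep(5, 300))
  expect_equal(sg_smooth(const, params_def)$dff[interior],
               const$dff[interior], tolerance = 1e-8)
  set.seed(1)
  noisy <- mk(rnorm(300))
  expect_lt(var(sg_smooth(noisy, params_def)$dff[interior]),
            var(noisy$dff[interior]))
  expect_error(sg_smooth(mk(rep(1, 300)),
                         detection_params(sg_window = 301)),
               "shorter than the trace")
})

test_that("derivative is exact for constants/ramps and accurate for sines", {
  t <- (0:499) / 55
  mk <- function(y) list(t = t, dff = y)
  d0 <- trace_derivative(structure(mk(rep(3, 500)), class = "dff_trace"))
  expect_equal(d0$deriv, rep(0, 500))
  d1 <- trace_derivative(structure(mk(2 * t), class = "dff_trace"))
  expect_equal(d1$deriv, rep(2, 500), tolerance = 1e-9)
  w <- 2 * pi * 1.5  # 1.5 Hz
  ds <- trace_derivative(structure(mk(sin(w * t)), class = "dff_trace"))
  expect_equal(max(ds$deriv[10:490]), w, tolerance = 0.02 * w)
})

test_that("initial threshold is a consistent robust scale estimate", {
  expect_warning(thr0 <- estimate_initial_threshold(rep(0, 100)),
                 "zero-variance")
  expect_equal(thr0, 0)
  set.seed(4)
  d <- rnorm(20000, 0, 2)
  thr <- estimate_initial_threshold(d, detection_params())
  expect_equal(thr, 3 * 2, tolerance = 0.05)
  # robustness: a single transient of the control-study scale (5.2% dF/F0)
  # moves the MAD-based threshold by <10%; for a larger (chronic-scale)
  # transient the MAD scale still inflates less than a plain SD would
  set.seed(5)
  noise <- rnorm(550)
  mkdv <- function(amp) {
    tr <- clean_transient_trace(amplitude = amp)
    tr$f_raw <- tr$f_raw + noise
    sm <- sg_smooth(compute_dff(tr, baseline = c(0, 1)), params_def)
    trace_derivative(sm)$deriv[12:538]
  }
  dv_cl <- mkdv(0)
  rel <- function(f, dv) abs(f(dv) - f(dv_cl)) / f(dv_cl)
  expect_lt(rel(mad, mkdv(5.2)), 0.10)
  dv_big <- mkdv(12)
  expect_gt(rel(sd, dv_big), rel(mad, dv_big))
})

test_that("candidate search finds clean transients with accurate onsets", {
  # flat trace: no candidates
  t <- (0:549) / 55
  flat <- structure(list(t = t, dff = rep(0, 550)), class = "dff_trace")
  dv <- trace_derivative(flat)
  expect_equal(nrow(find_candidate_events(dv, 0)), 0L)
  # one noise-free transient: exactly one candidate; onset within the
  # smoothing advance (half a filter window) plus one frame of truth
  tr <- clean_transient_trace(amplitude = 8, onset = 3)
  sm <- sg_smooth(compute_dff(tr, baseline = c(0, 1)), params_def)
  dv <- trace_derivative(sm)
  thr <- estimate_initial_threshold(dv, params_def)
  cand <- find_candidate_events(dv, thr)
  expect_equal(nrow(cand), 1L)
  lead <- (params_def$sg_window - 1) / 2 / 55
  expect_lt(abs(cand$t_onset + lead - 3), lead + 1 / 55)
  # three transients at ~1 Hz are resolved as three candidates
  t3 <- clean_transient_trace(amplitude = 8, onset = 2)
  k2 <- transient_kernel(t3$t, 8, 0.02, 0.5, onset = 3)
  k3 <- transient_kernel(t3$t, 8, 0.02, 0.5, onset = 4)
  t3$f_raw <- t3$f_raw + 100 * (k2 + k3) / 100
  sm3 <- sg_smooth(compute_dff(t3, baseline = c(0, 1)), params_def)
  dv3 <- trace_derivative(sm3)
  cand3 <- find_candidate_events(dv3, estimate_initial_threshold(dv3, params_def))
  expect_equal(nrow(cand3), 3L)
})

test_that("AUC threshold accepts clean transients and is monotone in k", {
  tr <- clean_transient_trace(amplitude = 6, onset = 2)
  sm <- sg_smooth(compute_dff(tr, baseline = c(0, 1)), params_def)
  dv <- trace_derivative(sm)
  cand <- find_candidate_events(dv, estimate_initial_threshold(dv, params_def))
  acc <- apply_auc_threshold(cand, sm, params_def)
  expect_equal(nrow(acc), 1L)
  expect_gt(acc$auc, 0)
  # monotonicity over seeded noisy traces
  set.seed(8)
  for (r in 1:5) {
    trn <- clean_transient_trace(amplitude = 6, onset = 2)
    trn$f_raw <- trn$f_raw + rnorm(550)
    counts <- vapply(c(0.5, 2, 5, 20), function(k) {
      p <- detection_params(auc_threshold_k = k)
      smn <- sg_smooth(compute_dff(trn, baseline = c(0, 1)), p)
      dvn <- trace_derivative(smn)
      cd <- find_candidate_events(dvn, estimate_initial_threshold(dvn, p))
      nrow(apply_auc_threshold(cd, smn, p))
    }, numeric(1))
    expect_true(all(diff(counts) <= 0))
  }
})

test_that("event characterization recovers decay analytics and amplitude", {
  # near-instantaneous rise, tau_decay = 0.5 s: decay90 - peak = tau ln(10)
  tr <- clean_transient_trace(amplitude = 10, tau_rise = 1e-3, onset = 2)
  ev <- detect_events(tr)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$decay_resolved)
  expect_equal(ev$decay90_time - ev$peak_time, 0.5 * log(10),
               tolerance = (1 / 55) / (0.5 * log(10)))
  expect_equal(ev$decay_tau, 0.5, tolerance = 0.05)
  # 5.2% noise-free fixture: peak within one frame's kernel change
  tr2 <- clean_transient_trace(amplitude = 5.2)
  ev2 <- detect_events(tr2)
  expect_equal(ev2$peak_dff, 5.2, tolerance = 0.025)
  # event AUC equals the analytic kernel integral A*(tau_d - tau_r)/h_max
  tp <- transient_peak_time(0.02, 0.5)
  h_max <- exp(-tp / 0.5) - exp(-tp / 0.02)
  expect_equal(ev2$auc, 5.2 * (0.5 - 0.02) / h_max, tolerance = 0.02)
})

test_that("detection is deterministic and monotone in its thresholds", {
  set.seed(12)
  tr <- clean_transient_trace(amplitude = 7, onset = 2)
  tr$f_raw <- tr$f_raw + rnorm(550)
  a <- detect_events(tr); b <- detect_events(tr)
  expect_identical(a, b)
  counts <- vapply(c(1, 3, 8), function(k)
    nrow(detect_events(tr, detection_params(deriv_threshold_k = k))),
    numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("stimulus assignment matches the brute-force interval check", {
  ev <- data.frame(onset_time = c(0.5, 2.03, 2.4, 3.6, 9))
  stim <- c(2, 3.5, 8.9)
  out <- classify_stimulus_responses(ev, stim, response_window = 0.5)
  expect_identical(out$assignment, assign_brute(ev$onset_time, stim, 0.5))
  expect_identical(out$responded, c(TRUE, TRUE, TRUE))
  # onset 30 ms after a stimulus responds; onset before the first is
  # spontaneous
  one <- classify_stimulus_responses(data.frame(onset_time = 2.03), 2, 0.5)
  expect_identical(one$assignment, 1L)
  pre <- classify_stimulus_responses(data.frame(onset_time = 1.0), 2, 0.5)
  expect_true(is.na(pre$assignment))
  # randomized sets against the oracle; overlapping windows allowed
  set.seed(21)
  for (r in 1:20) {
    stim <- sort(runif(5, 0, 10))
    on <- runif(8, 0, 11)
    got <- classify_stimulus_responses(data.frame(onset_time = on), stim, 0.8)
    expect_identical(got$assignment, assign_brute(on, stim, 0.8))
  }
})

test_that("flat noisy traces are almost never called as events", {
  set.seed(33)
  t <- (0:549) / 55
  fp <- 0
  for (r in 1:200) {
    tr <- sparsegate:::new_roi_trace("r", t, 100 + rnorm(550), 55, numeric(0))
    if (nrow(detect_events(tr)) > 0) fp <- fp + 1
  }
  expect_lte(fp / 200, 0.01)
})
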