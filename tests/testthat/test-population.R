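# helper: build long-format cell records from per-cell response maps
records_from <- function(resp) {
  # resp: named list cell -> named logical vector of conditions
  do.call(rbind, lapply(names(resp), function(id)
    data.frame(slice_id = "s1", roi_id = id,
               condition = names(resp[[id]]),
               responded = unname(resp[[id]]),
               stringsAsFactors = FALSE)))
}

test_that("viability filter removes only cells inactive everywhere", {
  cells <- records_from(list(
    dead  = c(ACSF = FALSE, PTX = FALSE),
    saved = c(ACSF = FALSE, PTX = TRUE),
    live  = c(ACSF = TRUE, PTX = TRUE),
    odd   = c(ACSF = TRUE, PTX = FALSE)))
  vf <- viability_filter(cells)
  kept <- unique(vf$cells$roi_id)
  expect_setequal(kept, c("saved", "live", "odd"))
  expect_equal(unique(vf$excluded$roi_id), "dead")
  expect_equal(vf$report$n_excluded, 1)
  # a missing viability condition is a data error
  expect_error(viability_filter(cells[cells$condition != "PTX", ]),
               "condition entry")
})

test_that("viability filter matches brute-force rule evaluation and never
           removes a responder", {
  set.seed(14)
  for (r in 1:10) {
    n <- 30
    cells <- data.frame(
      slice_id = sample(c("s1", "s2"), 3 * n, replace = TRUE)[1:(3 * n)],
      roi_id = rep(sprintf("c%02d", 1:n), each = 3),
      condition = rep(c("100uA", "400uA", "PTX"), n),
      responded = runif(3 * n) < 0.3, stringsAsFactors = FALSE)
    cells$slice_id <- rep(sample(c("s1", "s2"), n, replace = TRUE), each = 3)
    vf <- viability_filter(cells)
    # oracle: a cell stays iff it responded in any condition
    keep_oracle <- vapply(split(cells$responded,
                                paste(cells$slice_id, cells$roi_id)), any,
                          logical(1))
    kept <- unique(paste(vf$cells$slice_id, vf$cells$roi_id))
    expect_setequal(kept, names(keep_oracle)[keep_oracle])
    expect_true(all(vf$cells$roi_id[vf$cells$responded] %in% vf$cells$roi_id))
    expect_false(any(tapply(vf$excluded$responded,
                            vf$excluded$roi_id, any)))
  }
})

test_that("slice exclusion applies the 70% inactive boundary strictly", {
  mk <- function(n_inactive, n) data.frame(
    slice_id = "s", roi_id = sprintf("c%03d", 1:n), condition = "PTX",
    responded = rep(c(FALSE, TRUE), c(n_inactive, n - n_inactive)))
  expect_true(slice_exclusion(mk(7, 10))$excluded)    # 70% -> excluded
  expect_false(slice_exclusion(mk(0, 10))$excluded)   # fully active
  expect_false(slice_exclusion(mk(69, 100))$excluded) # 69% -> retained
  expect_true(slice_exclusion(mk(70, 100))$excluded)
})

test_that("proportional activation counts responders over viable cells", {
  cells <- data.frame(slice_id = "s1", roi_id = sprintf("c%03d", 1:100),
                      condition = "100uA",
                      responded = rep(c(TRUE, FALSE), c(13, 87)))
  expect_equal(proportional_activation(cells, "100uA")$pct_active, 13)
  cells$responded <- TRUE
  expect_equal(proportional_activation(cells, "100uA")$pct_active, 100)
  # invariant to row order and to adding rows for another (excluded) slice
  set.seed(3)
  shuffled <- cells[sample(nrow(cells)), ]
  expect_equal(proportional_activation(shuffled, "100uA")$pct_active, 100)
})

test_that("slice activation recovers the generator probability", {
  # 82%: the 3-7 d post-insult group's strong-stimulus activation
  prof <- group_profile("g", c("400uA" = 0.82), amplitude_median = 13.6)
  pop <- generate_population(prof, 6, 60, conditions = c("400uA", "PTX"),
                             seed = 2)
  vf <- viability_filter(pop$responses)
  act <- proportional_activation(vf$cells, "400uA")
  band <- 100 * qbinom(c(0.005, 0.995), 360, 0.82) / 360
  m <- mean(act$pct_active)
  expect_gte(m, band[1]); expect_lte(m, band[2])
})

test_that("amplitude summaries report median, IQR and a proper ECDF", {
  s <- amplitude_summary(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$iqr, c(1.5, 2.5))
  expect_equal(s$ecdf$fraction[nrow(s$ecdf)], 1)
  expect_equal(s$ecdf$value, c(1, 2, 3))
  expect_error(amplitude_summary(numeric(0)), "no amplitudes")
  # round trip: detected amplitudes of a synthetic group match the
  # generator's median within 10%. Dispersion is kept tight so every draw
  # stays above the detector's sensitivity floor (~4% dF/F0 at 1% noise);
  # censoring of smaller events is a documented detection limit, not a
  # measurement bias.
  set.seed(31)
  acq <- acquisition_config(n_frames = 275, stimulus_times = 2)
  prof <- group_profile("g", c("100uA" = 1), amplitude_median = 5.2,
                        amplitude_dispersion = 0.1)
  amps <- replicate(60, {
    g <- generate_trace(prof, acq, respond = TRUE, intensity = "100uA")
    ev <- detect_events(g$trace)
    if (nrow(ev)) max(ev$peak_dff) else NA_real_
  })
  expect_equal(amplitude_summary(amps[!is.na(amps)])$median, 5.2,
               tolerance = 0.10)
})

test_that("position-distribution comparison equals the brute-force KS gap", {
  expect_equal(compare_position_distributions(c(1, 5, 9), c(1, 5, 9))$statistic, 0)
  expect_equal(compare_position_distributions(c(1, 2, 3), c(50, 60, 70))$statistic, 1)
  set.seed(9)
  for (r in 1:10) {
    a <- runif(8, 0, 100); b <- runif(13, 0, 100)
    expect_equal(compare_position_distributions(a, b)$statistic,
                 ks_d_brute(a, b))
  }
})

test_that("inner/outer contingency counts and tests are correct", {
  io <- inner_outer_contingency(c(10, 20), c(80, 90))
  expect_equal(unname(io$table), rbind(c(2, 0), c(0, 2)))
  sym <- inner_outer_contingency(c(10, 80), c(20, 90))
  expect_equal(sym$test$p.value, 1)
  expect_error(inner_outer_contingency(numeric(0), c(1)), "non-empty")
  # published newborn-cell counts as direct table input
  tab <- rbind(c(33, 1), c(327, 46))
  p <- fisher_exact(tab)$p.value
  expect_equal(p, fisher_enum(tab), tolerance = 1e-10)
})
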