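# Independent brute-force oracles used across the suite.

# two-sided Fisher exact p by exhaustive enumeration over all tables with
# the observed margins
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  a_range <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(a_range, function(a) dhyper(a, r1, r2, c1), numeric(1))
  p_obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Kruskal-Wallis H with tie correction from first principles
kw_brute <- function(values, groups) {
  groups <- factor(groups)
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(x) length(x) * mean(x)^2)) - 3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

# one-way ANOVA F from sums of squares
anova_brute <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  ssb <- sum(tapply(values, groups, function(x) length(x) * (mean(x) - gm)^2))
  ssw <- sum(unlist(tapply(values, groups, function(x) (x - mean(x))^2)))
  k <- nlevels(groups); n <- length(values)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Brown-Forsythe F = ANOVA on |x - group median|
bf_brute <- function(values, groups) {
  z <- unlist(tapply(values, factor(groups),
                     function(x) abs(x - median(x))))
  g <- unlist(tapply(groups, factor(groups), identity))
  anova_brute(z, g)
}

# two-sample KS D by direct ECDF comparison
ks_d_brute <- function(a, b) {
  grid <- sort(unique(c(a, b)))
  max(abs(ecdf(a)(grid) - ecdf(b)(grid)))
}

# interval-check oracle for stimulus assignment
assign_brute <- function(onsets, stim, w) {
  vapply(onsets, function(o) {
    j <- which(stim < o & o <= stim + w)
    if (length(j)) max(j) else NA_integer_
  }, integer(1))
}

# single noise-free transient trace at 55 Hz
clean_transient_trace <- function(amplitude = 5.2, tau_rise = 0.02,
                                  tau_decay = 0.5, onset = 2,
                                  n_frames = 550, f0 = 100,
                                  stimulus_times = numeric(0)) {
  t <- (seq_len(n_frames) - 1) / 55
  dff <- transient_kernel(t, amplitude, tau_rise, tau_decay, onset)
  sparsegate:::new_roi_trace("roi1", t, f0 * (1 + dff / 100), 55,
                             stimulus_times)
}
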