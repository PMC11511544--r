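# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: explicit loops and determinant expansions only.

# direct convolution with edge-inclusive reflection padding
conv_loop_oracle <- function(x, w) {
  h <- (length(w) - 1L) %/% 2L
  n <- length(x)
  idx <- function(j) {
    if (j < 1L) 1L - j else if (j > n) 2L * n + 1L - j else j
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in -h:h) acc <- acc + w[k + h + 1L] * x[idx(i + k)]
    out[i] <- acc
  }
  out
}

# cross product by cofactor expansion of the symbolic determinant
cross_det_oracle <- function(a, b) {
  c(det(matrix(c(a[2], a[3], b[2], b[3]), 2, byrow = TRUE)),
    -det(matrix(c(a[1], a[3], b[1], b[3]), 2, byrow = TRUE)),
    det(matrix(c(a[1], a[2], b[1], b[2]), 2, byrow = TRUE)))
}

# block means of a window sliding over x, no padding
block_mean_oracle <- function(x, w) {
  vapply(seq_len(length(x) - w + 1L),
         function(j) sum(x[j:(j + w - 1L)]) / w, numeric(1))
}

# best alignment offset between a filtered table column and block means of
# the raw column; returns the offset with smallest max abs deviation
best_offset <- function(raw, filtered, w = 5L, offsets = 0:5) {
  block <- block_mean_oracle(raw, w)
  dev <- vapply(offsets, function(o) {
    n <- min(length(filtered), length(block) - o)
    if (n < 1L) return(Inf)
    max(abs(filtered[seq_len(n)] - block[seq_len(n) + o]))
  }, numeric(1))
  list(offset = offsets[which.min(dev)], max_dev = min(dev), all = dev)
}

session_channels <- c("hr_bpm", "spo2_pct", "ambient_c", "body_c", "speed_cm_s")

# quick constant-channel session for degenerate-input tests
constant_session <- function(n = 10, hr = 80, speed = 10,
                             phase = "resting", period = 1) {
  vital_session(
    tibble::tibble(hr_bpm = rep(hr, n), spo2_pct = 97, ambient_c = 32,
                   body_c = 36, speed_cm_s = speed, alert = 0),
    phase = phase, sample_period_s = period)
}

# episode tibble shorthand
ep <- function(start, end) {
  tibble::tibble(start_index = start, end_index = end,
                 n_samples = end - start + 1L, peak_hr_bpm = NA_real_)
}

# spike-heavy near-threshold running profile used for the false-alarm
# ordering property: baseline just under the 150 BPM threshold, frequent
# single-sample multiplicative spikes that cross it
spike_heavy_params <- function() {
  phase_params("running", hr_base_bpm = 143, hr_ramp_bpm_per_s = 0, hr_sd = 3,
               spike_rate_per_min = 2, spike_gain = 1.15)
}
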