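# Shared builders and independent oracles for the test suite.

# Straight-line track with a given per-second speed profile sampled at
# `frame_rate`; moves along x only so step lengths equal speed * dt.
line_track <- function(speeds_per_frame, frame_rate = 1, well_id = "w1") {
  dt <- 1 / frame_rate
  x <- c(0, cumsum(speeds_per_frame * dt))
  tibble::tibble(
    well_id = well_id,
    time_s = (seq_along(x) - 1) * dt,
    x_mm = x,
    y_mm = 0
  )
}

# Track with constant speed for a duration (seconds).
constant_track <- function(speed, duration_s, frame_rate = 1, well_id = "w1") {
  line_track(rep(speed, duration_s * frame_rate), frame_rate, well_id)
}

# Brute-force Benjamini-Hochberg step-up: sort, p * m / rank, cummin from
# the largest, restore order.
bh_brute <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(1, q_sorted)
  q
}

# Textbook one-way ANOVA F from explicit sums of squares.
anova_f_brute <- function(y, g) {
  g <- factor(g)
  grand <- mean(y)
  ssb <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
  ssw <- sum(unlist(tapply(y, g, function(v) (v - mean(v))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(y) - nlevels(g)
  (ssb / df1) / (ssw / df2)
}

# Welch t statistic from the definition.
welch_t_brute <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# Expected distance in a bin for the truncated-Gaussian speed model:
# E[max(0, mu + sigma Z)] summed over frames times dt.
expected_bin_distance <- function(mu_frames, sigma, dt) {
  if (sigma == 0) {
    return(sum(pmax(0, mu_frames)) * dt)
  }
  z <- mu_frames / sigma
  sum(mu_frames * pnorm(z) + sigma * dnorm(z)) * dt
}

# Imaging protocol used across the calcium tests.
imaging_schedule <- function() photokin::make_schedule(60, 30, 3, "on")

# Planted five-cluster trace spec with amplitude/noise ratio >= 5.
five_cluster_spec <- function(noise_sd = 0.1) {
  photokin::trace_cluster_spec(
    cluster_id = 1:5,
    n_neurons = c(12, 10, 10, 8, 8),
    preferred_state = c("on", "on", "off", "off", "none"),
    response_amplitude = c(1.5, 0.6, 1.5, 0.6, 0),
    kernel_tau = 1.8,
    noise_sd = noise_sd
  )
}
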