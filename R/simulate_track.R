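#' Simulate a single-larva locomotor track under a light schedule
#'
#' Generates per-frame speeds from the population speed model (baseline +
#' state-dependent sustained elevation + exponentially decaying transient at
#' each epoch entry + Gaussian noise, floored at zero) and integrates them
#' as a correlated random walk inside a circular well. Every per-frame
#' displacement has length `speed * dt` exactly, so binned distance moved
#' reproduces the speed model without boundary artifacts.
#'
#' @param params A [population_params()] object or a single row from
#'   [simulate_cross()].
#' @param schedule A [make_schedule()] light schedule.
#' @param frame_rate Sampling rate, Hz (the behavioral assay records at
#'   25 fps).
#' @param well_radius Well radius, mm (96-well plate wells are ~3.4 mm).
#' @param turn_sd Per-frame heading change SD, radians.
#' @param well_id Identifier carried into the output.
#' @param seed Optional integer seed; identical seeds give identical tracks.
#' @return Tibble with columns `well_id`, `time_s`, `x_mm`, `y_mm` and
#'   attributes `frame_rate` and `well_radius`. The track has
#'   `duration * frame_rate + 1` samples covering `[0, duration]`.
#' @export
#' @examples
#' sched <- make_schedule(0, 30, 1)
#' tr <- simulate_track(surface_params(noise_sd = 0), sched,
#'                      frame_rate = 5, seed = 1)
simulate_track <- function(params, schedule, frame_rate = 25,
                           well_radius = 3.4, turn_sd = 0.6,
                           well_id = NULL, seed = NULL) {
  validate_schedule(schedule)
  check_that(nrow(schedule) >= 1, "schedule must be non-empty")
  check_that(frame_rate > 0, "`frame_rate` must be > 0")
  if (inherits(params, "population_params")) params <- as_param_row(params)
  check_that(is.data.frame(params) && nrow(params) == 1,
             "`params` must be population_params or a one-row parameter table")
  use_seed(seed)

  dt <- 1 / frame_rate
  duration <- schedule_duration(schedule)
  n_steps <- as.integer(round(duration * frame_rate))
  t_step <- (seq_len(n_steps) - 1) * dt # time at the start of each step

  mu <- expected_speed(params, schedule, t_step)
  speed <- mu
  if (params$noise_sd > 0) speed <- speed + rnorm(n_steps, 0, params$noise_sd)
  speed <- pmax(0, speed)

  start_r <- sqrt(runif(1)) * well_radius * 0.9
  start_a <- runif(1) * 2 * pi
  pos <- track_walk(speed * dt, well_radius, turn_sd,
                    start_r * cos(start_a), start_r * sin(start_a))

  out <- tibble(
    well_id = well_id %||% params$label %||% "well",
    time_s = c(t_step, duration),
    x_mm = pos[, 1],
    y_mm = pos[, 2]
  )
  attr(out, "frame_rate") <- frame_rate
  attr(out, "well_radius") <- well_radius
  out
}

# Deterministic (noise-free) expected speed of the latent model at times t.
# Vectorized over t; used both by the generator and as the closed form the
# tests integrate against.
expected_speed <- function(params, schedule, t) {
  idx <- pmin(findInterval(t, schedule$start_s), nrow(schedule))
  state <- schedule$state[idx]
  t_entry <- schedule$start_s[idx]
  on <- state == "on"
  sus <- ifelse(on, params$sustained_on, params$sustained_off)
  tr <- ifelse(on, params$transient_on, params$transient_off)
  tau <- ifelse(on, params$tau_on, params$tau_off)
  params$baseline_speed + sus + tr * exp(-(t - t_entry) / tau)
}

#' Simulate a cohort of tracks
#'
#' Convenience wrapper that simulates one track per row of a per-fish
#' parameter table (from [simulate_cross()]) or `n` tracks from one
#' [population_params()]. Per-fish seeds are derived from `seed` and the
#' well id, so cohorts are reproducible and order-independent.
#'
#' @param params A `population_params` or a per-fish parameter tibble.
#' @param schedule Light schedule shared by the cohort.
#' @param n Number of fish (ignored when `params` is a table).
#' @param seed Top-level seed for the cohort.
#' @param ... Passed to [simulate_track()].
#' @return One long tibble of tracks (columns `well_id`, `time_s`, `x_mm`,
#'   `y_mm`) with `frame_rate` kept as an attribute.
#' @export
simulate_cohort <- function(params, schedule, n = NULL, seed = 1, ...) {
  if (inherits(params, "population_params")) {
    check_that(!is.null(n) && n >= 1, "`n` is required with population_params")
    label <- params$label
    params <- as_param_row(params)[rep(1, n), ]
    params$fish_id <- sprintf("%s_%03d", label, seq_len(n))
  }
  check_that(is.data.frame(params) && nrow(params) >= 1,
             "`params` must yield at least one fish")
  ids <- params$fish_id %||% sprintf("well_%03d", seq_len(nrow(params)))
  tracks <- purrr::map(seq_len(nrow(params)), function(i) {
    simulate_track(params[i, ], schedule,
                   well_id = ids[i],
                   seed = derive_seed(seed, ids[i]), ...)
  })
  out <- bind_rows(tracks)
  attr(out, "frame_rate") <- attr(tracks[[1]], "frame_rate")
  attr(out, "well_radius") <- attr(tracks[[1]], "well_radius")
  out
}
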