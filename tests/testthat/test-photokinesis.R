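test_that("binning sums steps into half-open 30-s bins", {
  tr <- constant_track(1, 60, frame_rate = 1)
  b <- bin_activity(tr, bin_s = 30, jitter_mm = 0)
  expect_equal(b$distance_mm, c(30, 30))
  expect_equal(b$bin_start_s, c(0, 30))

  stationary <- tibble::tibble(well_id = "w", time_s = 0:90, x_mm = 2, y_mm = 2)
  expect_equal(bin_activity(stationary)$distance_mm, c(0, 0, 0))
})

test_that("piecewise speeds match brute-force step summation", {
  speeds <- c(rep(2, 30), rep(0.5, 30))
  tr <- line_track(speeds, frame_rate = 1)
  b <- bin_activity(tr, bin_s = 30, jitter_mm = 0)
  # independent oracle: sum the raw steps per bin directly
  steps <- sqrt(diff(tr$x_mm)^2 + diff(tr$y_mm)^2)
  oracle <- c(sum(steps[1:30]), sum(steps[31:60]))
  expect_equal(b$distance_mm, oracle)
  expect_equal(b$distance_mm, c(60, 15))
})

test_that("jitter suppression zeroes sub-threshold steps", {
  speeds <- c(rep(0.05, 30), rep(1, 30)) # first bin below the 0.1 mm threshold
  tr <- line_track(speeds, frame_rate = 1)
  b <- bin_activity(tr, bin_s = 30, jitter_mm = 0.1)
  expect_equal(b$distance_mm, c(0, 30))
})

test_that("trailing partial bins are dropped and bad tracks error", {
  tr <- constant_track(1, 70, frame_rate = 1)
  expect_equal(nrow(bin_activity(tr, bin_s = 30, jitter_mm = 0)), 2)

  expect_error(bin_activity(tibble::tibble(time_s = 0, x_mm = 0, y_mm = 0)),
               "at least 2")
  bad <- tibble::tibble(time_s = c(0, 2, 1), x_mm = 0:2, y_mm = 0)
  expect_error(bin_activity(bad), "increasing")
  uneven <- tibble::tibble(time_s = c(0, 1, 3, 4), x_mm = 0:3, y_mm = 0)
  expect_error(bin_activity(uneven), "constant frame spacing")
})

test_that("single-transition delta equals the post-pre difference", {
  sched <- make_schedule(0, 60, 1, "on")
  binned <- tibble::tibble(well_id = "w1", bin_start_s = c(0, 30, 60, 90),
                           distance_mm = c(10, 10, 20, 20))
  attr(binned, "bin_s") <- 30
  d <- extract_transition_deltas(binned, sched)
  expect_equal(d$delta_on_off, 10)
  expect_equal(d$n_on_off, 1)
  # no off->on transition in a single cycle ending dark
  expect_false(d$valid)
  expect_match(d$reason, "missing transitions")
})

test_that("deltas average across transitions of the same type", {
  sched <- make_schedule(0, 60, 2, "on")
  # on->off transitions at 60 s and 180 s with planted deltas 8 and 12
  binned <- tibble::tibble(
    well_id = "w1",
    bin_start_s = seq(0, 210, by = 30),
    distance_mm = c(0, 0, 8, 8, 8, 8, 20, 20)
  )
  attr(binned, "bin_s") <- 30
  d <- extract_transition_deltas(binned, sched)
  expect_equal(d$delta_on_off, 10) # mean of 8 and 12
  expect_equal(d$delta_off_on, 0)
  expect_equal(d$n_on_off, 2)
  expect_true(d$valid)

  flat <- dplyr::mutate(binned, distance_mm = 5)
  attr(flat, "bin_s") <- 30
  df <- extract_transition_deltas(flat, sched)
  expect_equal(df$delta_on_off, 0)
  expect_equal(df$delta_off_on, 0)
})

test_that("acclimation boundary is excluded by default", {
  sched <- make_schedule(60, 60, 1, "on")
  binned <- tibble::tibble(well_id = "w1", bin_start_s = seq(0, 150, 30),
                           distance_mm = c(1, 1, 9, 9, 3, 3))
  attr(binned, "bin_s") <- 30
  d_skip <- extract_transition_deltas(binned, sched, skip_acclimation = TRUE)
  expect_equal(d_skip$n_off_on, 0)
  expect_false(d_skip$valid)
  d_all <- extract_transition_deltas(binned, sched, skip_acclimation = FALSE)
  expect_equal(d_all$n_off_on, 1)
  expect_equal(d_all$delta_off_on, 8)
  expect_equal(d_all$delta_on_off, -6)
})

test_that("misaligned transitions are rejected", {
  sched <- make_schedule(0, 45, 1, "on")
  binned <- tibble::tibble(well_id = "w1", bin_start_s = seq(0, 60, 30),
                           distance_mm = 1)
  attr(binned, "bin_s") <- 30
  expect_error(extract_transition_deltas(binned, sched), "align")
})

test_that("photokinesis index follows the printed formula", {
  d <- tibble::tibble(well_id = c("a", "b", "c"),
                      delta_on_off = c(5, 2, 1),
                      delta_off_on = c(0, 2, 3))
  rec <- photokinesis_index(d)
  expect_equal(rec$pi, c(1, 0, -0.5))
  expect_true(all(rec$valid))
})

test_that("PI is antisymmetric, scale invariant and bounded", {
  set.seed(401)
  n <- 500
  d1 <- runif(n, 0, 10)
  d2 <- runif(n, 0, 10)
  base <- photokinesis_index(tibble::tibble(delta_on_off = d1,
                                            delta_off_on = d2))
  swapped <- photokinesis_index(tibble::tibble(delta_on_off = d2,
                                               delta_off_on = d1))
  ok <- base$valid & swapped$valid
  expect_gt(sum(ok), 450)
  expect_equal(base$pi[ok], -swapped$pi[ok])

  for (c_scale in c(0.01, 3, 1000)) {
    scaled <- photokinesis_index(tibble::tibble(delta_on_off = c_scale * d1,
                                                delta_off_on = c_scale * d2))
    expect_equal(scaled$pi[ok & scaled$valid], base$pi[ok & scaled$valid],
                 tolerance = 1e-12)
  }

  expect_true(all(base$pi[ok] >= -1 & base$pi[ok] <= 1))
})

test_that("near-zero denominators are flagged invalid, not unbounded", {
  d <- tibble::tibble(well_id = c("a", "b"),
                      delta_on_off = c(1e-9, 4),
                      delta_off_on = c(-1e-9, -4 + 1e-9))
  rec <- photokinesis_index(d, denom_epsilon = 1e-6)
  expect_equal(rec$valid, c(FALSE, FALSE))
  expect_match(rec$reason, "near-zero", all = TRUE)
  expect_true(all(is.na(rec$pi)))
})

test_that("score_population books exclusions and summarises", {
  sched <- make_schedule(0, 60, 2, "on")
  moving <- simulate_cohort(surface_params(noise_sd = 0.3), sched, n = 3,
                            seed = 6, frame_rate = 5)
  still <- purrr::map_dfr(1:2, function(i) {
    tibble::tibble(well_id = paste0("still_", i),
                   time_s = seq(0, 240, by = 0.2), x_mm = 1, y_mm = 1)
  })
  pt <- score_population(dplyr::bind_rows(moving, still), sched,
                         population = "mix")
  expect_s3_class(pt, "pi_table")
  expect_equal(nrow(pt), 5)
  expect_equal(sum(!pt$valid), 2) # the two stationary larvae
  g <- glance(pt)
  expect_equal(g$n_excluded, 2)
  expect_equal(g$n, 5)

  expect_error(score_population(moving[0, ], sched), "empty")
})

test_that("scoring pipeline is deterministic for identical inputs", {
  sched <- make_schedule(0, 60, 2, "on")
  tracks <- simulate_cohort(cave_params(), sched, n = 4, seed = 9,
                            frame_rate = 5)
  expect_identical(score_population(tracks, sched, population = "cave"),
                   score_population(tracks, sched, population = "cave"))
})

test_that("mean PI responds monotonically to the trigger-state gain", {
  sched <- make_schedule(0, 120, 2, "on")
  gains <- c(0, 0.4, 0.8)
  mean_pi <- vapply(gains, function(gain) {
    tracks <- simulate_cohort(
      surface_params(sustained_gain = gain, transient_gain = 0.8,
                     noise_sd = 0.3),
      sched, n = 15, seed = 77, frame_rate = 5
    )
    glance(score_population(tracks, sched))$mean_pi
  }, numeric(1))
  expect_true(all(diff(mean_pi) > 0))

  mean_pi_cave <- vapply(gains, function(gain) {
    tracks <- simulate_cohort(
      cave_params(sustained_gain = gain, transient_gain = 0.8,
                  noise_sd = 0.3),
      sched, n = 15, seed = 78, frame_rate = 5
    )
    glance(score_population(tracks, sched))$mean_pi
  }, numeric(1))
  expect_true(all(diff(mean_pi_cave) < 0))
})
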