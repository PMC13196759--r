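test_that("dF/F normalization matches hand computation", {
  tr <- tibble::tibble(neuron_id = "n1", time_s = 0:2,
                       fluorescence = c(10, 10, 20))
  expect_equal(delta_f_over_f(tr, c(0, 1))$dff, c(0, 0, 1))

  const <- tibble::tibble(neuron_id = "n1", time_s = 0:9, fluorescence = 7)
  expect_equal(delta_f_over_f(const, c(0, 5))$dff, rep(0, 10))

  ramp <- tibble::tibble(neuron_id = "n1", time_s = 0:4,
                         fluorescence = c(2, 4, 6, 8, 10))
  f0 <- mean(c(2, 4)) # baseline window [0, 1]
  expect_equal(delta_f_over_f(ramp, c(0, 1))$dff, (ramp$fluorescence - f0) / f0)
})

test_that("dF/F rejects non-positive baselines and is gain invariant", {
  bad <- tibble::tibble(neuron_id = "n1", time_s = 0:3,
                        fluorescence = c(-2, -2, 1, 1))
  expect_error(delta_f_over_f(bad, c(0, 1)), "> 0")

  set.seed(71)
  tr <- tibble::tibble(neuron_id = "n1", time_s = 0:99,
                       fluorescence = 50 + abs(rnorm(100, 10)))
  g1 <- delta_f_over_f(tr, c(0, 20))$dff
  tr2 <- dplyr::mutate(tr, fluorescence = fluorescence * 8.5)
  expect_equal(delta_f_over_f(tr2, c(0, 20))$dff, g1, tolerance = 1e-12)
})

test_that("tuning recovers planted preferences and the kernel closed form", {
  img <- imaging_schedule()
  specs <- trace_cluster_spec(1:3, c(2, 2, 2), c("on", "off", "none"),
                              response_amplitude = c(0.5, 0.5, 0),
                              kernel_tau = 1.8, noise_sd = 0)
  sim <- simulate_traces(specs, img, frame_rate = 10, seed = 1)
  tun <- sim$traces |>
    delta_f_over_f(c(0, 60)) |>
    compute_tuning(img, dead_band = 0.05)
  pref <- tun$preference[match(sim$labels$neuron_id, tun$neuron_id)]
  expect_equal(pref, sim$labels$preferred_state)

  # ON-epoch mean of a saturating exponential response from zero:
  # amp * (1 - tau/T * (1 - exp(-T/tau)))
  amp <- 0.5; tau <- 1.8; T_ep <- 30
  closed <- amp * (1 - tau / T_ep * (1 - exp(-T_ep / tau)))
  on_neurons <- tun[pref == "on", ]
  expect_equal(mean(on_neurons$on_mean), closed, tolerance = 0.05 * closed)

  # untuned neurons are flat at baseline
  none_rows <- tun[pref == "none", ]
  expect_equal(none_rows$on_mean, rep(0, 2), tolerance = 1e-12)
  expect_equal(none_rows$off_mean, rep(0, 2), tolerance = 1e-12)
})

test_that("ON-tuned epoch means exceed OFF means by construction", {
  img <- imaging_schedule()
  sim <- simulate_traces(trace_cluster_spec(1, 3, "on", 0.4, 1.8, 0), img,
                         frame_rate = 10, seed = 2)
  tun <- sim$traces |> delta_f_over_f(c(0, 60)) |> compute_tuning(img)
  expect_true(all(tun$on_mean > tun$off_mean))
})

test_that("epochs shorter than two frames are rejected", {
  img <- make_schedule(0, 1, 2, "on") # 1-s epochs
  tr <- tibble::tibble(neuron_id = "n1", time_s = seq(0, 3.5, 1),
                       fluorescence = 10)
  dff <- delta_f_over_f(tr, c(0, 1))
  expect_error(compute_tuning(dff, img), "at least 2 frames")
})

test_that("clustering recovers two planted groups exactly", {
  img <- imaging_schedule()
  specs <- trace_cluster_spec(1:2, c(8, 8), c("on", "off"),
                              response_amplitude = 0.8, noise_sd = 0.05)
  sim <- simulate_traces(specs, img, frame_rate = 10, seed = 3)
  tun <- sim$traces |> delta_f_over_f(c(0, 60)) |> compute_tuning(img)
  cl <- cluster_tuning(tun, max_clusters = 2)
  expect_equal(adjusted_rand_index(tidy(cl)$cluster, sim$labels$cluster_id), 1)
  expect_setequal(cl$centers$preference, c("on", "off"))
})

test_that("identical tuning vectors merge at height zero", {
  tun <- tibble::tibble(neuron_id = sprintf("n%02d", 1:6),
                        epoch_01 = 0.3, epoch_02 = -0.1, epoch_03 = 0.3)
  attr(tun, "epoch_cols") <- c("epoch_01", "epoch_02", "epoch_03")
  attr(tun, "epoch_states") <- c("on", "off", "on")
  cl <- cluster_tuning(tun, max_clusters = 3)
  expect_equal(cl$merge_heights, rep(0, 5))
  expect_equal(nrow(unique(cl$centers[, c("epoch_01", "epoch_02")])), 1)
})

test_that("partitions are invariant to neuron order and affine gain", {
  img <- imaging_schedule()
  specs <- five_cluster_spec()
  sim <- simulate_traces(specs, img, frame_rate = 10, seed = 4)
  tun <- sim$traces |> delta_f_over_f(c(0, 60)) |> compute_tuning(img)
  cl <- cluster_tuning(tun, max_clusters = 5)

  set.seed(72)
  perm <- sample(nrow(tun))
  tun_p <- tun[perm, ]
  attr(tun_p, "epoch_cols") <- attr(tun, "epoch_cols")
  attr(tun_p, "epoch_states") <- attr(tun, "epoch_states")
  cl_p <- cluster_tuning(tun_p, max_clusters = 5)
  joined <- dplyr::inner_join(tidy(cl), tidy(cl_p), by = "neuron_id")
  expect_equal(adjusted_rand_index(joined$cluster.x, joined$cluster.y), 1)

  epoch_cols <- attr(tun, "epoch_cols")
  tun_a <- tun
  tun_a[epoch_cols] <- 2.5 * tun_a[epoch_cols] + 0.3
  attr(tun_a, "epoch_cols") <- epoch_cols
  attr(tun_a, "epoch_states") <- attr(tun, "epoch_states")
  cl_a <- cluster_tuning(tun_a, max_clusters = 5)
  expect_equal(adjusted_rand_index(tidy(cl)$cluster, tidy(cl_a)$cluster), 1)
})

test_that("cluster labels are 1..K by descending size and conserve the mean", {
  img <- imaging_schedule()
  sim <- simulate_traces(five_cluster_spec(), img, frame_rate = 10, seed = 5)
  tun <- sim$traces |> delta_f_over_f(c(0, 60)) |> compute_tuning(img)
  cl <- cluster_tuning(tun, max_clusters = 5)
  expect_equal(sort(unique(tidy(cl)$cluster)), 1:5)
  expect_false(is.unsorted(rev(cl$centers$size)))
  # size-weighted centre average equals the global mean tuning vector
  epoch_cols <- attr(tun, "epoch_cols")
  weighted <- colSums(cl$centers$size * as.matrix(cl$centers[, epoch_cols])) /
    sum(cl$centers$size)
  expect_equal(weighted, colMeans(as.matrix(tun[, epoch_cols])),
               tolerance = 1e-12)
})

test_that("adjusted_rand_index agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  set.seed(73)
  for (rep_i in 1:10) {
    a <- sample(1:4, 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b),
                 mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:5, c(2, 3, 4, 5, 6)), 1)
})

test_that("cluster response comparison flags planted opposite tuning", {
  set.seed(74)
  make_subjects <- function(pop, on_resp, off_resp, n = 5) {
    tidyr::crossing(subject = paste0(pop, "_", 1:n), cluster = 1:2,
                    condition = c("on", "off")) |>
      dplyr::mutate(
        population = pop,
        response = ifelse(condition == "on", on_resp, off_resp) +
          rnorm(dplyr::n(), 0, 0.02)
      )
  }
  d <- dplyr::bind_rows(make_subjects("surface", 0.05, 0.5),
                        make_subjects("cave", 0.5, 0.05))
  cmp <- compare_cluster_response(d)
  expect_equal(nrow(cmp), 4)
  expect_true(all(cmp$q < 0.01))
  expect_true(all(cmp$q >= cmp$p - 1e-12))

  # null: same distribution both populations
  d0 <- dplyr::bind_rows(make_subjects("surface", 0.2, 0.2, n = 6),
                         make_subjects("cave", 0.2, 0.2, n = 6))
  cmp0 <- compare_cluster_response(d0)
  expect_true(all(cmp0$p > 0.001))
})

test_that("degenerate zero-variance cells hit the p = 1 branch", {
  d <- tidyr::crossing(subject = sprintf("s%d", 1:6), cluster = 1,
                       condition = c("on", "off")) |>
    dplyr::mutate(population = rep(c("surface", "cave"), each = 6),
                  response = 0.3)
  cmp <- compare_cluster_response(d)
  expect_equal(cmp$p, c(1, 1))

  expect_error(compare_cluster_response(dplyr::filter(d, condition == "on")),
               "missing light condition")
})
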