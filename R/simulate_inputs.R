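#' Region volume specifications
#'
#' Helper building the per-region generative spec for
#' [simulate_region_volumes()]: each region has a mean volume, a between-
#' fish SD, and a linear dependence of volume on the fish's photokinesis
#' index (`behavior_slope`, um^3 per unit PI; 0 for uncorrelated regions).
#'
#' @param region Region names.
#' @param mean_volume Mean volumes, um^3 (> 0).
#' @param volume_sd Between-fish SDs, um^3 (>= 0).
#' @param behavior_slope Volume change per unit PI, um^3.
#' @return Tibble with one row per region.
#' @export
region_spec <- function(region, mean_volume, volume_sd = 0,
                        behavior_slope = 0) {
  out <- tibble(region = region, mean_volume = mean_volume,
                volume_sd = volume_sd, behavior_slope = behavior_slope)
  check_that(all(out$mean_volume > 0), "`mean_volume` must be > 0")
  check_that(all(out$volume_sd >= 0), "`volume_sd` must be >= 0")
  out
}

#' Default region panel with planted behavior correlations
#'
#' Three regions with negative volume-PI coupling (tegmentum,
#' hypothalamus, posterior tuberculum, as reported for the F2 screen) and
#' a configurable number of uncorrelated null regions.
#'
#' @param n_null Number of additional uncorrelated regions.
#' @return A [region_spec()] tibble.
#' @export
default_region_panel <- function(n_null = 7) {
  planted <- region_spec(
    region = c("tegmentum", "hypothalamus", "posterior_tuberculum"),
    mean_volume = c(2.2e6, 3.1e6, 8.5e5),
    volume_sd = c(2.4e5, 3.4e5, 9.5e4),
    behavior_slope = c(-1.6e5, -2.2e5, -6.5e4)
  )
  if (n_null > 0) {
    planted <- bind_rows(planted, region_spec(
      region = sprintf("null_region_%02d", seq_len(n_null)),
      mean_volume = 1.5e6, volume_sd = 1.8e5, behavior_slope = 0
    ))
  }
  planted
}

#' Simulate per-fish brain-region volumes tied to behavior
#'
#' Volume of region j in fish i is
#' `mean_volume_j + behavior_slope_j * PI_i + N(0, volume_sd_j)`.
#'
#' @param fish_pis Tibble with columns `fish_id` and `pi` (unique fish).
#' @param regions A [region_spec()] tibble.
#' @param seed Optional integer seed.
#' @return Long tibble `fish_id`, `region`, `volume_um3`.
#' @export
simulate_region_volumes <- function(fish_pis, regions = default_region_panel(),
                                    seed = NULL) {
  check_that(is.data.frame(fish_pis) &&
               all(c("fish_id", "pi") %in% names(fish_pis)),
             "`fish_pis` must have columns fish_id and pi")
  check_that(nrow(fish_pis) >= 2, "need at least 2 fish")
  check_that(!anyDuplicated(fish_pis$fish_id), "duplicate fish ids")
  check_that(all(c("region", "mean_volume", "volume_sd", "behavior_slope")
                 %in% names(regions)), "`regions` must be a region_spec tibble")
  use_seed(seed)
  out <- tidyr::crossing(fish_pis[, c("fish_id", "pi")], regions) |>
    arrange(.data$region, .data$fish_id) |>
    mutate(volume_um3 = .data$mean_volume + .data$behavior_slope * .data$pi +
             rnorm(dplyr::n(), 0, .data$volume_sd)) |>
    select("fish_id", "region", "volume_um3")
  out
}

#' Trace cluster specifications
#'
#' Generative spec for [simulate_traces()]: each planted cluster has a
#' number of neurons, a preferred light state (`"on"`, `"off"`, or
#' `"none"` for untuned), a response amplitude in dF/F units, a calcium
#' kernel time constant, and a per-frame noise SD (dF/F units).
#'
#' @param cluster_id Cluster identifiers.
#' @param n_neurons Neurons per cluster (>= 1).
#' @param preferred_state `"on"`, `"off"` or `"none"`.
#' @param response_amplitude Steady-state dF/F response in the preferred
#'   state.
#' @param kernel_tau Exponential kernel time constant, s (nuclear GCaMP6s
#'   dynamics are ~1.8 s).
#' @param noise_sd Per-frame noise SD in dF/F units.
#' @return Tibble with one row per cluster.
#' @export
trace_cluster_spec <- function(cluster_id, n_neurons, preferred_state,
                               response_amplitude = 0.5, kernel_tau = 1.8,
                               noise_sd = 0.05) {
  out <- tibble(cluster_id = cluster_id, n_neurons = as.integer(n_neurons),
                preferred_state = preferred_state,
                response_amplitude = response_amplitude,
                kernel_tau = kernel_tau, noise_sd = noise_sd)
  check_that(all(out$n_neurons >= 1), "`n_neurons` must be >= 1")
  check_that(all(out$kernel_tau > 0), "`kernel_tau` must be > 0")
  check_that(all(out$preferred_state %in% c("on", "off", "none")),
             "`preferred_state` must be on, off or none")
  out
}

#' Simulate stimulus-tuned calcium fluorescence traces
#'
#' Fluorescence of a neuron is
#' `baseline * (1 + amplitude * r(t) + noise)`, where `r(t)` is the
#' indicator of the neuron's preferred light state convolved with a
#' normalized exponential kernel (time constant `kernel_tau`), so the
#' response saturates at `amplitude` dF/F within a long preferred epoch.
#' Untuned (`"none"`) clusters have no stimulus component.
#'
#' @param specs A [trace_cluster_spec()] tibble (>= 1 neuron in total).
#' @param schedule Imaging light schedule (e.g.
#'   `make_schedule(60, 30, 3, "on")`).
#' @param frame_rate Imaging rate, Hz.
#' @param baseline Baseline fluorescence, arbitrary units.
#' @param seed Optional integer seed.
#' @return List with `traces` (long tibble `neuron_id`, `time_s`,
#'   `fluorescence`) and `labels` (tibble `neuron_id`, `cluster_id`,
#'   `preferred_state` - the planted ground truth).
#' @export
simulate_traces <- function(specs, schedule, frame_rate = 10, baseline = 100,
                            seed = NULL) {
  check_that(is.data.frame(specs) && nrow(specs) >= 1 &&
               sum(specs$n_neurons) >= 1, "`specs` must plant at least one neuron")
  validate_schedule(schedule)
  check_that(frame_rate > 0, "`frame_rate` must be > 0")
  use_seed(seed)

  dt <- 1 / frame_rate
  duration <- schedule_duration(schedule)
  t <- seq(0, duration - dt, by = dt)
  state <- schedule_state_at(schedule, t)

  # Normalized causal exponential kernel; truncated at 8 tau.
  response_for <- function(pref, tau) {
    if (pref == "none") {
      return(rep(0, length(t)))
    }
    ind <- as.numeric(state == pref)
    lk <- ceiling(8 * tau / dt)
    kern <- exp(-(0:lk) * dt / tau)
    kern <- kern / sum(kern)
    full <- stats::convolve(ind, rev(kern), type = "open")
    full[seq_along(ind)]
  }

  neuron_rows <- purrr::map_dfr(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    tibble(cluster_id = sp$cluster_id, preferred_state = sp$preferred_state,
           response_amplitude = sp$response_amplitude,
           kernel_tau = sp$kernel_tau, noise_sd = sp$noise_sd,
           member = seq_len(sp$n_neurons))
  })
  neuron_rows$neuron_id <- sprintf("n%04d", seq_len(nrow(neuron_rows)))

  traces <- purrr::map_dfr(seq_len(nrow(neuron_rows)), function(i) {
    nr <- neuron_rows[i, ]
    resp <- response_for(nr$preferred_state, nr$kernel_tau)
    f <- baseline * (1 + nr$response_amplitude * resp +
                       if (nr$noise_sd > 0) rnorm(length(t), 0, nr$noise_sd) else 0)
    tibble(neuron_id = nr$neuron_id, time_s = t, fluorescence = f)
  })
  list(
    traces = traces,
    labels = neuron_rows[, c("neuron_id", "cluster_id", "preferred_state")]
  )
}

#' Simulate paired voxel-volume groups with planted activation blobs
#'
#' Phantom for the voxelwise activity-mapping comparison: both groups are
#' i.i.d. Gaussian background noise; group A additionally carries a fixed
#' intensity offset (`effect`) inside each spherical blob. With no blobs
#' the groups are exchangeable (a true null).
#'
#' @param grid_shape Integer vector `(nx, ny, nz)`.
#' @param blobs Tibble with columns `x`, `y`, `z` (center, voxel
#'   coordinates), `radius` (voxels, > 0) and `effect`; may have zero
#'   rows. Blobs must lie inside the grid.
#' @param n_per_group Subjects per group (>= 2).
#' @param noise_sd Background noise SD.
#' @param voxel_size Isotropic voxel size, um (kept as an attribute).
#' @param seed Optional integer seed.
#' @return List with `group_a`, `group_b` (lists of 3D arrays),
#'   `blob_mask` (logical array of planted voxels) and `voxel_size`.
#' @export
simulate_voxel_groups <- function(grid_shape = c(40, 40, 20),
                                  blobs = tibble(x = numeric(), y = numeric(),
                                                 z = numeric(), radius = numeric(),
                                                 effect = numeric()),
                                  n_per_group = 10, noise_sd = 1,
                                  voxel_size = 2, seed = NULL) {
  check_that(length(grid_shape) == 3 && all(grid_shape >= 1),
             "`grid_shape` must be three positive integers")
  check_that(n_per_group >= 2, "`n_per_group` must be >= 2")
  check_that(is.data.frame(blobs) &&
               all(c("x", "y", "z", "radius", "effect") %in% names(blobs)),
             "`blobs` must have columns x, y, z, radius, effect")
  if (nrow(blobs) > 0) {
    check_that(all(blobs$radius > 0), "blob radius must be > 0")
    inside <- blobs$x - blobs$radius >= 1 & blobs$x + blobs$radius <= grid_shape[1] &
      blobs$y - blobs$radius >= 1 & blobs$y + blobs$radius <= grid_shape[2] &
      blobs$z - blobs$radius >= 1 & blobs$z + blobs$radius <= grid_shape[3]
    check_that(all(inside), "every blob must lie within the grid")
  }
  use_seed(seed)

  effect_vol <- array(0, grid_shape)
  mask <- array(FALSE, grid_shape)
  if (nrow(blobs) > 0) {
    coords <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                          z = seq_len(grid_shape[3]))
    for (b in seq_len(nrow(blobs))) {
      d2 <- (coords$x - blobs$x[b])^2 + (coords$y - blobs$y[b])^2 +
        (coords$z - blobs$z[b])^2
      inside <- d2 <= blobs$radius[b]^2
      effect_vol[inside] <- effect_vol[inside] + blobs$effect[b]
      mask[inside] <- TRUE
    }
  }
  draw <- function(add_effect) {
    noise <- array(rnorm(prod(grid_shape), 0, noise_sd), grid_shape)
    if (add_effect) noise + effect_vol else noise
  }
  list(
    group_a = purrr::map(seq_len(n_per_group), ~ draw(TRUE)),
    group_b = purrr::map(seq_len(n_per_group), ~ draw(FALSE)),
    blob_mask = mask,
    voxel_size = voxel_size
  )
}
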