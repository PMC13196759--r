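#' Pipeline run configuration
#'
#' Collects every tunable of the synthetic end-to-end demo with its
#' default, so a run is fully described by one object that round-trips
#' through JSON. All randomness derives from `seed` via named substreams.
#'
#' @param seed Top-level integer seed.
#' @param n_per_population Fish per population in the behavioral demo.
#' @param n_f2 F2 hybrids for the cross and volume screen.
#' @param n_loci Loci in the additive cross model.
#' @param acclimation_s,epoch_s,n_cycles Behavioral schedule parameters.
#' @param frame_rate Tracking rate, Hz.
#' @param bin_s,jitter_mm,window_bins,denom_epsilon Scoring parameters.
#' @param dead_band Tuning preference dead-band, dF/F.
#' @param max_clusters Tree cut for trace clustering.
#' @param q_level FDR level for screens and maps.
#' @param map_grid,map_n_per_group Activity-map phantom size.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(seed = 1,
                       n_per_population = 12,
                       n_f2 = 30,
                       n_loci = 8,
                       acclimation_s = 1800, epoch_s = 300, n_cycles = 3,
                       frame_rate = 25,
                       bin_s = 30, jitter_mm = 0.01, window_bins = 1,
                       denom_epsilon = 1e-6,
                       dead_band = 0.05, max_clusters = 5,
                       q_level = 0.05,
                       map_grid = c(20, 20, 10), map_n_per_group = 6) {
  cfg <- as.list(environment())
  structure(cfg, class = "run_config")
}

#' Run the synthetic end-to-end demo pipeline
#'
#' Simulates every input (tracks for the four populations, F2 region
#' volumes, tuned traces, voxel phantoms), scores behavior, runs the
#' population statistics, span analysis, volume screen, trace clustering
#' and activity map, and writes all outputs plus a manifest (config, its
#' hash, seed, package version, per-file hashes) into `out_dir`.
#' Identical configs produce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character subset of
#'   `c("score", "stats", "span", "screen", "cluster", "mapmap")`;
#'   simulation always runs for whatever the requested stages need.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config = run_config(), out_dir,
                         stages = c("score", "stats", "span", "screen",
                                    "cluster", "mapmap")) {
  check_that(inherits(config, "run_config"), "`config` must be a run_config")
  known <- c("score", "stats", "span", "screen", "cluster", "mapmap")
  check_that(all(stages %in% known),
             paste0("unknown stage(s): ",
                    paste(setdiff(stages, known), collapse = ", ")))
  need_score <- length(intersect(stages,
                                 c("score", "stats", "span", "screen"))) > 0
  check_that(!("stats" %in% stages) || need_score, "stats requires score")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  results <- list()
  files <- character()
  put <- function(writer, obj, name) {
    path <- file.path(out_dir, name)
    writer(obj, path)
    files[[name]] <<- unname(rlang::hash_file(path))
    path
  }

  sched <- make_schedule(config$acclimation_s, config$epoch_s,
                         config$n_cycles, "on")
  model <- cross_model(n_loci = config$n_loci)

  if (need_score) {
    gens <- list(
      surface = config$n_per_population,
      cave = config$n_per_population,
      f1 = config$n_per_population,
      f2 = config$n_f2
    )
    pi_tables <- purrr::imap(gens, function(n, gen) {
      fish <- simulate_cross(model, gen, n,
                             seed = derive_seed(config$seed, paste0("cross_", gen)))
      tracks <- simulate_cohort(fish, sched,
                                seed = derive_seed(config$seed, paste0("tracks_", gen)),
                                frame_rate = config$frame_rate)
      score_population(tracks, sched, bin_s = config$bin_s,
                       jitter_mm = config$jitter_mm,
                       window_bins = config$window_bins,
                       denom_epsilon = config$denom_epsilon,
                       population = gen)
    })
    results$pi <- bind_rows(pi_tables)
    class(results$pi) <- c("pi_table", class(tibble()))
    put(write_pi_table, results$pi, "pi_table.csv")
    put(write_schedule, sched, "schedule.csv")
  }

  if ("stats" %in% stages) {
    st <- compare_populations(results$pi)
    results$stats <- st
    path <- file.path(out_dir, "stats.json")
    jsonlite::write_json(
      list(glance = glance(st), groups = st$groups, pairwise = st$pairwise),
      path, digits = NA
    )
    files[["stats.json"]] <- unname(rlang::hash_file(path))
  }

  if ("span" %in% stages) {
    sp <- span_analysis(results$pi, value = pi, group = population)
    results$span <- sp
    path <- file.path(out_dir, "span.json")
    jsonlite::write_json(list(per_generation = tidy(sp), summary = glance(sp)),
                         path, digits = NA)
    files[["span.json"]] <- unname(rlang::hash_file(path))
  }

  if ("screen" %in% stages) {
    f2 <- results$pi[results$pi$population == "f2" & results$pi$valid, ]
    vols <- simulate_region_volumes(
      tibble(fish_id = f2$well_id, pi = f2$pi),
      seed = derive_seed(config$seed, "volumes")
    )
    results$screen <- volume_pi_screen(vols, tibble(fish_id = f2$well_id,
                                                    pi = f2$pi,
                                                    valid = TRUE))
    put(write_region_volumes, vols, "region_volumes.csv")
    put(function(x, p) readr::write_csv(as_tibble(x), p),
        results$screen, "volume_screen.csv")
  }

  if ("cluster" %in% stages) {
    imaging <- make_schedule(60, 30, 3, "on")
    specs <- trace_cluster_spec(
      cluster_id = 1:3, n_neurons = c(12, 10, 8),
      preferred_state = c("on", "off", "none"),
      response_amplitude = c(0.6, 0.6, 0), noise_sd = 0.05
    )
    sim <- simulate_traces(specs, imaging,
                           seed = derive_seed(config$seed, "traces"))
    tuning <- sim$traces |>
      delta_f_over_f(baseline_window = c(0, 60)) |>
      compute_tuning(imaging, dead_band = config$dead_band)
    results$clusters <- cluster_tuning(tuning,
                                       max_clusters = config$max_clusters)
    put(write_traces, sim$traces, "traces.csv")
    put(function(x, p) readr::write_csv(x, p), sim$labels,
        "trace_planted_labels.csv")
    put(function(x, p) readr::write_csv(tidy(x), p), results$clusters,
        "cluster_labels.csv")
    put(function(x, p) readr::write_csv(x$centers, p), results$clusters,
        "cluster_centers.csv")
  }

  if ("mapmap" %in% stages) {
    blob_r <- max(1, min(3, min(config$map_grid) / 2 - 1.5))
    phantom <- simulate_voxel_groups(
      grid_shape = config$map_grid,
      blobs = tibble(x = config$map_grid[1] / 2, y = config$map_grid[2] / 2,
                     z = config$map_grid[3] / 2, radius = blob_r, effect = 3),
      n_per_group = config$map_n_per_group,
      seed = derive_seed(config$seed, "phantom")
    )
    results$map <- signed_map(phantom$group_a, phantom$group_b,
                              q_level = config$q_level)
    put(function(x, p) write_volume(x, p, voxel_size = phantom$voxel_size),
        results$map$mask + 0, "map_mask.nii.gz")
    put(function(x, p) write_volume(x, p, voxel_size = phantom$voxel_size),
        results$map$q, "map_q.nii.gz")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("photokin")),
    seed = config$seed,
    config = unclass(config),
    config_hash = unname(rlang::hash(unclass(config))),
    stages = stages,
    files = as.list(files)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}
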