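#' Locomotor population parameters
#'
#' Latent model of light-evoked swimming used by the track generator.
#' Instantaneous speed is
#' `baseline + [state == trigger] * (sustained + transient * exp(-(t - t_entry)/tau)) + noise`,
#' i.e. a baseline, a sustained elevation held for the whole triggering
#' epoch, and a transient surge that decays from each entry into the
#' triggering state. Surface fish are dark-activated (`trigger = "off"`),
#' cave fish light-activated (`trigger = "on"`).
#'
#' @param baseline_speed Baseline swim speed, mm/s.
#' @param trigger_state Epoch state that evokes activity, `"on"` or `"off"`.
#' @param sustained_gain Sustained speed elevation in the triggering epoch,
#'   mm/s.
#' @param transient_gain Peak of the decaying surge at epoch entry, mm/s.
#' @param transient_tau Decay time constant of the surge, seconds.
#' @param noise_sd Per-frame Gaussian speed noise, mm/s.
#' @param label Population name carried into downstream tables.
#' @return An object of class `population_params`.
#' @export
#' @examples
#' population_params(trigger_state = "off", label = "surface")
population_params <- function(baseline_speed = 0.8,
                              trigger_state = c("off", "on"),
                              sustained_gain = 0.15,
                              transient_gain = 1.5,
                              transient_tau = 20,
                              noise_sd = 0.6,
                              label = "population") {
  trigger_state <- match.arg(trigger_state)
  check_that(baseline_speed >= 0, "`baseline_speed` must be >= 0")
  check_that(transient_tau > 0, "`transient_tau` must be > 0")
  check_that(noise_sd >= 0, "`noise_sd` must be >= 0")
  structure(
    list(baseline_speed = baseline_speed, trigger_state = trigger_state,
         sustained_gain = sustained_gain, transient_gain = transient_gain,
         transient_tau = transient_tau, noise_sd = noise_sd, label = label),
    class = "population_params"
  )
}

#' @export
print.population_params <- function(x, ...) {
  cat("<population_params> ", x$label, "\n", sep = "")
  cat(sprintf("  baseline %.3g mm/s; trigger %s; sustained %.3g mm/s; transient %.3g mm/s (tau %.3g s); noise sd %.3g mm/s\n",
              x$baseline_speed, x$trigger_state, x$sustained_gain,
              x$transient_gain, x$transient_tau, x$noise_sd))
  invisible(x)
}

#' Default surface-like (dark-activated) parameters
#' @param ... Overrides passed to [population_params()].
#' @return A `population_params` object.
#' @export
surface_params <- function(...) {
  args <- list(...)
  defaults <- list(trigger_state = "off", label = "surface")
  do.call(population_params, modifyList(defaults, args))
}

#' Default cave-like (light-activated) parameters
#' @param ... Overrides passed to [population_params()].
#' @return A `population_params` object.
#' @export
cave_params <- function(...) {
  args <- list(...)
  defaults <- list(trigger_state = "on", label = "cave")
  do.call(population_params, modifyList(defaults, args))
}

# Canonical per-fish parameter row: state-specific gains so that hybrids can
# respond to both transitions. A pure population has zeros in the
# non-trigger state.
as_param_row <- function(params) {
  check_that(inherits(params, "population_params"),
             "`params` must be a population_params object")
  on <- params$trigger_state == "on"
  tibble(
    label = params$label,
    baseline_speed = params$baseline_speed,
    sustained_on = if (on) params$sustained_gain else 0,
    transient_on = if (on) params$transient_gain else 0,
    sustained_off = if (on) 0 else params$sustained_gain,
    transient_off = if (on) 0 else params$transient_gain,
    tau_on = params$transient_tau,
    tau_off = params$transient_tau,
    noise_sd = params$noise_sd
  )
}

#' Additive polygenic cross model between surface and cave populations
#'
#' Hybrid phenotypes are modeled by a genetic value `g` in `[0, 1]` (the
#' fraction of surface alleles over `n_loci` unlinked equal-effect loci)
#' that linearly interpolates every locomotor parameter between the cave
#' (`g = 0`) and surface (`g = 1`) parameter sets, plus per-fish Gaussian
#' environmental noise on `g`.
#'
#' @param n_loci Number of equal-effect loci (`k >= 1`).
#' @param surface,cave Parental [population_params()].
#' @param env_sd SD of environmental noise added to `g` (clamped to
#'   `[0, 1]`).
#' @return An object of class `cross_model`.
#' @export
cross_model <- function(n_loci = 8, surface = surface_params(),
                        cave = cave_params(), env_sd = 0.05) {
  check_that(is.numeric(n_loci) && n_loci >= 1 && n_loci == floor(n_loci),
             "`n_loci` must be a positive integer")
  check_that(env_sd >= 0, "`env_sd` must be >= 0")
  structure(list(n_loci = as.integer(n_loci), surface = surface, cave = cave,
                 env_sd = env_sd),
            class = "cross_model")
}

#' @export
print.cross_model <- function(x, ...) {
  cat(sprintf("<cross_model> %d equal-effect loci, env_sd %.3g\n",
              x$n_loci, x$env_sd))
  invisible(x)
}

#' Simulate per-fish parameters for a cross generation
#'
#' Draws the latent genetic value `g` per fish: parents are fixed
#' (`g = 1` surface, `g = 0` cave), F1 fish are heterozygous at every
#' locus (`g = 0.5` exactly), and F2 fish carry Binomial(2, 1/2) surface
#' alleles per locus so `g = (surface alleles)/(2k)`. Environmental noise
#' with SD `env_sd` is added before interpolating the locomotor
#' parameters.
#'
#' @param model A [cross_model()].
#' @param generation One of `"surface"`, `"cave"`, `"f1"`, `"f2"`.
#' @param n Number of fish.
#' @param seed Optional integer seed.
#' @return Tibble with one row per fish: `fish_id`, `generation`, `g`
#'   (noise-free genetic value), `g_env` (after environmental noise) and
#'   the interpolated locomotor parameter columns.
#' @export
#' @examples
#' simulate_cross(cross_model(n_loci = 4), "f2", n = 5, seed = 1)
simulate_cross <- function(model, generation, n, seed = NULL) {
  check_that(inherits(model, "cross_model"), "`model` must be a cross_model")
  check_that(is.numeric(n) && n >= 1 && n == floor(n),
             "`n` must be a positive integer")
  check_that(is.character(generation) && length(generation) == 1 &&
               generation %in% c("surface", "cave", "f1", "f2"),
             paste0("unknown generation: ", paste(generation, collapse = ", ")))
  use_seed(seed)
  k <- model$n_loci
  g <- switch(generation,
    surface = rep(1, n),
    cave = rep(0, n),
    f1 = rep(0.5, n),
    f2 = rowSums(matrix(rbinom(n * k, 2L, 0.5), nrow = n)) / (2 * k)
  )
  g_env <- pmin(1, pmax(0, g + rnorm(n, 0, model$env_sd)))

  s <- as_param_row(model$surface)
  c_ <- as_param_row(model$cave)
  num <- setdiff(names(s), "label")
  interp <- purrr::map_dfc(num, function(col) {
    tibble(!!col := g_env * s[[col]] + (1 - g_env) * c_[[col]])
  })
  dplyr::bind_cols(
    tibble(fish_id = sprintf("%s_%03d", generation, seq_len(n)),
           generation = generation, g = g, g_env = g_env),
    interp
  )
}
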