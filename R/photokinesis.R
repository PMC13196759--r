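#' Bin a locomotor track into fixed intervals of distance moved
#'
#' Computes per-step Euclidean displacements, suppresses sub-threshold
#' jitter (tracker centroid noise), and sums steps into contiguous
#' half-open bins `[t, t + bin_s)` from time 0. A step belongs to the bin
#' containing its start time. A trailing bin not fully covered by the
#' track is dropped.
#'
#' @param track Tibble with columns `time_s`, `x_mm`, `y_mm` (and
#'   optionally `well_id`); samples at constant spacing. One well only —
#'   use [bin_cohort()] for many.
#' @param bin_s Bin width in seconds (the assay uses 30 s).
#' @param jitter_mm Steps shorter than this are counted as 0 mm.
#' @return Tibble of class `binned_activity` with columns `well_id`,
#'   `bin_start_s`, `distance_mm`; `bin_s` kept as an attribute.
#' @export
#' @examples
#' tr <- tibble::tibble(time_s = 0:60, x_mm = 0:60, y_mm = 0)
#' bin_activity(tr, bin_s = 30, jitter_mm = 0)
bin_activity <- function(track, bin_s = 30, jitter_mm = 0.01) {
  check_that(is.data.frame(track) && all(c("time_s", "x_mm", "y_mm") %in% names(track)),
             "`track` must have columns time_s, x_mm, y_mm")
  check_that(nrow(track) >= 2, "`track` must have at least 2 samples")
  check_that(bin_s > 0, "`bin_s` must be > 0")
  tt <- track$time_s
  dts <- diff(tt)
  check_that(all(dts > 0), "`time_s` must be strictly increasing")
  check_that(diff(range(dts)) < 1e-6 * max(dts),
             "`track` must be sampled at constant frame spacing")
  if ("well_id" %in% names(track)) {
    check_that(length(unique(track$well_id)) == 1,
               "`track` contains multiple wells; use bin_cohort()")
  }

  step <- sqrt(diff(track$x_mm)^2 + diff(track$y_mm)^2)
  check_that(all(is.finite(step)), "coordinates must be finite")
  step[step < jitter_mm] <- 0
  t_start <- tt[-length(tt)]
  bin_idx <- floor((t_start - tt[1]) / bin_s)

  n_full <- floor((tt[length(tt)] - tt[1]) / bin_s + 1e-9)
  check_that(n_full >= 1, "track shorter than one bin")
  keep <- bin_idx < n_full
  dist <- vapply(seq_len(n_full) - 1L,
                 function(b) sum(step[keep & bin_idx == b]), numeric(1))
  out <- tibble(
    well_id = if ("well_id" %in% names(track)) track$well_id[1] else "well",
    bin_start_s = tt[1] + bin_s * (seq_len(n_full) - 1),
    distance_mm = dist
  )
  attr(out, "bin_s") <- bin_s
  class(out) <- c("binned_activity", class(tibble()))
  out
}

#' Bin many tracks at once
#'
#' @param tracks Long tibble of tracks with a `well_id` column.
#' @inheritParams bin_activity
#' @return `binned_activity` tibble with one block of bins per well.
#' @export
bin_cohort <- function(tracks, bin_s = 30, jitter_mm = 0.01) {
  check_that(is.data.frame(tracks) && "well_id" %in% names(tracks),
             "`tracks` must have a well_id column")
  out <- tracks |>
    dplyr::group_split(.data$well_id) |>
    purrr::map(bin_activity, bin_s = bin_s, jitter_mm = jitter_mm) |>
    bind_rows()
  attr(out, "bin_s") <- bin_s
  class(out) <- c("binned_activity", class(tibble()))
  out
}

#' Average activity change at light transitions
#'
#' For every schedule transition of each type, takes the mean binned
#' distance in the `window_bins` bins after the transition minus the mean
#' in the `window_bins` bins before (the assay uses one 30-s bin each
#' side), then averages these deltas across transitions of the same type.
#' The boundary between the dark acclimation and the first epoch is not
#' part of the alternating cycles and is excluded by default.
#'
#' @param binned A [bin_activity()] table (one or many wells).
#' @param schedule The light schedule; transitions must align to bin edges.
#' @param window_bins Number of bins on each side of a transition.
#' @param skip_acclimation Exclude the acclimation boundary transition.
#' @return Tibble of class `transition_deltas`, one row per well:
#'   `well_id`, `delta_on_off`, `delta_off_on`, `n_on_off`, `n_off_on`,
#'   `valid`, `reason`. Wells lacking a transition type (or bin coverage)
#'   get `valid = FALSE` with a reason instead of an error.
#' @export
extract_transition_deltas <- function(binned, schedule, window_bins = 1,
                                      skip_acclimation = TRUE) {
  check_that(inherits(binned, "data.frame") &&
               all(c("well_id", "bin_start_s", "distance_mm") %in% names(binned)),
             "`binned` must have columns well_id, bin_start_s, distance_mm")
  check_that(window_bins >= 1 && window_bins == floor(window_bins),
             "`window_bins` must be a positive integer")
  bin_s <- attr(binned, "bin_s") %||%
    (sort(unique(binned$bin_start_s))[2] - sort(unique(binned$bin_start_s))[1])
  trans <- schedule_transitions(schedule)
  if (skip_acclimation) trans <- trans[!trans$acclimation_boundary, ]
  check_that(all(abs(trans$time_s / bin_s - round(trans$time_s / bin_s)) < 1e-9),
             "schedule transitions must align to bin edges")

  per_well <- function(df) {
    bins <- df[order(df$bin_start_s), ]
    one_delta <- function(t0) {
      pre <- bins$distance_mm[bins$bin_start_s >= t0 - window_bins * bin_s &
                                bins$bin_start_s < t0]
      post <- bins$distance_mm[bins$bin_start_s >= t0 &
                                 bins$bin_start_s < t0 + window_bins * bin_s]
      if (length(pre) < window_bins || length(post) < window_bins) {
        return(NA_real_)
      }
      mean(post) - mean(pre)
    }
    d <- vapply(trans$time_s, one_delta, numeric(1))
    d_onoff <- d[trans$type == "on_off" & !is.na(d)]
    d_offon <- d[trans$type == "off_on" & !is.na(d)]
    valid <- length(d_onoff) >= 1 && length(d_offon) >= 1
    tibble(
      well_id = df$well_id[1],
      delta_on_off = if (length(d_onoff)) mean(d_onoff) else NA_real_,
      delta_off_on = if (length(d_offon)) mean(d_offon) else NA_real_,
      n_on_off = length(d_onoff),
      n_off_on = length(d_offon),
      valid = valid,
      reason = if (valid) NA_character_ else "missing transitions of a required type"
    )
  }
  out <- binned |>
    dplyr::group_split(.data$well_id) |>
    purrr::map(per_well) |>
    bind_rows()
  class(out) <- c("transition_deltas", class(tibble()))
  out
}

#' Photokinesis index
#'
#' The per-fish index
#' \deqn{PI = \frac{\Delta t_{on \to off} - \Delta t_{off \to on}}
#'                 {\Delta t_{on \to off} + \Delta t_{off \to on}}}
#' where each \eqn{\Delta t} is the averaged transition activity change
#' from [extract_transition_deltas()]. Positive PI means dark-activated
#' (surface-like), negative means light-activated (cave-like). When both
#' deltas are non-negative the index lies in `[-1, 1]`. Records whose
#' delta sum is within `denom_epsilon` of zero are flagged invalid (the
#' index is unstable there) and carry a reason rather than a value.
#'
#' @param deltas A `transition_deltas` tibble (or any tibble with
#'   `delta_on_off`, `delta_off_on`).
#' @param denom_epsilon Guard on the denominator, mm per bin.
#' @param population Optional population label attached to the records.
#' @return Tibble of class `pi_table`: `well_id`, `delta_on_off`,
#'   `delta_off_on`, `pi`, `valid`, `reason`, `population`.
#' @export
#' @examples
#' d <- tibble::tibble(well_id = "w1", delta_on_off = 1, delta_off_on = 3)
#' photokinesis_index(d)$pi  # -0.5
photokinesis_index <- function(deltas, denom_epsilon = 1e-6,
                               population = NULL) {
  check_that(is.data.frame(deltas) &&
               all(c("delta_on_off", "delta_off_on") %in% names(deltas)),
             "`deltas` must have columns delta_on_off and delta_off_on")
  d1 <- deltas$delta_on_off
  d2 <- deltas$delta_off_on
  prior_valid <- if ("valid" %in% names(deltas)) deltas$valid else
    rep(TRUE, nrow(deltas))
  prior_valid <- prior_valid & is.finite(d1) & is.finite(d2)
  denom_ok <- prior_valid & abs(d1 + d2) >= denom_epsilon
  pi_val <- ifelse(denom_ok, (d1 - d2) / (d1 + d2), NA_real_)
  reason_prior <- if ("reason" %in% names(deltas)) deltas$reason else
    rep(NA_character_, nrow(deltas))
  reason <- dplyr::case_when(
    !prior_valid & !is.na(reason_prior) ~ reason_prior,
    !prior_valid ~ "invalid transition deltas",
    !denom_ok ~ "near-zero total transition change",
    TRUE ~ NA_character_
  )
  wells <- if ("well_id" %in% names(deltas)) deltas$well_id else
    sprintf("well_%03d", seq_len(nrow(deltas)))
  pop <- population %||%
    (if ("population" %in% names(deltas)) deltas$population else NA_character_)
  out <- tibble(
    well_id = wells,
    delta_on_off = d1,
    delta_off_on = d2,
    pi = pi_val,
    valid = denom_ok,
    reason = reason,
    population = pop
  )
  class(out) <- c("pi_table", class(tibble()))
  out
}

#' Score a cohort of tracks: bins, transition deltas and PI per well
#'
#' End-to-end behavioral scoring: bins every track, extracts transition
#' deltas against the schedule, and computes the photokinesis index per
#' well. Exclusions (wells with missing transitions or unstable
#' denominators) are kept in the table with `valid = FALSE` and a reason.
#'
#' @param tracks Long tibble of tracks with `well_id` (or a pre-binned
#'   `binned_activity` table).
#' @param schedule The shared light schedule.
#' @param bin_s,jitter_mm Passed to [bin_activity()].
#' @param window_bins,skip_acclimation Passed to
#'   [extract_transition_deltas()].
#' @param denom_epsilon,population Passed to [photokinesis_index()].
#' @return A `pi_table` tibble with one row per well. `glance()` gives the
#'   population summary (mean, SD, n, n excluded).
#' @export
score_population <- function(tracks, schedule, bin_s = 30, jitter_mm = 0.01,
                             window_bins = 1, skip_acclimation = TRUE,
                             denom_epsilon = 1e-6, population = NULL) {
  check_that(is.data.frame(tracks) && nrow(tracks) > 0, "`tracks` is empty")
  binned <- if (inherits(tracks, "binned_activity")) tracks else
    bin_cohort(tracks, bin_s = bin_s, jitter_mm = jitter_mm)
  deltas <- extract_transition_deltas(binned, schedule,
                                      window_bins = window_bins,
                                      skip_acclimation = skip_acclimation)
  photokinesis_index(deltas, denom_epsilon = denom_epsilon,
                     population = population)
}

#' @export
glance.pi_table <- function(x, ...) {
  ok <- x$valid & is.finite(x$pi)
  tibble(
    n = nrow(x),
    n_excluded = sum(!ok),
    mean_pi = if (any(ok)) mean(x$pi[ok]) else NA_real_,
    sd_pi = if (sum(ok) > 1) sd(x$pi[ok]) else NA_real_
  )
}
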