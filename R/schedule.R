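#' Build an alternating light/dark schedule
#'
#' Constructs the illumination protocol used throughout the package: an
#' optional dark acclimation period followed by `2 * n_cycles` alternating
#' light epochs of equal length. The behavioral assay uses a 30-minute dark
#' acclimation and 5-minute epochs; the imaging protocol uses a 1-minute
#' dark lead-in and 30-second epochs.
#'
#' @param acclimation_s Dark acclimation duration in seconds (0 for none).
#' @param epoch_s Duration of each alternating epoch in seconds.
#' @param n_cycles Number of full light/dark cycles (each contributes two
#'   epochs).
#' @param first_state State of the first post-acclimation epoch, `"on"` or
#'   `"off"`.
#' @return A tibble of class `photokin_schedule` with columns `state`,
#'   `start_s`, `end_s`; intervals are contiguous, start at 0 and alternate.
#'   The acclimation length is kept in the `acclimation_s` attribute.
#' @export
#' @examples
#' make_schedule()                 # 30-min dark, then 3 x (5-min on / 5-min off)
#' make_schedule(60, 30, 4, "on")  # imaging protocol: 4 min total
make_schedule <- function(acclimation_s = 1800, epoch_s = 300, n_cycles = 3,
                          first_state = c("on", "off")) {
  first_state <- match.arg(first_state)
  check_that(is.numeric(acclimation_s) && length(acclimation_s) == 1 &&
               acclimation_s >= 0, "`acclimation_s` must be a single non-negative number")
  check_that(is.numeric(epoch_s) && length(epoch_s) == 1 && epoch_s > 0,
             "`epoch_s` must be a single positive number")
  check_that(is.numeric(n_cycles) && length(n_cycles) == 1 && n_cycles >= 1 &&
               n_cycles == floor(n_cycles), "`n_cycles` must be a positive integer")

  n_epochs <- 2L * as.integer(n_cycles)
  states <- rep(c(first_state, setdiff(c("on", "off"), first_state)),
                length.out = n_epochs)
  starts <- acclimation_s + epoch_s * (seq_len(n_epochs) - 1)
  sched <- tibble(state = states, start_s = starts, end_s = starts + epoch_s)
  if (acclimation_s > 0) {
    # Acclimation is dark; it must differ from the first epoch to keep the
    # interval states alternating, so an "off"-first protocol folds the
    # acclimation into one long initial off interval.
    if (first_state == "off") {
      sched$start_s[1] <- 0
    } else {
      sched <- bind_rows(tibble(state = "off", start_s = 0, end_s = acclimation_s),
                         sched)
    }
  }
  new_schedule(sched, acclimation_s = acclimation_s)
}

new_schedule <- function(df, acclimation_s = 0) {
  out <- as_tibble(df)
  validate_schedule(out)
  attr(out, "acclimation_s") <- acclimation_s
  class(out) <- c("photokin_schedule", class(tibble()))
  out
}

#' Coerce a data frame of intervals to a schedule
#'
#' @param x Data frame with columns `state` ("on"/"off"), `start_s`, `end_s`.
#' @param acclimation_s Length of the initial acclimation period contained in
#'   the first interval, used to flag the acclimation boundary.
#' @return A `photokin_schedule` tibble.
#' @export
as_schedule <- function(x, acclimation_s = 0) {
  new_schedule(x[, c("state", "start_s", "end_s")], acclimation_s = acclimation_s)
}

validate_schedule <- function(sched) {
  check_that(is.data.frame(sched) &&
               all(c("state", "start_s", "end_s") %in% names(sched)) &&
               nrow(sched) >= 1,
             "schedule must have rows and columns state, start_s, end_s")
  check_that(all(sched$state %in% c("on", "off")),
             "schedule states must be \"on\" or \"off\"")
  check_that(sched$start_s[1] == 0, "schedule must start at 0 s")
  check_that(all(sched$end_s > sched$start_s),
             "every schedule interval must have end_s > start_s")
  if (nrow(sched) > 1) {
    check_that(all(abs(sched$start_s[-1] - sched$end_s[-nrow(sched)]) < 1e-9),
               "schedule intervals must be contiguous")
    check_that(all(sched$state[-1] != sched$state[-nrow(sched)]),
               "adjacent schedule intervals must differ in state")
  }
  invisible(sched)
}

#' Total duration of a schedule in seconds
#' @param schedule A `photokin_schedule`.
#' @return Duration in seconds.
#' @export
schedule_duration <- function(schedule) {
  validate_schedule(schedule)
  max(schedule$end_s)
}

#' Light state at given times
#'
#' @param schedule A `photokin_schedule`.
#' @param times Numeric vector of times in seconds within the schedule
#'   (`[0, duration)`; the final instant maps to the last interval).
#' @return Character vector of `"on"`/`"off"` states.
#' @export
schedule_state_at <- function(schedule, times) {
  validate_schedule(schedule)
  check_that(all(times >= 0 & times <= max(schedule$end_s)),
             "`times` must lie within the schedule")
  idx <- findInterval(times, schedule$start_s)
  schedule$state[pmin(idx, nrow(schedule))]
}

#' Light transitions of a schedule
#'
#' Interior boundaries between intervals, typed by direction. The boundary
#' at the end of the acclimation period (when present) is flagged so that
#' transition scoring can exclude it: it is not part of the alternating
#' cycles.
#'
#' @param schedule A `photokin_schedule`.
#' @return Tibble with columns `time_s`, `from`, `to`,
#'   `type` (`"on_off"`/`"off_on"`), `acclimation_boundary`.
#' @export
schedule_transitions <- function(schedule) {
  validate_schedule(schedule)
  n <- nrow(schedule)
  if (n < 2) {
    return(tibble(time_s = numeric(), from = character(), to = character(),
                  type = character(), acclimation_boundary = logical()))
  }
  acc <- attr(schedule, "acclimation_s") %||% 0
  tibble(
    time_s = schedule$end_s[-n],
    from = schedule$state[-n],
    to = schedule$state[-1],
    type = ifelse(schedule$state[-n] == "on", "on_off", "off_on"),
    acclimation_boundary = acc > 0 & abs(schedule$end_s[-n] - acc) < 1e-9
  )
}
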