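# ggplot2 views of the main result types. Each autoplot() returns a plot
# object the caller can restyle.

shade_epochs <- function(schedule) {
  sched <- as_tibble(schedule)
  ggplot2::geom_rect(
    data = sched[sched$state == "off", ],
    ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                 ymin = -Inf, ymax = Inf),
    inherit.aes = FALSE, fill = "grey80", alpha = 0.5
  )
}

#' Plot binned activity traces under the light schedule
#'
#' Per-well distance moved per bin with dark epochs shaded, optionally
#' averaged over wells.
#'
#' @param binned A [bin_activity()]/[bin_cohort()] table.
#' @param schedule The light schedule (for epoch shading).
#' @param average Plot the well average instead of per-well lines.
#' @return A ggplot object.
#' @export
plot_binned_activity <- function(binned, schedule = NULL, average = FALSE) {
  df <- as_tibble(binned)
  p <- ggplot2::ggplot()
  if (!is.null(schedule)) p <- p + shade_epochs(schedule)
  if (average) {
    avg <- df |>
      group_by(.data$bin_start_s) |>
      summarise(distance_mm = mean(.data$distance_mm), .groups = "drop")
    p <- p + ggplot2::geom_line(data = avg,
                                ggplot2::aes(.data$bin_start_s, .data$distance_mm))
  } else {
    p <- p + ggplot2::geom_line(
      data = df,
      ggplot2::aes(.data$bin_start_s, .data$distance_mm, group = .data$well_id),
      alpha = 0.5
    )
  }
  p + ggplot2::labs(x = "time (s)", y = "distance moved per bin (mm)")
}

#' @export
autoplot.pi_table <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[df$valid & is.finite(df$pi), ]
  ggplot2::ggplot(df, ggplot2::aes(.data$population, .data$pi)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "photokinesis index",
                  caption = "positive = dark-activated, negative = light-activated")
}

#' @export
autoplot.volume_screen <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[is.na(df$note), ]
  df$region <- factor(df$region, levels = rev(df$region))
  ggplot2::ggplot(df, ggplot2::aes(.data$r, .data$region,
                                   fill = .data$q <= 0.05)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "firebrick",
                                          `FALSE` = "grey60"),
                               name = "q <= 0.05") +
    ggplot2::labs(x = "Pearson r (volume vs PI)", y = NULL)
}

#' @export
autoplot.trace_clusters <- function(object, ...) {
  states <- object$epoch_states
  centers <- object$centers
  epoch_cols <- grep("^epoch_", names(centers), value = TRUE)
  long <- centers |>
    select("cluster", "size", all_of(epoch_cols)) |>
    tidyr::pivot_longer(all_of(epoch_cols), names_to = "epoch",
                        values_to = "mean_dff") |>
    mutate(epoch_i = as.integer(sub("epoch_", "", .data$epoch)))
  p <- ggplot2::ggplot(long, ggplot2::aes(.data$epoch_i, .data$mean_dff,
                                          group = .data$cluster))
  if (!is.null(states)) {
    off <- tibble(epoch_i = which(states == "off"))
    p <- p + ggplot2::geom_rect(
      data = off,
      ggplot2::aes(xmin = .data$epoch_i - 0.5, xmax = .data$epoch_i + 0.5,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey80", alpha = 0.5
    )
  }
  p +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cluster, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "epoch", y = "mean dF/F",
                  caption = "shaded = dark epochs")
}

#' @export
autoplot.activity_map <- function(object, slice = NULL, ...) {
  nz <- dim(object$mask)[3]
  slice <- slice %||% ceiling(nz / 2)
  check_that(slice >= 1 && slice <= nz, "`slice` out of range")
  df <- expand.grid(x = seq_len(dim(object$mask)[1]),
                    y = seq_len(dim(object$mask)[2]))
  df$mask <- as.vector(object$mask[, , slice])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = factor(.data$mask, c(-1, 0, 1)))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(
      values = c(`-1` = "magenta", `0` = "grey95", `1` = "green3"),
      name = NULL, drop = FALSE,
      labels = c("B higher", "n.s.", "A higher")
    ) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0("signed activity map, slice z = ", slice))
}
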