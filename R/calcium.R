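#' Baseline-normalize fluorescence traces (dF/F)
#'
#' Computes `(f - f0) / f0` per neuron, with `f0` the mean raw
#' fluorescence over a baseline window — by default the dark lead-in
#' before the first light epoch of the imaging protocol.
#'
#' @param traces Long tibble with columns `neuron_id`, `time_s`,
#'   `fluorescence`.
#' @param baseline_window Two-element numeric `(start_s, end_s)` of the
#'   baseline period.
#' @return The input tibble with an added `dff` column.
#' @export
#' @examples
#' tr <- tibble::tibble(neuron_id = "n1", time_s = 0:2,
#'                      fluorescence = c(10, 10, 20))
#' delta_f_over_f(tr, baseline_window = c(0, 1))$dff  # 0 0 1
delta_f_over_f <- function(traces, baseline_window = c(0, 60)) {
  check_that(is.data.frame(traces) &&
               all(c("neuron_id", "time_s", "fluorescence") %in% names(traces)),
             "`traces` must have columns neuron_id, time_s, fluorescence")
  check_that(length(baseline_window) == 2 &&
               baseline_window[2] > baseline_window[1],
             "`baseline_window` must be (start_s, end_s) with end > start")
  check_that(all(is.finite(traces$fluorescence)),
             "fluorescence values must be finite")
  out <- traces |>
    group_by(.data$neuron_id) |>
    mutate(.f0 = {
      w <- .data$time_s >= baseline_window[1] & .data$time_s <= baseline_window[2]
      if (!any(w)) abort("baseline window contains no samples for a neuron")
      mean(.data$fluorescence[w])
    }) |>
    ungroup()
  check_that(all(out$.f0 > 0), "baseline mean fluorescence must be > 0")
  out$dff <- (out$fluorescence - out$.f0) / out$.f0
  out$.f0 <- NULL
  out
}

#' Epoch-averaged stimulus tuning of dF/F traces
#'
#' Averages each neuron's dF/F within every post-acclimation light epoch,
#' summarises the ON-epoch and OFF-epoch means, and assigns a light
#' preference with a dead-band: `"none"` unless the |ON - OFF| difference
#' exceeds `dead_band` dF/F.
#'
#' @param dff Long tibble with `neuron_id`, `time_s`, `dff` (from
#'   [delta_f_over_f()]).
#' @param schedule Imaging schedule; every epoch must contain at least 2
#'   frames.
#' @param dead_band Minimum |ON - OFF| mean difference (dF/F) to call a
#'   preference.
#' @return Tibble of class `tuning_table`: `neuron_id`, one `epoch_*`
#'   column per post-acclimation epoch (named by order, state in the
#'   `epoch_states` attribute), `on_mean`, `off_mean`, `preference`.
#' @export
compute_tuning <- function(dff, schedule, dead_band = 0.05) {
  check_that(is.data.frame(dff) &&
               all(c("neuron_id", "time_s", "dff") %in% names(dff)),
             "`dff` must have columns neuron_id, time_s, dff (run delta_f_over_f first)")
  validate_schedule(schedule)
  acc <- attr(schedule, "acclimation_s") %||% 0
  epochs <- schedule[schedule$start_s >= acc - 1e-9, , drop = FALSE]
  check_that(nrow(epochs) >= 2, "schedule must contain alternating epochs")

  times <- sort(unique(dff$time_s))
  for (i in seq_len(nrow(epochs))) {
    nf <- sum(times >= epochs$start_s[i] & times < epochs$end_s[i])
    check_that(nf >= 2, "every epoch must contain at least 2 frames")
  }

  epoch_of <- function(ts) {
    idx <- findInterval(ts, epochs$start_s)
    idx[ts >= max(epochs$end_s)] <- nrow(epochs) # clamp final instant
    idx[idx == 0] <- NA_integer_ # acclimation frames
    idx
  }
  long <- dff |>
    mutate(.epoch = epoch_of(.data$time_s)) |>
    filter(!is.na(.data$.epoch) & .data$time_s < max(epochs$end_s)) |>
    group_by(.data$neuron_id, .data$.epoch) |>
    summarise(mean_dff = mean(.data$dff), .groups = "drop")

  wide <- long |>
    mutate(.epoch = sprintf("epoch_%02d", .data$.epoch)) |>
    tidyr::pivot_wider(names_from = ".epoch", values_from = "mean_dff")
  epoch_cols <- sprintf("epoch_%02d", seq_len(nrow(epochs)))
  check_that(all(epoch_cols %in% names(wide)), "missing epochs in dff data")
  wide <- wide[, c("neuron_id", epoch_cols)]

  on_cols <- epoch_cols[epochs$state == "on"]
  off_cols <- epoch_cols[epochs$state == "off"]
  wide$on_mean <- rowMeans(wide[, on_cols, drop = FALSE])
  wide$off_mean <- rowMeans(wide[, off_cols, drop = FALSE])
  diffm <- wide$on_mean - wide$off_mean
  wide$preference <- dplyr::case_when(
    abs(diffm) < dead_band ~ "none",
    diffm > 0 ~ "on",
    TRUE ~ "off"
  )
  attr(wide, "epoch_states") <- epochs$state
  attr(wide, "epoch_cols") <- epoch_cols
  class(wide) <- c("tuning_table", class(tibble()))
  wide
}

#' Hierarchically cluster neurons by stimulus tuning
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances between
#' per-epoch tuning vectors), with the tree cut into exactly
#' `max_clusters` groups — the ceiling used by the imaging analysis.
#' Clusters are renumbered by descending size (ties broken by first
#' occurrence in neuron order), which makes the labeling deterministic
#' and invariant to neuron permutation up to relabeling.
#'
#' @param tuning A [compute_tuning()] table.
#' @param max_clusters Number of groups to cut the tree into (default 5).
#' @return Object of class `trace_clusters` with `labels` (tibble
#'   `neuron_id`, `cluster`), `centers` (per-cluster mean tuning vector,
#'   size and preference), `merge_heights` and `k`. `tidy()` returns the
#'   labels, `glance()` the per-cluster summary.
#' @export
cluster_tuning <- function(tuning, max_clusters = 5) {
  check_that(inherits(tuning, "data.frame") && "neuron_id" %in% names(tuning),
             "`tuning` must be a compute_tuning() table")
  epoch_cols <- attr(tuning, "epoch_cols") %||%
    grep("^epoch_", names(tuning), value = TRUE)
  check_that(length(epoch_cols) >= 1, "no epoch columns found")
  check_that(max_clusters >= 1, "`max_clusters` must be >= 1")
  check_that(nrow(tuning) >= max_clusters,
             "need at least as many neurons as clusters")

  x <- as.matrix(tuning[, epoch_cols])
  hc <- hclust(dist(x, method = "euclidean"), method = "ward.D2")
  raw <- cutree(hc, k = max_clusters)

  sizes <- table(raw)
  first_seen <- vapply(names(sizes), function(l) min(which(raw == as.integer(l))),
                       numeric(1))
  ord <- order(-as.vector(sizes), first_seen)
  relabel <- setNames(seq_along(ord), names(sizes)[ord])
  labels <- unname(relabel[as.character(raw)])

  states <- attr(tuning, "epoch_states")
  centers <- purrr::map_dfr(seq_len(max_clusters), function(k) {
    member <- labels == k
    cm <- colMeans(x[member, , drop = FALSE])
    on_mean <- if (!is.null(states)) mean(cm[states == "on"]) else NA_real_
    off_mean <- if (!is.null(states)) mean(cm[states == "off"]) else NA_real_
    pref <- if (is.na(on_mean)) {
      NA_character_
    } else if (abs(on_mean - off_mean) < 0.05) {
      "none"
    } else if (on_mean > off_mean) "on" else "off"
    dplyr::bind_cols(
      tibble(cluster = k, size = sum(member), on_mean = on_mean,
             off_mean = off_mean, preference = pref),
      as_tibble(as.list(cm))
    )
  })
  structure(
    list(labels = tibble(neuron_id = tuning$neuron_id, cluster = labels),
         centers = centers, merge_heights = hc$height, k = max_clusters,
         epoch_states = states),
    class = "trace_clusters"
  )
}

#' @export
print.trace_clusters <- function(x, ...) {
  cat(sprintf("<trace_clusters> %d neurons in %d clusters\n",
              nrow(x$labels), x$k))
  print(as.data.frame(x$centers[, c("cluster", "size", "on_mean", "off_mean",
                                    "preference")]), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.trace_clusters <- function(x, ...) {
  x$labels
}

#' @export
glance.trace_clusters <- function(x, ...) {
  tibble(k = x$k, n_neurons = nrow(x$labels),
         max_merge_height = max(x$merge_heights),
         n_on = sum(x$centers$preference == "on", na.rm = TRUE),
         n_off = sum(x$centers$preference == "off", na.rm = TRUE))
}

#' Compare per-cluster responses between two populations
#'
#' For every cluster x light-condition cell, runs a Welch t-test of the
#' per-subject mean response between the two populations, then adjusts
#' the whole family of comparisons with Benjamini-Hochberg. Degenerate
#' cells where both groups are constant report p = 1 when the means are
#' equal and p = 0 otherwise.
#'
#' @param data Tibble with columns `subject`, `population`, `cluster`,
#'   `condition` (`"on"`/`"off"`), `response` (per-subject mean dF/F).
#' @param min_n Minimum subjects per population per cell.
#' @return Tibble of class `cluster_comparison`: `cluster`, `condition`,
#'   group means, `estimate`, `t`, `df`, `p`, `q`.
#' @export
compare_cluster_response <- function(data, min_n = 3) {
  need <- c("subject", "population", "cluster", "condition", "response")
  check_that(is.data.frame(data) && all(need %in% names(data)),
             paste0("`data` must have columns ", paste(need, collapse = ", ")))
  pops <- sort(unique(as.character(data$population)))
  check_that(length(pops) == 2, "exactly two populations are required")
  conds <- unique(as.character(data$condition))
  check_that(all(c("on", "off") %in% conds), "missing light condition")

  cells <- data |>
    dplyr::distinct(.data$cluster, .data$condition) |>
    arrange(.data$cluster, .data$condition)
  out <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    sub <- data[data$cluster == cc$cluster & data$condition == cc$condition, ]
    a <- sub$response[sub$population == pops[1]]
    b <- sub$response[sub$population == pops[2]]
    check_that(length(a) >= min_n && length(b) >= min_n,
               paste0("fewer than ", min_n, " subjects per population in cluster ",
                      cc$cluster, " / ", cc$condition))
    if (sd(a) == 0 && sd(b) == 0) {
      p <- if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0
      res <- tibble(estimate = mean(a) - mean(b), t = NA_real_,
                    df = NA_real_, p = p)
    } else {
      ht <- t.test(a, b)
      res <- tibble(estimate = unname(ht$estimate[1] - ht$estimate[2]),
                    t = unname(ht$statistic), df = unname(ht$parameter),
                    p = ht$p.value)
    }
    dplyr::bind_cols(
      tibble(cluster = cc$cluster, condition = cc$condition,
             mean_1 = mean(a), mean_2 = mean(b)), res
    )
  })
  out$q <- p.adjust(out$p, method = "BH")
  attr(out, "populations") <- pops
  class(out) <- c("cluster_comparison", class(tibble()))
  out
}
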