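#' Compare photokinesis indices between populations
#'
#' Two groups are compared with a Welch (unequal-variance) t-test; three or
#' more with a one-way ANOVA followed by Tukey HSD pairwise comparisons.
#' Shapiro-Wilk normality diagnostics are reported per group but do not
#' switch the test (normality is assessed, then the parametric test is
#' applied). Invalid PI records are dropped before testing.
#'
#' @param data A `pi_table` or any data frame with a value column and a
#'   group column.
#' @param value,group Column names (unquoted) of the response and the
#'   group label; default `pi` and `population`.
#' @return An object of class `photokin_stats` with fields `test`,
#'   `groups` (per-group n/mean/sd and Shapiro diagnostics), `statistic`,
#'   `df`, `p_value` and `pairwise` (estimate, raw and adjusted p per
#'   pair). `tidy()` returns the pairwise table, `glance()` the omnibus
#'   result.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   population = rep(c("surface", "cave"), each = 5),
#'   pi = c(rnorm(5, 0.4, 0.1), rnorm(5, -0.4, 0.1))
#' )
#' compare_populations(d)
compare_populations <- function(data, value = pi, group = population) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  y <- rlang::eval_tidy(value, data)
  g <- rlang::eval_tidy(group, data)
  check_that(length(y) == nrow(data) && length(g) == nrow(data),
             "`value` and `group` must name columns of `data`")
  df <- tibble(y = y, g = as.character(g))
  if ("valid" %in% names(data)) df <- df[data$valid, , drop = FALSE]
  df <- df[is.finite(df$y) & !is.na(df$g), , drop = FALSE]
  counts <- table(df$g)
  check_that(length(counts) >= 2, "need at least two groups")
  check_that(all(counts >= 3), "each group needs n >= 3")

  groups <- df |>
    group_by(.data$g) |>
    summarise(
      n = dplyr::n(),
      mean = mean(.data$y),
      sd = sd(.data$y),
      shapiro_w = if (sd(.data$y) > 0) shapiro.test(.data$y)$statistic[[1]] else NA_real_,
      shapiro_p = if (sd(.data$y) > 0) shapiro.test(.data$y)$p.value else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::rename(group = "g")

  if (length(counts) == 2) {
    labs <- sort(unique(df$g))
    ht <- t.test(df$y[df$g == labs[1]], df$y[df$g == labs[2]])
    pairwise <- tibble(
      group1 = labs[1], group2 = labs[2],
      estimate = unname(diff(rev(ht$estimate))),
      p_raw = ht$p.value, p_adj = ht$p.value
    )
    out <- list(test = "welch_t", groups = groups,
                statistic = unname(ht$statistic), df = unname(ht$parameter),
                p_value = ht$p.value, pairwise = pairwise)
  } else {
    out <- one_way_tukey(df$y, df$g)
    out$groups <- groups
  }
  structure(out, class = "photokin_stats")
}

# One-way ANOVA with Tukey HSD; handles the fully degenerate case
# (all groups identical constants) where the F ratio is 0/0 by reporting
# F = 0, p = 1, matching the no-signal interpretation.
one_way_tukey <- function(y, g) {
  g <- factor(g)
  k <- nlevels(g)
  n <- length(y)
  gm <- tapply(y, g, mean)
  gn <- tapply(y, g, length)
  ss_between <- sum(gn * (gm - mean(y))^2)
  ss_within <- sum((y - gm[g])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_between <= 1e-300 * max(1, ss_within)) {
    f_stat <- 0
    p <- 1
  } else if (ss_within <= 1e-300 * ss_between) {
    f_stat <- Inf
    p <- 0
  } else {
    f_stat <- (ss_between / df1) / (ss_within / df2)
    p <- stats::pf(f_stat, df1, df2, lower.tail = FALSE)
  }
  mse <- ss_within / df2

  labs <- levels(g)
  pairs <- utils::combn(labs, 2)
  pairwise <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]
    b <- pairs[2, j]
    est <- gm[[b]] - gm[[a]]
    se <- sqrt(mse * (1 / gn[[a]] + 1 / gn[[b]]))
    if (se == 0) {
      t_stat <- if (est == 0) 0 else Inf * sign(est)
    } else {
      t_stat <- est / se
    }
    p_raw <- if (is.infinite(t_stat)) 0 else 2 * pt(-abs(t_stat), df2)
    p_adj <- if (is.infinite(t_stat)) 0 else
      ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df2, lower.tail = FALSE)
    tibble(group1 = a, group2 = b, estimate = unname(est),
           p_raw = p_raw, p_adj = p_adj)
  })
  list(test = "anova_tukey", statistic = f_stat, df = c(df1, df2),
       p_value = p, pairwise = pairwise)
}

#' @export
print.photokin_stats <- function(x, ...) {
  lab <- if (x$test == "welch_t") "Welch two-sample t-test" else
    "One-way ANOVA with Tukey HSD"
  cat("<photokin_stats> ", lab, "\n", sep = "")
  stat_name <- if (x$test == "welch_t") "t" else "F"
  cat(sprintf("  %s = %.4g (df %s), p = %.4g\n", stat_name, x$statistic,
              paste(signif(x$df, 4), collapse = ", "), x$p_value))
  cat("  groups:\n")
  print(as.data.frame(x$groups), row.names = FALSE)
  cat("  pairwise:\n")
  print(as.data.frame(x$pairwise), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.photokin_stats <- function(x, ...) {
  x$pairwise
}

#' @export
glance.photokin_stats <- function(x, ...) {
  tibble(
    test = x$test,
    statistic = x$statistic,
    df1 = x$df[1],
    df2 = if (length(x$df) > 1) x$df[2] else NA_real_,
    p_value = x$p_value,
    n_groups = nrow(x$groups),
    n = sum(x$groups$n)
  )
}
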