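#' Trait span and variance structure across cross generations
#'
#' Summarises the photokinesis index per generation and quantifies the
#' hybrid trait structure expected under polygenic inheritance: F1 fish
#' intermediate between the parental morphs, F2 fish spanning the full
#' grandparental range with inflated variance. Reports per-generation
#' moments, the fraction of F2 fish beyond each parental mean (in that
#' parent's direction), and F2/F1 and F2/parental variance ratios.
#'
#' @param data Data frame with a PI column and a generation column with
#'   labels among `"surface"`, `"cave"`, `"f1"`, `"f2"` (`"f1"` optional).
#' @param value,group Unquoted column names; default `pi` and
#'   `generation`.
#' @return Object of class `span_summary`; `tidy()` returns the
#'   per-generation table, `glance()` the span fractions and variance
#'   ratios. Ratios against a zero-variance reference are `NA` (flagged
#'   degenerate).
#' @export
span_analysis <- function(data, value = pi, group = generation) {
  value <- rlang::enquo(value)
  group <- rlang::enquo(group)
  y <- rlang::eval_tidy(value, data)
  g <- tolower(as.character(rlang::eval_tidy(group, data)))
  check_that(length(y) == nrow(data) && length(g) == nrow(data),
             "`value` and `group` must name columns of `data`")
  if ("valid" %in% names(data)) {
    keep <- data$valid & is.finite(y)
  } else {
    keep <- is.finite(y)
  }
  y <- y[keep]
  g <- g[keep]
  check_that(all(g %in% c("surface", "cave", "f1", "f2")),
             "generation labels must be among surface, cave, f1, f2")
  for (req in c("surface", "cave", "f2")) {
    check_that(sum(g == req) >= 3, paste0("missing or too-small group: ", req))
  }
  check_that(!any(g == "f1") || sum(g == "f1") >= 3,
             "f1 group present but n < 3")

  per_gen <- tibble(generation = g, y = y) |>
    group_by(.data$generation) |>
    summarise(n = dplyr::n(), mean = mean(.data$y), sd = sd(.data$y),
              var = var(.data$y), min = min(.data$y), max = max(.data$y),
              .groups = "drop")
  gm <- setNames(per_gen$mean, per_gen$generation)
  gv <- setNames(per_gen$var, per_gen$generation)
  f2 <- y[g == "f2"]

  # "Beyond" a parental mean = more extreme in that parent's direction,
  # the direction being the sign of that parent's mean minus the other's.
  dir_surface <- sign(gm[["surface"]] - gm[["cave"]])
  frac_beyond_surface <- mean(dir_surface * f2 > dir_surface * gm[["surface"]])
  frac_beyond_cave <- mean(-dir_surface * f2 > -dir_surface * gm[["cave"]])

  ratio <- function(a, b) if (is.na(b) || b <= 0) NA_real_ else a / b
  parental_var <- mean(c(gv[["surface"]], gv[["cave"]]))
  structure(
    list(
      per_generation = per_gen,
      frac_f2_beyond_surface = unname(frac_beyond_surface),
      frac_f2_beyond_cave = unname(frac_beyond_cave),
      var_ratio_f2_f1 = if ("f1" %in% names(gv))
        ratio(gv[["f2"]], gv[["f1"]]) else NA_real_,
      var_ratio_f2_parental = ratio(gv[["f2"]], parental_var),
      degenerate = parental_var <= 0 || gv[["f2"]] <= 0
    ),
    class = "span_summary"
  )
}

#' @export
print.span_summary <- function(x, ...) {
  cat("<span_summary>\n")
  print(as.data.frame(x$per_generation), row.names = FALSE)
  cat(sprintf("  F2 beyond surface mean: %.3f; beyond cave mean: %.3f\n",
              x$frac_f2_beyond_surface, x$frac_f2_beyond_cave))
  cat(sprintf("  var ratios F2/F1 = %.3g, F2/parental = %.3g%s\n",
              x$var_ratio_f2_f1, x$var_ratio_f2_parental,
              if (x$degenerate) " (degenerate: zero variance)" else ""))
  invisible(x)
}

#' @export
tidy.span_summary <- function(x, ...) {
  x$per_generation
}

#' @export
glance.span_summary <- function(x, ...) {
  tibble(
    frac_f2_beyond_surface = x$frac_f2_beyond_surface,
    frac_f2_beyond_cave = x$frac_f2_beyond_cave,
    var_ratio_f2_f1 = x$var_ratio_f2_f1,
    var_ratio_f2_parental = x$var_ratio_f2_parental,
    degenerate = x$degenerate
  )
}

#' Screen brain-region volumes against photokinesis behavior
#'
#' For every brain region, fits the simple linear regression of volume on
#' PI and reports the Pearson correlation, slope, intercept, raw p-value
#' and Benjamini-Hochberg q across regions (the atlas screen tests many
#' regions at once). Fish present in only one table are dropped by an
#' inner join on `fish_id`; regions with constant volume are flagged and
#' excluded from the adjustment.
#'
#' @param volumes Long tibble with columns `fish_id`, `region`,
#'   `volume_um3`.
#' @param pis Tibble with `fish_id` and `pi` (e.g. a `pi_table`; invalid
#'   records are dropped).
#' @param min_n Minimum joined sample size.
#' @return Tibble of class `volume_screen`, one row per region sorted by
#'   q: `region`, `n`, `r`, `slope`, `intercept`, `p`, `q`, `note`.
#' @export
volume_pi_screen <- function(volumes, pis, min_n = 10) {
  check_that(is.data.frame(volumes) &&
               all(c("fish_id", "region", "volume_um3") %in% names(volumes)),
             "`volumes` must have columns fish_id, region, volume_um3")
  check_that(is.data.frame(pis) && all(c("fish_id", "pi") %in% names(pis)),
             "`pis` must have columns fish_id and pi")
  pis_ok <- pis
  if ("valid" %in% names(pis_ok)) pis_ok <- pis_ok[pis_ok$valid, ]
  pis_ok <- pis_ok[is.finite(pis_ok$pi), c("fish_id", "pi")]
  joined <- inner_join(volumes, pis_ok, by = "fish_id")
  n_dropped <- length(setdiff(unique(volumes$fish_id), unique(joined$fish_id)))
  if (n_dropped > 0) {
    rlang::inform(paste0("volume_pi_screen: dropped ", n_dropped,
                         " fish missing a valid PI"))
  }
  check_that(length(unique(joined$fish_id)) >= min_n,
             paste0("fewer than ", min_n, " fish after joining volumes and PI"))
  check_that(length(unique(joined$region)) >= 1, "no regions to screen")

  per_region <- joined |>
    dplyr::group_split(.data$region) |>
    purrr::map(function(df) {
      base <- tibble(region = df$region[1], n = nrow(df))
      if (sd(df$volume_um3) == 0 || sd(df$pi) == 0) {
        return(mutate(base, r = NA_real_, slope = NA_real_,
                      intercept = NA_real_, p = NA_real_,
                      note = "constant values; correlation undefined"))
      }
      ct <- cor.test(df$pi, df$volume_um3, method = "pearson")
      fit <- lm(volume_um3 ~ pi, data = df)
      mutate(base, r = unname(ct$estimate), slope = unname(coef(fit)[2]),
             intercept = unname(coef(fit)[1]), p = ct$p.value,
             note = NA_character_)
    }) |>
    bind_rows()
  per_region$q <- NA_real_
  testable <- is.na(per_region$note)
  per_region$q[testable] <- p.adjust(per_region$p[testable], method = "BH")
  out <- per_region |>
    select("region", "n", "r", "slope", "intercept", "p", "q", "note") |>
    arrange(.data$q)
  class(out) <- c("volume_screen", class(tibble()))
  out
}
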