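# Voxelwise nonparametric group comparison: a simplified reimplementation
# of the core of whole-brain activity (pERK) mapping — per-voxel two-sided
# Mann-Whitney rank-sum tests with FDR thresholding. Registration and
# deformation of the original method are out of scope; volumes are inputs.

check_congruent <- function(group_a, group_b) {
  check_that(is.list(group_a) && is.list(group_b) &&
               length(group_a) >= 2 && length(group_b) >= 2,
             "each group needs at least 2 subject volumes")
  dims <- lapply(c(group_a, group_b), dim)
  check_that(all(vapply(dims, length, integer(1)) == 3),
             "volumes must be 3D arrays")
  ref <- dims[[1]]
  check_that(all(vapply(dims, function(d) all(d == ref), logical(1))),
             "all volumes in a comparison must share the same grid shape")
  ref
}

as_voxel_matrix <- function(volumes) {
  do.call(cbind, lapply(volumes, as.vector))
}

#' Per-voxel Mann-Whitney rank-sum comparison of two groups
#'
#' Computes, for every voxel, the two-sided Mann-Whitney (Wilcoxon
#' rank-sum) test between the two groups of subject volumes. With a total
#' sample size of at most `exact_max_n` subjects the p-value comes from
#' exhaustive enumeration of all group assignments (tie-safe through
#' midranks). For larger samples, voxels without ties use the exact null
#' distribution of the rank sum (as `wilcox.test` does below n = 50) so
#' that mass-univariate FDR thresholds remain reachable; tied voxels fall
#' back to a tie-corrected, continuity-corrected normal approximation.
#' `approx = "normal"` forces the normal approximation throughout. The
#' returned statistic is the standardized rank sum (positive where group
#' A ranks higher).
#'
#' @param group_a,group_b Lists of congruent 3D arrays (one per subject).
#' @param exact_max_n Total-n threshold for the exact enumeration path.
#' @param approx Large-sample p-value method: `"auto"` (exact Wilcoxon
#'   distribution where there are no ties) or `"normal"`.
#' @return List with 3D arrays `stat` (z-like, sign = A higher) and `p`,
#'   plus `method` (`"enumeration"`, `"wilcox"` or `"normal"`).
#' @export
#' @examples
#' a <- lapply(1:4, function(i) array(i, c(2, 2, 1)))
#' b <- lapply(5:8, function(i) array(i, c(2, 2, 1)))
#' voxel_rank_sum(a, b)$p[1]  # 2/70
voxel_rank_sum <- function(group_a, group_b, exact_max_n = 10,
                           approx = c("auto", "normal")) {
  approx <- match.arg(approx)
  shape <- check_congruent(group_a, group_b)
  xa <- as_voxel_matrix(group_a)
  xb <- as_voxel_matrix(group_b)
  n1 <- ncol(xa)
  n2 <- ncol(xb)
  n <- n1 + n2
  x <- cbind(xa, xb)
  check_that(all(is.finite(x)), "volumes must contain finite values")

  if (n <= exact_max_n) {
    res <- rank_sum_exact(x, n1)
    method <- "enumeration"
  } else if (approx == "normal" || max(n1, n2) >= 50) {
    res <- rank_sum_approx(x, n1, wilcox_untied = FALSE)
    method <- "normal"
  } else {
    res <- rank_sum_approx(x, n1, wilcox_untied = TRUE)
    method <- "wilcox"
  }
  list(
    stat = array(res$z, shape),
    p = array(res$p, shape),
    method = method
  )
}

# Exact two-sided p by enumerating all choose(n, n1) assignments of the
# observed values to group A. Midranks make this tie-safe. Vectorized
# across voxels (rows of x).
rank_sum_exact <- function(x, n1) {
  n <- ncol(x)
  r <- t(apply(x, 1, rank)) # midranks, voxels x n
  if (nrow(x) == 1) r <- matrix(rank(x[1, ]), nrow = 1)
  w_obs <- rowSums(r[, seq_len(n1), drop = FALSE])
  combs <- combn(n, n1)
  sel <- matrix(0, n, ncol(combs))
  sel[cbind(as.vector(combs), rep(seq_len(ncol(combs)), each = n1))] <- 1
  w_all <- r %*% sel # voxels x n_combinations
  p_le <- rowMeans(w_all <= w_obs + 1e-9)
  p_ge <- rowMeans(w_all >= w_obs - 1e-9)
  p <- pmin(1, 2 * pmin(p_le, p_ge))
  sigma <- apply(w_all, 1, sd)
  mu <- n1 * (n + 1) / 2
  z <- ifelse(sigma > 0, (w_obs - mu) / sigma, 0)
  p[sigma == 0] <- 1
  list(z = z, p = p)
}

# Large-sample rank-sum p-values, vectorized across voxels. Untied voxels
# can use the exact Wilcoxon null distribution (pwilcox); tied voxels (and
# everything when wilcox_untied = FALSE) use the tie-corrected,
# continuity-corrected normal approximation.
rank_sum_approx <- function(x, n1, wilcox_untied = TRUE) {
  n <- ncol(x)
  n2 <- n - n1
  stats_vox <- t(apply(x, 1, function(v) {
    r <- rank(v)
    tie_tab <- table(v)
    c(sum(r[seq_len(n1)]), sum(tie_tab^3 - tie_tab))
  }))
  w <- stats_vox[, 1]
  tiesum <- stats_vox[, 2]
  mu <- n1 * (n + 1) / 2
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tiesum / (n * (n - 1)))
  sigma <- sqrt(pmax(sigma2, 0))
  d <- w - mu
  cc <- pmin(abs(d), 0.5) * sign(d) # continuity correction toward the null
  z <- ifelse(sigma > 0, (d - cc) / sigma, 0)
  p <- ifelse(sigma > 0, pmin(1, 2 * pnorm(-abs(z))), 1)
  if (wilcox_untied) {
    untied <- tiesum == 0
    if (any(untied)) {
      u <- w[untied] - n1 * (n1 + 1) / 2
      p_lo <- stats::pwilcox(u, n1, n2)
      p_hi <- stats::pwilcox(u - 1, n1, n2, lower.tail = FALSE)
      p[untied] <- pmin(1, 2 * pmin(p_lo, p_hi))
    }
  }
  z_raw <- ifelse(sigma > 0, d / sigma, 0)
  list(z = z_raw, p = p)
}

#' Benjamini-Hochberg FDR control for a vector or volume of p-values
#'
#' Step-up BH q-values plus the significance mask at level `q_level`.
#'
#' @param p Numeric vector or array of p-values in `[0, 1]` (`NA`s allowed
#'   and propagated).
#' @param q_level FDR level for the mask.
#' @return List with `q` (same shape as `p`) and `mask` (logical,
#'   `q <= q_level`).
#' @export
#' @examples
#' fdr_bh(c(0.01, 0.02, 0.03, 0.04))$q  # all 0.04
fdr_bh <- function(p, q_level = 0.05) {
  check_that(length(p) > 0, "`p` must be non-empty")
  check_that(all(is.na(p) | (p >= 0 & p <= 1)), "p-values must lie in [0, 1]")
  q <- p.adjust(as.vector(p), method = "BH")
  mask <- !is.na(q) & q <= q_level
  if (!is.null(dim(p))) {
    q <- array(q, dim(p))
    mask <- array(mask, dim(p))
  }
  list(q = q, mask = mask)
}

#' Signed voxelwise activity map
#'
#' Runs the per-voxel rank-sum comparison, controls the map at BH
#' `q <= q_level`, and signs significant voxels by the median group
#' difference: `+1` where group A is higher, `-1` where group B is
#' higher, `0` where not significant. Optional isotropic Gaussian
#' pre-smoothing (sigma in um) approximates the smoothing of the original
#' mapping method.
#'
#' @param group_a,group_b Lists of congruent 3D arrays.
#' @param q_level FDR level.
#' @param voxel_size Isotropic voxel size in um (used by smoothing).
#' @param smooth_sigma Optional Gaussian sigma in um applied to every
#'   volume before testing (`NULL` = no smoothing, the default).
#' @param exact_max_n,approx Passed to [voxel_rank_sum()].
#' @return Object of class `activity_map`: arrays `stat`, `p`, `q`,
#'   `mask` (signed -1/0/+1), plus `q_level`, `method`, `n_a`, `n_b`,
#'   `voxel_size`.
#' @export
signed_map <- function(group_a, group_b, q_level = 0.05, voxel_size = 2,
                       smooth_sigma = NULL, exact_max_n = 10,
                       approx = c("auto", "normal")) {
  if (!is.null(smooth_sigma)) {
    check_that(smooth_sigma > 0, "`smooth_sigma` must be > 0")
    group_a <- lapply(group_a, gaussian_smooth_3d, sigma = smooth_sigma / voxel_size)
    group_b <- lapply(group_b, gaussian_smooth_3d, sigma = smooth_sigma / voxel_size)
  }
  rs <- voxel_rank_sum(group_a, group_b, exact_max_n = exact_max_n,
                       approx = approx)
  fdr <- fdr_bh(rs$p, q_level = q_level)
  med_a <- apply(as_voxel_matrix(group_a), 1, median)
  med_b <- apply(as_voxel_matrix(group_b), 1, median)
  sign_map <- array(sign(med_a - med_b), dim(rs$p))
  mask <- array(0L, dim(rs$p))
  mask[fdr$mask] <- as.integer(sign_map[fdr$mask])
  structure(
    list(stat = rs$stat, p = rs$p, q = fdr$q, mask = mask,
         q_level = q_level, method = rs$method,
         n_a = length(group_a), n_b = length(group_b),
         voxel_size = voxel_size),
    class = "activity_map"
  )
}

#' @export
print.activity_map <- function(x, ...) {
  cat(sprintf("<activity_map> %s grid, n = %d vs %d (%s p-values)\n",
              paste(dim(x$p), collapse = " x "), x$n_a, x$n_b, x$method))
  cat(sprintf("  q <= %.3g: %d voxels A-higher, %d B-higher of %d\n",
              x$q_level, sum(x$mask > 0), sum(x$mask < 0), length(x$mask)))
  invisible(x)
}

#' @export
glance.activity_map <- function(x, ...) {
  tibble(
    n_voxels = length(x$mask),
    n_pos = sum(x$mask > 0),
    n_neg = sum(x$mask < 0),
    frac_significant = mean(x$mask != 0),
    q_level = x$q_level,
    method = x$method
  )
}

# Separable Gaussian smoothing of a 3D array (sigma in voxels), with
# renormalization at the edges. Kernel truncated at 3 sigma.
gaussian_smooth_3d <- function(vol, sigma) {
  if (sigma <= 0) {
    return(vol)
  }
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half):half)^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(a, axis) {
    apply_along <- function(v) {
      n <- length(v)
      padded <- c(rep(0, half), v, rep(0, half))
      ones <- c(rep(0, half), rep(1, n), rep(0, half))
      num <- stats::filter(padded, k, sides = 2)
      den <- stats::filter(ones, k, sides = 2)
      (num / den)[(half + 1):(half + n)]
    }
    apply(a, setdiff(1:3, axis), apply_along) |>
      aperm(order(c(axis, setdiff(1:3, axis))))
  }
  out <- vol
  for (ax in 1:3) out <- smooth_axis(out, ax)
  out
}

#' Per-region summary of a signed activity map
#'
#' Counts, within every labeled region of an atlas label volume, the
#' fraction of voxels significantly higher in each group. Label 0 is
#' background by convention and excluded; labels without voxels are
#' skipped with a warning.
#'
#' @param map An [signed_map()] `activity_map`.
#' @param labels Integer 3D array congruent with the map (0 =
#'   background).
#' @param names Optional named character vector mapping label integers to
#'   region names (e.g. `c("1" = "preoptic")`).
#' @return Tibble: `label`, `region`, `n_voxels`, `frac_pos`, `frac_neg`.
#' @export
region_summary <- function(map, labels, names = NULL) {
  check_that(inherits(map, "activity_map"), "`map` must be an activity_map")
  check_that(all(dim(labels) == dim(map$mask)),
             "label volume must be congruent with the map")
  lab_vals <- sort(unique(as.vector(labels)))
  lab_vals <- lab_vals[lab_vals != 0]
  if (!is.null(names)) {
    empty <- setdiff(base::names(names), as.character(lab_vals))
    if (length(empty) > 0) {
      warn(paste0("labels with zero voxels skipped: ",
                  paste(empty, collapse = ", ")))
    }
  }
  purrr::map_dfr(lab_vals, function(l) {
    in_lab <- labels == l
    tibble(
      label = l,
      region = if (!is.null(names) && as.character(l) %in% base::names(names))
        unname(names[as.character(l)]) else paste0("label_", l),
      n_voxels = sum(in_lab),
      frac_pos = mean(map$mask[in_lab] > 0),
      frac_neg = mean(map$mask[in_lab] < 0)
    )
  })
}
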