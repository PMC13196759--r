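vol_list <- function(values_matrix, shape) {
  lapply(seq_len(ncol(values_matrix)),
         function(j) array(values_matrix[, j], shape))
}

test_that("exact rank-sum p matches exhaustive enumeration", {
  a <- lapply(1:4, function(i) array(i, c(2, 2, 1)))
  b <- lapply(5:8, function(i) array(i, c(2, 2, 1)))
  rs <- voxel_rank_sum(a, b)
  expect_equal(rs$method, "enumeration")
  expect_equal(rs$p[1, 1, 1], 2 / 70, tolerance = 1e-12)
  expect_true(all(rs$p == 2 / 70))
  expect_true(all(rs$stat < 0)) # group A ranks lower

  cc <- lapply(1:3, function(i) array(2, c(2, 2, 1)))
  null_rs <- voxel_rank_sum(cc, cc)
  expect_true(all(null_rs$p == 1))
  expect_true(all(null_rs$stat == 0))
})

test_that("exact and approximate p agree with wilcox.test per voxel", {
  set.seed(81)
  shape <- c(5, 5, 4)
  x <- matrix(rnorm(prod(shape) * 10), prod(shape), 10)
  ga <- vol_list(x[, 1:5], shape)
  gb <- vol_list(x[, 6:10], shape)

  pe <- voxel_rank_sum(ga, gb)$p
  pa <- voxel_rank_sum(ga, gb, exact_max_n = 0, approx = "normal")$p
  pw_exact <- vapply(seq_len(nrow(x)), function(v)
    wilcox.test(x[v, 1:5], x[v, 6:10], exact = TRUE)$p.value, numeric(1))
  pw_approx <- vapply(seq_len(nrow(x)), function(v)
    wilcox.test(x[v, 1:5], x[v, 6:10], exact = FALSE,
                correct = TRUE)$p.value, numeric(1))
  expect_equal(as.vector(pe), pw_exact, tolerance = 1e-12)
  expect_equal(as.vector(pa), pw_approx, tolerance = 1e-12)
  # untied auto path uses the exact Wilcoxon distribution, matching the
  # enumeration exactly
  p_auto <- voxel_rank_sum(ga, gb, exact_max_n = 0)$p
  expect_equal(as.vector(p_auto), pw_exact, tolerance = 1e-12)
  expect_lt(max(abs(pa - pe)), 0.05) # approximation error stays small
})

test_that("tied data are handled by midranks on both paths", {
  set.seed(82)
  shape <- c(4, 4, 2)
  x <- matrix(sample(1:4, prod(shape) * 8, replace = TRUE), prod(shape), 8)
  ga <- vol_list(x[, 1:4], shape)
  gb <- vol_list(x[, 5:8], shape)
  pe <- voxel_rank_sum(ga, gb)$p
  expect_true(all(pe >= 0 & pe <= 1))
  pa <- voxel_rank_sum(ga, gb, exact_max_n = 0, approx = "normal")$p
  pw <- vapply(seq_len(nrow(x)), function(v)
    suppressWarnings(wilcox.test(x[v, 1:4], x[v, 5:8],
                                 exact = FALSE, correct = TRUE)$p.value),
    numeric(1))
  expect_equal(as.vector(pa), pw, tolerance = 1e-12)
})

test_that("rank-sum p is invariant under monotone intensity transforms", {
  set.seed(83)
  shape <- c(3, 3, 3)
  x <- matrix(rnorm(prod(shape) * 12, 5), prod(shape), 12)
  ga <- vol_list(x[, 1:6], shape)
  gb <- vol_list(x[, 7:12], shape)
  p0 <- voxel_rank_sum(ga, gb)$p
  ga_t <- lapply(ga, exp)
  gb_t <- lapply(gb, exp)
  expect_equal(voxel_rank_sum(ga_t, gb_t)$p, p0, tolerance = 1e-12)
})

test_that("mismatched or too-small groups are rejected", {
  a <- lapply(1:2, function(i) array(i, c(2, 2, 2)))
  b <- lapply(1:2, function(i) array(i, c(2, 2, 3)))
  expect_error(voxel_rank_sum(a, b), "same grid shape")
  expect_error(voxel_rank_sum(a[1], a), "at least 2")
})

test_that("fdr_bh reproduces the worked examples", {
  expect_equal(as.vector(fdr_bh(c(0.01, 0.02, 0.03, 0.04))$q),
               rep(0.04, 4), tolerance = 1e-12)
  r1 <- fdr_bh(rep(1, 5))
  expect_true(all(r1$q == 1) && !any(r1$mask))
  expect_equal(fdr_bh(0.031)$q, 0.031)
  expect_error(fdr_bh(numeric(0)), "non-empty")
  expect_error(fdr_bh(c(0.5, 1.2)), "\\[0, 1\\]")
  arr <- fdr_bh(array(runif(8), c(2, 2, 2)))
  expect_equal(dim(arr$q), c(2, 2, 2))
})

test_that("signed map marks planted blobs positive and respects q-level gating", {
  blobs <- tibble::tibble(x = 10, y = 10, z = 5, radius = 3, effect = 3)
  ph <- simulate_voxel_groups(c(20, 20, 10), blobs, n_per_group = 10,
                              noise_sd = 1, seed = 84)
  m <- signed_map(ph$group_a, ph$group_b, q_level = 0.05)
  expect_gt(mean(m$mask[ph$blob_mask] == 1), 0.8)
  expect_lt(mean(m$mask[!ph$blob_mask] != 0), 0.01)
  # mask nonzero exactly where q passes the threshold
  expect_equal(m$mask != 0, m$q <= m$q_level)
  # sign matches the median group difference wherever significant
  med_diff <- apply(simplify2array(ph$group_a), 1:3, median) -
    apply(simplify2array(ph$group_b), 1:3, median)
  sig <- m$mask != 0
  expect_equal(m$mask[sig], sign(med_diff)[sig])
})

test_that("swapping the groups negates the statistic and the mask", {
  blobs <- tibble::tibble(x = 6, y = 6, z = 3, radius = 2, effect = 2.5)
  ph <- simulate_voxel_groups(c(12, 12, 6), blobs, n_per_group = 6,
                              noise_sd = 1, seed = 85)
  m_ab <- signed_map(ph$group_a, ph$group_b)
  m_ba <- signed_map(ph$group_b, ph$group_a)
  expect_equal(m_ab$p, m_ba$p, tolerance = 1e-12)
  expect_equal(m_ab$q, m_ba$q, tolerance = 1e-12)
  expect_equal(m_ab$mask, -m_ba$mask)
  expect_equal(m_ab$stat, -m_ba$stat, tolerance = 1e-9)
})

test_that("gaussian pre-smoothing preserves constants and runs end to end", {
  const <- array(3, c(8, 8, 4))
  sm <- photokin:::gaussian_smooth_3d(const, sigma = 1.2)
  expect_equal(sm, const, tolerance = 1e-9)

  blobs <- tibble::tibble(x = 6, y = 6, z = 3, radius = 2, effect = 3)
  ph <- simulate_voxel_groups(c(12, 12, 6), blobs, n_per_group = 5,
                              noise_sd = 1, seed = 86)
  m <- signed_map(ph$group_a, ph$group_b, smooth_sigma = 2, voxel_size = 2)
  expect_s3_class(m, "activity_map")
})

test_that("region summary counts signed fractions per label", {
  blobs <- tibble::tibble(x = 6, y = 6, z = 4, radius = 2, effect = 10)
  ph <- simulate_voxel_groups(c(16, 16, 8), blobs, n_per_group = 10,
                              noise_sd = 0.5, seed = 87)
  m <- signed_map(ph$group_a, ph$group_b)

  labels <- array(0L, c(16, 16, 8))
  labels[1:10, 1:10, ] <- 1L # contains the whole blob
  labels[12:16, 12:16, ] <- 2L # pure background
  rs <- region_summary(m, labels, names = c("1" = "blob_region",
                                            "2" = "control"))
  expect_equal(rs$region, c("blob_region", "control"))
  # counting oracle: positive fraction = flagged blob voxels / label size
  expect_equal(rs$frac_pos[1], sum(m$mask[labels == 1L] > 0) / sum(labels == 1L))
  expect_gt(rs$frac_pos[1], 0.8 * sum(ph$blob_mask) / sum(labels == 1L))
  expect_lt(rs$frac_pos[2] + rs$frac_neg[2], 0.05)
  expect_true(all(rs$frac_pos + rs$frac_neg <= 1))

  # all-zero mask gives all-zero fractions
  null_map <- m
  null_map$mask[] <- 0L
  rs0 <- region_summary(null_map, labels)
  expect_equal(rs0$frac_pos, c(0, 0))
  expect_equal(rs0$frac_neg, c(0, 0))

  expect_warning(region_summary(m, labels, names = c("9" = "ghost")),
                 "zero voxels")
  expect_error(region_summary(m, array(0L, c(2, 2, 2))), "congruent")
})
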