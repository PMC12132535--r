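make_pair <- function(a, b) {
  volume_pair(array(a, dim(a)), array(b, dim(b)))
}

test_that("rank transform orders descending with average ties", {
  v <- array(8:1, c(8, 1, 1))        # strictly decreasing along the array
  r <- rank_transform(v, array(TRUE, dim(v)))
  expect_equal(as.vector(r), 1:8)
  # monotone transforms leave ranks unchanged
  expect_equal(rank_transform(exp(v / 3), array(TRUE, dim(v))), r)
  # hand-worked 8-voxel case with one tie pair
  v2 <- array(c(5, 4, 3, 3, 2, 1, 0.5, 0), c(2, 2, 2))
  r2 <- rank_transform(v2, array(TRUE, c(2, 2, 2)))
  expect_equal(as.vector(r2), c(1, 2, 3.5, 3.5, 5, 6, 7, 8))
  expect_error(rank_transform(array(1, c(2, 2, 2))), "constant")
})

test_that("identical maps give 100% of the attainable mutual information", {
  set.seed(1)
  v <- array(rnorm(10^3), c(10, 10, 10))   # 1000 voxels: exact deciles
  p <- make_pair(v, v)
  res <- mutual_information_percent(p, bins = 10)
  expect_equal(res$mi_percent, 100, tolerance = 1e-9)
  # equal-count bins without ties: the normaliser is log(bins) exactly
  expect_equal(res$h_min, log(10), tolerance = 1e-12)
})

test_that("mutual information is symmetric and bounded by the minimum marginal entropy", {
  set.seed(2)
  a <- array(rnorm(10^3), c(10, 10, 10))
  b <- array(rnorm(10^3), c(10, 10, 10))
  r_ab <- mutual_information_percent(make_pair(a, b))
  r_ba <- mutual_information_percent(make_pair(b, a))
  expect_equal(r_ab$mi_percent, r_ba$mi_percent, tolerance = 1e-12)
  expect_gte(r_ab$mi_nats, 0)
  expect_lte(r_ab$mi_nats, r_ab$h_min + 1e-12)
})

test_that("independent maps give near-zero percent overlap", {
  set.seed(3)
  vals <- vapply(1:10, function(s) {
    set.seed(s)
    a <- array(rnorm(22^3), c(22, 22, 22))
    b <- array(rnorm(22^3), c(22, 22, 22))
    mutual_information_percent(make_pair(a, b))$mi_percent
  }, 0)
  expect_lt(max(vals), 5)
})

test_that("the overlap statistic is invariant to monotone rescaling of either map", {
  vp <- generate_volume_pair(c(14, 14, 14), 0.8, seed = 6)
  base <- mutual_information_percent(vp)$mi_percent
  warped <- volume_pair(vp$tmap^3, exp(vp$efield), mask = vp$mask)
  expect_equal(mutual_information_percent(warped)$mi_percent, base,
               tolerance = 1e-9)
})

test_that("voxel rank correlation hits the sign bounds and a hand-worked case", {
  set.seed(4)
  v <- array(sample(1:512), c(8, 8, 8))   # distinct values, no ties
  expect_equal(voxel_rank_correlation(make_pair(v, v)), 1)
  expect_equal(voxel_rank_correlation(make_pair(v, -v)), -1)
  # 8-voxel case: ranks (1..8) vs (2,1,4,3,6,5,8,7) -> r = 1 - 6*8/(8*63)
  a <- array(8:1, c(2, 2, 2))
  b <- array(c(7, 8, 5, 6, 3, 4, 1, 2), c(2, 2, 2))
  expect_equal(voxel_rank_correlation(make_pair(a, b)),
               1 - 6 * 8 / (8 * 63), tolerance = 1e-12)
})

test_that("overlap-behaviour correlation matches the closed form", {
  mi <- c(10, 20, 30, 40, 55)
  beh <- 0.5 * mi + 3
  expect_equal(correlate_overlap_behavior(mi, beh)$r, 1, tolerance = 1e-12)
  set.seed(5)
  x <- rnorm(8); y <- rnorm(8)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  res <- correlate_overlap_behavior(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-12)
  expect_true(res$r >= -1 && res$r <= 1)
  expect_error(correlate_overlap_behavior(c(1, 1, 1), c(1, 2, 3)),
               "variance")
})

test_that("MNI distance is Euclidean and symmetric", {
  expect_equal(mni_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(mni_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(-27.61, 56.15, 1.22); b <- c(0, -10, 4)
  expect_equal(mni_distance(a, b), mni_distance(b, a))
  expect_error(mni_distance(c(1, 2), c(1, 2, 3)))
})
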