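test_that("the paired t-field equals a scalar paired t at every node", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(4:12, 1)
    q <- sample(c(20, 101), 1)
    a <- matrix(rnorm(n * q), n, q)
    b <- matrix(rnorm(n * q), n, q)
    tf <- paired_t_field(a, b)
    oracle <- vapply(seq_len(q), function(j) {
      unname(t.test(a[, j], b[, j], paired = TRUE)$statistic)
    }, numeric(1))
    expect_lt(max(abs(tf$t - oracle)), 1e-12)
  }
})

test_that("t-field hand examples and antisymmetry hold", {
  a <- matrix(c(1, 2, 3), 3, 1)
  b <- matrix(0, 3, 1)
  expect_equal(paired_t_field(a, b)$t, 3.4641016, tolerance = 1e-7)
  expect_equal(paired_t_field(cbind(a, a), cbind(a, a))$t, c(0, 0))
  set.seed(5)
  x <- matrix(rnorm(50), 5, 10); y <- matrix(rnorm(50), 5, 10)
  expect_equal(paired_t_field(x, y)$t, -paired_t_field(y, x)$t)
})

test_that("zero-variance nonzero-mean nodes flag infinite t", {
  a <- matrix(1, 4, 3); a[, 2] <- 2
  b <- matrix(1, 4, 3)
  tf <- paired_t_field(a, b)
  expect_identical(tf$inf_nodes, 2L)
  expect_identical(tf$t[2], Inf)
  expect_error(paired_t_field(a[1, , drop = FALSE], b[1, , drop = FALSE]),
               class = "cmj_data_error")
})

test_that("the smoothness estimator recovers known kernel widths", {
  set.seed(202)
  est20 <- replicate(200, estimate_fwhm(smooth_gaussian_fields(10, 101, 20))$fwhm)
  expect_gt(mean(est20), 16)
  expect_lt(mean(est20), 24)
  estw <- replicate(50, estimate_fwhm(smooth_gaussian_fields(10, 101, 0))$fwhm)
  expect_lt(max(estw), 3)
  expect_error(estimate_fwhm(matrix(0, 5, 101)), class = "cmj_data_error")
})

test_that("RFT threshold limits, monotonicity and bracketing hold", {
  expect_equal(rft_critical_threshold(9, 0, 0.05, tails = 2),
               qt(0.975, 9), tolerance = 1e-8)
  t_prev <- rft_critical_threshold(9, 0, 0.05)
  for (resels in c(2, 5, 10, 20)) {
    t_now <- rft_critical_threshold(9, resels, 0.05)
    expect_gt(t_now, t_prev)
    # Bonferroni over 101 nodes bounds the smooth-regime threshold
    expect_lte(t_now, qt(1 - 0.025 / 101, 9))
    t_prev <- t_now
  }
  expect_gt(rft_critical_threshold(9, 10, 0.01),
            rft_critical_threshold(9, 10, 0.05))
})

test_that("RFT and permutation thresholds agree on smooth fields", {
  set.seed(303)
  rel <- replicate(20, {
    d <- smooth_gaussian_fields(10, 101, 15)
    sm <- estimate_fwhm(sweep(d, 2, colMeans(d)))
    t_rft <- rft_critical_threshold(9, sm$resels, 0.05)
    t_perm <- permutation_threshold(d, 0.05)
    abs(t_rft - t_perm) / t_rft
  })
  expect_lt(median(rel), 0.10)
})

test_that("cluster extraction reports maximal runs at node resolution", {
  tt <- rep(0, 101)
  tt[37:38] <- 5   # nodes 36-37 in percent
  tt[93:100] <- -5 # nodes 92-99
  cl <- find_clusters(tt, 3, tails = 2)
  expect_equal(cl$start_pct, c(36, 92))
  expect_equal(cl$end_pct, c(37, 99))
  expect_equal(cl$extent, c(2, 8))
  expect_equal(cl$sign, c(1, -1))

  expect_identical(nrow(find_clusters(rep(1, 101), 3)), 0L)
  one <- find_clusters(replace(rep(0, 101), 51, 4), 3)
  expect_equal(one$start_pct, 50)
  expect_equal(one$extent, 1)
  # one-tailed ignores negative excursions
  expect_equal(find_clusters(tt, 3, tails = 1)$start_pct, 36)
})

test_that("cluster p-values are consistent at the zero-extent limit and monotone", {
  nu <- 9
  sm <- structure(list(fwhm = 15, resels = 100 / 15), class = "cmj_smoothness")
  t_star <- rft_critical_threshold(nu, sm$resels, 0.05, tails = 2)
  mk <- function(ext) data.frame(start_pct = 50, end_pct = 50 + ext - 1,
                                 extent = ext, sign = 1)
  p0 <- cluster_p_values(mk(1e-9), sm, nu, t_star, tails = 2)$p
  expect_lt(abs(p0 - 0.05), 0.005)
  ps <- vapply(c(1, 3, 6, 12), function(k) {
    cluster_p_values(mk(k), sm, nu, t_star, tails = 2)$p
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps > 0 & ps <= 1))
})

test_that("RFT cluster p agrees with the sign-flip cluster-extent oracle", {
  set.seed(404)
  d <- smooth_gaussian_fields(10, 101, 15)
  d[, 40:60] <- d[, 40:60] + 1.4 # moderate localized effect
  spm <- spm_paired_test(d, matrix(0, 10, 101), alpha = 0.05, method = "rft")
  expect_gt(nrow(spm$clusters), 0)
  cl <- spm$clusters[which.max(spm$clusters$extent), ]
  p_perm <- cmjkit:::perm_cluster_p(d, spm$t_star, cl$extent, tails = 2)
  expect_lt(abs(cl$p - p_perm), 0.02)
})

test_that("the permutation threshold is exhaustive, deterministic and sensitive", {
  set.seed(505)
  d <- matrix(rnorm(10 * 101), 10, 101)
  t1 <- permutation_threshold(d, 0.05)
  t2 <- permutation_threshold(d, 0.05)
  expect_identical(t1, t2) # 2^10 = 1024 <= 4096: exhaustive

  d2 <- matrix(rnorm(10 * 101, 0, 0.2), 10, 101)
  d2[, 50] <- d2[, 50] + 5 # huge single-node effect
  tf <- paired_t_field(d2, matrix(0, 10, 101))
  expect_gt(max(abs(tf$t)), permutation_threshold(d2, 0.05))

  expect_error(permutation_threshold(d, 0.05, n_resamples = 50),
               class = "cmj_data_error")
})

test_that("identical inputs give an empty cluster list", {
  a <- matrix(rnorm(101 * 5), 5, 101)
  spm <- spm_paired_test(a, a)
  expect_identical(nrow(spm$clusters), 0L)
  expect_equal(spm$t, rep(0, 101))
})

test_that("rft and permutation methods agree on the same data", {
  set.seed(606)
  a <- smooth_gaussian_fields(10, 101, 15)
  b <- smooth_gaussian_fields(10, 101, 15)
  b[, 70:90] <- b[, 70:90] - 1.5
  s_rft <- spm_paired_test(a, b, method = "rft")
  s_perm <- spm_paired_test(a, b, method = "perm")
  expect_lt(abs(s_rft$t_star - s_perm$t_star) / s_rft$t_star, 0.10)
  # cluster sets overlap
  expect_gt(nrow(s_rft$clusters), 0)
  expect_gt(nrow(s_perm$clusters), 0)
  expect_true(any(
    s_rft$clusters$start_pct <= max(s_perm$clusters$end_pct) &
      s_rft$clusters$end_pct >= min(s_perm$clusters$start_pct)
  ))
})
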