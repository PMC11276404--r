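test_that("Bland-Altman summarises paired differences with n-1 SDs", {
  r <- bland_altman(c(10, 12, 8), c(11, 11, 9))
  expect_equal(r$n, 3)
  expect_equal(r$mean_diff, -1 / 3, tolerance = 1e-12)
  expect_equal(r$sd_diff, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(r$loa_low, -1 / 3 - 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(r$loa_high, -1 / 3 + 1.96 * sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(r$loa_low, -2.5966, tolerance = 1e-4)
  expect_equal(r$loa_high, 1.9299, tolerance = 1e-4)
  expect_equal(r$pairs$diff, c(-1, 1, -1))
  expect_equal(r$pairs$mean, c(10.5, 11.5, 8.5))

  ident <- bland_altman(c(4, 7, 9), c(4, 7, 9))
  expect_equal(ident$mean_diff, 0)
  expect_equal(ident$sd_diff, 0)
  expect_equal(c(ident$loa_low, ident$loa_high), c(0, 0))
})

test_that("Bland-Altman translation: adding c to a shifts the mean only", {
  set.seed(11)
  a <- runif(20, 0, 40); b <- a + rnorm(20)
  r0 <- bland_altman(a, b)
  r5 <- bland_altman(a + 5, b)
  expect_equal(r5$mean_diff, r0$mean_diff + 5, tolerance = 1e-12)
  expect_equal(r5$sd_diff, r0$sd_diff, tolerance = 1e-12)
})

test_that("absolute-difference stats and the triangle inequality", {
  expect_equal(abs_diff_stats(c(1, 2, 3), c(1, 2, 3)),
               c(mean = 0, sd = 0))
  r <- abs_diff_stats(c(10, 12, 8), c(11, 11, 9))  # |d| = 1,1,1
  expect_equal(unname(r), c(1, 0), tolerance = 1e-12)
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8)
    expect_gte(abs_diff_stats(a, b)[["mean"]] + 1e-12,
               abs(mean(a - b)))
    ba <- bland_altman(a, b)
    expect_gte(ba$mean_abs_diff + 1e-12, abs(ba$mean_diff))
    expect_lte(ba$loa_low, ba$mean_diff)
    expect_gte(ba$loa_high, ba$mean_diff)
  }
})

test_that("Welch's t matches the hand example and base R", {
  x <- c(10, 12, 14); y <- c(11, 15, 19, 21)
  r <- welch_t(x, y)
  expect_equal(r$t, -1.8, tolerance = 1e-12)
  expect_equal(r$var[["x"]], 4, tolerance = 1e-12)
  expect_equal(r$var[["y"]], 59 / 3, tolerance = 1e-12)
  ref <- t.test(x, y)   # independent route through stats
  expect_equal(r$t, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$df, unname(ref$parameter), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)

  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(welch_t(c(1, 1), c(2, 2)), "zero variance")
})

test_that("the two-sample F test matches the hand example and base R", {
  x <- c(10, 12, 14); y <- c(11, 15, 19, 21)
  r <- variance_f_test(x, y)
  expect_equal(r$F, 4 / (59 / 3), tolerance = 1e-12)
  expect_equal(r$F, 0.2034, tolerance = 1e-4)
  expect_equal(c(r$df1, r$df2), c(2, 3))
  ref <- var.test(x, y)
  expect_equal(r$F, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(r$p, ref$p.value, tolerance = 1e-9)

  same <- variance_f_test(c(1, 5, 9), c(1, 5, 9))
  expect_equal(same$F, 1)
  expect_equal(same$p, 1)
  # reciprocity
  set.seed(13)
  a <- rnorm(9); b <- rnorm(7, sd = 2)
  fab <- variance_f_test(a, b); fba <- variance_f_test(b, a)
  expect_equal(fab$F * fba$F, 1, tolerance = 1e-12)
  expect_equal(fab$p, fba$p, tolerance = 1e-12)
})

test_that("Pearson correlation matches hand examples and is symmetric", {
  expect_equal(pearson_r(1:5, 2 * (1:5)), 1, tolerance = 1e-12)
  expect_equal(pearson_r(c(1, 2, 3), c(6, 4, 5)), -0.5, tolerance = 1e-12)
  set.seed(14)
  x <- rnorm(15); y <- rnorm(15)
  expect_equal(pearson_r(x, y), pearson_r(y, x), tolerance = 1e-12)
  expect_equal(pearson_r(x, y), cor(x, y), tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "constant")
})

test_that("Williams' test matches the hand evaluation of its formula", {
  r <- williams_test(0.5, 0.3, 0.4, 100)
  expect_equal(r$det_R, 0.62, tolerance = 1e-12)
  expect_equal(r$df, 97)
  # frozen from an explicit evaluation of the closed form
  expect_equal(r$t, 0.2 * sqrt(99 * 1.4 / (2 * (99 / 97) * 0.62 +
                                             0.16 * 0.6^3)),
               tolerance = 1e-12)
  expect_equal(r$t, 2.065, tolerance = 1e-3)
  # equal correlations give t = 0, p = 1 regardless of r23
  for (r23 in c(-0.2, 0, 0.5)) {
    z <- williams_test(0.4, 0.4, r23, 30)
    expect_equal(z$t, 0)
    expect_equal(z$p, 1)
  }
  expect_error(williams_test(0.9, -0.9, 0.9, 50), "positive definite")
  expect_error(williams_test(1, 0.5, 0.5, 50), "strictly")
})

test_that("Pearson and Williams are invariant to affine rescaling", {
  set.seed(15)
  x <- rmvnorm3(40, 0.5, 0.4, 0.3)
  t0 <- williams_t_of(x)
  x2 <- x
  x2[, 1] <- 3 * x2[, 1] - 7
  x2[, 2] <- 0.5 * x2[, 2] + 2
  t1 <- williams_t_of(x2)
  expect_equal(t0$t, t1$t, tolerance = 1e-9)
  expect_equal(t0$p, t1$p, tolerance = 1e-9)
  expect_equal(pearson_r(x[, 1], x[, 2]),
               pearson_r(3 * x[, 1] - 7, x[, 2]), tolerance = 1e-12)
})

test_that("p-values stay in (0, 1] across random inputs", {
  set.seed(16)
  for (i in 1:30) {
    x <- rnorm(sample(3:10, 1)); y <- rnorm(sample(3:10, 1))
    pw <- welch_t(x, y)$p
    pf_ <- variance_f_test(x, y)$p
    expect_gt(pw, 0); expect_lte(pw, 1)
    expect_gt(pf_, 0); expect_lte(pf_, 1)
  }
})

test_that("range truncation keeps pairs whose mean lies inside the bounds", {
  a <- c(2, 6, 42); b <- c(4, 4, 38)   # means 3, 5, 40
  r <- range_truncate(a, b, 4.3, 37.3)
  expect_equal(r$n_retained, 1)
  expect_equal(r$n_removed, 2)
  expect_equal(r$a, 6); expect_equal(r$b, 4)
  all_in <- range_truncate(a, b, -1000, 1000)
  expect_identical(all_in$a, a)
  expect_identical(all_in$b, b)
  # order preserved, output a subset
  set.seed(17)
  aa <- runif(30, 0, 50); bb <- runif(30, 0, 50)
  rr <- range_truncate(aa, bb, 10, 30)
  expect_identical(rr$a, aa[rr$kept])
  expect_error(range_truncate(a, b, 5, 5), "lo < hi")
})

test_that("consistency comparison bundles the mean and variance tests", {
  set.seed(18)
  ra <- rnorm(41, 0.25, 0.5); rb <- rnorm(41, 0.68, 1.5)
  cc <- consistency_compare(ra, rb)
  expect_equal(cc$summary$sd, c(sd(ra), sd(rb)), tolerance = 1e-12)
  expect_equal(cc$welch$p, welch_t(ra, rb)$p, tolerance = 1e-12)
  expect_equal(cc$f$p, variance_f_test(ra, rb)$p, tolerance = 1e-12)
  # identical inputs: both tests are exactly null
  same <- consistency_compare(ra, ra + 0)
  expect_equal(same$welch$p, 1)
  expect_equal(same$f$p, 1)
  # swapping the arguments inverts F and preserves its p
  sw <- consistency_compare(rb, ra)
  expect_equal(sw$f$F * cc$f$F, 1, tolerance = 1e-12)
  expect_equal(sw$f$p, cc$f$p, tolerance = 1e-12)
})
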