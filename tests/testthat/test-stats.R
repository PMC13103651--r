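# The inferential layer: pooled/Welch t tests, Pearson tests with Fisher
# CIs, delta-delta correlations. Cross-checked against stats::t.test and
# stats::cor.test as independent implementations.

test_that("pooled t from raw data equals the summary route and t.test", {
  set.seed(2)
  a <- rnorm(14, 1); b <- rnorm(19)
  raw <- two_sample_t(a, b)
  summ <- two_sample_t(list(mean = mean(a), sd = sd(a), n = length(a)),
                       list(mean = mean(b), sd = sd(b), n = length(b)))
  expect_identical(raw$t, summ$t)
  expect_identical(raw$p, summ$p)
  ref <- t.test(a, b, var.equal = TRUE)
  expect_equal(raw$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(raw$p, ref$p.value, tolerance = 1e-12)
  w <- two_sample_t(a, b, method = "welch")
  refw <- t.test(a, b)
  expect_equal(w$t, unname(refw$statistic), tolerance = 1e-12)
  expect_equal(w$df, unname(refw$parameter), tolerance = 1e-10)
})

test_that("t test handles hand-computed and degenerate cases", {
  # pooled SE = sqrt(2/3), diff = -1 -> t = -1.2247 on df 4
  tt <- two_sample_t(c(1, 2, 3), c(2, 3, 4))
  expect_equal(tt$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(tt$t, -1.2247, tolerance = 1e-4)
  expect_equal(tt$df, 4)
  same <- two_sample_t(c(3, 5, 7), c(3, 5, 7))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  const <- two_sample_t(c(2, 2, 2), c(2, 2, 2))
  expect_equal(const$t, 0)
  expect_error(two_sample_t(c(2, 2, 2), c(3, 3, 3)),
               class = "fctarget_data_error")
  expect_error(two_sample_t(1, c(1, 2)), class = "fctarget_arg_error")
})

test_that("pearson_test reproduces exact correlations and matches cor.test", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_test(x, x)$r, 1)
  expect_equal(pearson_test(x, x)$p, 0)
  expect_equal(pearson_test(x, -2 * x + 3)$r, -1)
  # hand covariance computation: cov = 5/3, var_x = var_y = 5/3 -> r = 0.8
  res <- pearson_test(x, c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  ref <- cor.test(x, c(1, 3, 2, 4))
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  set.seed(31)
  u <- rnorm(40); v <- 0.4 * u + rnorm(40)
  res2 <- pearson_test(u, v)
  ref2 <- cor.test(u, v)
  expect_equal(res2$r, unname(ref2$estimate), tolerance = 1e-12)
  expect_equal(res2$p, ref2$p.value, tolerance = 1e-12)
  expect_equal(res2$ci, as.numeric(ref2$conf.int), tolerance = 1e-3)
  expect_true(res2$ci[1] <= res2$r && res2$r <= res2$ci[2])
  expect_error(pearson_test(u, rep(1, 40)), class = "fctarget_data_error")
  expect_error(pearson_test(1:2, 1:2), class = "fctarget_arg_error")
})

test_that("pearson_test p values are uniform under the null", {
  set.seed(1)
  p <- replicate(2000, pearson_test(rnorm(30), rnorm(30))$p)
  ks <- suppressWarnings(ks.test(p, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("delta_correlation works on differences and flags degenerate input", {
  set.seed(7)
  pre <- rnorm(20); post <- pre + rnorm(20, 0.3)
  f_pre <- rnorm(20, 8); f_post <- f_pre - (post - pre) # exact anticoupling
  res <- delta_correlation(pre, post, f_pre, f_post)
  expect_equal(res$r, -1)
  expect_error(delta_correlation(pre, pre, f_pre, f_post),
               class = "fctarget_data_error")  # all-zero FC deltas
  expect_error(delta_correlation(pre, post[1:5], f_pre, f_post),
               class = "fctarget_arg_error")
})
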