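# The denoising chain: frame dropping, FD, censoring, 36P confounds,
# nuisance regression, band-pass, smoothing.

# Minimal surface-space run: one vertex per data column (padded to >= 3
# columns so a triangle exists).
toy_run <- function(data, tr = 2, ...) {
  data <- as.matrix(data)
  if (ncol(data) < 3) data <- cbind(data, matrix(0, nrow(data),
                                                 3 - ncol(data)))
  mesh <- surface_mesh(cbind(seq_len(ncol(data)) - 1, 0, 0), cbind(1, 2, 3))
  bold_run(data, tr, mesh, ...)
}

test_that("drop_initial_frames trims data, mask, motion and seed series", {
  mesh <- surface_mesh(cbind(0:10, 0, 0), cbind(1, 2, 3))
  n <- 240
  run <- bold_run(matrix(rnorm(n * 11), n, 11), 2, mesh,
                  mask = c(rep(TRUE, 239), FALSE),
                  motion = matrix(0, n, 6), seed_ts = seq_len(n))
  out <- drop_initial_frames(run, 10)
  expect_equal(nrow(out$data), 230)      # 240-frame acquisition -> 230 retained
  expect_equal(length(out$mask), 230)
  expect_equal(nrow(out$motion), 230)
  expect_equal(out$seed_ts[1], 11)
  expect_identical(drop_initial_frames(run, 0), run)
  expect_error(drop_initial_frames(run, 240), class = "fctarget_arg_error")
})

test_that("framewise displacement sums parameter steps, rotations as arc", {
  m <- matrix(0.3, 10, 6)
  expect_equal(framewise_displacement(m), rep(0, 10))  # constant -> 0
  m2 <- matrix(0, 10, 6)
  m2[5:10, 1] <- 0.3                                   # single-axis step
  expect_equal(framewise_displacement(m2)[5], 0.3)
  expect_equal(framewise_displacement(m2)[6], 0)
  m3 <- matrix(0, 10, 6)
  m3[4:10, 5] <- 0.01                                  # 0.01 rad rotation step
  expect_equal(framewise_displacement(m3, head_radius_mm = 50)[4], 0.5)
  expect_error(framewise_displacement(matrix(NA_real_, 5, 6)),
               class = "fctarget_data_error")
})

test_that("censoring is strict and monotone in the threshold", {
  run <- toy_run(matrix(rnorm(9), 3, 3))
  fd <- c(0.1, 0.6, 0.4)
  expect_identical(censor(run, fd, 0.5)$mask, c(TRUE, FALSE, TRUE))
  expect_identical(censor(run, c(0.2, 0.5, 0.3), 0.5)$mask, rep(TRUE, 3))
  # frame at exactly the threshold is retained (strictly greater-than)
  expect_identical(censor(run, c(0.5, 0.5, 0.5), 0.5)$mask, rep(TRUE, 3))
  expect_error(censor(run, c(0.1, 0.2), 0.5), class = "fctarget_arg_error")
  # lowering the threshold never increases the retained count
  set.seed(11)
  fd <- abs(rnorm(3))
  thresholds <- seq(1.5, 0.05, by = -0.05)
  kept <- vapply(thresholds, function(th) sum(censor(run, fd, th)$mask),
                 numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("the 36P confound matrix has the documented columns and structure", {
  n <- 30
  set.seed(4)
  motion <- matrix(rnorm(n * 6), n, 6)
  tissue <- matrix(rnorm(n * 3), n, 3)
  cm <- build_confounds_36p(motion, tissue)
  expect_equal(ncol(cm), 36)
  expect_equal(nrow(cm), n)
  expect_identical(colnames(cm)[1:9],
                   c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y",
                     "rot_z", "global_signal", "white_matter", "csf"))
  expect_true(all(grepl("_derivative1$", colnames(cm)[10:18])))
  expect_true(all(grepl("_power2$", colnames(cm)[19:36])))
  # derivative columns: backward differences with first element 0
  expect_equal(cm[, "trans_x_derivative1"], c(0, diff(motion[, 1])))
  # squares of the first 18 columns
  expect_equal(unname(cm[, 19:36]), unname(cm[, 1:18]^2))
  # all-zero inputs -> 36 zero columns
  z <- build_confounds_36p(matrix(0, n, 6), matrix(0, n, 3))
  expect_true(all(z == 0))
  # constant motion column -> zero derivative, constant square
  motion2 <- motion; motion2[, 2] <- 1.7
  cm2 <- build_confounds_36p(motion2, tissue)
  expect_true(all(cm2[, "trans_y_derivative1"] == 0))
  expect_true(all(cm2[, "trans_y_power2"] == 1.7^2))
  expect_error(build_confounds_36p(motion, tissue[, 1:2]),
               class = "fctarget_arg_error")
})

test_that("nuisance regression matches hand-computed least squares", {
  # 4 frames, 1 location: data [1,2,3,4] on regressor [1,1,2,2] + intercept.
  # Group means are 1.5 and 3.5, so residuals are [-0.5, 0.5, -0.5, 0.5].
  run <- toy_run(cbind(c(1, 2, 3, 4)))
  out <- regress_out(run, cbind(c(1, 1, 2, 2)))
  expect_equal(out$data[, 1], c(-0.5, 0.5, -0.5, 0.5))
})

test_that("regression residuals are orthogonal to confounds and idempotent", {
  set.seed(21)
  n <- 60
  run <- toy_run(matrix(rnorm(n * 8), n, 8),
                 mask = c(rep(TRUE, 25), FALSE, FALSE, rep(TRUE, 33)))
  conf <- matrix(rnorm(n * 5), n, 5)
  out <- regress_out(run, conf)
  keep <- out$mask
  cc <- abs(cor(out$data[keep, ], conf[keep, ]))
  expect_lt(max(cc), 1e-8)
  # residual at a censored frame is the linear interpolant of neighbours
  expect_equal(out$data[26, ], out$data[25, ] + (out$data[28, ] -
                 out$data[25, ]) * (26 - 25) / (28 - 25))
  # applying the regression twice equals once
  twice <- regress_out(out, conf)
  expect_equal(twice$data, out$data, tolerance = 1e-10)
  # run equal to a confound column -> zero residuals on retained frames
  run2 <- toy_run(cbind(conf[, 3]))
  out2 <- regress_out(run2, conf)
  expect_lt(max(abs(out2$data[, 1])), 1e-10)
  # collinear design columns are dropped with a warning
  expect_warning(regress_out(run, cbind(conf, conf[, 1] * 2)),
                 "collinear")
})

test_that("band-pass keeps the pass band and rejects DC and fast signals", {
  n <- 230; tr <- 2
  t <- (seq_len(n) - 1) * tr
  mesh <- path_mesh(4)
  mk <- function(f) {
    x <- if (f == 0) rep(1, n) else sin(2 * pi * f * t)
    bold_run(cbind(x, x, x, x, 0, 0, 0), tr, mesh)
  }
  amp_ratio <- function(f) {
    out <- bandpass(mk(f))
    sd(out$data[, 1]) / max(sd(mk(f)$data[, 1]), 1e-30)
  }
  out0 <- bandpass(mk(0))
  expect_lt(max(abs(out0$data)), 0.01)      # DC attenuated >= 99%
  expect_gt(amp_ratio(0.05), 0.8)           # pass-band centre retained
  expect_lt(amp_ratio(0.2), 0.2)            # stop band attenuated >= 80%
  expect_error(bandpass(mk(0.05), 0.01, 0.3), class = "fctarget_arg_error")
})

test_that("volume smoothing preserves constants, mass, and the kernel peak", {
  g <- make_grid(c(25, 25, 25), voxel_mm = 2)
  const <- fc_map(rep(2.5, prod(g$shape)), g, scale = "z")
  expect_equal(smooth_map(const, 6)$values, const$values)

  # unit impulse in the interior: mass conserved, peak = central kernel
  # weight, computed here from the analytic Gaussian independently
  arr <- array(0, dim = g$shape)
  arr[13, 13, 13] <- 1
  imp <- fc_map(as.vector(arr), g, scale = "z")
  sm <- smooth_map(imp, 6)
  expect_equal(sum(sm$values), 1, tolerance = 1e-6)
  sigma_vox <- 6 / (2 * sqrt(2 * log(2))) / 2    # 1.2740 voxels
  expect_equal(sigma_vox, 1.27398, tolerance = 1e-4)
  offs <- -ceiling(4 * sigma_vox):ceiling(4 * sigma_vox)
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  w0 <- (w / sum(w))[offs == 0]
  expect_equal(max(sm$values), w0^3, tolerance = 1e-10)
  expect_equal(which.max(array(sm$values, g$shape)[, 13, 13]), 13)
  expect_error(smooth_map(imp, -1), class = "fctarget_arg_error")
})

test_that("surface smoothing preserves constants and reduces local variance", {
  mesh <- small_mesh()
  const <- fc_map(rep(1.25, nrow(mesh$vertices)), mesh, scale = "z")
  expect_equal(smooth_map(const, 6)$values, const$values)
  set.seed(8)
  noisy <- fc_map(rnorm(nrow(mesh$vertices)), mesh, scale = "z")
  expect_lt(var(smooth_map(noisy, 12)$values), var(noisy$values))
})
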