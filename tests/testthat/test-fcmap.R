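# Seed FC maps: seed averaging, Pearson maps, Fisher z, map averaging.

test_that("seed_mean_timeseries averages labelled voxels on retained frames", {
  g <- make_grid(c(6, 6, 6), voxel_mm = 4)
  g$labels[] <- 0L
  g$labels[1, 1, 1] <- 231L
  g$labels[2, 1, 1] <- 240L
  n <- 6
  data <- matrix(0, n, prod(g$shape))
  data[, 1] <- c(1, 3, 5, 7, 9, 11)
  data[, 2] <- c(3, 5, 7, 9, 11, 13)
  run <- bold_run(data, 2, g, mask = c(rep(TRUE, 5), FALSE))
  expect_equal(seed_mean_timeseries(run), c(2, 4, 6, 8, 10))
  # single-location seed -> that location's series
  g2 <- g; g2$labels[2, 1, 1] <- 0L
  run2 <- bold_run(data, 2, g2)
  expect_equal(seed_mean_timeseries(run2), data[, 1])
  # label outside the default seed set -> empty seed is an error
  expect_error(seed_mean_timeseries(run, seed_labels = 999),
               class = "fctarget_arg_error")
})

test_that("correlation_map reproduces exact correlations", {
  set.seed(5)
  n <- 40
  s <- rnorm(n)
  ortho <- residuals(lm(rnorm(n) ~ s))      # constructed orthogonal series
  data <- cbind(s, -s, ortho, rnorm(n), 1)  # last column constant
  mesh <- surface_mesh(cbind(0:4, 0, 0), cbind(1, 2, 3))
  run <- bold_run(data, 2, mesh)
  expect_warning(m <- correlation_map(run, s), "constant")
  expect_equal(m$values[1], 1)
  expect_equal(m$values[2], -1)
  expect_lt(abs(m$values[3]), 1e-12)
  expect_equal(m$values[5], 0)
  expect_identical(m$scale, "r")
  expect_error(correlation_map(run, rep(1, n)), class = "fctarget_data_error")
})

test_that("correlation is invariant to positive affine rescaling", {
  set.seed(9)
  n <- 50
  s <- rnorm(n)
  data <- matrix(rnorm(n * 3), n, 3)
  mesh <- surface_mesh(cbind(0:2, 0, 0), cbind(1, 2, 3))
  r1 <- correlation_map(bold_run(data, 2, mesh), s)$values
  r2 <- correlation_map(bold_run(data * 3.7 + 11, 2, mesh), s)$values
  r3 <- correlation_map(bold_run(data, 2, mesh), 0.2 * s - 5)$values
  expect_equal(r1, r2, tolerance = 1e-12)
  expect_equal(r1, r3, tolerance = 1e-12)
})

test_that("fisher_z matches atanh, clips at |r| = 1, and is odd", {
  mesh <- surface_mesh(cbind(0:3, 0, 0), cbind(1, 2, 3))
  rvals <- c(0, 0.5, -0.5, 1)
  m <- fc_map(rvals, mesh, scale = "r")
  z <- fisher_z(m)
  expect_identical(z$scale, "z")
  expect_equal(z$values[1], 0)
  expect_equal(z$values[2], 0.549306, tolerance = 1e-6)
  expect_equal(z$values[2], atanh(0.5))
  expect_true(is.finite(z$values[4]))
  expect_equal(z$values[4], atanh(1 - 1e-7))
  # odd and strictly monotone over a grid of r values
  r <- seq(-0.95, 0.95, by = 0.05)
  zp <- fisher_z(fc_map(r, path_mesh(20), scale = "r"))$values
  zn <- fisher_z(fc_map(-r, path_mesh(20), scale = "r"))$values
  expect_equal(zp, -zn)
  expect_true(all(diff(zp) > 0))
  expect_error(fisher_z(z), class = "fctarget_arg_error")
})

test_that("multi-run subjects combine by map averaging or concatenation", {
  mesh <- tiny_mesh()
  f <- connectivity_field(mesh, neg_peak = 1L, pos_peak = 22L)
  r1 <- simulate_bold(f, 60, 2, seed = 1)
  r2 <- simulate_bold(f, 60, 2, seed = 2)
  z1 <- fisher_z(correlation_map(r1, r1$seed_ts))
  z2 <- fisher_z(correlation_map(r2, r2$seed_ts))
  comb <- combine_run_maps(list(z1, z2), provenance = "sub-p001")
  expect_equal(comb$values, (z1$values + z2$values) / 2)
  expect_identical(comb$provenance, "sub-p001")
  cat_run <- concatenate_runs(list(r1, r2))
  expect_equal(nrow(cat_run$data), 120)
  expect_equal(cat_run$seed_ts, c(r1$seed_ts, r2$seed_ts))
  # concatenating a run with itself reproduces that run's correlations
  twice <- concatenate_runs(list(r1, r1))
  expect_equal(correlation_map(twice, twice$seed_ts)$values,
               correlation_map(r1, r1$seed_ts)$values, tolerance = 1e-12)
  other <- simulate_bold(connectivity_field(small_mesh()), 60, 2, seed = 1)
  expect_error(concatenate_runs(list(r1, other)),
               class = "fctarget_arg_error")
})

test_that("average_maps equals a per-location loop and validates spaces", {
  mesh <- small_mesh()
  nv <- nrow(mesh$vertices)
  set.seed(3)
  maps <- lapply(1:5, function(i) fc_map(rnorm(nv), mesh, scale = "z",
                                         provenance = paste0("s", i)))
  avg <- average_maps(maps)
  # brute-force oracle: explicit per-location mean
  oracle <- vapply(seq_len(nv), function(v)
    mean(vapply(maps, function(m) m$values[v], numeric(1))), numeric(1))
  expect_identical(avg$values, oracle)
  expect_identical(avg$provenance, "normative")
  expect_equal(average_maps(maps[1])$values, maps[[1]]$values)
  neg <- fc_map(-maps[[1]]$values, mesh, scale = "z")
  expect_equal(average_maps(list(maps[[1]], neg))$values, rep(0, nv))
  raw <- fc_map(rnorm(nv), mesh, scale = "r")
  expect_error(average_maps(list(maps[[1]], raw)), class = "fctarget_arg_error")
  other <- fc_map(rnorm(12), make_mesh(0, 80), scale = "z")
  expect_error(average_maps(list(maps[[1]], other)),
               class = "fctarget_arg_error")
})
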