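# The synthetic-cohort generator: planted fields, BOLD synthesis, motion,
# cross-sectional and longitudinal cohorts. Sampling-variability checks use
# the generator's effective sample size (band-limited noise carries fewer
# independent samples than frames).

test_that("connectivity fields have their extrema at the planted peaks", {
  mesh <- small_mesh()
  f <- connectivity_field(mesh)
  expect_true(all(abs(f$rho) < 1))
  expect_equal(which.min(f$rho), f$neg_peak)
  expect_equal(which.max(f$rho), f$pos_peak)
  # peaks can be planted by vertex index too
  f2 <- connectivity_field(mesh, neg_peak = 5L, pos_peak = 100L)
  expect_equal(f2$neg_peak, 5L)
  expect_error(connectivity_field(mesh, neg_peak = 5L, pos_peak = 5L),
               class = "fctarget_arg_error")
})

test_that("simulate_bold is deterministic and respects degenerate mixing", {
  mesh <- tiny_mesh()
  f <- connectivity_field(mesh, neg_peak = 1L, pos_peak = 22L)
  r1 <- simulate_bold(f, 60, 2, seed = 42)
  r2 <- simulate_bold(f, 60, 2, seed = 42)
  expect_identical(r1$data, r2$data)
  expect_identical(r1$seed_ts, r2$seed_ts)
  r3 <- simulate_bold(f, 60, 2, seed = 43)
  expect_false(identical(r1$data, r3$data))
  # rho ~ 1 -> noise term vanishes, sample correlation -> 1
  f1 <- f; f1$rho[] <- 0.999999
  run <- simulate_bold(f1, 60, 2, seed = 1)
  expect_gt(min(cor(run$seed_ts, run$data)), 0.999)
  f_bad <- f; f_bad$rho[3] <- 1
  expect_error(simulate_bold(f_bad, 60), class = "fctarget_arg_error")
  expect_error(simulate_bold(f, 10), class = "fctarget_arg_error")
})

test_that("null-field sample correlations match the effective-n band", {
  mesh <- work_mesh()
  f0 <- connectivity_field(mesh)
  f0$rho[] <- 0
  neff <- fctarget:::effective_n(230, 2, 0.01, 0.08)
  frac <- vapply(mc_seeds(), function(s) {
    run <- simulate_bold(f0, 230, 2, seed = s)
    mean(abs(cor(run$seed_ts, run$data)) < 2 / sqrt(neff))
  }, numeric(1))
  # a 2-sigma band holds its nominal coverage (2*pnorm(2)-1 = 0.954)
  expect_lt(abs(mean(frac) - (2 * pnorm(2) - 1)), 0.01)
})

test_that("generator fidelity: sample r is unbiased with the predicted SD", {
  mesh <- work_mesh()
  f <- work_field(mesh)
  neff <- fctarget:::effective_n(230, 2, 0.01, 0.08)
  bias <- sdr <- numeric(20)
  for (s in mc_seeds()) {
    run <- simulate_bold(f, 230, 2, seed = s)
    r <- as.vector(cor(run$seed_ts, run$data))
    bias[s] <- mean(r - f$rho)
    sdr[s] <- sd(r - f$rho)
  }
  expect_lt(abs(mean(bias)), 0.02)
  expect_lt(abs(mean(sdr) / (1 / sqrt(neff - 1)) - 1), 0.2)
})

test_that("simulate_motion plants spikes and reproduces under a seed", {
  m <- simulate_motion(100, spike_frames = c(30, 60), spike_mm = 0.6, seed = 5)
  fd <- framewise_displacement(m)
  expect_gte(fd[30], 0.6)
  expect_gte(fd[60], 0.6)
  expect_lt(median(fd), 0.2)
  expect_identical(m, simulate_motion(100, c(30, 60), 0.6, seed = 5))
  # zero drift, no spikes -> exactly zero parameters
  z <- simulate_motion(50, seed = 1, drift_sd = 0)
  expect_true(all(z == 0))
  expect_error(simulate_motion(50, spike_frames = 60),
               class = "fctarget_arg_error")
})

test_that("cohorts couple FS14 to true connectivity as planted", {
  mesh <- small_mesh()
  f <- work_field(mesh)
  # b = 0, no score noise -> every patient FS14 equals round(a)
  t0 <- cohort_truth(f, coupling_r = 0, fs14_sd = 0)
  co <- simulate_cohort(t0, 5, seed = 3, signals = FALSE)
  pat <- co$phenotypes$group == "patient"
  expect_true(all(co$phenotypes$fs14[pat] == round(t0$a)))
  # scores always clipped to their scales
  t1 <- cohort_truth(f, fs14_mean = 13, fs14_sd = 6)
  co1 <- simulate_cohort(t1, 30, seed = 4, signals = FALSE)
  expect_true(all(co1$phenotypes$fs14 >= 0 & co1$phenotypes$fs14 <= 14))
  expect_true(all(co1$phenotypes$hamd >= 0 & co1$phenotypes$hamd <= 88))
  # full determinism including ordering
  co2 <- simulate_cohort(t1, 30, seed = 4, signals = FALSE)
  expect_identical(co1$phenotypes, co2$phenotypes)
  expect_error(simulate_cohort(t1, 2), class = "fctarget_arg_error")
})

test_that("planted FS14 coupling is recovered across generator seeds", {
  truth <- work_truth()
  band <- r_sampling_band(-0.3, 100)
  rs <- vapply(mc_seeds(), function(s) {
    co <- simulate_cohort(truth, 100, seed = s, signals = FALSE)
    pat <- co$phenotypes$group == "patient"
    z <- vapply(co$subjects[pat], `[[`, numeric(1), "z_neg_true")
    cor(z, co$phenotypes$fs14[pat])
  }, numeric(1))
  expect_gte(mean(rs >= band[1] & rs <= band[2]), 0.9)
  expect_lt(mean(rs), 0)
})

test_that("longitudinal cohorts plant the delta-delta coupling", {
  truth <- work_truth(mesh = small_mesh())
  # zero treatment effect and no score noise -> all deltas vanish
  t0 <- cohort_truth(work_field(small_mesh()), treat_effect_mean = 0,
                     treat_effect_sd = 0, delta_fs14_sd = 0)
  lo0 <- simulate_longitudinal(t0, 5, seed = 2, signals = FALSE)
  expect_equal(lo0$delta_z_true, rep(0, 5))
  expect_equal(lo0$phenotypes$fs14_post, lo0$phenotypes$fs14)
  # planted coupling of -0.4 at n = 35: recovered within +-0.3 in >= 90%
  # of seeds, and negative in sign
  dd <- vapply(mc_seeds(), function(s) {
    lo <- simulate_longitudinal(truth, 35, seed = s, signals = FALSE)
    cor(lo$delta_z_true, lo$phenotypes$fs14_post - lo$phenotypes$fs14)
  }, numeric(1))
  expect_gte(mean(abs(dd + 0.4) < 0.3), 0.9)
  expect_gt(mean(dd < 0), 0.9)
})

test_that("the pre-treatment arm equals the patient arm of a cohort", {
  truth <- work_truth(mesh = small_mesh())
  lo <- simulate_longitudinal(truth, 4, n_frames = 40, seed = 9)
  co <- simulate_cohort(truth, 4, n_frames = 40, seed = 9,
                        groups = "patient")
  for (i in 1:4) {
    expect_identical(lo$subjects[[i]]$pre$run$data, co$subjects[[i]]$run$data)
    expect_identical(lo$subjects[[i]]$pre$fs14, co$subjects[[i]]$fs14)
  }
})
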