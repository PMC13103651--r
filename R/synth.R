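# Synthetic cohorts with planted ground truth. The generator emulates the
# statistical structure the analysis assumes -- a smooth seed-correlation
# field with one positive and one negative peak, spatially smooth
# between-subject variation, band-limited BOLD noise, motion spikes,
# 36P-family confound contamination, and a fatigue score coupled to the
# subject's true connectivity at the negative peak -- so that every stage
# of the pipeline can be validated by parameter recovery.

#' Construct a planted seed-correlation field
#'
#' The per-location true correlation with the seed signal: a small positive
#' baseline (diffuse thalamocortical coupling) plus a positive and a
#' negative Gaussian bump centred on two planted peak locations. By
#' construction the field's maximum is at the positive peak and its minimum
#' at the negative peak.
#'
#' @param space A `surface_mesh` or `volume_grid`.
#' @param neg_peak,pos_peak Planted peak locations: a vertex/voxel index,
#'   or an xyz mm coordinate snapped to the nearest location. Defaults put
#'   the negative peak in left lateral-occipital direction and the positive
#'   peak in medial-frontal direction.
#' @param neg_amp,pos_amp Bump amplitudes (positive reals).
#' @param baseline Background correlation level.
#' @param sigma_mm Gaussian width of the bumps along the surface (geodesic)
#'   or through the volume (Euclidean), in mm.
#' @return An object of class `connectivity_field` with elements `rho`
#'   (per-location true correlation), `neg_peak`, `pos_peak` (indices),
#'   and `space`.
#' @export
connectivity_field <- function(space,
                               neg_peak = c(-51, -77.5, 7),
                               pos_peak = c(2.8, 29.7, 26.5),
                               neg_amp = 0.5, pos_amp = 0.45,
                               baseline = 0.05, sigma_mm = 18) {
  check_scalar_number(neg_amp, "neg_amp", positive = TRUE)
  check_scalar_number(pos_amp, "pos_amp", positive = TRUE)
  check_scalar_number(sigma_mm, "sigma_mm", positive = TRUE)
  resolve <- function(loc) {
    if (length(loc) == 3L && !inherits(space, "volume_grid") ||
        (length(loc) == 3L && any(loc != round(loc))))
      return(space_nearest(space, loc))
    if (length(loc) == 1L) return(as.integer(loc))
    space_nearest(space, loc)
  }
  ni <- resolve(neg_peak); pi_ <- resolve(pos_peak)
  if (ni == pi_) stop_arg("the two peaks must be distinct locations")
  dn <- space_distances(space, ni)
  dp <- space_distances(space, pi_)
  rho <- baseline + pos_amp * exp(-dp^2 / (2 * sigma_mm^2)) -
    neg_amp * exp(-dn^2 / (2 * sigma_mm^2))
  if (any(abs(rho) >= 1)) stop_arg("field parameters give |rho| >= 1")
  if (which.min(rho) != ni || which.max(rho) != pi_)
    stop_arg("bumps overlap: planted peaks are not the field extrema")
  structure(list(rho = rho, neg_peak = ni, pos_peak = pi_, space = space,
                 sigma_mm = sigma_mm),
            class = "connectivity_field")
}

space_nearest <- function(space, point) {
  if (inherits(space, "surface_mesh")) return(nearest_vertex(space, point))
  coords <- voxel_to_world(space, grid_index_table(space))
  which.min(rowSums(sweep(coords, 2, as.numeric(point))^2))
}

# Distances from one location to all locations of a space: geodesic along
# the mesh, Euclidean through the volume.
space_distances <- function(space, from) {
  if (inherits(space, "surface_mesh")) return(geodesic_distances(space, from))
  coords <- voxel_to_world(space, grid_index_table(space))
  sqrt(rowSums(sweep(coords, 2, coords[from, ])^2))
}

space_coordinates <- function(space) {
  if (inherits(space, "surface_mesh")) return(space$vertices)
  voxel_to_world(space, grid_index_table(space))
}

#' Define the ground truth of a synthetic cohort
#'
#' Bundles everything the generator needs: the per-group correlation
#' fields, the between-subject variability, the fatigue-coupling model
#' `FS14 = clip(round(a + b * z(neg peak) + noise), 0, 14)`, the
#' longitudinal treatment-effect model, and the confound-contamination
#' level. The slope `b` and noise SD are derived from the requested
#' cross-subject coupling `coupling_r` and score SD so that the planted
#' correlation is recoverable by construction.
#'
#' @param field Patient-group `connectivity_field`.
#' @param field_control Control-group field (defaults to the patient field,
#'   i.e. no planted group difference).
#' @param coupling_r Planted cross-subject correlation between true
#'   Fisher-z at the negative peak and FS14 in patients (default -0.3;
#'   0 plants no coupling).
#' @param jitter_sd Between-subject SD of the correlation field at each
#'   location (spatially smooth spherical-harmonic variation).
#' @param fs14_mean,fs14_sd Patient fatigue-score moments (0-14 scale).
#' @param fs14_mean_hc,fs14_sd_hc Control fatigue-score moments
#'   (uncoupled).
#' @param hamd_mean,hamd_sd,hamd_mean_hc,hamd_sd_hc Depression-score
#'   analog moments (clipped to 0-88, uncoupled).
#' @param delta_coupling_r Planted correlation between treatment-induced
#'   mean change in Fisher-z within the target region and the change in
#'   FS14 (longitudinal cohorts; default -0.4).
#' @param treat_effect_mean,treat_effect_sd Mean and SD of the per-subject
#'   treatment shift applied to the correlation field at the negative peak
#'   (decaying with the field's sigma); positive mean moves FC toward zero.
#' @param delta_fs14_sd SD of the change in FS14.
#' @param contamination Amplitude of shared 36P-family nuisance signals
#'   added to the BOLD data (0 disables).
#' @param seed Master RNG seed recorded with the truth.
#' @return An object of class `cohort_truth`.
#' @export
cohort_truth <- function(field,
                         field_control = field,
                         coupling_r = -0.3,
                         jitter_sd = 0.18,
                         fs14_mean = 10.35, fs14_sd = 2.90,
                         fs14_mean_hc = 4.73, fs14_sd_hc = 3.96,
                         hamd_mean = 5.81, hamd_sd = 4.97,
                         hamd_mean_hc = 4.96, hamd_sd_hc = 3.54,
                         delta_coupling_r = -0.4,
                         treat_effect_mean = 0.12, treat_effect_sd = 0.15,
                         delta_fs14_sd = 2.5,
                         contamination = 0.5,
                         seed = 1) {
  if (!inherits(field, "connectivity_field"))
    stop_arg("`field` must be a connectivity_field")
  if (abs(coupling_r) >= 1 || abs(delta_coupling_r) >= 1)
    stop_arg("planted correlations must lie in (-1, 1)")
  if (jitter_sd < 0 || fs14_sd < 0 || contamination < 0)
    stop_arg("spread parameters must be >= 0")
  rho_neg <- field$rho[field$neg_peak]
  # delta-method SD of true Fisher-z at the negative peak across subjects
  sd_z <- jitter_sd / (1 - rho_neg^2)
  b <- if (jitter_sd > 0) coupling_r * fs14_sd / sd_z else 0
  a <- fs14_mean - b * atanh(rho_neg)
  sigma_eps <- fs14_sd * sqrt(1 - coupling_r^2)
  # longitudinal: mean Fisher-z change in the target region per unit shift
  region <- which(space_distances(field$space, field$neg_peak) <= field$sigma_mm)
  kern <- exp(-space_distances(field$space, field$neg_peak)[region]^2 /
                (2 * field$sigma_mm^2))
  m_gain <- mean(kern / (1 - field$rho[region]^2))
  sd_dz <- treat_effect_sd * m_gain
  c_slope <- if (sd_dz > 0) delta_coupling_r * delta_fs14_sd / sd_dz else 0
  sigma_delta <- delta_fs14_sd * sqrt(1 - delta_coupling_r^2)
  structure(list(field = field, field_control = field_control,
                 coupling_r = coupling_r, jitter_sd = jitter_sd,
                 a = a, b = b, sigma_eps = sigma_eps,
                 fs14_mean = fs14_mean, fs14_sd = fs14_sd,
                 fs14_mean_hc = fs14_mean_hc, fs14_sd_hc = fs14_sd_hc,
                 hamd_mean = hamd_mean, hamd_sd = hamd_sd,
                 hamd_mean_hc = hamd_mean_hc, hamd_sd_hc = hamd_sd_hc,
                 delta_coupling_r = delta_coupling_r,
                 treat_effect_mean = treat_effect_mean,
                 treat_effect_sd = treat_effect_sd,
                 delta_fs14_sd = delta_fs14_sd,
                 region = region, c_slope = c_slope,
                 sigma_delta = sigma_delta,
                 contamination = contamination, seed = seed),
            class = "cohort_truth")
}

# --- noise synthesis ------------------------------------------------------

# Unit-variance band-limited Gaussian noise, synthesized spectrally:
# complex-Gaussian Fourier coefficients on the bins inside [low, high] Hz,
# Hermitian symmetry, inverse FFT, column standardization. Band-limiting
# gives the series realistic autocorrelation while keeping the planted
# correlations inside the analysis pass band.
band_limited_noise <- function(n_frames, n_series, tr_seconds,
                               low_hz = 0.01, high_hz = 0.08) {
  freqs <- (seq_len(n_frames) - 1) / (n_frames * tr_seconds)
  half <- seq(2L, floor((n_frames - 1) / 2) + 1L)  # positive-frequency bins
  keep <- half[freqs[half] >= low_hz & freqs[half] <= high_hz]
  if (length(keep) < 2L)
    stop_arg("too few frames for band-limited synthesis in [%g, %g] Hz",
             low_hz, high_hz)
  co <- matrix(0i, n_frames, n_series)
  co[keep, ] <- matrix(stats::rnorm(length(keep) * n_series), ncol = n_series) +
    1i * matrix(stats::rnorm(length(keep) * n_series), ncol = n_series)
  co[n_frames - keep + 2L, ] <- Conj(co[keep, ])
  x <- Re(stats::mvfft(co, inverse = TRUE))
  x <- sweep(x, 2, colMeans(x))
  sds <- sqrt(colSums(x^2) / (n_frames - 1))
  sweep(x, 2, sds, "/")
}

# Effective number of independent samples of band-limited noise: n scaled
# by twice the fractional bandwidth. Governs the sampling variability of
# correlation estimates from these series.
effective_n <- function(n_frames, tr_seconds = 2, low_hz = 0.01,
                        high_hz = 0.08) {
  nyq <- 1 / (2 * tr_seconds)
  n_frames * (high_hz - low_hz) / nyq
}

# --- BOLD and motion ------------------------------------------------------

#' Simulate one BOLD run with a planted correlation field
#'
#' Each location's series is `rho * s(t) + sqrt(1 - rho^2) * eta(t)` with
#' `s` (the seed signal) and `eta` independent unit-variance band-limited
#' noise, so the expected correlation with the seed equals the planted
#' `rho`. Identical seeds give bit-identical output.
#'
#' @param field A `connectivity_field` (its `rho` may have been jittered).
#' @param n_frames Number of frames (>= 20; the reference acquisition is
#'   240 volumes).
#' @param tr_seconds Repetition time (default 2 s).
#' @param seed RNG seed.
#' @param noise_band Generator noise band in Hz (default 0.01-0.08, inside
#'   the analysis pass band).
#' @return A `bold_run` whose `seed_ts` field holds the seed signal.
#' @export
simulate_bold <- function(field, n_frames = 240, tr_seconds = 2, seed = 1,
                          noise_band = c(0.01, 0.08)) {
  if (!inherits(field, "connectivity_field"))
    stop_arg("`field` must be a connectivity_field")
  if (!is.numeric(n_frames) || n_frames < 20)
    stop_arg("`n_frames` must be at least 20")
  rho <- field$rho
  if (any(abs(rho) >= 1)) stop_arg("|rho| must be < 1 everywhere")
  with_seed(seed, {
    v <- length(rho)
    s <- band_limited_noise(n_frames, 1L, tr_seconds, noise_band[1], noise_band[2])
    eta <- band_limited_noise(n_frames, v, tr_seconds, noise_band[1], noise_band[2])
    data <- s %*% rbind(rho) + eta * matrix(sqrt(1 - rho^2), n_frames, v,
                                            byrow = TRUE)
    bold_run(data, tr_seconds, field$space, seed_ts = as.vector(s))
  })
}

#' Simulate motion parameters with optional spikes
#'
#' Smooth small-amplitude drift on all six parameters plus, at each spike
#' frame, a translation step of `spike_mm` on one axis -- guaranteeing a
#' framewise displacement of at least `spike_mm` there.
#'
#' @param n_frames Number of frames.
#' @param spike_frames Integer frame indices of motion spikes (1-based).
#' @param spike_mm Translation step at each spike, in mm.
#' @param seed RNG seed.
#' @param drift_sd Per-frame SD of the translation drift increments in mm
#'   (rotation increments are scaled down by a 50 mm head radius so both
#'   contribute comparably to FD); 0 gives exactly zero baseline motion.
#' @return A frames x 6 matrix (class `motion_params`) with columns
#'   `trans_x..rot_z`.
#' @export
simulate_motion <- function(n_frames, spike_frames = integer(0), spike_mm = 0.8,
                            seed = 1, drift_sd = 0.01) {
  if (!is.numeric(n_frames) || n_frames < 1)
    stop_arg("`n_frames` must be positive")
  spike_frames <- as.integer(spike_frames)
  if (any(spike_frames < 1L | spike_frames > n_frames))
    stop_arg("spike frames must lie in 1..n_frames")
  check_scalar_number(spike_mm, "spike_mm", positive = TRUE)
  with_seed(seed, {
    m <- if (drift_sd > 0) {
      inc <- matrix(stats::rnorm(n_frames * 6, sd = drift_sd), ncol = 6)
      inc[, 4:6] <- inc[, 4:6] / 50  # radians: comparable FD at 50 mm radius
      apply(inc, 2, cumsum)
    } else matrix(0, n_frames, 6)
    m <- matrix(m, ncol = 6)
    for (k in seq_along(spike_frames)) {
      axis <- (k - 1L) %% 3L + 1L
      t <- spike_frames[k]
      m[t, axis] <- m[t, axis] + spike_mm
    }
    colnames(m) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    class(m) <- c("motion_params", class(m))
    m
  })
}

# --- between-subject variation -------------------------------------------

# Real spherical harmonics up to degree 2 (8 functions, excluding the
# constant), evaluated on unit direction vectors. Their summed square is
# 8/(4*pi) everywhere, so iid coefficients give spatially uniform variance.
sph_harmonics <- function(dirs) {
  x <- dirs[, 1]; y <- dirs[, 2]; z <- dirs[, 3]
  cbind(sqrt(3 / (4 * pi)) * x,
        sqrt(3 / (4 * pi)) * y,
        sqrt(3 / (4 * pi)) * z,
        sqrt(15 / (4 * pi)) * x * y,
        sqrt(15 / (4 * pi)) * y * z,
        sqrt(15 / (4 * pi)) * x * z,
        sqrt(5 / (16 * pi)) * (3 * z^2 - 1),
        sqrt(15 / (16 * pi)) * (x^2 - y^2))
}

# One subject's spatially smooth field perturbation with vertex-wise SD
# `jitter_sd`. Draws 8 N(0,1) coefficients from the current RNG stream.
# The harmonic basis is cached per space (meshes are immutable).
space_sph_basis <- function(space) {
  cache <- if (inherits(space, "surface_mesh")) space$cache else NULL
  if (!is.null(cache) && !is.null(cache$sph_basis)) return(cache$sph_basis)
  coords <- space_coordinates(space)
  ctr <- colMeans(coords)
  dirs <- sweep(coords, 2, ctr)
  nrm <- sqrt(rowSums(dirs^2))
  nrm[nrm == 0] <- 1
  basis <- sph_harmonics(dirs / nrm)
  if (!is.null(cache)) cache$sph_basis <- basis
  basis
}

jitter_field <- function(field, jitter_sd) {
  if (jitter_sd == 0) return(field)
  basis <- space_sph_basis(field$space)
  coef <- stats::rnorm(8) * jitter_sd / sqrt(8 / (4 * pi))
  field$rho <- pmin(pmax(field$rho + as.vector(basis %*% coef), -0.95), 0.95)
  field
}

clip_round <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

# --- cohorts --------------------------------------------------------------

# One subject: jittered field, symptom scores, motion, optional BOLD with
# confound contamination. All draws come from substreams of `seed`.
simulate_subject <- function(truth, group, subj_id, n_frames, tr_seconds,
                             seed, signals) {
  base_field <- if (group == "patient") truth$field else truth$field_control
  fld <- with_seed(substream_seed(seed, "jitter"),
                   jitter_field(base_field, truth$jitter_sd))
  z_neg <- atanh(fld$rho[truth$field$neg_peak])
  z_pos <- atanh(fld$rho[truth$field$pos_peak])
  scores <- with_seed(substream_seed(seed, "scores"), {
    if (group == "patient") {
      fs14 <- clip_round(truth$a + truth$b * z_neg +
                           stats::rnorm(1, sd = truth$sigma_eps), 0, 14)
      hamd <- clip_round(stats::rnorm(1, truth$hamd_mean, truth$hamd_sd), 0, 88)
    } else {
      fs14 <- clip_round(stats::rnorm(1, truth$fs14_mean_hc, truth$fs14_sd_hc),
                         0, 14)
      hamd <- clip_round(stats::rnorm(1, truth$hamd_mean_hc, truth$hamd_sd_hc),
                         0, 88)
    }
    c(fs14 = fs14, hamd = hamd)
  })
  n_spikes <- with_seed(substream_seed(seed, "spike-count"),
                        stats::rpois(1, 2))
  spike_frames <- with_seed(substream_seed(seed, "spike-frames"),
                            sort(sample.int(n_frames, min(n_spikes, n_frames))))
  motion <- simulate_motion(n_frames, spike_frames, spike_mm = 0.8,
                            seed = substream_seed(seed, "motion"))
  out <- list(subject_id = subj_id, group = group,
              fs14 = unname(scores["fs14"]), hamd = unname(scores["hamd"]),
              z_neg_true = z_neg, z_pos_true = z_pos, field = fld,
              motion = motion)
  if (signals) {
    run <- simulate_bold(fld, n_frames, tr_seconds,
                         seed = substream_seed(seed, "bold"))
    run$motion <- unclass(motion)
    v <- length(fld$rho)
    tissue <- with_seed(substream_seed(seed, "tissue"),
                        band_limited_noise(n_frames, 3L, tr_seconds))
    colnames(tissue) <- c("global_signal", "white_matter", "csf")
    if (truth$contamination > 0) {
      loadings <- with_seed(substream_seed(seed, "loadings"),
                            matrix(stats::rnorm(9 * v), nrow = 9))
      nuis <- cbind(unclass(motion), tissue)
      run$data <- run$data + truth$contamination * (nuis %*% loadings)
    }
    out$run <- run
    out$tissue <- tissue
  }
  out
}

#' Simulate a two-group cross-sectional cohort
#'
#' Patients and controls drawn around the truth's per-group correlation
#' fields with spatially smooth between-subject jitter; patient FS14 scores
#' are coupled to the subject's true Fisher-z at the planted negative peak.
#' Ordering (patients first, then controls) and every draw are fully
#' determined by `seed`.
#'
#' @param truth A `cohort_truth`.
#' @param n_per_group Subjects per group (>= 3).
#' @param n_frames,tr_seconds Acquisition length and repetition time.
#' @param seed Master seed for the cohort (defaults to the truth's).
#' @param signals If `FALSE`, skip BOLD synthesis and return only fields,
#'   scores and motion -- the fast path for statistical calibration
#'   studies.
#' @param groups `"both"` (default), `"patient"` or `"control"`: which
#'   arms to generate (a control-only cohort serves as a normative
#'   population).
#' @return An object of class `synthetic_cohort`: a list with `subjects`
#'   (per-subject records), `phenotypes` (data frame), `truth` and `space`.
#' @export
simulate_cohort <- function(truth, n_per_group, n_frames = 240,
                            tr_seconds = 2, seed = truth$seed,
                            signals = TRUE,
                            groups = c("both", "patient", "control")) {
  if (!inherits(truth, "cohort_truth")) stop_arg("`truth` must be a cohort_truth")
  if (!is.numeric(n_per_group) || n_per_group < 3)
    stop_arg("`n_per_group` must be at least 3")
  groups <- match.arg(groups)
  groups <- if (groups == "both") rep(c("patient", "control"),
                                      each = n_per_group)
            else rep(groups, n_per_group)
  ids <- sprintf("sub-%s%03d", ifelse(groups == "patient", "p", "c"),
                 stats::ave(seq_along(groups), groups, FUN = seq_along))
  subjects <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    subjects[[i]] <- simulate_subject(truth, groups[i], ids[i], n_frames,
                                      tr_seconds,
                                      seed = substream_seed(seed, "subject", i),
                                      signals = signals)
  }
  phen <- data.frame(subject_id = ids, group = groups,
                     fs14 = vapply(subjects, `[[`, numeric(1), "fs14"),
                     hamd = vapply(subjects, `[[`, numeric(1), "hamd"),
                     stringsAsFactors = FALSE)
  structure(list(subjects = subjects, phenotypes = phen, truth = truth,
                 space = truth$field$space, n_frames = n_frames,
                 tr_seconds = tr_seconds, seed = seed),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d subjects (%d patients / %d controls)%s\n",
              nrow(x$phenotypes), sum(x$phenotypes$group == "patient"),
              sum(x$phenotypes$group == "control"),
              if (is.null(x$subjects[[1]]$run)) ", no signals" else ""))
  invisible(x)
}

#' Simulate a longitudinal (pre/post treatment) patient cohort
#'
#' Pre-treatment subjects are generated exactly as the patient arm of
#' [simulate_cohort()]. Treatment shifts each subject's correlation field
#' inside the planted target region by a subject-specific amount, and the
#' change in FS14 is coupled to the subject's mean change in Fisher-z
#' within that region at the truth's planted delta-delta correlation.
#'
#' @param truth A `cohort_truth`.
#' @param n Number of patients (>= 3; the reference design has 35).
#' @param n_frames,tr_seconds Acquisition parameters.
#' @param seed Master seed.
#' @param signals If `FALSE`, skip BOLD synthesis.
#' @return An object of class `longitudinal_cohort` with per-subject
#'   `pre`/`post` records, a `phenotypes` data frame (fs14, fs14_post) and
#'   per-subject true region-mean Fisher-z changes (`delta_z_true`).
#' @export
simulate_longitudinal <- function(truth, n = 35, n_frames = 240,
                                  tr_seconds = 2, seed = truth$seed,
                                  signals = TRUE) {
  if (!inherits(truth, "cohort_truth")) stop_arg("`truth` must be a cohort_truth")
  if (!is.numeric(n) || n < 3) stop_arg("`n` must be at least 3")
  kern_full <- exp(-space_distances(truth$field$space, truth$field$neg_peak)^2 /
                     (2 * truth$field$sigma_mm^2))
  subjects <- vector("list", n)
  delta_z <- numeric(n)
  d_fs14 <- numeric(n)
  for (i in seq_len(n)) {
    sseed <- substream_seed(seed, "subject", i)
    pre <- simulate_subject(truth, "patient", sprintf("sub-p%03d", i),
                            n_frames, tr_seconds, seed = sseed,
                            signals = signals)
    delta_i <- with_seed(substream_seed(sseed, "treatment"),
                         stats::rnorm(1, truth$treat_effect_mean,
                                      truth$treat_effect_sd))
    post_field <- pre$field
    post_field$rho <- pmin(pmax(post_field$rho + delta_i * kern_full,
                                -0.95), 0.95)
    dz_vec <- atanh(post_field$rho) - atanh(pre$field$rho)
    delta_z[i] <- mean(dz_vec[truth$region])
    d_fs14[i] <- truth$c_slope * delta_z[i] +
      with_seed(substream_seed(sseed, "dfs14"),
                stats::rnorm(1, sd = truth$sigma_delta))
    post <- list(field = post_field)
    if (signals) {
      run <- simulate_bold(post_field, n_frames, tr_seconds,
                           seed = substream_seed(sseed, "bold-post"))
      motion <- simulate_motion(n_frames,
                                spike_frames = integer(0), spike_mm = 0.8,
                                seed = substream_seed(sseed, "motion-post"))
      run$motion <- unclass(motion)
      tissue <- with_seed(substream_seed(sseed, "tissue-post"),
                          band_limited_noise(n_frames, 3L, tr_seconds))
      colnames(tissue) <- c("global_signal", "white_matter", "csf")
      if (truth$contamination > 0) {
        loadings <- with_seed(substream_seed(sseed, "loadings-post"),
                              matrix(stats::rnorm(9 * length(post_field$rho)),
                                     nrow = 9))
        run$data <- run$data + truth$contamination *
          (cbind(unclass(motion), tissue) %*% loadings)
      }
      post$run <- run
      post$motion <- motion
      post$tissue <- tissue
    }
    subjects[[i]] <- list(pre = pre, post = post)
  }
  fs14_pre <- vapply(subjects, function(s) s$pre$fs14, numeric(1))
  fs14_post <- clip_round(fs14_pre + d_fs14, 0, 14)
  phen <- data.frame(subject_id = vapply(subjects, function(s) s$pre$subject_id,
                                         character(1)),
                     group = "patient", fs14 = fs14_pre, fs14_post = fs14_post,
                     stringsAsFactors = FALSE)
  structure(list(subjects = subjects, phenotypes = phen,
                 delta_z_true = delta_z, truth = truth,
                 space = truth$field$space, n_frames = n_frames,
                 tr_seconds = tr_seconds, seed = seed),
            class = "longitudinal_cohort")
}

#' @export
print.longitudinal_cohort <- function(x, ...) {
  cat(sprintf("<longitudinal_cohort> %d patients, pre/post%s\n",
              nrow(x$phenotypes),
              if (is.null(x$subjects[[1]]$pre$run)) ", no signals" else ""))
  invisible(x)
}
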