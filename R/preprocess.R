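# Denoising chain for standard-space BOLD time series: initial frame
# dropping, framewise-displacement censoring, 36-parameter nuisance
# regression, zero-phase band-pass, spatial smoothing. Anatomical
# preprocessing (registration, segmentation, surface reconstruction) is out
# of scope; runs are assumed co-registered in a common space already.

#' Construct a BOLD run
#'
#' @param data Numeric frames x locations matrix of BOLD signal.
#' @param tr_seconds Repetition time in seconds.
#' @param space A `surface_mesh` or `volume_grid` with one location per
#'   data column.
#' @param mask Logical retained-frame mask (default: all retained).
#' @param motion Optional frames x 6 motion-parameter matrix
#'   (translations mm, rotations rad).
#' @param seed_ts Optional seed time series carried through every
#'   preprocessing step alongside the data.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr_seconds, space, mask = NULL, motion = NULL,
                     seed_ts = NULL) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop_data("BOLD data must be finite")
  check_scalar_number(tr_seconds, "tr_seconds", positive = TRUE)
  if (ncol(data) != space_size(space))
    stop_arg("data has %d locations but the space has %d", ncol(data),
             space_size(space))
  n <- nrow(data)
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop_arg("mask length must equal the frame count")
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) != n || ncol(motion) != 6L)
      stop_arg("motion must be a frames x 6 matrix")
  }
  if (!is.null(seed_ts) && length(seed_ts) != n)
    stop_arg("seed_ts length must equal the frame count")
  structure(list(data = data, tr_seconds = tr_seconds, mask = as.logical(mask),
                 space = space, motion = motion, seed_ts = seed_ts),
            class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  cat(sprintf("<bold_run> %d frames (%d retained) x %d locations, TR %.3g s, %s space\n",
              nrow(x$data), sum(x$mask), ncol(x$data), x$tr_seconds,
              if (inherits(x$space, "surface_mesh")) "surface" else "volume"))
  invisible(x)
}

#' Drop initial frames of a run
#'
#' Removes the first `n` frames from the data, the retained-frame mask, and
#' any paired motion parameters or seed series (the usual discard of
#' pre-steady-state volumes; the acquisition protocol here drops 10 of 240).
#'
#' @param run A `bold_run`.
#' @param n Non-negative number of frames to drop; must be < frame count.
#' @return The shortened `bold_run`.
#' @export
drop_initial_frames <- function(run, n = 10) {
  if (!inherits(run, "bold_run")) stop_arg("`run` must be a bold_run")
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n))
    stop_arg("`n` must be a non-negative integer")
  if (n >= nrow(run$data))
    stop_arg("cannot drop %d frames from a %d-frame run", n, nrow(run$data))
  if (n == 0) return(run)
  keep <- -seq_len(n)
  run$data <- run$data[keep, , drop = FALSE]
  run$mask <- run$mask[keep]
  if (!is.null(run$motion)) run$motion <- run$motion[keep, , drop = FALSE]
  if (!is.null(run$seed_ts)) run$seed_ts <- run$seed_ts[keep]
  run
}

#' Framewise displacement from motion parameters
#'
#' Power's framewise displacement: the sum of absolute backward differences
#' of the six rigid-body parameters, with rotations converted to mm of arc
#' on a sphere of `head_radius_mm`. The first frame has FD 0.
#'
#' @param motion Frames x 6 matrix (3 translations mm, 3 rotations rad) or
#'   a `bold_run` carrying one.
#' @param head_radius_mm Head radius for the rotation-to-arc conversion.
#' @return Numeric vector of per-frame FD in mm.
#' @export
framewise_displacement <- function(motion, head_radius_mm = 50) {
  if (inherits(motion, "bold_run")) motion <- motion$motion
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop_arg("motion must have 6 columns")
  if (nrow(motion) < 2L) stop_arg("framewise displacement needs >= 2 frames")
  if (!all(is.finite(motion))) stop_data("motion parameters must be finite")
  check_scalar_number(head_radius_mm, "head_radius_mm", positive = TRUE)
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * head_radius_mm
  c(0, rowSums(d))
}

#' Censor high-motion frames
#'
#' Marks frames whose framewise displacement exceeds the threshold as not
#' retained. The comparison is strictly greater-than: a frame at exactly
#' the threshold survives. Data are untouched; censoring is logical.
#'
#' @param run A `bold_run`.
#' @param fd Per-frame FD series (default: computed from the run's motion).
#' @param threshold_mm Censoring threshold in mm (default 0.5).
#' @return The run with an updated retained-frame mask.
#' @export
censor <- function(run, fd = NULL, threshold_mm = 0.5) {
  if (!inherits(run, "bold_run")) stop_arg("`run` must be a bold_run")
  if (is.null(fd)) {
    if (is.null(run$motion)) stop_arg("no FD series given and run has no motion")
    fd <- framewise_displacement(run$motion)
  }
  if (length(fd) != nrow(run$data))
    stop_arg("FD length (%d) must equal the frame count (%d)", length(fd),
             nrow(run$data))
  check_scalar_number(threshold_mm, "threshold_mm", positive = TRUE)
  run$mask <- run$mask & !(fd > threshold_mm)
  run
}

#' Build the 36-parameter confound matrix
#'
#' The 36P nuisance family: 6 motion parameters; mean global, white-matter
#' and CSF signals; the 9 temporal (backward-difference) derivatives of all
#' of these, with the first element 0; and the squares of all 18 preceding
#' columns.
#'
#' @param motion Frames x 6 motion matrix.
#' @param tissue_means Frames x 3 matrix or list of 3 series, ordered
#'   global, white matter, CSF.
#' @return A frames x 36 matrix of class `confound_matrix` with named,
#'   ordered columns.
#' @export
build_confounds_36p <- function(motion, tissue_means) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6L) stop_arg("motion must have 6 columns")
  if (is.list(tissue_means) && !is.data.frame(tissue_means))
    tissue_means <- do.call(cbind, tissue_means)
  tissue_means <- as.matrix(tissue_means)
  if (ncol(tissue_means) != 3L)
    stop_arg("`tissue_means` must provide exactly 3 series (global, WM, CSF)")
  if (nrow(tissue_means) != nrow(motion))
    stop_arg("motion and tissue series must have equal frame counts")
  base <- cbind(motion, tissue_means)
  if (!all(is.finite(base))) stop_data("confound inputs must be finite")
  colnames(base) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z",
                      "global_signal", "white_matter", "csf")
  deriv <- rbind(0, diff(base))
  colnames(deriv) <- paste0(colnames(base), "_derivative1")
  lin <- cbind(base, deriv)
  quad <- lin^2
  colnames(quad) <- paste0(colnames(lin), "_power2")
  out <- cbind(lin, quad)
  stopifnot(ncol(out) == 36L)
  class(out) <- c("confound_matrix", class(out))
  out
}

# Fill censored rows of a matrix by linear interpolation between the
# nearest retained rows (nearest retained value at the ends). Keeps the
# series continuous for zero-phase filtering without letting censored
# frames re-enter statistics.
interpolate_censored <- function(x, mask) {
  if (all(mask)) return(x)
  kept <- which(mask)
  if (length(kept) == 0L) stop_data("no retained frames to interpolate from")
  miss <- which(!mask)
  prev <- findInterval(miss, kept)  # index into kept, 0 if before first
  nxt <- prev + 1L                  # miss is never in kept
  p <- kept[pmax(prev, 1L)]                    # nearest retained before (or first)
  q <- kept[pmin(nxt, length(kept))]           # nearest retained after (or last)
  w <- ifelse(q == p, 1, (q - miss) / (q - p)) # ends: collapse to nearest
  w[prev == 0L] <- 0                           # before the first retained frame
  w[nxt > length(kept)] <- 1                   # after the last retained frame
  x[miss, ] <- w * x[p, , drop = FALSE] + (1 - w) * x[q, , drop = FALSE]
  x
}

#' Regress nuisance confounds out of a run
#'
#' Ordinary least squares of every location's series on the confounds plus
#' an intercept, fitted over retained frames only; the run's data are
#' replaced by the residuals. Censored frames are filled by linear
#' interpolation from neighbouring retained residuals so that subsequent
#' zero-phase filtering sees a continuous series (they stay flagged and
#' never re-enter statistics). Collinear confound columns are dropped with
#' a warning.
#'
#' @param run A `bold_run`.
#' @param confounds Frames x p confound matrix (typically from
#'   [build_confounds_36p()]).
#' @return The residualized `bold_run`.
#' @export
regress_out <- function(run, confounds) {
  if (!inherits(run, "bold_run")) stop_arg("`run` must be a bold_run")
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(run$data))
    stop_arg("confounds have %d frames, run has %d", nrow(confounds),
             nrow(run$data))
  if (!all(is.finite(confounds))) stop_data("confounds must be finite")
  keep <- run$mask
  if (sum(keep) <= ncol(confounds) + 1L)
    stop_data("fewer retained frames than design columns")
  X <- cbind(`(intercept)` = 1, confounds)[keep, , drop = FALSE]
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    dropped <- colnames(X)[qrx$pivot[-seq_len(qrx$rank)]]
    warning(sprintf("dropping %d collinear confound column(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    X <- X[, qrx$pivot[seq_len(qrx$rank)], drop = FALSE]
    qrx <- qr(X)
  }
  res <- matrix(0, nrow(run$data), ncol(run$data))
  res[keep, ] <- qr.resid(qrx, run$data[keep, , drop = FALSE])
  res[!keep, ] <- NA_real_
  res <- interpolate_censored(res, keep)
  run$data <- res
  if (!is.null(run$seed_ts)) {
    s <- matrix(NA_real_, length(run$seed_ts), 1)
    s[keep, 1] <- qr.resid(qrx, run$seed_ts[keep])
    run$seed_ts <- as.vector(interpolate_censored(s, keep))
  }
  run
}

# Squared-magnitude frequency response of the band-pass at given
# frequencies (Hz): a 4th-order Butterworth applied forward and backward
# (zero phase), so the effective gain is |H(f)|^2.
bandpass_gain <- function(freqs_hz, low_hz, high_hz, tr_seconds) {
  nyq <- 1 / (2 * tr_seconds)
  bf <- signal::butter(2, c(low_hz, high_hz) / nyq, type = "pass")
  w <- 2 * pi * freqs_hz * tr_seconds  # rad/sample
  z <- exp(-1i * w)
  h <- sapply(seq_along(z), function(k) {
    sum(bf$b * z[k]^(seq_along(bf$b) - 1)) /
      sum(bf$a * z[k]^(seq_along(bf$a) - 1))
  })
  Mod(h)^2
}

#' Zero-phase band-pass filter a run
#'
#' Butterworth band-pass (order 4) applied with zero phase along time.
#' Censored frames are first filled by linear interpolation so the filter
#' sees a continuous series; they remain flagged afterwards. The filter is
#' applied spectrally -- each series' FFT is multiplied by the squared
#' magnitude response |H(f)|^2 of the Butterworth transfer function, the
#' frequency-domain equivalent of a forward-backward pass -- which makes
#' filtering thousands of locations a single matrix FFT.
#'
#' @param run A `bold_run`.
#' @param low_hz,high_hz Pass band edges in Hz (defaults 0.01 and 0.1).
#' @return The filtered `bold_run`.
#' @export
bandpass <- function(run, low_hz = 0.01, high_hz = 0.1) {
  if (!inherits(run, "bold_run")) stop_arg("`run` must be a bold_run")
  nyq <- 1 / (2 * run$tr_seconds)
  if (!(low_hz > 0) || !(high_hz > low_hz) || !(high_hz < nyq))
    stop_arg("band must satisfy 0 < low < high < Nyquist (%.4g Hz)", nyq)
  n <- nrow(run$data)
  x <- interpolate_censored(run$data, run$mask)
  mu <- colMeans(x)
  x <- sweep(x, 2, mu)
  freqs <- (seq_len(n) - 1) / (n * run$tr_seconds)
  freqs <- pmin(freqs, 1 / run$tr_seconds - freqs)  # fold to [0, Nyquist]
  gain <- bandpass_gain(freqs, low_hz, high_hz, run$tr_seconds)
  xf <- stats::mvfft(x) * gain
  run$data <- Re(stats::mvfft(xf, inverse = TRUE)) / n
  if (!is.null(run$seed_ts)) {
    s <- interpolate_censored(matrix(run$seed_ts, ncol = 1), run$mask)
    s <- s - mean(s)
    sf <- stats::fft(as.vector(s)) * gain
    run$seed_ts <- Re(stats::fft(sf, inverse = TRUE)) / n
  }
  run
}
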