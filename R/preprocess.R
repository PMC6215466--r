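# RSFC cleaning chain for surface time series: framewise displacement,
# two-pass motion scrubbing, nuisance regression with first-derivative
# terms, zero-phase band-pass filtering, and the minimum-data rule.

#' Framewise displacement from a six-parameter motion trace
#'
#' FD at frame t is the sum of absolute frame-to-frame differentials of
#' the three translations (mm) and the three rotations, the latter
#' converted to arc length on a sphere of radius `rot_radius_mm` before
#' summation.  The first frame has FD 0 by convention.
#'
#' @param motion frames x 6 matrix: tx, ty, tz (mm), rx, ry, rz (radians).
#' @param rot_radius_mm radius for the rotation-to-mm conversion
#'   (default 50 mm, the conventional head radius for this definition).
#' @return list of class `fd_trace`: `fd` (mm per frame), `rot_radius_mm`.
#' @export
framewise_displacement <- function(motion, rot_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stopf("motion trace must have 6 columns")
  if (nrow(motion) < 2) stopf("need at least 2 frames")
  d <- abs(diff(motion))
  d[, 4:6] <- d[, 4:6] * rot_radius_mm
  fd <- c(0, rowSums(d))
  structure(list(fd = fd, rot_radius_mm = rot_radius_mm), class = "fd_trace")
}

#' Motion-scrubbing keep-mask
#'
#' Frames with FD above `threshold_mm` are flagged, together with `pad`
#' frames on each side (default one frame before and after, absorbing the
#' temporal spread of artifact introduced by filtering); the keep-mask is
#' the complement.
#'
#' @param fd an `fd_trace` or numeric FD vector (mm).
#' @param threshold_mm flagging threshold (default 0.3 mm).
#' @param pad frames flagged on each side of a supra-threshold frame.
#' @return logical keep-mask, TRUE = retained frame.
#' @export
scrub_mask <- function(fd, threshold_mm = 0.3, pad = 1L) {
  if (inherits(fd, "fd_trace")) fd <- fd$fd
  if (pad < 0) stopf("pad must be >= 0")
  bad <- which(fd > threshold_mm)
  if (length(bad) && pad > 0)
    bad <- unique(as.vector(outer(bad, -pad:pad, `+`)))
  bad <- bad[bad >= 1 & bad <= length(fd)]
  keep <- rep(TRUE, length(fd))
  keep[bad] <- FALSE
  keep
}

#' Nuisance regression of surface time series
#'
#' Per-vertex ordinary least squares of the time series on the nuisance
#' signals (intercept always included; first-difference derivative terms
#' appended when requested, first row zero-padded), fitted on the masked
#' frames only.  Collinear design columns are dropped with a warning.
#'
#' @param timeseries vertex x frame matrix.
#' @param nuisance frame x k matrix of nuisance signals.
#' @param include_derivatives append first-difference terms (default TRUE).
#' @param frame_mask logical keep-mask (default all frames).
#' @return residual matrix, vertices x masked frames.
#' @export
nuisance_regress <- function(timeseries, nuisance, include_derivatives = TRUE,
                             frame_mask = NULL) {
  Tn <- ncol(timeseries)
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != Tn) stopf("nuisance frame count mismatch")
  X <- cbind(1, nuisance)
  if (include_derivatives)
    X <- cbind(X, rbind(0, diff(nuisance)))
  if (is.null(frame_mask)) frame_mask <- rep(TRUE, Tn)
  if (sum(frame_mask) < ncol(X) + 2)
    stopf("mask retains too few frames for the design")
  Xm <- X[frame_mask, , drop = FALSE]
  qrX <- qr(Xm)
  if (qrX$rank < ncol(Xm)) {
    keep_cols <- qrX$pivot[seq_len(qrX$rank)]
    warnf("dropping %d collinear nuisance column(s)", ncol(Xm) - qrX$rank)
    Xm <- Xm[, sort(keep_cols), drop = FALSE]
    qrX <- qr(Xm)
  }
  Y <- t(timeseries[, frame_mask, drop = FALSE])
  res <- qr.resid(qrX, Y)
  t(res)
}

#' Zero-phase band-pass filter
#'
#' Frequency-domain (FFT) filter retaining components with
#' `low_hz <= f <= high_hz`; the DC component is always removed.  Being
#' applied in the frequency domain, the filter is exactly zero-phase.
#'
#' @param timeseries vertex x frame matrix (or a single series).
#' @param tr_s sampling interval (repetition time), seconds.
#' @param low_hz,high_hz pass-band edges (defaults 0.009 and 0.08 Hz, the
#'   standard RSFC analysis band).
#' @return filtered matrix, same shape.
#' @export
bandpass <- function(timeseries, tr_s, low_hz = 0.009, high_hz = 0.08) {
  one <- is.null(dim(timeseries))
  x <- if (one) matrix(timeseries, 1) else as.matrix(timeseries)
  Tn <- ncol(x)
  if (Tn < 32) stopf("need at least 32 frames to filter")
  nyq <- 1 / (2 * tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stopf("band must satisfy 0 < low < high < Nyquist (%.4f Hz)", nyq)
  freqs <- seq(0, Tn - 1) / (Tn * tr_s)
  freqs <- pmin(freqs, 1 / tr_s - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  X <- t(stats::mvfft(t(x)))
  X[, !keep] <- 0
  out <- Re(t(stats::mvfft(t(X), inverse = TRUE))) / Tn
  if (one) out[1, ] else out
}

#' Full two-iteration preprocessing of a subject
#'
#' Iteration 1 regresses nuisance signals (detrended motion parameters,
#' global signal over non-medial vertices, and their first derivatives)
#' and band-pass filters on all frames; FD is computed from the motion
#' trace and supra-threshold frames (plus one frame each side) are
#' scrubbed; iteration 2 repeats regression and filtering using only the
#' retained frames (the censored series is concatenated before
#' filtering).  A subject retaining fewer than `min_frames` frames is
#' flagged unusable, never dropped silently.
#'
#' @param subject a `subject_data` (needs `timeseries`, `motion`).
#' @param mesh the `surface_mesh` (for the global-signal mask).
#' @param tr_s repetition time, seconds (default 2).
#' @param fd_threshold_mm scrub threshold (default 0.3 mm).
#' @param pad scrub padding, frames (default 1).
#' @param min_frames minimum retained frames for usability (default 75).
#' @param rot_radius_mm rotation-to-mm radius for FD (default 50).
#' @param low_hz,high_hz filter band (defaults 0.009, 0.08 Hz).
#' @param global_signal include the mean non-medial series as a nuisance
#'   regressor (default TRUE).
#' @return `clean_series`: `timeseries` (vertices x kept frames),
#'   `kept_frames`, `usable`, `fd`, `mean_fd`, `n_frames_kept`.
#' @export
preprocess_subject <- function(subject, mesh, tr_s = 2, fd_threshold_mm = 0.3,
                               pad = 1L, min_frames = 75L, rot_radius_mm = 50,
                               low_hz = 0.009, high_hz = 0.08,
                               global_signal = TRUE) {
  ts <- subject$timeseries
  motion <- subject$motion
  Tn <- ncol(ts)
  detrended <- apply(motion, 2, function(c) stats::residuals(lm(c ~ seq_along(c))))
  nuis <- detrended
  if (global_signal)
    nuis <- cbind(nuis, global = colMeans(ts[!mesh$medial_wall, , drop = FALSE]))

  # iteration 1: full-length cleaning (the temporal filtering here is what
  # spreads spike artifact to neighbouring frames, motivating the pad)
  r1 <- nuisance_regress(ts, nuis, include_derivatives = TRUE)
  f1 <- bandpass(r1, tr_s, low_hz, high_hz)

  fd <- framewise_displacement(motion, rot_radius_mm)
  keep <- scrub_mask(fd, fd_threshold_mm, pad)
  kept <- which(keep)

  usable <- length(kept) >= min_frames
  clean <- NULL
  if (length(kept) >= ncol(nuis) * 2 + 4) {
    nuis2 <- nuis
    if (global_signal)
      nuis2[, ncol(nuis2)] <- colMeans(ts[!mesh$medial_wall, , drop = FALSE])
    r2 <- nuisance_regress(ts, nuis2, include_derivatives = TRUE,
                           frame_mask = keep)
    clean <- if (length(kept) >= 32) bandpass(r2, tr_s, low_hz, high_hz) else r2
  } else {
    usable <- FALSE
    clean <- matrix(numeric(0), nrow(ts), 0)
    kept <- integer(0)
  }
  structure(list(
    timeseries = clean, kept_frames = kept, usable = usable,
    fd = fd$fd, mean_fd = mean(fd$fd), n_frames_kept = length(kept),
    age = subject$age, cohort = subject$cohort
  ), class = "clean_series")
}

#' Preprocess a whole cohort
#'
#' @param subjects list of `subject_data`.
#' @param mesh the `surface_mesh`.
#' @param ... passed to [preprocess_subject()].
#' @return list of `clean_series` (unusable subjects kept, flagged).
#' @export
preprocess_cohort <- function(subjects, mesh, ...) {
  lapply(subjects, preprocess_subject, mesh = mesh, ...)
}
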