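# Motion quality control: dummy-volume discard, detrending and bandpass
# filtering, framewise displacement (FD) and DVARS, binary volume censoring,
# truncation to a common retained length, and paired BL/EP motion
# comparisons.

#' Discard initial dummy volumes
#'
#' Removes the first `n_dummy` volumes acquired before signal stabilization.
#'
#' @param series Numeric matrix (volumes x ROIs) or vector.
#' @param n_dummy Number of initial volumes to discard (default 3).
#' @return The trimmed series, order preserved.
#' @export
#' @examples
#' nrow(discard_dummy_volumes(matrix(0, 205, 2), 3))  # 202
discard_dummy_volumes <- function(series, n_dummy = 3L) {
  vec <- is.null(dim(series))
  n <- if (vec) length(series) else nrow(series)
  if (n <= n_dummy) {
    stop(sprintf("series has %d volumes, cannot discard %d", n, n_dummy))
  }
  if (n_dummy == 0L) return(series)
  if (vec) series[-seq_len(n_dummy)] else series[-seq_len(n_dummy), , drop = FALSE]
}

#' Detrend and bandpass filter a BOLD series
#'
#' Removes the per-ROI linear trend, then applies an FFT bandpass retaining
#' spectral components within `[low_hz, high_hz]`. Components outside the
#' passband (including the DC term) are zeroed, so out-of-band attenuation
#' exceeds the 20 dB the censoring pipeline assumes. Missing (all-`NA`)
#' ROI columns pass through untouched.
#'
#' @param series Numeric matrix (volumes x ROIs) or vector.
#' @param tr_seconds Repetition time in seconds; the Nyquist frequency
#'   `1/(2 tr)` must exceed `high_hz`.
#' @param low_hz,high_hz Passband edges in Hz (defaults 0.01 and 0.08).
#' @return Filtered series, zero-mean per ROI, same shape as the input.
#' @export
detrend_bandpass <- function(series, tr_seconds, low_hz = 0.01, high_hz = 0.08) {
  vec <- is.null(dim(series))
  x <- if (vec) matrix(series, ncol = 1) else series
  n <- nrow(x)
  nyq <- 1 / (2 * tr_seconds)
  if (high_hz >= nyq) {
    stop(sprintf("high_hz (%.3f) must be below the Nyquist frequency (%.3f)",
                 high_hz, nyq))
  }
  t_c <- seq_len(n) - (n + 1) / 2
  freqs <- (seq_len(n) - 1) / (n * tr_seconds)
  freqs <- pmin(freqs, 1 / tr_seconds - freqs)  # fold to [0, Nyquist]
  keep <- freqs >= low_hz & freqs <= high_hz
  out <- x
  for (j in seq_len(ncol(x))) {
    col <- x[, j]
    if (all(is.na(col))) next
    # closed-form linear detrend
    beta <- sum(t_c * (col - mean(col))) / sum(t_c^2)
    col <- col - mean(col) - beta * t_c
    co <- fft(col)
    co[!keep] <- 0
    out[, j] <- Re(fft(co, inverse = TRUE)) / n
  }
  if (vec) out[, 1] else out
}

#' Framewise displacement from realignment parameters
#'
#' FD(t) is the sum of absolute backward differences of the three
#' translations (mm) plus `head_radius_mm` times the sum of absolute
#' backward differences of the three rotations (radians); FD(1) = 0.
#'
#' @param motion_params Numeric matrix (volumes x 6): translations in mm,
#'   rotations in radians.
#' @param head_radius_mm Rotation-to-displacement radius (default 50 mm).
#' @return Numeric vector of per-volume FD in mm.
#' @export
framewise_displacement <- function(motion_params, head_radius_mm = 50) {
  if (is.null(dim(motion_params)) || ncol(motion_params) != 6) {
    stop("motion_params must have 6 columns (3 translations, 3 rotations)")
  }
  d <- abs(diff(motion_params))
  fd <- rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
  c(0, fd)
}

#' DVARS: RMS volume-to-volume signal change
#'
#' The series is rescaled to a global median of 1000 so the conventional
#' censoring threshold of 50 corresponds to 5% of the signal;
#' DVARS(t) is then the root mean square over ROIs of the backward signal
#' difference, with DVARS(1) = 0. Missing (`NA`) ROIs are ignored.
#'
#' @param series Numeric matrix (volumes x ROIs).
#' @param rescale_median Target global median (default 1000); set `NULL` to
#'   skip rescaling.
#' @return Numeric vector of per-volume DVARS on the rescaled units.
#' @export
dvars <- function(series, rescale_median = 1000) {
  if (is.null(dim(series))) series <- matrix(series, ncol = 1)
  if (nrow(series) < 2) stop("DVARS requires at least 2 volumes")
  if (!is.null(rescale_median)) {
    med <- median(series, na.rm = TRUE)
    if (!is.finite(med) || med <= 0) {
      stop("cannot rescale series with non-positive global median")
    }
    series <- series * (rescale_median / med)
  }
  d <- diff(series)
  c(0, sqrt(rowMeans(d^2, na.rm = TRUE)))
}

#' Binary volume censoring on FD and DVARS
#'
#' A volume is retained iff `FD < fd_max` and `DVARS <= dvars_max`: the FD
#' boundary is censored, the DVARS boundary retained, following the printed
#' inequality directions of the thresholds they implement.
#'
#' @param fd,dvars Equal-length per-volume vectors.
#' @param fd_max FD censoring threshold in mm (default 0.5).
#' @param dvars_max DVARS censoring threshold (default 50).
#' @return Logical vector: `TRUE` for retained volumes.
#' @export
censor_volumes <- function(fd, dvars, fd_max = 0.5, dvars_max = 50) {
  if (length(fd) != length(dvars)) stop("fd and dvars must have equal length")
  fd < fd_max & dvars <= dvars_max
}

#' Truncate retained volumes to a common length across subjects
#'
#' For each subject, selects the earliest `target` surviving volumes in
#' temporal order. When `target` is `NULL` it is set to the minimum retained
#' count over subjects, so all subjects end with identical lengths.
#'
#' @param retained_masks Named list of per-subject logical retained masks.
#' @param target Common number of volumes, or `NULL` for the cohort minimum.
#' @return Named list of integer volume-index vectors, with attribute
#'   `"target"` giving the common length.
#' @export
#' @examples
#' truncate_to_common_length(list(a = c(FALSE, TRUE, FALSE, TRUE, TRUE)),
#'                           target = 2)
truncate_to_common_length <- function(retained_masks, target = NULL) {
  counts <- vapply(retained_masks, sum, numeric(1))
  if (is.null(target)) target <- min(counts)
  low <- which(counts < target)
  if (length(low)) {
    stop(sprintf("subject %s has only %d surviving volumes (target %d)",
                 names(retained_masks)[low[1]] %||% low[1],
                 counts[low[1]], target))
  }
  out <- lapply(retained_masks, function(m) head(which(m), target))
  attr(out, "target") <- as.integer(target)
  out
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a[1])) b else a

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-tailed signed-rank test with zero differences dropped (Wilcoxon's
#' original rule) and the exact permutation null enumerated for up to 15
#' non-zero pairs; beyond that a normal approximation is used and flagged.
#' With every difference zero the test is degenerate and p = 1.
#'
#' @param bl_summary,ep_summary Paired per-subject summaries (e.g. mean FD
#'   or mean DVARS at BL and EP).
#' @return List with `statistic` (sum of positive ranks), `p.value`,
#'   `n_used` (non-zero pairs) and `exact` (logical).
#' @export
#' @examples
#' compare_motion_paired(c(1, 2, 3, 4), c(2, 3, 4, 5))$p.value  # 0.125
compare_motion_paired <- function(bl_summary, ep_summary) {
  if (length(bl_summary) != length(ep_summary)) {
    stop("BL and EP summaries must be paired (equal length)")
  }
  if (length(bl_summary) < 2) stop("need at least 2 pairs")
  d <- ep_summary - bl_summary
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    return(list(statistic = 0, p.value = 1, n_used = 0L, exact = TRUE))
  }
  r <- rank(abs(d))
  s_obs <- sum(r * sign(d))
  v_stat <- sum(r[d > 0])
  if (n <= 15) {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    s_all <- as.vector(signs %*% r)
    p <- mean(abs(s_all) >= abs(s_obs) - 1e-12)
    list(statistic = v_stat, p.value = p, n_used = n, exact = TRUE)
  } else {
    mu <- 0
    sig <- sqrt(sum(r^2))
    z <- (abs(s_obs) - mu) / sig
    list(statistic = v_stat, p.value = 2 * stats::pnorm(-z), n_used = n,
         exact = FALSE)
  }
}

#' Run motion QC for one acquisition
#'
#' Applies the full scrubbing sequence to a raw acquisition: dummy-volume
#' discard, linear detrend + bandpass of the signal, FD from the realignment
#' parameters and DVARS from the unfiltered (post-discard) signal, and
#' binary censoring. The filtered series is what downstream connectivity
#' metrics consume; censoring masks refer to it volume-for-volume.
#'
#' @param ts An acquisition as returned by [simulate_bold()] (elements
#'   `data`, `motion`, `tr_seconds`), or a list with those elements.
#' @param n_dummy Dummy volumes to discard.
#' @param fd_max,dvars_max Censoring thresholds.
#' @param low_hz,high_hz Bandpass edges in Hz.
#' @return List with `trace` (data frame: volume, fd, dvars, retained),
#'   `filtered` (filtered series matrix) and `n_retained`.
#' @export
qc_acquisition <- function(ts, n_dummy = 3L, fd_max = 0.5, dvars_max = 50,
                           low_hz = 0.01, high_hz = 0.08) {
  series <- discard_dummy_volumes(ts$data, n_dummy)
  motion <- discard_dummy_volumes(ts$motion, n_dummy)
  fd <- framewise_displacement(motion)
  dv <- dvars(series)
  retained <- censor_volumes(fd, dv, fd_max, dvars_max)
  filtered <- detrend_bandpass(series, ts$tr_seconds, low_hz, high_hz)
  list(trace = data.frame(volume = seq_along(fd), fd = fd, dvars = dv,
                          retained = retained),
       filtered = filtered, n_retained = sum(retained))
}
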