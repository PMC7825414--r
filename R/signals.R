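# Signal conditioning: zero-lag Butterworth filtering, resampling, and the
# idealized insole projection that turns lab-style force-plate signals into
# wearable-style insole signals.

#' Zero-lag Butterworth low-pass filter
#'
#' Forward-backward Butterworth filtering (applied once in each direction, so
#' the magnitude response is squared and the phase shift is zero). The signal
#' is extended by odd reflection at both ends and the filter is initialized
#' at steady state, so constants pass through unchanged and edge transients
#' are suppressed.
#'
#' @param x Numeric vector.
#' @param cutoff Cutoff frequency in Hz (0 < cutoff < rate / 2).
#' @param rate Sampling rate in Hz.
#' @param order Filter order for each pass (default 3).
#' @return Filtered vector, same length as `x`.
#' @export
lowpass_zero_lag <- function(x, cutoff, rate, order = 3) {
  stop_if_not_scalar_number(cutoff, "cutoff", positive = TRUE)
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  if (cutoff >= rate / 2) abort("`cutoff` must be below the Nyquist frequency.")
  n <- length(x)
  if (n < 2) return(x)
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  pad <- min(n - 1L, max(3L * (order + 1L), ceiling(3 * rate / cutoff)))
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  pass <- function(v) {
    signal::filter(b, a, v, init.x = rep(v[1], length(b) - 1),
                   init.y = rep(v[1], length(a) - 1))
  }
  y <- pass(ext)
  y <- rev(pass(rev(y)))
  as.numeric(y[(pad + 1):(pad + n)])
}

#' Resample a uniformly sampled series
#'
#' Band-limited, zero-phase resampling: when downsampling, the signal is
#' first low-pass filtered at 90% of the new Nyquist frequency with the
#' zero-lag Butterworth, then cubic-spline interpolated onto the new time
#' grid (interpolation error on a band-limited signal sampled well above
#' its content is negligible). Duration is preserved to within one sample
#' period.
#'
#' @param x Numeric vector sampled at `rate` Hz.
#' @param rate Original sampling rate in Hz.
#' @param new_rate Target sampling rate in Hz.
#' @return Numeric vector of length `round(length(x) * new_rate / rate)`.
#' @export
resample_series <- function(x, rate, new_rate) {
  stop_if_not_scalar_number(rate, "rate", positive = TRUE)
  stop_if_not_scalar_number(new_rate, "new_rate", positive = TRUE)
  if (rate == new_rate) return(x)
  n_out <- round(length(x) * new_rate / rate)
  if (new_rate < rate) {
    x <- lowpass_zero_lag(x, 0.45 * new_rate, rate, order = 4)
  }
  t_old <- (seq_along(x) - 1) / rate
  t_new <- pmin((seq_len(n_out) - 1) / new_rate, max(t_old))
  stats::spline(t_old, x, xout = t_new, method = "fmm")$y
}

#' Project lab-style GRF and CoP onto idealized insole channels
#'
#' Maps each foot's 3D ground reaction force onto the 1D force normal to the
#' sole (the type of signal a pressure insole reports) and transforms the
#' global-frame centre of pressure into the foot's own planar frame. The
#' foot frame is X toe-ward, Y sole-normal, Z lateral, with origin at the
#' heel; the two in-plane CoP coordinates are returned as `cop_x` (toe-ward)
#' and `cop_y` (lateral), following the insole planar naming convention.
#' Negative normal forces are floored at zero (an insole cannot pull) with
#' the floored-sample count attached as an attribute.
#'
#' @param grf n x 3 matrix of ground reaction force (N, global frame).
#' @param cop_global n x 3 matrix of centre of pressure (m, global frame).
#' @param foot_quat n x 4 unit quaternion matrix (foot orientation,
#'   body-to-global).
#' @param heel_origin Heel position in the foot frame's parent (global)
#'   coordinates, n x 3 or length-3.
#' @return A tibble with `normal_force` (N), `cop_x`, `cop_y` (m) and a
#'   `floored` attribute.
#' @export
idealize_insole <- function(grf, cop_global, foot_quat, heel_origin = c(0, 0, 0)) {
  nrm <- sqrt(rowSums(foot_quat^2))
  if (max(abs(nrm - 1)) > 1e-6) abort("foot orientation quaternions are not unit norm.")
  R <- rotmat_from_quat(foot_quat)
  sole_normal <- rotmat_apply(R, c(0, 1, 0))
  f_n <- dot3(grf, sole_normal)
  floored <- sum(f_n < 0)
  f_n <- pmax(0, f_n)
  if (is.null(dim(heel_origin))) heel_origin <- mat3_const(heel_origin, nrow(R))
  cop_local <- rotmat_apply(rotmat_transpose(R), cop_global - heel_origin)
  out <- tibble::tibble(normal_force = f_n,
                        cop_x = cop_local[, 1], cop_y = cop_local[, 3])
  attr(out, "floored") <- floored
  out
}
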