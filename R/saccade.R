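#' Quintic saccade waveform
#'
#' Angular displacement during a saccade is modelled as a fifth-order
#' polynomial theta(t) = c0 + c1 t + ... + c5 t^5 on `[0, duration]`, held at
#' its final value afterwards. The published coefficient set stops at c4; the
#' quintic coefficient is recovered from the end-of-saccade rest condition
#' d(theta)/dt(duration) = 0, which also lands the final angle within 1% of
#' the nominal 50 degree amplitude (the cross-check is enforced here).
#'
#' Default coefficients give a 50 degree saccade in 0.137 s with peak angular
#' velocity ~547 deg/s attained ~0.034 s after onset. After the rotation the
#' eye is held fixed for one further `duration` (the post-saccade window), so
#' evaluators accept t in `[0, 2*duration]`.
#'
#' @param c0,c1,c2,c3,c4 Polynomial coefficients in deg, deg/s, ... deg/s^4.
#' @param duration Saccade duration T, seconds.
#' @param amplitude Nominal amplitude, degrees (used only for the c5
#'   cross-check).
#' @param rotation_axis Unit vector of the rotation axis in the anatomical
#'   frame; default the superior axis (horizontal saccade).
#' @param check When `TRUE`, verify theta(T) is within 1% of `amplitude`
#'   (skipped automatically when all coefficients are zero).
#' @return Object of class `saccade_wave`.
#' @examples
#' w <- saccade_wave()
#' saccade_theta(w, w$duration)
#' saccade_peak_velocity(w)
#' @export
saccade_wave <- function(c0 = 0, c1 = 0, c2 = 2.01e4, c3 = -3.29e5,
                         c4 = 2.30e6, duration = 0.137, amplitude = 50,
                         rotation_axis = c(0, 1, 0), check = TRUE) {
  stopifnot(duration > 0, length(rotation_axis) == 3)
  c5 <- complete_quintic_coefficient(c0, c1, c2, c3, c4, duration)
  coef <- c(c0, c1, c2, c3, c4, c5)
  w <- structure(list(
    coefficients = coef, duration = duration, amplitude = amplitude,
    post_saccade_window = duration,
    rotation_axis = rotation_axis / sqrt(sum(rotation_axis^2))
  ), class = "saccade_wave")
  if (check && any(coef != 0)) {
    thT <- saccade_theta(w, duration)
    if (abs(thT - amplitude) > 0.01 * amplitude)
      stop(sprintf(
        "end angle %.2f deg is not within 1%% of the %g deg amplitude",
        thT, amplitude), call. = FALSE)
  }
  w
}

#' Quintic coefficient from the end-of-saccade rest condition
#'
#' Solves d(theta)/dt(T) = 0 for c5 given c0..c4: the angular velocity
#' polynomial must vanish when the rotation ends, which keeps velocity (and
#' acceleration) continuous into the post-saccade hold.
#'
#' @inheritParams saccade_wave
#' @return c5 in deg/s^5.
#' @export
complete_quintic_coefficient <- function(c0, c1, c2, c3, c4, duration) {
  stopifnot(duration > 0)
  T <- duration
  -(c1 + 2 * c2 * T + 3 * c3 * T^2 + 4 * c4 * T^3) / (5 * T^4)
}

check_saccade_time <- function(wave, t) {
  if (any(t < -1e-12 | t > 2 * wave$duration + 1e-12))
    stop("t outside [0, 2*duration]", call. = FALSE)
}

polyval_asc <- function(coef, t) {
  ## Horner evaluation, ascending coefficients
  acc <- rep(0, length(t))
  for (ck in rev(coef)) acc <- acc * t + ck
  acc
}

#' Saccade kinematics evaluators
#'
#' Angular displacement (deg), velocity (deg/s) and acceleration (deg/s^2) at
#' times `t` in `[0, 2*duration]`. During the post-saccade window the angle
#' is held at theta(duration) and velocity/acceleration are zero.
#'
#' @param wave A [saccade_wave()].
#' @param t Times, seconds.
#' @return Numeric vector matching `t`.
#' @export
saccade_theta <- function(wave, t) {
  check_saccade_time(wave, t)
  T <- wave$duration
  out <- polyval_asc(wave$coefficients, pmin(t, T))
  out
}

#' @rdname saccade_theta
#' @export
saccade_omega <- function(wave, t) {
  check_saccade_time(wave, t)
  dcoef <- wave$coefficients[-1] * seq_len(5)
  ifelse(t > wave$duration, 0, polyval_asc(dcoef, t))
}

#' @rdname saccade_theta
#' @export
saccade_alpha <- function(wave, t) {
  check_saccade_time(wave, t)
  ddcoef <- wave$coefficients[c(-1, -2)] * c(2, 6, 12, 20)
  ifelse(t > wave$duration, 0, polyval_asc(ddcoef, t))
}

#' Peak angular velocity of the saccade
#'
#' Locates the global maximum of the angular velocity on `[0, duration]` from
#' the real roots of the acceleration polynomial (with the interval endpoints
#' as candidates).
#'
#' @param wave A [saccade_wave()].
#' @return List with `t_peak` (s) and `omega_peak` (deg/s).
#' @export
saccade_peak_velocity <- function(wave) {
  T <- wave$duration
  ddcoef <- wave$coefficients[c(-1, -2)] * c(2, 6, 12, 20)
  cand <- c(0, T)
  if (any(ddcoef != 0)) {
    r <- polyroot(ddcoef)
    r <- Re(r[abs(Im(r)) < 1e-8 * max(1, abs(Re(r)))])
    cand <- c(cand, r[r > 0 & r < T])
  }
  om <- saccade_omega(wave, cand)
  i <- which.max(om)
  list(t_peak = cand[i], omega_peak = om[i])
}

#' Tabulate the saccade waveform
#'
#' @param wave A [saccade_wave()].
#' @param dt Sampling step, seconds.
#' @return data.frame with `t_s`, `theta_deg`, `omega_deg_s`,
#'   `alpha_deg_s2` over `[0, 2*duration]`.
#' @export
saccade_table <- function(wave, dt = 1e-3) {
  t <- seq(0, 2 * wave$duration, by = dt)
  data.frame(t_s = t,
             theta_deg = saccade_theta(wave, t),
             omega_deg_s = saccade_omega(wave, t),
             alpha_deg_s2 = saccade_alpha(wave, t))
}

#' @export
print.saccade_wave <- function(x, ...) {
  pk <- saccade_peak_velocity(x)
  cat(sprintf(
    "saccade_wave: %.1f deg in %.3f s; peak %.0f deg/s at %.4f s\n",
    saccade_theta(x, x$duration), x$duration, pk$omega_peak, pk$t_peak))
  cat("  coefficients:", format(x$coefficients, digits = 6), "\n")
  invisible(x)
}
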