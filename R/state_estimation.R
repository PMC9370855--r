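#' State sequences
#'
#' A state sequence holds one motion state per trajectory sample:
#' positions, heading, speed, tangential acceleration and turn rate, plus a
#' variant tag recording how it was produced:
#'
#' * `"raw"` — finite differences of the sampled positions,
#' * `"offline"` — the same differences on the acausally smoothed baseline,
#' * `"realtime"` — the causal gait-compensated sequence.
#'
#' @param x,y,phi,v,a,w per-sample state channels (equal length).
#' @param dt sample interval, seconds.
#' @param variant one of `"raw"`, `"offline"`, `"realtime"`.
#' @return An object of class `"gc_states"`.
#' @export
state_sequence <- function(x, y, phi, v, a, w, dt, variant) {
  variant <- match.arg(variant, c("raw", "offline", "realtime"))
  n <- length(x)
  stopifnot(length(y) == n, length(phi) == n, length(v) == n,
            length(a) == n, length(w) == n, dt > 0)
  structure(list(x = x, y = y, phi = phi, v = v, a = a, w = w,
                 dt = dt, n = n, variant = variant),
            class = "gc_states")
}

#' @export
print.gc_states <- function(x, ...) {
  cat(sprintf("<state sequence> variant=%s, n=%d, dt=%.4g s, mean v=%.3f m/s\n",
              x$variant, x$n, x$dt, mean(x$v)))
  invisible(x)
}

#' Extract one sample of a state sequence as a motion state
#'
#' @param states a [state_sequence()].
#' @param k sample index (1-based).
#' @return A [motion_state()].
#' @export
state_at <- function(states, k) {
  stopifnot(inherits(states, "gc_states"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > states$n) {
    stop("k out of range", call. = FALSE)
  }
  motion_state(states$x[k], states$y[k], states$phi[k],
               states$v[k], states$a[k], states$w[k])
}

# ---- Butterworth low-pass design (analog prototype + bilinear transform) ----
#
# The `signal` package is not a dependency; for a fixed-order low-pass this is
# a short, well-conditioned computation. Verified against scipy.signal.butter
# in the test suite.
butter_lowpass <- function(order, cutoff_hz, fs) {
  if (cutoff_hz <= 0 || cutoff_hz >= fs / 2) {
    stop("cutoff must lie in (0, Nyquist)", call. = FALSE)
  }
  n <- as.integer(order)
  # analog Butterworth poles on the unit circle, prewarped cutoff
  k <- seq_len(n)
  pa <- exp(1i * pi * (2 * k + n - 1) / (2 * n))
  wc <- 2 * fs * tan(pi * cutoff_hz / fs)
  pa <- wc * pa
  # bilinear transform: s = 2*fs*(z-1)/(z+1)
  pd <- (1 + pa / (2 * fs)) / (1 - pa / (2 * fs))
  zd <- rep(-1 + 0i, n)
  poly_from_roots <- function(r) {
    p <- 1 + 0i
    for (ri in r) p <- c(p, 0) - c(0, p * ri)
    p
  }
  a <- poly_from_roots(pd)
  b <- poly_from_roots(zd)
  # unity DC gain: H(z=1) = 1
  g <- sum(a) / sum(b)
  list(b = Re(b * g), a = Re(a))
}

# direct-form I IIR filter, zero initial state
iir_filter <- function(b, a, x) {
  nb <- length(b); na_ <- length(a)
  n <- length(x)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (j in seq_len(nb)) {
      if (i - j + 1L >= 1L) acc <- acc + b[j] * x[i - j + 1L]
    }
    if (na_ >= 2L) {
      for (j in 2:na_) {
        if (i - j + 1L >= 1L) acc <- acc - a[j] * y[i - j + 1L]
      }
    }
    y[i] <- acc / a[1]
  }
  y
}

# filter one channel; subtracting the first sample removes the step transient
# a DC-unity causal filter would otherwise ring on (positions are far from 0)
filter_channel <- function(coef, x, zero_phase) {
  x0 <- x[1]
  z <- x - x0
  if (!zero_phase) {
    return(iir_filter(coef$b, coef$a, z) + x0)
  }
  # forward-backward pass with odd reflection padding at both ends
  npad <- min(length(z) - 1L, 3L * (length(coef$a) - 1L) * 10L)
  head_pad <- 2 * z[1] - z[seq(npad + 1L, 2L, by = -1L)]
  tail_pad <- 2 * z[length(z)] - z[seq(length(z) - 1L, length(z) - npad, by = -1L)]
  ze <- c(head_pad, z, tail_pad)
  y <- iir_filter(coef$b, coef$a, ze)
  y <- rev(iir_filter(coef$b, coef$a, rev(y)))
  y[seq(npad + 1L, npad + length(z))] + x0
}

#' Acquisition low-pass prefilter
#'
#' Butterworth low-pass applied to the position channels and pelvis yaw,
#' mirroring the acquisition-stage filtering of optical motion capture: by
#' default a 3rd-order filter with a 6 Hz cut-off, which passes everything
#' relevant to human gait and removes measurement jitter above it. DC gain is
#' exactly 1. The default mode is causal (suitable for the real-time path); a
#' zero-phase forward-backward mode is available for offline use.
#'
#' @param traj a [trajectory()].
#' @param order filter order (default 3).
#' @param cutoff_hz cut-off frequency, Hz (default 6); must be below the
#'   Nyquist frequency `1/(2 dt)`.
#' @param zero_phase if `TRUE`, filter forward and backward (acausal, no phase
#'   lag).
#' @return The filtered [trajectory()].
#' @export
lowpass_prefilter <- function(traj, order = 3, cutoff_hz = 6,
                              zero_phase = FALSE) {
  stopifnot(inherits(traj, "gc_trajectory"))
  fs <- 1 / traj$dt
  if (cutoff_hz >= fs / 2) {
    stop(sprintf("cutoff %.3g Hz >= Nyquist %.3g Hz", cutoff_hz, fs / 2),
         call. = FALSE)
  }
  coef <- butter_lowpass(order, cutoff_hz, fs)
  pelvis <- traj$phi_pelvis
  if (!is.null(pelvis)) {
    # filter the unwrapped angle so wrap jumps are not smeared
    pelvis <- filter_channel(coef, unwrap_angle(pelvis), zero_phase)
    pelvis <- wrap_angle(pelvis)
  }
  replace_channels(traj,
                   x = filter_channel(coef, traj$x, zero_phase),
                   y = filter_channel(coef, traj$y, zero_phase),
                   phi_pelvis = pelvis)
}

#' Estimate raw motion states from sampled positions
#'
#' Backward finite differences of the landmark positions give, per sample k:
#' heading `phi_k = atan2(y_k - y_{k-1}, x_k - x_{k-1})` (four-quadrant),
#' speed `v_k = ||displacement|| / dt`, then `a_k = (v_k - v_{k-1})/dt` and
#' `w_k = (phi_k - phi_{k-1})/dt` with `phi` unwrapped before differencing.
#' Samples where a difference is undefined (the first one or two) are filled
#' by copying the first defined value. Zero-displacement samples carry the
#' previous heading forward with `v = 0`.
#'
#' @param traj a [trajectory()] (at least 3 samples).
#' @return A [state_sequence()] with variant `"raw"`.
#' @export
estimate_raw_states <- function(traj) {
  stopifnot(inherits(traj, "gc_trajectory"))
  n <- traj$n
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  dt <- traj$dt
  dx <- diff(traj$x); dy <- diff(traj$y)
  disp <- sqrt(dx^2 + dy^2)
  v <- disp / dt                       # defined at samples 2..n
  phi <- atan2(dy, dx)                 # defined at samples 2..n
  zero <- disp == 0
  if (any(zero)) {
    # carry previous heading forward; leading zeros take the first defined one
    first_ok <- which(!zero)[1]
    if (is.na(first_ok)) {
      phi[] <- 0
    } else {
      if (first_ok > 1L) phi[seq_len(first_ok - 1L)] <- phi[first_ok]
      for (i in which(zero)) if (i > first_ok) phi[i] <- phi[i - 1L]
    }
  }
  phi_u <- unwrap_angle(phi)
  a <- diff(v) / dt                    # defined at samples 3..n
  w <- diff(phi_u) / dt
  state_sequence(
    x = traj$x, y = traj$y,
    phi = wrap_angle(c(phi_u[1], phi_u)),
    v = c(v[1], v),
    a = c(a[1], a[1], a),
    w = c(w[1], w[1], w),
    dt = dt, variant = "raw")
}
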