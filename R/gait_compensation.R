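#' Compensation parameters
#'
#' Tunables of the causal gait compensation.
#'
#' @param K orientation blend gain in `[0, 1]` weighting pelvis yaw against
#'   the position-derived heading, or `NA` (meaning "calibrate first", see
#'   [calibrate_K()]).
#' @param peak_min_interval_s minimum separation between detected foot-contact
#'   events, seconds. The default 0.25 s leaves margin below the fastest
#'   normal step (cadence up to about 1.3 strides/s, i.e. 2.6 steps/s).
#' @param peak_min_prominence_frac minimum prominence of an accepted extremum
#'   of `dv/dt`, as a fraction of the running peak-to-peak of that signal.
#' @param peak_min_prominence_abs absolute prominence floor, m/s^2; rejects
#'   the numerical-noise extrema of an essentially constant speed signal.
#' @param smooth_window odd number of samples of the causal moving average
#'   applied to `dv/dt` before extremum detection (noise guard); the reported
#'   event index is corrected for its known `(L-1)/2`-sample delay.
#' @param ptp_window_s length of the trailing window over which the running
#'   peak-to-peak of `dv/dt` (the prominence reference) is taken, seconds.
#'   A finite window lets the detector forget filter start-up transients;
#'   2.5 s covers at least 1.5 strides at the slowest normal cadence.
#' @param warmup_s initial stretch in which no event is accepted, seconds;
#'   finite-difference fills and the causal prefilter transient make the very
#'   first samples unreliable.
#' @param phi_offset constant mounting offset subtracted from pelvis yaw
#'   before blending, radians. Estimated by [calibrate_K()].
#' @return A list of class `"gc_params"`.
#' @export
compensation_params <- function(K = NA_real_,
                                peak_min_interval_s = 0.25,
                                peak_min_prominence_frac = 0.10,
                                peak_min_prominence_abs = 1e-6,
                                smooth_window = 5L,
                                ptp_window_s = 2.5,
                                warmup_s = 0.5,
                                phi_offset = 0) {
  if (!is.na(K) && (K < 0 || K > 1)) stop("K must lie in [0, 1]", call. = FALSE)
  if (peak_min_interval_s <= 0) {
    stop("peak_min_interval_s must be > 0", call. = FALSE)
  }
  smooth_window <- as.integer(smooth_window)
  if (smooth_window < 1L || smooth_window %% 2L == 0L) {
    stop("smooth_window must be a positive odd integer", call. = FALSE)
  }
  stopifnot(ptp_window_s > 0, warmup_s >= 0)
  structure(list(K = K,
                 peak_min_interval_s = peak_min_interval_s,
                 peak_min_prominence_frac = peak_min_prominence_frac,
                 peak_min_prominence_abs = peak_min_prominence_abs,
                 smooth_window = smooth_window,
                 ptp_window_s = ptp_window_s,
                 warmup_s = warmup_s,
                 phi_offset = phi_offset),
            class = "gc_params")
}

#' @export
print.gc_params <- function(x, ...) {
  cat(sprintf(
    "<compensation params> K=%s, min interval=%.3g s, prominence frac=%.3g, smoothing=%d samples, pelvis offset=%.4g rad\n",
    if (is.na(x$K)) "auto (uncalibrated)" else sprintf("%.4f", x$K),
    x$peak_min_interval_s, x$peak_min_prominence_frac,
    x$smooth_window, x$phi_offset))
  invisible(x)
}

#' Detect foot-contact events from the raw speed signal
#'
#' Initial and final foot contacts coincide with local maxima and minima of
#' the derivative of the walker's raw speed, i.e. with the mean crossings of
#' the once-per-stride speed oscillation. The detector is causal: `dv/dt`
#' (after a short causal moving average) is scanned sample by sample and an
#' extremum is confirmed one sample after it occurs. Accepted events must
#' alternate in type, be separated by at least `peak_min_interval_s`, and
#' differ from the previous accepted event by at least
#' `peak_min_prominence_frac` of the running peak-to-peak of `dv/dt`.
#'
#' @param states a raw [state_sequence()].
#' @param params [compensation_params()].
#' @return An object of class `"gc_events"`: list with `indices` (delay-
#'   corrected sample indices, strictly increasing), `labels` (alternating
#'   `"initial_contact"` / `"final_contact"`; minima of `dv/dt` are labelled
#'   initial contacts), and `apply_at` (the confirmation sample at which a
#'   causal consumer may start using each event). Zero rows when no extremum
#'   qualifies.
#' @export
detect_contacts <- function(states, params = compensation_params()) {
  stopifnot(inherits(states, "gc_states"), inherits(params, "gc_params"))
  if (states$variant != "raw") {
    stop("detect_contacts expects the raw state sequence", call. = FALSE)
  }
  n <- states$n
  dt <- states$dt
  d <- c(0, diff(states$v)) / dt
  L <- params$smooth_window
  if (L > 1L) {
    dm <- as.numeric(stats::filter(d, rep(1 / L, L), sides = 1))
    dm[seq_len(L - 1L)] <- d[seq_len(L - 1L)]
  } else {
    dm <- d
  }
  shift <- (L - 1L) %/% 2L
  min_sep <- max(1L, round(params$peak_min_interval_s / dt))
  idx <- integer(0); lab <- character(0); conf <- integer(0)
  last_type <- ""
  last_val <- NA_real_
  last_i <- -Inf
  wlen <- max(2L, round(params$ptp_window_s / dt))
  # v[1] and v[2] share a value (fill), so d is meaningful from sample 3 on
  start <- max(3L, L + 1L, round(params$warmup_s / dt))
  for (i in seq(start, length.out = max(0L, n - start))) {
    # i is confirmed using dm[i + 1] (one-sample confirmation lag)
    is_max <- dm[i] > dm[i - 1L] && dm[i] >= dm[i + 1L]
    is_min <- dm[i] < dm[i - 1L] && dm[i] <= dm[i + 1L]
    if (!is_max && !is_min) next
    typ <- if (is_max) "max" else "min"
    if (typ == last_type) next
    if (i - last_i < min_sep) next
    win <- dm[max(1L, i + 1L - wlen):(i + 1L)]
    rng <- max(win) - min(win)
    if (!is.finite(rng) || rng <= params$peak_min_prominence_abs) next
    ref <- if (is.na(last_val)) mean(win) else last_val
    if (abs(dm[i] - ref) < max(params$peak_min_prominence_frac * rng,
                               params$peak_min_prominence_abs)) next
    idx <- c(idx, i); conf <- c(conf, i + 1L)
    lab <- c(lab, if (typ == "min") "initial_contact" else "final_contact")
    last_type <- typ; last_val <- dm[i]; last_i <- i
  }
  # undo the known detection delay: (L-1)/2 samples from the moving average
  # plus 1 sample because the backward difference centres at k - 1
  corrected <- pmax(idx - shift - 1L, 1L)
  # delay correction must not reorder or collide events
  keep <- !duplicated(corrected)
  structure(list(indices = corrected[keep], labels = lab[keep],
                 apply_at = conf[keep], n = n, dt = dt),
            class = "gc_events")
}

#' @export
print.gc_events <- function(x, ...) {
  cat(sprintf("<gait events> %d contacts over %d samples (%.3g s mean spacing)\n",
              length(x$indices), x$n,
              if (length(x$indices) > 1) mean(diff(x$indices)) * x$dt else NA))
  invisible(x)
}

#' Hold the raw speed between foot-contact events
#'
#' The raw speed oscillates once per stride around the walking speed, and its
#' value at foot contacts approximately equals the stride mean. Holding the
#' event-sampled value (zero-order hold) therefore strips the oscillation
#' while tracking the mean in real time. The held acceleration is the speed
#' increment between consecutive events divided by the inter-event time, held
#' over the following segment.
#'
#' Causality: a hold only switches at the event's confirmation sample
#' (`apply_at`), using the speed value at the delay-corrected event index,
#' which is already in the past at confirmation time. Before the first event
#' the raw signals pass through; between the first and second events the held
#' acceleration is 0 (consistent with a constant held speed).
#'
#' @param states a raw [state_sequence()].
#' @param events a `"gc_events"` from [detect_contacts()] on the same
#'   sequence. With zero events the raw `v` and `a` pass through unchanged
#'   (fallback, reported via `message()`).
#' @return List with `v_tilde` and `a_tilde`, numeric vectors of length `n`.
#' @export
hold_velocity <- function(states, events) {
  stopifnot(inherits(states, "gc_states"), inherits(events, "gc_events"))
  n <- states$n
  if (length(events$indices) == 0L) {
    message("hold_velocity: no contact events detected; passing raw v, a through")
    return(list(v_tilde = states$v, a_tilde = states$a))
  }
  v <- states$v
  v_tilde <- v
  a_tilde <- states$a
  idx <- events$indices
  app <- events$apply_at
  t_ev <- (idx - 1) * states$dt
  for (j in seq_along(idx)) {
    from <- app[j]
    to <- if (j < length(idx)) app[j + 1L] - 1L else n
    if (from > n) break
    seg <- from:min(to, n)
    v_tilde[seg] <- v[idx[j]]
    a_tilde[seg] <- if (j == 1L) 0 else {
      (v[idx[j]] - v[idx[j - 1L]]) / (t_ev[j] - t_ev[j - 1L])
    }
  }
  list(v_tilde = v_tilde, a_tilde = a_tilde)
}

#' Blend position-derived heading with pelvis yaw
#'
#' During walking the position-derived heading and the pelvis yaw oscillate
#' in counter-phase around the true direction of travel, so the proportional
#' average `phi_tilde = K * phi_pelvis + (1 - K) * phi_raw` cancels the
#' oscillation for the right per-subject gain `K`. The blend operates on
#' unwrapped angles, after subtracting the constant mounting offset
#' `params$phi_offset` from the pelvis channel. The compensated turn rate is
#' the backward difference of `phi_tilde`.
#'
#' @param states a raw [state_sequence()].
#' @param traj the source [trajectory()]; must carry a pelvis channel.
#' @param params [compensation_params()] with a numeric `K`.
#' @return List with `phi_tilde` (wrapped to `(-pi, pi]`) and `w_tilde`.
#' @export
blend_orientation <- function(states, traj, params) {
  stopifnot(inherits(states, "gc_states"), inherits(traj, "gc_trajectory"),
            inherits(params, "gc_params"))
  if (is.null(traj$phi_pelvis)) {
    stop("blend_orientation: trajectory has no pelvis yaw channel",
         call. = FALSE)
  }
  K <- params$K
  if (is.na(K)) stop("K is not calibrated; run calibrate_K() first",
                     call. = FALSE)
  phi_r <- unwrap_angle(states$phi)
  phi_h <- unwrap_angle(traj$phi_pelvis) - params$phi_offset
  # resolve any residual whole-turn offset between the two unwrapped branches
  phi_h <- phi_h - 2 * pi * round((phi_h[1] - phi_r[1]) / (2 * pi))
  phi_tilde <- K * phi_h + (1 - K) * phi_r
  w_tilde <- diff(phi_tilde) / states$dt
  w_tilde <- c(w_tilde[1], w_tilde)
  list(phi_tilde = wrap_angle(phi_tilde), w_tilde = w_tilde)
}

#' Calibrate the orientation blend gain K
#'
#' Finds the per-subject gain `K*` minimising the summed squared difference
#' between the blended heading and the offline baseline heading:
#' `K* = argmin_K sum_k (K phi^h_k + (1-K) phi^r_k - phi^b_k)^2`,
#' a scalar least-squares problem with the closed form
#' `K* = sum(d r) / sum(d^2)` where `d = phi^h - phi^r` (after removing the
#' mean pelvis mounting offset) and `r = phi^b - phi^r`; the result is
#' clipped to `[0, 1]`. When pelvis and raw headings are indistinguishable
#' the gain is undefined and 0 is returned with a warning.
#'
#' @param raw raw [state_sequence()] of the calibration walk.
#' @param baseline offline [state_sequence()] of the same walk (from
#'   [estimate_offline_states()]).
#' @param traj the source [trajectory()] with pelvis channel.
#' @param params optional [compensation_params()] whose detector settings are
#'   kept in the returned object.
#' @return [compensation_params()] with calibrated `K` and `phi_offset`.
#' @export
calibrate_K <- function(raw, baseline, traj, params = compensation_params()) {
  stopifnot(inherits(raw, "gc_states"), inherits(baseline, "gc_states"),
            inherits(traj, "gc_trajectory"))
  if (raw$variant != "raw" || baseline$variant != "offline") {
    stop("calibrate_K needs a raw and an offline state sequence", call. = FALSE)
  }
  if (raw$n != traj$n || baseline$n != traj$n) {
    stop("sequences are not aligned to the trajectory", call. = FALSE)
  }
  if (is.null(traj$phi_pelvis)) {
    stop("calibrate_K: trajectory has no pelvis yaw channel", call. = FALSE)
  }
  phi_r <- unwrap_angle(raw$phi)
  phi_b <- unwrap_angle(baseline$phi)
  phi_h <- unwrap_angle(traj$phi_pelvis)
  offset <- mean(phi_h - phi_r)
  d <- (phi_h - offset) - phi_r
  r <- phi_b - phi_r
  denom <- sum(d^2)
  if (denom < 1e-12 * raw$n) {
    warning("pelvis and raw headings coincide; K is undefined, returning 0")
    K <- 0
  } else {
    K <- min(1, max(0, sum(d * r) / denom))
  }
  compensation_params(K = K,
                      peak_min_interval_s = params$peak_min_interval_s,
                      peak_min_prominence_frac = params$peak_min_prominence_frac,
                      peak_min_prominence_abs = params$peak_min_prominence_abs,
                      smooth_window = params$smooth_window,
                      ptp_window_s = params$ptp_window_s,
                      warmup_s = params$warmup_s,
                      phi_offset = offset)
}

#' Assemble the real-time estimated state sequence
#'
#' Combines the causal compensations into the real-time estimated trajectory:
#' raw positions, pelvis-blended heading, event-held speed and acceleration,
#' and the turn rate differenced from the blended heading. Every value at
#' sample `k` depends only on samples up to `k + 1` (one-sample extremum
#' confirmation lag).
#'
#' Graceful degradation: without a pelvis channel the raw heading and turn
#' rate are kept (and a message is emitted); without detected contact events
#' the raw speed and acceleration are kept.
#'
#' @param traj a [trajectory()] (already prefiltered if desired).
#' @param params calibrated [compensation_params()]; `K` must be numeric when
#'   a pelvis channel is present.
#' @return A [state_sequence()] with variant `"realtime"`; the detected
#'   events are attached as attribute `"events"`.
#' @export
build_realtime_states <- function(traj, params) {
  stopifnot(inherits(traj, "gc_trajectory"), inherits(params, "gc_params"))
  raw <- estimate_raw_states(traj)
  events <- detect_contacts(raw, params)
  hv <- hold_velocity(raw, events)
  if (is.null(traj$phi_pelvis)) {
    message("build_realtime_states: no pelvis channel; keeping raw heading")
    phi_tilde <- raw$phi
    w_tilde <- raw$w
  } else {
    bo <- blend_orientation(raw, traj, params)
    phi_tilde <- bo$phi_tilde
    w_tilde <- bo$w_tilde
  }
  out <- state_sequence(x = raw$x, y = raw$y, phi = phi_tilde,
                        v = hv$v_tilde, a = hv$a_tilde, w = w_tilde,
                        dt = raw$dt, variant = "realtime")
  attr(out, "events") <- events
  out
}
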