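#' Fit the offline polynomial baseline of a trajectory
#'
#' Batch least-squares polynomial regression of `x(t)` and `y(t)` against
#' time, removing the once-per-stride waviness that gait imprints on the
#' landmark path. Time is mapped to `[-1, 1]` per segment and the fit uses an
#' orthogonal polynomial basis, so degree 8 remains well conditioned. The
#' pelvis channel passes through unchanged.
#'
#' Degree 1 suits straight segments; degree 8 follows a single turn of a
#' curved segment. Walks spanning several turns must be split first: supply
#' `segments`, a list of `c(first, last)` 1-based inclusive sample index
#' pairs, and each segment is fitted independently (indices not covered pass
#' through unsmoothed).
#'
#' @param traj a [trajectory()].
#' @param degree polynomial degree (`>= 1`). Default: 8 when the trajectory's
#'   `path_type` attribute is `"curved"`, else 1.
#' @param segments optional list of `c(first, last)` index pairs.
#' @return The smoothed [trajectory()], tagged with attribute
#'   `smoothed = TRUE` (required by [estimate_offline_states()]).
#' @export
fit_baseline <- function(traj, degree = NULL, segments = NULL) {
  stopifnot(inherits(traj, "gc_trajectory"))
  if (is.null(degree)) {
    degree <- if (identical(attr(traj, "path_type"), "curved")) 8L else 1L
  }
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1", call. = FALSE)
  if (is.null(segments)) segments <- list(c(1L, traj$n))
  x <- traj$x; y <- traj$y
  for (seg in segments) {
    i0 <- as.integer(seg[1]); i1 <- as.integer(seg[2])
    if (i0 < 1L || i1 > traj$n || i1 <= i0) {
      stop("invalid segment [", i0, ", ", i1, "]", call. = FALSE)
    }
    idx <- i0:i1
    if (length(idx) <= degree + 1L) {
      stop("segment too short for degree ", degree,
           " fit (need n > degree + 1)", call. = FALSE)
    }
    tt <- traj$t[idx]
    tn <- 2 * (tt - tt[1]) / (tt[length(tt)] - tt[1]) - 1
    basis <- stats::poly(tn, degree = degree)
    x[idx] <- stats::fitted(stats::lm.fit(cbind(1, basis), traj$x[idx]))
    y[idx] <- stats::fitted(stats::lm.fit(cbind(1, basis), traj$y[idx]))
  }
  out <- replace_channels(traj, x = x, y = y)
  attr(out, "smoothed") <- TRUE
  attr(out, "baseline_degree") <- degree
  out
}

#' Derive offline states from a fitted baseline
#'
#' Applies the same backward-difference state estimation as
#' [estimate_raw_states()] to the smoothed positions. The result is tagged
#' `"offline"`: it is acausal by construction (the polynomial fit saw the
#' whole signal) and is refused by the real-time compensation path.
#'
#' @param baseline a trajectory produced by [fit_baseline()].
#' @return A [state_sequence()] with variant `"offline"`.
#' @export
estimate_offline_states <- function(baseline) {
  stopifnot(inherits(baseline, "gc_trajectory"))
  if (!isTRUE(attr(baseline, "smoothed"))) {
    stop("estimate_offline_states expects a trajectory from fit_baseline()",
         call. = FALSE)
  }
  st <- estimate_raw_states(baseline)
  st$variant <- "offline"
  st
}
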