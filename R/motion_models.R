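#' Kinematic motion models for short-horizon pedestrian prediction
#'
#' The four discrete planar kinematic models used throughout the package:
#'
#' * `"CV"`   constant velocity (w = a = 0),
#' * `"CA"`   constant acceleration (w = 0, a constant),
#' * `"CTRV"` constant turn rate and velocity (w constant, a = 0),
#' * `"CTRA"` constant turn rate and acceleration (w and a constant).
#'
#' All are exact discretisations of the continuous unicycle kinematics
#' \eqn{\dot x = v\cos\phi,\ \dot y = v\sin\phi,\ \dot\phi = w,\ \dot v = a}
#' under the model's constancy assumptions over a step of length `dt`.
#'
#' @name motion_models
#' @keywords internal
NULL

#' Supported model kinds
#'
#' @return Character vector `c("CV", "CA", "CTRV", "CTRA")`.
#' @export
model_kinds <- function() c("CV", "CA", "CTRV", "CTRA")

# turn rates below this magnitude (rad/s) use the analytic w -> 0 limit of the
# curvilinear models so propagation is continuous in w
.EPS_W <- 1e-6

#' Construct a motion state
#'
#' A motion state holds the planar position, heading and motion scalars of the
#' walker at one instant: `(x, y, phi, v, a, w)`.
#'
#' @param x,y position east/north components, metres.
#' @param phi heading, radians; stored wrapped to `(-pi, pi]`.
#' @param v translational speed, m/s.
#' @param a tangential acceleration, m/s^2.
#' @param w turn rate, rad/s.
#' @return A named numeric vector of class `"gc_state"`.
#' @examples
#' motion_state(0, 0, pi / 2, v = 1.3)
#' @export
motion_state <- function(x, y, phi, v, a = 0, w = 0) {
  s <- c(x = as.numeric(x), y = as.numeric(y), phi = as.numeric(phi),
         v = as.numeric(v), a = as.numeric(a), w = as.numeric(w))
  if (!all(is.finite(s))) {
    stop("motion_state: all fields must be finite", call. = FALSE)
  }
  s[["phi"]] <- wrap_angle(s[["phi"]])
  structure(s, class = "gc_state")
}

#' @export
print.gc_state <- function(x, ...) {
  cat(sprintf(
    "<motion state> x=%.4f m  y=%.4f m  phi=%.4f rad  v=%.4f m/s  a=%.4f m/s2  w=%.4f rad/s\n",
    x[["x"]], x[["y"]], x[["phi"]], x[["v"]], x[["a"]], x[["w"]]))
  invisible(x)
}

#' Wrap angles to the interval (-pi, pi]
#'
#' @param phi numeric vector of angles, radians.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(phi) {
  out <- -((-phi + pi) %% (2 * pi) - pi)
  # map the boundary so the range is (-pi, pi]
  out[out == -pi] <- pi
  out
}

#' Unwrap a sampled angle sequence
#'
#' Removes the 2*pi jumps introduced by wrapping, assuming successive samples
#' differ by less than pi.
#'
#' @param phi numeric vector of (possibly wrapped) angles, radians.
#' @return Unwrapped angles; `phi[1]` is kept as-is.
#' @export
unwrap_angle <- function(phi) {
  if (length(phi) < 2L) return(phi)
  d <- diff(phi)
  jumps <- -2 * pi * round(d / (2 * pi))
  phi + c(0, cumsum(d + jumps)) - c(0, cumsum(d))
}

# One propagation step for a state matrix S (columns x, y, phi, v, a, w).
# Vectorised over rows; this kernel backs propagate(), propagate_n() and the
# horizon sweep. Fields a model ignores pass through unchanged.
step_states <- function(S, model, dt) {
  x <- S[, 1L]; y <- S[, 2L]; phi <- S[, 3L]
  v <- S[, 4L]; a <- S[, 5L]; w <- S[, 6L]
  # expressions are arranged so that the zero-parameter cases are bit-exact
  # reductions: CA with a = 0 equals CV, CTRA with a = 0 equals CTRV
  if (model == "CV") {
    ds <- v * dt
    x1 <- x + ds * cos(phi)
    y1 <- y + ds * sin(phi)
    phi1 <- phi; v1 <- v
  } else if (model == "CA") {
    ds <- v * dt + (0.5 * a * dt) * dt
    x1 <- x + ds * cos(phi)
    y1 <- y + ds * sin(phi)
    phi1 <- phi; v1 <- v + a * dt
  } else if (model %in% c("CTRV", "CTRA")) {
    acc <- if (model == "CTRA") a else 0
    phi1 <- phi + w * dt
    v1 <- v + acc * dt
    small <- abs(w) < .EPS_W
    ws <- ifelse(small, 1, w)
    xg <- x + (v / ws) * (sin(phi1) - sin(phi)) +
      acc * ((dt / ws) * sin(phi1) + (cos(phi1) - cos(phi)) / ws^2)
    yg <- y - (v / ws) * (cos(phi1) - cos(phi)) -
      acc * ((dt / ws) * cos(phi1) - (sin(phi1) - sin(phi)) / ws^2)
    ds <- v * dt + (0.5 * acc * dt) * dt
    xl <- x + ds * cos(phi)
    yl <- y + ds * sin(phi)
    x1 <- ifelse(small, xl, xg)
    y1 <- ifelse(small, yl, yg)
  } else {
    stop("unknown model kind: ", model, call. = FALSE)
  }
  S[, 1L] <- x1; S[, 2L] <- y1; S[, 3L] <- wrap_angle(phi1); S[, 4L] <- v1
  S
}

check_model <- function(model) {
  model <- toupper(model)
  if (!(model %in% model_kinds())) {
    stop("model must be one of ", paste(model_kinds(), collapse = ", "),
         call. = FALSE)
  }
  model
}

as_state_row <- function(state) {
  s <- unclass(state)
  need <- c("x", "y", "phi", "v", "a", "w")
  if (!all(need %in% names(s))) {
    stop("state must have fields ", paste(need, collapse = ", "), call. = FALSE)
  }
  s <- as.numeric(s[need])
  if (!all(is.finite(s))) stop("state must be finite", call. = FALSE)
  matrix(s, nrow = 1L, dimnames = list(NULL, need))
}

#' Propagate a motion state one step ahead
#'
#' Applies the chosen model's discrete update over a step `dt`. For `CTRV` and
#' `CTRA`, turn rates with `|w| < 1e-6` rad/s use the analytic straight-line
#' limit so the update is continuous in `w`. The output heading is wrapped to
#' `(-pi, pi]`. Fields a model does not use (e.g. `w` under `CA`) are passed
#' through unchanged, so recursive application keeps the model's constants.
#'
#' @param state a [motion_state()].
#' @param model one of [model_kinds()].
#' @param dt step length, seconds, `> 0`.
#' @return The state one step ahead, a `"gc_state"`.
#' @examples
#' s <- motion_state(0, 0, 0, v = 1, w = pi / 2)
#' propagate(s, "CTRV", dt = 1) # quarter circle of radius 2/pi
#' @export
propagate <- function(state, model, dt) {
  model <- check_model(model)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number", call. = FALSE)
  }
  S <- step_states(as_state_row(state), model, dt)
  motion_state(S[1, 1], S[1, 2], S[1, 3], S[1, 4], S[1, 5], S[1, 6])
}

#' Propagate a motion state recursively over several steps
#'
#' Element `i` of the result equals `propagate` applied `i` times: the model is
#' re-fed its own output, exactly as in recursive fixed-horizon forecasting.
#'
#' @inheritParams propagate
#' @param n_steps number of steps, `>= 1`.
#' @return A data.frame with `n_steps` rows and columns
#'   `x, y, phi, v, a, w`.
#' @export
propagate_n <- function(state, model, dt, n_steps) {
  model <- check_model(model)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    stop("dt must be a single positive number", call. = FALSE)
  }
  n_steps <- as.integer(n_steps)
  if (is.na(n_steps) || n_steps < 1L) {
    stop("n_steps must be >= 1", call. = FALSE)
  }
  S <- as_state_row(state)
  out <- matrix(NA_real_, nrow = n_steps, ncol = 6L,
                dimnames = list(NULL, colnames(S)))
  for (i in seq_len(n_steps)) {
    S <- step_states(S, model, dt)
    out[i, ] <- S
  }
  as.data.frame(out)
}
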