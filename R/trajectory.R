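#' Construct a sampled trajectory
#'
#' A trajectory is a uniformly sampled sequence of time, planar position of a
#' waist-level landmark, and (optionally) pelvis yaw. Sampling must be
#' strictly uniform: the spacing of `t` may deviate from its mean by at most
#' 1e-9 s.
#'
#' @param t sample times, seconds, strictly increasing, uniformly spaced.
#' @param x,y landmark position, metres.
#' @param phi_pelvis pelvis yaw, radians, or `NULL` when no pelvis sensor is
#'   available.
#' @param path_type optional label, `"straight"` or `"curved"`, carried as an
#'   attribute and used to pick the default baseline polynomial degree.
#' @return An object of class `"gc_trajectory"`: a list with elements
#'   `t, x, y, phi_pelvis, dt, n`.
#' @examples
#' tr <- trajectory(t = seq(0, 1, 0.01), x = seq(0, 1.3, length.out = 101),
#'                  y = numeric(101))
#' tr
#' @export
trajectory <- function(t, x, y, phi_pelvis = NULL, path_type = NULL) {
  t <- as.numeric(t); x <- as.numeric(x); y <- as.numeric(y)
  n <- length(t)
  if (n < 3L) stop("trajectory needs at least 3 samples", call. = FALSE)
  if (length(x) != n || length(y) != n) {
    stop("t, x, y must have the same length", call. = FALSE)
  }
  if (!is.null(phi_pelvis)) {
    phi_pelvis <- as.numeric(phi_pelvis)
    if (length(phi_pelvis) != n) {
      stop("phi_pelvis must match the length of t", call. = FALSE)
    }
    if (!all(is.finite(phi_pelvis))) {
      stop("phi_pelvis must be finite", call. = FALSE)
    }
  }
  if (!all(is.finite(t)) || !all(is.finite(x)) || !all(is.finite(y))) {
    stop("t, x, y must be finite", call. = FALSE)
  }
  dts <- diff(t)
  if (any(dts <= 0)) stop("t must be strictly increasing", call. = FALSE)
  dt <- mean(dts)
  if (max(abs(dts - dt)) > 1e-9) {
    stop("t must be uniformly spaced (tolerance 1e-9 s)", call. = FALSE)
  }
  structure(
    list(t = t, x = x, y = y, phi_pelvis = phi_pelvis, dt = dt, n = n),
    path_type = path_type,
    class = "gc_trajectory")
}

#' @export
print.gc_trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> n=%d samples, dt=%.4g s (%.4g Hz), duration=%.3f s, pelvis yaw: %s%s\n",
    x$n, x$dt, 1 / x$dt, x$t[x$n] - x$t[1],
    if (is.null(x$phi_pelvis)) "absent" else "present",
    if (is.null(attr(x, "path_type"))) ""
    else paste0(", path_type=", attr(x, "path_type"))))
  invisible(x)
}

#' Read a trajectory from CSV
#'
#' The on-disk contract is a UTF-8 CSV with header
#' `t_s,x_m,y_m,pelvis_yaw_rad`, one row per sample, decimal point, no
#' thousands separators. The pelvis column may be empty (all `NA`), in which
#' case the trajectory is read without a pelvis channel.
#'
#' @param path file path.
#' @param path_type optional `"straight"`/`"curved"` label to attach.
#' @return A [trajectory()].
#' @export
read_trajectory <- function(path, path_type = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  d <- utils::read.csv(path, header = TRUE)
  need <- c("t_s", "x_m", "y_m")
  if (!all(need %in% names(d))) {
    stop("trajectory CSV must have columns t_s,x_m,y_m[,pelvis_yaw_rad]",
         call. = FALSE)
  }
  pelvis <- if ("pelvis_yaw_rad" %in% names(d) && !all(is.na(d$pelvis_yaw_rad)))
    d$pelvis_yaw_rad else NULL
  trajectory(d$t_s, d$x_m, d$y_m, pelvis, path_type = path_type)
}

#' Write a trajectory to CSV
#'
#' @param traj a [trajectory()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  stopifnot(inherits(traj, "gc_trajectory"))
  d <- data.frame(
    t_s = traj$t, x_m = traj$x, y_m = traj$y,
    pelvis_yaw_rad = if (is.null(traj$phi_pelvis)) NA_real_ else traj$phi_pelvis)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

# internal: rebuild a trajectory with replaced channels, keeping attributes
replace_channels <- function(traj, x = NULL, y = NULL, phi_pelvis) {
  out <- trajectory(
    traj$t,
    if (is.null(x)) traj$x else x,
    if (is.null(y)) traj$y else y,
    if (missing(phi_pelvis)) traj$phi_pelvis else phi_pelvis,
    path_type = attr(traj, "path_type"))
  out
}
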