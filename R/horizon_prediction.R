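#' Recursive fixed-horizon position prediction from one start sample
#'
#' Seeds the chosen kinematic model with the state at sample `k` and applies
#' it recursively for `H` steps, feeding each output back as the next input.
#'
#' @param states a [state_sequence()] (any variant).
#' @param k start sample, 1-based; requires `k + H <= n`.
#' @param model one of [model_kinds()].
#' @param H horizon length in steps (`>= 1`).
#' @return An `H x 2` matrix of predicted positions (columns `x`, `y`);
#'   row `h` is the prediction for sample `k + h`.
#' @export
predict_from <- function(states, k, model, H) {
  stopifnot(inherits(states, "gc_states"))
  model <- check_model(model)
  k <- as.integer(k); H <- as.integer(H)
  if (is.na(H) || H < 1L) stop("H must be >= 1", call. = FALSE)
  if (is.na(k) || k < 1L || k + H > states$n) {
    stop("start index k out of range (need 1 <= k and k + H <= n)",
         call. = FALSE)
  }
  S <- matrix(c(states$x[k], states$y[k], states$phi[k],
                states$v[k], states$a[k], states$w[k]), nrow = 1L)
  out <- matrix(NA_real_, nrow = H, ncol = 2L,
                dimnames = list(NULL, c("x", "y")))
  for (h in seq_len(H)) {
    S <- step_states(S, model, states$dt)
    out[h, ] <- S[1L, 1:2]
  }
  out
}

#' Euclidean prediction error sequence
#'
#' Element `h` is the Euclidean distance between the predicted position for
#' sample `k + h` and the measured (raw) position at that sample. Errors are
#' always measured against the measured positions, whichever state variant
#' seeded the prediction.
#'
#' @param predicted matrix of predicted positions from [predict_from()].
#' @param actual the measured [trajectory()].
#' @param k the start sample the prediction was seeded at.
#' @return Numeric vector of distances, metres.
#' @export
error_sequence <- function(predicted, actual, k) {
  stopifnot(inherits(actual, "gc_trajectory"), is.matrix(predicted),
            ncol(predicted) == 2L)
  H <- nrow(predicted)
  k <- as.integer(k)
  if (k + H > actual$n) {
    stop("prediction extends past the end of the trajectory", call. = FALSE)
  }
  idx <- k + seq_len(H)
  sqrt((predicted[, 1L] - actual$x[idx])^2 +
         (predicted[, 2L] - actual$y[idx])^2)
}

#' Horizon-error sweep over all admissible start samples
#'
#' Runs the recursive prediction from every start sample whose full horizon
#' fits in the data, and aggregates the root-mean-square Euclidean error
#' across starts at each horizon step. The first two samples are skipped
#' (their finite-difference states are fill values).
#'
#' @param states a [state_sequence()].
#' @param actual the measured [trajectory()] the errors are taken against.
#' @param model one of [model_kinds()].
#' @param H horizon steps; default `round(1 / dt)` (a 1 s horizon).
#' @param first_start first admissible start sample (default 3).
#' @return An object of class `"gc_profile"`: list with `model`, `variant`,
#'   `rms` (length `H`, metres), `H`, `n_starts`, `dt`, `path_type`.
#' @export
horizon_sweep <- function(states, actual, model, H = NULL, first_start = 3L) {
  stopifnot(inherits(states, "gc_states"), inherits(actual, "gc_trajectory"))
  model <- check_model(model)
  if (states$n != actual$n) {
    stop("states and trajectory lengths differ", call. = FALSE)
  }
  if (is.null(H)) H <- as.integer(round(1 / states$dt))
  H <- as.integer(H)
  if (states$n <= H + first_start - 1L) {
    stop("trajectory too short for horizon H = ", H, call. = FALSE)
  }
  starts <- seq.int(first_start, states$n - H)
  S <- cbind(states$x[starts], states$y[starts], states$phi[starts],
             states$v[starts], states$a[starts], states$w[starts])
  rms <- numeric(H)
  for (h in seq_len(H)) {
    S <- step_states(S, model, states$dt)
    idx <- starts + h
    rms[h] <- sqrt(mean((S[, 1L] - actual$x[idx])^2 +
                          (S[, 2L] - actual$y[idx])^2))
  }
  structure(list(model = model, variant = states$variant, rms = rms, H = H,
                 n_starts = length(starts), dt = states$dt,
                 path_type = attr(actual, "path_type") %||% "unknown"),
            class = "gc_profile")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gc_profile <- function(x, ...) {
  cat(sprintf(
    "<horizon profile> %s/%s (%s): RMS %.1f mm at %.2f s over %d starts\n",
    x$model, x$variant, x$path_type, 1000 * x$rms[x$H], x$H * x$dt, x$n_starts))
  invisible(x)
}

#' Pool horizon-error profiles across walks
#'
#' Combines profiles of the same model and variant by the weighted quadratic
#' mean (weights = number of starts), which is exactly the RMS over the union
#' of the start sets.
#'
#' @param profiles list of `"gc_profile"` objects sharing `model`, `variant`,
#'   `H` and `dt`.
#' @param path_type label for the pooled profile (default: common label, or
#'   `"aggregated"` when mixed).
#' @return A pooled `"gc_profile"`.
#' @export
aggregate_profiles <- function(profiles, path_type = NULL) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "gc_profile")))
  m <- unique(vapply(profiles, `[[`, "", "model"))
  v <- unique(vapply(profiles, `[[`, "", "variant"))
  H <- unique(vapply(profiles, function(p) as.numeric(p$H), 1))
  dts <- vapply(profiles, `[[`, 1, "dt")
  if (length(m) != 1L || length(v) != 1L || length(H) != 1L ||
      diff(range(dts)) > 1e-9) {
    stop("profiles must share model, variant, H and dt", call. = FALSE)
  }
  dt <- mean(dts)
  H <- as.integer(H)
  w <- vapply(profiles, function(p) as.numeric(p$n_starts), 1)
  ss <- Reduce(`+`, Map(function(p, wi) wi * p$rms^2, profiles, w))
  pt <- unique(vapply(profiles, `[[`, "", "path_type"))
  structure(list(model = m, variant = v, rms = sqrt(ss / sum(w)), H = H,
                 n_starts = sum(w), dt = dt,
                 path_type = path_type %||%
                   (if (length(pt) == 1L) pt else "aggregated")),
            class = "gc_profile")
}

#' Summarise RMS error at a fixed horizon
#'
#' Produces the model x variant x path-type table of RMS prediction error at
#' the requested horizon, in millimetres. Profiles from several walks are
#' pooled per (model, variant, path type), and an `"aggregated"` row pooling
#' all path types is added per (model, variant).
#'
#' @param profiles list of `"gc_profile"` objects (may mix walks and path
#'   types; all must share `H` and `dt`).
#' @param at_s horizon at which to report, seconds (default 1.0); must not
#'   exceed `H * dt`.
#' @return A data.frame with columns
#'   `model, variant, path_type, horizon_s, rms_mm, n_starts`.
#' @export
summarize_profiles <- function(profiles, at_s = 1.0) {
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, TRUE, "gc_profile")))
  H <- unique(vapply(profiles, function(p) as.numeric(p$H), 1))
  dts <- vapply(profiles, `[[`, 1, "dt")
  if (length(H) != 1L || diff(range(dts)) > 1e-9) {
    stop("profiles must share H and dt", call. = FALSE)
  }
  dt <- mean(dts)
  h_at <- as.integer(round(at_s / dt))
  if (h_at < 1L || h_at > H) {
    stop(sprintf("requested horizon %.3g s outside the profiled range", at_s),
         call. = FALSE)
  }
  key <- function(p, with_path = TRUE) {
    paste(p$model, p$variant, if (with_path) p$path_type else "", sep = "|")
  }
  rows <- list()
  for (k in unique(vapply(profiles, key, ""))) {
    grp <- profiles[vapply(profiles, key, "") == k]
    agg <- aggregate_profiles(grp)
    rows[[length(rows) + 1L]] <- data.frame(
      model = agg$model, variant = agg$variant, path_type = agg$path_type,
      horizon_s = h_at * dt, rms_mm = 1000 * agg$rms[h_at],
      n_starts = agg$n_starts)
  }
  for (k in unique(vapply(profiles, key, "", with_path = FALSE))) {
    grp <- profiles[vapply(profiles, key, "", with_path = FALSE) == k]
    if (length(unique(vapply(grp, `[[`, "", "path_type"))) < 2L) next
    agg <- aggregate_profiles(grp, path_type = "aggregated")
    rows[[length(rows) + 1L]] <- data.frame(
      model = agg$model, variant = agg$variant, path_type = agg$path_type,
      horizon_s = h_at * dt, rms_mm = 1000 * agg$rms[h_at],
      n_starts = agg$n_starts)
  }
  out <- do.call(rbind, rows)
  out[order(out$variant, out$model, out$path_type), , drop = FALSE]
}
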