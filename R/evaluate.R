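#' Evaluate prediction models on a set of walks
#'
#' Runs the full protocol on each walk: acquisition prefilter, raw state
#' estimation, offline polynomial baseline (degree 1 straight / 8 curved),
#' per-walk blend-gain calibration, real-time compensation, then a recursive
#' horizon-error sweep for every requested model and trajectory variant.
#' Errors are always measured against the measured (prefiltered) positions.
#'
#' @param walks list of `"gc_synth"` walks (e.g. from [benchmark_suite()]),
#'   or of [trajectory()] objects.
#' @param models character vector of model kinds (default all four).
#' @param variants subset of `c("raw", "offline", "realtime")`.
#' @param horizon_s horizon length, seconds (default 1).
#' @param params detector settings, a [compensation_params()]; the blend gain
#'   is calibrated per walk unless `params$K` is set.
#' @param prefilter apply the 6 Hz acquisition low-pass first (default TRUE).
#' @return List with `profiles` (list of `"gc_profile"`), `summary` (the
#'   [summarize_profiles()] table at `horizon_s`) and `K` (per-walk
#'   calibrated gains).
#' @export
evaluate_walks <- function(walks,
                           models = model_kinds(),
                           variants = c("raw", "offline", "realtime"),
                           horizon_s = 1.0,
                           params = compensation_params(),
                           prefilter = TRUE) {
  models <- vapply(models, check_model, "")
  variants <- match.arg(variants, c("raw", "offline", "realtime"),
                        several.ok = TRUE)
  profiles <- list()
  Ks <- numeric(0)
  for (i in seq_along(walks)) {
    w <- walks[[i]]
    traj <- if (inherits(w, "gc_synth")) w$traj else w
    stopifnot(inherits(traj, "gc_trajectory"))
    segments <- attr(traj, "segments_1based")
    if (prefilter) traj <- lowpass_prefilter(traj)
    H <- as.integer(round(horizon_s / traj$dt))
    raw <- estimate_raw_states(traj)
    seqs <- list(raw = raw)
    need_offline <- any(c("offline", "realtime") %in% variants) &&
      (is.na(params$K) || "offline" %in% variants)
    if (need_offline) {
      off <- estimate_offline_states(fit_baseline(traj, segments = segments))
      seqs$offline <- off
    }
    if ("realtime" %in% variants) {
      p <- params
      if (is.na(p$K)) {
        if (is.null(traj$phi_pelvis)) {
          p$K <- 0
        } else {
          p <- calibrate_K(raw, seqs$offline, traj, params = params)
        }
      }
      Ks <- c(Ks, p$K)
      seqs$realtime <- suppressMessages(build_realtime_states(traj, p))
    }
    for (variant in variants) {
      for (model in models) {
        profiles[[length(profiles) + 1L]] <-
          horizon_sweep(seqs[[variant]], traj, model, H = H)
      }
    }
  }
  list(profiles = profiles,
       summary = summarize_profiles(profiles, at_s = horizon_s),
       K = Ks)
}
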