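test_that("contact detection finds the derivative extrema of a sinusoidal speed", {
  t <- seq(0, 10, 0.01)
  v <- 1.2 + 0.15 * sin(2 * pi * 1.8 * t)
  st <- estimate_raw_states(straight_walk_with_speed(t, v))
  ev <- detect_contacts(st)
  # extrema of dv/dt sit at the zeros of sin: spacing 1/(2*1.8) ~ 0.2778 s
  expect_gte(length(ev$indices), 33)
  expect_lte(length(ev$indices), 35)
  expect_equal(mean(diff(ev$indices)) * 0.01, 1 / 3.6, tolerance = 0.02)
  expect_true(all(diff(ev$indices) > 0))
  expect_true(all(abs(diff(match(ev$labels,
                                 c("initial_contact", "final_contact")))) == 1))

  # constant speed: no extrema, no events
  st <- estimate_raw_states(straight_walk_with_speed(t, rep(1.2, length(t))))
  expect_length(detect_contacts(st)$indices, 0)
})

test_that("contact detection recovers the simulator's ground truth", {
  syn <- synthesize(synth_config("straight", noise_sd = 0, seed = 1,
                                 duration = 10))
  st <- estimate_raw_states(syn$traj)
  ev <- detect_contacts(st)
  t_det <- (ev$indices - 1) * st$dt
  truth <- syn$event_times_truth
  detectable <- truth[truth >= 0.5]   # detector warm-up excludes the start
  expect_lte(abs(length(t_det) - length(detectable)), 1)
  err <- vapply(t_det, function(x) min(abs(x - truth)), 1)
  expect_lt(max(err), 0.030)
})

test_that("velocity hold recovers the stride-mean speed", {
  t <- seq(0, 10, 0.01)
  v <- 1.2 + 0.15 * sin(2 * pi * 1.8 * t)
  st <- estimate_raw_states(straight_walk_with_speed(t, v))
  ev <- detect_contacts(st)
  hv <- hold_velocity(st, ev)
  after <- seq(ev$apply_at[1] + 1L, st$n)
  expect_lt(max(abs(hv$v_tilde[after] - 1.2)), 0.02)
  expect_lt(max(abs(hv$a_tilde[after])), 0.12)

  # no events: pass-through with a message
  st <- estimate_raw_states(straight_walk_with_speed(t, rep(1.2, length(t))))
  expect_message(hv <- hold_velocity(st, detect_contacts(st)), "no contact")
  expect_identical(hv$v_tilde, st$v)
  expect_identical(hv$a_tilde, st$a)
})

test_that("held acceleration tracks a ramping mean speed", {
  t <- seq(0, 10, 0.01)
  v <- 1.0 + 0.05 * t + 0.1 * sin(2 * pi * 1.8 * t)
  st <- estimate_raw_states(straight_walk_with_speed(t, v))
  hv <- hold_velocity(st, detect_contacts(st))
  mid <- 300:700
  expect_lt(abs(mean(hv$a_tilde[mid]) - 0.05), 0.1 * 0.05)
  expect_lt(mid_amplitude(hv$v_tilde[mid] - (1.0 + 0.05 * t[mid])), 0.02)
})

test_that("orientation blending satisfies its algebraic identities", {
  syn <- synthesize(synth_config("straight", noise_sd = 0, seed = 5))
  raw <- estimate_raw_states(syn$traj)
  p0 <- compensation_params(K = 0)
  expect_equal(blend_orientation(raw, syn$traj, p0)$phi_tilde, raw$phi,
               tolerance = 1e-12)
  p1 <- compensation_params(K = 1)
  expect_equal(blend_orientation(raw, syn$traj, p1)$phi_tilde,
               syn$traj$phi_pelvis, tolerance = 1e-12)

  # counter-phase symmetry: equal and opposite oscillations cancel at K = 0.5
  th <- seq(0, 20, 0.02)
  phi_r <- 0.5 + 0.1 * sin(th)
  phi_h <- 0.5 - 0.1 * sin(th)
  n <- length(th)
  st <- state_sequence(numeric(n), numeric(n), phi_r, rep(1, n),
                       numeric(n), numeric(n), dt = 0.02, variant = "raw")
  tr <- trajectory(seq(0, by = 0.02, length.out = n), cumsum(rep(0.02, n)),
                   numeric(n), phi_h)
  bo <- blend_orientation(st, tr, compensation_params(K = 0.5))
  expect_lt(max(abs(bo$phi_tilde - 0.5)), 1e-12)

  # missing pelvis channel is an error
  tr2 <- trajectory(seq(0, by = 0.02, length.out = n),
                    cumsum(rep(0.02, n)), numeric(n))
  expect_error(blend_orientation(st, tr2, p0), "pelvis")
})

test_that("K calibration solves the scalar least squares in closed form", {
  # amplitude-ratio case: K* = 0.1 / (0.1 + 0.3) = 0.25
  t <- seq(0, 10, 0.01)
  n <- length(t)
  base <- 0.4 + 0.02 * t
  s <- sin(2 * pi * 1.1 * t)
  mk_states <- function(phi, variant) {
    state_sequence(numeric(n), numeric(n), wrap_angle(phi), rep(1, n),
                   numeric(n), numeric(n), dt = 0.01, variant = variant)
  }
  raw <- mk_states(base + 0.1 * s, "raw")
  off <- mk_states(base, "offline")
  tr <- trajectory(t, 1.2 * t, numeric(n), base - 0.3 * s)
  p <- calibrate_K(raw, off, tr)
  expect_equal(p$K, 0.25, tolerance = 1e-6)

  # brute-force scan never beats the closed form
  sse <- function(K) {
    phi_t <- K * (base - 0.3 * s) + (1 - K) * (base + 0.1 * s)
    sum((phi_t - base)^2)
  }
  Ks <- seq(0, 1, 1e-4)
  expect_lte(sse(p$K), min(vapply(Ks, sse, 1)) + 1e-9)

  # pelvis equal to baseline: exact cancellation at K = 1
  tr1 <- trajectory(t, 1.2 * t, numeric(n), base)
  expect_equal(calibrate_K(raw, off, tr1)$K, 1, tolerance = 1e-9)

  # degenerate: pelvis identical to raw heading -> K = 0 with a warning
  tr0 <- trajectory(t, 1.2 * t, numeric(n), base + 0.1 * s)
  expect_warning(p0 <- calibrate_K(raw, off, tr0), "undefined")
  expect_equal(p0$K, 0)
})

test_that("K calibration recovers the simulator's ground truth", {
  syn <- synthesize(synth_config("straight", noise_sd = 0, seed = 21,
                                 duration = 10))
  traj <- syn$traj
  raw <- estimate_raw_states(traj)
  off <- estimate_offline_states(fit_baseline(traj, degree = 1))
  p <- calibrate_K(raw, off, traj)
  expect_lt(abs(p$K - syn$K_truth), 0.05)
})

test_that("the real-time sequence is causal and compensates the oscillations", {
  syn <- synthesize(synth_config("straight", noise_sd = 0, seed = 8,
                                 duration = 10))
  traj <- syn$traj
  raw <- estimate_raw_states(traj)
  off <- estimate_offline_states(fit_baseline(traj, degree = 1))
  p <- calibrate_K(raw, off, traj)
  rt <- build_realtime_states(traj, p)
  expect_equal(rt$variant, "realtime")
  expect_identical(rt$x, traj$x)

  # compensation quality on the middle strides
  expect_lt(mid_amplitude(rt$v), 0.25 * mid_amplitude(raw$v))
  expect_lt(mid_amplitude(unwrap_angle(rt$phi)),
            0.10 * mid_amplitude(unwrap_angle(raw$phi)))

  # causality: a prefix re-run reproduces the full run except the last samples
  for (cut in c(400, 700)) {
    sub <- trajectory(traj$t[1:cut], traj$x[1:cut], traj$y[1:cut],
                      traj$phi_pelvis[1:cut])
    rt_sub <- build_realtime_states(sub, p)
    keep <- 1:(cut - 2)
    expect_equal(rt_sub$v[keep], rt$v[keep], tolerance = 1e-12)
    expect_equal(rt_sub$a[keep], rt$a[keep], tolerance = 1e-12)
    expect_equal(rt_sub$phi[keep], rt$phi[keep], tolerance = 1e-12)
  }
})

test_that("the hold preserves the stride-mean walking speed within 2%", {
  for (seed in c(3, 13)) {
    syn <- synthesize(synth_config("straight", noise_sd = 0, seed = seed,
                                   duration = 10, stride_hz = 1.1))
    raw <- estimate_raw_states(syn$traj)
    hv <- hold_velocity(raw, detect_contacts(raw))
    mid <- 200:(raw$n - 100)
    expect_equal(mean(hv$v_tilde[mid]), syn$config$mean_speed,
                 tolerance = 0.02)
  }
})

test_that("degraded inputs fall back to the raw sequence", {
  syn <- synthesize(synth_config("straight", noise_sd = 0, seed = 6))
  traj_np <- trajectory(syn$traj$t, syn$traj$x, syn$traj$y)  # no pelvis
  raw <- estimate_raw_states(traj_np)
  expect_message(rt <- build_realtime_states(traj_np, compensation_params(K = 0.5)),
                 "pelvis")
  expect_identical(rt$phi, raw$phi)
  expect_error(compensation_params(K = 1.5), "K")
  expect_error(compensation_params(peak_min_interval_s = 0), "interval")
})
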