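# Independent oracles used across the suite.

# RK4 integration of the continuous unicycle kinematics
#   x' = v cos(phi), y' = v sin(phi), phi' = w, v' = a
# with piecewise-constant a and w. Independent of the package's closed-form
# discrete updates.
rk4_unicycle <- function(state, dt, n_sub = 100L) {
  f <- function(s, a, w) c(s[4] * cos(s[3]), s[4] * sin(s[3]), w, a)
  s <- c(state[["x"]], state[["y"]], state[["phi"]], state[["v"]])
  a <- state[["a"]]; w <- state[["w"]]
  h <- dt / n_sub
  for (i in seq_len(n_sub)) {
    k1 <- f(s, a, w)
    k2 <- f(s + h / 2 * k1, a, w)
    k3 <- f(s + h / 2 * k2, a, w)
    k4 <- f(s + h * k3, a, w)
    s <- s + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  s
}

# continuous-model constants per model kind (what the model holds constant)
model_effective_aw <- function(model, a, w) {
  switch(model,
         CV = c(0, 0),
         CA = c(a, 0),
         CTRV = c(0, w),
         CTRA = c(a, w))
}

# smallest signed angular difference
ang_diff <- function(x, y) {
  d <- (x - y + pi) %% (2 * pi) - pi
  ifelse(d == -pi, pi, d)
}

# build a trajectory whose speed profile is v(t), travelled along +x
straight_walk_with_speed <- function(t, v) {
  dt <- t[2] - t[1]
  x <- cumsum(c(0, (v[-1] + v[-length(v)]) / 2 * dt))
  trajectory(t, x, numeric(length(t)))
}

# oscillation amplitude as half the peak-to-peak over the middle 80%
mid_amplitude <- function(x) {
  n <- length(x)
  mid <- x[round(0.1 * n):round(0.9 * n)]
  diff(range(mid)) / 2
}
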