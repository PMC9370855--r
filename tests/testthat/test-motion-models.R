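test_that("closed-form single-step examples hold", {
  # CV heading north
  s <- propagate(motion_state(0, 0, pi / 2, v = 2), "CV", dt = 0.01)
  expect_equal(unclass(s)[c("x", "y", "phi", "v")],
               c(x = 0, y = 0.02, phi = pi / 2, v = 2), tolerance = 1e-12)

  # CA: v*dt + a/2*dt^2
  s <- propagate(motion_state(0, 0, 0, v = 1, a = 2), "CA", dt = 0.1)
  expect_equal(s[["x"]], 0.11, tolerance = 1e-12)
  expect_equal(s[["y"]], 0, tolerance = 1e-12)
  expect_equal(s[["v"]], 1.2, tolerance = 1e-12)
  expect_equal(s[["a"]], 2, tolerance = 1e-12)

  # CTRV quarter circle: chord of a quarter circle of radius v/w = 2/pi
  s <- propagate(motion_state(0, 0, 0, v = 1, w = pi / 2), "CTRV", dt = 1)
  expect_equal(s[["x"]], 2 / pi, tolerance = 1e-12)
  expect_equal(s[["y"]], 2 / pi, tolerance = 1e-12)
  expect_equal(s[["phi"]], pi / 2, tolerance = 1e-12)

  # CTRA against the independent RK4 oracle
  st <- motion_state(0, 0, 0, v = 1, a = 0.5, w = 0.3)
  s <- propagate(st, "CTRA", dt = 0.01)
  ref <- rk4_unicycle(st, 0.01)
  expect_lt(max(abs(c(s[["x"]], s[["y"]]) - ref[1:2])), 1e-8)
  expect_lt(abs(ang_diff(s[["phi"]], ref[3])), 1e-10)
  expect_equal(s[["v"]], ref[4], tolerance = 1e-12)
})

test_that("one-step propagation matches the RK4 oracle on random states", {
  set.seed(42)
  n <- 300
  for (i in seq_len(n)) {
    st <- motion_state(runif(1, -5, 5), runif(1, -5, 5), runif(1, -pi, pi),
                       v = runif(1, 0, 2), a = runif(1, -1, 1),
                       w = runif(1, -pi, pi))
    model <- sample(model_kinds(), 1)
    aw <- model_effective_aw(model, st[["a"]], st[["w"]])
    st_eff <- motion_state(st[["x"]], st[["y"]], st[["phi"]], st[["v"]],
                           aw[1], aw[2])
    out <- propagate(st, model, dt = 0.01)
    ref <- rk4_unicycle(st_eff, 0.01, n_sub = 20L)
    expect_lt(abs(out[["x"]] - ref[1]), 1e-8)
    expect_lt(abs(out[["y"]] - ref[2]), 1e-8)
    expect_lt(abs(ang_diff(out[["phi"]], ref[3])), 1e-8)
  }
})

test_that("curvilinear models are continuous across w = 0", {
  grid <- expand.grid(phi = seq(-pi, pi, length.out = 7),
                      v = c(0, 0.5, 2), a = c(-1, 0, 1))
  for (model in c("CTRV", "CTRA")) {
    for (i in seq_len(nrow(grid))) {
      s0 <- motion_state(1, -2, grid$phi[i], grid$v[i], grid$a[i], 0)
      base <- propagate(s0, model, 0.01)
      for (w in c(-1e-9, 1e-9)) {
        sp <- motion_state(1, -2, grid$phi[i], grid$v[i], grid$a[i], w)
        out <- propagate(sp, model, 0.01)
        expect_lt(abs(out[["x"]] - base[["x"]]), 1e-9)
        expect_lt(abs(out[["y"]] - base[["y"]]), 1e-9)
      }
    }
  }
})

test_that("degenerate parameter values reduce models to their parents", {
  set.seed(7)
  for (i in 1:20) {
    st0 <- motion_state(rnorm(1), rnorm(1), runif(1, -pi, pi),
                        v = runif(1, 0, 2), a = 0, w = runif(1, -2, 2))
    expect_identical(unclass(propagate(st0, "CA", 0.05)),
                     unclass(propagate(st0, "CV", 0.05)))
    expect_identical(unclass(propagate(st0, "CTRA", 0.05)),
                     unclass(propagate(st0, "CTRV", 0.05)))
  }
})

test_that("propagation is equivariant under rigid motions", {
  set.seed(11)
  rot <- function(p, th) c(cos(th) * p[1] - sin(th) * p[2],
                           sin(th) * p[1] + cos(th) * p[2])
  for (i in 1:25) {
    st <- motion_state(rnorm(1), rnorm(1), runif(1, -pi, pi),
                       v = runif(1, 0, 2), a = runif(1, -1, 1),
                       w = runif(1, -2, 2))
    th <- runif(1, -pi, pi); shift <- rnorm(2)
    model <- sample(model_kinds(), 1)
    base <- propagate(st, model, 0.02)
    moved <- motion_state(rot(c(st[["x"]], st[["y"]]), th)[1] + shift[1],
                          rot(c(st[["x"]], st[["y"]]), th)[2] + shift[2],
                          st[["phi"]] + th, st[["v"]], st[["a"]], st[["w"]])
    out <- propagate(moved, model, 0.02)
    ref <- rot(c(base[["x"]], base[["y"]]), th) + shift
    expect_lt(abs(out[["x"]] - ref[1]), 1e-10)
    expect_lt(abs(out[["y"]] - ref[2]), 1e-10)
    expect_lt(abs(ang_diff(out[["phi"]], base[["phi"]] + th)), 1e-10)
  }
})

test_that("propagate_n is the n-fold recursion with the stated geometry", {
  # straight line: collinear, evenly spaced
  out <- propagate_n(motion_state(1, 2, 0.3, v = 1.5), "CV", 0.01, 100)
  expect_equal(nrow(out), 100)
  steps <- sqrt(diff(c(1, out$x))^2 + diff(c(2, out$y))^2)
  expect_equal(steps, rep(1.5 * 0.01, 100), tolerance = 1e-12)
  cross <- (out$x - 1) * sin(0.3) - (out$y - 2) * cos(0.3)
  expect_lt(max(abs(cross)), 1e-12)

  # closed circle: v = 1, w = pi/5, 100 steps of 0.1 s = one full revolution
  out <- propagate_n(motion_state(0, 0, 0, v = 1, w = pi / 5), "CTRV", 0.1, 100)
  expect_lt(abs(out$x[100]), 1e-9)
  expect_lt(abs(out$y[100]), 1e-9)
  expect_lt(abs(ang_diff(out$phi[100], 0)), 1e-9)

  # fixed point: zero speed, zero acceleration
  out <- propagate_n(motion_state(3, 4, 1, v = 0), "CTRA", 0.01, 10)
  expect_true(all(out$x == 3) && all(out$y == 4))

  # element i equals propagate applied i times
  st <- motion_state(0, 0, 0.2, v = 1.1, a = 0.3, w = 0.4)
  out <- propagate_n(st, "CTRA", 0.05, 3)
  s <- st
  for (i in 1:3) s <- propagate(s, "CTRA", 0.05)
  expect_equal(out$x[3], s[["x"]], tolerance = 1e-12)
  expect_equal(out$y[3], s[["y"]], tolerance = 1e-12)
})

test_that("invalid inputs are rejected", {
  st <- motion_state(0, 0, 0, v = 1)
  expect_error(propagate(st, "CV", 0), "dt")
  expect_error(propagate(st, "CV", -0.1), "dt")
  expect_error(propagate(st, "XX", 0.1), "model")
  expect_error(motion_state(NA, 0, 0, 1), "finite")
  expect_error(motion_state(Inf, 0, 0, 1), "finite")
  expect_error(propagate_n(st, "CV", 0.1, 0), "n_steps")
})

test_that("headings are stored wrapped to (-pi, pi]", {
  s <- propagate(motion_state(0, 0, 3, v = 1, w = 3), "CTRV", 1)
  expect_lte(s[["phi"]], pi)
  expect_gt(s[["phi"]], -pi)
  expect_equal(s[["phi"]], 6 - 2 * pi, tolerance = 1e-12)
  expect_identical(wrap_angle(-pi), pi)
  expect_equal(wrap_angle(c(0, 2 * pi, -3 * pi)), c(0, 0, pi), tolerance = 1e-12)
})
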