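test_that("concentration follows the reciprocal-distance law", {
  f <- chemical_field(c0 = 10)
  expect_equal(concentration(f, c(2, 0)), 5.0)
  expect_equal(concentration(f, c(360, -360)), 10 / (360 * sqrt(2)),
               tolerance = 1e-12)
  expect_equal(concentration(f, c(360, -360)), 0.019642, tolerance = 1e-4)
  # exact 1/r scaling: c(r) * r = c0 at any sampled distance
  r <- c(1, 7, 50, 509.117, 12345)
  expect_equal(concentration(f, cbind(r, 0, 0)) * r, rep(10, 5),
               tolerance = 1e-12)
  # doubling the distance halves the concentration exactly
  expect_equal(concentration(f, c(100, 0)) / concentration(f, c(200, 0)), 2)
  expect_error(concentration(f, c(0, 0)), "singular")
})

test_that("constant-curvature 2D motion traces the closed circle of radius 1/kappa", {
  kappa <- 0.03; v <- 200
  s <- swimmer_state(x = c(360, -360), kappa = kappa)
  cfg <- motion_config(v = v)
  period <- 2 * pi / (v * kappa)
  out <- advance_frame(s, cfg, dt_total = period, n_sub = 2000)
  expect_lt(sqrt(sum((out$x - s$x)^2)), 1e-6)           # orbit closes
  path <- attr(out, "path")
  centre <- s$x + s$n / kappa
  radii <- sqrt(rowSums(sweep(path, 2, centre)^2))
  expect_equal(radii, rep(1 / kappa, length(radii)), tolerance = 1e-9)
  expect_equal(1 / kappa, 33.3333, tolerance = 1e-4)
})

test_that("zero curvature gives a straight segment with unchanged frame", {
  s <- swimmer_state(x = c(0, 0), t = c(1, 0), kappa = 0)
  out <- advance_frame(s, motion_config(v = 200), dt_total = 0.01, n_sub = 1)
  expect_equal(out$x, c(2, 0, 0), tolerance = 1e-12)
  expect_equal(out$t, s$t)
  expect_equal(out$n, s$n)
})

test_that("constant (kappa, tau) 3D motion matches the analytic helix", {
  kappa <- 0.03; tau <- 0.006; v <- 120
  a_helix <- kappa / (kappa^2 + tau^2)      # 32.0513 um
  pitch <- 2 * pi * tau / (kappa^2 + tau^2) # 40.273 um
  expect_equal(a_helix, 32.0513, tolerance = 1e-4)
  expect_equal(pitch, 40.273, tolerance = 1e-4)

  s <- swimmer_state(x = c(0, 0, 0), kappa = kappa, tau = tau)
  omega <- v * sqrt(kappa^2 + tau^2)
  turn_time <- 2 * pi / omega
  out <- advance_frame(s, motion_config(v = v), dt_total = 5 * turn_time,
                       n_sub = 5000)
  path <- attr(out, "path")
  # helix axis: through x0 + a n0, along the (constant) Darboux direction
  axis_dir <- (tau * s$t + kappa * s$b) / sqrt(kappa^2 + tau^2)
  axis_pt <- s$x + a_helix * s$n
  rel <- sweep(path, 2, axis_pt)
  along <- as.numeric(rel %*% axis_dir)
  radial <- sqrt(rowSums((rel - outer(along, axis_dir))^2))
  expect_equal(radial, rep(a_helix, length(radial)), tolerance = 1e-6)
  # advance along the axis over one full turn equals the pitch
  idx_turn <- nrow(path)            # exactly 5 turns from the total time
  expect_equal(along[idx_turn] / 5, pitch, tolerance = 1e-6)
})

test_that("zero curvature and torsion give uniform straight motion in 3D", {
  s <- swimmer_state(x = c(1, 2, 3), kappa = 0, tau = 0)
  out <- advance_frame(s, motion_config(v = 120), dt_total = 1, n_sub = 10)
  expect_equal(out$x, c(1, 2, 3) + 120 * c(1, 0, 0), tolerance = 1e-9)
  expect_equal(out$b, s$b)
})

test_that("planar initial conditions with tau = 0 stay exactly planar", {
  s <- swimmer_state(x = c(360, -360, 0), kappa = 0.03, tau = 0)
  out <- advance_frame(s, motion_config(v = 120), dt_total = 100, n_sub = 2000)
  expect_equal(max(abs(attr(out, "path")[, 3])), 0, tolerance = 1e-9)
})

test_that("the exact rotation integrator is independent of the sub-step count", {
  s <- swimmer_state(x = c(10, -5, 2), t = c(0.6, 0.8, 0), n = c(-0.8, 0.6, 0),
                     kappa = 0.025, tau = 0.004)
  cfg <- motion_config(v = 120, dt_learn = 0.5)
  a <- advance_frame(s, cfg, n_sub = 1)
  b <- advance_frame(s, cfg, n_sub = 1000)
  expect_equal(a$x, b$x, tolerance = 1e-9)
  expect_equal(a$t, b$t, tolerance = 1e-9)
  expect_equal(a$n, b$n, tolerance = 1e-9)
})

test_that("path length over a learning step equals speed times duration", {
  s <- swimmer_state(x = c(0, 0), kappa = 0.03)
  out <- advance_frame(s, motion_config(v = 120, dt_learn = 0.5), n_sub = 4000)
  path <- attr(out, "path")
  chord_sum <- sum(sqrt(rowSums(diff(path)^2)))
  expect_equal(chord_sum, 60, tolerance = 1e-5)  # chords converge to the arc
})

test_that("frame stays orthonormal to 1e-9 over a million sub-steps", {
  s <- swimmer_state(x = c(0, 0, 0), t = c(1, 1, 0), n = c(0, 1, 1),
                     kappa = 0.03, tau = 0.006)
  out <- advance_frame(s, motion_config(v = 120), dt_total = 1e4, n_sub = 1e6)
  expect_lt(frame_error(out), 1e-9)
})
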