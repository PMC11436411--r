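test_that("stable-orbit detection handles the boundary cases", {
  expect_true(detect_success(rep(10, 300), dt = 0.5))
  expect_false(detect_success(rep(500, 300), dt = 0.5))
  # first entry later than the horizon
  d <- c(rep(300, 100), rep(10, 300))
  expect_false(detect_success(d, dt = 0.5, t_p = 40))
  expect_true(detect_success(d, dt = 0.5, t_p = 100))
  # a brief early dip does not qualify if the cell then leaves for good
  d <- c(rep(60, 50), rep(10, 5), rep(700, 400))
  expect_false(detect_success(d, dt = 0.5))
  # ... but a dip followed by an excursion and a final stable stay does
  d <- c(rep(60, 50), rep(10, 5), rep(700, 50), rep(20, 400))
  expect_true(detect_success(d, dt = 0.5))
  expect_error(detect_success(numeric(0)), "empty")
})

test_that("success_rate counts successes", {
  expect_equal(success_rate(c(TRUE, FALSE, TRUE, TRUE)), 0.75)
  expect_equal(success_rate(rep(TRUE, 10)), 1)
  expect_error(success_rate(logical(0)), "no results")
})

test_that("time to reach is the first crossing times the step duration", {
  d <- c(rep(100, 100), rep(10, 50))
  tr <- time_to_reach(d, dt = 0.5)
  expect_equal(tr$n_r, 100L)
  expect_equal(tr$time_s, 50)
  never <- time_to_reach(rep(100, 10), dt = 0.5)
  expect_true(is.na(never$n_r))
})

test_that("cumulative steps are prefix sums with NA propagation", {
  expect_equal(cumulative_steps(c(100, 50, 30)), c(100, 150, 180))
  expect_equal(cumulative_steps(42), 42)
  expect_warning(cs <- cumulative_steps(c(100, NA, 30)), "without n_r")
  expect_true(all(is.na(cs[2:3])))
})

test_that("mean_sem matches its closed form", {
  expect_equal(mean_sem(c(1, 1, 1)), c(mean = 1, sem = 0))
  expect_equal(mean_sem(c(0, 2)), c(mean = 1, sem = 1))
  one <- mean_sem(3)
  expect_equal(unname(one["mean"]), 3)
  expect_true(is.na(one["sem"]))
})

test_that("trial tables are reproducible and internally consistent", {
  tr1 <- run_trials(n_trials = 4, episodes = 1, seed = 9, steps = 2000,
                    t_p = 1000)
  tr2 <- run_trials(n_trials = 4, episodes = 1, seed = 9, steps = 2000,
                    t_p = 1000)
  expect_identical(tr1, tr2)
  expect_equal(attr(tr1, "success_rate"), mean(tr1$success))
})

test_that("a degenerate one-cell sweep reduces to a plain success rate", {
  sw <- sweep_success(d_kappa_grid = 0.006, dt_grid = 0.5, n_trials = 4,
                      seed = 11, t_p = 500)
  expect_equal(dim(sw), c(1L, 1L))
  direct <- run_trials(n_trials = 4, episodes = 1, seed = 11 + 7919L,
                       steps = ceiling(500 / 0.5), t_p = 500)
  expect_equal(sw[1, 1], attr(direct, "success_rate"))
})

test_that("the sweep covers the full parameter grid", {
  sw <- sweep_success(n_trials = 1, seed = 2, t_p = 100)
  expect_equal(dim(sw), c(5L, 3L))
  expect_true(all(sw >= 0 & sw <= 1))
})

test_that("stored n_r and distances agree with the exported trajectory", {
  ag <- agent_config()
  q <- q_table(ag, 2)
  set.seed(14)
  res <- run_episode(q, ag, fast_motion(), chemical_field(), steps = 20000,
                     stop = "threshold")
  tr <- res$trajectory
  # distances recomputable from the positions and the egg centre
  d <- sqrt(tr$x_um^2 + tr$y_um^2 + tr$z_um^2)
  expect_equal(d, tr$dist_um, tolerance = 1e-9)
  expect_equal(tr$time_s, tr$step * 0.5)
  if (!is.na(res$n_r)) {
    expect_equal(time_to_reach(tr)$n_r, res$n_r)
  }
})

test_that("converged 2D and 3D strategies reach the egg on comparable scales", {
  cs2 <- convergence_steps(n_runs = 4, episodes = 5, seed = 8, steps = 20000)
  ag3 <- agent_config(d_kappa = 0.001, d_tau = 0.004)
  cs3 <- convergence_steps(n_runs = 4, episodes = 5, seed = 8, dim = 3,
                           agent = ag3, steps = 20000)
  s2 <- attr(cs2, "summary"); s3 <- attr(cs3, "summary")
  lo <- function(s) s["mean"] - 3 * s["sem"]
  hi <- function(s) s["mean"] + 3 * s["sem"]
  expect_lt(max(lo(s2), lo(s3)), min(hi(s2), hi(s3)))  # intervals overlap
})
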