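test_that("disabled noise passes the signal and curvature through unchanged", {
  off <- noise_config(FALSE)
  expect_equal(noisy_concentration(c(0.5, 2), off), c(0.5, 2))
  expect_equal(noisy_curvature(0.03, off), 0.03)
  on0 <- noise_config(TRUE, lambda = 10, sigma_kappa = 0)
  expect_equal(noisy_curvature(0.03, on0), 0.03)
})

test_that("detected stimulus has shot-noise moments lambda * c", {
  nz <- noise_config(TRUE, lambda = 10)
  set.seed(8)
  draws <- noisy_concentration(rep(1, 1e5), nz)
  expect_equal(mean(draws), 10, tolerance = 3 * sqrt(10 / 1e5) / 10)
  expect_equal(var(draws), 10, tolerance = 0.05)
  expect_error(noisy_concentration(-1, nz), "positive")
})

test_that("detected stimulus is floored at a small positive value", {
  nz <- noise_config(TRUE, lambda = 10)
  set.seed(1)
  tiny <- noisy_concentration(rep(1e-20, 1000), nz)
  expect_true(all(tiny >= 1e-12))
})

test_that("curvature noise has the configured variance", {
  nz <- noise_config(TRUE, sigma_kappa = 0.005)  # variance, as worded
  set.seed(9)
  draws <- noisy_curvature(rep(0.03, 1e5), nz)
  expect_equal(mean(draws), 0.03, tolerance = 3 * sqrt(0.005 / 1e5) / 0.03)
  expect_equal(var(draws), 0.005, tolerance = 0.01)
  # standard-deviation reading available as a toggle
  nz_sd <- noise_config(TRUE, sigma_kappa = 0.005, sigma_is_sd = TRUE)
  set.seed(9)
  draws <- noisy_curvature(rep(0.03, 1e5), nz_sd)
  expect_equal(sd(draws), 0.005, tolerance = 0.01)
})

test_that("curvature noise perturbs the motion but not the agent's state", {
  ag <- agent_config()
  q <- q_table(ag, 2)
  set.seed(5)
  res <- run_episode(q, ag, fast_motion(),
                     chemical_field(),
                     noise = noise_config(TRUE, lambda = 10,
                                          sigma_kappa = 0.005),
                     steps = 400, stop = "fixed")
  kgrid <- ag$kappa0 + (-ag$X:ag$X) * ag$d_kappa
  # the recorded commanded curvature stays on the discrete grid
  expect_true(all(res$trajectory$kappa_per_um %in% kgrid))
})

test_that("the noiseless pipeline is bit-identical between repeated seeded runs", {
  run <- function() suppressWarnings(
    rl_chemotaxis(episodes = 2, steps = 300, seed = 77, motion = fast_motion(),
                  stop = "fixed", record = "all"))
  a <- run(); b <- run()
  expect_identical(a$trajectories, b$trajectories)
  expect_identical(a$q, b$q)
  # and so is the noisy pipeline under the same seed
  runn <- function() suppressWarnings(
    rl_chemotaxis(episodes = 1, steps = 300, seed = 78, motion = fast_motion(),
                  noise = noise_config(TRUE), stop = "fixed", record = "all"))
  expect_identical(runn()$trajectories, runn()$trajectories)
})

test_that("noise slows learning but episode training remains robust", {
  nc <- noise_comparison(n_runs = 6, episodes = 6, seed = 31,
                         motion = motion_config(dt_learn = 0.75, n_sub = 1))
  expect_true(all(nc$mean_with >= nc$mean_without))
  expect_gte(sum(nc$noisy_success), 4)  # majority of seeds still reach
})
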