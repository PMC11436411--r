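test_that("reward is the weighted change in reciprocal concentration", {
  expect_equal(compute_reward(3, 3, 0.1), 0)
  expect_equal(compute_reward(5, 10, 0.1), 0.01)
  expect_gt(compute_reward(1, 2, 0.1), 0)   # positive iff c increased
  expect_lt(compute_reward(2, 1, 0.1), 0)
  expect_error(compute_reward(-1, 2, 0.1), "positive")
  # telescoping along an arbitrary concentration series
  cs <- c(0.02, 0.05, 0.01, 0.3, 0.2, 1.5)
  r <- compute_reward(cs[-length(cs)], cs[-1], 0.1)
  expect_equal(sum(r), 0.1 * (1 / cs[1] - 1 / cs[length(cs)]), tolerance = 1e-12)
})

test_that("q_update applies the standard backup to one entry only", {
  Q <- matrix(0, 4, 3)
  Q2 <- q_update(Q, 2, 1, r = 1, s_next = 3, alpha = 1, gamma = 0.8)
  expect_equal(Q2[2, 1], 1)                  # zero bootstrap term
  expect_equal(sum(Q2 != 0), 1)
  Q2[3, ] <- c(2, 1, 0)
  Q3 <- q_update(Q2, 2, 1, r = 1, s_next = 3, alpha = 1, gamma = 0.8)
  expect_equal(Q3[2, 1], 1 + 0.8 * 2)        # 2.6
  expect_equal(q_update(Q3, 2, 1, 5, 3, alpha = 0, gamma = 0.8), Q3)
})

test_that("iterated q_update converges to the brute-force Bellman fixed point", {
  set.seed(4)
  R <- matrix(round(rnorm(9), 2), 3, 3)
  gamma <- 0.8
  Qstar <- bellman_oracle(R, gamma)
  Q <- matrix(0, 3, 3)
  for (sweep in 1:200) {
    for (s in 1:3) for (a in 1:3) {
      Q <- q_update(Q, s, a, R[s, a], s_next = a, alpha = 1, gamma = gamma)
    }
  }
  expect_equal(Q, Qstar, tolerance = 1e-9)
})

test_that("epsilon-greedy selection has the right limiting behaviour", {
  Q <- rbind(c(0.5, 0.1, 0.2))
  expect_true(all(replicate(50, select_action(Q, 1, epsilon = 0)) == 1))
  set.seed(1)
  draws <- replicate(1e5, select_action(Q, 1, epsilon = 1))
  freq <- as.numeric(table(factor(draws, levels = 1:3))) / 1e5
  expect_equal(freq, rep(1/3, 3), tolerance = 0.015)
  # uniform tie-break over an all-equal row
  tied <- rbind(c(0.3, 0.3, 0.3))
  draws <- replicate(1e5, select_action(tied, 1, epsilon = 0,
                                        tie_break = "random"))
  freq <- as.numeric(table(factor(draws, levels = 1:3))) / 1e5
  expect_equal(freq, rep(1/3, 3), tolerance = 0.015)
  # deterministic preferences
  expect_equal(select_action(tied, 1, 0, tie_break = "keep"), 3L)
  expect_equal(select_action(tied, 1, 0, tie_break = "increase"), 1L)
})

test_that("actions shift the curvature level with clamping at the grid edge", {
  ag <- agent_config(kappa0 = 0.03, d_kappa = 0.001, X = 50)
  up <- apply_action(0, 1, ag)
  expect_equal(up$k_index, 1)
  expect_equal(up$kappa, 0.031)
  expect_false(up$clamped)
  edge <- apply_action(ag$X, 1, ag)
  expect_equal(edge$k_index, ag$X)
  expect_true(edge$clamped)
  expect_equal(apply_action(3, 3, ag)$k_index, 3)    # keep
  # 3D: the same shift applies to both levels; signs carried by the deltas
  ag3 <- agent_config(kappa0 = 0.03, tau0 = 0.006, d_kappa = 0.001,
                      d_tau = -0.004)
  up3 <- apply_action(0, 1, ag3, t_index = 0, dim = 3)
  expect_equal(up3$kappa, 0.031)
  expect_equal(up3$tau, 0.006 - 0.004)
})

test_that("the observed state is the sign of the concentration change", {
  expect_equal(observe_state(1.0, 1.5, 0)$dc_sign, 1)
  expect_equal(observe_state(1.5, 1.0, 0)$dc_sign, -1)
  # exact ties map deterministically to the negative sign
  expect_equal(observe_state(1.0, 1.0, 0)$dc_sign, -1)
  expect_equal(observe_state(1.0, 1.0, 0)$dc_sign,
               observe_state(1.0, 1.0, 0)$dc_sign)
  expect_error(observe_state(NA, 1.0, 0), "unavailable")
})

test_that("state indexing is a bijection onto the Q-table rows", {
  ag <- agent_config(X = 3)
  rows2 <- sapply(c(-1, 1), function(dc)
    sapply(-3:3, function(k) state_index(ag, dc, k)))
  expect_equal(sort(as.vector(rows2)), 1:(2 * ag$L))
  rows3 <- as.vector(sapply(c(-1, 1), function(dc)
    sapply(-3:3, function(k)
      sapply(-3:3, function(tq) state_index(ag, dc, k, tq, dim = 3)))))
  expect_equal(sort(rows3), 1:(2 * ag$L^2))
  expect_equal(nrow(q_table(ag, 2)), 2 * ag$L)
  expect_equal(nrow(q_table(ag, 3)), 2 * ag$L^2)
})

test_that("an episode with no steps leaves the Q-table untouched", {
  ag <- agent_config()
  q <- q_table(ag, 2)
  res <- run_episode(q, ag, fast_motion(), chemical_field(), steps = 0)
  expect_equal(res$steps, 0)
  expect_true(all(q == 0))
  expect_equal(nrow(res$trajectory), 1)  # only the initial state row
})

test_that("episode rewards telescope to the net change in reciprocal signal", {
  ag <- agent_config()
  q <- q_table(ag, 2)
  set.seed(10)
  res <- run_episode(q, ag, fast_motion(), chemical_field(), steps = 500,
                     stop = "fixed")
  tr <- res$trajectory
  beta <- 1 / 10
  # rewards start with the first action; conc at step 1 brackets the first one
  expected <- beta * (1 / tr$conc_pM[2] - 1 / tr$conc_pM[nrow(tr)])
  expect_equal(sum(tr$reward, na.rm = TRUE), expected, tolerance = 1e-9)
  expect_equal(res$cum_reward, expected, tolerance = 1e-9)
})

test_that("a keep-optimal policy holds the curvature constant under epsilon = 0", {
  ag <- agent_config(epsilon = 0, alpha = 0)
  q <- q_table(ag, 2)
  q[, "keep"] <- 1
  set.seed(2)
  res <- run_episode(q, ag, fast_motion(), chemical_field(), steps = 300,
                     stop = "fixed")
  expect_equal(unique(res$trajectory$kappa_per_um), ag$kappa0)
})

test_that("training with one episode reproduces a single seeded episode", {
  ag <- agent_config()
  fit <- suppressWarnings(rl_chemotaxis(episodes = 1, steps = 400, seed = 21,
                                        agent = ag, motion = fast_motion(),
                                        stop = "fixed", record = "last"))
  set.seed(21)
  q <- q_table(ag, 2)
  res <- run_episode(q, ag, fast_motion(), chemical_field(), steps = 400,
                     stop = "fixed")
  expect_identical(fit$trajectories[["1"]], res$trajectory)
  expect_equal(fit$q, q)
})

test_that("Q entries stay finite over a long run and episodes improve timing", {
  lens <- matrix(NA_real_, 8, 2)
  for (i in 1:8) {
    fit <- suppressWarnings(rl_chemotaxis(episodes = 10, steps = 50000,
                                          seed = 300 + i,
                                          motion = fast_motion(),
                                          stop = "threshold", record = "none"))
    expect_true(all(is.finite(fit$q)))
    lens[i, ] <- fit$episodes$steps[c(1, 10)]
  }
  # later episodes reach the egg in fewer steps on average than episode 1
  expect_lt(mean(lens[, 2]), mean(lens[, 1]))
})

test_that("model-object methods report the fit", {
  fit <- suppressWarnings(rl_chemotaxis(episodes = 2, steps = 300, seed = 3,
                                        motion = fast_motion(),
                                        stop = "fixed", record = "all"))
  expect_s3_class(fit, "rl_chemotaxis")
  expect_output(print(fit), "Q-learning chemotaxis model")
  expect_output(print(summary(fit)), "Episode summary")
  expect_equal(dim(coef(fit)), c(2 * fit$agent$L, 3))
  expect_true(predict(fit, dc_sign = 1, k_index = 0) %in%
                c("increase", "decrease", "keep"))
  ev <- simulate(fit, nsim = 2, seed = 4, steps = 50)
  expect_equal(nrow(ev), 2)
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
  expect_silent(plot(fit, which = "distance"))
})
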