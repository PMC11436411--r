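#' Decide whether a trajectory ends in a stable orbit around the source
#'
#' A run counts as successful when the swimmer reaches the source and then
#' circles it stably: the mean distance over the trailing stability window
#' is at or below the threshold, and the stay began -- at the first
#' sub-threshold entry after the last excursion above `guard` times the
#' threshold -- no later than the time horizon `t_p`.  The excursion guard
#' makes the criterion robust to brief early dips that the swimmer
#' subsequently abandons.
#'
#' @param trajectory A trajectory data frame (from [run_episode()] or
#'   [rl_chemotaxis()]) with columns `time_s` and `dist_um`, or a numeric
#'   vector of distances sampled every `dt` seconds.
#' @param d_threshold Success radius (um).
#' @param t_p Time horizon (s).
#' @param window Stability window (number of trailing samples).
#' @param guard Excursion multiple; distances above `guard * d_threshold`
#'   reset the qualifying entry.
#' @param dt Sampling interval (s), used when `trajectory` is a bare vector.
#' @return Logical.
#' @export
detect_success <- function(trajectory, d_threshold = 50, t_p = 25000,
                           window = 200, guard = 2, dt = 0.5) {
  if (is.data.frame(trajectory)) {
    d <- trajectory$dist_um
    tm <- trajectory$time_s
  } else {
    d <- as.numeric(trajectory)
    tm <- (seq_along(d) - 1) * dt
  }
  n <- length(d)
  if (n == 0) stop("empty trajectory")
  w <- min(window, n)
  tail_mean <- mean(d[(n - w + 1):n])
  below <- which(d < d_threshold)
  if (length(below) == 0) return(FALSE)
  exc <- which(d > guard * d_threshold)
  last_exc <- if (length(exc)) max(exc) else 0L
  entry <- below[below > last_exc]
  if (length(entry) == 0) return(FALSE)
  tm[entry[1]] <= t_p && tail_mean <= d_threshold
}

#' Fraction of successful runs
#'
#' @param successes A logical vector, or a list of episode results / fitted
#'   models whose `success` element is used.
#' @return `count(success) / count(total)`.
#' @export
success_rate <- function(successes) {
  if (is.list(successes) && !is.data.frame(successes))
    successes <- vapply(successes, function(r) {
      s <- r$success
      if (is.data.frame(s)) s <- s$success
      isTRUE(s[length(s)])
    }, logical(1))
  if (length(successes) == 0) stop("no results")
  mean(as.logical(successes))
}

#' Steps and time to first reach the success radius
#'
#' @param trajectory A trajectory data frame with `dist_um`, or a numeric
#'   distance vector sampled every `dt` seconds.
#' @param d_threshold Success radius (um).
#' @param dt Learning-step duration (s), used for bare vectors.
#' @return A list with `n_r` (first step index below the threshold, `NA` if
#'   never reached) and `time_s = n_r * dt`.
#' @export
time_to_reach <- function(trajectory, d_threshold = 50, dt = 0.5) {
  if (is.data.frame(trajectory)) {
    d <- trajectory$dist_um
    steps <- trajectory$step
    tms <- trajectory$time_s
  } else {
    d <- as.numeric(trajectory)
    steps <- seq_along(d) - 1
    tms <- steps * dt
  }
  i <- which(d < d_threshold)[1]
  if (is.na(i)) list(n_r = NA_integer_, time_s = NA_real_)
  else list(n_r = as.integer(steps[i]), time_s = tms[i])
}

#' Cumulative learning steps across episodes
#'
#' With episodes terminated at the success radius, the number of learning
#' steps `n_r` of an episode depends on the experience accumulated in the
#' previous ones; the running sum of `n_r` over episodes is therefore the
#' natural measure of the total learning effort invested up to each episode.
#'
#' @param fit A fitted [rl_chemotaxis()] model, or a numeric vector of
#'   per-episode `n_r`.
#' @return The running sum; `NA` from the first episode that never reached
#'   the threshold (with a warning).
#' @export
cumulative_steps <- function(fit) {
  n_r <- if (inherits(fit, "rl_chemotaxis")) fit$episodes$n_r else fit
  if (anyNA(n_r))
    warning("episode(s) without n_r; cumulative steps are NA from there on")
  cumsum(as.numeric(n_r))
}

#' Mean and standard error of the mean
#'
#' @param x Numeric values.
#' @return A named vector `c(mean, sem)`; `sem` is the sample standard
#'   deviation over `sqrt(n)` and `NA` for fewer than two values.
#' @export
mean_sem <- function(x) {
  x <- as.numeric(x)
  c(mean = mean(x), sem = if (length(x) >= 2) sd(x) / sqrt(length(x)) else NA_real_)
}

# per-trial seeds derived reproducibly from one master seed
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Multi-trial success-rate experiment
#'
#' Runs `n_trials` independent trials of episodic training and scores each
#' trial by its final episode.  With the default `"threshold"` termination a
#' trial succeeds when the final episode reaches the success radius within
#' the time horizon; with `"stable_orbit"` or `"fixed"` the stricter
#' stable-orbit criterion of [detect_success()] applies.  Per-trial seeds
#' are derived from the master seed, so the whole table is reproducible.
#'
#' @param n_trials Number of independent trials.
#' @param episodes Episodes per trial (Q-matrix carried across episodes).
#' @param seed Master seed.
#' @param dim 2 or 3.
#' @param agent,motion,field,noise Configuration objects.
#' @param x0 Initial position (um).
#' @param steps Maximum learning steps per episode.
#' @param stop Episode termination rule, see [run_episode()].
#' @param d_threshold,t_p,window Success criterion parameters.
#' @return A data frame with one row per trial: `trial`, `seed`, `success`,
#'   `n_r` (final episode), `steps_total`.  Attribute `"success_rate"` holds
#'   the fraction of successes.
#' @export
run_trials <- function(n_trials = 50, episodes = 1, seed = 1, dim = 2,
                       agent = agent_config(), motion = motion_config(n_sub = 1),
                       field = chemical_field(), noise = noise_config(),
                       x0 = c(360, -360, 0), steps = 50000,
                       stop = "threshold",
                       d_threshold = 50, t_p = 25000, window = 200) {
  seeds <- derive_seeds(seed, n_trials)
  out <- data.frame(trial = seq_len(n_trials), seed = seeds,
                    success = FALSE, n_r = NA_integer_,
                    steps_total = NA_integer_)
  for (i in seq_len(n_trials)) {
    fit <- suppressWarnings(
      rl_chemotaxis(dim = dim, episodes = episodes, steps = steps,
                    agent = agent, motion = motion, field = field,
                    noise = noise, x0 = x0, stop = stop,
                    d_threshold = d_threshold, t_p = t_p, window = window,
                    seed = seeds[i], record = "none"))
    last <- fit$episodes[nrow(fit$episodes), ]
    out$success[i] <- last$success
    out$n_r[i] <- last$n_r
    out$steps_total[i] <- sum(fit$episodes$steps)
  }
  attr(out, "success_rate") <- mean(out$success)
  out
}

#' Timing benchmark: learned policy versus stimulus-response model
#'
#' Trains the Q-learning swimmer to convergence, then measures the time to
#' first reach the success radius from a fixed starting distance over
#' `n_eval` random initial orientations -- once for the learned policy and
#' once for the stimulus-response model with the same starting conditions.
#'
#' @param n_eval Number of evaluation orientations per strategy.
#' @param train_episodes Training episodes before evaluation.
#' @param seed Master seed (training and orientation draws).
#' @param agent,motion,field Shared configuration.
#' @param baseline An [fj_config()].
#' @param x0_train Training start position (um).
#' @param x0_eval Evaluation start position (um).
#' @param steps Maximum learning steps per episode.
#' @param d_threshold Success radius (um).
#' @param dt_ode Sub-step (s) for the stimulus-response integration.
#' @param max_extra Additional training episodes allowed until the final
#'   episode reaches the target (convergence check); training that still has
#'   a failing final episode after the extension is evaluated as is, with a
#'   warning.
#' @param eval_epsilon Exploration rate during evaluation of the converged
#'   policy; 0 evaluates the greedy strategy (Q-updates continue on a
#'   private copy).
#' @return A list with per-orientation data frames `rl` and `fj`, the
#'   summary rows `rl_time` and `fj_time` (mean and SEM, s), and the fitted
#'   training object.
#' @export
navigation_benchmark <- function(n_eval = 10, train_episodes = 10, seed = 1,
                                 agent = agent_config(),
                                 motion = motion_config(n_sub = 1),
                                 field = chemical_field(),
                                 baseline = fj_config(),
                                 x0_train = c(360, -360, 0),
                                 x0_eval = c(180, -180, 0),
                                 steps = 50000, d_threshold = 50,
                                 dt_ode = 0.01, max_extra = 10,
                                 eval_epsilon = 0) {
  fit <- suppressWarnings(
    rl_chemotaxis(dim = 2, episodes = train_episodes, steps = steps,
                  agent = agent, motion = motion, field = field,
                  x0 = x0_train, stop = "threshold",
                  d_threshold = d_threshold, seed = seed, record = "none"))
  extra <- 0
  while (!fit$episodes$success[nrow(fit$episodes)] && extra < max_extra) {
    fit <- suppressWarnings(
      rl_chemotaxis(dim = 2, episodes = 1, steps = steps, agent = agent,
                    motion = motion, field = field, x0 = x0_train,
                    stop = "threshold", d_threshold = d_threshold,
                    record = "none", q = fit$q))
    extra <- extra + 1
  }
  if (!fit$episodes$success[nrow(fit$episodes)])
    warning("training did not converge within the episode budget")
  ang <- runif(n_eval, 0, 2 * pi)
  rl <- simulate(fit, nsim = n_eval, x0 = x0_eval, orientation = ang,
                 epsilon = eval_epsilon)
  fj <- data.frame(sim = seq_len(n_eval), orientation = ang,
                   time_s = NA_real_, reached = FALSE)
  for (i in seq_len(n_eval)) {
    run <- fj_chemotaxis(x0 = x0_eval, orientation = ang[i],
                         t_max = 4 * steps * motion$dt_learn, dt = dt_ode,
                         baseline = baseline, motion = motion, field = field,
                         d_threshold = d_threshold, sample_every = 100L,
                         response_dt = motion$dt_learn, latency = TRUE)
    fj$time_s[i] <- run$t_reach
    fj$reached[i] <- run$reached
  }
  list(rl = rl, fj = fj,
       rl_time = mean_sem(rl$time_s[!is.na(rl$time_s)]),
       fj_time = mean_sem(fj$time_s[!is.na(fj$time_s)]),
       extra_episodes = extra, fit = fit)
}

#' Convergence steps of the trained policy
#'
#' Trains with threshold-terminated episodes and reports `n_r` of the final
#' episode -- the number of learning steps a converged policy needs to bring
#' the swimmer from its start to the success radius -- over several seeded
#' runs.
#'
#' @param n_runs Number of independent seeded runs.
#' @param episodes Episodes per run.
#' @param seed Master seed.
#' @param dim 2 or 3.
#' @param agent,motion,field,noise Configuration objects.
#' @param x0 Start position (um).
#' @param steps Maximum learning steps per episode.
#' @param d_threshold Success radius (um).
#' @return A data frame (`run`, `seed`, `n_r`) with attribute `"summary"`
#'   holding mean and SEM of `n_r` over the runs that reached the target.
#' @export
convergence_steps <- function(n_runs = 10, episodes = 10, seed = 1, dim = 2,
                              agent = agent_config(),
                              motion = motion_config(n_sub = 1),
                              field = chemical_field(),
                              noise = noise_config(),
                              x0 = c(360, -360, 0), steps = 50000,
                              d_threshold = 50) {
  seeds <- derive_seeds(seed, n_runs)
  out <- data.frame(run = seq_len(n_runs), seed = seeds, n_r = NA_integer_)
  for (i in seq_len(n_runs)) {
    fit <- suppressWarnings(
      rl_chemotaxis(dim = dim, episodes = episodes, steps = steps,
                    agent = agent, motion = motion, field = field,
                    noise = noise, x0 = x0, stop = "threshold",
                    d_threshold = d_threshold, seed = seeds[i],
                    record = "none"))
    out$n_r[i] <- fit$episodes$n_r[episodes]
  }
  attr(out, "summary") <- mean_sem(out$n_r[!is.na(out$n_r)])
  out
}

#' Learning-effort comparison with and without noise
#'
#' Repeats threshold-terminated episodic training with the two noise sources
#' enabled and disabled and accumulates, per episode, the total number of
#' learning steps experienced so far (a failed episode contributes its full
#' length).  Noise makes the detected signal and the realised curvature
#' unreliable, so noisy swimmers need more learning steps before their
#' episodes terminate quickly; the cumulative curves separate accordingly.
#'
#' @param n_runs Seeded runs per condition.
#' @param episodes Episodes per run.
#' @param seed Master seed (same per-run seeds are used for both conditions).
#' @param agent,motion,field Shared configuration.
#' @param noise The [noise_config()] used for the noisy condition (must be
#'   enabled).
#' @param x0 Start position (um).
#' @param steps Maximum learning steps per episode.
#' @param d_threshold Success radius (um).
#' @return A list with matrices `with_noise` and `without_noise` (runs x
#'   episodes) of cumulative learning steps, their per-episode means, and
#'   the per-run success flag of the final noisy episode.
#' @export
noise_comparison <- function(n_runs = 10, episodes = 10, seed = 1,
                             agent = agent_config(),
                             motion = motion_config(dt_learn = 0.75, n_sub = 1),
                             field = chemical_field(),
                             noise = noise_config(enabled = TRUE),
                             x0 = c(360, -360, 0), steps = 50000,
                             d_threshold = 50) {
  stopifnot(noise$enabled)
  seeds <- derive_seeds(seed, n_runs)
  run_one <- function(s, nz) {
    fit <- suppressWarnings(
      rl_chemotaxis(dim = 2, episodes = episodes, steps = steps,
                    agent = agent, motion = motion, field = field,
                    noise = nz, x0 = x0, stop = "threshold",
                    d_threshold = d_threshold, seed = s, record = "none"))
    list(cum = cumsum(fit$episodes$steps),
         success = fit$episodes$success[episodes])
  }
  noisy <- lapply(seeds, run_one, nz = noise)
  quiet <- lapply(seeds, run_one, nz = noise_config(FALSE))
  with_noise <- do.call(rbind, lapply(noisy, `[[`, "cum"))
  without_noise <- do.call(rbind, lapply(quiet, `[[`, "cum"))
  list(with_noise = with_noise, without_noise = without_noise,
       mean_with = colMeans(with_noise),
       mean_without = colMeans(without_noise),
       noisy_success = vapply(noisy, `[[`, logical(1), "success"))
}

#' Success-rate sweep over learning parameters
#'
#' Success rate of single-episode learning over a grid of curvature
#' increments `d_kappa` and learning-step durations `dt_learn`; each cell
#' runs its own multi-trial experiment ([run_trials()]).
#'
#' @param d_kappa_grid Curvature increments (1/um).
#' @param dt_grid Learning-step durations (s).
#' @param n_trials Trials per cell.
#' @param seed Master seed; each cell derives its own per-trial seeds.
#' @param agent,motion,field Configuration templates (grid values override
#'   `agent$d_kappa` and `motion$dt_learn`; `steps` is set to `t_p /
#'   dt_learn` so each trial can use the whole horizon).
#' @param x0 Start position (um).
#' @param t_p,d_threshold,window Success criterion parameters.
#' @return A matrix of success rates, rows named by `d_kappa`, columns by
#'   `dt_learn`.
#' @export
sweep_success <- function(d_kappa_grid = c(0.002, 0.004, 0.006, 0.008, 0.010),
                          dt_grid = c(0.25, 0.5, 0.75),
                          n_trials = 20, seed = 1,
                          agent = agent_config(),
                          motion = motion_config(n_sub = 1),
                          field = chemical_field(),
                          x0 = c(360, -360, 0), t_p = 25000,
                          d_threshold = 50, window = 200) {
  out <- matrix(NA_real_, length(d_kappa_grid), length(dt_grid),
                dimnames = list(d_kappa = format(d_kappa_grid),
                                dt = format(dt_grid)))
  cell <- 0L
  for (j in seq_along(dt_grid)) {
    for (i in seq_along(d_kappa_grid)) {
      cell <- cell + 1L
      a <- agent; a$d_kappa <- d_kappa_grid[i]
      m <- motion; m$dt_learn <- dt_grid[j]
      trials <- run_trials(n_trials = n_trials, episodes = 1,
                           seed = seed + 7919L * cell, dim = 2, agent = a,
                           motion = m, field = field, x0 = x0,
                           steps = ceiling(t_p / dt_grid[j]),
                           d_threshold = d_threshold, t_p = t_p,
                           window = window)
      out[i, j] <- attr(trials, "success_rate")
    }
  }
  out
}
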