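stop_mode_code <- function(stop) {
  match(match.arg(stop, c("fixed", "threshold", "stable_orbit")),
        c("fixed", "threshold", "stable_orbit")) - 1L
}

resolve_beta <- function(agent, field, noise) {
  if (!is.null(agent$beta)) return(agent$beta)
  if (noise$enabled) 1 / (field$c0 * noise$lambda) else 1 / field$c0
}

action_labels <- c("increase", "decrease", "keep")

tie_pref_code <- function(tie_break) {
  switch(tie_break, keep = 2L, increase = 0L, 0L)
}

traj_to_df <- function(m) {
  df <- as.data.frame(m)
  names(df) <- c("step", "time_s", "x_um", "y_um", "z_um", "kappa_per_um",
                 "tau_per_um", "conc_pM", "dist_um", "action", "reward")
  df$action <- factor(action_labels[df$action + 1], levels = action_labels)
  df
}

#' Run one Q-learning episode
#'
#' Executes up to `steps` learning steps of the observe / select / act /
#' advance / reward / update cycle, starting from the given position and
#' orientation with the curvature (and torsion) at the grid centre.  The
#' first learning step is measurement-only -- the curvature is held at its
#' initial value while the signal memory acquires its second sample -- and
#' actions begin at the following step.  `q` is updated in place and carried
#' by the caller across episodes.
#'
#' @param q Q-matrix from [q_table()] (modified in place).
#' @param agent,motion,field,noise Configuration objects.
#' @param x0 Initial position (um).
#' @param t0,n0 Initial tangent and normal.
#' @param dim 2 or 3.
#' @param steps Maximum number of learning steps.
#' @param stop Termination rule: `"fixed"` runs all steps; `"threshold"`
#'   stops at the first step with distance below `d_threshold`;
#'   `"stable_orbit"` stops once the trailing `window` steps average below
#'   `d_threshold` with no excursion above twice the threshold since the
#'   qualifying entry.
#' @param d_threshold Success radius (um); the typical egg radius of 50 um.
#' @param t_p Success time horizon (s): a qualifying entry later than `t_p`
#'   does not count as success.
#' @param window Stability window (learning steps) for `"stable_orbit"`.
#' @param record Return the per-step trajectory?
#' @return A list: `n_r` (first step with d below threshold, `NA` if never),
#'   `success`, `steps`, `cum_reward`, clamp/floor event counts, final state,
#'   and (if recorded) the trajectory data frame with one row per learning
#'   step.
#' @export
run_episode <- function(q, agent, motion, field, noise = noise_config(),
                       x0 = c(360, -360, 0), t0 = c(1, 0, 0), n0 = c(0, 1, 0),
                       dim = 2, steps = 50000, stop = "threshold",
                       d_threshold = 50, t_p = 25000, window = 200,
                       record = TRUE) {
  stopifnot(inherits(agent, "agent_config"), inherits(motion, "motion_config"),
            inherits(field, "chemical_field"), inherits(noise, "noise_config"),
            dim %in% c(2, 3), steps >= 0)
  res <- cpp_run_episode(q, pad3(x0), pad3(t0), pad3(n0),
                         agent$kappa0, agent$tau0, agent$d_kappa, agent$d_tau,
                         agent$X, agent$alpha, agent$gamma, agent$epsilon,
                         resolve_beta(agent, field, noise),
                         as.integer(steps),
                         motion$v, motion$dt_learn, motion$n_sub,
                         field$c0, field$center, dim == 3,
                         noise$enabled, noise$lambda, kappa_noise_sd(noise),
                         stop_mode_code(stop), d_threshold,
                         as.integer(window), t_p, isTRUE(record),
                         !identical(agent$tie_break, "random"),
                         !identical(agent$credit, "prompt"),
                         identical(agent$sense, "integrated"),
                         tie_pref_code(agent$tie_break))
  if (!is.null(res$trajectory)) res$trajectory <- traj_to_df(res$trajectory)
  res
}

#' Train a chemotactic Q-learning swimmer
#'
#' Fits a navigation policy by episodic tabular Q-learning: the swimmer
#' starts each episode at the same position and orientation with curvature
#' `kappa0` (and torsion `tau0` in 3D) and an empty signal memory, while the
#' Q-matrix is carried over from episode to episode so that experience
#' accumulates.  Within an episode the agent repeatedly observes the sign of
#' the change in detected concentration, picks an action epsilon-greedily,
#' shifts its curvature level, swims one learning step, and applies the
#' Q-learning backup with the reciprocal-concentration reward.
#'
#' @param dim 2 for planar motion, 3 for helical motion with torsion.
#' @param episodes Number of learning episodes `Ne`.
#' @param steps Learning steps per episode `Nt` (upper bound when a
#'   termination rule is active).
#' @param agent,motion,field,noise Configuration objects; see
#'   [agent_config()], [motion_config()], [chemical_field()],
#'   [noise_config()].
#' @param x0,t0,n0 Initial position, tangent and normal (reset every
#'   episode).
#' @param stop,d_threshold,t_p,window Termination rule, see [run_episode()].
#' @param seed Integer seed; all action selection and noise draws flow
#'   through R's RNG, so the same seed reproduces a run bit for bit.
#' @param record Which episode trajectories to keep: the last, all, or none.
#' @param q Optional pre-trained Q-matrix to continue from (copied, not
#'   modified).
#' @return An object of class `rl_chemotaxis` with components `q` (the
#'   learned Q-matrix), `episodes` (one row per episode: `n_r`, `steps`,
#'   `success`, `cum_reward`, event counts, final distance), `trajectories`,
#'   and the configuration.  Methods: [print()], [summary()], [coef()]
#'   (the Q-matrix), [plot()], [simulate()] (evaluation episodes with the
#'   learned policy) and [predict()] (greedy action for a state).
#' @examples
#' fit <- rl_chemotaxis(episodes = 1, steps = 400, seed = 1,
#'                      motion = motion_config(n_sub = 1))
#' fit
#' @export
rl_chemotaxis <- function(dim = 2, episodes = 10, steps = 50000,
                          agent = agent_config(), motion = motion_config(),
                          field = chemical_field(), noise = noise_config(),
                          x0 = c(360, -360, 0), t0 = c(1, 0, 0),
                          n0 = c(0, 1, 0),
                          stop = c("threshold", "fixed", "stable_orbit"),
                          d_threshold = 50, t_p = 25000, window = 200,
                          seed = NULL, record = c("last", "all", "none"),
                          q = NULL) {
  stop <- match.arg(stop)
  record <- match.arg(record)
  stopifnot(episodes >= 1)
  if (!is.null(seed)) set.seed(seed)

  if (is.null(q)) {
    Q <- q_table(agent, dim)
  } else {
    stopifnot(is.matrix(q))
    Q <- matrix(as.numeric(q), nrow(q), ncol(q), dimnames = dimnames(q))
  }

  ep <- vector("list", episodes)
  trajs <- list()
  for (e in seq_len(episodes)) {
    rec <- record == "all" || (record == "last" && e == episodes)
    res <- run_episode(Q, agent, motion, field, noise, x0, t0, n0, dim,
                       steps, stop, d_threshold, t_p, window, record = rec)
    if (rec) trajs[[as.character(e)]] <- res$trajectory
    res$trajectory <- NULL
    ep[[e]] <- res
  }
  episodes_df <- data.frame(
    episode = seq_len(episodes),
    n_r = vapply(ep, function(r) as.integer(r$n_r), integer(1)),
    steps = vapply(ep, function(r) as.integer(r$steps), integer(1)),
    success = vapply(ep, function(r) r$success, logical(1)),
    cum_reward = vapply(ep, function(r) r$cum_reward, numeric(1)),
    clamp_events = vapply(ep, function(r) as.integer(r$clamp_events), integer(1)),
    floor_events = vapply(ep, function(r) as.integer(r$floor_events), integer(1)),
    final_d = vapply(ep, function(r) r$final_d, numeric(1)))
  if (sum(episodes_df$clamp_events) > 0)
    warning(sprintf("curvature grid boundary reached %d time(s); consider a larger X",
                    sum(episodes_df$clamp_events)))
  if (sum(episodes_df$floor_events) > 0)
    warning(sprintf("detected stimulus floored at 1e-12 %d time(s)",
                    sum(episodes_df$floor_events)))

  structure(list(q = Q, episodes = episodes_df, trajectories = trajs,
                 dim = dim, steps = steps, stop = stop,
                 d_threshold = d_threshold, t_p = t_p, window = window,
                 agent = agent, motion = motion, field = field, noise = noise,
                 x0 = pad3(x0), t0 = pad3(t0), n0 = pad3(n0), seed = seed,
                 call = match.call()),
            class = "rl_chemotaxis")
}

#' @export
print.rl_chemotaxis <- function(x, ...) {
  cat(sprintf("Q-learning chemotaxis model (%dD), %d episode(s)\n",
              x$dim, nrow(x$episodes)))
  last <- x$episodes[nrow(x$episodes), ]
  cat(sprintf("  final episode: %d steps, n_r = %s, success = %s, final d = %.1f um\n",
              last$steps, ifelse(is.na(last$n_r), "never", last$n_r),
              last$success, last$final_d))
  cat(sprintf("  kappa0 = %g, d_kappa = %g 1/um; dt = %g s; v = %g um/s; epsilon = %g\n",
              x$agent$kappa0, x$agent$d_kappa, x$motion$dt_learn,
              x$motion$v, x$agent$epsilon))
  if (x$noise$enabled) print(x$noise)
  invisible(x)
}

#' @export
summary.rl_chemotaxis <- function(object, ...) {
  structure(list(episodes = object$episodes, dim = object$dim,
                 cum_steps = suppressWarnings(cumulative_steps(object))),
            class = "summary.rl_chemotaxis")
}

#' @export
print.summary.rl_chemotaxis <- function(x, ...) {
  cat(sprintf("Episode summary (%dD):\n", x$dim))
  df <- x$episodes
  df$cum_n_r <- x$cum_steps
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
coef.rl_chemotaxis <- function(object, ...) object$q

#' Greedy action of a trained policy
#'
#' @param object A fitted [rl_chemotaxis()] model.
#' @param dc_sign +1 or -1, sign of the detected concentration change.
#' @param k_index Curvature level.
#' @param t_index Torsion level (3D).
#' @param ... Unused.
#' @return The greedy action name; ties are reported as the first maximal
#'   action in the order increase, decrease, keep.
#' @export
predict.rl_chemotaxis <- function(object, dc_sign = 1, k_index = 0,
                                  t_index = 0, ...) {
  s <- state_index(object$agent, dc_sign, k_index, t_index, object$dim)
  action_labels[which.max(object$q[s, ])]
}

#' Evaluate a trained policy from new starting conditions
#'
#' Runs `nsim` evaluation episodes with the learned Q-matrix.  Each episode
#' starts from `x0` with a planar orientation angle drawn uniformly (or
#' supplied via `orientation`), keeps the training exploration rate unless
#' `epsilon` is given, and continues Q-updates on a private copy so the
#' fitted object is untouched.
#'
#' @param object A fitted [rl_chemotaxis()] model.
#' @param nsim Number of evaluation episodes.
#' @param seed Optional seed.
#' @param x0 Starting position (um); default (180, -180, 0).
#' @param orientation Optional vector of orientation angles (radians, in the
#'   swimming plane); recycled to `nsim`.
#' @param epsilon Exploration rate during evaluation; default as trained.
#' @param steps Maximum learning steps per evaluation; default as trained.
#' @param stop Termination rule; default `"threshold"` so `n_r` is the first
#'   crossing of the success radius.
#' @param record Keep trajectories?
#' @param ... Unused.
#' @return A data frame with one row per evaluation: `sim`, `orientation`,
#'   `n_r`, `time_s` (`n_r * dt_learn`), `success`, `final_d`.  Recorded
#'   trajectories are attached as attribute `"trajectories"`.
#' @export
simulate.rl_chemotaxis <- function(object, nsim = 1, seed = NULL,
                                   x0 = c(180, -180, 0), orientation = NULL,
                                   epsilon = NULL, steps = NULL,
                                   stop = "threshold", record = FALSE, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(steps)) steps <- object$steps
  agent <- object$agent
  if (!is.null(epsilon)) agent$epsilon <- epsilon
  ang <- if (is.null(orientation)) runif(nsim, 0, 2 * pi)
         else rep_len(orientation, nsim)
  out <- data.frame(sim = seq_len(nsim), orientation = ang, n_r = NA_integer_,
                    time_s = NA_real_, success = FALSE, final_d = NA_real_)
  trajs <- list()
  for (i in seq_len(nsim)) {
    Qc <- matrix(as.numeric(object$q), nrow(object$q), ncol(object$q))
    t0 <- c(cos(ang[i]), sin(ang[i]), 0)
    n0 <- c(-sin(ang[i]), cos(ang[i]), 0)
    res <- run_episode(Qc, agent, object$motion, object$field, object$noise,
                       x0, t0, n0, object$dim, steps, stop,
                       object$d_threshold, object$t_p, object$window,
                       record = record)
    out$n_r[i] <- res$n_r
    out$time_s[i] <- if (is.na(res$n_r)) NA_real_
                     else res$n_r * object$motion$dt_learn
    out$success[i] <- res$success
    out$final_d[i] <- res$final_d
    if (record) trajs[[i]] <- res$trajectory
  }
  if (record) attr(out, "trajectories") <- trajs
  out
}

#' Plot a learned trajectory
#'
#' @param x A fitted [rl_chemotaxis()] model with at least one recorded
#'   trajectory.
#' @param which `"trajectory"` (path in the plane), `"distance"` (d versus
#'   learning step) or `"curvature"`.
#' @param episode Which recorded episode to plot; default the last.
#' @param ... Passed to [plot()].
#' @export
plot.rl_chemotaxis <- function(x, which = c("trajectory", "distance",
                                            "curvature"),
                               episode = NULL, ...) {
  which <- match.arg(which)
  if (length(x$trajectories) == 0)
    stop("no recorded trajectory; refit with record = \"last\" or \"all\"")
  if (is.null(episode)) episode <- names(x$trajectories)[length(x$trajectories)]
  tr <- x$trajectories[[as.character(episode)]]
  if (is.null(tr)) stop("episode ", episode, " was not recorded")
  if (which == "trajectory") {
    plot(tr$x_um, tr$y_um, type = "l", asp = 1, xlab = "x (um)",
         ylab = "y (um)", ...)
    symbols(x$field$center[1], x$field$center[2], circles = x$d_threshold,
            inches = FALSE, add = TRUE, fg = "red")
    points(tr$x_um[1], tr$y_um[1], pch = 19, col = "darkgreen")
    points(x$field$center[1], x$field$center[2], pch = 19, col = "red")
  } else if (which == "distance") {
    plot(tr$step, tr$dist_um, type = "l", xlab = "learning step",
         ylab = "d (um)", ...)
    abline(h = x$d_threshold, lty = 2, col = "red")
  } else {
    plot(tr$step, tr$kappa_per_um, type = "l", xlab = "learning step",
         ylab = "kappa (1/um)", ...)
  }
  invisible(x)
}
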