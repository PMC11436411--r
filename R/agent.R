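#' Q-learning agent configuration
#'
#' Hyperparameters of the tabular Q-learning agent.  The curvature is
#' discretised onto `L = 2X + 1` levels `kappa0 + k * d_kappa` with
#' `k in [-X, X]` (and likewise the torsion in 3D).  The agent's state is the
#' sign of the change in detected concentration over the last learning step
#' together with the current curvature (and torsion) level; its three actions
#' are increase, decrease and keep.  In 3D a single action shifts the
#' curvature and torsion levels together, so in-phase versus out-of-phase
#' modulation is selected through the signs of `d_kappa` and `d_tau`.
#'
#' @param kappa0 Initial curvature (1/um); the centre of the grid.
#' @param tau0 Initial torsion (1/um); 3D only.
#' @param d_kappa Curvature increment per action (1/um).
#' @param d_tau Torsion increment per action (1/um); its sign relative to
#'   `d_kappa` selects in-phase (same sign) or out-of-phase modulation.
#' @param X Half-width of the discretisation grid (levels `-X ... X`).
#'   Chosen large enough that the boundary is not reached in ordinary runs;
#'   hitting it clamps the level and is counted as a clamp event.
#' @param alpha Learning rate in `[0, 1]`; 1 (full overwrite) maximises
#'   learning speed for this effectively deterministic system.
#' @param gamma Discount factor in (0, 1).
#' @param epsilon Exploration probability of the epsilon-greedy policy.
#' @param beta Reward weight; `NULL` means the default `1/c0` without noise
#'   and `1/(c0 * lambda)` with signal noise enabled.
#' @param tie_break How a greedy tie among maximal Q entries is resolved:
#'   `"keep"` prefers keeping the curvature unchanged (then increase, then
#'   decrease) -- when the agent is indifferent it does not steer;
#'   `"increase"` scans in the storage order increase, decrease, keep (the
#'   convention of array-argmax implementations); `"random"` draws uniformly
#'   among the maximal entries.
#' @param credit Credit assignment under the one-step actuation latency:
#'   `"actuated"` credits each decision with the concentration change over
#'   the interval its curvature actually drove (one-step bookkeeping);
#'   `"prompt"` credits it with the interval completed at the next
#'   measurement.
#' @return An object of class `agent_config`.
#' @export
agent_config <- function(kappa0 = 0.03, tau0 = 0.006,
                         d_kappa = 0.006, d_tau = 0.004,
                         X = 50, alpha = 1, gamma = 0.8, epsilon = 0.1,
                         beta = NULL,
                         tie_break = c("keep", "increase", "random"),
                         credit = c("prompt", "actuated"),
                         sense = c("endpoint", "integrated")) {
  stopifnot(X >= 1, alpha >= 0, alpha <= 1, gamma > 0, gamma < 1,
            epsilon >= 0, epsilon <= 1)
  structure(list(kappa0 = kappa0, tau0 = tau0, d_kappa = d_kappa,
                 d_tau = d_tau, X = as.integer(X), L = 2L * as.integer(X) + 1L,
                 alpha = alpha, gamma = gamma, epsilon = epsilon, beta = beta,
                 tie_break = match.arg(tie_break),
                 credit = match.arg(credit),
                 sense = match.arg(sense)),
            class = "agent_config")
}

#' @export
print.agent_config <- function(x, ...) {
  cat("Q-learning agent configuration\n")
  cat(sprintf("  kappa grid: %g +/- %d x %g 1/um (%d levels)\n",
              x$kappa0, x$X, x$d_kappa, x$L))
  cat(sprintf("  tau grid (3D): %g +/- %d x %g 1/um\n", x$tau0, x$X, x$d_tau))
  cat(sprintf("  alpha = %g, gamma = %g, epsilon = %g, beta = %s\n",
              x$alpha, x$gamma, x$epsilon,
              if (is.null(x$beta)) "1/c0 (default)" else format(x$beta)))
  invisible(x)
}

#' Initialise a Q-table
#'
#' All-zero action-value matrix with one row per discrete agent state and one
#' column per action.  States are `2 * L` in 2D (sign of the concentration
#' change times the curvature level) and `2 * L^2` in 3D (adding the torsion
#' level).  Row names encode the state, e.g. `"dc=+,k=-3"`.
#'
#' @param agent An [agent_config()].
#' @param dim 2 or 3.
#' @return A numeric matrix with columns `increase`, `decrease`, `keep`.
#' @export
q_table <- function(agent, dim = 2) {
  stopifnot(inherits(agent, "agent_config"), dim %in% c(2, 3))
  X <- agent$X; L <- agent$L
  ks <- -X:X
  if (dim == 2) {
    rn <- as.vector(outer(ks, c("-", "+"),
                          function(k, s) sprintf("dc=%s,k=%d", s, k)))
  } else {
    rn <- as.vector(outer(outer(ks, ks, function(t, k)
      sprintf("k=%d,t=%d", k, t)), c("-", "+"),
      function(kt, s) sprintf("dc=%s,%s", s, kt)))
  }
  matrix(0, nrow = length(rn), ncol = 3,
         dimnames = list(rn, c("increase", "decrease", "keep")))
}

#' Row index of a discrete agent state
#'
#' @param agent An [agent_config()].
#' @param dc_sign +1 or -1: sign of the change in detected concentration.
#' @param k_index Curvature level in `[-X, X]`.
#' @param t_index Torsion level (3D only).
#' @param dim 2 or 3.
#' @return 1-based row index into the Q-table of [q_table()].
#' @export
state_index <- function(agent, dc_sign, k_index, t_index = 0, dim = 2) {
  X <- agent$X; L <- agent$L
  stopifnot(dc_sign %in% c(-1, 1), abs(k_index) <= X, abs(t_index) <= X)
  dcb <- as.integer(dc_sign > 0)
  if (dim == 2) dcb * L + (k_index + X) + 1L
  else dcb * L * L + (k_index + X) * L + (t_index + X) + 1L
}

#' Reward for a learning step
#'
#' The reward for the action in force over one learning step is
#' \deqn{r = \beta (1/c_n - 1/c_{n+1}),}
#' positive exactly when the detected concentration increased.  The
#' reciprocal form avoids the singularity of the field at the source: rewards
#' stay finite as the swimmer closes in.  Summed along a trajectory the
#' rewards telescope to `beta * (1/c_first - 1/c_last)`.
#'
#' @param c_n,c_next Detected concentrations before and after the step
#'   (positive).
#' @param beta Reward weight.
#' @return The scalar reward.
#' @export
compute_reward <- function(c_n, c_next, beta) {
  if (any(c_n <= 0) || any(c_next <= 0))
    stop("concentrations must be positive")
  beta * (1 / c_n - 1 / c_next)
}

#' One tabular Q-learning update
#'
#' Applies the standard backup
#' \deqn{Q(s,a) \leftarrow Q(s,a) +
#'   \alpha [ r + \gamma \max_{a'} Q(s',a') - Q(s,a) ]}
#' and returns the updated table; only the entry `(s, a)` changes.
#'
#' @param Q Q-matrix (rows = states, columns = actions).
#' @param s,s_next State row indices (1-based).
#' @param a Action: 1 = increase, 2 = decrease, 3 = keep (or a column name).
#' @param r Reward.
#' @param alpha Learning rate.
#' @param gamma Discount factor.
#' @return The updated Q-matrix.
#' @export
q_update <- function(Q, s, a, r, s_next, alpha, gamma) {
  Q[s, a] <- Q[s, a] + alpha * (r + gamma * max(Q[s_next, ]) - Q[s, a])
  Q
}

#' Epsilon-greedy action selection
#'
#' With probability `1 - epsilon` returns the greedy action for state row `s`;
#' with probability `epsilon` returns an action drawn uniformly from all
#' three (which may coincide with the greedy one).  Greedy ties are resolved
#' by `tie_break` (see [agent_config()]).  Draws come from R's RNG, so
#' `set.seed()` makes selections reproducible.
#'
#' @param Q Q-matrix.
#' @param s State row index.
#' @param epsilon Exploration probability.
#' @param tie_break `"keep"`, `"increase"` or `"random"`; see
#'   [agent_config()].
#' @return Action index in 1:3 (1 = increase, 2 = decrease, 3 = keep).
#' @export
select_action <- function(Q, s, epsilon, tie_break = "keep") {
  cpp_select_action(as.numeric(Q[s, ]), epsilon, tie_break != "random",
                    tie_pref_code(tie_break)) + 1L
}

#' Apply an action to the discrete agent state
#'
#' Shifts the curvature level (and, in 3D, the torsion level by the same
#' amount) up or down by one, or keeps it, clamping at the grid boundary.
#'
#' @param k_index Current curvature level.
#' @param action 1 = increase, 2 = decrease, 3 = keep.
#' @param agent An [agent_config()].
#' @param t_index Current torsion level (3D).
#' @param dim 2 or 3.
#' @return A list with the new `k_index`, `t_index`, the continuous `kappa`
#'   and `tau` they encode, and `clamped` (logical).
#' @export
apply_action <- function(k_index, action, agent, t_index = 0, dim = 2) {
  shift <- c(1L, -1L, 0L)[action]
  X <- agent$X
  k2 <- k_index + shift
  clamped <- k2 < -X || k2 > X
  k2 <- max(-X, min(X, k2))
  t2 <- t_index
  if (dim == 3 && shift != 0L) {
    t2 <- t_index + shift
    clamped <- clamped || t2 < -X || t2 > X
    t2 <- max(-X, min(X, t2))
  }
  list(k_index = k2, t_index = t2,
       kappa = agent$kappa0 + k2 * agent$d_kappa,
       tau = agent$tau0 + t2 * agent$d_tau,
       clamped = clamped)
}

#' Observe the discrete agent state from the signal memory
#'
#' The agent keeps a short-term memory of the detected concentration at the
#' previous learning step; the state is the sign of the difference together
#' with the current curvature (and torsion) level.  An exact tie
#' (`c_curr == c_prev`) maps to the negative sign, a fixed convention that
#' keeps runs reproducible (ties have probability ~0 in floating point).
#'
#' @param c_prev,c_curr Detected concentrations at the previous and current
#'   learning step; both must be available (use `NA` to signal absence).
#' @param k_index Current curvature level.
#' @param t_index Current torsion level (3D).
#' @return A list with `dc_sign` (+1 or -1), `k_index`, `t_index`.
#' @export
observe_state <- function(c_prev, c_curr, k_index, t_index = 0) {
  if (is.na(c_prev) || is.na(c_curr))
    stop("state unavailable: two concentration samples are required")
  list(dc_sign = if (c_curr - c_prev > 0) 1 else -1,
       k_index = k_index, t_index = t_index)
}
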