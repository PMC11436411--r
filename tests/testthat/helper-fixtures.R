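# small shared fixtures; everything is generated in code

fast_motion <- function(...) motion_config(v = 120, dt_learn = 0.5, n_sub = 1, ...)

# a Q-table preloaded with a uniform policy: action `up` in every dc=+1 state,
# `down` in every dc=-1 state
uniform_policy_q <- function(agent, up, down, dim = 2, value = 1) {
  q <- q_table(agent, dim)
  for (k in -agent$X:agent$X) {
    q[state_index(agent, 1, k, dim = dim), up] <- value
    q[state_index(agent, -1, k, dim = dim), down] <- value
  }
  q
}

# brute-force value iteration for a tiny deterministic MDP:
# next state = the action taken, rewards R[s, a]
bellman_oracle <- function(R, gamma, tol = 1e-12) {
  ns <- nrow(R); na <- ncol(R)
  Q <- matrix(0, ns, na)
  repeat {
    V <- apply(Q, 1, max)
    Qn <- R + gamma * matrix(V[col(R)], ns, na)  # next state index = action
    if (max(abs(Qn - Q)) < tol) return(Qn)
    Q <- Qn
  }
}
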