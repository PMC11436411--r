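#' Read a simulation configuration file
#'
#' Configurations are plain-text key/value files in YAML syntax.  Recognised
#' top-level keys mirror the constructor arguments: `v`, `dt_learn`, `n_sub`,
#' `c0`, `egg_center`, `x0`, `t0`, `kappa0`, `tau0`, `d_kappa`, `d_tau`, `X`,
#' `alpha`, `gamma`, `epsilon`, `beta`, `episodes`, `steps`, `seed`, `dim`,
#' and a `noise` block with `enabled`, `lambda`, `sigma_kappa`.  Missing keys
#' fall back to the package defaults.
#'
#' @param path Path to the file.
#' @return A list with elements `agent`, `motion`, `field`, `noise` (the
#'   corresponding configuration objects) and `run` (remaining scalar
#'   settings: `dim`, `episodes`, `steps`, `seed`, `x0`, `t0`).
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  pick <- function(key, default) if (!is.null(raw[[key]])) raw[[key]] else default
  noise_raw <- if (is.null(raw$noise)) list() else raw$noise
  npick <- function(key, default)
    if (!is.null(noise_raw[[key]])) noise_raw[[key]] else default
  list(
    agent = agent_config(
      kappa0 = pick("kappa0", 0.03), tau0 = pick("tau0", 0.006),
      d_kappa = pick("d_kappa", 0.006), d_tau = pick("d_tau", 0.004),
      X = pick("X", 50), alpha = pick("alpha", 1),
      gamma = pick("gamma", 0.8), epsilon = pick("epsilon", 0.1),
      beta = raw$beta),
    motion = motion_config(v = pick("v", 120),
                           dt_learn = pick("dt_learn", 0.5),
                           n_sub = pick("n_sub", 50)),
    field = chemical_field(c0 = pick("c0", 10),
                           center = pick("egg_center", c(0, 0, 0))),
    noise = noise_config(enabled = npick("enabled", FALSE),
                         lambda = npick("lambda", 10),
                         sigma_kappa = npick("sigma_kappa", 0.005),
                         sigma_is_sd = npick("sigma_is_sd", FALSE)),
    run = list(dim = pick("dim", 2), episodes = pick("episodes", 10),
               steps = pick("steps", 50000), seed = raw$seed,
               x0 = pick("x0", c(360, -360, 0)), t0 = pick("t0", c(1, 0, 0))))
}

#' Write a trajectory table
#'
#' Delimited text (CSV), one row per learning step with the schema
#' `step, time_s, x_um, y_um, z_um, kappa_per_um, tau_per_um, conc_pM,
#' dist_um` plus the per-step `action` and `reward`.
#'
#' @param trajectory Trajectory data frame.
#' @param path Output path.
#' @export
write_trajectory <- function(trajectory, path) {
  write.csv(trajectory, path, row.names = FALSE)
}

#' @rdname write_trajectory
#' @return `read_trajectory()` returns the trajectory data frame.
#' @export
read_trajectory <- function(path) {
  df <- read.csv(path)
  if ("action" %in% names(df))
    df$action <- factor(df$action, levels = action_labels)
  df
}

#' Serialise a Q-table to JSON
#'
#' Writes the action-value matrix as a JSON object mapping state labels to
#' 3-vectors of action values, together with an echo of the discretisation
#' so the table can be interpreted on its own.
#'
#' @param q Q-matrix with state row names (see [q_table()]), or a fitted
#'   [rl_chemotaxis()] model.
#' @param path Output path.
#' @export
write_qtable <- function(q, path) {
  cfg <- NULL
  if (inherits(q, "rl_chemotaxis")) {
    cfg <- list(dim = q$dim, kappa0 = q$agent$kappa0, tau0 = q$agent$tau0,
                d_kappa = q$agent$d_kappa, d_tau = q$agent$d_tau,
                X = q$agent$X, gamma = q$agent$gamma,
                epsilon = q$agent$epsilon)
    q <- q$q
  }
  states <- lapply(seq_len(nrow(q)), function(i) unname(q[i, ]))
  names(states) <- rownames(q)
  jsonlite::write_json(list(actions = colnames(q), config = cfg,
                            values = states),
                       path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_qtable
#' @return `read_qtable()` returns the Q-matrix (attribute `"config"` holds
#'   the echoed configuration, if present).
#' @export
read_qtable <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  q <- do.call(rbind, obj$values)
  dimnames(q) <- list(names(obj$values), obj$actions)
  if (!is.null(obj$config)) attr(q, "config") <- obj$config
  q
}
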