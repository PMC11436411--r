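#' Stimulus-response model configuration
#'
#' Parameters of the adaptation model of chemotactic steering used as the
#' benchmark strategy.  A response variable `a` and an adaptation variable
#' `p` evolve as
#' \deqn{\eta \dot a = p c - a, \qquad \mu \dot p = 1 - a,}
#' and the path curvature follows the response,
#' \eqn{\kappa(t) = \kappa_0 + \kappa_1 (a(t) - 1)}.  At constant
#' concentration `c` the unique fixed point is `a* = 1`, `p* = 1/c`, where
#' the curvature sits at its base value: the system adapts perfectly and
#' responds only to relative changes in the stimulus.
#'
#' @param kappa0 Base curvature (1/um).
#' @param kappa1 Curvature modulation amplitude (1/um).
#' @param eta Response relaxation constant (s), positive.
#' @param mu Adaptation constant (numeric value as conventionally quoted),
#'   positive.
#' @return An object of class `fj_config`.
#' @export
fj_config <- function(kappa0 = 0.03, kappa1 = 0.025, eta = 0.14, mu = 0.725) {
  stopifnot(eta > 0, mu > 0)
  structure(list(kappa0 = kappa0, kappa1 = kappa1, eta = eta, mu = mu),
            class = "fj_config")
}

#' @export
print.fj_config <- function(x, ...) {
  cat("Stimulus-response steering: eta a' = p c - a, mu p' = 1 - a,",
      "kappa = kappa0 + kappa1 (a - 1)\n")
  cat(sprintf("  kappa0 = %g, kappa1 = %g 1/um; eta = %g s; mu = %g\n",
              x$kappa0, x$kappa1, x$eta, x$mu))
  invisible(x)
}

#' Advance the stimulus-response variables
#'
#' Integrates the coupled ODEs at a (held) concentration `c` by classical
#' 4th-order Runge-Kutta.
#'
#' @param a,p Current response and adaptation values.
#' @param c Concentration (pM).
#' @param cfg An [fj_config()].
#' @param dt Sub-step (s), small relative to `eta` and `mu`.
#' @param n_steps Number of sub-steps.
#' @return Numeric vector `c(a, p)` after integration.
#' @export
step_stimulus_response <- function(a, p, c, cfg, dt, n_steps = 1L) {
  cpp_fj_relax(a, p, c, cfg$eta, cfg$mu, dt, as.integer(n_steps))
}

#' Curvature commanded by the response variable
#'
#' @param a Response value(s).
#' @param cfg An [fj_config()].
#' @return `kappa0 + kappa1 * (a - 1)`.
#' @export
curvature_from_response <- function(a, cfg) {
  cfg$kappa0 + cfg$kappa1 * (a - 1)
}

#' Simulate the stimulus-response chemotaxis strategy
#'
#' Co-integrates the planar Frenet-Serret swimmer with the adaptation ODEs:
#' at every sub-step the local concentration drives `(a, p)` one Runge-Kutta
#' step, the curvature is updated from the response, and the frame advances
#' along the exact arc for that curvature.  `(a, p)` start at the adapted
#' fixed point for the initial local concentration, avoiding a startup
#' transient.
#'
#' @param x0 Initial position (um).
#' @param orientation Planar orientation angle (radians); tangent
#'   `(cos, sin)`.  Alternatively supply `t0`/`n0`.
#' @param t0,n0 Initial tangent and normal (override `orientation`).
#' @param t_max Maximum simulated time (s).
#' @param dt Integration sub-step (s).
#' @param baseline An [fj_config()].
#' @param motion A [motion_config()] (only `v` is used).
#' @param field A [chemical_field()].
#' @param d_threshold Radius (um) whose first crossing defines the arrival
#'   time `t_reach`.
#' @param stop_on_reach Stop integrating at first arrival?
#' @param sample_every Record every k-th sub-step.
#' @param response_dt Sensing/response cadence (s).  `NULL` updates the
#'   response continuously on the sub-step grid.  A number (e.g. the
#'   learning-step duration of the Q-learning swimmer) samples the
#'   concentration once per cadence window, relaxes `(a, p)` over the window
#'   at that frozen value and, with `latency = TRUE`, steers each window with
#'   the curvature computed in the previous one -- the same
#'   sensing-to-actuation lag as the learning agent's decision cycle.  Use
#'   this mode for like-for-like timing comparisons with the learned policy.
#' @param latency Apply the one-window actuation lag in cadence mode?
#' @return An object of class `fj_chemotaxis`: trajectory data frame
#'   (`time_s`, positions, `kappa_per_um`, `a`, `p`, `conc_pM`, `dist_um`),
#'   `reached` flag, arrival time `t_reach` and final state.
#' @examples
#' fit <- fj_chemotaxis(t_max = 50, dt = 0.02)
#' fit$reached
#' @export
fj_chemotaxis <- function(x0 = c(180, -180, 0), orientation = 0,
                          t0 = NULL, n0 = NULL,
                          t_max = 1000, dt = 0.01,
                          baseline = fj_config(), motion = motion_config(),
                          field = chemical_field(), d_threshold = 50,
                          stop_on_reach = TRUE, sample_every = 10L,
                          response_dt = NULL, latency = TRUE) {
  stopifnot(inherits(baseline, "fj_config"), t_max > 0, dt > 0)
  if (is.null(t0)) {
    t0 <- c(cos(orientation), sin(orientation), 0)
    n0 <- c(-sin(orientation), cos(orientation), 0)
  }
  response_every <- if (is.null(response_dt)) 1L
                    else max(1L, as.integer(round(response_dt / dt)))
  res <- cpp_simulate_fj(pad3(x0), pad3(t0), pad3(n0),
                         baseline$kappa0, baseline$kappa1, baseline$eta,
                         baseline$mu, motion$v, field$c0, field$center,
                         t_max, dt, d_threshold, isTRUE(stop_on_reach),
                         as.integer(sample_every), response_every,
                         isTRUE(latency))
  tr <- as.data.frame(res$trajectory)
  names(tr) <- c("time_s", "x_um", "y_um", "z_um", "kappa_per_um", "a", "p",
                 "conc_pM", "dist_um")
  structure(list(trajectory = tr, reached = res$reached,
                 t_reach = res$t_reach, a = res$a, p = res$p,
                 final_d = res$final_d, baseline = baseline, motion = motion,
                 field = field, x0 = pad3(x0), dt = dt,
                 d_threshold = d_threshold),
            class = "fj_chemotaxis")
}

#' @export
print.fj_chemotaxis <- function(x, ...) {
  cat("Stimulus-response chemotaxis simulation\n")
  if (x$reached) {
    cat(sprintf("  reached d < %g um at t = %.2f s\n", x$d_threshold, x$t_reach))
  } else {
    cat(sprintf("  did not reach d < %g um (final d = %.1f um)\n",
                x$d_threshold, x$final_d))
  }
  invisible(x)
}

#' @export
plot.fj_chemotaxis <- function(x, which = c("trajectory", "distance",
                                            "curvature"), ...) {
  which <- match.arg(which)
  tr <- x$trajectory
  if (which == "trajectory") {
    plot(tr$x_um, tr$y_um, type = "l", asp = 1, xlab = "x (um)",
         ylab = "y (um)", ...)
    symbols(x$field$center[1], x$field$center[2], circles = x$d_threshold,
            inches = FALSE, add = TRUE, fg = "red")
    points(x$field$center[1], x$field$center[2], pch = 19, col = "red")
  } else if (which == "distance") {
    plot(tr$time_s, tr$dist_um, type = "l", xlab = "time (s)",
         ylab = "d (um)", ...)
    abline(h = x$d_threshold, lty = 2, col = "red")
  } else {
    plot(tr$time_s, tr$kappa_per_um, type = "l", xlab = "time (s)",
         ylab = "kappa (1/um)", ...)
  }
  invisible(x)
}
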