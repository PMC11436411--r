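#' Motion configuration
#'
#' Physical parameters of the swimmer and the time discretisation.  The agent
#' makes one decision per learning step of duration `dt_learn`; within a
#' learning step the frame equations are integrated over `n_sub` sub-steps.
#' Because the integrator applies the exact rotation for piecewise-constant
#' curvature and torsion, positions at learning-step boundaries do not depend
#' on `n_sub`; sub-steps only refine the sampled path in between.
#'
#' @param v Swimming speed (um/s), positive.  Measured speeds for sperm cells
#'   are of order 100--200 um/s.
#' @param dt_learn Learning-step duration (s), positive.
#' @param n_sub Integration sub-steps per learning step (>= 1).
#' @return An object of class `motion_config`.
#' @export
motion_config <- function(v = 120, dt_learn = 0.5, n_sub = 50) {
  stopifnot(v > 0, dt_learn > 0, n_sub >= 1)
  structure(list(v = v, dt_learn = dt_learn, n_sub = as.integer(n_sub)),
            class = "motion_config")
}

#' @export
print.motion_config <- function(x, ...) {
  cat(sprintf("Swimmer motion: v = %g um/s, learning step %g s (%d sub-steps)\n",
              x$v, x$dt_learn, x$n_sub))
  invisible(x)
}

#' Swimmer state: position and orthonormal moving frame
#'
#' Bundles the position `x` with the Frenet-Serret frame: unit tangent `t`,
#' unit normal `n` and unit binormal `b = t x n`, plus the current curvature
#' and torsion.  In 2D the motion is confined to the z = 0 plane with
#' `tau = 0` and `b` fixed along z; the same code path handles both cases.
#'
#' @param x Position (um), length 2 or 3.
#' @param t Unit tangent; defaults to (1, 0, 0).
#' @param n Unit normal, orthogonal to `t`; defaults to (0, 1, 0).
#' @param kappa Path curvature (1/um).
#' @param tau Path torsion (1/um); 0 for planar motion.
#' @return An object of class `swimmer_state`.
#' @export
swimmer_state <- function(x = c(0, 0, 0), t = c(1, 0, 0), n = c(0, 1, 0),
                          kappa = 0.03, tau = 0) {
  x <- pad3(x); t <- pad3(t); n <- pad3(n)
  t <- t / sqrt(sum(t^2))
  n <- n - sum(n * t) * t
  nn <- sqrt(sum(n^2))
  if (nn < 1e-12) stop("'n' must not be parallel to 't'")
  n <- n / nn
  b <- c(t[2] * n[3] - t[3] * n[2],
         t[3] * n[1] - t[1] * n[3],
         t[1] * n[2] - t[2] * n[1])
  structure(list(x = x, t = t, n = n, b = b, kappa = kappa, tau = tau),
            class = "swimmer_state")
}

#' @export
print.swimmer_state <- function(x, ...) {
  cat("Swimmer state\n")
  cat("  x:", sprintf("%.4f", x$x), "um\n")
  cat("  t:", sprintf("%.6f", x$t), "\n")
  cat("  n:", sprintf("%.6f", x$n), "\n")
  cat("  b:", sprintf("%.6f", x$b), "\n")
  cat(sprintf("  kappa: %g 1/um, tau: %g 1/um\n", x$kappa, x$tau))
  invisible(x)
}

#' Advance the swimmer frame over one learning step
#'
#' Integrates the Frenet-Serret equations
#' \deqn{\dot x = v t, \quad \dot t = v \kappa n, \quad
#'       \dot n = -v \kappa t + v \tau b, \quad \dot b = -v \tau n}
#' for constant curvature and torsion over a total duration `dt_total`,
#' split into `n_sub` sub-steps.  Each sub-step rotates the frame exactly
#' about the Darboux vector \eqn{\omega = v(\tau t + \kappa b)} and advances
#' the position along the corresponding circular arc (2D) or helix (3D);
#' the frame is re-orthonormalised after every sub-step.
#'
#' @param state A [swimmer_state()].
#' @param cfg A [motion_config()]; `cfg$dt_learn` is used when `dt_total`
#'   is missing.
#' @param dt_total Total integration time (s).
#' @param n_sub Number of sub-steps; defaults to `cfg$n_sub`.
#' @return The advanced `swimmer_state`, with the sampled sub-step positions
#'   ((n_sub + 1) x 3 matrix) attached as attribute `"path"`.
#' @examples
#' s <- swimmer_state(kappa = 0.03)
#' cfg <- motion_config(v = 200, dt_learn = 0.5)
#' advance_frame(s, cfg)
#' @export
advance_frame <- function(state, cfg, dt_total = cfg$dt_learn,
                          n_sub = cfg$n_sub) {
  stopifnot(inherits(state, "swimmer_state"), inherits(cfg, "motion_config"),
            dt_total > 0, n_sub >= 1)
  res <- cpp_advance_frame(state$x, state$t, state$n, state$b,
                           state$kappa, state$tau, cfg$v, dt_total,
                           as.integer(n_sub))
  out <- state
  out$x <- res$x; out$t <- res$t; out$n <- res$n; out$b <- res$b
  attr(out, "path") <- res$path
  out
}

#' Frame orthonormality error
#'
#' Largest deviation of the moving frame from an orthonormal right-handed
#' triad: unit-norm errors of t, n, b and their pairwise dot products.
#'
#' @param state A [swimmer_state()].
#' @return A single non-negative number.
#' @export
frame_error <- function(state) {
  with(state, max(abs(sum(t^2) - 1), abs(sum(n^2) - 1), abs(sum(b^2) - 1),
                  abs(sum(t * n)), abs(sum(t * b)), abs(sum(n * b))))
}
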