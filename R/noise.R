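#' Noise configuration
#'
#' Two noise sources can act on the swimmer.  Signal noise: chemoattractant
#' molecules bind flagellar receptors at total rate `q(t) = lambda * c(x(t))`;
#' coarse-grained over a learning step the detected stimulus is
#' `q + sqrt(q) * xi_c` with `xi_c` standard normal (shot-noise statistics:
#' mean and variance both `lambda * c`).  Curvature noise: fluctuations of
#' the flagellar beat add a zero-mean Gaussian `xi_kappa` to the commanded
#' curvature, affecting the realised motion but not the agent's discrete
#' curvature state.
#'
#' @param enabled Logical; both noise sources on or off.
#' @param lambda Binding constant (1/(pM s)).
#' @param sigma_kappa Curvature noise parameter.  Interpreted as the
#'   *variance* of `xi_kappa` by default, following the wording that
#'   accompanies the model; set `sigma_is_sd = TRUE` to interpret it as the
#'   standard deviation instead (the usual reading of the symbol sigma).
#' @param sigma_is_sd Logical toggle for the interpretation of `sigma_kappa`.
#' @return An object of class `noise_config`.
#' @export
noise_config <- function(enabled = FALSE, lambda = 10, sigma_kappa = 0.005,
                         sigma_is_sd = FALSE) {
  stopifnot(is.logical(enabled), sigma_kappa >= 0)
  if (enabled) stopifnot(lambda > 0)
  structure(list(enabled = enabled, lambda = lambda,
                 sigma_kappa = sigma_kappa, sigma_is_sd = sigma_is_sd),
            class = "noise_config")
}

#' @export
print.noise_config <- function(x, ...) {
  if (!x$enabled) {
    cat("Noise: disabled\n")
  } else {
    cat(sprintf("Noise: lambda = %g 1/(pM s), sigma_kappa = %g (%s)\n",
                x$lambda, x$sigma_kappa,
                if (x$sigma_is_sd) "standard deviation" else "variance"))
  }
  invisible(x)
}

# standard deviation of the curvature noise implied by a noise_config
kappa_noise_sd <- function(noise) {
  if (!noise$enabled) return(0)
  if (noise$sigma_is_sd) noise$sigma_kappa else sqrt(noise$sigma_kappa)
}

#' Detected stimulus under stochastic receptor binding
#'
#' Returns `q + sqrt(q) * xi_c` with `q = lambda * c` and `xi_c` a standard
#' normal draw (one per concentration value).  The detected stimulus has mean
#' and variance `lambda * c`.  Values at or below zero -- possible at very low
#' concentration -- are floored at 1e-12 so the reciprocal reward stays
#' defined; flooring is rare and the episode driver counts occurrences.
#'
#' @param c Concentration(s), pM, positive.
#' @param noise A [noise_config()]; if disabled, returns `c` unchanged.
#' @return Detected stimulus values (units of a binding rate, 1/s).
#' @export
noisy_concentration <- function(c, noise) {
  if (any(c <= 0)) stop("concentrations must be positive")
  if (!noise$enabled) return(c)
  q <- noise$lambda * c
  pmax(q + sqrt(q) * rnorm(length(q)), 1e-12)
}

#' Realised curvature under flagellar fluctuation
#'
#' Adds a zero-mean Gaussian perturbation to the commanded (mean) curvature.
#' The perturbed value drives the motion for one learning step only; the
#' agent's discrete curvature level is unaffected.
#'
#' @param kappa_bar Commanded curvature(s), 1/um.
#' @param noise A [noise_config()].
#' @return Realised curvature(s).
#' @export
noisy_curvature <- function(kappa_bar, noise) {
  if (!noise$enabled || noise$sigma_kappa == 0) return(kappa_bar)
  kappa_bar + rnorm(length(kappa_bar), sd = kappa_noise_sd(noise))
}
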