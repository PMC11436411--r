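#' Chemoattractant field of a point source
#'
#' The egg releases a chemoattractant that sets up a radially decaying
#' concentration field \eqn{c(x) = c_0 / |x - x_c|}, where \eqn{c_0} is the
#' field strength and \eqn{x_c} the source centre.  The reciprocal decay is
#' the steady-state solution of diffusion from a point source and is the form
#' used throughout the package.
#'
#' @param c0 Field strength (pM at 1 um from the centre). Must be positive.
#' @param center Source centre, a numeric vector of length 2 or 3 (um).
#'   Padded with a zero z-coordinate internally.
#' @return An object of class `chemical_field`.
#' @examples
#' f <- chemical_field(c0 = 10)
#' concentration(f, c(2, 0))
#' @export
chemical_field <- function(c0 = 10, center = c(0, 0, 0)) {
  stopifnot(is.numeric(c0), length(c0) == 1L, c0 > 0,
            is.numeric(center), length(center) %in% c(2L, 3L))
  structure(list(c0 = c0, center = pad3(center)), class = "chemical_field")
}

#' @export
print.chemical_field <- function(x, ...) {
  cat("Point-source chemoattractant field: c(x) = c0 / |x - x_c|\n")
  cat("  c0:", x$c0, "  centre:", paste(x$center, collapse = ", "), "um\n")
  invisible(x)
}

#' Evaluate the concentration field
#'
#' @param field A [chemical_field()].
#' @param x Position(s): a numeric vector of length 2 or 3, or a matrix with
#'   one position per row.
#' @return Concentration(s) in pM.  Evaluating at the source centre is a
#'   singularity and raises an error.
#' @export
concentration <- function(field, x) {
  stopifnot(inherits(field, "chemical_field"))
  if (is.matrix(x)) {
    xm <- t(apply(x, 1L, pad3))
    d <- sqrt(rowSums(sweep(xm, 2L, field$center)^2))
  } else {
    d <- sqrt(sum((pad3(x) - field$center)^2))
  }
  if (any(d == 0))
    stop("concentration is singular at the source centre")
  field$c0 / d
}

# pad a 2D position/direction with z = 0
pad3 <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 2L) c(x, 0) else x[1:3]
}

dist_to <- function(x, center) sqrt(sum((pad3(x) - pad3(center))^2))
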