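#' Gaussian population receptive field
#'
#' A (possibly elliptical) 2-D Gaussian receptive field with five parameters:
#' center `(x0, y0)`, the standard deviations of the two ellipse axes
#' (`sigmaMajor >= sigmaMinor`), and the angle `theta` of the major axis,
#' measured counterclockwise from the positive x axis. The field is
#' unnormalized — its peak equals `gain` — because downstream fitting treats
#' overall amplitude as a free linear parameter. A circular field has
#' `sigmaMajor == sigmaMinor`, in which case `theta` is irrelevant and is
#' normalized to 0.
#'
#' @param x0,y0 center, degrees.
#' @param sigmaMajor,sigmaMinor axis standard deviations, degrees;
#'   `sigmaMinor` defaults to `sigmaMajor` (circular).
#' @param theta major-axis angle, radians. Default 0.
#' @param gain peak amplitude, unitless. Default 1.
#' @return An object of class `"gaussian_prf"`.
#' @examples
#' gaussian_prf(3, 3, 2)   # the circular 2-deg pRF used throughout
#' @export
gaussian_prf <- function(x0, y0, sigmaMajor, sigmaMinor = sigmaMajor,
                         theta = 0, gain = 1) {
  stopifnot_scalar_pos(sigmaMajor, "sigmaMajor")
  stopifnot_scalar_pos(sigmaMinor, "sigmaMinor")
  if (sigmaMinor > sigmaMajor)
    stop("`sigmaMajor` must be >= `sigmaMinor`")
  if (sigmaMajor == sigmaMinor) theta <- 0
  structure(list(x0 = x0, y0 = y0, sigmaMajor = sigmaMajor,
                 sigmaMinor = sigmaMinor, theta = theta, gain = gain),
            class = "gaussian_prf")
}

#' Difference-of-Gaussians receptive field
#'
#' Center-minus-surround field: `DoG = Gc - relAmplitude * Gs`, where center
#' and surround are independent [gaussian_prf()] shapes sharing the center
#' position. The surround carries its own sigmas and angle.
#'
#' @param center a [gaussian_prf()] for the excitatory center.
#' @param surroundSigmaMajor,surroundSigmaMinor surround standard deviations,
#'   degrees.
#' @param surroundTheta surround major-axis angle, radians.
#' @param relAmplitude relative surround amplitude `a >= 0`.
#' @return An object of class `"dog_prf"`.
#' @export
dog_prf <- function(center, surroundSigmaMajor,
                    surroundSigmaMinor = surroundSigmaMajor,
                    surroundTheta = 0, relAmplitude = 0.5) {
  stopifnot(inherits(center, "gaussian_prf"))
  stopifnot_scalar_pos(surroundSigmaMajor, "surroundSigmaMajor")
  stopifnot_scalar_pos(surroundSigmaMinor, "surroundSigmaMinor")
  if (!is.numeric(relAmplitude) || relAmplitude < 0)
    stop("`relAmplitude` must be >= 0")
  structure(list(center = center,
                 surroundSigmaMajor = surroundSigmaMajor,
                 surroundSigmaMinor = surroundSigmaMinor,
                 surroundTheta = surroundTheta,
                 relAmplitude = relAmplitude),
            class = "dog_prf")
}

#' Evaluate a Gaussian receptive field on a grid
#'
#' Returns the rows x cols field matrix
#' `gain * exp(-(u^2 / sigmaMajor^2 + v^2 / sigmaMinor^2) / 2)` where
#' `(u, v)` are the offsets from the center rotated into the ellipse frame.
#'
#' @param prf a [gaussian_prf()].
#' @param grid a [make_grid()] object.
#' @return Numeric matrix of dimension `nRows x nCols`.
#' @export
evaluate_gaussian <- function(prf, grid) {
  stopifnot(inherits(prf, "gaussian_prf"), inherits(grid, "prf_grid"))
  X <- matrix(grid$x, grid$nRows, grid$nCols, byrow = TRUE)
  Y <- matrix(grid$y, grid$nRows, grid$nCols)
  dx <- X - prf$x0
  dy <- Y - prf$y0
  u <- dx * cos(prf$theta) + dy * sin(prf$theta)
  v <- -dx * sin(prf$theta) + dy * cos(prf$theta)
  prf$gain * exp(-0.5 * (u^2 / prf$sigmaMajor^2 + v^2 / prf$sigmaMinor^2))
}

#' Evaluate a difference-of-Gaussians receptive field on a grid
#'
#' @param dog a [dog_prf()].
#' @param grid a [make_grid()] object.
#' @return Numeric matrix `centerField - relAmplitude * surroundField`.
#' @export
evaluate_dog <- function(dog, grid) {
  stopifnot(inherits(dog, "dog_prf"))
  ctr <- dog$center
  sur <- gaussian_prf(ctr$x0, ctr$y0,
                      max(dog$surroundSigmaMajor, dog$surroundSigmaMinor),
                      min(dog$surroundSigmaMajor, dog$surroundSigmaMinor),
                      dog$surroundTheta, gain = ctr$gain)
  evaluate_gaussian(ctr, grid) - dog$relAmplitude * evaluate_gaussian(sur, grid)
}

#' @export
print.gaussian_prf <- function(x, ...) {
  shape <- if (x$sigmaMajor == x$sigmaMinor) "circular" else "elliptical"
  cat(sprintf("%s Gaussian pRF: center (%.3g, %.3g) deg, sigma (%.3g, %.3g) deg, theta %.3g rad, gain %.3g\n",
              shape, x$x0, x$y0, x$sigmaMajor, x$sigmaMinor, x$theta, x$gain))
  invisible(x)
}
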