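#' Visual-field sampling grid
#'
#' Builds the square sampling lattice on which stimulus apertures and
#' receptive fields are evaluated. The lattice spans `fieldExtentDeg` degrees
#' of visual angle with an odd number of samples per axis so that the central
#' sample maps exactly to (0, 0) degrees. Columns map to x (rightward
#' positive) and rows to y (upward positive), so row index increases
#' downward in the stored array: row `r` sits at
#' `y = (centerRow - r) * degPerSample`.
#'
#' @param fieldExtentDeg total visual angle spanned per axis, degrees.
#'   Default 20.
#' @param nSamples samples per axis; must be odd and at least 3. Default 101.
#' @return An object of class `"prf_grid"` with fields `fieldExtentDeg`,
#'   `nRows`, `nCols`, `degPerSample`, and the per-index coordinate vectors
#'   `x` (by column) and `y` (by row).
#' @examples
#' g <- make_grid()
#' g$degPerSample        # 0.2
#' grid_coords(g, 51, 51) # centre sample -> (0, 0)
#' @export
make_grid <- function(fieldExtentDeg = 20, nSamples = 101) {
  stopifnot_scalar_pos(fieldExtentDeg, "fieldExtentDeg")
  if (!is.numeric(nSamples) || length(nSamples) != 1L || nSamples < 3)
    stop("`nSamples` must be a single count >= 3")
  nSamples <- as.integer(nSamples)
  if (nSamples %% 2L == 0L)
    stop("`nSamples` must be odd so the central sample maps exactly to (0, 0) deg")
  dps <- fieldExtentDeg / (nSamples - 1L)
  center <- (nSamples + 1L) %/% 2L
  structure(list(
    fieldExtentDeg = fieldExtentDeg,
    nRows = nSamples,
    nCols = nSamples,
    degPerSample = dps,
    x = (seq_len(nSamples) - center) * dps,
    y = (center - seq_len(nSamples)) * dps
  ), class = "prf_grid")
}

#' Map sample indices to visual-field coordinates
#'
#' @param grid a [make_grid()] object.
#' @param row,col 1-based sample indices.
#' @return Named numeric vector `c(x, y)` in degrees.
#' @export
grid_coords <- function(grid, row, col) {
  stopifnot(inherits(grid, "prf_grid"))
  if (any(row < 1 | row > grid$nRows | col < 1 | col > grid$nCols))
    stop("sample index out of range")
  c(x = grid$x[col], y = grid$y[row])
}

#' Map visual-field coordinates to the nearest sample index
#'
#' Inverse of [grid_coords()]; exact on the lattice.
#'
#' @param grid a [make_grid()] object.
#' @param x,y coordinates in degrees.
#' @return Named integer vector `c(row, col)`.
#' @export
grid_index <- function(grid, x, y) {
  stopifnot(inherits(grid, "prf_grid"))
  c(row = which.min(abs(grid$y - y)), col = which.min(abs(grid$x - x)))
}

#' @export
print.prf_grid <- function(x, ...) {
  cat(sprintf("Visual-field grid: %d x %d samples, %.4g deg extent (%.4g deg/sample)\n",
              x$nRows, x$nCols, x$fieldExtentDeg, x$degPerSample))
  invisible(x)
}

#' Convert Cartesian pRF centers to polar coordinates and back
#'
#' Eccentricity is the radial distance from fixation; polar angle is measured
#' counterclockwise from the positive x axis via `atan2`. The origin maps to
#' eccentricity 0 and angle 0 by convention.
#'
#' @param x0,y0 Cartesian center, degrees.
#' @return `cartesian_to_polar`: named vector `c(eccentricity, polarAngle)`
#'   (degrees, radians). `polar_to_cartesian`: named vector `c(x0, y0)`.
#' @examples
#' cartesian_to_polar(3, 3)  # ecc = sqrt(18), angle = pi/4
#' @export
cartesian_to_polar <- function(x0, y0) {
  ecc <- sqrt(x0^2 + y0^2)
  ang <- ifelse(ecc == 0, 0, atan2(y0, x0))
  c(eccentricity = ecc, polarAngle = ang)
}

#' @rdname cartesian_to_polar
#' @param eccentricity radial distance, degrees.
#' @param polarAngle angle, radians.
#' @export
polar_to_cartesian <- function(eccentricity, polarAngle) {
  c(x0 = eccentricity * cos(polarAngle), y0 = eccentricity * sin(polarAngle))
}

# Wrap an angle difference into (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}
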