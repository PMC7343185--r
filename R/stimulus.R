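#' Bar-sweep stimulus specification
#'
#' Describes the moving-bar retinotopy protocol: a bar of fixed width sweeps
#' across the visual field along several motion directions, with blank (mean
#' luminance) periods interleaved. The default schedule is 8 sweeps — four
#' motion axes, each traversed in both directions (two cardinal axes and the
#' two diagonals) — at 18 s per sweep with 1 s frames, and a 14 s blank after
#' every second sweep, giving 8*18 + 4*14 = 200 frames. Slower protocols
#' keep the frame rate and lengthen the movie: blank length scales with
#' `secondsPerSweep` so the 18/28/38 s variants keep the same structure.
#'
#' @param barWidthDeg bar width, degrees. Default 2.
#' @param secondsPerSweep duration of one sweep, seconds. Default 18.
#' @param frameDurationSec seconds per stimulus frame (the sampling TR).
#'   Default 1.
#' @param sweepDirections motion direction of each sweep, degrees
#'   counterclockwise from rightward; the bar is oriented perpendicular to
#'   its motion.
#' @param blankAfter sweep indices after which a blank period is inserted.
#' @param blankSec blank duration, seconds; default `round(14 *
#'   secondsPerSweep / 18)` so blanks scale with sweep speed.
#' @param randomize if `TRUE` the frames of the sweep movie (blanks included)
#'   are emitted in a seed-determined random temporal order.
#' @param seed integer seed; required when `randomize = TRUE`.
#' @return An object of class `"bar_sweep_spec"`.
#' @seealso [generate_aperture()]
#' @export
bar_sweep_spec <- function(barWidthDeg = 2,
                           secondsPerSweep = 18,
                           frameDurationSec = 1,
                           sweepDirections = c(0, 180, 90, 270, 45, 225, 135, 315),
                           blankAfter = c(2, 4, 6, 8),
                           blankSec = round(14 * secondsPerSweep / 18),
                           randomize = FALSE,
                           seed = NULL) {
  stopifnot_scalar_pos(barWidthDeg, "barWidthDeg")
  stopifnot_scalar_pos(secondsPerSweep, "secondsPerSweep")
  stopifnot_scalar_pos(frameDurationSec, "frameDurationSec")
  if (length(sweepDirections) < 1L) stop("at least one sweep direction is required")
  if (isTRUE(randomize) && is.null(seed))
    stop("`seed` must be set when `randomize = TRUE`")
  framesPerSweep <- max(1L, round(secondsPerSweep / frameDurationSec))
  blankFrames <- max(0L, round(blankSec / frameDurationSec))
  blankAfter <- intersect(as.integer(blankAfter), seq_along(sweepDirections))
  totalFrames <- length(sweepDirections) * framesPerSweep +
    length(blankAfter) * blankFrames
  structure(list(
    barWidthDeg = barWidthDeg,
    secondsPerSweep = secondsPerSweep,
    frameDurationSec = frameDurationSec,
    sweepDirections = sweepDirections,
    blankAfter = blankAfter,
    blankSec = blankSec,
    framesPerSweep = framesPerSweep,
    blankFrames = blankFrames,
    totalFrames = totalFrames,
    randomize = isTRUE(randomize),
    seed = seed
  ), class = "bar_sweep_spec")
}

#' Generate a binary stimulus aperture movie
#'
#' Renders the bar-sweep protocol of a [bar_sweep_spec()] on a visual-field
#' grid as a binary (0/1) rows x cols x frames array. In sweep mode the bar
#' center advances linearly from one field edge to the other within each
#' sweep; blank frames are all-zero. In random mode the identical set of
#' frames is emitted in a seed-determined permutation of temporal order, so
#' sweep and random movies of the same spec contain the same frames as
#' multisets and are signal-matched except for timing.
#'
#' @param spec a [bar_sweep_spec()].
#' @param grid a [make_grid()] object.
#' @return An object of class `"prf_stimulus"`: list with `aperture`
#'   (binary array), `frameDurationSec`, `grid`, `designLabel`
#'   (`"sweep"` or `"random"`) and `seed`.
#' @examples
#' stim <- generate_aperture(bar_sweep_spec(), make_grid())
#' dim(stim$aperture)  # 101 101 200
#' @export
generate_aperture <- function(spec, grid) {
  stopifnot(inherits(spec, "bar_sweep_spec"), inherits(grid, "prf_grid"))
  if (spec$barWidthDeg > grid$fieldExtentDeg)
    stop("bar width (", spec$barWidthDeg, " deg) exceeds the field extent (",
         grid$fieldExtentDeg, " deg)")
  if (spec$totalFrames < 1L) stop("stimulus must contain at least one frame")

  X <- matrix(grid$x, grid$nRows, grid$nCols, byrow = TRUE)
  Y <- matrix(grid$y, grid$nRows, grid$nCols)
  half <- grid$fieldExtentDeg / 2
  ap <- array(0, c(grid$nRows, grid$nCols, spec$totalFrames))
  frame <- 0L
  for (i in seq_along(spec$sweepDirections)) {
    ang <- spec$sweepDirections[i] * pi / 180
    # snap the direction vector so cardinal sweeps are exactly axis-aligned
    # (sin(pi) etc. are not exactly zero, which would tilt the bar edges)
    u <- round(c(cos(ang), sin(ang)), 12)
    proj <- X * u[1] + Y * u[2]
    centers <- seq(-half, half, length.out = spec$framesPerSweep)
    for (c0 in centers) {
      frame <- frame + 1L
      ap[, , frame] <- (abs(proj - c0) <= spec$barWidthDeg / 2) * 1
    }
    if (i %in% spec$blankAfter) frame <- frame + spec$blankFrames
  }
  label <- "sweep"
  if (spec$randomize) {
    perm <- with_seed(spec$seed, sample.int(spec$totalFrames))
    ap <- ap[, , perm, drop = FALSE]
    label <- "random"
  }
  structure(list(
    aperture = ap,
    frameDurationSec = spec$frameDurationSec,
    grid = grid,
    designLabel = label,
    seed = spec$seed,
    spec = spec
  ), class = "prf_stimulus")
}

#' Default bar-sweep stimulus
#'
#' Convenience wrapper: default grid (20 deg, 101 samples) and default sweep
#' protocol, giving the standard 101 x 101 x 200 aperture movie.
#'
#' @param ... passed to [bar_sweep_spec()].
#' @return A `"prf_stimulus"`.
#' @export
default_stimulus <- function(...) {
  generate_aperture(bar_sweep_spec(...), make_grid())
}

#' @export
print.prf_stimulus <- function(x, ...) {
  d <- dim(x$aperture)
  cat(sprintf("pRF stimulus (%s): %d x %d x %d frames, %.3g s/frame, %.3g deg field\n",
              x$designLabel, d[1], d[2], d[3], x$frameDurationSec,
              x$grid$fieldExtentDeg))
  invisible(x)
}

#' Write / read a stimulus aperture as NIfTI
#'
#' The aperture is stored as a rows x cols x 1 x frames unsigned 8-bit NIfTI
#' volume alongside a JSON sidecar carrying `FieldExtentDeg`,
#' `FrameDurationSec`, `DesignLabel` and `Seed`. `read_stimulus()` rejects
#' files with non-binary voxel values, reporting how many entries offend.
#'
#' @param stimulus a `"prf_stimulus"`.
#' @param path output `.nii` / `.nii.gz` path; the sidecar replaces the
#'   extension with `.json`.
#' @return `write_stimulus()` returns `path` invisibly; `read_stimulus()`
#'   returns the reconstructed `"prf_stimulus"`.
#' @export
write_stimulus <- function(stimulus, path) {
  stopifnot(inherits(stimulus, "prf_stimulus"))
  d <- dim(stimulus$aperture)
  vol <- array(as.integer(stimulus$aperture), c(d[1], d[2], 1L, d[3]))
  RNifti::writeNifti(RNifti::asNifti(vol, datatype = "uint8"), path,
                     datatype = "uint8")
  jsonlite::write_json(list(
    FieldExtentDeg = stimulus$grid$fieldExtentDeg,
    FrameDurationSec = stimulus$frameDurationSec,
    DesignLabel = stimulus$designLabel,
    Seed = stimulus$seed
  ), sidecar_path(path), auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_stimulus
#' @export
read_stimulus <- function(path) {
  side <- sidecar_path(path)
  if (!file.exists(side))
    stop("missing stimulus sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("FieldExtentDeg", "FrameDurationSec"))
    if (is.null(meta[[f]])) stop("stimulus sidecar lacks required field ", f)
  vol <- as.array(RNifti::readNifti(path))
  if (length(dim(vol)) == 4L) vol <- vol[, , 1, , drop = TRUE]
  bad <- sum(!(vol %in% c(0, 1)))
  if (bad > 0)
    stop("stimulus aperture must be binary; found ", bad, " non-binary entries")
  grid <- make_grid(meta$FieldExtentDeg, dim(vol)[1])
  structure(list(
    aperture = array(as.numeric(vol), dim(vol)),
    frameDurationSec = meta$FrameDurationSec,
    grid = grid,
    designLabel = meta$DesignLabel %||% "sweep",
    seed = meta$Seed,
    spec = NULL
  ), class = "prf_stimulus")
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}
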