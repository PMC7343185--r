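#' Neural response of a receptive field to a stimulus
#'
#' The per-frame inner product of the binary aperture with the receptive
#' field matrix: `r(t) = sum_ij aperture[i, j, t] * field[i, j]`. Blank
#' (all-zero) frames yield exactly 0.
#'
#' @param stimulus a `"prf_stimulus"`.
#' @param field rows x cols receptive-field matrix matching the stimulus
#'   grid.
#' @return Numeric vector of length `nFrames`, unitless.
#' @export
neural_response <- function(stimulus, field) {
  stopifnot(inherits(stimulus, "prf_stimulus"))
  d <- dim(stimulus$aperture)
  if (!identical(dim(field), d[1:2]))
    stop("receptive-field matrix (", paste(dim(field), collapse = "x"),
         ") does not match the stimulus spatial shape (", d[1], "x", d[2], ")")
  S <- matrix(stimulus$aperture, nrow = d[1] * d[2])
  as.vector(crossprod(S, as.vector(field)))
}

#' Convolve a neural response with an HRF and scale to percent signal
#'
#' Causal convolution (zero stimulus history before frame 1, output truncated
#' to the input length) followed by an affine rescaling so that the
#' noise-free modulation attains `amplitudePSC` percent at its peak:
#' `out = meanSignal + amplitudePSC * conv / refPeak`. When `refPeak` is not
#' supplied it is `max(abs(conv))`, pinning the peak of this series; callers
#' synthesizing a family of signals pass a shared gain-normalized reference
#' peak so that amplitude remains proportional to receptive-field gain.
#' With `amplitudePSC = NULL` the raw convolution (plus `meanSignal`) is
#' returned unscaled.
#'
#' @param series neural response vector.
#' @param kernel unit-sum HRF kernel (shorter than the series).
#' @param meanSignal constant offset, arbitrary units. Default 0, i.e.
#'   percent-signal change around zero.
#' @param amplitudePSC target peak modulation, percent. Default 10.
#' @param refPeak optional reference peak used for scaling.
#' @return BOLD series in percent-signal units (plus `meanSignal`).
#' @export
convolve_and_scale <- function(series, kernel, meanSignal = 0,
                               amplitudePSC = 10, refPeak = NULL) {
  conv <- conv_causal(series, kernel)
  if (is.null(amplitudePSC)) return(meanSignal + conv)
  refPeak <- refPeak %||% max(abs(conv))
  if (refPeak == 0) return(rep(meanSignal, length(series)))
  meanSignal + amplitudePSC * conv / refPeak
}

#' Synthesize one voxel's BOLD time series
#'
#' The full forward model: evaluate the receptive field on the stimulus
#' grid, project the aperture movie through it, convolve with the sampled
#' HRF, scale so a unit-gain field would peak at `amplitudePSC` percent
#' (making the output exactly linear in the field's gain), and add a seeded
#' noise realization.
#'
#' @param prf a [gaussian_prf()] or [dog_prf()].
#' @param stimulus a `"prf_stimulus"`.
#' @param hrf an [hrf_spec()].
#' @param noise a [noise_spec()] or `NULL` for noise-free.
#' @param seed integer seed for the noise realization.
#' @param amplitudePSC peak percent-signal modulation at unit gain.
#'   Default 10.
#' @param meanSignal constant offset. Default 0 (zero-mean PSC convention).
#' @param hrfDurationSec HRF kernel support, seconds. Default 40.
#' @param voxelId identifier recorded in the ground-truth row.
#' @param repetitionIndex repetition label recorded in the ground-truth row.
#' @return List with `bold` (numeric series) and `truth` (one-row
#'   data.frame: voxelId, pRF parameters, hrf name and widthScale, noise
#'   level, seed, repetitionIndex).
#' @export
synthesize_voxel <- function(prf, stimulus, hrf, noise = NULL, seed = NULL,
                             amplitudePSC = 10, meanSignal = 0,
                             hrfDurationSec = 40, voxelId = 1L,
                             repetitionIndex = 1L) {
  stopifnot(inherits(stimulus, "prf_stimulus"), inherits(hrf, "hrf_spec"))
  field <- if (inherits(prf, "dog_prf")) evaluate_dog(prf, stimulus$grid)
           else evaluate_gaussian(prf, stimulus$grid)
  gain <- if (inherits(prf, "dog_prf")) prf$center$gain else prf$gain
  r <- neural_response(stimulus, field)
  kernel <- sample_hrf(hrf, dt = stimulus$frameDurationSec,
                       durationSec = hrfDurationSec)
  conv <- conv_causal(r, kernel)
  refPeak <- if (gain != 0) max(abs(conv)) / abs(gain) else 0
  bold <- if (refPeak == 0) rep(meanSignal, length(r))
          else meanSignal + amplitudePSC * conv / refPeak
  if (!is.null(noise) && !identical(noise$level, "none"))
    bold <- bold + generate_noise(noise, length(bold),
                                  dt = stimulus$frameDurationSec, seed = seed)
  p <- if (inherits(prf, "dog_prf")) prf$center else prf
  truth <- data.frame(
    voxelId = voxelId,
    x0 = p$x0, y0 = p$y0,
    sigmaMajor = p$sigmaMajor, sigmaMinor = p$sigmaMinor,
    theta = p$theta, gain = gain,
    model = if (inherits(prf, "dog_prf")) "dog" else "gaussian",
    hrf = hrf$name, hrfWidthScale = hrf$widthScale,
    noiseLevel = if (is.null(noise)) "none" else noise$level,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    repetitionIndex = repetitionIndex,
    stringsAsFactors = FALSE
  )
  list(bold = bold, truth = truth)
}

#' Synthesize a ground-truth dataset
#'
#' Builds the Cartesian product of pRFs x HRFs x noise levels x repetitions,
#' one voxel per combination, with per-voxel seeds derived from the master
#' seed by a counter scheme (`voxelSeed = seed + voxelIndex`), so any single
#' voxel is reproducible in isolation and the whole dataset is bit-identical
#' under the same master seed.
#'
#' @param prfs list of [gaussian_prf()] / [dog_prf()] objects.
#' @param stimulus a `"prf_stimulus"`.
#' @param hrfs named list of [hrf_spec()] objects (or preset id strings).
#' @param noiseLevels character vector of [noise_preset()] levels and/or
#'   list of [noise_spec()] objects.
#' @param repetitions repetitions per condition. Default 1.
#' @param seed master integer seed. Default 1.
#' @param ... passed to [synthesize_voxel()].
#' @return An object of class `"prf_dataset"`: `bold` (nVoxels x nFrames
#'   matrix), `tr`, `stimulus`, `truth` (data.frame, one row per voxel).
#' @export
synthesize_dataset <- function(prfs, stimulus, hrfs, noiseLevels = "none",
                               repetitions = 1, seed = 1, ...) {
  if (length(prfs) == 0 || length(hrfs) == 0 || length(noiseLevels) == 0)
    stop("condition lists (prfs, hrfs, noiseLevels) must be non-empty")
  if (inherits(prfs, c("gaussian_prf", "dog_prf"))) prfs <- list(prfs)
  if (inherits(hrfs, "hrf_spec")) hrfs <- list(hrfs)
  hrfs <- lapply(hrfs, hrf_preset)
  noiseSpecs <- lapply(noiseLevels, function(nl)
    if (inherits(nl, "noise_spec")) nl else noise_preset(nl))
  nFrames <- dim(stimulus$aperture)[3]
  nVox <- length(prfs) * length(hrfs) * length(noiseSpecs) * repetitions
  bold <- matrix(0, nVox, nFrames)
  truth <- vector("list", nVox)
  v <- 0L
  for (pi in seq_along(prfs)) for (hi in seq_along(hrfs))
    for (ni in seq_along(noiseSpecs)) for (ri in seq_len(repetitions)) {
      v <- v + 1L
      vox <- synthesize_voxel(prfs[[pi]], stimulus, hrfs[[hi]],
                              noise = noiseSpecs[[ni]], seed = seed + v,
                              voxelId = v, repetitionIndex = ri, ...)
      bold[v, ] <- vox$bold
      truth[[v]] <- vox$truth
    }
  structure(list(bold = bold, tr = stimulus$frameDurationSec,
                 stimulus = stimulus, truth = do.call(rbind, truth),
                 seed = seed),
            class = "prf_dataset")
}

#' @export
print.prf_dataset <- function(x, ...) {
  cat(sprintf("Synthetic pRF dataset: %d voxel(s) x %d frames, TR %.3g s\n",
              nrow(x$bold), ncol(x$bold), x$tr))
  invisible(x)
}

#' Write / read a synthetic dataset in BIDS layout
#'
#' The BOLD matrix is stored as an nVoxels x 1 x 1 x nFrames NIfTI under
#' `sub-<label>/func/sub-<label>_task-<task>_bold.nii.gz` with
#' `RepetitionTime` in the JSON sidecar; the stimulus goes to
#' `stimuli/task-<task>_stim.nii.gz` and the ground-truth table to
#' `derivatives/prfsynth/sub-<label>_task-<task>_truth.tsv`.
#'
#' @param dataset a `"prf_dataset"`.
#' @param dir output directory (created if needed).
#' @param subject,task BIDS entity labels.
#' @return `write_bids()` returns `dir` invisibly; `read_bids()` returns the
#'   reconstructed `"prf_dataset"` (BOLD within float precision).
#' @export
write_bids <- function(dataset, dir, subject = "01", task = "prf") {
  stopifnot(inherits(dataset, "prf_dataset"))
  func <- file.path(dir, paste0("sub-", subject), "func")
  deriv <- file.path(dir, "derivatives", "prfsynth")
  stimdir <- file.path(dir, "stimuli")
  for (d in c(func, deriv, stimdir)) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("sub-%s_task-%s", subject, task)
  vol <- aperm(array(dataset$bold, c(nrow(dataset$bold), ncol(dataset$bold), 1L, 1L)),
               c(1L, 3L, 4L, 2L))
  RNifti::writeNifti(RNifti::asNifti(vol), file.path(func, paste0(stem, "_bold.nii.gz")))
  jsonlite::write_json(list(RepetitionTime = dataset$tr, TaskName = task),
                       file.path(func, paste0(stem, "_bold.json")),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(dataset$stimulus))
    write_stimulus(dataset$stimulus,
                   file.path(stimdir, sprintf("task-%s_stim.nii.gz", task)))
  utils::write.table(dataset$truth,
                     file.path(deriv, paste0(stem, "_truth.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(Name = "prfval synthetic dataset", BIDSVersion = "1.8.0"),
                       file.path(dir, "dataset_description.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bids
#' @export
read_bids <- function(dir) {
  bold_files <- Sys.glob(file.path(dir, "sub-*", "func", "*_bold.nii.gz"))
  if (length(bold_files) == 0)
    stop("malformed BIDS layout: no sub-*/func/*_bold.nii.gz found under ", dir)
  path <- bold_files[1]
  side <- sub("\\.nii\\.gz$", ".json", path)
  if (!file.exists(side))
    stop("malformed BIDS layout: missing BOLD sidecar ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  vol <- as.array(RNifti::readNifti(path))
  bold <- matrix(vol, dim(vol)[1], dim(vol)[4])
  truth_files <- Sys.glob(file.path(dir, "derivatives", "prfsynth", "*_truth.tsv"))
  truth <- if (length(truth_files) > 0)
    utils::read.table(truth_files[1], header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  stim_files <- Sys.glob(file.path(dir, "stimuli", "*_stim.nii.gz"))
  stimulus <- if (length(stim_files) > 0) read_stimulus(stim_files[1]) else NULL
  structure(list(bold = bold, tr = meta$RepetitionTime, stimulus = stimulus,
                 truth = truth, seed = NULL),
            class = "prf_dataset")
}
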