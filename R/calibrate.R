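#' On/off block-design scan container
#'
#' A set of voxel time series acquired (or synthesized) under a periodic
#' full-field on/off contrast stimulus, used to calibrate noise levels.
#'
#' @param bold nVoxels x nFrames matrix, raw signal units.
#' @param tr sampling interval, seconds.
#' @param cyclePeriodSec stimulus on/off cycle length, seconds.
#' @param nCycles number of cycles in the run (>= 2).
#' @return An object of class `"onoff_scan"`.
#' @export
onoff_scan <- function(bold, tr, cyclePeriodSec, nCycles) {
  bold <- as.matrix(bold)
  if (nCycles < 2) stop("`nCycles` must be >= 2")
  stopifnot_scalar_pos(tr, "tr")
  stopifnot_scalar_pos(cyclePeriodSec, "cyclePeriodSec")
  if (abs(ncol(bold) * tr - nCycles * cyclePeriodSec) > cyclePeriodSec)
    stop("scan length (", ncol(bold) * tr, " s) does not match ",
         nCycles, " cycles of ", cyclePeriodSec, " s")
  structure(list(bold = bold, tr = tr, cyclePeriodSec = cyclePeriodSec,
                 nCycles = nCycles), class = "onoff_scan")
}

#' Synthesize an on/off calibration scan
#'
#' Generates voxels whose percent modulation is a sinusoid at the stimulus
#' frequency plus white noise, around a raw mean level — the synthetic
#' stand-in for a measured block-design run used to exercise the
#' calibration pipeline with known ground truth.
#'
#' @param amplitudes per-voxel sinusoid amplitudes, percent.
#' @param noiseSd per-voxel white-noise standard deviations, percent
#'   (recycled).
#' @param meanLevel per-voxel raw mean signal levels (recycled).
#' @param nCycles number of stimulus cycles. Default 8.
#' @param cyclePeriodSec cycle length, seconds. Default 24.
#' @param tr sampling interval, seconds. Default 1.5.
#' @param seed integer seed.
#' @return An `"onoff_scan"`.
#' @export
synthesize_onoff_scan <- function(amplitudes, noiseSd = 2, meanLevel = 1000,
                                  nCycles = 8, cyclePeriodSec = 24, tr = 1.5,
                                  seed = NULL) {
  nVox <- length(amplitudes)
  noiseSd <- rep_len(noiseSd, nVox)
  meanLevel <- rep_len(meanLevel, nVox)
  nFrames <- round(nCycles * cyclePeriodSec / tr)
  t <- (seq_len(nFrames) - 1L) * tr
  f <- 1 / cyclePeriodSec
  with_seed(seed, {
    bold <- t(vapply(seq_len(nVox), function(v) {
      psc <- amplitudes[v] * sin(2 * pi * f * t) +
        (if (noiseSd[v] > 0) stats::rnorm(nFrames, 0, noiseSd[v]) else 0)
      meanLevel[v] * (1 + psc / 100)
    }, numeric(nFrames)))
    onoff_scan(bold, tr, cyclePeriodSec, nCycles)
  })
}

#' Stimulus frequency of a periodic block design
#'
#' @param cyclePeriodSec cycle length in seconds.
#' @return Frequency in Hz (`1 / cyclePeriodSec`); a 24 s cycle gives
#'   0.0417 Hz, printing as 0.042.
#' @export
stimulus_frequency <- function(cyclePeriodSec) {
  stopifnot_scalar_pos(cyclePeriodSec, "cyclePeriodSec")
  1 / cyclePeriodSec
}

#' Spectral coherence at the stimulus frequency
#'
#' The amplitude at the discrete frequency bin nearest `stimFreqHz` divided
#' by the mean amplitude over the `windowBins` bins on each side (the
#' stimulus bin itself excluded). Responsive voxels show coherence well
#' above 1; pure noise sits near 1.
#'
#' @param series one voxel's time series.
#' @param stimFreqHz stimulus frequency, Hz.
#' @param tr sampling interval, seconds.
#' @param windowBins half-width of the comparison window in frequency bins.
#'   Default 10.
#' @return Unitless coherence.
#' @export
coherence <- function(series, stimFreqHz, tr, windowBins = 10) {
  n <- length(series)
  if (n < 2 * windowBins) stop("series too short for the coherence window")
  amp <- Mod(stats::fft(series - mean(series)))
  freqs <- (seq_len(n) - 1L) / (n * tr)
  half <- floor(n / 2) + 1L
  bin <- which.min(abs(freqs[seq_len(half)] - stimFreqHz))
  if (bin == 1L) stop("stimulus frequency is unresolvable at this series length")
  window <- setdiff(intersect((bin - windowBins):(bin + windowBins), 2:half), bin)
  if (length(window) == 0)
    stop("stimulus bin at the spectrum edge leaves an empty coherence window")
  amp[bin] / mean(amp[window])
}

#' Convert a time series to percent signal change
#'
#' Subtracts and divides by the temporal mean (times 100); the result has
#' exactly zero mean.
#'
#' @param x numeric series with nonzero mean.
#' @return PSC series, percent.
#' @export
psc <- function(x) {
  m <- mean(x)
  if (m == 0) stop("cannot convert a zero-mean series to percent signal change")
  100 * (x - m) / m
}

#' Least-squares fit of a whole-run sinusoid
#'
#' Fits `A * sin(2*pi*nCycles*t/T + phi) + offset` by linear least squares
#' on sine/cosine regressors at the cycle frequency.
#'
#' @param series numeric series.
#' @param nCycles number of whole cycles spanned by the series (>= 1).
#' @return List with `amplitude`, `phase` (radians), `offset`, `fitted`
#'   (full fitted series) and `modulation` (fitted minus offset).
#' @export
fit_cycle_sinusoid <- function(series, nCycles) {
  if (nCycles < 1) stop("`nCycles` must be >= 1")
  n <- length(series)
  w <- 2 * pi * nCycles * (seq_len(n) - 1L) / n
  s <- sin(w); cc <- cos(w)
  fit <- stats::lm.fit(cbind(1, s, cc), series)
  b <- fit$coefficients
  list(amplitude = sqrt(b[2]^2 + b[3]^2),
       phase = atan2(b[3], b[2]),
       offset = b[1],
       fitted = as.vector(cbind(1, s, cc) %*% b),
       modulation = as.vector(cbind(s, cc) %*% b[2:3]))
}

#' Three-stage responsive-voxel selection
#'
#' Applies, in order: (1) a mean-signal filter keeping voxels whose temporal
#' mean exceeds `meanFrac` of the grand mean signal; (2) a coherence filter
#' keeping survivors within `cohFrac` of the maximum coherence among them;
#' (3) conversion to percent signal change and an amplitude filter keeping
#' modulation (peak-to-peak / 2 of the PSC series) inside `pscRange`.
#' Zero survivors at any stage is a valid (empty) outcome, not an error.
#'
#' @param scan an [onoff_scan()].
#' @param meanFrac stage-1 fraction of the grand mean. Default 0.75.
#' @param cohFrac stage-2 fraction of the maximum coherence. Default 0.8.
#' @param pscRange stage-3 modulation band, percent. Default `c(8, 12)`.
#' @param windowBins coherence window half-width. Default 10.
#' @return List with `indices` (surviving voxel indices) and `stageCounts`
#'   (survivors after each stage).
#' @export
select_voxels <- function(scan, meanFrac = 0.75, cohFrac = 0.8,
                          pscRange = c(8, 12), windowBins = 10) {
  stopifnot(inherits(scan, "onoff_scan"))
  f <- stimulus_frequency(scan$cyclePeriodSec)
  means <- rowMeans(scan$bold)
  s1 <- which(means > meanFrac * mean(scan$bold))
  if (length(s1) == 0)
    return(list(indices = integer(0), stageCounts = c(0L, 0L, 0L)))
  coh <- vapply(s1, function(v)
    coherence(scan$bold[v, ], f, scan$tr, windowBins), numeric(1))
  s2 <- s1[coh >= cohFrac * max(coh)]
  if (length(s2) == 0)
    return(list(indices = integer(0), stageCounts = c(length(s1), 0L, 0L)))
  amp <- vapply(s2, function(v) {
    p <- psc(scan$bold[v, ])
    (max(p) - min(p)) / 2
  }, numeric(1))
  s3 <- as.integer(unname(s2[amp >= pscRange[1] & amp <= pscRange[2]]))
  list(indices = s3,
       stageCounts = c(length(s1), length(s2), length(s3)))
}

#' Estimate SNR of one on/off voxel
#'
#' Converts the voxel to percent signal change, fits the `nCycles`-cycle
#' sinusoid, takes the residual as the noise series and the fitted
#' modulation as the signal, and returns [measure_snr()] of the two.
#'
#' @param scan an [onoff_scan()].
#' @param voxelIdx voxel row index.
#' @return List with `snrDb`, `noise` (residual series), `fit`
#'   (the [fit_cycle_sinusoid()] result) and `pscSeries`.
#' @export
estimate_snr_from_scan <- function(scan, voxelIdx) {
  stopifnot(inherits(scan, "onoff_scan"))
  p <- psc(scan$bold[voxelIdx, ])
  fit <- fit_cycle_sinusoid(p, scan$nCycles)
  noise <- p - fit$fitted
  list(snrDb = measure_snr(fit$modulation, noise),
       noise = noise, fit = fit, pscSeries = p)
}

#' Pick reference voxels at quantiles of the noise distribution
#'
#' Ranks surviving voxels by residual-noise RMS and returns the voxels
#' sitting at the requested quantiles of that distribution (type-1
#' quantiles on the sorted noise levels).
#'
#' @param scan an [onoff_scan()].
#' @param indices candidate voxel indices (e.g. [select_voxels()] output).
#' @param quantiles noise-level quantiles to pick. Default
#'   `c(0.95, 0.45, 0.10)`.
#' @return Data frame with `voxel`, `quantile`, `noiseRms`, `snrDb`.
#' @export
pick_reference_voxels <- function(scan, indices,
                                  quantiles = c(0.95, 0.45, 0.10)) {
  if (length(indices) == 0) stop("no candidate voxels supplied")
  est <- lapply(indices, function(v) estimate_snr_from_scan(scan, v))
  nrms <- vapply(est, function(e) rms(e$noise), numeric(1))
  ord <- order(nrms)
  pick <- vapply(quantiles, function(q)
    ord[max(1L, ceiling(q * length(ord)))], integer(1))
  data.frame(voxel = indices[pick], quantile = quantiles,
             noiseRms = nrms[pick],
             snrDb = vapply(est[pick], function(e) e$snrDb, numeric(1)))
}
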