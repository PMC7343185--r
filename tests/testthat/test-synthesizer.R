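test_that("neural response is the per-frame stimulus-field inner product", {
  stim <- small_stim()
  g <- stim$grid
  expect_identical(neural_response(stim, matrix(0, g$nRows, g$nCols)),
                   numeric(dim(stim$aperture)[3]))
  # single-pixel field projects that pixel's aperture trace
  f <- matrix(0, g$nRows, g$nCols)
  f[11, 14] <- 2.5
  expect_equal(neural_response(stim, f), 2.5 * stim$aperture[11, 14, ])
  # linearity in gain
  fld <- evaluate_gaussian(gaussian_prf(1, 1, 1.5), g)
  expect_equal(neural_response(stim, 3 * fld), 3 * neural_response(stim, fld),
               tolerance = 1e-12)
  expect_error(neural_response(stim, matrix(0, 2, 2)), "does not match")
})

test_that("blank frames yield exactly zero response", {
  stim <- small_stim()
  fld <- evaluate_gaussian(gaussian_prf(0, 0, 2), stim$grid)
  r <- neural_response(stim, fld)
  blanks <- which(apply(stim$aperture, 3, sum) == 0)
  expect_gt(length(blanks), 0)
  expect_identical(r[blanks], numeric(length(blanks)))
})

test_that("causal convolution matches a direct-summation oracle", {
  set.seed(5)
  x <- c(rep(0, 10), rep(1, 20), rep(0, 30))      # boxcar
  k <- sample_hrf(hrf_two_gamma(), dt = 1, durationSec = 30)
  expect_equal(convolve_and_scale(x, k, amplitudePSC = NULL),
               conv_oracle(x, k), tolerance = 1e-10)
  expect_equal(convolve_and_scale(x, 1, amplitudePSC = NULL), x) # delta kernel
  expect_error(convolve_and_scale(x[1:5], k, amplitudePSC = NULL), "longer")
})

test_that("noise-free synthesis is deterministic, scaled and linear in gain", {
  stim <- small_stim()
  hrf <- hrf_two_gamma()
  v1 <- synthesize_voxel(gaussian_prf(1, 1, 1.5), stim, hrf)
  expect_equal(max(abs(v1$bold)), 10)             # 10% peak modulation
  v2 <- synthesize_voxel(gaussian_prf(1, 1, 1.5), stim, hrf)
  expect_identical(v1$bold, v2$bold)
  # end-to-end linearity: scaling gain scales the modulation exactly
  v3 <- synthesize_voxel(gaussian_prf(1, 1, 1.5, gain = 3), stim, hrf)
  expect_equal(v3$bold, 3 * v1$bold, tolerance = 1e-12)
  # noisy synthesis reproducible from the recorded seed
  sp <- noise_preset("mid")
  n1 <- synthesize_voxel(gaussian_prf(1, 1, 1.5), stim, hrf, noise = sp, seed = 4)
  n2 <- synthesize_voxel(gaussian_prf(1, 1, 1.5), stim, hrf, noise = sp, seed = 4)
  expect_identical(n1$bold, n2$bold)
  expect_false(identical(n1$bold, v1$bold))
})

test_that("the default sweep drives one response excursion per sweep", {
  stim <- default_stimulus()
  fld <- evaluate_gaussian(gaussian_prf(3, 3, 2), stim$grid)
  r <- neural_response(stim, fld)
  above <- r > 0.5 * max(r)
  rises <- sum(diff(c(FALSE, above)) == 1)
  expect_equal(rises, 8)
})

test_that("reversing the sweep direction reverses the neural response exactly", {
  g <- small_grid()
  fwd <- generate_aperture(bar_sweep_spec(secondsPerSweep = 6,
                                          sweepDirections = 0,
                                          blankAfter = integer(0)), g)
  rev_ <- generate_aperture(bar_sweep_spec(secondsPerSweep = 6,
                                           sweepDirections = 180,
                                           blankAfter = integer(0)), g)
  # frame-level exactness: frame t of the reversed sweep is frame n+1-t
  nf <- dim(fwd$aperture)[3]
  for (t in seq_len(nf))
    expect_identical(rev_$aperture[, , t], fwd$aperture[, , nf + 1 - t])
  fld <- evaluate_gaussian(gaussian_prf(2, -1, 1.5), g)
  expect_equal(neural_response(rev_, fld), rev(neural_response(fwd, fld)),
               tolerance = 1e-12)
})

test_that("batch synthesis builds the full condition product with derived seeds", {
  stim <- small_stim()
  ds <- synthesize_dataset(list(gaussian_prf(3, 3, 2)), stim,
                           default_hrf_set(), noiseLevels = "mid",
                           repetitions = 100, seed = 7)
  expect_equal(nrow(ds$bold), 400)                # 1 pRF x 4 HRFs x 100 reps
  expect_equal(nrow(ds$truth), 400)
  expect_equal(ds$truth$seed, 7 + seq_len(400))
  ds2 <- synthesize_dataset(list(gaussian_prf(3, 3, 2)), stim,
                            default_hrf_set(), noiseLevels = "mid",
                            repetitions = 100, seed = 7)
  expect_identical(ds$bold, ds2$bold)             # bit-identical under one seed
  expect_error(synthesize_dataset(list(), stim, default_hrf_set()),
               "non-empty")
})

test_that("a degenerate one-rep noise-free batch equals single-voxel synthesis", {
  stim <- small_stim()
  hrf <- hrf_two_gamma()
  ds <- synthesize_dataset(list(gaussian_prf(1, 1, 1.5)), stim, list(hrf),
                           noiseLevels = "none", repetitions = 1, seed = 3)
  vox <- synthesize_voxel(gaussian_prf(1, 1, 1.5), stim, hrf)
  expect_equal(ds$bold[1, ], vox$bold)
})

test_that("percent-signal conversion of a synthesized series has zero mean", {
  stim <- small_stim()
  vox <- synthesize_voxel(gaussian_prf(1, 1, 1.5), stim, hrf_two_gamma(),
                          meanSignal = 1000)
  expect_equal(mean(psc(vox$bold)), 0, tolerance = 1e-12)
})

test_that("BIDS round trip preserves the dataset within float precision", {
  stim <- small_stim()
  ds <- synthesize_dataset(list(gaussian_prf(1, 1, 1.5)), stim,
                           list(hrf_two_gamma()), noiseLevels = "mid",
                           repetitions = 3, seed = 2)
  dir <- withr::local_tempdir()
  write_bids(ds, dir)
  expect_length(Sys.glob(file.path(dir, "sub-*", "func", "*_bold.nii.gz")), 1)
  back <- read_bids(dir)
  expect_lt(max(abs(back$bold - ds$bold)), 1e-6)
  expect_equal(back$tr, ds$tr)
  expect_equal(nrow(back$truth), nrow(ds$truth))
  expect_equal(back$truth$x0, ds$truth$x0)
  expect_identical(back$stimulus$aperture, stim$aperture)
  expect_error(read_bids(withr::local_tempdir()), "sub-\\*/func")
})
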