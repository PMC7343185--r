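test_that("fitter and synthesizer share one forward model", {
  stim <- small_stim()
  hrf <- hrf_two_gamma()
  truth <- gaussian_prf(1.5, -0.5, 1.2, gain = 1.3)
  vox <- synthesize_voxel(truth, stim, hrf)
  pred <- predict_response(1.5, -0.5, 1.2, gain = 1.3, baseline = 0,
                           stimulus = stim, hrf = hrf)
  expect_lt(max(abs(pred - vox$bold)), 1e-10)
  expect_lt(rms(pred - vox$bold), 1e-9)
  # gain 0 gives a flat baseline series
  flat <- predict_response(1, 1, 1, gain = 0, baseline = 2.5,
                           stimulus = stim, hrf = hrf)
  expect_identical(flat, rep(2.5, dim(stim$aperture)[3]))
})

test_that("grid search finds an on-lattice truth exactly and profiles the objective", {
  stim <- small_stim()
  cfg <- quick_config()
  d <- prf_design(stim, hrf_two_gamma(), cfg)
  vox <- synthesize_voxel(gaussian_prf(2, -2, 1), stim, hrf_two_gamma())
  gs <- grid_search(vox$bold, d)
  expect_equal(unlist(gs$best[, c("x", "y", "sigma")]),
               c(x = 2, y = -2, sigma = 1))
  expect_equal(nrow(gs$profile), nrow(d$nodes))
  # exhaustive oracle: the winner attains the minimum of the profile
  expect_equal(gs$best$rmse, min(gs$profile$rmse))
})

test_that("pure noise wins little variance on the lattice", {
  stim <- small_stim()
  d <- prf_design(stim, hrf_two_gamma(), quick_config())
  bold <- prfval:::with_seed(21, stats::rnorm(dim(stim$aperture)[3]))
  gs <- grid_search(bold, d)
  fit <- prf_fit(bold, design = d)
  expect_lt(fit$varexp, 0.2)
})

test_that("ties break deterministically toward smaller eccentricity", {
  # horizontal sweeps only: the response is independent of y, so all-y nodes
  # tie; the smallest-eccentricity node (y = 0) must win
  g <- small_grid()
  stim <- generate_aperture(bar_sweep_spec(secondsPerSweep = 24,
                                           sweepDirections = c(0, 180)), g)
  d <- prf_design(stim, hrf_two_gamma(), quick_config())
  vox <- synthesize_voxel(gaussian_prf(2, 2, 1), stim, hrf_two_gamma())
  gs <- grid_search(vox$bold, d)
  expect_equal(gs$best$y, 0)
  expect_equal(gs$best$x, 2)
})

test_that("an all-constant series is flagged degenerate with zero gain", {
  stim <- small_stim()
  d <- prf_design(stim, hrf_two_gamma(), quick_config())
  fit <- prf_fit(rep(3, dim(stim$aperture)[3]), design = d)
  expect_true(fit$degenerate)
  expect_equal(fit$gain, 0)
  expect_equal(fit$baseline, 3)
})

test_that("noise-free matched-HRF refinement recovers off-lattice truths", {
  stim <- small_stim()
  d <- prf_design(stim, hrf_two_gamma(), quick_config())
  for (truth in list(c(1.3, -0.7, 1.1), c(-2.1, 0.4, 0.8))) {
    vox <- synthesize_voxel(gaussian_prf(truth[1], truth[2], truth[3]),
                            stim, hrf_two_gamma())
    fit <- prf_fit(vox$bold, design = d)
    expect_lt(abs(fit$x0 - truth[1]), 0.1)
    expect_lt(abs(fit$y0 - truth[2]), 0.1)
    expect_lt(abs(fit$sigma - truth[3]), 0.1)
    expect_gt(fit$varexp, 0.999)
  }
})

test_that("refinement never degrades the initialization objective", {
  stim <- small_stim()
  d <- prf_design(stim, hrf_two_gamma(), quick_config())
  vox <- synthesize_voxel(gaussian_prf(2, -2, 1), stim, hrf_two_gamma())
  gs <- grid_search(vox$bold, d)
  fit <- prf_fit(vox$bold, design = d)
  expect_lte(fit$rmse, gs$best$rmse + 1e-12)
})

test_that("a narrower synthesis HRF leads to pRF size underestimation", {
  stim <- small_stim()
  analysis <- hrf_boynton()
  d <- prf_design(stim, analysis, quick_config())
  narrow <- hrf_boynton(tau = 1.5 * 0.75, delay = 2.25)
  vox <- synthesize_voxel(gaussian_prf(2, 1, 1.5), stim, narrow)
  fit <- prf_fit(vox$bold, design = d)
  expect_lt(fit$sigma, 1.5)
})

test_that("median-of-seeds aggregation suppresses outlier fits", {
  stim <- small_stim()
  d <- prf_design(stim, hrf_two_gamma(), quick_config())
  vox <- synthesize_voxel(gaussian_prf(2, -2, 1), stim, hrf_two_gamma(),
                          noise = noise_preset("mid"), seed = 12)
  single <- prf_fit(vox$bold, design = d)
  agg1 <- aggregate_median(vox$bold, d, k = 1)
  expect_equal(coef(agg1), coef(single))
  agg3 <- aggregate_median(vox$bold, d, k = 3)
  fits <- lapply(0:2, function(i) {
    di <- d; di$config$seed <- d$config$seed + i
    prf_fit(vox$bold, design = di)
  })
  worst <- max(vapply(fits, function(f) abs(f$sigma - 1), numeric(1)))
  expect_lte(abs(agg3$sigma - 1), worst + 1e-12)
  expect_error(aggregate_median(vox$bold, d, k = 0), ">= 1")
})

test_that("dataset fitting maps over voxels and survives per-voxel failure", {
  stim <- small_stim()
  ds <- synthesize_dataset(list(gaussian_prf(2, -2, 1)), stim,
                           list(hrf_two_gamma()), noiseLevels = "none",
                           repetitions = 2, seed = 5)
  ds$bold[2, ] <- NA_real_                        # poisoned voxel
  est <- fit_dataset(ds, hrf_two_gamma(), quick_config())
  expect_equal(nrow(est), 2)
  expect_false(est$failed[1])
  expect_true(est$failed[2])
  expect_lt(abs(est$x0[1] - 2), 0.1)
})

test_that("the fitted-model methods are mutually consistent", {
  stim <- small_stim()
  vox <- synthesize_voxel(gaussian_prf(2, -2, 1), stim, hrf_two_gamma(),
                          noise = noise_preset("low"), seed = 30)
  fit <- prf_fit(vox$bold, stim, hrf_two_gamma(), quick_config())
  expect_named(coef(fit), c("x0", "y0", "sigma", "gain", "baseline"))
  expect_equal(fitted(fit) + residuals(fit), fit$bold, tolerance = 1e-12)
  expect_equal(rms(residuals(fit)), fit$rmse, tolerance = 1e-9)
  # predict() re-runs the synthesizer's forward path for the estimates
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-8)
  s <- summary(fit)
  expect_equal(s$eccentricity, sqrt(fit$x0^2 + fit$y0^2))
  expect_output(print(fit), "Circular Gaussian pRF fit")
  expect_output(print(s), "variance explained")
  sims <- simulate(fit, nsim = 2, seed = 77)
  expect_identical(dim(sims), c(2L, length(vox$bold)))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 77))
})
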