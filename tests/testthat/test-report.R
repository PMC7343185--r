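make_truth <- function(n, x = 3, y = 3, sigma = 2) {
  data.frame(voxelId = seq_len(n), x0 = x, y0 = y,
             sigmaMajor = sigma, sigmaMinor = sigma,
             hrf = "boynton-medium", noiseLevel = "mid")
}

make_est <- function(truth, dx = 0, dy = 0, ds = 0) {
  data.frame(voxelId = truth$voxelId, x0 = truth$x0 + dx, y0 = truth$y0 + dy,
             sigma = truth$sigmaMajor + ds)
}

test_that("error records are exact joins with signed, wrapped errors", {
  truth <- make_truth(5)
  err0 <- compute_errors(truth, make_est(truth))
  expect_true(all(err0$dx == 0 & err0$dy == 0 & err0$dSigma == 0 &
                  err0$eccErr == 0 & err0$polarErr == 0))
  err1 <- compute_errors(truth, make_est(truth, dx = 1))
  expect_true(all(err1$dx == 1 & err1$dy == 0 & err1$dSigma == 0))
  # polar error oracle via the coordinate conversion itself
  est <- make_est(truth); est$y0 <- -3
  errp <- compute_errors(truth, est)
  oracle <- cartesian_to_polar(3, -3)[2] - cartesian_to_polar(3, 3)[2]
  expect_equal(errp$polarErr, rep(unname(oracle), 5))
  expect_equal(errp$polarErr[1], -pi / 2)
  expect_identical(err0$hrf, truth$hrf)          # condition labels carried
})

test_that("missing and duplicate keys are rejected with the offending ids", {
  truth <- make_truth(4)
  est <- make_est(truth)
  expect_error(compute_errors(truth, est[-2, ]), "unmatched.*2")
  expect_error(compute_errors(rbind(truth, truth[1, ]), est), "duplicate.*1")
})

test_that("rank-based trimming keeps the central mass of sigma estimates", {
  truth <- make_truth(100)
  s <- summarize_errors(compute_errors(truth, make_est(truth)))
  expect_equal(s$trimmedN, 90)
  expect_equal(s$outlierCount, 10)
  expect_true(all(s$sigmaQuantiles == 2))        # zero-width quantiles
  s_all <- summarize_errors(compute_errors(truth, make_est(truth)),
                            trimQuantile = 1)
  expect_equal(s_all$trimmedN, 100)
  expect_equal(s_all$outlierCount, 0)
  expect_error(summarize_errors(compute_errors(truth, make_est(truth)), 0),
               "trimQuantile")
})

test_that("trimming leaves the median of symmetric errors near zero", {
  meds <- vapply(1:50, function(s) {
    truth <- make_truth(60)
    est <- make_est(truth)
    est$sigma <- est$sigma + prfval:::with_seed(s, stats::rnorm(60, 0, 0.5))
    summarize_errors(compute_errors(truth, est))$medianErrors["dSigma"]
  }, numeric(1))
  expect_lt(abs(stats::median(meds)), 0.1)
})

test_that("small samples degrade gracefully", {
  truth <- make_truth(2)
  s <- summarize_errors(compute_errors(truth, make_est(truth)))
  expect_true(s$warningFlag)
  expect_null(s$ellipse)
})

test_that("the coverage ellipse attains its nominal mass on normal draws", {
  pts <- prfval:::with_seed(123, matrix(stats::rnorm(2e4), ncol = 2))
  ell <- coverage_ellipse(pts, mass = 0.9)
  cov <- mean(ellipse_contains(ell, pts))
  expect_gte(cov, 0.885)
  expect_lte(cov, 0.915)
  # isotropy: semi-axes agree within sampling tolerance
  expect_lt(abs(diff(ell$semiAxes)) / mean(ell$semiAxes), 0.05)
  # affine equivariance: doubling the cloud doubles the axes
  ell2 <- coverage_ellipse(2 * pts, mass = 0.9)
  expect_equal(ell2$semiAxes, 2 * ell$semiAxes, tolerance = 1e-12)
  line <- cbind(1:10, 2 * (1:10))
  expect_error(coverage_ellipse(line), "rank-deficient")
  expect_error(coverage_ellipse(pts[1:2, ]), "3 points")
})

test_that("the mismatch matrix carries the width-bias sign structure", {
  set.seed(4)
  levels <- c("narrow", "medium", "wide")
  rows <- list()
  for (i in seq_along(levels)) for (j in seq_along(levels)) {
    truth <- make_truth(9)
    truth$hrf <- levels[i]
    est <- make_est(truth, ds = 0.8 * (i - j) + stats::rnorm(9, 0, 0.01))
    err <- compute_errors(truth, est)
    err$analysisHrf <- levels[j]
    rows[[length(rows) + 1]] <- err
  }
  errors <- do.call(rbind, rows)
  m <- hrf_mismatch_matrix(errors, levels, levels)
  expect_true(all(abs(diag(m$bias)) < 0.1))
  expect_true(all(m$signPattern[upper.tri(m$bias)] == -1))
  expect_true(all(m$signPattern[lower.tri(m$bias)] == 1))
  # fixed analysis column is strictly increasing in synthesis width
  expect_true(all(diff(m$bias[, 2]) > 0))
  expect_error(hrf_mismatch_matrix(errors[errors$hrf != "narrow" |
                                          errors$analysisHrf != "wide", ],
                                   levels, levels),
               "missing cells.*narrow, wide")
  # single-cell factorial equals the plain median
  one <- errors[errors$hrf == "narrow" & errors$analysisHrf == "narrow", ]
  m1 <- hrf_mismatch_matrix(one, "narrow", "narrow")
  expect_equal(unname(m1$bias[1, 1]), stats::median(one$dSigma))
})

test_that("report export writes readable files and a complete manifest", {
  truth <- make_truth(20)
  est <- make_est(truth, dx = 0.1)
  errors <- compute_errors(truth, est)
  summ <- summarize_errors(errors)
  dir <- file.path(withr::local_tempdir(), "rpt")
  manifest <- export_report(summ, errors, dir, plots = TRUE)
  expect_true(all(file.exists(manifest)))
  expect_setequal(basename(manifest),
                  c("report.json", "errors.tsv", "centers.png", "centers.svg"))
  back <- jsonlite::read_json(file.path(dir, "report.json"),
                              simplifyVector = TRUE)
  expect_equal(back$trimmedN, summ$trimmedN)
  expect_equal(unname(unlist(back$medianCenter)),
               unname(summ$medianCenter))
  tsv <- utils::read.table(file.path(dir, "errors.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(nrow(tsv), nrow(errors))
})
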