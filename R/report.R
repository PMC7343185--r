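#' Join estimates to ground truth and compute per-voxel errors
#'
#' Exact inner join on `voxelId`; missing or duplicated keys on either side
#' are an error listing the offending ids. Errors are signed differences in
#' degrees (`dx`, `dy`, `dSigma`), signed eccentricity error and polar-angle
#' error wrapped to (-pi, pi]. Truth condition labels (synthesis HRF, noise
#' level, ...) are carried through.
#'
#' @param truth ground-truth table (as produced by [synthesize_dataset()]),
#'   with columns `voxelId`, `x0`, `y0`, `sigmaMajor`.
#' @param estimates estimates table (as produced by [fit_dataset()]), with
#'   columns `voxelId`, `x0`, `y0`, `sigma`.
#' @return Data frame of error records, one row per voxel.
#' @export
compute_errors <- function(truth, estimates) {
  for (tbl in list(truth, estimates))
    if (!"voxelId" %in% names(tbl)) stop("both tables need a `voxelId` column")
  dup_t <- truth$voxelId[duplicated(truth$voxelId)]
  dup_e <- estimates$voxelId[duplicated(estimates$voxelId)]
  if (length(dup_t) || length(dup_e))
    stop("duplicate voxelId keys: ",
         paste(unique(c(dup_t, dup_e)), collapse = ", "))
  only_t <- setdiff(truth$voxelId, estimates$voxelId)
  only_e <- setdiff(estimates$voxelId, truth$voxelId)
  if (length(only_t) || length(only_e))
    stop("unmatched voxelId keys: ",
         paste(unique(c(only_t, only_e)), collapse = ", "))
  m <- merge(truth, estimates, by = "voxelId",
             suffixes = c(".true", ".est"), sort = TRUE)
  sigTrue <- m$sigmaMajor
  eccTrue <- sqrt(m$x0.true^2 + m$y0.true^2)
  eccEst <- sqrt(m$x0.est^2 + m$y0.est^2)
  angTrue <- ifelse(eccTrue == 0, 0, atan2(m$y0.true, m$x0.true))
  angEst <- ifelse(eccEst == 0, 0, atan2(m$y0.est, m$x0.est))
  out <- data.frame(
    voxelId = m$voxelId,
    xTrue = m$x0.true, yTrue = m$y0.true, sigmaTrue = sigTrue,
    xEst = m$x0.est, yEst = m$y0.est, sigmaEst = m$sigma,
    dx = m$x0.est - m$x0.true,
    dy = m$y0.est - m$y0.true,
    dSigma = m$sigma - sigTrue,
    eccErr = eccEst - eccTrue,
    polarErr = wrap_angle(angEst - angTrue),
    stringsAsFactors = FALSE
  )
  for (lab in intersect(c("hrf", "hrfWidthScale", "noiseLevel",
                          "repetitionIndex", "model", "analysisHrf",
                          "design"), names(m)))
    out[[lab]] <- m[[lab]]
  out
}

#' Trimmed summary of an error table
#'
#' Trims the table to the central `trimQuantile` mass of the sigma
#' estimates by rank (keeping the middle `ceiling(trimQuantile * n)` order
#' statistics), then reports medians and quantiles on the trimmed set —
#' the outlier-robust view used for nonlinear pRF estimates. With fewer
#' than 3 rows the summary is still emitted, without ellipse fields and
#' with a warning flag.
#'
#' @param errors a [compute_errors()] table (one condition).
#' @param trimQuantile central mass retained, in (0, 1]. Default 0.9.
#' @return List of class `"prf_summary"`: `n`, `trimmedN`, `outlierCount`,
#'   `medianCenter`, `medianErrors`, `sigmaQuantiles` (5/25/50/75/95% of
#'   trimmed sigma estimates), `ellipse` (90% center-coverage ellipse or
#'   `NULL`), `warningFlag`.
#' @export
summarize_errors <- function(errors, trimQuantile = 0.9) {
  if (trimQuantile <= 0 || trimQuantile > 1)
    stop("`trimQuantile` must be in (0, 1]")
  n <- nrow(errors)
  keepN <- ceiling(trimQuantile * n)
  ord <- order(errors$sigmaEst)
  dropLow <- floor((n - keepN) / 2)
  keep <- ord[seq.int(dropLow + 1L, dropLow + keepN)]
  tr <- errors[keep, , drop = FALSE]
  ell <- NULL
  warn <- n < 3
  if (!warn)
    ell <- tryCatch(coverage_ellipse(cbind(tr$xEst, tr$yEst)),
                    error = function(e) NULL)
  structure(list(
    n = n, trimmedN = keepN, outlierCount = n - keepN,
    medianCenter = c(x = stats::median(tr$xEst), y = stats::median(tr$yEst)),
    medianErrors = c(dx = stats::median(tr$dx), dy = stats::median(tr$dy),
                     dSigma = stats::median(tr$dSigma),
                     eccErr = stats::median(tr$eccErr),
                     polarErr = stats::median(tr$polarErr)),
    sigmaQuantiles = stats::quantile(tr$sigmaEst,
                                     c(0.05, 0.25, 0.5, 0.75, 0.95)),
    ellipse = ell,
    warningFlag = warn
  ), class = "prf_summary")
}

#' Covariance-based coverage ellipse
#'
#' Sample-mean-centered, sample-covariance-shaped ellipse scaled by the
#' chi-square (2 df) quantile so that it covers the requested probability
#' mass of a bivariate normal cloud.
#'
#' @param points n x 2 matrix of (x, y) points, n >= 3, not collinear.
#' @param mass coverage mass in (0, 1). Default 0.9.
#' @return List with `center`, `semiAxes` (major, minor), `angle` (radians,
#'   major axis from +x), `cov`, `mass`.
#' @export
coverage_ellipse <- function(points, mass = 0.9) {
  points <- as.matrix(points)
  if (nrow(points) < 3) stop("at least 3 points are required")
  S <- stats::cov(points)
  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) <= .Machine$double.eps * max(ev$values))
    stop("points are collinear or degenerate: covariance is rank-deficient")
  k <- stats::qchisq(mass, df = 2)
  list(center = colMeans(points),
       semiAxes = sqrt(ev$values * k),
       angle = atan2(ev$vectors[2, 1], ev$vectors[1, 1]),
       cov = S, mass = mass)
}

#' Does an ellipse contain each point?
#'
#' Membership test for a [coverage_ellipse()] via the Mahalanobis distance.
#'
#' @param ellipse a [coverage_ellipse()] result.
#' @param points n x 2 matrix.
#' @return Logical vector.
#' @export
ellipse_contains <- function(ellipse, points) {
  d2 <- stats::mahalanobis(as.matrix(points), ellipse$center, ellipse$cov)
  d2 <= stats::qchisq(ellipse$mass, df = 2)
}

#' HRF-mismatch bias matrix
#'
#' Summarizes the sigma bias over a complete synthesis-HRF x analysis-HRF
#' factorial: cell (i, j) holds the median signed sigma error for voxels
#' synthesized with HRF i and analyzed with HRF j. With HRFs ordered
#' narrow-to-wide, cells above the diagonal (synthesis narrower than
#' analysis) are negative — the pRF size is underestimated — and cells
#' below are positive; the matched diagonal is unbiased.
#'
#' @param errors a [compute_errors()] table with `hrf` (synthesis label) and
#'   `analysisHrf` columns.
#' @param synthLevels,analysisLevels optional explicit level orderings
#'   (narrow to wide).
#' @return List of class `"hrf_mismatch_matrix"`: `bias` (matrix of median
#'   dSigma), `diagonal` (logical matrix), `signPattern` (matrix of
#'   `sign(bias)` off the diagonal).
#' @export
hrf_mismatch_matrix <- function(errors, synthLevels = NULL,
                                analysisLevels = NULL) {
  if (!all(c("hrf", "analysisHrf") %in% names(errors)))
    stop("`errors` needs `hrf` and `analysisHrf` columns")
  synthLevels <- synthLevels %||% unique(errors$hrf)
  analysisLevels <- analysisLevels %||% unique(errors$analysisHrf)
  combos <- expand.grid(s = synthLevels, a = analysisLevels,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  have <- paste(errors$hrf, errors$analysisHrf)
  missing <- combos[!(paste(combos$s, combos$a) %in% have), , drop = FALSE]
  if (nrow(missing) > 0)
    stop("incomplete factorial; missing cells: ",
         paste(sprintf("(%s, %s)", missing$s, missing$a), collapse = ", "))
  bias <- matrix(NA_real_, length(synthLevels), length(analysisLevels),
                 dimnames = list(synth = synthLevels,
                                 analysis = analysisLevels))
  for (i in seq_along(synthLevels)) for (j in seq_along(analysisLevels)) {
    sel <- errors$hrf == synthLevels[i] & errors$analysisHrf == analysisLevels[j]
    bias[i, j] <- stats::median(errors$dSigma[sel])
  }
  diagonal <- outer(synthLevels, analysisLevels, "==")
  structure(list(bias = bias, diagonal = diagonal,
                 signPattern = ifelse(diagonal, NA, sign(bias))),
            class = "hrf_mismatch_matrix")
}

#' @export
print.hrf_mismatch_matrix <- function(x, ...) {
  cat("Median sigma error (deg), synthesis HRF (rows) x analysis HRF (columns):\n")
  print(round(x$bias, 3))
  invisible(x)
}

#' Write report files
#'
#' Always writes `report.json` (the summary structure) and `errors.tsv`;
#' with `plots = TRUE` also a PNG and an SVG center-scatter figure. Returns
#' the manifest of written files.
#'
#' @param summary a [summarize_errors()] result (or list of them).
#' @param errors the [compute_errors()] table.
#' @param dir output directory, created if needed.
#' @param plots emit figure files? Default `FALSE`.
#' @return Character vector of written paths, invisibly.
#' @export
export_report <- function(summary, errors, dir, plots = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  jpath <- file.path(dir, "report.json")
  jsonlite::write_json(unclass_recursive(summary), jpath,
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- c(manifest, jpath)
  tpath <- file.path(dir, "errors.tsv")
  utils::write.table(errors, tpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest <- c(manifest, tpath)
  if (plots) {
    draw <- function() {
      graphics::plot(errors$xEst, errors$yEst, asp = 1, pch = 19,
                     col = grDevices::adjustcolor("grey30", 0.5),
                     xlab = "x (deg)", ylab = "y (deg)",
                     main = "Estimated pRF centers")
      graphics::points(errors$xTrue, errors$yTrue, pch = 3, col = "blue")
    }
    ppath <- file.path(dir, "centers.png")
    grDevices::png(ppath, width = 600, height = 600)
    draw(); grDevices::dev.off()
    spath <- file.path(dir, "centers.svg")
    grDevices::svg(spath, width = 6, height = 6)
    draw(); grDevices::dev.off()
    manifest <- c(manifest, ppath, spath)
  }
  invisible(manifest)
}

unclass_recursive <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_recursive) else x
}
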