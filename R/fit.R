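#' Fitter configuration
#'
#' Settings for the reference circular-Gaussian pRF estimator: the coarse
#' search lattices, the box bounds of the nonlinear refinement, optimizer
#' tolerance and the multi-start scheme.
#'
#' @param gridX,gridY candidate center lattices, degrees.
#' @param gridSigma candidate size lattice, degrees.
#' @param xlim,ylim,sigmalim refinement bounds (must contain the lattices;
#'   sigma lower bound > 0).
#' @param tol optimizer convergence tolerance. Default 1e-6.
#' @param nStarts number of refinement starts: the best grid node plus
#'   `nStarts - 1` seeded perturbations of it. Default 3.
#' @param seed seed for the start perturbations. Default 1.
#' @param hrfDurationSec HRF kernel support, seconds. Default 40.
#' @param amplitudePSC amplitude convention used when converting the linear
#'   gain back to receptive-field gain units. Default 10.
#' @return An object of class `"fit_config"`.
#' @export
fit_config <- function(gridX = seq(-10, 10, by = 1),
                       gridY = seq(-10, 10, by = 1),
                       gridSigma = c(0.5, 1, 2, 4, 8),
                       xlim = c(-20, 20), ylim = c(-20, 20),
                       sigmalim = c(0.1, 10),
                       tol = 1e-6, nStarts = 3, seed = 1,
                       hrfDurationSec = 40, amplitudePSC = 10) {
  if (length(gridX) == 0 || length(gridY) == 0 || length(gridSigma) == 0)
    stop("search lattices must be non-empty")
  if (sigmalim[1] <= 0) stop("sigma lower bound must be > 0")
  if (min(gridX) < xlim[1] || max(gridX) > xlim[2] ||
      min(gridY) < ylim[1] || max(gridY) > ylim[2] ||
      min(gridSigma) < sigmalim[1] || max(gridSigma) > sigmalim[2])
    stop("refinement bounds must contain the search lattices")
  if (nStarts < 1) stop("`nStarts` must be >= 1")
  structure(list(gridX = gridX, gridY = gridY, gridSigma = gridSigma,
                 xlim = xlim, ylim = ylim, sigmalim = sigmalim,
                 tol = tol, nStarts = nStarts, seed = seed,
                 hrfDurationSec = hrfDurationSec,
                 amplitudePSC = amplitudePSC),
            class = "fit_config")
}

#' Precomputed fitting design
#'
#' Caches everything about a (stimulus, analysis HRF, config) combination
#' that is shared across voxels: the aperture matrix, the sampled kernel,
#' and the HRF-convolved neural responses of every grid-search node
#' (computed by a separable row/column projection of the aperture, cheap
#' even for the full 101 x 101 x 200 default). Build it once and pass it to
#' [prf_fit()] when fitting many voxels.
#'
#' @param stimulus a `"prf_stimulus"`.
#' @param hrf an [hrf_spec()] (or preset id) assumed by the fitter.
#' @param config a [fit_config()].
#' @return An object of class `"prf_design"`.
#' @export
prf_design <- function(stimulus, hrf, config = fit_config()) {
  stopifnot(inherits(stimulus, "prf_stimulus"), inherits(config, "fit_config"))
  hrf <- hrf_preset(hrf)
  d <- dim(stimulus$aperture)
  kernel <- sample_hrf(hrf, dt = stimulus$frameDurationSec,
                       durationSec = config$hrfDurationSec)
  S <- matrix(stimulus$aperture, nrow = d[1] * d[2])
  nodes <- expand.grid(x = config$gridX, y = config$gridY,
                       sigma = config$gridSigma, KEEP.OUT.ATTRS = FALSE)
  # separable evaluation: r(t; x, y, sigma) = gy' A_t gx
  grid <- stimulus$grid
  nx <- length(config$gridX); ny <- length(config$gridY)
  nf <- d[3]
  A2 <- matrix(stimulus$aperture, nrow = d[1])      # rows x (cols*frames)
  P <- matrix(0, nrow(nodes), nf)
  for (si in seq_along(config$gridSigma)) {
    s <- config$gridSigma[si]
    Gy <- exp(-0.5 * outer(grid$y, config$gridY, "-")^2 / s^2)  # rows x ny
    Gx <- exp(-0.5 * outer(grid$x, config$gridX, "-")^2 / s^2)  # cols x nx
    T1 <- array(crossprod(Gy, A2), c(ny, d[2], nf))
    T2 <- crossprod(Gx, matrix(aperm(T1, c(2, 1, 3)), nrow = d[2])) # nx x (ny*nf)
    R <- matrix(aperm(array(T2, c(nx, ny, nf)), c(1, 2, 3)), nx * ny, nf)
    rows <- (si - 1L) * nx * ny + seq_len(nx * ny)
    P[rows, ] <- conv_causal_rows(R, kernel)
  }
  structure(list(stimulus = stimulus, hrf = hrf, config = config,
                 kernel = kernel, S = S, nodes = nodes, P = P,
                 Sp = rowSums(P), Spp = rowSums(P * P)),
            class = "prf_design")
}

# Closed-form linear solve of bold ~ intercept + slope * pred, returning the
# residual rmse; vectorized over design rows when given sums.
lin_solve <- function(p, y, sp = sum(p), spp = sum(p * p)) {
  n <- length(y)
  sy <- sum(y); syy <- sum(y * y); spy <- sum(p * y)
  denom <- n * spp - sp^2
  if (denom <= .Machine$double.eps * n * max(spp, 1)) {
    slope <- 0; intercept <- sy / n
  } else {
    slope <- (n * spy - sp * sy) / denom
    intercept <- (sy - slope * sp) / n
  }
  rss <- syy + slope^2 * spp + n * intercept^2 +
    2 * (slope * intercept * sp - slope * spy - intercept * sy)
  list(slope = slope, intercept = intercept,
       rmse = sqrt(max(rss, 0) / n),
       varexp = if (syy - sy^2 / n > 0) 1 - max(rss, 0) / (syy - sy^2 / n) else 0)
}

#' Coarse grid search over pRF candidates
#'
#' Evaluates every (x, y, sigma) node of the design's lattices, solving gain
#' and baseline in closed form by linear least squares, and returns the node
#' minimizing the residual RMSE. Ties (within 1e-12) break toward smaller
#' sigma, then smaller eccentricity, then x and y order.
#'
#' @param bold one voxel's BOLD series.
#' @param design a [prf_design()].
#' @return List with `best` (row of the node table plus `slope`,
#'   `intercept`, `rmse`, `varexp`, `degenerate`) and `profile` (data.frame
#'   of the objective over all nodes).
#' @export
grid_search <- function(bold, design) {
  stopifnot(inherits(design, "prf_design"))
  n <- length(bold)
  if (n != ncol(design$P)) stop("BOLD length does not match the design")
  if (stats::sd(bold) == 0) {
    best <- cbind(design$nodes[1, ], slope = 0, intercept = mean(bold),
                  rmse = 0, varexp = 0, degenerate = TRUE)
    return(list(best = best, profile = NULL))
  }
  sy <- sum(bold); syy <- sum(bold * bold)
  spy <- as.vector(design$P %*% bold)
  denom <- n * design$Spp - design$Sp^2
  ok <- denom > .Machine$double.eps * n * pmax(design$Spp, 1)
  slope <- ifelse(ok, (n * spy - design$Sp * sy) / denom, 0)
  intercept <- (sy - slope * design$Sp) / n
  rss <- syy + slope^2 * design$Spp + n * intercept^2 +
    2 * (slope * intercept * design$Sp - slope * spy - intercept * sy)
  rss <- pmax(rss, 0)
  rmse <- sqrt(rss / n)
  ecc <- sqrt(design$nodes$x^2 + design$nodes$y^2)
  tied <- which(rmse <= min(rmse) + 1e-12)
  tied <- tied[order(design$nodes$sigma[tied], ecc[tied],
                     design$nodes$x[tied], design$nodes$y[tied])]
  w <- tied[1]
  sstot <- syy - sy^2 / n
  best <- cbind(design$nodes[w, , drop = FALSE],
                slope = slope[w], intercept = intercept[w], rmse = rmse[w],
                varexp = 1 - rss[w] / sstot, degenerate = FALSE)
  profile <- cbind(design$nodes, rmse = rmse, slope = slope,
                   intercept = intercept)
  list(best = best, profile = profile)
}

# Forward prediction of the unit-gain convolved response for parameters
# (x0, y0, sigma) through exactly the same code path as the synthesizer.
unit_response <- function(par, design) {
  grid <- design$stimulus$grid
  f <- exp(-0.5 * outer((grid$y - par[2])^2, (grid$x - par[1])^2, "+") / par[3]^2)
  r <- as.vector(crossprod(design$S, as.vector(f)))
  conv_causal(r, design$kernel)
}

#' Fit the circular Gaussian linear pRF model to one voxel
#'
#' The reference estimator validated throughout the package: a coarse
#' [grid_search()] over (x, y, sigma) candidates followed by bounded
#' nonlinear refinement (`L-BFGS-B`) of the residual RMSE, with gain and
#' baseline solved in closed form inside the objective. Refinement is run
#' from the best grid node and from `nStarts - 1` seeded perturbations of
#' it; the best converged solution wins and is never worse than its
#' initialization. The forward model inside the objective is the identical
#' code path used by [synthesize_voxel()], so a noise-free voxel fitted with
#' its own synthesis HRF is recovered to optimizer tolerance.
#'
#' @param bold numeric BOLD series (percent-signal units).
#' @param stimulus a `"prf_stimulus"`; ignored when `design` is given.
#' @param hrf analysis HRF ([hrf_spec()] or preset id); ignored when
#'   `design` is given.
#' @param config a [fit_config()].
#' @param design optional precomputed [prf_design()] (recommended when
#'   fitting many voxels).
#' @return An object of class `"prf_fit"` with estimated `x0`, `y0`,
#'   `sigma`, `gain`, `baseline`, diagnostics (`rmse`, `varexp`,
#'   `converged`, `startIndex`, `negativeGain`) and the inputs needed by the
#'   methods ([predict.prf_fit()], [plot.prf_fit()], ...).
#' @examples
#' \donttest{
#' stim <- default_stimulus()
#' vox <- synthesize_voxel(gaussian_prf(3, 3, 2), stim, hrf_two_gamma())
#' fit <- prf_fit(vox$bold, stim, hrf_two_gamma())
#' coef(fit)   # recovers (3, 3, 2)
#' }
#' @export
prf_fit <- function(bold, stimulus = NULL, hrf = NULL,
                    config = fit_config(), design = NULL) {
  if (is.null(design)) {
    if (is.null(stimulus) || is.null(hrf))
      stop("supply either `design` or both `stimulus` and `hrf`")
    design <- prf_design(stimulus, hrf, config)
  }
  config <- design$config
  gs <- grid_search(bold, design)
  best <- gs$best
  if (isTRUE(best$degenerate)) {
    return(new_prf_fit(c(best$x, best$y, best$sigma), 0, mean(bold), 0, 0,
                       FALSE, 0L, design, bold, degenerate = TRUE))
  }
  obj <- function(par) {
    p <- unit_response(par, design)
    lin_solve(p, bold)$rmse
  }
  init <- c(best$x, best$y, best$sigma)
  starts <- list(init)
  if (config$nStarts > 1) {
    perturb <- with_seed(config$seed, {
      lapply(seq_len(config$nStarts - 1L), function(i)
        init + stats::rnorm(3, 0, c(1, 1, 0.3 * init[3])))
    })
    starts <- c(starts, lapply(perturb, function(s) c(
      min(max(s[1], config$xlim[1]), config$xlim[2]),
      min(max(s[2], config$ylim[1]), config$ylim[2]),
      min(max(s[3], config$sigmalim[1]), config$sigmalim[2]))))
  }
  lower <- c(config$xlim[1], config$ylim[1], config$sigmalim[1])
  upper <- c(config$xlim[2], config$ylim[2], config$sigmalim[2])
  bestPar <- init; bestVal <- obj(init); bestConv <- FALSE; bestStart <- 0L
  for (k in seq_along(starts)) {
    opt <- tryCatch(
      stats::optim(starts[[k]], obj, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(factr = config$tol * 1e10, maxit = 500)),
      error = function(e) NULL)
    if (!is.null(opt) && opt$value <= bestVal) {
      bestPar <- opt$par; bestVal <- opt$value
      # an exactly-zero objective aborts the line search; that is convergence
      bestConv <- opt$convergence == 0 || opt$value <= config$tol
      bestStart <- k
    }
  }
  p <- unit_response(bestPar, design)
  ls <- lin_solve(p, bold)
  # convert the linear slope on the unit-gain response into receptive-field
  # gain units under the synthesizer's peak-amplitude convention
  refPeak <- max(abs(p))
  gain <- if (refPeak > 0) ls$slope * refPeak / config$amplitudePSC else 0
  new_prf_fit(bestPar, gain, ls$intercept, ls$rmse, ls$varexp,
              bestConv, bestStart, design, bold,
              slope = ls$slope)
}

new_prf_fit <- function(par, gain, baseline, rmse, varexp, converged,
                        startIndex, design, bold, degenerate = FALSE,
                        slope = 0) {
  structure(list(
    x0 = unname(par[1]), y0 = unname(par[2]), sigma = unname(par[3]),
    gain = gain, baseline = baseline, slope = slope,
    rmse = rmse, varexp = varexp, converged = converged,
    startIndex = startIndex, degenerate = degenerate,
    negativeGain = gain < 0,
    design = design, bold = bold
  ), class = "prf_fit")
}

#' Forward-model prediction for explicit parameters
#'
#' Runs the synthesizer's noise-free pipeline for circular-Gaussian
#' parameters `(x0, y0, sigma, gain, baseline)` under a given stimulus and
#' HRF — the same forward model the fitter inverts.
#'
#' @param x0,y0,sigma circular pRF parameters, degrees.
#' @param gain receptive-field gain.
#' @param baseline constant offset added to the series.
#' @param stimulus a `"prf_stimulus"`.
#' @param hrf an [hrf_spec()] or preset id.
#' @param amplitudePSC peak percent modulation at unit gain. Default 10.
#' @param hrfDurationSec kernel support, seconds. Default 40.
#' @return Predicted BOLD series.
#' @export
predict_response <- function(x0, y0, sigma, gain = 1, baseline = 0,
                             stimulus, hrf, amplitudePSC = 10,
                             hrfDurationSec = 40) {
  vox <- synthesize_voxel(gaussian_prf(x0, y0, sigma, gain = gain),
                          stimulus, hrf_preset(hrf), noise = NULL,
                          amplitudePSC = amplitudePSC,
                          meanSignal = baseline,
                          hrfDurationSec = hrfDurationSec)
  vox$bold
}

#' Fit every voxel of a dataset
#'
#' Maps [prf_fit()] over the rows of a synthetic (or measured) dataset with
#' one shared [prf_design()]; a voxel's failure is recorded, not fatal.
#'
#' @param dataset a `"prf_dataset"`.
#' @param hrf analysis HRF assumed by the fitter.
#' @param config a [fit_config()].
#' @param design optional prebuilt [prf_design()].
#' @return Data frame of estimates, one row per voxel: `voxelId`, `x0`,
#'   `y0`, `sigma`, `gain`, `baseline`, `rmse`, `varexp`, `converged`,
#'   `startIndex`, `failed`.
#' @export
fit_dataset <- function(dataset, hrf, config = fit_config(), design = NULL) {
  stopifnot(inherits(dataset, "prf_dataset"))
  if (is.null(design)) design <- prf_design(dataset$stimulus, hrf, config)
  rows <- lapply(seq_len(nrow(dataset$bold)), function(v) {
    fit <- tryCatch(prf_fit(dataset$bold[v, ], design = design),
                    error = function(e) NULL)
    if (is.null(fit))
      return(data.frame(voxelId = v, x0 = NA_real_, y0 = NA_real_,
                        sigma = NA_real_, gain = NA_real_,
                        baseline = NA_real_, rmse = NA_real_,
                        varexp = NA_real_, converged = FALSE,
                        startIndex = NA_integer_, failed = TRUE))
    data.frame(voxelId = v, x0 = fit$x0, y0 = fit$y0, sigma = fit$sigma,
               gain = fit$gain, baseline = fit$baseline, rmse = fit$rmse,
               varexp = fit$varexp, converged = fit$converged,
               startIndex = fit$startIndex, failed = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(dataset$truth) && "voxelId" %in% names(dataset$truth))
    out$voxelId <- dataset$truth$voxelId
  out
}

#' Median-of-seeds aggregate fit
#'
#' Runs `k` fits of the same voxel with different multi-start seeds and
#' returns the component-wise median of the estimates — the practical
#' outlier-suppression strategy for nonlinear pRF searches: a handful of
#' repeated fits approximates the median solution.
#'
#' @param bold one voxel's BOLD series.
#' @param design a [prf_design()].
#' @param k number of repeated fits (>= 1). Default 3.
#' @return A `"prf_fit"` whose parameters are the component-wise medians,
#'   with diagnostics recomputed at the median parameters.
#' @export
aggregate_median <- function(bold, design, k = 3) {
  if (k < 1) stop("`k` must be >= 1")
  fits <- lapply(seq_len(k), function(i) {
    d <- design
    d$config$seed <- design$config$seed + i - 1L
    prf_fit(bold, design = d)
  })
  if (k == 1) return(fits[[1]])
  par <- c(stats::median(vapply(fits, `[[`, numeric(1), "x0")),
           stats::median(vapply(fits, `[[`, numeric(1), "y0")),
           stats::median(vapply(fits, `[[`, numeric(1), "sigma")))
  p <- unit_response(par, design)
  ls <- lin_solve(p, bold)
  refPeak <- max(abs(p))
  gain <- if (refPeak > 0) ls$slope * refPeak / design$config$amplitudePSC else 0
  new_prf_fit(par, gain, ls$intercept, ls$rmse, ls$varexp,
              all(vapply(fits, `[[`, logical(1), "converged")),
              NA_integer_, design, bold, slope = ls$slope)
}

# ---- methods -------------------------------------------------------------

#' @export
coef.prf_fit <- function(object, ...) {
  c(x0 = object$x0, y0 = object$y0, sigma = object$sigma,
    gain = object$gain, baseline = object$baseline)
}

#' Predict from a fitted pRF model
#'
#' @param object a `"prf_fit"`.
#' @param newstimulus optional `"prf_stimulus"` to predict under; defaults
#'   to the stimulus the model was fitted to.
#' @param ... unused.
#' @return Predicted BOLD series.
#' @export
predict.prf_fit <- function(object, newstimulus = NULL, ...) {
  stim <- newstimulus %||% object$design$stimulus
  predict_response(object$x0, object$y0, object$sigma,
                   gain = object$gain, baseline = object$baseline,
                   stimulus = stim, hrf = object$design$hrf,
                   amplitudePSC = object$design$config$amplitudePSC,
                   hrfDurationSec = object$design$config$hrfDurationSec)
}

#' @export
fitted.prf_fit <- function(object, ...) {
  p <- unit_response(c(object$x0, object$y0, object$sigma), object$design)
  object$baseline + object$slope * p
}

#' @export
residuals.prf_fit <- function(object, ...) object$bold - fitted(object)

#' @export
print.prf_fit <- function(x, ...) {
  cat("Circular Gaussian pRF fit\n")
  cat(sprintf("  center (x0, y0): (%.3f, %.3f) deg\n", x$x0, x$y0))
  cat(sprintf("  size (sigma):    %.3f deg\n", x$sigma))
  cat(sprintf("  gain %.4g, baseline %.4g\n", x$gain, x$baseline))
  cat(sprintf("  rmse %.4g, variance explained %.3f%s\n", x$rmse, x$varexp,
              if (x$converged) "" else " (optimizer did not converge)"))
  if (x$negativeGain) cat("  warning: negative gain — degenerate fit\n")
  invisible(x)
}

#' Summary of a fitted pRF model
#'
#' @param object a `"prf_fit"`.
#' @param ... unused.
#' @return An object of class `"summary.prf_fit"` adding polar coordinates
#'   and fit diagnostics.
#' @export
summary.prf_fit <- function(object, ...) {
  pol <- cartesian_to_polar(object$x0, object$y0)
  structure(list(coef = coef(object),
                 eccentricity = unname(pol[1]),
                 polarAngle = unname(pol[2]),
                 rmse = object$rmse, varexp = object$varexp,
                 converged = object$converged,
                 negativeGain = object$negativeGain,
                 n = length(object$bold)),
            class = "summary.prf_fit")
}

#' @export
print.summary.prf_fit <- function(x, ...) {
  cat("Circular Gaussian pRF fit\n\nParameters:\n")
  print(round(x$coef, 4))
  cat(sprintf("\nEccentricity %.3f deg, polar angle %.3f rad\n",
              x$eccentricity, x$polarAngle))
  cat(sprintf("RMSE %.4g over %d frames, variance explained %.3f\n",
              x$rmse, x$n, x$varexp))
  cat(if (x$converged) "Optimizer converged.\n" else "Optimizer did not converge.\n")
  invisible(x)
}

#' Plot a fitted pRF model
#'
#' Two panels: the estimated receptive field in the visual field (1-SD and
#' 2-SD circles) and the observed versus fitted time series.
#'
#' @param x a `"prf_fit"`.
#' @param ... unused.
#' @export
plot.prf_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  half <- x$design$stimulus$grid$fieldExtentDeg / 2
  graphics::plot(NA, xlim = c(-half, half), ylim = c(-half, half), asp = 1,
                 xlab = "x (deg)", ylab = "y (deg)", main = "Estimated pRF")
  graphics::abline(h = 0, v = 0, col = "grey80")
  th <- seq(0, 2 * pi, length.out = 200)
  for (k in 1:2)
    graphics::lines(x$x0 + k * x$sigma * cos(th), x$y0 + k * x$sigma * sin(th),
                    col = c("black", "grey60")[k])
  graphics::points(x$x0, x$y0, pch = 19)
  t <- (seq_along(x$bold) - 1L) * x$design$stimulus$frameDurationSec
  graphics::plot(t, x$bold, type = "l", col = "grey40",
                 xlab = "time (s)", ylab = "BOLD (PSC)",
                 main = sprintf("Fit (R² = %.2f)", x$varexp))
  graphics::lines(t, fitted(x), col = "red")
  invisible(x)
}

#' Simulate noisy realizations from a fitted pRF model
#'
#' @param object a `"prf_fit"`.
#' @param nsim number of realizations. Default 1.
#' @param seed integer seed.
#' @param noise a [noise_spec()]; default the mid-level preset.
#' @param ... unused.
#' @return `nsim` x nFrames matrix of simulated series.
#' @export
simulate.prf_fit <- function(object, nsim = 1, seed = NULL,
                             noise = noise_preset("mid"), ...) {
  base <- fitted(object)
  dt <- object$design$stimulus$frameDurationSec
  out <- with_seed(seed, {
    t(vapply(seq_len(nsim), function(i)
      base + generate_noise(noise, length(base), dt = dt,
                            seed = if (is.null(seed)) NULL else seed + i),
      numeric(length(base))))
  })
  out
}
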