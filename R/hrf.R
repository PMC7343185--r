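#' Hemodynamic response function specification
#'
#' Two kernel families are supported. The `"twoGamma"` form is a peak Gamma
#' density minus a scaled undershoot Gamma density,
#' `h(t) = dgamma(t, a1, b1) - c * dgamma(t, a2, b2)`; with `c = 0` it is a
#' literal single Gamma. The `"boynton"` form is a delayed single Gamma with
#' no undershoot (all-positive), `h(t) = dgamma(t - delay, n, scale = tau)`.
#' `widthScale` dilates the time axis before sampling, so full width at half
#' maximum and time-to-peak scale together; it is the controlled mechanism
#' behind the width-mismatch experiments. Sampled kernels are normalized to
#' unit sum so that convolution preserves the mean of a series: HRF mismatch
#' then perturbs response shape, not overall gain (gain is a free fit
#' parameter regardless).
#'
#' Default two-Gamma parameters are the canonical a1 = 6, b1 = 1, a2 = 16,
#' b2 = 1, c = 1/6; Boynton defaults are n = 3, tau = 1.5 s, delay = 2.25 s.
#'
#' @param form `"twoGamma"` or `"boynton"`.
#' @param a1,b1 shape/rate of the peak Gamma (twoGamma).
#' @param a2,b2 shape/rate of the undershoot Gamma (twoGamma).
#' @param c relative undershoot scaling, `>= 0` (twoGamma).
#' @param n,tau,delay Boynton shape, time constant (s) and onset delay (s).
#' @param widthScale time-dilation factor, unitless. Default 1.
#' @param name optional label used in reports.
#' @return An object of class `"hrf_spec"`.
#' @examples
#' hrf_two_gamma()
#' hrf_boynton(widthScale = 1.5)
#' @export
hrf_spec <- function(form = c("twoGamma", "boynton"),
                     a1 = 6, b1 = 1, a2 = 16, b2 = 1, c = 1/6,
                     n = 3, tau = 1.5, delay = 2.25,
                     widthScale = 1, name = NULL) {
  form <- match.arg(form)
  stopifnot_scalar_pos(widthScale, "widthScale")
  if (form == "twoGamma") {
    for (p in c(a1 = a1, b1 = b1, a2 = a2, b2 = b2))
      if (p <= 0) stop("two-Gamma shape/rate parameters must be positive")
    if (c < 0) stop("`c` must be >= 0")
  } else {
    stopifnot_scalar_pos(n, "n")
    stopifnot_scalar_pos(tau, "tau")
    if (delay < 0) stop("`delay` must be >= 0")
  }
  structure(list(form = form, a1 = a1, b1 = b1, a2 = a2, b2 = b2, c = c,
                 n = n, tau = tau, delay = delay, widthScale = widthScale,
                 name = name %||% if (form == "twoGamma") "canonical" else "boynton"),
            class = "hrf_spec")
}

#' @rdname hrf_spec
#' @param ... passed to [hrf_spec()].
#' @export
hrf_two_gamma <- function(...) hrf_spec("twoGamma", ...)

#' @rdname hrf_spec
#' @export
hrf_boynton <- function(...) hrf_spec("boynton", ...)

# Continuous-time kernel value before normalization.
hrf_value <- function(spec, t) {
  ts <- t / spec$widthScale
  if (spec$form == "twoGamma") {
    stats::dgamma(ts, shape = spec$a1, rate = spec$b1) -
      spec$c * stats::dgamma(ts, shape = spec$a2, rate = spec$b2)
  } else {
    stats::dgamma(ts - spec$delay, shape = spec$n, scale = spec$tau)
  }
}

#' Sample an HRF kernel
#'
#' Samples the continuous kernel at interval `dt` over `[0, durationSec)`
#' (time axis dilated by `widthScale` first) and normalizes it to unit sum.
#'
#' @param spec an [hrf_spec()].
#' @param dt sampling interval, seconds. Default 1.
#' @param durationSec kernel support, seconds; must cover the response
#'   (at least 20 s). Default 40.
#' @return Numeric vector of length `round(durationSec / dt)` summing to 1.
#' @export
sample_hrf <- function(spec, dt = 1, durationSec = 40) {
  stopifnot(inherits(spec, "hrf_spec"))
  stopifnot_scalar_pos(dt, "dt")
  if (durationSec < 20) stop("`durationSec` must be at least 20 s to cover the response")
  t <- (seq_len(round(durationSec / dt)) - 1L) * dt
  h <- hrf_value(spec, t)
  s <- sum(h)
  if (!is.finite(s) || s <= 0)
    stop("degenerate HRF parameterization: unnormalized kernel sum is not positive")
  h / s
}

#' Scale the width of an HRF
#'
#' Multiplies the spec's `widthScale`, i.e. dilates the kernel in time: both
#' the full width at half maximum and the peak time scale by `factor`.
#'
#' @param spec an [hrf_spec()].
#' @param factor positive dilation factor.
#' @return The modified `"hrf_spec"`.
#' @export
hrf_scale_width <- function(spec, factor) {
  stopifnot(inherits(spec, "hrf_spec"))
  stopifnot_scalar_pos(factor, "factor")
  spec$widthScale <- spec$widthScale * factor
  if (factor != 1) spec$name <- sprintf("%s-w%.3g", sub("-w[0-9.]+$", "", spec$name), spec$widthScale)
  spec
}

#' Full width at half maximum of an HRF kernel
#'
#' Measured on a finely sampled kernel by linear interpolation of the
#' half-maximum crossings of the positive lobe.
#'
#' @param spec an [hrf_spec()].
#' @param dt fine sampling interval, seconds. Default 0.01.
#' @param durationSec support used for the measurement. Default 60.
#' @return FWHM in seconds.
#' @export
hrf_fwhm <- function(spec, dt = 0.01, durationSec = 60) {
  t <- seq(0, durationSec, by = dt)
  h <- hrf_value(spec, t)
  pk <- which.max(h)
  half <- h[pk] / 2
  cross <- function(idx) {
    # linear interpolation between the bracketing samples
    i0 <- idx[1]; i1 <- idx[2]
    t[i0] + (half - h[i0]) * (t[i1] - t[i0]) / (h[i1] - h[i0])
  }
  left <- max(which(h[seq_len(pk)] < half))
  right <- pk - 1L + min(which(h[pk:length(h)] < half))
  cross(c(right - 1L, right)) - cross(c(left, left + 1L))
}

#' Four width-ordered HRFs for mismatch experiments
#'
#' A family of four all-positive (Boynton-form) kernels with strictly
#' increasing full width at half maximum (about 3.8, 5.1, 6.4 and 7.9 s),
#' standing in for the heterogeneous default kernels of published pRF
#' analysis tools when building HRF-mismatch matrices. The time constant
#' scales as `tau = 1.5 * w` with the onset delay set to `7.5 - 4.5 * w`
#' so every member has the same mean response latency (first temporal
#' moment, 7.5 s): estimated pRF center position couples to the kernel's
#' mean latency, so an aligned family isolates the width effect on size
#' from latency effects on position.
#'
#' @return Named list of four [hrf_spec()] objects ordered by increasing
#'   width: `boynton-narrow`, `boynton-medium`, `boynton-wide`,
#'   `boynton-broad`.
#' @export
default_hrf_set <- function() {
  scales <- c(0.75, 1, 1.25, 1.55)
  labels <- c("boynton-narrow", "boynton-medium", "boynton-wide",
              "boynton-broad")
  out <- Map(function(w, nm)
    hrf_boynton(tau = 1.5 * w, delay = 7.5 - 4.5 * w, name = nm),
    scales, labels)
  names(out) <- labels
  out
}

#' @export
print.hrf_spec <- function(x, ...) {
  if (x$form == "twoGamma")
    cat(sprintf("HRF '%s': two-Gamma (a1=%g, b1=%g, a2=%g, b2=%g, c=%g), widthScale %g\n",
                x$name, x$a1, x$b1, x$a2, x$b2, x$c, x$widthScale))
  else
    cat(sprintf("HRF '%s': Boynton single-Gamma (n=%g, tau=%g s, delay=%g s), widthScale %g\n",
                x$name, x$n, x$tau, x$delay, x$widthScale))
  invisible(x)
}

#' Resolve an HRF preset id
#'
#' String ids address named kernels in configs and the command line:
#' `"canonical"` (two-Gamma default), `"boynton"`, optionally suffixed
#' `-w<factor>` for a width-scaled variant (e.g. `"boynton-w1.5"`).
#'
#' @param id preset string, or an [hrf_spec()] passed through unchanged.
#' @return An `"hrf_spec"`.
#' @export
hrf_preset <- function(id) {
  if (inherits(id, "hrf_spec")) return(id)
  stopifnot(is.character(id), length(id) == 1L)
  m <- regmatches(id, regexec("^([a-zA-Z]+)(-w([0-9.]+))?$", id))[[1]]
  if (length(m) == 0) stop("unknown HRF preset: ", id)
  base <- switch(m[2],
                 canonical = hrf_two_gamma(),
                 twogamma = hrf_two_gamma(),
                 boynton = hrf_boynton(),
                 stop("unknown HRF preset: ", id))
  if (nzchar(m[4])) base <- hrf_scale_width(base, as.numeric(m[4]))
  base
}
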