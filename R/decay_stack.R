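#' TCSPC decay stack
#'
#' Container for per-pixel photon-count decay histograms: a 3-D array of
#' non-negative counts indexed (time-bin, row, col), with bin-center times
#' spanning exactly one laser period.
#'
#' @param counts 3-D numeric array (time-bin, row, col) of counts (>= 0).
#' @param bin_centers_ns Strictly increasing bin-center times in ns.
#' @param laser_period_ns Laser period in ns.
#' @param channel Channel label, `"NADPH"` or `"FAD"`.
#' @param harmonic Default harmonic for downstream phasor transforms.
#' @return An object of class `decay_stack`.
#' @export
decay_stack <- function(counts, bin_centers_ns, laser_period_ns,
                        channel = c("NADPH", "FAD"), harmonic = 1L) {
  channel <- match.arg(channel)
  if (length(dim(counts)) != 3L) stop("counts must be a 3-D array (time, row, col)")
  if (any(counts < 0)) stop("negative counts in decay stack")
  if (dim(counts)[1] != length(bin_centers_ns)) {
    stop("time dimension of counts does not match bin_centers_ns")
  }
  if (any(diff(bin_centers_ns) <= 0)) stop("bin centers must be strictly increasing")
  structure(list(
    counts = counts,
    bin_centers_ns = as.numeric(bin_centers_ns),
    laser_period_ns = as.numeric(laser_period_ns),
    channel = channel,
    harmonic = as.integer(harmonic)
  ), class = "decay_stack")
}

#' @export
print.decay_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("decay_stack (%s): %d bins x %dx%d px, period %.4g ns, %.4g photons\n",
              x$channel, d[1], d[2], d[3], x$laser_period_ns, sum(x$counts)))
  invisible(x)
}

#' Total-intensity image of a decay stack
#'
#' @param stack A `decay_stack`.
#' @return Matrix of per-pixel total photon counts.
#' @export
intensity_image <- function(stack) {
  stopifnot(inherits(stack, "decay_stack"))
  apply(stack$counts, c(2, 3), sum)
}

#' Unit-area wrapped exponential decay shape
#'
#' Evaluates, at the acquisition's bin centers, the density of a
#' single-exponential decay with its infinite tail folded back into one
#' laser period (geometric-series closed form):
#' f(t; tau) = exp(-t / tau) / (tau * (1 - exp(-T / tau))), t in \[0, T).
#' With this wrapping the analytic semicircle phasor is exact at every
#' lifetime up to time-discretization error. Optionally circularly convolved
#' with a Gaussian IRF.
#'
#' @param tau Lifetime in ns (> 0).
#' @param acq An `acquisition_config`.
#' @param irf_sigma_ns IRF sigma override in ns (default from `acq`).
#' @return Numeric vector of per-bin probabilities (sums to 1).
#' @export
decay_shape <- function(tau, acq, irf_sigma_ns = NULL) {
  stopifnot(tau > 0)
  tc <- bin_centers(acq)
  period <- acq$laser_period_ns
  v <- exp(-tc / tau) / (tau * (1 - exp(-period / tau)))
  p <- v / sum(v)  # per-bin photon probability; phasor is scale-invariant
  sig <- irf_sigma_ns %||% acq$irf_sigma_ns
  if (sig > 0) {
    p <- circular_gaussian_blur(p, sig / acq$bin_width_ns)
  }
  p
}

# Circular convolution of a periodic signal with a discrete Gaussian kernel
# (sigma in bins), via FFT. Kernel centered on offset 0 so the decay peak
# spreads symmetrically, as a detection IRF does.
circular_gaussian_blur <- function(p, sigma_bins) {
  n <- length(p)
  off <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-off^2 / (2 * sigma_bins^2))
  k <- k / sum(k)
  out <- Re(stats::fft(stats::fft(p) * stats::fft(k), inverse = TRUE)) / n
  pmax(out, 0)
}
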