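#' Acquisition configuration for synthetic FLIM fields
#'
#' Describes the timing and geometry of a TCSPC acquisition: the laser period,
#' the number of time bins the decay histogram is divided into, the phasor
#' harmonic, the width of the Gaussian instrument response (IRF), a flat
#' background photon rate, and the frame size. The decay histogram always
#' spans exactly one laser period, so the bin width is derived as
#' `laser_period_ns / n_time_bins`.
#'
#' The default timing (12.5 ns period, i.e. an 80 MHz pulsed laser, 256 bins,
#' first harmonic) is a common two-photon FLIM configuration; every value is
#' overridable.
#'
#' @param laser_period_ns Laser repetition period in ns (> 0).
#' @param n_time_bins Number of histogram bins per period (>= 2).
#' @param harmonic Phasor harmonic (integer >= 1).
#' @param irf_sigma_ns Standard deviation of the circular Gaussian IRF in ns
#'   (>= 0; 0 disables IRF convolution).
#' @param background_rate Expected background photons per pixel, spread
#'   uniformly over the laser period (>= 0).
#' @param frame_shape Integer vector `c(rows, cols)` of the field of view.
#' @param seed Optional integer seed recorded with the configuration.
#' @return An object of class `acquisition_config`.
#' @examples
#' acq <- acquisition_config()
#' omega(acq)  # 2 * pi / 12.5
#' @export
acquisition_config <- function(laser_period_ns = 12.5,
                               n_time_bins = 256L,
                               harmonic = 1L,
                               irf_sigma_ns = 0,
                               background_rate = 0,
                               frame_shape = c(128L, 128L),
                               seed = NULL) {
  stopifnot(
    is.numeric(laser_period_ns), length(laser_period_ns) == 1L, laser_period_ns > 0,
    is.numeric(n_time_bins), length(n_time_bins) == 1L, n_time_bins >= 2,
    n_time_bins == as.integer(n_time_bins),
    is.numeric(harmonic), length(harmonic) == 1L, harmonic >= 1,
    harmonic == as.integer(harmonic),
    is.numeric(irf_sigma_ns), irf_sigma_ns >= 0,
    is.numeric(background_rate), background_rate >= 0,
    length(frame_shape) == 2L, all(frame_shape >= 1)
  )
  structure(list(
    laser_period_ns = as.numeric(laser_period_ns),
    n_time_bins = as.integer(n_time_bins),
    bin_width_ns = as.numeric(laser_period_ns) / as.integer(n_time_bins),
    harmonic = as.integer(harmonic),
    irf_sigma_ns = as.numeric(irf_sigma_ns),
    background_rate = as.numeric(background_rate),
    frame_shape = as.integer(frame_shape),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "acquisition_config")
}

#' Angular frequency of the phasor transform
#'
#' @param x An `acquisition_config` or a laser period in ns.
#' @param harmonic Harmonic override (defaults to the configuration's).
#' @return omega = 2 * pi * harmonic / laser_period, in rad/ns.
#' @export
omega <- function(x, harmonic = NULL) {
  if (inherits(x, "acquisition_config")) {
    h <- if (is.null(harmonic)) x$harmonic else harmonic
    2 * pi * h / x$laser_period_ns
  } else {
    h <- if (is.null(harmonic)) 1L else harmonic
    2 * pi * h / x
  }
}

#' Time-bin centers of an acquisition
#'
#' Bin centers are at `(k - 1/2) * bin_width` for k = 1..n_time_bins, so the
#' histogram tiles one full laser period.
#'
#' @param acq An `acquisition_config`.
#' @return Numeric vector of bin-center times in ns.
#' @export
bin_centers <- function(acq) {
  stopifnot(inherits(acq, "acquisition_config"))
  (seq_len(acq$n_time_bins) - 0.5) * acq$bin_width_ns
}

#' @export
print.acquisition_config <- function(x, ...) {
  cat(sprintf(
    "acquisition_config: period %.4g ns, %d bins (%.4g ns), harmonic %d, IRF sigma %.3g ns, frame %dx%d\n",
    x$laser_period_ns, x$n_time_bins, x$bin_width_ns, x$harmonic,
    x$irf_sigma_ns, x$frame_shape[1], x$frame_shape[2]
  ))
  invisible(x)
}

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's RNG afterwards. Keeps generator determinism independent of any
# surrounding set.seed() usage.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
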