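#' Point on the universal semicircle for a single-exponential decay
#'
#' A mono-exponential decay of lifetime tau has phasor coordinates
#' g = 1 / (1 + (omega * tau)^2), s = omega * tau * g, which trace the
#' "universal semicircle" (g - 1/2)^2 + s^2 = 1/4 as tau runs from 0
#' (at (1, 0)) to infinity (at (0, 0)).
#'
#' @param tau Lifetime in ns (>= 0); vectorized.
#' @param omega Angular frequency in rad/ns.
#' @return A matrix with columns `g` and `s` (one row per tau).
#' @export
semicircle_point <- function(tau, omega) {
  if (any(tau < 0)) stop("negative lifetime in semicircle_point()")
  u <- omega * tau
  g <- 1 / (1 + u^2)
  cbind(g = g, s = u * g)
}

#' Phasor of a two-component (free/bound) exponential mixture
#'
#' By linearity of the phasor transform, a mixture contributing a fraction
#' `alpha` of its photons from the bound (long-lifetime) species lies on the
#' chord between the two single-exponential semicircle points:
#' P = alpha * P(tau_bound) + (1 - alpha) * P(tau_free).
#'
#' @param alpha_bound Photon fraction of the bound species, in \[0, 1\].
#' @param tau_bound,tau_free Lifetimes in ns, `tau_bound > tau_free`.
#' @param omega Angular frequency in rad/ns.
#' @return Named numeric vector `c(g, s)`.
#' @export
mixture_phasor <- function(alpha_bound, tau_bound, tau_free, omega) {
  stopifnot(alpha_bound >= 0, alpha_bound <= 1, tau_free > 0, tau_bound > 0)
  pb <- semicircle_point(tau_bound, omega)
  pf <- semicircle_point(tau_free, omega)
  p <- alpha_bound * pb + (1 - alpha_bound) * pf
  c(g = unname(p[1, "g"]), s = unname(p[1, "s"]))
}

#' Phasor transform of a decay stack
#'
#' Computes per-pixel phasor coordinates at the requested harmonic:
#' g = sum_t I(t) cos(n omega t) / sum_t I(t) and
#' s = sum_t I(t) sin(n omega t) / sum_t I(t), with omega = 2 pi / period and
#' t the bin centers. Pixels with zero photons get NA coordinates. An optional
#' calibration (from [calibrate_from_reference()]) rotates the phasor by its
#' phase shift and scales it by its modulation factor.
#'
#' @param stack A `decay_stack` (see [decay_stack()]).
#' @param harmonic Harmonic n >= 1 (defaults to the stack's).
#' @param calibration Optional `phasor_calibration`.
#' @return A `phasor_image`: list with matrices `g`, `s`, `total_counts`,
#'   plus `omega`, `harmonic`, `laser_period_ns` and `channel`.
#' @export
phasor_transform <- function(stack, harmonic = NULL, calibration = NULL) {
  stopifnot(inherits(stack, "decay_stack"))
  n <- as.integer(harmonic %||% stack$harmonic %||% 1L)
  if (n < 1) stop("harmonic must be >= 1")
  tc <- stack$bin_centers_ns
  nt <- length(tc)
  period <- stack$laser_period_ns
  dt <- diff(tc)
  if (nt < 2 || any(abs(dt - dt[1]) > 1e-9 * period) ||
      abs(nt * dt[1] - period) > 1e-6 * period) {
    stop("bin grid does not uniformly span one laser period; phasor normalization invalid")
  }
  om <- 2 * pi / period
  dims <- dim(stack$counts)
  cmat <- matrix(as.numeric(stack$counts), nrow = dims[1])
  cw <- cos(n * om * tc)
  sw <- sin(n * om * tc)
  tot <- colSums(cmat)
  gnum <- crossprod(cmat, cw)[, 1]
  snum <- crossprod(cmat, sw)[, 1]
  g <- ifelse(tot > 0, gnum / tot, NA_real_)
  s <- ifelse(tot > 0, snum / tot, NA_real_)
  if (!is.null(calibration)) {
    stopifnot(inherits(calibration, "phasor_calibration"))
    z <- complex(real = g, imaginary = s) *
      calibration$modulation_factor *
      exp(1i * calibration$phase_shift)
    g <- Re(z)
    s <- Im(z)
  }
  structure(list(
    g = matrix(g, dims[2], dims[3]),
    s = matrix(s, dims[2], dims[3]),
    total_counts = matrix(tot, dims[2], dims[3]),
    omega = n * om,
    harmonic = n,
    laser_period_ns = period,
    channel = stack$channel
  ), class = "phasor_image")
}

#' @export
print.phasor_image <- function(x, ...) {
  cat(sprintf(
    "phasor_image: %dx%d px, harmonic %d (omega %.5g rad/ns), channel %s, %.3g photons\n",
    nrow(x$g), ncol(x$g), x$harmonic, x$omega, x$channel, sum(x$total_counts)
  ))
  invisible(x)
}

#' Phasor calibration against a reference fluorophore
#'
#' The pooled phasor of a reference decay with known single-exponential
#' lifetime `tau_ref_ns` is mapped onto its theoretical semicircle point;
#' the returned phase shift and modulation factor correct the instrument
#' response (IRF) and timing offsets of subsequent measurements. Applying
#' the calibration to the reference itself lands it back on the semicircle.
#'
#' Note the correction is a fixed rotation/scaling: applying it twice
#' over-corrects (calibration is not idempotent).
#'
#' @param reference A `decay_stack` of the reference measurement.
#' @param tau_ref_ns Known reference lifetime in ns (> 0).
#' @param harmonic Harmonic at which to calibrate.
#' @return A `phasor_calibration` with `phase_shift` (radians) and
#'   `modulation_factor` (> 0).
#' @export
calibrate_from_reference <- function(reference, tau_ref_ns, harmonic = NULL) {
  stopifnot(inherits(reference, "decay_stack"), tau_ref_ns > 0)
  pooled <- pooled_decay(reference)
  if (sum(pooled$counts) <= 0) stop("zero-count reference decay; cannot calibrate")
  ph <- phasor_transform(pooled, harmonic = harmonic)
  m <- complex(real = ph$g[1, 1], imaginary = ph$s[1, 1])
  th_gs <- semicircle_point(tau_ref_ns, ph$omega)
  th <- complex(real = th_gs[1, "g"], imaginary = th_gs[1, "s"])
  structure(list(
    phase_shift = Arg(th / m),
    modulation_factor = Mod(th) / Mod(m),
    tau_ref_ns = tau_ref_ns,
    harmonic = ph$harmonic
  ), class = "phasor_calibration")
}

#' Pool a decay stack over a pixel set into a 1x1 stack
#'
#' @param stack A `decay_stack`.
#' @param pixels Optional integer indices (into the frame, column-major) to
#'   pool; default all pixels.
#' @return A `decay_stack` with a single pixel holding the summed decay.
#' @export
pooled_decay <- function(stack, pixels = NULL) {
  dims <- dim(stack$counts)
  cmat <- matrix(as.numeric(stack$counts), nrow = dims[1])
  if (!is.null(pixels)) cmat <- cmat[, pixels, drop = FALSE]
  decay_stack(array(rowSums(cmat), dim = c(dims[1], 1L, 1L)),
              bin_centers_ns = stack$bin_centers_ns,
              laser_period_ns = stack$laser_period_ns,
              channel = stack$channel,
              harmonic = stack$harmonic)
}

#' Photon-weighted cell-average phasor
#'
#' Averages (g, s) over a set of pixels, weighting each pixel by its photon
#' count. By linearity of the phasor transform this equals the phasor of the
#' pooled decay of those pixels.
#'
#' @param phasor A `phasor_image`.
#' @param pixels Integer pixel indices (column-major into the frame), or a
#'   logical matrix of the frame shape.
#' @param min_counts Pixels with fewer total photons are excluded from the
#'   average (default 0; the per-cell extractor uses its own threshold).
#' @return Named numeric vector `c(g, s)` with attribute `total_counts`.
#' @export
cell_phasor <- function(phasor, pixels, min_counts = 0) {
  stopifnot(inherits(phasor, "phasor_image"))
  if (is.matrix(pixels) && is.logical(pixels)) pixels <- which(pixels)
  if (length(pixels) == 0L) stop("empty pixel set in cell_phasor()")
  w <- phasor$total_counts[pixels]
  keep <- w >= min_counts & w > 0 & is.finite(phasor$g[pixels])
  w <- w[keep]
  if (length(w) == 0L || sum(w) <= 0) {
    stop("pixel set has no photons above threshold in cell_phasor()")
  }
  g <- sum(phasor$g[pixels][keep] * w) / sum(w)
  s <- sum(phasor$s[pixels][keep] * w) / sum(w)
  structure(c(g = g, s = s), total_counts = sum(w))
}

#' Two-component decomposition with a fixed free lifetime
#'
#' Resolves a cell phasor into free and enzyme-bound NAD(P)H components.
#' With tau_free fixed, the free-species point P_f lies on the universal
#' semicircle; the line through P_f and the cell phasor intersects the circle
#' (g - 1/2)^2 + s^2 = 1/4 in exactly one further point P_b, which identifies
#' the bound species: tau_bound = s_b / (omega * g_b). The bound photon
#' fraction follows from linear phasor mixing:
#' alpha_bound = |P_cell - P_f| / |P_b - P_f|.
#'
#' The quadratic is solved in the chord parameterization anchored at P_f, so
#' P_f is an exact root and the second root is unique. Cell phasors that fall
#' outside the semicircle (shot noise) are first projected radially toward
#' (1/2, 0) onto the boundary; alpha values outside \[0, 1\] are clipped. Both
#' conditions set `residual_flag`.
#'
#' Within `free_tol` of the free-species point the decomposition is
#' ill-conditioned (any chord direction fits the data equally well), so such
#' cells are reported as pure free with an undefined bound lifetime rather
#' than an arbitrary one; the default is chosen above the phasor shot noise
#' of a well-exposed cell (1e4-1e5 photons).
#'
#' @param cell_gs Numeric `c(g, s)` of the cell phasor.
#' @param tau_free Free-NAD(P)H lifetime in ns (default 0.45).
#' @param omega Angular frequency in rad/ns.
#' @param free_tol Distance below which the cell phasor is treated as pure
#'   free.
#' @param tol Geometric tolerance for root selection and projection.
#' @return A list of class `two_component_fit`: `alpha_bound`, `tau_bound`
#'   (NA when undefined), `tau_free`, `residual_flag`, `valid`.
#' @export
decompose_fixed_free <- function(cell_gs, tau_free = 0.45, omega,
                                 free_tol = 5e-3, tol = 1e-9) {
  stopifnot(tau_free > 0, is.numeric(omega), omega > 0)
  g <- unname(cell_gs[1])
  s <- unname(cell_gs[2])
  if (!is.finite(g) || !is.finite(s)) stop("non-finite cell phasor")
  pf <- semicircle_point(tau_free, omega)
  pf <- c(pf[1, "g"], pf[1, "s"])
  flag <- FALSE
  # project out-of-semicircle points radially toward the circle center (1/2, 0)
  rad <- sqrt((g - 0.5)^2 + s^2)
  if (rad > 0.5 + tol) {
    g <- 0.5 + (g - 0.5) * 0.5 / rad
    s <- s * 0.5 / rad
    flag <- TRUE
  }
  d <- c(g, s) - pf
  dist_cell <- sqrt(sum(d^2))
  out <- function(alpha, tau_b, flag, valid) {
    structure(list(alpha_bound = unname(alpha), tau_bound = unname(tau_b),
                   tau_free = tau_free, residual_flag = flag, valid = valid),
              class = "two_component_fit")
  }
  if (dist_cell < free_tol) {
    return(out(0, NA_real_, flag, TRUE))  # pure free: bound lifetime undefined
  }
  # chord parameterization P(u) = P_f + u d; P_f on the circle makes u = 0 a
  # root, so the other intersection is u* = -b/a with no root-selection step
  a <- sum(d^2)
  b <- 2 * sum(d * (pf - c(0.5, 0)))
  ustar <- -b / a
  if (ustar <= tol) {
    return(out(NA_real_, NA_real_, TRUE, FALSE))  # chord leaves circle on the wrong side
  }
  pb <- pf + ustar * d
  if (pb[2] <= 0 || pb[1] <= 0) {
    return(out(NA_real_, NA_real_, TRUE, FALSE))
  }
  tau_b <- pb[2] / (omega * pb[1])
  if (tau_b <= tau_free) {
    return(out(NA_real_, NA_real_, TRUE, FALSE))
  }
  alpha <- 1 / ustar  # == |P_cell - P_f| / |P_b - P_f|
  if (alpha > 1) {
    alpha <- 1
    flag <- TRUE
  }
  out(alpha, tau_b, flag, TRUE)
}

#' Lifetime trajectory fit through a phasor cloud
#'
#' Fits a weighted total-least-squares line through a cloud of (g, s) points
#' (the principal axis of their weighted covariance) and intersects it with
#' the universal semicircle. The two intersections are reported as the short
#' (free) and long (bound) lifetime of the underlying two-component mixture.
#'
#' @param g,s Numeric vectors of phasor coordinates (>= 10 points).
#' @param omega Angular frequency in rad/ns.
#' @param weights Optional non-negative weights (e.g. photon counts).
#' @return List with `tau_free_est`, `tau_bound_est` (ns), the line
#'   (`point`, `direction`) and the two intersection points.
#' @export
fit_trajectory <- function(g, s, omega, weights = NULL) {
  stopifnot(is.numeric(omega), omega > 0)
  keep <- is.finite(g) & is.finite(s)
  g <- g[keep]
  s <- s[keep]
  if (is.null(weights)) weights <- rep(1, length(g)) else weights <- weights[keep]
  if (length(g) < 10) stop("need at least 10 finite phasor points for a trajectory fit")
  if (any(weights < 0) || sum(weights) <= 0) stop("invalid weights")
  w <- weights / sum(weights)
  mu <- c(sum(w * g), sum(w * s))
  dg <- g - mu[1]
  ds <- s - mu[2]
  cv <- matrix(c(sum(w * dg * dg), sum(w * dg * ds),
                 sum(w * dg * ds), sum(w * ds * ds)), 2, 2)
  if (sum(diag(cv)) < 1e-14) stop("degenerate phasor cloud: all points identical")
  ev <- eigen(cv, symmetric = TRUE)
  dir <- ev$vectors[, 1]
  # intersect mu + t * dir with (g - 1/2)^2 + s^2 = 1/4
  m <- mu - c(0.5, 0)
  b <- 2 * sum(dir * m)
  cc <- sum(m^2) - 0.25
  disc <- b^2 - 4 * cc
  if (disc <= 0) stop("trajectory line does not intersect the universal semicircle")
  t1 <- (-b - sqrt(disc)) / 2
  t2 <- (-b + sqrt(disc)) / 2
  p1 <- mu + t1 * dir
  p2 <- mu + t2 * dir
  if (p1[1] <= 0 || p2[1] <= 0) {
    stop("trajectory intersects the semicircle at a non-physical point (g <= 0)")
  }
  taus <- sort(c(p1[2] / (omega * p1[1]), p2[2] / (omega * p2[1])))
  list(tau_free_est = taus[1], tau_bound_est = taus[2],
       point = mu, direction = dir,
       intersections = rbind(p1, p2))
}

#' Median filtering of a phasor image
#'
#' Component-wise median filtering of the g and s maps over a square
#' neighborhood of half-width `radius`, applied `passes` times. Pixels below
#' `min_counts` photons (or with undefined phasors) are excluded both as
#' filter targets and as neighbors. A standard phasor-denoising step: it
#' tightens the pixel cloud without biasing photon-weighted cell averages
#' appreciably.
#'
#' @param phasor A `phasor_image`.
#' @param radius Neighborhood half-width in pixels (0 = identity).
#' @param passes Number of filter passes.
#' @param min_counts Photon threshold for participating pixels.
#' @return A filtered `phasor_image`.
#' @export
phasor_median_filter <- function(phasor, radius = 1L, passes = 1L, min_counts = 1) {
  stopifnot(inherits(phasor, "phasor_image"), radius >= 0, passes >= 0)
  if (radius == 0L || passes == 0L) return(phasor)
  valid <- phasor$total_counts >= min_counts & is.finite(phasor$g)
  filt <- function(m) {
    nr <- nrow(m)
    nc <- ncol(m)
    offs <- expand.grid(dr = -radius:radius, dc = -radius:radius)
    stackv <- array(NA_real_, dim = c(nr, nc, nrow(offs)))
    mm <- m
    mm[!valid] <- NA_real_
    for (k in seq_len(nrow(offs))) {
      dr <- offs$dr[k]
      dc <- offs$dc[k]
      src_r <- seq_len(nr) + dr
      src_c <- seq_len(nc) + dc
      ok_r <- src_r >= 1 & src_r <= nr
      ok_c <- src_c >= 1 & src_c <= nc
      stackv[ok_r, ok_c, k] <- mm[src_r[ok_r], src_c[ok_c]]
    }
    out <- apply(stackv, c(1, 2), stats::median, na.rm = TRUE)
    out[!valid] <- m[!valid]
    out[is.nan(out)] <- m[is.nan(out)]
    out
  }
  for (i in seq_len(passes)) {
    phasor$g <- filt(phasor$g)
    phasor$s <- filt(phasor$s)
  }
  phasor
}
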