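#' Population specification for the synthetic generator
#'
#' Describes one cell population as per-parameter normal distributions
#' (mean and standard deviation) for every ground-truth cell parameter, plus
#' the number of cells to draw. Sampled values are clipped to each
#' parameter's valid range (see [sample_population()]).
#'
#' The shipped presets (see [load_population_presets()]) encode the
#' qualitative ordering of the hematopoietic populations: HSCs with low
#' optical redox ratio and high alpha_bound, tau_bound, edge enrichment and
#' polarity; differentiated cells the reverse. Only tau_free (0.45 ns) and
#' the HSC tau_bound anchor (3.56 ns) are measurement-anchored; the other
#' preset values are plausible defaults, not measurements.
#'
#' @param name Population label (e.g. "HSC", "MPP").
#' @param n_cells Number of cells (>= 0).
#' @param means Named list overriding default parameter means. Parameters:
#'   `radius_px`, `alpha_bound`, `tau_bound_ns`, `tau_free_ns`,
#'   `total_photons`, `orr`, `edge_enrichment`, `polarity_offset`.
#' @param sds Named list overriding default parameter standard deviations.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(name, n_cells,
                            means = list(), sds = list()) {
  def_means <- list(radius_px = 6, alpha_bound = 0.65, tau_bound_ns = 3.0,
                    tau_free_ns = 0.45, total_photons = 1e4, orr = 0.3,
                    edge_enrichment = 1.0, polarity_offset = 0.1)
  def_sds <- list(radius_px = 0.5, alpha_bound = 0.03, tau_bound_ns = 0.12,
                  tau_free_ns = 0, total_photons = 1e3, orr = 0.04,
                  edge_enrichment = 0.1, polarity_offset = 0.04)
  bad <- setdiff(c(names(means), names(sds)), names(def_means))
  if (length(bad)) stop("unknown population parameters: ", paste(bad, collapse = ", "))
  m <- utils::modifyList(def_means, means)
  s <- utils::modifyList(def_sds, sds)
  if (any(unlist(s) < 0)) stop("parameter dispersions must be >= 0")
  if (n_cells < 0) stop("n_cells must be >= 0")
  # configuration errors: a mean outside its invariant range cannot yield a
  # valid population even after clipping
  if (m$radius_px < 2) stop("radius_px mean must be >= 2 px")
  if (m$alpha_bound < 0 || m$alpha_bound > 1) stop("alpha_bound mean must be in [0, 1]")
  if (m$tau_free_ns <= 0) stop("tau_free_ns mean must be > 0")
  if (m$tau_bound_ns <= m$tau_free_ns) stop("tau_bound_ns mean must exceed tau_free_ns")
  if (m$orr < 0 || m$orr >= 1) stop("orr mean must be in [0, 1)")
  if (m$edge_enrichment < 0) stop("edge_enrichment mean must be >= 0")
  if (m$polarity_offset < 0 || m$polarity_offset >= 1) {
    stop("polarity_offset mean must be in [0, 1)")
  }
  if (m$total_photons <= 0) stop("total_photons mean must be > 0")
  structure(list(name = as.character(name), n_cells = as.integer(n_cells),
                 means = m, sds = s),
            class = "population_spec")
}

#' Draw ground-truth cells from a population specification
#'
#' Each cell's parameters are drawn independently from the specification's
#' normal distributions and clipped to their invariant ranges
#' (alpha_bound in \[0, 1\], tau_bound > tau_free, radius >= 2 px,
#' orr in \[0, 0.95\], polarity_offset in \[0, 0.95\), edge_enrichment >= 0,
#' total_photons >= 1). Cell centers are placed by rejection sampling so
#' that no two cell disks overlap and every disk fits inside the frame.
#' Deterministic given `seed`.
#'
#' @param spec A `population_spec`.
#' @param frame_shape Integer `c(rows, cols)` of the target field.
#' @param seed Integer seed.
#' @param min_gap Minimum background gap between cell boundaries, in pixels.
#' @param id_offset Added to 1..n cell ids (for multi-population fields).
#' @return A `data.frame` of cell truths, one row per cell, with columns
#'   `cell_id`, `population`, `center_row`, `center_col`, `radius_px`,
#'   `alpha_bound_true`, `tau_bound_true`, `tau_free_true`, `total_photons`,
#'   `orr_true`, `edge_enrichment`, `polarity_offset`, `polarity_angle`.
#' @export
sample_population <- function(spec, frame_shape, seed, min_gap = 2, id_offset = 0L) {
  stopifnot(inherits(spec, "population_spec"), length(frame_shape) == 2L)
  n <- spec$n_cells
  empty <- data.frame(
    cell_id = integer(0), population = character(0),
    center_row = numeric(0), center_col = numeric(0), radius_px = numeric(0),
    alpha_bound_true = numeric(0), tau_bound_true = numeric(0),
    tau_free_true = numeric(0), total_photons = numeric(0),
    orr_true = numeric(0), edge_enrichment = numeric(0),
    polarity_offset = numeric(0), polarity_angle = numeric(0),
    stringsAsFactors = FALSE
  )
  if (n == 0L) return(empty)
  m <- spec$means
  s <- spec$sds
  with_seed(seed, {
    draw <- function(p, lo, hi) {
      pmin(pmax(stats::rnorm(n, m[[p]], s[[p]]), lo), hi)
    }
    radius <- draw("radius_px", 2, Inf)
    tau_free <- draw("tau_free_ns", 0.05, Inf)
    tau_bound <- pmax(draw("tau_bound_ns", 0, Inf), tau_free + 0.05)
    truths <- data.frame(
      cell_id = seq_len(n) + as.integer(id_offset),
      population = spec$name,
      center_row = NA_real_, center_col = NA_real_,
      radius_px = radius,
      alpha_bound_true = draw("alpha_bound", 0, 1),
      tau_bound_true = tau_bound,
      tau_free_true = tau_free,
      total_photons = draw("total_photons", 1, Inf),
      orr_true = draw("orr", 0, 0.95),
      edge_enrichment = draw("edge_enrichment", 0, Inf),
      polarity_offset = draw("polarity_offset", 0, 0.95),
      polarity_angle = stats::runif(n, 0, 2 * pi),
      stringsAsFactors = FALSE
    )
    # rejection-sample non-overlapping disk centers inside the frame
    placed_r <- numeric(0)
    placed_c <- numeric(0)
    for (i in seq_len(n)) {
      r <- truths$radius_px[i]
      lo_r <- r + 1
      hi_r <- frame_shape[1] - r
      hi_c <- frame_shape[2] - r
      if (hi_r <= lo_r || hi_c <= lo_r) {
        stop("frame too small for cell of radius ", round(r, 1))
      }
      ok <- FALSE
      for (try in seq_len(20000L)) {
        cr <- stats::runif(1, lo_r, hi_r)
        cc <- stats::runif(1, lo_r, hi_c)
        if (i == 1L || all(sqrt((placed_r - cr)^2 + (placed_c - cc)^2) >=
                           truths$radius_px[seq_len(i - 1)] + r + min_gap)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("could not place ", n, " non-overlapping cells in a ",
                    frame_shape[1], "x", frame_shape[2], " frame")
      placed_r[i] <- cr
      placed_c[i] <- cc
    }
    truths$center_row <- placed_r
    truths$center_col <- placed_c
    truths
  })
}

#' Perturbation model for paired treatment experiments
#'
#' Linear response of the bound-NAD(P)H lifetime to a treatment (e.g. LDH
#' inhibition): delta tau_bound = intercept + slope * tau_bound_initial +
#' noise, so that the magnitude of the induced decrease correlates with the
#' initial lifetime.
#'
#' @param intercept Intercept a, in ns.
#' @param slope Dimensionless slope b.
#' @param noise_sd Standard deviation of the added Gaussian noise, in ns.
#' @return An object of class `perturbation_model`.
#' @export
perturbation_model <- function(intercept = 0, slope = 0, noise_sd = 0) {
  stopifnot(is.numeric(intercept), is.numeric(slope), is.numeric(noise_sd),
            noise_sd >= 0)
  structure(list(intercept = intercept, slope = slope, noise_sd = noise_sd),
            class = "perturbation_model")
}

#' Apply a treatment perturbation to ground-truth cells
#'
#' Produces the post-treatment truth table: per cell,
#' `tau_bound_post = tau_bound + intercept + slope * tau_bound + noise`,
#' clipped to stay above tau_free. Cell ids are preserved so pre/post tables
#' pair by id.
#'
#' @param truths Truth table from [sample_population()].
#' @param model A `perturbation_model`.
#' @param seed Integer seed for the noise draw.
#' @return The truth table with updated `tau_bound_true`.
#' @export
apply_perturbation <- function(truths, model, seed = 1L) {
  stopifnot(inherits(model, "perturbation_model"))
  n <- nrow(truths)
  if (n == 0L) return(truths)
  with_seed(seed, {
    eps <- if (model$noise_sd > 0) stats::rnorm(n, 0, model$noise_sd) else numeric(n)
    tau_post <- truths$tau_bound_true + model$intercept +
      model$slope * truths$tau_bound_true + eps
    truths$tau_bound_true <- pmax(tau_post, truths$tau_free_true + 1e-3)
    truths
  })
}

#' Render a synthetic FLIM field from ground-truth cells
#'
#' Builds, for every pixel of every cell, the expected NAD(P)H decay
#' `lambda_p(t) = A_p * (alpha * f(t; tau_bound) + (1 - alpha) * f(t; tau_free))
#' + background`, where f is the unit-area laser-period-wrapped exponential of
#' [decay_shape()] (optionally IRF-convolved), and draws observed counts as
#' Poisson. The pixel amplitude A_p is a uniform disk profile times the
#' `edge_enrichment` factor on the peripheral band (pixels farther than
#' `(1 - band_fraction) * radius` from the center) times a clipped linear
#' intensity ramp whose steepness is solved numerically so the noiseless
#' intensity centroid is displaced by `polarity_offset * r_eq` from the
#' geometric centroid. The FAD channel is intensity-only: pixel intensities
#' are `orr / (1 - orr)` times the expected NAD(P)H intensity, so the
#' noiseless per-cell mean of FAD / (FAD + NAD(P)H) equals `orr_true`.
#'
#' @param truths Truth table from [sample_population()] (possibly several
#'   populations row-bound together; cell_ids must be unique).
#' @param acq An `acquisition_config`.
#' @param seed Integer seed for the Poisson draws.
#' @param band_fraction Peripheral band width as a fraction of the radius.
#' @param fad_noise Add Poisson noise to the FAD intensity image?
#' @return A list of class `flim_field`: `nadph` (`decay_stack`), `fad`
#'   (matrix), `mask` (integer label matrix), `truth` (the input table),
#'   `expected_nadph` (noiseless amplitude image), `acq`, `band_fraction`.
#' @export
render_field <- function(truths, acq, seed = 1L, band_fraction = 0.3,
                         fad_noise = TRUE) {
  stopifnot(inherits(acq, "acquisition_config"), nrow(truths) >= 0)
  if (anyDuplicated(truths$cell_id)) stop("cell ids must be unique in a field")
  nr <- acq$frame_shape[1]
  nc <- acq$frame_shape[2]
  nt <- acq$n_time_bins
  mask <- matrix(0L, nr, nc)
  amp <- matrix(0, nr, nc)
  rowg <- matrix(rep(seq_len(nr), nc), nr, nc)
  colg <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  cmat <- matrix(0, nt, nr * nc)  # time x pixel (column-major frame index)
  fad <- matrix(0, nr, nc)
  with_seed(seed, {
    for (i in seq_len(nrow(truths))) {
      tr <- truths[i, ]
      if (tr$center_row - tr$radius_px < 0.5 || tr$center_row + tr$radius_px > nr + 0.5 ||
          tr$center_col - tr$radius_px < 0.5 || tr$center_col + tr$radius_px > nc + 0.5) {
        stop("cell ", tr$cell_id, " overlaps the frame boundary")
      }
      d2 <- (rowg - tr$center_row)^2 + (colg - tr$center_col)^2
      disk <- d2 <= tr$radius_px^2
      if (any(mask[disk] != 0L)) stop("cell masks overlap in the field")
      mask[disk] <- tr$cell_id
      px <- which(disk)
      a <- cell_amplitude_profile(
        rows = rowg[px], cols = colg[px],
        center = c(tr$center_row, tr$center_col), radius = tr$radius_px,
        edge_enrichment = tr$edge_enrichment,
        polarity_offset = tr$polarity_offset,
        polarity_angle = tr$polarity_angle,
        band_fraction = band_fraction
      )
      a <- a / sum(a) * tr$total_photons  # photon conservation per cell
      amp[px] <- a
      shp <- tr$alpha_bound_true * decay_shape(tr$tau_bound_true, acq) +
        (1 - tr$alpha_bound_true) * decay_shape(tr$tau_free_true, acq)
      rate <- outer(shp, a)  # nt x npx expected counts
      if (any(rate < 0)) stop("negative expected rates")
      cmat[, px] <- cmat[, px] + stats::rpois(length(rate), rate)
      fad[px] <- tr$orr_true / (1 - tr$orr_true) * a
    }
    if (acq$background_rate > 0) {
      cmat <- cmat + stats::rpois(length(cmat), acq$background_rate / nt)
    }
    if (fad_noise) fad <- matrix(stats::rpois(length(fad), fad), nr, nc)
  })
  counts <- array(cmat, dim = c(nt, nr, nc))
  structure(list(
    nadph = decay_stack(counts, bin_centers(acq), acq$laser_period_ns,
                        channel = "NADPH", harmonic = acq$harmonic),
    fad = fad,
    mask = mask,
    truth = truths,
    expected_nadph = amp,
    acq = acq,
    band_fraction = band_fraction
  ), class = "flim_field")
}

# Noiseless per-pixel amplitude of one disk cell: edge band factor times a
# clipped linear ramp. The ramp steepness beta is solved so the discrete
# intensity centroid is displaced from the pixel centroid by exactly
# polarity_offset * r_eq (clipped weights make the analytic beta = 4 * offset
# only approximate, hence the root solve).
cell_amplitude_profile <- function(rows, cols, center, radius, edge_enrichment,
                                   polarity_offset, polarity_angle,
                                   band_fraction) {
  dist_c <- sqrt((rows - center[1])^2 + (cols - center[2])^2)
  base <- rep(1, length(rows))
  base[dist_c > (1 - band_fraction) * radius] <- edge_enrichment
  if (sum(base) <= 0) stop("edge_enrichment produced an all-zero cell profile")
  r_eq <- sqrt(length(rows) / pi)
  gc <- c(mean(rows), mean(cols))
  proj <- (rows - gc[1]) * cos(polarity_angle) + (cols - gc[2]) * sin(polarity_angle)
  pol_of <- function(beta) {
    w <- base * pmax(0, 1 + beta * proj / radius)
    if (sum(w) <= 0) return(Inf)
    mc <- c(sum(w * rows), sum(w * cols)) / sum(w)
    sqrt(sum((mc - gc)^2)) / r_eq
  }
  if (polarity_offset <= 1e-8) return(base)
  hi <- 4
  while (pol_of(hi) < polarity_offset && hi < 1024) hi <- hi * 2
  if (pol_of(hi) < polarity_offset) {
    beta <- hi  # requested polarity unreachable for this geometry; saturate
  } else {
    beta <- stats::uniroot(function(b) pol_of(b) - polarity_offset,
                           c(0, hi), tol = 1e-6)$root
  }
  base * pmax(0, 1 + beta * proj / radius)
}
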