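#' Per-cell optical redox ratio
#'
#' The optical redox ratio ORR = FAD / (FAD + NAD(P)H) is computed per pixel
#' and averaged over each cell's valid pixels; pixels whose summed intensity
#' falls below `sum_threshold` are excluded. Cells with no valid pixel get
#' `NA`.
#'
#' @param fad,nadph Co-registered intensity matrices.
#' @param mask Integer label matrix (0 = background).
#' @param sum_threshold Minimum FAD + NAD(P)H intensity for a pixel to count.
#' @return `data.frame` with `cell_id` and `orr`.
#' @export
compute_orr <- function(fad, nadph, mask, sum_threshold = 0) {
  if (!all(dim(fad) == dim(nadph)) || !all(dim(fad) == dim(mask))) {
    stop("fad, nadph and mask shapes differ")
  }
  ids <- sort(setdiff(unique(as.integer(mask)), 0L))
  orr <- vapply(ids, function(id) {
    px <- which(mask == id)
    tot <- fad[px] + nadph[px]
    ok <- tot > sum_threshold
    if (!any(ok)) return(NA_real_)
    mean(fad[px][ok] / tot[ok])
  }, numeric(1))
  data.frame(cell_id = ids, orr = orr)
}

#' Edge-to-center intensity ratio of one cell
#'
#' The cell mask is split into a "center" (mask eroded by
#' `d = round(band_fraction * r_eq)` pixels, with `r_eq = sqrt(area / pi)`)
#' and the complementary peripheral "edge" band; the statistic is the mean
#' edge intensity over the mean center intensity. A ratio above 1 indicates
#' peripheral NAD(P)H accumulation. If the erosion empties the center, the
#' single most interior pixel (maximum distance transform) is used instead.
#'
#' @param img Intensity matrix.
#' @param pixels Integer (column-major) pixel indices of the cell, or a
#'   logical matrix.
#' @param band_fraction Band width as a fraction of the equivalent radius.
#' @return Ratio, or `NA` (with attribute `flag = "zero_center"`) when the
#'   center mean is zero.
#' @export
edge_center_ratio <- function(img, pixels, band_fraction = 0.3) {
  if (is.matrix(pixels) && is.logical(pixels)) pixels <- which(pixels)
  if (length(pixels) == 0L) stop("empty cell pixel set")
  area <- length(pixels)
  r_eq <- sqrt(area / pi)
  d <- round(band_fraction * r_eq)
  m <- matrix(0, nrow(img), ncol(img))
  m[pixels] <- 1
  dm <- as.matrix(EBImage::distmap(EBImage::Image(m)))
  center <- pixels[dm[pixels] > d]
  if (length(center) == 0L) {
    center <- pixels[which.max(dm[pixels])]
  }
  edge <- setdiff(pixels, center)
  if (length(edge) == 0L) return(NA_real_)
  ce <- mean(img[center])
  if (ce == 0) return(structure(NA_real_, flag = "zero_center"))
  mean(img[edge]) / ce
}

#' Intensity polarity of one cell
#'
#' Polarity is the distance between the cell's intensity-weighted centroid
#' ("mass center") and its unweighted geometric centroid, normalized by the
#' equivalent radius `r_eq = sqrt(area / pi)`. A uniform cell has polarity 0;
#' a cell with all its signal at the boundary approaches 1.
#'
#' @param img Intensity matrix.
#' @param pixels Integer (column-major) pixel indices of the cell, or a
#'   logical matrix.
#' @return Non-negative polarity, or `NA` when the total intensity is zero.
#' @export
polarity <- function(img, pixels) {
  if (is.matrix(pixels) && is.logical(pixels)) pixels <- which(pixels)
  if (length(pixels) == 0L) stop("empty cell pixel set")
  nr <- nrow(img)
  rr <- ((pixels - 1L) %% nr) + 1L
  cc <- ((pixels - 1L) %/% nr) + 1L
  w <- img[pixels]
  if (sum(w) <= 0) return(NA_real_)
  gc <- c(mean(rr), mean(cc))
  mc <- c(sum(w * rr), sum(w * cc)) / sum(w)
  sqrt(sum((mc - gc)^2)) / sqrt(length(pixels) / pi)
}

#' Extract the five metabolic optical biomarkers per cell
#'
#' Runs the full per-cell feature chain on one field: the NAD(P)H decay stack
#' is phasor-transformed; each cell's photon-weighted pooled phasor is
#' decomposed against the fixed free lifetime into (alpha_bound, tau_bound);
#' the optical redox ratio, edge/center intensity ratio and polarity are
#' computed from the intensity images. Missing values (e.g. tau_bound of a
#' pure-free cell) are propagated as `NA`, never dropped.
#'
#' @param decay NAD(P)H `decay_stack`.
#' @param fad FAD intensity matrix.
#' @param mask Integer label matrix.
#' @param tau_free Fixed free-NAD(P)H lifetime in ns.
#' @param band_fraction Edge-band fraction for [edge_center_ratio()].
#' @param count_threshold Minimum photons for a pixel to enter the pooled
#'   cell phasor.
#' @param orr_sum_threshold Pixel-intensity-sum threshold for [compute_orr()].
#' @param calibration Optional `phasor_calibration`.
#' @param truth Optional truth/annotation table with `cell_id` plus any of
#'   `population`, `timepoint`, `hoxb5` to carry into the output.
#' @param min_area Cells smaller than this are reported with `NA` features.
#' @return `data.frame` with the fixed columns `cell_id`, `population`,
#'   `orr`, `alpha_bound`, `tau_bound_ns`, `edge_center_ratio`, `polarity`,
#'   `area_px`, `mean_nadph`, `mean_fad`, `timepoint`, `hoxb5`, ordered by
#'   `cell_id`.
#' @export
extract_mob_table <- function(decay, fad, mask, tau_free = 0.45,
                              band_fraction = 0.3, count_threshold = 30,
                              orr_sum_threshold = 0, calibration = NULL,
                              truth = NULL, min_area = 4L) {
  stopifnot(inherits(decay, "decay_stack"))
  dims <- dim(decay$counts)
  if (!all(dims[2:3] == dim(mask)) || !all(dim(fad) == dim(mask))) {
    stop("decay stack, FAD image and mask shapes differ")
  }
  phasor <- phasor_transform(decay, calibration = calibration)
  nadph <- intensity_image(decay)
  ids <- sort(setdiff(unique(as.integer(mask)), 0L))
  orr_tab <- compute_orr(fad, nadph, mask, sum_threshold = orr_sum_threshold)
  rows <- lapply(ids, function(id) {
    px <- which(mask == id)
    area <- length(px)
    alpha <- tau_b <- ec <- pol <- NA_real_
    if (area >= min_area) {
      gs <- tryCatch(cell_phasor(phasor, px, min_counts = count_threshold),
                     error = function(e) NULL)
      if (!is.null(gs)) {
        fit <- decompose_fixed_free(gs, tau_free = tau_free, omega = phasor$omega)
        alpha <- fit$alpha_bound
        tau_b <- fit$tau_bound
      }
      ec <- as.numeric(edge_center_ratio(nadph, px, band_fraction = band_fraction))
      pol <- polarity(nadph, px)
    }
    data.frame(
      cell_id = id,
      orr = orr_tab$orr[match(id, orr_tab$cell_id)],
      alpha_bound = alpha,
      tau_bound_ns = tau_b,
      edge_center_ratio = ec,
      polarity = pol,
      area_px = area,
      mean_nadph = mean(nadph[px]),
      mean_fad = mean(fad[px])
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(cell_id = integer(0), orr = numeric(0),
                      alpha_bound = numeric(0), tau_bound_ns = numeric(0),
                      edge_center_ratio = numeric(0), polarity = numeric(0),
                      area_px = integer(0), mean_nadph = numeric(0),
                      mean_fad = numeric(0))
  }
  ann <- function(col) {
    if (!is.null(truth) && col %in% names(truth)) {
      truth[[col]][match(out$cell_id, truth$cell_id)]
    } else {
      rep(NA, nrow(out))
    }
  }
  out$population <- as.character(ann("population"))
  out$timepoint <- ann("timepoint")
  out$hoxb5 <- ann("hoxb5")
  out <- out[order(out$cell_id),
             c("cell_id", "population", "orr", "alpha_bound", "tau_bound_ns",
               "edge_center_ratio", "polarity", "area_px", "mean_nadph",
               "mean_fad", "timepoint", "hoxb5")]
  rownames(out) <- NULL
  out
}

#' Extract the MOB table directly from a rendered synthetic field
#'
#' Convenience wrapper using the field's ground-truth mask and annotations.
#'
#' @param field A `flim_field` from [render_field()].
#' @param ... Passed to [extract_mob_table()].
#' @return See [extract_mob_table()].
#' @export
extract_mob_field <- function(field, ...) {
  stopifnot(inherits(field, "flim_field"))
  extract_mob_table(field$nadph, field$fad, field$mask, truth = field$truth, ...)
}

#' Paired pre/post comparison of tau_bound
#'
#' Pairs two MOB tables by `cell_id`, computes per-cell
#' `delta = tau_bound_post - tau_bound_pre`, and regresses delta on the
#' initial tau_bound (ordinary least squares), as in paired drug-treatment
#' FLIM experiments where the induced lifetime drop scales with the initial
#' lifetime.
#'
#' @param pre,post MOB tables sharing cell ids (columns `cell_id`,
#'   `tau_bound_ns`).
#' @return List with `table` (cell_id, tau_pre, tau_post, delta), `slope`,
#'   `intercept`, `r` (Pearson correlation of delta vs tau_pre), `n`.
#' @export
paired_delta <- function(pre, post) {
  shared <- intersect(pre$cell_id, post$cell_id)
  if (length(shared) == 0L) stop("pre and post tables share no cell ids")
  tab <- data.frame(
    cell_id = shared,
    tau_pre = pre$tau_bound_ns[match(shared, pre$cell_id)],
    tau_post = post$tau_bound_ns[match(shared, post$cell_id)]
  )
  tab$delta <- tab$tau_post - tab$tau_pre
  ok <- stats::complete.cases(tab)
  tab2 <- tab[ok, ]
  if (nrow(tab2) < 2L) stop("fewer than 2 complete pairs")
  if (stats::var(tab2$tau_pre) == 0) {
    slope <- 0
    intercept <- mean(tab2$delta)
    r <- NA_real_
  } else {
    fit <- stats::lm(delta ~ tau_pre, data = tab2)
    slope <- unname(stats::coef(fit)[2])
    intercept <- unname(stats::coef(fit)[1])
    r <- if (stats::var(tab2$delta) == 0) NA_real_ else
      stats::cor(tab2$tau_pre, tab2$delta)
  }
  list(table = tab, slope = slope, intercept = intercept, r = r, n = nrow(tab2))
}
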