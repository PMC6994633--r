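#' Segment cells in an intensity image
#'
#' Standard single-cell segmentation for fields of isolated cells: a global
#' intensity threshold (Otsu by default, or an absolute override), 8-connected
#' component labeling, hole filling, removal of components smaller than
#' `min_area`, and renumbering of the surviving labels 1..K in raster order
#' of their centroids. Touching cells are not split.
#'
#' Photon-count images are Poisson-noisy, so the automatic threshold is
#' computed on a lightly smoothed, variance-stabilized (square-root) copy of
#' the image and mapped back to the intensity scale; an absolute `threshold`
#' override is applied to the raw image directly.
#'
#' @param img 2-D non-negative intensity matrix.
#' @param min_area Minimum component area in pixels.
#' @param threshold Absolute intensity threshold; `NULL` (default) uses Otsu's
#'   method on the smoothed square-root image.
#' @param fill_holes Fill enclosed background holes inside components?
#' @param smooth_sigma Gaussian sigma (pixels) of the pre-threshold smoothing
#'   used only for the automatic threshold; 0 disables.
#' @return Integer label matrix (0 = background), with the chosen threshold
#'   in attribute `threshold`.
#' @export
segment_cells <- function(img, min_area = 20L, threshold = NULL,
                          fill_holes = TRUE, smooth_sigma = 1) {
  stopifnot(is.matrix(img), all(img >= 0))
  if (all(img == 0)) {
    return(structure(matrix(0L, nrow(img), ncol(img)), threshold = NA_real_))
  }
  if (is.null(threshold)) {
    sm <- if (smooth_sigma > 0) {
      as.matrix(EBImage::gblur(EBImage::Image(img), sigma = smooth_sigma))
    } else img
    vs <- sqrt(pmax(sm, 0))
    mx <- max(vs)
    thr_vs <- EBImage::otsu(EBImage::Image(vs / mx), range = c(0, 1)) * mx
    threshold <- thr_vs^2
  }
  bw <- img > threshold
  if (fill_holes) {
    bw <- EBImage::fillHull(EBImage::Image(bw * 1)) > 0
    bw <- matrix(as.logical(bw), nrow(img), ncol(img))
  }
  lab <- label_components_8(bw)
  if (max(lab) == 0L) return(structure(lab, threshold = threshold))
  sizes <- tabulate(lab[lab > 0L], nbins = max(lab))
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(img), ncol(img))
  if (length(keep)) {
    # raster (row-major) order of rounded centroids for stable numbering
    cent <- t(vapply(keep, function(k) {
      px <- which(lab == k, arr.ind = TRUE)
      c(mean(px[, 1]), mean(px[, 2]))
    }, numeric(2)))
    ord <- order(round(cent[, 1]), round(cent[, 2]))
    for (j in seq_along(ord)) out[lab == keep[ord[j]]] <- j
  }
  structure(out, threshold = threshold)
}

# 8-connected component labeling of a logical matrix via the pixel-adjacency
# graph (EBImage::bwlabel is 4-connected).
label_components_8 <- function(bw) {
  nr <- nrow(bw)
  nc <- ncol(bw)
  idx <- which(bw)
  lab <- matrix(0L, nr, nc)
  if (length(idx) == 0L) return(lab)
  pr <- ((idx - 1L) %% nr) + 1L
  pc <- ((idx - 1L) %/% nr) + 1L
  pos <- matrix(0L, nr, nc)
  pos[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    rr <- pr + off[1]
    cc <- pc + off[2]
    ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
    ok[ok] <- bw[cbind(rr[ok], cc[ok])]
    if (any(ok)) {
      edges <- c(edges, rbind(pos[idx[ok]], pos[cbind(rr[ok], cc[ok])]))
    }
  }
  gr <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(gr)$membership
  lab[idx] <- as.integer(comp)
  lab
}

#' Overlap of a segmentation with a ground-truth mask
#'
#' For each truth label, the fraction of its pixels covered by the single
#' best-matching segmented label (Jaccard-free recall; used to validate
#' segmentation on generated fields).
#'
#' @param labels Segmented label matrix.
#' @param truth_mask Ground-truth label matrix.
#' @return Named numeric vector of per-truth-cell overlap fractions.
#' @export
segmentation_overlap <- function(labels, truth_mask) {
  stopifnot(all(dim(labels) == dim(truth_mask)))
  ids <- sort(setdiff(unique(as.integer(truth_mask)), 0L))
  vapply(ids, function(id) {
    px <- truth_mask == id
    seg <- labels[px]
    seg <- seg[seg > 0L]
    if (!length(seg)) return(0)
    max(tabulate(seg)) / sum(px)
  }, numeric(1)) -> ov
  names(ov) <- ids
  ov
}
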