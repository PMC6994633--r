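# Shared fixtures: everything is generated in code at test time.

default_acq <- function(...) acquisition_config(...)

# Noiseless single- or two-component decay as a 1x1-pixel stack.
make_decay <- function(tau_bound, alpha = 1, tau_free = 0.45, photons = 1e6,
                       acq = default_acq(), poisson = FALSE, seed = 1) {
  p <- alpha * decay_shape(tau_bound, acq) +
    (1 - alpha) * decay_shape(tau_free, acq)
  lam <- photons * p
  cnt <- if (poisson) {
    set.seed(seed)
    stats::rpois(length(lam), lam)
  } else lam
  decay_stack(array(cnt, dim = c(length(cnt), 1L, 1L)),
              bin_centers(acq), acq$laser_period_ns,
              harmonic = acq$harmonic)
}

# Disk image fixture: intensity given by f(dr, dc, dist) over a disk.
make_disk <- function(radius = 10, size = 2 * radius + 7,
                      value = function(dr, dc, dist) rep(1, length(dr))) {
  ctr <- (size + 1) / 2
  img <- matrix(0, size, size)
  rows <- matrix(rep(seq_len(size), size), size, size)
  cols <- matrix(rep(seq_len(size), each = size), size, size)
  d <- sqrt((rows - ctr)^2 + (cols - ctr)^2)
  px <- which(d <= radius)
  img[px] <- value(rows[px] - ctr, cols[px] - ctr, d[px])
  list(img = img, pixels = px, center = ctr, radius = radius)
}

# Paint a peripheral band of the given depth on a disk, using a brute-force
# nearest-background distance (independent of the package's distance
# transform): pixels within `depth` of the boundary get `edge_value`.
paint_edge_band <- function(disk, depth, edge_value = 2, center_value = 1) {
  img <- disk$img
  nr <- nrow(img)
  inside <- disk$pixels
  bg <- setdiff(seq_along(img), inside)
  ri <- ((inside - 1) %% nr) + 1
  ci <- ((inside - 1) %/% nr) + 1
  rb <- ((bg - 1) %% nr) + 1
  cb <- ((bg - 1) %/% nr) + 1
  img[inside] <- vapply(seq_along(inside), function(k) {
    dmin <- sqrt(min((rb - ri[k])^2 + (cb - ci[k])^2))
    if (dmin <= depth) edge_value else center_value
  }, numeric(1))
  disk$img <- img
  disk
}

# MOB records drawn directly from population truths (no rendering): the truth
# parameters are the features, which is what the gate/classifier layers see.
records_from_spec <- function(spec, seed, id_offset = 0L,
                              frame = c(600, 600)) {
  tr <- sample_population(spec, frame, seed = seed, id_offset = id_offset)
  data.frame(
    cell_id = tr$cell_id,
    population = tr$population,
    orr = tr$orr_true,
    alpha_bound = tr$alpha_bound_true,
    tau_bound_ns = tr$tau_bound_true,
    edge_center_ratio = tr$edge_enrichment,
    polarity = tr$polarity_offset,
    stringsAsFactors = FALSE
  )
}
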