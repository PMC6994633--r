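test_that("segmentation finds isolated bright objects and ignores blanks", {
  img <- matrix(0, 60, 60)
  d1 <- make_disk(6, 25)
  img[10:34, 10:34] <- d1$img
  img[30:54, 36:60] <- d1$img
  seg <- segment_cells(img, min_area = 20)
  expect_equal(max(seg), 2L)
  blank <- segment_cells(matrix(0, 32, 32))
  expect_equal(max(blank), 0L)
})

test_that("segmentation recovers generated cells with high overlap", {
  acq <- default_acq(frame_shape = c(128, 128))
  tr <- sample_population(population_spec("HSC", 20), acq$frame_shape,
                          seed = 7)
  f <- render_field(tr, acq, seed = 8)
  seg <- segment_cells(intensity_image(f$nadph), min_area = 20)
  expect_equal(max(seg), 20L)
  expect_true(all(segmentation_overlap(seg, f$mask) >= 0.9))
})

test_that("ORR follows its symmetry points and the generator truth", {
  d <- make_disk(8)
  mask <- matrix(0L, nrow(d$img), ncol(d$img))
  mask[d$pixels] <- 1L
  nadph <- d$img * 50
  # FAD = 0 -> ORR 0; FAD = NADPH -> 0.5
  expect_equal(compute_orr(nadph * 0, nadph, mask)$orr, 0)
  expect_equal(compute_orr(nadph, nadph, mask)$orr, 0.5)
  expect_error(compute_orr(nadph[1:10, ], nadph, mask), "shapes")
  # generator round trip at high intensity
  acq <- default_acq(frame_shape = c(48, 48))
  spec <- population_spec("X", 1, means = list(orr = 0.3, total_photons = 5e4),
                          sds = list(orr = 0, total_photons = 0))
  tr <- sample_population(spec, acq$frame_shape, seed = 71)
  f <- render_field(tr, acq, seed = 72)
  orr <- compute_orr(f$fad, intensity_image(f$nadph), f$mask)$orr
  expect_equal(orr, 0.30, tolerance = 0.02 / 0.3)
})

test_that("edge/center ratio reads uniform and edge-weighted disks", {
  du <- make_disk(10)
  expect_equal(edge_center_ratio(du$img, du$pixels), 1.0, tolerance = 0.05)
  # band painted via a brute-force boundary-distance oracle at the erosion
  # depth round(0.3 * r_eq) = 3
  d2 <- paint_edge_band(make_disk(10), depth = 3)
  expect_equal(edge_center_ratio(d2$img, d2$pixels), 2.0, tolerance = 0.1 / 2)
  # zero center intensity flags a missing value instead of dividing by zero
  dz <- paint_edge_band(make_disk(10), depth = 3, center_value = 0)
  expect_true(is.na(edge_center_ratio(dz$img, dz$pixels)))
  # tiny cells fall back to the most interior pixel
  d3 <- make_disk(2)
  expect_true(is.finite(edge_center_ratio(d3$img, d3$pixels)))
})

test_that("polarity matches centroid oracles", {
  du <- make_disk(10)
  expect_lt(polarity(du$img, du$pixels), 0.02)
  # all intensity in one boundary pixel: polarity ~ 1
  db <- make_disk(10, value = function(dr, dc, dist) as.numeric(dc > 9.4))
  expect_gt(polarity(db$img, db$pixels), 0.9)
  # half-bright disk (even grid, so the cut passes between pixel columns):
  # analytic centroid offset 4R/(3*pi)
  dh <- make_disk(12, size = 32, value = function(dr, dc, dist) as.numeric(dc > 0))
  p <- polarity(dh$img, dh$pixels)
  expect_equal(p, 4 / (3 * pi), tolerance = 0.02 / (4 / (3 * pi)))
  # brute-force pixel-centroid oracle agrees exactly
  px <- dh$pixels
  nr <- nrow(dh$img)
  r <- ((px - 1) %% nr) + 1
  c_ <- ((px - 1) %/% nr) + 1
  w <- dh$img[px]
  oracle <- sqrt(sum((c(sum(w * r) / sum(w), sum(w * c_) / sum(w)) -
                        c(mean(r), mean(c_)))^2)) / sqrt(length(px) / pi)
  expect_equal(p, oracle, tolerance = 1e-12)
  # zero intensity -> missing
  expect_true(is.na(polarity(dh$img * 0, dh$pixels)))
})

test_that("the extractor propagates a pure-free cell as alpha 0, tau missing", {
  acq <- default_acq(frame_shape = c(48, 48))
  spec <- population_spec("free", 1, means = list(alpha_bound = 0,
                                                  total_photons = 1e5),
                          sds = list(alpha_bound = 0, total_photons = 0))
  tr <- sample_population(spec, acq$frame_shape, seed = 81)
  f <- render_field(tr, acq, seed = 82)
  tab <- extract_mob_field(f)
  expect_equal(nrow(tab), 1)
  expect_lt(tab$alpha_bound, 0.02)
  # at alpha = 0 the bound lifetime is undefined or meaningless; shot noise
  # may yield a tiny alpha with an arbitrary tau, but never a crash
  expect_true(is.na(tab$tau_bound_ns) || tab$alpha_bound < 0.02)
})

test_that("per-population parameter recovery from rendered fields", {
  acq <- default_acq(frame_shape = c(160, 160))
  presets <- load_population_presets(n_cells = 10)
  tabs <- list()
  for (i in seq_along(c("HSC", "MPP", "OPP"))) {
    nm <- c("HSC", "MPP", "OPP")[i]
    tr <- sample_population(presets[[nm]], acq$frame_shape, seed = 90 + i,
                            id_offset = 1000L * i)
    f <- render_field(tr, acq, seed = 95 + i)
    tabs[[nm]] <- extract_mob_field(f)
  }
  presets_tau <- c(HSC = 3.56, MPP = 3.05, OPP = 2.85)
  for (nm in names(tabs)) {
    expect_lt(abs(mean(tabs[[nm]]$tau_bound_ns, na.rm = TRUE) -
                    presets_tau[[nm]]), 0.1)
  }
})

test_that("extraction is deterministic down to the CSV bytes", {
  acq <- default_acq(frame_shape = c(96, 96))
  tr <- sample_population(population_spec("HSC", 6), acq$frame_shape,
                          seed = 101)
  f <- render_field(tr, acq, seed = 102)
  t1 <- extract_mob_field(f)
  t2 <- extract_mob_field(f)
  f1 <- tempfile(fileext = ".csv")
  f2 <- tempfile(fileext = ".csv")
  write_cell_table(t1, f1)
  write_cell_table(t2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("MOBs are invariant to uniform intensity rescaling", {
  acq <- default_acq(frame_shape = c(96, 96))
  tr <- sample_population(population_spec("HSC", 5), acq$frame_shape,
                          seed = 111)
  f <- render_field(tr, acq, seed = 112)
  tab1 <- extract_mob_field(f)
  f2 <- f
  f2$nadph$counts <- f2$nadph$counts * 3
  f2$fad <- f2$fad * 3  # both channels rescale together
  tab2 <- extract_mob_table(f2$nadph, f2$fad, f2$mask, truth = f2$truth)
  for (col in c("orr", "alpha_bound", "tau_bound_ns", "edge_center_ratio",
                "polarity")) {
    expect_equal(tab1[[col]], tab2[[col]], tolerance = 1e-9)
  }
})

test_that("paired tables report the treatment slope and fail on disjoint ids", {
  mk <- function(ids, tau) data.frame(cell_id = ids, tau_bound_ns = tau)
  pre <- mk(1:6, c(3.1, 3.3, 3.5, 3.6, 3.4, 3.2))
  # post = pre: all deltas zero, slope zero
  pd <- paired_delta(pre, pre)
  expect_equal(pd$table$delta, rep(0, 6))
  expect_equal(pd$slope, 0)
  # generator perturbation with zero noise recovers the slope exactly
  spec <- population_spec("HSC", 60, means = list(tau_bound_ns = 3.5),
                          sds = list(tau_bound_ns = 0.15))
  tr <- sample_population(spec, c(400, 400), seed = 121)
  post_tr <- apply_perturbation(tr, perturbation_model(0.2, -0.1, 0),
                                seed = 122)
  pd2 <- paired_delta(mk(tr$cell_id, tr$tau_bound_true),
                      mk(post_tr$cell_id, post_tr$tau_bound_true))
  expect_equal(pd2$slope, -0.1, tolerance = 1e-9)
  expect_error(paired_delta(pre, mk(7:9, c(3, 3, 3))), "no cell ids")
})
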