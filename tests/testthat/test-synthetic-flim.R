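test_that("population sampling honors n_cells, dispersion and the seed", {
  spec0 <- population_spec("HSC", 0)
  expect_equal(nrow(sample_population(spec0, c(64, 64), seed = 1)), 0)
  # zero dispersion: every cell identical at the means
  spec <- population_spec("HSC", 50, sds = list(
    radius_px = 0, alpha_bound = 0, tau_bound_ns = 0, tau_free_ns = 0,
    total_photons = 0, orr = 0, edge_enrichment = 0, polarity_offset = 0))
  tr <- sample_population(spec, c(300, 300), seed = 2)
  expect_equal(nrow(tr), 50)
  for (col in c("alpha_bound_true", "tau_bound_true", "orr_true",
                "edge_enrichment", "polarity_offset", "total_photons")) {
    expect_equal(length(unique(tr[[col]])), 1)
  }
  expect_equal(tr$alpha_bound_true[1], 0.65)
  # determinism
  spec2 <- population_spec("MPP", 12)
  expect_identical(sample_population(spec2, c(128, 128), seed = 9),
                   sample_population(spec2, c(128, 128), seed = 9))
  # placed disks never overlap
  tr2 <- sample_population(spec2, c(128, 128), seed = 9)
  dd <- as.matrix(dist(tr2[, c("center_row", "center_col")]))
  rr <- outer(tr2$radius_px, tr2$radius_px, "+")
  expect_true(all(dd[upper.tri(dd)] >= rr[upper.tri(rr)]))
})

test_that("invalid population configurations are rejected", {
  expect_error(population_spec("X", 5, means = list(alpha_bound = 1.4)),
               "alpha_bound")
  expect_error(population_spec("X", 5, means = list(tau_bound_ns = 0.3)),
               "tau_bound")
  expect_error(population_spec("X", 5, means = list(orr = 1.2)), "orr")
  expect_error(population_spec("X", 5, sds = list(orr = -1)), "dispersions")
  expect_error(population_spec("X", 5, means = list(nonsense = 1)), "unknown")
})

test_that("rendered fields conserve photons and respect the frame", {
  acq <- default_acq(frame_shape = c(64, 64))
  spec <- population_spec("HSC", 1, means = list(total_photons = 1e4),
                          sds = list(total_photons = 0))
  tr <- sample_population(spec, acq$frame_shape, seed = 3)
  f <- render_field(tr, acq, seed = 4)
  # noiseless amplitude field holds exactly the requested photons
  expect_equal(sum(f$expected_nadph), 1e4, tolerance = 1e-9)
  # observed counts agree within Poisson error
  expect_lt(abs(sum(f$nadph$counts) - 1e4), 3 * sqrt(1e4))
  # a cell pushed over the boundary errors
  tr_bad <- tr
  tr_bad$center_row <- 2
  expect_error(render_field(tr_bad, acq, seed = 4), "boundary")
})

test_that("a pure-bound cell renders a single wrapped exponential", {
  acq <- default_acq(frame_shape = c(48, 48))
  spec <- population_spec("X", 1, means = list(alpha_bound = 1,
                                               tau_bound_ns = 3.5,
                                               total_photons = 3e5),
                          sds = list(alpha_bound = 0, tau_bound_ns = 0,
                                     total_photons = 0))
  tr <- sample_population(spec, acq$frame_shape, seed = 5)
  f <- render_field(tr, acq, seed = 6)
  ph <- phasor_transform(f$nadph)
  gs <- cell_phasor(ph, f$mask == tr$cell_id)
  truth <- semicircle_point(3.5, omega(acq))[1, ]
  expect_equal(unname(gs["g"]), unname(truth["g"]), tolerance = 5e-3)
  expect_equal(unname(gs["s"]), unname(truth["s"]), tolerance = 5e-3)
})

test_that("pooled phasors of generated cells match the closed-form mixture", {
  acq <- default_acq(frame_shape = c(48, 48))
  om <- omega(acq)
  spec <- population_spec("X", 1, means = list(alpha_bound = 0.7,
                                               tau_bound_ns = 3.5,
                                               total_photons = 2e5),
                          sds = list(alpha_bound = 0, tau_bound_ns = 0,
                                     total_photons = 0))
  tr <- sample_population(spec, acq$frame_shape, seed = 11)
  f <- render_field(tr, acq, seed = 12)
  gs <- cell_phasor(phasor_transform(f$nadph), f$mask == tr$cell_id)
  expect_equal(unname(gs["g"]), 0.4563, tolerance = 0.01 / 0.4563)
  expect_equal(unname(gs["s"]), 0.3653, tolerance = 0.01 / 0.3653)
})

test_that("rendered subcellular structure is monotone in the presets", {
  acq <- default_acq(frame_shape = c(48, 48))
  ec_of <- function(enr, pol) {
    spec <- population_spec("X", 1, means = list(edge_enrichment = enr,
                                                 polarity_offset = pol),
                            sds = list(edge_enrichment = 0,
                                       polarity_offset = 0))
    tr <- sample_population(spec, acq$frame_shape, seed = 21)
    f <- render_field(tr, acq, seed = 22)
    px <- which(f$mask == tr$cell_id)
    c(edge_center_ratio(f$expected_nadph, px),
      polarity(f$expected_nadph, px))
  }
  enr_grid <- c(0.8, 1, 1.4, 1.8, 2.2)
  ec <- vapply(enr_grid, function(e) ec_of(e, 0)[1], numeric(1))
  expect_true(all(diff(ec) > 0))
  pol_grid <- c(0, 0.1, 0.25, 0.4, 0.6)
  pol <- vapply(pol_grid, function(p) ec_of(1, p)[2], numeric(1))
  expect_true(all(diff(pol) > 0))
  # the rendered polarity reproduces the requested displacement
  expect_equal(pol, pol_grid, tolerance = 0.02)
})

test_that("FAD intensities encode the requested redox ratio", {
  acq <- default_acq(frame_shape = c(48, 48))
  spec <- population_spec("X", 1, means = list(orr = 0.3),
                          sds = list(orr = 0))
  tr <- sample_population(spec, acq$frame_shape, seed = 31)
  f <- render_field(tr, acq, seed = 32, fad_noise = FALSE)
  px <- which(f$mask == tr$cell_id)
  orr <- mean(f$fad[px] / (f$fad[px] + f$expected_nadph[px]))
  expect_equal(orr, 0.3, tolerance = 1e-9)
})

test_that("render is deterministic given the seed", {
  acq <- default_acq(frame_shape = c(64, 64))
  spec <- population_spec("HSC", 4)
  tr <- sample_population(spec, acq$frame_shape, seed = 41)
  f1 <- render_field(tr, acq, seed = 42)
  f2 <- render_field(tr, acq, seed = 42)
  expect_identical(f1$nadph$counts, f2$nadph$counts)
  expect_identical(f1$fad, f2$fad)
})

test_that("perturbation shifts tau_bound linearly and preserves pairing", {
  spec <- population_spec("HSC", 20, means = list(tau_bound_ns = 3.5))
  tr <- sample_population(spec, c(200, 200), seed = 51)
  # identity model
  same <- apply_perturbation(tr, perturbation_model(0, 0, 0), seed = 52)
  expect_equal(same$tau_bound_true, tr$tau_bound_true)
  # direct arithmetic: tau 3.5 -> 3.35
  one <- tr[1, ]
  one$tau_bound_true <- 3.5
  post <- apply_perturbation(one, perturbation_model(0.2, -0.1, 0), seed = 53)
  expect_equal(post$tau_bound_true, 3.35)
  expect_identical(post$cell_id, one$cell_id)
})

test_that("regression on perturbed cells recovers the model slope", {
  spec <- population_spec("HSC", 200, means = list(tau_bound_ns = 3.5),
                          sds = list(tau_bound_ns = 0.15))
  tr <- sample_population(spec, c(600, 600), seed = 61)
  post <- apply_perturbation(tr, perturbation_model(0.2, -0.1, 0.02),
                             seed = 62)
  delta <- post$tau_bound_true - tr$tau_bound_true
  fit <- lm(delta ~ tr$tau_bound_true)
  expect_lt(abs(coef(fit)[2] - (-0.1)), 0.02)
})
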