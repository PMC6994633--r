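test_that("semicircle closed form matches its limits and derived values", {
  om <- 2 * pi / 12.5
  expect_equal(unname(semicircle_point(0, om)[1, ]), c(1, 0))
  expect_lt(sum(abs(semicircle_point(1e9, om)[1, ])), 1e-6)
  # omega * tau = 1 sits at the top of the semicircle
  expect_equal(unname(semicircle_point(1 / om, om)[1, ]), c(0.5, 0.5))
  p <- semicircle_point(3.5, om)
  expect_equal(unname(p[1, "g"]), 0.2442, tolerance = 0.0005 / 0.2442)
  expect_equal(unname(p[1, "s"]), 0.4296, tolerance = 0.0005 / 0.4296)
  expect_error(semicircle_point(-1, om), "negative")
})

test_that("phasor transform reproduces closed forms on wrapped decays", {
  acq <- default_acq()
  om <- omega(acq)
  # all photons in the first bin: near the zero-lifetime corner (1, 0)
  cnt <- array(0, dim = c(256, 1, 1))
  cnt[1, 1, 1] <- 1e5
  st <- decay_stack(cnt, bin_centers(acq), 12.5)
  ph <- phasor_transform(st)
  expect_equal(ph$g[1, 1], 1, tolerance = 1e-3)
  expect_equal(ph$s[1, 1], 0, tolerance = 0.02)
  # free-NAD(P)H lifetime
  ph <- phasor_transform(make_decay(0.45, acq = acq))
  expect_equal(ph$g[1, 1], 0.9513, tolerance = 1e-3 / 0.9513)
  expect_equal(ph$s[1, 1], 0.2152, tolerance = 1e-3 / 0.2152)
  # tau = 1/omega lands at (0.5, 0.5)
  ph <- phasor_transform(make_decay(1 / om, acq = acq))
  expect_equal(c(ph$g[1, 1], ph$s[1, 1]), c(0.5, 0.5), tolerance = 2e-3)
})

test_that("zero-count pixels get NA phasors and bad bin grids error", {
  acq <- default_acq(frame_shape = c(2, 2))
  cnt <- array(0, dim = c(256, 2, 2))
  cnt[, 1, 1] <- decay_shape(2, acq) * 1e4
  st <- decay_stack(cnt, bin_centers(acq), 12.5)
  ph <- phasor_transform(st)
  expect_false(is.na(ph$g[1, 1]))
  expect_true(all(is.na(ph$g[-1])))
  bad <- decay_stack(cnt[1:200, , , drop = FALSE],
                     bin_centers(acq)[1:200], 12.5)
  expect_error(phasor_transform(bad), "laser period")
})

test_that("phasor transform is linear: pooled decay equals weighted mean", {
  acq <- default_acq()
  set.seed(101)
  for (i in 1:25) {
    t1 <- runif(1, 0.2, 5)
    t2 <- runif(1, 0.2, 5)
    n1 <- runif(1, 1e3, 1e5)
    n2 <- runif(1, 1e3, 1e5)
    d1 <- decay_shape(t1, acq) * n1
    d2 <- decay_shape(t2, acq) * n2
    ph <- function(v) {
      p <- phasor_transform(decay_stack(array(v, c(256, 1, 1)),
                                        bin_centers(acq), 12.5))
      c(p$g[1, 1], p$s[1, 1])
    }
    lhs <- ph(d1 + d2)
    rhs <- (n1 * ph(d1) + n2 * ph(d2)) / (n1 + n2)
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("cell averaging is photon-weighted and matches the pooled decay", {
  acq <- default_acq(frame_shape = c(3, 3))
  cnt <- array(0, dim = c(256, 3, 3))
  set.seed(7)
  for (i in 1:9) {
    cnt[, ((i - 1) %% 3) + 1, ((i - 1) %/% 3) + 1] <-
      rpois(256, decay_shape(runif(1, 0.3, 4), acq) * runif(1, 500, 5000))
  }
  st <- decay_stack(cnt, bin_centers(acq), 12.5)
  ph <- phasor_transform(st)
  # single-pixel set is the identity
  one <- cell_phasor(ph, 1L)
  expect_equal(unname(one["g"]), ph$g[1, 1])
  # weighted mean over all pixels equals the pooled-decay phasor exactly
  all9 <- cell_phasor(ph, 1:9)
  pooled <- phasor_transform(pooled_decay(st))
  expect_equal(unname(all9["g"]), pooled$g[1, 1], tolerance = 1e-12)
  expect_equal(unname(all9["s"]), pooled$s[1, 1], tolerance = 1e-12)
  expect_error(cell_phasor(ph, integer(0)), "empty")
})

test_that("two equal-weight pixels average to the midpoint", {
  ph <- structure(list(
    g = matrix(c(1, 0), 1, 2), s = matrix(c(0, 0), 1, 2),
    total_counts = matrix(c(100, 100), 1, 2),
    omega = 0.5, harmonic = 1L, laser_period_ns = 12.5, channel = "NADPH"
  ), class = "phasor_image")
  gs <- cell_phasor(ph, 1:2)
  expect_equal(as.numeric(gs), c(0.5, 0))
})

test_that("fixed-free decomposition inverts mixtures and flags edge cases", {
  om <- 2 * pi / 12.5
  pf <- semicircle_point(0.45, om)[1, ]
  # pure free: alpha 0, tau_bound undefined but not an error
  fit <- decompose_fixed_free(pf, 0.45, om)
  expect_equal(fit$alpha_bound, 0)
  expect_true(is.na(fit$tau_bound))
  # pure bound
  fit <- decompose_fixed_free(semicircle_point(3.5, om)[1, ], 0.45, om)
  expect_equal(fit$alpha_bound, 1, tolerance = 1e-9)
  expect_equal(fit$tau_bound, 3.5, tolerance = 1e-9)
  # the derived mixture example
  fit <- decompose_fixed_free(c(0.4563, 0.3653), 0.45, om)
  expect_equal(fit$alpha_bound, 0.700, tolerance = 0.005 / 0.7)
  expect_equal(fit$tau_bound, 3.50, tolerance = 0.05 / 3.5)
  # out-of-semicircle points are projected and flagged
  out_pt <- c(0.5, 0.52)
  fit <- decompose_fixed_free(out_pt, 0.45, om)
  expect_true(fit$residual_flag)
  expect_true(fit$valid)
})

test_that("decomposition is exact on a noiseless alpha x tau grid", {
  om <- 2 * pi / 12.5
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    for (tb in c(1, 2, 3.5, 4.5)) {
      fit <- decompose_fixed_free(mixture_phasor(a, tb, 0.45, om), 0.45, om)
      expect_equal(fit$alpha_bound, a, tolerance = 1e-8)
      if (a > 0) expect_equal(fit$tau_bound, tb, tolerance = 1e-8)
    }
  }
})

test_that("tau_bound is invariant to uniform intensity rescaling", {
  acq <- default_acq()
  om <- omega(acq)
  st <- make_decay(3.2, alpha = 0.6, photons = 2e4, poisson = TRUE, seed = 5)
  fit1 <- decompose_fixed_free(unclass(cell_phasor(phasor_transform(st), 1L)),
                               0.45, om)
  st$counts <- st$counts * 7
  fit2 <- decompose_fixed_free(unclass(cell_phasor(phasor_transform(st), 1L)),
                               0.45, om)
  expect_equal(fit1$tau_bound, fit2$tau_bound, tolerance = 1e-12)
  expect_equal(fit1$alpha_bound, fit2$alpha_bound, tolerance = 1e-12)
})

test_that("trajectory fit recovers the free and bound lifetimes", {
  om <- 2 * pi / 12.5
  # exact chord construction
  alphas <- seq(0.05, 0.95, length.out = 20)
  pts <- t(vapply(alphas, function(a) mixture_phasor(a, 3.5, 0.45, om),
                  numeric(2)))
  tf <- fit_trajectory(pts[, 1], pts[, 2], om)
  expect_equal(tf$tau_free_est, 0.45, tolerance = 0.01 / 0.45)
  expect_equal(tf$tau_bound_est, 3.5, tolerance = 0.01 / 3.5)
  # noisy cloud
  set.seed(33)
  a <- runif(500)
  cloud <- t(vapply(a, function(x) mixture_phasor(x, 3.5, 0.45, om),
                    numeric(2)))
  g <- cloud[, 1] + rnorm(500, 0, 0.005)
  s <- cloud[, 2] + rnorm(500, 0, 0.005)
  tf <- fit_trajectory(g, s, om)
  expect_lt(abs(tf$tau_free_est - 0.45), 0.05)
  expect_lt(abs(tf$tau_bound_est - 3.5), 0.05)
  # degenerate clouds error
  expect_error(fit_trajectory(rep(0.4, 20), rep(0.3, 20), om), "degenerate")
  # a horizontal line at s = 0.8 never touches the semicircle
  expect_error(fit_trajectory(seq(0.2, 0.8, length.out = 20),
                              rep(0.8, 20), om),
               "intersect")
  expect_error(fit_trajectory(g[1:5], s[1:5], om), "at least 10")
})

test_that("reference calibration corrects an IRF-broadened measurement", {
  acq <- default_acq(irf_sigma_ns = 0.1)
  ideal <- make_decay(2.0, acq = default_acq())
  cal0 <- calibrate_from_reference(ideal, 2.0)
  expect_equal(cal0$phase_shift, 0, tolerance = 1e-3)
  expect_equal(cal0$modulation_factor, 1, tolerance = 1e-3)
  # IRF-broadened reference: calibration puts it back on the semicircle
  p <- decay_shape(2.0, acq)
  ref <- decay_stack(array(p * 1e6, c(256, 1, 1)), bin_centers(acq), 12.5)
  cal <- calibrate_from_reference(ref, 2.0)
  ph <- phasor_transform(ref, calibration = cal)
  dist_to_circle <- abs(sqrt((ph$g[1, 1] - 0.5)^2 + ph$s[1, 1]^2) - 0.5)
  expect_lt(dist_to_circle, 0.005)
  # applying the fixed correction twice over-corrects (not idempotent)
  ph2 <- phasor_transform(ref, calibration = cal)
  z <- complex(real = ph2$g[1, 1], imaginary = ph2$s[1, 1]) *
    cal$modulation_factor * exp(1i * cal$phase_shift)
  ph1 <- phasor_transform(ref, calibration = cal)
  expect_false(isTRUE(all.equal(c(Re(z), Im(z)),
                                c(ph1$g[1, 1], ph1$s[1, 1]),
                                tolerance = 1e-6)))
  empty <- decay_stack(array(0, c(256, 1, 1)), bin_centers(acq), 12.5)
  expect_error(calibrate_from_reference(empty, 2.0), "zero-count")
})

test_that("phasor median filter removes outliers and preserves constants", {
  ph <- structure(list(
    g = matrix(0.4, 5, 5), s = matrix(0.3, 5, 5),
    total_counts = matrix(100, 5, 5),
    omega = 0.5, harmonic = 1L, laser_period_ns = 12.5, channel = "NADPH"
  ), class = "phasor_image")
  expect_identical(phasor_median_filter(ph, radius = 0L), ph)
  flt <- phasor_median_filter(ph, radius = 1L)
  expect_equal(flt$g, ph$g)
  ph$g[3, 3] <- 0.9
  flt <- phasor_median_filter(ph, radius = 1L)
  expect_equal(flt$g[3, 3], 0.4)
})

test_that("binned single-exponential phasors stay on the semicircle", {
  acq <- default_acq()
  set.seed(9)
  for (tau in runif(20, 0.2, 5)) {
    ph <- phasor_transform(make_decay(tau, acq = acq))
    resid <- abs((ph$g[1, 1] - 0.5)^2 + ph$s[1, 1]^2 - 0.25)
    expect_lt(resid, 1e-3)
  }
})

test_that("the FAD channel runs through the identical phasor machinery", {
  # a synthetic bound-FAD stack: same transform, same decomposition
  acq <- default_acq()
  om <- omega(acq)
  p <- decay_shape(2.8, acq)
  st <- decay_stack(array(p * 5e5, c(256, 1, 1)), bin_centers(acq), 12.5,
                    channel = "FAD")
  ph <- phasor_transform(st)
  fit <- decompose_fixed_free(c(ph$g[1, 1], ph$s[1, 1]), 0.45, om)
  expect_equal(fit$tau_bound, 2.8, tolerance = 2e-3)
  expect_identical(ph$channel, "FAD")
})
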