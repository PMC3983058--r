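test_that("radius of gyration matches closed forms and brute force", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(4, 0, 0))), 2)

  # discrete rod: N collinear points spacing d -> sqrt(d^2 (N^2 - 1) / 12)
  for (N in c(3, 10, 47)) {
    d <- 1.7
    m <- cbind((seq_len(N) - 1) * d, 0, 0)
    expect_equal(radius_of_gyration(m), sqrt(d^2 * (N^2 - 1) / 12),
                 tolerance = 1e-12)
  }

  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(rnorm(3 * 40, sd = 10), ncol = 3)
    expect_equal(radius_of_gyration(m), rgyr_bruteforce(m),
                 tolerance = 1e-9)
  }

  expect_error(radius_of_gyration(matrix(numeric(0), ncol = 3)), "non-empty")
})

test_that("ensemble summary recovers Gaussian FWHM and handles degeneracy", {
  set.seed(2)
  x <- rnorm(1e5, mean = 50, sd = 10)
  s <- ensemble_summary(x, histogram_bin = 2)
  expect_equal(s$fwhm, 2.3548 * 10, tolerance = 0.5)
  expect_equal(s$mean, 50, tolerance = 0.2)
  expect_equal(s$peak, 50, tolerance = 2)

  expect_warning(sc <- ensemble_summary(rep(7, 10)), "FWHM")
  expect_equal(sc$peak, 7)
  expect_equal(sc$mean, 7)
  expect_equal(sc$median, 7)
  expect_equal(sc$fwhm, 0)

  expect_error(ensemble_summary(5), "at least 2")
})

test_that("hydrodynamic closed forms reproduce their printed anchors", {
  # Kohn denatured-state scaling
  expect_equal(kohn_rgyr(323), 61.0, tolerance = 0.05)
  expect_equal(kohn_rgyr(1), 1.927)
  expect_true(all(diff(kohn_rgyr(1:500)) > 0))

  # minimal anhydrous sphere
  expect_equal(erickson_min_radius(34900), 21.6, tolerance = 0.05)
  expect_equal(erickson_min_radius(2000) / erickson_min_radius(1000),
               2^(1 / 3), tolerance = 1e-12)
  expect_equal(erickson_min_radius(1000), 6.6, tolerance = 0.05)

  # friction ratio and its empirical shape bands
  expect_equal(friction_ratio(48.1, 21.6), 2.23, tolerance = 0.005)
  expect_equal(friction_ratio(5, 5), 1)
  expect_equal(friction_class(1.25), "nearly globular")
  expect_equal(friction_class(2.23), "elongated")
  expect_equal(friction_class(1.6), "intermediate")

  # R_Gyr / R_H = 1.06 conversion
  expect_equal(rh_from_rgyr(53), 50)
  expect_equal(rgyr_from_rh(rh_from_rgyr(77.3)), 77.3, tolerance = 1e-12)
  expect_lt(abs(rh_from_rgyr(50.0) - 48.1), 1)
  expect_error(rh_from_rgyr(-1), "positive")
})

test_that("Flory tag correction evaluates the stated constant range", {
  fc <- flory_tag_correction(323, 306)
  expect_lt(abs(fc$mid - 1.3), 0.05)
  expect_lt(abs(fc$half_range - 0.1), 0.05)

  expect_equal(flory_tag_correction(306, 306)$mid, 0)
  # correction grows with the square root of added length
  mids <- vapply(c(310, 320, 340), function(n) {
    flory_tag_correction(n, 306)$mid
  }, numeric(1))
  expect_true(all(diff(mids) > 0))
})

test_that("denatured > disordered ensemble > globular size ordering holds", {
  mw <- 34900
  coil_mean <- 50.0
  rg_globular <- rgyr_from_rh(erickson_min_radius(mw))
  expect_gt(kohn_rgyr(323), coil_mean)
  expect_gt(coil_mean, rg_globular)
})

test_that("secondary-structure content profiles sum sensibly per bin", {
  # a hand-built single-conformer ensemble, all residues at the PPII center
  L <- 20
  fake <- structure(list(
    sequence = paste(rep("A", L), collapse = ""), preset = "coil", seed = 1,
    n = 2,
    phi = matrix(-75, 2, L), psi = matrix(145, 2, L),
    omega = matrix(180, 2, L), rgyr = c(12, 13), cis_count = c(0, 0),
    acceptance_rate = 1
  ), class = "conformer_ensemble")
  prof <- ss_content_by_rgyr(fake)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$f_ppii, 1)
  expect_equal(prof$n_conformers, 2)

  s <- substr(synthetic_cassd(1), 1, 100)
  e <- generate_ensemble(s, "coil", n = 150, seed = 3)
  pr <- ss_content_by_rgyr(e)
  expect_true(all(pr$f_ppii + pr$f_alpha + pr$f_beta <= 1 + 1e-12))
  expect_true(all(pr$n_conformers >= 1)) # empty bins are absent, not zero
  expect_true(all(pr$f_ppii > pr$f_beta))

  eb <- generate_ensemble(s, "beta", n = 100, seed = 3)
  prb <- ss_content_by_rgyr(eb)
  expect_true(all(prb$f_beta > prb$f_ppii))
})

test_that("hydrodynamic record composes the conversions", {
  hr <- hydrodynamic_record(rh = 48.1, mw = 34900, n_residues = 323)
  expect_equal(hr$friction_ratio, 2.23, tolerance = 0.005)
  expect_equal(hr$shape_class, "elongated")
  expect_equal(hr$kohn_rgyr, 61.0, tolerance = 0.05)
  expect_equal(hr$rgyr_equiv, 48.1 * 1.06)
})
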