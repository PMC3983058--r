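test_that("backbone builder reproduces ideal virtual-bond geometry", {
  # trans chain: CA-CA virtual bond is 3.80 A regardless of phi/psi
  d <- tibble::tibble(phi = c(-180, -75, -120, 60, -63),
                      psi = c(180, 145, 130, 45, -43),
                      omega = rep(180, 5))
  co <- build_backbone(d)
  ca <- as.matrix(co[co$atom == "CA", c("x", "y", "z")])
  bonds <- sqrt(rowSums((ca[-1, ] - ca[-5, ])^2))
  expect_true(all(abs(bonds - 3.80) < 0.02))

  # single residue: 4 atoms at canonical positions
  one <- build_backbone(tibble::tibble(phi = -75, psi = 145, omega = 180))
  expect_equal(nrow(one), 4)
  expect_equal(unname(unlist(one[one$atom == "N", c("x", "y", "z")])),
               c(0, 0, 0))

  # cis peptide bond: independent planar construction of the CA-CA distance
  # from the same ideal lengths/angles (law-of-cosines chain in the plane)
  ang <- function(a) a * pi / 180
  C <- c(0, 0)
  N <- c(1.329, 0)
  ca1 <- 1.525 * c(cos(ang(116.2)), sin(ang(116.2)))
  ca2 <- N + 1.458 * c(-cos(ang(121.7)), sin(ang(121.7)))
  d_cis_expected <- sqrt(sum((ca2 - ca1)^2))

  dc <- tibble::tibble(phi = c(-75, -75), psi = c(145, 145),
                       omega = c(180, 0))
  coc <- build_backbone(dc)
  cac <- as.matrix(coc[coc$atom == "CA", c("x", "y", "z")])
  d_cis <- sqrt(sum((cac[2, ] - cac[1, ])^2))
  expect_equal(d_cis, d_cis_expected, tolerance = 1e-6)
  expect_true(d_cis > 2.7 && d_cis < 3.0)
})

test_that("dihedral -> coordinates -> dihedral round trip is exact to 1e-3 deg", {
  set.seed(21)
  for (rep in 1:5) {
    L <- 15
    d <- tibble::tibble(
      phi = runif(L, -179, 179), psi = runif(L, -179, 179),
      omega = sample(c(180, 0), L, replace = TRUE, prob = c(0.9, 0.1))
    )
    m <- measure_dihedrals(build_backbone(d))
    expect_lt(max(abs(m$phi[-1] - d$phi[-1])), 1e-3)
    expect_lt(max(abs(m$psi - d$psi)), 1e-3)
    werr <- abs(m$omega[-1] - d$omega[-1])
    expect_lt(max(pmin(werr, abs(werr - 360))), 1e-3)
  }
})

test_that("clash check accepts extended chains and reports offending pairs", {
  ext <- build_backbone(tibble::tibble(phi = rep(-120, 30),
                                       psi = rep(130, 30),
                                       omega = rep(180, 30)))
  res <- clash_check(ext)
  expect_true(res$accept)
  expect_equal(nrow(res$pairs), 0)

  # fold the chain so two distal CAs coincide
  folded <- ext
  i1 <- which(folded$atom == "CA")[1]
  i25 <- which(folded$atom == "CA")[25]
  folded[i25, c("x", "y", "z")] <- folded[i1, c("x", "y", "z")] + 0.5
  res2 <- clash_check(folded)
  expect_false(res2$accept)
  expect_true(any(res2$pairs$i == 1 & res2$pairs$j == 25))
})

test_that("conformation classifier labels basin centers and respects areas", {
  expect_equal(classify_conformation(-75, 145), "PPII")
  expect_equal(classify_conformation(-63, -43), "alpha")
  expect_equal(classify_conformation(60, 45), "alpha")
  expect_equal(classify_conformation(-135, 135), "beta")
  expect_equal(classify_conformation(0, 0), "other")

  # uniform angles: label frequencies match rectangle-area fractions
  set.seed(4)
  n <- 200000
  phi <- runif(n, -180, 180)
  psi <- runif(n, -180, 180)
  lab <- classify_conformation(phi, psi)
  b <- basin_library()
  area <- function(nm) {
    r <- b[b$basin == nm, ]
    (r$phi_max - r$phi_min) * (r$psi_max - r$psi_min) / 360^2
  }
  expect_lt(abs(mean(lab == "PPII") - area("ppii")), 0.01)
  expect_lt(abs(mean(lab == "beta") - area("beta")), 0.01)
  expect_lt(abs(mean(lab == "alpha") - (area("alpha_r") + area("alpha_l"))),
            0.01)
})

test_that("basin rectangles are pairwise disjoint and contain their centers", {
  b <- basin_library()
  for (i in seq_len(nrow(b))) {
    expect_true(b$phi_c[i] > b$phi_min[i] && b$phi_c[i] <= b$phi_max[i])
    expect_true(b$psi_c[i] > b$psi_min[i] && b$psi_c[i] <= b$psi_max[i])
    for (j in seq_len(nrow(b))) {
      if (i >= j) next
      overlap_phi <- b$phi_min[i] < b$phi_max[j] && b$phi_min[j] < b$phi_max[i]
      overlap_psi <- b$psi_min[i] < b$psi_max[j] && b$psi_min[j] < b$psi_max[i]
      expect_false(overlap_phi && overlap_psi)
    }
  }
})

test_that("coil-weighted sampling is PPII-dominant; beta weighting degenerate", {
  poly_a <- paste(rep("A", 10000), collapse = "")
  d <- sample_dihedrals(poly_a, seed = 8)
  lab <- classify_conformation(d$phi, d$psi)
  expect_gt(mean(lab == "PPII"), 0.5)

  wb <- weight_profile(poly_a, "beta")
  db <- sample_dihedrals(poly_a, weights = wb, seed = 8)
  labb <- classify_conformation(db$phi, db$psi)
  expect_gt(mean(labb == "beta"), 0.99)

  bad <- weight_profile(poly_a, "coil")
  bad$w_coil <- 0.5
  expect_error(sample_dihedrals(poly_a, weights = bad), "normalized")
})

test_that("cis-proline counts stay within the 0-6 cap", {
  s <- paste(rep("PA", 60), collapse = "") # 60 prolines
  counts <- vapply(1:30, function(i) {
    attr(sample_dihedrals(s, seed = i), "cis_count")
  }, numeric(1))
  expect_true(all(counts >= 0 & counts <= 6))
  expect_gt(mean(counts), 0) # cis events do occur

  e <- generate_ensemble(s, "coil", n = 50, seed = 2)
  expect_true(all(e$cis_count >= 0 & e$cis_count <= 6))
  # proline phi clamped near -65 in every conformer
  pro <- strsplit(s, "")[[1]] == "P"
  expect_true(all(abs(e$phi[, pro] + 65) < 40))
})

test_that("ensembles are reproducible, sized as requested, and clash-free", {
  s <- synthetic_cassd(seed = 1)
  short <- substr(s, 1, 80)
  e1 <- generate_ensemble(short, "coil", n = 25, seed = 5)
  e2 <- generate_ensemble(short, "coil", n = 25, seed = 5)
  expect_identical(e1$phi, e2$phi)
  expect_identical(e1$rgyr, e2$rgyr)
  expect_equal(e1$n, 25)
  expect_true(e1$acceptance_rate > 0 && e1$acceptance_rate <= 1)

  e3 <- generate_ensemble(short, "coil", n = 25, seed = 6)
  expect_false(identical(e1$phi, e3$phi))

  # singleton ensemble is a valid conformer
  e4 <- generate_ensemble(short, "beta", n = 1, seed = 1)
  cf <- conformer(e4, 1)
  expect_equal(nrow(cf), 80)

  # independent all-pairs scan: no accepted conformer violates the clash rule
  for (i in seq_len(10)) {
    co <- build_backbone(conformer(e1, i))
    ca <- as.matrix(co[co$atom == "CA", c("x", "y", "z")])
    dm <- as.matrix(stats::dist(ca))
    sep <- abs(outer(seq_len(nrow(ca)), seq_len(nrow(ca)), `-`))
    expect_gte(min(dm[sep >= 3]), 4)
  }

  # cached radii match the R-level radius over backbone atoms
  co1 <- build_backbone(conformer(e1, 1))
  expect_equal(radius_of_gyration(as.matrix(co1[, c("x", "y", "z")])),
               e1$rgyr[1], tolerance = 1e-8)
})

test_that("threestate preset demands a profile and uses it", {
  s <- substr(synthetic_cassd(1), 1, 60)
  expect_error(generate_ensemble(s, "threestate", n = 2, seed = 1),
               "profile")
  pr <- gen_threestate_profile(60, seed = 1)
  e <- generate_ensemble(s, "threestate", n = 5, seed = 1, profile = pr)
  expect_equal(e$n, 5)
})

test_that("multi-model PDB output is well-formed", {
  s <- substr(synthetic_cassd(1), 1, 30)
  e <- generate_ensemble(s, "coil", n = 3, seed = 1)
  path <- tempfile(fileext = ".pdb")
  write_pdb_ensemble(e, path, models = 1:3)
  lines <- readLines(path)
  expect_equal(sum(grepl("^MODEL", lines)), 3)
  expect_equal(sum(grepl("^ENDMDL", lines)), 3)
  atoms <- lines[grepl("^ATOM", lines)]
  expect_equal(length(atoms), 3 * 4 * 30)
  # fixed-width coordinate fields parse back to numbers
  x <- as.numeric(substr(atoms[1], 31, 38))
  expect_false(is.na(x))
})
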