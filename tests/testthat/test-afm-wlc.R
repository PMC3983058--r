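test_that("Marko-Siggia force matches direct evaluation everywhere", {
  expect_equal(wlc_force(0, 100, 0.4), 0)
  # x/L = 0.5, p = 0.4 nm, T = 298 K -> 1.25 kBT/p = 12.9 pN
  expect_equal(wlc_force(50, 100, 0.4), 12.9, tolerance = 0.05)
  expect_error(wlc_force(100, 100, 0.4), "diverges")
  expect_error(wlc_force(-1, 100, 0.4))

  # strictly increasing, divergent near L
  x <- seq(0, 99, by = 0.5)
  f <- wlc_force(x, 100, 0.4)
  expect_true(all(diff(f) > 0))
  expect_gt(wlc_force(99.99, 100, 0.4), 1e4)

  # independently written symbolic form at random (x, L, p)
  set.seed(3)
  n <- 1e5
  L <- runif(n, 10, 300)
  xx <- runif(n) * 0.98 * L
  p <- runif(n, 0.1, 2)
  kbt <- 0.0138064852 * 298
  ref <- kbt / p * (0.25 * (1 - xx / L)^-2 - 0.25 + xx / L)
  got <- wlc_force(xx, L, p) # vectorized over x only when L, p match length
  expect_equal(got, ref, tolerance = 1e-12)
})

test_that("peak detection finds scripted events and applies the 15 pN floor", {
  tr <- gen_afm_trace(c(28, 28), c(150, 160), noise_sd = 0)
  pk <- detect_peaks(tr)
  expect_equal(nrow(pk), 2)
  expect_equal(sort(pk$force), c(150, 160), tolerance = 2)

  # monotone trace: no unfolding peaks
  mono <- tibble::tibble(extension = 1:100,
                         force = seq(0, 50, length.out = 100))
  expect_equal(nrow(detect_peaks(mono)), 0)

  # an event below the 15 pN detection limit is suppressed at defaults
  tr_weak <- gen_afm_trace(c(30, 28, 28), c(12, 150, 160), noise_sd = 0)
  pk_weak <- detect_peaks(tr_weak)
  expect_equal(nrow(pk_weak), 2)
  expect_true(all(pk_weak$force > 100))
})

test_that("WLC fits recover contour-length increments on clean traces", {
  tr <- gen_afm_trace(c(28, 28), c(150, 160), noise_sd = 0)
  ev <- fit_wlc_events(tr)
  expect_equal(nrow(ev), 2)
  expect_true(all(ev$converged))
  expect_true(all(abs(ev$dL - 28) < 0.5))

  # fixed persistence length mode
  ev_fixed <- fit_wlc_events(tr, p_fixed = 0.4)
  expect_true(all(ev_fixed$p == 0.4))
  expect_true(all(abs(ev_fixed$dL - 28) < 0.5))

  # a trace truncated at its single peak has no Delta-L reference
  tr1 <- gen_afm_trace(28, 120, noise_sd = 0)
  pk1 <- detect_peaks(tr1)
  cut <- tr1[tr1$extension <= pk1$extension[1], ]
  class(cut) <- class(tr1)
  ev1 <- fit_wlc_events(cut, pk1[1, ])
  expect_equal(nrow(ev1), 1)
  expect_true(is.na(ev1$dL))
})

test_that("contour and persistence recover within 5% clean, 10% at 5 pN noise", {
  # noiseless
  tr <- gen_afm_trace(c(28), c(140), noise_sd = 0)
  ev <- fit_wlc_events(tr)
  expect_lt(abs(ev$L[1] - 60) / 60, 0.05)
  expect_lt(abs(ev$p[1] - 0.4) / 0.4, 0.05)

  # 100 seeded noisy replicates: mean recovery within 10%, dL within 1 nm
  fits <- lapply(1:100, function(s) {
    trn <- gen_afm_trace(c(28, 28), c(150, 160), noise_sd = 5, seed = s)
    pk <- detect_peaks(trn, smooth = 5)
    if (nrow(pk) != 2) return(NULL)
    fit_wlc_events(trn, pk)
  })
  fits <- fits[!vapply(fits, is.null, TRUE)]
  expect_gt(length(fits), 90)
  L1 <- vapply(fits, function(e) e$L[1], numeric(1))
  p1 <- vapply(fits, function(e) e$p[1], numeric(1))
  dL <- unlist(lapply(fits, function(e) e$dL[!is.na(e$dL)]))
  expect_lt(abs(mean(L1) - 60) / 60, 0.10)
  expect_lt(abs(mean(p1) - 0.4) / 0.4, 0.10)
  expect_lt(abs(mean(dL) - 28), 1)
})

test_that("I27-signature gating classifies traces exactly", {
  mk_ev <- function(f, dl) {
    tibble::tibble(peak_extension = seq_along(f) * 30, peak_force = f,
                   L = cumsum(c(60, dl))[seq_along(f)],
                   p = 0.4, dL = dl, converged = TRUE)
  }
  # two I27 events only -> type1
  expect_equal(classify_trace(mk_ev(c(150, 160), c(28, 28)))$label, "type1")
  # two I27 plus a weak CasSD feature -> type2
  t2 <- classify_trace(mk_ev(c(40, 150, 160), c(45, 28, 28)))
  expect_equal(t2$label, "type2")
  expect_equal(nrow(t2$i27_events), 2)
  expect_equal(nrow(t2$other_events), 1)
  # one I27 -> rejected
  expect_equal(classify_trace(mk_ev(c(150), c(28)))$label, "rejected")
  # boundary gating: dL exactly at 26/30 is in, outside the band is out
  expect_equal(classify_trace(mk_ev(c(150, 150), c(26, 30)))$label, "type1")
  expect_equal(classify_trace(mk_ev(c(150, 150), c(25.9, 28)))$label,
               "rejected")
  expect_equal(classify_trace(mk_ev(c(150, 150), c(30.1, 28)))$label,
               "rejected")
  # force must exceed 100 pN
  expect_equal(classify_trace(mk_ev(c(100, 150), c(28, 28)))$label,
               "rejected")

  # invariant to event ordering
  ev <- mk_ev(c(40, 150, 160), c(45, 28, 28))
  expect_equal(classify_trace(ev[c(3, 1, 2), ])$label, "type2")
})

test_that("generator round trip: simulated polyprotein traces gate correctly", {
  # two I27 domains -> type1
  tr <- gen_afm_trace(c(28, 28), c(150, 160), noise_sd = 0)
  cl <- classify_trace(fit_wlc_events(tr))
  expect_equal(cl$label, "type1")

  # two I27 plus one weak broad event -> type2
  tr2 <- gen_afm_trace(c(40, 28, 28), c(45, 150, 160), noise_sd = 0)
  cl2 <- classify_trace(fit_wlc_events(tr2))
  expect_equal(cl2$label, "type2")
  expect_equal(nrow(cl2$i27_events), 2)
})

test_that("uncorrelated synthetic events show near-zero force/dL correlation", {
  set.seed(17)
  ev <- tibble::tibble(
    peak_extension = runif(1000, 20, 200),
    peak_force = runif(1000, 30, 120),
    L = NA_real_, p = 0.4,
    dL = runif(1000, 5, 120), converged = TRUE
  )
  st <- event_scatter_stats(ev)
  expect_lt(abs(st$r), 0.1)
  expect_gte(st$force_min, 30)
  expect_lte(st$force_max, 120)
  expect_gte(st$dl_min, 5)
  expect_lte(st$dl_max, 120)

  lin <- tibble::tibble(peak_force = 1:10, dL = 2 * (1:10))
  expect_equal(event_scatter_stats(lin)$r, 1)
  expect_error(event_scatter_stats(lin[1:2, ]), "at least 3")
})

test_that("trace TSV round trip preserves the data", {
  tr <- gen_afm_trace(c(28), c(120), noise_sd = 2, seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_trace_tsv(tr, path)
  back <- read_trace_tsv(path)
  expect_equal(back$extension, tr$extension, tolerance = 1e-9)
  expect_equal(back$force, tr$force, tolerance = 1e-9)
})
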