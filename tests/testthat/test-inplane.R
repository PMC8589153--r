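test_that("hexagonal spacing and area-per-tail relations are exact", {
  expect_equal(tail_spacing(4 * pi / sqrt(3)), 1, tolerance = 1e-12)
  expect_equal(tail_spacing(1.727), 4.201, tolerance = 1e-3)
  expect_equal(tail_spacing(0.700), 10.365, tolerance = 1e-3)
  expect_equal(area_per_tail(1), sqrt(3) / 2, tolerance = 1e-12)
  # printed-table identities: a -> A_T
  expect_equal(area_per_tail(4.69), 19.04, tolerance = 5e-3)
  expect_equal(area_per_tail(5.413), 25.38, tolerance = 5e-3)
  expect_error(tail_spacing(0), class = "rbcmem_invalid_parameter")
  expect_error(area_per_tail(-1), class = "rbcmem_invalid_parameter")
  # monotonicity: A_T increasing in a, a decreasing in q
  a <- seq(3, 8, by = 0.5)
  expect_true(all(diff(area_per_tail(a)) > 0))
  expect_true(all(diff(tail_spacing(seq(0.5, 2, by = 0.1))) < 0))
})

test_that("Scherrer sizing matches the chained closed form and its limits", {
  lam <- 1.5418
  w <- 0.20; qc <- 1.35
  th <- asin(qc * lam / (4 * pi))
  b2 <- w * lam / (2 * pi * cos(th))
  expect_equal(scherrer_size(w, qc, lam), 0.94 * lam / (b2 * cos(th)),
               tolerance = 1e-12)
  # halving the width doubles the size
  expect_equal(scherrer_size(w / 2, qc, lam), 2 * scherrer_size(w, qc, lam),
               tolerance = 1e-12)
  # small-angle limit: L -> 0.94 * 2 pi / width
  expect_equal(scherrer_size(0.05, 0.05, lam), 0.94 * 2 * pi / 0.05,
               tolerance = 5e-3)
  expect_error(scherrer_size(0.2, 4 * pi / lam, lam),
               class = "rbcmem_invalid_parameter")
})

test_that("background correction removes polynomials and is idempotent", {
  q <- seq(0.35, 2.2, length.out = 500)
  qc <- (q - mean(q)) / diff(range(q))
  pat <- tibble::tibble(q_par = q, intensity = 30 + 12 * qc)
  class(pat) <- c("inplane_pattern", class(pat))
  corr <- correct_background(pat)
  expect_lt(max(abs(corr$intensity)), 1e-9)
  expect_true(attr(corr, "background_corrected"))
  corr2 <- correct_background(corr)
  expect_equal(corr2$intensity, corr$intensity, tolerance = 1e-9)
  expect_error(correct_background(pat, anchors = list(c(5, 6))),
               class = "rbcmem_invalid_parameter")
  expect_error(correct_background(pat, degree = 4),
               class = "rbcmem_invalid_parameter")
})

test_that("three-peak decomposition recovers the synthetic triplet", {
  pk <- ref_inplane_peaks()
  pat <- gen_inplane_pattern(pk, background = c(80, -30), noise_seed = NULL)
  st <- fit_three_peaks(correct_background(pat))
  expect_identical(st$component, c("protein", "l_d", "l_o"))
  expect_equal(st$q_center, pk$center, tolerance = 0.005 / 0.7)
  expect_equal(st$area, pk$area, tolerance = 0.02)
  # lattice annotations follow the hexagonal relations
  expect_equal(st$a, tail_spacing(st$q_center), tolerance = 1e-12)
  expect_equal(st$area_per_tail, area_per_tail(st$a), tolerance = 1e-12)
  # noisy pattern: centers within 0.005 1/angstrom
  patn <- gen_inplane_pattern(pk, background = c(80, -30), noise_seed = 4)
  stn <- fit_three_peaks(correct_background(patn))
  expect_true(all(abs(stn$q_center - pk$center) < 0.005))
  # missing l_o peak: near-zero area, no crash
  pk0 <- ref_inplane_peaks(area_lo = 0.001)
  st0 <- fit_three_peaks(correct_background(
    gen_inplane_pattern(pk0, background = c(10, 0), noise_seed = NULL)))
  expect_lt(st0$area[st0$component == "l_o"],
            0.05 * st0$area[st0$component == "l_d"])
})

test_that("domain fractions exclude the protein peak and rescale exactly", {
  st <- tibble::tibble(component = c("protein", "l_d", "l_o"),
                       area = c(500, 10, 10))
  fr <- domain_fractions(st)
  expect_equal(fr$pct_ld, 50)
  expect_equal(fr$pct_lo, 50)
  st2 <- st; st2$area <- c(1, 3, 2)
  fr2 <- domain_fractions(st2)
  expect_equal(fr2$pct_ld, 60)
  expect_equal(fr2$pct_lo, 40)
  expect_equal(fr2$pct_ld + fr2$pct_lo, 100, tolerance = 1e-12)
  # invariant to global rescaling
  st3 <- st2; st3$area <- st3$area * 1e4
  expect_equal(domain_fractions(st3), fr2, tolerance = 1e-12)
  st4 <- st; st4$area <- c(5, 0, 0)
  expect_error(domain_fractions(st4), class = "rbcmem_degenerate")
})

test_that("the full in-plane pipeline recovers ground truth within 2%", {
  pk <- ref_inplane_peaks(area_ld = 2700, area_lo = 2300)
  pat <- gen_inplane_pattern(pk, background = c(60, -20), noise_seed = 9,
                             q_grid = seq(0.35, 2.2, length.out = 900))
  st <- fit_three_peaks(correct_background(pat))
  truth_a <- tail_spacing(pk$center[2:3])
  expect_equal(st$a[st$component %in% c("l_d", "l_o")], truth_a,
               tolerance = 0.02)
  truth_L <- vapply(2:3, function(i) {
    scherrer_size(rbcmem:::sigma_to_fwhm(pk$sigma[i]), pk$center[i])
  }, numeric(1))
  expect_equal(st$scherrer_size[st$component %in% c("l_d", "l_o")], truth_L,
               tolerance = 0.02)
  fr <- domain_fractions(st)
  expect_equal(fr$pct_ld, 54, tolerance = 0.02)
  expect_equal(fr$pct_lo, 46, tolerance = 0.02)
})
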