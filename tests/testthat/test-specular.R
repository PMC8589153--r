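test_that("reflectivity extraction integrates the meridional band", {
  # separable synthetic map: I = f(qz) g(qpar) -> curve proportional to f
  qp <- seq(-0.1, 0.1, length.out = 41)
  qz <- seq(0.05, 0.6, length.out = 50)
  f <- exp(-(qz - 0.3)^2 / 0.002)
  g <- 1 + cos(qp * 10)
  map <- intensity_map(qp, qz, outer(f, g))
  refl <- extract_reflectivity(map, 0.05)
  expect_equal(refl$intensity / max(refl$intensity), f / max(f),
               tolerance = 1e-10)
  # all-zero map -> all-zero curve
  map0 <- intensity_map(qp, qz, matrix(0, 50, 41))
  expect_true(all(extract_reflectivity(map0, 0.05)$intensity == 0))
  expect_error(extract_reflectivity(map, 5),
               class = "rbcmem_invalid_parameter")
})

test_that("lamellar peak finder recovers d and handles degenerate input", {
  # noise-free Gaussian peaks at n * 0.1104 -> d = 2 pi / 0.1104
  qz <- seq(0.02, 0.6, length.out = 1200)
  y <- rowSums(vapply(1:4, function(n) {
    1000 / n * exp(-(qz - n * 0.1104)^2 / (2 * 0.004^2))
  }, numeric(length(qz)))) + 1
  peaks <- find_lamellar_peaks(tibble::tibble(q_z = qz, intensity = y))
  expect_equal(d_spacing(peaks), 2 * pi / 0.1104, tolerance = 1e-4)
  expect_equal(peaks$order, 1:4)
  # single order: d = 2 pi / q1
  y1 <- 1000 * exp(-(qz - 0.1)^2 / (2 * 0.004^2)) + 1
  p1 <- find_lamellar_peaks(tibble::tibble(q_z = qz, intensity = y1))
  expect_equal(d_spacing(p1), 62.83, tolerance = 1e-3)
  # featureless curve: empty set with a warning, not an exception
  expect_warning(
    pf <- find_lamellar_peaks(tibble::tibble(q_z = qz,
                                             intensity = rep(1, length(qz)))),
    "noise floor")
  expect_equal(nrow(pf), 0)
})

test_that("d from the multi-order fit is invariant to intensity rescaling", {
  qz <- seq(0.02, 0.6, length.out = 1200)
  y <- rowSums(vapply(1:4, function(n) {
    1000 / n * exp(-(qz - n * 0.1134)^2 / (2 * 0.004^2))
  }, numeric(length(qz)))) + 1
  p1 <- find_lamellar_peaks(tibble::tibble(q_z = qz, intensity = y))
  p2 <- find_lamellar_peaks(tibble::tibble(q_z = qz, intensity = 37.5 * y))
  expect_equal(d_spacing(p1), d_spacing(p2), tolerance = 1e-6)
})

test_that("Hermans orientation reproduces its limits and a quadrature oracle", {
  dm <- density_model(head_position = 20, d = 55.4)
  q1 <- 2 * pi / 55.4
  # sharply oriented stack -> H near 1
  sc <- synth_scene(dm, mosaic_width = 0.4, resolution_width = 0.004,
                    n_orders = 2)
  map <- gen_lamellar_map(sc, noise = FALSE, n_par = 401,
                          q_par_range = c(-0.15, 0.15))
  H_sharp <- hermans_h(hermans_orientation(map, q1))
  expect_equal(H_sharp, 1, tolerance = 1e-3)
  # sigma = 15 degrees: against direct numeric quadrature
  sc15 <- synth_scene(dm, mosaic_width = 15, resolution_width = 0.004,
                      n_orders = 2)
  map15 <- gen_lamellar_map(sc15, noise = FALSE, n_par = 401,
                            q_par_range = c(-0.15, 0.15))
  prof <- hermans_orientation(map15, q1)
  f <- function(p) exp(-(rad2deg <- p * 180 / pi)^2 / (2 * 15^2))
  num <- integrate(function(p) cos(p)^2 * f(p) * sin(p), 0, pi / 2)$value
  den <- integrate(function(p) f(p) * sin(p), 0, pi / 2)$value
  expect_equal(hermans_h(prof), (3 * num / den - 1) / 2, tolerance = 1e-3)
  # isotropic profile -> H = 0 (raw integration path)
  qp <- seq(-0.15, 0.15, length.out = 301)
  qzg <- seq(0.02, 0.2, length.out = 301)
  iso <- intensity_map(qp, qzg, matrix(1, 301, 301))
  expect_equal(hermans_h(hermans_orientation(iso, 0.11, method = "raw")), 0,
               tolerance = 1e-6)
  # H invariant to intensity scaling
  map2 <- intensity_map(map15$q_par, map15$q_z, map15$intensity * 123)
  expect_equal(hermans_h(hermans_orientation(map2, q1)), hermans_h(prof),
               tolerance = 1e-9)
})

test_that("form-factor phase handling follows the head-group conventions", {
  dm <- density_model(head_position = 21.5, d = 55.4)
  truth <- model_peak_intensities(dm, 5)
  peaks <- tibble::tibble(order = truth$order, q = truth$q,
                          intensity = truth$intensity)
  # default phase array for 5 orders
  ff <- fit_form_factor(peaks, d = 55.4)
  expect_identical(ff$phases, c(-1L, -1L, 1L, -1L, 1L))
  # enumeration recovers the generating signs
  ffe <- fit_form_factor(peaks, enumerate = TRUE, d = 55.4)
  expect_identical(ffe$phases, as.integer(truth$nu))
  # single order picks nu = -1 (head maxima away from the centre)
  p1 <- peaks[1, ]
  ff1 <- fit_form_factor(p1, enumerate = TRUE, d = 55.4)
  expect_identical(ff1$phases, -1L)
  # T(q_z) interpolates the signed amplitudes at the Bragg points
  expect_equal(ff$fun(truth$q), truth$form_factor, tolerance = 1e-6)
  expect_error(fit_form_factor(peaks, phases = c(1, 1)),
               class = "rbcmem_invalid_parameter")
})

test_that("Fourier density reconstruction is symmetric, normalised and measures d_HH", {
  dm <- density_model(head_position = 21.5, d = 55.4)
  truth <- model_peak_intensities(dm, 5)
  peaks <- tibble::tibble(order = truth$order, q = truth$q,
                          intensity = truth$intensity)
  prof <- fourier_density(peaks, truth$nu, d = 55.4)
  expect_equal(prof$rho, rev(prof$rho), tolerance = 1e-9)   # rho(z) = rho(-z)
  expect_equal(prof$rho[which.min(abs(prof$z))], 0, tolerance = 1e-12)
  expect_equal(prof$rho[1], 1, tolerance = 1e-12)
  # d_HH against dense evaluation of the truncated cosine series
  zg <- seq(0, 55.4 / 2, length.out = 40001)
  series <- drop(cos(2 * pi * outer(zg, 1:5) / 55.4) %*% truth$form_factor)
  d_hh_oracle <- 2 * zg[which.max(series)]
  expect_equal(attr(prof, "d_hh"), d_hh_oracle, tolerance = 1e-3)
  expect_equal(attr(prof, "water_layer"), 55.4 - attr(prof, "d_hh"),
               tolerance = 1e-9)
  # single order, nu = -1: maxima at the boundaries
  p1 <- peaks[1, ]
  prof1 <- fourier_density(p1, -1, d = 55.4)
  expect_equal(abs(prof1$z[which.max(prof1$rho)]), 55.4 / 2, tolerance = 0.2)
})

test_that("water layer arithmetic reproduces the stored-sample values", {
  # d = 56.9 with d_HH = 46 -> 10.9 angstrom water layer
  expect_equal(56.9 - 46, 10.9, tolerance = 1e-12)
  # full reconstruction route: scene built at the 2-week geometry
  dm <- density_model(head_position = 23, d = 56.9)
  sc <- synth_scene(dm, mosaic_width = 0.5, resolution_width = 0.003,
                    n_orders = 5, counts_scale = 1e6)
  map <- gen_lamellar_map(sc, noise = FALSE)
  peaks <- find_lamellar_peaks(extract_reflectivity(map, 0.05))
  expect_equal(d_spacing(peaks), 56.9, tolerance = 0.01)
  prof <- fourier_density(peaks, fit_form_factor(peaks, enumerate = TRUE)$phases)
  expect_equal(attr(prof, "water_layer"),
               d_spacing(peaks) - attr(prof, "d_hh"), tolerance = 1e-9)
})
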