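test_that("the transform convention satisfies Parseval-style closed forms", {
  # single pure cosine mode of amplitude c: under H_q = (dx^2/sqrt(A)) FFT,
  # |H_q|^2 at the mode = (c/2)^2 * A
  g <- 32; L <- 320
  x <- (0:(g - 1)) * L / g
  cmod <- 1.7
  h <- cmod * cos(2 * pi * 3 * outer(x, rep(1, g)) / L)
  Hq <- rbcmem:::height_transform(h, L)
  p <- Mod(Hq)^2
  expect_equal(p[4, 1], (cmod / 2)^2 * L^2, tolerance = 1e-9)
  expect_equal(p[g - 2, 1], (cmod / 2)^2 * L^2, tolerance = 1e-9)
  expect_lt(sum(p) - 2 * (cmod / 2)^2 * L^2, 1e-6)
})

test_that("leaflet gridding reproduces planes, cosines and handles degeneracies", {
  set.seed(4)
  box <- c(320, 320)
  n <- 3000
  fr <- tibble::tibble(x = runif(n, 0, 320), y = runif(n, 0, 320),
                       z = 7.5, leaflet = "upper", role = "head",
                       time_ns = 200)
  h <- leaflet_surface(fr, 32, "upper", box)
  expect_equal(as.vector(h), rep(7.5, 32^2), tolerance = 1e-12)
  # cosine field
  fr2 <- fr
  fr2$z <- 3 * cos(2 * pi * fr2$x / 320)
  h2 <- leaflet_surface(fr2, 32, "upper", box)
  xg <- (0:31) * 10
  expect_equal(rowMeans(h2), 3 * cos(2 * pi * xg / 320), tolerance = 0.15)
  # duplicate positions average deterministically
  fr3 <- tibble::tibble(x = c(5, 5, rep(seq(20, 300, by = 20), 2)),
                        y = c(5, 5, rep(seq(20, 300, by = 20), 2)),
                        z = c(0, 10, rep(1, 30)),
                        leaflet = "upper", role = "head", time_ns = 200)
  h3a <- leaflet_surface(fr3, 16, "upper", box)
  h3b <- leaflet_surface(fr3, 16, "upper", box)
  expect_identical(h3a, h3b)
  expect_equal(h3a[1, 1], 5)   # mean of the two duplicate beads
  # collinear beads are rejected
  fr4 <- tibble::tibble(x = seq(10, 100, by = 10), y = 50, z = 1,
                        leaflet = "upper", role = "head", time_ns = 200)
  expect_error(leaflet_surface(fr4, 16, "upper", box),
               class = "rbcmem_degenerate")
  expect_error(leaflet_surface(fr4[1:2, ], 16, "upper", box),
               class = "rbcmem_invalid_parameter")
})

test_that("mid-plane field averages leaflets and removes the mean", {
  u <- matrix(rnorm(64), 8, 8)
  expect_equal(midplane_field(u, -u), matrix(0, 8, 8))
  m <- midplane_field(u, u)
  expect_equal(m, u - mean(u), tolerance = 1e-12)
  expect_equal(mean(m), 0, tolerance = 1e-12)
  expect_error(midplane_field(u, matrix(0, 4, 4)),
               class = "rbcmem_invalid_parameter")
})

test_that("spectra vanish for flat membranes and antisymmetric thickness modes", {
  traj <- make_flat_trajectory()
  sp <- spectrum(traj, grid_n = 16)
  expect_lt(max(sp$power), 1e-12)
  # thickness-fluctuation-only: upper = -lower + noise -> tiny low-q power
  set.seed(8)
  frames <- lapply(1:12, function(i) {
    n <- 400
    x <- runif(n, 0, 320); y <- runif(n, 0, 320)
    thick <- 4 * cos(2 * pi * x / 320)
    dplyr::bind_rows(
      tibble::tibble(x = x, y = y, z = 20 + thick, leaflet = "upper",
                     role = "head", time_ns = 200 + (i - 1) * 4),
      tibble::tibble(x = x, y = y, z = -20 - thick, leaflet = "lower",
                     role = "head", time_ns = 200 + (i - 1) * 4))
  })
  traj2 <- structure(list(frames = frames, box = c(320, 320),
                          frame_interval = 4), class = "bead_trajectory")
  sp2 <- spectrum(traj2, grid_n = 16)
  expect_lt(sp2$power[1], 1e-6)
})

test_that("the spectrum is invariant to rigid z-translation", {
  traj <- gen_height_trajectory(3.2, box_side = 320, grid_n = 32,
                                n_frames = 15, seed = 21)
  shifted <- traj
  shifted$frames <- lapply(traj$frames, function(f) {
    f$z <- f$z + 133.7
    f
  })
  s1 <- spectrum(traj, grid_n = 32)
  s2 <- spectrum(shifted, grid_n = 32)
  expect_equal(s1$power, s2$power, tolerance = 1e-9)
})

test_that("Helfrich fit inverts exact spectra and flags the regime", {
  q <- seq(0.02, 0.09, by = 0.01)
  spec <- tibble::tibble(q = q, power = 1 / (5.3 * q^4),
                         n_modes = rep(8L, length(q)))
  class(spec) <- c("fluctuation_spectrum", class(spec))
  attr(spec, "n_frames") <- 100
  fit <- fit_hc(spec)
  expect_equal(fit$kappa, 5.3, tolerance = 1e-9)
  expect_false(fit$out_of_regime)
  expect_true(fit_hc(spec, q_max = 0.15)$out_of_regime)
  expect_error(fit_hc(spec[1:3, ]), class = "rbcmem_invalid_parameter")
})

test_that("doubling the frame count shrinks the spectral scatter by about sqrt(2)", {
  # spread of log power across seeds at fixed q-bin
  pow_at <- function(n_frames, seed) {
    traj <- gen_height_trajectory(3.2, box_side = 320, grid_n = 32,
                                  n_frames = n_frames, seed = seed)
    spectrum(traj, grid_n = 32)$power[2]
  }
  p1 <- vapply(1:8, function(s) pow_at(25, s), numeric(1))
  p2 <- vapply(1:8, function(s) pow_at(50, s + 100), numeric(1))
  ratio <- sd(log(p1)) / sd(log(p2))
  expect_gt(ratio, 0.9)
  expect_lt(ratio, 2.4)
})

test_that("equilibration frames are discarded and starved spectra error out", {
  traj <- gen_height_trajectory(3.2, box_side = 320, grid_n = 32,
                                n_frames = 30, start_ns = 100, seed = 2)
  sp <- spectrum(traj, grid_n = 32, discard_before = 140)
  expect_equal(attr(sp, "n_frames"), sum(vapply(traj$frames, function(f)
    f$time_ns[1], numeric(1)) >= 140))
  expect_error(spectrum(traj, grid_n = 32, discard_before = 1e5),
               class = "rbcmem_invalid_parameter")
})
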