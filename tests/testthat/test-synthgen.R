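test_that("lamellar map places Bragg orders at n 2pi/d with form-factor intensities", {
  dm <- density_model(head_position = 20, d = 55.4)
  sc <- synth_scene(dm, mosaic_width = 0.5, resolution_width = 0.003,
                    n_orders = 4, counts_scale = 1e6)
  map <- gen_lamellar_map(sc, noise = FALSE)
  refl <- extract_reflectivity(map, 0.05)
  # first peak position
  q1 <- 2 * pi / 55.4
  expect_equal(refl$q_z[which.max(refl$intensity)], q1, tolerance = 0.02)
  peaks <- find_lamellar_peaks(refl)
  expect_equal(nrow(peaks), 4)
  expect_equal(peaks$q, (1:4) * q1, tolerance = 1e-3)
  # noise-free round trip: I_n q_n proportional to F(q_n)^2
  truth <- model_peak_intensities(dm, 4)
  ratio <- (peaks$intensity * peaks$q) / (truth$form_factor^2)
  expect_lt(diff(range(ratio)) / mean(ratio), 0.05)
})

test_that("noise-free maps are deterministic and independent of the noise seed", {
  sc1 <- synth_scene(noise_seed = 1L)
  sc2 <- synth_scene(noise_seed = 999L)
  m1 <- gen_lamellar_map(sc1, noise = FALSE)
  m2 <- gen_lamellar_map(sc2, noise = FALSE)
  expect_identical(m1$intensity, m2$intensity)
  # Poisson sampling is reproducible under a fixed seed
  n1 <- gen_lamellar_map(sc1, noise = TRUE)
  n2 <- gen_lamellar_map(sc1, noise = TRUE)
  expect_identical(n1$intensity, n2$intensity)
})

test_that("invalid scene parameters are rejected", {
  expect_error(density_model(head_position = 30, d = 55),
               class = "rbcmem_invalid_parameter")
  expect_error(synth_scene(counts_scale = -1),
               class = "rbcmem_invalid_parameter")
  expect_error(synth_scene(mosaic_width = 0),
               class = "rbcmem_invalid_parameter")
})

test_that("diffuse-cut generator records ground truth and respects the noise contract", {
  stk <- smectic_stack(1.9, 1.2e-5, 56, n_layers = 100)
  cuts <- gen_diffuse_cuts(stk, noise_level = 0, seed = 1,
                           qr_grid = seq(0.005, 0.04, by = 0.005))
  expect_length(cuts, 2)
  # zero noise: cuts equal the analytic structure factor exactly
  model <- caille_model(1.9, 1.2e-5, 56, n_layers = 100, r_domain = 2000)
  S <- structure_factor(model, attr(cuts[[1]], "q_z"), cuts[[1]]$q_r,
                        cache = rbcmem:::caille_sf_cache(
                          cuts[[1]]$q_r, r_max = 48 * 2000))
  expect_equal(cuts[[1]]$intensity, S, tolerance = 1e-10)
  # both cuts carry the same ground truth
  expect_identical(attr(cuts[[1]], "ground_truth"),
                   attr(cuts[[2]], "ground_truth"))
  expect_equal(attr(cuts[[1]], "ground_truth")$kappa, 1.9)
  expect_error(gen_diffuse_cuts(stk, qz_factors = numeric()),
               class = "rbcmem_invalid_parameter")
})

test_that("stiffening the stack reduces the far diffuse tail of the 2 q1 cut", {
  qr_tail <- seq(0.025, 0.05, by = 0.005)
  qz <- 2 * 2 * pi / 56
  S_soft <- structure_factor(caille_model(1.9, 1.2e-5, 56), qz, qr_tail)
  S_stiff <- structure_factor(caille_model(3.8, 1.2e-5, 56), qz, qr_tail)
  expect_true(all(S_stiff < S_soft))
})

test_that("height-field generator obeys the Helfrich q^-4 spectrum", {
  traj <- gen_height_trajectory(kappa = 3.2, box_side = 340, grid_n = 64,
                                n_frames = 200, seed = 7)
  sp <- spectrum(traj, grid_n = 64)
  fit <- fit_hc(sp, free_slope = TRUE)
  expect_equal(fit$slope, -4, tolerance = 0.05)  # tolerance on -4 +/- 0.2
  # identical seeds give identical trajectories
  t2 <- gen_height_trajectory(kappa = 3.2, box_side = 340, grid_n = 64,
                              n_frames = 2, seed = 11)
  t3 <- gen_height_trajectory(kappa = 3.2, box_side = 340, grid_n = 64,
                              n_frames = 2, seed = 11)
  expect_identical(t2$frames, t3$frames)
  expect_error(gen_height_trajectory(kappa = 0),
               class = "rbcmem_invalid_parameter")
})

test_that("in-plane pattern generator is exact without noise and keeps truth metadata", {
  pk <- ref_inplane_peaks()
  pat <- gen_inplane_pattern(pk, background = c(40, -10), noise_seed = NULL)
  # analytic sum reproduced exactly
  q <- pat$q_par
  qc <- (q - mean(q)) / diff(range(q))
  expected <- 40 - 10 * qc
  for (i in 1:3) {
    expected <- expected + pk$area[i] / (pk$sigma[i] * sqrt(2 * pi)) *
      exp(-(q - pk$center[i])^2 / (2 * pk$sigma[i]^2))
  }
  expect_equal(pat$intensity, pmax(expected, 0), tolerance = 1e-12)
  expect_false(attr(pat, "background_corrected"))
  expect_error(gen_inplane_pattern(tibble::tibble(center = 5, sigma = 1,
                                                  area = 10)),
               class = "rbcmem_invalid_parameter")
})

test_that("lipidomics generator reproduces the fresh/stored signatures", {
  fresh <- gen_lipidomics_table(seed = 3)
  stored <- gen_lipidomics_table(storage_shift = TRUE, seed = 3)
  fa_fresh <- sum(fresh$abundance_pct[fresh$lipid_class == "FA"])
  fa_stored <- sum(stored$abundance_pct[stored$lipid_class == "FA"])
  expect_lt(fa_fresh, 1)
  expect_equal(fa_stored, 5, tolerance = 0.2)
  expect_equal(sum(fresh$abundance_pct), 100, tolerance = 1e-9)
  expect_equal(sum(stored$abundance_pct), 100, tolerance = 1e-9)
  expect_error(gen_lipidomics_table(n_species = 3),
               class = "rbcmem_invalid_parameter")
})
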