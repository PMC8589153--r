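test_that("Caille parameter and correlation length follow the defining relations", {
  p <- caille_params(1, 1, 1)
  expect_equal(p$eta, 1 / (8 * pi), tolerance = 1e-12)
  expect_equal(p$xi, 1, tolerance = 1e-12)
  expect_equal(caille_params(16, 1, 1)$xi, 2, tolerance = 1e-12)
  # algebraic inverse: eta * 8 pi sqrt(B kappa) / q1^2 == 1 (kBT units)
  p2 <- caille_params(1.9, 1.2e-5, 0.112)
  expect_equal(p2$eta * 8 * pi * sqrt(1.9 * 1.2e-5) / 0.112^2, 1,
               tolerance = 1e-12)
})

test_that("layer-index lattice Green's function matches numeric Brillouin-zone quadrature", {
  # z^n / sqrt(a (a + 4B)) vs direct integration of cos(n theta) /
  # (a + 2B (1 - cos theta)) over the zone
  for (a in c(1e-7, 1e-4, 0.1)) {
    B <- 1.2e-5
    root <- sqrt(a * (a + 4 * B))
    z <- 2 * B / (a + 2 * B + root)
    for (n in c(0, 1, 5, 40)) {
      ref <- integrate(function(th) cos(n * th) / (a + 2 * B * (1 - cos(th))),
                       0, pi, rel.tol = 1e-9, subdivisions = 2000L)$value / pi
      expect_equal(z^n / root, ref, tolerance = 1e-6)
    }
  }
})

test_that("same-site correlations match the digamma closed form", {
  m <- caille_model(1.9, 1.2e-5, 56)
  n <- c(1, 2, 4, 16, 64)
  grid <- rbcmem:::caille_delta_grid(m$xi, r = 1e-3, n_q = 3000,
                                     span_lo = 1e-5, span_hi = 300)
  dq <- rbcmem:::caille_delta_bulk(1.9, 1.2e-5, n, 1e-3, grid = grid)[, 1]
  expect_equal(dq, caille_delta0(m, n), tolerance = 2e-3)
})

test_that("rigid stacks reduce to the interference function times the envelope transform", {
  m <- caille_model(1e8, 1e4, 56, n_layers = 50, r_domain = 1500)
  qz1 <- 2 * pi / 56
  qr <- seq(0, 0.012, by = 0.002)
  S <- structure_factor(m, qz1, qr)
  n <- 0:49
  interf <- sum((1 - n / 50) * cos(qz1 * n * 56) * c(1, rep(2, 49)))
  hank <- 1500^2 / (1 + (qr * 1500)^2)^1.5
  expect_equal(S / (interf * hank), rep(1, length(qr)), tolerance = 0.02)
})

test_that("structure factor is non-negative and symmetric in q_r", {
  m <- caille_model(1.9, 1.2e-5, 56, n_layers = 100, r_domain = 2000)
  for (f in c(1.5, 2, 2.5)) {
    S <- structure_factor(m, f * 2 * pi / 56, seq(0, 0.05, by = 0.005))
    expect_true(all(S >= 0))
  }
  # symmetry: S depends on |q_r| only (J0 is even) - evaluate both signs
  cache_p <- rbcmem:::caille_sf_cache(c(0.01, 0.02), r_max = 48 * 2000)
  Sp <- rbcmem:::caille_sf_eval(m, 2 * 2 * pi / 56, cache_p)[[1]]
  cache_n <- rbcmem:::caille_sf_cache(abs(c(-0.01, -0.02)), r_max = 48 * 2000)
  Sn <- rbcmem:::caille_sf_eval(m, 2 * 2 * pi / 56, cache_n)[[1]]
  expect_equal(Sp, Sn, tolerance = 1e-12)
})

test_that("analytic finite-stack expectation matches the Monte-Carlo oracle", {
  stk <- smectic_stack(1.9, 1.2e-5, 56, n_layers = 4, box_side = 2000)
  qz <- 2.5 * 2 * pi / 56
  th <- expected_smectic_scattering(stk, qz, grid_n = 64)
  mc <- simulate_smectic_scattering(stk, qz, n_realizations = 120,
                                    grid_n = 64, seed = 42)
  j <- match(round(th$q_r, 10), round(mc$q_r, 10))
  logdev <- abs(log(mc$S[j]) - log(th$S))
  rel_se <- mc$se[j] / mc$S[j]
  expect_lt(mean(logdev), 3 * mean(rel_se))
  # reproducibility of the oracle
  mc2 <- simulate_smectic_scattering(stk, qz, n_realizations = 5,
                                     grid_n = 32, seed = 9)
  mc3 <- simulate_smectic_scattering(stk, qz, n_realizations = 5,
                                     grid_n = 32, seed = 9)
  expect_identical(mc2$S, mc3$S)
  expect_error(simulate_smectic_scattering(stk, qz, grid_n = 48),
               class = "rbcmem_invalid_parameter")
  expect_error(simulate_smectic_scattering(stk, qz, grid_n = 1024,
                                           max_cells = 1e4),
               class = "rbcmem_resource_error")
})

test_that("near-Bragg line shape decays with the Caille exponent -(1 - eta)", {
  m <- caille_model(1.9, 1.2e-5, 56, n_layers = 1e5 / 3)
  f <- exp(seq(log(0.001), log(0.008), length.out = 10))
  S <- caille_qz_profile(m, m$q1 * (1 + f))
  slope <- unname(coef(lm(log(S) ~ log(f)))[2])
  expect_equal(slope, -(1 - m$eta), tolerance = 0.05)
})

test_that("fitting the model to its own noise-free output recovers it exactly", {
  stk <- smectic_stack(4.6, 1.2e-5, 56, n_layers = 100)
  cuts <- gen_diffuse_cuts(stk, noise_level = 0, seed = 1)
  init <- caille_model(2.2, 4e-5, 56, n_layers = 100, r_domain = 2000)
  fit <- fit_diffuse(cuts, init)
  expect_equal(fit$model$kappa, 4.6, tolerance = 1e-4)
  expect_equal(fit$model$B_mod, 1.2e-5, tolerance = 1e-4)
  expect_true(fit$converged)
  expect_false(fit$at_bounds)
  # derived parameters propagate
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "eta"], fit$model$eta)
  expect_error(fit_diffuse(cuts[1], init),
               class = "rbcmem_invalid_parameter")
})

test_that("noisy two-cut fits recover kappa and report calibrated intervals", {
  init <- caille_model(2.5, 3e-5, 56, n_layers = 100, r_domain = 2000)
  errs <- c(); cover <- c()
  for (seed in 1:5) {
    stk <- smectic_stack(4.6, 1.2e-5, 56, n_layers = 100)
    cuts <- gen_diffuse_cuts(stk, noise_level = 0.03, seed = seed)
    f <- fit_diffuse(cuts, init)
    errs <- c(errs, abs(f$model$kappa - 4.6) / 4.6)
    ci <- f$params$conf95[f$params$term == "kappa"]
    cover <- c(cover, is.finite(ci) && abs(f$model$kappa - 4.6) <= ci)
  }
  expect_lt(median(errs), 0.15)
  expect_gte(sum(cover), 4)  # >= 80% coverage
})
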