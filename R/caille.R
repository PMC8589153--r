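#' Caillé smectic model of a hydrated membrane stack
#'
#' Parameter container for the harmonic theory of a stack of fluctuating
#' membranes: per-layer bending energy `kappa/2 (laplacian u_n)^2` and
#' harmonic inter-layer compression `B/2 (u_{n+1} - u_n)^2`. Energies are
#' expressed in units of kBT at `temperature`, so `kappa` is in kBT and `B`
#' in kBT/angstrom^4. Derived quantities are the Caillé parameter
#' `eta = q1^2 / (8 pi sqrt(B kappa))` and the in-plane correlation length
#' `xi = (kappa / B)^(1/4)`.
#'
#' @param kappa Bending modulus, kBT (> 0).
#' @param B_mod Inter-membrane compression modulus, kBT/angstrom^4 (> 0).
#' @param d Lamellar period, angstrom.
#' @param n_layers Number of coherently scattering layers N (default 100;
#'   the deposited stacks contain several hundred membranes but the
#'   coherent subset is smaller and is treated as a configuration
#'   parameter).
#' @param q1 First-order lamellar peak position; defaults to `2 pi / d`.
#' @param temperature Kelvin (bookkeeping only: energies are in kBT).
#' @param r_domain Lateral finite-size scale of the exponential in-plane
#'   envelope `H_r(r) = exp(-r / r_domain)`, angstrom.
#' @return An object of class `caille_model`.
#' @export
caille_model <- function(kappa, B_mod, d, n_layers = 100, q1 = NULL,
                         temperature = .rbcmem_default_temperature,
                         r_domain = 2000) {
  check_number(kappa, "kappa", positive = TRUE)
  check_number(B_mod, "B_mod", positive = TRUE)
  check_number(d, "d", positive = TRUE)
  check_number(n_layers, "n_layers", positive = TRUE)
  check_number(r_domain, "r_domain", positive = TRUE)
  q1 <- q1 %||% (2 * pi / d)
  pars <- caille_params(kappa, B_mod, q1)
  structure(list(kappa = kappa, B_mod = B_mod, d = d,
                 n_layers = as.integer(n_layers), q1 = q1,
                 temperature = temperature, r_domain = r_domain,
                 eta = pars$eta, xi = pars$xi),
            class = "caille_model")
}

#' @export
print.caille_model <- function(x, ...) {
  cat(sprintf(
    "<caille_model> kappa %.3g kBT | B %.3g kBT/A^4 | d %.4g A | N %d | eta %.4g | xi %.4g A\n",
    x$kappa, x$B_mod, x$d, x$n_layers, x$eta, x$xi))
  invisible(x)
}

#' Caillé parameter and in-plane correlation length
#'
#' `eta = kBT q1^2 / (8 pi sqrt(B kappa))` and `xi = (kappa / B)^(1/4)`.
#' With `kappa` in kBT and `B` in kBT/angstrom^4 the factors of kBT cancel.
#'
#' @param kappa Bending modulus, kBT.
#' @param B_mod Compression modulus, kBT/angstrom^4.
#' @param q1 First lamellar peak position, 1/angstrom.
#' @param temperature Kelvin (kept for interface symmetry; does not enter
#'   in kBT units).
#' @return A tibble with columns `eta` (dimensionless) and `xi` (angstrom).
#' @export
caille_params <- function(kappa, B_mod, q1,
                          temperature = .rbcmem_default_temperature) {
  check_number(kappa, "kappa", positive = TRUE)
  check_number(B_mod, "B_mod", positive = TRUE)
  check_number(q1, "q1", positive = TRUE)
  tibble(eta = q1^2 / (8 * pi * sqrt(B_mod * kappa)),
         xi = (kappa / B_mod)^(1 / 4))
}

# ---------------------------------------------------------------------------
# Height-difference correlation function of the bulk discrete smectic,
#   delta_n(r) = <(u_n(r) - u_0(0))^2>,
# via the analytic Brillouin-zone integral over the layer index:
#   delta_n(r) = 2 int q dq/(2pi) [1 - z(q)^n J0(q r)] / sqrt(a (a + 4B)),
# with a = kappa q^4 and lattice Green's function weight
#   z(q) = 2B / (a + 2B + sqrt(a (a + 4B)))  in (0, 1).
# kBT = 1; result in angstrom^2 (length(n) x length(r)). A constant
# analytic tail for q > q_hi (integrand ~ 1/(kappa q^3)) is added.
# `grid`, built by caille_delta_grid(), may be supplied to reuse the
# q-nodes and Bessel matrix across calls with identical (n is free) r.
caille_delta_grid <- function(xi_ref, r, n_q = 2000, span_lo = 1e-4,
                              span_hi = 30) {
  q <- exp(seq(log(span_lo / xi_ref), log(span_hi / xi_ref),
               length.out = n_q))
  dq <- diff(q)
  tw <- c(dq[1] / 2, (dq[-1] + dq[-length(dq)]) / 2, dq[length(dq)] / 2)
  J <- outer(q, r, function(qq, rr) j0_safe(qq * rr))
  list(q = q, tw = tw, J = J, r = r, q_hi = max(q))
}

caille_delta_bulk <- function(kappa, B_mod, n, r, n_q = 2000, grid = NULL) {
  xi <- (kappa / B_mod)^(1 / 4)
  grid <- grid %||% caille_delta_grid(xi, r, n_q = n_q)
  q <- grid$q
  a <- kappa * q^4
  root <- sqrt(a * (a + 4 * B_mod))
  z <- 2 * B_mod / (a + 2 * B_mod + root)
  base <- q * grid$tw / (2 * pi) / root
  Zn <- exp(outer(n, log(z)))
  const_term <- sum(base)
  cross <- Zn %*% (base * grid$J)
  tail_corr <- 1 / (4 * pi * kappa * grid$q_hi^2)
  2 * (const_term - cross) + 2 * tail_corr
}

# Hybrid delta: grid quadrature where the Bessel factor is resolved
# (small q*r), exact large-separation asymptotics elsewhere. The
# asymptotic form is the continuum-smectic result matched to the discrete
# stack (pref = 2 eta / q1^2 = 1 / (4 pi sqrt(kappa B))):
#   n >= 1:  delta = pref [psi(n + 1/2) - psi(1/2) + ln u + E1(u) + gamma],
#            u = r^2 / (4 xi^2 n)
#   n  = 0:  delta = pref [2 ln(r / xi) + 2 gamma]
# accurate to well below 0.1 angstrom^2 once u > 6 (n >= 1) or r > 8 xi
# (n = 0), which is exactly where the oscillatory quadrature degrades.
caille_delta_hybrid <- function(kappa, B_mod, n, r, grid, u_switch = 6) {
  euler_gamma <- 0.57721566490153286
  xi <- (kappa / B_mod)^(1 / 4)
  pref <- 1 / (4 * pi * sqrt(kappa * B_mod))
  del <- caille_delta_bulk(kappa, B_mod, n, r, grid = grid)
  # asymptotic region masks (n x r)
  u <- outer(ifelse(n >= 1, n, NA_real_), r,
             function(nn, rr) rr^2 / (4 * xi^2 * nn))
  for (i in seq_along(n)) {
    if (n[i] == 0) {
      far <- r > 8 * xi
      if (any(far)) {
        del[i, far] <- pref * (2 * log(r[far] / xi) + 2 * euler_gamma)
      }
    } else {
      far <- u[i, ] > u_switch
      if (any(far)) {
        uu <- u[i, far]
        del[i, far] <- pref * (digamma(n[i] + 0.5) - digamma(0.5) +
                                 log(uu) + pracma::expint_E1(uu) +
                                 euler_gamma)
      }
    }
  }
  del
}

#' Same-site inter-layer height-difference correlation (closed form)
#'
#' `delta_n(r = 0)` of the discrete smectic has the exact closed form
#' `(2 eta / q1^2) * (digamma(n + 1/2) - digamma(1/2))`, i.e. it grows
#' logarithmically in the layer separation `n` with prefactor
#' `2 eta / q1^2` — the discrete analogue of the Caillé logarithm.
#'
#' @param model A [caille_model()].
#' @param n Layer separations (non-negative integers).
#' @return `delta_n(0)` in angstrom^2.
#' @export
caille_delta0 <- function(model, n) {
  stopifnot(inherits(model, "caille_model"))
  (2 * model$eta / model$q1^2) * (digamma(n + 0.5) - digamma(0.5))
}

#' In-plane-integrated (one-dimensional) Caillé line shape
#'
#' The q_z profile of the stack after integrating over the in-plane
#' direction: `S1(q_z) = sum_n H_z(n) cos(q_z n d) exp(-q_z^2
#' delta_n(0)/2)` with the exact same-site correlations of
#' [caille_delta0()]. Near the m-th Bragg peak this line shape decays as
#' `|q_z - q_m|^-(1 - eta m^2)` over the asymptotic window between the
#' finite-size cutoff and the inter-peak region — the classical Caillé
#' power law.
#'
#' @param model A [caille_model()].
#' @param q_z Out-of-plane wavevectors, 1/angstrom.
#' @param envelope_decades Sum layers until `H_z` falls below
#'   `10^-envelope_decades` (default 4).
#' @return Numeric vector `S1(q_z)` (relative units).
#' @export
caille_qz_profile <- function(model, q_z, envelope_decades = 4) {
  stopifnot(inherits(model, "caille_model"))
  N <- model$n_layers
  n_max <- ceiling(envelope_decades * log(10) * N)
  n <- seq_len(n_max)
  hz <- exp(-n / N)
  delta0 <- caille_delta0(model, n)
  vapply(q_z, function(qz) {
    1 + 2 * sum(hz * cos(qz * n * model$d) * exp(-qz^2 * delta0 / 2))
  }, numeric(1))
}

# ---------------------------------------------------------------------------
# Radial (Hankel-type) quadrature for the structure factor.
#
# The integral  f_n(q_r) = int_0^inf r dr H_r(r) J0(q_r r) g_n(r),
# g_n(r) = exp(-q_z^2 delta_n(r)/2), is computed by expanding the smooth
# factor H_r * g_n as piecewise-linear in ln r on a coarse log grid and
# precomputing the oscillatory moments
#   W_j(q_r) = int r J0(q_r r) phi_j(ln r) dr
# of the hat functions phi_j once (Gauss-Legendre sub-panels sized to the
# Bessel oscillation). Per model evaluation only the coarse-grid values of
# H_r * g_n change, so S costs two small matrix products.
caille_sf_cache <- function(q_r, r_max, n_coarse = 200, xi_ref = 20,
                            n_q_delta = 1500, r_lo = 0.5,
                            nodes_per_cycle = 10) {
  x <- seq(log(r_lo), log(r_max), length.out = n_coarse)  # ln r knots
  r_knots <- exp(x)
  qr_max <- max(q_r, 1e-6)
  W <- matrix(0, n_coarse, length(q_r))
  for (j in seq_len(n_coarse - 1)) {
    a <- r_knots[j]; b <- r_knots[j + 1]
    n_cycles <- qr_max * (b - a) / (2 * pi)
    n_sub <- max(8L, ceiling(n_cycles * nodes_per_cycle))
    gl <- gauss_legendre(min(n_sub, 64L), a, b)
    if (n_sub > 64L) {
      # split long intervals into panels of <= 64 nodes
      n_panels <- ceiling(n_sub / 64)
      gl <- gauss_legendre_panels(seq(a, b, length.out = n_panels + 1), 64L)
    }
    rr <- gl$nodes; ww <- gl$weights
    t_right <- (log(rr) - x[j]) / (x[j + 1] - x[j])
    J0 <- outer(rr, q_r, function(r0, q0) j0_safe(r0 * q0))
    contrib <- (rr * ww) * J0
    W[j, ] <- W[j, ] + colSums(contrib * (1 - t_right))
    W[j + 1, ] <- W[j + 1, ] + colSums(contrib * t_right)
  }
  # leading segment [0, r_lo]: integrand ~ r * g(r_lo) (J0 ~ 1)
  W[1, ] <- W[1, ] + r_lo^2 / 2
  delta_grid <- caille_delta_grid(xi_ref, r_knots, n_q = n_q_delta,
                                  span_lo = 1e-5, span_hi = 300)
  list(r = r_knots, W = W, q_r = q_r, delta_grid = delta_grid)
}

# structure factor engine on a prepared cache; returns S over cache$q_r for
# each q_z supplied
caille_sf_eval <- function(model, q_z, cache) {
  N <- model$n_layers
  n <- 0:(N - 1)
  delta <- caille_delta_hybrid(model$kappa, model$B_mod, n, cache$r,
                               grid = cache$delta_grid)
  hr <- exp(-cache$r / model$r_domain)
  lapply(q_z, function(qz) {
    g <- exp(-qz^2 * delta / 2) * rep(hr, each = N)
    fn <- g %*% cache$W
    # triangular (Fejer) layer window: the exact finite-stack count of
    # layer pairs at separation n; keeps S >= 0
    wn <- (1 - n / N) * cos(qz * n * model$d) * c(1, rep(2, N - 1))
    drop(wn %*% fn)
  })
}

#' Smectic diffuse-scattering structure factor
#'
#' Evaluates the thermal structure factor of a stack of fluctuating
#' membranes,
#' `S(q_z, q_r) = sum_n H_z(n) cos(q_z n d) int r dr H_r(r) J0(q_r r) exp(-q_z^2 delta_n(r)/2)`,
#' where `delta_n(r)` is the height-difference correlation function of the
#' discrete smectic (bulk lattice-Green's-function form, validated against
#' the Monte-Carlo oracle), `H_z(n) = 1 - n/N` is the triangular layer
#' window of an N-layer stack (the exact pair count, which keeps S
#' non-negative) and `H_r(r) = exp(-r/r_domain)` is the lateral
#' finite-size envelope. The radial
#' integral uses precomputed oscillatory moments on a logarithmic grid
#' (relative accuracy about 1e-3 over the fitted q-range).
#'
#' @param model A [caille_model()].
#' @param q_z Out-of-plane wavevector (single value), 1/angstrom.
#' @param q_r In-plane wavevector grid, 1/angstrom (>= 0).
#' @param cache Optional cache from an earlier call (matching `q_r`);
#'   built automatically otherwise. The cache uses a canonical node
#'   placement independent of the model parameters, so cuts generated and
#'   fitted with default settings share one quadrature.
#' @param n_coarse,n_q_delta Quadrature resolution (coarse radial knots,
#'   correlation-integral nodes).
#' @return Numeric vector `S(q_z, q_r)` (relative units), same length as
#'   `q_r`.
#' @export
structure_factor <- function(model, q_z, q_r, cache = NULL,
                             n_coarse = 200, n_q_delta = 1500) {
  stopifnot(inherits(model, "caille_model"))
  check_number(q_z, "q_z", positive = TRUE)
  cache <- cache %||% caille_sf_cache(q_r, r_max = 48 * model$r_domain,
                                      n_coarse = n_coarse,
                                      n_q_delta = n_q_delta)
  caille_sf_eval(model, q_z, cache)[[1]]
}
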