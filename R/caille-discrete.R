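#' Finite smectic stack for brute-force simulation
#'
#' Ground-truth description of a small periodic membrane stack used by the
#' Monte-Carlo scattering oracle and its closed-form counterpart: `N`
#' free-ended layers of lateral size `box_side` (periodic in-plane),
#' bending modulus `kappa` per layer and harmonic inter-layer coupling
#' `B_mod`.
#'
#' @param kappa Bending modulus, kBT.
#' @param B_mod Compression modulus, kBT/angstrom^4.
#' @param d Layer period, angstrom.
#' @param n_layers Number of layers (>= 2).
#' @param box_side In-plane box side, angstrom.
#' @param temperature Kelvin.
#' @return An object of class `smectic_stack`.
#' @export
smectic_stack <- function(kappa, B_mod, d, n_layers = 4, box_side = 5000,
                          temperature = .rbcmem_default_temperature) {
  check_number(kappa, "kappa", positive = TRUE)
  check_number(B_mod, "B_mod", positive = TRUE)
  check_number(d, "d", positive = TRUE)
  check_number(box_side, "box_side", positive = TRUE)
  if (n_layers < 2) {
    stop_rbcmem("`n_layers` must be >= 2.", class = "rbcmem_invalid_parameter")
  }
  structure(list(kappa = kappa, B_mod = B_mod, d = d,
                 n_layers = as.integer(n_layers), box_side = box_side,
                 temperature = temperature),
            class = "smectic_stack")
}

# free-end chain (path graph) Laplacian eigensystem: eigenvalues
# lambda_k = 2 (1 - cos(k pi / N)) and orthonormal DCT-II eigenvectors
chain_modes <- function(N) {
  k <- 0:(N - 1)
  lambda <- 2 * (1 - cos(k * pi / N))
  n <- 0:(N - 1)
  V <- outer(n, k, function(nn, kk) cos((nn + 0.5) * kk * pi / N))
  V <- sweep(V, 2, sqrt(c(N, rep(N / 2, N - 1))), `/`)
  list(lambda = lambda, V = V)
}

# squared in-plane wavevector magnitudes on the FFT grid of a periodic box
fft_q2 <- function(grid_n, box_side) {
  f <- c(0:(grid_n %/% 2), -((grid_n - 1) %/% 2):-1) * (2 * pi / box_side)
  outer(f^2, f^2, `+`)
}

#' Closed-form expected scattering of a finite periodic stack
#'
#' Computes the exact Gaussian-theory expectation of the brute-force
#' scattering intensity of [simulate_smectic_scattering()] for the same
#' periodic `N`-layer instance: pair height-difference correlations
#' `delta_nm(r)` are assembled from the discrete reciprocal-lattice mode
#' sums (free-end chain eigenmodes in the layer index, FFT modes in-plane),
#' exponentiated, and Fourier-transformed. This is the finite-instance form
#' of the Caillé structure factor against which the Monte-Carlo oracle is
#' validated.
#'
#' @param stack A [smectic_stack()].
#' @param q_z Out-of-plane wavevector, 1/angstrom.
#' @param grid_n In-plane grid size (power of two recommended).
#' @return A tibble with columns `q_r` (bin centre) and `S` (expected
#'   intensity per unit area), radially binned with bin width `2 pi /
#'   box_side`.
#' @export
expected_smectic_scattering <- function(stack, q_z, grid_n = 64) {
  stopifnot(inherits(stack, "smectic_stack"))
  check_number(q_z, "q_z", positive = TRUE)
  N <- stack$n_layers
  L <- stack$box_side
  A <- L^2
  dx <- L / grid_n
  modes <- chain_modes(N)
  q2 <- fft_q2(grid_n, L)
  # per-chain-mode in-plane correlation fields c_k(r) (real, grid_n^2)
  ck <- vector("list", N)
  for (k in seq_len(N)) {
    M <- 1 / (stack$kappa * q2^2 + stack$B_mod * modes$lambda[k])
    M[1, 1] <- 0                     # remove the rigid translation / zero mode
    if (k > 1) M[1, 1] <- 1 / (stack$B_mod * modes$lambda[k])
    ck[[k]] <- Re(fft(M, inverse = TRUE)) / A
  }
  # G(s) = sum_nm exp(i qz d (n - m)) exp(-qz^2 delta_nm(s)/2)
  G <- matrix(0, grid_n, grid_n)
  V <- modes$V
  c0 <- vapply(seq_len(N), function(k) ck[[k]][1, 1], numeric(1))
  var_n <- drop(V^2 %*% c0)          # C_nn(0) per layer
  for (n in seq_len(N)) {
    for (m in seq_len(N)) {
      Cnm <- Reduce(`+`, lapply(seq_len(N), function(k) {
        V[n, k] * V[m, k] * ck[[k]]
      }))
      delta <- var_n[n] + var_n[m] - 2 * Cnm
      G <- G + cos(q_z * stack$d * (n - m)) * exp(-q_z^2 * delta / 2)
    }
  }
  I <- Re(fft(G)) * dx^2
  radial_bin_map(I, grid_n, L)
}

# radially bin an FFT-indexed intensity matrix into annuli of width 2 pi / L
radial_bin_map <- function(I, grid_n, L, drop_zero = TRUE) {
  qmag <- sqrt(fft_q2(grid_n, L))
  dqbin <- 2 * pi / L
  bin <- floor(qmag / dqbin + 0.5)
  keep <- bin <= (grid_n %/% 2) & (!drop_zero | bin > 0)
  df <- tibble(bin = as.vector(bin[keep]), I = as.vector(I[keep]))
  out <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(S = mean(.data$I), n_modes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::mutate(q_r = .data$bin * dqbin) |>
    dplyr::select("q_r", "S", "n_modes")
  out
}

#' Brute-force Monte-Carlo smectic scattering oracle
#'
#' Samples layer displacement fields `u_n(r)` of a finite periodic stack
#' from the exact Gaussian distribution of the harmonic stack energy
#' (independent Fourier/chain-eigenmode amplitudes with analytically known
#' variances) and computes the scattering intensity
#' `|sum_n int d^2r exp(i q_z (n d + u_n(r)) + i q_par . r)|^2 / A`
#' by direct summation (FFT per layer), averaged over realisations. Serves
#' as the independent source of truth for the analytic structure factor on
#' small instances.
#'
#' @param stack A [smectic_stack()].
#' @param q_z Out-of-plane wavevector, 1/angstrom.
#' @param n_realizations Number of independent field realisations.
#' @param grid_n In-plane grid size (power of two).
#' @param seed Integer seed.
#' @param max_cells Resource cap on `n_layers * grid_n^2`.
#' @return A tibble with columns `q_r`, `S` (mean intensity per unit area),
#'   `se` (Monte-Carlo standard error of the bin mean) and `n_modes`.
#' @export
simulate_smectic_scattering <- function(stack, q_z, n_realizations = 100,
                                        grid_n = 64, seed = 1L,
                                        max_cells = 2^24) {
  stopifnot(inherits(stack, "smectic_stack"))
  check_number(q_z, "q_z", positive = TRUE)
  if (bitwAnd(grid_n, grid_n - 1L) != 0L) {
    stop_rbcmem("`grid_n` must be a power of two.",
                class = "rbcmem_invalid_parameter")
  }
  if (n_realizations < 1) {
    stop_rbcmem("`n_realizations` must be >= 1.",
                class = "rbcmem_invalid_parameter")
  }
  if (stack$n_layers * grid_n^2 > max_cells) {
    stop_rbcmem("instance exceeds the configured resource cap.",
                class = "rbcmem_resource_error")
  }
  N <- stack$n_layers
  L <- stack$box_side
  A <- L^2
  dx <- L / grid_n
  modes <- chain_modes(N)
  q2 <- fft_q2(grid_n, L)
  # per-mode amplitude scale: u_k field with target spectrum
  scale_k <- lapply(seq_len(N), function(k) {
    D <- stack$kappa * q2^2 + stack$B_mod * modes$lambda[k]
    s <- sqrt(A / D) / grid_n         # kBT = 1
    s[1, 1] <- if (k == 1) 0 else sqrt(A / (stack$B_mod * modes$lambda[k])) / grid_n
    s
  })
  phase_n <- exp(1i * q_z * stack$d * (0:(N - 1)))
  sums <- matrix(0, grid_n, grid_n)
  sums2 <- matrix(0, grid_n, grid_n)
  with_seed(seed, {
    for (rep in seq_len(n_realizations)) {
      # sample chain-eigenmode fields and rotate into layer fields
      uk <- lapply(seq_len(N), function(k) {
        W <- fft(matrix(rnorm(grid_n^2), grid_n, grid_n))
        Re(fft(W * scale_k[[k]], inverse = TRUE)) / A * grid_n^0 # see below
      })
      # u_k(r) = (1/A) sum_q u_hat e^{iqr} = ifft(u_hat)/ (A / Ngrid^2) ... :
      # fft(..., inverse = TRUE) already sums modes; divide by A and multiply
      # by nothing further because scale includes sqrt(A).
      amp <- matrix(0 + 0i, grid_n, grid_n)
      for (n in seq_len(N)) {
        un <- Reduce(`+`, lapply(seq_len(N), function(k) modes$V[n, k] * uk[[k]]))
        amp <- amp + phase_n[n] * fft(exp(1i * q_z * un))
      }
      I <- Mod(amp * dx^2)^2 / A
      sums <- sums + I
      sums2 <- sums2 + I^2
    }
  })
  mean_map <- sums / n_realizations
  var_map <- pmax(sums2 / n_realizations - mean_map^2, 0)
  binned <- radial_bin_map(mean_map, grid_n, L)
  se_binned <- radial_bin_map(var_map, grid_n, L)
  # SE of the bin mean: sqrt(mean variance / (n_real * n_modes))
  binned$se <- sqrt(se_binned$S / (n_realizations * binned$n_modes))
  binned
}
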