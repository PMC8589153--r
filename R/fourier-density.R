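#' Continuous form factor fitted through lamellar peak amplitudes
#'
#' Builds the band-limited continuous form factor
#' `T(q_z) = sum_n sqrt(I_n q_n) nu_n sinc(d q_z / 2 - pi n)`
#' from the fitted peak set, with signs `nu_n = +/- 1`. For a
#' centrosymmetric bilayer the form factor is real and the phase problem
#' reduces to choosing these signs. Signs may be supplied explicitly,
#' taken from the default head-group phase array `[-1, -1, 1, -1, 1]`
#' (extended beyond order 5 by the sign of `cos(q_n z_ref)` with
#' `z_ref = 20` angstrom, the head-group cosine heuristic), or chosen by
#' exhaustive enumeration ranked by physical plausibility of the
#' reconstructed density (head maxima away from the centre, minimum at
#' `z = 0`).
#'
#' @param peaks A `lamellar_peaks` tibble (columns `order`, `q`,
#'   `intensity`) with attribute `d`, or any tibble with those columns plus
#'   a `d` argument.
#' @param phases Optional integer vector of signs, one per order.
#' @param enumerate If TRUE, search all `2^N` sign arrays (N <= 12).
#' @param d Lamellar period; defaults to `attr(peaks, "d")`.
#' @param z_ref Head-position reference (angstrom) for the default-phase
#'   extension rule.
#' @return An object of class `form_factor`: function-like list with
#'   elements `amplitude` (`sqrt(I_n q_n)`), `phases`, `d`, and `fun(q_z)`
#'   evaluating `T`.
#' @export
fit_form_factor <- function(peaks, phases = NULL, enumerate = FALSE,
                            d = NULL, z_ref = 20) {
  d <- d %||% attr(peaks, "d")
  check_number(d, "d", positive = TRUE)
  n <- peaks$order
  if (length(n) < 2L && is.null(phases) && !enumerate) {
    # single order: both signs give mirror densities; pick head maxima away
    # from the centre
    phases <- -1L
  }
  amp <- sqrt(peaks$intensity * peaks$q)
  if (enumerate) {
    if (length(n) > 12L) {
      stop_rbcmem("phase enumeration is capped at 12 orders.",
                  class = "rbcmem_invalid_parameter")
    }
    phases <- enumerate_phases(amp, n, d)
  } else if (is.null(phases)) {
    default5 <- c(-1, -1, 1, -1, 1)
    phases <- vapply(n, function(k) {
      if (k <= 5) default5[k] else sign(cos(2 * pi * k * z_ref / d))
    }, numeric(1))
  }
  if (length(phases) != length(n) || !all(phases %in% c(-1, 1))) {
    stop_rbcmem("`phases` must be +/- 1, one per order.",
                class = "rbcmem_invalid_parameter")
  }
  sinc <- function(x) ifelse(abs(x) < 1e-12, 1, sin(x) / x)
  fun <- function(q_z) {
    vapply(q_z, function(qz) {
      sum(amp * phases * sinc(d * qz / 2 - pi * n))
    }, numeric(1))
  }
  structure(list(amplitude = amp, phases = as.integer(phases),
                 order = n, d = d, fun = fun),
            class = "form_factor")
}

# Exhaustive phase search: reconstruct rho for every sign array and score
# physical plausibility. The head-group band is |z| in [0.25, 0.47] d. The
# score rewards (i) a head maximum well above the centre (CH3 trough)
# density, (ii) a head maximum well above the boundary (water) density --
# inter-membrane water sits between trough and head densities -- and
# penalises profiles whose global maximum falls outside the head band.
enumerate_phases <- function(amp, orders, d, head_band = c(0.25, 0.47)) {
  N <- length(orders)
  z <- seq(0, d / 2, length.out = 257)
  basis <- outer(z, orders, function(zz, k) cos(2 * pi * k * zz / d))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), N)))
  rho <- basis %*% t(signs * rep(amp, each = nrow(signs)))
  in_band <- z >= head_band[1] * d & z <= head_band[2] * d
  scores <- vapply(seq_len(ncol(rho)), function(j) {
    r <- rho[, j]
    span <- max(r) - min(r)
    if (span <= 0) return(-Inf)
    head_max <- max(r[in_band])
    centre <- r[1]
    boundary <- r[length(r)]
    peak_in_band <- which.max(r) %in% which(in_band)
    (head_max - centre) / span + (head_max - boundary) / span +
      ifelse(peak_in_band, 1, -1)
  }, numeric(1))
  as.integer(signs[which.max(scores), ])
}

#' Relative electron-density profile by Fourier synthesis
#'
#' Reconstructs the one-dimensional relative electron density
#' `rho(z) = (2/d) sum_n sqrt(I_n q_n) nu_n cos(2 pi n z / d)` on a
#' symmetric z-grid and normalises it affinely so that `rho(0) = 0` and
#' `rho(+/- d/2) = 1`. The head-head distance `d_HH` is the separation of
#' the two global maxima (parabolic sub-grid refinement); the water layer
#' is `d - d_HH`.
#'
#' @param peaks A `lamellar_peaks` tibble (columns `order`, `q`,
#'   `intensity`).
#' @param phases Sign array, one per order (see [fit_form_factor()]).
#' @param d Lamellar period; defaults to `attr(peaks, "d")`.
#' @param n_z Number of z-grid points per period (default 512).
#' @return A `density_profile` tibble with columns `z`, `rho`, and
#'   attributes `d`, `d_hh`, `water_layer`, `phases`.
#' @export
fourier_density <- function(peaks, phases, d = NULL, n_z = 512) {
  d <- d %||% attr(peaks, "d")
  check_number(d, "d", positive = TRUE)
  n <- peaks$order
  if (length(phases) != length(n) || !all(phases %in% c(-1, 1))) {
    stop_rbcmem("`phases` must be +/- 1, one per order.",
                class = "rbcmem_invalid_parameter")
  }
  amp <- sqrt(peaks$intensity * peaks$q) * phases
  z <- seq(-d / 2, d / 2, length.out = n_z + 1)
  rho <- (2 / d) * drop(outer(z, n, function(zz, k) cos(2 * pi * k * zz / d)) %*% amp)
  # affine normalisation rho(0) -> 0, rho(boundary) -> 1
  i0 <- which.min(abs(z))
  rho0 <- rho[i0]
  rhob <- rho[1]          # == rho[length(rho)] by symmetry
  if (abs(rhob - rho0) < 1e-12 * max(abs(rho), 1)) {
    stop_rbcmem("degenerate normalisation: rho(0) equals the boundary density.",
                class = "rbcmem_degenerate")
  }
  rho <- (rho - rho0) / (rhob - rho0)
  # head-head distance: global maximum on the z > 0 half, refined
  pos <- z > 0
  zp <- z[pos]; rp <- rho[pos]
  imax <- which.max(rp)
  z_head <- if (imax > 1 && imax < length(zp)) {
    # parabola through the three points around the discrete maximum
    y1 <- rp[imax - 1]; y2 <- rp[imax]; y3 <- rp[imax + 1]
    h <- zp[2] - zp[1]
    zp[imax] + h * (y1 - y3) / (2 * (y1 - 2 * y2 + y3))
  } else {
    zp[imax]
  }
  out <- tibble(z = z, rho = rho)
  class(out) <- c("density_profile", class(out))
  attr(out, "d") <- d
  attr(out, "d_hh") <- 2 * z_head
  attr(out, "water_layer") <- d - 2 * z_head
  attr(out, "phases") <- as.integer(phases)
  out
}

#' @export
glance.density_profile <- function(x, ...) {
  tibble(d = attr(x, "d"), d_hh = attr(x, "d_hh"),
         water_layer = attr(x, "water_layer"),
         phases = paste(attr(x, "phases"), collapse = " "))
}

#' Plot a reconstructed electron-density profile
#' @param object A `density_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$z, .data$rho)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(z ~ (ring(A))),
                  y = expression(rho(z) ~ "(relative)"))
}
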