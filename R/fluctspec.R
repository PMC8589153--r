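# Transform convention, fixed package-wide:
#   H_q = (dx^2 / sqrt(A)) * sum_r h(r) exp(-i q.r)
# so that the Helfrich-Canham equipartition reads <|H_q|^2> = kBT / (kappa q^4)
# with no extra area factor. kBT = 1 internally.

# forward transform of a real height grid under the package convention
height_transform <- function(h, box_side) {
  g <- nrow(h)
  dx <- box_side / g
  fft(h) * dx^2 / box_side
}

#' Generate a Helfrich-distributed bead trajectory
#'
#' Draws independent membrane height fields whose Fourier amplitudes follow
#' the Helfrich-Canham equipartition `<|H_q|^2> = kBT / (kappa q^4)` (q = 0
#' excluded), inverse-transforms them to real height grids, and scatters
#' head-group beads for two leaflets at the local height plus/minus half a
#' nominal bilayer thickness, with small positional jitter. Bead positions
#' are resampled uniformly each frame, emulating laterally diffusing lipids.
#'
#' @param kappa Bending modulus, kBT (> 0).
#' @param box_side In-plane box side, angstrom.
#' @param grid_n Fourier grid size (>= 8).
#' @param n_frames Number of frames (>= 1).
#' @param beads_per_area Areal head-bead density per leaflet, 1/angstrom^2
#'   (default 0.022, about one bead per 45 angstrom^2 lipid).
#' @param thickness Nominal head-to-head distance separating the two
#'   leaflet bead sheets, angstrom.
#' @param z_jitter Gaussian sigma of bead height noise, angstrom.
#' @param frame_interval Nanoseconds between frames (metadata).
#' @param start_ns Time stamp of the first frame, ns.
#' @param temperature Kelvin (metadata).
#' @param seed Integer seed.
#' @return A `bead_trajectory`: list with `frames` (list of tibbles with
#'   columns `x`, `y`, `z`, `leaflet`, `role`, `time_ns`), `box` (Lx, Ly),
#'   `frame_interval`, and the generating `kappa` as attribute
#'   `"ground_truth"`.
#' @export
gen_height_trajectory <- function(kappa, box_side = 340, grid_n = 128,
                                  n_frames = 450, beads_per_area = 0.022,
                                  thickness = 40, z_jitter = 0.5,
                                  frame_interval = 4, start_ns = 200,
                                  temperature = .rbcmem_default_temperature,
                                  seed = 1L) {
  check_number(kappa, "kappa", positive = TRUE)
  check_number(box_side, "box_side", positive = TRUE)
  if (grid_n < 8) {
    stop_rbcmem("`grid_n` must be >= 8.", class = "rbcmem_invalid_parameter")
  }
  if (n_frames < 1) {
    stop_rbcmem("`n_frames` must be >= 1.", class = "rbcmem_invalid_parameter")
  }
  A <- box_side^2
  q2 <- fft_q2(grid_n, box_side)
  amp <- sqrt(1 / (kappa * q2^2))      # target |H_q| scale, kBT = 1
  amp[1, 1] <- 0                       # q = 0 removed by construction
  n_beads <- max(4L, round(beads_per_area * A))
  frames <- with_seed(seed, lapply(seq_len(n_frames), function(i) {
    W <- fft(matrix(rnorm(grid_n^2), grid_n, grid_n)) / grid_n
    Hq <- W * amp
    # invert the package convention: h = ifft(Hq * sqrt(A) / dx^2)
    h <- Re(fft(Hq, inverse = TRUE)) / grid_n^2 * box_side / (box_side / grid_n)^2
    purrr::map_dfr(c(upper = 1, lower = -1), function(sgn) {
      x <- runif(n_beads, 0, box_side)
      y <- runif(n_beads, 0, box_side)
      z <- grid_bilinear(h, box_side, x, y) + sgn * thickness / 2 +
        rnorm(n_beads, sd = z_jitter)
      tibble(x = x, y = y, z = z,
             leaflet = if (sgn > 0) "upper" else "lower",
             role = "head",
             time_ns = start_ns + (i - 1) * frame_interval)
    })
  }))
  out <- structure(list(frames = frames,
                        box = c(box_side, box_side),
                        frame_interval = frame_interval),
                   class = "bead_trajectory")
  attr(out, "ground_truth") <- list(kappa = kappa, grid_n = grid_n,
                                    thickness = thickness)
  out
}

# periodic bilinear interpolation of a square grid at scattered points
grid_bilinear <- function(h, box_side, x, y) {
  g <- nrow(h)
  dx <- box_side / g
  fx <- (x / dx) %% g
  fy <- (y / dx) %% g
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  i0 <- i0 %% g; j0 <- j0 %% g
  i1 <- (i0 + 1) %% g; j1 <- (j0 + 1) %% g
  h00 <- h[cbind(i0 + 1, j0 + 1)]; h10 <- h[cbind(i1 + 1, j0 + 1)]
  h01 <- h[cbind(i0 + 1, j1 + 1)]; h11 <- h[cbind(i1 + 1, j1 + 1)]
  (1 - tx) * (1 - ty) * h00 + tx * (1 - ty) * h10 +
    (1 - tx) * ty * h01 + tx * ty * h11
}

#' Interpolate a leaflet's head beads onto a regular grid
#'
#' Deterministic gridding of scattered head-bead heights: beads are
#' averaged onto their nearest grid node over the periodic box (exact
#' duplicates therefore average deterministically), and empty nodes are
#' filled by iterative relaxation from their filled 8-neighbourhoods
#' (periodic), which converges to a nearest-neighbour-style fill.
#'
#' @param frame A tibble of beads (columns `x`, `y`, `z`, `leaflet`,
#'   `role`).
#' @param grid_n Output grid size.
#' @param leaflet `"upper"` or `"lower"`.
#' @param box Box sides `c(Lx, Ly)`; Lx is used for the (square) grid.
#' @param role Bead role defining the surface (default `"head"`; taken
#'   from the trajectory, never inferred).
#' @return A `grid_n` x `grid_n` matrix of heights.
#' @export
leaflet_surface <- function(frame, grid_n, leaflet, box, role = "head") {
  sel <- frame$leaflet == leaflet & frame$role == role
  if (sum(sel) < 4L) {
    stop_rbcmem(sprintf("need >= 4 '%s' beads in leaflet '%s'.", role, leaflet),
                class = "rbcmem_invalid_parameter")
  }
  x <- frame$x[sel]; y <- frame$y[sel]; z <- frame$z[sel]
  if (sd(x) < 1e-9 || sd(y) < 1e-9) {
    stop_rbcmem("degenerate (collinear) bead geometry.",
                class = "rbcmem_degenerate")
  }
  L <- box[1]
  dx <- L / grid_n
  ix <- (round(x / dx) %% grid_n) + 1
  iy <- (round(y / dx) %% grid_n) + 1
  lin <- (iy - 1L) * grid_n + ix
  sums <- numeric(grid_n^2)
  cnts <- numeric(grid_n^2)
  agg <- rowsum(z, lin)
  cnt <- rowsum(rep(1, length(lin)), lin)
  idx <- as.integer(rownames(agg))
  sums[idx] <- agg[, 1]
  cnts[idx] <- cnt[, 1]
  h <- matrix(ifelse(cnts > 0, sums / pmax(cnts, 1), NA_real_),
              grid_n, grid_n)
  fill_periodic(h)
}

# iterative 8-neighbour relaxation fill of NA cells on a torus
fill_periodic <- function(h) {
  shift <- function(m, di, dj) {
    g <- nrow(m)
    m[((seq_len(g) - 1 + di) %% g) + 1, ((seq_len(g) - 1 + dj) %% g) + 1]
  }
  offsets <- expand.grid(di = -1:1, dj = -1:1)
  offsets <- offsets[!(offsets$di == 0 & offsets$dj == 0), ]
  it <- 0
  while (anyNA(h)) {
    filled <- !is.na(h)
    hv <- h; hv[!filled] <- 0
    s <- matrix(0, nrow(h), ncol(h))
    cnt <- matrix(0, nrow(h), ncol(h))
    for (o in seq_len(nrow(offsets))) {
      s <- s + shift(hv, offsets$di[o], offsets$dj[o])
      cnt <- cnt + shift(filled, offsets$di[o], offsets$dj[o])
    }
    upd <- !filled & cnt > 0
    h[upd] <- s[upd] / cnt[upd]
    it <- it + 1
    if (it > nrow(h) + ncol(h)) {
      stop_rbcmem("gap filling failed to converge.", class = "rbcmem_error")
    }
  }
  h
}

#' Mid-plane undulation field from two leaflet surfaces
#'
#' Pointwise average of the upper and lower leaflet height grids with the
#' mean removed (the q = 0 mode carries no curvature information and is
#' always dropped). Antisymmetric (thickness) fluctuations cancel.
#'
#' @param upper,lower Equal-shaped height matrices.
#' @return A mean-zero matrix.
#' @export
midplane_field <- function(upper, lower) {
  if (!all(dim(upper) == dim(lower))) {
    stop_rbcmem("leaflet grids must have identical shapes.",
                class = "rbcmem_invalid_parameter")
  }
  m <- (upper + lower) / 2
  m - mean(m)
}

#' Radially averaged membrane fluctuation spectrum
#'
#' For every usable frame, grids both leaflets, forms the mid-plane
#' undulation field, transforms it under the package convention
#' `H_q = (dx^2 / sqrt(A)) sum_r h(r) e^(-i q.r)`, and accumulates
#' `|H_q|^2`. The time-averaged power is radially binned in annuli of
#' width `2 pi / L` (elliptical bins in `(q_x L_x, q_y L_y)` for
#' non-square boxes); the q = 0 mode is excluded and the first bin starts
#' at `2 pi / L`.
#'
#' @param traj A `bead_trajectory`.
#' @param grid_n Interpolation grid size (default 128).
#' @param discard_before Discard frames with `time_ns` below this
#'   equilibration cutoff (default 200 ns).
#' @return A `fluctuation_spectrum` tibble with columns `q` (1/angstrom),
#'   `power` (angstrom^2 units of the convention), `n_modes`, and
#'   attributes `n_frames`, `box`.
#' @export
spectrum <- function(traj, grid_n = 128, discard_before = 200) {
  stopifnot(inherits(traj, "bead_trajectory"))
  frames <- purrr::keep(traj$frames, function(f) f$time_ns[1] >= discard_before)
  if (length(frames) < 10L) {
    stop_rbcmem(sprintf(
      "only %d usable frames after the %g ns equilibration discard (>= 10 required).",
      length(frames), discard_before),
      class = "rbcmem_invalid_parameter")
  }
  L <- traj$box[1]
  Ly <- traj$box[2]
  acc <- matrix(0, grid_n, grid_n)
  for (f in frames) {
    up <- leaflet_surface(f, grid_n, "upper", traj$box)
    lo <- leaflet_surface(f, grid_n, "lower", traj$box)
    h <- midplane_field(up, lo)
    Hq <- height_transform(h, L)
    acc <- acc + Mod(Hq)^2
  }
  acc <- acc / length(frames)
  # elliptical mode-index binning (reduces to circular for square boxes);
  # each annulus is labelled with the q^-4-unbiased effective magnitude
  # (mean q^-4 over member modes)^(-1/4), so that averaging a Helfrich
  # spectrum over an annulus introduces no abscissa bias
  fx <- c(0:(grid_n %/% 2), -((grid_n - 1) %/% 2):-1)
  mmag <- sqrt(outer(fx^2, fx^2 * (L / Ly)^2, `+`))
  bin <- floor(mmag + 0.5)
  keep <- bin > 0 & bin <= grid_n %/% 2
  df <- tibble(bin = as.vector(bin[keep]), p = as.vector(acc[keep]),
               qmag = as.vector(mmag[keep]) * 2 * pi / L)
  out <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(power = mean(.data$p),
                     q = mean(.data$qmag^-4)^(-1 / 4),
                     n_modes = dplyr::n(),
                     .groups = "drop") |>
    dplyr::select("q", "power", "n_modes")
  class(out) <- c("fluctuation_spectrum", class(out))
  attr(out, "n_frames") <- length(frames)
  attr(out, "box") <- traj$box
  out
}

#' Helfrich-Canham fit of a fluctuation spectrum
#'
#' Weighted least squares of `log(power)` against `log(q)` for
#' `q < q_max` with the slope fixed at -4 (the Helfrich-Canham form
#' `<|h(q)|^2> = kBT / (kappa q^4)`); the intercept gives
#' `kappa = kBT / exp(intercept)`. Weights are the per-bin mode counts.
#' A free-slope diagnostic reports the fitted exponent; fits requested
#' above the q^4 regime (`q_max > 0.1`) are flagged.
#'
#' @param spec A `fluctuation_spectrum`.
#' @param q_max Upper fit limit, 1/angstrom (default 0.1, the upper edge of
#'   the q^-4 regime).
#' @param free_slope If TRUE, also fit the exponent as a diagnostic.
#' @return An `hc_fit` list: `kappa` (kBT), `conf95` (2 sigma), `slope`
#'   (fixed -4 or fitted), `q_max`, `n_bins`, `out_of_regime` flag.
#' @export
fit_hc <- function(spec, q_max = 0.1, free_slope = FALSE) {
  stopifnot(inherits(spec, "fluctuation_spectrum"))
  sel <- spec$q < q_max & spec$power > 0
  if (sum(sel) < 4L) {
    stop_rbcmem("fewer than 4 spectrum bins below `q_max`.",
                class = "rbcmem_invalid_parameter")
  }
  lq <- log(spec$q[sel])
  lp <- log(spec$power[sel])
  w <- spec$n_modes[sel]
  if (free_slope) {
    fit <- stats::lm(lp ~ lq, weights = w)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    se_int <- 2 * summary(fit)$coefficients[1, 2]
  } else {
    slope <- -4
    y <- lp + 4 * lq
    intercept <- weighted.mean(y, w)
    se <- sqrt(sum(w * (y - intercept)^2) / (sum(w) * max(1, sum(sel) - 1)))
    se_int <- 2 * se
  }
  kappa <- exp(-intercept)
  structure(list(kappa = kappa,
                 conf95 = kappa * se_int,
                 slope = slope, intercept = intercept,
                 q_max = q_max, n_bins = sum(sel),
                 out_of_regime = q_max > 0.1 + 1e-12),
            class = "hc_fit")
}

#' @export
print.hc_fit <- function(x, ...) {
  cat(sprintf("<hc_fit> kappa = %.3g +/- %.2g kBT (q < %.3g 1/A, %d bins%s)\n",
              x$kappa, x$conf95, x$q_max, x$n_bins,
              if (x$out_of_regime) ", OUT OF q^4 REGIME" else ""))
  invisible(x)
}

#' @export
tidy.hc_fit <- function(x, ...) {
  tibble(term = "kappa", estimate = x$kappa, conf95 = x$conf95)
}

#' @export
glance.hc_fit <- function(x, ...) {
  tibble(kappa = x$kappa, conf95 = x$conf95, slope = x$slope,
         q_max = x$q_max, n_bins = x$n_bins,
         out_of_regime = x$out_of_regime)
}

#' Plot a fluctuation spectrum (log-log) with optional HC fit
#' @param object A `fluctuation_spectrum`.
#' @param fit Optional `hc_fit` to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fluctuation_spectrum <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$q, .data$power)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(q ~ (ring(A)^-1)),
                  y = expression("<|h(q)|"^2 * "> " * (ring(A)^2)))
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_line(
      data = tibble(q = object$q,
                    power = exp(fit$intercept + fit$slope * log(object$q))),
      colour = "red")
  }
  p
}
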