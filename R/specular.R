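#' Extract the specular reflectivity from an intensity map
#'
#' Integrates the two-dimensional map along the in-plane direction over the
#' band `|q_par| <= q_par_halfwidth` (trapezoid rule), one value per `q_z`
#' row — the digital equivalent of summing the detector counts inside the
#' rectangular box drawn around the meridian.
#'
#' @param map An [intensity_map()].
#' @param q_par_halfwidth Half width of the integration band, 1/angstrom.
#' @return A tibble (`reflectivity` subclass) with columns `q_z`, `intensity`.
#' @export
extract_reflectivity <- function(map, q_par_halfwidth = 0.05) {
  stopifnot(inherits(map, "intensity_map"))
  check_number(q_par_halfwidth, "q_par_halfwidth", positive = TRUE)
  if (q_par_halfwidth > max(abs(map$q_par))) {
    stop_rbcmem("`q_par_halfwidth` exceeds the map's q_par extent.",
                class = "rbcmem_invalid_parameter")
  }
  sel <- abs(map$q_par) <= q_par_halfwidth
  if (sum(sel) < 2L) {
    stop_rbcmem("integration band contains fewer than 2 q_par columns.",
                class = "rbcmem_invalid_parameter")
  }
  x <- map$q_par[sel]
  inten <- apply(map$intensity[, sel, drop = FALSE], 1, function(row) trapz(x, row))
  out <- tibble(q_z = map$q_z, intensity = inten)
  class(out) <- c("reflectivity", class(out))
  attr(out, "wavelength") <- map$wavelength
  out
}

#' Locate and fit lamellar diffraction peaks
#'
#' Finds candidate maxima above a robust noise floor, fits a Gaussian plus
#' local linear background around each, assigns integer diffraction orders
#' by bootstrapping from the strongest peak, and determines the lamellar
#' repeat `d` from a least-squares fit of `q_n = n (2 pi / d)` through the
#' origin. Candidates whose position is incompatible with an integer order
#' (`|q_n / q_1 - n| > 0.05`) are rejected.
#'
#' @param curve A reflectivity tibble with columns `q_z`, `intensity` (as
#'   returned by [extract_reflectivity()] or read from a two-column TSV).
#' @param max_order Largest diffraction order considered.
#' @param noise_floor_k Multiplier on the robust scale (MAD) above the
#'   median used as detection threshold.
#' @param window_halfwidth Half width (1/angstrom) of the fit window around
#'   each candidate; defaults to 40% of the first-order spacing estimate.
#' @return A `lamellar_peaks` tibble with columns `order`, `q`, `sigma`,
#'   `fwhm`, `intensity` (analytic Gaussian area) and attributes `d`
#'   (angstrom) and `q1`. Returns an empty set with a warning when no peak
#'   clears the noise floor.
#' @export
find_lamellar_peaks <- function(curve, max_order = 6, noise_floor_k = 5,
                                window_halfwidth = NULL) {
  stopifnot(all(c("q_z", "intensity") %in% names(curve)))
  q <- curve$q_z
  y <- curve$intensity
  if (length(q) < 5L) stop_rbcmem("reflectivity curve too short.")
  floor_level <- median(y) + noise_floor_k * mad(y)
  # local maxima: larger than both neighbours and above the floor
  is_max <- c(FALSE, diff(sign(diff(y))) == -2, FALSE) & y > floor_level
  idx <- which(is_max)
  if (length(idx) == 0L) {
    warn("no lamellar peak found above the noise floor; returning empty set.")
    out <- tibble(order = integer(), q = numeric(), sigma = numeric(),
                  fwhm = numeric(), intensity = numeric())
    class(out) <- c("lamellar_peaks", class(out))
    attr(out, "d") <- NA_real_
    return(out)
  }
  # order bootstrap from the strongest candidate: try assigning it order
  # 1..max_order and keep the hypothesis that explains the most candidates
  q_cand <- q[idx]
  y_cand <- y[idx]
  strongest <- q_cand[which.max(y_cand)]
  best <- NULL
  for (m in seq_len(max_order)) {
    q1_try <- strongest / m
    ords <- round(q_cand / q1_try)
    ok <- ords >= 1 & ords <= max_order & abs(q_cand / q1_try - ords) <= 0.05 &
      !duplicated(ords)
    score <- sum(ok)
    if (is.null(best) || score > best$score) {
      best <- list(score = score, q1 = q1_try, ok = ok, ords = ords)
    }
  }
  keep <- which(best$ok)
  orders <- best$ords[keep]
  centers <- q_cand[keep]
  if (is.null(window_halfwidth)) window_halfwidth <- 0.4 * best$q1

  fits <- purrr::map2(centers, orders, function(ctr, ord) {
    sel <- abs(q - ctr) <= window_halfwidth
    if (sum(sel) < 7L) sel <- abs(q - ctr) <= 2 * window_halfwidth
    xx <- q[sel]; yy <- y[sel]
    sig0 <- max(diff(q)[1] * 2, window_halfwidth / 10)
    fit <- tryCatch(
      fit_gaussians(xx, yy, init_centers = ctr, init_sigmas = sig0,
                    init_amps = max(yy) - min(yy), bg_degree = 1),
      rbcmem_fit_error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    tibble(order = ord, q = fit$centers[1], sigma = fit$sigmas[1],
           fwhm = sigma_to_fwhm(fit$sigmas[1]), intensity = fit$areas[1])
  })
  out <- dplyr::bind_rows(fits)
  out <- dplyr::arrange(out, .data$order)
  # least-squares slope through the origin: q_n = n * (2 pi / d)
  slope <- sum(out$order * out$q) / sum(out$order^2)
  class(out) <- c("lamellar_peaks", class(out))
  attr(out, "d") <- 2 * pi / slope
  attr(out, "q1") <- slope
  out
}

#' Lamellar repeat distance of a peak set
#' @param peaks A `lamellar_peaks` object.
#' @return `d` in angstrom.
#' @export
d_spacing <- function(peaks) {
  attr(peaks, "d")
}

#' @export
glance.lamellar_peaks <- function(x, ...) {
  tibble(d = attr(x, "d"), q1 = attr(x, "q1"), n_orders = nrow(x))
}

#' Hermans orientation analysis of a diffraction map
#'
#' Extracts the intensity along the arc `|q| = q_mag` as a function of the
#' meridional angle Phi (0 on the `q_z` axis), fits a Gaussian centred at
#' Phi = 0, and evaluates the Hermans orientation function
#' `H = (3 <cos^2 Phi> - 1) / 2` with solid-angle (`sin Phi`) weighting, so
#' that an isotropic profile gives `H = 0` and a perfectly oriented stack
#' `H = 1`.
#'
#' @param map An [intensity_map()].
#' @param q_mag Arc radius, 1/angstrom; typically the first-order lamellar
#'   peak position.
#' @param method `"fitted"` (default) computes `<cos^2 Phi>` under the
#'   fitted Gaussian; `"raw"` integrates the extracted profile directly.
#' @param n_phi Number of angular samples across `[-90, 90]` degrees.
#' @return An `orientation_profile` tibble with columns `phi` (degrees) and
#'   `intensity`, and attributes `H`, `sigma_phi` (fitted Gaussian sigma,
#'   degrees) and `method`.
#' @export
hermans_orientation <- function(map, q_mag, method = c("fitted", "raw"),
                                n_phi = 181) {
  stopifnot(inherits(map, "intensity_map"))
  method <- match.arg(method)
  check_number(q_mag, "q_mag", positive = TRUE)
  phi <- seq(-90, 90, length.out = n_phi)
  qp <- q_mag * sin(deg2rad(phi))
  qz <- q_mag * cos(deg2rad(phi))
  inten <- map_interp(map, qp, qz)
  if (all(is.na(inten))) {
    stop_rbcmem("arc |q| = q_mag lies outside the map.",
                class = "rbcmem_invalid_parameter")
  }
  ok <- !is.na(inten)
  profile <- tibble(phi = phi[ok], intensity = inten[ok])

  if (method == "fitted") {
    fit <- fit_gaussians(profile$phi, profile$intensity,
                         init_centers = 0, init_sigmas = 10,
                         init_amps = max(profile$intensity), bg_degree = 0,
                         fix_centers = TRUE)
    sigma_deg <- fit$sigmas[1]
    baseline <- max(fit$bg[1], 0)
    amp <- fit$amps[1]
    f <- function(phi_rad) {
      amp * exp(-rad2deg(phi_rad)^2 / (2 * sigma_deg^2)) + baseline
    }
  } else {
    sigma_deg <- NA_real_
    prof_fun <- stats::approxfun(deg2rad(abs(profile$phi)), profile$intensity,
                                 rule = 2, ties = mean)
    f <- prof_fun
  }
  num <- integrate(function(p) cos(p)^2 * f(p) * sin(p), 0, pi / 2,
                   rel.tol = 1e-9)$value
  den <- integrate(function(p) f(p) * sin(p), 0, pi / 2, rel.tol = 1e-9)$value
  cos2 <- num / den
  H <- (3 * cos2 - 1) / 2
  class(profile) <- c("orientation_profile", class(profile))
  attr(profile, "H") <- H
  attr(profile, "cos2") <- cos2
  attr(profile, "sigma_phi") <- sigma_deg
  attr(profile, "method") <- method
  profile
}

#' @export
glance.orientation_profile <- function(x, ...) {
  tibble(H = attr(x, "H"), cos2 = attr(x, "cos2"),
         sigma_phi = attr(x, "sigma_phi"), method = attr(x, "method"))
}

#' Hermans orientation parameter from a fitted profile
#' @param profile An `orientation_profile`.
#' @return `H`, dimensionless, in `[-0.5, 1]`.
#' @export
hermans_h <- function(profile) attr(profile, "H")
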