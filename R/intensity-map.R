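#' Gridded two-dimensional scattering intensity map
#'
#' Container for a detector-style intensity map over an in-plane wavevector
#' grid `q_par` and an out-of-plane grid `q_z`. Rows of `intensity` index
#' `q_z`, columns index `q_par`.
#'
#' @param q_par In-plane wavevector grid, 1/angstrom, strictly ascending.
#' @param q_z Out-of-plane wavevector grid, 1/angstrom, strictly ascending.
#' @param intensity Matrix of counts, `length(q_z)` rows by `length(q_par)`
#'   columns, non-negative.
#' @param wavelength X-ray wavelength in angstrom (Cu K-alpha 1.5418 by
#'   default).
#' @return An object of class `intensity_map`.
#' @export
intensity_map <- function(q_par, q_z, intensity,
                          wavelength = .rbcmem_default_wavelength) {
  check_ascending(q_par, "q_par")
  check_ascending(q_z, "q_z")
  check_number(wavelength, "wavelength", positive = TRUE)
  if (!is.matrix(intensity) ||
      nrow(intensity) != length(q_z) || ncol(intensity) != length(q_par)) {
    stop_rbcmem(sprintf(
      "`intensity` must be a %d x %d matrix (q_z rows x q_par columns); got %s.",
      length(q_z), length(q_par),
      paste(dim(intensity), collapse = " x ")),
      class = "rbcmem_invalid_parameter")
  }
  if (anyNA(intensity)) {
    stop_rbcmem(sprintf("`intensity` contains %d NA/NaN pixels.",
                        sum(is.na(intensity))),
                class = "rbcmem_invalid_parameter")
  }
  if (any(intensity < 0)) {
    stop_rbcmem("`intensity` must be non-negative.",
                class = "rbcmem_invalid_parameter")
  }
  structure(list(q_par = as.numeric(q_par), q_z = as.numeric(q_z),
                 intensity = intensity, wavelength = wavelength),
            class = "intensity_map")
}

#' @export
print.intensity_map <- function(x, ...) {
  cat(sprintf(
    "<intensity_map> %d x %d pixels | q_par [%.4f, %.4f] 1/A | q_z [%.4f, %.4f] 1/A | lambda %.4f A\n",
    length(x$q_z), length(x$q_par),
    min(x$q_par), max(x$q_par), min(x$q_z), max(x$q_z), x$wavelength))
  invisible(x)
}

#' @export
as_tibble.intensity_map <- function(x, ...) {
  tidyr::expand_grid(q_z = x$q_z, q_par = x$q_par) |>
    dplyr::mutate(intensity = as.vector(t(x$intensity)))
}

# bilinear interpolation on the map grid; points outside return NA
map_interp <- function(map, q_par, q_z) {
  gx <- map$q_par
  gz <- map$q_z
  ix <- findInterval(q_par, gx)
  iz <- findInterval(q_z, gz)
  out <- rep(NA_real_, length(q_par))
  ok <- ix >= 1 & ix < length(gx) & iz >= 1 & iz < length(gz)
  if (!any(ok)) return(out)
  ix <- ix[ok]; iz <- iz[ok]
  tx <- (q_par[ok] - gx[ix]) / (gx[ix + 1] - gx[ix])
  tz <- (q_z[ok] - gz[iz]) / (gz[iz + 1] - gz[iz])
  m <- map$intensity
  v <- (1 - tz) * ((1 - tx) * m[cbind(iz, ix)] + tx * m[cbind(iz, ix + 1)]) +
    tz * ((1 - tx) * m[cbind(iz + 1, ix)] + tx * m[cbind(iz + 1, ix + 1)])
  out[ok] <- v
  out
}

#' Plot an intensity map
#'
#' @param object An [intensity_map()].
#' @param trans Transformation for the fill scale (default `"log10"` with a
#'   small offset applied to zero pixels).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intensity_map <- function(object, trans = "log10", ...) {
  df <- as_tibble(object)
  if (identical(trans, "log10")) {
    eps <- min(df$intensity[df$intensity > 0], na.rm = TRUE)
    df$intensity <- df$intensity + eps
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$q_par, .data$q_z,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(trans = trans, name = "I (counts)") +
    ggplot2::labs(x = expression(q["||"] ~ (ring(A)^-1)),
                  y = expression(q[z] ~ (ring(A)^-1))) +
    ggplot2::coord_fixed()
}
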