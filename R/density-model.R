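#' Two-Gaussian bilayer electron-density model
#'
#' Parametric model of the relative electron density of one bilayer period:
#' a pair of positive Gaussians at `+/- head_position` (the electron-rich
#' phosphate head groups) and a negative Gaussian trough at the bilayer
#' centre (the CH3-rich core). The profile is symmetric under `z -> -z` by
#' construction, as required for a centrosymmetric stack.
#'
#' @param head_position Head-group peak position `z_H` in angstrom (> 0).
#' @param head_width Gaussian width (sigma) of the head peaks, angstrom.
#' @param head_amplitude Relative amplitude of the head peaks.
#' @param trough_width Gaussian width of the central trough, angstrom.
#' @param trough_amplitude Relative (negative) amplitude of the trough.
#' @param d Lamellar repeat distance in angstrom; must exceed `2 * head_position`.
#'
#' @return An object of class `density_model`.
#' @examples
#' dm <- density_model(head_position = 20, d = 55.4)
#' rho <- eval_density(dm, seq(-dm$d / 2, dm$d / 2, length.out = 11))
#' @export
density_model <- function(head_position = 20, head_width = 3,
                          head_amplitude = 1, trough_width = 6,
                          trough_amplitude = -0.7, d = 55.4) {
  check_number(head_position, "head_position", positive = TRUE)
  check_number(head_width, "head_width", positive = TRUE)
  check_number(trough_width, "trough_width", positive = TRUE)
  check_number(head_amplitude, "head_amplitude")
  check_number(trough_amplitude, "trough_amplitude")
  check_number(d, "d", positive = TRUE)
  if (d <= 2 * head_position) {
    stop_rbcmem("lamellar period `d` must exceed twice the head position.",
                class = "rbcmem_invalid_parameter")
  }
  structure(
    list(head_position = head_position, head_width = head_width,
         head_amplitude = head_amplitude, trough_width = trough_width,
         trough_amplitude = trough_amplitude, d = d),
    class = "density_model"
  )
}

#' Evaluate a bilayer density model
#'
#' @param model A [density_model()].
#' @param z Heights in angstrom (bilayer centre at 0).
#' @return Numeric vector of relative electron density.
#' @export
eval_density <- function(model, z) {
  stopifnot(inherits(model, "density_model"))
  g <- function(z0, w, a) a * exp(-(z - z0)^2 / (2 * w^2))
  g(model$head_position, model$head_width, model$head_amplitude) +
    g(-model$head_position, model$head_width, model$head_amplitude) +
    g(0, model$trough_width, model$trough_amplitude)
}

#' Continuous form factor of a density model
#'
#' Cosine transform of the symmetric density profile over one period,
#' `F(q) = integral rho(z) cos(q z) dz`. For the Gaussian components the
#' transform is analytic (tails beyond `+/- d/2` are negligible for
#' physically sensible widths).
#'
#' @param model A [density_model()].
#' @param q Wavevectors in 1/angstrom.
#' @return `F(q)` (signed, relative units).
#' @export
model_form_factor <- function(model, q) {
  stopifnot(inherits(model, "density_model"))
  # Gaussian pair at +/- z0: 2 a w sqrt(2 pi) cos(q z0) exp(-q^2 w^2 / 2) / 2 each
  head <- 2 * model$head_amplitude * model$head_width * sqrt(2 * pi) *
    cos(q * model$head_position) * exp(-q^2 * model$head_width^2 / 2)
  trough <- model$trough_amplitude * model$trough_width * sqrt(2 * pi) *
    exp(-q^2 * model$trough_width^2 / 2)
  head + trough
}

#' Lamellar peak intensities implied by a density model
#'
#' Samples the continuous form factor at the Bragg positions
#' `q_n = 2 pi n / d` and converts to integrated peak intensities through
#' `I_n = F(q_n)^2 / q_n`, the convention under which `F(q_n) = sqrt(I_n q_n)`.
#'
#' @param model A [density_model()].
#' @param n_orders Number of lamellar orders.
#' @return A tibble with columns `order`, `q`, `form_factor`, `intensity`,
#'   and the generating sign `nu` (sign of `F(q_n)`).
#' @export
model_peak_intensities <- function(model, n_orders = 5) {
  check_number(n_orders, "n_orders", positive = TRUE)
  n <- seq_len(n_orders)
  qn <- 2 * pi * n / model$d
  f <- model_form_factor(model, qn)
  tibble(order = n, q = qn, form_factor = f,
         intensity = f^2 / qn, nu = ifelse(f >= 0, 1, -1))
}
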