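#' Synthetic specular-diffraction scene
#'
#' Parameters for the forward model of a two-dimensional lamellar diffraction
#' map: a bilayer density model, instrument smearing (radial resolution width
#' and a Gaussian mosaic spread of the stack normal), number of observable
#' orders, and a counting-noise scale.
#'
#' @param density_model A [density_model()].
#' @param mosaic_width Gaussian sigma of the meridional-angle spread, degrees.
#' @param resolution_width Radial Gaussian smearing sigma, 1/angstrom.
#' @param n_orders Number of lamellar orders to include (>= 1).
#' @param noise_seed Integer seed used when Poisson noise is applied.
#' @param counts_scale Expected counts corresponding to one intensity unit.
#' @return An object of class `synth_scene`.
#' @export
synth_scene <- function(density_model = rbcmem::density_model(),
                        mosaic_width = 8, resolution_width = 0.004,
                        n_orders = 5, noise_seed = 1L,
                        counts_scale = 1e6) {
  stopifnot(inherits(density_model, "density_model"))
  check_number(mosaic_width, "mosaic_width", positive = TRUE)
  check_number(resolution_width, "resolution_width", positive = TRUE)
  check_number(n_orders, "n_orders", positive = TRUE)
  check_number(counts_scale, "counts_scale", positive = TRUE)
  structure(list(density_model = density_model,
                 mosaic_width = mosaic_width,
                 resolution_width = resolution_width,
                 n_orders = as.integer(n_orders),
                 noise_seed = as.integer(noise_seed),
                 counts_scale = counts_scale),
            class = "synth_scene")
}

#' Forward-model a lamellar diffraction map
#'
#' Places `n_orders` lamellar peaks at `q_z = n 2 pi / d` on the meridian
#' (`q_par = 0`), each carrying integrated intensity `I_n = F(q_n)^2 / q_n`
#' with `F` the cosine-transform form factor of the scene's density model.
#' Peaks are smeared radially by a Gaussian of sigma `resolution_width` and
#' in the meridional angle by a Gaussian of sigma `mosaic_width`; the map is
#' expressed in expected counts (`counts_scale` counts per unit intensity)
#' and optionally Poisson-sampled.
#'
#' @param scene A [synth_scene()].
#' @param q_par_range,q_z_range Grid extents, 1/angstrom. Defaults cover all
#'   requested orders with margin.
#' @param n_par,n_z Grid sizes.
#' @param noise Apply Poisson noise (using `scene$noise_seed`)? Default TRUE.
#' @return An [intensity_map()] with the scene attached as attribute
#'   `"ground_truth"`.
#' @export
gen_lamellar_map <- function(scene, q_par_range = NULL, q_z_range = NULL,
                             n_par = 201, n_z = 400, noise = TRUE) {
  stopifnot(inherits(scene, "synth_scene"))
  dm <- scene$density_model
  q1 <- 2 * pi / dm$d
  if (is.null(q_par_range)) q_par_range <- c(-0.25, 0.25) * q1 * scene$n_orders
  if (is.null(q_z_range)) q_z_range <- c(0.25 * q1, (scene$n_orders + 0.75) * q1)
  q_par <- seq(q_par_range[1], q_par_range[2], length.out = n_par)
  q_z <- seq(q_z_range[1], q_z_range[2], length.out = n_z)

  peaks <- model_peak_intensities(dm, scene$n_orders)
  qq <- sqrt(outer(q_z^2, q_par^2, `+`))          # |q| per pixel
  phi <- atan2(matrix(rep(abs(q_par), each = length(q_z)), nrow = length(q_z)),
               matrix(rep(q_z, length(q_par)), nrow = length(q_z)))
  sig_phi <- deg2rad(scene$mosaic_width)
  expected <- matrix(0, length(q_z), length(q_par))
  for (i in seq_len(nrow(peaks))) {
    radial <- stats::dnorm(qq - peaks$q[i], sd = scene$resolution_width)
    angular <- stats::dnorm(phi, sd = sig_phi)
    expected <- expected + peaks$intensity[i] * radial * angular / qq
  }
  # counts_scale sets the expected counts in the brightest pixel
  expected <- expected / max(expected) * scene$counts_scale
  counts <- if (noise) {
    with_seed(scene$noise_seed,
              matrix(rpois(length(expected), lambda = expected),
                     nrow = nrow(expected)))
  } else {
    expected
  }
  out <- intensity_map(q_par, q_z, counts)
  attr(out, "ground_truth") <- list(scene = scene, peaks = peaks)
  out
}
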