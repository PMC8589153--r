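# shared builders for synthetic fixtures used across test files

make_flat_trajectory <- function(z0 = 0, n_frames = 12, n_beads = 100,
                                 box = 200, seed = 1) {
  frames <- rbcmem:::with_seed(seed, lapply(seq_len(n_frames), function(i) {
    tibble::tibble(
      x = runif(2 * n_beads, 0, box), y = runif(2 * n_beads, 0, box),
      z = rep(c(z0 + 20, z0 - 20), each = n_beads),
      leaflet = rep(c("upper", "lower"), each = n_beads),
      role = "head", time_ns = 200 + (i - 1) * 4)
  }))
  structure(list(frames = frames, box = c(box, box), frame_interval = 4),
            class = "bead_trajectory")
}

make_density_map <- function(m, bin_size = 5, component = "chol") {
  g <- nrow(m)
  structure(list(x = (seq_len(g) - 0.5) * bin_size,
                 y = (seq_len(ncol(m)) - 0.5) * bin_size,
                 counts_per_area = m, component = component,
                 frames_averaged = 1,
                 box = c(g * bin_size, ncol(m) * bin_size)),
            class = "density_map")
}

# reference three-peak synthetic pattern matching the wide-angle geometry
ref_inplane_peaks <- function(area_ld = 3000, area_lo = 2000,
                              area_prot = 150) {
  tibble::tibble(center = c(0.70, 1.35, 1.73),
                 sigma = c(0.10, 0.086, 0.157),
                 area = c(area_prot, area_ld, area_lo))
}
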