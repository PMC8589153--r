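# Readers and writers for the package's plain-text interchange formats:
# intensity maps (TSV matrix or float TIFF + JSON sidecar), two-column
# curves (TSV), multi-frame XYZ bead trajectories with leaflet/role tags,
# and lipidomics CSV tables.

#' Write an intensity map with a JSON sidecar
#'
#' Writes the intensity matrix as a whitespace-delimited text matrix
#' (default) or a float TIFF, plus a JSON sidecar carrying the q-grids,
#' wavelength and (for TIFF) the intensity scale.
#'
#' @param map An [intensity_map()].
#' @param path Output path for the matrix/TIFF.
#' @param sidecar Sidecar path; defaults to `paste0(path, ".json")`.
#' @param format `"tsv"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_intensity_map <- function(map, path, sidecar = paste0(path, ".json"),
                                format = c("tsv", "tiff")) {
  stopifnot(inherits(map, "intensity_map"))
  format <- match.arg(format)
  scale <- 1
  if (format == "tsv") {
    write.table(map$intensity, path, row.names = FALSE, col.names = FALSE)
  } else {
    scale <- max(map$intensity, 1e-300)
    tiff::writeTIFF(map$intensity / scale, path, bits.per.sample = 32L,
                    compression = "none", reduce = FALSE)
  }
  jsonlite::write_json(
    list(q_par = map$q_par, q_z = map$q_z,
         wavelength = list(value = map$wavelength, units = "angstrom"),
         intensity_scale = scale, format = format),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an intensity map written by [write_intensity_map()]
#'
#' @param path Matrix/TIFF path.
#' @param sidecar Sidecar path supplying the grids and wavelength.
#' @return An [intensity_map()]. A missing wavelength falls back to
#'   1.5418 angstrom (Cu K-alpha) with a warning; NaN pixels are rejected
#'   with their count reported.
#' @export
read_intensity_map <- function(path, sidecar = paste0(path, ".json")) {
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$wavelength$value) && is.null(meta$wavelength)) {
    warn("sidecar carries no wavelength; defaulting to 1.5418 angstrom.")
  }
  wl <- meta$wavelength$value %||% meta$wavelength %||% {
    .rbcmem_default_wavelength
  }
  fmt <- meta$format %||% "tsv"
  m <- if (identical(fmt, "tiff")) {
    tiff::readTIFF(path) * (meta$intensity_scale %||% 1)
  } else {
    as.matrix(read.table(path, header = FALSE))
  }
  dimnames(m) <- NULL
  if (nrow(m) != length(meta$q_z) || ncol(m) != length(meta$q_par)) {
    stop_rbcmem(sprintf(
      "matrix shape %d x %d does not match sidecar grids %d x %d.",
      nrow(m), ncol(m), length(meta$q_z), length(meta$q_par)),
      class = "rbcmem_invalid_parameter")
  }
  intensity_map(meta$q_par, meta$q_z, m, wavelength = wl)
}

#' Write a two-column curve as TSV
#' @param curve Data frame whose first two columns are written.
#' @param path Output path.
#' @param col_names Column names to use.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path, col_names = names(curve)[1:2]) {
  df <- as.data.frame(curve)[, 1:2]
  names(df) <- col_names
  write.table(df, path, row.names = FALSE, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read a two-column TSV curve
#' @param path Input path.
#' @param col_names Names to assign (defaults to the file header).
#' @return A tibble with two numeric columns.
#' @export
read_curve <- function(path, col_names = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t")
  if (!is.null(col_names)) names(df) <- col_names
  as_tibble(df)
}

#' Write a bead trajectory as multi-frame XYZ
#'
#' One XYZ block per frame; the atom-name column carries the
#' `leaflet:role` tag and the comment line records the time stamp and box.
#'
#' @param traj A `bead_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in traj$frames) {
    writeLines(as.character(nrow(f)), con)
    writeLines(sprintf("time_ns= %.6g box %.6f %.6f", f$time_ns[1],
                       traj$box[1], traj$box[2]), con)
    writeLines(sprintf("%s:%s %.6f %.6f %.6f", f$leaflet, f$role,
                       f$x, f$y, f$z), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ bead trajectory
#' @param path Path written by [write_trajectory_xyz()] (or compatible:
#'   atom names tagged `leaflet:role`).
#' @param frame_interval Frame interval in ns (metadata fallback when the
#'   comment lines carry no time stamps).
#' @return A `bead_trajectory`.
#' @export
read_trajectory_xyz <- function(path, frame_interval = 4) {
  lines <- readLines(path)
  frames <- list()
  box <- c(NA_real_, NA_real_)
  i <- 1L
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1L]
    tm <- as.numeric(sub(".*time_ns=\\s*([-0-9.eE+]+).*", "\\1", comment))
    bx <- regmatches(comment, regexec("box\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
                                      comment))[[1]]
    if (length(bx) == 3) box <- as.numeric(bx[2:3])
    rows <- lines[(i + 2L):(i + 1L + n)]
    parts <- strsplit(trimws(rows), "\\s+")
    tag <- vapply(parts, `[[`, character(1), 1)
    tagparts <- strsplit(tag, ":", fixed = TRUE)
    frames[[length(frames) + 1L]] <- tibble(
      x = as.numeric(vapply(parts, `[[`, character(1), 2)),
      y = as.numeric(vapply(parts, `[[`, character(1), 3)),
      z = as.numeric(vapply(parts, `[[`, character(1), 4)),
      leaflet = vapply(tagparts, `[[`, character(1), 1),
      role = vapply(tagparts, function(p) p[min(2, length(p))], character(1)),
      time_ns = if (is.na(tm)) (length(frames)) * frame_interval else tm)
    i <- i + 2L + n
  }
  structure(list(frames = frames, box = box,
                 frame_interval = frame_interval),
            class = "bead_trajectory")
}

#' Write / read a lipidomics table as CSV
#' @param table A lipidomics tibble.
#' @param path CSV path.
#' @return `path` (write) or a tibble (read).
#' @export
write_lipid_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lipid_table
#' @export
read_lipid_table <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
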