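#' Curated coarse-grained lipid model catalogue
#'
#' Loads the catalogue of coarse-grained lipid models shipped with the
#' package: a curated plain-text table of Martini-2.2-style model lipids
#' (name, head-group class, two tail lengths in carbons, double bonds per
#' tail). Single-tail classes (FA) use a zero second tail. The catalogue
#' carries only the attributes the mapping needs; it is not a force field.
#'
#' @param path Optional path to an alternative catalogue CSV.
#' @return A tibble with columns `name`, `lipid_class`, `tail1_length`,
#'   `tail2_length`, `double_bonds1`, `double_bonds2`.
#' @export
cg_catalogue <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cg_lipid_catalogue.csv",
                                package = "rbcmem")
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(out)
}

#' Map measured lipid species to coarse-grained models
#'
#' For every species, finds the same-class catalogue model minimising the
#' error coefficient
#' `e = w_len * (|dt1| + |dt2|) + w_sat * (|ddb1| + |ddb2|)`
#' (tail-length and tail-saturation differences; equal weights by
#' default). Ties are broken lexicographically by model name. Class must
#' match exactly; an empty same-class catalogue raises an error naming the
#' class unless `cross_class_fallback` is set, in which case the best
#' match over the whole catalogue is used and flagged.
#'
#' @param species A tibble with columns `lipid_class`, `tail1_length`,
#'   `tail2_length`, `double_bonds1`, `double_bonds2` (one or many rows).
#' @param catalogue A catalogue tibble, default [cg_catalogue()].
#' @param weights Length-2 numeric `c(w_len, w_sat)`, default `c(1, 1)`.
#' @param cross_class_fallback Allow cross-class matches when a class has
#'   no model? Default FALSE.
#' @return The `species` tibble with added columns `cg_name`, `cg_error`
#'   and `cross_class` (logical).
#' @export
map_species <- function(species, catalogue = cg_catalogue(),
                        weights = c(1, 1), cross_class_fallback = FALSE) {
  needed <- c("lipid_class", "tail1_length", "tail2_length",
              "double_bonds1", "double_bonds2")
  stopifnot(all(needed %in% names(species)))
  w_len <- weights[1]; w_sat <- weights[2]
  pick <- function(cls, t1, t2, d1, d2) {
    cand <- catalogue[catalogue$lipid_class == cls, , drop = FALSE]
    cross <- FALSE
    if (nrow(cand) == 0L) {
      if (!cross_class_fallback) {
        stop_rbcmem(sprintf("no coarse-grained model for class '%s'.", cls),
                    class = "rbcmem_invalid_parameter")
      }
      cand <- catalogue
      cross <- TRUE
    }
    e <- w_len * (abs(cand$tail1_length - t1) + abs(cand$tail2_length - t2)) +
      w_sat * (abs(cand$double_bonds1 - d1) + abs(cand$double_bonds2 - d2))
    ord <- order(e, cand$name)
    list(name = cand$name[ord[1]], error = e[ord[1]], cross = cross)
  }
  res <- purrr::pmap(list(species$lipid_class, species$tail1_length,
                          species$tail2_length, species$double_bonds1,
                          species$double_bonds2), pick)
  dplyr::mutate(as_tibble(species),
                cg_name = vapply(res, `[[`, character(1), "name"),
                cg_error = vapply(res, `[[`, numeric(1), "error"),
                cross_class = vapply(res, `[[`, logical(1), "cross"))
}

#' Distribute lipid counts between leaflets
#'
#' Splits per-model (or per-class) lipid counts into upper- and
#' lower-leaflet integer counts according to per-class upper fractions
#' (e.g. 75% of PC in the upper leaflet), using largest-remainder rounding
#' so that totals are conserved exactly; on a remainder tie the upper
#' leaflet is filled first.
#'
#' @param composition A tibble with columns `lipid_class`, `count` and
#'   optionally `name`.
#' @param asymmetry Named numeric vector of upper-leaflet fractions in
#'   `[0, 1]`, one entry per class present.
#' @return The composition tibble with added integer columns `upper` and
#'   `lower` (`upper + lower == count` rowwise).
#' @export
assign_leaflets <- function(composition, asymmetry) {
  stopifnot(all(c("lipid_class", "count") %in% names(composition)))
  missing_cls <- setdiff(unique(composition$lipid_class), names(asymmetry))
  if (length(missing_cls) > 0) {
    stop_rbcmem(sprintf("no asymmetry fraction for class(es): %s.",
                        paste(missing_cls, collapse = ", ")),
                class = "rbcmem_invalid_parameter")
  }
  if (any(asymmetry < 0 | asymmetry > 1)) {
    stop_rbcmem("asymmetry fractions must lie in [0, 1].",
                class = "rbcmem_invalid_parameter")
  }
  f <- asymmetry[composition$lipid_class]
  exact_up <- composition$count * f
  up <- floor(exact_up)
  lo <- floor(composition$count - exact_up)
  leftover <- composition$count - up - lo          # 0 or 1 per row
  rem_up <- exact_up - up
  rem_lo <- (composition$count - exact_up) - lo
  # largest remainder; tie -> upper first
  up <- up + ifelse(leftover > 0 & rem_up >= rem_lo, 1L, 0L)
  lo <- composition$count - up
  dplyr::mutate(as_tibble(composition), upper = as.integer(up),
                lower = as.integer(lo))
}

#' Summarise a lipidomics table
#'
#' Per-class abundance totals, tail-length histogram and double-bond
#' histogram (abundance-weighted, percentages renormalised to 100). When a
#' reference table is supplied, per-class storage deltas (table minus
#' reference) are included.
#'
#' @param table A lipidomics tibble (columns `lipid_class`, `tail1_length`,
#'   `tail2_length`, `double_bonds1`, `double_bonds2`, `abundance_pct`).
#' @param reference Optional second table (e.g. fresh sample) for deltas.
#' @return A list with tibbles `by_class`, `tail_length_hist`,
#'   `double_bond_hist`, and `delta_by_class` when `reference` is given.
#' @export
composition_summary <- function(table, reference = NULL) {
  check_lipid_table(table)
  tot <- sum(table$abundance_pct)
  if (abs(tot - 100) > 0.5) {
    stop_rbcmem(sprintf("abundances must sum to 100 +/- 0.5 (got %.3f).", tot),
                class = "rbcmem_invalid_parameter")
  }
  tab <- dplyr::mutate(as_tibble(table),
                       abundance_pct = .data$abundance_pct / tot * 100)
  by_class <- tab |>
    dplyr::group_by(.data$lipid_class) |>
    dplyr::summarise(abundance_pct = sum(.data$abundance_pct),
                     .groups = "drop")
  long_tails <- dplyr::bind_rows(
    tibble(length = tab$tail1_length, db = tab$double_bonds1,
           w = tab$abundance_pct),
    tibble(length = tab$tail2_length, db = tab$double_bonds2,
           w = tab$abundance_pct))
  long_tails <- long_tails[long_tails$length > 0, , drop = FALSE]
  long_tails$w <- long_tails$w / sum(long_tails$w) * 100
  tl <- long_tails |>
    dplyr::group_by(length = .data$length) |>
    dplyr::summarise(pct = sum(.data$w), .groups = "drop")
  db <- long_tails |>
    dplyr::group_by(db = .data$db) |>
    dplyr::summarise(pct = sum(.data$w), .groups = "drop")
  out <- list(by_class = by_class, tail_length_hist = tl,
              double_bond_hist = db)
  if (!is.null(reference)) {
    ref <- composition_summary(reference)
    out$delta_by_class <- dplyr::full_join(
      by_class, ref$by_class, by = "lipid_class",
      suffix = c("", "_ref")) |>
      dplyr::mutate(dplyr::across(dplyr::where(is.numeric),
                                  ~tidyr::replace_na(.x, 0))) |>
      dplyr::mutate(delta = .data$abundance_pct - .data$abundance_pct_ref)
  }
  out
}

check_lipid_table <- function(table) {
  needed <- c("lipid_class", "tail1_length", "tail2_length",
              "double_bonds1", "double_bonds2", "abundance_pct")
  stopifnot(all(needed %in% names(table)))
  if (any(table$abundance_pct < 0)) {
    stop_rbcmem("negative abundances are not allowed.",
                class = "rbcmem_invalid_parameter")
  }
  invisible(table)
}

#' Generate a synthetic red-cell membrane lipidomics table
#'
#' Emits lipid species across the classes PC, PE, PS, PI, PG, PA, SM, CER,
#' MG, DG and FA with tail lengths in 8-24 carbons and 0-6 double bonds,
#' with class abundances patterned on a fresh red-cell cytoplasmic
#' membrane (fatty acids below 1%). With `storage_shift = TRUE` the table
#' emulates long-term cold storage: free fatty acids rise to about 5%,
#' roughly 5 percentage points of tail abundance move from >= 16-carbon
#' tails to 8-12-carbon tails, and unsaturation increases slightly.
#' Abundances are normalised to sum to exactly 100.
#'
#' @param n_species Number of species (>= 5, default 60).
#' @param storage_shift Apply the storage signature? Default FALSE.
#' @param seed Integer seed.
#' @return A lipidomics tibble (columns `lipid_class`, `tail1_length`,
#'   `tail2_length`, `double_bonds1`, `double_bonds2`, `abundance_pct`).
#' @export
gen_lipidomics_table <- function(n_species = 60, storage_shift = FALSE,
                                 seed = 1L) {
  if (n_species < 5) {
    stop_rbcmem("`n_species` must be >= 5.",
                class = "rbcmem_invalid_parameter")
  }
  class_profile <- c(PC = 32, PE = 24, SM = 14, PS = 9, PI = 3.5, PG = 1.2,
                     PA = 1.5, CER = 4, MG = 3.5, DG = 4, FA = 0.6)
  single_tail <- c("FA")
  with_seed(seed, {
    classes <- sample(names(class_profile), n_species, replace = TRUE,
                      prob = class_profile)
    # guarantee every class is represented when there is room
    if (n_species >= length(class_profile)) {
      classes[seq_along(class_profile)] <- names(class_profile)
    }
    lengths_pool <- seq(8, 24, by = 2)
    # fresh membranes are dominated by 16-22 carbon tails
    len_prob <- stats::dnorm(lengths_pool, mean = 18, sd = 2.6)
    t1 <- sample(lengths_pool, n_species, replace = TRUE, prob = len_prob)
    t2 <- ifelse(classes %in% single_tail, 0,
                 sample(lengths_pool, n_species, replace = TRUE,
                        prob = len_prob))
    d1 <- pmin(rpois(n_species, 0.9), 6)
    d2 <- ifelse(t2 == 0, 0, pmin(rpois(n_species, 0.9), 6))
    # within-class abundance: exponential weights, then scaled to the
    # class profile
    w <- stats::rexp(n_species)
    tab <- tibble(lipid_class = classes, tail1_length = t1,
                  tail2_length = t2, double_bonds1 = d1, double_bonds2 = d2,
                  abundance_pct = w)
    tab <- tab |>
      dplyr::group_by(.data$lipid_class) |>
      dplyr::mutate(abundance_pct = .data$abundance_pct /
                      sum(.data$abundance_pct) *
                      class_profile[.data$lipid_class[1]]) |>
      dplyr::ungroup()
    if (storage_shift) {
      # fatty acids rise to about 5% of the lipidome
      fa <- tab$lipid_class == "FA"
      target_fa <- 5
      cur_fa <- sum(tab$abundance_pct[fa])
      if (cur_fa > 0) {
        tab$abundance_pct[fa] <- tab$abundance_pct[fa] / cur_fa * target_fa
        tab$abundance_pct[!fa] <- tab$abundance_pct[!fa] /
          sum(tab$abundance_pct[!fa]) * (100 - target_fa)
      }
      # ~5% of abundance moves from long-tail to short-tail species
      short <- tab$tail1_length <= 12 & tab$lipid_class != "FA"
      long <- tab$tail1_length >= 16 & tab$lipid_class != "FA"
      if (!any(short)) {
        # inject short-tail species by shortening the least abundant ones
        idx <- order(tab$abundance_pct + ifelse(fa, Inf, 0))[1:2]
        tab$tail1_length[idx] <- sample(c(8, 10, 12), 2, replace = TRUE)
        short <- tab$tail1_length <= 12 & !fa
        long <- tab$tail1_length >= 16 & !fa
      }
      move <- min(5, sum(tab$abundance_pct[long]) * 0.5)
      tab$abundance_pct[long] <- tab$abundance_pct[long] *
        (1 - move / sum(tab$abundance_pct[long]))
      tab$abundance_pct[short] <- tab$abundance_pct[short] +
        move * tab$abundance_pct[short] / sum(tab$abundance_pct[short])
      # slight unsaturation increase
      bump <- runif(n_species) < 0.25
      tab$double_bonds1 <- pmin(tab$double_bonds1 + ifelse(bump, 1L, 0L), 6L)
    }
    tab$abundance_pct <- tab$abundance_pct / sum(tab$abundance_pct) * 100
    tab
  })
}
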