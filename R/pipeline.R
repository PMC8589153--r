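#' Pipeline configuration
#'
#' Builds and validates the configuration driving [run_pipeline()]. Every
#' stochastic stage has an explicit seed; unknown keys are rejected. The
#' configuration can also be loaded from a YAML file.
#'
#' @param output_dir Directory for stage outputs.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "specular", "inplane", "diffuse", "spectrum", "maps",
#'   "lipids")` in execution order, or `"all"`.
#' @param seeds Named list of integer seeds (`map`, `inplane`, `diffuse`,
#'   `trajectory`, `lipids`).
#' @param params Named list of stage parameters; recognised entries are
#'   `d`, `kappa`, `B_mod`, `n_layers`, `q_par_halfwidth`, `q_max`,
#'   `grid_n`, `n_frames`, `box_side`, `temperature`, `anchor_windows`,
#'   `init_centers`, `r_domain`.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(output_dir = tempfile("rbcmem_run_"),
                            stages = "all",
                            seeds = list(),
                            params = list()) {
  all_stages <- c("simulate", "specular", "inplane", "diffuse", "spectrum",
                  "maps", "lipids")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) {
    stop_rbcmem(sprintf("unknown stage(s): %s.", paste(bad, collapse = ", ")),
                class = "rbcmem_invalid_parameter")
  }
  seed_defaults <- list(map = 101L, inplane = 102L, diffuse = 103L,
                        trajectory = 104L, lipids = 105L)
  bad_seed <- setdiff(names(seeds), names(seed_defaults))
  if (length(bad_seed) > 0) {
    stop_rbcmem(sprintf("unknown seed key(s): %s.",
                        paste(bad_seed, collapse = ", ")),
                class = "rbcmem_invalid_parameter")
  }
  param_defaults <- list(
    d = 55.4, kappa = 1.9, B_mod = 1.2e-5, n_layers = 100,
    q_par_halfwidth = 0.05, q_max = 0.1, grid_n = 64, n_frames = 60,
    box_side = 340, temperature = .rbcmem_default_temperature,
    anchor_windows = list(c(0.35, 0.5), c(0.95, 1.1), c(2.0, 2.2)),
    init_centers = c(0.7, 1.3, 1.7), r_domain = 2000)
  bad_par <- setdiff(names(params), names(param_defaults))
  if (length(bad_par) > 0) {
    stop_rbcmem(sprintf("unknown parameter key(s): %s.",
                        paste(bad_par, collapse = ", ")),
                class = "rbcmem_invalid_parameter")
  }
  structure(list(output_dir = output_dir,
                 stages = stages,
                 seeds = modifyList(seed_defaults, seeds),
                 params = modifyList(param_defaults, params)),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#' @param path YAML file with keys `output_dir`, `stages`, `seeds`,
#'   `params`.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(output_dir = y$output_dir %||% tempfile("rbcmem_run_"),
                  stages = y$stages %||% "all",
                  seeds = y$seeds %||% list(),
                  params = y$params %||% list())
}

with_units <- function(value, units) list(value = value, units = units)

#' Run the analysis pipeline on all-synthetic inputs
#'
#' Executes the requested stages in order. The `simulate` stage writes
#' synthetic inputs (diffraction map, in-plane pattern, diffuse cuts, bead
#' trajectory, fresh/stored lipidomics tables) into `output_dir`; analysis
#' stages read them back through the package's file formats, run the
#' corresponding module, and write one JSON results record each (every
#' numeric output carries a units field), plus a run manifest with the
#' configuration hash and seeds. A stage failure halts the run with the
#' stage name; outputs of completed stages persist.
#'
#' @param config A `pipeline_config` (or path to a YAML file).
#' @param quiet Suppress per-stage messages?
#' @return Named list of per-stage results (also serialised as JSON).
#' @export
run_pipeline <- function(config = pipeline_config(), quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  p <- config$params
  say <- function(...) if (!quiet) inform(sprintf(...))
  results <- list()
  paths <- list(
    map = file.path(config$output_dir, "lamellar_map.tsv"),
    pattern = file.path(config$output_dir, "inplane_pattern.tsv"),
    cuts = file.path(config$output_dir, paste0("diffuse_cut_", 1:2, ".tsv")),
    cuts_meta = file.path(config$output_dir, "diffuse_cuts.json"),
    traj = file.path(config$output_dir, "trajectory.xyz"),
    lipids_fresh = file.path(config$output_dir, "lipids_fresh.csv"),
    lipids_stored = file.path(config$output_dir, "lipids_stored.csv"))

  run_stage <- function(name, fun) {
    say("stage %s ...", name)
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(fun(), error = function(e) {
      stop_rbcmem(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                  class = "rbcmem_stage_error", stage = name)
    })
    out$elapsed_s <- round(proc.time()[["elapsed"]] - t0, 3)
    jsonlite::write_json(out, file.path(config$output_dir,
                                        paste0(name, "_results.json")),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    results[[name]] <<- out
    out
  }

  for (stage in config$stages) {
    switch(stage,
      simulate = run_stage("simulate", function() {
        scene <- synth_scene(density_model(d = p$d),
                             noise_seed = config$seeds$map)
        map <- gen_lamellar_map(scene)
        write_intensity_map(map, paths$map)
        pat <- gen_inplane_pattern(
          tibble(center = c(0.70, 1.35, 1.73), sigma = c(0.10, 0.086, 0.157),
                 area = c(120, 3000, 2000)),
          noise_seed = config$seeds$inplane)
        write_curve(pat, paths$pattern, c("q_par", "intensity"))
        stk <- smectic_stack(p$kappa, p$B_mod, p$d, n_layers = p$n_layers)
        cuts <- gen_diffuse_cuts(stk, seed = config$seeds$diffuse,
                                 r_domain = p$r_domain)
        for (i in seq_along(cuts)) {
          write_curve(cuts[[i]], paths$cuts[i], c("q_r", "intensity"))
        }
        jsonlite::write_json(
          list(q_z = vapply(cuts, attr, numeric(1), "q_z"),
               d = p$d, n_layers = p$n_layers),
          paths$cuts_meta, auto_unbox = TRUE, digits = NA)
        traj <- gen_height_trajectory(kappa = 3.2, box_side = p$box_side,
                                      grid_n = p$grid_n,
                                      n_frames = p$n_frames,
                                      seed = config$seeds$trajectory)
        write_trajectory_xyz(traj, paths$traj)
        write_lipid_table(gen_lipidomics_table(seed = config$seeds$lipids),
                          paths$lipids_fresh)
        write_lipid_table(gen_lipidomics_table(storage_shift = TRUE,
                                               seed = config$seeds$lipids),
                          paths$lipids_stored)
        list(written = unlist(paths, use.names = FALSE))
      }),
      specular = run_stage("specular", function() {
        map <- read_intensity_map(paths$map)
        refl <- extract_reflectivity(map, p$q_par_halfwidth)
        peaks <- find_lamellar_peaks(refl)
        ori <- hermans_orientation(map, attr(peaks, "q1"))
        ff <- fit_form_factor(peaks)
        prof <- fourier_density(peaks, ff$phases)
        write_curve(prof, file.path(config$output_dir,
                                    "electron_density.tsv"), c("z", "rho"))
        list(d = with_units(attr(peaks, "d"), "angstrom"),
             n_orders = nrow(peaks),
             H = with_units(hermans_h(ori), "dimensionless"),
             d_hh = with_units(attr(prof, "d_hh"), "angstrom"),
             water_layer = with_units(attr(prof, "water_layer"), "angstrom"),
             phases = attr(prof, "phases"))
      }),
      inplane = run_stage("inplane", function() {
        pat <- read_curve(paths$pattern)
        class(pat) <- c("inplane_pattern", class(pat))
        attr(pat, "background_corrected") <- FALSE
        corr <- correct_background(pat, anchors = p$anchor_windows)
        stats <- fit_three_peaks(corr, init_centers = p$init_centers)
        fr <- domain_fractions(stats)
        list(domains = lapply(seq_len(nrow(stats)), function(i) {
          list(component = stats$component[i],
               q_center = with_units(stats$q_center[i], "1/angstrom"),
               a = with_units(stats$a[i], "angstrom"),
               area_per_tail = with_units(stats$area_per_tail[i],
                                          "angstrom^2"),
               scherrer_size = with_units(stats$scherrer_size[i],
                                          "angstrom"))
        }),
        pct_ld = with_units(fr$pct_ld, "percent"),
        pct_lo = with_units(fr$pct_lo, "percent"))
      }),
      diffuse = run_stage("diffuse", function() {
        meta <- jsonlite::read_json(paths$cuts_meta, simplifyVector = TRUE)
        cuts <- lapply(seq_along(paths$cuts), function(i) {
          ct <- read_curve(paths$cuts[i])
          class(ct) <- c("diffuse_cut", class(ct))
          attr(ct, "q_z") <- meta$q_z[i]
          ct
        })
        init <- caille_model(2 * p$kappa, p$B_mod / 2, meta$d,
                             n_layers = meta$n_layers,
                             r_domain = p$r_domain)
        fit <- fit_diffuse(cuts, init)
        list(kappa = with_units(fit$model$kappa, "kBT"),
             B_mod = with_units(fit$model$B_mod, "kBT/angstrom^4"),
             eta = with_units(fit$model$eta, "dimensionless"),
             xi = with_units(fit$model$xi, "angstrom"),
             kappa_conf95 = with_units(
               fit$params$conf95[fit$params$term == "kappa"], "kBT"),
             converged = fit$converged, at_bounds = fit$at_bounds)
      }),
      spectrum = run_stage("spectrum", function() {
        traj <- read_trajectory_xyz(paths$traj)
        spec <- spectrum(traj, grid_n = p$grid_n)
        fit <- fit_hc(spec, q_max = p$q_max)
        write_curve(spec, file.path(config$output_dir, "spectrum.tsv"),
                    c("q", "power"))
        list(kappa = with_units(fit$kappa, "kBT"),
             conf95 = with_units(fit$conf95, "kBT"),
             n_frames = attr(spec, "n_frames"),
             q_max = with_units(fit$q_max, "1/angstrom"))
      }),
      maps = run_stage("maps", function() {
        traj <- read_trajectory_xyz(paths$traj)
        dm <- density_map(traj, "head", bin_size = 10)
        doms <- domain_sizes(dm, "rich")
        prof <- density_profile(traj, masses = c(head = 72),
                                bin_width = 2)
        write_curve(prof, file.path(config$output_dir, "z_profile.tsv"),
                    c("z", "mass_density"))
        list(n_domains = nrow(doms),
             mean_domain_diameter = with_units(
               if (nrow(doms) > 0) mean(doms$equivalent_diameter) else NA,
               "angstrom"),
             threshold = with_units(attr(doms, "threshold"), "1/angstrom^2"))
      }),
      lipids = run_stage("lipids", function() {
        fresh <- read_lipid_table(paths$lipids_fresh)
        stored <- read_lipid_table(paths$lipids_stored)
        summ <- composition_summary(stored, reference = fresh)
        mapped <- map_species(stored)
        counts <- mapped |>
          dplyr::count(.data$cg_name, .data$lipid_class, wt = NULL,
                       name = "n_species")
        fa_delta <- summ$delta_by_class$delta[
          summ$delta_by_class$lipid_class == "FA"]
        list(fa_pct_stored = with_units(
          summ$by_class$abundance_pct[summ$by_class$lipid_class == "FA"],
          "percent"),
          fa_delta = with_units(fa_delta, "percentage points"),
          n_models_used = nrow(counts),
          mean_mapping_error = with_units(mean(mapped$cg_error),
                                          "carbons + double bonds"))
      }),
      stop_rbcmem(sprintf("unknown stage '%s'.", stage))
    )
  }
  manifest <- list(
    package_version = as.character(utils::packageVersion("rbcmem")),
    config_hash = rlang::hash(config[c("stages", "seeds", "params")]),
    seeds = config$seeds,
    stages = config$stages)
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(results)
}
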