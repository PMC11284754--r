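# Run configuration, presets, the patch-layout experiment, and run
# reports.

#' Default run configuration
#'
#' Two presets: `"reduced"` (a ~30 x 30 sigma membrane of ~1,600
#' lipids, particle scaled to 6 sigma maximum radius with proportional
#' tips, horizon 2e3 tau; sized so property suites run on one CPU) and
#' `"paper"` (the full published protocol: 10,452 lipids in a 77 x 77
#' sigma box, 12 sigma particles, 5 replicas of 1e4 tau each).
#'
#' @param scale_preset "reduced" or "paper".
#' @return A nested `run_config` list with all defaults materialized.
#' @export
default_config <- function(scale_preset = c("reduced", "paper")) {
  scale_preset <- match.arg(scale_preset)
  if (scale_preset == "paper") {
    cfg <- list(
      scale_preset = "paper",
      particle = list(shape = "star", core_radius = 7, tip_count = 35L,
                      tip_length = 5, basal_tip_radius = 3,
                      tip_radius = 1.5, sphere_radius = 12,
                      bead_spacing = 1, ligand_depth = 3, n_patches = 35L,
                      ligands_per_site = 8L),
      membrane = list(n_lipids_x = 78L, n_lipids_y = 67L,
                      area_per_lipid = 1.1345, receptor_fraction = 0.5,
                      equilibration_tau = 1000),
      integrator = list(dt = 0.01, temperature = 1, gamma = 1,
                        barostat_damp = 1, area_modulus = 20,
                        bond_check_interval = 10L),
      kinetics = list(r_form = 1.3, p_form = 0.5, r_break = 4),
      run = list(horizon_tau = 10000, replicas = 5L, master_seed = 1L,
                 obs_stride = 100, frame_stride = 10000,
                 completion_threshold = 0.9, completion_hold = 100,
                 standoff = 1)
    )
  } else {
    cfg <- list(
      scale_preset = "reduced",
      particle = list(shape = "star", core_radius = 3.5, tip_count = 20L,
                      tip_length = 2.5, basal_tip_radius = 1.5,
                      tip_radius = 0.75, sphere_radius = 6,
                      bead_spacing = 1, ligand_depth = 2, n_patches = 20L,
                      ligands_per_site = 6L),
      membrane = list(n_lipids_x = 28L, n_lipids_y = 28L,
                      area_per_lipid = 1.1345, receptor_fraction = 0.5,
                      equilibration_tau = 200),
      integrator = list(dt = 0.01, temperature = 1, gamma = 1,
                        barostat_damp = 1, area_modulus = 20,
                        bond_check_interval = 10L),
      kinetics = list(r_form = 1.3, p_form = 0.5, r_break = 4),
      run = list(horizon_tau = 2000, replicas = 1L, master_seed = 1L,
                 obs_stride = 100, frame_stride = 1000,
                 completion_threshold = 0.9, completion_hold = 100,
                 standoff = 1)
    )
  }
  class(cfg) <- "run_config"
  cfg
}

flatten_config <- function(cfg, prefix = character(0)) {
  out <- character(0)
  for (nm in names(cfg)) {
    val <- cfg[[nm]]
    key <- paste(c(prefix, nm), collapse = ".")
    if (is.list(val)) {
      out <- c(out, flatten_config(val, c(prefix, nm)))
    } else {
      out <- c(out, sprintf("%s = %s", key,
                            if (is.character(val)) val else
                              paste(format(val, digits = 17), collapse = " ")))
    }
  }
  out
}

#' Load a run configuration from a flat key-value file
#'
#' The format is a hand-editable, diffable list of `section.key =
#' value` lines (`#` comments allowed). Unknown keys are rejected by
#' name; all unstated keys take their preset defaults (an empty file is
#' the all-defaults reduced preset). Setting `scale_preset = paper`
#' switches the default block before overrides are applied.
#'
#' @param path Config file path.
#' @return A fully materialized `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln)
  ln <- ln[nzchar(ln)]
  kv <- lapply(ln, function(l) {
    p <- regmatches(l, regexpr("=", l), invert = TRUE)[[1]]
    if (length(p) != 2) stop("config line not key = value: ", l)
    c(trimws(p[1]), trimws(p[2]))
  })
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  preset <- if ("scale_preset" %in% keys) vals[match("scale_preset", keys)] else "reduced"
  cfg <- default_config(preset)
  for (i in seq_along(keys)) {
    if (keys[i] == "scale_preset") next
    parts <- strsplit(keys[i], ".", fixed = TRUE)[[1]]
    node <- cfg
    for (d in seq_along(parts)) {
      if (is.null(node[[parts[d]]])) {
        stop("unknown config key: ", keys[i])
      }
      node <- node[[parts[d]]]
    }
    old <- cfg[[parts]]
    if (is.character(old)) {
      new_val <- vals[i]
    } else {
      new_val <- as.numeric(strsplit(vals[i], "\\s+")[[1]])
      if (anyNA(new_val)) {
        stop("non-numeric value for key ", keys[i], ": ", vals[i])
      }
      if (is.integer(old) && all(new_val == round(new_val))) {
        new_val <- as.integer(new_val)
      }
    }
    cfg[[parts]] <- new_val
  }
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$integrator$dt <= 0) stop("config error: integrator.dt must be positive")
  if (cfg$integrator$gamma <= 0) stop("config error: integrator.gamma must be positive")
  if (cfg$kinetics$r_form >= cfg$kinetics$r_break) {
    stop("config error: kinetics.r_form must be < kinetics.r_break")
  }
  if (cfg$membrane$receptor_fraction < 0 || cfg$membrane$receptor_fraction > 1) {
    stop("config error: membrane.receptor_fraction must be in [0, 1]")
  }
  if (cfg$run$replicas < 1) stop("config error: run.replicas must be >= 1")
  invisible(cfg)
}

#' Write a materialized configuration
#'
#' Every output directory receives this file so a run can be repeated
#' without the original config.
#'
#' @param cfg A `run_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  writeLines(flatten_config(unclass(cfg)), path)
  invisible(path)
}

particle_from_config <- function(cfg, shape = NULL, n_patches = NULL,
                                 ligands_per_site = NULL, seed = 1) {
  p <- cfg$particle
  if (!is.null(shape)) p$shape <- shape
  if (!is.null(n_patches)) p$n_patches <- n_patches
  if (!is.null(ligands_per_site)) p$ligands_per_site <- ligands_per_site
  spec <- nanoparticle_spec(shape = p$shape, core_radius = p$core_radius,
                            tip_count = p$tip_count,
                            tip_length = p$tip_length,
                            basal_tip_radius = p$basal_tip_radius,
                            tip_radius = p$tip_radius,
                            sphere_radius = p$sphere_radius,
                            bead_spacing = p$bead_spacing,
                            ligand_depth = p$ligand_depth,
                            n_patches = p$n_patches,
                            ligands_per_site = p$ligands_per_site)
  build_particle(spec, seed = seed)
}

#' Build a ligand-decorated particle from a spec
#'
#' @param spec A [nanoparticle_spec()].
#' @param seed Seed for ligand placement.
#' @return A `surface_beads` with ligands placed.
#' @export
build_particle <- function(spec, seed = 1) {
  if (spec$shape == "star") {
    surf <- generate_nanostar_surface(spec)
    place_tip_ligands(surf, spec$ligand_depth, spec$ligands_per_site, seed)
  } else {
    surf <- generate_sphere_surface(spec$sphere_radius, spec$bead_spacing)
    place_patch_ligands(surf, spec$n_patches, spec$ligands_per_site, seed)
  }
}

#' The seven published sphere patch layouts (plus the star baseline)
#'
#' Patch count x ligands-per-patch combinations compared against the
#' 35-tip star; every layout carries 56x5 = ... = 10x28 = 280 ligands.
#'
#' @return data.frame with columns `n_patches`, `ligands_per_site`.
#' @export
uptake_layouts <- function() {
  data.frame(n_patches = c(56L, 40L, 35L, 28L, 20L, 14L, 10L),
             ligands_per_site = c(5L, 7L, 8L, 10L, 14L, 20L, 28L))
}

#' Run (or plan) the patch-layout uptake experiment
#'
#' Simulates the star baseline plus the seven sphere layouts at the
#' configured scale, reporting per-layout separation metrics,
#' per-replica wrapping times and the sphere/star wrapping-time ratio
#' ("N/A" layouts propagate as NA). At the published scale this is an
#' hours-to-days computation; `dry_run = TRUE` returns the planned
#' layout table (with particles built and separations measured) without
#' running any dynamics.
#'
#' @param cfg A `run_config`.
#' @param dry_run If TRUE, skip all dynamics.
#' @param out_dir Optional output directory (materialized config,
#'   observable CSVs, summary JSON).
#' @return List with `layouts` (data.frame) and, unless dry_run,
#'   `star_times`, `sphere_times` (list) and `summary`.
#' @export
uptake_experiment <- function(cfg = default_config("paper"), dry_run = FALSE,
                              out_dir = NULL) {
  layouts <- uptake_layouts()
  star <- particle_from_config(cfg, shape = "star",
                               seed = cfg$run$master_seed)
  n_lig_star <- sum(star$kind == "ligand")
  layouts$total_ligands <- layouts$n_patches * layouts$ligands_per_site
  spheres <- lapply(seq_len(nrow(layouts)), function(i) {
    particle_from_config(cfg, shape = "sphere",
                         n_patches = layouts$n_patches[i],
                         ligands_per_site = layouts$ligands_per_site[i],
                         seed = cfg$run$master_seed)
  })
  layouts$sep_chord <- vapply(spheres, patch_separation, 0, variant = "chord")
  layouts$sep_geodesic <- vapply(spheres, patch_separation, 0,
                                 variant = "geodesic")
  out <- list(layouts = layouts, star_ligands = n_lig_star)
  if (dry_run) return(out)

  ff <- forcefield()
  icfg <- integrator_config(dt = cfg$integrator$dt,
                            temperature = cfg$integrator$temperature,
                            gamma = cfg$integrator$gamma,
                            barostat_damp = cfg$integrator$barostat_damp,
                            area_modulus = cfg$integrator$area_modulus,
                            bond_check_interval = cfg$integrator$bond_check_interval)
  kin <- bond_kinetics(cfg$kinetics$r_form, cfg$kinetics$p_form,
                       cfg$kinetics$r_break)
  run_group <- function(particle, seed_shift) {
    run_wrapping(particle, membrane = cfg$membrane,
                 horizon_tau = cfg$run$horizon_tau,
                 replicas = cfg$run$replicas,
                 master_seed = cfg$run$master_seed + seed_shift,
                 ff = ff, cfg = icfg, kinetics = kin,
                 obs_stride = cfg$run$obs_stride,
                 frame_stride = cfg$run$frame_stride,
                 standoff = cfg$run$standoff)
  }
  star_traces <- run_group(star, 0)
  tw <- function(traces) {
    vapply(traces, wrapping_time, 0,
           threshold = cfg$run$completion_threshold,
           hold = cfg$run$completion_hold)
  }
  star_tw <- tw(star_traces)
  sphere_tw <- vector("list", nrow(layouts))
  ratios <- rep(NA_real_, nrow(layouts))
  for (i in seq_len(nrow(layouts))) {
    traces <- run_group(spheres[[i]], 1000 * i)
    sphere_tw[[i]] <- tw(traces)
    ratios[i] <- if (all(is.na(sphere_tw[[i]])) || all(is.na(star_tw))) {
      NA_real_
    } else {
      mean(sphere_tw[[i]], na.rm = TRUE) / mean(star_tw, na.rm = TRUE)
    }
  }
  layouts$tw_ratio <- ratios
  layouts$n_completed <- vapply(sphere_tw, function(x) sum(!is.na(x)), 0L)
  out$layouts <- layouts
  out$star_times <- star_tw
  out$sphere_times <- sphere_tw
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_config(cfg, file.path(out_dir, "config.materialized"))
    utils::write.csv(layouts, file.path(out_dir, "table_layouts.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(star_times = star_tw, sphere_times = sphere_tw,
           ratios = ratios),
      file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  out
}

#' Emit a run report
#'
#' Human-readable summary plus machine-readable JSON for a completed
#' (or failed) run directory produced by the CLI or
#' [uptake_experiment()]: config hash, seeds, thresholds, completion
#' counts and observable summaries. Identical configs and seeds yield
#' identical report hashes.
#'
#' @param run_dir Directory containing `config.materialized` and run
#'   outputs.
#' @return Invisibly, the report list (also written to `report.json`
#'   and `report.txt` in `run_dir`).
#' @export
emit_run_report <- function(run_dir) {
  if (!dir.exists(run_dir)) stop("missing run dir: ", run_dir)
  cfg_path <- file.path(run_dir, "config.materialized")
  if (!file.exists(cfg_path)) stop("run dir has no materialized config")
  cfg_lines <- readLines(cfg_path)
  cfg_hash <- sum(utils::head(
    as.integer(charToRaw(paste(cfg_lines, collapse = "\n"))), 1e6) *
      (seq_along(charToRaw(paste(cfg_lines, collapse = "\n"))) %% 97 + 1)) %%
    .Machine$integer.max
  cfg <- load_config(cfg_path)
  report <- list(
    config_hash = cfg_hash,
    scale_preset = cfg$scale_preset,
    master_seed = cfg$run$master_seed,
    replicas = cfg$run$replicas,
    completion_threshold = cfg$run$completion_threshold,
    completion_hold = cfg$run$completion_hold,
    bond_check_interval = cfg$integrator$bond_check_interval,
    files = sort(list.files(run_dir))
  )
  sj <- file.path(run_dir, "summary.json")
  if (file.exists(sj)) report$summary <- jsonlite::read_json(sj)
  jsonlite::write_json(report, file.path(run_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- c("starwrap run report",
           sprintf("  config hash: %s", report$config_hash),
           sprintf("  preset: %s, master seed: %s, replicas: %s",
                   report$scale_preset, report$master_seed, report$replicas),
           sprintf("  completion: threshold %.3g sustained %.3g tau",
                   report$completion_threshold, report$completion_hold),
           sprintf("  bond check interval: %d steps",
                   as.integer(report$bond_check_interval)),
           sprintf("  files: %s", paste(report$files, collapse = ", ")))
  writeLines(txt, file.path(run_dir, "report.txt"))
  invisible(report)
}
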