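#' Default run configuration
#'
#' Nested configuration for the end-to-end pipeline. Every field can be
#' overridden from a YAML file ([read_run_config()]) or programmatically;
#' unknown keys are rejected. The defaults reproduce the probe's study
#' conditions: a 333 Hz spiral ramping to a 1.3 mm radius over 1 s with
#' 0.2 s braking and 0.3 s free decay, the five-step PRF schedule, the
#' printed transducer stack, and a 512 x 512 grid over the 2.6 mm field of
#' view. The acquisition stage divides every PRF by `prf_divisor`
#' (default 100) so that a full synthetic acquisition stays desk-scale.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    global = list(seed = 1L, out_dir = NULL),
    scanner = list(
      scan_frequency = 333, imaging_duration = 1, braking_duration = 0.2,
      decay_duration = 0.3, max_radius = 1.3e-3, ramp_shape = "linear",
      decay_time_constant = 0.1, sample_rate = 5e5, model = "kinematic",
      cantilever = list(youngs_modulus = 73e9, density = 2200,
                        radius = 62.5e-6, length = 18e-3,
                        mode_constant = 1.87510407^2 / 2)
    ),
    schedule = list(
      t_start = c(0.05, 0.1, 0.2, 0.3, 0.4),
      t_end = c(0.1, 0.2, 0.3, 0.4, 1.0),
      prf = c(20e3, 100e3, 200e3, 250e3, 500e3)
    ),
    transducer = list(
      source_impedance = 50, n_freq = 4096, f_max = 150e6,
      materials = NULL # NULL = pam_materials() defaults
    ),
    phantom = list(
      type = "vessel_tree", shape = c(128, 128, 48),
      voxel_size = c(2.6e-3 / 127, 2.6e-3 / 127, 6e-6),
      n_roots = 3, diameter_range = c(1e-4, 3e-4), tortuosity = 0.12,
      branching_prob = 0.02
    ),
    acquisition = list(
      sampling_rate = 250e6, speed_of_sound = 1500, record_length = 256L,
      focal_spot_sigma = 12e-6, noise_sigma = 0, prf_divisor = 100,
      use_transducer_impulse = FALSE
    ),
    reconstruction = list(grid_size = 128L, k_neighbors = 4L, idw_power = 1),
    quantification = list(mask_method = "otsu", threshold_diameter = 1e-4)
  ), class = "run_config")
}

check_known_keys <- function(cfg, template, path = "") {
  extra <- setdiff(names(cfg), names(template))
  if (length(extra)) {
    abort(sprintf("Unknown config key%s: %s", if (length(extra) > 1) "s" else "",
                  paste0(path, extra, collapse = ", ")),
          class = "spiralpam_config_error")
  }
  for (nm in names(cfg)) {
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]])) &&
        is.list(cfg[[nm]])) {
      check_known_keys(cfg[[nm]], template[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

#' Read (and validate) a run configuration from YAML
#'
#' Values present in the file override the defaults; unknown keys raise a
#' config error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list applied on top of the file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    check_known_keys(user, cfg)
    cfg <- modifyList(cfg, user)
  }
  if (!is.null(overrides)) {
    check_known_keys(overrides, cfg)
    cfg <- modifyList(cfg, overrides)
  }
  class(cfg) <- "run_config"
  cfg
}

# one global seed fans out to fixed per-stage seeds so a stage re-run alone
# reproduces its part of a full run
stage_seed <- function(cfg, stage) {
  order <- c("schedule", "trajectory", "density", "klm", "phantom",
             "acquire", "recon", "quantify")
  as.integer(cfg$global$seed) + 101L * match(stage, order)
}

#' Run the simulation/analysis pipeline
#'
#' Executes the requested stages in dependency order (`schedule`,
#' `trajectory`, `density`, `klm`, `phantom`, `acquire`, `recon`,
#' `quantify`), writes artifacts and a resolved copy of the configuration to
#' `out_dir`, and returns a manifest. Deterministic for a fixed
#' `config$global$seed`.
#'
#' @param config A `run_config`.
#' @param stages Character subset of stages; the default runs everything.
#' @param out_dir Output directory; created if needed. `NULL` (with no
#'   `config$global$out_dir`) keeps all artifacts in memory only.
#' @return A list with `manifest` (tibble: stage, artifact, path, detail)
#'   and `results` (named list of in-memory stage outputs).
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("schedule", "trajectory", "density",
                                    "klm", "phantom", "acquire", "recon",
                                    "quantify"),
                         out_dir = config$global$out_dir) {
  all_stages <- c("schedule", "trajectory", "density", "klm", "phantom",
                  "acquire", "recon", "quantify")
  stages <- intersect(all_stages, stages)
  res <- list()
  manifest <- list()
  emit <- function(stage, artifact, path = NA_character_,
                   detail = NA_character_) {
    manifest[[length(manifest) + 1]] <<-
      tibble::tibble(stage = stage, artifact = artifact, path = path,
                     detail = detail)
  }
  need <- function(stage, dep) {
    if (is.null(res[[dep]])) {
      abort(sprintf("Stage '%s' needs upstream stage '%s'.", stage, dep),
            class = "spiralpam_dependency_error")
    }
  }
  save_dir <- NULL
  if (length(stages) && !is.null(out_dir)) {
    save_dir <- out_dir
    dir.create(save_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_path <- file.path(save_dir, "resolved_config.yaml")
    yaml::write_yaml(unclass(config), cfg_path)
    emit("config", "resolved_config", cfg_path)
  }
  out_path <- function(name) {
    if (is.null(save_dir)) NULL else file.path(save_dir, name)
  }

  sc <- config$scanner
  protocol <- scan_protocol(sc$scan_frequency, sc$imaging_duration,
                            sc$braking_duration, sc$decay_duration,
                            sc$max_radius, sc$ramp_shape,
                            sc$decay_time_constant)
  if ("schedule" %in% stages) {
    res$schedule <- prf_schedule(config$schedule$t_start,
                                 config$schedule$t_end, config$schedule$prf)
    emit("schedule", "prf_schedule",
         detail = sprintf("%d steps, %d triggers", nrow(res$schedule),
                          length(fire_times(res$schedule))))
  }
  if ("trajectory" %in% stages) {
    spec <- do.call(cantilever_spec, sc$cantilever)
    res$trajectory <- simulate_trajectory(protocol, spec, sc$sample_rate,
                                          sc$model)
    p <- out_path("trajectory.csv")
    if (!is.null(p)) write_trajectory_csv(res$trajectory, p)
    emit("trajectory", "tip_path", p %||% NA_character_,
         sprintf("%d samples, model %s", nrow(res$trajectory), sc$model))
  }
  if ("density" %in% stages) {
    need("density", "trajectory"); need("density", "schedule")
    res$density <- density_map(res$trajectory, res$schedule,
                               grid_size = 512)
    g <- glance(res$density)
    p <- out_path("density_map.tif")
    if (!is.null(p)) write_density_map(res$density, p,
                                       out_path("density_summary.csv"))
    emit("density", "density_map", p %||% NA_character_,
         sprintf("min %d max %d fill %.3f", g$min_visited, g$max_visited,
                 g$fill_factor))
  }
  if ("klm" %in% stages) {
    mats <- config$transducer$materials %||% pam_materials()
    stack <- tut_layer_stack(mats)
    grid <- seq(config$transducer$f_max / config$transducer$n_freq,
                config$transducer$f_max,
                length.out = config$transducer$n_freq)
    res$klm <- klm_two_way_response(stack, grid,
                                    config$transducer$source_impedance)
    bm <- extract_band_metrics(res$klm)
    p <- out_path("band_metrics.json")
    if (!is.null(p)) {
      write_klm_outputs(res$klm, out_path("klm_spectrum.csv"),
                        out_path("klm_waveform.csv"), p)
    }
    emit("klm", "band_metrics", p %||% NA_character_,
         sprintf("Fc %.1f MHz, FBW %.1f%%", bm$center_frequency / 1e6,
                 100 * bm$fractional_bandwidth))
  }
  if ("phantom" %in% stages) {
    ph <- config$phantom
    res$phantom <- make_vessel_phantom(
      vessel_tree_params(n_roots = ph$n_roots,
                         diameter_range = ph$diameter_range,
                         tortuosity = ph$tortuosity,
                         branching_prob = ph$branching_prob,
                         seed = stage_seed(config, "phantom")),
      shape = ph$shape, voxel_size = ph$voxel_size)
    p <- out_path("phantom.tif")
    if (!is.null(p)) write_phantom(res$phantom, p)
    emit("phantom", "vessel_phantom", p %||% NA_character_,
         sprintf("%.1f%% filled", 100 * mean(res$phantom > 0)))
  }
  if ("acquire" %in% stages) {
    need("acquire", "trajectory"); need("acquire", "schedule")
    need("acquire", "phantom")
    aq <- config$acquisition
    sched <- res$schedule
    sched$prf <- sched$prf / aq$prf_divisor
    impulse <- NULL
    if (isTRUE(aq$use_transducer_impulse)) {
      need("acquire", "klm")
      impulse <- resample_impulse(res$klm, aq$sampling_rate)
    }
    settings <- acquisition_settings(aq$sampling_rate, aq$speed_of_sound,
                                     aq$record_length, aq$focal_spot_sigma,
                                     aq$noise_sigma,
                                     stage_seed(config, "acquire"))
    res$acquire <- acquire(res$trajectory, sched, res$phantom, impulse,
                           settings)
    p <- out_path("samples")
    if (!is.null(p)) write_sample_set(res$acquire, p)
    emit("acquire", "sample_set", p %||% NA_character_,
         sprintf("%d A-scans", nrow(res$acquire$ascans)))
  }
  if ("recon" %in% stages) {
    need("recon", "acquire")
    rc <- config$reconstruction
    res$recon <- grid_assign(res$acquire, rc$grid_size,
                             2 * protocol$max_radius, rc$k_neighbors,
                             rc$idw_power)
    res$map <- map_projection(res$recon)
    p <- out_path("map.tif")
    if (!is.null(p)) {
      write_volume(res$recon, out_path("volume.tif"))
      write_map_image(res$map, p)
      write_map_image(depth_encode(res$recon), out_path("depth.tif"))
    }
    emit("recon", "map_image", p %||% NA_character_,
         sprintf("%d px grid, %.0f%% hit", rc$grid_size,
                 100 * mean(res$recon$fill_mask)))
  }
  if ("quantify" %in% stages) {
    need("quantify", "recon")
    qc <- config$quantification
    mask <- vessel_mask(res$map, method = qc$mask_method)
    res$quantify <- vessel_metrics(mask, res$recon$pixel_size)
    p <- out_path("vessel_metrics.json")
    if (!is.null(p)) write_metrics(res$quantify, out_path("vessel_metrics.csv"), p)
    emit("quantify", "vessel_metrics", p %||% NA_character_,
         sprintf("VAD %.3f", res$quantify$vad))
  }
  manifest <- if (length(manifest)) dplyr::bind_rows(manifest) else
    tibble::tibble(stage = character(), artifact = character(),
                   path = character(), detail = character())
  list(manifest = manifest, results = res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# resample the KLM pulse-echo waveform onto the digitizer clock
resample_impulse <- function(klm, sampling_rate) {
  wf <- klm$waveform
  n <- floor(max(wf$time) * sampling_rate)
  tt <- (0:n) / sampling_rate
  approx(wf$time, wf$amplitude, tt, rule = 2)$y
}
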