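config_schema <- list(
  geometry = c("n_segments", "length_um", "thickness_um_distal",
               "thickness_um_proximal", "width_um_distal",
               "width_um_proximal", "duct_height_um", "taper"),
  materials = c("E_dw", "E_av_wall", "E_capcell", "E_dendrite", "E_tm",
                "E_tp", "E_prf", "rho_cuticle", "rho_fluid", "mu_fluid",
                "nu"),
  network = c("stiffness_scale", "kca_scale"),
  drive = c("d0_um", "frequencies_hz", "drive_end"),
  ablation = c("mode", "E_dw_override_Pa", "uniform_thickness_um"),
  analysis = c("window_db", "P1_um", "P2_um"),
  calibration = c("anchor_frequencies_hz", "anchor_peaks_um",
                  "tolerance_um", "variant", "free_parameters"),
  rheology = c("n_particles", "n_frames", "viscosity_Pa_s",
               "localization_noise_sd_m", "max_lag_frames"),
  time_domain = c("n_cycles", "ramp_cycles", "frequencies_hz"),
  seed = NULL
)

#' Default run configuration
#'
#' Every tunable of the pipeline with its default value, as a nested list.
#' The schema is closed: [validate_run_config()] rejects unknown keys.
#'
#' @return nested configuration list
#' @export
default_run_config <- function() {
  list(
    geometry = list(n_segments = 201L, length_um = 600,
                    thickness_um_distal = 4.84, thickness_um_proximal = 4.10,
                    width_um_distal = 40, width_um_proximal = 120,
                    duct_height_um = 100, taper = "linear"),
    materials = list(E_dw = 3e6, E_av_wall = 15e9, E_capcell = 1e7,
                     E_dendrite = 2e7, E_tm = 5e7, E_tp = 1e9, E_prf = 2.5e7,
                     rho_cuticle = 1200, rho_fluid = 1000,
                     mu_fluid = 1.002e-3, nu = 0.3),
    network = list(stiffness_scale = 1, kca_scale = 1),
    drive = list(d0_um = 10, frequencies_hz = seq(10e3, 80e3, by = 10e3),
                 drive_end = "distal"),
    ablation = list(mode = "intact", E_dw_override_Pa = 13e6,
                    uniform_thickness_um = 15),
    analysis = list(window_db = 10, P1_um = 0, P2_um = 600),
    calibration = list(anchor_frequencies_hz = c(20e3, 80e3),
                       anchor_peaks_um = c(470, 130), tolerance_um = 6,
                       variant = "no_ca",
                       free_parameters = c("stiffness_scale", "width_ratio",
                                           "duct_height_um")),
    rheology = list(n_particles = 100L, n_frames = 2000L,
                    viscosity_Pa_s = 1.002e-3,
                    localization_noise_sd_m = 20e-9, max_lag_frames = 25L),
    time_domain = list(n_cycles = 30L, ramp_cycles = 10L,
                       frequencies_hz = c(20e3, 40e3, 80e3)),
    seed = 1L
  )
}

#' Validate a run configuration against the schema
#'
#' Unknown sections or keys are rejected before any computation; known keys
#' missing from the input are filled with defaults. Returns the resolved
#' configuration.
#'
#' @param config nested list (possibly partial)
#' @return resolved configuration list
#' @export
validate_run_config <- function(config) {
  defaults <- default_run_config()
  bad <- setdiff(names(config), names(config_schema))
  if (length(bad) > 0)
    stop("config error: unknown section(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(config)) {
    if (sec == "seed") next
    badk <- setdiff(names(config[[sec]]), config_schema[[sec]])
    if (length(badk) > 0)
      stop("config error: unknown key(s) in '", sec, "': ",
           paste(badk, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$drive$drive_end %in% c("distal", "proximal"))
    stop("config error: drive.drive_end must be distal or proximal",
         call. = FALSE)
  if (!cfg$ablation$mode %in% c("intact", "no_ca", "uniform_dw"))
    stop("config error: unknown ablation.mode", call. = FALSE)
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path file ending in `.yaml`/`.yml` or `.json`
#' @return resolved configuration (see [validate_run_config()])
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_run_config(cfg)
}

# assemble model pieces from a resolved config
model_from_config <- function(cfg, mode = NULL) {
  g <- cfg$geometry
  materials <- do.call(material_set, cfg$materials)
  drive <- drive_spec(cfg$drive$d0_um, sort(cfg$drive$frequencies_hz),
                      cfg$drive$drive_end)
  mode <- mode %||% cfg$ablation$mode
  build_ear_model(
    stiffness_scale = cfg$network$stiffness_scale,
    width_ratio = g$width_um_proximal / g$width_um_distal,
    kca_scale = cfg$network$kca_scale,
    ablation = ablation_spec(mode,
                             E_dw_override = cfg$ablation$E_dw_override_Pa,
                             uniform_thickness = cfg$ablation$uniform_thickness_um),
    n_segments = g$n_segments, length = g$length_um,
    thickness_endpoints = c(g$thickness_um_distal, g$thickness_um_proximal),
    width_distal = g$width_um_distal, duct_height = g$duct_height_um,
    taper = g$taper, materials = materials, drive = drive)
}

write_json_report <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}

#' Run a named analysis scenario end to end
#'
#' Scenarios mirror the structure of the original study:
#' \describe{
#'   \item{tonotopy}{frequency sweep of the intact model; tonotopic map.}
#'   \item{ablation_no_ca}{sweep with the crista removed.}
#'   \item{ablation_uniform_dw}{sweep with the thickness taper removed.}
#'   \item{travelling_wave}{time-domain runs (20/40/80 kHz by default) on
#'     the crista-removed model: envelopes, peak positions, asymmetry
#'     ratios; frequency-domain phase lags.}
#'   \item{calibrate}{anchor fit plus held-out 40 kHz prediction.}
#'   \item{rheology}{synthetic Brownian data, MSD, viscosity recovery.}
#' }
#' Every run writes the resolved configuration (with its MD5 hash embedded
#' in the report) next to the outputs; identical configurations reproduce
#' identical files.
#'
#' @param config nested list (see [default_run_config()]); validated first
#' @param scenario one of the names above
#' @param out_dir output directory (created if missing); `NULL` for no file
#'   output
#' @param quiet suppress progress messages
#' @return the report, invisibly (a list; also serialized as JSON)
#' @export
run_experiment <- function(config = list(),
                           scenario = c("tonotopy", "ablation_no_ca",
                                        "ablation_uniform_dw",
                                        "travelling_wave", "calibrate",
                                        "rheology"),
                           out_dir = NULL, quiet = FALSE) {
  scenario <- match.arg(scenario)
  cfg <- validate_run_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- Sys.time()

  cfg_json <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    cfg_json <- file.path(out_dir, "resolved_config.json")
    write_json_report(cfg, cfg_json)
  } else {
    cfg_json <- tempfile(fileext = ".json")
    write_json_report(cfg, cfg_json)
    on.exit(unlink(cfg_json), add = TRUE)
  }
  cfg_hash <- unname(tools::md5sum(cfg_json))

  sweep_map <- function(mode) {
    model <- model_from_config(cfg, mode)
    sols <- lapply(cfg$drive$frequencies_hz, function(f)
      solve_frequency(model$profile, model$network, model$drive, f))
    # the uniform-DW experiment reads the maximum off the crista surface
    tonotopic_map(sols, source = mode,
                  field = if (mode == "uniform_dw") "tm" else "dw")
  }

  report <- switch(scenario,
    tonotopy = ,
    ablation_no_ca = ,
    ablation_uniform_dw = {
      mode <- switch(scenario, tonotopy = "intact",
                     ablation_no_ca = "no_ca",
                     ablation_uniform_dw = "uniform_dw")
      say("scenario %s: sweeping %d frequencies (%s model)", scenario,
          length(cfg$drive$frequencies_hz), mode)
      tmap <- sweep_map(mode)
      r2 <- if (sum(!is.na(tmap$map$peak_um)) >= 4 &&
                diff(range(tmap$map$peak_um, na.rm = TRUE)) > 0)
        map_linearity(tmap) else NA_real_
      if (!is.null(out_dir))
        utils::write.csv(tmap$map,
                         file.path(out_dir, paste0(scenario, "_map.csv")),
                         row.names = FALSE)
      list(scenario = scenario, source = tmap$source, map = tmap$map,
           monotone = tmap$monotone, r_squared = r2)
    },
    travelling_wave = {
      model <- model_from_config(cfg, "no_ca")
      freqs <- cfg$time_domain$frequencies_hz
      say("scenario travelling_wave: %d time-domain runs", length(freqs))
      per_f <- lapply(freqs, function(f) {
        ts <- solve_time(model$profile, model$network, model$drive, f,
                         n_cycles = cfg$time_domain$n_cycles,
                         ramp_cycles = cfg$time_domain$ramp_cycles)
        env <- envelope(ts)
        peak <- peak_distance_from_distal(env, ts$x)
        fs <- solve_frequency(model$profile, model$network, model$drive, f)
        pp <- phase_profile(fs, cfg$analysis$P1_um, cfg$analysis$P2_um)
        list(frequency_hz = f, env = env, x = ts$x,
             peak_um = as.numeric(peak),
             asym_ratio = as.numeric(asymmetry_ratio(
               env, ts$x, as.numeric(peak), cfg$analysis$window_db,
               model$drive$drive_end)),
             phase_lag_deg = phase_accumulation(pp))
      })
      if (!is.null(out_dir)) {
        env_df <- data.frame(
          x_um = per_f[[1]]$x,
          do.call(cbind, lapply(per_f, function(p) p$env)))
        names(env_df)[-1] <- paste0("env_m_", sapply(per_f, `[[`,
                                                     "frequency_hz"), "hz")
        utils::write.csv(env_df, file.path(out_dir, "envelopes.csv"),
                         row.names = FALSE)
      }
      list(scenario = scenario,
           results = lapply(per_f, function(p)
             p[c("frequency_hz", "peak_um", "asym_ratio",
                 "phase_lag_deg")]))
    },
    calibrate = {
      say("scenario calibrate: fitting %d anchors (%s variant)",
          length(cfg$calibration$anchor_frequencies_hz),
          cfg$calibration$variant)
      problem <- calibration_problem(
        anchors = data.frame(
          frequency_hz = cfg$calibration$anchor_frequencies_hz,
          peak_um = cfg$calibration$anchor_peaks_um),
        free_parameters = cfg$calibration$free_parameters,
        tolerance_um = cfg$calibration$tolerance_um,
        variant = cfg$calibration$variant,
        n_segments = cfg$geometry$n_segments)
      materials <- do.call(material_set, cfg$materials)
      drive <- drive_spec(cfg$drive$d0_um, sort(cfg$drive$frequencies_hz),
                          cfg$drive$drive_end)
      res <- calibrate(problem, materials, drive)
      heldout <- predict_heldout(res, 40e3)
      list(scenario = scenario,
           parameters = as.list(res$parameters),
           residuals_um = as.list(res$residuals_um),
           converged = res$converged,
           heldout_40khz_um = heldout,
           phase_lag_deg = as.list(res$phase_lag_deg),
           phase_lag_deg_intact = as.list(res$phase_lag_deg_intact))
    },
    rheology = {
      rc <- cfg$rheology
      say("scenario rheology: %d particles x %d frames", rc$n_particles,
          rc$n_frames)
      bead <- bead_spec(localization_noise_sd = rc$localization_noise_sd_m)
      ts <- simulate_trajectories(rc$n_particles, rc$n_frames, bead,
                                  rc$viscosity_Pa_s, seed = cfg$seed)
      fit <- fit_viscosity(msd(ts, rc$max_lag_frames), bead)
      list(scenario = scenario, seed = cfg$seed,
           true_viscosity_Pa_s = rc$viscosity_Pa_s,
           viscosity_Pa_s = fit$viscosity,
           viscosity_ci = fit$viscosity_ci,
           powerlaw_exponent = fit$powerlaw_exponent,
           newtonian = fit$newtonian)
    })

  report$config_md5 <- cfg_hash
  report$package_version <- as.character(utils::packageVersion("katytw"))
  report$seed <- cfg$seed
  report$elapsed_s <- round(as.numeric(difftime(Sys.time(), t0,
                                                units = "secs")), 3)
  if (!is.null(out_dir)) {
    # elapsed time varies run to run; keep it out of the serialized report
    # so identical configs give byte-identical files
    ser <- report[setdiff(names(report), "elapsed_s")]
    write_json_report(ser, file.path(out_dir,
                                     paste0(scenario, "_report.json")))
  }
  say("scenario %s done in %.2f s", scenario, report$elapsed_s)
  invisible(report)
}
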