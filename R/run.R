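# Configuration and run commands binding the modules together. Each command
# is reproducible from its (echoed) config plus seed; a thin command-line
# wrapper over these functions ships in inst/cli/lungtrack.

#' Default run configuration
#'
#' A single nested list, serializable to YAML, holding every tunable of the
#' pipeline: lung/tree parameters, chain settings, PDFE grid and binning,
#' patient demographics and spirometry, forecast parameters, and the
#' synthetic-patient generator. [load_config()] reads a YAML file and fills
#' unset fields from these defaults.
#'
#' @return A nested list of class `lungtrack_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1L,
    lung = list(n_voxels = 64L, voxel_levels = 11L,
                trachea_diameter_cm = 1.8, trachea_length_cm = 12,
                scale_factor = 2^(-1 / 3), viscosity = 1.81e-5),
    chain = list(n_steps = 20000L, burn_in = NULL, thin = 10L,
                 temperature = 0.01, w1 = 1, w2 = 1),
    pdfe = list(fraction_step = 0.2, n_ratio = 100L, n_aa = 100L,
                log_ratio_max = 6),
    patient = list(age = 22, height = 170, sex = "male",
                   fev1 = NULL, fvc = NULL),
    forecast = list(rate_mm3_yr = NULL, horizon_yr = 1, n_draws = 1000L),
    synthetic = list(n_pockets = 3L, pocket_radius = 1.5,
                     fraction_min = 0.3, fraction_max = 0.8)
  ), class = "lungtrack_config")
}

#' @rdname default_config
#' @param path YAML file; missing fields fall back to [default_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(paste0("config file not found: ", path),
                 class = "lungtrack_input_error")
  }
  user <- yaml::read_yaml(path)
  cfg <- default_config()
  for (section in names(user)) {
    if (is.list(cfg[[section]]) && is.list(user[[section]])) {
      for (field in names(user[[section]])) {
        cfg[[section]][[field]] <- user[[section]][[field]]
      }
    } else {
      cfg[[section]] <- user[[section]]
    }
  }
  cfg
}

#' @rdname default_config
#' @param config A `lungtrack_config`.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

.config_lung <- function(config) {
  l <- config$lung
  lung_model(n_voxels = l$n_voxels, voxel_levels = l$voxel_levels,
             trachea_diameter_cm = l$trachea_diameter_cm,
             trachea_length_cm = l$trachea_length_cm,
             scale_factor = l$scale_factor, viscosity = l$viscosity)
}

.config_settings <- function(config, seed_offset = 0L) {
  ch <- config$chain
  chain_settings(n_steps = ch$n_steps, burn_in = ch$burn_in, thin = ch$thin,
                 temperature = ch$temperature, w1 = ch$w1, w2 = ch$w2,
                 seed = if (is.null(config$seed)) NULL else
                   as.integer(config$seed) + seed_offset)
}

.config_patient <- function(config) {
  p <- config$patient
  patient_spirometry(p$age, p$height, p$sex,
                     fev1 = p$fev1 %||% NA_real_, fvc = p$fvc %||% NA_real_)
}

.echo_config <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_config(config, file.path(out_dir, "config_echo.yaml"))
}

#' Run commands: the five pipeline entry points
#'
#' Thin, file-oriented wrappers over the package functions, used by the
#' `inst/cli/lungtrack` command-line script. Every command echoes its
#' configuration into the output location so a run is reproducible from its
#' outputs alone.
#'
#' @param config A `lungtrack_config` (see [default_config()]).
#' @param out_file,out_dir Output locations.
#' @name run_commands
NULL

#' @rdname run_commands
#' @export
run_build_pdfe <- function(config, out_file) {
  lung <- .config_lung(config)
  fractions <- seq(0, 1, by = config$pdfe$fraction_step)
  bins <- pdfe_bins(config$pdfe$n_ratio, config$pdfe$n_aa,
                    config$pdfe$log_ratio_max)
  table <- build_pdfe_table(lung$voxel_tree, fractions,
                            .config_settings(config), bins)
  write_pdfe(table, out_file)
  invisible(out_file)
}

#' @rdname run_commands
#' @param voxel_file Voxel table path ([read_voxel_table()] format).
#' @param pdfe_file Persisted PDFE table ([write_pdfe()]).
#' @export
run_fit <- function(config, voxel_file, pdfe_file, out_dir) {
  lung <- .config_lung(config)
  pdfe <- read_pdfe(pdfe_file)
  voxels <- read_voxel_table(voxel_file)
  targets <- .config_patient(config)
  fit <- fit_lung(voxels, targets, pdfe, lung, .config_settings(config))
  .echo_config(config, out_dir)
  utils::write.csv(as.data.frame(tidy(fit)),
                   file.path(out_dir, "fit_samples.csv"), row.names = FALSE)
  b <- fit$best_index
  best <- dplyr::mutate(fit$voxels,
                        resistance_ratio = fit$ratio_samples[b, ],
                        aa_percent = fit$aa_samples[b, ])
  utils::write.csv(as.data.frame(best),
                   file.path(out_dir, "fit_best_state.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(glance(fit)),
                   file.path(out_dir, "fit_summary.csv"), row.names = FALSE)
  if (!fit$feasible) {
    rlang::warn("fit flagged infeasible (minimum energy above threshold)",
                class = "lungtrack_infeasible")
  }
  invisible(fit)
}

#' @rdname run_commands
#' @param state_file `fit_best_state.csv` written by [run_fit()].
#' @param voxel Voxel row index to drill into.
#' @export
run_drilldown <- function(config, state_file, voxel, out_dir) {
  lung <- .config_lung(config)
  state <- tibble::as_tibble(utils::read.csv(state_file))
  if (voxel < 1 || voxel > nrow(state)) {
    rlang::abort("voxel index out of range", class = "lungtrack_input_error")
  }
  profile <- drilldown_voxel(
    lung$voxel_tree,
    mucus_mm3 = state$mucus_mm3[voxel],
    ratio_target = state$resistance_ratio[voxel],
    aa_target = state$aa_percent[voxel],
    settings = .config_settings(config)
  )
  .echo_config(config, out_dir)
  out <- dplyr::mutate(tibble::as_tibble(profile),
                       voxel = voxel, feasible = attr(profile, "feasible"),
                       residual_energy = attr(profile, "residual_energy"))
  utils::write.csv(as.data.frame(out),
                   file.path(out_dir, "generation_profile.csv"),
                   row.names = FALSE)
  invisible(profile)
}

#' @rdname run_commands
#' @export
run_predict <- function(config, voxel_file, pdfe_file, out_dir) {
  lung <- .config_lung(config)
  pdfe <- read_pdfe(pdfe_file)
  voxels <- read_voxel_table(voxel_file)
  patient <- .config_patient(config)
  grown <- grow_mucus(voxels, lung,
                      rate_mm3_yr = config$forecast$rate_mm3_yr,
                      horizon_yr = config$forecast$horizon_yr)
  fc <- predict_spirometry(grown, pdfe, lung, patient,
                           n_draws = config$forecast$n_draws,
                           seed = config$seed)
  .echo_config(config, out_dir)
  utils::write.csv(as.data.frame(tidy(fc)),
                   file.path(out_dir, "forecast_draws.csv"), row.names = FALSE)
  utils::write.csv(as.data.frame(glance(fc)),
                   file.path(out_dir, "forecast_summary.csv"), row.names = FALSE)
  invisible(fc)
}

#' @rdname run_commands
#' @export
run_simulate_patient <- function(config, out_dir) {
  lung <- .config_lung(config)
  sp <- generate_patient(
    lung,
    n_pockets = config$synthetic$n_pockets,
    pocket_radius = config$synthetic$pocket_radius,
    fraction_range = c(config$synthetic$fraction_min,
                       config$synthetic$fraction_max),
    age = config$patient$age, height = config$patient$height,
    sex = config$patient$sex,
    seed = config$seed
  )
  .echo_config(config, out_dir)
  write_patient(sp, file.path(out_dir, "patient"))
  invisible(sp)
}
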