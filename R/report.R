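# Report bundle: wire config + data through geometry and budgeting, write
# the per-compartment and per-ice-type tables, the volume-fraction table,
# and a machine-readable JSON summary.

#' Run the full standing-stock budget and write the report bundle
#'
#' Reads (or takes) a run configuration, derives unit volumes from the
#' morphology and drafts, loads the per-compartment concentration table,
#' builds the budget, and writes four files to `out_dir`:
#' `compartment_stocks.csv` (per-compartment table),
#' `ice_type_stocks.csv` (per-volume/area/coverage/relative table),
#' `volume_fractions.csv`, and `summary.json`. A config echo and the
#' versioned constants are logged via `message()`.
#'
#' @param config A [read_run_config()] result, a path to a YAML config, or
#'   `NULL` for the packaged study configuration.
#' @param out_dir Output directory (created if absent), or `NULL` to skip
#'   writing files.
#' @param concentrations Optional concentration table overriding the
#'   config's `concentrations` path.
#' @return The [build_budget()] object, invisibly when writing files.
#' @export
#' @examples
#' b <- run_budget(out_dir = NULL)
#' format_budget(b)
run_budget <- function(config = NULL, out_dir = NULL,
                       concentrations = NULL) {
  config <- as_run_config(config)
  log_config(config)
  volumes <- config_volumes(config)
  if (is.null(concentrations)) {
    concentrations <- if (is.null(config$concentrations_path)) {
      mosaic_concentrations()
    } else {
      read_concentrations(config$concentrations_path)
    }
  }
  budget <- build_budget(concentrations, volumes, config$cover)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    vf <- volume_fractions(volumes, config$cover)
    hv <- habitable_ice_volume(volumes, config$cover)
    write_csv_plain(budget$compartments,
                    file.path(out_dir, "compartment_stocks.csv"))
    write_csv_plain(format_budget(budget, config$precision),
                    file.path(out_dir, "ice_type_stocks.csv"))
    write_csv_plain(vf, file.path(out_dir, "volume_fractions.csv"))
    summary <- list(
      config = utils::modifyList(unclass(config$morphology),
                                 list(source = config$source)),
      habitable_volume = stats::setNames(as.list(hv$habitable_volume),
                                         hv$ice_type),
      ice_types = budget$ice_types,
      constants = list(
        phase_relations = brine_phase_coefficients()$citation,
        chla_dried_factor = 1.8,
        leucine_kg_c_per_mol = 1.5
      )
    )
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    message("report bundle written to ", out_dir)
    return(invisible(budget))
  }
  budget
}

#' Run the geometry-only report
#'
#' Computes unit volumes for every ice type, the volume-fraction and
#' habitable-volume tables, the rubble surface-area ratio, and the
#' ridge-to-level brine volume ratio under the packaged winter brine
#' scenario.
#'
#' @inheritParams run_budget
#' @param vb_rubble,vb_level Brine volume fractions for the brine-volume
#'   ratio; default to the [winter_brine_scenario()] values derived from
#'   the configured morphology.
#' @return A list: `volumes`, `volume_fractions`, `habitable_volume`,
#'   `surface_area_ratio`, `brine_volume_ratio`, `scenario`.
#' @export
#' @examples
#' g <- run_geometry()
#' g$surface_area_ratio
run_geometry <- function(config = NULL, out_dir = NULL,
                         vb_rubble = NULL, vb_level = NULL) {
  config <- as_run_config(config)
  log_config(config)
  volumes <- config_volumes(config)
  scen <- winter_brine_scenario()
  vb_rubble <- vb_rubble %||%
    scen$brine_volume_fraction[scen$ice_class == "rubble"]
  vb_level <- vb_level %||%
    scen$brine_volume_fraction[scen$ice_class == "level"]
  out <- list(
    volumes = volumes,
    volume_fractions = volume_fractions(volumes, config$cover),
    habitable_volume = habitable_ice_volume(volumes, config$cover),
    surface_area_ratio = surface_area_ratio(config$morphology),
    brine_volume_ratio = brine_volume_ratio(
      consolidated_thickness = config$morphology$consolidated_thickness,
      rubble_thickness = rubble_thickness(config$morphology),
      level_thickness = config$level$fyi$draft,
      macroporosity = config$morphology$macroporosity,
      vb_rubble = vb_rubble,
      vb_level = vb_level
    ),
    scenario = scen
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_csv_plain(out$volume_fractions,
                    file.path(out_dir, "volume_fractions.csv"))
    write_csv_plain(out$habitable_volume,
                    file.path(out_dir, "habitable_volume.csv"))
    jsonlite::write_json(
      list(surface_area_ratio = out$surface_area_ratio,
           brine_volume_ratio = out$brine_volume_ratio),
      file.path(out_dir, "geometry.json"), auto_unbox = TRUE, digits = NA
    )
  }
  out
}

as_run_config <- function(config) {
  if (is.null(config) || is.character(config)) {
    return(read_run_config(config))
  }
  stopifnot(inherits(config, "run_config"))
  config
}

config_volumes <- function(config) {
  dplyr::bind_rows(
    ridge_unit_volumes(config$morphology),
    level_unit_volumes(config$level$fyi, "fyi"),
    level_unit_volumes(config$level$syi, "syi")
  )
}

log_config <- function(config) {
  m <- config$morphology
  message(sprintf(
    "config %s: keel %.2f m, consolidated %.2f m, porosity %.2f, block %.2f x %.2f m",
    config$source %||% "<in-memory>", m$keel_depth, m$consolidated_thickness,
    m$macroporosity, m$block_thickness, m$block_length
  ))
  if (isTRUE(config$defaulted_block_length)) {
    message("block_length not set; defaulted to 3.5 x block_thickness = ",
            format(m$block_length), " m")
  }
  invisible(config)
}

write_csv_plain <- function(df, path) {
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
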