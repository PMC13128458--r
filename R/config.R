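# Packaged study configuration and YAML config reading.
#
# The packaged defaults describe the drifting-station study floe in July:
# one representative ridge keel, first- and second-year level ice, their
# areal coverages from airborne laser scanning, and the per-compartment
# chlorophyll-a / POC concentration summary.

#' Packaged ridge morphology (study defaults)
#'
#' Keel depth 3.9 m (sonar), consolidated layer 2.2 m and rubble
#' macroporosity 17% (drilling, n = 8), block thickness 0.3 m (tape),
#' block length 3.5 x thickness, 0.1 m exterior skin and bottom layer.
#'
#' @return A [ridge_morphology()].
#' @export
mosaic_morphology <- function() {
  ridge_morphology(
    keel_depth = 3.9,
    consolidated_thickness = 2.2,
    macroporosity = 0.17,
    block_thickness = 0.3
  )
}

#' Packaged level-ice drafts (study defaults)
#'
#' First-year ice draft 1.3 m and second-year ice draft 1.4 m (the
#' submerged part of 1.4/1.5 m thick ice; freeboard hosts no under-ice
#' habitat).
#'
#' @return A named list of [level_ice()] objects (`fyi`, `syi`).
#' @export
mosaic_level_ice <- function() {
  list(fyi = level_ice(1.3), syi = level_ice(1.4))
}

#' Packaged areal coverage (study defaults)
#'
#' Ridges 22%, first-year ice 50%, second-year ice 28%, from airborne
#' laser scanning of about 40 km^2 around the floe.
#'
#' @return An [ice_cover()] tibble.
#' @export
mosaic_cover <- function() {
  ice_cover(ridge = 0.22, fyi = 0.50, syi = 0.28)
}

#' Packaged unit volumes for all ice types (study defaults)
#'
#' @return Row-bound [ridge_unit_volumes()] and [level_unit_volumes()] for
#'   the packaged morphology and drafts.
#' @export
mosaic_volumes <- function() {
  lvl <- mosaic_level_ice()
  dplyr::bind_rows(
    ridge_unit_volumes(mosaic_morphology()),
    level_unit_volumes(lvl$fyi, "fyi"),
    level_unit_volumes(lvl$syi, "syi")
  )
}

#' Packaged per-compartment concentration summary (study defaults)
#'
#' July chlorophyll-a and POC means, standard errors and sample counts for
#' every (ice type, compartment) cell, shipped as plain text in
#' `inst/extdata/mosaic_concentrations.csv`.
#'
#' @return A [concentration_table()].
#' @export
mosaic_concentrations <- function() {
  read_concentrations(
    system.file("extdata", "mosaic_concentrations.csv",
                package = "ridgebudget", mustWork = TRUE)
  )
}

#' Read a run configuration from a YAML file
#'
#' The config is flat key-value YAML; see
#' `system.file("extdata", "mosaic_config.yaml", package = "ridgebudget")`
#' for the packaged example. Lengths are meters, fractions in \[0, 1\].
#' `block_length` defaults to 3.5 x `block_thickness` when omitted.
#'
#' @param path Path to the YAML file, or `NULL` for the packaged study
#'   config.
#' @return A list of class `run_config`: `morphology`
#'   ([ridge_morphology()]), `level` (named list of [level_ice()]),
#'   `cover` ([ice_cover()]), `concentrations_path`, `seed`, `precision`.
#' @export
read_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "mosaic_config.yaml",
                        package = "ridgebudget", mustWork = TRUE)
  }
  raw <- yaml::yaml.load_file(path)
  problems <- character(0)
  need <- c("keel_depth", "consolidated_thickness", "macroporosity",
            "block_thickness", "fyi_draft", "syi_draft",
            "cover_ridge", "cover_fyi", "cover_syi")
  missing_keys <- setdiff(need, names(raw))
  if (length(missing_keys) > 0) {
    problems <- c(problems, paste("missing config keys:",
                                  paste(missing_keys, collapse = ", ")))
  }
  if (length(problems) > 0) {
    stop("invalid run config (", path, "): ",
         paste(problems, collapse = "; "), call. = FALSE)
  }
  defaulted_block_length <- is.null(raw$block_length)
  morph <- ridge_morphology(
    keel_depth = raw$keel_depth,
    consolidated_thickness = raw$consolidated_thickness,
    macroporosity = raw$macroporosity,
    block_thickness = raw$block_thickness,
    block_length = raw$block_length %||% 3.5 * raw$block_thickness,
    skin_thickness = raw$skin_thickness %||% 0.1,
    bottom_thickness = raw$bottom_thickness %||% 0.1
  )
  concs_path <- raw$concentrations
  if (!is.null(concs_path) && !file.exists(concs_path)) {
    # allow package-relative fixture paths
    candidate <- system.file("extdata", concs_path, package = "ridgebudget")
    if (nzchar(candidate)) {
      concs_path <- candidate
    } else {
      stop("invalid run config: concentrations file not found: ",
           raw$concentrations, call. = FALSE)
    }
  }
  structure(
    list(
      morphology = morph,
      level = list(
        fyi = level_ice(raw$fyi_draft,
                        bottom_thickness = raw$bottom_thickness %||% 0.1),
        syi = level_ice(raw$syi_draft,
                        bottom_thickness = raw$bottom_thickness %||% 0.1)
      ),
      cover = ice_cover(ridge = raw$cover_ridge, fyi = raw$cover_fyi,
                        syi = raw$cover_syi),
      concentrations_path = concs_path,
      seed = raw$seed %||% 1L,
      precision = raw$precision %||% 2L,
      defaulted_block_length = defaulted_block_length,
      source = path
    ),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config> from", x$source, "\n")
  print(x$morphology)
  cat(sprintf("  drafts: fyi %.2f m, syi %.2f m\n",
              x$level$fyi$draft, x$level$syi$draft))
  cat(sprintf("  cover: ridge %.2f, fyi %.2f, syi %.2f\n",
              x$cover$areal_fraction[1], x$cover$areal_fraction[2],
              x$cover$areal_fraction[3]))
  invisible(x)
}
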