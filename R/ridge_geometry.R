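# Geometric model of ridge keels and level ice: surface-area ratio,
# brine-volume ratio, and per-compartment unit volumes.
#
# All vertical extents are in meters measured downward from the waterline;
# "unit volume" is m^3 per m^2 of an ice type's areal footprint, i.e. meters.

#' Describe the morphology of a ridge keel
#'
#' Constructs a validated description of a pressure-ridge keel: total keel
#' depth, thickness of the consolidated layer (blocks frozen together),
#' macroporosity of the unconsolidated rubble beneath it, and the
#' dimensions of the ice blocks making up the rubble.
#'
#' @param keel_depth Keel depth below the waterline, m (> 0).
#' @param consolidated_thickness Consolidated-layer thickness, m
#'   (0 < value <= `keel_depth`).
#' @param macroporosity Rubble macroporosity, fraction of the rubble volume
#'   occupied by water-filled voids, in \[0, 1\].
#' @param block_thickness Ice block thickness, m (> 0).
#' @param block_length Ice block length, m; defaults to
#'   `3.5 * block_thickness` (typical block length-to-thickness ratio).
#' @param skin_thickness Thickness of the "exterior" skin layer counted on
#'   each large face of a block, m; default 0.1.
#' @param bottom_thickness Thickness of the bottom habitat layer, m;
#'   default 0.1.
#' @return An object of class `ridge_morphology`.
#' @export
#' @examples
#' ridge_morphology(keel_depth = 3.9, consolidated_thickness = 2.2,
#'                  macroporosity = 0.17, block_thickness = 0.3)
ridge_morphology <- function(keel_depth,
                             consolidated_thickness,
                             macroporosity,
                             block_thickness,
                             block_length = 3.5 * block_thickness,
                             skin_thickness = 0.1,
                             bottom_thickness = 0.1) {
  stopifnot(
    keel_depth > 0,
    consolidated_thickness > 0,
    consolidated_thickness <= keel_depth,
    macroporosity >= 0, macroporosity <= 1,
    block_thickness > 0,
    block_length >= block_thickness,
    skin_thickness >= 0,
    skin_thickness <= block_thickness / 2,
    bottom_thickness >= 0
  )
  structure(
    list(
      keel_depth = keel_depth,
      consolidated_thickness = consolidated_thickness,
      macroporosity = macroporosity,
      block_thickness = block_thickness,
      block_length = block_length,
      skin_thickness = skin_thickness,
      bottom_thickness = bottom_thickness
    ),
    class = "ridge_morphology"
  )
}

#' @export
print.ridge_morphology <- function(x, ...) {
  cat("<ridge_morphology>\n")
  cat(sprintf("  keel depth            %.2f m\n", x$keel_depth))
  cat(sprintf("  consolidated layer    %.2f m\n", x$consolidated_thickness))
  cat(sprintf("  rubble thickness      %.2f m\n", rubble_thickness(x)))
  cat(sprintf("  rubble macroporosity  %.0f%%\n", 100 * x$macroporosity))
  cat(sprintf("  block  %.2f m thick x %.2f m long (skin %.2f m)\n",
              x$block_thickness, x$block_length, x$skin_thickness))
  invisible(x)
}

#' Rubble-layer thickness of a ridge keel
#'
#' @param morph A [ridge_morphology()].
#' @return Keel depth minus consolidated thickness, m.
#' @export
rubble_thickness <- function(morph) {
  morph$keel_depth - morph$consolidated_thickness
}

#' Describe level (undeformed) sea ice
#'
#' @param draft Ice draft (depth below the waterline), m; must exceed
#'   `bottom_thickness`.
#' @param bottom_thickness Bottom habitat layer thickness, m; default 0.1.
#' @return An object of class `level_ice`.
#' @export
#' @examples
#' level_ice(draft = 1.3)
level_ice <- function(draft, bottom_thickness = 0.1) {
  stopifnot(draft > 0, bottom_thickness >= 0)
  if (draft <= bottom_thickness) {
    stop("`draft` must exceed `bottom_thickness`", call. = FALSE)
  }
  structure(
    list(draft = draft, bottom_thickness = bottom_thickness),
    class = "level_ice"
  )
}

#' @export
print.level_ice <- function(x, ...) {
  cat(sprintf("<level_ice> draft %.2f m (bottom layer %.2f m)\n",
              x$draft, x$bottom_thickness))
  invisible(x)
}

#' Convert level-ice thickness to draft
#'
#' Level-ice drafts are the thickness times the submerged fraction given by
#' the ice/seawater density ratio (about 0.9); the emergent freeboard does
#' not host an under-ice habitat.
#'
#' @param thickness Ice thickness, m (> 0).
#' @param submerged_fraction Fraction of the thickness below the waterline,
#'   in (0, 1\]; default 0.9.
#' @return Draft, m.
#' @export
#' @examples
#' thickness_to_draft(1.4) # 1.26
thickness_to_draft <- function(thickness, submerged_fraction = 0.9) {
  stopifnot(all(thickness > 0),
            submerged_fraction > 0, submerged_fraction <= 1)
  thickness * submerged_fraction
}

#' Ice surface area of ridge rubble relative to level ice
#'
#' Ratio of the total surface area of the ice blocks in the rubble layer to
#' the horizontal projection of the keel (equal to the surface area of the
#' same footprint of level ice):
#' \deqn{S_{rbl}/S_{li} = \frac{h_{rbl}(1-\mu)}{h_b l_b} (l_b + 2 h_b)}
#' counting the two large faces and the two end faces of each block.
#'
#' @param morph A [ridge_morphology()].
#' @param rubble_thickness_override Optional rubble thickness, m, replacing
#'   the morphology's `keel_depth - consolidated_thickness` (useful for
#'   young, fully unconsolidated ridges).
#' @return Dimensionless area ratio.
#' @export
#' @examples
#' m <- ridge_morphology(7.2, 0.2, 0.30, 0.3) # young, barely consolidated keel
#' surface_area_ratio(m) # ~25: rubble has 20-30x the ice surface of level ice
surface_area_ratio <- function(morph, rubble_thickness_override = NULL) {
  h_rbl <- rubble_thickness_override %||% rubble_thickness(morph)
  if (h_rbl <= 0) {
    stop("rubble thickness must be > 0 for a surface-area ratio", call. = FALSE)
  }
  h_b <- morph$block_thickness
  l_b <- morph$block_length
  if (h_b * l_b == 0) {
    stop("block dimensions must be positive", call. = FALSE)
  }
  h_rbl * (1 - morph$macroporosity) / (h_b * l_b) * (l_b + 2 * h_b)
}

#' Ratio of total brine volume in a ridge to that in level ice
#'
#' The consolidated layer holds brine like level ice, while each submerged
#' rubble block holds brine at the (warmer) rubble brine fraction:
#' \deqn{V_{b,rdg}/V_{b,li} = h_{cl}/h_{li} +
#'   \frac{h_{rbl}(1-\mu)}{h_{li}} \frac{v_{b,rbl}}{v_{b,li}}}
#'
#' @param consolidated_thickness Consolidated-layer thickness, m (> 0).
#' @param rubble_thickness Rubble thickness, m (>= 0).
#' @param level_thickness Level-ice thickness, m (> 0).
#' @param macroporosity Rubble macroporosity, fraction.
#' @param vb_rubble Brine volume fraction of rubble blocks (> 0).
#' @param vb_level Brine volume fraction of level ice (> 0).
#' @return Dimensionless brine-volume ratio.
#' @export
#' @examples
#' brine_volume_ratio(1.5, 6.5, 1.5, 0.30, vb_rubble = 0.10, vb_level = 0.05)
brine_volume_ratio <- function(consolidated_thickness, rubble_thickness,
                               level_thickness, macroporosity,
                               vb_rubble, vb_level) {
  stopifnot(consolidated_thickness > 0, rubble_thickness >= 0,
            level_thickness > 0, macroporosity >= 0, macroporosity <= 1,
            vb_rubble >= 0)
  if (vb_level <= 0) {
    stop("`vb_level` must be > 0", call. = FALSE)
  }
  consolidated_thickness / level_thickness +
    rubble_thickness * (1 - macroporosity) / level_thickness *
      (vb_rubble / vb_level)
}

#' Per-compartment unit volumes of a ridge keel
#'
#' Decomposes a keel into habitat compartments, each expressed as a unit
#' volume (m^3 per m^2 of ridge footprint):
#' * `voids`: water-filled rubble voids, `h_rbl * mu`;
#' * `exterior`: the outer skin (two faces, `skin_thickness` each) of every
#'   rubble block, `h_rbl * (1 - mu) / h_b * 2 * skin`;
#' * `interior`: the consolidated layer plus block interiors,
#'   `h_c + h_rbl * (1 - mu) / h_b * (h_b - 2 * skin)`;
#' * `bottom`: the bottom layer, `bottom_thickness`.
#'
#' The total ice volume is always the sum of the ice compartments
#' (exterior + interior), never computed from a separate closed form, so
#' the decomposition is additive by construction.
#'
#' @param morph A [ridge_morphology()].
#' @return A tibble with columns `ice_type` ("ridge"), `compartment`
#'   (`interior`, `exterior`, `voids`, `bottom`) and `unit_volume` (m).
#' @export
#' @examples
#' ridge_unit_volumes(mosaic_morphology())
ridge_unit_volumes <- function(morph) {
  stopifnot(inherits(morph, "ridge_morphology"))
  h_rbl <- rubble_thickness(morph)
  if (h_rbl < 0) {
    stop("negative rubble thickness", call. = FALSE)
  }
  mu <- morph$macroporosity
  h_b <- morph$block_thickness
  skin <- morph$skin_thickness
  blocks_per_m <- h_rbl * (1 - mu) / h_b # stacked block count per m^2
  tibble::tibble(
    ice_type = "ridge",
    compartment = c("interior", "exterior", "voids", "bottom"),
    unit_volume = c(
      morph$consolidated_thickness + blocks_per_m * (h_b - 2 * skin),
      blocks_per_m * 2 * skin,
      h_rbl * mu,
      morph$bottom_thickness
    )
  )
}

#' Per-compartment unit volumes of level ice
#'
#' @param level A [level_ice()].
#' @param ice_type Label for the output (`"fyi"` or `"syi"` in the packaged
#'   configuration).
#' @return A tibble with columns `ice_type`, `compartment` (`interior`,
#'   `bottom`) and `unit_volume` (m).
#' @export
#' @examples
#' level_unit_volumes(level_ice(1.3), "fyi")
level_unit_volumes <- function(level, ice_type = "level") {
  stopifnot(inherits(level, "level_ice"))
  tibble::tibble(
    ice_type = ice_type,
    compartment = c("interior", "bottom"),
    unit_volume = c(level$draft - level$bottom_thickness,
                    level$bottom_thickness)
  )
}

#' Areal coverage of the ice types
#'
#' @param ridge,fyi,syi Areal fractions of ridges, first-year and
#'   second-year level ice, each in \[0, 1\] with sum <= 1.
#' @return A tibble with columns `ice_type` and `areal_fraction`.
#' @export
#' @examples
#' ice_cover(ridge = 0.22, fyi = 0.50, syi = 0.28)
ice_cover <- function(ridge, fyi, syi) {
  a <- c(ridge = ridge, fyi = fyi, syi = syi)
  if (any(a < 0 | a > 1)) {
    stop("areal fractions must lie in [0, 1]", call. = FALSE)
  }
  if (sum(a) > 1 + 1e-9) {
    stop("areal fractions sum to more than 1", call. = FALSE)
  }
  tibble::tibble(ice_type = names(a), areal_fraction = unname(a))
}

#' Fraction of total ice volume held by each compartment
#'
#' Weights every compartment's unit volume by its ice type's areal fraction
#' and normalizes over all (ice type, compartment) cells, giving each
#' cell's share of the total ice (plus void) volume per m^2 of sea ice.
#'
#' @param volumes A tibble of unit volumes, the row-bound output of
#'   [ridge_unit_volumes()] and [level_unit_volumes()].
#' @param cover An [ice_cover()] tibble covering every ice type in
#'   `volumes`.
#' @return `volumes` with columns `areal_fraction`, `weighted_volume`
#'   (unit volume x areal fraction, m per m^2 of total area) and
#'   `volume_fraction` (normalized; sums to 1).
#' @export
volume_fractions <- function(volumes, cover) {
  missing_types <- setdiff(unique(volumes$ice_type), cover$ice_type)
  if (length(missing_types) > 0) {
    stop("no areal fraction for ice type(s): ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::inner_join(volumes, cover, by = "ice_type")
  out$weighted_volume <- out$unit_volume * out$areal_fraction
  total <- sum(out$weighted_volume)
  if (total <= 0) {
    stop("total weighted volume is zero; cannot normalize", call. = FALSE)
  }
  out$volume_fraction <- out$weighted_volume / total
  out
}

#' Habitable ice volume per ice type, per m^2 of total sea-ice area
#'
#' Sums the ice compartments of each type (voids excluded: they are water,
#' not ice) and scales by the type's areal coverage.
#'
#' @inheritParams volume_fractions
#' @return A tibble with columns `ice_type` and `habitable_volume`
#'   (m^3 per m^2 of total area).
#' @export
habitable_ice_volume <- function(volumes, cover) {
  ice_only <- dplyr::filter(volumes, .data$compartment != "voids")
  vf <- dplyr::inner_join(
    dplyr::summarise(dplyr::group_by(ice_only, .data$ice_type),
                     unit_volume = sum(.data$unit_volume), .groups = "drop"),
    cover,
    by = "ice_type"
  )
  tibble::tibble(
    ice_type = vf$ice_type,
    habitable_volume = vf$unit_volume * vf$areal_fraction
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
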