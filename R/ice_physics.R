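# Brine volume fraction parameterizations and permeability classification.

#' Phase-relation coefficients for sea-ice brine volume
#'
#' Returns the versioned coefficient table used by [brine_fraction_cw()].
#' Each row gives the cubic polynomial coefficients of F1(T) and F2(T)
#' (T in degrees Celsius) over one temperature interval, together with a
#' citation string so the provenance of every number is auditable. The
#' brine volume fraction of gas-free sea ice is
#' \deqn{v_b = \rho_i S / (F_1(T) - \rho_i S F_2(T))}
#' with \eqn{\rho_i} the pure-ice density in g cm^-3.
#'
#' @return A tibble with columns `piece`, `t_min`, `t_max` (degC, the
#'   half-open validity interval), `f1_0`..`f1_3`, `f2_0`..`f2_3`
#'   (polynomial coefficients, constant term first), `citation`, and
#'   `version`.
#' @export
#' @examples
#' brine_phase_coefficients()
brine_phase_coefficients <- function() {
  tibble::tibble(
    piece = c("lm_warm", "cw_mid", "cw_cold"),
    t_min = c(-2, -22.9, -30),
    t_max = c(0, -2, -22.9),
    f1_0 = c(-0.041221, -4.732, 9899),
    f1_1 = c(-18.407, -22.45, 1309),
    f1_2 = c(0.58402, -0.6397, 55.27),
    f1_3 = c(0.21454, -0.01074, 0.7160),
    f2_0 = c(0.090312, 8.903e-2, 8.547),
    f2_1 = c(-0.016111, -1.763e-2, 1.089),
    f2_2 = c(1.2291e-4, -5.330e-4, 4.518e-2),
    f2_3 = c(1.3603e-4, -8.801e-6, 5.819e-4),
    citation = c(
      "Lepparanta & Manninen (1988), FIMR Internal Report 88-2, 0 > T > -2 C",
      "Cox & Weeks (1983), J. Glaciol. 29(102), -2 >= T >= -22.9 C",
      "Cox & Weeks (1983), J. Glaciol. 29(102), -22.9 > T >= -30 C"
    ),
    version = "1.0"
  )
}

# Pure-ice density, g cm^-3, T in degC (Pounder 1965 linear fit used by the
# phase-relation papers).
ice_density <- function(temperature) {
  0.917 - 1.403e-4 * temperature
}

#' Brine volume fraction from the Frankenstein-Garner closed form
#'
#' Closed-form approximation of the relative brine volume of sea ice,
#' \deqn{v_b = S (0.532 + 49.185 / |T|) / 1000,}
#' valid for ice temperatures between -22.9 and -0.5 degC.
#'
#' @param bulk_salinity Bulk ice salinity (PSS-78, dimensionless), >= 0.
#'   Vectorized.
#' @param temperature Ice temperature in degrees Celsius, within
#'   \[-22.9, -0.5\]. Vectorized (recycled against `bulk_salinity`).
#' @return Brine volume fraction(s) in \[0, 1\].
#' @seealso [brine_fraction_cw()] for the piecewise phase relations.
#' @export
#' @examples
#' brine_fraction_fg(5, -5) # ~0.052
brine_fraction_fg <- function(bulk_salinity, temperature) {
  check_salinity(bulk_salinity)
  if (any(temperature > 0)) {
    stop("`temperature` must be negative (degC); got positive values",
         call. = FALSE)
  }
  bad <- temperature < -22.9 | temperature > -0.5
  if (any(bad)) {
    stop(sprintf(
      "`temperature` outside the Frankenstein-Garner validity range [-22.9, -0.5] degC: %s",
      paste(format(temperature[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  vb <- bulk_salinity * (0.532 + 49.185 / abs(temperature)) / 1000
  pmin(vb, 1)
}

#' Brine volume fraction from the Cox-Weeks phase relations
#'
#' Brine volume fraction of gas-free sea ice via the piecewise polynomial
#' phase relations: Cox-Weeks coefficients for T <= -2 degC and the
#' Lepparanta-Manninen coefficients for -2 < T < 0 degC (see
#' [brine_phase_coefficients()] for the exact numbers and citations).
#'
#' @inheritParams brine_fraction_fg
#' @param temperature Ice temperature in degC, within \[-30, 0).
#' @return Brine volume fraction(s) in \[0, 1\].
#' @export
#' @examples
#' brine_fraction_cw(5, -5)
#' brine_fraction_cw(6.9, -1.5) > brine_fraction_cw(6.9, -2.5) # warming -> more brine
brine_fraction_cw <- function(bulk_salinity, temperature) {
  check_salinity(bulk_salinity)
  if (any(temperature >= 0)) {
    stop("`temperature` must be strictly below 0 degC", call. = FALSE)
  }
  if (any(temperature < -30)) {
    stop("`temperature` below the phase-relation validity range [-30, 0) degC",
         call. = FALSE)
  }
  n <- max(length(bulk_salinity), length(temperature))
  s <- rep_len(bulk_salinity, n)
  t <- rep_len(temperature, n)
  co <- brine_phase_coefficients()
  # piece selection: warm piece on (-2, 0), CW mid on [-22.9, -2], cold below
  idx <- ifelse(t > -2, 1L, ifelse(t >= -22.9, 2L, 3L))
  f1 <- co$f1_0[idx] + co$f1_1[idx] * t + co$f1_2[idx] * t^2 + co$f1_3[idx] * t^3
  f2 <- co$f2_0[idx] + co$f2_1[idx] * t + co$f2_2[idx] * t^2 + co$f2_3[idx] * t^3
  rho <- ice_density(t)
  vb <- rho * s / (f1 - rho * s * f2)
  pmin(pmax(vb, 0), 1)
}

#' Classify sea-ice permeability from brine volume fraction
#'
#' Sea ice is conventionally considered permeable to fluid transport when
#' its brine volume fraction strictly exceeds 5% (the "law of fives").
#'
#' @param brine_volume_fraction Fraction(s) in \[0, 1\].
#' @param threshold Permeability threshold (fraction), default 0.05. The
#'   comparison is a strict `>`: exactly at the threshold is impermeable.
#' @return A tibble with columns `brine_volume_fraction` and `permeable`.
#' @export
#' @examples
#' classify_permeability(c(0.04, 0.05, 0.06))
classify_permeability <- function(brine_volume_fraction, threshold = 0.05) {
  if (any(brine_volume_fraction < 0 | brine_volume_fraction > 1)) {
    stop("`brine_volume_fraction` must lie in [0, 1]", call. = FALSE)
  }
  tibble::tibble(
    brine_volume_fraction = brine_volume_fraction,
    permeable = brine_volume_fraction > threshold
  )
}

#' Compute brine state for a whole ice-core profile
#'
#' Applies a brine volume parameterization to every depth section of a core
#' profile and classifies each section's permeability.
#'
#' @param sections A data frame of ice sections with columns `depth_top_m`,
#'   `depth_bottom_m`, `bulk_salinity`, `temperature_c` (see
#'   [read_ice_profile()]).
#' @param method `"fg"` (Frankenstein-Garner) or `"cw"`
#'   (Cox-Weeks / Lepparanta-Manninen).
#' @param threshold Permeability threshold passed to
#'   [classify_permeability()].
#' @return The input tibble with `brine_volume_fraction` and `permeable`
#'   columns appended, row order preserved.
#' @export
profile_brine_fractions <- function(sections, method = c("fg", "cw"),
                                    threshold = 0.05) {
  method <- match.arg(method)
  sections <- tibble::as_tibble(sections)
  if (nrow(sections) == 0) {
    stop("`sections` is empty: a profile needs at least one ice section",
         call. = FALSE)
  }
  required <- c("depth_top_m", "depth_bottom_m", "bulk_salinity", "temperature_c")
  missing_cols <- setdiff(required, names(sections))
  if (length(missing_cols) > 0) {
    stop("`sections` is missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  bad <- which(
    !(sections$depth_bottom_m > sections$depth_top_m) |
      sections$bulk_salinity < 0 |
      sections$temperature_c > 0
  )
  if (length(bad) > 0) {
    stop("invalid ice section(s) at index: ", paste(bad, collapse = ", "),
         " (need depth_bottom > depth_top, salinity >= 0, temperature <= 0)",
         call. = FALSE)
  }
  fn <- switch(method, fg = brine_fraction_fg, cw = brine_fraction_cw)
  vb <- fn(sections$bulk_salinity, sections$temperature_c)
  dplyr::mutate(
    sections,
    brine_volume_fraction = vb,
    permeable = vb > threshold
  )
}

#' Read an ice-core profile from delimited text
#'
#' @param path Path to a comma- or tab-separated file with columns
#'   `depth_top_m`, `depth_bottom_m`, `bulk_salinity`, `temperature_c`.
#' @param sep Field separator; default comma.
#' @return A tibble of ice sections.
#' @export
read_ice_profile <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Write an ice-core profile (with brine columns) to delimited text
#'
#' @param profile A tibble as returned by [profile_brine_fractions()].
#' @param path Output file path.
#' @param sep Field separator; default comma.
#' @return `path`, invisibly.
#' @export
write_ice_profile <- function(profile, path, sep = ",") {
  utils::write.table(profile, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Winter brine scenario for ridge rubble vs level ice
#'
#' Evaluates the Frankenstein-Garner brine volume for the canonical winter
#' contrast between submerged ridge rubble and colder level ice. Rubble
#' blocks sit in seawater and are evaluated at the seawater freezing point;
#' level ice is evaluated at a mid-ice temperature, taken as the mean of
#' the ice surface temperature and the bottom (freezing-point) temperature.
#' Both conventions are overridable.
#'
#' @param rubble_salinity Bulk salinity of rubble blocks (default 4).
#' @param level_salinity Bulk salinity of level ice (default 5).
#' @param surface_temperature Ice surface temperature, degC (default -10).
#' @param freezing_point Seawater freezing point, degC (default -1.9).
#' @param level_temperature Level-ice evaluation temperature; defaults to
#'   `mean(c(surface_temperature, freezing_point))` (mid-ice convention).
#' @param rubble_temperature Rubble evaluation temperature; defaults to
#'   `freezing_point`.
#' @return A tibble with one row per ice class (`rubble`, `level`) giving
#'   the evaluation temperature, salinity and brine volume fraction.
#' @export
#' @examples
#' winter_brine_scenario() # rubble ~10%, level ~5%
winter_brine_scenario <- function(rubble_salinity = 4,
                                  level_salinity = 5,
                                  surface_temperature = -10,
                                  freezing_point = -1.9,
                                  level_temperature = NULL,
                                  rubble_temperature = NULL) {
  if (is.null(level_temperature)) {
    level_temperature <- mean(c(surface_temperature, freezing_point))
  }
  if (is.null(rubble_temperature)) {
    rubble_temperature <- freezing_point
  }
  tibble::tibble(
    ice_class = c("rubble", "level"),
    salinity = c(rubble_salinity, level_salinity),
    temperature_c = c(rubble_temperature, level_temperature),
    brine_volume_fraction = brine_fraction_fg(
      c(rubble_salinity, level_salinity),
      c(rubble_temperature, level_temperature)
    )
  )
}

check_salinity <- function(s) {
  if (any(s < 0)) {
    stop("`bulk_salinity` must be >= 0", call. = FALSE)
  }
  invisible(TRUE)
}
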