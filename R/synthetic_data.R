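# Seeded generators for synthetic field data: per-compartment concentration
# samples, drill-line void/ice logs, and ice-core temperature/salinity
# profiles. Everything is bit-reproducible given (spec, seed).

#' Draw synthetic concentration samples for a set of compartments
#'
#' For each row of `specs`, draws `n` concentration values from the stated
#' distribution. `true_mean` and `true_sd` parameterize the latent
#' distribution: for `"truncated_normal_at_zero"` they are the mean and SD
#' of the untruncated normal (the realized mean of the truncated draw is
#' higher whenever truncation bites; see [truncnorm_mean()]); for
#' `"lognormal"` they are the mean and SD of the lognormal itself
#' (moment-matched).
#'
#' @param specs A tibble with columns `variable`, `ice_type`,
#'   `compartment`, `true_mean`, `true_sd`, `n`, and optionally
#'   `distribution` (`"truncated_normal_at_zero"`, the default, or
#'   `"lognormal"`).
#' @param seed Integer seed; identical (specs, seed) gives identical
#'   output.
#' @return A sample tibble (columns `variable`, `ice_type`, `compartment`,
#'   `value`) consumable by [aggregate_samples()].
#' @export
#' @examples
#' spec <- data.frame(variable = "chla", ice_type = "ridge",
#'                    compartment = "interior", true_mean = 2.6,
#'                    true_sd = 4.3, n = 23)
#' gen_samples(spec, seed = 1)
gen_samples <- function(specs, seed) {
  specs <- tibble::as_tibble(specs)
  if (!"distribution" %in% names(specs)) {
    specs$distribution <- "truncated_normal_at_zero"
  }
  stopifnot(all(specs$true_mean >= 0), all(specs$true_sd >= 0),
            all(specs$n >= 1))
  bad <- setdiff(unique(specs$distribution),
                 c("truncated_normal_at_zero", "lognormal"))
  if (length(bad) > 0) {
    stop("unsupported distribution(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  seed_rng(seed)
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    sp <- specs[i, ]
    value <- draw_values(sp$distribution, sp$n, sp$true_mean, sp$true_sd)
    tibble::tibble(
      variable = sp$variable,
      ice_type = sp$ice_type,
      compartment = sp$compartment,
      value = value
    )
  })
  dplyr::bind_rows(rows)
}

draw_values <- function(distribution, n, mu, sd) {
  if (sd == 0) {
    return(rep(mu, n))
  }
  switch(
    distribution,
    truncated_normal_at_zero = rtruncnorm0(n, mu, sd),
    lognormal = {
      # moment-match: lognormal with mean mu, sd `sd`
      sigma2 <- log(1 + (sd / mu)^2)
      rlnorm_mu <- log(mu) - sigma2 / 2
      stats::rlnorm(n, meanlog = rlnorm_mu, sdlog = sqrt(sigma2))
    }
  )
}

# zero-truncated normal draws by inverse-CDF (deterministic under seed)
rtruncnorm0 <- function(n, mu, sd) {
  p0 <- stats::pnorm(0, mean = mu, sd = sd)
  u <- stats::runif(n, min = p0, max = 1)
  stats::qnorm(u, mean = mu, sd = sd)
}

#' Analytic mean of a zero-truncated normal
#'
#' The mean of a normal(mu, sd) conditioned on being positive:
#' `mu + sd * dnorm(a) / (1 - pnorm(a))` with `a = -mu/sd`.
#'
#' @param mu,sd Latent (untruncated) mean and SD.
#' @return The truncated distribution's mean.
#' @export
truncnorm_mean <- function(mu, sd) {
  ifelse(sd == 0, mu, {
    a <- -mu / sd
    mu + sd * stats::dnorm(a) / (1 - stats::pnorm(a))
  })
}

#' Simulate drill-line void/ice logs through a ridge keel
#'
#' Each drill line logs, at a fixed vertical resolution, whether each cell
#' in the rubble layer (consolidated depth down to keel depth) is a
#' water-filled void or ice. Cells are void independently with probability
#' equal to the morphology's macroporosity; the consolidated layer is
#' all ice. Independence between cells is a deliberate simplification:
#' real voids are spatially correlated, but the macroporosity estimator,
#' not void geometry, is what these logs exercise.
#'
#' @param morph A [ridge_morphology()].
#' @param n_drill_lines Number of drill lines (>= 1).
#' @param resolution Vertical cell size, m (> 0, no larger than the rubble
#'   thickness).
#' @param seed Integer seed.
#' @return A tibble with columns `line`, `depth_top_m`, `depth_bottom_m`,
#'   `layer` (`"consolidated"` / `"rubble"`), `void` (logical).
#' @export
gen_drill_profiles <- function(morph, n_drill_lines, resolution, seed) {
  stopifnot(inherits(morph, "ridge_morphology"), n_drill_lines >= 1,
            resolution > 0)
  h_rbl <- rubble_thickness(morph)
  if (resolution > h_rbl) {
    stop("`resolution` exceeds the rubble thickness: nothing to log",
         call. = FALSE)
  }
  seed_rng(seed)
  n_rbl <- floor(h_rbl / resolution)
  n_cl <- floor(morph$consolidated_thickness / resolution)
  cl_top <- seq_len(n_cl) - 1
  rbl_top <- morph$consolidated_thickness + (seq_len(n_rbl) - 1) * resolution
  lines <- lapply(seq_len(n_drill_lines), function(l) {
    tibble::tibble(
      line = l,
      depth_top_m = c(cl_top * resolution, rbl_top),
      depth_bottom_m = c(cl_top * resolution, rbl_top) + resolution,
      layer = rep(c("consolidated", "rubble"), c(n_cl, n_rbl)),
      void = c(rep(FALSE, n_cl),
               stats::runif(n_rbl) < morph$macroporosity)
    )
  })
  dplyr::bind_rows(lines)
}

#' Estimate rubble macroporosity from drill-line logs
#'
#' Pooled void-cell fraction over all rubble cells; the SE comes from the
#' between-line variability of per-line void fractions
#' (sd of line fractions / sqrt(number of lines)).
#'
#' @param logs A tibble as produced by [gen_drill_profiles()] (columns
#'   `line`, `layer`, `void`).
#' @return A list with `estimate`, `se`, `n_lines`, and `se_degenerate`
#'   (TRUE when only one line is available and SE is reported as NA).
#' @export
estimate_macroporosity <- function(logs) {
  logs <- tibble::as_tibble(logs)
  rbl <- logs[logs$layer == "rubble", ]
  if (nrow(rbl) == 0) {
    stop("no rubble cells in the drill logs", call. = FALSE)
  }
  per_line <- dplyr::summarise(dplyr::group_by(rbl, .data$line),
                               frac = mean(.data$void), .groups = "drop")
  n_lines <- nrow(per_line)
  list(
    estimate = mean(rbl$void),
    se = if (n_lines > 1) stats::sd(per_line$frac) / sqrt(n_lines) else NA_real_,
    n_lines = n_lines,
    se_degenerate = n_lines == 1
  )
}

#' Generate a synthetic ice-core temperature/salinity profile
#'
#' Splits an ice column into as many equal-thickness sections as there are
#' salinity values, assigns each section its salinity, and sets each
#' section's temperature by linear interpolation between the surface and
#' bottom temperatures evaluated at the section midpoint. Optional
#' Gaussian jitter on temperature is deterministic under the seed.
#'
#' @param surface_t,bottom_t Surface and bottom ice temperatures, degC.
#' @param salinity_profile Numeric vector of bulk salinities, top to
#'   bottom (>= 0, non-empty).
#' @param thickness Total ice thickness, m; default 1 (depths scale
#'   linearly).
#' @param jitter_sd SD of temperature jitter, degC; default 0.
#' @param seed Integer seed (used only when `jitter_sd > 0`).
#' @return A tibble of ice sections (`depth_top_m`, `depth_bottom_m`,
#'   `bulk_salinity`, `temperature_c`).
#' @export
#' @examples
#' gen_ice_profile(-10, -1.9, c(5, 5)) # midpoints at -8.0 and -3.9 degC
gen_ice_profile <- function(surface_t, bottom_t, salinity_profile,
                            thickness = 1, jitter_sd = 0, seed = 1) {
  if (length(salinity_profile) == 0) {
    stop("`salinity_profile` must be non-empty", call. = FALSE)
  }
  if (any(salinity_profile < 0)) {
    stop("salinities must be >= 0", call. = FALSE)
  }
  k <- length(salinity_profile)
  tops <- (seq_len(k) - 1) / k * thickness
  mids <- (seq_len(k) - 0.5) / k
  temp <- surface_t + mids * (bottom_t - surface_t)
  if (jitter_sd > 0) {
    seed_rng(seed)
    temp <- temp + stats::rnorm(k, sd = jitter_sd)
  }
  tibble::tibble(
    depth_top_m = tops,
    depth_bottom_m = tops + thickness / k,
    bulk_salinity = salinity_profile,
    temperature_c = temp
  )
}

# validate and set the RNG seed
seed_rng <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  set.seed(as.integer(seed))
  invisible(seed)
}
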