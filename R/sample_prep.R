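# Measurement-level corrections and per-compartment aggregation applied
# before budgeting.

#' Correct chlorophyll-a measured on dried filters
#'
#' Filters dried before extraction retain systematically less extractable
#' chlorophyll-a; measurements flagged as dried are multiplied by a
#' calibration factor (default 1.8) to put them on the non-dried scale.
#'
#' @param value Chl-a concentration(s), mg m^-3, >= 0.
#' @param factor Correction factor (> 0); default 1.8.
#' @return Corrected concentration(s).
#' @export
#' @examples
#' correct_dried_chla(1.0) # 1.8
correct_dried_chla <- function(value, factor = 1.8) {
  if (any(value < 0)) {
    stop("`value` must be >= 0", call. = FALSE)
  }
  stopifnot(factor > 0)
  value * factor
}

#' Convert leucine incorporation to bacterial carbon production
#'
#' 3H-leucine incorporation rates are converted to carbon production with a
#' conversion factor of 1.5 kg C per mole of incorporated leucine (derived
#' from 1797 g protein per mol leucine and a C:protein weight ratio of
#' 0.86, assuming no isotope dilution; the two constants are provenance of
#' the factor and are not re-multiplied). The unit algebra collapses to
#' 1 nmol L^-1 d^-1 -> 1.5 mg C m^-3 d^-1.
#'
#' @param leu_incorporation Leucine incorporation, nmol L^-1 d^-1, >= 0.
#' @param conversion_factor kg C per mol leucine; default 1.5.
#' @return Bacterial carbon production, mg C m^-3 d^-1.
#' @export
#' @examples
#' leucine_to_carbon(10) # 15
leucine_to_carbon <- function(leu_incorporation, conversion_factor = 1.5) {
  if (any(leu_incorporation < 0)) {
    stop("`leu_incorporation` must be >= 0", call. = FALSE)
  }
  # nmol/L/d * (1e-9 mol/nmol) * (cf*1e3 g/mol) * (1e3 L/m^3) * (1e3 mg/g)
  leu_incorporation * conversion_factor
}

#' Constants behind the leucine-to-carbon conversion factor
#'
#' @return A named list: grams of protein produced per mole of incorporated
#'   leucine (1797), the C:protein weight ratio in bacteria (0.86), and the
#'   resulting kg C per mol factor.
#' @export
leucine_conversion_constants <- function() {
  list(
    protein_per_mol_leucine_g = 1797,
    carbon_to_protein_ratio = 0.86,
    kg_c_per_mol_leucine = 1.5
  )
}

#' Split biogenic from lithogenic silica in a digestion time-course
#'
#' In a time-course alkaline digestion, biogenic silica (BSi) dissolves
#' quickly while lithogenic silica (LSi) leaches at a slow, nearly constant
#' rate. Ordinary least squares is fitted to the trailing (linear) part of
#' the cumulative liberated-Si curve; BSi is the fit's y-intercept at t = 0
#' and the alkaline-phase LSi is the remainder of the liberated Si. Total
#' LSi adds the Si solubilized in the subsequent hydrofluoric-acid phase.
#'
#' @param time_h Digestion time points, hours, strictly increasing.
#' @param si_umol_l Cumulative liberated Si at each time point,
#'   umol L^-1, non-decreasing.
#' @param hf_si Si quantified in the hydrofluoric-acid phase, umol L^-1.
#' @param linear_window Number of trailing time points used for the linear
#'   fit; default 3.
#' @return A list with `bsi`, `lsi` (umol L^-1), the fitted `slope`
#'   (umol L^-1 h^-1) and `intercept_clipped` (TRUE if a negative fitted
#'   intercept was clipped to 0, with a warning).
#' @export
#' @examples
#' t <- 1:5
#' bsi_lsi_split(t, 10 + 2 * t, hf_si = 5) # bsi 10, lsi 15
bsi_lsi_split <- function(time_h, si_umol_l, hf_si, linear_window = 3) {
  stopifnot(length(time_h) == length(si_umol_l), hf_si >= 0,
            linear_window >= 2)
  if (any(diff(time_h) <= 0)) {
    stop("`time_h` must be strictly increasing", call. = FALSE)
  }
  if (any(diff(si_umol_l) < 0)) {
    stop("cumulative `si_umol_l` must be non-decreasing", call. = FALSE)
  }
  if (length(time_h) < linear_window + 1) {
    stop(sprintf("need at least linear_window + 1 = %d time points, got %d",
                 linear_window + 1, length(time_h)), call. = FALSE)
  }
  tail_idx <- utils::tail(seq_along(time_h), linear_window)
  fit <- stats::lm(si ~ t, data = data.frame(t = time_h[tail_idx],
                                             si = si_umol_l[tail_idx]))
  intercept <- unname(stats::coef(fit)[1])
  slope <- unname(stats::coef(fit)[2])
  clipped <- FALSE
  if (intercept < 0) {
    warning("fitted BSi intercept was negative; clipped to 0")
    intercept <- 0
    clipped <- TRUE
  }
  bsi <- intercept
  lsi <- (si_umol_l[length(si_umol_l)] - bsi) + hf_si
  list(bsi = bsi, lsi = lsi, slope = slope, intercept_clipped = clipped)
}

#' Apply measurement-level corrections to raw samples
#'
#' Currently: chlorophyll-a values with `dried_flag` set are multiplied by
#' the dried-filter correction factor. Other variables pass through.
#'
#' @param samples A sample table with columns `variable`, `ice_type`,
#'   `compartment`, `value`, and optionally `dried_flag` (logical) and
#'   `date`.
#' @param chla_dried_factor Correction factor for dried Chl-a filters.
#' @return The sample tibble with corrected `value`s.
#' @export
prepare_samples <- function(samples, chla_dried_factor = 1.8) {
  samples <- tibble::as_tibble(samples)
  if (any(samples$value < 0)) {
    stop("sample `value`s must be >= 0", call. = FALSE)
  }
  if ("dried_flag" %in% names(samples)) {
    fix <- samples$variable == "chla" & as.logical(samples$dried_flag)
    samples$value[fix] <- correct_dried_chla(samples$value[fix],
                                             chla_dried_factor)
  }
  samples
}

#' Aggregate samples to per-compartment concentration estimates
#'
#' Mean and standard error (sample SD / sqrt(n)) per
#' (variable, ice type, compartment) cell. Cells with a single sample get
#' SE = 0 and `se_degenerate = TRUE` rather than failing: single-core
#' sampling does occur under difficult field conditions.
#'
#' @param samples A (corrected) sample tibble; see [prepare_samples()].
#' @return A [concentration_table()] with an extra `se_degenerate` column.
#' @export
#' @examples
#' s <- data.frame(variable = "chla", ice_type = "fyi",
#'                 compartment = "interior", value = c(1, 2, 3))
#' aggregate_samples(s) # mean 2, se 0.577
aggregate_samples <- function(samples) {
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) {
    stop("no samples to aggregate", call. = FALSE)
  }
  out <- dplyr::summarise(
    dplyr::group_by(samples, .data$variable, .data$ice_type,
                    .data$compartment),
    mean = mean(.data$value),
    se = if (dplyr::n() > 1) {
      stats::sd(.data$value) / sqrt(dplyr::n())
    } else {
      0
    },
    n = dplyr::n(),
    se_degenerate = dplyr::n() == 1,
    .groups = "drop"
  )
  concentration_table(out)
}

#' Read a raw sample table from delimited text
#'
#' @param path File with columns `variable`, `ice_type`, `compartment`,
#'   `date` (ISO-8601), `value`, and optionally `dried_flag`.
#' @param sep Field separator; default comma.
#' @return A sample tibble.
#' @export
read_samples <- function(path, sep = ",") {
  tibble::as_tibble(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  )
}
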