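# Standing-stock accounting: per-volume, per-area, per-coverage and
# relative stocks with first-order SE propagation.
#
# Conventions. A "concentration table" has one row per (variable, ice_type,
# compartment) with columns mean, se, n (mg m^-3). SEs are propagated to
# first order assuming independent compartment errors and error-free unit
# volumes and areal coverages: exact constants scale an SE linearly; sums
# combine in quadrature; ratios use the delta method.

#' Build a concentration table
#'
#' Light validation wrapper turning a data frame into the per-compartment
#' concentration table the budgeting functions consume.
#'
#' @param x A data frame with columns `variable`, `ice_type`,
#'   `compartment`, `mean`, `se`, `n`.
#' @return A validated tibble.
#' @export
concentration_table <- function(x) {
  x <- tibble::as_tibble(x)
  required <- c("variable", "ice_type", "compartment", "mean", "se", "n")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    stop("concentration table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (any(x$mean < 0) || any(x$se < 0) || any(x$n < 1)) {
    stop("concentration table needs mean >= 0, se >= 0, n >= 1",
         call. = FALSE)
  }
  dup <- duplicated(x[, c("variable", "ice_type", "compartment")])
  if (any(dup)) {
    stop("duplicated (variable, ice_type, compartment) rows", call. = FALSE)
  }
  x
}

#' Read a concentration table from delimited text
#'
#' @param path File with columns `variable`, `ice_type`, `compartment`,
#'   `mean`, `se`, `n`.
#' @param sep Field separator; default comma.
#' @return A validated concentration tibble.
#' @export
read_concentrations <- function(path, sep = ",") {
  concentration_table(
    utils::read.table(path, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE)
  )
}

#' Standing stock of one compartment per m^2 of total sea ice
#'
#' `mean * unit_volume * areal_fraction`, with the SE scaled by the same
#' exact constants.
#'
#' @param mean,se Concentration mean and standard error, mg m^-3.
#' @param unit_volume Compartment unit volume, m.
#' @param areal_fraction Areal fraction of the compartment's ice type.
#' @return A tibble with columns `mean` and `se` (mg m^-2).
#' @export
#' @examples
#' compartment_stock(2.6, 0.9, unit_volume = 2.67, areal_fraction = 0.22)
compartment_stock <- function(mean, se, unit_volume, areal_fraction) {
  stopifnot(all(unit_volume >= 0),
            all(areal_fraction >= 0), all(areal_fraction <= 1))
  k <- unit_volume * areal_fraction
  tibble::tibble(mean = mean * k, se = se * k)
}

#' Per-area standing stock of one ice type
#'
#' Volume-weighted sum of compartment concentrations over one ice type,
#' per m^2 of that type's own footprint:
#' value = sum_i mean_i v_i; SE = sqrt(sum_i (se_i v_i)^2) under
#' independent compartment errors.
#'
#' @param concs Concentration table rows for a single (variable, ice type).
#' @param volumes Unit-volume tibble for the same ice type
#'   ([ridge_unit_volumes()] / [level_unit_volumes()] output).
#' @return A one-row tibble with `mean` and `se`, mg m^-2.
#' @export
#' @examples
#' concs <- data.frame(
#'   variable = "chla", ice_type = "ridge",
#'   compartment = c("interior", "exterior", "voids", "bottom"),
#'   mean = c(2.6, 19, 3, 1.2), se = c(0.9, 9, 1, 0.2), n = c(23, 16, 3, 5)
#' )
#' per_area_stock(concs, ridge_unit_volumes(mosaic_morphology())) # ~25.8
per_area_stock <- function(concs, volumes) {
  concs <- tibble::as_tibble(concs)
  no_vol <- setdiff(concs$compartment, volumes$compartment)
  no_conc <- setdiff(volumes$compartment, concs$compartment)
  if (length(no_vol) > 0 || length(no_conc) > 0) {
    stop("compartment mismatch between concentrations and volumes: ",
         if (length(no_vol) > 0)
           paste0("no volume for {", paste(no_vol, collapse = ", "), "} "),
         if (length(no_conc) > 0)
           paste0("no concentration for {", paste(no_conc, collapse = ", "), "}"),
         call. = FALSE)
  }
  j <- dplyr::inner_join(concs, volumes[, c("compartment", "unit_volume")],
                         by = "compartment")
  tibble::tibble(
    mean = sum(j$mean * j$unit_volume),
    se = sqrt(sum((j$se * j$unit_volume)^2))
  )
}

#' Per-volume stock from a per-area stock
#'
#' @param per_area A one-row tibble (`mean`, `se`) in mg m^-2.
#' @param total_unit_volume Total unit volume of the ice type, m (> 0).
#' @return A one-row tibble (`mean`, `se`) in mg m^-3.
#' @export
per_volume_stock <- function(per_area, total_unit_volume) {
  if (total_unit_volume <= 0) {
    stop("`total_unit_volume` must be > 0", call. = FALSE)
  }
  tibble::tibble(mean = per_area$mean / total_unit_volume,
                 se = per_area$se / total_unit_volume)
}

#' Per-coverage stock from a per-area stock
#'
#' Rescales a per-footprint stock to a per-m^2-of-total-sea-ice stock.
#'
#' @param per_area A one-row tibble (`mean`, `se`) in mg m^-2.
#' @param areal_fraction Areal fraction of the ice type, in \[0, 1\].
#' @return A one-row tibble (`mean`, `se`) in mg m^-2 of total area.
#' @export
per_coverage_stock <- function(per_area, areal_fraction) {
  stopifnot(areal_fraction >= 0, areal_fraction <= 1)
  tibble::tibble(mean = per_area$mean * areal_fraction,
                 se = per_area$se * areal_fraction)
}

#' Relative contribution of each ice type to the total stock
#'
#' `percent_i = 100 x_i / sum_j x_j`, with SEs from a first-order delta
#' method treating the per-coverage stocks as independent:
#' \deqn{SE(p_i)^2 = (100/S^2)^2 [ (S - x_i)^2 se_i^2 +
#'   x_i^2 \sum_{j \ne i} se_j^2 ]}
#'
#' @param per_coverage A tibble with columns `ice_type`, `mean`, `se`
#'   (per-coverage stocks in mg m^-2 of total area).
#' @return The input with `percent` and `percent_se` columns appended;
#'   `percent` sums to 100.
#' @export
relative_fractions <- function(per_coverage) {
  x <- per_coverage$mean
  se <- per_coverage$se
  total <- sum(x)
  if (total <= 0) {
    stop("all per-coverage stocks are zero; relative fractions undefined",
         call. = FALSE)
  }
  pct <- 100 * x / total
  var_p <- vapply(seq_along(x), function(i) {
    (100 / total^2)^2 *
      ((total - x[i])^2 * se[i]^2 + x[i]^2 * sum(se[-i]^2))
  }, numeric(1))
  dplyr::mutate(per_coverage, percent = pct, percent_se = sqrt(var_p))
}

#' Build the full standing-stock budget
#'
#' Runs the whole accounting for every variable and ice type: compartment
#' stocks (mirroring the per-compartment table), then per-area, per-volume,
#' per-coverage and relative stocks per ice type (mirroring the summary
#' table), with first-order SE propagation throughout. Internal values are
#' kept unrounded; use [format_budget()] for a 2-significant-figure
#' display.
#'
#' @param concs A [concentration_table()] covering every
#'   (variable, ice type, compartment) cell implied by `volumes`.
#' @param volumes Row-bound unit-volume tibble for all ice types.
#' @param cover An [ice_cover()] tibble.
#' @return An object of class `stock_budget`: a list with tibbles
#'   `compartments` (per-compartment stocks incl. volume fractions) and
#'   `ice_types` (per-volume / per-area / per-coverage / relative stocks),
#'   plus the inputs.
#' @export
#' @examples
#' b <- build_budget(mosaic_concentrations(), mosaic_volumes(), mosaic_cover())
#' format_budget(b)
build_budget <- function(concs, volumes, cover) {
  concs <- concentration_table(concs)
  vf <- volume_fractions(volumes, cover)

  # every variable must cover every (ice_type, compartment) cell
  cells <- unique(vf[, c("ice_type", "compartment")])
  for (v in unique(concs$variable)) {
    got <- concs[concs$variable == v, c("ice_type", "compartment")]
    miss <- dplyr::anti_join(cells, got, by = c("ice_type", "compartment"))
    if (nrow(miss) > 0) {
      stop("missing concentration cells for variable '", v, "': ",
           paste(paste(miss$ice_type, miss$compartment, sep = "/"),
                 collapse = ", "), call. = FALSE)
    }
  }

  comp <- dplyr::inner_join(
    concs, vf,
    by = c("ice_type", "compartment")
  )
  st <- compartment_stock(comp$mean, comp$se,
                          comp$unit_volume, comp$areal_fraction)
  comp$stock_mean <- st$mean
  comp$stock_se <- st$se

  per_type <- dplyr::group_by(comp, .data$variable, .data$ice_type)
  per_type <- dplyr::summarise(
    per_type,
    total_unit_volume = sum(.data$unit_volume),
    areal_fraction = .data$areal_fraction[1],
    per_area = sum(.data$mean * .data$unit_volume),
    per_area_se = sqrt(sum((.data$se * .data$unit_volume)^2)),
    .groups = "drop"
  )
  per_type <- dplyr::mutate(
    per_type,
    per_volume = .data$per_area / .data$total_unit_volume,
    per_volume_se = .data$per_area_se / .data$total_unit_volume,
    per_coverage = .data$per_area * .data$areal_fraction,
    per_coverage_se = .data$per_area_se * .data$areal_fraction
  )
  per_type <- dplyr::group_modify(
    dplyr::group_by(per_type, .data$variable),
    function(df, key) {
      rel <- relative_fractions(
        tibble::tibble(ice_type = df$ice_type,
                       mean = df$per_coverage, se = df$per_coverage_se)
      )
      df$percent <- rel$percent
      df$percent_se <- rel$percent_se
      df
    }
  )
  per_type <- dplyr::ungroup(per_type)

  structure(
    list(
      compartments = comp,
      ice_types = per_type,
      concentrations = concs,
      volumes = volumes,
      cover = cover
    ),
    class = "stock_budget"
  )
}

#' @export
print.stock_budget <- function(x, ...) {
  cat("<stock_budget>",
      sprintf("%d variables x %d ice types, %d compartment cells\n",
              length(unique(x$ice_types$variable)),
              length(unique(x$ice_types$ice_type)),
              nrow(x$compartments)))
  print(format_budget(x), n = Inf)
  invisible(x)
}

#' Display-round a budget to significant figures
#'
#' @param budget A [build_budget()] result.
#' @param digits Significant figures for display; default 2 (the
#'   convention of the source tables).
#' @return The `ice_types` tibble with all stock columns rounded.
#' @export
format_budget <- function(budget, digits = 2) {
  stopifnot(digits >= 1)
  df <- budget$ice_types
  num <- c("per_volume", "per_volume_se", "per_area", "per_area_se",
           "per_coverage", "per_coverage_se", "percent", "percent_se")
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}

#' Carbon-to-chlorophyll ratio between two stocks
#'
#' @param budget A [build_budget()] result containing `poc` and `chla`
#'   variables.
#' @param basis `"per_area"` or `"per_volume"`: which stock basis to take
#'   the ratio on. Recorded in the output for auditability, since the two
#'   bases differ whenever ice types have different total unit volumes.
#' @return A tibble with columns `ice_type`, `basis`, `ratio`.
#' @export
c_to_chla_ratio <- function(budget, basis = c("per_area", "per_volume")) {
  basis <- match.arg(basis)
  df <- budget$ice_types
  poc <- df[df$variable == "poc", c("ice_type", basis)]
  chla <- df[df$variable == "chla", c("ice_type", basis)]
  j <- dplyr::inner_join(poc, chla, by = "ice_type",
                         suffix = c("_poc", "_chla"))
  denom <- j[[paste0(basis, "_chla")]]
  if (any(denom <= 0)) {
    stop("chlorophyll stock is zero; C:Chl-a ratio undefined", call. = FALSE)
  }
  ratio <- j[[paste0(basis, "_poc")]] / denom
  tibble::tibble(ice_type = j$ice_type, basis = basis, ratio = ratio)
}
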