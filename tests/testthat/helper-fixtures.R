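# Shared fixtures: the packaged study configuration expressed directly, and
# the per-compartment concentration summary with the latent SDs implied by
# SE and n (sd = se * sqrt(n)), used by the synthetic-recovery tests.

study_concentration_specs <- function() {
  concs <- mosaic_concentrations()
  concs$true_mean <- concs$mean
  concs$true_sd <- concs$se * sqrt(concs$n)
  concs[, c("variable", "ice_type", "compartment",
            "true_mean", "true_sd", "n")]
}

# unit volumes exactly as printed in the per-compartment summary table
# (2 decimal places), for frozen-value comparisons
printed_volumes <- function() {
  tibble::tibble(
    ice_type = c(rep("ridge", 4), "fyi", "fyi", "syi", "syi"),
    compartment = c("interior", "exterior", "voids", "bottom",
                    "interior", "bottom", "interior", "bottom"),
    unit_volume = c(2.67, 0.94, 0.29, 0.1, 1.2, 0.1, 1.3, 0.1)
  )
}
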