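---
title: "Budgeting biological habitat in sea-ice pressure ridges"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Budgeting biological habitat in sea-ice pressure ridges}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ridgebudget)
```

## The problem

Pressure ridges are the deformed fraction of the Arctic sea-ice cover:
piles of broken ice blocks with an underwater keel that can reach several
times the draft of the surrounding level ice. The keel's unconsolidated
rubble is bathed in seawater, stays near the freezing point, and offers far
more ice surface and pore space than cold level ice — which makes ridges a
candidate refuge for ice-associated algae and the food web that depends on
them. Quantifying that role requires an accounting exercise: convert what
can be measured (keel depth, consolidation, rubble macroporosity, block
sizes, level-ice drafts, areal coverage from airborne laser scanning, and
per-compartment chlorophyll-a and particulate organic carbon
concentrations) into standing stocks per square meter of sea ice, with
uncertainties.

`ridgebudget` implements that accounting as a tested pipeline:

1. **Brine physics** (`brine_fraction_fg()`, `brine_fraction_cw()`,
   `classify_permeability()`): how much liquid, habitable pore space bulk
   salinity and temperature imply.
2. **Keel geometry** (`ridge_unit_volumes()`, `level_unit_volumes()`,
   `surface_area_ratio()`, `brine_volume_ratio()`): per-compartment unit
   volumes (m^3 per m^2 of footprint) from morphology.
3. **Stock budgeting** (`build_budget()` and friends): concentrations x
   volumes x areal coverage, with first-order SE propagation.
4. **Sample preparation** (`correct_dried_chla()`, `leucine_to_carbon()`,
   `bsi_lsi_split()`, `aggregate_samples()`): the measurement-level
   corrections applied before budgeting.
5. **Synthetic data** (`gen_samples()`, `gen_drill_profiles()`,
   `gen_ice_profile()`): seeded generators with the statistical structure
   the analysis assumes, so the full pipeline is testable without field
   data.

## The geometric model

A keel of depth $h_k$ consists of a consolidated layer of thickness $h_c$
(blocks frozen together, hydraulically similar to level ice) and a rubble
layer of thickness $h_{rbl} = h_k - h_c$ in which a fraction $\mu$ (the
macroporosity) is open, water-filled voids. The rubble is modelled as a
stack of rectangular blocks of thickness $h_b$ and length $l_b$ (default
aspect ratio $l_b/h_b = 3.5$).

The ice surface area of the rubble relative to the same footprint of level
ice counts the two large faces and two end faces of each block:

$$\frac{S_{rbl}}{S_{li}} = \frac{h_{rbl}(1-\mu)}{h_b\,l_b}\,(l_b + 2h_b).$$

For winter-typical young keels (rubble 6–8 m, $\mu = 30\%$, blocks
0.2–0.4 m) this is roughly 20–30: even a 5% areal fraction of ridges
matches the ice–water interface of all the surrounding level ice.

Habitat compartments are expressed as *unit volumes* (m^3 per m^2 of the
ice type's footprint, i.e. meters):

* ridge voids: $v_v = h_{rbl}\,\mu$;
* ridge exterior: a skin of thickness $\delta_{ext}$ (default 0.1 m) on
  the two large faces of each block,
  $v_{ext} = h_{rbl}(1-\mu)/h_b \cdot 2\delta_{ext}$;
* ridge interior: the consolidated layer plus block cores,
  $v_{int} = h_c + h_{rbl}(1-\mu)/h_b \cdot (h_b - 2\delta_{ext})$;
* a bottom layer $\delta_{bot}$ (default 0.1 m) for every ice type;
* level-ice interior: draft minus the bottom layer.

Totals are always sums of these components. The decomposition is additive
by construction — voids + exterior + interior + bottom equals keel depth
plus bottom layer — and the test suite enforces that identity over random
morphologies, which is also why the package never carries a separate
closed form for "total ridge ice volume": a standalone total can (and in
one published instance does) disagree with its own components.

```{r}
ridge_unit_volumes(mosaic_morphology())
```

### Thickness vs draft

Only the submerged part of level ice borders the under-ice habitat, so
budgets use drafts. Where only total thickness is known,
`thickness_to_draft()` multiplies by a submerged fraction (default 0.9,
the ice/seawater density ratio). The packaged configuration states drafts
directly (1.3 m first-year, 1.4 m second-year) because those are the
values its interior unit volumes (1.2/1.3 m) imply; the corresponding
reported thicknesses (1.4/1.5 m) are consistent with these drafts under
the 0.9 convention.

## Brine physics

Two parameterizations of brine volume fraction are provided. The
Frankenstein–Garner closed form,
$v_b = S\,(0.532 + 49.185/|T|)/1000$, is used for scenario arithmetic; the
Cox–Weeks phase relations (with the Leppäranta–Manninen coefficients above
−2 °C) are used for measured core profiles. Coefficients live in one
versioned, citable table (`brine_phase_coefficients()`) so tests can pin
them. The two parameterizations agree within a few percent over the
salinity/temperature range of interest; the suite documents a ≤25%
relative envelope rather than hiding the divergence. At the −2 °C piece
boundary the polynomials meet within 10^-3 (absolute, in brine fraction)
at the bulk salinities of interest (~4); the small gap grows linearly with
salinity.

Permeability uses the conventional "law of fives" with a *strict*
inequality: exactly 5% brine volume is classified impermeable, matching
the ">5%" convention.

### The winter scenario convention

The canonical winter contrast gives rubble ~10% and level ice ~5% brine
volume (salinities 4 and 5, surface temperature −10 °C). The evaluation
temperatures behind those round numbers are not uniquely determined, so
the package adopts a named, overridable convention
(`winter_brine_scenario()`): rubble sits in seawater and is evaluated at
the freezing point (−1.9 °C, itself a configurable constant — no
salinity-dependent freezing-point formula is applied); level ice is
evaluated mid-ice, at the mean of surface and bottom temperature
(−5.95 °C). This yields 0.106 and 0.044 — both within one percentage
point of the narrative 10%/5%. Note the level-ice value back-computes
exactly to 5% only at about −5.2 °C; the mid-ice convention is an
inference, and the function exposes both temperatures as arguments so any
other convention is one call away.

## Stock budgeting and error propagation

For each variable (chlorophyll-a, POC) and ice type, per-compartment
concentration means $c_i \pm se_i$ (mg m^-3) combine with unit volumes
$v_i$ and the type's areal fraction $a$:

* per area (per m^2 of the type's footprint): $\sum_i c_i v_i$, with
  $SE = \sqrt{\sum_i (se_i v_i)^2}$ under independent compartment errors;
* per volume: per-area divided by the total unit volume;
* per coverage (per m^2 of total sea ice): per-area times $a$;
* relative contribution: $100\,x_i/\sum_j x_j$, SEs by the first-order
  delta method treating the per-coverage stocks as independent.

Volumes and coverages are treated as exact: they scale SEs linearly. This
is the standard first-order reading of "SE calculated as propagation of
error"; published summary SEs are not all reproducible under it (some are
smaller than independence allows), so the package asserts the exact
algebraic properties of its own propagation — single-compartment SEs scale
exactly, percents sum to 100, conservation across aggregation levels —
rather than chasing unreproducible printed SEs. For the same reason the
published C:Chl-a ratios are not targets: `c_to_chla_ratio()` computes the
stock quotient and records the basis (per-area or per-volume) it was taken
on, because no basis reproduces the printed values from the printed
stocks.

Internal values are kept unrounded; `format_budget()` applies the
2-significant-figure display convention of the source tables. When the
goal is to reproduce a published table built from printed inputs, budget
on volumes rounded to the table's precision (as `scripts/acceptance.R`
does); the sub-percent difference from the unrounded pipeline is purely a
rounding-order effect.

```{r}
b <- build_budget(mosaic_concentrations(), mosaic_volumes(), mosaic_cover())
format_budget(b)
```

## The synthetic-data generator

`gen_samples()` draws per-compartment concentration samples from a
zero-truncated normal by default: concentrations are non-negative while
several compartments have SDs comparable to their means (e.g. ridge
exterior chlorophyll 19 with latent SD 36), so an untruncated normal would
produce negative mass. A moment-matched lognormal is offered as an
alternative; no distributional claim is inherited from the field data. The
`true_mean`/`true_sd` parameters are those of the *latent* normal — the
truncated distribution's realized mean is higher whenever truncation
bites, and `truncnorm_mean()` gives it analytically. Parameter-recovery
experiments therefore compare pipeline output against the budget evaluated
at the analytic distribution means: that is the consistency property an
unbiased estimator has; comparing against latent means would build
truncation bias into the target.

`gen_drill_profiles()` emulates drilling-based macroporosity estimation:
each vertical cell of the rubble layer is void independently with
probability $\mu$. Real voids are spatially correlated; independence is a
deliberate simplification, acceptable because the logs exercise the
estimator (`estimate_macroporosity()`: pooled void fraction, SE from
between-line variability), not void geometry. Passing recovery tests on
these generators shows the pipeline arithmetic and uncertainty bookkeeping
are sound — not that field data meet the distributional assumptions.

Problem sizes used by the validation suite: sample counts as published
(3–160 per compartment), 200 replicates for end-to-end budget recovery
(per-cell 2-SE coverage ≥ 90%), 500 replicates x 8 drill lines at 0.05 m
resolution for macroporosity (bias < 0.01). All generators are
bit-reproducible given (spec, seed).

## Numerical and design choices

* Degenerate inputs: single-sample compartments report SE = 0 with an
  explicit `se_degenerate` flag (single-core sampling happens in the
  field); a fully consolidated keel yields zero void and exterior volume;
  an all-void rubble ($\mu = 1$) has zero block surface.
* The dried-filter chlorophyll correction *multiplies* by 1.8 ("1.8 times
  less" on dried filters): corrected values must rise to be comparable.
  It is applied wherever the sample table sets `dried_flag`; flag
  assignment is the data's responsibility.
* The leucine conversion uses the net 1.5 kg C mol^-1 factor; the
  constants behind it (1797 g protein mol^-1, 0.86 g C per g protein) are
  recorded as provenance (`leucine_conversion_constants()`) and never
  re-multiplied. Per-day normalization is assumed done upstream.
* The silica split fits ordinary least squares to the trailing 3 points of
  the digestion time-course by default (the window is configurable; the
  method literature does not fix it), takes biogenic silica as the t = 0
  intercept (clipped at zero with a warning), and reports lithogenic
  silica as the alkaline remainder plus the hydrofluoric-acid phase.
* Block length defaults to 3.5 x block thickness; the exterior skin
  counts two faces per block and must fit within the block
  (`skin_thickness <= block_thickness / 2`).

## Limitations

The geometry is a one-dimensional, per-footprint idealization: no 3-D
keel shape, no consolidation time evolution, no melt modeling, no
above-water sail/freeboard contribution (deliberately excluded — not
habitat). Concentration sampling is snapshot-in-time; no seasonal
interpolation or spatial structure. SE propagation assumes independent
compartment errors and exact volumes/coverages; a bootstrap would relax
this but is out of scope.
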