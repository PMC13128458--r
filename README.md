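# ridgebudget

Standing-stock budgets for biological habitat in Arctic sea-ice pressure
ridges.

Pressure-ridge keels — underwater piles of broken ice blocks — hold far
more ice surface area and near-freezing, permeable pore space than the
level ice around them, and so can concentrate a disproportionate share of
the ice-algal biomass of a floe. `ridgebudget` turns field-measurable
quantities into that accounting, for sea-ice ecologists and
biogeochemists:

* **keel geometry → unit volumes.** A keel of depth *h_k* with
  consolidated layer *h_c*, rubble macroporosity *μ*, and blocks of
  thickness *h_b* and length *l_b* decomposes into habitat compartments
  (interior ice, a 0.1 m exterior skin per block face, water-filled
  voids, a bottom layer), each as m³ per m² of footprint. The rubble's
  relative ice surface area is
  `S_rbl/S_li = h_rbl (1-μ) / (h_b l_b) · (l_b + 2 h_b)` — about 20–30
  for winter-typical young keels.
* **brine physics.** Brine volume fraction from bulk salinity and
  temperature via the Frankenstein–Garner closed form
  `v_b = S (0.532 + 49.185/|T|)/1000` or the Cox–Weeks /
  Leppäranta–Manninen phase relations, with the strict >5% permeability
  classification.
* **stock budgeting.** Per-compartment chlorophyll-a / POC concentrations
  (mean ± SE, mg m⁻³) × unit volumes × areal coverage give per-area,
  per-volume, per-coverage and relative standing stocks with first-order
  SE propagation.
* **sample prep.** Dried-filter chlorophyll correction (×1.8),
  leucine→carbon conversion (1.5 kg C mol⁻¹), biogenic/lithogenic silica
  split from digestion time-courses (BSi = the trailing-linear-fit
  intercept at t = 0).
* **synthetic data.** Seeded zero-truncated-normal concentration samples,
  drill-line void/ice logs, and ice-core T/S profiles for end-to-end
  validation without any data download.

## Worked example

The packaged configuration describes a drifting-station floe in July:
keel depth 3.9 m, consolidated layer 2.2 m, rubble macroporosity 17%,
0.3 m blocks; level-ice drafts 1.3/1.4 m; areal coverage 22% ridges,
50% first-year ice (FYI), 28% second-year ice (SYI).

```r
library(ridgebudget)

ridge_unit_volumes(mosaic_morphology())
#> # A tibble: 4 × 3
#>   ice_type compartment unit_volume
#>   <chr>    <chr>             <dbl>
#> 1 ridge    interior          2.67
#> 2 ridge    exterior          0.941
#> 3 ridge    voids             0.289
#> 4 ridge    bottom            0.1
```

The ridge packs 2.67 m of interior ice, a 0.94 m exterior skin and
0.29 m of water-filled voids into every m² of its footprint. Combining
all ice types with the July concentration summary:

```r
b <- build_budget(mosaic_concentrations(), mosaic_volumes(), mosaic_cover())
format_budget(b)
#> # A tibble: 6 × 12
#>   variable ice_type total_unit_volume areal_fraction per_area per_area_se
#> 1 chla     fyi                    1.3           0.5       1.5        0.15
#> 2 chla     ridge                  4             0.22     26          8.8
#> 3 chla     syi                    1.4           0.28      1.3        0.15
#> 4 poc      fyi                    1.3           0.5     430         42
#> 5 poc      ridge                  4             0.22   1600        190
#> 6 poc      syi                    1.4           0.28   1000         92
#>   per_volume per_volume_se per_coverage per_coverage_se percent percent_se
#> 1       1.1           0.12         0.74           0.075    11          3.2
#> 2       6.5           2.2          5.7            1.9      84          4.8
#> 3       0.96          0.11         0.38           0.041     5.6        1.7
#> 4     330            32          220             21        25          2.3
#> 5     390            47          350             41        41          3.3
#> 6     740            65          290             26        34          2.7
```

Reading the chlorophyll rows: ridges hold ~26 mg Chl-a per m² of their own
footprint versus 1.3–1.5 mg m⁻² for level ice, and after weighting by
areal coverage they account for ~84% (± 4.8 SE) of the floe's ice-algal
standing stock despite covering 22% of its area. For POC the ridge share
is 41%. `run_budget(out_dir = "report")` writes these tables, the
volume-fraction table, and a JSON summary with the constants used;
`run_geometry()` exposes the geometric ratios standalone.

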