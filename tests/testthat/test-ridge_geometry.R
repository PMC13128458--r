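# Keel geometry: unit volumes, surface-area ratio, brine-volume ratio.

test_that("study morphology reproduces the printed unit volumes", {
  v <- ridge_unit_volumes(mosaic_morphology())
  uv <- setNames(v$unit_volume, v$compartment)
  expect_equal(round(unname(uv["voids"]), 2), 0.29)
  expect_equal(round(unname(uv["exterior"]), 2), 0.94)
  expect_equal(round(unname(uv["interior"]), 2), 2.67)
  expect_equal(unname(uv["bottom"]), 0.1)
})

test_that("a fully consolidated keel has no voids or exterior skin", {
  m <- ridge_morphology(keel_depth = 2.2, consolidated_thickness = 2.2,
                        macroporosity = 0, block_thickness = 0.3)
  v <- ridge_unit_volumes(m)
  uv <- setNames(v$unit_volume, v$compartment)
  expect_equal(unname(uv["voids"]), 0)
  expect_equal(unname(uv["exterior"]), 0)
  expect_equal(unname(uv["interior"]), 2.2)
})

test_that("compartment volumes are additive: they sum to keel + bottom", {
  set.seed(101)
  for (i in 1:50) {
    h_k <- runif(1, 2, 10)
    h_c <- runif(1, 0.5, h_k)
    h_b <- runif(1, 0.21, 0.5) # skin 0.1 must fit twice into a block
    m <- ridge_morphology(h_k, h_c, runif(1), h_b)
    v <- ridge_unit_volumes(m)
    expect_equal(sum(v$unit_volume), h_k + m$bottom_thickness,
                 tolerance = 1e-9)
  }
})

test_that("surface-area ratio matches direct evaluation", {
  # h_rbl (1-mu) / (h_b l_b) * (l_b + 2 h_b), evaluated by hand
  m1 <- ridge_morphology(7.5, 0.5, 0.30, 0.3) # rubble 7 m
  expect_equal(surface_area_ratio(m1), 25.67, tolerance = 1e-3)
  m2 <- ridge_morphology(6.5, 0.5, 0.30, 0.4) # rubble 6 m, blocks 0.4 x 1.4
  expect_equal(surface_area_ratio(m2), 16.5)
  # all-void rubble has no blocks and no surface
  expect_equal(surface_area_ratio(ridge_morphology(7.5, 0.5, 1, 0.3)), 0)
  # the override replaces the morphology's rubble thickness
  expect_equal(surface_area_ratio(m2, rubble_thickness_override = 3), 8.25)
  expect_error(
    surface_area_ratio(ridge_morphology(2, 2, 0.3, 0.3)),
    "rubble thickness"
  )
})

test_that("surface-area ratio decreases with block size at fixed aspect", {
  ratios <- vapply(seq(0.2, 0.5, by = 0.05), function(h_b) {
    surface_area_ratio(ridge_morphology(7.5, 0.5, 0.30, h_b))
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("brine-volume ratio has the right limits and magnitude", {
  # a ridge that degenerates to level ice
  expect_equal(brine_volume_ratio(1.5, 0, 1.5, 0.3, 0.1, 0.05), 1)
  # winter contrast: warm porous rubble doubles the per-block brine
  expect_equal(brine_volume_ratio(1.5, 6.5, 1.5, 0.30, 0.10, 0.05),
               7.07, tolerance = 1e-3)
  # isothermal melt: collapses to the ice-thickness ratio
  expect_equal(brine_volume_ratio(1.5, 6.5, 1.5, 0.30, 0.08, 0.08),
               (1.5 + 6.5 * 0.7) / 1.5)
  expect_error(brine_volume_ratio(1.5, 6.5, 1.5, 0.3, 0.1, 0), "vb_level")
})

test_that("level-ice unit volumes exclude the bottom layer", {
  expect_equal(level_unit_volumes(level_ice(1.3), "fyi")$unit_volume,
               c(1.2, 0.1))
  expect_equal(level_unit_volumes(level_ice(1.4), "syi")$unit_volume,
               c(1.3, 0.1))
  eps <- 1e-6
  expect_equal(level_unit_volumes(level_ice(0.1 + eps))$unit_volume[1], eps)
  expect_error(level_ice(0.05), "exceed")
})

test_that("thickness-to-draft applies the submerged fraction", {
  expect_equal(thickness_to_draft(1.4), 1.26)
  expect_equal(thickness_to_draft(1.5), 1.35)
  expect_equal(thickness_to_draft(1.5, submerged_fraction = 1), 1.5)
})

test_that("volume fractions normalize to one and match the printed shares", {
  vf <- volume_fractions(mosaic_volumes(), mosaic_cover())
  expect_equal(sum(vf$volume_fraction), 1)
  share <- function(type, comp) {
    vf$volume_fraction[vf$ice_type == type & vf$compartment == comp]
  }
  expect_equal(round(share("ridge", "interior"), 2), 0.31)
  expect_equal(round(share("syi", "interior"), 2), 0.19)
  # a single ice type and compartment holds everything
  one <- volume_fractions(
    level_unit_volumes(level_ice(0.3), "fyi")[1, ],
    tibble::tibble(ice_type = "fyi", areal_fraction = 0.4)
  )
  expect_equal(one$volume_fraction, 1)
  expect_error(volume_fractions(mosaic_volumes(),
                                ice_cover(ridge = 0.2, fyi = 0.5, syi = 0.3)[1:2, ]),
               "syi")
})

test_that("habitable ice volume excludes voids and scales with coverage", {
  hv <- habitable_ice_volume(mosaic_volumes(), mosaic_cover())
  h <- setNames(hv$habitable_volume, hv$ice_type)
  expect_equal(round(unname(h["ridge"]), 2), 0.82)
  expect_equal(unname(h["fyi"]), 0.65)
  expect_equal(round(unname(h["syi"]), 2), 0.39)
  none <- habitable_ice_volume(mosaic_volumes(),
                               ice_cover(ridge = 0, fyi = 0.5, syi = 0.28))
  expect_equal(none$habitable_volume[none$ice_type == "ridge"], 0)
})

test_that("morphology invariants are enforced at construction", {
  expect_error(ridge_morphology(3.9, 4.0, 0.17, 0.3)) # h_c > h_k
  expect_error(ridge_morphology(3.9, 2.2, 1.2, 0.3))  # porosity > 1
  expect_error(ridge_morphology(3.9, 2.2, 0.17, 0.3, block_length = 0.1))
  expect_error(ridge_morphology(3.9, 2.2, 0.17, 0.15)) # skin > h_b / 2
})
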