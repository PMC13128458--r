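# Standing-stock accounting and SE propagation.

ridge_chla <- function() {
  tibble::tibble(
    variable = "chla", ice_type = "ridge",
    compartment = c("interior", "exterior", "voids", "bottom"),
    mean = c(2.6, 19, 3, 1.2), se = c(0.9, 9, 1, 0.2), n = c(23, 16, 3, 5)
  )
}

test_that("compartment stocks scale mean and SE by the same constants", {
  st <- compartment_stock(2.6, 0.9, unit_volume = 2.67, areal_fraction = 0.22)
  expect_equal(st$mean, 2.6 * 2.67 * 0.22) # prints as 1.5
  expect_equal(st$se, 0.9 * 2.67 * 0.22)   # prints as 0.5
  poc <- compartment_stock(420, 60, 2.67, 0.22)
  expect_equal(signif(poc$mean, 2), 250)
  zero <- compartment_stock(0, 0, 2.67, 0.22)
  expect_equal(c(zero$mean, zero$se), c(0, 0))
})

test_that("per-area stock equals an exact integer-arithmetic oracle", {
  st <- per_area_stock(ridge_chla(), printed_volumes()[1:4, ])
  # oracle: scale means by 10 and volumes by 100, sum integer products
  oracle <- (26 * 267 + 190 * 94 + 30 * 29 + 12 * 10) / 1000
  expect_equal(st$mean, oracle, tolerance = 1e-12)
  expect_equal(st$mean, 25.792)
  expect_equal(st$se, sqrt((0.9 * 2.67)^2 + (9 * 0.94)^2 +
                             (1 * 0.29)^2 + (0.2 * 0.1)^2))
  # first-year ice: interior plus bottom only
  fyi <- tibble::tibble(variable = "chla", ice_type = "fyi",
                        compartment = c("interior", "bottom"),
                        mean = c(0.9, 3.9), se = c(0.1, 0.9), n = c(160, 5))
  expect_equal(per_area_stock(fyi, printed_volumes()[5:6, ])$mean, 1.47)
  zero <- fyi
  zero$mean <- 0
  zero$se <- 0
  st0 <- per_area_stock(zero, printed_volumes()[5:6, ])
  expect_equal(c(st0$mean, st0$se), c(0, 0))
})

test_that("per-area stock reports compartment mismatches by name", {
  expect_error(per_area_stock(ridge_chla()[1:3, ], printed_volumes()[1:4, ]),
               "no concentration for \\{bottom\\}")
  expect_error(per_area_stock(ridge_chla(), printed_volumes()[1:3, ]),
               "no volume for \\{bottom\\}")
})

test_that("per-volume and per-coverage stocks rescale linearly", {
  pa <- tibble::tibble(mean = 25.792, se = 8.8)
  pv <- per_volume_stock(pa, 4.0)
  expect_equal(pv$mean, 6.448) # prints as 6
  expect_equal(pv$se, 8.8 / 4)
  expect_error(per_volume_stock(pa, 0), "> 0")
  expect_equal(per_volume_stock(tibble::tibble(mean = 0, se = 0), 4)$mean, 0)

  syi <- per_volume_stock(tibble::tibble(mean = 1035, se = 91), 1.4)
  expect_equal(signif(syi$mean, 2), 740) # prints as 730 from unrounded means

  pc <- per_coverage_stock(pa, 0.22)
  expect_equal(pc$mean, 25.792 * 0.22) # prints as 6
  expect_equal(per_coverage_stock(pa, 1), pa)
})

test_that("relative fractions sum to 100 and match the printed shares", {
  chla <- relative_fractions(tibble::tibble(
    ice_type = c("ridge", "fyi", "syi"),
    mean = c(5.68, 0.735, 0.378), se = c(1.9, 0.075, 0.041)
  ))
  expect_equal(sum(chla$percent), 100)
  expect_equal(chla$percent[1], 100 * 5.68 / (5.68 + 0.735 + 0.378))
  expect_true(abs(chla$percent[1] - 80) <= 20) # inside the printed band

  poc <- relative_fractions(tibble::tibble(
    ice_type = c("ridge", "fyi", "syi"),
    mean = c(346, 215.5, 289.8), se = c(41, 21, 26)
  ))
  expect_equal(round(poc$percent[1]), 41)

  single <- relative_fractions(tibble::tibble(
    ice_type = c("ridge", "fyi"), mean = c(3, 0), se = c(1, 0)
  ))
  expect_equal(single$percent, c(100, 0))
  expect_error(relative_fractions(tibble::tibble(
    ice_type = "ridge", mean = 0, se = 0
  )), "all-zero|zero")
})

test_that("relative-fraction SEs follow the first-order delta method", {
  x <- c(5, 3, 2)
  se <- c(0.5, 0.3, 0.2)
  out <- relative_fractions(tibble::tibble(ice_type = c("a", "b", "c"),
                                           mean = x, se = se))
  # independent numerical oracle: finite-difference gradient
  p1 <- function(x) 100 * x[1] / sum(x)
  h <- 1e-6
  grad <- vapply(1:3, function(i) {
    xp <- x
    xp[i] <- xp[i] + h
    (p1(xp) - p1(x)) / h
  }, numeric(1))
  expect_equal(out$percent_se[1], sqrt(sum(grad^2 * se^2)), tolerance = 1e-4)
})

test_that("the full budget reproduces the summary-table stocks", {
  b <- build_budget(mosaic_concentrations(), mosaic_volumes(), mosaic_cover())
  row <- function(v, t) b$ice_types[b$ice_types$variable == v &
                                      b$ice_types$ice_type == t, ]
  expect_equal(row("poc", "ridge")$per_area, 1574.8, tolerance = 1e-3)
  expect_equal(signif(row("poc", "syi")$per_area, 3), 1040) # unrounded 1035
  expect_equal(round(row("chla", "ridge")$percent), 84)
  # conservation: per-coverage stocks are additive in one pass
  total <- sum(b$compartments$stock_mean[b$compartments$variable == "chla"])
  expect_equal(sum(b$ice_types$per_coverage[b$ice_types$variable == "chla"]),
               total, tolerance = 1e-9)
  # per_area * coverage == per_coverage exactly
  expect_equal(b$ice_types$per_area * b$ice_types$areal_fraction,
               b$ice_types$per_coverage, tolerance = 1e-12)
})

test_that("budget errors enumerate missing concentration cells", {
  concs <- mosaic_concentrations()
  concs <- concs[!(concs$variable == "poc" & concs$ice_type == "syi"), ]
  expect_error(build_budget(concs, mosaic_volumes(), mosaic_cover()),
               "poc.*syi/interior.*syi/bottom")
  expect_error(build_budget(concs[0, ], mosaic_volumes(), mosaic_cover()))
})

test_that("budgets are scale-equivariant in the concentrations", {
  concs <- mosaic_concentrations()
  b1 <- build_budget(concs, mosaic_volumes(), mosaic_cover())
  concs_k <- concs
  concs_k$mean <- concs_k$mean * 3
  concs_k$se <- concs_k$se * 3
  b3 <- build_budget(concs_k, mosaic_volumes(), mosaic_cover())
  expect_equal(b3$ice_types$per_area, 3 * b1$ice_types$per_area)
  expect_equal(b3$ice_types$per_coverage_se, 3 * b1$ice_types$per_coverage_se)
  expect_equal(b3$ice_types$percent, b1$ice_types$percent)
})

test_that("carbon-to-chlorophyll ratios record their basis", {
  b <- build_budget(mosaic_concentrations(), printed_volumes(), mosaic_cover())
  pa <- c_to_chla_ratio(b, "per_area")
  expect_equal(unique(pa$basis), "per_area")
  expect_equal(pa$ratio[pa$ice_type == "ridge"], 1574.8 / 25.792,
               tolerance = 1e-6)
  pv <- c_to_chla_ratio(b, "per_volume")
  # per-volume and per-area bases coincide within an ice type
  expect_equal(pv$ratio, pa$ratio, tolerance = 1e-9)
})

test_that("display rounding keeps two significant figures", {
  b <- build_budget(mosaic_concentrations(), mosaic_volumes(), mosaic_cover())
  f <- format_budget(b)
  expect_equal(f$per_area[f$variable == "chla" & f$ice_type == "ridge"], 26)
  expect_equal(f$per_area[f$variable == "poc" & f$ice_type == "ridge"], 1600)
})
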