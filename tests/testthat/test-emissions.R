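p_cal <- bod_params()
cc <- bod_constants()

test_that("population_to_pe applies the 1.23 uplift linearly", {
  expect_equal(population_to_pe(0), 0)
  expect_equal(population_to_pe(1), 1.23)
  expect_equal(population_to_pe(1000), 1230)
  expect_error(population_to_pe(-1), "non-negative")
})

test_that("domestic point emissions follow the rate/loss/efficiency chain", {
  d1000 <- function(col) {
    d <- data.frame(id = "a", pe_untreated = 0, pe_primary = 0,
                    pe_secondary = 0, pe_tertiary = 0)
    d[[col]] <- 1000
    d
  }
  # 1000 PE * 60 g/d * 365.25 d = 21.915 t/y; x0.9 sewer; x(1 - eff)
  expect_equal(domestic_point_emissions(d1000("pe_tertiary"), p_cal, cc),
               0.78894, tolerance = 1e-10)
  expect_equal(domestic_point_emissions(d1000("pe_untreated"), p_cal, cc),
               19.7235, tolerance = 1e-10)
  expect_equal(domestic_point_emissions(d1000("pe_secondary"), p_cal, cc),
               21.915 * 0.9 * 0.06, tolerance = 1e-10)
  d0 <- d1000("pe_tertiary"); d0$pe_tertiary <- 0
  expect_equal(domestic_point_emissions(d0, p_cal, cc), 0)
})

test_that("domestic diffuse emissions treat SD as septic and IAS as primary", {
  d <- data.frame(id = "a", pe_untreated = 0, pe_primary = 0,
                  pe_secondary = 0, pe_tertiary = 0, pe_ias = 0, pe_sd = 100)
  expect_equal(domestic_diffuse_emissions(d, p_cal, cc), 1.3149,
               tolerance = 1e-10)
  d$pe_sd <- 0; d$pe_ias <- 100
  expect_equal(domestic_diffuse_emissions(d, p_cal, cc), 1.09575,
               tolerance = 1e-10)
  d$pe_sd <- 100; d$pe_ias <- 0
  expect_equal(domestic_diffuse_emissions(d, bod_params(eff_sd = 1), cc), 0)
  # sewer-loss re-emission switch adds the 10% of connected load
  d$pe_sd <- 0; d$pe_untreated <- 1000
  expect_equal(domestic_diffuse_emissions(d, p_cal, cc,
                                          reemit_sewer_loss = TRUE),
               21.915 * 0.1, tolerance = 1e-10)
})

test_that("industrial emissions scale TOC by the bod/toc ratio", {
  expect_equal(industrial_emissions(100, p_cal), 75)
  expect_equal(industrial_emissions(0, p_cal), 0)
  expect_equal(industrial_emissions(10, bod_params(bod_toc = 2.2)), 22)
  expect_error(industrial_emissions(-1, p_cal), "non-negative")
})

test_that("livestock intensive/extensive split flips at 25 LU/km2", {
  lv <- function(cattle = 0, pig = 0) {
    data.frame(id = "a", lu_cattle = cattle, lu_sheep_goat = 0,
               lu_pig = pig, lu_chicken = 0)
  }
  # pigs are always intensive: 100 LU -> 14.61 raw, x0.06 after secondary
  r <- livestock_emissions(lv(pig = 100), 1, p_cal, cc)
  expect_equal(r$point, 0.8766, tolerance = 1e-10)
  expect_equal(r$diffuse, 0)
  # 10 cattle LU on 1 km2 (<= 25): extensive, untreated at source
  r <- livestock_emissions(lv(cattle = 10), 1, p_cal, cc)
  expect_equal(r$point, 0)
  expect_equal(r$diffuse, 1.461, tolerance = 1e-10)
  # 30 cattle LU on 1 km2 (> 25): intensive, secondary-treated
  r <- livestock_emissions(lv(cattle = 30), 1, p_cal, cc)
  expect_equal(r$point, 0.26298, tolerance = 1e-10)
  expect_equal(r$diffuse, 0)
  # step is exactly at the threshold (25 is NOT intensive)
  r <- livestock_emissions(lv(cattle = 25), 1, p_cal, cc)
  expect_equal(r$point, 0)
  r <- livestock_emissions(lv(cattle = 25 + 1e-9), 1, p_cal, cc)
  expect_gt(r$point, 0)
  # per-type switch: cattle below, sheep above threshold
  lv2 <- data.frame(id = "a", lu_cattle = 10, lu_sheep_goat = 30,
                    lu_pig = 0, lu_chicken = 0)
  r_comb <- livestock_emissions(lv2, 1, p_cal, cc, combined_density = TRUE)
  r_type <- livestock_emissions(lv2, 1, p_cal, cc, combined_density = FALSE)
  expect_equal(r_comb$diffuse, 0)                   # 40 LU/km2 combined
  expect_equal(r_type$diffuse, 10 * 0.1461, tolerance = 1e-10)
})

test_that("urban wash-off and natural exports are linear export relations", {
  expect_equal(urban_washoff(1, p_cal, cc), 347.1336, tolerance = 1e-10)
  expect_equal(urban_washoff(0, p_cal, cc), 0)
  expect_equal(urban_washoff(1, bod_params(emc_u = 1), cc), 31.5576,
               tolerance = 1e-10)
  expect_equal(natural_emissions(100, p_cal), 16)
  expect_equal(natural_emissions(0, p_cal), 0)
  expect_equal(natural_emissions(10, bod_params(e_nat = 0.5)), 5)
})

test_that("emissions are linear in their drivers and efficiency endpoints hold", {
  d <- data.frame(id = "a", pe_untreated = 11, pe_primary = 22,
                  pe_secondary = 33, pe_tertiary = 44, pe_ias = 5, pe_sd = 6)
  d2 <- d; d2[-1] <- d[-1] * 2
  expect_equal(domestic_point_emissions(d2, p_cal, cc),
               2 * domestic_point_emissions(d, p_cal, cc))
  expect_equal(domestic_diffuse_emissions(d2, p_cal, cc),
               2 * domestic_diffuse_emissions(d, p_cal, cc))

  perfect <- bod_params(eff1 = 1, eff2 = 1, eff3 = 1, eff_sd = 1)
  expect_equal(domestic_point_emissions(
    within(d, pe_untreated <- 0), perfect, cc), 0)
  expect_equal(domestic_diffuse_emissions(d, perfect, cc), 0)

  # zero efficiency and zero sewer loss: emitted equals raw generated load
  none <- bod_params(eff1 = 0, eff2 = 0, eff3 = 0, eff_sd = 0)
  cc0 <- bod_constants(sewer_loss_fraction = 0)
  raw <- sum(d[c("pe_untreated", "pe_primary", "pe_secondary",
                 "pe_tertiary")]) * 60 * 365.25 / 1e6
  expect_equal(domestic_point_emissions(d, none, cc0), raw, tolerance = 1e-12)
})

test_that("allocate_treatment_levels fills best levels by density rank", {
  # denser of two equal populations takes all the tertiary share
  pops <- data.frame(id = c("a", "b"), inhabitants = c(100, 100),
                     area_km2 = c(10, 100))
  sh <- allocate_treatment_levels(pops, c(tertiary = 0.5, primary = 0.5))
  expect_equal(sh$tertiary[sh$id == "a"], 1)
  expect_equal(sh$primary[sh$id == "b"], 1)

  # single subbasin takes the full share
  sh1 <- allocate_treatment_levels(
    data.frame(id = "x", inhabitants = 10, area_km2 = 1), c(tertiary = 1))
  expect_equal(sh1$tertiary, 1)

  # uniform density: everyone gets the national shares (proportional ties)
  pops <- data.frame(id = letters[1:4], inhabitants = rep(50, 4),
                     area_km2 = rep(5, 4))
  shares <- c(tertiary = 0.4, secondary = 0.3, primary = 0.2, none = 0.1)
  sh <- allocate_treatment_levels(pops, shares)
  for (lvl in names(shares))
    expect_equal(sh[[lvl]], rep(shares[[lvl]], 4), tolerance = 1e-12)

  # boundary subbasin split between two levels; PE conserved
  pops <- data.frame(id = c("a", "b", "c"), inhabitants = c(60, 30, 10),
                     area_km2 = c(1, 2, 3))
  sh <- allocate_treatment_levels(pops, c(tertiary = 0.75, secondary = 0.25))
  expect_equal(sh$tertiary, c(1, 0.5, 0))
  expect_equal(sh$secondary, c(0, 0.5, 1))
  alloc <- colSums(sh[c("tertiary", "secondary", "primary", "none")] *
                     pops$inhabitants)
  expect_equal(unname(alloc / sum(pops$inhabitants)),
               c(0.75, 0.25, 0, 0), tolerance = 1e-12)

  expect_error(allocate_treatment_levels(pops, c(tertiary = 0.6)), "sum to 1")
})

test_that("compute_emissions assembles all categories over the network", {
  net <- chain_network(3, area_km2 = c(1, 4, 9), natural_area_km2 = c(1, 2, 3),
                       urban_runoff_m3s = c(0, 0.1, 0))
  demog <- data.frame(id = "n2", pe_untreated = 0, pe_primary = 0,
                      pe_secondary = 0, pe_tertiary = 1000, pe_ias = 0,
                      pe_sd = 100)
  lv <- data.frame(id = "n1", lu_cattle = 10, lu_sheep_goat = 0,
                   lu_pig = 50, lu_chicken = 0)
  ind <- data.frame(id = "n3", toc_t_y = 100)
  em <- compute_emissions(net, demog, lv, ind, p_cal, cc)
  expect_equal(em$domestic_point, c(0, 0.78894, 0), tolerance = 1e-9)
  expect_equal(em$domestic_diffuse, c(0, 1.3149, 0), tolerance = 1e-9)
  expect_equal(em$industrial, c(0, 0, 75))
  expect_equal(em$livestock_intensive[1], 50 * 0.1461 * 0.06,
               tolerance = 1e-9)
  expect_equal(em$livestock_extensive[1], 1.461, tolerance = 1e-9)
  expect_equal(em$urban_washoff, c(0, 34.71336, 0), tolerance = 1e-9)
  expect_equal(em$natural, 0.16 * c(1, 2, 3))
  expect_true(all(as.matrix(em[bod_categories()$all]) >= 0))

  bad <- data.frame(id = "ghost", toc_t_y = 1)
  expect_error(compute_emissions(net, industrial = bad), "unknown subbasin")
})
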