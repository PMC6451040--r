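p_cal <- bod_params()
cc <- bod_constants()

test_that("decay_rate applies the Arrhenius correction around 20 C", {
  expect_identical(decay_rate(0.56, 20), 0.56)
  expect_identical(decay_rate(0.35, 20), 0.35)
  expect_equal(decay_rate(0.56, 10), 0.3538, tolerance = 1e-4)
  expect_equal(decay_rate(0.56, 10), 0.56 / 1.047^10, tolerance = 1e-15)
  expect_error(decay_rate(0, 20), "positive")
})

test_that("attenuate is exponential decay with composition property", {
  expect_equal(attenuate(100, 0.29, 7), 100 * exp(-2.03), tolerance = 1e-12)
  expect_equal(attenuate(100, 0.29, 7), 13.1336, tolerance = 1e-4)
  expect_equal(attenuate(100, 0.49, 7), 100 * exp(-3.43), tolerance = 1e-12)
  expect_equal(attenuate(100, 0.49, 7), 3.2387, tolerance = 1e-4)
  expect_equal(attenuate(42, 0.5, 0), 42)
  # decay composition to 1e-12 relative
  set.seed(1)
  for (i in 1:20) {
    L <- runif(1, 0, 100); k <- runif(1, 0.1, 1)
    t1 <- runif(1, 0, 5); t2 <- runif(1, 0, 5)
    expect_equal(attenuate(attenuate(L, k, t1), k, t2),
                 attenuate(L, k, t1 + t2), tolerance = 1e-12)
  }
})

test_that("basin_attenuation applies pathway-specific delays", {
  net <- chain_network(1, area_km2 = 1, water_temp_C = 20,
                       reach_travel_time_days = 0)
  em <- random_emissions(net)
  p <- bod_params(k20 = 0.35, dd_days = 7, lvst_days = 5)
  dl <- basin_attenuation(em, net, p, cc)
  t_b <- 0.43 / 24
  expect_equal(dl[, "natural"], em$natural * exp(-0.35 * t_b),
               ignore_attr = TRUE)
  expect_equal(dl[, "domestic_diffuse"],
               em$domestic_diffuse * exp(-0.35 * (t_b + 7)),
               ignore_attr = TRUE)
  expect_equal(dl[, "livestock_extensive"],
               em$livestock_extensive * exp(-0.35 * (t_b + 5)),
               ignore_attr = TRUE)
  expect_equal(dl[, "urban_washoff"],
               em$urban_washoff * exp(-0.35 * (t_b + 4 / 24)),
               ignore_attr = TRUE)
  # ~8.6% of a 7-day-delayed diffuse load survives at k_T = 0.35
  expect_equal(unname(dl[, "domestic_diffuse"] / em$domestic_diffuse),
               exp(-0.35 * (7 + t_b)), tolerance = 1e-12)
  expect_equal(unname(dl[, "domestic_diffuse"] / em$domestic_diffuse), 0.086,
               tolerance = 1e-2)
})

test_that("route_network matches hand-computable cases", {
  # single subbasin, point source, no reach decay
  net <- chain_network(1, reach_travel_time_days = 0)
  em <- random_emissions(net); em[bod_categories()$all] <- 0
  em$domestic_point <- 10
  fl <- route_network(net, em, p_cal, cc)
  expect_equal(fl$outflux_t_y, 10)
  # chain of two reaches, each with decay factor 1/2 (k*TT = ln 2)
  net2 <- chain_network(2, water_temp_C = 20,
                        reach_travel_time_days = log(2) / 0.56)
  em2 <- random_emissions(net2); em2[bod_categories()$all] <- 0
  em2$industrial <- c(8, 0)
  fl2 <- route_network(net2, em2, p_cal, cc)
  expect_equal(fl2$outflux_t_y, c(4, 2), tolerance = 1e-12)
  expect_equal(fl2$influx_t_y, c(0, 4), tolerance = 1e-12)
  # all-zero emissions route to all-zero fluxes
  em2$industrial <- 0
  expect_true(all(route_network(net2, em2, p_cal, cc)$outflux_t_y == 0))
  # half-travel-time entry decays local loads less
  net3 <- chain_network(1, reach_travel_time_days = 1)
  em3 <- random_emissions(net3)
  full <- route_network(net3, em3, p_cal, cc, local_entry = "full")
  half <- route_network(net3, em3, p_cal, cc, local_entry = "half")
  expect_gt(half$outflux_t_y, full$outflux_t_y)
})

test_that("routed fluxes respect mass and apportionment invariants", {
  for (seed in 1:5) {
    net <- random_network(30, n_roots = 2, seed = seed)
    em <- random_emissions(net, seed)
    fl <- route_network(net, em, p_cal, cc)
    # decay only removes mass
    local <- fl$local_point_t_y + fl$local_diffuse_t_y
    expect_true(all(fl$outflux_t_y <= fl$influx_t_y + local + 1e-9))
    expect_true(all(as.matrix(fl[sapply(fl, is.numeric)]) >= 0, na.rm = TRUE))
    # per-source columns sum to the total outflux
    src <- unname(rowSums(fl[paste0("src_", bod_categories()$all)]))
    expect_equal(src, fl$outflux_t_y, tolerance = 1e-9)
    # routing one category alone equals its src_ column (linearity)
    em1 <- em; em1[setdiff(bod_categories()$all, "natural")] <- 0
    fl1 <- route_network(net, em1, p_cal, cc)
    expect_equal(fl1$outflux_t_y, fl$src_natural, tolerance = 1e-9)
  }
})

test_that("sea loads are monotone in decay/treatment and in export parameters", {
  net <- random_network(40, n_roots = 2, seed = 99)
  em_at <- function(p) compute_emissions(
    net,
    demographics = data.frame(id = net$subbasins$id, pe_untreated = 50,
                              pe_primary = 100, pe_secondary = 200,
                              pe_tertiary = 400, pe_ias = 30, pe_sd = 30),
    livestock = data.frame(id = net$subbasins$id, lu_cattle = 40,
                           lu_sheep_goat = 10, lu_pig = 20, lu_chicken = 5),
    industrial = data.frame(id = net$subbasins$id[1], toc_t_y = 50),
    params = p)
  total_sea <- function(p) sum(sea_loads(net, route_network(net, em_at(p), p))$total_t_y)
  base <- bod_params(eff1 = 0.5, eff2 = 0.9, eff3 = 0.95, eff_sd = 0.37,
                     dd_days = 6, lvst_days = 6, k20 = 0.5, emc_u = 10,
                     e_nat = 0.3, bod_toc = 1)
  t0 <- total_sea(base)
  bump <- function(name, v) {
    q <- unclass(base); q[[name]] <- v; do.call(bod_params, q)
  }
  for (nm in c("k20", "dd_days", "lvst_days", "eff1", "eff2", "eff3", "eff_sd"))
    expect_lt(total_sea(bump(nm, unclass(base)[[nm]] * 1.05)), t0)
  for (nm in c("emc_u", "e_nat", "bod_toc"))
    expect_gt(total_sea(bump(nm, unclass(base)[[nm]] * 1.05)), t0)
})

test_that("concentration converts loads with the annual-volume factor", {
  expect_equal(concentration(31.5576, 1), 1)
  expect_equal(concentration(347.1336, 1), 11, tolerance = 1e-12)
  expect_equal(concentration(0, 1), 0)
  expect_true(is.na(concentration(10, 0)))   # undefined, not an error
  expect_error(concentration(-1, 1), "non-negative")
})

test_that("sea_loads apportions per outlet and flags coastal catchments", {
  # two outlets: a 2-headwater tree and a lone coastal (Shreve 1) subbasin
  net <- build_network(make_subbasins(
    c("h1", "h2", "out", "coastal"), c("out", "out", "sea", "sea"),
    reach_travel_time_days = 0))
  em <- random_emissions(net); em[bod_categories()$all] <- 0
  em$industrial <- c(1, 2, 4, 8)  # point source: no basin attenuation
  sl <- sea_loads(net, route_network(net, em, p_cal, cc))
  expect_setequal(sl$id, c("out", "coastal"))
  expect_equal(sl$total_t_y[sl$id == "out"], 7)
  expect_false(sl$coastal[sl$id == "out"])
  expect_true(sl$coastal[sl$id == "coastal"])
  expect_equal(unname(attr(sl, "totals")["industrial"]), 15)

  # single-category world: the whole sea load carries that category's tag
  em$industrial <- 0; em$natural <- c(1, 2, 4, 8)
  sl2 <- sea_loads(net, route_network(net, em, p_cal, cc))
  expect_equal(sl2$src_natural, sl2$total_t_y, tolerance = 1e-12)
})
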