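# Fixture builders and independent oracles shared across test files.

# minimal subbasin row set with sensible physical defaults
make_subbasins <- function(id, downstream_id, area_km2 = 5,
                           natural_area_km2 = 0, urban_runoff_m3s = 0,
                           reach_length_km = 0, discharge_m3s = 1,
                           water_temp_C = 20,
                           reach_travel_time_days = NULL,
                           velocity_ms = NULL) {
  df <- data.frame(id = id, downstream_id = downstream_id,
                   area_km2 = area_km2, natural_area_km2 = natural_area_km2,
                   urban_runoff_m3s = urban_runoff_m3s,
                   reach_length_km = reach_length_km,
                   discharge_m3s = discharge_m3s,
                   water_temp_C = water_temp_C, stringsAsFactors = FALSE)
  if (!is.null(reach_travel_time_days))
    df$reach_travel_time_days <- reach_travel_time_days
  if (!is.null(velocity_ms)) df$velocity_ms <- velocity_ms
  df
}

chain_network <- function(n, ...) {
  ids <- paste0("n", seq_len(n))
  build_network(make_subbasins(ids, c(ids[-1], "sea"), ...))
}

# random forest (uniform parent attachment), independent of the package's
# preferential-attachment generator
random_forest_network <- function(n, n_roots = 1, seed = 1,
                                  tt_max_days = 0.5) {
  set.seed(seed)
  ids <- paste0("r", seq_len(n))
  down <- rep(NA_integer_, n)
  if (n > n_roots)
    for (i in (n_roots + 1):n) down[i] <- sample.int(i - 1, 1)
  area <- runif(n, 0.5, 20)
  build_network(make_subbasins(
    ids, ifelse(is.na(down), "sea", ids[down]),
    area_km2 = area,
    natural_area_km2 = runif(n, 0, 0.5) * area,
    urban_runoff_m3s = runif(n, 0, 0.05),
    reach_length_km = runif(n, 0, 10),
    discharge_m3s = runif(n, 0.05, 5),
    water_temp_C = runif(n, 5, 25),
    reach_travel_time_days = runif(n, 0, tt_max_days)))
}

random_network <- random_forest_network

random_emissions <- function(net, seed = 1) {
  set.seed(seed)
  n <- nrow(net$subbasins)
  em <- data.frame(id = net$subbasins$id, stringsAsFactors = FALSE)
  for (cat in bod_categories()$all) em[[cat]] <- runif(n, 0, 50)
  structure(em, class = c("bod_emissions", "data.frame"))
}

# Brute-force path-product oracle: outlet loads computed by enumerating,
# for every (subbasin, category), the product of decay factors along its
# path to the outlet. Deliberately re-derives basin attenuation and reach
# decay with plain arithmetic, independent of route_network().
oracle_outlet_loads <- function(net, em, p = bod_params(),
                                cc = bod_constants()) {
  sb <- net$subbasins
  n <- nrow(sb)
  k_t <- p$k20 * 1.047^(sb$water_temp_C - 20)
  t_b <- (0.43 * sb$area_km2^0.418) / 24
  tt_r <- sb$reach_travel_time_days
  delay <- c(domestic_diffuse = p$dd_days, livestock_extensive = p$lvst_days,
             urban_washoff = cc$sewer_time_days, natural = 0)
  delivered <- sapply(bod_categories()$all, function(cat) {
    v <- em[[cat]]
    if (cat %in% names(delay)) v * exp(-k_t * (t_b + delay[[cat]])) else v
  })
  delivered <- matrix(delivered, nrow = n)
  outlet_of <- integer(n)
  path_factor <- numeric(n)
  for (i in seq_len(n)) {
    f <- 1
    j <- i
    repeat {
      f <- f * exp(-k_t[j] * tt_r[j])
      d <- net$down[j]
      if (is.na(d)) break
      j <- d
    }
    outlet_of[i] <- j
    path_factor[i] <- f
  }
  totals <- numeric(n)
  for (i in seq_len(n))
    totals[outlet_of[i]] <- totals[outlet_of[i]] + sum(delivered[i, ]) * path_factor[i]
  stats::setNames(totals[match(net$outlets, sb$id)], net$outlets)
}
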