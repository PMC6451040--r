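#' Temperature-corrected decay rate
#'
#' First-order BOD degradation rate adjusted from its 20 degree C reference
#' with the Arrhenius-type relation `k_T = k20 * 1.047^(T - 20)`.
#'
#' @param k20 Decay rate at 20 C (1/day, > 0).
#' @param temp_C Water temperature (degrees C, vectorised).
#' @return Decay rate(s), 1/day.
#' @export
#' @examples
#' decay_rate(0.56, 20)  # exactly 0.56
#' decay_rate(0.56, 10)  # ~0.354
decay_rate <- function(k20, temp_C) {
  if (any(k20 <= 0)) stop("'k20' must be positive")
  k20 * 1.047^(temp_C - 20)
}

#' Exponential decay over a travel time
#'
#' `load * exp(-k * tt)`: the surviving fraction of a BOD load after
#' first-order decay over `tt` days at rate `k` per day.
#'
#' @param load_t_y Load (t/y, >= 0, vectorised).
#' @param k_per_day Decay rate (1/day).
#' @param tt_days Travel time (days, >= 0).
#' @return Surviving load, t/y.
#' @export
attenuate <- function(load_t_y, k_per_day, tt_days) {
  if (any(load_t_y < 0) || any(tt_days < 0) || any(k_per_day < 0))
    stop("'load_t_y', 'k_per_day' and 'tt_days' must be non-negative")
  load_t_y * exp(-k_per_day * tt_days)
}

# per-subbasin basin travel time (days) per diffuse category
.pathway_tt <- function(net, params, constants) {
  t_b <- basin_time_lag(net$subbasins$area_km2, as_days = TRUE)
  cbind(domestic_diffuse    = t_b + params$dd_days,
        livestock_extensive = t_b + params$lvst_days,
        urban_washoff       = t_b + constants$sewer_time_days,
        natural             = t_b)
}

#' Basin attenuation of diffuse emissions
#'
#' Diffuse sources are degraded within the subbasin before they reach the
#' main reach. Each category travels its own pathway: disconnected domestic
#' waste takes the basin lag plus `dd_days`, extensive livestock waste the
#' lag plus `lvst_days`, urban wash-off the lag plus 4 h of sewer time, and
#' natural-area load the lag alone. Decay uses the subbasin's
#' temperature-corrected rate.
#'
#' @param emissions A [compute_emissions()] object (or data frame with the
#'   diffuse category columns).
#' @param net The [build_network()] the emissions belong to.
#' @param params,constants Model parameters and constants.
#' @return Matrix (subbasins x diffuse categories) of loads delivered to
#'   the reach head, t/y.
#' @export
basin_attenuation <- function(emissions, net, params = bod_params(),
                              constants = bod_constants()) {
  stopifnot(inherits(net, "bod_network"))
  missing_cols <- setdiff(diffuse_categories, names(emissions))
  if (length(missing_cols))
    stop("emissions lack diffuse categories: ",
         paste(missing_cols, collapse = ", "))
  if (!identical(as.character(emissions$id), net$subbasins$id))
    stop("emission ids do not match the network")
  k_t <- decay_rate(params$k20, net$subbasins$water_temp_C)
  tt <- .pathway_tt(net, params, constants)
  out <- sapply(diffuse_categories, function(cat)
    attenuate(emissions[[cat]], k_t, tt[, cat]))
  matrix(out, nrow = nrow(net$subbasins),
         dimnames = list(net$subbasins$id, diffuse_categories))
}

#' Route emissions through the river network
#'
#' Processes subbasins in topological order. The load at the head of each
#' reach is the sum of upstream outfluxes, local point emissions, and
#' basin-attenuated local diffuse deliveries; the outflux is that load
#' decayed over the reach travel time at the subbasin's temperature-corrected
#' rate. Source categories are routed independently (the model is linear in
#' its loads), so the per-source columns sum exactly to the totals.
#'
#' @param net A [build_network()] object.
#' @param emissions A [compute_emissions()] object over the same ids.
#' @param params,constants Model parameters and constants.
#' @param velocity_model Optional velocity model for [reach_travel_time()].
#' @param local_entry Either `"full"` (default; local loads enter at the
#'   reach head and decay over the full reach travel time) or `"half"`
#'   (local loads decay over half the travel time).
#' @return An object of class `bod_fluxes`: a data frame with columns `id`,
#'   `influx_t_y`, `local_point_t_y`, `local_diffuse_t_y`, `outflux_t_y`,
#'   `concentration_mg_l` (`NA` where discharge is zero) and one `src_*`
#'   column per category.
#' @export
route_network <- function(net, emissions, params = bod_params(),
                          constants = bod_constants(),
                          velocity_model = NULL,
                          local_entry = c("full", "half")) {
  stopifnot(inherits(net, "bod_network"))
  local_entry <- match.arg(local_entry)
  if (!identical(as.character(emissions$id), net$subbasins$id))
    stop("emission ids do not match the network")
  sb <- net$subbasins
  n <- nrow(sb)
  k_t <- decay_rate(params$k20, sb$water_temp_C)
  tt_r <- reach_travel_time(net, velocity_model)
  reach_fac <- exp(-k_t * tt_r)
  local_fac <- if (local_entry == "half") exp(-k_t * tt_r / 2) else reach_fac

  delivered <- basin_attenuation(emissions, net, params, constants)
  local <- cbind(as.matrix(as.data.frame(emissions)[point_categories]),
                 delivered)[, all_categories, drop = FALSE]

  influx <- matrix(0, n, length(all_categories),
                   dimnames = list(NULL, all_categories))
  outflux <- influx
  for (i in net$order) {
    outflux[i, ] <- influx[i, ] * reach_fac[i] + local[i, ] * local_fac[i]
    d <- net$down[i]
    if (!is.na(d)) influx[d, ] <- influx[d, ] + outflux[i, ]
  }
  out_total <- rowSums(outflux)
  fl <- data.frame(
    id = sb$id,
    influx_t_y = rowSums(influx),
    local_point_t_y = rowSums(local[, point_categories, drop = FALSE]),
    local_diffuse_t_y = rowSums(delivered),
    outflux_t_y = out_total,
    concentration_mg_l = concentration(out_total, sb$discharge_m3s, constants),
    stringsAsFactors = FALSE
  )
  for (cat in all_categories) fl[[paste0("src_", cat)]] <- outflux[, cat]
  structure(fl, class = c("bod_fluxes", "data.frame"))
}

#' Load-to-concentration conversion
#'
#' Mean annual concentration implied by an annual load and a mean annual
#' discharge: `C = load / (31.5576 * Q)` with the factor converting
#' mg/L * m3/s to t/y over a 365.25-day year. Zero or negative discharge
#' yields `NA` (undefined concentration; water-scarce reaches exist) rather
#' than an error.
#'
#' @param load_t_y Load (t/y, >= 0).
#' @param discharge_m3s Mean annual discharge (m3/s).
#' @param constants A [bod_constants()] object.
#' @return Concentration, mg O2/L (`NA` where discharge <= 0).
#' @export
concentration <- function(load_t_y, discharge_m3s,
                          constants = bod_constants()) {
  if (any(load_t_y < 0)) stop("'load_t_y' must be non-negative")
  ifelse(discharge_m3s > 0,
         load_t_y / (constants$t_y_per_mgl_m3s * discharge_m3s),
         NA_real_)
}

#' Loads delivered to the sea
#'
#' Totals the outflux of every sea outlet, apportioned by source category,
#' and flags coastal catchments (outlets of Shreve order 1, which discharge
#' to the sea without joining a larger river).
#'
#' @param net A [build_network()] object.
#' @param fluxes The matching [route_network()] result.
#' @return An object of class `bod_sea_loads`: data frame with one row per
#'   outlet (`id`, `total_t_y`, `coastal`, one `src_*` column per category)
#'   and attribute `totals`, the network-wide per-source sums.
#' @export
sea_loads <- function(net, fluxes) {
  stopifnot(inherits(net, "bod_network"))
  idx <- match(net$outlets, fluxes$id)
  if (anyNA(idx)) stop("fluxes do not cover all outlets")
  shreve <- shreve_order(net)
  src_cols <- paste0("src_", all_categories)
  rep <- data.frame(id = net$outlets,
                    total_t_y = fluxes$outflux_t_y[idx],
                    coastal = unname(shreve[net$outlets] == 1L),
                    stringsAsFactors = FALSE)
  rep[src_cols] <- as.data.frame(fluxes)[idx, src_cols]
  totals <- colSums(rep[, src_cols, drop = FALSE])
  structure(rep, class = c("bod_sea_loads", "data.frame"),
            totals = stats::setNames(as.numeric(totals), all_categories))
}
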