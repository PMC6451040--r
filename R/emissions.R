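#' Convert inhabitants to person equivalents
#'
#' Person equivalents (PE) measure generated waste load; across reporting
#' countries 1 inhabitant generates about 1.23 PE, the excess reflecting
#' commercial, industrial and touristic discharges into sewers.
#'
#' @param inhabitants Resident population (vectorised, >= 0).
#' @param constants A [bod_constants()] object.
#' @return PE, same length as `inhabitants`.
#' @export
population_to_pe <- function(inhabitants, constants = bod_constants()) {
  if (any(inhabitants < 0)) stop("'inhabitants' must be non-negative")
  constants$pe_per_inhabitant * inhabitants
}

#' Allocate national treatment-level shares across subbasins
#'
#' Distributes national shares of population per treatment level spatially,
#' assuming the most densely populated subbasins benefit of the best
#' treatments: subbasins are ranked by population density (descending) and
#' the best levels are filled greedily down the ranking until each national
#' share is exhausted. A subbasin straddling a share boundary is split
#' between the two levels; subbasins tied on density share their level mix
#' proportionally to population.
#'
#' @param populations Data frame with columns `id`, `inhabitants`,
#'   `area_km2`.
#' @param national_shares Named numeric vector over
#'   `c("tertiary", "secondary", "primary", "none")` (any subset), summing
#'   to 1.
#' @return Data frame `id`, `tertiary`, `secondary`, `primary`, `none`:
#'   the fraction of each subbasin's population served at each level
#'   (rows sum to 1).
#' @export
allocate_treatment_levels <- function(populations, national_shares) {
  levels_best_first <- c("tertiary", "secondary", "primary", "none")
  unknown <- setdiff(names(national_shares), levels_best_first)
  if (length(unknown))
    stop("unknown treatment level(s): ", paste(unknown, collapse = ", "))
  shares <- stats::setNames(numeric(4L), levels_best_first)
  shares[names(national_shares)] <- national_shares
  if (abs(sum(shares) - 1) > 1e-9)
    stop("national shares must sum to 1")

  df <- populations[order(-populations$inhabitants / populations$area_km2,
                          populations$id), , drop = FALSE]
  pop <- df$inhabitants
  total <- sum(pop)
  out <- matrix(0, nrow(df), 4L, dimnames = list(NULL, levels_best_first))
  if (total <= 0) {
    out[] <- rep(shares, each = nrow(df))
  } else {
    dens <- df$inhabitants / df$area_km2
    grp <- cumsum(!duplicated(signif(dens, 12)))  # tie groups on density
    bounds <- cumsum(shares) * total              # level upper bounds (pop)
    lower <- c(0, bounds[-4L])
    cum_end <- cumsum(rowsum(pop, grp)[, 1L])
    cum_start <- c(0, cum_end[-length(cum_end)])
    for (g in seq_along(cum_end)) {
      members <- which(grp == g)
      gpop <- sum(pop[members])
      if (gpop <= 0) next
      # overlap of this tie-group's population span with each level band
      ov <- pmax(0, pmin(cum_end[g], bounds) - pmax(cum_start[g], lower))
      frac <- ov / gpop
      out[members, ] <- matrix(frac, length(members), 4L, byrow = TRUE)
    }
  }
  res <- data.frame(id = df$id, out, stringsAsFactors = FALSE)
  res[match(populations$id, res$id), , drop = FALSE]
}

# shared rate: t/y generated by one PE (or LU with its own g/day rate)
.raw_rate_t_y <- function(n_units, g_per_day, constants) {
  n_units * g_per_day * constants$year_days / 1e6
}

#' Domestic point-source emissions
#'
#' BOD emitted to reaches by sewer-connected population. The generated load
#' (60 g BOD/PE/day) is reduced by sewerage losses (10%, removed from the
#' system by default) and then by the treatment efficiency of the level
#' serving each PE cohort (none/primary/secondary/tertiary).
#'
#' @param demographics Data frame with columns `id`, `pe_untreated`,
#'   `pe_primary`, `pe_secondary`, `pe_tertiary` (PE per cohort) and, for
#'   [domestic_diffuse_emissions()], `pe_ias`, `pe_sd`.
#' @param params A [bod_params()] object.
#' @param constants A [bod_constants()] object.
#' @param reemit_sewer_loss If `TRUE`, the 10% sewerage loss is re-emitted
#'   untreated as diffuse domestic load instead of being removed; see
#'   [domestic_diffuse_emissions()].
#' @return Numeric vector, t/y per subbasin (ordered as `demographics`).
#' @export
domestic_point_emissions <- function(demographics, params = bod_params(),
                                     constants = bod_constants()) {
  need <- c("pe_untreated", "pe_primary", "pe_secondary", "pe_tertiary")
  missing_cols <- setdiff(need, names(demographics))
  if (length(missing_cols))
    stop("demographics table is missing: ", paste(missing_cols, collapse = ", "))
  eff <- c(pe_untreated = 0, pe_primary = params$eff1,
           pe_secondary = params$eff2, pe_tertiary = params$eff3)
  delivered <- 1 - constants$sewer_loss_fraction
  load <- 0
  for (col in need) {
    if (any(demographics[[col]] < 0)) stop("PE must be non-negative")
    raw <- .raw_rate_t_y(demographics[[col]], constants$bod_per_pe_g_day,
                         constants)
    load <- load + raw * delivered * (1 - eff[[col]])
  }
  load
}

#' Domestic diffuse emissions
#'
#' BOD released to the subbasin by disconnected population: scattered
#' dwellings (septic tanks, efficiency `eff_sd`) and Individual Appropriate
#' Systems (equivalent to primary treatment, `eff1`). No sewerage loss is
#' applied (these dwellings are not connected). The load travels on the
#' slow disconnected-domestic pathway (basin lag + `dd_days`).
#'
#' @inheritParams domestic_point_emissions
#' @return Numeric vector, t/y per subbasin.
#' @export
domestic_diffuse_emissions <- function(demographics, params = bod_params(),
                                       constants = bod_constants(),
                                       reemit_sewer_loss = FALSE) {
  missing_cols <- setdiff(c("pe_ias", "pe_sd"), names(demographics))
  if (length(missing_cols))
    stop("demographics table is missing: ", paste(missing_cols, collapse = ", "))
  if (any(demographics$pe_ias < 0) || any(demographics$pe_sd < 0))
    stop("PE must be non-negative")
  rate <- function(pe) .raw_rate_t_y(pe, constants$bod_per_pe_g_day, constants)
  load <- rate(demographics$pe_sd) * (1 - params$eff_sd) +
    rate(demographics$pe_ias) * (1 - params$eff1)
  if (reemit_sewer_loss) {
    connected <- demographics$pe_untreated + demographics$pe_primary +
      demographics$pe_secondary + demographics$pe_tertiary
    load <- load + rate(connected) * constants$sewer_loss_fraction
  }
  load
}

#' Industrial point-source emissions
#'
#' Large facilities report total organic carbon (TOC) releases; BOD is
#' obtained through the calibrated effective BOD/TOC ratio and discharged
#' directly to the hosting subbasin's reach.
#'
#' @param toc_t_y TOC emissions per subbasin (t/y, vectorised, >= 0).
#' @param params A [bod_params()] object.
#' @return BOD load, t/y.
#' @export
industrial_emissions <- function(toc_t_y, params = bod_params()) {
  if (any(toc_t_y < 0)) stop("'toc_t_y' must be non-negative")
  toc_t_y * params$bod_toc
}

#' Livestock emissions
#'
#' Livestock units (LU) emit 400 g BOD/LU/day. Pig and chicken production is
#' always intensive; cattle and sheep/goats are intensive where their
#' combined density exceeds 25 LU/km2 (set `combined_density = FALSE` to
#' apply the threshold per type). Intensive waste is treated at secondary
#' level and enters the reach as a point source; extensive waste is diffuse
#' and is attenuated on the livestock pathway (basin lag + `lvst_days`).
#'
#' @param livestock Data frame with columns `id`, `lu_cattle`,
#'   `lu_sheep_goat`, `lu_pig`, `lu_chicken`.
#' @param area_km2 Subbasin areas aligned with `livestock` rows.
#' @param params A [bod_params()] object.
#' @param constants A [bod_constants()] object.
#' @param combined_density Apply the 25 LU/km2 threshold to the combined
#'   ruminant density (default) rather than per type.
#' @return List with numeric vectors `point` (intensive, treated) and
#'   `diffuse` (extensive, untreated at source), t/y per subbasin.
#' @export
livestock_emissions <- function(livestock, area_km2, params = bod_params(),
                                constants = bod_constants(),
                                combined_density = TRUE) {
  need <- c("lu_cattle", "lu_sheep_goat", "lu_pig", "lu_chicken")
  missing_cols <- setdiff(need, names(livestock))
  if (length(missing_cols))
    stop("livestock table is missing: ", paste(missing_cols, collapse = ", "))
  if (any(as.matrix(livestock[need]) < 0)) stop("LU must be non-negative")
  if (any(area_km2 <= 0)) stop("'area_km2' must be positive")
  thr <- constants$intensive_threshold_lu_km2
  if (combined_density) {
    rum <- livestock$lu_cattle + livestock$lu_sheep_goat
    intensive_rum <- ifelse(rum / area_km2 > thr, rum, 0)
    extensive_rum <- rum - intensive_rum
  } else {
    int_c <- ifelse(livestock$lu_cattle / area_km2 > thr, livestock$lu_cattle, 0)
    int_s <- ifelse(livestock$lu_sheep_goat / area_km2 > thr,
                    livestock$lu_sheep_goat, 0)
    intensive_rum <- int_c + int_s
    extensive_rum <- livestock$lu_cattle + livestock$lu_sheep_goat - intensive_rum
  }
  intensive_lu <- intensive_rum + livestock$lu_pig + livestock$lu_chicken
  rate <- function(lu) .raw_rate_t_y(lu, constants$bod_per_lu_g_day, constants)
  list(point = rate(intensive_lu) * (1 - params$eff2),
       diffuse = rate(extensive_rum))
}

#' Urban wash-off emissions
#'
#' Combined-sewer overflow load from urban land, proportional to the mean
#' annual urban runoff volume: `BOD_U = EMC_U * R_U * 3600 * 24 * 365.25 /
#' 1e6` (t/y). The load spends the basin lag plus 4 hours of sewer time
#' before reaching the reach.
#'
#' @param urban_runoff_m3s Mean annual urban runoff (m3/s, vectorised).
#' @param params A [bod_params()] object.
#' @param constants A [bod_constants()] object.
#' @return BOD load, t/y.
#' @export
urban_washoff <- function(urban_runoff_m3s, params = bod_params(),
                          constants = bod_constants()) {
  if (any(urban_runoff_m3s < 0)) stop("'urban_runoff_m3s' must be >= 0")
  params$emc_u * urban_runoff_m3s * constants$t_y_per_mgl_m3s
}

#' Natural-area emissions
#'
#' Export-coefficient load of organic matter washed off forests, other
#' natural land and lakes: `BOD_NAT = E_NAT * Area_NAT`. Transport is by
#' surface flow, so only the basin time lag applies (no extra delay).
#'
#' @param natural_area_km2 Natural area per subbasin (km2, vectorised).
#' @param params A [bod_params()] object.
#' @return BOD load, t/y.
#' @export
natural_emissions <- function(natural_area_km2, params = bod_params()) {
  if (any(natural_area_km2 < 0)) stop("'natural_area_km2' must be >= 0")
  params$e_nat * natural_area_km2
}

#' Assemble the full emission set of a network
#'
#' Computes all seven source categories for every subbasin and tags each
#' with its delivery pathway. Point categories (`domestic_point`,
#' `industrial`, `livestock_intensive`) enter the reach directly; diffuse
#' categories (`domestic_diffuse`, `livestock_extensive`, `urban_washoff`,
#' `natural`) are later attenuated over pathway-specific basin travel times
#' by [basin_attenuation()].
#'
#' @param net A [build_network()] object.
#' @param demographics Data frame as for [domestic_point_emissions()];
#'   subbasins absent from the table get zero domestic load.
#' @param livestock Data frame as for [livestock_emissions()]; optional.
#' @param industrial Data frame with columns `id`, `toc_t_y`; optional.
#' @param params,constants Model parameters and constants.
#' @param reemit_sewer_loss Passed to [domestic_diffuse_emissions()].
#' @param combined_density Passed to [livestock_emissions()].
#' @return An object of class `bod_emissions`: a data frame with column
#'   `id` plus one column per category (t/y).
#' @export
compute_emissions <- function(net, demographics = NULL, livestock = NULL,
                              industrial = NULL, params = bod_params(),
                              constants = bod_constants(),
                              reemit_sewer_loss = FALSE,
                              combined_density = TRUE) {
  stopifnot(inherits(net, "bod_network"))
  sb <- net$subbasins
  n <- nrow(sb)
  em <- data.frame(id = sb$id, stringsAsFactors = FALSE)
  for (cat in all_categories) em[[cat]] <- numeric(n)

  expand <- function(tbl, fun) {
    # map a per-id table onto network rows, zero where absent
    idx <- match(tbl$id, sb$id)
    if (anyNA(idx))
      stop("emission input references unknown subbasin id(s): ",
           paste(utils::head(tbl$id[is.na(idx)], 3L), collapse = ", "))
    v <- numeric(n)
    v[idx] <- fun(tbl, idx)
    v
  }
  if (!is.null(demographics)) {
    em$domestic_point <- expand(demographics, function(t, i)
      domestic_point_emissions(t, params, constants))
    em$domestic_diffuse <- expand(demographics, function(t, i)
      domestic_diffuse_emissions(t, params, constants, reemit_sewer_loss))
  }
  if (!is.null(industrial))
    em$industrial <- expand(industrial, function(t, i)
      industrial_emissions(t$toc_t_y, params))
  if (!is.null(livestock)) {
    idx <- match(livestock$id, sb$id)
    lv <- livestock_emissions(livestock, sb$area_km2[idx], params, constants,
                              combined_density)
    em$livestock_intensive[idx] <- lv$point
    em$livestock_extensive[idx] <- lv$diffuse
  }
  em$urban_washoff <- urban_washoff(sb$urban_runoff_m3s, params, constants)
  em$natural <- natural_emissions(sb$natural_area_km2, params)
  structure(em, class = c("bod_emissions", "data.frame"))
}
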