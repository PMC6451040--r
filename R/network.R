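#' Build a river network from a subbasin table
#'
#' Validates a semi-distributed network description (one main reach per
#' subbasin, each draining to at most one downstream subbasin) and caches a
#' topological order (headwaters first) plus Shreve magnitudes. Sea outlets
#' are marked by a reserved sentinel in `downstream_id`: the string `"sea"`,
#' an empty string, or `NA`.
#'
#' @param subbasins Data frame with one row per subbasin and columns `id`,
#'   `downstream_id`, `area_km2`, `natural_area_km2`, `urban_runoff_m3s`,
#'   `reach_length_km`, `discharge_m3s`, `water_temp_C` and optionally
#'   `reach_travel_time_days` and/or `velocity_ms`.
#' @return An object of class `bod_network`: a list with elements
#'   `subbasins` (the validated table, ids as character), `down` (integer
#'   index of the downstream subbasin, `NA` at outlets), `order` (row
#'   indices in topological order) and `outlets` (character ids).
#' @export
#' @examples
#' net <- build_network(data.frame(
#'   id = c("a", "b", "c"), downstream_id = c("b", "c", "sea"),
#'   area_km2 = c(5, 7, 9), natural_area_km2 = c(4, 3, 2),
#'   urban_runoff_m3s = 0, reach_length_km = c(2, 3, 4),
#'   discharge_m3s = c(0.1, 0.25, 0.4), water_temp_C = 12,
#'   velocity_ms = 0.8))
#' net$outlets
build_network <- function(subbasins) {
  required <- c("id", "downstream_id", "area_km2", "natural_area_km2",
                "urban_runoff_m3s", "reach_length_km", "discharge_m3s",
                "water_temp_C")
  missing_cols <- setdiff(required, names(subbasins))
  if (length(missing_cols))
    stop("subbasin table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  sb <- as.data.frame(subbasins, stringsAsFactors = FALSE)
  sb$id <- as.character(sb$id)
  sb$downstream_id <- as.character(sb$downstream_id)
  if (anyDuplicated(sb$id))
    stop("duplicated subbasin ids: ",
         paste(unique(sb$id[duplicated(sb$id)]), collapse = ", "))
  if (any(!is.finite(sb$area_km2)) || any(sb$area_km2 <= 0))
    stop("'area_km2' must be positive")
  if (any(sb$natural_area_km2 < 0) || any(sb$natural_area_km2 > sb$area_km2))
    stop("'natural_area_km2' must lie in [0, area_km2]")
  if (any(sb$discharge_m3s < 0)) stop("'discharge_m3s' must be >= 0")
  if (any(sb$reach_length_km < 0)) stop("'reach_length_km' must be >= 0")
  if (any(sb$urban_runoff_m3s < 0)) stop("'urban_runoff_m3s' must be >= 0")

  is_outlet <- is.na(sb$downstream_id) | sb$downstream_id %in% c("", "sea")
  down <- rep(NA_integer_, nrow(sb))
  down[!is_outlet] <- match(sb$downstream_id[!is_outlet], sb$id)
  if (anyNA(down[!is_outlet])) {
    bad <- sb$downstream_id[!is_outlet][is.na(down[!is_outlet])]
    stop("dangling downstream_id reference: ", paste(unique(bad), collapse = ", "))
  }
  if (any(which(!is_outlet) == down[!is_outlet]))
    stop("topology error: subbasin drains into itself: ",
         sb$id[which(!is_outlet)[which(!is_outlet) == down[!is_outlet]][1L]])

  # Kahn's algorithm on the downstream DAG; leftover nodes indicate a cycle
  n <- nrow(sb)
  indeg <- tabulate(down[!is.na(down)], nbins = n)
  queue <- which(indeg == 0L)
  ord <- integer(n)
  k <- 0L
  while (length(queue)) {
    # deterministic order: smallest row index first
    i <- queue[1L]
    queue <- queue[-1L]
    k <- k + 1L
    ord[k] <- i
    d <- down[i]
    if (!is.na(d)) {
      indeg[d] <- indeg[d] - 1L
      if (indeg[d] == 0L) queue <- c(queue, d)
    }
  }
  if (k < n) {
    in_cycle <- setdiff(seq_len(n), ord[seq_len(k)])
    stop("topology error: cycle detected involving subbasin '",
         sb$id[in_cycle[1L]], "'")
  }
  structure(list(subbasins = sb, down = down, order = ord,
                 outlets = sb$id[is_outlet]),
            class = "bod_network")
}

#' @export
print.bod_network <- function(x, ...) {
  cat(sprintf("BOD river network: %d subbasins, %d outlet(s)\n",
              nrow(x$subbasins), length(x$outlets)))
  cat(sprintf("  total area %.1f km2, total reach length %.1f km\n",
              sum(x$subbasins$area_km2), sum(x$subbasins$reach_length_km)))
  invisible(x)
}

#' Shreve magnitude of every subbasin
#'
#' The Shreve order (magnitude) of a reach is the number of headwater
#' sources upstream of it: headwaters get 1, every confluence the sum of
#' its upstream magnitudes. Order-1 outlets identify coastal catchments
#' that discharge to the sea without joining a larger river.
#'
#' @param net A [build_network()] object.
#' @return Named integer vector of magnitudes, one per subbasin id.
#' @export
shreve_order <- function(net) {
  stopifnot(inherits(net, "bod_network"))
  n <- nrow(net$subbasins)
  shreve <- integer(n)
  has_upstream <- tabulate(net$down[!is.na(net$down)], nbins = n) > 0L
  for (i in net$order) {
    if (!has_upstream[i] && shreve[i] == 0L) shreve[i] <- 1L
    d <- net$down[i]
    if (!is.na(d)) shreve[d] <- shreve[d] + shreve[i]
  }
  stats::setNames(shreve, net$subbasins$id)
}

#' Subbasin time lag
#'
#' Empirical power-law time lag of a subbasin as a function of its drainage
#' area: `T_B = 0.43 * A^0.418` hours. This is the surface-flow travel time
#' within the subbasin; pathway delays for slower routes (interflow,
#' soil storage, sewers) are added on top during basin attenuation.
#'
#' @param area_km2 Drainage area (km2), vectorised.
#' @param as_days Return days instead of hours (default `FALSE`).
#' @return Time lag in hours (or days).
#' @export
#' @examples
#' basin_time_lag(7)                 # ~0.97 h
#' basin_time_lag(7, as_days = TRUE) # ~0.040 d
basin_time_lag <- function(area_km2, as_days = FALSE) {
  if (any(!is.finite(area_km2)) || any(area_km2 <= 0))
    stop("'area_km2' must be positive")
  lag_h <- 0.43 * area_km2^0.418
  if (as_days) lag_h / 24 else lag_h
}

#' Reach travel time
#'
#' Travel time (days) of water in each subbasin's main reach. A precomputed
#' `reach_travel_time_days` column always wins; otherwise the time is reach
#' length divided by velocity, with velocity taken per subbasin
#' (`velocity_ms`) or from a power-law velocity model `v = a * Q^b`.
#' The velocity-model defaults (`a = 0.3`, `b = 0.2`) are generic
#' literature-style hydraulic geometry coefficients, not fitted values, and
#' should be overridden when site-specific hydraulics are known.
#'
#' @param net A [build_network()] object (or a subbasin data frame with the
#'   relevant columns).
#' @param velocity_model Optional list `list(a = , b = )` giving the
#'   power-law coefficients; used only where no precomputed travel time and
#'   no per-subbasin velocity is available.
#' @return Numeric vector of travel times (days), one per subbasin.
#' @export
reach_travel_time <- function(net, velocity_model = NULL) {
  sb <- if (inherits(net, "bod_network")) net$subbasins else net
  n <- nrow(sb)
  tt <- rep(NA_real_, n)
  if (!is.null(sb$reach_travel_time_days))
    tt <- as.numeric(sb$reach_travel_time_days)
  need <- is.na(tt)
  if (any(need)) {
    v <- rep(NA_real_, n)
    if (!is.null(sb$velocity_ms)) v <- as.numeric(sb$velocity_ms)
    no_v <- need & (is.na(v) | v <= 0)
    if (any(no_v)) {
      if (is.null(velocity_model))
        stop("no precomputed travel time and no velocity for subbasin(s) ",
             paste(utils::head(sb$id[no_v], 3L), collapse = ", "),
             "; supply 'velocity_model = list(a =, b =)'")
      q <- sb$discharge_m3s[no_v]
      if (any(q <= 0))
        stop("velocity model requires positive discharge")
      v[no_v] <- velocity_model$a * q^velocity_model$b
    }
    tt[need] <- ifelse(sb$reach_length_km[need] == 0, 0,
                       sb$reach_length_km[need] * 1000 / v[need] / 86400)
  }
  if (any(tt < 0)) stop("negative reach travel time")
  tt
}

#' Read a subbasin table from CSV
#'
#' @param path CSV file with the [build_network()] columns; an empty
#'   `downstream_id` marks a sea outlet.
#' @return A `bod_network` object.
#' @export
read_subbasins <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  build_network(df)
}
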