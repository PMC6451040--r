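#' Model parameter set
#'
#' Bundle of the ten calibratable parameters of the BOD model. Defaults are
#' the calibrated values obtained at European scale; see [param_ranges()] for
#' the literature-based sampling ranges used in calibration.
#'
#' @param eff1 BOD removal efficiency of primary treatment, fraction in
#'   \[0, 1\].
#' @param eff2 Efficiency of secondary treatment; also applied to waste from
#'   intensive (high-density) livestock systems.
#' @param eff3 Efficiency of tertiary treatment.
#' @param eff_sd Efficiency of septic tanks serving scattered dwellings.
#' @param dd_days Extra travel time (days) of disconnected-domestic waste in
#'   excess of the basin time lag (groundwater/interflow pathway).
#' @param lvst_days Extra travel time (days) of extensive-livestock waste in
#'   excess of the basin time lag.
#' @param k20 First-order BOD decay rate at 20 degrees C (1/day).
#' @param emc_u Effective mean BOD concentration of urban wash-off
#'   (mg O2/L).
#' @param e_nat BOD export coefficient of natural areas (t/km2/y).
#' @param bod_toc BOD/TOC ratio of industrial effluents (dimensionless).
#' @return An object of class `bod_params` (named list).
#' @seealso [param_ranges()], [bod_constants()]
#' @export
#' @examples
#' p <- bod_params()          # calibrated defaults
#' p$k20
#' bod_params(k20 = 0.35)     # override a single parameter
bod_params <- function(eff1 = 0.50, eff2 = 0.94, eff3 = 0.96, eff_sd = 0.40,
                       dd_days = 7, lvst_days = 7, k20 = 0.56, emc_u = 11,
                       e_nat = 0.16, bod_toc = 0.75) {
  p <- list(eff1 = eff1, eff2 = eff2, eff3 = eff3, eff_sd = eff_sd,
            dd_days = dd_days, lvst_days = lvst_days, k20 = k20,
            emc_u = emc_u, e_nat = e_nat, bod_toc = bod_toc)
  for (nm in c("eff1", "eff2", "eff3", "eff_sd")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a single fraction in [0, 1]", nm))
  }
  if (p$dd_days < 0 || p$lvst_days < 0)
    stop("pathway delays must be non-negative")
  if (p$k20 <= 0) stop("'k20' must be positive")
  if (p$emc_u < 0) stop("'emc_u' must be non-negative")
  if (p$e_nat < 0) stop("'e_nat' must be non-negative")
  if (p$bod_toc <= 0) stop("'bod_toc' must be positive")
  structure(p, class = "bod_params")
}

#' @export
print.bod_params <- function(x, ...) {
  cat("BOD model parameters:\n")
  print(unlist(unclass(x)))
  invisible(x)
}

#' Calibration ranges of the model parameters
#'
#' Literature-based initial ranges used for uniform Latin Hypercube sampling
#' of the ten model parameters.
#'
#' @return A data frame with columns `parameter`, `lower`, `upper`, one row
#'   per parameter, in the canonical parameter order of [bod_params()].
#' @export
param_ranges <- function() {
  data.frame(
    parameter = c("eff1", "eff2", "eff3", "eff_sd", "dd_days", "lvst_days",
                  "k20", "emc_u", "e_nat", "bod_toc"),
    lower = c(0.35, 0.80, 0.92, 0.35, 4, 4, 0.35, 1, 0.0, 0.2),
    upper = c(0.75, 0.95, 0.98, 0.40, 8, 8, 0.60, 21, 0.5, 2.2),
    stringsAsFactors = FALSE
  )
}

#' Fixed model constants
#'
#' Physical and bookkeeping constants of the model. All are overridable but
#' default to the standard values: 60 g BOD per person-equivalent (PE) per
#' day, 1.23 PE per inhabitant, 10% sewerage losses, 400 g BOD per livestock
#' unit (LU) per day, a 25 LU/km2 intensive-livestock density threshold, a
#' 4-hour sewer residence time, a 365.25-day year and the BOD7 -> BOD5
#' divisor of 1.16.
#'
#' @param bod_per_pe_g_day BOD generation rate, g/PE/day.
#' @param pe_per_inhabitant PE generated per resident inhabitant.
#' @param sewer_loss_fraction Fraction of connected loadings lost from the
#'   sewerage system before treatment.
#' @param bod_per_lu_g_day BOD generation rate of livestock, g/LU/day.
#' @param intensive_threshold_lu_km2 Ruminant density above which cattle and
#'   sheep/goat systems are treated as intensive (LU/km2).
#' @param sewer_time_days Residence time of urban runoff in sewers (days).
#' @param year_days Days per year used in all load/flow conversions.
#' @param bod7_to_bod5_divisor Divisor converting BOD7 to BOD5.
#' @return An object of class `bod_constants` (named list). The derived
#'   element `t_y_per_mgl_m3s` (= 3600 * 24 * year_days / 1e6) converts
#'   mg/L * m3/s into t/y.
#' @export
bod_constants <- function(bod_per_pe_g_day = 60,
                          pe_per_inhabitant = 1.23,
                          sewer_loss_fraction = 0.10,
                          bod_per_lu_g_day = 400,
                          intensive_threshold_lu_km2 = 25,
                          sewer_time_days = 4 / 24,
                          year_days = 365.25,
                          bod7_to_bod5_divisor = 1.16) {
  cc <- list(bod_per_pe_g_day = bod_per_pe_g_day,
             pe_per_inhabitant = pe_per_inhabitant,
             sewer_loss_fraction = sewer_loss_fraction,
             bod_per_lu_g_day = bod_per_lu_g_day,
             intensive_threshold_lu_km2 = intensive_threshold_lu_km2,
             sewer_time_days = sewer_time_days,
             year_days = year_days,
             bod7_to_bod5_divisor = bod7_to_bod5_divisor)
  if (any(!vapply(cc, function(v) is.numeric(v) && length(v) == 1L && v > 0,
                  logical(1L)) & names(cc) != "sewer_loss_fraction"))
    stop("all constants must be positive scalars")
  if (cc$sewer_loss_fraction < 0 || cc$sewer_loss_fraction > 1)
    stop("'sewer_loss_fraction' must be in [0, 1]")
  cc$t_y_per_mgl_m3s <- 3600 * 24 * cc$year_days / 1e6
  structure(cc, class = "bod_constants")
}

# canonical source categories; the first three enter the reach directly,
# the last four are diffuse and pass through basin attenuation first
point_categories   <- c("domestic_point", "industrial", "livestock_intensive")
diffuse_categories <- c("domestic_diffuse", "livestock_extensive",
                        "urban_washoff", "natural")
all_categories     <- c(point_categories, diffuse_categories)

#' Source categories of the model
#'
#' @return Named list with elements `point`, `diffuse` and `all`, each a
#'   character vector of category names.
#' @export
bod_categories <- function() {
  list(point = point_categories, diffuse = diffuse_categories,
       all = all_categories)
}
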