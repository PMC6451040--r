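#' Convert BOD7 to BOD5
#'
#' Seven-day incubation values are divided by 1.16 to align them with the
#' five-day standard used throughout the model.
#'
#' @param x Concentration (mg O2/L) or load (t/y), vectorised, >= 0.
#' @param constants A [bod_constants()] object.
#' @return Same units as `x`.
#' @export
bod7_to_bod5 <- function(x, constants = bod_constants()) {
  if (any(x < 0, na.rm = TRUE)) stop("'x' must be non-negative")
  x / constants$bod7_to_bod5_divisor
}

quality_levels <- c("High", "Good", "Moderate", "Poor", "Bad")
quality_breaks <- c(2.5, 5, 10, 15)

#' Classify concentrations into water-quality classes
#'
#' Five ordered classes of organic-pollution status with thresholds at 2.5,
#' 5, 10 and 15 mg O2/L: High < 2.5, Good 2.5-5, Moderate 5-10, Poor 10-15,
#' Bad > 15. Intervals are lower-closed, so a boundary value falls in the
#' worse class. `NA` concentrations (undefined, e.g. zero discharge) stay
#' `NA` (unclassified).
#'
#' @param conc_mg_l Concentrations (mg O2/L, vectorised).
#' @return Ordered factor with levels High < Good < Moderate < Poor < Bad.
#' @export
#' @examples
#' classify(c(1, 2.5, 5, 20))
classify <- function(conc_mg_l) {
  if (any(conc_mg_l < 0, na.rm = TRUE))
    stop("'conc_mg_l' must be non-negative")
  cut(conc_mg_l, breaks = c(-Inf, quality_breaks, Inf),
      labels = quality_levels, right = FALSE, ordered_result = TRUE)
}

#' Confusion matrix of predicted vs observed quality classes
#'
#' Counts with predicted classes as rows and observed classes as columns.
#' User's accuracy is the per-row share of correct predictions, producer's
#' accuracy the per-column share, overall accuracy the trace over the
#' total. Over-predictions (predicted worse by two classes or more) and
#' under-predictions (better by two or more) are reported as percentages.
#'
#' @param obs,pred Paired class vectors (as from [classify()]).
#' @return An object of class `bod_confusion`: list with `counts` (5 x 5),
#'   `user_accuracy`, `producer_accuracy` (percent, per class),
#'   `overall_accuracy`, `overprediction_pct`, `underprediction_pct`, `n`.
#' @export
confusion <- function(obs, pred) {
  if (length(obs) != length(pred)) stop("'obs' and 'pred' lengths differ")
  obs <- factor(obs, levels = quality_levels, ordered = TRUE)
  pred <- factor(pred, levels = quality_levels, ordered = TRUE)
  ok <- !is.na(obs) & !is.na(pred)
  obs <- obs[ok]; pred <- pred[ok]
  if (!length(obs)) stop("no classified pairs")
  counts <- table(pred = pred, obs = obs)
  total <- sum(counts)
  diagc <- diag(counts)
  gap <- as.integer(pred) - as.integer(obs)
  structure(list(
    counts = counts,
    user_accuracy = 100 * diagc / pmax(rowSums(counts), 1L),
    producer_accuracy = 100 * diagc / pmax(colSums(counts), 1L),
    overall_accuracy = 100 * sum(diagc) / total,
    overprediction_pct = 100 * mean(gap >= 2L),
    underprediction_pct = 100 * mean(gap <= -2L),
    n = total
  ), class = "bod_confusion")
}

#' @export
print.bod_confusion <- function(x, ...) {
  print(x$counts)
  cat(sprintf("overall accuracy %.1f%% (n = %d); over-pred %.1f%%, under-pred %.1f%%\n",
              x$overall_accuracy, x$n, x$overprediction_pct,
              x$underprediction_pct))
  invisible(x)
}

#' Class agreement with a concentration tolerance at the thresholds
#'
#' A pair agrees when the classes match outright, or when shifting the
#' predicted concentration by up to `tol` mg O2/L could place it in the
#' observed class (the interval `pred +/- tol` overlaps the observed
#' class's concentration band). With `tol = 0` this reduces to plain
#' classification accuracy. Set `rule = "class"` to instead accept any
#' one-class disagreement where the prediction lies within `tol` of the
#' shared threshold.
#'
#' @param obs_conc,pred_conc Paired concentrations (mg O2/L).
#' @param tol Tolerance (mg O2/L), default 0.5.
#' @param rule `"concentration"` (default) or `"class"`.
#' @return Agreement percentage.
#' @export
tolerant_accuracy <- function(obs_conc, pred_conc, tol = 0.5,
                              rule = c("concentration", "class")) {
  rule <- match.arg(rule)
  if (length(obs_conc) != length(pred_conc)) stop("paired series required")
  if (tol < 0) stop("'tol' must be >= 0")
  ok <- is.finite(obs_conc) & is.finite(pred_conc)
  obs_conc <- obs_conc[ok]; pred_conc <- pred_conc[ok]
  br <- c(0, quality_breaks, Inf)
  obs_cls <- as.integer(classify(obs_conc))
  if (rule == "concentration") {
    lo <- br[obs_cls]
    hi <- br[obs_cls + 1L]
    agree <- pred_conc + tol >= lo & pred_conc - tol < hi
  } else {
    pred_cls <- as.integer(classify(pred_conc))
    shared <- br[pmax(obs_cls, pred_cls)]  # threshold between adjacent classes
    agree <- pred_cls == obs_cls |
      (abs(pred_cls - obs_cls) == 1L & abs(pred_conc - shared) <= tol)
  }
  100 * mean(agree)
}

#' Summary statistics of a flux series
#'
#' Order statistics used in model evaluation tables: 5th percentile, mean,
#' 90th and 95th percentiles, and maximum. Percentiles use linear
#' interpolation between order statistics (R's default type 7 rule).
#'
#' @param x Non-empty numeric series (concentrations or specific loads).
#' @return Named numeric vector `p5`, `mean`, `p90`, `p95`, `max`.
#' @export
summarize_series <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) stop("empty series")
  c(p5 = unname(stats::quantile(x, 0.05, type = 7)),
    mean = mean(x),
    p90 = unname(stats::quantile(x, 0.90, type = 7)),
    p95 = unname(stats::quantile(x, 0.95, type = 7)),
    max = max(x))
}

#' Share of network length per quality class
#'
#' Length-weighted share of the reach network failing good status
#' (concentration > 5 mg O2/L) plus the share in each quality class.
#' Reaches with undefined concentration are reported as `unclassified`.
#'
#' @param fluxes A [route_network()] result.
#' @param net The matching [build_network()] object.
#' @return List with `failing_pct` (share > 5 mg O2/L of total length) and
#'   `class_pct` (named shares per class plus `unclassified`, summing
#'   to 100).
#' @export
network_quality_share <- function(fluxes, net) {
  stopifnot(inherits(net, "bod_network"))
  len <- net$subbasins$reach_length_km[match(fluxes$id, net$subbasins$id)]
  total <- sum(len)
  if (total <= 0) stop("network has zero total reach length")
  cls <- classify(fluxes$concentration_mg_l)
  by_class <- vapply(quality_levels, function(l)
    sum(len[!is.na(cls) & cls == l]), numeric(1L))
  shares <- 100 * c(by_class, unclassified = sum(len[is.na(cls)])) / total
  failing <- 100 * sum(len[!is.na(fluxes$concentration_mg_l) &
                             fluxes$concentration_mg_l > 5]) / total
  list(failing_pct = failing, class_pct = shares)
}

#' Complete an observation with load/concentration conversions
#'
#' Converts between mean-annual concentration and load with a long-term
#' mean annual discharge (`load = conc * 31.5576 * Q`) and derives the
#' specific load per unit drainage area. Non-positive discharge skips the
#' conversion and flags the record instead of erroring.
#'
#' @param observations Data frame with `mean_conc_mg_l` and/or `load_t_y`.
#' @param discharge_m3s Discharge per record (m3/s).
#' @param area_km2 Optional upstream area per record for specific loads.
#' @param constants A [bod_constants()] object.
#' @return The table with `load_t_y`, `mean_conc_mg_l`,
#'   `specific_load_t_km2_y` (if `area_km2` given) filled where possible
#'   and a logical `conversion_flagged` column marking skipped records.
#' @export
load_concentration_convert <- function(observations, discharge_m3s,
                                       area_km2 = NULL,
                                       constants = bod_constants()) {
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  fac <- constants$t_y_per_mgl_m3s
  bad_q <- !is.finite(discharge_m3s) | discharge_m3s <= 0
  if (is.null(obs$load_t_y)) obs$load_t_y <- NA_real_
  if (is.null(obs$mean_conc_mg_l)) obs$mean_conc_mg_l <- NA_real_
  need_load <- is.na(obs$load_t_y) & !is.na(obs$mean_conc_mg_l) & !bad_q
  obs$load_t_y[need_load] <-
    obs$mean_conc_mg_l[need_load] * fac * discharge_m3s[need_load]
  need_conc <- is.na(obs$mean_conc_mg_l) & !is.na(obs$load_t_y) & !bad_q
  obs$mean_conc_mg_l[need_conc] <-
    obs$load_t_y[need_conc] / (fac * discharge_m3s[need_conc])
  if (!is.null(area_km2))
    obs$specific_load_t_km2_y <- obs$load_t_y / area_km2
  obs$conversion_flagged <- bad_q &
    (is.na(obs$load_t_y) | is.na(obs$mean_conc_mg_l))
  obs
}
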