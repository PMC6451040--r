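#' Latin Hypercube sample of the parameter space
#'
#' Stratified uniform sampling: each parameter's range is divided into `n`
#' equal-probability strata and exactly one draw is taken from each stratum,
#' with strata permuted independently per dimension. Marginals are uniform
#' over the range; the design is reproducible under `seed`.
#'
#' @param ranges Data frame `parameter`, `lower`, `upper`; defaults to
#'   [param_ranges()].
#' @param n Number of parameter sets (>= 1).
#' @param seed Integer seed.
#' @return Numeric matrix `n` x `nrow(ranges)` with parameter names as
#'   column names.
#' @export
lhs_sample <- function(ranges = param_ranges(), n, seed = 1L) {
  if (n < 1) stop("'n' must be >= 1")
  if (any(ranges$lower >= ranges$upper))
    stop("invalid ranges: lower must be < upper")
  set.seed(seed)
  d <- nrow(ranges)
  m <- matrix(NA_real_, n, d, dimnames = list(NULL, ranges$parameter))
  for (j in seq_len(d)) {
    u <- (sample.int(n) - stats::runif(n)) / n
    m[, j] <- ranges$lower[j] + u * (ranges$upper[j] - ranges$lower[j])
  }
  m
}

#' Kling-Gupta efficiency
#'
#' 2009 formulation: `KGE = 1 - sqrt((r - 1)^2 + (alpha - 1)^2 +
#' (beta - 1)^2)` with `r` the Pearson correlation, `alpha` the ratio of
#' standard deviations (sim/obs) and `beta` the ratio of means. Perfect
#' agreement scores 1; the score is unbounded below. Degenerate inputs
#' (constant observations or simulations, zero observed mean) return `NA`.
#'
#' @param obs,sim Paired numeric series of equal length >= 2.
#' @return KGE (<= 1), or `NA` if undefined.
#' @export
kge <- function(obs, sim) {
  if (length(obs) != length(sim)) stop("'obs' and 'sim' lengths differ")
  ok <- is.finite(obs) & is.finite(sim)
  obs <- obs[ok]; sim <- sim[ok]
  if (length(obs) < 2) stop("need at least two paired values")
  if (stats::sd(obs) == 0 || stats::sd(sim) == 0 || mean(obs) == 0)
    return(NA_real_)
  r <- stats::cor(obs, sim)
  alpha <- stats::sd(sim) / stats::sd(obs)
  beta <- mean(sim) / mean(obs)
  1 - sqrt((r - 1)^2 + (alpha - 1)^2 + (beta - 1)^2)
}

#' Goodness-of-fit suite for concentration series
#'
#' KGE and R-squared are computed on log-transformed concentrations (BOD
#' data are right-skewed with a prevalence of low values); MAE, RMSE and
#' percent bias on the natural scale. Before the log transform both series
#' are floored at `floor_mg_l`, half the modal reported detection limit of
#' 0.5 mg O2/L, to guard against zeros. R-squared is the squared Pearson
#' correlation of the log series (bounded \[0, 1\]); set
#' `r2 = "regression"` for the regression coefficient of determination.
#'
#' @param obs,sim Paired concentrations (mg O2/L).
#' @param floor_mg_l Detection-limit floor applied before the log transform.
#' @param r2 `"correlation"` (default) or `"regression"`.
#' @return An object of class `bod_gof`: list with `kge`, `r2`, `mae`,
#'   `rmse`, `pbias` (percent), `n`.
#' @export
gof_suite <- function(obs, sim, floor_mg_l = 0.25,
                      r2 = c("correlation", "regression")) {
  r2 <- match.arg(r2)
  if (length(obs) != length(sim)) stop("'obs' and 'sim' lengths differ")
  ok <- is.finite(obs) & is.finite(sim)
  obs <- obs[ok]; sim <- sim[ok]
  if (!length(obs)) stop("no paired observations")
  lobs <- log(pmax(obs, floor_mg_l))
  lsim <- log(pmax(sim, floor_mg_l))
  err <- sim - obs
  r2val <- if (stats::sd(lobs) == 0 || stats::sd(lsim) == 0) NA_real_
  else if (r2 == "correlation") stats::cor(lobs, lsim)^2
  else 1 - sum((lobs - lsim)^2) / sum((lobs - mean(lobs))^2)
  structure(list(
    kge = kge(lobs, lsim),
    r2 = r2val,
    mae = mean(abs(err)),
    rmse = sqrt(mean(err^2)),
    pbias = 100 * sum(err) / sum(obs),
    n = length(obs)
  ), class = "bod_gof")
}

#' @export
print.bod_gof <- function(x, ...) {
  cat(sprintf(
    "GOF (n = %d): KGE %.3f | R2 %.3f | MAE %.3f | RMSE %.3f | PBIAS %.1f%%\n",
    x$n, x$kge, x$r2, x$mae, x$rmse, x$pbias))
  invisible(x)
}

#' Prepare an observation table for scoring
#'
#' Applies the reliability filter (drops records with fewer than
#' `min_samples` measurements per year), converts BOD7 records to BOD5, and
#' resolves each station to a network subbasin.
#'
#' @param observations Data frame with columns `station_id`, `subbasin_id`,
#'   `mean_conc_mg_l`, `n_samples` and optionally `variant`
#'   (`"BOD5"`/`"BOD7"`, default BOD5).
#' @param net A [build_network()] object.
#' @param min_samples Minimum yearly sample size retained (default 6).
#' @param constants A [bod_constants()] object.
#' @return Filtered data frame with `mean_conc_mg_l` as BOD5 and an `idx`
#'   column giving the subbasin row in the network.
#' @export
prepare_observations <- function(observations, net, min_samples = 6,
                                 constants = bod_constants()) {
  stopifnot(inherits(net, "bod_network"))
  obs <- as.data.frame(observations, stringsAsFactors = FALSE)
  if (!is.null(obs$n_samples)) obs <- obs[obs$n_samples >= min_samples, ]
  if (!is.null(obs$variant)) {
    is7 <- obs$variant == "BOD7"
    obs$mean_conc_mg_l[is7] <- bod7_to_bod5(obs$mean_conc_mg_l[is7], constants)
    obs$variant <- "BOD5"
  }
  obs$idx <- match(as.character(obs$subbasin_id), net$subbasins$id)
  if (anyNA(obs$idx))
    stop("observations reference unknown subbasin id(s): ",
         paste(utils::head(obs$subbasin_id[is.na(obs$idx)], 3L), collapse = ", "))
  obs
}

#' Latin Hypercube calibration of the ten model parameters
#'
#' Samples `n` parameter sets uniformly within `ranges`, runs the forward
#' model (emissions, basin attenuation, network routing) for each, and
#' scores predicted against observed mean-annual concentrations with
#' [gof_suite()]. Behavioral sets are those in the upper quartile of both
#' KGE and R-squared (inclusive at the quartile boundary). The recommended
#' set is the behavioral set with maximal KGE; the shipped calibrated
#' default [bod_params()] remains the canonical parameterisation.
#'
#' @param net A [build_network()] object.
#' @param inputs List with elements `demographics`, `livestock`,
#'   `industrial` (any may be `NULL`) as taken by [compute_emissions()].
#' @param observations Observation table; see [prepare_observations()].
#' @param ranges Sampling ranges, default [param_ranges()].
#' @param n Number of parameter sets.
#' @param seed Integer seed for the Latin Hypercube design.
#' @param constants A [bod_constants()] object.
#' @param velocity_model Optional velocity model for [reach_travel_time()].
#' @return An object of class `bod_calibration`: list with `sets` (data
#'   frame of parameters, GOF scores and a `behavioral` flag), `best`
#'   (a [bod_params()] of the max-KGE behavioral set), `n`, `seed`.
#' @export
run_calibration <- function(net, inputs, observations,
                            ranges = param_ranges(), n = 1500, seed = 1L,
                            constants = bod_constants(),
                            velocity_model = NULL) {
  obs <- prepare_observations(observations, net, constants = constants)
  if (!nrow(obs)) stop("no scorable observation stations after filtering")
  design <- lhs_sample(ranges, n, seed)
  scores <- matrix(NA_real_, n, 5L,
                   dimnames = list(NULL, c("kge", "r2", "mae", "rmse", "pbias")))
  for (i in seq_len(n)) {
    p <- do.call(bod_params, as.list(design[i, ]))
    fl <- route_network(net,
                        compute_emissions(net, inputs$demographics,
                                          inputs$livestock, inputs$industrial,
                                          p, constants),
                        p, constants, velocity_model)
    g <- gof_suite(obs$mean_conc_mg_l, fl$concentration_mg_l[obs$idx])
    scores[i, ] <- c(g$kge, g$r2, g$mae, g$rmse, g$pbias)
  }
  q_kge <- stats::quantile(scores[, "kge"], 0.75, na.rm = TRUE)
  q_r2 <- stats::quantile(scores[, "r2"], 0.75, na.rm = TRUE)
  behavioral <- !is.na(scores[, "kge"]) & !is.na(scores[, "r2"]) &
    scores[, "kge"] >= q_kge & scores[, "r2"] >= q_r2
  sets <- data.frame(design, scores, behavioral = behavioral)
  best_i <- which(behavioral)[which.max(scores[behavioral, "kge"])]
  structure(list(sets = sets,
                 best = do.call(bod_params, as.list(design[best_i, ])),
                 n = n, seed = seed, n_stations = nrow(obs)),
            class = "bod_calibration")
}

#' @export
print.bod_calibration <- function(x, ...) {
  cat(sprintf("LHS calibration: %d sets, %d behavioral, %d stations\n",
              x$n, sum(x$sets$behavioral), x$n_stations))
  cat(sprintf("  best KGE %.3f (R2 %.3f)\n",
              max(x$sets$kge[x$sets$behavioral]),
              x$sets$r2[x$sets$behavioral][
                which.max(x$sets$kge[x$sets$behavioral])]))
  invisible(x)
}

#' Pearson correlations among behavioral parameters and scores
#'
#' Correlation matrix over the ten parameters plus KGE and R-squared,
#' computed on the behavioral subset (or all sets), with two-sided
#' significance at the 0.05 level. Constant columns yield `NA` entries.
#'
#' @param run A [run_calibration()] result.
#' @param subset `"behavioral"` (default) or `"all"`.
#' @param alpha Significance level for the `significant` flags.
#' @return List with `correlation` (12 x 12 matrix), `p_value` and
#'   `significant` (logical matrix, `P < alpha`).
#' @export
parameter_correlations <- function(run, subset = c("behavioral", "all"),
                                   alpha = 0.05) {
  subset <- match.arg(subset)
  stopifnot(inherits(run, "bod_calibration"))
  cols <- c(param_ranges()$parameter, "kge", "r2")
  df <- run$sets[if (subset == "behavioral") run$sets$behavioral else TRUE,
                 cols, drop = FALSE]
  m <- nrow(df)
  if (m < 3) stop("need at least 3 parameter sets (have ", m, ")")
  x <- as.matrix(df)
  const <- apply(x, 2L, function(v) stats::sd(v) == 0 || anyNA(v))
  r <- suppressWarnings(stats::cor(x))
  r[const, ] <- NA; r[, const] <- NA
  diag(r)[!const] <- 1
  tstat <- r * sqrt((m - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = m - 2)
  diag(p) <- 0
  list(correlation = r, p_value = p, significant = !is.na(p) & p < alpha,
       n = m)
}
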