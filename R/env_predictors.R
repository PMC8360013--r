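## Environmental predictors: yearly summaries of monthly series (mean,
## coefficient of variation, log-mean for discharge), 10-year period
## averaging, climate-model ensemble averaging, the glacier-retreat
## pixel-replacement heuristic, the water-temperature linear mixed model
## and collinearity screens.

#' Summarize one year of a monthly series
#'
#' @param values numeric vector of exactly 12 monthly values.
#' @param log_mean also return the natural log of the mean (used for the
#'   hydrological predictor); requires a strictly positive mean.
#' @return list with \code{mean}, \code{cv} (sample SD divided by the
#'   mean) and, if requested, \code{log_mean}.
#' @export
summarize_monthly <- function(values, log_mean = FALSE) {
  if (length(values) != 12 || !all(is.finite(values)))
    stop("window must contain exactly 12 finite monthly values")
  m <- mean(values)
  if (m <= 0) stop("non-positive mean: cv/log-mean undefined")
  out <- list(mean = m, cv = stats::sd(values) / m)
  if (log_mean) out$log_mean <- log(m)
  out
}

#' Average yearly summaries over a multi-year period
#'
#' Per-year means and coefficients of variation are averaged arithmetically
#' across the period's years; the hydrological log-mean is computed per year
#' and averaged on the log scale.
#'
#' @param yearly data frame with columns \code{mean}, \code{cv} and
#'   optionally \code{log_mean}, one row per year.
#' @return list with period-level \code{mean}, \code{cv} and (if present)
#'   \code{log_mean}.
#' @export
period_average <- function(yearly) {
  if (nrow(yearly) < 1) stop("empty period")
  out <- list(mean = mean(yearly$mean), cv = mean(yearly$cv))
  if (!is.null(yearly$log_mean)) out$log_mean <- mean(yearly$log_mean)
  out
}

#' Average two climate simulations month by month
#'
#' @param series_a,series_b equally indexed monthly matrices or vectors.
#' @return element-wise arithmetic mean.
#' @export
climate_ensemble <- function(series_a, series_b) {
  if (!identical(dim(series_a), dim(series_b)) ||
      length(series_a) != length(series_b))
    stop("misaligned month indices")
  (series_a + series_b) / 2
}

#' Glacier retreat by lowest-elevation pixel replacement
#'
#' Removes the fraction \code{q} of glacier cells with the lowest
#' elevations ("replaced by bare rock"). The removal count is
#' \code{round(q * n)} with half rounded up; ties at the cutoff elevation
#' are broken by cell id, so the operation is deterministic and monotone
#' in \code{q}.
#'
#' @param cells data frame with \code{cell_id}, \code{elevation},
#'   \code{area} (and optionally \code{reach_id}).
#' @param q fraction in [0, 1], or a \code{\link{scenario_spec}}.
#' @return the surviving cells.
#' @export
glacier_retreat <- function(cells, q) {
  if (inherits(q, "scenario_spec")) q <- q$glacier_replace_fraction
  if (q < 0 || q > 1) stop("q must be in [0, 1]")
  n <- nrow(cells)
  if (n == 0 || q == 0) return(cells)
  n_remove <- floor(q * n + 0.5)
  ord <- order(cells$elevation, cells$cell_id)
  out <- cells[setdiff(seq_len(n), ord[seq_len(n_remove)]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit the water-temperature linear mixed model
#'
#' Monthly water temperature is modelled from monthly air temperature and
#' its interaction with the catchment's glacier-or-lake cover, with a
#' station-level random intercept and random air-temperature slope to
#' account for repeated measures:
#' \code{water ~ air + air:cover + (air | station)}.
#' Marginal and conditional R-squared follow the Nakagawa variance
#' decomposition (random-slope variance averaged over the observed design).
#'
#' @param records data frame with columns \code{station}, \code{air_temp},
#'   \code{glacier_lake_pct}, \code{water_temp}.
#' @return object of class \code{water_temp_model} with elements
#'   \code{beta} (named fixed effects: intercept, air, air:cover),
#'   \code{varcomp}, \code{marginal_R2}, \code{conditional_R2},
#'   \code{singular}, and the underlying \code{lme4} fit.
#' @export
fit_water_temperature <- function(records) {
  stopifnot(all(c("station", "air_temp", "glacier_lake_pct",
                  "water_temp") %in% names(records)))
  if (length(unique(records$station)) < 2)
    stop("need >= 2 stations with repeated measures")
  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(water_temp ~ air_temp + air_temp:glacier_lake_pct +
                 (air_temp | station),
               data = records, REML = TRUE,
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  if (singular)
    warning("singular random-effect fit (variance component at boundary)")
  b <- lme4::fixef(fit)
  beta <- c(intercept = unname(b[["(Intercept)"]]),
            air = unname(b[["air_temp"]]),
            interaction = unname(b[["air_temp:glacier_lake_pct"]]))
  ## Nakagawa R2: fixed-effect variance over fitted fixed part; random
  ## variance averaged over the design for the random slope.
  Xf <- stats::model.matrix(fit)
  var_fixed <- stats::var(as.vector(Xf %*% b))
  vc <- lme4::VarCorr(fit)$station
  air <- records$air_temp
  var_random <- vc[1, 1] + 2 * vc[1, 2] * mean(air) + vc[2, 2] * mean(air^2)
  var_resid <- attr(lme4::VarCorr(fit), "sc")^2
  tot <- var_fixed + var_random + var_resid
  structure(list(beta = beta,
                 varcomp = list(intercept = vc[1, 1], slope = vc[2, 2],
                                cov = vc[1, 2], residual = var_resid),
                 marginal_R2 = var_fixed / tot,
                 conditional_R2 = (var_fixed + var_random) / tot,
                 singular = singular, fit = fit),
            class = "water_temp_model")
}

#' @export
print.water_temp_model <- function(x, ...) {
  cat("Water-temperature mixed model (fixed effects):\n")
  print(round(x$beta, 5))
  cat(sprintf("marginal R2 = %.3f, conditional R2 = %.3f%s\n",
              x$marginal_R2, x$conditional_R2,
              if (x$singular) " [singular fit]" else ""))
  invisible(x)
}

#' Predict water temperature from fixed effects only
#'
#' Random effects are station-specific and unavailable for unmonitored
#' reaches, so projections use the fixed effects alone.
#'
#' @param model a \code{water_temp_model}, or a named coefficient vector
#'   \code{c(intercept=, air=, interaction=)}.
#' @param air_temp air temperature (degrees C), vector or matrix.
#' @param glacier_lake_pct glacier-or-lake cover (\%), recycled against
#'   \code{air_temp} rows when it is a matrix.
#' @return predicted water temperature, same shape as \code{air_temp}.
#' @export
predict_water_temperature <- function(model, air_temp, glacier_lake_pct) {
  beta <- if (inherits(model, "water_temp_model")) model$beta else model
  beta[["intercept"]] + beta[["air"]] * air_temp +
    beta[["interaction"]] * air_temp * glacier_lake_pct
}

#' Collinearity screen: pairwise Pearson correlation and VIF
#'
#' @param X numeric predictor matrix or data frame (>= 2 non-constant
#'   columns).
#' @param r_max,vif_max pass thresholds (defaults: |r| < 0.7, VIF < 4).
#' @return list with \code{max_abs_pearson}, \code{cor} (matrix),
#'   \code{vif} (named vector, \code{1/(1 - R2_j)} from regressing column j
#'   on the others), and logical \code{pass}.
#' @export
collinearity_check <- function(X, r_max = 0.7, vif_max = 4) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need >= 2 columns")
  if (any(apply(X, 2, stats::sd) == 0)) stop("constant column in predictors")
  C <- stats::cor(X)
  off <- abs(C[upper.tri(C)])
  vif <- vapply(seq_len(ncol(X)), function(j) {
    r2 <- suppressWarnings(
      summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, 0)
  names(vif) <- colnames(X)
  list(max_abs_pearson = max(off), cor = C, vif = vif,
       pass = max(off) < r_max && max(vif) < vif_max)
}

## Default air->water coefficients used by the synthetic riverscape when no
## fitted water_temp_model is supplied: warming damped in glaciated/lake
## catchments, floored near 0 C (ice cover).
.default_wt_beta <- c(intercept = 2, air = 0.75, interaction = -0.005)

#' Derive the environmental predictor matrix for a riverscape
#'
#' Computes the eight environmental predictors per reach: mean and
#' coefficient of variation of monthly water temperature, log-transformed
#' mean and coefficient of variation of monthly discharge (per-year values
#' averaged across years), plus slope and urban/forest/agriculture cover.
#' Water temperature is predicted from air temperature and glacier-or-lake
#' cover via \code{\link{predict_water_temperature}} and floored at
#' \code{water_floor} (streams do not cool much below freezing).
#'
#' @param riverscape a \code{riverscape}.
#' @param wt_model optional fitted \code{water_temp_model} or coefficient
#'   vector; defaults to the generator's reference coefficients.
#' @param water_floor lower bound for monthly water temperature (degrees C).
#' @return data frame, one row per reach, with rownames = reach ids and
#'   columns \code{water_temp_mean}, \code{water_temp_cv},
#'   \code{discharge_logmean}, \code{discharge_cv}, \code{slope},
#'   \code{urban}, \code{forest}, \code{agri}.
#' @export
reach_predictors <- function(riverscape, wt_model = NULL, water_floor = 0.2) {
  stopifnot(inherits(riverscape, "riverscape"))
  beta <- if (is.null(wt_model)) .default_wt_beta else
    if (inherits(wt_model, "water_temp_model")) wt_model$beta else wt_model
  water <- predict_water_temperature(beta, riverscape$air_temp,
                                     riverscape$reaches$glacier_lake_pct)
  water <- pmax(water, water_floor)
  years <- riverscape$months$year
  n <- nrow(riverscape$reaches)
  per_reach <- function(i) {
    yw <- lapply(unique(years), function(yy) {
      w <- summarize_monthly(water[i, years == yy])
      q <- summarize_monthly(riverscape$discharge[i, years == yy],
                             log_mean = TRUE)
      data.frame(w_mean = w$mean, w_cv = w$cv,
                 q_cv = q$cv, q_logmean = q$log_mean)
    })
    colMeans(do.call(rbind, yw))
  }
  s <- t(vapply(seq_len(n), per_reach, numeric(4)))
  out <- data.frame(
    water_temp_mean = s[, "w_mean"], water_temp_cv = s[, "w_cv"],
    discharge_logmean = s[, "q_logmean"], discharge_cv = s[, "q_cv"],
    slope = riverscape$reaches$slope,
    urban = riverscape$reaches$urban_cover,
    forest = riverscape$reaches$forest_cover,
    agri = riverscape$reaches$agri_cover)
  rownames(out) <- riverscape$reaches$reach_id
  out
}

#' Names of the eight environmental predictors
#' @return character vector.
#' @export
env_predictor_names <- function() {
  c("water_temp_mean", "water_temp_cv", "discharge_logmean", "discharge_cv",
    "slope", "urban", "forest", "agri")
}
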