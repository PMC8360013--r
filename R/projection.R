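## Scenario projection and reporting: per-reach probability and richness
## cubes across periods and scenarios, mean occurrence probabilities,
## relative changes versus the baseline period, regional richness
## summaries and method/scenario comparisons.

#' Project species probabilities and expected richness over scenarios
#'
#' Applies the fitted species ensembles and the macroecological model to a
#' predictor matrix per (scenario, period) combination and assembles a
#' long-format projection cube. Stacked-SDM richness is the row sum of the
#' species probabilities.
#'
#' @param sdm_fits named list of \code{sdm_ensemble} (one per species).
#' @param mem_fit a \code{mem_ensemble}, or NULL to skip the MEM rows.
#' @param predictor_sets nested named list:
#'   \code{predictor_sets[[scenario]][[period]]} is a predictor data frame
#'   whose rownames are reach ids.
#' @param regions optional named vector mapping reach id to region label.
#' @return data frame of class \code{ept_projection} with columns
#'   \code{reach_id}, \code{region}, \code{scenario}, \code{period},
#'   \code{quantity} ("species" or "richness"), \code{name} (species id,
#'   "S-SDM" or "MEM") and \code{value}.
#' @export
project <- function(sdm_fits, mem_fit, predictor_sets, regions = NULL) {
  rows <- list()
  for (sc in names(predictor_sets)) {
    for (pd in names(predictor_sets[[sc]])) {
      X <- predictor_sets[[sc]][[pd]]
      if (is.null(X)) stop("missing predictor matrix for ", sc, "/", pd)
      ids <- rownames(X)
      reg <- if (is.null(regions)) "all" else unname(regions[ids])
      P <- vapply(sdm_fits, function(f) stats::predict(f, X),
                  numeric(nrow(X)))
      for (sp in colnames(P))
        rows[[length(rows) + 1L]] <- data.frame(
          reach_id = ids, region = reg, scenario = sc, period = pd,
          quantity = "species", name = sp, value = P[, sp],
          stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        reach_id = ids, region = reg, scenario = sc, period = pd,
        quantity = "richness", name = "S-SDM", value = stack_sdms(P),
        stringsAsFactors = FALSE)
      if (!is.null(mem_fit))
        rows[[length(rows) + 1L]] <- data.frame(
          reach_id = ids, region = reg, scenario = sc, period = pd,
          quantity = "richness", name = "MEM",
          value = stats::predict(mem_fit, X), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ept_projection", "data.frame")
  out
}

proj_subset <- function(projection, name, period, scenario, region) {
  d <- projection[projection$name == name & projection$period == period &
                    projection$scenario == scenario, , drop = FALSE]
  if (!identical(region, "all")) {
    d <- d[d$region == region, , drop = FALSE]
    if (nrow(d) == 0) stop("unknown or empty region: ", region)
  }
  if (nrow(d) == 0) stop("no projection rows for ", name, " ", period,
                         " ", scenario)
  d
}

#' Mean occurrence probability over reaches
#'
#' @param projection a \code{\link{project}} cube.
#' @param species species id.
#' @param period,scenario selection.
#' @param region region label or "all" (unweighted mean over reaches in
#'   scope).
#' @return mean probability.
#' @export
mean_occurrence <- function(projection, species, period, scenario,
                            region = "all") {
  mean(proj_subset(projection, species, period, scenario, region)$value)
}

#' Relative change versus the baseline period
#'
#' \code{100 (future - base) / base}, rounded half away from zero to one
#' decimal (the convention of the projection tables).
#'
#' @param base baseline value (> 0).
#' @param future future value.
#' @param digits decimals (default 1); \code{NA} to skip rounding.
#' @return relative change in percent.
#' @export
relative_change <- function(base, future, digits = 1) {
  if (any(base <= 0)) stop("zero or negative baseline")
  d <- 100 * (future - base) / base
  if (is.na(digits)) d else round_half_out(d, digits)
}

#' Mean predicted richness over a region
#'
#' @param projection a \code{\link{project}} cube.
#' @param method "S-SDM" or "MEM".
#' @param period,scenario,region selection.
#' @return mean expected richness.
#' @export
summarize_richness <- function(projection, method, period, scenario,
                               region = "all") {
  mean(proj_subset(projection, method, period, scenario, region)$value)
}

#' Relative difference between two summaries
#'
#' \code{100 (v_a - v_b) / v_b} per element — used for S-SDM versus MEM
#' and RCP8.5 versus RCP2.6 comparisons.
#'
#' @param v_a,v_b numeric vectors (named alike).
#' @param digits decimals (default 1), \code{NA} for unrounded.
#' @return relative differences in percent.
#' @export
compare_summaries <- function(v_a, v_b, digits = 1) {
  if (length(v_a) != length(v_b)) stop("missing side in comparison")
  d <- 100 * (v_a - v_b) / v_b
  if (is.na(digits)) d else round_half_out(d, digits)
}

#' Order statistics of a relative-change column
#'
#' @param deltas numeric vector of relative changes (>= 1 entry).
#' @return list with \code{min}, \code{median}, \code{max} (median = the
#'   middle element for odd counts).
#' @export
change_table_stats <- function(deltas) {
  if (!length(deltas)) stop("empty change column")
  list(min = min(deltas), median = stats::median(deltas), max = max(deltas))
}

#' Published projected mean occurrence probabilities (Swiss EPT study)
#'
#' Loads the package's copy of the published projection tables for the 41
#' modelled EPT species: mean occurrence probability over all Swiss
#' reaches per period (2015-2025, 2055-2065, 2080-2090) and the printed
#' relative changes versus the baseline period, for one forcing scenario.
#' Used for the worked examples that reproduce the tables' arithmetic.
#'
#' @param scenario "RCP2.6" or "RCP8.5".
#' @return data frame with columns \code{species}, \code{p_t1},
#'   \code{p_t2}, \code{delta_t2}, \code{p_t3}, \code{delta_t3} (deltas in
#'   percent as printed).
#' @export
load_change_table <- function(scenario = c("RCP2.6", "RCP8.5")) {
  scenario <- match.arg(scenario)
  f <- system.file("extdata",
                   if (scenario == "RCP2.6") "occurrence_change_rcp26.csv"
                   else "occurrence_change_rcp85.csv",
                   package = "eptr", mustWork = TRUE)
  utils::read.csv(f, stringsAsFactors = FALSE)
}
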