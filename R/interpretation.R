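## Model interpretation: permutation variable importance, grouped
## (standardized) importance by predictor type, evaluation-strip response
## curves.

predict_response <- function(model, X) {
  if (inherits(model, c("sdm_ensemble", "mem_ensemble")))
    stats::predict(model, X)
  else if (inherits(model, "glm"))
    unname(stats::predict(model, X, type = "response"))
  else as.numeric(stats::predict(model, X))
}

#' Permutation variable importance
#'
#' Importance of a variable is one minus the Pearson correlation between
#' the model's predictions on the data and on the data with that
#' variable's column randomly permuted, averaged over \code{n_perm}
#' permutations and clipped at zero.
#'
#' @param model fitted model (an \code{sdm_ensemble}, \code{mem_ensemble},
#'   or anything with a \code{predict} method returning numbers).
#' @param X predictor data frame used for the permutations.
#' @param variable column name to permute.
#' @param n_perm number of permutations (default 10).
#' @param seed integer seed.
#' @return importance value >= 0.
#' @export
permutation_importance <- function(model, X, variable, n_perm = 10,
                                   seed = 1) {
  if (!variable %in% names(X)) stop("unknown variable: ", variable)
  p0 <- predict_response(model, X)
  if (stats::sd(p0) == 0) {
    warning("constant predictions: importance defined as 0")
    return(0)
  }
  with_seed(seed, {
    r <- vapply(seq_len(n_perm), function(i) {
      Xp <- X
      Xp[[variable]] <- sample(Xp[[variable]])
      p1 <- predict_response(model, Xp)
      if (stats::sd(p1) == 0) 0 else stats::cor(p0, p1)
    }, 0)
    max(0, 1 - mean(r))
  })
}

#' Importance table for a fitted model
#'
#' Convenience wrapper running \code{\link{permutation_importance}} over a
#' set of variables with their predictor types.
#'
#' @param model fitted model.
#' @param X predictor data frame.
#' @param types named character vector mapping variable name to predictor
#'   type (hydrological, thermal, land-cover, topographic, spatial).
#' @param n_perm,seed passed on.
#' @return data frame \code{variable}, \code{type}, \code{importance}.
#' @export
importance_table <- function(model, X, types, n_perm = 10, seed = 1) {
  data.frame(variable = names(types), type = unname(types),
             importance = vapply(names(types), function(v)
               permutation_importance(model, X, v, n_perm, seed), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Default predictor-type mapping
#' @return named character vector over the eight environmental predictors
#'   plus five eigenvectors.
#' @export
predictor_types <- function() {
  c(water_temp_mean = "thermal", water_temp_cv = "thermal",
    discharge_logmean = "hydrological", discharge_cv = "hydrological",
    slope = "topographic", urban = "land-cover", forest = "land-cover",
    agri = "land-cover",
    ev1 = "spatial", ev2 = "spatial", ev3 = "spatial", ev4 = "spatial",
    ev5 = "spatial")
}

#' Grouped, standardized variable importance by predictor type
#'
#' The standardized value of a type is the sum of its variables'
#' importances divided by the number of variables of that type (so types
#' with many variables are not favoured); the pairwise relative
#' difference of type A over type B is \code{100 (v_A - v_B) / v_B}.
#' Rows sharing a variable (e.g. per-split replicates) are averaged first.
#'
#' @param table data frame with \code{variable}, \code{type},
#'   \code{importance}.
#' @return list with \code{values} (named per-type standardized values)
#'   and \code{relative_diff} (matrix, A over B in percent).
#' @export
grouped_importance <- function(table) {
  if (any(is.na(table$type))) stop("every variable must have a type")
  per_var <- tapply(table$importance, table$variable, mean)
  vtype <- table$type[match(names(per_var), table$variable)]
  vals <- tapply(per_var, vtype, sum) / tapply(per_var, vtype, length)
  vals <- vals[!is.na(vals)]
  k <- length(vals)
  rd <- outer(vals, vals, function(a, b) 100 * (a - b) / b)
  dimnames(rd) <- list(names(vals), names(vals))
  list(values = vals, relative_diff = rd)
}

#' Evaluation-strip response curve
#'
#' Sweeps one predictor over an even grid spanning its observed range
#' while all other predictors are held at their medians, recording the
#' model's prediction — the standard way to trace a fitted response shape.
#'
#' @param model fitted model.
#' @param X predictor data frame defining the observed ranges and medians.
#' @param variable focal predictor name.
#' @param n_points grid size (default 100).
#' @param fixed_at "median" (default) or "mean" for the non-focal
#'   variables.
#' @return data frame with columns \code{value} (grid) and
#'   \code{response}.
#' @export
response_curve <- function(model, X, variable, n_points = 100,
                           fixed_at = c("median", "mean")) {
  fixed_at <- match.arg(fixed_at)
  if (!variable %in% names(X)) stop("unknown variable: ", variable)
  rng <- range(X[[variable]])
  if (diff(rng) == 0) stop("zero-range variable: ", variable)
  grid <- seq(rng[1], rng[2], length.out = n_points)
  center <- if (fixed_at == "median") vapply(X, stats::median, 0)
            else vapply(X, mean, 0)
  Xnew <- as.data.frame(lapply(center, rep, n_points))
  Xnew[[variable]] <- grid
  data.frame(value = grid, response = predict_response(model, Xnew))
}
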