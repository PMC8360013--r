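## Per-species ensemble SDMs: binomial GLM (degree-2 polynomial terms on
## the environmental predictors, linear on the spatial eigenvectors) plus a
## random-forest classifier, evaluated by community cross-validation
## (identical repeated 80/20 splits for every species) and combined by
## AUC-weighted averaging.

#' Community cross-validation splits
#'
#' Repeated random train/test partitions reused identically across every
#' species and the richness models, so community metrics are comparable.
#'
#' @param site_ids character vector of site ids (>= 10).
#' @param n_splits number of repetitions (default 50).
#' @param train_frac training fraction in (0, 1) (default 0.8; sizes are
#'   rounded).
#' @param seed integer seed; identical seeds give identical splits.
#' @return object of class \code{ccv_splits}: list of
#'   \code{list(train =, test =)} id vectors.
#' @export
make_splits <- function(site_ids, n_splits = 50, train_frac = 0.8, seed = 1) {
  n <- length(site_ids)
  if (n < 10) stop("need >= 10 sites")
  if (train_frac <= 0 || train_frac >= 1)
    stop("train_frac must be in (0, 1)")
  n_train <- round(train_frac * n)
  with_seed(seed, {
    splits <- lapply(seq_len(n_splits), function(s) {
      tr <- sort(sample.int(n, n_train))
      list(train = site_ids[tr], test = site_ids[-tr])
    })
    structure(splits, class = "ccv_splits", seed = seed)
  })
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' Probability that a randomly drawn positive outscores a randomly drawn
#' negative, with ties counted one half; computed from midranks.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (0/1 or logical).
#' @return AUC in [0, 1].
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' True skill statistic, maximized over thresholds
#'
#' TSS = sensitivity + specificity - 1, maximized over candidate
#' thresholds (midpoints between sorted unique scores plus endpoints).
#'
#' @inheritParams auc
#' @return list is not returned; a single TSS value in [-1, 1], with the
#'   maximizing threshold as attribute \code{threshold}.
#' @export
tss <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  vals <- vapply(thr, function(t) {
    pred <- scores > t
    sum(pred & labels == 1) / n1 + sum(!pred & labels == 0) / n0 - 1
  }, 0)
  best <- which.max(vals)
  structure(vals[best], threshold = thr[best])
}

band_auc <- function(x) {
  cut(x, c(-Inf, 0.6, 0.7, 0.8, 0.9, Inf),
      labels = c("poor", "poor", "fair", "good", "excellent"),
      right = TRUE)
}

band_tss <- function(x) {
  cut(x, c(-Inf, 0.4, 0.75, Inf),
      labels = c("poor", "good", "excellent"), right = TRUE)
}

sdm_formula <- function(env_vars, spatial_vars, degree, response = "y") {
  env_terms <- if (degree > 1)
    sprintf("poly(%s, %d)", env_vars, degree) else env_vars
  stats::as.formula(paste(response, "~",
                          paste(c(env_terms, spatial_vars), collapse = " + ")))
}

fit_glm_member <- function(formula, data, family) {
  warned <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = family),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  attr(fit, "flagged") <- warned || !fit$converged
  fit
}

#' Fit an ensemble species distribution model
#'
#' Member A is a binomial GLM with orthogonal polynomial terms (default
#' degree 2, allowing unimodal responses) on the environmental predictors
#' and linear terms on the spatial eigenvectors; member B is a random
#' forest classifier. Each community cross-validation split yields
#' test-fold AUCs per member; the ensemble weight of a member is its mean
#' test AUC transformed to a skill score (\code{max(AUC - 0.5, 0)}, so a
#' no-skill member gets zero weight; \code{weighting = "raw"} uses the AUC
#' itself). Final members are refit on all sites; the splits serve only
#' for evaluation and weights.
#'
#' @param X predictor data frame (rows = sites, rownames = site ids).
#' @param y binary presence/absence vector aligned with \code{X}.
#' @param splits a \code{\link{make_splits}} object.
#' @param env_vars,spatial_vars column names; defaults: the eight
#'   environmental predictors and any \code{ev*} columns.
#' @param degree polynomial degree for member A (default 2).
#' @param ntree random-forest tree count (default 500).
#' @param seed base seed; the forest of split s uses \code{seed + s}.
#' @param weighting "skill" (default) or "raw".
#' @return object of class \code{sdm_ensemble} with members, weights,
#'   per-split evaluation records and skipped-split log.
#' @export
fit_sdm_ensemble <- function(X, y, splits, env_vars = NULL,
                             spatial_vars = NULL, degree = 2, ntree = 500,
                             seed = 1, weighting = c("skill", "raw")) {
  weighting <- match.arg(weighting)
  y <- as.integer(y)
  if (length(unique(y)) < 2) stop("both classes required in y")
  if (anyNA(X)) stop("missing predictor values")
  env_vars <- env_vars %||% intersect(env_predictor_names(), names(X))
  spatial_vars <- spatial_vars %||% grep("^ev", names(X), value = TRUE)
  fml <- sdm_formula(env_vars, spatial_vars, degree)
  dat <- cbind(y = y, X[, c(env_vars, spatial_vars), drop = FALSE])
  ids <- rownames(X)

  eval_rows <- list(); skipped <- character()
  for (s in seq_along(splits)) {
    tr <- match(splits[[s]]$train, ids)
    te <- match(splits[[s]]$test, ids)
    if (length(unique(y[tr])) < 2 || length(unique(y[te])) < 2) {
      skipped <- c(skipped, sprintf("split %d: single-class fold", s))
      next
    }
    g <- tryCatch(fit_glm_member(fml, dat[tr, ], stats::binomial()),
                  error = function(e) NULL)
    if (is.null(g)) {
      skipped <- c(skipped, sprintf("split %d: GLM failed", s))
      next
    }
    rf <- with_seed(seed + s, randomForest::randomForest(
      x = dat[tr, -1, drop = FALSE], y = factor(y[tr], levels = 0:1),
      ntree = ntree))
    pa <- stats::predict(g, dat[te, ], type = "response")
    pb <- stats::predict(rf, dat[te, -1, drop = FALSE],
                         type = "prob")[, "1"]
    eval_rows[[length(eval_rows) + 1L]] <- data.frame(
      split = s, auc_glm = auc(pa, y[te]), auc_rf = auc(pb, y[te]),
      pa = I(list(pa)), pb = I(list(pb)), yte = I(list(y[te])),
      flagged = attr(g, "flagged"))
  }
  if (!length(eval_rows)) stop("no usable cross-validation split")
  ev <- do.call(rbind, eval_rows)
  w_raw <- c(glm = mean(ev$auc_glm), rf = mean(ev$auc_rf))
  w <- if (weighting == "skill") pmax(w_raw - 0.5, 0) else w_raw
  if (sum(w) == 0) w <- c(glm = 0.5, rf = 0.5)
  w <- w / sum(w)

  ## ensemble metrics per split under the final weights
  ev$auc_ens <- mapply(function(pa, pb, yy)
    auc(w[1] * pa + w[2] * pb, yy), ev$pa, ev$pb, ev$yte)
  ev$tss_ens <- mapply(function(pa, pb, yy)
    as.numeric(tss(w[1] * pa + w[2] * pb, yy)), ev$pa, ev$pb, ev$yte)
  eval_df <- ev[, c("split", "auc_glm", "auc_rf", "auc_ens", "tss_ens",
                    "flagged")]

  final_glm <- fit_glm_member(fml, dat, stats::binomial())
  final_rf <- with_seed(seed, randomForest::randomForest(
    x = dat[, -1, drop = FALSE], y = factor(y, levels = 0:1),
    ntree = ntree))
  structure(list(members = list(glm = final_glm, rf = final_rf),
                 weights = w, eval = eval_df, skipped = skipped,
                 formula = fml, env_vars = env_vars,
                 spatial_vars = spatial_vars, degree = degree,
                 mean_member_auc = w_raw, weighting = weighting,
                 n_sites = nrow(X), prevalence = mean(y)),
            class = "sdm_ensemble")
}

#' Predict occurrence probability from an ensemble SDM
#'
#' The ensemble prediction is the weight-normalized convex combination of
#' the member probabilities, hence always between the two member values.
#'
#' @param object an \code{sdm_ensemble}.
#' @param newdata predictor data frame.
#' @param members if TRUE, return a matrix with member columns alongside
#'   the ensemble.
#' @param ... unused.
#' @return probability vector (or matrix when \code{members = TRUE}).
#' @export
predict.sdm_ensemble <- function(object, newdata, members = FALSE, ...) {
  pa <- stats::predict(object$members$glm, newdata, type = "response")
  pb <- stats::predict(object$members$rf,
                       newdata[, c(object$env_vars, object$spatial_vars),
                               drop = FALSE], type = "prob")[, "1"]
  p <- object$weights[1] * pa + object$weights[2] * pb
  if (members) cbind(ensemble = p, glm = pa, rf = pb) else unname(p)
}

#' @export
print.sdm_ensemble <- function(x, ...) {
  cat(sprintf(
    "Ensemble SDM (binomial GLM + random forest), %d sites, prevalence %.2f\n",
    x$n_sites, x$prevalence))
  cat(sprintf("  weights: GLM %.2f / RF %.2f (%s, member AUC %.3f / %.3f)\n",
              x$weights[1], x$weights[2], x$weighting,
              x$mean_member_auc[1], x$mean_member_auc[2]))
  cat(sprintf("  CCV (%d splits): median AUC %.3f [%s], median TSS %.3f [%s]\n",
              nrow(x$eval), stats::median(x$eval$auc_ens),
              band_auc(stats::median(x$eval$auc_ens)),
              stats::median(x$eval$tss_ens),
              band_tss(stats::median(x$eval$tss_ens))))
  if (length(x$skipped)) cat("  skipped:", length(x$skipped), "split(s)\n")
  invisible(x)
}

#' @export
summary.sdm_ensemble <- function(object, ...) {
  ev <- object$eval
  out <- list(
    auc = stats::quantile(ev$auc_ens, c(0, .25, .5, .75, 1)),
    tss = stats::quantile(ev$tss_ens, c(0, .25, .5, .75, 1)),
    auc_band = as.character(band_auc(stats::median(ev$auc_ens))),
    tss_band = as.character(band_tss(stats::median(ev$tss_ens))),
    weights = object$weights, skipped = object$skipped)
  class(out) <- "summary.sdm_ensemble"
  out
}

#' @export
print.summary.sdm_ensemble <- function(x, ...) {
  cat("CCV AUC quantiles:\n"); print(round(x$auc, 3))
  cat("CCV TSS quantiles:\n"); print(round(x$tss, 3))
  cat(sprintf("bands: AUC %s, TSS %s\n", x$auc_band, x$tss_band))
  invisible(x)
}

#' Fit ensemble SDMs for a whole community
#'
#' @param X predictor data frame (rows = sites).
#' @param occ binary occurrence matrix (sites x species), rows aligned
#'   with \code{X}.
#' @param splits shared \code{\link{make_splits}} object.
#' @param ... passed to \code{\link{fit_sdm_ensemble}}.
#' @return named list of \code{sdm_ensemble} objects, class
#'   \code{sdm_community}.
#' @export
fit_all_sdms <- function(X, occ, splits, ...) {
  fits <- lapply(colnames(occ), function(sp)
    fit_sdm_ensemble(X, occ[, sp], splits, ...))
  names(fits) <- colnames(occ)
  structure(fits, class = "sdm_community")
}

#' @export
print.sdm_community <- function(x, ...) {
  ev <- evaluate_ccv(x)
  cat("Ensemble SDM community:", length(x), "species\n")
  cat(sprintf("  community median AUC %.3f, median TSS %.3f\n",
              attr(ev, "community")["auc"], attr(ev, "community")["tss"]))
  invisible(x)
}

#' Community cross-validation evaluation summary
#'
#' Per-species median AUC/TSS over the splits with the conventional
#' performance bands (AUC: > 0.90 excellent, 0.80-0.90 good, 0.70-0.80
#' fair, <= 0.70 poor; TSS: > 0.75 excellent, 0.40-0.75 good, < 0.40
#' poor), plus community medians as attribute \code{community}.
#'
#' @param fits an \code{sdm_community} (or list of \code{sdm_ensemble}).
#' @return data frame: species, median_auc, auc_band, median_tss,
#'   tss_band.
#' @export
evaluate_ccv <- function(fits) {
  out <- do.call(rbind, lapply(names(fits), function(sp) {
    ev <- fits[[sp]]$eval
    data.frame(species = sp,
               median_auc = stats::median(ev$auc_ens),
               auc_band = as.character(band_auc(stats::median(ev$auc_ens))),
               median_tss = stats::median(ev$tss_ens),
               tss_band = as.character(band_tss(stats::median(ev$tss_ens))),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  all_auc <- unlist(lapply(fits, function(f) f$eval$auc_ens))
  all_tss <- unlist(lapply(fits, function(f) f$eval$tss_ens))
  attr(out, "community") <- c(auc = stats::median(all_auc),
                              tss = stats::median(all_tss))
  out
}
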