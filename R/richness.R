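## Richness models: macroecological ensemble (Poisson GLM + random-forest
## regressor, Spearman-weighted), stacked-SDM richness as the sum of
## occurrence probabilities, the exact Poisson-binomial distribution of
## richness, per-site exact tests and obs-vs-pred calibration tests.

#' Fit a macroecological richness model (MEM)
#'
#' Member A is a Poisson GLM with the same polynomial term structure as
#' the species models; member B is a random-forest regressor. Member
#' weights are the mean test-fold Spearman correlation between observed
#' and predicted richness, floored at zero (a member that cannot rank
#' sites gets no weight); an undefined correlation (constant fold) counts
#' as zero with a warning. Final members are refit on all sites.
#'
#' @param X predictor data frame (rows = sites, rownames = site ids).
#' @param richness non-negative integer richness per site.
#' @param splits a \code{\link{make_splits}} object.
#' @param env_vars,spatial_vars,degree,ntree,seed as in
#'   \code{\link{fit_sdm_ensemble}}.
#' @return object of class \code{mem_ensemble}.
#' @export
fit_mem <- function(X, richness, splits, env_vars = NULL,
                    spatial_vars = NULL, degree = 2, ntree = 500, seed = 1) {
  if (any(richness < 0) || any(richness != round(richness)))
    stop("richness must be non-negative integers")
  env_vars <- env_vars %||% intersect(env_predictor_names(), names(X))
  spatial_vars <- spatial_vars %||% grep("^ev", names(X), value = TRUE)
  fml <- sdm_formula(env_vars, spatial_vars, degree, response = "richness")
  dat <- cbind(richness = richness,
               X[, c(env_vars, spatial_vars), drop = FALSE])
  ids <- rownames(X)

  rho_na <- FALSE
  spearman <- function(obs, pred) {
    if (stats::sd(obs) == 0 || stats::sd(pred) == 0) {
      rho_na <<- TRUE
      return(0)
    }
    stats::cor(obs, pred, method = "spearman")
  }
  eval_rows <- list()
  for (s in seq_along(splits)) {
    tr <- match(splits[[s]]$train, ids)
    te <- match(splits[[s]]$test, ids)
    g <- fit_glm_member(fml, dat[tr, ], stats::poisson())
    rf <- with_seed(seed + s, suppressWarnings(randomForest::randomForest(
      x = dat[tr, -1, drop = FALSE], y = richness[tr], ntree = ntree)))
    pa <- stats::predict(g, dat[te, ], type = "response")
    pb <- stats::predict(rf, dat[te, -1, drop = FALSE])
    eval_rows[[s]] <- data.frame(split = s,
                                 rho_glm = spearman(richness[te], pa),
                                 rho_rf = spearman(richness[te], pb),
                                 pa = I(list(pa)), pb = I(list(pb)),
                                 obs = I(list(richness[te])))
  }
  if (rho_na)
    warning("constant richness in a test fold: Spearman weight set to 0")
  ev <- do.call(rbind, eval_rows)
  w <- pmax(c(glm = mean(ev$rho_glm), rf = mean(ev$rho_rf)), 0)
  if (sum(w) == 0) {
    warning("both member weights zero; falling back to equal weights")
    w <- c(glm = 0.5, rf = 0.5)
  }
  w <- w / sum(w)
  eval_df <- ev[, c("split", "rho_glm", "rho_rf")]
  final_glm <- fit_glm_member(fml, dat, stats::poisson())
  final_rf <- with_seed(seed, suppressWarnings(randomForest::randomForest(
    x = dat[, -1, drop = FALSE], y = richness, ntree = ntree)))
  structure(list(members = list(glm = final_glm, rf = final_rf),
                 weights = w, eval = eval_df, formula = fml,
                 env_vars = env_vars, spatial_vars = spatial_vars,
                 degree = degree, n_sites = nrow(X),
                 splits_eval = ev),
            class = "mem_ensemble")
}

#' Predict expected richness from a macroecological ensemble
#'
#' @param object a \code{mem_ensemble}.
#' @param newdata predictor data frame.
#' @param members if TRUE, include member columns.
#' @param ... unused.
#' @return non-negative expected richness vector.
#' @export
predict.mem_ensemble <- function(object, newdata, members = FALSE, ...) {
  pa <- stats::predict(object$members$glm, newdata, type = "response")
  pb <- stats::predict(object$members$rf,
                       newdata[, c(object$env_vars, object$spatial_vars),
                               drop = FALSE])
  p <- object$weights[1] * pa + object$weights[2] * pb
  if (members) cbind(ensemble = p, glm = pa, rf = pb) else unname(p)
}

#' @export
print.mem_ensemble <- function(x, ...) {
  cat(sprintf("Macroecological richness ensemble, %d sites\n", x$n_sites))
  cat(sprintf(
    "  weights: Poisson GLM %.2f / RF %.2f (mean Spearman %.3f / %.3f)\n",
    x$weights[1], x$weights[2], mean(x$eval$rho_glm), mean(x$eval$rho_rf)))
  invisible(x)
}

#' Stack species distribution models into expected richness
#'
#' Expected richness at a site is the sum over species of the predicted
#' occurrence probabilities — exactly the mean of the Poisson-binomial
#' distribution of the site's richness.
#'
#' @param prob_matrix sites x species matrix of probabilities in [0, 1].
#' @return expected richness per site (row sums).
#' @export
stack_sdms <- function(prob_matrix) {
  prob_matrix <- as.matrix(prob_matrix)
  if (any(prob_matrix < 0 | prob_matrix > 1, na.rm = FALSE) ||
      anyNA(prob_matrix))
    stop("probabilities must be in [0, 1]")
  rowSums(prob_matrix)
}

#' Exact Poisson-binomial probability mass function
#'
#' Distribution of the number of successes among independent Bernoulli
#' trials with unequal probabilities, computed by iterative convolution
#' (dynamic programming), exact up to floating-point error.
#'
#' @param p vector of probabilities in [0, 1].
#' @return object of class \code{poisbinom_pmf}: list with \code{pmf}
#'   (length n+1, over 0..n), \code{p}, \code{mean} (= sum(p)) and
#'   \code{variance} (= sum(p(1-p))).
#' @export
poisson_binomial_pmf <- function(p) {
  if (any(p < 0 | p > 1) || anyNA(p)) stop("p must be in [0, 1]")
  f <- 1
  for (pi in p) f <- c(f * (1 - pi), 0) + c(0, f * pi)
  structure(list(pmf = f, p = p, mean = sum(p),
                 variance = sum(p * (1 - p))),
            class = "poisbinom_pmf")
}

#' @export
print.poisbinom_pmf <- function(x, ...) {
  cat(sprintf("Poisson-binomial pmf over 0..%d: mean %.3f, variance %.3f\n",
              length(x$p), x$mean, x$variance))
  invisible(x)
}

#' Exact per-site richness test
#'
#' Two-sided exact test of the null that the observed richness was drawn
#' from the Poisson-binomial distribution implied by the stacked
#' occurrence probabilities. The default "mass" convention sums the
#' probabilities of all outcomes no more likely than the observed one; the
#' "central" alternative doubles the smaller tail (capped at 1).
#'
#' @param p occurrence-probability vector for the site.
#' @param observed observed richness, integer in [0, length(p)].
#' @param alpha significance level (default 0.05).
#' @param method "mass" (default) or "central".
#' @return list with \code{p_value}, \code{reject}, \code{expected}.
#' @export
richness_site_test <- function(p, observed, alpha = 0.05,
                               method = c("mass", "central")) {
  method <- match.arg(method)
  if (observed < 0 || observed > length(p) || observed != round(observed))
    stop("observed richness out of range")
  pmf <- poisson_binomial_pmf(p)$pmf
  k <- observed + 1L
  pv <- if (method == "mass") {
    sum(pmf[pmf <= pmf[k] * (1 + 1e-10)])
  } else {
    min(1, 2 * min(sum(pmf[seq_len(k)]), sum(pmf[k:length(pmf)])))
  }
  list(p_value = min(pv, 1), reject = pv < alpha, expected = sum(p))
}

#' Linear hypothesis test of prediction calibration
#'
#' Regresses observations on predictions and jointly tests intercept 0 and
#' slope 1 with a 2-degree-of-freedom F test; the calibration is accepted
#' when the test does not reject at \code{alpha}. A zero-residual fit is
#' flagged degenerate (accepted with p = 1 when observations equal
#' predictions exactly, rejected otherwise).
#'
#' @param observed,predicted numeric vectors (>= 3 sites; predictions not
#'   constant).
#' @param alpha significance level (default 0.05).
#' @return list with \code{F}, \code{p_value}, \code{accepted},
#'   \code{coef} (intercept, slope), \code{degenerate}.
#' @export
linear_hypothesis_test <- function(observed, predicted, alpha = 0.05) {
  n <- length(observed)
  if (n < 3) stop("need >= 3 sites")
  if (stats::sd(predicted) == 0) stop("constant predictions")
  fit <- stats::lm(observed ~ predicted)
  rss1 <- sum(stats::residuals(fit)^2)
  rss0 <- sum((observed - predicted)^2)
  scale <- max(sum(observed^2), 1)
  if (rss1 < 1e-12 * scale) {
    degen <- TRUE
    if (rss0 < 1e-12 * scale)
      return(list(F = 0, p_value = 1, accepted = TRUE,
                  coef = stats::coef(fit), degenerate = TRUE))
    return(list(F = Inf, p_value = 0, accepted = FALSE,
                coef = stats::coef(fit), degenerate = TRUE))
  }
  Fstat <- ((rss0 - rss1) / 2) / (rss1 / (n - 2))
  pv <- stats::pf(Fstat, 2, n - 2, lower.tail = FALSE)
  list(F = Fstat, p_value = pv, accepted = pv >= alpha,
       coef = stats::coef(fit), degenerate = FALSE)
}

#' Standardized richness error
#'
#' Per-site difference between prediction and observation standardized by
#' the mean observed richness.
#'
#' @param observed,predicted numeric vectors; mean(observed) must be > 0.
#' @return list with \code{errors}, \code{mean}, \code{sd}.
#' @export
standardized_error <- function(observed, predicted) {
  m <- mean(observed)
  if (m <= 0) stop("mean observed richness must be > 0")
  e <- (predicted - observed) / m
  list(errors = e, mean = mean(e), sd = stats::sd(e))
}

#' Summary of per-site exact tests across splits
#'
#' @param rejects list (one element per split) of logical rejection flags
#'   over sites.
#' @return list with per-split fraction of sites not rejected
#'   (\code{fractions}) and their \code{min}, \code{median}, \code{max}.
#' @export
site_test_summary <- function(rejects) {
  fr <- vapply(rejects, function(r) mean(!r), 0)
  list(fractions = fr, min = min(fr), median = stats::median(fr),
       max = max(fr))
}
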