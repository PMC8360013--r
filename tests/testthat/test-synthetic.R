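test_that("riverscape generation is deterministic and satisfies invariants", {
  a <- generate_riverscape(100, seed = 1)
  b <- generate_riverscape(100, seed = 1)
  expect_identical(a, b)
  expect_false(identical(a, generate_riverscape(100, seed = 2)))

  r <- a$reaches
  covers <- c(r$urban_cover, r$forest_cover, r$agri_cover,
              r$glacier_lake_pct)
  expect_true(all(covers >= 0 & covers <= 100))
  expect_true(all(r$urban_cover + r$forest_cover + r$agri_cover <= 100))
  expect_true(all(a$discharge > 0))
  expect_error(generate_riverscape(5), "n_reaches")
  expect_error(riverscape_config(elev_range = c(500, 500)), "degenerate")
})

test_that("lapse rate translates elevation into air temperature linearly", {
  cfg <- riverscape_config(lapse_rate = -6, elev_range = c(200, 3000),
                           temp_noise_sd = 0, seasonal_amplitude = 0)
  rs <- generate_riverscape(200, seed = 3, config = cfg)
  mean_air <- rowMeans(rs$air_temp)
  fit <- lm(mean_air ~ elevation, data = rs$reaches)
  expect_lt(max(abs(residuals(fit))), 1e-9)
  # 2.8 km of relief at -6 C/km
  expect_equal(unname(coef(fit)[2]) * (3000 - 200), -16.8, tolerance = 1e-9)
})

test_that("elevation and mean air temperature are strongly anticorrelated", {
  rs <- generate_riverscape(500, seed = 7)
  expect_lte(cor(rs$reaches$elevation, rowMeans(rs$air_temp)), -0.9)
})

test_that("Gaussian niche probability has its closed form", {
  sp <- list(species_id = "spX", genus = "g", family = "f", pmax = 0.8,
             mu = c(temp = 10), sigma = c(temp = 2))
  expect_equal(occurrence_probability(sp, c(temp = 10)), 0.8)
  expect_equal(occurrence_probability(sp, c(temp = 12)), 0.8 * exp(-0.5))
  # monotone decay with distance from the optimum
  d <- seq(0, 10, by = 0.5)
  p <- vapply(d, function(z) occurrence_probability(sp, c(temp = 10 + z)), 0)
  expect_true(all(diff(p) < 0))
  expect_lt(p[length(p)], 1e-5)
  expect_error(occurrence_probability(sp, c(other = 1)), "missing predictor")
})

test_that("species pools have consistent taxonomy and valid niches", {
  rng <- data.frame(var = c("a", "b"), min = c(0, 1), max = c(10, 3))
  pool <- make_species_pool(30, rng, seed = 5)
  expect_length(pool, 30)
  g2f <- tapply(vapply(pool, `[[`, "", "family"),
                vapply(pool, `[[`, "", "genus"),
                function(f) length(unique(f)))
  expect_true(all(g2f == 1))  # each genus maps to exactly one family
  for (sp in pool) {
    expect_true(all(sp$sigma > 0))
    expect_true(sp$pmax > 0 && sp$pmax <= 1)
  }
})

test_that("surveys record all detections at species rank when asked", {
  fx <- community_fixture()
  sv <- simulate_surveys(fx$rs, fx$pool, n_sites = 50,
                         ident_rates = c(species = 1, genus = 0, family = 0),
                         seed = 11, predictors = fx$X)
  expect_true(all(sv$rank == "species"))
  expect_true(all(sv$taxon %in% names(fx$pool)))
})

test_that("a species that can never occur is never recorded", {
  fx <- community_fixture()
  pool <- fx$pool[1:3]
  pool[[2]]$pmax <- 0
  class(pool) <- "species_pool"
  sv <- simulate_surveys(fx$rs, pool, n_sites = 100, seed = 12,
                         ident_rates = c(species = 1, genus = 0, family = 0),
                         predictors = fx$X)
  expect_false(pool[[2]]$species_id %in% sv$taxon)
})

test_that("detected prevalence matches true mean probability (binomial)", {
  rs <- generate_riverscape(450, seed = 31)
  X <- reach_predictors(rs)
  rng <- data.frame(
    var = c("water_temp_mean", "discharge_logmean"),
    min = c(quantile(X$water_temp_mean, .1), quantile(X$discharge_logmean, .1)),
    max = c(quantile(X$water_temp_mean, .9), quantile(X$discharge_logmean, .9)))
  pool <- make_species_pool(30, rng, seed = 32)
  sv <- simulate_surveys(rs, pool, n_sites = 400, seed = 3,
                         ident_rates = c(species = 1, genus = 0, family = 0),
                         predictors = X)
  truth <- attr(sv, "truth")
  n <- length(truth$sites)
  z <- vapply(names(pool), function(sp) {
    p <- truth$prob[, sp]
    phat <- sum(sv$taxon == sp) / n
    abs(phat - mean(p)) / (sqrt(sum(p * (1 - p))) / n)
  }, 0)
  # 30 simultaneous z-scores: allow a stray 3-SD exceedance
  expect_lte(sum(z > 3), 1)
  expect_true(all(z <= 4.5))
})

test_that("observed richness follows the Poisson-binomial law by construction", {
  fx <- community_fixture()
  p <- true_probability_matrix(fx$pool, fx$X[17, , drop = FALSE])[1, ]
  draws <- matrix(rbinom(8000 * length(p), 1, rep(p, each = 8000)), 8000)
  v <- var(rowSums(draws))
  expect_lt(abs(v - sum(p * (1 - p))) / sum(p * (1 - p)), 0.05)
})

test_that("scenario defaults encode the glacier replacement schedule", {
  expect_equal(scenario_spec("RCP2.6", "t2")$glacier_replace_fraction, 0.45)
  expect_equal(scenario_spec("RCP8.5", "t2")$glacier_replace_fraction, 0.50)
  expect_equal(scenario_spec("RCP2.6", "t3")$glacier_replace_fraction, 0.60)
  expect_equal(scenario_spec("RCP8.5", "t3")$glacier_replace_fraction, 0.90)
  expect_equal(scenario_spec("RCP2.6", "t1")$glacier_replace_fraction, 0)
  expect_equal(scenario_spec("RCP8.5", "t1")$temp_offset, 0)
})

test_that("the baseline scenario is the identity perturbation", {
  fx <- community_fixture()
  sc <- scenario_spec("RCP8.5", "t1")
  out <- apply_scenario(fx$rs, sc)
  expect_equal(out$air_temp, fx$rs$air_temp)
  expect_equal(out$discharge, fx$rs$discharge)
  expect_equal(out$reaches, fx$rs$reaches)
})

test_that("a warming offset shifts every monthly air temperature exactly", {
  fx <- community_fixture()
  sc <- scenario_spec("RCP8.5", "t3", temp_offset = 4,
                      discharge_multiplier = 1,
                      glacier_replace_fraction = 0)
  out <- apply_scenario(fx$rs, sc)
  expect_equal(out$air_temp, fx$rs$air_temp + 4)
  expect_equal(out$discharge, fx$rs$discharge)
})

test_that("warming strictly lowers a cold-adapted species' true probability", {
  fx <- community_fixture()
  X0 <- fx$X
  cold <- list(species_id = "cold", genus = "g", family = "f", pmax = 0.9,
               mu = c(water_temp_mean = min(X0$water_temp_mean) - 1),
               sigma = c(water_temp_mean = 2))
  sc <- scenario_spec("RCP8.5", "t3", temp_offset = 4,
                      discharge_multiplier = 1,
                      glacier_replace_fraction = 0)
  X1 <- reach_predictors(apply_scenario(fx$rs, sc))
  p0 <- vapply(seq_len(nrow(X0)), function(i)
    occurrence_probability(cold, c(water_temp_mean = X0$water_temp_mean[i])), 0)
  p1 <- vapply(seq_len(nrow(X1)), function(i)
    occurrence_probability(cold, c(water_temp_mean = X1$water_temp_mean[i])), 0)
  expect_true(all(p1 <= p0))
  expect_lt(mean(p1), mean(p0))
})
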