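## Synthetic riverscape, virtual species and survey simulation.
##
## The generator emulates the statistical structure the downstream models
## assume: an elevation gradient driving air temperature (negative lapse
## rate), discharge and land cover; Gaussian-niche virtual species with a
## species -> genus -> family taxonomy; Bernoulli survey sampling with
## imperfect (genus/family level) identification; and climate-scenario
## perturbations (warming offset, discharge multiplier, glacier retreat)
## with the true occurrence probabilities retained as ground truth.

#' Configuration for the synthetic riverscape generator
#'
#' @param elev_range numeric length 2, reach elevation range (m a.s.l.).
#' @param lapse_rate air-temperature lapse rate in degrees C per km of
#'   elevation (negative: higher is colder).
#' @param sea_level_temp mean annual air temperature at 0 m (degrees C).
#' @param seasonal_amplitude half-range of the seasonal air-temperature
#'   cycle (degrees C), peaking in July.
#' @param temp_noise_sd standard deviation of monthly air-temperature
#'   noise (degrees C).
#' @param n_years number of simulated years of monthly series.
#' @param domain_size side of the square study domain (m).
#' @param n_regions number of categorical region labels (coordinate bands).
#' @return a list of class \code{riverscape_config}.
#' @export
riverscape_config <- function(elev_range = c(200, 3000),
                              lapse_rate = -6,
                              sea_level_temp = 12,
                              seasonal_amplitude = 9,
                              temp_noise_sd = 1,
                              n_years = 1,
                              domain_size = 1e5,
                              n_regions = 4) {
  if (diff(elev_range) <= 0) stop("degenerate config: zero elevation range")
  if (n_years < 1) stop("n_years must be >= 1")
  structure(list(elev_range = elev_range, lapse_rate = lapse_rate,
                 sea_level_temp = sea_level_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 temp_noise_sd = temp_noise_sd, n_years = n_years,
                 domain_size = domain_size, n_regions = n_regions),
            class = "riverscape_config")
}

#' Generate a synthetic riverscape
#'
#' Builds a table of river reaches with projected coordinates, elevation,
#' region label, slope, land-cover percentages, glacier/lake cover and
#' monthly air-temperature and discharge series. Elevation is drawn
#' uniformly over \code{config$elev_range} and drives mean air temperature
#' through the configured lapse rate; land cover and discharge are
#' elevation-structured with multiplicative noise, so the predictor
#' correlations the distribution models exploit are present by construction.
#'
#' @param n_reaches number of reaches (>= 10).
#' @param seed integer seed; identical seeds give bit-identical riverscapes.
#' @param config a \code{\link{riverscape_config}}.
#' @return an object of class \code{riverscape}: a list with elements
#'   \code{reaches} (data frame of static covariates), \code{air_temp} and
#'   \code{discharge} (matrices, reaches x 12*n_years), \code{months}
#'   (year/month index), \code{glacier_cells} (elevation/area table used by
#'   \code{\link{glacier_retreat}}) and \code{config}.
#' @export
generate_riverscape <- function(n_reaches, seed = 1,
                                config = riverscape_config()) {
  if (n_reaches < 10) stop("n_reaches must be >= 10")
  stopifnot(inherits(config, "riverscape_config"))
  with_seed(seed, {
    elev <- runif(n_reaches, config$elev_range[1], config$elev_range[2])
    x <- runif(n_reaches, 0, config$domain_size)
    y <- runif(n_reaches, 0, config$domain_size)
    region <- paste0("R", 1 + pmin(config$n_regions - 1,
                                   floor(config$n_regions * x / config$domain_size)))
    slope <- pmin(60, pmax(0.1, 3 + 0.004 * (elev - config$elev_range[1]) +
                                  rnorm(n_reaches, 0, 5)))
    urban <- pmin(90, 30 * exp(-elev / 1200) * exp(rnorm(n_reaches, 0, 0.9)))
    agri <- pmin(90, 25 * exp(-elev / 1200) * exp(rnorm(n_reaches, 0, 0.9)))
    forest <- pmin(90, 40 * exp(-((elev - 1200) / 1000)^2) *
                         exp(rnorm(n_reaches, 0, 0.5)))
    tot <- urban + forest + agri
    over <- tot > 95
    if (any(over)) {
      f <- 95 / tot[over]
      urban[over] <- urban[over] * f
      forest[over] <- forest[over] * f
      agri[over] <- agri[over] * f
    }
    glacier <- pmax(0, (elev - 2200) / 800) * 25 *
      exp(rnorm(n_reaches, 0, 0.3))
    glacier <- pmin(glacier, 60)
    lake <- ifelse(runif(n_reaches) < 0.15, runif(n_reaches, 0, 5), 0)

    n_months <- 12L * config$n_years
    months <- data.frame(
      year = rep(seq_len(config$n_years), each = 12L),
      month = rep(1:12, config$n_years))
    ## seasonal amplitude tapers with elevation (thermal buffering of
    ## high-altitude, snow/groundwater-fed catchments) with independent
    ## reach-level heterogeneity, so temperature mean and variability are
    ## not lockstep
    elev_scaled <- (elev - config$elev_range[1]) / diff(config$elev_range)
    base_temp <- config$sea_level_temp + config$lapse_rate * elev / 1000
    amp <- config$seasonal_amplitude *
      pmax(0.25, pmin(1, (base_temp + 2) / 14)) *
      exp(rnorm(n_reaches, 0, 0.25))
    seas <- cos(2 * pi * (months$month - 7) / 12)
    air <- outer(base_temp, rep(1, n_months)) + outer(amp, seas) +
      matrix(rnorm(n_reaches * n_months, 0, config$temp_noise_sd),
             n_reaches, n_months)

    mean_q <- exp(log(5) - 0.4 * (elev - mean(config$elev_range)) / 1000 +
                    rnorm(n_reaches, 0, 0.7))
    ## snowmelt-driven summer peak, stronger for high/glaciated reaches
    peak_amp <- (0.25 + 0.45 * pmin(1, glacier / 30) + 0.15 * elev_scaled) *
      exp(rnorm(n_reaches, 0, 0.35))
    qseas <- exp(outer(peak_amp, cos(2 * pi * (months$month - 7) / 12)))
    discharge <- mean_q * qseas *
      matrix(exp(rnorm(n_reaches * n_months, 0, 0.2)), n_reaches, n_months)

    reach_id <- sprintf("reach%04d", seq_len(n_reaches))
    cells <- lapply(which(glacier > 0), function(i) {
      nc <- max(1L, ceiling(glacier[i] / 2))
      data.frame(reach_id = reach_id[i],
                 cell_id = sprintf("%s_c%02d", reach_id[i], seq_len(nc)),
                 elevation = elev[i] + 300 + sort(runif(nc, 0, 1200)),
                 area = glacier[i] / nc)
    })
    cells <- if (length(cells)) do.call(rbind, cells) else
      data.frame(reach_id = character(), cell_id = character(),
                 elevation = numeric(), area = numeric())
    rownames(cells) <- NULL

    reaches <- data.frame(
      reach_id = reach_id, x = x, y = y, elevation = elev, region = region,
      slope = slope, urban_cover = urban, forest_cover = forest,
      agri_cover = agri, glacier_pct = glacier, lake_pct = lake,
      glacier_lake_pct = glacier + lake, stringsAsFactors = FALSE)
    rownames(air) <- rownames(discharge) <- reach_id
    structure(list(reaches = reaches, air_temp = air, discharge = discharge,
                   months = months, glacier_cells = cells, config = config),
              class = "riverscape")
  })
}

#' @export
print.riverscape <- function(x, ...) {
  cat("Synthetic riverscape:", nrow(x$reaches), "reaches,",
      ncol(x$air_temp), "monthly steps\n")
  cat("  elevation", round(min(x$reaches$elevation)), "-",
      round(max(x$reaches$elevation)), "m;",
      length(unique(x$reaches$region)), "regions;",
      sum(x$reaches$glacier_pct > 0), "glaciated reaches\n")
  invisible(x)
}

#' Define a pool of Gaussian-niche virtual species
#'
#' Each species has a niche optimum and breadth per predictor and a maximal
#' occurrence probability \code{pmax}; its occurrence probability at a site
#' is \code{pmax * exp(-sum((x - mu)^2 / (2 sigma^2)))}. Species are nested
#' in genera and families so surveys can record partial identifications.
#'
#' @param n_species number of species.
#' @param predictor_ranges data frame with columns \code{var}, \code{min},
#'   \code{max}: the predictor space the optima are drawn from (typically
#'   the observed ranges of the niche predictors).
#' @param seed integer seed.
#' @param breadth_frac range for niche breadth as a fraction of each
#'   predictor's range.
#' @param pmax_range range for the maximal occurrence probability.
#' @param species_per_genus,genera_per_family average taxonomy branching.
#' @return an object of class \code{species_pool}: a list of species, each
#'   with \code{species_id}, \code{genus}, \code{family}, \code{pmax},
#'   named vectors \code{mu} and \code{sigma}.
#' @export
make_species_pool <- function(n_species, predictor_ranges, seed = 1,
                              breadth_frac = c(0.15, 0.4),
                              pmax_range = c(0.5, 0.95),
                              species_per_genus = 2.5,
                              genera_per_family = 2) {
  stopifnot(all(c("var", "min", "max") %in% names(predictor_ranges)),
            n_species >= 1)
  with_seed(seed, {
    n_gen <- max(1L, round(n_species / species_per_genus))
    n_fam <- max(1L, round(n_gen / genera_per_family))
    genus_of <- sort(sample(n_gen, n_species, replace = TRUE))
    family_of_genus <- sort(sample(n_fam, n_gen, replace = TRUE))
    vars <- predictor_ranges$var
    width <- predictor_ranges$max - predictor_ranges$min
    pool <- lapply(seq_len(n_species), function(i) {
      mu <- stats::setNames(runif(length(vars), predictor_ranges$min,
                                  predictor_ranges$max), vars)
      sigma <- stats::setNames(runif(length(vars), breadth_frac[1],
                                     breadth_frac[2]) * width, vars)
      list(species_id = sprintf("sp%02d", i),
           genus = sprintf("g%02d", genus_of[i]),
           family = sprintf("f%02d", family_of_genus[genus_of[i]]),
           pmax = runif(1, pmax_range[1], pmax_range[2]),
           mu = mu, sigma = sigma)
    })
    names(pool) <- vapply(pool, `[[`, "", "species_id")
    structure(pool, class = "species_pool")
  })
}

#' @export
print.species_pool <- function(x, ...) {
  cat("Virtual species pool:", length(x), "species,",
      length(unique(vapply(x, `[[`, "", "genus"))), "genera,",
      length(unique(vapply(x, `[[`, "", "family"))), "families\n")
  cat("  niche predictors:", paste(names(x[[1]]$mu), collapse = ", "), "\n")
  invisible(x)
}

#' Gaussian-niche occurrence probability
#'
#' @param species one element of a \code{\link{make_species_pool}} pool.
#' @param predictors named numeric vector covering all niche predictors.
#' @return probability in (0, pmax], maximal exactly at the niche optimum.
#' @export
occurrence_probability <- function(species, predictors) {
  vars <- names(species$mu)
  if (!all(vars %in% names(predictors)))
    stop("missing predictor(s): ",
         paste(setdiff(vars, names(predictors)), collapse = ", "))
  x <- predictors[vars]
  stop_if_not_finite(x, "predictors")
  species$pmax * exp(-sum((x - species$mu)^2 / (2 * species$sigma^2)))
}

#' True occurrence-probability matrix for a pool over a predictor matrix
#'
#' @param pool a \code{species_pool}.
#' @param X data frame/matrix with the niche predictors as named columns.
#' @return matrix, rows of X by species.
#' @export
true_probability_matrix <- function(pool, X) {
  vars <- names(pool[[1]]$mu)
  Xm <- as.matrix(X[, vars, drop = FALSE])
  out <- vapply(pool, function(sp) {
    z <- sweep(Xm, 2, sp$mu[vars], "-")
    z <- sweep(z^2, 2, 2 * sp$sigma[vars]^2, "/")
    sp$pmax * exp(-rowSums(z))
  }, numeric(nrow(Xm)))
  if (is.null(dim(out)))
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(out)))
  rownames(out) <- rownames(X)
  out
}

#' Simulate surveys with imperfect identification
#'
#' Samples \code{n_sites} reaches, draws each species' presence as a
#' Bernoulli trial at the reach's true occurrence probability, and records
#' every detection at species, genus or family rank according to
#' \code{ident_rates}. Partial identifications inherit the true species'
#' lineage. The true probabilities, site set and presence draws are kept as
#' attributes (hidden ground truth).
#'
#' @param riverscape a \code{riverscape}.
#' @param pool a \code{species_pool}.
#' @param n_sites number of surveyed reaches (<= number of reaches).
#' @param ident_rates named probabilities for \code{species}, \code{genus},
#'   \code{family} identification; must sum to 1.
#' @param seed integer seed.
#' @param predictors optional precomputed predictor matrix (rows = reaches,
#'   in riverscape order); defaults to \code{\link{reach_predictors}}.
#' @return data frame with columns \code{site_id}, \code{date},
#'   \code{taxon}, \code{rank}, \code{genus}, \code{family}; attributes
#'   \code{truth} (list with \code{sites}, \code{prob}, \code{presence}).
#' @export
simulate_surveys <- function(riverscape, pool, n_sites,
                             ident_rates = c(species = 0.8, genus = 0.15,
                                             family = 0.05),
                             seed = 1, predictors = NULL) {
  n_reaches <- nrow(riverscape$reaches)
  if (n_sites > n_reaches) stop("n_sites exceeds the number of reaches")
  if (abs(sum(ident_rates) - 1) > 1e-8) stop("ident_rates must sum to 1")
  X <- predictors %||% reach_predictors(riverscape)
  with_seed(seed, {
    idx <- sort(sample(n_reaches, n_sites))
    sites <- riverscape$reaches$reach_id[idx]
    P <- true_probability_matrix(pool, X[idx, , drop = FALSE])
    rownames(P) <- sites
    Y <- matrix(rbinom(length(P), 1, P), nrow(P), ncol(P),
                dimnames = dimnames(P))
    dates <- format(as.Date("2016-06-01") + (seq_len(n_sites) %% 90),
                    "%Y-%m-%d")
    rows <- list()
    ranks <- names(ident_rates)
    for (s in seq_len(n_sites)) {
      det <- which(Y[s, ] == 1)
      if (!length(det)) next
      rk <- ranks[sample.int(length(ranks), length(det), replace = TRUE,
                             prob = ident_rates)]
      sp <- pool[det]
      rows[[length(rows) + 1L]] <- data.frame(
        site_id = sites[s], date = dates[s],
        taxon = ifelse(rk == "species",
                       vapply(sp, `[[`, "", "species_id"),
                       ifelse(rk == "genus", vapply(sp, `[[`, "", "genus"),
                              vapply(sp, `[[`, "", "family"))),
        rank = rk,
        genus = ifelse(rk == "family", NA_character_,
                       vapply(sp, `[[`, "", "genus")),
        family = vapply(sp, `[[`, "", "family"),
        stringsAsFactors = FALSE)
    }
    surveys <- if (length(rows)) do.call(rbind, rows) else
      data.frame(site_id = character(), date = character(),
                 taxon = character(), rank = character(),
                 genus = character(), family = character())
    ## one row per (site, date, taxon): duplicate genus/family records merge
    surveys <- surveys[!duplicated(surveys[c("site_id", "date", "taxon")]), ]
    rownames(surveys) <- NULL
    attr(surveys, "truth") <- list(sites = sites, prob = P, presence = Y)
    surveys
  })
}

#' Climate-scenario specification
#'
#' Captures one forcing pathway x period combination: an air-temperature
#' offset, a discharge multiplier and the fraction of lowest-elevation
#' glacier pixels replaced by bare rock. The default replacement fractions
#' follow the study design: 45\% (RCP2.6) / 50\% (RCP8.5) by 2055-2065 and
#' 60\% / 90\% by 2080-2090; the 2015-2025 baseline is the identity.
#' Default warming offsets and discharge multipliers are desk-scale stand-ins
#' for the CH2018 forcings (see the methods vignette).
#'
#' @param rcp "RCP2.6" or "RCP8.5".
#' @param period "t1" (2015-2025), "t2" (2055-2065) or "t3" (2080-2090).
#' @param temp_offset optional override, degrees C added to monthly air
#'   temperature.
#' @param discharge_multiplier optional override, > 0.
#' @param glacier_replace_fraction optional override in [0, 1].
#' @return list of class \code{scenario_spec}.
#' @export
scenario_spec <- function(rcp = c("RCP2.6", "RCP8.5"),
                          period = c("t1", "t2", "t3"),
                          temp_offset = NULL,
                          discharge_multiplier = NULL,
                          glacier_replace_fraction = NULL) {
  rcp <- match.arg(rcp)
  period <- match.arg(period)
  qtab <- list("RCP2.6" = c(t1 = 0, t2 = 0.45, t3 = 0.60),
               "RCP8.5" = c(t1 = 0, t2 = 0.50, t3 = 0.90))
  ttab <- list("RCP2.6" = c(t1 = 0, t2 = 1.0, t3 = 1.1),
               "RCP8.5" = c(t1 = 0, t2 = 2.6, t3 = 4.6))
  dtab <- list("RCP2.6" = c(t1 = 1, t2 = 0.97, t3 = 0.95),
               "RCP8.5" = c(t1 = 1, t2 = 0.93, t3 = 0.88))
  q <- glacier_replace_fraction %||% unname(qtab[[rcp]][period])
  if (q < 0 || q > 1) stop("glacier_replace_fraction must be in [0, 1]")
  dm <- discharge_multiplier %||% unname(dtab[[rcp]][period])
  if (dm <= 0) stop("discharge_multiplier must be > 0")
  structure(list(rcp = rcp, period = period,
                 temp_offset = temp_offset %||% unname(ttab[[rcp]][period]),
                 discharge_multiplier = dm,
                 glacier_replace_fraction = q),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("Scenario %s %s: +%.1f C, discharge x%.2f, glacier q=%.2f\n",
              x$rcp, x$period, x$temp_offset, x$discharge_multiplier,
              x$glacier_replace_fraction))
  invisible(x)
}

#' Apply a climate scenario to a riverscape
#'
#' Shifts all monthly air temperatures by the scenario offset, scales all
#' monthly discharges by the multiplier, and removes the lowest-elevation
#' fraction of glacier cells (see \code{\link{glacier_retreat}}), updating
#' per-reach glacier and glacier-or-lake cover.
#'
#' @param riverscape a \code{riverscape}.
#' @param scenario a \code{\link{scenario_spec}}.
#' @return a perturbed \code{riverscape}.
#' @export
apply_scenario <- function(riverscape, scenario) {
  stopifnot(inherits(riverscape, "riverscape"),
            inherits(scenario, "scenario_spec"))
  out <- riverscape
  out$air_temp <- riverscape$air_temp + scenario$temp_offset
  out$discharge <- riverscape$discharge * scenario$discharge_multiplier
  cells <- glacier_retreat(riverscape$glacier_cells,
                           scenario$glacier_replace_fraction)
  out$glacier_cells <- cells
  gl <- tapply(cells$area, cells$reach_id, sum)
  new_gl <- rep(0, nrow(out$reaches))
  names(new_gl) <- out$reaches$reach_id
  new_gl[names(gl)] <- gl
  out$reaches$glacier_pct <- unname(new_gl)
  out$reaches$glacier_lake_pct <- out$reaches$glacier_pct +
    out$reaches$lake_pct
  out
}
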