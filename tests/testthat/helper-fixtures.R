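# Shared synthetic fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# Desk-scale community: riverscape, predictors, eigenvectors, virtual
# species, surveys, occurrence matrix, CCV splits. Deterministic.
community_fixture <- function() {
  if (!is.null(.fixture_env$comm)) return(.fixture_env$comm)
  rs <- generate_riverscape(300, seed = 101)
  X <- reach_predictors(rs)
  ev <- spatial_eigenvectors(rs$reaches[, c("x", "y")], k = 5,
                             centering = "raw")
  Xev <- cbind(X, as.data.frame(ev$vectors))
  rng <- data.frame(
    var = c("water_temp_mean", "discharge_logmean"),
    min = c(quantile(X$water_temp_mean, .1), quantile(X$discharge_logmean, .1)),
    max = c(quantile(X$water_temp_mean, .9), quantile(X$discharge_logmean, .9)))
  pool <- make_species_pool(15, rng, seed = 102)
  surveys <- simulate_surveys(rs, pool, n_sites = 220, seed = 103,
                              predictors = X)
  kept <- dedupe_sites(completeness_filter(surveys))
  occ <- build_occurrence_matrix(kept)
  occ <- select_species(occ, min_occurrences = 20)
  sites <- rownames(occ)
  splits <- make_splits(sites, n_splits = 10, seed = 104)
  .fixture_env$comm <- list(rs = rs, X = X, Xev = Xev, ev = ev, pool = pool,
                            surveys = surveys, occ = occ,
                            Xsites = Xev[sites, ], splits = splits)
  .fixture_env$comm
}

# A small survey table with known structure for the data-quality rules.
toy_surveys <- function() {
  rec <- function(site, date, taxon, rank, genus, family)
    data.frame(site_id = site, date = date, taxon = taxon, rank = rank,
               genus = genus, family = family, stringsAsFactors = FALSE)
  rbind(
    rec("s1", "2016-06-01", "A", "species", "g1", "f1"),
    rec("s1", "2016-06-01", "B", "species", "g2", "f1"),
    rec("s1", "2016-06-01", "g3", "genus", "g3", "f2"),
    rec("s1", "2016-06-01", "f3", "family", NA, "f3"),
    rec("s2", "2016-06-10", "A", "species", "g1", "f1"),
    rec("s2", "2016-06-10", "C", "species", "g1", "f1"))
}
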