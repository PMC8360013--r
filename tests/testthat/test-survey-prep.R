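test_that("minimum potential richness applies the exclusion rules", {
  ts <- toy_surveys()
  s1 <- ts[ts$site_id == "s1", ]
  # 2 species + genus g3 (no species) + family f3 (no covered genus)
  expect_equal(min_potential_richness(s1), 4)
  # species-rank only: k distinct species
  s2 <- ts[ts$site_id == "s2", ]
  expect_equal(min_potential_richness(s2), 2)
  # covered genus and family records contribute nothing
  rec <- data.frame(
    site_id = "s", date = "2016-01-01",
    taxon = c("A", "g1", "f1"), rank = c("species", "genus", "family"),
    genus = c("g1", "g1", NA), family = c("f1", "f1", "f1"),
    stringsAsFactors = FALSE)
  expect_equal(min_potential_richness(rec), 1)
  # unresolvable lineage fails loudly
  bad <- data.frame(site_id = "s", date = "d", taxon = "A",
                    rank = "species", genus = NA, family = "f1")
  expect_error(min_potential_richness(bad), "lineage")
})

test_that("completeness filter keeps surveys at or above the threshold", {
  ts <- toy_surveys()
  out <- completeness_filter(ts, threshold = 0.70)
  rep_ <- attr(out, "report")
  # s1: 2 species / min potential 4 = 0.5 -> discarded
  expect_false(rep_$kept[rep_$site_id == "s1"])
  expect_false("s1" %in% out$site_id)
  # s2: all species-rank, completeness 1 -> kept
  expect_equal(rep_$completeness[rep_$site_id == "s2"], 1)
  expect_true(all(out$site_id == "s2"))
  expect_error(completeness_filter(ts, threshold = 0), "threshold")
})

test_that("completeness filtering is idempotent", {
  fx <- community_fixture()
  once <- completeness_filter(fx$surveys)
  twice <- completeness_filter(once)
  attr(once, "report") <- attr(twice, "report") <- NULL
  attr(once, "truth") <- attr(twice, "truth") <- NULL
  expect_identical(once, twice)
})

test_that("identifying one more species in a known genus raises completeness", {
  # (S+1)/(M+1) > S/M whenever S < M
  base <- data.frame(
    site_id = "s", date = "d",
    taxon = c("A", "g2", "f9"), rank = c("species", "genus", "family"),
    genus = c("g1", "g2", NA), family = c("f1", "f2", "f9"),
    stringsAsFactors = FALSE)
  extra <- rbind(base, data.frame(site_id = "s", date = "d", taxon = "B",
                                  rank = "species", genus = "g1",
                                  family = "f1"))
  c0 <- survey_completeness(base)$completeness
  c1 <- survey_completeness(extra)$completeness
  expect_gt(c1, c0)
})

test_that("min potential richness is bounded below by identified species", {
  fx <- community_fixture()
  rep_ <- survey_completeness(fx$surveys)
  expect_true(all(rep_$min_potential >= rep_$n_species))
  expect_true(all(rep_$completeness <= 1, na.rm = TRUE))
})

test_that("duplicate surveys resolve to the most complete, then most recent", {
  mk <- function(site, date, n_sp, n_gen) {
    sp <- if (n_sp) data.frame(site_id = site, date = date,
                               taxon = paste0("A", seq_len(n_sp)),
                               rank = "species",
                               genus = paste0("ga", seq_len(n_sp)),
                               family = "f1") else NULL
    gn <- if (n_gen) data.frame(site_id = site, date = date,
                                taxon = paste0("G", seq_len(n_gen)),
                                rank = "genus",
                                genus = paste0("G", seq_len(n_gen)),
                                family = "f2") else NULL
    rbind(sp, gn)
  }
  sv <- rbind(mk("s1", "2016-05-01", 4, 1),   # completeness 0.8
              mk("s1", "2016-08-01", 19, 1),  # completeness 0.95
              mk("s2", "2016-05-01", 3, 0))
  out <- dedupe_sites(sv)
  expect_equal(sort(unique(out$site_id)), c("s1", "s2"))
  expect_true(all(out$date[out$site_id == "s1"] == "2016-08-01"))
  expect_equal(nrow(out[out$site_id == "s2", ]), 3)  # single survey untouched
  # tie on completeness: latest date wins
  tie <- rbind(mk("s3", "2016-04-01", 9, 1), mk("s3", "2016-09-01", 9, 1))
  expect_true(all(dedupe_sites(tie)$date == "2016-09-01"))
})

test_that("dedupe keeps every site and equals an exhaustive small-case oracle", {
  set.seed(20)
  sv <- do.call(rbind, lapply(1:12, function(i) {
    n_surv <- sample(1:3, 1)
    do.call(rbind, lapply(seq_len(n_surv), function(j) {
      n_sp <- sample(1:6, 1); n_gen <- sample(0:2, 1)
      date <- sprintf("2016-%02d-01", sample(1:12, 1))
      rbind(
        data.frame(site_id = paste0("s", i), date = date,
                   taxon = paste0("A", seq_len(n_sp)), rank = "species",
                   genus = paste0("g", seq_len(n_sp)), family = "f1"),
        if (n_gen) data.frame(site_id = paste0("s", i), date = date,
                              taxon = paste0("X", seq_len(n_gen)),
                              rank = "genus",
                              genus = paste0("X", seq_len(n_gen)),
                              family = "f2"))
    }))
  }))
  sv <- sv[!duplicated(sv[c("site_id", "date", "taxon")]), ]
  out <- dedupe_sites(sv)
  expect_setequal(unique(out$site_id), unique(sv$site_id))
  # oracle: enumerate surveys per site, pick max completeness then max date
  rep_ <- survey_completeness(sv)
  for (s in unique(rep_$site_id)) {
    d <- rep_[rep_$site_id == s, ]
    best <- d[order(-d$completeness, as.Date(d$date)), ]
    best <- best[best$completeness == best$completeness[1], ]
    want <- best$date[which.max(as.Date(best$date))]
    expect_true(all(out$date[out$site_id == s] == want))
  }
})

test_that("site snapping is nearest-neighbour with an inclusive tolerance", {
  reaches <- data.frame(reach_id = c("r1", "r2"), x = c(0, 100), y = c(0, 0))
  sites <- data.frame(site_id = c("a", "b", "c"),
                      x = c(0, 70, 0), y = c(0, 0, 31))
  out <- snap_sites_to_reaches(sites, reaches, tolerance = 30)
  expect_equal(out$reach_id[out$site_id == "a"], "r1")
  expect_equal(out$distance[out$site_id == "a"], 0)
  expect_equal(out$reach_id[out$site_id == "b"], "r2")  # 30 m, inclusive
  expect_false("c" %in% out$site_id)                    # 31 m, dropped
  expect_equal(attr(out, "dropped")$site_id, "c")
  expect_error(snap_sites_to_reaches(sites, reaches[0, ]), "empty")
})

test_that("snapping equals a brute-force nearest-neighbour scan", {
  set.seed(40)
  reaches <- data.frame(reach_id = paste0("r", 1:60),
                        x = runif(60, 0, 1000), y = runif(60, 0, 1000))
  sites <- data.frame(site_id = paste0("s", 1:80),
                      x = runif(80, 0, 1000), y = runif(80, 0, 1000))
  out <- snap_sites_to_reaches(sites, reaches, tolerance = 150)
  for (i in seq_len(nrow(sites))) {
    d <- sqrt((sites$x[i] - reaches$x)^2 + (sites$y[i] - reaches$y)^2)
    j <- which.min(d)
    row <- out[out$site_id == sites$site_id[i], ]
    if (min(d) <= 150) {
      expect_equal(row$reach_id, reaches$reach_id[j])
      expect_equal(row$distance, d[j])
    } else {
      expect_equal(nrow(row), 0)
    }
  }
})

test_that("species selection filters by presence count and recomputes prevalence", {
  set.seed(50)
  occ <- matrix(rbinom(200 * 12, 1, runif(12, 0.05, 0.6)), 200, 12,
                byrow = TRUE, dimnames = list(paste0("s", 1:200), paste0("sp", 1:12)))
  out <- select_species(occ, min_occurrences = 25)
  expect_identical(colnames(out),
                   colnames(occ)[colSums(occ) >= 25])  # brute-force filter
  expect_equal(attr(out, "prevalence"), colMeans(out))
  # boundary: exactly 24 presences is removed at threshold 25
  occ2 <- cbind(occ, rare = c(rep(1L, 24), rep(0L, 176)))
  expect_false("rare" %in% colnames(select_species(occ2, 25)))
  expect_identical(select_species(occ, 0), structure(occ, prevalence = colMeans(occ)))
  expect_error(select_species(occ, 1e6), "no species")
})

test_that("occurrence matrices are binary and use species records only", {
  fx <- community_fixture()
  occ <- build_occurrence_matrix(fx$surveys)
  expect_true(all(occ %in% c(0L, 1L)))
  expect_true(all(colnames(occ) %in% names(fx$pool)))
  sp <- fx$surveys[fx$surveys$rank == "species", ]
  expect_equal(sum(occ), nrow(unique(sp[, c("site_id", "taxon")])))
})
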