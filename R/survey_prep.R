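## Survey data-quality rules: completeness via minimum potential richness,
## duplicate-survey resolution, site-reach snapping and prevalence-based
## species selection.

survey_key <- function(surveys) paste(surveys$site_id, surveys$date, sep = "|")

check_lineage <- function(records) {
  bad <- (records$rank == "species" &
            (is.na(records$genus) | is.na(records$family))) |
    (records$rank == "genus" & is.na(records$family))
  if (any(bad))
    stop("records with unresolvable lineage: ",
         paste(utils::head(records$taxon[bad], 5), collapse = ", "))
  invisible(records)
}

#' Minimum potential species richness of one survey
#'
#' Sums the number of identified species, the number of genus-rank records
#' whose genus contains none of the identified species, and the number of
#' family-rank records whose family contains neither a genus-rank record
#' nor the genus of an identified species.
#'
#' @param records data frame of one survey's records with columns
#'   \code{taxon}, \code{rank} (species/genus/family), \code{genus},
#'   \code{family}.
#' @return integer count.
#' @export
min_potential_richness <- function(records) {
  check_lineage(records)
  sp <- records[records$rank == "species", , drop = FALSE]
  gn <- records[records$rank == "genus", , drop = FALSE]
  fm <- records[records$rank == "family", , drop = FALSE]
  S <- length(unique(sp$taxon))
  sp_genera <- unique(sp$genus)
  g_extra <- unique(gn$taxon[!(gn$taxon %in% sp_genera)])
  covered_genera <- union(unique(gn$taxon), sp_genera)
  covered_families <- unique(c(sp$family, gn$family))
  f_extra <- unique(fm$taxon[!(fm$taxon %in% covered_families)])
  S + length(g_extra) + length(f_extra)
}

#' Per-survey completeness of identification
#'
#' @param surveys survey record table (one row per site/date/taxon).
#' @return data frame with one row per survey: \code{site_id}, \code{date},
#'   \code{n_species}, \code{min_potential}, \code{completeness}.
#' @export
survey_completeness <- function(surveys) {
  key <- survey_key(surveys)
  out <- do.call(rbind, lapply(split(surveys, key), function(rec) {
    m <- min_potential_richness(rec)
    s <- length(unique(rec$taxon[rec$rank == "species"]))
    data.frame(site_id = rec$site_id[1], date = rec$date[1],
               n_species = s, min_potential = m,
               completeness = if (m > 0) s / m else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Discard incomplete surveys
#'
#' A survey is kept iff its number of identified species is at least
#' \code{threshold} of its minimum potential richness (kept when the ratio
#' equals the threshold). Surveys with zero minimum potential richness are
#' dropped. The per-survey completeness report is attached as attribute
#' \code{report}.
#'
#' @param surveys survey record table.
#' @param threshold completeness fraction in (0, 1], default 0.70.
#' @return filtered survey table.
#' @export
completeness_filter <- function(surveys, threshold = 0.70) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  rep_ <- survey_completeness(surveys)
  rep_$kept <- !is.na(rep_$completeness) & rep_$completeness >= threshold
  keep_keys <- paste(rep_$site_id, rep_$date, sep = "|")[rep_$kept]
  out <- surveys[survey_key(surveys) %in% keep_keys, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "report") <- rep_
  attr(out, "truth") <- attr(surveys, "truth")
  out
}

#' Resolve duplicate surveys per site
#'
#' Keeps exactly one survey per site: the one with maximal completeness,
#' ties broken by most recent date, then lexicographically largest survey
#' key — deterministic and auditable.
#'
#' @param surveys survey record table.
#' @return survey table with one survey (site/date) per site.
#' @export
dedupe_sites <- function(surveys) {
  rep_ <- survey_completeness(surveys)
  rep_$completeness[is.na(rep_$completeness)] <- -Inf
  keep <- do.call(rbind, lapply(split(rep_, rep_$site_id), function(d) {
    d <- d[order(d$completeness, as.Date(d$date),
                 paste(d$site_id, d$date, sep = "|"),
                 decreasing = TRUE), , drop = FALSE]
    d[1, , drop = FALSE]
  }))
  keep_keys <- paste(keep$site_id, keep$date, sep = "|")
  out <- surveys[survey_key(surveys) %in% keep_keys, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "truth") <- attr(surveys, "truth")
  out
}

#' Snap survey sites to river reaches
#'
#' Maps each site to its nearest reach by Euclidean distance, keeping only
#' sites within \code{tolerance} metres (inclusive at the tolerance).
#' Dropped sites are reported in attribute \code{dropped}.
#'
#' @param sites data frame with \code{site_id}, \code{x}, \code{y}.
#' @param reaches data frame with \code{reach_id}, \code{x}, \code{y}.
#' @param tolerance snap distance in metres (default 30).
#' @return data frame \code{site_id}, \code{reach_id}, \code{distance}.
#' @export
snap_sites_to_reaches <- function(sites, reaches, tolerance = 30) {
  if (nrow(reaches) == 0) stop("empty reach set")
  d2 <- outer(sites$x, reaches$x, "-")^2 + outer(sites$y, reaches$y, "-")^2
  j <- max.col(-d2, ties.method = "first")
  dist <- sqrt(d2[cbind(seq_len(nrow(sites)), j)])
  map <- data.frame(site_id = sites$site_id,
                    reach_id = reaches$reach_id[j],
                    distance = dist, stringsAsFactors = FALSE)
  keep <- dist <= tolerance
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- map[!keep, , drop = FALSE]
  out
}

#' Build a binary sites-by-species occurrence matrix
#'
#' Uses species-rank records only (genus/family records cannot be assigned
#' to a species).
#'
#' @param surveys survey record table (ideally after
#'   \code{\link{completeness_filter}} and \code{\link{dedupe_sites}}).
#' @return binary matrix, sites as rows, species as columns.
#' @export
build_occurrence_matrix <- function(surveys) {
  sp <- surveys[surveys$rank == "species", , drop = FALSE]
  sites <- sort(unique(surveys$site_id))
  species <- sort(unique(sp$taxon))
  m <- matrix(0L, length(sites), length(species),
              dimnames = list(sites, species))
  m[cbind(match(sp$site_id, sites), match(sp$taxon, species))] <- 1L
  m
}

#' Select species by minimum number of occurrences
#'
#' @param occ binary occurrence matrix (sites x species).
#' @param min_occurrences minimum presence count (default 25).
#' @return filtered matrix with attribute \code{prevalence} (column means).
#' @export
select_species <- function(occ, min_occurrences = 25) {
  stopifnot(all(occ %in% c(0, 1)))
  keep <- colSums(occ) >= min_occurrences
  if (!any(keep)) stop("no species with >= ", min_occurrences, " occurrences")
  out <- occ[, keep, drop = FALSE]
  attr(out, "prevalence") <- colMeans(out)
  out
}
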