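# Decade aggregation, discovery accumulation and description lag.

#' Bin years into decades
#'
#' Decade `d` covers calendar years \eqn{[d, d+9]} and is labelled by
#' its starting year (the 1940s are 1940-1949).  Years before
#' `min_year` (default 1820, reflecting data scarcity in the earliest
#' records) and missing years are excluded and reported.
#'
#' @param years integer vector (NA allowed).
#' @param min_year earliest year retained.
#' @return list with `counts` (named integer vector, names = decade
#'   start years, only non-empty decades), `n_excluded_early`,
#'   `n_missing`.
#' @export
bin_by_decade <- function(years, min_year = 1820) {
  miss <- is.na(years)
  early <- !miss & years < min_year
  keep <- years[!miss & !early]
  dec <- (keep %/% 10) * 10
  counts <- table(factor(dec, levels = sort(unique(dec))))
  list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    n_excluded_early = sum(early),
    n_missing = sum(miss)
  )
}

.decade_table <- function(years, min_year) {
  b <- bin_by_decade(years, min_year)
  data.frame(decade_start = as.integer(names(b$counts)), n = b$counts,
             row.names = NULL)
}

#' Discovery accumulation curves by decade
#'
#' Aggregates specimen collections and taxon publications by decade and
#' accumulates each series as a fraction of its total, tracing the
#' progression of botanical knowledge.  Collections count every
#' non-neotype specimen with a usable year; publications count one event
#' per taxon at its protologue year, taken across the taxon's full
#' non-neotype type series.  When a taxon's series disagrees on the
#' protologue year the minimum is used with a warning.
#'
#' @param ds canonical record data frame (full table).
#' @param min_year earliest year retained (default 1820).
#' @param overrides optional year-override table.
#' @param names `"accepted"` restricts the publication series to
#'   accepted names; `"all"` counts every name (synonyms as their own
#'   taxa).
#' @return data frame with columns `decade_start`, `n_collected`,
#'   `n_published`, `cum_fraction_collected`, `cum_fraction_published`.
#' @export
accumulation_curves <- function(ds, min_year = 1820, overrides = NULL,
                                names = c("accepted", "all")) {
  names <- match.arg(names)
  non_neo <- ds[is.na(ds$type_status) | ds$type_status != "neotype", ,
                drop = FALSE]
  coll_years <- apply_year_overrides(non_neo, overrides)
  pub_pool <- non_neo
  if (names == "accepted") {
    pub_pool <- pub_pool[!is.na(pub_pool$name_status) &
                           pub_pool$name_status == "accepted", , drop = FALSE]
  }
  # protologue year per taxon from the full type series (disagreements
  # are visible only before deduplication)
  pub_years <- tapply(pub_pool$publication_year, pub_pool$accepted_name,
                      function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0) return(NA_integer_)
    if (length(unique(v)) > 1) {
      warning("protologue years disagree within a taxon; using the minimum")
    }
    min(v)
  })
  pub_years <- as.integer(pub_years[!is.na(pub_years)])

  ct <- .decade_table(coll_years, min_year)
  pt <- .decade_table(pub_years, min_year)
  decades <- sort(unique(c(ct$decade_start, pt$decade_start)))
  if (length(decades) == 0) {
    return(data.frame(decade_start = integer(0), n_collected = integer(0),
                      n_published = integer(0),
                      cum_fraction_collected = numeric(0),
                      cum_fraction_published = numeric(0)))
  }
  decades <- seq(min(decades), max(decades), by = 10)
  out <- data.frame(decade_start = decades)
  out$n_collected <- ct$n[match(decades, ct$decade_start)]
  out$n_published <- pt$n[match(decades, pt$decade_start)]
  out$n_collected[is.na(out$n_collected)] <- 0L
  out$n_published[is.na(out$n_published)] <- 0L
  out$cum_fraction_collected <- if (sum(out$n_collected) > 0) {
    cumsum(out$n_collected) / sum(out$n_collected)
  } else rep(NA_real_, nrow(out))
  out$cum_fraction_published <- if (sum(out$n_published) > 0) {
    cumsum(out$n_published) / sum(out$n_published)
  } else rep(NA_real_, nrow(out))
  out
}

#' Collection-to-publication time lags
#'
#' For each taxon, the lag is the difference between the protologue
#' publication year and the earliest specimen collection year.  Taxa
#' with a negative lag are flagged and excluded with a warning (a
#' negative lag signals a data error such as neotype leakage).  Lags are
#' also averaged by the decade of the first collection year, the period
#' in which each taxon entered scientific knowledge.
#'
#' @param ds canonical record data frame *already* reduced by
#'   [temporal_subset()] (one earliest specimen per taxon, no neotypes).
#' @param min_year earliest collection year retained in the per-decade
#'   means (default 1820).
#' @return list with `lags` (data frame `accepted_name`,
#'   `first_collection_year`, `publication_year`, `lag`), `by_decade`
#'   (data frame `decade_start`, `mean_lag`, `n_taxa`), `mean_lag`
#'   (overall mean over taxa first collected from `min_year` on, so the
#'   decade means weighted by taxon counts reproduce it exactly), and
#'   `n_excluded_negative`.
#' @export
time_lags <- function(ds, min_year = 1820) {
  ok <- !is.na(ds$collection_year) & !is.na(ds$publication_year)
  d <- ds[ok, , drop = FALSE]
  lag <- d$publication_year - d$collection_year
  neg <- lag < 0
  if (any(neg)) {
    warning(sprintf("excluded %d taxon/taxa with negative collection-to-publication lag",
                    sum(neg)))
  }
  d <- d[!neg, , drop = FALSE]
  lag <- lag[!neg]
  lags <- data.frame(
    accepted_name = d$accepted_name,
    first_collection_year = d$collection_year,
    publication_year = d$publication_year,
    lag = lag,
    stringsAsFactors = FALSE
  )
  in_range <- lags$first_collection_year >= min_year
  lr <- lags[in_range, , drop = FALSE]
  if (nrow(lr) > 0) {
    dec <- (lr$first_collection_year %/% 10) * 10
    by_decade <- do.call(rbind, lapply(split(lr$lag, dec), function(v) {
      data.frame(mean_lag = mean(v), n_taxa = length(v))
    }))
    by_decade <- data.frame(decade_start = as.integer(rownames(by_decade)),
                            by_decade, row.names = NULL)
  } else {
    by_decade <- data.frame(decade_start = integer(0), mean_lag = numeric(0),
                            n_taxa = integer(0))
  }
  list(
    lags = lags,
    by_decade = by_decade,
    mean_lag = if (nrow(lr) > 0) mean(lr$lag) else NA_real_,
    n_excluded_negative = sum(neg)
  )
}
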