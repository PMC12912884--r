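# Collector metrics and the weighted importance index.

#' Split a joint-collection string into individual collector names
#'
#' Herbarium labels frequently record joint collections under combined
#' names ("Barbosa & Lemos"); each listed individual is credited the
#' specimen once.  Fragments are whitespace-trimmed and empty fragments
#' dropped.
#'
#' @param collectors_raw a single character string (NA allowed).
#' @param delimiters separator tokens treated as name boundaries.
#'   Defaults cover "&", ";", ",", " and ", " e ", " et ", " with ".
#' @return character vector of names (zero-length for empty input).
#' @export
disaggregate_collectors <- function(collectors_raw,
                                    delimiters = c("&", ";", ",", " and ",
                                                   " e ", " et ", " with ")) {
  if (length(collectors_raw) != 1) {
    stop("collectors_raw must be a single string", call. = FALSE)
  }
  if (is.na(collectors_raw) || !nzchar(trimws(collectors_raw))) {
    return(character(0))
  }
  pattern <- paste(vapply(delimiters, function(d) {
    if (grepl("^\\s.*\\s$", d)) {
      # word delimiter: require word boundaries so "Anderson" survives "and"
      paste0("\\s+", gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", trimws(d)), "\\s+")
    } else {
      gsub("([][{}()+*^$|\\\\.?])", "\\\\\\1", d)
    }
  }, character(1)), collapse = "|")
  parts <- strsplit(collectors_raw, pattern)[[1]]
  parts <- trimws(parts)
  parts[nzchar(parts)]
}

#' Canonicalize collector names
#'
#' Case-folds, collapses internal whitespace and strips punctuation
#' around initials; an optional alias table maps variant spellings to a
#' canonical form.  No fuzzy matching is attempted.
#'
#' @param names character vector of collector names.
#' @param aliases optional data frame with columns `variant`, `canonical`.
#' @return character vector of canonical names (title-cased key form).
#' @export
canonicalize_collector <- function(names, aliases = NULL) {
  key <- tolower(trimws(names))
  key <- gsub("\\.", " ", key)
  key <- gsub("\\s+", " ", key)
  key <- trimws(key)
  if (!is.null(aliases) && nrow(aliases) > 0) {
    akey <- tolower(trimws(aliases$variant))
    akey <- gsub("\\.", " ", akey)
    akey <- gsub("\\s+", " ", akey)
    hit <- match(key, akey)
    key[!is.na(hit)] <- aliases$canonical[hit[!is.na(hit)]]
  }
  key
}

#' Per-collector activity metrics
#'
#' For each individual collector credits the number of type specimens
#' (`nesp`), the number of distinct provinces collected in
#' (`nlocality`), and the span in years between the earliest and latest
#' collection (`duration`, 0 when fewer than two dated specimens).
#' Joint collections credit every co-collector with the full specimen by
#' default, so the column sum of `nesp` may exceed the number of
#' specimens; a fractional mode splits each specimen equally instead.
#'
#' @param ds canonical record data frame.
#' @param overrides optional year-override table; overridden decades
#'   contribute their midpoint year to `duration`.
#' @param aliases optional alias table passed to
#'   [canonicalize_collector()].
#' @param credit `"full"` (default) or `"fractional"` specimen credit
#'   for joint collections.
#' @return data frame with columns `name`, `nesp`, `nlocality`,
#'   `duration`, one row per distinct collector.
#' @export
collector_metrics <- function(ds, overrides = NULL, aliases = NULL,
                              credit = c("full", "fractional")) {
  credit <- match.arg(credit)
  if (nrow(ds) == 0) stop("dataset is empty", call. = FALSE)
  years <- apply_year_overrides(ds, overrides)
  rows <- vector("list", nrow(ds))
  for (i in seq_len(nrow(ds))) {
    nm <- disaggregate_collectors(ds$collectors_raw[i])
    if (length(nm) == 0) next
    nm <- canonicalize_collector(nm, aliases)
    rows[[i]] <- data.frame(
      name = nm,
      share = if (credit == "full") 1 else 1 / length(nm),
      year = years[i],
      province = ds$province[i],
      stringsAsFactors = FALSE
    )
  }
  long <- do.call(rbind, rows)
  if (is.null(long) || nrow(long) == 0) {
    return(data.frame(name = character(0), nesp = numeric(0),
                      nlocality = integer(0), duration = numeric(0)))
  }
  split_by <- split(long, long$name)
  out <- do.call(rbind, lapply(split_by, function(d) {
    yrs <- d$year[!is.na(d$year)]
    data.frame(
      name = d$name[1],
      nesp = sum(d$share),
      nlocality = length(unique(d$province[!is.na(d$province)])),
      duration = if (length(yrs) >= 2) max(yrs) - min(yrs) else 0,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(out$name), , drop = FALSE]
}

#' Min-max normalisation to the unit interval
#'
#' Rescales values to \eqn{(v - \min)/(\max - \min)}.  When all values
#' are equal the metric carries no information and every output is 0, so
#' a degenerate metric contributes nothing to a weighted index and the
#' index stays interpretable as "share of best observed".
#'
#' @param values non-empty numeric vector, all finite.
#' @return numeric vector in \eqn{[0, 1]}.
#' @export
min_max_normalize <- function(values) {
  if (length(values) == 0) stop("values must be non-empty", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(0, length(values)))
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Weights for the collector-importance index
#'
#' The default weighting (0.5, 0.3, 0.2) gives the greatest influence to
#' the number of specimens collected, then spatial coverage, then
#' temporal coverage.
#'
#' @param w_nesp,w_nlocality,w_duration non-negative weights summing to 1.
#' @return named numeric vector of class `index_weights`.
#' @export
index_weights <- function(w_nesp = 0.5, w_nlocality = 0.3, w_duration = 0.2) {
  w <- c(nesp = w_nesp, nlocality = w_nlocality, duration = w_duration)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (abs(sum(w) - 1) > 1e-12) stop("weights must sum to 1", call. = FALSE)
  class(w) <- c("index_weights", class(w))
  w
}

#' Composite collector-importance index
#'
#' Min-max-normalises each metric across collectors and combines them as
#' a weighted sum: `index = w_nesp * nesp_norm + w_nlocality *
#' nlocality_norm + w_duration * duration_norm`.  The weights apply to
#' the normalised metrics, so the index lies in \eqn{[0, 1]}.  Output is
#' sorted by decreasing index; ties go to the higher `nesp`, then to the
#' lexicographically smaller name, so the ranking is deterministic.
#'
#' @param metrics output of [collector_metrics()].
#' @param weights an [index_weights()] vector.
#' @return `metrics` with added columns `nesp_norm`, `nlocality_norm`,
#'   `duration_norm`, `index`, `rank`, sorted by rank.
#' @export
collector_importance <- function(metrics, weights = index_weights()) {
  if (abs(sum(weights) - 1) > 1e-12) stop("weights must sum to 1", call. = FALSE)
  m <- metrics
  m$nesp_norm      <- min_max_normalize(m$nesp)
  m$nlocality_norm <- min_max_normalize(m$nlocality)
  m$duration_norm  <- min_max_normalize(m$duration)
  m$index <- weights[["nesp"]] * m$nesp_norm +
    weights[["nlocality"]] * m$nlocality_norm +
    weights[["duration"]] * m$duration_norm
  ord <- order(-m$index, -m$nesp, m$name)
  m <- m[ord, , drop = FALSE]
  m$rank <- seq_len(nrow(m))
  rownames(m) <- NULL
  m
}

#' Rank stability of the importance index under weight perturbation
#'
#' Perturbs each weight over a grid (default each weight shifted by
#' \eqn{\pm 0.05} and \eqn{\pm 0.10}), renormalises every perturbed
#' triple to sum 1, recomputes the ranking, and reports the fraction of
#' grid points whose top-`k` *set* equals the default top-`k`, plus the
#' range of ranks each collector attains across the grid.
#'
#' @param metrics output of [collector_metrics()].
#' @param weights baseline [index_weights()].
#' @param deltas positive perturbation magnitudes; each weight takes
#'   offsets `c(-rev(deltas), 0, deltas)`.  Every `delta` must be
#'   smaller than the smallest baseline weight.
#' @param top_k size of the leading set compared (default 10).
#' @return list with `agreement` (fraction of grid points reproducing
#'   the default top-`k` set), `n_grid`, and `rank_range` (data frame
#'   `name`, `rank_min`, `rank_max`).
#' @export
weight_sensitivity <- function(metrics, weights = index_weights(),
                               deltas = c(0.05, 0.10), top_k = 10) {
  if (length(deltas) && max(deltas) >= min(weights)) {
    stop("perturbation delta must be smaller than the smallest weight",
         call. = FALSE)
  }
  offsets <- sort(unique(c(-deltas, 0, deltas)))
  grid <- expand.grid(d1 = offsets, d2 = offsets, d3 = offsets)
  base <- collector_importance(metrics, weights)
  k <- min(top_k, nrow(base))
  top_default <- sort(base$name[seq_len(k)])
  ranks <- matrix(NA_integer_, nrow(base), nrow(grid),
                  dimnames = list(base$name, NULL))
  agree <- logical(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    w <- unclass(weights) + c(grid$d1[g], grid$d2[g], grid$d3[g])
    w <- w / sum(w)
    ranked <- collector_importance(metrics, structure(w, class = "index_weights"))
    agree[g] <- identical(sort(ranked$name[seq_len(k)]), top_default)
    ranks[ranked$name, g] <- ranked$rank
  }
  list(
    agreement = mean(agree),
    n_grid = nrow(grid),
    top_default = top_default,
    rank_range = data.frame(
      name = rownames(ranks),
      rank_min = apply(ranks, 1, min),
      rank_max = apply(ranks, 1, max),
      stringsAsFactors = FALSE
    )
  )
}

# All permutations of 1..n (n <= 9), one per row.
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub, n)[, append(seq_len(n - 1L), n, after = pos - 1L),
                           drop = FALSE]
    out[r + seq_len(nrow(sub)), ] <- block
    r <- r + nrow(sub)
  }
  out
}

#' Spearman rank correlation with two-sided p-value
#'
#' Computes rho as the Pearson correlation of average-ranked values
#' (ties receive average ranks).  The two-sided p-value uses the
#' t approximation for `n >= 10` and exact permutation enumeration for
#' smaller samples.
#'
#' @param x,y numeric vectors of equal length `n >= 3`.
#' @return list with `rho`, `p_value`, `n`, `method`.
#' @export
spearman_cor <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need at least 3 observations", call. = FALSE)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    stop("rho undefined: zero variance in ranks", call. = FALSE)
  }
  rho <- stats::cor(rx, ry)
  if (n >= 10) {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    method <- "t approximation"
  } else {
    perms <- .permutations(n)
    t_obs <- sum(rx * ry)
    # statistic sum(rx * ry[perm]) is affine in rho given fixed marginal ranks
    t_all <- as.vector(matrix(ry[perms], nrow(perms)) %*% rx)
    centre <- n * mean(rx) * mean(ry)
    p <- mean(abs(t_all - centre) >= abs(t_obs - centre) - 1e-9)
    method <- "exact permutation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, method = method)
}

#' Long-format heatmap counts of collector activity
#'
#' Counts specimens per collector by decade or by province, the data
#' behind collector-activity heatmaps.  Records with an unknown decade
#' or province are omitted.
#'
#' @param ds canonical record data frame.
#' @param collectors collector names to include (canonical form); by
#'   default all.
#' @param by `"decade"` or `"province"`.
#' @param overrides optional year-override table (decade mode).
#' @param aliases optional alias table.
#' @return long data frame `name`, `decade`/`province`, `n`.
#' @export
collector_heatmap <- function(ds, collectors = NULL,
                              by = c("decade", "province"),
                              overrides = NULL, aliases = NULL) {
  by <- match.arg(by)
  years <- apply_year_overrides(ds, overrides)
  rows <- vector("list", nrow(ds))
  for (i in seq_len(nrow(ds))) {
    nm <- canonicalize_collector(disaggregate_collectors(ds$collectors_raw[i]),
                                 aliases)
    if (length(nm) == 0) next
    key <- if (by == "decade") {
      if (is.na(years[i])) NA_character_ else as.character((years[i] %/% 10) * 10)
    } else {
      ds$province[i]
    }
    rows[[i]] <- data.frame(name = nm, key = key, stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, rows)
  if (is.null(long)) {
    return(stats::setNames(
      data.frame(character(0), character(0), integer(0)),
      c("name", by, "n")
    ))
  }
  long <- long[!is.na(long$key), , drop = FALSE]
  if (!is.null(collectors)) long <- long[long$name %in% collectors, , drop = FALSE]
  agg <- stats::aggregate(list(n = rep(1L, nrow(long))),
                          by = list(name = long$name, key = long$key), FUN = sum)
  names(agg)[2] <- by
  agg <- agg[order(agg$name, agg[[by]]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}
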