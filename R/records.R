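#' @keywords internal
"_PACKAGE"

# Canonical record fields -------------------------------------------------

.record_fields <- c(
  "specimen_id", "accepted_name", "name_status", "type_status",
  "collectors_raw", "collection_year", "publication_year", "province",
  "latitude", "longitude", "native_status", "growth_form", "iucn"
)

.mandatory_fields <- c("specimen_id", "accepted_name", "type_status")

.type_status_levels <- c(
  "holotype", "isotype", "syntype", "isosyntype",
  "paratype", "isoparatype", "lectotype", "neotype"
)

# Preference order used to break earliest-specimen ties within a taxon.
.type_priority <- c(
  holotype = 1, lectotype = 2, isotype = 3, syntype = 4,
  isosyntype = 5, paratype = 6, isoparatype = 7, neotype = 8
)

.name_status_levels <- c("accepted", "synonym")

.native_status_levels <- c("strict_endemic", "near_endemic", "native_non_endemic")

.growth_form_levels <- c(
  "annual_or_biennial_herb", "perennial_herb", "perennial_climbing_herb",
  "shrub_or_subshrub", "tree", "woody_climber"
)

.iucn_levels <- c("CR", "EN", "VU", "NT", "LC", "DD", "NE")

#' Default Darwin-Core-style column mapping
#'
#' Maps the column headers of a GBIF-style occurrence export onto the
#' canonical specimen-record fields used throughout the package.  Any
#' entry can be overridden by supplying a named character vector to
#' [read_specimen_table()]: names are canonical field names, values are
#' the headers found in the file.
#'
#' @return Named character vector (field -> file header).
#' @export
dwc_column_map <- function() {
  c(
    specimen_id      = "catalogNumber",
    accepted_name    = "scientificName",
    name_status      = "taxonomicStatus",
    type_status      = "typeStatus",
    collectors_raw   = "recordedBy",
    collection_year  = "year",
    publication_year = "namePublishedInYear",
    province         = "stateProvince",
    latitude         = "decimalLatitude",
    longitude        = "decimalLongitude",
    native_status    = "establishmentMeans",
    growth_form      = "growthForm",
    iucn             = "iucnStatus"
  )
}

#' Extract the earliest four-digit year from free text
#'
#' Date ranges ("1890-1902") yield their earliest year; text with no
#' parseable four-digit year yields `NA`.
#'
#' @param x character or numeric vector.
#' @return integer vector of years (NA where unparseable).
#' @export
parse_year <- function(x) {
  if (is.numeric(x)) {
    out <- as.integer(round(x))
    out[!is.finite(x)] <- NA_integer_
    return(out)
  }
  x <- as.character(x)
  vapply(x, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return(NA_integer_)
    m <- regmatches(s, gregexpr("[0-9]{4}", s))[[1]]
    if (length(m) == 0) return(NA_integer_)
    min(as.integer(m))
  }, integer(1), USE.NAMES = FALSE)
}

.blank_to_na <- function(x) {
  x <- trimws(as.character(x))
  x[!nzchar(x) | toupper(x) %in% c("NA", "N/A")] <- NA_character_
  x
}

.check_enum <- function(x, levels, field) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf(
      "invalid %s value(s): %s", field,
      paste(unique(x[bad]), collapse = ", ")
    ), call. = FALSE)
  }
  x
}

#' Read a specimen-record table
#'
#' Reads an RFC 4180 CSV (UTF-8, header row) of type-specimen records
#' into the canonical record data frame.  Unmapped columns are ignored
#' and missing cells become `NA`, never defaults.  Records with
#' coordinates outside \eqn{[-90, 90] \times [-180, 180]} are rejected
#' with a warning; collection years in the future are set to `NA` with a
#' warning.
#'
#' @param path path to a CSV file.
#' @param column_map named character vector mapping canonical fields to
#'   file headers; defaults to [dwc_column_map()].  Only mapped columns
#'   present in the file are used.
#' @return A `data.frame` with one row per specimen record and the
#'   canonical columns (`specimen_id`, `accepted_name`, `name_status`,
#'   `type_status`, `collectors_raw`, `collection_year`,
#'   `publication_year`, `province`, `latitude`, `longitude`,
#'   `native_status`, `growth_form`, `iucn`), carrying a `provenance`
#'   attribute.
#' @export
read_specimen_table <- function(path, column_map = dwc_column_map()) {
  map <- dwc_column_map()
  map[names(column_map)] <- column_map
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = "character", fileEncoding = "UTF-8")
  ds <- as.data.frame(
    stats::setNames(rep(list(rep(NA_character_, nrow(raw))), length(.record_fields)),
                    .record_fields),
    stringsAsFactors = FALSE
  )
  for (field in .record_fields) {
    header <- map[[field]]
    if (!is.null(header) && !is.na(header) && header %in% names(raw)) {
      ds[[field]] <- .blank_to_na(raw[[header]])
    }
  }
  missing_mandatory <- .mandatory_fields[
    !vapply(.mandatory_fields, function(f) map[[f]] %in% names(raw), logical(1))
  ]
  if (nrow(raw) == 0 && ncol(raw) == 0) {
    stop("file has no header row", call. = FALSE)
  }
  if (length(missing_mandatory) > 0) {
    stop(sprintf("missing mandatory column(s): %s",
                 paste(missing_mandatory, collapse = ", ")), call. = FALSE)
  }

  ds$collection_year  <- parse_year(ds$collection_year)
  ds$publication_year <- parse_year(ds$publication_year)
  ds$latitude  <- suppressWarnings(as.numeric(ds$latitude))
  ds$longitude <- suppressWarnings(as.numeric(ds$longitude))
  ds$type_status <- tolower(trimws(ds$type_status))
  ds$name_status <- tolower(trimws(ds$name_status))
  ds$name_status[is.na(ds$name_status) | !nzchar(ds$name_status)] <- NA_character_

  dup <- ds$specimen_id[duplicated(ds$specimen_id) & !is.na(ds$specimen_id)]
  if (length(dup) > 0) {
    stop(sprintf("duplicate specimen_id: %s", paste(unique(dup), collapse = ", ")),
         call. = FALSE)
  }
  .check_enum(ds$type_status, .type_status_levels, "type_status")
  .check_enum(ds$name_status, .name_status_levels, "name_status")
  .check_enum(ds$native_status, .native_status_levels, "native_status")
  .check_enum(ds$growth_form, .growth_form_levels, "growth_form")
  .check_enum(ds$iucn, .iucn_levels, "iucn")

  bad_coord <- (!is.na(ds$latitude) & abs(ds$latitude) > 90) |
    (!is.na(ds$longitude) & abs(ds$longitude) > 180)
  if (any(bad_coord)) {
    warning(sprintf("rejected %d record(s) with out-of-range coordinates: %s",
                    sum(bad_coord),
                    paste(ds$specimen_id[bad_coord], collapse = ", ")))
    ds <- ds[!bad_coord, , drop = FALSE]
  }
  this_year <- as.integer(format(Sys.Date(), "%Y"))
  future <- !is.na(ds$collection_year) & ds$collection_year > this_year
  if (any(future)) {
    warning(sprintf("%d record(s) with collection_year in the future set to NA",
                    sum(future)))
    ds$collection_year[future] <- NA_integer_
  }
  rownames(ds) <- NULL
  attr(ds, "provenance") <- normalizePath(path, mustWork = FALSE)
  ds
}

#' Write a specimen-record table
#'
#' Inverse of [read_specimen_table()] under the default column map:
#' writing then re-reading round-trips all non-missing fields.
#'
#' @param ds canonical record data frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_specimen_table <- function(ds, path) {
  out <- ds[, .record_fields, drop = FALSE]
  names(out) <- unname(dwc_column_map()[.record_fields])
  utils::write.csv(out, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a record table
#'
#' Counts records lacking a collection year, a province or coordinates,
#' and flags each record, to quantify data incompleteness.  Validation
#' never raises on content and never mutates the input.
#'
#' @param ds canonical record data frame.
#' @return An object of class `validation_report`: a list with
#'   `n_records`, `missing_year`, `missing_province`,
#'   `missing_coordinates`, and a per-record `flags` data frame.
#' @export
validate_records <- function(ds) {
  miss_year  <- is.na(ds$collection_year)
  miss_prov  <- is.na(ds$province)
  miss_coord <- is.na(ds$latitude) | is.na(ds$longitude)
  rep <- list(
    n_records           = nrow(ds),
    missing_year        = sum(miss_year),
    missing_province    = sum(miss_prov),
    missing_coordinates = sum(miss_coord),
    flags = data.frame(
      specimen_id         = ds$specimen_id,
      missing_year        = miss_year,
      missing_province    = miss_prov,
      missing_coordinates = miss_coord,
      stringsAsFactors = FALSE
    )
  )
  class(rep) <- "validation_report"
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Specimen record validation: %d records\n", x$n_records))
  cat(sprintf("  missing collection year: %d\n", x$missing_year))
  cat(sprintf("  missing province:        %d\n", x$missing_province))
  cat(sprintf("  missing coordinates:     %d\n", x$missing_coordinates))
  invisible(x)
}

#' Serialize a validation report to JSON
#'
#' @param report a `validation_report`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
validation_report_json <- function(report, path = NULL) {
  obj <- report[c("n_records", "missing_year", "missing_province",
                  "missing_coordinates")]
  obj$flags <- report$flags
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Keep only georeferenced records
#'
#' @param ds canonical record data frame.
#' @return The subset of `ds` with both latitude and longitude present.
#'   Idempotent.
#' @export
filter_georeferenced <- function(ds) {
  keep <- !is.na(ds$latitude) & !is.na(ds$longitude)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reduce a record table to one earliest specimen per taxon
#'
#' Applies the inclusion rules used for temporal work: neotypes are
#' removed (their collection dates postdate the protologue and would
#' generate meaningless discovery lags); for each taxon only the record
#' with the earliest collection year is retained, avoiding
#' pseudoreplication from syntype/paratype series.  Records with a
#' missing collection year are excluded unless a year override resolves
#' them.  Ties on year are broken by type-status preference (holotype >
#' lectotype > isotype > syntype > isosyntype > paratype > isoparatype)
#' and then by specimen id, so output is deterministic.
#'
#' @param ds canonical record data frame.
#' @param overrides optional year-override table (see
#'   [read_year_overrides()]): a data frame with columns
#'   `collector_or_specimen_id` and `assigned_decade`.  A record whose
#'   `specimen_id` or collector string matches an override and lacks a
#'   collection year is assigned the decade midpoint (decade start + 5).
#' @return Subset data frame with at most one record per `accepted_name`
#'   and zero neotypes; the effective year used is in column
#'   `collection_year`.
#' @export
temporal_subset <- function(ds, overrides = NULL) {
  ds <- ds[is.na(ds$type_status) | ds$type_status != "neotype", , drop = FALSE]
  yr <- apply_year_overrides(ds, overrides)
  ds$collection_year <- yr
  ds <- ds[!is.na(ds$collection_year), , drop = FALSE]
  if (nrow(ds) == 0) {
    rownames(ds) <- NULL
    return(ds)
  }
  prio <- .type_priority[ds$type_status]
  prio[is.na(prio)] <- max(.type_priority) + 1
  ord <- order(ds$accepted_name, ds$collection_year, prio, ds$specimen_id)
  ds <- ds[ord, , drop = FALSE]
  keep <- !duplicated(ds$accepted_name)
  out <- ds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a year-override table
#'
#' Some historical records carry no parseable collection year but can be
#' assigned to a decade from expedition history (e.g., a collector's
#' whole output grouped under one decade).  The override table is a side
#' CSV with columns `collector_or_specimen_id` and `assigned_decade`
#' (decade start year); it is applied only in the temporal and collector
#' modules and never mutates source data.
#'
#' @param path CSV path.
#' @return data frame with the two canonical columns.
#' @export
read_year_overrides <- function(path) {
  ov <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("collector_or_specimen_id", "assigned_decade")
  if (!all(need %in% names(ov))) {
    stop("override table must have columns collector_or_specimen_id, assigned_decade",
         call. = FALSE)
  }
  ov$assigned_decade <- as.integer(ov$assigned_decade)
  ov
}

#' Apply year overrides to a record table
#'
#' Returns the effective collection year per record: the recorded year
#' where present, otherwise the midpoint (start + 5) of an overridden
#' decade matched by specimen id or by collector string, otherwise `NA`.
#'
#' @param ds canonical record data frame.
#' @param overrides override data frame or `NULL`.
#' @return integer vector of effective years.
#' @export
apply_year_overrides <- function(ds, overrides = NULL) {
  yr <- ds$collection_year
  if (is.null(overrides) || nrow(overrides) == 0) return(yr)
  for (i in seq_len(nrow(overrides))) {
    key <- overrides$collector_or_specimen_id[i]
    mid <- overrides$assigned_decade[i] + 5L
    hit <- is.na(yr) &
      (ds$specimen_id == key |
         (!is.na(ds$collectors_raw) & grepl(key, ds$collectors_raw, fixed = TRUE)))
    yr[hit] <- mid
  }
  yr
}
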