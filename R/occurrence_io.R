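#' Column-name dialects for occurrence CSV files
#'
#' Maps the package's canonical record fields to the column names found in
#' an input file. Two presets are provided: `"plain"` (`species, lon, lat,
#' year, locality`) and `"dwc"` for Darwin-Core-named exports
#' (`scientificName, decimalLongitude, decimalLatitude, year,
#' stateProvince`). Any entry can be overridden; optional fields mapped to
#' columns absent from the file are simply left empty.
#'
#' @param preset `"plain"` or `"dwc"`.
#' @param ... Named overrides, e.g. `species = "taxon"`. Valid names:
#'   `species`, `lon`, `lat`, `year`, `locality`, `locality_text`,
#'   `cultivated`, `outside_range`.
#' @return Named character vector mapping canonical field -> file column.
#' @export
occurrence_dialect <- function(preset = c("plain", "dwc"), ...) {
  preset <- match.arg(preset)
  d <- switch(preset,
    plain = c(species = "species", lon = "lon", lat = "lat", year = "year",
              locality = "locality", locality_text = "locality_text",
              cultivated = "cultivated", outside_range = "outside_range"),
    dwc = c(species = "scientificName", lon = "decimalLongitude",
            lat = "decimalLatitude", year = "year",
            locality = "stateProvince", locality_text = "locality",
            cultivated = "cultivated", outside_range = "outside_range"))
  dots <- c(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(d))
    if (length(bad)) stop("unknown dialect fields: ", paste(bad, collapse = ", "))
    d[names(dots)] <- dots
  }
  d
}

#' Read specimen occurrence records from a delimited text file
#'
#' Reads a CSV of herbarium specimen records (one row per specimen) into
#' the package's canonical occurrence table. Coordinates outside valid
#' WGS84 bounds and collection years outside a plausible range (1600 to the
#' current year) are set to missing with a warning rather than failing:
#' herbarium data are messy, and a record without usable coordinates still
#' contributes to specimen counts and (via its locality) to the
#' triage decision tree.
#'
#' @param path Path to a CSV file with a header row (UTF-8).
#' @param dialect Named mapping from [occurrence_dialect()].
#' @return A data.frame with columns `species_id`, `longitude`, `latitude`,
#'   `collection_year`, `locality_code`, `locality_text`, `is_cultivated`,
#'   `is_outside_native_range`.
#' @export
read_occurrences <- function(path, dialect = occurrence_dialect("plain")) {
  stopifnot(file.exists(path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!dialect[["species"]] %in% names(raw)) {
    stop("species column '", dialect[["species"]], "' not found in ", path)
  }
  if (nrow(raw) == 0) return(.empty_occurrences())
  col <- function(field) {
    nm <- dialect[[field]]
    if (!is.null(nm) && !is.na(nm) && nm %in% names(raw)) raw[[nm]] else rep(NA, nrow(raw))
  }
  num <- function(x, what) {
    x0 <- suppressWarnings(as.numeric(as.character(x)))
    bad <- !is.na(x) & is.na(x0)
    if (any(bad)) warning(sum(bad), " unparseable ", what, " value(s) set to NA")
    x0
  }
  lon <- num(col("lon"), "longitude")
  lat <- num(col("lat"), "latitude")
  # out-of-bounds coordinates invalidate the whole pair
  oob <- (!is.na(lon) & abs(lon) > 180) | (!is.na(lat) & abs(lat) > 90)
  if (any(oob)) {
    warning(sum(oob), " record(s) with coordinates outside WGS84 bounds set to NA")
    lon[oob] <- NA_real_
    lat[oob] <- NA_real_
  }
  yr <- suppressWarnings(as.integer(num(col("year"), "collection year")))
  bad_yr <- !is.na(yr) & (yr < 1600 | yr > as.integer(format(Sys.Date(), "%Y")))
  if (any(bad_yr)) {
    warning(sum(bad_yr), " implausible collection year(s) set to NA")
    yr[bad_yr] <- NA_integer_
  }
  flag <- function(x) {
    out <- tolower(as.character(x)) %in% c("true", "t", "1", "yes")
    out[is.na(x)] <- FALSE
    out
  }
  data.frame(
    species_id = as.character(raw[[dialect[["species"]]]]),
    longitude = lon,
    latitude = lat,
    collection_year = yr,
    locality_code = as.character(col("locality")),
    locality_text = as.character(col("locality_text")),
    is_cultivated = flag(col("cultivated")),
    is_outside_native_range = flag(col("outside_range")),
    stringsAsFactors = FALSE
  )
}

.empty_occurrences <- function() {
  data.frame(species_id = character(0), longitude = numeric(0),
             latitude = numeric(0), collection_year = integer(0),
             locality_code = character(0), locality_text = character(0),
             is_cultivated = logical(0), is_outside_native_range = logical(0),
             stringsAsFactors = FALSE)
}

#' Clean occurrence records: drop flagged records and duplicates
#'
#' Applies the standard pre-assessment cleaning rules: records flagged as
#' cultivated or as outside the species' native range are removed, and
#' exact duplicates are collapsed to one record. Herbarium duplicates are
#' sheets of the same gathering distributed to several institutions and
#' share label data, so the duplicate key is
#' `(species_id, longitude, latitude, collection_year)` with coordinates
#' rounded to `coord_dp` decimal places (default 4, about 11 m — finer than
#' typical georeference precision). The first record of each duplicate set
#' survives; input order is otherwise preserved, and the operation is
#' idempotent.
#'
#' @param records Canonical occurrence data.frame.
#' @param coord_dp Decimal places for the coordinate part of the duplicate
#'   key.
#' @param quiet Suppress the per-action message.
#' @return The cleaned data.frame (possibly 0 rows).
#' @export
clean_occurrences <- function(records, coord_dp = 4, quiet = TRUE) {
  if (nrow(records) == 0) return(records)
  flagged <- records$is_cultivated | records$is_outside_native_range
  kept <- records[!flagged, , drop = FALSE]
  key <- paste(kept$species_id,
               round(kept$longitude, coord_dp),
               round(kept$latitude, coord_dp),
               kept$collection_year, sep = "|")
  dup <- duplicated(key)
  if (!quiet) {
    message(sum(flagged), " flagged record(s) removed; ",
            sum(dup), " duplicate record(s) removed")
  }
  out <- kept[!dup, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude species whose records straddle the 180th meridian
#'
#' Range polygons and planar grids misbehave for species whose occurrences
#' wrap around the antimeridian, so such species are excluded from
#' coordinate-based approaches rather than mis-measured. A species is
#' treated as a spanner when its georeferenced longitudes include values
#' both in `(band, 180]` and in `[-180, -band)` (default band 150 degrees)
#' — a deliberately blunt sentinel test that flags every problem species
#' without attempting true range topology.
#'
#' @param occurrences Canonical occurrence data.frame (any number of
#'   species).
#' @param band Sentinel longitude in degrees (default 150).
#' @return A list with `kept` (data.frame) and `excluded_species`
#'   (character vector of species ids).
#' @export
exclude_antimeridian_spanners <- function(occurrences, band = 150) {
  stopifnot(band > 0, band < 180)
  sp <- unique(occurrences$species_id)
  spans <- vapply(sp, function(s) {
    lon <- occurrences$longitude[occurrences$species_id == s]
    lon <- lon[!is.na(lon)]
    any(lon > band & lon <= 180) && any(lon < -band & lon >= -180)
  }, logical(1))
  excluded <- sp[spans]
  kept <- occurrences[!occurrences$species_id %in% excluded, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, excluded_species = excluded)
}
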