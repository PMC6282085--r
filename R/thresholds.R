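#' IUCN criterion-B style category thresholds
#'
#' Bundle the range-size thresholds that separate the threatened Red List
#' bands (CR, EN, VU) under a criterion-B style rule set. Defaults are the
#' standard IUCN criterion B1/B2 values: extent of occurrence (EOO) bands at
#' 100 / 5000 / 20000 km^2, area of occupancy (AOO) bands at 10 / 500 /
#' 2000 km^2, and location-count bands at 1 / 5 / 10.
#'
#' Band comparisons elsewhere in the package are strict `<` against the band
#' upper bound (the "less than X" phrasing of criterion B), so a species
#' sitting exactly on a threshold falls in the less-threatened band.
#'
#' @param eoo_km2 Named numeric vector with elements `CR`, `EN`, `VU`: upper
#'   EOO bounds (km^2) of each threatened band.
#' @param aoo_km2 Named numeric vector with elements `CR`, `EN`, `VU`: upper
#'   AOO bounds (km^2).
#' @param locations Named numeric vector with elements `CR`, `EN`, `VU`:
#'   maximum number of locations compatible with each band (inclusive).
#' @return An object of class `category_thresholds` (a named list).
#' @examples
#' th <- category_thresholds()
#' th$eoo_km2[["VU"]]
#' @export
category_thresholds <- function(eoo_km2 = c(CR = 100, EN = 5000, VU = 20000),
                                aoo_km2 = c(CR = 10, EN = 500, VU = 2000),
                                locations = c(CR = 1, EN = 5, VU = 10)) {
  for (nm in c("eoo_km2", "aoo_km2", "locations")) {
    v <- get(nm)
    if (!all(c("CR", "EN", "VU") %in% names(v))) {
      stop(sprintf("`%s` must have named elements CR, EN, VU", nm))
    }
    v <- v[c("CR", "EN", "VU")]
    if (any(!is.finite(v)) || any(diff(v) <= 0)) {
      stop(sprintf("`%s` thresholds must be finite and strictly increasing CR < EN < VU", nm))
    }
    assign(nm, v)
  }
  structure(list(eoo_km2 = eoo_km2, aoo_km2 = aoo_km2, locations = locations),
            class = "category_thresholds")
}

#' @export
print.category_thresholds <- function(x, ...) {
  cat("Criterion-B category thresholds (band upper bounds, strict '<'):\n")
  m <- rbind(`EOO km^2` = x$eoo_km2, `AOO km^2` = x$aoo_km2,
             `locations (<=)` = x$locations)
  print(m)
  invisible(x)
}

# Ordered category levels, most threatened first. Used for band arithmetic.
.iucn_levels <- c("CR", "EN", "VU", "NT", "LC")
.threatened_levels <- c("CR", "EN", "VU", "PotentiallyExtinct", "PotentiallyThreatened")
.not_threatened_levels <- c("NT", "LC", "NotThreatened")

# Band of a range metric under strict '<' against the upper bounds.
# Returns "CR", "EN", "VU" or NA (NA = exceeds the VU bound).
.metric_band <- function(value, bounds) {
  band <- rep(NA_character_, length(value))
  band[value < bounds[["VU"]]] <- "VU"
  band[value < bounds[["EN"]]] <- "EN"
  band[value < bounds[["CR"]]] <- "CR"
  band
}
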