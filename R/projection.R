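#' Equal-area projection used for all range-metric geometry
#'
#' Projects WGS84 longitude/latitude to planar kilometres with a Lambert
#' azimuthal equal-area projection on the authalic sphere, centred on the
#' (supplied or computed) centroid of the points. Equal-area is the one
#' property EOO and AOO computations need; centring the projection on the
#' data keeps shape distortion negligible over the span of a species range,
#' so straight projected edges stay close to geodesics and hull areas agree
#' with geodesic polygon areas to well under a percent for ranges up to a
#' couple of thousand kilometres across.
#'
#' @param lon,lat Numeric vectors of equal length, decimal degrees WGS84.
#' @param lon0,lat0 Projection centre in degrees; default to the centroid
#'   (mean) of the points.
#' @return A data.frame with columns `x`, `y` in kilometres.
#' @keywords internal
equal_area_project <- function(lon, lat, lon0 = NULL, lat0 = NULL) {
  stopifnot(length(lon) == length(lat))
  if (length(lon) == 0) return(data.frame(x = numeric(0), y = numeric(0)))
  if (is.null(lon0)) lon0 <- mean(lon)
  if (is.null(lat0)) lat0 <- mean(lat)
  R <- 6371.0071809  # authalic Earth radius, km
  rad <- pi / 180
  dl <- ((lon - lon0 + 180) %% 360 - 180) * rad  # wrap into [-180, 180)
  phi <- lat * rad
  phi0 <- lat0 * rad
  c0 <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)
  c0 <- pmax(c0, 1e-12)  # antipode guard
  k <- sqrt(2 / c0)
  data.frame(x = R * k * cos(phi) * sin(dl),
             y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl)))
}

# Shoelace (surveyor's) polygon area for a planar ring given as x/y vectors.
# Vertices in order, ring need not be explicitly closed. Returns absolute area.
.shoelace_area <- function(x, y) {
  n <- length(x)
  if (n < 3) return(0)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Drop NA coordinate pairs; returns a two-column data.frame lon/lat.
.complete_coords <- function(lon, lat) {
  keep <- !is.na(lon) & !is.na(lat)
  data.frame(lon = lon[keep], lat = lat[keep])
}
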