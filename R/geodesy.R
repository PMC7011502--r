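# Spherical-earth geodesy. All distances in km, all coordinates WGS84
# lon/lat degrees. Mean earth radius (IUGG R1).
EARTH_RADIUS_KM <- 6371.0088

DEG2RAD <- pi / 180

#' Great-circle distance between points
#'
#' Haversine distance on a sphere of radius 6371.0088 km. Vectorized over
#' all arguments.
#'
#' @param lon1,lat1 Coordinates of the first point(s), degrees.
#' @param lon2,lat2 Coordinates of the second point(s), degrees.
#' @return Distance(s) in km.
#' @export
geodesic_distance_km <- function(lon1, lat1, lon2, lat2) {
  phi1 <- lat1 * DEG2RAD
  phi2 <- lat2 * DEG2RAD
  dphi <- (lat2 - lat1) * DEG2RAD
  dlam <- (lon2 - lon1) * DEG2RAD
  a <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

#' Offset a point by a bearing and distance
#'
#' Forward geodesic on a spherical earth: moves a lon/lat point a given
#' distance along a given bearing (clockwise from north). Used to convert a
#' simulated geomask displacement into coordinates. At displacement scales
#' relevant to geomasking (<= 10 km) the spherical formula differs from a
#' full ellipsoidal geodesic by well under 0.1%.
#'
#' @param lon,lat Origin coordinates, degrees. Vectorized.
#' @param bearing_rad Bearing in radians, clockwise from north, in
#'   `[0, 2*pi)`.
#' @param distance_km Displacement distance in km (0 to 150).
#' @return A data.frame with columns `lon`, `lat`.
#' @export
offset_point <- function(lon, lat, bearing_rad, distance_km) {
  if (any(distance_km < 0)) stop("distance_km must be nonnegative")
  if (any(distance_km > 150)) stop("distance_km above 150 km sanity bound")
  if (any(abs(lat) > 89)) stop("unsupported region: |lat| > 89 degrees")
  phi1 <- lat * DEG2RAD
  lam1 <- lon * DEG2RAD
  delta <- distance_km / EARTH_RADIUS_KM
  phi2 <- asin(sin(phi1) * cos(delta) + cos(phi1) * sin(delta) * cos(bearing_rad))
  lam2 <- lam1 + atan2(
    sin(bearing_rad) * sin(delta) * cos(phi1),
    cos(delta) - sin(phi1) * sin(phi2)
  )
  lam2 <- (lam2 + pi) %% (2 * pi) - pi
  data.frame(lon = lam2 / DEG2RAD, lat = phi2 / DEG2RAD)
}

# Local planar (equirectangular) projection about a reference point, in km.
# Adequate for the sub-10-km scales of geomask displacement and snapping.
local_xy_km <- function(lon, lat, lon0, lat0) {
  kx <- EARTH_RADIUS_KM * DEG2RAD * cos(lat0 * DEG2RAD)
  ky <- EARTH_RADIUS_KM * DEG2RAD
  cbind(x = (lon - lon0) * kx, y = (lat - lat0) * ky)
}
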