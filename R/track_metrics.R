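#' Great-circle distance (haversine)
#'
#' Shortest distance between two points on a sphere of mean Earth radius.
#' This is the distance definition used for migration distances throughout
#' the package.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84,
#'   longitude east-positive). Vectorised.
#' @param radius_km Sphere radius, km (default mean Earth radius 6371).
#' @return Distance(s) in km.
#' @export
#' @examples
#' haversine(0, 0, 0, 180)             # pi * 6371
#' haversine(56.2328, 16.4111, 55.2328, 16.4111)  # one degree of meridian
haversine <- function(lat1, lon1, lat2, lon2, radius_km = 6371) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 360))
  p <- .deg2rad
  dlat <- (lat2 - lat1) * p
  dlon <- (lon2 - lon1) * p
  h <- sin(dlat / 2)^2 + cos(lat1 * p) * cos(lat2 * p) * sin(dlon / 2)^2
  2 * radius_km * asin(pmin(1, sqrt(h)))
}

#' Total route distance along an ordered set of points
#'
#' Sum of consecutive great-circle legs, e.g. breeding site, mean stopover
#' positions, wintering site.
#'
#' @param points data.frame with columns `lat`, `lon` (decimal degrees), in
#'   travel order.
#' @param radius_km Sphere radius, km.
#' @return Route length in km.
#' @export
route_distance <- function(points, radius_km = 6371) {
  stopifnot(is.data.frame(points), all(c("lat", "lon") %in% names(points)),
            nrow(points) >= 2)
  n <- nrow(points)
  sum(haversine(points$lat[-n], points$lon[-n],
                points$lat[-1], points$lon[-1], radius_km))
}

#' Detour index of a route
#'
#' Ratio of the summed leg distances to the direct great-circle distance
#' between the route endpoints. 1 means no detour; the ratio is >= 1 up to
#' numerical tolerance.
#'
#' @param points data.frame with `lat`, `lon` in travel order (>= 2 rows).
#' @param origin,destination Optional `c(lat, lon)` endpoints; default the
#'   first and last rows of `points`.
#' @param radius_km Sphere radius, km.
#' @return A list with `endpoint_distance_km`, `route_distance_km` and
#'   `detour_index` (NA with a warning when origin equals destination).
#' @export
detour_index <- function(points, origin = NULL, destination = NULL,
                         radius_km = 6371) {
  if (is.null(origin)) origin <- c(points$lat[1], points$lon[1])
  if (is.null(destination)) {
    destination <- c(points$lat[nrow(points)], points$lon[nrow(points)])
  }
  d0 <- haversine(origin[1], origin[2], destination[1], destination[2],
                  radius_km)
  dr <- route_distance(points, radius_km)
  if (d0 == 0) {
    warning("origin equals destination; detour index undefined")
    idx <- NA_real_
  } else {
    idx <- dr / d0
  }
  list(endpoint_distance_km = d0, route_distance_km = dr, detour_index = idx)
}

# Spherical linear interpolation along the great circle from p1 to p2.
# frac in [0,1]; returns cbind(lat, lon). Undefined for antipodal endpoints.
.gc_interpolate <- function(lat1, lon1, lat2, lon2, frac) {
  p <- .deg2rad
  a <- c(cos(lat1 * p) * cos(lon1 * p), cos(lat1 * p) * sin(lon1 * p),
         sin(lat1 * p))
  b <- c(cos(lat2 * p) * cos(lon2 * p), cos(lat2 * p) * sin(lon2 * p),
         sin(lat2 * p))
  ang <- acos(min(1, max(-1, sum(a * b))))
  if (ang < 1e-12) {
    return(cbind(lat = rep(lat1, length(frac)), lon = rep(lon1, length(frac))))
  }
  if (ang > pi - 1e-6) stop("antipodal endpoints: great circle is ambiguous")
  w1 <- sin((1 - frac) * ang) / sin(ang)
  w2 <- sin(frac * ang) / sin(ang)
  x <- w1 * a[1] + w2 * b[1]
  y <- w1 * a[2] + w2 * b[2]
  z <- w1 * a[3] + w2 * b[3]
  cbind(lat = asin(pmin(1, pmax(-1, z))) / p, lon = atan2(y, x) / p)
}
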