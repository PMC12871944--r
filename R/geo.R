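EARTH_RADIUS_M <- 6371000

#' Haversine great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance in meters.
#' @examples
#' haversine_m(0, 0, 0, 180) # half the Earth circumference
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(!is.finite(c(lat1, lon1, lat2, lon2)))) {
    stop_phenosense("Coordinates must be finite.",
                    "phenosense_validation_error")
  }
  if (any(abs(c(lat1, lat2)) > 90)) {
    stop_phenosense("Latitudes must lie in [-90, 90].",
                    "phenosense_validation_error")
  }
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad / 2
  dlon <- (lon2 - lon1) * rad / 2
  a <- sin(dlat)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon)^2
  a <- pmin(pmax(a, 0), 1)
  2 * EARTH_RADIUS_M * asin(sqrt(a))
}

#' Filter spurious GPS jumps by implied speed
#'
#' Scans a chronologically sorted track and drops every fix whose implied
#' speed from the previously *retained* fix exceeds `max_speed_kmh`. The
#' first fix is always retained.
#'
#' @param track A data frame with `hour` (decimal hour of day), `lat`, `lon`;
#'   sorted by time.
#' @param max_speed_kmh Speed threshold, default 200 km/h.
#' @return The filtered track.
#' @export
filter_gps_jumps <- function(track, max_speed_kmh = 200) {
  n <- nrow(track)
  if (n <= 1L) return(track)
  keep <- logical(n)
  keep[1] <- TRUE
  last <- 1L
  for (i in 2:n) {
    dt_h <- track$hour[i] - track$hour[last]
    d_km <- haversine_m(track$lat[last], track$lon[last],
                        track$lat[i], track$lon[i]) / 1000
    # Zero/negative time gaps: any displacement is an infinite-speed jump.
    speed <- if (dt_h <= 0) ifelse(d_km > 0, Inf, 0) else d_km / dt_h
    if (speed <= max_speed_kmh) {
      keep[i] <- TRUE
      last <- i
    }
  }
  track[keep, , drop = FALSE]
}

# Grid cell ids: lat/lon rounded to 3 decimals (~111 m cells).
grid_cell <- function(lat, lon, digits = 3) {
  paste0(round(lat, digits), ":", round(lon, digits))
}

#' Infer a user's home grid cell
#'
#' Home is the modal ~111 m grid cell among night-window fixes across the
#' whole study; ties are broken by the earliest-observed cell. With no
#' nighttime fixes the modal overall cell is used; with no fixes at all the
#' home is undefined (`NULL`) and home-dependent features emit the sentinel.
#'
#' @param fixes Data frame of all of one user's GPS fixes: `day`, `hour`,
#'   `lat`, `lon`.
#' @param digits Grid resolution in decimal places.
#' @return A list with `lat`, `lon`, `cell`, or `NULL` if no fixes exist.
#' @export
infer_home <- function(fixes, digits = 3) {
  if (is.null(fixes) || nrow(fixes) == 0L) return(NULL)
  ord <- order(fixes$day, fixes$hour)
  fixes <- fixes[ord, , drop = FALSE]
  pool <- fixes[is_night_hour(fixes$hour), , drop = FALSE]
  if (nrow(pool) == 0L) pool <- fixes
  cells <- grid_cell(pool$lat, pool$lon, digits)
  counts <- table(factor(cells, levels = unique(cells))) # unique() keeps
  best <- names(counts)[which.max(counts)]               # first-seen order,
  i <- match(best, cells)                                # so ties -> earliest
  list(lat = round(pool$lat[i], digits), lon = round(pool$lon[i], digits),
       cell = best)
}

#' Radius of gyration of a GPS track
#'
#' Root-mean-square haversine distance of the fixes from their centroid
#' (arithmetic mean latitude/longitude); order-invariant.
#'
#' @param track Data frame with `lat`, `lon`.
#' @return Meters, or the sentinel for an empty track.
#' @export
radius_of_gyration <- function(track) {
  if (is.null(track) || nrow(track) == 0L) return(SENTINEL)
  clat <- mean(track$lat)
  clon <- mean(track$lon)
  sqrt(mean(haversine_m(track$lat, track$lon, clat, clon)^2))
}

#' Shannon location entropy of a GPS track
#'
#' Entropy (nats) of the distribution of fixes over ~111 m grid cells.
#'
#' @param track Data frame with `lat`, `lon`.
#' @param digits Grid resolution in decimal places.
#' @return Nats, or the sentinel for an empty track.
#' @export
location_entropy <- function(track, digits = 3) {
  if (is.null(track) || nrow(track) == 0L) return(SENTINEL)
  p <- as.numeric(table(grid_cell(track$lat, track$lon, digits)))
  p <- p / sum(p)
  -sum(p * log(p))
}
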