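#' Great-circle distance between coordinates
#'
#' Haversine distance on a sphere of radius 6371.0 km (mean Earth radius).
#' Vectorised over all four coordinate arguments.
#'
#' @param lat1,lon1,lat2,lon2 Numeric vectors of decimal-degree coordinates
#'   (latitudes in \[-90, 90\], longitudes in \[-180, 180\]).
#' @param radius_km Sphere radius; defaults to 6371.0 km.
#' @return Numeric vector of distances in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2, radius_km = 6371.0) {
  check_coords(lat1, lon1)
  check_coords(lat2, lon2)
  rad <- pi / 180
  dlat <- (lat2 - lat1) * rad
  dlon <- (lon2 - lon1) * rad
  a <- sin(dlat / 2)^2 + cos(lat1 * rad) * cos(lat2 * rad) * sin(dlon / 2)^2
  # guard tiny negative / >1 from roundoff before asin
  a <- pmin(1, pmax(0, a))
  2 * radius_km * asin(sqrt(a))
}

check_coords <- function(lat, lon) {
  bad <- which(!is.na(lat) & abs(lat) > 90)
  if (length(bad)) stop("latitude out of range [-90, 90] at position ", bad[1L])
  bad <- which(!is.na(lon) & abs(lon) > 180)
  if (length(bad)) stop("longitude out of range [-180, 180] at position ", bad[1L])
  invisible(TRUE)
}

#' Map each herd to its nearest weather station
#'
#' Computes all pairwise great-circle distances and assigns every herd to the
#' station at minimal distance. Ties are broken deterministically by the
#' lowest station id (in sort order).
#'
#' @param herds data.frame with columns `herd_id`, `lat`, `lon`.
#' @param stations data.frame with columns `station_id`, `lat`, `lon`.
#' @return data.frame with columns `herd_id`, `station_id`, `distance_km`,
#'   one row per herd.
#' @export
assign_nearest_station <- function(herds, stations) {
  stopifnot(is.data.frame(herds), all(c("herd_id", "lat", "lon") %in% names(herds)))
  stopifnot(is.data.frame(stations),
            all(c("station_id", "lat", "lon") %in% names(stations)))
  if (nrow(stations) < 1L) stop("at least one weather station is required")
  # stable tie-break: evaluate stations in id order so which.min picks lowest
  ord <- order(stations$station_id)
  stations <- stations[ord, , drop = FALSE]
  d <- outer(seq_len(nrow(herds)), seq_len(nrow(stations)),
             function(i, j) haversine_km(herds$lat[i], herds$lon[i],
                                         stations$lat[j], stations$lon[j]))
  k <- apply(d, 1L, which.min)
  data.frame(herd_id = herds$herd_id,
             station_id = stations$station_id[k],
             distance_km = d[cbind(seq_len(nrow(herds)), k)],
             stringsAsFactors = FALSE)
}
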