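# Shared geometry and RNG plumbing.

#' Great-circle distance in kilometres
#'
#' Haversine distance on a sphere of radius 6371 km. All coordinates are
#' WGS84 decimal degrees. Inputs are recycled to a common length.
#'
#' @param lat1,lon1 Coordinates of the first point(s).
#' @param lat2,lon2 Coordinates of the second point(s).
#' @return Numeric vector of distances in km.
#' @export
#' @examples
#' haversine_km(29.5, -90, 29.5, -89) # ~96.7 km along a parallel
haversine_km <- function(lat1, lon1, lat2, lon2) {
  n <- max(length(lat1), length(lon1), length(lat2), length(lon2))
  p1 <- cbind(rep_len(lon1, n), rep_len(lat1, n))
  p2 <- cbind(rep_len(lon2, n), rep_len(lat2, n))
  as.numeric(geosphere::distHaversine(p1, p2, r = 6371000)) / 1000
}

# Named substreams off one root seed so partial pipelines are reproducible.
# Offsets are arbitrary fixed constants; result kept inside 32-bit range.
substream_seed <- function(seed, stream) {
  offsets <- c(sites = 101L, gauges = 211L, inventory = 307L,
               scenarios = 401L, projection = 503L)
  if (!stream %in% names(offsets)) {
    stop("unknown RNG substream: ", stream, call. = FALSE)
  }
  (as.integer(seed) %% 1000000L) * 2011L + offsets[[stream]]
}

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop("`", name, "` must be finite numeric", call. = FALSE)
  }
  if (any(x < lower) || any(x > upper)) {
    stop("`", name, "` must lie in [", lower, ", ", upper, "]", call. = FALSE)
  }
  invisible(x)
}
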