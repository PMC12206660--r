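# Internal helpers shared across modules.

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic package operations funnel through
# this so that results are reproducible and never perturb the user's RNG.
withSeed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Derive a child seed from a parent seed and a stage index, staying within
# 32-bit integer range.
childSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + 104729 * as.numeric(k)) %% 2147483647L)
}

# Cell-center coordinate vectors (km) for a grid spec.
gridCoords <- function(grid) {
  list(x = grid$xll + (seq_len(grid$nx) - 0.5) * grid$cellSize,
       y = grid$yll + (grid$ny - seq_len(grid$ny) + 0.5) * grid$cellSize)
}

# Map point coordinates (km) to (row, col) on a grid; NA outside the grid.
pointToCell <- function(grid, x, y) {
  col <- floor((x - grid$xll) / grid$cellSize) + 1
  row <- grid$ny - floor((y - grid$yll) / grid$cellSize)
  bad <- col < 1 | col > grid$nx | row < 1 | row > grid$ny
  col[bad] <- NA_integer_
  row[bad] <- NA_integer_
  list(row = as.integer(row), col = as.integer(col))
}

#' Convert local projected km to latitude/longitude and back
#'
#' Local equirectangular conversion with cos-latitude scaling around a fixed
#' origin. Intended for small study domains (a few hundred km) where a full
#' geodesic projection is unnecessary; distances in the km plane are metric.
#'
#' @param x,y coordinates in km east/north of the origin
#' @param lat,lon coordinates in decimal degrees
#' @param originLat,originLon origin of the local plane (decimal degrees)
#' @return `kmToLatLon`: data.frame with `lat`, `lon`; `latLonToKm`:
#'   data.frame with `x`, `y` in km.
#' @examples
#' ll <- kmToLatLon(10, 5)
#' latLonToKm(ll$lat, ll$lon)
#' @export
kmToLatLon <- function(x, y, originLat = 24.5, originLon = -82.0) {
  lat <- originLat + y / 110.574
  lon <- originLon + x / (111.320 * cos(originLat * pi / 180))
  data.frame(lat = lat, lon = lon)
}

#' @rdname kmToLatLon
#' @export
latLonToKm <- function(lat, lon, originLat = 24.5, originLon = -82.0) {
  y <- (lat - originLat) * 110.574
  x <- (lon - originLon) * 111.320 * cos(originLat * pi / 180)
  data.frame(x = x, y = y)
}

# logit / inverse logit
logit <- function(p) log(p / (1 - p))
invlogit <- function(x) 1 / (1 + exp(-x))
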