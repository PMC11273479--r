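# WGS84 transverse Mercator (UTM) without external projection libraries.
# Forward/inverse use the Krueger series in the third flattening n, carried to
# n^6, which is accurate to well below 1 mm over a UTM zone.

.wgs84 <- list(a = 6378137.0, f = 1 / 298.257223563)

.tm_consts <- local({
  f <- .wgs84$f
  n <- f / (2 - f)
  e2 <- f * (2 - f)
  A <- .wgs84$a / (1 + n) * (1 + n^2 / 4 + n^4 / 64 + n^6 / 256)
  alpha <- c(
    n / 2 - 2 * n^2 / 3 + 5 * n^3 / 16 + 41 * n^4 / 180 - 127 * n^5 / 288 + 7891 * n^6 / 37800,
    13 * n^2 / 48 - 3 * n^3 / 5 + 557 * n^4 / 1440 + 281 * n^5 / 630 - 1983433 * n^6 / 1935360,
    61 * n^3 / 240 - 103 * n^4 / 140 + 15061 * n^5 / 26880 + 167603 * n^6 / 181440,
    49561 * n^4 / 161280 - 179 * n^5 / 168 + 6601661 * n^6 / 7257600,
    34729 * n^5 / 80640 - 3418889 * n^6 / 1995840,
    212378941 * n^6 / 319334400
  )
  beta <- c(
    n / 2 - 2 * n^2 / 3 + 37 * n^3 / 96 - n^4 / 360 - 81 * n^5 / 512 + 96199 * n^6 / 604800,
    n^2 / 48 + n^3 / 15 - 437 * n^4 / 1440 + 46 * n^5 / 105 - 1118711 * n^6 / 3870720,
    17 * n^3 / 480 - 37 * n^4 / 840 - 209 * n^5 / 4480 + 5569 * n^6 / 90720,
    4397 * n^4 / 161280 - 11 * n^5 / 504 - 830251 * n^6 / 7257600,
    4583 * n^5 / 161280 - 108847 * n^6 / 3991680,
    20648693 * n^6 / 638668800
  )
  list(n = n, e = sqrt(e2), A = A, alpha = alpha, beta = beta, k0 = 0.9996)
})

#' UTM zone containing a longitude
#'
#' @param lon Longitude in decimal degrees.
#' @return Integer UTM zone (1-60).
#' @export
utm_zone <- function(lon) {
  as.integer(floor((lon + 180) / 6) %% 60) + 1L
}

#' Project longitude/latitude to planar UTM kilometres
#'
#' Converts geographic coordinates to the universal transverse Mercator grid
#' (WGS84, scale factor 0.9996, false easting 500 km). One zone is used for
#' the whole dataset so that all points share a single planar system; by
#' default the zone containing the mean longitude.
#'
#' @param lon,lat Numeric vectors of coordinates in decimal degrees.
#' @param zone UTM zone to project into; default derived from `mean(lon)`.
#' @return A data.frame with columns `x`, `y` (kilometres) and attribute
#'   `zone`. Round-tripping through [plane_to_lonlat()] reproduces the inputs
#'   to well below 1e-5 degrees.
#' @seealso [plane_to_lonlat()]
#' @export
project_to_plane <- function(lon, lat, zone = NULL) {
  if (length(lon) != length(lat)) stop("lon and lat must have equal length")
  if (any(!is.finite(lon)) || any(!is.finite(lat))) stop("coordinates must be finite")
  if (any(abs(lon) > 180) || any(abs(lat) > 90)) {
    stop("coordinates out of range: |lon| <= 180, |lat| <= 90 required")
  }
  if (is.null(zone)) zone <- utm_zone(mean(lon))
  cst <- .tm_consts
  lon0 <- (zone * 6 - 183) * pi / 180
  phi <- lat * pi / 180
  lam <- lon * pi / 180 - lon0
  e <- cst$e
  # conformal latitude
  t <- sinh(asinh(tan(phi)) - e * atanh(e * sin(phi)))
  xi_p <- atan2(t, cos(lam))
  eta_p <- asinh(sin(lam) / sqrt(t^2 + cos(lam)^2))
  xi <- xi_p
  eta <- eta_p
  for (j in 1:6) {
    xi <- xi + cst$alpha[j] * sin(2 * j * xi_p) * cosh(2 * j * eta_p)
    eta <- eta + cst$alpha[j] * cos(2 * j * xi_p) * sinh(2 * j * eta_p)
  }
  easting <- cst$k0 * cst$A * eta + 500000
  northing <- cst$k0 * cst$A * xi
  out <- data.frame(x = easting / 1000, y = northing / 1000)
  attr(out, "zone") <- zone
  out
}

#' Inverse UTM projection back to longitude/latitude
#'
#' @param x,y Planar coordinates in kilometres as produced by
#'   [project_to_plane()].
#' @param zone UTM zone the coordinates live in.
#' @return data.frame with columns `lon`, `lat` in decimal degrees.
#' @export
plane_to_lonlat <- function(x, y, zone) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  cst <- .tm_consts
  lon0 <- (zone * 6 - 183) * pi / 180
  xi <- (y * 1000) / (cst$k0 * cst$A)
  eta <- (x * 1000 - 500000) / (cst$k0 * cst$A)
  xi_p <- xi
  eta_p <- eta
  for (j in 1:6) {
    xi_p <- xi_p - cst$beta[j] * sin(2 * j * xi) * cosh(2 * j * eta)
    eta_p <- eta_p - cst$beta[j] * cos(2 * j * xi) * sinh(2 * j * eta)
  }
  tau_p <- sin(xi_p) / sqrt(sinh(eta_p)^2 + cos(xi_p)^2)
  lam <- atan2(sinh(eta_p), cos(xi_p))
  e <- cst$e
  # Newton solve tau from conformal tau'
  tau <- tau_p
  for (it in 1:8) {
    sigma <- sinh(e * atanh(e * tau / sqrt(1 + tau^2)))
    ftau <- tau * sqrt(1 + sigma^2) - sigma * sqrt(1 + tau^2) - tau_p
    dftau <- (sqrt((1 + sigma^2) * (1 + tau^2)) - sigma * tau) *
      (1 - e^2) * sqrt(1 + tau^2) / (1 + (1 - e^2) * tau^2)
    tau <- tau - ftau / dftau
  }
  data.frame(
    lon = (lam + lon0) * 180 / pi,
    lat = atan(tau) * 180 / pi
  )
}
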