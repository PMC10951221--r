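#' Zone geometry of an 8-zone pressure insole
#'
#' An insole reports one force per anatomical zone; the center of pressure is
#' the force-weighted centroid of the zone coordinates. A `zone_geometry`
#' holds the mediolateral (ML) and anteroposterior (AP) coordinate, in mm,
#' of each of the 8 zones, in the same order as the force columns of an
#' [insole_recording()].
#'
#' The ML sign convention is positive = lateral (away from the body midline),
#' so left and right feet are mirror-consistent. AP is measured from the heel
#' end of the insole, positive towards the toes.
#'
#' @param ml,ap Numeric vectors of length 8: zone coordinates in mm.
#' @param zone_names Character vector of length 8 of anatomical labels.
#' @return A `zone_geometry`: a data.frame with columns `zone`, `ml`, `ap`.
#' @export
zone_geometry <- function(ml, ap, zone_names = default_zone_names()) {
  stopifnot(length(ml) == 8L, length(ap) == 8L, length(zone_names) == 8L)
  if (anyDuplicated(cbind(ml, ap)))
    stop("zone geometry: the 8 (ml, ap) coordinate pairs must be distinct")
  if (!all(is.finite(ml)) || !all(is.finite(ap)))
    stop("zone geometry: coordinates must be finite")
  hull <- grDevices::chull(ml, ap)
  if (length(hull) < 3L || polygon_area(ml[hull], ap[hull]) <= 0)
    stop("zone geometry: zones must span a convex hull of positive area")
  structure(
    data.frame(zone = zone_names, ml = as.numeric(ml), ap = as.numeric(ap),
               stringsAsFactors = FALSE),
    class = c("zone_geometry", "data.frame"))
}

default_zone_names <- function() {
  c("big_toe", "smaller_toes", "metatarsal_1_2", "metatarsal_3_4",
    "medial_arch", "lateral_arch", "medial_heel", "lateral_heel")
}

#' Default 8-zone insole layout
#'
#' A documented anatomically plausible layout on a ~100 mm (ML) x 250 mm (AP)
#' insole footprint. Vendors do not publish zone coordinates, so the geometry
#' is a configurable parameter of every COP computation; this default is only
#' a reasonable stand-in with the correct medial/lateral ordering.
#'
#' @return A [zone_geometry()].
#' @export
default_zone_geometry <- function() {
  zone_geometry(
    ml = c(-15, 18, -18, 20, -14, 26, -16, 18),
    ap = c(228, 215, 175, 168, 115, 105, 35, 32))
}

# Shoelace area of a polygon given vertex coordinates in order.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# TRUE for points inside (or on) the convex hull of the geometry points.
# tol is an absolute slack in mm on the signed distance to each edge.
in_zone_hull <- function(ml, ap, geom, tol = 1e-6) {
  hull <- grDevices::chull(geom$ml, geom$ap)
  hx <- geom$ml[hull]; hy <- geom$ap[hull]
  n <- length(hull)
  ok <- rep(TRUE, length(ml))
  # chull() returns vertices clockwise; interior points then have
  # non-positive cross products along every edge
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    len <- sqrt((hx[j] - hx[i])^2 + (hy[j] - hy[i])^2)
    cr <- (hx[j] - hx[i]) * (ap - hy[i]) - (hy[j] - hy[i]) * (ml - hx[i])
    ok <- ok & (cr / len <= tol)
  }
  ok
}
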