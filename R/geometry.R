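# Closest-approach geometry between telemetry and turbine hubs.
#
# Distances follow the 2-D-first convention: the closest pass of a flight
# line to a hub is located in the horizontal plane, the bird's altitude is
# linearly interpolated to that pass point, and the 3-D distance follows by
# trigonometry from the horizontal distance and the altitude difference to
# the hub. This is deliberately not the true 3-D minimum over the segment;
# it is conservative (never larger than the per-endpoint distances in 2-D).

#' Closest 2-D approach of a point to a segment
#'
#' Vectorised over all arguments. The foot of the perpendicular from the
#' point `(px, py)` onto the infinite line through `(ax, ay)`–`(bx, by)` is
#' clamped to the segment; degenerate (zero-length) segments reduce to the
#' point–point distance with `fraction = 0`.
#'
#' @param px,py Point coordinates (planar metres).
#' @param ax,ay,bx,by Segment endpoint coordinates (planar metres).
#' @return A tibble with `fraction` (position of the closest pass along the
#'   segment, in `[0, 1]`) and `d2d` (metres).
#' @export
closest_approach_2d <- function(px, py, ax, ay, bx, by) {
  for (nm in c("px", "py", "ax", "ay", "bx", "by")) {
    assert_finite(get(nm), nm)
  }
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  # raw projection parameter; 0 for degenerate segments
  t_raw <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  fraction <- pmin(1, pmax(0, t_raw))
  cx <- ax + fraction * dx
  cy <- ay + fraction * dy
  tibble(fraction = fraction, d2d = sqrt((px - cx)^2 + (py - cy)^2))
}

#' Linearly interpolate altitude along a flight segment
#'
#' @param alt_start,alt_end Endpoint altitudes (metres asl).
#' @param fraction Position along the segment in `[0, 1]`.
#' @return Altitude (metres asl) at `fraction`.
#' @export
interpolate_altitude <- function(alt_start, alt_end, fraction) {
  if (any(is.na(alt_start) | is.na(alt_end))) {
    abort("segment endpoint altitude missing; cannot interpolate")
  }
  if (any(fraction < 0 | fraction > 1)) abort("fraction outside [0, 1]")
  alt_start + fraction * (alt_end - alt_start)
}

#' Hub altitude above sea level
#'
#' @param turbines Tibble with `base_elevation_asl` and `hub_height_agl`
#'   columns (metres).
#' @return Numeric vector of hub altitudes (metres asl).
#' @export
hub_altitude <- function(turbines) {
  assert_cols(turbines, c("base_elevation_asl", "hub_height_agl"), "turbines")
  if (any(is.na(turbines$base_elevation_asl) | is.na(turbines$hub_height_agl))) {
    abort("turbine base elevation or hub height missing")
  }
  if (any(turbines$hub_height_agl < 0)) abort("negative hub height")
  turbines$base_elevation_asl + turbines$hub_height_agl
}

#' Trigonometric 3-D distance from a 2-D distance and altitudes
#'
#' @param d2d Horizontal distance (metres).
#' @param alt Altitude of the bird at the closest 2-D pass (metres asl).
#' @param hub_alt Hub altitude (metres asl).
#' @return 3-D distance (metres), `sqrt(d2d^2 + (alt - hub_alt)^2)`.
#' @export
distance_3d <- function(d2d, alt, hub_alt) {
  assert_finite(d2d, "d2d"); assert_finite(alt, "alt")
  assert_finite(hub_alt, "hub_alt")
  sqrt(d2d^2 + (alt - hub_alt)^2)
}

#' 3-D approach of point fixes to a single turbine hub
#'
#' The degenerate (zero-length segment) case of [segment_to_hub()]: the 2-D
#' distance is the planar fix–hub distance and the fix's own altitude is used.
#'
#' @param fixes Tibble with `easting`, `northing`, `altitude_asl`.
#' @param turbine One-row tibble (or list) with `easting`, `northing`,
#'   `base_elevation_asl`, `hub_height_agl`.
#' @return Tibble with `fraction` (all 0), `d2d`, `alt_at_pass`, `hub_alt`,
#'   `d3d`.
#' @export
fix_to_hub_3d <- function(fixes, turbine) {
  assert_cols(fixes, c("easting", "northing", "altitude_asl"), "fixes")
  if (any(is.na(fixes$altitude_asl))) abort("fix altitude missing")
  turbine <- as_tibble(turbine)
  ha <- hub_altitude(turbine)
  ca <- closest_approach_2d(fixes$easting, fixes$northing,
                            turbine$easting, turbine$northing,
                            turbine$easting, turbine$northing)
  tibble(
    fraction = ca$fraction,
    d2d = ca$d2d,
    alt_at_pass = fixes$altitude_asl,
    hub_alt = ha,
    d3d = distance_3d(ca$d2d, fixes$altitude_asl, ha)
  )
}

#' 3-D closest approach of flight segments to a single turbine hub
#'
#' Composition of [closest_approach_2d()], [interpolate_altitude()] and
#' [distance_3d()] — the 2-D-first convention (see module header).
#'
#' @param segments Tibble with `x1`, `y1`, `alt1`, `x2`, `y2`, `alt2`
#'   (endpoint planar coordinates in metres and altitudes in metres asl).
#' @param turbine One-row tibble (or list) as in [fix_to_hub_3d()].
#' @return Tibble with `fraction`, `d2d`, `alt_at_pass`, `hub_alt`, `d3d`.
#' @export
segment_to_hub <- function(segments, turbine) {
  assert_cols(segments, c("x1", "y1", "alt1", "x2", "y2", "alt2"), "segments")
  turbine <- as_tibble(turbine)
  ha <- hub_altitude(turbine)
  ca <- closest_approach_2d(turbine$easting, turbine$northing,
                            segments$x1, segments$y1,
                            segments$x2, segments$y2)
  alt <- interpolate_altitude(segments$alt1, segments$alt2, ca$fraction)
  tibble(
    fraction = ca$fraction,
    d2d = ca$d2d,
    alt_at_pass = alt,
    hub_alt = ha,
    d3d = distance_3d(ca$d2d, alt, ha)
  )
}
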