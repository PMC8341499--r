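# Fix-level quality control for raptor GPS telemetry.
#
# A "fix" is one GPS record of one tagged bird: planar easting/northing (m),
# geographic lat/lon (degrees), altitude above sea level (m), horizontal
# dilution of precision (HDOP) and the tag type (GSM tags fix at up to
# 1/min, Argos-relay tags at most hourly).

#' Read raw GPS tag fixes from delimited text
#'
#' Reads a telemetry table (CSV or TSV, autodetected from the header line
#' unless `delim` is given), renames columns to the package's canonical names
#' through `dialect`, parses timestamps as UTC, drops unparseable rows with a
#' warning, and collapses duplicated (bird, timestamp) keys to the first
#' occurrence.
#'
#' @param path Path to a delimited text file.
#' @param dialect Named character vector mapping canonical names
#'   (`bird_id`, `timestamp`, `easting`, `northing`, `lat`, `lon`,
#'   `altitude_asl`, `hdop`, `tag_type`) to the column names used in the file.
#'   Canonical names already present in the file need not be mapped.
#' @param delim Field delimiter; `NULL` (default) autodetects `","` vs `"\t"`.
#'
#' @return A tibble of fixes sorted by (`bird_id`, `timestamp`), one row per
#'   retained fix, with attribute `"n_duplicates"` giving the number of
#'   collapsed duplicate rows.
#' @export
read_fixes <- function(path, dialect = NULL, delim = NULL) {
  if (!file.exists(path)) abort(sprintf("telemetry file not found: %s", path))
  if (is.null(delim)) {
    header <- readLines(path, n = 1L)
    delim <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default = readr::col_character()))
  for (canon in names(dialect)) {
    src <- dialect[[canon]]
    if (!src %in% names(raw)) {
      abort(sprintf("dialect maps `%s` to column `%s`, absent from %s",
                    canon, src, path))
    }
    names(raw)[names(raw) == src] <- canon
  }
  required <- c("bird_id", "timestamp", "easting", "northing",
                "lat", "lon", "altitude_asl", "hdop", "tag_type")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("telemetry file lacks column(s) %s; supply a `dialect` mapping",
                  paste(missing, collapse = ", ")))
  }

  fixes <- raw %>%
    mutate(
      timestamp    = readr::parse_datetime(.data$timestamp),
      easting      = as.numeric(.data$easting),
      northing     = as.numeric(.data$northing),
      lat          = as.numeric(.data$lat),
      lon          = as.numeric(.data$lon),
      altitude_asl = as.numeric(.data$altitude_asl),
      hdop         = as.numeric(.data$hdop),
      tag_type     = toupper(as.character(.data$tag_type))
    )

  bad <- is.na(fixes$timestamp) | is.na(fixes$easting) | is.na(fixes$northing) |
    is.na(fixes$hdop) | fixes$hdop < 0
  if (any(bad)) {
    warn(sprintf("%d unparseable telemetry row(s) dropped", sum(bad)))
    fixes <- fixes[!bad, , drop = FALSE]
  }

  fixes <- arrange(fixes, .data$bird_id, .data$timestamp)
  dup <- duplicated(fixes[, c("bird_id", "timestamp")])
  if (any(dup)) {
    inform(sprintf("%d duplicate (bird, timestamp) row(s) collapsed to first",
                   sum(dup)))
    fixes <- fixes[!dup, , drop = FALSE]
  }
  attr(fixes, "n_duplicates") <- sum(dup)
  fixes
}

# Solar geometry --------------------------------------------------------------

# NOAA solar-position equations (Julian-century polynomial form): equation
# of time in minutes and solar declination in radians, at fractional Julian
# day `jd` (UT).
solar_eqtime_decl <- function(jd) {
  T <- (jd - 2451545) / 36525
  L0 <- (280.46646 + T * (36000.76983 + 0.0003032 * T)) %% 360
  M <- 357.52911 + T * (35999.05029 - 0.0001537 * T)
  Mr <- M * pi / 180
  e <- 0.016708634 - T * (0.000042037 + 0.0000001267 * T)
  C <- sin(Mr) * (1.914602 - T * (0.004817 + 0.000014 * T)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * T) + sin(3 * Mr) * 0.000289
  true_long <- L0 + C
  omega <- 125.04 - 1934.136 * T
  app_long <- true_long - 0.00569 - 0.00478 * sin(omega * pi / 180)
  eps0 <- 23 + (26 + (21.448 - T * (46.815 + T * (0.00059 -
                                                    T * 0.001813))) / 60) / 60
  eps <- eps0 + 0.00256 * cos(omega * pi / 180)
  epsr <- eps * pi / 180
  decl <- asin(sin(epsr) * sin(app_long * pi / 180))
  y <- tan(epsr / 2)^2
  L0r <- L0 * pi / 180
  eqtime <- 4 * (180 / pi) *
    (y * sin(2 * L0r) - 2 * e * sin(Mr) + 4 * e * y * sin(Mr) * cos(2 * L0r) -
       0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  list(eqtime = eqtime, decl = decl)
}

#' Sunrise and sunset for a date and location
#'
#' Standard solar geometry with the sun centre at −0.833° altitude (geometric
#' rise/set including mean refraction). Vectorised over all arguments.
#'
#' @param lat,lon Degrees (WGS84); `abs(lat)` must be ≤ 90.
#' @param date A `Date` (or string coercible to one); the UTC calendar day.
#'
#' @return A tibble with one row per input: `sunrise`, `sunset` (POSIXct UTC;
#'   `NA` when the sun never crosses −0.833°) and `polar` — `"normal"`,
#'   `"day"` (sun always up) or `"night"` (sun never up).
#' @export
solar_times <- function(lat, lon, date) {
  if (any(abs(lat) > 90, na.rm = TRUE)) abort("latitude out of range [-90, 90]")
  date <- as.Date(date)
  n <- max(length(lat), length(lon), length(date))
  lat <- rep_len(lat, n); lon <- rep_len(lon, n); date <- rep_len(date, n)

  jd_noon <- as.numeric(date) + 2440587.5 + 0.5   # 12:00 UT that day
  zenith <- 90.833 * pi / 180
  latr <- lat * pi / 180
  event_minutes <- function(jd_eval, rising) {
    s <- solar_eqtime_decl(jd_eval)
    cos_ha <- (cos(zenith) - sin(latr) * sin(s$decl)) /
      (cos(latr) * cos(s$decl))
    ha <- acos(pmin(1, pmax(-1, cos_ha))) * 180 / pi   # degrees
    sign <- if (rising) 1 else -1
    list(minutes = 720 - 4 * (lon + sign * ha) - s$eqtime, cos_ha = cos_ha)
  }
  # evaluate at solar noon, then refine once at the event-time estimate
  sr <- event_minutes(jd_noon, TRUE)
  sr <- event_minutes(jd_noon + (sr$minutes - 720) / 1440, TRUE)
  ss <- event_minutes(jd_noon, FALSE)
  ss <- event_minutes(jd_noon + (ss$minutes - 720) / 1440, FALSE)

  polar <- dplyr::case_when(sr$cos_ha > 1 ~ "night", sr$cos_ha < -1 ~ "day",
                            TRUE ~ "normal")
  sunrise_min <- sr$minutes
  sunset_min <- ss$minutes

  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = "UTC")
  sunrise <- midnight + sunrise_min * 60
  sunset  <- midnight + sunset_min * 60
  sunrise[polar != "normal"] <- NA
  sunset[polar != "normal"] <- NA
  tibble(sunrise = sunrise, sunset = sunset, polar = polar)
}

#' Quality-filter GPS fixes
#'
#' Applies the fix-level exclusion rules in a fixed order so that every
#' excluded record is attributed to exactly one reason:
#' 1. `hdop`: HDOP not strictly below `max_hdop`;
#' 2. `missing_altitude`: altitude unavailable;
#' 3. `altitude_gt_max`: altitude above `max_alt` (default 6 km, implausible);
#' 4. `night`: fix outside the closed sunrise–sunset interval at its own
#'    lat/lon/date (roosting birds are uninformative about turbines).
#'
#' @param fixes Tibble of fixes (see [read_fixes()]).
#' @param max_hdop Retain only `hdop < max_hdop` (strict). Default 3.5.
#' @param max_alt Maximum plausible altitude asl in metres. Default 6000.
#' @param daylight_only Apply the sunrise/sunset filter? Default `TRUE`.
#'
#' @return The retained fixes, with attribute `"qc_report"`: a named list of
#'   exclusion counts (`hdop`, `missing_altitude`, `altitude_gt_max`, `night`),
#'   `retained` and `input`. Counts always conserve:
#'   `retained + sum(excluded) == input`.
#' @export
qc_filter <- function(fixes, max_hdop = 3.5, max_alt = 6000,
                      daylight_only = TRUE) {
  assert_cols(fixes, c("hdop", "altitude_asl"), "fixes")
  n_in <- nrow(fixes)
  reason <- rep(NA_character_, n_in)

  fail_hdop <- !(fixes$hdop < max_hdop)
  reason[is.na(reason) & fail_hdop] <- "hdop"
  fail_noalt <- is.na(fixes$altitude_asl)
  reason[is.na(reason) & fail_noalt] <- "missing_altitude"
  fail_alt <- !is.na(fixes$altitude_asl) & fixes$altitude_asl > max_alt
  reason[is.na(reason) & fail_alt] <- "altitude_gt_max"

  if (daylight_only && n_in > 0) {
    assert_cols(fixes, c("lat", "lon", "timestamp"), "fixes")
    undecided <- which(is.na(reason))
    if (length(undecided) > 0) {
      st <- solar_times(fixes$lat[undecided], fixes$lon[undecided],
                        as.Date(fixes$timestamp[undecided], tz = "UTC"))
      t <- fixes$timestamp[undecided]
      is_day <- ifelse(
        st$polar == "day", TRUE,
        ifelse(st$polar == "night", FALSE,
               t >= st$sunrise & t <= st$sunset))   # closed interval
      reason[undecided[!is_day]] <- "night"
    }
  }

  keep <- is.na(reason)
  report <- list(
    input = n_in,
    retained = sum(keep),
    excluded = c(
      hdop = sum(reason == "hdop", na.rm = TRUE),
      missing_altitude = sum(reason == "missing_altitude", na.rm = TRUE),
      altitude_gt_max = sum(reason == "altitude_gt_max", na.rm = TRUE),
      night = sum(reason == "night", na.rm = TRUE)
    )
  )
  out <- fixes[keep, , drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Extract the QC report attached by [qc_filter()]
#' @param fixes A tibble returned by [qc_filter()].
#' @return The report list (`input`, `retained`, `excluded` counts).
#' @export
qc_report <- function(fixes) {
  rep <- attr(fixes, "qc_report")
  if (is.null(rep)) abort("no qc_report attribute; was qc_filter() run?")
  rep
}

#' Drop birds with too few records in an analysis phase
#'
#' Birds contributing fewer than `min_n` records in the named phase are
#' removed entirely from the analysis set (their records in *all* phases are
#' dropped), so that bird-level random intercepts are estimable.
#'
#' @param records Tibble with `bird_id` and `phase` columns.
#' @param phase Phase in which the minimum applies (e.g. `"AFTER"`).
#' @param min_n Minimum record count (strict: birds with `< min_n` dropped).
#' @return Filtered tibble.
#' @export
filter_min_records_per_bird <- function(records, phase, min_n = 10) {
  if (nrow(records) == 0) return(records)
  assert_cols(records, c("bird_id", "phase"), "records")
  counts <- records %>%
    filter(.data$phase == !!phase) %>%
    dplyr::count(.data$bird_id)
  keep_birds <- counts$bird_id[counts$n >= min_n]
  filter(records, .data$bird_id %in% keep_birds)
}
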