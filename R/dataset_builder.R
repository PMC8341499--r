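# Assembly of the two proximity modelling datasets.
#
# * Before/after dataset: one row per QC-passed fix whose nearest turbine
#   (2-D planar) lies within the inclusion buffer (default 1 km), with the
#   3-D fix-to-hub distance, the operational phase at the fix time, and GET
#   scores at the turbine and at the fix.
# * After-operation dataset: one row per flight segment (consecutive GSM
#   fixes <= 5 min apart) whose 2-D closest approach to its nearest turbine
#   is within the buffer, with the interpolated-altitude 3-D distance, the
#   3-h-rounded SCADA wind speed and blade-motion status, and GET scores at
#   the turbine and at the closest-pass point.
#
# Every input row is accounted for: rows dropped by the buffer, by a raster
# miss, or by missing SCADA are counted in a `drops` attribute.

#' Build flight segments from consecutive fixes
#'
#' One segment per consecutive pair of fixes of the same bird separated by at
#' most `max_gap` seconds (pairs further apart are excluded because the
#' straight-line approximation degrades).
#'
#' @param fixes QC-passed fixes, sorted by bird and time (see [read_fixes()]).
#' @param max_gap Maximum allowed gap in seconds (default 300 = 5 min).
#' @return Tibble of segments: `bird_id`, `t1`, `t2`, `duration` (s),
#'   `x1`, `y1`, `alt1`, `x2`, `y2`, `alt2`.
#' @export
build_segments <- function(fixes, max_gap = 300) {
  assert_cols(fixes, c("bird_id", "timestamp", "easting", "northing",
                       "altitude_asl"), "fixes")
  fixes <- arrange(fixes, .data$bird_id, .data$timestamp)
  segs <- fixes %>%
    group_by(.data$bird_id) %>%
    mutate(
      t2 = dplyr::lead(.data$timestamp),
      x2 = dplyr::lead(.data$easting),
      y2 = dplyr::lead(.data$northing),
      alt2 = dplyr::lead(.data$altitude_asl)
    ) %>%
    ungroup() %>%
    filter(!is.na(.data$t2)) %>%
    mutate(duration = as.numeric(.data$t2) - as.numeric(.data$timestamp)) %>%
    filter(.data$duration <= max_gap, .data$duration > 0) %>%
    select(bird_id = "bird_id", t1 = "timestamp", t2 = "t2",
           duration = "duration", x1 = "easting", y1 = "northing",
           alt1 = "altitude_asl", x2 = "x2", y2 = "y2", alt2 = "alt2")
  segs
}

# nearest turbine (2-D planar) for point fixes: index + distance
nearest_turbine_fix <- function(fixes, turbines) {
  dx <- outer(fixes$easting, turbines$easting, "-")
  dy <- outer(fixes$northing, turbines$northing, "-")
  d <- sqrt(dx^2 + dy^2)
  idx <- max.col(-d, ties.method = "first")
  list(idx = idx, d2d = d[cbind(seq_len(nrow(d)), idx)])
}

#' Build the before/after fix-based proximity dataset
#'
#' @param fixes QC-passed fixes with non-missing altitude.
#' @param turbines Turbine metadata (see [read_turbines()]).
#' @param raster GET-score surface ([get_raster()]).
#' @param buffer Inclusion buffer on 2-D planar distance to the nearest
#'   turbine, metres (default 1000).
#' @return Tibble of proximity records (`bird_id`, `farm_id`, `turbine_id`,
#'   `phase`, `d2d`, `d3d`, `get_turbine`, `get_location`, `blade_length`,
#'   `timestamp`), with attribute `"drops"` counting rows lost to the buffer
#'   and to raster misses.
#' @export
build_before_after_records <- function(fixes, turbines, raster,
                                       buffer = 1000) {
  assert_cols(fixes, c("bird_id", "timestamp", "easting", "northing",
                       "altitude_asl"), "fixes")
  n_in <- nrow(fixes)
  if (n_in == 0) {
    out <- tibble(bird_id = character(), farm_id = character(),
                  turbine_id = character(), phase = character(),
                  d2d = numeric(), d3d = numeric(), get_turbine = integer(),
                  get_location = integer(), blade_length = numeric(),
                  timestamp = as.POSIXct(character(), tz = "UTC"))
    attr(out, "drops") <- c(buffer = 0, raster_miss = 0)
    return(out)
  }
  nt <- nearest_turbine_fix(fixes, turbines)
  in_buffer <- nt$d2d <= buffer
  n_buffer <- sum(!in_buffer)

  fixes <- fixes[in_buffer, , drop = FALSE]
  idx <- nt$idx[in_buffer]
  d2d <- nt$d2d[in_buffer]
  tb <- turbines[idx, , drop = FALSE]

  hub_alt <- hub_altitude(tb)
  d3d <- distance_3d(d2d, fixes$altitude_asl, hub_alt)
  phase <- classify_phase(fixes$timestamp, tb$operation_date)

  get_turb <- turbine_get_score(raster, tb$easting, tb$northing)
  inside <- raster_contains(raster, fixes$easting, fixes$northing)
  get_loc <- rep(NA_integer_, nrow(fixes))
  get_loc[inside] <- point_get_score(raster, fixes$easting[inside],
                                     fixes$northing[inside])
  miss <- is.na(get_loc)

  out <- tibble(
    bird_id = fixes$bird_id, farm_id = tb$farm_id,
    turbine_id = tb$turbine_id, phase = phase,
    d2d = d2d, d3d = d3d,
    get_turbine = get_turb, get_location = get_loc,
    blade_length = tb$blade_length, timestamp = fixes$timestamp
  )[!miss, , drop = FALSE]
  attr(out, "drops") <- c(buffer = n_buffer, raster_miss = sum(miss))
  out
}

#' Build the after-operation segment-based proximity dataset
#'
#' For each flight segment: the nearest turbine is the one with the smallest
#' 2-D closest approach; the closest-pass time (`t1 + fraction * duration`)
#' is rounded to the nearest 3 h and the simultaneous SCADA wind speed and
#' blade-motion status joined; GET is sampled at the closest-pass point.
#' Segments beyond the buffer, with no (or incomplete) SCADA record, or over
#' a raster miss are dropped and counted.
#'
#' @param segments Segments from [build_segments()].
#' @param turbines,raster,buffer As in [build_before_after_records()].
#' @param status SCADA status tibble (see [read_status()]).
#' @return Tibble of segment proximity records with attribute `"drops"`
#'   (`buffer`, `scada_miss`, `raster_miss` counts).
#' @export
build_after_records <- function(segments, turbines, raster, status,
                                buffer = 1000) {
  assert_cols(segments, c("bird_id", "t1", "duration", "x1", "y1", "alt1",
                          "x2", "y2", "alt2"), "segments")
  n_seg <- nrow(segments)
  empty <- tibble(bird_id = character(), farm_id = character(),
                  turbine_id = character(), d2d = numeric(), d3d = numeric(),
                  get_turbine = integer(), get_location = integer(),
                  wind_speed = numeric(), blade_status = character(),
                  blade_length = numeric(),
                  timestamp = as.POSIXct(character(), tz = "UTC"))
  if (n_seg == 0) {
    attr(empty, "drops") <- c(buffer = 0, scada_miss = 0, raster_miss = 0)
    return(empty)
  }

  # closest approach of every segment to every turbine; keep the per-segment
  # minimum (2-D criterion, matching the buffer convention)
  best_d <- rep(Inf, n_seg); best_i <- rep(NA_integer_, n_seg)
  best_f <- rep(NA_real_, n_seg)
  for (j in seq_len(nrow(turbines))) {
    ca <- closest_approach_2d(turbines$easting[j], turbines$northing[j],
                              segments$x1, segments$y1,
                              segments$x2, segments$y2)
    upd <- ca$d2d < best_d
    best_d[upd] <- ca$d2d[upd]; best_i[upd] <- j; best_f[upd] <- ca$fraction[upd]
  }

  in_buffer <- best_d <= buffer
  n_buffer <- sum(!in_buffer)
  segments <- segments[in_buffer, , drop = FALSE]
  if (nrow(segments) == 0) {
    attr(empty, "drops") <- c(buffer = n_buffer, scada_miss = 0, raster_miss = 0)
    return(empty)
  }
  idx <- best_i[in_buffer]; d2d <- best_d[in_buffer]
  fraction <- best_f[in_buffer]
  tb <- turbines[idx, , drop = FALSE]

  alt_pass <- interpolate_altitude(segments$alt1, segments$alt2, fraction)
  d3d <- distance_3d(d2d, alt_pass, hub_altitude(tb))
  x_pass <- segments$x1 + fraction * (segments$x2 - segments$x1)
  y_pass <- segments$y1 + fraction * (segments$y2 - segments$y1)
  t_pass <- round_to_3h(segments$t1 + fraction * segments$duration)

  rec <- tibble(
    bird_id = segments$bird_id, farm_id = tb$farm_id,
    turbine_id = tb$turbine_id, d2d = d2d, d3d = d3d,
    x_pass = x_pass, y_pass = y_pass,
    blade_length = tb$blade_length, timestamp = t_pass
  )
  rec <- left_join(rec,
                   select(status, "turbine_id", "timestamp", "wind_speed",
                          "blade_status"),
                   by = c("turbine_id", "timestamp"))
  scada_miss <- is.na(rec$wind_speed) | is.na(rec$blade_status)
  rec <- rec[!scada_miss, , drop = FALSE]

  rec$get_turbine <- if (nrow(rec) > 0)
    turbine_get_score(raster,
                      turbines$easting[match(rec$turbine_id, turbines$turbine_id)],
                      turbines$northing[match(rec$turbine_id, turbines$turbine_id)])
  else integer(0)
  inside <- raster_contains(raster, rec$x_pass, rec$y_pass)
  rec$get_location <- NA_integer_
  rec$get_location[inside] <- point_get_score(raster, rec$x_pass[inside],
                                              rec$y_pass[inside])
  raster_miss <- is.na(rec$get_location)
  out <- rec[!raster_miss,
             c("bird_id", "farm_id", "turbine_id", "d2d", "d3d",
               "get_turbine", "get_location", "wind_speed", "blade_status",
               "blade_length", "timestamp"), drop = FALSE]
  attr(out, "drops") <- c(buffer = n_buffer, scada_miss = sum(scada_miss),
                          raster_miss = sum(raster_miss))
  out
}

#' Descriptive distance summaries by group
#'
#' Mean, sample SD, the empirical 2.5th/97.5th percentile range (`range95`,
#' reported because repeated telemetry records make a data range more
#' interpretable than a standard error), and the count, per group.
#'
#' @param records A proximity tibble with a `d3d` column.
#' @param ... Grouping columns (tidy-select); empty for an overall summary.
#' @return A tibble with `mean`, `sd`, `lo95`, `hi95`, `n` per group; empty
#'   groups are omitted.
#' @export
summarize_distances <- function(records, ...) {
  records %>%
    group_by(...) %>%
    summarise(
      mean = mean(.data$d3d),
      sd = sd(.data$d3d),
      lo95 = as.numeric(quantile(.data$d3d, 0.025, type = 7)),
      hi95 = as.numeric(quantile(.data$d3d, 0.975, type = 7)),
      n = dplyr::n(),
      .groups = "drop"
    )
}

#' Count records within k rotor diameters of their paired turbine hub
#'
#' A record counts when `d3d < k * 2 * blade_length` (strict) of the turbine
#' it is paired with.
#'
#' @param records Proximity tibble with `d3d` and `blade_length`.
#' @param k Rotor-diameter multiplier (default 1).
#' @return A one-row tibble: `count`, `n`, `proportion`.
#' @export
proportion_within_diameters <- function(records, k = 1) {
  assert_cols(records, c("d3d", "blade_length"), "records")
  count <- sum(records$d3d < k * 2 * records$blade_length)
  tibble(count = count, n = nrow(records),
         proportion = if (nrow(records) > 0) count / nrow(records) else NA_real_)
}

#' Empirical distance quantile by group
#'
#' Linear interpolation between order statistics (R quantile type 7).
#'
#' @param records Proximity tibble with a `d3d` column.
#' @param q Probability (default 0.025).
#' @param ... Grouping columns (tidy-select), e.g. `farm_id, blade_status`.
#' @return A tibble with one `quantile` value (metres) per group.
#' @export
quantile_by_group <- function(records, q = 0.025, ...) {
  records %>%
    group_by(...) %>%
    summarise(quantile = as.numeric(quantile(.data$d3d, q, type = 7)),
              n = dplyr::n(), .groups = "drop")
}

#' Drop-accounting report attached by the dataset builders
#' @param records A tibble returned by [build_before_after_records()] or
#'   [build_after_records()].
#' @return Named integer vector of drop counts.
#' @export
drop_report <- function(records) {
  d <- attr(records, "drops")
  if (is.null(d)) abort("no drops attribute; was a build_* function used?")
  d
}
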