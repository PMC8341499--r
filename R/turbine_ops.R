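# Turbine metadata and 3-hourly operational state.
#
# Per-turbine SCADA streams carry hub-height wind speed (m s^-1) and rotor
# speed (rpm) every 3 h. Rotor speed is binarised to a blade-motion status
# (STILL / MOVING); telemetry timestamps are rounded to the nearest 3-h grid
# instant to join the simultaneous wind/blade state.

#' Read turbine metadata from delimited text
#'
#' Expected columns: `turbine_id`, `farm_id`, `easting`, `northing`,
#' `base_elevation_asl`, `hub_height_agl`, `blade_length`, `erection_date`,
#' `operation_date` (ISO-8601 dates; operation date may be empty for
#' never-operational turbines).
#'
#' @param path Path to a CSV file.
#' @return A tibble, dates parsed as `Date`.
#' @export
read_turbines <- function(path) {
  if (!file.exists(path)) abort(sprintf("turbine file not found: %s", path))
  tb <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(tb, c("turbine_id", "farm_id", "easting", "northing",
                    "base_elevation_asl", "hub_height_agl", "blade_length",
                    "erection_date", "operation_date"), "turbines")
  tb <- mutate(tb,
               erection_date = as.Date(.data$erection_date),
               operation_date = as.Date(.data$operation_date))
  if (any(tb$blade_length <= 0, na.rm = TRUE)) abort("blade_length must be > 0")
  bad <- !is.na(tb$erection_date) & !is.na(tb$operation_date) &
    tb$operation_date < tb$erection_date
  if (any(bad)) abort("operation_date earlier than erection_date")
  tb
}

#' Read 3-hourly SCADA status records from delimited text
#'
#' Expected columns: `turbine_id`, `timestamp` (UTC, on the 3-h grid),
#' `wind_speed` (m s^-1), `rotor_speed` (rpm, may be empty). A
#' `blade_status` column is derived via [blade_status_from_rotor()].
#'
#' @param path Path to a CSV file.
#' @param rotor_still_threshold Rotor speeds at or below this (rpm) count as
#'   STILL; default 0.
#' @return A tibble of status records.
#' @export
read_status <- function(path, rotor_still_threshold = 0) {
  if (!file.exists(path)) abort(sprintf("status file not found: %s", path))
  st <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  assert_cols(st, c("turbine_id", "timestamp", "wind_speed", "rotor_speed"),
              "status records")
  st <- mutate(st, timestamp = as.POSIXct(.data$timestamp, tz = "UTC"))
  if (any(st$wind_speed < 0, na.rm = TRUE)) abort("negative wind speed")
  st$blade_status <- blade_status_from_rotor(st$rotor_speed,
                                             threshold = rotor_still_threshold)
  st
}

#' Classify a record as before or after turbine operation
#'
#' A record strictly earlier than the turbine's operation date is BEFORE
#' (construction periods, and turbines that never became operational, fold
#' into BEFORE); records at or after the operation instant are AFTER. Dates
#' are promoted to midnight UTC.
#'
#' @param t POSIXct timestamps (UTC).
#' @param operation_date `Date` (or POSIXct) of first operation, `NA` for
#'   never-operational turbines.
#' @return Character vector, `"BEFORE"` or `"AFTER"`.
#' @export
classify_phase <- function(t, operation_date) {
  op <- if (inherits(operation_date, "POSIXct")) operation_date else
    as.POSIXct(as.numeric(as.Date(operation_date)) * 86400,
               origin = "1970-01-01", tz = "UTC")
  n <- max(length(t), length(op))
  t <- rep_len(t, n); op <- rep_len(op, n)
  ifelse(is.na(op) | t < op, "BEFORE", "AFTER")
}

#' Round an instant to the nearest 3-hour grid point
#'
#' Grid instants are 00:00, 03:00, ..., 21:00 UTC; an exact 90-minute tie
#' rounds up. Idempotent, and never displaces an instant by more than 90 min.
#'
#' @param t POSIXct timestamps (UTC).
#' @return POSIXct on the 3-h grid.
#' @export
round_to_3h <- function(t) {
  step <- 3 * 3600
  secs <- as.numeric(t)
  as.POSIXct(floor(secs / step + 0.5) * step,
             origin = "1970-01-01", tz = "UTC")
}

#' Binarise rotor speed into blade-motion status
#'
#' @param rotor_speed Rotor speed in rpm; `NA` for missing.
#' @param threshold Speeds at or below this are STILL. Default 0 rpm.
#' @return Character vector `"STILL"`/`"MOVING"`, `NA` where rotor speed is
#'   missing (such records are unusable for blade-status models).
#' @export
blade_status_from_rotor <- function(rotor_speed, threshold = 0) {
  if (any(rotor_speed < 0, na.rm = TRUE)) abort("negative rotor speed")
  ifelse(is.na(rotor_speed), NA_character_,
         ifelse(rotor_speed <= threshold, "STILL", "MOVING"))
}

#' Look up the SCADA status record for a turbine at a grid instant
#'
#' Exact-key match on (`turbine_id`, `timestamp`); the timestamp must already
#' be 3-h grid aligned (see [round_to_3h()]).
#'
#' @param turbine_id Turbine identifier.
#' @param t POSIXct instant, grid-aligned.
#' @param status Status tibble (see [read_status()]).
#' @return A one-row tibble, or `NULL` when no record exists.
#' @export
lookup_status <- function(turbine_id, t, status) {
  if (!identical(round_to_3h(t), t)) {
    abort("lookup_status() requires a 3-h grid-aligned timestamp; call round_to_3h() first")
  }
  hit <- status[status$turbine_id == turbine_id & status$timestamp == t, ,
                drop = FALSE]
  if (nrow(hit) == 0) return(NULL)
  hit[1, , drop = FALSE]
}
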