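# Shared fixtures, all built in code.

# constant-score raster over [0, size] x [0, size]
flat_raster <- function(score = 5L, n = 40, cellsize = 50) {
  get_raster(matrix(as.integer(score), n, n), xll = 0, yll = 0,
             cellsize = cellsize)
}

make_turbines <- function(n = 1, x = 0, y = 0, farm_id = "F1",
                          base = 700, hub = 80, blade = 40,
                          operation_date = as.Date("2017-01-01")) {
  tibble::tibble(
    turbine_id = sprintf("%s_T%02d", farm_id, seq_len(n)),
    farm_id = farm_id,
    easting = rep_len(x, n), northing = rep_len(y, n),
    base_elevation_asl = base, hub_height_agl = hub, blade_length = blade,
    erection_date = operation_date - 180,
    operation_date = rep_len(operation_date, n)
  )
}

make_fixes <- function(easting, northing, altitude_asl,
                       timestamp = as.POSIXct("2018-06-21 12:00:00",
                                              tz = "UTC"),
                       bird_id = "B1", hdop = 1, lat = 57.2, lon = -4.3,
                       tag_type = "GSM") {
  n <- length(easting)
  tibble::tibble(
    bird_id = rep_len(bird_id, n),
    timestamp = rep_len(timestamp, n) + seq_len(n) - 1,
    easting = easting, northing = rep_len(northing, n),
    lat = rep_len(lat, n), lon = rep_len(lon, n),
    altitude_asl = rep_len(altitude_asl, n), hdop = rep_len(hdop, n),
    tag_type = rep_len(tag_type, n)
  )
}

# one small simulated study, shared across test files (seeded, ~2 s)
shared_study <- local({
  cfg <- sim_config(seed = 7, steps_before = 300, steps_after = 300,
                    n_birds_gsm = 4, n_birds_argos = 2)
  simulate_study(cfg)
})

shared_ba_records <- local({
  fx <- qc_filter(shared_study$fixes)
  build_before_after_records(fx, shared_study$turbines, shared_study$raster)
})

shared_after_records <- local({
  fx <- qc_filter(shared_study$fixes)
  segs <- build_segments(dplyr::filter(fx, tag_type == "GSM"))
  build_after_records(segs, shared_study$turbines, shared_study$raster,
                      shared_study$status)
})
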