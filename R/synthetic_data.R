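# Seeded synthetic study system: landscape, wind farms, SCADA series and
# eagle telemetry.
#
# The generator emulates the statistical structure the analysis assumes: a
# spatially autocorrelated 1-10 habitat-preference surface; two wind farms
# (33 turbines with 80 m hubs / 40 m blades, and 66 turbines with 73 m hubs
# / 57.5 m blades) with staggered operation dates; 3-hourly AR(1) wind with
# Weibull marginals and cut-in-driven blade stoppage; and birds following a
# biased correlated random walk attracted to preferred habitat and to a
# per-bird activity centre, with an exponential-decay repulsion from the
# nearest *operational* turbine (the injected avoidance). Observed fixes add
# HDOP-scaled GPS noise, an HDOP tail beyond the QC threshold, occasional
# missing/implausible altitudes and a night-time fraction, so that every QC
# rule is exercised. All randomness derives from a single integer seed;
# identical configurations give byte-identical outputs.

#' Build a simulation configuration
#'
#' Defaults describe the emulated study system; any field can be overridden
#' by name. Key fields:
#' * `landscape_size` (m), `cellsize` (m), `autocorr_range` (m): the
#'   preference surface;
#' * `farms`: list of farm layouts (`n_turbines`, `hub_height_agl`,
#'   `blade_length`, `spacing` m, `origin` (x, y) m, operation-date window);
#' * `weibull_shape`, `weibull_scale` (m/s), `ar1` persistence, `cut_in`
#'   (m/s), `maintenance_prob`: the 3-hourly wind/rotor model;
#' * movement: `step_scale` (m), `kappa` (heading persistence),
#'   `alpha` (preference weight on the GET score), `beta` (avoidance
#'   strength), `rho` (avoidance decay range, m), `wind_coupling` (fraction
#'   by which the strongest wind suppresses avoidance), `home_scale` (m);
#' * sampling: `n_birds_gsm`, `n_birds_argos`, cadences (s), steps per
#'   phase per bird, HDOP mixture and data-quality blemish fractions.
#'
#' @param seed Integer master seed.
#' @param ... Named overrides of any default field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, ...) {
  cfg <- list(
    seed = as.integer(seed),
    landscape_size = 12000, cellsize = 50, autocorr_range = 500,
    farms = list(
      list(farm_id = "FARM_A", n_turbines = 33, hub_height_agl = 80,
           blade_length = 40, spacing = 350, origin = c(2000, 7500),
           base_elevation_range = c(650, 750),
           op_start = "2016-11-07", op_end = "2017-03-26"),
      list(farm_id = "FARM_B", n_turbines = 66, hub_height_agl = 73,
           blade_length = 57.5, spacing = 350, origin = c(6500, 1500),
           base_elevation_range = c(620, 720),
           op_start = "2018-03-26", op_end = "2018-11-06")
    ),
    jitter = 40,
    weibull_shape = 2, weibull_scale = 8, ar1 = 0.8,
    cut_in = 3.5, maintenance_prob = 0.02,
    step_scale = 600, kappa = 1.5, alpha = 0.25,
    beta = 2.5, rho = 300, wind_coupling = 0.5,
    home_scale = 1200, home_offset = 600,
    alt_mean_agl = 110, alt_sd = 70, alt_ar1 = 0.9, alt_wind_coupling = 0,
    n_birds_gsm = 7, n_birds_argos = 4,
    gsm_interval = 60, argos_interval = 3600,
    steps_before = 700, steps_after = 700,
    session_start_hour = 10, session_hours = 4,
    before_start = "2015-06-01", after_start = "2019-04-01",
    hdop_bad_frac = 0.12, frac_missing_alt = 0.01, frac_high_alt = 0.002,
    frac_night = 0.04,
    gps_noise_per_hdop = 5
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("unknown sim_config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "sim_config")
}

# derive a reproducible sub-seed (< 2^31) for one generator stage
sub_seed <- function(cfg, k) (cfg$seed * 1009L + k * 7919L) %% 2147483647L

#' Generate a spatially autocorrelated GET landscape
#'
#' A Gaussian random field (white noise smoothed with a Gaussian kernel of
#' range `autocorr_range`, circular convolution via FFT) rank-quantised to
#' scores 1-10 with equal marginal frequencies.
#'
#' @param config A [sim_config()].
#' @return A [get_raster()] with lower-left corner (0, 0).
#' @export
gen_landscape <- function(config) {
  set.seed(sub_seed(config, 1L))
  n <- as.integer(config$landscape_size / config$cellsize)
  z <- matrix(rnorm(n * n), n, n)
  if (config$autocorr_range > 0) {
    s <- config$autocorr_range / config$cellsize
    d <- pmin(0:(n - 1), n - (0:(n - 1)))          # circular distance
    k1 <- exp(-0.5 * (d / s)^2)
    K <- outer(k1, k1)
    K <- K / sum(K)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(K), inverse = TRUE)) / (n * n)
  }
  scores <- matrix(as.integer(cut(rank(z, ties.method = "first"),
                                  breaks = seq(0, n * n, length.out = 11),
                                  labels = FALSE)), n, n)
  get_raster(scores, xll = 0, yll = 0, cellsize = config$cellsize)
}

#' Generate the turbine arrays
#'
#' Each farm is laid out as a near-square grid at the configured spacing
#' with small positional jitter; turbines on the grid boundary are labelled
#' `outer`, the rest `inner`. Base elevations are uniform over the
#' configured range; operation dates are evenly staggered over the farm's
#' commissioning window, with erection 180 days earlier.
#'
#' @param config A [sim_config()].
#' @param raster The landscape ([gen_landscape()]); layouts must fall inside
#'   its extent.
#' @return A turbine tibble (see [read_turbines()] for columns, plus
#'   `position` = `"inner"`/`"outer"`).
#' @export
gen_windfarm <- function(config, raster) {
  set.seed(sub_seed(config, 2L))
  farms <- purrr::map_dfr(config$farms, function(f) {
    ncols <- ceiling(sqrt(f$n_turbines))
    nrows <- ceiling(f$n_turbines / ncols)
    g <- tidyr::expand_grid(row = seq_len(nrows), col = seq_len(ncols))
    g <- g[seq_len(f$n_turbines), ]
    x <- f$origin[1] + (g$col - 1) * f$spacing +
      runif(f$n_turbines, -config$jitter, config$jitter)
    y <- f$origin[2] + (g$row - 1) * f$spacing +
      runif(f$n_turbines, -config$jitter, config$jitter)
    op <- as.Date(f$op_start) +
      round(seq(0, as.numeric(as.Date(f$op_end) - as.Date(f$op_start)),
                length.out = f$n_turbines))
    outer_ring <- g$row %in% c(1, nrows) | g$col %in% c(1, ncols)
    tibble(
      turbine_id = sprintf("%s_T%02d", f$farm_id, seq_len(f$n_turbines)),
      farm_id = f$farm_id, easting = x, northing = y,
      base_elevation_asl = runif(f$n_turbines, f$base_elevation_range[1],
                                 f$base_elevation_range[2]),
      hub_height_agl = f$hub_height_agl, blade_length = f$blade_length,
      erection_date = op - 180, operation_date = op,
      position = ifelse(outer_ring, "outer", "inner")
    )
  })
  if (!all(raster_contains(raster, farms$easting, farms$northing))) {
    abort("wind farm layout falls outside the landscape raster")
  }
  farms
}

#' Generate 3-hourly SCADA wind and rotor status
#'
#' Per turbine, an AR(1) latent Gaussian series mapped to Weibull marginal
#' wind speeds; rotor speed is 0 below the cut-in wind speed and during
#' random maintenance windows, otherwise increases with wind.
#'
#' @param config A [sim_config()].
#' @param turbines Turbine tibble.
#' @param start,end POSIXct/date bounds of the series (aligned to the 3-h
#'   grid internally).
#' @return A status tibble (`turbine_id`, `timestamp`, `wind_speed`,
#'   `rotor_speed`, `blade_status`).
#' @export
gen_weather_status <- function(config, turbines,
                               start = config$after_start,
                               end = NULL) {
  set.seed(sub_seed(config, 3L))
  start <- round_to_3h(as.POSIXct(paste(as.Date(start), "00:00:00"),
                                  tz = "UTC"))
  if (is.null(end)) {
    n_days <- ceiling(max(config$steps_after, 1) /
                        (config$session_hours * 3600 / config$gsm_interval)) + 2
    end <- start + n_days * 86400
  } else {
    end <- round_to_3h(as.POSIXct(paste(as.Date(end), "00:00:00"), tz = "UTC"))
  }
  times <- seq(start, end, by = 3 * 3600)
  nt <- length(times)
  purrr::map_dfr(seq_len(nrow(turbines)), function(j) {
    z <- numeric(nt)
    z[1] <- rnorm(1)
    innov <- rnorm(nt)
    for (i in seq_len(nt - 1)) {
      z[i + 1] <- config$ar1 * z[i] + sqrt(1 - config$ar1^2) * innov[i]
    }
    wind <- qweibull(pnorm(z), shape = config$weibull_shape,
                     scale = config$weibull_scale)
    maint <- runif(nt) < config$maintenance_prob
    rotor <- ifelse(wind < config$cut_in | maint, 0, 4 + 0.7 * wind)
    tibble(turbine_id = turbines$turbine_id[j], timestamp = times,
           wind_speed = wind, rotor_speed = rotor,
           blade_status = blade_status_from_rotor(rotor))
  })
}

# fixed affine mock projection (documented; solar filtering needs lat/lon)
mock_latlon <- function(easting, northing) {
  lat0 <- 57.15; lon0 <- -4.35
  list(lat = lat0 + northing / 111320,
       lon = lon0 + easting / (111320 * cos(lat0 * pi / 180)))
}

# daylight-session timestamps: `n` fixes at `interval` s, sessions of
# `session_hours` h starting at `session_start_hour` UTC each day
session_times <- function(start_date, n, interval, start_hour, hours) {
  per_day <- max(1, floor(hours * 3600 / interval))
  day <- (seq_len(n) - 1) %/% per_day
  within <- (seq_len(n) - 1) %% per_day
  as.POSIXct(paste(as.Date(start_date), "00:00:00"), tz = "UTC") +
    day * 86400 + start_hour * 3600 + within * interval
}

#' Simulate GPS telemetry tracks
#'
#' Biased correlated random walk (see the module header). Per step, 16
#' candidate headings are scored by heading persistence, the GET score at
#' the candidate location, attraction to the bird's activity centre, and -
#' when the nearest turbine is operational at that instant - an
#' exponential-decay avoidance penalty `beta * exp(-d/rho)`, optionally
#' damped at high wind speed; one candidate is drawn from the softmax. True
#' positions are retained alongside HDOP-noised observed positions.
#'
#' @param config A [sim_config()].
#' @param raster Landscape ([gen_landscape()]).
#' @param turbines Turbine tibble ([gen_windfarm()]).
#' @param status SCADA tibble ([gen_weather_status()]); only needed when
#'   `wind_coupling > 0`.
#' @return A fix tibble (columns of [read_fixes()] plus `true_easting`,
#'   `true_northing`, `true_altitude_asl`).
#' @export
simulate_tracks <- function(config, raster, turbines, status = NULL) {
  n_birds <- config$n_birds_gsm + config$n_birds_argos
  tx <- turbines$easting; ty <- turbines$northing
  op_time <- as.POSIXct(paste(turbines$operation_date, "00:00:00"), tz = "UTC")

  # farm-level wind lookup for the avoidance damping: the farm's first
  # turbine's series, pre-indexed by grid timestamp
  farm_wind <- list()
  if (!is.null(status)) {
    for (f in unique(turbines$farm_id)) {
      first_tid <- turbines$turbine_id[match(f, turbines$farm_id)]
      sub <- status[status$turbine_id == first_tid, , drop = FALSE]
      farm_wind[[f]] <- list(t = as.numeric(sub$timestamp), w = sub$wind_speed)
    }
  }
  wind_at <- function(t3h, farm) {
    fw <- farm_wind[[farm]]
    if (is.null(fw)) return(0)
    i <- match(as.numeric(t3h), fw$t)
    if (is.na(i)) 0 else fw$w[i]
  }

  # activity centres ring the farms at `home_offset` m outside the array
  centres <- purrr::map_dfr(config$farms, function(f) {
    ncols <- ceiling(sqrt(f$n_turbines))
    nrows <- ceiling(f$n_turbines / ncols)
    w <- (ncols - 1) * f$spacing; h <- (nrows - 1) * f$spacing
    off <- config$home_offset
    tibble(
      farm_id = f$farm_id,
      cx = f$origin[1] + c(-off, w + off, w / 2, w / 2),
      cy = f$origin[2] + c(h / 2, h / 2, -off, h + off)
    )
  })
  # interleave farms so consecutive birds alternate between them
  within_farm <- stats::ave(seq_len(nrow(centres)), centres$farm_id,
                            FUN = seq_along)
  centres <- centres[order(within_farm, centres$farm_id), , drop = FALSE]

  K <- 16
  headings <- seq(0, 2 * pi, length.out = K + 1)[-(K + 1)]

  one_phase <- function(bird, start_date, n_steps, interval, bseed) {
    set.seed(bseed)
    times <- session_times(start_date, n_steps, interval,
                           config$session_start_hour, config$session_hours)
    cidx <- ((bird - 1) %% nrow(centres)) + 1
    cx <- centres$cx[cidx]; cy <- centres$cy[cidx]
    farm <- centres$farm_id[cidx]

    x <- cx + runif(1, -200, 200); y <- cy + runif(1, -200, 200)
    heading <- runif(1, 0, 2 * pi)
    lens <- rgamma(n_steps, shape = 2, scale = config$step_scale / 2)
    alt_noise <- numeric(n_steps)
    alt_noise[1] <- rnorm(1, 0, config$alt_sd)
    xs <- numeric(n_steps); ys <- numeric(n_steps)
    t3h <- round_to_3h(times)

    for (i in seq_len(n_steps)) {
      candx <- x + lens[i] * cos(headings)
      candy <- y + lens[i] * sin(headings)
      ok <- raster_contains(raster, candx, candy)
      lw <- rep(-Inf, K)
      if (any(ok)) {
        g <- point_get_score(raster, candx[ok], candy[ok])
        g[is.na(g)] <- 5
        # nearest turbine per candidate (vectorised over turbines)
        dmat <- sqrt(outer(candx[ok], tx, "-")^2 + outer(candy[ok], ty, "-")^2)
        nearest <- max.col(-dmat, ties.method = "first")
        dnear <- dmat[cbind(seq_len(sum(ok)), nearest)]
        operational <- times[i] >= op_time[nearest]
        damp <- 1
        if (config$wind_coupling > 0 && any(operational)) {
          wn <- min(wind_at(t3h[i], farm) / 15, 1)
          damp <- 1 - config$wind_coupling * wn
        }
        pen <- ifelse(operational,
                      config$beta * damp * exp(-dnear / config$rho), 0)
        home <- ((candx[ok] - cx)^2 + (candy[ok] - cy)^2) / config$home_scale^2
        lw[ok] <- config$kappa * cos(headings[ok] - heading) +
          config$alpha * g - home - pen
      }
      w <- exp(lw - max(lw))
      pick <- sample.int(K, 1, prob = w)
      heading <- headings[pick]
      x <- x + lens[i] * cos(headings[pick])
      y <- y + lens[i] * sin(headings[pick])
      xs[i] <- x; ys[i] <- y
      if (i < n_steps) {
        alt_noise[i + 1] <- config$alt_ar1 * alt_noise[i] +
          sqrt(1 - config$alt_ar1^2) * rnorm(1, 0, config$alt_sd)
      }
    }

    wind_alt <- if (config$alt_wind_coupling > 0) {
      vapply(t3h, function(tt) wind_at(tt, farm), numeric(1)) *
        config$alt_wind_coupling
    } else 0
    terrain <- mean(turbines$base_elevation_asl[turbines$farm_id == farm])
    true_alt <- terrain + pmax(5, config$alt_mean_agl + alt_noise + wind_alt)

    hdop <- ifelse(runif(n_steps) < config$hdop_bad_frac,
                   runif(n_steps, 3.5, 7), runif(n_steps, 0.6, 3.2))
    noise_sd <- config$gps_noise_per_hdop * hdop
    ox <- xs + rnorm(n_steps, 0, noise_sd)
    oy <- ys + rnorm(n_steps, 0, noise_sd)
    oalt <- true_alt + rnorm(n_steps, 0, 1.2 * noise_sd)
    oalt[runif(n_steps) < config$frac_high_alt] <- runif(1, 6500, 9000)
    oalt[runif(n_steps) < config$frac_missing_alt] <- NA
    night <- runif(n_steps) < config$frac_night
    if (any(night)) {
      times[night] <- as.POSIXct(paste(as.Date(times[night], tz = "UTC"),
                                       "23:00:00"), tz = "UTC") +
        seq_len(sum(night))
    }

    ll <- mock_latlon(ox, oy)
    tibble(
      bird_id = sprintf("BIRD_%02d", bird), timestamp = times,
      easting = ox, northing = oy, lat = ll$lat, lon = ll$lon,
      altitude_asl = oalt, hdop = hdop,
      tag_type = if (bird <= config$n_birds_gsm) "GSM" else "ARGOS",
      true_easting = xs, true_northing = ys, true_altitude_asl = true_alt
    )
  }

  fixes <- purrr::map_dfr(seq_len(n_birds), function(b) {
    interval <- if (b <= config$n_birds_gsm) config$gsm_interval else
      config$argos_interval
    bind_rows(
      one_phase(b, config$before_start, config$steps_before, interval,
                sub_seed(config, 100L + b)),
      one_phase(b, config$after_start, config$steps_after, interval,
                sub_seed(config, 200L + b))
    )
  })
  arrange(fixes, .data$bird_id, .data$timestamp)
}

#' Generate a complete synthetic study
#'
#' Runs [gen_landscape()], [gen_windfarm()], [gen_weather_status()] and
#' [simulate_tracks()] from one seed lineage.
#'
#' @param config A [sim_config()].
#' @return A list: `config`, `raster`, `turbines`, `status`, `fixes`.
#' @export
simulate_study <- function(config = sim_config()) {
  raster <- gen_landscape(config)
  turbines <- gen_windfarm(config, raster)
  status <- gen_weather_status(config, turbines)
  fixes <- simulate_tracks(config, raster, turbines, status)
  list(config = config, raster = raster, turbines = turbines,
       status = status, fixes = fixes)
}

#' Write a synthetic fixture bundle to disk
#'
#' Emits exactly the formats the pipeline readers consume: `telemetry.csv`,
#' `turbines.csv`, `scada.csv`, `get_raster.asc` and `manifest.json` (seed
#' and full parameter echo).
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_fixture_bundle <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  study <- simulate_study(config)
  paths <- list(
    telemetry = file.path(dir, "telemetry.csv"),
    turbines = file.path(dir, "turbines.csv"),
    scada = file.path(dir, "scada.csv"),
    raster = file.path(dir, "get_raster.asc"),
    manifest = file.path(dir, "manifest.json")
  )
  fx <- study$fixes
  fx$timestamp <- strftime(fx$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(fx, paths$telemetry, progress = FALSE)
  readr::write_csv(study$turbines, paths$turbines, progress = FALSE)
  st <- study$status
  st$timestamp <- strftime(st$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  readr::write_csv(st, paths$scada, progress = FALSE)
  write_ascii_grid(study$raster, paths$raster)
  manifest <- list(seed = study$config$seed,
                   parameters = unclass(study$config),
                   files = lapply(paths[1:4], basename))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(paths)
}

#' True injected displacement of a simulated study
#'
#' The generator's ground truth for the before/after contrast: using *true*
#' (noise-free) positions, the difference in mean 3-D distance to the
#' nearest turbine hub between after-phase and before-phase fixes within the
#' buffer. The pipeline's estimate of the same contrast from observed,
#' QC-filtered fixes should recover this.
#'
#' @param fixes Simulated fixes (with `true_*` columns).
#' @param turbines Turbine tibble.
#' @param buffer Inclusion buffer (m), as in the pipeline.
#' @return A one-row tibble: `mean_before`, `mean_after`, `displacement`.
#' @export
true_displacement <- function(fixes, turbines, buffer = 1000) {
  tf <- fixes %>%
    select(bird_id = "bird_id", timestamp = "timestamp",
           easting = "true_easting", northing = "true_northing",
           altitude_asl = "true_altitude_asl")
  nt <- nearest_turbine_fix(tf, turbines)
  keep <- nt$d2d <= buffer
  tb <- turbines[nt$idx[keep], , drop = FALSE]
  d3d <- distance_3d(nt$d2d[keep], tf$altitude_asl[keep], hub_altitude(tb))
  phase <- classify_phase(tf$timestamp[keep], tb$operation_date)
  mb <- mean(d3d[phase == "BEFORE"]); ma <- mean(d3d[phase == "AFTER"])
  tibble(mean_before = mb, mean_after = ma, displacement = ma - mb)
}
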