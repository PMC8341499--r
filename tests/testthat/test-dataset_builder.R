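# Assembly of the modelling datasets and descriptive summaries.

ts_utc <- function(s) as.POSIXct(s, tz = "UTC")

test_that("build_segments pairs consecutive fixes within the gap limit", {
  t0 <- ts_utc("2019-05-01 12:00:00")
  fx <- make_fixes(c(0, 100, 300), 0, 500)
  fx$timestamp <- t0 + c(0, 120, 400)     # gaps 120 s and 280 s, both kept
  segs <- build_segments(fx)
  expect_equal(nrow(segs), 2)
  expect_equal(segs$duration, c(120, 280))

  fx2 <- make_fixes(c(0, 100), 0, 500)
  fx2$timestamp <- t0 + c(0, 301)         # > 5 min gap excluded
  expect_equal(nrow(build_segments(fx2)), 0)

  expect_equal(nrow(build_segments(make_fixes(0, 0, 500))), 0)

  # birds never pair across identities
  fx3 <- dplyr::bind_rows(
    make_fixes(0, 0, 500, bird_id = "A", timestamp = t0),
    make_fixes(0, 0, 500, bird_id = "B", timestamp = t0 + 60)
  )
  expect_equal(nrow(build_segments(fx3)), 0)
})

test_that("build_before_after_records applies the buffer and hand geometry", {
  r <- flat_raster(7, n = 100)
  tb <- make_turbines(x = 2500, y = 2500, base = 700, hub = 80)  # hub 780 asl
  far <- make_fixes(2500 + 1200, 2500, 800)
  out <- build_before_after_records(far, tb, r)
  expect_equal(nrow(out), 0)
  expect_equal(unname(drop_report(out)["buffer"]), 1)

  fx <- make_fixes(c(2500 + 300, 2500), 2500, c(780 + 400, 780 + 500),
                   timestamp = ts_utc("2016-01-01 12:00:00"))
  fx$northing <- c(2500, 2500 + 300)
  out <- build_before_after_records(fx, tb, r)
  expect_equal(nrow(out), 2)
  expect_equal(out$d3d, c(500, sqrt(300^2 + 500^2)))   # hand trigonometry
  expect_equal(out$phase, c("BEFORE", "BEFORE"))
  expect_equal(out$get_turbine, c(7L, 7L))
  expect_equal(out$get_location, c(7L, 7L))

  after <- dplyr::mutate(fx, timestamp = ts_utc("2018-01-01 12:00:00"))
  expect_equal(build_before_after_records(after, tb, r)$phase,
               c("AFTER", "AFTER"))
})

test_that("nearest-turbine pairing matches an exhaustive search", {
  set.seed(51)
  r <- flat_raster(5, n = 120)
  tb <- make_turbines(8, x = runif(8, 1000, 5000), y = 1000)
  tb$northing <- runif(8, 1000, 5000)
  fx <- make_fixes(runif(300, 0, 6000), 0, 800)
  fx$northing <- runif(300, 0, 6000)
  out <- build_before_after_records(fx, tb, r, buffer = 1000)

  # brute force: all-pairs distances, per-fix minimum
  d <- outer(fx$easting, tb$easting, "-")^2 +
    outer(fx$northing, tb$northing, "-")^2
  nearest <- tb$turbine_id[apply(d, 1, which.min)]
  within <- sqrt(apply(d, 1, min)) <= 1000
  expect_equal(nrow(out), sum(within))
  expect_equal(out$turbine_id, nearest[within])
})

test_that("build_after_records joins SCADA through the rounding chain", {
  r <- flat_raster(6, n = 100)
  tb <- make_turbines(x = 2500, y = 2500, base = 700, hub = 80)
  # segment whose perpendicular pass is at its midpoint: start 11:58,
  # 240 s duration -> pass at 12:00, already on the 3-h grid
  seg <- tibble::tibble(
    bird_id = "B1", t1 = ts_utc("2019-05-04 11:58:00"),
    t2 = ts_utc("2019-05-04 12:02:00"), duration = 240,
    x1 = 2500 - 200, y1 = 2500 + 300, alt1 = 900,
    x2 = 2500 + 200, y2 = 2500 + 300, alt2 = 940
  )
  status <- tibble::tibble(
    turbine_id = tb$turbine_id, timestamp = ts_utc("2019-05-04 12:00:00"),
    wind_speed = 9.1, rotor_speed = 11, blade_status = "MOVING"
  )
  out <- build_after_records(seg, tb, r, status)
  expect_equal(nrow(out), 1)
  expect_equal(out$wind_speed, 9.1)
  expect_equal(out$blade_status, "MOVING")
  expect_equal(out$d2d, 300)
  expect_equal(out$d3d, sqrt(300^2 + (920 - 780)^2))
  expect_equal(out$timestamp, ts_utc("2019-05-04 12:00:00"))

  # no SCADA row at the rounded instant -> dropped and counted
  late <- dplyr::mutate(status, timestamp = ts_utc("2019-05-04 15:00:00"))
  out2 <- build_after_records(seg, tb, r, late)
  expect_equal(nrow(out2), 0)
  expect_equal(unname(attr(out2, "drops")["scada_miss"]), 1)
})

test_that("after-record counts equal in-buffer segments with SCADA", {
  fx <- qc_filter(shared_study$fixes)
  segs <- build_segments(dplyr::filter(fx, tag_type == "GSM"))
  out <- shared_after_records
  drops <- attr(out, "drops")
  expect_equal(nrow(out) + sum(drops), nrow(segs))
  # recount oracle: per-segment min distance over all turbines
  d_min <- rep(Inf, nrow(segs))
  for (j in seq_len(nrow(shared_study$turbines))) {
    ca <- closest_approach_2d(shared_study$turbines$easting[j],
                              shared_study$turbines$northing[j],
                              segs$x1, segs$y1, segs$x2, segs$y2)
    d_min <- pmin(d_min, ca$d2d)
  }
  expect_equal(unname(drops["buffer"]), sum(d_min > 1000))
})

test_that("drops are conserved and the buffer is monotone", {
  fx <- qc_filter(shared_study$fixes)
  for (buf in c(400, 700, 1000)) {
    out <- build_before_after_records(fx, shared_study$turbines,
                                      shared_study$raster, buffer = buf)
    expect_equal(nrow(out) + sum(drop_report(out)), nrow(fx))
  }
  n_by_buffer <- vapply(c(250, 500, 750, 1000), function(buf) {
    nrow(build_before_after_records(fx, shared_study$turbines,
                                    shared_study$raster, buffer = buf))
  }, numeric(1))
  expect_true(all(diff(n_by_buffer) >= 0))   # shrinking never adds records
  expect_true(all(shared_ba_records$d3d >= shared_ba_records$d2d - 1e-9))
})

test_that("summarize_distances reports mean, sd, 95% range and n", {
  rec <- tibble::tibble(d3d = c(100, 200, 300), g = "a")
  got <- summarize_distances(rec)
  expect_equal(got$mean, 200)
  expect_equal(got$n, 3)
  expect_equal(summarize_distances(tibble::tibble(d3d = rep(5, 4)))$sd, 0)

  set.seed(52)
  x <- rlnorm(5000, log(500), 0.4)
  got <- summarize_distances(tibble::tibble(d3d = x))
  # order-statistics oracle via an independent sort-based computation
  s <- sort(x)
  h <- function(p) { hh <- (length(s) - 1) * p + 1
    s[floor(hh)] + (hh - floor(hh)) * (s[floor(hh) + 1] - s[floor(hh)]) }
  expect_equal(got$lo95, h(0.025))
  expect_equal(got$hi95, h(0.975))
})

test_that("proportion_within_diameters uses a strict threshold", {
  rec <- tibble::tibble(d3d = c(79, 80), blade_length = 40)
  got <- proportion_within_diameters(rec, k = 1)
  expect_equal(got$count, 1)          # 79 < 80 counted, 80 is not
  expect_equal(got$proportion, 0.5)

  set.seed(53)
  rec2 <- tibble::tibble(d3d = seq(150, 168, by = 2), blade_length = 40)
  got2 <- proportion_within_diameters(rec2, k = 2)   # threshold 160
  expect_equal(got2$count, sum(rec2$d3d < 160))
})

test_that("quantile_by_group interpolates between order statistics", {
  rec <- tibble::tibble(d3d = seq(100, 1000, by = 100), g = "a")
  got <- quantile_by_group(rec, q = 0.1, g)
  expect_equal(got$quantile, 190)     # (n-1)q + 1 = 1.9 -> 100 + 0.9 * 100
  expect_equal(quantile_by_group(rec, q = 0)$quantile, 100)

  set.seed(54)
  x <- rweibull(40000, shape = 2, scale = 600)
  got <- quantile_by_group(tibble::tibble(d3d = x), q = 0.025)
  truth <- 600 * (-log(1 - 0.025))^(1 / 2)
  expect_lt(abs(got$quantile - truth) / truth, 0.05)   # Monte-Carlo error
})
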