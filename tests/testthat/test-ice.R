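uniform_field <- function(value = 0.8, nx = 20, ny = 20, times_ka = 5:0) {
  synth_ice_field(nx = nx, ny = ny, times_ka = times_ka, base = value,
                  trend_per_ka = 0, seasonal_amplitude = 0,
                  gradient_per_km = 0, noise_sd = 0, land_fraction = 0)
}

test_that("the polar equal-area projection behaves at its reference points", {
  # the pole maps to the origin
  p <- laea_project(0, 90, lon0 = 100)
  expect_equal(c(p$x, p$y), c(0, 0), tolerance = 1e-9)
  # a point on the central meridian maps to x = 0, y < 0
  q <- laea_project(100, 70, lon0 = 100)
  expect_equal(q$x, 0, tolerance = 1e-9)
  expect_lt(q$y, 0)
  # chord distance from the pole: 2 R sin(colat / 2)
  R <- 6371.0088
  expect_equal(sqrt(q$x^2 + q$y^2), 2 * R * sin((20 * pi / 180) / 2),
               tolerance = 1e-9)
})

test_that("centroids and buffered points follow the uniform-disc law", {
  herds <- tibble::tibble(
    herd = c("h1", "h2", "h3"),
    population = c("P1", "P1", "P2"),
    lon = c(10, 30, 90), lat = c(70, 72, 75))
  eb <- event_buffer_points(herds, c("P1", "P2"), buffer_km = 100,
                            n_points = 10000, seed = 2)
  xy <- laea_project(herds$lon, herds$lat, 0, 90)
  expect_equal(eb$centroids$x[eb$centroids$population == "P1"],
               mean(xy$x[1:2]), tolerance = 1e-9)
  # single-herd population: centroid is the herd itself
  expect_equal(eb$centroids$x[eb$centroids$population == "P2"], xy$x[3],
               tolerance = 1e-9)
  # event centroid is the midpoint of the two population centroids
  expect_equal(eb$event_centroid$x, mean(eb$centroids$x), tolerance = 1e-9)
  # all points within the buffer; radial CDF ~ (r/R)^2
  r <- sqrt((eb$points$x - eb$event_centroid$x)^2 +
              (eb$points$y - eb$event_centroid$y)^2)
  expect_true(all(r <= 100 + 1e-9))
  ks <- suppressWarnings(stats::ks.test(r, function(q) (q / 100)^2))
  expect_gt(ks$p.value, 0.01)
  expect_error(event_buffer_points(herds, c("P1", "Nowhere")), "no herds")
})

test_that("a uniform field extracts its value with zero sd at any radius", {
  fld <- uniform_field(0.8)
  pts <- tibble::tibble(x = c(0, 50), y = c(0, -40))
  for (radius in c(100, 250, 400)) {
    ser <- extract_ice_series(fld, pts, radius_km = radius)
    expect_equal(unique(ser$mean), 0.8, tolerance = 1e-12)
    expect_equal(unique(ser$sd), 0, tolerance = 1e-12)
  }
  expect_error(extract_ice_series(fld, pts, radius_km = 10), "cell size")
})

test_that("extraction matches a brute-force cell enumeration on a gradient field", {
  fld <- synth_ice_field(nx = 30, ny = 25, times_ka = 3:0, base = 0.4,
                         trend_per_ka = 0.02, seasonal_amplitude = 0.2,
                         gradient_per_km = 3e-4, noise_sd = 0.015,
                         land_fraction = 0.15, seed = 8)
  pts <- tibble::tibble(x = c(-100, 200), y = c(0, 150))
  radius <- 220
  ser <- extract_ice_series(fld, pts, radius_km = radius)
  # oracle: loop over every cell for every point / slice / month
  for (ti in seq_along(fld$times_ka)) {
    for (m in c(3, 12)) {
      means <- sds <- c()
      for (p in seq_len(nrow(pts))) {
        vals <- c()
        for (iy in seq_along(fld$y_km)) for (ix in seq_along(fld$x_km)) {
          if (fld$land[ti, iy, ix]) next
          if ((fld$x_km[ix] - pts$x[p])^2 +
              (fld$y_km[iy] - pts$y[p])^2 <= radius^2) {
            vals <- c(vals, fld$sic[ti, m, iy, ix])
          }
        }
        means <- c(means, mean(vals)); sds <- c(sds, sd(vals))
      }
      row <- ser[ser$time_ka == fld$times_ka[ti] & ser$month == m, ]
      expect_equal(row$mean, mean(means), tolerance = 1e-12)
      expect_equal(row$sd, mean(sds), tolerance = 1e-12)
    }
  }
})

test_that("an all-land neighbourhood is flagged missing", {
  fld <- synth_ice_field(nx = 20, ny = 20, times_ka = 2:0,
                         land_fraction = 0.5, noise_sd = 0)
  # points deep inside the land half (largest x)
  pts <- tibble::tibble(x = max(fld$x_km) - 30, y = 0)
  ser <- extract_ice_series(fld, pts, radius_km = 65)
  expect_true(all(ser$flag_empty))
  expect_true(all(is.na(ser$mean)))
})

test_that("crossing windows match closed-form evaluation of a seasonal cycle", {
  # monthly means 0.55 + 0.3 cos(2 pi (m - 1)/12): above 0.70 away from summer
  ser <- tidyr::expand_grid(time_ka = c(1, 0), month = as.character(1:12))
  ser$mean <- 0.55 + 0.3 * cos(2 * pi * (as.numeric(ser$month) - 1) / 12)
  ser$sd <- 0; ser$n_cells <- 10; ser$flag_empty <- FALSE
  class(ser) <- c("coal_iceseries", class(ser))
  cw <- crossing_window(ser, threshold = 0.70)
  open_months <- sort(unique(cw$month[cw$open]))
  oracle <- which(0.55 + 0.3 * cos(2 * pi * (1:12 - 1) / 12) >= 0.70)
  expect_equal(open_months, oracle)
  # all months open when concentration is always high
  ser$mean <- 0.9
  cw2 <- crossing_window(ser)
  expect_true(all(cw2$open))
  expect_equal(nrow(cw2), 24L)
})

test_that("events map to the nearest slice with half-ka ties toward older", {
  fld <- uniform_field(0.75, times_ka = 14:0)
  ser <- extract_ice_series(fld, tibble::tibble(x = 0, y = 0), 100)
  ev <- tibble::tibble(event = c("div1", "div2", "div3"),
                       kind = "divergence",
                       median_ka = c(10.7, 10.5, 10.4),
                       ci_lower_ka = c(7.4, 9, 9),
                       ci_upper_ka = c(13.7, 12, 12))
  ov <- overlay_events(ev, ser)
  expect_equal(ov$slice_ka, c(11, 11, 10))
  expect_equal(ov$slice_lower_ka[1], 7)
  expect_equal(ov$slice_upper_ka[1], 14)
  expect_equal(ov$ice_mean, rep(0.75, 3), tolerance = 1e-12)
  # older than the record: clamped with a warning
  expect_warning(
    ov2 <- overlay_events(tibble::tibble(event = "x", kind = "divergence",
                                         median_ka = 30, ci_lower_ka = 25,
                                         ci_upper_ka = 40), ser),
    "clamp")
  expect_equal(ov2$slice_ka, 14)
})

test_that("ice fields round-trip through the text serialization", {
  fld <- synth_ice_field(nx = 12, ny = 10, times_ka = 2:0, noise_sd = 0.01,
                         seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ice_field(fld, path)
  back <- read_ice_field(path)
  expect_equal(back$sic, fld$sic, tolerance = 1e-12)
  expect_equal(back$land, fld$land)
  expect_equal(back$times_ka, fld$times_ka)
  expect_equal(back$x_km, fld$x_km)
})

test_that("ice series plots build, with events and threshold overlays", {
  fld <- uniform_field(0.75, times_ka = 5:0)
  ser <- extract_ice_series(fld, tibble::tibble(x = 0, y = 0), 100)
  ev <- tibble::tibble(event = "d", kind = "divergence", median_ka = 3,
                       ci_lower_ka = 2, ci_upper_ka = 4)
  p <- autoplot(ser, events = ev, threshold = 0.7)
  expect_s3_class(p, "ggplot")
})
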