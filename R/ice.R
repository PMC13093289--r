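#' Gridded paleo sea-ice concentration snapshots
#'
#' An `ice_field` holds monthly mean sea-ice concentration grids (fraction
#' in `[0, 1]`) on an equal-area projected grid, for a set of time slices
#' at 1 ka resolution, plus a land mask per slice. Concentration over land
#' is undefined and stored as `NA`.
#'
#' @param sic 4-d numeric array `[time, month, y, x]` with 12 months.
#' @param land logical array `[time, y, x]` (TRUE = land).
#' @param times_ka numeric vector of slice ages (ka before present).
#' @param x_km,y_km cell-center coordinates (km) on the projected plane.
#' @param cell_km nominal cell size (km), default 30.
#' @param proj projection descriptor `list(lon0 =, lat0 =)` for the
#'   Lambert azimuthal equal-area plane the coordinates live on.
#' @return An `ice_field` object.
#' @export
ice_field <- function(sic, land, times_ka, x_km, y_km, cell_km = 30,
                      proj = list(lon0 = 0, lat0 = 90)) {
  stopifnot(length(dim(sic)) == 4L, dim(sic)[2L] == 12L,
            dim(sic)[1L] == length(times_ka),
            dim(sic)[3L] == length(y_km), dim(sic)[4L] == length(x_km),
            all(dim(land) == dim(sic)[c(1L, 3L, 4L)]))
  vals <- sic[!is.na(sic)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    abort("sea-ice concentration must lie in [0, 1]")
  }
  structure(list(sic = sic, land = land, times_ka = as.numeric(times_ka),
                 x_km = as.numeric(x_km), y_km = as.numeric(y_km),
                 cell_km = cell_km, proj = proj),
            class = "ice_field")
}

#' @export
print.ice_field <- function(x, ...) {
  cat("<ice_field> ", length(x$times_ka), " slices (",
      max(x$times_ka), "-", min(x$times_ka), " ka) x 12 months x ",
      length(x$y_km), "x", length(x$x_km), " cells @ ", x$cell_km,
      " km\n", sep = "")
  invisible(x)
}

#' Annual mean grids of an ice field
#' @param field an `ice_field`.
#' @return numeric array `[time, y, x]`, the mean of the 12 monthly grids.
#' @export
annual_mean_grid <- function(field) {
  apply(field$sic, c(1L, 3L, 4L), mean)
}

#' Write / read an ice field as JSON header + long TSV
#'
#' Plain-text serialization of the gridded snapshots: a JSON header
#' (dimensions, coordinates, projection) plus a long-format TSV with
#' columns `time_ka, month, y, x, sic, land`.
#'
#' @param field an `ice_field`.
#' @param path TSV path; the header goes to `<path>.json`.
#' @return `read_ice_field` returns the `ice_field`.
#' @export
write_ice_field <- function(field, path) {
  d <- dim(field$sic)
  grid <- expand.grid(time = seq_len(d[1L]), month = seq_len(d[2L]),
                      y = seq_len(d[3L]), x = seq_len(d[4L]))
  land_long <- field$land[cbind(grid$time, grid$y, grid$x)]
  df <- data.frame(time_ka = field$times_ka[grid$time], month = grid$month,
                   y = grid$y, x = grid$x,
                   sic = as.vector(field$sic), land = as.integer(land_long))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(times_ka = field$times_ka, x_km = field$x_km, y_km = field$y_km,
         cell_km = field$cell_km, proj = field$proj),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(field)
}

#' @rdname write_ice_field
#' @export
read_ice_field <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.delim(path, sep = "\t")
  nt <- length(hdr$times_ka); ny <- length(hdr$y_km); nx <- length(hdr$x_km)
  sic <- array(NA_real_, c(nt, 12L, ny, nx))
  ti <- match(df$time_ka, hdr$times_ka)
  sic[cbind(ti, df$month, df$y, df$x)] <- df$sic
  land <- array(FALSE, c(nt, ny, nx))
  land[cbind(ti, df$y, df$x)] <- df$land == 1L
  ice_field(sic, land, hdr$times_ka, hdr$x_km, hdr$y_km, hdr$cell_km,
            proj = as.list(hdr$proj))
}

#' Lambert azimuthal equal-area projection (spherical)
#'
#' Forward projection of WGS84 lon/lat (degrees) to a polar/oblique
#' Lambert azimuthal equal-area plane in km, on the authalic sphere
#' (R = 6371.0088 km). The central meridian is configurable (the
#' polar-Arctic convention uses lat0 = 90 with a region-specific lon0)
#' and is recorded with the results.
#'
#' @param lon,lat coordinates in degrees.
#' @param lon0 central meridian (degrees).
#' @param lat0 latitude of projection origin (degrees), default 90
#'   (north-polar aspect).
#' @return A tibble with `x`, `y` in km.
#' @export
laea_project <- function(lon, lat, lon0 = 0, lat0 = 90) {
  R <- 6371.0088
  to_rad <- pi / 180
  lam <- (lon - lon0) * to_rad
  phi <- lat * to_rad
  phi0 <- lat0 * to_rad
  denom <- 1 + sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(lam)
  k <- sqrt(2 / denom)
  tibble(x = R * k * cos(phi) * sin(lam),
         y = R * k * (cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(lam)))
}

#' Population centroids and buffered random points around an event
#'
#' Population centroids are means of the member herds' projected
#' coordinates; the geographic position of a two-population event is the
#' midpoint of the two centroids. To reduce the influence of the
#' arbitrary centroid, `n_points` points are sampled uniformly over the
#' disc of radius `buffer_km` around the event centroid (`r = R sqrt(u)`).
#'
#' @param herds tibble with columns `herd`, `population`, `lon`, `lat`
#'   (WGS84 degrees).
#' @param populations the two population labels participating in the
#'   event.
#' @param buffer_km disc radius (km), default 100.
#' @param n_points number of sampled points, default 100.
#' @param seed integer seed.
#' @param proj projection `list(lon0 =, lat0 =)`.
#' @return A list: `centroids` (tibble population, x, y), `event_centroid`
#'   (tibble x, y), `points` (tibble point, x, y).
#' @export
event_buffer_points <- function(herds, populations, buffer_km = 100,
                                n_points = 100, seed = 1,
                                proj = list(lon0 = 0, lat0 = 90)) {
  stopifnot(length(populations) == 2L)
  missing_pop <- setdiff(populations, herds$population)
  if (length(missing_pop)) {
    abort(paste0("population(s) with no herds: ",
                 paste(missing_pop, collapse = ", ")))
  }
  xy <- laea_project(herds$lon, herds$lat, proj$lon0, proj$lat0)
  herds_xy <- dplyr::bind_cols(herds, xy)
  centroids <- herds_xy |>
    dplyr::filter(.data$population %in% populations) |>
    dplyr::group_by(.data$population) |>
    dplyr::summarise(x = mean(.data$x), y = mean(.data$y), .groups = "drop")
  ec <- tibble(x = mean(centroids$x), y = mean(centroids$y))
  set.seed(seed)
  u <- runif(n_points)
  theta <- runif(n_points, 0, 2 * pi)
  r <- buffer_km * sqrt(u)
  list(centroids = centroids,
       event_centroid = ec,
       points = tibble(point = seq_len(n_points),
                       x = ec$x + r * cos(theta),
                       y = ec$y + r * sin(theta)))
}

#' Extract sea-ice concentration series around points
#'
#' For each point, takes all non-land cells whose centers lie within
#' `radius_km`, computes the mean and standard deviation of concentration
#' over those cells (per month, plus the annual mean, per time slice),
#' then averages the per-point means and sds over the points. A slice
#' where no point has any eligible cell yields `NA` with a flag.
#'
#' @param field an `ice_field`.
#' @param points tibble with `x`, `y` (km, same projection as the field).
#' @param radius_km extraction radius; must exceed the cell size.
#' @return A `coal_iceseries` tibble: `time_ka`, `month`
#'   (`"1"`–`"12"` or `"annual"`), `mean`, `sd`, `n_cells` (average
#'   eligible cells per point), `flag_empty`.
#' @export
extract_ice_series <- function(field, points, radius_km) {
  if (radius_km <= field$cell_km) abort("radius must exceed the cell size")
  nt <- length(field$times_ka)
  ny <- length(field$y_km); nx <- length(field$x_km)
  cx <- rep(field$x_km, each = ny)
  cy <- rep(field$y_km, times = nx)
  annual <- annual_mean_grid(field)
  r2 <- radius_km^2
  months <- c(as.character(1:12), "annual")
  acc_mean <- acc_sd <- acc_n <- array(0, c(nt, 13L))
  cnt <- array(0L, c(nt, 13L))
  for (p in seq_len(nrow(points))) {
    within <- (cx - points$x[p])^2 + (cy - points$y[p])^2 <= r2
    for (ti in seq_len(nt)) {
      sel <- within & !as.vector(field$land[ti, , ])
      if (!any(sel)) next
      for (m in 1:12) {
        v <- as.vector(field$sic[ti, m, , ])[sel]
        acc_mean[ti, m] <- acc_mean[ti, m] + mean(v)
        acc_sd[ti, m] <- acc_sd[ti, m] + (if (length(v) > 1L) sd(v) else 0)
        acc_n[ti, m] <- acc_n[ti, m] + length(v)
        cnt[ti, m] <- cnt[ti, m] + 1L
      }
      v <- as.vector(annual[ti, , ])[sel]
      acc_mean[ti, 13L] <- acc_mean[ti, 13L] + mean(v)
      acc_sd[ti, 13L] <- acc_sd[ti, 13L] + (if (length(v) > 1L) sd(v) else 0)
      acc_n[ti, 13L] <- acc_n[ti, 13L] + length(v)
      cnt[ti, 13L] <- cnt[ti, 13L] + 1L
    }
  }
  out <- tidyr::expand_grid(time_ka = field$times_ka, month = months)
  idx <- cbind(match(out$time_ka, field$times_ka), match(out$month, months))
  has <- cnt[idx] > 0L
  out$mean <- ifelse(has, acc_mean[idx] / cnt[idx], NA_real_)
  out$sd <- ifelse(has, acc_sd[idx] / cnt[idx], NA_real_)
  out$n_cells <- ifelse(has, acc_n[idx] / cnt[idx], 0)
  out$flag_empty <- !has
  class(out) <- c("coal_iceseries", class(out))
  attr(out, "radius_km") <- radius_km
  out
}

#' Months above / below a crossing threshold
#'
#' For each time slice, classifies calendar months as "open" for crossing
#' (mean concentration at or above the threshold, default 70% — the
#' minimum sea-ice cover associated with large-ungulate sea-ice
#' crossings) or "closed". Missing months propagate as `NA`.
#'
#' @param series a `coal_iceseries` (monthly rows are used).
#' @param threshold concentration threshold in `[0, 1]`, default 0.70.
#' @return A tibble `time_ka`, `month` (integer 1–12), `mean`, `open`.
#' @export
crossing_window <- function(series, threshold = 0.70) {
  series |>
    dplyr::filter(.data$month != "annual") |>
    dplyr::transmute(time_ka = .data$time_ka,
                     month = as.integer(.data$month),
                     mean = .data$mean,
                     open = .data$mean >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$time_ka), .data$month)
}

#' Map event times onto ice slices and tabulate ice state at each event
#'
#' Each event's median and credible-interval bounds (in ka) are mapped to
#' the nearest available 1 ka slice, with exact half-ka ties resolved
#' toward the older slice (conservative toward the pre-event ice state).
#' Events older than the oldest slice are clamped with a warning.
#'
#' @param events tibble with columns `event`, `kind`, `median_ka`,
#'   `ci_lower_ka`, `ci_upper_ka`.
#' @param series a `coal_iceseries`.
#' @param month which series to report at the event slice, default
#'   `"annual"`.
#' @return A tibble adding `slice_ka`, `slice_lower_ka`, `slice_upper_ka`,
#'   `ice_mean`, `ice_sd`.
#' @export
overlay_events <- function(events, series, month = "annual") {
  slices <- sort(unique(series$time_ka))
  snap <- function(t) {
    out <- vapply(t, function(ti) {
      d <- abs(slices - ti)
      best <- d == min(d)
      max(slices[best])  # tie toward the older slice
    }, numeric(1))
    if (any(t > max(slices) + 0.5)) {
      warn("event time(s) older than the oldest slice; clamped")
    }
    out
  }
  ms <- dplyr::filter(series, .data$month == !!month)
  events |>
    dplyr::mutate(slice_ka = snap(.data$median_ka),
                  slice_lower_ka = snap(.data$ci_lower_ka),
                  slice_upper_ka = snap(.data$ci_upper_ka)) |>
    dplyr::left_join(dplyr::select(ms, "time_ka", ice_mean = "mean",
                                   ice_sd = "sd"),
                     by = c(slice_ka = "time_ka"))
}

#' @export
autoplot.coal_iceseries <- function(object, month = "annual",
                                    events = NULL, threshold = NULL, ...) {
  dat <- dplyr::filter(object, .data$month == !!month)
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_ka, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                                      ymax = pmin(1, .data$mean + .data$sd)),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "ka before present",
                  y = paste0("sea-ice concentration (", month, ")")) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dotdash")
  }
  if (!is.null(events)) {
    p <- p +
      ggplot2::geom_vline(data = events,
                          ggplot2::aes(xintercept = .data$median_ka),
                          linetype = "dashed") +
      ggplot2::geom_vline(data = events,
                          ggplot2::aes(xintercept = .data$ci_lower_ka),
                          linetype = "dotted") +
      ggplot2::geom_vline(data = events,
                          ggplot2::aes(xintercept = .data$ci_upper_ka),
                          linetype = "dotted")
  }
  p
}
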