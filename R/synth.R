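#' Example demographic scenarios
#'
#' Small ready-made scenarios for examples, tests and synthetic bundles.
#'
#' `synth_scenario_pair()` returns two single-divergence two-population
#' scenarios that differ only in the divergence-time prior (a recent and
#' an old window) — a well-separated model-choice pair.
#' `synth_scenario_island()` is a four-population island system in the
#' style of an Arctic-archipelago model: two nested divergences from a
#' mainland ancestor, one mainland-to-archipelago admixture pulse, and
#' founder bottlenecks on the two island populations, with an ancient
#' (serially sampled) population at 502 generations.
#'
#' @param n_per_pop samples per population.
#' @param L sequence length (bp).
#' @param ne haploid effective size prior or value.
#' @param mu mutation rate (per site per generation) prior or value.
#' @return A list of `coal_scenario` objects.
#' @export
synth_scenario_pair <- function(n_per_pop = 10, L = 300, ne = 1000,
                                mu = 1e-5) {
  mk <- function(id, tmin, tmax) {
    scenario(
      id = id,
      populations = list(
        pop_spec("A", ne = ne, sample_size = n_per_pop),
        pop_spec("B", ne = ne, sample_size = n_per_pop)),
      events = list(
        event_divergence("split", daughter = "B", parent = "A",
                         time = prior_uniform(tmin, tmax))),
      mutation = hky_model(mu = mu, kappa = 2,
                           pi = c(0.3, 0.2, 0.2, 0.3), alpha = 0.5),
      L = L)
  }
  list(recent = mk("recent_split", 10, 200),
       old = mk("old_split", 2000, 10000))
}

#' @rdname synth_scenario_pair
#' @export
synth_scenario_island <- function(n_per_pop = 20, L = 135) {
  scenario(
    id = "island_colonisation",
    populations = list(
      pop_spec("Mainland", ne = prior_uniform(5000, 50000),
               sample_size = n_per_pop),
      pop_spec("Archipelago", ne = prior_uniform(1000, 20000),
               sample_size = n_per_pop),
      pop_spec("EastIsland", ne = prior_uniform(500, 10000),
               sample_size = n_per_pop),
      pop_spec("AncientIsland", ne = prior_uniform(500, 10000),
               sample_size = 3, sampling_age = 502)),
    events = list(
      event_divergence("anc_split", daughter = "AncientIsland",
                       parent = "Archipelago",
                       time = prior_uniform(600, 2000)),
      event_divergence("east_split", daughter = "EastIsland",
                       parent = "Archipelago",
                       time = prior_uniform(700, 2500)),
      event_admixture("pulse", recipient = "Archipelago",
                      donor = "Mainland",
                      time = prior_uniform(100, 600),
                      rate = prior_uniform(0.05, 0.5)),
      event_divergence("main_split", daughter = "Archipelago",
                       parent = "Mainland",
                       time = prior_uniform(1000, 3000)),
      event_bottleneck("arch_founder", population = "Archipelago",
                       time = prior_ref("t_main_split"),
                       nb = prior_uniform(10, 500)),
      event_bottleneck("east_founder", population = "EastIsland",
                       time = prior_ref("t_east_split"),
                       nb = prior_uniform(10, 500))),
    mutation = hky_model(mu = prior_loguniform(1e-6, 1e-4), kappa = 10,
                         pi = c(0.32, 0.25, 0.13, 0.30), alpha = 0.5,
                         p_inv = 0.2),
    L = L,
    constraints = list(c("t_east_split", "t_anc_split")))
}

#' Simulate a complete sequence dataset with known truth
#'
#' Simulates one dataset at given (or prior-drawn) "true" parameter
#' values, attaches herd coordinates to the samples, and optionally
#' writes a bundle: FASTA alignment, metadata TSV, truth JSON and the
#' scenario document.
#'
#' @param scn a `coal_scenario`.
#' @param truth named parameter values to simulate at; drawn from the
#'   priors when omitted.
#' @param herds optional herd-location tibble (from
#'   [synth_herd_locations()]); sample coordinates are assigned by cycling
#'   through each population's herds.
#' @param seed integer seed.
#' @param dir optional output directory for the bundle.
#' @return A list: `alignment`, `truth` (1-row tibble), `genealogy`.
#' @export
synth_sequence_dataset <- function(scn, truth = NULL, herds = NULL,
                                   seed = 1, dir = NULL) {
  set.seed(seed)
  if (is.null(truth)) truth <- sample_parameters(scn, 1L)
  truth <- as_tibble(as.list(truth))
  sim <- simulate_dataset(scn, draw = truth)
  aln <- sim$alignment
  if (!is.null(herds)) {
    meta <- aln$meta
    for (p in unique(meta$population)) {
      hp <- herds[herds$population == p, , drop = FALSE]
      if (nrow(hp)) {
        rows <- which(meta$population == p)
        pick <- rep(seq_len(nrow(hp)), length.out = length(rows))
        meta$lon[rows] <- hp$lon[pick]
        meta$lat[rows] <- hp$lat[pick]
      }
    }
    aln <- coal_alignment(aln$seqs, meta, validated = TRUE)
  }
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_alignment(aln, file.path(dir, "alignment.fasta"),
                    file.path(dir, "metadata.tsv"))
    jsonlite::write_json(list(seed = seed, scenario = scn$id,
                              truth = as.list(truth)),
                         file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA)
    write_scenario(scn, file.path(dir, "scenario.json"))
  }
  list(alignment = aln, truth = truth, genealogy = sim$genealogy)
}

#' Synthetic herd location tables
#'
#' Draws herd coordinates around given population centers with isotropic
#' dispersion on the projected plane (then mapped back is unnecessary —
#' dispersion is applied directly in degrees scaled by latitude).
#'
#' @param centers tibble with `population`, `lon`, `lat`.
#' @param herds_per_pop herds per population.
#' @param dispersion_km typical herd spread around the center (km).
#' @param seed integer seed.
#' @return A tibble `herd`, `population`, `lon`, `lat`.
#' @export
synth_herd_locations <- function(centers, herds_per_pop = 3,
                                 dispersion_km = 50, seed = 1) {
  set.seed(seed)
  km_per_deg_lat <- 111.32
  purrr::map_dfr(seq_len(nrow(centers)), function(i) {
    lat0 <- centers$lat[i]
    dx <- stats::rnorm(herds_per_pop, 0, dispersion_km)
    dy <- stats::rnorm(herds_per_pop, 0, dispersion_km)
    tibble(herd = paste0(centers$population[i], "_h", seq_len(herds_per_pop)),
           population = centers$population[i],
           lon = centers$lon[i] + dx / (km_per_deg_lat * cos(lat0 * pi / 180)),
           lat = lat0 + dy / km_per_deg_lat)
  })
}

#' Synthetic gridded sea-ice field with known structure
#'
#' Generates monthly sea-ice concentration snapshots
#' `sic(t, m, y, x) = clip(base + trend * t + A cos(2 pi (m - peak_month)/12)
#' + g * x + noise, 0, 1)` with a land mask, emulating climate-model
#' output at 1 ka slices on a 30 km equal-area grid. Truth parameters are
#' recorded as an attribute.
#'
#' @param nx,ny grid size (>= 10 each).
#' @param cell_km cell size in km, default 30.
#' @param times_ka time slices, default `24:0`.
#' @param base base concentration at t = 0, month offset 0, x = 0.
#' @param trend_per_ka linear trend per ka of age (older = `+trend * t`).
#' @param seasonal_amplitude amplitude A of the monthly cosine.
#' @param peak_month calendar month of maximum ice, default 3 (March).
#' @param gradient_per_km spatial gradient g along x (per km).
#' @param noise_sd iid Gaussian noise sd (0 gives the exact closed form).
#' @param land_fraction fraction of columns (x edge) masked as land.
#' @param seed integer seed.
#' @return An [ice_field()] with attribute `truth`.
#' @export
synth_ice_field <- function(nx = 40, ny = 40, cell_km = 30, times_ka = 24:0,
                            base = 0.35, trend_per_ka = 0.012,
                            seasonal_amplitude = 0.25, peak_month = 3,
                            gradient_per_km = 2e-4, noise_sd = 0.02,
                            land_fraction = 0.1, seed = 1) {
  if (nx < 10 || ny < 10) abort("grid must be at least 10 x 10")
  set.seed(seed)
  x_km <- (seq_len(nx) - (nx + 1) / 2) * cell_km
  y_km <- (seq_len(ny) - (ny + 1) / 2) * cell_km
  nt <- length(times_ka)
  sic <- array(NA_real_, c(nt, 12L, ny, nx))
  n_land <- floor(land_fraction * nx)
  land1 <- matrix(rep(seq_len(nx) > nx - n_land, each = ny), ny, nx)
  land <- array(FALSE, c(nt, ny, nx))
  for (ti in seq_len(nt)) land[ti, , ] <- land1
  for (ti in seq_len(nt)) {
    for (m in 1:12) {
      det <- base + trend_per_ka * times_ka[ti] +
        seasonal_amplitude * cos(2 * pi * (m - peak_month) / 12) +
        outer(rep(0, ny), gradient_per_km * x_km, `+`)
      eps <- if (noise_sd > 0) matrix(stats::rnorm(ny * nx, 0, noise_sd),
                                      ny, nx) else 0
      grid <- pmin(1, pmax(0, det + eps))
      grid[land1] <- NA_real_
      sic[ti, m, , ] <- grid
    }
  }
  out <- ice_field(sic, land, times_ka, x_km, y_km, cell_km)
  attr(out, "truth") <- list(base = base, trend_per_ka = trend_per_ka,
                             seasonal_amplitude = seasonal_amplitude,
                             peak_month = peak_month,
                             gradient_per_km = gradient_per_km,
                             noise_sd = noise_sd, seed = seed)
  out
}
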