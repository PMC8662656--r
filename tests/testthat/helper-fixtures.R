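# Shared fixtures: the scenario-1 parameter vector used as simulation truth
# (posterior point estimates of the demographic model), small genotype
# builders, and a lazily built reference table shared by the acceptance
# tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

reference_medians <- c(T1 = 1220, T2 = 6410, T3 = 11800, TA = 24400,
                    N_A = 97400, N_JRpOH = 38900, N_JR = 10700,
                    N_OH = 51400, N_KK = 43800, N_OT = 98200, N_KKP = 650)

reference_bands <- list(TA = c(21700, 31900), T3 = c(10700, 13800),
                     T1 = c(1040, 2010), N_OT = c(94900, 99600),
                     N_KKP = c(155, 967))

scenario1_truth <- function() scenario_params(1, reference_medians)

desk_config <- function() sample_config(10, 10, 10, 10)

# genotype matrix from explicit per-group genotype row lists
gm_from_groups <- function(...) {
  grp <- list(...)
  gt <- do.call(rbind, lapply(grp, function(g) do.call(rbind, g)))
  genotype_matrix(gt, rep(names(grp), vapply(grp, length, integer(1))))
}

.acc_cache <- new.env(parent = emptyenv())

acceptance_table <- function() {
  if (is.null(.acc_cache$tab)) {
    .acc_cache$tab <- build_reference_table(
      prior_spec(), scenarios = 1:3, config = desk_config(),
      n_sims = 20000, n_loci = 500, rng_seed = 20211109)
  }
  .acc_cache$tab
}

acceptance_observed <- function() {
  if (is.null(.acc_cache$obs)) {
    .acc_cache$obs <- summary_stats(
      simulate_dataset(scenario1_truth(), desk_config(), 500,
                       rng_seed = 424242),
      groups = names(desk_config()))
  }
  .acc_cache$obs
}

# one observed summary-statistic vector per replicate, simulated under the
# scenario-1 truth with distinct seeds
acceptance_replicates <- function(n = 20) {
  if (is.null(.acc_cache$reps) || nrow(.acc_cache$reps) < n) {
    .acc_cache$reps <- t(vapply(seq_len(n), function(i) {
      summary_stats(simulate_dataset(scenario1_truth(), desk_config(), 500,
                                     rng_seed = 5000 + i),
                    groups = names(desk_config()))
    }, numeric(40)))
  }
  .acc_cache$reps[seq_len(n), , drop = FALSE]
}

# solid-body-rotation velocity field on a flat-bottomed equatorial grid:
# u = -Omega * y, v = Omega * x in local tangent coordinates, giving a
# closed-form circular trajectory of period 2*pi/Omega
rotation_field <- function(period_days = 20, half_deg = 1, res = 0.05) {
  omega <- 2 * pi / (period_days * 86400)
  r_earth <- 6371000
  lon <- seq(-half_deg, half_deg, by = res)
  lat <- seq(-half_deg, half_deg, by = res)
  u <- -omega * r_earth * outer(rep(1, length(lon)), lat * pi / 180)
  v <- omega * r_earth * outer(lon * pi / 180, rep(1, length(lat)))
  structure(list(lon = lon, lat = lat, depth = 0,
                 time = as.Date("2011-01-01"),
                 u = array(u, c(length(lon), length(lat), 1, 1)),
                 v = array(v, c(length(lon), length(lat), 1, 1)),
                 bathy = matrix(10000, length(lon), length(lat)),
                 config = NULL),
            class = "velocity_field")
}

release_at <- function(field, lonlat, depth, n = 1, radius_km = 0,
                       seed = 1) {
  release_particles(field, center = lonlat, depth = depth, n = n,
                    radius_km = radius_km, rng_seed = seed)
}
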