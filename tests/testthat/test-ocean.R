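quiet_config <- function(...) {
  ocean_config(eddy_energy = 0, n_days = 10, ...)
}

test_that("the jet decays from 1 m/s at the surface to 0.1 m/s at 1000 m", {
  f <- make_synthetic_ocean(quiet_config())
  core_j <- which.min(abs(f$lat - 27))
  core_i <- which.min(abs(f$lon - 124))          # inside the trough
  expect_equal(f$u[core_i, core_j, which(f$depth == 0), 1], 1.0,
               tolerance = 1e-12)
  expect_equal(f$u[core_i, core_j, which(f$depth == 1000), 1], 0.1,
               tolerance = 1e-12)
  expect_equal(jet_speed(1000), 0.1, tolerance = 1e-12)
})

test_that("velocities vanish wherever the bathymetry is shallower than the level", {
  f <- make_synthetic_ocean(ocean_config(eddy_energy = 0.4, n_days = 5),
                            rng_seed = 101)
  for (k in seq_along(f$depth)) {
    shallow <- f$bathy < f$depth[k]
    for (ti in seq_along(f$time)) {
      expect_true(all(f$u[, , k, ti][shallow] == 0))
      expect_true(all(f$v[, , k, ti][shallow] == 0))
    }
  }
  # any level deeper than the ridge crest has zero velocity over the ridge
  ridge <- f$bathy == 400
  deep <- which(f$depth > 400)
  expect_true(all(f$u[, , deep[1], 1][ridge] == 0))
})

test_that("zero eddy energy yields a time-invariant field", {
  f <- make_synthetic_ocean(quiet_config())
  expect_identical(dim(f$u)[4], 1L)
})

test_that("gate validation rejects inconsistent geometry", {
  expect_error(ocean_config(gates = list(bad = list(side = "north",
                                                    center = 124,
                                                    width = 0.5,
                                                    depth = 3000))),
               "sill deeper than the trough")
  expect_error(ocean_config(gates = list(bad = list(side = "north",
                                                    center = 124,
                                                    width = 0.5,
                                                    depth = 300))),
               "deeper than the ridge crest")
  expect_error(ocean_config(gates = list(bad = list(side = "east",
                                                    center = 40,
                                                    width = 0.5,
                                                    depth = 700))),
               "outside the ridge")
})

test_that("seasonal means average the requested daily slices", {
  f <- make_synthetic_ocean(quiet_config())
  sm <- seasonal_mean(f, "winter", years = 2010)
  expect_equal(sm$u, f$u, tolerance = 1e-12)
  # alternating +A / -A field averages to zero over an even-length season
  lon <- seq(0, 1, 0.5)
  lat <- seq(0, 1, 0.5)
  days <- as.Date("2011-03-01") + 0:61
  a <- array(rep(c(1, -1), each = 9, length.out = 9 * 62), c(3, 3, 1, 62))
  fld <- structure(list(lon = lon, lat = lat, depth = 0, time = days,
                        u = a, v = -a, bathy = matrix(1e4, 3, 3),
                        config = NULL), class = "velocity_field")
  sm2 <- seasonal_mean(fld, "spring", years = 2011)
  expect_equal(max(abs(sm2$u)), 0, tolerance = 1e-12)
  expect_error(seasonal_mean(fld, "fall", years = 2011), "no daily fields")
})

test_that("eddies average out of the seasonal mean at depth", {
  cfg <- ocean_config(eddy_energy = 0.4, n_days = 92,
                      origin = "2011-03-01", levels = c(0, 1000))
  f <- make_synthetic_ocean(cfg, rng_seed = 102)
  sm <- seasonal_mean(f, "spring", years = 2011)
  core_j <- which.min(abs(f$lat - 27))
  core_i <- which.min(abs(f$lon - 124))
  expect_lt(abs(sm$u[core_i, core_j, 2, 1] - 0.1) / 0.1, 0.1)
})

test_that("the eddy field is discretely non-divergent", {
  cfg <- ocean_config(trough_lon = c(120, 128), trough_lat = c(24, 30),
                      gates = list(), eddy_energy = 0.5, n_days = 3,
                      levels = c(500))
  f <- make_synthetic_ocean(cfg, rng_seed = 103)
  div <- field_divergence(f, 1, 2)
  expect_lt(max(abs(div), na.rm = TRUE), 1e-18)
})

test_that("particle release is area-uniform within the disk", {
  f <- make_synthetic_ocean(quiet_config())
  rel <- release_particles(f, center = c(124, 27), depth = 1250, n = 10000,
                           radius_km = 25, rng_seed = 104)
  d_km <- geosphere::distGeo(cbind(rel$lon, rel$lat), c(124, 27)) / 1000
  expect_true(all(d_km <= 25 + 1e-6))
  expect_lt(abs(mean(d_km) - 2 / 3 * 25) / (2 / 3 * 25), 0.01)
  r0 <- release_particles(f, center = c(124, 27), depth = 1250, n = 50,
                          radius_km = 0, rng_seed = 105)
  expect_true(all(abs(r0$lon - 124) < 1e-9 & abs(r0$lat - 27) < 1e-9))
  # on the ridge crest (400 m) a 1-km disk is entirely blocked at 1250 m
  expect_error(release_particles(f, center = c(121.2, 25.7), depth = 1250,
                                 n = 10, radius_km = 1, rng_seed = 1),
               "blocked")
})

test_that("solid-body rotation returns particles to their start", {
  f <- rotation_field(period_days = 20)
  rel <- release_at(f, c(0.3, 0), 0)
  traj <- advect(rel, f, duration_days = 20)
  expect_identical(traj$status, "active")
  r_daily <- sqrt(traj$lon^2 + traj$lat^2)
  expect_lt(max(abs(r_daily - 0.3)) / 0.3, 0.001)       # radius drift < 0.1%
  end_err <- sqrt((traj$lon[21] - 0.3)^2 + traj$lat[21]^2)
  expect_lt(end_err, 1e-3 * 0.3)
  # tightening the tolerance changes the answer by less than its own error
  traj2 <- advect(rel, f, duration_days = 20, rtol = 1e-8)
  expect_lt(abs(traj$lon[21] - traj2$lon[21]), 1e-4)
  expect_lt(abs(traj$lat[21] - traj2$lat[21]), 1e-4)
})

test_that("particles are stationary in a zero velocity field", {
  f <- rotation_field()
  f$u[] <- 0
  f$v[] <- 0
  rel <- release_at(f, c(0.2, 0.1), 0)
  traj <- advect(rel, f, duration_days = 10)
  expect_equal(as.numeric(traj$lon), rep(0.2, 11), tolerance = 1e-12)
  expect_equal(as.numeric(traj$lat), rep(0.1, 11), tolerance = 1e-12)
})

test_that("no active particle ever sits on a cell shallower than its depth", {
  cfg <- ocean_config(eddy_energy = 0.3, n_days = 40)
  f <- make_synthetic_ocean(cfg, rng_seed = 106)
  rel <- release_particles(f, center = c(124, 27), depth = 800, n = 150,
                           radius_km = 25, rng_seed = 107)
  traj <- advect(rel, f, duration_days = 35)
  ii <- round((traj$lon - f$lon[1]) / 0.25) + 1
  jj <- round((traj$lat - f$lat[1]) / 0.25) + 1
  ii <- pmin(pmax(ii, 1), length(f$lon))
  jj <- pmin(pmax(jj, 1), length(f$lat))
  depth_at <- matrix(f$bathy[cbind(as.vector(ii), as.vector(jj))],
                     nrow(ii), ncol(ii))
  for (p in seq_len(nrow(ii))) {
    ok_days <- if (is.na(traj$event_day[p])) seq_len(ncol(ii)) else
      seq_len(floor(traj$event_day[p]))
    expect_true(all(depth_at[p, ok_days] >= 800))
  }
})

test_that("release and advection are deterministic end to end", {
  cfg <- ocean_config(eddy_energy = 0.3, n_days = 12)
  f1 <- make_synthetic_ocean(cfg, rng_seed = 108)
  f2 <- make_synthetic_ocean(cfg, rng_seed = 108)
  expect_identical(f1$u, f2$u)
  r1 <- release_particles(f1, c(124, 27), 500, 50, rng_seed = 109)
  r2 <- release_particles(f2, c(124, 27), 500, 50, rng_seed = 109)
  expect_identical(r1, r2)
  t1 <- advect(r1, f1, 10)
  t2 <- advect(r2, f2, 10)
  expect_identical(t1$lon, t2$lon)
})

trough_polygon <- function(cfg) {
  tl <- cfg$trough_lon + c(-cfg$ridge_width, cfg$ridge_width)
  tt <- cfg$trough_lat + c(-cfg$ridge_width, cfg$ridge_width)
  cbind(c(tl[1], tl[2], tl[2], tl[1]), c(tt[1], tt[1], tt[2], tt[2]))
}

test_that("a single gate is passable above its floor and sealed below", {
  cfg <- ocean_config(gates = list(east = list(side = "east", center = 27,
                                               width = 0.75, depth = 700)),
                      eddy_energy = 0.25, n_days = 130,
                      levels = c(500, 800))
  f <- make_synthetic_ocean(cfg, rng_seed = 110)
  poly <- trough_polygon(cfg)
  gates <- list(east = rbind(c(127, 26.6), c(127, 27.4)))
  run <- function(depth) {
    rel <- release_particles(f, c(124, 27), depth, 400, rng_seed = 111)
    traj <- advect(rel, f, 120)
    basin_exchange(traj, poly, gates)
  }
  at500 <- run(500)
  at800 <- run(800)
  expect_gt(max(at500$counts$cum_exited), 0)
  expect_identical(max(at800$counts$cum_exited), 0L)
  # crossings at 500 m are attributed to the east gate
  ex <- at500$crossings[at500$crossings$direction == "exit", ]
  expect_true(all(ex$gate == "east"))
})

test_that("basin accounting handles trivial and degenerate cases", {
  f <- rotation_field()
  f$u[] <- 0
  f$v[] <- 0
  rel <- release_particles(f, c(0, 0), 0, 30, radius_km = 5, rng_seed = 112)
  traj <- advect(rel, f, 5)
  poly <- cbind(c(-0.5, 0.5, 0.5, -0.5), c(-0.5, -0.5, 0.5, 0.5))
  ex <- basin_exchange(traj, poly)
  expect_true(all(ex$counts$inside == 30))
  expect_identical(nrow(ex$crossings), 0L)
  bowtie <- cbind(c(0, 1, 1, 0), c(0, 1, 0, 1))
  expect_error(basin_exchange(traj, bowtie), "self-intersecting")
  # a straight crossing of a gate segment is attributed to it
  traj$lon[1, ] <- seq(0, 1, length.out = 6)
  traj$lat[1, ] <- 0
  ex2 <- basin_exchange(traj, poly, gates = list(g = rbind(c(0.5, -0.2),
                                                           c(0.5, 0.2))))
  cr <- ex2$crossings
  expect_identical(nrow(cr), 1L)
  expect_identical(cr$gate, "g")
  expect_identical(cr$direction, "exit")
})
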