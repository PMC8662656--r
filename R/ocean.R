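#' Configuration of the synthetic trough / boundary-current ocean
#'
#' The synthetic domain emulates a semi-enclosed deep trough: a deep basin
#' (`trough_depth`) elongated east-west, bounded by a flanking ridge whose
#' crest sits at `ridge_depth`, cut by named gate channels whose floors are
#' deeper than the crest; outside lies open ocean (`open_depth`). The
#' deepest gate floor is the basin's effective sill: lateral export below it
#' is topographically blocked. The flow is an along-axis jet whose speed
#' decays with depth as `U(z) = U0 * exp(-z / H)` with `H` fixed so that
#' `U(1000 m) = 0.1 * U0` (about 1 m/s at the surface decaying to 0.1 m/s at
#' 1,000 m for the default `U0 = 1`), plus a stochastic non-divergent
#' mesoscale eddy field derived from a smoothed random stream function per
#' depth level with AR(1) day-to-day persistence.
#'
#' @param lon_range,lat_range domain extent (degrees)
#' @param resolution grid spacing (degrees)
#' @param levels depth levels (m, positive down)
#' @param n_days number of daily velocity snapshots
#' @param origin first day (Date or string)
#' @param trough_lon,trough_lat trough extent (degrees)
#' @param trough_depth,ridge_depth,open_depth bathymetry (m)
#' @param ridge_width ridge band width (degrees)
#' @param gates named list; each gate has `side` ("north"/"south"/"east"/
#'   "west"), `center` (lon for north/south, lat for east/west), `width`
#'   (degrees) and `depth` (gate floor, m; must lie between the ridge crest
#'   and the trough floor)
#' @param jet_speed_surface surface jet speed `U0` (m/s)
#' @param jet_lat,jet_width jet core latitude and Gaussian half-width (deg)
#' @param seasonal_amplitude relative annual modulation of the jet speed
#' @param eddy_energy eddy RMS speed as a fraction of the local jet scale
#'   `U(z)` (0 disables eddies and makes the field time-invariant)
#' @param eddy_length eddy correlation length (degrees)
#' @param eddy_time_scale eddy decorrelation time (days)
#' @return an object of class `ocean_config`
#' @export
ocean_config <- function(lon_range = c(120, 128), lat_range = c(24, 30),
                         resolution = 0.25,
                         levels = c(0, 500, 600, 700, 800, 1000, 1250),
                         n_days = 365, origin = "2011-01-01",
                         trough_lon = c(121.5, 126.5),
                         trough_lat = c(26, 28), trough_depth = 2500,
                         ridge_depth = 400, open_depth = 5000,
                         ridge_width = 0.5,
                         gates = list(
                           okinawa_east = list(side = "north", center = 124.5,
                                               width = 0.5, depth = 600),
                           east_taiwan = list(side = "west", center = 27,
                                              width = 0.5, depth = 700),
                           kerama = list(side = "east", center = 27,
                                         width = 0.5, depth = 850)),
                         jet_speed_surface = 1.0, jet_lat = 27,
                         jet_width = 0.5, seasonal_amplitude = 0,
                         eddy_energy = 0.3, eddy_length = 0.75,
                         eddy_time_scale = 10) {
  cfg <- as.list(environment())
  cfg$jet_decay_scale <- 1000 / log(10)       # U(1000 m) = U0 / 10
  for (g in names(cfg$gates)) {
    gate <- cfg$gates[[g]]
    if (!gate$side %in% c("north", "south", "east", "west")) {
      stop("gate ", g, ": unknown side ", gate$side)
    }
    if (gate$depth >= trough_depth) {
      stop("gate ", g, ": sill deeper than the trough floor")
    }
    if (gate$depth <= ridge_depth) {
      stop("gate ", g, ": gate floor must be deeper than the ridge crest")
    }
    on_lon <- gate$side %in% c("north", "south")
    rng <- if (on_lon) trough_lon else trough_lat
    if (gate$center < rng[1] || gate$center > rng[2]) {
      stop("gate ", g, ": gap outside the ridge")
    }
  }
  cfg$sill_depth <- if (length(cfg$gates)) {
    max(vapply(cfg$gates, `[[`, numeric(1), "depth"))
  } else {
    ridge_depth
  }
  structure(cfg, class = "ocean_config")
}

#' Jet speed at depth
#'
#' @param depth depth in m
#' @param config an [ocean_config()]
#' @return speed in m/s at the jet core
#' @export
jet_speed <- function(depth, config = ocean_config()) {
  config$jet_speed_surface * exp(-depth / config$jet_decay_scale)
}

.gaussian_smooth <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  sm_rows <- apply(m, 2, function(col) {
    as.numeric(stats::filter(c(rev(col[seq_len(half)]), col,
                               rev(col[length(col) - seq_len(half) + 1])),
                             k, sides = 2))[half + seq_along(col)]
  })
  t(apply(sm_rows, 1, function(row) {
    as.numeric(stats::filter(c(rev(row[seq_len(half)]), row,
                               rev(row[length(row) - seq_len(half) + 1])),
                             k, sides = 2))[half + seq_along(row)]
  }))
}

.r_earth <- 6371000

# velocities (u, v) from a stream function on the cell-centred grid, by
# centred differences of the spherical form u = -(1/R) dpsi/dphi,
# v = (1/(R cos phi)) dpsi/dlambda; discretely non-divergent for the
# matching centred-difference spherical divergence (see field_divergence)
.psi_to_uv <- function(psi, lat, dlon, dlat) {
  nlon <- nrow(psi)
  nlat <- ncol(psi)
  u <- v <- matrix(0, nlon, nlat)
  dphi <- dlat * pi / 180
  dlam <- dlon * pi / 180
  u[, 2:(nlat - 1)] <- -(psi[, 3:nlat] - psi[, 1:(nlat - 2)]) /
    (2 * dphi * .r_earth)
  cphi <- cos(lat * pi / 180)
  v[2:(nlon - 1), ] <- (psi[3:nlon, ] - psi[1:(nlon - 2), ]) /
    (2 * dlam * .r_earth)
  v <- sweep(v, 2, cphi, "/")
  list(u = u, v = v)
}

#' Generate a synthetic velocity field and bathymetry
#'
#' @param config an [ocean_config()]
#' @param rng_seed integer seed or `NULL`
#' @return an object of class `velocity_field`: `lon`, `lat`, `depth`,
#'   `time` (Date), arrays `u`, `v` (lon x lat x depth x time, m/s), matrix
#'   `bathy` (lon x lat, m positive down) and the `config`. Velocities are
#'   exactly zero wherever the bathymetry is shallower than the level depth.
#' @export
make_synthetic_ocean <- function(config = ocean_config(), rng_seed = NULL) {
  stopifnot(inherits(config, "ocean_config"))
  lon <- seq(config$lon_range[1], config$lon_range[2], by = config$resolution)
  lat <- seq(config$lat_range[1], config$lat_range[2], by = config$resolution)
  nlon <- length(lon)
  nlat <- length(lat)
  tl <- config$trough_lon
  tt <- config$trough_lat
  w <- config$ridge_width

  bathy <- matrix(config$open_depth, nlon, nlat)
  in_ridge <- outer(lon >= tl[1] - w & lon <= tl[2] + w,
                    lat >= tt[1] - w & lat <= tt[2] + w, "&")
  bathy[in_ridge] <- config$ridge_depth
  for (g in config$gates) {
    cells <- switch(g$side,
      north = outer(abs(lon - g$center) <= g$width / 2,
                    lat > tt[2] & lat <= tt[2] + w, "&"),
      south = outer(abs(lon - g$center) <= g$width / 2,
                    lat >= tt[1] - w & lat < tt[1], "&"),
      east = outer(lon > tl[2] & lon <= tl[2] + w,
                   abs(lat - g$center) <= g$width / 2, "&"),
      west = outer(lon >= tl[1] - w & lon < tl[1],
                   abs(lat - g$center) <= g$width / 2, "&"))
    bathy[cells & in_ridge] <- g$depth
  }
  in_trough <- outer(lon >= tl[1] & lon <= tl[2],
                     lat >= tt[1] & lat <= tt[2], "&")
  bathy[in_trough] <- config$trough_depth

  ndep <- length(config$levels)
  ntime <- if (config$eddy_energy > 0) config$n_days else 1L
  u <- array(0, c(nlon, nlat, ndep, ntime))
  v <- array(0, c(nlon, nlat, ndep, ntime))
  time <- as.Date(config$origin) + seq_len(ntime) - 1L
  doy <- as.numeric(format(time, "%j"))
  season_fac <- 1 + config$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)

  jet_profile <- exp(-((lat - config$jet_lat) / config$jet_width)^2)
  with_seed(rng_seed, {
    for (k in seq_len(ndep)) {
      uz <- jet_speed(config$levels[k], config)
      ujet <- outer(rep(1, nlon), jet_profile) * uz
      mask <- bathy < config$levels[k] | bathy <= 0
      psi <- NULL
      rho <- exp(-1 / config$eddy_time_scale)
      for (ti in seq_len(ntime)) {
        uu <- ujet * season_fac[ti]
        vv <- matrix(0, nlon, nlat)
        if (config$eddy_energy > 0) {
          noise <- .gaussian_smooth(matrix(rnorm(nlon * nlat), nlon, nlat),
                                    config$eddy_length / config$resolution)
          psi <- if (is.null(psi)) noise else
            rho * psi + sqrt(1 - rho^2) * noise
          ed <- .psi_to_uv(psi, lat, config$resolution, config$resolution)
          spd <- sqrt(ed$u^2 + ed$v^2)
          rms <- sqrt(mean(spd[!mask]^2))
          if (rms > 0) {
            s <- config$eddy_energy * uz / rms
            uu <- uu + ed$u * s
            vv <- vv + ed$v * s
          }
        }
        uu[mask] <- 0
        vv[mask] <- 0
        u[, , k, ti] <- uu
        v[, , k, ti] <- vv
      }
    }
  })
  structure(list(lon = lon, lat = lat, depth = config$levels, time = time,
                 u = u, v = v, bathy = bathy, config = config),
            class = "velocity_field")
}

#' @export
print.velocity_field <- function(x, ...) {
  cat("velocity_field:", length(x$lon), "x", length(x$lat), "grid,",
      length(x$depth), "levels,", length(x$time), "daily snapshots\n")
  cat("levels (m):", paste(x$depth, collapse = ", "), "\n")
  invisible(x)
}

#' Seasonal-mean velocity field
#'
#' Arithmetic mean of the daily fields over a season across an ensemble of
#' years; winter spans December of each requested year together with the
#' following January and February.
#'
#' @param field a `velocity_field`
#' @param season one of `"spring"` (MAM), `"summer"` (JJA), `"fall"` (SON),
#'   `"winter"` (DJF)
#' @param years calendar years of the ensemble
#' @return a time-invariant `velocity_field` (single time slice)
#' @export
seasonal_mean <- function(field, season = c("spring", "summer", "fall",
                                            "winter"),
                          years = unique(as.numeric(format(field$time, "%Y")))) {
  season <- match.arg(season)
  mo <- as.numeric(format(field$time, "%m"))
  yr <- as.numeric(format(field$time, "%Y"))
  sel <- switch(season,
    spring = mo %in% 3:5 & yr %in% years,
    summer = mo %in% 6:8 & yr %in% years,
    fall = mo %in% 9:11 & yr %in% years,
    winter = (mo == 12 & yr %in% years) | (mo %in% 1:2 & (yr - 1) %in% years))
  if (!any(sel)) stop("no daily fields in the requested season/years")
  um <- rowMeans(field$u[, , , sel, drop = FALSE], dims = 3)
  vm <- rowMeans(field$v[, , , sel, drop = FALSE], dims = 3)
  out <- field
  out$u <- array(um, c(dim(um), 1))
  out$v <- array(vm, c(dim(vm), 1))
  out$time <- field$time[which(sel)[1]]
  out
}

#' Discrete spherical divergence of a field level
#'
#' Centred-difference flux divergence
#' `(1/(R cos phi)) (du/dlambda + d(v cos phi)/dphi)` on the interior of the
#' grid, the operator for which the eddy stream-function construction is
#' exactly non-divergent.
#'
#' @param field a `velocity_field`
#' @param level_index depth level index
#' @param time_index time slice index
#' @return matrix (lon x lat) with `NA` on the boundary
#' @export
field_divergence <- function(field, level_index = 1, time_index = 1) {
  u <- field$u[, , level_index, time_index]
  v <- field$v[, , level_index, time_index]
  nlon <- nrow(u)
  nlat <- ncol(u)
  dlam <- (field$lon[2] - field$lon[1]) * pi / 180
  dphi <- (field$lat[2] - field$lat[1]) * pi / 180
  cphi <- cos(field$lat * pi / 180)
  div <- matrix(NA_real_, nlon, nlat)
  i <- 2:(nlon - 1)
  j <- 2:(nlat - 1)
  dudl <- (u[i + 1, j] - u[i - 1, j]) / (2 * dlam)
  vc <- sweep(v, 2, cphi, "*")
  dvdp <- (vc[i, j + 1] - vc[i, j - 1]) / (2 * dphi)
  div[i, j] <- (dudl + dvdp) / (.r_earth * matrix(cphi[j], length(i),
                                                  length(j), byrow = TRUE))
  div
}

#' Save / load a velocity field
#'
#' Serialized with R's native format; intended for caching generated fields
#' between pipeline stages, not for archival exchange.
#'
#' @param field a `velocity_field`
#' @param path file path
#' @return `path` (write) or the `velocity_field` (read)
#' @export
write_field <- function(field, path) {
  saveRDS(field, path)
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path) readRDS(path)
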