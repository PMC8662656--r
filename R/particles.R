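#' Release particles uniformly within a disk
#'
#' Positions are area-uniform over a great-circle disk of radius
#' `radius_km` around the release site (radius drawn as `R * sqrt(U)`,
#' bearing uniform). Particles landing on cells shallower than the release
#' depth are resampled; an entirely blocked disk is an error.
#'
#' @param field a `velocity_field`
#' @param center release site, `c(lon, lat)` in degrees
#' @param depth release depth (m); must match one of the field's levels
#' @param n number of particles
#' @param radius_km release radius (default 25 km)
#' @param date release date (Date or string; default: first field day)
#' @param rng_seed integer seed or `NULL`
#' @param max_rounds resampling budget
#' @return a `particle_set` data.frame (id, lon, lat) with release metadata
#'   in attributes
#' @export
release_particles <- function(field, center, depth, n, radius_km = 25,
                              date = NULL, rng_seed = NULL,
                              max_rounds = 100L) {
  stopifnot(inherits(field, "velocity_field"), n >= 1, radius_km >= 0)
  if (!depth %in% field$depth) {
    stop("depth ", depth, " is not one of the field's levels")
  }
  date <- as.Date(date %||% field$time[1])
  dlon <- field$lon[2] - field$lon[1]
  dlat <- field$lat[2] - field$lat[1]
  blocked <- function(lon, lat) {
    i <- pmin(pmax(round((lon - field$lon[1]) / dlon) + 1, 1),
              length(field$lon))
    j <- pmin(pmax(round((lat - field$lat[1]) / dlat) + 1, 1),
              length(field$lat))
    field$bathy[cbind(i, j)] < depth
  }
  with_seed(rng_seed, {
    out <- matrix(NA_real_, n, 2)
    need <- seq_len(n)
    for (round in seq_len(max_rounds)) {
      m <- length(need)
      pts <- geosphere::destPoint(p = matrix(center, m, 2, byrow = TRUE),
                                  b = runif(m, 0, 360),
                                  d = radius_km * 1000 * sqrt(runif(m)))
      ok <- !blocked(pts[, 1], pts[, 2])
      out[need[ok], ] <- pts[ok, , drop = FALSE]
      need <- need[!ok]
      if (!length(need)) break
    }
    if (length(need)) {
      stop("release disk appears entirely blocked at ", depth, " m")
    }
    structure(data.frame(id = seq_len(n), lon = out[, 1], lat = out[, 2]),
              class = c("particle_set", "data.frame"),
              center = center, depth = depth, radius_km = radius_km,
              date = date)
  })
}

#' Advect particles through a velocity field
#'
#' Horizontal-only advection at the particles' fixed release depth, with
#' adaptive Dormand-Prince RK5(4) stepping, bicubic spatial interpolation of
#' the velocities and linear interpolation in time between daily snapshots.
#' A particle entering a cell shallower than its depth beaches and stops; a
#' particle leaving the domain stops with status `exited`. Positions are
#' recorded daily.
#'
#' @param particles a `particle_set` from [release_particles()]
#' @param field a `velocity_field`
#' @param duration_days advection duration
#' @param rtol,atol relative / absolute local error tolerances (degrees)
#' @return a `trajectory_set`: matrices `lon`, `lat`
#'   (particles x days + 1), `status` (active/beached/exited), `event_day`,
#'   `time`, and the release metadata
#' @export
advect <- function(particles, field, duration_days, rtol = 1e-5,
                   atol = 1e-6) {
  stopifnot(inherits(particles, "particle_set"),
            inherits(field, "velocity_field"), duration_days >= 1)
  depth <- attr(particles, "depth")
  lev <- match(depth, field$depth)
  if (is.na(lev)) stop("particle depth not among field levels")
  ntime <- length(field$time)
  start_day <- as.numeric(attr(particles, "date") - field$time[1])
  if (ntime > 1) {
    if (start_day < 0 || start_day + duration_days > ntime - 1) {
      stop("advection window extends beyond the field's time span")
    }
  }
  u <- field$u[, , lev, , drop = TRUE]
  v <- field$v[, , lev, , drop = TRUE]
  res <- advect_cpp(particles$lon, particles$lat, as.numeric(u),
                    as.numeric(v), as.numeric(field$bathy),
                    field$lon[1], field$lon[2] - field$lon[1],
                    length(field$lon),
                    field$lat[1], field$lat[2] - field$lat[1],
                    length(field$lat), ntime, start_day,
                    as.integer(duration_days), depth, rtol, atol)
  if (any(!is.finite(res$lon[res$status == 0, ]))) {
    stop("non-finite positions produced; velocity field corrupt?")
  }
  structure(list(lon = res$lon, lat = res$lat,
                 status = c("active", "beached", "exited")[res$status + 1L],
                 event_day = res$event_day,
                 time = attr(particles, "date") + 0:duration_days,
                 depth = depth, particles = particles),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  cat("trajectory_set:", nrow(x$lon), "particles,",
      ncol(x$lon) - 1, "days at", x$depth, "m\n")
  print(table(status = x$status))
  invisible(x)
}

#' Write trajectories as CSV (id, day, lon, lat, status)
#'
#' @param traj a `trajectory_set`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_trajectories <- function(traj, path) {
  n <- nrow(traj$lon)
  days <- ncol(traj$lon) - 1
  df <- data.frame(id = rep(seq_len(n), days + 1),
                   day = rep(0:days, each = n),
                   lon = as.vector(traj$lon), lat = as.vector(traj$lat),
                   status = rep(traj$status, days + 1))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# even-odd ray-casting point-in-polygon, vectorized over points
.point_in_polygon <- function(lon, lat, poly) {
  inside <- rep(FALSE, length(lon))
  m <- nrow(poly)
  j <- m
  for (i in seq_len(m)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > lat) != (yj > lat)) &
      (lon < (xj - xi) * (lat - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

.segments_intersect <- function(p1, p2, p3, p4) {
  d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
  d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
  (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &
     ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0)))
}

.check_simple_polygon <- function(poly) {
  m <- nrow(poly)
  seg <- function(i) list(poly[i, ], poly[i %% m + 1, ])
  for (i in seq_len(m - 2)) {
    for (j in (i + 2):m) {
      if (i == 1 && j == m) next
      s1 <- seg(i); s2 <- seg(j)
      if (.segments_intersect(s1[[1]], s1[[2]], s2[[1]], s2[[2]])) {
        stop("basin polygon is self-intersecting")
      }
    }
  }
  invisible(TRUE)
}

.dist_point_segment_km <- function(lon, lat, a, b) {
  # planar approximation scaled by cos(lat); adequate at gate scales
  kx <- 111.32 * cos(lat * pi / 180)
  ky <- 110.57
  px <- (lon - a[1]) * kx; py <- (lat - a[2]) * ky
  vx <- (b[1] - a[1]) * kx; vy <- (b[2] - a[2]) * ky
  tt <- pmin(pmax((px * vx + py * vy) / (vx^2 + vy^2), 0), 1)
  sqrt((px - tt * vx)^2 + (py - tt * vy)^2)
}

#' Basin occupancy and gate-crossing accounting
#'
#' Counts, at every output time, the particles inside and outside a basin
#' polygon, and attributes each particle's first boundary crossing to the
#' nearest named gate segment (or `"other"` when no gate lies within
#' `gate_tol_km` of the crossing point). Cumulative exit and entry counts
#' are monotone by construction.
#'
#' @param traj a `trajectory_set`
#' @param basin_polygon matrix of (lon, lat) vertices (closed implicitly)
#' @param gates named list of gate segments, each a 2 x 2 matrix of
#'   (lon, lat) endpoints lying on the basin boundary
#' @param gate_tol_km attribution radius around gate segments
#' @return list: `counts` (data.frame day, inside, outside, cum_exited,
#'   cum_entered) and `crossings` (data.frame id, day, direction, gate)
#' @export
basin_exchange <- function(traj, basin_polygon, gates = list(),
                           gate_tol_km = 50) {
  stopifnot(inherits(traj, "trajectory_set"))
  poly <- as.matrix(basin_polygon)
  if (nrow(poly) < 3) stop("polygon needs at least 3 vertices")
  .check_simple_polygon(poly)
  n <- nrow(traj$lon)
  nt <- ncol(traj$lon)
  inside <- matrix(FALSE, n, nt)
  for (tday in seq_len(nt)) {
    inside[, tday] <- .point_in_polygon(traj$lon[, tday], traj$lat[, tday],
                                        poly)
  }
  counts <- data.frame(day = 0:(nt - 1), inside = colSums(inside),
                       outside = n - colSums(inside))
  crossings <- data.frame(id = integer(0), day = integer(0),
                          direction = character(0), gate = character(0))
  for (ip in seq_len(n)) {
    tr <- which(inside[ip, -nt] != inside[ip, -1])
    if (!length(tr)) next
    tday <- tr[1]                       # first crossing only
    mid_lon <- (traj$lon[ip, tday] + traj$lon[ip, tday + 1]) / 2
    mid_lat <- (traj$lat[ip, tday] + traj$lat[ip, tday + 1]) / 2
    gate <- "other"
    if (length(gates)) {
      dists <- vapply(gates, function(g) {
        g <- as.matrix(g)
        .dist_point_segment_km(mid_lon, mid_lat, g[1, ], g[2, ])
      }, numeric(1))
      if (min(dists) <= gate_tol_km) gate <- names(gates)[which.min(dists)]
    }
    crossings[nrow(crossings) + 1L, ] <-
      list(ip, tday, if (inside[ip, tday]) "exit" else "entry", gate)
  }
  first_cross <- rep(NA_integer_, n)
  first_dir <- rep(NA_character_, n)
  if (nrow(crossings)) {
    first_cross[crossings$id] <- crossings$day
    first_dir[crossings$id] <- crossings$direction
  }
  cum_exit <- cum_entry <- integer(nt)
  for (tday in seq_len(nt)) {
    cum_exit[tday] <- sum(!is.na(first_cross) & first_dir == "exit" &
                            first_cross < tday)
    cum_entry[tday] <- sum(!is.na(first_cross) & first_dir == "entry" &
                             first_cross < tday)
  }
  counts$cum_exited <- cum_exit
  counts$cum_entered <- cum_entry
  list(counts = counts, crossings = crossings)
}
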