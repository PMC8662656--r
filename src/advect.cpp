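#include <Rcpp.h>
using namespace Rcpp;

// Horizontal Lagrangian advection at a fixed depth level.
//
// Velocities are sampled by Catmull-Rom bicubic interpolation on the
// cell-centred lon/lat grid and linear interpolation in time between daily
// snapshots; positions are advanced on the sphere (angular rates u/(R cos
// phi), v/R) with a Dormand-Prince RK5(4) adaptive pair. A particle whose
// nearest grid cell is shallower than its depth (including land) beaches and
// stops; a particle leaving the grid exits the domain. Both transitions are
// one-way.

static inline double cr_w(double t, int k) {
  // Catmull-Rom kernel weights for offsets k = -1..2
  switch (k) {
    case -1: return 0.5 * (-t * t * t + 2.0 * t * t - t);
    case 0:  return 0.5 * (3.0 * t * t * t - 5.0 * t * t + 2.0);
    case 1:  return 0.5 * (-3.0 * t * t * t + 4.0 * t * t + t);
    default: return 0.5 * (t * t * t - t * t);
  }
}

static inline int clampi(int i, int lo, int hi) {
  return i < lo ? lo : (i > hi ? hi : i);
}

struct Grid {
  const double *u, *v, *bathy;
  int nlon, nlat, ntime;
  double lon0, dlon, lat0, dlat;
};

static double interp2(const double *f, const Grid &g, double x, double y,
                      int tslice) {
  const int i0 = (int)std::floor(x), j0 = (int)std::floor(y);
  const double tx = x - i0, ty = y - j0;
  const double *base = f + (size_t)tslice * g.nlon * g.nlat;
  double acc = 0.0;
  for (int kj = -1; kj <= 2; ++kj) {
    const int j = clampi(j0 + kj, 0, g.nlat - 1);
    const double wy = cr_w(ty, kj);
    double row = 0.0;
    for (int ki = -1; ki <= 2; ++ki) {
      const int i = clampi(i0 + ki, 0, g.nlon - 1);
      row += cr_w(tx, ki) * base[(size_t)j * g.nlon + i];
    }
    acc += wy * row;
  }
  return acc;
}

static void velocity(const Grid &g, double x, double y, double tday,
                     double *uu, double *vv) {
  if (g.ntime == 1) {
    *uu = interp2(g.u, g, x, y, 0);
    *vv = interp2(g.v, g, x, y, 0);
    return;
  }
  double tc = tday;
  if (tc < 0.0) tc = 0.0;
  if (tc > g.ntime - 1.0) tc = g.ntime - 1.0;
  int t0 = (int)std::floor(tc);
  if (t0 > g.ntime - 2) t0 = g.ntime - 2;
  const double f = tc - t0;
  *uu = (1.0 - f) * interp2(g.u, g, x, y, t0) + f * interp2(g.u, g, x, y, t0 + 1);
  *vv = (1.0 - f) * interp2(g.v, g, x, y, t0) + f * interp2(g.v, g, x, y, t0 + 1);
}

static const double R_EARTH = 6371000.0;
static const double DEG = 57.29577951308232;   // 180/pi
static const double SPD = 86400.0;             // seconds per day

// derivative of (lon, lat) in degrees/day
static void deriv(const Grid &g, double lon, double lat, double tday,
                  double *dlon, double *dlat) {
  const double x = (lon - g.lon0) / g.dlon, y = (lat - g.lat0) / g.dlat;
  double uu, vv;
  velocity(g, x, y, tday, &uu, &vv);
  double cphi = std::cos(lat / DEG);
  if (cphi < 1e-6) cphi = 1e-6;
  *dlon = uu * SPD / (R_EARTH * cphi) * DEG;
  *dlat = vv * SPD / R_EARTH * DEG;
}

// Dormand-Prince 5(4) coefficients
static const double C2 = 1.0 / 5, C3 = 3.0 / 10, C4 = 4.0 / 5, C5 = 8.0 / 9;
static const double A21 = 1.0 / 5;
static const double A31 = 3.0 / 40, A32 = 9.0 / 40;
static const double A41 = 44.0 / 45, A42 = -56.0 / 15, A43 = 32.0 / 9;
static const double A51 = 19372.0 / 6561, A52 = -25360.0 / 2187,
                    A53 = 64448.0 / 6561, A54 = -212.0 / 729;
static const double A61 = 9017.0 / 3168, A62 = -355.0 / 33,
                    A63 = 46732.0 / 5247, A64 = 49.0 / 176,
                    A65 = -5103.0 / 18656;
static const double B1 = 35.0 / 384, B3 = 500.0 / 1113, B4 = 125.0 / 192,
                    B5 = -2187.0 / 6784, B6 = 11.0 / 84;
static const double E1 = 71.0 / 57600, E3 = -71.0 / 16695, E4 = 71.0 / 1920,
                    E5 = -17253.0 / 339200, E6 = 22.0 / 525, E7 = -1.0 / 40;

// [[Rcpp::export]]
List advect_cpp(NumericVector lon, NumericVector lat, NumericVector u,
                NumericVector v, NumericVector bathy, double lon0,
                double dlon, int nlon, double lat0, double dlat, int nlat,
                int ntime, double start_day, int duration_days, double depth,
                double rtol, double atol) {
  Grid g;
  g.u = u.begin(); g.v = v.begin(); g.bathy = bathy.begin();
  g.nlon = nlon; g.nlat = nlat; g.ntime = ntime;
  g.lon0 = lon0; g.dlon = dlon; g.lat0 = lat0; g.dlat = dlat;

  const int np = lon.size();
  NumericMatrix out_lon(np, duration_days + 1), out_lat(np, duration_days + 1);
  IntegerVector status(np, 0);          // 0 active, 1 beached, 2 exited
  NumericVector event_day(np, NA_REAL);

  const double lon_min = lon0, lon_max = lon0 + dlon * (nlon - 1);
  const double lat_min = lat0, lat_max = lat0 + dlat * (nlat - 1);

  for (int ip = 0; ip < np; ++ip) {
    double plon = lon[ip], plat = lat[ip];
    int st = 0;
    out_lon(ip, 0) = plon;
    out_lat(ip, 0) = plat;

    // immediate checks at release
    {
      const int ri = clampi((int)std::lround((plon - lon0) / dlon), 0, nlon - 1);
      const int rj = clampi((int)std::lround((plat - lat0) / dlat), 0, nlat - 1);
      if (plon < lon_min || plon > lon_max || plat < lat_min || plat > lat_max) {
        st = 2; event_day[ip] = 0.0;
      } else if (bathy[(size_t)rj * nlon + ri] < depth) {
        st = 1; event_day[ip] = 0.0;
      }
    }

    double h = 0.25;
    double k1lon = 0.0, k1lat = 0.0;
    bool have_k1 = false;

    for (int day = 0; day < duration_days; ++day) {
      if (st != 0) {
        out_lon(ip, day + 1) = plon;
        out_lat(ip, day + 1) = plat;
        continue;
      }
      double t = 0.0;                    // time within the day
      while (t < 1.0 && st == 0) {
        if (h > 1.0 - t) h = 1.0 - t;
        if (h < 1e-7) h = 1e-7;
        const double ftime = start_day + day + t;
        if (!have_k1) {
          deriv(g, plon, plat, ftime, &k1lon, &k1lat);
          have_k1 = true;
        }
        double k2lon, k2lat, k3lon, k3lat, k4lon, k4lat, k5lon, k5lat,
            k6lon, k6lat, k7lon, k7lat;
        deriv(g, plon + h * A21 * k1lon, plat + h * A21 * k1lat,
              ftime + C2 * h, &k2lon, &k2lat);
        deriv(g, plon + h * (A31 * k1lon + A32 * k2lon),
              plat + h * (A31 * k1lat + A32 * k2lat), ftime + C3 * h,
              &k3lon, &k3lat);
        deriv(g, plon + h * (A41 * k1lon + A42 * k2lon + A43 * k3lon),
              plat + h * (A41 * k1lat + A42 * k2lat + A43 * k3lat),
              ftime + C4 * h, &k4lon, &k4lat);
        deriv(g, plon + h * (A51 * k1lon + A52 * k2lon + A53 * k3lon + A54 * k4lon),
              plat + h * (A51 * k1lat + A52 * k2lat + A53 * k3lat + A54 * k4lat),
              ftime + C5 * h, &k5lon, &k5lat);
        deriv(g, plon + h * (A61 * k1lon + A62 * k2lon + A63 * k3lon +
                             A64 * k4lon + A65 * k5lon),
              plat + h * (A61 * k1lat + A62 * k2lat + A63 * k3lat +
                          A64 * k4lat + A65 * k5lat),
              ftime + h, &k6lon, &k6lat);
        const double ylon = plon + h * (B1 * k1lon + B3 * k3lon + B4 * k4lon +
                                        B5 * k5lon + B6 * k6lon);
        const double ylat = plat + h * (B1 * k1lat + B3 * k3lat + B4 * k4lat +
                                        B5 * k5lat + B6 * k6lat);
        deriv(g, ylon, ylat, ftime + h, &k7lon, &k7lat);
        const double elon = h * (E1 * k1lon + E3 * k3lon + E4 * k4lon +
                                 E5 * k5lon + E6 * k6lon + E7 * k7lon);
        const double elat = h * (E1 * k1lat + E3 * k3lat + E4 * k4lat +
                                 E5 * k5lat + E6 * k6lat + E7 * k7lat);
        const double sclon = atol + rtol * std::max(std::fabs(plon), std::fabs(ylon));
        const double sclat = atol + rtol * std::max(std::fabs(plat), std::fabs(ylat));
        const double err = std::sqrt(0.5 * ((elon / sclon) * (elon / sclon) +
                                            (elat / sclat) * (elat / sclat)));
        if (err <= 1.0 || h <= 1e-7) {
          t += h;
          plon = ylon;
          plat = ylat;
          k1lon = k7lon; k1lat = k7lat;  // FSAL
          if (plon < lon_min || plon > lon_max || plat < lat_min ||
              plat > lat_max) {
            st = 2;
            event_day[ip] = day + t;
          } else {
            const int ri = clampi((int)std::lround((plon - lon0) / dlon), 0, nlon - 1);
            const int rj = clampi((int)std::lround((plat - lat0) / dlat), 0, nlat - 1);
            if (bathy[(size_t)rj * nlon + ri] < depth) {
              st = 1;
              event_day[ip] = day + t;
            }
          }
        } else {
          have_k1 = true;                // k1 still valid at unchanged state
        }
        double fac = 0.9 * std::pow(std::max(err, 1e-10), -0.2);
        if (fac < 0.2) fac = 0.2;
        if (fac > 5.0) fac = 5.0;
        h *= fac;
        if (h > 1.0) h = 1.0;
      }
      out_lon(ip, day + 1) = plon;
      out_lat(ip, day + 1) = plat;
      status[ip] = st;
    }
    status[ip] = st;
  }
  return List::create(_["lon"] = out_lon, _["lat"] = out_lat,
                      _["status"] = status, _["event_day"] = event_day);
}
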