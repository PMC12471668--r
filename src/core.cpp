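#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Internal unit system: length Angstrom, time ps, mass g/mol, temperature K.
// Gas constant in g/mol * A^2 / ps^2 / K  (= J/mol/K divided by 10).
static const double R_INTERNAL = 0.8314462618;

// Marsaglia polar method on R's uniform stream; one cached spare.
struct NormGen {
  bool has;
  double spare;
  NormGen() : has(false), spare(0.0) {}
  inline double next() {
    if (has) { has = false; return spare; }
    double u, v, s;
    do {
      u = 2.0 * unif_rand() - 1.0;
      v = 2.0 * unif_rand() - 1.0;
      s = u * u + v * v;
    } while (s >= 1.0 || s == 0.0);
    double m = std::sqrt(-2.0 * std::log(s) / s);
    spare = v * m;
    has = true;
    return u * m;
  }
};

// Linear interpolation into a precomputed acceleration table on a uniform grid.
static inline double accel_interp(double z, const double *acc, double z0,
                                  double inv_h, int n) {
  double x = (z - z0) * inv_h;
  if (x <= 0.0) return acc[0];
  if (x >= n - 1) return acc[n - 1];
  int i = (int)x;
  double w = x - i;
  return acc[i] * (1.0 - w) + acc[i + 1] * w;
}

// BAOAB inertial Langevin chunk. Positions/velocities evolve in place from
// (z_in, v_in); snapshots are stored every `save_stride` steps (the initial
// state is NOT stored -- the R wrapper prepends it for fresh runs).
// Reflecting walls at +/- box_half.
// [[Rcpp::export]]
List cpp_langevin_chunk(NumericVector z_in, NumericVector v_in, int n_steps,
                        int save_stride, double dt, double friction,
                        double temperature, double mass, NumericVector acc_table,
                        double grid_z0, double grid_h, double box_half,
                        bool save_velocities) {
  const int np = z_in.size();
  if (v_in.size() != np) stop("position/velocity length mismatch");
  if (save_stride < 1) stop("save_stride must be >= 1");
  const int n_save = n_steps / save_stride;
  const double half_dt = 0.5 * dt;
  const double c1 = std::exp(-friction * dt);
  const double kT_m = R_INTERNAL * temperature / mass;
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT_m);
  const double *acc = acc_table.begin();
  const double inv_h = 1.0 / grid_h;
  const int ntab = acc_table.size();

  std::vector<double> Z(z_in.begin(), z_in.end());
  std::vector<double> V(v_in.begin(), v_in.end());
  NumericMatrix z_out(n_save, np);
  NumericMatrix v_out(save_velocities ? n_save : 0, save_velocities ? np : 0);
  NormGen ng;

  // Saved frames are staged in a small cache-resident buffer (per-particle
  // columns of length BUF) and flushed by contiguous column copies; writing
  // frames straight into the big output matrix would scatter every frame
  // across columns megabytes apart.
  const int BUF = 1024;
  std::vector<double> zbuf((size_t)BUF * np), vbuf;
  if (save_velocities) vbuf.resize((size_t)BUF * np);
  double *zo = z_out.begin();
  double *vo = save_velocities ? v_out.begin() : (double *)0;
  int row = 0, nbuf = 0;

  for (int s = 1; s <= n_steps; ++s) {
    for (int p = 0; p < np; ++p) {
      double z = Z[p], v = V[p];
      v += half_dt * accel_interp(z, acc, grid_z0, inv_h, ntab);
      z += half_dt * v;
      v = c1 * v + c2 * ng.next();
      z += half_dt * v;
      v += half_dt * accel_interp(z, acc, grid_z0, inv_h, ntab);
      if (z > box_half) {
        z = 2.0 * box_half - z;
        v = -v;
      } else if (z < -box_half) {
        z = -2.0 * box_half - z;
        v = -v;
      }
      Z[p] = z;
      V[p] = v;
    }
    if (s % save_stride == 0) {
      for (int p = 0; p < np; ++p) zbuf[(size_t)p * BUF + nbuf] = Z[p];
      if (save_velocities)
        for (int p = 0; p < np; ++p) vbuf[(size_t)p * BUF + nbuf] = V[p];
      ++nbuf;
      if (nbuf == BUF) {
        for (int p = 0; p < np; ++p)
          std::copy(&zbuf[(size_t)p * BUF], &zbuf[(size_t)p * BUF] + nbuf,
                    zo + (size_t)p * n_save + row);
        if (save_velocities)
          for (int p = 0; p < np; ++p)
            std::copy(&vbuf[(size_t)p * BUF], &vbuf[(size_t)p * BUF] + nbuf,
                      vo + (size_t)p * n_save + row);
        row += nbuf;
        nbuf = 0;
      }
    }
  }
  if (nbuf > 0) {
    for (int p = 0; p < np; ++p)
      std::copy(&zbuf[(size_t)p * BUF], &zbuf[(size_t)p * BUF] + nbuf,
                zo + (size_t)p * n_save + row);
    if (save_velocities)
      for (int p = 0; p < np; ++p)
        std::copy(&vbuf[(size_t)p * BUF], &vbuf[(size_t)p * BUF] + nbuf,
                  vo + (size_t)p * n_save + row);
  }

  return List::create(_["z"] = z_out, _["vz"] = v_out,
                      _["z_final"] = NumericVector(Z.begin(), Z.end()),
                      _["v_final"] = NumericVector(V.begin(), V.end()));
}

// Lateral (x, y) Langevin walk confined to a reflecting cylinder of radius R,
// flat potential. Companion to cpp_langevin_chunk for 3-D runs.
// [[Rcpp::export]]
List cpp_langevin_lateral(NumericVector x_in, NumericVector y_in,
                          NumericVector vx_in, NumericVector vy_in,
                          int n_steps, int save_stride, double dt,
                          double friction, double temperature, double mass,
                          double radius) {
  const int np = x_in.size();
  const int n_save = n_steps / save_stride;
  const double half_dt = 0.5 * dt;
  const double c1 = std::exp(-friction * dt);
  const double kT_m = R_INTERNAL * temperature / mass;
  const double c2 = std::sqrt((1.0 - c1 * c1) * kT_m);
  std::vector<double> X(x_in.begin(), x_in.end());
  std::vector<double> Y(y_in.begin(), y_in.end());
  std::vector<double> VX(vx_in.begin(), vx_in.end());
  std::vector<double> VY(vy_in.begin(), vy_in.end());
  NumericMatrix x_out(n_save, np), y_out(n_save, np);
  NormGen ng;
  int row = 0;
  for (int s = 1; s <= n_steps; ++s) {
    for (int p = 0; p < np; ++p) {
      double x = X[p], y = Y[p], vx = VX[p], vy = VY[p];
      x += half_dt * vx;
      y += half_dt * vy;
      vx = c1 * vx + c2 * ng.next();
      vy = c1 * vy + c2 * ng.next();
      x += half_dt * vx;
      y += half_dt * vy;
      double r = std::sqrt(x * x + y * y);
      if (r > radius && r > 0.0) {
        // specular reflection at the cylinder wall
        const double nx = x / r, ny = y / r;
        const double rr = 2.0 * radius - r;
        x = rr * nx;
        y = rr * ny;
        const double vn = vx * nx + vy * ny;
        vx -= 2.0 * vn * nx;
        vy -= 2.0 * vn * ny;
      }
      X[p] = x; Y[p] = y; VX[p] = vx; VY[p] = vy;
    }
    if (s % save_stride == 0) {
      for (int p = 0; p < np; ++p) { x_out(row, p) = X[p]; y_out(row, p) = Y[p]; }
      ++row;
    }
  }
  return List::create(_["x"] = x_out, _["y"] = y_out,
                      _["x_final"] = NumericVector(X.begin(), X.end()),
                      _["y_final"] = NumericVector(Y.begin(), Y.end()),
                      _["vx_final"] = NumericVector(VX.begin(), VX.end()),
                      _["vy_final"] = NumericVector(VY.begin(), VY.end()));
}

// Dividing-plane crossing-event state machine.
//
// An event opens at a sign change of (z - z_divide) between consecutive frames
// while the particle is laterally eligible on both frames. An open IC->EC
// event resolves as success when z >= z_bulk_ec, as recross when z drops back
// below z_divide, or as recross-equivalent failure when the particle leaves
// the lateral gate inside the slab; mirrored for EC->IC. The transition that
// resolves an event never opens a new one. Events still open when `finalize`
// is TRUE are emitted as unresolved.
//
// State vectors (one entry per particle) allow chunked scans:
//   open_dir: 0 none, +1 IC->EC, -1 EC->IC
//   open_t:   opening time of the open event
//   z_prev:   last z of the previous chunk (NaN for a fresh scan)
//   lat_prev: lateral eligibility at the last frame of the previous chunk
// Outcome codes: 1 success, 2 recross, 3 unresolved.
// [[Rcpp::export]]
List cpp_event_machine(NumericMatrix z, Nullable<LogicalMatrix> lateral,
                       NumericVector times, double z_divide, double z_bulk_ic,
                       double z_bulk_ec, IntegerVector open_dir,
                       NumericVector open_t, NumericVector z_prev,
                       LogicalVector lat_prev, bool finalize) {
  const int nf = z.nrow(), np = z.ncol();
  if (times.size() != nf) stop("times/frames length mismatch");
  const bool has_lat = lateral.isNotNull();
  LogicalMatrix lat;
  if (has_lat) lat = LogicalMatrix(lateral);

  std::vector<int> ev_particle, ev_dir, ev_outcome;
  std::vector<double> ev_tcross, ev_tresolve;

  for (int p = 0; p < np; ++p) {
    int open = open_dir[p];
    double topen = open_t[p];
    double zp = z_prev[p];
    bool lp = lat_prev[p];
    int i0 = 0;
    if (ISNAN(zp)) {  // fresh track: first frame is the initial previous state
      if (nf == 0) continue;
      zp = z(0, p);
      lp = has_lat ? (bool)lat(0, p) : true;
      i0 = 1;
    }
    for (int i = i0; i < nf; ++i) {
      const double zc = z(i, p);
      const bool lc = has_lat ? (bool)lat(i, p) : true;
      const double t = times[i];
      if (open != 0) {
        int outcome = 0;
        if (open > 0) {
          if (zc >= z_bulk_ec) outcome = 1;
          else if (zc < z_divide) outcome = 2;
          else if (!lc) outcome = 2;  // sideways exit inside the slab
        } else {
          if (zc <= z_bulk_ic) outcome = 1;
          else if (zc >= z_divide) outcome = 2;
          else if (!lc) outcome = 2;
        }
        if (outcome != 0) {
          ev_particle.push_back(p + 1);
          ev_dir.push_back(open);
          ev_tcross.push_back(topen);
          ev_tresolve.push_back(t);
          ev_outcome.push_back(outcome);
          open = 0;  // resolving transition cannot open a new event
        }
      } else {
        const bool side_p = zp >= z_divide, side_c = zc >= z_divide;
        if (side_p != side_c && lp && lc) {
          open = side_c ? 1 : -1;
          topen = t;
          // a single transition may carry straight into the bulk
          if ((open > 0 && zc >= z_bulk_ec) || (open < 0 && zc <= z_bulk_ic)) {
            ev_particle.push_back(p + 1);
            ev_dir.push_back(open);
            ev_tcross.push_back(topen);
            ev_tresolve.push_back(t);
            ev_outcome.push_back(1);
            open = 0;
          }
        }
      }
      zp = zc;
      lp = lc;
    }
    if (finalize && open != 0) {
      ev_particle.push_back(p + 1);
      ev_dir.push_back(open);
      ev_tcross.push_back(topen);
      ev_tresolve.push_back(NA_REAL);
      ev_outcome.push_back(3);
      open = 0;
    }
    open_dir[p] = open;
    open_t[p] = topen;
    z_prev[p] = zp;
    lat_prev[p] = lp;
  }

  return List::create(
      _["particle"] = IntegerVector(ev_particle.begin(), ev_particle.end()),
      _["direction"] = IntegerVector(ev_dir.begin(), ev_dir.end()),
      _["t_cross"] = NumericVector(ev_tcross.begin(), ev_tcross.end()),
      _["t_resolve"] = NumericVector(ev_tresolve.begin(), ev_tresolve.end()),
      _["outcome"] = IntegerVector(ev_outcome.begin(), ev_outcome.end()),
      _["open_dir"] = open_dir, _["open_t"] = open_t, _["z_prev"] = z_prev,
      _["lat_prev"] = lat_prev);
}

// Total occupancy counts per bin over all frames; bin i is the half-open
// interval [z_lo + i*h, z_lo + (i+1)*h). Entries with lateral == FALSE or
// falling outside the grid are skipped.
// [[Rcpp::export]]
NumericVector cpp_bin_counts(NumericMatrix z, Nullable<LogicalMatrix> lateral,
                             double z_lo, double h, int n_bins) {
  const int nf = z.nrow(), np = z.ncol();
  const bool has_lat = lateral.isNotNull();
  LogicalMatrix lat;
  if (has_lat) lat = LogicalMatrix(lateral);
  std::vector<double> counts(n_bins, 0.0);
  const double inv_h = 1.0 / h;
  for (int p = 0; p < np; ++p) {
    for (int i = 0; i < nf; ++i) {
      if (has_lat && !lat(i, p)) continue;
      const double x = (z(i, p) - z_lo) * inv_h;
      if (x < 0.0 || x >= n_bins) continue;
      counts[(int)x] += 1.0;
    }
  }
  return NumericVector(counts.begin(), counts.end());
}

// One-way dividing-plane sign-change counts between consecutive frames,
// with optional carried previous-frame state for chunked scans.
// Returns c(up = IC->EC crossings, down = EC->IC crossings).
// [[Rcpp::export]]
NumericVector cpp_crossing_counts(NumericMatrix z, double z_divide,
                                  NumericVector z_prev) {
  const int nf = z.nrow(), np = z.ncol();
  double up = 0.0, down = 0.0;
  for (int p = 0; p < np; ++p) {
    double zp = z_prev[p];
    int i0 = 0;
    if (ISNAN(zp)) {
      if (nf == 0) continue;
      zp = z(0, p);
      i0 = 1;
    }
    bool sp = zp >= z_divide;
    for (int i = i0; i < nf; ++i) {
      const bool sc = z(i, p) >= z_divide;
      if (sc != sp) {
        if (sc) up += 1.0; else down += 1.0;
        sp = sc;
      }
    }
    z_prev[p] = z(nf - 1, p);
  }
  return NumericVector::create(_["up"] = up, _["down"] = down);
}
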