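// Bead-spring polymer kernels: self-avoiding-walk initialization,
// Polak-Ribiere conjugate-gradient relaxation, steered overdamped-free
// Langevin dynamics (GJF velocity Verlet) with time-ramped restraint
// springs, and ensemble distance/contact kernels.
//
// All lengths here are in reduced units (bead diameter sigma = 1, kT = 1);
// conversion to nm happens at the R interface.

#include <RcppArmadillo.h>
#include <random>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Self-contained deterministic RNG: raw mt19937_64 bits -> doubles, so the
// stream does not depend on the standard library's distribution internals.
struct Rng {
  std::mt19937_64 eng;
  bool has_spare = false;
  double spare = 0.0;
  explicit Rng(uint64_t seed) : eng(seed ^ 0x9e3779b97f4a7c15ULL) {}
  double unif() {  // (0, 1)
    return ((eng() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double gauss() {  // Box-Muller
    if (has_spare) { has_spare = false; return spare; }
    double u1 = unif(), u2 = unif();
    double r = std::sqrt(-2.0 * std::log(u1));
    spare = r * std::sin(2.0 * M_PI * u2);
    has_spare = true;
    return r * std::cos(2.0 * M_PI * u2);
  }
};

// Kremer-Grest force-field constants (reduced units)
static const double K_FENE = 30.0;
static const double R0_FENE = 1.5;
static const double WCA_CUT2 = std::pow(2.0, 1.0 / 3.0);  // (2^{1/6})^2
static const double NL_SKIN = 0.35;

struct Restraints {
  std::vector<int> i, j, kind;        // kind: 0 harmonic, 1 lower bound
  std::vector<double> deq, kmax;
};

// Verlet neighbour list built through a uniform cell grid.
struct NeighborList {
  std::vector<std::pair<int, int> > pairs;
  arma::mat ref;  // coordinates at build time
  double rlist = 0.0;

  void build(const arma::mat& x, double rcut) {
    rlist = rcut + NL_SKIN;
    const int n = x.n_rows;
    pairs.clear();
    ref = x;
    arma::rowvec lo = arma::min(x, 0), hi = arma::max(x, 0);
    double cell = rlist;
    int nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / cell) + 1);
    int ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / cell) + 1);
    int nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / cell) + 1);
    std::vector<std::vector<int> > bins((size_t)nx * ny * nz);
    std::vector<int> cx(n), cy(n), cz(n);
    for (int a = 0; a < n; ++a) {
      cx[a] = std::min(nx - 1, (int)((x(a, 0) - lo[0]) / cell));
      cy[a] = std::min(ny - 1, (int)((x(a, 1) - lo[1]) / cell));
      cz[a] = std::min(nz - 1, (int)((x(a, 2) - lo[2]) / cell));
      bins[cx[a] + (size_t)nx * (cy[a] + (size_t)ny * cz[a])].push_back(a);
    }
    const double r2 = rlist * rlist;
    for (int a = 0; a < n; ++a) {
      for (int dx = -1; dx <= 1; ++dx) {
        int ix = cx[a] + dx; if (ix < 0 || ix >= nx) continue;
        for (int dy = -1; dy <= 1; ++dy) {
          int iy = cy[a] + dy; if (iy < 0 || iy >= ny) continue;
          for (int dz = -1; dz <= 1; ++dz) {
            int iz = cz[a] + dz; if (iz < 0 || iz >= nz) continue;
            const std::vector<int>& b = bins[ix + (size_t)nx * (iy + (size_t)ny * iz)];
            for (size_t q = 0; q < b.size(); ++q) {
              int c = b[q];
              if (c <= a) continue;
              double d2 = 0.0;
              for (int k = 0; k < 3; ++k) {
                double d = x(a, k) - x(c, k); d2 += d * d;
              }
              if (d2 < r2) pairs.push_back(std::make_pair(a, c));
            }
          }
        }
      }
    }
  }

  bool stale(const arma::mat& x) const {
    double lim = 0.25 * NL_SKIN * NL_SKIN;  // (skin/2)^2
    for (arma::uword a = 0; a < x.n_rows; ++a) {
      double d2 = 0.0;
      for (int k = 0; k < 3; ++k) {
        double d = x(a, k) - ref(a, k); d2 += d * d;
      }
      if (d2 > lim) return true;
    }
    return false;
  }
};

// Full potential energy and forces. Returns energy; sets `overstretch` if a
// FENE bond reached its extension limit (forces there are undefined).
static double forces(const arma::mat& x, arma::mat& f, const NeighborList& nl,
                     const Restraints& rs, double ramp, double k_tether,
                     bool& overstretch) {
  const int n = x.n_rows;
  f.zeros(n, 3);
  double u = 0.0;
  overstretch = false;
  // FENE bonds between consecutive beads
  const double r02 = R0_FENE * R0_FENE;
  for (int a = 0; a + 1 < n; ++a) {
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x(a + 1, k) - x(a, k); r2 += d[k] * d[k]; }
    if (r2 >= 0.998 * r02) { overstretch = true; return INFINITY; }
    double fac = -K_FENE / (1.0 - r2 / r02);  // dU/dr / r
    u += -0.5 * K_FENE * r02 * std::log(1.0 - r2 / r02);
    for (int k = 0; k < 3; ++k) {
      double fk = fac * d[k];
      f(a, k) -= fk;  // force on a along -d is attractive toward a+1
      f(a + 1, k) += fk;
    }
  }
  // WCA excluded volume over the neighbour list
  for (size_t q = 0; q < nl.pairs.size(); ++q) {
    int a = nl.pairs[q].first, c = nl.pairs[q].second;
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x(c, k) - x(a, k); r2 += d[k] * d[k]; }
    if (r2 >= WCA_CUT2) continue;
    double inv2 = 1.0 / r2;
    double inv6 = inv2 * inv2 * inv2;
    double inv12 = inv6 * inv6;
    u += 4.0 * (inv12 - inv6) + 1.0;
    double fac = (48.0 * inv12 - 24.0 * inv6) * inv2;  // |F|/r, repulsive
    for (int k = 0; k < 3; ++k) {
      double fk = fac * d[k];
      f(a, k) -= fk;
      f(c, k) += fk;
    }
  }
  // centre-of-mass tether: U = k_t * |Rcom|^2
  arma::rowvec com = arma::mean(x, 0);
  u += k_tether * arma::dot(com, com);
  arma::rowvec ft = (-2.0 * k_tether / n) * com;
  f.each_row() += ft;
  // data restraints, spring constants ramped by `ramp`
  for (size_t q = 0; q < rs.i.size(); ++q) {
    int a = rs.i[q], c = rs.j[q];
    double d[3], r2 = 0.0;
    for (int k = 0; k < 3; ++k) { d[k] = x(c, k) - x(a, k); r2 += d[k] * d[k]; }
    double r = std::sqrt(r2);
    double dev = r - rs.deq[q];
    if (rs.kind[q] == 1 && dev >= 0.0) continue;  // lower bound inactive
    double kk = ramp * rs.kmax[q];
    u += kk * dev * dev;
    if (r < 1e-12) continue;
    double fac = 2.0 * kk * dev / r;  // dU/dr / r
    for (int k = 0; k < 3; ++k) {
      double fk = fac * d[k];
      f(a, k) += fk;
      f(c, k) -= fk;
    }
  }
  return u;
}

// [[Rcpp::export]]
arma::mat cpp_saw_init(int n, double placement_half, int seed) {
  Rng rng((uint64_t)seed);
  const int max_restarts = 200, max_tries = 400;
  for (int attempt = 0; attempt < max_restarts; ++attempt) {
    arma::mat x(n, 3);
    for (int k = 0; k < 3; ++k) {
      x(0, k) = (2.0 * rng.unif() - 1.0) * placement_half;
    }
    bool failed = false;
    for (int a = 1; a < n && !failed; ++a) {
      int t = 0;
      for (; t < max_tries; ++t) {
        // uniform direction on the sphere, step length 1 sigma
        double z = 2.0 * rng.unif() - 1.0;
        double phi = 2.0 * M_PI * rng.unif();
        double s = std::sqrt(1.0 - z * z);
        double cand[3] = {x(a - 1, 0) + s * std::cos(phi),
                          x(a - 1, 1) + s * std::sin(phi),
                          x(a - 1, 2) + z};
        bool clash = false;
        for (int b = 0; b < a - 1; ++b) {
          double d2 = 0.0;
          for (int k = 0; k < 3; ++k) {
            double d = cand[k] - x(b, k); d2 += d * d;
          }
          if (d2 < 0.999 * 0.999) { clash = true; break; }
        }
        if (!clash) {
          for (int k = 0; k < 3; ++k) x(a, k) = cand[k];
          break;
        }
      }
      if (t == max_tries) failed = true;
    }
    if (!failed) return x;
  }
  stop("self-avoiding-walk initialization failed for seed %d", seed);
  return arma::mat();  // unreached
}

// Polak-Ribiere conjugate-gradient relaxation of the bare polymer energy
// (no data restraints), with a backtracking line search.
// [[Rcpp::export]]
arma::mat cpp_minimize(arma::mat x, int max_iter, double k_tether) {
  NeighborList nl;
  nl.build(x, std::sqrt(WCA_CUT2));
  Restraints none;
  arma::mat f, f_new, dir;
  bool ovs = false;
  double u = forces(x, f, nl, none, 0.0, k_tether, ovs);
  dir = f;
  for (int it = 0; it < max_iter; ++it) {
    double fnorm = arma::norm(f, "fro");
    if (fnorm < 1e-4 * std::sqrt((double)x.n_rows)) break;
    // cap the initial trial step so no bead moves more than 0.02 sigma:
    // large collective steps can bury a bead overlap inside a net energy
    // decrease from bond relaxation
    double dmax = arma::abs(dir).max();
    double alpha = (dmax > 0) ? 0.02 / dmax : 0.0;
    if (alpha == 0.0) break;
    double u_new = INFINITY;
    arma::mat x_new;
    int ls = 0;
    for (; ls < 30; ++ls) {
      x_new = x + alpha * dir;
      if (nl.stale(x_new)) nl.build(x_new, std::sqrt(WCA_CUT2));
      u_new = forces(x_new, f_new, nl, none, 0.0, k_tether, ovs);
      if (!ovs && u_new <= u) break;
      alpha *= 0.5;
    }
    if (ls == 30) break;  // no descent possible: converged enough
    double beta = 0.0;
    double denom = arma::dot(f, f);
    if (denom > 0) beta = std::max(0.0, arma::dot(f_new, f_new - f) / denom);
    dir = f_new + beta * dir;
    x = x_new;
    u = u_new;
    f = f_new;
  }
  return x;
}

// Steered Langevin dynamics (Gronbech-Jensen/Farago velocity Verlet).
// Restraint spring constants ramp linearly from 0 to kmax over the run.
// A step that overstretches a FENE bond is rejected and retried with a
// halved timestep (fresh noise); the timestep resets afterwards.
// [[Rcpp::export]]
List cpp_steer(arma::mat x, IntegerVector r_i, IntegerVector r_j,
               IntegerVector r_kind, NumericVector r_deq, NumericVector r_kmax,
               int n_steps, double dt, double gamma, double k_tether,
               int seed, double sat_tol) {
  Rng rng((uint64_t)seed * 2654435761ULL + 17ULL);
  const int n = x.n_rows;
  Restraints rs;
  rs.i.assign(r_i.begin(), r_i.end());
  rs.j.assign(r_j.begin(), r_j.end());
  rs.kind.assign(r_kind.begin(), r_kind.end());
  rs.deq.assign(r_deq.begin(), r_deq.end());
  rs.kmax.assign(r_kmax.begin(), r_kmax.end());

  double rcut_nl = std::sqrt(WCA_CUT2);
  NeighborList nl;
  nl.build(x, rcut_nl);
  arma::mat v(n, 3, arma::fill::zeros);
  arma::mat f(n, 3), f_new(n, 3), noise(n, 3), x_new(n, 3), v_new(n, 3);
  bool ovs = false;
  forces(x, f, nl, rs, 0.0, k_tether, ovs);
  if (ovs) stop("initial conformation overstretches a FENE bond");

  for (int step = 0; step < n_steps; ++step) {
    double ramp_next = (double)(step + 1) / n_steps;
    double dtl = dt;
    int halvings = 0;
    for (;;) {
      double a = (1.0 - gamma * dtl / 2.0) / (1.0 + gamma * dtl / 2.0);
      double b = 1.0 / (1.0 + gamma * dtl / 2.0);
      double bsd = std::sqrt(2.0 * gamma * dtl);  // kT = 1
      for (int p = 0; p < n; ++p) {
        for (int k = 0; k < 3; ++k) noise(p, k) = bsd * rng.gauss();
      }
      x_new = x + b * dtl * v + 0.5 * b * dtl * dtl * f +
              0.5 * b * dtl * noise;
      if (nl.stale(x_new)) nl.build(x_new, rcut_nl);
      forces(x_new, f_new, nl, rs, ramp_next, k_tether, ovs);
      if (!ovs) {
        v_new = a * v + 0.5 * dtl * (a * f + f_new) + b * noise;
        break;
      }
      if (++halvings > 40) {
        stop("FENE bond repeatedly overstretched at step %d (seed %d)",
             step, seed);
      }
      dtl *= 0.5;
    }
    x = x_new;
    v = v_new;
    f = f_new;
  }

  // fraction of restraints satisfied at the end of steering
  int sat = 0;
  const int nr = rs.i.size();
  for (int q = 0; q < nr; ++q) {
    double d2 = 0.0;
    for (int k = 0; k < 3; ++k) {
      double d = x(rs.j[q], k) - x(rs.i[q], k); d2 += d * d;
    }
    double r = std::sqrt(d2);
    bool ok = (rs.kind[q] == 0) ? (r <= rs.deq[q] + sat_tol)
                                : (r >= rs.deq[q] - sat_tol);
    if (ok) ++sat;
  }
  double satisfaction = nr > 0 ? (double)sat / nr : 1.0;
  return List::create(Named("coords") = x,
                      Named("satisfaction") = satisfaction);
}

// Per-pair fraction of models with distance strictly below `cutoff`.
// coords: M x N x 3 array (column-major R array).
// [[Rcpp::export]]
NumericMatrix cpp_contact_fractions(NumericVector coords, double cutoff) {
  IntegerVector dm = coords.attr("dim");
  const int M = dm[0], N = dm[1];
  NumericMatrix out(N, N);
  const double c2 = cutoff * cutoff;
  const double* p = coords.begin();
  for (int i = 0; i < N; ++i) {
    out(i, i) = 1.0;
    for (int j = i + 1; j < N; ++j) {
      int cnt = 0;
      for (int m = 0; m < M; ++m) {
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double d = p[m + (size_t)M * (i + (size_t)N * k)] -
                     p[m + (size_t)M * (j + (size_t)N * k)];
          d2 += d * d;
        }
        if (d2 < c2) ++cnt;
      }
      out(i, j) = out(j, i) = (double)cnt / M;
    }
  }
  return out;
}

// Per-pair median inter-particle distance over the ensemble.
// [[Rcpp::export]]
NumericMatrix cpp_median_distances(NumericVector coords) {
  IntegerVector dm = coords.attr("dim");
  const int M = dm[0], N = dm[1];
  NumericMatrix out(N, N);
  const double* p = coords.begin();
  std::vector<double> buf(M);
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      for (int m = 0; m < M; ++m) {
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double d = p[m + (size_t)M * (i + (size_t)N * k)] -
                     p[m + (size_t)M * (j + (size_t)N * k)];
          d2 += d * d;
        }
        buf[m] = std::sqrt(d2);
      }
      std::sort(buf.begin(), buf.end());
      double med = (M % 2 == 1) ? buf[M / 2]
                                : 0.5 * (buf[M / 2 - 1] + buf[M / 2]);
      out(i, j) = out(j, i) = med;
    }
  }
  return out;
}

// All-vs-all distance RMSD between models (superposition-free).
// [[Rcpp::export]]
NumericMatrix cpp_drmsd_matrix(NumericVector coords) {
  IntegerVector dm = coords.attr("dim");
  const int M = dm[0], N = dm[1];
  const double* p = coords.begin();
  const size_t np = (size_t)N * (N - 1) / 2;
  // precompute per-model condensed distance vectors
  std::vector<std::vector<double> > dv(M, std::vector<double>(np));
  for (int m = 0; m < M; ++m) {
    size_t q = 0;
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j, ++q) {
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double d = p[m + (size_t)M * (i + (size_t)N * k)] -
                     p[m + (size_t)M * (j + (size_t)N * k)];
          d2 += d * d;
        }
        dv[m][q] = std::sqrt(d2);
      }
    }
  }
  NumericMatrix out(M, M);
  for (int a = 0; a < M; ++a) {
    for (int b = a + 1; b < M; ++b) {
      double s = 0.0;
      for (size_t q = 0; q < np; ++q) {
        double d = dv[a][q] - dv[b][q];
        s += d * d;
      }
      out(a, b) = out(b, a) = std::sqrt(s / np);
    }
  }
  return out;
}

// Coordinate RMSD after optimal proper rotation (Kabsch, no reflection)
// and translation. A and B are N x 3.
// [[Rcpp::export]]
double cpp_kabsch_rmsd(arma::mat A, arma::mat B) {
  A.each_row() -= arma::mean(A, 0);
  B.each_row() -= arma::mean(B, 0);
  arma::mat H = A.t() * B;
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(U * V.t()) < 0 ? -1.0 : 1.0;
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = d;
  arma::mat R = U * D * V.t();  // proper rotation maximizing tr(R' A' B)
  arma::mat diff = A * R - B;
  return std::sqrt(arma::accu(arma::square(diff)) / A.n_rows);
}

// Pairwise Kabsch RMSD matrix over an ensemble (proper rotations only).
// [[Rcpp::export]]
NumericMatrix cpp_rmsd_matrix(NumericVector coords) {
  IntegerVector dm = coords.attr("dim");
  const int M = dm[0], N = dm[1];
  const double* p = coords.begin();
  std::vector<arma::mat> xs(M, arma::mat(N, 3));
  for (int m = 0; m < M; ++m) {
    for (int i = 0; i < N; ++i) {
      for (int k = 0; k < 3; ++k) {
        xs[m](i, k) = p[m + (size_t)M * (i + (size_t)N * k)];
      }
    }
  }
  NumericMatrix out(M, M);
  for (int a = 0; a < M; ++a) {
    for (int b = a + 1; b < M; ++b) {
      double r = cpp_kabsch_rmsd(xs[a], xs[b]);
      out(a, b) = out(b, a) = r;
    }
  }
  return out;
}
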