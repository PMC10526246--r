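// Core DPD kernels: pair forces with cell-list search, harmonic bond and
// angle-bending forces, the Groot-Warren modified velocity-Verlet loop,
// Muller-Plathe slab momentum swaps, and periodic-aware clustering.
//
// Conventions: cubic box [0,L)^3, minimum-image distances, all masses 1,
// species passed as 0-based integers indexing the repulsion matrix.
// Pair noise is a counter-based hash of (seed, step, i, j) so the value is
// shared by the (i,j) pair and independent of enumeration order.
#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline uint64_t sm64(uint64_t z) {
  z += 0x9e3779b97f4a7c15ULL;
  z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
  z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
  return z ^ (z >> 31);
}
static inline double u01(uint64_t h) {
  return ((h >> 11) + 0.5) * (1.0 / 9007199254740992.0);
}

struct NoiseGen {
  uint64_t key;
  bool gaussian;
  NoiseGen(uint64_t seed, uint64_t step, bool gauss) : gaussian(gauss) {
    key = sm64(seed ^ sm64(step + 0x51ed270b7f7fcb11ULL));
  }
  // symmetric in (i,j); mean 0, variance 1
  double zeta(uint32_t i, uint32_t j) const {
    uint64_t a = i < j ? i : j, b = i < j ? j : i;
    uint64_t h = sm64(key ^ sm64(((uint64_t)a << 32) | (uint64_t)b));
    if (!gaussian) return 1.7320508075688772 * (2.0 * u01(h) - 1.0);
    double u1 = u01(h), u2 = u01(sm64(h ^ 0x9e3779b97f4a7c15ULL));
    return std::sqrt(-2.0 * std::log(u1)) * std::cos(6.283185307179586 * u2);
  }
};

static inline double min_image(double d, double L) {
  if (d > 0.5 * L) d -= L;
  else if (d < -0.5 * L) d += L;
  return d;
}

struct FFParams {
  const double* a;   // 5x5 column-major (symmetric, so order irrelevant)
  int nspec;
  double gamma, sigma, rc, ks, rs, ktheta, theta0, dt, L;
  bool gaussian;
  bool with_cons, with_diss, with_rand;
};

struct Workspace {
  std::vector<int> head, nxt, cellof;
  std::vector<double> fx, fy, fz;
};

// Accumulate all forces into ws.fx/fy/fz; returns pair/bond/angle potential energies.
static void compute_forces(int N,
                           const double* px, const double* py, const double* pz,
                           const double* vx, const double* vy, const double* vz,
                           const int* sp,
                           const int* bonds, int nb,
                           const int* angles, int na,
                           const FFParams& P,
                           uint64_t seed, uint64_t step,
                           bool brute,
                           Workspace& ws,
                           double& pe_pair, double& pe_bond, double& pe_angle) {
  const double L = P.L, rc = P.rc, rc2 = rc * rc;
  const double inv_sqrt_dt = 1.0 / std::sqrt(P.dt);
  pe_pair = pe_bond = pe_angle = 0.0;
  ws.fx.assign(N, 0.0); ws.fy.assign(N, 0.0); ws.fz.assign(N, 0.0);
  double* fx = ws.fx.data(); double* fy = ws.fy.data(); double* fz = ws.fz.data();
  NoiseGen ng(seed, step, P.gaussian);

  auto pair_kernel = [&](int i, int j) {
    double dx = px[i] - px[j], dy = py[i] - py[j], dz = pz[i] - pz[j];
    dx = min_image(dx, L); dy = min_image(dy, L); dz = min_image(dz, L);
    double r2 = dx * dx + dy * dy + dz * dz;
    if (r2 >= rc2) return;
    double r = std::sqrt(r2);
    double aij = P.a[sp[i] * P.nspec + sp[j]];
    double w = 1.0 - r / rc;
    pe_pair += 0.5 * aij * rc * w * w;
    if (r < 1e-12) return;  // coincident beads: direction undefined, soft core
    double ex = dx / r, ey = dy / r, ez = dz / r;
    double f = 0.0;
    if (P.with_cons) f += aij * w;
    if (P.with_diss) {
      double vdotr = (vx[i] - vx[j]) * ex + (vy[i] - vy[j]) * ey + (vz[i] - vz[j]) * ez;
      f += -P.gamma * w * w * vdotr;
    }
    if (P.with_rand) f += P.sigma * w * ng.zeta((uint32_t)i, (uint32_t)j) * inv_sqrt_dt;
    fx[i] += f * ex; fy[i] += f * ey; fz[i] += f * ez;
    fx[j] -= f * ex; fy[j] -= f * ey; fz[j] -= f * ez;
  };

  int nc = (int)std::floor(L / rc);
  if (brute || nc < 3) {
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) pair_kernel(i, j);
  } else {
    double cw = L / nc;
    int ncells = nc * nc * nc;
    ws.head.assign(ncells, -1);
    ws.nxt.assign(N, -1);
    ws.cellof.assign(N, 0);
    for (int i = 0; i < N; ++i) {
      int cx = (int)(px[i] / cw); if (cx >= nc) cx = nc - 1; if (cx < 0) cx = 0;
      int cy = (int)(py[i] / cw); if (cy >= nc) cy = nc - 1; if (cy < 0) cy = 0;
      int cz = (int)(pz[i] / cw); if (cz >= nc) cz = nc - 1; if (cz < 0) cz = 0;
      int c = cx + nc * (cy + nc * cz);
      ws.cellof[i] = c;
      ws.nxt[i] = ws.head[c];
      ws.head[c] = i;
    }
    // 13 half-shell neighbour offsets + self cell
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int cz = 0; cz < nc; ++cz)
      for (int cy = 0; cy < nc; ++cy)
        for (int cx = 0; cx < nc; ++cx) {
          int c = cx + nc * (cy + nc * cz);
          for (int i = ws.head[c]; i >= 0; i = ws.nxt[i])
            for (int j = ws.nxt[i]; j >= 0; j = ws.nxt[j]) pair_kernel(i, j);
          for (int k = 0; k < 13; ++k) {
            int ox = (cx + off[k][0] + nc) % nc;
            int oy = (cy + off[k][1] + nc) % nc;
            int oz = (cz + off[k][2] + nc) % nc;
            int c2 = ox + nc * (oy + nc * oz);
            for (int i = ws.head[c]; i >= 0; i = ws.nxt[i])
              for (int j = ws.head[c2]; j >= 0; j = ws.nxt[j]) pair_kernel(i, j);
          }
        }
  }

  // harmonic bonds: F = ks (1 - r/rs) rhat, U = ks/(2 rs) (r - rs)^2
  for (int b = 0; b < nb; ++b) {
    int i = bonds[b], j = bonds[nb + b];
    double dx = min_image(px[i] - px[j], L);
    double dy = min_image(py[i] - py[j], L);
    double dz = min_image(pz[i] - pz[j], L);
    double r = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (r < 1e-12) stop("bond between beads %d and %d has zero length", i + 1, j + 1);
    double f = P.ks * (1.0 - r / P.rs) / r;  // includes 1/r for direction
    fx[i] += f * dx; fy[i] += f * dy; fz[i] += f * dz;
    fx[j] -= f * dx; fy[j] -= f * dy; fz[j] -= f * dz;
    double dr = r - P.rs;
    pe_bond += 0.5 * P.ks / P.rs * dr * dr;
  }

  // angle bending: U = ktheta (theta - theta0)^2 on triples (i, j, k), j central
  for (int t = 0; t < na; ++t) {
    int i = angles[t], j = angles[na + t], k = angles[2 * na + t];
    double ax = min_image(px[i] - px[j], L);
    double ay = min_image(py[i] - py[j], L);
    double az = min_image(pz[i] - pz[j], L);
    double bx = min_image(px[k] - px[j], L);
    double by = min_image(py[k] - py[j], L);
    double bz = min_image(pz[k] - pz[j], L);
    double la = std::sqrt(ax * ax + ay * ay + az * az);
    double lb = std::sqrt(bx * bx + by * by + bz * bz);
    if (la < 1e-12 || lb < 1e-12)
      stop("degenerate angle (zero-length arm) at triple %d-%d-%d", i + 1, j + 1, k + 1);
    double c = (ax * bx + ay * by + az * bz) / (la * lb);
    if (c > 1.0) c = 1.0; else if (c < -1.0) c = -1.0;
    double th = std::acos(c);
    double s = std::sqrt(1.0 - c * c);
    if (s < 1e-10) s = 1e-10;
    double dU = 2.0 * P.ktheta * (th - P.theta0);
    pe_angle += P.ktheta * (th - P.theta0) * (th - P.theta0);
    // grad theta wrt r_i and r_k
    double gix = (c * ax / la - bx / lb) / (la * s);
    double giy = (c * ay / la - by / lb) / (la * s);
    double giz = (c * az / la - bz / lb) / (la * s);
    double gkx = (c * bx / lb - ax / la) / (lb * s);
    double gky = (c * by / lb - ay / la) / (lb * s);
    double gkz = (c * bz / lb - az / la) / (lb * s);
    double Fix = -dU * gix, Fiy = -dU * giy, Fiz = -dU * giz;
    double Fkx = -dU * gkx, Fky = -dU * gky, Fkz = -dU * gkz;
    fx[i] += Fix; fy[i] += Fiy; fz[i] += Fiz;
    fx[k] += Fkx; fy[k] += Fky; fz[k] += Fkz;
    fx[j] -= (Fix + Fkx); fy[j] -= (Fiy + Fky); fz[j] -= (Fiz + Fkz);
  }
}

static FFParams make_params(const NumericMatrix& a, double gamma, double sigma,
                            double rc, double ks, double rs, double ktheta,
                            double theta0, double dt, double L, bool gaussian,
                            bool with_cons, bool with_diss, bool with_rand) {
  FFParams P;
  P.a = a.begin(); P.nspec = a.nrow();
  P.gamma = gamma; P.sigma = sigma; P.rc = rc; P.ks = ks; P.rs = rs;
  P.ktheta = ktheta; P.theta0 = theta0; P.dt = dt; P.L = L;
  P.gaussian = gaussian;
  P.with_cons = with_cons; P.with_diss = with_diss; P.with_rand = with_rand;
  return P;
}

// [[Rcpp::export]]
List forces_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
                NumericMatrix a, double gamma, double sigma, double rc,
                IntegerMatrix bonds0, double ks, double rs,
                IntegerMatrix angles0, double ktheta, double theta0,
                double L, double dt, double seed, double step,
                bool gaussian = false, bool brute = false,
                bool with_cons = true, bool with_diss = true, bool with_rand = true) {
  int N = pos.nrow();
  FFParams P = make_params(a, gamma, sigma, rc, ks, rs, ktheta, theta0, dt, L,
                           gaussian, with_cons, with_diss, with_rand);
  Workspace ws;
  std::vector<double> px(N), py(N), pz(N), vx(N), vy(N), vz(N);
  for (int i = 0; i < N; ++i) {
    px[i] = pos(i, 0); py[i] = pos(i, 1); pz[i] = pos(i, 2);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  double pe_pair, pe_bond, pe_angle;
  compute_forces(N, px.data(), py.data(), pz.data(), vx.data(), vy.data(), vz.data(),
                 species0.begin(), bonds0.begin(), bonds0.nrow(),
                 angles0.begin(), angles0.nrow(), P,
                 (uint64_t)seed, (uint64_t)step, brute, ws, pe_pair, pe_bond, pe_angle);
  NumericMatrix f(N, 3);
  for (int i = 0; i < N; ++i) {
    f(i, 0) = ws.fx[i]; f(i, 1) = ws.fy[i]; f(i, 2) = ws.fz[i];
  }
  return List::create(_["forces"] = f, _["pe_pair"] = pe_pair,
                      _["pe_bond"] = pe_bond, _["pe_angle"] = pe_angle);
}

static inline double wrap0L(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;  // guard rounding edge
  if (x < 0) x = 0;
  return x;
}

// [[Rcpp::export]]
List run_cpp(NumericMatrix pos, NumericMatrix vel, IntegerVector species0,
             NumericMatrix a, double gamma, double sigma, double rc,
             IntegerMatrix bonds0, double ks, double rs,
             IntegerMatrix angles0, double ktheta, double theta0,
             double L, double dt, int n_steps, double seed,
             double step0 = 0, double time0 = 0,
             int swap_every = 0, int n_slabs = 20, int slab_lo = 0, int slab_hi = -1,
             LogicalVector eligible = LogicalVector::create(true, true, true, true, true),
             int energy_every = 100, int frame_every = 0, int profile_every = 0,
             bool gaussian = false, double lambda = 0.5) {
  int N = pos.nrow();
  FFParams P = make_params(a, gamma, sigma, rc, ks, rs, ktheta, theta0, dt, L,
                           gaussian, true, true, true);
  if (slab_hi < 0) slab_hi = n_slabs - 1;
  Workspace ws;
  std::vector<double> px(N), py(N), pz(N), vx(N), vy(N), vz(N);
  std::vector<double> fx(N), fy(N), fz(N);
  const int* sp = species0.begin();
  for (int i = 0; i < N; ++i) {
    px[i] = wrap0L(pos(i, 0), L); py[i] = wrap0L(pos(i, 1), L); pz[i] = wrap0L(pos(i, 2), L);
    vx[i] = vel(i, 0); vy[i] = vel(i, 1); vz[i] = vel(i, 2);
  }
  double pe_pair, pe_bond, pe_angle;
  compute_forces(N, px.data(), py.data(), pz.data(), vx.data(), vy.data(), vz.data(),
                 sp, bonds0.begin(), bonds0.nrow(), angles0.begin(), angles0.nrow(),
                 P, (uint64_t)seed, (uint64_t)step0, false, ws, pe_pair, pe_bond, pe_angle);
  fx = ws.fx; fy = ws.fy; fz = ws.fz;

  int n_erec = (energy_every > 0) ? n_steps / energy_every : 0;
  NumericMatrix energy(n_erec, 8);
  int erow = 0;
  List frames;
  double swap_px = 0.0;
  int swap_count = 0, swap_skipped = 0;
  std::vector<double> prof_vx(n_slabs, 0.0);
  std::vector<double> prof_n(n_slabs, 0.0);
  double slabw = L / n_slabs;
  std::vector<double> vtx(N), vty(N), vtz(N);

  for (int s = 1; s <= n_steps; ++s) {
    uint64_t step_id = (uint64_t)(step0 + s);
    for (int i = 0; i < N; ++i) {
      px[i] = wrap0L(px[i] + dt * vx[i] + 0.5 * dt * dt * fx[i], L);
      py[i] = wrap0L(py[i] + dt * vy[i] + 0.5 * dt * dt * fy[i], L);
      pz[i] = wrap0L(pz[i] + dt * vz[i] + 0.5 * dt * dt * fz[i], L);
      vtx[i] = vx[i] + lambda * dt * fx[i];
      vty[i] = vy[i] + lambda * dt * fy[i];
      vtz[i] = vz[i] + lambda * dt * fz[i];
    }
    compute_forces(N, px.data(), py.data(), pz.data(), vtx.data(), vty.data(), vtz.data(),
                   sp, bonds0.begin(), bonds0.nrow(), angles0.begin(), angles0.nrow(),
                   P, (uint64_t)seed, step_id, false, ws, pe_pair, pe_bond, pe_angle);
    for (int i = 0; i < N; ++i) {
      vx[i] += 0.5 * dt * (fx[i] + ws.fx[i]);
      vy[i] += 0.5 * dt * (fy[i] + ws.fy[i]);
      vz[i] += 0.5 * dt * (fz[i] + ws.fz[i]);
      fx[i] = ws.fx[i]; fy[i] = ws.fy[i]; fz[i] = ws.fz[i];
    }

    if (swap_every > 0 && s % swap_every == 0) {
      int imin = -1, imax = -1;
      double vmin = 0, vmax = 0;
      for (int i = 0; i < N; ++i) {
        if (!eligible[sp[i]]) continue;
        int isl = (int)(pz[i] / slabw); if (isl >= n_slabs) isl = n_slabs - 1;
        if (isl == slab_lo && (imin < 0 || vx[i] < vmin)) { imin = i; vmin = vx[i]; }
        if (isl == slab_hi && (imax < 0 || vx[i] > vmax)) { imax = i; vmax = vx[i]; }
      }
      if (imin >= 0 && imax >= 0 && imin != imax) {
        double tmp = vx[imin]; vx[imin] = vx[imax]; vx[imax] = tmp;
        swap_px += std::fabs(vmax - vmin);
        ++swap_count;
      } else {
        ++swap_skipped;
      }
    }

    if (profile_every > 0 && s % profile_every == 0) {
      for (int i = 0; i < N; ++i) {
        int isl = (int)(pz[i] / slabw); if (isl >= n_slabs) isl = n_slabs - 1;
        prof_vx[isl] += vx[i];
        prof_n[isl] += 1.0;
      }
    }

    if (energy_every > 0 && s % energy_every == 0) {
      double ke = 0;
      for (int i = 0; i < N; ++i)
        ke += 0.5 * (vx[i] * vx[i] + vy[i] * vy[i] + vz[i] * vz[i]);
      if (!std::isfinite(ke) || !std::isfinite(pe_pair))
        stop("non-finite state at step %g (kinetic=%g pair=%g): reduce dt or check input",
             step0 + s, ke, pe_pair);
      energy(erow, 0) = step0 + s;
      energy(erow, 1) = time0 + s * dt;
      energy(erow, 2) = ke;
      energy(erow, 3) = pe_pair;
      energy(erow, 4) = pe_bond;
      energy(erow, 5) = pe_angle;
      energy(erow, 6) = ke + pe_pair + pe_bond + pe_angle;
      energy(erow, 7) = 2.0 * ke / (3.0 * N);
      ++erow;
    }

    if (frame_every > 0 && s % frame_every == 0) {
      NumericMatrix fp(N, 3), fv(N, 3);
      for (int i = 0; i < N; ++i) {
        fp(i, 0) = px[i]; fp(i, 1) = py[i]; fp(i, 2) = pz[i];
        fv(i, 0) = vx[i]; fv(i, 1) = vy[i]; fv(i, 2) = vz[i];
      }
      frames.push_back(List::create(_["pos"] = fp, _["vel"] = fv,
                                    _["step"] = step0 + s, _["time"] = time0 + s * dt));
    }
  }

  NumericMatrix outp(N, 3), outv(N, 3);
  for (int i = 0; i < N; ++i) {
    outp(i, 0) = px[i]; outp(i, 1) = py[i]; outp(i, 2) = pz[i];
    outv(i, 0) = vx[i]; outv(i, 1) = vy[i]; outv(i, 2) = vz[i];
  }
  return List::create(_["pos"] = outp, _["vel"] = outv, _["energy"] = energy,
                      _["frames"] = frames, _["swap_count"] = swap_count,
                      _["swap_px"] = swap_px, _["swap_skipped"] = swap_skipped,
                      _["prof_vx"] = NumericVector(prof_vx.begin(), prof_vx.end()),
                      _["prof_n"] = NumericVector(prof_n.begin(), prof_n.end()),
                      _["step"] = step0 + n_steps, _["time"] = time0 + n_steps * dt);
}

// Connected components of the contact graph (min-image distance <= cutoff),
// with per-component periodic spanning flags found by BFS unwrapping.
// [[Rcpp::export]]
List cluster_cpp(NumericMatrix pos, double L, double cutoff) {
  int N = pos.nrow();
  std::vector<double> px(N), py(N), pz(N);
  for (int i = 0; i < N; ++i) {
    px[i] = wrap0L(pos(i, 0), L); py[i] = wrap0L(pos(i, 1), L); pz[i] = wrap0L(pos(i, 2), L);
  }
  double c2 = cutoff * cutoff;
  // adjacency via cell list (or brute for small/coarse boxes)
  std::vector<std::vector<int>> adj(N);
  int nc = (int)std::floor(L / cutoff);
  auto try_edge = [&](int i, int j) {
    double dx = min_image(px[i] - px[j], L);
    double dy = min_image(py[i] - py[j], L);
    double dz = min_image(pz[i] - pz[j], L);
    if (dx * dx + dy * dy + dz * dz <= c2) {
      adj[i].push_back(j);
      adj[j].push_back(i);
    }
  };
  if (nc < 3 || N < 64) {
    for (int i = 0; i < N - 1; ++i)
      for (int j = i + 1; j < N; ++j) try_edge(i, j);
  } else {
    double cw = L / nc;
    std::vector<int> head(nc * nc * nc, -1), nxt(N, -1);
    for (int i = 0; i < N; ++i) {
      int cx = std::min((int)(px[i] / cw), nc - 1);
      int cy = std::min((int)(py[i] / cw), nc - 1);
      int cz = std::min((int)(pz[i] / cw), nc - 1);
      int c = cx + nc * (cy + nc * cz);
      nxt[i] = head[c]; head[c] = i;
    }
    static const int off[13][3] = {
      {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
      {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
    for (int cz = 0; cz < nc; ++cz)
      for (int cy = 0; cy < nc; ++cy)
        for (int cx = 0; cx < nc; ++cx) {
          int c = cx + nc * (cy + nc * cz);
          for (int i = head[c]; i >= 0; i = nxt[i])
            for (int j = nxt[i]; j >= 0; j = nxt[j]) try_edge(i, j);
          for (int k = 0; k < 13; ++k) {
            int ox = (cx + off[k][0] + nc) % nc;
            int oy = (cy + off[k][1] + nc) % nc;
            int oz = (cz + off[k][2] + nc) % nc;
            int cc = ox + nc * (oy + nc * oz);
            for (int i = head[c]; i >= 0; i = nxt[i])
              for (int j = head[cc]; j >= 0; j = nxt[j]) try_edge(i, j);
          }
        }
  }

  std::vector<int> comp(N, -1);
  std::vector<double> ux(N), uy(N), uz(N);  // unwrapped coordinates
  std::vector<int> queue;
  int ncomp = 0;
  std::vector<std::array<bool, 3>> spans;
  std::vector<int> sizes;
  std::vector<std::array<double, 3>> centroids;
  for (int seed = 0; seed < N; ++seed) {
    if (comp[seed] >= 0) continue;
    int cid = ncomp++;
    spans.push_back({false, false, false});
    sizes.push_back(0);
    centroids.push_back({0.0, 0.0, 0.0});
    comp[seed] = cid;
    ux[seed] = px[seed]; uy[seed] = py[seed]; uz[seed] = pz[seed];
    queue.clear(); queue.push_back(seed);
    while (!queue.empty()) {
      int i = queue.back(); queue.pop_back();
      ++sizes[cid];
      centroids[cid][0] += ux[i]; centroids[cid][1] += uy[i]; centroids[cid][2] += uz[i];
      for (int j : adj[i]) {
        double cux = ux[i] + min_image(px[j] - px[i], L);
        double cy = uy[i] + min_image(py[j] - py[i], L);
        double cz = uz[i] + min_image(pz[j] - pz[i], L);
        if (comp[j] < 0) {
          comp[j] = cid;
          ux[j] = cux; uy[j] = cy; uz[j] = cz;
          queue.push_back(j);
        } else {
          // already placed: a mismatch of ~L along an axis means the component
          // connects to its own periodic image there
          if (std::fabs(cux - ux[j]) > 0.5 * L) spans[cid][0] = true;
          if (std::fabs(cy - uy[j]) > 0.5 * L) spans[cid][1] = true;
          if (std::fabs(cz - uz[j]) > 0.5 * L) spans[cid][2] = true;
        }
      }
    }
  }
  IntegerVector labels(N);
  for (int i = 0; i < N; ++i) labels[i] = comp[i] + 1;
  IntegerVector osizes(ncomp);
  LogicalMatrix ospan(ncomp, 3);
  NumericMatrix ocent(ncomp, 3);
  for (int c = 0; c < ncomp; ++c) {
    osizes[c] = sizes[c];
    for (int d = 0; d < 3; ++d) {
      ospan(c, d) = spans[c][d];
      ocent(c, d) = wrap0L(centroids[c][d] / sizes[c], L);
    }
  }
  return List::create(_["labels"] = labels, _["sizes"] = osizes,
                      _["spanning"] = ospan, _["centroid"] = ocent);
}
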