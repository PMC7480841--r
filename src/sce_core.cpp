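// Core numerical kernels of the subcellular-element model: pairwise Morse and
// spring forces, per-cell area (2D volume) penalty, total energy, the explicit
// Euler overdamped update, and the spatial searches used to maintain dynamic
// interaction pair lists. Everything above this file (tissue construction,
// scenario scheduling, metrics) lives in R.
//
// Conventions: positions in um, forces in nN, time in AU. Pair index vectors
// arriving from R are 1-based and converted here. A "packed" List (built by
// pack_interactions() in R) carries the flattened interaction tables:
//   si, sj, sk, sr0, sbrk          all spring bonds (brk = Inf if unbreakable)
//   vi, vj, vprm                   volume-exclusion Morse pairs + c(U0,xi0,W0,ga0,cut)
//   ni, nj, nprm                   nucleus-cohesion Morse pairs + same layout
//   ring_idx, ring_off, area0, kvol  cell polygon rings (concatenated, 0-based
//                                    after conversion) and target areas

#include <Rcpp.h>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

namespace {

struct Packed {
  std::vector<int> si, sj;
  std::vector<double> sk, sr0, sbrk;
  std::vector<int> vi, vj, ni, nj;
  double vprm[5], nprm[5];
  std::vector<int> ring_idx;
  std::vector<int> ring_off;
  std::vector<double> area0;
  double kvol;
};

void unpack(const List& p, Packed& pk) {
  IntegerVector si = p["si"], sj = p["sj"], vi = p["vi"], vj = p["vj"],
                ni = p["ni"], nj = p["nj"], ridx = p["ring_idx"],
                roff = p["ring_off"];
  NumericVector sk = p["sk"], sr0 = p["sr0"], sbrk = p["sbrk"],
                vprm = p["vprm"], nprm = p["nprm"], a0 = p["area0"];
  pk.si.assign(si.begin(), si.end());
  pk.sj.assign(sj.begin(), sj.end());
  pk.sk.assign(sk.begin(), sk.end());
  pk.sr0.assign(sr0.begin(), sr0.end());
  pk.sbrk.assign(sbrk.begin(), sbrk.end());
  pk.vi.assign(vi.begin(), vi.end());
  pk.vj.assign(vj.begin(), vj.end());
  pk.ni.assign(ni.begin(), ni.end());
  pk.nj.assign(nj.begin(), nj.end());
  for (int k = 0; k < 5; ++k) { pk.vprm[k] = vprm[k]; pk.nprm[k] = nprm[k]; }
  pk.ring_idx.assign(ridx.begin(), ridx.end());
  pk.ring_off.assign(roff.begin(), roff.end());
  pk.area0.assign(a0.begin(), a0.end());
  pk.kvol = as<double>(p["kvol"]);
  // 1-based R indices -> 0-based
  for (auto& v : pk.si) --v;  for (auto& v : pk.sj) --v;
  for (auto& v : pk.vi) --v;  for (auto& v : pk.vj) --v;
  for (auto& v : pk.ni) --v;  for (auto& v : pk.nj) --v;
  for (auto& v : pk.ring_idx) --v;
}

inline void morse_accum(const double* x, const double* y, int i, int j,
                        const double* prm, double* fx, double* fy,
                        double* energy) {
  const double U0 = prm[0], xi0 = prm[1], W0 = prm[2], ga0 = prm[3],
               cut = prm[4];
  double dx = x[i] - x[j], dy = y[i] - y[j];
  double r = std::sqrt(dx * dx + dy * dy);
  if (r >= cut - 1e-9) return;  // 1 nm guard band: rest gaps placed exactly
                                // at the cutoff stay force-free under rounding
  if (r <= 0.0)
    stop("degenerate Morse pair: nodes %d and %d coincide", i + 1, j + 1);
  double er = std::exp(-r / xi0), ea = std::exp(-r / ga0);
  if (energy) *energy += U0 * er - W0 * ea;
  if (fx) {
    // -dU/dr, positive = repulsive along (xi - xj)
    double fr = U0 / xi0 * er - W0 / ga0 * ea;
    double s = fr / r;
    fx[i] += s * dx; fy[i] += s * dy;
    fx[j] -= s * dx; fy[j] -= s * dy;
  }
}

void eval_all(const double* x, const double* y, int n, const Packed& pk,
              double* fx, double* fy, double* energy) {
  if (fx) {
    std::fill(fx, fx + n, 0.0);
    std::fill(fy, fy + n, 0.0);
  }
  // springs
  for (size_t b = 0; b < pk.si.size(); ++b) {
    int i = pk.si[b], j = pk.sj[b];
    double dx = x[i] - x[j], dy = y[i] - y[j];
    double r = std::sqrt(dx * dx + dy * dy);
    if (r > pk.sbrk[b]) continue;        // breakable spring past its limit
    double r0 = pk.sr0[b], k = pk.sk[b];
    if (r <= 0.0) {
      if (r0 == 0.0) continue;           // zero-rest spring at zero length
      stop("degenerate spring: nodes %d and %d coincide", i + 1, j + 1);
    }
    if (energy) *energy += 0.5 * k * (r - r0) * (r - r0);
    if (fx) {
      double s = -k * (r - r0) / r;
      fx[i] += s * dx; fy[i] += s * dy;
      fx[j] -= s * dx; fy[j] -= s * dy;
    }
  }
  // Morse families
  for (size_t b = 0; b < pk.vi.size(); ++b)
    morse_accum(x, y, pk.vi[b], pk.vj[b], pk.vprm, fx, fy, energy);
  for (size_t b = 0; b < pk.ni.size(); ++b)
    morse_accum(x, y, pk.ni[b], pk.nj[b], pk.nprm, fx, fy, energy);
  // area penalty per cell ring (shoelace)
  int ncell = (int)pk.area0.size();
  for (int c = 0; c < ncell; ++c) {
    int a = pk.ring_off[c], bnd = pk.ring_off[c + 1], m = bnd - a;
    if (m < 3) continue;
    double A = 0.0;
    for (int k = 0; k < m; ++k) {
      int i = pk.ring_idx[a + k], j = pk.ring_idx[a + (k + 1) % m];
      A += x[i] * y[j] - x[j] * y[i];
    }
    A *= 0.5;
    double dA = A - pk.area0[c];
    if (energy) *energy += 0.5 * pk.kvol * dA * dA;
    if (fx) {
      double s = -pk.kvol * dA;
      for (int k = 0; k < m; ++k) {
        int ip = pk.ring_idx[a + (k - 1 + m) % m];
        int i0 = pk.ring_idx[a + k];
        int in = pk.ring_idx[a + (k + 1) % m];
        // dA/dx_k = (y_{k+1} - y_{k-1})/2 ; dA/dy_k = (x_{k-1} - x_{k+1})/2
        fx[i0] += s * 0.5 * (y[in] - y[ip]);
        fy[i0] += s * 0.5 * (x[ip] - x[in]);
      }
    }
  }
}

}  // namespace

// [[Rcpp::export]]
NumericMatrix cpp_forces(NumericMatrix pos, List packed) {
  Packed pk;
  unpack(packed, pk);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  eval_all(x.data(), y.data(), n, pk, fx.data(), fy.data(), nullptr);
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = fx[i]; out(i, 1) = fy[i]; }
  return out;
}

// [[Rcpp::export]]
double cpp_energy(NumericMatrix pos, List packed) {
  Packed pk;
  unpack(packed, pk);
  int n = pos.nrow();
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  double e = 0.0;
  eval_all(x.data(), y.data(), n, pk, nullptr, nullptr, &e);
  return e;
}

// Advance n_steps of overdamped explicit Euler: x <- x + dt * F / C.
// inv_damp is 1/C per node. Returns the updated positions; stops with an
// informative error if any coordinate leaves the finite range (blow-up).
// [[Rcpp::export]]
NumericMatrix cpp_step_n(NumericMatrix pos, NumericVector inv_damp,
                         List packed, int n_steps, double dt) {
  Packed pk;
  unpack(packed, pk);
  int n = pos.nrow();
  std::vector<double> x(n), y(n), fx(n), fy(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(i, 0); y[i] = pos(i, 1); }
  for (int s = 0; s < n_steps; ++s) {
    eval_all(x.data(), y.data(), n, pk, fx.data(), fy.data(), nullptr);
    double chk = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += dt * fx[i] * inv_damp[i];
      y[i] += dt * fy[i] * inv_damp[i];
      chk += x[i] + y[i];
    }
    if (!std::isfinite(chk)) {
      int worst = 0;
      double wmag = -1.0;
      for (int i = 0; i < n; ++i) {
        double m = std::abs(x[i]) + std::abs(y[i]);
        if (!std::isfinite(m)) { worst = i; break; }
        if (m > wmag) { wmag = m; worst = i; }
      }
      stop("integration blew up at substep %d (node %d non-finite); reduce dt",
           s + 1, worst + 1);
    }
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = x[i]; out(i, 1) = y[i]; }
  return out;
}

// Candidate volume-exclusion pairs within `cutoff`, found on a uniform grid.
// klass: 1 nucleus, 2 membrane, 3 ecm; cell: cell id (0 for ECM nodes);
// ring_pos / ring_len: position of a membrane node in its cell ring and the
// ring length (-1 / 0 otherwise). Admissible pairs: nucleus-membrane of the
// SAME cell, membrane-membrane of different cells OR non-adjacent in the
// same ring (bonded neighbours are excluded -- E_memb covers them), and
// membrane-ECM. Returns a 2-column 1-based index matrix.
// [[Rcpp::export]]
IntegerMatrix cpp_grid_pairs(NumericMatrix pos, double cutoff,
                             IntegerVector klass, IntegerVector cell,
                             IntegerVector ring_pos, IntegerVector ring_len) {
  int n = pos.nrow();
  std::unordered_map<long long, std::vector<int>> grid;
  grid.reserve(n * 2);
  auto key = [](long long ix, long long iy) { return (ix << 32) ^ (iy & 0xffffffffLL); };
  std::vector<long long> gx(n), gy(n);
  for (int i = 0; i < n; ++i) {
    gx[i] = (long long)std::floor(pos(i, 0) / cutoff);
    gy[i] = (long long)std::floor(pos(i, 1) / cutoff);
    grid[key(gx[i], gy[i])].push_back(i);
  }
  std::vector<int> out_i, out_j;
  double c2 = (cutoff - 1e-9) * (cutoff - 1e-9);
  for (int i = 0; i < n; ++i) {
    for (long long dx = -1; dx <= 1; ++dx) {
      for (long long dy = -1; dy <= 1; ++dy) {
        auto it = grid.find(key(gx[i] + dx, gy[i] + dy));
        if (it == grid.end()) continue;
        for (int j : it->second) {
          if (j <= i) continue;
          int ki = klass[i], kj = klass[j];
          bool ok;
          if (ki == 1 || kj == 1) {            // nucleus involved
            ok = ((ki == 1 && kj == 2) || (ki == 2 && kj == 1)) &&
                 cell[i] == cell[j];
          } else if (ki == 2 && kj == 2) {     // membrane-membrane
            if (cell[i] != cell[j]) ok = true;
            else {                             // same ring: skip bonded pairs
              int d = std::abs(ring_pos[i] - ring_pos[j]);
              ok = d > 1 && d < ring_len[i] - 1;
            }
          } else {                             // one of them ECM
            ok = (ki == 2 && kj == 3) || (ki == 3 && kj == 2);
          }
          if (!ok) continue;
          double ddx = pos(i, 0) - pos(j, 0), ddy = pos(i, 1) - pos(j, 1);
          if (ddx * ddx + ddy * ddy < c2) {
            out_i.push_back(i + 1);
            out_j.push_back(j + 1);
          }
        }
      }
    }
  }
  IntegerMatrix out(out_i.size(), 2);
  for (size_t k = 0; k < out_i.size(); ++k) {
    out(k, 0) = out_i[k];
    out(k, 1) = out_j[k];
  }
  return out;
}

// Mutual nearest-neighbour matching between two node subsets (1-based ids into
// pos). A pair (a, b) is kept iff b is a's nearest partner in B, a is b's
// nearest in A, and their distance is below cutoff. One partner per node.
// [[Rcpp::export]]
IntegerMatrix cpp_mutual_nn(NumericMatrix pos, IntegerVector idxA,
                            IntegerVector idxB, double cutoff) {
  int na = idxA.size(), nb = idxB.size();
  std::vector<int> bestA(na, -1), bestB(nb, -1);
  std::vector<double> dA(na, cutoff), dB(nb, cutoff);
  for (int a = 0; a < na; ++a) {
    double xa = pos(idxA[a] - 1, 0), ya = pos(idxA[a] - 1, 1);
    for (int b = 0; b < nb; ++b) {
      double dx = xa - pos(idxB[b] - 1, 0), dy = ya - pos(idxB[b] - 1, 1);
      double d = std::sqrt(dx * dx + dy * dy);
      if (d < dA[a]) { dA[a] = d; bestA[a] = b; }
      if (d < dB[b]) { dB[b] = d; bestB[b] = a; }
    }
  }
  std::vector<int> out_a, out_b;
  for (int a = 0; a < na; ++a) {
    int b = bestA[a];
    if (b >= 0 && bestB[b] == a) {
      out_a.push_back(idxA[a]);
      out_b.push_back(idxB[b]);
    }
  }
  IntegerMatrix out(out_a.size(), 2);
  for (size_t k = 0; k < out_a.size(); ++k) {
    out(k, 0) = out_a[k];
    out(k, 1) = out_b[k];
  }
  return out;
}
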