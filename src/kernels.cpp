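#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Squared distance with optional minimum-image convention (orthorhombic box).
static inline double dist2_mi(const double* a, const double* b,
                              const double* box, bool pbc) {
  double s = 0.0;
  for (int k = 0; k < 3; ++k) {
    double d = a[k] - b[k];
    if (pbc) d -= box[k] * std::round(d / box[k]);
    s += d * d;
  }
  return s;
}

typedef std::unordered_map<uint64_t, int> PairCount;

static inline void add_pair(PairCount& pc, int ri, int rj) {
  if (ri == rj) return;
  int a = std::min(ri, rj), b = std::max(ri, rj);
  pc[(uint64_t)a * 0x100000000ULL + (uint64_t)b] += 1;
}

// Brute-force atom-pair scan; coords stored column-major (n x 3).
static void scan_brute(const double* xyz, int n, const int* resid,
                       const double* box, double cutoff, bool pbc,
                       PairCount& pc) {
  const double c2 = cutoff * cutoff;
  for (int i = 0; i < n; ++i) {
    double ai[3] = { xyz[i], xyz[i + n], xyz[i + 2 * n] };
    for (int j = i + 1; j < n; ++j) {
      double bj[3] = { xyz[j], xyz[j + n], xyz[j + 2 * n] };
      if (dist2_mi(ai, bj, box, pbc) <= c2) add_pair(pc, resid[i], resid[j]);
    }
  }
}

// Cell-list scan. Requires pbc with >= 3 cells per dimension (caller checks).
static void scan_cells(const double* xyz, int n, const int* resid,
                       const double* box, double cutoff, PairCount& pc) {
  const double c2 = cutoff * cutoff;
  int nc[3];
  double cw[3];
  for (int k = 0; k < 3; ++k) {
    nc[k] = std::max(3, (int)std::floor(box[k] / cutoff));
    cw[k] = box[k] / nc[k];
  }
  int ncells = nc[0] * nc[1] * nc[2];
  std::vector<int> head(ncells, -1), next(n, -1);
  std::vector<double> wrapped(3 * n);
  std::vector<int> cell_of(n);
  for (int i = 0; i < n; ++i) {
    int ic[3];
    for (int k = 0; k < 3; ++k) {
      double x = xyz[i + k * n];
      x -= box[k] * std::floor(x / box[k]);   // wrap into [0, box)
      if (x >= box[k]) x = 0.0;
      wrapped[i + k * n] = x;
      int c = (int)std::floor(x / cw[k]);
      if (c >= nc[k]) c = nc[k] - 1;
      ic[k] = c;
    }
    int cell = ic[0] + nc[0] * (ic[1] + nc[1] * ic[2]);
    cell_of[i] = cell;
    next[i] = head[cell];
    head[cell] = i;
  }
  // atom-centric: visit each atom's 27 neighbor cells, pair with j > i
  const double* w = wrapped.data();
  for (int i = 0; i < n; ++i) {
    double ai[3] = { w[i], w[i + n], w[i + 2 * n] };
    int cell = cell_of[i];
    int cx = cell % nc[0];
    int cy = (cell / nc[0]) % nc[1];
    int cz = cell / (nc[0] * nc[1]);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          int ncell = ((cx + dx + nc[0]) % nc[0]) +
                      nc[0] * (((cy + dy + nc[1]) % nc[1]) +
                               nc[1] * ((cz + dz + nc[2]) % nc[2]));
          for (int j = head[ncell]; j >= 0; j = next[j]) {
            if (j <= i) continue;
            double bj[3] = { w[j], w[j + n], w[j + 2 * n] };
            if (dist2_mi(ai, bj, box, true) <= c2)
              add_pair(pc, resid[i], resid[j]);
          }
        }
  }
}

static bool cells_usable(int n, const double* box, double cutoff, bool pbc) {
  if (!pbc || n < 200) return false;
  for (int k = 0; k < 3; ++k)
    if (std::floor(box[k] / cutoff) < 3) return false;
  return true;
}

// Residue-residue contacts in one frame.
// coords: n x 3; resid: 1-based residue index per atom; res_chain: 1-based
// chain index per residue (length nres). method: 0 auto, 1 cells, 2 brute.
// Returns pairs (m x 2, residue indices, i < j), atom_counts (m),
// chain_counts (nchain x nchain residue-pair counts; symmetric with both
// triangles filled, diagonal = intra-chain residue pairs).
// [[Rcpp::export(name = ".cpp_frame_contacts")]]
List cpp_frame_contacts(NumericMatrix coords, IntegerVector resid,
                        IntegerVector res_chain, NumericVector box,
                        double cutoff, bool pbc, int method) {
  int n = coords.nrow();
  PairCount pc;
  bool use_cells = (method == 1) ||
                   (method == 0 && cells_usable(n, box.begin(), cutoff, pbc));
  if (use_cells) {
    scan_cells(REAL(coords), n, INTEGER(resid), REAL(box), cutoff, pc);
  } else {
    scan_brute(REAL(coords), n, INTEGER(resid), REAL(box), cutoff, pbc, pc);
  }
  std::vector<uint64_t> keys;
  keys.reserve(pc.size());
  for (auto& kv : pc) keys.push_back(kv.first);
  std::sort(keys.begin(), keys.end());
  int m = keys.size(), nchain = 0;
  for (int r = 0; r < res_chain.size(); ++r)
    nchain = std::max(nchain, res_chain[r]);
  IntegerMatrix pairs(m, 2);
  IntegerVector acnt(m);
  IntegerMatrix ccnt(nchain, nchain);
  for (int t = 0; t < m; ++t) {
    int ri = (int)(keys[t] >> 32), rj = (int)(keys[t] & 0xffffffffULL);
    pairs(t, 0) = ri;
    pairs(t, 1) = rj;
    acnt[t] = pc[keys[t]];
    int ci = res_chain[ri - 1] - 1, cj = res_chain[rj - 1] - 1;
    ccnt(ci, cj) += 1;
    if (ci != cj) ccnt(cj, ci) += 1;
  }
  return List::create(_["pairs"] = pairs, _["atom_counts"] = acnt,
                      _["chain_counts"] = ccnt);
}

// Per-frame chain-pair residue-contact counts over a whole trajectory.
// coords: array n x 3 x nframes (as a flat vector); box: nframes x 3.
// Returns integer array nchain x nchain x nframes.
// [[Rcpp::export(name = ".cpp_traj_chain_counts")]]
IntegerVector cpp_traj_chain_counts(NumericVector coords, int natoms,
                                    int nframes, IntegerVector resid,
                                    IntegerVector res_chain,
                                    NumericMatrix box, double cutoff,
                                    bool pbc, int method) {
  int nchain = 0;
  for (int r = 0; r < res_chain.size(); ++r)
    nchain = std::max(nchain, res_chain[r]);
  IntegerVector out(nchain * nchain * nframes);
  const double* base = REAL(coords);
  for (int f = 0; f < nframes; ++f) {
    double bx[3] = { box(f, 0), box(f, 1), box(f, 2) };
    const double* xyz = base + (size_t)f * 3 * natoms;
    PairCount pc;
    bool use_cells = (method == 1) ||
                     (method == 0 && cells_usable(natoms, bx, cutoff, pbc));
    if (use_cells) scan_cells(xyz, natoms, INTEGER(resid), bx, cutoff, pc);
    else scan_brute(xyz, natoms, INTEGER(resid), bx, cutoff, pbc, pc);
    int* slab = INTEGER(out) + (size_t)f * nchain * nchain;
    for (auto& kv : pc) {
      int ri = (int)(kv.first >> 32), rj = (int)(kv.first & 0xffffffffULL);
      int ci = res_chain[ri - 1] - 1, cj = res_chain[rj - 1] - 1;
      slab[ci + nchain * cj] += 1;
      if (ci != cj) slab[cj + nchain * ci] += 1;
    }
    if (f % 256 == 0) Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(nchain, nchain, nframes);
  return out;
}

// Overdamped Langevin dynamics of bead chains in a periodic box.
// Nonbonded: harmonic-core repulsion below r_rep plus a Gaussian attraction
// well of depth eps_ij centred at r_min. eps_ij: peptide-peptide pairs use
// eps_pp, peptide-inhibitor pairs use the inhibitor bead's stickiness.
// Beads with moving == FALSE are frozen. Uses R's RNG (seed via set.seed()).
// [[Rcpp::export(name = ".cpp_brownian")]]
List cpp_brownian(NumericMatrix coords0, LogicalVector moving,
                  IntegerVector chain, IntegerVector seqidx,
                  IntegerVector type, NumericVector sticky, double eps_pp,
                  double k_bond, double r_bond, IntegerMatrix bonds,
                  double k_rep, double r_rep, double r_min, double width,
                  double r_cut, double diff_coef, double kBT, double dt,
                  int n_steps, int save_every, NumericVector box,
                  double max_disp) {
  int n = coords0.nrow();
  std::vector<double> x(3 * n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) x[3 * i + k] = coords0(i, k);
  int n_save = n_steps / save_every;
  NumericVector out((size_t)n * 3 * n_save);
  NumericVector times(n_save);
  std::vector<double> force(3 * n);
  const double mob = diff_coef / kBT * dt;
  const double sig = std::sqrt(2.0 * diff_coef * dt);
  const double rc2 = r_cut * r_cut;
  const double w2 = width * width;
  int saved = 0;
  RNGScope rng;
  for (int step = 1; step <= n_steps; ++step) {
    std::fill(force.begin(), force.end(), 0.0);
    // bonds
    for (int b = 0; b < bonds.nrow(); ++b) {
      int i = bonds(b, 0) - 1, j = bonds(b, 1) - 1;
      double d[3], r2 = 0;
      for (int k = 0; k < 3; ++k) {
        d[k] = x[3 * i + k] - x[3 * j + k];
        d[k] -= box[k] * std::round(d[k] / box[k]);
        r2 += d[k] * d[k];
      }
      double r = std::sqrt(r2);
      if (r < 1e-9) continue;
      double fmag = -2.0 * k_bond * (r - r_bond) / r;
      for (int k = 0; k < 3; ++k) {
        force[3 * i + k] += fmag * d[k];
        force[3 * j + k] -= fmag * d[k];
      }
    }
    // nonbonded (brute force; systems are small)
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        if (chain[i] == chain[j] && std::abs(seqidx[i] - seqidx[j]) <= 2)
          continue;
        if (!moving[i] && !moving[j]) continue;
        double d[3], r2 = 0;
        for (int k = 0; k < 3; ++k) {
          d[k] = x[3 * i + k] - x[3 * j + k];
          d[k] -= box[k] * std::round(d[k] / box[k]);
          r2 += d[k] * d[k];
        }
        if (r2 > rc2 || r2 < 1e-12) continue;
        double r = std::sqrt(r2);
        double eps;
        if (type[i] == 0 && type[j] == 0) eps = eps_pp;
        else if (type[i] != type[j]) eps = sticky[type[i] == 1 ? i : j];
        else continue;   // inhibitor-inhibitor (frozen anyway)
        double fmag = 0.0;
        if (r < r_rep) fmag += -2.0 * k_rep * (r - r_rep) / r;  // repulsive
        double g = (r - r_min);
        fmag += -eps * g / w2 * std::exp(-g * g / (2.0 * w2)) / r;
        for (int k = 0; k < 3; ++k) {
          force[3 * i + k] += fmag * d[k];
          force[3 * j + k] -= fmag * d[k];
        }
      }
    }
    // update
    NumericVector noise = rnorm(3 * n, 0.0, 1.0);
    for (int i = 0; i < n; ++i) {
      if (!moving[i]) continue;
      for (int k = 0; k < 3; ++k) {
        double dx = mob * force[3 * i + k] + sig * noise[3 * i + k];
        if (!std::isfinite(dx) || std::fabs(dx) > max_disp)
          stop("unstable integration step at step %d (|dx| = %.2f A); "
               "reduce dt or force constants", step, std::fabs(dx));
        double xn = x[3 * i + k] + dx;
        xn -= box[k] * std::floor(xn / box[k]);
        x[3 * i + k] = xn;
      }
    }
    if (step % save_every == 0) {
      double* slab = REAL(out) + (size_t)saved * 3 * n;
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) slab[i + k * n] = x[3 * i + k];
      times[saved] = step * dt;
      ++saved;
    }
    if (step % 64 == 0) Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(n, 3, n_save);
  return List::create(_["coords"] = out, _["times"] = times);
}
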