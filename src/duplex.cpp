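#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <limits>
using namespace Rcpp;

// Bases encoded A=0, C=1, G=2, U=3. Pair types indexed
// 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG (query base first, target base second).
static inline int pair_index(int q, int t, bool allow_gu) {
  if (q == 0 && t == 3) return 0;
  if (q == 3 && t == 0) return 1;
  if (q == 1 && t == 2) return 2;
  if (q == 2 && t == 1) return 3;
  if (allow_gu) {
    if (q == 2 && t == 3) return 4;
    if (q == 3 && t == 2) return 5;
  }
  return -1;
}

struct DuplexModel {
  const double *stacks;          // 6x6, column-major: stacks[prev + 6*cur]
  std::vector<int> loop_di, loop_dj; // bulge/internal-loop predecessor offsets
  std::vector<double> loop_cost;
  bool allow_gu;

  DuplexModel(const NumericMatrix &s, double bulge_open, double bulge_ext,
              double internal_open, double internal_ext, int max_bulge,
              int max_internal, bool gu)
    : stacks(s.begin()), allow_gu(gu) {
    // enumerate every legal non-stacking transition once: a bulge of g
    // unpaired nt on one strand, or an internal loop of g1+g2 nt
    for (int g = 1; g <= max_bulge; ++g) {
      loop_di.push_back(1 + g); loop_dj.push_back(1);
      loop_cost.push_back(bulge_open + bulge_ext * g);
      loop_di.push_back(1); loop_dj.push_back(1 + g);
      loop_cost.push_back(bulge_open + bulge_ext * g);
    }
    for (int g1 = 1; g1 <= max_internal - 1; ++g1)
      for (int g2 = 1; g1 + g2 <= max_internal; ++g2) {
        loop_di.push_back(1 + g1); loop_dj.push_back(1 + g2);
        loop_cost.push_back(internal_open + internal_ext * (g1 + g2));
      }
  }
};

struct DuplexResult {
  double mfe = 0.0;
  std::vector<int> qpos, tpos; // 1-based, 5'->3' on the query
};

// Intermolecular duplex DP, antiparallel, no intramolecular structure.
// E[i][j] = best (most negative) energy of a duplex whose 3'-most query
// pair is (i, j); successive query positions pair with strictly
// decreasing target positions. Stacked adjacent pairs add a
// nearest-neighbor term; bulges/internal loops add affine penalties and
// break stacking. A lone pair scores 0 (no helix initiation term).
// `pc` holds pair codes for the full target (n x M, row-major); the DP
// runs on the window of width m starting at target offset s.
static DuplexResult duplex_dp(const int8_t *pc, int n, int M, int s, int m,
                              const DuplexModel &mod) {
  const double INF = std::numeric_limits<double>::infinity();
  static thread_local std::vector<double> E;
  static thread_local std::vector<int> bp;
  E.assign((size_t)n * m, INF);
  bp.assign((size_t)n * m, -1);

  double best = 0.0;
  int best_cell = -1;
  const size_t nloop = mod.loop_di.size();

  for (int i = 0; i < n; ++i) {
    const int8_t *pcrow = pc + (size_t)i * M + s;
    for (int j = m - 1; j >= 0; --j) {
      int p = pcrow[j];
      if (p < 0) continue;
      double e = 0.0; // open a new duplex with this single pair
      int from = -1;
      if (i > 0 && j + 1 < m) { // stacked extension
        int p2 = pc[(size_t)(i - 1) * M + s + j + 1];
        if (p2 >= 0) {
          double prev = E[(size_t)(i - 1) * m + j + 1];
          if (prev < INF) {
            double cand = prev + mod.stacks[p2 + 6 * p];
            if (cand < e) { e = cand; from = (i - 1) * m + j + 1; }
          }
        }
      }
      for (size_t k = 0; k < nloop; ++k) { // bulge / internal-loop extension
        int i2 = i - mod.loop_di[k], j2 = j + mod.loop_dj[k];
        if (i2 < 0 || j2 >= m) continue;
        double prev = E[(size_t)i2 * m + j2];
        if (prev >= INF) continue;
        double cand = prev + mod.loop_cost[k];
        if (cand < e) { e = cand; from = i2 * m + j2; }
      }
      size_t idx = (size_t)i * m + j;
      E[idx] = e;
      bp[idx] = from;
      if (e < best) { best = e; best_cell = (int)idx; }
    }
  }

  DuplexResult res;
  res.mfe = best;
  if (best_cell >= 0) {
    int cell = best_cell;
    while (cell >= 0) {
      res.qpos.push_back(cell / m + 1);
      res.tpos.push_back(cell % m + 1);
      cell = bp[cell];
    }
    std::reverse(res.qpos.begin(), res.qpos.end());
    std::reverse(res.tpos.begin(), res.tpos.end());
  }
  return res;
}

static std::vector<int8_t> pair_codes(const IntegerVector &q,
                                      const IntegerVector &t, bool allow_gu) {
  std::vector<int8_t> pc((size_t)q.size() * t.size());
  for (int i = 0; i < q.size(); ++i)
    for (int j = 0; j < t.size(); ++j)
      pc[(size_t)i * t.size() + j] = (int8_t)pair_index(q[i], t[j], allow_gu);
  return pc;
}

// [[Rcpp::export(name = ".duplex_mfe_cpp")]]
List duplex_mfe_cpp(IntegerVector query, IntegerVector target,
                    NumericMatrix stacks, double bulge_open, double bulge_ext,
                    double internal_open, double internal_ext,
                    int max_bulge, int max_internal, bool allow_gu) {
  DuplexModel mod(stacks, bulge_open, bulge_ext, internal_open, internal_ext,
                  max_bulge, max_internal, allow_gu);
  std::vector<int8_t> pc = pair_codes(query, target, allow_gu);
  DuplexResult r = duplex_dp(pc.data(), query.size(), target.size(), 0,
                             target.size(), mod);
  return List::create(_["mfe"] = r.mfe,
                      _["qpos"] = IntegerVector(r.qpos.begin(), r.qpos.end()),
                      _["tpos"] = IntegerVector(r.tpos.begin(), r.tpos.end()));
}

// Slide fixed-size windows along the target and keep the minimum-energy
// hit (first window wins ties). Window starts are 0-based multiples of
// `step`, with a final window flushed to the target end.
// [[Rcpp::export(name = ".scan_duplex_cpp")]]
List scan_duplex_cpp(IntegerVector query, IntegerVector target, int window,
                     int step, NumericMatrix stacks, double bulge_open,
                     double bulge_ext, double internal_open,
                     double internal_ext, int max_bulge, int max_internal,
                     bool allow_gu) {
  const int n = query.size(), m = target.size();
  DuplexModel mod(stacks, bulge_open, bulge_ext, internal_open, internal_ext,
                  max_bulge, max_internal, allow_gu);
  if (window > m) window = m;
  if (step < 1) step = 1;
  std::vector<int8_t> pc = pair_codes(query, target, allow_gu);

  double best = 1.0; // any real hit is <= 0
  int best_start = 0;
  DuplexResult best_res;
  bool done_last = false;
  for (int s = 0; ; s += step) {
    if (s + window >= m) { s = m - window; done_last = true; }
    DuplexResult r = duplex_dp(pc.data(), n, m, s, window, mod);
    if (r.mfe < best) { best = r.mfe; best_start = s; best_res = r; }
    if (done_last) break;
  }
  if (best > 0) { best = 0.0; best_res.qpos.clear(); best_res.tpos.clear(); }
  // lift window coordinates to the transcript
  IntegerVector tpos(best_res.tpos.size());
  for (size_t k = 0; k < best_res.tpos.size(); ++k)
    tpos[k] = best_res.tpos[k] + best_start;
  return List::create(_["mfe"] = best, _["window_start"] = best_start,
                      _["qpos"] = IntegerVector(best_res.qpos.begin(),
                                                best_res.qpos.end()),
                      _["tpos"] = tpos);
}
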