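#include <Rcpp.h>
#include <vector>
#include <string>
#include <cstring>
using namespace Rcpp;

// Deterministic bundled folding engine: weighted maximum base-pairing
// (Nussinov-style O(n^3) DP) with a helix-initiation penalty charged once
// at the outermost pair of every helix.  Pair energies (kcal/mol): GC -3,
// AU -2, GU -1; minimum hairpin loop 3 nt.  The initiation penalty is what
// keeps shuffled sequence from accumulating arbitrarily many short spurious
// helices, so that the MFEI of non-hairpin sequence stays low.  Energies are
// engine-relative, not ViennaRNA-comparable; the engine is deterministic
// (fixed tie-breaking) so results are byte-stable across runs.

static const double INF = 1e18;

static inline double pair_energy(char a, char b, double eGC, double eAU,
                                 double eGU) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return eGC;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return eAU;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return eGU;
  return INF;
}

struct FoldDP {
  int n;
  int minloop;
  double pinit;
  const std::string &s;
  double eGC, eAU, eGU;
  std::vector<double> H; // H[i*n+j]: min energy of [i,j] with (i,j) paired,
                         // initiation of the enclosing helix not yet charged
  std::vector<double> M; // M[i*n+j]: min energy of [i,j], unconstrained

  FoldDP(const std::string &seq, int minloop_, double pinit_, double eGC_,
         double eAU_, double eGU_)
      : n((int)seq.size()), minloop(minloop_), pinit(pinit_), s(seq),
        eGC(eGC_), eAU(eAU_), eGU(eGU_), H((size_t)n * n, INF),
        M((size_t)n * n, 0.0) {}

  inline double h(int i, int j) const {
    return (i < 0 || j >= n || i >= j) ? INF : H[(size_t)i * n + j];
  }
  inline double m(int i, int j) const {
    return (i > j || i < 0 || j >= n) ? 0.0 : M[(size_t)i * n + j];
  }

  void run() {
    for (int len = minloop + 2; len <= n; ++len) {
      for (int i = 0; i + len - 1 < n; ++i) {
        int j = i + len - 1;
        double e = pair_energy(s[i], s[j], eGC, eAU, eGU);
        if (e < INF / 2) {
          // (i,j) paired: either stacks on (i+1,j-1) within the same helix,
          // or closes this helix over a general inner structure
          double best = m(i + 1, j - 1);
          double hs = h(i + 1, j - 1);
          if (hs < best) best = hs;
          H[(size_t)i * n + j] = e + best;
        }
        // unconstrained: j unpaired, or j paired to some k starting a helix
        double best = m(i, j - 1);
        for (int k = i; k <= j - minloop - 1; ++k) {
          double hk = h(k, j);
          if (hk >= INF / 2) continue;
          double cand = m(i, k - 1) + hk + pinit;
          if (cand < best) best = cand;
        }
        M[(size_t)i * n + j] = best;
      }
    }
  }

  // traceback: deterministic, mirrors the recurrences with fixed preference
  void trace(std::string &db) {
    db.assign(n, '.');
    std::vector<std::pair<std::pair<int, int>, int>> stack; // ((i,j), inH)
    if (n > 0) stack.push_back({{0, n - 1}, 0});
    const double eps = 1e-9;
    while (!stack.empty()) {
      auto top = stack.back();
      stack.pop_back();
      int i = top.first.first, j = top.first.second, inH = top.second;
      if (i >= j) continue;
      if (inH) {
        db[i] = '(';
        db[j] = ')';
        double e = pair_energy(s[i], s[j], eGC, eAU, eGU);
        double target = h(i, j) - e;
        if (h(i + 1, j - 1) < INF / 2 &&
            std::abs(h(i + 1, j - 1) - target) < eps) {
          stack.push_back({{i + 1, j - 1}, 1});
        } else {
          stack.push_back({{i + 1, j - 1}, 0});
        }
      } else {
        double target = m(i, j);
        if (std::abs(m(i, j - 1) - target) < eps) {
          stack.push_back({{i, j - 1}, 0});
          continue;
        }
        bool done = false;
        for (int k = i; k <= j - minloop - 1 && !done; ++k) {
          double hk = h(k, j);
          if (hk >= INF / 2) continue;
          if (std::abs(m(i, k - 1) + hk + pinit - target) < eps) {
            stack.push_back({{i, k - 1}, 0});
            stack.push_back({{k, j}, 1});
            done = true;
          }
        }
        if (!done) stack.push_back({{i, j - 1}, 0}); // numerical fallback
      }
    }
  }
};

// [[Rcpp::export(name = ".fold_engine_cpp")]]
List fold_engine_cpp(std::string seq, int minloop, double pinit, double eGC,
                     double eAU, double eGU) {
  int n = (int)seq.size();
  for (int i = 0; i < n; ++i) {
    char c = seq[i];
    if (c == 'T') seq[i] = 'U';
    else if (c == 't') seq[i] = 'U';
    else if (c >= 'a' && c <= 'z') seq[i] = c - 32;
  }
  if (n == 0)
    return List::create(_["structure"] = "", _["dG"] = 0.0);
  FoldDP dp(seq, minloop, pinit, eGC, eAU, eGU);
  dp.run();
  double e = dp.m(0, n - 1);
  if (e > 0) { // an empty structure is always available at 0
    e = 0.0;
  }
  std::string db;
  if (e < 0) {
    dp.trace(db);
  } else {
    db.assign(n, '.');
  }
  return List::create(_["structure"] = db, _["dG"] = e);
}

// Ungapped Hamming-distance scan of each tag against one reference strand.
// Returns all placements with at most max_mm mismatches.
// [[Rcpp::export(name = ".hamming_scan_cpp")]]
DataFrame hamming_scan_cpp(CharacterVector tags, std::string ref, int max_mm) {
  std::vector<int> tag_idx, offset, mm_out;
  int L = (int)ref.size();
  for (int t = 0; t < tags.size(); ++t) {
    std::string tag = as<std::string>(tags[t]);
    int m = (int)tag.size();
    for (int off = 0; off + m <= L; ++off) {
      int mm = 0;
      for (int k = 0; k < m; ++k) {
        if (tag[k] != ref[off + k]) {
          if (++mm > max_mm) break;
        }
      }
      if (mm <= max_mm) {
        tag_idx.push_back(t + 1);
        offset.push_back(off);
        mm_out.push_back(mm);
      }
    }
  }
  return DataFrame::create(_["tag"] = tag_idx, _["offset"] = offset,
                           _["mismatches"] = mm_out);
}
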