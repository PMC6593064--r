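// Zuker-style minimum-free-energy folding, constrained folding, and
// intermolecular duplex hybridization under a nearest-neighbor model.
//
// Bases are encoded A=0, C=1, G=2, U=3. Legal pairs are Watson-Crick plus
// G:U wobble. Energy semantics (shared with the R structure evaluator):
//  - helix stack between (i,j) and (i+1,j-1): tabulated stack energy;
//  - hairpin closed by (i,j): hairpin(size) + AU-end(i,j);
//  - bulge/internal loop: loop(size) + AU-end on both flanking pairs;
//  - multiloop with h branches, u unpaired: a + b*(h+1) + c*u, plus
//    AU-end on the closing pair and on every branch pair;
//  - exterior loop: AU-end on every external-facing helix end.
// The AU-end penalty applies to AU, UA, GU and UG pairs only.

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

static inline bool can_pair(int a, int b) {
  // a+b==3 covers {A,U} and {C,G}; a+b==5 covers the G:U wobble
  int s = a + b;
  return s == 3 || s == 5;
}

struct Model {
  const double *stack;     // 256 entries, index ((i*4+j)*4+ip)*4+jm
  const double *hp, *bu, *il;
  int nhp, nbu, nil;
  double ml_a, ml_b, ml_c, au_end, duplex_init;
  int max_loop;

  double stack_e(int bi, int bj, int bip, int bjm) const {
    return stack[((bi * 4 + bj) * 4 + bip) * 4 + bjm];
  }
  double hairpin(int s) const {
    if (s < 1) return INF;
    return s <= nhp ? hp[s - 1] : hp[nhp - 1];
  }
  double bulge_e(int s) const { return s <= nbu ? bu[s - 1] : bu[nbu - 1]; }
  double internal_e(int s) const { return s <= nil ? il[s - 1] : il[nil - 1]; }
  double au(int a, int b) const {
    return ((a == 0 && b == 3) || (a == 3 && b == 0) ||
            (a == 2 && b == 3) || (a == 3 && b == 2)) ? au_end : 0.0;
  }
};

class Folder {
public:
  Folder(const std::vector<int> &seq, const std::vector<bool> &blocked,
         const Model &md) : s(seq), blk(blocked), m(md), n((int)seq.size()) {
    V.assign(n * n, INF);
    WM.assign(n * n, INF);
  }

  // fill V and WM bottom-up, then the exterior array W
  void run() {
    for (int d = 4; d < n; ++d) {          // minimal span for a pair: d>=4
      for (int i = 0; i + d < n; ++i) {
        int j = i + d;
        computeV(i, j);
        computeWM(i, j);
      }
    }
    // shorter spans of WM stay +Inf (no branch fits); exterior pass:
    W.assign(n + 1, 0.0);
    for (int j = 0; j < n; ++j) {
      double best = W[j];                  // j unpaired (preferred on ties)
      for (int k = 0; k + 4 <= j; ++k) {
        double v = getV(k, j);
        if (v < INF) {
          double cand = (k > 0 ? W[k] : 0.0) + v + m.au(s[k], s[j]);
          if (cand < best) best = cand;
        }
      }
      W[j + 1] = best;
    }
  }

  double mfe() const { return n > 0 ? W[n] : 0.0; }

  // traceback into a pairing vector (partner index or -1)
  std::vector<int> traceback() const {
    std::vector<int> pr(n, -1);
    tbW(n - 1, pr);
    return pr;
  }

private:
  const std::vector<int> &s;
  const std::vector<bool> &blk;
  const Model &m;
  int n;
  std::vector<double> V, WM, W;

  double getV(int i, int j) const {
    return (j - i >= 4) ? V[i * n + j] : INF;
  }
  double getWM(int p, int q) const {
    return (q >= p && q - p >= 4) ? WM[p * n + q] : INF;
  }
  bool pairable(int i, int j) const {
    return !blk[i] && !blk[j] && can_pair(s[i], s[j]);
  }
  // branch term inside a multiloop
  double vb(int a, int b) const {
    double v = getV(a, b);
    return v < INF ? v + m.ml_b + m.au(s[a], s[b]) : INF;
  }

  void computeV(int i, int j) {
    if (!pairable(i, j)) return;
    double aup = m.au(s[i], s[j]);
    // hairpin (checked first: fewest pairs wins ties)
    double best = m.hairpin(j - i - 1) + aup;
    // stack / bulge / internal: inner pair (k,l)
    int kmax = std::min(j - 5, i + 1 + m.max_loop);
    for (int k = i + 1; k <= kmax; ++k) {
      int s1 = k - i - 1;
      int lmin = std::max(k + 4, j - 1 - (m.max_loop - s1));
      for (int l = j - 1; l >= lmin; --l) {
        double v = getV(k, l);
        if (v >= INF) continue;
        int s2 = j - l - 1;
        double e;
        if (s1 == 0 && s2 == 0)
          e = m.stack_e(s[i], s[j], s[k], s[l]);
        else {
          double lp = (s1 == 0 || s2 == 0) ? m.bulge_e(s1 + s2)
                                           : m.internal_e(s1 + s2);
          e = lp + aup + m.au(s[k], s[l]);
        }
        if (e + v < best) best = e + v;
      }
    }
    // multiloop: closing (i,j), interior [i+1, j-1] with >= 2 branches
    int p = i + 1, q = j - 1;
    for (int a = p; a + 4 <= q; ++a) {
      for (int b = a + 4; b <= q; ++b) {
        double first = vb(a, b);
        if (first >= INF) continue;
        double rest = getWM(b + 1, q);
        if (rest >= INF) continue;
        double cand = m.ml_a + m.ml_b + aup + m.ml_c * (a - p) + first + rest;
        if (cand < best) best = cand;
      }
    }
    V[i * n + j] = best;
  }

  void computeWM(int p, int q) {
    double best = getWM(p + 1, q);
    if (best < INF) best += m.ml_c;
    for (int l = p + 4; l <= q; ++l) {
      double br = vb(p, l);
      if (br >= INF) continue;
      double tail = m.ml_c * (q - l);            // all-unpaired tail first
      double wmr = getWM(l + 1, q);
      if (wmr < tail) tail = wmr;
      if (br + tail < best) best = br + tail;
    }
    WM[p * n + q] = best;
  }

  // --- traceback (re-derives each argmin in the same evaluation order) ---

  void tbW(int j, std::vector<int> &pr) const {
    if (j < 0) return;
    if (W[j + 1] == W[j]) { tbW(j - 1, pr); return; }
    for (int k = 0; k + 4 <= j; ++k) {
      double v = getV(k, j);
      if (v < INF &&
          W[j + 1] == (k > 0 ? W[k] : 0.0) + v + m.au(s[k], s[j])) {
        tbV(k, j, pr);
        tbW(k - 1, pr);
        return;
      }
    }
    Rcpp::stop("traceback failure in exterior loop");
  }

  void tbV(int i, int j, std::vector<int> &pr) const {
    pr[i] = j; pr[j] = i;
    double tgt = getV(i, j);
    double aup = m.au(s[i], s[j]);
    if (tgt == m.hairpin(j - i - 1) + aup) return;
    int kmax = std::min(j - 5, i + 1 + m.max_loop);
    for (int k = i + 1; k <= kmax; ++k) {
      int s1 = k - i - 1;
      int lmin = std::max(k + 4, j - 1 - (m.max_loop - s1));
      for (int l = j - 1; l >= lmin; --l) {
        double v = getV(k, l);
        if (v >= INF) continue;
        int s2 = j - l - 1;
        double e;
        if (s1 == 0 && s2 == 0)
          e = m.stack_e(s[i], s[j], s[k], s[l]);
        else {
          double lp = (s1 == 0 || s2 == 0) ? m.bulge_e(s1 + s2)
                                           : m.internal_e(s1 + s2);
          e = lp + aup + m.au(s[k], s[l]);
        }
        if (tgt == e + v) { tbV(k, l, pr); return; }
      }
    }
    int p = i + 1, q = j - 1;
    for (int a = p; a + 4 <= q; ++a) {
      for (int b = a + 4; b <= q; ++b) {
        double first = vb(a, b);
        if (first >= INF) continue;
        double rest = getWM(b + 1, q);
        if (rest >= INF) continue;
        if (tgt == m.ml_a + m.ml_b + aup + m.ml_c * (a - p) + first + rest) {
          tbV(a, b, pr);
          tbWM(b + 1, q, pr);
          return;
        }
      }
    }
    Rcpp::stop("traceback failure in V");
  }

  void tbWM(int p, int q, std::vector<int> &pr) const {
    double tgt = getWM(p, q);
    double up = getWM(p + 1, q);
    if (up < INF && tgt == up + m.ml_c) { tbWM(p + 1, q, pr); return; }
    for (int l = p + 4; l <= q; ++l) {
      double br = vb(p, l);
      if (br >= INF) continue;
      if (tgt == br + m.ml_c * (q - l)) { tbV(p, l, pr); return; }
      double wmr = getWM(l + 1, q);
      if (wmr < INF && tgt == br + wmr) {
        tbV(p, l, pr);
        tbWM(l + 1, q, pr);
        return;
      }
    }
    Rcpp::stop("traceback failure in WM");
  }
};

static Model build_model(const List &par) {
  static thread_local NumericVector st, hp, bu, il;   // keep storage alive
  st = par["stack_flat"]; hp = par["hairpin"];
  bu = par["bulge"]; il = par["internal"];
  Model m;
  m.stack = REAL(st); m.hp = REAL(hp); m.bu = REAL(bu); m.il = REAL(il);
  m.nhp = hp.size(); m.nbu = bu.size(); m.nil = il.size();
  m.ml_a = as<double>(par["ml_init"]);
  m.ml_b = as<double>(par["ml_branch"]);
  m.ml_c = as<double>(par["ml_unpaired"]);
  m.au_end = as<double>(par["au_end"]);
  m.duplex_init = as<double>(par["duplex_init"]);
  m.max_loop = as<int>(par["max_loop"]);
  return m;
}

// [[Rcpp::export]]
List c_mfe_fold(IntegerVector seq, LogicalVector forced_unpaired, List par) {
  int n = seq.size();
  std::vector<int> s(seq.begin(), seq.end());
  std::vector<bool> blk(n, false);
  if (forced_unpaired.size() == n)
    for (int i = 0; i < n; ++i) blk[i] = forced_unpaired[i];
  Model m = build_model(par);
  Folder f(s, blk, m);
  f.run();
  std::vector<int> pr = f.traceback();
  IntegerVector pairs(n);
  for (int i = 0; i < n; ++i) pairs[i] = pr[i];
  return List::create(_["energy"] = f.mfe(), _["pairs"] = pairs);
}

// RNAduplex-style hybridization between two strands (both 5'->3').
// A duplex is a chain of pairs (i_t on strand 1 increasing, j_t on strand 2
// decreasing); consecutive pairs are joined by a stack or a bulge/internal
// loop with each side capped at `loop_cap` unpaired bases. Total energy =
// duplex_init + steps + AU-end on both terminal pairs (loop-flanking pairs
// also carry the AU-end term, mirroring the intramolecular semantics).
// [[Rcpp::export]]
List c_duplex(IntegerVector seq1, IntegerVector seq2, List par, int loop_cap) {
  int n1 = seq1.size(), n2 = seq2.size();
  Model m = build_model(par);
  std::vector<double> D(n1 * n2, INF);
  std::vector<int> from(n1 * n2, -1);
  // D[i][j]: best duplex whose last pair (3'-most on strand 1) is (i,j);
  // includes init and the AU-end of the 5'-terminal pair, not of (i,j).
  for (int i = 0; i < n1; ++i) {
    for (int j = n2 - 1; j >= 0; --j) {
      if (!can_pair(seq1[i], seq2[j])) continue;
      double best = m.duplex_init + m.au(seq1[i], seq2[j]);   // first pair
      int bfrom = -1;
      for (int ip = std::max(0, i - 1 - loop_cap); ip < i; ++ip) {
        for (int jp = j + 1; jp <= std::min(n2 - 1, j + 1 + loop_cap); ++jp) {
          double prev = D[ip * n2 + jp];
          if (prev >= INF) continue;
          int g1 = i - ip - 1, g2 = jp - j - 1;
          double e;
          if (g1 == 0 && g2 == 0)
            e = m.stack_e(seq1[ip], seq2[jp], seq1[i], seq2[j]);
          else {
            double lp = (g1 == 0 || g2 == 0) ? m.bulge_e(g1 + g2)
                                             : m.internal_e(g1 + g2);
            e = lp + m.au(seq1[ip], seq2[jp]) + m.au(seq1[i], seq2[j]);
          }
          if (prev + e < best) { best = prev + e; bfrom = ip * n2 + jp; }
        }
      }
      D[i * n2 + j] = best;
      from[i * n2 + j] = bfrom;
    }
  }
  double best = 0.0;      // no binding scores 0
  int bi = -1, bj = -1;
  for (int i = 0; i < n1; ++i)
    for (int j = 0; j < n2; ++j) {
      double d = D[i * n2 + j];
      if (d < INF) {
        double tot = d + m.au(seq1[i], seq2[j]);   // 3'-terminal AU end
        if (tot < best) { best = tot; bi = i; bj = j; }
      }
    }
  std::vector<int> pi, pj;
  if (bi >= 0) {
    int cur = bi * n2 + bj;
    while (cur >= 0) {
      pi.push_back(cur / n2);
      pj.push_back(cur % n2);
      cur = from[cur];
    }
  }
  std::reverse(pi.begin(), pi.end());
  std::reverse(pj.begin(), pj.end());
  return List::create(_["energy"] = (bi >= 0 ? best : 0.0),
                      _["i"] = wrap(pi), _["j"] = wrap(pj));
}
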