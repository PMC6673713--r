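#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exhaustive enumeration of transition-valid nucleosome placements for one
// molecule. A path is parameterized by the ordered nucleosome start rows
// (1-based; starts <= 0 encode a nucleosome truncated at the molecule start,
// starts past l - 146 one truncated at the end), with at least one linker
// base between consecutive nucleosomes. Site emissions are added strictly in
// increasing site order so candidate log-likelihoods are bit-identical to the
// row-by-row sums of the dynamic-programming decoder.

namespace {

struct Enumerator {
  int l, n;
  const int *pos;           // 1-based site rows, ascending
  const double *lqP, *lqN;  // per-site log emissions (linker / nucleosome)
  double best_ll;
  bool has_best;
  std::vector<int> best_starts, cur_starts;
  std::vector<int> best_cols;  // incumbent path materialized per base
  // admissible completion bound: suffix sums of the per-site max emission.
  // Branches whose bound falls below the incumbent by more than a small
  // guard are provably suboptimal and are skipped; the guard keeps every
  // exact tie alive, so the argmax set and the tie-break are unaffected.
  std::vector<double> smax;
  static constexpr double kGuard = 1e-9;

  void init_bounds() {
    smax.assign(n + 1, 0.0);
    for (int t = n - 1; t >= 0; --t) {
      smax[t] = smax[t + 1] + std::max(lqP[t], lqN[t]);
    }
  }

  void cols_from_starts(const std::vector<int> &starts, std::vector<int> &cols) const {
    cols.assign(l, 1);
    for (int s : starts) {
      int lo = std::max(1, s), hi = std::min(l, s + 146);
      for (int r = lo; r <= hi; ++r) cols[r - 1] = r - s + 2;
    }
  }

  void take_current() {
    best_starts = cur_starts;
    cols_from_starts(best_starts, best_cols);
  }

  // ties resolve to the reverse-lexicographically smallest column sequence
  // (prefer linker, then lower nucleosome index, from the molecule end back);
  // the candidate's columns are derived lazily from its start list, walking
  // from the molecule end until the first difference decides
  void consider(double ll) {
    if (!has_best || ll > best_ll) {
      best_ll = ll;
      take_current();
      has_best = true;
      return;
    }
    if (ll != best_ll) return;
    int k = (int)cur_starts.size() - 1;
    for (int r = l; r >= 1; --r) {  // r: 1-based row
      while (k >= 0 && r < cur_starts[k]) --k;
      int col = 1;
      if (k >= 0 && r <= cur_starts[k] + 146) col = r - cur_starts[k] + 2;
      int bcol = best_cols[r - 1];
      if (col != bcol) {
        if (col < bcol) take_current();
        return;
      }
    }
  }

  // min_start: smallest admissible next nucleosome start row;
  // site_from: first site not yet labeled; ll: ordered sum so far
  void rec(int min_start, int site_from, double ll) {
    double ll_end = ll;
    for (int t = site_from; t < n; ++t) ll_end += lqP[t];
    consider(ll_end);  // no further nucleosome: remainder is linker

    double ll_lin = ll;
    int t = site_from;
    for (int p = min_start; p <= l; ++p) {
      while (t < n && pos[t] < p) ll_lin += lqP[t++];  // linker gap before p
      int hi = std::min(l, p + 146);
      double ll2 = ll_lin;
      int t2 = t;
      while (t2 < n && pos[t2] <= hi) ll2 += lqN[t2++];
      if (has_best && ll2 + smax[t2] < best_ll - kGuard) continue;
      cur_starts.push_back(p);
      if (p + 146 >= l) {
        consider(ll2);  // nucleosome reaches the molecule end
      } else {
        rec(p + 148, t2, ll2);  // >=1 linker base after a complete nucleosome
      }
      cur_starts.pop_back();
    }
  }
};

}  // namespace

// [[Rcpp::export]]
List bf_decode_cpp(int l, IntegerVector site_pos, NumericVector lqP,
                   NumericVector lqN) {
  int n = site_pos.size();
  if (n != lqP.size() || n != lqN.size()) stop("emission length mismatch");
  if (l < 1) stop("molecule length must be >= 1");
  Enumerator e;
  e.l = l;
  e.n = n;
  e.pos = INTEGER(site_pos);
  e.lqP = REAL(lqP);
  e.lqN = REAL(lqN);
  e.best_ll = R_NegInf;
  e.has_best = false;
  e.init_bounds();
  e.rec(-145, 0, 0.0);  // first nucleosome may overhang the start (state N_147 at row 1)
  return List::create(
      _["cols"] = IntegerVector(e.best_cols.begin(), e.best_cols.end()),
      _["log_likelihood"] = e.best_ll);
}
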