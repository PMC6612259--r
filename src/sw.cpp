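#include <Rcpp.h>
using namespace Rcpp;

// Local pairwise alignment with affine gaps (Smith-Waterman / Gotoh).
//
// Sequences arrive as 1-based indices into the scoring matrix S. A gap of
// length k costs gap_open + (k - 1) * gap_extend (both negative).
//
// Among all cells attaining the maximal score, the traceback yielding the
// longest aligned span is returned; remaining ties break to the smallest
// start in `a`, then in `b`. Within one traceback, ambiguity resolves
// diagonal > vertical > horizontal.

struct Trace {
  int start_a, start_b, end_a, end_b;
  std::vector<int> col_a, col_b; // 1-based residue index, 0 = gap
};

// [[Rcpp::export]]
List sw_align_cpp(IntegerVector a, IntegerVector b, NumericMatrix S,
                  double gap_open, double gap_extend) {
  const int m = a.size(), n = b.size();
  const double NEG = -1e18;
  std::vector<double> H((size_t)(m + 1) * (n + 1), 0.0);
  std::vector<double> E((size_t)(m + 1) * (n + 1), NEG);
  std::vector<double> F((size_t)(m + 1) * (n + 1), NEG);
  const size_t W = n + 1;
  double best = 0.0;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const size_t k = (size_t)i * W + j;
      const double e = std::max(H[k - 1] + gap_open, E[k - 1] + gap_extend);
      const double f = std::max(H[k - W] + gap_open, F[k - W] + gap_extend);
      double h = H[k - W - 1] + S(a[i - 1] - 1, b[j - 1] - 1);
      h = std::max(h, std::max(e, f));
      h = std::max(h, 0.0);
      E[k] = e; F[k] = f; H[k] = h;
      if (h > best) best = h;
    }
  }

  List out;
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["start_a"] = 0, _["end_a"] = 0,
                        _["start_b"] = 0, _["end_b"] = 0,
                        _["col_a"] = IntegerVector(0),
                        _["col_b"] = IntegerVector(0));
  }

  Trace bestTr;
  bool have = false;
  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      if (H[(size_t)i * W + j] != best) continue;
      Trace tr;
      tr.end_a = i; tr.end_b = j;
      int ci = i, cj = j;
      char state = 'H';
      while (true) {
        const size_t k = (size_t)ci * W + cj;
        if (state == 'H') {
          if (H[k] == 0.0) break;
          const double s = S(a[ci - 1] - 1, b[cj - 1] - 1);
          if (ci >= 1 && cj >= 1 && H[k] == H[k - W - 1] + s) {
            tr.col_a.push_back(ci); tr.col_b.push_back(cj);
            --ci; --cj;
          } else if (H[k] == F[k]) {
            state = 'F';
          } else {
            state = 'E';
          }
        } else if (state == 'F') { // gap in b, consume a
          tr.col_a.push_back(ci); tr.col_b.push_back(0);
          if (F[k] == H[k - W] + gap_open) { --ci; state = 'H'; }
          else { --ci; }
        } else { // 'E': gap in a, consume b
          tr.col_a.push_back(0); tr.col_b.push_back(cj);
          if (E[k] == H[k - 1] + gap_open) { --cj; state = 'H'; }
          else { --cj; }
        }
      }
      tr.start_a = ci + 1; tr.start_b = cj + 1;
      std::reverse(tr.col_a.begin(), tr.col_a.end());
      std::reverse(tr.col_b.begin(), tr.col_b.end());
      const bool better = !have ||
        tr.col_a.size() > bestTr.col_a.size() ||
        (tr.col_a.size() == bestTr.col_a.size() &&
         (tr.start_a < bestTr.start_a ||
          (tr.start_a == bestTr.start_a && tr.start_b < bestTr.start_b)));
      if (better) { bestTr = tr; have = true; }
    }
  }

  return List::create(_["score"] = best,
                      _["start_a"] = bestTr.start_a, _["end_a"] = bestTr.end_a,
                      _["start_b"] = bestTr.start_b, _["end_b"] = bestTr.end_b,
                      _["col_a"] = wrap(bestTr.col_a),
                      _["col_b"] = wrap(bestTr.col_b));
}
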