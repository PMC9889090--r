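#include <Rcpp.h>
#include <vector>
#include <string>
#include <cctype>
using namespace Rcpp;

// Scores are doubled to integers internally so that half-unit gap-extension
// penalties (the EMBOSS Water DNA default of 0.5) never hit float comparisons.
// Gap convention (Water): a gap of length L costs open + (L-1) * ext.

namespace {

inline int subst(char x, char y, int match2, int mismatch2) {
  // N never matches anything, including another N
  if (x == 'N' || y == 'N') return mismatch2;
  return (x == y) ? match2 : mismatch2;
}

std::string upper(const std::string& s) {
  std::string r(s);
  for (char& c : r) c = std::toupper(static_cast<unsigned char>(c));
  return r;
}

inline int dbl_score(double x, const char* what) {
  double t = x * 2.0;
  int ti = static_cast<int>(std::lround(t));
  if (std::abs(t - ti) > 1e-9)
    stop("%s must be a multiple of 0.5 (got %f)", what, x);
  return ti;
}

} // namespace

// Optimal local alignment (Smith-Waterman, affine gaps).
// Returns score and per-column positions (1-based; NA at a gap).
// Traceback tie-break: diagonal, then up (gap in b), then left (gap in a);
// the start cell is the highest-scoring one at smallest (i, j) lexicographic.
// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string a, std::string b,
                  double match, double mismatch,
                  double gap_open, double gap_extend) {
  a = upper(a); b = upper(b);
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0) stop("sequences must be non-empty");
  const int ms2 = dbl_score(match, "match");
  const int mm2 = dbl_score(mismatch, "mismatch");
  const int go2 = dbl_score(gap_open, "gap_open");
  const int ge2 = dbl_score(gap_extend, "gap_extend");
  const int NEG = INT_MIN / 4;

  // M: column aligns a[i] with b[j]; X: gap in b (consumes a); Y: gap in a
  std::vector<int> M((n + 1) * (m + 1), 0), X((n + 1) * (m + 1), NEG),
      Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int dprev = std::max(std::max(M[at(i - 1, j - 1)], X[at(i - 1, j - 1)]),
                           std::max(Y[at(i - 1, j - 1)], 0));
      M[at(i, j)] = dprev + subst(a[i - 1], b[j - 1], ms2, mm2);
      X[at(i, j)] = std::max(std::max(M[at(i - 1, j)] - go2,
                                      Y[at(i - 1, j)] - go2),
                             X[at(i - 1, j)] - ge2);
      Y[at(i, j)] = std::max(std::max(M[at(i, j - 1)] - go2,
                                      X[at(i, j - 1)] - go2),
                             Y[at(i, j - 1)] - ge2);
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  std::vector<int> apos, bpos; // reversed during traceback
  if (best > 0) {
    int i = bi, j = bj, state = 0; // 0 = M, 1 = X, 2 = Y
    while (true) {
      if ((state == 0 && (i < 1 || j < 1)) || (state == 1 && i < 1) ||
          (state == 2 && j < 1)) break; // zero-cost gap pathologies
      if (state == 0) {
        apos.push_back(i); bpos.push_back(j);
        int here = M[at(i, j)];
        int s = subst(a[i - 1], b[j - 1], ms2, mm2);
        int prev = here - s;
        if (prev <= 0 ||
            (M[at(i - 1, j - 1)] < prev && X[at(i - 1, j - 1)] < prev &&
             Y[at(i - 1, j - 1)] < prev)) break; // local start
        if (M[at(i - 1, j - 1)] == prev) state = 0;
        else if (X[at(i - 1, j - 1)] == prev) state = 1;
        else state = 2;
        --i; --j;
      } else if (state == 1) {
        apos.push_back(i); bpos.push_back(NA_INTEGER);
        int here = X[at(i, j)];
        if (M[at(i - 1, j)] - go2 == here) state = 0;
        else if (X[at(i - 1, j)] - ge2 == here) state = 1;
        else state = 2;
        --i;
      } else {
        apos.push_back(NA_INTEGER); bpos.push_back(j);
        int here = Y[at(i, j)];
        if (M[at(i, j - 1)] - go2 == here) state = 0;
        else if (X[at(i, j - 1)] - go2 == here) state = 1;
        else state = 2;
        --j;
      }
    }
    std::reverse(apos.begin(), apos.end());
    std::reverse(bpos.begin(), bpos.end());
  }

  return List::create(_["score"] = best / 2.0,
                      _["a_pos"] = IntegerVector(apos.begin(), apos.end()),
                      _["b_pos"] = IntegerVector(bpos.begin(), bpos.end()));
}

namespace {

struct Enum {
  const std::string *a, *b;
  int n, m, ms2, mm2, go2, ge2, best;

  inline int gapcost(int g) const { return g > 0 ? go2 + (g - 1) * ge2 : 0; }

  // extend a chain whose last matched pair is (i, j) [1-based], score so far sc
  void dfs(int i, int j, int sc) {
    if (sc > best) best = sc;
    int left = std::min(n - i, m - j);
    if (left <= 0) return;
    if (sc + left * ms2 <= best) return; // bound: every future column <= match
    for (int i2 = i + 1; i2 <= n; ++i2) {
      for (int j2 = j + 1; j2 <= m; ++j2) {
        int s = sc - gapcost(i2 - i - 1) - gapcost(j2 - j - 1) +
                subst((*a)[i2 - 1], (*b)[j2 - 1], ms2, mm2);
        dfs(i2, j2, s);
      }
    }
  }
};

} // namespace

// Brute-force oracle: exhaustively enumerates every gapped local alignment
// as an increasing chain of matched column pairs (gap runs between
// consecutive pairs costed with the same affine convention) and returns the
// maximum score. Exponential; intended for sequences of ~12 nt or fewer.
// [[Rcpp::export(name = ".sw_enumerate_cpp")]]
double sw_enumerate_cpp(std::string a, std::string b,
                        double match, double mismatch,
                        double gap_open, double gap_extend) {
  a = upper(a); b = upper(b);
  Enum e;
  e.a = &a; e.b = &b; e.n = a.size(); e.m = b.size();
  e.ms2 = dbl_score(match, "match");
  e.mm2 = dbl_score(mismatch, "mismatch");
  e.go2 = dbl_score(gap_open, "gap_open");
  e.ge2 = dbl_score(gap_extend, "gap_extend");
  e.best = 0;
  for (int i = 1; i <= e.n; ++i)
    for (int j = 1; j <= e.m; ++j)
      e.dfs(i, j, subst(a[i - 1], b[j - 1], e.ms2, e.mm2));
  return e.best / 2.0;
}
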