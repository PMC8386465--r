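#include <Rcpp.h>
#include <cctype>
using namespace Rcpp;

// Alignment characters: A,C,G,T,U,N plus '-' and '.' as gaps.  Comparison is
// case-insensitive and treats U as T; N is compared literally (N != A, N == N).
static inline char norm_base(char c) {
  c = std::toupper(static_cast<unsigned char>(c));
  if (c == 'U') return 'T';
  if (c == '.') return '-';
  return c;
}

// mode: 1 = each-gap-a-difference, 2 = gap-run-single-difference,
//       3 = ignore-gap-columns.
// Columns where both sequences have gaps are never counted.  With
// count_terminal = false the comparison is restricted to the columns between
// the first and last positions where BOTH sequences carry a base.  A pair
// with no comparable units is maximally distant (1.0).
static double pair_dist(const std::string& a, const std::string& b,
                        int mode, bool count_terminal) {
  const int L = static_cast<int>(a.size());
  int start = 0, end = L - 1;
  if (!count_terminal) {
    while (start < L &&
           (norm_base(a[start]) == '-' || norm_base(b[start]) == '-')) ++start;
    while (end >= start &&
           (norm_base(a[end]) == '-' || norm_base(b[end]) == '-')) --end;
  }
  long units = 0, diffs = 0;
  int run = 0;  // 0 none, 1 gap run in a, 2 gap run in b
  for (int i = start; i <= end; ++i) {
    const char ca = norm_base(a[i]), cb = norm_base(b[i]);
    const bool ga = (ca == '-'), gb = (cb == '-');
    if (ga && gb) continue;  // both-gap column: skipped, run state kept
    if (!ga && !gb) {
      ++units;
      if (ca != cb) ++diffs;
      run = 0;
    } else if (mode == 3) {
      run = 0;
    } else if (mode == 1) {
      ++units;
      ++diffs;
      run = 0;
    } else {  // mode 2: a maximal one-sided gap run is one unit, one difference
      const int cur = ga ? 1 : 2;
      if (run != cur) {
        ++units;
        ++diffs;
        run = cur;
      }
    }
  }
  if (units == 0) return 1.0;
  return static_cast<double>(diffs) / static_cast<double>(units);
}

// [[Rcpp::export]]
double dist_pair_cpp(std::string a, std::string b, int mode, bool count_terminal) {
  if (a.size() != b.size())
    stop("aligned sequences have different lengths (%d vs %d)",
         (int)a.size(), (int)b.size());
  return pair_dist(a, b, mode, count_terminal);
}

// Sparse all-vs-all: every unordered pair (i < j) with distance <= d_max
// (inclusive, with a small tolerance so ties at the cutoff are kept).
// [[Rcpp::export]]
List neighbor_pairs_cpp(CharacterVector seqs, double d_max, int mode,
                        bool count_terminal) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 1; i < n; ++i)
    if (s[i].size() != s[0].size())
      stop("aligned sequences have different lengths");
  std::vector<int> ii, jj;
  std::vector<double> dd;
  const double cut = d_max + 1e-12;
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = pair_dist(s[i], s[j], mode, count_terminal);
      if (d <= cut) {
        ii.push_back(i + 1);
        jj.push_back(j + 1);
        dd.push_back(d);
      }
    }
  }
  return List::create(_["i"] = wrap(ii), _["j"] = wrap(jj),
                      _["distance"] = wrap(dd));
}

// Dense matrix, for small inputs and the furthest-neighbor oracle.
// [[Rcpp::export]]
NumericMatrix dist_matrix_cpp(CharacterVector seqs, int mode, bool count_terminal) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  for (int i = 1; i < n; ++i)
    if (s[i].size() != s[0].size())
      stop("aligned sequences have different lengths");
  NumericMatrix m(n, n);
  for (int i = 0; i < n - 1; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double d = pair_dist(s[i], s[j], mode, count_terminal);
      m(i, j) = d;
      m(j, i) = d;
    }
  }
  return m;
}
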