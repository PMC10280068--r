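#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Gotoh global alignment with affine gaps. A gap of length k costs
// gapOpen + (k-1)*gapExtend. Traceback is deterministic: ties prefer the
// substitution state over either gap state, and gap runs are extended in the
// backward pass so that gaps land leftmost in the forward sequence.
//
// States: M = a[i-1] paired with b[j-1]; X = gap in b (a base over '-');
// Y = gap in a.
// [[Rcpp::export(name = ".nwAlign")]]
List nwAlign(std::string a, std::string b,
             double match = 1.0, double mismatch = -1.0,
             double gapOpen = -4.0, double gapExtend = -1.0) {
  const int n = a.size(), m = b.size();
  const double NEG = -1e18;
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) X[at(i, 0)] = gapOpen + (i - 1) * gapExtend;
  for (int j = 1; j <= m; ++j) Y[at(0, j)] = gapOpen + (j - 1) * gapExtend;

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double dm = std::max(M[at(i - 1, j - 1)],
                  std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = dm + s;
      X[at(i, j)] = std::max(X[at(i - 1, j)] + gapExtend,
                    std::max(M[at(i - 1, j)] + gapOpen,
                             Y[at(i - 1, j)] + gapOpen));
      Y[at(i, j)] = std::max(Y[at(i, j - 1)] + gapExtend,
                    std::max(M[at(i, j - 1)] + gapOpen,
                             X[at(i, j - 1)] + gapOpen));
    }
  }

  double best = std::max(M[at(n, m)], std::max(X[at(n, m)], Y[at(n, m)]));
  int state;  // 0 = M, 1 = X, 2 = Y; preference M > X > Y on ties
  if (M[at(n, m)] >= best) state = 0;
  else if (X[at(n, m)] >= best) state = 1;
  else state = 2;

  std::string ra, rb;
  ra.reserve(n + m);
  rb.reserve(n + m);
  int i = n, j = m;
  const double eps = 1e-9;
  while (i > 0 || j > 0) {
    if (state == 0) {
      if (i == 0 || j == 0) Rcpp::stop("traceback error in M state");
      ra.push_back(a[i - 1]);
      rb.push_back(b[j - 1]);
      double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      double target = M[at(i, j)] - s;
      --i; --j;
      if (i == 0 && j == 0) break;
      if (std::abs(M[at(i, j)] - target) < eps) state = 0;
      else if (std::abs(X[at(i, j)] - target) < eps) state = 1;
      else state = 2;
    } else if (state == 1) {
      if (i == 0) Rcpp::stop("traceback error in X state");
      ra.push_back(a[i - 1]);
      rb.push_back('-');
      double target = X[at(i, j)];
      --i;
      // prefer continuing the gap run (pushes it leftmost), then M, then Y
      if (i > 0 && std::abs(X[at(i, j)] + gapExtend - target) < eps) state = 1;
      else if (std::abs(M[at(i, j)] + gapOpen - target) < eps) state = 0;
      else state = 2;
    } else {
      if (j == 0) Rcpp::stop("traceback error in Y state");
      ra.push_back('-');
      rb.push_back(b[j - 1]);
      double target = Y[at(i, j)];
      --j;
      if (j > 0 && std::abs(Y[at(i, j)] + gapExtend - target) < eps) state = 2;
      else if (std::abs(M[at(i, j)] + gapOpen - target) < eps) state = 0;
      else state = 1;
    }
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(rb.begin(), rb.end());
  return List::create(_["a"] = ra, _["b"] = rb, _["score"] = best);
}

// Two-parent chimera scan over dereplicated sequences sorted by count
// descending. A candidate is flagged iff two distinct equal-length parents A
// and B exist, each with count >= parentFactor * candidate count, and a
// breakpoint b in [1, L-1] such that candidate[0:b] == A[0:b] and
// candidate[b:L] == B[b:L]. Only the top maxParents eligible parents (by
// abundance rank) are examined per candidate.
// [[Rcpp::export(name = ".chimeraScan")]]
LogicalVector chimeraScan(CharacterVector seqs, IntegerVector counts,
                          double parentFactor = 2.0, int maxParents = 32) {
  const int M = seqs.size();
  std::vector<std::string> ss(M);
  for (int i = 0; i < M; ++i) ss[i] = as<std::string>(seqs[i]);
  LogicalVector flag(M, false);

  for (int i = 1; i < M; ++i) {  // rank-1 sequence can have no eligible parent
    const std::string &cand = ss[i];
    const int L = cand.size();
    if (L < 2) continue;
    double need = parentFactor * counts[i];
    // best prefix/suffix match lengths over eligible parents, with top-2
    // bookkeeping so the two parents can be required to be distinct
    int p1 = 0, p1id = -1, p2 = 0;  // longest and second-longest common prefix
    int s1 = 0, s1id = -1, s2 = 0;  // longest and second-longest common suffix
    int used = 0;
    for (int j = 0; j < M && used < maxParents; ++j) {
      if (j == i) continue;
      if (counts[j] < need) break;  // sorted by count descending
      if ((int)ss[j].size() != L) continue;
      ++used;
      const std::string &par = ss[j];
      int p = 0;
      while (p < L && cand[p] == par[p]) ++p;
      int s = 0;
      while (s < L && cand[L - 1 - s] == par[L - 1 - s]) ++s;
      if (p > p1) { p2 = p1; p1 = p; p1id = j; }
      else if (p > p2) p2 = p;
      if (s > s1) { s2 = s1; s1 = s; s1id = j; }
      else if (s > s2) s2 = s;
    }
    if (used < 2) continue;
    // max over distinct pairs of prefix(A) + suffix(B); both sides >= 1
    int bestPair = 0;
    if (p1id != s1id) bestPair = p1 + s1;
    else bestPair = std::max(p1 + s2, p2 + s1);
    if (p1 >= 1 && s1 >= 1 && bestPair >= L) flag[i] = true;
  }
  return flag;
}
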