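// Affine-gap (Gotoh) global pairwise alignment used by the amplicon
// classification pipeline. A gap of length L costs open + L * extend.
#include <Rcpp.h>
#include <vector>
#include <string>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

// Global alignment of one query against the reference, returning the
// score and the indels in reference coordinates. Deletions are ranges
// of reference positions missing from the query; insertions are
// (boundary, length) with boundary = last reference position preceding
// the inserted bases (0 = before the reference start).
static List alignOne(const std::string& q, const std::string& r,
                     double match, double mismatch, double gapOpen,
                     double gapExtend) {
  const int n = q.size(), m = r.size();
  std::vector<double> Mc((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Xc((n + 1) * (m + 1), NEG_INF); // gap in reference
  std::vector<double> Yc((n + 1) * (m + 1), NEG_INF); // gap in query
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  Mc[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) Xc[at(i, 0)] = -gapOpen - gapExtend * i;
  for (int j = 1; j <= m; ++j) Yc[at(0, j)] = -gapOpen - gapExtend * j;
  for (int i = 1; i <= n; ++i) {
    const char qi = q[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double s = (qi == r[j - 1]) ? match : mismatch;
      double best = Mc[at(i - 1, j - 1)];
      if (Yc[at(i - 1, j - 1)] > best) best = Yc[at(i - 1, j - 1)];
      if (Xc[at(i - 1, j - 1)] > best) best = Xc[at(i - 1, j - 1)];
      Mc[at(i, j)] = best + s;
      double x = Mc[at(i - 1, j)] - gapOpen - gapExtend;
      double xe = Xc[at(i - 1, j)] - gapExtend;
      if (xe > x) x = xe;
      double xs = Yc[at(i - 1, j)] - gapOpen - gapExtend;
      if (xs > x) x = xs;
      Xc[at(i, j)] = x;
      double y = Mc[at(i, j - 1)] - gapOpen - gapExtend;
      double ye = Yc[at(i, j - 1)] - gapExtend;
      if (ye > y) y = ye;
      double ys = Xc[at(i, j - 1)] - gapOpen - gapExtend;
      if (ys > y) y = ys;
      Yc[at(i, j)] = y;
    }
  }
  // traceback, collecting consumed reference positions of deletions and
  // the reference boundaries of insertion steps
  const double eps = 1e-9;
  int i = n, j = m, layer = 0;
  double sc = Mc[at(n, m)];
  if (Yc[at(n, m)] > sc + eps) { sc = Yc[at(n, m)]; layer = 1; }
  if (Xc[at(n, m)] > sc + eps) { sc = Xc[at(n, m)]; layer = 2; }
  std::vector<int> delPos, insBound;
  while (i > 0 || j > 0) {
    if (layer == 0) {
      const double v = Mc[at(i, j)] -
        ((q[i - 1] == r[j - 1]) ? match : mismatch);
      int nl;
      if (std::fabs(Mc[at(i - 1, j - 1)] - v) < eps) nl = 0;
      else if (std::fabs(Yc[at(i - 1, j - 1)] - v) < eps) nl = 1;
      else nl = 2;
      --i; --j;
      layer = nl;
    } else if (layer == 1) { // gap in query: r_j deleted
      delPos.push_back(j);
      const double v = Yc[at(i, j)];
      int nl;
      if (std::fabs(Yc[at(i, j - 1)] - gapExtend - v) < eps) nl = 1;
      else if (std::fabs(Mc[at(i, j - 1)] - gapOpen - gapExtend - v) < eps) nl = 0;
      else nl = 2;
      --j;
      layer = nl;
    } else { // gap in reference: q_i inserted after boundary j
      insBound.push_back(j);
      const double v = Xc[at(i, j)];
      int nl;
      if (std::fabs(Xc[at(i - 1, j)] - gapExtend - v) < eps) nl = 2;
      else if (std::fabs(Mc[at(i - 1, j)] - gapOpen - gapExtend - v) < eps) nl = 0;
      else nl = 1;
      --i;
      layer = nl;
    }
  }
  // collapse into runs (positions were collected right-to-left)
  std::vector<int> delStart, delEnd, insPos, insLen;
  for (int k = (int)delPos.size() - 1; k >= 0;) {
    int start = delPos[k], end = delPos[k];
    int k2 = k - 1;
    while (k2 >= 0 && delPos[k2] == end + 1) { end = delPos[k2]; --k2; }
    delStart.push_back(start);
    delEnd.push_back(end);
    k = k2;
  }
  for (int k = (int)insBound.size() - 1; k >= 0;) {
    int b = insBound[k], len = 1;
    int k2 = k - 1;
    while (k2 >= 0 && insBound[k2] == b) { ++len; --k2; }
    insPos.push_back(b);
    insLen.push_back(len);
    k = k2;
  }
  const int nd = delStart.size(), ni = insPos.size();
  IntegerMatrix dels(nd, 2), ins(ni, 2);
  for (int k = 0; k < nd; ++k) { dels(k, 0) = delStart[k]; dels(k, 1) = delEnd[k]; }
  for (int k = 0; k < ni; ++k) { ins(k, 0) = insPos[k]; ins(k, 1) = insLen[k]; }
  colnames(dels) = CharacterVector::create("start", "end");
  colnames(ins) = CharacterVector::create("pos", "length");
  return List::create(_["score"] = sc, _["deletions"] = dels,
                      _["insertions"] = ins);
}

// [[Rcpp::export]]
List cppAlignGlobal(CharacterVector queries, std::string reference,
                    double match, double mismatch, double gapOpen,
                    double gapExtend) {
  const int nq = queries.size();
  List out(nq);
  for (int k = 0; k < nq; ++k) {
    out[k] = alignOne(as<std::string>(queries[k]), reference, match,
                      mismatch, gapOpen, gapExtend);
  }
  return out;
}
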