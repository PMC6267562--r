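#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Local alignment with affine gaps over plain nucleotide strings.
// Among all optimal-score alignments we report the one maximizing matched
// columns, then minimizing gap columns (lexicographic, additive per column,
// hence valid as a DP objective). Any base outside {A,C,G,T} scores as a
// mismatch against everything, including itself.

struct Cand {
  int score;
  int matches;
  int mismatches;
  int gaps; // gap columns
  bool valid;
};

static inline bool better(const Cand &a, const Cand &b) {
  if (!b.valid) return a.valid;
  if (!a.valid) return false;
  if (a.score != b.score) return a.score > b.score;
  if (a.matches != b.matches) return a.matches > b.matches;
  return a.gaps < b.gaps;
}

static inline Cand invalid() {
  Cand c; c.score = 0; c.matches = 0; c.mismatches = 0; c.gaps = 0;
  c.valid = false; return c;
}

static inline Cand zero() {
  Cand c; c.score = 0; c.matches = 0; c.mismatches = 0; c.gaps = 0;
  c.valid = true; return c;
}

static inline bool isACGT(char x) {
  return x == 'A' || x == 'C' || x == 'G' || x == 'T';
}

static inline Cand extendDiag(const Cand &p, bool match, int sMatch, int sMis) {
  Cand c = p;
  if (!p.valid) return invalid();
  if (match) { c.score += sMatch; c.matches += 1; }
  else       { c.score += sMis;   c.mismatches += 1; }
  return c;
}

static inline Cand extendGap(const Cand &p, int cost) {
  Cand c = p;
  if (!p.valid) return invalid();
  c.score += cost;
  c.gaps += 1;
  return c;
}

static List candToList(const Cand &b) {
  int alen = b.matches + b.mismatches + b.gaps;
  return List::create(_["score"] = b.score,
                      _["matches"] = b.matches,
                      _["mismatches"] = b.mismatches,
                      _["gaps"] = b.gaps,
                      _["alignment_length"] = alen);
}

// [[Rcpp::export(name = ".sw_align")]]
List sw_align(std::string a, std::string b,
              int match = 5, int mismatch = -4,
              int gapOpen = -12, int gapExt = -4) {
  int n = a.size(), m = b.size();
  // M: ends in an aligned (match/mismatch) column; X: gap in b (a residue
  // vs '-'); Y: gap in a. A score-optimal local alignment never starts or
  // ends in a gap column (gap scores are negative), so gap states extend
  // only existing alignments and the optimum is read from M cells.
  std::vector<Cand> Mrow(m + 1), Xrow(m + 1), Yrow(m + 1);
  std::vector<Cand> Mprev(m + 1), Xprev(m + 1), Yprev(m + 1);
  for (int j = 0; j <= m; ++j) { Mprev[j] = invalid(); Xprev[j] = invalid(); Yprev[j] = invalid(); }
  Cand best = zero();
  for (int i = 1; i <= n; ++i) {
    Mrow[0] = invalid(); Xrow[0] = invalid(); Yrow[0] = invalid();
    for (int j = 1; j <= m; ++j) {
      bool mt = isACGT(a[i - 1]) && a[i - 1] == b[j - 1];
      // diagonal: from M/X/Y at (i-1,j-1) or a fresh start (zero)
      Cand d = zero();
      if (better(Mprev[j - 1], d)) d = Mprev[j - 1];
      if (better(Xprev[j - 1], d)) d = Xprev[j - 1];
      if (better(Yprev[j - 1], d)) d = Yprev[j - 1];
      Mrow[j] = extendDiag(d, mt, match, mismatch);
      // gap in b: consume a[i-1]
      Cand x1 = extendGap(Mprev[j], gapOpen + gapExt);
      Cand x2 = extendGap(Xprev[j], gapExt);
      Cand x3 = extendGap(Yprev[j], gapOpen + gapExt);
      Xrow[j] = x1;
      if (better(x2, Xrow[j])) Xrow[j] = x2;
      if (better(x3, Xrow[j])) Xrow[j] = x3;
      // gap in a: consume b[j-1]
      Cand y1 = extendGap(Mrow[j - 1], gapOpen + gapExt);
      Cand y2 = extendGap(Yrow[j - 1], gapExt);
      Cand y3 = extendGap(Xrow[j - 1], gapOpen + gapExt);
      Yrow[j] = y1;
      if (better(y2, Yrow[j])) Yrow[j] = y2;
      if (better(y3, Yrow[j])) Yrow[j] = y3;
      if (better(Mrow[j], best)) best = Mrow[j];
    }
    std::swap(Mrow, Mprev); std::swap(Xrow, Xprev); std::swap(Yrow, Yprev);
  }
  return candToList(best);
}

// Exhaustive reference: the optimal local alignment equals the best global
// (end-to-end, Needleman-Wunsch) alignment over all pairs of substrings.
// For every start (i0, j0) one unclamped DP scores all ends at once; gap
// states may open from the origin (leading gaps), unlike the local DP above.
// Same scoring and the same tie objective; empty alignment allowed.
// [[Rcpp::export(name = ".brute_local_align")]]
List brute_local_align(std::string a, std::string b,
                       int match = 5, int mismatch = -4,
                       int gapOpen = -12, int gapExt = -4) {
  int n = a.size(), m = b.size();
  Cand best = zero();
  std::vector<Cand> M((n + 1) * (m + 1)), X((n + 1) * (m + 1)), Y((n + 1) * (m + 1));
  for (int i0 = 0; i0 < n; ++i0) {
    for (int j0 = 0; j0 < m; ++j0) {
      int nr = n - i0, nc = m - j0;
      auto at = [nc](int i, int j) { return i * (nc + 1) + j; };
      M[at(0, 0)] = zero(); X[at(0, 0)] = invalid(); Y[at(0, 0)] = invalid();
      for (int j = 1; j <= nc; ++j) {
        M[at(0, j)] = invalid();
        Cand y1 = extendGap(M[at(0, j - 1)], gapOpen + gapExt);
        Cand y2 = extendGap(Y[at(0, j - 1)], gapExt);
        Y[at(0, j)] = better(y1, y2) ? y1 : y2;
        X[at(0, j)] = invalid();
      }
      for (int i = 1; i <= nr; ++i) {
        M[at(i, 0)] = invalid();
        Cand x1 = extendGap(M[at(i - 1, 0)], gapOpen + gapExt);
        Cand x2 = extendGap(X[at(i - 1, 0)], gapExt);
        X[at(i, 0)] = better(x1, x2) ? x1 : x2;
        Y[at(i, 0)] = invalid();
        for (int j = 1; j <= nc; ++j) {
          bool mt = isACGT(a[i0 + i - 1]) && a[i0 + i - 1] == b[j0 + j - 1];
          Cand d = M[at(i - 1, j - 1)];
          if (better(X[at(i - 1, j - 1)], d)) d = X[at(i - 1, j - 1)];
          if (better(Y[at(i - 1, j - 1)], d)) d = Y[at(i - 1, j - 1)];
          M[at(i, j)] = extendDiag(d, mt, match, mismatch);
          Cand x1 = extendGap(M[at(i - 1, j)], gapOpen + gapExt);
          Cand x2 = extendGap(X[at(i - 1, j)], gapExt);
          Cand x3 = extendGap(Y[at(i - 1, j)], gapOpen + gapExt);
          X[at(i, j)] = x1;
          if (better(x2, X[at(i, j)])) X[at(i, j)] = x2;
          if (better(x3, X[at(i, j)])) X[at(i, j)] = x3;
          Cand y1 = extendGap(M[at(i, j - 1)], gapOpen + gapExt);
          Cand y2 = extendGap(Y[at(i, j - 1)], gapExt);
          Cand y3 = extendGap(X[at(i, j - 1)], gapOpen + gapExt);
          Y[at(i, j)] = y1;
          if (better(y2, Y[at(i, j)])) Y[at(i, j)] = y2;
          if (better(y3, Y[at(i, j)])) Y[at(i, j)] = y3;
          // a global alignment of a[i0..i0+i) vs b[j0..j0+j) may end in any state
          if (better(M[at(i, j)], best)) best = M[at(i, j)];
          if (better(X[at(i, j)], best)) best = X[at(i, j)];
          if (better(Y[at(i, j)], best)) best = Y[at(i, j)];
        }
      }
    }
  }
  return candToList(best);
}
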