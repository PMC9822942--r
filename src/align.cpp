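#include <Rcpp.h>
#include <string>
#include <vector>
using namespace Rcpp;

// Base-pair classification for an antiparallel RNA duplex position:
// 0 = no pair, 1 = Watson-Crick, 2 = G:U wobble.
static inline int pair_class(char a, char b) {
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
      (a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 1;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return 2;
  return 0;
}

// Local affine-gap complementarity alignment of a miRNA (5'->3') against a
// candidate site read 3'->5' (the site string is reversed internally, so the
// duplex is antiparallel). Gap of length k costs gap_open + (k-1)*gap_extend.
// Ties in the optimum are broken toward the smallest miRNA end position, then
// the smallest reversed-site end position, and traceback prefers pairing over
// gaps, so results are deterministic.
//
// Returns: score; pairing class per miRNA position (0/1/2, wobble reported
// only when allow_wobble); 1-based start/end of the aligned region in the
// site's original orientation (0/0 when no positive-scoring alignment).
// [[Rcpp::export(name = ".alignCoreCpp")]]
List align_core_cpp(std::string mirna, std::string site,
                    double match_score, double wobble_score,
                    double mismatch_penalty, double gap_open,
                    double gap_extend, bool allow_wobble) {
  const int n = mirna.size();
  const int m = site.size();
  std::string b(site.rbegin(), site.rend());

  const double NEG = -1e18;
  // DP matrices: M pair/mismatch state, X gap in site (miRNA base vs '-'),
  // Y gap in miRNA.
  std::vector<double> M((n + 1) * (m + 1), 0.0);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  double best = 0.0;
  int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      int pc = pair_class(mirna[i - 1], b[j - 1]);
      double s = (pc == 1) ? match_score
               : (pc == 2 && allow_wobble) ? wobble_score
               : mismatch_penalty;
      double diag = std::max(M[at(i - 1, j - 1)],
                    std::max(X[at(i - 1, j - 1)], Y[at(i - 1, j - 1)]));
      M[at(i, j)] = std::max(0.0, s + std::max(diag, 0.0));
      X[at(i, j)] = std::max(M[at(i - 1, j)] + gap_open,
                             X[at(i - 1, j)] + gap_extend);
      Y[at(i, j)] = std::max(M[at(i, j - 1)] + gap_open,
                             Y[at(i, j - 1)] + gap_extend);
      if (M[at(i, j)] > best) { best = M[at(i, j)]; bi = i; bj = j; }
    }
  }

  IntegerVector pairing(n, 0);
  IntegerVector site_pos(n, 0); // original-orientation site coordinate
                                // aligned to each miRNA position (0 = none)
  if (best <= 0.0) {
    return List::create(_["score"] = 0.0, _["pairing"] = pairing,
                        _["site_pos"] = site_pos,
                        _["site_start"] = 0, _["site_end"] = 0);
  }

  // Traceback from the optimum, M state only at the ends (local alignments
  // neither start nor end in a gap).
  int i = bi, j = bj, state = 0; // 0 = M, 1 = X, 2 = Y
  int jmin = bj, jmax = bj;
  while (true) {
    if (state == 0) {
      int pc = pair_class(mirna[i - 1], b[j - 1]);
      double s = (pc == 1) ? match_score
               : (pc == 2 && allow_wobble) ? wobble_score
               : mismatch_penalty;
      pairing[i - 1] = (pc == 1) ? 1 : (pc == 2 && allow_wobble) ? 2 : 0;
      site_pos[i - 1] = m - j + 1;
      if (j < jmin) jmin = j;
      double prevM = M[at(i - 1, j - 1)];
      double prevX = X[at(i - 1, j - 1)];
      double prevY = Y[at(i - 1, j - 1)];
      double diag = std::max(prevM, std::max(prevX, prevY));
      if (diag <= 0.0) break;            // alignment starts here
      i--; j--;
      state = (diag == prevM) ? 0 : (diag == prevX) ? 1 : 2;
    } else if (state == 1) {
      double fromM = M[at(i - 1, j)] + gap_open;
      state = (X[at(i, j)] == fromM) ? 0 : 1;
      i--;
    } else {
      double fromM = M[at(i, j - 1)] + gap_open;
      state = (Y[at(i, j)] == fromM) ? 0 : 2;
      j--;
    }
  }

  // Map the aligned span of the reversed site back to original coordinates.
  int site_start = m - jmax + 1;
  int site_end = m - jmin + 1;
  return List::create(_["score"] = best, _["pairing"] = pairing,
                      _["site_pos"] = site_pos,
                      _["site_start"] = site_start, _["site_end"] = site_end);
}

// Length of the longest common subsequence; the maximum number of identical
// aligned positions over all global alignments of a and b.
// [[Rcpp::export(name = ".lcsLengthCpp")]]
int lcs_length_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      cur[j] = (a[i - 1] == b[j - 1]) ? prev[j - 1] + 1
                                      : std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}
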