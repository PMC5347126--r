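#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Banded global (Needleman-Wunsch) alignment of a query against a reference.
// Mitogenomes are near-identical to the reference, so a narrow band around
// the main diagonal (shifted by the length difference) is exact in practice.
//
// Scoring: match +1, mismatch -1, gap -2 (linear). 'N' matches anything.
// Returns the two gapped strings, or throws if the optimal path leaves the
// band (caller should retry with a larger band).

static inline bool base_match(char a, char b) {
  return a == b || a == 'N' || b == 'N';
}

// [[Rcpp::export(name = ".banded_align_cpp")]]
List banded_align_cpp(std::string ref, std::string qry, int band) {
  const int n = ref.size(), m = qry.size();
  if (band < 1) stop("band must be >= 1");
  if (std::abs(n - m) > band)
    stop("length difference exceeds alignment band");
  const int MATCH = 1, MISMATCH = -1, GAP = -2;
  const int NEG = INT_MIN / 4;
  const int W = 2 * band + 1;        // j stored at offset j - (i + shift) + band
  const int shift = (m - n);         // centre band so the end cell is inside

  // diag centre for row i: j0(i) = i + round(i * shift / n)
  std::vector<int> centre(n + 1);
  for (int i = 0; i <= n; ++i)
    centre[i] = i + (n > 0 ? (int)std::lround((double)i * shift / n) : 0);

  std::vector<int> score((size_t)(n + 1) * W, NEG);
  std::vector<unsigned char> tb((size_t)(n + 1) * W, 0); // 1 diag, 2 up(ref gap? no: del), 3 left
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - centre[i] + band); };
  auto inband = [&](int i, int j) {
    int off = j - centre[i] + band;
    return j >= 0 && j <= m && off >= 0 && off < W;
  };

  score[idx(0, 0)] = 0;
  for (int j = 1; j <= m && inband(0, j); ++j) {
    score[idx(0, j)] = GAP * j;
    tb[idx(0, j)] = 3;
  }
  for (int i = 1; i <= n; ++i) {
    for (int j = std::max(0, centre[i] - band); j <= std::min(m, centre[i] + band); ++j) {
      int best = NEG; unsigned char dir = 0;
      if (j == 0) {
        best = GAP * i; dir = 2;
      } else {
        if (inband(i - 1, j - 1) && score[idx(i - 1, j - 1)] > NEG) {
          int s = score[idx(i - 1, j - 1)] +
            (base_match(ref[i - 1], qry[j - 1]) ? MATCH : MISMATCH);
          if (s > best) { best = s; dir = 1; }
        }
        if (inband(i - 1, j) && score[idx(i - 1, j)] > NEG) {
          int s = score[idx(i - 1, j)] + GAP;      // deletion in query
          if (s > best) { best = s; dir = 2; }
        }
        if (inband(i, j - 1) && score[idx(i, j - 1)] > NEG) {
          int s = score[idx(i, j - 1)] + GAP;      // insertion in query
          if (s > best) { best = s; dir = 3; }
        }
      }
      if (dir == 0) continue;
      score[idx(i, j)] = best;
      tb[idx(i, j)] = dir;
    }
  }
  if (!inband(n, m) || score[idx(n, m)] <= NEG)
    stop("alignment band exceeded; retry with a larger band");

  std::string ra, qa;
  ra.reserve(n + band); qa.reserve(m + band);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    unsigned char d = tb[idx(i, j)];
    if (d == 1)      { ra.push_back(ref[i - 1]); qa.push_back(qry[j - 1]); --i; --j; }
    else if (d == 2) { ra.push_back(ref[i - 1]); qa.push_back('-');       --i; }
    else if (d == 3) { ra.push_back('-');        qa.push_back(qry[j - 1]); --j; }
    else stop("traceback left the band; retry with a larger band");
  }
  std::reverse(ra.begin(), ra.end());
  std::reverse(qa.begin(), qa.end());
  return List::create(_["ref"] = ra, _["qry"] = qa,
                      _["score"] = score[idx(n, m)]);
}
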