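#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

// Bisulfite-asymmetric substitution score. In CT mode a genomic C aligned to
// a read T is rewarded as a full match (bisulfite conversion of an
// unmethylated cytosine), while genomic T vs read C stays a mismatch.
// GA mode mirrors this for bottom-strand reads mapped onto the forward
// reference (genomic G vs read A is a match). mode 0 = symmetric.
static inline int sub_score(char q, char r, int mode, int match, int mismatch) {
  if (q == r && (q == 'A' || q == 'C' || q == 'G' || q == 'T')) return match;
  if (mode == 1 && r == 'C' && q == 'T') return match;
  if (mode == 2 && r == 'G' && q == 'A') return match;
  return mismatch;
}

// Affine-gap local alignment (Smith–Waterman style). First gap base costs
// gap_open, each further base gap_extend; gaps open from the match state
// only. Traceback tie-break: diagonal, then deletion (ref gap op 'D'),
// then insertion ('I').
// [[Rcpp::export]]
List cpp_bisulfite_sw(std::string read, std::string ref, int match, int mismatch,
                      int gap_open, int gap_extend, std::string mode) {
  int md = (mode == "ct") ? 1 : (mode == "ga") ? 2 : 0;
  if (md == 0 && mode != "none") stop("mode must be 'ct', 'ga' or 'none'");
  int n = (int)read.size(), m = (int)ref.size();
  if (n == 0 || m == 0) stop("empty read or segment");
  for (auto &c : read) c = (char)toupper((unsigned char)c);
  for (auto &c : ref) c = (char)toupper((unsigned char)c);

  const int NEG = INT_MIN / 4;
  size_t W = (size_t)m + 1;
  std::vector<int> H((size_t)(n + 1) * W, 0), D((size_t)(n + 1) * W, NEG),
      I((size_t)(n + 1) * W, NEG);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      size_t c = (size_t)i * W + j;
      int d = std::max(H[c - W - 1], std::max(D[c - W - 1], I[c - W - 1]));
      int h = d + sub_score(read[i - 1], ref[j - 1], md, match, mismatch);
      if (h < 0) h = 0;
      H[c] = h;
      D[c] = std::max(H[c - 1] + gap_open, D[c - 1] + gap_extend);
      I[c] = std::max(H[c - W] + gap_open, I[c - W] + gap_extend);
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  if (best == 0) {
    return List::create(_["score"] = 0, _["ref_start"] = NA_INTEGER,
                        _["ref_end"] = NA_INTEGER, _["query_start"] = NA_INTEGER,
                        _["query_end"] = NA_INTEGER, _["cigar"] = NA_STRING);
  }

  // traceback
  std::string ops;
  int i = bi, j = bj, state = 0; // 0=H, 1=D, 2=I
  while (true) {
    size_t c = (size_t)i * W + j;
    if (state == 0) {
      ops.push_back('M');
      int prevH = H[c - W - 1], prevD = D[c - W - 1], prevI = I[c - W - 1];
      int pbest = std::max(prevH, std::max(prevD, prevI));
      --i; --j;
      if (pbest <= 0) break;           // local alignment start
      if (prevH == pbest) state = 0;
      else if (prevD == pbest) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D');
      bool opened = (D[c] == H[c - 1] + gap_open);
      --j;
      state = opened ? 0 : 1;
    } else {
      ops.push_back('I');
      bool opened = (I[c] == H[c - W] + gap_open);
      --i;
      state = opened ? 0 : 2;
    }
  }
  // ops are reversed; compress into CIGAR
  std::string cigar;
  int run = 0; char cur = 0;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it) {
    if (*it == cur) { ++run; }
    else { if (run) cigar += std::to_string(run) + cur; cur = *it; run = 1; }
  }
  if (run) cigar += std::to_string(run) + cur;

  return List::create(_["score"] = best, _["ref_start"] = j, _["ref_end"] = bj,
                      _["query_start"] = i, _["query_end"] = bi,
                      _["cigar"] = cigar);
}
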