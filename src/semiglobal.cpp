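#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Semi-global affine-gap alignment (Gotoh): the read is aligned end-to-end,
// leading/trailing reference positions are free.  A gap of length L costs
// gapOpen + (L-1)*gapExtend.  CIGAR uses M (match-or-mismatch), I (gap in
// reference, read base consumed), D (gap in read, reference base consumed).
// Ties at the terminal column are broken toward the smallest reference
// coordinate; indel placement is afterwards left-normalized in R.

static const int NEG = std::numeric_limits<int>::min() / 4;

// [[Rcpp::export(name = ".semiglobal_align_cpp")]]
List semiglobal_align_cpp(std::string read, std::string ref,
                          int match, int mismatch,
                          int gapOpen, int gapExtend) {
  const int m = read.size(), n = ref.size();
  if (m == 0) stop("empty read");
  if (n == 0) stop("empty reference");

  std::vector<int> M((m + 1) * (n + 1), NEG);
  std::vector<int> X((m + 1) * (n + 1), NEG); // gap in ref (I)
  std::vector<int> Y((m + 1) * (n + 1), NEG); // gap in read (D)
  std::vector<int> B((m + 1) * (n + 1), NEG); // best of the three
  auto at = [n](int i, int j) { return i * (n + 1) + j; };

  for (int j = 0; j <= n; ++j) B[at(0, j)] = 0;   // free leading reference
  for (int i = 1; i <= m; ++i) {                  // read prefix must be gapped
    X[at(i, 0)] = gapOpen + (i - 1) * gapExtend;
    B[at(i, 0)] = X[at(i, 0)];
  }

  for (int i = 1; i <= m; ++i) {
    for (int j = 1; j <= n; ++j) {
      const int s = (read[i - 1] == ref[j - 1]) ? match : mismatch;
      M[at(i, j)] = B[at(i - 1, j - 1)] + s;
      X[at(i, j)] = std::max(B[at(i - 1, j)] + gapOpen,
                             X[at(i - 1, j)] + gapExtend);
      Y[at(i, j)] = std::max(B[at(i, j - 1)] + gapOpen,
                             Y[at(i, j - 1)] + gapExtend);
      B[at(i, j)] = std::max(M[at(i, j)], std::max(X[at(i, j)], Y[at(i, j)]));
    }
  }

  // terminal: free trailing reference; smallest j on ties
  int best = NEG, jEnd = 0;
  for (int j = 0; j <= n; ++j)
    if (B[at(m, j)] > best) { best = B[at(m, j)]; jEnd = j; }

  // state achieving B at (i,j), preference M > D > I
  auto pick = [&](int i, int j) -> char {
    const int b = B[at(i, j)];
    if (b == M[at(i, j)]) return 'M';
    if (b == Y[at(i, j)]) return 'D';
    return 'I';
  };

  std::string ops;
  int i = m, j = jEnd;
  char state = pick(i, j);
  while (i > 0) {
    if (j == 0) { ops.push_back('I'); --i; continue; }
    if (state == 'M') {
      ops.push_back('M');
      --i; --j;
      if (i > 0) state = pick(i, j);
    } else if (state == 'I') {
      ops.push_back('I');
      const bool opn = (X[at(i, j)] == B[at(i - 1, j)] + gapOpen);
      const bool ext = (X[at(i, j)] == X[at(i - 1, j)] + gapExtend);
      --i;
      if (i > 0) state = opn ? pick(i, j) : (ext ? 'I' : pick(i, j));
    } else { // 'D'
      ops.push_back('D');
      const bool opn = (Y[at(i, j)] == B[at(i, j - 1)] + gapOpen);
      const bool ext = (Y[at(i, j)] == Y[at(i, j - 1)] + gapExtend);
      --j;
      state = opn ? pick(i, j) : (ext ? 'D' : pick(i, j));
    }
  }
  const int refStart = j; // 0-based offset of first aligned reference base

  // run-length encode reversed ops
  std::string cigar;
  for (int k = (int)ops.size() - 1; k >= 0;) {
    int k2 = k;
    while (k2 >= 0 && ops[k2] == ops[k]) --k2;
    cigar += std::to_string(k - k2);
    cigar.push_back(ops[k]);
    k = k2;
  }

  return List::create(_["score"] = best,
                      _["ref_start"] = refStart,
                      _["cigar"] = cigar);
}
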