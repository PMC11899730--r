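#include <Rcpp.h>
using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with affine gaps over a precomputed
// position-by-position score matrix. Works for residue-residue scores
// (pairwise alignment) and for profile-column scores (progressive MSA).
//
// Traceback tie-breaking is deterministic: diagonal (match/mismatch) is
// preferred over gaps, and a gap in the first sequence is preferred over a
// gap in the second.
//
// Returns 1-based index paths; 0 marks a gap.
// [[Rcpp::export]]
List dp_affine_align(NumericMatrix s, double gap_open, double gap_extend) {
  const int n = s.nrow();  // length of a
  const int m = s.ncol();  // length of b
  const double NEG = -1e30;

  // M: a_i aligned to b_j; GA: gap in a (consumes b_j); GB: gap in b
  // (consumes a_i).
  NumericMatrix M(n + 1, m + 1), GA(n + 1, m + 1), GB(n + 1, m + 1);
  // traceback: which of the three states fed each cell's maximum
  IntegerMatrix tM(n + 1, m + 1), tGA(n + 1, m + 1), tGB(n + 1, m + 1);
  const int FROM_M = 0, FROM_GA = 1, FROM_GB = 2;

  M(0, 0) = 0.0;
  GA(0, 0) = GB(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG;
    GA(i, 0) = NEG;
    GB(i, 0) = -gap_open - (i - 1) * gap_extend;
    tGB(i, 0) = (i == 1) ? FROM_M : FROM_GB;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG;
    GB(0, j) = NEG;
    GA(0, j) = -gap_open - (j - 1) * gap_extend;
    tGA(0, j) = (j == 1) ? FROM_M : FROM_GA;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: preference M > GA > GB on ties
      double best = M(i - 1, j - 1);
      int from = FROM_M;
      if (GA(i - 1, j - 1) > best) { best = GA(i - 1, j - 1); from = FROM_GA; }
      if (GB(i - 1, j - 1) > best) { best = GB(i - 1, j - 1); from = FROM_GB; }
      M(i, j) = best + s(i - 1, j - 1);
      tM(i, j) = from;

      // GA: gap in a, consume b_j (move left)
      double open_ga = M(i, j - 1) - gap_open;
      double ext_ga  = GA(i, j - 1) - gap_extend;
      if (open_ga >= ext_ga) { GA(i, j) = open_ga; tGA(i, j) = FROM_M; }
      else                   { GA(i, j) = ext_ga;  tGA(i, j) = FROM_GA; }

      // GB: gap in b, consume a_i (move up)
      double open_gb = M(i - 1, j) - gap_open;
      double ext_gb  = GB(i - 1, j) - gap_extend;
      if (open_gb >= ext_gb) { GB(i, j) = open_gb; tGB(i, j) = FROM_M; }
      else                   { GB(i, j) = ext_gb;  tGB(i, j) = FROM_GB; }
    }
  }

  // terminal state: prefer M, then GA (gap in a), then GB
  double score = M(n, m);
  int state = FROM_M;
  if (GA(n, m) > score) { score = GA(n, m); state = FROM_GA; }
  if (GB(n, m) > score) { score = GB(n, m); state = FROM_GB; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == FROM_M) {
      int from = tM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = from;
    } else if (state == FROM_GA) {
      int from = tGA(i, j);
      ai.push_back(0); bi.push_back(j);
      --j;
      state = from;
    } else {
      int from = tGB(i, j);
      ai.push_back(i); bi.push_back(0);
      --i;
      state = from;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["a"] = wrap(ai), _["b"] = wrap(bi),
                      _["score"] = score);
}
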