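#include <Rcpp.h>
using namespace Rcpp;

// Score-only Smith-Waterman local alignment with affine gaps (Gotoh),
// linear memory in the shorter sequence. Sequences arrive as 1-based
// integer codes into the substitution matrix.
//
// Gap model: a gap of length k costs gap_open + (k-1) * gap_extend, with
// both penalties supplied as non-positive numbers. Setting
// gap_open == gap_extend gives the linear gap model used by the simple
// match/mismatch scoring mode.

// [[Rcpp::export]]
double sw_score_cpp(IntegerVector a, IntegerVector b,
                    NumericMatrix subst, double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  if (n == 0 || m == 0)
    stop("empty sequence");

  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), F(m + 1, 0.0);
  // F[j]: best score ending with a gap in b (vertical move) at column j
  double best = 0.0;
  for (int j = 0; j <= m; ++j) F[j] = R_NegInf;

  for (int i = 1; i <= n; ++i) {
    double E = R_NegInf;  // gap in a (horizontal move)
    Hcur[0] = 0.0;
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] + gap_open, E + gap_extend);
      F[j] = std::max(Hprev[j] + gap_open, F[j] + gap_extend);
      double h = Hprev[j - 1] + subst(ai, b[j - 1] - 1);
      h = std::max(h, E);
      h = std::max(h, F[j]);
      h = std::max(h, 0.0);
      Hcur[j] = h;
      if (h > best) best = h;
    }
    std::swap(Hprev, Hcur);
  }
  return best;
}
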