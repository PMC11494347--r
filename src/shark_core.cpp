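#include <Rcpp.h>
using namespace Rcpp;

// Fill W (column-major, n1 x n2) with the k-mer similarity matrix of the
// integer-encoded sequences x (length L1) and y (length L2), where
// n1 = L1 - k + 1, n2 = L2 - k + 1. Entries whose window touches an invalid
// residue code (<= 0) are set to NA. Rolling window sums along diagonals
// make the fill O(L1 * L2) independent of k.
static void fill_kmer_matrix(const int* x, int L1, const int* y, int L2,
                             const double* S, int nS, int k, double* W) {
  const int n1 = L1 - k + 1, n2 = L2 - k + 1;
  auto run_diag = [&](int i0, int j0) {
    int len = std::min(L1 - i0, L2 - j0);
    double s = 0.0;
    int bad = 0; // invalid codes inside the current window
    for (int t = 0; t < len; ++t) {
      int xi = x[i0 + t], yj = y[j0 + t];
      if (xi <= 0 || yj <= 0) ++bad; else s += S[(xi - 1) + nS * (yj - 1)];
      if (t >= k) {
        int xo = x[i0 + t - k], yo = y[j0 + t - k];
        if (xo <= 0 || yo <= 0) --bad; else s -= S[(xo - 1) + nS * (yo - 1)];
      }
      if (t >= k - 1) {
        int i = i0 + t - k + 1, j = j0 + t - k + 1;
        W[i + (R_xlen_t)n1 * j] = bad ? NA_REAL : s / k;
      }
    }
  };
  for (int j0 = 0; j0 < L2; ++j0) run_diag(0, j0);
  for (int i0 = 1; i0 < L1; ++i0) run_diag(i0, 0);
}

// Pairwise k-mer similarity matrix between two integer-encoded sequences.
// x, y: 1-based residue codes into S (codes <= 0 mark invalid residues whose
// k-mers become NA). S: residue similarity matrix in [0,1].
// [[Rcpp::export]]
NumericMatrix kmer_sim_matrix_cpp(IntegerVector x, IntegerVector y,
                                  NumericMatrix S, int k) {
  const int L1 = x.size(), L2 = y.size();
  if (L1 < k || L2 < k) stop("sequence shorter than k");
  NumericMatrix W(L1 - k + 1, L2 - k + 1);
  fill_kmer_matrix(INTEGER(x), L1, INTEGER(y), L2, REAL(S), S.nrow(), k,
                   REAL(W));
  return W;
}

// SHARK-score (best): mean over each sequence's k-mers of the best-matching
// similarity in the other sequence, symmetrized as the mean of the two
// directions. Invalid k-mers are skipped; NA if either side has none valid.
// [[Rcpp::export]]
double shark_best_cpp(IntegerVector x, IntegerVector y, NumericMatrix S,
                      int k) {
  const int L1 = x.size(), L2 = y.size();
  if (L1 < k || L2 < k) stop("sequence shorter than k");
  const int n1 = L1 - k + 1, n2 = L2 - k + 1;
  std::vector<double> W((size_t)n1 * n2);
  fill_kmer_matrix(INTEGER(x), L1, INTEGER(y), L2, REAL(S), S.nrow(), k,
                   W.data());
  std::vector<double> rmax(n1, -1.0), cmax(n2, -1.0);
  for (int j = 0; j < n2; ++j) {
    const double* col = W.data() + (size_t)n1 * j;
    for (int i = 0; i < n1; ++i) {
      double w = col[i];
      if (ISNA(w)) continue;
      if (w > rmax[i]) rmax[i] = w;
      if (w > cmax[j]) cmax[j] = w;
    }
  }
  double mr = 0.0, mc = 0.0;
  int nr = 0, nc = 0;
  for (int i = 0; i < n1; ++i) if (rmax[i] >= 0) { mr += rmax[i]; ++nr; }
  for (int j = 0; j < n2; ++j) if (cmax[j] >= 0) { mc += cmax[j]; ++nc; }
  if (!nr || !nc) return NA_REAL;
  return (mr / nr + mc / nc) / 2.0;
}

// SHARK-score (T): sum of k-mer similarities >= T over all valid k-mer
// pairs, normalized by the number of valid pairs. NA if no valid pair.
// [[Rcpp::export]]
double shark_T_cpp(IntegerVector x, IntegerVector y, NumericMatrix S,
                   int k, double T) {
  const int L1 = x.size(), L2 = y.size();
  if (L1 < k || L2 < k) stop("sequence shorter than k");
  const int n1 = L1 - k + 1, n2 = L2 - k + 1;
  std::vector<double> W((size_t)n1 * n2);
  fill_kmer_matrix(INTEGER(x), L1, INTEGER(y), L2, REAL(S), S.nrow(), k,
                   W.data());
  double acc = 0.0;
  long long nvalid = 0;
  for (size_t t = 0; t < W.size(); ++t) {
    double w = W[t];
    if (ISNA(w)) continue;
    ++nvalid;
    if (w >= T) acc += w;
  }
  if (!nvalid) return NA_REAL;
  return acc / (double)nvalid;
}

// Smith-Waterman local alignment score with affine gaps (Gotoh).
// A gap of length L costs gap_open + (L-1)*gap_extend (EMBOSS convention).
// S: substitution scores indexed by the 1-based codes in x/y.
// [[Rcpp::export]]
double sw_score_cpp(IntegerVector x, IntegerVector y, NumericMatrix S,
                    double gap_open, double gap_extend) {
  const int n = x.size(), m = y.size();
  if (n == 0 || m == 0) return 0.0;
  const double NEG = -1e30;
  const double* pS = REAL(S);
  const int nS = S.nrow();
  const int* px = INTEGER(x);
  const int* py = INTEGER(y);
  // H: best local score ending at (i,j); E: gap in x (horizontal move);
  // F: gap in y (vertical move). Rolling rows over j.
  std::vector<double> Hprev(m + 1, 0.0), Hcur(m + 1, 0.0), F(m + 1, NEG);
  double best = 0.0;
  for (int i = 1; i <= n; ++i) {
    double E = NEG;
    Hcur[0] = 0.0;
    for (int j = 1; j <= m; ++j) {
      E = std::max(Hcur[j - 1] - gap_open, E - gap_extend);
      F[j] = std::max(Hprev[j] - gap_open, F[j] - gap_extend);
      double h = Hprev[j - 1] + pS[(px[i - 1] - 1) + nS * (py[j - 1] - 1)];
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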