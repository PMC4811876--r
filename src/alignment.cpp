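#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap Smith-Waterman. Sequences are 1-based integer encodings into the
// rows/columns of the substitution matrix S. A gap of length L costs
// gap_open + L * gap_extend. Traceback tie-break: diagonal > up (gap in b) >
// left (gap in a), so results are deterministic.
// Returns the optimal local score plus the aligned column index vectors
// (0 marks a gap in that sequence).
// [[Rcpp::export]]
List cpp_align_local(IntegerVector a, IntegerVector b, NumericMatrix S,
                     double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double og = gap_open + gap_extend; // cost of a length-1 gap
  const double NEG = -1e18;

  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  // pointer codes for M: 0 start, 1 diag-M, 2 diag-Ix, 3 diag-Iy
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);

  for (int j = 0; j <= m; ++j) { M(0, j) = NEG; Ix(0, j) = NEG; Iy(0, j) = NEG; }
  for (int i = 0; i <= n; ++i) { M(i, 0) = NEG; Ix(i, 0) = NEG; Iy(i, 0) = NEG; }

  double best = 0.0; int bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: column (a_i, b_j) aligned
      double prevM = M(i - 1, j - 1), prevX = Ix(i - 1, j - 1), prevY = Iy(i - 1, j - 1);
      double base = 0.0; int ptr = 0;
      if (prevM >= base) { base = prevM; ptr = 1; }
      if (prevX > base) { base = prevX; ptr = 2; }
      if (prevY > base) { base = prevY; ptr = 3; }
      M(i, j) = S(a[i - 1] - 1, b[j - 1] - 1) + base;
      PM(i, j) = ptr;
      // Ix: gap in b, consuming a (move "up")
      double fromM = M(i - 1, j) - og, fromX = Ix(i - 1, j) - gap_extend;
      if (fromM >= fromX) { Ix(i, j) = fromM; PX(i, j) = 1; }
      else { Ix(i, j) = fromX; PX(i, j) = 2; }
      // Iy: gap in a, consuming b (move "left")
      double fromM2 = M(i, j - 1) - og, fromY = Iy(i, j - 1) - gap_extend;
      if (fromM2 >= fromY) { Iy(i, j) = fromM2; PY(i, j) = 1; }
      else { Iy(i, j) = fromY; PY(i, j) = 3; }
      if (M(i, j) > best) { best = M(i, j); bi = i; bj = j; }
    }
  }

  std::vector<int> ai, bj_;
  if (best > 0) {
    int i = bi, j = bj, state = 1; // local alignments end in a match column
    while (i > 0 && j > 0) {
      if (state == 1) {
        ai.push_back(i); bj_.push_back(j);
        int ptr = PM(i, j);
        --i; --j;
        if (ptr == 0) break;
        state = ptr;
      } else if (state == 2) {
        ai.push_back(i); bj_.push_back(0);
        state = PX(i, j);
        --i;
      } else {
        ai.push_back(0); bj_.push_back(j);
        state = PY(i, j);
        --j;
      }
    }
    std::reverse(ai.begin(), ai.end());
    std::reverse(bj_.begin(), bj_.end());
  }
  return List::create(_["score"] = best > 0 ? best : 0.0,
                      _["a_idx"] = wrap(ai), _["b_idx"] = wrap(bj_));
}

// Affine-gap global alignment of two profiles given the precomputed
// column-vs-column score matrix SM (n1 x n2). With free_ends, leading and
// trailing gap runs cost nothing (overlap/semi-global alignment).
// Returns aligned column index vectors (0 = gap column).
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix SM, double gap_open, double gap_extend,
                       bool free_ends) {
  const int n = SM.nrow(), m = SM.ncol();
  const double og = gap_open + gap_extend;
  const double NEG = -1e18;
  NumericMatrix M(n + 1, m + 1), Ix(n + 1, m + 1), Iy(n + 1, m + 1);
  IntegerMatrix PM(n + 1, m + 1), PX(n + 1, m + 1), PY(n + 1, m + 1);

  M(0, 0) = 0.0; Ix(0, 0) = NEG; Iy(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Iy(i, 0) = NEG;
    Ix(i, 0) = free_ends ? 0.0 : -(gap_open + i * gap_extend);
    PX(i, 0) = (i == 1) ? 1 : 2;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; Ix(0, j) = NEG;
    Iy(0, j) = free_ends ? 0.0 : -(gap_open + j * gap_extend);
    PY(0, j) = (j == 1) ? 1 : 3;
  }

  for (int i = 1; i <= n; ++i) {
    const bool edge_i = (i == n);
    for (int j = 1; j <= m; ++j) {
      const bool edge_j = (j == m);
      double base = M(i - 1, j - 1); int ptr = 1;
      if (Ix(i - 1, j - 1) > base) { base = Ix(i - 1, j - 1); ptr = 2; }
      if (Iy(i - 1, j - 1) > base) { base = Iy(i - 1, j - 1); ptr = 3; }
      M(i, j) = SM(i - 1, j - 1) + base;
      PM(i, j) = ptr;
      // trailing gaps free when the other profile is exhausted
      double ogx = (free_ends && edge_j) ? 0.0 : og;
      double ex = (free_ends && edge_j) ? 0.0 : gap_extend;
      double fromM = M(i - 1, j) - ogx, fromX = Ix(i - 1, j) - ex;
      if (fromM >= fromX) { Ix(i, j) = fromM; PX(i, j) = 1; }
      else { Ix(i, j) = fromX; PX(i, j) = 2; }
      double ogy = (free_ends && edge_i) ? 0.0 : og;
      double ey = (free_ends && edge_i) ? 0.0 : gap_extend;
      double fromM2 = M(i, j - 1) - ogy, fromY = Iy(i, j - 1) - ey;
      if (fromM2 >= fromY) { Iy(i, j) = fromM2; PY(i, j) = 1; }
      else { Iy(i, j) = fromY; PY(i, j) = 3; }
    }
  }

  int state = 1; double bestv = M(n, m);
  if (Ix(n, m) > bestv) { bestv = Ix(n, m); state = 2; }
  if (Iy(n, m) > bestv) { bestv = Iy(n, m); state = 3; }

  std::vector<int> ai, bj_;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 1) {
      ai.push_back(i); bj_.push_back(j);
      state = PM(i, j); --i; --j;
    } else if (state == 2) {
      ai.push_back(i); bj_.push_back(0);
      state = PX(i, j); --i;
    } else {
      ai.push_back(0); bj_.push_back(j);
      state = PY(i, j); --j;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bj_.begin(), bj_.end());
  return List::create(_["a_idx"] = wrap(ai), _["b_idx"] = wrap(bj_),
                      _["score"] = bestv);
}

// Score-only affine Smith-Waterman over many sequence pairs at once.
// Same recurrences as cpp_align_local, without traceback bookkeeping.
// [[Rcpp::export]]
NumericMatrix cpp_align_score_block(List a_list, List b_list, NumericMatrix S,
                                    double gap_open, double gap_extend) {
  const double og = gap_open + gap_extend;
  const double NEG = -1e18;
  const int na = a_list.size(), nb = b_list.size();
  NumericMatrix out(na, nb);
  for (int x = 0; x < na; ++x) {
    IntegerVector a = a_list[x];
    const int n = a.size();
    for (int y = 0; y < nb; ++y) {
      IntegerVector b = b_list[y];
      const int m = b.size();
      std::vector<double> M(m + 1, NEG), Ix(m + 1, NEG), Iy(m + 1, NEG);
      double best = 0.0;
      for (int i = 1; i <= n; ++i) {
        double diagM = NEG, diagX = NEG, diagY = NEG; // cell (i-1, j-1)
        for (int j = 1; j <= m; ++j) {
          double nextDiagM = M[j], nextDiagX = Ix[j], nextDiagY = Iy[j];
          double base = 0.0;
          if (diagM > base) base = diagM;
          if (diagX > base) base = diagX;
          if (diagY > base) base = diagY;
          double Mij = S(a[i - 1] - 1, b[j - 1] - 1) + base;
          double Ixij = std::max(M[j] - og, Ix[j] - gap_extend);
          double Iyij = std::max(M[j - 1] - og, Iy[j - 1] - gap_extend);
          M[j] = Mij; Ix[j] = Ixij; Iy[j] = Iyij;
          diagM = nextDiagM; diagX = nextDiagX; diagY = nextDiagY;
          if (Mij > best) best = Mij;
        }
        M[0] = NEG; Ix[0] = NEG; Iy[0] = NEG;
      }
      out(x, y) = best;
    }
  }
  return out;
}

// Pairwise p-distances on an integer-encoded alignment (rows = sequences,
// 0 = gap). p = mismatches / mutually ungapped columns; comparable-column
// counts are returned so callers can flag pairs with no overlap.
// [[Rcpp::export]]
List cpp_pdist(IntegerMatrix msa) {
  const int n = msa.nrow(), L = msa.ncol();
  NumericMatrix P(n, n);
  IntegerMatrix C(n, n);
  for (int i = 0; i < n; ++i) {
    C(i, i) = L;
    for (int j = i + 1; j < n; ++j) {
      int comp = 0, diff = 0;
      for (int k = 0; k < L; ++k) {
        int x = msa(i, k), y = msa(j, k);
        if (x > 0 && y > 0) { ++comp; if (x != y) ++diff; }
      }
      double p = comp > 0 ? (double)diff / comp : NA_REAL;
      P(i, j) = p; P(j, i) = p;
      C(i, j) = comp; C(j, i) = comp;
    }
  }
  return List::create(_["p"] = P, _["n_comparable"] = C);
}
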