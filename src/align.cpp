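#include <Rcpp.h>
using namespace Rcpp;

// Global profile-profile alignment with affine gap penalties.
//
// A and B are integer matrices (rows = sequences, columns = alignment
// positions) whose entries are 1-based indices into the score matrix S;
// existing gap characters carry their own index so merged profiles are
// scored through S like any residue. New gaps introduced by this
// alignment pay the affine penalties go (open) + ge (extend).
//
// Returns the move string of the optimal path: 1 = consume a column of
// both profiles, 2 = consume A only (gap inserted into B), 3 = consume
// B only. Ties are broken deterministically: diagonal, then up (2),
// then left (3), so outputs are byte-for-byte reproducible.
// [[Rcpp::export(name = ".profile_align_cpp")]]
IntegerVector profile_align_cpp(IntegerMatrix A, IntegerMatrix B,
                                NumericMatrix S, double go, double ge) {
  const int La = A.ncol(), Lb = B.ncol();
  const int nA = A.nrow(), nB = B.nrow();
  const double NEG = -1e30;

  // Mean sum-of-pairs score for each column pair.
  NumericMatrix col(La, Lb);
  for (int a = 0; a < La; ++a) {
    for (int b = 0; b < Lb; ++b) {
      double s = 0.0;
      for (int i = 0; i < nA; ++i)
        for (int j = 0; j < nB; ++j)
          s += S(A(i, a) - 1, B(j, b) - 1);
      col(a, b) = s / (nA * nB);
    }
  }

  // Three-state affine DP. M(i,j): columns i of A and j of B aligned.
  // X(i,j): column i of A against a gap; Y(i,j): column j of B against
  // a gap. Stored as (La+1) x (Lb+1).
  NumericMatrix M(La + 1, Lb + 1), X(La + 1, Lb + 1), Y(La + 1, Lb + 1);
  IntegerMatrix tM(La + 1, Lb + 1), tX(La + 1, Lb + 1), tY(La + 1, Lb + 1);

  M(0, 0) = 0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= La; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = go + ge * (i - 1);
    tX(i, 0) = 2;
  }
  for (int j = 1; j <= Lb; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = go + ge * (j - 1);
    tY(0, j) = 3;
  }

  for (int i = 1; i <= La; ++i) {
    for (int j = 1; j <= Lb; ++j) {
      // M: prefer diagonal continuation, then X, then Y on ties.
      double m1 = M(i - 1, j - 1), m2 = X(i - 1, j - 1), m3 = Y(i - 1, j - 1);
      int src = 1; double best = m1;
      if (m2 > best) { best = m2; src = 2; }
      if (m3 > best) { best = m3; src = 3; }
      M(i, j) = best + col(i - 1, j - 1);
      tM(i, j) = src;

      // X: gap in B (consume A column i).
      double xo = M(i - 1, j) + go, xe = X(i - 1, j) + ge;
      if (xo >= xe) { X(i, j) = xo; tX(i, j) = 1; }
      else          { X(i, j) = xe; tX(i, j) = 2; }

      // Y: gap in A (consume B column j).
      double yo = M(i, j - 1) + go, ye = Y(i, j - 1) + ge;
      if (yo >= ye) { Y(i, j) = yo; tY(i, j) = 1; }
      else          { Y(i, j) = ye; tY(i, j) = 3; }
    }
  }

  // Traceback from the best final state (prefer M, then X, then Y).
  int state = 1; double best = M(La, Lb);
  if (X(La, Lb) > best) { best = X(La, Lb); state = 2; }
  if (Y(La, Lb) > best) { best = Y(La, Lb); state = 3; }

  std::vector<int> moves;
  int i = La, j = Lb;
  while (i > 0 || j > 0) {
    if (state == 1) {
      int src = tM(i, j);
      moves.push_back(1); --i; --j;
      state = src;
    } else if (state == 2) {
      int src = tX(i, j);
      moves.push_back(2); --i;
      state = (src == 1) ? 1 : 2;
    } else {
      int src = tY(i, j);
      moves.push_back(3); --j;
      state = (src == 1) ? 1 : 3;
    }
  }
  std::reverse(moves.begin(), moves.end());
  return wrap(moves);
}
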