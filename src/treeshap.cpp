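#include <Rcpp.h>
using namespace Rcpp;

// Exact interventional Shapley values for a tree ensemble.
//
// Each leaf of each tree is reduced to its hyper-rectangle of feature
// constraints [lo, hi).  For one explained sample x and one reference
// (baseline) sample r, the game value v(S) is the ensemble output with
// features in S taken from x and the rest from r.  A leaf is reached
// under coalition S iff every constrained feature satisfied by x but not
// by r lies in S (set X) and every feature satisfied by r but not by x
// lies outside S (set R); leaves violating a constraint for both samples
// are unreachable for this (x, r) pair.  For such an indicator game the
// Shapley weight has closed form: features in X receive
// value * (|X|-1)! |R|! / (|X|+|R|)!, features in R receive
// -value * |X|! (|R|-1)! / (|X|+|R|)!.  Averaging over the reference set
// gives the marginal-expectation (interventional) Shapley values, which
// satisfy local accuracy exactly: base + sum(phi) = f(x).

static const int MAXF = 170;

static void factorials(double *fact) {
  fact[0] = 1.0;
  for (int i = 1; i <= MAXF; ++i) fact[i] = fact[i - 1] * i;
}

// [[Rcpp::export]]
NumericVector treeShapInterventionalCpp(IntegerVector leafConsStart,
                                        NumericVector leafValue,
                                        IntegerVector consFeat,
                                        NumericVector consLo,
                                        NumericVector consHi,
                                        NumericVector x,
                                        NumericMatrix refs) {
  const int nLeaf = leafValue.size();
  const int nFeat = x.size();
  const int nRef = refs.nrow();
  double fact[MAXF + 1];
  factorials(fact);
  NumericVector phi(nFeat);
  std::vector<int> setX(nFeat), setR(nFeat);

  for (int l = 0; l < nLeaf; ++l) {
    const int c0 = leafConsStart[l], c1 = leafConsStart[l + 1];
    const double val = leafValue[l];
    if (c1 - c0 > MAXF) stop("tree depth exceeds supported constraint count");
    // precompute x-side pass/fail once per leaf
    for (int r = 0; r < nRef; ++r) {
      int a = 0, b = 0;
      bool reachable = true;
      for (int c = c0; c < c1; ++c) {
        const int f = consFeat[c];
        // xgboost evaluates split conditions in float32; replicate the
        // cast so leaf membership matches the booster bit-for-bit
        const float xv = (float)x[f];
        const float lo = (float)consLo[c], hi = (float)consHi[c];
        const bool xin = (xv >= lo) && (xv < hi);
        const float rv = (float)refs(r, f);
        const bool rin = (rv >= lo) && (rv < hi);
        if (xin && !rin) setX[a++] = f;
        else if (!xin && rin) setR[b++] = f;
        else if (!xin && !rin) { reachable = false; break; }
      }
      if (!reachable || (a == 0 && b == 0)) continue;
      const double denom = fact[a + b];
      if (a > 0) {
        const double w = val * fact[a - 1] * fact[b] / denom;
        for (int i = 0; i < a; ++i) phi[setX[i]] += w;
      }
      if (b > 0) {
        const double w = val * fact[a] * fact[b - 1] / denom;
        for (int i = 0; i < b; ++i) phi[setR[i]] -= w;
      }
    }
  }
  for (int f = 0; f < nFeat; ++f) phi[f] /= nRef;
  return phi;
}

// Ensemble output (sum of reached leaf values) per row, from the same
// leaf-constraint representation; used to anchor base value and f(x) in
// double precision.
// [[Rcpp::export]]
NumericVector treeSumCpp(IntegerVector leafConsStart,
                         NumericVector leafValue,
                         IntegerVector consFeat,
                         NumericVector consLo,
                         NumericVector consHi,
                         NumericMatrix X) {
  const int nLeaf = leafValue.size();
  const int nRow = X.nrow();
  NumericVector out(nRow);
  for (int i = 0; i < nRow; ++i) {
    double s = 0.0;
    for (int l = 0; l < nLeaf; ++l) {
      bool in = true;
      for (int c = leafConsStart[l]; c < leafConsStart[l + 1]; ++c) {
        const float v = (float)X(i, consFeat[c]);
        if (v < (float)consLo[c] || v >= (float)consHi[c]) { in = false; break; }
      }
      if (in) s += leafValue[l];
    }
    out[i] = s;
  }
  return out;
}
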