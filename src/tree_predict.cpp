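#include <Rcpp.h>
using namespace Rcpp;

// Route one row of X through a tree encoded as parallel node arrays.
// Convention (from the extracted ensemble): nodes are 0-based; `splitvar`
// holds the 0-based column index at internal nodes and -1 at leaves;
// x <= splitval goes to the left child; `pred` holds the leaf class
// (0/1) at leaves and -1 elsewhere.
static inline int route(const NumericMatrix& X, int row,
                        const IntegerVector& left, const IntegerVector& right,
                        const IntegerVector& splitvar, const NumericVector& splitval,
                        const IntegerVector& pred,
                        int replace_col, const NumericVector& replace_vals) {
  int node = 0;
  while (splitvar[node] >= 0) {
    int v = splitvar[node];
    double x = (v == replace_col) ? replace_vals[row] : X(row, v);
    node = (x <= splitval[node]) ? left[node] : right[node];
  }
  return pred[node];
}

// [[Rcpp::export(name = ".tree_predict_cpp")]]
IntegerVector tree_predict_cpp(NumericMatrix X, IntegerVector left,
                               IntegerVector right, IntegerVector splitvar,
                               NumericVector splitval, IntegerVector pred) {
  int n = X.nrow();
  IntegerVector out(n);
  NumericVector dummy(0);
  for (int i = 0; i < n; ++i)
    out[i] = route(X, i, left, right, splitvar, splitval, pred, -1, dummy);
  return out;
}

// Predict with column `col` (0-based) virtually replaced by `vals`;
// avoids copying the matrix once per permutation.
// [[Rcpp::export(name = ".tree_predict_replace_cpp")]]
IntegerVector tree_predict_replace_cpp(NumericMatrix X, IntegerVector left,
                                       IntegerVector right, IntegerVector splitvar,
                                       NumericVector splitval, IntegerVector pred,
                                       int col, NumericVector vals) {
  int n = X.nrow();
  if (vals.size() != n) stop("replacement column length mismatch");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = route(X, i, left, right, splitvar, splitval, pred, col, vals);
  return out;
}

// Votes for class 1 accumulated over a list of trees (each a list with
// elements left, right, splitvar, splitval, pred).
// [[Rcpp::export(name = ".forest_votes_cpp")]]
IntegerVector forest_votes_cpp(NumericMatrix X, List trees) {
  int n = X.nrow(), B = trees.size();
  IntegerVector votes(n);
  NumericVector dummy(0);
  for (int b = 0; b < B; ++b) {
    List tr = trees[b];
    IntegerVector left = tr["left"], right = tr["right"],
                  splitvar = tr["splitvar"], pred = tr["pred"];
    NumericVector splitval = tr["splitval"];
    for (int i = 0; i < n; ++i)
      votes[i] += route(X, i, left, right, splitvar, splitval, pred, -1, dummy);
  }
  return votes;
}
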