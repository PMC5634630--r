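#include <Rcpp.h>
using namespace Rcpp;

// Sum of squared errors and analytic gradient for the pseudolinear rate
// model  pred_i = max(0, sum_j k_j * pos(X_ij + b_j))           (threshold)
//        pred_i = max(0, sum_j k_j * (pos(X_ij) + b_j))         (as printed)
// with optional competing-influence evaluation for the 2-component force
// model (the smaller of two simultaneously supra-threshold components is
// zeroed; ties keep component 1). theta = (k_1..k_p, b_1..b_p).
// Gradients at rectifier kinks use the right-hand subgradient.

// [[Rcpp::export(name = ".sse_objective")]]
List sse_objective(NumericVector theta, NumericMatrix X, NumericVector y,
                   bool threshold_form, bool competing,
                   double comp_threshold) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (theta.size() != 2 * p)
    stop("theta must have length 2 * ncol(X)");
  if (competing && p != 2)
    stop("competing evaluation needs exactly 2 components");

  std::vector<double> k(p), b(p), gk(p, 0.0), gb(p, 0.0);
  for (int j = 0; j < p; ++j) {
    k[j] = theta[j];
    b[j] = theta[p + j];
  }

  double sse = 0.0;
  std::vector<double> comp(p), zval(p);
  std::vector<int> active(p); // d comp_j / d b_j carries k_j iff active

  for (int i = 0; i < n; ++i) {
    double g = 0.0;
    for (int j = 0; j < p; ++j) {
      double x = X(i, j);
      double z, c;
      int act;
      if (threshold_form) {
        double u = x + b[j];
        z = u > 0.0 ? u : 0.0;
        act = u > 0.0 ? 1 : 0;
        c = k[j] * z;
      } else {
        z = (x > 0.0 ? x : 0.0) + b[j];
        act = 1;
        c = k[j] * z;
      }
      comp[j] = c;
      zval[j] = z;
      active[j] = act;
    }

    bool keep[2] = {true, true};
    if (competing) {
      if (comp[0] > comp_threshold && comp[1] > comp_threshold) {
        if (std::abs(comp[1]) > std::abs(comp[0]))
          keep[0] = false; // dF/dt wins strictly
        else
          keep[1] = false; // force kept on ties
      }
      g = (keep[0] ? comp[0] : 0.0) + (keep[1] ? comp[1] : 0.0);
    } else {
      for (int j = 0; j < p; ++j) g += comp[j];
    }

    double pred = g > 0.0 ? g : 0.0;
    double r = pred - y[i];
    sse += r * r;
    if (g >= 0.0) { // right subgradient at the output kink
      double w = 2.0 * r;
      for (int j = 0; j < p; ++j) {
        if (competing && !keep[j]) continue;
        gk[j] += w * zval[j];
        if (active[j]) gb[j] += w * k[j];
      }
    }
  }

  NumericVector grad(2 * p);
  for (int j = 0; j < p; ++j) {
    grad[j] = gk[j];
    grad[p + j] = gb[j];
  }
  return List::create(_["value"] = sse, _["gradient"] = grad);
}

// Predicted rates under the same conventions (used by fast evaluation of
// held-out cost without rebuilding R-level sweeps).
// [[Rcpp::export(name = ".pseudolinear_pred")]]
NumericVector pseudolinear_pred(NumericVector theta, NumericMatrix X,
                                bool threshold_form, bool competing,
                                double comp_threshold) {
  const int n = X.nrow();
  const int p = X.ncol();
  if (theta.size() != 2 * p)
    stop("theta must have length 2 * ncol(X)");
  NumericVector out(n);
  std::vector<double> comp(p);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < p; ++j) {
      double x = X(i, j);
      double z;
      if (threshold_form) {
        double u = x + theta[p + j];
        z = u > 0.0 ? u : 0.0;
      } else {
        z = (x > 0.0 ? x : 0.0) + theta[p + j];
      }
      comp[j] = theta[j] * z;
    }
    double g = 0.0;
    if (competing && p == 2) {
      bool keep0 = true, keep1 = true;
      if (comp[0] > comp_threshold && comp[1] > comp_threshold) {
        if (std::abs(comp[1]) > std::abs(comp[0]))
          keep0 = false;
        else
          keep1 = false;
      }
      g = (keep0 ? comp[0] : 0.0) + (keep1 ? comp[1] : 0.0);
    } else {
      for (int j = 0; j < p; ++j) g += comp[j];
    }
    out[i] = g > 0.0 ? g : 0.0;
  }
  return out;
}
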