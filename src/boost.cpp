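// AdaBoost on depth-1 decision stumps, plus the greedy sequential forward
// feature-selection loop. Kept in C++ because selection evaluates tens of
// thousands of boosted fits; the stump search is O(n) per feature per round
// given cached sort orders.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Stump {
  int j;        // column index (0-based) into the fitting matrix
  double thr;
  int pol;      // +1: predict +1 when x > thr; -1: flipped
  double alpha;
};

// Sort order (ascending) of each requested column.
static std::vector<std::vector<int>> col_orders(const NumericMatrix& X,
                                                const std::vector<int>& cols) {
  int n = X.nrow();
  std::vector<std::vector<int>> ord(X.ncol());
  for (int j : cols) {
    std::vector<int>& o = ord[j];
    o.resize(n);
    for (int i = 0; i < n; ++i) o[i] = i;
    const double* xj = &X(0, j);
    std::stable_sort(o.begin(), o.end(),
                     [xj](int a, int b) { return xj[a] < xj[b]; });
  }
  return ord;
}

// Best stump over the given columns for weights w. Deterministic
// tie-breaking: first column in `cols` order, then smallest threshold.
static bool best_stump(const NumericMatrix& X, const IntegerVector& y,
                       const std::vector<double>& w,
                       const std::vector<std::vector<int>>& ord,
                       const std::vector<int>& cols, Stump& out) {
  int n = X.nrow();
  double wTot = 0, wNeg = 0;
  for (int i = 0; i < n; ++i) {
    wTot += w[i];
    if (y[i] < 0) wNeg += w[i];
  }
  double bestErr = R_PosInf;
  for (int j : cols) {
    const std::vector<int>& o = ord[j];
    const double* xj = &X(0, j);
    // polarity +1, left side (predicted -1) initially empty
    double err = wNeg;
    // k = 0 split (threshold below the minimum)
    {
      double cand[2] = {err, wTot - err};
      for (int s = 0; s < 2; ++s) {
        if (cand[s] < bestErr - 1e-15) {
          bestErr = cand[s];
          out.j = j; out.thr = xj[o[0]] - 1.0;
          out.pol = s == 0 ? 1 : -1;
        }
      }
    }
    for (int k = 1; k <= n; ++k) {
      int i = o[k - 1];
      err += (y[i] > 0) ? w[i] : -w[i];
      bool valid = (k == n) || (xj[o[k - 1]] < xj[o[k]]);
      if (!valid) continue;
      double thr = (k == n) ? xj[o[n - 1]] + 1.0
                            : 0.5 * (xj[o[k - 1]] + xj[o[k]]);
      double cand[2] = {err, wTot - err};
      for (int s = 0; s < 2; ++s) {
        if (cand[s] < bestErr - 1e-15) {
          bestErr = cand[s];
          out.j = j; out.thr = thr; out.pol = s == 0 ? 1 : -1;
        }
      }
    }
  }
  out.alpha = bestErr / wTot;  // store the weighted error rate here for now
  return R_finite(bestErr);
}

static std::vector<Stump> fit_core(const NumericMatrix& X,
                                   const IntegerVector& y,
                                   const std::vector<std::vector<int>>& ord,
                                   const std::vector<int>& cols,
                                   int rounds, double lr) {
  int n = X.nrow();
  std::vector<double> w(n, 1.0 / n);
  std::vector<Stump> model;
  for (int t = 0; t < rounds; ++t) {
    Stump st;
    if (!best_stump(X, y, w, ord, cols, st)) break;
    double err = st.alpha;  // weighted error rate from best_stump
    if (err >= 0.5 - 1e-12) break;          // no better than chance
    double errC = std::max(err, 1e-12);
    st.alpha = lr * 0.5 * std::log((1.0 - errC) / errC);
    model.push_back(st);
    if (err < 1e-12) break;                 // perfect stump: margins fixed
    const double* xj = &X(0, st.j);
    double wSum = 0;
    for (int i = 0; i < n; ++i) {
      int h = ((xj[i] > st.thr) ? 1 : -1) * st.pol;
      w[i] *= std::exp(-st.alpha * y[i] * h);
      wSum += w[i];
    }
    for (int i = 0; i < n; ++i) w[i] /= wSum;
  }
  return model;
}

static NumericVector margin_core(const std::vector<Stump>& model,
                                 const NumericMatrix& X,
                                 const std::vector<int>& colMap) {
  int n = X.nrow();
  NumericVector m(n);
  for (const Stump& st : model) {
    int col = colMap.empty() ? st.j : colMap[st.j];
    for (int i = 0; i < n; ++i)
      m[i] += st.alpha * (((X(i, col) > st.thr) ? 1 : -1) * st.pol);
  }
  return m;
}

static List model_to_list(const std::vector<Stump>& model) {
  int T = model.size();
  IntegerVector j(T), pol(T);
  NumericVector thr(T), alpha(T);
  for (int t = 0; t < T; ++t) {
    j[t] = model[t].j + 1;
    thr[t] = model[t].thr;
    pol[t] = model[t].pol;
    alpha[t] = model[t].alpha;
  }
  return List::create(_["feature"] = j, _["threshold"] = thr,
                      _["polarity"] = pol, _["alpha"] = alpha);
}

static std::vector<Stump> model_from_list(const List& model) {
  IntegerVector j = model["feature"], pol = model["polarity"];
  NumericVector thr = model["threshold"], alpha = model["alpha"];
  std::vector<Stump> out(j.size());
  for (int t = 0; t < j.size(); ++t)
    out[t] = Stump{j[t] - 1, thr[t], pol[t], alpha[t]};
  return out;
}

// [[Rcpp::export]]
List cpp_boost_fit(NumericMatrix X, IntegerVector y, int rounds, double lr) {
  std::vector<int> cols(X.ncol());
  for (int j = 0; j < X.ncol(); ++j) cols[j] = j;
  auto ord = col_orders(X, cols);
  return model_to_list(fit_core(X, y, ord, cols, rounds, lr));
}

// [[Rcpp::export]]
NumericVector cpp_boost_margin(List model, NumericMatrix X) {
  return margin_core(model_from_list(model), X, std::vector<int>());
}

// Pooled confusion counts -> (accuracy, mcc)
static void acc_mcc(double tp, double fp, double tn, double fn,
                    double& acc, double& mcc) {
  double tot = tp + fp + tn + fn;
  acc = (tp + tn) / tot;
  double den = std::sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn));
  mcc = den > 0 ? (tp * tn - fp * fn) / den : 0.0;
}

// Greedy sequential forward selection of at most maxFeatures columns.
// trainX/testX are per-fold matrices over the SAME full feature set
// (already scaled and oversampled); labels are +1 (positive class) / -1.
// Score = pooled CV accuracy; ties broken by pooled MCC, then first column.
// [[Rcpp::export]]
List cpp_sfs(List trainX, List trainY, List testX, List testY,
             int maxFeatures, int rounds, double lr) {
  int F = trainX.size();
  std::vector<NumericMatrix> Xtr(F), Xte(F);
  std::vector<IntegerVector> ytr(F), yte(F);
  for (int f = 0; f < F; ++f) {
    Xtr[f] = as<NumericMatrix>(trainX[f]);
    Xte[f] = as<NumericMatrix>(testX[f]);
    ytr[f] = as<IntegerVector>(trainY[f]);
    yte[f] = as<IntegerVector>(testY[f]);
  }
  int p = Xtr[0].ncol();
  std::vector<int> all(p);
  for (int j = 0; j < p; ++j) all[j] = j;
  std::vector<std::vector<std::vector<int>>> ord(F);
  for (int f = 0; f < F; ++f) ord[f] = col_orders(Xtr[f], all);

  std::vector<int> selected;
  std::vector<bool> used(p, false);
  int nSteps = std::min(maxFeatures, p);
  NumericVector stepAcc(nSteps), stepMcc(nSteps);
  IntegerVector orderOut(nSteps);

  for (int step = 0; step < nSteps; ++step) {
    double bestAcc = -1, bestMcc = -2;
    int bestJ = -1;
    std::vector<int> cand(selected);
    cand.push_back(-1);
    for (int j = 0; j < p; ++j) {
      if (used[j]) continue;
      cand.back() = j;
      double tp = 0, fp = 0, tn = 0, fn = 0;
      for (int f = 0; f < F; ++f) {
        auto model = fit_core(Xtr[f], ytr[f], ord[f], cand, rounds, lr);
        NumericVector m = margin_core(model, Xte[f], std::vector<int>());
        for (int i = 0; i < m.size(); ++i) {
          int pred = m[i] > 0 ? 1 : -1;
          if (yte[f][i] > 0) { if (pred > 0) ++tp; else ++fn; }
          else               { if (pred > 0) ++fp; else ++tn; }
        }
      }
      double acc, mcc;
      acc_mcc(tp, fp, tn, fn, acc, mcc);
      if (acc > bestAcc + 1e-12 ||
          (std::abs(acc - bestAcc) <= 1e-12 && mcc > bestMcc + 1e-12)) {
        bestAcc = acc; bestMcc = mcc; bestJ = j;
      }
    }
    selected.push_back(bestJ);
    used[bestJ] = true;
    orderOut[step] = bestJ + 1;
    stepAcc[step] = bestAcc;
    stepMcc[step] = bestMcc;
  }
  return List::create(_["order"] = orderOut, _["accuracy"] = stepAcc,
                      _["mcc"] = stepMcc);
}
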