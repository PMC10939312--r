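#include <Rcpp.h>
using namespace Rcpp;

// Helpers for the biological-plausibility screen of modulated neural response
// spaces. The expensive part of the screen is the minimum-response criterion:
// for every candidate expected position x_j in the (clipped) feature grid, the
// summed modulated population response must stay above a threshold at every
// grid position x. The scans below enumerate (a, b) combinations and report,
// per combination, whether any (x_j, x) pair drops below the threshold.
//
// All population activities are non-negative, so partial sums can early-exit
// as soon as they reach the threshold. Populations are visited in decreasing
// order of unmodulated activity at x, which makes the early exit bite after
// one or two terms for most grid positions.

static void order_by_column_desc(const NumericMatrix &M, std::vector<int> &ord) {
  const int npop = M.nrow(), nx = M.ncol();
  ord.resize((size_t)npop * nx);
  std::vector<std::pair<double, int> > buf(npop);
  for (int x = 0; x < nx; ++x) {
    for (int i = 0; i < npop; ++i) buf[i] = std::make_pair(-M(i, x), i);
    std::sort(buf.begin(), buf.end());
    for (int i = 0; i < npop; ++i) ord[(size_t)x * npop + i] = buf[i].second;
  }
}

static inline double supp_factor(double d, double a, double b, int dist_type) {
  // dist_type: 0 = local, 1 = remote
  double r = std::fabs(d / b) * (1.0 - a);
  if (dist_type == 0) {
    double c = a + r;
    return c < 1.0 ? c : 1.0;
  }
  double c = 1.0 - r;
  return c > a ? c : a;
}

// Gain modulation: S_mod(x; x_j) = sum_i c(i, x_j) * G(i, x).
// [[Rcpp::export]]
LogicalVector crit2_scan_gain(NumericMatrix G, NumericMatrix Dxj,
                              NumericVector a, NumericVector b,
                              int dist_type, double thr,
                              IntegerVector eval_idx) {
  const int npop = G.nrow(), nxj = Dxj.ncol(), ncomb = a.size(),
            nx = eval_idx.size();
  std::vector<int> ord;
  order_by_column_desc(G, ord);
  LogicalVector fail(ncomb);
  std::vector<double> c(npop);
  for (int k = 0; k < ncomb; ++k) {
    bool bad = false;
    for (int j = 0; j < nxj && !bad; ++j) {
      for (int i = 0; i < npop; ++i)
        c[i] = supp_factor(Dxj(i, j), a[k], b[k], dist_type);
      for (int xi = 0; xi < nx; ++xi) {
        const int x = eval_idx[xi] - 1;
        const int *po = &ord[(size_t)x * npop];
        double s = 0.0;
        for (int i = 0; i < npop; ++i) {
          s += c[po[i]] * G(po[i], x);
          if (s >= thr) break;
        }
        if (s < thr) { bad = true; break; }
      }
    }
    fail[k] = bad;
  }
  return fail;
}

// Tuning modulation: curve i is re-evaluated with width c(i, x_j) * sigma.
// T holds the width-free curve shape (see build_bank); activity is
// exp(T(i, x) / w^power) with w the modulated width.
// [[Rcpp::export]]
LogicalVector crit2_scan_tuning(NumericMatrix T, NumericMatrix Dxj,
                                NumericVector a, NumericVector b,
                                int dist_type, double sigma, double power,
                                double thr, IntegerVector eval_idx) {
  const int npop = T.nrow(), nxj = Dxj.ncol(), ncomb = a.size(),
            nx = eval_idx.size();
  std::vector<int> ord;
  order_by_column_desc(T, ord);
  LogicalVector fail(ncomb);
  std::vector<double> rate(npop);
  for (int k = 0; k < ncomb; ++k) {
    bool bad = false;
    for (int j = 0; j < nxj && !bad; ++j) {
      for (int i = 0; i < npop; ++i) {
        double w = supp_factor(Dxj(i, j), a[k], b[k], dist_type) * sigma;
        rate[i] = 1.0 / std::pow(w, power);
      }
      for (int xi = 0; xi < nx; ++xi) {
        const int x = eval_idx[xi] - 1;
        const int *po = &ord[(size_t)x * npop];
        double s = 0.0;
        for (int i = 0; i < npop; ++i) {
          s += std::exp(T(po[i], x) * rate[po[i]]);
          if (s >= thr) break;
        }
        if (s < thr) { bad = true; break; }
      }
    }
    fail[k] = bad;
  }
  return fail;
}

// Minimum over the evaluated grid of the summed response when every
// population is narrowed to the same width (global tuning; also the exact
// lower bound for local/remote tuning at the same a).
// [[Rcpp::export]]
double min_summed_tuning(NumericMatrix T, double width, double power,
                         IntegerVector eval_idx) {
  const int npop = T.nrow(), nx = eval_idx.size();
  const double rate = 1.0 / std::pow(width, power);
  double mn = R_PosInf;
  for (int xi = 0; xi < nx; ++xi) {
    const int x = eval_idx[xi] - 1;
    double s = 0.0;
    for (int i = 0; i < npop; ++i) s += std::exp(T(i, x) * rate);
    if (s < mn) mn = s;
  }
  return mn;
}

// 4-connected component labelling of a binary mask (used by the shape
// complexity metrics to count concavities without an image-analysis
// dependency).
// [[Rcpp::export]]
IntegerMatrix label_components(LogicalMatrix mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j)) continue;
      ++next;
      stack.push_back(i + j * nr);
      lab(i, j) = next;
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pi = p % nr, pj = p / nr;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int q = 0; q < 4; ++q) {
          int qi = pi + di[q], qj = pj + dj[q];
          if (qi < 0 || qi >= nr || qj < 0 || qj >= nc) continue;
          if (mask(qi, qj) && !lab(qi, qj)) {
            lab(qi, qj) = next;
            stack.push_back(qi + qj * nr);
          }
        }
      }
    }
  }
  return lab;
}
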