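#include <Rcpp.h>
using namespace Rcpp;

// Felsenstein pruning for a fixed (possibly multifurcating) topology under
// JC69 or K80, with per-edge maximum-likelihood branch lengths obtained by
// coordinate-wise Brent optimisation. Polytomies are handled natively: a
// node's partial likelihood is the product over all its child edges.
//
// Node numbering (0-based): tips 0..ntip-1, internal nodes follow. Tips
// carry pattern states coded 0=A,1=C,2=G,3=T,4=missing (missing ->
// uninformative partial of all ones).

struct TransProb { double same, ti, tv; };

static inline TransProb ptrans(double t, int model, double kappa) {
  TransProb p;
  if (model == 0) {                      // JC69
    double e = std::exp(-4.0 * t / 3.0);
    p.same = 0.25 + 0.75 * e;
    p.ti = p.tv = 0.25 - 0.25 * e;
  } else {                               // K80
    double k = kappa;
    double e1 = std::exp(-4.0 * t / (k + 2.0));
    double e2 = std::exp(-2.0 * t * (k + 1.0) / (k + 2.0));
    p.tv = 0.25 - 0.25 * e1;
    p.ti = 0.25 + 0.25 * e1 - 0.5 * e2;
    p.same = 0.25 + 0.25 * e1 + 0.5 * e2;
  }
  return p;
}

// transition partner under A,C,G,T coding: A<->G, C<->T
static inline int tipartner(int x) { return x ^ 2; }

class Pruner {
public:
  int ntip, nnode, npat;
  std::vector<std::vector<int>> children;    // per internal node
  std::vector<std::vector<int>> child_edges; // per internal node
  std::vector<int> postorder;                // internal node ids
  IntegerMatrix tipstate;                    // npat x ntip
  NumericVector weights;
  int model; double kappa;
  std::vector<std::vector<double>> part;     // per internal node: npat*4
  std::vector<double> logscale;              // per pattern, current eval

  Pruner(List ch, List che, IntegerVector post, IntegerMatrix ts,
         NumericVector w, int model_, double kappa_)
    : tipstate(ts), weights(w), model(model_), kappa(kappa_) {
    ntip = ts.ncol(); npat = ts.nrow();
    nnode = ntip + ch.size();
    children.resize(ch.size());
    child_edges.resize(ch.size());
    for (int i = 0; i < ch.size(); ++i) {
      children[i] = as<std::vector<int>>(ch[i]);
      child_edges[i] = as<std::vector<int>>(che[i]);
    }
    postorder = as<std::vector<int>>(post);
    part.assign(ch.size(), std::vector<double>(npat * 4));
    logscale.resize(npat);
  }

  double loglik(const std::vector<double>& len) {
    std::fill(logscale.begin(), logscale.end(), 0.0);
    int root = postorder.back();
    for (int node : postorder) {
      int ii = node - ntip;
      std::vector<double>& P = part[ii];
      std::fill(P.begin(), P.end(), 1.0);
      const std::vector<int>& ch = children[ii];
      const std::vector<int>& ce = child_edges[ii];
      for (size_t c = 0; c < ch.size(); ++c) {
        TransProb tp = ptrans(len[ce[c]], model, kappa);
        int child = ch[c];
        if (child < ntip) {
          for (int s = 0; s < npat; ++s) {
            int st = tipstate(s, child);
            if (st >= 4) continue;       // missing: multiply by 1
            int tip_ti = tipartner(st);
            for (int x = 0; x < 4; ++x) {
              double w = (x == st) ? tp.same : (x == tip_ti ? tp.ti : tp.tv);
              P[s * 4 + x] *= w;
            }
          }
        } else {
          const std::vector<double>& V = part[child - ntip];
          for (int s = 0; s < npat; ++s) {
            const double* v = &V[s * 4];
            for (int x = 0; x < 4; ++x) {
              double w = tp.same * v[x] + tp.ti * v[tipartner(x)];
              int o1 = x ^ 1, o2 = (x ^ 1) ^ 2;  // the two transversion states
              w += tp.tv * (v[o1] + v[o2]);
              P[s * 4 + x] *= w;
            }
          }
        }
      }
      // rescale per pattern to avoid underflow
      for (int s = 0; s < npat; ++s) {
        double m = 0.0;
        for (int x = 0; x < 4; ++x) m = std::max(m, P[s * 4 + x]);
        if (m > 0 && m < 1e-200) m = 1e-200;
        if (m > 0) {
          for (int x = 0; x < 4; ++x) P[s * 4 + x] /= m;
          logscale[s] += std::log(m);
        }
      }
    }
    const std::vector<double>& R = part[root - ntip];
    double ll = 0.0;
    for (int s = 0; s < npat; ++s) {
      double site = 0.0;
      for (int x = 0; x < 4; ++x) site += 0.25 * R[s * 4 + x];
      ll += weights[s] * (std::log(site) + logscale[s]);
    }
    return ll;
  }
};

// bounded Brent maximisation of f(edge e), other lengths fixed
static double brent_edge(Pruner& pr, std::vector<double>& len, int e,
                         double lo, double hi, double tol) {
  const double gold = 0.3819660112501051;
  double a = lo, b = hi;
  double x = std::min(std::max(len[e], lo), hi), w = x, v = x;
  auto f = [&](double t) { len[e] = t; return -pr.loglik(len); };
  double fx = f(x), fw = fx, fv = fx;
  double d = 0.0, ee = 0.0;
  for (int iter = 0; iter < 100; ++iter) {
    double xm = 0.5 * (a + b);
    double tol1 = tol * std::fabs(x) + 1e-10, tol2 = 2.0 * tol1;
    if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
    double etemp = ee;
    bool parab = false;
    if (std::fabs(etemp) > tol1) {
      double r = (x - w) * (fx - fv);
      double q = (x - v) * (fx - fw);
      double p = (x - v) * q - (x - w) * r;
      q = 2.0 * (q - r);
      if (q > 0.0) p = -p;
      q = std::fabs(q);
      if (std::fabs(p) < std::fabs(0.5 * q * etemp) &&
          p > q * (a - x) && p < q * (b - x)) {
        ee = d; d = p / q;
        double u = x + d;
        if (u - a < tol2 || b - u < tol2) d = (xm >= x) ? tol1 : -tol1;
        parab = true;
      }
    }
    if (!parab) { ee = (x >= xm) ? a - x : b - x; d = gold * ee; }
    double u = (std::fabs(d) >= tol1) ? x + d : x + (d > 0 ? tol1 : -tol1);
    double fu = f(u);
    if (fu <= fx) {
      if (u >= x) a = x; else b = x;
      v = w; w = x; x = u; fv = fw; fw = fx; fx = fu;
    } else {
      if (u < x) a = u; else b = u;
      if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
      else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
    }
  }
  len[e] = x;
  return -fx;
}

// [[Rcpp::export(name = ".pruning_loglik_cpp")]]
double pruning_loglik_cpp(List children, List child_edges,
                          IntegerVector postorder, IntegerMatrix tipstate,
                          NumericVector weights, NumericVector lengths,
                          int model, double kappa) {
  Pruner pr(children, child_edges, postorder, tipstate, weights, model, kappa);
  std::vector<double> len = as<std::vector<double>>(lengths);
  return pr.loglik(len);
}

// [[Rcpp::export(name = ".pruning_optimize_cpp")]]
List pruning_optimize_cpp(List children, List child_edges,
                          IntegerVector postorder, IntegerMatrix tipstate,
                          NumericVector weights, NumericVector lengths,
                          int model, double kappa,
                          double lower, double upper, double tol,
                          int max_sweeps) {
  Pruner pr(children, child_edges, postorder, tipstate, weights, model, kappa);
  std::vector<double> len = as<std::vector<double>>(lengths);
  double ll = pr.loglik(len);
  for (int sweep = 0; sweep < max_sweeps; ++sweep) {
    double prev = ll;
    for (size_t e = 0; e < len.size(); ++e)
      ll = brent_edge(pr, len, e, lower, upper, tol);
    if (ll - prev < 1e-6) break;
  }
  return List::create(_["loglik"] = ll,
                      _["lengths"] = NumericVector(len.begin(), len.end()));
}
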