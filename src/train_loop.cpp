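// Compiled full-batch training loop. Mirrors, arithmetic step for step, the
// reference R implementation in R/trainer.R (batch_gradients + csbp_step):
// forward LIF simulation, surrogate-gradient BPTT with the reset factor
// detached, analytic chaotic gradients on masked neurons, plain gradient
// descent, geometric annealing of z. Exists so that 10^4-epoch desk-scale
// experiments over tens of seeds run in seconds.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double sigmoid(double x) {
  if (x >= 0.0) return 1.0 / (1.0 + std::exp(-x));
  double e = std::exp(x);
  return e / (1.0 + e);
}

static inline double surrogate(double u, int kind, double width) {
  if (kind == 0) {  // rectangular
    return (std::fabs(u) <= width / 2.0) ? 1.0 / width : 0.0;
  }
  double s = sigmoid(u / width);  // sigmoid_derivative
  return s * (1.0 - s) / width;
}

struct Net {
  int l;                         // number of weight layers
  std::vector<int> M;            // sizes M_0..M_l
  std::vector<std::vector<double>> w;  // per layer, column-major Mi x (M_{i-1}+1)
};

// One full-batch gradient evaluation + in-place update + anneal.
// Returns loss_bp and loss_chaos of the pre-update weights.
static void csbp_epoch(Net &net,
                       const std::vector<NumericMatrix> &inputs,
                       const NumericMatrix &targets,
                       double k_tau, double v_th, int T,
                       int sg_kind, double sg_width, int loss_kind,
                       double eta, double z, double I0,
                       const std::vector<std::vector<int>> &mask0, // 0-based rows
                       bool chaos_bias,
                       std::vector<std::vector<double>> &grad,   // scratch
                       std::vector<std::vector<double>> &O,      // scratch, layers 0..l
                       std::vector<std::vector<double>> &V,      // scratch, layers 1..l
                       std::vector<std::vector<double>> &dV,     // scratch
                       double &loss_bp_out, double &loss_ch_out) {
  const int l = net.l;
  const int n = (int)inputs.size();
  const int Ml = net.M[l];
  bool any_chaos = false;
  if (z > 0.0)
    for (int i = 0; i < l; ++i) if (!mask0[i].empty()) any_chaos = true;

  for (int i = 0; i < l; ++i)
    std::fill(grad[i].begin(), grad[i].end(), 0.0);
  double loss_bp = 0.0, loss_ch = 0.0;
  std::vector<double> rates(Ml), dO_out(Ml);

  for (int nn = 0; nn < n; ++nn) {
    const NumericMatrix &inp = inputs[nn];
    // forward: O[0] = input
    for (int t = 0; t < T; ++t)
      for (int j = 0; j < net.M[0]; ++j)
        O[0][j + net.M[0] * t] = inp(j, t);
    for (int t = 0; t < T; ++t) {
      for (int i = 0; i < l; ++i) {
        const int Mi = net.M[i + 1], Mp = net.M[i];
        const std::vector<double> &wi = net.w[i];
        for (int j = 0; j < Mi; ++j) {
          double drive = wi[j];  // bias column k=0
          for (int k = 0; k < Mp; ++k)
            drive += wi[j + Mi * (k + 1)] * O[i][k + Mp * t];
          double v = drive;
          if (t > 0)
            v = k_tau * V[i][j + Mi * (t - 1)] *
                (1.0 - O[i + 1][j + Mi * (t - 1)]) + drive;
          V[i][j + Mi * t] = v;
          O[i + 1][j + Mi * t] = (v >= v_th) ? 1.0 : 0.0;
        }
      }
    }
    // loss on output rates
    for (int j = 0; j < Ml; ++j) {
      double s = 0.0;
      for (int t = 0; t < T; ++t) s += O[l][j + Ml * t];
      rates[j] = s / T;
    }
    double sample_loss = 0.0;
    for (int j = 0; j < Ml; ++j) {
      double tgt = targets(j, nn);
      if (loss_kind == 0) {  // mse_rate
        double d = rates[j] - tgt;
        sample_loss += d * d / Ml;
        dO_out[j] = 2.0 * d / Ml / T;
      } else {               // cross_entropy_rate
        double rc = std::min(std::max(rates[j], 1e-12), 1.0 - 1e-12);
        sample_loss += -(tgt * std::log(rc) + (1.0 - tgt) * std::log(1.0 - rc)) / Ml;
        dO_out[j] = (-tgt / rc + (1.0 - tgt) / (1.0 - rc)) / Ml / T;
      }
    }
    loss_bp += sample_loss / n;
    // backward, layers l..1, reset factor detached
    for (int i = l - 1; i >= 0; --i) {
      const int Mi = net.M[i + 1], Mp = net.M[i];
      for (int t = T - 1; t >= 0; --t) {
        for (int j = 0; j < Mi; ++j) {
          double dO;
          if (i == l - 1) {
            dO = dO_out[j];
          } else {
            const int Mn = net.M[i + 2];
            const std::vector<double> &wn = net.w[i + 1];
            dO = 0.0;
            for (int r = 0; r < Mn; ++r)
              dO += wn[r + Mn * (j + 1)] * dV[i + 1][r + Mn * t];
          }
          double dv = dO * surrogate(V[i][j + Mi * t] - v_th, sg_kind, sg_width);
          if (t < T - 1)
            dv += dV[i][j + Mi * (t + 1)] * k_tau *
                  (1.0 - O[i + 1][j + Mi * t]);
          dV[i][j + Mi * t] = dv;
        }
      }
      // grad += deltaV %*% t(presyn) / n
      std::vector<double> &gi = grad[i];
      for (int j = 0; j < Mi; ++j) {
        for (int k = 0; k <= Mp; ++k) {
          double acc = 0.0;
          for (int t = 0; t < T; ++t) {
            double pre = (k == 0) ? 1.0 : O[i][(k - 1) + Mp * t];
            acc += dV[i][j + Mi * t] * pre;
          }
          gi[j + Mi * k] += acc / n;
        }
      }
    }
    // chaotic gradients of masked neurons at intensity z
    if (any_chaos) {
      for (int i = 0; i < l; ++i) {
        if (mask0[i].empty()) continue;
        const int Mi = net.M[i + 1], Mp = net.M[i];
        std::vector<double> s(Mp + 1);
        s[0] = 1.0;
        for (int k = 0; k < Mp; ++k) {
          double acc = 0.0;
          for (int t = 0; t < T; ++t) acc += O[i][k + Mp * t];
          s[k + 1] = acc / T;
        }
        const std::vector<double> &wi = net.w[i];
        for (int jj : mask0[i]) {
          double dot = 0.0;
          for (int k = 0; k <= Mp; ++k) dot += wi[jj + Mi * k] * s[k];
          double h = sigmoid(dot);
          double hc = std::min(std::max(h, 1e-12), 1.0 - 1e-12);
          loss_ch += -z * (I0 * std::log(hc) +
                           (1.0 - I0) * std::log(1.0 - hc)) / n;
          int k0 = chaos_bias ? 0 : 1;
          for (int k = k0; k <= Mp; ++k)
            grad[i][jj + Mi * k] += -z * (I0 - h) * s[k] / n;
        }
      }
    }
  }
  // gradient-descent update
  for (int i = 0; i < l; ++i)
    for (size_t p = 0; p < net.w[i].size(); ++p)
      net.w[i][p] -= eta * grad[i][p];
  loss_bp_out = loss_bp;
  loss_ch_out = loss_ch;
}

// [[Rcpp::export]]
List csbp_train_cpp(List w0, List inputs_, NumericMatrix targets,
                    double k_tau, double v_th, int T,
                    int sg_kind, double sg_width, int loss_kind,
                    double eta, double z0, double beta, double I0,
                    List mask_, bool chaos_bias, int epochs,
                    IntegerMatrix track, bool record_weights) {
  Net net;
  net.l = w0.size();
  net.M.resize(net.l + 1);
  net.w.resize(net.l);
  for (int i = 0; i < net.l; ++i) {
    NumericMatrix wi = w0[i];
    if (i == 0) net.M[0] = wi.ncol() - 1;
    net.M[i + 1] = wi.nrow();
    net.w[i].assign(wi.begin(), wi.end());
  }
  std::vector<NumericMatrix> inputs;
  for (int k = 0; k < inputs_.size(); ++k)
    inputs.push_back(as<NumericMatrix>(inputs_[k]));
  std::vector<std::vector<int>> mask0(net.l);
  for (int i = 0; i < net.l; ++i) {
    IntegerVector mi = mask_[i];
    for (int v : mi) mask0[i].push_back(v - 1);
  }
  // scratch buffers
  std::vector<std::vector<double>> grad(net.l), O(net.l + 1), V(net.l), dV(net.l);
  O[0].assign((size_t)net.M[0] * T, 0.0);
  for (int i = 0; i < net.l; ++i) {
    grad[i].assign(net.w[i].size(), 0.0);
    O[i + 1].assign((size_t)net.M[i + 1] * T, 0.0);
    V[i].assign((size_t)net.M[i + 1] * T, 0.0);
    dV[i].assign((size_t)net.M[i + 1] * T, 0.0);
  }
  int ntrack = track.nrow();
  int nw = 0;
  for (int i = 0; i < net.l; ++i) nw += (int)net.w[i].size();
  NumericMatrix log(epochs, 4 + ntrack);
  NumericMatrix hist = record_weights ? NumericMatrix(epochs, nw)
                                      : NumericMatrix(0, 0);
  double z = z0;
  for (int ep = 0; ep < epochs; ++ep) {
    double lb, lc;
    double z_used = z;
    csbp_epoch(net, inputs, targets, k_tau, v_th, T, sg_kind, sg_width,
               loss_kind, eta, z, I0, mask0, chaos_bias,
               grad, O, V, dV, lb, lc);
    z *= beta;
    log(ep, 0) = ep;
    log(ep, 1) = z_used;
    log(ep, 2) = lb;
    log(ep, 3) = lc;
    for (int q = 0; q < ntrack; ++q) {
      int li = track(q, 0) - 1, row = track(q, 1) - 1, col = track(q, 2);
      log(ep, 4 + q) = net.w[li][row + net.M[li + 1] * col];
    }
    if (record_weights) {
      int off = 0;
      for (int i = 0; i < net.l; ++i) {
        for (size_t p = 0; p < net.w[i].size(); ++p)
          hist(ep, off + (int)p) = net.w[i][p];
        off += (int)net.w[i].size();
      }
    }
    if (!std::isfinite(lb)) stop("non-finite loss at epoch %d", ep);
  }
  List wout(net.l);
  for (int i = 0; i < net.l; ++i) {
    NumericMatrix wi(net.M[i + 1], net.M[i] + 1);
    std::copy(net.w[i].begin(), net.w[i].end(), wi.begin());
    wout[i] = wi;
  }
  return List::create(_["log"] = log, _["weights"] = wout,
                      _["weights_hist"] = record_weights ? (SEXP)hist : R_NilValue);
}

// One application of the frozen-z full-batch update map to a flat weight
// vector. Used by the dynamical-systems tools (Lyapunov windows, fixed
// points) where the map must be evaluated thousands of times.
// [[Rcpp::export]]
NumericVector csbp_map_cpp(NumericVector wflat, IntegerVector layer_sizes,
                           List inputs_, NumericMatrix targets,
                           double k_tau, double v_th, int T,
                           int sg_kind, double sg_width, int loss_kind,
                           double eta, double z, double I0,
                           List mask_, bool chaos_bias) {
  Net net;
  net.l = layer_sizes.size() - 1;
  net.M.assign(layer_sizes.begin(), layer_sizes.end());
  net.w.resize(net.l);
  int off = 0;
  for (int i = 0; i < net.l; ++i) {
    int sz = net.M[i + 1] * (net.M[i] + 1);
    net.w[i].assign(wflat.begin() + off, wflat.begin() + off + sz);
    off += sz;
  }
  std::vector<NumericMatrix> inputs;
  for (int k = 0; k < inputs_.size(); ++k)
    inputs.push_back(as<NumericMatrix>(inputs_[k]));
  std::vector<std::vector<int>> mask0(net.l);
  for (int i = 0; i < net.l; ++i) {
    IntegerVector mi = mask_[i];
    for (int v : mi) mask0[i].push_back(v - 1);
  }
  std::vector<std::vector<double>> grad(net.l), O(net.l + 1), V(net.l), dV(net.l);
  O[0].assign((size_t)net.M[0] * T, 0.0);
  for (int i = 0; i < net.l; ++i) {
    grad[i].assign(net.w[i].size(), 0.0);
    O[i + 1].assign((size_t)net.M[i + 1] * T, 0.0);
    V[i].assign((size_t)net.M[i + 1] * T, 0.0);
    dV[i].assign((size_t)net.M[i + 1] * T, 0.0);
  }
  double lb, lc;
  csbp_epoch(net, inputs, targets, k_tau, v_th, T, sg_kind, sg_width,
             loss_kind, eta, z, I0, mask0, chaos_bias, grad, O, V, dV, lb, lc);
  NumericVector out(wflat.size());
  off = 0;
  for (int i = 0; i < net.l; ++i) {
    std::copy(net.w[i].begin(), net.w[i].end(), out.begin() + off);
    off += (int)net.w[i].size();
  }
  return out;
}
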