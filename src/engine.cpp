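// Compiled engine for the online training / evaluation loop.
//
// Mirrors the R reference implementation exactly (same update order, same
// gradient expressions, same optimizer recurrences); the R path remains
// available and the test suite asserts numerical equivalence of the two on
// small problems. Feature maps use the channel-last flat layout the R fast
// path uses: maps are (batch, units) matrices with unit order (y, x,
// channel); inputs arrive as (T, B, ...) arrays already permuted by the R
// wrapper.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;
using arma::mat;
using arma::uvec;
using arma::vec;

namespace {

struct Layer {
  bool conv;
  mat W;      // dense: (n_out x n_in); conv: (F x C*k*k)
  vec b;
  mat Gt;     // (n_units x n_targets)
  mat Ht;     // (n_units x n_targets): backprojection uses err = dY * Ht.t()
  double dropout;
  int n_in, n_out;
  // conv geometry
  int C, H, Wd, k, pad, pool, F, Hp, Wp, Ho, Wo, Hq, Wq;
  // im2col gather indices into the padded flat map, and pool row indices
  uvec gather;
  int n_rows, n_cols;
  uvec pr[4];
  // persistent state
  mat P, Q, R, U, S;
  // optimizer state
  mat mW, uW;
  vec mb, ub;
};

void build_plan(Layer &L, int B) {
  // linear index of (b, y, x, ch) in (B, Hp, Wp, C): b + B*y + B*Hp*x +
  // B*Hp*Wp*ch; decomposes into a row part (b, oy, ox) and a column part
  // (ch, dy, dx) with channel fastest in the column order
  L.n_rows = B * L.Ho * L.Wo;
  L.n_cols = L.C * L.k * L.k;
  uvec row0(L.n_rows), col0(L.n_cols);
  int r = 0;
  for (int ox = 0; ox < L.Wo; ++ox)
    for (int oy = 0; oy < L.Ho; ++oy)
      for (int b = 0; b < B; ++b)
        row0[r++] = b + B * oy + B * L.Hp * ox;
  int c = 0;
  for (int dx = 0; dx < L.k; ++dx)
    for (int dy = 0; dy < L.k; ++dy)
      for (int ch = 0; ch < L.C; ++ch)
        col0[c++] = B * dy + B * L.Hp * dx + B * L.Hp * L.Wp * ch;
  L.gather.set_size((size_t)L.n_rows * L.n_cols);
  size_t q = 0;
  for (int j = 0; j < L.n_cols; ++j)
    for (int i = 0; i < L.n_rows; ++i)
      L.gather[q++] = row0[i] + col0[j];
  if (L.pool == 2) {
    int n = B * L.Hq * L.Wq;
    for (int p = 0; p < 4; ++p) L.pr[p].set_size(n);
    int i = 0;
    for (int px = 0; px < L.Wq; ++px)
      for (int py = 0; py < L.Hq; ++py)
        for (int b = 0; b < B; ++b) {
          L.pr[0][i] = b + B * (2 * py) + B * L.Ho * (2 * px);
          L.pr[1][i] = b + B * (2 * py + 1) + B * L.Ho * (2 * px);
          L.pr[2][i] = b + B * (2 * py) + B * L.Ho * (2 * px + 1);
          L.pr[3][i] = b + B * (2 * py + 1) + B * L.Ho * (2 * px + 1);
          ++i;
        }
  }
}

} // namespace

// [[Rcpp::export(name = ".cpp_run_network")]]
List cpp_run_network(List layers_in, NumericVector input, IntegerVector input_dim,
                     List targets, List opt_in, List cfg) {
  const int T = input_dim[0];
  const int B = input_dim[1];
  int frame_len = 1;
  for (int i = 1; i < input_dim.size(); ++i) frame_len *= input_dim[i];
  const int n_layers = layers_in.size();

  const bool training = as<bool>(cfg["training"]);
  const bool dropout_active = as<bool>(cfg["dropout_active"]);
  const double alpha = as<double>(cfg["alpha"]);
  const double beta = as<double>(cfg["beta"]);
  const double gamma = as<double>(cfg["gamma"]);
  const double rho = as<double>(cfg["rho"]);
  const int burn_steps = as<int>(cfg["burn_steps"]);
  const double eta0 = as<double>(cfg["eta"]);
  const double beta1 = as<double>(cfg["beta1"]);
  const double beta2 = as<double>(cfg["beta2"]);
  const double eps = as<double>(cfg["eps"]);
  const double lambda1 = as<double>(cfg["lambda1"]);
  const double lambda2 = as<double>(cfg["lambda2"]);
  const int loss_kind = as<int>(cfg["loss_kind"]); // 0 mse, 1 smooth_l1
  const double sched_div = as<double>(cfg["schedule_divisor"]);
  const double sched_int = as<double>(cfg["schedule_interval"]);
  const int log_every = as<int>(cfg["log_every"]);
  long n_updates = as<double>(cfg["n_updates"]);

  std::vector<Layer> L(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    List ld = layers_in[l];
    Layer &y = L[l];
    y.conv = as<int>(ld["conv"]) == 1;
    y.W = as<mat>(ld["W"]);
    y.b = as<vec>(ld["b"]);
    y.Gt = as<mat>(ld["Gt"]);
    y.Ht = as<mat>(ld["Ht"]);
    y.dropout = as<double>(ld["dropout"]);
    y.n_in = as<int>(ld["n_in"]);
    y.n_out = as<int>(ld["n_out"]);
    if (y.conv) {
      y.C = as<int>(ld["C"]); y.H = as<int>(ld["H"]); y.Wd = as<int>(ld["Wd"]);
      y.k = as<int>(ld["k"]); y.pad = as<int>(ld["pad"]); y.pool = as<int>(ld["pool"]);
      y.F = as<int>(ld["F"]);
      y.Hp = y.H + 2 * y.pad; y.Wp = y.Wd + 2 * y.pad;
      y.Ho = y.Hp - y.k + 1; y.Wo = y.Wp - y.k + 1;
      y.Hq = (y.pool == 2) ? y.Ho / 2 : y.Ho;
      y.Wq = (y.pool == 2) ? y.Wo / 2 : y.Wo;
      build_plan(y, B);
    }
    List st = ld["state"];
    y.P = as<mat>(st["P"]);
    y.Q = as<mat>(st["Q"]);
    y.R = as<mat>(st["R"]);
    y.U = as<mat>(st["U"]);
    y.S = as<mat>(st["S"]);
    if (training) {
      List ol = opt_in[l];
      y.mW = as<mat>(ol["mW"]); y.uW = as<mat>(ol["uW"]);
      y.mb = as<vec>(ol["mb"]); y.ub = as<vec>(ol["ub"]);
    }
  }

  // per-layer readout accumulators (evaluation) and spike counts of the
  // last layer
  std::vector<mat> accY(n_layers);
  for (int l = 0; l < n_layers; ++l) accY[l].zeros(B, L[l].Gt.n_cols);
  mat accS(B, L[n_layers - 1].n_out, arma::fill::zeros);

  std::vector<double> met_step, met_layer, met_loss, met_reg, met_rate;
  RNGScope rng; // dropout masks come from R's RNG stream

  const int frame_units = frame_len / B;
  mat frame(B, frame_units, arma::fill::none);
  const double *in_ptr = input.begin();

  for (int t = 0; t < T; ++t) {
    // gather the time slice: input linear index t + T*(b + B*u)
    for (int u = 0; u < frame_units; ++u)
      for (int b = 0; b < B; ++b)
        frame(b, u) = in_ptr[t + (size_t)T * (b + (size_t)B * u)];

    const bool updating = training && t >= burn_steps;
    mat S_in = frame;
    std::vector<mat> Ys(n_layers), masks(n_layers), Ms(n_layers);
    std::vector<arma::umat> pidx(n_layers);

    for (int l = 0; l < n_layers; ++l) {
      Layer &y = L[l];
      y.P = alpha * y.P + (1 - alpha) * y.Q;
      y.Q = beta * y.Q + (1 - beta) * S_in;
      mat Unew;
      if (!y.conv) {
        Unew = y.P * y.W.t() - rho * y.R;
        Unew.each_row() += y.b.t();
      } else {
        // pad, gather patches, convolve
        vec Xp;
        const vec Pv(y.P.memptr(), y.P.n_elem);
        if (y.pad > 0) {
          Xp.zeros((size_t)B * y.Hp * y.Wp * y.C);
          for (int ch = 0; ch < y.C; ++ch)
            for (int x = 0; x < y.Wd; ++x)
              for (int yy = 0; yy < y.H; ++yy) {
                size_t src = (size_t)B * (yy + (size_t)y.H * (x + (size_t)y.Wd * ch));
                size_t dst = (size_t)B * ((yy + y.pad) +
                              (size_t)y.Hp * ((x + y.pad) + (size_t)y.Wp * ch));
                std::memcpy(Xp.memptr() + dst, Pv.memptr() + src, B * sizeof(double));
              }
        } else {
          Xp = Pv;
        }
        mat M(y.n_rows, y.n_cols, arma::fill::none);
        double *mp = M.memptr();
        const double *xp = Xp.memptr();
        const arma::uword *gi = y.gather.memptr();
        const size_t nn = (size_t)y.n_rows * y.n_cols;
        for (size_t i = 0; i < nn; ++i) mp[i] = xp[gi[i]];
        mat V = M * y.W.t();
        V.each_row() += y.b.t();
        if (y.pool == 2) {
          mat v1 = V.rows(y.pr[0]), v2 = V.rows(y.pr[1]);
          mat v3 = V.rows(y.pr[2]), v4 = V.rows(y.pr[3]);
          mat pooled = arma::max(arma::max(v1, v2), arma::max(v3, v4));
          arma::umat id(pooled.n_rows, pooled.n_cols);
          for (size_t j = 0; j < pooled.n_elem; ++j) {
            double p = pooled[j];
            id[j] = (v1[j] == p) ? 1 : (v2[j] == p) ? 2 : (v3[j] == p) ? 3 : 4;
          }
          pidx[l] = id;
          Unew = mat(pooled.memptr(), B, y.n_out);
        } else {
          Unew = mat(V.memptr(), B, y.n_out);
        }
        Unew -= rho * y.R;
        if (updating) Ms[l] = M;
      }
      mat Snew = arma::conv_to<mat>::from(Unew >= 0.0);
      y.R = gamma * y.R + (1 - gamma) * Snew;
      y.U = Unew;
      y.S = Snew;
      mat Smask = Snew;
      if (y.dropout > 0 && (training || dropout_active)) {
        mat mk(B, y.n_out);
        const double scale = 1.0 / (1.0 - y.dropout);
        for (size_t j = 0; j < mk.n_elem; ++j)
          mk[j] = (unif_rand() >= y.dropout) ? scale : 0.0;
        masks[l] = mk;
        Smask = Snew % mk;
      }
      Ys[l] = Smask * y.Gt;
      S_in = Smask;
    }

    if (t >= burn_steps) {
      for (int l = 0; l < n_layers; ++l) accY[l] += Ys[l];
      accS += L[n_layers - 1].S;
    }

    if (updating) {
      double eta_t = eta0;
      if (R_finite(sched_int))
        eta_t = eta0 / std::pow(sched_div, std::floor(n_updates / sched_int));
      std::vector<double> losses(n_layers), regs(n_layers);
      for (int l = 0; l < n_layers; ++l) {
        Layer &y = L[l];
        // target slice (T, B, K) -> (B, K)
        NumericVector tg = targets[l];
        int K = y.Gt.n_cols;
        mat Yhat(B, K);
        const double *tp = tg.begin();
        for (int kk = 0; kk < K; ++kk)
          for (int b = 0; b < B; ++b)
            Yhat(b, kk) = tp[t + (size_t)T * (b + (size_t)B * kk)];
        mat D = Ys[l] - Yhat;
        double loss;
        mat dY;
        if (loss_kind == 0) {
          loss = 0.5 * arma::accu(arma::square(D)) / B;
          dY = D;
        } else {
          mat a = arma::abs(D);
          loss = 0.0;
          for (size_t j = 0; j < a.n_elem; ++j)
            loss += (a[j] <= 1.0) ? 0.5 * D[j] * D[j] : a[j] - 0.5;
          loss /= B;
          dY = arma::clamp(D, -1.0, 1.0);
        }
        mat err = dY * y.Ht.t();
        if (masks[l].n_elem) err %= masks[l];
        // regularizer on U (per batch row, averaged over neurons)
        const int n = y.n_out;
        vec mu = arma::mean(y.U, 1);
        double reg = 0.0;
        for (int b = 0; b < B; ++b) {
          double up = 0.0;
          for (int j = 0; j < n; ++j) up += std::max(y.U(b, j) + 0.01, 0.0);
          reg += lambda1 * up / n + lambda2 * std::max(0.1 - mu[b], 0.0);
        }
        reg /= B;
        mat d(B, n);
        for (int j = 0; j < n; ++j)
          for (int b = 0; b < B; ++b) {
            double u = y.U(b, j);
            double gate = (u >= -0.5 && u <= 0.5) ? 1.0 : 0.0;
            double dreg = lambda1 * ((u > -0.01) ? 1.0 : 0.0) / n -
                          lambda2 * ((mu[b] < 0.1) ? 1.0 : 0.0) / n;
            d(b, j) = err(b, j) * gate + dreg;
          }
        mat gW;
        vec gb;
        if (!y.conv) {
          gW = d.t() * y.P / B;
          gb = arma::sum(d, 0).t() / B;
        } else {
          mat dmat(d.memptr(), (size_t)B * y.Hq * y.Wq, y.F);
          mat dpre;
          if (y.pool == 2) {
            dpre.zeros((size_t)B * y.Ho * y.Wo, y.F);
            const arma::umat &id = pidx[l];
            for (int p = 0; p < 4; ++p) {
              const uvec &rowsp = y.pr[p];
              for (int f = 0; f < y.F; ++f)
                for (size_t i = 0; i < rowsp.n_elem; ++i)
                  if (id(i, f) == (arma::uword)(p + 1))
                    dpre(rowsp[i], f) += dmat(i, f);
            }
          } else {
            dpre = dmat;
          }
          gW = dpre.t() * Ms[l] / B;
          gb = arma::sum(dmat, 0).t() / B;
        }
        // AdaMax
        double corr = (beta1 > 0) ? 1.0 - std::pow(beta1, (double)(n_updates + 1)) : 1.0;
        y.mW = beta1 * y.mW + (1 - beta1) * gW;
        y.uW = arma::max(beta2 * y.uW, arma::abs(gW));
        y.W -= (eta_t / corr) * y.mW / (y.uW + eps);
        y.mb = beta1 * y.mb + (1 - beta1) * gb;
        y.ub = arma::max(beta2 * y.ub, arma::abs(gb));
        y.b -= (eta_t / corr) * y.mb / (y.ub + eps);
        losses[l] = loss;
        regs[l] = reg;
      }
      ++n_updates;
      if (n_updates % log_every == 0 || t == T - 1) {
        for (int l = 0; l < n_layers; ++l) {
          met_step.push_back((double)n_updates);
          met_layer.push_back(l + 1);
          met_loss.push_back(losses[l]);
          met_reg.push_back(regs[l]);
          met_rate.push_back(arma::mean(arma::vectorise(L[l].S)));
        }
      }
    }
  }

  List out_layers(n_layers), out_opt(n_layers), out_state(n_layers), out_accY(n_layers);
  for (int l = 0; l < n_layers; ++l) {
    out_layers[l] = List::create(_["W"] = L[l].W, _["b"] = L[l].b);
    if (training)
      out_opt[l] = List::create(_["mW"] = L[l].mW, _["uW"] = L[l].uW,
                                _["mb"] = L[l].mb, _["ub"] = L[l].ub);
    out_state[l] = List::create(_["P"] = L[l].P, _["Q"] = L[l].Q, _["R"] = L[l].R,
                                _["U"] = L[l].U, _["S"] = L[l].S);
    out_accY[l] = accY[l];
  }
  return List::create(
    _["layers"] = out_layers, _["opt"] = out_opt, _["state"] = out_state,
    _["n_updates"] = (double)n_updates, _["accY"] = out_accY, _["accS"] = accS,
    _["metrics"] = DataFrame::create(
      _["step"] = met_step, _["layer"] = met_layer, _["loss"] = met_loss,
      _["reg_loss"] = met_reg, _["spike_rate"] = met_rate)
  );
}
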