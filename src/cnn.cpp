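// Minimal CPU convolutional-network engine for 2-class patch
// classification: stacked blocks of conv (stride 1, zero "same" padding)
// -> batch norm -> ReLU -> 2x2/2 max-pool, then FC -> ReLU -> FC ->
// softmax, trained by plain SGD on cross-entropy.
//
// Layout conventions (internal only):
//  - a batch activation is an (B*P) x C float matrix, P = Ds*Df spatial
//    cells per sample (Df the fast dimension), channels as columns;
//  - conv weights are (Cin*k*k) x Cout, column index (ci*k + ks)*k + kf
//    matching im2col;
//  - flattened features are ci*P + pos, fed to the first FC layer.
// Single precision keeps the GEMMs (the entire cost) fast; all results
// are returned to R as doubles.
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
namespace {
// Large activation/weight buffers are allocated and freed on every call;
// with glibc's default mmap threshold each cycle returns the pages to the
// kernel and re-faults them on the next call, which dominates runtime on
// some kernels.  Keep big blocks on the heap so they are reused.
struct MallocTuner {
  MallocTuner() {
    mallopt(M_MMAP_THRESHOLD, 1 << 30);
    mallopt(M_TRIM_THRESHOLD, 1 << 30);
  }
};
static MallocTuner malloc_tuner;
}  // namespace
#endif
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::fmat;
using arma::fvec;
using arma::umat;
using arma::uword;

static const float BN_EPS = 1e-5f;

struct ConvLayer {
  fmat W;
  fvec b, gamma, beta, rmean, rvar;
  int k, cin, cout;
};

struct Net {
  std::vector<ConvLayer> conv;
  fmat Wf1, Wf2;
  fvec bf1, bf2;
  std::vector<int> ds, df;  // spatial dims entering block i; last entry = post-pool
  int fc_nodes, classes;
  uword flat;
};

static fmat as_f(SEXP x) { return arma::conv_to<fmat>::from(as<arma::mat>(x)); }
static fvec as_fv(SEXP x) { return arma::conv_to<fvec>::from(as<arma::vec>(x)); }
static SEXP wrap_f(const fmat& x) { return wrap(arma::conv_to<arma::mat>::from(x)); }
static SEXP wrap_fv(const fvec& x) { return wrap(arma::conv_to<arma::vec>::from(x)); }

static Net load_net(List weights, List arch) {
  Net net;
  List convs = weights["conv"];
  IntegerVector ksize = arch["ksize"];
  IntegerVector channels = arch["channels"];
  const int nb = convs.size();
  int cin = 1;
  int ds = as<int>(arch["ds"]), df = as<int>(arch["df"]);
  for (int i = 0; i < nb; ++i) {
    List li = convs[i];
    ConvLayer L;
    L.W = as_f(li["W"]);
    L.b = as_fv(li["b"]);
    L.gamma = as_fv(li["gamma"]);
    L.beta = as_fv(li["beta"]);
    L.rmean = as_fv(li["rmean"]);
    L.rvar = as_fv(li["rvar"]);
    L.k = ksize[i];
    L.cin = cin;
    L.cout = channels[i];
    net.conv.push_back(std::move(L));
    net.ds.push_back(ds);
    net.df.push_back(df);
    ds /= 2;
    df /= 2;
    cin = channels[i];
  }
  net.ds.push_back(ds);
  net.df.push_back(df);
  List fc1 = weights["fc1"], fc2 = weights["fc2"];
  net.Wf1 = as_f(fc1["W"]);
  net.bf1 = as_fv(fc1["b"]);
  net.Wf2 = as_f(fc2["W"]);
  net.bf2 = as_fv(fc2["b"]);
  net.fc_nodes = net.Wf1.n_cols;
  net.classes = net.Wf2.n_cols;
  net.flat = net.Wf1.n_rows;
  return net;
}

static List dump_net(const Net& net) {
  List convs(net.conv.size());
  for (size_t i = 0; i < net.conv.size(); ++i) {
    const ConvLayer& L = net.conv[i];
    convs[i] = List::create(_["W"] = wrap_f(L.W), _["b"] = wrap_fv(L.b),
                            _["gamma"] = wrap_fv(L.gamma), _["beta"] = wrap_fv(L.beta),
                            _["rmean"] = wrap_fv(L.rmean), _["rvar"] = wrap_fv(L.rvar));
  }
  return List::create(_["conv"] = convs,
                      _["fc1"] = List::create(_["W"] = wrap_f(net.Wf1), _["b"] = wrap_fv(net.bf1)),
                      _["fc2"] = List::create(_["W"] = wrap_f(net.Wf2), _["b"] = wrap_fv(net.bf2)));
}

// im2col for sample s of activation A into rows [row_base, row_base+P) of
// cols (zero padding).
static void im2col_sample(const fmat& A, int s, int Ds, int Df, int k, fmat& cols,
                          uword row_base) {
  const int pad = (k - 1) / 2;
  const int Cin = A.n_cols;
  const uword P = (uword)Ds * Df;
  const uword base = (uword)s * P;
  for (int ci = 0; ci < Cin; ++ci) {
    const float* src = A.colptr(ci) + base;
    for (int ks = 0; ks < k; ++ks) {
      for (int kf = 0; kf < k; ++kf) {
        const int col = (ci * k + ks) * k + kf;
        float* dst = cols.colptr(col) + row_base;
        for (int a = 0; a < Ds; ++a) {
          const int as = a + ks - pad;
          float* drow = dst + (size_t)a * Df;
          if (as < 0 || as >= Ds) {
            std::fill(drow, drow + Df, 0.0f);
            continue;
          }
          const float* srow = src + (size_t)as * Df;
          const int off = kf - pad;
          const int b0 = std::max(0, -off);
          const int b1 = std::min(Df, Df - off);
          if (b0 > 0) std::fill(drow, drow + b0, 0.0f);
          if (b1 > b0) std::copy(srow + b0 + off, srow + b1 + off, drow + b0);
          const int b2 = std::max(b0, b1);
          if (b2 < Df) std::fill(drow + b2, drow + Df, 0.0f);
        }
      }
    }
  }
}

// Scatter-add rows [row_base, row_base+P) of dcols into sample s of dA.
static void col2im_sample(const fmat& dcols, int s, int Ds, int Df, int Cin, int k,
                          fmat& dA, uword row_base) {
  const int pad = (k - 1) / 2;
  const uword P = (uword)Ds * Df;
  const uword base = (uword)s * P;
  for (int ci = 0; ci < Cin; ++ci) {
    float* dst = dA.colptr(ci) + base;
    for (int ks = 0; ks < k; ++ks) {
      for (int kf = 0; kf < k; ++kf) {
        const int col = (ci * k + ks) * k + kf;
        const float* src = dcols.colptr(col) + row_base;
        for (int a = 0; a < Ds; ++a) {
          const int as = a + ks - pad;
          if (as < 0 || as >= Ds) continue;
          const int off = kf - pad;
          const int b0 = std::max(0, -off);
          const int b1 = std::min(Df, Df - off);
          const float* srow = src + (size_t)a * Df;
          float* drow = dst + (size_t)as * Df + off;
          for (int b = b0; b < b1; ++b) drow[b] += srow[b];
        }
      }
    }
  }
}

// The whole minibatch goes through one large GEMM per conv layer (the
// im2col buffer spans every sample); large GEMMs run far closer to peak
// than per-sample ones.
static fmat conv_forward(const fmat& A, int B, int Ds, int Df, const ConvLayer& L) {
  const uword P = (uword)Ds * Df;
  fmat cols((uword)B * P, (uword)L.cin * L.k * L.k);
  for (int s = 0; s < B; ++s)
    im2col_sample(A, s, Ds, Df, L.k, cols, (uword)s * P);
  fmat Z = cols * L.W;
  Z.each_row() += L.b.t();
  return Z;
}

static void conv_backward(const fmat& A, const fmat& dZ, int B, int Ds, int Df,
                          const ConvLayer& L, fmat& dW, fvec& db, fmat* dA) {
  const uword P = (uword)Ds * Df;
  db = arma::conv_to<fvec>::from(arma::sum(dZ, 0).t());
  fmat cols((uword)B * P, (uword)L.cin * L.k * L.k);
  for (int s = 0; s < B; ++s)
    im2col_sample(A, s, Ds, Df, L.k, cols, (uword)s * P);
  dW = cols.t() * dZ;
  if (dA) {
    cols.reset();  // release before allocating the equally large dcols
    fmat dcols = dZ * L.W.t();
    dA->zeros(A.n_rows, A.n_cols);
    for (int s = 0; s < B; ++s)
      col2im_sample(dcols, s, Ds, Df, L.cin, L.k, *dA, (uword)s * P);
  }
}

// In-place batch norm (training): Z <- gamma*xhat + beta; caches xhat/invstd.
static void bn_forward_train(fmat& Z, const fvec& gamma, const fvec& beta,
                             fmat& xhat, fvec& invstd, fvec& bmean, fvec& bvar) {
  const uword N = Z.n_rows, C = Z.n_cols;
  xhat.set_size(N, C);
  invstd.set_size(C);
  bmean.set_size(C);
  bvar.set_size(C);
  for (uword c = 0; c < C; ++c) {
    const float* z = Z.colptr(c);
    double s = 0.0, s2 = 0.0;
    for (uword i = 0; i < N; ++i) {
      s += z[i];
      s2 += (double)z[i] * z[i];
    }
    const double mu = s / N;
    double var = s2 / N - mu * mu;
    if (var < 0) var = 0;
    bmean[c] = (float)mu;
    bvar[c] = (float)var;
    const float is = 1.0f / std::sqrt((float)var + BN_EPS);
    invstd[c] = is;
    const float g = gamma[c], be = beta[c], m = (float)mu;
    float* xh = xhat.colptr(c);
    float* zz = Z.colptr(c);
    for (uword i = 0; i < N; ++i) {
      const float x = (zz[i] - m) * is;
      xh[i] = x;
      zz[i] = g * x + be;
    }
  }
}

static void bn_forward_eval(fmat& Z, const ConvLayer& L) {
  const uword N = Z.n_rows, C = Z.n_cols;
  for (uword c = 0; c < C; ++c) {
    const float is = 1.0f / std::sqrt(L.rvar[c] + BN_EPS);
    const float g = L.gamma[c], be = L.beta[c], m = L.rmean[c];
    float* z = Z.colptr(c);
    for (uword i = 0; i < N; ++i) z[i] = g * (z[i] - m) * is + be;
  }
}

static fmat bn_backward(const fmat& dY, const fmat& xhat, const fvec& invstd,
                        const fvec& gamma, fvec& dgamma, fvec& dbeta) {
  const uword N = dY.n_rows, C = dY.n_cols;
  fmat dZ(N, C);
  dgamma.set_size(C);
  dbeta.set_size(C);
  for (uword c = 0; c < C; ++c) {
    const float* dy = dY.colptr(c);
    const float* xh = xhat.colptr(c);
    double sg = 0.0, sb = 0.0;
    for (uword i = 0; i < N; ++i) {
      sg += (double)dy[i] * xh[i];
      sb += dy[i];
    }
    dgamma[c] = (float)sg;
    dbeta[c] = (float)sb;
    // dZ = invstd*gamma * (dY - mean(dY) - xhat * mean(dY*xhat))
    const float coef = invstd[c] * gamma[c];
    const float mg = (float)(sg / N), mb = (float)(sb / N);
    float* dz = dZ.colptr(c);
    for (uword i = 0; i < N; ++i)
      dz[i] = coef * (dy[i] - mb - xh[i] * mg);
  }
  return dZ;
}

static fmat maxpool_forward(const fmat& A, int B, int Ds, int Df, umat& arg) {
  const int Ds2 = Ds / 2, Df2 = Df / 2;
  const uword P = (uword)Ds * Df, P2 = (uword)Ds2 * Df2;
  const int C = A.n_cols;
  fmat out((uword)B * P2, C);
  arg.set_size((uword)B * P2, C);
  for (int c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    float* dst = out.colptr(c);
    uword* am = arg.colptr(c);
    for (int s = 0; s < B; ++s) {
      const uword base = (uword)s * P, obase = (uword)s * P2;
      for (int a = 0; a < Ds2; ++a) {
        for (int b = 0; b < Df2; ++b) {
          const uword i00 = base + (uword)(2 * a) * Df + 2 * b;
          const uword i01 = i00 + 1;
          const uword i10 = i00 + Df;
          const uword i11 = i10 + 1;
          uword bi = i00;
          float bv = src[i00];
          if (src[i01] > bv) { bv = src[i01]; bi = i01; }
          if (src[i10] > bv) { bv = src[i10]; bi = i10; }
          if (src[i11] > bv) { bv = src[i11]; bi = i11; }
          const uword o = obase + (uword)a * Df2 + b;
          dst[o] = bv;
          am[o] = bi;
        }
      }
    }
  }
  return out;
}

static fmat maxpool_backward(const fmat& dP, const umat& arg, uword in_rows) {
  fmat dA(in_rows, dP.n_cols, arma::fill::zeros);
  for (uword c = 0; c < dP.n_cols; ++c) {
    const float* src = dP.colptr(c);
    const uword* am = arg.colptr(c);
    float* dst = dA.colptr(c);
    for (uword i = 0; i < dP.n_rows; ++i) dst[am[i]] += src[i];
  }
  return dA;
}

static fmat flatten(const fmat& A, int B) {
  const uword P = A.n_rows / B;
  const uword C = A.n_cols;
  fmat F(B, P * C);
  for (uword c = 0; c < C; ++c) {
    const float* src = A.colptr(c);
    for (uword p = 0; p < P; ++p) {
      float* dst = F.colptr(c * P + p);
      for (int s = 0; s < B; ++s) dst[s] = src[(uword)s * P + p];
    }
  }
  return F;
}

static fmat unflatten(const fmat& F, int B, uword P, uword C) {
  fmat A((uword)B * P, C);
  for (uword c = 0; c < C; ++c) {
    float* dst = A.colptr(c);
    for (uword p = 0; p < P; ++p) {
      const float* src = F.colptr(c * P + p);
      for (int s = 0; s < B; ++s) dst[(uword)s * P + p] = src[s];
    }
  }
  return A;
}

static void softmax_rows(fmat& Z) {
  for (uword i = 0; i < Z.n_rows; ++i) {
    const float m = Z.row(i).max();
    float s = 0.0f;
    for (uword c = 0; c < Z.n_cols; ++c) {
      const float e = std::exp(Z(i, c) - m);
      Z(i, c) = e;
      s += e;
    }
    Z.row(i) /= s;
  }
}

// Builds the batch input (B*P0 x 1) from rows `idx` (0-based) of X.
static fmat gather_batch(const arma::mat& X, const std::vector<int>& idx) {
  const uword P = X.n_cols;
  fmat A((uword)idx.size() * P, 1);
  float* dst = A.colptr(0);
  for (size_t s = 0; s < idx.size(); ++s) {
    const int r = idx[s];
    for (uword p = 0; p < P; ++p) dst[(uword)s * P + p] = (float)X(r, p);
  }
  return A;
}

// Eval-mode forward for a batch; returns class probabilities (B x classes).
static fmat forward_eval(const Net& net, fmat A) {
  const int B = A.n_rows / ((uword)net.ds[0] * net.df[0]);
  for (size_t i = 0; i < net.conv.size(); ++i) {
    fmat Z = conv_forward(A, B, net.ds[i], net.df[i], net.conv[i]);
    bn_forward_eval(Z, net.conv[i]);
    Z.transform([](float v) { return v > 0 ? v : 0.0f; });
    umat arg;
    A = maxpool_forward(Z, B, net.ds[i], net.df[i], arg);
  }
  fmat F = flatten(A, B);
  fmat H = F * net.Wf1;
  H.each_row() += net.bf1.t();
  H.transform([](float v) { return v > 0 ? v : 0.0f; });
  fmat L = H * net.Wf2;
  L.each_row() += net.bf2.t();
  softmax_rows(L);
  return L;
}

// Converting the (large) R weight list to the float net is expensive, so
// the net lives behind an external pointer between calls; the pointer is
// created once per trained model and never serialized.
// [[Rcpp::export]]
SEXP cpp_cnn_make_handle(List weights, List arch) {
  XPtr<Net> p(new Net(load_net(weights, arch)), true);
  return p;
}

// [[Rcpp::export]]
bool cpp_cnn_handle_valid(SEXP h) {
  if (TYPEOF(h) != EXTPTRSXP) return false;
  XPtr<Net> p(h);
  return p.get() != nullptr;
}

// [[Rcpp::export]]
List cpp_cnn_get_weights(SEXP h) {
  XPtr<Net> p(h);
  return dump_net(*p);
}

static arma::mat predict_net(const Net& net, const arma::mat& X, int batch_size) {
  const int N = X.n_rows;
  arma::mat out(N, net.classes);
  for (int start = 0; start < N; start += batch_size) {
    const int end = std::min(N, start + batch_size);
    std::vector<int> idx;
    for (int i = start; i < end; ++i) idx.push_back(i);
    fmat P = forward_eval(net, gather_batch(X, idx));
    for (int s = 0; s < (int)idx.size(); ++s)
      for (int c = 0; c < net.classes; ++c) out(idx[s], c) = P(s, c);
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict_ptr(SEXP h, const arma::mat& X, int batch_size) {
  XPtr<Net> p(h);
  return predict_net(*p, X, batch_size);
}

// [[Rcpp::export]]
arma::mat cpp_cnn_predict(List weights, List arch, const arma::mat& X, int batch_size) {
  Net net = load_net(weights, arch);
  return predict_net(net, X, batch_size);
}

// One SGD epoch over X (N x P0) with 0-based labels y and a 1-based
// permutation from R; updates the net behind the handle in place and
// returns the mean loss and the running (pre-update, per-batch) training
// accuracy.
// [[Rcpp::export]]
List cpp_cnn_epoch_ptr(SEXP h, const arma::mat& X, const IntegerVector& y,
                       double lr, int batch_size, const IntegerVector& perm,
                       double bn_momentum) {
  XPtr<Net> hp(h);
  Net& net = *hp;
  const int N = X.n_rows;
  const int nb = net.conv.size();
  const float flr = (float)lr;
  const float mom = (float)bn_momentum;
  double loss_sum = 0.0;
  int correct = 0, seen = 0;

  for (int start = 0; start < N; start += batch_size) {
    const int end = std::min(N, start + batch_size);
    std::vector<int> idx;
    for (int i = start; i < end; ++i) idx.push_back(perm[i] - 1);
    const int B = (int)idx.size();

    // ---- forward (training mode) with caches
    std::vector<fmat> inputs(nb);   // activation entering each conv
    std::vector<fmat> xhats(nb);
    std::vector<fvec> invstds(nb);
    std::vector<umat> args(nb);
    fmat A = gather_batch(X, idx);
    for (int i = 0; i < nb; ++i) {
      inputs[i] = A;
      fmat Z = conv_forward(A, B, net.ds[i], net.df[i], net.conv[i]);
      fvec bmean, bvar;
      bn_forward_train(Z, net.conv[i].gamma, net.conv[i].beta, xhats[i], invstds[i], bmean, bvar);
      net.conv[i].rmean = (1.0f - mom) * net.conv[i].rmean + mom * bmean;
      net.conv[i].rvar = (1.0f - mom) * net.conv[i].rvar + mom * bvar;
      Z.transform([](float v) { return v > 0 ? v : 0.0f; });
      A = maxpool_forward(Z, B, net.ds[i], net.df[i], args[i]);
    }
    fmat F = flatten(A, B);
    fmat H = F * net.Wf1;
    H.each_row() += net.bf1.t();
    fmat Hr = H;
    Hr.transform([](float v) { return v > 0 ? v : 0.0f; });
    fmat P = Hr * net.Wf2;
    P.each_row() += net.bf2.t();
    softmax_rows(P);

    for (int s = 0; s < B; ++s) {
      const int cls = y[idx[s]];
      float p = P(s, cls);
      if (p < 1e-12f) p = 1e-12f;
      loss_sum += -std::log((double)p);
      uword am;
      P.row(s).max(am);
      if ((int)am == cls) ++correct;
      ++seen;
    }

    // ---- backward
    fmat dL = P;
    for (int s = 0; s < B; ++s) dL(s, y[idx[s]]) -= 1.0f;
    dL /= (float)B;

    fmat dWf2 = Hr.t() * dL;
    fvec dbf2 = arma::conv_to<fvec>::from(arma::sum(dL, 0).t());
    fmat dHr = dL * net.Wf2.t();
    for (uword i = 0; i < dHr.n_elem; ++i)
      if (H.at(i) <= 0) dHr.at(i) = 0.0f;
    fmat dWf1 = F.t() * dHr;
    fvec dbf1 = arma::conv_to<fvec>::from(arma::sum(dHr, 0).t());
    fmat dF = dHr * net.Wf1.t();
    const uword Pl = (uword)net.ds[nb] * net.df[nb];
    fmat dA = unflatten(dF, B, Pl, net.conv[nb - 1].cout);

    std::vector<fmat> dWs(nb);
    std::vector<fvec> dbs(nb), dgs(nb), dbes(nb);
    for (int i = nb - 1; i >= 0; --i) {
      // through pool
      fmat dZr = maxpool_backward(dA, args[i], (uword)B * net.ds[i] * net.df[i]);
      // through ReLU: mask from pre-ReLU value gamma*xhat+beta
      const fvec& g = net.conv[i].gamma;
      const fvec& be = net.conv[i].beta;
      for (uword c = 0; c < dZr.n_cols; ++c) {
        const float gg = g[c], bb = be[c];
        const float* xh = xhats[i].colptr(c);
        float* d = dZr.colptr(c);
        for (uword r = 0; r < dZr.n_rows; ++r)
          if (gg * xh[r] + bb <= 0) d[r] = 0.0f;
      }
      // through BN
      fvec dgamma, dbeta;
      fmat dZ = bn_backward(dZr, xhats[i], invstds[i], g, dgamma, dbeta);
      dgs[i] = dgamma;
      dbes[i] = dbeta;
      // through conv
      conv_backward(inputs[i], dZ, B, net.ds[i], net.df[i], net.conv[i],
                    dWs[i], dbs[i], i > 0 ? &dA : (fmat*)nullptr);
    }

    // ---- SGD update
    for (int i = 0; i < nb; ++i) {
      net.conv[i].W -= flr * dWs[i];
      net.conv[i].b -= flr * dbs[i];
      net.conv[i].gamma -= flr * dgs[i];
      net.conv[i].beta -= flr * dbes[i];
    }
    net.Wf1 -= flr * dWf1;
    net.bf1 -= flr * dbf1;
    net.Wf2 -= flr * dWf2;
    net.bf2 -= flr * dbf2;
  }

  return List::create(_["loss"] = loss_sum / std::max(1, seen),
                      _["batch_accuracy"] = (double)correct / std::max(1, seen));
}
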