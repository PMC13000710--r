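// 1D convolutional network for fused spectral feature vectors.
// Single-precision internals; all heavy work goes through BLAS sgemm and
// hand-fused elementwise passes (the network is trained on one CPU core,
// so memory traffic matters as much as flops).
//
// Layout convention: a batch activation with C channels and length L over
// B samples is an fmat of size (C, L*B), sample b occupying columns
// [b*L, (b+1)*L). Flattening a (C, Lp*B) block is then a plain reshape.
//
// Convolutions are restricted to "same" geometry (2*padding == kernel-1,
// stride 1), which lets each kernel tap run as one shifted sgemm per sample
// with no im2col buffer. The R layer enforces this geometry.
//
// Block order inside a conv block is conv -> ReLU -> batch norm -> max pool.
// Because batch norm sees post-ReLU values, the ReLU backward mask can be
// recovered from the cached normalised values: relu(z) > 0 iff
// xhat > -mu * invstd, so no pre-activation copy is kept.

// [[Rcpp::depends(RcppArmadillo)]]
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#include <random>
#ifdef __GLIBC__
#include <malloc.h>
#endif

using namespace arma;

extern "C" void sgemm_(const char* ta, const char* tb, const int* m,
                       const int* n, const int* k, const float* alpha,
                       const float* A, const int* lda, const float* B,
                       const int* ldb, const float* beta, float* C,
                       const int* ldc);

namespace {

const float BN_EPS = 1e-5f;

inline void sgemm(char ta, char tb, int m, int n, int k, float alpha,
                  const float* A, int lda, const float* B, int ldb,
                  float beta, float* C, int ldc) {
  if (m == 0 || n == 0) return;
  sgemm_(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb, &beta, C, &ldc);
}

struct ConvBlock {
  fmat W;                 // (Cout, Cin*k), tap j occupies cols [j*Cin, (j+1)*Cin)
  fvec b;
  fvec gamma, beta, rmean, rvar;
};

struct Net {
  int input_len = 0, n_class = 0, k = 3, pad = 1, pool = 2;
  std::vector<ConvBlock> conv;
  std::vector<fmat> Wd;   // hidden dense layers
  std::vector<fvec> bd;
  std::vector<float> drop;
  fmat Wo;
  fvec bo;
};

fmat as_f(const Rcpp::NumericMatrix& m) {
  return conv_to<fmat>::from(Rcpp::as<mat>(m));
}
fvec as_fv(const Rcpp::NumericVector& v) {
  return conv_to<fvec>::from(Rcpp::as<vec>(v));
}

Net parse_net(const Rcpp::List& net_in) {
  Net net;
  Rcpp::List cfg = net_in["config"];
  net.input_len = Rcpp::as<int>(cfg["input_length"]);
  net.n_class = Rcpp::as<int>(cfg["n_classes"]);
  net.k = Rcpp::as<int>(cfg["kernel_size"]);
  net.pad = Rcpp::as<int>(cfg["padding"]);
  net.pool = Rcpp::as<int>(cfg["pool_size"]);
  if (2 * net.pad != net.k - 1)
    Rcpp::stop("only 'same' convolutions are supported (2*padding == kernel_size - 1)");
  Rcpp::List conv = net_in["conv"];
  for (int i = 0; i < conv.size(); ++i) {
    Rcpp::List bl = conv[i];
    ConvBlock cb;
    cb.W = as_f(bl["W"]); cb.b = as_fv(bl["b"]);
    cb.gamma = as_fv(bl["gamma"]); cb.beta = as_fv(bl["beta"]);
    cb.rmean = as_fv(bl["running_mean"]); cb.rvar = as_fv(bl["running_var"]);
    net.conv.push_back(cb);
  }
  Rcpp::List dense = net_in["dense"];
  Rcpp::NumericVector drop = cfg["dropout_rates"];
  for (int i = 0; i < dense.size(); ++i) {
    Rcpp::List dl = dense[i];
    net.Wd.push_back(as_f(dl["W"]));
    net.bd.push_back(as_fv(dl["b"]));
    net.drop.push_back((float)drop[i]);
  }
  Rcpp::List out = net_in["out"];
  net.Wo = as_f(out["W"]); net.bo = as_fv(out["b"]);
  return net;
}

Rcpp::List export_net(const Net& net, const Rcpp::List& net_in) {
  Rcpp::List out = Rcpp::clone(net_in);
  Rcpp::List conv(net.conv.size());
  for (size_t i = 0; i < net.conv.size(); ++i) {
    const ConvBlock& cb = net.conv[i];
    conv[i] = Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(cb.W)),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(cb.b)),
      Rcpp::Named("gamma") = Rcpp::wrap(conv_to<vec>::from(cb.gamma)),
      Rcpp::Named("beta") = Rcpp::wrap(conv_to<vec>::from(cb.beta)),
      Rcpp::Named("running_mean") = Rcpp::wrap(conv_to<vec>::from(cb.rmean)),
      Rcpp::Named("running_var") = Rcpp::wrap(conv_to<vec>::from(cb.rvar)));
  }
  out["conv"] = conv;
  Rcpp::List dense(net.Wd.size());
  for (size_t i = 0; i < net.Wd.size(); ++i) {
    dense[i] = Rcpp::List::create(
      Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(net.Wd[i])),
      Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(net.bd[i])));
  }
  out["dense"] = dense;
  out["out"] = Rcpp::List::create(
    Rcpp::Named("W") = Rcpp::wrap(conv_to<mat>::from(net.Wo)),
    Rcpp::Named("b") = Rcpp::wrap(conv_to<vec>::from(net.bo)));
  return out;
}

// Z (Cout, L*B) = same-conv of X (Cin, L*B). Z may be uninitialised: the
// centre tap covers every output column and runs first with beta = 0.
void conv_fwd(const fmat& W, const fmat& X, fmat& Z,
              int Cin, int Cout, int L, int B, int k, int pad) {
  const float* Wp = W.memptr();
  const float* Xp = X.memptr();
  float* Zp = Z.memptr();
  for (int b = 0; b < B; ++b) {
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < k; ++j) {
        if ((j == pad) != (pass == 0)) continue;
        int s = j - pad;
        int i0 = std::max(0, -s);
        int i1 = L - std::max(0, s);  // out cols [i0, i1)
        sgemm('N', 'N', Cout, i1 - i0, Cin, 1.0f,
              Wp + (size_t)j * Cin * Cout, Cout,
              Xp + ((size_t)b * L + i0 + s) * Cin, Cin,
              pass == 0 ? 0.0f : 1.0f, Zp + ((size_t)b * L + i0) * Cout, Cout);
      }
    }
  }
}

// dX (Cin, L*B) = transposed conv of dZ. Centre tap first with beta = 0.
void conv_bwd_data(const fmat& W, const fmat& dZ, fmat& dX,
                   int Cin, int Cout, int L, int B, int k, int pad) {
  const float* Wp = W.memptr();
  const float* Gp = dZ.memptr();
  float* Dp = dX.memptr();
  for (int b = 0; b < B; ++b) {
    for (int pass = 0; pass < 2; ++pass) {
      for (int j = 0; j < k; ++j) {
        if ((j == pad) != (pass == 0)) continue;
        int s = j - pad;
        int i0 = std::max(0, -s);
        int i1 = L - std::max(0, s);
        sgemm('T', 'N', Cin, i1 - i0, Cout, 1.0f,
              Wp + (size_t)j * Cin * Cout, Cout,
              Gp + ((size_t)b * L + i0) * Cout, Cout,
              pass == 0 ? 0.0f : 1.0f,
              Dp + ((size_t)b * L + i0 + s) * Cin, Cin);
      }
    }
  }
}

// gW (Cout, Cin*k) = dZ * shifted(X)^T accumulated over the batch.
void conv_bwd_weights(const fmat& dZ, const fmat& X, fmat& gW,
                      int Cin, int Cout, int L, int B, int k, int pad) {
  const float* Gp = dZ.memptr();
  const float* Xp = X.memptr();
  float* Wp = gW.memptr();
  for (int b = 0; b < B; ++b) {
    for (int j = 0; j < k; ++j) {
      int s = j - pad;
      int i0 = std::max(0, -s);
      int i1 = L - std::max(0, s);
      sgemm('N', 'T', Cout, Cin, i1 - i0, 1.0f,
            Gp + ((size_t)b * L + i0) * Cout, Cout,
            Xp + ((size_t)b * L + i0 + s) * Cin, Cin,
            b == 0 ? 0.0f : 1.0f, Wp + (size_t)j * Cin * Cout, Cout);
    }
  }
}

// Max pool with a per-channel affine map y = scale[c]*x + shift[c] applied
// on the fly, so the batch-norm output never has to be materialised.
fmat maxpool_affine(const fmat& A, int L, int B, int s,
                    const fvec& scale, const fvec& shift, umat* arg) {
  int C = A.n_rows;
  int Lp = L / s;  // floor division, remainder dropped
  fmat P(C, (size_t)Lp * B);
  if (arg) arg->set_size(C, (size_t)Lp * B);
  const float* ap = A.memptr();
  const float* sc = scale.memptr();
  const float* sh = shift.memptr();
  float* pp = P.memptr();
  uword* gp = arg ? arg->memptr() : nullptr;
  for (int b = 0; b < B; ++b) {
    for (int i = 0; i < Lp; ++i) {
      size_t oc = (size_t)b * Lp + i;
      size_t base = (size_t)b * L + (size_t)i * s;
      const float* col0 = ap + base * C;
      for (int c = 0; c < C; ++c) {
        float best = sc[c] * col0[c] + sh[c];
        size_t bi = base;
        for (int t = 1; t < s; ++t) {
          float v = sc[c] * col0[(size_t)t * C + c] + sh[c];
          if (v > best) { best = v; bi = base + t; }
        }
        pp[oc * C + c] = best;
        if (gp) gp[oc * C + c] = bi;
      }
    }
  }
  return P;
}

inline void relu_(fmat& A) {
  float* p = A.memptr();
  for (uword i = 0; i < A.n_elem; ++i) if (p[i] < 0) p[i] = 0;
}

// Fused in-place Adam step; no temporaries.
void adam_update(float* w, const float* g, float* m, float* v, size_t n,
                 float lr, float b1, float b2, float eps,
                 float bc1, float bc2) {
  for (size_t i = 0; i < n; ++i) {
    float mi = m[i] = b1 * m[i] + (1 - b1) * g[i];
    float vi = v[i] = b2 * v[i] + (1 - b2) * g[i] * g[i];
    w[i] -= lr * (mi / bc1) / (std::sqrt(vi / bc2) + eps);
  }
}

struct AdamState {
  fmat mW, vW;
  explicit AdamState(const fmat& W) { mW.zeros(size(W)); vW.zeros(size(W)); }
  void step(fmat& W, const fmat& g, float lr, float b1, float b2, float eps,
            float bc1, float bc2) {
    adam_update(W.memptr(), g.memptr(), mW.memptr(), vW.memptr(), W.n_elem,
                lr, b1, b2, eps, bc1, bc2);
  }
};
struct AdamStateV {
  fvec m, v;
  explicit AdamStateV(const fvec& w) { m.zeros(size(w)); v.zeros(size(w)); }
  void step(fvec& w, const fvec& g, float lr, float b1, float b2, float eps,
            float bc1, float bc2) {
    adam_update(w.memptr(), g.memptr(), m.memptr(), v.memptr(), w.n_elem,
                lr, b1, b2, eps, bc1, bc2);
  }
};

// Inference-mode forward; optionally captures the final pooled feature
// maps and dense pre-activations for class-activation mapping.
fmat infer_forward(const Net& net, const fmat& X0, int B,
                   fmat* final_maps = nullptr,
                   std::vector<fvec>* dense_pre = nullptr,
                   fvec* flat_out = nullptr) {
  int L = net.input_len;
  fmat cur = reshape(X0, 1, (size_t)L * B);
  int Cin = 1;
  for (size_t bl = 0; bl < net.conv.size(); ++bl) {
    const ConvBlock& cb = net.conv[bl];
    int Cout = cb.W.n_rows;
    fmat Z(Cout, (size_t)L * B);
    conv_fwd(cb.W, cur, Z, Cin, Cout, L, B, net.k, net.pad);
    // bias + ReLU in one pass; batch-norm affine folded into pooling
    {
      float* zp = Z.memptr();
      const float* bp = cb.b.memptr();
      for (size_t j = 0; j < Z.n_cols; ++j)
        for (int c = 0; c < Cout; ++c) {
          float v = zp[j * Cout + c] + bp[c];
          zp[j * Cout + c] = v > 0 ? v : 0;
        }
    }
    fvec scale = cb.gamma / sqrt(cb.rvar + BN_EPS);
    fvec shift = cb.beta - cb.rmean % scale;
    cur = maxpool_affine(Z, L, B, net.pool, scale, shift, nullptr);
    L = L / net.pool;
    Cin = Cout;
  }
  if (final_maps) *final_maps = cur;  // (C_last, Lp*B)
  fmat H = reshape(cur, (size_t)cur.n_rows * L, B);
  if (flat_out && B == 1) *flat_out = H.col(0);
  for (size_t d = 0; d < net.Wd.size(); ++d) {
    fmat Zd = net.Wd[d] * H;
    Zd.each_col() += net.bd[d];
    if (dense_pre && B == 1) dense_pre->push_back(Zd.col(0));
    relu_(Zd);
    H = std::move(Zd);  // no dropout at inference
  }
  fmat logits = net.Wo * H;
  logits.each_col() += net.bo;
  return logits;
}

}  // namespace

// [[Rcpp::export]]
Rcpp::List cpp_cnn_train(Rcpp::List net_in, const arma::mat& X,
                         const arma::ivec& y, int epochs, double lr0,
                         int batch, int seed, double bn_momentum) {
  Net net = parse_net(net_in);
  const int n = X.n_cols;
  const int p = X.n_rows;
  if (p != net.input_len) Rcpp::stop("feature length does not match input_length");
#ifdef __GLIBC__
  // keep the large per-batch buffers on the heap instead of mmap-ing and
  // unmapping tens of megabytes every minibatch
  mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
#endif
  fmat Xf = conv_to<fmat>::from(X);

  std::mt19937 rng((unsigned)seed);
  std::uniform_real_distribution<float> unif(0.0f, 1.0f);
  const float b1 = 0.9f, b2 = 0.999f, aeps = 1e-8f;
  const float mom = (float)bn_momentum;
  const size_t nconv = net.conv.size(), ndense = net.Wd.size();

  std::vector<AdamState> sWc, sWd;
  std::vector<AdamStateV> sbc, sgam, sbet, sbd;
  std::vector<fmat> gWd_buf;  // reusable dense-layer gradient buffers
  for (size_t i = 0; i < nconv; ++i) {
    sWc.emplace_back(net.conv[i].W);
    sbc.emplace_back(net.conv[i].b);
    sgam.emplace_back(net.conv[i].gamma);
    sbet.emplace_back(net.conv[i].beta);
  }
  for (size_t i = 0; i < ndense; ++i) {
    sWd.emplace_back(net.Wd[i]);
    sbd.emplace_back(net.bd[i]);
    gWd_buf.emplace_back(size(net.Wd[i]));
  }
  AdamState sWo(net.Wo);
  AdamStateV sbo(net.bo);

  long tstep = 0;
  std::vector<double> epoch_loss;
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  for (int e = 0; e < epochs; ++e) {
    float lr = (float)(lr0 * 0.5 * (1.0 + std::cos(M_PI * (double)e / epochs)));
    std::shuffle(order.begin(), order.end(), rng);
    double loss_sum = 0;
    int n_batches = 0;

    for (int start = 0; start < n; start += batch) {
      int B = std::min(batch, n - start);
      fmat Xb(p, B);
      ivec yb(B);
      for (int i = 0; i < B; ++i) {
        Xb.col(i) = Xf.col(order[start + i]);
        yb[i] = y[order[start + i]];
      }

      // ---- forward (training mode) ----
      int L = net.input_len, Cin = 1;
      fmat cur = reshape(Xb, 1, (size_t)L * B);
      std::vector<fmat> cache_in, cache_xhat;
      std::vector<fvec> cache_invstd, cache_mu;
      std::vector<umat> cache_arg;
      std::vector<int> cache_L;

      for (size_t bl = 0; bl < nconv; ++bl) {
        ConvBlock& cb = net.conv[bl];
        int Cout = cb.W.n_rows;
        cache_in.push_back(std::move(cur));
        cache_L.push_back(L);
        fmat Z(Cout, (size_t)L * B);
        conv_fwd(cb.W, cache_in.back(), Z, Cin, Cout, L, B, net.k, net.pad);
        const size_t ncols = Z.n_cols;
        const float nn = (float)ncols;
        fvec mu(Cout), var(Cout);
        {
          // fused: bias + ReLU + first/second-moment accumulation.
          // Float partial sums flushed to double every CHUNK columns keep
          // the loop SIMD-friendly without losing precision.
          const size_t CHUNK = 1024;
          std::vector<double> sum(Cout, 0.0), sq(Cout, 0.0);
          std::vector<float> ps(Cout, 0.0f), pq(Cout, 0.0f);
          float* zp = Z.memptr();
          const float* bp = cb.b.memptr();
          for (size_t j = 0; j < ncols; ++j) {
            float* col = zp + j * Cout;
            for (int c = 0; c < Cout; ++c) {
              float v = col[c] + bp[c];
              v = v > 0 ? v : 0;
              col[c] = v;
              ps[c] += v;
              pq[c] += v * v;
            }
            if ((j + 1) % CHUNK == 0 || j + 1 == ncols) {
              for (int c = 0; c < Cout; ++c) {
                sum[c] += ps[c]; sq[c] += pq[c];
                ps[c] = 0; pq[c] = 0;
              }
            }
          }
          for (int c = 0; c < Cout; ++c) {
            mu[c] = (float)(sum[c] / nn);
            double vv = sq[c] / nn - (double)mu[c] * mu[c];
            var[c] = (float)(vv > 0 ? vv : 0);
          }
        }
        fvec invstd = 1.0f / sqrt(var + BN_EPS);
        {
          // normalise in place: Z becomes xhat
          float* zp = Z.memptr();
          const float* mp = mu.memptr();
          const float* ip = invstd.memptr();
          for (size_t j = 0; j < ncols; ++j)
            for (int c = 0; c < Cout; ++c)
              zp[j * Cout + c] = (zp[j * Cout + c] - mp[c]) * ip[c];
        }
        cb.rmean = (1 - mom) * cb.rmean + mom * mu;
        float ub = nn > 1 ? nn / (nn - 1) : 1.0f;
        cb.rvar = (1 - mom) * cb.rvar + mom * ub * var;
        umat arg;
        fmat pooled = maxpool_affine(Z, L, B, net.pool, cb.gamma, cb.beta, &arg);
        cache_xhat.push_back(std::move(Z));
        cache_invstd.push_back(invstd);
        cache_mu.push_back(mu);
        cache_arg.push_back(std::move(arg));
        cur = std::move(pooled);
        L = L / net.pool;
        Cin = Cout;
      }

      int Clast = cur.n_rows;
      fmat H = reshape(cur, (size_t)Clast * L, B);
      std::vector<fmat> cache_Hin, cache_Zd, cache_mask;
      for (size_t d = 0; d < ndense; ++d) {
        cache_Hin.push_back(std::move(H));
        fmat Zd = net.Wd[d] * cache_Hin.back();
        Zd.each_col() += net.bd[d];
        cache_Zd.push_back(Zd);
        relu_(Zd);
        float keep = 1.0f - net.drop[d];
        fmat mask(size(Zd));
        float* mp = mask.memptr();
        for (uword ii = 0; ii < mask.n_elem; ++ii)
          mp[ii] = (unif(rng) < keep) ? 1.0f / keep : 0.0f;
        Zd %= mask;
        cache_mask.push_back(std::move(mask));
        H = std::move(Zd);
      }
      fmat logits = net.Wo * H;
      logits.each_col() += net.bo;

      // ---- softmax cross-entropy ----
      fmat P = logits;
      P.each_row() -= max(P, 0);
      P = exp(P);
      frowvec colsum = sum(P, 0);
      P.each_row() /= colsum;
      double loss = 0;
      for (int i = 0; i < B; ++i)
        loss -= std::log(std::max(P(yb[i], i), 1e-12f));
      loss /= B;
      loss_sum += loss;
      ++n_batches;

      fmat G = std::move(P);
      for (int i = 0; i < B; ++i) G(yb[i], i) -= 1.0f;
      G /= (float)B;

      // ---- backward ----
      ++tstep;
      float bc1 = 1.0f - std::pow(b1, (float)tstep);
      float bc2 = 1.0f - std::pow(b2, (float)tstep);

      fmat gWo = G * H.t();
      fvec gbo = sum(G, 1);
      fmat dH = net.Wo.t() * G;
      sWo.step(net.Wo, gWo, lr, b1, b2, aeps, bc1, bc2);
      sbo.step(net.bo, gbo, lr, b1, b2, aeps, bc1, bc2);

      for (int d = (int)ndense - 1; d >= 0; --d) {
        dH %= cache_mask[d];
        {
          float* dp = dH.memptr();
          const float* zp = cache_Zd[d].memptr();
          for (uword ii = 0; ii < dH.n_elem; ++ii) if (zp[ii] <= 0) dp[ii] = 0;
        }
        fmat& gW = gWd_buf[d];
        const fmat& Hin = cache_Hin[d];
        sgemm('N', 'T', dH.n_rows, Hin.n_rows, B, 1.0f,
              dH.memptr(), dH.n_rows, Hin.memptr(), Hin.n_rows,
              0.0f, gW.memptr(), gW.n_rows);
        fvec gb = sum(dH, 1);
        fmat dprev = net.Wd[d].t() * dH;
        sWd[d].step(net.Wd[d], gW, lr, b1, b2, aeps, bc1, bc2);
        sbd[d].step(net.bd[d], gb, lr, b1, b2, aeps, bc1, bc2);
        dH = std::move(dprev);
      }

      // un-flatten
      fmat dcur = reshape(dH, Clast, (size_t)L * B);
      for (int bl = (int)nconv - 1; bl >= 0; --bl) {
        ConvBlock& cb = net.conv[bl];
        int Lo = cache_L[bl];
        int Cout = cb.W.n_rows;
        int Cin_b = cb.W.n_cols / net.k;
        const fmat& xhat = cache_xhat[bl];
        const fvec& invstd = cache_invstd[bl];
        const fvec& mu = cache_mu[bl];
        const size_t ncols = xhat.n_cols;
        const float nn = (float)ncols;
        // pool backward: scatter pooled gradients (w.r.t. the affine output)
        fmat dR(Cout, ncols, fill::zeros);
        {
          const umat& arg = cache_arg[bl];
          float* dst = dR.memptr();
          const float* src = dcur.memptr();
          const uword* ag = arg.memptr();
          const uword C = dcur.n_rows;
          for (uword j = 0; j < dcur.n_cols; ++j)
            for (uword c = 0; c < C; ++c) {
              size_t idx = (size_t)j * C + c;
              dst[ag[idx] * C + c] += src[idx];
            }
        }
        // batch-norm backward, fused with the ReLU mask; dR holds dL/dy
        fvec dgamma(Cout), dbeta(Cout), gb(Cout);
        {
          const size_t CHUNK = 1024;
          std::vector<double> t1(Cout, 0.0), t2(Cout, 0.0);
          std::vector<float> p1(Cout, 0.0f), p2(Cout, 0.0f);
          const float* xp = xhat.memptr();
          float* dp = dR.memptr();
          for (size_t j = 0; j < ncols; ++j) {
            const float* dc = dp + j * Cout;
            const float* xc = xp + j * Cout;
            for (int c = 0; c < Cout; ++c) {
              p1[c] += dc[c];
              p2[c] += dc[c] * xc[c];
            }
            if ((j + 1) % CHUNK == 0 || j + 1 == ncols) {
              for (int c = 0; c < Cout; ++c) {
                t1[c] += p1[c]; t2[c] += p2[c];
                p1[c] = 0; p2[c] = 0;
              }
            }
          }
          fvec s1(Cout), s2(Cout), thr(Cout);
          for (int c = 0; c < Cout; ++c) {
            dbeta[c] = (float)t1[c];
            dgamma[c] = (float)t2[c];
            s1[c] = cb.gamma[c] * (float)t1[c] / nn;
            s2[c] = cb.gamma[c] * (float)t2[c] / nn;
            thr[c] = -mu[c] * invstd[c];  // xhat value at pre-ReLU zero
          }
          std::vector<double> gsum(Cout, 0.0);
          std::vector<float> pg(Cout, 0.0f);
          const float* gp = cb.gamma.memptr();
          const float* ip = invstd.memptr();
          const float* s1p = s1.memptr();
          const float* s2p = s2.memptr();
          const float* tp = thr.memptr();
          for (size_t j = 0; j < ncols; ++j) {
            float* dc = dp + j * Cout;
            const float* xc = xp + j * Cout;
            for (int c = 0; c < Cout; ++c) {
              float g = (gp[c] * dc[c] - s1p[c] - xc[c] * s2p[c]) * ip[c];
              if (xc[c] <= tp[c]) g = 0;  // ReLU backward
              dc[c] = g;
              pg[c] += g;
            }
            if ((j + 1) % CHUNK == 0 || j + 1 == ncols) {
              for (int c = 0; c < Cout; ++c) { gsum[c] += pg[c]; pg[c] = 0; }
            }
          }
          for (int c = 0; c < Cout; ++c) gb[c] = (float)gsum[c];
        }
        // conv backward
        fmat gW(size(cb.W));
        conv_bwd_weights(dR, cache_in[bl], gW, Cin_b, Cout, Lo, B, net.k, net.pad);
        if (bl > 0) {
          fmat dX(Cin_b, (size_t)Lo * B);
          conv_bwd_data(cb.W, dR, dX, Cin_b, Cout, Lo, B, net.k, net.pad);
          dcur = std::move(dX);
        }
        sWc[bl].step(cb.W, gW, lr, b1, b2, aeps, bc1, bc2);
        sbc[bl].step(cb.b, gb, lr, b1, b2, aeps, bc1, bc2);
        sgam[bl].step(cb.gamma, dgamma, lr, b1, b2, aeps, bc1, bc2);
        sbet[bl].step(cb.beta, dbeta, lr, b1, b2, aeps, bc1, bc2);
      }
    }
    epoch_loss.push_back(loss_sum / n_batches);
    Rcpp::checkUserInterrupt();
  }

  return Rcpp::List::create(
    Rcpp::Named("net") = export_net(net, net_in),
    Rcpp::Named("loss") = Rcpp::wrap(epoch_loss));
}

// [[Rcpp::export]]
arma::mat cpp_cnn_forward(Rcpp::List net_in, const arma::mat& X, int chunk) {
  Net net = parse_net(net_in);
  int n = X.n_cols;
  if ((int)X.n_rows != net.input_len)
    Rcpp::stop("feature length does not match input_length");
  mat out(net.n_class, n);
  for (int start = 0; start < n; start += chunk) {
    int B = std::min(chunk, n - start);
    fmat Xb = conv_to<fmat>::from(X.cols(start, start + B - 1));
    fmat logits = infer_forward(net, Xb, B);
    out.cols(start, start + B - 1) = conv_to<mat>::from(logits);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_cnn_activations(Rcpp::List net_in, const arma::vec& x) {
  Net net = parse_net(net_in);
  if ((int)x.n_elem != net.input_len)
    Rcpp::stop("feature length does not match input_length");
  fmat Xb = conv_to<fmat>::from(x);
  fmat maps;
  std::vector<fvec> dense_pre;
  fvec flat;
  fmat logits = infer_forward(net, Xb, 1, &maps, &dense_pre, &flat);
  Rcpp::List pre(dense_pre.size());
  for (size_t i = 0; i < dense_pre.size(); ++i)
    pre[i] = Rcpp::wrap(conv_to<vec>::from(dense_pre[i]));
  return Rcpp::List::create(
    Rcpp::Named("maps") = Rcpp::wrap(conv_to<mat>::from(maps)),
    Rcpp::Named("flat") = Rcpp::wrap(conv_to<vec>::from(flat)),
    Rcpp::Named("dense_pre") = pre,
    Rcpp::Named("logits") = Rcpp::wrap(conv_to<vec>::from(logits.col(0))));
}

// Pairwise Minkowski distances between rows of A and rows of B.
// [[Rcpp::export]]
arma::mat cpp_minkowski(const arma::mat& A, const arma::mat& B, double p) {
  if (A.n_cols != B.n_cols) Rcpp::stop("dimension mismatch");
  int na = A.n_rows, nb = B.n_rows;
  if (p == 2.0) {
    vec a2 = sum(square(A), 1);
    vec b2 = sum(square(B), 1);
    mat D = repmat(a2, 1, nb) + repmat(b2.t(), na, 1) - 2.0 * (A * B.t());
    D.transform([](double v) { return v > 0 ? std::sqrt(v) : 0.0; });
    return D;
  }
  mat At = A.t();  // column-major access per sample
  mat Bt = B.t();
  uword d = At.n_rows;
  mat D(na, nb);
  for (int j = 0; j < nb; ++j) {
    const double* bj = Bt.colptr(j);
    for (int i = 0; i < na; ++i) {
      const double* ai = At.colptr(i);
      double s = 0;
      if (p == 1.0) {
        for (uword t = 0; t < d; ++t) s += std::abs(ai[t] - bj[t]);
        D(i, j) = s;
      } else {
        for (uword t = 0; t < d; ++t) s += std::pow(std::abs(ai[t] - bj[t]), p);
        D(i, j) = std::pow(s, 1.0 / p);
      }
    }
  }
  return D;
}
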