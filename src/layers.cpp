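// Batched 1-D layer kernels for the convolutional autoencoder.
// Feature maps are R arrays (n, L, C) in column-major order:
// element (i, l, c) sits at i + n*(l + L*c). Convolutions use the
// cross-correlation convention, stride 1; "same" padding is zero padding,
// pooling pads by replicating the final position. Activation codes:
// 0 = identity, 1 = tanh.

#include <Rcpp.h>
#define USE_FC_LEN_T
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double act1(double z, int a) { return a == 1 ? std::tanh(z) : z; }
// derivative expressed through the activation output y
static inline double dact1(double y, int a) { return a == 1 ? 1.0 - y * y : 1.0; }

// ---- raw-pointer helpers ---------------------------------------------------
// Convolutions run as im2col + BLAS dgemm: xcol is (n*Lout) x (s*Cin) in
// column-major order with row index i + n*l, matching the (n, L, C) feature
// map layout.

static void im2col(const double *__restrict__ x, int n, int L, int Cin,
                   int s, int lpad, int Lout, double *__restrict__ xcol) {
  const size_t M = (size_t)n * Lout;
  for (int k = 0; k < s; ++k)
    for (int ci = 0; ci < Cin; ++ci) {
      double *__restrict__ col = xcol + M * (k * Cin + ci);
      for (int l = 0; l < Lout; ++l) {
        const int lin = l + k - lpad;
        double *__restrict__ dst = col + (size_t)n * l;
        if (lin < 0 || lin >= L) {
          for (int i = 0; i < n; ++i) dst[i] = 0.0;
        } else {
          const double *__restrict__ src =
            x + (size_t)n * (lin + (size_t)L * ci);
          for (int i = 0; i < n; ++i) dst[i] = src[i];
        }
      }
    }
}

static void conv_fwd_raw(const double *x, int n, int L, int Cin,
                         const double *W, int s, int Cout,
                         const double *b, int activation,
                         int same, double *y) {
  const int lpad = same ? (s - 1) / 2 : 0;
  const int Lout = same ? L : L - s + 1;
  const int M = n * Lout, Kd = s * Cin;
  std::vector<double> xcol((size_t)M * Kd);
  im2col(x, n, L, Cin, s, lpad, Lout, xcol.data());
  const double one = 1.0, zero = 0.0;
  F77_CALL(dgemm)("N", "N", &M, &Cout, &Kd, &one, xcol.data(), &M,
                  W, &Kd, &zero, y, &M FCONE FCONE);
  for (int co = 0; co < Cout; ++co) {
    double *__restrict__ yp = y + (size_t)M * co;
    const double bc = b[co];
    if (activation == 1)
      for (int i = 0; i < M; ++i) yp[i] = std::tanh(yp[i] + bc);
    else
      for (int i = 0; i < M; ++i) yp[i] += bc;
  }
}

// dx must be zero-initialised by the caller; dW, db accumulated in place
static void conv_bwd_raw(const double *dy, const double *y, const double *x,
                         int n, int L, int Cin, const double *W, int s,
                         int Cout, int activation, int same, double *dx,
                         double *dW, double *db, double *scratch) {
  (void)scratch;
  const int lpad = same ? (s - 1) / 2 : 0;
  const int Lout = same ? L : L - s + 1;
  const int M = n * Lout, Kd = s * Cin;
  std::vector<double> xcol((size_t)M * Kd), dz((size_t)M * Cout),
      dxcol((size_t)M * Kd);
  im2col(x, n, L, Cin, s, lpad, Lout, xcol.data());
  for (int co = 0; co < Cout; ++co) {
    const double *__restrict__ dyp = dy + (size_t)M * co,
                 *__restrict__ yp = y + (size_t)M * co;
    double *__restrict__ dzp = dz.data() + (size_t)M * co;
    double bsum = 0.0;
    for (int i = 0; i < M; ++i) {
      dzp[i] = dyp[i] * dact1(yp[i], activation);
      bsum += dzp[i];
    }
    db[co] += bsum;
  }
  const double one = 1.0, zero = 0.0;
  // dW += xcol^T dz ; dxcol = dz W^T
  F77_CALL(dgemm)("T", "N", &Kd, &Cout, &M, &one, xcol.data(), &M,
                  dz.data(), &M, &one, dW, &Kd FCONE FCONE);
  F77_CALL(dgemm)("N", "T", &M, &Kd, &Cout, &one, dz.data(), &M,
                  W, &Kd, &zero, dxcol.data(), &M FCONE FCONE);
  for (int k = 0; k < s; ++k)
    for (int ci = 0; ci < Cin; ++ci) {
      const double *__restrict__ col =
        dxcol.data() + (size_t)M * (k * Cin + ci);
      for (int l = 0; l < Lout; ++l) {
        const int lin = l + k - lpad;
        if (lin < 0 || lin >= L) continue;
        double *__restrict__ dst = dx + (size_t)n * (lin + (size_t)L * ci);
        const double *__restrict__ src = col + (size_t)n * l;
        for (int i = 0; i < n; ++i) dst[i] += src[i];
      }
    }
}

static void pool_fwd_raw(const double *__restrict__ x, int n, int L, int C,
                         int p, const double *__restrict__ beta,
                         const double *__restrict__ bias, int activation,
                         double *__restrict__ y, double *__restrict__ m) {
  const int r = (p - L % p) % p, L2 = (L + r) / p;
  for (int c = 0; c < C; ++c) {
    for (int w = 0; w < L2; ++w) {
      const size_t off = (size_t)n * (w + (size_t)L2 * c);
      double *__restrict__ mp = m + off, *__restrict__ yp = y + off;
      for (int i = 0; i < n; ++i) mp[i] = 0.0;
      for (int o = 0; o < p; ++o) {
        int l = w * p + o;
        if (l >= L) l = L - 1;  // replicate-pad the last position
        const double *__restrict__ xp = x + (size_t)n * (l + (size_t)L * c);
        for (int i = 0; i < n; ++i) mp[i] += xp[i];
      }
      const double bc = beta[c], bb = bias[c];
      for (int i = 0; i < n; ++i) {
        mp[i] /= p;
        yp[i] = act1(bc * mp[i] + bb, activation);
      }
    }
  }
}

// dx zero-initialised by caller; dbeta, dbias accumulated
static void pool_bwd_raw(const double *__restrict__ dy,
                         const double *__restrict__ y,
                         const double *__restrict__ m, int n, int L, int C,
                         int p, const double *__restrict__ beta,
                         int activation, double *__restrict__ dx,
                         double *__restrict__ dbeta,
                         double *__restrict__ dbias) {
  const int r = (p - L % p) % p, L2 = (L + r) / p;
  for (int c = 0; c < C; ++c) {
    double bsum = 0.0, bbsum = 0.0;
    const double bc = beta[c];
    for (int w = 0; w < L2; ++w) {
      const size_t off = (size_t)n * (w + (size_t)L2 * c);
      const double *__restrict__ dyp = dy + off, *__restrict__ yp = y + off,
                   *__restrict__ mp = m + off;
      for (int i = 0; i < n; ++i) {
        const double dpre = dyp[i] * dact1(yp[i], activation);
        bsum += dpre * mp[i];
        bbsum += dpre;
        const double dm = dpre * bc / p;
        for (int o = 0; o < p; ++o) {
          int l = w * p + o;
          if (l >= L) l = L - 1;
          dx[i + (size_t)n * (l + (size_t)L * c)] += dm;
        }
      }
    }
    dbeta[c] += bsum;
    dbias[c] += bbsum;
  }
}

// ---- exported per-layer wrappers ------------------------------------------

// [[Rcpp::export(name = ".cpp_conv_fwd")]]
NumericVector cpp_conv_fwd(NumericVector x, int n, int L, int Cin,
                           NumericMatrix W, NumericVector b,
                           int activation, int same) {
  const int s = W.nrow() / Cin, Cout = W.ncol();
  const int Lout = same ? L : L - s + 1;
  NumericVector y((size_t)n * Lout * Cout);
  conv_fwd_raw(x.begin(), n, L, Cin, W.begin(), s, Cout, b.begin(),
               activation, same, y.begin());
  y.attr("dim") = IntegerVector::create(n, Lout, Cout);
  return y;
}

// [[Rcpp::export(name = ".cpp_conv_bwd")]]
List cpp_conv_bwd(NumericVector dy, NumericVector y, NumericVector x,
                  int n, int L, int Cin, NumericMatrix W,
                  int activation, int same) {
  const int s = W.nrow() / Cin, Cout = W.ncol();
  NumericVector dx((size_t)n * L * Cin);
  NumericMatrix dW(s * Cin, Cout);
  NumericVector db(Cout);
  std::vector<double> scratch(n);
  conv_bwd_raw(dy.begin(), y.begin(), x.begin(), n, L, Cin, W.begin(), s,
               Cout, activation, same, dx.begin(), dW.begin(), db.begin(),
               scratch.data());
  dx.attr("dim") = IntegerVector::create(n, L, Cin);
  return List::create(_["dx"] = dx, _["dW"] = dW, _["db"] = db);
}

// [[Rcpp::export(name = ".cpp_pool_fwd")]]
List cpp_pool_fwd(NumericVector x, int n, int L, int C, int p,
                  NumericVector beta, NumericVector bias, int activation) {
  const int r = (p - L % p) % p, L2 = (L + r) / p;
  NumericVector y((size_t)n * L2 * C), m((size_t)n * L2 * C);
  pool_fwd_raw(x.begin(), n, L, C, p, beta.begin(), bias.begin(), activation,
               y.begin(), m.begin());
  y.attr("dim") = IntegerVector::create(n, L2, C);
  m.attr("dim") = IntegerVector::create(n, L2, C);
  return List::create(_["y"] = y, _["m"] = m);
}

// [[Rcpp::export(name = ".cpp_pool_bwd")]]
List cpp_pool_bwd(NumericVector dy, NumericVector y, NumericVector m,
                  int n, int L, int C, int p,
                  NumericVector beta, int activation) {
  NumericVector dx((size_t)n * L * C), dbeta(C), dbias(C);
  pool_bwd_raw(dy.begin(), y.begin(), m.begin(), n, L, C, p, beta.begin(),
               activation, dx.begin(), dbeta.begin(), dbias.begin());
  dx.attr("dim") = IntegerVector::create(n, L, C);
  return List::create(_["dx"] = dx, _["dbeta"] = dbeta, _["dbias"] = dbias);
}

// [[Rcpp::export(name = ".cpp_upsample_fwd")]]
NumericVector cpp_upsample_fwd(NumericVector x, int n, int L2, int C,
                               int p, int L_target) {
  NumericVector y((size_t)n * L_target * C);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < L_target; ++l) {
      const int w = l / p;
      const double *xp = x.begin() + (size_t)n * (w + (size_t)L2 * c);
      double *yp = y.begin() + (size_t)n * (l + (size_t)L_target * c);
      for (int i = 0; i < n; ++i) yp[i] = xp[i];
    }
  y.attr("dim") = IntegerVector::create(n, L_target, C);
  return y;
}

// [[Rcpp::export(name = ".cpp_upsample_bwd")]]
NumericVector cpp_upsample_bwd(NumericVector dy, int n, int L_target, int C,
                               int p, int L2) {
  NumericVector dx((size_t)n * L2 * C);
  for (int c = 0; c < C; ++c)
    for (int l = 0; l < L_target; ++l) {
      const int w = l / p;
      const double *dyp = dy.begin() + (size_t)n * (l + (size_t)L_target * c);
      double *dxp = dx.begin() + (size_t)n * (w + (size_t)L2 * c);
      for (int i = 0; i < n; ++i) dxp[i] += dyp[i];
    }
  dx.attr("dim") = IntegerVector::create(n, L2, C);
  return dx;
}

// ---- fused greedy block-autoencoder step ----------------------------------
// One mini-batch of one convolution block's local autoencoder:
// conv -> pool -> nearest-neighbour upsample -> reconstruction convolution,
// squared-error loss against the block input, full backward pass.
// act_out is identity when the target is the (unbounded) standardized input.

// [[Rcpp::export(name = ".cpp_block_ae_step")]]
List cpp_block_ae_step(NumericVector H, int n, int Lin, int Cin,
                       NumericMatrix convWm, NumericVector convb,
                       NumericVector beta, NumericVector bias,
                       NumericMatrix deconvWm, NumericVector deconvb,
                       int s, int p, int Cout, int Lpool,
                       int activation, int same, int act_out) {
  const int Lc = same ? Lin : Lin - s + 1;
  std::vector<double> y1((size_t)n * Lc * Cout), z((size_t)n * Lpool * Cout),
      m((size_t)n * Lpool * Cout), u((size_t)n * Lc * Cout),
      hhat((size_t)n * Lc * Cin);
  conv_fwd_raw(H.begin(), n, Lin, Cin, convWm.begin(), s, Cout, convb.begin(),
               activation, same, y1.data());
  pool_fwd_raw(y1.data(), n, Lc, Cout, p, beta.begin(), bias.begin(),
               activation, z.data(), m.data());
  for (int c = 0; c < Cout; ++c)  // upsample to length Lc
    for (int l = 0; l < Lc; ++l) {
      const int w = l / p;
      const double *zp = z.data() + (size_t)n * (w + (size_t)Lpool * c);
      double *up = u.data() + (size_t)n * (l + (size_t)Lc * c);
      for (int i = 0; i < n; ++i) up[i] = zp[i];
    }
  conv_fwd_raw(u.data(), n, Lc, Cout, deconvWm.begin(), s, Cin,
               deconvb.begin(), act_out, 1, hhat.data());
  const size_t total = (size_t)n * Lc * Cin;
  double loss = 0.0;
  std::vector<double> dh(total);
  for (size_t q = 0; q < total; ++q) {
    const double diff = hhat[q] - H[q];
    loss += diff * diff;
    dh[q] = 2.0 * diff / total;
  }
  loss /= total;

  std::vector<double> scratch(n);
  NumericMatrix ddeconvW(s * Cout, Cin);
  NumericVector ddeconvb(Cin);
  std::vector<double> du((size_t)n * Lc * Cout, 0.0);
  conv_bwd_raw(dh.data(), hhat.data(), u.data(), n, Lc, Cout,
               deconvWm.begin(), s, Cin, act_out, 1, du.data(),
               ddeconvW.begin(), ddeconvb.begin(), scratch.data());
  std::vector<double> dz((size_t)n * Lpool * Cout, 0.0);
  for (int c = 0; c < Cout; ++c)
    for (int l = 0; l < Lc; ++l) {
      const int w = l / p;
      const double *dup = du.data() + (size_t)n * (l + (size_t)Lc * c);
      double *dzp = dz.data() + (size_t)n * (w + (size_t)Lpool * c);
      for (int i = 0; i < n; ++i) dzp[i] += dup[i];
    }
  NumericVector dbeta(Cout), dbias(Cout);
  std::vector<double> dy1((size_t)n * Lc * Cout, 0.0);
  pool_bwd_raw(dz.data(), z.data(), m.data(), n, Lc, Cout, p, beta.begin(),
               activation, dy1.data(), dbeta.begin(), dbias.begin());
  NumericMatrix dconvW(s * Cin, Cout);
  NumericVector dconvb(Cout);
  std::vector<double> dH((size_t)n * Lin * Cin, 0.0);
  conv_bwd_raw(dy1.data(), y1.data(), H.begin(), n, Lin, Cin, convWm.begin(),
               s, Cout, activation, same, dH.data(), dconvW.begin(),
               dconvb.begin(), scratch.data());
  return List::create(_["loss"] = loss,
                      _["convW"] = dconvW, _["convb"] = dconvb,
                      _["beta"] = dbeta, _["bias"] = dbias,
                      _["deconvW"] = ddeconvW, _["deconvb"] = ddeconvb);
}

// ---- fused supervised fine-tuning epoch -----------------------------------
// One full epoch of mini-batch gradient descent on the classifier. R keeps
// ownership of the shuffle (so the RNG stream and results match the
// per-batch reference path); the batch loop, forward/backward pass and SGD
// update all run here. Parameters are cloned, updated in place and returned.

// [[Rcpp::export(name = ".cpp_finetune_epoch")]]
List cpp_finetune_epoch(NumericMatrix X, NumericMatrix Y, IntegerVector idx,
                        int bs, List convW_in, List convB_in,
                        List poolBeta_in, List poolBias_in,
                        NumericMatrix encW_in, NumericVector encB_in,
                        NumericMatrix headW_in, NumericVector headB_in,
                        IntegerMatrix blockinfo, int activation, int same,
                        int enc_trainable, double lr, double wd) {
  const int n = X.nrow(), L0 = X.ncol(), K = Y.ncol();
  const int B = blockinfo.nrow();
  List convW(B), convB(B), poolBeta(B), poolBias(B);
  for (int b = 0; b < B; ++b) {
    convW[b] = clone(as<NumericMatrix>(convW_in[b]));
    convB[b] = clone(as<NumericVector>(convB_in[b]));
    poolBeta[b] = clone(as<NumericVector>(poolBeta_in[b]));
    poolBias[b] = clone(as<NumericVector>(poolBias_in[b]));
  }
  NumericMatrix encW = clone(encW_in), headW = clone(headW_in);
  NumericVector encB = clone(encB_in), headB = clone(headB_in);
  const int latent = encW.ncol(), flat = encW.nrow();

  // workspace sized for the largest batch
  std::vector<std::vector<double>> conv_y(B), pool_y(B), pool_m(B);
  std::vector<int> Lconv(B);
  for (int b = 0; b < B; ++b) {
    const int s = blockinfo(b, 0), Cout = blockinfo(b, 3);
    const int Lin = blockinfo(b, 4), Lpool = blockinfo(b, 5);
    Lconv[b] = same ? Lin : Lin - s + 1;
    conv_y[b].resize((size_t)bs * Lconv[b] * Cout);
    pool_y[b].resize((size_t)bs * Lpool * Cout);
    pool_m[b].resize((size_t)bs * Lpool * Cout);
  }
  std::vector<double> Xb((size_t)bs * L0), Yb((size_t)bs * K),
      z((size_t)bs * latent), prob((size_t)bs * K), dlog((size_t)bs * K),
      dz((size_t)bs * latent), dflat((size_t)bs * flat), scratch(bs);
  double loss_sum = 0.0;

  for (int st = 0; st < n; st += bs) {
    const int nb = std::min(bs, n - st);
    for (int l = 0; l < L0; ++l)
      for (int i = 0; i < nb; ++i)
        Xb[i + (size_t)nb * l] = X(idx[st + i] - 1, l);
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < nb; ++i)
        Yb[i + (size_t)nb * k] = Y(idx[st + i] - 1, k);

    // ---- forward ----
    const double *cur = Xb.data();
    for (int b = 0; b < B; ++b) {
      const int s = blockinfo(b, 0), p = blockinfo(b, 1);
      const int Cin = blockinfo(b, 2), Cout = blockinfo(b, 3);
      const int Lin = blockinfo(b, 4);
      NumericMatrix Wb = convW[b];
      NumericVector bb = convB[b], beta = poolBeta[b], bias = poolBias[b];
      conv_fwd_raw(cur, nb, Lin, Cin, Wb.begin(), s, Cout, bb.begin(),
                   activation, same, conv_y[b].data());
      pool_fwd_raw(conv_y[b].data(), nb, Lconv[b], Cout, p, beta.begin(),
                   bias.begin(), activation, pool_y[b].data(),
                   pool_m[b].data());
      cur = pool_y[b].data();
    }
    for (int j = 0; j < latent; ++j) {
      double *zp = z.data() + (size_t)nb * j;
      for (int i = 0; i < nb; ++i) zp[i] = encB[j];
      for (int q = 0; q < flat; ++q) {
        const double w = encW(q, j);
        const double *fp = cur + (size_t)nb * q;
        for (int i = 0; i < nb; ++i) zp[i] += w * fp[i];
      }
      if (activation == 1)
        for (int i = 0; i < nb; ++i) zp[i] = std::tanh(zp[i]);
    }
    for (int k = 0; k < K; ++k) {
      double *pp = prob.data() + (size_t)nb * k;
      for (int i = 0; i < nb; ++i) pp[i] = headB[k];
      for (int j = 0; j < latent; ++j) {
        const double w = headW(j, k);
        const double *zp = z.data() + (size_t)nb * j;
        for (int i = 0; i < nb; ++i) pp[i] += w * zp[i];
      }
    }
    double loss = 0.0;
    for (int i = 0; i < nb; ++i) {
      double mx = prob[i];
      for (int k = 1; k < K; ++k)
        mx = std::max(mx, prob[i + (size_t)nb * k]);
      double se = 0.0;
      for (int k = 0; k < K; ++k) {
        double e = std::exp(prob[i + (size_t)nb * k] - mx);
        prob[i + (size_t)nb * k] = e;
        se += e;
      }
      double ptrue = 0.0;
      for (int k = 0; k < K; ++k) {
        prob[i + (size_t)nb * k] /= se;
        ptrue += prob[i + (size_t)nb * k] * Yb[i + (size_t)nb * k];
      }
      loss -= std::log(std::max(ptrue, 1e-300));
    }
    loss /= nb;
    loss_sum += loss * nb;

    // ---- backward + immediate SGD update (head first, grads via copies) --
    for (int k = 0; k < K; ++k)
      for (int i = 0; i < nb; ++i)
        dlog[i + (size_t)nb * k] =
          (prob[i + (size_t)nb * k] - Yb[i + (size_t)nb * k]) / nb;

    // latent gradient must use the *pre-update* head weights
    if (enc_trainable) {
      for (int j = 0; j < latent; ++j) {
        double *dzp = dz.data() + (size_t)nb * j;
        for (int i = 0; i < nb; ++i) dzp[i] = 0.0;
        for (int k = 0; k < K; ++k) {
          const double w = headW(j, k);
          const double *dlp = dlog.data() + (size_t)nb * k;
          for (int i = 0; i < nb; ++i) dzp[i] += w * dlp[i];
        }
        const double *zp = z.data() + (size_t)nb * j;
        for (int i = 0; i < nb; ++i) dzp[i] *= dact1(zp[i], activation);
      }
    }
    for (int k = 0; k < K; ++k) {
      double bsum = 0.0;
      const double *dlp = dlog.data() + (size_t)nb * k;
      for (int i = 0; i < nb; ++i) bsum += dlp[i];
      for (int j = 0; j < latent; ++j) {
        double wsum = 0.0;
        const double *zp = z.data() + (size_t)nb * j;
        for (int i = 0; i < nb; ++i) wsum += zp[i] * dlp[i];
        headW(j, k) -= lr * (wsum + wd * headW(j, k));
      }
      headB[k] -= lr * (bsum + wd * headB[k]);
    }
    if (!enc_trainable) continue;

    for (int q = 0; q < flat; ++q) {
      double *dfp = dflat.data() + (size_t)nb * q;
      for (int i = 0; i < nb; ++i) dfp[i] = 0.0;
    }
    for (int j = 0; j < latent; ++j) {
      const double *dzp = dz.data() + (size_t)nb * j;
      double bsum = 0.0;
      for (int i = 0; i < nb; ++i) bsum += dzp[i];
      for (int q = 0; q < flat; ++q) {
        const double *fp = cur + (size_t)nb * q;
        double *dfp = dflat.data() + (size_t)nb * q;
        const double w = encW(q, j);
        double wsum = 0.0;
        for (int i = 0; i < nb; ++i) {
          wsum += fp[i] * dzp[i];
          dfp[i] += w * dzp[i];
        }
        encW(q, j) -= lr * (wsum + wd * encW(q, j));
      }
      encB[j] -= lr * (bsum + wd * encB[j]);
    }

    std::vector<double> dcur(dflat.begin(),
                             dflat.begin() + (size_t)nb * flat);
    for (int b = B - 1; b >= 0; --b) {
      const int s = blockinfo(b, 0), p = blockinfo(b, 1);
      const int Cin = blockinfo(b, 2), Cout = blockinfo(b, 3);
      const int Lin = blockinfo(b, 4);
      NumericMatrix Wb = convW[b];
      NumericVector bb = convB[b], beta = poolBeta[b], bias = poolBias[b];
      NumericVector dbeta(Cout), dbias(Cout);
      std::vector<double> dconv((size_t)nb * Lconv[b] * Cout, 0.0);
      pool_bwd_raw(dcur.data(), pool_y[b].data(), pool_m[b].data(), nb,
                   Lconv[b], Cout, p, beta.begin(), activation, dconv.data(),
                   dbeta.begin(), dbias.begin());
      NumericMatrix dW(s * Cin, Cout);
      NumericVector db(Cout);
      std::vector<double> dprev((size_t)nb * Lin * Cin, 0.0);
      conv_bwd_raw(dconv.data(), conv_y[b].data(),
                   b == 0 ? Xb.data() : pool_y[b - 1].data(), nb, Lin, Cin,
                   Wb.begin(), s, Cout, activation, same, dprev.data(),
                   dW.begin(), db.begin(), scratch.data());
      for (int q = 0; q < s * Cin; ++q)
        for (int co = 0; co < Cout; ++co)
          Wb(q, co) -= lr * (dW(q, co) + wd * Wb(q, co));
      for (int co = 0; co < Cout; ++co) {
        bb[co] -= lr * (db[co] + wd * bb[co]);
        beta[co] -= lr * (dbeta[co] + wd * beta[co]);
        bias[co] -= lr * (dbias[co] + wd * bias[co]);
      }
      dcur.swap(dprev);
    }
  }

  return List::create(
    _["loss"] = loss_sum / n,
    _["convW"] = convW, _["convB"] = convB,
    _["poolBeta"] = poolBeta, _["poolBias"] = poolBias,
    _["encW"] = encW, _["encB"] = encB,
    _["headW"] = headW, _["headB"] = headB);
}

// ---- fused supervised training step ---------------------------------------
// One mini-batch of the classifier: encoder forward (conv/pool blocks, dense
// to latent), softmax head, cross-entropy, full backward pass. Fusing the
// whole step into one call removes the per-layer call overhead that would
// otherwise dominate at soil-vector sizes.
//
// blockinfo: B x 6 integer matrix, rows (kernel, pool, Cin, Cout, len_in,
// len_pool); lengths follow the architecture bookkeeping done in R.

// [[Rcpp::export(name = ".cpp_clf_step")]]
List cpp_clf_step(NumericMatrix X, NumericMatrix Y, List convW, List convB,
                  List poolBeta, List poolBias, NumericMatrix encW,
                  NumericVector encB, NumericMatrix headW,
                  NumericVector headB, IntegerMatrix blockinfo,
                  int activation, int same, int enc_trainable) {
  const int n = X.nrow(), B = blockinfo.nrow();
  const int latent = encW.ncol(), K = headW.ncol(), flat = encW.nrow();

  // forward through the blocks, keeping every intermediate for backward
  std::vector<std::vector<double>> conv_y(B), pool_y(B), pool_m(B);
  const double *cur = X.begin();
  int cur_L = blockinfo(0, 4), cur_C = 1;
  std::vector<const double *> block_in(B);
  std::vector<int> Lconv(B);
  for (int b = 0; b < B; ++b) {
    const int s = blockinfo(b, 0), p = blockinfo(b, 1);
    const int Cin = blockinfo(b, 2), Cout = blockinfo(b, 3);
    const int Lin = blockinfo(b, 4), Lpool = blockinfo(b, 5);
    const int Lc = same ? Lin : Lin - s + 1;
    Lconv[b] = Lc;
    block_in[b] = cur;
    NumericMatrix Wb = convW[b];
    NumericVector bb = convB[b], beta = poolBeta[b], bias = poolBias[b];
    conv_y[b].assign((size_t)n * Lc * Cout, 0.0);
    conv_fwd_raw(cur, n, Lin, Cin, Wb.begin(), s, Cout, bb.begin(),
                 activation, same, conv_y[b].data());
    pool_y[b].assign((size_t)n * Lpool * Cout, 0.0);
    pool_m[b].assign((size_t)n * Lpool * Cout, 0.0);
    pool_fwd_raw(conv_y[b].data(), n, Lc, Cout, p, beta.begin(), bias.begin(),
                 activation, pool_y[b].data(), pool_m[b].data());
    cur = pool_y[b].data();
    cur_L = Lpool; cur_C = Cout;
  }
  // dense to latent (activation), then linear head + softmax
  std::vector<double> z((size_t)n * latent), prob((size_t)n * K);
  for (int j = 0; j < latent; ++j) {
    double *zp = z.data() + (size_t)n * j;
    for (int i = 0; i < n; ++i) zp[i] = encB[j];
    for (int q = 0; q < flat; ++q) {
      const double w = encW(q, j);
      const double *fp = cur + (size_t)n * q;
      for (int i = 0; i < n; ++i) zp[i] += w * fp[i];
    }
    if (activation == 1)
      for (int i = 0; i < n; ++i) zp[i] = std::tanh(zp[i]);
  }
  for (int k = 0; k < K; ++k) {
    double *pp = prob.data() + (size_t)n * k;
    for (int i = 0; i < n; ++i) pp[i] = headB[k];
    for (int j = 0; j < latent; ++j) {
      const double w = headW(j, k);
      const double *zp = z.data() + (size_t)n * j;
      for (int i = 0; i < n; ++i) pp[i] += w * zp[i];
    }
  }
  double loss = 0.0;
  for (int i = 0; i < n; ++i) {
    double mx = prob[i];
    for (int k = 1; k < K; ++k) mx = std::max(mx, prob[i + (size_t)n * k]);
    double se = 0.0;
    for (int k = 0; k < K; ++k) {
      double e = std::exp(prob[i + (size_t)n * k] - mx);
      prob[i + (size_t)n * k] = e;
      se += e;
    }
    double ptrue = 0.0;
    for (int k = 0; k < K; ++k) {
      prob[i + (size_t)n * k] /= se;
      ptrue += prob[i + (size_t)n * k] * Y(i, k);
    }
    loss -= std::log(std::max(ptrue, 1e-300));
  }
  loss /= n;

  // backward
  NumericMatrix dheadW(latent, K);
  NumericVector dheadB(K);
  std::vector<double> dlog((size_t)n * K);
  for (int k = 0; k < K; ++k) {
    double bsum = 0.0;
    for (int i = 0; i < n; ++i) {
      dlog[i + (size_t)n * k] = (prob[i + (size_t)n * k] - Y(i, k)) / n;
      bsum += dlog[i + (size_t)n * k];
    }
    dheadB[k] = bsum;
    for (int j = 0; j < latent; ++j) {
      double wsum = 0.0;
      const double *zp = z.data() + (size_t)n * j;
      for (int i = 0; i < n; ++i) wsum += zp[i] * dlog[i + (size_t)n * k];
      dheadW(j, k) = wsum;
    }
  }
  List grads = List::create(_["headW"] = dheadW, _["headB"] = dheadB);
  if (!enc_trainable)
    return List::create(_["loss"] = loss, _["grads"] = grads);

  std::vector<double> dz((size_t)n * latent, 0.0);
  for (int j = 0; j < latent; ++j) {
    double *dzp = dz.data() + (size_t)n * j;
    for (int k = 0; k < K; ++k) {
      const double w = headW(j, k);
      const double *dlp = dlog.data() + (size_t)n * k;
      for (int i = 0; i < n; ++i) dzp[i] += w * dlp[i];
    }
    const double *zp = z.data() + (size_t)n * j;
    for (int i = 0; i < n; ++i) dzp[i] *= dact1(zp[i], activation);
  }
  NumericMatrix dencW(flat, latent);
  NumericVector dencB(latent);
  std::vector<double> dflat((size_t)n * flat, 0.0);
  for (int j = 0; j < latent; ++j) {
    const double *dzp = dz.data() + (size_t)n * j;
    double bsum = 0.0;
    for (int i = 0; i < n; ++i) bsum += dzp[i];
    dencB[j] = bsum;
    for (int q = 0; q < flat; ++q) {
      const double *fp = cur + (size_t)n * q;
      double *dfp = dflat.data() + (size_t)n * q;
      const double w = encW(q, j);
      double wsum = 0.0;
      for (int i = 0; i < n; ++i) {
        wsum += fp[i] * dzp[i];
        dfp[i] += w * dzp[i];
      }
      dencW(q, j) += wsum;
    }
  }

  List dconvW(B), dconvB(B), dpoolBeta(B), dpoolBias(B);
  std::vector<double> dcur = dflat, scratch(n);
  for (int b = B - 1; b >= 0; --b) {
    const int s = blockinfo(b, 0), p = blockinfo(b, 1);
    const int Cin = blockinfo(b, 2), Cout = blockinfo(b, 3);
    const int Lin = blockinfo(b, 4);
    NumericMatrix Wb = convW[b];
    NumericVector beta = poolBeta[b];
    NumericVector dbeta(Cout), dbias(Cout);
    std::vector<double> dconv((size_t)n * Lconv[b] * Cout, 0.0);
    pool_bwd_raw(dcur.data(), pool_y[b].data(), pool_m[b].data(), n,
                 Lconv[b], Cout, p, beta.begin(), activation, dconv.data(),
                 dbeta.begin(), dbias.begin());
    NumericMatrix dW(s * Cin, Cout);
    NumericVector db(Cout);
    std::vector<double> dprev((size_t)n * Lin * Cin, 0.0);
    conv_bwd_raw(dconv.data(), conv_y[b].data(), block_in[b], n, Lin, Cin,
                 Wb.begin(), s, Cout, activation, same, dprev.data(),
                 dW.begin(), db.begin(), scratch.data());
    dconvW[b] = dW; dconvB[b] = db;
    dpoolBeta[b] = dbeta; dpoolBias[b] = dbias;
    dcur.swap(dprev);
  }
  grads["convW"] = dconvW; grads["convB"] = dconvB;
  grads["poolBeta"] = dpoolBeta; grads["poolBias"] = dpoolBias;
  grads["encW"] = dencW; grads["encB"] = dencB;
  return List::create(_["loss"] = loss, _["grads"] = grads);
}
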