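// Compiled kernels for the 3D conv net. Index plans are built in R
// (conv_plan / pool_plan); indices are 1-based and a value of n_in + 1
// denotes a zero-padded position. Convolution is per-sample im2col gather
// + GEMM, so the unfold buffer (27x the activations) stays a few MB and
// cache-resident instead of being materialized batch-wide.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Whole-extractor fused path. The convolutional stack (conv -> batch norm ->
// ReLU -> channelwise dropout -> max-pool, repeated) runs in single
// precision with all intermediates held in C++-owned memory, which roughly
// halves memory traffic and removes per-op R allocations. The dense layers
// and heads stay in R (they are small). Weight gradients are accumulated in
// single precision and returned as doubles.

struct BlockCache {
  arma::fmat Xin;        // (n_in x B) block input
  arma::fmat xhat;       // (ch x ov*B) normalized pre-activation
  arma::fvec inv_sd;     // ch
  arma::Col<int> argmax; // n_out*B, 0-based winner rows
  arma::fvec scale;      // ch*B channelwise dropout scale (empty = off)
};

struct ExtCache {
  std::vector<BlockCache> blocks;
};

// branch-free im2col via a zero-padded copy of the sample volume:
// the padded neighborhood makes every kernel offset an interior read, so
// the unfold is plain strided copies with no per-element bounds test.
// Xcol rows are ordered channel-fastest within kernel offset (dx fastest,
// then dy, dz), matching the weight-matrix column order.
static void pad_sample(const float* xb, int in_ch, int D, float* pad) {
  const int Dp = D + 2;
  std::fill(pad, pad + (std::size_t)in_ch * Dp * Dp * Dp, 0.0f);
  for (int z = 0; z < D; ++z) {
    for (int y = 0; y < D; ++y) {
      const float* src = xb + (std::size_t)in_ch * D * (y + (std::size_t)D * z);
      float* dst = pad + (std::size_t)in_ch *
        (1 + (std::size_t)Dp * (y + 1 + (std::size_t)Dp * (z + 1)));
      std::copy(src, src + (std::size_t)in_ch * D, dst);
    }
  }
}

static void im2col_padded(const float* pad, int in_ch, int D, float* Xcol) {
  const int Dp = D + 2;
  const int K = in_ch * 27;
  for (int dz = -1; dz <= 1; ++dz)
  for (int dy = -1; dy <= 1; ++dy)
  for (int dx = -1; dx <= 1; ++dx) {
    // kernel offsets enumerated dx fastest, matching the weight layout
    const int kk = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
    for (int z = 0; z < D; ++z) {
      for (int y = 0; y < D; ++y) {
        const float* src = pad + (std::size_t)in_ch *
          (1 + dx + (std::size_t)Dp * (y + 1 + dy + (std::size_t)Dp * (z + 1 + dz)));
        float* dst = Xcol + (std::size_t)kk * in_ch +
          (std::size_t)K * (std::size_t)D * (y + (std::size_t)D * z);
        for (int x = 0; x < D; ++x) {
          for (int c = 0; c < in_ch; ++c) dst[c] = src[c];
          src += in_ch;
          dst += K;
        }
      }
    }
  }
}

static void col2im_padded(const float* dXcol, int in_ch, int D, float* pad) {
  const int Dp = D + 2;
  const int K = in_ch * 27;
  std::fill(pad, pad + (std::size_t)in_ch * Dp * Dp * Dp, 0.0f);
  for (int dz = -1; dz <= 1; ++dz)
  for (int dy = -1; dy <= 1; ++dy)
  for (int dx = -1; dx <= 1; ++dx) {
    const int kk = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
    for (int z = 0; z < D; ++z) {
      for (int y = 0; y < D; ++y) {
        float* dst = pad + (std::size_t)in_ch *
          (1 + dx + (std::size_t)Dp * (y + 1 + dy + (std::size_t)Dp * (z + 1 + dz)));
        const float* src = dXcol + (std::size_t)kk * in_ch +
          (std::size_t)K * (std::size_t)D * (y + (std::size_t)D * z);
        for (int x = 0; x < D; ++x) {
          for (int c = 0; c < in_ch; ++c) dst[c] += src[c];
          dst += in_ch;
          src += K;
        }
      }
    }
  }
}

static void unpad_sample(const float* pad, int in_ch, int D, float* xb) {
  const int Dp = D + 2;
  for (int z = 0; z < D; ++z) {
    for (int y = 0; y < D; ++y) {
      const float* src = pad + (std::size_t)in_ch *
        (1 + (std::size_t)Dp * (y + 1 + (std::size_t)Dp * (z + 1)));
      float* dst = xb + (std::size_t)in_ch * D * (y + (std::size_t)D * z);
      std::copy(src, src + (std::size_t)in_ch * D, dst);
    }
  }
}

// [[Rcpp::export(name = ".cpp_ext_fw")]]
List cpp_ext_fw(const arma::mat& X, List blocks, bool training, double eps) {
  const int B = X.n_cols;
  const int nb = blocks.size();
  arma::fmat A = arma::conv_to<arma::fmat>::from(X);
  XPtr<ExtCache> cache(new ExtCache(), true);
  if (training) cache->blocks.resize(nb);
  List mus(nb), vars(nb);
  for (int bl = 0; bl < nb; ++bl) {
    List bp = blocks[bl];
    arma::fmat W = arma::conv_to<arma::fmat>::from(as<arma::mat>(bp["W"]));
    arma::fvec bias = arma::conv_to<arma::fvec>::from(as<arma::vec>(bp["b"]));
    arma::fvec gamma = arma::conv_to<arma::fvec>::from(as<arma::vec>(bp["gamma"]));
    arma::fvec beta = arma::conv_to<arma::fvec>::from(as<arma::vec>(bp["beta"]));
    IntegerVector pidx = bp["pool_idx"];
    const int K = bp["K"], ov = bp["ov"];
    const int D = bp["D"], in_ch = bp["in_ch"];
    const int pool_n_out = bp["pool_n_out"];
    const int ch = W.n_rows;
    // convolution
    arma::fmat Y(ch, (std::size_t)ov * B);
    {
      arma::fvec pad((std::size_t)in_ch * (D + 2) * (D + 2) * (D + 2));
      arma::fmat Xcol(K, ov);
      for (int b = 0; b < B; ++b) {
        pad_sample(A.colptr(b), in_ch, D, pad.memptr());
        im2col_padded(pad.memptr(), in_ch, D, Xcol.memptr());
        Y.cols((std::size_t)b * ov, (std::size_t)(b + 1) * ov - 1) = W * Xcol;
      }
      Y.each_col() += bias;
    }
    // batch norm statistics
    const std::size_t n = (std::size_t)ov * B;
    arma::fvec mu(ch), var(ch);
    if (training) {
      arma::fvec m1(ch, arma::fill::zeros), m2(ch, arma::fill::zeros);
      const float* yp = Y.memptr();
      for (std::size_t i = 0; i < n; ++i) {
        const float* yi = yp + i * ch;
        for (int c = 0; c < ch; ++c) { m1[c] += yi[c]; m2[c] += yi[c] * yi[c]; }
      }
      mu = m1 / (float)n;
      var = m2 / (float)n - mu % mu;
      var.transform([](float v) { return v > 0 ? v : 0.0f; });
    } else {
      mu = arma::conv_to<arma::fvec>::from(as<arma::vec>(bp["run_mean"]));
      var = arma::conv_to<arma::fvec>::from(as<arma::vec>(bp["run_var"]));
    }
    arma::fvec inv_sd = 1.0f / arma::sqrt(var + (float)eps);
    // dropout scale per (channel, sample); empty vector means off
    arma::fvec scale;
    if (training && bp.containsElementNamed("drop_scale")) {
      NumericVector ds = bp["drop_scale"];
      if (ds.size() > 0) scale = arma::conv_to<arma::fvec>::from(as<arma::vec>(ds));
    }
    const bool has_scale = scale.n_elem > 0;
    // fused normalize + affine + ReLU + dropout scale, xhat retained
    arma::fmat xhat;
    if (training) xhat.set_size(ch, n);
    {
      float* yp = Y.memptr();
      float* hp = training ? xhat.memptr() : nullptr;
      for (std::size_t i = 0; i < n; ++i) {
        const int b = (int)(i / ov);
        float* yi = yp + i * ch;
        for (int c = 0; c < ch; ++c) {
          const float h = (yi[c] - mu[c]) * inv_sd[c];
          if (training) hp[i * ch + c] = h;
          float v = h * gamma[c] + beta[c];
          v = v > 0 ? v : 0.0f;
          if (has_scale) v *= scale[c + (std::size_t)b * ch];
          yi[c] = v;
        }
      }
    }
    // max-pool: view Y as (ch*ov) x B
    arma::fmat Yv(Y.memptr(), (std::size_t)ch * ov, B, false, true);
    arma::fmat P(pool_n_out, B);
    arma::Col<int> argmax((std::size_t)pool_n_out * B);
    for (int b = 0; b < B; ++b) {
      const float* xb = Yv.colptr(b);
      float* ob = P.colptr(b);
      int* ab = argmax.memptr() + (std::size_t)b * pool_n_out;
      for (int e = 0; e < pool_n_out; ++e) {
        const int base = e * 8;
        float m = xb[pidx[base] - 1];
        int a = pidx[base] - 1;
        for (int j = 1; j < 8; ++j) {
          const float v = xb[pidx[base + j] - 1];
          if (v > m) { m = v; a = pidx[base + j] - 1; }
        }
        ob[e] = m;
        ab[e] = a;
      }
    }
    if (training) {
      BlockCache& bc = cache->blocks[bl];
      bc.Xin = std::move(A);
      bc.xhat = std::move(xhat);
      bc.inv_sd = inv_sd;
      bc.argmax = std::move(argmax);
      bc.scale = scale;
      mus[bl] = wrap(arma::conv_to<arma::vec>::from(mu));
      vars[bl] = wrap(arma::conv_to<arma::vec>::from(var));
    }
    A = std::move(P);
  }
  arma::mat out = arma::conv_to<arma::mat>::from(A);
  if (training) {
    return List::create(_["out"] = out, _["mu"] = mus, _["var"] = vars,
                        _["cache"] = cache);
  }
  return List::create(_["out"] = out);
}

// [[Rcpp::export(name = ".cpp_ext_bw")]]
List cpp_ext_bw(SEXP cache_ptr, const arma::mat& dOut, List blocks) {
  XPtr<ExtCache> cache(cache_ptr);
  const int nb = blocks.size();
  const int B = dOut.n_cols;
  arma::fmat dA = arma::conv_to<arma::fmat>::from(dOut);
  List dWs(nb), dbs(nb), dgammas(nb), dbetas(nb);
  for (int bl = nb - 1; bl >= 0; --bl) {
    List bp = blocks[bl];
    arma::fmat W = arma::conv_to<arma::fmat>::from(as<arma::mat>(bp["W"]));
    arma::fvec gamma = arma::conv_to<arma::fvec>::from(as<arma::vec>(bp["gamma"]));
    arma::fvec beta = arma::conv_to<arma::fvec>::from(as<arma::vec>(bp["beta"]));
    const int K = bp["K"], ov = bp["ov"], n_in = bp["n_in"];
    const int D = bp["D"], in_ch = bp["in_ch"];
    const int pool_n_out = bp["pool_n_out"];
    const int ch = W.n_rows;
    BlockCache& bc = cache->blocks[bl];
    const std::size_t n = (std::size_t)ov * B;
    // un-pool into (ch*ov) x B, viewed as (ch) x (ov*B)
    arma::fmat dY(ch, n, arma::fill::zeros);
    {
      arma::fmat dYv(dY.memptr(), (std::size_t)ch * ov, B, false, true);
      for (int b = 0; b < B; ++b) {
        const float* dbp = dA.colptr(b);
        float* gb = dYv.colptr(b);
        const int* ab = bc.argmax.memptr() + (std::size_t)b * pool_n_out;
        for (int e = 0; e < pool_n_out; ++e) gb[ab[e]] += dbp[e];
      }
    }
    // fused dropout-scale + ReLU mask + batch-norm backward
    const bool has_scale = bc.scale.n_elem > 0;
    arma::fvec dgamma(ch, arma::fill::zeros), dbeta(ch, arma::fill::zeros);
    {
      float* dp = dY.memptr();
      const float* hp = bc.xhat.memptr();
      for (std::size_t i = 0; i < n; ++i) {
        const int b = (int)(i / ov);
        float* di = dp + i * ch;
        const float* hi = hp + i * ch;
        for (int c = 0; c < ch; ++c) {
          float g = di[c];
          if (has_scale) g *= bc.scale[c + (std::size_t)b * ch];
          const float pre = hi[c] * gamma[c] + beta[c];
          g = pre > 0 ? g : 0.0f;
          di[c] = g;
          dgamma[c] += g * hi[c];
          dbeta[c] += g;
        }
      }
      arma::fvec mean_dxhat = (gamma % dbeta) / (float)n;
      arma::fvec mean_dxhat_xhat = (gamma % dgamma) / (float)n;
      for (std::size_t i = 0; i < n; ++i) {
        float* di = dp + i * ch;
        const float* hi = hp + i * ch;
        for (int c = 0; c < ch; ++c) {
          const float dxhat = di[c] * gamma[c];
          di[c] = (dxhat - mean_dxhat[c] - hi[c] * mean_dxhat_xhat[c]) *
            bc.inv_sd[c];
        }
      }
    }
    // convolution backward
    arma::fmat dW(ch, K, arma::fill::zeros);
    arma::fvec db = arma::sum(dY, 1);
    arma::fmat dX(n_in, B);
    {
      arma::fvec pad((std::size_t)in_ch * (D + 2) * (D + 2) * (D + 2));
      arma::fmat Xcol(K, ov), dXcol(K, ov);
      for (int b = 0; b < B; ++b) {
        const arma::fmat dYb = dY.cols((std::size_t)b * ov,
                                       (std::size_t)(b + 1) * ov - 1);
        pad_sample(bc.Xin.colptr(b), in_ch, D, pad.memptr());
        im2col_padded(pad.memptr(), in_ch, D, Xcol.memptr());
        dW += dYb * Xcol.t();
        dXcol = W.t() * dYb;
        col2im_padded(dXcol.memptr(), in_ch, D, pad.memptr());
        unpad_sample(pad.memptr(), in_ch, D, dX.colptr(b));
      }
    }
    dWs[bl] = wrap(arma::conv_to<arma::mat>::from(dW));
    dbs[bl] = wrap(arma::conv_to<arma::vec>::from(db));
    dgammas[bl] = wrap(arma::conv_to<arma::vec>::from(dgamma));
    dbetas[bl] = wrap(arma::conv_to<arma::vec>::from(dbeta));
    dA = std::move(dX);
  }
  return List::create(_["dW"] = dWs, _["db"] = dbs, _["dgamma"] = dgammas,
                      _["dbeta"] = dbetas,
                      _["dX"] = wrap(arma::conv_to<arma::mat>::from(dA)));
}

// deterministically release the native activation caches; the R garbage
// collector cannot see C++-side memory, so training frees each forward
// cache as soon as its backward pass has consumed it
// [[Rcpp::export(name = ".cpp_free_cache")]]
void cpp_free_cache(SEXP cache_ptr) {
  XPtr<ExtCache> cache(cache_ptr);
  std::vector<BlockCache>().swap(cache->blocks);
}
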