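// Low-level numerical kernels: im2col/col2im for the 2-D convolution towers,
// max-pooling with argmax bookkeeping for backprop, an order-(k-1) Markov
// sequence sampler driven by a 3-mer profile, and a skip-gram
// negative-sampling trainer. All randomness goes through R's RNG so results
// are reproducible with set.seed().
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Feature maps are stored as (B*H*W) x C matrices; rows enumerate spatial
// positions of B stacked segments, h fastest, then w, then segment index.

// [[Rcpp::export]]
NumericMatrix cpp_im2col(const NumericMatrix& M, int B, int H, int W,
                         int kh, int kw) {
  const int C = M.ncol(), HW = H * W, K = kh * kw;
  const int ph = kh / 2, pw = kw / 2;  // zero padding, odd kernels
  if (M.nrow() != B * HW) stop("im2col: row count does not match B*H*W");
  NumericMatrix col(B * HW, K * C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int oc = c * K + dw * kh + dh;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw - pw;
            if (sw < 0 || sw >= W) continue;
            const int h0 = std::max(0, ph - dh);
            const int h1 = std::min(H, H + ph - dh);
            const double* src = &M(b * HW + sw * H, c);
            double* dst = &col(b * HW + w * H, oc);
            for (int h = h0; h < h1; ++h) dst[h] = src[h + dh - ph];
          }
        }
      }
    }
  }
  return col;
}

// [[Rcpp::export]]
NumericMatrix cpp_col2im(const NumericMatrix& col, int B, int H, int W,
                         int C, int kh, int kw) {
  const int HW = H * W, K = kh * kw;
  const int ph = kh / 2, pw = kw / 2;
  if (col.nrow() != B * HW || col.ncol() != K * C)
    stop("col2im: shape mismatch");
  NumericMatrix M(B * HW, C);
  for (int c = 0; c < C; ++c) {
    for (int dw = 0; dw < kw; ++dw) {
      for (int dh = 0; dh < kh; ++dh) {
        const int oc = c * K + dw * kh + dh;
        for (int b = 0; b < B; ++b) {
          for (int w = 0; w < W; ++w) {
            const int sw = w + dw - pw;
            if (sw < 0 || sw >= W) continue;
            const int h0 = std::max(0, ph - dh);
            const int h1 = std::min(H, H + ph - dh);
            const double* src = &col(b * HW + w * H, oc);
            double* dst = &M(b * HW + sw * H, c);
            for (int h = h0; h < h1; ++h) dst[h + dh - ph] += src[h];
          }
        }
      }
    }
  }
  return M;
}

// [[Rcpp::export]]
List cpp_maxpool(const NumericMatrix& M, int B, int H, int W,
                 int ph, int pw) {
  const int C = M.ncol(), H2 = H / ph, W2 = W / pw;
  const int HW = H * W, HW2 = H2 * W2;
  if (H2 < 1 || W2 < 1) stop("maxpool: window larger than input");
  if (M.nrow() != B * HW) stop("maxpool: row count does not match B*H*W");
  NumericMatrix out(B * HW2, C);
  IntegerMatrix arg(B * HW2, C);
  for (int c = 0; c < C; ++c) {
    for (int b = 0; b < B; ++b) {
      for (int w2 = 0; w2 < W2; ++w2) {
        for (int h2 = 0; h2 < H2; ++h2) {
          double best = R_NegInf;
          int bestr = -1;
          for (int dw = 0; dw < pw; ++dw) {
            for (int dh = 0; dh < ph; ++dh) {
              const int r = b * HW + (w2 * pw + dw) * H + (h2 * ph + dh);
              const double v = M(r, c);
              if (v > best) { best = v; bestr = r; }
            }
          }
          const int r2 = b * HW2 + w2 * H2 + h2;
          out(r2, c) = best;
          arg(r2, c) = bestr + 1;  // 1-based into M
        }
      }
    }
  }
  return List::create(_["out"] = out, _["argmax"] = arg,
                      _["H"] = H2, _["W"] = W2);
}

// [[Rcpp::export]]
NumericMatrix cpp_maxpool_bwd(const NumericMatrix& dout,
                              const IntegerMatrix& arg, int nrow_in) {
  NumericMatrix dM(nrow_in, dout.ncol());
  for (int c = 0; c < dout.ncol(); ++c)
    for (int r = 0; r < dout.nrow(); ++r)
      dM(arg(r, c) - 1, c) += dout(r, c);
  return dM;
}

// Sample a DNA sequence whose stationary 3-mer statistics follow `profile`
// (length 64, lexicographic AAA..TTT, A=0 C=1 G=2 T=3, index 16a+4b+c),
// via the induced order-2 Markov chain. Contexts with zero mass fall back
// to the uniform distribution.
// [[Rcpp::export]]
std::string cpp_markov_sample(const NumericVector& profile, int len) {
  if (profile.size() != 64) stop("profile must have length 64");
  if (len < 1) stop("len must be >= 1");
  static const char* bases = "ACGT";
  std::string s(len, 'A');
  double marg1[4] = {0, 0, 0, 0};
  for (int a = 0; a < 4; ++a)
    for (int b = 0; b < 4; ++b)
      for (int c = 0; c < 4; ++c) marg1[a] += profile[16 * a + 4 * b + c];
  auto draw = [](const double* p, int n) -> int {
    double tot = 0;
    for (int i = 0; i < n; ++i) tot += p[i];
    double u = unif_rand();
    if (tot <= 0) return (int)std::min((double)(n - 1), std::floor(u * n));
    u *= tot;
    double acc = 0;
    for (int i = 0; i < n; ++i) {
      acc += p[i];
      if (u <= acc) return i;
    }
    return n - 1;
  };
  int a = draw(marg1, 4);
  s[0] = bases[a];
  if (len == 1) return s;
  double p2[4];
  for (int b = 0; b < 4; ++b) {
    p2[b] = 0;
    for (int c = 0; c < 4; ++c) p2[b] += profile[16 * a + 4 * b + c];
  }
  int b = draw(p2, 4);
  s[1] = bases[b];
  int pa = a, pb = b;
  for (int i = 2; i < len; ++i) {
    double p3[4];
    for (int c = 0; c < 4; ++c) p3[c] = profile[16 * pa + 4 * pb + c];
    const int cc = draw(p3, 4);
    s[i] = bases[cc];
    pa = pb;
    pb = cc;
  }
  return s;
}

// Skip-gram with negative sampling (SGNS). `corpus` is a list of integer
// vectors of token ids in 1..vocab (UNK must already be filtered out).
// Returns the input-embedding matrix (vocab x dim). Single-threaded and
// deterministic under R's RNG. Negative sampling uses the unigram^0.75
// distribution; the learning rate decays linearly from alpha0 to alpha_min.
// [[Rcpp::export]]
NumericMatrix cpp_sgns_train(const List& corpus, int vocab, int dim,
                             int window, int negative, int epochs,
                             double alpha0, double alpha_min) {
  const int S = corpus.size();
  std::vector<double> cnt(vocab, 0.0);
  long long total = 0;
  for (int s = 0; s < S; ++s) {
    IntegerVector v = corpus[s];
    for (int i = 0; i < v.size(); ++i) {
      const int t = v[i];
      if (t < 1 || t > vocab) stop("token id out of range");
      cnt[t - 1] += 1;
      ++total;
    }
  }
  if (total == 0) stop("empty corpus");
  std::vector<double> cum(vocab);
  double z = 0;
  for (int t = 0; t < vocab; ++t) {
    z += std::pow(cnt[t], 0.75);
    cum[t] = z;
  }
  std::vector<double> Win((size_t)vocab * dim), Wout((size_t)vocab * dim, 0.0);
  for (size_t i = 0; i < Win.size(); ++i) Win[i] = (unif_rand() - 0.5) / dim;
  std::vector<double> acc(dim);
  const long long steps_total = (long long)epochs * total;
  long long step = 0;
  for (int ep = 0; ep < epochs; ++ep) {
    for (int s = 0; s < S; ++s) {
      IntegerVector sent = corpus[s];
      const int n = sent.size();
      for (int i = 0; i < n; ++i) {
        double alpha = alpha0 * (1.0 - (double)step / (double)steps_total);
        if (alpha < alpha_min) alpha = alpha_min;
        ++step;
        const int center = sent[i] - 1;
        const size_t ci = (size_t)center * dim;
        const int j0 = std::max(0, i - window);
        const int j1 = std::min(n - 1, i + window);
        for (int j = j0; j <= j1; ++j) {
          if (j == i) continue;
          const int ctx = sent[j] - 1;
          std::fill(acc.begin(), acc.end(), 0.0);
          for (int neg = 0; neg <= negative; ++neg) {
            int target;
            double label;
            if (neg == 0) {
              target = ctx;
              label = 1.0;
            } else {
              const double u = unif_rand() * z;
              target = (int)(std::lower_bound(cum.begin(), cum.end(), u) -
                             cum.begin());
              if (target >= vocab) target = vocab - 1;
              if (target == ctx) continue;
              label = 0.0;
            }
            const size_t ti = (size_t)target * dim;
            double f = 0;
            for (int d = 0; d < dim; ++d) f += Win[ci + d] * Wout[ti + d];
            const double g = (label - 1.0 / (1.0 + std::exp(-f))) * alpha;
            for (int d = 0; d < dim; ++d) {
              acc[d] += g * Wout[ti + d];
              Wout[ti + d] += g * Win[ci + d];
            }
          }
          for (int d = 0; d < dim; ++d) Win[ci + d] += acc[d];
        }
      }
    }
  }
  NumericMatrix Wmat(vocab, dim);
  for (int t = 0; t < vocab; ++t)
    for (int d = 0; d < dim; ++d) Wmat(t, d) = Win[(size_t)t * dim + d];
  return Wmat;
}

// ---- fused batch-norm (+ReLU) kernels for the CNN towers ----------------
// Column-wise over (n x C) feature matrices; biased variance.

// [[Rcpp::export]]
List cpp_bn_stats(const NumericMatrix& Z) {
  const int n = Z.nrow(), C = Z.ncol();
  NumericVector mean(C), var(C);
  for (int c = 0; c < C; ++c) {
    const double* z = &Z(0, c);
    double s = 0, s2 = 0;
    for (int i = 0; i < n; ++i) { s += z[i]; s2 += z[i] * z[i]; }
    const double mu = s / n;
    mean[c] = mu;
    double v = s2 / n - mu * mu;
    var[c] = v > 0 ? v : 0;
  }
  return List::create(_["mean"] = mean, _["var"] = var);
}

// out = relu(gamma * (Z - mean) / sqrt(var + eps) + beta). The caller keeps
// Z itself as the backward cache; only `out` is allocated here.
// with_relu=false gives the plain BN affine.
// [[Rcpp::export]]
List cpp_bn_relu_fwd(const NumericMatrix& Z, const NumericVector& gamma,
                     const NumericVector& beta, const NumericVector& mean,
                     const NumericVector& var, double eps, bool with_relu) {
  const int n = Z.nrow(), C = Z.ncol();
  NumericMatrix out(n, C);
  NumericVector invsd(C);
  const double* zp = REAL(Z);
  double* op = REAL(out);
  for (int c = 0; c < C; ++c) {
    const double isd = 1.0 / std::sqrt(var[c] + eps);
    invsd[c] = isd;
    const double a = gamma[c] * isd;
    const double b = beta[c] - gamma[c] * isd * mean[c];
    const double* z = zp + (size_t)n * c;
    double* o = op + (size_t)n * c;
    if (with_relu)
      for (int i = 0; i < n; ++i) { const double y = a * z[i] + b; o[i] = y > 0 ? y : 0.0; }
    else
      for (int i = 0; i < n; ++i) o[i] = a * z[i] + b;
  }
  return List::create(_["out"] = out, _["invsd"] = invsd);
}

// Backward through ReLU and batch norm (batch statistics are part of the
// graph). `dA` is transformed IN PLACE into dZ (the caller must own the
// only reference); the ReLU mask and xhat are recomputed from the cached
// pre-BN activations Z. Returns dgamma and dbeta.
// [[Rcpp::export]]
List cpp_bn_relu_bwd(NumericMatrix dA, const NumericMatrix& Z,
                     const NumericVector& mean, const NumericVector& invsd,
                     const NumericVector& gamma, const NumericVector& beta,
                     bool with_relu) {
  const int n = dA.nrow(), C = dA.ncol();
  NumericVector dgamma(C), dbeta(C);
  double* dap = REAL(dA);
  const double* zp = REAL(Z);
  for (int c = 0; c < C; ++c) {
    double* da = dap + (size_t)n * c;
    const double* z = zp + (size_t)n * c;
    const double isd = invsd[c], mu = mean[c], g = gamma[c], b = beta[c];
    double s1 = 0, s2 = 0;
    for (int i = 0; i < n; ++i) {
      const double xh = (z[i] - mu) * isd;
      double dy = da[i];
      if (with_relu && g * xh + b <= 0) dy = 0.0;
      da[i] = dy;          // stash masked dy
      s1 += dy;
      s2 += dy * xh;
    }
    dbeta[c] = s1;
    dgamma[c] = s2;
    const double k = g * isd;
    const double m1 = s1 / n, m2 = s2 / n;
    for (int i = 0; i < n; ++i) {
      const double xh = (z[i] - mu) * isd;
      da[i] = k * (da[i] - m1 - xh * m2);
    }
  }
  return List::create(_["dgamma"] = dgamma, _["dbeta"] = dbeta);
}
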