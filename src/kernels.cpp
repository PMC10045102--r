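// Compiled numerical kernels: centered orthonormal 2-D FFTs, the SENSE
// normal operator and its conjugate-gradient solve, and im2col convolution
// forward/backward passes. These are the inner loops of unrolled training;
// the R layer owns all orchestration and bookkeeping.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// Centered orthonormal 1-D DFT matrix with both index shifts folded in:
// A(r, c) = exp(-2*pi*i * s(r) * s(c) / n) / sqrt(n), s(r) = (r + n/2) mod n.
// A is symmetric unitary, so the centered inverse transform matrix is
// conj(A). The centered 2-D transform of an H x W image is A_H * x * A_W
// (no transpose needed by symmetry). At the image sizes used here these
// BLAS products beat generic FFTs and avoid all shift copies.
static const cx_mat& dft_matrix(int n) {
  static std::map<int, cx_mat> cache;
  auto it = cache.find(n);
  if (it != cache.end()) return it->second;
  cx_mat A(n, n);
  const double scale = 1.0 / std::sqrt(double(n));
  for (int r = 0; r < n; ++r) {
    const int sr = (r + n / 2) % n;
    for (int c = 0; c < n; ++c) {
      const int sc = (c + n / 2) % n;
      const double ang = -2.0 * M_PI * double(sr) * double(sc) / double(n);
      A(r, c) = std::complex<double>(std::cos(ang), std::sin(ang)) * scale;
    }
  }
  return cache.emplace(n, std::move(A)).first->second;
}

static cx_mat fft2c_one(const cx_mat& x, bool inverse) {
  const cx_mat& AH = dft_matrix(x.n_rows);
  const cx_mat& AW = dft_matrix(x.n_cols);
  if (inverse) return conj(AH) * x * conj(AW);
  return AH * x * AW;
}

// [[Rcpp::export]]
arma::cx_mat cpp_fft2c(const arma::cx_mat& x, bool inverse) {
  return fft2c_one(x, inverse);
}

// [[Rcpp::export]]
arma::cx_cube cpp_apply_A(const arma::cx_mat& x, const arma::cx_cube& maps,
                          const arma::uvec& drop_cols) {
  cx_cube y(maps.n_rows, maps.n_cols, maps.n_slices);
  for (uword c = 0; c < maps.n_slices; ++c) {
    cx_mat k = fft2c_one(maps.slice(c) % x, false);
    for (uword j = 0; j < drop_cols.n_elem; ++j) k.col(drop_cols[j]).zeros();
    y.slice(c) = k;
  }
  return y;
}

// [[Rcpp::export]]
arma::cx_mat cpp_apply_AH(const arma::cx_cube& y, const arma::cx_cube& maps,
                          const arma::uvec& drop_cols) {
  cx_mat x(maps.n_rows, maps.n_cols, fill::zeros);
  for (uword c = 0; c < maps.n_slices; ++c) {
    cx_mat k = y.slice(c);
    for (uword j = 0; j < drop_cols.n_elem; ++j) k.col(drop_cols[j]).zeros();
    x += conj(maps.slice(c)) % fft2c_one(k, true);
  }
  return x;
}

// Phase-encode mask kernel: because the mask zeroes whole PE columns, the
// readout-direction transform cancels in F^H P F and the normal operator
// reduces per coil to a right-multiplication by the Hermitian W x W matrix
// B = A_W D A_W^H (D = diagonal 0/1 column selector):
//   A^H A x = sum_c conj(S_c) o ((S_c o x) B).
// [[Rcpp::export]]
arma::cx_mat cpp_mask_kernel(int n, const arma::uvec& drop_cols) {
  const cx_mat& A = dft_matrix(n);
  std::vector<uword> kept;
  std::vector<bool> dropped(n, false);
  for (uword j = 0; j < drop_cols.n_elem; ++j) dropped[drop_cols[j]] = true;
  for (int j = 0; j < n; ++j) if (!dropped[j]) kept.push_back(j);
  cx_mat Ak = A.cols(uvec(kept));
  return Ak * Ak.t();  // .t() is the Hermitian transpose: B = Ak Ak^H
}

static inline cx_mat gram_apply(const cx_mat& x, const cx_cube& maps,
                                const cx_mat& B) {
  cx_mat out(x.n_rows, x.n_cols, fill::zeros);
  for (uword c = 0; c < maps.n_slices; ++c) {
    out += conj(maps.slice(c)) % ((maps.slice(c) % x) * B);
  }
  return out;
}

// [[Rcpp::export]]
arma::cx_mat cpp_apply_gram(const arma::cx_mat& x, const arma::cx_cube& maps,
                            const arma::cx_mat& kmask) {
  return gram_apply(x, maps, kmask);
}

// Fixed-iteration CG on (A^H A + lam I) z = rhs, optionally warm-started.
// [[Rcpp::export]]
arma::cx_mat cpp_cg_gram(const arma::cx_mat& rhs, const arma::cx_cube& maps,
                         const arma::cx_mat& kmask, double lam, int n_iter,
                         const arma::cx_mat& init, bool use_init) {
  cx_mat z, r;
  if (use_init) {
    z = init;
    r = rhs - (gram_apply(z, maps, kmask) + lam * z);
  } else {
    z.zeros(rhs.n_rows, rhs.n_cols);
    r = rhs;
  }
  cx_mat p = r;
  double rs = accu(square(abs(r)));
  for (int i = 0; i < n_iter; ++i) {
    if (rs < 1e-30) break;
    cx_mat Ap = gram_apply(p, maps, kmask) + lam * p;
    double pAp = std::real(accu(conj(p) % Ap));
    double alpha = rs / pAp;
    z += alpha * p;
    r -= alpha * Ap;
    double rs_new = accu(square(abs(r)));
    p = r + (rs_new / rs) * p;
    rs = rs_new;
  }
  return z;
}

// im2col: patch matrix for a k x k same-padding convolution of an
// H x W x Cin input. Row r = output pixel (column-major), column
// (ci * k * k + dj * k + di) = tap (di, dj) of input channel ci.
static mat im2col(const cube& x, int k) {
  const int H = x.n_rows, W = x.n_cols, Cin = x.n_slices;
  const int p = (k - 1) / 2;
  mat P(H * W, k * k * Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const int col = ci * k * k + dj * k + di;
        double* dst = P.colptr(col);
        const int off = di - p;                 // row shift
        const int i0 = std::max(0, -off);       // first valid output row
        const int i1 = std::min(H, H - off);    // one past last valid row
        for (int j = 0; j < W; ++j) {
          double* d = dst + j * H;
          const int sj = j + dj - p;
          if (sj < 0 || sj >= W || i1 <= i0) {
            std::memset(d, 0, sizeof(double) * H);
            continue;
          }
          const double* src = x.slice_colptr(ci, sj) + off;
          if (i0 > 0) std::memset(d, 0, sizeof(double) * i0);
          std::memcpy(d + i0, src + i0, sizeof(double) * (i1 - i0));
          if (i1 < H) std::memset(d + i1, 0, sizeof(double) * (H - i1));
        }
      }
    }
  }
  return P;
}

// [[Rcpp::export]]
arma::cube cpp_conv_forward(const arma::cube& x, const arma::mat& K,
                            const arma::vec& b, int k) {
  const int H = x.n_rows, W = x.n_cols;
  mat P = im2col(x, k);
  mat out = P * K;
  out.each_row() += b.t();
  return cube(out.memptr(), H, W, K.n_cols);
}

// Backward pass; `x` is the layer input saved by the forward pass (the patch
// matrix is recomputed here — cheaper than shipping it through R).
// [[Rcpp::export]]
Rcpp::List cpp_conv_backward(const arma::cube& g_out, const arma::cube& x,
                             const arma::mat& K, int k, int Cin) {
  const int H = g_out.n_rows, W = g_out.n_cols, Cout = g_out.n_slices;
  mat G(const_cast<double*>(g_out.memptr()), H * W, Cout, false, true);
  mat patches = im2col(x, k);
  mat dK = patches.t() * G;
  vec db = sum(G, 0).t();
  // input gradient: convolve g_out with the spatially flipped kernel,
  // input/output channel roles swapped
  mat Kb(k * k * Cout, Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int co = 0; co < Cout; ++co) {
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          Kb(co * k * k + (k - 1 - dj) * k + (k - 1 - di), ci) =
              K(ci * k * k + dj * k + di, co);
        }
      }
    }
  }
  mat Pg = im2col(g_out, k);
  mat dxm = Pg * Kb;
  cube dx(dxm.memptr(), H, W, Cin);
  return Rcpp::List::create(Rcpp::Named("dx") = dx, Rcpp::Named("dK") = dK,
                            Rcpp::Named("db") = db);
}

// ---------------------------------------------------------------------------
// Full encoder-decoder denoiser forward/backward. The layer layout matches
// the R-side plan: enc1..encS, dec(S-1)..dec1, out. A forward pass run with
// keep=TRUE stores per-layer inputs and pre-activations in an external
// cache (one slot per unroll) that the backward pass consumes, so nothing
// large crosses the R/C++ boundary during training.

static cube conv_fwd_core(const cube& x, const mat& K, const vec& b, int k) {
  mat P = im2col(x, k);
  mat out = P * K;
  out.each_row() += b.t();
  return cube(out.memptr(), x.n_rows, x.n_cols, K.n_cols);
}

static void conv_bwd_core(const cube& g_out, const cube& x, const mat& K,
                          int k, cube& dx, mat& dK, vec& db) {
  const int H = g_out.n_rows, W = g_out.n_cols;
  const int Cout = g_out.n_slices, Cin = x.n_slices;
  mat G(const_cast<double*>(g_out.memptr()), H * W, Cout, false, true);
  mat patches = im2col(x, k);
  dK = patches.t() * G;
  db = sum(G, 0).t();
  mat Kb(k * k * Cout, Cin);
  for (int ci = 0; ci < Cin; ++ci) {
    for (int co = 0; co < Cout; ++co) {
      for (int dj = 0; dj < k; ++dj) {
        for (int di = 0; di < k; ++di) {
          Kb(co * k * k + (k - 1 - dj) * k + (k - 1 - di), ci) =
              K(ci * k * k + dj * k + di, co);
        }
      }
    }
  }
  mat Pg = im2col(g_out, k);
  mat dxm = Pg * Kb;
  dx = cube(dxm.memptr(), H, W, Cin);
}

static cube avgpool2(const cube& x) {
  const int H = x.n_rows / 2, W = x.n_cols / 2, C = x.n_slices;
  cube o(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        o(i, j, c) = 0.25 * (x(2 * i, 2 * j, c) + x(2 * i + 1, 2 * j, c) +
                             x(2 * i, 2 * j + 1, c) + x(2 * i + 1, 2 * j + 1, c));
      }
    }
  }
  return o;
}

static cube avgpool2_bwd(const cube& g) {
  const int H = g.n_rows, W = g.n_cols, C = g.n_slices;
  cube o(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = 0.25 * g(i, j, c);
        o(2 * i, 2 * j, c) = v; o(2 * i + 1, 2 * j, c) = v;
        o(2 * i, 2 * j + 1, c) = v; o(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return o;
}

static cube upsample2(const cube& x) {
  const int H = x.n_rows, W = x.n_cols, C = x.n_slices;
  cube o(2 * H, 2 * W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        const double v = x(i, j, c);
        o(2 * i, 2 * j, c) = v; o(2 * i + 1, 2 * j, c) = v;
        o(2 * i, 2 * j + 1, c) = v; o(2 * i + 1, 2 * j + 1, c) = v;
      }
    }
  }
  return o;
}

static cube upsample2_bwd(const cube& g) {
  const int H = g.n_rows / 2, W = g.n_cols / 2, C = g.n_slices;
  cube o(H, W, C);
  for (int c = 0; c < C; ++c) {
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) {
        o(i, j, c) = g(2 * i, 2 * j, c) + g(2 * i + 1, 2 * j, c) +
                     g(2 * i, 2 * j + 1, c) + g(2 * i + 1, 2 * j + 1, c);
      }
    }
  }
  return o;
}

struct DenoiserCache {
  // per slot (unroll), per layer
  std::vector<std::vector<cube>> inputs;
  std::vector<std::vector<cube>> pres;
  std::vector<std::vector<int>> n_up;
};

// [[Rcpp::export]]
SEXP cpp_den_cache_new(int n_slots) {
  DenoiserCache* c = new DenoiserCache();
  c->inputs.resize(n_slots);
  c->pres.resize(n_slots);
  c->n_up.resize(n_slots);
  return Rcpp::XPtr<DenoiserCache>(c, true);
}

static std::vector<mat> unpack_mats(const Rcpp::List& Ks) {
  std::vector<mat> v;
  for (int i = 0; i < Ks.size(); ++i) v.push_back(Rcpp::as<mat>(Ks[i]));
  return v;
}

static std::vector<vec> unpack_vecs(const Rcpp::List& bs) {
  std::vector<vec> v;
  for (int i = 0; i < bs.size(); ++i) v.push_back(Rcpp::as<vec>(bs[i]));
  return v;
}

// [[Rcpp::export]]
arma::cx_mat cpp_denoise_forward(const arma::cx_mat& x, const Rcpp::List& Ks,
                                 const Rcpp::List& bs, int S, int k,
                                 SEXP cache_ptr, int slot, bool keep) {
  const int H = x.n_rows, W = x.n_cols;
  std::vector<mat> Kv = unpack_mats(Ks);
  std::vector<vec> bv = unpack_vecs(bs);
  DenoiserCache* cc = nullptr;
  if (keep) {
    cc = Rcpp::XPtr<DenoiserCache>(cache_ptr).get();
    cc->inputs[slot].clear(); cc->pres[slot].clear(); cc->n_up[slot].clear();
  }
  cube cur(H, W, 2);
  cur.slice(0) = real(x);
  cur.slice(1) = imag(x);
  std::vector<cube> enc_acts(S);
  for (int s = 0; s < S; ++s) {
    if (s > 0) cur = avgpool2(cur);
    cube pre = conv_fwd_core(cur, Kv[s], bv[s], k);
    if (keep) { cc->inputs[slot].push_back(cur); cc->pres[slot].push_back(pre);
                cc->n_up[slot].push_back(0); }
    enc_acts[s] = clamp(pre, 0.0, datum::inf);
    cur = enc_acts[s];
  }
  cube dec = cur;
  for (int li = S; li <= 2 * S - 2; ++li) {  // dec_{S-1} ... dec_1
    const int s = 2 * S - 1 - li;            // skip level (1-based)
    cube up = upsample2(dec);
    cube cat = join_slices(up, enc_acts[s - 1]);
    cube pre = conv_fwd_core(cat, Kv[li], bv[li], k);
    if (keep) { cc->inputs[slot].push_back(cat); cc->pres[slot].push_back(pre);
                cc->n_up[slot].push_back(up.n_slices); }
    dec = clamp(pre, 0.0, datum::inf);
  }
  const int li_out = (S > 1) ? (2 * S - 1) : 1;
  cube co = conv_fwd_core(dec, Kv[li_out], bv[li_out], k);
  if (keep) { cc->inputs[slot].push_back(dec);
              cc->pres[slot].push_back(cube());
              cc->n_up[slot].push_back(0); }
  cx_mat out = x + cx_mat(co.slice(0), co.slice(1));
  return out;
}

// [[Rcpp::export]]
Rcpp::List cpp_denoise_backward(const arma::cx_mat& g, const Rcpp::List& Ks,
                                int S, int k, SEXP cache_ptr, int slot) {
  std::vector<mat> Kv = unpack_mats(Ks);
  DenoiserCache* cc = Rcpp::XPtr<DenoiserCache>(cache_ptr).get();
  const std::vector<cube>& inputs = cc->inputs[slot];
  const std::vector<cube>& pres = cc->pres[slot];
  const std::vector<int>& n_up = cc->n_up[slot];
  const int n_layers = (S > 1) ? 2 * S : 2;
  std::vector<mat> dKs(n_layers);
  std::vector<vec> dbs(n_layers);
  cube g_out(g.n_rows, g.n_cols, 2);
  g_out.slice(0) = real(g);
  g_out.slice(1) = imag(g);
  // output conv
  const int li_out = n_layers - 1;
  cube g_cur;
  conv_bwd_core(g_out, inputs[li_out], Kv[li_out], k, g_cur, dKs[li_out],
                dbs[li_out]);
  std::vector<cube> g_enc(S);
  for (int li = 2 * S - 2; li >= S; --li) {   // dec_1 ... dec_{S-1}
    const int s = 2 * S - 1 - li;             // skip level (1-based)
    cube g_pre = g_cur % conv_to<cube>::from(pres[li] > 0.0);
    cube dx;
    conv_bwd_core(g_pre, inputs[li], Kv[li], k, dx, dKs[li], dbs[li]);
    const int nu = n_up[li];
    g_enc[s - 1] = dx.slices(nu, dx.n_slices - 1);
    g_cur = upsample2_bwd(dx.slices(0, nu - 1));
  }
  for (int s = S; s >= 1; --s) {              // enc_S ... enc_1
    const int li = s - 1;
    cube g_act = g_cur;
    if (s < S && g_enc[s - 1].n_elem > 0) g_act += g_enc[s - 1];
    cube g_pre = g_act % conv_to<cube>::from(pres[li] > 0.0);
    cube dx;
    conv_bwd_core(g_pre, inputs[li], Kv[li], k, dx, dKs[li], dbs[li]);
    g_cur = (s > 1) ? avgpool2_bwd(dx) : dx;
  }
  cx_mat g_in = g + cx_mat(g_cur.slice(0), g_cur.slice(1));
  Rcpp::List gK(n_layers), gb(n_layers);
  for (int i = 0; i < n_layers; ++i) { gK[i] = dKs[i]; gb[i] = dbs[i]; }
  return Rcpp::List::create(Rcpp::Named("g_in") = g_in,
                            Rcpp::Named("gK") = gK, Rcpp::Named("gb") = gb);
}

// Sliding-window sums over all w x w windows fully inside x.
// [[Rcpp::export]]
arma::mat cpp_box_sum_valid(const arma::mat& x, int w) {
  const int H = x.n_rows, W = x.n_cols;
  mat S(H + 1, W + 1, fill::zeros);
  for (int j = 0; j < W; ++j) {
    double acc = 0.0;
    for (int i = 0; i < H; ++i) {
      acc += x(i, j);
      S(i + 1, j + 1) = S(i + 1, j) + acc;
    }
  }
  mat out(H - w + 1, W - w + 1);
  for (int j = 0; j < W - w + 1; ++j) {
    for (int i = 0; i < H - w + 1; ++i) {
      out(i, j) = S(i + w, j + w) - S(i, j + w) - S(i + w, j) + S(i, j);
    }
  }
  return out;
}
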