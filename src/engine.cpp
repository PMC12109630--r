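// Compact CNN engine for the GlandNet classifier family.
//
// Activations for a mini-batch of B single-channel images at spatial H x W
// are stored zero-padded: a matrix of shape (C, B * Sp) with Sp =
// (H+2) * (W+2), column index b*Sp + (c+1)*(H+2) + (r+1) for image pixel
// (r, c); the one-pixel border columns are kept at zero. A 3x3 same-padding
// convolution is then nine shifted BLAS gemms over the whole batch: shifting
// a pixel by (dr, dc) shifts the global column index by dc*(H+2) + dr, and
// interior outputs never read across image boundaries because the border
// ring absorbs the spill.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::vec;
using arma::uword;

namespace {

struct NetSpec {
  std::vector<int> conv_widths;   // 13 output widths
  std::vector<int> pool_after;    // conv layer indices (0-based) followed by 2x2 maxpool
  int d1, d2, n_class;
  int input_size, channels;
  double noise_sigma;
  bool noise_on_input;            // alternative noise placement
};

NetSpec spec_from_list(const List& s) {
  NetSpec sp;
  sp.conv_widths = as<std::vector<int>>(s["conv_widths"]);
  sp.pool_after  = as<std::vector<int>>(s["pool_after"]);
  sp.d1 = as<int>(s["d1"]);
  sp.d2 = as<int>(s["d2"]);
  sp.n_class = as<int>(s["n_class"]);
  sp.input_size = as<int>(s["input_size"]);
  sp.channels = as<int>(s["channels"]);
  sp.noise_sigma = as<double>(s["noise_sigma"]);
  sp.noise_on_input = as<bool>(s["noise_on_input"]);
  if (sp.channels != 1)
    stop("the engine operates on single-channel patches; collapse channels upstream");
  return sp;
}

struct Weights {
  std::vector<mat> convW;  // (Cout, 9*Cin), kernel offset k = (dc+1)*3 + (dr+1)
  std::vector<vec> convB;
  mat W1, W2, W3;
  vec b1, b2, b3;
};

Weights weights_from_list(const List& w) {
  Weights ww;
  List cw = w["convW"], cb = w["convB"];
  for (int i = 0; i < cw.size(); ++i) {
    ww.convW.push_back(as<mat>(cw[i]));
    ww.convB.push_back(as<vec>(cb[i]));
  }
  ww.W1 = as<mat>(w["W1"]); ww.b1 = as<vec>(w["b1"]);
  ww.W2 = as<mat>(w["W2"]); ww.b2 = as<vec>(w["b2"]);
  ww.W3 = as<mat>(w["W3"]); ww.b3 = as<vec>(w["b3"]);
  return ww;
}

List weights_to_list(const Weights& w) {
  List cw(w.convW.size()), cb(w.convB.size());
  for (size_t i = 0; i < w.convW.size(); ++i) { cw[i] = w.convW[i]; cb[i] = w.convB[i]; }
  return List::create(_["convW"] = cw, _["convB"] = cb,
                      _["W1"] = w.W1, _["b1"] = w.b1,
                      _["W2"] = w.W2, _["b2"] = w.b2,
                      _["W3"] = w.W3, _["b3"] = w.b3);
}

inline uword padded_cols(int H, int W, int B) {
  return (uword)(H + 2) * (W + 2) * B;
}

// zero the one-pixel border ring of every image
void zero_border(mat& A, int H, int W, int B) {
  const int Hp = H + 2, Wp = W + 2;
  const uword Sp = (uword)Hp * Wp;
  for (int b = 0; b < B; ++b) {
    const uword base = (uword)b * Sp;
    A.cols(base, base + Hp - 1).zeros();                       // c = 0
    A.cols(base + (uword)(Wp - 1) * Hp, base + Sp - 1).zeros(); // c = Wp-1
    for (int c = 1; c < Wp - 1; ++c) {
      A.col(base + (uword)c * Hp).zeros();                     // r = 0
      A.col(base + (uword)c * Hp + Hp - 1).zeros();            // r = Hp-1
    }
  }
}

// 3x3 convolution on padded activations: Y(g) = sum_k W_k A(g + off_k) + b,
// then ReLU, then border re-zeroed. A: (Cin, B*Sp); Y: (Cout, B*Sp).
void conv_forward(const mat& A, const mat& W9, const vec& bias,
                  int H, int W, int B, mat& Y) {
  const int Cin = A.n_rows, Hp = H + 2;
  const uword N = A.n_cols;
  Y.zeros(W9.n_rows, N);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = (dc + 1) * 3 + (dr + 1);
      const long off = (long)dc * Hp + dr;
      const uword d0 = off < 0 ? (uword)(-off) : 0;
      const uword d1 = N - 1 - (off > 0 ? (uword)off : 0);
      Y.cols(d0, d1) += W9.cols(k * Cin, (k + 1) * Cin - 1) *
                        A.cols(d0 + off, d1 + off);
    }
  }
  Y.each_col() += bias;
  Y.transform([](double v) { return v > 0 ? v : 0.0; });
  zero_border(Y, H, W, B);
}

// Adjoint: accumulates weight/bias gradients and the input gradient.
// dY must be zero on the border ring (guaranteed by the ReLU masks).
void conv_backward(const mat& A, const mat& W9, const mat& dY,
                   int H, int W, int B, mat& gW, vec& gb, mat& dA,
                   bool want_dA) {
  const int Cin = A.n_rows, Hp = H + 2;
  const uword N = A.n_cols;
  gW.zeros(W9.n_rows, W9.n_cols);
  gb = arma::sum(dY, 1);
  if (want_dA) dA.zeros(Cin, N);
  for (int dc = -1; dc <= 1; ++dc) {
    for (int dr = -1; dr <= 1; ++dr) {
      const int k = (dc + 1) * 3 + (dr + 1);
      const long off = (long)dc * Hp + dr;
      const uword d0 = off < 0 ? (uword)(-off) : 0;
      const uword d1 = N - 1 - (off > 0 ? (uword)off : 0);
      gW.cols(k * Cin, (k + 1) * Cin - 1) =
        dY.cols(d0, d1) * A.cols(d0 + off, d1 + off).t();
      if (want_dA)
        dA.cols(d0 + off, d1 + off) +=
          W9.cols(k * Cin, (k + 1) * Cin - 1).t() * dY.cols(d0, d1);
    }
  }
}

// 2x2 max pooling (stride 2) from padded (H, W) to padded (H/2, W/2).
void maxpool2(const mat& A, int H, int W, int B, mat& out, arma::umat& argmax) {
  const int H2 = H / 2, W2 = W / 2, C = A.n_rows;
  const int Hp = H + 2, Hp2 = H2 + 2;
  const uword Sp = (uword)Hp * (W + 2), Sp2 = (uword)Hp2 * (W2 + 2);
  out.zeros(C, Sp2 * B);
  argmax.set_size(C, Sp2 * B);
  for (int b = 0; b < B; ++b) {
    const uword bi = (uword)b * Sp, bo = (uword)b * Sp2;
    for (int c2 = 0; c2 < W2; ++c2) {
      for (int r2 = 0; r2 < H2; ++r2) {
        const uword o = bo + (uword)(c2 + 1) * Hp2 + (r2 + 1);
        const uword i00 = bi + (uword)(2 * c2 + 1) * Hp + (2 * r2 + 1);
        const uword cand[4] = { i00, i00 + 1, i00 + (uword)Hp, i00 + (uword)Hp + 1 };
        for (int ch = 0; ch < C; ++ch) {
          double best = A(ch, cand[0]); uword bidx = cand[0];
          for (int q = 1; q < 4; ++q)
            if (A(ch, cand[q]) > best) { best = A(ch, cand[q]); bidx = cand[q]; }
          out(ch, o) = best; argmax(ch, o) = bidx;
        }
      }
    }
  }
}

void maxpool2_backward(const mat& dOut, const arma::umat& argmax,
                       int H, int W, int B, mat& dA) {
  const int H2 = H / 2, W2 = W / 2, C = dOut.n_rows;
  const int Hp2 = H2 + 2;
  const uword Sp2 = (uword)Hp2 * (W2 + 2);
  dA.zeros();
  for (int b = 0; b < B; ++b) {
    const uword bo = (uword)b * Sp2;
    for (int c2 = 0; c2 < W2; ++c2) {
      for (int r2 = 0; r2 < H2; ++r2) {
        const uword o = bo + (uword)(c2 + 1) * Hp2 + (r2 + 1);
        for (int ch = 0; ch < C; ++ch)
          dA(ch, argmax(ch, o)) += dOut(ch, o);
      }
    }
  }
}

struct ForwardCache {
  mat x0;                          // padded network input (cache mode)
  std::vector<mat> conv_out;       // post-ReLU conv outputs, padded
  std::vector<mat> pooled;         // maxpool outputs, padded
  std::vector<arma::umat> pool_arg;
  std::vector<int> Hs, Ws;         // spatial size at each conv layer input
  mat gap;                         // (C_last, B)
  mat h1, h1r, h2, h2r;            // dense pre/post activations
  mat probs;                       // (n_class, B)

  const mat& conv_input(int l, const std::vector<int>& pool_after) const {
    if (l == 0) return x0;
    for (size_t p = 0; p < pool_after.size(); ++p)
      if (pool_after[p] == l - 1) return pooled[p];
    return conv_out[l - 1];
  }
};

mat softmax_cols(const mat& logits) {
  mat z = logits;
  arma::rowvec mx = arma::max(z, 0);
  z.each_row() -= mx;
  z = arma::exp(z);
  arma::rowvec s = arma::sum(z, 0);
  z.each_row() /= s;
  return z;
}

// Forward pass over a padded input batch X0 (1, B*Sp). In training mode the
// Gaussian noise layers are active (or input noise when spec.noise_on_input).
// cache=true keeps the intermediate activations for the backward pass.
void forward(const Weights& w, const NetSpec& sp, mat X0, int B,
             bool training, bool cache, std::mt19937& rng, ForwardCache& fc) {
  const int nconv = (int)sp.conv_widths.size();
  int H = sp.input_size, W = sp.input_size;
  if (training && sp.noise_on_input && sp.noise_sigma > 0) {
    std::normal_distribution<double> nd(0.0, sp.noise_sigma);
    for (uword i = 0; i < X0.n_elem; ++i) X0(i) += nd(rng);
    zero_border(X0, H, W, B);
  }
  fc.conv_out.assign(nconv, mat());
  fc.pooled.clear(); fc.pooled.reserve(sp.pool_after.size());
  fc.Hs.resize(nconv); fc.Ws.resize(nconv);
  fc.pool_arg.clear();
  mat hold;
  const mat* A;
  if (cache) { fc.x0 = std::move(X0); A = &fc.x0; }
  else { hold = std::move(X0); A = &hold; }
  size_t pool_ptr = 0;
  mat Y;
  for (int l = 0; l < nconv; ++l) {
    fc.Hs[l] = H; fc.Ws[l] = W;
    conv_forward(*A, w.convW[l], w.convB[l], H, W, B, Y);
    if (pool_ptr < sp.pool_after.size() && sp.pool_after[pool_ptr] == l) {
      mat P; arma::umat am;
      maxpool2(Y, H, W, B, P, am);
      if (cache) {
        fc.conv_out[l] = std::move(Y);
        fc.pool_arg.push_back(std::move(am));
        fc.pooled.push_back(std::move(P));
        A = &fc.pooled.back();
      } else { hold = std::move(P); A = &hold; }
      H /= 2; W /= 2; ++pool_ptr;
    } else {
      if (cache) { fc.conv_out[l] = std::move(Y); A = &fc.conv_out[l]; }
      else { hold = std::move(Y); A = &hold; }
    }
    Y.reset();
  }
  // global average pooling over the interior
  const int Hp = H + 2;
  const uword Sp = (uword)Hp * (W + 2);
  const int C = A->n_rows, HW = H * W;
  fc.gap.zeros(C, B);
  for (int b = 0; b < B; ++b) {
    vec acc(C, arma::fill::zeros);
    for (int c = 1; c <= W; ++c) {
      const uword base = (uword)b * Sp + (uword)c * Hp;
      acc += arma::sum(A->cols(base + 1, base + H), 1);
    }
    fc.gap.col(b) = acc / HW;
  }
  // head: dense -> ReLU -> noise -> dense -> ReLU -> noise -> dense -> softmax
  fc.h1 = w.W1 * fc.gap; fc.h1.each_col() += w.b1;
  fc.h1r = fc.h1; fc.h1r.transform([](double v) { return v > 0 ? v : 0.0; });
  if (training && !sp.noise_on_input && sp.noise_sigma > 0) {
    std::normal_distribution<double> nd(0.0, sp.noise_sigma);
    for (uword i = 0; i < fc.h1r.n_elem; ++i) fc.h1r(i) += nd(rng);
  }
  fc.h2 = w.W2 * fc.h1r; fc.h2.each_col() += w.b2;
  fc.h2r = fc.h2; fc.h2r.transform([](double v) { return v > 0 ? v : 0.0; });
  if (training && !sp.noise_on_input && sp.noise_sigma > 0) {
    std::normal_distribution<double> nd(0.0, sp.noise_sigma);
    for (uword i = 0; i < fc.h2r.n_elem; ++i) fc.h2r(i) += nd(rng);
  }
  mat logits = w.W3 * fc.h2r; logits.each_col() += w.b3;
  fc.probs = softmax_cols(logits);
}

// Backward pass from the weighted-CE gradient at the logits.
void backward(const Weights& w, const NetSpec& sp, const ForwardCache& fc,
              const mat& dLogits, int B, Weights& g) {
  g.W3 = dLogits * fc.h2r.t(); g.b3 = arma::sum(dLogits, 1);
  mat dh2r = w.W3.t() * dLogits;
  mat dh2 = dh2r % arma::conv_to<mat>::from(fc.h2 > 0);
  g.W2 = dh2 * fc.h1r.t(); g.b2 = arma::sum(dh2, 1);
  mat dh1r = w.W2.t() * dh2;
  mat dh1 = dh1r % arma::conv_to<mat>::from(fc.h1 > 0);
  g.W1 = dh1 * fc.gap.t(); g.b1 = arma::sum(dh1, 1);
  mat dgap = w.W1.t() * dh1;                       // (C_last, B)

  const int nconv = (int)sp.conv_widths.size();
  g.convW.resize(nconv); g.convB.resize(nconv);

  // expand the GAP gradient over the interior of the last activation
  int H = fc.Hs[nconv - 1], W = fc.Ws[nconv - 1];
  bool last_pooled = !sp.pool_after.empty() && sp.pool_after.back() == nconv - 1;
  int Ho = last_pooled ? H / 2 : H, Wo = last_pooled ? W / 2 : W;
  const int Hpo = Ho + 2;
  const uword Spo = (uword)Hpo * (Wo + 2);
  const int HWo = Ho * Wo;
  mat dA(dgap.n_rows, Spo * B, arma::fill::zeros);
  for (int b = 0; b < B; ++b) {
    const vec v = dgap.col(b) / HWo;
    for (int c = 1; c <= Wo; ++c) {
      const uword base = (uword)b * Spo + (uword)c * Hpo;
      dA.cols(base + 1, base + Ho) = arma::repmat(v, 1, Ho);
    }
  }

  size_t pool_ptr = fc.pool_arg.size();
  for (int l = nconv - 1; l >= 0; --l) {
    const int Hl = fc.Hs[l], Wl = fc.Ws[l];
    bool pooled = false;
    for (int p : sp.pool_after) if (p == l) pooled = true;
    if (pooled) {
      --pool_ptr;
      mat dPre;
      dPre.set_size(fc.conv_out[l].n_rows, fc.conv_out[l].n_cols);
      maxpool2_backward(dA, fc.pool_arg[pool_ptr], Hl, Wl, B, dPre);
      dA = std::move(dPre);
    }
    dA %= arma::conv_to<mat>::from(fc.conv_out[l] > 0);   // ReLU gate
    const mat& Ain = fc.conv_input(l, sp.pool_after);
    mat dPrev;
    conv_backward(Ain, w.convW[l], dA, Hl, Wl, B,
                  g.convW[l], g.convB[l], dPrev, l > 0);
    if (l > 0) dA = std::move(dPrev);
  }
}

// copy one raw (H x W column-major) image into the padded batch layout
inline void load_padded(mat& A, int b, const double* src, int H, int W) {
  const int Hp = H + 2;
  const uword Sp = (uword)Hp * (W + 2), base = (uword)b * Sp;
  for (int c = 0; c < W; ++c)
    std::memcpy(A.colptr(base + (uword)(c + 1) * Hp) + 1,
                src + (uword)c * H, sizeof(double) * H);
}

// mirror-fold an index into [0, n) (symmetric reflection, edge included)
inline int fold_index(int i, int n) {
  if (n == 1) return 0;
  const int period = 2 * n;
  int k = i % period; if (k < 0) k += period;
  return (k < n) ? k : (period - 1 - k);
}

// Affine resample of a square patch: flip -> rotate -> zoom -> shift,
// bilinear interpolation, mirror fill. Angles in degrees; shifts in pixels.
mat warp_patch(const mat& img, bool hflip, bool vflip, double angle_deg,
               double zoom, double shift_r, double shift_c) {
  const int n = img.n_rows;
  const double cr = (n - 1) / 2.0, cc = (n - 1) / 2.0;
  const double th = angle_deg * M_PI / 180.0;
  const double ct = std::cos(th), st = std::sin(th);
  mat out(n, n);
  for (int c = 0; c < n; ++c) {
    for (int r = 0; r < n; ++r) {
      // invert the forward chain: undo shift, zoom, rotation, flips
      double yr = r - shift_r - cr, yc = c - shift_c - cc;
      yr /= zoom; yc /= zoom;
      double xr =  ct * yr + st * yc;       // R(-th)
      double xc = -st * yr + ct * yc;
      xr += cr; xc += cc;
      if (vflip) xr = (n - 1) - xr;
      if (hflip) xc = (n - 1) - xc;
      const int r0 = (int)std::floor(xr), c0 = (int)std::floor(xc);
      const double fr = xr - r0, fcq = xc - c0;
      const int rA = fold_index(r0, n), rB = fold_index(r0 + 1, n);
      const int cA = fold_index(c0, n), cB = fold_index(c0 + 1, n);
      out(r, c) = (1 - fr) * (1 - fcq) * img(rA, cA) + (1 - fr) * fcq * img(rA, cB)
                + fr * (1 - fcq) * img(rB, cA) + fr * fcq * img(rB, cB);
    }
  }
  return out;
}

struct AugPolicy {
  double hflip, vflip, rot, zoom, wshift, hshift;
};

AugPolicy policy_from_list(const List& policy) {
  AugPolicy p;
  p.hflip = as<double>(policy["hflip_prob"]);
  p.vflip = as<double>(policy["vflip_prob"]);
  p.rot = as<double>(policy["rotation_degrees"]);
  p.zoom = as<double>(policy["zoom_fraction"]);
  p.wshift = as<double>(policy["width_shift_fraction"]);
  p.hshift = as<double>(policy["height_shift_fraction"]);
  return p;
}

mat augment_with_rng(const mat& img, const AugPolicy& p, std::mt19937& rng) {
  std::uniform_real_distribution<double> U(0.0, 1.0);
  const bool hflip = U(rng) < p.hflip;
  const bool vflip = U(rng) < p.vflip;
  const double sign = (U(rng) < 0.5) ? -1.0 : 1.0;
  const double angle = sign * p.rot * U(rng);
  const double zoom = 1.0 + p.zoom * (2.0 * U(rng) - 1.0);
  const int n = img.n_rows;
  const double sr = p.hshift * n * (2.0 * U(rng) - 1.0);
  const double sc = p.wshift * n * (2.0 * U(rng) - 1.0);
  if (!hflip && !vflip && angle == 0 && zoom == 1 && sr == 0 && sc == 0)
    return img;
  if (!hflip && !vflip && p.rot == 0 && p.zoom == 0 && p.wshift == 0 &&
      p.hshift == 0)
    return img;
  if (vflip && !hflip && p.rot == 0 && p.zoom == 0 && p.wshift == 0 &&
      p.hshift == 0)
    return arma::flipud(img);
  if (hflip && !vflip && p.rot == 0 && p.zoom == 0 && p.wshift == 0 &&
      p.hshift == 0)
    return arma::fliplr(img);
  if (hflip && vflip && p.rot == 0 && p.zoom == 0 && p.wshift == 0 &&
      p.hshift == 0)
    return arma::flipud(arma::fliplr(img));
  return warp_patch(img, hflip, vflip, angle, zoom, sr, sc);
}

} // namespace

// [[Rcpp::export(name = ".gn_init_weights")]]
List gn_init_weights(List spec, int seed) {
  NetSpec sp = spec_from_list(spec);
  std::mt19937 rng((unsigned)seed);
  std::normal_distribution<double> nd(0.0, 1.0);
  auto he = [&](int rows, int cols, int fan_in) {
    mat W(rows, cols);
    const double s = std::sqrt(2.0 / fan_in);
    for (uword i = 0; i < W.n_elem; ++i) W(i) = s * nd(rng);
    return W;
  };
  Weights w;
  int cin = sp.channels;
  for (size_t l = 0; l < sp.conv_widths.size(); ++l) {
    const int cout = sp.conv_widths[l];
    w.convW.push_back(he(cout, 9 * cin, 9 * cin));
    w.convB.push_back(vec(cout, arma::fill::zeros));
    cin = cout;
  }
  // hidden dense biases start slightly positive so ReLU units cannot all be
  // dead at initialization (the narrow desk-scale heads are vulnerable)
  w.W1 = he(sp.d1, cin, cin);        w.b1 = vec(sp.d1); w.b1.fill(0.05);
  w.W2 = he(sp.d2, sp.d1, sp.d1);    w.b2 = vec(sp.d2); w.b2.fill(0.05);
  w.W3 = he(sp.n_class, sp.d2, sp.d2); w.b3 = vec(sp.n_class, arma::fill::zeros);
  return weights_to_list(w);
}

// [[Rcpp::export(name = ".gn_predict")]]
NumericMatrix gn_predict(List weights, NumericVector X, List spec, int batch_size) {
  NetSpec sp = spec_from_list(spec);
  Weights w = weights_from_list(weights);
  IntegerVector dims = X.attr("dim");
  const int H = dims[0], W = dims[1];
  const int n = (dims.size() == 3) ? dims[2] : 1;
  if (H != sp.input_size || W != sp.input_size)
    stop("patch size %d does not match model input size %d", H, sp.input_size);
  const uword HW = (uword)H * W;
  NumericMatrix out(n, sp.n_class);
  std::mt19937 rng(0);
  ForwardCache fc;
  for (int start = 0; start < n; start += batch_size) {
    const int B = std::min(batch_size, n - start);
    mat A(1, padded_cols(H, W, B), arma::fill::zeros);
    for (int b = 0; b < B; ++b)
      load_padded(A, b, &X[(uword)(start + b) * HW], H, W);
    forward(w, sp, std::move(A), B, false, false, rng, fc);
    for (int b = 0; b < B; ++b)
      for (int k = 0; k < sp.n_class; ++k)
        out(start + b, k) = fc.probs(k, b);
  }
  return out;
}

// [[Rcpp::export(name = ".gn_train")]]
List gn_train(List weights, NumericVector X, IntegerVector y, List spec, List config,
              Nullable<NumericVector> Xval, Nullable<IntegerVector> yval,
              Nullable<NumericVector> sample_weights) {
  NetSpec sp = spec_from_list(spec);
  Weights w = weights_from_list(weights);
  IntegerVector dims = X.attr("dim");
  const int H = dims[0], Wd = dims[1], n = (dims.size() == 3) ? dims[2] : 1;
  if (H != sp.input_size || Wd != sp.input_size)
    stop("patch size %d does not match model input size %d", H, sp.input_size);
  const uword HW = (uword)H * Wd;

  vec lr_epochs = as<vec>(config["learning_rate"]);   // scalar or per-epoch
  const double beta1 = as<double>(config["beta1"]);
  const double beta2 = as<double>(config["beta2"]);
  const int epochs = as<int>(config["epochs"]);
  const int batch_size = std::min<int>(as<int>(config["batch_size"]), n);
  const vec cls_w = as<vec>(config["class_weights"]);
  const int seed = as<int>(config["seed"]);
  const bool do_aug = as<bool>(config["augment"]);
  AugPolicy policy = policy_from_list(config["augment_policy"]);

  std::mt19937 rng((unsigned)seed);

  // Adam state over all weight tensors (biases handled as 1-col mats)
  std::vector<mat> params;   // convW..., W1, W2, W3, convB..., b1, b2, b3
  const int nconv = (int)w.convW.size();
  for (auto& m_ : w.convW) params.push_back(m_);
  params.push_back(w.W1); params.push_back(w.W2); params.push_back(w.W3);
  for (auto& b_ : w.convB) params.push_back(mat(b_));
  params.push_back(mat(w.b1)); params.push_back(mat(w.b2)); params.push_back(mat(w.b3));
  std::vector<mat> mA, vA;
  for (auto& p : params) { mA.emplace_back(arma::size(p), arma::fill::zeros);
                           vA.emplace_back(arma::size(p), arma::fill::zeros); }
  long tstep = 0;

  auto sync_from_params = [&]() {
    for (int l = 0; l < nconv; ++l) w.convW[l] = params[l];
    w.W1 = params[nconv]; w.W2 = params[nconv + 1]; w.W3 = params[nconv + 2];
    for (int l = 0; l < nconv; ++l) w.convB[l] = params[nconv + 3 + l].col(0);
    w.b1 = params[2 * nconv + 3].col(0);
    w.b2 = params[2 * nconv + 4].col(0);
    w.b3 = params[2 * nconv + 5].col(0);
  };

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;
  std::vector<double> sw(n, 1.0);
  if (sample_weights.isNotNull()) {
    NumericVector s_(sample_weights);
    if ((int)s_.size() != n) stop("sample_weights length must match n");
    for (int i = 0; i < n; ++i) sw[i] = s_[i];
  }

  const int nep = epochs;
  NumericVector ep_loss(nep), ep_acc(nep), ep_vloss(nep, NA_REAL), ep_vacc(nep, NA_REAL);

  NumericVector XV;
  std::vector<int> yv;
  int nval = 0;
  if (Xval.isNotNull() && yval.isNotNull()) {
    XV = NumericVector(Xval);
    IntegerVector YV(yval);
    IntegerVector dv = XV.attr("dim");
    nval = (dv.size() == 3) ? dv[2] : 1;
    yv = as<std::vector<int>>(YV);
  }

  ForwardCache fc;
  Weights g;
  for (int ep = 0; ep < nep; ++ep) {
    const double lr = lr_epochs((uword)std::min<int>(ep, (int)lr_epochs.n_elem - 1));
    std::shuffle(idx.begin(), idx.end(), rng);
    double run_loss = 0; long run_correct = 0; long run_n = 0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      mat A(1, padded_cols(H, Wd, B), arma::fill::zeros);
      arma::Col<int> yb(B);
      std::vector<double> swb(B);
      for (int b = 0; b < B; ++b) {
        const int i = idx[start + b];
        swb[b] = sw[i];
        if (do_aug) {
          mat img(const_cast<double*>(&X[(uword)i * HW]), H, Wd, false, true);
          mat pimg = augment_with_rng(img, policy, rng);
          load_padded(A, b, pimg.memptr(), H, Wd);
        } else {
          load_padded(A, b, &X[(uword)i * HW], H, Wd);
        }
        yb(b) = y[i];
      }
      forward(w, sp, std::move(A), B, true, true, rng, fc);
      // weighted CE loss and gradient at the logits
      mat dLogits = fc.probs;
      double loss = 0;
      for (int b = 0; b < B; ++b) {
        const int c = yb(b);
        const double wc = cls_w(c) * swb[b];
        const double p = std::max(fc.probs(c, b), 1e-12);
        loss += -wc * std::log(p);
        for (uword k = 0; k < dLogits.n_rows; ++k)
          dLogits(k, b) = wc * (fc.probs(k, b) - (k == (uword)c ? 1.0 : 0.0));
        if ((int)fc.probs.col(b).index_max() == c) ++run_correct;
      }
      dLogits /= B;
      run_loss += loss; run_n += B;
      backward(w, sp, fc, dLogits, B, g);
      std::vector<mat> grads;
      for (auto& m_ : g.convW) grads.push_back(std::move(m_));
      grads.push_back(std::move(g.W1)); grads.push_back(std::move(g.W2));
      grads.push_back(std::move(g.W3));
      for (auto& b_ : g.convB) grads.push_back(mat(b_));
      grads.push_back(mat(g.b1)); grads.push_back(mat(g.b2)); grads.push_back(mat(g.b3));
      ++tstep;
      const double c1 = 1.0 - std::pow(beta1, (double)tstep);
      const double c2 = 1.0 - std::pow(beta2, (double)tstep);
      for (size_t i = 0; i < params.size(); ++i) {
        mA[i] = beta1 * mA[i] + (1 - beta1) * grads[i];
        vA[i] = beta2 * vA[i] + (1 - beta2) * arma::square(grads[i]);
        params[i] -= lr * (mA[i] / c1) / (arma::sqrt(vA[i] / c2) + 1e-8);
      }
      sync_from_params();
      if (!std::isfinite(run_loss))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
    }
    ep_loss[ep] = run_loss / run_n;
    ep_acc[ep] = (double)run_correct / run_n;
    if (nval > 0) {
      double vloss = 0; long vcorrect = 0;
      const int vb = 64;
      for (int start = 0; start < nval; start += vb) {
        const int B = std::min(vb, nval - start);
        mat A(1, padded_cols(H, Wd, B), arma::fill::zeros);
        for (int b = 0; b < B; ++b)
          load_padded(A, b, &XV[(uword)(start + b) * HW], H, Wd);
        forward(w, sp, std::move(A), B, false, false, rng, fc);
        for (int b = 0; b < B; ++b) {
          const int c = yv[start + b];
          vloss += -cls_w(c) * std::log(std::max(fc.probs(c, b), 1e-12));
          if ((int)fc.probs.col(b).index_max() == c) ++vcorrect;
        }
      }
      ep_vloss[ep] = vloss / nval;
      ep_vacc[ep] = (double)vcorrect / nval;
    }
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["weights"] = weights_to_list(w),
                      _["loss"] = ep_loss, _["accuracy"] = ep_acc,
                      _["val_loss"] = ep_vloss, _["val_accuracy"] = ep_vacc);
}

// [[Rcpp::export(name = ".gn_augment")]]
NumericMatrix gn_augment(NumericMatrix img, List policy, int seed) {
  std::mt19937 rng((unsigned)seed);
  mat m(img.begin(), img.nrow(), img.ncol(), false);
  mat out = augment_with_rng(m, policy_from_list(policy), rng);
  return wrap(out);
}

// Point-in-polygon, even-odd rule, boundary-inclusive.
// points: (n,2) as (row,col); poly: (m,2) closed implicitly.
// [[Rcpp::export(name = ".pip_test")]]
IntegerVector pip_test(NumericMatrix points, NumericMatrix poly) {
  const int n = points.nrow(), m = poly.nrow();
  if (m < 3) stop("polygon must have at least 3 vertices");
  IntegerVector res(n);
  const double eps = 1e-9;
  for (int i = 0; i < n; ++i) {
    const double px = points(i, 0), py = points(i, 1);
    bool inside = false, on_edge = false;
    for (int j = 0; j < m; ++j) {
      const int k = (j + 1) % m;
      const double x1 = poly(j, 0), y1 = poly(j, 1);
      const double x2 = poly(k, 0), y2 = poly(k, 1);
      // on-segment check
      const double cross = (x2 - x1) * (py - y1) - (y2 - y1) * (px - x1);
      if (std::abs(cross) < eps &&
          px >= std::min(x1, x2) - eps && px <= std::max(x1, x2) + eps &&
          py >= std::min(y1, y2) - eps && py <= std::max(y1, y2) + eps) {
        on_edge = true; break;
      }
      // even-odd ray cast along +y (col axis)
      if ((x1 > px) != (x2 > px)) {
        const double yint = y1 + (px - x1) / (x2 - x1) * (y2 - y1);
        if (yint > py) inside = !inside;
      }
    }
    res[i] = (on_edge || inside) ? 1 : 0;
  }
  return res;
}

// Separable Gaussian blur with symmetric (edge-included) reflection.
// [[Rcpp::export(name = ".gaussian_blur")]]
NumericMatrix gaussian_blur(NumericMatrix img, double sigma) {
  if (sigma <= 0) return img;
  const int H = img.nrow(), W = img.ncol();
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  vec k(2 * rad + 1);
  for (int i = -rad; i <= rad; ++i) k(i + rad) = std::exp(-0.5 * i * i / (sigma * sigma));
  k /= arma::accu(k);
  mat A(img.begin(), H, W, false);
  mat tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) s += k(i + rad) * A(fold_index(r + i, H), c);
      tmp(r, c) = s;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0;
      for (int i = -rad; i <= rad; ++i) s += k(i + rad) * tmp(r, fold_index(c + i, W));
      out(r, c) = s;
    }
  return wrap(out);
}
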