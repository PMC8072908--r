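#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Sliding min/max filter over an arbitrary boolean structuring element.
// Border policy: edge replication (out-of-bounds samples clamp to the
// nearest image pixel), so constant images are fixed points.
// [[Rcpp::export]]
NumericMatrix cpp_minmax_filter(const NumericMatrix& img, const LogicalMatrix& mask,
                                int anchor_r, int anchor_c, bool take_max) {
  const int H = img.nrow(), W = img.ncol();
  const int mh = mask.nrow(), mw = mask.ncol();
  std::vector<int> dr, dc;
  dr.reserve((size_t)mh * mw);
  dc.reserve((size_t)mh * mw);
  for (int c = 0; c < mw; ++c)
    for (int r = 0; r < mh; ++r)
      if (mask(r, c)) { dr.push_back(r - anchor_r); dc.push_back(c - anchor_c); }
  const int K = (int)dr.size();
  NumericMatrix out(H, W);
  // interior fast path: constant linear offsets into the column-major data
  int rlo = 0, rhi = 0, clo = 0, chi = 0;
  std::vector<ptrdiff_t> off(K);
  for (int k = 0; k < K; ++k) {
    off[k] = (ptrdiff_t)dc[k] * H + dr[k];
    rlo = std::max(rlo, -dr[k]);
    rhi = std::max(rhi, dr[k]);
    clo = std::max(clo, -dc[k]);
    chi = std::max(chi, dc[k]);
  }
  const double* src = img.begin();
  double* dst = out.begin();
  for (int c = 0; c < W; ++c) {
    const bool c_in = (c >= clo) && (c < W - chi);
    for (int r = 0; r < H; ++r) {
      double best = take_max ? R_NegInf : R_PosInf;
      if (c_in && r >= rlo && r < H - rhi) {
        const double* p = src + (ptrdiff_t)c * H + r;
        if (take_max) {
          for (int k = 0; k < K; ++k) {
            const double v = p[off[k]];
            if (v > best) best = v;
          }
        } else {
          for (int k = 0; k < K; ++k) {
            const double v = p[off[k]];
            if (v < best) best = v;
          }
        }
      } else {
        for (int k = 0; k < K; ++k) {
          int rr = r + dr[k];
          if (rr < 0) rr = 0; else if (rr >= H) rr = H - 1;
          int cc = c + dc[k];
          if (cc < 0) cc = 0; else if (cc >= W) cc = W - 1;
          const double v = src[(ptrdiff_t)cc * H + rr];
          if (take_max ? (v > best) : (v < best)) best = v;
        }
      }
      dst[(ptrdiff_t)c * H + r] = best;
    }
  }
  return out;
}

// Sum of squared differences between the template and every fully
// contained image patch; out(i,j) scores the patch with top-left (i,j)
// (0-based in the returned matrix's own indexing).
// [[Rcpp::export]]
NumericMatrix cpp_ssd_map(const NumericMatrix& img, const NumericMatrix& tmpl) {
  const int H = img.nrow(), W = img.ncol();
  const int th = tmpl.nrow(), tw = tmpl.ncol();
  const int oh = H - th + 1, ow = W - tw + 1;
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j) {
    for (int i = 0; i < oh; ++i) {
      double s = 0.0;
      for (int n = 0; n < tw; ++n) {
        const double* ic = &img(i, j + n);
        const double* tc = &tmpl(0, n);
        for (int m = 0; m < th; ++m) {
          const double d = ic[m] - tc[m];
          s += d * d;
        }
      }
      out(i, j) = s;
    }
  }
  return out;
}

// Per-patch sum of squared intensities via a summed-area table of img^2.
// Exact for integer-valued images (sums stay far below 2^53).
// [[Rcpp::export]]
NumericMatrix cpp_patch_sumsq_map(const NumericMatrix& img, int th, int tw) {
  const int H = img.nrow(), W = img.ncol();
  std::vector<double> sat((size_t)(H + 1) * (W + 1), 0.0);
  const size_t S = (size_t)H + 1;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const double v = img(r, c);
      sat[(size_t)(c + 1) * S + (r + 1)] =
        v * v + sat[(size_t)c * S + (r + 1)] + sat[(size_t)(c + 1) * S + r] -
        sat[(size_t)c * S + r];
    }
  const int oh = H - th + 1, ow = W - tw + 1;
  NumericMatrix out(oh, ow);
  for (int j = 0; j < ow; ++j)
    for (int i = 0; i < oh; ++i)
      out(i, j) = sat[(size_t)(j + tw) * S + (i + th)] - sat[(size_t)j * S + (i + th)] -
                  sat[(size_t)(j + tw) * S + i] + sat[(size_t)j * S + i];
  return out;
}

// Bilinear resize with centre-aligned sampling: output pixel centres map to
// src = (i + 0.5) * scale - 0.5, clamped.  Identity sizes copy exactly.
// [[Rcpp::export]]
NumericMatrix cpp_bilinear_resize(const NumericMatrix& img, int out_h, int out_w) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(out_h, out_w);
  const double sr = (double)H / out_h, sc = (double)W / out_w;
  std::vector<int> c0v(out_w), c1v(out_w);
  std::vector<double> fcv(out_w);
  for (int j = 0; j < out_w; ++j) {
    double src = (j + 0.5) * sc - 0.5;
    if (src < 0) src = 0;
    if (src > W - 1) src = W - 1;
    const int c0 = (int)std::floor(src);
    c0v[j] = c0;
    c1v[j] = std::min(c0 + 1, W - 1);
    fcv[j] = src - c0;
  }
  for (int i = 0; i < out_h; ++i) {
    double srr = (i + 0.5) * sr - 0.5;
    if (srr < 0) srr = 0;
    if (srr > H - 1) srr = H - 1;
    const int r0 = (int)std::floor(srr);
    const int r1 = std::min(r0 + 1, H - 1);
    const double fr = srr - r0;
    for (int j = 0; j < out_w; ++j) {
      const double fc = fcv[j];
      const double v00 = img(r0, c0v[j]), v01 = img(r0, c1v[j]);
      const double v10 = img(r1, c0v[j]), v11 = img(r1, c1v[j]);
      out(i, j) = (1 - fr) * ((1 - fc) * v00 + fc * v01) +
                  fr * ((1 - fc) * v10 + fc * v11);
    }
  }
  return out;
}

// Separable Gaussian blur, edge-replicated borders, kernel radius 3*sigma.
// [[Rcpp::export]]
NumericMatrix cpp_gaussian_blur(const NumericMatrix& img, double sigma) {
  const int H = img.nrow(), W = img.ncol();
  if (sigma <= 0) return clone(img);
  const int rad = std::max(1, (int)std::ceil(3.0 * sigma));
  std::vector<double> k(2 * rad + 1);
  double ksum = 0.0;
  for (int i = -rad; i <= rad; ++i) {
    k[i + rad] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    ksum += k[i + rad];
  }
  for (double& v : k) v /= ksum;
  NumericMatrix tmp(H, W), out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int rr = r + i;
        if (rr < 0) rr = 0; else if (rr >= H) rr = H - 1;
        s += k[i + rad] * img(rr, c);
      }
      tmp(r, c) = s;
    }
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      double s = 0.0;
      for (int i = -rad; i <= rad; ++i) {
        int cc = c + i;
        if (cc < 0) cc = 0; else if (cc >= W) cc = W - 1;
        s += k[i + rad] * tmp(r, cc);
      }
      out(r, c) = s;
    }
  return out;
}
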