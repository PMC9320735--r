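// Low-level kernels for the segmentation network and utilities.
//
// Feature maps are (H*W) x C matrices, pixels column-major within the
// spatial grid: row p = h + H*w (0-based).  Convolution weights are
// (k*k*cin_per_group) x cout matrices; weight row r = kh + k*kw + k*k*c
// with c the channel index inside the group, and weight columns are
// grouped consecutively by output group.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <functional>
using namespace Rcpp;

static inline int out_dim(int n, int stride) { return (n + stride - 1) / stride; }

// Gather the k x k x C neighbourhood of every output pixel ("same" padding,
// zeros outside) into a (oH*oW) x (k*k*C) matrix.
static arma::mat im2col(const arma::mat& X, int H, int W, int c0, int nc,
                        int k, int stride, int dil) {
  const int pad = dil * (k - 1) / 2;
  const int oH = out_dim(H, stride), oW = out_dim(W, stride);
  arma::mat cols(static_cast<size_t>(oH) * oW, static_cast<size_t>(k) * k * nc,
                 arma::fill::zeros);
  for (int c = 0; c < nc; ++c) {
    const double* xc = X.colptr(c0 + c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * kw + k * k * c;
        double* cj = cols.colptr(j);
        for (int ow = 0; ow < oW; ++ow) {
          const int w = ow * stride + kw * dil - pad;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            const int h = oh * stride + kh * dil - pad;
            if (h < 0 || h >= H) continue;
            cj[oh + oH * ow] = xc[h + H * w];
          }
        }
      }
    }
  }
  return cols;
}

// Scatter-add transpose of im2col.
static void col2im_acc(const arma::mat& cols, arma::mat& GX, int H, int W,
                       int c0, int nc, int k, int stride, int dil) {
  const int pad = dil * (k - 1) / 2;
  const int oH = out_dim(H, stride), oW = out_dim(W, stride);
  for (int c = 0; c < nc; ++c) {
    double* gc = GX.colptr(c0 + c);
    for (int kw = 0; kw < k; ++kw) {
      for (int kh = 0; kh < k; ++kh) {
        const int j = kh + k * kw + k * k * c;
        const double* cj = cols.colptr(j);
        for (int ow = 0; ow < oW; ++ow) {
          const int w = ow * stride + kw * dil - pad;
          if (w < 0 || w >= W) continue;
          for (int oh = 0; oh < oH; ++oh) {
            const int h = oh * stride + kh * dil - pad;
            if (h < 0 || h >= H) continue;
            gc[h + H * w] += cj[oh + oH * ow];
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_conv2d_fwd(const arma::mat& X, int H, int W, const arma::mat& Wt,
                    int k, int stride, int dil, int groups) {
  const int cin = X.n_cols, cout = Wt.n_cols;
  const int cing = cin / groups, coutg = cout / groups;
  const int oH = out_dim(H, stride), oW = out_dim(W, stride);
  arma::mat Y(static_cast<size_t>(oH) * oW, cout);
  for (int g = 0; g < groups; ++g) {
    arma::mat cols = im2col(X, H, W, g * cing, cing, k, stride, dil);
    Y.cols(g * coutg, (g + 1) * coutg - 1) =
        cols * Wt.cols(g * coutg, (g + 1) * coutg - 1);
  }
  return List::create(_["y"] = Y, _["oh"] = oH, _["ow"] = oW);
}

// [[Rcpp::export]]
List cpp_conv2d_bwd(const arma::mat& X, int H, int W, const arma::mat& Wt,
                    int k, int stride, int dil, int groups, const arma::mat& GY,
                    bool want_gx) {
  const int cin = X.n_cols, cout = Wt.n_cols;
  const int cing = cin / groups, coutg = cout / groups;
  arma::mat GX(want_gx ? X.n_rows : 0, want_gx ? cin : 0, arma::fill::zeros);
  arma::mat GW(Wt.n_rows, cout);
  for (int g = 0; g < groups; ++g) {
    arma::mat cols = im2col(X, H, W, g * cing, cing, k, stride, dil);
    const arma::mat GYg = GY.cols(g * coutg, (g + 1) * coutg - 1);
    GW.cols(g * coutg, (g + 1) * coutg - 1) = cols.t() * GYg;
    if (want_gx) {
      arma::mat gcols = GYg * Wt.cols(g * coutg, (g + 1) * coutg - 1).t();
      col2im_acc(gcols, GX, H, W, g * cing, cing, k, stride, dil);
    }
  }
  return List::create(_["gx"] = GX, _["gw"] = GW);
}

// Connected components of a binary mask, two-pass union-find.
// mask: H x W integer matrix (0 background); connectivity 4 or 8.
// Returns H x W label matrix with labels 1..n in first-encounter order.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const IntegerMatrix& mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  std::vector<int> parent(1, 0);  // parent[0] unused
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  IntegerMatrix lab(H, W);
  int next = 0;
  const bool diag = (connectivity == 8);
  for (int w = 0; w < W; ++w) {
    for (int h = 0; h < H; ++h) {
      if (mask(h, w) == 0) continue;
      int neigh[4], nn = 0;
      if (h > 0 && lab(h - 1, w)) neigh[nn++] = lab(h - 1, w);
      if (w > 0 && lab(h, w - 1)) neigh[nn++] = lab(h, w - 1);
      if (diag && w > 0 && h > 0 && lab(h - 1, w - 1)) neigh[nn++] = lab(h - 1, w - 1);
      if (diag && w > 0 && h < H - 1 && lab(h + 1, w - 1)) neigh[nn++] = lab(h + 1, w - 1);
      if (nn == 0) {
        parent.push_back(++next);
        lab(h, w) = next;
      } else {
        int m = find(neigh[0]);
        for (int i = 1; i < nn; ++i) {
          int r = find(neigh[i]);
          if (r < m) { parent[m] = r; m = r; } else parent[r] = m;
        }
        lab(h, w) = m;
      }
    }
  }
  // relabel roots consecutively in first-encounter order
  std::vector<int> remap(parent.size(), 0);
  int nlab = 0;
  for (int w = 0; w < W; ++w)
    for (int h = 0; h < H; ++h)
      if (lab(h, w)) {
        int r = find(lab(h, w));
        if (!remap[r]) remap[r] = ++nlab;
        lab(h, w) = remap[r];
      }
  return lab;
}

// CRC-32 (PNG chunk checksum) and Adler-32 (zlib checksum) over raw bytes.
// [[Rcpp::export]]
double cpp_crc32(const RawVector& data, double init) {
  static uint32_t table[256];
  static bool have = false;
  if (!have) {
    for (uint32_t n = 0; n < 256; ++n) {
      uint32_t c = n;
      for (int j = 0; j < 8; ++j) c = (c & 1) ? 0xEDB88320u ^ (c >> 1) : c >> 1;
      table[n] = c;
    }
    have = true;
  }
  uint32_t crc = static_cast<uint32_t>(init) ^ 0xFFFFFFFFu;
  for (R_xlen_t i = 0; i < data.size(); ++i)
    crc = table[(crc ^ data[i]) & 0xFFu] ^ (crc >> 8);
  return static_cast<double>(crc ^ 0xFFFFFFFFu);
}

// [[Rcpp::export]]
double cpp_adler32(const RawVector& data) {
  uint32_t a = 1, b = 0;
  for (R_xlen_t i = 0; i < data.size(); ++i) {
    a = (a + data[i]) % 65521u;
    b = (b + a) % 65521u;
  }
  return static_cast<double>((b << 16) | a);
}
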