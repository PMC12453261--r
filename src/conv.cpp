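// Hot loops of the convolutional front-end. Valid (no-padding) stride-1
// convolution and 2x2/stride-2 max pooling, forward and backward. Arrays
// are column-major R arrays: feature maps H x W x C, kernels
// KH x KW x CIN x COUT. Loops stream over whole output columns per kernel
// offset so the inner loop is a contiguous fused multiply-add.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_conv_forward")]]
NumericVector cpp_conv_forward(NumericVector x, NumericVector w,
                               NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int H = xd[0], W = xd[1], CIN = xd[2];
  const int KH = wd[0], KW = wd[1], COUT = wd[3];
  const int OH = H - KH + 1, OW = W - KW + 1;
  NumericVector out((size_t)OH * OW * COUT);
  out.attr("dim") = IntegerVector::create(OH, OW, COUT);
  const double* xp = x.begin();
  const double* wp = w.begin();
  double* op = out.begin();
  for (int co = 0; co < COUT; ++co) {
    double* oc = op + (size_t)OH * OW * co;
    std::fill(oc, oc + (size_t)OH * OW, b[co]);
    for (int ci = 0; ci < CIN; ++ci) {
      const double* xc = xp + (size_t)H * W * ci;
      const double* wc = wp + (size_t)KH * KW * (ci + (size_t)CIN * co);
      for (int dj = 0; dj < KW; ++dj) {
        for (int di = 0; di < KH; ++di) {
          const double wv = wc[di + KH * dj];
          for (int j = 0; j < OW; ++j) {
            const double* src = xc + (size_t)(j + dj) * H + di;
            double* dst = oc + (size_t)j * OH;
            for (int i = 0; i < OH; ++i) dst[i] += wv * src[i];
          }
        }
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".cpp_conv_backward")]]
List cpp_conv_backward(NumericVector x, NumericVector w, NumericVector dout,
                       bool need_dx) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim"),
                od = dout.attr("dim");
  const int H = xd[0], W = xd[1], CIN = xd[2];
  const int KH = wd[0], KW = wd[1], COUT = wd[3];
  const int OH = od[0], OW = od[1];
  NumericVector dw(w.size()), db(COUT);
  dw.attr("dim") = wd;
  NumericVector dx(need_dx ? x.size() : 0);
  if (need_dx) dx.attr("dim") = xd;
  const double* xp = x.begin();
  const double* wp = w.begin();
  const double* gp = dout.begin();
  double* dwp = dw.begin();
  double* dxp = need_dx ? dx.begin() : nullptr;
  for (int co = 0; co < COUT; ++co) {
    const double* gc = gp + (size_t)OH * OW * co;
    double bsum = 0.0;
    for (size_t k = 0; k < (size_t)OH * OW; ++k) bsum += gc[k];
    db[co] = bsum;
    for (int ci = 0; ci < CIN; ++ci) {
      const double* xc = xp + (size_t)H * W * ci;
      const double* wc = wp + (size_t)KH * KW * (ci + (size_t)CIN * co);
      double* dwc = dwp + (size_t)KH * KW * (ci + (size_t)CIN * co);
      double* dxc = need_dx ? dxp + (size_t)H * W * ci : nullptr;
      for (int dj = 0; dj < KW; ++dj) {
        for (int di = 0; di < KH; ++di) {
          double acc = 0.0;
          const double wv = wc[di + KH * dj];
          for (int j = 0; j < OW; ++j) {
            const double* xcol = xc + (size_t)(j + dj) * H + di;
            const double* gcol = gc + (size_t)j * OH;
            if (need_dx) {
              double* dxcol = dxc + (size_t)(j + dj) * H + di;
              for (int i = 0; i < OH; ++i) {
                acc += gcol[i] * xcol[i];
                dxcol[i] += wv * gcol[i];
              }
            } else {
              for (int i = 0; i < OH; ++i) acc += gcol[i] * xcol[i];
            }
          }
          dwc[di + KH * dj] = acc;
        }
      }
    }
  }
  return List::create(_["dw"] = dw, _["db"] = db,
                      _["dx"] = need_dx ? (SEXP)dx : R_NilValue);
}

// 2x2 max pooling, stride 2. amax records the winning quadrant 1..4 in
// fixed (top-left, bottom-left, top-right, bottom-right) priority order.
// [[Rcpp::export(name = ".cpp_pool_forward")]]
List cpp_pool_forward(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int H = xd[0], W = xd[1], C = xd[2];
  const int OH = H / 2, OW = W / 2;
  NumericVector out((size_t)OH * OW * C);
  IntegerVector amax((size_t)OH * OW * C);
  out.attr("dim") = IntegerVector::create(OH, OW, C);
  amax.attr("dim") = IntegerVector::create(OH, OW, C);
  const double* xp = x.begin();
  for (int c = 0; c < C; ++c) {
    const double* xc = xp + (size_t)H * W * c;
    for (int j = 0; j < OW; ++j) {
      for (int i = 0; i < OH; ++i) {
        const double v1 = xc[2 * i + (size_t)H * (2 * j)];
        const double v2 = xc[2 * i + 1 + (size_t)H * (2 * j)];
        const double v3 = xc[2 * i + (size_t)H * (2 * j + 1)];
        const double v4 = xc[2 * i + 1 + (size_t)H * (2 * j + 1)];
        double m = v4; int a = 4;
        if (v3 >= m) { m = v3; a = 3; }
        if (v2 >= m) { m = v2; a = 2; }
        if (v1 >= m) { m = v1; a = 1; }
        const size_t o = i + (size_t)OH * (j + (size_t)OW * c);
        out[o] = m;
        amax[o] = a;
      }
    }
  }
  return List::create(_["out"] = out, _["amax"] = amax);
}

// [[Rcpp::export(name = ".cpp_pool_backward")]]
NumericVector cpp_pool_backward(IntegerVector amax, NumericVector dout,
                                IntegerVector in_dim) {
  const int H = in_dim[0], W = in_dim[1], C = in_dim[2];
  IntegerVector od = dout.attr("dim");
  const int OH = od[0], OW = od[1];
  NumericVector dx((size_t)H * W * C);
  dx.attr("dim") = in_dim;
  for (int c = 0; c < C; ++c) {
    double* dxc = dx.begin() + (size_t)H * W * c;
    for (int j = 0; j < OW; ++j) {
      for (int i = 0; i < OH; ++i) {
        const size_t o = i + (size_t)OH * (j + (size_t)OW * c);
        const int a = amax[o];
        const int di = (a == 2 || a == 4) ? 1 : 0;
        const int dj = (a >= 3) ? 1 : 0;
        dxc[2 * i + di + (size_t)H * (2 * j + dj)] += dout[o];
      }
    }
  }
  return dx;
}
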