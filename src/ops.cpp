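#include <Rcpp.h>
#include <deque>
using namespace Rcpp;

// Dense 2-D filtering (cross-correlation) with edge replication, output same
// size as input. Kernel sides must be odd.
// [[Rcpp::export]]
NumericMatrix conv2d_replicate_cpp(const NumericMatrix& img,
                                   const NumericMatrix& ker) {
  const int h = img.nrow(), w = img.ncol();
  const int kh = ker.nrow(), kw = ker.ncol();
  const int ri = kh / 2, rj = kw / 2;
  NumericMatrix out(h, w);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kw; ++b) {
        int jj = j + b - rj;
        if (jj < 0) jj = 0; else if (jj >= w) jj = w - 1;
        for (int a = 0; a < kh; ++a) {
          int ii = i + a - ri;
          if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
          acc += img(ii, jj) * ker(a, b);
        }
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// Separable filtering with a 1-D kernel applied along rows then columns,
// edge replication. Used for Gaussian pyramid construction.
// [[Rcpp::export]]
NumericMatrix sep_filter_replicate_cpp(const NumericMatrix& img,
                                       const NumericVector& k) {
  const int h = img.nrow(), w = img.ncol();
  const int kl = k.size(), r = kl / 2;
  NumericMatrix tmp(h, w), out(h, w);
  for (int j = 0; j < w; ++j)      // filter along columns (vertical)
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int a = 0; a < kl; ++a) {
        int ii = i + a - r;
        if (ii < 0) ii = 0; else if (ii >= h) ii = h - 1;
        acc += img(ii, j) * k[a];
      }
      tmp(i, j) = acc;
    }
  for (int j = 0; j < w; ++j)      // then along rows (horizontal)
    for (int i = 0; i < h; ++i) {
      double acc = 0.0;
      for (int b = 0; b < kl; ++b) {
        int jj = j + b - r;
        if (jj < 0) jj = 0; else if (jj >= w) jj = w - 1;
        acc += tmp(i, jj) * k[b];
      }
      out(i, j) = acc;
    }
  return out;
}

static inline int idx3(int i, int j, int c, int h, int w) {
  return i + j * h + c * h * w;
}

// Valid-region multi-channel convolution. input: h x w x C (column-major),
// weights: m x m x C x F, stride S. Output (h-m)/S+1 x (w-m)/S+1 x F.
// [[Rcpp::export]]
NumericVector conv_stack_valid_cpp(const NumericVector& input,
                                   const IntegerVector& idim,
                                   const NumericVector& wts,
                                   const IntegerVector& wdim,
                                   int stride) {
  const int h = idim[0], w = idim[1], C = idim[2];
  const int m = wdim[0], F = wdim[3];
  const int oh = (h - m) / stride + 1, ow = (w - m) / stride + 1;
  NumericVector out(oh * ow * F);
  for (int f = 0; f < F; ++f)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        double acc = 0.0;
        for (int c = 0; c < C; ++c)
          for (int b = 0; b < m; ++b)
            for (int a = 0; a < m; ++a)
              acc += input[idx3(i * stride + a, j * stride + b, c, h, w)] *
                     wts[a + b * m + c * m * m + f * m * m * C];
        out[i + j * oh + f * oh * ow] = acc;
      }
  out.attr("dim") = IntegerVector::create(oh, ow, F);
  return out;
}

// Gradients of the valid convolution: given d f / d out, returns
// d f / d input and d f / d weights.
// [[Rcpp::export]]
List conv_stack_backward_cpp(const NumericVector& input,
                             const IntegerVector& idim,
                             const NumericVector& wts,
                             const IntegerVector& wdim,
                             const NumericVector& dout,
                             int stride) {
  const int h = idim[0], w = idim[1], C = idim[2];
  const int m = wdim[0], F = wdim[3];
  const int oh = (h - m) / stride + 1, ow = (w - m) / stride + 1;
  NumericVector din(h * w * C), dw(m * m * C * F);
  for (int f = 0; f < F; ++f)
    for (int j = 0; j < ow; ++j)
      for (int i = 0; i < oh; ++i) {
        const double g = dout[i + j * oh + f * oh * ow];
        if (g == 0.0) continue;
        for (int c = 0; c < C; ++c)
          for (int b = 0; b < m; ++b)
            for (int a = 0; a < m; ++a) {
              const int ii = idx3(i * stride + a, j * stride + b, c, h, w);
              const int wi = a + b * m + c * m * m + f * m * m * C;
              din[ii] += g * wts[wi];
              dw[wi] += g * input[ii];
            }
      }
  din.attr("dim") = idim;
  dw.attr("dim") = wdim;
  return List::create(_["dinput"] = din, _["dweights"] = dw);
}

// Max pooling over non-overlapping 3x3 tiles, border tiles filled by edge
// replication (index clamping). Returns pooled planes plus the 1-based source
// coordinates of each maximum so the gradient can be routed back.
// [[Rcpp::export]]
List pool3_forward_cpp(const NumericVector& input, const IntegerVector& idim) {
  const int h = idim[0], w = idim[1], C = idim[2];
  const int oh = (h + 2) / 3, ow = (w + 2) / 3;
  NumericVector out(oh * ow * C);
  IntegerVector ai(oh * ow * C), aj(oh * ow * C);
  for (int c = 0; c < C; ++c)
    for (int tj = 0; tj < ow; ++tj)
      for (int ti = 0; ti < oh; ++ti) {
        double best = R_NegInf;
        int bi = 0, bj = 0;
        for (int b = 0; b < 3; ++b) {
          int jj = 3 * tj + b; if (jj >= w) jj = w - 1;
          for (int a = 0; a < 3; ++a) {
            int ii = 3 * ti + a; if (ii >= h) ii = h - 1;
            const double v = input[idx3(ii, jj, c, h, w)];
            if (v > best) { best = v; bi = ii; bj = jj; }
          }
        }
        const int o = ti + tj * oh + c * oh * ow;
        out[o] = best; ai[o] = bi + 1; aj[o] = bj + 1;
      }
  out.attr("dim") = IntegerVector::create(oh, ow, C);
  return List::create(_["out"] = out, _["arg_i"] = ai, _["arg_j"] = aj);
}

// [[Rcpp::export]]
NumericVector pool3_backward_cpp(const NumericVector& dout,
                                 const IntegerVector& arg_i,
                                 const IntegerVector& arg_j,
                                 const IntegerVector& idim,
                                 const IntegerVector& odim) {
  const int h = idim[0], w = idim[1];
  const int oh = odim[0], ow = odim[1], C = odim[2];
  NumericVector din(h * w * idim[2]);
  for (int c = 0; c < C; ++c)
    for (int tj = 0; tj < ow; ++tj)
      for (int ti = 0; ti < oh; ++ti) {
        const int o = ti + tj * oh + c * oh * ow;
        din[idx3(arg_i[o] - 1, arg_j[o] - 1, c, h, w)] += dout[o];
      }
  din.attr("dim") = idim;
  return din;
}

// Iterative 4-connected flood fill: all pixels reachable from the seed whose
// intensity is within tol of the SEED intensity. 1-based seed coordinates.
// [[Rcpp::export]]
LogicalMatrix flood_fill_cpp(const NumericMatrix& img, int seed_i, int seed_j,
                             double tol) {
  const int h = img.nrow(), w = img.ncol();
  LogicalMatrix mask(h, w);
  const int si = seed_i - 1, sj = seed_j - 1;
  const double ref = img(si, sj);
  std::deque<std::pair<int, int> > q;
  mask(si, sj) = true;
  q.push_back(std::make_pair(si, sj));
  const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    const std::pair<int, int> p = q.front();
    q.pop_front();
    for (int d = 0; d < 4; ++d) {
      const int ni = p.first + di[d], nj = p.second + dj[d];
      if (ni < 0 || nj < 0 || ni >= h || nj >= w || mask(ni, nj)) continue;
      if (std::abs(img(ni, nj) - ref) <= tol) {
        mask(ni, nj) = true;
        q.push_back(std::make_pair(ni, nj));
      }
    }
  }
  return mask;
}

// Strict 26-neighborhood extrema of a difference-of-Gaussians stack
// (h x w x L). Interior pixels and interior levels only. Returns 1-based
// (i, j, level) rows.
// [[Rcpp::export]]
IntegerMatrix find_extrema_cpp(const NumericVector& dog,
                               const IntegerVector& dim) {
  const int h = dim[0], w = dim[1], L = dim[2];
  std::vector<int> ri, rj, rl;
  for (int l = 1; l + 1 < L; ++l)
    for (int j = 1; j + 1 < w; ++j)
      for (int i = 1; i + 1 < h; ++i) {
        const double v = dog[idx3(i, j, l, h, w)];
        bool mx = true, mn = true;
        for (int dl = -1; dl <= 1 && (mx || mn); ++dl)
          for (int dj = -1; dj <= 1 && (mx || mn); ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dl == 0) continue;
              const double u = dog[idx3(i + di, j + dj, l + dl, h, w)];
              if (u >= v) mx = false;
              if (u <= v) mn = false;
              if (!mx && !mn) break;
            }
        if (mx || mn) { ri.push_back(i + 1); rj.push_back(j + 1); rl.push_back(l + 1); }
      }
  IntegerMatrix out(ri.size(), 3);
  for (int k = 0; k < (int)ri.size(); ++k) {
    out(k, 0) = ri[k]; out(k, 1) = rj[k]; out(k, 2) = rl[k];
  }
  colnames(out) = CharacterVector::create("i", "j", "level");
  return out;
}
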