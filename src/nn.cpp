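// Minimal convolutional Q-network core: stacks of (3x3 valid conv -> ReLU ->
// 2x2 max pool), one ReLU fully-connected layer, then either a plain linear
// output or a dueling value/advantage head with mean-centred aggregation.
// Forward and gradient passes only; the optimizer lives on the R side.
//
// Weight list layout (names fixed, shared with R/nn.R):
//   Wc<l> : n_filters x (9 * in_channels)   conv kernels, row r = ci*9+dx*3+dy
//   bc<l> : n_filters
//   Wf, bf: fully-connected layer
//   plain head: Wo (n_out x fc), bo
//   dueling:    Wv (1 x fc), bv, Wa (n_out x fc), ba
//
// Input X is an R array with dim (H, W, C, N); column-major layout matches
// arma::cube (rows, cols, slices) per sample.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::umat;
using arma::vec;

static mat im2col3(const cube& a) {
  const int h = a.n_rows, w = a.n_cols, c = a.n_slices;
  const int oh = h - 2, ow = w - 2;
  mat col(9 * c, (size_t)oh * ow);
  for (int ci = 0; ci < c; ci++)
    for (int dx = 0; dx < 3; dx++)
      for (int dy = 0; dy < 3; dy++) {
        const int r = ci * 9 + dx * 3 + dy;
        for (int ox = 0; ox < ow; ox++)
          for (int oy = 0; oy < oh; oy++)
            col(r, (size_t)ox * oh + oy) = a(oy + dy, ox + dx, ci);
      }
  return col;
}

static cube col2im3(const mat& g, int h, int w, int c) {
  cube out(h, w, c, arma::fill::zeros);
  const int oh = h - 2, ow = w - 2;
  for (int ci = 0; ci < c; ci++)
    for (int dx = 0; dx < 3; dx++)
      for (int dy = 0; dy < 3; dy++) {
        const int r = ci * 9 + dx * 3 + dy;
        for (int ox = 0; ox < ow; ox++)
          for (int oy = 0; oy < oh; oy++)
            out(oy + dy, ox + dx, ci) += g(r, (size_t)ox * oh + oy);
      }
  return out;
}

// max pool 2x2 stride 2 on Y (n_filters x oh*ow, position index ox*oh+oy);
// odd trailing rows/cols are dropped. idx records the argmax column of Y.
static void maxpool2(const mat& Y, int oh, int ow, mat& P, umat& idx) {
  const int nf = Y.n_rows, ph = oh / 2, pw = ow / 2;
  P.set_size(nf, (size_t)ph * pw);
  idx.set_size(nf, (size_t)ph * pw);
  for (int px = 0; px < pw; px++)
    for (int py = 0; py < ph; py++) {
      const size_t pc = (size_t)px * ph + py;
      for (int f = 0; f < nf; f++) {
        double best = -1e300;
        size_t bi = 0;
        for (int dx = 0; dx < 2; dx++)
          for (int dy = 0; dy < 2; dy++) {
            const size_t cc = (size_t)(2 * px + dx) * oh + (2 * py + dy);
            if (Y(f, cc) > best) { best = Y(f, cc); bi = cc; }
          }
        P(f, pc) = best;
        idx(f, pc) = bi;
      }
    }
}

static cube pooled_to_cube(const mat& P, int ph, int pw) {
  const int nf = P.n_rows;
  cube a(ph, pw, nf);
  for (int f = 0; f < nf; f++)
    for (int x = 0; x < pw; x++)
      for (int y = 0; y < ph; y++)
        a(y, x, f) = P(f, (size_t)x * ph + y);
  return a;
}

struct NetDef {
  std::vector<mat> Wc;
  std::vector<vec> bc;
  mat Wf, Wo, Wv, Wa;
  vec bf, bo, bv, ba;
  bool dueling;
  int n_out;
};

static NetDef read_net(const List& w, const List& spec) {
  NetDef d;
  IntegerVector cf = spec["conv_filters"];
  const int L = cf.size();
  d.dueling = as<bool>(spec["dueling"]);
  d.n_out = as<int>(spec["n_out"]);
  for (int l = 0; l < L; l++) {
    std::string s = std::to_string(l + 1);
    d.Wc.push_back(as<mat>(w["Wc" + s]));
    d.bc.push_back(as<vec>(w["bc" + s]));
  }
  d.Wf = as<mat>(w["Wf"]);
  d.bf = as<vec>(w["bf"]);
  if (d.dueling) {
    d.Wv = as<mat>(w["Wv"]); d.bv = as<vec>(w["bv"]);
    d.Wa = as<mat>(w["Wa"]); d.ba = as<vec>(w["ba"]);
  } else {
    d.Wo = as<mat>(w["Wo"]); d.bo = as<vec>(w["bo"]);
  }
  return d;
}

// [[Rcpp::export]]
arma::mat nn_forward_cpp(List weights, List spec, NumericVector X) {
  NetDef d = read_net(weights, spec);
  IntegerVector xd = X.attr("dim");
  if (xd.size() != 4) stop("input must be an (H, W, C, N) array");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int L = d.Wc.size();
  mat out(d.n_out, N);
  const double* xp = X.begin();
  const size_t sz = (size_t)H * W * C;
  for (int n = 0; n < N; n++) {
    cube a(H, W, C);
    std::copy(xp + n * sz, xp + (n + 1) * sz, a.memptr());
    for (int l = 0; l < L; l++) {
      const int oh = a.n_rows - 2, ow = a.n_cols - 2;
      mat col = im2col3(a);
      mat Y = d.Wc[l] * col;
      Y.each_col() += d.bc[l];
      Y.clamp(0.0, arma::datum::inf);
      mat P; umat idx;
      maxpool2(Y, oh, ow, P, idx);
      a = pooled_to_cube(P, oh / 2, ow / 2);
    }
    vec f0 = arma::vectorise(a);
    vec h = d.Wf * f0 + d.bf;
    h.clamp(0.0, arma::datum::inf);
    if (d.dueling) {
      const double V = arma::as_scalar(d.Wv * h) + d.bv(0);
      vec A = d.Wa * h + d.ba;
      out.col(n) = V + A - arma::mean(A);
    } else {
      out.col(n) = d.Wo * h + d.bo;
    }
  }
  return out;
}

// Forward + backward for a batch. grad_out (n_out x N) is dLoss/d(output);
// returned gradients are summed over the batch (scale grad_out on the R side
// for a mean loss). Also returns the forward output.
// [[Rcpp::export]]
List nn_grad_cpp(List weights, List spec, NumericVector X, arma::mat grad_out) {
  NetDef d = read_net(weights, spec);
  IntegerVector xd = X.attr("dim");
  if (xd.size() != 4) stop("input must be an (H, W, C, N) array");
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int L = d.Wc.size();
  if ((int)grad_out.n_cols != N || (int)grad_out.n_rows != d.n_out)
    stop("grad_out must be n_out x N");

  std::vector<mat> gWc(L);
  std::vector<vec> gbc(L);
  for (int l = 0; l < L; l++) {
    gWc[l] = arma::zeros<mat>(d.Wc[l].n_rows, d.Wc[l].n_cols);
    gbc[l] = arma::zeros<vec>(d.bc[l].n_elem);
  }
  mat gWf = arma::zeros<mat>(d.Wf.n_rows, d.Wf.n_cols);
  vec gbf = arma::zeros<vec>(d.bf.n_elem);
  mat gWo, gWv, gWa;
  vec gbo, gbv, gba;
  if (d.dueling) {
    gWv = arma::zeros<mat>(d.Wv.n_rows, d.Wv.n_cols);
    gbv = arma::zeros<vec>(1);
    gWa = arma::zeros<mat>(d.Wa.n_rows, d.Wa.n_cols);
    gba = arma::zeros<vec>(d.ba.n_elem);
  } else {
    gWo = arma::zeros<mat>(d.Wo.n_rows, d.Wo.n_cols);
    gbo = arma::zeros<vec>(d.bo.n_elem);
  }
  mat out(d.n_out, N);

  const double* xp = X.begin();
  const size_t sz = (size_t)H * W * C;
  for (int n = 0; n < N; n++) {
    // ---- forward with caches ----
    cube a(H, W, C);
    std::copy(xp + n * sz, xp + (n + 1) * sz, a.memptr());
    std::vector<mat> cols(L), masks(L);
    std::vector<umat> pidx(L);
    std::vector<int> ih(L), iw(L), ic(L), oh(L), ow(L);
    for (int l = 0; l < L; l++) {
      ih[l] = a.n_rows; iw[l] = a.n_cols; ic[l] = a.n_slices;
      oh[l] = ih[l] - 2; ow[l] = iw[l] - 2;
      cols[l] = im2col3(a);
      mat Y = d.Wc[l] * cols[l];
      Y.each_col() += d.bc[l];
      masks[l] = arma::conv_to<mat>::from(Y > 0.0);
      Y.clamp(0.0, arma::datum::inf);
      mat P;
      maxpool2(Y, oh[l], ow[l], P, pidx[l]);
      a = pooled_to_cube(P, oh[l] / 2, ow[l] / 2);
    }
    const int fh = a.n_rows, fw = a.n_cols, fc = a.n_slices;
    vec f0 = arma::vectorise(a);
    vec zf = d.Wf * f0 + d.bf;
    vec fmask = arma::conv_to<vec>::from(zf > 0.0);
    vec h = zf;
    h.clamp(0.0, arma::datum::inf);
    vec go = grad_out.col(n);
    vec gh;
    if (d.dueling) {
      const double V = arma::as_scalar(d.Wv * h) + d.bv(0);
      vec A = d.Wa * h + d.ba;
      out.col(n) = V + A - arma::mean(A);
      const double gV = arma::accu(go);
      vec gA = go - arma::mean(go);
      gWv += gV * h.t();
      gbv(0) += gV;
      gWa += gA * h.t();
      gba += gA;
      gh = d.Wv.t() * gV + d.Wa.t() * gA;
    } else {
      out.col(n) = d.Wo * h + d.bo;
      gWo += go * h.t();
      gbo += go;
      gh = d.Wo.t() * go;
    }
    // ---- backward ----
    gh %= fmask;
    gWf += gh * f0.t();
    gbf += gh;
    vec gf0 = d.Wf.t() * gh;
    // gradient w.r.t. pooled output of the last conv stage
    cube gac(gf0.memptr(), fh, fw, fc);
    for (int l = L - 1; l >= 0; l--) {
      const int ph = oh[l] / 2, pw = ow[l] / 2, nf = d.Wc[l].n_rows;
      mat gP(nf, (size_t)ph * pw);
      for (int f = 0; f < nf; f++)
        for (int x = 0; x < pw; x++)
          for (int y = 0; y < ph; y++)
            gP(f, (size_t)x * ph + y) = gac(y, x, f);
      mat gY(nf, (size_t)oh[l] * ow[l], arma::fill::zeros);
      for (int f = 0; f < nf; f++)
        for (size_t pc = 0; pc < (size_t)ph * pw; pc++)
          gY(f, pidx[l](f, pc)) += gP(f, pc);
      gY %= masks[l];
      gWc[l] += gY * cols[l].t();
      gbc[l] += arma::sum(gY, 1);
      if (l > 0) {
        mat gcol = d.Wc[l].t() * gY;
        gac = col2im3(gcol, ih[l], iw[l], ic[l]);
      }
    }
  }

  List g;
  for (int l = 0; l < L; l++) {
    std::string s = std::to_string(l + 1);
    g["Wc" + s] = gWc[l];
    g["bc" + s] = gbc[l];
  }
  g["Wf"] = gWf;
  g["bf"] = gbf;
  if (d.dueling) {
    g["Wv"] = gWv; g["bv"] = gbv; g["Wa"] = gWa; g["ba"] = gba;
  } else {
    g["Wo"] = gWo; g["bo"] = gbo;
  }
  return List::create(_["grads"] = g, _["out"] = out);
}
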