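// Batched dense kernels for the encoding models.
// Tensor layout everywhere: column-major R arrays (H, W, C, N) --
// height fastest, image index slowest. Valid convolution, stride 1.
//
// The patch matrix Pt is (Ho*Wo*N) x (kh*kw*Cin): column r = (di, dj, ci)
// holds x shifted by (di, dj) in channel ci, so both the im2col gather and
// the col2im scatter move contiguous runs of Ho doubles. During training the
// forward pass hands Pt to the backward pass as an external pointer; the
// backward pass frees it deterministically.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline void get_dim4(const NumericVector& x, int* d) {
  IntegerVector dm = x.attr("dim");
  if (dm.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  for (int i = 0; i < 4; ++i) d[i] = dm[i];
}

static void fill_im2col(const double* x, int H, int W, int Cin, int N,
                        int kh, int kw, arma::mat& Pt) {
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  int r = 0;
  for (int ci = 0; ci < Cin; ++ci) {
    for (int dj = 0; dj < kw; ++dj) {
      for (int di = 0; di < kh; ++di, ++r) {
        double* dst = Pt.colptr(r);
        for (int n = 0; n < N; ++n) {
          const double* xc = x + (size_t)H * W * (ci + (size_t)Cin * n);
          for (int j0 = 0; j0 < Wo; ++j0) {
            std::memcpy(dst + (size_t)Ho * (j0 + (size_t)Wo * n),
                        xc + di + (size_t)H * (j0 + dj), Ho * sizeof(double));
          }
        }
      }
    }
  }
}

// Valid convolution + bias, optional ReLU. Returns list(out, p) where p is
// an external pointer to the patch matrix (or NULL if !keep_patches).
// [[Rcpp::export]]
List cpp_conv2d_fwd(NumericVector x, NumericVector w, NumericVector b,
                    bool relu, bool keep_patches) {
  int xd[4], wd[4];
  get_dim4(x, xd); get_dim4(w, wd);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  if (wd[2] != Cin) stop("channel mismatch between input and kernel");
  const int Ho = H - kh + 1, Wo = W - kw + 1;
  if (Ho < 1 || Wo < 1) stop("input too small for valid convolution");

  arma::mat* Pt = new arma::mat((size_t)Ho * Wo * N, (size_t)kh * kw * Cin);
  fill_im2col(REAL(x), H, W, Cin, N, kh, kw, *Pt);
  const arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)kh * kw * Cin,
                     Cout, false, true);
  arma::mat Y = (*Pt) * Wm;  // (Ho*Wo*N) x Cout

  NumericVector out((R_xlen_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  double* o = REAL(out);
  const double* bp = REAL(b);
  const size_t plane = (size_t)Ho * Wo;
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const double* yc = Y.colptr(co) + plane * n;
      double* oc = o + plane * (co + (size_t)Cout * n);
      const double bias = bp[co];
      if (relu) {
        for (size_t p = 0; p < plane; ++p) {
          double v = yc[p] + bias;
          oc[p] = v > 0.0 ? v : 0.0;
        }
      } else {
        for (size_t p = 0; p < plane; ++p) oc[p] = yc[p] + bias;
      }
    }
  }
  if (keep_patches) {
    XPtr<arma::mat> pxp(Pt, true);
    return List::create(_["out"] = out, _["p"] = pxp);
  }
  delete Pt;
  return List::create(_["out"] = out, _["p"] = R_NilValue);
}

// Backward pass. If `out` (the forward ReLU output) is non-NULL, dy is
// masked by out > 0. `p` is the patch pointer from the forward call
// (recomputed from x when NULL) and is freed after use.
// [[Rcpp::export]]
List cpp_conv2d_bwd(NumericVector x, NumericVector w, NumericVector dy,
                    Nullable<NumericVector> out_, SEXP p_, bool need_dx) {
  int xd[4], wd[4], yd[4];
  get_dim4(x, xd); get_dim4(w, wd); get_dim4(dy, yd);
  const int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  const int kh = wd[0], kw = wd[1], Cout = wd[3];
  const int Ho = yd[0], Wo = yd[1];
  if (yd[2] != Cout || yd[3] != N || Ho != H - kh + 1 || Wo != W - kw + 1)
    stop("gradient shape mismatch");
  const size_t plane = (size_t)Ho * Wo;

  // Re-pack dy (Ho,Wo,Cout,N) into (Ho*Wo*N) x Cout, applying the ReLU mask.
  arma::mat dY((size_t)Ho * Wo * N, Cout);
  const double* dyp = REAL(dy);
  NumericVector outv;
  const double* op = nullptr;
  if (out_.isNotNull()) { outv = NumericVector(out_); op = REAL(outv); }
  for (int n = 0; n < N; ++n) {
    for (int co = 0; co < Cout; ++co) {
      const size_t off = plane * (co + (size_t)Cout * n);
      double* dst = dY.colptr(co) + plane * n;
      if (op) {
        for (size_t p = 0; p < plane; ++p)
          dst[p] = op[off + p] > 0.0 ? dyp[off + p] : 0.0;
      } else {
        std::memcpy(dst, dyp + off, plane * sizeof(double));
      }
    }
  }

  arma::mat* Pt = nullptr;
  bool own = false;
  if (p_ != R_NilValue) {
    XPtr<arma::mat> xp(p_);
    Pt = xp.get();
    if (Pt != nullptr && (Pt->n_rows != (size_t)Ho * Wo * N ||
                          Pt->n_cols != (size_t)kh * kw * Cin))
      stop("patch matrix shape mismatch");
  }
  if (Pt == nullptr) {  // none kept, or already consumed: recompute
    Pt = new arma::mat((size_t)Ho * Wo * N, (size_t)kh * kw * Cin);
    own = true;
    fill_im2col(REAL(x), H, W, Cin, N, kh, kw, *Pt);
  }

  arma::mat dWm = Pt->t() * dY;  // (kh*kw*Cin) x Cout
  NumericVector dw(dWm.n_elem);
  dw.attr("dim") = IntegerVector::create(kh, kw, Cin, Cout);
  std::memcpy(REAL(dw), dWm.memptr(), dWm.n_elem * sizeof(double));

  NumericVector db(Cout);
  arma::rowvec dbv = arma::sum(dY, 0);
  std::memcpy(REAL(db), dbv.memptr(), Cout * sizeof(double));

  if (own) {
    delete Pt;
  } else {
    // free the forward pass's patches now rather than at GC time
    // (XPtr::release runs the delete finalizer and clears the pointer)
    XPtr<arma::mat> xp(p_);
    xp.release();
  }
  Pt = nullptr;

  NumericVector dx;
  if (need_dx) {
    const arma::mat Wm(const_cast<double*>(REAL(w)), (size_t)kh * kw * Cin,
                       Cout, false, true);
    arma::mat dPt = dY * Wm.t();  // (Ho*Wo*N) x (kh*kw*Cin)
    dx = NumericVector((R_xlen_t)H * W * Cin * N);
    dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
    double* dxp = REAL(dx);
    int r = 0;
    for (int ci = 0; ci < Cin; ++ci) {
      for (int dj = 0; dj < kw; ++dj) {
        for (int di = 0; di < kh; ++di, ++r) {
          const double* src = dPt.colptr(r);
          for (int n = 0; n < N; ++n) {
            double* xc = dxp + (size_t)H * W * (ci + (size_t)Cin * n);
            for (int j0 = 0; j0 < Wo; ++j0) {
              double* dst = xc + di + (size_t)H * (j0 + dj);
              const double* s = src + (size_t)Ho * (j0 + (size_t)Wo * n);
              for (int i0 = 0; i0 < Ho; ++i0) dst[i0] += s[i0];
            }
          }
        }
      }
    }
  }
  return List::create(_["dw"] = dw, _["db"] = db, _["dx"] = dx);
}

// 2x2 max pooling, stride 2, floor division (odd trailing row/col dropped).
// Returns list(out, idx) with idx the 1-based linear index into x of each
// selected element (first-seen maximum wins ties).
// [[Rcpp::export]]
List cpp_maxpool2_fwd(NumericVector x) {
  int xd[4];
  get_dim4(x, xd);
  const int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  const int H2 = H / 2, W2 = W / 2;
  if (H2 < 1 || W2 < 1) stop("input too small for 2x2 pooling");

  NumericVector out((R_xlen_t)H2 * W2 * C * N);
  IntegerVector idx((R_xlen_t)H2 * W2 * C * N);
  out.attr("dim") = IntegerVector::create(H2, W2, C, N);
  idx.attr("dim") = IntegerVector::create(H2, W2, C, N);
  const double* xp = REAL(x);
  double* op = REAL(out);
  int* ip = INTEGER(idx);
  size_t o = 0;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const size_t base = (size_t)H * W * (c + (size_t)C * n);
      for (int j = 0; j < W2; ++j) {
        for (int i = 0; i < H2; ++i, ++o) {
          size_t best = base + (size_t)2 * i + (size_t)H * (2 * j);
          double bv = xp[best];
          const size_t cand[3] = {
              base + (size_t)2 * i + 1 + (size_t)H * (2 * j),
              base + (size_t)2 * i + (size_t)H * (2 * j + 1),
              base + (size_t)2 * i + 1 + (size_t)H * (2 * j + 1)};
          for (int t = 0; t < 3; ++t)
            if (xp[cand[t]] > bv) { bv = xp[cand[t]]; best = cand[t]; }
          op[o] = bv;
          ip[o] = (int)(best + 1);
        }
      }
    }
  }
  return List::create(_["out"] = out, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool2_bwd(IntegerVector idx, NumericVector dy,
                               IntegerVector xdim) {
  R_xlen_t nx = (R_xlen_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(nx);
  dx.attr("dim") = xdim;
  double* dxp = REAL(dx);
  const double* dyp = REAL(dy);
  const int* ip = INTEGER(idx);
  const R_xlen_t m = dy.size();
  for (R_xlen_t k = 0; k < m; ++k) dxp[ip[k] - 1] += dyp[k];
  return dx;
}

static void add_bias_rows(arma::mat& M, const double* b) {
  for (size_t j = 0; j < M.n_cols; ++j) M.col(j) += b[j];
}

static void row_softmax_inplace(arma::mat& L) {
  for (size_t i = 0; i < L.n_rows; ++i) {
    double mx = L.row(i).max();
    L.row(i) = arma::exp(L.row(i) - mx);
    L.row(i) /= arma::accu(L.row(i));
  }
}

// Single-headed spatial self-attention forward over a (h, w, c, N) batch.
// Features at image n are viewed as M (np x c), np = h*w positions.
// out = M + s * O2 with O2 the (optionally projected) attention readout.
// Returns the output and the per-image intermediates needed for backprop:
// Q, K (np x c x N), A (np x np x N), O and (gamma) O2 (np x c x N).
// [[Rcpp::export]]
List cpp_sa_fwd(NumericVector x, NumericMatrix Wq, NumericVector bq,
                NumericMatrix Wk, NumericVector bk, double s, bool gamma,
                Nullable<NumericMatrix> Wv_, Nullable<NumericVector> bv_,
                Nullable<NumericMatrix> Wo_, Nullable<NumericVector> bo_) {
  int xd[4];
  get_dim4(x, xd);
  const int h = xd[0], w = xd[1], c = xd[2], N = xd[3];
  const size_t np = (size_t)h * w;
  const arma::mat WQ(const_cast<double*>(REAL(Wq)), c, c, false, true);
  const arma::mat WK(const_cast<double*>(REAL(Wk)), c, c, false, true);
  arma::mat WV, WO;
  NumericMatrix Wvv, Wov;
  NumericVector bvv, bov;
  if (gamma) {
    Wvv = NumericMatrix(Wv_); Wov = NumericMatrix(Wo_);
    bvv = NumericVector(bv_); bov = NumericVector(bo_);
    WV = arma::mat(REAL(Wvv), c, c, false, true);
    WO = arma::mat(REAL(Wov), c, c, false, true);
  }
  const double scl = 1.0 / std::sqrt((double)c);

  NumericVector out((R_xlen_t)np * c * N);
  out.attr("dim") = IntegerVector::create(h, w, c, N);
  NumericVector Qs((R_xlen_t)np * c * N), Ks((R_xlen_t)np * c * N),
      As((R_xlen_t)np * np * N), Os((R_xlen_t)np * c * N);
  NumericVector O2s, Vs;
  if (gamma) {
    O2s = NumericVector((R_xlen_t)np * c * N);
    Vs = NumericVector((R_xlen_t)np * c * N);
  }

  for (int n = 0; n < N; ++n) {
    const arma::mat M(const_cast<double*>(REAL(x)) + np * c * n, np, c,
                      false, true);
    arma::mat Q(REAL(Qs) + np * c * n, np, c, false, true);
    arma::mat K(REAL(Ks) + np * c * n, np, c, false, true);
    arma::mat A(REAL(As) + np * np * n, np, np, false, true);
    arma::mat O(REAL(Os) + np * c * n, np, c, false, true);
    Q = M * WQ; add_bias_rows(Q, REAL(bq));
    K = M * WK; add_bias_rows(K, REAL(bk));
    A = Q * K.t() * scl;
    row_softmax_inplace(A);
    arma::mat outn(REAL(out) + np * c * n, np, c, false, true);
    if (gamma) {
      arma::mat V(REAL(Vs) + np * c * n, np, c, false, true);
      V = M * WV; add_bias_rows(V, REAL(bvv));
      O = A * V;
      arma::mat O2(REAL(O2s) + np * c * n, np, c, false, true);
      O2 = O * WO; add_bias_rows(O2, REAL(bov));
      outn = M + s * O2;
    } else {
      O = A * M;
      outn = M + s * O;
    }
  }
  return List::create(_["out"] = out, _["Q"] = Qs, _["K"] = Ks, _["A"] = As,
                      _["O"] = Os, _["O2"] = gamma ? (SEXP)O2s : R_NilValue,
                      _["V"] = gamma ? (SEXP)Vs : R_NilValue);
}

// Backward pass for the SA layer. dout is (h, w, c, N). Returns parameter
// gradients and (optionally) the input gradient.
// [[Rcpp::export]]
List cpp_sa_bwd(NumericVector x, NumericMatrix Wq, NumericMatrix Wk,
                double s, bool gamma, Nullable<NumericMatrix> Wv_,
                Nullable<NumericMatrix> Wo_, List cache, NumericVector dout,
                bool need_dx) {
  int xd[4];
  get_dim4(x, xd);
  const int h = xd[0], w = xd[1], c = xd[2], N = xd[3];
  const size_t np = (size_t)h * w;
  const arma::mat WQ(const_cast<double*>(REAL(Wq)), c, c, false, true);
  const arma::mat WK(const_cast<double*>(REAL(Wk)), c, c, false, true);
  arma::mat WV, WO;
  NumericMatrix Wvv, Wov;
  if (gamma) {
    Wvv = NumericMatrix(Wv_); Wov = NumericMatrix(Wo_);
    WV = arma::mat(REAL(Wvv), c, c, false, true);
    WO = arma::mat(REAL(Wov), c, c, false, true);
  }
  const double scl = 1.0 / std::sqrt((double)c);
  NumericVector Qs = cache["Q"], Ks = cache["K"], As = cache["A"],
                Os = cache["O"];
  NumericVector O2s, Vs;
  if (gamma) {
    O2s = NumericVector(cache["O2"]);
    Vs = NumericVector(cache["V"]);
  }

  arma::mat gWq(c, c, arma::fill::zeros), gWk(c, c, arma::fill::zeros);
  arma::vec gbq(c, arma::fill::zeros), gbk(c, arma::fill::zeros);
  arma::mat gWv, gWo;
  arma::vec gbv, gbo;
  if (gamma) {
    gWv.zeros(c, c); gWo.zeros(c, c); gbv.zeros(c); gbo.zeros(c);
  }
  double gs = 0;
  NumericVector dx;
  double* dxp = nullptr;
  if (need_dx) {
    dx = NumericVector((R_xlen_t)np * c * N);
    dx.attr("dim") = IntegerVector::create(h, w, c, N);
    dxp = REAL(dx);
  }

  for (int n = 0; n < N; ++n) {
    const arma::mat M(const_cast<double*>(REAL(x)) + np * c * n, np, c,
                      false, true);
    const arma::mat Q(const_cast<double*>(REAL(Qs)) + np * c * n, np, c,
                      false, true);
    const arma::mat K(const_cast<double*>(REAL(Ks)) + np * c * n, np, c,
                      false, true);
    const arma::mat A(const_cast<double*>(REAL(As)) + np * np * n, np, np,
                      false, true);
    const arma::mat O(const_cast<double*>(REAL(Os)) + np * c * n, np, c,
                      false, true);
    const arma::mat dOut(const_cast<double*>(REAL(dout)) + np * c * n, np, c,
                         false, true);
    arma::mat dM = dOut;  // residual path
    arma::mat dO;
    if (gamma) {
      const arma::mat O2(const_cast<double*>(REAL(O2s)) + np * c * n, np, c,
                         false, true);
      gs += arma::accu(dOut % O2);
      arma::mat dO2 = s * dOut;
      gWo += O.t() * dO2;
      gbo += arma::sum(dO2, 0).t();
      dO = dO2 * WO.t();
    } else {
      gs += arma::accu(dOut % O);
      dO = s * dOut;
    }
    arma::mat dA;
    if (gamma) {
      const arma::mat V(const_cast<double*>(REAL(Vs)) + np * c * n, np, c,
                        false, true);
      dA = dO * V.t();
    } else {
      dA = dO * M.t();
    }
    arma::mat dV = A.t() * dO;
    if (gamma) {
      gWv += M.t() * dV;
      gbv += arma::sum(dV, 0).t();
      dM += dV * WV.t();
    } else {
      dM += dV;
    }
    // softmax rows: dL = A % (dA - rowsum(dA % A)), scaled
    arma::vec rs = arma::sum(dA % A, 1);
    arma::mat dL = A % (dA.each_col() - rs) * scl;
    arma::mat dQ = dL * K;
    arma::mat dK = dL.t() * Q;
    gWq += M.t() * dQ;
    gbq += arma::sum(dQ, 0).t();
    gWk += M.t() * dK;
    gbk += arma::sum(dK, 0).t();
    dM += dQ * WQ.t() + dK * WK.t();
    if (need_dx) {
      arma::mat dxn(dxp + np * c * n, np, c, false, true);
      dxn = dM;
    }
  }
  List g = List::create(_["Wq"] = wrap(gWq), _["bq"] = wrap(gbq),
                        _["Wk"] = wrap(gWk), _["bk"] = wrap(gbk),
                        _["s"] = gs);
  if (gamma) {
    g["Wv"] = wrap(gWv); g["bv"] = wrap(gbv);
    g["Wo"] = wrap(gWo); g["bo"] = wrap(gbo);
  }
  return List::create(_["grads"] = g, _["dx"] = dx);
}
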