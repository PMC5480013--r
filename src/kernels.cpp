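// Low-level numeric kernels for the encoder-decoder networks and the
// connected-component analysis. Tensors are R arrays in column-major
// layout with dimensions (H, W, C, N): rows, columns, channels, batch.
//
// Convolutions use an im2col + GEMM strategy. The patch-matrix row index
// for input channel ci and kernel offset (kr, kc) is ci*k*k + kr*k + kc,
// matching the weight-matrix layout (Cout x Cin*k*k) used on the R side.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static void get_dims4(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("expected a 4-d array (H, W, C, N)");
  H = d[0]; W = d[1]; C = d[2]; N = d[3];
}

// col: (C*k*k) x (H*W); output pixel (r, c) maps to column r + c*H.
static void im2col(const double* x, int H, int W, int C, int k, int pad,
                   arma::mat& col) {
  const int kk = k * k;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      double* dst = col.colptr(r + c * H);
      for (int ci = 0; ci < C; ++ci) {
        const double* xc = x + (size_t)ci * H * W;
        double* d2 = dst + ci * kk;
        for (int kr = 0; kr < k; ++kr) {
          const int rr = r + kr - pad;
          for (int kc = 0; kc < k; ++kc) {
            const int cc = c + kc - pad;
            d2[kr * k + kc] = (rr >= 0 && rr < H && cc >= 0 && cc < W)
              ? xc[rr + (size_t)cc * H] : 0.0;
          }
        }
      }
    }
  }
}

// Scatter-add the transpose access of A (H*W x C*k*k) back to image space.
static void col2im_acc(const arma::mat& A, int H, int W, int C, int k, int pad,
                       double* gx) {
  const int kk = k * k;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const int j = r + c * H;
      for (int ci = 0; ci < C; ++ci) {
        double* gc = gx + (size_t)ci * H * W;
        for (int kr = 0; kr < k; ++kr) {
          const int rr = r + kr - pad;
          if (rr < 0 || rr >= H) continue;
          for (int kc = 0; kc < k; ++kc) {
            const int cc = c + kc - pad;
            if (cc < 0 || cc >= W) continue;
            gc[rr + (size_t)cc * H] += A(j, ci * kk + kr * k + kc);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector conv2d_fwd(NumericVector x, NumericMatrix Wm, NumericVector b,
                         int k, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = Wm.nrow();
  if (Wm.ncol() != C * k * k) stop("weight matrix does not match input channels");
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat Wt(Wm.begin(), Cout, C * k * k, false);
  arma::mat col(C * k * k, H * W);
  const size_t slab_in = (size_t)H * W * C, slab_out = (size_t)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * slab_in, H, W, C, k, pad, col);
    // (H*W x Cout) is exactly the memory layout of the output slab.
    arma::mat Y(out.begin() + n * slab_out, H * W, Cout, false, true);
    Y = col.t() * Wt.t();
    for (int co = 0; co < Cout; ++co) Y.col(co) += b[co];
  }
  return out;
}

// [[Rcpp::export]]
List conv2d_bwd(NumericVector x, NumericMatrix Wm, NumericVector gy,
                int k, int pad) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  const int Cout = Wm.nrow();
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericMatrix gW(Cout, C * k * k);
  NumericVector gb(Cout);
  arma::mat Wt(Wm.begin(), Cout, C * k * k, false);
  arma::mat gWt(gW.begin(), Cout, C * k * k, false, true);
  arma::mat col(C * k * k, H * W);
  const size_t slab_in = (size_t)H * W * C, slab_out = (size_t)H * W * Cout;
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + n * slab_in, H, W, C, k, pad, col);
    arma::mat Gt(const_cast<double*>(gy.begin()) + n * slab_out,
                 H * W, Cout, false, true);
    gWt += (col * Gt).t();
    for (int co = 0; co < Cout; ++co) gb[co] += arma::accu(Gt.col(co));
    arma::mat A = Gt * Wt;                    // (H*W) x (C*k*k)
    col2im_acc(A, H, W, C, k, pad, gx.begin() + n * slab_in);
  }
  return List::create(_["gx"] = gx, _["gW"] = gW, _["gb"] = gb);
}

// Max pooling over non-overlapping window x window cells, stride = window.
// The mask stores the within-window argmax as a 0-based row-major index
// wr*window + wc; ties are broken by the first position in row-major order.
// [[Rcpp::export]]
List maxpool_fwd(NumericVector x, int window) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  if (H % window != 0 || W % window != 0)
    stop("spatial dimensions must be divisible by the pooling window");
  const int Hp = H / window, Wp = W / window;
  NumericVector out((size_t)Hp * Wp * C * N);
  out.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  IntegerVector mask((size_t)Hp * Wp * C * N);
  mask.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  const size_t slab = (size_t)H * W, slabp = (size_t)Hp * Wp;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* xc = x.begin() + ((size_t)n * C + c) * slab;
      double* oc = out.begin() + ((size_t)n * C + c) * slabp;
      int* mc = mask.begin() + ((size_t)n * C + c) * slabp;
      for (int pc = 0; pc < Wp; ++pc) {
        for (int pr = 0; pr < Hp; ++pr) {
          double best = R_NegInf;
          int besti = 0;
          for (int wr = 0; wr < window; ++wr) {     // row-major scan:
            for (int wc = 0; wc < window; ++wc) {   // strict > keeps first
              const double v = xc[(pr * window + wr) +
                                  (size_t)(pc * window + wc) * H];
              if (v > best) { best = v; besti = wr * window + wc; }
            }
          }
          oc[pr + (size_t)pc * Hp] = best;
          mc[pr + (size_t)pc * Hp] = besti;
        }
      }
    }
  }
  return List::create(_["out"] = out, _["mask"] = mask);
}

// Sparse upsampling: each pooled value is placed at its recorded position,
// all other entries are zero.
// [[Rcpp::export]]
NumericVector unpool_fwd(NumericVector p, IntegerVector mask, int window) {
  int Hp, Wp, C, N;
  get_dims4(p, Hp, Wp, C, N);
  IntegerVector md = mask.attr("dim");
  if (md.size() != 4 || md[0] != Hp || md[1] != Wp || md[2] != C || md[3] != N)
    stop("pooling mask does not match the pooled map");
  const int H = Hp * window, W = Wp * window;
  NumericVector out((size_t)H * W * C * N);
  out.attr("dim") = IntegerVector::create(H, W, C, N);
  const size_t slab = (size_t)H * W, slabp = (size_t)Hp * Wp;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* pc_ = p.begin() + ((size_t)n * C + c) * slabp;
      const int* mc = mask.begin() + ((size_t)n * C + c) * slabp;
      double* oc = out.begin() + ((size_t)n * C + c) * slab;
      for (int pcx = 0; pcx < Wp; ++pcx) {
        for (int pr = 0; pr < Hp; ++pr) {
          const int m = mc[pr + (size_t)pcx * Hp];
          const int wr = m / window, wc = m % window;
          oc[(pr * window + wr) + (size_t)(pcx * window + wc) * H] =
            pc_[pr + (size_t)pcx * Hp];
        }
      }
    }
  }
  return out;
}

// Gather at recorded positions: the adjoint of unpool_fwd (and the
// gradient route of maxpool_fwd).
// [[Rcpp::export]]
NumericVector mask_gather(NumericVector g, IntegerVector mask, int window) {
  IntegerVector md = mask.attr("dim");
  if (md.size() != 4) stop("mask must be a 4-d array");
  const int Hp = md[0], Wp = md[1], C = md[2], N = md[3];
  int H, W, Cg, Ng;
  get_dims4(g, H, W, Cg, Ng);
  if (H != Hp * window || W != Wp * window || Cg != C || Ng != N)
    stop("gradient shape does not match mask and window");
  NumericVector out((size_t)Hp * Wp * C * N);
  out.attr("dim") = IntegerVector::create(Hp, Wp, C, N);
  const size_t slab = (size_t)H * W, slabp = (size_t)Hp * Wp;
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < C; ++c) {
      const double* gc = g.begin() + ((size_t)n * C + c) * slab;
      const int* mc = mask.begin() + ((size_t)n * C + c) * slabp;
      double* oc = out.begin() + ((size_t)n * C + c) * slabp;
      for (int pcx = 0; pcx < Wp; ++pcx) {
        for (int pr = 0; pr < Hp; ++pr) {
          const int m = mc[pr + (size_t)pcx * Hp];
          oc[pr + (size_t)pcx * Hp] =
            gc[(pr * window + m / window) +
               (size_t)(pcx * window + m % window) * H];
        }
      }
    }
  }
  return out;
}

// Connected-component labelling of a binary 2-d mask. connectivity is 4 or
// 8; labels are assigned in scan order (column-major, as stored) starting
// at 1. Uses an explicit stack flood fill.
// [[Rcpp::export]]
IntegerMatrix label_components(IntegerMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * H);
      while (!stack.empty()) {
        const int p = stack.back(); stack.pop_back();
        const int pr = p % H, pc = p / H;
        for (int d = 0; d < nd; ++d) {
          const int rr = pr + dr[d], cc = pc + dc[d];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            stack.push_back(rr + cc * H);
          }
        }
      }
    }
  }
  return lab;
}

// Batch normalisation over the (H, W, N) positions of each channel.
// Returns the normalised output plus the statistics actually used.
// [[Rcpp::export]]
List bn_fwd(NumericVector x, NumericVector gamma, NumericVector beta,
            NumericVector mean_in, NumericVector var_in, bool use_batch_stats) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector y((size_t)H * W * C * N);
  y.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector mu(C), va(C);
  const size_t slab = (size_t)H * W;
  const double M = (double)slab * N;
  for (int c = 0; c < C; ++c) {
    if (use_batch_stats) {
      double s = 0.0, s2 = 0.0;
      for (int n = 0; n < N; ++n) {
        const double* xc = x.begin() + ((size_t)n * C + c) * slab;
        for (size_t i = 0; i < slab; ++i) { s += xc[i]; s2 += xc[i] * xc[i]; }
      }
      mu[c] = s / M;
      va[c] = s2 / M - mu[c] * mu[c];
    } else {
      mu[c] = mean_in[c];
      va[c] = var_in[c];
    }
    const double invstd = 1.0 / std::sqrt(va[c] + 1e-5);
    const double a = gamma[c] * invstd;
    const double b0 = beta[c] - a * mu[c];
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * slab;
      double* yc = y.begin() + ((size_t)n * C + c) * slab;
      for (size_t i = 0; i < slab; ++i) yc[i] = a * xc[i] + b0;
    }
  }
  return List::create(_["y"] = y, _["mean"] = mu, _["var"] = va);
}

// [[Rcpp::export]]
List bn_bwd(NumericVector x, NumericVector g, NumericVector gamma,
            NumericVector mu, NumericVector va, bool train_stats) {
  int H, W, C, N;
  get_dims4(x, H, W, C, N);
  NumericVector gx((size_t)H * W * C * N);
  gx.attr("dim") = IntegerVector::create(H, W, C, N);
  NumericVector ggamma(C), gbeta(C);
  const size_t slab = (size_t)H * W;
  const double M = (double)slab * N;
  for (int c = 0; c < C; ++c) {
    const double invstd = 1.0 / std::sqrt(va[c] + 1e-5);
    double s1 = 0.0, s2 = 0.0;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * slab;
      const double* gc = g.begin() + ((size_t)n * C + c) * slab;
      for (size_t i = 0; i < slab; ++i) {
        const double xh = (xc[i] - mu[c]) * invstd;
        s1 += gc[i];
        s2 += gc[i] * xh;
      }
    }
    gbeta[c] = s1;
    ggamma[c] = s2;
    const double gs1 = s1 / M, gs2 = s2 / M;
    for (int n = 0; n < N; ++n) {
      const double* xc = x.begin() + ((size_t)n * C + c) * slab;
      const double* gc = g.begin() + ((size_t)n * C + c) * slab;
      double* oc = gx.begin() + ((size_t)n * C + c) * slab;
      if (train_stats) {
        for (size_t i = 0; i < slab; ++i) {
          const double xh = (xc[i] - mu[c]) * invstd;
          oc[i] = gamma[c] * invstd * (gc[i] - gs1 - xh * gs2);
        }
      } else {
        for (size_t i = 0; i < slab; ++i)
          oc[i] = gamma[c] * invstd * gc[i];
      }
    }
  }
  return List::create(_["gx"] = gx, _["ggamma"] = ggamma, _["gbeta"] = gbeta);
}

// [[Rcpp::export]]
NumericVector relu_fwd(NumericVector x) {
  NumericVector y(x.size());
  y.attr("dim") = x.attr("dim");
  for (R_xlen_t i = 0; i < x.size(); ++i) y[i] = x[i] > 0 ? x[i] : 0.0;
  return y;
}

// [[Rcpp::export]]
NumericVector relu_bwd(NumericVector g, NumericVector y) {
  NumericVector gx(g.size());
  gx.attr("dim") = g.attr("dim");
  for (R_xlen_t i = 0; i < g.size(); ++i) gx[i] = y[i] > 0 ? g[i] : 0.0;
  return gx;
}

// Two-class per-pixel softmax and its backward pass, specialised for the
// (H, W, 2, N) probability-map layout.
// [[Rcpp::export]]
NumericVector softmax2_fwd(NumericVector z) {
  int H, W, C, N;
  get_dims4(z, H, W, C, N);
  if (C != 2) stop("softmax2_fwd expects 2 channels");
  NumericVector p(z.size());
  p.attr("dim") = z.attr("dim");
  const size_t slab = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* z1 = z.begin() + ((size_t)n * 2) * slab;
    const double* z2 = z1 + slab;
    double* p1 = p.begin() + ((size_t)n * 2) * slab;
    double* p2 = p1 + slab;
    for (size_t i = 0; i < slab; ++i) {
      const double m = z1[i] > z2[i] ? z1[i] : z2[i];
      const double e1 = std::exp(z1[i] - m), e2 = std::exp(z2[i] - m);
      p1[i] = e1 / (e1 + e2);
      p2[i] = 1.0 - p1[i];
    }
  }
  return p;
}

// [[Rcpp::export]]
NumericVector softmax2_bwd(NumericVector p, NumericVector dp) {
  int H, W, C, N;
  get_dims4(p, H, W, C, N);
  if (C != 2) stop("softmax2_bwd expects 2 channels");
  NumericVector dz(p.size());
  dz.attr("dim") = p.attr("dim");
  const size_t slab = (size_t)H * W;
  for (int n = 0; n < N; ++n) {
    const double* p1 = p.begin() + ((size_t)n * 2) * slab;
    const double* p2 = p1 + slab;
    const double* d1 = dp.begin() + ((size_t)n * 2) * slab;
    const double* d2 = d1 + slab;
    double* o1 = dz.begin() + ((size_t)n * 2) * slab;
    double* o2 = o1 + slab;
    for (size_t i = 0; i < slab; ++i) {
      const double s = d1[i] * p1[i] + d2[i] * p2[i];
      o1[i] = p1[i] * (d1[i] - s);
      o2[i] = p2[i] * (d2[i] - s);
    }
  }
  return dz;
}

// Cross-entropy of a 2-class probability map against binary labels,
// averaged over pixels and batch, with probabilities clipped to
// [1e-7, 1 - 1e-7]; and its gradient with respect to the map.
// [[Rcpp::export]]
double ce_prob(NumericVector p, NumericVector y) {
  int H, W, C, N;
  get_dims4(p, H, W, C, N);
  const size_t slab = (size_t)H * W;
  double total = 0.0;
  for (int n = 0; n < N; ++n) {
    const double* p1 = p.begin() + ((size_t)n * 2) * slab;
    const double* p2 = p1 + slab;
    const double* yy = y.begin() + (size_t)n * slab;
    for (size_t i = 0; i < slab; ++i) {
      double pt = yy[i] > 0.5 ? p2[i] : p1[i];
      if (pt < 1e-7) pt = 1e-7;
      if (pt > 1.0 - 1e-7) pt = 1.0 - 1e-7;
      total -= std::log(pt);
    }
  }
  return total / (slab * (double)N);
}

// [[Rcpp::export]]
NumericVector ce_prob_grad(NumericVector p, NumericVector y, double lambda) {
  int H, W, C, N;
  get_dims4(p, H, W, C, N);
  NumericVector g(p.size());
  g.attr("dim") = p.attr("dim");
  const size_t slab = (size_t)H * W;
  const double M = slab * (double)N;
  for (int n = 0; n < N; ++n) {
    const double* p1 = p.begin() + ((size_t)n * 2) * slab;
    const double* p2 = p1 + slab;
    const double* yy = y.begin() + (size_t)n * slab;
    double* g1 = g.begin() + ((size_t)n * 2) * slab;
    double* g2 = g1 + slab;
    for (size_t i = 0; i < slab; ++i) {
      if (yy[i] > 0.5) {
        double pt = p2[i] < 1e-7 ? 1e-7 : (p2[i] > 1.0 - 1e-7 ? 1.0 - 1e-7 : p2[i]);
        g2[i] = -lambda / (M * pt);
      } else {
        double pt = p1[i] < 1e-7 ? 1e-7 : (p1[i] > 1.0 - 1e-7 ? 1.0 - 1e-7 : p1[i]);
        g1[i] = -lambda / (M * pt);
      }
    }
  }
  return g;
}
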