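// Batched forward/backward passes of the all-convolutional network.
//
// Layer activations are (H, W, B, C) column-major arrays. Each 3x3
// zero-padded convolution is an im2col patch-matrix multiplication done
// with the BLAS dgemm R links against; the patch buffers are scratch
// std::vectors reused across layers so the training loop allocates almost
// nothing per batch. The layout (columns grouped by kernel offset, then
// input channel) matches the (9*c_in) x c_out weight matrices of
// build_network().

#define USE_FC_LEN_T
#include <Rcpp.h>
#include <R_ext/BLAS.h>
#ifndef FCONE
#define FCONE
#endif
#include <vector>
#include <cstring>

namespace {

// fill the im2col patch matrix: M is (H*W*B) x (9*C)
void im2col_fill(const double *a, double *m, int H, int W, int B, int C) {
  const long long planeHW = (long long)H * W;
  const long long planeHWB = planeHW * B;
  int blk = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int c = 0; c < C; ++c) {
        double *mcol = m + ((long long)blk * C + c) * planeHWB;
        const double *ac = a + c * planeHWB;
        for (int b = 0; b < B; ++b) {
          const double *ab = ac + b * planeHW;
          double *mb = mcol + b * planeHW;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dx;
            double *mw = mb + (long long)w * H;
            if (ws < 0 || ws >= W) {
              std::memset(mw, 0, sizeof(double) * H);
              continue;
            }
            const double *aw = ab + (long long)ws * H;
            if (dy == 0) {
              std::memcpy(mw, aw, sizeof(double) * H);
            } else if (dy < 0) {
              mw[0] = 0.0;
              std::memcpy(mw + 1, aw, sizeof(double) * (H - 1));
            } else {
              std::memcpy(mw, aw + 1, sizeof(double) * (H - 1));
              mw[H - 1] = 0.0;
            }
          }
        }
      }
      ++blk;
    }
  }
}

// scatter-add the patch-matrix gradient back onto the input grid
void col2im_add(const double *m, double *a, int H, int W, int B, int C) {
  const long long planeHW = (long long)H * W;
  const long long planeHWB = planeHW * B;
  std::memset(a, 0, sizeof(double) * planeHWB * C);
  int blk = 0;
  for (int dx = -1; dx <= 1; ++dx) {
    for (int dy = -1; dy <= 1; ++dy) {
      for (int c = 0; c < C; ++c) {
        const double *mcol = m + ((long long)blk * C + c) * planeHWB;
        double *ac = a + c * planeHWB;
        for (int b = 0; b < B; ++b) {
          const double *mb = mcol + b * planeHW;
          double *ab = ac + b * planeHW;
          for (int w = 0; w < W; ++w) {
            const int ws = w + dx;
            if (ws < 0 || ws >= W) continue;
            const double *mw = mb + (long long)w * H;
            double *aw = ab + (long long)ws * H;
            const int h0 = (dy < 0) ? 1 : 0;
            const int h1 = (dy > 0) ? H - 1 : H;
            for (int h = h0; h < h1; ++h) aw[h + dy] += mw[h];
          }
        }
      }
      ++blk;
    }
  }
}

void dgemm(char ta, char tb, int m, int n, int k, const double *A, int lda,
           const double *B, int ldb, double beta, double *C, int ldc) {
  const double one = 1.0;
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &one, A, &lda, B, &ldb, &beta, C,
                  &ldc FCONE FCONE);
}

} // namespace

// Forward pass. x: (H, W, B, c_in) activations; Ws: list of (9*c_in) x
// c_out weight matrices; bs: list of bias vectors. Returns the list of
// layer inputs (index l = input of layer l) plus the final prediction,
// which is everything the backward pass needs.
// [[Rcpp::export]]
Rcpp::List conv_net_forward_cpp(Rcpp::NumericVector x, Rcpp::List Ws,
                                Rcpp::List bs, bool final_relu) {
  Rcpp::IntegerVector dims = x.attr("dim");
  const int H = dims[0], W = dims[1], B = dims[2];
  const long long rows = (long long)H * W * B;
  const int n_layers = Ws.size();

  Rcpp::List acts(n_layers + 1);
  acts[0] = x;
  std::vector<double> M;
  for (int l = 0; l < n_layers; ++l) {
    Rcpp::NumericVector a_in = acts[l];
    Rcpp::IntegerVector din = a_in.attr("dim");
    const int C_in = din[3];
    Rcpp::NumericMatrix Wl = Ws[l];
    Rcpp::NumericVector bl = bs[l];
    const int C_out = Wl.ncol();
    M.resize(rows * 9 * C_in);
    im2col_fill(a_in.begin(), M.data(), H, W, B, C_in);

    Rcpp::NumericVector z(Rcpp::no_init(rows * C_out));
    z.attr("dim") = Rcpp::IntegerVector::create(H, W, B, C_out);
    dgemm('N', 'N', (int)rows, C_out, 9 * C_in, M.data(), (int)rows,
          Wl.begin(), 9 * C_in, 0.0, z.begin(), (int)rows);
    const bool relu = (l < n_layers - 1) || final_relu;
    for (int c = 0; c < C_out; ++c) {
      double *zc = z.begin() + (long long)c * rows;
      const double bias = bl[c];
      if (relu) {
        for (long long r = 0; r < rows; ++r) {
          const double v = zc[r] + bias;
          zc[r] = v > 0 ? v : 0;
        }
      } else {
        for (long long r = 0; r < rows; ++r) zc[r] += bias;
      }
    }
    acts[l + 1] = z;
  }
  return acts;
}

// Backward pass from d(loss)/d(prediction); returns per-layer weight and
// bias gradients. acts is the list returned by the forward pass.
// [[Rcpp::export]]
Rcpp::List conv_net_backward_cpp(Rcpp::List acts, Rcpp::List Ws,
                                 Rcpp::NumericVector dpred, bool final_relu) {
  const int n_layers = Ws.size();
  Rcpp::NumericVector a0 = acts[0];
  Rcpp::IntegerVector dims = a0.attr("dim");
  const int H = dims[0], W = dims[1], B = dims[2];
  const long long rows = (long long)H * W * B;

  Rcpp::List dWs(n_layers), dbs(n_layers);
  std::vector<double> M, dA(dpred.begin(), dpred.end()), dM, dA_prev;

  for (int l = n_layers - 1; l >= 0; --l) {
    Rcpp::NumericMatrix Wl = Ws[l];
    const int C_in9 = Wl.nrow();
    const int C_in = C_in9 / 9;
    const int C_out = Wl.ncol();
    Rcpp::NumericVector a_out = acts[l + 1];
    Rcpp::NumericVector a_in = acts[l];

    // dZ = dA, masked by the activation where a ReLU was applied
    const bool relu = (l < n_layers - 1) || final_relu;
    if (relu) {
      const double *ao = a_out.begin();
      for (long long i = 0; i < rows * C_out; ++i) {
        if (ao[i] <= 0) dA[i] = 0.0;
      }
    }

    M.resize(rows * C_in9);
    im2col_fill(a_in.begin(), M.data(), H, W, B, C_in);

    Rcpp::NumericMatrix dW(C_in9, C_out);
    dgemm('T', 'N', C_in9, C_out, (int)rows, M.data(), (int)rows,
          dA.data(), (int)rows, 0.0, dW.begin(), C_in9);
    dWs[l] = dW;

    Rcpp::NumericVector db(C_out);
    for (int c = 0; c < C_out; ++c) {
      const double *dc = dA.data() + (long long)c * rows;
      double s = 0;
      for (long long r = 0; r < rows; ++r) s += dc[r];
      db[c] = s;
    }
    dbs[l] = db;

    if (l > 0) {
      dM.resize(rows * C_in9);
      dgemm('N', 'T', (int)rows, C_in9, C_out, dA.data(), (int)rows,
            Wl.begin(), C_in9, 0.0, dM.data(), (int)rows);
      dA_prev.resize(rows * C_in);
      col2im_add(dM.data(), dA_prev.data(), H, W, B, C_in);
      dA.swap(dA_prev);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dW") = dWs,
                            Rcpp::Named("db") = dbs);
}
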