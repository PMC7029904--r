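// Bidirectional recurrent network core.
//
// Three two-layer perceptrons: a forward update N^F mapping
// (x_j, h_{j-1}^F) -> h_j^F, a backward update N^B mapping
// (x_j, h_{j+1}^B) -> h_j^B, and an output net N^O mapping
// (x_j, h_j^F, h_j^B) -> o_j in (0,1). Hidden activations are tanh, the
// output is a sigmoid. Boundary states h_0^F = h_{N+1}^B = 0.
//
// Parameters live in one flat vector (column-major blocks, in order):
//   W1F [M x (I+H)], b1F [M], W2F [H x M], b2F [H],
//   W1B [M x (I+H)], b1B [M], W2B [H x M], b2B [H],
//   W1O [M x (I+2H)], b1O [M], W2O [1 x M], b2O [1]
// where I = input width, H = hidden-state size, M = perceptron hidden size.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Dims {
  int I, H, M;
  int w1f, b1f, w2f, b2f, w1b, b1b, w2b, b2b, w1o, b1o, w2o, b2o, total;
  Dims(int I_, int H_, int M_) : I(I_), H(H_), M(M_) {
    int p = 0;
    w1f = p; p += M * (I + H);
    b1f = p; p += M;
    w2f = p; p += H * M;
    b2f = p; p += H;
    w1b = p; p += M * (I + H);
    b1b = p; p += M;
    w2b = p; p += H * M;
    b2b = p; p += H;
    w1o = p; p += M * (I + 2 * H);
    b1o = p; p += M;
    w2o = p; p += M;
    b2o = p; p += 1;
    total = p;
  }
};

inline double sigmoid(double x) { return 1.0 / (1.0 + std::exp(-x)); }

// y[0..M) = tanh(W (M x K, col-major) * x + b)
inline void mlp_layer(const double* W, const double* b, const double* x,
                      int M, int K, double* y) {
  for (int m = 0; m < M; ++m) y[m] = b[m];
  for (int k = 0; k < K; ++k) {
    const double xk = x[k];
    const double* col = W + (size_t)k * M;
    for (int m = 0; m < M; ++m) y[m] += col[m] * xk;
  }
  for (int m = 0; m < M; ++m) y[m] = std::tanh(y[m]);
}

struct Workspace {
  int N;
  std::vector<double> hF, hB;      // (N+2) x H, index shifted by 1
  std::vector<double> zF, zB, zO;  // N x M
  std::vector<double> o;           // N
};

void run_forward(const double* th, const Dims& d, const NumericMatrix& X,
                 Workspace& ws) {
  const int N = X.nrow(), I = d.I, H = d.H, M = d.M;
  ws.N = N;
  ws.hF.assign((size_t)(N + 2) * H, 0.0);
  ws.hB.assign((size_t)(N + 2) * H, 0.0);
  ws.zF.assign((size_t)N * M, 0.0);
  ws.zB.assign((size_t)N * M, 0.0);
  ws.zO.assign((size_t)N * M, 0.0);
  ws.o.assign(N, 0.0);
  std::vector<double> in(I + 2 * H), u(std::max(H, M));

  // forward chain, j = 1..N (hF row j stored at offset j*H; row 0 is zero)
  for (int j = 1; j <= N; ++j) {
    for (int i = 0; i < I; ++i) in[i] = X(j - 1, i);
    for (int h = 0; h < H; ++h) in[I + h] = ws.hF[(size_t)(j - 1) * H + h];
    mlp_layer(th + d.w1f, th + d.b1f, in.data(), M, I + H,
              &ws.zF[(size_t)(j - 1) * M]);
    mlp_layer(th + d.w2f, th + d.b2f, &ws.zF[(size_t)(j - 1) * M], H, M, u.data());
    for (int h = 0; h < H; ++h) ws.hF[(size_t)j * H + h] = u[h];
  }
  // backward chain, j = N..1 (hB row N+1 is zero)
  for (int j = N; j >= 1; --j) {
    for (int i = 0; i < I; ++i) in[i] = X(j - 1, i);
    for (int h = 0; h < H; ++h) in[I + h] = ws.hB[(size_t)(j + 1) * H + h];
    mlp_layer(th + d.w1b, th + d.b1b, in.data(), M, I + H,
              &ws.zB[(size_t)(j - 1) * M]);
    mlp_layer(th + d.w2b, th + d.b2b, &ws.zB[(size_t)(j - 1) * M], H, M, u.data());
    for (int h = 0; h < H; ++h) ws.hB[(size_t)j * H + h] = u[h];
  }
  // output net per position
  for (int j = 1; j <= N; ++j) {
    for (int i = 0; i < I; ++i) in[i] = X(j - 1, i);
    for (int h = 0; h < H; ++h) in[I + h] = ws.hF[(size_t)j * H + h];
    for (int h = 0; h < H; ++h) in[I + H + h] = ws.hB[(size_t)j * H + h];
    double* zo = &ws.zO[(size_t)(j - 1) * M];
    mlp_layer(th + d.w1o, th + d.b1o, in.data(), M, I + 2 * H, zo);
    double s = th[d.b2o];
    for (int m = 0; m < M; ++m) s += th[d.w2o + m] * zo[m];
    ws.o[j - 1] = sigmoid(s);
  }
}

} // namespace

// [[Rcpp::export(name = ".brnn_npar_cpp")]]
int brnn_npar_cpp(int I, int H, int M) { return Dims(I, H, M).total; }

// [[Rcpp::export(name = ".brnn_forward_cpp")]]
NumericVector brnn_forward_cpp(NumericVector params, int I, int H, int M,
                               NumericMatrix X) {
  Dims d(I, H, M);
  if (params.size() != d.total) stop("parameter vector has wrong length");
  if (X.ncol() != I) stop("feature width does not match model input_dim");
  Workspace ws;
  run_forward(params.begin(), d, X, ws);
  return NumericVector(ws.o.begin(), ws.o.end());
}

// [[Rcpp::export(name = ".brnn_grad_cpp")]]
List brnn_grad_cpp(NumericVector params, int I, int H, int M,
                   NumericMatrix X, NumericVector y) {
  Dims d(I, H, M);
  if (params.size() != d.total) stop("parameter vector has wrong length");
  if (X.ncol() != I) stop("feature width does not match model input_dim");
  const int N = X.nrow();
  if (y.size() != N) stop("label length does not match input");
  const double* th = params.begin();
  Workspace ws;
  run_forward(th, d, X, ws);

  NumericVector grad(d.total);
  double* g = grad.begin();
  const double eps = 1e-12;
  double loss = 0.0;
  for (int j = 0; j < N; ++j) {
    double o = std::min(std::max(ws.o[j], eps), 1.0 - eps);
    loss += -(y[j] * std::log(o) + (1.0 - y[j]) * std::log(1.0 - o));
  }
  loss /= N;

  // accumulated dL/dh for the two chains coming from the output net
  std::vector<double> dhF_out((size_t)(N + 2) * d.H, 0.0);
  std::vector<double> dhB_out((size_t)(N + 2) * d.H, 0.0);
  std::vector<double> in(d.I + 2 * d.H), da(d.M), du(d.H);

  // output net backprop (positions independent)
  for (int j = 1; j <= N; ++j) {
    const double ds = (ws.o[j - 1] - y[j - 1]) / N;  // dL/ds_j for BCE+sigmoid
    const double* zo = &ws.zO[(size_t)(j - 1) * d.M];
    for (int i = 0; i < d.I; ++i) in[i] = X(j - 1, i);
    for (int h = 0; h < d.H; ++h) in[d.I + h] = ws.hF[(size_t)j * d.H + h];
    for (int h = 0; h < d.H; ++h) in[d.I + d.H + h] = ws.hB[(size_t)j * d.H + h];
    for (int m = 0; m < d.M; ++m) {
      g[d.w2o + m] += ds * zo[m];
      da[m] = ds * th[d.w2o + m] * (1.0 - zo[m] * zo[m]);
    }
    g[d.b2o] += ds;
    const int K = d.I + 2 * d.H;
    for (int k = 0; k < K; ++k) {
      double* col = g + d.w1o + (size_t)k * d.M;
      const double xk = in[k];
      for (int m = 0; m < d.M; ++m) col[m] += da[m] * xk;
    }
    for (int m = 0; m < d.M; ++m) g[d.b1o + m] += da[m];
    // route into the hidden-state sensitivities
    for (int h = 0; h < d.H; ++h) {
      double sF = 0.0, sB = 0.0;
      for (int m = 0; m < d.M; ++m) {
        sF += th[d.w1o + (size_t)(d.I + h) * d.M + m] * da[m];
        sB += th[d.w1o + (size_t)(d.I + d.H + h) * d.M + m] * da[m];
      }
      dhF_out[(size_t)j * d.H + h] += sF;
      dhB_out[(size_t)j * d.H + h] += sB;
    }
  }

  // backprop through the forward chain, j = N..1
  std::vector<double> carry(d.H, 0.0);
  for (int j = N; j >= 1; --j) {
    const double* zf = &ws.zF[(size_t)(j - 1) * d.M];
    for (int h = 0; h < d.H; ++h) {
      const double hv = ws.hF[(size_t)j * d.H + h];
      du[h] = (dhF_out[(size_t)j * d.H + h] + carry[h]) * (1.0 - hv * hv);
    }
    for (int m = 0; m < d.M; ++m) {
      double s = 0.0;
      for (int h = 0; h < d.H; ++h) {
        g[d.w2f + (size_t)m * d.H + h] += du[h] * zf[m];
        s += th[d.w2f + (size_t)m * d.H + h] * du[h];
      }
      da[m] = s * (1.0 - zf[m] * zf[m]);
    }
    for (int h = 0; h < d.H; ++h) g[d.b2f + h] += du[h];
    for (int i = 0; i < d.I; ++i) in[i] = X(j - 1, i);
    for (int h = 0; h < d.H; ++h) in[d.I + h] = ws.hF[(size_t)(j - 1) * d.H + h];
    const int K = d.I + d.H;
    for (int k = 0; k < K; ++k) {
      double* col = g + d.w1f + (size_t)k * d.M;
      const double xk = in[k];
      for (int m = 0; m < d.M; ++m) col[m] += da[m] * xk;
    }
    for (int m = 0; m < d.M; ++m) g[d.b1f + m] += da[m];
    for (int h = 0; h < d.H; ++h) {
      double s = 0.0;
      for (int m = 0; m < d.M; ++m)
        s += th[d.w1f + (size_t)(d.I + h) * d.M + m] * da[m];
      carry[h] = s;
    }
  }

  // backprop through the backward chain, j = 1..N
  std::fill(carry.begin(), carry.end(), 0.0);
  for (int j = 1; j <= N; ++j) {
    const double* zb = &ws.zB[(size_t)(j - 1) * d.M];
    for (int h = 0; h < d.H; ++h) {
      const double hv = ws.hB[(size_t)j * d.H + h];
      du[h] = (dhB_out[(size_t)j * d.H + h] + carry[h]) * (1.0 - hv * hv);
    }
    for (int m = 0; m < d.M; ++m) {
      double s = 0.0;
      for (int h = 0; h < d.H; ++h) {
        g[d.w2b + (size_t)m * d.H + h] += du[h] * zb[m];
        s += th[d.w2b + (size_t)m * d.H + h] * du[h];
      }
      da[m] = s * (1.0 - zb[m] * zb[m]);
    }
    for (int h = 0; h < d.H; ++h) g[d.b2b + h] += du[h];
    for (int i = 0; i < d.I; ++i) in[i] = X(j - 1, i);
    for (int h = 0; h < d.H; ++h) in[d.I + h] = ws.hB[(size_t)(j + 1) * d.H + h];
    const int K = d.I + d.H;
    for (int k = 0; k < K; ++k) {
      double* col = g + d.w1b + (size_t)k * d.M;
      const double xk = in[k];
      for (int m = 0; m < d.M; ++m) col[m] += da[m] * xk;
    }
    for (int m = 0; m < d.M; ++m) g[d.b1b + m] += da[m];
    for (int h = 0; h < d.H; ++h) {
      double s = 0.0;
      for (int m = 0; m < d.M; ++m)
        s += th[d.w1b + (size_t)(d.I + h) * d.M + m] * da[m];
      carry[h] = s;
    }
  }

  return List::create(_["loss"] = loss, _["grad"] = grad,
                      _["scores"] = NumericVector(ws.o.begin(), ws.o.end()));
}
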