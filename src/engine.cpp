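// Compact sequence-model engine: 1D convolution, bidirectional LSTM/GRU,
// average pooling, dropout, dense layers with softmax output; trained by
// backpropagation(-through-time) with Adam on categorical cross-entropy.
//
// Activation layout before the flatten stage is a cube (batch x channels x
// time); slice t is the (batch x channels) matrix at time step t.
//
// Performance notes (single-core budget): the engine is templated on the
// element type -- training and prediction run in float32, while the
// gradient entry point used by the finite-difference tests runs in
// float64. Recurrent input projections and weight gradients are computed
// chunk-wise over blocks of time steps so the projection buffers stay
// cache-resident; only the recurrent hidden-state product remains a
// per-step GEMM. Convolutions use im2col; gate nonlinearities run as raw
// loops over contiguous slice memory with a polynomial exp
// (relative error < 1e-8).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using namespace arma;

struct LayerSpec {
  std::string type;
  int in_ch = 0, out_ch = 0, kernel = 0, units = 0, pool = 2;
  int in_dim = 0, out_dim = 0;
  double rate = 0.0;
};

static std::vector<LayerSpec> parse_layers(const List& layers) {
  std::vector<LayerSpec> out;
  for (int i = 0; i < layers.size(); ++i) {
    List l = layers[i];
    LayerSpec s;
    s.type = as<std::string>(l["type"]);
    if (s.type == "conv") {
      s.in_ch = as<int>(l["in_ch"]);
      s.out_ch = as<int>(l["filters"]);
      s.kernel = as<int>(l["kernel"]);
    } else if (s.type == "bilstm" || s.type == "bigru") {
      s.in_ch = as<int>(l["in_ch"]);
      s.units = as<int>(l["units"]);
      s.out_ch = 2 * s.units;
    } else if (s.type == "avgpool") {
      s.pool = as<int>(l["pool"]);
    } else if (s.type == "dropout") {
      s.rate = as<double>(l["rate"]);
    } else if (s.type == "dense" || s.type == "output") {
      s.in_dim = as<int>(l["in_dim"]);
      s.out_dim = as<int>(l["units"]);
    } else if (s.type != "flatten") {
      stop("unknown layer type '%s'", s.type);
    }
    out.push_back(s);
  }
  return out;
}

// ---------------------------------------------------------------------------
// fast elementwise nonlinearities (exp via 2^k * poly(r), |rel err| < 1e-8)

static inline double fexp(double x) {
  if (x > 40.0) x = 40.0;
  if (x < -40.0) x = -40.0;
  const double LOG2E = 1.4426950408889634074;
  const double LN2HI = 6.93147180369123816490e-01;
  const double LN2LO = 1.90821492927058770002e-10;
  double k = std::floor(x * LOG2E + 0.5);
  double r = (x - k * LN2HI) - k * LN2LO;
  double p = 1.0 + r * (1.0 + r * (1.0 / 2 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r * (1.0 / 5040 +
             r * (1.0 / 40320))))))));
  union { double d; int64_t i; } u;
  u.i = (static_cast<int64_t>(k) + 1023) << 52;
  return p * u.d;
}

// float32 variant (degree-6 polynomial, relative error < 2e-7)
static inline float fexpf32(float x) {
  if (x > 30.0f) x = 30.0f;
  if (x < -30.0f) x = -30.0f;
  const float LOG2E = 1.4426950408889634f;
  const float LN2 = 0.6931471805599453f;
  float k = std::floor(x * LOG2E + 0.5f);
  float r = x - k * LN2;
  float p = 1.0f + r * (1.0f + r * (0.5f + r * (0.16666667f +
            r * (0.041666667f + r * (0.0083333333f + r * 0.0013888889f)))));
  union { float f; int32_t i; } u;
  u.i = (static_cast<int32_t>(k) + 127) << 23;
  return p * u.f;
}

template <typename eT> static inline eT e_sigm(eT x);
template <typename eT> static inline eT e_tanh(eT x);
template <> inline double e_sigm(double x) { return 1.0 / (1.0 + fexp(-x)); }
template <> inline double e_tanh(double x) {
  return 2.0 / (1.0 + fexp(-2.0 * x)) - 1.0;
}
template <> inline float e_sigm(float x) {
  return 1.0f / (1.0f + fexpf32(-x));
}
template <> inline float e_tanh(float x) {
  return 2.0f / (1.0f + fexpf32(-2.0f * x)) - 1.0f;
}

// time-chunk length keeping per-chunk gate buffers around a few MB
static inline uword chunk_len(uword B, uword gate_cols, uword T) {
  uword ch = (4u * 1024u * 1024u) / (std::max<uword>(1, gate_cols * B * 4));
  if (ch < 16) ch = 16;
  if (ch > T) ch = T;
  return ch;
}

// ---------------------------------------------------------------------------
// initialization (always double; converted to the compute type on entry)

typedef std::vector<arma::mat> ParamSetD;
typedef std::vector<ParamSetD> ParamsD;

static void glorot_fill(mat& W, std::mt19937& rng) {
  double limit = std::sqrt(6.0 / (W.n_rows + W.n_cols));
  std::uniform_real_distribution<double> U(-limit, limit);
  for (uword j = 0; j < W.n_cols; ++j)
    for (uword i = 0; i < W.n_rows; ++i)
      W(i, j) = U(rng);
}

static ParamsD init_params(const std::vector<LayerSpec>& specs, int seed) {
  std::mt19937 rng(static_cast<unsigned>(seed));
  ParamsD params;
  for (const LayerSpec& s : specs) {
    ParamSetD p;
    if (s.type == "conv") {
      mat W(s.in_ch * s.kernel, s.out_ch);
      glorot_fill(W, rng);
      p.push_back(W);
      p.push_back(mat(1, s.out_ch, fill::zeros));
    } else if (s.type == "bilstm") {
      for (int dir = 0; dir < 2; ++dir) {
        mat Wx(s.in_ch, 4 * s.units), Wh(s.units, 4 * s.units);
        glorot_fill(Wx, rng);
        glorot_fill(Wh, rng);
        mat b(1, 4 * s.units, fill::zeros);
        b.cols(s.units, 2 * s.units - 1).fill(1.0);  // forget-gate bias
        p.push_back(Wx); p.push_back(Wh); p.push_back(b);
      }
    } else if (s.type == "bigru") {
      for (int dir = 0; dir < 2; ++dir) {
        mat Wx(s.in_ch, 3 * s.units), Wh(s.units, 3 * s.units);
        glorot_fill(Wx, rng);
        glorot_fill(Wh, rng);
        p.push_back(Wx); p.push_back(Wh);
        p.push_back(mat(1, 3 * s.units, fill::zeros));
      }
    } else if (s.type == "dense" || s.type == "output") {
      mat W(s.in_dim, s.out_dim);
      glorot_fill(W, rng);
      p.push_back(W);
      p.push_back(mat(1, s.out_dim, fill::zeros));
    }
    params.push_back(p);
  }
  return params;
}

// ---------------------------------------------------------------------------
// templated core

template <typename eT>
struct Engine {
  typedef Mat<eT> TMat;
  typedef Cube<eT> TCube;
  typedef std::vector<TMat> ParamSet;
  typedef std::vector<ParamSet> Params;

  static TMat reluM(const TMat& x) {
    TMat y = x;
    y.elem(find(y < eT(0))).zeros();
    return y;
  }

  static TMat relu_maskM(const TMat& g, const TMat& out) {
    TMat y = g;
    y.elem(find(out <= eT(0))).zeros();
    return y;
  }

  // ---- conv (im2col) ------------------------------------------------------

  static void im2col(const TCube& A, int kernel, TMat& Xcol) {
    const uword B = A.n_rows, C = A.n_cols, To = A.n_slices - kernel + 1;
    Xcol.set_size(B * To, C * kernel);
    for (uword t = 0; t < To; ++t)
      for (int j = 0; j < kernel; ++j)
        Xcol.submat(t * B, j * C, (t + 1) * B - 1, (j + 1) * C - 1) =
          A.slice(t + j);
  }

  static void conv_forward(const TMat& Xcol, const TMat& W, const TMat& b,
                           uword B, TCube& Out) {
    const uword To = Xcol.n_rows / B, f = W.n_cols;
    TMat Z = Xcol * W;
    Z.each_row() += b.row(0);
    Z.elem(find(Z < eT(0))).zeros();
    Out.set_size(B, f, To);
    for (uword t = 0; t < To; ++t)
      Out.slice(t) = Z.rows(t * B, (t + 1) * B - 1);
  }

  static void conv_backward(const TMat& Xcol, const TMat& W, int kernel,
                            const TCube& Out, const TCube& dOut,
                            uword inT, TCube& dA, TMat& dW, TMat& db) {
    const uword B = Out.n_rows, C = W.n_rows / kernel, To = Out.n_slices;
    TMat dpre(B * To, W.n_cols);
    for (uword t = 0; t < To; ++t)
      dpre.rows(t * B, (t + 1) * B - 1) =
        relu_maskM(dOut.slice(t), Out.slice(t));
    dW = Xcol.t() * dpre;
    db = sum(dpre, 0);
    TMat dXcol = dpre * W.t();
    dA.zeros(B, C, inT);
    for (uword t = 0; t < To; ++t)
      for (int j = 0; j < kernel; ++j)
        dA.slice(t + j) +=
          dXcol.submat(t * B, j * C, (t + 1) * B - 1, (j + 1) * C - 1);
  }

  // ---- LSTM (one direction) ----------------------------------------------
  // Xflat: (B*T x C) inputs, row block t*B..t*B+B-1 = time step t.
  // Gate cache G stores the activated gates [i f g o] per slice.

  static void lstm_forward(const TMat& Xflat, const TMat& Wx, const TMat& Wh,
                           const TMat& b, bool reverse, uword B, uword T,
                           TCube& H, TCube& Cc, TCube& G) {
    const uword u = Wh.n_rows, n = B * u;
    H.set_size(B, u, T); Cc.set_size(B, u, T); G.set_size(B, 4 * u, T);
    const uword CH = chunk_len(B, 4 * u, T);
    TMat Xp, gbuf(B, 4 * u);
    for (uword s0 = 0; s0 < T; s0 += CH) {
      const uword s1 = std::min(T, s0 + CH);
      // forward-order steps s0..s1-1 occupy a contiguous time range
      const uword tlo = reverse ? T - s1 : s0;
      const uword thi = reverse ? T - 1 - s0 : s1 - 1;
      Xp = Xflat.rows(tlo * B, (thi + 1) * B - 1) * Wx;
      Xp.each_row() += b.row(0);
      for (uword s = s0; s < s1; ++s) {
        const uword t = reverse ? T - 1 - s : s;
        const uword off = (t - tlo) * B;
        gbuf = Xp.rows(off, off + B - 1);
        if (s > 0) gbuf += H.slice(reverse ? t + 1 : t - 1) * Wh;
        const eT* g = gbuf.memptr();
        eT* Gt = G.slice_memptr(t);
        eT* Ct = Cc.slice_memptr(t);
        eT* Ht = H.slice_memptr(t);
        const eT* Cp = (s > 0) ? Cc.slice_memptr(reverse ? t + 1 : t - 1)
                               : nullptr;
        for (uword i = 0; i < n; ++i) {
          const eT I = e_sigm<eT>(g[i]);
          const eT F = e_sigm<eT>(g[n + i]);
          const eT Gg = e_tanh<eT>(g[2 * n + i]);
          const eT O = e_sigm<eT>(g[3 * n + i]);
          const eT c = F * (Cp ? Cp[i] : eT(0)) + I * Gg;
          Gt[i] = I; Gt[n + i] = F; Gt[2 * n + i] = Gg; Gt[3 * n + i] = O;
          Ct[i] = c;
          Ht[i] = O * e_tanh<eT>(c);
        }
      }
    }
  }

  static void lstm_backward(const TMat& Xflat, const TMat& Wx, const TMat& Wh,
                            const TCube& H, const TCube& Cc, const TCube& G,
                            const TCube& dOut, uword col_off, bool reverse,
                            TMat& dXflat, TMat& dWx, TMat& dWh, TMat& db) {
    const uword B = H.n_rows, T = H.n_slices, u = Wh.n_rows, n = B * u;
    const uword CH = chunk_len(B, 4 * u, T);
    TMat dh(B, u, fill::zeros), dc(B, u, fill::zeros);
    TMat dgbuf(B, 4 * u), dG_chunk, Hprev_chunk;
    // iterate chunks in reverse of forward order
    for (uword s1 = T; s1 > 0;) {
      const uword s0 = (s1 > CH) ? s1 - CH : 0;
      const uword tlo = reverse ? T - s1 : s0;
      const uword thi = reverse ? T - 1 - s0 : s1 - 1;
      const uword csteps = s1 - s0;
      dG_chunk.set_size(B * csteps, 4 * u);
      Hprev_chunk.zeros(B * csteps, u);
      for (uword s = s1; s-- > s0;) {
        const uword t = reverse ? T - 1 - s : s;
        const uword off = (t - tlo) * B;
        dh += dOut.slice(t).cols(col_off, col_off + u - 1);
        const eT* Gt = G.slice_memptr(t);
        const eT* Ct = Cc.slice_memptr(t);
        const eT* Cp = (s > 0) ? Cc.slice_memptr(reverse ? t + 1 : t - 1)
                               : nullptr;
        eT* dhp = dh.memptr();
        eT* dcp = dc.memptr();
        eT* dg = dgbuf.memptr();
        for (uword i = 0; i < n; ++i) {
          const eT I = Gt[i], F = Gt[n + i], Gg = Gt[2 * n + i],
                   O = Gt[3 * n + i];
          const eT tc = e_tanh<eT>(Ct[i]);
          const eT dci = dcp[i] + dhp[i] * O * (eT(1) - tc * tc);
          dg[i] = dci * Gg * I * (eT(1) - I);
          dg[n + i] = dci * (Cp ? Cp[i] : eT(0)) * F * (eT(1) - F);
          dg[2 * n + i] = dci * I * (eT(1) - Gg * Gg);
          dg[3 * n + i] = dhp[i] * tc * O * (eT(1) - O);
          dcp[i] = dci * F;
        }
        dG_chunk.rows(off, off + B - 1) = dgbuf;
        if (s > 0)
          Hprev_chunk.rows(off, off + B - 1) =
            H.slice(reverse ? t + 1 : t - 1);
        dh = dgbuf * Wh.t();
      }
      dWx += Xflat.rows(tlo * B, (thi + 1) * B - 1).t() * dG_chunk;
      dWh += Hprev_chunk.t() * dG_chunk;
      db += sum(dG_chunk, 0);
      dXflat.rows(tlo * B, (thi + 1) * B - 1) += dG_chunk * Wx.t();
      s1 = s0;
      if (s1 == 0) break;
    }
  }

  // ---- GRU (one direction) -----------------------------------------------
  // update z, reset r, candidate n: h' = z*h + (1-z)*n with
  // n = tanh(x Wn + (r*h) Un + bn). Gate cache G stores activated [z r n];
  // RH caches r_t * h_{t-1} for the candidate weight gradient.

  static void gru_forward(const TMat& Xflat, const TMat& Wx, const TMat& Wh,
                          const TMat& b, bool reverse, uword B, uword T,
                          TCube& H, TCube& G, TCube& RH) {
    const uword u = Wh.n_rows, n = B * u;
    H.set_size(B, u, T); G.set_size(B, 3 * u, T); RH.set_size(B, u, T);
    const uword CH = chunk_len(B, 3 * u, T);
    TMat Xp, zrbuf(B, 2 * u), nbuf(B, u);
    for (uword s0 = 0; s0 < T; s0 += CH) {
      const uword s1 = std::min(T, s0 + CH);
      const uword tlo = reverse ? T - s1 : s0;
      const uword thi = reverse ? T - 1 - s0 : s1 - 1;
      Xp = Xflat.rows(tlo * B, (thi + 1) * B - 1) * Wx;
      Xp.each_row() += b.row(0);
      for (uword s = s0; s < s1; ++s) {
        const uword t = reverse ? T - 1 - s : s;
        const uword off = (t - tlo) * B;
        const TMat* hp = (s > 0) ? &H.slice(reverse ? t + 1 : t - 1) : nullptr;
        zrbuf = Xp.submat(off, 0, off + B - 1, 2 * u - 1);
        if (hp) zrbuf += (*hp) * Wh.cols(0, 2 * u - 1);
        const eT* zr = zrbuf.memptr();
        eT* Gt = G.slice_memptr(t);
        const eT* hprev = hp ? hp->memptr() : nullptr;
        eT* rhp = RH.slice_memptr(t);
        for (uword i = 0; i < n; ++i) {
          const eT z = e_sigm<eT>(zr[i]);
          const eT r = e_sigm<eT>(zr[n + i]);
          Gt[i] = z; Gt[n + i] = r;
          rhp[i] = r * (hprev ? hprev[i] : eT(0));
        }
        nbuf = Xp.submat(off, 2 * u, off + B - 1, 3 * u - 1);
        if (hp) nbuf += RH.slice(t) * Wh.cols(2 * u, 3 * u - 1);
        const eT* np = nbuf.memptr();
        eT* Ht = H.slice_memptr(t);
        for (uword i = 0; i < n; ++i) {
          const eT nn = e_tanh<eT>(np[i]);
          const eT z = Gt[i];
          Gt[2 * n + i] = nn;
          Ht[i] = z * (hprev ? hprev[i] : eT(0)) + (eT(1) - z) * nn;
        }
      }
    }
  }

  static void gru_backward(const TMat& Xflat, const TMat& Wx, const TMat& Wh,
                           const TCube& H, const TCube& G, const TCube& RH,
                           const TCube& dOut, uword col_off, bool reverse,
                           TMat& dXflat, TMat& dWx, TMat& dWh, TMat& db) {
    const uword B = H.n_rows, T = H.n_slices, u = Wh.n_rows, n = B * u;
    const uword CH = chunk_len(B, 3 * u, T);
    TMat dh(B, u, fill::zeros);
    TMat dgbuf(B, 3 * u), d_rh(B, u), dn_pre(B, u);
    TMat dG_chunk, Hprev_chunk, RH_chunk;
    for (uword s1 = T; s1 > 0;) {
      const uword s0 = (s1 > CH) ? s1 - CH : 0;
      const uword tlo = reverse ? T - s1 : s0;
      const uword thi = reverse ? T - 1 - s0 : s1 - 1;
      const uword csteps = s1 - s0;
      dG_chunk.set_size(B * csteps, 3 * u);
      Hprev_chunk.zeros(B * csteps, u);
      RH_chunk.set_size(B * csteps, u);
      for (uword s = s1; s-- > s0;) {
        const uword t = reverse ? T - 1 - s : s;
        const uword off = (t - tlo) * B;
        dh += dOut.slice(t).cols(col_off, col_off + u - 1);
        const eT* Gt = G.slice_memptr(t);
        const eT* hprev = (s > 0)
          ? H.slice_memptr(reverse ? t + 1 : t - 1) : nullptr;
        eT* dhp = dh.memptr();
        eT* dg = dgbuf.memptr();
        eT* dnp = dn_pre.memptr();
        for (uword i = 0; i < n; ++i) {
          const eT z = Gt[i], nn = Gt[2 * n + i];
          dnp[i] = dhp[i] * (eT(1) - z) * (eT(1) - nn * nn);
        }
        d_rh = dn_pre * Wh.cols(2 * u, 3 * u - 1).t();
        const eT* drh = d_rh.memptr();
        for (uword i = 0; i < n; ++i) {
          const eT z = Gt[i], r = Gt[n + i], nn = Gt[2 * n + i];
          const eT hp = hprev ? hprev[i] : eT(0);
          const eT dz = dhp[i] * (hp - nn);
          const eT dr = drh[i] * hp;
          dg[i] = dz * z * (eT(1) - z);
          dg[n + i] = dr * r * (eT(1) - r);
          dg[2 * n + i] = dnp[i];
          dhp[i] = dhp[i] * z + drh[i] * r;  // direct + reset-gate paths
        }
        dG_chunk.rows(off, off + B - 1) = dgbuf;
        if (s > 0)
          Hprev_chunk.rows(off, off + B - 1) =
            H.slice(reverse ? t + 1 : t - 1);
        RH_chunk.rows(off, off + B - 1) = RH.slice(t);
        // recurrent path of the z/r gates
        dh += dgbuf.cols(0, 2 * u - 1) * Wh.cols(0, 2 * u - 1).t();
      }
      dWx += Xflat.rows(tlo * B, (thi + 1) * B - 1).t() * dG_chunk;
      db += sum(dG_chunk, 0);
      dXflat.rows(tlo * B, (thi + 1) * B - 1) += dG_chunk * Wx.t();
      dWh.cols(0, 2 * u - 1) += Hprev_chunk.t() * dG_chunk.cols(0, 2 * u - 1);
      dWh.cols(2 * u, 3 * u - 1) +=
        RH_chunk.t() * dG_chunk.cols(2 * u, 3 * u - 1);
      s1 = s0;
      if (s1 == 0) break;
    }
  }

  // ---- whole network ------------------------------------------------------

  struct LayerCache {
    TMat Xflat;                 // rnn input (time-flat) / conv im2col
    TCube out;                  // conv output (for relu mask)
    TCube Hf, Hb, Cf, Cb, Gf, Gb, RHf, RHb;
    TCube mask;                 // dropout
    TMat Min, Mout;             // dense input / output
    uword inB = 0, inC = 0, inT = 0;
  };

  static TMat softmax_rows(TMat z) {
    z.each_col() -= max(z, 1);
    z = exp(z);
    z.each_col() /= sum(z, 1);
    return z;
  }

  static void cube_to_flat(const TCube& A, TMat& F) {
    const uword B = A.n_rows, C = A.n_cols, T = A.n_slices;
    F.set_size(B * T, C);
    for (uword t = 0; t < T; ++t) F.rows(t * B, (t + 1) * B - 1) = A.slice(t);
  }

  static void bidir_concat(const TCube& Hf, const TCube& Hb, TCube& out) {
    const uword u = Hf.n_cols;
    out.set_size(Hf.n_rows, 2 * u, Hf.n_slices);
    for (uword t = 0; t < Hf.n_slices; ++t) {
      out.slice(t).cols(0, u - 1) = Hf.slice(t);
      out.slice(t).cols(u, 2 * u - 1) = Hb.slice(t);
    }
  }

  // forward pass; fills caches when train = true (dropout active then too)
  static TMat net_forward(const std::vector<LayerSpec>& specs, const Params& P,
                          const TMat& X, bool train, std::mt19937& rng,
                          std::vector<LayerCache>& K) {
    const int L = specs.size();
    K.assign(L, LayerCache());
    TCube A(X.n_rows, 1, X.n_cols);
    for (uword t = 0; t < X.n_cols; ++t) A.slice(t) = X.col(t);
    TMat M;
    bool flat = false;

    for (int l = 0; l < L; ++l) {
      const LayerSpec& s = specs[l];
      LayerCache& k = K[l];
      if (!flat) { k.inB = A.n_rows; k.inC = A.n_cols; k.inT = A.n_slices; }
      if (s.type == "conv") {
        if ((int)A.n_slices < s.kernel)
          stop("conv: temporal dimension collapsed");
        TMat Xcol;
        im2col(A, s.kernel, Xcol);
        TCube out;
        conv_forward(Xcol, P[l][0], P[l][1], A.n_rows, out);
        if (train) { k.Xflat = std::move(Xcol); k.out = out; }
        A = std::move(out);
      } else if (s.type == "bilstm") {
        TMat Xflat;
        cube_to_flat(A, Xflat);
        lstm_forward(Xflat, P[l][0], P[l][1], P[l][2], false,
                     A.n_rows, A.n_slices, k.Hf, k.Cf, k.Gf);
        lstm_forward(Xflat, P[l][3], P[l][4], P[l][5], true,
                     A.n_rows, A.n_slices, k.Hb, k.Cb, k.Gb);
        TCube out;
        bidir_concat(k.Hf, k.Hb, out);
        if (train) k.Xflat = std::move(Xflat);
        else { k.Hf.reset(); k.Hb.reset(); k.Cf.reset(); k.Cb.reset();
               k.Gf.reset(); k.Gb.reset(); }
        A = std::move(out);
      } else if (s.type == "bigru") {
        TMat Xflat;
        cube_to_flat(A, Xflat);
        gru_forward(Xflat, P[l][0], P[l][1], P[l][2], false,
                    A.n_rows, A.n_slices, k.Hf, k.Gf, k.RHf);
        gru_forward(Xflat, P[l][3], P[l][4], P[l][5], true,
                    A.n_rows, A.n_slices, k.Hb, k.Gb, k.RHb);
        TCube out;
        bidir_concat(k.Hf, k.Hb, out);
        if (train) k.Xflat = std::move(Xflat);
        else { k.Hf.reset(); k.Hb.reset(); k.Gf.reset(); k.Gb.reset();
               k.RHf.reset(); k.RHb.reset(); }
        A = std::move(out);
      } else if (s.type == "avgpool") {
        const int To = A.n_slices / s.pool;
        if (To < 1) stop("avgpool: temporal dimension collapsed to 0");
        TCube out(A.n_rows, A.n_cols, To, fill::zeros);
        for (int t = 0; t < To; ++t) {
          for (int j = 0; j < s.pool; ++j)
            out.slice(t) += A.slice(t * s.pool + j);
          out.slice(t) /= eT(s.pool);
        }
        A = std::move(out);
      } else if (s.type == "dropout") {
        if (train && s.rate > 0) {
          std::uniform_real_distribution<double> U(0.0, 1.0);
          TCube m(A.n_rows, A.n_cols, A.n_slices);
          const eT keep = eT(1.0 / (1.0 - s.rate));
          for (uword i = 0; i < m.n_elem; ++i)
            m(i) = (U(rng) < s.rate) ? eT(0) : keep;
          A %= m;
          k.mask = std::move(m);
        }
      } else if (s.type == "flatten") {
        const int C = A.n_cols, T = A.n_slices;
        M.set_size(A.n_rows, C * T);
        for (int t = 0; t < T; ++t)
          M.cols(t * C, (t + 1) * C - 1) = A.slice(t);
        flat = true;
      } else if (s.type == "dense") {
        if (!flat) stop("dense before flatten");
        if (train) k.Min = M;
        TMat z = M * P[l][0];
        z.each_row() += P[l][1].row(0);
        M = reluM(z);
        if (train) k.Mout = M;
      } else if (s.type == "output") {
        if (!flat) stop("output before flatten");
        if (train) k.Min = M;
        TMat z = M * P[l][0];
        z.each_row() += P[l][1].row(0);
        M = softmax_rows(z);
      }
    }
    return M;  // probabilities (batch x n_classes)
  }

  // backward pass from probabilities; Y is one-hot (batch x K)
  static Params net_backward(const std::vector<LayerSpec>& specs,
                             const Params& P, const TMat& probs, const TMat& Y,
                             std::vector<LayerCache>& K) {
    const int L = specs.size();
    Params G(L);
    for (int l = 0; l < L; ++l) {
      G[l].resize(P[l].size());
      for (size_t j = 0; j < P[l].size(); ++j)
        G[l][j] = TMat(P[l][j].n_rows, P[l][j].n_cols, fill::zeros);
    }
    TMat dM = (probs - Y) / eT(probs.n_rows);
    TCube dA;
    for (int l = L - 1; l >= 0; --l) {
      const LayerSpec& s = specs[l];
      LayerCache& k = K[l];
      if (s.type == "output") {
        G[l][0] = k.Min.t() * dM;
        G[l][1] = sum(dM, 0);
        dM = dM * P[l][0].t();
      } else if (s.type == "dense") {
        TMat dz = relu_maskM(dM, k.Mout);
        G[l][0] = k.Min.t() * dz;
        G[l][1] = sum(dz, 0);
        dM = dz * P[l][0].t();
      } else if (s.type == "flatten") {
        dA.set_size(k.inB, k.inC, k.inT);
        for (uword t = 0; t < k.inT; ++t)
          dA.slice(t) = dM.cols(t * k.inC, (t + 1) * k.inC - 1);
      } else if (s.type == "dropout") {
        if (k.mask.n_elem > 0) dA %= k.mask;
      } else if (s.type == "avgpool") {
        TCube d(k.inB, k.inC, k.inT, fill::zeros);
        for (uword t = 0; t < dA.n_slices; ++t)
          for (int j = 0; j < s.pool; ++j)
            d.slice(t * s.pool + j) = dA.slice(t) / eT(s.pool);
        dA = std::move(d);
      } else if (s.type == "bilstm") {
        TMat dXflat(k.inB * k.inT, k.inC, fill::zeros);
        lstm_backward(k.Xflat, P[l][0], P[l][1], k.Hf, k.Cf, k.Gf, dA, 0,
                      false, dXflat, G[l][0], G[l][1], G[l][2]);
        lstm_backward(k.Xflat, P[l][3], P[l][4], k.Hb, k.Cb, k.Gb, dA,
                      s.units, true, dXflat, G[l][3], G[l][4], G[l][5]);
        dA.set_size(k.inB, k.inC, k.inT);
        for (uword t = 0; t < k.inT; ++t)
          dA.slice(t) = dXflat.rows(t * k.inB, (t + 1) * k.inB - 1);
      } else if (s.type == "bigru") {
        TMat dXflat(k.inB * k.inT, k.inC, fill::zeros);
        gru_backward(k.Xflat, P[l][0], P[l][1], k.Hf, k.Gf, k.RHf, dA, 0,
                     false, dXflat, G[l][0], G[l][1], G[l][2]);
        gru_backward(k.Xflat, P[l][3], P[l][4], k.Hb, k.Gb, k.RHb, dA,
                     s.units, true, dXflat, G[l][3], G[l][4], G[l][5]);
        dA.set_size(k.inB, k.inC, k.inT);
        for (uword t = 0; t < k.inT; ++t)
          dA.slice(t) = dXflat.rows(t * k.inB, (t + 1) * k.inB - 1);
      } else if (s.type == "conv") {
        TCube din;
        conv_backward(k.Xflat, P[l][0], s.kernel, k.out, dA, k.inT,
                      din, G[l][0], G[l][1]);
        dA = std::move(din);
      }
    }
    return G;
  }
};

// ---------------------------------------------------------------------------
// R interface

static ParamsD params_from_r(const List& rp) {
  ParamsD P(rp.size());
  for (int l = 0; l < rp.size(); ++l) {
    List pl = rp[l];
    for (int j = 0; j < pl.size(); ++j)
      P[l].push_back(as<mat>(pl[j]));
  }
  return P;
}

static List params_to_r(const ParamsD& P) {
  List out(P.size());
  for (size_t l = 0; l < P.size(); ++l) {
    List pl(P[l].size());
    for (size_t j = 0; j < P[l].size(); ++j) pl[j] = P[l][j];
    out[l] = pl;
  }
  return out;
}

template <typename eT>
static typename Engine<eT>::Params params_cast(const ParamsD& P) {
  typename Engine<eT>::Params Q(P.size());
  for (size_t l = 0; l < P.size(); ++l)
    for (size_t j = 0; j < P[l].size(); ++j)
      Q[l].push_back(conv_to<Mat<eT>>::from(P[l][j]));
  return Q;
}

// [[Rcpp::export]]
List cpp_init_params(List layers, int seed) {
  std::vector<LayerSpec> specs = parse_layers(layers);
  return params_to_r(init_params(specs, seed));
}

// [[Rcpp::export]]
arma::mat cpp_predict(List layers, List params, arma::mat X, int batch_size) {
  std::vector<LayerSpec> specs = parse_layers(layers);
  typedef Engine<float> E;
  E::Params P = params_cast<float>(params_from_r(params));
  fmat Xf = conv_to<fmat>::from(X);
  std::mt19937 rng(0);
  std::vector<E::LayerCache> K;
  const int n = Xf.n_rows;
  mat probs;
  for (int i0 = 0; i0 < n; i0 += batch_size) {
    const int i1 = std::min(n, i0 + batch_size) - 1;
    fmat p = E::net_forward(specs, P, Xf.rows(i0, i1), false, rng, K);
    mat pd = conv_to<mat>::from(p);
    if (probs.n_rows == 0) probs = pd; else probs = join_cols(probs, pd);
  }
  return probs;
}

// gradients in float64 (used by the finite-difference tests)
// [[Rcpp::export]]
List cpp_gradients(List layers, List params, arma::mat X,
                   arma::ivec y, int n_classes) {
  std::vector<LayerSpec> specs = parse_layers(layers);
  typedef Engine<double> E;
  E::Params P = params_from_r(params);
  std::mt19937 rng(0);
  std::vector<E::LayerCache> K;
  mat probs = E::net_forward(specs, P, X, true, rng, K);
  mat Y(X.n_rows, n_classes, fill::zeros);
  for (uword i = 0; i < y.n_elem; ++i) Y(i, y(i)) = 1.0;
  double loss = -accu(Y % log(probs + 1e-12)) / X.n_rows;
  E::Params G = E::net_backward(specs, P, probs, Y, K);
  ParamsD Gd(G.size());
  for (size_t l = 0; l < G.size(); ++l)
    for (size_t j = 0; j < G[l].size(); ++j) Gd[l].push_back(G[l][j]);
  return List::create(_["loss"] = loss, _["grads"] = params_to_r(Gd));
}

// [[Rcpp::export]]
List cpp_train(List layers, List params, arma::mat X, arma::ivec y,
               int n_classes, int epochs, int batch_size, double lr,
               int seed, bool verbose = false) {
  std::vector<LayerSpec> specs = parse_layers(layers);
  typedef Engine<float> E;
  E::Params P = params_cast<float>(params_from_r(params));
  fmat Xf = conv_to<fmat>::from(X);
  const int n = Xf.n_rows;

  E::Params M(P.size()), V(P.size());
  for (size_t l = 0; l < P.size(); ++l)
    for (size_t j = 0; j < P[l].size(); ++j) {
      M[l].push_back(fmat(P[l][j].n_rows, P[l][j].n_cols, fill::zeros));
      V[l].push_back(fmat(P[l][j].n_rows, P[l][j].n_cols, fill::zeros));
    }
  const float b1 = 0.9f, b2 = 0.999f, eps = 1e-7f;
  const float lrf = static_cast<float>(lr);
  long step = 0;
  std::mt19937 rng(static_cast<unsigned>(seed));
  std::vector<double> losses;
  bool diverged = false;

  std::vector<int> idx(n);
  for (int i = 0; i < n; ++i) idx[i] = i;

  for (int e = 0; e < epochs && !diverged; ++e) {
    std::shuffle(idx.begin(), idx.end(), rng);
    double epoch_loss = 0.0;
    int n_batches = 0;
    for (int i0 = 0; i0 < n; i0 += batch_size) {
      const int i1 = std::min(n, i0 + batch_size);
      uvec rows(i1 - i0);
      for (int i = i0; i < i1; ++i) rows(i - i0) = idx[i];
      fmat Xb = Xf.rows(rows);
      fmat Y(i1 - i0, n_classes, fill::zeros);
      for (int i = i0; i < i1; ++i) Y(i - i0, y(idx[i])) = 1.0f;

      std::vector<E::LayerCache> K;
      fmat probs = E::net_forward(specs, P, Xb, true, rng, K);
      double loss = -accu(Y % log(probs + 1e-12f)) / Xb.n_rows;
      if (!std::isfinite(loss)) { diverged = true; break; }
      epoch_loss += loss;
      ++n_batches;
      E::Params G = E::net_backward(specs, P, probs, Y, K);

      ++step;
      const float corr = std::sqrt(1.0f - std::pow(b2, (float)step)) /
                         (1.0f - std::pow(b1, (float)step));
      for (size_t l = 0; l < P.size(); ++l)
        for (size_t j = 0; j < P[l].size(); ++j) {
          M[l][j] = b1 * M[l][j] + (1.0f - b1) * G[l][j];
          V[l][j] = b2 * V[l][j] + (1.0f - b2) * (G[l][j] % G[l][j]);
          P[l][j] -= (lrf * corr) * M[l][j] / (sqrt(V[l][j]) + eps);
        }
    }
    losses.push_back(n_batches > 0 ? epoch_loss / n_batches : NA_REAL);
    if (verbose)
      Rcpp::Rcout << "epoch " << (e + 1) << "/" << epochs
                  << " loss " << losses.back() << std::endl;
    Rcpp::checkUserInterrupt();
  }
  ParamsD Pd(P.size());
  for (size_t l = 0; l < P.size(); ++l)
    for (size_t j = 0; j < P[l].size(); ++j)
      Pd[l].push_back(conv_to<mat>::from(P[l][j]));
  return List::create(_["params"] = params_to_r(Pd),
                      _["loss"] = losses,
                      _["diverged"] = diverged);
}
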