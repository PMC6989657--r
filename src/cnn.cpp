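// Convolutional text classifier core: forward pass, Adadelta training with
// class-weighted cross-entropy, max-norm projection, and selective embedding
// gradient routing (word branch only). All randomness comes from R's RNG so
// set.seed() on the R side makes every run reproducible.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

struct FilterGroup {
  int l;          // filter length (tokens)
  mat W;          // n_maps x (l*d)
  vec b;          // n_maps
};

static std::vector<FilterGroup> parse_groups(List groups) {
  std::vector<FilterGroup> out;
  for (int i = 0; i < groups.size(); ++i) {
    List g = groups[i];
    FilterGroup fg;
    fg.l = as<int>(g["l"]);
    fg.W = as<mat>(g["W"]);
    fg.b = as<vec>(g["b"]);
    out.push_back(fg);
  }
  return out;
}

static List groups_to_list(const std::vector<FilterGroup>& gs) {
  List out(gs.size());
  for (size_t i = 0; i < gs.size(); ++i) {
    out[i] = List::create(_["l"] = gs[i].l,
                          _["W"] = wrap(gs[i].W),
                          _["b"] = wrap(gs[i].b));
  }
  return out;
}

static int total_maps(const std::vector<FilterGroup>& gs) {
  int n = 0;
  for (const auto& g : gs) n += g.W.n_rows;
  return n;
}

// windows of X stacked row-wise: row t = flatten(X[t..t+l-1, ])
static mat im2col(const mat& X, int l) {
  const int L = X.n_rows, d = X.n_cols, T = L - l + 1;
  mat M(T, l * d);
  for (int j = 0; j < l; ++j)
    M.cols(j * d, (j + 1) * d - 1) = X.rows(j, j + T - 1);
  return M;
}

// [[Rcpp::export]]
NumericMatrix cpp_conv_feature_map(NumericMatrix X_, NumericMatrix W_,
                                   NumericVector b_) {
  mat X = as<mat>(X_);
  mat W = as<mat>(W_);
  vec b = as<vec>(b_);
  const int d = X.n_cols;
  const int l = W.n_cols / d;
  if ((int)W.n_cols != l * d)
    stop("filter width is not a multiple of the embedding dimension");
  if ((int)X.n_rows < l) stop("input shorter than the filter length");
  mat M = im2col(X, l);              // T x (l*d)
  mat A = M * W.t();                 // T x n_maps
  A.each_row() += b.t();
  A.transform([](double v) { return v > 0.0 ? v : 0.0; });
  return wrap(mat(A.t()));           // n_maps x T
}

// sentence embeddings: pool the first len[s] token vectors of each sentence
static mat pool_sentences(const mat& E, const imat& sidx, const ivec& slen,
                          int pooling /* 0 = sum, 1 = average */) {
  const int S = sidx.n_rows, d = E.n_cols;
  mat Ep(S, d, fill::zeros);
  for (int s = 0; s < S; ++s) {
    const int len = slen(s);
    if (len == 0) continue;
    rowvec acc(d, fill::zeros);
    for (int j = 0; j < len; ++j) acc += E.row(sidx(s, j) - 1);
    if (pooling == 1) acc /= (double)len;
    Ep.row(s) = acc;
  }
  return Ep;
}

struct BranchCache {
  std::vector<uvec> argmax;  // per group: window index of the max, per map
  std::vector<vec>  maxval;  // per group: pre-ReLU max, per map
};

// conv + max-over-time for one branch; fills V[offset..] and the cache
static void branch_forward(const mat& X, const std::vector<FilterGroup>& gs,
                           vec& V, int offset, BranchCache* cache) {
  for (const auto& g : gs) {
    mat M = im2col(X, g.l);
    mat A = M * g.W.t();
    A.each_row() += g.b.t();
    const int n_maps = g.W.n_rows;
    uvec am(n_maps);
    vec mv(n_maps);
    for (int m = 0; m < n_maps; ++m) {
      uword idx;
      mv(m) = A.col(m).max(idx);
      am(m) = idx;
      V(offset + m) = mv(m) > 0.0 ? mv(m) : 0.0;
    }
    if (cache) {
      cache->argmax.push_back(am);
      cache->maxval.push_back(mv);
    }
    offset += n_maps;
  }
}

static inline double sigmoid(double z) { return 1.0 / (1.0 + std::exp(-z)); }

struct ModelState {
  mat E;
  std::vector<FilterGroup> wgrp, sgrp;
  vec w_out;
  double b_out;
  int pooling;
  bool has_sent;
};

// full forward for one note; caches are optional (training needs them)
static double forward_note(const ModelState& ms, const irowvec& widx,
                           const imat* sidx, const ivec* slen,
                           const vec* drop_mask, vec* V_out,
                           BranchCache* wc, BranchCache* sc, mat* Ep_out) {
  const int Fw = total_maps(ms.wgrp);
  const int Fs = ms.has_sent ? total_maps(ms.sgrp) : 0;
  vec V(Fw + Fs, fill::zeros);
  uvec rows = conv_to<uvec>::from(widx.t()) - 1;
  mat X = ms.E.rows(rows);
  branch_forward(X, ms.wgrp, V, 0, wc);
  if (ms.has_sent) {
    mat Ep = pool_sentences(ms.E, *sidx, *slen, ms.pooling);
    branch_forward(Ep, ms.sgrp, V, Fw, sc);
    if (Ep_out) *Ep_out = Ep;
  }
  if (drop_mask) V %= *drop_mask;
  if (V_out) *V_out = V;
  return sigmoid(dot(ms.w_out, V) + ms.b_out);
}

static ModelState parse_model(NumericMatrix E_, List word_filters,
                              List sent_filters, int pooling,
                              NumericVector w_out_, double b_out) {
  ModelState ms;
  ms.E = as<mat>(E_);
  ms.wgrp = parse_groups(word_filters);
  ms.has_sent = sent_filters.size() > 0;
  if (ms.has_sent) ms.sgrp = parse_groups(sent_filters);
  ms.w_out = as<vec>(w_out_);
  ms.b_out = b_out;
  ms.pooling = pooling;
  return ms;
}

// [[Rcpp::export]]
NumericVector cpp_forward_cnn(NumericMatrix E_, List word_filters,
                              List sent_filters, int pooling,
                              NumericVector w_out_, double b_out,
                              IntegerMatrix word_idx, List sent_idx,
                              List sent_len, double dropout,
                              bool dropout_active) {
  ModelState ms = parse_model(E_, word_filters, sent_filters, pooling,
                              w_out_, b_out);
  const int n = word_idx.nrow();
  const int F = total_maps(ms.wgrp) + (ms.has_sent ? total_maps(ms.sgrp) : 0);
  imat widx = as<imat>(word_idx);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    vec mask;
    if (dropout_active && dropout > 0.0) {
      mask.set_size(F);
      const double keep = 1.0 - dropout;
      for (int f = 0; f < F; ++f)
        mask(f) = unif_rand() < keep ? 1.0 / keep : 0.0;
    }
    imat si;
    ivec sl;
    if (ms.has_sent) {
      si = as<imat>(sent_idx[i]);
      sl = as<ivec>(sent_len[i]);
    }
    out[i] = forward_note(ms, widx.row(i), ms.has_sent ? &si : nullptr,
                          ms.has_sent ? &sl : nullptr,
                          mask.n_elem ? &mask : nullptr,
                          nullptr, nullptr, nullptr, nullptr);
  }
  return out;
}

// Adadelta state for one tensor
struct AdaState {
  mat g2, d2;
  void init(int r, int c) { g2.zeros(r, c); d2.zeros(r, c); }
};

static void adadelta_update(mat& x, const mat& g, AdaState& st, double lr,
                            double rho, double eps) {
  st.g2 = rho * st.g2 + (1.0 - rho) * (g % g);
  mat dx = -(sqrt(st.d2 + eps) / sqrt(st.g2 + eps)) % g * lr;
  st.d2 = rho * st.d2 + (1.0 - rho) * (dx % dx);
  x += dx;
}

static void adadelta_update_row(mat& x, const rowvec& g, AdaState& st,
                                int row, double lr, double rho, double eps) {
  st.g2.row(row) = rho * st.g2.row(row) + (1.0 - rho) * (g % g);
  rowvec dx = -(sqrt(st.d2.row(row) + eps) / sqrt(st.g2.row(row) + eps)) % g * lr;
  st.d2.row(row) = rho * st.d2.row(row) + (1.0 - rho) * (dx % dx);
  x.row(row) += dx;
}

static void max_norm_project(std::vector<FilterGroup>& gs, double max_norm) {
  if (max_norm <= 0) return;
  for (auto& g : gs)
    for (uword m = 0; m < g.W.n_rows; ++m) {
      double n = norm(g.W.row(m), 2);
      if (n > max_norm) g.W.row(m) *= max_norm / n;
    }
}

static double note_loss(double p, int y, const vec& cw, double eps_clip) {
  p = std::min(std::max(p, eps_clip), 1.0 - eps_clip);
  double w = y == 1 ? cw(1) : cw(0);
  return -w * (y == 1 ? std::log(p) : std::log(1.0 - p));
}

// [[Rcpp::export]]
List cpp_train_cnn(NumericMatrix E_, List word_filters, List sent_filters,
                   int pooling, NumericVector w_out_, double b_out,
                   IntegerMatrix word_idx, List sent_idx, List sent_len,
                   IntegerVector y_, NumericVector class_w_,
                   IntegerMatrix v_word_idx, List v_sent_idx, List v_sent_len,
                   IntegerVector v_y_,
                   double lr, int batch_size, int epochs, double dropout,
                   double max_norm, bool train_embedding,
                   double rho, double eps) {
  ModelState ms = parse_model(E_, word_filters, sent_filters, pooling,
                              w_out_, b_out);
  imat widx = as<imat>(word_idx);
  ivec y = as<ivec>(y_);
  vec cw = as<vec>(class_w_);
  imat v_widx = as<imat>(v_word_idx);
  ivec v_y = as<ivec>(v_y_);
  const int n = widx.n_rows, n_valid = v_widx.n_rows;
  const int d = ms.E.n_cols;
  const int Fw = total_maps(ms.wgrp);
  const int Fs = ms.has_sent ? total_maps(ms.sgrp) : 0;
  const int F = Fw + Fs;
  const double eps_clip = 1e-12;

  // pre-extract sentence inputs once (list access is slow inside the loop)
  std::vector<imat> sx(ms.has_sent ? n : 0);
  std::vector<ivec> sl(ms.has_sent ? n : 0);
  std::vector<imat> vsx(ms.has_sent ? n_valid : 0);
  std::vector<ivec> vsl(ms.has_sent ? n_valid : 0);
  if (ms.has_sent) {
    for (int i = 0; i < n; ++i) {
      sx[i] = as<imat>(sent_idx[i]);
      sl[i] = as<ivec>(sent_len[i]);
    }
    for (int i = 0; i < n_valid; ++i) {
      vsx[i] = as<imat>(v_sent_idx[i]);
      vsl[i] = as<ivec>(v_sent_len[i]);
    }
  }

  // optimizer state
  std::vector<AdaState> st_wW(ms.wgrp.size()), st_wb(ms.wgrp.size());
  for (size_t g = 0; g < ms.wgrp.size(); ++g) {
    st_wW[g].init(ms.wgrp[g].W.n_rows, ms.wgrp[g].W.n_cols);
    st_wb[g].init(ms.wgrp[g].b.n_elem, 1);
  }
  std::vector<AdaState> st_sW(ms.sgrp.size()), st_sb(ms.sgrp.size());
  for (size_t g = 0; g < ms.sgrp.size(); ++g) {
    st_sW[g].init(ms.sgrp[g].W.n_rows, ms.sgrp[g].W.n_cols);
    st_sb[g].init(ms.sgrp[g].b.n_elem, 1);
  }
  AdaState st_out, st_bout, st_E;
  st_out.init(ms.w_out.n_elem, 1);
  st_bout.init(1, 1);
  if (train_embedding) st_E.init(ms.E.n_rows, d);

  std::vector<double> tr_loss(epochs), va_loss(epochs);

  // gradient buffers
  std::vector<mat> gwW(ms.wgrp.size());
  std::vector<vec> gwb(ms.wgrp.size());
  std::vector<mat> gsW(ms.sgrp.size());
  std::vector<vec> gsb(ms.sgrp.size());
  mat gE;
  if (train_embedding) gE.zeros(ms.E.n_rows, d);
  std::vector<int> touched;

  for (int ep = 0; ep < epochs; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    std::vector<int> perm(n);
    for (int i = 0; i < n; ++i) perm[i] = i;
    for (int i = n - 1; i > 0; --i) {
      int j = (int)std::floor(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(perm[i], perm[j]);
    }
    double ep_loss = 0.0;
    for (int start = 0; start < n; start += batch_size) {
      const int B = std::min(batch_size, n - start);
      for (size_t g = 0; g < ms.wgrp.size(); ++g) {
        gwW[g].zeros(ms.wgrp[g].W.n_rows, ms.wgrp[g].W.n_cols);
        gwb[g].zeros(ms.wgrp[g].b.n_elem);
      }
      for (size_t g = 0; g < ms.sgrp.size(); ++g) {
        gsW[g].zeros(ms.sgrp[g].W.n_rows, ms.sgrp[g].W.n_cols);
        gsb[g].zeros(ms.sgrp[g].b.n_elem);
      }
      vec gout(F, fill::zeros);
      double gbout = 0.0;
      touched.clear();

      for (int bi = 0; bi < B; ++bi) {
        const int i = perm[start + bi];
        vec mask(F);
        const double keep = 1.0 - dropout;
        if (dropout > 0.0)
          for (int f = 0; f < F; ++f)
            mask(f) = unif_rand() < keep ? 1.0 / keep : 0.0;
        else
          mask.ones();
        vec V;
        BranchCache wc, sc;
        mat Ep;
        const imat* sip = ms.has_sent ? &sx[i] : nullptr;
        const ivec* slp = ms.has_sent ? &sl[i] : nullptr;
        double p = forward_note(ms, widx.row(i), sip, slp, &mask, &V, &wc,
                                ms.has_sent ? &sc : nullptr,
                                ms.has_sent ? &Ep : nullptr);
        ep_loss += note_loss(p, y(i), cw, eps_clip);
        const double w = y(i) == 1 ? cw(1) : cw(0);
        const double dz = w * (p - y(i)) / B;  // weighted-mean reduction
        // output layer
        gout += dz * V;
        gbout += dz;
        vec dV = dz * ms.w_out % mask;
        // word branch
        int off = 0;
        for (size_t g = 0; g < ms.wgrp.size(); ++g) {
          const FilterGroup& fg = ms.wgrp[g];
          const int l = fg.l, n_maps = fg.W.n_rows;
          for (int m = 0; m < n_maps; ++m) {
            if (wc.maxval[g](m) <= 0.0) continue;
            const double gr = dV(off + m);
            if (gr == 0.0) continue;
            const int t = wc.argmax[g](m);
            rowvec xwin(l * d);
            for (int j = 0; j < l; ++j)
              xwin.subvec(j * d, (j + 1) * d - 1) =
                  ms.E.row(widx(i, t + j) - 1);
            gwW[g].row(m) += gr * xwin;
            gwb[g](m) += gr;
            if (train_embedding) {
              for (int j = 0; j < l; ++j) {
                const int row = widx(i, t + j) - 1;
                if (gE.row(row).is_zero()) touched.push_back(row);
                gE.row(row) += gr * fg.W.row(m).subvec(j * d, (j + 1) * d - 1);
              }
            }
          }
          off += n_maps;
        }
        // sentence branch: filter gradients only; pooled embeddings are a
        // detached view of E, so no gradient reaches the embedding table
        if (ms.has_sent) {
          for (size_t g = 0; g < ms.sgrp.size(); ++g) {
            const FilterGroup& fg = ms.sgrp[g];
            const int l = fg.l, n_maps = fg.W.n_rows;
            for (int m = 0; m < n_maps; ++m) {
              if (sc.maxval[g](m) <= 0.0) continue;
              const double gr = dV(off + m);
              if (gr == 0.0) continue;
              const int t = sc.argmax[g](m);
              rowvec xwin(l * d);
              for (int j = 0; j < l; ++j)
                xwin.subvec(j * d, (j + 1) * d - 1) = Ep.row(t + j);
              gsW[g].row(m) += gr * xwin;
              gsb[g](m) += gr;
            }
            off += n_maps;
          }
        }
      }

      // parameter updates
      for (size_t g = 0; g < ms.wgrp.size(); ++g) {
        adadelta_update(ms.wgrp[g].W, gwW[g], st_wW[g], lr, rho, eps);
        mat bmat(ms.wgrp[g].b.memptr(), ms.wgrp[g].b.n_elem, 1, false, true);
        adadelta_update(bmat, mat(gwb[g]), st_wb[g], lr, rho, eps);
      }
      for (size_t g = 0; g < ms.sgrp.size(); ++g) {
        adadelta_update(ms.sgrp[g].W, gsW[g], st_sW[g], lr, rho, eps);
        mat bmat(ms.sgrp[g].b.memptr(), ms.sgrp[g].b.n_elem, 1, false, true);
        adadelta_update(bmat, mat(gsb[g]), st_sb[g], lr, rho, eps);
      }
      {
        mat wmat(ms.w_out.memptr(), ms.w_out.n_elem, 1, false, true);
        adadelta_update(wmat, mat(gout), st_out, lr, rho, eps);
        mat bm(1, 1);
        bm(0, 0) = ms.b_out;
        mat gb(1, 1);
        gb(0, 0) = gbout;
        adadelta_update(bm, gb, st_bout, lr, rho, eps);
        ms.b_out = bm(0, 0);
      }
      if (train_embedding) {
        std::sort(touched.begin(), touched.end());
        touched.erase(std::unique(touched.begin(), touched.end()),
                      touched.end());
        for (int row : touched) {
          adadelta_update_row(ms.E, gE.row(row), st_E, row, lr, rho, eps);
          gE.row(row).zeros();
        }
      }
      max_norm_project(ms.wgrp, max_norm);
      max_norm_project(ms.sgrp, max_norm);
      if (!std::isfinite(ep_loss))
        stop("training diverged: non-finite loss at epoch %d", ep + 1);
    }
    tr_loss[ep] = ep_loss / n;
    if (n_valid > 0) {
      double vl = 0.0;
      for (int i = 0; i < n_valid; ++i) {
        const imat* sip = ms.has_sent ? &vsx[i] : nullptr;
        const ivec* slp = ms.has_sent ? &vsl[i] : nullptr;
        double p = forward_note(ms, v_widx.row(i), sip, slp, nullptr, nullptr,
                                nullptr, nullptr, nullptr);
        vl += note_loss(p, v_y(i), cw, eps_clip);
      }
      va_loss[ep] = vl / n_valid;
    } else {
      va_loss[ep] = NA_REAL;
    }
  }

  return List::create(
      _["E"] = wrap(ms.E), _["word_filters"] = groups_to_list(ms.wgrp),
      _["sent_filters"] = ms.has_sent ? groups_to_list(ms.sgrp) : List(0),
      _["w_out"] = wrap(ms.w_out), _["b_out"] = ms.b_out,
      _["train_loss"] = wrap(tr_loss), _["valid_loss"] = wrap(va_loss));
}
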