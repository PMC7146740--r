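#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Per-pixel Gaussian-mixture background maintenance (grayscale, K small).
// State vectors are pixel-major (w[p*K + k]) and updated in place.
// Returns the raw foreground mask (1 = foreground) before any morphology.
// [[Rcpp::export]]
LogicalMatrix mog_apply(NumericVector w, NumericVector mu, NumericVector var,
                        NumericMatrix frame, int K, double alpha,
                        double alpha_w, double t_match, double cf,
                        double var_init, double var_min, double var_max,
                        bool shadow, double shadow_lo, double shadow_hi) {
  const int nr = frame.nrow(), nc = frame.ncol();
  const R_xlen_t N = (R_xlen_t)nr * nc;
  if (w.size() != N * K || mu.size() != N * K || var.size() != N * K)
    stop("background-model state does not match frame dimensions");
  LogicalMatrix mask(nr, nc);
  double *pw = REAL(w), *pm = REAL(mu), *pv = REAL(var);
  const double *pf = REAL(frame);
  int *pmask = LOGICAL(mask);

  for (R_xlen_t p = 0; p < N; ++p) {
    const double v = pf[p];
    double *wp = pw + p * K, *mp = pm + p * K, *vp = pv + p * K;

    // find matching component with the largest weight
    int m = -1; double bestw = -1.0;
    for (int k = 0; k < K; ++k) {
      if (wp[k] <= 1e-9) continue;
      const double d = v - mp[k];
      if (d * d < t_match * vp[k] && wp[k] > bestw) { m = k; bestw = wp[k]; }
    }

    bool fg;
    if (m >= 0) {
      // weights evolve on their own (slower) time constant so that a
      // repeatedly-occupied pixel is not absorbed into the background,
      // while means/variances track slow illumination drift faster
      for (int k = 0; k < K; ++k)
        wp[k] = (1.0 - alpha_w) * wp[k] + (k == m ? alpha_w : 0.0);
      const double d = v - mp[m];
      mp[m] += alpha * d;
      vp[m] += alpha * (d * d - vp[m]);
      if (vp[m] < var_min) vp[m] = var_min;
      // cap the variance so the match radius can never grow to span the
      // background-to-player contrast (prevents one component swallowing
      // both modes of a bimodal pixel)
      if (vp[m] > var_max) vp[m] = var_max;
      // background set: highest-weight components up to cumulative cf
      double above = 0.0;
      for (int k = 0; k < K; ++k)
        if (wp[k] > wp[m] || (wp[k] == wp[m] && k < m)) above += wp[k];
      fg = (above >= cf);
    } else {
      fg = true;
      if (shadow) {
        // grayscale shadow heuristic: proportionally darker than the
        // dominant background component
        int dom = 0;
        for (int k = 1; k < K; ++k) if (wp[k] > wp[dom]) dom = k;
        if (mp[dom] > 1e-6) {
          const double r = v / mp[dom];
          if (r >= shadow_lo && r <= shadow_hi) {
            pmask[p] = FALSE;
            continue;                     // suppressed: no model change
          }
        }
      }
      // replace the weakest component with a new one seeded at v
      int worst = 0;
      for (int k = 1; k < K; ++k) if (wp[k] < wp[worst]) worst = k;
      wp[worst] = alpha_w;
      mp[worst] = v;
      vp[worst] = var_init;
      double s = 0.0;
      for (int k = 0; k < K; ++k) s += wp[k];
      for (int k = 0; k < K; ++k) wp[k] /= s;
    }
    pmask[p] = fg;
  }
  return mask;
}

static void pass_rows(const int *in, int *out, int nr, int nc, int half,
                      bool dilate) {
  // vertical pass (along columns of the column-major matrix)
  for (int c = 0; c < nc; ++c) {
    const int *col = in + (R_xlen_t)c * nr;
    int *ocol = out + (R_xlen_t)c * nr;
    for (int r = 0; r < nr; ++r) {
      int lo = r - half, hi = r + half;
      if (lo < 0) lo = 0;
      if (hi >= nr) hi = nr - 1;
      int acc = dilate ? 0 : 1;
      if (dilate) {
        for (int i = lo; i <= hi; ++i) if (col[i]) { acc = 1; break; }
      } else {
        for (int i = lo; i <= hi; ++i) if (!col[i]) { acc = 0; break; }
      }
      ocol[r] = acc;
    }
  }
}

static void pass_cols(const int *in, int *out, int nr, int nc, int half,
                      bool dilate) {
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int lo = c - half, hi = c + half;
      if (lo < 0) lo = 0;
      if (hi >= nc) hi = nc - 1;
      int acc = dilate ? 0 : 1;
      if (dilate) {
        for (int i = lo; i <= hi; ++i)
          if (in[(R_xlen_t)i * nr + r]) { acc = 1; break; }
      } else {
        for (int i = lo; i <= hi; ++i)
          if (!in[(R_xlen_t)i * nr + r]) { acc = 0; break; }
      }
      out[(R_xlen_t)c * nr + r] = acc;
    }
  }
}

static LogicalMatrix box_morph(const LogicalMatrix &m, int size, bool dilate) {
  const int nr = m.nrow(), nc = m.ncol(), half = size / 2;
  LogicalMatrix tmp(nr, nc), out(nr, nc);
  pass_rows(LOGICAL(m), LOGICAL(tmp), nr, nc, half, dilate);
  pass_cols(LOGICAL(tmp), LOGICAL(out), nr, nc, half, dilate);
  return out;
}

// opening/closing restricted to the bounding box of the foreground
// (plus a margin) — the player occupies a small part of the frame
static LogicalMatrix roi_morph(const LogicalMatrix &m, int size, bool open) {
  const int nr = m.nrow(), nc = m.ncol();
  const int *pm = LOGICAL(m);
  int r0 = nr, r1 = -1, c0 = nc, c1 = -1;
  for (int c = 0; c < nc; ++c) {
    const int *col = pm + (R_xlen_t)c * nr;
    for (int r = 0; r < nr; ++r) {
      if (col[r]) {
        if (r < r0) r0 = r;
        if (r > r1) r1 = r;
        if (c < c0) c0 = c;
        if (c > c1) c1 = c;
      }
    }
  }
  LogicalMatrix out(nr, nc);
  if (r1 < 0) return out;
  const int mg = size;
  r0 = std::max(0, r0 - mg); r1 = std::min(nr - 1, r1 + mg);
  c0 = std::max(0, c0 - mg); c1 = std::min(nc - 1, c1 + mg);
  const int snr = r1 - r0 + 1, snc = c1 - c0 + 1;
  LogicalMatrix sub(snr, snc);
  int *ps = LOGICAL(sub);
  for (int c = 0; c < snc; ++c)
    for (int r = 0; r < snr; ++r)
      ps[(R_xlen_t)c * snr + r] = pm[(R_xlen_t)(c + c0) * nr + (r + r0)];
  LogicalMatrix res = open ? box_morph(box_morph(sub, size, false), size, true)
                           : box_morph(box_morph(sub, size, true), size, false);
  const int *pr = LOGICAL(res);
  int *po = LOGICAL(out);
  for (int c = 0; c < snc; ++c)
    for (int r = 0; r < snr; ++r)
      po[(R_xlen_t)(c + c0) * nr + (r + r0)] = pr[(R_xlen_t)c * snr + r];
  return out;
}

// Connected components (4-connectivity) of a binary mask by flood fill.
// Components below min_area are cleared from the returned mask.  `stats`
// holds one row per kept component, sorted by decreasing area:
// [area, x, y, w, h] with 0-based pixel coordinates (x = column).
// [[Rcpp::export]]
List mask_components(LogicalMatrix m, double min_area) {
  const int nr = m.nrow(), nc = m.ncol();
  const R_xlen_t N = (R_xlen_t)nr * nc;
  IntegerVector lab(N);                 // scratch labels
  LogicalMatrix out(nr, nc);
  const int *pm = LOGICAL(m);
  int *pl = INTEGER(lab);
  int *po = LOGICAL(out);
  std::vector<R_xlen_t> stack;
  std::vector<double> area;
  std::vector<int> bx0, bx1, by0, by1;
  int K = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (!pm[i] || pl[i]) continue;
    ++K;
    stack.clear();
    stack.push_back(i);
    pl[i] = K;
    double a = 0;
    int cx0 = nc, cx1 = -1, cy0 = nr, cy1 = -1;
    while (!stack.empty()) {
      const R_xlen_t p = stack.back();
      stack.pop_back();
      const int r = (int)(p % nr), c = (int)(p / nr);
      ++a;
      if (c < cx0) cx0 = c;
      if (c > cx1) cx1 = c;
      if (r < cy0) cy0 = r;
      if (r > cy1) cy1 = r;
      if (r > 0      && pm[p - 1]  && !pl[p - 1])  { pl[p - 1] = K;  stack.push_back(p - 1); }
      if (r < nr - 1 && pm[p + 1]  && !pl[p + 1])  { pl[p + 1] = K;  stack.push_back(p + 1); }
      if (c > 0      && pm[p - nr] && !pl[p - nr]) { pl[p - nr] = K; stack.push_back(p - nr); }
      if (c < nc - 1 && pm[p + nr] && !pl[p + nr]) { pl[p + nr] = K; stack.push_back(p + nr); }
    }
    area.push_back(a);
    bx0.push_back(cx0); bx1.push_back(cx1);
    by0.push_back(cy0); by1.push_back(cy1);
  }
  std::vector<int> keep_id(K + 1, 0);
  std::vector<int> ord;
  for (int k = 0; k < K; ++k) if (area[k] >= min_area) ord.push_back(k);
  std::sort(ord.begin(), ord.end(),
            [&](int u, int v) { return area[u] > area[v]; });
  const int nk = (int)ord.size();
  for (int k = 0; k < nk; ++k) keep_id[ord[k] + 1] = 1;
  NumericMatrix stats(nk, 5);
  for (int k = 0; k < nk; ++k) {
    const int s = ord[k];
    stats(k, 0) = area[s];
    stats(k, 1) = bx0[s];
    stats(k, 2) = by0[s];
    stats(k, 3) = bx1[s] - bx0[s] + 1;
    stats(k, 4) = by1[s] - by0[s] + 1;
  }
  for (R_xlen_t i = 0; i < N; ++i)
    po[i] = (pl[i] && keep_id[pl[i]]) ? TRUE : FALSE;
  colnames(stats) = CharacterVector::create("area", "x", "y", "w", "h");
  return List::create(_["mask"] = out, _["stats"] = stats);
}

// Binary opening with a size x size box structuring element.
// [[Rcpp::export]]
LogicalMatrix bin_open(LogicalMatrix m, int size) {
  if (size < 1) stop("structuring element size must be >= 1");
  if (size == 1) return m;
  return roi_morph(m, size, true);
}

// Binary closing with a size x size box structuring element.
// [[Rcpp::export]]
LogicalMatrix bin_close(LogicalMatrix m, int size) {
  if (size < 1) stop("structuring element size must be >= 1");
  if (size == 1) return m;
  return roi_morph(m, size, false);
}
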