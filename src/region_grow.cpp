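#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Seeded region growing: breadth-first growth from seed pixels over all
// pixels strictly darker than the brightness threshold. A seed sitting on a
// pixel at or above the threshold contributes nothing. Connectivity is
// 4-neighbour by default, 8-neighbour optional.
// [[Rcpp::export]]
LogicalMatrix region_grow_cpp(IntegerMatrix img,
                              IntegerVector seed_row,
                              IntegerVector seed_col,
                              double threshold,
                              bool conn8) {
  const int nr = img.nrow(), nc = img.ncol();
  LogicalMatrix mask(nr, nc);
  std::vector<int> stack;
  stack.reserve(256);

  for (int s = 0; s < seed_row.size(); ++s) {
    int r = seed_row[s] - 1, c = seed_col[s] - 1;  // 1-based from R
    if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
    if (mask(r, c) || !(img(r, c) < threshold)) continue;
    mask(r, c) = true;
    stack.push_back(r + nr * c);
    while (!stack.empty()) {
      int idx = stack.back();
      stack.pop_back();
      int cr = idx % nr, cc = idx / nr;
      const int dr4[4] = {-1, 1, 0, 0};
      const int dc4[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        int r2 = cr + dr4[k], c2 = cc + dc4[k];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (!mask(r2, c2) && img(r2, c2) < threshold) {
          mask(r2, c2) = true;
          stack.push_back(r2 + nr * c2);
        }
      }
      if (conn8) {
        const int dr8[4] = {-1, -1, 1, 1};
        const int dc8[4] = {-1, 1, -1, 1};
        for (int k = 0; k < 4; ++k) {
          int r2 = cr + dr8[k], c2 = cc + dc8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (!mask(r2, c2) && img(r2, c2) < threshold) {
            mask(r2, c2) = true;
            stack.push_back(r2 + nr * c2);
          }
        }
      }
    }
  }
  return mask;
}

// Per-frame glottal areas for a whole stack: total pixel count of the grown
// region and the weighted count against a per-pixel left-side weight matrix
// (1 left of the midline, 0 right of it, 0.5 exactly on it). Frames are the
// third array dimension.
// [[Rcpp::export]]
NumericMatrix segment_stack_cpp(IntegerVector stack_arr,
                                int nr, int nc, int nf,
                                IntegerVector seed_row,
                                IntegerVector seed_col,
                                double threshold,
                                bool conn8,
                                NumericMatrix wleft) {
  NumericMatrix out(nf, 2);
  std::vector<int> st;
  st.reserve(256);
  std::vector<char> mask((size_t)nr * nc);
  const int dr4[4] = {-1, 1, 0, 0};
  const int dc4[4] = {0, 0, -1, 1};
  const int dr8[4] = {-1, -1, 1, 1};
  const int dc8[4] = {-1, 1, -1, 1};

  for (int f = 0; f < nf; ++f) {
    std::fill(mask.begin(), mask.end(), 0);
    const int *img = &stack_arr[(size_t)f * nr * nc];
    double area = 0.0, left = 0.0;
    for (int s = 0; s < seed_row.size(); ++s) {
      int r = seed_row[s] - 1, c = seed_col[s] - 1;
      if (r < 0 || r >= nr || c < 0 || c >= nc) continue;
      size_t idx0 = (size_t)r + (size_t)nr * c;
      if (mask[idx0] || !(img[idx0] < threshold)) continue;
      mask[idx0] = 1;
      area += 1.0;
      left += wleft(r, c);
      st.push_back((int)idx0);
      while (!st.empty()) {
        int idx = st.back();
        st.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int k = 0; k < 4; ++k) {
          int r2 = cr + dr4[k], c2 = cc + dc4[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          size_t i2 = (size_t)r2 + (size_t)nr * c2;
          if (!mask[i2] && img[i2] < threshold) {
            mask[i2] = 1;
            area += 1.0;
            left += wleft(r2, c2);
            st.push_back((int)i2);
          }
        }
        if (conn8) {
          for (int k = 0; k < 4; ++k) {
            int r2 = cr + dr8[k], c2 = cc + dc8[k];
            if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
            size_t i2 = (size_t)r2 + (size_t)nr * c2;
            if (!mask[i2] && img[i2] < threshold) {
              mask[i2] = 1;
              area += 1.0;
              left += wleft(r2, c2);
              st.push_back((int)i2);
            }
          }
        }
      }
    }
    out(f, 0) = area;
    out(f, 1) = left;
  }
  return out;
}

// Add Gaussian pixel noise (polar Box-Muller on R's RNG stream), clip to
// [0, 255] and round to nearest integer in one pass.
// [[Rcpp::export]]
IntegerVector add_noise_clip_cpp(IntegerVector px, double sd) {
  R_xlen_t n = px.size();
  IntegerVector out(no_init(n));
  RNGScope scope;
  double g1 = 0.0, g2 = 0.0;
  bool have = false;
  for (R_xlen_t i = 0; i < n; ++i) {
    double z;
    if (have) {
      z = g2;
      have = false;
    } else {
      double u, v, s;
      do {
        u = 2.0 * unif_rand() - 1.0;
        v = 2.0 * unif_rand() - 1.0;
        s = u * u + v * v;
      } while (s >= 1.0 || s == 0.0);
      double m = std::sqrt(-2.0 * std::log(s) / s);
      g1 = u * m;
      g2 = v * m;
      z = g1;
      have = true;
    }
    double x = px[i] + sd * z;
    if (x < 0.0) x = 0.0;
    if (x > 255.0) x = 255.0;
    out[i] = (int)(x + 0.5);
  }
  out.attr("dim") = px.attr("dim");
  return out;
}
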