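#include <Rcpp.h>
using namespace Rcpp;

// Raw (unsymmetrized) gray-level co-occurrence counts for one offset.
// Levels are 1-based; cells outside the mask never contribute.
// [[Rcpp::export]]
NumericMatrix cpp_glcm_counts(IntegerMatrix levels, LogicalMatrix mask,
                              int dr, int dc, int nlev) {
  NumericMatrix out(nlev, nlev);
  int nr = levels.nrow(), nc = levels.ncol();
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int i2 = i + dr, j2 = j + dc;
      if (i2 < 0 || i2 >= nr || j2 < 0 || j2 >= nc) continue;
      if (!mask(i2, j2)) continue;
      out(levels(i, j) - 1, levels(i2, j2) - 1) += 1.0;
    }
  }
  return out;
}

// Gray-level run-length counts for one direction. A run is a maximal
// constant-level segment along (dr,dc), truncated at the mask boundary.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm_counts(IntegerMatrix levels, LogicalMatrix mask,
                               int dr, int dc, int nlev, int maxrun) {
  NumericMatrix out(nlev, maxrun);
  int nr = levels.nrow(), nc = levels.ncol();
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!mask(i, j)) continue;
      int lev = levels(i, j);
      // run starts here iff the predecessor along the direction is
      // out of bounds, out of mask, or a different level
      int ip = i - dr, jp = j - dc;
      bool starts = (ip < 0 || ip >= nr || jp < 0 || jp >= nc ||
                     !mask(ip, jp) || levels(ip, jp) != lev);
      if (!starts) continue;
      int len = 1;
      int in = i + dr, jn = j + dc;
      while (in >= 0 && in < nr && jn >= 0 && jn < nc &&
             mask(in, jn) && levels(in, jn) == lev) {
        ++len;
        in += dr;
        jn += dc;
      }
      if (len > maxrun) len = maxrun;
      out(lev - 1, len - 1) += 1.0;
    }
  }
  return out;
}

// Rotation-invariant uniform LBP codes (P = 8, R = 1). Code 0..8 is the
// number of set bits for uniform patterns, 9 for non-uniform, and -1 for
// pixels whose 8-neighborhood is not fully inside the mask.
// [[Rcpp::export]]
IntegerMatrix cpp_lbp_codes(NumericMatrix img, LogicalMatrix mask) {
  int nr = img.nrow(), nc = img.ncol();
  IntegerMatrix out(nr, nc);
  // circular neighbor order
  const int dr[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  const int dc[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      out(i, j) = -1;
      if (!mask(i, j)) continue;
      if (i == 0 || j == 0 || i == nr - 1 || j == nc - 1) continue;
      bool ok = true;
      int bits[8];
      for (int k = 0; k < 8; ++k) {
        int i2 = i + dr[k], j2 = j + dc[k];
        if (!mask(i2, j2)) { ok = false; break; }
        bits[k] = img(i2, j2) >= img(i, j) ? 1 : 0;
      }
      if (!ok) continue;
      int trans = 0, ones = 0;
      for (int k = 0; k < 8; ++k) {
        ones += bits[k];
        if (bits[k] != bits[(k + 1) % 8]) ++trans;
      }
      out(i, j) = (trans <= 2) ? ones : 9;
    }
  }
  return out;
}

// Label of the largest 8-connected TRUE component (BFS).
// [[Rcpp::export]]
LogicalMatrix cpp_largest_component(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> labels(nr * nc, 0);
  int cur = 0, best_lab = 0, best_n = 0;
  std::vector<int> queue;
  for (int s = 0; s < nr * nc; ++s) {
    if (!mask[s] || labels[s]) continue;
    ++cur;
    queue.clear();
    queue.push_back(s);
    labels[s] = cur;
    int n = 0;
    while (!queue.empty()) {
      int p = queue.back();
      queue.pop_back();
      ++n;
      int pr = p % nr, pc = p / nr;
      for (int dr = -1; dr <= 1; ++dr) for (int dc = -1; dc <= 1; ++dc) {
        int r2 = pr + dr, c2 = pc + dc;
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        int q = c2 * nr + r2;
        if (mask[q] && !labels[q]) {
          labels[q] = cur;
          queue.push_back(q);
        }
      }
    }
    if (n > best_n) { best_n = n; best_lab = cur; }
  }
  LogicalMatrix out(nr, nc);
  for (int s = 0; s < nr * nc; ++s) out[s] = labels[s] == best_lab;
  return out;
}
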