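// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <queue>
using namespace arma;

// Topographical burst detection on a z-scored time-frequency map.
// Seeds are 2-D local maxima with z >= z_thresh; each seed, visited in
// descending z order, is grown by flood fill (4-connectivity) to its
// half-maximum contour: cells whose baseline-relative power excess
// (rel = (P - baseline) / baseline, per frequency row) is at least half
// the seed's excess and that are not yet claimed by a stronger burst.
// The relative excess keeps contours comparable across the 1/f-scaled
// rows without the degenerate tightening a z-relative threshold shows for
// very strong bursts (z is variance-normalized and unbounded).
// Returns one row per burst: seed_row, seed_col (1-based), onset_col,
// offset_col, power (sum of raw magnitude^2 in the contour), seed_z.

// [[Rcpp::export]]
arma::mat detect_bursts_core(const arma::mat& z, const arma::mat& raw,
                             const arma::mat& rel, double z_thresh) {
  const sword F = z.n_rows, T = z.n_cols;
  if (F == 0 || T == 0) return mat(0, 6);

  // local maxima (>= over the 3x3 neighbourhood)
  std::vector<std::pair<double, uword>> seeds;
  for (sword i = 0; i < F; ++i)
    for (sword j = 0; j < T; ++j) {
      double v = z(i, j);
      if (v < z_thresh) continue;
      bool is_max = true;
      for (sword di = -1; di <= 1 && is_max; ++di)
        for (sword dj = -1; dj <= 1; ++dj) {
          if (di == 0 && dj == 0) continue;
          sword ii = i + di, jj = j + dj;
          if (ii < 0 || ii >= F || jj < 0 || jj >= T) continue;
          if (z(ii, jj) > v) { is_max = false; break; }
        }
      if (is_max) seeds.emplace_back(v, (uword)(i + j * F));
    }
  std::sort(seeds.begin(), seeds.end(),
            [](const std::pair<double, uword>& a,
               const std::pair<double, uword>& b) { return a.first > b.first; });

  Mat<int> visited(F, T, fill::zeros);
  std::vector<std::array<double, 6>> out;

  for (auto& s : seeds) {
    uword lin = s.second;
    sword si = lin % F, sj = lin / F;
    if (visited(si, sj)) continue;  // inside a stronger burst's contour
    double thr_rel = 0.5 * rel(si, sj);
    sword jmin = sj, jmax = sj;
    double power = 0.0;
    std::queue<std::pair<sword, sword>> q;
    q.push({si, sj});
    visited(si, sj) = 1;
    while (!q.empty()) {
      auto [i, j] = q.front();
      q.pop();
      power += raw(i, j);
      if (j < jmin) jmin = j;
      if (j > jmax) jmax = j;
      const sword di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
      for (int k = 0; k < 4; ++k) {
        sword ii = i + di[k], jj = j + dj[k];
        if (ii < 0 || ii >= F || jj < 0 || jj >= T) continue;
        if (visited(ii, jj) || rel(ii, jj) < thr_rel) continue;
        visited(ii, jj) = 1;
        q.push({ii, jj});
      }
    }
    out.push_back({(double)(si + 1), (double)(sj + 1), (double)(jmin + 1),
                   (double)(jmax + 1), power, s.first});
  }

  mat res(out.size(), 6);
  for (uword r = 0; r < out.size(); ++r)
    for (uword c = 0; c < 6; ++c) res(r, c) = out[r][c];
  return res;
}
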