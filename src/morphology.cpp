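#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <queue>
using namespace Rcpp;

// All routines operate on 3D logical volumes in R's column-major layout
// (dims d1 x d2 x d3; a 2D image is passed with d3 = 1). Structuring
// elements / neighbourhoods arrive as an n x 3 integer matrix of offsets.

static inline int idx3(int i, int j, int k, int d1, int d2) {
  return i + d1 * (j + d2 * k);
}

// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   IntegerMatrix offsets) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims.size() > 2 ? dims[2] : 1;
  const int n = d1 * d2 * d3, noff = offsets.nrow();
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<int> queue;
  queue.reserve(1024);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = idx3(i, j, k, d1, d2);
        if (!mask[v] || lab[v]) continue;
        lab[v] = ++next;
        queue.clear();
        queue.push_back(v);
        while (!queue.empty()) {
          int cur = queue.back();
          queue.pop_back();
          int ci = cur % d1, cj = (cur / d1) % d2, ck = cur / (d1 * d2);
          for (int o = 0; o < noff; ++o) {
            int ni = ci + offsets(o, 0), nj = cj + offsets(o, 1),
                nk = ck + offsets(o, 2);
            if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3)
              continue;
            int nv = idx3(ni, nj, nk, d1, d2);
            if (mask[nv] && !lab[nv]) {
              lab[nv] = next;
              queue.push_back(nv);
            }
          }
        }
      }
  lab.attr("dim") = dims;
  return lab;
}

// Erosion: a voxel survives iff every offset lands inside the volume on a
// foreground voxel (outside counts as background).
// [[Rcpp::export(name = ".cpp_binary_erode")]]
LogicalVector cpp_binary_erode(LogicalVector mask, IntegerVector dims,
                               IntegerMatrix offsets) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims.size() > 2 ? dims[2] : 1;
  const int n = d1 * d2 * d3, noff = offsets.nrow();
  LogicalVector out(n, false);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = idx3(i, j, k, d1, d2);
        if (!mask[v]) continue;
        bool keep = true;
        for (int o = 0; o < noff && keep; ++o) {
          int ni = i + offsets(o, 0), nj = j + offsets(o, 1),
              nk = k + offsets(o, 2);
          if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3 ||
              !mask[idx3(ni, nj, nk, d1, d2)])
            keep = false;
        }
        out[v] = keep;
      }
  out.attr("dim") = dims;
  return out;
}

// [[Rcpp::export(name = ".cpp_binary_dilate")]]
LogicalVector cpp_binary_dilate(LogicalVector mask, IntegerVector dims,
                                IntegerMatrix offsets) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims.size() > 2 ? dims[2] : 1;
  const int n = d1 * d2 * d3, noff = offsets.nrow();
  LogicalVector out(n, false);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j)
      for (int i = 0; i < d1; ++i) {
        int v = idx3(i, j, k, d1, d2);
        if (!mask[v]) continue;
        for (int o = 0; o < noff; ++o) {
          int ni = i + offsets(o, 0), nj = j + offsets(o, 1),
              nk = k + offsets(o, 2);
          if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 || nk < 0 || nk >= d3)
            continue;
          out[idx3(ni, nj, nk, d1, d2)] = true;
        }
      }
  out.attr("dim") = dims;
  return out;
}

static inline int reflect(int i, int n) {
  // 'symmetric' boundary: ... 2 1 0 | 0 1 2 ... | n-1 n-2 ...
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Median filter over an arbitrary (odd-sized) neighbourhood given as
// offsets, with reflected edges.
// [[Rcpp::export(name = ".cpp_median_filter")]]
NumericMatrix cpp_median_filter(NumericMatrix img, IntegerMatrix offsets) {
  const int nr = img.nrow(), nc = img.ncol(), noff = offsets.nrow();
  NumericMatrix out(nr, nc);
  std::vector<double> window(noff);
  const int mid = noff / 2;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      for (int o = 0; o < noff; ++o) {
        int ri = reflect(i + offsets(o, 0), nr);
        int rj = reflect(j + offsets(o, 1), nc);
        window[o] = img(ri, rj);
      }
      std::nth_element(window.begin(), window.begin() + mid, window.end());
      out(i, j) = window[mid];
    }
  return out;
}
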