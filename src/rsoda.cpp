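#include <Rcpp.h>
#include <functional>
using namespace Rcpp;

// Separable convolution with a symmetric 1-D kernel inserted with holes
// (a-trous): taps are spaced `step` pixels apart. Reflective boundary.
// Applied along rows then columns.
// [[Rcpp::export(name = ".conv_sep")]]
NumericMatrix conv_sep(const NumericMatrix& img, const NumericVector& kernel,
                       const int step) {
  const int nr = img.nrow(), nc = img.ncol();
  const int kn = kernel.size();
  const int half = (kn - 1) / 2;
  NumericMatrix tmp(nr, nc), out(nr, nc);

  // reflect index into [0, n-1]
  auto reflect = [](int i, int n) {
    if (n == 1) return 0;
    const int period = 2 * n - 2;
    i = i % period;
    if (i < 0) i += period;
    return (i < n) ? i : period - i;
  };

  // along columns (vertical pass)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kn; ++t) {
        int ii = reflect(i + (t - half) * step, nr);
        acc += kernel[t] * img(ii, j);
      }
      tmp(i, j) = acc;
    }
  }
  // along rows (horizontal pass)
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double acc = 0.0;
      for (int t = 0; t < kn; ++t) {
        int jj = reflect(j + (t - half) * step, nc);
        acc += kernel[t] * tmp(i, jj);
      }
      out(i, j) = acc;
    }
  }
  return out;
}

// 8-connected component labelling of a logical matrix, two-pass union-find.
// Returns an integer matrix of labels (0 = background), labelled 1..n in
// raster order of first appearance.
// [[Rcpp::export(name = ".label_components")]]
IntegerMatrix label_components(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused

  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  auto unite = [&](int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  };

  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // neighbours already visited in column-major order:
      // (i-1, j), (i-1, j-1), (i, j-1), (i+1, j-1)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int lbl = 0;
      for (auto& n : nb) {
        if (n[0] < 0 || n[0] >= nr || n[1] < 0) continue;
        int l = lab(n[0], n[1]);
        if (l > 0) {
          if (lbl == 0) lbl = l;
          else unite(lbl, l);
        }
      }
      if (lbl == 0) {
        lbl = ++next;
        parent.push_back(lbl);
      }
      lab(i, j) = lbl;
    }
  }
  // second pass: flatten + relabel consecutively
  std::vector<int> remap(next + 1, 0);
  int nlab = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j) > 0) {
        int r = find(lab(i, j));
        if (remap[r] == 0) remap[r] = ++nlab;
        lab(i, j) = remap[r];
      }
  return lab;
}

// Chamfer (3,4)/3 distance transform to the background (mask == FALSE),
// in pixel units. Background pixels get 0. Two-pass algorithm; distances
// underestimate/overestimate Euclidean by at most ~8%, callers must keep
// a safety margin when using it as an exact bound.
// [[Rcpp::export(name = ".chamfer_dt")]]
NumericMatrix chamfer_dt(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG = 1e12, A = 1.0, D = 4.0 / 3.0;
  NumericMatrix d(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      d(i, j) = mask(i, j) ? BIG : 0.0;

  auto upd = [&](int i, int j, int ii, int jj, double w) {
    if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) {
      // outside the frame counts as background at distance w
      if (d(i, j) > w) d(i, j) = w;
      return;
    }
    if (d(i, j) > d(ii, jj) + w) d(i, j) = d(ii, jj) + w;
  };

  // forward pass
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      if (d(i, j) == 0.0) continue;
      upd(i, j, i - 1, j, A);
      upd(i, j, i, j - 1, A);
      upd(i, j, i - 1, j - 1, D);
      upd(i, j, i + 1, j - 1, D);
    }
  // backward pass
  for (int j = nc - 1; j >= 0; --j)
    for (int i = nr - 1; i >= 0; --i) {
      if (d(i, j) == 0.0) continue;
      upd(i, j, i + 1, j, A);
      upd(i, j, i, j + 1, A);
      upd(i, j, i + 1, j + 1, D);
      upd(i, j, i - 1, j + 1, D);
    }
  return d;
}
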