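// Raster kernels: exact Euclidean distance transform (Felzenszwalb &
// Huttenlocher two-pass parabolic envelope), nearest-point labelling with
// lowest-id tie-breaking, and 4-connected component labelling.
//
// All matrices are column-major with nrow = ny (rows, streamwise) and
// ncol = nx, matching R. Distances are computed between pixel centres on the
// integer grid and returned as *squared* integer distances where exactness
// matters for tie-breaking.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cstdint>

using namespace Rcpp;

static const double DINF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform of sampled function f, lower envelope of
// parabolas. n values; out[q] = min_p (q-p)^2 + f[p]; arg[q] = argmin p.
static void dt1d(const std::vector<double>& f, int n,
                 std::vector<double>& out, std::vector<int>& arg) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -DINF;
  z[1] = DINF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == DINF) continue;
    if (f[v[0]] == DINF) { v[0] = q; continue; }
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = DINF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == DINF) { out[q] = DINF; arg[q] = -1; continue; }
    while (z[k + 1] < q) ++k;
    double d = q - (double)v[k];
    out[q] = d * d + f[v[k]];
    arg[q] = v[k];
  }
}

// Exact squared Euclidean distance from every pixel to the nearest TRUE
// ("feature") pixel, plus the (row, col) of that nearest feature pixel.
// Returns list(dist2, row, col); row/col are 1-based, NA where no feature.
// [[Rcpp::export(name = ".edt_cpp")]]
List edt_cpp(LogicalMatrix feature) {
  int ny = feature.nrow(), nx = feature.ncol();
  // pass 1: per-column 1D transform along rows
  std::vector<double> d1(ny * (size_t)nx);
  std::vector<int> src_row(ny * (size_t)nx);
  std::vector<double> f(std::max(ny, nx)), out(std::max(ny, nx));
  std::vector<int> arg(std::max(ny, nx));
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) f[j] = feature(j, i) ? 0.0 : DINF;
    dt1d(f, ny, out, arg);
    for (int j = 0; j < ny; ++j) {
      d1[j + (size_t)ny * i] = out[j];
      src_row[j + (size_t)ny * i] = arg[j];
    }
  }
  // pass 2: per-row transform along columns
  NumericMatrix dist2(ny, nx);
  IntegerMatrix nr(ny, nx), nc(ny, nx);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) f[i] = d1[j + (size_t)ny * i];
    dt1d(f, nx, out, arg);
    for (int i = 0; i < nx; ++i) {
      if (arg[i] < 0) {
        dist2(j, i) = R_PosInf;
        nr(j, i) = NA_INTEGER;
        nc(j, i) = NA_INTEGER;
      } else {
        dist2(j, i) = out[i];
        nc(j, i) = arg[i] + 1;
        nr(j, i) = src_row[j + (size_t)ny * arg[i]] + 1;
      }
    }
  }
  return List::create(_["dist2"] = dist2, _["row"] = nr, _["col"] = nc);
}

// For every pixel, squared distance to the nearest of K points (rows, cols,
// 1-based) and the 1-based index of that point. Ties go to the lowest index.
// [[Rcpp::export(name = ".nearest_point_cpp")]]
List nearest_point_cpp(int ny, int nx, IntegerVector rows, IntegerVector cols) {
  int k = rows.size();
  NumericMatrix dist2(ny, nx);
  IntegerMatrix which(ny, nx);
  std::fill(dist2.begin(), dist2.end(), R_PosInf);
  std::fill(which.begin(), which.end(), NA_INTEGER);
  for (int p = 0; p < k; ++p) {
    double pr = rows[p] - 1, pc = cols[p] - 1;
    for (int i = 0; i < nx; ++i) {
      double dx = i - pc, dx2 = dx * dx;
      for (int j = 0; j < ny; ++j) {
        double dy = j - pr;
        double d2 = dx2 + dy * dy;
        if (d2 < dist2(j, i)) {  // strict: earlier (lower) index wins ties
          dist2(j, i) = d2;
          which(j, i) = p + 1;
        }
      }
    }
  }
  return List::create(_["dist2"] = dist2, _["which"] = which);
}

// 4-connected component labelling of TRUE pixels; 0 elsewhere.
// [[Rcpp::export(name = ".label4_cpp")]]
IntegerMatrix label4_cpp(LogicalMatrix mask) {
  int ny = mask.nrow(), nx = mask.ncol();
  IntegerMatrix lab(ny, nx);
  std::fill(lab.begin(), lab.end(), 0);
  int next = 0;
  std::vector<std::pair<int, int> > stack;
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      if (!mask(j, i) || lab(j, i)) continue;
      ++next;
      stack.push_back(std::make_pair(j, i));
      lab(j, i) = next;
      while (!stack.empty()) {
        int cj = stack.back().first, ci = stack.back().second;
        stack.pop_back();
        const int dj[4] = {-1, 1, 0, 0}, di[4] = {0, 0, -1, 1};
        for (int d = 0; d < 4; ++d) {
          int aj = cj + dj[d], ai = ci + di[d];
          if (aj < 0 || aj >= ny || ai < 0 || ai >= nx) continue;
          if (mask(aj, ai) && !lab(aj, ai)) {
            lab(aj, ai) = next;
            stack.push_back(std::make_pair(aj, ai));
          }
        }
      }
    }
  }
  return lab;
}
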