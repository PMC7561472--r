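#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF_ = std::numeric_limits<double>::infinity();

// Cube corner offsets (dim1, dim2, dim3) and a 6-tetrahedron decomposition
// sharing the 0-6 main diagonal; face diagonals are consistent between
// neighbouring cubes, so the triangulated isosurface is crack-free.
static const int OFF[8][3] = {
  {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}
};
static const int TETS[6][4] = {
  {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}
};

// Marching tetrahedra over a scalar field (column-major 3D array).
// Vertex of voxel (i,j,k) (0-based) sits at physical (i*s1, j*s2, k*s3).
// Returns an ntri x 9 matrix: each row one triangle, three vertices in
// dim-order coordinates.
// [[Rcpp::export]]
NumericMatrix mt_triangles_cpp(NumericVector field, NumericVector spacing,
                               double level) {
  IntegerVector dims = field.attr("dim");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double s1 = spacing[0], s2 = spacing[1], s3 = spacing[2];
  std::vector<double> out;
  out.reserve(1 << 14);
  double cv[8];
  double cp[8][3];

  for (int k = 0; k < d3 - 1; ++k) {
    for (int j = 0; j < d2 - 1; ++j) {
      for (int i = 0; i < d1 - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          const int ii = i + OFF[c][0], jj = j + OFF[c][1], kk = k + OFF[c][2];
          cv[c] = field[(size_t)ii + (size_t)d1 * ((size_t)jj + (size_t)d2 * kk)];
          cp[c][0] = ii * s1; cp[c][1] = jj * s2; cp[c][2] = kk * s3;
          if (cv[c] >= level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          int vin[4], vout[4], nin = 0, nout = 0;
          for (int m = 0; m < 4; ++m) {
            const int c = TETS[t][m];
            if (cv[c] >= level) vin[nin++] = c; else vout[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;

          auto interp = [&](int a, int b, double* p) {
            const double fa = cv[a], fb = cv[b];
            const double tt = (level - fa) / (fb - fa);
            for (int d = 0; d < 3; ++d) p[d] = cp[a][d] + tt * (cp[b][d] - cp[a][d]);
          };
          double p1[3], p2[3], p3[3], p4[3];
          if (nin == 1 || nin == 3) {
            const int a = (nin == 1) ? vin[0] : vout[0];
            const int* o = (nin == 1) ? vout : vin;
            interp(a, o[0], p1); interp(a, o[1], p2); interp(a, o[2], p3);
            for (double* p : {p1, p2, p3})
              for (int d = 0; d < 3; ++d) out.push_back(p[d]);
          } else { // 2 in / 2 out: quad split into two triangles
            const int a = vin[0], b = vin[1], c = vout[0], dd = vout[1];
            interp(a, c, p1); interp(a, dd, p2); interp(b, dd, p3); interp(b, c, p4);
            for (double* p : {p1, p2, p3})
              for (int d = 0; d < 3; ++d) out.push_back(p[d]);
            for (double* p : {p1, p3, p4})
              for (int d = 0; d < 3; ++d) out.push_back(p[d]);
          }
        }
      }
    }
  }

  const int ntri = (int)(out.size() / 9);
  NumericMatrix M(ntri, 9);
  for (int r = 0; r < ntri; ++r)
    for (int c = 0; c < 9; ++c)
      M(r, c) = out[9 * (size_t)r + c];
  return M;
}

// 1D squared-distance transform (Felzenszwalb & Huttenlocher lower envelope)
// with grid step s; f holds squared distances on input and output.
static void dt1d(std::vector<double>& f, double s) {
  const int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1), d(n);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF_) continue;
    double sx = 0.0;
    while (k >= 0) {
      const double qs = q * s, vs = v[k] * s;
      sx = ((f[q] + qs * qs) - (f[v[k]] + vs * vs)) / (2.0 * qs - 2.0 * vs);
      if (sx <= z[k]) --k; else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF_; z[1] = INF_; }
    else { ++k; v[k] = q; z[k] = sx; z[k + 1] = INF_; }
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF_;
  } else {
    int kk = 0;
    for (int q = 0; q < n; ++q) {
      const double qs = q * s;
      while (z[kk + 1] < qs) ++kk;
      const double diff = qs - v[kk] * s;
      d[q] = diff * diff + f[v[kk]];
    }
  }
  f.swap(d);
}

// Exact anisotropic 3D Euclidean distance transform: distance from every
// voxel centre to the nearest TRUE voxel centre of `mask`.
// [[Rcpp::export]]
NumericVector edt3d_cpp(LogicalVector mask, NumericVector spacing) {
  IntegerVector dims = mask.attr("dim");
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const size_t N = (size_t)d1 * d2 * d3;
  std::vector<double> D(N);
  for (size_t i = 0; i < N; ++i) D[i] = mask[i] ? 0.0 : INF_;

  std::vector<double> line;
  // pass along dim 1
  line.resize(d1);
  for (int k = 0; k < d3; ++k)
    for (int j = 0; j < d2; ++j) {
      const size_t base = (size_t)d1 * ((size_t)j + (size_t)d2 * k);
      for (int i = 0; i < d1; ++i) line[i] = D[base + i];
      dt1d(line, spacing[0]);
      for (int i = 0; i < d1; ++i) D[base + i] = line[i];
    }
  // pass along dim 2
  line.resize(d2);
  for (int k = 0; k < d3; ++k)
    for (int i = 0; i < d1; ++i) {
      const size_t base = (size_t)i + (size_t)d1 * (size_t)d2 * k;
      for (int j = 0; j < d2; ++j) line[j] = D[base + (size_t)d1 * j];
      dt1d(line, spacing[1]);
      for (int j = 0; j < d2; ++j) D[base + (size_t)d1 * j] = line[j];
    }
  // pass along dim 3
  line.resize(d3);
  const size_t stride3 = (size_t)d1 * d2;
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      const size_t base = (size_t)i + (size_t)d1 * j;
      for (int k = 0; k < d3; ++k) line[k] = D[base + stride3 * k];
      dt1d(line, spacing[2]);
      for (int k = 0; k < d3; ++k) D[base + stride3 * k] = line[k];
    }

  NumericVector out(N);
  for (size_t i = 0; i < N; ++i) out[i] = std::sqrt(D[i]);
  out.attr("dim") = dims;
  return out;
}

// For each row of A (n x 3), the minimum Euclidean distance to any row of B.
// [[Rcpp::export]]
NumericVector min_cross_dist_cpp(NumericMatrix A, NumericMatrix B) {
  const int nA = A.nrow(), nB = B.nrow();
  NumericVector out(nA);
  if (nB == 0) { std::fill(out.begin(), out.end(), R_PosInf); return out; }
  std::vector<double> bx(nB), by(nB), bz(nB);
  for (int j = 0; j < nB; ++j) { bx[j] = B(j,0); by[j] = B(j,1); bz[j] = B(j,2); }
  for (int i = 0; i < nA; ++i) {
    const double ax = A(i,0), ay = A(i,1), az = A(i,2);
    double best = R_PosInf;
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - bx[j];
      double d = dx * dx;
      if (d >= best) continue;
      const double dy = ay - by[j];
      d += dy * dy;
      if (d >= best) continue;
      const double dz = az - bz[j];
      d += dz * dz;
      if (d < best) best = d;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
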