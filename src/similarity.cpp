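#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Point-set Hausdorff distance between streamlines: no segment
// interpolation, the distance is taken over the stored polyline vertices.
// Points are handled as contiguous xyz triples for speed.

static double one_sided_hd(const double* a, int na, const double* b, int nb) {
  double maxmin = 0.0;
  for (int i = 0; i < na; ++i) {
    const double ax = a[3 * i], ay = a[3 * i + 1], az = a[3 * i + 2];
    double best = R_PosInf;
    for (int j = 0; j < nb; ++j) {
      const double dx = ax - b[3 * j];
      const double dy = ay - b[3 * j + 1];
      const double dz = az - b[3 * j + 2];
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    if (best > maxmin) maxmin = best;
  }
  return maxmin;
}

static void flatten(const NumericMatrix& m, std::vector<double>& out) {
  const int n = m.nrow();
  out.resize(3 * n);
  for (int i = 0; i < n; ++i) {
    out[3 * i] = m(i, 0);
    out[3 * i + 1] = m(i, 1);
    out[3 * i + 2] = m(i, 2);
  }
}

// [[Rcpp::export]]
double cpp_hausdorff(NumericMatrix a, NumericMatrix b) {
  std::vector<double> fa, fb;
  flatten(a, fa);
  flatten(b, fb);
  const double d2 = std::max(
    one_sided_hd(fa.data(), a.nrow(), fb.data(), b.nrow()),
    one_sided_hd(fb.data(), b.nrow(), fa.data(), a.nrow()));
  return std::sqrt(d2);
}

// Lower-triangle rows of the pairwise Hausdorff matrix. `rows` are 1-based
// tract indices; for row i the vector holds d(i, j) for j = 1..i-1.
// [[Rcpp::export]]
List cpp_hd_rows(List tracts, IntegerVector rows) {
  const int n = tracts.size();
  std::vector<std::vector<double> > pts(n);
  std::vector<int> npts(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix m = tracts[i];
    npts[i] = m.nrow();
    flatten(m, pts[i]);
  }
  const int nr = rows.size();
  List out(nr);
  for (int r = 0; r < nr; ++r) {
    const int i = rows[r] - 1;
    NumericVector row(i);
    const double* a = pts[i].data();
    for (int j = 0; j < i; ++j) {
      const double d2 = std::max(
        one_sided_hd(a, npts[i], pts[j].data(), npts[j]),
        one_sided_hd(pts[j].data(), npts[j], a, npts[i]));
      row[j] = std::sqrt(d2);
    }
    out[r] = row;
  }
  return out;
}
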