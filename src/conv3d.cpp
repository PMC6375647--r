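// Dense 3D "valid" convolution used by the voxel CNN.
//
// Arrays follow R's column-major layout: inputs are (N1,N2,N3,Cin),
// weights (k,k,k,Cin,Cout), outputs (M1,M2,M3,Cout) with Mi = Ni - k + 1.
// The convolution is evaluated as a sum of k^3 shifted GEMMs, which keeps
// the working set small (one Mflat x Cin buffer) while all heavy lifting
// goes through BLAS.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Dims4 {
  int n1, n2, n3, c;
};

Dims4 get_dims4(const NumericVector& x, const char* what) {
  IntegerVector d = x.attr("dim");
  if (d.size() != 4) stop("%s must be a 4-d array", what);
  return Dims4{d[0], d[1], d[2], d[3]};
}

// Copy x[(o1+d1, o2+d2, o3+d3, c)] for all output positions into
// the Mflat x Cin matrix `buf` (one column per input channel).
void fill_shifted(const double* x, const Dims4& xd,
                  int m1, int m2, int m3,
                  int d1, int d2, int d3, arma::mat& buf) {
  const int cin = xd.c;
  for (int c = 0; c < cin; ++c) {
    double* dst = buf.colptr(c);
    for (int o3 = 0; o3 < m3; ++o3) {
      for (int o2 = 0; o2 < m2; ++o2) {
        const double* src = x + (size_t)(d1) +
          (size_t)xd.n1 * ((o2 + d2) + (size_t)xd.n2 * ((o3 + d3) + (size_t)xd.n3 * c));
        std::memcpy(dst, src, sizeof(double) * m1);
        dst += m1;
      }
    }
  }
}

// Scatter-add `buf` (Mflat x Cin) back into gx at the shifted positions.
void scatter_shifted(double* gx, const Dims4& xd,
                     int m1, int m2, int m3,
                     int d1, int d2, int d3, const arma::mat& buf) {
  const int cin = xd.c;
  for (int c = 0; c < cin; ++c) {
    const double* src = buf.colptr(c);
    for (int o3 = 0; o3 < m3; ++o3) {
      for (int o2 = 0; o2 < m2; ++o2) {
        double* dst = gx + (size_t)(d1) +
          (size_t)xd.n1 * ((o2 + d2) + (size_t)xd.n2 * ((o3 + d3) + (size_t)xd.n3 * c));
        for (int o1 = 0; o1 < m1; ++o1) dst[o1] += src[o1];
        src += m1;
      }
    }
  }
}

arma::mat weight_slice(const double* w, int k, int cin, int cout,
                       int d1, int d2, int d3) {
  arma::mat wd(cin, cout);
  for (int co = 0; co < cout; ++co)
    for (int ci = 0; ci < cin; ++ci)
      wd(ci, co) = w[d1 + (size_t)k * (d2 + (size_t)k * (d3 + (size_t)k * (ci + (size_t)cin * co)))];
  return wd;
}

} // namespace

// Voxelized pockets leave most of the input cube empty, so the first
// convolution usually sees a highly sparse input.  Below this density the
// gather/scatter path over nonzero entries beats the dense GEMM.
static const double kSparseThreshold = 0.08;

namespace {

struct NzEntry {
  int i1, i2, i3, c;
  double v;
};

std::vector<NzEntry> nonzeros(const double* x, const Dims4& xd) {
  std::vector<NzEntry> nz;
  size_t idx = 0;
  for (int c = 0; c < xd.c; ++c)
    for (int i3 = 0; i3 < xd.n3; ++i3)
      for (int i2 = 0; i2 < xd.n2; ++i2)
        for (int i1 = 0; i1 < xd.n1; ++i1, ++idx)
          if (x[idx] != 0.0) nz.push_back(NzEntry{i1, i2, i3, c, x[idx]});
  return nz;
}

} // namespace

// [[Rcpp::export(name = ".conv3d_forward")]]
NumericVector conv3d_forward(NumericVector x, NumericVector w, NumericVector b) {
  Dims4 xd = get_dims4(x, "x");
  IntegerVector wd5 = w.attr("dim");
  if (wd5.size() != 5) stop("w must be a 5-d array");
  const int k = wd5[0], cin = wd5[3], cout = wd5[4];
  if (wd5[1] != k || wd5[2] != k) stop("kernel must be cubic");
  if (cin != xd.c) stop("input channel mismatch");
  const int m1 = xd.n1 - k + 1, m2 = xd.n2 - k + 1, m3 = xd.n3 - k + 1;
  if (m1 <= 0 || m2 <= 0 || m3 <= 0) stop("kernel larger than input");
  if (b.size() != cout) stop("bias length mismatch");

  const size_t mflat = (size_t)m1 * m2 * m3;
  arma::mat Y(mflat, cout);
  for (int co = 0; co < cout; ++co) Y.col(co).fill(b[co]);

  std::vector<NzEntry> nz = nonzeros(REAL(x), xd);
  if ((double)nz.size() < kSparseThreshold * x.size()) {
    // scatter each nonzero input into the outputs it contributes to
    const double* wp = REAL(w);
    const size_t wstride_ci = (size_t)k * k * k;
    for (const NzEntry& e : nz) {
      for (int d3 = std::max(0, e.i3 - m3 + 1); d3 <= std::min(k - 1, e.i3); ++d3)
        for (int d2 = std::max(0, e.i2 - m2 + 1); d2 <= std::min(k - 1, e.i2); ++d2)
          for (int d1 = std::max(0, e.i1 - m1 + 1); d1 <= std::min(k - 1, e.i1); ++d1) {
            const size_t of = (size_t)(e.i1 - d1) +
              (size_t)m1 * ((e.i2 - d2) + (size_t)m2 * (e.i3 - d3));
            const size_t wbase = d1 + (size_t)k * (d2 + (size_t)k * d3) +
              wstride_ci * e.c;
            for (int co = 0; co < cout; ++co)
              Y(of, co) += e.v * wp[wbase + wstride_ci * (size_t)cin * co];
          }
    }
  } else {
    arma::mat buf(mflat, cin);
    for (int d3 = 0; d3 < k; ++d3)
      for (int d2 = 0; d2 < k; ++d2)
        for (int d1 = 0; d1 < k; ++d1) {
          fill_shifted(REAL(x), xd, m1, m2, m3, d1, d2, d3, buf);
          Y += buf * weight_slice(REAL(w), k, cin, cout, d1, d2, d3);
        }
  }

  NumericVector out(Y.begin(), Y.end());
  out.attr("dim") = IntegerVector::create(m1, m2, m3, cout);
  return out;
}

// [[Rcpp::export(name = ".conv3d_backward")]]
List conv3d_backward(NumericVector x, NumericVector w, NumericVector gy,
                     bool want_gx) {
  Dims4 xd = get_dims4(x, "x");
  Dims4 gd = get_dims4(gy, "gy");
  IntegerVector wd5 = w.attr("dim");
  const int k = wd5[0], cin = wd5[3], cout = wd5[4];
  const int m1 = xd.n1 - k + 1, m2 = xd.n2 - k + 1, m3 = xd.n3 - k + 1;
  if (gd.n1 != m1 || gd.n2 != m2 || gd.n3 != m3 || gd.c != cout)
    stop("gy shape mismatch");

  const size_t mflat = (size_t)m1 * m2 * m3;
  const arma::mat GY(REAL(gy), mflat, cout, false, true);

  NumericVector gw(w.size());
  gw.attr("dim") = wd5;
  NumericVector gb(cout);
  for (int co = 0; co < cout; ++co) gb[co] = arma::accu(GY.col(co));

  NumericVector gx;
  if (want_gx) {
    gx = NumericVector(x.size());
    gx.attr("dim") = IntegerVector::create(xd.n1, xd.n2, xd.n3, xd.c);
  }

  std::vector<NzEntry> nz = nonzeros(REAL(x), xd);
  if (!want_gx && (double)nz.size() < kSparseThreshold * x.size()) {
    double* gwp = REAL(gw);
    const size_t wstride_ci = (size_t)k * k * k;
    for (const NzEntry& e : nz) {
      for (int d3 = std::max(0, e.i3 - m3 + 1); d3 <= std::min(k - 1, e.i3); ++d3)
        for (int d2 = std::max(0, e.i2 - m2 + 1); d2 <= std::min(k - 1, e.i2); ++d2)
          for (int d1 = std::max(0, e.i1 - m1 + 1); d1 <= std::min(k - 1, e.i1); ++d1) {
            const size_t of = (size_t)(e.i1 - d1) +
              (size_t)m1 * ((e.i2 - d2) + (size_t)m2 * (e.i3 - d3));
            const size_t wbase = d1 + (size_t)k * (d2 + (size_t)k * d3) +
              wstride_ci * e.c;
            for (int co = 0; co < cout; ++co)
              gwp[wbase + wstride_ci * (size_t)cin * co] += e.v * GY(of, co);
          }
    }
  } else {
    arma::mat buf(mflat, cin);
    for (int d3 = 0; d3 < k; ++d3)
      for (int d2 = 0; d2 < k; ++d2)
        for (int d1 = 0; d1 < k; ++d1) {
          fill_shifted(REAL(x), xd, m1, m2, m3, d1, d2, d3, buf);
          arma::mat gwd = buf.t() * GY; // cin x cout
          for (int co = 0; co < cout; ++co)
            for (int ci = 0; ci < cin; ++ci)
              gw[d1 + (size_t)k * (d2 + (size_t)k * (d3 + (size_t)k * (ci + (size_t)cin * co)))] =
                gwd(ci, co);
          if (want_gx) {
            arma::mat gxd = GY * weight_slice(REAL(w), k, cin, cout, d1, d2, d3).t();
            scatter_shifted(REAL(gx), xd, m1, m2, m3, d1, d2, d3, gxd);
          }
        }
  }

  List out = List::create(_["gw"] = gw, _["gb"] = gb);
  if (want_gx) out["gx"] = gx;
  return out;
}
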