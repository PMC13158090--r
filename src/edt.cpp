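#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas), weight w is
// the squared voxel spacing along this axis. f holds squared distances in,
// d squared distances out.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n, double w) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double s = 0.0;
        while (true) {
            int p = v[k];
            s = ((f[q] + w * q * q) - (f[p] + w * p * p)) / (2.0 * w * (q - p));
            if (s <= z[k] && k > 0) {
                --k;
            } else {
                break;
            }
        }
        ++k;
        v[k] = q;
        z[k] = s;
        z[k + 1] = INF;
    }
    k = 0;
    for (int q = 0; q < n; ++q) {
        while (z[k + 1] < q) ++k;
        int p = v[k];
        double dq = (double)(q - p);
        d[q] = w * dq * dq + f[p];
    }
}

// Squared Euclidean distance from every voxel to the nearest feature voxel
// centre, with per-axis spacing (mm). Column-major layout matching R arrays.
// [[Rcpp::export]]
NumericVector edt3d_sq(LogicalVector feature, IntegerVector dims,
                       NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double LARGE = 1e300;
    NumericVector out(nx * (R_xlen_t)ny * nz);
    for (R_xlen_t i = 0; i < out.size(); ++i)
        out[i] = feature[i] ? 0.0 : LARGE;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    double wx = spacing[0] * spacing[0];
    double wy = spacing[1] * spacing[1];
    double wz = spacing[2] * spacing[2];

    // pass along x
    for (int zi = 0; zi < nz; ++zi)
        for (int yi = 0; yi < ny; ++yi) {
            R_xlen_t base = (R_xlen_t)nx * (yi + (R_xlen_t)ny * zi);
            for (int xi = 0; xi < nx; ++xi) f[xi] = out[base + xi];
            dt1d(f, d, v, z, nx, wx);
            for (int xi = 0; xi < nx; ++xi) out[base + xi] = d[xi];
        }
    // pass along y
    for (int zi = 0; zi < nz; ++zi)
        for (int xi = 0; xi < nx; ++xi) {
            R_xlen_t base = xi + (R_xlen_t)nx * ny * (R_xlen_t)zi;
            for (int yi = 0; yi < ny; ++yi) f[yi] = out[base + (R_xlen_t)nx * yi];
            dt1d(f, d, v, z, ny, wy);
            for (int yi = 0; yi < ny; ++yi) out[base + (R_xlen_t)nx * yi] = d[yi];
        }
    // pass along z
    R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int yi = 0; yi < ny; ++yi)
        for (int xi = 0; xi < nx; ++xi) {
            R_xlen_t base = xi + (R_xlen_t)nx * yi;
            for (int zi = 0; zi < nz; ++zi) f[zi] = out[base + nxy * zi];
            dt1d(f, d, v, z, nz, wz);
            for (int zi = 0; zi < nz; ++zi) out[base + nxy * zi] = d[zi];
        }

    out.attr("dim") = dims;
    return out;
}
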