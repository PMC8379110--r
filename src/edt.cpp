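#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

// Exact squared Euclidean distance transform of a 3D binary volume with
// anisotropic voxel spacing, computed separably one axis at a time with the
// lower-envelope-of-parabolas algorithm (Felzenszwalb & Huttenlocher).
// Distances are between voxel centers, in physical units (mm).

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared distance transform of sampled function f on a grid with step s.
// d[q] = min_p ( s^2 (q-p)^2 + f[p] )
static void dt1d(const double *f, double *d, int n, double s2,
                 std::vector<int> &v, std::vector<double> &z) {
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        if (f[q] == INF) continue;
        if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
        double sq = s2 * q * q;
        double inter;
        while (true) {
            int p = v[k];
            inter = (f[q] + sq - f[p] - s2 * p * p) / (2.0 * s2 * (q - p));
            if (inter <= z[k]) { --k; } else break;
        }
        ++k;
        v[k] = q;
        z[k] = inter;
        z[k + 1] = INF;
    }
    int kk = 0;
    for (int q = 0; q < n; ++q) {
        if (f[v[0]] == INF) { d[q] = INF; continue; }
        while (z[kk + 1] < q) ++kk;
        int p = v[kk];
        d[q] = s2 * (q - p) * (q - p) + f[p];
    }
}

// [[Rcpp::export(name = ".edt_sq")]]
Rcpp::NumericVector edt_sq(Rcpp::IntegerVector mask, Rcpp::IntegerVector dims,
                           Rcpp::NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const double sx2 = spacing[0] * spacing[0];
    const double sy2 = spacing[1] * spacing[1];
    const double sz2 = spacing[2] * spacing[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;

    Rcpp::NumericVector out(n);
    double *g = REAL(out);
    for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] != 0 ? 0.0 : INF;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // axis 1 (fastest-varying index)
    for (int kzy = 0; kzy < ny * nz; ++kzy) {
        double *col = g + (R_xlen_t)kzy * nx;
        dt1d(col, d.data(), nx, sx2, v, z);
        for (int i = 0; i < nx; ++i) col[i] = d[i];
    }
    // axis 2
    for (int kz = 0; kz < nz; ++kz) {
        for (int ix = 0; ix < nx; ++ix) {
            R_xlen_t base = (R_xlen_t)kz * nx * ny + ix;
            for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)j * nx];
            dt1d(f.data(), d.data(), ny, sy2, v, z);
            for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)j * nx] = d[j];
        }
    }
    // axis 3
    const R_xlen_t stride = (R_xlen_t)nx * ny;
    for (R_xlen_t kxy = 0; kxy < stride; ++kxy) {
        for (int kz = 0; kz < nz; ++kz) f[kz] = g[kxy + (R_xlen_t)kz * stride];
        dt1d(f.data(), d.data(), nz, sz2, v, z);
        for (int kz = 0; kz < nz; ++kz) g[kxy + (R_xlen_t)kz * stride] = d[kz];
    }

    out.attr("dim") = dims;
    return out;
}
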