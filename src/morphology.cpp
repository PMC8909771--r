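#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Squared Euclidean distance transform of a 3-D grid, spacing-aware.
// Felzenszwalb & Huttenlocher lower-envelope algorithm applied separably
// along each axis; exact for the squared metric, so margins built from it
// carry no chamfer error.  Distances are measured between voxel centers.

static const double BIG = 1e15;

static void dt1d(std::vector<double> &f, std::vector<double> &d, int n,
                 double w2, std::vector<double> &z, std::vector<int> &v) {
    const double INF = std::numeric_limits<double>::infinity();
    int k = 0;
    v[0] = 0;
    z[0] = -INF;
    z[1] = INF;
    for (int q = 1; q < n; ++q) {
        double fq = f[q] + w2 * (double)q * q;
        double s;
        while (true) {
            double fv = f[v[k]] + w2 * (double)v[k] * v[k];
            s = (fq - fv) / (2.0 * w2 * (q - v[k]));
            if (s <= z[k]) {
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
        double dq = (double)q - v[k];
        d[q] = w2 * dq * dq + f[v[k]];
    }
}

// [[Rcpp::export(name = ".edt_squared")]]
NumericVector edt_squared(LogicalVector bits, IntegerVector dims,
                          NumericVector spacing) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    NumericVector D(n);
    for (R_xlen_t i = 0; i < n; ++i) D[i] = bits[i] ? 0.0 : BIG;

    int nmax = std::max(nx, std::max(ny, nz));
    std::vector<double> f(nmax), d(nmax), z(nmax + 1);
    std::vector<int> v(nmax);

    // x axis (fastest-varying)
    {
        double w2 = spacing[0] * spacing[0];
        for (int kz = 0; kz < nz; ++kz) {
            for (int ky = 0; ky < ny; ++ky) {
                R_xlen_t base = ((R_xlen_t)kz * ny + ky) * nx;
                for (int i = 0; i < nx; ++i) f[i] = D[base + i];
                dt1d(f, d, nx, w2, z, v);
                for (int i = 0; i < nx; ++i) D[base + i] = d[i];
            }
        }
    }
    // y axis
    {
        double w2 = spacing[1] * spacing[1];
        for (int kz = 0; kz < nz; ++kz) {
            for (int kx = 0; kx < nx; ++kx) {
                R_xlen_t base = (R_xlen_t)kz * ny * nx + kx;
                for (int j = 0; j < ny; ++j) f[j] = D[base + (R_xlen_t)j * nx];
                dt1d(f, d, ny, w2, z, v);
                for (int j = 0; j < ny; ++j) D[base + (R_xlen_t)j * nx] = d[j];
            }
        }
    }
    // z axis
    {
        double w2 = spacing[2] * spacing[2];
        R_xlen_t sxy = (R_xlen_t)nx * ny;
        for (int ky = 0; ky < ny; ++ky) {
            for (int kx = 0; kx < nx; ++kx) {
                R_xlen_t base = (R_xlen_t)ky * nx + kx;
                for (int k = 0; k < nz; ++k) f[k] = D[base + (R_xlen_t)k * sxy];
                dt1d(f, d, nz, w2, z, v);
                for (int k = 0; k < nz; ++k) D[base + (R_xlen_t)k * sxy] = d[k];
            }
        }
    }
    for (R_xlen_t i = 0; i < n; ++i) {
        if (D[i] >= BIG / 2.0) D[i] = R_PosInf;
    }
    return D;
}

// 6-connected component labelling of a 3-D logical grid; labels are
// assigned in raster-scan order of the first voxel reached, so the
// result is deterministic.

// [[Rcpp::export(name = ".label_components6")]]
IntegerVector label_components6(LogicalVector bits, IntegerVector dims) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const R_xlen_t n = (R_xlen_t)nx * ny * nz;
    const R_xlen_t sxy = (R_xlen_t)nx * ny;
    IntegerVector lab(n);
    std::vector<R_xlen_t> stack;
    int cur = 0;
    for (R_xlen_t s = 0; s < n; ++s) {
        if (!bits[s] || lab[s] != 0) continue;
        ++cur;
        lab[s] = cur;
        stack.push_back(s);
        while (!stack.empty()) {
            R_xlen_t p = stack.back();
            stack.pop_back();
            int x = (int)(p % nx);
            R_xlen_t r = p / nx;
            int y = (int)(r % ny);
            int zz = (int)(r / ny);
            if (x > 0) {
                R_xlen_t q = p - 1;
                if (bits[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
            if (x < nx - 1) {
                R_xlen_t q = p + 1;
                if (bits[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
            if (y > 0) {
                R_xlen_t q = p - nx;
                if (bits[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
            if (y < ny - 1) {
                R_xlen_t q = p + nx;
                if (bits[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
            if (zz > 0) {
                R_xlen_t q = p - sxy;
                if (bits[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
            if (zz < nz - 1) {
                R_xlen_t q = p + sxy;
                if (bits[q] && lab[q] == 0) { lab[q] = cur; stack.push_back(q); }
            }
        }
    }
    return lab;
}
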