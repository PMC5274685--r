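#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform lower envelope (Felzenszwalb & Huttenlocher).
// f: input costs (0 at sources, INF elsewhere); d: output min_j f[j] + (i-j)^2.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z) {
    const int n = (int)f.size();
    int k = -1;
    for (int q = 0; q < n; ++q) {
        if (f[q] == INF) continue;
        if (k < 0) {
            k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
            continue;
        }
        double s;
        while (true) {
            int p = v[k];
            s = ((f[q] + (double)q * q) - (f[p] + (double)p * p)) /
                (2.0 * q - 2.0 * p);
            if (s <= z[k]) {
                --k;
                if (k < 0) break;
            } else break;
        }
        if (k < 0) {
            k = 0; v[0] = q; z[0] = -INF;
        } else {
            ++k; v[k] = q; z[k] = s;
        }
        z[k + 1] = INF;
    }
    if (k < 0) {
        for (int q = 0; q < n; ++q) d[q] = INF;
        return;
    }
    int j = 0;
    for (int q = 0; q < n; ++q) {
        while (z[j + 1] < q) ++j;
        double dq = (double)q - v[j];
        d[q] = dq * dq + f[v[j]];
    }
}

// One separable pass along an axis; wrap => periodic distances via 3x tiling.
static void pass_axis(std::vector<double>& d, int nx, int ny, int nz,
                      int axis, bool wrap) {
    int L = (axis == 0) ? nx : (axis == 1) ? ny : nz;
    int stride = (axis == 0) ? 1 : (axis == 1) ? nx : nx * ny;
    int n1 = (axis == 0) ? ny : nx;
    int s1 = (axis == 0) ? nx : 1;
    int n2 = (axis == 2) ? ny : nz;
    int s2 = (axis == 2) ? nx : nx * ny;
    int buflen = wrap ? 3 * L : L;
    std::vector<double> f(buflen), out(buflen);
    std::vector<int> v(buflen);
    std::vector<double> z(buflen + 1);
    for (int b = 0; b < n2; ++b) {
        for (int a = 0; a < n1; ++a) {
            int base = a * s1 + b * s2;
            if (wrap) {
                for (int i = 0; i < L; ++i) {
                    double val = d[base + i * stride];
                    f[i] = f[i + L] = f[i + 2 * L] = val;
                }
                dt1d(f, out, v, z);
                for (int i = 0; i < L; ++i)
                    d[base + i * stride] = out[i + L];
            } else {
                for (int i = 0; i < L; ++i) f[i] = d[base + i * stride];
                dt1d(f, out, v, z);
                for (int i = 0; i < L; ++i) d[base + i * stride] = out[i];
            }
        }
    }
}

// Squared Euclidean distance (in voxels) from every TRUE voxel to the
// nearest FALSE voxel centre. FALSE voxels get 0. Voxels of a phase with no
// complement anywhere get Inf. wrap: per-axis periodic boundary.
// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector vol, IntegerVector dims,
                         LogicalVector wrap) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    size_t n = (size_t)nx * ny * nz;
    std::vector<double> d(n);
    for (size_t i = 0; i < n; ++i) d[i] = vol[i] ? INF : 0.0;
    pass_axis(d, nx, ny, nz, 0, wrap[0]);
    pass_axis(d, nx, ny, nz, 1, wrap[1]);
    pass_axis(d, nx, ny, nz, 2, wrap[2]);
    NumericVector res(n);
    for (size_t i = 0; i < n; ++i) res[i] = d[i];
    res.attr("dim") = dims;
    return res;
}

// Local thickness map (Hildebrand-Ruegsegger): for every phase voxel the
// diameter of the largest inscribed sphere containing it. Sphere radii are
// centre-to-centre EDT distances (sqrt(edt_sq)); this convention is exact
// for even-width slabs and within one voxel elsewhere. Returns diameters
// in voxel units; non-phase voxels get 0.
// [[Rcpp::export]]
NumericVector local_thickness_cpp(NumericVector dt2, IntegerVector dims,
                                  LogicalVector wrap) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    size_t n = (size_t)nx * ny * nz;
    std::vector<double> r(n, 0.0);
    for (size_t i = 0; i < n; ++i)
        if (dt2[i] > 0.0) r[i] = std::sqrt(dt2[i]);

    bool wx = wrap[0], wy = wrap[1], wz = wrap[2];
    std::vector<double> out(n, 0.0);
    // redundancy prune: sphere at c is inside a 26-neighbour's sphere
    auto idx = [&](int x, int y, int z) -> size_t {
        return (size_t)x + (size_t)nx * (y + (size_t)ny * z);
    };
    for (int z0 = 0; z0 < nz; ++z0)
    for (int y0 = 0; y0 < ny; ++y0)
    for (int x0 = 0; x0 < nx; ++x0) {
        double rc = r[idx(x0, y0, z0)];
        if (rc <= 0.0 && dt2[idx(x0, y0, z0)] <= 0.0) continue;
        bool contained = false;
        for (int dz = -1; dz <= 1 && !contained; ++dz)
        for (int dy = -1; dy <= 1 && !contained; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int x = x0 + dx, y = y0 + dy, z = z0 + dz;
            if (wx) x = (x + nx) % nx; else if (x < 0 || x >= nx) continue;
            if (wy) y = (y + ny) % ny; else if (y < 0 || y >= ny) continue;
            if (wz) z = (z + nz) % nz; else if (z < 0 || z >= nz) continue;
            double ru = r[idx(x, y, z)];
            if (ru >= rc + std::sqrt((double)(dx*dx + dy*dy + dz*dz)) - 1e-9) {
                contained = true;
                break;
            }
        }
        if (contained) continue;
        // paint sphere of radius rc (voxel centres within rc)
        int R = (int)std::floor(rc + 1e-9);
        double rc2 = rc * rc + 1e-9;
        for (int dz = -R; dz <= R; ++dz)
        for (int dy = -R; dy <= R; ++dy)
        for (int dx = -R; dx <= R; ++dx) {
            if ((double)(dx*dx + dy*dy + dz*dz) > rc2) continue;
            int x = x0 + dx, y = y0 + dy, z = z0 + dz;
            if (wx) x = (x + nx) % nx; else if (x < 0 || x >= nx) continue;
            if (wy) y = (y + ny) % ny; else if (y < 0 || y >= ny) continue;
            if (wz) z = (z + nz) % nz; else if (z < 0 || z >= nz) continue;
            size_t i = idx(x, y, z);
            if (dt2[i] > 0.0 && out[i] < 2.0 * rc) out[i] = 2.0 * rc;
        }
    }
    NumericVector res(n);
    for (size_t i = 0; i < n; ++i) res[i] = out[i];
    res.attr("dim") = dims;
    return res;
}

// Connected-component labeling of TRUE voxels, connectivity 6 or 26.
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector vol, IntegerVector dims,
                                   int connectivity) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    size_t n = (size_t)nx * ny * nz;
    IntegerVector lab(n, 0);
    std::vector<int> offx, offy, offz;
    for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
    for (int dx = -1; dx <= 1; ++dx) {
        if (!dx && !dy && !dz) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
    }
    int next = 0;
    std::vector<size_t> stack;
    for (size_t s = 0; s < n; ++s) {
        if (!vol[s] || lab[s]) continue;
        ++next;
        lab[s] = next;
        stack.push_back(s);
        while (!stack.empty()) {
            size_t c = stack.back(); stack.pop_back();
            int x0 = (int)(c % nx), y0 = (int)((c / nx) % ny),
                z0 = (int)(c / ((size_t)nx * ny));
            for (size_t k = 0; k < offx.size(); ++k) {
                int x = x0 + offx[k], y = y0 + offy[k], z = z0 + offz[k];
                if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz)
                    continue;
                size_t i = (size_t)x + (size_t)nx * (y + (size_t)ny * z);
                if (vol[i] && !lab[i]) {
                    lab[i] = next;
                    stack.push_back(i);
                }
            }
        }
    }
    lab.attr("dim") = dims;
    return lab;
}
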