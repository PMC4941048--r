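#include "atlasmap.h"
using namespace Rcpp;

// Separable Gaussian with half-sample reflect boundary (scipy-style "reflect").
// Kernel: normalized samples of exp(-i^2 / 2 sigma^2), radius ceil(4 sigma).
static std::vector<double> gauss_kernel(double sigma) {
    int r = (int)std::ceil(4.0 * sigma);
    if (r < 1) r = 1;
    std::vector<double> k(2 * r + 1);
    double s = 0.0;
    for (int i = -r; i <= r; ++i) {
        k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
        s += k[i + r];
    }
    for (auto &v : k) v /= s;
    return k;
}

static inline int reflect_idx(int i, int n) {
    if (n == 1) return 0;
    while (i < 0 || i >= n) {
        if (i < 0) i = -i - 1;
        if (i >= n) i = 2 * n - i - 1;
    }
    return i;
}

static void smooth_axis(std::vector<double> &v, int nx, int ny, int nz,
                        int axis, double sigma) {
    if (sigma <= 0.0) return;
    std::vector<double> k = gauss_kernel(sigma);
    int r = ((int)k.size() - 1) / 2;
    int n = axis == 0 ? nx : (axis == 1 ? ny : nz);
    size_t stride = axis == 0 ? 1 : (axis == 1 ? (size_t)nx : (size_t)nx * ny);
    std::vector<double> line(n);
    // iterate over all lines along `axis`
    int d1 = axis == 0 ? ny : nx;
    int d2 = axis == 2 ? ny : nz;
    for (int j2 = 0; j2 < d2; ++j2) {
        for (int j1 = 0; j1 < d1; ++j1) {
            size_t base;
            if (axis == 0)      base = (size_t)nx * (j1 + (size_t)ny * j2);
            else if (axis == 1) base = j1 + (size_t)nx * ny * j2;
            else                base = j1 + (size_t)nx * j2;
            for (int i = 0; i < n; ++i) line[i] = v[base + stride * i];
            for (int i = 0; i < n; ++i) {
                double acc = 0.0;
                for (int o = -r; o <= r; ++o)
                    acc += k[o + r] * line[reflect_idx(i + o, n)];
                v[base + stride * i] = acc;
            }
        }
    }
}

// [[Rcpp::export(name = ".gaussianSmoothCpp")]]
NumericVector gaussian_smooth_cpp(NumericVector vol, IntegerVector dims,
                                  NumericVector sigma) {
    int nx = dims[0], ny = dims[1], nz = dims[2];
    std::vector<double> v(vol.begin(), vol.end());
    for (int a = 0; a < 3; ++a) smooth_axis(v, nx, ny, nz, a, sigma[a]);
    NumericVector out(v.begin(), v.end());
    out.attr("dim") = dims;
    return out;
}
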