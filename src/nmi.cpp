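#include "atlasmap.h"
using namespace Rcpp;

// Normalized mutual information (H(A)+H(B))/H(A,B), entropies in nats,
// joint histogram with first-order (linear) Parzen binning.

struct HistScale {
    double mn, width;  // continuous bin coordinate y = (v - mn)/width in [0, bins-1]
};

static HistScale hist_scale(double mn, double mx, int bins) {
    HistScale s;
    s.mn = mn;
    s.width = (mx > mn) ? (mx - mn) / (bins - 1) : 1.0;
    return s;
}

static inline void bin_weights(double v, const HistScale &s, int bins,
                               int *b0, double *f) {
    double y = (v - s.mn) / s.width;
    if (y < 0.0) y = 0.0;
    if (y > bins - 1.0) y = bins - 1.0;
    int b = (int)std::floor(y);
    if (b > bins - 2) b = bins - 2;
    *b0 = b;
    *f = y - b;
}

static double entropy(const std::vector<double> &p) {
    double h = 0.0;
    for (double v : p) if (v > 0.0) h -= v * std::log(v);
    return h;
}

// [[Rcpp::export(name = ".nmiPairCpp")]]
List nmi_pair_cpp(NumericVector a, NumericVector b, int bins) {
    if (a.size() != b.size()) stop("images must have the same size");
    R_xlen_t n = a.size();
    double amn = R_PosInf, amx = R_NegInf, bmn = R_PosInf, bmx = R_NegInf;
    for (R_xlen_t i = 0; i < n; ++i) {
        if (a[i] < amn) amn = a[i];
        if (a[i] > amx) amx = a[i];
        if (b[i] < bmn) bmn = b[i];
        if (b[i] > bmx) bmx = b[i];
    }
    HistScale sa = hist_scale(amn, amx, bins), sb = hist_scale(bmn, bmx, bins);
    std::vector<double> H((size_t)bins * bins, 0.0);
    for (R_xlen_t i = 0; i < n; ++i) {
        int a0, b0; double fa, fb;
        bin_weights(a[i], sa, bins, &a0, &fa);
        bin_weights(b[i], sb, bins, &b0, &fb);
        H[a0 + (size_t)bins * b0]           += (1 - fa) * (1 - fb);
        H[a0 + 1 + (size_t)bins * b0]       += fa * (1 - fb);
        H[a0 + (size_t)bins * (b0 + 1)]     += (1 - fa) * fb;
        H[a0 + 1 + (size_t)bins * (b0 + 1)] += fa * fb;
    }
    std::vector<double> pj(H), pa(bins, 0.0), pb(bins, 0.0);
    for (auto &v : pj) v /= (double)n;
    for (int jb = 0; jb < bins; ++jb)
        for (int ia = 0; ia < bins; ++ia) {
            pa[ia] += pj[ia + (size_t)bins * jb];
            pb[jb] += pj[ia + (size_t)bins * jb];
        }
    double ha = entropy(pa), hb = entropy(pb), hab = entropy(pj);
    double nmi = hab > 0.0 ? (ha + hb) / hab : 1.0;
    NumericMatrix counts(bins, bins);
    std::copy(H.begin(), H.end(), counts.begin());
    return List::create(_["nmi"] = nmi, _["ha"] = ha, _["hb"] = hb,
                        _["hab"] = hab, _["counts"] = counts, _["n"] = (double)n);
}

// NMI of reference vs floating warped through T(x) = A x + D(x), with optional
// analytic gradient with respect to the control-point displacements.
// Histogram ranges are fixed from the full intensity ranges of both inputs.
// [[Rcpp::export(name = ".ffdNmiCpp")]]
List ffd_nmi_cpp(NumericVector ref, IntegerVector rdim, NumericVector rspc,
                 NumericVector rorg, NumericVector flt, IntegerVector fdim,
                 NumericVector fspc, NumericVector forg, NumericMatrix A,
                 List grid, NumericVector coef, int bins, bool want_grad,
                 Nullable<NumericVector> fgx_, Nullable<NumericVector> fgy_,
                 Nullable<NumericVector> fgz_) {
    IntegerVector nkv = grid["nknots"];
    NumericVector gh = grid["spacing"], go = grid["origin"];
    FFDGrid G;
    G.cx = nkv[0]; G.cy = nkv[1]; G.cz = nkv[2];
    G.hx = gh[0]; G.hy = gh[1]; G.hz = gh[2];
    G.ox = go[0]; G.oy = go[1]; G.oz = go[2];
    G.coef = coef.begin();
    const int nx = rdim[0], ny = rdim[1], nz = rdim[2];
    const int fx = fdim[0], fy = fdim[1], fz = fdim[2];
    const size_t nvox = (size_t)nx * ny * nz;
    double rmn = R_PosInf, rmx = R_NegInf, fmn = R_PosInf, fmx = R_NegInf;
    for (R_xlen_t i = 0; i < ref.size(); ++i) {
        if (ref[i] < rmn) rmn = ref[i];
        if (ref[i] > rmx) rmx = ref[i];
    }
    for (R_xlen_t i = 0; i < flt.size(); ++i) {
        if (flt[i] < fmn) fmn = flt[i];
        if (flt[i] > fmx) fmx = flt[i];
    }
    HistScale sr = hist_scale(rmn, rmx, bins), sw = hist_scale(fmn, fmx, bins);
    std::vector<double> H((size_t)bins * bins, 0.0);
    std::vector<double> wval;
    std::vector<float> px, py, pz;
    std::vector<char> valid(nvox, 0);
    if (want_grad) {
        wval.resize(nvox);
        px.resize(nvox); py.resize(nvox); pz.resize(nvox);
    }
    const double *fptr = flt.begin();
    double d[3];
    double N = 0.0;
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
        double wz = rorg[2] + k * rspc[2];
        for (int j = 0; j < ny; ++j) {
            double wy = rorg[1] + j * rspc[1];
            for (int i = 0; i < nx; ++i, ++idx) {
                double wx = rorg[0] + i * rspc[0];
                double qx = A(0,0)*wx + A(0,1)*wy + A(0,2)*wz + A(0,3);
                double qy = A(1,0)*wx + A(1,1)*wy + A(1,2)*wz + A(1,3);
                double qz = A(2,0)*wx + A(2,1)*wy + A(2,2)*wz + A(2,3);
                ffd_displacement(G, wx, wy, wz, d);
                qx += d[0]; qy += d[1]; qz += d[2];
                double vx = (qx - forg[0]) / fspc[0];
                double vy = (qy - forg[1]) / fspc[1];
                double vz = (qz - forg[2]) / fspc[2];
                bool inside;
                double w = trilinear(fptr, fx, fy, fz, vx, vy, vz, 0.0, &inside);
                if (!inside) continue;
                valid[idx] = 1;
                if (want_grad) {
                    wval[idx] = w;
                    px[idx] = (float)vx; py[idx] = (float)vy; pz[idx] = (float)vz;
                }
                int a0, b0; double fa, fb;
                bin_weights(ref[idx], sr, bins, &a0, &fa);
                bin_weights(w, sw, bins, &b0, &fb);
                H[a0 + (size_t)bins * b0]           += (1 - fa) * (1 - fb);
                H[a0 + 1 + (size_t)bins * b0]       += fa * (1 - fb);
                H[a0 + (size_t)bins * (b0 + 1)]     += (1 - fa) * fb;
                H[a0 + 1 + (size_t)bins * (b0 + 1)] += fa * fb;
                N += 1.0;
            }
        }
    }
    if (N <= 0.0) stop("empty overlap between reference and warped floating image");
    std::vector<double> pj(H), pa(bins, 0.0), pb(bins, 0.0);
    for (auto &v : pj) v /= N;
    for (int jb = 0; jb < bins; ++jb)
        for (int ia = 0; ia < bins; ++ia) {
            pa[ia] += pj[ia + (size_t)bins * jb];
            pb[jb] += pj[ia + (size_t)bins * jb];
        }
    double ha = entropy(pa), hb = entropy(pb), hab = entropy(pj);
    double nmi = hab > 0.0 ? (ha + hb) / hab : 1.0;
    if (!want_grad)
        return List::create(_["nmi"] = nmi, _["n"] = N);

    // dNMI/dn_ab with fixed N; probabilities clamped away from zero in logs
    const double eps = 1e-12;
    std::vector<double> D((size_t)bins * bins);
    for (int jb = 0; jb < bins; ++jb) {
        double lb = std::log(std::max(pb[jb], eps)) + 1.0;
        for (int ia = 0; ia < bins; ++ia) {
            double la = std::log(std::max(pa[ia], eps)) + 1.0;
            double lj = std::log(std::max(pj[ia + (size_t)bins * jb], eps)) + 1.0;
            D[ia + (size_t)bins * jb] =
                (-(la + lb) * hab + (ha + hb) * lj) / (N * hab * hab);
        }
    }
    NumericVector grad((size_t)G.cx * G.cy * G.cz * 3);
    grad.attr("dim") = IntegerVector::create(G.cx, G.cy, G.cz, 3);
    const size_t nk = (size_t)G.cx * G.cy * G.cz;
    if (fgx_.isNull() || fgy_.isNull() || fgz_.isNull())
        stop("floating-image gradient volumes are required for the NMI gradient");
    NumericVector fgx(fgx_.get()), fgy(fgy_.get()), fgz(fgz_.get());
    const double *gxp = fgx.begin(), *gyp = fgy.begin(), *gzp = fgz.begin();
    double bxw[4], byw[4], bzw[4];
    idx = 0;
    for (int k = 0; k < nz; ++k) {
        double wz = rorg[2] + k * rspc[2];
        for (int j = 0; j < ny; ++j) {
            double wy = rorg[1] + j * rspc[1];
            for (int i = 0; i < nx; ++i, ++idx) {
                if (!valid[idx]) continue;
                double wx = rorg[0] + i * rspc[0];
                int a0, b0; double fa, fb;
                bin_weights(ref[idx], sr, bins, &a0, &fa);
                bin_weights(wval[idx], sw, bins, &b0, &fb);
                double dndw = ((1 - fa) * (D[a0 + (size_t)bins * (b0 + 1)] -
                                           D[a0 + (size_t)bins * b0]) +
                               fa * (D[a0 + 1 + (size_t)bins * (b0 + 1)] -
                                     D[a0 + 1 + (size_t)bins * b0])) / sw.width;
                double gx = trilinear(gxp, fx, fy, fz, px[idx], py[idx], pz[idx], 0.0, nullptr);
                double gy = trilinear(gyp, fx, fy, fz, px[idx], py[idx], pz[idx], 0.0, nullptr);
                double gz = trilinear(gzp, fx, fy, fz, px[idx], py[idx], pz[idx], 0.0, nullptr);
                double vgx = dndw * gx, vgy = dndw * gy, vgz = dndw * gz;
                // scatter to the 64 surrounding control points
                double ux = (wx - G.ox) / G.hx, uy = (wy - G.oy) / G.hy,
                       uz = (wz - G.oz) / G.hz;
                int cxi = (int)std::floor(ux), cyi = (int)std::floor(uy),
                    czi = (int)std::floor(uz);
                double tx = ux - cxi, ty = uy - cyi, tz = uz - czi;
                if (cxi < 1) { cxi = 1; tx = 0; }
                if (cxi > G.cx - 3) { cxi = G.cx - 3; tx = 1; }
                if (cyi < 1) { cyi = 1; ty = 0; }
                if (cyi > G.cy - 3) { cyi = G.cy - 3; ty = 1; }
                if (czi < 1) { czi = 1; tz = 0; }
                if (czi > G.cz - 3) { czi = G.cz - 3; tz = 1; }
                bspline_basis(tx, bxw); bspline_basis(ty, byw); bspline_basis(tz, bzw);
                for (int c2 = 0; c2 < 4; ++c2) {
                    for (int b2 = 0; b2 < 4; ++b2) {
                        double wbc = byw[b2] * bzw[c2];
                        size_t base = (size_t)G.cx *
                            ((cyi - 1 + b2) + (size_t)G.cy * (czi - 1 + c2));
                        for (int a2 = 0; a2 < 4; ++a2) {
                            double w = bxw[a2] * wbc;
                            size_t kk = (cxi - 1 + a2) + base;
                            grad[kk]          += w * vgx;
                            grad[kk + nk]     += w * vgy;
                            grad[kk + 2 * nk] += w * vgz;
                        }
                    }
                }
            }
        }
    }
    return List::create(_["nmi"] = nmi, _["n"] = N, _["grad"] = grad);
}
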