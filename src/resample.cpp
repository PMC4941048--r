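#include "atlasmap.h"
using namespace Rcpp;

static FFDGrid grid_from_list(const List &g, const NumericVector &coef) {
    FFDGrid G;
    IntegerVector n = g["nknots"];
    NumericVector h = g["spacing"], o = g["origin"];
    G.cx = n[0]; G.cy = n[1]; G.cz = n[2];
    G.hx = h[0]; G.hy = h[1]; G.hz = h[2];
    G.ox = o[0]; G.oy = o[1]; G.oz = o[2];
    G.coef = coef.begin();
    return G;
}

// Resample `src` onto the reference grid through the composed transform
// T(x) = A x + D(x)  (D optional), pull-back convention.
// [[Rcpp::export(name = ".resampleCpp")]]
NumericVector resample_cpp(NumericVector src, IntegerVector sdim,
                           NumericVector sspc, NumericVector sorg,
                           IntegerVector rdim, NumericVector rspc,
                           NumericVector rorg, NumericMatrix A,
                           Nullable<List> grid, Nullable<NumericVector> coef,
                           int interp, double pad) {
    int nx = rdim[0], ny = rdim[1], nz = rdim[2];
    int sx = sdim[0], sy = sdim[1], sz = sdim[2];
    NumericVector out((size_t)nx * ny * nz);
    bool has_ffd = grid.isNotNull() && coef.isNotNull();
    NumericVector coef_;
    FFDGrid G;
    if (has_ffd) {
        coef_ = coef.get();
        G = grid_from_list(grid.get(), coef_);
    }
    const double *s = src.begin();
    double d[3] = {0, 0, 0};
    size_t idx = 0;
    for (int k = 0; k < nz; ++k) {
        double wz = rorg[2] + k * rspc[2];
        for (int j = 0; j < ny; ++j) {
            double wy = rorg[1] + j * rspc[1];
            for (int i = 0; i < nx; ++i, ++idx) {
                double wx = rorg[0] + i * rspc[0];
                double px = A(0,0)*wx + A(0,1)*wy + A(0,2)*wz + A(0,3);
                double py = A(1,0)*wx + A(1,1)*wy + A(1,2)*wz + A(1,3);
                double pz = A(2,0)*wx + A(2,1)*wy + A(2,2)*wz + A(2,3);
                if (has_ffd) {
                    ffd_displacement(G, wx, wy, wz, d);
                    px += d[0]; py += d[1]; pz += d[2];
                }
                double vx = (px - sorg[0]) / sspc[0];
                double vy = (py - sorg[1]) / sspc[1];
                double vz = (pz - sorg[2]) / sspc[2];
                if (interp == 0)
                    out[idx] = nearestsample(s, sx, sy, sz, vx, vy, vz, pad);
                else
                    out[idx] = trilinear(s, sx, sy, sz, vx, vy, vz, pad, nullptr);
            }
        }
    }
    out.attr("dim") = rdim;
    return out;
}

// Map world points through T(x) = A x + D(x).
// [[Rcpp::export(name = ".deformPointsCpp")]]
NumericMatrix deform_points_cpp(NumericMatrix pts, NumericMatrix A,
                                Nullable<List> grid, Nullable<NumericVector> coef) {
    int n = pts.nrow();
    NumericMatrix out(n, 3);
    bool has_ffd = grid.isNotNull() && coef.isNotNull();
    NumericVector coef_;
    FFDGrid G;
    if (has_ffd) {
        coef_ = coef.get();
        G = grid_from_list(grid.get(), coef_);
    }
    double d[3];
    for (int r = 0; r < n; ++r) {
        double wx = pts(r,0), wy = pts(r,1), wz = pts(r,2);
        out(r,0) = A(0,0)*wx + A(0,1)*wy + A(0,2)*wz + A(0,3);
        out(r,1) = A(1,0)*wx + A(1,1)*wy + A(1,2)*wz + A(1,3);
        out(r,2) = A(2,0)*wx + A(2,1)*wy + A(2,2)*wz + A(2,3);
        if (has_ffd) {
            ffd_displacement(G, wx, wy, wz, d);
            out(r,0) += d[0]; out(r,1) += d[1]; out(r,2) += d[2];
        }
    }
    return out;
}

// Jacobian determinant of T(x) = A x + D(x) sampled on the reference grid.
// [[Rcpp::export(name = ".jacobianDetCpp")]]
NumericVector jacobian_det_cpp(NumericMatrix A, List grid, NumericVector coef,
                               IntegerVector rdim, NumericVector rspc,
                               NumericVector rorg, int stride) {
    FFDGrid G = grid_from_list(grid, coef);
    const size_t nk = (size_t)G.cx * G.cy * G.cz;
    std::vector<double> dets;
    dets.reserve(((size_t)rdim[0] / stride + 1) * (rdim[1] / stride + 1) *
                 (rdim[2] / stride + 1));
    double bx[4], by[4], bz[4], dbx[4], dby[4], dbz[4];
    for (int k = 0; k < rdim[2]; k += stride) {
        double wz = rorg[2] + k * rspc[2];
        for (int j = 0; j < rdim[1]; j += stride) {
            double wy = rorg[1] + j * rspc[1];
            for (int i = 0; i < rdim[0]; i += stride) {
                double wx = rorg[0] + i * rspc[0];
                double ux = (wx - G.ox) / G.hx, uy = (wy - G.oy) / G.hy,
                       uz = (wz - G.oz) / G.hz;
                int cx = (int)std::floor(ux), cy = (int)std::floor(uy),
                    cz = (int)std::floor(uz);
                double tx = ux - cx, ty = uy - cy, tz = uz - cz;
                if (cx < 1) { cx = 1; tx = 0; }  if (cx > G.cx - 3) { cx = G.cx - 3; tx = 1; }
                if (cy < 1) { cy = 1; ty = 0; }  if (cy > G.cy - 3) { cy = G.cy - 3; ty = 1; }
                if (cz < 1) { cz = 1; tz = 0; }  if (cz > G.cz - 3) { cz = G.cz - 3; tz = 1; }
                bspline_basis(tx, bx); bspline_basis(ty, by); bspline_basis(tz, bz);
                bspline_basis_d1(tx, dbx); bspline_basis_d1(ty, dby); bspline_basis_d1(tz, dbz);
                // J = A[1:3,1:3] + dD/dx ; dD/du scaled by 1/h
                double J[3][3];
                for (int r = 0; r < 3; ++r)
                    for (int c = 0; c < 3; ++c) J[r][c] = A(r, c);
                for (int c2 = 0; c2 < 4; ++c2) {
                    for (int b2 = 0; b2 < 4; ++b2) {
                        size_t base = (size_t)G.cx *
                            ((cy - 1 + b2) + (size_t)G.cy * (cz - 1 + c2));
                        for (int a2 = 0; a2 < 4; ++a2) {
                            size_t kk = (cx - 1 + a2) + base;
                            double wdx = dbx[a2] * by[b2] * bz[c2] / G.hx;
                            double wdy = bx[a2] * dby[b2] * bz[c2] / G.hy;
                            double wdz = bx[a2] * by[b2] * dbz[c2] / G.hz;
                            for (int m = 0; m < 3; ++m) {
                                double cv = G.coef[kk + m * nk];
                                J[m][0] += cv * wdx;
                                J[m][1] += cv * wdy;
                                J[m][2] += cv * wdz;
                            }
                        }
                    }
                }
                double det = J[0][0]*(J[1][1]*J[2][2]-J[1][2]*J[2][1])
                           - J[0][1]*(J[1][0]*J[2][2]-J[1][2]*J[2][0])
                           + J[0][2]*(J[1][0]*J[2][1]-J[1][1]*J[2][0]);
                dets.push_back(det);
            }
        }
    }
    return NumericVector(dets.begin(), dets.end());
}
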