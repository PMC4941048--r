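#include "atlasmap.h"
using namespace Rcpp;

// Bending energy of the B-spline displacement field: mean over a dense sampling
// of the reference grid of the sum of squared second derivatives (mixed terms
// doubled). Convention: displacements in millimetres, derivatives taken with
// respect to the control-grid index coordinate, following the clinical
// registration toolkit convention under which the usual penalty weights are
// quoted. Control coefficients are passed in micrometres and scaled here.
// [[Rcpp::export(name = ".bendingEnergyCpp")]]
List bending_energy_cpp(List grid, NumericVector coef, IntegerVector rdim,
                        NumericVector rspc, NumericVector rorg, int stride,
                        bool want_grad) {
    IntegerVector n = grid["nknots"];
    NumericVector h = grid["spacing"], o = grid["origin"];
    const int cx = n[0], cy = n[1], cz = n[2];
    const size_t nk = (size_t)cx * cy * cz;
    const double um2mm = 1e-3;
    NumericVector grad;
    if (want_grad) {
        grad = NumericVector(nk * 3);
        grad.attr("dim") = IntegerVector::create(cx, cy, cz, 3);
    }
    double bx[4], by[4], bz[4], d1x[4], d1y[4], d1z[4], d2x[4], d2y[4], d2z[4];
    double be = 0.0;
    size_t nsamp = 0;
    for (int k = 0; k < rdim[2]; k += stride) {
        double wz = rorg[2] + k * rspc[2];
        for (int j = 0; j < rdim[1]; j += stride) {
            double wy = rorg[1] + j * rspc[1];
            for (int i = 0; i < rdim[0]; i += stride) {
                double wx = rorg[0] + i * rspc[0];
                double ux = (wx - o[0]) / h[0], uy = (wy - o[1]) / h[1],
                       uz = (wz - o[2]) / h[2];
                int ax = (int)std::floor(ux), ay = (int)std::floor(uy),
                    az = (int)std::floor(uz);
                double tx = ux - ax, ty = uy - ay, tz = uz - az;
                if (ax < 1) { ax = 1; tx = 0; }  if (ax > cx - 3) { ax = cx - 3; tx = 1; }
                if (ay < 1) { ay = 1; ty = 0; }  if (ay > cy - 3) { ay = cy - 3; ty = 1; }
                if (az < 1) { az = 1; tz = 0; }  if (az > cz - 3) { az = cz - 3; tz = 1; }
                bspline_basis(tx, bx); bspline_basis(ty, by); bspline_basis(tz, bz);
                bspline_basis_d1(tx, d1x); bspline_basis_d1(ty, d1y); bspline_basis_d1(tz, d1z);
                bspline_basis_d2(tx, d2x); bspline_basis_d2(ty, d2y); bspline_basis_d2(tz, d2z);
                // second derivatives of each displacement component:
                // order: xx, yy, zz, xy, xz, yz
                double D[3][6] = {{0}};
                for (int c2 = 0; c2 < 4; ++c2) {
                    for (int b2 = 0; b2 < 4; ++b2) {
                        size_t base = (size_t)cx * ((ay - 1 + b2) + (size_t)cy * (az - 1 + c2));
                        for (int a2 = 0; a2 < 4; ++a2) {
                            size_t kk = (ax - 1 + a2) + base;
                            double w[6];
                            w[0] = d2x[a2] * by[b2] * bz[c2];
                            w[1] = bx[a2] * d2y[b2] * bz[c2];
                            w[2] = bx[a2] * by[b2] * d2z[c2];
                            w[3] = d1x[a2] * d1y[b2] * bz[c2];
                            w[4] = d1x[a2] * by[b2] * d1z[c2];
                            w[5] = bx[a2] * d1y[b2] * d1z[c2];
                            for (int m = 0; m < 3; ++m) {
                                double cv = coef[kk + m * nk] * um2mm;
                                for (int t = 0; t < 6; ++t) D[m][t] += cv * w[t];
                            }
                        }
                    }
                }
                for (int m = 0; m < 3; ++m)
                    be += D[m][0]*D[m][0] + D[m][1]*D[m][1] + D[m][2]*D[m][2]
                        + 2.0 * (D[m][3]*D[m][3] + D[m][4]*D[m][4] + D[m][5]*D[m][5]);
                if (want_grad) {
                    for (int c2 = 0; c2 < 4; ++c2) {
                        for (int b2 = 0; b2 < 4; ++b2) {
                            size_t base = (size_t)cx * ((ay - 1 + b2) + (size_t)cy * (az - 1 + c2));
                            for (int a2 = 0; a2 < 4; ++a2) {
                                size_t kk = (ax - 1 + a2) + base;
                                double w[6];
                                w[0] = d2x[a2] * by[b2] * bz[c2];
                                w[1] = bx[a2] * d2y[b2] * bz[c2];
                                w[2] = bx[a2] * by[b2] * d2z[c2];
                                w[3] = d1x[a2] * d1y[b2] * bz[c2];
                                w[4] = d1x[a2] * by[b2] * d1z[c2];
                                w[5] = bx[a2] * d1y[b2] * d1z[c2];
                                for (int m = 0; m < 3; ++m) {
                                    double g = 2.0 * (D[m][0]*w[0] + D[m][1]*w[1] +
                                               D[m][2]*w[2] + 2.0*(D[m][3]*w[3] +
                                               D[m][4]*w[4] + D[m][5]*w[5]));
                                    grad[kk + m * nk] += g * um2mm;
                                }
                            }
                        }
                    }
                }
                ++nsamp;
            }
        }
    }
    be /= (double)nsamp;
    if (want_grad) {
        for (R_xlen_t q = 0; q < grad.size(); ++q) grad[q] /= (double)nsamp;
        return List::create(_["value"] = be, _["grad"] = grad);
    }
    return List::create(_["value"] = be);
}
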