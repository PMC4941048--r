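#ifndef ATLASMAP_H
#define ATLASMAP_H

#include <Rcpp.h>
#include <cmath>

// Volumes are R arrays (column-major), first index fastest: v[i + nx*(j + ny*k)].
// World convention: world = origin + index * spacing, 0-based indices, voxel centres.

inline double trilinear(const double *v, int nx, int ny, int nz,
                        double x, double y, double z, double pad, bool *inside) {
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
        if (inside) *inside = false;
        return pad;
    }
    if (inside) *inside = true;
    int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
    if (x0 > nx - 2) x0 = nx - 2;
    if (x0 < 0) x0 = 0;
    if (y0 > ny - 2) y0 = ny - 2;
    if (y0 < 0) y0 = 0;
    if (z0 > nz - 2) z0 = nz - 2;
    if (z0 < 0) z0 = 0;
    double fx = x - x0, fy = y - y0, fz = z - z0;
    if (nx == 1) { x0 = 0; fx = 0.0; }
    if (ny == 1) { y0 = 0; fy = 0.0; }
    if (nz == 1) { z0 = 0; fz = 0.0; }
    int x1 = (nx == 1) ? x0 : x0 + 1;
    int y1 = (ny == 1) ? y0 : y0 + 1;
    int z1 = (nz == 1) ? z0 : z0 + 1;
    const size_t sx = 1, sy = (size_t)nx, sz = (size_t)nx * ny;
    #define V(i,j,k) v[(i)*sx + (j)*sy + (k)*sz]
    double c00 = V(x0,y0,z0) * (1-fx) + V(x1,y0,z0) * fx;
    double c10 = V(x0,y1,z0) * (1-fx) + V(x1,y1,z0) * fx;
    double c01 = V(x0,y0,z1) * (1-fx) + V(x1,y0,z1) * fx;
    double c11 = V(x0,y1,z1) * (1-fx) + V(x1,y1,z1) * fx;
    #undef V
    double c0 = c00 * (1-fy) + c10 * fy;
    double c1 = c01 * (1-fy) + c11 * fy;
    return c0 * (1-fz) + c1 * fz;
}

inline double nearestsample(const double *v, int nx, int ny, int nz,
                            double x, double y, double z, double pad) {
    int i = (int)std::lround(x), j = (int)std::lround(y), k = (int)std::lround(z);
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return pad;
    return v[i + (size_t)nx * (j + (size_t)ny * k)];
}

// Cubic B-spline basis on [0,1) for knots c-1..c+2, plus first/second derivatives
// with respect to the knot-index coordinate.
inline void bspline_basis(double t, double *b) {
    double t2 = t * t, t3 = t2 * t;
    b[0] = (1.0 - 3.0*t + 3.0*t2 - t3) / 6.0;
    b[1] = (4.0 - 6.0*t2 + 3.0*t3) / 6.0;
    b[2] = (1.0 + 3.0*t + 3.0*t2 - 3.0*t3) / 6.0;
    b[3] = t3 / 6.0;
}
inline void bspline_basis_d1(double t, double *b) {
    double t2 = t * t;
    b[0] = -(1.0 - t) * (1.0 - t) / 2.0;
    b[1] = (3.0 * t2 - 4.0 * t) / 2.0;
    b[2] = (-3.0 * t2 + 2.0 * t + 1.0) / 2.0;
    b[3] = t2 / 2.0;
}
inline void bspline_basis_d2(double t, double *b) {
    b[0] = 1.0 - t;
    b[1] = 3.0 * t - 2.0;
    b[2] = 1.0 - 3.0 * t;
    b[3] = t;
}

// FFD control grid descriptor: knot world position = gorg + index * h (per axis).
struct FFDGrid {
    int cx, cy, cz;        // knots per axis
    double hx, hy, hz;     // knot spacing, world units (um)
    double ox, oy, oz;     // world position of knot (0,0,0)
    const double *coef;    // displacements, dim (cx, cy, cz, 3), world units (um)
};

// Evaluate displacement at world position; cell index clamped to the margin so
// queries outside the lattice use the border cells.
inline void ffd_displacement(const FFDGrid &g, double wx, double wy, double wz,
                             double *d) {
    double ux = (wx - g.ox) / g.hx, uy = (wy - g.oy) / g.hy, uz = (wz - g.oz) / g.hz;
    int cxi = (int)std::floor(ux), cyi = (int)std::floor(uy), czi = (int)std::floor(uz);
    double tx = ux - cxi, ty = uy - cyi, tz = uz - czi;
    if (cxi < 1) { cxi = 1; tx = 0.0; }  if (cxi > g.cx - 3) { cxi = g.cx - 3; tx = 1.0; }
    if (cyi < 1) { cyi = 1; ty = 0.0; }  if (cyi > g.cy - 3) { cyi = g.cy - 3; ty = 1.0; }
    if (czi < 1) { czi = 1; tz = 0.0; }  if (czi > g.cz - 3) { czi = g.cz - 3; tz = 1.0; }
    double bx[4], by[4], bz[4];
    bspline_basis(tx, bx); bspline_basis(ty, by); bspline_basis(tz, bz);
    const size_t nk = (size_t)g.cx * g.cy * g.cz;
    d[0] = d[1] = d[2] = 0.0;
    for (int c = 0; c < 4; ++c) {
        for (int b = 0; b < 4; ++b) {
            double wbc = by[b] * bz[c];
            size_t base = (size_t)g.cx * ((cyi - 1 + b) + (size_t)g.cy * (czi - 1 + c));
            for (int a = 0; a < 4; ++a) {
                double w = bx[a] * wbc;
                size_t k = (cxi - 1 + a) + base;
                d[0] += w * g.coef[k];
                d[1] += w * g.coef[k + nk];
                d[2] += w * g.coef[k + 2 * nk];
            }
        }
    }
}

#endif
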