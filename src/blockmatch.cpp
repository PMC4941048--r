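#include "atlasmap.h"
#include <algorithm>
using namespace Rcpp;

// Symmetric block-matching primitive: partition the reference into
// non-overlapping cubes, rank them by intensity variance, keep the most
// informative fraction, and match each retained block to the displacement
// (within +/- radius voxels) maximizing normalized cross-correlation in the
// floating image (both on the same grid). Returns one row per matched block:
// block-centre voxel coordinates (0-based) and the best displacement.
// [[Rcpp::export(name = ".blockMatchCpp")]]
NumericMatrix block_match_cpp(NumericVector ref, NumericVector flt,
                              IntegerVector dims, int bs, double keep_frac,
                              int radius) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int mbx = nx / bs, mby = ny / bs, mbz = nz / bs;
    if (mbx < 1 || mby < 1 || mbz < 1)
        stop("volume too small for a single block");
    const double *r = ref.begin(), *f = flt.begin();
    const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
    const int bn = bs * bs * bs;

    struct Block { int ix, iy, iz; double var; };
    std::vector<Block> blocks;
    blocks.reserve((size_t)mbx * mby * mbz);
    for (int bz2 = 0; bz2 < mbz; ++bz2)
        for (int by2 = 0; by2 < mby; ++by2)
            for (int bx2 = 0; bx2 < mbx; ++bx2) {
                double s = 0.0, ss = 0.0;
                for (int k = 0; k < bs; ++k)
                    for (int j = 0; j < bs; ++j)
                        for (int i = 0; i < bs; ++i) {
                            double v = r[(bx2*bs+i) + sy*(by2*bs+j) + sz*(bz2*bs+k)];
                            s += v; ss += v * v;
                        }
                double var = ss / bn - (s / bn) * (s / bn);
                if (var > 1e-12) blocks.push_back({bx2*bs, by2*bs, bz2*bs, var});
            }
    if (blocks.empty())
        stop("no informative blocks: reference has no intensity variance");
    std::sort(blocks.begin(), blocks.end(),
              [](const Block &a, const Block &b) { return a.var > b.var; });
    size_t nkeep = (size_t)std::ceil(keep_frac * blocks.size());
    if (nkeep < 1) nkeep = 1;
    if (nkeep > blocks.size()) nkeep = blocks.size();

    std::vector<double> rows;
    std::vector<double> rb(bn);
    for (size_t q = 0; q < nkeep; ++q) {
        const Block &B = blocks[q];
        double rs = 0.0, rss = 0.0;
        int t = 0;
        for (int k = 0; k < bs; ++k)
            for (int j = 0; j < bs; ++j)
                for (int i = 0; i < bs; ++i, ++t) {
                    double v = r[(B.ix+i) + sy*(B.iy+j) + sz*(B.iz+k)];
                    rb[t] = v; rs += v; rss += v * v;
                }
        double rmean = rs / bn, rvar = rss / bn - rmean * rmean;
        double best = -2.0;
        int bdx = 0, bdy = 0, bdz = 0;
        const int nsh = 2 * radius + 1;
        std::vector<double> nccGrid((size_t)nsh * nsh * nsh, -2.0);
        for (int dz = -radius; dz <= radius; ++dz) {
            int oz = B.iz + dz;
            if (oz < 0 || oz + bs > nz) continue;
            for (int dy = -radius; dy <= radius; ++dy) {
                int oy = B.iy + dy;
                if (oy < 0 || oy + bs > ny) continue;
                for (int dx = -radius; dx <= radius; ++dx) {
                    int ox = B.ix + dx;
                    if (ox < 0 || ox + bs > nx) continue;
                    double fs = 0.0, fss = 0.0, cp = 0.0;
                    int u = 0;
                    for (int k = 0; k < bs; ++k)
                        for (int j = 0; j < bs; ++j)
                            for (int i = 0; i < bs; ++i, ++u) {
                                double v = f[(ox+i) + sy*(oy+j) + sz*(oz+k)];
                                fs += v; fss += v * v; cp += v * rb[u];
                            }
                    double fmean = fs / bn, fvar = fss / bn - fmean * fmean;
                    if (fvar <= 1e-12) continue;
                    double ncc = (cp / bn - rmean * fmean) /
                                 std::sqrt(rvar * fvar);
                    nccGrid[(dx + radius) +
                            (size_t)nsh * ((dy + radius) +
                            (size_t)nsh * (dz + radius))] = ncc;
                    if (ncc > best) { best = ncc; bdx = dx; bdy = dy; bdz = dz; }
                }
            }
        }
        if (best < -1.5) continue;  // no valid candidate
        // sub-voxel refinement: per-axis parabola through the NCC peak
        double rdx = bdx, rdy = bdy, rdz = bdz;
        auto nccAt = [&](int dx, int dy, int dz) -> double {
            if (dx < -radius || dx > radius || dy < -radius || dy > radius ||
                dz < -radius || dz > radius) return -2.0;
            return nccGrid[(dx + radius) + (size_t)nsh * ((dy + radius) +
                           (size_t)nsh * (dz + radius))];
        };
        int dd[3] = {bdx, bdy, bdz};
        double *rr[3] = {&rdx, &rdy, &rdz};
        for (int ax = 0; ax < 3; ++ax) {
            int e[3] = {0, 0, 0}; e[ax] = 1;
            double nm = nccAt(dd[0] - e[0], dd[1] - e[1], dd[2] - e[2]);
            double np = nccAt(dd[0] + e[0], dd[1] + e[1], dd[2] + e[2]);
            double n0 = best;
            if (nm > -1.5 && np > -1.5) {
                double den = nm - 2.0 * n0 + np;
                if (den < -1e-12) {
                    double delta = 0.5 * (nm - np) / den;
                    if (delta > 0.5) delta = 0.5;
                    if (delta < -0.5) delta = -0.5;
                    *rr[ax] += delta;
                }
            }
        }
        double c = (bs - 1) / 2.0;
        rows.insert(rows.end(), {B.ix + c, B.iy + c, B.iz + c,
                                 rdx, rdy, rdz, best});
    }
    NumericMatrix out(rows.size() / 7, 7);
    for (size_t q = 0; q < rows.size() / 7; ++q)
        for (int c = 0; c < 7; ++c) out(q, c) = rows[7 * q + c];
    colnames(out) = CharacterVector::create("cx", "cy", "cz",
                                            "dx", "dy", "dz", "ncc");
    return out;
}

// Exact symmetric Hausdorff distance between two point sets (all-pairs).
// [[Rcpp::export(name = ".hausdorffCpp")]]
double hausdorff_cpp(NumericMatrix a, NumericMatrix b) {
    int na = a.nrow(), nb = b.nrow(), dc = a.ncol();
    double hmax = 0.0;
    for (int pass = 0; pass < 2; ++pass) {
        const NumericMatrix &P = pass == 0 ? a : b;
        const NumericMatrix &Q = pass == 0 ? b : a;
        int np = pass == 0 ? na : nb, nq = pass == 0 ? nb : na;
        for (int i = 0; i < np; ++i) {
            double dmin = R_PosInf;
            for (int j = 0; j < nq; ++j) {
                double d = 0.0;
                for (int c = 0; c < dc; ++c) {
                    double t = P(i, c) - Q(j, c);
                    d += t * t;
                }
                if (d < dmin) dmin = d;
            }
            if (dmin > hmax) hmax = dmin;
        }
    }
    return std::sqrt(hmax);
}
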