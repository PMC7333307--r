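// 3D alpha-shape volume via incremental Delaunay tetrahedralisation
// (Bowyer-Watson) followed by a circumradius cutoff: a tetrahedron of the
// Delaunay complex is kept when its circumsphere radius is <= alpha, and the
// alpha-shape volume is the summed volume of the kept tetrahedra.  alpha is a
// length in the units of the input coordinates (meters here); alpha = Inf
// reduces to the convex-hull volume.
//
// Robustness strategy: coordinates are rescaled to the unit box and a
// deterministic per-point jitter of relative magnitude ~1e-10 is applied
// before triangulating, which resolves cospherical degeneracies (regular
// grids) with consistent sign decisions; volumes and circumradii of the
// resulting simplices are then evaluated on the ORIGINAL coordinates, so in
// general position the output is bit-for-bit the sum over the true Delaunay
// tetrahedra, and in degenerate configurations the error is bounded by the
// jitter (far below any tolerance used downstream).  Flat tetrahedra
// (volume ~ 0) contribute nothing and are dropped.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <array>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

// splitmix64-style hash -> uniform double in [-1, 1]; deterministic in the
// point index and coordinate dimension only (no RNG state involved).
inline double jitterUnit(uint64_t i, uint64_t dim) {
    uint64_t z = (i + 1) * 0x9E3779B97F4A7C15ULL + (dim + 1) * 0xBF58476D1CE4E5B9ULL;
    z ^= z >> 30; z *= 0xBF58476D1CE4E5B9ULL;
    z ^= z >> 27; z *= 0x94D049BB133111EBULL;
    z ^= z >> 31;
    return 2.0 * ((double)(z >> 11) / 9007199254740992.0) - 1.0;
}

struct Tet {
    int v[4];       // stored positively oriented (orient3d > 0)
    bool alive;
};

inline double det3(double a, double b, double c,
                   double d, double e, double f,
                   double g, double h, double i) {
    return a * (e * i - f * h) - b * (d * i - f * g) + c * (d * h - e * g);
}

// circumcenter/radius^2 of tetra given 4 point pointers; returns false when
// (near-)degenerate.
bool circumsphere(const double* p0, const double* p1,
                  const double* p2, const double* p3,
                  double cc[3], double& r2) {
    double a[3][3], rhs[3];
    for (int k = 0; k < 3; ++k) {
        const double* pk = (k == 0) ? p1 : (k == 1) ? p2 : p3;
        double s = 0.0;
        for (int d = 0; d < 3; ++d) {
            a[k][d] = 2.0 * (pk[d] - p0[d]);
            s += pk[d] * pk[d] - p0[d] * p0[d];
        }
        rhs[k] = s;
    }
    double D = det3(a[0][0], a[0][1], a[0][2],
                    a[1][0], a[1][1], a[1][2],
                    a[2][0], a[2][1], a[2][2]);
    // scale-aware singularity guard
    double scale = 0.0;
    for (int k = 0; k < 3; ++k)
        for (int d = 0; d < 3; ++d)
            scale = std::max(scale, std::fabs(a[k][d]));
    if (std::fabs(D) < 1e-13 * scale * scale * scale) return false;
    double Dx = det3(rhs[0], a[0][1], a[0][2],
                     rhs[1], a[1][1], a[1][2],
                     rhs[2], a[2][1], a[2][2]);
    double Dy = det3(a[0][0], rhs[0], a[0][2],
                     a[1][0], rhs[1], a[1][2],
                     a[2][0], rhs[2], a[2][2]);
    double Dz = det3(a[0][0], a[0][1], rhs[0],
                     a[1][0], a[1][1], rhs[1],
                     a[2][0], a[2][1], rhs[2]);
    cc[0] = Dx / D; cc[1] = Dy / D; cc[2] = Dz / D;
    double dx = cc[0] - p0[0], dy = cc[1] - p0[1], dz = cc[2] - p0[2];
    r2 = dx * dx + dy * dy + dz * dz;
    return true;
}

inline double tetVolume(const double* a, const double* b,
                        const double* c, const double* d) {
    double m00 = b[0] - a[0], m01 = b[1] - a[1], m02 = b[2] - a[2];
    double m10 = c[0] - a[0], m11 = c[1] - a[1], m12 = c[2] - a[2];
    double m20 = d[0] - a[0], m21 = d[1] - a[1], m22 = d[2] - a[2];
    return std::fabs(det3(m00, m01, m02, m10, m11, m12, m20, m21, m22)) / 6.0;
}

inline double orient3d(const double* a, const double* b,
                       const double* c, const double* d) {
    return det3(b[0] - a[0], b[1] - a[1], b[2] - a[2],
                c[0] - a[0], c[1] - a[1], c[2] - a[2],
                d[0] - a[0], d[1] - a[1], d[2] - a[2]);
}

inline double det4(double a00, double a01, double a02, double a03,
                   double a10, double a11, double a12, double a13,
                   double a20, double a21, double a22, double a23,
                   double a30, double a31, double a32, double a33) {
    return a00 * det3(a11, a12, a13, a21, a22, a23, a31, a32, a33)
         - a01 * det3(a10, a12, a13, a20, a22, a23, a30, a32, a33)
         + a02 * det3(a10, a11, a13, a20, a21, a23, a30, a31, a33)
         - a03 * det3(a10, a11, a12, a20, a21, a22, a30, a31, a32);
}

// insphere predicate: for a POSITIVELY oriented tetra (a,b,c,d), returns
// > 0 when e lies strictly inside the circumsphere (division-free, so no
// sliver amplification)
inline double inSphere(const double* a, const double* b, const double* c,
                       const double* d, const double* e) {
    double ax = a[0] - e[0], ay = a[1] - e[1], az = a[2] - e[2];
    double bx = b[0] - e[0], by = b[1] - e[1], bz = b[2] - e[2];
    double cx = c[0] - e[0], cy = c[1] - e[1], cz = c[2] - e[2];
    double dx = d[0] - e[0], dy = d[1] - e[1], dz = d[2] - e[2];
    return det4(ax, ay, az, ax * ax + ay * ay + az * az,
                bx, by, bz, bx * bx + by * by + bz * bz,
                cx, cy, cz, cx * cx + cy * cy + cz * cz,
                dx, dy, dz, dx * dx + dy * dy + dz * dz);
}

} // namespace

// [[Rcpp::export(name = ".alphaVolumeCpp")]]
List alphaVolumeCpp(NumericMatrix pts, double alpha) {
    const int n = pts.nrow();
    if (pts.ncol() != 3) stop("point matrix must have 3 columns");
    if (n < 4) return List::create(_["volume"] = 0.0, _["nKept"] = 0,
                                   _["nTetra"] = 0, _["hullVolume"] = 0.0);

    // --- rescale to unit box + deterministic jitter (triangulation coords)
    double lo[3], hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
    for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
            double v = pts(i, d);
            if (!R_finite(v)) stop("non-finite coordinate at point %d", i + 1);
            lo[d] = std::min(lo[d], v); hi[d] = std::max(hi[d], v);
        }
    double span = 0.0;
    for (int d = 0; d < 3; ++d) span = std::max(span, hi[d] - lo[d]);
    if (span <= 0.0)            // all points coincide
        return List::create(_["volume"] = 0.0, _["nKept"] = 0,
                            _["nTetra"] = 0, _["hullVolume"] = 0.0);

    const double jit = 1e-10;
    std::vector<double> q((n + 4) * 3);          // triangulation coords
    std::vector<double> orig(n * 3);             // original coords
    for (int i = 0; i < n; ++i)
        for (int d = 0; d < 3; ++d) {
            orig[3 * i + d] = pts(i, d);
            q[3 * i + d] = (pts(i, d) - lo[d]) / span
                + jit * jitterUnit((uint64_t)i, (uint64_t)d);
        }
    // super-tetra enclosing the unit box by a wide margin, so that the
    // (possibly large) circumspheres of flat hull slivers rarely reach a
    // super vertex; hull-boundary decisions against supers have margins
    // scaling with the same coordinate magnitudes, so double precision
    // remains adequate
    const double S[4][3] = {{-1e5, -1e5, -1e5}, {3e5, -1e5, -1e5},
                            {-1e5, 3e5, -1e5}, {-1e5, -1e5, 3e5}};
    for (int k = 0; k < 4; ++k)
        for (int d = 0; d < 3; ++d) q[3 * (n + k) + d] = S[k][d];

    const double* Q = q.data();
    auto pushTet = [&](int v0, int v1, int v2, int v3,
                       std::vector<Tet>& store) {
        Tet t; t.v[0] = v0; t.v[1] = v1; t.v[2] = v2; t.v[3] = v3;
        if (orient3d(Q + 3 * v0, Q + 3 * v1, Q + 3 * v2, Q + 3 * v3) < 0)
            std::swap(t.v[2], t.v[3]);           // normalise orientation
        t.alive = true;
        store.push_back(t);
    };

    std::vector<Tet> tets;
    tets.reserve(16 * (size_t)n + 16);
    pushTet(n, n + 1, n + 2, n + 3, tets);

    std::vector<int> bad;
    std::map<std::array<int, 3>, std::pair<int, std::array<int, 3>>> facets;
    size_t nDead = 0;

    for (int i = 0; i < n; ++i) {
        const double* p = Q + 3 * i;
        bad.clear();
        for (size_t t = 0; t < tets.size(); ++t) {
            if (!tets[t].alive) continue;
            const int* v = tets[t].v;
            if (inSphere(Q + 3 * v[0], Q + 3 * v[1], Q + 3 * v[2],
                         Q + 3 * v[3], p) < 0)
                bad.push_back((int)t);
        }
        if (bad.empty())
            stop("triangulation failure: point %d in no circumsphere", i + 1);

        facets.clear();
        for (int bi : bad) {
            const int* v = tets[bi].v;
            static const int F[4][3] = {{0,1,2},{0,1,3},{0,2,3},{1,2,3}};
            for (int f = 0; f < 4; ++f) {
                std::array<int, 3> key = {v[F[f][0]], v[F[f][1]], v[F[f][2]]};
                std::array<int, 3> raw = key;
                std::sort(key.begin(), key.end());
                auto it = facets.find(key);
                if (it == facets.end())
                    facets[key] = {1, raw};
                else
                    it->second.first += 1;
            }
            tets[bi].alive = false; ++nDead;
        }
        for (auto& kv : facets) {
            if (kv.second.first != 1) continue;   // interior facet of cavity
            pushTet(kv.second.second[0], kv.second.second[1],
                    kv.second.second[2], i, tets);
        }
        // periodic compaction
        if (nDead > tets.size() / 2 && tets.size() > 1024) {
            std::vector<Tet> keep;
            keep.reserve(tets.size() - nDead);
            for (auto& t : tets) if (t.alive) keep.push_back(t);
            tets.swap(keep);
            nDead = 0;
        }
    }

    // --- collect real tetrahedra, evaluate on original coordinates
    const double alpha2 = R_finite(alpha) ? alpha * alpha : R_PosInf;
    double vol = 0.0, volAll = 0.0;
    int nKept = 0, nTetra = 0;
    for (auto& t : tets) {
        if (!t.alive) continue;
        if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
        ++nTetra;
        const double* a = &orig[3 * t.v[0]];
        const double* b = &orig[3 * t.v[1]];
        const double* c = &orig[3 * t.v[2]];
        const double* d = &orig[3 * t.v[3]];
        double V = tetVolume(a, b, c, d);
        if (V <= 1e-300) continue;                 // flat: contributes nothing
        volAll += V;
        double cc[3], r2;
        if (!circumsphere(a, b, c, d, cc, r2)) continue;  // degenerate: r -> Inf
        if (r2 <= alpha2) { vol += V; ++nKept; }
    }
    return List::create(_["volume"] = vol, _["nKept"] = nKept,
                        _["nTetra"] = nTetra, _["hullVolume"] = volAll);
}
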