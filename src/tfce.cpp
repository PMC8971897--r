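#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Neighbour offsets for 6/18/26-connectivity on a 3D grid.
static int build_offsets(int conn, int off[26][3]) {
    int n = 0;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int nz = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (nz == 0) continue;
                if (conn == 6 && nz > 1) continue;
                if (conn == 18 && nz > 2) continue;
                off[n][0] = dx; off[n][1] = dy; off[n][2] = dz;
                ++n;
            }
    return n;
}

struct UnionFind {
    std::vector<int> parent;
    std::vector<double> size;
    explicit UnionFind(int n) : parent(n, -1), size(n, 0.0) {}
    int find(int v) {
        int r = v;
        while (parent[r] != r) r = parent[r];
        while (parent[v] != r) { int nxt = parent[v]; parent[v] = r; v = nxt; }
        return r;
    }
    void add(int v) { parent[v] = v; size[v] = 1.0; }
    bool added(int v) const { return parent[v] >= 0; }
    void unite(int a, int b) {
        a = find(a); b = find(b);
        if (a == b) return;
        if (size[a] < size[b]) std::swap(a, b);
        parent[b] = a; size[a] += size[b];
    }
};

// TFCE of the positive part of a 3D map: sum over n_steps equal-height
// thresholds h in (0, max] of e_h(v)^E * h^H * dh, where e_h(v) is the size
// (voxel count) of the suprathreshold connected component containing v.
// Components are accumulated incrementally (descending h) via union-find.
static void tfce_pos_impl(const double *img, const int *dim,
                          double E, double H, int nsteps, int conn,
                          double *out) {
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int V = nx * ny * nz;
    std::fill(out, out + V, 0.0);
    double hmax = 0.0;
    std::vector<int> active;
    for (int v = 0; v < V; ++v)
        if (img[v] > 0.0) { active.push_back(v); if (img[v] > hmax) hmax = img[v]; }
    if (active.empty() || hmax <= 0.0 || nsteps < 1) return;

    std::sort(active.begin(), active.end(),
              [img](int a, int b) { return img[a] > img[b]; });

    int off[26][3];
    const int noff = build_offsets(conn, off);
    UnionFind uf(V);
    const double dh = hmax / nsteps;
    size_t ptr = 0;

    for (int k = nsteps; k >= 1; --k) {
        const double h = k * dh;
        while (ptr < active.size() && img[active[ptr]] >= h) {
            const int v = active[ptr++];
            uf.add(v);
            const int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
            for (int o = 0; o < noff; ++o) {
                const int xx = x + off[o][0], yy = y + off[o][1], zz = z + off[o][2];
                if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
                    continue;
                const int w = xx + nx * (yy + ny * zz);
                if (uf.added(w)) uf.unite(v, w);
            }
        }
        const double hH = std::pow(h, H) * dh;
        for (size_t i = 0; i < ptr; ++i) {
            const int v = active[i];
            out[v] += std::pow(uf.size[uf.find(v)], E) * hH;
        }
    }
}

// [[Rcpp::export]]
NumericVector tfce_pos_cpp(NumericVector img, IntegerVector dim,
                           double E, double H, int nsteps, int conn) {
    NumericVector out(img.size());
    int d[3] = { dim[0], dim[1], dim[2] };
    tfce_pos_impl(REAL(img), d, E, H, nsteps, conn, REAL(out));
    return out;
}

// Separable Gaussian smoothing along one axis with in-bounds kernel
// renormalisation (no implicit zero padding mass).
static void smooth_axis(std::vector<double> &a, const int *dim, int axis,
                        double sigma, std::vector<double> &buf) {
    if (sigma <= 0.0) return;
    const int nx = dim[0], ny = dim[1], nz = dim[2];
    const int n = dim[axis];
    if (n == 1) return;
    const int R = std::max(1, (int)std::ceil(3.0 * sigma));
    std::vector<double> w(2 * R + 1);
    for (int k = -R; k <= R; ++k) w[k + R] = std::exp(-0.5 * k * k / (sigma * sigma));

    const int stride = (axis == 0) ? 1 : (axis == 1 ? nx : nx * ny);
    // iterate over all lines along `axis`
    const int n1 = (axis == 0) ? ny : nx;
    const int n2 = (axis == 2) ? ny : nz;
    const int s1 = (axis == 0) ? nx : 1;
    const int s2 = (axis == 2) ? nx : nx * ny;
    buf = a;
    for (int j2 = 0; j2 < n2; ++j2)
        for (int j1 = 0; j1 < n1; ++j1) {
            const int base = j1 * s1 + j2 * s2;
            for (int i = 0; i < n; ++i) {
                double num = 0.0, den = 0.0;
                const int lo = std::max(-R, -i), hi = std::min(R, n - 1 - i);
                for (int k = lo; k <= hi; ++k) {
                    const double wk = w[k + R];
                    num += wk * buf[base + (i + k) * stride];
                    den += wk;
                }
                a[base + i * stride] = num / den;
            }
        }
}

static void smooth3d(std::vector<double> &a, const int *dim, const double *sigma) {
    std::vector<double> buf;
    for (int ax = 0; ax < 3; ++ax) smooth_axis(a, dim, ax, sigma[ax], buf);
}

// [[Rcpp::export]]
NumericVector gauss_smooth3d_cpp(NumericVector img, IntegerVector dim,
                                 NumericVector sigma_vox) {
    int d[3] = { dim[0], dim[1], dim[2] };
    double s[3] = { sigma_vox[0], sigma_vox[1], sigma_vox[2] };
    std::vector<double> a(img.begin(), img.end());
    smooth3d(a, d, s);
    return NumericVector(a.begin(), a.end());
}

// One-sample smoothed-variance t map for a given sign pattern, evaluated on
// `domain`; t = 0 where the smoothed variance vanishes or outside the domain.
static void signed_tmap(const double *stack, int V, int N, const double *signs,
                        const double *sumsq, const int *dim, const double *sigma,
                        const int *domain, std::vector<double> &mean,
                        std::vector<double> &var, std::vector<double> &t) {
    for (int v = 0; v < V; ++v) mean[v] = 0.0;
    for (int i = 0; i < N; ++i) {
        const double s = signs[i];
        const double *col = stack + (size_t)i * V;
        for (int v = 0; v < V; ++v) mean[v] += s * col[v];
    }
    for (int v = 0; v < V; ++v) mean[v] /= N;
    for (int v = 0; v < V; ++v) {
        double va = (sumsq[v] - N * mean[v] * mean[v]) / (N - 1);
        var[v] = va > 0.0 ? va : 0.0;
    }
    smooth3d(var, dim, sigma);
    for (int v = 0; v < V; ++v) {
        if (!domain[v] || var[v] <= 1e-12) t[v] = 0.0;
        else t[v] = mean[v] / std::sqrt(var[v] / N);
    }
}

// Sign-flip permutation engine: returns the observed TFCE map (identity
// signs) and the max-TFCE null distribution over the supplied sign matrix.
// stack: V x N (column per subject); signs: N x P (column per permutation).
// [[Rcpp::export]]
List perm_maxtfce_cpp(NumericMatrix stack, IntegerVector dim,
                      NumericMatrix signs, NumericVector sigma_vox,
                      double E, double H, int nsteps, int conn,
                      LogicalVector domain) {
    const int V = stack.nrow(), N = stack.ncol(), P = signs.ncol();
    int d[3] = { dim[0], dim[1], dim[2] };
    double sg[3] = { sigma_vox[0], sigma_vox[1], sigma_vox[2] };
    if (d[0] * d[1] * d[2] != V) stop("stack rows do not match grid dimensions");
    if (signs.nrow() != N) stop("sign matrix rows must equal number of subjects");

    std::vector<double> sumsq(V, 0.0);
    for (int i = 0; i < N; ++i) {
        const double *col = &stack(0, i);
        for (int v = 0; v < V; ++v) sumsq[v] += col[v] * col[v];
    }
    std::vector<int> dom(V);
    for (int v = 0; v < V; ++v) dom[v] = domain[v] ? 1 : 0;

    std::vector<double> mean(V), var(V), t(V), tf(V);
    std::vector<double> ones(N, 1.0);

    signed_tmap(&stack(0, 0), V, N, ones.data(), sumsq.data(), d, sg,
                dom.data(), mean, var, t);
    std::vector<double> tpos(V);
    for (int v = 0; v < V; ++v) tpos[v] = t[v] > 0.0 ? t[v] : 0.0;
    NumericVector tfce_obs(V);
    tfce_pos_impl(tpos.data(), d, E, H, nsteps, conn, REAL(tfce_obs));
    NumericVector t_obs(t.begin(), t.end());

    NumericVector max_null(P);
    for (int p = 0; p < P; ++p) {
        signed_tmap(&stack(0, 0), V, N, &signs(0, p), sumsq.data(), d, sg,
                    dom.data(), mean, var, t);
        for (int v = 0; v < V; ++v) tpos[v] = t[v] > 0.0 ? t[v] : 0.0;
        tfce_pos_impl(tpos.data(), d, E, H, nsteps, conn, tf.data());
        double m = 0.0;
        for (int v = 0; v < V; ++v) if (tf[v] > m) m = tf[v];
        max_null[p] = m;
        if (p % 64 == 0) Rcpp::checkUserInterrupt();
    }
    return List::create(_["tfce_obs"] = tfce_obs, _["t_obs"] = t_obs,
                        _["max_null"] = max_null);
}
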