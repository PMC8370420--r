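#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

int uf_find(std::vector<int> &parent, int i) {
    while (parent[i] != i) {
        parent[i] = parent[parent[i]];
        i = parent[i];
    }
    return i;
}

void uf_union(std::vector<int> &parent, std::vector<int> &rank_, int a, int b) {
    a = uf_find(parent, a);
    b = uf_find(parent, b);
    if (a == b) return;
    if (rank_[a] < rank_[b]) std::swap(a, b);
    parent[b] = a;
    if (rank_[a] == rank_[b]) rank_[a]++;
}

// neighbour offsets for 6/18/26-connectivity on a 3D grid
std::vector<std::array<int, 3>> neighbour_offsets(int connectivity) {
    int max_l1 = (connectivity == 6) ? 1 : (connectivity == 18 ? 2 : 3);
    std::vector<std::array<int, 3>> off;
    for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
                int l1 = std::abs(dx) + std::abs(dy) + std::abs(dz);
                if (l1 == 0 || l1 > max_l1) continue;
                off.push_back({dx, dy, dz});
            }
    return off;
}

} // namespace

// Threshold-free cluster enhancement of a 3D statistic map.
// TFCE(v) = sum over h = dh, 2dh, ..., h_max of extent(v, h)^E * h^H * dh,
// where extent(v, h) is the size of the connected component containing v
// among voxels with value >= h. Non-positive voxels receive 0.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims, double E,
                       double H, int n_steps, int connectivity) {
    const int nx = dims[0], ny = dims[1], nz = dims[2];
    const int n = nx * ny * nz;
    if (map.size() != n) stop("map length does not match dims");
    if (connectivity != 6 && connectivity != 18 && connectivity != 26)
        stop("connectivity must be 6, 18 or 26");

    NumericVector out(n, 0.0);
    double hmax = 0.0;
    for (int i = 0; i < n; ++i)
        if (map[i] > hmax) hmax = map[i];
    if (hmax <= 0.0) return out;

    const double dh = hmax / n_steps;
    const auto offs = neighbour_offsets(connectivity);

    std::vector<int> parent(n), rank_(n), csize(n);
    std::vector<char> in(n);

    for (int step = 1; step <= n_steps; ++step) {
        // clamp the top threshold to hmax exactly so the maximum voxel is
        // never lost to floating-point rounding of step * dh
        const double h = (step == n_steps) ? hmax : step * dh;
        for (int i = 0; i < n; ++i) {
            in[i] = map[i] >= h;
            parent[i] = i;
            rank_[i] = 0;
        }
        for (int z = 0; z < nz; ++z)
            for (int y = 0; y < ny; ++y)
                for (int x = 0; x < nx; ++x) {
                    const int i = x + nx * (y + ny * z);
                    if (!in[i]) continue;
                    for (const auto &o : offs) {
                        const int x2 = x + o[0], y2 = y + o[1], z2 = z + o[2];
                        if (x2 < 0 || x2 >= nx || y2 < 0 || y2 >= ny ||
                            z2 < 0 || z2 >= nz)
                            continue;
                        const int j = x2 + nx * (y2 + ny * z2);
                        if (in[j]) uf_union(parent, rank_, i, j);
                    }
                }
        std::fill(csize.begin(), csize.end(), 0);
        for (int i = 0; i < n; ++i)
            if (in[i]) csize[uf_find(parent, i)]++;
        const double hH = std::pow(h, H);
        for (int i = 0; i < n; ++i)
            if (in[i])
                out[i] += std::pow((double)csize[uf_find(parent, i)], E) * hH * dh;
    }
    return out;
}
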