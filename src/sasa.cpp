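#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// Each atom is expanded to radius r_i + probe and covered with n quasi-uniform
// sphere points (golden-section spiral, deterministic).  A point is accessible
// iff it lies outside every neighbouring atom's expanded sphere; the atom's
// SASA is (accessible fraction) * 4*pi*(r_i + probe)^2.
//
// Neighbour search uses a cell list with cell size 2*(r_max + probe), which
// guarantees all occluding atoms of any centre lie in the 3x3x3 cell block.

namespace {

struct CellKey {
    int64_t k;
    CellKey(int ix, int iy, int iz) {
        // pack three 21-bit signed cell indices
        k = (static_cast<int64_t>(ix + 1048576) << 42) |
            (static_cast<int64_t>(iy + 1048576) << 21) |
            static_cast<int64_t>(iz + 1048576);
    }
};

} // namespace

// [[Rcpp::export(name = ".sasa_shrake_rupley")]]
NumericVector sasa_shrake_rupley(NumericMatrix coords,
                                 NumericVector radii,
                                 double probe,
                                 int n_points) {
    const int n = coords.nrow();
    if (n == 0) stop("no atoms");
    if (radii.size() != n) stop("radii length must match atom count");
    if (probe <= 0) stop("probe radius must be positive");
    if (n_points < 60) stop("n_points must be at least 60");

    std::vector<double> x(n), y(n), z(n), R(n);
    double rmax = 0.0;
    for (int i = 0; i < n; ++i) {
        x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
        if (!R_finite(x[i]) || !R_finite(y[i]) || !R_finite(z[i]))
            stop("non-finite coordinate at atom %d", i + 1);
        if (radii[i] <= 0) stop("non-positive radius at atom %d", i + 1);
        R[i] = radii[i] + probe;
        if (R[i] > rmax) rmax = R[i];
    }

    // golden-section spiral unit sphere points (deterministic)
    std::vector<double> px(n_points), py(n_points), pz(n_points);
    const double golden = M_PI * (3.0 - std::sqrt(5.0));
    for (int k = 0; k < n_points; ++k) {
        double zz = 1.0 - (2.0 * k + 1.0) / n_points;
        double rr = std::sqrt(std::max(0.0, 1.0 - zz * zz));
        double th = golden * k;
        px[k] = rr * std::cos(th);
        py[k] = rr * std::sin(th);
        pz[k] = zz;
    }

    // cell list
    const double cell = 2.0 * rmax;
    std::unordered_map<int64_t, std::vector<int>> grid;
    grid.reserve(static_cast<size_t>(n) * 2);
    auto cidx = [cell](double v) { return static_cast<int>(std::floor(v / cell)); };
    for (int i = 0; i < n; ++i)
        grid[CellKey(cidx(x[i]), cidx(y[i]), cidx(z[i])).k].push_back(i);

    NumericVector area(n);
    std::vector<int> nbr;
    nbr.reserve(256);

    for (int i = 0; i < n; ++i) {
        // collect neighbours from the 27 surrounding cells
        nbr.clear();
        int cx = cidx(x[i]), cy = cidx(y[i]), cz = cidx(z[i]);
        for (int dx = -1; dx <= 1; ++dx)
            for (int dy = -1; dy <= 1; ++dy)
                for (int dz = -1; dz <= 1; ++dz) {
                    auto it = grid.find(CellKey(cx + dx, cy + dy, cz + dz).k);
                    if (it == grid.end()) continue;
                    for (int j : it->second) {
                        if (j == i) continue;
                        double ddx = x[j] - x[i], ddy = y[j] - y[i], ddz = z[j] - z[i];
                        double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
                        double cut = R[i] + R[j];
                        if (d2 < cut * cut) nbr.push_back(j);
                    }
                }

        int acc = 0;
        for (int k = 0; k < n_points; ++k) {
            double sx = x[i] + R[i] * px[k];
            double sy = y[i] + R[i] * py[k];
            double sz = z[i] + R[i] * pz[k];
            bool buried = false;
            for (int j : nbr) {
                double ddx = sx - x[j], ddy = sy - y[j], ddz = sz - z[j];
                if (ddx * ddx + ddy * ddy + ddz * ddz < R[j] * R[j]) {
                    buried = true;
                    break;
                }
            }
            if (!buried) ++acc;
        }
        area[i] = (static_cast<double>(acc) / n_points) * 4.0 * M_PI * R[i] * R[i];
    }
    return area;
}
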