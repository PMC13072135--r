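#include <Rcpp.h>
using namespace Rcpp;

// Reflect a coordinate into [0, len]; flips the sign of v on each bounce.
static inline void reflect(double &p, double &v, double len) {
    // loop: a single step can overshoot both walls only for absurd speeds,
    // but the loop makes containment unconditional
    while (p < 0.0 || p > len) {
        if (p < 0.0) p = -p; else p = 2.0 * len - p;
        v = -v;
    }
}

// Persistent random walk with vertical mean reversion and a two-state
// moving/frozen gate. Positions in cm, velocities in cm/s. Uses R's RNG,
// so results are reproducible under set.seed().
//
// [[Rcpp::export]]
NumericMatrix sim_path_cpp(int n_frames, double dt,
                           double x0, double y0, double z0,
                           double lx, double ly, double lz,
                           double speed_cm, double phi,
                           double k_attr, double zstar,
                           double p_freeze, double p_unfreeze) {
    NumericMatrix out(n_frames, 3);
    double x = x0, y = y0, z = z0;
    double vx = 0.0, vy = 0.0, vz = 0.0;
    bool moving = true;
    // stationary per-axis velocity s.d. equals speed_cm
    const double sigma = speed_cm * std::sqrt(1.0 - phi * phi);
    const bool can_move = speed_cm > 0.0;

    out(0, 0) = x; out(0, 1) = y; out(0, 2) = z;
    for (int i = 1; i < n_frames; ++i) {
        if (moving) {
            if (p_freeze > 0.0 && unif_rand() < p_freeze) {
                moving = false;
                vx = vy = vz = 0.0;
            }
        } else {
            if (unif_rand() < p_unfreeze) moving = true;
        }
        if (moving && can_move) {
            vx = phi * vx + sigma * norm_rand();
            vy = phi * vy + sigma * norm_rand();
            vz = phi * vz + sigma * norm_rand();
            x += vx * dt;
            y += vy * dt;
            z += (vz + k_attr * (zstar - z)) * dt;
            reflect(x, vx, lx);
            reflect(y, vy, ly);
            reflect(z, vz, lz);
        }
        out(i, 0) = x; out(i, 1) = y; out(i, 2) = z;
    }
    return out;
}
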