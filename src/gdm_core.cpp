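#include <Rcpp.h>
using namespace Rcpp;

// reverse Michaelis-Menten flux: k * C * B / (K + B); zero when K + B == 0
static inline double rmm(double k, double c, double b, double kh) {
    double den = kh + b;
    if (den <= 0.0) return 0.0;
    return k * c * b / den;
}

// Fixed-step explicit Euler integration of the guild decomposition model.
//
// Operator order within a step (fixed):
//   decay fluxes -> pool decrements (clipped at pool content) ->
//   assimilation -> growth + basal respiration -> biomass turnover cap.
//
// Returns a matrix with one row per step (including the initial state),
// columns: time, c1d, c1t, c2, c3, b1, b2, b3, cum_co2, cum_released,
// necromass, clip_events (cumulative count of clipping events).
// [[Rcpp::export]]
NumericMatrix gdm_integrate_cpp(List par, NumericVector init, double dt,
                                int n_steps, bool lci_feedback) {
    const double k1max = par["k1max"], k2max = par["k2max"], k3max = par["k3max"];
    const double m2 = par["m2"], m3 = par["m3"];
    const double e1 = par["e1"], e2 = par["e2"], e3 = par["e3"];
    const double g = par["g"], bc_max = par["bc_max"];
    const double lci_t = par["lci_t"], lci_max = par["lci_max"];
    const double kb11 = par["k_b11"], kb22 = par["k_b22"];
    const double kb32 = par["k_b32"], kb33 = par["k_b33"];

    double c1d = init["c1d"], c1t = init["c1t"], c2 = init["c2"], c3 = init["c3"];
    double b1 = init["b1"], b2 = init["b2"], b3 = init["b3"];
    double cum_co2 = init["cum_co2"], cum_rel = init["cum_released"];
    double necro = init["necromass"];
    double t = init["time"];
    double clip = 0.0;

    NumericMatrix out(n_steps + 1, 12);
    colnames(out) = CharacterVector::create(
        "time", "c1d", "c1t", "c2", "c3", "b1", "b2", "b3",
        "cum_co2", "cum_released", "necromass", "clip_events");

    for (int s = 0; s <= n_steps; ++s) {
        out(s, 0) = t;    out(s, 1) = c1d;  out(s, 2) = c1t;  out(s, 3) = c2;
        out(s, 4) = c3;   out(s, 5) = b1;   out(s, 6) = b2;   out(s, 7) = b3;
        out(s, 8) = cum_co2; out(s, 9) = cum_rel; out(s, 10) = necro;
        out(s, 11) = clip;
        if (s == n_steps) break;

        // effective decay rate coefficients under lignocellulose feedback
        double k2 = k2max, k3 = k3max;
        if (lci_feedback) {
            double den = c2 + c3;
            if (den <= 0.0) {
                k2 = 0.0; k3 = 0.0;
            } else {
                double lci = c3 / den;
                if (lci >= lci_max) k2 = 0.0;
                else k2 = std::max(0.0, m2 * lci + k2max);
                if (lci <= lci_t || lci >= lci_max) k3 = 0.0;
                else k3 = std::min(k3max, m3 * (lci - lci_t));
            }
        }

        // per-(guild, pool) decay fluxes; guild access: G1 -> C1D;
        // G2 -> C1D, C2; G3 -> C1D, C2, C3; all guilds share K for C1D
        double f1_1 = rmm(k1max, c1d, b1, kb11);
        double f1_2 = rmm(k1max, c1d, b2, kb11);
        double f1_3 = rmm(k1max, c1d, b3, kb11);
        double f2_2 = rmm(k2, c2, b2, kb22);
        double f2_3 = rmm(k2, c2, b3, kb32);
        double f3_3 = rmm(k3, c3, b3, kb33);

        // clip so no pool goes negative within the step
        double d1 = (f1_1 + f1_2 + f1_3) * dt;
        if (d1 > c1d && d1 > 0.0) {
            double sc = c1d / d1;
            f1_1 *= sc; f1_2 *= sc; f1_3 *= sc; clip += 1.0;
        }
        double d2 = (f2_2 + f2_3) * dt;
        if (d2 > c2 && d2 > 0.0) {
            double sc = c2 / d2;
            f2_2 *= sc; f2_3 *= sc; clip += 1.0;
        }
        double d3 = f3_3 * dt;
        if (d3 > c3 && d3 > 0.0) {
            f3_3 *= c3 / d3; clip += 1.0;
        }

        double rel1 = f1_1 + f1_2 + f1_3;
        double rel2 = f2_2 + f2_3;
        double rel3 = f3_3;
        double released = rel1 + rel2 + rel3;

        c1d -= rel1 * dt;
        c2  -= rel2 * dt;
        c3  -= rel3 * dt;
        if (c1d < 0.0) c1d = 0.0;
        if (c2 < 0.0) c2 = 0.0;
        if (c3 < 0.0) c3 = 0.0;

        // assimilation (e_i of flux) and growth respiration (1 - e_i)
        b1 += e1 * f1_1 * dt;
        b2 += (e1 * f1_2 + e2 * f2_2) * dt;
        b3 += (e1 * f1_3 + e2 * f2_3 + e3 * f3_3) * dt;
        double growth_resp = (1.0 - e1) * rel1 + (1.0 - e2) * rel2 +
                             (1.0 - e3) * rel3;

        // basal (maintenance) respiration, clipped at available biomass
        double r1 = std::min(g * b1 * dt, b1);
        double r2 = std::min(g * b2 * dt, b2);
        double r3 = std::min(g * b3 * dt, b3);
        b1 -= r1; b2 -= r2; b3 -= r3;

        cum_co2 += growth_resp * dt + r1 + r2 + r3;
        cum_rel += released * dt;

        // turnover cap: keep B_tot <= bc_max * (B_tot + substrates) by
        // removing the excess proportionally into necromass
        double S = c1d + c1t + c2 + c3;
        double btot = b1 + b2 + b3;
        if (btot > 0.0 && btot > bc_max * (btot + S)) {
            double target = bc_max * S / (1.0 - bc_max);
            double excess = btot - target;
            double sc = excess / btot;
            b1 -= sc * b1; b2 -= sc * b2; b3 -= sc * b3;
            necro += excess;
        }

        t += dt;

        if (!R_finite(c1d) || !R_finite(c2) || !R_finite(c3) ||
            !R_finite(b1) || !R_finite(b2) || !R_finite(b3)) {
            stop("non-finite state at step %d (t = %f days)", s + 1, t);
        }
    }
    return out;
}
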