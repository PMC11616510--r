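#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Reaction operator for one transport step, applied cell-by-cell.
//
// Mn(II) decays by pseudo-first-order (bacterially catalysed) oxidation,
// optionally augmented by an autocatalytic surface term; the decay is solved
// exactly within each substep with the autocatalyst inventory frozen.  Zn(II)
// follows linear-driving-force sorption onto the birnessite inventory; with
// the sorbent mass frozen at the substep midpoint the ODE is linear and is
// advanced with its closed-form solution, which is unconditionally stable and
// recovers the local sorption equilibrium exactly as km -> Inf.
static void react_core(std::vector<double>& cmn, std::vector<double>& czn,
                       std::vector<double>& qzn, std::vector<double>& msol,
                       std::vector<double>& mnox,
                       double k1, double k2, double km, double kd,
                       double mmo, bool growth, double dt, int nsub,
                       double& clipmax)
{
    const int n = (int)cmn.size();
    const double h = dt / nsub;
    for (int i = 0; i < n; ++i) {
        double cm = cmn[i], cz = czn[i], q = qzn[i], mi = msol[i], ox = mnox[i];
        for (int s = 0; s < nsub; ++s) {
            const double lambda = k1 + k2 * ox;
            const double cm1 = (lambda > 0.0) ? cm * std::exp(-lambda * h) : cm;
            const double d = cm - cm1;            // mol/L oxidised this substep
            ox += d;
            const double mmid = growth ? mi + 0.5 * d * mmo : mi;
            if (growth) mi += d * mmo;
            cm = cm1;
            if (km > 0.0 && kd > 0.0 && mmid > 0.0) {
                const double T   = cz + q;        // Zn per litre pore water is conserved
                const double ceq = T / (1.0 + mmid * kd);
                const double a   = km * (1.0 + 1.0 / (mmid * kd));
                cz = ceq + (cz - ceq) * std::exp(-a * h);
                q  = T - cz;
            }
        }
        if (cm < 0.0) { clipmax = std::max(clipmax, -cm); cm = 0.0; }
        if (cz < 0.0) { clipmax = std::max(clipmax, -cz); cz = 0.0; }
        if (q  < 0.0) { clipmax = std::max(clipmax, -q);  q  = 0.0; }
        cmn[i] = cm; czn[i] = cz; qzn[i] = q; msol[i] = mi; mnox[i] = ox;
    }
}

// [[Rcpp::export]]
List react_cells_cpp(NumericVector c_mn, NumericVector c_zn, NumericVector q_zn,
                     NumericVector m_solid, NumericVector mnox,
                     double k1, double k2, double km, double kd,
                     double mmo, bool growth, double dt, int nsub)
{
    std::vector<double> cm(c_mn.begin(), c_mn.end());
    std::vector<double> cz(c_zn.begin(), c_zn.end());
    std::vector<double> q(q_zn.begin(), q_zn.end());
    std::vector<double> m(m_solid.begin(), m_solid.end());
    std::vector<double> ox(mnox.begin(), mnox.end());
    double clipmax = 0.0;
    react_core(cm, cz, q, m, ox, k1, k2, km, kd, mmo, growth, dt, nsub, clipmax);
    return List::create(_["c_mn"] = wrap(cm), _["c_zn"] = wrap(cz),
                        _["q_zn"] = wrap(q), _["m_solid"] = wrap(m),
                        _["mnox"] = wrap(ox), _["clip_max"] = clipmax);
}

// One no-flux mixing sweep; fs is the per-sweep mixing fraction (<= 1/3).
static void mix_sweep(std::vector<double>& c, double fs, std::vector<double>& tmp)
{
    const int n = (int)c.size();
    if (n < 2) return;
    tmp = c;
    for (int i = 0; i < n; ++i) {
        const double lo = (i == 0)     ? tmp[i] : tmp[i - 1];
        const double hi = (i == n - 1) ? tmp[i] : tmp[i + 1];
        c[i] = tmp[i] + fs * (lo - 2.0 * tmp[i] + hi);
    }
}

// Cells-in-series advective transport: each step moves every parcel one cell
// downstream (dt = HRT / n_cells, zero numerical dispersion), then applies
// optional diffusive mixing (mixf = dispersivity / cell length, split into
// sweeps of at most 0.25 for stability), then the reaction operator.  The
// sorbent (birnessite inventory) is immobile.  The parcel popped from the last
// cell at the start of a step has resided exactly one HRT in the column.
// [[Rcpp::export]]
List engine_cpp(NumericVector c_mn0, NumericVector c_zn0, NumericVector q_zn0,
                NumericVector m0, NumericVector mnox0,
                double k1, double k2, double km, double kd,
                double mmo, bool growth,
                NumericVector in_t, NumericVector in_mn, NumericVector in_zn,
                double t0, double dt, int n_steps,
                double mixf, int nsub, int snapshot_every)
{
    const int n = c_mn0.size();
    std::vector<double> cmn(c_mn0.begin(), c_mn0.end());
    std::vector<double> czn(c_zn0.begin(), c_zn0.end());
    std::vector<double> qzn(q_zn0.begin(), q_zn0.end());
    std::vector<double> msol(m0.begin(), m0.end());
    std::vector<double> mnox(mnox0.begin(), mnox0.end());
    std::vector<double> tmp;

    NumericVector times(n_steps), out_mn(n_steps), out_zn(n_steps), ox_cum(n_steps);
    double imp_mn = 0.0, exp_mn = 0.0, imp_zn = 0.0, exp_zn = 0.0, clipmax = 0.0;

    int nsweep = 0; double fs = 0.0;
    if (mixf > 0.0) { nsweep = (int)std::ceil(mixf / 0.25); fs = mixf / nsweep; }

    int nsnap = 0;
    NumericMatrix snap_mn, snap_zn, snap_q, snap_m;
    NumericVector snap_t;
    if (snapshot_every > 0) {
        nsnap = (n_steps - 1) / snapshot_every + 1;
        snap_mn = NumericMatrix(nsnap, n); snap_zn = NumericMatrix(nsnap, n);
        snap_q  = NumericMatrix(nsnap, n); snap_m  = NumericMatrix(nsnap, n);
        snap_t  = NumericVector(nsnap);
    }
    int isnap = 0, idx = 0;
    const int nin = in_t.size();

    for (int s = 0; s < n_steps; ++s) {
        const double t_entry = t0 + s * dt;
        while (idx + 1 < nin && in_t[idx + 1] <= t_entry) ++idx;
        const double cin_mn = in_mn[idx], cin_zn = in_zn[idx];

        // pop outlet parcel, then shift downstream and admit the inlet parcel
        const double omn = cmn[n - 1], ozn = czn[n - 1];
        exp_mn += omn; exp_zn += ozn;
        for (int i = n - 1; i > 0; --i) { cmn[i] = cmn[i - 1]; czn[i] = czn[i - 1]; }
        cmn[0] = cin_mn; czn[0] = cin_zn;
        imp_mn += cin_mn; imp_zn += cin_zn;

        for (int w = 0; w < nsweep; ++w) { mix_sweep(cmn, fs, tmp); mix_sweep(czn, fs, tmp); }

        react_core(cmn, czn, qzn, msol, mnox, k1, k2, km, kd, mmo, growth, dt, nsub, clipmax);

        times[s] = t_entry; out_mn[s] = omn; out_zn[s] = ozn;
        double oxs = 0.0; for (int i = 0; i < n; ++i) oxs += mnox[i];
        ox_cum[s] = oxs;

        if (snapshot_every > 0 && s % snapshot_every == 0 && isnap < nsnap) {
            for (int i = 0; i < n; ++i) {
                snap_mn(isnap, i) = cmn[i]; snap_zn(isnap, i) = czn[i];
                snap_q(isnap, i) = qzn[i];  snap_m(isnap, i) = msol[i];
            }
            snap_t[isnap] = t_entry + dt;
            ++isnap;
        }
        if (!std::isfinite(cmn[0]) || !std::isfinite(czn[0]))
            stop("non-finite state at step %d (t = %g s)", s, t_entry);
    }

    List out = List::create(
        _["times_s"] = times, _["out_mn"] = out_mn, _["out_zn"] = out_zn,
        _["mnox_cum"] = ox_cum,
        _["state"] = List::create(_["c_mn"] = wrap(cmn), _["c_zn"] = wrap(czn),
                                  _["q_zn"] = wrap(qzn), _["m_solid"] = wrap(msol),
                                  _["mnox"] = wrap(mnox)),
        _["budget"] = NumericVector::create(
            _["imp_mn"] = imp_mn, _["exp_mn"] = exp_mn,
            _["imp_zn"] = imp_zn, _["exp_zn"] = exp_zn),
        _["clip_max"] = clipmax);
    if (snapshot_every > 0)
        out["snapshots"] = List::create(_["times_s"] = snap_t, _["c_mn"] = snap_mn,
                                        _["c_zn"] = snap_zn, _["q_zn"] = snap_q,
                                        _["m_solid"] = snap_m);
    return out;
}
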