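// Forward model for one-state bilinear DCM with balloon/windkessel haemodynamics.
//
// The neuronal subsystem dz/dt = (A + sum_j u_j B_j) z + C u is linear for a
// fixed input vector, so within each microtime bin (inputs are piecewise
// constant on the bin grid) the state is propagated exactly by the matrix
// exponential of the augmented system; the propagator is cached and rebuilt
// only when the input vector changes. The nonlinear haemodynamic states
// (vasodilatory signal, log blood flow, log venous volume, log deoxyhaemoglobin)
// are advanced by classical fourth-order Runge-Kutta on the same grid, with the
// neuronal drive linearly interpolated across the bin.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

// balloon-model constants (standard one-state DCM defaults)
const double H_KAPPA = 0.64; // vasodilatory signal decay rate (1/s)
const double H_GAMMA = 0.32; // flow autoregulation rate (1/s)
const double H_TAU   = 2.0;  // mean venous transit time (s), scaled per region
const double H_ALPHA = 0.32; // vessel stiffness exponent (Grubb)
const double H_E0    = 0.4;  // resting oxygen extraction fraction
const double H_V0    = 4.0;  // resting venous volume (percent signal units)
const double Z_CAP   = 1e6;  // neuronal amplitude treated as divergence
const double C_SCALE = 1.0 / 16.0; // driving-input scaling (units convention)
const double LOG_CAP = 8.0;  // clamp for haemodynamic log-states
const double S_CAP   = 50.0; // clamp for the vasodilatory signal

inline void haemo_deriv(double z, const double* x, double tau, double gn,
                        double* d)
{
    const double s = x[0];
    const double f = std::exp(x[1]);
    const double v = std::exp(x[2]);
    const double q = std::exp(x[3]);
    const double fout = std::pow(v, 1.0 / H_ALPHA);
    const double Ef = 1.0 - std::pow(1.0 - H_E0, 1.0 / f);
    d[0] = gn * z - H_KAPPA * s - H_GAMMA * (f - 1.0);
    d[1] = s / f;
    d[2] = (f - fout) / (tau * v);
    d[3] = (f * Ef / H_E0 - fout * q / v) / (tau * q);
}

// core integrator; returns false on divergence and reports where
bool sim_core(const mat& A, const mat& Bself, const mat& C,
              const vec& transit, const vec& gain, const mat& u,
              int n_vol, int bins, double dt,
              mat& Y, int& bad_region, double& bad_time)
{
    const int N = A.n_rows;
    const int J = u.n_cols;
    vec z(N, fill::zeros), znew(N);
    mat h(4, N, fill::zeros); // rows: s, log f, log v, log q
    vec tau(N), gn(N);
    for (int i = 0; i < N; ++i) {
        tau(i) = H_TAU * std::exp(transit(i));
        gn(i)  = std::exp(gain(i));
    }
    const double k1 = 7.0 * H_E0, k2 = 2.0, k3 = 2.0 * H_E0 - 0.2;
    mat Ez(N, N, fill::eye);
    vec bz(N, fill::zeros);
    rowvec uprev;
    bool have_prop = false;
    int vol = 0;
    const int steps = n_vol * bins;
    double xa[4], xb[4], d1[4], d2[4], d3[4], d4[4];

    for (int t = 0; t < steps; ++t) {
        bool changed = !have_prop;
        rowvec ut;
        if (J > 0) {
            ut = u.row(t);
            if (have_prop) changed = any(ut != uprev);
        }
        if (changed) {
            mat Aeff = A;
            for (int i = 0; i < N; ++i) {
                double self = A(i, i);
                for (int j = 0; j < J; ++j) self += ut(j) * Bself(i, j);
                Aeff(i, i) = -0.5 * std::exp(self);
            }
            // augmented exponential gives the exact affine propagator
            mat M(N + 1, N + 1, fill::zeros);
            M.submat(0, 0, N - 1, N - 1) = Aeff;
            if (J > 0) M.submat(0, N, N - 1, N) = C_SCALE * C * ut.t();
            mat E = expmat(M * dt);
            Ez = E.submat(0, 0, N - 1, N - 1);
            bz = E.submat(0, N, N - 1, N);
            if (J > 0) uprev = ut;
            have_prop = true;
        }
        znew = Ez * z + bz;

        for (int i = 0; i < N; ++i) {
            const double zi0 = z(i);
            const double zim = 0.5 * (z(i) + znew(i));
            const double zi1 = znew(i);
            double* xc = h.colptr(i);
            haemo_deriv(zi0, xc, tau(i), gn(i), d1);
            for (int k = 0; k < 4; ++k) xa[k] = xc[k] + 0.5 * dt * d1[k];
            haemo_deriv(zim, xa, tau(i), gn(i), d2);
            for (int k = 0; k < 4; ++k) xa[k] = xc[k] + 0.5 * dt * d2[k];
            haemo_deriv(zim, xa, tau(i), gn(i), d3);
            for (int k = 0; k < 4; ++k) xb[k] = xc[k] + dt * d3[k];
            haemo_deriv(zi1, xb, tau(i), gn(i), d4);
            for (int k = 0; k < 4; ++k)
                xc[k] += dt / 6.0 * (d1[k] + 2.0 * d2[k] + 2.0 * d3[k] + d4[k]);
            // keep haemodynamics in a physical regime (flow/volume/dHb are
            // logs; runaway excursions are clamped rather than propagated)
            xc[0] = std::max(-S_CAP, std::min(S_CAP, xc[0]));
            for (int k = 1; k < 4; ++k)
                xc[k] = std::max(-LOG_CAP, std::min(LOG_CAP, xc[k]));
        }
        z = znew;

        bool bad = !z.is_finite() || !h.is_finite() || abs(z).max() > Z_CAP;
        if (bad) {
            bad_time = (t + 1) * dt;
            bad_region = 1;
            for (int i = 0; i < N; ++i) {
                bool b = !std::isfinite(z(i)) || std::fabs(z(i)) > Z_CAP;
                for (int k = 0; k < 4 && !b; ++k) b = !std::isfinite(h(k, i));
                if (b) { bad_region = i + 1; break; }
            }
            return false;
        }
        if ((t + 1) % bins == 0) {
            for (int i = 0; i < N; ++i) {
                const double v = std::exp(h(2, i));
                const double q = std::exp(h(3, i));
                Y(vol, i) = H_V0 * (k1 * (1.0 - q) + k2 * (1.0 - q / v) +
                                    k3 * (1.0 - v));
            }
            ++vol;
        }
    }
    return true;
}

void build_params(const vec& theta, const ivec& type, const ivec& ri,
                  const ivec& ci, int N, int J,
                  mat& A, mat& Bself, mat& C, vec& transit, vec& gain)
{
    const int Jc = std::max(J, 1);
    A.zeros(N, N);
    Bself.zeros(N, Jc);
    C.zeros(N, Jc);
    transit.zeros(N);
    gain.zeros(N);
    for (uword k = 0; k < theta.n_elem; ++k) {
        const int i = ri(k) - 1, j = ci(k) - 1;
        switch (type(k)) {
        case 0: A(i, j) = theta(k); break;
        case 1: Bself(i, j) = theta(k); break; // row = region, col = input
        case 2: C(i, j) = theta(k); break;
        case 3: transit(i) = theta(k); break;
        case 4: gain(i) = theta(k); break;
        default: Rcpp::stop("unknown parameter type code");
        }
    }
}

} // namespace

// [[Rcpp::export]]
List dcm_simulate_cpp(const arma::mat& A, const arma::mat& Bself,
                      const arma::mat& C, const arma::vec& transit,
                      const arma::vec& gain, const arma::mat& u,
                      int n_vol, int bins, double dt)
{
    mat Y(n_vol, A.n_rows, fill::zeros);
    int bad_region = 0;
    double bad_time = 0.0;
    bool ok = sim_core(A, Bself, C, transit, gain, u, n_vol, bins, dt,
                       Y, bad_region, bad_time);
    return List::create(_["y"] = Y, _["ok"] = ok,
                        _["bad_region"] = bad_region, _["bad_time"] = bad_time);
}

// [[Rcpp::export]]
List dcm_predict_cpp(const arma::vec& theta, const arma::ivec& type,
                     const arma::ivec& ri, const arma::ivec& ci,
                     int N, const arma::mat& u, int n_vol, int bins, double dt)
{
    mat A, Bself, C;
    vec transit, gain;
    build_params(theta, type, ri, ci, N, u.n_cols, A, Bself, C, transit, gain);
    mat Y(n_vol, N, fill::zeros);
    int bad_region = 0;
    double bad_time = 0.0;
    bool ok = sim_core(A, Bself, C, transit, gain, u, n_vol, bins, dt,
                       Y, bad_region, bad_time);
    return List::create(_["y"] = vectorise(Y), _["ok"] = ok,
                        _["bad_region"] = bad_region, _["bad_time"] = bad_time);
}

// Central finite-difference Jacobian of the sampled BOLD prediction with
// respect to the free parameters (columns of the returned matrix follow
// free_idx, 1-based into theta).
// [[Rcpp::export]]
List dcm_jacobian_cpp(const arma::vec& theta, const arma::ivec& type,
                      const arma::ivec& ri, const arma::ivec& ci,
                      int N, const arma::mat& u, int n_vol, int bins,
                      double dt, const arma::uvec& free_idx, double step)
{
    const int J = u.n_cols;
    mat A, Bself, C;
    vec transit, gain;
    mat Y(n_vol, N, fill::zeros);
    int bad_region = 0;
    double bad_time = 0.0;

    build_params(theta, type, ri, ci, N, J, A, Bself, C, transit, gain);
    bool ok = sim_core(A, Bself, C, transit, gain, u, n_vol, bins, dt,
                       Y, bad_region, bad_time);
    if (!ok)
        return List::create(_["ok"] = false, _["bad_region"] = bad_region,
                            _["bad_time"] = bad_time);
    vec y0 = vectorise(Y);

    mat Jac(y0.n_elem, free_idx.n_elem, fill::zeros);
    vec th = theta;
    for (uword k = 0; k < free_idx.n_elem; ++k) {
        const uword p = free_idx(k) - 1;
        const double orig = th(p);
        th(p) = orig + step;
        build_params(th, type, ri, ci, N, J, A, Bself, C, transit, gain);
        mat Yp(n_vol, N, fill::zeros);
        bool okp = sim_core(A, Bself, C, transit, gain, u, n_vol, bins, dt,
                            Yp, bad_region, bad_time);
        th(p) = orig - step;
        build_params(th, type, ri, ci, N, J, A, Bself, C, transit, gain);
        mat Ym(n_vol, N, fill::zeros);
        bool okm = sim_core(A, Bself, C, transit, gain, u, n_vol, bins, dt,
                            Ym, bad_region, bad_time);
        th(p) = orig;
        if (!okp || !okm)
            return List::create(_["ok"] = false, _["bad_region"] = bad_region,
                                _["bad_time"] = bad_time);
        Jac.col(k) = vectorise(Yp - Ym) / (2.0 * step);
    }
    return List::create(_["y"] = y0, _["J"] = Jac, _["ok"] = true,
                        _["bad_region"] = 0, _["bad_time"] = 0.0);
}
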