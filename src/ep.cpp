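// Expectation propagation for Bayesian logistic regression under a
// multivariate Laplace prior.
//
// Model: y_t ~ Bernoulli(sigmoid(x_t' beta + b))
//        beta_i | u_i, v_i ~ N(0, u_i^2 + v_i^2)
//        u ~ N(0, J^-1), v ~ N(0, J^-1) independently (J unit-diagonal scaled)
//        b ~ N(0, bias_var)
//
// Sites: one Gaussian site per likelihood term on the linear predictor
// a_t = z_t' theta, and per feature a Gaussian site on beta_i plus a
// zero-mean precision site on u_i (= v_i by symmetry).  Tilted moments use
// Gauss-Hermite quadrature (logistic x Gaussian) and Gauss-Laguerre
// quadrature over the exponential mixing scale s = u^2 + v^2.  Updates are
// parallel with damping; sites with non-positive cavity precision are
// skipped for that sweep.  Fully deterministic for fixed inputs.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// [[Rcpp::export(name = ".ep_mvlaplace")]]
Rcpp::List ep_mvlaplace(const arma::mat& X,     // n x d, standardized features
                        const arma::vec& sgn,   // +1 / -1 labels
                        const arma::mat& J,     // d x d prior precision (dense)
                        const double bias_var,
                        const arma::vec& ghx, const arma::vec& ghw,
                        const arma::vec& glx, const arma::vec& glw,
                        const int max_iter,
                        const double tol,
                        const double damping,
                        const double lambda_min_J)
{
    const uword n = X.n_rows, d = X.n_cols, D = d + 1;
    mat Z(n, D);
    Z.cols(0, d - 1) = X;
    Z.col(d).ones();

    vec tau(n, fill::zeros), nu(n, fill::zeros);     // likelihood sites
    vec kap(d, fill::ones), eta(d, fill::zeros);     // beta sites
    vec tauu(d, fill::zeros);                        // u/v sites
    const double tauu_floor = -0.95 * lambda_min_J;

    vec prior_diag(D);
    mat P, Sig, ZS, Au, Su;
    vec m, mu_a, va, rho2;
    bool converged = false;
    int it = 0;
    double maxdelta = datum::nan;

    const uword K = ghx.n_elem, L = glx.n_elem;

    for (it = 1; it <= max_iter; ++it) {
        // global Gaussian approximation over (beta, bias)
        prior_diag.subvec(0, d - 1) = kap;
        prior_diag(d) = 1.0 / bias_var;
        P = Z.t() * (Z.each_col() % tau) + diagmat(prior_diag);
        Sig = inv_sympd(symmatu(P));
        vec h = Z.t() * nu;
        h.subvec(0, d - 1) += eta;
        m = Sig * h;
        mu_a = Z * m;
        ZS = Z * Sig;
        va = sum(ZS % Z, 1);

        // marginal variances of u under q(u) = N(0, (J + diag(tauu))^-1)
        Au = J + diagmat(tauu);
        Su = inv_sympd(symmatu(Au));
        rho2 = Su.diag();

        double dl = 0.0, dc = 0.0;

        // ---- likelihood sites (parallel update) ----
        for (uword t = 0; t < n; ++t) {
            const double tc = 1.0 / va(t) - tau(t);
            if (tc <= 1e-10) continue;
            const double nc = mu_a(t) / va(t) - nu(t);
            const double mc = nc / tc, vc = 1.0 / tc;
            const double sd2 = std::sqrt(2.0 * vc);
            double z0 = 0.0, z1 = 0.0, z2 = 0.0;
            for (uword k = 0; k < K; ++k) {
                const double a = mc + sd2 * ghx(k);
                const double g = 1.0 / (1.0 + std::exp(-sgn(t) * a));
                const double w = ghw(k) * g;
                z0 += w; z1 += w * a; z2 += w * a * a;
            }
            if (z0 <= 0.0) continue;
            const double m1 = z1 / z0;
            double vt = z2 / z0 - m1 * m1;
            if (vt < 1e-12) vt = 1e-12;
            double tau_new = 1.0 / vt - tc;
            if (tau_new < 0.0) tau_new = 0.0;
            const double nu_new = m1 / vt - nc;
            dl = std::max(dl, std::fabs(tau_new - tau(t)));
            dl = std::max(dl, std::fabs(nu_new - nu(t)));
            tau(t) = (1.0 - damping) * tau(t) + damping * tau_new;
            nu(t)  = (1.0 - damping) * nu(t)  + damping * nu_new;
        }

        // ---- coupling sites (parallel update) ----
        for (uword i = 0; i < d; ++i) {
            const double sb2 = Sig(i, i);
            const double tcb = 1.0 / sb2 - kap(i);
            const double tcu = 1.0 / rho2(i) - tauu(i);
            if (tcb <= 1e-10 || tcu <= 1e-10) continue;
            const double ncb = m(i) / sb2 - eta(i);
            const double mc = ncb / tcb, vc = 1.0 / tcb;
            const double rc2 = 1.0 / tcu;
            // quadrature over s = 2 * rc2 * t, t ~ Gauss-Laguerre
            double lmax = -datum::inf;
            vec logl(L);
            for (uword k = 0; k < L; ++k) {
                const double s = 2.0 * rc2 * glx(k);
                const double tot = s + vc;
                logl(k) = -0.5 * std::log(tot) - mc * mc / (2.0 * tot);
                if (logl(k) > lmax) lmax = logl(k);
            }
            double z0 = 0.0, zm = 0.0, zm2 = 0.0, zs = 0.0;
            for (uword k = 0; k < L; ++k) {
                const double s = 2.0 * rc2 * glx(k);
                const double tot = s + vc;
                const double w = glw(k) * std::exp(logl(k) - lmax);
                const double mk = mc * s / tot;
                const double vk = s * vc / tot;
                z0 += w; zm += w * mk; zm2 += w * (vk + mk * mk); zs += w * s;
            }
            if (z0 <= 0.0) continue;
            const double m1 = zm / z0;
            double vt = zm2 / z0 - m1 * m1;
            if (vt < 1e-12) vt = 1e-12;
            double eu2 = 0.5 * zs / z0;
            if (eu2 < 1e-12) eu2 = 1e-12;
            const double kap_new = 1.0 / vt - tcb;
            const double eta_new = m1 / vt - ncb;
            double tauu_new = 1.0 / eu2 - tcu;
            if (tauu_new < tauu_floor) tauu_new = tauu_floor;
            dc = std::max(dc, std::fabs(kap_new - kap(i)));
            dc = std::max(dc, std::fabs(eta_new - eta(i)));
            dc = std::max(dc, std::fabs(tauu_new - tauu(i)));
            kap(i)  = (1.0 - damping) * kap(i)  + damping * kap_new;
            eta(i)  = (1.0 - damping) * eta(i)  + damping * eta_new;
            tauu(i) = (1.0 - damping) * tauu(i) + damping * tauu_new;
        }

        maxdelta = std::max(dl, dc);
        if (maxdelta < tol) { converged = true; break; }
    }
    if (it > max_iter) it = max_iter;

    // final global approximation from the last site values
    prior_diag.subvec(0, d - 1) = kap;
    prior_diag(d) = 1.0 / bias_var;
    P = Z.t() * (Z.each_col() % tau) + diagmat(prior_diag);
    Sig = inv_sympd(symmatu(P));
    vec h = Z.t() * nu;
    h.subvec(0, d - 1) += eta;
    m = Sig * h;
    Au = J + diagmat(tauu);
    Su = inv_sympd(symmatu(Au));
    rho2 = Su.diag();

    return Rcpp::List::create(
        Rcpp::Named("mean") = m,
        Rcpp::Named("cov") = Sig,
        Rcpp::Named("aux_variance") = rho2,
        Rcpp::Named("iterations") = it,
        Rcpp::Named("converged") = converged,
        Rcpp::Named("max_site_change") = maxdelta);
}
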