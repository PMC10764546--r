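#include <Rcpp.h>
using namespace Rcpp;

// One Gibbs chain for the three-level hierarchy
//   y_i  ~ Normal(mu_i, precision tau / wpow_i)
//   mu_i ~ Normal(M, precision T)
//   M    ~ Normal(m0, variance v0)
//   tau, T ~ Gamma(a, b)   (rate parameterization)
// wpow_i is omega_i^2 (omega scales the study SD) or omega_i (omega scales
// the variance). All full conditionals are conjugate and sampled exactly.
// Uses R's RNG stream, so results are reproducible under set.seed().
// [[Rcpp::export]]
NumericMatrix gibbs_chain_cpp(NumericVector y, NumericVector wpow,
                              double m0, double v0, double a, double b,
                              int iters, int burn, int thin,
                              NumericVector muInit, double MInit,
                              double tauInit, double TInit,
                              bool fixTau, bool fixT) {
    const int K = y.size();
    const int kept = (iters - burn) / thin;
    NumericMatrix out(kept, K + 3);
    std::vector<double> mu(muInit.begin(), muInit.end());
    double M = MInit, tau = tauInit, Tprec = TInit;
    int row = 0;
    for (int it = 1; it <= iters; ++it) {
        double summu = 0.0;
        for (int i = 0; i < K; ++i) {
            const double py = tau / wpow[i];
            const double prec = py + Tprec;
            const double mean = (py * y[i] + Tprec * M) / prec;
            mu[i] = R::rnorm(mean, 1.0 / std::sqrt(prec));
            summu += mu[i];
        }
        const double precM = K * Tprec + 1.0 / v0;
        M = R::rnorm((Tprec * summu + m0 / v0) / precM,
                     1.0 / std::sqrt(precM));
        if (!fixTau) {
            double ss = 0.0;
            for (int i = 0; i < K; ++i) {
                const double e = y[i] - mu[i];
                ss += e * e / wpow[i];
            }
            tau = R::rgamma(a + 0.5 * K, 1.0 / (b + 0.5 * ss));
        }
        if (!fixT) {
            double ss = 0.0;
            for (int i = 0; i < K; ++i) {
                const double e = mu[i] - M;
                ss += e * e;
            }
            Tprec = R::rgamma(a + 0.5 * K, 1.0 / (b + 0.5 * ss));
        }
        if (it > burn && (it - burn) % thin == 0 && row < kept) {
            out(row, 0) = M;
            for (int i = 0; i < K; ++i) out(row, 1 + i) = mu[i];
            out(row, K + 1) = tau;
            out(row, K + 2) = Tprec;
            ++row;
        }
    }
    return out;
}
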