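// Scaled forward-backward and Viterbi passes for a Bernoulli-emission HMM.
// Emission probabilities arrive as a T x K matrix of per-bin per-state
// likelihoods (computed in R from the clipped emission parameters); scaling
// constants keep the recursions in linear space without underflow.
#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export(name = ".fb_pass")]]
List fb_pass(NumericMatrix B, NumericVector pi, NumericMatrix A) {
    const int T = B.nrow(), K = B.ncol();
    NumericMatrix alpha(T, K), beta(T, K), gamma(T, K);
    NumericVector c(T);
    NumericMatrix xi(K, K);

    // forward
    double s = 0.0;
    for (int k = 0; k < K; ++k) { alpha(0, k) = pi[k] * B(0, k); s += alpha(0, k); }
    if (s <= 0) stop("zero forward mass at t=1");
    c[0] = s;
    for (int k = 0; k < K; ++k) alpha(0, k) /= s;
    for (int t = 1; t < T; ++t) {
        s = 0.0;
        for (int k = 0; k < K; ++k) {
            double a = 0.0;
            for (int j = 0; j < K; ++j) a += alpha(t - 1, j) * A(j, k);
            a *= B(t, k);
            alpha(t, k) = a;
            s += a;
        }
        if (s <= 0) stop("zero forward mass");
        c[t] = s;
        for (int k = 0; k < K; ++k) alpha(t, k) /= s;
    }

    // backward (same scaling constants)
    for (int k = 0; k < K; ++k) beta(T - 1, k) = 1.0;
    for (int t = T - 2; t >= 0; --t) {
        for (int j = 0; j < K; ++j) {
            double b = 0.0;
            for (int k = 0; k < K; ++k) b += A(j, k) * B(t + 1, k) * beta(t + 1, k);
            beta(t, j) = b / c[t + 1];
        }
    }

    // posteriors and pooled two-slice statistics
    for (int t = 0; t < T; ++t) {
        double g = 0.0;
        for (int k = 0; k < K; ++k) { gamma(t, k) = alpha(t, k) * beta(t, k); g += gamma(t, k); }
        for (int k = 0; k < K; ++k) gamma(t, k) /= g;
    }
    for (int t = 0; t < T - 1; ++t) {
        for (int j = 0; j < K; ++j) {
            const double aj = alpha(t, j);
            for (int k = 0; k < K; ++k)
                xi(j, k) += aj * A(j, k) * B(t + 1, k) * beta(t + 1, k) / c[t + 1];
        }
    }

    double ll = 0.0;
    for (int t = 0; t < T; ++t) ll += std::log(c[t]);
    return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}

// [[Rcpp::export(name = ".viterbi_pass")]]
IntegerVector viterbi_pass(NumericMatrix logB, NumericVector logPi,
                           NumericMatrix logA) {
    const int T = logB.nrow(), K = logB.ncol();
    NumericMatrix delta(T, K);
    IntegerMatrix psi(T, K);
    for (int k = 0; k < K; ++k) delta(0, k) = logPi[k] + logB(0, k);
    for (int t = 1; t < T; ++t) {
        for (int k = 0; k < K; ++k) {
            double best = R_NegInf; int arg = 0;
            for (int j = 0; j < K; ++j) {
                const double v = delta(t - 1, j) + logA(j, k);
                if (v > best) { best = v; arg = j; }
            }
            delta(t, k) = best + logB(t, k);
            psi(t, k) = arg;
        }
    }
    IntegerVector path(T);
    double best = R_NegInf; int arg = 0;
    for (int k = 0; k < K; ++k)
        if (delta(T - 1, k) > best) { best = delta(T - 1, k); arg = k; }
    path[T - 1] = arg;
    for (int t = T - 1; t > 0; --t) path[t - 1] = psi(t, path[t]);
    return path + 1;  // 1-based state indices
}
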