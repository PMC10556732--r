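#include <Rcpp.h>
using namespace Rcpp;

// Direct non-iterative solver for the 1-D total-variation proximity problem
//   min_x  1/2 * sum_i (y_i - x_i)^2  +  lambda * sum_i |x_{i+1} - x_i|
// (Condat's taut-string-equivalent sweep, O(n) amortized, exact in
// floating point). Bins belonging to one fitted plateau receive the
// identical double, so plateaus can be recovered by exact equality.

// [[Rcpp::export]]
NumericVector tv1d_prox(NumericVector y, double lambda) {
    const int width = y.size();
    NumericVector out(width);
    if (width == 0) return out;
    if (lambda <= 0.0) {
        for (int i = 0; i < width; ++i) out[i] = y[i];
        return out;
    }
    const double twolambda = 2.0 * lambda;
    const double minlambda = -lambda;
    int k = 0, k0 = 0, kminus = 0, kplus = 0;
    double umin = lambda, umax = minlambda;
    double vmin = y[0] - lambda, vmax = y[0] + lambda;
    for (;;) {
        while (k == width - 1) {
            if (umin < 0.0) {            // negative jump forced at kminus
                do { out[k0++] = vmin; } while (k0 <= kminus);
                umax = (vmin = y[kminus = k = k0]) + (umin = lambda) - vmax;
            } else if (umax > 0.0) {     // positive jump forced at kplus
                do { out[k0++] = vmax; } while (k0 <= kplus);
                umin = (vmax = y[kplus = k = k0]) + (umax = minlambda) - vmin;
            } else {                     // tail segment at its mean
                vmin += umin / (k - k0 + 1);
                do { out[k0++] = vmin; } while (k0 <= k);
                return out;
            }
        }
        umin += y[k + 1] - vmin;
        if (umin < minlambda) {          // lower constraint violated
            do { out[k0++] = vmin; } while (k0 <= kminus);
            vmax = (vmin = y[kplus = kminus = k = k0]) + twolambda;
            umin = lambda;
            umax = minlambda;
        } else {
            umax += y[k + 1] - vmax;
            if (umax > lambda) {         // upper constraint violated
                do { out[k0++] = vmax; } while (k0 <= kplus);
                vmin = (vmax = y[kplus = kminus = k = k0]) - twolambda;
                umin = lambda;
                umax = minlambda;
            } else {                     // feasible: extend current segment
                ++k;
                if (umin >= lambda) {
                    vmin += (umin - lambda) / ((kminus = k) - k0 + 1);
                    umin = lambda;
                }
                if (umax <= minlambda) {
                    vmax += (umax + lambda) / ((kplus = k) - k0 + 1);
                    umax = minlambda;
                }
            }
        }
    }
}
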