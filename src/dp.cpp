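#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Numerically safe log-sum-exp for two operands.
static inline double lse(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    double m = a > b ? a : b;
    return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// Log match emission; residue codes 0..3 = A,C,G,U; 4 = N.
// N emits the marginal (mean over the four bases).
static inline double lem(const NumericMatrix &emitM, int a, int b) {
    double p;
    if (a < 4 && b < 4) {
        p = emitM(a, b);
    } else if (a == 4 && b == 4) {
        p = 0.0;
        for (int i = 0; i < 4; ++i)
            for (int j = 0; j < 4; ++j) p += emitM(i, j);
        p /= 16.0;
    } else if (a == 4) {
        p = 0.0;
        for (int i = 0; i < 4; ++i) p += emitM(i, b);
        p /= 4.0;
    } else {
        p = 0.0;
        for (int j = 0; j < 4; ++j) p += emitM(a, j);
        p /= 4.0;
    }
    return p > 0 ? std::log(p) : R_NegInf;
}

static inline double lei(const NumericVector &emitI, int a) {
    double p = (a < 4) ? emitI[a] : 0.25;
    return p > 0 ? std::log(p) : R_NegInf;
}

// Pair-HMM forward-backward posterior match probabilities.
// States: 0 = M (emit x_i,y_j), 1 = Ix (emit x_i), 2 = Iy (emit y_j).
// A path's probability is init[s1] * prod(trans) * prod(emissions); the
// total marginalizes over all monotone global alignments (no end state).
// [[Rcpp::export]]
List phmm_posterior_cpp(IntegerVector x, IntegerVector y,
                        NumericMatrix emitM, NumericVector emitI,
                        NumericMatrix trans, NumericVector init) {
    const int n1 = x.size(), n2 = y.size();
    if (n1 < 1 || n2 < 1) stop("sequences must be nonempty");
    const int W = n2 + 1;
    const int NC = (n1 + 1) * W;
    std::vector<double> F[3], B[3];
    for (int s = 0; s < 3; ++s) {
        F[s].assign(NC, R_NegInf);
        B[s].assign(NC, R_NegInf);
    }
    double ltr[3][3], lin[3];
    for (int s = 0; s < 3; ++s) {
        lin[s] = init[s] > 0 ? std::log(init[s]) : R_NegInf;
        for (int t = 0; t < 3; ++t)
            ltr[s][t] = trans(s, t) > 0 ? std::log(trans(s, t)) : R_NegInf;
    }
    // Forward.
    for (int i = 0; i <= n1; ++i) {
        for (int j = 0; j <= n2; ++j) {
            const int c = i * W + j;
            if (i >= 1 && j >= 1) {
                double acc = (i == 1 && j == 1) ? lin[0] : R_NegInf;
                const int p = (i - 1) * W + (j - 1);
                for (int s = 0; s < 3; ++s)
                    acc = lse(acc, F[s][p] + ltr[s][0]);
                F[0][c] = acc + lem(emitM, x[i - 1], y[j - 1]);
            }
            if (i >= 1) {
                double acc = (i == 1 && j == 0) ? lin[1] : R_NegInf;
                const int p = (i - 1) * W + j;
                for (int s = 0; s < 3; ++s)
                    acc = lse(acc, F[s][p] + ltr[s][1]);
                F[1][c] = acc + lei(emitI, x[i - 1]);
            }
            if (j >= 1) {
                double acc = (i == 0 && j == 1) ? lin[2] : R_NegInf;
                const int p = i * W + (j - 1);
                for (int s = 0; s < 3; ++s)
                    acc = lse(acc, F[s][p] + ltr[s][2]);
                F[2][c] = acc + lei(emitI, y[j - 1]);
            }
        }
    }
    const int end = n1 * W + n2;
    double logZf = R_NegInf;
    for (int s = 0; s < 3; ++s) logZf = lse(logZf, F[s][end]);
    if (logZf == R_NegInf) stop("degenerate pair-HMM parameters: zero partition value");

    // Backward: B[s][i][j] = log P(emit the rest | state s just consumed (i,j)).
    for (int s = 0; s < 3; ++s) B[s][end] = 0.0;
    for (int i = n1; i >= 0; --i) {
        for (int j = n2; j >= 0; --j) {
            const int c = i * W + j;
            if (i == n1 && j == n2) continue;
            double em = (i < n1 && j < n2)
                            ? lem(emitM, x[i], y[j]) + B[0][(i + 1) * W + (j + 1)]
                            : R_NegInf;
            double ex = (i < n1) ? lei(emitI, x[i]) + B[1][(i + 1) * W + j] : R_NegInf;
            double ey = (j < n2) ? lei(emitI, y[j]) + B[2][i * W + (j + 1)] : R_NegInf;
            for (int s = 0; s < 3; ++s) {
                double acc = R_NegInf;
                if (em != R_NegInf) acc = lse(acc, ltr[s][0] + em);
                if (ex != R_NegInf) acc = lse(acc, ltr[s][1] + ex);
                if (ey != R_NegInf) acc = lse(acc, ltr[s][2] + ey);
                B[s][c] = acc;
            }
        }
    }
    double logZb = R_NegInf;
    logZb = lse(logZb, lin[0] + lem(emitM, x[0], y[0]) + B[0][1 * W + 1]);
    logZb = lse(logZb, lin[1] + lei(emitI, x[0]) + B[1][1 * W + 0]);
    logZb = lse(logZb, lin[2] + lei(emitI, y[0]) + B[2][0 * W + 1]);

    NumericMatrix post(n1, n2);
    for (int i = 1; i <= n1; ++i)
        for (int j = 1; j <= n2; ++j) {
            double lp = F[0][i * W + j] + B[0][i * W + j] - logZf;
            post(i - 1, j - 1) = std::exp(lp);
        }
    return List::create(_["post"] = post, _["logZf"] = logZf, _["logZb"] = logZb);
}

// Boltzmann-weighted Nussinov-style partition function with stacking, via
// inside-outside decomposition.  w is a 5x5 matrix of pair weights (0 for
// non-canonical and for anything involving N); h is the minimum hairpin
// loop length; `stack` multiplies the weight of every directly stacked
// pair of pairs ((i,j) enclosing (i+1,j-1)), which concentrates the
// ensemble on contiguous helices as thermodynamic models do.
//   qb(i,j) = w(i,j) * ( q(i+1,j-1) + (stack-1) * qb(i+1,j-1) )
//   q(i,j)  = q(i+1,j) + sum_k qb(i,k) q(k+1,j)
// Every nested structure is counted once (partition by the state of base i),
// with total weight prod(pair weights) * stack^(number of stacked pairs).
// [[Rcpp::export]]
NumericMatrix mccaskill_cpp(IntegerVector x, NumericMatrix w, int h,
                            double stack = 1.0) {
    const int n = x.size();
    NumericMatrix p(n, n);
    if (n < 2) return p;
    // q/qb over closed intervals, 1-based with empty-interval padding.
    std::vector< std::vector<double> > q(n + 2, std::vector<double>(n + 2, 1.0));
    std::vector< std::vector<double> > qb(n + 2, std::vector<double>(n + 2, 0.0));
    auto pw = [&](int i, int k) -> double {  // 1-based positions
        int a = x[i - 1], b = x[k - 1];
        if (a > 4 || b > 4) return 0.0;
        return w(a, b);
    };
    for (int span = 1; span < n; ++span) {
        for (int i = 1; i + span <= n; ++i) {
            int j = i + span;
            double wij = pw(i, j);
            if (wij > 0 && span - 1 >= h)
                qb[i][j] = wij * (q[i + 1][j - 1] +
                                  (stack - 1.0) * qb[i + 1][j - 1]);
            double acc = q[i + 1][j];
            for (int k = i + h + 1; k <= j; ++k)
                if (qb[i][k] > 0)
                    acc += qb[i][k] * (k + 1 <= j ? q[k + 1][j] : 1.0);
            if (!std::isfinite(acc)) stop("partition function overflow");
            q[i][j] = acc;
        }
    }
    const double Z = q[1][n];
    // Pairable pairs, outermost (largest span) first.
    std::vector<int> pi, pj;
    std::vector< std::vector<int> > idx(n + 2, std::vector<int>(n + 2, -1));
    for (int span = n - 1; span >= h + 1; --span)
        for (int i = 1; i + span <= n; ++i)
            if (pw(i, i + span) > 0) {
                idx[i][i + span] = (int)pi.size();
                pi.push_back(i); pj.push_back(i + span);
            }
    const int np = (int)pi.size();
    std::vector<double> qout(np);
    for (int a = 0; a < np; ++a) {
        int i = pi[a], j = pj[a];
        // Exterior case: no pair encloses (i,j).
        double acc = (i >= 2 ? q[1][i - 1] : 1.0) * (j + 1 <= n ? q[j + 1][n] : 1.0);
        // Innermost enclosing pair (k,l); stacking bonus when flush.
        for (int b = 0; b < a; ++b) {
            int k = pi[b], l = pj[b];
            if (k < i && l > j) {
                double fac = (k == i - 1 && l == j + 1) ? stack : 1.0;
                acc += fac * pw(k, l) * qout[b] * q[k + 1][i - 1] * q[j + 1][l - 1];
            }
        }
        qout[a] = acc;
        p(i - 1, j - 1) = qb[i][j] * acc / Z;
    }
    return p;
}
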