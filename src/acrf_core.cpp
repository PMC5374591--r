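// Exact dynamic programming over one secondary-structure segment.
//
// Because doublet potentials never span two segments, the model factorises
// over segments; each segment is a variable-order chain whose trellis state
// at position j encodes the last min(j, k) labels (k = 1 on coils, 2 on
// strands, 4 on helices).  State encoding: bit r of the integer code holds
// the label of position j - r, so the most recent label is the low bit.
//
// Potentials are passed in pre-assembled:
//   node    : M x 2 matrix of singlet log-potentials (columns y = 0, 1)
//   pairPots: one M x 4 matrix per active separation d; row j (1-based) is
//             used when j >= d + 1 and column yp*2 + y (0-based) holds the
//             log-potential of label pair (Y_{j-d} = yp, Y_j = y)
//   seps    : the active separations (coil {1}, strand {1,2}, helix {1,3,4})

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double lse2(double a, double b) {
    if (a == R_NegInf) return b;
    if (b == R_NegInf) return a;
    double m = a > b ? a : b;
    return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static double lse_vec(const std::vector<double> &v) {
    double m = R_NegInf;
    for (double x : v) if (x > m) m = x;
    if (m == R_NegInf) return R_NegInf;
    double s = 0.0;
    for (double x : v) s += std::exp(x - m);
    return m + std::log(s);
}

// log-potential added when position j (1-based, j >= 2) takes label y and
// the previous state (labels j-1, j-2, ...) is coded by c
static inline double step_weight(int j, int c, int y,
                                 const NumericMatrix &node,
                                 const std::vector<NumericMatrix> &pp,
                                 const std::vector<int> &seps) {
    double w = node(j - 1, y);
    for (size_t t = 0; t < seps.size(); ++t) {
        int d = seps[t];
        if (j >= d + 1) {
            int yp = (c >> (d - 1)) & 1;
            w += pp[t](j - 1, yp * 2 + y);
        }
    }
    return w;
}

static void run_forward(const NumericMatrix &node,
                        const std::vector<NumericMatrix> &pp,
                        const std::vector<int> &seps, int k,
                        std::vector< std::vector<double> > &alpha) {
    int M = node.nrow();
    alpha.resize(M);
    alpha[0] = { node(0, 0), node(0, 1) };
    for (int j = 2; j <= M; ++j) {
        int mprev = std::min(j - 1, k), m = std::min(j, k);
        int mask = (1 << m) - 1;
        alpha[j - 1].assign(1 << m, R_NegInf);
        for (int c = 0; c < (1 << mprev); ++c) {
            double a = alpha[j - 2][c];
            if (a == R_NegInf) continue;
            for (int y = 0; y < 2; ++y) {
                double w = step_weight(j, c, y, node, pp, seps);
                int nc = ((c << 1) | y) & mask;
                alpha[j - 1][nc] = lse2(alpha[j - 1][nc], a + w);
            }
        }
    }
}

// [[Rcpp::export]]
List cpp_segment_fb(NumericMatrix node, List pairPots, IntegerVector sepsIn,
                    int k, bool wantMarginals) {
    int M = node.nrow();
    std::vector<int> seps(sepsIn.begin(), sepsIn.end());
    std::vector<NumericMatrix> pp;
    for (int t = 0; t < pairPots.size(); ++t)
        pp.push_back(as<NumericMatrix>(pairPots[t]));

    std::vector< std::vector<double> > alpha, beta;
    run_forward(node, pp, seps, k, alpha);
    double logZf = lse_vec(alpha[M - 1]);

    beta.resize(M);
    beta[M - 1].assign(1 << std::min(M, k), 0.0);
    for (int j = M; j >= 2; --j) {
        int mprev = std::min(j - 1, k), m = std::min(j, k);
        int mask = (1 << m) - 1;
        beta[j - 2].assign(1 << mprev, R_NegInf);
        for (int c = 0; c < (1 << mprev); ++c) {
            for (int y = 0; y < 2; ++y) {
                double w = step_weight(j, c, y, node, pp, seps);
                int nc = ((c << 1) | y) & mask;
                beta[j - 2][c] = lse2(beta[j - 2][c], w + beta[j - 1][nc]);
            }
        }
    }
    double logZb = lse2(node(0, 0) + beta[0][0], node(0, 1) + beta[0][1]);

    List out = List::create(Named("logZ") = logZf,
                            Named("logZ_backward") = logZb);
    if (wantMarginals) {
        NumericMatrix nodeM(M, 2);
        List pairM(seps.size());
        std::vector<NumericMatrix> pm;
        for (size_t t = 0; t < seps.size(); ++t) {
            NumericMatrix x(M, 4);
            pairM[t] = x;
            pm.push_back(x);
        }
        for (int y = 0; y < 2; ++y)
            nodeM(0, y) = std::exp(alpha[0][y] + beta[0][y] - logZf);
        for (int j = 2; j <= M; ++j) {
            int mprev = std::min(j - 1, k), m = std::min(j, k);
            int mask = (1 << m) - 1;
            for (int c = 0; c < (1 << mprev); ++c) {
                double a = alpha[j - 2][c];
                if (a == R_NegInf) continue;
                for (int y = 0; y < 2; ++y) {
                    double w = step_weight(j, c, y, node, pp, seps);
                    int nc = ((c << 1) | y) & mask;
                    double jp = std::exp(a + w + beta[j - 1][nc] - logZf);
                    nodeM(j - 1, y) += jp;
                    for (size_t t = 0; t < seps.size(); ++t) {
                        int d = seps[t];
                        if (j >= d + 1) {
                            int yp = (c >> (d - 1)) & 1;
                            pm[t](j - 1, yp * 2 + y) += jp;
                        }
                    }
                }
            }
        }
        out["nodeMarginals"] = nodeM;
        out["pairMarginals"] = pairM;
    }
    return out;
}

// Forward-filtering backward-sampling: exact draws from the segment
// distribution.  Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix cpp_segment_sample(NumericMatrix node, List pairPots,
                                 IntegerVector sepsIn, int k, int nsamples) {
    int M = node.nrow();
    std::vector<int> seps(sepsIn.begin(), sepsIn.end());
    std::vector<NumericMatrix> pp;
    for (int t = 0; t < pairPots.size(); ++t)
        pp.push_back(as<NumericMatrix>(pairPots[t]));

    std::vector< std::vector<double> > alpha;
    run_forward(node, pp, seps, k, alpha);

    IntegerMatrix draws(nsamples, M);
    int nfinal = alpha[M - 1].size();
    std::vector<double> pfinal(nfinal);
    double zf = lse_vec(alpha[M - 1]);
    for (int c = 0; c < nfinal; ++c)
        pfinal[c] = std::exp(alpha[M - 1][c] - zf);

    for (int s = 0; s < nsamples; ++s) {
        // final state
        double u = R::unif_rand(), acc = 0.0;
        int cj = nfinal - 1;
        for (int c = 0; c < nfinal; ++c) {
            acc += pfinal[c];
            if (u <= acc) { cj = c; break; }
        }
        std::vector<int> states(M);
        states[M - 1] = cj;
        for (int j = M; j >= 2; --j) {
            int y = states[j - 1] & 1;
            int cnow = states[j - 1];
            int cand[2];
            int ncand;
            if (j - 1 >= k) {          // previous state also has k bits
                cand[0] = cnow >> 1;
                cand[1] = (cnow >> 1) | (1 << (k - 1));
                ncand = 2;
            } else {                   // growing phase: inverse is unique
                cand[0] = cnow >> 1;
                ncand = 1;
            }
            int cprev = cand[0];
            if (ncand == 2) {
                double w0 = alpha[j - 2][cand[0]] == R_NegInf ? R_NegInf :
                    alpha[j - 2][cand[0]] + step_weight(j, cand[0], y, node, pp, seps);
                double w1 = alpha[j - 2][cand[1]] == R_NegInf ? R_NegInf :
                    alpha[j - 2][cand[1]] + step_weight(j, cand[1], y, node, pp, seps);
                double z = lse2(w0, w1);
                double p0 = std::exp(w0 - z);
                cprev = (R::unif_rand() <= p0) ? cand[0] : cand[1];
            }
            states[j - 2] = cprev;
        }
        for (int j = 0; j < M; ++j)
            draws(s, j) = states[j] & 1;
    }
    return draws;
}
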