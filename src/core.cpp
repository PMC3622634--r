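#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Sampling helper: draw an index 0..(n-1) proportional to w.
static inline int sample_from(const std::vector<double>& w, int n) {
    double tot = 0.0;
    for (int k = 0; k < n; ++k) tot += w[k];
    double u = unif_rand() * tot, acc = 0.0;
    for (int k = 0; k < n; ++k) {
        acc += w[k];
        if (u <= acc) return k;
    }
    return n - 1;
}

static inline int argmax_strict(const std::vector<double>& w, int n) {
    int best = 0;
    for (int k = 1; k < n; ++k) if (w[k] > w[best]) best = k;
    return best;
}

// ---------------------------------------------------------------------------
// Single-chain forward-summation / backward-sampling for the haplotype layer
// (phased input). States are 1..P where P = nrow(lth1); state P is the
// collapsed "super" state for all unoccupied state labels. The transition
// kernel at SNP j is K(s -> t) = (1-rho_j)[s==t] + rho_j * v_t (a transition
// event redraws the state from v and may land on the same state).
//
// lth1/lth0: P x L log Bernoulli emission (minor present / absent)
// h:         length-L 0/1 observed alleles of this chain
// rho:       length-L collapsed per-SNP transition probability (rho[0] unused)
// v:         length-P state weights (last = residual super mass)
// mode:      0 = backward sampling, 1 = backward maximization (Viterbi)
// [[Rcpp::export]]
List cpp_chain_fb(NumericMatrix lth1, NumericMatrix lth0, IntegerVector h,
                  NumericVector rho, NumericVector v, int mode,
                  bool return_forward = false) {
    const int Pt = lth1.nrow();  // emission rows (last = super/new-state row)
    const int P = v.size();      // states incl. super
    const int L = h.size();
    NumericMatrix F(P, L);  // normalized forward (or max-product) messages
    double logZ = 0.0;
    std::vector<double> cur(P), e(P);
    auto er = [&](int s) { return (s < Pt - 1) ? s : Pt - 1; };

    for (int j = 0; j < L; ++j) {
        double emax = R_NegInf;
        for (int s = 0; s < P; ++s) {
            e[s] = (h[j] == 1) ? lth1(er(s), j) : lth0(er(s), j);
            if (e[s] > emax) emax = e[s];
        }
        if (j == 0) {
            for (int s = 0; s < P; ++s) cur[s] = v[s] * std::exp(e[s] - emax);
        } else {
            const double r = rho[j];
            if (mode == 0) {
                double tot = 0.0;
                for (int s = 0; s < P; ++s) tot += F(s, j - 1);
                for (int t = 0; t < P; ++t)
                    cur[t] = ((1.0 - r) * F(t, j - 1) + r * v[t] * tot) *
                             std::exp(e[t] - emax);
            } else {
                double mx = 0.0;
                for (int s = 0; s < P; ++s) mx = std::max(mx, F(s, j - 1));
                for (int t = 0; t < P; ++t) {
                    double stay = ((1.0 - r) + r * v[t]) * F(t, j - 1);
                    double mv = r * v[t] * mx;
                    cur[t] = std::max(stay, mv) * std::exp(e[t] - emax);
                }
            }
        }
        double tot = 0.0;
        for (int s = 0; s < P; ++s) tot += cur[s];
        if (tot <= 0.0) stop("forward message vanished (degenerate emissions)");
        logZ += std::log(tot) + emax;
        for (int s = 0; s < P; ++s) F(s, j) = cur[s] / tot;
    }

    IntegerVector path(L), phi(L);
    std::vector<double> w(P);
    phi[0] = 0;
    if (mode == 0) {
        for (int s = 0; s < P; ++s) w[s] = F(s, L - 1);
        path[L - 1] = sample_from(w, P) + 1;
        for (int j = L - 2; j >= 0; --j) {
            const int t = path[j + 1] - 1;
            const double r = rho[j + 1];
            double tot = 0.0;
            for (int s = 0; s < P; ++s) tot += F(s, j);
            const double stayw = (1.0 - r) * F(t, j);
            const double movew = r * v[t] * tot;
            if (unif_rand() * (stayw + movew) <= stayw) {
                path[j] = t + 1;
                phi[j + 1] = 0;
            } else {
                for (int s = 0; s < P; ++s) w[s] = F(s, j);
                path[j] = sample_from(w, P) + 1;
                phi[j + 1] = 1;
            }
        }
    } else {
        for (int s = 0; s < P; ++s) w[s] = F(s, L - 1);
        path[L - 1] = argmax_strict(w, P) + 1;
        for (int j = L - 2; j >= 0; --j) {
            const int t = path[j + 1] - 1;
            const double r = rho[j + 1];
            for (int s = 0; s < P; ++s) w[s] = F(s, j);
            const int smax = argmax_strict(w, P);
            const double stayw = ((1.0 - r) + r * v[t]) * F(t, j);
            const double movew = r * v[t] * F(smax, j);
            if (stayw >= movew) {
                path[j] = t + 1;
                phi[j + 1] = (r * v[t] > (1.0 - r)) ? 1 : 0;
            } else {
                path[j] = smax + 1;
                phi[j + 1] = 1;
            }
        }
    }
    List out = List::create(_["path"] = path, _["phi"] = phi,
                            _["loglik"] = logZ);
    if (return_forward) out["forward"] = F;
    return out;
}

// ---------------------------------------------------------------------------
// Diploid pair forward/backward for the haplotype layer with latent alleles
// (read-count and genotype input). The two chains of an individual are
// updated jointly so genotype likelihoods factor correctly.
//
// logPg: 3 x L genotype log-likelihood (dosage 0,1,2) from reads/genotypes
// lth1/lth0: P x L log Bernoulli state emissions; rho, v as in cpp_chain_fb
// [[Rcpp::export]]
List cpp_pair_fb(NumericMatrix logPg, NumericMatrix lth1, NumericMatrix lth0,
                 NumericVector rho, NumericVector v, int mode) {
    const int Pt = lth1.nrow();  // emission rows (last = super/new-state row)
    const int P = v.size();      // states incl. super
    const int L = logPg.ncol();
    NumericVector Fs(static_cast<R_xlen_t>(P) * P * L);
    std::vector<double> cur(P * P), tmp(P * P), th(P), om(P), pg(3);
    double logZ = 0.0;
    auto er = [&](int s) { return (s < Pt - 1) ? s : Pt - 1; };

    for (int j = 0; j < L; ++j) {
        double mg = std::max(logPg(0, j), std::max(logPg(1, j), logPg(2, j)));
        for (int g = 0; g < 3; ++g) pg[g] = std::exp(logPg(g, j) - mg);
        for (int s = 0; s < P; ++s) {
            th[s] = std::exp(lth1(er(s), j));
            om[s] = std::exp(lth0(er(s), j));
        }
        if (j == 0) {
            for (int s2 = 0; s2 < P; ++s2)
                for (int s1 = 0; s1 < P; ++s1)
                    cur[s1 + P * s2] = v[s1] * v[s2];
        } else {
            const double r = rho[j];
            // previous normalized messages
            for (int k = 0; k < P * P; ++k) cur[k] = Fs[k + (R_xlen_t)P * P * (j - 1)];
            if (mode == 0) {
                for (int s2 = 0; s2 < P; ++s2) {  // collapse axis 1
                    double cs = 0.0;
                    for (int s1 = 0; s1 < P; ++s1) cs += cur[s1 + P * s2];
                    for (int t1 = 0; t1 < P; ++t1)
                        tmp[t1 + P * s2] =
                            (1.0 - r) * cur[t1 + P * s2] + r * v[t1] * cs;
                }
                for (int t1 = 0; t1 < P; ++t1) {  // collapse axis 2
                    double cs = 0.0;
                    for (int s2 = 0; s2 < P; ++s2) cs += tmp[t1 + P * s2];
                    for (int t2 = 0; t2 < P; ++t2)
                        cur[t1 + P * t2] =
                            (1.0 - r) * tmp[t1 + P * t2] + r * v[t2] * cs;
                }
            } else {
                for (int s2 = 0; s2 < P; ++s2) {
                    double cm = 0.0;
                    for (int s1 = 0; s1 < P; ++s1)
                        cm = std::max(cm, cur[s1 + P * s2]);
                    for (int t1 = 0; t1 < P; ++t1)
                        tmp[t1 + P * s2] = std::max(
                            ((1.0 - r) + r * v[t1]) * cur[t1 + P * s2],
                            r * v[t1] * cm);
                }
                for (int t1 = 0; t1 < P; ++t1) {
                    double cm = 0.0;
                    for (int s2 = 0; s2 < P; ++s2)
                        cm = std::max(cm, tmp[t1 + P * s2]);
                    for (int t2 = 0; t2 < P; ++t2)
                        cur[t1 + P * t2] = std::max(
                            ((1.0 - r) + r * v[t2]) * tmp[t1 + P * t2],
                            r * v[t2] * cm);
                }
            }
        }
        // multiply marginal-over-alleles emission
        double tot = 0.0;
        for (int s2 = 0; s2 < P; ++s2)
            for (int s1 = 0; s1 < P; ++s1) {
                double E = pg[0] * om[s1] * om[s2] +
                           pg[1] * (th[s1] * om[s2] + om[s1] * th[s2]) +
                           pg[2] * th[s1] * th[s2];
                cur[s1 + P * s2] *= E;
                tot += cur[s1 + P * s2];
            }
        if (tot <= 0.0) stop("forward message vanished in diploid update");
        logZ += std::log(tot) + mg;
        for (int k = 0; k < P * P; ++k) Fs[k + (R_xlen_t)P * P * j] = cur[k] / tot;
    }

    IntegerVector s1p(L), s2p(L), phi1(L), phi2(L), h1(L), h2(L);
    phi1[0] = phi2[0] = 0;
    std::vector<double> w(P * P);
    {
        for (int k = 0; k < P * P; ++k) w[k] = Fs[k + (R_xlen_t)P * P * (L - 1)];
        int k = (mode == 0) ? sample_from(w, P * P) : argmax_strict(w, P * P);
        s1p[L - 1] = k % P + 1;
        s2p[L - 1] = k / P + 1;
    }
    for (int j = L - 2; j >= 0; --j) {
        const int t1 = s1p[j + 1] - 1, t2 = s2p[j + 1] - 1;
        const double r = rho[j + 1];
        for (int s2 = 0; s2 < P; ++s2)
            for (int s1 = 0; s1 < P; ++s1) {
                double k1 = r * v[t1] + ((s1 == t1) ? (1.0 - r) : 0.0);
                double k2 = r * v[t2] + ((s2 == t2) ? (1.0 - r) : 0.0);
                w[s1 + P * s2] = Fs[s1 + P * s2 + (R_xlen_t)P * P * j] * k1 * k2;
            }
        int k = (mode == 0) ? sample_from(w, P * P) : argmax_strict(w, P * P);
        const int a1 = k % P, a2 = k / P;
        s1p[j] = a1 + 1;
        s2p[j] = a2 + 1;
        // transition indicators (redraw may keep the same state)
        if (a1 != t1) phi1[j + 1] = 1;
        else {
            double pmove = r * v[t1] / ((1.0 - r) + r * v[t1]);
            phi1[j + 1] = (mode == 0) ? (unif_rand() < pmove ? 1 : 0)
                                      : (r * v[t1] > (1.0 - r) ? 1 : 0);
        }
        if (a2 != t2) phi2[j + 1] = 1;
        else {
            double pmove = r * v[t2] / ((1.0 - r) + r * v[t2]);
            phi2[j + 1] = (mode == 0) ? (unif_rand() < pmove ? 1 : 0)
                                      : (r * v[t2] > (1.0 - r) ? 1 : 0);
        }
    }
    // allele call given states and genotype likelihood
    std::vector<double> wh(4);
    for (int j = 0; j < L; ++j) {
        double mg = std::max(logPg(0, j), std::max(logPg(1, j), logPg(2, j)));
        const int a1 = er(s1p[j] - 1), a2 = er(s2p[j] - 1);
        double t1v = std::exp(lth1(a1, j)), o1v = std::exp(lth0(a1, j));
        double t2v = std::exp(lth1(a2, j)), o2v = std::exp(lth0(a2, j));
        wh[0] = std::exp(logPg(0, j) - mg) * o1v * o2v;        // (0,0)
        wh[1] = std::exp(logPg(1, j) - mg) * t1v * o2v;        // (1,0)
        wh[2] = std::exp(logPg(1, j) - mg) * o1v * t2v;        // (0,1)
        wh[3] = std::exp(logPg(2, j) - mg) * t1v * t2v;        // (1,1)
        int k = (mode == 0) ? sample_from(wh, 4) : argmax_strict(wh, 4);
        h1[j] = (k == 1 || k == 3) ? 1 : 0;
        h2[j] = (k == 2 || k == 3) ? 1 : 0;
    }
    return List::create(_["s1"] = s1p, _["s2"] = s2p, _["phi1"] = phi1,
                        _["phi2"] = phi2, _["h1"] = h1, _["h2"] = h2,
                        _["loglik"] = logZ);
}

// ---------------------------------------------------------------------------
// Population-specific haplotype-state emission table.
// S, Q: 2N x L integer matrices (state / population per chain per SNP).
// P: number of population slots (labels 1..P; column P+1 is the super /
// unoccupied-population row, uniform 1/K_j).
// Entry (s, q, j) = (y + 1) / (n + K_j) where y counts chains with state s
// and population q at SNP j, and n counts chains in population q at j.
// Returns logT (maxS x (P+1) x L) and Kj.
// [[Rcpp::export]]
List cpp_admix_table(IntegerMatrix S, IntegerMatrix Q, int P) {
    const int C = S.nrow(), L = S.ncol();
    int maxS = 1;
    for (int k = 0; k < C * L; ++k) maxS = std::max(maxS, S[k]);
    NumericVector logT(static_cast<R_xlen_t>(maxS) * (P + 1) * L);
    IntegerVector Kj(L);
    std::vector<int> y(maxS * P), n(P), seen(maxS);
    for (int j = 0; j < L; ++j) {
        std::fill(y.begin(), y.end(), 0);
        std::fill(n.begin(), n.end(), 0);
        std::fill(seen.begin(), seen.end(), 0);
        int K = 0;
        for (int c = 0; c < C; ++c) {
            const int s = S(c, j) - 1, q = Q(c, j) - 1;
            if (!seen[s]) { seen[s] = 1; ++K; }
            if (q >= 0 && q < P) { ++y[s + maxS * q]; ++n[q]; }
        }
        Kj[j] = K;
        const double lu = -std::log((double)K);
        const R_xlen_t off = (R_xlen_t)maxS * (P + 1) * j;
        for (int q = 0; q < P; ++q)
            for (int s = 0; s < maxS; ++s)
                logT[off + s + (R_xlen_t)maxS * q] =
                    std::log((y[s + maxS * q] + 1.0) / (n[q] + (double)K));
        for (int s = 0; s < maxS; ++s)
            logT[off + s + (R_xlen_t)maxS * P] = lu;
    }
    logT.attr("dim") = IntegerVector::create(maxS, P + 1, L);
    return List::create(_["logT"] = logT, _["Kj"] = Kj);
}

// Raw co-occurrence counts behind the emission table: y (maxS x P x L) and
// n (P x L), plus K_j. Used for leave-one-out emission lookups.
// [[Rcpp::export]]
List cpp_admix_counts(IntegerMatrix S, IntegerMatrix Q, int P) {
    const int C = S.nrow(), L = S.ncol();
    int maxS = 1;
    for (int k = 0; k < C * L; ++k) maxS = std::max(maxS, S[k]);
    IntegerVector y(static_cast<R_xlen_t>(maxS) * P * L);
    IntegerMatrix n(P, L);
    IntegerVector Kj(L);
    std::vector<int> seen(maxS);
    for (int j = 0; j < L; ++j) {
        std::fill(seen.begin(), seen.end(), 0);
        int K = 0;
        const R_xlen_t off = (R_xlen_t)maxS * P * j;
        for (int c = 0; c < C; ++c) {
            const int s = S(c, j) - 1, q = Q(c, j) - 1;
            if (!seen[s]) { seen[s] = 1; ++K; }
            if (q >= 0 && q < P) {
                y[off + s + (R_xlen_t)maxS * q] += 1;
                n(q, j) += 1;
            }
        }
        Kj[j] = K;
    }
    y.attr("dim") = IntegerVector::create(maxS, P, L);
    return List::create(_["y"] = y, _["n"] = n, _["Kj"] = Kj);
}

// Weighted leave-one-out log emission matrix for one strand of the
// individual being updated: M(q, j) = w_j * log((y' + 1) / (n' + K_j)),
// where y'/n' exclude the individual's own two (delta-corrected) previous
// contributions. Row P+1 is the super/new-population row log(1 / K_j).
// s: the strand's emission states; sOwn, qOwn: 2 x L previous (state, label)
// contributions of the individual's two chains.
// runId (1-based, non-decreasing, one entry per SNP) collapses SNP runs
// between event-admissible sites into single grid columns by summation —
// exact, because the population state cannot change within a run.
// [[Rcpp::export]]
NumericMatrix cpp_strand_emission_loo(IntegerVector y, IntegerMatrix n,
                                      IntegerVector Kj, IntegerVector s,
                                      IntegerMatrix sOwn, IntegerMatrix qOwn,
                                      NumericVector w, int P,
                                      IntegerVector runId, int G) {
    IntegerVector dm = y.attr("dim");
    const int maxS = dm[0], Py = dm[1];
    const int L = s.size();
    NumericMatrix M(P + 1, G);
    for (int j = 0; j < L; ++j) {
        const R_xlen_t off = (R_xlen_t)maxS * Py * j;
        const int sj = s[j] - 1;
        const int g = runId[j] - 1;
        const double lu = -std::log((double)Kj[j]);
        for (int q = 0; q < P; ++q) {
            double yc, nc;
            if (q < Py) {
                yc = y[off + sj + (R_xlen_t)maxS * q];
                nc = n(q, j);
                for (int o = 0; o < 2; ++o) {
                    if (qOwn(o, j) - 1 == q) {
                        nc -= 1;
                        if (sOwn(o, j) - 1 == sj) yc -= 1;
                    }
                }
            } else { yc = 0; nc = 0; }
            M(q, g) += w[j] * std::log((yc + 1.0) / (nc + (double)Kj[j]));
        }
        M(P, g) += w[j] * lu;
    }
    return M;
}

// Bernoulli allele-emission counts of the haplotype layer: y1 (K x L)
// minor-allele counts and n (K x L) chain totals per state.
// [[Rcpp::export]]
List cpp_hap_counts(IntegerMatrix S, IntegerMatrix H, int K) {
    const int C = S.nrow(), L = S.ncol();
    IntegerMatrix y1(K, L), n(K, L);
    for (int j = 0; j < L; ++j)
        for (int c = 0; c < C; ++c) {
            const int s = S(c, j) - 1;
            if (s >= 0 && s < K) {
                n(s, j) += 1;
                y1(s, j) += H(c, j);
            }
        }
    return List::create(_["y1"] = y1, _["n"] = n);
}

// Leave-one-out Bernoulli emission parameters for the chain(s) being
// updated: theta = (y1' + 1) / (n' + 2) excluding the given chains' own
// previous contributions. Row K+1 = super/new-state row (0.5).
// sOwn/hOwn: nEx x L previous states / alleles of the excluded chains.
// [[Rcpp::export]]
List cpp_hap_theta_loo(IntegerMatrix y1, IntegerMatrix n, IntegerMatrix sOwn,
                       IntegerMatrix hOwn) {
    const int K = y1.nrow(), L = y1.ncol(), nEx = sOwn.nrow();
    NumericMatrix lth1(K + 1, L), lth0(K + 1, L);
    for (int j = 0; j < L; ++j) {
        for (int s = 0; s < K; ++s) {
            double yc = y1(s, j), nc = n(s, j);
            for (int o = 0; o < nEx; ++o)
                if (sOwn(o, j) - 1 == s) {
                    nc -= 1;
                    yc -= hOwn(o, j);
                }
            const double p = (yc + 1.0) / (nc + 2.0);
            lth1(s, j) = std::log(p);
            lth0(s, j) = std::log1p(-p);
        }
        lth1(K, j) = lth0(K, j) = std::log(0.5);
    }
    return List::create(_["lth1"] = lth1, _["lth0"] = lth0);
}


// Number of distinct labels per column of an integer matrix.
// [[Rcpp::export]]
IntegerVector cpp_distinct_per_column(IntegerMatrix Q) {
    const int C = Q.nrow(), L = Q.ncol();
    int mx = 1;
    for (int k = 0; k < C * L; ++k) mx = std::max(mx, Q[k]);
    IntegerVector out(L);
    std::vector<int> seen(mx);
    for (int j = 0; j < L; ++j) {
        std::fill(seen.begin(), seen.end(), 0);
        int K = 0;
        for (int c = 0; c < C; ++c)
            if (!seen[Q(c, j) - 1]) { seen[Q(c, j) - 1] = 1; ++K; }
        out[j] = K;
    }
    return out;
}

// Accumulate per-(label, chain, SNP) occupancy counts in place.
// acc must be an integer array of dim (nLab, C, L) owned by the caller.
// [[Rcpp::export]]
void cpp_accumulate_labels(IntegerMatrix Q, IntegerVector acc, int nLab) {
    const int C = Q.nrow(), L = Q.ncol();
    for (int j = 0; j < L; ++j)
        for (int c = 0; c < C; ++c) {
            const int q = Q(c, j) - 1;
            if (q >= 0 && q < nLab)
                acc[q + (R_xlen_t)nLab * (c + (R_xlen_t)C * j)] += 1;
        }
}

// ---------------------------------------------------------------------------
// Admixture-layer forward-summation / backward-sampling for one individual
// over the joint diploid + switch-error state (q1, q2, delta).
//
// M1, M2 : (Pt+1) x L weighted log emissions for strand 1 / strand 2 (last
//          row = uniform row used for the super state and any label created
//          after the emission table was built)
// A1, A2 : length-L, TRUE where the strand may admix (segment starts, j>=2)
// gam    : length-L collapsed predictive admix probability (gam[0] unused)
// v      : length-(P+1) population weights, last = super mass (0 in fixed-K
//          mode); labels in 1..P
// dsite  : length-L, TRUE at interior double-recombination sites where the
//          switch indicator delta may flip (stay 1-eps / flip eps); the
//          anchor before SNP 1 is delta = 0, so the first block's delta has
//          prior (1-eps, eps)
// mode   : 0 = backward sampling, 1 = backward maximization
// [[Rcpp::export]]
List cpp_admix_fb(NumericMatrix M1, NumericMatrix M2, LogicalVector A1,
                  LogicalVector A2, NumericVector gam, NumericVector v,
                  LogicalVector dsite, double eps, int mode,
                  bool return_forward = false) {
    const int Pt = M1.nrow();          // emission rows (incl. uniform row)
    const int P = v.size();            // states incl. super (labels 1..P)
    const int L = M1.ncol();
    const int PP = P * P, NS = PP * 2;
    NumericVector Fs(static_cast<R_xlen_t>(NS) * L);
    std::vector<double> cur(NS), tmp(NS), a1(P), a2(P);
    double logZ = 0.0;
    auto er = [&](int q) { return (q < Pt - 1) ? q : Pt - 1; };

    for (int j = 0; j < L; ++j) {
        double m1 = R_NegInf, m2 = R_NegInf;
        for (int q = 0; q < P; ++q) {
            m1 = std::max(m1, M1(er(q), j));
            m2 = std::max(m2, M2(er(q), j));
        }
        for (int q = 0; q < P; ++q) {
            a1[q] = std::exp(M1(er(q), j) - m1);
            a2[q] = std::exp(M2(er(q), j) - m2);
        }
        if (j == 0) {
            for (int d = 0; d < 2; ++d) {
                const double pd = d ? eps : (1.0 - eps);
                for (int q2 = 0; q2 < P; ++q2)
                    for (int q1 = 0; q1 < P; ++q1) {
                        const double E = d ? a2[q1] * a1[q2] : a1[q1] * a2[q2];
                        cur[q1 + P * q2 + PP * d] = v[q1] * v[q2] * pd * E;
                    }
            }
        } else {
            for (int k = 0; k < NS; ++k) cur[k] = Fs[k + (R_xlen_t)NS * (j - 1)];
            if (dsite[j]) {  // switch-error chain step
                for (int k = 0; k < PP; ++k) {
                    const double f0 = cur[k], f1 = cur[k + PP];
                    if (mode == 0) {
                        tmp[k] = (1.0 - eps) * f0 + eps * f1;
                        tmp[k + PP] = eps * f0 + (1.0 - eps) * f1;
                    } else {
                        tmp[k] = std::max((1.0 - eps) * f0, eps * f1);
                        tmp[k + PP] = std::max(eps * f0, (1.0 - eps) * f1);
                    }
                }
                std::swap(cur, tmp);
            }
            const double g = gam[j];
            if (A1[j]) {  // strand-1 admix step
                for (int d = 0; d < 2; ++d)
                    for (int q2 = 0; q2 < P; ++q2) {
                        const int base = P * q2 + PP * d;
                        if (mode == 0) {
                            double cs = 0.0;
                            for (int q1 = 0; q1 < P; ++q1) cs += cur[q1 + base];
                            for (int t1 = 0; t1 < P; ++t1)
                                tmp[t1 + base] = (1.0 - g) * cur[t1 + base] +
                                                 g * v[t1] * cs;
                        } else {
                            double cm = 0.0;
                            for (int q1 = 0; q1 < P; ++q1)
                                cm = std::max(cm, cur[q1 + base]);
                            for (int t1 = 0; t1 < P; ++t1)
                                tmp[t1 + base] = std::max(
                                    ((1.0 - g) + g * v[t1]) * cur[t1 + base],
                                    g * v[t1] * cm);
                        }
                    }
                std::swap(cur, tmp);
            }
            if (A2[j]) {  // strand-2 admix step
                for (int d = 0; d < 2; ++d)
                    for (int q1 = 0; q1 < P; ++q1) {
                        if (mode == 0) {
                            double cs = 0.0;
                            for (int q2 = 0; q2 < P; ++q2)
                                cs += cur[q1 + P * q2 + PP * d];
                            for (int t2 = 0; t2 < P; ++t2)
                                tmp[q1 + P * t2 + PP * d] =
                                    (1.0 - g) * cur[q1 + P * t2 + PP * d] +
                                    g * v[t2] * cs;
                        } else {
                            double cm = 0.0;
                            for (int q2 = 0; q2 < P; ++q2)
                                cm = std::max(cm, cur[q1 + P * q2 + PP * d]);
                            for (int t2 = 0; t2 < P; ++t2)
                                tmp[q1 + P * t2 + PP * d] = std::max(
                                    ((1.0 - g) + g * v[t2]) *
                                        cur[q1 + P * t2 + PP * d],
                                    g * v[t2] * cm);
                        }
                    }
                std::swap(cur, tmp);
            }
            for (int d = 0; d < 2; ++d)
                for (int q2 = 0; q2 < P; ++q2)
                    for (int q1 = 0; q1 < P; ++q1) {
                        const double E = d ? a2[q1] * a1[q2] : a1[q1] * a2[q2];
                        cur[q1 + P * q2 + PP * d] *= E;
                    }
        }
        double tot = 0.0;
        for (int k = 0; k < NS; ++k) tot += cur[k];
        if (tot <= 0.0) stop("forward message vanished in admixture update");
        logZ += std::log(tot) + m1 + m2;
        for (int k = 0; k < NS; ++k) Fs[k + (R_xlen_t)NS * j] = cur[k] / tot;
    }

    IntegerVector q1p(L), q2p(L), I1(L), I2(L), del(L);
    I1[0] = I2[0] = 0;
    std::vector<double> w(NS);
    {
        for (int k = 0; k < NS; ++k) w[k] = Fs[k + (R_xlen_t)NS * (L - 1)];
        int k = (mode == 0) ? sample_from(w, NS) : argmax_strict(w, NS);
        del[L - 1] = k / PP;
        k %= PP;
        q1p[L - 1] = k % P + 1;
        q2p[L - 1] = k / P + 1;
    }
    for (int j = L - 2; j >= 0; --j) {
        const int t1 = q1p[j + 1] - 1, t2 = q2p[j + 1] - 1, dt = del[j + 1];
        const double g = gam[j + 1];
        for (int d = 0; d < 2; ++d) {
            double kd;
            if (dsite[j + 1]) kd = (d == dt) ? (1.0 - eps) : eps;
            else kd = (d == dt) ? 1.0 : 0.0;
            for (int q2 = 0; q2 < P; ++q2)
                for (int q1 = 0; q1 < P; ++q1) {
                    double k1 = A1[j + 1]
                                    ? (g * v[t1] + ((q1 == t1) ? (1.0 - g) : 0.0))
                                    : ((q1 == t1) ? 1.0 : 0.0);
                    double k2 = A2[j + 1]
                                    ? (g * v[t2] + ((q2 == t2) ? (1.0 - g) : 0.0))
                                    : ((q2 == t2) ? 1.0 : 0.0);
                    w[q1 + P * q2 + PP * d] =
                        Fs[q1 + P * q2 + PP * d + (R_xlen_t)NS * j] * kd * k1 * k2;
                }
        }
        int k = (mode == 0) ? sample_from(w, NS) : argmax_strict(w, NS);
        del[j] = k / PP;
        k %= PP;
        const int a1i = k % P, a2i = k / P;
        q1p[j] = a1i + 1;
        q2p[j] = a2i + 1;
        if (!A1[j + 1]) I1[j + 1] = 0;
        else if (a1i != t1) I1[j + 1] = 1;
        else {
            const double pm = g * v[t1] / ((1.0 - g) + g * v[t1]);
            I1[j + 1] = (mode == 0) ? (unif_rand() < pm ? 1 : 0)
                                    : (g * v[t1] > (1.0 - g) ? 1 : 0);
        }
        if (!A2[j + 1]) I2[j + 1] = 0;
        else if (a2i != t2) I2[j + 1] = 1;
        else {
            const double pm = g * v[t2] / ((1.0 - g) + g * v[t2]);
            I2[j + 1] = (mode == 0) ? (unif_rand() < pm ? 1 : 0)
                                    : (g * v[t2] > (1.0 - g) ? 1 : 0);
        }
    }
    List out = List::create(_["q1"] = q1p, _["q2"] = q2p, _["I1"] = I1,
                            _["I2"] = I2, _["delta"] = del, _["loglik"] = logZ);
    if (return_forward) {
        Fs.attr("dim") = IntegerVector::create(P, P, 2, L);
        out["forward"] = Fs;
    }
    return out;
}
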