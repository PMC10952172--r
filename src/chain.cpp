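#include <Rcpp.h>
using namespace Rcpp;

// Uniform integer in [0, n). Uses R's RNG so set.seed() governs the chain.
static inline int unif_int(int n) {
    int k = (int) (R::unif_rand() * n);
    return k >= n ? n - 1 : k;
}

// Propose uniformly random (row pair, column pair) submatrices and accept the
// first checkerboard ([[1,0],[0,1]] up to the random order of the draws).
// Returns false if max_tries proposals are all rejected (frozen matrix).
static bool propose_swap(const IntegerMatrix& M, int max_tries,
                         int& r1, int& r2, int& c1, int& c2) {
    const int n = M.nrow(), p = M.ncol();
    if (n < 2 || p < 2) return false;
    for (int t = 0; t < max_tries; ++t) {
        int a = unif_int(n), b = unif_int(n - 1);
        if (b >= a) ++b;
        int u = unif_int(p), v = unif_int(p - 1);
        if (v >= u) ++v;
        if (M(a, u) == 1 && M(a, v) == 0 && M(b, u) == 0 && M(b, v) == 1) {
            r1 = a; r2 = b; c1 = u; c2 = v;
            return true;
        }
    }
    return false;
}

static inline void apply_swap(IntegerMatrix& M, int r1, int r2, int c1, int c2) {
    M(r1, c1) = 0; M(r1, c2) = 1;
    M(r2, c1) = 1; M(r2, c2) = 0;
}

// [[Rcpp::export]]
List cpp_swap_chain(IntegerMatrix M, int n_swaps, int max_tries) {
    IntegerMatrix out = clone(M);
    int frozen = 0;
    int r1, r2, c1, c2;
    for (int s = 0; s < n_swaps; ++s) {
        if (propose_swap(out, max_tries, r1, r2, c1, c2)) {
            apply_swap(out, r1, r2, c1, c2);
        } else {
            ++frozen;
        }
    }
    return List::create(_["matrix"] = out, _["n_frozen"] = frozen);
}

// Maintain the co-occurrence matrix X = t(M) %*% M incrementally: removing or
// adding a single incidence touches one column's row of X.
static inline void x_remove(IntegerMatrix& M, IntegerMatrix& X, int r, int c) {
    const int p = M.ncol();
    for (int j = 0; j < p; ++j) {
        if (M(r, j) == 1) {
            X(c, j) -= 1;
            if (j != c) X(j, c) -= 1;
        }
    }
    M(r, c) = 0;
}

static inline void x_add(IntegerMatrix& M, IntegerMatrix& X, int r, int c) {
    M(r, c) = 1;
    const int p = M.ncol();
    for (int j = 0; j < p; ++j) {
        if (M(r, j) == 1) {
            X(c, j) += 1;
            if (j != c) X(j, c) += 1;
        }
    }
}

// Datastream permutation chain. Performs burn_in steps, then n_perm blocks of
// swaps_per steps; after each block computes the SRI weight of every
// unordered column pair from the running co-occurrence counts, records the CV
// of edge weights, and accumulates per-dyad >= / <= counts against the
// observed weights (ties count toward both tails).
//
// kernel = 0 ("trial"): a step is a single uniform (row pair, column pair)
// proposal, applied only if it is a checkerboard. This kernel is symmetric,
// so its stationary distribution is uniform over the margin-fixed matrices.
// kernel = 1 ("swap"): a step retries proposals until one is accepted (up to
// max_tries, else the step freezes); classic sequential datastream swapping,
// whose stationary distribution weights matrices by their checkerboard count.
// [[Rcpp::export]]
List cpp_null_chain(IntegerMatrix M0, NumericMatrix Wobs,
                    int n_perm, int swaps_per, int burn_in, int kernel,
                    int max_tries, bool include_zeros, bool check_margins) {
    const int n = M0.nrow(), p = M0.ncol();
    IntegerMatrix M = clone(M0);
    IntegerMatrix X(p, p);
    std::vector<int> colcnt(p), rowcnt0(n);
    for (int a = 0; a < p; ++a)
        for (int b = 0; b <= a; ++b) {
            int x = 0;
            for (int i = 0; i < n; ++i) x += M(i, a) * M(i, b);
            X(a, b) = x; X(b, a) = x;
        }
    for (int a = 0; a < p; ++a) colcnt[a] = X(a, a);
    for (int i = 0; i < n; ++i) {
        int s = 0;
        for (int a = 0; a < p; ++a) s += M(i, a);
        rowcnt0[i] = s;
    }

    NumericVector null_cv(n_perm);
    IntegerMatrix count_geq(p, p), count_leq(p, p);
    int frozen = 0;
    long long accepted = 0;
    bool margins_ok = true;
    const double eps = 1e-12;
    int r1, r2, c1, c2;
    const int tries = kernel == 0 ? 1 : max_tries;

    for (int s = 0; s < burn_in; ++s) {
        if (propose_swap(M, tries, r1, r2, c1, c2)) {
            x_remove(M, X, r1, c1);
            x_remove(M, X, r2, c2);
            x_add(M, X, r1, c2);
            x_add(M, X, r2, c1);
            ++accepted;
        } else if (kernel == 1) {
            ++frozen;
        }
    }

    for (int it = 0; it < n_perm; ++it) {
        for (int s = 0; s < swaps_per; ++s) {
            if (propose_swap(M, tries, r1, r2, c1, c2)) {
                x_remove(M, X, r1, c1);
                x_remove(M, X, r2, c2);
                x_add(M, X, r1, c2);
                x_add(M, X, r2, c1);
                ++accepted;
            } else if (kernel == 1) {
                ++frozen;
            }
        }
        double sum = 0.0, sumsq = 0.0;
        long cnt_dyads = 0;
        for (int a = 0; a < p; ++a) {
            for (int b = a + 1; b < p; ++b) {
                int denom = colcnt[a] + colcnt[b] - X(a, b);
                double w = denom > 0 ? (double) X(a, b) / denom : 0.0;
                if (include_zeros || w > 0.0) {
                    sum += w; sumsq += w * w; ++cnt_dyads;
                }
                double wo = Wobs(a, b);
                if (w >= wo - eps) count_geq(a, b) += 1;
                if (w <= wo + eps) count_leq(a, b) += 1;
            }
        }
        if (cnt_dyads >= 2 && sum > 0.0) {
            double mean = sum / cnt_dyads;
            double var = (sumsq - cnt_dyads * mean * mean) / (cnt_dyads - 1);
            if (var < 0) var = 0;
            null_cv[it] = std::sqrt(var) / mean;
        } else {
            null_cv[it] = NA_REAL;
        }
        if (check_margins) {
            for (int a = 0; a < p && margins_ok; ++a) {
                int s2 = 0;
                for (int i = 0; i < n; ++i) s2 += M(i, a);
                if (s2 != colcnt[a]) margins_ok = false;
            }
            for (int i = 0; i < n && margins_ok; ++i) {
                int s2 = 0;
                for (int a = 0; a < p; ++a) s2 += M(i, a);
                if (s2 != rowcnt0[i]) margins_ok = false;
            }
            if (!margins_ok) stop("internal error: permutation violated margins");
        }
    }

    return List::create(_["null_cv"] = null_cv,
                        _["count_geq"] = count_geq,
                        _["count_leq"] = count_leq,
                        _["n_frozen"] = frozen,
                        _["n_accepted"] = (double) accepted,
                        _["matrix"] = M);
}
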