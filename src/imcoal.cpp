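#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// HKY85 transition probabilities, rate matrix normalized to mean rate 1 so
// branch lengths are expected substitutions per site. Base order A,C,G,T
// (A,G purines; C,T pyrimidines).
// ---------------------------------------------------------------------------

static void hky_pmat_fill(double t, const double *pi, double kappa, double *P) {
    const double piA = pi[0], piC = pi[1], piG = pi[2], piT = pi[3];
    const double piR = piA + piG, piY = piC + piT;
    const double beta = 1.0 /
        (2.0 * kappa * (piA * piG + piC * piT) + 2.0 * piR * piY);
    const double e2 = std::exp(-beta * t);
    const double eR = std::exp(-beta * t * (piR * kappa + piY));
    const double eY = std::exp(-beta * t * (piY * kappa + piR));
    for (int i = 0; i < 4; ++i) {
        const bool ipur = (i == 0 || i == 2);
        for (int j = 0; j < 4; ++j) {
            const bool jpur = (j == 0 || j == 2);
            const double Pj = jpur ? piR : piY;
            const double ej = jpur ? eR : eY;
            const double pj = pi[j];
            double val;
            if (i == j)
                val = pj + pj * (1.0 / Pj - 1.0) * e2 + ((Pj - pj) / Pj) * ej;
            else if (ipur == jpur)
                val = pj + pj * (1.0 / Pj - 1.0) * e2 - (pj / Pj) * ej;
            else
                val = pj * (1.0 - e2);
            P[4 * i + j] = val;
        }
    }
}

// [[Rcpp::export]]
NumericMatrix cpp_hky_pmat(double t, NumericVector pi, double kappa) {
    if (t < 0) stop("branch length must be nonnegative");
    NumericMatrix out(4, 4);
    double P[16];
    hky_pmat_fill(t, &pi[0], kappa, P);
    for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) out(i, j) = P[4 * i + j];
    return out;
}

// Per-site log-likelihood by Felsenstein pruning with per-node scaling.
// children: (2N-1) x 2, 1-based node ids, 0/NA rows for leaves.
// postorder: internal node ids, children-before-parents, root last.
// leaf_codes: N x n, values 1..4 (A,C,G,T).
// [[Rcpp::export]]
NumericVector cpp_hky_site_loglik(IntegerMatrix children, IntegerVector postorder,
                                  NumericVector times, IntegerMatrix leaf_codes,
                                  NumericVector pi, double kappa, double u) {
    const int M = times.size();
    const int N = leaf_codes.nrow();
    const int n = leaf_codes.ncol();
    std::vector<double> CL((size_t)M * 4 * n);
    std::vector<double> logscale(n, 0.0);
    double P[16];
    const int root = postorder[postorder.size() - 1] - 1;

    for (int oi = 0; oi < postorder.size(); ++oi) {
        const int v = postorder[oi] - 1;
        double *clv = &CL[(size_t)v * 4 * n];
        std::fill(clv, clv + (size_t)4 * n, 1.0);
        for (int ci = 0; ci < 2; ++ci) {
            const int c = children(v, ci) - 1;
            const double bl = (times[v] - times[c]) * u;
            hky_pmat_fill(bl, &pi[0], kappa, P);
            if (c < N) { // leaf child: select transition-matrix column
                for (int j = 0; j < n; ++j) {
                    const int b = leaf_codes(c, j) - 1;
                    double *x = clv + (size_t)4 * j;
                    x[0] *= P[0 + b]; x[1] *= P[4 + b];
                    x[2] *= P[8 + b]; x[3] *= P[12 + b];
                }
            } else {     // internal child: matrix-vector product
                const double *clc = &CL[(size_t)c * 4 * n];
                for (int j = 0; j < n; ++j) {
                    const double *y = clc + (size_t)4 * j;
                    double *x = clv + (size_t)4 * j;
                    for (int a = 0; a < 4; ++a) {
                        const double s = P[4 * a] * y[0] + P[4 * a + 1] * y[1] +
                                         P[4 * a + 2] * y[2] + P[4 * a + 3] * y[3];
                        x[a] *= s;
                    }
                }
            }
        }
        for (int j = 0; j < n; ++j) { // guard underflow at large N
            double *x = clv + (size_t)4 * j;
            const double mx = std::max(std::max(x[0], x[1]), std::max(x[2], x[3]));
            if (mx > 0.0 && mx < 1e-200) {
                x[0] /= mx; x[1] /= mx; x[2] /= mx; x[3] /= mx;
                logscale[j] += std::log(mx);
            }
        }
    }

    NumericVector out(n);
    const double *clr = &CL[(size_t)root * 4 * n];
    for (int j = 0; j < n; ++j) {
        const double *x = clr + (size_t)4 * j;
        const double s = pi[0] * x[0] + pi[1] * x[1] + pi[2] * x[2] + pi[3] * x[3];
        out[j] = (s > 0.0 ? std::log(s) : R_NegInf) + logscale[j];
    }
    return out;
}

// ---------------------------------------------------------------------------
// Structured-coalescent log-density of a timed, population-labeled genealogy
// with migration events under the two-population IM model. Returns -Inf when
// the genealogy is inconsistent with the parameters (migration at/above
// t_split, mismatched lineage labels at a coalescence below t_split, events
// realized in a zero-rate class).
// ---------------------------------------------------------------------------

struct Ev { double t; int type; int idx; }; // type 0 = coalescence, 1 = migration

// [[Rcpp::export]]
double cpp_coal_logdens(NumericVector times, IntegerVector parent,
                        IntegerMatrix children, IntegerVector leaf_pop, int nleaf,
                        NumericVector mig_time, IntegerVector mig_node,
                        IntegerVector mig_from, IntegerVector mig_to,
                        double th1, double th2, double thA,
                        double m1, double m2, double tsplit) {
    const int M = times.size();
    const int nm = mig_time.size();
    std::vector<Ev> ev;
    ev.reserve(M - nleaf + nm);
    for (int v = nleaf; v < M; ++v) ev.push_back({times[v], 0, v});
    for (int i = 0; i < nm; ++i) ev.push_back({mig_time[i], 1, i});
    std::sort(ev.begin(), ev.end(),
              [](const Ev &a, const Ev &b) {
                  return a.t < b.t || (a.t == b.t && a.type > b.type);
              });

    std::vector<int> lab(M, 0);
    int k1 = 0, k2 = 0;
    for (int i = 0; i < nleaf; ++i) {
        lab[i] = leaf_pop[i];
        if (lab[i] == 1) ++k1; else ++k2;
    }
    bool anc = !(tsplit > 0.0);
    double cur = 0.0, ld = 0.0;

    auto interval = [&](double to) -> bool {
        const double dt = to - cur;
        if (dt < 0) return false;
        if (dt > 0) {
            double rate = 0.0;
            if (!anc) {
                if (k1 >= 2) { if (th1 <= 0) return false; rate += k1 * (k1 - 1.0) / th1; }
                if (k2 >= 2) { if (th2 <= 0) return false; rate += k2 * (k2 - 1.0) / th2; }
                rate += k1 * m1 + k2 * m2;
            } else {
                const int k = k1 + k2;
                if (k >= 2) { if (thA <= 0) return false; rate += k * (k - 1.0) / thA; }
            }
            ld -= dt * rate;
        }
        cur = to;
        return true;
    };

    for (size_t i = 0; i < ev.size(); ++i) {
        const Ev &e = ev[i];
        if (!anc && e.t >= tsplit) {
            if (!interval(tsplit)) return R_NegInf;
            anc = true;
        }
        if (!interval(e.t)) return R_NegInf;
        if (e.type == 1) {
            if (anc) return R_NegInf; // migration at/above t_split
            const int c = mig_node[e.idx] - 1;
            const int p = parent[c] - 1;
            if (p < 0) return R_NegInf;
            if (!(times[c] < e.t && e.t < times[p])) return R_NegInf;
            const int f = mig_from[e.idx], t2 = mig_to[e.idx];
            if (lab[c] != f || f == t2) return R_NegInf;
            const double mr = (f == 1 ? m1 : m2);
            if (mr <= 0) return R_NegInf;
            lab[c] = t2;
            ld += std::log(mr);
            if (f == 1) { --k1; ++k2; } else { --k2; ++k1; }
        } else {
            const int v = e.idx;
            const int a = children(v, 0) - 1, b = children(v, 1) - 1;
            if (a < 0 || b < 0) return R_NegInf;
            if (!anc) {
                if (lab[a] != lab[b]) return R_NegInf;
                lab[v] = lab[a];
                if (lab[v] == 1) {
                    if (th1 <= 0) return R_NegInf;
                    ld += std::log(2.0 / th1); --k1;
                } else {
                    if (th2 <= 0) return R_NegInf;
                    ld += std::log(2.0 / th2); --k2;
                }
            } else {
                if (thA <= 0) return R_NegInf;
                ld += std::log(2.0 / thA);
                if (k1 > 0) --k1; else --k2;
            }
        }
    }
    if (k1 + k2 != 1) return R_NegInf;
    return ld;
}

NumericVector cpp_coal_stats(NumericVector times, IntegerVector parent,
                             IntegerMatrix children, IntegerVector leaf_pop,
                             int nleaf, NumericVector mig_time,
                             IntegerVector mig_node, IntegerVector mig_from,
                             IntegerVector mig_to, double tsplit);

// Per-locus sufficient statistics for a list of array-form genealogies in
// one call (hot path of the t updates); returns the 10 x L matrix and the
// row sums, first entries NaN when any genealogy is inconsistent with
// t_split.
// [[Rcpp::export]]
List cpp_coal_stats_multi(List arl, double tsplit) {
    const int L = arl.size();
    NumericMatrix stats(10, L);
    NumericVector total(10);
    bool ok = true;
    for (int l = 0; l < L; ++l) {
        // positional access into the array-form genealogy (fixed layout:
        // time, parent0, ch0, post, leaf_pop, N, mt, mn, mf, mto)
        List ar = arl[l];
        if (l == 0) { // guard the layout once per call
            CharacterVector nms = ar.names();
            if (nms.size() < 10 || nms[0] != "time" || nms[6] != "mt")
                stop("unexpected genealogy array layout");
        }
        NumericVector times = ar[0];
        IntegerVector parent = ar[1];
        IntegerMatrix children = ar[2];
        IntegerVector leafpop = ar[4];
        int nleaf = as<int>(ar[5]);
        NumericVector mt = ar[6];
        IntegerVector mn = ar[7];
        IntegerVector mf = ar[8];
        IntegerVector mto = ar[9];
        // reuse the exported single-locus sweep
        NumericVector s = cpp_coal_stats(times, parent, children, leafpop,
                                         nleaf, mt, mn, mf, mto, tsplit);
        for (int k = 0; k < 10; ++k) stats(k, l) = s[k];
        if (NumericVector::is_na(s[0])) ok = false;
        else if (ok) for (int k = 0; k < 10; ++k) total[k] += s[k];
    }
    if (!ok) total[0] = NA_REAL;
    return List::create(_["stats"] = stats, _["total"] = total,
                        _["ok"] = ok);
}

// Sufficient statistics of the structured-coalescent density for fixed
// genealogy and t_split: the log-density is
//   c1 log(2/th1) + c2 log(2/th2) + cA log(2/thA) + n1 log(m1) + n2 log(m2)
//   - S1/th1 - S2/th2 - SA/thA - L1 m1 - L2 m2
// with c* coalescence counts, n* migration counts, S* = sum over intervals
// of len*k*(k-1) per class and L* = sum of len*k lineage exposures.
// Returns a 10-vector (c1,c2,cA,n1,n2,S1,S2,SA,L1,L2); first element NaN
// when the genealogy is structurally inconsistent with t_split.
// [[Rcpp::export]]
NumericVector cpp_coal_stats(NumericVector times, IntegerVector parent,
                             IntegerMatrix children, IntegerVector leaf_pop,
                             int nleaf, NumericVector mig_time,
                             IntegerVector mig_node, IntegerVector mig_from,
                             IntegerVector mig_to, double tsplit) {
    const int M = times.size();
    const int nm = mig_time.size();
    NumericVector out(10);
    NumericVector bad(10, NA_REAL);
    std::vector<Ev> ev;
    ev.reserve(M - nleaf + nm);
    for (int v = nleaf; v < M; ++v) ev.push_back({times[v], 0, v});
    for (int i = 0; i < nm; ++i) ev.push_back({mig_time[i], 1, i});
    std::sort(ev.begin(), ev.end(),
              [](const Ev &a, const Ev &b) {
                  return a.t < b.t || (a.t == b.t && a.type > b.type);
              });
    std::vector<int> lab(M, 0);
    int k1 = 0, k2 = 0;
    for (int i = 0; i < nleaf; ++i) {
        lab[i] = leaf_pop[i];
        if (lab[i] == 1) ++k1; else ++k2;
    }
    bool anc = !(tsplit > 0.0);
    double cur = 0.0;
    double c1 = 0, c2 = 0, cA = 0, n1 = 0, n2 = 0;
    double S1 = 0, S2 = 0, SA = 0, L1 = 0, L2 = 0;
    auto interval = [&](double to) -> bool {
        const double dt = to - cur;
        if (dt < 0) return false;
        if (dt > 0) {
            if (!anc) {
                S1 += dt * k1 * (k1 - 1.0);
                S2 += dt * k2 * (k2 - 1.0);
                L1 += dt * k1;
                L2 += dt * k2;
            } else {
                const int k = k1 + k2;
                SA += dt * k * (k - 1.0);
            }
        }
        cur = to;
        return true;
    };
    for (size_t i = 0; i < ev.size(); ++i) {
        const Ev &e = ev[i];
        if (!anc && e.t >= tsplit) {
            if (!interval(tsplit)) return bad;
            anc = true;
        }
        if (!interval(e.t)) return bad;
        if (e.type == 1) {
            if (anc) return bad;
            const int c = mig_node[e.idx] - 1;
            const int p = parent[c] - 1;
            if (p < 0) return bad;
            if (!(times[c] < e.t && e.t < times[p])) return bad;
            const int f = mig_from[e.idx], t2 = mig_to[e.idx];
            if (lab[c] != f || f == t2) return bad;
            lab[c] = t2;
            if (f == 1) { ++n1; --k1; ++k2; } else { ++n2; --k2; ++k1; }
        } else {
            const int v = e.idx;
            const int a = children(v, 0) - 1, b = children(v, 1) - 1;
            if (a < 0 || b < 0) return bad;
            if (!anc) {
                if (lab[a] != lab[b]) return bad;
                lab[v] = lab[a];
                if (lab[v] == 1) { ++c1; --k1; } else { ++c2; --k2; }
            } else {
                ++cA;
                if (k1 > 0) --k1; else --k2;
            }
        }
    }
    if (k1 + k2 != 1) return bad;
    out[0] = c1; out[1] = c2; out[2] = cA; out[3] = n1; out[4] = n2;
    out[5] = S1; out[6] = S2; out[7] = SA; out[8] = L1; out[9] = L2;
    return out;
}

// ---------------------------------------------------------------------------
// Structured-coalescent simulation: exponential waiting times with the
// class rates, event class proportional to rate, all lineages pooled into
// the ancestral population at t_split. Randomness from R's RNG.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_simulate_genealogy(double th1, double th2, double thA,
                            double m1, double m2, double tsplit,
                            int N1, int N2) {
    const int N = N1 + N2;
    const int M = 2 * N - 1;
    NumericVector time(M);
    IntegerVector parent(M, 0);
    IntegerMatrix children(M, 2); // 0 = leaf
    std::vector<int> act, pop;
    for (int i = 0; i < N; ++i) {
        act.push_back(i);
        pop.push_back(i < N1 ? 1 : 2);
    }
    std::vector<double> mt;
    std::vector<int> mn, mf;
    double tnow = 0.0;
    int nxt = N;
    bool below = tsplit > 0.0;
    while ((int)act.size() > 1) {
        int k1 = 0, k2 = 0;
        for (size_t i = 0; i < act.size(); ++i)
            if (pop[i] == 1) ++k1; else ++k2;
        if (below) {
            double r1 = (k1 >= 2 && th1 > 0) ? k1 * (k1 - 1.0) / th1 : 0.0;
            double r2 = (k2 >= 2 && th2 > 0) ? k2 * (k2 - 1.0) / th2 : 0.0;
            double r3 = k1 * m1, r4 = k2 * m2;
            double tot = r1 + r2 + r3 + r4;
            double jump = (tot > 0) ? exp_rand() / tot : R_PosInf;
            if (tnow + jump >= tsplit) {
                tnow = tsplit;
                below = false;
                continue;
            }
            tnow += jump;
            double x = unif_rand() * tot;
            if (x < r1 + r2) { // coalescence in population 1 or 2
                const int cpop = (x < r1) ? 1 : 2;
                const int kk = (cpop == 1) ? k1 : k2;
                int i1 = (int)(unif_rand() * kk), i2 = (int)(unif_rand() * (kk - 1));
                if (i2 >= i1) ++i2;
                // map to positions among lineages of cpop
                int a = -1, b = -1, seen = 0;
                for (size_t i = 0; i < act.size(); ++i) {
                    if (pop[i] != cpop) continue;
                    if (seen == i1) a = (int)i;
                    if (seen == i2) b = (int)i;
                    ++seen;
                }
                time[nxt] = tnow;
                children(nxt, 0) = act[a] + 1;
                children(nxt, 1) = act[b] + 1;
                parent[act[a]] = nxt + 1;
                parent[act[b]] = nxt + 1;
                if (a > b) std::swap(a, b);
                act.erase(act.begin() + b); pop.erase(pop.begin() + b);
                act.erase(act.begin() + a); pop.erase(pop.begin() + a);
                act.push_back(nxt); pop.push_back(cpop);
                ++nxt;
            } else { // migration out of population 1 or 2
                const int from = (x < r1 + r2 + r3) ? 1 : 2;
                const int kk = (from == 1) ? k1 : k2;
                int pickn = (int)(unif_rand() * kk);
                int w = -1, seen = 0;
                for (size_t i = 0; i < act.size(); ++i) {
                    if (pop[i] != from) continue;
                    if (seen == pickn) { w = (int)i; break; }
                    ++seen;
                }
                mn.push_back(act[w] + 1);
                mt.push_back(tnow);
                mf.push_back(from);
                pop[w] = 3 - from;
            }
        } else {
            const int k = (int)act.size();
            tnow += exp_rand() / (k * (k - 1.0) / thA);
            int i1 = (int)(unif_rand() * k), i2 = (int)(unif_rand() * (k - 1));
            if (i2 >= i1) ++i2;
            time[nxt] = tnow;
            children(nxt, 0) = act[i1] + 1;
            children(nxt, 1) = act[i2] + 1;
            parent[act[i1]] = nxt + 1;
            parent[act[i2]] = nxt + 1;
            int a = std::min(i1, i2), b = std::max(i1, i2);
            act.erase(act.begin() + b); pop.erase(pop.begin() + b);
            act.erase(act.begin() + a); pop.erase(pop.begin() + a);
            act.push_back(nxt); pop.push_back(0);
            ++nxt;
        }
    }
    const int nm = (int)mn.size();
    IntegerVector mn2(nm), mf2(nm);
    NumericVector mt2(nm);
    for (int i = 0; i < nm; ++i) { mn2[i] = mn[i]; mf2[i] = mf[i]; mt2[i] = mt[i]; }
    return List::create(_["time"] = time, _["parent0"] = parent,
                        _["children0"] = children, _["mig_node"] = mn2,
                        _["mig_time"] = mt2, _["mig_from"] = mf2);
}

// ===========================================================================
// Compiled per-locus genealogy update: proposes one reversible move (node
// slide / regraft / migration birth-death), evaluates the structured-
// coalescent density and the locus likelihood, and applies the Metropolis-
// Hastings accept step, all in one call. Mirrors the R reference moves in
// R/moves.R; randomness comes from R's RNG so runs stay reproducible.
// ===========================================================================

struct GTree {
    int N, M;
    std::vector<double> time;
    std::vector<int> parent;      // -1 = root
    std::vector<int> ch1, ch2;    // -1 = leaf
    std::vector<int> leafpop;
    std::vector<double> mt;       // migration times
    std::vector<int> mn, mf, mto; // migration edge (child node), from, to
};

static bool stats_sweep(const GTree &g, double tsplit, double *out) {
    const int nm = (int)g.mt.size();
    std::vector<Ev> ev;
    ev.reserve(g.M - g.N + nm);
    for (int v = g.N; v < g.M; ++v) ev.push_back({g.time[v], 0, v});
    for (int i = 0; i < nm; ++i) ev.push_back({g.mt[i], 1, i});
    std::sort(ev.begin(), ev.end(),
              [](const Ev &a, const Ev &b) {
                  return a.t < b.t || (a.t == b.t && a.type > b.type);
              });
    std::vector<int> lab(g.M, 0);
    int k1 = 0, k2 = 0;
    for (int i = 0; i < g.N; ++i) {
        lab[i] = g.leafpop[i];
        if (lab[i] == 1) ++k1; else ++k2;
    }
    bool anc = !(tsplit > 0.0);
    double cur = 0.0;
    double st[10] = {0, 0, 0, 0, 0, 0, 0, 0, 0, 0};
    auto interval = [&](double to) -> bool {
        const double dt = to - cur;
        if (dt < 0) return false;
        if (dt > 0) {
            if (!anc) {
                st[5] += dt * k1 * (k1 - 1.0);
                st[6] += dt * k2 * (k2 - 1.0);
                st[8] += dt * k1;
                st[9] += dt * k2;
            } else {
                const int k = k1 + k2;
                st[7] += dt * k * (k - 1.0);
            }
        }
        cur = to;
        return true;
    };
    for (size_t i = 0; i < ev.size(); ++i) {
        const Ev &e = ev[i];
        if (!anc && e.t >= tsplit) {
            if (!interval(tsplit)) return false;
            anc = true;
        }
        if (!interval(e.t)) return false;
        if (e.type == 1) {
            if (anc) return false;
            const int c = g.mn[e.idx];
            const int p = g.parent[c];
            if (p < 0) return false;
            if (!(g.time[c] < e.t && e.t < g.time[p])) return false;
            const int f = g.mf[e.idx], t2 = g.mto[e.idx];
            if (lab[c] != f || f == t2) return false;
            lab[c] = t2;
            if (f == 1) { ++st[3]; --k1; ++k2; } else { ++st[4]; --k2; ++k1; }
        } else {
            const int v = e.idx;
            const int a = g.ch1[v], b = g.ch2[v];
            if (a < 0 || b < 0) return false;
            if (!anc) {
                if (lab[a] != lab[b]) return false;
                lab[v] = lab[a];
                if (lab[v] == 1) { ++st[0]; --k1; } else { ++st[1]; --k2; }
            } else {
                ++st[2];
                if (k1 > 0) --k1; else --k2;
            }
        }
    }
    if (k1 + k2 != 1) return false;
    for (int i = 0; i < 10; ++i) out[i] = st[i];
    return true;
}

static double dens_from_stats_c(const double *S, double th1, double th2,
                                double thA, double m1, double m2) {
    double val = 0;
    if (S[0] > 0 || S[5] > 0) {
        if (th1 <= 0) return R_NegInf;
        val += S[0] * std::log(2 / th1) - S[5] / th1;
    }
    if (S[1] > 0 || S[6] > 0) {
        if (th2 <= 0) return R_NegInf;
        val += S[1] * std::log(2 / th2) - S[6] / th2;
    }
    if (S[2] > 0 || S[7] > 0) {
        if (thA <= 0) return R_NegInf;
        val += S[2] * std::log(2 / thA) - S[7] / thA;
    }
    if (S[3] > 0) { if (m1 <= 0) return R_NegInf; val += S[3] * std::log(m1); }
    if (S[4] > 0) { if (m2 <= 0) return R_NegInf; val += S[4] * std::log(m2); }
    return val - S[8] * m1 - S[9] * m2;
}

static void postorder_of(const GTree &g, std::vector<int> &po) {
    po.resize(g.M - g.N);
    for (int i = 0; i < g.M - g.N; ++i) po[i] = g.N + i;
    std::sort(po.begin(), po.end(),
              [&](int a, int b) { return g.time[a] < g.time[b]; });
}

static double total_blen(const GTree &g) {
    double bt = 0;
    for (int v = 0; v < g.M; ++v)
        if (g.parent[v] >= 0) bt += g.time[g.parent[v]] - g.time[v];
    return bt;
}

// infinite-sites log-likelihood via clade mapping (carriers: ns x N)
static double is_loglik_c(const GTree &g, const LogicalMatrix &carriers,
                          double u) {
    const double BT = total_blen(g);
    const int ns = carriers.nrow();
    if (ns == 0) return -BT * u;
    const int W = (g.N + 63) / 64;
    std::vector<uint64_t> mask((size_t)g.M * W, 0);
    for (int i = 0; i < g.N; ++i)
        mask[(size_t)i * W + i / 64] = (uint64_t)1 << (i % 64);
    std::vector<int> po;
    postorder_of(g, po);
    int root = po.back();
    for (size_t oi = 0; oi < po.size(); ++oi) {
        const int v = po[oi];
        for (int w = 0; w < W; ++w)
            mask[(size_t)v * W + w] = mask[(size_t)g.ch1[v] * W + w] |
                                      mask[(size_t)g.ch2[v] * W + w];
    }
    std::vector<int> cnt(g.M, 0);
    std::vector<uint64_t> cm(W);
    double ll = -BT * u;
    for (int s = 0; s < ns; ++s) {
        std::fill(cm.begin(), cm.end(), 0);
        for (int i = 0; i < g.N; ++i)
            if (carriers(s, i)) cm[i / 64] |= (uint64_t)1 << (i % 64);
        int hit = -1;
        for (int v = 0; v < g.M; ++v) {
            if (v == root) continue;
            bool eq = true;
            for (int w = 0; w < W; ++w)
                if (mask[(size_t)v * W + w] != cm[w]) { eq = false; break; }
            if (eq) { hit = v; break; }
        }
        if (hit < 0) return R_NegInf;
        ll += std::log((g.time[g.parent[hit]] - g.time[hit]) * u);
        cnt[hit]++;
    }
    for (int v = 0; v < g.M; ++v)
        if (cnt[v] > 1) ll -= std::lgamma(cnt[v] + 1.0);
    return ll;
}

// HKY total log-likelihood on raw arrays (codes: N x n, 1..4)
static double hky_loglik_c(const GTree &g, const IntegerMatrix &codes,
                           const double *pi, double kappa, double u) {
    const int n = codes.ncol();
    std::vector<int> po;
    postorder_of(g, po);
    const int root = po.back();
    std::vector<double> CL((size_t)g.M * 4 * n);
    std::vector<double> logscale(n, 0.0);
    double P[16];
    for (size_t oi = 0; oi < po.size(); ++oi) {
        const int v = po[oi];
        double *clv = &CL[(size_t)v * 4 * n];
        std::fill(clv, clv + (size_t)4 * n, 1.0);
        const int cc[2] = {g.ch1[v], g.ch2[v]};
        for (int ci = 0; ci < 2; ++ci) {
            const int c = cc[ci];
            hky_pmat_fill((g.time[v] - g.time[c]) * u, pi, kappa, P);
            if (c < g.N) {
                for (int j = 0; j < n; ++j) {
                    const int b = codes(c, j) - 1;
                    double *x = clv + (size_t)4 * j;
                    x[0] *= P[0 + b]; x[1] *= P[4 + b];
                    x[2] *= P[8 + b]; x[3] *= P[12 + b];
                }
            } else {
                const double *clc = &CL[(size_t)c * 4 * n];
                for (int j = 0; j < n; ++j) {
                    const double *y = clc + (size_t)4 * j;
                    double *x = clv + (size_t)4 * j;
                    for (int a = 0; a < 4; ++a) {
                        const double s = P[4 * a] * y[0] + P[4 * a + 1] * y[1] +
                                         P[4 * a + 2] * y[2] +
                                         P[4 * a + 3] * y[3];
                        x[a] *= s;
                    }
                }
            }
        }
        for (int j = 0; j < n; ++j) {
            double *x = clv + (size_t)4 * j;
            const double mx = std::max(std::max(x[0], x[1]),
                                       std::max(x[2], x[3]));
            if (mx > 0.0 && mx < 1e-200) {
                x[0] /= mx; x[1] /= mx; x[2] /= mx; x[3] /= mx;
                logscale[j] += std::log(mx);
            }
        }
    }
    double tot = 0;
    const double *clr = &CL[(size_t)root * 4 * n];
    for (int j = 0; j < n; ++j) {
        const double s = pi[0] * clr[4 * j] + pi[1] * clr[4 * j + 1] +
                         pi[2] * clr[4 * j + 2] + pi[3] * clr[4 * j + 3];
        if (!(s > 0)) return R_NegInf;
        tot += std::log(s) + logscale[j];
    }
    return tot;
}

// --- move proposals on GTree; each returns log-Hastings or -Inf -----------

static int mig_count_on_edge(const GTree &g, int v) {
    int k = 0;
    for (size_t i = 0; i < g.mn.size(); ++i) if (g.mn[i] == v) ++k;
    return k;
}

static int pairs_count(const GTree &g) {
    int tot = 0;
    for (int v = 0; v < g.M; ++v) {
        int k = mig_count_on_edge(g, v);
        if (k >= 2) tot += k - 1;
    }
    return tot;
}

static double propose_slide(GTree &g, double root_delta) {
    const int nint = g.M - g.N;
    const int v = g.N + (int)(unif_rand() * nint);
    if (g.parent[v] < 0) { // root: log-uniform height multiplier
        const double eps = std::exp((unif_rand() * 2 - 1) * root_delta);
        double lo = std::max(g.time[g.ch1[v]], g.time[g.ch2[v]]);
        for (size_t i = 0; i < g.mn.size(); ++i)
            if (g.mn[i] == g.ch1[v] || g.mn[i] == g.ch2[v])
                lo = std::max(lo, g.mt[i]);
        const double nt = g.time[v] * eps;
        if (!(nt > lo)) return R_NegInf;
        g.time[v] = nt;
        return std::log(eps);
    }
    double lo = std::max(g.time[g.ch1[v]], g.time[g.ch2[v]]);
    double hi = g.time[g.parent[v]];
    for (size_t i = 0; i < g.mn.size(); ++i) {
        if (g.mn[i] == g.ch1[v] || g.mn[i] == g.ch2[v])
            lo = std::max(lo, g.mt[i]);
        if (g.mn[i] == v) hi = std::min(hi, g.mt[i]);
    }
    if (!(hi > lo)) return R_NegInf;
    g.time[v] = lo + unif_rand() * (hi - lo);
    return 0.0;
}

static double propose_regraft(GTree &g) {
    // choose a non-root node uniformly
    int v = (int)(unif_rand() * (g.M - 1));
    {   // skip the root in the draw
        int root = -1;
        for (int w = 0; w < g.M; ++w) if (g.parent[w] < 0) { root = w; break; }
        if (v >= root) ++v;
    }
    const int p = g.parent[v];
    if (p < 0 || g.parent[p] < 0) return R_NegInf;
    if (mig_count_on_edge(g, v) > 0) return R_NegInf;
    const int sib = (g.ch1[p] == v) ? g.ch2[p] : g.ch1[p];
    const int gp = g.parent[p];
    // prune
    g.parent[sib] = gp;
    if (g.ch1[gp] == p) g.ch1[gp] = sib; else g.ch2[gp] = sib;
    g.parent[p] = -1;
    for (size_t i = 0; i < g.mn.size(); ++i)
        if (g.mn[i] == p) g.mn[i] = sib;
    // mark v's subtree
    std::vector<char> sub(g.M, 0);
    std::vector<int> stack{v};
    while (!stack.empty()) {
        const int w = stack.back(); stack.pop_back();
        sub[w] = 1;
        if (g.ch1[w] >= 0) { stack.push_back(g.ch1[w]); stack.push_back(g.ch2[w]); }
    }
    // candidate intervals
    std::vector<int> cand;
    std::vector<double> lo, len;
    double total = 0;
    for (int w = 0; w < g.M; ++w) {
        if (w == p || sub[w] || g.parent[w] < 0) continue;
        const double l = std::max(g.time[v], g.time[w]);
        const double h = g.time[g.parent[w]];
        if (h > l) {
            cand.push_back(w); lo.push_back(l); len.push_back(h - l);
            total += h - l;
        }
    }
    if (!(total > 0)) return R_NegInf;
    double x = unif_rand() * total;
    int i = 0;
    while (i + 1 < (int)cand.size() && x > len[i]) { x -= len[i]; ++i; }
    const int dest = cand[i];
    const double tau = lo[i] + std::min(x, len[i]);
    // attach
    const int q = g.parent[dest];
    g.ch1[p] = v; g.ch2[p] = dest;
    g.parent[dest] = p;
    g.parent[v] = p;
    g.parent[p] = q;
    if (g.ch1[q] == dest) g.ch1[q] = p; else g.ch2[q] = p;
    g.time[p] = tau;
    for (size_t k = 0; k < g.mn.size(); ++k)
        if (g.mn[k] == dest && g.mt[k] > tau) g.mn[k] = p;
    return 0.0;
}

static int edge_label_at_c(const GTree &g, int v, double tt) {
    int w = v;
    while (g.ch1[w] >= 0) w = g.ch1[w];
    int lab = g.leafpop[w];
    int flips = 0;
    // flips on the path from leaf w up to v, plus those on v's edge <= tt
    std::vector<char> onpath(g.M, 0);
    while (w != v) { onpath[w] = 1; w = g.parent[w]; }
    for (size_t i = 0; i < g.mn.size(); ++i) {
        if (onpath[g.mn[i]]) ++flips;
        else if (g.mn[i] == v && g.mt[i] <= tt) ++flips;
    }
    return (flips % 2 == 1) ? 3 - lab : lab;
}

// single-event birth/death on edges whose parent lies above t_split: the
// edge-top label is unconstrained there, so one flip keeps the genealogy
// consistent. These moves change migration-count parity, which the
// pair moves alone cannot.
static double propose_mig_single(GTree &g, double tsplit) {
    // split-crossing edges and their below-split portions
    std::vector<int> node;
    std::vector<double> lo, len;
    double total = 0;
    for (int w = 0; w < g.M; ++w) {
        if (g.parent[w] < 0) continue;
        if (!(g.time[g.parent[w]] > tsplit)) continue;
        const double l = g.time[w];
        if (l < tsplit) {
            node.push_back(w); lo.push_back(l); len.push_back(tsplit - l);
            total += tsplit - l;
        }
    }
    if (unif_rand() < 0.5) { // birth
        if (!(total > 0)) return R_NegInf;
        double x = unif_rand() * total;
        int i = 0;
        while (i + 1 < (int)node.size() && x > len[i]) { x -= len[i]; ++i; }
        const int v = node[i];
        const double tau = lo[i] + std::min(x, len[i]);
        for (size_t k = 0; k < g.mn.size(); ++k)
            if (g.mn[k] == v && g.mt[k] > tau)
                return R_NegInf; // must stay topmost on its edge
        const int lab = edge_label_at_c(g, v, tau);
        g.mn.push_back(v); g.mt.push_back(tau);
        g.mf.push_back(lab); g.mto.push_back(3 - lab);
        int Ds = 0; // split-crossing edges carrying >= 1 migration
        for (size_t ii = 0; ii < node.size(); ++ii)
            for (size_t k = 0; k < g.mn.size(); ++k)
                if (g.mn[k] == node[ii]) { ++Ds; break; }
        return std::log(total) - std::log((double)Ds);
    } else { // death of the topmost migration on a split-crossing edge
        std::vector<int> top;
        for (size_t ii = 0; ii < node.size(); ++ii) {
            int best = -1;
            for (size_t k = 0; k < g.mn.size(); ++k)
                if (g.mn[k] == node[ii] &&
                    (best < 0 || g.mt[k] > g.mt[best])) best = (int)k;
            if (best >= 0) top.push_back(best);
        }
        if (top.empty()) return R_NegInf;
        const int del = top[(int)(unif_rand() * top.size())];
        const double h = std::log((double)top.size()) - std::log(total);
        g.mn.erase(g.mn.begin() + del);
        g.mt.erase(g.mt.begin() + del);
        g.mf.erase(g.mf.begin() + del);
        g.mto.erase(g.mto.begin() + del);
        return h;
    }
}

static double propose_mig(GTree &g, double tsplit) {
    if (unif_rand() < 0.5) return propose_mig_single(g, tsplit);
    if (unif_rand() < 0.5) { // birth of a flip-and-return pair
        double total = 0;
        std::vector<int> node;
        std::vector<double> lo, len, hi;
        for (int w = 0; w < g.M; ++w) {
            if (g.parent[w] < 0) continue;
            const double l = g.time[w];
            const double h = std::min(g.time[g.parent[w]], tsplit);
            if (h > l) { node.push_back(w); lo.push_back(l); hi.push_back(h);
                         len.push_back(h - l); total += h - l; }
        }
        if (!(total > 0)) return R_NegInf;
        double x = unif_rand() * total;
        int i = 0;
        while (i + 1 < (int)node.size() && x > len[i]) { x -= len[i]; ++i; }
        const int v = node[i];
        const double tau1 = lo[i] + std::min(x, len[i]);
        const double tau2 = tau1 + unif_rand() * (hi[i] - tau1);
        for (size_t k = 0; k < g.mn.size(); ++k)
            if (g.mn[k] == v && g.mt[k] > tau1 && g.mt[k] < tau2)
                return R_NegInf; // would break existing flips
        const int lab = edge_label_at_c(g, v, tau1);
        g.mn.push_back(v); g.mt.push_back(tau1);
        g.mf.push_back(lab); g.mto.push_back(3 - lab);
        g.mn.push_back(v); g.mt.push_back(tau2);
        g.mf.push_back(3 - lab); g.mto.push_back(lab);
        const int D = pairs_count(g);
        return std::log(total) + std::log(hi[i] - tau1) - std::log((double)D);
    } else { // death of a consecutive same-edge pair
        const int D = pairs_count(g);
        if (D == 0) return R_NegInf;
        int pick = (int)(unif_rand() * D);
        // locate the pick-th consecutive pair (edges in node order, times sorted)
        int del1 = -1, del2 = -1;
        for (int w = 0; w < g.M && del1 < 0; ++w) {
            std::vector<int> idx;
            for (size_t i = 0; i < g.mn.size(); ++i)
                if (g.mn[i] == w) idx.push_back((int)i);
            if ((int)idx.size() < 2) continue;
            std::sort(idx.begin(), idx.end(),
                      [&](int a, int b) { return g.mt[a] < g.mt[b]; });
            const int np = (int)idx.size() - 1;
            if (pick < np) { del1 = idx[pick]; del2 = idx[pick + 1]; }
            else pick -= np;
        }
        const int v = g.mn[del1];
        const double tau1 = g.mt[del1];
        double total = 0, hi_v = 0;
        for (int w = 0; w < g.M; ++w) {
            if (g.parent[w] < 0) continue;
            const double l = g.time[w];
            const double h = std::min(g.time[g.parent[w]], tsplit);
            if (h > l) { total += h - l; if (w == v) hi_v = h; }
        }
        const double h = std::log((double)D) - std::log(total) -
                         std::log(hi_v - tau1);
        std::vector<int> keep;
        for (int i = 0; i < (int)g.mn.size(); ++i)
            if (i != del1 && i != del2) keep.push_back(i);
        GTree tmp = g;
        g.mn.clear(); g.mt.clear(); g.mf.clear(); g.mto.clear();
        for (size_t i = 0; i < keep.size(); ++i) {
            g.mn.push_back(tmp.mn[keep[i]]);
            g.mt.push_back(tmp.mt[keep[i]]);
            g.mf.push_back(tmp.mf[keep[i]]);
            g.mto.push_back(tmp.mto[keep[i]]);
        }
        return h;
    }
}

// One genealogy update for one locus. likmode: 0 = off, 1 = IS, 2 = HKY.
// Returns list(accepted, and on acceptance the new arrays + cached terms).
// [[Rcpp::export]]
List cpp_tree_update(NumericVector time, IntegerVector parent0,
                     IntegerMatrix children0, IntegerVector leaf_pop,
                     int nleaf, NumericVector mig_time, IntegerVector mig_node,
                     IntegerVector mig_from, IntegerVector mig_to,
                     NumericVector par, double cur_dens, double cur_loglik,
                     double beta, bool post_temp, int likmode,
                     LogicalMatrix carriers, IntegerMatrix codes,
                     NumericVector pi, double kappa, double u,
                     double root_delta) {
    GTree g;
    g.N = nleaf; g.M = time.size();
    g.time.assign(time.begin(), time.end());
    g.parent.resize(g.M); g.ch1.resize(g.M); g.ch2.resize(g.M);
    for (int i = 0; i < g.M; ++i) {
        g.parent[i] = parent0[i] - 1;
        g.ch1[i] = children0(i, 0) - 1;
        g.ch2[i] = children0(i, 1) - 1;
    }
    g.leafpop.assign(leaf_pop.begin(), leaf_pop.end());
    g.mt.assign(mig_time.begin(), mig_time.end());
    g.mn.resize(mig_node.size()); g.mf.resize(mig_node.size());
    g.mto.resize(mig_node.size());
    for (int i = 0; i < mig_node.size(); ++i) {
        g.mn[i] = mig_node[i] - 1;
        g.mf[i] = mig_from[i];
        g.mto[i] = mig_to[i];
    }
    const double th1 = par[0], th2 = par[1], thA = par[2];
    const double m1 = par[3], m2 = par[4], tsplit = par[5];

    const int mv = (int)(unif_rand() * 3);
    double h;
    if (mv == 0) h = propose_slide(g, root_delta);
    else if (mv == 1) h = propose_regraft(g);
    else h = propose_mig(g, tsplit);
    if (h == R_NegInf)
        return List::create(_["accepted"] = false, _["move"] = mv);

    double S[10];
    double nd, ll;
    if (!stats_sweep(g, tsplit, S)) nd = R_NegInf;
    else nd = dens_from_stats_c(S, th1, th2, thA, m1, m2);
    if (nd == R_NegInf) ll = R_NegInf;
    else if (likmode == 0) ll = 0.0;
    else if (likmode == 1) ll = is_loglik_c(g, carriers, u);
    else ll = hky_loglik_c(g, codes, &pi[0], kappa, u);

    double d;
    if (post_temp) d = beta * ((nd + ll) - (cur_dens + cur_loglik));
    else d = (nd - cur_dens) + beta * (ll - cur_loglik);
    d += h;
    const bool acc = !ISNAN(d) && (d >= 0 || unif_rand() < std::exp(d));
    if (!acc)
        return List::create(_["accepted"] = false, _["move"] = mv);

    IntegerVector np(g.M);
    IntegerMatrix nc(g.M, 2);
    for (int i = 0; i < g.M; ++i) {
        np[i] = g.parent[i] + 1;
        nc(i, 0) = g.ch1[i] + 1;
        nc(i, 1) = g.ch2[i] + 1;
    }
    const int nm = (int)g.mn.size();
    IntegerVector mn2(nm), mf2(nm), mto2(nm);
    NumericVector mt2(nm);
    for (int i = 0; i < nm; ++i) {
        mn2[i] = g.mn[i] + 1; mt2[i] = g.mt[i];
        mf2[i] = g.mf[i]; mto2[i] = g.mto[i];
    }
    return List::create(_["accepted"] = true, _["move"] = mv,
                        _["time"] = NumericVector(g.time.begin(), g.time.end()),
                        _["parent0"] = np, _["children0"] = nc,
                        _["mig_time"] = mt2, _["mig_node"] = mn2,
                        _["mig_from"] = mf2, _["mig_to"] = mto2,
                        _["stats"] = NumericVector(S, S + 10),
                        _["dens"] = nd, _["loglik"] = ll);
}

// ---------------------------------------------------------------------------
// Infinite-sites clade mapping: for each site's derived-carrier leaf set, the
// unique edge whose subtended leaf set equals it (edge named by its child
// node), 0 if no such edge exists or the carriers are all leaves.
// carriers: nsites x nleaf logical.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_is_map(IntegerMatrix children, IntegerVector postorder,
                         int nleaf, LogicalMatrix carriers) {
    const int M = children.nrow();
    const int W = (nleaf + 63) / 64;
    std::vector<uint64_t> mask((size_t)M * W, 0);
    for (int i = 0; i < nleaf; ++i)
        mask[(size_t)i * W + i / 64] = (uint64_t)1 << (i % 64);
    const int root = postorder[postorder.size() - 1] - 1;
    for (int oi = 0; oi < postorder.size(); ++oi) {
        const int v = postorder[oi] - 1;
        const int a = children(v, 0) - 1, b = children(v, 1) - 1;
        for (int w = 0; w < W; ++w)
            mask[(size_t)v * W + w] =
                mask[(size_t)a * W + w] | mask[(size_t)b * W + w];
    }
    const int ns = carriers.nrow();
    IntegerVector out(ns);
    std::vector<uint64_t> cm(W);
    for (int s = 0; s < ns; ++s) {
        std::fill(cm.begin(), cm.end(), 0);
        for (int i = 0; i < nleaf; ++i)
            if (carriers(s, i)) cm[i / 64] |= (uint64_t)1 << (i % 64);
        int hit = 0;
        for (int v = 0; v < M && !hit; ++v) {
            if (v == root) continue;
            bool eq = true;
            for (int w = 0; w < W; ++w)
                if (mask[(size_t)v * W + w] != cm[w]) { eq = false; break; }
            if (eq) hit = v + 1;
        }
        out[s] = hit;
    }
    return out;
}
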