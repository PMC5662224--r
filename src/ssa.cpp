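#include <Rcpp.h>
#include <random>
#include <cmath>
using namespace Rcpp;

// Exact direct-method SSA with piecewise-constant modulation of flagged
// (translation) propensities.  Time unit: seconds.  The state is recorded
// at every grid boundary k * record_sec (state just before/at the
// boundary); the extrinsic factor extr[k] applies on the half-open
// interval [k * record_sec, (k+1) * record_sec).  Between boundaries all
// propensities are constant, so sampling is statistically exact.
//
// schedule_times_sec / schedule_counts optionally reset the free-inducer
// count (species index ind_index) at grid-aligned times.
//
// [[Rcpp::export]]
IntegerMatrix ssa_run_cpp(IntegerVector init,
                          IntegerMatrix reactants, // S x R reactant orders
                          IntegerMatrix net,       // S x R net changes
                          NumericVector rates,
                          LogicalVector is_translation,
                          double t_end_sec,
                          double record_sec,
                          NumericVector extr,      // length >= n_intervals
                          int seed,
                          NumericVector schedule_times_sec,
                          IntegerVector schedule_counts,
                          int ind_index)           // 0-based; -1 if unused
{
    const int S = reactants.nrow();
    const int R = reactants.ncol();
    const int n_rec = (int)std::floor(t_end_sec / record_sec + 1e-9) + 1;
    if (extr.size() < n_rec - 1)
        stop("extrinsic series too short: need %d intervals, got %d",
             n_rec - 1, (int)extr.size());

    // sparse reactant lists per reaction
    std::vector<std::vector<std::pair<int,int>>> rlist(R);
    for (int j = 0; j < R; ++j)
        for (int i = 0; i < S; ++i)
            if (reactants(i, j) > 0)
                rlist[j].push_back({i, reactants(i, j)});

    std::vector<long long> x(S);
    for (int i = 0; i < S; ++i) x[i] = init[i];

    IntegerMatrix out(n_rec, S);
    for (int i = 0; i < S; ++i) out(0, i) = (int)x[i];

    std::mt19937_64 rng((uint64_t)seed);
    std::uniform_real_distribution<double> unif(0.0, 1.0);

    std::vector<double> a(R);
    int sched_i = 0;
    const int n_sched = schedule_times_sec.size();

    double t = 0.0;
    for (int k = 1; k < n_rec; ++k) {
        const double t_boundary = k * record_sec;
        const double f = extr[k - 1];

        // apply any schedule step falling at the start of this interval
        while (sched_i < n_sched &&
               schedule_times_sec[sched_i] <= (k - 1) * record_sec + 1e-9) {
            x[ind_index] = schedule_counts[sched_i];
            ++sched_i;
        }

        // constant propensities within the interval
        bool stale = true;
        double a0 = 0.0;
        while (true) {
            if (stale) {
                a0 = 0.0;
                for (int j = 0; j < R; ++j) {
                    double aj = rates[j];
                    for (auto &pr : rlist[j]) {
                        long long c = x[pr.first];
                        if (pr.second == 1) aj *= (double)c;
                        else aj *= (double)c * (c - 1) / 2.0; // order 2
                    }
                    if (is_translation[j]) aj *= f;
                    a[j] = aj;
                    a0 += aj;
                }
                if (!std::isfinite(a0))
                    stop("non-finite total propensity at t = %f s", t);
                stale = false;
            }
            if (a0 <= 0.0) { t = t_boundary; break; }
            double u1 = unif(rng);
            // guard against log(0)
            double dt = -std::log(u1 > 0 ? u1 : 1e-300) / a0;
            if (t + dt >= t_boundary) { t = t_boundary; break; }
            t += dt;
            double target = unif(rng) * a0;
            double cum = 0.0;
            int j = 0;
            for (; j < R - 1; ++j) {
                cum += a[j];
                if (target < cum) break;
            }
            for (int i = 0; i < S; ++i) x[i] += net(i, j);
            stale = true;
        }
        for (int i = 0; i < S; ++i) out(k, i) = (int)x[i];
    }
    return out;
}
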