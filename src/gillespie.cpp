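#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation of a labelled continuous-time Markov chain.
//
// States are 0-based integers.  Transitions are supplied grouped by
// source state (offset[s] .. offset[s+1]-1 index into `to` / `rate`).
// A state flagged in `is_branch` resolves instantaneously: its outgoing
// "rates" are interpreted as branch weights and no time elapses.
// A cycle is the walk from the initial state back to itself; the cycle
// counter increments on re-entry.
//
// Uses R's RNG so runs are reproducible under set.seed().

// [[Rcpp::export(name = ".gillespie_cpp")]]
List gillespie_cpp(int n_states, int init, int n_cycles,
                   IntegerVector offset, IntegerVector to,
                   NumericVector rate, LogicalVector is_branch,
                   NumericVector rate_sum, double max_events) {
  std::vector<int> ev_cycle, ev_from, ev_to;
  std::vector<double> ev_time;
  const size_t reserve0 = (size_t)std::min(max_events, 4e6);
  ev_cycle.reserve(reserve0);
  ev_from.reserve(reserve0);
  ev_to.reserve(reserve0);
  ev_time.reserve(reserve0);

  RNGScope scope;
  int s = init;
  int cycle = 1;
  double t = 0.0;
  while (cycle <= n_cycles) {
    if ((double)ev_time.size() >= max_events)
      stop("event budget exceeded (%.0f events); the network may contain "
           "a rate far smaller than the rest", max_events);
    const int lo = offset[s], hi = offset[s + 1];
    if (hi <= lo)
      stop("absorbing state reached: state index %d has no outgoing "
           "transitions", s + 1);
    int nxt = -1;
    if (is_branch[s]) {
      double u = unif_rand() * rate_sum[s];
      double acc = 0.0;
      for (int j = lo; j < hi; ++j) {
        acc += rate[j];
        if (u <= acc) { nxt = to[j]; break; }
      }
      if (nxt < 0) nxt = to[hi - 1];
    } else {
      const double tot = rate_sum[s];
      t += exp_rand() / tot;
      double u = unif_rand() * tot;
      double acc = 0.0;
      for (int j = lo; j < hi; ++j) {
        acc += rate[j];
        if (u <= acc) { nxt = to[j]; break; }
      }
      if (nxt < 0) nxt = to[hi - 1];
    }
    ev_cycle.push_back(cycle);
    ev_time.push_back(t);
    ev_from.push_back(s + 1);
    ev_to.push_back(nxt + 1);
    s = nxt;
    if (s == init) cycle++;
  }
  return List::create(_["cycle"] = wrap(ev_cycle),
                      _["time"] = wrap(ev_time),
                      _["from"] = wrap(ev_from),
                      _["to"] = wrap(ev_to));
}
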