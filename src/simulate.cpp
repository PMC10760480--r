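#include <Rcpp.h>
#include <vector>
#include <set>
using namespace Rcpp;

// Monte Carlo state path for a Markov gating scheme at fixed voltage.
// exit_rate[i]: total rate out of state i (1/s); cumprob(i, j): cumulative
// transition probability from state i into states 0..j. Dwells are drawn as
// d = -log(U)/exit_rate (U ~ Unif(0,1)); the final dwell is truncated at
// `duration`. Uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
List sim_path_cpp(NumericVector exit_rate, NumericMatrix cumprob,
                  int start_state, double duration) {
  const int ns = exit_rate.size();
  if (start_state < 0 || start_state >= ns)
    stop("invalid start state");
  std::vector<int> states;
  std::vector<double> dwells;
  // reserve using the expected number of events to avoid regrowth
  double mean_rate = 0.0;
  for (int i = 0; i < ns; ++i) mean_rate += exit_rate[i];
  mean_rate /= ns;
  const std::size_t guess = (std::size_t)std::min(5e7, duration * mean_rate * 1.2 + 64);
  states.reserve(guess);
  dwells.reserve(guess);

  double t = 0.0;
  int s = start_state;
  while (t < duration) {
    double u = unif_rand();
    if (u <= 0.0) u = 1e-300; // guard log(0)
    double d = -std::log(u) / exit_rate[s];
    if (t + d > duration) d = duration - t;
    states.push_back(s);
    dwells.push_back(d);
    t += d;
    if (t >= duration) break;
    // draw successor from the cumulative row
    double v = unif_rand();
    int nxt = ns - 1;
    for (int j = 0; j < ns; ++j) {
      if (v <= cumprob(s, j)) { nxt = j; break; }
    }
    s = nxt;
  }
  return List::create(_["state"] = IntegerVector(states.begin(), states.end()),
                      _["duration"] = NumericVector(dwells.begin(), dwells.end()));
}

// Point-sample a piecewise-constant amplitude path at sample midpoints
// t_k = (k - 0.5)/f_s, k = 1..n_samples. `ends` is the cumulative end time of
// each event; `amp` its amplitude. Samples beyond the last event hold the
// final amplitude.
// [[Rcpp::export]]
NumericVector point_sample_cpp(NumericVector ends, NumericVector amp,
                               int n_samples, double fs) {
  const int ne = ends.size();
  NumericVector out(n_samples);
  int j = 0;
  for (int k = 0; k < n_samples; ++k) {
    double t = (k + 0.5) / fs;
    while (j < ne - 1 && t >= ends[j]) ++j;
    out[k] = amp[j];
  }
  return out;
}

// Dead-time censoring of an alternating event list. Repeatedly removes the
// shortest event with duration < td, absorbing its duration into the merge of
// its two flanking (same-class) neighbours; at a record edge the duration is
// absorbed into the single neighbour. Shortest-first order makes the result
// deterministic and idempotent. cls is any integer class code; durations in s.
// [[Rcpp::export]]
List dead_time_censor_cpp(IntegerVector cls, NumericVector dur, double td) {
  const int n = cls.size();
  if (n == 0)
    return List::create(_["class"] = IntegerVector(0), _["duration"] = NumericVector(0));
  std::vector<double> d(dur.begin(), dur.end());
  std::vector<int> c(cls.begin(), cls.end());
  std::vector<int> prev(n), next(n);
  std::vector<bool> alive(n, true);
  for (int i = 0; i < n; ++i) { prev[i] = i - 1; next[i] = (i == n - 1) ? -1 : i + 1; }

  // ordered set of (duration, id) for deterministic shortest-first retrieval
  std::set<std::pair<double,int> > q;
  for (int i = 0; i < n; ++i)
    if (d[i] < td) q.insert(std::make_pair(d[i], i));

  int n_alive = n;
  while (!q.empty() && n_alive > 1) {
    std::pair<double,int> top = *q.begin();
    q.erase(q.begin());
    int i = top.second;
    if (!alive[i] || d[i] != top.first) continue; // stale entry
    int a = prev[i], b = next[i];
    alive[i] = false; --n_alive;
    if (a >= 0 && b >= 0) {
      // merge a and b (same class, alternation) absorbing i's duration
      if (d[a] < td) q.erase(std::make_pair(d[a], a));
      if (d[b] < td) q.erase(std::make_pair(d[b], b));
      d[a] += d[i] + d[b];
      alive[b] = false; --n_alive;
      next[a] = next[b];
      if (next[b] >= 0) prev[next[b]] = a;
      if (d[a] < td) q.insert(std::make_pair(d[a], a));
    } else if (a >= 0) {
      if (d[a] < td) q.erase(std::make_pair(d[a], a));
      d[a] += d[i];
      next[a] = -1;
      if (d[a] < td) q.insert(std::make_pair(d[a], a));
    } else if (b >= 0) {
      if (d[b] < td) q.erase(std::make_pair(d[b], b));
      d[b] += d[i];
      prev[b] = -1;
      if (d[b] < td) q.insert(std::make_pair(d[b], b));
    }
  }

  std::vector<int> oc; std::vector<double> od;
  oc.reserve(n_alive); od.reserve(n_alive);
  int head = -1;
  for (int i = 0; i < n; ++i) if (alive[i] && prev[i] < 0) { head = i; break; }
  // prev pointers of the head may still reference dead nodes; walk from first alive
  if (head < 0) for (int i = 0; i < n; ++i) if (alive[i]) { head = i; break; }
  for (int i = head; i >= 0; i = next[i]) {
    if (!alive[i]) continue;
    oc.push_back(c[i]);
    od.push_back(d[i]);
  }
  return List::create(_["class"] = IntegerVector(oc.begin(), oc.end()),
                      _["duration"] = NumericVector(od.begin(), od.end()));
}

// Bin samples into uniform bins defined by (lo, width, nbins); samples outside
// [lo, lo + nbins*width) are dropped. Returns integer counts.
// [[Rcpp::export]]
IntegerVector bin_counts_cpp(NumericVector x, double lo, double width, int nbins) {
  IntegerVector out(nbins);
  const int n = x.size();
  for (int i = 0; i < n; ++i) {
    double z = (x[i] - lo) / width;
    if (z < 0) continue;
    int b = (int)z;
    if (b >= nbins) continue;
    out[b] += 1;
  }
  return out;
}
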