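#include <Rcpp.h>
#include "model_rates.h"
using namespace Rcpp;

// Exact stochastic simulation of a continuous-time Markov chain with a
// fixed generator.  Sojourns are exponential with the state's exit rate;
// the successor state is drawn proportionally to the off-diagonal rates.
// Uses R's RNG so set.seed() gives byte-identical trajectories.
//
// Q: n x n generator (time unit defines the sojourn unit), p0: start
// distribution, duration: total simulated time (last sojourn truncated).
// [[Rcpp::export]]
List cpp_sim_ctmc(NumericMatrix Q, NumericVector p0, double duration) {
  const int n = Q.nrow();
  if (Q.ncol() != n || p0.size() != n)
    stop("dimension mismatch between Q and p0");
  if (duration < 0) stop("duration must be nonnegative");

  std::vector<int> states;
  std::vector<double> sojourn;
  states.reserve(1024);
  sojourn.reserve(1024);

  // draw the initial state
  double u = unif_rand(), acc = 0.0;
  int s = n - 1;
  for (int i = 0; i < n; ++i) {
    acc += p0[i];
    if (u <= acc) { s = i; break; }
  }

  double t = 0.0;
  while (t < duration) {
    const double exit = -Q(s, s);
    double dt;
    if (exit <= 0.0) {
      dt = duration - t;  // absorbing: sit out the rest of the record
    } else {
      dt = exp_rand() / exit;
      if (t + dt > duration) dt = duration - t;
    }
    states.push_back(s + 1);
    sojourn.push_back(dt);
    t += dt;
    if (t >= duration) break;

    double v = unif_rand() * exit, a2 = 0.0;
    int nxt = -1;
    for (int jx = 0; jx < n; ++jx) {
      if (jx == s) continue;
      a2 += Q(s, jx);
      if (v <= a2) { nxt = jx; break; }
    }
    if (nxt < 0) {  // rounding guard: take the largest-rate neighbour
      double best = -1.0;
      for (int jx = 0; jx < n; ++jx)
        if (jx != s && Q(s, jx) > best) { best = Q(s, jx); nxt = jx; }
    }
    s = nxt;
  }

  return List::create(_["state"] = wrap(states),
                      _["sojourn"] = wrap(sojourn));
}

// Generator assembly in C++ (same construction as build_generator() in R;
// cross-checked against it in the test suite).  K in canonical state
// order, j in flux_params() order.
// [[Rcpp::export]]
NumericMatrix cpp_build_Q(NumericVector K, NumericVector j,
                          double ca, double ip3) {
  if (K.size() != 12 || j.size() != 18) stop("K must have 12 and j 18 entries");
  NumericMatrix Q(12, 12);
  std::vector<double> buf(144);
  ip3r::build_generator(K.begin(), j.begin(), ca, ip3, buf.data());
  for (int a = 0; a < 12; ++a)
    for (int b = 0; b < 12; ++b)
      Q(a, b) = buf[12 * a + b];
  return Q;
}
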