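#include <Rcpp.h>
using namespace Rcpp;

// Asynchronous Markov-chain simulation of a compiled Boolean network.
//
// Semantics: at each step one of the n nodes is chosen uniformly at random
// (probability 1/n, clamped and stable nodes included) and updated.
// Termination is detected by an incrementally maintained fixed-point test,
// never by "no change this step", so null steps cannot end a run early.
// Uses R's RNG stream, so results are reproducible under set.seed().

// [[Rcpp::export]]
List cpp_simulate_runs(List regulators, List truth_tables,
                       LogicalVector clamped, IntegerVector clamp_values,
                       IntegerMatrix init, double max_steps) {
  const int n = clamped.size();
  const int runs = init.nrow();
  if (init.ncol() != n) stop("init width does not match node count");

  // flatten regulators / truth tables
  std::vector<std::vector<int>> regs(n);
  std::vector<std::vector<int>> tts(n);
  std::vector<std::vector<int>> dependents(n);
  for (int i = 0; i < n; ++i) {
    if (clamped[i]) continue;
    IntegerVector r = regulators[i];
    IntegerVector t = truth_tables[i];
    regs[i].assign(r.begin(), r.end());          // 0-based
    tts[i].assign(t.begin(), t.end());
    for (int j : regs[i]) dependents[j].push_back(i);
  }

  IntegerMatrix terminal(runs, n);
  LogicalVector converged(runs);
  NumericVector steps_taken(runs);

  std::vector<int> state(n), nxt(n);
  std::vector<char> unstable(n);

  RNGScope scope;
  for (int run = 0; run < runs; ++run) {
    int n_unstable = 0;
    for (int i = 0; i < n; ++i)
      state[i] = clamped[i] ? clamp_values[i] : init(run, i);
    auto feval = [&](int i) {
      int idx = 0;
      for (size_t j = 0; j < regs[i].size(); ++j)
        idx |= state[regs[i][j]] << j;
      return tts[i][idx];
    };
    for (int i = 0; i < n; ++i) {
      if (clamped[i]) { nxt[i] = state[i]; unstable[i] = 0; continue; }
      nxt[i] = feval(i);
      unstable[i] = (nxt[i] != state[i]);
      n_unstable += unstable[i];
    }
    double step = 0;
    while (n_unstable > 0 && step < max_steps) {
      step += 1;
      int u = (int)(unif_rand() * n);
      if (u >= n) u = n - 1;
      if (clamped[u] || !unstable[u]) continue;   // null step
      state[u] = nxt[u];
      // u and every node reading u may change stability
      n_unstable -= 1;
      unstable[u] = 0;
      if (!clamped[u]) {
        int v = feval(u);
        if (v != state[u]) { nxt[u] = v; unstable[u] = 1; n_unstable += 1; }
        else nxt[u] = v;
      }
      for (int d : dependents[u]) {
        if (d == u) continue;
        int v = feval(d);
        if (v != nxt[d]) {
          nxt[d] = v;
          char was = unstable[d];
          unstable[d] = (v != state[d]);
          n_unstable += unstable[d] - was;
        }
      }
    }
    for (int i = 0; i < n; ++i) terminal(run, i) = state[i];
    converged[run] = (n_unstable == 0);
    steps_taken[run] = step;
  }
  return List::create(_["terminal"] = terminal,
                      _["converged"] = converged,
                      _["steps"] = steps_taken);
}
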