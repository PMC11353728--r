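#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time SIR with recovery probability 1: newly infected nodes are
// infectious for exactly one step, then recover. Each infectious node
// independently infects each susceptible neighbour with probability beta.
// Uses R's RNG so runs are reproducible under set.seed().

static int sir_once(const std::vector< std::vector<int> > &adj,
                    const std::vector<int> &sources,
                    double beta,
                    std::vector<int> &status,
                    std::vector<int> &frontier,
                    std::vector<int> &next_frontier) {
  const int n = (int) adj.size();
  std::fill(status.begin(), status.end(), 0); // 0=S, 1=I, 2=R
  frontier.clear();
  for (int s : sources) { status[s] = 1; frontier.push_back(s); }
  int recovered = 0;
  while (!frontier.empty()) {
    next_frontier.clear();
    for (int v : frontier) {
      const std::vector<int> &nb = adj[v];
      for (int u : nb) {
        if (status[u] == 0 && unif_rand() < beta) {
          status[u] = 1;
          next_frontier.push_back(u);
        }
      }
      status[v] = 2;
      ++recovered;
    }
    frontier.swap(next_frontier);
  }
  (void) n;
  return recovered;
}

static std::vector< std::vector<int> > build_adj(const List &adj0) {
  int n = adj0.size();
  std::vector< std::vector<int> > adj(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector nb = adj0[i];
    adj[i].assign(nb.begin(), nb.end());
  }
  return adj;
}

// Mean outbreak size (recovered count, seed included) per source node.
// [[Rcpp::export]]
NumericVector sir_label_engine(List adj0, double beta, int reps) {
  std::vector< std::vector<int> > adj = build_adj(adj0);
  const int n = (int) adj.size();
  std::vector<int> status(n), frontier, next_frontier;
  frontier.reserve(n); next_frontier.reserve(n);
  NumericVector out(n);
  std::vector<int> src(1);
  for (int v = 0; v < n; ++v) {
    src[0] = v;
    double acc = 0.0;
    for (int r = 0; r < reps; ++r) {
      acc += sir_once(adj, src, beta, status, frontier, next_frontier);
    }
    out[v] = acc / reps;
  }
  return out;
}

// Final recovered counts of `reps` independent epidemics seeded at `sources`
// (0-based), all sources initially infected.
// [[Rcpp::export]]
NumericVector sir_spread_engine(List adj0, IntegerVector sources, double beta,
                                int reps) {
  std::vector< std::vector<int> > adj = build_adj(adj0);
  const int n = (int) adj.size();
  std::vector<int> status(n), frontier, next_frontier;
  frontier.reserve(n); next_frontier.reserve(n);
  std::vector<int> src(sources.begin(), sources.end());
  NumericVector out(reps);
  for (int r = 0; r < reps; ++r) {
    out[r] = sir_once(adj, src, beta, status, frontier, next_frontier);
  }
  return out;
}
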