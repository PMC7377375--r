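// Sliding-window graph measures.
//
// Window graphs are tiny (<= window_length nodes, <= window_length - 1
// directed edges before deduplication), but null-model runs visit millions
// of windows (reports x shuffles x windows), so the per-window work is done
// here with stamped, reusable buffers: union-find for weakly connected
// components and Tarjan's algorithm for strongly connected components.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

namespace {

class WindowEngine {
public:
  WindowEngine(int n_tokens, int window, int step, int vocab)
    : n(n_tokens), w(window), step(step),
      stamp(vocab + 1, -1), local(vocab + 1, 0),
      estamp(window * window, -1),
      parent(window), comp_size(window),
      head(window), nxt(window), adj(window),
      order(window), lowlink(window), onstack(window, false),
      wid(0) {
    efrom.reserve(window);
    eto.reserve(window);
    stk.reserve(window);
  }

  int n_windows() const { return (n - w) / step + 1; }

  // Measures for the window starting at 0-based position s.
  // no_edge[i] (0-based, length n-1): no transition between i and i+1.
  void window_measures(const int* tok, const unsigned char* no_edge, int s,
                       int& edges, int& lcc, int& lsc) {
    ++wid;
    int nloc = 0;
    for (int i = s; i < s + w; ++i) {
      const int v = tok[i];
      if (stamp[v] != wid) { stamp[v] = wid; local[v] = nloc++; }
    }
    efrom.clear();
    eto.clear();
    for (int i = s; i < s + w - 1; ++i) {
      if (no_edge[i]) continue;
      const int a = local[tok[i]], b = local[tok[i + 1]];
      const int key = a * w + b;
      if (estamp[key] != wid) {
        estamp[key] = wid;
        efrom.push_back(a);
        eto.push_back(b);
      }
    }
    edges = static_cast<int>(efrom.size());
    lcc = weak_lcc(nloc);
    lsc = strong_lsc(nloc);
  }

  // Mean measures across all windows of the current token array.
  void windowed_means(const int* tok, const unsigned char* no_edge,
                      double& mean_edges, double& mean_lcc, double& mean_lsc,
                      double* per_window = nullptr) {
    const int nw = n_windows();
    long double se = 0, sl = 0, ss = 0;
    int e, l, s2;
    for (int k = 0; k < nw; ++k) {
      window_measures(tok, no_edge, k * step, e, l, s2);
      se += e; sl += l; ss += s2;
      if (per_window) {
        per_window[k] = e;
        per_window[nw + k] = l;
        per_window[2 * nw + k] = s2;
      }
    }
    mean_edges = static_cast<double>(se / nw);
    mean_lcc = static_cast<double>(sl / nw);
    mean_lsc = static_cast<double>(ss / nw);
  }

private:
  int n, w, step;
  std::vector<int> stamp, local, estamp;
  std::vector<int> efrom, eto;
  std::vector<int> parent, comp_size;
  std::vector<int> head, nxt, adj;
  std::vector<int> order, lowlink, stk;
  std::vector<bool> onstack;
  int wid;
  int idx_counter, best_scc;

  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }

  int weak_lcc(int nloc) {
    for (int i = 0; i < nloc; ++i) parent[i] = i;
    for (size_t e = 0; e < efrom.size(); ++e) {
      const int ra = find(efrom[e]), rb = find(eto[e]);
      if (ra != rb) parent[ra] = rb;
    }
    for (int i = 0; i < nloc; ++i) comp_size[i] = 0;
    int best = 1;
    for (int i = 0; i < nloc; ++i) {
      const int r = find(i);
      if (++comp_size[r] > best) best = comp_size[r];
    }
    return best;
  }

  int strong_lsc(int nloc) {
    for (int v = 0; v < nloc; ++v) head[v] = -1;
    for (size_t e = 0; e < efrom.size(); ++e) {
      nxt[e] = head[efrom[e]];
      head[efrom[e]] = static_cast<int>(e);
      adj[e] = eto[e];
    }
    for (int v = 0; v < nloc; ++v) { order[v] = -1; onstack[v] = false; }
    stk.clear();
    idx_counter = 0;
    best_scc = 1;
    for (int v = 0; v < nloc; ++v) {
      if (order[v] == -1) strongconnect(v);
    }
    return best_scc;
  }

  void strongconnect(int v) {  // recursion depth bounded by window length
    order[v] = lowlink[v] = idx_counter++;
    stk.push_back(v);
    onstack[v] = true;
    for (int e = head[v]; e != -1; e = nxt[e]) {
      const int u = adj[e];
      if (order[u] == -1) {
        strongconnect(u);
        if (lowlink[u] < lowlink[v]) lowlink[v] = lowlink[u];
      } else if (onstack[u] && order[u] < lowlink[v]) {
        lowlink[v] = order[u];
      }
    }
    if (lowlink[v] == order[v]) {
      int sz = 0, u;
      do {
        u = stk.back();
        stk.pop_back();
        onstack[u] = false;
        ++sz;
      } while (u != v);
      if (sz > best_scc) best_scc = sz;
    }
  }
};

std::vector<unsigned char> break_flags(int n, const IntegerVector& breaks) {
  std::vector<unsigned char> no_edge(n > 1 ? n - 1 : 0, 0);
  for (int i = 0; i < breaks.size(); ++i) {
    const int b = breaks[i];  // 1-based: no transition between b and b+1
    if (b < 1 || b >= n) stop("break position out of range");
    no_edge[b - 1] = 1;
  }
  return no_edge;
}

int vocab_size(const IntegerVector& tokens) {
  int v = 0;
  for (int i = 0; i < tokens.size(); ++i) {
    if (tokens[i] < 1) stop("token codes must be positive integers");
    if (tokens[i] > v) v = tokens[i];
  }
  return v;
}

}  // namespace

// [[Rcpp::export]]
List cpp_windowed_measures(IntegerVector tokens, IntegerVector breaks,
                           int window, int step, bool per_window = false) {
  const int n = tokens.size();
  if (window < 2) stop("window length must be at least 2");
  if (step < 1) stop("step must be at least 1");
  if (n < window) stop("report has fewer tokens than the window length");
  WindowEngine eng(n, window, step, vocab_size(tokens));
  const std::vector<unsigned char> no_edge = break_flags(n, breaks);
  const int nw = eng.n_windows();
  double me, ml, ms;
  if (per_window) {
    NumericMatrix pw(nw, 3);
    colnames(pw) = CharacterVector::create("edges", "lcc", "lsc");
    eng.windowed_means(&tokens[0], no_edge.data(), me, ml, ms, &pw[0]);
    return List::create(_["n_windows"] = nw, _["mean_edges"] = me,
                        _["mean_lcc"] = ml, _["mean_lsc"] = ms,
                        _["per_window"] = pw);
  }
  eng.windowed_means(&tokens[0], no_edge.data(), me, ml, ms);
  return List::create(_["n_windows"] = nw, _["mean_edges"] = me,
                      _["mean_lcc"] = ml, _["mean_lsc"] = ms);
}

// Windowed mean measures for n_shuffles uniform permutations of the token
// sequence (break positions held fixed).  Uses R's RNG, so results are
// reproducible under set.seed().  Successive in-place Fisher-Yates passes
// yield i.i.d. uniform permutations.
// [[Rcpp::export]]
NumericMatrix cpp_null_windowed(IntegerVector tokens, IntegerVector breaks,
                                int window, int step, int n_shuffles) {
  const int n = tokens.size();
  if (n < window) stop("report has fewer tokens than the window length");
  if (n_shuffles < 1) stop("n_shuffles must be at least 1");
  WindowEngine eng(n, window, step, vocab_size(tokens));
  const std::vector<unsigned char> no_edge = break_flags(n, breaks);
  std::vector<int> tok(tokens.begin(), tokens.end());
  NumericMatrix out(n_shuffles, 3);
  colnames(out) = CharacterVector::create("mean_edges", "mean_lcc", "mean_lsc");
  for (int s = 0; s < n_shuffles; ++s) {
    for (int i = n - 1; i > 0; --i) {
      const int j = static_cast<int>(unif_rand() * (i + 1));
      std::swap(tok[i], tok[j]);
    }
    double me, ml, ms;
    eng.windowed_means(tok.data(), no_edge.data(), me, ml, ms);
    out(s, 0) = me;
    out(s, 1) = ml;
    out(s, 2) = ms;
  }
  return out;
}
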