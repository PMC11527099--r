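// Aho-Corasick multi-pattern automaton over the DNA alphabet.
// Alphabet: A,C,G,T map to 0..3; every other character (N, ambiguity
// codes) maps to symbol 4, which occurs in no pattern and therefore
// breaks any match through the failure function.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>

using namespace Rcpp;

static inline int sym(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;
  }
}

// [[Rcpp::export(name = ".acSearch")]]
DataFrame acSearch(std::string text, std::vector<std::string> patterns) {
  const int SIGMA = 5;
  // trie with goto function
  std::vector<std::array<int, SIGMA>> go;
  std::vector<int> fail;
  std::vector<std::vector<int>> out;  // pattern indices ending at node
  go.push_back({-1, -1, -1, -1, -1});
  out.emplace_back();

  for (int p = 0; p < (int)patterns.size(); ++p) {
    int node = 0;
    for (char c : patterns[p]) {
      int s = sym(c);
      if (s == 4) stop("pattern contains a character outside {A,C,G,T}");
      if (go[node][s] == -1) {
        go[node][s] = (int)go.size();
        go.push_back({-1, -1, -1, -1, -1});
        out.emplace_back();
      }
      node = go[node][s];
    }
    out[node].push_back(p);
  }

  // BFS: failure links, convert goto to full transition function, and
  // merge output sets along suffix links
  fail.assign(go.size(), 0);
  std::queue<int> q;
  for (int s = 0; s < SIGMA; ++s) {
    if (go[0][s] == -1) go[0][s] = 0;
    else { fail[go[0][s]] = 0; q.push(go[0][s]); }
  }
  while (!q.empty()) {
    int u = q.front(); q.pop();
    for (int idx : out[fail[u]]) out[u].push_back(idx);
    for (int s = 0; s < SIGMA; ++s) {
      int v = go[u][s];
      if (v == -1) go[u][s] = go[fail[u]][s];
      else { fail[v] = go[fail[u]][s]; q.push(v); }
    }
  }

  std::vector<int> starts, pidx;
  int node = 0;
  for (int i = 0; i < (int)text.size(); ++i) {
    node = go[node][sym(text[i])];
    for (int p : out[node]) {
      starts.push_back(i - (int)patterns[p].size() + 1);  // 0-based
      pidx.push_back(p + 1);                              // 1-based for R
    }
  }
  return DataFrame::create(Named("start") = starts,
                           Named("pattern") = pidx);
}
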