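// Aho-Corasick multi-keyword automaton over the DNA alphabet.
//
// The automaton is the core of the tag-based annotator: all V/J tag
// keywords are compiled once into a goto/fail trie, and every read is
// scanned in a single left-to-right pass reporting every occurrence of
// every keyword (including overlapping ones). Search time is linear in
// the target length plus the number of matches.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <string>
#include <unordered_set>

using namespace Rcpp;

static const int AC_ALPHA = 4;

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

struct ACTrie {
  // nodes[i][b] = child of node i on base b (-1 if absent before fail links)
  std::vector<std::array<int, AC_ALPHA>> go;
  std::vector<int> fail;
  std::vector<std::vector<int>> out;   // keyword ids (0-based) ending at node
  std::vector<int> kw_len;             // keyword lengths, by id
  int n_keywords = 0;

  int new_node() {
    go.push_back({-1, -1, -1, -1});
    fail.push_back(0);
    out.emplace_back();
    return (int)go.size() - 1;
  }
};

// [[Rcpp::export(name = ".ac_build")]]
SEXP ac_build(CharacterVector keywords) {
  ACTrie* trie = new ACTrie();
  trie->new_node(); // root
  std::unordered_set<std::string> seen;
  trie->n_keywords = keywords.size();

  for (int k = 0; k < keywords.size(); ++k) {
    std::string kw = as<std::string>(keywords[k]);
    if (kw.empty()) {
      delete trie;
      stop("keyword %d is empty", k + 1);
    }
    if (!seen.insert(kw).second) {
      delete trie;
      stop("duplicate keyword: %s", kw.c_str());
    }
    int node = 0;
    for (char c : kw) {
      int b = base_code(c);
      if (b < 0) {
        delete trie;
        stop("keyword %d contains a non-ACGT character", k + 1);
      }
      if (trie->go[node][b] < 0) trie->go[node][b] = trie->new_node();
      node = trie->go[node][b];
    }
    trie->out[node].push_back(k);
    trie->kw_len.push_back((int)kw.size());
  }

  // BFS to set failure links and convert to a full goto function.
  std::queue<int> q;
  for (int b = 0; b < AC_ALPHA; ++b) {
    int v = trie->go[0][b];
    if (v < 0) {
      trie->go[0][b] = 0;
    } else {
      trie->fail[v] = 0;
      q.push(v);
    }
  }
  while (!q.empty()) {
    int u = q.front(); q.pop();
    // merge output of fail state (suffix matches)
    const std::vector<int>& fo = trie->out[trie->fail[u]];
    trie->out[u].insert(trie->out[u].end(), fo.begin(), fo.end());
    for (int b = 0; b < AC_ALPHA; ++b) {
      int v = trie->go[u][b];
      if (v < 0) {
        trie->go[u][b] = trie->go[trie->fail[u]][b];
      } else {
        trie->fail[v] = trie->go[trie->fail[u]][b];
        q.push(v);
      }
    }
  }

  XPtr<ACTrie> ptr(trie, true);
  ptr.attr("class") = "ac_trie_ptr";
  return ptr;
}

// Scan targets; report each hit as (target index, keyword id, start),
// all 1-based. Non-ACGT characters reset the automaton to the root.
// [[Rcpp::export(name = ".ac_search")]]
DataFrame ac_search(SEXP trie_ptr, CharacterVector targets) {
  XPtr<ACTrie> trie(trie_ptr);
  std::vector<int> t_idx, kw_id, start;

  for (int i = 0; i < targets.size(); ++i) {
    if (targets[i] == NA_STRING) continue;
    const char* s = CHAR(STRING_ELT(targets, i));
    int node = 0;
    for (int pos = 0; s[pos] != '\0'; ++pos) {
      int b = base_code(s[pos]);
      if (b < 0) { node = 0; continue; }
      node = trie->go[node][b];
      for (int k : trie->out[node]) {
        t_idx.push_back(i + 1);
        kw_id.push_back(k + 1);
        start.push_back(pos + 2 - trie->kw_len[k]); // 1-based start
      }
    }
  }
  return DataFrame::create(_["target"] = t_idx,
                           _["keyword"] = kw_id,
                           _["start"] = start);
}

// [[Rcpp::export(name = ".ac_n_keywords")]]
int ac_n_keywords(SEXP trie_ptr) {
  XPtr<ACTrie> trie(trie_ptr);
  return trie->n_keywords;
}
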