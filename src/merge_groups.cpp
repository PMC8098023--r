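// Iterative pairwise merging of barcode groups (the UMI error-correction
// clustering step). Groups arrive sorted in the deterministic processing
// order (descending read count, then barcode); each sweep walks ordered
// pairs (i, j), i < j, and merges j into i when the barcode Levenshtein
// distance is within th_bc AND the percentage Levenshtein distance of the
// groups' dominant TCR sequences is within th_tcr. Sweeps repeat until a
// fixed point (or the sweep cap).
//
// Pair enumeration uses a pigeonhole (PEX) filter when all barcodes share
// one length: a pair within distance k must share one of k+1 barcode
// pieces exactly, up to a +/-k positional shift, so only bucket-mates are
// compared. This is a filter only - every candidate is verified with an
// exact banded edit-distance computation - so the result is identical to
// the all-pairs scan, which is used as fallback for mixed-length input.

#include <Rcpp.h>
#include <vector>
#include <string>
#include <unordered_map>
#include <algorithm>

using namespace Rcpp;

int lev_bounded(const char* a, int la, const char* b, int lb, int k);

// [[Rcpp::export(name = ".merge_groups_cpp")]]
List merge_groups_cpp(CharacterVector barcodes,
                      IntegerVector tab_group, IntegerVector tab_tcr,
                      IntegerVector tab_count,
                      CharacterVector tcr_strings, IntegerVector tcr_rank,
                      int th_bc, double th_tcr, int max_sweeps) {
  int n = barcodes.size();
  int n_tcr = tcr_strings.size();

  std::vector<std::string> bc(n);
  bool same_len = true;
  for (int i = 0; i < n; ++i) {
    bc[i] = as<std::string>(barcodes[i]);
    if (bc[i].size() != bc[0].size()) same_len = false;
  }
  std::vector<int> tlen(n_tcr);
  std::vector<const char*> tstr(n_tcr);
  for (int t = 0; t < n_tcr; ++t) {
    tstr[t] = CHAR(STRING_ELT(tcr_strings, t));
    tlen[t] = (int)strlen(tstr[t]);
  }

  // per-group TCR frequency tables
  std::vector<std::unordered_map<int, double>> counts(n);
  for (int r = 0; r < tab_group.size(); ++r)
    counts[tab_group[r] - 1][tab_tcr[r] - 1] += tab_count[r];

  std::vector<int> top(n, -1);
  auto recompute_top = [&](int g) {
    double best = -1; int best_id = -1;
    for (auto& kv : counts[g]) {
      if (kv.second > best ||
          (kv.second == best && tcr_rank[kv.first] < tcr_rank[best_id])) {
        best = kv.second; best_id = kv.first;
      }
    }
    top[g] = best_id;
  };
  for (int g = 0; g < n; ++g) recompute_top(g);

  // ---- candidate adjacency (j > i) ----
  std::vector<std::vector<int>> adj(n);
  int k = th_bc;
  int L = n ? (int)bc[0].size() : 0;
  bool use_pex = same_len && k > 0 && L >= (k + 1);
  if (k > 0 && n > 1) {
    if (use_pex) {
      int nparts = k + 1;
      std::unordered_map<std::string, std::vector<int>> buckets;
      std::vector<int> off(nparts + 1);
      for (int p = 0; p <= nparts; ++p) off[p] = (int)((long long)p * L / nparts);
      for (int j = 0; j < n; ++j)
        for (int p = 0; p < nparts; ++p) {
          std::string key = std::to_string(p) + ":" +
            bc[j].substr(off[p], off[p + 1] - off[p]);
          buckets[key].push_back(j);
        }
      std::vector<int> cand;
      for (int i = 0; i < n; ++i) {
        cand.clear();
        for (int p = 0; p < nparts; ++p) {
          int plen = off[p + 1] - off[p];
          for (int d = -k; d <= k; ++d) {
            int s = off[p] + d;
            if (s < 0 || s + plen > L) continue;
            auto it = buckets.find(std::to_string(p) + ":" + bc[i].substr(s, plen));
            if (it == buckets.end()) continue;
            for (int j : it->second) if (j > i) cand.push_back(j);
          }
        }
        std::sort(cand.begin(), cand.end());
        cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
        adj[i] = cand;
      }
    } else {
      for (int i = 0; i < n; ++i) {
        adj[i].resize(n - i - 1);
        for (int j = i + 1; j < n; ++j) adj[i][j - i - 1] = j;
      }
    }
  }

  std::vector<int> parent(n);
  for (int i = 0; i < n; ++i) parent[i] = i;

  int sweeps = 0;
  bool converged = false;
  while (sweeps < max_sweeps) {
    ++sweeps;
    bool merged_any = false;
    for (int i = 0; i < n; ++i) {
      if (parent[i] != i) continue;
      for (int j : adj[i]) {
        if (parent[j] != j) continue;
        int d = lev_bounded(bc[i].c_str(), (int)bc[i].size(),
                            bc[j].c_str(), (int)bc[j].size(), k);
        if (d > k) continue;
        int ti = top[i], tj = top[j];
        int maxlen = std::max(tlen[ti], tlen[tj]);
        int kk = (int)std::floor(th_tcr * maxlen / 100.0 + 1e-9);
        if (lev_bounded(tstr[ti], tlen[ti], tstr[tj], tlen[tj], kk) > kk)
          continue;
        // merge j into i (i is earlier in the deterministic order)
        for (auto& kv : counts[j]) counts[i][kv.first] += kv.second;
        counts[j].clear();
        parent[j] = i;
        recompute_top(i);
        merged_any = true;
      }
    }
    if (!merged_any) { converged = true; break; }
  }

  IntegerVector parent_out(n), top_out(n);
  for (int i = 0; i < n; ++i) {
    parent_out[i] = parent[i] + 1;
    top_out[i] = (parent[i] == i) ? top[i] + 1 : NA_INTEGER;
  }
  return List::create(_["parent"] = parent_out, _["top"] = top_out,
                      _["sweeps"] = sweeps, _["converged"] = converged);
}
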