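// Connected maximum common induced subgraph search (branch and bound).
// Atoms are compatible when their labels match (element + ring/acyclic
// class, built on the R side); bonds must match in order class (single/
// double/triple/aromatic). The search adds one atom pair at a time, always
// adjacent to the already-mapped core, with a McSplit-style exclusion
// branch, a reachability upper bound, and a wall-clock deadline that
// returns the best mapping found so far.

#include <Rcpp.h>
#include <chrono>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct McsState {
  int nA, nB;
  std::vector<int> labA, labB;
  std::vector<std::vector<int>> bA, bB;   // bond class matrices, 0 = no bond
  std::vector<std::vector<int>> adjA;     // adjacency lists for A
  std::vector<int> mapA, mapB;            // partial mapping, -1 = unmapped
  std::vector<char> excl;                 // A atoms excluded on this path
  std::vector<int> order;                 // mapped A atoms in insertion order
  std::vector<int> bestA, bestB;
  int best = 0;
  int ceiling = 0;                        // min(nA, nB): global optimum
  bool timed_out = false;
  bool done = false;
  long iter = 0;
  std::chrono::steady_clock::time_point deadline;

  bool time_up() {
    if (timed_out) return true;
    if (++iter % 4096 == 0 &&
        std::chrono::steady_clock::now() > deadline) {
      timed_out = true;
    }
    return timed_out;
  }

  // induced-subgraph consistency of adding (a, b) to the current mapping
  bool consistent(int a, int b) const {
    for (int a2 : order) {
      if (bA[a][a2] != bB[b][mapA[a2]]) return false;
    }
    return true;
  }

  // count A atoms reachable from the mapped core through unmapped,
  // non-excluded atoms (upper bound on how much the core can still grow)
  int reachable() const {
    std::vector<char> seen(nA, 0);
    std::vector<int> queue;
    for (int a : order) {
      for (int u : adjA[a]) {
        if (mapA[u] < 0 && !excl[u] && !seen[u]) {
          seen[u] = 1;
          queue.push_back(u);
        }
      }
    }
    int count = 0;
    while (!queue.empty()) {
      int v = queue.back();
      queue.pop_back();
      ++count;
      for (int u : adjA[v]) {
        if (mapA[u] < 0 && !excl[u] && !seen[u]) {
          seen[u] = 1;
          queue.push_back(u);
        }
      }
    }
    return count;
  }

  void record_if_best() {
    int size = static_cast<int>(order.size());
    if (size > best) {
      best = size;
      bestA = order;
      bestB.clear();
      for (int a : order) bestB.push_back(mapA[a]);
      if (best == ceiling) done = true;
    }
  }

  void search() {
    if (done || time_up()) return;
    record_if_best();
    if (done) return;

    int size = static_cast<int>(order.size());
    std::vector<int> cand;
    if (size == 0) {
      for (int a = 0; a < nA; ++a) {
        if (!excl[a]) cand.push_back(a);
      }
    } else {
      int room = std::min(reachable(), nB - size);
      if (size + room <= best) return;
      std::vector<char> seen(nA, 0);
      for (int a : order) {
        for (int u : adjA[a]) {
          if (mapA[u] < 0 && !excl[u] && !seen[u]) {
            seen[u] = 1;
            cand.push_back(u);
          }
        }
      }
      std::sort(cand.begin(), cand.end());
    }
    if (cand.empty()) return;

    // branch on the candidate atom with fewest compatible partners
    int pick = -1;
    std::vector<int> pick_bs;
    for (int a : cand) {
      std::vector<int> bs;
      for (int b = 0; b < nB; ++b) {
        if (mapB[b] < 0 && labA[a] == labB[b] && consistent(a, b)) {
          bs.push_back(b);
        }
      }
      if (pick < 0 || bs.size() < pick_bs.size()) {
        pick = a;
        pick_bs = bs;
        if (pick_bs.empty()) break;
      }
    }

    for (int b : pick_bs) {
      mapA[pick] = b;
      mapB[b] = pick;
      order.push_back(pick);
      search();
      order.pop_back();
      mapA[pick] = -1;
      mapB[b] = -1;
      if (done || timed_out) return;
    }
    // exclusion branch: best mapping never containing `pick`
    excl[pick] = 1;
    search();
    excl[pick] = 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".mcs_search_cpp")]]
List mcs_search_cpp(IntegerVector labA, IntegerVector labB,
                    IntegerMatrix bondA, IntegerMatrix bondB,
                    double timeout_s) {
  McsState st;
  st.nA = labA.size();
  st.nB = labB.size();
  st.labA.assign(labA.begin(), labA.end());
  st.labB.assign(labB.begin(), labB.end());
  st.bA.assign(st.nA, std::vector<int>(st.nA, 0));
  st.bB.assign(st.nB, std::vector<int>(st.nB, 0));
  st.adjA.assign(st.nA, {});
  for (int i = 0; i < st.nA; ++i) {
    for (int j = 0; j < st.nA; ++j) {
      st.bA[i][j] = bondA(i, j);
      if (bondA(i, j) > 0 && i != j) st.adjA[i].push_back(j);
    }
  }
  for (int i = 0; i < st.nB; ++i) {
    for (int j = 0; j < st.nB; ++j) {
      st.bB[i][j] = bondB(i, j);
    }
  }
  st.mapA.assign(st.nA, -1);
  st.mapB.assign(st.nB, -1);
  st.excl.assign(st.nA, 0);
  st.ceiling = std::min(st.nA, st.nB);
  st.deadline = std::chrono::steady_clock::now() +
    std::chrono::microseconds(static_cast<long long>(timeout_s * 1e6));

  st.search();

  IntegerVector outA(st.best), outB(st.best);
  for (int k = 0; k < st.best; ++k) {
    outA[k] = st.bestA[k] + 1;   // 1-based for R
    outB[k] = st.bestB[k] + 1;
  }
  return List::create(_["map_a"] = outA, _["map_b"] = outB,
                      _["size"] = st.best, _["timed_out"] = st.timed_out);
}
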