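#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Dynamic-programming decomposition of a satellite array into template-sized
// blocks. State (i, j): the first i array bases are consumed and the current
// block has aligned the first j template bases. Transitions are the usual
// match/mismatch/indel moves; reaching j == L allows a free restart to j == 0,
// which closes a block. The array start/end get semi-global treatment (free
// template prefix at i == 0, best over all j at i == n), so terminal blocks may
// be partial. Ambiguous bases ('N') mismatch everything.
//
// Returns the 0-based block cut points (ascending, excluding 0 and n).

static inline int base_code(char a, bool is_template) {
  if (a >= 'a' && a <= 'z') a -= 32;
  switch (a) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return is_template ? 4 : 5;  // N/other never matches anything
  }
}

// [[Rcpp::export(name = ".decompose_cuts_cpp")]]
IntegerVector decompose_cuts_cpp(std::string seq, std::string tmpl,
                                 int match, int mismatch, int indel) {
  const int n = (int)seq.size();
  const int L = (int)tmpl.size();
  const int NEG = -1000000000;

  std::vector<int> sc(n), tc(L);
  for (int i = 0; i < n; ++i) sc[i] = base_code(seq[i], false);
  for (int j = 0; j < L; ++j) tc[j] = base_code(tmpl[j], true);

  std::vector<int> dp_prev(L + 1), dp_cur(L + 1);
  std::vector<int> st_prev(L + 1), st_cur(L + 1);
  std::vector<int> B(n + 1, 0);  // start of the block ending (complete) at i

  // free template prefix at the array start
  for (int j = 0; j <= L; ++j) { dp_prev[j] = 0; st_prev[j] = 0; }
  B[0] = 0;

  for (int i = 1; i <= n; ++i) {
    const int c = sc[i - 1];
    int *dpp = dp_prev.data(), *dpc = dp_cur.data();
    int *stp = st_prev.data(), *stc = st_cur.data();
    dpc[0] = std::max(dpp[0] + indel, NEG);
    stc[0] = stp[0];
    for (int j = 1; j <= L; ++j) {
      int best = dpp[j - 1] + (c == tc[j - 1] ? match : mismatch);
      int st = stp[j - 1];
      const int up = dpp[j] + indel;
      if (up > best) { best = up; st = stp[j]; }
      const int left = dpc[j - 1] + indel;
      if (left > best) { best = left; st = stc[j - 1]; }
      dpc[j] = best;
      stc[j] = st;
    }
    // record the best complete-block parse ending at i, then allow a restart
    B[i] = stc[L];
    if (dpc[L] > dpc[0]) {
      dpc[0] = dpc[L];
      stc[0] = i;
      for (int j = 1; j <= L; ++j) {  // deletions flowing from the restart
        const int cand = dpc[j - 1] + indel;
        if (cand > dpc[j]) { dpc[j] = cand; stc[j] = stc[j - 1]; }
        else break;  // once the old value wins, later cells are unaffected
      }
    }
    dp_prev.swap(dp_cur);
    st_prev.swap(st_cur);
  }

  // pick the end state: prefer a completed template on ties, then longer j
  int jbest = L;
  for (int j = L; j >= 0; --j)
    if (dp_prev[j] > dp_prev[jbest]) jbest = j;

  std::vector<int> cuts;
  int cur = st_prev[jbest];
  while (cur > 0 && cur <= n) {
    if (cur < n) cuts.push_back(cur);
    int nxt = B[cur];
    if (nxt >= cur) break;  // defensive: chains always decrease
    cur = nxt;
  }
  std::reverse(cuts.begin(), cuts.end());
  return wrap(cuts);
}
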