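#include <Rcpp.h>
#include <cstring>
#include <vector>
using namespace Rcpp;

// Myers bit-parallel algorithm (Hyyro's blocked formulation) for unit-cost
// Levenshtein distance. Pattern bits are laid out over ceil(m/64) words; the
// running score is tracked at the pattern's last row via the high bit of the
// final block.

typedef uint64_t word;

struct MyersPattern {
  int m;
  int w;                       // number of 64-bit blocks
  std::vector<word> peq;       // 256 * w, indexed peq[c * w + b]
  word last_mask;              // bit of row m-1 within the final block
  explicit MyersPattern(const char *p, int m_) : m(m_) {
    w = (m + 63) / 64;
    peq.assign(256 * (size_t)w, 0);
    for (int i = 0; i < m; ++i) {
      unsigned char c = (unsigned char)p[i];
      peq[(size_t)c * w + i / 64] |= ((word)1) << (i % 64);
    }
    last_mask = ((word)1) << ((m - 1) % 64);
  }
};

static int myers_distance(const MyersPattern &pat, const char *t, int n) {
  const int w = pat.w;
  std::vector<word> Pv(w, ~(word)0), Mv(w, 0);
  int score = pat.m;
  for (int j = 0; j < n; ++j) {
    const word *eq = &pat.peq[(size_t)(unsigned char)t[j] * w];
    int hin = 1;  // global-distance boundary: D[0][j] = j
    for (int b = 0; b < w; ++b) {
      word Eq = eq[b];
      word pv = Pv[b], mv = Mv[b];
      word Xv = Eq | mv;
      if (hin < 0) Eq |= (word)1;
      word Xh = (((Eq & pv) + pv) ^ pv) | Eq;
      word Ph = mv | ~(Xh | pv);
      word Mh = pv & Xh;
      word hbit = (b == w - 1) ? pat.last_mask : (((word)1) << 63);
      int hout = 0;
      if (Ph & hbit) hout = 1;
      else if (Mh & hbit) hout = -1;
      Ph <<= 1;
      Mh <<= 1;
      if (hin < 0) Mh |= (word)1;
      else if (hin > 0) Ph |= (word)1;
      Pv[b] = Mh | ~(Xv | Ph);
      Mv[b] = Ph & Xv;
      hin = hout;
    }
    score += hin;
  }
  return score;
}

// [[Rcpp::export(name = ".edit_distance_cpp")]]
int edit_distance_cpp(std::string a, std::string b) {
  if (a.empty()) return (int)b.size();
  if (b.empty()) return (int)a.size();
  // pattern = shorter string keeps the block count minimal
  const std::string &p = (a.size() <= b.size()) ? a : b;
  const std::string &t = (a.size() <= b.size()) ? b : a;
  MyersPattern pat(p.c_str(), (int)p.size());
  return myers_distance(pat, t.c_str(), (int)t.size());
}

// Full pairwise edit-distance matrix over a set of sequences.
// [[Rcpp::export(name = ".edist_matrix_cpp")]]
IntegerMatrix edist_matrix_cpp(CharacterVector seqs) {
  int n = seqs.size();
  std::vector<std::string> ss(n);
  for (int i = 0; i < n; ++i) ss[i] = as<std::string>(seqs[i]);
  IntegerMatrix D(n, n);
  for (int i = 0; i < n; ++i) {
    if (ss[i].empty()) {
      for (int j = 0; j < n; ++j) { D(i, j) = (int)ss[j].size(); D(j, i) = D(i, j); }
      continue;
    }
    MyersPattern pat(ss[i].c_str(), (int)ss[i].size());
    for (int j = i + 1; j < n; ++j) {
      int d;
      if (ss[j].empty()) d = (int)ss[i].size();
      else if (ss[j].size() >= ss[i].size())
        d = myers_distance(pat, ss[j].c_str(), (int)ss[j].size());
      else {
        MyersPattern pj(ss[j].c_str(), (int)ss[j].size());
        d = myers_distance(pj, ss[i].c_str(), (int)ss[i].size());
      }
      D(i, j) = d;
      D(j, i) = d;
    }
    D(i, i) = 0;
  }
  return D;
}
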