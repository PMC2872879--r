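#include <Rcpp.h>
#include <algorithm>
#include <numeric>
#include <string>
#include <vector>

using namespace Rcpp;

// Suffix-array index over the concatenation of all region sequences, with a
// region boundary map.  Queries walk the array by binary-search descent,
// branching over the base set of each degenerate IUPAC symbol, so a motif is
// never expanded into its full word list.  Regions are separated by a
// sentinel ('$') that no motif symbol matches, so matches cannot span
// regions.

struct SuffixIndex {
  std::string text;              // concatenated sequences + sentinels
  std::vector<int> sa;           // suffix array
  std::vector<int> region_start; // start offset of each region in text
  std::vector<int> region_len;   // length of each region
};

// sequence alphabet is {A,C,G,T,N,$}; motif symbols map to the set of
// sequence characters they accept.  Sequence N is matched only by motif N.
static bool symbol_accepts(char sym, std::string &out) {
  switch (sym) {
  case 'A': out = "A"; return true;
  case 'C': out = "C"; return true;
  case 'G': out = "G"; return true;
  case 'T': out = "T"; return true;
  case 'W': out = "AT"; return true;
  case 'S': out = "CG"; return true;
  case 'R': out = "AG"; return true;
  case 'Y': out = "CT"; return true;
  case 'K': out = "GT"; return true;
  case 'M': out = "AC"; return true;
  case 'N': out = "ACGTN"; return true;
  default: return false;
  }
}

// O(n log^2 n) rank-doubling suffix array construction; robust on highly
// repetitive inputs (e.g. poly-T regions) unlike direct suffix std::sort.
static void build_sa(const std::string &s, std::vector<int> &sa) {
  int n = (int)s.size();
  sa.resize(n);
  std::vector<int> rank(n), tmp(n);
  for (int i = 0; i < n; ++i) { sa[i] = i; rank[i] = (unsigned char)s[i]; }
  for (int k = 1;; k <<= 1) {
    auto cmp = [&](int a, int b) {
      if (rank[a] != rank[b]) return rank[a] < rank[b];
      int ra = a + k < n ? rank[a + k] : -1;
      int rb = b + k < n ? rank[b + k] : -1;
      return ra < rb;
    };
    std::sort(sa.begin(), sa.end(), cmp);
    tmp[sa[0]] = 0;
    for (int i = 1; i < n; ++i)
      tmp[sa[i]] = tmp[sa[i - 1]] + (cmp(sa[i - 1], sa[i]) ? 1 : 0);
    rank = tmp;
    if (rank[sa[n - 1]] == n - 1) break;
  }
}

// character of suffix sa[i] at offset depth ('\0' past the end)
static inline char suf_char(const SuffixIndex &idx, int i, int depth) {
  size_t p = (size_t)idx.sa[i] + depth;
  return p < idx.text.size() ? idx.text[p] : '\0';
}

// narrow [lo, hi) to suffixes whose character at `depth` equals c
static void narrow(const SuffixIndex &idx, int depth, char c, int &lo, int &hi) {
  int l = lo, r = hi;
  // lower bound
  while (l < r) {
    int mid = (l + r) / 2;
    if (suf_char(idx, mid, depth) < c) l = mid + 1; else r = mid;
  }
  int new_lo = l;
  r = hi;
  while (l < r) {
    int mid = (l + r) / 2;
    if (suf_char(idx, mid, depth) <= c) l = mid + 1; else r = mid;
  }
  lo = new_lo;
  hi = l;
}

// depth-first branching descent; collects text offsets of match starts
static void descend(const SuffixIndex &idx, const std::string &motif,
                    size_t depth, int lo, int hi, std::vector<int> &hits) {
  if (lo >= hi) return;
  if (depth == motif.size()) {
    for (int i = lo; i < hi; ++i) hits.push_back(idx.sa[i]);
    return;
  }
  std::string accept;
  symbol_accepts(motif[depth], accept); // validated R-side
  for (char c : accept) {
    int l = lo, h = hi;
    narrow(idx, (int)depth, c, l, h);
    descend(idx, motif, depth + 1, l, h, hits);
  }
}

// map a text offset to its region (0-based); -1 for a sentinel position
static int offset_region(const SuffixIndex &idx, int pos) {
  // region_start is sorted; find last start <= pos
  auto it = std::upper_bound(idx.region_start.begin(), idx.region_start.end(), pos);
  int r = (int)(it - idx.region_start.begin()) - 1;
  if (r < 0) return -1;
  if (pos - idx.region_start[r] >= idx.region_len[r]) return -1; // sentinel
  return r;
}

// [[Rcpp::export(name = ".si_build")]]
SEXP si_build(CharacterVector seqs) {
  SuffixIndex *idx = new SuffixIndex();
  size_t total = 0;
  for (R_xlen_t i = 0; i < seqs.size(); ++i) total += Rf_xlength(STRING_ELT(seqs, i)) + 1;
  idx->text.reserve(total);
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    idx->region_start.push_back((int)idx->text.size());
    idx->region_len.push_back((int)s.size());
    idx->text += s;
    idx->text += '$';
  }
  build_sa(idx->text, idx->sa);
  XPtr<SuffixIndex> ptr(idx, true);
  return ptr;
}

// [[Rcpp::export(name = ".si_n_positions")]]
int si_n_positions(SEXP xp) {
  XPtr<SuffixIndex> idx(xp);
  int n = 0;
  for (size_t i = 0; i < idx->region_len.size(); ++i) n += idx->region_len[i];
  return n;
}

// [[Rcpp::export(name = ".si_query_regions")]]
IntegerVector si_query_regions(SEXP xp, std::string motif) {
  XPtr<SuffixIndex> idx(xp);
  std::vector<int> hits;
  descend(*idx, motif, 0, 0, (int)idx->sa.size(), hits);
  std::vector<bool> seen(idx->region_len.size(), false);
  std::vector<int> out;
  for (int p : hits) {
    int r = offset_region(*idx, p);
    if (r >= 0 && !seen[r]) { seen[r] = true; out.push_back(r + 1); }
  }
  std::sort(out.begin(), out.end());
  return wrap(out);
}

// [[Rcpp::export(name = ".si_query_positions")]]
DataFrame si_query_positions(SEXP xp, std::string motif) {
  XPtr<SuffixIndex> idx(xp);
  std::vector<int> hits;
  descend(*idx, motif, 0, 0, (int)idx->sa.size(), hits);
  std::sort(hits.begin(), hits.end());
  std::vector<int> region, offset;
  for (int p : hits) {
    int r = offset_region(*idx, p);
    if (r < 0) continue;
    region.push_back(r + 1);
    offset.push_back(p - idx->region_start[r]);
  }
  return DataFrame::create(_["region"] = region, _["offset"] = offset);
}
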