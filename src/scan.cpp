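#include <Rcpp.h>
#include <climits>
using namespace Rcpp;

// Semi-global bounded-edit-distance scan of `pattern` against `read`
// (substitutions and indels, unit costs). Returns one row per local-minimum
// match end with edit distance <= max_edit: columns start, end (0-based,
// half-open) and edit. Plateaus of equal score emit their leftmost position;
// overlapping hits from different patterns are resolved by the caller.
// [[Rcpp::export]]
IntegerMatrix cpp_scan_edit(const std::string& read, const std::string& pattern,
                            int max_edit) {
  const int n = read.size(), m = pattern.size();
  std::vector<int> starts, ends, edits;
  if (n == 0 || m == 0) {
    IntegerMatrix out(0, 3);
    colnames(out) = CharacterVector::create("start", "end", "edit");
    return out;
  }
  if (m > 64) stop("pattern longer than 64 nt not supported");
  // Myers bit-parallel semi-global scan: E[j] = best edit distance of the
  // pattern against any window ending at read position j
  std::vector<int> E(n + 1);
  {
    uint64_t Peq[256] = {0};
    for (int i = 0; i < m; ++i) Peq[(unsigned char)pattern[i]] |= (1ULL << i);
    uint64_t Pv = ~0ULL, Mv = 0;
    int score = m;
    const uint64_t hb = 1ULL << (m - 1);
    E[0] = m;
    for (int j = 0; j < n; ++j) {
      uint64_t Eq = Peq[(unsigned char)read[j]];
      uint64_t Xv = Eq | Mv;
      uint64_t Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
      uint64_t Ph = Mv | ~(Xh | Pv);
      uint64_t Mh = Pv & Xh;
      if (Ph & hb) ++score; else if (Mh & hb) --score;
      Ph <<= 1; Mh <<= 1;
      Pv = Mh | ~(Xv | Ph);
      Mv = Ph & Xv;
      E[j + 1] = score;
    }
  }
  for (int j = 1; j <= n; ++j) {
    const int nxt = (j < n) ? E[j + 1] : INT_MAX;
    if (E[j] <= max_edit && E[j] < E[j - 1] && E[j] <= nxt) {
      // recover the start by aligning the reversed pattern against the
      // reversed window ending at j
      int w0 = j - m - max_edit;
      if (w0 < 0) w0 = 0;
      const int L = j - w0;
      std::vector<int> p2(m + 1), c2(m + 1);
      for (int i = 0; i <= m; ++i) p2[i] = i;
      int best_l = 0, best_e = m;
      for (int l = 1; l <= L; ++l) {
        c2[0] = l;  // the alignment must reach back through every used base
        const char rl = read[j - l];
        for (int i = 1; i <= m; ++i) {
          // pattern is consumed right-to-left while walking the read backwards
          int d = p2[i - 1] + (rl != pattern[m - i] ? 1 : 0);
          int v = p2[i] + 1;
          if (v < d) d = v;
          v = c2[i - 1] + 1;
          if (v < d) d = v;
          c2[i] = d;
        }
        if (c2[m] < best_e ||
            (c2[m] == best_e && std::abs(l - m) < std::abs(best_l - m))) {
          best_e = c2[m];
          best_l = l;
        }
        std::swap(p2, c2);
      }
      starts.push_back(j - best_l);
      ends.push_back(j);
      edits.push_back(E[j]);
    }
  }
  IntegerMatrix out(starts.size(), 3);
  for (size_t r = 0; r < starts.size(); ++r) {
    out(r, 0) = starts[r];
    out(r, 1) = ends[r];
    out(r, 2) = edits[r];
  }
  colnames(out) = CharacterVector::create("start", "end", "edit");
  return out;
}

// Longest prefix of each string that is a run of `base` tolerating at most
// `tol` (fraction) other characters. Returns the run length per string.
// [[Rcpp::export]]
IntegerVector cpp_prefix_run(CharacterVector x, char base, double tol) {
  const int n = x.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    if (x[k] == NA_STRING) {
      out[k] = NA_INTEGER;
      continue;
    }
    const char* s = CHAR(STRING_ELT(x, k));
    int len = LENGTH(STRING_ELT(x, k));
    int mism = 0, best = 0;
    for (int i = 0; i < len; ++i) {
      if (s[i] != base) ++mism;
      if ((double)mism <= tol * (i + 1)) best = i + 1;
    }
    // a qualifying run must end on the run base, not on tolerated mismatches
    while (best > 0 && s[best - 1] != base) --best;
    out[k] = best;
  }
  return out;
}

// Whitelist lookup with single-mismatch rescue: for each query return the
// 1-based whitelist index of an exact match, else of a unique Hamming-1
// neighbour; 0 if absent, -1 if the Hamming-1 neighbour is ambiguous.
// [[Rcpp::export]]
IntegerVector cpp_match_hamming1(CharacterVector queries, CharacterVector whitelist) {
  const int nq = queries.size(), nw = whitelist.size();
  std::vector<std::string> wl(nw);
  std::map<std::string, int> exact;
  for (int i = 0; i < nw; ++i) {
    wl[i] = as<std::string>(whitelist[i]);
    exact[wl[i]] = i + 1;
  }
  IntegerVector out(nq);
  for (int q = 0; q < nq; ++q) {
    std::string s = as<std::string>(queries[q]);
    std::map<std::string, int>::iterator it = exact.find(s);
    if (it != exact.end()) {
      out[q] = it->second;
      continue;
    }
    int hit = 0, nhit = 0;
    for (int i = 0; i < nw; ++i) {
      if (wl[i].size() != s.size()) continue;
      int d = 0;
      for (size_t j = 0; j < s.size() && d < 2; ++j)
        if (s[j] != wl[i][j]) ++d;
      if (d == 1) {
        ++nhit;
        hit = i + 1;
        if (nhit > 1) break;
      }
    }
    out[q] = (nhit == 1) ? hit : (nhit == 0 ? 0 : -1);
  }
  return out;
}

// Hamming distance between equal-length string pairs (NA if lengths differ).
// [[Rcpp::export]]
IntegerVector cpp_hamming(CharacterVector a, CharacterVector b) {
  const int n = a.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char* s1 = CHAR(STRING_ELT(a, k));
    const char* s2 = CHAR(STRING_ELT(b, k));
    int l1 = LENGTH(STRING_ELT(a, k)), l2 = LENGTH(STRING_ELT(b, k));
    if (l1 != l2) {
      out[k] = NA_INTEGER;
      continue;
    }
    int d = 0;
    for (int i = 0; i < l1; ++i)
      if (s1[i] != s2[i]) ++d;
    out[k] = d;
  }
  return out;
}
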