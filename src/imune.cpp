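#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <array>
#include <string>
#include <cstdint>
#include <climits>
using namespace Rcpp;

// Canonical residue order used throughout the package.
static const char AA20[] = "ACDEFGHIKLMNPQRSTVWY";

static inline int aa_code(char c) {
  switch (c) {
    case 'A': return 0;  case 'C': return 1;  case 'D': return 2;
    case 'E': return 3;  case 'F': return 4;  case 'G': return 5;
    case 'H': return 6;  case 'I': return 7;  case 'K': return 8;
    case 'L': return 9;  case 'M': return 10; case 'N': return 11;
    case 'P': return 12; case 'Q': return 13; case 'R': return 14;
    case 'S': return 15; case 'T': return 16; case 'V': return 17;
    case 'W': return 18; case 'Y': return 19;
    default:  return -1;
  }
}

// Total residue tallies over all positions of all peptides.
// [[Rcpp::export]]
IntegerVector cpp_aa_counts(CharacterVector peptides) {
  IntegerVector out(20);
  for (R_xlen_t i = 0; i < peptides.size(); ++i) {
    const char *s = CHAR(STRING_ELT(peptides, i));
    for (; *s; ++s) {
      int c = aa_code(*s);
      if (c < 0) stop("invalid residue '%c'", *s);
      out[c]++;
    }
  }
  return out;
}

// Greedy sequencing-error collapse. `peptides` must already be ordered by
// descending read count (ties lexicographic). A peptide is dropped when some
// earlier retained peptide lies within Hamming distance <= max_mut; candidate
// neighbours are found with a pigeonhole partition index (max_mut + 1 exact
// segments), so only near matches are ever compared in full.
// [[Rcpp::export]]
LogicalVector cpp_collapse(CharacterVector peptides, int max_mut) {
  R_xlen_t n = peptides.size();
  LogicalVector keep(n);
  if (n == 0) return keep;
  int len = LENGTH(STRING_ELT(peptides, 0));
  int nseg = max_mut + 1;
  if (nseg > len) stop("max_mutations must be smaller than the peptide length");

  std::vector<int> seg_start(nseg + 1);
  for (int s = 0; s <= nseg; ++s) seg_start[s] = (int)((long long)s * len / nseg);

  std::vector<std::unordered_map<std::string, std::vector<R_xlen_t> > > index(nseg);
  for (R_xlen_t i = 0; i < n; ++i) {
    const char *pi = CHAR(STRING_ELT(peptides, i));
    bool absorbed = false;
    for (int s = 0; s < nseg && !absorbed; ++s) {
      std::string key(pi + seg_start[s], pi + seg_start[s + 1]);
      auto it = index[s].find(key);
      if (it == index[s].end()) continue;
      for (R_xlen_t j : it->second) {
        const char *pj = CHAR(STRING_ELT(peptides, j));
        int d = 0;
        for (int t = 0; t < len; ++t) {
          if (pi[t] != pj[t] && ++d > max_mut) break;
        }
        if (d <= max_mut) { absorbed = true; break; }
      }
    }
    keep[i] = !absorbed;
    if (!absorbed) {
      for (int s = 0; s < nseg; ++s) {
        std::string key(pi + seg_start[s], pi + seg_start[s + 1]);
        index[s][key].push_back(i);
      }
    }
  }
  return keep;
}

// Exhaustive sub-pattern counting by per-peptide emission. `layouts` is a
// list of sorted 1-based defined-position vectors (first element always 1);
// every (layout, offset) instance of every peptide emits one pattern whose
// defined residues must all lie in `allowed`, with the first defined residue
// additionally in `first_allowed` (the sharding hook). A pattern is keyed by
// layout id (high bits) plus its defined residues packed base-20 (low bits);
// keys are below 2^40 and therefore exact as doubles. Counting uses a dense
// accumulator indexed by compact residue codes when the allowed alphabet is
// small enough, and a hash otherwise. Returns one row per observed pattern:
// key, count, span L, defined positions k and the product of `profile`
// frequencies over the defined residues.
// [[Rcpp::export]]
DataFrame cpp_count_subpatterns(CharacterVector peptides, List layouts,
                                LogicalVector allowed, LogicalVector first_allowed,
                                NumericVector profile) {
  int nlay = layouts.size();
  if (nlay > 4095) stop("too many layouts");
  std::vector<std::vector<int> > lay(nlay);
  std::vector<int> span(nlay);
  int kmax = 0;
  for (int i = 0; i < nlay; ++i) {
    IntegerVector v = layouts[i];
    lay[i] = std::vector<int>(v.begin(), v.end());
    span[i] = lay[i].back();
    kmax = std::max(kmax, (int)lay[i].size());
  }
  bool allow20[20], first20[20];
  int compact[20];  // 20-code -> compact code within the allowed alphabet
  int nallow = 0;
  for (int c = 0; c < 20; ++c) {
    allow20[c] = allowed[c];
    first20[c] = first_allowed[c];
    compact[c] = allow20[c] ? nallow++ : -1;
  }
  std::vector<int> expand(nallow);  // compact code -> 20-code
  for (int c = 0; c < 20; ++c) if (compact[c] >= 0) expand[compact[c]] = c;

  double dense_size = (double)nlay * std::pow((double)nallow, kmax);
  bool use_dense = dense_size <= (double)(1 << 25);

  std::vector<uint32_t> dense;
  std::vector<uint64_t> apow(kmax + 1, 1);
  std::unordered_map<uint64_t, uint32_t> acc;
  if (use_dense) {
    for (int q = 1; q <= kmax; ++q) apow[q] = apow[q - 1] * (uint64_t)nallow;
    dense.assign((size_t)dense_size, 0u);
  } else {
    acc.reserve(1 << 20);
  }

  std::vector<int> codes;
  for (R_xlen_t ip = 0; ip < peptides.size(); ++ip) {
    const char *s = CHAR(STRING_ELT(peptides, ip));
    int l = (int)LENGTH(STRING_ELT(peptides, ip));
    codes.resize(l);
    for (int t = 0; t < l; ++t) {
      codes[t] = aa_code(s[t]);
      if (codes[t] < 0) stop("invalid residue '%c'", s[t]);
    }
    for (int li = 0; li < nlay; ++li) {
      int L = span[li];
      const std::vector<int> &pos = lay[li];
      int k = (int)pos.size();
      for (int off = 0; off + L <= l; ++off) {
        int c0 = codes[off];  // first defined position is always 1
        if (!first20[c0] || !allow20[c0]) continue;
        if (use_dense) {
          uint64_t idx = (uint64_t)compact[c0];
          bool ok = true;
          for (int q = 1; q < k; ++q) {
            int c = compact[codes[off + pos[q] - 1]];
            if (c < 0) { ok = false; break; }
            idx = idx * (uint64_t)nallow + (uint64_t)c;
          }
          // layouts with k < kmax use the leading block of their stratum
          if (ok) dense[(size_t)li * (size_t)apow[kmax] + (size_t)(idx * apow[kmax - k])]++;
        } else {
          uint64_t key = ((uint64_t)li << 28) | (uint64_t)c0;
          bool ok = true;
          for (int q = 1; q < k; ++q) {
            int c = codes[off + pos[q] - 1];
            if (!allow20[c]) { ok = false; break; }
            key = (key & 0xFFFFFFFFF0000000ULL) |
                  (((key & 0x0FFFFFFFULL) * 20ULL) + (uint64_t)c);
          }
          if (ok) acc[key]++;
        }
      }
    }
  }

  // harvest (key, count) pairs
  std::vector<uint64_t> keys;
  std::vector<uint32_t> counts;
  if (use_dense) {
    for (int li = 0; li < nlay; ++li) {
      int k = (int)lay[li].size();
      size_t base = (size_t)li * (size_t)apow[kmax];
      for (uint64_t idx = 0; idx < apow[k]; ++idx) {
        uint32_t n = dense[base + (size_t)(idx * apow[kmax - k])];
        if (n == 0) continue;
        // compact digits -> 20-code digits, packed base-20
        uint64_t rest = idx, packed = 0, mult = 1;
        for (int q = 0; q < k; ++q) {
          packed += (uint64_t)expand[rest % (uint64_t)nallow] * mult;
          rest /= (uint64_t)nallow;
          mult *= 20ULL;
        }
        keys.push_back(((uint64_t)li << 28) | packed);
        counts.push_back(n);
      }
    }
  } else {
    keys.reserve(acc.size());
    counts.reserve(acc.size());
    for (auto &kvp : acc) {
      keys.push_back(kvp.first);
      counts.push_back(kvp.second);
    }
  }

  R_xlen_t nout = (R_xlen_t)keys.size();
  NumericVector keyv(nout), count(nout), prodf(nout);
  IntegerVector Lv(nout), kv(nout);
  for (R_xlen_t r = 0; r < nout; ++r) {
    uint64_t key = keys[r];
    int li = (int)(key >> 28);
    uint64_t res = key & 0x0FFFFFFFULL;
    int k = (int)lay[li].size();
    double pf = 1.0;
    for (int q = 0; q < k; ++q) {
      pf *= profile[(int)(res % 20ULL)];
      res /= 20ULL;
    }
    keyv[r] = (double)key;
    count[r] = (double)counts[r];
    Lv[r] = span[li];
    kv[r] = k;
    prodf[r] = pf;
  }
  return DataFrame::create(_["key"] = keyv, _["O"] = count,
                           _["L"] = Lv, _["k"] = kv, _["prod_f"] = prodf);
}

// Convert packed pattern keys back to notation strings.
// [[Rcpp::export]]
CharacterVector cpp_keys_to_patterns(NumericVector keys, List layouts) {
  int nlay = layouts.size();
  std::vector<std::vector<int> > lay(nlay);
  for (int i = 0; i < nlay; ++i) {
    IntegerVector v = layouts[i];
    lay[i] = std::vector<int>(v.begin(), v.end());
  }
  CharacterVector out(keys.size());
  std::string buf;
  for (R_xlen_t r = 0; r < keys.size(); ++r) {
    uint64_t key = (uint64_t)keys[r];
    int li = (int)(key >> 28);
    if (li < 0 || li >= nlay) stop("key does not match the layout set");
    uint64_t res = key & 0x0FFFFFFFULL;
    const std::vector<int> &pos = lay[li];
    int k = (int)pos.size();
    buf.assign(pos.back(), 'x');
    for (int q = k - 1; q >= 0; --q) {
      buf[pos[q] - 1] = AA20[(int)(res % 20ULL)];
      res /= 20ULL;
    }
    out[r] = buf;
  }
  return out;
}

// Offset-match totals for a set of motifs over one peptide set. Each motif is
// an IntegerVector of per-column residue bitmasks (bit r set = residue AA20[r]
// allowed; wildcard columns carry all 20 bits).
// [[Rcpp::export]]
NumericVector cpp_motif_count_multi(CharacterVector peptides, List masks_list) {
  int nm = masks_list.size();
  std::vector<std::vector<int> > masks(nm);
  for (int m = 0; m < nm; ++m) {
    IntegerVector v = masks_list[m];
    masks[m] = std::vector<int>(v.begin(), v.end());
  }
  NumericVector out(nm);
  std::vector<int> codes;
  for (R_xlen_t ip = 0; ip < peptides.size(); ++ip) {
    const char *s = CHAR(STRING_ELT(peptides, ip));
    int l = (int)LENGTH(STRING_ELT(peptides, ip));
    codes.resize(l);
    for (int t = 0; t < l; ++t) {
      codes[t] = aa_code(s[t]);
      if (codes[t] < 0) stop("invalid residue '%c'", s[t]);
    }
    for (int m = 0; m < nm; ++m) {
      int L = (int)masks[m].size();
      for (int off = 0; off + L <= l; ++off) {
        bool hit = true;
        for (int t = 0; t < L; ++t) {
          if (!((masks[m][t] >> codes[off + t]) & 1)) { hit = false; break; }
        }
        if (hit) out[m] += 1.0;
      }
    }
  }
  return out;
}

// Per-peptide offset-match counts for a single motif mask vector.
// [[Rcpp::export]]
IntegerVector cpp_motif_hits(CharacterVector peptides, IntegerVector masks) {
  int L = masks.size();
  std::vector<int> mk(masks.begin(), masks.end());
  IntegerVector out(peptides.size());
  std::vector<int> codes;
  for (R_xlen_t ip = 0; ip < peptides.size(); ++ip) {
    const char *s = CHAR(STRING_ELT(peptides, ip));
    int l = (int)LENGTH(STRING_ELT(peptides, ip));
    codes.resize(l);
    for (int t = 0; t < l; ++t) {
      codes[t] = aa_code(s[t]);
      if (codes[t] < 0) stop("invalid residue '%c'", s[t]);
    }
    int n = 0;
    for (int off = 0; off + L <= l; ++off) {
      bool hit = true;
      for (int t = 0; t < L; ++t) {
        if (!((mk[t] >> codes[off + t]) & 1)) { hit = false; break; }
      }
      if (hit) ++n;
    }
    out[ip] = n;
  }
  return out;
}

// Containment pairs over pattern notation strings ('x' = wildcard): one row
// (i, j), 1-based, for every ordered pair where pattern j fits inside
// pattern i at some offset (every defined column of j on an identical
// defined column of i). Self-pairs are not reported.
// [[Rcpp::export]]
IntegerMatrix cpp_containment(CharacterVector patterns) {
  int n = patterns.size();
  std::vector<std::string> ps(n);
  for (int i = 0; i < n; ++i) ps[i] = CHAR(STRING_ELT(patterns, i));
  std::vector<int> pi, pj;
  for (int i = 0; i < n; ++i) {
    int Li = (int)ps[i].size();
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      int Lj = (int)ps[j].size();
      if (Lj > Li) continue;
      bool found = false;
      for (int off = 0; off + Lj <= Li && !found; ++off) {
        bool ok = true;
        for (int t = 0; t < Lj; ++t) {
          char cj = ps[j][t];
          if (cj != 'x' && ps[i][off + t] != cj) { ok = false; break; }
        }
        found = ok;
      }
      if (found) { pi.push_back(i + 1); pj.push_back(j + 1); }
    }
  }
  IntegerMatrix out((int)pi.size(), 2);
  for (size_t r = 0; r < pi.size(); ++r) {
    out(r, 0) = pi[r];
    out(r, 1) = pj[r];
  }
  return out;
}

// Best ungapped alignment of every pattern in `a` against every pattern in
// `b` under a 20x20 substitution matrix in AA20 code order. Frames need at
// least one position where both patterns are defined; wildcard pairings
// score 0. Returns the maximum score (-Inf when no frame overlaps) and the
// smallest offset of b's first column relative to a's (0-based) achieving it.
// [[Rcpp::export]]
List cpp_align_best(CharacterVector a, CharacterVector b, IntegerMatrix pam) {
  int na = a.size(), nb = b.size();
  std::vector<std::string> pa(na), pb(nb);
  for (int i = 0; i < na; ++i) pa[i] = CHAR(STRING_ELT(a, i));
  for (int j = 0; j < nb; ++j) pb[j] = CHAR(STRING_ELT(b, j));
  NumericMatrix score(na, nb);
  IntegerMatrix offset(na, nb);
  for (int i = 0; i < na; ++i) {
    int La = (int)pa[i].size();
    for (int j = 0; j < nb; ++j) {
      int Lb = (int)pb[j].size();
      double best = R_NegInf;
      int best_off = NA_INTEGER;
      for (int off = -(Lb - 1); off <= La - 1; ++off) {
        int sc = 0;
        bool overlap = false;
        int t0 = std::max(0, -off), t1 = std::min(Lb, La - off);
        for (int t = t0; t < t1; ++t) {
          char cb = pb[j][t], ca = pa[i][t + off];
          if (cb == 'x' || ca == 'x') continue;
          overlap = true;
          sc += pam(aa_code(ca), aa_code(cb));
        }
        if (overlap && (double)sc > best) { best = sc; best_off = off; }
      }
      score(i, j) = best;
      offset(i, j) = best_off;
    }
  }
  return List::create(_["score"] = score, _["offset"] = offset);
}

// Pairwise motif alignment scores. Each motif arrives as per-column residue
// bitmasks (0 = wildcard column here, unlike the matching masks) plus the
// code of its most enriched residue per column (-1 for wildcards). A column
// pair scores the better of: motif 1's top residue against every residue in
// motif 2's column, and vice versa; the frame score sums column pairs where
// both are defined, and the best frame wins.
// [[Rcpp::export]]
NumericMatrix cpp_motif_pair_scores(List masks_list, List tops_list,
                                    IntegerMatrix pam) {
  int n = masks_list.size();
  std::vector<std::vector<int> > masks(n), tops(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector mv = masks_list[i], tv = tops_list[i];
    masks[i] = std::vector<int>(mv.begin(), mv.end());
    tops[i] = std::vector<int>(tv.begin(), tv.end());
  }
  // colmax[i][c][t]: best pam score of residue t against motif i's column c
  std::vector<std::vector<std::array<int, 20> > > colmax(n);
  for (int i = 0; i < n; ++i) {
    int L = (int)masks[i].size();
    colmax[i].resize(L);
    for (int c = 0; c < L; ++c) {
      for (int t = 0; t < 20; ++t) {
        int m = INT_MIN;
        for (int r = 0; r < 20; ++r) {
          if ((masks[i][c] >> r) & 1) m = std::max(m, (int)pam(t, r));
        }
        colmax[i][c][t] = m;
      }
    }
  }
  NumericMatrix out(n, n);
  for (int i = 0; i < n; ++i) {
    for (int j = i; j < n; ++j) {
      int Li = (int)masks[i].size(), Lj = (int)masks[j].size();
      double best = R_NegInf;
      for (int off = -(Lj - 1); off <= Li - 1; ++off) {
        int sc = 0;
        bool overlap = false;
        int t0 = std::max(0, -off), t1 = std::min(Lj, Li - off);
        for (int t = t0; t < t1; ++t) {
          if (masks[j][t] == 0 || masks[i][t + off] == 0) continue;
          overlap = true;
          sc += std::max(colmax[j][t][tops[i][t + off]],
                         colmax[i][t + off][tops[j][t]]);
        }
        if (overlap && (double)sc > best) best = sc;
      }
      out(i, j) = best;
      out(j, i) = best;
    }
  }
  return out;
}

// Product of profile frequencies over each string of defined residues.
// [[Rcpp::export]]
NumericVector cpp_profile_products(CharacterVector residues, NumericVector profile) {
  NumericVector out(residues.size());
  for (R_xlen_t i = 0; i < residues.size(); ++i) {
    const char *s = CHAR(STRING_ELT(residues, i));
    double pf = 1.0;
    for (; *s; ++s) {
      int c = aa_code(*s);
      if (c < 0) stop("invalid residue '%c'", *s);
      pf *= profile[c];
    }
    out[i] = pf;
  }
  return out;
}
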