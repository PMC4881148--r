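#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <climits>
#include <cmath>
#include <vector>
#include <string>

using namespace Rcpp;

// A=0 C=1 G=2 T=3, anything else = 4 (never matches, breaks k-mers)
static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return 4;
  }
}

static std::vector<uint8_t> encode_seq(const std::string &s) {
  std::vector<uint8_t> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) v[i] = (uint8_t) base_code(s[i]);
  return v;
}

static std::vector<uint8_t> revcomp_codes(const std::vector<uint8_t> &v) {
  std::vector<uint8_t> r(v.size());
  for (size_t i = 0; i < v.size(); ++i) {
    uint8_t c = v[v.size() - 1 - i];
    r[i] = (c < 4) ? (uint8_t)(3 - c) : (uint8_t)4;
  }
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  int n = x.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); ++j) {
      char c = s[s.size() - 1 - j];
      switch (c) {
      case 'A': r[j] = 'T'; break; case 'a': r[j] = 't'; break;
      case 'C': r[j] = 'G'; break; case 'c': r[j] = 'g'; break;
      case 'G': r[j] = 'C'; break; case 'g': r[j] = 'c'; break;
      case 'T': r[j] = 'A'; break; case 't': r[j] = 'a'; break;
      default: r[j] = c;
      }
    }
    out[i] = r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Best gapless window on one diagonal.
//
// A[i] is aligned to B[i - d] for i in [max(0,d), min(na, nb+d)).
// A window qualifies when its length >= min_len and its identity >= p.
// Equivalently, with per-column weight (1-p) for a match and -p for a
// mismatch, a window qualifies iff its weight sum >= 0; the maximising
// window of length >= min_len is found with a prefix-sum / sliding-minimum
// scan in O(overlap).
// ---------------------------------------------------------------------------
struct WinHit {
  bool pass;
  int matches;
  int len;
  double wsum;
};

static WinHit scan_diagonal(const std::vector<uint8_t> &A,
                            const std::vector<uint8_t> &B,
                            int d, int min_len, double p) {
  WinHit out; out.pass = false; out.matches = 0; out.len = 0; out.wsum = -1e18;
  int na = (int) A.size(), nb = (int) B.size();
  int lo = std::max(0, d);
  int hi = std::min(na, nb + d);
  int L = hi - lo;
  if (L < min_len) return out;

  // prefix sums of weights and matches
  std::vector<double> S(L + 1, 0.0);
  std::vector<int> M(L + 1, 0);
  for (int t = 0; t < L; ++t) {
    int i = lo + t;
    bool match = (A[i] < 4) && (A[i] == B[i - d]);
    S[t + 1] = S[t] + (match ? (1.0 - p) : (-p));
    M[t + 1] = M[t] + (match ? 1 : 0);
  }
  double best = -1e18;
  int bi = 0, bj = 0;
  double minS = S[0]; int min_at = 0;
  for (int j = min_len; j <= L; ++j) {
    int cand = j - min_len;          // window [cand, j) allowed
    if (S[cand] < minS) { minS = S[cand]; min_at = cand; }
    double w = S[j] - minS;
    if (w > best) { best = w; bi = min_at; bj = j; }
  }
  if (best >= -1e-9) {
    out.pass = true;
    out.matches = M[bj] - M[bi];
    out.len = bj - bi;
    out.wsum = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Seeded similarity graph.
//
// Candidate (pair, strand, diagonal) triples come from shared k-mers; each
// candidate diagonal is verified with scan_diagonal. With the default k = 8
// the seeding is lossless for substitution-only data at identity >= 90% and
// coverage >= 0.55 (any qualifying gapless window must contain an exact
// match run of at least 8 nt; see the package vignette for the pigeonhole
// argument).
// ---------------------------------------------------------------------------

struct Occ { int read; int pos; };

static void index_kmers(const std::vector<std::vector<uint8_t> > &seqs,
                        int k,
                        std::unordered_map<uint64_t, std::vector<Occ> > &map) {
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (int r = 0; r < (int) seqs.size(); ++r) {
    const std::vector<uint8_t> &s = seqs[r];
    if ((int) s.size() < k) continue;
    uint64_t key = 0;
    int valid = 0;
    for (int i = 0; i < (int) s.size(); ++i) {
      if (s[i] >= 4) { valid = 0; key = 0; continue; }
      key = ((key << 2) | s[i]) & mask;
      if (++valid >= k) {
        Occ o; o.read = r; o.pos = i - k + 1;
        map[key].push_back(o);
      }
    }
  }
}

struct UF {
  std::vector<int> parent;
  UF(int n) : parent(n) { for (int i = 0; i < n; ++i) parent[i] = i; }
  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[std::max(a, b)] = std::min(a, b);
  }
};

// packed candidate: (a, b, strand, diag). diag shifted to be non-negative.
static inline uint64_t pack_cand(int a, int b, int strand, int diag, int shift) {
  return (((uint64_t) a) << 42) | (((uint64_t) b) << 20) |
         (((uint64_t) strand) << 19) | ((uint64_t)(diag + shift));
}

// [[Rcpp::export]]
List cpp_edges_seeded(CharacterVector seqs, int k, double min_identity,
                      double min_coverage, bool cluster_mode) {
  int n = seqs.size();
  std::vector<std::vector<uint8_t> > fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = encode_seq(as<std::string>(seqs[i]));
    rev[i] = revcomp_codes(fwd[i]);
  }
  double p = min_identity / 100.0;

  std::unordered_map<uint64_t, std::vector<Occ> > fmap, rmap;
  index_kmers(fwd, k, fmap);
  index_kmers(rev, k, rmap);

  UF uf(n);
  std::vector<uint64_t> cands;
  int shift = 1 << 18;

  std::vector<int> e_a, e_b, e_strand, e_len;
  std::vector<double> e_ident, e_cov;

  // verification shared by both modes; in cluster mode we verify lazily and
  // skip candidates whose endpoints are already connected.
  auto verify = [&](int a, int b, int strand, int diag) -> WinHit {
    const std::vector<uint8_t> &A = fwd[a];
    const std::vector<uint8_t> &B = (strand == 0) ? fwd[b] : rev[b];
    int min_len = (int) std::ceil(min_coverage *
                    (double) std::min(A.size(), B.size()));
    if (min_len < 1) min_len = 1;
    return scan_diagonal(A, B, diag, min_len, p);
  };

  auto handle = [&](int a, int b, int strand, int diag) {
    if (cluster_mode) {
      if (uf.find(a) == uf.find(b)) return;
      WinHit h = verify(a, b, strand, diag);
      if (h.pass) uf.unite(a, b);
    } else {
      cands.push_back(pack_cand(a, b, strand, diag, shift));
    }
  };

  // forward-forward hits
  for (std::unordered_map<uint64_t, std::vector<Occ> >::iterator it = fmap.begin();
       it != fmap.end(); ++it) {
    std::vector<Occ> &v = it->second;
    if (v.size() < 2) continue;
    for (size_t x = 0; x < v.size(); ++x)
      for (size_t y = x + 1; y < v.size(); ++y) {
        int a = v[x].read, b = v[y].read;
        if (a == b) continue;
        if (a < b) handle(a, b, 0, v[x].pos - v[y].pos);
        else       handle(b, a, 0, v[y].pos - v[x].pos);
      }
  }
  // forward vs reverse-complement hits
  for (std::unordered_map<uint64_t, std::vector<Occ> >::iterator it = fmap.begin();
       it != fmap.end(); ++it) {
    std::unordered_map<uint64_t, std::vector<Occ> >::iterator jt = rmap.find(it->first);
    if (jt == rmap.end()) continue;
    std::vector<Occ> &vf = it->second;
    std::vector<Occ> &vr = jt->second;
    for (size_t x = 0; x < vf.size(); ++x)
      for (size_t y = 0; y < vr.size(); ++y) {
        int a = vf[x].read, b = vr[y].read;
        if (a == b) continue;
        if (a < b) {
          handle(a, b, 1, vf[x].pos - vr[y].pos);
        } else {
          // re-express the hit with the smaller read index on the forward
          // strand: seq_a fwd matching rc(seq_b) at (p, q) is seq_b fwd
          // matching rc(seq_a) at (nb-q-k, na-p-k).
          int p2 = (int) fwd[b].size() - vr[y].pos - k;
          int q2 = (int) fwd[a].size() - vf[x].pos - k;
          handle(b, a, 1, p2 - q2);
        }
      }
  }

  if (cluster_mode) {
    IntegerVector parent(n);
    for (int i = 0; i < n; ++i) parent[i] = uf.find(i) + 1;
    return List::create(_["parent"] = parent);
  }

  std::sort(cands.begin(), cands.end());
  cands.erase(std::unique(cands.begin(), cands.end()), cands.end());

  // per (a,b): keep the best passing window across strands/diagonals
  int cur_a = -1, cur_b = -1;
  bool have = false;
  WinHit best; int best_strand = 0, best_minlen = 1;
  auto flush = [&]() {
    if (have) {
      e_a.push_back(cur_a + 1);
      e_b.push_back(cur_b + 1);
      e_strand.push_back(best_strand);
      e_len.push_back(best.len);
      e_ident.push_back(100.0 * (double) best.matches / (double) best.len);
      int shorter = std::min((int) fwd[cur_a].size(), (int) fwd[cur_b].size());
      e_cov.push_back((double) best.len / (double) shorter);
      (void) best_minlen;
    }
    have = false;
  };
  for (size_t c = 0; c < cands.size(); ++c) {
    int a = (int) (cands[c] >> 42);
    int b = (int) ((cands[c] >> 20) & 0x3FFFFF);
    int strand = (int) ((cands[c] >> 19) & 1);
    int diag = (int) (cands[c] & 0x7FFFF) - shift;
    if (a != cur_a || b != cur_b) { flush(); cur_a = a; cur_b = b; }
    WinHit h = verify(a, b, strand, diag);
    if (h.pass && (!have || h.wsum > best.wsum ||
                   (h.wsum == best.wsum && h.len > best.len))) {
      best = h; best_strand = strand; have = true;
    }
  }
  flush();

  return List::create(
    _["a"] = wrap(e_a), _["b"] = wrap(e_b), _["strand"] = wrap(e_strand),
    _["identity"] = wrap(e_ident), _["coverage"] = wrap(e_cov),
    _["length"] = wrap(e_len));
}

// ---------------------------------------------------------------------------
// Exhaustive all-pairs, all-diagonals edge finder (no seeding). Used as an
// independent oracle for the seeded graph. Deliberately written as a plain
// direct scan: for every pair, every strand and every diagonal, walk the
// overlap once accumulating running best windows.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_edges_exhaustive(CharacterVector seqs, double min_identity,
                          double min_coverage) {
  int n = seqs.size();
  std::vector<std::vector<uint8_t> > fwd(n), rev(n);
  for (int i = 0; i < n; ++i) {
    fwd[i] = encode_seq(as<std::string>(seqs[i]));
    rev[i] = revcomp_codes(fwd[i]);
  }
  double p = min_identity / 100.0;
  std::vector<int> e_a, e_b;
  std::vector<double> e_ident;

  for (int a = 0; a < n; ++a) {
    for (int b = a + 1; b < n; ++b) {
      int na = (int) fwd[a].size(), nb = (int) fwd[b].size();
      int min_len = (int) std::ceil(min_coverage * (double) std::min(na, nb));
      if (min_len < 1) min_len = 1;
      bool found = false;
      double found_ident = 0.0;
      for (int strand = 0; strand < 2 && !found; ++strand) {
        const std::vector<uint8_t> &A = fwd[a];
        const std::vector<uint8_t> &B = (strand == 0) ? fwd[b] : rev[b];
        for (int d = -(nb - 1); d < na && !found; ++d) {
          int lo = std::max(0, d), hi = std::min(na, (int) B.size() + d);
          int L = hi - lo;
          if (L < min_len) continue;
          // running prefix minimum scan on this diagonal
          double S = 0.0, minS = 0.0;
          std::vector<double> pref(L + 1);
          std::vector<int> mat(L + 1, 0);
          pref[0] = 0.0;
          for (int t = 0; t < L; ++t) {
            int i = lo + t;
            bool m = (A[i] < 4) && (A[i] == B[i - d]);
            S += m ? (1.0 - p) : (-p);
            pref[t + 1] = S;
            mat[t + 1] = mat[t] + (m ? 1 : 0);
          }
          minS = pref[0];
          int min_at = 0;
          for (int j = min_len; j <= L; ++j) {
            if (pref[j - min_len] < minS) { minS = pref[j - min_len]; min_at = j - min_len; }
            if (pref[j] - minS >= -1e-9) {
              found = true;
              found_ident = 100.0 * (double)(mat[j] - mat[min_at]) /
                            (double)(j - min_at);
              break;
            }
          }
        }
      }
      if (found) {
        e_a.push_back(a + 1); e_b.push_back(b + 1); e_ident.push_back(found_ident);
      }
    }
  }
  return List::create(_["a"] = wrap(e_a), _["b"] = wrap(e_b),
                      _["identity"] = wrap(e_ident));
}

// ---------------------------------------------------------------------------
// Smith-Waterman local alignment, affine gaps.
// Gap of length L costs gap_open + gap_extend * L (so the first gapped base
// costs gap_open + gap_extend), matching the convention of
// Biostrings::pairwiseAlignment.
// ---------------------------------------------------------------------------

static int sw_score_only(const std::vector<uint8_t> &A,
                         const std::vector<uint8_t> &B,
                         int match, int mismatch, int go, int ge) {
  int na = (int) A.size(), nb = (int) B.size();
  if (na == 0 || nb == 0) return 0;
  std::vector<int> H(nb + 1, 0), E(nb + 1, INT_MIN / 4);
  int best = 0;
  int open_cost = go + ge;
  for (int i = 1; i <= na; ++i) {
    int Hdiag = 0;      // H[i-1][0]
    int F = INT_MIN / 4;
    int Hprev = 0;      // H[i][0]
    for (int j = 1; j <= nb; ++j) {
      E[j] = std::max(E[j] - ge, H[j] - open_cost);
      F = std::max(F - ge, Hprev - open_cost);
      int sub = (A[i - 1] < 4 && A[i - 1] == B[j - 1]) ? match : mismatch;
      int h = Hdiag + sub;
      if (E[j] > h) h = E[j];
      if (F > h) h = F;
      if (h < 0) h = 0;
      Hdiag = H[j];
      H[j] = h;
      Hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_sw_score_pairs(CharacterVector queries, CharacterVector subjects,
                                 IntegerVector qi, IntegerVector si,
                                 int match, int mismatch, int gap_open,
                                 int gap_extend) {
  int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<uint8_t> > Q(nq), S(ns);
  for (int i = 0; i < nq; ++i) Q[i] = encode_seq(as<std::string>(queries[i]));
  for (int i = 0; i < ns; ++i) S[i] = encode_seq(as<std::string>(subjects[i]));
  int np = qi.size();
  IntegerVector out(np);
  for (int t = 0; t < np; ++t) {
    out[t] = sw_score_only(Q[qi[t] - 1], S[si[t] - 1],
                           match, mismatch, gap_open, gap_extend);
    if (t % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full DP with traceback for a single pair; returns score, matches,
// alignment length (columns), and 1-based start/end coordinates. Explicit
// per-cell state bytes keep the affine-gap traceback exact.
// [[Rcpp::export]]
List cpp_sw_traceback(std::string a, std::string b, int match, int mismatch,
                      int gap_open, int gap_extend) {
  std::vector<uint8_t> A = encode_seq(a), B = encode_seq(b);
  int na = (int) A.size(), nb = (int) B.size();
  int open_cost = gap_open + gap_extend;
  const int NEG = INT_MIN / 4;
  size_t ncell = (size_t)(na + 1) * (nb + 1);
  std::vector<int> H(ncell, 0), Em(ncell, NEG), Fm(ncell, NEG);
  // htrace: 0 = stop (H==0), 1 = diagonal, 2 = E (gap in A), 3 = F (gap in B)
  // etrace/ftrace: 1 = opened from H, 0 = extended
  std::vector<uint8_t> htrace(ncell, 0), etrace(ncell, 0), ftrace(ncell, 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= na; ++i) {
    for (int j = 1; j <= nb; ++j) {
      size_t idx = (size_t) i * (nb + 1) + j;
      size_t up = idx - (nb + 1), left = idx - 1, diag = up - 1;
      int e_open = H[left] - open_cost, e_ext = Em[left] - gap_extend;
      Em[idx] = std::max(e_open, e_ext);
      etrace[idx] = (e_open >= e_ext) ? 1 : 0;
      int f_open = H[up] - open_cost, f_ext = Fm[up] - gap_extend;
      Fm[idx] = std::max(f_open, f_ext);
      ftrace[idx] = (f_open >= f_ext) ? 1 : 0;
      int sub = (A[i - 1] < 4 && A[i - 1] == B[j - 1]) ? match : mismatch;
      int h = H[diag] + sub;
      uint8_t tr = 1;
      if (Em[idx] > h) { h = Em[idx]; tr = 2; }
      if (Fm[idx] > h) { h = Fm[idx]; tr = 3; }
      if (h <= 0) { h = 0; tr = 0; }
      H[idx] = h;
      htrace[idx] = tr;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }
  int i = bi, j = bj, matches = 0, cols = 0;
  int state = 0; // 0 = in H, 2 = in E, 3 = in F
  while (i > 0 && j > 0) {
    size_t idx = (size_t) i * (nb + 1) + j;
    if (state == 0) {
      uint8_t tr = htrace[idx];
      if (tr == 0) break;
      if (tr == 1) {
        if (A[i - 1] < 4 && A[i - 1] == B[j - 1]) ++matches;
        ++cols; --i; --j;
      } else {
        state = tr;
      }
    } else if (state == 2) {
      ++cols;
      uint8_t tr = etrace[idx];
      --j;
      if (tr == 1) state = 0;
    } else {
      ++cols;
      uint8_t tr = ftrace[idx];
      --i;
      if (tr == 1) state = 0;
    }
  }
  return List::create(_["score"] = best, _["matches"] = matches,
                      _["length"] = cols,
                      _["a_start"] = i + 1, _["a_end"] = bi,
                      _["b_start"] = j + 1, _["b_end"] = bj);
}

// ---------------------------------------------------------------------------
// Longest exact suffix(a)/prefix(b) overlap >= min_o, for greedy assembly.
// ---------------------------------------------------------------------------

static int max_overlap_one(const std::string &a, const std::string &b, int min_o) {
  int na = (int) a.size(), nb = (int) b.size();
  int lim = std::min(na, nb);
  for (int o = lim; o >= min_o; --o) {
    if (a.compare(na - o, o, b, 0, o) == 0) return o;
  }
  return 0;
}

// [[Rcpp::export]]
IntegerMatrix cpp_overlap_matrix(CharacterVector a_seqs, CharacterVector b_seqs,
                                 int min_o) {
  int n = a_seqs.size(), m = b_seqs.size();
  std::vector<std::string> A(n), B(m);
  for (int i = 0; i < n; ++i) A[i] = as<std::string>(a_seqs[i]);
  for (int j = 0; j < m; ++j) B[j] = as<std::string>(b_seqs[j]);
  IntegerMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = max_overlap_one(A[i], B[j], min_o);
  return out;
}

// ---------------------------------------------------------------------------
// k-mer candidate pairs between queries and subjects (both query strands),
// used as an optional mapping prefilter.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
DataFrame cpp_kmer_candidates(CharacterVector queries, CharacterVector subjects,
                              int k) {
  int nq = queries.size(), ns = subjects.size();
  std::vector<std::vector<uint8_t> > S(ns);
  for (int i = 0; i < ns; ++i) S[i] = encode_seq(as<std::string>(subjects[i]));
  std::unordered_map<uint64_t, std::vector<int> > smap;
  {
    std::unordered_map<uint64_t, std::vector<Occ> > tmp;
    index_kmers(S, k, tmp);
    for (std::unordered_map<uint64_t, std::vector<Occ> >::iterator it = tmp.begin();
         it != tmp.end(); ++it) {
      std::vector<int> &v = smap[it->first];
      for (size_t x = 0; x < it->second.size(); ++x) {
        int r = it->second[x].read;
        if (v.empty() || v.back() != r) {
          if (std::find(v.begin(), v.end(), r) == v.end()) v.push_back(r);
        }
      }
    }
  }
  uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  std::vector<int> o_q, o_s, o_strand;
  for (int q = 0; q < nq; ++q) {
    std::vector<uint8_t> f = encode_seq(as<std::string>(queries[q]));
    for (int strand = 0; strand < 2; ++strand) {
      std::vector<uint8_t> seq = (strand == 0) ? f : revcomp_codes(f);
      if ((int) seq.size() < k) continue;
      std::vector<bool> seen(ns, false);
      uint64_t key = 0; int valid = 0;
      for (int i = 0; i < (int) seq.size(); ++i) {
        if (seq[i] >= 4) { valid = 0; key = 0; continue; }
        key = ((key << 2) | seq[i]) & mask;
        if (++valid >= k) {
          std::unordered_map<uint64_t, std::vector<int> >::iterator it = smap.find(key);
          if (it != smap.end()) {
            for (size_t x = 0; x < it->second.size(); ++x) {
              int s = it->second[x];
              if (!seen[s]) {
                seen[s] = true;
                o_q.push_back(q + 1); o_s.push_back(s + 1); o_strand.push_back(strand);
              }
            }
          }
        }
      }
    }
  }
  return DataFrame::create(_["query"] = wrap(o_q), _["subject"] = wrap(o_s),
                           _["strand"] = wrap(o_strand));
}
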