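#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <climits>
#include <algorithm>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Local alignment with linear gap penalties, optionally banded around a
// diagonal.  Scores: match > 0, mismatch < 0, gap < 0.  Identity is defined
// over alignment columns, with gap columns counting as mismatches.
// ---------------------------------------------------------------------------

namespace {

struct Aln {
  int score = 0;
  int qs = 0, qe = 0;   // query interval, 0-based half-open
  int rs = 0, re = 0;   // reference interval, 0-based half-open
  int matches = 0, columns = 0;
  std::vector<int> col_ref;   // reference positions carrying a query base
  std::string col_base;       // the query base placed at col_ref[i]
  bool valid = false;
};

inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
  }
}

std::string revcomp(const std::string& s) {
  std::string out(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    out[s.size() - 1 - i] = comp_base(s[i]);
  return out;
}

// Banded Smith-Waterman.  Cells with reference offset j - i outside
// [diag_center - band, diag_center + band] are not computed; out-of-band
// predecessors contribute the local-alignment floor of zero.  With
// band >= len(ref) and diag_center = 0 every cell is inside the band and the
// result is the exact full dynamic program.
Aln banded_sw(const std::string& q, const std::string& r,
              int match, int mismatch, int gap,
              int diag_center, int band) {
  Aln a;
  const int m = (int)q.size(), n = (int)r.size();
  if (m == 0 || n == 0) return a;
  const int W = 2 * band + 1;
  std::vector<int> prev((size_t)W, 0), cur((size_t)W, 0);
  // traceback codes: 0 stop, 1 diag, 2 up (query base vs gap), 3 left (ref base vs gap)
  std::vector<uint8_t> tb((size_t)(m + 1) * W, 0);
  int best = 0, bi = 0, bb = 0;

  for (int i = 1; i <= m; ++i) {
    for (int b = 0; b < W; ++b) {
      int j = i + diag_center - band + b;
      if (j < 1 || j > n) { cur[b] = 0; continue; }
      int sc = prev[b] + (q[i - 1] == r[j - 1] ? match : mismatch); // diag
      uint8_t dir = 1;
      if (b + 1 < W) {
        int up = prev[b + 1] + gap;          // (i-1, j)
        if (up > sc) { sc = up; dir = 2; }
      }
      if (b - 1 >= 0) {
        int left = cur[b - 1] + gap;         // (i, j-1)
        if (left > sc) { sc = left; dir = 3; }
      }
      if (sc <= 0) { sc = 0; dir = 0; }
      cur[b] = sc;
      tb[(size_t)i * W + b] = dir;
      if (sc > best) { best = sc; bi = i; bb = b; }
    }
    std::swap(prev, cur);
  }
  if (best <= 0) return a;

  // traceback
  int i = bi, b = bb;
  a.score = best;
  a.qe = bi;
  a.re = bi + diag_center - band + bb;
  std::vector<int> cref;
  std::string cbase;
  while (i > 0) {
    uint8_t dir = tb[(size_t)i * W + b];
    if (dir == 0) break;
    int j = i + diag_center - band + b;
    if (dir == 1) {
      ++a.columns;
      if (q[i - 1] == r[j - 1]) ++a.matches;
      cref.push_back(j - 1);
      cbase.push_back(q[i - 1]);
      --i; // b unchanged: (i-1, j-1) has the same offset index
    } else if (dir == 2) {
      ++a.columns;
      --i; ++b;
    } else { // 3
      ++a.columns;
      --b;
    }
  }
  a.qs = i;
  a.rs = i + diag_center - band + b;
  std::reverse(cref.begin(), cref.end());
  std::reverse(cbase.begin(), cbase.end());
  a.col_ref = std::move(cref);
  a.col_base = std::move(cbase);
  a.valid = true;
  return a;
}

inline bool base2bits(char c, uint64_t& v) {
  switch (c) {
    case 'A': case 'a': v = 0; return true;
    case 'C': case 'c': v = 1; return true;
    case 'G': case 'g': v = 2; return true;
    case 'T': case 't': v = 3; return true;
    default: return false;
  }
}

// rolling 2-bit k-mer scan; calls f(kmer, pos) for every valid k-mer
template <typename F>
void for_each_kmer(const std::string& s, int k, F f) {
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  uint64_t cur = 0;
  int run = 0;
  for (int i = 0; i < (int)s.size(); ++i) {
    uint64_t v;
    if (!base2bits(s[i], v)) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | v) & mask;
    if (++run >= k) f(cur, i - k + 1);
  }
}

struct KmerIndex {
  std::unordered_map<uint64_t, std::vector<std::pair<int, int>>> map; // kmer -> (ref, pos)
  int k;
  void build(const std::vector<std::string>& refs, int k_) {
    k = k_;
    for (int r = 0; r < (int)refs.size(); ++r) {
      for_each_kmer(refs[r], k, [&](uint64_t km, int pos) {
        map[km].emplace_back(r, pos);
      });
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string ref,
                  int match, int mismatch, int gap,
                  int diag_center, int band) {
  if (band < 0) { band = (int)ref.size(); diag_center = 0; }
  Aln a = banded_sw(query, ref, match, mismatch, gap, diag_center, band);
  return List::create(
    _["score"] = a.score, _["valid"] = a.valid,
    _["q_start"] = a.qs, _["q_end"] = a.qe,
    _["r_start"] = a.rs, _["r_end"] = a.re,
    _["matches"] = a.matches, _["columns"] = a.columns,
    _["col_ref"] = IntegerVector(a.col_ref.begin(), a.col_ref.end()),
    _["col_base"] = a.col_base);
}

// Seeded best-hit placement of contigs on a reference panel.  Both strands
// are tried; the accepted placement with the highest score wins, score ties
// across distinct references are broken by the lowest reference index and
// flagged ambiguous.  Reverse-strand hits are reported in reference-forward
// coordinates (the contig is reverse-complemented before alignment).
// [[Rcpp::export(name = ".map_contigs_cpp")]]
List map_contigs_cpp(CharacterVector contigs, CharacterVector refs,
                     int k, int band,
                     int match, int mismatch, int gap,
                     double min_identity, double min_len_frac) {
  const int nc = contigs.size(), nr = refs.size();
  std::vector<std::string> rseq(nr);
  for (int i = 0; i < nr; ++i) rseq[i] = as<std::string>(refs[i]);
  KmerIndex idx;
  idx.build(rseq, k);

  IntegerVector out_ref(nc, NA_INTEGER);
  CharacterVector out_strand(nc, NA_STRING);
  IntegerVector out_rs(nc, NA_INTEGER), out_re(nc, NA_INTEGER);
  NumericVector out_score(nc, NA_REAL), out_id(nc, NA_REAL), out_af(nc, NA_REAL);
  LogicalVector out_amb(nc, false);
  List out_colref(nc), out_colbase(nc);

  for (int c = 0; c < nc; ++c) {
    std::string fwd = as<std::string>(contigs[c]);
    std::string rev = revcomp(fwd);
    const int qlen = (int)fwd.size();

    int best_score = INT_MIN, best_ref = -1;
    bool ambiguous = false;
    Aln best_aln; int best_strand = 0;
    bool any_candidate = false;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      // vote per (ref, diagonal)
      std::unordered_map<int64_t, int> votes;
      for_each_kmer(q, k, [&](uint64_t km, int qpos) {
        auto it = idx.map.find(km);
        if (it == idx.map.end()) return;
        for (auto& hit : it->second) {
          int diag = hit.second - qpos;
          int64_t key = ((int64_t)hit.first << 24) | (uint32_t)(diag + (1 << 23));
          ++votes[key];
        }
      });
      // best diagonal per candidate reference
      std::unordered_map<int, std::pair<int, int>> cand; // ref -> (diag, votes)
      for (auto& kv : votes) {
        int rid = (int)(kv.first >> 24);
        int diag = (int)(kv.first & 0xFFFFFF) - (1 << 23);
        auto it = cand.find(rid);
        if (it == cand.end() || kv.second > it->second.second)
          cand[rid] = std::make_pair(diag, kv.second);
      }
      if (!cand.empty()) any_candidate = true;
      for (auto& kv : cand) {
        int rid = kv.first;
        Aln a = banded_sw(q, rseq[rid], match, mismatch, gap,
                          kv.second.first, band);
        if (!a.valid || a.columns == 0) continue;
        double identity = (double)a.matches / a.columns;
        double af = (double)(a.qe - a.qs) / qlen;
        if (identity < min_identity || af < min_len_frac) continue;
        if (a.score > best_score ||
            (a.score == best_score && rid < best_ref)) {
          if (a.score == best_score && rid != best_ref) ambiguous = true;
          best_score = a.score; best_ref = rid;
          best_aln = a; best_strand = strand;
        } else if (a.score == best_score && rid != best_ref) {
          ambiguous = true;
        }
      }
    }

    // Seed-miss fallback: a contig with no seed hit anywhere in the panel
    // gets the exact full dynamic program against every reference, so the
    // seeded path makes the same accept/reject decisions as full DP.  In
    // practice seed hits (true or spurious) exist for almost every contig,
    // so this path is rarely taken.
    if (!any_candidate) {
      for (int strand = 0; strand < 2; ++strand) {
        const std::string& q = strand == 0 ? fwd : rev;
        for (int rid = 0; rid < nr; ++rid) {
          Aln a = banded_sw(q, rseq[rid], match, mismatch, gap,
                            0, (int)rseq[rid].size());
          if (!a.valid || a.columns == 0) continue;
          double identity = (double)a.matches / a.columns;
          double af = (double)(a.qe - a.qs) / qlen;
          if (identity < min_identity || af < min_len_frac) continue;
          if (a.score > best_score ||
              (a.score == best_score && rid < best_ref)) {
            if (a.score == best_score && rid != best_ref) ambiguous = true;
            best_score = a.score; best_ref = rid;
            best_aln = a; best_strand = strand;
          } else if (a.score == best_score && rid != best_ref) {
            ambiguous = true;
          }
        }
      }
    }

    if (best_ref >= 0) {
      out_ref[c] = best_ref + 1;
      out_strand[c] = best_strand == 0 ? "+" : "-";
      out_rs[c] = best_aln.rs; out_re[c] = best_aln.re;
      out_score[c] = best_score;
      out_id[c] = (double)best_aln.matches / best_aln.columns;
      out_af[c] = (double)(best_aln.qe - best_aln.qs) /
                  std::max(1, (int)fwd.size());
      out_amb[c] = ambiguous;
      out_colref[c] = IntegerVector(best_aln.col_ref.begin(), best_aln.col_ref.end());
      out_colbase[c] = best_aln.col_base;
    }
  }

  return List::create(
    _["ref"] = out_ref, _["strand"] = out_strand,
    _["r_start"] = out_rs, _["r_end"] = out_re,
    _["score"] = out_score, _["identity"] = out_id,
    _["aligned_fraction"] = out_af, _["ambiguous"] = out_amb,
    _["col_ref"] = out_colref, _["col_base"] = out_colbase);
}

// Best-hit ungapped read placement against the combined reference.  Seeds
// vote for (reference, diagonal) candidates; each candidate is verified by
// direct base comparison over the read/reference overlap.  Reads whose best
// score is shared by two distinct references are discarded as unresolved
// ties.  Non-ACGT reference symbols (N and IUPAC codes from consensus
// extraction) never seed and count as mismatches during verification.
// assignment codes: >0 reference index (1-based), 0 unmapped, -1 tie.
// [[Rcpp::export(name = ".map_reads_cpp")]]
List map_reads_cpp(CharacterVector reads, CharacterVector refs,
                   int k, double min_identity, double min_len_frac) {
  const int nreads = reads.size(), nr = refs.size();
  std::vector<std::string> rseq(nr);
  for (int i = 0; i < nr; ++i) rseq[i] = as<std::string>(refs[i]);
  KmerIndex idx;
  idx.build(rseq, k);

  IntegerVector assign(nreads, 0), astart(nreads, NA_INTEGER);
  IntegerVector counts(nr, 0);
  std::vector<std::vector<bool>> covered(nr);
  for (int i = 0; i < nr; ++i) covered[i].assign(rseq[i].size(), false);
  long long mapped_len_sum = 0;
  int n_mapped = 0, n_tie = 0;

  for (int ri = 0; ri < nreads; ++ri) {
    std::string fwd = as<std::string>(reads[ri]);
    const int rl = (int)fwd.size();
    if (rl == 0) continue;
    std::string rev = revcomp(fwd);

    int best_score = -1, best_ref = -1, best_qs = 0, best_re0 = 0, best_ovl = 0;
    bool tie = false;

    for (int strand = 0; strand < 2; ++strand) {
      const std::string& q = strand == 0 ? fwd : rev;
      std::unordered_map<int64_t, int> votes;
      for_each_kmer(q, k, [&](uint64_t km, int qpos) {
        auto it = idx.map.find(km);
        if (it == idx.map.end()) return;
        for (auto& hit : it->second) {
          int diag = hit.second - qpos;
          int64_t key = ((int64_t)hit.first << 24) | (uint32_t)(diag + (1 << 23));
          ++votes[key];
        }
      });
      for (auto& kv : votes) {
        int rid = (int)(kv.first >> 24);
        int diag = (int)(kv.first & 0xFFFFFF) - (1 << 23);
        const std::string& rs = rseq[rid];
        int qs = std::max(0, -diag);
        int qe = std::min(rl, (int)rs.size() - diag);
        int ovl = qe - qs;
        if (ovl <= 0) continue;
        if ((double)ovl / rl < min_len_frac) continue;
        int matches = 0;
        for (int p = qs; p < qe; ++p)
          if (q[p] == rs[p + diag]) ++matches;
        if ((double)matches / ovl < min_identity) continue;
        if (matches > best_score) {
          best_score = matches; best_ref = rid;
          best_qs = qs + diag; best_re0 = qe + diag; best_ovl = ovl;
          tie = false;
        } else if (matches == best_score && rid != best_ref) {
          tie = true;
        }
      }
    }

    if (best_ref < 0) { assign[ri] = 0; continue; }
    if (tie) { assign[ri] = -1; ++n_tie; continue; }
    assign[ri] = best_ref + 1;
    astart[ri] = best_qs; // 0-based reference start of the overlap
    ++counts[best_ref];
    ++n_mapped;
    mapped_len_sum += rl;
    for (int p = best_qs; p < best_re0; ++p) covered[best_ref][p] = true;
  }

  IntegerVector covlen(nr, 0);
  for (int i = 0; i < nr; ++i)
    covlen[i] = (int)std::count(covered[i].begin(), covered[i].end(), true);

  return List::create(
    _["assignment"] = assign, _["start"] = astart,
    _["counts"] = counts, _["covered_length"] = covlen,
    _["n_mapped"] = n_mapped, _["n_tie"] = n_tie,
    _["mapped_length_sum"] = (double)mapped_len_sum);
}

// Per-base substitution errors at a fixed rate, using R's RNG so results are
// reproducible under set.seed().
// [[Rcpp::export(name = ".mutate_seqs_cpp")]]
CharacterVector mutate_seqs_cpp(CharacterVector seqs, double rate) {
  static const char alt[4][3] = {
    {'C', 'G', 'T'}, {'A', 'G', 'T'}, {'A', 'C', 'T'}, {'A', 'C', 'G'}};
  if (rate <= 0) return clone(seqs);
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    for (size_t p = 0; p < s.size(); ++p) {
      if (unif_rand() < rate) {
        uint64_t b;
        if (!base2bits(s[p], b)) continue;
        s[p] = alt[b][(int)(unif_rand() * 3) % 3];
      }
    }
    out[i] = s;
  }
  return out;
}

// Modified-Mott quality trimming: per-base error probabilities from
// Phred+33 qualities, running score limit - e_i, keep the maximal-scoring
// contiguous segment.  Returns 1-based [start, end]; start > end means the
// whole read is discarded.
// [[Rcpp::export(name = ".mott_bounds_cpp")]]
IntegerMatrix mott_bounds_cpp(CharacterVector quals, double limit) {
  IntegerMatrix out(quals.size(), 2);
  for (int i = 0; i < quals.size(); ++i) {
    std::string q = as<std::string>(quals[i]);
    double run = 0, best = 0;
    int run_start = 0, bs = 1, be = 0; // empty by default
    for (int p = 0; p < (int)q.size(); ++p) {
      double e = std::pow(10.0, -((double)q[p] - 33.0) / 10.0);
      run += limit - e;
      if (run <= 0) { run = 0; run_start = p + 1; continue; }
      if (run > best) { best = run; bs = run_start + 1; be = p + 1; }
    }
    out(i, 0) = bs; out(i, 1) = be;
  }
  return out;
}

// 3' adapter trimming: earliest read position where the remaining suffix
// matches a prefix of the adapter over >= min_match bases with at most
// max_mismatch mismatches.  Returns the number of bases to keep.
// [[Rcpp::export(name = ".adapter_cut_cpp")]]
IntegerVector adapter_cut_cpp(CharacterVector seqs, std::string adapter,
                              int min_match, int max_mismatch) {
  const int al = (int)adapter.size();
  IntegerVector keep(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    const int n = (int)s.size();
    int cut = n;
    for (int p = 0; p + min_match <= n; ++p) {
      int len = std::min(n - p, al);
      int mm = 0;
      bool ok = true;
      for (int j = 0; j < len; ++j) {
        if (s[p + j] != adapter[j] && ++mm > max_mismatch) { ok = false; break; }
      }
      if (ok && len >= min_match) { cut = p; break; }
    }
    keep[i] = cut;
  }
  return keep;
}
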