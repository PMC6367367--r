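// Seed-and-extend read placement engine.
//
// Two modes: full-length ungapped placement against an indexed target set
// (k-mer seeds at pigeonhole offsets guarantee detection of every placement
// with <= max_mm substitutions when floor(len/k) > max_mm), and a clipped
// mode against a single short target (element template) where the read may
// overhang either end, used for element pileups and junction-read capture.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

static inline char comp_base(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.size(), 'N');
  for (size_t i = 0; i < s.size(); ++i)
    r[s.size() - 1 - i] = comp_base(s[i]);
  return r;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

struct KmerIndex {
  std::vector<std::string> targets;
  int k;
  std::unordered_map<uint64_t, std::vector<uint64_t>> map; // kmer -> tgt<<40|pos0
};

// [[Rcpp::export]]
SEXP cpp_index_build(CharacterVector targets, int k) {
  if (k < 4 || k > 31) stop("k must be in [4, 31]");
  XPtr<KmerIndex> ptr(new KmerIndex(), true);
  ptr->k = k;
  ptr->targets.reserve(targets.size());
  for (R_xlen_t t = 0; t < targets.size(); ++t) {
    std::string s = as<std::string>(targets[t]);
    if (s.empty()) stop("empty target sequence");
    ptr->targets.push_back(s);
  }
  const uint64_t mask = (k == 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);
  for (size_t t = 0; t < ptr->targets.size(); ++t) {
    const std::string& s = ptr->targets[t];
    if ((int)s.size() < k) continue;
    uint64_t h = 0;
    int valid = 0;
    for (size_t i = 0; i < s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { valid = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++valid >= k) {
        uint64_t pos0 = i - (size_t)k + 1;
        ptr->map[h].push_back(((uint64_t)t << 40) | pos0);
      }
    }
  }
  return ptr;
}

// [[Rcpp::export]]
IntegerVector cpp_index_info(SEXP xp) {
  XPtr<KmerIndex> ptr(xp);
  return IntegerVector::create(_["k"] = ptr->k,
                               _["n_targets"] = (int)ptr->targets.size());
}

// Count substitutions between read (oriented) and target at offset s0,
// stopping once the count exceeds `cap`.
static inline int count_mm(const std::string& seq, const std::string& tgt,
                           long s0, int cap) {
  int mm = 0;
  const size_t len = seq.size();
  for (size_t i = 0; i < len; ++i) {
    char a = seq[i], b = tgt[s0 + i];
    if (a != b || base_code(a) < 0) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_align_full(SEXP xp, CharacterVector reads, int max_mm) {
  XPtr<KmerIndex> ptr(xp);
  const int k = ptr->k;
  std::vector<int> o_read, o_tgt, o_pos, o_mm, o_nbest, o_second;
  std::vector<int> o_strand; // 0 = +, 1 = -

  std::vector<int64_t> cands;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const int len = (int)fwd.size();
    if (len < k) continue;
    int best = max_mm + 1, second = max_mm + 1, nbest = 0;
    int bt = -1; long bp = -1; int bs = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string seq = strand ? revcomp(fwd) : fwd;
      cands.clear();
      const uint64_t mask = (1ULL << (2 * k)) - 1;
      // seeds at offsets 0, k, 2k, ... plus the 3'-anchored len-k
      std::vector<int> offsets;
      for (int off = 0; off + k <= len; off += k) offsets.push_back(off);
      if (offsets.empty() || offsets.back() != len - k)
        offsets.push_back(len - k);
      for (int o : offsets) {
        uint64_t h = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          int c = base_code(seq[o + i]);
          if (c < 0) { ok = false; break; }
          h = ((h << 2) | (uint64_t)c) & mask;
        }
        if (!ok) continue;
        auto it = ptr->map.find(h);
        if (it == ptr->map.end()) continue;
        for (uint64_t packed : it->second) {
          int t = (int)(packed >> 40);
          long pos0 = (long)(packed & ((1ULL << 40) - 1));
          long s0 = pos0 - o;
          if (s0 < 0) continue;
          if (s0 + len > (long)ptr->targets[t].size()) continue;
          cands.push_back(((int64_t)t << 40) | s0);
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (int64_t c : cands) {
        int t = (int)(c >> 40);
        long s0 = (long)(c & ((1LL << 40) - 1));
        int mm = count_mm(seq, ptr->targets[t], s0, max_mm);
        if (mm > max_mm) continue;
        if (mm < best) {
          second = best; best = mm; nbest = 1;
          bt = t; bp = s0; bs = strand;
        } else if (mm == best) {
          ++nbest;
          if (mm < second) second = mm;
        } else if (mm < second) {
          second = mm;
        }
      }
    }
    if (best <= max_mm) {
      o_read.push_back((int)r + 1);
      o_tgt.push_back(bt + 1);
      o_pos.push_back((int)bp + 1);
      o_strand.push_back(bs);
      o_mm.push_back(best);
      o_nbest.push_back(nbest);
      o_second.push_back(second);
    }
  }
  return List::create(_["read"] = wrap(o_read), _["target"] = wrap(o_tgt),
                      _["start"] = wrap(o_pos), _["strand"] = wrap(o_strand),
                      _["mismatches"] = wrap(o_mm), _["n_best"] = wrap(o_nbest),
                      _["second_mm"] = wrap(o_second));
}

// Clipped placement against a single target: the read may overhang either
// target end; mismatches are counted over the overlap only.
// [[Rcpp::export]]
List cpp_align_clip(CharacterVector reads, std::string target,
                    int max_mm, int min_overlap) {
  const long tlen = (long)target.size();
  if (tlen == 0) stop("empty target sequence");
  // prefilter holds 12-mers of the target AND its reverse complement, so a
  // single forward scan of each read decides whether any strand can match
  const int pk = 12;
  std::unordered_set<uint32_t> pre;
  if (tlen >= pk) {
    std::string trc = revcomp(target);
    for (int v = 0; v < 2; ++v) {
      const std::string& s = v ? trc : target;
      uint32_t h = 0; int valid = 0;
      const uint32_t pmask = (1u << (2 * pk)) - 1;
      for (long i = 0; i < tlen; ++i) {
        int c = base_code(s[i]);
        if (c < 0) { valid = 0; h = 0; continue; }
        h = ((h << 2) | (uint32_t)c) & pmask;
        if (++valid >= pk) pre.insert(h);
      }
    }
  }
  std::vector<int> o_read, o_start, o_strand, o_mm, o_ovs, o_ove, o_lclip, o_rclip;
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string fwd = as<std::string>(reads[r]);
    const long len = (long)fwd.size();
    if (len < min_overlap) continue;
    // strand-agnostic prefilter on the forward read
    bool hit = false;
    if ((long)pre.size() > 0 && len >= pk) {
      const uint32_t pmask = (1u << (2 * pk)) - 1;
      for (long o = 0; o + pk <= len && !hit; o += 4) {
        uint32_t h = 0; bool ok = true;
        for (int i = 0; i < pk; ++i) {
          int c = base_code(fwd[o + i]);
          if (c < 0) { ok = false; break; }
          h = ((h << 2) | (uint32_t)c) & pmask;
        }
        if (ok && pre.count(h)) hit = true;
      }
      if (!hit) {
        long o = len - pk;  // final 12-mer so 3' overhangs are not missed
        uint32_t h = 0; bool ok = true;
        for (int i = 0; i < pk; ++i) {
          int c = base_code(fwd[o + i]);
          if (c < 0) { ok = false; break; }
          h = ((h << 2) | (uint32_t)c) & pmask;
        }
        if (ok && pre.count(h)) hit = true;
      }
    } else {
      hit = true; // tiny target: no prefilter
    }
    if (!hit) continue;
    int best_score = -1, best_mm = 0, best_strand = 0;
    long best_s = 0, best_a = 0, best_b = 0;
    for (int strand = 0; strand < 2; ++strand) {
      std::string seq = strand ? revcomp(fwd) : fwd;
      for (long s = -(len - min_overlap); s <= tlen - min_overlap; ++s) {
        long a = s < 0 ? -s : 0;
        long b = std::min(len, tlen - s);
        long ov = b - a;
        if (ov < min_overlap) continue;
        int mm = 0; bool bad = false;
        for (long i = a; i < b; ++i) {
          char x = seq[i], y = target[s + i];
          if (x != y || base_code(x) < 0) {
            if (++mm > max_mm) { bad = true; break; }
          }
        }
        if (bad) continue;
        int score = (int)ov - mm;
        if (score > best_score) {
          best_score = score; best_mm = mm; best_strand = strand;
          best_s = s; best_a = a; best_b = b;
        }
      }
    }
    if (best_score >= 0) {
      o_read.push_back((int)r + 1);
      o_start.push_back((int)best_s + 1);
      o_strand.push_back(best_strand);
      o_mm.push_back(best_mm);
      o_ovs.push_back((int)(best_s + best_a) + 1);
      o_ove.push_back((int)(best_s + best_b));
      o_lclip.push_back((int)best_a);
      o_rclip.push_back((int)(len - best_b));
    }
  }
  return List::create(_["read"] = wrap(o_read), _["start"] = wrap(o_start),
                      _["strand"] = wrap(o_strand), _["mismatches"] = wrap(o_mm),
                      _["ov_start"] = wrap(o_ovs), _["ov_end"] = wrap(o_ove),
                      _["left_clip"] = wrap(o_lclip), _["right_clip"] = wrap(o_rclip));
}

// Per-position depth and base counts. `seqs` are the oriented overlap
// substrings, `starts1` their 1-based target start positions. Reads are
// processed in order; positions already at `depth_cap` stop accumulating,
// mirroring a capped pileup.
// [[Rcpp::export]]
List cpp_pileup(CharacterVector seqs, IntegerVector starts1, int tlen,
                int depth_cap) {
  IntegerMatrix counts(5, tlen);
  IntegerVector depth(tlen);
  for (R_xlen_t r = 0; r < seqs.size(); ++r) {
    std::string s = as<std::string>(seqs[r]);
    long st = starts1[r] - 1;
    if (st < 0 || st + (long)s.size() > tlen)
      stop("alignment exceeds target bounds");
    for (size_t i = 0; i < s.size(); ++i) {
      long p = st + i;
      if (depth[p] >= depth_cap) continue;
      int c = base_code(s[i]);
      counts(c < 0 ? 4 : c, p) += 1;
      depth[p] += 1;
    }
  }
  return List::create(_["counts"] = counts, _["depth"] = depth);
}
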