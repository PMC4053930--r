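// Minimal seed-and-extend read mapper: exact seed index over the reference,
// ungapped extension, best hit by match count, ties -> unmapped. Mapping is
// plumbing here; the similarity / length-fraction filters are the interface
// that matters.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <algorithm>

using namespace Rcpp;

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp(c);
  return r;
}

struct Hit { int ref; int pos; };  // pos = implied 0-based start of the read

// [[Rcpp::export]]
DataFrame cpp_map_reads(CharacterVector reads, CharacterVector refs,
                        int seed_len, double min_similarity,
                        double min_len_frac, int max_seed_hits) {
  int nref = refs.size();
  std::vector<std::string> R(nref);
  for (int i = 0; i < nref; ++i) R[i] = as<std::string>(refs[i]);
  if (nref == 0) stop("empty assembly: no reference sequences to map against");

  std::unordered_map<std::string, std::vector<Hit>> index;
  index.reserve(1 << 20);
  for (int r = 0; r < nref; ++r) {
    int L = (int)R[r].size();
    for (int p = 0; p + seed_len <= L; ++p) {
      bool ok = true;
      for (int q = p; q < p + seed_len; ++q) {
        char c = R[r][q];
        if (c != 'A' && c != 'C' && c != 'G' && c != 'T') { ok = false; break; }
      }
      if (!ok) continue;
      index[R[r].substr(p, seed_len)].push_back({r, p});
    }
  }

  int n = reads.size();
  IntegerVector o_ref(n), o_pos(n), o_start(n), o_matches(n), o_alen(n),
      o_nm(n);
  LogicalVector o_mapped(n);
  CharacterVector o_strand(n);

  for (int i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int L = (int)fwd.size();
    std::string rev = revcomp(fwd);
    int best_score = -1, best_count = 0;
    int b_ref = -1, b_pos = -1, b_start = 0, b_matches = 0, b_alen = 0;
    char b_strand = '+';
    // candidate alignment starts, deduped per strand
    for (int st = 0; st < 2; ++st) {
      const std::string& rd = (st == 0) ? fwd : rev;
      std::vector<long long> cand;
      int noff = 4;
      for (int t = 0; t < noff; ++t) {
        int off = (L - seed_len) * t / (noff - 1 > 0 ? noff - 1 : 1);
        if (off < 0) off = 0;
        if (off + seed_len > L) break;
        auto it = index.find(rd.substr(off, seed_len));
        if (it == index.end()) continue;
        if ((int)it->second.size() > max_seed_hits) continue;  // repeat seed
        for (const Hit& h : it->second)
          cand.push_back((long long)h.ref * 100000000LL + (h.pos - off) + 1000000LL);
      }
      std::sort(cand.begin(), cand.end());
      cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
      for (long long c : cand) {
        int ref = (int)(c / 100000000LL);
        int start = (int)(c % 100000000LL) - 1000000;
        int rl = (int)R[ref].size();
        int a0 = std::max(0, start), a1 = std::min(rl, start + L);
        int alen = a1 - a0;
        if (alen <= 0) continue;
        int matches = 0;
        for (int p = a0; p < a1; ++p)
          if (R[ref][p] == rd[p - start] && R[ref][p] != 'N') ++matches;
        if (matches > best_score) {
          best_score = matches; best_count = 1;
          b_ref = ref; b_pos = a0; b_start = start; b_matches = matches;
          b_alen = alen;
          b_strand = (st == 0) ? '+' : '-';
        } else if (matches == best_score) {
          // same location found twice via different seeds counts once
          if (!(ref == b_ref && a0 == b_pos &&
                b_strand == ((st == 0) ? '+' : '-')))
            ++best_count;
        }
      }
    }
    bool ok = best_score >= 0 && best_count == 1;
    if (ok) {
      double sim = (double)b_matches / b_alen;
      double lf = (double)b_alen / L;
      if (sim < min_similarity || lf < min_len_frac) ok = false;
    }
    o_mapped[i] = ok;
    if (ok) {
      o_ref[i] = b_ref + 1; o_pos[i] = b_pos; o_start[i] = b_start;
      o_matches[i] = b_matches;
      o_alen[i] = b_alen; o_nm[i] = b_alen - b_matches;
      o_strand[i] = std::string(1, b_strand);
    } else {
      o_ref[i] = NA_INTEGER; o_pos[i] = NA_INTEGER; o_start[i] = NA_INTEGER;
      o_matches[i] = NA_INTEGER;
      o_alen[i] = NA_INTEGER; o_nm[i] = NA_INTEGER; o_strand[i] = NA_STRING;
    }
  }
  return DataFrame::create(_["mapped"] = o_mapped, _["ref"] = o_ref,
                           _["pos"] = o_pos, _["start"] = o_start,
                           _["strand"] = o_strand,
                           _["matches"] = o_matches, _["aligned_len"] = o_alen,
                           _["nm"] = o_nm,
                           _["stringsAsFactors"] = false);
}
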