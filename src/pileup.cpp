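// Per-site base counting from ungapped alignments, with the optional
// neighbourhood-quality rule used by the pooled SNP caller: a read base
// supports a site only if every base of that read inside the centred
// window meets the quality threshold.

#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static inline int base_idx(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3;
    default:  return -1;
  }
}

// aln_*: one row per mapped read, already oriented to the reference strand
// (sequence and quality reversed/complemented as needed by the caller).
// ref_len: lengths of the reference sequences.  window = 1 checks the
// central base only; window = 0 disables quality checking entirely.
// Returns a list (one entry per reference) of 4 x len integer matrices.
// [[Rcpp::export]]
List cpp_pileup(IntegerVector ref_len, IntegerVector aln_ref,
                IntegerVector aln_pos, CharacterVector aln_seq,
                CharacterVector aln_qual, int min_qual, int window,
                int qual_offset) {
  int nref = ref_len.size();
  std::vector<IntegerMatrix> mats;
  for (int r = 0; r < nref; ++r) mats.push_back(IntegerMatrix(4, ref_len[r]));

  int n = aln_ref.size();
  int w2 = window > 0 ? (window - 1) / 2 : 0;
  for (int i = 0; i < n; ++i) {
    int r = aln_ref[i] - 1;
    int p0 = aln_pos[i];
    std::string s = as<std::string>(aln_seq[i]);
    int L = (int)s.size();
    std::vector<int> lowq_prefix;
    bool have_qual = window > 0 && aln_qual[i] != NA_STRING;
    std::string q;
    if (have_qual) {
      q = as<std::string>(aln_qual[i]);
      lowq_prefix.assign(L + 1, 0);
      for (int j = 0; j < L; ++j)
        lowq_prefix[j + 1] =
            lowq_prefix[j] + ((int)q[j] - qual_offset < min_qual ? 1 : 0);
    }
    IntegerMatrix& M = mats[r];
    int rl = ref_len[r];
    for (int j = 0; j < L; ++j) {
      int rp = p0 + j;
      if (rp < 0 || rp >= rl) continue;
      int b = base_idx(s[j]);
      if (b < 0) continue;
      if (have_qual) {
        int lo = std::max(0, j - w2), hi = std::min(L - 1, j + w2);
        if (lowq_prefix[hi + 1] - lowq_prefix[lo] > 0) continue;
      }
      ++M(b, rp);
    }
  }
  List out(nref);
  for (int r = 0; r < nref; ++r) out[r] = mats[r];
  return out;
}
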