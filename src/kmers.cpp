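// de Bruijn substrate: canonical k-mer counting and unitig compaction.
// Strings are used as keys throughout so any k up to the read length works.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <set>
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

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    out[i] = revcomp(s);
  }
  return out;
}

static inline bool valid_acgt(const std::string& s, size_t from, size_t len) {
  for (size_t i = from; i < from + len; ++i) {
    char c = s[i];
    if (c != 'A' && c != 'C' && c != 'G' && c != 'T') return false;
  }
  return true;
}

// 2-bit packing helpers for the fast path (k+1 <= 32)
static inline int code2(char c) {
  switch (c) { case 'A': return 0; case 'C': return 1;
               case 'G': return 2; case 'T': return 3; default: return -1; }
}
static inline uint64_t rc_bits(uint64_t x, int k) {
  // complement then reverse 2-bit fields
  x = ~x;
  x = ((x & 0x3333333333333333ULL) << 2) | ((x >> 2) & 0x3333333333333333ULL);
  x = ((x & 0x0F0F0F0F0F0F0F0FULL) << 4) | ((x >> 4) & 0x0F0F0F0F0F0F0F0FULL);
  x = ((x & 0x00FF00FF00FF00FFULL) << 8) | ((x >> 8) & 0x00FF00FF00FF00FFULL);
  x = ((x & 0x0000FFFF0000FFFFULL) << 16) | ((x >> 16) & 0x0000FFFF0000FFFFULL);
  x = (x << 32) | (x >> 32);
  return x >> (64 - 2 * k);
}
static std::string decode_bits(uint64_t x, int k) {
  static const char b[] = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) { s[i] = b[x & 3]; x >>= 2; }
  return s;
}

// roll over a sequence calling f(pos, packed) for every valid k-mer
template <typename F>
static void roll_kmers(const std::string& s, int k, F f) {
  int L = (int)s.size();
  uint64_t cur = 0, mask = (k < 32) ? ((1ULL << (2 * k)) - 1) : ~0ULL;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int c = code2(s[i]);
    if (c < 0) { run = 0; cur = 0; continue; }
    cur = ((cur << 2) | (uint64_t)c) & mask;
    if (++run >= k) f(i - k + 1, cur);
  }
}

// Count canonical k-mers and record observed (k+1)-mers (canonical) that
// support edges. k-mers spanning N are skipped; other characters error.
// A 2-bit rolling encoding is used when k+1 fits in 64 bits (k <= 31);
// larger k falls back to string keys.
// [[Rcpp::export]]
List cpp_count_kmers(CharacterVector reads, int k, int min_mult) {
  std::unordered_map<std::string, int> kc;
  std::unordered_set<std::string> ec;
  std::unordered_map<uint64_t, int> kcb;
  std::unordered_set<uint64_t> ecb;
  bool packed = (k + 1) <= 32;
  kc.reserve(1 << 16); ec.reserve(1 << 16);
  if (packed) { kcb.reserve(1 << 20); ecb.reserve(1 << 20); }
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string s = as<std::string>(reads[r]);
    for (auto& c : s) {
      c = std::toupper(c);
      if (c != 'A' && c != 'C' && c != 'G' && c != 'T' && c != 'N')
        stop("non-ACGTN character '%s' in read %d", std::string(1, c).c_str(),
             (int)(r + 1));
    }
    int L = (int)s.size();
    if (L < k) stop("read %d is shorter than k = %d", (int)(r + 1), k);
    if (packed) {
      roll_kmers(s, k, [&](int, uint64_t x) {
        uint64_t rc = rc_bits(x, k);
        ++kcb[x < rc ? x : rc];
      });
      roll_kmers(s, k + 1, [&](int, uint64_t x) {
        uint64_t rc = rc_bits(x, k + 1);
        ecb.insert(x < rc ? x : rc);
      });
    } else {
      for (int i = 0; i + k <= L; ++i) {
        if (!valid_acgt(s, i, k)) continue;
        std::string km = s.substr(i, k);
        std::string rc = revcomp(km);
        ++kc[km < rc ? km : rc];
      }
      for (int i = 0; i + k + 1 <= L; ++i) {
        if (!valid_acgt(s, i, k + 1)) continue;
        std::string em = s.substr(i, k + 1);
        std::string rc = revcomp(em);
        ec.insert(em < rc ? em : rc);
      }
    }
  }
  if (packed) {
    // decode into the string maps; canonical form by string comparison
    // (2-bit packing orders A<C<G<T consistently with lexicographic order)
    for (auto& p : kcb) kc[decode_bits(p.first, k)] = p.second;
    for (auto& e : ecb) ec.insert(decode_bits(e, k + 1));
    kcb.clear(); ecb.clear();
  }
  // prune nodes below min_mult, then edges whose endpoints were pruned
  std::vector<std::string> kms;
  std::vector<int> cnts;
  kms.reserve(kc.size());
  for (auto& p : kc) {
    if (p.second >= min_mult) { kms.push_back(p.first); cnts.push_back(p.second); }
  }
  std::unordered_set<std::string> keep(kms.begin(), kms.end());
  std::vector<std::string> edges;
  edges.reserve(ec.size());
  for (auto& e : ec) {
    std::string a = e.substr(0, k), b = e.substr(1, k);
    std::string ca = revcomp(a); if (ca > a) ca = a;
    std::string cb = revcomp(b); if (cb > b) cb = b;
    if (keep.count(ca) && keep.count(cb)) edges.push_back(e);
  }
  std::sort(kms.begin(), kms.end());
  std::sort(edges.begin(), edges.end());
  // counts must follow the sort
  std::vector<int> cnts2(kms.size());
  for (size_t i = 0; i < kms.size(); ++i) cnts2[i] = kc[kms[i]];
  return List::create(_["kmer"] = wrap(kms), _["count"] = wrap(cnts2),
                      _["edge"] = wrap(edges));
}

// Oriented-node bookkeeping for compaction. Node = canonical k-mer index;
// orientation 0 = canonical (forward), 1 = reverse complement.
struct ONode { int id; int o; };

// [[Rcpp::export]]
List cpp_assemble_unitigs(CharacterVector kmers, IntegerVector counts,
                          CharacterVector edges, int k) {
  int n = kmers.size();
  std::unordered_map<std::string, int> idx;
  idx.reserve(n * 2);
  std::vector<std::string> kv(n);
  for (int i = 0; i < n; ++i) { kv[i] = as<std::string>(kmers[i]); idx[kv[i]] = i; }

  // oriented adjacency: out[2*i + o] -> list of (node, orientation)
  std::vector<std::vector<ONode>> out(2 * (size_t)n);
  auto lookup = [&](const std::string& s, int& id, int& o) -> bool {
    std::string rc = revcomp(s);
    const std::string& canon = (s < rc) ? s : rc;
    auto it = idx.find(canon);
    if (it == idx.end()) return false;
    id = it->second;
    o = (s <= rc) ? 0 : 1;
    return true;
  };
  for (R_xlen_t e = 0; e < edges.size(); ++e) {
    std::string em = as<std::string>(edges[e]);
    for (int rep = 0; rep < 2; ++rep) {  // both strands of the (k+1)-mer
      std::string a = em.substr(0, k), b = em.substr(1, k);
      int ia, oa, ib, ob;
      if (lookup(a, ia, oa) && lookup(b, ib, ob))
        out[2 * (size_t)ia + oa].push_back({ib, ob});
      std::string rc = revcomp(em);
      if (rc == em) break;  // palindromic (k+1)-mer: one strand only
      em = rc;
    }
  }
  // dedupe adjacency lists
  for (auto& v : out) {
    std::sort(v.begin(), v.end(), [](const ONode& x, const ONode& y) {
      return x.id != y.id ? x.id < y.id : x.o < y.o;
    });
    v.erase(std::unique(v.begin(), v.end(), [](const ONode& x, const ONode& y) {
      return x.id == y.id && x.o == y.o;
    }), v.end());
  }
  auto outdeg = [&](int id, int o) { return (int)out[2 * (size_t)id + o].size(); };
  auto indeg = [&](int id, int o) { return outdeg(id, 1 - o); };
  auto succ = [&](int id, int o) { return out[2 * (size_t)id + o][0]; };

  std::vector<char> used(n, 0);
  // per-kmer placement: unitig id, position along unitig, orientation in unitig
  std::vector<int> uid(n, -1), upos(n, -1), uork(n, 0);
  std::vector<std::string> seqs;
  std::vector<double> covs;

  for (int s0 = 0; s0 < n; ++s0) {
    if (used[s0]) continue;
    // walk backward from (s0, forward) to a path start
    ONode cur{s0, 0};
    std::unordered_set<long long> seen;
    seen.insert((long long)cur.id * 2 + cur.o);
    while (indeg(cur.id, cur.o) == 1) {
      ONode pr = succ(cur.id, 1 - cur.o);
      ONode prev{pr.id, 1 - pr.o};  // predecessor in forward sense
      if (outdeg(prev.id, prev.o) != 1) break;
      if (used[prev.id]) break;
      long long key = (long long)prev.id * 2 + prev.o;
      if (seen.count(key)) break;  // cycle
      seen.insert(key);
      cur = prev;
    }
    // walk forward collecting the maximal non-branching path
    std::vector<ONode> path;
    path.push_back(cur);
    used[cur.id] = 1;
    while (true) {
      ONode& last = path.back();
      if (outdeg(last.id, last.o) != 1) break;
      ONode nx = succ(last.id, last.o);
      if (used[nx.id]) break;
      if (indeg(nx.id, nx.o) != 1) break;
      path.push_back(nx);
      used[nx.id] = 1;
    }
    // build sequence
    std::string sq = path[0].o == 0 ? kv[path[0].id] : revcomp(kv[path[0].id]);
    double cov = counts[path[0].id];
    for (size_t i = 1; i < path.size(); ++i) {
      std::string km = path[i].o == 0 ? kv[path[i].id] : revcomp(kv[path[i].id]);
      sq.push_back(km[k - 1]);
      cov += counts[path[i].id];
    }
    cov /= path.size();
    // canonical orientation: min(seq, revcomp)
    std::string rc = revcomp(sq);
    bool flip = rc < sq;
    if (flip) sq = rc;
    int id = (int)seqs.size();
    int m = (int)path.size();
    for (int i = 0; i < m; ++i) {
      int pos = flip ? (m - 1 - i) : i;
      int ork = flip ? (1 - path[i].o) : path[i].o;
      uid[path[i].id] = id; upos[path[i].id] = pos; uork[path[i].id] = ork;
    }
    seqs.push_back(sq);
    covs.push_back(cov);
  }

  // sort unitigs by sequence for read-order independence
  int nu = (int)seqs.size();
  std::vector<int> ord(nu);
  for (int i = 0; i < nu; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) { return seqs[a] < seqs[b]; });
  std::vector<int> rank(nu);
  for (int i = 0; i < nu; ++i) rank[ord[i]] = i;
  std::vector<int> ulen(nu);

  // unitig-level oriented edges from boundary k-mer adjacencies
  std::set<std::pair<int,int>> uedges;
  for (int i = 0; i < n; ++i) {
    for (int o = 0; o < 2; ++o) {
      for (const ONode& t : out[2 * (size_t)i + o]) {
        int ua = uid[i], ub = uid[t.id];
        int la = (int)seqs[ua].size() - k + 1;
        int lb = (int)seqs[ub].size() - k + 1;
        int from = 0, to = 0;
        if (o == uork[i] && upos[i] == la - 1) from = rank[ua] + 1;
        else if (o != uork[i] && upos[i] == 0) from = -(rank[ua] + 1);
        else continue;
        if (t.o == uork[t.id] && upos[t.id] == 0) to = rank[ub] + 1;
        else if (t.o != uork[t.id] && upos[t.id] == lb - 1) to = -(rank[ub] + 1);
        else continue;
        // interior adjacencies (consecutive kmers of one unitig) fail the
        // boundary tests above; what remains are genuine unitig-level edges,
        // including loops back into the same unitig.
        uedges.insert({from, to});
      }
    }
  }
  // drop edges that are internal to a unitig (consecutive kmers): those were
  // skipped by the boundary test above unless the unitig has length 1 kmer.
  std::vector<std::string> oseqs(nu);
  std::vector<double> ocovs(nu);
  for (int i = 0; i < nu; ++i) { oseqs[rank[i]] = seqs[i]; ocovs[rank[i]] = covs[i]; }

  IntegerVector ef(uedges.size()), et(uedges.size());
  int j = 0;
  for (auto& e : uedges) { ef[j] = e.first; et[j] = e.second; ++j; }
  return List::create(_["seq"] = wrap(oseqs), _["cov"] = wrap(ocovs),
                      _["edge_from"] = ef, _["edge_to"] = et);
}
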