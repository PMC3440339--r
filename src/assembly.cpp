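// de Bruijn graph core: canonical k-mer counting, adjacency collection,
// tip clipping and unitig compression. Nodes are canonical k-mers
// (lexicographic min of the k-mer and its reverse complement); edges are
// strand-aware (k-1)-overlaps observed between consecutive read k-mers.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <deque>
using namespace Rcpp;

static inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// 2-bit packed k-mers (A=0, C=1, G=2, T=3; first base most significant),
// so integer order equals lexicographic order and a rolling update costs
// O(1) per position. __uint128_t supports k up to 63.
typedef unsigned __int128 kmer_t;

struct KmerHash {
  size_t operator()(kmer_t x) const {
    uint64_t lo = (uint64_t)x, hi = (uint64_t)(x >> 64);
    return std::hash<uint64_t>()(lo ^ (hi * 0x9e3779b97f4a7c15ULL));
  }
};

static inline int base_code(char c) {
  switch (c) {
  case 'A': return 0;
  case 'C': return 1;
  case 'G': return 2;
  case 'T': return 3;
  default:  return -1;
  }
}

static std::string decode_kmer(kmer_t x, int k) {
  static const char* b = "ACGT";
  std::string s(k, 'A');
  for (int i = k - 1; i >= 0; --i) {
    s[i] = b[(int)(x & 3)];
    x >>= 2;
  }
  return s;
}

// iterate the valid k-mers of a read, calling f(pos, canonical, is_fwd)
template <typename F>
static void for_kmers(const std::string& rd, int k, F f) {
  int L = (int)rd.size();
  kmer_t fwd = 0, rc = 0;
  const kmer_t mask = (k == 64) ? ~(kmer_t)0 : (((kmer_t)1 << (2 * k)) - 1);
  int run = 0; // consecutive valid bases ending here
  for (int i = 0; i < L; ++i) {
    int c = base_code(rd[i]);
    if (c < 0) { run = 0; fwd = 0; rc = 0; continue; }
    fwd = ((fwd << 2) | (kmer_t)c) & mask;
    rc = (rc >> 2) | ((kmer_t)(3 - c) << (2 * (k - 1)));
    if (++run >= k) {
      bool is_fwd = fwd <= rc;
      f(i - k + 1, is_fwd ? fwd : rc, is_fwd);
    }
  }
}

// [[Rcpp::export]]
List cpp_build_graph(CharacterVector reads, int k) {
  if (k < 1 || k > 63) stop("k must be between 1 and 63");
  std::unordered_map<kmer_t, int, KmerHash> counts;
  // pass 1: multiplicities
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    if ((int)rd.size() < k)
      stop("all reads must be at least k nucleotides long");
    for_kmers(rd, k, [&](int, kmer_t can, bool) { counts[can] += 1; });
  }
  std::vector<kmer_t> keys;
  keys.reserve(counts.size());
  for (auto& p : counts) keys.push_back(p.first);
  std::sort(keys.begin(), keys.end()); // integer order == lexicographic
  std::unordered_map<kmer_t, int, KmerHash> idx;
  for (int i = 0; i < (int)keys.size(); ++i) idx[keys[i]] = i;

  // pass 2: unique oriented adjacencies, canonicalised so that an edge and
  // its reverse-complement traversal are stored once
  std::unordered_set<uint64_t> seen;
  std::vector<int> ef, et;
  std::vector<int> efo, eto; // 1 = canonical string used forward
  for (R_xlen_t r = 0; r < reads.size(); ++r) {
    std::string rd = as<std::string>(reads[r]);
    int prev = -1, prev_pos = -2; bool prev_fwd = true;
    for_kmers(rd, k, [&](int pos, kmer_t can, bool fwd) {
      int cur = idx[can];
      if (prev >= 0 && prev_pos == pos - 1) {
        uint32_t a = 2u * (uint32_t)prev + (prev_fwd ? 1u : 0u);
        uint32_t b = 2u * (uint32_t)cur + (fwd ? 1u : 0u);
        // reverse traversal: (cur, !fwd) -> (prev, !prev_fwd)
        uint32_t ra = 2u * (uint32_t)cur + (fwd ? 0u : 1u);
        uint32_t rb = 2u * (uint32_t)prev + (prev_fwd ? 0u : 1u);
        uint64_t key1 = ((uint64_t)a << 32) | b;
        uint64_t key2 = ((uint64_t)ra << 32) | rb;
        uint64_t key = std::min(key1, key2);
        if (seen.insert(key).second) {
          uint32_t u = (uint32_t)(key >> 32), v = (uint32_t)(key & 0xffffffffu);
          ef.push_back((int)(u >> 1) + 1);
          efo.push_back((int)(u & 1u));
          et.push_back((int)(v >> 1) + 1);
          eto.push_back((int)(v & 1u));
        }
      }
      prev = cur; prev_fwd = fwd; prev_pos = pos;
    });
  }
  // deterministic edge order
  int ne = (int)ef.size();
  std::vector<int> ord(ne);
  for (int i = 0; i < ne; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (ef[a] != ef[b]) return ef[a] < ef[b];
    if (efo[a] != efo[b]) return efo[a] < efo[b];
    if (et[a] != et[b]) return et[a] < et[b];
    return eto[a] < eto[b];
  });
  IntegerVector from(ne), to(ne);
  LogicalVector from_fwd(ne), to_fwd(ne);
  for (int i = 0; i < ne; ++i) {
    from[i] = ef[ord[i]]; to[i] = et[ord[i]];
    from_fwd[i] = efo[ord[i]] == 1; to_fwd[i] = eto[ord[i]] == 1;
  }
  IntegerVector cnt(keys.size());
  CharacterVector km(keys.size());
  for (int i = 0; i < (int)keys.size(); ++i) {
    km[i] = decode_kmer(keys[i], k);
    cnt[i] = counts[keys[i]];
  }
  return List::create(_["kmer"] = km, _["count"] = cnt,
                      _["edge_from"] = from, _["edge_to"] = to,
                      _["edge_from_fwd"] = from_fwd, _["edge_to_fwd"] = to_fwd);
}

// ---- unitig machinery ------------------------------------------------------

struct Adj {
  // out[2*u + o]: oriented successors encoded 2*v + vo, o/vo: 1 = forward
  std::vector<std::vector<int>> out;
  Adj(int n) : out(2 * (size_t)n) {}
  void add(int u, int uo, int v, int vo) {
    out[2 * (size_t)u + uo].push_back(2 * v + vo);
  }
  void finalize() {
    for (auto& v : out) {
      std::sort(v.begin(), v.end());
      v.erase(std::unique(v.begin(), v.end()), v.end());
    }
  }
};

static int unique_succ(const Adj& adj, const std::vector<char>& alive,
                       int u, int uo) {
  const auto& lst = adj.out[2 * (size_t)u + uo];
  int found = -1;
  for (int enc : lst) {
    if (!alive[enc >> 1]) continue;
    if (found >= 0) return -2; // ambiguous
    found = enc;
  }
  return found; // -1 dead end, else encoded successor
}

static int out_degree(const Adj& adj, const std::vector<char>& alive,
                      int u, int uo) {
  int d = 0;
  for (int enc : adj.out[2 * (size_t)u + uo])
    if (alive[enc >> 1]) ++d;
  return d;
}

// maximal non-branching oriented paths over alive nodes; deterministic
// because nodes are scanned in lexicographic (input) order
static std::vector<std::vector<std::pair<int,int>>> find_unitigs(
    const Adj& adj, const std::vector<char>& alive, int n) {
  std::vector<char> visited(n, 0);
  std::vector<std::vector<std::pair<int,int>>> paths;
  for (int u = 0; u < n; ++u) {
    if (!alive[u] || visited[u]) continue;
    std::deque<std::pair<int,int>> path;
    path.push_back({u, 1});
    visited[u] = 1;
    // right extension
    int cu = u, co = 1;
    while (true) {
      int enc = unique_succ(adj, alive, cu, co);
      if (enc < 0) break;
      int v = enc >> 1, vo = enc & 1;
      // backwards uniqueness: (v,!vo) must see exactly one alive successor
      if (unique_succ(adj, alive, v, vo ^ 1) < 0) break;
      if (visited[v]) break;
      path.push_back({v, vo});
      visited[v] = 1;
      cu = v; co = vo;
    }
    // left extension (walk the reverse orientation, prepend flipped)
    cu = u; co = 0;
    while (true) {
      int enc = unique_succ(adj, alive, cu, co);
      if (enc < 0) break;
      int v = enc >> 1, vo = enc & 1;
      if (unique_succ(adj, alive, v, vo ^ 1) < 0) break;
      if (visited[v]) break;
      path.push_front({v, vo ^ 1});
      visited[v] = 1;
      cu = v; co = vo;
    }
    paths.push_back(std::vector<std::pair<int,int>>(path.begin(), path.end()));
  }
  return paths;
}

// [[Rcpp::export]]
List cpp_unitigs(CharacterVector kmer, IntegerVector count,
                 IntegerVector edge_from, IntegerVector edge_to,
                 LogicalVector edge_from_fwd, LogicalVector edge_to_fwd,
                 int k, double tip_clip_len, int min_contig_len) {
  int n = (int)kmer.size();
  std::vector<std::string> kms(n);
  for (int i = 0; i < n; ++i) kms[i] = as<std::string>(kmer[i]);
  Adj adj(n);
  for (R_xlen_t e = 0; e < edge_from.size(); ++e) {
    int u = edge_from[e] - 1, v = edge_to[e] - 1;
    int uo = edge_from_fwd[e] ? 1 : 0, vo = edge_to_fwd[e] ? 1 : 0;
    adj.add(u, uo, v, vo);
    adj.add(v, vo ^ 1, u, uo ^ 1);
  }
  adj.finalize();
  std::vector<char> alive(n, 1);

  // median multiplicity of the post-cutoff graph (fixed before clipping)
  double median = 0;
  if (n > 0) {
    std::vector<int> cs(count.begin(), count.end());
    std::sort(cs.begin(), cs.end());
    median = (n % 2 == 1) ? cs[n / 2] : (cs[n / 2 - 1] + cs[n / 2]) / 2.0;
  }

  // iterative tip clipping: dead-end paths shorter than tip_clip_len with
  // mean multiplicity below the graph median
  for (int iter = 0; iter < 100; ++iter) {
    auto paths = find_unitigs(adj, alive, n);
    bool removed = false;
    for (auto& p : paths) {
      int lu = p.front().first, lo = p.front().second;
      int ru = p.back().first, ro = p.back().second;
      int dl = out_degree(adj, alive, lu, lo ^ 1);
      int dr = out_degree(adj, alive, ru, ro);
      bool is_tip = (dl == 0) != (dr == 0); // exactly one dead end
      if (!is_tip) continue;
      double len_nt = k + (double)p.size() - 1.0;
      if (len_nt >= tip_clip_len) continue;
      double mc = 0;
      for (auto& nd : p) mc += count[nd.first];
      mc /= p.size();
      if (mc >= median) continue;
      for (auto& nd : p) alive[nd.first] = 0;
      removed = true;
    }
    if (!removed) break;
  }

  // final unitigs
  auto paths = find_unitigs(adj, alive, n);
  std::vector<std::string> seqs;
  std::vector<double> covs;
  for (auto& p : paths) {
    std::string s = p[0].second ? kms[p[0].first] : revcomp_str(kms[p[0].first]);
    for (size_t i = 1; i < p.size(); ++i) {
      const std::string& km2 = p[i].second ? kms[p[i].first]
                                           : revcomp_str(kms[p[i].first]);
      s.push_back(km2[k - 1]);
    }
    if ((int)s.size() < min_contig_len) continue;
    std::string rc = revcomp_str(s);
    if (rc < s) s = rc; // canonical orientation
    double mc = 0;
    for (auto& nd : p) mc += count[nd.first];
    covs.push_back(mc / p.size());
    seqs.push_back(s);
  }
  std::vector<int> ord(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = (int)i;
  std::sort(ord.begin(), ord.end(), [&](int a, int b) {
    if (seqs[a].size() != seqs[b].size()) return seqs[a].size() > seqs[b].size();
    return seqs[a] < seqs[b];
  });
  CharacterVector out_seq(seqs.size());
  NumericVector out_cov(seqs.size());
  for (size_t i = 0; i < ord.size(); ++i) {
    out_seq[i] = seqs[ord[i]];
    out_cov[i] = covs[ord[i]];
  }
  return List::create(_["sequence"] = out_seq, _["mean_kmer_coverage"] = out_cov);
}
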