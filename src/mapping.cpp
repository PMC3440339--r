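// Bounded-mismatch single-best read placement against a contig set.
// Pigeonhole seeding: a read is split into max_mismatches+1 non-overlapping
// exact seed chunks, so every placement with at most max_mismatches
// mismatches is guaranteed to be found; ties are resolved by (fewest
// mismatches, contig rank, smallest start, forward strand first). Contigs
// must be supplied in lexicographic id order so that contig rank encodes
// the id tie-break.

#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <climits>
using namespace Rcpp;

static inline char comp_base2(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static std::string revcomp2(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base2(c);
  return r;
}

struct Hit {
  int mm, contig, pos, strand; // strand: 0 fwd, 1 rev
  bool better_than(const Hit& o) const {
    if (mm != o.mm) return mm < o.mm;
    if (contig != o.contig) return contig < o.contig;
    if (pos != o.pos) return pos < o.pos;
    return strand < o.strand;
  }
};

static inline int count_mm(const std::string& read, const std::string& ctg,
                           int start, int cap) {
  int mm = 0, L = (int)read.size();
  for (int i = 0; i < L; ++i) {
    if (read[i] != ctg[start + i]) {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
IntegerMatrix cpp_map_reads(CharacterVector reads, CharacterVector contigs,
                            int max_mm, int seed_len) {
  int nr = (int)reads.size(), nc = (int)contigs.size();
  std::vector<std::string> ctg(nc);
  for (int i = 0; i < nc; ++i) ctg[i] = as<std::string>(contigs[i]);
  int min_rl = INT_MAX;
  std::vector<std::string> rds(nr);
  for (int i = 0; i < nr; ++i) {
    rds[i] = as<std::string>(reads[i]);
    min_rl = std::min(min_rl, (int)rds[i].size());
  }
  IntegerMatrix out(nr, 4); // contig (1-based; 0 unmapped), pos, strand, mm
  if (nr == 0 || nc == 0) return out;

  int eff = std::min(seed_len, min_rl / (max_mm + 1));
  bool full_scan = eff < 4;

  std::unordered_map<std::string, std::vector<std::pair<int,int>>> index;
  if (!full_scan) {
    for (int c = 0; c < nc; ++c) {
      int L = (int)ctg[c].size();
      for (int p = 0; p + eff <= L; ++p)
        index[ctg[c].substr(p, eff)].push_back({c, p});
    }
  }

  for (int r = 0; r < nr; ++r) {
    Hit best{max_mm + 1, INT_MAX, INT_MAX, 0};
    bool found = false;
    std::string oriented[2] = {rds[r], revcomp2(rds[r])};
    int L = (int)rds[r].size();
    for (int strand = 0; strand < 2; ++strand) {
      const std::string& s = oriented[strand];
      if (full_scan) {
        for (int c = 0; c < nc; ++c) {
          int cl = (int)ctg[c].size();
          for (int start = 0; start + L <= cl; ++start) {
            int mm = count_mm(s, ctg[c], start, max_mm);
            if (mm > max_mm) continue;
            Hit h{mm, c, start, strand};
            if (!found || h.better_than(best)) { best = h; found = true; }
          }
        }
      } else {
        for (int chunk = 0; chunk <= max_mm; ++chunk) {
          int off = chunk * eff;
          auto it = index.find(s.substr(off, eff));
          if (it == index.end()) continue;
          for (auto& cp : it->second) {
            int c = cp.first, start = cp.second - off;
            if (start < 0 || start + L > (int)ctg[c].size()) continue;
            int mm = count_mm(s, ctg[c], start, max_mm);
            if (mm > max_mm) continue;
            Hit h{mm, c, start, strand};
            if (!found || h.better_than(best)) { best = h; found = true; }
          }
        }
      }
    }
    if (found) {
      out(r, 0) = best.contig + 1;
      out(r, 1) = best.pos + 1;
      out(r, 2) = best.strand + 1;
      out(r, 3) = best.mm;
    } else {
      out(r, 3) = -1;
    }
  }
  return out;
}
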