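#ifndef GRAPHPOLISH_GRAPH_H
#define GRAPHPOLISH_GRAPH_H

#include <Rcpp.h>
#include <string>
#include <vector>
#include <unordered_map>
#include <set>
#include <map>
#include <utility>

// IUPAC base bitmasks: A=1, C=2, G=4, T=8
inline int base_bit(char c) {
  switch (c) {
  case 'A': return 1;
  case 'C': return 2;
  case 'G': return 4;
  case 'T': return 8;
  }
  return 0;
}

inline char comp_base(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  }
  return 'N';
}

// complement of a base bitmask (A<->T, C<->G)
inline int comp_mask(int m) {
  int r = 0;
  if (m & 1) r |= 8;
  if (m & 8) r |= 1;
  if (m & 2) r |= 4;
  if (m & 4) r |= 2;
  return r;
}

inline std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

inline std::string canonical(const std::string& s) {
  std::string rc = revcomp(s);
  return (s <= rc) ? s : rc;
}

struct Unitig {
  std::string seq;
  std::vector<int> cov;                   // one per k-mer start offset
  std::vector<std::vector<int>> colors;   // one sorted set per k-mer start offset
  std::vector<int> snp;                   // per-base IUPAC bitmask, 0 = none
};

struct Graph {
  int k;
  std::vector<Unitig> unitigs;
  // canonical k-mer -> (unitig id, offset); strand recovered by slice comparison
  std::unordered_map<std::string, std::pair<int, int>> index;

  // returns uid, off, strand(+1 fwd / -1 rev) ; uid = -1 when absent
  bool lookup(const std::string& kmer, int& uid, int& off, int& strand) const {
    std::string can = canonical(kmer);
    auto it = index.find(can);
    if (it == index.end()) { uid = -1; return false; }
    uid = it->second.first;
    off = it->second.second;
    const std::string& s = unitigs[uid].seq;
    // strand of the *queried* k-mer relative to the stored unitig slice
    bool slice_is_query = std::equal(kmer.begin(), kmer.end(), s.begin() + off);
    strand = slice_is_query ? 1 : -1;
    return true;
  }

  size_t n_kmers() const { return index.size(); }
};

#endif
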