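#include "graph.h"
#include <algorithm>

using namespace Rcpp;

typedef std::unordered_map<std::string, int> KmerCounts;

// split a read at non-ACGT symbols and count canonical k-mers
static void count_kmers(const std::string& read, int k, KmerCounts& counts) {
  int n = (int)read.size();
  int run_start = 0;
  for (int i = 0; i <= n; ++i) {
    bool brk = (i == n) || base_bit(read[i]) == 0;
    if (brk) {
      int run_len = i - run_start;
      for (int p = run_start; p + k <= run_start + run_len; ++p)
        counts[canonical(read.substr(p, k))]++;
      run_start = i + 1;
    }
  }
}

struct OKmer {  // oriented k-mer: index into sorted list + orientation
  int idx;
  bool fwd;
};

// compaction of a filtered canonical k-mer set into maximal non-branching unitigs
static std::vector<std::string> compact_kmers(const std::vector<std::string>& kmers, int k) {
  std::unordered_map<std::string, int> pos;
  int n = (int)kmers.size();
  pos.reserve(n * 2);
  for (int i = 0; i < n; ++i) pos[kmers[i]] = i;

  auto repr = [&](const OKmer& o) {
    return o.fwd ? kmers[o.idx] : revcomp(kmers[o.idx]);
  };
  auto successors = [&](const OKmer& o) {
    std::vector<OKmer> out;
    std::string s = repr(o);
    std::string t = s.substr(1) + 'A';
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    for (char b : bases) {
      t[k - 1] = b;
      std::string can = canonical(t);
      auto it = pos.find(can);
      if (it != pos.end()) out.push_back(OKmer{it->second, t == can});
    }
    return out;
  };
  auto flip = [](OKmer o) { return OKmer{o.idx, !o.fwd}; };

  std::vector<bool> visited(n, false);
  std::vector<std::string> unitigs;
  for (int i = 0; i < n; ++i) {
    if (visited[i]) continue;
    std::vector<OKmer> chain;
    chain.push_back(OKmer{i, true});
    visited[i] = true;
    // forward extension
    while (true) {
      OKmer cur = chain.back();
      std::vector<OKmer> succ = successors(cur);
      if (succ.size() != 1) break;
      OKmer nxt = succ[0];
      if (successors(flip(nxt)).size() != 1) break;  // nxt has another predecessor
      if (nxt.idx == cur.idx || visited[nxt.idx]) break;  // hairpin / cycle closure
      chain.push_back(nxt);
      visited[nxt.idx] = true;
    }
    // backward extension (successors of the flipped front, prepended flipped)
    while (true) {
      OKmer cur = flip(chain.front());
      std::vector<OKmer> succ = successors(cur);
      if (succ.size() != 1) break;
      OKmer prv = succ[0];
      if (successors(flip(prv)).size() != 1) break;
      if (prv.idx == cur.idx || visited[prv.idx]) break;
      chain.insert(chain.begin(), flip(prv));
      visited[prv.idx] = true;
    }
    std::string seq = repr(chain[0]);
    for (size_t j = 1; j < chain.size(); ++j) seq.push_back(repr(chain[j])[k - 1]);
    // store the canonical orientation of the unitig sequence (deterministic)
    std::string rc = revcomp(seq);
    unitigs.push_back(seq <= rc ? seq : rc);
  }
  std::sort(unitigs.begin(), unitigs.end());
  return unitigs;
}

static Graph* graph_from_parts(const std::vector<std::string>& unitig_seqs, int k,
                               const KmerCounts* counts) {
  Graph* g = new Graph();
  g->k = k;
  for (const std::string& seq : unitig_seqs) {
    Unitig u;
    u.seq = seq;
    int nk = (int)seq.size() - k + 1;
    u.cov.assign(nk, 0);
    u.colors.assign(nk, std::vector<int>());
    u.snp.assign(seq.size(), 0);
    g->unitigs.push_back(std::move(u));
  }
  for (int uid = 0; uid < (int)g->unitigs.size(); ++uid) {
    Unitig& u = g->unitigs[uid];
    int nk = (int)u.seq.size() - k + 1;
    for (int off = 0; off < nk; ++off) {
      std::string can = canonical(u.seq.substr(off, k));
      auto it = g->index.find(can);
      if (it != g->index.end()) {
        delete g;
        stop("k-mer '%s' occurs at more than one unitig position; not a valid compacted graph",
             can.c_str());
      }
      g->index[can] = std::make_pair(uid, off);
      if (counts) {
        auto c = counts->find(can);
        u.cov[off] = (c == counts->end()) ? 0 : c->second;
      } else {
        u.cov[off] = 1;
      }
    }
  }
  return g;
}

// [[Rcpp::export]]
SEXP cpp_build_graph(CharacterVector reads, int k, int min_count) {
  KmerCounts counts;
  for (R_xlen_t i = 0; i < reads.size(); ++i)
    count_kmers(as<std::string>(reads[i]), k, counts);
  std::vector<std::string> kept;
  for (auto& kv : counts)
    if (kv.second >= min_count) kept.push_back(kv.first);
  std::sort(kept.begin(), kept.end());
  std::vector<std::string> unitigs = compact_kmers(kept, k);
  Graph* g = graph_from_parts(unitigs, k, &counts);
  return XPtr<Graph>(g, true);
}

// [[Rcpp::export]]
SEXP cpp_graph_from_unitigs(CharacterVector seqs, int k) {
  std::vector<std::string> unitigs;
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    unitigs.push_back(as<std::string>(seqs[i]));
  Graph* g = graph_from_parts(unitigs, k, NULL);
  return XPtr<Graph>(g, true);
}

// [[Rcpp::export]]
List cpp_graph_stats(SEXP gp) {
  XPtr<Graph> g(gp);
  return List::create(_["k"] = g->k,
                      _["n_unitigs"] = (int)g->unitigs.size(),
                      _["n_kmers"] = (double)g->n_kmers());
}

// [[Rcpp::export]]
CharacterVector cpp_unitig_seqs(SEXP gp) {
  XPtr<Graph> g(gp);
  CharacterVector out(g->unitigs.size());
  for (size_t i = 0; i < g->unitigs.size(); ++i) out[i] = g->unitigs[i].seq;
  return out;
}

// [[Rcpp::export]]
List cpp_unitig_info(SEXP gp, int uid) {
  XPtr<Graph> g(gp);
  if (uid < 1 || uid > (int)g->unitigs.size()) stop("unitig id out of range");
  const Unitig& u = g->unitigs[uid - 1];
  List cols(u.colors.size());
  for (size_t i = 0; i < u.colors.size(); ++i) cols[i] = wrap(u.colors[i]);
  IntegerVector snp_pos, snp_mask;
  for (size_t i = 0; i < u.snp.size(); ++i) {
    if (u.snp[i]) {
      snp_pos.push_back((int)i + 1);  // 1-based at the interface
      snp_mask.push_back(u.snp[i]);
    }
  }
  return List::create(_["seq"] = u.seq, _["cov"] = wrap(u.cov), _["colors"] = cols,
                      _["snp_pos"] = snp_pos, _["snp_mask"] = snp_mask);
}

// [[Rcpp::export]]
DataFrame cpp_lookup(SEXP gp, CharacterVector kmers) {
  XPtr<Graph> g(gp);
  int n = (int)kmers.size();
  IntegerVector uid(n), off(n), strand(n);
  LogicalVector present(n);
  for (int i = 0; i < n; ++i) {
    std::string km = as<std::string>(kmers[i]);
    if ((int)km.size() != g->k) stop("k-mer length %d does not match graph k = %d",
                                     (int)km.size(), g->k);
    int u, o, s;
    if (g->lookup(km, u, o, s)) {
      present[i] = true; uid[i] = u + 1; off[i] = o + 1; strand[i] = s;
    } else {
      present[i] = false; uid[i] = NA_INTEGER; off[i] = NA_INTEGER; strand[i] = NA_INTEGER;
    }
  }
  return DataFrame::create(_["present"] = present, _["unitig"] = uid,
                           _["offset"] = off, _["strand"] = strand);
}

// add color id to every k-mer position of the graph shared with any of `seqs`
static void color_with_unit(Graph* g, const std::vector<std::string>& seqs, int color_id) {
  std::set<std::pair<int, int>> hits;  // unique (uid, off)
  for (const std::string& s : seqs) {
    int n = (int)s.size(), k = g->k;
    int run_start = 0;
    for (int i = 0; i <= n; ++i) {
      bool brk = (i == n) || base_bit(s[i]) == 0;
      if (brk) {
        for (int p = run_start; p + k <= i; ++p) {
          int uid, off, strand;
          if (g->lookup(s.substr(p, k), uid, off, strand)) hits.insert({uid, off});
        }
        run_start = i + 1;
      }
    }
  }
  for (auto& h : hits) {
    std::vector<int>& v = g->unitigs[h.first].colors[h.second];
    auto it = std::lower_bound(v.begin(), v.end(), color_id);
    if (it == v.end() || *it != color_id) v.insert(it, color_id);
  }
}

// [[Rcpp::export]]
void cpp_color_graph(SEXP gp, List units, IntegerVector ids) {
  XPtr<Graph> g(gp);
  if (units.size() != ids.size()) stop("units and ids differ in length");
  for (R_xlen_t i = 0; i < units.size(); ++i) {
    CharacterVector seqs(units[i]);
    std::vector<std::string> ss;
    for (R_xlen_t j = 0; j < seqs.size(); ++j) ss.push_back(as<std::string>(seqs[j]));
    color_with_unit(g, ss, ids[i]);
  }
}

// [[Rcpp::export]]
List cpp_kmer_colors(SEXP gp, IntegerVector uid, IntegerVector off) {
  XPtr<Graph> g(gp);
  int n = (int)uid.size();
  List out(n);
  for (int i = 0; i < n; ++i) {
    const Unitig& u = g->unitigs[uid[i] - 1];
    out[i] = wrap(u.colors[off[i] - 1]);
  }
  return out;
}

// rebuild the graph keeping only k-mers with >= min_colors colors; coverage and
// color sets are carried over, SNP annotations must be recomputed afterwards
// [[Rcpp::export]]
SEXP cpp_prune_low_colors(SEXP gp, int min_colors) {
  XPtr<Graph> g(gp);
  std::vector<std::string> kept;
  KmerCounts counts;
  for (const Unitig& u : g->unitigs) {
    for (size_t off = 0; off < u.colors.size(); ++off) {
      if ((int)u.colors[off].size() >= min_colors) {
        std::string can = canonical(u.seq.substr(off, g->k));
        kept.push_back(can);
        counts[can] = u.cov[off];
      }
    }
  }
  std::sort(kept.begin(), kept.end());
  std::vector<std::string> unitigs = compact_kmers(kept, g->k);
  Graph* g2 = graph_from_parts(unitigs, g->k, &counts);
  // carry colors over (color sets attach to the k-mer, orientation-free)
  for (Unitig& u : g2->unitigs) {
    for (size_t off = 0; off < u.colors.size(); ++off) {
      int uid0, off0, s0;
      if (g->lookup(u.seq.substr(off, g2->k), uid0, off0, s0))
        u.colors[off] = g->unitigs[uid0].colors[off0];
    }
  }
  return XPtr<Graph>(g2, true);
}

// Hamming-distance-1 candidate-SNP annotation: for every unitig k-mer slice,
// substitute each base and query the graph; on a hit, annotate this unitig at
// the substituted base with the IUPAC mask of the two observed bases. Symmetric
// counterparts are produced when the partner unitig is scanned.
// [[Rcpp::export]]
void cpp_annotate_snps(SEXP gp) {
  XPtr<Graph> g(gp);
  int k = g->k;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  for (int uid = 0; uid < (int)g->unitigs.size(); ++uid) {
    Unitig& u = g->unitigs[uid];
    int nk = (int)u.seq.size() - k + 1;
    for (int off = 0; off < nk; ++off) {
      std::string slice = u.seq.substr(off, k);
      for (int i = 0; i < k; ++i) {
        char orig = slice[i];
        for (char b : bases) {
          if (b == orig) continue;
          slice[i] = b;
          int uid2, off2, s2;
          if (g->lookup(slice, uid2, off2, s2) && !(uid2 == uid && off2 == off))
            u.snp[off + i] |= base_bit(orig) | base_bit(b);
        }
        slice[i] = orig;
      }
    }
  }
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) out[i] = revcomp(as<std::string>(seqs[i]));
  return out;
}

// [[Rcpp::export]]
void cpp_set_snp_annotations(SEXP gp, IntegerVector uid, IntegerVector off,
                             IntegerVector mask) {
  XPtr<Graph> g(gp);
  for (R_xlen_t i = 0; i < uid.size(); ++i) {
    if (uid[i] < 1 || uid[i] > (int)g->unitigs.size()) stop("unitig id out of range");
    Unitig& u = g->unitigs[uid[i] - 1];
    if (off[i] < 1 || off[i] > (int)u.seq.size()) stop("annotation offset out of range");
    u.snp[off[i] - 1] |= mask[i];
  }
}

// classify every k-mer window of a long read as solid / near-solid (unique) / weak
// edit codes: 0 = substitution, 1 = read insertion (graph k-mer lacks one read
// base), 2 = read deletion (graph k-mer has one extra base)
// [[Rcpp::export]]
List cpp_classify_read(SEXP gp, std::string read) {
  XPtr<Graph> g(gp);
  int k = g->k, n = (int)read.size();
  std::vector<int> s_pos, s_uid, s_off, s_strand;
  std::vector<int> n_pos, n_uid, n_off, n_strand, n_edit;
  static const char bases[4] = {'A', 'C', 'G', 'T'};
  std::string cand;
  for (int p = 0; p + k <= n; ++p) {
    std::string w = read.substr(p, k);
    int uid, off, strand;
    if (g->lookup(w, uid, off, strand)) {
      s_pos.push_back(p + 1); s_uid.push_back(uid + 1);
      s_off.push_back(off + 1); s_strand.push_back(strand);
      continue;  // solid: near-solid interpretations discarded
    }
    // enumerate all distance-1 candidates; count distinct matched loci
    std::map<std::pair<int,int>, std::pair<int,int>> hits;  // (uid,off) -> (strand, edit)
    auto try_cand = [&](const std::string& c, int edit) {
      int u2, o2, s2;
      if (g->lookup(c, u2, o2, s2)) {
        auto key = std::make_pair(u2, o2);
        auto it = hits.find(key);
        if (it == hits.end()) hits[key] = std::make_pair(s2, edit);
        else if (edit < it->second.second) it->second = std::make_pair(s2, edit);
      }
    };
    for (int i = 0; i < k; ++i) {  // substitutions
      char orig = w[i];
      cand = w;
      for (char b : bases) {
        if (b == orig) continue;
        cand[i] = b;
        try_cand(cand, 0);
      }
    }
    if (p + k < n) {  // read insertion: drop one window base, append next read base
      for (int i = 0; i < k; ++i) {
        cand = w.substr(0, i) + w.substr(i + 1) + read[p + k];
        if (cand != w) try_cand(cand, 1);
      }
    }
    for (int i = 0; i < k; ++i) {  // read deletion: insert a base, drop last window base
      for (char b : bases) {
        cand = w.substr(0, i) + b + w.substr(i, k - 1 - i);
        if (cand != w) try_cand(cand, 2);
      }
    }
    if (hits.size() == 1) {  // unique near-solid match
      auto& h = *hits.begin();
      n_pos.push_back(p + 1); n_uid.push_back(h.first.first + 1);
      n_off.push_back(h.first.second + 1); n_strand.push_back(h.second.first);
      n_edit.push_back(h.second.second);
    }
  }
  DataFrame solid = DataFrame::create(_["pos"] = wrap(s_pos), _["unitig"] = wrap(s_uid),
                                      _["offset"] = wrap(s_off), _["strand"] = wrap(s_strand));
  DataFrame near = DataFrame::create(_["pos"] = wrap(n_pos), _["unitig"] = wrap(n_uid),
                                     _["offset"] = wrap(n_off), _["strand"] = wrap(n_strand),
                                     _["edit"] = wrap(n_edit));
  return List::create(_["solid"] = solid, _["near_solid"] = near);
}
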