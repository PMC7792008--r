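#include "graph.h"
#include <cmath>

using namespace Rcpp;

int edit_dist_bits(const std::string& a, const std::string& b, bool mode_global);

namespace {

struct Pos {
  int uid, off, strand;  // 0-based unitig offset, strand +1/-1, oriented to walk
  bool operator==(const Pos& o) const {
    return uid == o.uid && off == o.off && strand == o.strand;
  }
};

// number of elements of sorted `colors` present in sorted `C`
static int count_in(const std::vector<int>& colors, const std::vector<int>& C) {
  int cnt = 0;
  size_t i = 0, j = 0;
  while (i < colors.size() && j < C.size()) {
    if (colors[i] < C[j]) ++i;
    else if (colors[i] > C[j]) ++j;
    else { ++cnt; ++i; ++j; }
  }
  return cnt;
}

struct Cand {
  std::string app;                  // bases appended during the current stage
  Pos pos;
  std::string tail;                 // last k bases of the path
  int transitions = 0;              // unitigs entered this stage
  std::vector<std::pair<int, int>> entered;  // (uid, strand) entered this stage
  bool hit_target = false;
  std::vector<int> ann, annuid;     // per appended base: IUPAC mask (path strand), unitig
  std::vector<int> walk_uid, walk_strand;
  std::set<int> cmatch;             // colors of C seen on appended k-mers
  std::set<int> call;               // all colors seen on appended k-mers

  bool entered_before(int uid, int strand) const {
    for (auto& e : entered)
      if (e.first == uid && e.second == strand) return true;
    return false;
  }
};

struct Walker {
  Graph* g;
  int k;
  std::vector<int> C;
  int TC, Pmax, B, max_bases, min_bases, want_len;
  bool base_mode;
  double F;
  const std::string* region;

  // committed state
  std::string seq;
  std::vector<int> ann, annuid, walk_uid, walk_strand;
  std::set<int> cmatch, call;
  Pos pos;
  Pos target;
  bool has_target;

  // last base of the k-mer at `p`, as written along the walk, with annotation
  void base_meta(const Pos& p, int& mask, int& uid1) const {
    const Unitig& u = g->unitigs[p.uid];
    int bp = (p.strand > 0) ? p.off + k - 1 : p.off;
    mask = u.snp[bp];
    if (p.strand < 0) mask = comp_mask(mask);
    uid1 = p.uid + 1;
  }

  void add_colors(const Pos& p, std::set<int>& match_set, std::set<int>& all_set) const {
    const std::vector<int>& cols = g->unitigs[p.uid].colors[p.off];
    for (int c : cols) {
      all_set.insert(c);
      if (std::binary_search(C.begin(), C.end(), c)) match_set.insert(c);
    }
  }

  bool floor_ok(const Pos& p) const {
    if (TC <= 0) return true;
    return count_in(g->unitigs[p.uid].colors[p.off], C) >= TC;
  }

  // conflated score plus the raw sequence similarity (secondary tie-break key:
  // when the color evidence saturates the conflation, s_q still discriminates)
  std::pair<double, double> score(const std::string& path_cand,
                                  const std::set<int>& cm) const {
    double sc = C.empty() ? 1.0 : (double)cm.size() / (double)C.size();
    int wlen = std::min((int)region->size(),
                        (int)std::ceil(path_cand.size() * (1.0 + F)) + k);
    int d = edit_dist_bits(path_cand, region->substr(0, wlen), false);
    double sq = 1.0 - (double)d / (double)path_cand.size();
    if (sq < 0) sq = 0;
    double num = sc * sq, den = sc * sq + (1.0 - sc) * (1.0 - sq);
    return {(den == 0) ? 0.0 : num / den, sq};
  }

  // apply one step to a candidate; returns true when the candidate became a
  // leaf (target hit or frontier reached) and was moved into `leaves`
  bool apply_step(Cand& c, char b, const Pos& p2, const std::string& t,
                  std::vector<Cand>& leaves) const {
    bool new_unitig = (p2.uid != c.pos.uid || p2.strand != c.pos.strand);
    if (new_unitig) {
      c.entered.push_back({p2.uid, p2.strand});
      c.transitions++;
      c.walk_uid.push_back(p2.uid + 1);
      c.walk_strand.push_back(p2.strand);
    }
    c.app.push_back(b);
    c.pos = p2;
    c.tail = t;
    int mask, u1;
    base_meta(p2, mask, u1);
    c.ann.push_back(mask);
    c.annuid.push_back(u1);
    add_colors(p2, c.cmatch, c.call);
    int total = (int)(seq.size() + c.app.size());
    if (has_target && p2 == target && total >= min_bases) {
      c.hit_target = true;
      leaves.push_back(std::move(c));
      return true;
    }
    if (!has_target && want_len > 0 && total >= want_len) {
      c.hit_target = true;  // open-ended walk reached its length goal
      leaves.push_back(std::move(c));
      return true;
    }
    bool frontier = base_mode ? ((int)c.app.size() >= B) : (c.transitions >= Pmax);
    if (frontier) {
      leaves.push_back(std::move(c));
      return true;
    }
    return false;
  }

  // enumerate one stage of extensions from the committed state
  std::vector<Cand> stage() const {
    std::vector<Cand> leaves, stack;
    Cand root;
    root.pos = pos;
    root.tail = seq.substr(seq.size() - k);
    root.entered.push_back({pos.uid, pos.strand});
    stack.push_back(std::move(root));
    static const char bases[4] = {'A', 'C', 'G', 'T'};
    struct Succ { char b; Pos p; };
    while (!stack.empty()) {
      Cand cur = std::move(stack.back());
      stack.pop_back();
      while (true) {
        std::string t = cur.tail.substr(1) + 'A';
        Succ succ[4];
        int ns = 0;
        if ((int)(seq.size() + cur.app.size()) + 1 <= max_bases) {
          for (char b : bases) {
            t[k - 1] = b;
            int uid, off, strand;
            if (!g->lookup(t, uid, off, strand)) continue;
            Pos p2{uid, off, strand};
            if (!floor_ok(p2)) continue;
            bool new_unitig = (p2.uid != cur.pos.uid || p2.strand != cur.pos.strand);
            if (new_unitig && cur.entered_before(p2.uid, p2.strand)) continue;
            succ[ns++] = Succ{b, p2};
          }
        }
        if (ns == 0) break;  // dead branch: no leaf
        if (ns == 1) {
          t[k - 1] = succ[0].b;
          if (apply_step(cur, succ[0].b, succ[0].p, t, leaves)) break;
          continue;  // extended in place
        }
        for (int i = 1; i < ns; ++i) {
          Cand nxt = cur;
          t[k - 1] = succ[i].b;
          if (!apply_step(nxt, succ[i].b, succ[i].p, t, leaves)) {
            stack.push_back(std::move(nxt));
          }
        }
        t[k - 1] = succ[0].b;
        if (apply_step(cur, succ[0].b, succ[0].p, t, leaves)) break;
      }
    }
    return leaves;
  }

  void commit(const Cand& c) {
    seq += c.app;
    ann.insert(ann.end(), c.ann.begin(), c.ann.end());
    annuid.insert(annuid.end(), c.annuid.begin(), c.annuid.end());
    walk_uid.insert(walk_uid.end(), c.walk_uid.begin(), c.walk_uid.end());
    walk_strand.insert(walk_strand.end(), c.walk_strand.begin(), c.walk_strand.end());
    cmatch.insert(c.cmatch.begin(), c.cmatch.end());
    call.insert(c.call.begin(), c.call.end());
    pos = c.pos;
  }
};

}  // namespace

// Greedy staged graph walk from a source k-mer locus towards a target locus
// (or open-ended when t_uid = 0). All loci are 1-based at the interface.
// [[Rcpp::export]]
List cpp_traverse(SEXP gp, int s_uid, int s_off, int s_strand,
                  int t_uid, int t_off, int t_strand, std::string region,
                  int max_bases, int min_bases, IntegerVector colorC, int TC,
                  int Pmax, int B, bool base_length_mode, double F, int want_len) {
  XPtr<Graph> g(gp);
  Walker w;
  w.g = g.get();
  w.k = g->k;
  w.C = as<std::vector<int>>(colorC);
  std::sort(w.C.begin(), w.C.end());
  w.TC = TC; w.Pmax = Pmax; w.B = B;
  w.max_bases = max_bases; w.min_bases = min_bases; w.want_len = want_len;
  w.base_mode = base_length_mode; w.F = F;
  w.region = &region;
  w.pos = Pos{s_uid - 1, s_off - 1, s_strand};
  w.has_target = (t_uid > 0);
  if (w.has_target) w.target = Pos{t_uid - 1, t_off - 1, t_strand};
  if (w.pos.uid < 0 || w.pos.uid >= (int)g->unitigs.size()) stop("source unitig out of range");
  const Unitig& su = g->unitigs[w.pos.uid];
  if (w.pos.off < 0 || w.pos.off + g->k > (int)su.seq.size()) stop("source offset out of range");

  // committed path starts with the source k-mer as written along the walk
  std::string slice = su.seq.substr(w.pos.off, g->k);
  w.seq = (w.pos.strand > 0) ? slice : revcomp(slice);
  for (int i = 0; i < g->k; ++i) {
    int bp = (w.pos.strand > 0) ? w.pos.off + i : w.pos.off + g->k - 1 - i;
    int mask = su.snp[bp];
    if (w.pos.strand < 0) mask = comp_mask(mask);
    w.ann.push_back(mask);
    w.annuid.push_back(w.pos.uid + 1);
  }
  w.walk_uid.push_back(w.pos.uid + 1);
  w.walk_strand.push_back(w.pos.strand);
  w.add_colors(w.pos, w.cmatch, w.call);

  bool found = false;
  int n_stages = 0;
  while (true) {
    if ((int)w.seq.size() >= w.max_bases) break;
    std::vector<Cand> leaves = w.stage();
    ++n_stages;
    if (leaves.empty()) break;  // dead end or floor exhaustion
    // prefer candidates that reached the target / length goal
    std::vector<Cand*> pool;
    for (Cand& c : leaves)
      if (c.hit_target) pool.push_back(&c);
    bool finishing = !pool.empty();
    if (!finishing)
      for (Cand& c : leaves) pool.push_back(&c);
    Cand* best = pool[0];
    std::pair<double, double> best_s(-1, -1);
    for (Cand* c : pool) {
      std::set<int> cm = w.cmatch;
      cm.insert(c->cmatch.begin(), c->cmatch.end());
      std::pair<double, double> s = w.score(w.seq + c->app, cm);
      if (s > best_s || (s == best_s && c->app < best->app)) {
        best_s = s; best = c;
      }
    }
    w.commit(*best);
    if (finishing) { found = true; break; }
    if (!w.has_target && w.want_len > 0 && (int)w.seq.size() >= w.want_len) {
      found = true;
      break;
    }
  }
  // open-ended walks that stalled early still count when long enough
  if (!found && !w.has_target && w.want_len > 0 && (int)w.seq.size() >= w.min_bases)
    found = true;

  return List::create(_["found"] = found, _["seq"] = w.seq,
                      _["ann"] = wrap(w.ann), _["ann_unitig"] = wrap(w.annuid),
                      _["walk_unitig"] = wrap(w.walk_uid),
                      _["walk_strand"] = wrap(w.walk_strand),
                      _["colors_all"] = wrap(std::vector<int>(w.call.begin(), w.call.end())),
                      _["colors_matched"] = wrap(std::vector<int>(w.cmatch.begin(), w.cmatch.end())),
                      _["n_stages"] = n_stages);
}
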