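// Core engine for the codon-frame de Bruijn graph: 2-bit packed k-mers
// (k <= 128), open-addressing depth tables, flank-anchored seed scan,
// frame-preserving traversal and exact-match read re-alignment.
#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>
#include <unordered_set>
#include <unordered_map>
#include <algorithm>
using namespace Rcpp;

// ---------- packed k-mer ----------

struct Key {
  uint64_t w[4];
  Key() { w[0] = w[1] = w[2] = w[3] = 0; }
  bool operator==(const Key& o) const {
    return w[0] == o.w[0] && w[1] == o.w[1] && w[2] == o.w[2] && w[3] == o.w[3];
  }
};

static inline uint64_t mix64(uint64_t x) {
  x += 0x9e3779b97f4a7c15ULL;
  x = (x ^ (x >> 30)) * 0xbf58476d1ce4e5b9ULL;
  x = (x ^ (x >> 27)) * 0x94d049bb133111ebULL;
  return x ^ (x >> 31);
}
static inline uint64_t khash(const Key& k) {
  uint64_t h = 0x6a09e667f3bcc908ULL;
  for (int i = 0; i < 4; ++i) h = mix64(h ^ k.w[i]);
  return h;
}
struct KeyHash { size_t operator()(const Key& k) const { return khash(k); } };

static inline void shl2(Key& k) {
  k.w[3] = (k.w[3] << 2) | (k.w[2] >> 62);
  k.w[2] = (k.w[2] << 2) | (k.w[1] >> 62);
  k.w[1] = (k.w[1] << 2) | (k.w[0] >> 62);
  k.w[0] <<= 2;
}
static inline Key shr(const Key& k, int s) {
  Key r;
  int wshift = s / 64, bshift = s % 64;
  for (int i = 0; i < 4; ++i) {
    int j = i + wshift;
    uint64_t v = (j < 4) ? k.w[j] : 0;
    if (bshift) {
      v >>= bshift;
      if (j + 1 < 4) v |= k.w[j + 1] << (64 - bshift);
    }
    r.w[i] = v;
  }
  return r;
}
// mask keeping the low 2*nbases bits
static Key low_mask(int nbases) {
  Key m;
  int bits = 2 * nbases;
  for (int i = 0; i < 4; ++i) {
    if (bits >= 64) { m.w[i] = ~0ULL; bits -= 64; }
    else if (bits > 0) { m.w[i] = (1ULL << bits) - 1; bits = 0; }
    else m.w[i] = 0;
  }
  return m;
}
static inline void and_mask(Key& k, const Key& m) {
  for (int i = 0; i < 4; ++i) k.w[i] &= m.w[i];
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}
static const char BASES[5] = "ACGT";

static bool pack_string(const char* s, int len, Key& out) {
  Key k;
  for (int i = 0; i < len; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    shl2(k);
    k.w[0] |= (uint64_t)c;
  }
  out = k;
  return true;
}
static std::string unpack_key(const Key& k, int len) {
  std::string s(len, 'A');
  for (int i = 0; i < len; ++i) {
    Key t = shr(k, 2 * (len - 1 - i));
    s[i] = BASES[t.w[0] & 3ULL];
  }
  return s;
}
static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break; case 'T': c = 'A'; break;
      case 'C': c = 'G'; break; case 'G': c = 'C'; break;
      case 'a': c = 't'; break; case 't': c = 'a'; break;
      case 'c': c = 'g'; break; case 'g': c = 'c'; break;
      default: break;
    }
  }
  return r;
}

// ---------- open-addressing depth table ----------

struct KTable {
  std::vector<Key> keys;
  std::vector<int32_t> vals;
  std::vector<uint8_t> used;
  size_t mask = 0, n = 0;
  explicit KTable(size_t cap0 = 64) { init(cap0); }
  void init(size_t cap) {
    size_t c = 64;
    while (c < cap) c <<= 1;
    keys.assign(c, Key());
    vals.assign(c, 0);
    used.assign(c, 0);
    mask = c - 1;
    n = 0;
  }
  void grow() {
    KTable t((mask + 1) * 2);
    for (size_t i = 0; i <= mask; ++i)
      if (used[i]) *t.slot(keys[i]) = vals[i];
    std::swap(keys, t.keys); std::swap(vals, t.vals); std::swap(used, t.used);
    mask = t.mask; n = t.n;
  }
  int32_t* slot(const Key& k) {
    if (10 * (n + 1) >= 7 * (mask + 1)) grow();
    size_t i = khash(k) & mask;
    while (used[i]) {
      if (keys[i] == k) return &vals[i];
      i = (i + 1) & mask;
    }
    used[i] = 1; keys[i] = k; vals[i] = 0; ++n;
    return &vals[i];
  }
  const int32_t* find(const Key& k) const {
    size_t i = khash(k) & mask;
    while (used[i]) {
      if (keys[i] == k) return &vals[i];
      i = (i + 1) & mask;
    }
    return nullptr;
  }
};

struct Graph {
  int k = 0;          // edge length; node length is k-3
  KTable nodes, edges;
};

typedef XPtr<Graph> GraphPtr;

// ---------- graph construction ----------

// walk all length-len windows of s, calling f(key) on each fully valid window
template <typename F>
static void each_window(const std::string& s, int len, const Key& msk, F f) {
  int L = (int)s.size();
  if (L < len) return;
  Key k;
  int run = 0;
  for (int i = 0; i < L; ++i) {
    int c = base_code(s[i]);
    if (c < 0) { run = 0; k = Key(); continue; }
    shl2(k);
    k.w[0] |= (uint64_t)c;
    and_mask(k, msk);
    if (++run >= len) f(k);
  }
}

static void count_layer(const std::vector<std::string>& seqs, int len,
                        KTable& tab, int min_count, int sketch_log2) {
  Key msk = low_mask(len);
  if (min_count <= 1) {
    for (const auto& s : seqs)
      each_window(s, len, msk, [&](const Key& k) { (*tab.slot(k))++; });
    return;
  }
  // saturating counting sketch: keys never reaching min_count in the sketch
  // cannot reach it exactly, so skipping them equals build-then-prune.
  size_t ssz = ((size_t)1) << sketch_log2;
  std::vector<uint8_t> sk(ssz, 0);
  uint64_t smask = ssz - 1;
  uint8_t cap = (uint8_t)std::min(min_count, 255);
  for (const auto& s : seqs)
    each_window(s, len, msk, [&](const Key& k) {
      uint8_t& c = sk[khash(k) & smask];
      if (c < cap) ++c;
    });
  for (const auto& s : seqs)
    each_window(s, len, msk, [&](const Key& k) {
      if (sk[khash(k) & smask] >= cap) (*tab.slot(k))++;
    });
}

// [[Rcpp::export]]
SEXP kg_build_cpp(CharacterVector reads, int k, bool include_rc,
                  int min_count, int sketch_log2) {
  if (k % 3 != 0) stop("k must be a multiple of 3");
  if (k > 128 || k - 3 < 1) stop("k must be in [6, 128]");
  Graph* g = new Graph();
  g->k = k;
  std::vector<std::string> seqs;
  seqs.reserve(reads.size() * (include_rc ? 2 : 1));
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string s = as<std::string>(reads[i]);
    if (include_rc) seqs.push_back(revcomp_str(s));
    seqs.push_back(std::move(s));
  }
  if (sketch_log2 <= 0) {  // auto-size: ~4 slots per window, capped at 2^30
    size_t tot = 0;
    for (const auto& s : seqs) tot += s.size();
    sketch_log2 = 16;
    while (sketch_log2 < 30 && (((size_t)1) << sketch_log2) < 4 * tot)
      ++sketch_log2;
  }
  count_layer(seqs, k - 3, g->nodes, min_count, sketch_log2);
  count_layer(seqs, k, g->edges, min_count, sketch_log2);
  // singleton-filtered construction can leave edges whose endpoints were
  // dropped; those are removed again at prune time, which tolerates them.
  return GraphPtr(g, true);
}

// [[Rcpp::export]]
SEXP kg_merge_cpp(SEXP gp1, SEXP gp2) {
  Graph* a = GraphPtr(gp1).get();
  Graph* b = GraphPtr(gp2).get();
  if (a->k != b->k) stop("cannot merge graphs with different k");
  Graph* g = new Graph();
  g->k = a->k;
  for (const Graph* src : {a, b}) {
    for (size_t i = 0; i <= src->nodes.mask; ++i)
      if (src->nodes.used[i])
        *g->nodes.slot(src->nodes.keys[i]) += src->nodes.vals[i];
    for (size_t i = 0; i <= src->edges.mask; ++i)
      if (src->edges.used[i])
        *g->edges.slot(src->edges.keys[i]) += src->edges.vals[i];
  }
  return GraphPtr(g, true);
}

// [[Rcpp::export]]
List kg_stats_cpp(SEXP gp) {
  Graph* g = GraphPtr(gp).get();
  double sn = 0, se = 0;
  for (size_t i = 0; i <= g->nodes.mask; ++i)
    if (g->nodes.used[i]) sn += g->nodes.vals[i];
  for (size_t i = 0; i <= g->edges.mask; ++i)
    if (g->edges.used[i]) se += g->edges.vals[i];
  return List::create(_["k"] = g->k,
                      _["n_nodes"] = (double)g->nodes.n,
                      _["n_edges"] = (double)g->edges.n,
                      _["sum_node_depth"] = sn,
                      _["sum_edge_depth"] = se);
}

// [[Rcpp::export]]
List kg_tables_cpp(SEXP gp, double max_entries) {
  Graph* g = GraphPtr(gp).get();
  if ((double)g->nodes.n + (double)g->edges.n > max_entries)
    stop("graph too large to materialise as tables (", g->nodes.n, " nodes, ",
         g->edges.n, " edges)");
  int nl = g->k - 3;
  CharacterVector nk(g->nodes.n), ek(g->edges.n);
  IntegerVector nd(g->nodes.n), ed(g->edges.n);
  size_t j = 0;
  for (size_t i = 0; i <= g->nodes.mask; ++i)
    if (g->nodes.used[i]) {
      nk[j] = unpack_key(g->nodes.keys[i], nl);
      nd[j++] = g->nodes.vals[i];
    }
  j = 0;
  for (size_t i = 0; i <= g->edges.mask; ++i)
    if (g->edges.used[i]) {
      ek[j] = unpack_key(g->edges.keys[i], g->k);
      ed[j++] = g->edges.vals[i];
    }
  return List::create(
      _["nodes"] = DataFrame::create(_["kmer"] = nk, _["depth"] = nd,
                                     _["stringsAsFactors"] = false),
      _["edges"] = DataFrame::create(_["kmer"] = ek, _["depth"] = ed,
                                     _["stringsAsFactors"] = false));
}

// [[Rcpp::export]]
IntegerVector kg_depth_cpp(SEXP gp, CharacterVector kmers, bool edge) {
  Graph* g = GraphPtr(gp).get();
  int len = edge ? g->k : g->k - 3;
  IntegerVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    Key k;
    if ((int)s.size() != len || !pack_string(s.c_str(), len, k)) {
      out[i] = 0;
      continue;
    }
    const int32_t* v = (edge ? g->edges : g->nodes).find(k);
    out[i] = v ? *v : 0;
  }
  return out;
}

// ---------- pruning ----------

// [[Rcpp::export]]
SEXP kg_prune_cpp(SEXP gp, int min_depth, double edge_prune_ratio) {
  Graph* g = GraphPtr(gp).get();
  int nl = g->k - 3;
  Key nmask = low_mask(nl);
  Graph* out = new Graph();
  out->k = g->k;

  // stage 1: depth filter on nodes
  KTable ok(std::max<size_t>(64, g->nodes.n * 2));
  for (size_t i = 0; i <= g->nodes.mask; ++i)
    if (g->nodes.used[i] && g->nodes.vals[i] >= min_depth)
      *ok.slot(g->nodes.keys[i]) = g->nodes.vals[i];

  // stage 2: depth filter on edges + both endpoints must survive;
  // record the max outgoing depth at each prefix node
  std::vector<size_t> cand;
  cand.reserve(g->edges.n);
  KTable outmax(std::max<size_t>(64, g->nodes.n));
  for (size_t i = 0; i <= g->edges.mask; ++i) {
    if (!g->edges.used[i] || g->edges.vals[i] < min_depth) continue;
    const Key& e = g->edges.keys[i];
    Key pre = shr(e, 6);
    Key suf = e;
    and_mask(suf, nmask);
    if (!ok.find(pre) || !ok.find(suf)) continue;
    cand.push_back(i);
    int32_t* m = outmax.slot(pre);
    if (g->edges.vals[i] > *m) *m = g->edges.vals[i];
  }

  // stage 3: per-node relative depth pruning of outgoing edges
  KTable incident(std::max<size_t>(64, g->nodes.n));
  for (size_t i : cand) {
    const Key& e = g->edges.keys[i];
    int32_t d = g->edges.vals[i];
    Key pre = shr(e, 6);
    const int32_t* m = outmax.find(pre);
    if (m && (double)d < edge_prune_ratio * (double)(*m)) continue;
    *out->edges.slot(e) = d;
    Key suf = e;
    and_mask(suf, nmask);
    *incident.slot(pre) = 1;
    *incident.slot(suf) = 1;
  }

  // stage 4: drop dangling nodes
  for (size_t i = 0; i <= ok.mask; ++i)
    if (ok.used[i] && incident.find(ok.keys[i]))
      *out->nodes.slot(ok.keys[i]) = ok.vals[i];
  return GraphPtr(out, true);
}

// ---------- seed detection ----------

// Initial seeds: nodes whose first b bases equal the 3'-terminal b bases of
// the forward flank for some b in [min_anchor, k-6] (largest b reported).
// Terminal seeds symmetrically on the node suffix vs the reverse flank start.
// [[Rcpp::export]]
List kg_seed_scan_cpp(SEXP gp, std::string fwd_flank, std::string rev_flank,
                      int min_anchor) {
  Graph* g = GraphPtr(gp).get();
  int nl = g->k - 3;
  int bmax = std::min<int>(nl - 3, std::min(fwd_flank.size(), rev_flank.size()));
  if (min_anchor > bmax) stop("flanks shorter than min_seed_anchor");
  int fa = min_anchor;  // fast-filter anchor length (<= 32 bases fits a word)
  if (fa > 32) fa = 32;

  // packed flank suffix/prefix for every admissible b
  int FL = fwd_flank.size(), RL = rev_flank.size();
  std::vector<Key> fsuf(bmax + 1), rpre(bmax + 1);
  std::vector<char> fvalid(bmax + 1, 0), rvalid(bmax + 1, 0);
  for (int b = min_anchor; b <= bmax; ++b) {
    fvalid[b] = pack_string(fwd_flank.c_str() + (FL - b), b, fsuf[b]);
    rvalid[b] = pack_string(rev_flank.c_str(), b, rpre[b]);
  }
  // fast filter: first fa bases of each admissible flank window
  std::unordered_map<uint64_t, std::vector<int>> f_by_head, r_by_tail;
  for (int b = min_anchor; b <= bmax; ++b) {
    if (fvalid[b]) {
      Key h = shr(fsuf[b], 2 * (b - fa));
      f_by_head[h.w[0]].push_back(b);
    }
    if (rvalid[b]) {
      Key t;
      if (pack_string(rev_flank.c_str() + (b - fa), fa, t))
        r_by_tail[t.w[0]].push_back(b);
    }
  }
  Key famask = low_mask(fa);

  std::vector<std::string> ini_node, ter_node;
  std::vector<int> ini_b, ter_b, ini_d, ter_d;
  for (size_t i = 0; i <= g->nodes.mask; ++i) {
    if (!g->nodes.used[i]) continue;
    const Key& nd = g->nodes.keys[i];
    // initial: compare node head
    Key head = shr(nd, 2 * (nl - fa));
    auto fit = f_by_head.find(head.w[0]);
    if (fit != f_by_head.end()) {
      int best = 0;
      for (int b : fit->second) {
        Key pre = shr(nd, 2 * (nl - b));
        if (pre == fsuf[b] && b > best) best = b;
      }
      if (best >= min_anchor) {
        ini_node.push_back(unpack_key(nd, nl));
        ini_b.push_back(best);
        ini_d.push_back(g->nodes.vals[i]);
      }
    }
    // terminal: compare node tail
    Key tail = nd;
    and_mask(tail, famask);
    auto rit = r_by_tail.find(tail.w[0]);
    if (rit != r_by_tail.end()) {
      int best = 0;
      for (int b : rit->second) {
        Key suf = nd;
        Key m = low_mask(b);
        and_mask(suf, m);
        if (suf == rpre[b] && b > best) best = b;
      }
      if (best >= min_anchor) {
        ter_node.push_back(unpack_key(nd, nl));
        ter_b.push_back(best);
        ter_d.push_back(g->nodes.vals[i]);
      }
    }
  }
  return List::create(
      _["initial"] = DataFrame::create(_["node"] = ini_node,
                                       _["overlap"] = ini_b,
                                       _["depth"] = ini_d,
                                       _["stringsAsFactors"] = false),
      _["terminal"] = DataFrame::create(_["node"] = ter_node,
                                        _["overlap"] = ter_b,
                                        _["depth"] = ter_d,
                                        _["stringsAsFactors"] = false));
}

// ---------- traversal ----------

// [[Rcpp::export]]
List kg_traverse_cpp(SEXP gp, CharacterVector init_nodes,
                     IntegerVector init_overlap, CharacterVector term_nodes,
                     IntegerVector term_overlap, int max_path_len,
                     double max_steps, int max_candidates, bool roots_only) {
  Graph* g = GraphPtr(gp).get();
  int nl = g->k - 3;
  Key nmask = low_mask(nl), emask = low_mask(g->k);

  std::unordered_map<Key, int, KeyHash> term;  // node -> flank overlap
  for (R_xlen_t i = 0; i < term_nodes.size(); ++i) {
    Key k;
    std::string s = as<std::string>(term_nodes[i]);
    if ((int)s.size() == nl && pack_string(s.c_str(), nl, k))
      term[k] = term_overlap[i];
  }
  std::unordered_set<Key, KeyHash> initset;
  std::vector<Key> roots;
  std::vector<int> root_b, root_idx;
  for (R_xlen_t i = 0; i < init_nodes.size(); ++i) {
    Key k;
    std::string s = as<std::string>(init_nodes[i]);
    if ((int)s.size() != nl || !pack_string(s.c_str(), nl, k)) continue;
    initset.insert(k);
    roots.push_back(k);
    root_b.push_back(init_overlap[i]);
    root_idx.push_back(i + 1);
  }

  std::vector<std::string> cseq;
  std::vector<int> ccopy, cib, ctb, croot;
  double steps = 0;
  bool truncated = false;

  struct Frame { Key node; int choice; int mind; };

  for (size_t r = 0; r < roots.size() && !truncated; ++r) {
    const Key& root = roots[r];
    const int32_t* rd = g->nodes.find(root);
    if (!rd) continue;
    if (roots_only) {
      // skip seeds reachable from another initial seed by one 3-nt step:
      // their paths are suffixes of the root's and trim to the same insert
      bool has_pred = false;
      for (int c = 0; c < 64 && !has_pred; ++c) {
        Key e = root;
        // prepend 3 bases: e = c-bases + root, length k
        Key pref;
        pref.w[0] = (uint64_t)c;
        Key shifted = pref;
        for (int t = 0; t < nl; ++t) shl2(shifted);
        Key cand = root;
        for (int i2 = 0; i2 < 4; ++i2) cand.w[i2] |= shifted.w[i2];
        e = cand;
        if (g->edges.find(e)) {
          Key pre = shr(e, 6);
          if (initset.count(pre)) has_pred = true;
        }
      }
      if (has_pred) continue;
    }
    std::string path = unpack_key(root, nl);
    std::unordered_set<Key, KeyHash> visited;
    visited.insert(root);
    std::vector<Frame> stack;
    stack.push_back({root, 0, *rd});

    auto emit = [&](const Key& node, int mind, int tb) {
      cseq.push_back(path);
      ccopy.push_back(mind);
      cib.push_back(root_b[r]);
      ctb.push_back(tb);
      croot.push_back(root_idx[r]);
    };
    {  // degenerate case: root is itself terminal
      auto t = term.find(root);
      if (t != term.end()) emit(root, *rd, t->second);
    }
    while (!stack.empty()) {
      if ((double)cseq.size() >= max_candidates || steps >= max_steps) {
        truncated = true;
        break;
      }
      Frame& f = stack.back();
      if (f.choice >= 64 || (int)path.size() >= max_path_len) {
        visited.erase(f.node);
        stack.pop_back();
        path.resize(path.size() - 3);
        continue;
      }
      int c = f.choice++;
      Key e = f.node;
      shl2(e); shl2(e); shl2(e);
      e.w[0] |= (uint64_t)c;
      and_mask(e, emask);
      if (!g->edges.find(e)) continue;
      Key nxt = e;
      and_mask(nxt, nmask);
      const int32_t* ndep = g->nodes.find(nxt);
      if (!ndep) continue;
      if (visited.count(nxt)) continue;  // cycle budget 0
      ++steps;
      int mind = std::min(f.mind, (int)*ndep);
      path.push_back(BASES[(c >> 4) & 3]);
      path.push_back(BASES[(c >> 2) & 3]);
      path.push_back(BASES[c & 3]);
      auto t = term.find(nxt);
      if (t != term.end()) {
        emit(nxt, mind, t->second);
        path.resize(path.size() - 3);
        continue;  // successful termination: do not extend past the seed
      }
      visited.insert(nxt);
      stack.push_back({nxt, 0, mind});
    }
    // unwind path for next root (stack may be non-empty after truncation)
    // (path/visited are re-initialised per root, nothing else to do)
  }
  return List::create(_["sequence"] = cseq, _["copy_number"] = ccopy,
                      _["init_overlap"] = cib, _["term_overlap"] = ctb,
                      _["root"] = croot, _["truncated"] = truncated,
                      _["steps"] = steps);
}

// ---------- exact-match re-alignment for the CV filter ----------

// [[Rcpp::export]]
List cv_align_cpp(CharacterVector candidates, CharacterVector reads,
                  int anchor) {
  if (anchor < 8 || anchor > 32) stop("anchor must be in [8, 32]");
  int nc = candidates.size();
  std::vector<std::string> cs(nc);
  for (int i = 0; i < nc; ++i) cs[i] = as<std::string>(candidates[i]);

  struct Hit { uint64_t key; uint32_t cand; uint32_t pos; };
  std::vector<Hit> idx;
  for (int ci = 0; ci < nc; ++ci) {
    const std::string& s = cs[ci];
    if ((int)s.size() < anchor) continue;
    Key k;
    Key msk = low_mask(anchor);
    int run = 0;
    for (int i = 0; i < (int)s.size(); ++i) {
      int c = base_code(s[i]);
      if (c < 0) { run = 0; k = Key(); continue; }
      shl2(k);
      k.w[0] |= (uint64_t)c;
      and_mask(k, msk);
      if (++run >= anchor)
        idx.push_back({k.w[0], (uint32_t)ci, (uint32_t)(i - anchor + 1)});
    }
  }
  std::sort(idx.begin(), idx.end(),
            [](const Hit& a, const Hit& b) { return a.key < b.key; });

  std::vector<std::vector<int64_t>> diff(nc);
  for (int i = 0; i < nc; ++i) diff[i].assign(cs[i].size() + 1, 0);
  std::vector<double> nmatch(nc, 0.0);

  auto try_match = [&](const std::string& rd) {
    int L = (int)rd.size();
    if (L < anchor) return;
    Key k;
    if (!pack_string(rd.c_str(), anchor, k)) return;
    uint64_t key = k.w[0];
    auto lo = std::lower_bound(idx.begin(), idx.end(), key,
                               [](const Hit& h, uint64_t v) { return h.key < v; });
    for (auto it = lo; it != idx.end() && it->key == key; ++it) {
      const std::string& c = cs[it->cand];
      uint32_t p = it->pos;
      if (p + L > c.size()) continue;
      if (std::memcmp(c.data() + p + anchor, rd.data() + anchor, L - anchor) != 0)
        continue;
      diff[it->cand][p] += 1;
      diff[it->cand][p + L] -= 1;
      nmatch[it->cand] += 1;
    }
  };
  for (R_xlen_t i = 0; i < reads.size(); ++i) {
    std::string rd = as<std::string>(reads[i]);
    try_match(rd);
    try_match(revcomp_str(rd));
  }
  List profs(nc);
  for (int i = 0; i < nc; ++i) {
    IntegerVector p(cs[i].size());
    int64_t acc = 0;
    for (size_t j = 0; j < cs[i].size(); ++j) {
      acc += diff[i][j];
      p[j] = (int)acc;
    }
    profs[i] = p;
  }
  return List::create(_["profile"] = profs,
                      _["n_reads"] = NumericVector(nmatch.begin(), nmatch.end()));
}

// ---------- read trimming ----------

// [[Rcpp::export]]
List trim_reads_cpp(CharacterVector seqs, CharacterVector quals, int min_q,
                    int min_len, int polya_min) {
  R_xlen_t n = seqs.size();
  if (quals.size() != n) stop("seq/qual length mismatch");
  std::vector<std::string> os, oq;
  std::vector<int> keep;
  os.reserve(n); oq.reserve(n); keep.reserve(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    std::string q = as<std::string>(quals[i]);
    if (s.size() != q.size()) stop("record ", i + 1, ": seq/qual length differ");
    int lo = 0, hi = (int)s.size() - 1;
    while (lo <= hi && (q[lo] - 33) < min_q) ++lo;
    while (hi >= lo && (q[hi] - 33) < min_q) --hi;
    // strip a 3' homopolymer A run longer than polya_min - 1
    int run = 0;
    while (hi - run >= lo && (s[hi - run] == 'A' || s[hi - run] == 'a')) ++run;
    if (run >= polya_min) hi -= run;
    int len = hi - lo + 1;
    if (len < min_len) continue;
    os.push_back(s.substr(lo, len));
    oq.push_back(q.substr(lo, len));
    keep.push_back((int)(i + 1));
  }
  return List::create(_["seq"] = os, _["qual"] = oq, _["kept"] = keep);
}

// ---------- substitution sequencing errors (uses R's RNG) ----------

// [[Rcpp::export]]
CharacterVector add_subst_errors_cpp(CharacterVector seqs, double rate) {
  RNGScope rng;
  R_xlen_t n = seqs.size();
  CharacterVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int L = (int)s.size();
    int ne = (int)R::rbinom((double)L, rate);
    for (int e = 0; e < ne; ++e) {
      int p = (int)std::floor(R::unif_rand() * L);
      if (p >= L) p = L - 1;
      int c = base_code(s[p]);
      if (c < 0) continue;
      int alt = (c + 1 + (int)std::floor(R::unif_rand() * 3)) & 3;
      s[p] = BASES[alt];
    }
    out[i] = s;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector revcomp_cpp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i)
    out[i] = revcomp_str(as<std::string>(seqs[i]));
  return out;
}

// Approximate containment of reads in a backbone: seed the read's leading
// bases at several offsets against an exact index of backbone windows, then
// count mismatches over the full read at each seeded position.
// Returns, per read: best start (1-based, 0 = unaligned), strand, mismatches.
// [[Rcpp::export]]
List backbone_align_cpp(CharacterVector reads, std::string backbone,
                        int anchor, double max_mismatch_frac) {
  int BL = (int)backbone.size();
  if (anchor < 8 || anchor > 32) stop("anchor must be in [8, 32]");
  std::unordered_map<uint64_t, std::vector<int>> widx;
  {
    Key k, msk = low_mask(anchor);
    int run = 0;
    for (int i = 0; i < BL; ++i) {
      int c = base_code(backbone[i]);
      if (c < 0) { run = 0; k = Key(); continue; }
      shl2(k);
      k.w[0] |= (uint64_t)c;
      and_mask(k, msk);
      if (++run >= anchor) widx[k.w[0]].push_back(i - anchor + 1);
    }
  }
  R_xlen_t n = reads.size();
  IntegerVector start(n), mism(n);
  CharacterVector strand(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    std::string fwd = as<std::string>(reads[i]);
    int best_mm = INT32_MAX, best_pos = -1;
    char best_st = '*';
    for (int si = 0; si < 2; ++si) {
      std::string rd = si == 0 ? fwd : revcomp_str(fwd);
      int L = (int)rd.size();
      if (L < anchor) continue;
      for (int off : {0, L / 2, L - anchor}) {
        if (off < 0 || off + anchor > L) continue;
        Key k;
        if (!pack_string(rd.c_str() + off, anchor, k)) continue;
        auto it = widx.find(k.w[0]);
        if (it == widx.end()) continue;
        for (int wpos : it->second) {
          int s0 = wpos - off;
          if (s0 < 0 || s0 + L > BL) continue;
          int mm = 0;
          for (int j = 0; j < L; ++j)
            if (backbone[s0 + j] != rd[j]) ++mm;
          if (mm < best_mm) { best_mm = mm; best_pos = s0; best_st = si == 0 ? '+' : '-'; }
        }
      }
    }
    if (best_pos >= 0 &&
        best_mm <= max_mismatch_frac * (double)fwd.size()) {
      start[i] = best_pos + 1;
      mism[i] = best_mm;
      strand[i] = std::string(1, best_st);
    } else {
      start[i] = 0;
      mism[i] = NA_INTEGER;
      strand[i] = NA_STRING;
    }
  }
  return List::create(_["start"] = start, _["mismatches"] = mism,
                      _["strand"] = strand);
}
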