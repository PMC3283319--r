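// Fast DCJ-[C] engine: implicit treap per chromosome with lazy reversal and
// subtree summaries (size, sensitive-gene count), so cut-point location,
// fragment sensitive-gene counting and move application are O(log N).
//
// All stochastic choices draw from R's RNG (unif_rand) in the same documented
// order as the naive R engine (dcj_naive.R): cut position 1, cut position 2
// (redrawn until distinct), rejoin bit, then one Bernoulli draw for gated
// classes under DCJ-pfix (only when p_fix < 1). Treap priorities come from a
// private splitmix64 stream so they never perturb the model RNG stream.

#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Node {
  Node *l, *r;
  int gene;       // signed gene id (sign = orientation)
  int size;       // subtree size
  int scnt;       // subtree sensitive count
  bool sens;      // this gene sensitive?
  bool rev;       // lazy: reverse subtree order and flip all orientations
  uint32_t prio;
};

inline int sz(Node* t) { return t ? t->size : 0; }
inline int sc(Node* t) { return t ? t->scnt : 0; }

inline void upd(Node* t) {
  t->size = 1 + sz(t->l) + sz(t->r);
  t->scnt = (t->sens ? 1 : 0) + sc(t->l) + sc(t->r);
}

inline void push(Node* t) {
  if (t->rev) {
    Node* tmp = t->l; t->l = t->r; t->r = tmp;
    t->gene = -t->gene;
    if (t->l) t->l->rev = !t->l->rev;
    if (t->r) t->r->rev = !t->r->rev;
    t->rev = false;
  }
}

Node* merge2(Node* a, Node* b) {
  if (!a) return b;
  if (!b) return a;
  if (a->prio > b->prio) {
    push(a);
    a->r = merge2(a->r, b);
    upd(a);
    return a;
  } else {
    push(b);
    b->l = merge2(a, b->l);
    upd(b);
    return b;
  }
}

// first k elements into *a, rest into *b
void split2(Node* t, int k, Node** a, Node** b) {
  if (!t) { *a = *b = nullptr; return; }
  push(t);
  if (sz(t->l) >= k) {
    split2(t->l, k, a, &t->l);
    upd(t);
    *b = t;
  } else {
    split2(t->r, k - sz(t->l) - 1, &t->r, b);
    upd(t);
    *a = t;
  }
}

// sensitive count among the first k elements
int sens_prefix(Node* t, int k) {
  int acc = 0;
  while (t && k > 0) {
    push(t);
    int ls = sz(t->l);
    if (k <= ls) { t = t->l; continue; }
    acc += sc(t->l) + (t->sens ? 1 : 0);
    k -= ls + 1;
    t = t->r;
  }
  return acc;
}

struct Splitmix {
  uint64_t x;
  explicit Splitmix(uint64_t seed) : x(seed) {}
  uint32_t next() {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return (uint32_t)((z ^ (z >> 31)) >> 16);
  }
};

void collect(Node* t, std::vector<int>& out) {
  if (!t) return;
  push(t);
  collect(t->l, out);
  out.push_back(t->gene);
  collect(t->r, out);
}

void depth_sum(Node* t, long d, long& sum, long& maxd) {
  if (!t) return;
  if (d > maxd) maxd = d;
  sum += d;
  depth_sum(t->l, d + 1, sum, maxd);
  depth_sum(t->r, d + 1, sum, maxd);
}

struct Engine {
  std::vector<Node> pool;
  std::vector<Node*> roots;
  std::vector<char> circ;
  Splitmix prio;
  bool telomeres, allow_fusion;
  std::vector<long> cum;  // cumulative cut-position counts, lazily rebuilt
  bool cum_dirty = true;

  Engine(const List& chrom, const LogicalVector& circular,
         const LogicalVector& sensitive, bool telomeres_, bool allow_fusion_)
      : prio(88172645463325252ULL),
        telomeres(telomeres_), allow_fusion(allow_fusion_) {
    int N = 0;
    for (int k = 0; k < chrom.size(); ++k) N += ((IntegerVector)chrom[k]).size();
    pool.resize(N);
    int at = 0;
    for (int k = 0; k < chrom.size(); ++k) {
      IntegerVector v = chrom[k];
      Node* root = nullptr;
      for (int i = 0; i < v.size(); ++i) {
        Node* nd = &pool[at++];
        nd->l = nd->r = nullptr;
        nd->gene = v[i];
        int id = v[i] < 0 ? -v[i] : v[i];
        nd->sens = sensitive[id - 1];
        nd->rev = false;
        nd->prio = prio.next();
        nd->size = 1; nd->scnt = nd->sens ? 1 : 0;
        root = merge2(root, nd);
      }
      roots.push_back(root);
      circ.push_back(circular[k]);
    }
  }

  int n_positions(int k) const {
    int L = sz(roots[k]);
    return circ[k] ? L : (telomeres ? L + 1 : L - 1);
  }

  long total_positions() {
    if (cum_dirty) {
      cum.resize(roots.size());
      long K = 0;
      for (size_t k = 0; k < roots.size(); ++k) {
        K += n_positions(k);
        cum[k] = K;
      }
      cum_dirty = false;
    }
    return cum.empty() ? 0 : cum.back();
  }

  // map global position index to (chromosome, gap index)
  void locate(long pos, int& k, int& g) const {
    size_t i = std::lower_bound(cum.begin(), cum.end(), pos + 1) - cum.begin();
    k = (int)i;
    g = (int)(pos - (i ? cum[i - 1] : 0));
    if (!circ[k] && !telomeres) g += 1;  // internal gaps are 1..L-1
  }

  void drop_empty() {
    cum_dirty = true;  // every size- or topology-changing move passes here
    size_t w = 0;
    for (size_t k = 0; k < roots.size(); ++k) {
      if (roots[k]) { roots[w] = roots[k]; circ[w] = circ[k]; ++w; }
    }
    roots.resize(w);
    circ.resize(w);
  }

  List snapshot() const {
    int nk = roots.size();
    List ch(nk);
    LogicalVector ci(nk);
    for (int k = 0; k < nk; ++k) {
      std::vector<int> out;
      out.reserve(sz(roots[k]));
      collect(roots[k], out);
      ch[k] = IntegerVector(out.begin(), out.end());
      ci[k] = (bool)circ[k];
    }
    return List::create(_["chromosomes"] = ch, _["circular"] = ci);
  }
};

enum Model { DCJ = 0, DS = 1, MAXT = 2, MAXL = 3, PFIX = 4 };
enum Cls { INV = 0, TRA = 1, EXC = 2, REI = 3, FIS = 4, FUS = 5 };

} // namespace

// [[Rcpp::export(name = ".dcj_run_cpp")]]
List dcj_run_cpp(List chrom, LogicalVector circular, LogicalVector sensitive,
                 int model, double param, double n_moves,
                 IntegerVector checkpoints, bool telomeres, bool allow_fusion,
                 bool pfix_all, double max_proposals) {
  Engine E(chrom, circular, sensitive, telomeres, allow_fusion);
  double Tmax = R_PosInf, Lmax = R_PosInf, pfix = 1.0;
  if (model == MAXT) Tmax = param;
  if (model == MAXL) { Tmax = param; Lmax = param; }
  if (model == PFIX) pfix = param;

  long acc = 0, prop = 0;
  std::vector<long> acc_cls(6, 0);
  long rej_model = 0, rej_fusion = 0;
  List snaps(checkpoints.size());
  int cp_i = 0;

  while (acc < (long)n_moves) {
    if (++prop > (long)max_proposals)
      stop("proposal budget exceeded (%g proposals, %d accepted): "
           "acceptance may be impossible under this configuration",
           (double)prop, (int)acc);
    long K = E.total_positions();
    if (K < 2) stop("genome has fewer than two cut points");
    long p1 = (long)(unif_rand() * K);
    long p2;
    do { p2 = (long)(unif_rand() * K); } while (p2 == p1);
    if (p2 < p1) { long t = p1; p1 = p2; p2 = t; }
    int k1, g1, k2, g2;
    E.locate(p1, k1, g1);
    E.locate(p2, k2, g2);
    int r = (unif_rand() < 0.5) ? 0 : 1;

    if (k1 == k2) {
      int k = k1;
      if (g1 == g2) continue;  // unreachable: positions are distinct
      int mlen = g2 - g1;
      if (r == 0) {  // inversion of segment (g1, g2]
        bool ok = (model == MAXL) ? (mlen <= Lmax) : true;
        if (!ok) { ++rej_model; continue; }
        Node *A, *M, *B;
        split2(E.roots[k], g2, &A, &B);
        split2(A, g1, &A, &M);
        M->rev = !M->rev;
        E.roots[k] = merge2(merge2(A, M), B);
        ++acc; ++acc_cls[INV];
      } else {
        // linear: excision of segment as circular fragment; circular: fission
        bool is_exc = !E.circ[k];
        bool ok = true;
        if (model == DS) {
          if (is_exc)
            ok = (sens_prefix(E.roots[k], g2) - sens_prefix(E.roots[k], g1)) == 0;
        } else if (model == MAXT || model == MAXL) {
          if (is_exc) ok = mlen <= Tmax;
        } else if (model == PFIX) {
          if (is_exc || pfix_all)
            if (pfix < 1.0) ok = unif_rand() < pfix;
        }
        if (!ok) { ++rej_model; continue; }
        Node *A, *M, *B;
        split2(E.roots[k], g2, &A, &B);
        split2(A, g1, &A, &M);
        E.roots[k] = merge2(A, B);
        E.roots.push_back(M);
        E.circ.push_back(true);
        E.drop_empty();
        ++acc; ++acc_cls[is_exc ? EXC : FIS];
      }
    } else if (!E.circ[k1] && !E.circ[k2]) {
      // two linear chromosomes: translocation (or fusion at two telomeres)
      int L1 = sz(E.roots[k1]), L2 = sz(E.roots[k2]);
      bool ea = g1 == 0, eb = g1 == L1, ec = g2 == 0, ed = g2 == L2;
      bool id0 = (ea && ec) || (eb && ed);
      bool id1 = (ea && ed) || (eb && ec);
      if (r == 0 && id0) r = 1; else if (r == 1 && id1) r = 0;
      if ((r == 0 && id0) || (r == 1 && id1)) continue;  // both identity
      bool is_fusion = (r == 0) ? ((ea && ed) || (eb && ec))
                                : ((ea && ec) || (eb && ed));
      if (is_fusion && !E.allow_fusion) { ++rej_fusion; continue; }
      bool ok = true;
      if (model == DS) {
        int s1 = sens_prefix(E.roots[k1], g1);
        int s2 = sens_prefix(E.roots[k2], g2);
        bool af = s1 == 0, bf = sc(E.roots[k1]) == s1;
        bool cf = s2 == 0, df = sc(E.roots[k2]) == s2;
        ok = (r == 0) ? ((af && cf) || (bf && df)) : ((bf && cf) || (af && df));
      } else if (model == MAXT || model == MAXL) {
        int la = g1, lb = L1 - g1, lc = g2, ld = L2 - g2;
        ok = (r == 0) ? ((la <= Tmax && lc <= Tmax) || (lb <= Tmax && ld <= Tmax))
                      : ((lb <= Tmax && lc <= Tmax) || (la <= Tmax && ld <= Tmax));
      } else if (model == PFIX) {
        bool gated = is_fusion ? pfix_all : true;  // literal scope gates translocations
        if (gated && pfix < 1.0) ok = unif_rand() < pfix;
      }
      if (!ok) { ++rej_model; continue; }
      Node *A, *B, *C, *D;
      split2(E.roots[k1], g1, &A, &B);
      split2(E.roots[k2], g2, &C, &D);
      if (r == 0) {
        E.roots[k1] = merge2(A, D);
        E.roots[k2] = merge2(C, B);
      } else {
        if (C) C->rev = !C->rev;
        if (B) B->rev = !B->rev;
        E.roots[k1] = merge2(A, C);
        E.roots[k2] = merge2(B, D);
      }
      E.drop_empty();
      ++acc; ++acc_cls[is_fusion ? FUS : TRA];
    } else if (E.circ[k1] && E.circ[k2]) {
      // fusion of two circular fragments into one
      if (model == PFIX && pfix_all && pfix < 1.0) {
        if (!(unif_rand() < pfix)) { ++rej_model; continue; }
      }
      Node *X, *Y;
      split2(E.roots[k1], g1, &X, &Y);
      Node* e1 = merge2(Y, X);
      split2(E.roots[k2], g2, &X, &Y);
      Node* e2 = merge2(Y, X);
      if (r == 1) e2->rev = !e2->rev;
      E.roots[k1] = merge2(e1, e2);
      E.roots[k2] = nullptr;
      E.drop_empty();
      ++acc; ++acc_cls[FUS];
    } else {
      // one circular fragment + one linear chromosome: reintegration
      int kc = E.circ[k1] ? k1 : k2;
      int kl = E.circ[k1] ? k2 : k1;
      int gc = E.circ[k1] ? g1 : g2;
      int gl = E.circ[k1] ? g2 : g1;
      bool ok = true;
      if (model == DS) ok = sc(E.roots[kc]) == 0;
      else if (model == PFIX && pfix_all && pfix < 1.0) ok = unif_rand() < pfix;
      if (!ok) { ++rej_model; continue; }
      Node *X, *Y;
      split2(E.roots[kc], gc, &X, &Y);
      Node* e = merge2(Y, X);
      if (r == 1) e->rev = !e->rev;
      Node *P, *Q;
      split2(E.roots[kl], gl, &P, &Q);
      E.roots[kl] = merge2(merge2(P, e), Q);
      E.roots[kc] = nullptr;
      E.drop_empty();
      ++acc; ++acc_cls[REI];
    }

    if (cp_i < checkpoints.size() && acc == checkpoints[cp_i]) {
      snaps[cp_i] = E.snapshot();
      ++cp_i;
    }
  }

  long dsum = 0, dmax = 0, nnodes = 0;
  for (size_t k = 0; k < E.roots.size(); ++k) {
    depth_sum(E.roots[k], 0, dsum, dmax);
    nnodes += sz(E.roots[k]);
  }

  IntegerVector by_class = IntegerVector::create(
      _["inversion"] = (int)acc_cls[INV], _["translocation"] = (int)acc_cls[TRA],
      _["excision"] = (int)acc_cls[EXC], _["reintegration"] = (int)acc_cls[REI],
      _["fission"] = (int)acc_cls[FIS], _["fusion"] = (int)acc_cls[FUS]);
  long nt = acc_cls[TRA] + acc_cls[EXC] + acc_cls[REI] + acc_cls[FIS] + acc_cls[FUS];
  List log = List::create(
      _["n"] = (double)acc, _["n_t"] = (double)nt, _["by_class"] = by_class,
      _["proposed"] = (double)prop,
      _["rejected_model"] = (double)rej_model,
      _["rejected_fusion_disabled"] = (double)rej_fusion,
      _["mean_depth"] = nnodes ? (double)dsum / nnodes : 0.0,
      _["max_depth"] = (double)dmax);
  return List::create(_["genome"] = E.snapshot(), _["log"] = log,
                      _["snapshots"] = snaps);
}

// Segment summary on the order-statistic tree: length and sensitive count of
// the half-open gap interval (from, to] of one chromosome. Used to cross-check
// the tree summaries against a linear scan.
// [[Rcpp::export(name = ".dcj_segment_summary_cpp")]]
IntegerVector dcj_segment_summary_cpp(List chrom, LogicalVector circular,
                                      LogicalVector sensitive, int k,
                                      int from, int to) {
  Engine E(chrom, circular, sensitive, true, true);
  if (k < 1 || k > (int)E.roots.size()) stop("no such chromosome");
  Node* root = E.roots[k - 1];
  if (from < 0 || to > sz(root) || from > to) stop("invalid segment bounds");
  int len = to - from;
  int scount = sens_prefix(root, to) - sens_prefix(root, from);
  return IntegerVector::create(_["length"] = len, _["sensitive"] = scount);
}
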