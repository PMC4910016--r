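// Neutral structured-coalescent simulator with recombination (Hudson ARG).
//
// Scaling conventions (ms-style): time in units of 4N0 generations; a
// population of relative size x has pairwise coalescence rate 2/x; rho =
// 4*N0*r*L with recombination positions on [0,1); per-lineage backward
// migration rate from deme i to deme j is M_ij = 4*N0*m_ij; mutations fall
// at rate theta = 4*N0*mu per unit of (span-weighted) branch length.
// Exponential growth g means relative size x(t) = x_ref * exp(-g*(t-t_ref))
// going back in time.
//
// Output is a tskit-style table pair: node times plus edges
// (left, right, parent, child) on [0,1). Mutations are dropped afterwards,
// either exactly S of them (fixed-S conditioning, branch-length weighted)
// or Poisson with rate theta.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {
  double l, r;   // half-open [l, r)
  int node;      // node id carrying this material
  int cnt;       // number of sample leaves below
};

struct Lineage {
  int pop;
  std::vector<Seg> segs;  // sorted, non-overlapping
  double extent() const { return segs.back().r - segs.front().l; }
};

struct PopState {
  bool active;
  double size;    // relative size at tref
  double growth;  // backward-time shrink rate (ms -G convention)
  double tref;
};

// merge two sorted segment lists at a coalescence; returns merged list and
// records edges for overlapping pieces.  Pieces whose descendant count hits
// n_samples have found their local MRCA and are dropped.
std::vector<Seg> merge_segs(const std::vector<Seg>& A, const std::vector<Seg>& B,
                            int new_node, double /*time*/, int n_samples,
                            std::vector<double>& e_l, std::vector<double>& e_r,
                            std::vector<int>& e_p, std::vector<int>& e_c,
                            bool& any_overlap) {
  std::vector<Seg> out;
  size_t ia = 0, ib = 0;
  double pos = std::min(A.front().l, B.front().l);
  any_overlap = false;
  while (ia < A.size() || ib < B.size()) {
    bool inA = ia < A.size() && A[ia].l <= pos && pos < A[ia].r;
    bool inB = ib < B.size() && B[ib].l <= pos && pos < B[ib].r;
    // next boundary strictly greater than pos
    double nxt = 2.0;
    if (ia < A.size()) {
      if (A[ia].l > pos) nxt = std::min(nxt, A[ia].l);
      if (A[ia].r > pos) nxt = std::min(nxt, A[ia].r);
    }
    if (ib < B.size()) {
      if (B[ib].l > pos) nxt = std::min(nxt, B[ib].l);
      if (B[ib].r > pos) nxt = std::min(nxt, B[ib].r);
    }
    if (inA && inB) {
      any_overlap = true;
      e_l.push_back(pos); e_r.push_back(nxt); e_p.push_back(new_node); e_c.push_back(A[ia].node);
      e_l.push_back(pos); e_r.push_back(nxt); e_p.push_back(new_node); e_c.push_back(B[ib].node);
      int cnt = A[ia].cnt + B[ib].cnt;
      if (cnt < n_samples) out.push_back({pos, nxt, new_node, cnt});
    } else if (inA) {
      out.push_back({pos, nxt, A[ia].node, A[ia].cnt});
    } else if (inB) {
      out.push_back({pos, nxt, B[ib].node, B[ib].cnt});
    }
    // advance
    pos = nxt;
    while (ia < A.size() && A[ia].r <= pos) ia++;
    while (ib < B.size() && B[ib].r <= pos) ib++;
    if (pos >= 1.5) break;
  }
  // squash adjacent pieces that share a node (keeps tables small)
  std::vector<Seg> sq;
  for (const Seg& s : out) {
    if (!sq.empty() && sq.back().node == s.node && sq.back().cnt == s.cnt &&
        std::abs(sq.back().r - s.l) < 1e-15) {
      sq.back().r = s.r;
    } else sq.push_back(s);
  }
  return sq;
}

}  // namespace

// [[Rcpp::export(name = ".arg_simulate")]]
List arg_simulate(IntegerVector sample_sizes, NumericVector pop_sizes,
                  NumericVector pop_growth, NumericMatrix migration,
                  DataFrame events, double rho) {
  RNGScope scope;
  const int npop = sample_sizes.size();
  int n = 0;
  for (int p = 0; p < npop; p++) n += sample_sizes[p];
  if (n < 2) stop("need at least two samples in total");

  std::vector<PopState> ps(npop);
  std::vector<std::vector<double>> M(npop, std::vector<double>(npop, 0.0));
  for (int i = 0; i < npop; i++) {
    ps[i] = {true, pop_sizes[i], pop_growth[i], 0.0};
    for (int j = 0; j < npop; j++) if (i != j) M[i][j] = migration(i, j);
  }

  // event table columns: time, type (1 merge i->j, 2 size, 3 growth,
  // 4 migration entry, 5 migration all), i, j, value
  NumericVector ev_time = events["time"];
  IntegerVector ev_type = events["type"];
  IntegerVector ev_i = events["i"];
  IntegerVector ev_j = events["j"];
  NumericVector ev_val = events["value"];
  const int nev = ev_time.size();

  std::vector<double> node_time;
  node_time.reserve(4 * n);
  std::vector<Lineage> lin;
  lin.reserve(2 * n);
  int id = 0;
  for (int p = 0; p < npop; p++)
    for (int s = 0; s < sample_sizes[p]; s++) {
      node_time.push_back(0.0);
      lin.push_back({p, {{0.0, 1.0, id, 1}}});
      id++;
    }

  std::vector<double> e_l, e_r;
  std::vector<int> e_p, e_c;

  double t = 0.0;
  int ei = 0;
  long guard = 0;
  while (!lin.empty()) {
    if (++guard > 100000000L) stop("coalescent simulation failed to terminate");
    // per-pop lineage counts
    std::vector<int> k(npop, 0);
    for (const Lineage& L : lin) k[L.pop]++;

    // candidate waiting times
    double w_rec = R_PosInf, w_mig = R_PosInf, w_coal = R_PosInf;
    int coal_pop = -1;
    double tot_ext = 0.0, tot_mig = 0.0;
    if (rho > 0) for (const Lineage& L : lin) tot_ext += L.extent();
    for (int p = 0; p < npop; p++) {
      if (k[p] == 0) continue;
      double mo = 0.0;
      for (int j = 0; j < npop; j++) mo += M[p][j];
      tot_mig += k[p] * mo;
    }
    if (rho > 0 && tot_ext > 0) w_rec = R::exp_rand() / (rho * tot_ext);
    if (tot_mig > 0) w_mig = R::exp_rand() / tot_mig;
    for (int p = 0; p < npop; p++) {
      if (k[p] < 2) continue;
      double rate0 = k[p] * (k[p] - 1.0) / ps[p].size;  // at ps[p].tref scale
      double g = ps[p].growth;
      double w;
      double E = R::exp_rand();
      if (g == 0.0) {
        w = E / rate0;
      } else {
        // rate(t+s) = rate0 * exp(g*(t+s-tref))
        double c = rate0 * std::exp(g * (t - ps[p].tref));
        double arg = 1.0 + E * g / c;
        w = (arg <= 0.0) ? R_PosInf : std::log(arg) / g;
      }
      if (w < w_coal) { w_coal = w; coal_pop = p; }
    }

    double w_min = std::min({w_rec, w_mig, w_coal});
    double t_next_ev = (ei < nev) ? ev_time[ei] : R_PosInf;

    if (t + w_min >= t_next_ev) {
      if (!R_finite(t_next_ev)) {
        std::string bad;
        std::vector<bool> seen(npop, false);
        for (const Lineage& L : lin) seen[L.pop] = true;
        for (int p = 0; p < npop; p++)
          if (seen[p]) bad += (bad.empty() ? "" : ", ") + std::to_string(p + 1);
        stop("lineages cannot coalesce: populations {" + bad +
             "} remain isolated with zero rates and no pending events");
      }
      // apply all events at this time
      t = t_next_ev;
      while (ei < nev && ev_time[ei] <= t + 1e-12) {
        int ty = ev_type[ei], i = ev_i[ei] - 1, j = ev_j[ei] - 1;
        double v = ev_val[ei];
        if (ty == 1) {            // merge: move lineages i -> j
          for (Lineage& L : lin) if (L.pop == i) L.pop = j;
          ps[i].active = false;
          for (int q = 0; q < npop; q++) { M[i][q] = 0.0; M[q][i] = 0.0; }
        } else if (ty == 2) {     // size change (also resets growth)
          ps[i].size = v; ps[i].growth = 0.0; ps[i].tref = t;
        } else if (ty == 3) {     // growth change
          ps[i].size = ps[i].size * std::exp(-ps[i].growth * (t - ps[i].tref));
          ps[i].growth = v; ps[i].tref = t;
        } else if (ty == 4) {     // single migration entry
          M[i][j] = v;
        } else if (ty == 5) {     // all off-diagonal entries
          for (int a = 0; a < npop; a++)
            for (int b = 0; b < npop; b++)
              if (a != b && ps[a].active && ps[b].active) M[a][b] = v;
        }
        ei++;
      }
      continue;
    }

    t += w_min;
    if (w_min == w_coal) {
      // pick two distinct lineages in coal_pop
      std::vector<int> idx;
      for (size_t q = 0; q < lin.size(); q++) if (lin[q].pop == coal_pop) idx.push_back((int)q);
      int a = (int)(R::unif_rand() * idx.size());
      int b = (int)(R::unif_rand() * (idx.size() - 1));
      if (b >= a) b++;
      int ia = idx[a], ib = idx[b];
      node_time.push_back(t);
      int w_node = (int)node_time.size() - 1;
      bool any_overlap = false;
      std::vector<Seg> merged = merge_segs(lin[ia].segs, lin[ib].segs, w_node, t,
                                           n, e_l, e_r, e_p, e_c, any_overlap);
      if (!any_overlap) node_time.back() = t;  // node unused by edges; harmless
      lin[ia].segs = std::move(merged);
      // remove ib (and ia too if empty)
      if (ib != (int)lin.size() - 1) std::swap(lin[ib], lin.back());
      if (ia == (int)lin.size() - 1) ia = ib;  // ia had been moved into slot ib
      lin.pop_back();
      if (lin[ia].segs.empty()) {
        if (ia != (int)lin.size() - 1) std::swap(lin[ia], lin.back());
        lin.pop_back();
      }
    } else if (w_min == w_rec) {
      // pick lineage weighted by extent
      double u = R::unif_rand() * tot_ext, acc = 0.0;
      int pick = (int)lin.size() - 1;
      for (size_t q = 0; q < lin.size(); q++) {
        acc += lin[q].extent();
        if (u <= acc) { pick = (int)q; break; }
      }
      Lineage& L = lin[pick];
      double lo = L.segs.front().l, hi = L.segs.back().r;
      double x = R::runif(lo, hi);
      std::vector<Seg> left, right;
      for (const Seg& s : L.segs) {
        if (s.r <= x) left.push_back(s);
        else if (s.l >= x) right.push_back(s);
        else { left.push_back({s.l, x, s.node, s.cnt}); right.push_back({x, s.r, s.node, s.cnt}); }
      }
      if (!left.empty() && !right.empty()) {
        L.segs = std::move(left);
        lin.push_back({L.pop, std::move(right)});
      }
    } else {
      // migration: pick (lineage, dest) weighted
      double u = R::unif_rand() * tot_mig, acc = 0.0;
      for (size_t q = 0; q < lin.size(); q++) {
        int p = lin[q].pop;
        for (int j = 0; j < npop; j++) {
          acc += M[p][j];
          if (u <= acc) { lin[q].pop = j; goto done_mig; }
        }
      }
      done_mig: ;
    }
  }

  return List::create(
    _["node_time"] = NumericVector(node_time.begin(), node_time.end()),
    _["edge_left"] = NumericVector(e_l.begin(), e_l.end()),
    _["edge_right"] = NumericVector(e_r.begin(), e_r.end()),
    _["edge_parent"] = IntegerVector(e_p.begin(), e_p.end()),
    _["edge_child"] = IntegerVector(e_c.begin(), e_c.end()),
    _["n_samples"] = n);
}

namespace {

// leaves below `node` restricted to the interval containing midpoint x
void collect_leaves(int node, double x, int n_samples,
                    const std::vector<std::vector<int>>& by_parent,
                    const std::vector<double>& e_l, const std::vector<double>& e_r,
                    const std::vector<int>& e_c, std::vector<int>& out) {
  if (node < n_samples) { out.push_back(node); return; }
  const std::vector<int>& kids = by_parent[node];
  for (int e : kids)
    if (e_l[e] <= x && x < e_r[e])
      collect_leaves(e_c[e], x, n_samples, by_parent, e_l, e_r, e_c, out);
}

}  // namespace

// [[Rcpp::export(name = ".arg_drop_mutations")]]
List arg_drop_mutations(List arg, double s_or_theta, bool fixed_s) {
  RNGScope scope;
  NumericVector node_time = arg["node_time"];
  NumericVector el = arg["edge_left"], er = arg["edge_right"];
  IntegerVector ep = arg["edge_parent"], ec = arg["edge_child"];
  int n = as<int>(arg["n_samples"]);
  int ne = el.size();

  std::vector<double> e_l(el.begin(), el.end()), e_r(er.begin(), er.end());
  std::vector<int> e_p(ep.begin(), ep.end()), e_c(ec.begin(), ec.end());

  // genome intervals between recombination breakpoints
  std::vector<double> bp;
  bp.reserve(2 * ne + 2);
  for (int e = 0; e < ne; e++) { bp.push_back(e_l[e]); bp.push_back(e_r[e]); }
  bp.push_back(0.0); bp.push_back(1.0);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::abs(a - b) < 1e-15; }),
           bp.end());
  int ni = (int)bp.size() - 1;

  // per-interval edge lists and branch-length totals
  std::vector<std::vector<int>> iv_edges(ni);
  std::vector<double> iv_len(ni, 0.0), iv_w(ni, 0.0);
  for (int j = 0; j < ni; j++) {
    double mid = 0.5 * (bp[j] + bp[j + 1]);
    for (int e = 0; e < ne; e++)
      if (e_l[e] <= mid && mid < e_r[e]) {
        iv_edges[j].push_back(e);
        iv_len[j] += node_time[e_p[e]] - node_time[e_c[e]];
      }
    iv_w[j] = iv_len[j] * (bp[j + 1] - bp[j]);
  }
  double W = 0.0;
  for (int j = 0; j < ni; j++) W += iv_w[j];

  int S;
  if (fixed_s) S = (int)std::lround(s_or_theta);
  else S = (int)R::rpois(s_or_theta * W);

  std::vector<std::vector<int>> by_parent(node_time.size());
  for (int e = 0; e < ne; e++) by_parent[e_p[e]].push_back(e);

  NumericVector pos(S);
  IntegerMatrix G(n, S);
  for (int s = 0; s < S; s++) {
    if (W <= 0) stop("cannot place mutations on a zero-length genealogy");
    double u = R::unif_rand() * W, acc = 0.0;
    int j = ni - 1;
    for (int q = 0; q < ni; q++) { acc += iv_w[q]; if (u <= acc) { j = q; break; } }
    double v = R::unif_rand() * iv_len[j], acc2 = 0.0;
    int e = iv_edges[j].back();
    for (int q : iv_edges[j]) {
      acc2 += node_time[e_p[q]] - node_time[e_c[q]];
      if (v <= acc2) { e = q; break; }
    }
    pos[s] = R::runif(bp[j], bp[j + 1]);
    std::vector<int> leaves;
    collect_leaves(e_c[e], 0.5 * (bp[j] + bp[j + 1]), n, by_parent,
                   e_l, e_r, e_c, leaves);
    for (int lf : leaves) G(lf, s) = 1;
  }

  // order columns by position
  IntegerVector ord(S);
  std::vector<int> idx(S);
  for (int s = 0; s < S; s++) idx[s] = s;
  std::sort(idx.begin(), idx.end(), [&](int a, int b) { return pos[a] < pos[b]; });
  NumericVector pos2(S);
  IntegerMatrix G2(n, S);
  for (int s = 0; s < S; s++) {
    pos2[s] = pos[idx[s]];
    for (int i = 0; i < n; i++) G2(i, s) = G(i, idx[s]);
  }

  return List::create(_["positions"] = pos2, _["genotypes"] = G2,
                      _["n_trees"] = ni, _["total_branch_weight"] = W);
}

// [[Rcpp::export(name = ".arg_tmrca")]]
double arg_tmrca(List arg, double x) {
  NumericVector node_time = arg["node_time"];
  NumericVector el = arg["edge_left"], er = arg["edge_right"];
  IntegerVector ep = arg["edge_parent"];
  double tm = 0.0;
  for (int e = 0; e < el.size(); e++)
    if (el[e] <= x && x < er[e]) tm = std::max(tm, node_time[ep[e]]);
  return tm;
}

// [[Rcpp::export(name = ".arg_n_trees")]]
int arg_n_trees(List arg) {
  NumericVector el = arg["edge_left"], er = arg["edge_right"];
  std::vector<double> bp;
  for (int e = 0; e < el.size(); e++) { bp.push_back(el[e]); bp.push_back(er[e]); }
  bp.push_back(0.0); bp.push_back(1.0);
  std::sort(bp.begin(), bp.end());
  bp.erase(std::unique(bp.begin(), bp.end(),
                       [](double a, double b) { return std::abs(a - b) < 1e-15; }),
           bp.end());
  return (int)bp.size() - 1;
}
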