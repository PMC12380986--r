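#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Multiresolution region merging for 3-band reflectance images.
//
// Each region tracks cell count, per-band sum / sum of squares, perimeter in
// cell sides, bounding box and a neighbour map (neighbour id -> shared sides).
// The merge cost between adjacent regions a, b is
//   f = (1 - shape_w) * dh_color + shape_w * dh_shape
//   dh_color = sum_bands [ n_m * sd_m - (n_a * sd_a + n_b * sd_b) ]
//   dh_shape = compact_w * dh_cmpct + (1 - compact_w) * dh_smooth
//   h_cmpct(region) = n * p / sqrt(n),  h_smooth(region) = n * p / b
// with p the region perimeter, b its bounding-box perimeter (sides), sd the
// population standard deviation of band values. Merges run while f < scale^2
// using local mutual-best-fitting with a fixed ascending-id scan; ties break
// to the lower candidate id, so the result is deterministic.

struct Region {
  bool active = false;
  double n = 0;
  double sum[3] = {0, 0, 0};
  double ssq[3] = {0, 0, 0};
  double perim = 0;
  int rmin = 0, rmax = 0, cmin = 0, cmax = 0;
  std::map<int, double> nb;  // ordered: deterministic iteration
};

static inline double h_color(const Region &r) {
  double h = 0;
  for (int b = 0; b < 3; ++b) {
    double mu = r.sum[b] / r.n;
    double var = r.ssq[b] / r.n - mu * mu;
    if (var < 0) var = 0;
    h += r.n * std::sqrt(var);
  }
  return h;
}

static inline double h_shape(const Region &r, double compact_w) {
  double bbox = 2.0 * ((r.rmax - r.rmin + 1) + (r.cmax - r.cmin + 1));
  double h_cmpct = r.perim * std::sqrt(r.n);        // n * p / sqrt(n)
  double h_smooth = r.n * r.perim / bbox;
  return compact_w * h_cmpct + (1.0 - compact_w) * h_smooth;
}

static double merge_cost(const Region &a, const Region &b, double shared,
                         double shape_w, double compact_w) {
  Region m;
  m.n = a.n + b.n;
  for (int k = 0; k < 3; ++k) {
    m.sum[k] = a.sum[k] + b.sum[k];
    m.ssq[k] = a.ssq[k] + b.ssq[k];
  }
  m.perim = a.perim + b.perim - 2.0 * shared;
  m.rmin = std::min(a.rmin, b.rmin); m.rmax = std::max(a.rmax, b.rmax);
  m.cmin = std::min(a.cmin, b.cmin); m.cmax = std::max(a.cmax, b.cmax);
  double dc = h_color(m) - h_color(a) - h_color(b);
  double ds = h_shape(m, compact_w) - h_shape(a, compact_w) - h_shape(b, compact_w);
  return (1.0 - shape_w) * dc + shape_w * ds;
}

// best neighbour of region id: minimal merge cost, ties -> lower neighbour id
static int best_neighbour(const std::vector<Region> &reg, int id,
                          double shape_w, double compact_w, double *cost_out) {
  const Region &r = reg[id];
  int best = -1;
  double best_cost = R_PosInf;
  for (std::map<int, double>::const_iterator it = r.nb.begin();
       it != r.nb.end(); ++it) {
    double f = merge_cost(r, reg[it->first], it->second, shape_w, compact_w);
    if (f < best_cost) { best_cost = f; best = it->first; }
  }
  *cost_out = best_cost;
  return best;
}

static void merge_regions(std::vector<Region> &reg, std::vector<int> &parent,
                          int keep, int drop) {
  Region &a = reg[keep];
  Region &b = reg[drop];
  double shared = a.nb[drop];
  a.n += b.n;
  for (int k = 0; k < 3; ++k) { a.sum[k] += b.sum[k]; a.ssq[k] += b.ssq[k]; }
  a.perim += b.perim - 2.0 * shared;
  a.rmin = std::min(a.rmin, b.rmin); a.rmax = std::max(a.rmax, b.rmax);
  a.cmin = std::min(a.cmin, b.cmin); a.cmax = std::max(a.cmax, b.cmax);
  a.nb.erase(drop);
  for (std::map<int, double>::iterator it = b.nb.begin(); it != b.nb.end(); ++it) {
    int other = it->first;
    if (other == keep) continue;
    a.nb[other] += it->second;
    reg[other].nb.erase(drop);
    reg[other].nb[keep] += it->second;
  }
  b.active = false;
  b.nb.clear();
  parent[drop] = keep;
}

static int find_root(std::vector<int> &parent, int i) {
  int r = i;
  while (parent[r] != r) r = parent[r];
  while (parent[i] != r) { int nxt = parent[i]; parent[i] = r; i = nxt; }
  return r;
}

// Relabel active regions 1..K in order of first (column-major) member cell.
static IntegerMatrix finalize_labels(std::vector<int> &parent, int nr, int nc,
                                     const LogicalMatrix &valid) {
  IntegerMatrix out(nr, nc);
  std::map<int, int> renum;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!valid(r, c)) { out(r, c) = 0; continue; }
      int root = find_root(parent, r + c * nr);
      std::map<int, int>::iterator it = renum.find(root);
      if (it == renum.end()) { renum[root] = ++next; out(r, c) = next; }
      else out(r, c) = it->second;
    }
  }
  return out;
}

// [[Rcpp::export(name = ".segment_cpp")]]
IntegerMatrix segment_cpp(NumericMatrix b1, NumericMatrix b2, NumericMatrix b3,
                          LogicalMatrix valid, double scale, double shape_w,
                          double compact_w) {
  const int nr = b1.nrow(), nc = b1.ncol();
  const int ncell = nr * nc;
  const double thr = R_FINITE(scale) ? scale * scale : R_PosInf;
  std::vector<Region> reg(ncell);
  std::vector<int> parent(ncell);
  for (int i = 0; i < ncell; ++i) parent[i] = i;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!valid(r, c)) continue;
      int id = r + c * nr;
      Region &rg = reg[id];
      rg.active = true;
      rg.n = 1;
      double v[3] = {b1(r, c), b2(r, c), b3(r, c)};
      for (int k = 0; k < 3; ++k) { rg.sum[k] = v[k]; rg.ssq[k] = v[k] * v[k]; }
      rg.perim = 4;
      rg.rmin = rg.rmax = r;
      rg.cmin = rg.cmax = c;
      if (r + 1 < nr && valid(r + 1, c)) {
        rg.nb[id + 1] = 1; reg[id + 1].nb[id] = 1;
      }
      if (c + 1 < nc && valid(r, c + 1)) {
        rg.nb[id + nr] = 1; reg[id + nr].nb[id] = 1;
      }
    }
  }

  bool merged_any = true;
  while (merged_any) {
    merged_any = false;
    for (int id = 0; id < ncell; ++id) {
      if (!reg[id].active || reg[id].nb.empty()) continue;
      double f1;
      int cand = best_neighbour(reg, id, shape_w, compact_w, &f1);
      if (cand < 0 || !(f1 < thr)) continue;
      double f2;
      int back = best_neighbour(reg, cand, shape_w, compact_w, &f2);
      if (back != id) continue;  // not mutual best
      int keep = std::min(id, cand), drop = std::max(id, cand);
      merge_regions(reg, parent, keep, drop);
      merged_any = true;
    }
    Rcpp::checkUserInterrupt();
  }
  return finalize_labels(parent, nr, nc, valid);
}

// Iteratively merge segments below a cell-count threshold into the adjacent
// segment sharing the longest boundary (ties -> lower label id); sub-threshold
// segments with no neighbour become nodata (0).
//
// [[Rcpp::export(name = ".enforce_min_area_cpp")]]
IntegerMatrix enforce_min_area_cpp(IntegerMatrix labels, double min_cells) {
  const int nr = labels.nrow(), nc = labels.ncol();
  int maxlab = 0;
  for (int i = 0; i < nr * nc; ++i) maxlab = std::max(maxlab, labels[i]);
  if (maxlab == 0) return clone(labels);

  std::vector<double> count(maxlab + 1, 0);
  std::vector< std::map<int, double> > nb(maxlab + 1);
  std::vector<int> alias(maxlab + 1);
  for (int l = 0; l <= maxlab; ++l) alias[l] = l;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int a = labels(r, c);
      if (a == 0) continue;
      count[a] += 1;
      if (r + 1 < nr) {
        int b = labels(r + 1, c);
        if (b != 0 && b != a) { nb[a][b] += 1; nb[b][a] += 1; }
      }
      if (c + 1 < nc) {
        int b = labels(r, c + 1);
        if (b != 0 && b != a) { nb[a][b] += 1; nb[b][a] += 1; }
      }
    }
  }

  bool again = true;
  while (again) {
    again = false;
    for (int l = 1; l <= maxlab; ++l) {
      if (alias[l] != l || count[l] == 0 || count[l] >= min_cells) continue;
      // neighbour with longest shared boundary; ties -> lower id
      int best = -1;
      double best_shared = -1;
      for (std::map<int, double>::iterator it = nb[l].begin();
           it != nb[l].end(); ++it) {
        if (it->second > best_shared) { best_shared = it->second; best = it->first; }
      }
      if (best < 0) {         // isolated: remove
        count[l] = 0;
        alias[l] = 0;
        again = true;
        continue;
      }
      // merge l into best (the neighbour keeps its label)
      count[best] += count[l];
      count[l] = 0;
      nb[best].erase(l);
      for (std::map<int, double>::iterator it = nb[l].begin();
           it != nb[l].end(); ++it) {
        int other = it->first;
        if (other == best) continue;
        nb[best][other] += it->second;
        nb[other].erase(l);
        nb[other][best] += it->second;
      }
      nb[l].clear();
      alias[l] = best;
      again = true;
    }
  }

  // resolve alias chains, then relabel 1..K by first column-major cell
  for (int l = 1; l <= maxlab; ++l) {
    int r = l;
    while (r != 0 && alias[r] != r) r = alias[r];
    alias[l] = r;
  }
  IntegerMatrix out(nr, nc);
  std::map<int, int> renum;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int a = labels(r, c);
      if (a == 0) { out(r, c) = 0; continue; }
      int root = alias[a];
      if (root == 0) { out(r, c) = 0; continue; }
      std::map<int, int>::iterator it = renum.find(root);
      if (it == renum.end()) { renum[root] = ++next; out(r, c) = next; }
      else out(r, c) = it->second;
    }
  }
  return out;
}
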