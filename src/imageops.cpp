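#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// ---- union-find ------------------------------------------------------------

static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

// ---- connected components, 8-connectivity ---------------------------------

// Two-pass labeling. mask: integer matrix (0 = background, nonzero = fg).
// Returns integer matrix with labels 1..K in first-encounter order.
// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent(1, 0); // parent[0] unused
  int next = 0;

  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j)) continue;
      // neighbours already visited in column-major order:
      // (i-1,j), (i-1,j-1), (i,j-1), (i+1,j-1)
      int nb[4][2] = {{i - 1, j}, {i - 1, j - 1}, {i, j - 1}, {i + 1, j - 1}};
      int best = 0;
      for (int k = 0; k < 4; ++k) {
        int ii = nb[k][0], jj = nb[k][1];
        if (ii < 0 || jj < 0 || ii >= nr) continue;
        int l = lab(ii, jj);
        if (l == 0) continue;
        int r = uf_find(parent, l);
        if (best == 0) best = r;
        else if (r != best) {
          // union: keep smaller root
          int a = std::min(best, r), b = std::max(best, r);
          parent[b] = a;
          best = a;
        }
      }
      if (best == 0) {
        ++next;
        parent.push_back(next);
        lab(i, j) = next;
      } else {
        lab(i, j) = best;
      }
    }
  }
  // second pass: flatten and renumber consecutively in first-appearance order
  std::vector<int> newid(next + 1, 0);
  int k = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (lab(i, j)) {
        int r = uf_find(parent, lab(i, j));
        if (!newid[r]) newid[r] = ++k;
        lab(i, j) = newid[r];
      }
  lab.attr("n_labels") = k;
  return lab;
}

// ---- exact Euclidean distance transform ------------------------------------

// Felzenszwalb-Huttenlocher 1D squared distance transform with implicit
// zero-valued sentinels just outside both ends (image border counts as
// background, so object peaks near edges are not inflated).
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n) {
  // work on extended array of size n+2 with f=-? sentinel value 0 at -1 and n
  int m = n + 2;
  std::vector<int> v(m);
  std::vector<double> z(m + 1), fe(m);
  fe[0] = 0.0;
  for (int q = 0; q < n; ++q) fe[q + 1] = f[q];
  fe[m - 1] = 0.0;
  int kk = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < m; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((fe[q] + (double)q * q) - (fe[p] + (double)p * p)) / (2.0 * q - 2.0 * p);
      if (s <= z[kk]) { --kk; } else break;
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 1; q <= n; ++q) {
    while (z[kk + 1] < q) ++kk;
    int p = v[kk];
    d[q - 1] = (double)(q - p) * (q - p) + fe[p];
  }
}

// Squared EDT to nearest background (or border) for foreground pixels.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericMatrix edt_cpp(IntegerMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix d(nr, nc);
  std::vector<double> f(std::max(nr, nc)), out(std::max(nr, nc));
  // columns first
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) f[i] = mask(i, j) ? INF : 0.0;
    dt1d(f, out, nr);
    for (int i = 0; i < nr; ++i) d(i, j) = out[i];
  }
  // then rows
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) f[j] = d(i, j);
    dt1d(f, out, nc);
    for (int j = 0; j < nc; ++j) d(i, j) = out[j];
  }
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) d(i, j) = std::sqrt(d(i, j));
  return d;
}

// ---- declustering ----------------------------------------------------------

// Watershed-style splitting of every labeled component on its distance
// transform.  Peaks found by flooding in decreasing EDT order; a saddle at
// level h between two lobes with peak heights p1 <= p2 merges them when
// h >= factor * p1.  Every pixel is then assigned to the nearest surviving
// centre within its parent component.
// Returns list: labels (child labels 1..M), parent (length M, original
// component of each child), center_row/center_col (0-based peak pixel).
// [[Rcpp::export(name = ".decluster_cpp")]]
List decluster_cpp(IntegerMatrix labels, NumericMatrix edt, double factor,
                   double min_drop = 0.5) {
  int nr = labels.nrow(), nc = labels.ncol();
  long n = (long)nr * nc;

  // foreground pixels sorted by decreasing EDT (stable on index)
  std::vector<long> fg;
  fg.reserve(1024);
  for (long p = 0; p < n; ++p)
    if (labels[p]) fg.push_back(p);
  std::stable_sort(fg.begin(), fg.end(), [&](long a, long b) {
    return edt[a] > edt[b];
  });

  std::vector<int> region(n, 0);     // original flooding region id per pixel
  std::vector<int> parent1(1, 0);    // DSU over flooding trees
  std::vector<double> peakval(1, 0); // founding EDT per region
  std::vector<long> peakpix(1, 0);   // founding pixel per region
  int nreg = 0;

  struct Edge { int a, b; double lev; };
  std::vector<Edge> edges;

  int di[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  int dj[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

  for (size_t t = 0; t < fg.size(); ++t) {
    long p = fg[t];
    int i = (int)(p % nr), j = (int)(p / nr);
    int mylab = labels[p];
    int myreg = 0;
    int roots_seen[8]; int nseen = 0;
    for (int k = 0; k < 8; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
      long q = (long)ii + (long)jj * nr;
      if (labels[q] != mylab || region[q] == 0) continue;
      int r = uf_find(parent1, region[q]);
      bool seen = false;
      for (int s = 0; s < nseen; ++s) if (roots_seen[s] == r) { seen = true; break; }
      if (seen) continue;
      roots_seen[nseen++] = r;
      if (myreg == 0) {
        myreg = region[q]; // join first tree via this neighbour's region
      } else {
        // saddle between p's tree and this tree at level edt[p]
        edges.push_back({region[p] ? region[p] : myreg, region[q], edt[p]});
        int ra = uf_find(parent1, myreg), rb = r;
        parent1[std::max(ra, rb)] = std::min(ra, rb);
      }
    }
    if (myreg == 0) {
      ++nreg;
      parent1.push_back(nreg);
      peakval.push_back(edt[p]);
      peakpix.push_back(p);
      myreg = nreg;
    }
    region[p] = myreg;
  }

  // cluster regions: process saddles in recorded (decreasing-level) order
  std::vector<int> parent2(nreg + 1);
  std::vector<double> cpeak(nreg + 1);
  std::vector<long> cpix(nreg + 1);
  for (int r = 0; r <= nreg; ++r) { parent2[r] = r; cpeak[r] = (r ? peakval[r] : 0); cpix[r] = (r ? peakpix[r] : 0); }
  for (size_t e = 0; e < edges.size(); ++e) {
    int ra = uf_find(parent2, edges[e].a);
    int rb = uf_find(parent2, edges[e].b);
    if (ra == rb) continue;
    double lo = std::min(cpeak[ra], cpeak[rb]);
    // merge on a shallow relative saddle, or on a sub-pixel absolute dip
    // (discretisation ripple on thin-rod distance ridges)
    if (edges[e].lev >= factor * lo || (lo - edges[e].lev) <= min_drop) {
      // merge; representative keeps the higher peak (tie: earlier region)
      int keep = (cpeak[ra] > cpeak[rb] || (cpeak[ra] == cpeak[rb] && ra < rb)) ? ra : rb;
      int drop = (keep == ra) ? rb : ra;
      parent2[drop] = keep;
    }
  }

  // final child ids, grouped by parent component in first-encounter order
  std::vector<int> childof(nreg + 1, 0);
  std::vector<int> childparent;  // original component label per child
  std::vector<long> childcenter;
  int nchild = 0;
  for (size_t t = 0; t < fg.size(); ++t) {
    long p = fg[t];
    int r = uf_find(parent2, region[p]);
    if (!childof[r]) {
      childof[r] = ++nchild;
      childparent.push_back(labels[p]);
      childcenter.push_back(cpix[r]);
    }
  }

  // group children by parent component for nearest-centre assignment
  int nlab = 0;
  for (size_t t = 0; t < fg.size(); ++t) nlab = std::max(nlab, labels[fg[t]]);
  std::vector<std::vector<int> > comp_children(nlab + 1);
  for (int c = 0; c < nchild; ++c) comp_children[childparent[c]].push_back(c + 1);

  IntegerMatrix out(nr, nc);
  for (size_t t = 0; t < fg.size(); ++t) {
    long p = fg[t];
    int L = labels[p];
    const std::vector<int> &ch = comp_children[L];
    if (ch.size() == 1) { out[p] = ch[0]; continue; }
    int i = (int)(p % nr), j = (int)(p / nr);
    double best = std::numeric_limits<double>::infinity();
    int bestc = 0;
    for (size_t s = 0; s < ch.size(); ++s) {
      long cp = childcenter[ch[s] - 1];
      double dr = i - (double)(cp % nr), dc = j - (double)(cp / nr);
      double dd = dr * dr + dc * dc;
      if (dd < best || (dd == best && ch[s] < bestc)) { best = dd; bestc = ch[s]; }
    }
    out[p] = bestc;
  }

  IntegerVector par(nchild), crow(nchild), ccol(nchild);
  for (int c = 0; c < nchild; ++c) {
    par[c] = childparent[c];
    crow[c] = (int)(childcenter[c] % nr);
    ccol[c] = (int)(childcenter[c] / nr);
  }
  return List::create(_["labels"] = out, _["parent"] = par,
                      _["center_row"] = crow, _["center_col"] = ccol,
                      _["n_children"] = nchild);
}

// ---- per-label statistics --------------------------------------------------

// Returns matrix with one row per label 1..nlab:
// npix, sum_int, max_int, sum_row, sum_col, rmin, rmax, cmin, cmax
// [[Rcpp::export(name = ".region_stats_cpp")]]
NumericMatrix region_stats_cpp(IntegerMatrix labels, NumericMatrix img, int nlab) {
  NumericMatrix st(nlab, 9);
  for (int l = 0; l < nlab; ++l) { st(l, 5) = 1e18; st(l, 7) = 1e18; st(l, 6) = -1; st(l, 8) = -1; }
  int nr = labels.nrow(), nc = labels.ncol();
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = labels(i, j);
      if (!l) continue;
      int r = l - 1;
      st(r, 0) += 1;
      double v = img(i, j);
      st(r, 1) += v;
      if (v > st(r, 2)) st(r, 2) = v;
      st(r, 3) += i;
      st(r, 4) += j;
      if (i < st(r, 5)) st(r, 5) = i;
      if (i > st(r, 6)) st(r, 6) = i;
      if (j < st(r, 7)) st(r, 7) = j;
      if (j > st(r, 8)) st(r, 8) = j;
    }
  return st;
}

// ---- perimeter by Moore boundary tracing -----------------------------------

// Chain-code contour length per label with Vossepoel-Smeulders weights
// (straight 0.980, diagonal 1.406), which corrects the systematic bias of
// raw chain length on discretised smooth contours.  Single-pixel objects
// return 0 (caller substitutes the pixel-boundary perimeter).
// [[Rcpp::export(name = ".perimeter_cpp")]]
NumericVector perimeter_cpp(IntegerMatrix labels, int nlab) {
  int nr = labels.nrow(), nc = labels.ncol();
  NumericVector per(nlab);
  std::vector<long> start(nlab + 1, -1);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      int l = labels(i, j);
      if (l && start[l] < 0) start[l] = (long)i + (long)j * nr;
    }
  // Moore neighbourhood in clockwise order starting from W
  int di[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  int dj[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  double w[8] = {0.980, 1.406, 0.980, 1.406, 0.980, 1.406, 0.980, 1.406};
  for (int l = 1; l <= nlab; ++l) {
    long s = start[l];
    if (s < 0) continue;
    int si = (int)(s % nr), sj = (int)(s / nr);
    // is it isolated?
    bool alone = true;
    for (int k = 0; k < 8; ++k) {
      int ii = si + di[k], jj = sj + dj[k];
      if (ii >= 0 && jj >= 0 && ii < nr && jj < nc && labels(ii, jj) == l) { alone = false; break; }
    }
    if (alone) { per[l - 1] = 0.0; continue; }
    double len = 0.0;
    int ci = si, cj = sj;
    int dir = 0; // backtrack direction: came from W initially (column-major scan
                 // guarantees nothing left/up of start belongs to the object)
    int firstmove = -1;
    long guard = 4L * (nr + nc) * 8L + 64;
    while (guard-- > 0) {
      int k, found = -1;
      for (int t = 0; t < 8; ++t) {
        k = (dir + 1 + t) % 8; // start scanning just past the backtrack dir
        int ii = ci + di[k], jj = cj + dj[k];
        if (ii < 0 || jj < 0 || ii >= nr || jj >= nc) continue;
        if (labels(ii, jj) == l) { found = k; break; }
      }
      if (found < 0) break; // cannot happen for non-isolated objects
      if (ci == si && cj == sj) {
        if (firstmove < 0) firstmove = found;
        else if (found == firstmove && len > 0) break; // closed the contour
      }
      ci += di[found];
      cj += dj[found];
      len += w[found];
      dir = (found + 4) % 8; // new backtrack = opposite of travel
      if (ci == si && cj == sj) {
        // peek: next move from start; loop top will decide termination
      }
    }
    per[l - 1] = len;
  }
  return per;
}
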