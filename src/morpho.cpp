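// Low-level image-morphology kernels used by segmentation and background
// subtraction. All matrices are column-major (R layout); coordinates are
// 0-based (row, col) internally.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const int DR8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int DC8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Connected-component labelling (8-connectivity). Labels are assigned
// 1..n in order of first encounter in a row-major raster scan, so label k
// is the k-th object by raster position of its top-left pixel.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<int> stack;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.clear();
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % nr, pc = p / nr;
        for (int k = 0; k < 8; ++k) {
          int qr = pr + DR8[k], qc = pc + DC8[k];
          if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
          if (mask(qr, qc) && lab(qr, qc) == 0) {
            lab(qr, qc) = next;
            stack.push_back(qr + qc * nr);
          }
        }
      }
    }
  }
  return lab;
}

// 1-D squared distance transform (Felzenszwalb & Huttenlocher).
static void edt1d(const std::vector<double>& f, std::vector<double>& d,
                  std::vector<int>& v, std::vector<double>& z) {
  int n = (int)f.size();
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance transform: distance from each foreground pixel
// to the nearest background pixel (pixels outside the image count as
// background, so objects touching the border stay thin there).
// [[Rcpp::export(name = ".edt")]]
NumericMatrix edt(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  // columns first
  {
    std::vector<double> f(nr), d(nr), z(nr + 1);
    std::vector<int> v(nr);
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
      edt1d(f, d, v, z);
      for (int r = 0; r < nr; ++r) {
        // image border acts as background one step outside
        double db1 = (double)(r + 1) * (r + 1);
        double db2 = (double)(nr - r) * (nr - r);
        g(r, c) = std::min(d[r], std::min(db1, db2));
      }
    }
  }
  {
    std::vector<double> f(nc), d(nc), z(nc + 1);
    std::vector<int> v(nc);
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) f[c] = g(r, c);
      edt1d(f, d, v, z);
      for (int c = 0; c < nc; ++c) {
        double db1 = (double)(c + 1) * (c + 1);
        double db2 = (double)(nc - c) * (nc - c);
        double val = std::min(d[c], std::min(db1, db2));
        g(r, c) = std::sqrt(val);
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i) if (!mask[i]) g[i] = 0.0;
  return g;
}

// Morphological (grayscale) reconstruction by dilation of `marker` under
// `mask`, 8-connectivity. Hybrid raster/anti-raster algorithm (Vincent
// 1993) followed by a FIFO propagation pass.
// [[Rcpp::export(name = ".gray_reconstruct")]]
NumericMatrix gray_reconstruct(NumericMatrix marker, NumericMatrix mask) {
  int nr = marker.nrow(), nc = marker.ncol();
  NumericMatrix J(clone(marker));
  // raster scan
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double m = J(r, c);
      if (r > 0) m = std::max(m, J(r - 1, c));
      if (c > 0) m = std::max(m, J(r, c - 1));
      if (r > 0 && c > 0) m = std::max(m, J(r - 1, c - 1));
      if (r < nr - 1 && c > 0) m = std::max(m, J(r + 1, c - 1));
      J(r, c) = std::min(m, mask(r, c));
    }
  // anti-raster scan, queueing unstable pixels
  std::queue<int> q;
  for (int c = nc - 1; c >= 0; --c)
    for (int r = nr - 1; r >= 0; --r) {
      double m = J(r, c);
      if (r < nr - 1) m = std::max(m, J(r + 1, c));
      if (c < nc - 1) m = std::max(m, J(r, c + 1));
      if (r < nr - 1 && c < nc - 1) m = std::max(m, J(r + 1, c + 1));
      if (r > 0 && c < nc - 1) m = std::max(m, J(r - 1, c + 1));
      J(r, c) = std::min(m, mask(r, c));
      for (int k = 0; k < 8; ++k) {
        int qr = r + DR8[k], qc = c + DC8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        if (J(qr, qc) < J(r, c) && J(qr, qc) < mask(qr, qc)) {
          q.push(r + c * nr);
          break;
        }
      }
    }
  while (!q.empty()) {
    int p = q.front(); q.pop();
    int pr = p % nr, pc = p / nr;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      if (J(qr, qc) < J(pr, pc) && mask(qr, qc) != J(qr, qc)) {
        J(qr, qc) = std::min(J(pr, pc), mask(qr, qc));
        q.push(qr + qc * nr);
      }
    }
  }
  return J;
}

// Marker-driven watershed (Meyer flooding) on elevation -edt restricted to
// `mask`. Pixels where two labels meet become 0 (separation lines).
// [[Rcpp::export(name = ".watershed_flood")]]
IntegerMatrix watershed_flood(NumericMatrix edtmap, IntegerMatrix markers,
                              LogicalMatrix mask) {
  int nr = edtmap.nrow(), nc = edtmap.ncol();
  IntegerMatrix lab(clone(markers));
  // priority queue: highest EDT first; FIFO order within ties
  typedef std::pair<double, long long> Node; // (-edt, order*ncells + index)
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  long long order = 0;
  long long n = (long long)nr * nc;
  std::vector<char> queued(nr * nc, 0);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      if (lab(r, c) <= 0) continue;
      for (int k = 0; k < 8; ++k) {
        int qr = r + DR8[k], qc = c + DC8[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        int qi = qr + qc * nr;
        if (mask(qr, qc) && lab(qr, qc) == 0 && !queued[qi]) {
          queued[qi] = 1;
          pq.push(Node(-edtmap(qr, qc), order * n + qi));
          ++order;
        }
      }
    }
  while (!pq.empty()) {
    Node nd = pq.top(); pq.pop();
    int pi = (int)(nd.second % n);
    int pr = pi % nr, pc = pi / nr;
    if (lab(pr, pc) != 0) continue;
    int found = 0;
    bool conflict = false;
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int l = lab(qr, qc);
      if (l > 0) {
        if (found == 0) found = l;
        else if (found != l) { conflict = true; break; }
      }
    }
    if (conflict) {
      lab(pr, pc) = -1; // watershed line
      continue;
    }
    lab(pr, pc) = found; // found > 0 by construction
    for (int k = 0; k < 8; ++k) {
      int qr = pr + DR8[k], qc = pc + DC8[k];
      if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
      int qi = qr + qc * nr;
      if (mask(qr, qc) && lab(qr, qc) == 0 && !queued[qi]) {
        queued[qi] = 1;
        pq.push(Node(-edtmap(qr, qc), order * n + qi));
        ++order;
      }
    }
  }
  for (int i = 0; i < nr * nc; ++i) if (lab[i] < 0) lab[i] = 0;
  return lab;
}

// Rolling-ball background: grayscale opening with a spherical structuring
// element of the given radius. Direct O(n * r^2) evaluation; adequate for
// the image sizes this package targets.
// [[Rcpp::export(name = ".rolling_ball_bg")]]
NumericMatrix rolling_ball_bg(NumericMatrix img, double radius) {
  int nr = img.nrow(), nc = img.ncol();
  int ri = (int)std::floor(radius);
  // precompute ball heights (offset so the element's top is 0)
  std::vector<int> offs_r, offs_c;
  std::vector<double> h;
  for (int dr = -ri; dr <= ri; ++dr)
    for (int dc = -ri; dc <= ri; ++dc) {
      double d2 = (double)dr * dr + (double)dc * dc;
      if (d2 <= radius * radius) {
        offs_r.push_back(dr);
        offs_c.push_back(dc);
        h.push_back(std::sqrt(radius * radius - d2) - radius);
      }
    }
  int m = (int)h.size();
  NumericMatrix ero(nr, nc), bg(nr, nc);
  const double INF = std::numeric_limits<double>::infinity();
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double mn = INF;
      for (int k = 0; k < m; ++k) {
        int qr = r + offs_r[k], qc = c + offs_c[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        double v = img(qr, qc) - h[k];
        if (v < mn) mn = v;
      }
      ero(r, c) = mn;
    }
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double mx = -INF;
      for (int k = 0; k < m; ++k) {
        int qr = r - offs_r[k], qc = c - offs_c[k];
        if (qr < 0 || qr >= nr || qc < 0 || qc >= nc) continue;
        double v = ero(qr, qc) + h[k];
        if (v > mx) mx = v;
      }
      bg(r, c) = mx;
    }
  return bg;
}
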