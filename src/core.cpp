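#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// 8-neighbour offsets in row-major order: (-1,-1),(-1,0),(-1,1),(0,-1),(0,1),(1,-1),(1,0),(1,1)
static const int NB_DR[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
static const int NB_DC[8] = {-1, 0, 1, -1, 1, -1, 0, 1};

// Moore neighbourhood in clockwise order starting north (image rows grow downward)
static const int CW_DR[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
static const int CW_DC[8] = {0, 1, 1, 1, 0, -1, -1, -1};

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(LogicalMatrix mask) {
  int M = mask.nrow(), N = mask.ncol();
  IntegerMatrix labels(M, N);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  // scan rows fastest within columns (R storage order); label ids follow discovery order
  for (int c = 0; c < N; ++c) {
    for (int r = 0; r < M; ++r) {
      if (!mask(r, c) || labels(r, c) != 0) continue;
      ++next;
      labels(r, c) = next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front();
        q.pop();
        for (int k = 0; k < 8; ++k) {
          int nr = p.first + NB_DR[k], nc = p.second + NB_DC[k];
          if (nr < 0 || nr >= M || nc < 0 || nc >= N) continue;
          if (mask(nr, nc) && labels(nr, nc) == 0) {
            labels(nr, nc) = next;
            q.push(std::make_pair(nr, nc));
          }
        }
      }
    }
  }
  labels.attr("n_components") = next;
  return labels;
}

static int dir_index(int dr, int dc) {
  for (int k = 0; k < 8; ++k)
    if (CW_DR[k] == dr && CW_DC[k] == dc) return k;
  return -1;
}

// Outer-boundary chain-code length of one labelled component (Moore tracing).
// Axis moves count 1, diagonal moves sqrt(2); isolated pixels get 4.
static double trace_perimeter(const IntegerMatrix& labels, int lab, int sr, int sc) {
  int M = labels.nrow(), N = labels.ncol();
  // start pixel must be the topmost-leftmost pixel of the component (row-major)
  int cr = sr, cc = sc;
  int bdir = 6; // backtrack cell initially to the west
  double len = 0.0;
  int first_r = -1, first_c = -1, first_dir = -1;
  long guard = 0, maxit = 8L * (long)M * (long)N + 16;
  while (true) {
    if (++guard > maxit) break; // defensive; cannot trigger for valid masks
    int found = -1;
    for (int k = 1; k <= 8; ++k) {
      int d = (bdir + k) % 8;
      int nr = cr + CW_DR[d], nc = cc + CW_DC[d];
      if (nr >= 0 && nr < M && nc >= 0 && nc < N && labels(nr, nc) == lab) {
        found = d;
        break;
      }
    }
    if (found < 0) return 4.0; // single-pixel component
    int nr = cr + CW_DR[found], nc = cc + CW_DC[found];
    if (first_dir < 0) {
      first_r = nr; first_c = nc; first_dir = found;
    } else if (cr == sr && cc == sc && nr == first_r && nc == first_c && found == first_dir) {
      break; // boundary closed: about to repeat the first move
    }
    len += (CW_DR[found] != 0 && CW_DC[found] != 0) ? M_SQRT2 : 1.0;
    // new backtrack = last background cell checked before the move
    int pd = (found + 7) % 8;
    int br = cr + CW_DR[pd], bc = cc + CW_DC[pd];
    cr = nr; cc = nc;
    bdir = dir_index(br - cr, bc - cc);
    if (bdir < 0) bdir = 6; // unreachable for consecutive Moore cells
  }
  return len;
}

// [[Rcpp::export(name = ".component_stats_cpp")]]
DataFrame component_stats_cpp(IntegerMatrix labels, int n) {
  int M = labels.nrow(), N = labels.ncol();
  std::vector<double> area(n, 0), sum_r(n, 0), sum_c(n, 0);
  std::vector<int> rmin(n, M), rmax(n, -1), cmin(n, N), cmax(n, -1);
  std::vector<int> start_r(n, -1), start_c(n, -1);
  std::vector<bool> border(n, false);
  // row-major scan so start pixel is topmost-leftmost (needed by the tracer)
  for (int r = 0; r < M; ++r) {
    for (int c = 0; c < N; ++c) {
      int lab = labels(r, c);
      if (lab == 0) continue;
      int i = lab - 1;
      if (start_r[i] < 0) { start_r[i] = r; start_c[i] = c; }
      area[i] += 1;
      sum_r[i] += r + 1; // 1-based centroids for R
      sum_c[i] += c + 1;
      if (r < rmin[i]) rmin[i] = r;
      if (r > rmax[i]) rmax[i] = r;
      if (c < cmin[i]) cmin[i] = c;
      if (c > cmax[i]) cmax[i] = c;
      if (r == 0 || r == M - 1 || c == 0 || c == N - 1) border[i] = true;
    }
  }
  NumericVector a(n), cr(n), cc(n), per(n);
  IntegerVector id(n), r0(n), r1(n), c0(n), c1(n);
  LogicalVector bd(n);
  for (int i = 0; i < n; ++i) {
    id[i] = i + 1;
    a[i] = area[i];
    cr[i] = sum_r[i] / area[i];
    cc[i] = sum_c[i] / area[i];
    r0[i] = rmin[i] + 1; r1[i] = rmax[i] + 1;
    c0[i] = cmin[i] + 1; c1[i] = cmax[i] + 1;
    bd[i] = border[i];
    per[i] = trace_perimeter(labels, i + 1, start_r[i], start_c[i]);
  }
  return DataFrame::create(
    _["id"] = id, _["area"] = a,
    _["centroid_r"] = cr, _["centroid_c"] = cc,
    _["rmin"] = r0, _["rmax"] = r1, _["cmin"] = c0, _["cmax"] = c1,
    _["border"] = bd, _["perimeter"] = per);
}

// 3x3 median filter on an integer-valued matrix. Border pixels use the
// clipped neighbourhood; an even-sized neighbourhood takes the rounded mean
// of the two central order statistics.
// [[Rcpp::export(name = ".median3x3_cpp")]]
IntegerMatrix median3x3_cpp(IntegerMatrix img) {
  int M = img.nrow(), N = img.ncol();
  IntegerMatrix out(M, N);
  int win[9];
  for (int c = 0; c < N; ++c) {
    for (int r = 0; r < M; ++r) {
      int n = 0;
      for (int dc = -1; dc <= 1; ++dc) {
        for (int dr = -1; dr <= 1; ++dr) {
          int rr = r + dr, cc = c + dc;
          if (rr >= 0 && rr < M && cc >= 0 && cc < N) win[n++] = img(rr, cc);
        }
      }
      std::sort(win, win + n);
      out(r, c) = (n % 2 == 1) ? win[n / 2]
                               : (int)std::lround((win[n / 2 - 1] + win[n / 2]) / 2.0);
    }
  }
  return out;
}

// Seeded region growing with a running-mean similarity rule.
// Intensities are normalised to [0,1]; a frontier pixel is absorbed when its
// normalised distance to the current region mean is <= max_distance. The
// frontier is a FIFO queue and neighbours are examined in row-major order,
// which fixes the visit order and makes the result deterministic.
// [[Rcpp::export(name = ".grow_region_cpp")]]
LogicalMatrix grow_region_cpp(NumericMatrix img, LogicalMatrix mask,
                              int seed_r, int seed_c, double max_distance) {
  int M = img.nrow(), N = img.ncol();
  LogicalMatrix region(M, N);
  int sr = seed_r - 1, sc = seed_c - 1;
  if (sr < 0 || sr >= M || sc < 0 || sc >= N || !mask(sr, sc))
    stop("seed must lie inside the lung mask");
  std::queue<std::pair<int, int> > q;
  double sum = img(sr, sc) / 255.0;
  long cnt = 1;
  region(sr, sc) = true;
  q.push(std::make_pair(sr, sc));
  const double eps = 1e-12;
  while (!q.empty()) {
    std::pair<int, int> p = q.front();
    q.pop();
    for (int k = 0; k < 8; ++k) {
      int nr = p.first + NB_DR[k], nc = p.second + NB_DC[k];
      if (nr < 0 || nr >= M || nc < 0 || nc >= N) continue;
      if (!mask(nr, nc) || region(nr, nc)) continue;
      double v = img(nr, nc) / 255.0;
      if (std::fabs(v - sum / cnt) <= max_distance + eps) {
        region(nr, nc) = true;
        sum += v;
        ++cnt;
        q.push(std::make_pair(nr, nc));
      }
    }
  }
  return region;
}
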