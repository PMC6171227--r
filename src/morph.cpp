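// Morphological primitives used by the seed-detection and cell-delineation
// steps: 8-connected labeling, flat box erosion/dilation (any kernel size,
// including even), grayscale reconstruction by erosion, regional minima,
// h-minima marker extraction, and a marker-controlled (seeded) watershed.
//
// Conventions shared by every routine here:
//  * matrices are R column-major, pixel index p = r + nrow * c;
//  * object connectivity is 8;
//  * the watershed priority queue orders by (surface value, insertion order),
//    i.e. FIFO among equal-priority pixels, and neighbors are enqueued in a
//    fixed (dr, dc) raster order. This tie discipline is part of the
//    determinism contract and is mirrored by the plain-R reference
//    implementation used in the tests.
#include <Rcpp.h>
#include <queue>
#include <deque>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const int DR8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
static const int DC8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

// [[Rcpp::export]]
IntegerMatrix cpp_label8(const IntegerMatrix &mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    if (mask(r, c) == 0 || lab(r, c) != 0) continue;
    ++next;
    lab(r, c) = next;
    stack.push_back(r + H * c);
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int pr = p % H, pc = p / H;
      for (int k = 0; k < 8; ++k) {
        int rr = pr + DR8[k], cc = pc + DC8[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
          lab(rr, cc) = next;
          stack.push_back(rr + H * cc);
        }
      }
    }
  }
  return lab;
}

// Sliding-window minimum along one line via a monotonic deque.
// Window for output i covers [i - lo, i + hi]; out-of-range samples are
// ignored (equivalently padded with +Inf for min, -Inf for max).
static void run_min_line(const double *x, double *out, int n, int lo, int hi,
                         bool do_max) {
  std::deque<int> q;  // indices with monotone values
  int j = 0;          // next index to admit
  for (int i = 0; i < n; ++i) {
    int right = std::min(n - 1, i + hi);
    for (; j <= right; ++j) {
      while (!q.empty() &&
             (do_max ? x[q.back()] <= x[j] : x[q.back()] >= x[j]))
        q.pop_back();
      q.push_back(j);
    }
    int left = std::max(0, i - lo);
    while (!q.empty() && q.front() < left) q.pop_front();
    out[i] = x[q.front()];
  }
}

// Flat box filter of size k (k >= 1, possibly even). For erosion the window
// is [i - floor((k-1)/2), i + (k-1) - floor((k-1)/2)]; dilation uses the
// reflected structuring element so that dilate(erode(.)) is a proper
// (anti-extensive, idempotent) opening for every k.
static NumericMatrix box_filter(const NumericMatrix &img, int k, bool do_max,
                                bool reflected) {
  const int H = img.nrow(), W = img.ncol();
  int lo = (k - 1) / 2, hi = (k - 1) - lo;
  if (reflected) std::swap(lo, hi);
  NumericMatrix tmp(H, W), out(H, W);
  std::vector<double> line(std::max(H, W)), res(std::max(H, W));
  for (int c = 0; c < W; ++c) {  // columns first
    for (int r = 0; r < H; ++r) line[r] = img(r, c);
    run_min_line(line.data(), res.data(), H, lo, hi, do_max);
    for (int r = 0; r < H; ++r) tmp(r, c) = res[r];
  }
  for (int r = 0; r < H; ++r) {  // then rows
    for (int c = 0; c < W; ++c) line[c] = tmp(r, c);
    run_min_line(line.data(), res.data(), W, lo, hi, do_max);
    for (int c = 0; c < W; ++c) out(r, c) = res[c];
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_box_erode(const NumericMatrix &img, int k) {
  return box_filter(img, k, false, false);
}

// [[Rcpp::export]]
NumericMatrix cpp_box_dilate_reflected(const NumericMatrix &img, int k) {
  return box_filter(img, k, true, true);
}

// Grayscale reconstruction by erosion of `mask` from `marker` (marker >=
// mask pointwise). Sequential forward/backward raster sweeps iterated to
// stability; 8-connectivity.
// [[Rcpp::export]]
NumericMatrix cpp_reconstruct_erosion(const NumericMatrix &marker,
                                      const NumericMatrix &mask) {
  const int H = marker.nrow(), W = marker.ncol();
  NumericMatrix R = clone(marker);
  bool changed = true;
  int guard = 0;
  while (changed && guard++ < 1000) {
    changed = false;
    for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
      double v = R(r, c);
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (cc < c || (cc == c && rr < r)) v = std::min(v, R(rr, cc));
      }
      v = std::max(v, mask(r, c));
      if (v < R(r, c)) { R(r, c) = v; changed = true; }
    }
    for (int c = W - 1; c >= 0; --c) for (int r = H - 1; r >= 0; --r) {
      double v = R(r, c);
      for (int k = 0; k < 8; ++k) {
        int rr = r + DR8[k], cc = c + DC8[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        if (cc > c || (cc == c && rr > r)) v = std::min(v, R(rr, cc));
      }
      v = std::max(v, mask(r, c));
      if (v < R(r, c)) { R(r, c) = v; changed = true; }
    }
  }
  return R;
}

// Regional minima: 8-connected plateaus with no strictly lower neighbor.
// Returns a label image (0 = not a minimum).
// [[Rcpp::export]]
IntegerMatrix cpp_regional_minima(const NumericMatrix &img) {
  const int H = img.nrow(), W = img.ncol();
  IntegerMatrix lab(H, W);
  std::vector<signed char> state(H * (size_t)W, 0);  // 0 unseen, 1 visited
  std::vector<int> plateau, stack;
  int next = 0;
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    int p0 = r + H * c;
    if (state[p0]) continue;
    double v = img(r, c);
    bool is_min = true;
    plateau.clear();
    stack.assign(1, p0);
    state[p0] = 1;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      plateau.push_back(p);
      int pr = p % H, pc = p / H;
      for (int k = 0; k < 8; ++k) {
        int rr = pr + DR8[k], cc = pc + DC8[k];
        if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
        double u = img(rr, cc);
        if (u < v) { is_min = false; continue; }
        if (u == v && !state[rr + H * cc]) {
          state[rr + H * cc] = 1;
          stack.push_back(rr + H * cc);
        }
      }
    }
    if (is_min) {
      ++next;
      for (int p : plateau) lab[p] = next;
    }
  }
  return lab;
}

// Extended h-minima markers of `surface` restricted to `mask` (> 0):
// suppress regional minima shallower than h (reconstruction by erosion of
// surface from surface + h), then label the surviving regional minima.
// [[Rcpp::export]]
IntegerMatrix cpp_hminima_markers(const NumericMatrix &surface, double h,
                                  const IntegerMatrix &mask) {
  NumericMatrix marker = clone(surface);
  for (R_xlen_t i = 0; i < marker.size(); ++i) marker[i] += h;
  NumericMatrix R = cpp_reconstruct_erosion(marker, surface);
  IntegerMatrix mins = cpp_regional_minima(R);
  for (R_xlen_t i = 0; i < mins.size(); ++i) if (mask[i] == 0) mins[i] = 0;
  return cpp_label8(mins);
}

struct QItem {
  double prio;
  std::int64_t order;
  int pixel;
  int label;
};
struct QCmp {
  bool operator()(const QItem &a, const QItem &b) const {
    if (a.prio != b.prio) return a.prio > b.prio;  // min-heap on value
    return a.order > b.order;                      // FIFO among equals
  }
};

// Marker-controlled watershed (Meyer's flooding) of `surface`, restricted to
// pixels where mask > 0. Markers are positive integer labels; every floodable
// pixel ends with the label of the first flood that reaches it (no watershed
// line pixels). Pixels outside the mask keep label 0.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix &surface,
                            const IntegerMatrix &markers,
                            const IntegerMatrix &mask) {
  const int H = surface.nrow(), W = surface.ncol();
  IntegerMatrix lab(H, W);
  std::vector<char> queued(H * (size_t)W, 0);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  std::int64_t order = 0;
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r)
    if (markers(r, c) > 0 && mask(r, c) > 0) {
      lab(r, c) = markers(r, c);
      queued[r + H * c] = 1;
    }
  // enqueue the unlabeled mask neighbors of every marker pixel, raster order
  for (int c = 0; c < W; ++c) for (int r = 0; r < H; ++r) {
    if (lab(r, c) == 0) continue;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int p = rr + H * cc;
      if (mask(rr, cc) > 0 && lab(rr, cc) == 0 && !queued[p]) {
        queued[p] = 1;
        pq.push({surface(rr, cc), order++, p, lab(r, c)});
      }
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int r = it.pixel % H, c = it.pixel / H;
    if (lab(r, c) != 0) continue;
    lab(r, c) = it.label;
    for (int k = 0; k < 8; ++k) {
      int rr = r + DR8[k], cc = c + DC8[k];
      if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
      int p = rr + H * cc;
      if (mask(rr, cc) > 0 && lab(rr, cc) == 0 && !queued[p]) {
        queued[p] = 1;
        pq.push({surface(rr, cc), order++, p, lab(r, c)});
      }
    }
  }
  return lab;
}
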