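#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Minimum-image displacement on a periodic square box.
static inline double min_image(double dx, double box) {
  dx -= box * std::round(dx / box);
  return dx;
}

// Squared minimum distance between two 2D segments (Ericson's clamped
// closed form). Segment i runs from (pi - si*ui) to (pi + si*ui).
static double seg_seg_dist2(double px, double py, double ux, double uy, double sa,
                            double qx, double qy, double vx, double vy, double sb) {
  // endpoints
  double a1x = px - sa * ux, a1y = py - sa * uy;
  double d1x = 2.0 * sa * ux, d1y = 2.0 * sa * uy;
  double b1x = qx - sb * vx, b1y = qy - sb * vy;
  double d2x = 2.0 * sb * vx, d2y = 2.0 * sb * vy;

  double rx = a1x - b1x, ry = a1y - b1y;
  double a = d1x * d1x + d1y * d1y;        // |d1|^2
  double e = d2x * d2x + d2y * d2y;        // |d2|^2
  double f = d2x * rx + d2y * ry;

  double s, t;
  const double EPS = 1e-14;
  if (a <= EPS && e <= EPS) {              // both points
    s = t = 0.0;
  } else if (a <= EPS) {                   // first is a point
    s = 0.0;
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = d1x * rx + d1y * ry;
    if (e <= EPS) {                        // second is a point
      t = 0.0;
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = d1x * d2x + d1y * d2y;
      double denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  double cx = a1x + s * d1x - (b1x + t * d2x);
  double cy = a1y + s * d1y - (b1y + t * d2y);
  return cx * cx + cy * cy;
}

// [[Rcpp::export(name = ".segment_min_dist")]]
double segment_min_dist(NumericVector a, NumericVector b, double box) {
  // a, b: (x, y, theta, L) with L the axis (shaft) length
  double dx = min_image(b[0] - a[0], box);
  double dy = min_image(b[1] - a[1], box);
  double d2 = seg_seg_dist2(0.0, 0.0, std::cos(a[2]), std::sin(a[2]), a[3] / 2.0,
                            dx, dy, std::cos(b[2]), std::sin(b[2]), b[3] / 2.0);
  return std::sqrt(d2);
}

// Random sequential adsorption of congruent spherocylinders (axis length L,
// diameter d -> total tip-to-tip length L + d) on a periodic square box.
// Positions and orientations uniform; a trial is accepted iff the minimum
// axis-axis distance to every neighbour is >= d (hard-core exclusion).
// Uses R's RNG so set.seed() governs the run. Returns the configuration,
// the attempt index of every success, and windowed acceptance counts.
// In addition to the placement run, the kernel can freeze the configuration
// each time the particle count reaches an entry of probe_counts and measure
// the acceptance probability there by probe_trials ghost insertions, giving
// an unbiased estimate of the available-surface (blocking) function.
// [[Rcpp::export(name = ".rsa_kernel")]]
List rsa_kernel(double L, double d, double box, double max_attempts,
                double stop_attempts, int n_windows,
                IntegerVector probe_counts, double probe_trials) {
  if (box < (L + d)) stop("box side must exceed the particle length");
  double Lt = L + d;                      // tip-to-tip length = interaction range
  int m = std::max(1, (int)std::floor(box / Lt));
  if (m < 3) m = 1;                       // degenerate: single cell
  double cell = box / m;
  std::vector<std::vector<int> > cells((size_t)m * m);

  std::vector<double> X, Y, TH;
  std::vector<double> succ_at;            // attempt index of each success
  double win_len = max_attempts / n_windows;
  std::vector<double> win_att(n_windows, 0.0), win_acc(n_windows, 0.0);

  RNGScope scope;
  double since_last = 0.0;
  double att = 0.0;
  double d2min = d * d;

  std::vector<int> pcounts(probe_counts.begin(), probe_counts.end());
  std::sort(pcounts.begin(), pcounts.end());
  size_t next_probe = 0;
  std::vector<double> probe_n, probe_acc;

  int reach = (m == 1) ? 0 : 1;
  // acceptance test for a trial placement against the current configuration
  auto trial_ok = [&](double x, double y, double th) -> bool {
    double ux = std::cos(th), uy = std::sin(th);
    int ci = (int)(x / cell); if (ci >= m) ci = m - 1;
    int cj = (int)(y / cell); if (cj >= m) cj = m - 1;
    for (int di = -reach; di <= reach; ++di) {
      for (int dj = -reach; dj <= reach; ++dj) {
        int ii = (ci + di + m) % m, jj = (cj + dj + m) % m;
        const std::vector<int> &cv = cells[(size_t)ii * m + jj];
        for (size_t k = 0; k < cv.size(); ++k) {
          int id = cv[k];
          double dx = min_image(X[id] - x, box);
          double dy = min_image(Y[id] - y, box);
          if (dx * dx + dy * dy >= (Lt + 1e-12) * (Lt + 1e-12)) continue;
          double s2 = seg_seg_dist2(0.0, 0.0, ux, uy, L / 2.0,
                                    dx, dy, std::cos(TH[id]), std::sin(TH[id]), L / 2.0);
          if (s2 < d2min) return false;
        }
      }
    }
    return true;
  };

  while (att < max_attempts) {
    if (next_probe < pcounts.size() && (int)X.size() == pcounts[next_probe]) {
      double acc = 0.0;
      for (double j = 0.0; j < probe_trials; j += 1.0)
        if (trial_ok(unif_rand() * box, unif_rand() * box, unif_rand() * M_PI))
          acc += 1.0;
      probe_n.push_back((double)X.size());
      probe_acc.push_back(acc / probe_trials);
      ++next_probe;
    }
    att += 1.0;
    since_last += 1.0;
    double x = unif_rand() * box;
    double y = unif_rand() * box;
    double th = unif_rand() * M_PI;
    int w = std::min(n_windows - 1, (int)(att / win_len));
    win_att[w] += 1.0;

    bool ok = trial_ok(x, y, th);
    if (ok) {
      int id = (int)X.size();
      int ci = (int)(x / cell); if (ci >= m) ci = m - 1;
      int cj = (int)(y / cell); if (cj >= m) cj = m - 1;
      X.push_back(x); Y.push_back(y); TH.push_back(th);
      cells[(size_t)ci * m + cj].push_back(id);
      succ_at.push_back(att);
      win_acc[w] += 1.0;
      since_last = 0.0;
    }
    if (since_last >= stop_attempts) break;
    if (((long long)att) % 1000000LL == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["x"] = NumericVector(X.begin(), X.end()),
    _["y"] = NumericVector(Y.begin(), Y.end()),
    _["theta"] = NumericVector(TH.begin(), TH.end()),
    _["success_attempt"] = NumericVector(succ_at.begin(), succ_at.end()),
    _["attempts"] = att,
    _["window_attempts"] = NumericVector(win_att.begin(), win_att.end()),
    _["window_accepted"] = NumericVector(win_acc.begin(), win_acc.end()),
    _["probe_count"] = NumericVector(probe_n.begin(), probe_n.end()),
    _["probe_acceptance"] = NumericVector(probe_acc.begin(), probe_acc.end()));
}
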