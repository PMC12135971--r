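#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Periodic minimum-image displacement along one axis.
static inline double min_image(double d, double l) {
  if (d >  0.5 * l) d -= l;
  if (d < -0.5 * l) d += l;
  return d;
}

static inline double wrap(double x, double l) {
  x -= l * std::floor(x / l);
  if (x >= l) x = 0;      // guard the x/l rounding-up edge
  return x;
}

// [[Rcpp::export]]
double cpp_min_image_distance(NumericVector p, NumericVector q, double l) {
  double dx = min_image(p[0] - q[0], l);
  double dy = min_image(p[1] - q[1], l);
  return std::sqrt(dx * dx + dy * dy);
}

// Minimum pairwise minimum-image distance, brute force O(N^2).
// [[Rcpp::export]]
double cpp_brute_min_dist(NumericMatrix pos, double l) {
  int n = pos.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n - 1; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = min_image(pos(i, 0) - pos(j, 0), l);
      double dy = min_image(pos(i, 1) - pos(j, 1), l);
      double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
  return std::sqrt(best);
}

// Occupancy grid: n_tiles x n_tiles integers, -1 empty, else 0-based disk id.
// [[Rcpp::export]]
IntegerMatrix cpp_build_tile_grid(NumericMatrix pos, double l, int n_tiles) {
  IntegerMatrix grid(n_tiles, n_tiles);
  std::fill(grid.begin(), grid.end(), -1);
  double ts = l / n_tiles;
  for (int i = 0; i < pos.nrow(); ++i) {
    int tx = (int)(wrap(pos(i, 0), l) / ts); if (tx >= n_tiles) tx = n_tiles - 1;
    int ty = (int)(wrap(pos(i, 1), l) / ts); if (ty >= n_tiles) ty = n_tiles - 1;
    if (grid(tx, ty) != -1)
      stop("two disks map to one tile: overlapping configuration upstream");
    grid(tx, ty) = i;
  }
  return grid;
}

// Collision test of a proposed center against the current configuration.
// Scans the 5x5 tile block around the proposal minus its four corners (the
// 20 tiles within centre-to-centre distance 4 plus the proposal's own tile,
// where only the mover itself can sit).  A corner tile is additionally
// examined when the proposal lies within 2 of that tile's nearest point,
// closing the hairline gap where tile_side < sqrt(2) leaves the corner
// diagonal marginally inside the contact distance.
static bool collide(const IntegerMatrix &grid, const NumericMatrix &pos,
                    double l, int n_tiles, int self, double px, double py) {
  double ts = l / n_tiles;
  if (n_tiles < 5) { // block would wrap onto itself; fall back to all pairs
    for (int j = 0; j < pos.nrow(); ++j) {
      if (j == self) continue;
      double dx = min_image(px - pos(j, 0), l);
      double dy = min_image(py - pos(j, 1), l);
      if (dx * dx + dy * dy < 4.0) return true;
    }
    return false;
  }
  int tx = (int)(px / ts); if (tx >= n_tiles) tx = n_tiles - 1;
  int ty = (int)(py / ts); if (ty >= n_tiles) ty = n_tiles - 1;
  for (int ox = -2; ox <= 2; ++ox) {
    for (int oy = -2; oy <= 2; ++oy) {
      bool corner = (std::abs(ox) == 2 && std::abs(oy) == 2);
      int gx = tx + ox; if (gx < 0) gx += n_tiles; else if (gx >= n_tiles) gx -= n_tiles;
      int gy = ty + oy; if (gy < 0) gy += n_tiles; else if (gy >= n_tiles) gy -= n_tiles;
      int occ = grid(gx, gy);
      if (occ < 0 || occ == self) continue;
      if (corner) {
        // nearest corner of the corner tile to the proposal
        double cx = (ox > 0) ? (tx + 2) * ts : (tx - 1) * ts;
        double cy = (oy > 0) ? (ty + 2) * ts : (ty - 1) * ts;
        double ddx = min_image(px - cx, l), ddy = min_image(py - cy, l);
        if (ddx * ddx + ddy * ddy >= 4.0) continue;
      }
      double dx = min_image(px - pos(occ, 0), l);
      double dy = min_image(py - pos(occ, 1), l);
      if (dx * dx + dy * dy < 4.0) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
bool cpp_collision_check(IntegerMatrix grid, NumericMatrix pos, double l,
                         int disk_id, double px, double py) {
  return collide(grid, pos, l, grid.nrow(), disk_id, px, py);
}

// Metropolis sweep driver: n_attempts single-disk moves with normal steps of
// sd sigma.  Modifies pos and grid in place (both are duplicated R-side by
// the calling wrapper).  Uses R's RNG so set.seed() governs the trajectory.
// [[Rcpp::export]]
int cpp_mc_run(NumericMatrix pos, IntegerMatrix grid, double l, double sigma,
               double n_attempts) {
  int n = pos.nrow(), n_tiles = grid.nrow();
  double ts = l / n_tiles;
  int accepted = 0;
  RNGScope scope;
  for (double k = 0; k < n_attempts; ++k) {
    int i = (int)(unif_rand() * n); if (i == n) i = n - 1;
    double px = wrap(pos(i, 0) + norm_rand() * sigma, l);
    double py = wrap(pos(i, 1) + norm_rand() * sigma, l);
    if (!collide(grid, pos, l, n_tiles, i, px, py)) {
      int oldx = (int)(pos(i, 0) / ts); if (oldx >= n_tiles) oldx = n_tiles - 1;
      int oldy = (int)(pos(i, 1) / ts); if (oldy >= n_tiles) oldy = n_tiles - 1;
      int newx = (int)(px / ts); if (newx >= n_tiles) newx = n_tiles - 1;
      int newy = (int)(py / ts); if (newy >= n_tiles) newy = n_tiles - 1;
      grid(oldx, oldy) = -1;
      grid(newx, newy) = i;
      pos(i, 0) = px;
      pos(i, 1) = py;
      ++accepted;
    }
  }
  return accepted;
}

// Pair-distance histogram over the circle of diameter l inscribed in the box.
// Distances are direct (no minimum image): the circle replaces the periodic
// geometry.  Returns counts (n_bins) and the number of centers in the circle.
// [[Rcpp::export]]
List cpp_pair_hist(NumericMatrix pos, double l, double w_b, int n_bins) {
  int n = pos.nrow();
  double cx = 0.5 * l, cy = 0.5 * l, r2max = 0.25 * l * l;
  std::vector<double> xs, ys;
  xs.reserve(n); ys.reserve(n);
  for (int i = 0; i < n; ++i) {
    double dx = pos(i, 0) - cx, dy = pos(i, 1) - cy;
    if (dx * dx + dy * dy < r2max) { xs.push_back(pos(i, 0)); ys.push_back(pos(i, 1)); }
  }
  int n0 = (int)xs.size();
  std::vector<double> counts(n_bins, 0.0);
  double inv = 1.0 / w_b;
  for (int i = 0; i < n0 - 1; ++i) {
    double xi = xs[i], yi = ys[i];
    for (int j = i + 1; j < n0; ++j) {
      double dx = xi - xs[j], dy = yi - ys[j];
      int b = (int)(std::sqrt(dx * dx + dy * dy) * inv);
      if (b < n_bins) counts[b] += 1.0;
    }
  }
  return List::create(_["counts"] = NumericVector(counts.begin(), counts.end()),
                      _["n0"] = n0);
}
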