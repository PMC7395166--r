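// Neighbourhood geometry for point-cloud morphometry: grid-accelerated
// k-nearest-neighbour search, moving-least-squares surface smoothing and
// principal-curvature estimation by local quadric fitting.

#include <RcppArmadillo.h>
#include <queue>
#include <unordered_map>

// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

// Uniform hash grid over the bounding box; cell size h.
struct Grid {
  const arma::mat& P;           // N x 3
  double h;
  arma::rowvec lo;
  int nx, ny, nz;
  std::unordered_map<long long, std::vector<int>> cells;

  Grid(const arma::mat& pts, double cell) : P(pts), h(cell) {
    lo = arma::min(P, 0);
    arma::rowvec hi = arma::max(P, 0);
    nx = std::max(1, (int)std::floor((hi[0] - lo[0]) / h) + 1);
    ny = std::max(1, (int)std::floor((hi[1] - lo[1]) / h) + 1);
    nz = std::max(1, (int)std::floor((hi[2] - lo[2]) / h) + 1);
    cells.reserve(P.n_rows / 2 + 1);
    for (arma::uword i = 0; i < P.n_rows; ++i)
      cells[key(cx(P(i, 0)), cy(P(i, 1)), cz(P(i, 2)))].push_back((int)i);
  }
  int cx(double x) const {
    int c = (int)std::floor((x - lo[0]) / h);
    return std::min(std::max(c, 0), nx - 1);
  }
  int cy(double y) const {
    int c = (int)std::floor((y - lo[1]) / h);
    return std::min(std::max(c, 0), ny - 1);
  }
  int cz(double z) const {
    int c = (int)std::floor((z - lo[2]) / h);
    return std::min(std::max(c, 0), nz - 1);
  }
  long long key(int ix, int iy, int iz) const {
    return ((long long)ix * ny + iy) * nz + iz;
  }

  // Indices of points within `radius` of query q (squared-distance check).
  void radius_query(const arma::rowvec& q, double radius,
                    std::vector<int>& out) const {
    out.clear();
    const double r2 = radius * radius;
    const int reach = (int)std::ceil(radius / h);
    const int ix = cx(q[0]), iy = cy(q[1]), iz = cz(q[2]);
    for (int a = std::max(0, ix - reach); a <= std::min(nx - 1, ix + reach); ++a)
      for (int b = std::max(0, iy - reach); b <= std::min(ny - 1, iy + reach); ++b)
        for (int c = std::max(0, iz - reach); c <= std::min(nz - 1, iz + reach); ++c) {
          auto it = cells.find(key(a, b, c));
          if (it == cells.end()) continue;
          for (int j : it->second) {
            const double dx = P(j, 0) - q[0], dy = P(j, 1) - q[1],
                         dz = P(j, 2) - q[2];
            if (dx * dx + dy * dy + dz * dz <= r2) out.push_back(j);
          }
        }
  }

  // k nearest neighbours of q, optionally excluding index `self`.
  // Expands Chebyshev shells; a shell at ring r is at distance >= (r-1)*h,
  // so the search stops once the kth best distance is <= (ring)*h.
  void knn_query(const arma::rowvec& q, int k, int self,
                 std::vector<int>& idx, std::vector<double>& dist) const {
    typedef std::pair<double, int> DI;  // (squared distance, index)
    std::priority_queue<DI> heap;       // max-heap on distance
    const int ix = cx(q[0]), iy = cy(q[1]), iz = cz(q[2]);
    const int max_ring = std::max(std::max(nx, ny), nz);
    for (int r = 0; r <= max_ring; ++r) {
      bool any_cell = false;
      for (int a = std::max(0, ix - r); a <= std::min(nx - 1, ix + r); ++a)
        for (int b = std::max(0, iy - r); b <= std::min(ny - 1, iy + r); ++b)
          for (int c = std::max(0, iz - r); c <= std::min(nz - 1, iz + r); ++c) {
            if (std::max(std::abs(a - ix),
                         std::max(std::abs(b - iy), std::abs(c - iz))) != r)
              continue;  // shell only
            any_cell = true;
            auto it = cells.find(key(a, b, c));
            if (it == cells.end()) continue;
            for (int j : it->second) {
              if (j == self) continue;
              const double dx = P(j, 0) - q[0], dy = P(j, 1) - q[1],
                           dz = P(j, 2) - q[2];
              const double d2 = dx * dx + dy * dy + dz * dz;
              if ((int)heap.size() < k)
                heap.push(DI(d2, j));
              else if (d2 < heap.top().first) {
                heap.pop();
                heap.push(DI(d2, j));
              }
            }
          }
      if ((int)heap.size() >= k &&
          std::sqrt(heap.top().first) <= (double)r * h)
        break;
      if (!any_cell && r > 0 && (int)heap.size() >= k) break;
    }
    idx.resize(heap.size());
    dist.resize(heap.size());
    for (int m = (int)heap.size() - 1; m >= 0; --m) {
      idx[m] = heap.top().second;
      dist[m] = std::sqrt(heap.top().first);
      heap.pop();
    }
  }
};

double knn_cell_size(const arma::mat& P, int k) {
  arma::rowvec lo = arma::min(P, 0), hi = arma::max(P, 0);
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(hi[d] - lo[d], 1e-9);
  double h = std::cbrt(vol * std::max(k, 1) / (double)P.n_rows);
  double maxext = std::max(hi[0] - lo[0], std::max(hi[1] - lo[1], hi[2] - lo[2]));
  return std::max(h, maxext / 96.0);  // cap the grid resolution
}

// Local orthonormal frame from the covariance of the rows of Q: normal is
// the eigenvector of the smallest eigenvalue, (u, v) span the tangent plane.
void local_frame(const arma::mat& Q, arma::vec& n, arma::vec& u, arma::vec& v) {
  arma::rowvec m = arma::mean(Q, 0);
  arma::mat C = Q.each_row() - m;
  arma::mat S = (C.t() * C) / (double)Q.n_rows;
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, S);   // ascending eigenvalues
  n = evec.col(0);
  u = evec.col(2);
  v = arma::cross(n, u);
  v /= arma::norm(v);
  u = arma::cross(v, n);          // re-orthogonalise
  u /= arma::norm(u);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_knn")]]
List cpp_knn(const arma::mat& pts, int k) {
  const int N = (int)pts.n_rows;
  if (k >= N) stop("k must be smaller than the number of points");
  Grid g(pts, knn_cell_size(pts, k));
  IntegerMatrix idx(N, k);
  NumericMatrix dist(N, k);
  std::vector<int> ii;
  std::vector<double> dd;
  for (int i = 0; i < N; ++i) {
    g.knn_query(pts.row(i), k, i, ii, dd);
    for (int m = 0; m < k; ++m) {
      idx(i, m) = ii[m] + 1;  // 1-based for R
      dist(i, m) = dd[m];
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// [[Rcpp::export(name = ".cpp_mls_smooth")]]
List cpp_mls_smooth(const arma::mat& pts, double radius) {
  const int N = (int)pts.n_rows;
  Grid g(pts, radius);
  arma::mat out(N, 3);
  int n_unsmoothed = 0;
  double total_disp = 0.0;
  std::vector<int> nb;
  const double sigma2 = (radius * radius) / 4.0;  // Gaussian weight scale r/2
  for (int i = 0; i < N; ++i) {
    arma::rowvec p = pts.row(i);
    g.radius_query(p, radius, nb);
    if ((int)nb.size() < 6) {
      out.row(i) = p;
      ++n_unsmoothed;
      continue;
    }
    const int n = (int)nb.size();
    arma::mat Q(n, 3);
    arma::vec w(n);
    for (int j = 0; j < n; ++j) {
      Q.row(j) = pts.row(nb[j]);
      double d2 = arma::accu(arma::square(Q.row(j) - p));
      w[j] = std::exp(-d2 / sigma2);
    }
    // weighted reference plane
    arma::rowvec m = (w.t() * Q) / arma::accu(w);
    arma::mat C = Q.each_row() - m;
    arma::mat Cw = C.each_col() % arma::sqrt(w);
    arma::mat S = Cw.t() * Cw;
    arma::vec eval;
    arma::mat evec;
    arma::eig_sym(eval, evec, S);
    arma::vec nrm = evec.col(0), u = evec.col(2);
    arma::vec v = arma::cross(nrm, u);
    v /= arma::norm(v);
    u = arma::cross(v, nrm);
    // degree-2 polynomial height field over the tangent plane
    arma::mat A(n, 6);
    arma::vec f(n);
    for (int j = 0; j < n; ++j) {
      double x = arma::dot(C.row(j), u), y = arma::dot(C.row(j), v);
      f[j] = arma::dot(C.row(j), nrm);
      A(j, 0) = 1.0; A(j, 1) = x; A(j, 2) = y;
      A(j, 3) = x * x; A(j, 4) = x * y; A(j, 5) = y * y;
    }
    arma::mat Aw = A.each_col() % w;
    arma::mat AtA = A.t() * Aw;
    arma::vec Atf = A.t() * (w % f);
    arma::vec beta;
    if (!arma::solve(beta, AtA, Atf, arma::solve_opts::no_approx)) {
      out.row(i) = p;
      ++n_unsmoothed;
      continue;
    }
    arma::rowvec rel = p - m;
    double x0 = arma::dot(rel, u), y0 = arma::dot(rel, v);
    double h0 = beta[0] + beta[1] * x0 + beta[2] * y0 +
                beta[3] * x0 * x0 + beta[4] * x0 * y0 + beta[5] * y0 * y0;
    arma::rowvec pnew = m + x0 * u.t() + y0 * v.t() + h0 * nrm.t();
    out.row(i) = pnew;
    total_disp += arma::norm(pnew - p, 2);
  }
  return List::create(_["points"] = out,
                      _["n_unsmoothed"] = n_unsmoothed,
                      _["mean_displacement"] =
                          N > n_unsmoothed ? total_disp / (N - n_unsmoothed) : 0.0);
}

// Per-point principal curvatures from a quadric height field
// z = a x^2 + b xy + c y^2 fitted over the k-NN neighbourhood in the local
// tangent frame; k1 >= k2 are the eigenvalues of [[2a, b], [b, 2c]].
// Normals are oriented away from `centroid`.
// [[Rcpp::export(name = ".cpp_quadric_curvatures")]]
List cpp_quadric_curvatures(const arma::mat& pts, int k,
                            const arma::rowvec& centroid) {
  const int N = (int)pts.n_rows;
  if (k >= N) stop("k_neighbours must be smaller than the number of points");
  Grid g(pts, knn_cell_size(pts, k));
  arma::vec k1(N), k2(N);
  arma::mat normals(N, 3);
  LogicalVector flagged(N);
  std::vector<int> ii;
  std::vector<double> dd;
  for (int i = 0; i < N; ++i) {
    arma::rowvec p = pts.row(i);
    g.knn_query(p, k, i, ii, dd);
    const int n = (int)ii.size();
    arma::mat Q(n + 1, 3);
    Q.row(0) = p;
    for (int j = 0; j < n; ++j) Q.row(j + 1) = pts.row(ii[j]);
    arma::vec nrm, u, v;
    local_frame(Q, nrm, u, v);
    if (arma::dot(nrm.t(), p - centroid) < 0) nrm = -nrm;
    v = arma::cross(nrm, u);
    v /= arma::norm(v);
    u = arma::cross(v, nrm);
    arma::mat A(n, 3);
    arma::vec f(n);
    for (int j = 0; j < n; ++j) {
      arma::rowvec rel = Q.row(j + 1) - p;
      double x = arma::dot(rel, u), y = arma::dot(rel, v);
      f[j] = arma::dot(rel, nrm);
      A(j, 0) = x * x;
      A(j, 1) = x * y;
      A(j, 2) = y * y;
    }
    arma::mat AtA = A.t() * A;
    arma::vec beta;
    bool ok = n >= 3 && arma::rcond(AtA) > 1e-12 &&
              arma::solve(beta, AtA, A.t() * f, arma::solve_opts::no_approx);
    if (!ok) {
      k1[i] = k2[i] = NA_REAL;
      flagged[i] = true;
      normals.row(i) = nrm.t();
      continue;
    }
    arma::mat22 S = {{2.0 * beta[0], beta[1]}, {beta[1], 2.0 * beta[2]}};
    arma::vec ev;
    arma::eig_sym(ev, S);
    k1[i] = ev[1];
    k2[i] = ev[0];
    flagged[i] = false;
    normals.row(i) = nrm.t();
  }
  return List::create(_["k1"] = k1, _["k2"] = k2, _["normal"] = normals,
                      _["flagged"] = flagged);
}
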