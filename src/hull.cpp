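// Incremental 3D convex hull returning facet half-spaces (outward unit
// normal n and offset d such that interior points satisfy n.p <= d).
// Point counts here are protein atom counts (hundreds), so the simple
// O(n * F) insertion scheme is more than fast enough.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Face {
  int a, b, c;
  arma::vec3 n;
  double off;
  bool alive;
};

arma::vec3 row3(const arma::mat& P, int i) {
  return arma::vec3{P(i, 0), P(i, 1), P(i, 2)};
}

Face make_face(const arma::mat& P, int a, int b, int c, const arma::vec3& inside,
               double tol) {
  arma::vec3 pa = row3(P, a), pb = row3(P, b), pc = row3(P, c);
  arma::vec3 n = arma::cross(pb - pa, pc - pa);
  double nn = arma::norm(n);
  if (nn > 0) n /= nn;
  double off = arma::dot(n, pa);
  if (arma::dot(n, inside) - off > tol) { // flip outward
    std::swap(b, c);
    n = -n;
    off = -off;
  }
  return Face{a, b, c, n, off, true};
}

} // namespace

// [[Rcpp::export(name = ".hull_facets")]]
List hull_facets(NumericMatrix pts_in) {
  arma::mat P(pts_in.begin(), pts_in.nrow(), pts_in.ncol(), false, true);
  const int n = P.n_rows;
  List degenerate = List::create(_["ok"] = false);
  if (P.n_cols != 3 || n < 4) return degenerate;

  double scale = std::max(1.0, arma::abs(P).max());
  const double tol = 1e-9 * scale;

  // Initial simplex: extreme pair, farthest from the line, farthest from plane.
  arma::uword i0 = P.col(0).index_min(), i1 = P.col(0).index_max();
  if (arma::norm(row3(P, i1) - row3(P, i0)) < tol) {
    // degenerate along x; try the overall farthest pair from point 0
    arma::vec d(n);
    for (int i = 0; i < n; ++i) d(i) = arma::norm(row3(P, i) - row3(P, 0));
    i0 = 0; i1 = d.index_max();
    if (d(i1) < tol) return degenerate;
  }
  arma::vec3 u = row3(P, i1) - row3(P, i0);
  int i2 = -1; double best = tol;
  for (int i = 0; i < n; ++i) {
    arma::vec3 v = row3(P, i) - row3(P, i0);
    double d = arma::norm(arma::cross(u, v)) / arma::norm(u);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) return degenerate;
  arma::vec3 nrm = arma::cross(u, row3(P, i2) - row3(P, i0));
  nrm /= arma::norm(nrm);
  int i3 = -1; best = tol;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(arma::dot(nrm, row3(P, i) - row3(P, i0)));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) return degenerate; // coplanar cloud

  arma::vec3 inside = (row3(P, i0) + row3(P, i1) + row3(P, i2) + row3(P, i3)) / 4.0;
  std::vector<Face> faces;
  faces.push_back(make_face(P, (int)i0, (int)i1, (int)i2, inside, tol));
  faces.push_back(make_face(P, (int)i0, (int)i1, (int)i3, inside, tol));
  faces.push_back(make_face(P, (int)i0, (int)i2, (int)i3, inside, tol));
  faces.push_back(make_face(P, (int)i1, (int)i2, (int)i3, inside, tol));

  for (int p = 0; p < n; ++p) {
    if (p == (int)i0 || p == (int)i1 || p == i2 || p == i3) continue;
    arma::vec3 q = row3(P, p);
    std::vector<int> visible;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && arma::dot(faces[f].n, q) - faces[f].off > tol)
        visible.push_back((int)f);
    if (visible.empty()) continue;

    // Horizon = undirected edges of visible faces seen exactly once.
    std::map<std::pair<int, int>, std::pair<int, int>> edges; // key -> (count, a-directed)
    auto add_edge = [&](int a, int b) {
      auto key = std::minmax(a, b);
      auto it = edges.find(key);
      if (it == edges.end()) edges[key] = {1, a};
      else it->second.first++;
    };
    for (int f : visible) {
      add_edge(faces[f].a, faces[f].b);
      add_edge(faces[f].b, faces[f].c);
      add_edge(faces[f].c, faces[f].a);
      faces[f].alive = false;
    }
    for (auto& e : edges) {
      if (e.second.first != 1) continue;
      int a = e.second.second;
      int b = (e.first.first == a) ? e.first.second : e.first.first;
      faces.push_back(make_face(P, a, b, p, inside, tol));
    }
  }

  std::vector<double> normals, offs;
  for (const Face& f : faces) {
    if (!f.alive) continue;
    normals.push_back(f.n(0));
    normals.push_back(f.n(1));
    normals.push_back(f.n(2));
    offs.push_back(f.off);
  }
  const int nf = (int)offs.size();
  NumericMatrix N(3, nf);
  std::copy(normals.begin(), normals.end(), N.begin());
  return List::create(_["ok"] = true,
                      _["normals"] = transpose(N),
                      _["offsets"] = NumericVector(offs.begin(), offs.end()));
}
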