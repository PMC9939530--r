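// 3D computational-geometry kernels: quickhull convex hull, Bowyer-Watson
// Delaunay tetrahedralisation (basis of the alpha complex), and multi-source
// Dijkstra on a kNN graph (geodesic region growing for leaf instances).
#include <RcppArmadillo.h>
#include <unordered_map>
#include <queue>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline arma::vec3 row3(const arma::mat& P, int i) {
  return arma::vec3{P(i, 0), P(i, 1), P(i, 2)};
}

// ---------------------------------------------------------------------------
// Quickhull
// ---------------------------------------------------------------------------

struct Face {
  int a, b, c;            // vertex indices, counter-clockwise seen from outside
  arma::vec3 n;           // unit outward normal
  double off;             // n . x = off on the face plane
  std::vector<int> outside;
  int far_pt;
  double far_d;
  bool alive;
};

static inline long long ekey(int a, int b, long long n) { return (long long)a * n + b; }

static inline double fdist(const Face& f, const arma::vec3& p) {
  return arma::dot(f.n, p) - f.off;
}

static void face_geom(Face& f, const arma::mat& P) {
  arma::vec3 A = row3(P, f.a), B = row3(P, f.b), C = row3(P, f.c);
  arma::vec3 nn = arma::cross(B - A, C - A);
  double nl = arma::norm(nn);
  f.n = (nl > 0) ? arma::vec3(nn / nl) : arma::vec3{0, 0, 0};
  f.off = arma::dot(f.n, A);
}

// [[Rcpp::export(name = ".convexHull3dCpp")]]
List convexHull3dCpp(const arma::mat& P) {
  const int n = P.n_rows;
  if (n < 4) stop("convex hull requires at least 4 points");
  // characteristic scale for tolerances
  arma::rowvec lo = arma::min(P, 0), hi = arma::max(P, 0);
  double scale = arma::norm(hi - lo);
  if (!(scale > 0)) stop("degenerate point set: all points coincide");
  const double eps = 1e-10 * scale;

  // initial simplex: extremes along x, farthest from segment, farthest from plane
  int i0 = (int)arma::index_min(P.col(0)), i1 = (int)arma::index_max(P.col(0));
  if (i0 == i1) { i0 = (int)arma::index_min(P.col(1)); i1 = (int)arma::index_max(P.col(1)); }
  arma::vec3 p0 = row3(P, i0), p1 = row3(P, i1);
  if (arma::norm(p1 - p0) < eps) stop("degenerate point set: zero extent");
  int i2 = -1; double best = eps;
  arma::vec3 d01 = arma::normalise(p1 - p0);
  for (int i = 0; i < n; ++i) {
    arma::vec3 w = row3(P, i) - p0;
    double d = arma::norm(w - arma::dot(w, d01) * d01);
    if (d > best) { best = d; i2 = i; }
  }
  if (i2 < 0) stop("degenerate point set: all points collinear");
  arma::vec3 p2 = row3(P, i2);
  arma::vec3 nrm = arma::normalise(arma::cross(p1 - p0, p2 - p0));
  int i3 = -1; best = eps;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(arma::dot(row3(P, i) - p0, nrm));
    if (d > best) { best = d; i3 = i; }
  }
  if (i3 < 0) stop("degenerate point set: all points coplanar");

  arma::vec3 p3 = row3(P, i3);
  arma::vec3 centroid = (p0 + p1 + p2 + p3) / 4.0;

  std::vector<Face> faces;
  std::unordered_map<long long, int> emap;  // directed edge (a,b) -> face index
  auto add_face = [&](int a, int b, int c) -> int {
    Face f; f.a = a; f.b = b; f.c = c; f.alive = true; f.far_pt = -1; f.far_d = 0;
    face_geom(f, P);
    if (fdist(f, centroid) > 0) { std::swap(f.b, f.c); face_geom(f, P); }
    faces.push_back(f);
    int id = (int)faces.size() - 1;
    emap[ekey(faces[id].a, faces[id].b, n)] = id;
    emap[ekey(faces[id].b, faces[id].c, n)] = id;
    emap[ekey(faces[id].c, faces[id].a, n)] = id;
    return id;
  };
  add_face(i0, i1, i2); add_face(i0, i1, i3); add_face(i0, i2, i3); add_face(i1, i2, i3);

  // assign points to faces
  std::queue<int> work;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    for (size_t f = 0; f < faces.size(); ++f) {
      double d = fdist(faces[f], row3(P, i));
      if (d > eps) {
        faces[f].outside.push_back(i);
        if (d > faces[f].far_d) { faces[f].far_d = d; faces[f].far_pt = i; }
        break;
      }
    }
  }
  for (size_t f = 0; f < faces.size(); ++f) if (faces[f].far_pt >= 0) work.push((int)f);

  while (!work.empty()) {
    int fi = work.front(); work.pop();
    if (!faces[fi].alive || faces[fi].far_pt < 0) continue;
    int pi = faces[fi].far_pt;
    arma::vec3 p = row3(P, pi);

    // BFS over visible faces
    std::vector<int> visible; std::vector<char> seen(faces.size(), 0);
    std::vector<std::pair<int, int>> horizon;  // directed edges as in visible faces
    std::queue<int> bfs; bfs.push(fi); seen[fi] = 1;
    while (!bfs.empty()) {
      int g = bfs.front(); bfs.pop();
      visible.push_back(g);
      int vs[3] = {faces[g].a, faces[g].b, faces[g].c};
      for (int e = 0; e < 3; ++e) {
        int a = vs[e], b = vs[(e + 1) % 3];
        auto it = emap.find(ekey(b, a, n));
        if (it == emap.end()) continue;
        int nb = it->second;
        if (seen[nb]) continue;
        if (fdist(faces[nb], p) > eps) { seen[nb] = 1; bfs.push(nb); }
        else horizon.push_back({a, b});
      }
    }
    // collect orphaned outside points, kill visible faces
    std::vector<int> orphans;
    for (int g : visible) {
      for (int q : faces[g].outside) if (q != pi) orphans.push_back(q);
      faces[g].alive = false;
      emap.erase(ekey(faces[g].a, faces[g].b, n));
      emap.erase(ekey(faces[g].b, faces[g].c, n));
      emap.erase(ekey(faces[g].c, faces[g].a, n));
      faces[g].outside.clear();
    }
    // new cone of faces from the horizon to p
    std::vector<int> fresh;
    for (auto& e : horizon) fresh.push_back(add_face(e.first, e.second, pi));
    for (int q : orphans) {
      arma::vec3 pq = row3(P, q);
      for (int g : fresh) {
        double d = fdist(faces[g], pq);
        if (d > eps) {
          faces[g].outside.push_back(q);
          if (d > faces[g].far_d) { faces[g].far_d = d; faces[g].far_pt = q; }
          break;
        }
      }
    }
    for (int g : fresh) if (faces[g].far_pt >= 0) work.push(g);
  }

  // volume + vertex set from surviving faces
  double vol = 0.0;
  std::vector<int> fa, fb, fc;
  std::vector<char> used(n, 0);
  for (const Face& f : faces) {
    if (!f.alive) continue;
    arma::vec3 A = row3(P, f.a) - centroid, B = row3(P, f.b) - centroid,
               C = row3(P, f.c) - centroid;
    vol += arma::dot(A, arma::cross(B, C)) / 6.0;
    fa.push_back(f.a + 1); fb.push_back(f.b + 1); fc.push_back(f.c + 1);
    used[f.a] = used[f.b] = used[f.c] = 1;
  }
  std::vector<int> verts;
  for (int i = 0; i < n; ++i) if (used[i]) verts.push_back(i + 1);
  IntegerMatrix fm(fa.size(), 3);
  for (size_t i = 0; i < fa.size(); ++i) { fm(i, 0) = fa[i]; fm(i, 1) = fb[i]; fm(i, 2) = fc[i]; }
  return List::create(_["volume"] = vol, _["vertices"] = wrap(verts), _["faces"] = fm);
}

// ---------------------------------------------------------------------------
// Bowyer-Watson Delaunay tetrahedralisation
// ---------------------------------------------------------------------------

struct Tet {
  int v[4];
  int nb[4];     // neighbour across the face opposite v[k]; -1 = none
  bool alive;
};

static inline long double orient3d(const arma::vec3& a, const arma::vec3& b,
                                   const arma::vec3& c, const arma::vec3& d) {
  long double adx = a[0] - d[0], ady = a[1] - d[1], adz = a[2] - d[2];
  long double bdx = b[0] - d[0], bdy = b[1] - d[1], bdz = b[2] - d[2];
  long double cdx = c[0] - d[0], cdy = c[1] - d[1], cdz = c[2] - d[2];
  return adx * (bdy * cdz - bdz * cdy) - ady * (bdx * cdz - bdz * cdx) +
         adz * (bdx * cdy - bdy * cdx);
}

static inline long double insphere(const arma::vec3& a, const arma::vec3& b,
                                   const arma::vec3& c, const arma::vec3& d,
                                   const arma::vec3& p) {
  // > 0 when p lies inside the circumsphere of the positively oriented (a,b,c,d)
  long double ax = a[0] - p[0], ay = a[1] - p[1], az = a[2] - p[2];
  long double bx = b[0] - p[0], by = b[1] - p[1], bz = b[2] - p[2];
  long double cx = c[0] - p[0], cy = c[1] - p[1], cz = c[2] - p[2];
  long double dx = d[0] - p[0], dy = d[1] - p[1], dz = d[2] - p[2];
  long double a2 = ax * ax + ay * ay + az * az;
  long double b2 = bx * bx + by * by + bz * bz;
  long double c2 = cx * cx + cy * cy + cz * cz;
  long double d2 = dx * dx + dy * dy + dz * dz;
  long double m01 = ax * by - bx * ay, m02 = ax * cy - cx * ay, m03 = ax * dy - dx * ay;
  long double m12 = bx * cy - cx * by, m13 = bx * dy - dx * by, m23 = cx * dy - dx * cy;
  long double det =
      -a2 * (bz * m23 - cz * m13 + dz * m12) + b2 * (az * m23 - cz * m03 + dz * m02) -
      c2 * (az * m13 - bz * m03 + dz * m01) + d2 * (az * m12 - bz * m02 + cz * m01);
  // sign convention: for positively oriented tet the determinant above is > 0
  // exactly when p is inside the circumsphere
  return det;
}

// [[Rcpp::export(name = ".delaunay3dCpp")]]
List delaunay3dCpp(const arma::mat& Pin) {
  const int n = Pin.n_rows;
  if (n < 4) stop("Delaunay tetrahedralisation requires at least 4 points");
  // normalise to the unit cube for conditioning
  arma::rowvec lo = arma::min(Pin, 0), hi = arma::max(Pin, 0);
  double scale = (hi - lo).max();
  if (!(scale > 0)) stop("degenerate point set");
  arma::mat P(n + 4, 3);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) P(i, j) = (Pin(i, j) - lo(j)) / scale;
  const double C = 2000.0;  // super-tetrahedron scale
  P.row(n + 0) = arma::rowvec{0.5, 0.5, 3.0 * C};
  P.row(n + 1) = arma::rowvec{0.5, 2.0 * C, -C};
  P.row(n + 2) = arma::rowvec{2.0 * C, -C, -C};
  P.row(n + 3) = arma::rowvec{-2.0 * C, -C, -C};

  std::vector<Tet> tets;
  {
    Tet t; t.alive = true;
    t.v[0] = n; t.v[1] = n + 1; t.v[2] = n + 2; t.v[3] = n + 3;
    if (orient3d(row3(P, t.v[0]), row3(P, t.v[1]), row3(P, t.v[2]), row3(P, t.v[3])) < 0)
      std::swap(t.v[2], t.v[3]);
    t.nb[0] = t.nb[1] = t.nb[2] = t.nb[3] = -1;
    tets.push_back(t);
  }

  int last = 0;
  for (int ip = 0; ip < n; ++ip) {
    arma::vec3 p = row3(P, ip);
    // locate a tetra containing p by walking
    int cur = last, steps = 0;
    bool located = false;
    while (steps++ < (int)tets.size() + 16) {
      if (!tets[cur].alive) { located = false; break; }
      const Tet& t = tets[cur];
      int moved = -1;
      for (int f = 0; f < 3 + 1; ++f) {
        // face opposite v[f]
        int a = t.v[(f + 1) % 4], b = t.v[(f + 2) % 4], c = t.v[(f + 3) % 4];
        // orient face consistently with the tet's positive orientation
        long double o = orient3d(row3(P, a), row3(P, b), row3(P, c), row3(P, t.v[f]));
        long double op = orient3d(row3(P, a), row3(P, b), row3(P, c), p);
        if ((o > 0 && op < 0) || (o < 0 && op > 0)) {
          if (t.nb[f] >= 0) { moved = t.nb[f]; break; }
        }
      }
      if (moved < 0) { located = true; break; }
      cur = moved;
    }
    if (!located) {  // fallback: linear scan
      cur = -1;
      for (size_t k = 0; k < tets.size(); ++k) {
        if (!tets[k].alive) continue;
        const Tet& t = tets[k];
        bool inside = true;
        for (int f = 0; f < 4 && inside; ++f) {
          int a = t.v[(f + 1) % 4], b = t.v[(f + 2) % 4], c = t.v[(f + 3) % 4];
          long double o = orient3d(row3(P, a), row3(P, b), row3(P, c), row3(P, t.v[f]));
          long double op = orient3d(row3(P, a), row3(P, b), row3(P, c), p);
          if ((o > 0 && op < 0) || (o < 0 && op > 0)) inside = false;
        }
        if (inside) { cur = (int)k; break; }
      }
      if (cur < 0) stop("point location failed during Delaunay construction");
    }

    // cavity = connected tets whose circumsphere contains p
    std::vector<int> cavity;
    std::vector<int> stack{cur};
    std::unordered_map<int, char> inCav;
    inCav[cur] = 1;
    while (!stack.empty()) {
      int k = stack.back(); stack.pop_back();
      cavity.push_back(k);
      for (int f = 0; f < 4; ++f) {
        int nb = tets[k].nb[f];
        if (nb < 0 || inCav.count(nb)) continue;
        const Tet& t = tets[nb];
        arma::vec3 A = row3(P, t.v[0]), B = row3(P, t.v[1]), Cc = row3(P, t.v[2]),
                   D = row3(P, t.v[3]);
        long double ins = (orient3d(A, B, Cc, D) > 0) ? insphere(A, B, Cc, D, p)
                                                      : -insphere(A, B, Cc, D, p);
        if (ins > 0) { inCav[nb] = 1; stack.push_back(nb); }
      }
    }
    // boundary faces of the cavity
    struct BFace { int a, b, c, outer; };
    std::vector<BFace> bfaces;
    for (int k : cavity) {
      const Tet& t = tets[k];
      for (int f = 0; f < 4; ++f) {
        int nb = t.nb[f];
        if (nb >= 0 && inCav.count(nb)) continue;
        BFace bf;
        bf.a = t.v[(f + 1) % 4]; bf.b = t.v[(f + 2) % 4]; bf.c = t.v[(f + 3) % 4];
        bf.outer = nb;
        bfaces.push_back(bf);
      }
    }
    for (int k : cavity) tets[k].alive = false;

    // retriangulate: one new tet per boundary face
    std::unordered_map<long long, std::pair<int, int>> fmap;  // sorted edge -> (tet, facepos)
    long long NN = n + 4;
    std::vector<int> fresh;
    for (const BFace& bf : bfaces) {
      Tet t; t.alive = true;
      t.v[0] = ip; t.v[1] = bf.a; t.v[2] = bf.b; t.v[3] = bf.c;
      if (orient3d(row3(P, t.v[0]), row3(P, t.v[1]), row3(P, t.v[2]), row3(P, t.v[3])) < 0)
        std::swap(t.v[2], t.v[3]);
      t.nb[0] = bf.outer;  // across the face opposite p = the boundary face
      t.nb[1] = t.nb[2] = t.nb[3] = -1;
      tets.push_back(t);
      int id = (int)tets.size() - 1;
      fresh.push_back(id);
      // hook the external neighbour back
      if (bf.outer >= 0) {
        Tet& o = tets[bf.outer];
        for (int f = 0; f < 4; ++f) {
          int x = o.v[(f + 1) % 4], y = o.v[(f + 2) % 4], z = o.v[(f + 3) % 4];
          int s1 = x + y + z, s2 = t.v[1] + t.v[2] + t.v[3];
          if (s1 == s2) {
            int mn1 = std::min({x, y, z}), mn2 = std::min({t.v[1], t.v[2], t.v[3]});
            int mx1 = std::max({x, y, z}), mx2 = std::max({t.v[1], t.v[2], t.v[3]});
            if (mn1 == mn2 && mx1 == mx2) { o.nb[f] = id; break; }
          }
        }
      }
      // internal faces contain ip and one boundary edge
      int vv[3] = {tets[id].v[1], tets[id].v[2], tets[id].v[3]};
      for (int e = 0; e < 3; ++e) {
        int a = vv[e], b = vv[(e + 1) % 3];
        int facepos = -1;  // position of the vertex opposite the face {ip, a, b}
        for (int f = 1; f < 4; ++f) {
          int w = tets[id].v[f];
          if (w != a && w != b) { facepos = f; break; }
        }
        long long key = (long long)std::min(a, b) * NN + std::max(a, b);
        auto it = fmap.find(key);
        if (it == fmap.end()) fmap[key] = {id, facepos};
        else {
          tets[id].nb[facepos] = it->second.first;
          tets[it->second.first].nb[it->second.second] = id;
          fmap.erase(it);
        }
      }
    }
    last = fresh.empty() ? last : fresh.back();
  }

  // collect real tets, their volumes and circumradii (in original units)
  std::vector<int> t1, t2, t3, t4;
  std::vector<double> vol, crad;
  for (const Tet& t : tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    arma::vec3 A = row3(Pin, t.v[0]), B = row3(Pin, t.v[1]), Cc = row3(Pin, t.v[2]),
               D = row3(Pin, t.v[3]);
    double v = std::fabs(arma::dot(B - A, arma::cross(Cc - A, D - A))) / 6.0;
    // circumcentre from the linear system 2 (X - A) . (c - A) = |X - A|^2
    arma::mat33 M;
    arma::vec3 rhs;
    arma::vec3 ba = B - A, ca = Cc - A, da = D - A;
    M.row(0) = 2.0 * ba.t(); M.row(1) = 2.0 * ca.t(); M.row(2) = 2.0 * da.t();
    rhs = {arma::dot(ba, ba), arma::dot(ca, ca), arma::dot(da, da)};
    arma::vec3 x;
    double r = NA_REAL;
    if (arma::solve(x, M, rhs)) r = arma::norm(x);
    t1.push_back(t.v[0] + 1); t2.push_back(t.v[1] + 1);
    t3.push_back(t.v[2] + 1); t4.push_back(t.v[3] + 1);
    vol.push_back(v); crad.push_back(r);
  }
  IntegerMatrix tm(t1.size(), 4);
  for (size_t i = 0; i < t1.size(); ++i) {
    tm(i, 0) = t1[i]; tm(i, 1) = t2[i]; tm(i, 2) = t3[i]; tm(i, 3) = t4[i];
  }
  return List::create(_["tetrahedra"] = tm, _["volume"] = wrap(vol),
                      _["circumradius"] = wrap(crad));
}

// ---------------------------------------------------------------------------
// Multi-source Dijkstra on an explicit edge list (CSR layout)
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".multiSourceDijkstraCpp")]]
List multiSourceDijkstraCpp(int n, const IntegerVector& offsets,
                            const IntegerVector& targets, const NumericVector& weights,
                            const IntegerVector& seeds, double cap) {
  // offsets: length n+1, 0-based CSR; targets/weights: edge arrays (targets 0-based)
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> lab(n, 0);  // 1-based seed rank, 0 = unreached
  typedef std::pair<double, int> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE>> pq;
  for (int s = 0; s < seeds.size(); ++s) {
    int v = seeds[s] - 1;
    if (v < 0 || v >= n) stop("seed index out of range");
    if (0.0 < dist[v]) { dist[v] = 0.0; lab[v] = s + 1; pq.push({0.0, v}); }
  }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    double d = top.first; int v = top.second;
    if (d > dist[v]) continue;
    if (d > cap) continue;
    for (int e = offsets[v]; e < offsets[v + 1]; ++e) {
      int w = targets[e];
      double nd = d + weights[e];
      if (nd < dist[w] && nd <= cap) {
        dist[w] = nd; lab[w] = lab[v];
        pq.push({nd, w});
      }
    }
  }
  for (int v = 0; v < n; ++v) if (dist[v] > cap) { lab[v] = 0; dist[v] = R_PosInf; }
  return List::create(_["seed"] = wrap(lab), _["distance"] = wrap(dist));
}
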