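// 3D Delaunay tetrahedralization and mesh helpers.
//
// Two engines:
//  * cpp_delaunay: incremental Bowyer-Watson with a deterministic joggle,
//    for generic point clouds (atlas-scale, up to a few thousand points).
//  * cpp_lattice_tets: Kuhn (Freudenthal) split of complete unit cells of an
//    integer lattice. For a regular voxel grid this is a Delaunay
//    triangulation of the occupied region (each Kuhn tet's circumsphere is
//    the cell's circumsphere, which contains no other lattice point), and it
//    sidesteps the cospherical degeneracy that makes grid data hostile to
//    floating-point incremental insertion.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cstdint>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct Tet {
  int v[4];
  double cc[3];   // circumcenter
  double r2;      // squared circumradius
  bool alive;
};

inline double det3(double a00, double a01, double a02,
                   double a10, double a11, double a12,
                   double a20, double a21, double a22) {
  return a00 * (a11 * a22 - a12 * a21)
       - a01 * (a10 * a22 - a12 * a20)
       + a02 * (a10 * a21 - a11 * a20);
}

// signed volume * 6 of tetrahedron (a,b,c,d)
inline double orient6(const double* a, const double* b,
                      const double* c, const double* d) {
  return det3(b[0] - a[0], b[1] - a[1], b[2] - a[2],
              c[0] - a[0], c[1] - a[1], c[2] - a[2],
              d[0] - a[0], d[1] - a[1], d[2] - a[2]);
}

// circumcenter of 4 points; returns false if degenerate
inline bool circumsphere(const double* a, const double* b, const double* c,
                         const double* d, double* cc, double& r2) {
  double A[3][3], rhs[3];
  const double* pts[3] = {b, c, d};
  for (int i = 0; i < 3; ++i) {
    double n2 = 0.0;
    for (int j = 0; j < 3; ++j) {
      A[i][j] = 2.0 * (pts[i][j] - a[j]);
      n2 += pts[i][j] * pts[i][j] - a[j] * a[j];
    }
    rhs[i] = n2;
  }
  double det = det3(A[0][0], A[0][1], A[0][2],
                    A[1][0], A[1][1], A[1][2],
                    A[2][0], A[2][1], A[2][2]);
  if (std::fabs(det) < 1e-300) return false;
  // Cramer
  for (int j = 0; j < 3; ++j) {
    double M[3][3];
    for (int i = 0; i < 3; ++i)
      for (int k = 0; k < 3; ++k) M[i][k] = A[i][k];
    for (int i = 0; i < 3; ++i) M[i][j] = rhs[i];
    cc[j] = det3(M[0][0], M[0][1], M[0][2],
                 M[1][0], M[1][1], M[1][2],
                 M[2][0], M[2][1], M[2][2]) / det;
  }
  r2 = 0.0;
  for (int j = 0; j < 3; ++j) r2 += (cc[j] - a[j]) * (cc[j] - a[j]);
  return true;
}

// deterministic per-point jitter in [-1, 1], splitmix-style hash
inline double hash_unit(uint64_t x) {
  x += 0x9E3779B97F4A7C15ULL;
  x = (x ^ (x >> 30)) * 0xBF58476D1CE4E5B9ULL;
  x = (x ^ (x >> 27)) * 0x94D049BB133111EBULL;
  x = x ^ (x >> 31);
  return 2.0 * (double)(x >> 11) / 9007199254740992.0 - 1.0;
}

inline uint64_t face_key(int a, int b, int c) {
  // sort 3 ints then pack (node counts stay far below 2^21)
  int x = a, y = b, z = c, t;
  if (x > y) { t = x; x = y; y = t; }
  if (y > z) { t = y; y = z; z = t; }
  if (x > y) { t = x; x = y; y = t; }
  return ((uint64_t)x << 42) | ((uint64_t)y << 21) | (uint64_t)z;
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_delaunay(NumericMatrix pts, double joggle) {
  const int n = pts.nrow();
  if (n < 4) stop("need at least 4 points");

  // scale to centred unit box, apply deterministic joggle
  double lo[3], hi[3];
  for (int j = 0; j < 3; ++j) { lo[j] = R_PosInf; hi[j] = R_NegInf; }
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j) {
      double v = pts(i, j);
      if (!R_finite(v)) stop("non-finite coordinate");
      if (v < lo[j]) lo[j] = v;
      if (v > hi[j]) hi[j] = v;
    }
  double span = 0.0;
  for (int j = 0; j < 3; ++j) span = std::max(span, hi[j] - lo[j]);
  if (span <= 0.0) stop("degenerate geometry: all points coincide");

  std::vector<double> P(3 * (n + 4));
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 3; ++j)
      P[3 * i + j] = (pts(i, j) - 0.5 * (lo[j] + hi[j])) / span
                   + joggle * hash_unit((uint64_t)i * 3u + (uint64_t)j + 1u);

  // enclosing super-tetrahedron, far away
  const double L = 1e3;
  double super[4][3] = {{0, 0, 3 * L}, {2 * L, 0, -L},
                        {-L, 1.8 * L, -L}, {-L, -1.8 * L, -L}};
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 3; ++j) P[3 * (n + i) + j] = super[i][j];

  std::vector<Tet> tets;
  tets.reserve(8 * n);
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    if (orient6(&P[3 * t0.v[0]], &P[3 * t0.v[1]], &P[3 * t0.v[2]],
                &P[3 * t0.v[3]]) < 0) std::swap(t0.v[2], t0.v[3]);
    circumsphere(&P[3 * t0.v[0]], &P[3 * t0.v[1]], &P[3 * t0.v[2]],
                 &P[3 * t0.v[3]], t0.cc, t0.r2);
    t0.alive = true;
    tets.push_back(t0);
  }

  // deterministic insertion order (large odd stride modulo n)
  std::vector<int> order(n);
  {
    auto gcd_ll = [](long long a, long long b) {
      while (b) { long long t = a % b; a = b; b = t; }
      return a;
    };
    long long stride = 2654435761LL % n;
    if (stride < 1) stride = 1;
    if (stride % 2 == 0) ++stride;
    while (gcd_ll((long long)n, stride) != 1) stride += 2;
    for (int i = 0; i < n; ++i) order[i] = (int)(((long long)i * stride) % n);
  }

  std::vector<int> cavity;
  std::vector<char> in_cavity;
  for (int oi = 0; oi < n; ++oi) {
    const int ip = order[oi];
    const double* p = &P[3 * ip];

    cavity.clear();
    for (int t = 0; t < (int)tets.size(); ++t) {
      if (!tets[t].alive) continue;
      double d2 = 0.0;
      for (int j = 0; j < 3; ++j)
        d2 += (p[j] - tets[t].cc[j]) * (p[j] - tets[t].cc[j]);
      if (d2 < tets[t].r2) cavity.push_back(t);
    }
    if (cavity.empty()) {
      // numeric fallback: containing tet by orientation tests
      for (int t = 0; t < (int)tets.size(); ++t) {
        if (!tets[t].alive) continue;
        const int* v = tets[t].v;
        bool inside = true;
        for (int f = 0; f < 4 && inside; ++f) {
          int a = v[f], b = v[(f + 1) % 4], c = v[(f + 2) % 4],
              d = v[(f + 3) % 4];
          double s = orient6(&P[3 * a], &P[3 * b], &P[3 * c], &P[3 * d]);
          double sp = orient6(&P[3 * a], &P[3 * b], &P[3 * c], p);
          if (s * sp < 0) inside = false;
        }
        if (inside) { cavity.push_back(t); break; }
      }
      if (cavity.empty()) stop("point location failed");
    }

    in_cavity.assign(tets.size(), 0);
    for (int t : cavity) in_cavity[t] = 1;

    // grow cavity until every boundary face makes a non-degenerate,
    // positively-oriented tet with p (star-shapedness repair)
    for (int repair = 0; repair < 64; ++repair) {
      std::unordered_map<uint64_t, std::pair<int, std::array<int, 3>>> faces;
      faces.reserve(cavity.size() * 4);
      for (int t : cavity) {
        const int* v = tets[t].v;
        const int idx[4][3] = {{v[1], v[2], v[3]}, {v[0], v[3], v[2]},
                               {v[0], v[1], v[3]}, {v[0], v[2], v[1]}};
        for (int f = 0; f < 4; ++f) {
          uint64_t k = face_key(idx[f][0], idx[f][1], idx[f][2]);
          auto it = faces.find(k);
          if (it == faces.end())
            faces[k] = {1, {idx[f][0], idx[f][1], idx[f][2]}};
          else
            it->second.first++;
        }
      }
      bool grew = false;
      for (auto& kv : faces) {
        if (kv.second.first != 1) continue; // interior to cavity
        const auto& fv = kv.second.second;
        double vol = orient6(&P[3 * fv[0]], &P[3 * fv[1]], &P[3 * fv[2]], p);
        if (std::fabs(vol) > 1e-14) continue;
        // degenerate new tet: pull the outside neighbour into the cavity
        uint64_t k = kv.first;
        for (int t = 0; t < (int)tets.size() && !grew; ++t) {
          if (!tets[t].alive || in_cavity[t]) continue;
          const int* v = tets[t].v;
          const int idx[4][3] = {{v[1], v[2], v[3]}, {v[0], v[3], v[2]},
                                 {v[0], v[1], v[3]}, {v[0], v[2], v[1]}};
          for (int f = 0; f < 4; ++f)
            if (face_key(idx[f][0], idx[f][1], idx[f][2]) == k) {
              cavity.push_back(t);
              in_cavity[t] = 1;
              grew = true;
              break;
            }
        }
        if (grew) break;
      }
      if (!grew) {
        // cavity is sound: carve and fill
        for (int t : cavity) tets[t].alive = false;
        for (auto& kv : faces) {
          if (kv.second.first != 1) continue;
          const auto& fv = kv.second.second;
          Tet nt;
          nt.v[0] = ip; nt.v[1] = fv[0]; nt.v[2] = fv[1]; nt.v[3] = fv[2];
          if (orient6(&P[3 * nt.v[0]], &P[3 * nt.v[1]], &P[3 * nt.v[2]],
                      &P[3 * nt.v[3]]) < 0) std::swap(nt.v[2], nt.v[3]);
          if (!circumsphere(&P[3 * nt.v[0]], &P[3 * nt.v[1]],
                            &P[3 * nt.v[2]], &P[3 * nt.v[3]], nt.cc, nt.r2)) {
            nt.cc[0] = nt.cc[1] = nt.cc[2] = 0.0;
            nt.r2 = -1.0; // degenerate: empty circumsphere
          }
          nt.alive = true;
          tets.push_back(nt);
          in_cavity.push_back(0);
        }
        break;
      }
    }
  }

  // keep finite tets (no super vertices)
  std::vector<std::array<int, 4>> out;
  out.reserve(tets.size());
  for (const auto& t : tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    out.push_back({t.v[0], t.v[1], t.v[2], t.v[3]});
  }
  IntegerMatrix res(out.size(), 4);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < 4; ++j) res(i, j) = out[i][j] + 1;
  return res;
}

// [[Rcpp::export]]
IntegerMatrix cpp_lattice_tets(IntegerMatrix idx) {
  const int n = idx.nrow();
  std::unordered_map<uint64_t, int> lookup;
  lookup.reserve(2 * n);
  auto key = [](int i, int j, int k) {
    return ((uint64_t)(uint32_t)(i + 1048576) << 42)
         | ((uint64_t)(uint32_t)(j + 1048576) << 21)
         | (uint64_t)(uint32_t)(k + 1048576);
  };
  for (int i = 0; i < n; ++i) lookup[key(idx(i, 0), idx(i, 1), idx(i, 2))] = i;

  // Kuhn split: 6 tets per complete cell, each along the main diagonal
  const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                           {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};
  std::vector<std::array<int, 4>> out;
  for (int i = 0; i < n; ++i) {
    int c[3] = {idx(i, 0), idx(i, 1), idx(i, 2)};
    int corner[8];
    bool complete = true;
    for (int b = 0; b < 8 && complete; ++b) {
      auto it = lookup.find(key(c[0] + (b & 1), c[1] + ((b >> 1) & 1),
                                c[2] + ((b >> 2) & 1)));
      if (it == lookup.end()) complete = false;
      else corner[b] = it->second;
    }
    if (!complete) continue;
    for (int pidx = 0; pidx < 6; ++pidx) {
      int bits = 0;
      std::array<int, 4> tv;
      tv[0] = corner[0];
      for (int s = 0; s < 3; ++s) {
        bits |= (1 << perms[pidx][s]);
        tv[s + 1] = corner[bits];
      }
      out.push_back(tv);
    }
  }
  IntegerMatrix res(out.size(), 4);
  for (size_t i = 0; i < out.size(); ++i)
    for (int j = 0; j < 4; ++j) res(i, j) = out[i][j] + 1;
  return res;
}

// [[Rcpp::export]]
List cpp_face_multiplicity(IntegerMatrix tets) {
  const int nt = tets.nrow();
  std::unordered_map<uint64_t, std::pair<int, std::array<int, 3>>> faces;
  faces.reserve(4 * nt);
  for (int t = 0; t < nt; ++t) {
    int v[4] = {tets(t, 0), tets(t, 1), tets(t, 2), tets(t, 3)};
    const int idx[4][3] = {{v[1], v[2], v[3]}, {v[0], v[2], v[3]},
                           {v[0], v[1], v[3]}, {v[0], v[1], v[2]}};
    for (int f = 0; f < 4; ++f) {
      uint64_t k = face_key(idx[f][0], idx[f][1], idx[f][2]);
      auto it = faces.find(k);
      if (it == faces.end())
        faces[k] = {1, {idx[f][0], idx[f][1], idx[f][2]}};
      else
        it->second.first++;
    }
  }
  int nsurf = 0, maxmult = 0;
  for (auto& kv : faces) {
    if (kv.second.first == 1) ++nsurf;
    if (kv.second.first > maxmult) maxmult = kv.second.first;
  }
  IntegerMatrix surf(nsurf, 3);
  int r = 0;
  std::vector<std::pair<uint64_t, std::array<int, 3>>> ordered;
  ordered.reserve(nsurf);
  for (auto& kv : faces)
    if (kv.second.first == 1) ordered.push_back({kv.first, kv.second.second});
  std::sort(ordered.begin(), ordered.end(),
            [](const std::pair<uint64_t, std::array<int, 3>>& a,
               const std::pair<uint64_t, std::array<int, 3>>& b) {
              return a.first < b.first;
            });
  for (auto& kv : ordered) {
    surf(r, 0) = kv.second[0];
    surf(r, 1) = kv.second[1];
    surf(r, 2) = kv.second[2];
    ++r;
  }
  return List::create(Named("surface_faces") = surf,
                      Named("max_multiplicity") = maxmult);
}

// [[Rcpp::export]]
NumericVector cpp_tet_volumes(NumericMatrix pts, IntegerMatrix tets) {
  const int nt = tets.nrow();
  NumericVector vol(nt);
  for (int t = 0; t < nt; ++t) {
    const double a[3] = {pts(tets(t, 0) - 1, 0), pts(tets(t, 0) - 1, 1),
                         pts(tets(t, 0) - 1, 2)};
    const double b[3] = {pts(tets(t, 1) - 1, 0), pts(tets(t, 1) - 1, 1),
                         pts(tets(t, 1) - 1, 2)};
    const double c[3] = {pts(tets(t, 2) - 1, 0), pts(tets(t, 2) - 1, 1),
                         pts(tets(t, 2) - 1, 2)};
    const double d[3] = {pts(tets(t, 3) - 1, 0), pts(tets(t, 3) - 1, 1),
                         pts(tets(t, 3) - 1, 2)};
    vol[t] = orient6(a, b, c, d) / 6.0;
  }
  return vol;
}

// [[Rcpp::export]]
NumericVector cpp_max_edge(NumericMatrix pts, IntegerMatrix tets) {
  const int nt = tets.nrow();
  NumericVector me(nt);
  for (int t = 0; t < nt; ++t) {
    double best = 0.0;
    for (int i = 0; i < 4; ++i)
      for (int j = i + 1; j < 4; ++j) {
        double d2 = 0.0;
        for (int k = 0; k < 3; ++k) {
          double dd = pts(tets(t, i) - 1, k) - pts(tets(t, j) - 1, k);
          d2 += dd * dd;
        }
        if (d2 > best) best = d2;
      }
    me[t] = std::sqrt(best);
  }
  return me;
}
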