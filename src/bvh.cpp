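// AABB bounding-volume hierarchy over mesh triangles with exact
// nearest-triangle queries (closest point on triangle after Ericson,
// Real-Time Collision Detection, ch. 5).
#include <Rcpp.h>
#include <vector>
#include <array>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3() : x(0), y(0), z(0) {}
  Vec3(double x_, double y_, double z_) : x(x_), y(y_), z(z_) {}
  Vec3 operator-(const Vec3 &o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator+(const Vec3 &o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
};
static inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}

// closest point on triangle abc to p
static Vec3 closestPointTriangle(const Vec3 &p, const Vec3 &a, const Vec3 &b,
                                 const Vec3 &c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + ab * v;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + ac * w;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + (c - b) * w;
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + ab * v + ac * w;
}

struct BVHNode {
  double lo[3], hi[3];
  int left, right;   // child node indices, -1 for leaf
  int begin, end;    // triangle index range for leaves
};

struct BVH {
  std::vector<Vec3> va, vb, vc;     // triangle vertices, reordered
  std::vector<int> id;              // original 1-based face ids
  std::vector<BVHNode> nodes;
  int root;
};

static inline double boxDist2(const BVHNode &n, const Vec3 &p) {
  double d2 = 0.0;
  double c[3] = {p.x, p.y, p.z};
  for (int k = 0; k < 3; ++k) {
    double d = 0.0;
    if (c[k] < n.lo[k]) d = n.lo[k] - c[k];
    else if (c[k] > n.hi[k]) d = c[k] - n.hi[k];
    d2 += d * d;
  }
  return d2;
}

static int buildNode(BVH &bvh, std::vector<int> &order,
                     std::vector<std::array<double, 3> > &cent,
                     int begin, int end) {
  BVHNode node;
  for (int k = 0; k < 3; ++k) {
    node.lo[k] = std::numeric_limits<double>::infinity();
    node.hi[k] = -std::numeric_limits<double>::infinity();
  }
  for (int i = begin; i < end; ++i) {
    int t = order[i];
    const Vec3 *vv[3] = {&bvh.va[t], &bvh.vb[t], &bvh.vc[t]};
    for (int j = 0; j < 3; ++j) {
      double c[3] = {vv[j]->x, vv[j]->y, vv[j]->z};
      for (int k = 0; k < 3; ++k) {
        node.lo[k] = std::min(node.lo[k], c[k]);
        node.hi[k] = std::max(node.hi[k], c[k]);
      }
    }
  }
  int n = end - begin;
  if (n <= 4) {
    node.left = node.right = -1;
    node.begin = begin; node.end = end;
    bvh.nodes.push_back(node);
    return (int)bvh.nodes.size() - 1;
  }
  // split along widest centroid axis at median
  double clo[3] = {1e300, 1e300, 1e300}, chi[3] = {-1e300, -1e300, -1e300};
  for (int i = begin; i < end; ++i) {
    for (int k = 0; k < 3; ++k) {
      clo[k] = std::min(clo[k], cent[order[i]][k]);
      chi[k] = std::max(chi[k], cent[order[i]][k]);
    }
  }
  int axis = 0;
  double wmax = chi[0] - clo[0];
  for (int k = 1; k < 3; ++k)
    if (chi[k] - clo[k] > wmax) { wmax = chi[k] - clo[k]; axis = k; }
  int mid = begin + n / 2;
  std::nth_element(order.begin() + begin, order.begin() + mid,
                   order.begin() + end,
                   [&](int a, int b) { return cent[a][axis] < cent[b][axis]; });
  node.begin = node.end = -1;
  bvh.nodes.push_back(node);
  int self = (int)bvh.nodes.size() - 1;
  int l = buildNode(bvh, order, cent, begin, mid);
  int r = buildNode(bvh, order, cent, mid, end);
  bvh.nodes[self].left = l;
  bvh.nodes[self].right = r;
  return self;
}

// [[Rcpp::export(name = ".bvh_build")]]
SEXP bvh_build_cpp(NumericMatrix V, IntegerMatrix F) {
  if (F.nrow() == 0) stop("cannot build a spatial index over an empty mesh");
  BVH *bvh = new BVH();
  int m = F.nrow();
  bvh->va.resize(m); bvh->vb.resize(m); bvh->vc.resize(m);
  bvh->id.resize(m);
  std::vector<std::array<double, 3> > cent(m);
  for (int i = 0; i < m; ++i) {
    int a = F(i, 0) - 1, b = F(i, 1) - 1, c = F(i, 2) - 1;
    bvh->va[i] = Vec3(V(a, 0), V(a, 1), V(a, 2));
    bvh->vb[i] = Vec3(V(b, 0), V(b, 1), V(b, 2));
    bvh->vc[i] = Vec3(V(c, 0), V(c, 1), V(c, 2));
    bvh->id[i] = i + 1;
    cent[i][0] = (bvh->va[i].x + bvh->vb[i].x + bvh->vc[i].x) / 3.0;
    cent[i][1] = (bvh->va[i].y + bvh->vb[i].y + bvh->vc[i].y) / 3.0;
    cent[i][2] = (bvh->va[i].z + bvh->vb[i].z + bvh->vc[i].z) / 3.0;
  }
  std::vector<int> order(m);
  for (int i = 0; i < m; ++i) order[i] = i;
  bvh->root = buildNode(*bvh, order, cent, 0, m);
  // reorder triangles by `order` so leaves address contiguous ranges
  {
    std::vector<Vec3> ta(m), tb(m), tc(m);
    std::vector<int> tid(m);
    for (int i = 0; i < m; ++i) {
      ta[i] = bvh->va[order[i]];
      tb[i] = bvh->vb[order[i]];
      tc[i] = bvh->vc[order[i]];
      tid[i] = bvh->id[order[i]];
    }
    bvh->va.swap(ta); bvh->vb.swap(tb); bvh->vc.swap(tc); bvh->id.swap(tid);
  }
  XPtr<BVH> ptr(bvh, true);
  return ptr;
}

// nearest triangle for each query point; ties broken toward the lowest
// original face index
// [[Rcpp::export(name = ".bvh_query")]]
List bvh_query_cpp(SEXP bvh_ptr, NumericMatrix Q) {
  XPtr<BVH> bvh(bvh_ptr);
  int nq = Q.nrow();
  NumericVector dist(nq);
  IntegerVector face(nq);
  NumericMatrix closest(nq, 3);
  std::vector<int> stack;
  stack.reserve(64);
  for (int q = 0; q < nq; ++q) {
    Vec3 p(Q(q, 0), Q(q, 1), Q(q, 2));
    double best2 = std::numeric_limits<double>::infinity();
    int bestFace = NA_INTEGER;
    Vec3 bestPt;
    stack.clear();
    stack.push_back(bvh->root);
    while (!stack.empty()) {
      int ni = stack.back();
      stack.pop_back();
      const BVHNode &node = bvh->nodes[ni];
      if (boxDist2(node, p) > best2) continue;
      if (node.left < 0) {
        for (int i = node.begin; i < node.end; ++i) {
          Vec3 cp = closestPointTriangle(p, bvh->va[i], bvh->vb[i], bvh->vc[i]);
          Vec3 d = p - cp;
          double d2 = dot(d, d);
          if (d2 < best2 - 1e-300 ||
              (d2 <= best2 && bestFace != NA_INTEGER && bvh->id[i] < bestFace)) {
            best2 = d2;
            bestFace = bvh->id[i];
            bestPt = cp;
          }
        }
      } else {
        // descend nearer child first
        double dl = boxDist2(bvh->nodes[node.left], p);
        double dr = boxDist2(bvh->nodes[node.right], p);
        if (dl < dr) {
          stack.push_back(node.right);
          stack.push_back(node.left);
        } else {
          stack.push_back(node.left);
          stack.push_back(node.right);
        }
      }
    }
    dist[q] = std::sqrt(best2);
    face[q] = bestFace;
    closest(q, 0) = bestPt.x;
    closest(q, 1) = bestPt.y;
    closest(q, 2) = bestPt.z;
  }
  return List::create(_["distance"] = dist, _["face"] = face,
                      _["closest"] = closest);
}

// [[Rcpp::export(name = ".bvh_size")]]
int bvh_size_cpp(SEXP bvh_ptr) {
  XPtr<BVH> bvh(bvh_ptr);
  return (int)bvh->id.size();
}
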