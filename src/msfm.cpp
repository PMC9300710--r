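#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Multi-stencil fast marching for |grad T| = 1/F on a 2D/3D grid.
//
// Each stencil is a set of (not necessarily orthogonal) grid directions.
// With unit physical directions stacked in U, the directional differences
// D satisfy D = U grad T, so |grad T|^2 = D' (U U')^{-1} D, and the upwind
// discretisation of D_i is linear in the unknown T. The resulting scalar
// quadratic is solved per stencil and the smallest causal value kept.
// Second-order one-sided differences are used where the two-step upwind
// neighbour is accepted and strictly smaller (the strictness guards
// against curvature-induced underestimates near the source).

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Dir {
  int d1, d2, d3;   // grid step
  double h;         // physical length of the step
  double u[3];      // unit physical direction
};

struct Stencil {
  std::vector<Dir> dirs;
};

struct Node {
  double t;
  R_xlen_t idx;
  bool operator<(const Node& o) const { return t > o.t; }  // min-heap
};

// invert the Gram matrix of the included unit directions (size 1..3)
bool invert_gram(const std::vector<const Dir*>& ds, double M[3][3]) {
  int m = (int)ds.size();
  double G[3][3];
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < m; ++j) {
      G[i][j] = 0.0;
      for (int k = 0; k < 3; ++k) G[i][j] += ds[i]->u[k] * ds[j]->u[k];
    }
  if (m == 1) {
    if (G[0][0] <= 0) return false;
    M[0][0] = 1.0 / G[0][0];
    return true;
  }
  if (m == 2) {
    double det = G[0][0] * G[1][1] - G[0][1] * G[1][0];
    if (std::fabs(det) < 1e-12) return false;
    M[0][0] = G[1][1] / det;
    M[1][1] = G[0][0] / det;
    M[0][1] = M[1][0] = -G[0][1] / det;
    return true;
  }
  double det = G[0][0] * (G[1][1] * G[2][2] - G[1][2] * G[2][1]) -
               G[0][1] * (G[1][0] * G[2][2] - G[1][2] * G[2][0]) +
               G[0][2] * (G[1][0] * G[2][1] - G[1][1] * G[2][0]);
  if (std::fabs(det) < 1e-12) return false;
  M[0][0] = (G[1][1] * G[2][2] - G[1][2] * G[2][1]) / det;
  M[0][1] = (G[0][2] * G[2][1] - G[0][1] * G[2][2]) / det;
  M[0][2] = (G[0][1] * G[1][2] - G[0][2] * G[1][1]) / det;
  M[1][0] = M[0][1];
  M[1][1] = (G[0][0] * G[2][2] - G[0][2] * G[2][0]) / det;
  M[1][2] = (G[0][2] * G[1][0] - G[0][0] * G[1][2]) / det;
  M[2][0] = M[0][2];
  M[2][1] = M[1][2];
  M[2][2] = (G[0][0] * G[1][1] - G[0][1] * G[1][0]) / det;
  return true;
}

}  // namespace

// [[Rcpp::export(name = ".msfm_cpp")]]
NumericVector msfm_cpp(NumericVector speed, IntegerVector dims,
                       NumericVector spacing, IntegerMatrix sources,
                       bool second_order = true) {
  const int n1 = dims[0], n2 = dims[1], n3 = (dims.size() > 2) ? dims[2] : 1;
  const double h1 = spacing[0], h2 = spacing[1],
               h3 = (spacing.size() > 2) ? spacing[2] : 1.0;
  const R_xlen_t n = (R_xlen_t)n1 * n2 * n3;
  if (speed.size() != n) stop("speed length does not match dims");

  NumericVector T(n, INF);
  std::vector<unsigned char> state(n, 0);  // 0 far, 1 trial, 2 accepted
  std::priority_queue<Node> heap;

  auto make_dir = [&](int a, int b, int c) -> Dir {
    Dir d;
    d.d1 = a; d.d2 = b; d.d3 = c;
    double p1 = a * h1, p2 = b * h2, p3 = c * h3;
    d.h = std::sqrt(p1 * p1 + p2 * p2 + p3 * p3);
    d.u[0] = p1 / d.h; d.u[1] = p2 / d.h; d.u[2] = p3 / d.h;
    return d;
  };

  std::vector<Stencil> stencils;
  {
    Stencil s;
    s.dirs.push_back(make_dir(1, 0, 0));
    s.dirs.push_back(make_dir(0, 1, 0));
    if (n3 > 1) s.dirs.push_back(make_dir(0, 0, 1));
    stencils.push_back(s);
    Stencil sd;  // in-plane diagonals
    sd.dirs.push_back(make_dir(1, 1, 0));
    sd.dirs.push_back(make_dir(1, -1, 0));
    if (n3 > 1) sd.dirs.push_back(make_dir(0, 0, 1));
    stencils.push_back(sd);
    if (n3 > 1) {
      Stencil sa, sb;
      sa.dirs.push_back(make_dir(1, 0, 1));
      sa.dirs.push_back(make_dir(1, 0, -1));
      sa.dirs.push_back(make_dir(0, 1, 0));
      stencils.push_back(sa);
      sb.dirs.push_back(make_dir(0, 1, 1));
      sb.dirs.push_back(make_dir(0, 1, -1));
      sb.dirs.push_back(make_dir(1, 0, 0));
      stencils.push_back(sb);
    }
  }

  auto at = [&](int i, int j, int k) -> R_xlen_t {
    return (R_xlen_t)i + (R_xlen_t)j * n1 + (R_xlen_t)k * n1 * n2;
  };
  auto inside = [&](int i, int j, int k) -> bool {
    return i >= 0 && i < n1 && j >= 0 && j < n2 && k >= 0 && k < n3;
  };

  struct Term {
    const Dir* dir;
    double g;     // slope factor (signed): D approx g * (T - v)
    double v;     // value part
    double tlow;  // first-order upwind value (causality bound)
  };

  auto update = [&](int i, int j, int k) {
    R_xlen_t p = at(i, j, k);
    double F = speed[p];
    if (!(F > 0.0)) return;
    double rhs = 1.0 / (F * F);
    double best = INF;
    for (const Stencil& st : stencils) {
      std::vector<Term> terms;
      for (const Dir& d : st.dirs) {
        double t1 = INF;
        int sgn = 0;
        for (int s = -1; s <= 1; s += 2) {
          int ii = i + s * d.d1, jj = j + s * d.d2, kk = k + s * d.d3;
          if (inside(ii, jj, kk) && state[at(ii, jj, kk)] == 2 &&
              T[at(ii, jj, kk)] < t1) {
            t1 = T[at(ii, jj, kk)];
            sgn = s;
          }
        }
        if (!std::isfinite(t1)) continue;
        // backward difference along +u uses the neighbour at -u; if the
        // accepted neighbour sits at +u the derivative flips sign
        double sign = (sgn < 0) ? 1.0 : -1.0;
        Term tm;
        tm.dir = &d;
        tm.tlow = t1;
        bool used2 = false;
        if (second_order) {
          int ii = i + 2 * sgn * d.d1, jj = j + 2 * sgn * d.d2,
              kk = k + 2 * sgn * d.d3;
          if (inside(ii, jj, kk) && state[at(ii, jj, kk)] == 2) {
            double t2 = T[at(ii, jj, kk)];
            if (t2 < t1) {
              tm.g = sign * 1.5 / d.h;
              tm.v = (4.0 * t1 - t2) / 3.0;
              used2 = true;
            }
          }
        }
        if (!used2) {
          tm.g = sign * 1.0 / d.h;
          tm.v = t1;
        }
        terms.push_back(tm);
      }
      // solve, dropping causality violators (largest upwind value first)
      while (!terms.empty()) {
        std::vector<const Dir*> ds;
        for (const Term& tm : terms) ds.push_back(tm.dir);
        double M[3][3];
        if (!invert_gram(ds, M)) break;
        double A = 0.0, B = 0.0, C = -rhs;
        int m = (int)terms.size();
        for (int a = 0; a < m; ++a)
          for (int b = 0; b < m; ++b) {
            double w = M[a][b] * terms[a].g * terms[b].g;
            A += w;
            B += -w * (terms[a].v + terms[b].v);
            C += w * terms[a].v * terms[b].v;
          }
        double disc = B * B - 4.0 * A * C;
        bool ok = false;
        double Ts = INF;
        if (disc >= 0.0 && A > 0.0) {
          Ts = (-B + std::sqrt(disc)) / (2.0 * A);
          ok = true;
          for (const Term& tm : terms)
            if (Ts < tm.tlow) { ok = false; break; }
        }
        if (ok) {
          if (Ts < best) best = Ts;
          break;
        }
        size_t imax = 0;
        for (size_t a = 1; a < terms.size(); ++a)
          if (terms[a].tlow > terms[imax].tlow) imax = a;
        terms.erase(terms.begin() + imax);
      }
    }
    if (best < T[p]) {
      T[p] = best;
      state[p] = 1;
      heap.push({best, p});
    }
  };

  // Exact initialisation in a small box around each source (local speed
  // assumed constant there): the front is strongly curved near a point
  // source and the upwind differences are biased exactly where their
  // error propagates to the whole domain.
  const int R0 = 4;
  for (int r = 0; r < sources.nrow(); ++r) {
    int i = sources(r, 0), j = sources(r, 1),
        k = (sources.ncol() > 2) ? sources(r, 2) : 0;
    if (!inside(i, j, k)) stop("source outside volume");
    double F0 = speed[at(i, j, k)];
    if (!(F0 > 0.0)) F0 = 1.0;
    for (int dk = (n3 > 1 ? -R0 : 0); dk <= (n3 > 1 ? R0 : 0); ++dk)
      for (int dj = -R0; dj <= R0; ++dj)
        for (int di = -R0; di <= R0; ++di) {
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (!inside(ii, jj, kk)) continue;
          // only freeze where the medium still looks like the source
          if (std::fabs(speed[at(ii, jj, kk)] - F0) > 0.1 * F0 &&
              (di != 0 || dj != 0 || dk != 0))
            continue;
          double dist = std::sqrt(di * h1 * di * h1 + dj * h2 * dj * h2 +
                                  dk * h3 * dk * h3) / F0;
          R_xlen_t p = at(ii, jj, kk);
          if (dist < T[p]) {
            T[p] = dist;
            state[p] = 2;  // frozen: exact by construction
          }
        }
  }
  // seed the march from the frontier of the frozen boxes
  for (R_xlen_t p = 0; p < n; ++p) {
    if (state[p] != 2) continue;
    int k = (int)(p / ((R_xlen_t)n1 * n2));
    R_xlen_t rem = p - (R_xlen_t)k * n1 * n2;
    int j = (int)(rem / n1);
    int i = (int)(rem - (R_xlen_t)j * n1);
    for (int dk = (n3 > 1 ? -1 : 0); dk <= (n3 > 1 ? 1 : 0); ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (inside(ii, jj, kk) && state[at(ii, jj, kk)] != 2)
            update(ii, jj, kk);
        }
  }

  while (!heap.empty()) {
    Node nd = heap.top();
    heap.pop();
    if (state[nd.idx] == 2) continue;
    state[nd.idx] = 2;
    int k = (int)(nd.idx / ((R_xlen_t)n1 * n2));
    R_xlen_t rem = nd.idx - (R_xlen_t)k * n1 * n2;
    int j = (int)(rem / n1);
    int i = (int)(rem - (R_xlen_t)j * n1);
    for (int dk = (n3 > 1 ? -1 : 0); dk <= (n3 > 1 ? 1 : 0); ++dk)
      for (int dj = -1; dj <= 1; ++dj)
        for (int di = -1; di <= 1; ++di) {
          if (di == 0 && dj == 0 && dk == 0) continue;
          int ii = i + di, jj = j + dj, kk = k + dk;
          if (inside(ii, jj, kk) && state[at(ii, jj, kk)] != 2)
            update(ii, jj, kk);
        }
  }

  T.attr("dim") = dims;
  return T;
}
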