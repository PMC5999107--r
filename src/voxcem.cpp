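#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Flat index into an nx*ny*nz array stored in R's column-major layout.
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

static inline bool inside(int i, int j, int k, int nx, int ny, int nz) {
  return i >= 0 && j >= 0 && k >= 0 && i < nx && j < ny && k < nz;
}

// ---------------------------------------------------------------------------
// Connected-component labelling of a binary mask (6- or 26-connectivity).
// Components are labelled 1..n in order of their lexicographically first
// (column-major) seed voxel; callers reorder by size if needed.
// [[Rcpp::export]]
IntegerVector cc_label_cpp(IntegerVector mask, IntegerVector dims, int connectivity) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector out(n, 0);

  std::vector<int> di, dj, dk;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1) continue;
        di.push_back(a); dj.push_back(b); dk.push_back(c);
      }
  int noff = (int)di.size();

  std::vector<R_xlen_t> stack;
  int lab = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (mask[s] == 0 || out[s] != 0) continue;
    ++lab;
    out[s] = lab;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int ci = (int)(cur % nx);
      int cj = (int)((cur / nx) % ny);
      int ck = (int)(cur / ((R_xlen_t)nx * ny));
      for (int o = 0; o < noff; ++o) {
        int ti = ci + di[o], tj = cj + dj[o], tk = ck + dk[o];
        if (!inside(ti, tj, tk, nx, ny, nz)) continue;
        R_xlen_t t = idx3(ti, tj, tk, nx, ny);
        if (mask[t] != 0 && out[t] == 0) {
          out[t] = lab;
          stack.push_back(t);
        }
      }
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// Settlement: place a particle at pos if VOID, otherwise uniformly among VOID
// voxels in expanding Chebyshev shells up to max_radius.  Returns 1-based
// position or blocked flag.  Uses R's RNG.
static bool settle_one(const std::vector<int>& lab, int nx, int ny, int nz,
                       int ci, int cj, int ck, int max_radius,
                       int& si, int& sj, int& sk) {
  if (lab[idx3(ci, cj, ck, nx, ny)] == 0) { si = ci; sj = cj; sk = ck; return true; }
  std::vector<int> vi, vj, vk;
  for (int r = 1; r <= max_radius; ++r) {
    vi.clear(); vj.clear(); vk.clear();
    for (int a = -r; a <= r; ++a)
      for (int b = -r; b <= r; ++b)
        for (int c = -r; c <= r; ++c) {
          if (std::max(std::abs(a), std::max(std::abs(b), std::abs(c))) != r) continue;
          int ti = ci + a, tj = cj + b, tk = ck + c;
          if (!inside(ti, tj, tk, nx, ny, nz)) continue;
          if (lab[idx3(ti, tj, tk, nx, ny)] == 0) { vi.push_back(ti); vj.push_back(tj); vk.push_back(tk); }
        }
    if (!vi.empty()) {
      int pick = (int)std::floor(unif_rand() * vi.size());
      if (pick >= (int)vi.size()) pick = (int)vi.size() - 1;
      si = vi[pick]; sj = vj[pick]; sk = vk[pick];
      return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List settle_cpp(IntegerVector labels, IntegerVector dims, IntegerVector pos0, int max_radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> lab(labels.begin(), labels.end());
  int si, sj, sk;
  bool ok = settle_one(lab, nx, ny, nz, pos0[0], pos0[1], pos0[2], max_radius, si, sj, sk);
  if (!ok) return List::create(_["blocked"] = true);
  return List::create(_["blocked"] = false,
                      _["pos"] = IntegerVector::create(si + 1, sj + 1, sk + 1));
}

// ---------------------------------------------------------------------------
// One biased step: weight the offsets whose immediate neighbour is VOID by
// their class probabilities, draw one, advance up to `jump` voxels along it
// through VOID only (no tunnelling through bone or settled cement).
static bool step_one(const std::vector<int>& lab, int nx, int ny, int nz,
                     const std::vector<int>& di, const std::vector<int>& dj,
                     const std::vector<int>& dk, const std::vector<double>& probs,
                     int jump, int& ci, int& cj, int& ck, int& sel_out) {
  int noff = (int)di.size();
  double tot = 0.0;
  std::vector<double> w(noff);
  for (int o = 0; o < noff; ++o) {
    int ti = ci + di[o], tj = cj + dj[o], tk = ck + dk[o];
    if (inside(ti, tj, tk, nx, ny, nz) && lab[idx3(ti, tj, tk, nx, ny)] == 0) {
      w[o] = probs[o]; tot += w[o];
    } else w[o] = 0.0;
  }
  if (tot <= 0.0) return false;  // jammed: no admissible offset
  double u = unif_rand() * tot, acc = 0.0;
  int sel = -1;
  for (int o = 0; o < noff; ++o) {
    if (w[o] <= 0.0) continue;
    acc += w[o];
    sel = o;
    if (u <= acc) break;
  }
  for (int m = 0; m < jump; ++m) {
    int ti = ci + di[sel], tj = cj + dj[sel], tk = ck + dk[sel];
    if (!inside(ti, tj, tk, nx, ny, nz) || lab[idx3(ti, tj, tk, nx, ny)] != 0) break;
    ci = ti; cj = tj; ck = tk;
  }
  sel_out = sel;
  return true;
}

// [[Rcpp::export]]
List sample_step_cpp(IntegerVector labels, IntegerVector dims, IntegerMatrix offs,
                     NumericVector probs, IntegerVector pos0, int jump) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> lab(labels.begin(), labels.end());
  int noff = offs.nrow();
  std::vector<int> di(noff), dj(noff), dk(noff);
  std::vector<double> pr(probs.begin(), probs.end());
  for (int o = 0; o < noff; ++o) { di[o] = offs(o, 0); dj[o] = offs(o, 1); dk[o] = offs(o, 2); }
  int ci = pos0[0], cj = pos0[1], ck = pos0[2], sel = -1;
  bool moved = step_one(lab, nx, ny, nz, di, dj, dk, pr, jump, ci, cj, ck, sel);
  return List::create(_["blocked"] = !moved,
                      _["pos"] = IntegerVector::create(ci + 1, cj + 1, ck + 1),
                      _["offset_index"] = sel + 1);
}

// Batch of independent single-step draws from the same starting position
// (the grid is not modified): returns the n displacement vectors.
// [[Rcpp::export]]
IntegerMatrix sample_steps_cpp(IntegerVector labels, IntegerVector dims,
                               IntegerMatrix offs, NumericVector probs,
                               IntegerVector pos0, int jump, int n) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> lab(labels.begin(), labels.end());
  int noff = offs.nrow();
  std::vector<int> di(noff), dj(noff), dk(noff);
  std::vector<double> pr(probs.begin(), probs.end());
  for (int o = 0; o < noff; ++o) { di[o] = offs(o, 0); dj[o] = offs(o, 1); dk[o] = offs(o, 2); }
  IntegerMatrix out(n, 3);
  for (int s = 0; s < n; ++s) {
    int ci = pos0[0], cj = pos0[1], ck = pos0[2], sel = -1;
    bool moved = step_one(lab, nx, ny, nz, di, dj, dk, pr, jump, ci, cj, ck, sel);
    out(s, 0) = moved ? ci - pos0[0] : 0;
    out(s, 1) = moved ? cj - pos0[1] : 0;
    out(s, 2) = moved ? ck - pos0[2] : 0;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Full sequential injection.  Particles are released one by one from the entry
// voxel, walk up to max_steps biased steps (early stop when jammed), then
// settle; settled voxels become CEMENT (label 2) and obstruct later particles.
// [[Rcpp::export]]
List walk_injection_cpp(IntegerVector labels, IntegerVector dims, IntegerMatrix offs,
                        NumericVector probs, double n_particles, IntegerVector entry0,
                        int jump, int max_steps, int settle_radius) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<int> lab(labels.begin(), labels.end());
  int noff = offs.nrow();
  std::vector<int> di(noff), dj(noff), dk(noff);
  std::vector<double> pr(probs.begin(), probs.end());
  for (int o = 0; o < noff; ++o) { di[o] = offs(o, 0); dj[o] = offs(o, 1); dk[o] = offs(o, 2); }

  R_xlen_t np = (R_xlen_t)n_particles;
  std::vector<int> set_i, set_j, set_k;
  IntegerVector steps_taken(np);
  R_xlen_t n_blocked = 0;

  for (R_xlen_t p = 0; p < np; ++p) {
    int ci = entry0[0], cj = entry0[1], ck = entry0[2];
    int s = 0, sel = -1;
    for (; s < max_steps; ++s) {
      if (!step_one(lab, nx, ny, nz, di, dj, dk, pr, jump, ci, cj, ck, sel)) break;
    }
    int si, sj, sk;
    if (settle_one(lab, nx, ny, nz, ci, cj, ck, settle_radius, si, sj, sk)) {
      lab[idx3(si, sj, sk, nx, ny)] = 2;
      set_i.push_back(si + 1); set_j.push_back(sj + 1); set_k.push_back(sk + 1);
    } else {
      ++n_blocked;
    }
    steps_taken[p] = s;
  }

  IntegerVector out(lab.begin(), lab.end());
  IntegerMatrix pos((int)set_i.size(), 3);
  for (int q = 0; q < (int)set_i.size(); ++q) {
    pos(q, 0) = set_i[q]; pos(q, 1) = set_j[q]; pos(q, 2) = set_k[q];
  }
  return List::create(_["labels"] = out, _["settled"] = pos,
                      _["n_blocked"] = (double)n_blocked,
                      _["steps_taken"] = steps_taken);
}

// ---------------------------------------------------------------------------
// Isosurface area by marching tetrahedra on a scalar field sampled at lattice
// points spaced h apart.  Each cell is split into 6 tetrahedra sharing the
// main diagonal; interface polygons are built with linear interpolation along
// edges.  Table-free: the four tetrahedron cases are enumerated directly.
static inline void interp_pt(const double* A, const double* B, double fa, double fb,
                             double level, double* out) {
  double t = (level - fa) / (fb - fa);
  for (int d = 0; d < 3; ++d) out[d] = A[d] + t * (B[d] - A[d]);
}

static inline double tri_area(const double* a, const double* b, const double* c) {
  double u[3], v[3], w[3];
  for (int d = 0; d < 3; ++d) { u[d] = b[d] - a[d]; v[d] = c[d] - a[d]; }
  w[0] = u[1] * v[2] - u[2] * v[1];
  w[1] = u[2] * v[0] - u[0] * v[2];
  w[2] = u[0] * v[1] - u[1] * v[0];
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

// [[Rcpp::export]]
double mt_area_cpp(NumericVector field, IntegerVector dims, double level, double h) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  // cube corner offsets (standard ordering)
  static const int co[8][3] = {
    {0,0,0},{1,0,0},{1,1,0},{0,1,0},{0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  // 6 tetrahedra around the main diagonal c0-c6
  static const int tets[6][4] = {
    {0,1,2,6},{0,2,3,6},{0,3,7,6},{0,7,4,6},{0,4,5,6},{0,5,1,6}};
  double area = 0.0;
  double P[8][3], F[8];
  for (int k = 0; k < nz - 1; ++k)
    for (int j = 0; j < ny - 1; ++j)
      for (int i = 0; i < nx - 1; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + co[c][0], cj = j + co[c][1], ck = k + co[c][2];
          F[c] = field[idx3(ci, cj, ck, nx, ny)];
          P[c][0] = ci * h; P[c][1] = cj * h; P[c][2] = ck * h;
          if (F[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int in[4], nin = 0, out[4], nout = 0;
          for (int v = 0; v < 4; ++v) {
            if (F[tv[v]] > level) in[nin++] = tv[v]; else out[nout++] = tv[v];
          }
          if (nin == 0 || nin == 4) continue;
          double p1[3], p2[3], p3[3], p4[3];
          if (nin == 1 || nin == 3) {
            int apex = (nin == 1) ? in[0] : out[0];
            const int* others = (nin == 1) ? out : in;
            interp_pt(P[apex], P[others[0]], F[apex], F[others[0]], level, p1);
            interp_pt(P[apex], P[others[1]], F[apex], F[others[1]], level, p2);
            interp_pt(P[apex], P[others[2]], F[apex], F[others[2]], level, p3);
            area += tri_area(p1, p2, p3);
          } else {  // 2 in, 2 out: quad on edges AC, AD, BD, BC (cyclic)
            int A = in[0], B = in[1], C = out[0], D = out[1];
            interp_pt(P[A], P[C], F[A], F[C], level, p1);
            interp_pt(P[A], P[D], F[A], F[D], level, p2);
            interp_pt(P[B], P[D], F[B], F[D], level, p3);
            interp_pt(P[B], P[C], F[B], F[C], level, p4);
            area += tri_area(p1, p2, p3) + tri_area(p1, p3, p4);
          }
        }
      }
  return area;
}

// ---------------------------------------------------------------------------
// Element-by-element operations for the voxel FE solver.  edofT is 24 x nel
// (0-based global dof indices, one contiguous column per element), escale the
// per-element stiffness scale (E * voxel_size relative to the unit element
// matrix Ke).
// [[Rcpp::export]]
NumericVector ebe_matvec_cpp(IntegerMatrix edofT, NumericVector escale,
                             NumericMatrix Ke, NumericVector x, int ndof) {
  NumericVector y(ndof);
  int nel = edofT.ncol();
  double ke[576];
  for (int a = 0; a < 24; ++a)
    for (int b = 0; b < 24; ++b) ke[a * 24 + b] = Ke(a, b);
  const int* ed = INTEGER(edofT);  // column-major: element-contiguous
  const double* xp = REAL(x);
  double* yp = REAL(y);
  double xe[24], ye[24];
  for (int e = 0; e < nel; ++e) {
    const int* dofs = &ed[(size_t)e * 24];
    const double s = escale[e];
    for (int a = 0; a < 24; ++a) xe[a] = xp[dofs[a]];
    for (int a = 0; a < 24; ++a) ye[a] = 0.0;
    // broadcast form vectorizes without FP reassociation (Ke is symmetric,
    // so the column walk reuses the row-major buffer)
    for (int b = 0; b < 24; ++b) {
      const double xb = xe[b];
      const double* col = &ke[b * 24];
      for (int a = 0; a < 24; ++a) ye[a] += col[a] * xb;
    }
    for (int a = 0; a < 24; ++a) yp[dofs[a]] += s * ye[a];
  }
  return y;
}

// [[Rcpp::export]]
NumericVector ebe_diag_cpp(IntegerMatrix edofT, NumericVector escale,
                           NumericMatrix Ke, int ndof) {
  NumericVector d(ndof);
  int nel = edofT.ncol();
  for (int e = 0; e < nel; ++e) {
    double s = escale[e];
    for (int a = 0; a < 24; ++a) d[edofT(a, e)] += s * Ke(a, a);
  }
  return d;
}

// Fused damped-Jacobi sweep: e += minv * (r - K e), with Ae as caller-owned
// scratch.  minv is zero at constrained/inactive dofs, which keeps e zero
// there.  Mutates e in place (caller guarantees e is not shared).
// [[Rcpp::export]]
void mg_sweep_cpp(IntegerMatrix edofT, NumericVector escale, NumericMatrix Ke,
                  NumericVector r, NumericVector minv, NumericVector e,
                  NumericVector Ae) {
  int nel = edofT.ncol();
  R_xlen_t ndof = e.size();
  double ke[576];
  for (int a = 0; a < 24; ++a)
    for (int b = 0; b < 24; ++b) ke[a * 24 + b] = Ke(a, b);
  const int* ed = INTEGER(edofT);
  const double* ep = REAL(e);
  double* ap = REAL(Ae);
  std::fill(ap, ap + ndof, 0.0);
  double xe[24], ye[24];
  for (int el = 0; el < nel; ++el) {
    const int* dofs = &ed[(size_t)el * 24];
    const double s = escale[el];
    for (int a = 0; a < 24; ++a) xe[a] = ep[dofs[a]];
    for (int a = 0; a < 24; ++a) ye[a] = 0.0;
    for (int b = 0; b < 24; ++b) {
      const double xb = xe[b];
      const double* col = &ke[b * 24];
      for (int a = 0; a < 24; ++a) ye[a] += col[a] * xb;
    }
    for (int a = 0; a < 24; ++a) ap[dofs[a]] += s * ye[a];
  }
  double* ew = REAL(e);
  const double* rp = REAL(r);
  const double* mp = REAL(minv);
  for (R_xlen_t i = 0; i < ndof; ++i) ew[i] += mp[i] * (rp[i] - ap[i]);
}

// Residual rr = r - K e, zeroed wherever minv is zero (constrained dofs).
// [[Rcpp::export]]
NumericVector mg_residual_cpp(IntegerMatrix edofT, NumericVector escale,
                              NumericMatrix Ke, NumericVector r,
                              NumericVector e, NumericVector minv) {
  R_xlen_t ndof = e.size();
  NumericVector rr(ndof);
  int nel = edofT.ncol();
  double ke[576];
  for (int a = 0; a < 24; ++a)
    for (int b = 0; b < 24; ++b) ke[a * 24 + b] = Ke(a, b);
  const int* ed = INTEGER(edofT);
  const double* ep = REAL(e);
  double* op = REAL(rr);
  double xe[24], ye[24];
  for (int el = 0; el < nel; ++el) {
    const int* dofs = &ed[(size_t)el * 24];
    const double s = escale[el];
    for (int a = 0; a < 24; ++a) xe[a] = ep[dofs[a]];
    for (int a = 0; a < 24; ++a) ye[a] = 0.0;
    for (int b = 0; b < 24; ++b) {
      const double xb = xe[b];
      const double* col = &ke[b * 24];
      for (int a = 0; a < 24; ++a) ye[a] += col[a] * xb;
    }
    for (int a = 0; a < 24; ++a) op[dofs[a]] += s * ye[a];
  }
  const double* rp = REAL(r);
  const double* mp = REAL(minv);
  for (R_xlen_t i = 0; i < ndof; ++i)
    op[i] = (mp[i] > 0.0) ? (rp[i] - op[i]) : 0.0;
  return rr;
}

// ---------------------------------------------------------------------------
// Lattice transfer operators for the geometric multigrid preconditioner.
// Node grids: fn / cn node counts per axis (fine / coarse); vectors hold the
// three displacement components interleaved (dof = 3 * node + comp).
// Fine node coordinate i maps to coarse coordinate i / 2: even i takes its
// coarse node with weight 1, odd i averages the two flanking coarse nodes.
static inline void axis_weights(int i, int cn, int* c0, int* c1, double* w0) {
  if (i % 2 == 0) { *c0 = i / 2; *c1 = -1; *w0 = 1.0; }
  else { *c0 = (i - 1) / 2; *c1 = (i + 1) / 2 < cn ? (i + 1) / 2 : -1; *w0 = 0.5; }
}

// [[Rcpp::export]]
NumericVector mg_prolong_cpp(NumericVector xc, IntegerVector cn, IntegerVector fn) {
  int fnx = fn[0], fny = fn[1], fnz = fn[2];
  int cnx = cn[0], cny = cn[1], cnz = cn[2];
  NumericVector xf(3 * (R_xlen_t)fnx * fny * fnz);
  const double* cp = REAL(xc);
  double* fp = REAL(xf);
  for (int k = 0; k < fnz; ++k) {
    int k0, k1; double wk;
    axis_weights(k, cnz, &k0, &k1, &wk);
    for (int j = 0; j < fny; ++j) {
      int j0, j1; double wj;
      axis_weights(j, cny, &j0, &j1, &wj);
      for (int i = 0; i < fnx; ++i) {
        int i0, i1; double wi;
        axis_weights(i, cnx, &i0, &i1, &wi);
        double acc[3] = {0.0, 0.0, 0.0};
        for (int kk = 0; kk < 2; ++kk) {
          int ck = kk == 0 ? k0 : k1; if (ck < 0) continue;
          for (int jj = 0; jj < 2; ++jj) {
            int cj = jj == 0 ? j0 : j1; if (cj < 0) continue;
            for (int ii = 0; ii < 2; ++ii) {
              int ci = ii == 0 ? i0 : i1; if (ci < 0) continue;
              double w = (ii == 0 ? wi : 1 - wi) * (jj == 0 ? wj : 1 - wj) *
                         (kk == 0 ? wk : 1 - wk);
              if (w == 0.0) continue;
              R_xlen_t cnode = (R_xlen_t)ci + (R_xlen_t)cnx * (cj + (R_xlen_t)cny * ck);
              acc[0] += w * cp[3 * cnode];
              acc[1] += w * cp[3 * cnode + 1];
              acc[2] += w * cp[3 * cnode + 2];
            }
          }
        }
        R_xlen_t fnode = (R_xlen_t)i + (R_xlen_t)fnx * (j + (R_xlen_t)fny * k);
        fp[3 * fnode] = acc[0];
        fp[3 * fnode + 1] = acc[1];
        fp[3 * fnode + 2] = acc[2];
      }
    }
  }
  return xf;
}

// [[Rcpp::export]]
NumericVector mg_restrict_cpp(NumericVector xf, IntegerVector fn, IntegerVector cn) {
  int fnx = fn[0], fny = fn[1], fnz = fn[2];
  int cnx = cn[0], cny = cn[1], cnz = cn[2];
  NumericVector xc(3 * (R_xlen_t)cnx * cny * cnz);
  const double* fp = REAL(xf);
  double* cp = REAL(xc);
  for (int k = 0; k < fnz; ++k) {
    int k0, k1; double wk;
    axis_weights(k, cnz, &k0, &k1, &wk);
    for (int j = 0; j < fny; ++j) {
      int j0, j1; double wj;
      axis_weights(j, cny, &j0, &j1, &wj);
      for (int i = 0; i < fnx; ++i) {
        int i0, i1; double wi;
        axis_weights(i, cnx, &i0, &i1, &wi);
        R_xlen_t fnode = (R_xlen_t)i + (R_xlen_t)fnx * (j + (R_xlen_t)fny * k);
        double v0 = fp[3 * fnode], v1 = fp[3 * fnode + 1], v2 = fp[3 * fnode + 2];
        if (v0 == 0.0 && v1 == 0.0 && v2 == 0.0) continue;
        for (int kk = 0; kk < 2; ++kk) {
          int ck = kk == 0 ? k0 : k1; if (ck < 0) continue;
          for (int jj = 0; jj < 2; ++jj) {
            int cj = jj == 0 ? j0 : j1; if (cj < 0) continue;
            for (int ii = 0; ii < 2; ++ii) {
              int ci = ii == 0 ? i0 : i1; if (ci < 0) continue;
              double w = (ii == 0 ? wi : 1 - wi) * (jj == 0 ? wj : 1 - wj) *
                         (kk == 0 ? wk : 1 - wk);
              if (w == 0.0) continue;
              R_xlen_t cnode = (R_xlen_t)ci + (R_xlen_t)cnx * (cj + (R_xlen_t)cny * ck);
              cp[3 * cnode] += w * v0;
              cp[3 * cnode + 1] += w * v1;
              cp[3 * cnode + 2] += w * v2;
            }
          }
        }
      }
    }
  }
  return xc;
}
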