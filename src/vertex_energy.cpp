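#include <Rcpp.h>
using namespace Rcpp;

// Mechanical energy of the 3D vertex model and its exact gradient.
//
// The tissue is a fixed-topology polygonal complex: per cell one apical and
// one basal polygon (paired, equal length) plus lateral quads, periodic in
// x and y. All faces are fan-triangulated about their centroid; the same
// triangulation is used for surface areas and for the divergence-theorem
// cell volumes so that the volume-penalty gradient is exactly consistent.
//
// Index tables are built once per mesh on the R side (0-based here):
//  * area incidences: one row per (face, vertex-in-cycle) with a frozen
//    integer periodic image shift, plus the row of the next cycle vertex;
//  * volume incidences: one row per (cell, vertex) with cell-consistent
//    shifts; centroids (apical face, basal face, one per lateral quad) are
//    defined by membership lists; oriented triangles reference a virtual
//    point array [incidences, centroids];
//  * junctional edges and basal anchor springs are flat vectors.
//
// Periodic image shifts are frozen at build time: topology never changes and
// cells are much smaller than the half-box, so W is smooth in the positions.

static inline void cross3(const double* u, const double* v, double* out) {
  out[0] = u[1] * v[2] - u[2] * v[1];
  out[1] = u[2] * v[0] - u[0] * v[2];
  out[2] = u[0] * v[1] - u[1] * v[0];
}

// [[Rcpp::export]]
List vm_energy_grad(NumericMatrix P, NumericVector box,
                    IntegerVector a_v, NumericVector a_sx, NumericVector a_sy,
                    IntegerVector a_face, IntegerVector a_next,
                    IntegerVector face_cnt, NumericVector face_w,
                    IntegerVector e_v1, IntegerVector e_v2,
                    NumericVector e_sx, NumericVector e_sy, NumericVector e_w,
                    IntegerVector v_v, NumericVector v_sx, NumericVector v_sy,
                    IntegerVector cen_mem_c, IntegerVector cen_mem_p,
                    IntegerVector cen_cnt,
                    IntegerVector tri_p0, IntegerVector tri_p1,
                    IntegerVector tri_p2, IntegerVector tri_cell,
                    NumericVector cell_V0, double KV,
                    IntegerVector s_v, NumericMatrix s_anchor,
                    NumericVector s_k,
                    bool want_grad, double smooth_eps) {
  const int nv = P.nrow();
  const double Lx = box[0], Ly = box[1];
  const int m = a_v.size();
  const int nf = face_cnt.size();
  const int mv = v_v.size();
  const int nc = cen_cnt.size();
  const int nt = tri_p0.size();
  const int ncell = cell_V0.size();

  NumericMatrix G(nv, 3);
  double E_surf = 0.0, E_edge = 0.0, E_spring = 0.0, E_vol = 0.0;

  // ---- unwrapped positions for area incidences -------------------------
  std::vector<double> U(3 * m);
  for (int r = 0; r < m; ++r) {
    const int v = a_v[r];
    U[3 * r]     = P(v, 0) + a_sx[r] * Lx;
    U[3 * r + 1] = P(v, 1) + a_sy[r] * Ly;
    U[3 * r + 2] = P(v, 2);
  }

  // face centroids
  std::vector<double> C(3 * nf, 0.0);
  for (int r = 0; r < m; ++r) {
    const int f = a_face[r];
    C[3 * f] += U[3 * r]; C[3 * f + 1] += U[3 * r + 1]; C[3 * f + 2] += U[3 * r + 2];
  }
  for (int f = 0; f < nf; ++f) {
    const double inv = 1.0 / face_cnt[f];
    C[3 * f] *= inv; C[3 * f + 1] *= inv; C[3 * f + 2] *= inv;
  }

  // surface tension: fan triangles (centroid, v_r, v_next)
  std::vector<double> Cg(3 * nf, 0.0);  // gradient wrt centroids
  NumericVector face_area(nf);
  for (int r = 0; r < m; ++r) {
    const int f = a_face[r];
    const int r2 = a_next[r];
    double u[3], v[3], n[3];
    for (int d = 0; d < 3; ++d) {
      u[d] = U[3 * r + d] - C[3 * f + d];
      v[d] = U[3 * r2 + d] - C[3 * f + d];
    }
    cross3(u, v, n);
    // smooth regularization: |n| -> sqrt(|n|^2 + eps^2) keeps the energy
    // differentiable when a fan triangle degenerates (e.g. a collapsing
    // junction during deep folding); for healthy triangles the correction
    // is O(eps^2 / area), far below every tolerance used.
    const double nn = std::sqrt(n[0] * n[0] + n[1] * n[1] + n[2] * n[2] +
                                smooth_eps * smooth_eps);
    const double A = 0.5 * nn;
    face_area[f] += A;
    const double w = face_w[f];
    E_surf += w * A;
    if (want_grad) {
      double nh[3] = { n[0] / nn, n[1] / nn, n[2] / nn };
      double ga[3], gb[3];
      cross3(v, nh, ga);            // dA/d(u endpoint) = 0.5 (v x n_hat)
      cross3(nh, u, gb);            // dA/d(v endpoint) = 0.5 (n_hat x u)
      const int va = a_v[r], vb = a_v[r2];
      for (int d = 0; d < 3; ++d) {
        const double gad = 0.5 * w * ga[d], gbd = 0.5 * w * gb[d];
        G(va, d) += gad;
        G(vb, d) += gbd;
        Cg[3 * f + d] -= gad + gbd; // centroid gets minus the sum
      }
    }
  }
  if (want_grad) {
    for (int r = 0; r < m; ++r) {
      const int f = a_face[r];
      const double inv = 1.0 / face_cnt[f];
      const int v = a_v[r];
      for (int d = 0; d < 3; ++d) G(v, d) += Cg[3 * f + d] * inv;
    }
  }

  // ---- junctional edge tensions ---------------------------------------
  for (int e = 0; e < e_v1.size(); ++e) {
    const int i = e_v1[e], j = e_v2[e];
    double dvec[3] = { P(j, 0) + e_sx[e] * Lx - P(i, 0),
                       P(j, 1) + e_sy[e] * Ly - P(i, 1),
                       P(j, 2) - P(i, 2) };
    const double len = std::sqrt(dvec[0] * dvec[0] + dvec[1] * dvec[1] +
                                 dvec[2] * dvec[2] +
                                 smooth_eps * smooth_eps);
    const double w = e_w[e];
    E_edge += w * len;
    if (want_grad) {
      for (int d = 0; d < 3; ++d) {
        const double g = w * dvec[d] / len;
        G(j, d) += g;
        G(i, d) -= g;
      }
    }
  }

  // ---- cell volumes (divergence theorem over oriented fan triangles) ---
  std::vector<double> VU(3 * (mv + nc), 0.0);
  for (int r = 0; r < mv; ++r) {
    const int v = v_v[r];
    VU[3 * r]     = P(v, 0) + v_sx[r] * Lx;
    VU[3 * r + 1] = P(v, 1) + v_sy[r] * Ly;
    VU[3 * r + 2] = P(v, 2);
  }
  for (int k = 0; k < cen_mem_c.size(); ++k) {
    const int c = cen_mem_c[k], p = cen_mem_p[k];
    for (int d = 0; d < 3; ++d) VU[3 * (mv + c) + d] += VU[3 * p + d];
  }
  for (int c = 0; c < nc; ++c) {
    const double inv = 1.0 / cen_cnt[c];
    for (int d = 0; d < 3; ++d) VU[3 * (mv + c) + d] *= inv;
  }

  NumericVector vol(ncell);
  for (int t = 0; t < nt; ++t) {
    const double* p0 = &VU[3 * tri_p0[t]];
    const double* p1 = &VU[3 * tri_p1[t]];
    const double* p2 = &VU[3 * tri_p2[t]];
    double cr[3];
    cross3(p1, p2, cr);
    vol[tri_cell[t]] += (p0[0] * cr[0] + p0[1] * cr[1] + p0[2] * cr[2]) / 6.0;
  }
  NumericVector q(ncell);
  for (int c = 0; c < ncell; ++c) {
    const double dv = vol[c] - cell_V0[c];
    E_vol += 0.5 * KV * dv * dv / cell_V0[c];
    q[c] = KV * dv / cell_V0[c];
  }
  if (want_grad) {
    std::vector<double> PG(3 * (mv + nc), 0.0);
    for (int t = 0; t < nt; ++t) {
      const double qc = q[tri_cell[t]] / 6.0;
      if (qc == 0.0) continue;
      const double* p0 = &VU[3 * tri_p0[t]];
      const double* p1 = &VU[3 * tri_p1[t]];
      const double* p2 = &VU[3 * tri_p2[t]];
      double c12[3], c20[3], c01[3];
      cross3(p1, p2, c12);
      cross3(p2, p0, c20);
      cross3(p0, p1, c01);
      for (int d = 0; d < 3; ++d) {
        PG[3 * tri_p0[t] + d] += qc * c12[d];
        PG[3 * tri_p1[t] + d] += qc * c20[d];
        PG[3 * tri_p2[t] + d] += qc * c01[d];
      }
    }
    // centroid gradients flow back to their member incidence rows
    for (int k = 0; k < cen_mem_c.size(); ++k) {
      const int c = cen_mem_c[k], p = cen_mem_p[k];
      const double inv = 1.0 / cen_cnt[c];
      for (int d = 0; d < 3; ++d) PG[3 * p + d] += PG[3 * (mv + c) + d] * inv;
    }
    for (int r = 0; r < mv; ++r) {
      const int v = v_v[r];
      for (int d = 0; d < 3; ++d) G(v, d) += PG[3 * r + d];
    }
  }

  // ---- basal anchor springs --------------------------------------------
  for (int s = 0; s < s_v.size(); ++s) {
    const int v = s_v[s];
    double dx[3] = { P(v, 0) - s_anchor(s, 0),
                     P(v, 1) - s_anchor(s, 1),
                     P(v, 2) - s_anchor(s, 2) };
    E_spring += 0.5 * s_k[s] * (dx[0] * dx[0] + dx[1] * dx[1] + dx[2] * dx[2]);
    if (want_grad) {
      for (int d = 0; d < 3; ++d) G(v, d) += s_k[s] * dx[d];
    }
  }

  const double E = E_surf + E_edge + E_spring + E_vol;
  return List::create(
    _["energy"] = E,
    _["parts"] = NumericVector::create(_["surface"] = E_surf,
                                       _["edge"] = E_edge,
                                       _["spring"] = E_spring,
                                       _["volume_penalty"] = E_vol),
    _["grad"] = G,
    _["volumes"] = vol,
    _["face_areas"] = face_area);
}
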