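#' Mechanical parameters of the vertex model
#'
#' All quantities are nondimensional: the unit of tension is the reference
#' apical surface tension and the unit of length is the cube root of the cell
#' target volume. The defaults encode the calibrated baseline: basal surface
#' and junctional edge tensions four times the apical ones, and normalized
#' edge tension and ECM spring stiffness equal to 1
#' (`Lambda_a / (T_a V0^(1/3)) = 1`, `k V0^(1/3) / T_a = 1`).
#'
#' @param T_a,T_b Apical and basal surface tension per cell.
#' @param T_l Lateral surface tension per cell. `NULL` means "calibrate at
#'   build time" so that the requested flat aspect ratio is the in-plane
#'   stress-free state (see [build_hex_tissue()]).
#' @param Lambda_a,Lambda_b Apical and basal junctional edge tension per cell.
#' @param k ECM spring constant per basal vertex (springs anchor each basal
#'   vertex to its position in the relaxed pre-fold state; full 3D
#'   displacement is penalised).
#' @param K_V Stiffness of the quadratic cell-volume penalty
#'   `K_V/2 (V - V0)^2 / V0`. The default keeps relative volume violations
#'   below 0.1% in all shipped scenarios.
#' @param smooth_eps Numerical regularization scale: edge lengths and
#'   (twice-) triangle areas enter the energy as `sqrt(x^2 + smooth_eps^2)`
#'   so the energy stays differentiable when a junction collapses to zero
#'   length inside a deep fold (topology is fixed; no neighbour exchanges).
#'   For healthy elements the correction is `O(smooth_eps^2 / x)`, orders of
#'   magnitude below every tolerance used.
#' @return An object of class `mech_params`.
#' @export
mech_params <- function(T_a = 1, T_b = 4, T_l = NULL,
                        Lambda_a = 1, Lambda_b = 4,
                        k = 1, K_V = 2e4, smooth_eps = 5e-4) {
  vals <- c(T_a = T_a, T_b = T_b, Lambda_a = Lambda_a, Lambda_b = Lambda_b,
            k = k, T_l = T_l %||% NA_real_)
  if (any(vals < 0, na.rm = TRUE)) {
    abort("tensions and spring constants must be >= 0", class = "epifold_input_error")
  }
  if (K_V <= 0) abort("K_V must be > 0", class = "epifold_input_error")
  structure(list(T_a = T_a, T_b = T_b, T_l = T_l,
                 Lambda_a = Lambda_a, Lambda_b = Lambda_b,
                 k = k, K_V = K_V, smooth_eps = smooth_eps,
                 region_scale = list(), ablated = list()),
            class = "mech_params")
}

#' @export
print.mech_params <- function(x, ...) {
  cat("<mech_params> T_a=", x$T_a, " T_b=", x$T_b,
      " T_l=", if (is.null(x$T_l)) "(calibrated at build)" else signif(x$T_l, 4),
      " Lambda_a=", x$Lambda_a, " Lambda_b=", x$Lambda_b,
      " k=", x$k, " K_V=", x$K_V, "\n", sep = "")
  for (rg in names(x$region_scale)) {
    sc <- x$region_scale[[rg]]
    cat("  region ", rg, ": ", paste(names(sc), signif(sc, 4), sep = " x ",
                                     collapse = ", "), "\n", sep = "")
  }
  if (length(x$ablated)) {
    ab <- vapply(x$ablated, function(a) paste0(a$kind, "#", a$id), character(1))
    cat("  ablated:", paste(ab, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Scale parameters of one cell region
#'
#' Multiplies the named parameters of every cell in a region by a factor;
#' this is how tension ramps act on the pre-fold stripe. Scalings compose by
#' replacement, not accumulation: the factor is always relative to the
#' baseline parameter.
#'
#' @param params A [mech_params()] object.
#' @param region Region label (e.g. `"pre_fold"`).
#' @param ... Named scale factors among `T_a`, `T_b`, `T_l`, `Lambda_a`,
#'   `Lambda_b`.
#' @return Updated `mech_params`.
#' @export
scale_region_params <- function(params, region, ...) {
  sc <- c(...)
  ok <- c("T_a", "T_b", "T_l", "Lambda_a", "Lambda_b")
  if (length(sc) == 0 || is.null(names(sc)) || !all(names(sc) %in% ok)) {
    abort(paste("scale factors must be named among:", paste(ok, collapse = ", ")),
          class = "epifold_input_error")
  }
  if (any(sc < 0)) abort("scalings must keep tensions >= 0", class = "epifold_input_error")
  old <- params$region_scale[[region]] %||% numeric(0)
  params$region_scale[[region]] <- c(sc, old[setdiff(names(old), names(sc))])
  params
}

# per-cell value of one parameter, after region scaling
cell_param <- function(mesh, params, name) {
  base <- params[[name]]
  if (is.null(base)) {
    abort(paste0(name, " is unset; calibrate or supply it explicitly"),
          class = "epifold_input_error")
  }
  out <- rep(base, nrow(mesh$cells))
  for (rg in names(params$region_scale)) {
    f <- params$region_scale[[rg]][name]
    if (!is.na(f)) out[mesh$cells$region == rg] <- base * f
  }
  out
}

# Resolve params into per-element weights for the kernel. Shared lateral
# faces and junctional edges take the MEAN of the two adjacent cells'
# parameters and are counted once; ablated elements get weight zero.
compile_weights <- function(mesh, params) {
  ncell <- nrow(mesh$cells)
  Ta <- cell_param(mesh, params, "T_a")
  Tb <- cell_param(mesh, params, "T_b")
  Tl <- cell_param(mesh, params, "T_l")
  La <- cell_param(mesh, params, "Lambda_a")
  Lb <- cell_param(mesh, params, "Lambda_b")

  pair_mean <- function(vals, c1, c2) {
    ifelse(is.na(c2), vals[c1], (vals[c1] + vals[ifelse(is.na(c2), c1, c2)]) / 2)
  }
  lf <- mesh$lateral_faces
  lat_w <- pair_mean(Tl, lf$cell1, lf$cell2)
  ae <- mesh$apical_edges
  ea_w <- pair_mean(La, ae$cell1, ae$cell2)
  eb_w <- pair_mean(Lb, ae$cell1, ae$cell2)

  for (ab in params$ablated) {
    switch(ab$kind,
      apical_edge = { ea_w[ab$id] <- 0 },
      basal_edge = { eb_w[ab$id] <- 0 },
      lateral_face = { lat_w[ab$id] <- 0 },
      abort(paste("unknown ablated element kind:", ab$kind),
            class = "epifold_input_error")
    )
  }

  n <- mesh$n_apical
  if (!is.null(mesh$anchors) && params$k > 0) {
    s_v <- n + seq_len(n) - 1L
    s_anchor <- mesh$anchors
    s_k <- rep(params$k, n)
  } else {
    s_v <- integer(0)
    s_anchor <- matrix(0, 0, 3)
    s_k <- numeric(0)
  }

  list(face_w = c(Ta, Tb, lat_w),
       e_v1 = c(ae$v1, ae$v1 + n) - 1L,
       e_v2 = c(ae$v2, ae$v2 + n) - 1L,
       e_sx = c(ae$sx, ae$sx), e_sy = c(ae$sy, ae$sy),
       e_w = c(ea_w, eb_w),
       s_v = s_v, s_anchor = s_anchor, s_k = s_k,
       cell_V0 = mesh$cells$target_volume, KV = params$K_V,
       smooth_eps = params$smooth_eps %||% 5e-4)
}

# single entry point to the C++ kernel
eval_mesh <- function(mesh, params = NULL, positions = NULL, want_grad = TRUE,
                      weights = NULL) {
  cmp <- mesh$compiled
  w <- weights %||% compile_weights(mesh, params %||% mech_params(T_l = 0))
  P <- positions %||% mesh$positions
  vm_energy_grad(P, mesh$box,
                 cmp$a_v, cmp$a_sx, cmp$a_sy, cmp$a_face, cmp$a_next,
                 cmp$face_cnt, w$face_w,
                 w$e_v1, w$e_v2, w$e_sx, w$e_sy, w$e_w,
                 cmp$v_v, cmp$v_sx, cmp$v_sy,
                 cmp$cen_mem_c, cmp$cen_mem_p, cmp$cen_cnt,
                 cmp$tri_p0, cmp$tri_p1, cmp$tri_p2, cmp$tri_cell,
                 w$cell_V0, w$KV,
                 w$s_v, w$s_anchor, w$s_k,
                 want_grad, w$smooth_eps)
}

# geometry-only state (volumes, face areas) independent of tensions
mesh_state <- function(mesh) {
  eval_mesh(mesh, params = mech_params(T_a = 0, T_b = 0, T_l = 0, Lambda_a = 0,
                                       Lambda_b = 0, k = 0, K_V = 1),
            want_grad = FALSE)
}

#' Total mechanical energy of a tissue
#'
#' The work function summed over the mesh:
#' apical/basal/lateral surface tension times face area, apical/basal edge
#' tension times junction length (shared elements take the mean of the
#' adjacent cells' parameters and are counted once), ECM springs
#' `k/2 |x_b - X_ref|^2` on basal vertices, and the volume penalty
#' `K_V/2 (V_c - V0_c)^2 / V0_c`.
#'
#' @param mesh A `tissue_mesh`.
#' @param params A [mech_params()] object.
#' @param parts If `TRUE`, return the named energy decomposition instead of
#'   the total.
#' @return Scalar energy, or a named vector of the four energy terms.
#' @export
total_energy <- function(mesh, params, parts = FALSE) {
  res <- eval_mesh(mesh, params, want_grad = FALSE)
  if (parts) res$parts else res$energy
}

#' Forces on all vertices
#'
#' Analytic negative gradient of [total_energy()] with respect to every
#' vertex position.
#'
#' @inheritParams total_energy
#' @return A `2n x 3` matrix (apical rows first, then basal partners).
#' @export
vertex_forces <- function(mesh, params) {
  -eval_mesh(mesh, params, want_grad = TRUE)$grad
}

#' Current cell volumes
#'
#' @param mesh A `tissue_mesh`.
#' @return Numeric vector, one signed volume per cell.
#' @export
cell_volumes <- function(mesh) {
  as.numeric(mesh_state(mesh)$volumes)
}

# largest per-vertex force norm, used as the convergence criterion
max_force_norm <- function(grad) {
  sqrt(max(rowSums(grad^2)))
}
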