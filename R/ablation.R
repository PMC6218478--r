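#' Ablate a junctional edge or lateral face
#'
#' In-silico analog of a pulsed-laser cut: the tension parameter of the
#' targeted element (the mean edge tension of an apical or basal junction,
#' or the mean surface tension of a lateral face) is set to zero; all other
#' parameters are untouched and the geometry is unchanged at the instant of
#' ablation.
#'
#' @param params [mech_params()] describing the pre-ablation tissue.
#' @param element_id Integer id of the element in the mesh's
#'   `apical_edges`/`basal_edges`/`lateral_faces` table.
#' @param kind `"apical_edge"`, `"basal_edge"` or `"lateral_face"`.
#' @param mesh Optional mesh used to validate that the element exists.
#' @return The post-ablation `mech_params`.
#' @export
ablate_element <- function(params, element_id,
                           kind = c("apical_edge", "basal_edge", "lateral_face"),
                           mesh = NULL) {
  kind <- match.arg(kind)
  if (!is.null(mesh)) {
    nmax <- switch(kind, apical_edge = nrow(mesh$apical_edges),
                   basal_edge = nrow(mesh$basal_edges),
                   lateral_face = nrow(mesh$lateral_faces))
    if (element_id < 1 || element_id > nmax) {
      abort(paste0("unknown ", kind, " id ", element_id), class = "epifold_input_error")
    }
  }
  params$ablated <- c(params$ablated,
                      list(list(kind = kind, id = as.integer(element_id))))
  params
}

#' Pick the junctional edge (or lateral face) nearest the box centre
#'
#' Convenience selector for an interior element to ablate.
#'
#' @param mesh A `tissue_mesh`.
#' @param layer `"apical"` or `"basal"` for edges; `"lateral"` for a face.
#' @return Integer element id.
#' @export
central_element <- function(mesh, layer = c("apical", "basal", "lateral")) {
  layer <- match.arg(layer)
  ae <- mesh$apical_edges
  ref <- mesh$reference
  mx <- (ref[ae$v1, 1] + ref[ae$v2, 1] + ae$sx * mesh$box[1]) / 2
  my <- (ref[ae$v1, 2] + ref[ae$v2, 2] + ae$sy * mesh$box[2]) / 2
  d2 <- (mx - mesh$box[1] / 2)^2 + (my - mesh$box[2] / 2)^2
  which.min(d2)  # same id indexes apical edge, basal edge and lateral face
}

#' Overdamped recoil after ablation
#'
#' Integrates the overdamped dynamics `dx/dt = F / drag` with an explicit
#' Euler scheme, starting from the pre-ablation equilibrium and using the
#' post-ablation parameters, and records the two points bounding the ablated
#' element at regular frame times. For an edge these are its two vertices;
#' for a lateral face they are the midpoints of the face's apical and basal
#' edges, so the separation is the apical-basal extent of the released
#' interface. The first recorded frame (t = 0) is the pre-ablation state.
#'
#' Frame times are in reduced time units; recoil velocities are only ever
#' compared as ratios between elements sampled with the same frame interval,
#' so the drag coefficient and the time unit cancel.
#'
#' @param mesh The pre-ablation equilibrated `tissue_mesh`.
#' @param params_after Post-ablation parameters from [ablate_element()]
#'   (must contain at least one ablated element for a real cut; unchanged
#'   parameters give a flat track with zero recoil).
#' @param element_id,kind The tracked element (defaults to the last entry of
#'   `params_after$ablated`).
#' @param drag Uniform isotropic per-vertex drag coefficient.
#' @param dt Euler time step; must resolve the stiff volume penalty (a
#'   halving test is the standard check).
#' @param frame_dt Interval between recorded frames.
#' @param n_frames Number of post-ablation frames.
#' @return A `recoil_track` tibble: `t`, `x1`,`y1`,`z1`, `x2`,`y2`,`z2`,
#'   `separation`.
#' @export
simulate_recoil <- function(mesh, params_after, element_id = NULL, kind = NULL,
                            drag = 1, dt = 1e-5, frame_dt = 0.01, n_frames = 6) {
  if (is.null(element_id) || is.null(kind)) {
    nab <- length(params_after$ablated)
    if (nab == 0 && (is.null(element_id) || is.null(kind))) {
      abort("give element_id and kind, or params_after with an ablated element",
            class = "epifold_input_error")
    }
    last <- params_after$ablated[[nab]]
    element_id <- element_id %||% last$id
    kind <- kind %||% last$kind
  }
  steps_per_frame <- max(1L, round(frame_dt / dt))
  dt <- frame_dt / steps_per_frame
  w <- compile_weights(mesh, params_after)
  nv <- nrow(mesh$positions)
  P <- mesh$positions

  n <- mesh$n_apical
  ae <- mesh$apical_edges
  track_points <- function(P) {
    if (kind == "lateral_face") {
      lf <- mesh$lateral_faces[element_id, ]
      sh <- c(lf$sx * mesh$box[1], lf$sy * mesh$box[2], 0)
      p1 <- (P[lf$a1, ] + P[lf$a2, ] + sh) / 2        # apical edge midpoint
      p2 <- (P[lf$a1 + n, ] + P[lf$a2 + n, ] + sh) / 2 # basal edge midpoint
    } else {
      ed <- ae[element_id, ]
      off <- if (kind == "basal_edge") n else 0L
      p1 <- P[ed$v1 + off, ]
      p2 <- P[ed$v2 + off, ] + c(ed$sx * mesh$box[1], ed$sy * mesh$box[2], 0)
    }
    list(p1 = p1, p2 = p2)
  }

  rows <- list()
  record <- function(tt, P) {
    tp <- track_points(P)
    rows[[length(rows) + 1L]] <<- tibble(
      t = tt, x1 = tp$p1[1], y1 = tp$p1[2], z1 = tp$p1[3],
      x2 = tp$p2[1], y2 = tp$p2[2], z2 = tp$p2[3],
      separation = sqrt(sum((tp$p2 - tp$p1)^2)))
  }
  record(0, P)
  res <- eval_mesh(mesh, positions = P, weights = w)
  E_prev <- res$energy
  for (f in seq_len(n_frames)) {
    for (s in seq_len(steps_per_frame)) {
      P <- P - (dt / drag) * res$grad
      res <- eval_mesh(mesh, positions = P, weights = w)
    }
    if (res$energy > E_prev + 1e-8 * (abs(E_prev) + 1)) {
      abort(sprintf("unstable recoil integration (energy increased at frame %d); use a smaller dt", f),
            class = "epifold_instability_error")
    }
    E_prev <- res$energy
    record(f * frame_dt, P)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "kind") <- kind
  attr(out, "element_id") <- element_id
  attr(out, "frame_dt") <- frame_dt
  class(out) <- c("recoil_track", class(out))
  out
}

#' First-frame recoil velocity
#'
#' The average recoil velocity `v0`: the increase in separation of the two
#' tracked points between the last pre-ablation sample (t <= 0) and the
#' first post-ablation sample, divided by the sampling window. This is the
#' standard relative measure of the tension that the ablated element carried
#' before the cut.
#'
#' @param track A `recoil_track` (simulated or from tracked experimental
#'   vertices via [read_track_csv()]).
#' @param window Averaging window in the track's time units; defaults to the
#'   interval between the pre- and first post-ablation samples (0.25 s in
#'   apical/basal edge experiments, 1 s for lateral interfaces).
#' @return Scalar `v0` (separation units per time unit).
#' @export
recoil_velocity <- function(track, window = NULL) {
  if (!all(c("t", "separation") %in% names(track))) {
    if (all(c("x1", "x2") %in% names(track))) {
      track$separation <- sqrt((track$x2 - track$x1)^2 + (track$y2 - track$y1)^2 +
                                 (track$z2 - track$z1)^2)
    } else {
      abort("track needs columns t and separation (or the vertex coordinates)",
            class = "epifold_schema_error")
    }
  }
  pre <- track[track$t <= 0, ]
  post <- track[track$t > 0, ]
  if (nrow(pre) == 0) {
    abort("track has no pre-ablation sample (t <= 0)", class = "epifold_input_error")
  }
  if (nrow(post) == 0) {
    abort("track has no post-ablation sample", class = "epifold_input_error")
  }
  pre <- pre[which.max(pre$t), ]
  post <- post[which.min(post$t), ]
  window <- window %||% (post$t - pre$t)
  (post$separation - pre$separation) / window
}

#' Recoil velocity of one ablated element in one call
#'
#' Convenience wrapper: ablates the element, simulates the overdamped
#' recoil from the given equilibrium and returns the first-frame estimate.
#'
#' @inheritParams simulate_recoil
#' @param params Pre-ablation [mech_params()].
#' @param ... Passed to [simulate_recoil()].
#' @return Scalar `v0`.
#' @export
ablation_v0 <- function(mesh, params, element_id, kind, ...) {
  p_after <- ablate_element(params, element_id, kind, mesh = mesh)
  recoil_velocity(simulate_recoil(mesh, p_after, element_id, kind, ...))
}
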