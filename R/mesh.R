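#' Construct a columnar tissue mesh
#'
#' A `tissue_mesh` represents a laterally periodic columnar epithelium with
#' fixed topology: paired apical and basal vertices (one basal partner per
#' apical vertex), one apical and one basal polygonal face per cell in the
#' same cyclic order, lateral quadrilaterals shared by at most two cells, and
#' apical/basal junctional edges. The z axis points from basal to apical in
#' the flat reference state; apical indentation during folding is a negative
#' z displacement of apical fold vertices.
#'
#' Periodic images are handled by integer lattice shifts frozen at
#' construction from the reference positions; this is valid because the
#' topology never changes and cells are far smaller than the half-box.
#'
#' @param apical,basal Numeric `n x 3` matrices of paired vertex positions
#'   (row `i` of `basal` is the basal partner of row `i` of `apical`).
#' @param cycles List of integer vectors: the apical vertex cycle of each
#'   cell (indices into the rows of `apical`). Cycles are re-oriented so that
#'   every cell volume is positive.
#' @param box Lateral periodic box `c(Lx, Ly)`; z is aperiodic. Use a box
#'   much larger than the tissue for effectively non-periodic test meshes.
#' @param region Character vector of per-cell region labels
#'   (`"neighbor"`/`"pre_fold"`), recycled.
#' @param rows,cols Optional integer per-cell lattice coordinates (used for
#'   stripe assignment and cross-section labelling).
#' @param anchors Optional `n x 3` matrix of ECM anchor points for the basal
#'   vertices; `NULL` means springs are not yet attached.
#' @param target_volume Per-cell preferred volume (recycled).
#' @param reference Optional `2n x 3` reference positions used to freeze the
#'   periodic image shifts (defaults to the given positions).
#' @return An object of class `tissue_mesh`.
#' @export
tissue_mesh <- function(apical, basal, cycles, box,
                        region = "neighbor", rows = NA_integer_,
                        cols = NA_integer_, anchors = NULL,
                        target_volume = 1, reference = NULL) {
  apical <- as.matrix(apical)
  basal <- as.matrix(basal)
  n <- nrow(apical)
  if (nrow(basal) != n) {
    abort("every apical vertex needs exactly one basal partner", class = "epifold_input_error")
  }
  stopifnot_finite(apical, "apical positions")
  stopifnot_finite(basal, "basal positions")
  if (length(box) != 2L || any(box <= 0)) {
    abort("box must be positive lateral dimensions c(Lx, Ly)", class = "epifold_input_error")
  }
  positions <- unname(rbind(apical, basal))
  reference <- if (is.null(reference)) positions else as.matrix(reference)
  nc <- length(cycles)
  cycles <- lapply(cycles, as.integer)
  for (cyc in cycles) {
    if (length(cyc) < 3L) abort("cell cycles need >= 3 vertices", class = "epifold_input_error")
    if (anyDuplicated(cyc)) abort("degenerate cell cycle: repeated vertex", class = "epifold_input_error")
    if (any(cyc < 1L | cyc > n)) abort("cycle indexes a missing vertex", class = "epifold_input_error")
  }

  # orient all cycles so volumes are positive (apical CCW seen from apical side)
  for (ci in seq_len(nc)) {
    v <- cell_volume(cycles[[ci]], cycles[[ci]] + n, reference, box)
    if (v < 0) cycles[[ci]] <- rev(cycles[[ci]])
  }

  cells <- tibble(
    cell_id = seq_len(nc),
    region = rep_len(as.character(region), nc),
    row = rep_len(as.integer(rows), nc),
    col = rep_len(as.integer(cols), nc),
    target_volume = rep_len(target_volume, nc)
  )

  mesh <- structure(
    list(positions = positions, n_apical = n, cells = cells, cycles = cycles,
         box = as.numeric(box), anchors = anchors, reference = reference,
         meta = list()),
    class = "tissue_mesh"
  )
  mesh <- build_topology(mesh)
  mesh$compiled <- compile_mesh(mesh)
  mesh
}

# derive edge and lateral-face tables from the cell cycles
build_topology <- function(mesh) {
  n <- mesh$n_apical
  ref <- mesh$reference
  box <- mesh$box
  # directed apical edges per cell
  ecell <- list()
  for (ci in seq_along(mesh$cycles)) {
    cyc <- mesh$cycles[[ci]]
    nxt <- c(cyc[-1], cyc[1])
    for (t in seq_along(cyc)) {
      key <- paste(min(cyc[t], nxt[t]), max(cyc[t], nxt[t]), sep = "-")
      ecell[[key]] <- c(ecell[[key]], ci)
    }
  }
  keys <- names(ecell)
  vs <- do.call(rbind, strsplit(keys, "-"))
  v1 <- as.integer(vs[, 1]); v2 <- as.integer(vs[, 2])
  ncells <- lengths(ecell)
  if (any(ncells > 2L)) {
    abort("an edge borders more than two cells", class = "epifold_input_error")
  }
  cell1 <- vapply(ecell, `[`, integer(1), 1L)
  cell2 <- vapply(ecell, function(x) if (length(x) > 1L) x[2] else NA_integer_, integer(1))
  sx <- -round((ref[v2, 1] - ref[v1, 1]) / box[1])
  sy <- -round((ref[v2, 2] - ref[v1, 2]) / box[2])
  ne <- length(v1)
  mesh$apical_edges <- tibble(edge_id = seq_len(ne), v1 = v1, v2 = v2,
                              sx = sx, sy = sy, cell1 = unname(cell1),
                              cell2 = unname(cell2))
  mesh$basal_edges <- tibble(edge_id = seq_len(ne), v1 = v1 + n, v2 = v2 + n,
                             sx = sx, sy = sy, cell1 = unname(cell1),
                             cell2 = unname(cell2))
  # one lateral quad per apical edge: (a1, a2, b2, b1)
  mesh$lateral_faces <- tibble(face_id = seq_len(ne), edge_id = seq_len(ne),
                               a1 = v1, a2 = v2, cell1 = unname(cell1),
                               cell2 = unname(cell2), sx = sx, sy = sy)
  mesh
}

# Build the flat 0-based index tables consumed by the C++ energy kernel.
# Faces are ordered: apical (per cell), basal (per cell), lateral (per edge).
compile_mesh <- function(mesh) {
  n <- mesh$n_apical
  ref <- mesh$reference
  box <- mesh$box
  ncell <- nrow(mesh$cells)

  a_v <- integer(0); a_sx <- numeric(0); a_sy <- numeric(0)
  a_face <- integer(0); a_next <- integer(0); face_cnt <- integer(0)
  add_face <- function(ids, shifts) {
    k <- length(ids)
    base <- length(a_v)
    a_v <<- c(a_v, ids - 1L)
    a_sx <<- c(a_sx, shifts[, 1]); a_sy <<- c(a_sy, shifts[, 2])
    a_face <<- c(a_face, rep.int(length(face_cnt), k))
    a_next <<- c(a_next, base + c(2:k, 1L) - 1L)
    face_cnt <<- c(face_cnt, k)
  }
  ap_shifts <- vector("list", ncell)
  for (ci in seq_len(ncell)) {
    cyc <- mesh$cycles[[ci]]
    s <- seq_unwrap_shifts(cyc, ref, box)
    ap_shifts[[ci]] <- s
    add_face(cyc, s)
  }
  for (ci in seq_len(ncell)) {
    cyc <- mesh$cycles[[ci]] + n
    add_face(cyc, ap_shifts[[ci]])   # basal partners share the apical shifts
  }
  lf <- mesh$lateral_faces
  for (fi in seq_len(nrow(lf))) {
    ids <- c(lf$a1[fi], lf$a2[fi], lf$a2[fi] + n, lf$a1[fi] + n)
    s <- rbind(c(0, 0), c(lf$sx[fi], lf$sy[fi]), c(lf$sx[fi], lf$sy[fi]), c(0, 0))
    add_face(ids, s)
  }

  # volume tables: cell-consistent incidences, centroids, oriented triangles
  v_v <- integer(0); v_sx <- numeric(0); v_sy <- numeric(0)
  cen_mem_c <- integer(0); cen_mem_p <- integer(0); cen_cnt <- integer(0)
  tri <- list()
  n_cen <- 0L
  for (ci in seq_len(ncell)) {
    cyc <- mesh$cycles[[ci]]
    k <- length(cyc)
    s <- ap_shifts[[ci]]
    baseA <- length(v_v)
    v_v <- c(v_v, cyc - 1L, cyc + n - 1L)
    v_sx <- c(v_sx, s[, 1], s[, 1]); v_sy <- c(v_sy, s[, 2], s[, 2])
    Arow <- baseA + seq_len(k) - 1L
    Brow <- baseA + k + seq_len(k) - 1L
    ca <- n_cen; cb <- n_cen + 1L; cq <- n_cen + 1L + seq_len(k)
    cen_mem_c <- c(cen_mem_c, rep.int(ca, k), rep.int(cb, k))
    cen_mem_p <- c(cen_mem_p, Arow, Brow)
    cen_cnt <- c(cen_cnt, k, k)
    nxt <- c(2:k, 1L)
    for (i in seq_len(k)) {
      j <- nxt[i]
      cen_mem_c <- c(cen_mem_c, rep.int(cq[i], 4))
      cen_mem_p <- c(cen_mem_p, c(Arow[i], Brow[i], Brow[j], Arow[j]))
      cen_cnt <- c(cen_cnt, 4L)
    }
    n_cen <- n_cen + 2L + k
    # triangle point ids: incidences first, centroids appended after all mv
    tri[[ci]] <- list(ca = ca, cb = cb, cq = cq, A = Arow, B = Brow,
                      k = k, cell = ci - 1L)
  }
  mv <- length(v_v)
  tri_p0 <- integer(0); tri_p1 <- integer(0); tri_p2 <- integer(0)
  tri_cell <- integer(0)
  for (ci in seq_len(ncell)) {
    tt <- tri[[ci]]
    k <- tt$k; nxt <- c(2:k, 1L)
    A <- tt$A; B <- tt$B
    caid <- mv + tt$ca; cbid <- mv + tt$cb; cqid <- mv + tt$cq
    for (i in seq_len(k)) {
      j <- nxt[i]
      tri_p0 <- c(tri_p0, caid, cbid, cqid[i], cqid[i], cqid[i], cqid[i])
      tri_p1 <- c(tri_p1, A[i], B[j], A[i], B[i], B[j], A[j])
      tri_p2 <- c(tri_p2, A[j], B[i], B[i], B[j], A[j], A[i])
      tri_cell <- c(tri_cell, rep.int(tt$cell, 6))
    }
  }

  list(a_v = a_v, a_sx = a_sx, a_sy = a_sy, a_face = a_face, a_next = a_next,
       face_cnt = face_cnt,
       v_v = v_v, v_sx = v_sx, v_sy = v_sy,
       cen_mem_c = cen_mem_c, cen_mem_p = cen_mem_p, cen_cnt = cen_cnt,
       tri_p0 = tri_p0, tri_p1 = tri_p1, tri_p2 = tri_p2, tri_cell = tri_cell,
       n_face_apical = ncell, n_face_basal = ncell,
       n_face_lateral = nrow(mesh$lateral_faces))
}

#' @export
print.tissue_mesh <- function(x, ...) {
  cat("<tissue_mesh> ", nrow(x$cells), " cells, ", x$n_apical,
      " apical vertices, box ", signif(x$box[1], 4), " x ", signif(x$box[2], 4),
      "\n", sep = "")
  if (!is.null(x$meta$aspect_ratio)) {
    cat("  built aspect ratio ", signif(x$meta$aspect_ratio, 4), "\n", sep = "")
  }
  reg <- table(x$cells$region)
  cat("  regions:", paste(names(reg), reg, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Per-cell table of a tissue mesh
#'
#' @param x A `tissue_mesh`.
#' @param ... Unused.
#' @return A tibble with one row per cell: region labels, lattice
#'   coordinates, target and current volume, apical/basal face area and cell
#'   height.
#' @method tidy tissue_mesh
#' @export
tidy.tissue_mesh <- function(x, ...) {
  st <- mesh_state(x)
  hts <- cell_heights(x)
  dplyr::mutate(x$cells, volume = st$volumes,
                apical_area = st$face_areas[seq_len(nrow(x$cells))],
                basal_area = st$face_areas[nrow(x$cells) + seq_len(nrow(x$cells))],
                height = hts)
}

# mean apical-basal distance of each cell's paired vertices
cell_heights <- function(mesh) {
  n <- mesh$n_apical
  vapply(mesh$cycles, function(cyc) {
    mean(sqrt(rowSums((mesh$positions[cyc, , drop = FALSE] -
                         mesh$positions[cyc + n, , drop = FALSE])^2)))
  }, numeric(1))
}

#' Measured aspect ratio (height over equivalent diameter) of a mesh
#'
#' The columnar aspect ratio is the mean cell height divided by the diameter
#' of the circle with the mean apical face area.
#'
#' @param mesh A `tissue_mesh`.
#' @return Scalar aspect ratio.
#' @export
aspect_ratio <- function(mesh) {
  st <- mesh_state(mesh)
  a_mean <- mean(st$face_areas[seq_len(nrow(mesh$cells))])
  mean(cell_heights(mesh)) / (2 * sqrt(a_mean / pi))
}

# unwrapped 3D polygon coordinates of one cell (apical and basal cycles)
cell_polygons <- function(mesh, cell_id) {
  cyc <- mesh$cycles[[cell_id]]
  n <- mesh$n_apical
  s <- seq_unwrap_shifts(cyc, mesh$reference, mesh$box)
  shift <- cbind(s[, 1] * mesh$box[1], s[, 2] * mesh$box[2], 0)
  list(apical = mesh$positions[cyc, , drop = FALSE] + shift,
       basal = mesh$positions[cyc + n, , drop = FALSE] + shift)
}
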