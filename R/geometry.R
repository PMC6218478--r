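#' Area of a (possibly non-planar) polygonal face
#'
#' Computes the area of a face given as an ordered vertex cycle by fan
#' triangulation about the cycle centroid. This is the same triangulation the
#' mechanical energy uses for every surface-tension term, so areas reported
#' here are exactly the areas the forces act on. For planar polygons the
#' result equals the usual polygon area.
#'
#' @param cycle Integer vector of vertex indices (length >= 3) into the rows
#'   of `positions`, in cyclic order.
#' @param positions Numeric matrix with one 3D position per row.
#' @param box Optional lateral periodic box `c(Lx, Ly)`. When given, the cycle
#'   is sequentially unwrapped by the minimum-image convention before the area
#'   is computed; the z direction is aperiodic.
#' @return Non-negative scalar area.
#' @examples
#' sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' face_area(1:4, sq)
#' @export
face_area <- function(cycle, positions, box = NULL) {
  if (length(cycle) < 3L) {
    abort("face cycle must have at least 3 vertices", class = "epifold_input_error")
  }
  if (anyDuplicated(cycle)) {
    abort("degenerate face cycle: repeated vertex", class = "epifold_input_error")
  }
  pts <- seq_unwrap(positions[cycle, , drop = FALSE], box)
  stopifnot_finite(pts, "face vertex positions")
  ctr <- colMeans(pts)
  nxt <- c(2:nrow(pts), 1L)
  U <- sweep(pts, 2, ctr)
  V <- U[nxt, , drop = FALSE]
  sum(sqrt(rowSums(rows_cross(U, V)^2))) / 2
}

#' Length of a cell edge under the minimum-image convention
#'
#' @param edge Integer vector `c(i, j)` indexing two rows of `positions`.
#' @param positions Numeric matrix of 3D positions.
#' @param box Optional lateral periodic box `c(Lx, Ly)`.
#' @return Euclidean length (zero for coincident vertices).
#' @export
edge_length <- function(edge, positions, box = NULL) {
  if (length(edge) != 2L) {
    abort("an edge has exactly two vertices", class = "epifold_input_error")
  }
  d <- positions[edge[2], ] - positions[edge[1], ]
  if (!is.null(box)) {
    d[1] <- min_image(d[1], box[1])
    d[2] <- min_image(d[2], box[2])
  }
  sqrt(sum(d^2))
}

#' Volume of a prismatic cell
#'
#' Signed volume of the closed surface formed by the apical face, the basal
#' face and the lateral quadrilaterals connecting paired apical/basal
#' vertices, computed with the divergence theorem over the centroid fan
#' triangulation (the same discretisation used by the mechanical energy).
#' Positive for cells whose apical cycle is counter-clockwise seen from the
#' apical side.
#'
#' @param apical_cycle,basal_cycle Integer vertex cycles of equal length
#'   (>= 3) in the same cyclic order (vertex `i` of the two cycles are the
#'   apico-basal partners).
#' @inheritParams face_area
#' @return Signed scalar volume.
#' @examples
#' cube <- rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1),
#'               c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
#' cell_volume(1:4, 5:8, cube)
#' @export
cell_volume <- function(apical_cycle, basal_cycle, positions, box = NULL) {
  k <- length(apical_cycle)
  if (k < 3L || length(basal_cycle) != k) {
    abort("open cell surface: apical and basal cycles must pair up (equal length >= 3)",
          class = "epifold_input_error")
  }
  if (anyDuplicated(apical_cycle) || anyDuplicated(basal_cycle)) {
    abort("degenerate cell: repeated vertex in a face cycle", class = "epifold_input_error")
  }
  A <- seq_unwrap(positions[apical_cycle, , drop = FALSE], box)
  B <- positions[basal_cycle, , drop = FALSE]
  if (!is.null(box)) {
    # unwrap each basal vertex to the image nearest its apical partner
    for (i in seq_len(k)) {
      for (d in 1:2) B[i, d] <- A[i, d] + min_image(B[i, d] - A[i, d], box[d])
    }
  }
  stopifnot_finite(rbind(A, B), "cell vertex positions")

  vol <- 0
  tet <- function(p0, p1, p2) sum(p0 * vec_cross(p1, p2)) / 6
  nxt <- c(2:k, 1L)
  ca <- colMeans(A)
  cb <- colMeans(B)
  for (i in seq_len(k)) {
    j <- nxt[i]
    # apical face, outward towards the apical side
    vol <- vol + tet(ca, A[i, ], A[j, ])
    # basal face, outward away from the cell
    vol <- vol + tet(cb, B[j, ], B[i, ])
    # lateral quad (a_i, b_i, b_j, a_j), fan about its centroid
    cq <- (A[i, ] + B[i, ] + B[j, ] + A[j, ]) / 4
    vol <- vol + tet(cq, A[i, ], B[i, ]) + tet(cq, B[i, ], B[j, ]) +
      tet(cq, B[j, ], A[j, ]) + tet(cq, A[j, ], A[i, ])
  }
  vol
}
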