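#' Build a periodic hexagonal columnar tissue at mechanical equilibrium
#'
#' Prepares a regular packing of identical hexagonal-prism cells with unit
#' target volume on a laterally periodic box, sized so that the columnar
#' aspect ratio (height over equivalent-area diameter) equals
#' `aspect_ratio` exactly. If `params$T_l` is `NULL`, the lateral surface
#' tension is calibrated so that this packing is also the in-plane
#' stress-free state of the uniform tissue (the derivative of the
#' regular-prism energy with respect to the cell radius vanishes); the
#' requested aspect ratio is then a true mechanical property, not just a
#' box choice. The packing is relaxed at zero perturbation and the ECM
#' anchors are set to the relaxed basal vertex positions, so springs are at
#' rest in the reference state.
#'
#' @param nx,ny Number of cell columns and rows (`>= 4`; `ny` must be even
#'   for the offset rows to tile periodically).
#' @param aspect_ratio Target cell height / diameter (wing-disc columnar
#'   cells prior to folding are tall; default 5).
#' @param params Baseline [mech_params()].
#' @param relax Relax the built packing (default). Only disable for tests
#'   that need the unrelaxed reference lattice.
#' @param tol Force tolerance passed to [relax_tissue()].
#' @return A relaxed `tissue_mesh` with calibrated `T_l` stored in
#'   `mesh$meta$params`.
#' @export
build_hex_tissue <- function(nx, ny, aspect_ratio = 5, params = mech_params(),
                             relax = TRUE, tol = 1e-6) {
  if (nx < 4 || ny < 4) {
    abort("nx and ny must both be >= 4", class = "epifold_input_error")
  }
  if (ny %% 2 != 0) {
    abort("ny must be even: odd row counts are incompatible with the periodic hexagonal tiling",
          class = "epifold_input_error")
  }
  if (aspect_ratio <= 0) abort("aspect_ratio must be > 0", class = "epifold_input_error")

  V0 <- 1
  # height from aspect = h / (2 sqrt(A/pi)) with A h = V0
  h0 <- (2 * aspect_ratio / sqrt(pi))^(2 / 3) * V0^(1 / 3)
  A0 <- V0 / h0
  a <- sqrt(2 * A0 / (3 * sqrt(3)))   # hexagon side
  w <- sqrt(3) * a                    # width across flats (pointy-top)
  Lx <- nx * w
  Ly <- ny * 1.5 * a

  # pointy-top hexagon vertices, counter-clockwise seen from apical (+z)
  ang <- (30 + 60 * (0:5)) * pi / 180
  hx <- a * cos(ang)
  hy <- a * sin(ang)

  key_of <- function(x, y) paste(round(x * 1e7), round(y * 1e7))
  vid <- new.env(parent = emptyenv())
  vx <- numeric(0); vy <- numeric(0)
  cycles <- vector("list", nx * ny)
  rows <- integer(nx * ny); cols <- integer(nx * ny)
  ci <- 0L
  for (j in 0:(ny - 1)) {
    cy <- 1.5 * a * j
    for (i in 0:(nx - 1)) {
      cx <- w * (i + 0.5 * (j %% 2))
      ci <- ci + 1L
      ids <- integer(6)
      for (t in 1:6) {
        x <- wrap_coord(cx + hx[t], Lx)
        y <- wrap_coord(cy + hy[t], Ly)
        k <- key_of(x, y)
        id <- vid[[k]]
        if (is.null(id)) {
          vx <- c(vx, x); vy <- c(vy, y)
          id <- length(vx)
          assign(k, id, envir = vid)
        }
        ids[t] <- id
      }
      cycles[[ci]] <- ids
      rows[ci] <- j; cols[ci] <- i
    }
  }
  n <- length(vx)
  if (n != 2L * nx * ny) {
    abort("hexagonal tiling produced an unexpected vertex count",
          class = "epifold_internal_error")
  }
  apical <- cbind(vx, vy, rep(h0, n))
  basal <- cbind(vx, vy, rep(0, n))

  if (is.null(params$T_l)) {
    params$T_l <- calibrate_lateral_tension(a, params, V0 = V0)
  }
  mesh <- tissue_mesh(apical, basal, cycles, box = c(Lx, Ly),
                      rows = rows, cols = cols, target_volume = V0)
  mesh$meta <- list(a = a, h0 = h0, nx = nx, ny = ny,
                    aspect_ratio = aspect_ratio, params = params)
  if (relax) {
    mesh <- relax_tissue(mesh, params, tol = tol)
  }
  mesh$anchors <- mesh$positions[mesh$n_apical + seq_len(mesh$n_apical), , drop = FALSE]
  mesh$meta$aspect_ratio_measured <- aspect_ratio(mesh)
  mesh
}

#' Lateral tension that makes a regular packing in-plane stress free
#'
#' For a uniform tissue of regular hexagonal prisms with side `a` and cell
#' volume `V0`, the per-cell energy along the constant-volume regular-prism
#' family is
#' `W(a) = (T_a + T_b) (3 sqrt(3)/2) a^2 + 3 (Lambda_a + Lambda_b) a
#'  + 2 T_l V0 / (sqrt(3) a)`
#' (shared lateral faces and edges counted half per cell). Setting
#' `dW/da = 0` yields the lateral tension under which the packing neither
#' spreads nor contracts in-plane, used to pin the built aspect ratio.
#'
#' @param a Hexagon side length of the packing.
#' @param params [mech_params()] providing the other tensions.
#' @param V0 Cell volume.
#' @return Calibrated scalar `T_l`.
#' @export
calibrate_lateral_tension <- function(a, params, V0 = 1) {
  sqrt(3) * a^2 * (3 * sqrt(3) * (params$T_a + params$T_b) * a +
                     3 * (params$Lambda_a + params$Lambda_b)) / (2 * V0)
}

#' Label a centred stripe of pre-fold cells
#'
#' Marks a contiguous band of cell rows (or columns) as `pre_fold`; tension
#' ramps then act on this stripe while the rest of the tissue keeps the
#' baseline parameters.
#'
#' @param mesh A `tissue_mesh` built by [build_hex_tissue()].
#' @param width Stripe width in cell rows (`1 <= width < ny`).
#' @param axis `"x"` (default): the stripe spans the box along x and is a
#'   band of rows in y — the fold then runs along x. `"y"`: band of columns.
#' @return The mesh with updated region labels.
#' @export
assign_stripe <- function(mesh, width = 2, axis = c("x", "y")) {
  axis <- match.arg(axis)
  idx <- if (axis == "x") mesh$cells$row else mesh$cells$col
  if (any(is.na(idx))) {
    abort("mesh has no lattice coordinates; build it with build_hex_tissue()",
          class = "epifold_input_error")
  }
  nlev <- max(idx) + 1L
  if (width < 1 || width >= nlev) {
    abort(paste0("stripe width must satisfy 1 <= width < ", nlev),
          class = "epifold_input_error")
  }
  start <- floor((nlev - width) / 2)
  sel <- idx >= start & idx < start + width
  mesh$cells$region <- ifelse(sel, "pre_fold", "neighbor")
  mesh$meta$stripe <- list(axis = axis, width = width, rows = start:(start + width - 1L))
  mesh
}

#' Randomly perturb vertex positions
#'
#' Adds independent uniform noise to every coordinate; used to create
#' replicate initial conditions before the zero-magnitude relaxation.
#'
#' @param mesh A `tissue_mesh`.
#' @param amplitude Half-width of the uniform perturbation (length units).
#' @param seed Integer seed; the perturbation is a pure function of it.
#' @return The perturbed mesh.
#' @export
perturb_mesh <- function(mesh, amplitude = 0.01, seed = 1) {
  noise <- withr::with_seed(seed, {
    matrix(runif(length(mesh$positions), -amplitude, amplitude),
           nrow(mesh$positions), 3)
  })
  mesh$positions <- mesh$positions + noise
  mesh
}
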