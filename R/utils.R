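# internal helpers ----------------------------------------------------------

# minimum-image displacement for a lateral (periodic) coordinate
min_image <- function(d, L) d - round(d / L) * L

# wrap coordinates into [0, L); values within 1e-9 of L map to 0
wrap_coord <- function(x, L) {
  y <- x - floor(x / L) * L
  y[y > L - 1e-9] <- 0
  y
}

# sequentially unwrap a cycle of 3D points across periodic x/y boundaries:
# each point is moved to the periodic image closest to its predecessor.
seq_unwrap <- function(pts, box) {
  if (is.null(box)) return(pts)
  k <- nrow(pts)
  if (k < 2L) return(pts)
  for (t in 2:k) {
    for (d in 1:2) {
      pts[t, d] <- pts[t - 1, d] + min_image(pts[t, d] - pts[t - 1, d], box[d])
    }
  }
  pts
}

# lattice shifts (integer multiples of the box) that sequentially unwrap a
# cycle of vertex ids; returns a k x 2 matrix of shifts in box units
seq_unwrap_shifts <- function(ids, ref, box) {
  k <- length(ids)
  s <- matrix(0, k, 2)
  if (is.null(box) || k < 2L) return(s)
  for (t in 2:k) {
    for (d in 1:2) {
      prev <- ref[ids[t - 1], d] + s[t - 1, d] * box[d]
      s[t, d] <- -round((ref[ids[t], d] - prev) / box[d])
    }
  }
  s
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort(paste0(what, " contains non-finite values"), class = "epifold_input_error")
  }
}

vec_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

# row-wise cross product for n x 3 matrices
rows_cross <- function(U, V) {
  cbind(U[, 2] * V[, 3] - U[, 3] * V[, 2],
        U[, 3] * V[, 1] - U[, 1] * V[, 3],
        U[, 1] * V[, 2] - U[, 2] * V[, 1])
}
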