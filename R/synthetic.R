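#' Synthetic wedge-shaped fold cross-section
#'
#' Builds a deterministic piecewise-linear cross-section realising the
#' requested fold geometry exactly: flat neighbouring tissue with apical
#' outline at `z = h_tissue` and basal outline at `z = 0`, and a symmetric
#' wedge of fold-centre cells whose apical chain dips to depth `d_a` with
#' segments of length `l_a` and whose basal chain deviates outward (below
#' the basal plane) by `d_b` with segments of length `l_b`. Feeding the
#' result to [measure_fold_geometry()] recovers the construction parameters
#' exactly in the noise-free case.
#'
#' @param d_a Apical indentation depth (>= 0).
#' @param d_b Basal outward deformation (>= 0 bulges outward; < 0 indents).
#' @param l_a,l_b Apical/basal segment length of each fold-centre cell.
#' @param h_tissue Height of the neighbouring tissue (> 0).
#' @param n_neighbor_cells Neighbour cells per side (>= 1; the innermost one
#'   on each side is labelled `near` when there are at least 3, mirroring
#'   the mesh extractor's exclusion zone).
#' @param n_fold_cells Number of fold-centre cells (>= 1).
#' @param jitter_sd Standard deviation of seeded Gaussian jitter applied to
#'   every tracked vertex coordinate (0 = exact fixture).
#' @param seed Seed for the jitter.
#' @param cell_width In-plane width of neighbour cells (defaults to `l_a`).
#' @return A `cross_section` tibble (same schema as
#'   [extract_cross_section()]).
#' @export
gen_wedge_cross_section <- function(d_a, d_b, l_a, l_b, h_tissue,
                                    n_neighbor_cells = 4, n_fold_cells = 4,
                                    jitter_sd = 0, seed = 1,
                                    cell_width = NULL) {
  if (h_tissue <= 0 || l_a <= 0 || l_b <= 0) {
    abort("h_tissue, l_a and l_b must be > 0", class = "epifold_input_error")
  }
  if (n_neighbor_cells < 1 || n_fold_cells < 1) {
    abort("cell counts must be >= 1", class = "epifold_input_error")
  }
  if (h_tissue - d_a + d_b <= 0) {
    abort("geometrically impossible wedge: fold cells would have non-positive height",
          class = "epifold_input_error")
  }
  w <- cell_width %||% l_a

  # symmetric chain of n segments of length len dipping to depth at centre
  chain <- function(n_seg, len, depth) {
    m <- n_seg %/% 2
    if (m == 0 && abs(depth) > 0) {
      abort("geometrically impossible wedge: a single segment cannot dip",
            class = "epifold_input_error")
    }
    if (m > 0 && len < abs(depth) / m) {
      abort("geometrically impossible wedge: segments shorter than the required drop",
            class = "epifold_input_error")
    }
    dz <- if (m > 0) depth / m else 0
    dy <- if (m > 0) sqrt(len^2 - dz^2) else len
    y <- dy * (0:m)
    z <- -dz * (0:m)
    if (n_seg %% 2 == 1) {  # flat bottom segment
      y <- c(y, y[m + 1] + len)
      z <- c(z, z[m + 1])
    }
    if (m > 0) {           # ascending mirror of the descending part
      y <- c(y, y[length(y)] + dy * seq_len(m))
      z <- c(z, -dz * ((m - 1):0))
    }
    list(y = y, z = z)
  }
  ca <- chain(n_fold_cells, l_a, d_a)
  cb <- chain(n_fold_cells, l_b, d_b)
  # centre both chains on y = 0; apical nodes at z = h_tissue + dip
  ya <- ca$y - max(ca$y) / 2
  za <- h_tissue + ca$z
  yb <- cb$y - max(cb$y) / 2
  zb <- cb$z

  # tracked-vertex node chains: fold chains plus, per side, a columnar
  # neighbour chain; jitter is applied per NODE (a tracked vertex is one
  # noisy measurement shared by the two cells that border it)
  edge <- max(abs(c(ya, yb)))
  nn <- n_neighbor_cells + 1L
  nodes <- list(
    fold_a = cbind(ya, za),
    fold_b = cbind(yb, zb),
    right_a = cbind(edge + w * (0:(nn - 1)), rep(h_tissue, nn)),
    right_b = cbind(edge + w * (0:(nn - 1)), rep(0, nn)),
    left_a = cbind(-edge - w * (0:(nn - 1)), rep(h_tissue, nn)),
    left_b = cbind(-edge - w * (0:(nn - 1)), rep(0, nn)))
  if (jitter_sd > 0) {
    total <- sum(vapply(nodes, nrow, integer(1)))
    noise <- withr::with_seed(seed, {
      matrix(rnorm(2 * total, sd = jitter_sd), total, 2)
    })
    off <- 0L
    for (nm in names(nodes)) {
      k <- nrow(nodes[[nm]])
      nodes[[nm]] <- nodes[[nm]] + noise[off + seq_len(k), , drop = FALSE]
      off <- off + k
    }
  }

  seg_rows <- function(cell_id, label, dist, layer, p0, p1) {
    tibble(cell_id = cell_id, label = label, dist = dist, layer = layer,
           y0 = p0[1], z0 = p0[2], y1 = p1[1], z1 = p1[2],
           length = sqrt(sum((p1 - p0)^2)))
  }
  rows <- list()
  for (i in seq_len(n_fold_cells)) {
    rows[[length(rows) + 1L]] <-
      seg_rows(i, "fold_center", 0, "apical",
               nodes$fold_a[i, ], nodes$fold_a[i + 1, ])
    rows[[length(rows) + 1L]] <-
      seg_rows(i, "fold_center", 0, "basal",
               nodes$fold_b[i, ], nodes$fold_b[i + 1, ])
  }
  next_id <- n_fold_cells
  for (side in c("right", "left")) {
    na <- nodes[[paste0(side, "_a")]]
    nb <- nodes[[paste0(side, "_b")]]
    for (i in seq_len(n_neighbor_cells)) {
      next_id <- next_id + 1L
      lab <- if (n_neighbor_cells >= 3 && i == 1) "near" else "neighbor"
      rows[[length(rows) + 1L]] <-
        seg_rows(next_id, lab, i, "apical", na[i, ], na[i + 1, ])
      rows[[length(rows) + 1L]] <-
        seg_rows(next_id, lab, i, "basal", nb[i, ], nb[i + 1, ])
    }
  }
  sec <- dplyr::bind_rows(rows)
  new_cross_section(dplyr::arrange(sec, .data$layer, .data$y0))
}

#' Synthetic recoil track with known true velocity
#'
#' Two tracked points separating at a constant rate along x, with optional
#' seeded Gaussian positional noise; includes one pre-ablation frame at
#' t = 0. The noise-free track satisfies `recoil_velocity(track) == v_true`
#' exactly.
#'
#' @param v_true True separation rate.
#' @param window Frame interval (> 0), e.g. 0.25 s.
#' @param n_frames Number of post-ablation frames.
#' @param noise_sd Positional noise s.d. per coordinate.
#' @param seed Seed for the noise.
#' @param separation0 Initial separation.
#' @return A `recoil_track` tibble.
#' @export
gen_recoil_track <- function(v_true, window = 0.25, n_frames = 8,
                             noise_sd = 0, seed = 1, separation0 = 1) {
  if (window <= 0) abort("window must be > 0", class = "epifold_input_error")
  tt <- c(0, window * seq_len(n_frames))
  sep <- separation0 + v_true * tt
  tr <- tibble(t = tt,
               x1 = -sep / 2, y1 = 0, z1 = 0,
               x2 = sep / 2, y2 = 0, z2 = 0)
  if (noise_sd > 0) {
    noise <- withr::with_seed(seed, {
      matrix(rnorm(6 * nrow(tr), sd = noise_sd), nrow(tr), 6)
    })
    tr[, c("x1", "y1", "z1", "x2", "y2", "z2")] <-
      tr[, c("x1", "y1", "z1", "x2", "y2", "z2")] + noise
  }
  tr$separation <- sqrt((tr$x2 - tr$x1)^2 + (tr$y2 - tr$y1)^2 + (tr$z2 - tr$z1)^2)
  class(tr) <- c("recoil_track", class(tr))
  tr
}

#' Synthetic coupled intensity/height time series
#'
#' Emulates the pulsatile dynamics of fold cells: the log lateral intensity
#' follows a seeded mean-reverting (Ornstein-Uhlenbeck) fluctuation process,
#' and the log cell height is driven by the delayed, negatively coupled
#' intensity plus independent mean-reverting noise and an optional linear
#' trend:
#' `log h(t) = log h0 - coupling * x(t - delay) + trend * t + eta(t)`,
#' with `x` the centred log-intensity process. The relative height rate is
#' then `-coupling` times the delayed relative intensity rate (plus noise
#' and the constant trend), so the cross-correlation minimum sits at
#' `tau = delay`. Both series are strictly positive by construction and are
#' pure functions of the seed.
#'
#' @param n_cells Number of cells.
#' @param duration Record length (seconds), must be much longer than
#'   `delay`.
#' @param dt_sample Sampling cadence (seconds; 10 s matches lateral-surface
#'   imaging).
#' @param delay Coupling delay in seconds (rounded to the internal grid).
#' @param coupling Dimensionless coupling strength (>= 0; 0 decouples the
#'   two series).
#' @param noise_sd S.d. of the independent height fluctuation process.
#' @param trend Linear trend of log-height per second (negative values give
#'   the slow height decrease of fold cells).
#' @param seed Seed.
#' @param tau_c Correlation time of the pulsatile intensity process
#'   (seconds).
#' @param sigma_a S.d. of the log-intensity fluctuations.
#' @param dt_internal Internal simulation grid (seconds); `dt_sample` and
#'   (approximately) `delay` must be multiples of it.
#' @param a0,h0 Mean intensity (arbitrary units) and mean height (length
#'   units).
#' @return Tibble `cell_id`, `t`, `a_l`, `h`.
#' @export
gen_coupled_timeseries <- function(n_cells = 12, duration = 600,
                                   dt_sample = 10, delay = 22, coupling = 1,
                                   noise_sd = 0.05, trend = 0, seed = 1,
                                   tau_c = 40, sigma_a = 0.15,
                                   dt_internal = 1, a0 = 100, h0 = 30) {
  if (dt_sample <= 0 || dt_internal <= 0) {
    abort("sampling intervals must be > 0", class = "epifold_input_error")
  }
  if (abs(dt_sample / dt_internal - round(dt_sample / dt_internal)) > 1e-9) {
    abort("dt_sample must be a multiple of dt_internal", class = "epifold_input_error")
  }
  if (duration < 4 * delay + 2 * dt_sample) {
    abort("duration must be much longer than the delay", class = "epifold_input_error")
  }
  if (coupling < 0) abort("coupling must be >= 0", class = "epifold_input_error")
  d_steps <- round(delay / dt_internal)
  burn <- 5 * tau_c
  t_fine <- seq(-delay - burn, duration, by = dt_internal)
  n_fine <- length(t_fine)
  phi <- exp(-dt_internal / tau_c)
  sd_step <- sigma_a * sqrt(1 - phi^2)
  sd_eta_step <- noise_sd * sqrt(1 - phi^2)

  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_cells), function(ci) {
      x <- numeric(n_fine)
      eta <- numeric(n_fine)
      x[1] <- rnorm(1, sd = sigma_a)
      eta[1] <- rnorm(1, sd = noise_sd)
      zx <- rnorm(n_fine - 1, sd = sd_step)
      ze <- rnorm(n_fine - 1, sd = sd_eta_step)
      for (i in 2:n_fine) {
        x[i] <- phi * x[i - 1] + zx[i - 1]
        eta[i] <- phi * eta[i - 1] + ze[i - 1]
      }
      keep <- t_fine >= 0 & (round(t_fine / dt_internal) %% round(dt_sample / dt_internal) == 0)
      idx <- which(keep)
      xd <- x[idx - d_steps]          # delayed intensity process
      tibble(cell_id = ci, t = t_fine[idx],
             a_l = a0 * exp(x[idx]),
             h = h0 * exp(-coupling * xd + trend * t_fine[idx] + eta[idx]))
    })
  })
}

#' Synthetic per-cell intensity table
#'
#' Neighbour cells have mean intensity 1 and fold cells mean `contrast`,
#' with multiplicative log-normal noise (mean-corrected so group means equal
#' their targets exactly in expectation).
#'
#' @param n_fold,n_neighbor Cell counts (>= 1).
#' @param contrast Fold/neighbour mean intensity ratio (> 0); ~0.8 mimics a
#'   20% collagen reduction under the fold.
#' @param noise_sd S.d. of the multiplicative (log) noise.
#' @param seed Seed.
#' @return Tibble `cell_id`, `label` (`fold`/`neighbor`), `intensity`.
#' @export
gen_intensity_table <- function(n_fold, n_neighbor, contrast = 0.8,
                                noise_sd = 0.1, seed = 1) {
  if (n_fold < 1 || n_neighbor < 1) {
    abort("cell counts must be >= 1", class = "epifold_input_error")
  }
  if (contrast <= 0) abort("contrast must be > 0", class = "epifold_input_error")
  withr::with_seed(seed, {
    lev <- c(rep(contrast, n_fold), rep(1, n_neighbor))
    tibble(
      cell_id = seq_len(n_fold + n_neighbor),
      label = c(rep("fold", n_fold), rep("neighbor", n_neighbor)),
      intensity = lev * exp(rnorm(n_fold + n_neighbor, sd = noise_sd) - noise_sd^2 / 2))
  })
}
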