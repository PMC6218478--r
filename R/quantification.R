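#' Extract a 2D cross-section through a tissue mesh
#'
#' Intersects a plane of constant x (or y) with every apical and basal cell
#' face and records, per cell, the resulting in-plane segment in
#' (section coordinate, z). Sections are taken perpendicular to the fold:
#' with the default stripe along x, the section plane `x = offset` shows the
#' fold profile across the stripe.
#'
#' Cells are labelled `fold_center` (the pre-fold stripe), `near`
#' (immediately adjacent row on either side of the stripe) or `neighbor`
#' (two or more cell rows away); only `neighbor` cells enter the reference
#' plane fits of [measure_fold_geometry()], mirroring measurements that use
#' cells outside the fold.
#'
#' @param mesh A `tissue_mesh`.
#' @param axis `"x"` (default) or `"y"`: the coordinate held constant on the
#'   section plane; must run along the stripe.
#' @param offset Plane position inside the box. Defaults to a plane through
#'   cell interiors near the box centre.
#' @return A `cross_section`: a tibble with one row per (cell, surface)
#'   segment and columns `cell_id`, `label`, `dist` (cell rows from the
#'   stripe), `layer`, `y0`, `z0`, `y1`, `z1`, `length`.
#' @export
extract_cross_section <- function(mesh, axis = c("x", "y"), offset = NULL) {
  axis <- match.arg(axis)
  d_cut <- if (axis == "x") 1L else 2L
  d_par <- if (axis == "x") 2L else 1L
  L_cut <- mesh$box[d_cut]
  if (is.null(offset)) {
    # default: centre of the box, nudged to a quarter cell width so the
    # plane passes through cell interiors rather than along vertex columns
    wcell <- if (!is.null(mesh$meta$a)) sqrt(3) * mesh$meta$a else L_cut / 8
    offset <- (round(L_cut / 2 / wcell)) * wcell + 0.25 * wcell
  }
  if (offset < 0 || offset >= L_cut) offset <- wrap_coord(offset, L_cut)

  labels <- section_labels(mesh)
  out <- list()
  for (ci in seq_len(nrow(mesh$cells))) {
    poly <- cell_polygons(mesh, ci)
    for (layer in c("apical", "basal")) {
      P <- poly[[layer]]
      # bring the cell image next to the plane
      ctr <- mean(P[, d_cut])
      P[, d_cut] <- P[, d_cut] - round((ctr - offset) / L_cut) * L_cut
      x <- P[, d_cut] - offset
      if (any(abs(x) < 1e-12)) x <- x + 1e-9 * L_cut  # degeneracy nudge
      k <- nrow(P)
      nxt <- c(2:k, 1L)
      crossing <- which(x * x[nxt] < 0)
      if (length(crossing) != 2L) next
      pts <- t(vapply(crossing, function(i) {
        j <- nxt[i]
        t_ <- x[i] / (x[i] - x[j])
        P[i, ] + t_ * (P[j, ] - P[i, ])
      }, numeric(3)))
      yy <- pts[, d_par]; zz <- pts[, 3]
      o <- order(yy)
      out[[length(out) + 1L]] <- tibble(
        cell_id = ci, label = labels$label[ci], dist = labels$dist[ci],
        layer = layer, y0 = yy[o[1]], z0 = zz[o[1]],
        y1 = yy[o[2]], z1 = zz[o[2]],
        length = sqrt(diff(yy)^2 + diff(zz)^2))
    }
  }
  if (length(out) == 0) {
    abort("section plane misses the mesh", class = "epifold_input_error")
  }
  sec <- dplyr::arrange(dplyr::bind_rows(out), .data$layer, .data$y0)
  new_cross_section(sec)
}

new_cross_section <- function(tbl) {
  class(tbl) <- c("cross_section", class(tbl))
  tbl
}

# fold_center / near / neighbor labels from the stripe row distance
section_labels <- function(mesh) {
  region <- mesh$cells$region
  nc <- length(region)
  dist <- rep(NA_real_, nc)
  stripe <- mesh$meta$stripe
  if (!is.null(stripe)) {
    idx <- if (stripe$axis == "x") mesh$cells$row else mesh$cells$col
    nlev <- max(idx) + 1L
    dmin <- rep(Inf, nc)
    for (r in stripe$rows) {
      d <- abs(idx - r)
      d <- pmin(d, nlev - d)  # periodic row distance
      dmin <- pmin(dmin, d)
    }
    dist <- dmin
  } else {
    dist <- ifelse(region == "pre_fold", 0, 2)
  }
  label <- ifelse(region == "pre_fold", "fold_center",
                  ifelse(dist <= 1, "near", "neighbor"))
  list(label = label, dist = dist)
}

#' Measure fold geometry from a cross-section
#'
#' Implements the standard fold-shape readout: the apical indentation depth
#' `d_a` (reference apical plane of the neighbouring tissue minus the lowest
#' apical point of the fold cells; positive when indented), the signed basal
#' deformation `d_b` (deviation of the fold cells' basal extremum from the
#' neighbours' basal plane; positive when the basal surface bulges outward,
#' i.e. away from the apical side), the mean apical and basal
#' cross-sectional lengths `l_a`, `l_b` of the fold-centre cells, and the
#' tissue height `h_tissue` (mean apico-basal extent of neighbour cells).
#' All quantities are also returned normalised by `h_tissue`.
#'
#' Reference planes are least-squares lines through the apical (resp. basal)
#' segment endpoints of `neighbor`-labelled cells, i.e. cells at least two
#' rows away from the fold.
#'
#' @param section A `cross_section` (from [extract_cross_section()],
#'   [gen_wedge_cross_section()], or [read_section_csv()]).
#' @return A one-row `fold_geometry` tibble: `d_a`, `d_b`, `l_a`, `l_b`,
#'   `h_tissue`, `d_a_norm`, `d_b_norm`, `l_a_norm`, `l_b_norm`.
#' @export
measure_fold_geometry <- function(section) {
  seg <- as_tibble(section)
  need <- c("cell_id", "label", "layer", "y0", "z0", "y1", "z1")
  miss <- setdiff(need, names(seg))
  if (length(miss)) {
    abort(paste("cross-section is missing column(s):", paste(miss, collapse = ", ")),
          class = "epifold_schema_error")
  }
  fold_a <- seg[seg$label == "fold_center" & seg$layer == "apical", ]
  fold_b <- seg[seg$label == "fold_center" & seg$layer == "basal", ]
  nb_a <- seg[seg$label == "neighbor" & seg$layer == "apical", ]
  nb_b <- seg[seg$label == "neighbor" & seg$layer == "basal", ]
  if (nrow(fold_a) == 0) {
    abort("cross-section has no fold_center cells", class = "epifold_input_error")
  }
  y_center <- mean(c(fold_a$y0, fold_a$y1))
  for (side in c(-1, 1)) {
    n_side <- sum(side * (nb_a$y0 + nb_a$y1) / 2 > side * y_center)
    if (n_side < 2) {
      abort("need at least two neighbor cells on each side of the fold",
            class = "epifold_input_error")
    }
  }

  ends <- function(d) tibble(y = c(d$y0, d$y1), z = c(d$z0, d$z1))
  fit_a <- lm(z ~ y, data = ends(nb_a))
  fit_b <- lm(z ~ y, data = ends(nb_b))

  pa <- ends(fold_a)
  i_min <- which.min(pa$z)
  d_a <- predict(fit_a, newdata = pa[i_min, ]) - pa$z[i_min]

  pb <- ends(fold_b)
  dev_b <- predict(fit_b, newdata = pb) - pb$z
  d_b <- dev_b[which.max(abs(dev_b))]

  l_a <- mean(fold_a$length %||% sqrt((fold_a$y1 - fold_a$y0)^2 + (fold_a$z1 - fold_a$z0)^2))
  l_b <- mean(fold_b$length %||% sqrt((fold_b$y1 - fold_b$y0)^2 + (fold_b$z1 - fold_b$z0)^2))

  mid <- function(d) cbind((d$y0 + d$y1) / 2, (d$z0 + d$z1) / 2)
  ma <- mid(nb_a); mb <- mid(nb_b)
  common <- intersect(nb_a$cell_id, nb_b$cell_id)
  ia <- match(common, nb_a$cell_id); ib <- match(common, nb_b$cell_id)
  h_tissue <- mean(sqrt(rowSums((ma[ia, , drop = FALSE] - mb[ib, , drop = FALSE])^2)))
  if (!is.finite(h_tissue) || h_tissue <= 0) {
    abort("could not measure a positive tissue height from neighbor cells",
          class = "epifold_input_error")
  }

  out <- tibble(d_a = unname(d_a), d_b = unname(d_b), l_a = l_a, l_b = l_b,
                h_tissue = h_tissue,
                d_a_norm = unname(d_a) / h_tissue, d_b_norm = unname(d_b) / h_tissue,
                l_a_norm = l_a / h_tissue, l_b_norm = l_b / h_tissue)
  class(out) <- c("fold_geometry", class(out))
  out
}

#' @method tidy fold_geometry
#' @export
tidy.fold_geometry <- function(x, ...) as_tibble(unclass(x))

#' Fold versus neighbour intensity ratio
#'
#' Ratio of the mean per-cell intensity of fold cells to the mean of
#' neighbouring cells (e.g. basal collagen-IV reporter levels), with an
#' optional per-cell bootstrap confidence interval.
#'
#' @param data Data frame with one row per cell.
#' @param intensity,label Column names (strings) of the intensity values
#'   (>= 0) and the group labels.
#' @param fold_label,neighbor_label Values of `label` defining the groups.
#' @param boot Number of bootstrap resamples for a 95% CI (0 = none).
#' @param seed Seed for the bootstrap.
#' @return One-row tibble: `ratio`, `n_fold`, `n_neighbor` (and `ci_lo`,
#'   `ci_hi` when `boot > 0`).
#' @export
intensity_ratio <- function(data, intensity = "intensity", label = "label",
                            fold_label = "fold", neighbor_label = "neighbor",
                            boot = 0, seed = 1) {
  if (!all(c(intensity, label) %in% names(data))) {
    abort(paste0("data must have columns '", intensity, "' and '", label, "'"),
          class = "epifold_schema_error")
  }
  iv <- data[[intensity]]
  if (any(iv < 0)) abort("intensities must be >= 0", class = "epifold_input_error")
  f <- iv[data[[label]] == fold_label]
  nb <- iv[data[[label]] == neighbor_label]
  if (length(f) == 0 || length(nb) == 0) {
    abort("both label groups must be non-empty", class = "epifold_input_error")
  }
  out <- tibble(ratio = mean(f) / mean(nb), n_fold = length(f),
                n_neighbor = length(nb))
  if (boot > 0) {
    rs <- withr::with_seed(seed, {
      vapply(seq_len(boot), function(i) {
        mean(sample(f, replace = TRUE)) / mean(sample(nb, replace = TRUE))
      }, numeric(1))
    })
    qs <- quantile(rs, c(0.025, 0.975), names = FALSE)
    out$ci_lo <- qs[1]
    out$ci_hi <- qs[2]
  }
  out
}
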