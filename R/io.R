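MESH_SCHEMA <- "epifold-mesh/1"

# doubles as %.17g strings: guarantees bit-exact JSON round-trips
num2chr <- function(x) {
  if (is.null(x)) return(NULL)
  out <- sprintf("%.17g", x)
  dim(out) <- dim(x)
  out
}
chr2num <- function(x) {
  if (is.null(x)) return(NULL)
  out <- as.numeric(x)
  dim(out) <- dim(x)
  out
}

#' Write / read a tissue mesh as JSON
#'
#' Lossless full-precision serialization of the mesh (positions, pairing,
#' cell cycles, box, anchors, labels, reference lattice) with a versioned
#' schema field; positions round-trip bit-exactly.
#'
#' @param mesh A `tissue_mesh`.
#' @param path File path.
#' @return `write_mesh_json` returns `path` invisibly; `read_mesh_json`
#'   returns the reconstructed `tissue_mesh`.
#' @export
write_mesh_json <- function(mesh, path) {
  n <- mesh$n_apical
  obj <- list(
    schema = MESH_SCHEMA,
    box = num2chr(mesh$box),
    apical = num2chr(mesh$positions[seq_len(n), , drop = FALSE]),
    basal = num2chr(mesh$positions[n + seq_len(n), , drop = FALSE]),
    reference = num2chr(mesh$reference),
    cycles = mesh$cycles,
    cells = mesh$cells,
    anchors = num2chr(mesh$anchors),
    meta = mesh$meta[c("a", "h0", "nx", "ny", "aspect_ratio", "stripe")]
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_mesh_json
#' @export
read_mesh_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("schema", "box", "apical", "basal", "cycles", "cells")
  miss <- setdiff(need, names(obj))
  if (length(miss)) {
    abort(paste("mesh file is missing field(s):", paste(miss, collapse = ", ")),
          class = "epifold_schema_error")
  }
  if (!identical(obj$schema, MESH_SCHEMA)) {
    abort(paste0("unsupported mesh schema '", obj$schema, "' (field: schema)"),
          class = "epifold_schema_error")
  }
  cycles <- if (is.matrix(obj$cycles)) {
    lapply(seq_len(nrow(obj$cycles)), function(i) obj$cycles[i, ])
  } else obj$cycles
  mesh <- tissue_mesh(
    apical = chr2num(obj$apical), basal = chr2num(obj$basal),
    cycles = cycles, box = chr2num(obj$box),
    region = obj$cells$region,
    rows = obj$cells$row, cols = obj$cells$col,
    anchors = chr2num(obj$anchors),
    target_volume = obj$cells$target_volume,
    reference = chr2num(obj$reference))
  meta <- obj$meta
  if (!is.null(meta$stripe)) meta$stripe$rows <- as.integer(unlist(meta$stripe$rows))
  mesh$meta <- utils::modifyList(mesh$meta, meta %||% list())
  mesh
}

check_columns <- function(df, need, what) {
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")),
          class = "epifold_schema_error")
  }
  df
}

#' Read / write tracked-vertex recoil tracks
#'
#' CSV schema: `t, x1, y1, z1, x2, y2, z2` (one row per frame; rows with
#' `t <= 0` are pre-ablation). The same schema is produced by
#' [simulate_recoil()] and accepted from experimental vertex tracking.
#'
#' @param path File path.
#' @param track A `recoil_track` or compatible data frame.
#' @return `read_track_csv` returns a `recoil_track` tibble.
#' @export
read_track_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  df <- check_columns(df, c("t", "x1", "y1", "z1", "x2", "y2", "z2"),
                      "recoil track")
  df$separation <- sqrt((df$x2 - df$x1)^2 + (df$y2 - df$y1)^2 + (df$z2 - df$z1)^2)
  class(df) <- c("recoil_track", class(df))
  df
}

#' @rdname read_track_csv
#' @export
write_track_csv <- function(track, path) {
  utils::write.csv(as.data.frame(track), path, row.names = FALSE)
  invisible(path)
}

#' Read / write coupled intensity/height series
#'
#' CSV schema: `cell_id, t, a_l, h` plus any extra per-cell signal columns
#' (e.g. `area_a, i_a` for medial-pool analyses).
#'
#' @param path File path.
#' @param series Tibble as produced by [gen_coupled_timeseries()].
#' @export
read_series_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  check_columns(df, c("cell_id", "t", "a_l", "h"), "coupled series")
}

#' @rdname read_series_csv
#' @export
write_series_csv <- function(series, path) {
  utils::write.csv(as.data.frame(series), path, row.names = FALSE)
  invisible(path)
}

#' Read / write cross-sections
#'
#' CSV schema: `cell_id, label, dist, layer, y0, z0, y1, z1` (per-frame
#' tracked apical/basal vertex pairs in a section plane).
#'
#' @param path File path.
#' @param section A `cross_section`.
#' @export
read_section_csv <- function(path) {
  df <- as_tibble(utils::read.csv(path))
  df <- check_columns(df, c("cell_id", "label", "layer", "y0", "z0", "y1", "z1"),
                      "cross-section")
  if (is.null(df$length)) {
    df$length <- sqrt((df$y1 - df$y0)^2 + (df$z1 - df$z0)^2)
  }
  new_cross_section(df)
}

#' @rdname read_section_csv
#' @export
write_section_csv <- function(section, path) {
  utils::write.csv(as.data.frame(section), path, row.names = FALSE)
  invisible(path)
}

#' Export tissue surfaces as VTK legacy polydata or Wavefront OBJ
#'
#' Writes the apical, basal and/or lateral faces as polygons with per-face
#' duplicated, periodically unwrapped points (so faces crossing the box
#' boundary render correctly in any 3D viewer).
#'
#' @param mesh A `tissue_mesh`.
#' @param path Output file.
#' @param surfaces Subset of `c("apical", "basal", "lateral")`.
#' @return `path`, invisibly.
#' @export
write_vtk <- function(mesh, path, surfaces = c("apical", "basal")) {
  polys <- collect_surface_polys(mesh, surfaces)
  npts <- sum(vapply(polys, nrow, integer(1)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "epifold tissue surfaces", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", npts)), con)
  for (p in polys) {
    writeLines(apply(p, 1, function(r) sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])), con)
  }
  sizes <- vapply(polys, nrow, integer(1))
  writeLines(sprintf("POLYGONS %d %d", length(polys), length(polys) + npts), con)
  off <- 0L
  for (i in seq_along(polys)) {
    writeLines(paste(c(sizes[i], off + seq_len(sizes[i]) - 1L), collapse = " "), con)
    off <- off + sizes[i]
  }
  invisible(path)
}

#' @rdname write_vtk
#' @export
write_obj <- function(mesh, path, surfaces = c("apical", "basal")) {
  polys <- collect_surface_polys(mesh, surfaces)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# epifold tissue surfaces", con)
  for (p in polys) {
    writeLines(apply(p, 1, function(r) sprintf("v %.9g %.9g %.9g", r[1], r[2], r[3])), con)
  }
  off <- 0L
  for (p in polys) {
    writeLines(paste(c("f", off + seq_len(nrow(p))), collapse = " "), con)
    off <- off + nrow(p)
  }
  invisible(path)
}

collect_surface_polys <- function(mesh, surfaces) {
  surfaces <- match.arg(surfaces, c("apical", "basal", "lateral"),
                        several.ok = TRUE)
  polys <- list()
  if (any(c("apical", "basal") %in% surfaces)) {
    for (ci in seq_len(nrow(mesh$cells))) {
      poly <- cell_polygons(mesh, ci)
      if ("apical" %in% surfaces) polys[[length(polys) + 1L]] <- poly$apical
      if ("basal" %in% surfaces) polys[[length(polys) + 1L]] <- poly$basal
    }
  }
  if ("lateral" %in% surfaces) {
    lf <- mesh$lateral_faces
    n <- mesh$n_apical
    for (i in seq_len(nrow(lf))) {
      sh <- c(lf$sx[i] * mesh$box[1], lf$sy[i] * mesh$box[2], 0)
      polys[[length(polys) + 1L]] <- rbind(
        mesh$positions[lf$a1[i], ],
        mesh$positions[lf$a2[i], ] + sh,
        mesh$positions[lf$a2[i] + n, ] + sh,
        mesh$positions[lf$a1[i] + n, ])
    }
  }
  polys
}
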