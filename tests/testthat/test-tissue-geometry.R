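test_that("face_area matches closed forms for planar polygons", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(face_area(1:4, sq), 1.0)
  hexp <- cbind(cos((0:5) * pi / 3), sin((0:5) * pi / 3), 0)
  expect_equal(face_area(1:6, hexp), 3 * sqrt(3) / 2, tolerance = 1e-12)
})

test_that("face_area of a non-planar quad equals the triangle-sum oracle", {
  quad <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0.2), c(0, 1, 0))
  # independent oracle: explicit loop over centroid-fan triangles
  ctr <- colMeans(quad)
  oracle <- 0
  for (i in 1:4) {
    j <- i %% 4 + 1
    u <- quad[i, ] - ctr
    v <- quad[j, ] - ctr
    cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
            u[1] * v[2] - u[2] * v[1])
    oracle <- oracle + sqrt(sum(cr^2)) / 2
  }
  expect_equal(face_area(1:4, quad), oracle, tolerance = 1e-12)
})

test_that("face_area rejects degenerate cycles and is cyclic-invariant", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_error(face_area(c(1, 2, 2, 4), sq), class = "epifold_input_error")
  expect_error(face_area(c(1, 2), sq), class = "epifold_input_error")
  hexp <- cbind(cos((0:5) * pi / 3), sin((0:5) * pi / 3), 0.1 * (0:5))
  a0 <- face_area(1:6, hexp)
  for (s in 1:5) {
    expect_equal(face_area(c((s + 1):6, 1:s), hexp), a0, tolerance = 1e-12)
  }
})

test_that("edge_length handles the minimum image and coincident vertices", {
  pts <- rbind(c(0, 0, 0), c(3, 4, 0), c(0.5, 1, 2), c(9.5, 1, 2), c(0.5, 1, 2))
  expect_equal(edge_length(c(1, 2), pts), 5.0)
  expect_equal(edge_length(c(3, 4), pts, box = c(10, 10)), 1.0)
  expect_equal(edge_length(c(3, 5), pts), 0.0)
})

test_that("cell_volume is exact for prisms and matches the tet oracle when twisted", {
  cube <- rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1),
                c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(cell_volume(1:4, 5:8, cube), 1.0, tolerance = 1e-12)

  a <- 0.7; h <- 1.9
  ang <- (30 + 60 * (0:5)) * pi / 180
  prism <- rbind(cbind(a * cos(ang), a * sin(ang), h),
                 cbind(a * cos(ang), a * sin(ang), 0))
  A <- 3 * sqrt(3) / 2 * a^2
  expect_equal(cell_volume(1:6, 7:12, prism), A * h, tolerance = 1e-12)

  # twisted prism: independent signed-tetrahedra accumulation from the cell
  # centroid over the same centroid-fan surface
  twist <- 10 * pi / 180
  tw <- rbind(cbind(a * cos(ang + twist), a * sin(ang + twist), h),
              cbind(a * cos(ang), a * sin(ang), 0))
  tet_oracle <- local({
    A_ <- tw[1:6, ]; B_ <- tw[7:12, ]
    cc <- colMeans(rbind(A_, B_))
    vol <- 0
    tet <- function(p0, p1, p2) {
      u0 <- p0 - cc; u1 <- p1 - cc; u2 <- p2 - cc
      (u0[1] * (u1[2] * u2[3] - u1[3] * u2[2]) -
         u0[2] * (u1[1] * u2[3] - u1[3] * u2[1]) +
         u0[3] * (u1[1] * u2[2] - u1[2] * u2[1])) / 6
    }
    ca <- colMeans(A_); cb <- colMeans(B_)
    for (i in 1:6) {
      j <- i %% 6 + 1
      vol <- vol + tet(ca, A_[i, ], A_[j, ]) + tet(cb, B_[j, ], B_[i, ])
      cq <- (A_[i, ] + B_[i, ] + B_[j, ] + A_[j, ]) / 4
      vol <- vol + tet(cq, A_[i, ], B_[i, ]) + tet(cq, B_[i, ], B_[j, ]) +
        tet(cq, B_[j, ], A_[j, ]) + tet(cq, A_[j, ], A_[i, ])
    }
    as.numeric(vol)
  })
  expect_equal(cell_volume(1:6, 7:12, tw), tet_oracle, tolerance = 1e-10)
})

test_that("cell_volume rejects open surfaces", {
  cube <- rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1),
                c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_error(cell_volume(1:4, 5:7, cube), class = "epifold_input_error")
})

test_that("flat tissue volumes tessellate the box exactly", {
  mesh <- build_hex_tissue(6, 6, aspect_ratio = 5, params = baseline_params(),
                           relax = FALSE)
  h0 <- mesh$meta$h0
  vols <- cell_volumes(mesh)
  expect_equal(sum(vols), mesh$box[1] * mesh$box[2] * h0, tolerance = 1e-9)
  expect_equal(vols, rep(1, 36), tolerance = 1e-9)
})

test_that("geometry is invariant under lattice translations", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  E0 <- total_energy(mesh, p)
  v0 <- cell_volumes(mesh)
  shifted <- mesh
  shifted$positions <- sweep(mesh$positions, 2,
                             c(-mesh$box[1], 2 * mesh$box[2], 0))
  shifted$anchors <- sweep(mesh$anchors, 2, c(-mesh$box[1], 2 * mesh$box[2], 0))
  expect_equal(total_energy(shifted, p), E0, tolerance = 1e-9)
  expect_equal(cell_volumes(shifted), v0, tolerance = 1e-12)
})

test_that("constructor enforces pairing and valid cycles", {
  ap <- rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  expect_error(tissue_mesh(ap, ap[1:3, ], list(1:4), box = c(10, 10)),
               class = "epifold_input_error")
  expect_error(tissue_mesh(ap, ap, list(c(1, 2)), box = c(10, 10)),
               class = "epifold_input_error")
  expect_error(tissue_mesh(ap, ap, list(c(1, 2, 2, 3)), box = c(10, 10)),
               class = "epifold_input_error")
})
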