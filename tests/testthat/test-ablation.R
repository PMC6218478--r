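test_that("ablating an element only touches its tension parameter", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  eid <- central_element(mesh)
  vols_before <- cell_volumes(mesh)
  pa <- ablate_element(p, eid, "lateral_face", mesh = mesh)
  # geometry untouched at the instant of ablation: volumes identical
  expect_identical(cell_volumes(mesh), vols_before)
  w0 <- epifold:::compile_weights(mesh, p)
  w1 <- epifold:::compile_weights(mesh, pa)
  ncell <- nrow(mesh$cells)
  lat_idx <- 2 * ncell + eid
  expect_equal(w1$face_w[lat_idx], 0)
  expect_equal(w1$face_w[-lat_idx], w0$face_w[-lat_idx])
  expect_equal(w1$e_w, w0$e_w)
  expect_error(ablate_element(p, 10000, "apical_edge", mesh = mesh),
               class = "epifold_input_error")
})

test_that("ablating an edge whose tension is already zero releases nothing", {
  mesh <- tissue_6x6()
  p0 <- mech_params(Lambda_a = 0, T_l = params_of(mesh)$T_l)
  m <- relax_tissue(mesh, p0)
  eid <- central_element(m)
  v0 <- ablation_v0(m, p0, eid, "apical_edge", n_frames = 2)
  expect_lt(abs(v0), 1e-4)
})

test_that("a basal cut releases more force than an apical cut in the 4x tissue", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  eid <- central_element(mesh)
  released <- function(kind) {
    pa <- ablate_element(p, eid, kind, mesh = mesh)
    max(sqrt(rowSums(vertex_forces(mesh, pa)^2)))
  }
  expect_gt(released("basal_edge"), 2.5 * released("apical_edge"))
})

test_that("without ablation the separation stays constant and v0 = 0", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  eid <- central_element(mesh)
  tr <- simulate_recoil(mesh, p, eid, "apical_edge", n_frames = 3)
  expect_lt(diff(range(tr$separation)), 1e-8)
  expect_lt(abs(recoil_velocity(tr)), 1e-8)
})

test_that("halving the integration step changes the first frame by < 1%", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  eid <- central_element(mesh)
  pa <- ablate_element(p, eid, "basal_edge", mesh = mesh)
  s1 <- simulate_recoil(mesh, pa, dt = 1e-5, n_frames = 1)$separation[2]
  s2 <- simulate_recoil(mesh, pa, dt = 5e-6, n_frames = 1)$separation[2]
  expect_lt(abs(s1 - s2) / s2, 0.01)
})

test_that("apical and basal recoils are symmetric when tensions are symmetric", {
  mesh <- tissue_6x6()
  p_sym <- mech_params(T_b = 1, Lambda_b = 1, k = 0,
                       T_l = params_of(mesh)$T_l)
  m <- relax_tissue(mesh, p_sym)
  eid <- central_element(m)
  va <- ablation_v0(m, p_sym, eid, "apical_edge")
  vb <- ablation_v0(m, p_sym, eid, "basal_edge")
  expect_equal(vb / va, 1, tolerance = 0.05)
})

test_that("recoil_velocity implements the first-frame estimator", {
  track <- tibble::tibble(t = c(0, 0.25, 0.5), separation = c(10, 10.5, 10.8))
  expect_equal(recoil_velocity(track), 2.0)
  # explicit window (lateral interfaces are sampled at 1 s)
  expect_equal(recoil_velocity(track, window = 1), 0.5)
  expect_error(recoil_velocity(track[track$t > 0, ]),
               class = "epifold_input_error")
  expect_error(recoil_velocity(tibble::tibble(t = 1, foo = 2)),
               class = "epifold_schema_error")
})

test_that("recoil velocity scales roughly linearly with the released tension", {
  mesh <- tissue_6x6()
  base <- params_of(mesh)
  v0s <- vapply(c(0.5, 1, 2), function(sc) {
    p <- mech_params(Lambda_a = sc * base$Lambda_a, T_l = base$T_l)
    m <- relax_tissue(mesh, p)
    ablation_v0(m, p, central_element(m), "apical_edge")
  }, numeric(1))
  # ratios track the tension ratios within 25%
  expect_equal(v0s[2] / v0s[1], 2, tolerance = 0.25)
  expect_equal(v0s[3] / v0s[2], 2, tolerance = 0.25)
})

test_that("lateral-face recoil reads out the apical-basal extent", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  eid <- central_element(mesh, "lateral")
  pa <- ablate_element(p, eid, "lateral_face", mesh = mesh)
  tr <- simulate_recoil(mesh, pa, n_frames = 3)
  # the released interface widens along the apical-basal axis
  expect_gt(tail(tr$separation, 1), tr$separation[1])
  expect_gt(recoil_velocity(tr), 0)
  # the pre-ablation separation is the cell height scale
  expect_equal(tr$separation[1], mean(epifold:::cell_heights(mesh)),
               tolerance = 0.1)
})
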