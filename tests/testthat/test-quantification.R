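test_that("a flat tissue yields straight outlines and zero deformations", {
  mesh <- tissue_6x8_striped()
  sec <- extract_cross_section(mesh)
  z_ap <- c(sec$z0[sec$layer == "apical"], sec$z1[sec$layer == "apical"])
  z_ba <- c(sec$z0[sec$layer == "basal"], sec$z1[sec$layer == "basal"])
  expect_lt(diff(range(z_ap)), 1e-5)
  expect_lt(diff(range(z_ba)), 1e-5)
  fg <- measure_fold_geometry(sec)
  expect_equal(fg$d_a, 0, tolerance = 1e-5)
  expect_equal(fg$d_b, 0, tolerance = 1e-5)
  expect_equal(fg$l_a, fg$l_b, tolerance = 1e-5)
  # separation of the outlines is the tissue height
  expect_equal(fg$h_tissue, mean(z_ap) - mean(z_ba), tolerance = 1e-4)
  expect_equal(fg$l_a_norm, fg$l_a / fg$h_tissue)
})

test_that("wedge fixtures round-trip through measure_fold_geometry exactly", {
  for (pars in list(c(0, 0, 0.7, 0.7, 1), c(0.4, 0.1, 1.0, 1.8, 1.0),
                    c(0.3, -0.15, 0.8, 1.1, 1.2))) {
    sec <- gen_wedge_cross_section(pars[1], pars[2], pars[3], pars[4], pars[5])
    fg <- measure_fold_geometry(sec)
    expect_equal(fg$d_a, pars[1], tolerance = 1e-12)
    expect_equal(fg$d_b, pars[2], tolerance = 1e-12)
    expect_equal(fg$l_a, pars[3], tolerance = 1e-12)
    expect_equal(fg$l_b, pars[4], tolerance = 1e-12)
    expect_equal(fg$h_tissue, pars[5], tolerance = 1e-12)
    expect_equal(fg$d_a_norm, pars[1] / pars[5], tolerance = 1e-12)
  }
})

test_that("sections one lattice period apart give identical fold geometry", {
  ramp <- short_basal_ramp()
  m <- ramp$meshes[[1]]
  w <- sqrt(3) * m$meta$a
  off <- 0.25 * w
  f1 <- measure_fold_geometry(extract_cross_section(m, offset = off))
  f2 <- measure_fold_geometry(extract_cross_section(m, offset = off + w))
  for (col in names(f1)) expect_equal(f1[[col]], f2[[col]], tolerance = 1e-6)
})

test_that("fold geometry is invariant to rigid motion and fold-plane reflection", {
  sec <- gen_wedge_cross_section(0.4, 0.1, 1.0, 1.8, 1.0)
  fg <- measure_fold_geometry(sec)
  moved <- sec
  moved$y0 <- moved$y0 + 13.7; moved$y1 <- moved$y1 + 13.7
  moved$z0 <- moved$z0 - 2.2; moved$z1 <- moved$z1 - 2.2
  expect_equal(as.data.frame(measure_fold_geometry(moved)), as.data.frame(fg),
               tolerance = 1e-10)
  refl <- sec
  refl$y0 <- -refl$y0; refl$y1 <- -refl$y1
  expect_equal(as.data.frame(measure_fold_geometry(refl)), as.data.frame(fg),
               tolerance = 1e-10)
})

test_that("a deep basal-decrease fold is a wedge: indented apically, wide basally", {
  s <- tidy(short_basal_ramp())
  last <- s[nrow(s), ]
  expect_gt(last$d_a, 0)
  expect_gt(last$l_b, last$l_a)
  # bookkeeping identity on every step
  expect_equal(s$d_a_norm, s$d_a / s$h_tissue, tolerance = 1e-12)
  expect_equal(s$l_b_norm, s$l_b / s$h_tissue, tolerance = 1e-12)
})

test_that("measure_fold_geometry validates its input", {
  sec <- gen_wedge_cross_section(0.2, 0, 1, 1, 1)
  expect_error(measure_fold_geometry(sec[sec$label != "fold_center", ]),
               class = "epifold_input_error")
  expect_error(measure_fold_geometry(sec[, setdiff(names(sec), "z0")]),
               class = "epifold_schema_error")
  # fewer than two neighbours per side
  thin <- gen_wedge_cross_section(0.2, 0, 1, 1, 1, n_neighbor_cells = 1)
  expect_error(measure_fold_geometry(thin), class = "epifold_input_error")
})

test_that("intensity_ratio matches group means and validates groups", {
  tab <- tibble::tibble(label = rep(c("fold", "neighbor"), each = 4),
                        intensity = c(rep(0.8, 4), rep(1.0, 4)))
  expect_equal(intensity_ratio(tab)$ratio, 0.8)
  same <- tibble::tibble(label = rep(c("fold", "neighbor"), each = 4),
                         intensity = rep(2.5, 8))
  expect_equal(intensity_ratio(same)$ratio, 1.0)
  expect_error(intensity_ratio(tab[tab$label == "fold", ]),
               class = "epifold_input_error")
  neg <- tab; neg$intensity[1] <- -1
  expect_error(intensity_ratio(neg), class = "epifold_input_error")
  # bootstrap CI covers the generator contrast
  big <- gen_intensity_table(200, 200, contrast = 0.8, noise_sd = 0.1, seed = 7)
  res <- intensity_ratio(big, boot = 200, seed = 1)
  expect_gt(0.8, res$ci_lo)
  expect_lt(0.8, res$ci_hi)
})
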