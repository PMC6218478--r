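test_that("a perturbed flat tissue relaxes back to the flat equilibrium", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  E_ref <- glance(mesh)$energy
  m <- perturb_mesh(mesh, 0.01, seed = 3)
  m$anchors <- mesh$anchors
  m <- relax_tissue(m, p)
  z_ap <- m$positions[seq_len(m$n_apical), 3]
  expect_lt(diff(range(z_ap)), 1e-5)
  expect_equal(glance(m)$energy, E_ref, tolerance = 1e-8)
  expect_lt(glance(m)$max_force, 1e-6)
})

test_that("a single free prism cell relaxes to the brute-force prism optimum", {
  m <- make_hex_prism(a = 0.45, h = 1.6)
  m$cells$target_volume <- 1
  p <- mech_params(T_a = 1, T_b = 1, T_l = 1.5, Lambda_a = 0.5, Lambda_b = 0.5,
                   k = 0, K_V = 1e4)
  m <- relax_tissue(m, p)
  h_relaxed <- mean(m$positions[1:6, 3] - m$positions[7:12, 3])

  # scalar brute-force oracle: regular prism with A = V0 / h (volume
  # constraint exact), minimise the prism energy over the height alone
  W1 <- function(h) {
    A <- 1 / h
    a <- sqrt(2 * A / (3 * sqrt(3)))
    2 * A + 1.5 * 6 * a * h + 0.5 * 2 * 6 * a
  }
  h_star <- optimize(W1, c(0.2, 5))$minimum
  # the penalty keeps volumes within ~3e-4 of V0, so heights agree to ~1e-3
  expect_equal(h_relaxed, h_star, tolerance = 2e-3)
  # and the relaxed energy is no higher than the best regular prism
  expect_lte(glance(m)$energy, W1(h_star) + 1e-3)
})

test_that("flat tissue equilibrium height matches the 1D oracle", {
  p0 <- mech_params(k = 0)
  mesh <- build_hex_tissue(6, 6, aspect_ratio = 5, params = p0, relax = FALSE)
  p <- mesh$meta$params
  n <- mesh$n_apical
  z_b <- mesh$positions[n + 1:n, 3][1]

  # 1D brute-force oracle: total energy as a function of the uniform
  # apical-plane height above the (fixed) basal plane
  W1 <- function(h) {
    m <- mesh
    m$positions[1:n, 3] <- z_b + h
    total_energy(m, p)
  }
  h_star <- optimize(W1, c(1, 6), tol = 1e-10)$minimum

  relaxed <- relax_tissue(mesh, p)
  h_relaxed <- mean(relaxed$positions[1:n, 3] - relaxed$positions[n + 1:n, 3])
  expect_equal(h_relaxed, h_star, tolerance = 1e-4)
})

test_that("the flat tissue at its 1D-optimal height is force free", {
  p0 <- mech_params(k = 0)
  mesh <- build_hex_tissue(6, 6, aspect_ratio = 5, params = p0, relax = FALSE)
  p <- mesh$meta$params
  n <- mesh$n_apical
  z_b <- mesh$positions[n + 1:n, 3][1]
  # root of the net vertical force on the apical plane (exact 1D stationarity)
  Fz <- function(h) {
    m <- mesh
    m$positions[1:n, 3] <- z_b + h
    sum(vertex_forces(m, p)[1:n, 3])
  }
  h_star <- uniroot(Fz, c(2, 4), tol = 1e-13)$root
  m <- mesh
  m$positions[1:n, 3] <- z_b + h_star
  f <- vertex_forces(m, p)
  expect_lt(sqrt(max(rowSums(f^2))), 1e-8)
})

test_that("looser tolerance cannot lower the relaxed energy", {
  mesh <- perturb_mesh(tissue_6x6(), 0.01, seed = 8)
  mesh$anchors <- tissue_6x6()$anchors
  p <- params_of(tissue_6x6())
  e_loose <- glance(relax_tissue(mesh, p, tol = 1e-4))$energy
  e_tight <- glance(relax_tissue(mesh, p, tol = 1e-6))$energy
  expect_gte(e_loose, e_tight - 1e-10)
})

test_that("a zero-magnitude ramp is a no-op", {
  mesh <- tissue_6x8_striped()
  p <- params_of(mesh)
  r <- run_ramp(mesh, p, ramp_protocol("basal_decrease", grid = 0),
                perturb_amplitude = 0)
  expect_equal(r$meshes[[1]]$positions, mesh$positions, tolerance = 1e-8)
  expect_equal(nrow(tidy(r)), 1L)
  expect_equal(tidy(r)$d_a, 0, tolerance = 1e-6)
})

test_that("small up-down ramps are reversible (quasistatic hysteresis)", {
  mesh <- tissue_6x8_striped()
  p <- params_of(mesh)
  E0 <- glance(mesh)$energy
  m <- mesh
  for (d in c(-0.1, -0.2, -0.1, 0)) {
    m <- relax_tissue(m, epifold:::apply_delta(p, "basal_decrease", d, "pre_fold"))
  }
  expect_equal(glance(m)$energy, E0, tolerance = 1e-6)
})

test_that("ramp protocols validate their grids", {
  expect_error(ramp_protocol("basal_decrease", grid = c(-0.4, -0.2)),
               class = "epifold_input_error")
  expect_error(ramp_protocol("basal_decrease", grid = c(0.1, 0.2)),
               class = "epifold_input_error")
  expect_error(ramp_protocol("lateral_increase", grid = c(-0.5)),
               class = "epifold_input_error")
  expect_error(ramp_protocol("basal_decrease", grid = c(-0.5, -1.5)),
               class = "epifold_input_error")
  expect_silent(ramp_protocol("lateral_increase"))
})

test_that("fold formation is insensitive to the two normalized free parameters", {
  # the normalized edge tension and spring stiffness are free parameters set
  # to 1; halving/doubling them must not change the folding behaviour
  # qualitatively
  grid <- seq(-0.1, -0.4, by = -0.1)
  sweep_ramp <- function(lam_hat, k_hat) {
    p <- mech_params(Lambda_a = lam_hat, Lambda_b = 4 * lam_hat, k = k_hat)
    m <- assign_stripe(build_hex_tissue(6, 8, aspect_ratio = 5, params = p),
                       width = 2)
    tidy(run_ramp(m, params_of(m),
                  ramp_protocol("basal_decrease", grid = grid)))
  }
  base <- tail(sweep_ramp(1, 1)$d_a_norm, 1)
  expect_gt(base, 0.05)
  for (v in list(c(0.5, 1), c(2, 1), c(1, 0.5), c(1, 2))) {
    s <- sweep_ramp(v[1], v[2])
    last <- s[nrow(s), ]
    # same qualitative behaviour: a growing apical indentation forming a
    # wedge (basally wide), with a depth of the same order as the default
    expect_true(all(diff(s$d_a) > -1e-6))
    expect_gt(last$d_a_norm, 0.05)
    expect_gt(last$l_b, last$l_a)
    expect_gt(last$d_a_norm / base, 0.25)
    expect_lt(last$d_a_norm / base, 4)
  }
})

test_that("non-convergence raises a diagnostic error", {
  mesh <- tissue_6x6()
  p <- params_of(mesh)
  err <- tryCatch(
    relax_tissue(perturb_mesh(mesh, 0.05, seed = 1), p,
                 tol = 1e-6, max_restarts = 1, maxit = 3),
    error = function(e) e)
  expect_s3_class(err, "epifold_convergence_error")
  expect_true(is.finite(err$report$max_force))
  expect_true(length(err$report$energy_trace) >= 1)
})
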