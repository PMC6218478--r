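# Shared fixtures, all built in code. Expensive meshes are created lazily and
# cached for the test run.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(build)()
  .fixtures[[name]]
}

# single unit-cube cell in an effectively non-periodic box
make_cube_mesh <- function() {
  ap <- rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))
  ba <- ap
  ba[, 3] <- 0
  tissue_mesh(ap, ba, list(1:4), box = c(100, 100))
}

# single free regular hexagonal prism (side a, height h), unit volume if
# a, h chosen accordingly
make_hex_prism <- function(a = 0.4, h = 2, twist_deg = 0) {
  ang_a <- (30 + 60 * (0:5) + twist_deg) * pi / 180
  ang_b <- (30 + 60 * (0:5)) * pi / 180
  ap <- cbind(a * cos(ang_a) + 50, a * sin(ang_a) + 50, h)
  ba <- cbind(a * cos(ang_b) + 50, a * sin(ang_b) + 50, 0)
  tissue_mesh(ap, ba, list(1:6), box = c(100, 100),
              target_volume = 3 * sqrt(3) / 2 * a^2 * h)
}

baseline_params <- function() mech_params()

# relaxed 6x6 baseline tissue with calibrated T_l
tissue_6x6 <- function() {
  fixture("t66", function() build_hex_tissue(6, 6, aspect_ratio = 5,
                                             params = baseline_params()))
}

# relaxed 6x8 tissue with a centred 2-row pre-fold stripe
tissue_6x8_striped <- function() {
  fixture("t68", function() {
    assign_stripe(build_hex_tissue(6, 8, aspect_ratio = 5,
                                   params = baseline_params()), width = 2)
  })
}

params_of <- function(mesh) mesh$meta$params

# short basal-decrease ramp on the 6x8 stripe (8 steps to -0.8), reused by
# quantification and ramp-property tests
short_basal_ramp <- function() {
  fixture("ramp68", function() {
    m <- tissue_6x8_striped()
    run_ramp(m, params_of(m),
             ramp_protocol("basal_decrease", grid = seq(-0.1, -0.8, by = -0.1)))
  })
}
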