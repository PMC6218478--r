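#' Relax a tissue to mechanical equilibrium
#'
#' Deterministic quasi-Newton (L-BFGS-B) descent on all vertex coordinates
#' with the analytic force field, restarted until the largest per-vertex
#' force norm falls below `tol`. There are no stochastic elements: runs are
#' reproducible given the starting mesh and parameters.
#'
#' @param mesh A `tissue_mesh` (any finite starting configuration).
#' @param params [mech_params()].
#' @param tol Convergence tolerance on the maximum per-vertex force norm
#'   (reduced units; default `1e-6`).
#' @param max_restarts Number of L-BFGS-B restarts before giving up.
#' @param maxit Iteration cap per restart.
#' @return The equilibrated mesh; the convergence report (energy, max force,
#'   volume violation, iteration counts, energy trace over restarts) is
#'   stored in `mesh$last_relax` and returned by [glance.tissue_mesh()].
#'   Non-convergence raises an `epifold_convergence_error` carrying the
#'   diagnostics.
#' @export
relax_tissue <- function(mesh, params, tol = 1e-6, max_restarts = 8,
                         maxit = 20000) {
  w <- compile_weights(mesh, params)
  nv <- nrow(mesh$positions)
  cache <- new.env(parent = emptyenv())
  cache$par <- NULL
  cache$nev <- 0L
  eval_at <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- eval_mesh(mesh, positions = matrix(par, nv, 3), weights = w)
    cache$par <- par
    cache$res <- res
    cache$nev <- cache$nev + 1L
    res
  }
  fn <- function(par) eval_at(par)$energy
  gr <- function(par) as.vector(eval_at(par)$grad)

  par <- as.vector(mesh$positions)
  energy_trace <- numeric(0)
  iters <- 0L
  fmax <- Inf
  for (r in seq_len(max_restarts)) {
    opt <- optim(par, fn, gr, method = "L-BFGS-B",
                 control = list(maxit = maxit, pgtol = tol / 3, factr = 1))
    par <- opt$par
    iters <- iters + opt$counts[["function"]]
    res <- eval_at(par)
    energy_trace <- c(energy_trace, res$energy)
    fmax <- max_force_norm(res$grad)
    if (fmax < tol) break
    # L-BFGS line searches stall once energy decrements reach the rounding
    # noise of the total energy; switch to the gradient-only polish, which
    # resolves the force criterion to arbitrary tolerance.
    bb <- bb_descent(function(par) eval_at(par)$grad, par, tol = tol,
                     maxit = maxit)
    par <- bb$par
    iters <- iters + bb$iterations
    res <- eval_at(par)
    energy_trace <- c(energy_trace, res$energy)
    fmax <- max_force_norm(res$grad)
    if (fmax < tol) break
  }
  res <- eval_at(par)
  vol_violation <- max(abs(res$volumes - w$cell_V0) / w$cell_V0)
  report <- list(converged = fmax < tol, energy = res$energy,
                 energy_parts = res$parts, max_force = fmax,
                 vol_violation = vol_violation, fn_evals = cache$nev,
                 iterations = iters, energy_trace = energy_trace, tol = tol)
  if (fmax >= tol) {
    abort(sprintf("relaxation did not converge: max force %.3g after %d evaluations (tol %.3g)",
                  fmax, cache$nev, tol),
          class = "epifold_convergence_error", report = report)
  }
  mesh$positions <- matrix(par, nv, 3)
  mesh$last_relax <- report
  mesh
}

# Barzilai-Borwein gradient descent polish. Near the minimum the basin is
# quadratic and BB steps (spectral step length s.s/s.y, safeguarded) converge
# the FORCE norm quickly without ever comparing energies, so the
# double-precision floor of energy differences is irrelevant. Deterministic.
bb_descent <- function(grad_fn, par, tol, maxit = 20000,
                       dt0 = 1e-4, dt_max = 0.5, dt_min = 1e-6) {
  nv3 <- length(par) / 3
  g <- as.vector(grad_fn(par))
  dt <- dt0
  for (it in seq_len(maxit)) {
    fmax <- sqrt(max(rowSums(matrix(g, nv3, 3)^2)))
    if (fmax < tol) return(list(par = par, iterations = it, fmax = fmax))
    par_new <- par - dt * g
    g_new <- as.vector(grad_fn(par_new))
    s <- par_new - par
    y <- g_new - g
    sy <- sum(s * y)
    dt <- if (sy > 0) max(dt_min, min(dt_max, sum(s * s) / sy)) else dt0
    par <- par_new
    g <- g_new
  }
  list(par = par, iterations = maxit, fmax = fmax)
}

#' Convergence report of the last relaxation
#'
#' @param x A `tissue_mesh` returned by [relax_tissue()].
#' @param ... Unused.
#' @return One-row tibble: energy, max force, volume violation, iterations.
#' @method glance tissue_mesh
#' @export
glance.tissue_mesh <- function(x, ...) {
  r <- x$last_relax
  if (is.null(r)) {
    return(tibble(converged = NA, energy = NA_real_, max_force = NA_real_,
                  vol_violation = NA_real_, iterations = NA_integer_))
  }
  tibble(converged = r$converged, energy = r$energy, max_force = r$max_force,
         vol_violation = r$vol_violation, iterations = r$iterations)
}

#' Quasistatic tension-ramp protocol
#'
#' Defines how the tension parameters of the target stripe are rescaled,
#' step by step, along a magnitude grid; the grid plays the role of the time
#' axis of the quasistatic simulation. Modes:
#' \describe{
#'   \item{`basal_decrease`}{`T_b' = (1 + delta) T_b`, `Lambda_b' = (1 +
#'     delta) Lambda_b` with `delta <= 0` (fold formation by basal tension
#'     decrease; plots use `-delta`).}
#'   \item{`lateral_increase`}{`T_l' = (1 + delta) T_l`, `delta >= 0`.}
#'   \item{`apical_increase`}{`T_a' = (1 + delta) T_a`, `Lambda_a' = (1 +
#'     delta) Lambda_a`, `delta >= 0` (control: apical tension increase does
#'     not fold the columnar tissue appreciably).}
#' }
#'
#' @param mode One of `"basal_decrease"`, `"lateral_increase"`,
#'   `"apical_increase"`.
#' @param grid Numeric vector of delta values, monotone in magnitude. The
#'   default is 40 uniform steps to `-0.8` for the basal mode (motivated by
#'   the measured ~70% basal recoil reduction in pre-fold cells) and to
#'   `+1` for the lateral and apical modes.
#' @param region Target region label.
#' @return A `ramp_protocol` object.
#' @export
ramp_protocol <- function(mode = c("basal_decrease", "lateral_increase",
                                   "apical_increase"),
                          grid = NULL, region = "pre_fold") {
  mode <- match.arg(mode)
  if (is.null(grid)) {
    grid <- if (mode == "basal_decrease") {
      seq(-0.02, -0.8, by = -0.02)
    } else {
      seq(0.025, 1, by = 0.025)
    }
  }
  if (length(grid) > 1 && any(diff(abs(grid)) < 0)) {
    abort("ramp grid must be monotone in |delta|", class = "epifold_input_error")
  }
  if (any(1 + grid < 0)) {
    abort("ramp would make tensions negative (1 + delta < 0)",
          class = "epifold_input_error")
  }
  sgn_ok <- switch(mode,
    basal_decrease = all(grid <= 0),
    lateral_increase = ,
    apical_increase = all(grid >= 0))
  if (!sgn_ok) {
    abort(paste0("grid sign incompatible with mode ", mode),
          class = "epifold_input_error")
  }
  structure(list(mode = mode, grid = grid, region = region),
            class = "ramp_protocol")
}

# rescale stripe parameters for one ramp step
apply_delta <- function(params, mode, delta, region) {
  switch(mode,
    basal_decrease = scale_region_params(params, region,
                                         T_b = 1 + delta, Lambda_b = 1 + delta),
    lateral_increase = scale_region_params(params, region, T_l = 1 + delta),
    apical_increase = scale_region_params(params, region,
                                          T_a = 1 + delta, Lambda_a = 1 + delta))
}

#' Run a quasistatic tension ramp
#'
#' For each grid magnitude the stripe parameters are rescaled and the tissue
#' re-relaxed, warm-started from the previous equilibrium (this defines the
#' quasistatic branch being followed). The fold cross-section geometry is
#' measured at every step.
#'
#' @param mesh A relaxed `tissue_mesh` with an assigned stripe (equilibrium
#'   at `delta = 0`).
#' @param params Baseline [mech_params()].
#' @param protocol A [ramp_protocol()].
#' @param tol Relaxation force tolerance per step.
#' @param replicates Number of replicate simulations; replicates differ by a
#'   seeded vertex perturbation (amplitude `perturb_amplitude`) applied and
#'   re-relaxed at `delta = 0` before ramping.
#' @param perturb_amplitude Replicate perturbation amplitude.
#' @param seed Base seed for replicate perturbations.
#' @param section_offset Position of the measurement cross-section plane
#'   (defaults to a plane through cell interiors).
#' @param keep_meshes `"last"` (default), `"all"`, or `"none"`.
#' @return A `fold_ramp` object; [tidy()] returns the per-step geometry
#'   table `(replicate, delta, d_a, d_b, l_a, l_b, h_tissue, normalized
#'   copies, energy, max_force, vol_violation)`.
#' @export
run_ramp <- function(mesh, params, protocol, tol = 1e-6, replicates = 1,
                     perturb_amplitude = 0.01, seed = 1,
                     section_offset = NULL, keep_meshes = c("last", "all", "none")) {
  keep_meshes <- match.arg(keep_meshes)
  stopifnot(inherits(protocol, "ramp_protocol"))
  steps <- list()
  meshes <- list()
  for (rep_i in seq_len(replicates)) {
    m <- mesh
    if (replicates > 1 || perturb_amplitude > 0 && rep_i > 1) {
      m <- perturb_mesh(m, amplitude = perturb_amplitude, seed = seed + rep_i - 1L)
      m <- relax_tissue(m, params, tol = tol)
    }
    for (si in seq_along(protocol$grid)) {
      delta <- protocol$grid[si]
      p_step <- apply_delta(params, protocol$mode, delta, protocol$region)
      m <- tryCatch(
        relax_tissue(m, p_step, tol = tol),
        epifold_convergence_error = function(e) {
          abort(paste0(conditionMessage(e),
                       sprintf(" [ramp %s at delta = %.4g]", protocol$mode, delta)),
                class = "epifold_convergence_error", report = e$report)
        })
      fg <- measure_fold_geometry(
        extract_cross_section(m, offset = section_offset))
      rep_row <- dplyr::bind_cols(
        tibble(replicate = rep_i, delta = delta),
        fg,
        glance(m)[, c("energy", "max_force", "vol_violation")])
      steps[[length(steps) + 1L]] <- rep_row
      if (keep_meshes == "all") meshes[[length(meshes) + 1L]] <- m
    }
    if (keep_meshes == "last") meshes[[rep_i]] <- m
  }
  structure(list(steps = dplyr::bind_rows(steps), protocol = protocol,
                 params = params, meshes = meshes),
            class = "fold_ramp")
}

#' @export
print.fold_ramp <- function(x, ...) {
  cat("<fold_ramp> mode ", x$protocol$mode, ", ",
      length(x$protocol$grid), " steps, ",
      max(x$steps$replicate), " replicate(s)\n", sep = "")
  last <- dplyr::slice_tail(x$steps, n = 1)
  cat(sprintf("  final |delta| = %.3g: d_a/h = %.3f, d_b/h = %.3f, l_b/h = %.3f\n",
              abs(last$delta), last$d_a_norm, last$d_b_norm, last$l_b_norm))
  invisible(x)
}

#' @method tidy fold_ramp
#' @export
tidy.fold_ramp <- function(x, ...) x$steps

#' Per-step ramp summary across replicates (mean and s.e.m.)
#'
#' @param x A `fold_ramp`.
#' @param ... Unused.
#' @return Tibble with one row per delta step and `mean`/`sem` columns for
#'   each geometric readout.
#' @method glance fold_ramp
#' @export
glance.fold_ramp <- function(x, ...) {
  x$steps |>
    tidyr::pivot_longer(cols = c("d_a", "d_b", "l_a", "l_b", "h_tissue",
                                 "d_a_norm", "d_b_norm", "l_a_norm", "l_b_norm"),
                        names_to = "quantity") |>
    dplyr::group_by(.data$delta, .data$quantity) |>
    dplyr::summarise(mean = mean(.data$value),
                     sem = stats::sd(.data$value) / sqrt(dplyr::n()),
                     n = dplyr::n(), .groups = "drop")
}
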