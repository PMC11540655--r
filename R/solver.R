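# Total-Lagrangian explicit dynamics: force assembly, lumped mass, stable
# time step, damped central-difference stepping and dynamic relaxation.
#
# Unit conventions: lengths mm, stresses kPa, forces mN, energies uJ,
# masses kg, time s. With these, acceleration = force/mass is in mm/s^2.

#' Create a simulation state
#'
#' Nodal displacements and velocities start at zero. Nodes in the domain's
#' `fixed_external` boundary set are fixed (u = 0, all components);
#' additional degrees of freedom can be prescribed to targets (the
#' constraint sets are kept disjoint, with fixed taking precedence).
#'
#' @param domain A `bs_domain`.
#' @param fix Name of the boundary node set to fix, or `NULL` for none.
#' @return Object of class `bs_sim_state` with fields `u`, `v` (n x 3, mm
#'   and mm/s), `time` (s), `fixed_dof`, `prescribed_dof`,
#'   `prescribed_target`, and needle bookkeeping used by the insertion
#'   procedure.
#' @export
sim_state <- function(domain, fix = "fixed_external") {
  n <- nrow(domain$nodes)
  fixed_nodes <- if (is.null(fix)) integer(0) else domain$boundary[[fix]]
  structure(list(u = matrix(0, n, 3), v = matrix(0, n, 3), time = 0,
                 fixed_dof = node_dofs(fixed_nodes, n),
                 prescribed_dof = integer(0),
                 prescribed_target = numeric(0),
                 tip_depth = numeric(0),
                 n_nodes = n),
            class = "bs_sim_state")
}

# dof index (1-based, column-major n x 3 layout) for nodes x components
node_dofs <- function(nodes, n, comps = 1:3) {
  as.integer(outer(nodes, (comps - 1) * n, "+"))
}

#' @export
print.bs_sim_state <- function(x, ...) {
  umag <- sqrt(rowSums(x$u^2))
  cat("<bs_sim_state> ", x$n_nodes, " nodes, t=", format(x$time), " s\n",
      sep = "")
  cat(sprintf("  |u|: mean %.4f mm, max %.4f mm; %d fixed dof, %d prescribed dof\n",
              mean(umag), max(umag), length(x$fixed_dof),
              length(x$prescribed_dof)))
  if (length(x$tip_depth) > 0) {
    cat("  needles at depth:", paste(names(x$tip_depth),
                                     round(x$tip_depth, 1), sep = "=",
                                     collapse = ", "), "\n")
  }
  invisible(x)
}

# merged constraint arrays (0-based dofs) for the compiled kernels; fixed
# dofs win over prescribed ones
state_constraints <- function(state, extra_dof = integer(0),
                              extra_target = numeric(0)) {
  dof <- c(state$fixed_dof, state$prescribed_dof, extra_dof)
  tgt <- c(rep(0, length(state$fixed_dof)), state$prescribed_target,
           extra_target)
  keep <- !duplicated(dof)
  list(dof = as.integer(dof[keep]) - 1L, target = tgt[keep])
}

#' Assemble internal nodal forces
#'
#' Total-Lagrangian assembly: at every integration point the deformation
#' gradient `F = I + sum_a u_a (x) grad0 phi_a` is formed, the first
#' Piola-Kirchhoff stress evaluated, and `w_ip P grad0 phi_a` scattered to
#' the supporting nodes. Forces vanish identically for rigid translations.
#'
#' @param state A `bs_sim_state` (or an n x 3 displacement matrix).
#' @param shape A `bs_shape_table`.
#' @param field A `bs_material_field`.
#' @param domain A `bs_domain`.
#' @return n x 3 matrix of internal forces (mN), with attributes `energy`
#'   (total strain energy, uJ) and `J_min` (smallest Jacobian determinant).
#' @export
internal_forces <- function(state, shape, field, domain) {
  u <- if (inherits(state, "bs_sim_state")) state$u else as.matrix(state)
  eff <- effective_moduli(field)
  res <- cpp_internal_forces(u, shape$ip$ptr - 1L, shape$ip$idx - 1L,
                             shape$ip$gx, shape$ip$gy, shape$ip$gz,
                             domain$ip_weight, eff$mu, eff$kappa)
  if (res$bad_ip > 0) {
    stop("inverted element (det F <= 0) at integration point ", res$bad_ip,
         call. = FALSE)
  }
  structure(res$f, energy = res$energy, J_min = res$J_min)
}

#' Total strain energy of a state
#'
#' @inheritParams internal_forces
#' @return Total strain energy in microjoule.
#' @export
total_strain_energy <- function(state, shape, field, domain) {
  attr(internal_forces(state, shape, field, domain), "energy")
}

#' Row-sum lumped nodal masses
#'
#' `m_a = sum_q w_q rho_q phi_a(X_q)` over a mass quadrature. The default
#' places the quadrature points at the nodes themselves with lattice
#' (Voronoi) volume weights: because the MMLS shape functions are
#' interpolating, `phi_a(X_b) = delta_ab` to 1e-6 and the row sum collapses
#' to `m_a = rho_a w_a` — exactly `rho h^3` at interior nodes, halved per
#' boundary face, always positive and exactly mass-conserving.
#'
#' `points = "integration_points"` instead row-sums over the Galerkin
#' integration points. The cardinal functions of the interpolating MMLS
#' integrate slightly negative at block corners, so this variant can
#' produce non-positive entries; with `positivity = "repair"` (default)
#' such entries are raised to a tenth of the median mass and the excess
#' removed proportionally elsewhere, keeping the total exact;
#' `positivity = "error"` raises a discretisation error instead.
#'
#' @param domain A `bs_domain`.
#' @param shape A `bs_shape_table`.
#' @param field A `bs_material_field`.
#' @param points Mass quadrature: `"nodes"` (default, delta-collocation) or
#'   `"integration_points"` (row sum over the Galerkin points).
#' @param positivity `"repair"` (default) or `"error"`; only relevant for
#'   the integration-point variant.
#' @return Numeric vector of nodal masses in kg.
#' @export
lumped_mass <- function(domain, shape, field,
                        points = c("nodes", "integration_points"),
                        positivity = c("repair", "error")) {
  points <- match.arg(points)
  positivity <- match.arg(positivity)
  if (points == "nodes") {
    # lattice volume share: h^3, halved for each block face the node sits on
    ext <- domain$block_dims
    lo <- apply(domain$nodes, 2, min)
    nb <- 0L
    for (i in 1:3) {
      on_face <- domain$nodes[, i] < lo[i] + 1e-9 |
        domain$nodes[, i] > lo[i] + ext[i] - 1e-9
      nb <- nb + as.integer(on_face)
    }
    w_node <- domain$spacing^3 / 2^nb
    rho_node <- vapply(domain$node_region,
                       function(r) field$materials[[r]]$rho, 0)
    return(unname(w_node * rho_node * 1e-9))
  }
  ip <- shape$ip
  m_ip <- domain$ip_weight * field$rho * 1e-9  # mm^3 * kg/m^3 -> kg
  ent <- rep(seq_len(length(ip$ptr) - 1L), diff(ip$ptr))
  contrib <- ip$phi * m_ip[ent]
  masses <- rowsum_full(contrib, ip$idx, nrow(domain$nodes))
  floor_m <- 0.1 * stats::median(masses)
  low <- masses < floor_m
  if (any(low)) {
    if (positivity == "error" && any(masses <= 0)) {
      stop("discretisation error: non-positive lumped mass at node ",
           which(masses <= 0)[1], call. = FALSE)
    }
    total <- sum(masses)
    masses[low] <- floor_m
    excess <- sum(masses) - total
    masses[!low] <- masses[!low] * (1 - excess / sum(masses[!low]))
  }
  masses
}

#' Stable explicit time step
#'
#' CFL-type bound `dt = safety * h_min / c_max` with the dilatational wave
#' speed `c = sqrt((kappa + 4 mu/3) / rho)` evaluated with the effective
#' (stiffened) moduli at every integration point.
#'
#' @param domain A `bs_domain`.
#' @param field A `bs_material_field`.
#' @param masses Unused; accepted so the signature mirrors the stepping API.
#' @param safety Safety factor, default 0.5.
#' @return Time step in seconds.
#' @export
stable_timestep <- function(domain, field, masses = NULL, safety = 0.5) {
  eff <- effective_moduli(field)
  # kPa / (kg/m^3) = 1e3 m^2/s^2; convert to mm/s
  c_mm <- 1e3 * sqrt(1e3 * (eff$kappa + 4 * eff$mu / 3) / field$rho)
  safety * domain$spacing / max(c_mm)
}

#' One damped central-difference step
#'
#' `v <- ((1 - a dt/2) v + dt f/m) / (1 + a dt/2)`, `u <- u + dt v`, with
#' mass-proportional damping `a`. Fixed degrees of freedom stay at zero and
#' prescribed ones are snapped to their targets after the update.
#'
#' @param state A `bs_sim_state`.
#' @param forces n x 3 applied force matrix (mN); note the equation of
#'   motion is `m a = -f_int`, so pass internal forces directly.
#' @param masses Nodal masses (kg).
#' @param dt Time step (s); must not exceed [stable_timestep()].
#' @param damping Mass-proportional damping coefficient (1/s).
#' @return The updated `bs_sim_state`.
#' @export
step_state <- function(state, forces, masses, dt, damping = 0) {
  stopifnot(inherits(state, "bs_sim_state"))
  con <- state_constraints(state)
  res <- cpp_step(state$u, state$v, as.matrix(forces), masses, dt, damping,
                  con$dof, con$target)
  if (any(!is.finite(res$u))) {
    stop("divergence error: non-finite displacement after step; ",
         "reduce dt below the stable limit", call. = FALSE)
  }
  state$u <- res$u
  state$v <- res$v
  state$time <- state$time + dt
  state
}

#' Relax a state to quasi-static equilibrium
#'
#' Damped explicit stepping until the maximum nodal displacement increment
#' over a 50-step window falls below `tol`, or `max_iter` steps. Velocities
#' are reset to zero on entry (standard dynamic relaxation restart).
#'
#' @param state A `bs_sim_state`.
#' @param shape,field,domain Discretisation and material context.
#' @param masses Nodal masses from [lumped_mass()].
#' @param dt Time step; defaults to [stable_timestep()].
#' @param damping Mass-proportional damping (1/s). `NULL` (default) starts
#'   at `0.05 / dt` and then adapts each window to twice the
#'   Rayleigh-quotient estimate of the slowest active mode — the standard
#'   dynamic-relaxation tuning, which also handles the near-zero-energy
#'   modes of single-point cell quadrature. A numeric value fixes the
#'   damping (used by the dynamic-accuracy tests).
#' @param tol Convergence tolerance on the windowed displacement increment,
#'   mm. Default 1e-3.
#' @param window Steps per convergence check. Default 50.
#' @param max_iter Iteration cap. Default 5000.
#' @param mass_scaling Uniform factor applied to the masses (quasi-static
#'   runs only); the usable time step grows with its square root.
#' @param extra_dof,extra_target Additional prescribed constraints (1-based
#'   dof indices) active during this relaxation only.
#' @param alpha_init Starting value for the adaptive damping (1/s); used to
#'   warm-start successive relaxations of a slowly changing problem.
#' @param warn Emit a warning when the iteration cap is reached. Incremental
#'   drivers that deliberately bound the per-increment effort disable this
#'   and check convergence at the end of the motion instead.
#' @param ramp Number of initial steps over which prescribed targets are
#'   approached linearly from the current state (0 = applied
#'   instantaneously). Ramping avoids constraint shock next to stiff or
#'   pre-strained regions.
#' @return List with the updated `state` and a one-row tibble `report`
#'   (iterations, converged flag, final displacement-increment norm, final
#'   kinetic energy).
#' @export
relax_to_equilibrium <- function(state, shape, field, domain, masses,
                                 dt = NULL, damping = NULL, tol = 1e-3,
                                 window = 50, max_iter = 5000,
                                 mass_scaling = 1,
                                 extra_dof = integer(0),
                                 extra_target = numeric(0),
                                 alpha_init = NULL, warn = TRUE,
                                 ramp = 0) {
  stopifnot(inherits(state, "bs_sim_state"))
  if (is.null(dt)) {
    dt <- stable_timestep(domain, field) * sqrt(mass_scaling)
  }
  adaptive <- is.null(damping)
  if (adaptive) damping <- if (!is.null(alpha_init)) alpha_init else 0.05 / dt
  eff <- effective_moduli(field)
  con <- state_constraints(state, extra_dof, extra_target)
  res <- cpp_relax(state$u, shape$ip$ptr - 1L, shape$ip$idx - 1L,
                   shape$ip$gx, shape$ip$gy, shape$ip$gz,
                   domain$ip_weight, eff$mu, eff$kappa,
                   masses * mass_scaling, dt, damping,
                   con$dof, con$target, tol, as.integer(window),
                   as.integer(max_iter), adaptive, as.integer(ramp))
  if (res$bad_ip > 0) {
    stop("inverted element (det F <= 0) at integration point ", res$bad_ip,
         " during relaxation", call. = FALSE)
  }
  if (res$diverged) {
    stop("divergence error: non-finite displacements during relaxation; ",
         "reduce dt", call. = FALSE)
  }
  report <- tibble::tibble(iterations = res$iterations,
                           converged = res$converged,
                           final_incr = res$final_incr,
                           kinetic_energy = res$kinetic_energy,
                           alpha_final = res$alpha_final)
  if (!res$converged && warn) {
    warning("relaxation did not converge within ", max_iter,
            " iterations (increment ", format(res$final_incr, digits = 3),
            " mm)", call. = FALSE)
  }
  state$u <- res$u
  state$v <- res$v
  state$time <- state$time + res$iterations * dt
  list(state = state, report = report)
}
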