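# Kinematic needle insertion: tip-following displacement, anchor and
# catheter stiffening, and orchestration of the sequential procedure.

#' Insertion configuration
#'
#' @param influence_radius Radius of the tip-following region, mm; must
#'   exceed the largest needle radius. Default 3 (about four catheter
#'   radii).
#' @param decay Radial decay of the displacement weight between the needle
#'   surface and the influence radius: `"linear"` (default) or
#'   `"exponential"`.
#' @param increment Advance per insertion increment, mm. Default 2.
#' @param stiffening_factor Multiplicative stiffening applied behind anchors
#'   and around placed catheters. Default 30.
#' @param catheter_stiffening_radius Radius of the stiffened sleeve around a
#'   placed catheter, mm. Default 2.
#' @param anchor_region_rule Geometry of the anchor-stiffened region; the
#'   single built-in rule stiffens surrounding tissue in the half-space
#'   distal to the anchors' tip plane.
#' @param bore_retention Shaft-adhesion factor in `[0, 1]`: the fraction of
#'   the tip-passage drive retained when a node inside the needle bore is
#'   permanently captured. 1 freezes nodes at their driven peak (full
#'   stick, which compounds the axial drag of successive captures), 0
#'   captures at the fully relaxed position (full slip, leaving almost no
#'   residual deformation). Default 0.5 (partial slip).
#' @return Object of class `bs_insertion_config`.
#' @export
insertion_config <- function(influence_radius = 3,
                             decay = c("linear", "exponential"),
                             increment = 2,
                             stiffening_factor = 30,
                             catheter_stiffening_radius = 2,
                             anchor_region_rule = "behind_tip_surrounding",
                             bore_retention = 0.5) {
  decay <- match.arg(decay)
  stopifnot(influence_radius > 0, increment > 0, stiffening_factor >= 1,
            catheter_stiffening_radius > 0,
            bore_retention >= 0, bore_retention <= 1)
  structure(list(influence_radius = influence_radius, decay = decay,
                 increment = increment,
                 stiffening_factor = stiffening_factor,
                 catheter_stiffening_radius = catheter_stiffening_radius,
                 anchor_region_rule = anchor_region_rule,
                 bore_retention = bore_retention),
            class = "bs_insertion_config")
}

# distance from points (k x 3) to the segment [a, a + L*d] (d unit)
dist_to_segment <- function(points, a, d, L) {
  rel <- sweep(points, 2, a)
  t <- pmin(pmax(rel %*% d, 0), L)
  dvec <- rel - outer(as.vector(t), as.vector(d))
  sqrt(rowSums(dvec^2))
}

needle_entry <- function(needle) {
  c(needle$entry_x, needle$entry_y, needle$entry_z)
}
needle_dir <- function(needle) {
  c(needle$dir_x, needle$dir_y, needle$dir_z)
}

#' Tip-following displacement weight
#'
#' Weight of the kinematic tip-following rule for material points near a
#' needle whose tip has penetrated to `tip_depth`: 1 on and inside the
#' needle surface (distance to the penetrated axis segment at most the
#' needle radius), decaying to 0 at the influence radius, and 0 beyond it —
#' in particular for points distal to the tip plane by more than the
#' influence radius.
#'
#' @param points k x 3 matrix of reference coordinates (mm), or length-3
#'   vector.
#' @param needle One needle (a row of a [generate_needle_plan()] tibble).
#' @param tip_depth Current penetration depth, mm, in
#'   `[0, needle$depth_mm]`.
#' @param cfg An [insertion_config()].
#' @return Numeric weights in `[0, 1]`.
#' @export
tip_influence <- function(points, needle, tip_depth, cfg) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(tip_depth >= 0, tip_depth <= needle$depth_mm + 1e-9)
  a <- needle$radius_mm
  R <- cfg$influence_radius
  if (R <= a) {
    stop("influence_radius must exceed the needle radius", call. = FALSE)
  }
  if (tip_depth == 0) return(rep(0, nrow(points)))
  r <- dist_to_segment(points, needle_entry(needle), needle_dir(needle),
                       tip_depth)
  w <- numeric(nrow(points))
  w[r <= a] <- 1
  mid <- r > a & r < R
  rt <- (r[mid] - a) / (R - a)
  w[mid] <- switch(cfg$decay,
                   linear = 1 - rt,
                   exponential = (exp(-3 * rt) - exp(-3)) / (1 - exp(-3)))
  w
}

#' Advance a needle by one increment
#'
#' Increases the tip depth by `delta_d` (clamped at the needle's full
#' depth), prescribes the displacement increment `w * delta_d * direction`
#' on all nodes with positive tip-following weight (composed with their
#' accumulated motion), relaxes the free nodes to equilibrium, then releases
#' the temporarily prescribed nodes. Nodes inside the needle bore stay
#' permanently prescribed while the needle is present.
#'
#' The drive is tip-local: the per-increment weight is evaluated on the
#' trailing tip segment (from one influence radius behind the previous tip
#' position to the new tip), so material points are carried while the tip
#' passes them and released once it has moved on; tissue alongside the
#' shaft further back is not dragged again on later increments. The drive
#' is kinematic and overrides the material: stiffened regions near the tip
#' move with it like everything else (prescribing motion only to soft
#' nodes would shear the gaps between driven and held material); the
#' stiffening governs the free elastic response instead. Nodes permanently
#' captured by earlier needle bores keep their constraints.
#'
#' @param state A `bs_sim_state`.
#' @param needle One row of a needle plan.
#' @param delta_d Advance, mm.
#' @param cfg An [insertion_config()].
#' @param ctx A [solver_context()].
#' @return List with updated `state` and a one-row relaxation `report`.
#' @export
advance_needle <- function(state, needle, delta_d, cfg, ctx) {
  stopifnot(inherits(state, "bs_sim_state"), delta_d >= 0)
  id <- needle$needle_id
  prev <- if (id %in% names(state$tip_depth)) state$tip_depth[[id]] else 0
  new_depth <- min(prev + delta_d, needle$depth_mm)
  dd <- new_depth - prev
  if (dd == 0) {
    return(list(state = state,
                report = tibble::tibble(iterations = 0L, converged = TRUE,
                                        final_incr = 0,
                                        kinetic_energy = 0)))
  }
  dirv <- needle_dir(needle)
  # tip-local drive weight: radial law of tip_influence, but measured from
  # the trailing tip segment of this increment only
  seg_start <- max(0, prev - cfg$influence_radius)
  r <- dist_to_segment(ctx$domain$nodes,
                       needle_entry(needle) + seg_start * dirv,
                       dirv, new_depth - seg_start)
  a <- needle$radius_mm
  R <- cfg$influence_radius
  w <- numeric(length(r))
  w[r <= a] <- 1
  mid <- r > a & r < R
  rt <- (r[mid] - a) / (R - a)
  w[mid] <- switch(cfg$decay,
                   linear = 1 - rt,
                   exponential = (exp(-3 * rt) - exp(-3)) / (1 - exp(-3)))
  act <- which(w > 0)
  n <- state$n_nodes
  # temporary targets: current displacement plus the axial tip-following
  # increment; nodes already permanently prescribed keep their constraints
  tmp_dof <- node_dofs(act, n)
  tmp_target <- as.numeric(state$u[act, ] +
                             outer(w[act] * dd, dirv))
  cap <- ctx$increment_max_iter %||% ctx$max_iter
  res <- relax_core(state, ctx, tmp_dof, tmp_target, cap,
                    ramp = ctx$ramp %||% 100)
  u_driven <- res$state$u
  state <- res$state
  state$tip_depth[[id]] <- new_depth
  # release the tip-following constraints and re-equilibrate, then capture
  # bore nodes at the released position plus the retained fraction of the
  # tip-passage drive. Freezing at the driven peak (retention 1) compounds
  # the axial drag of successive captures; capturing fully relaxed
  # (retention 0) lets the tissue slide off the shaft entirely.
  rbore <- dist_to_segment(ctx$domain$nodes, needle_entry(needle), dirv,
                           new_depth)
  bore <- which(rbore <= needle$radius_mm)
  new_bore <- setdiff(node_dofs(bore, n), state$prescribed_dof)
  if (length(new_bore) == 0) {
    # no node enters the bore on this increment: nothing to capture, so
    # the release-equilibration can wait for the next capture or the
    # end-of-needle relaxation
    return(list(state = state, report = res$report))
  }
  res2 <- relax_core(state, ctx, integer(0), numeric(0), cap)
  state <- res2$state
  beta0 <- cfg$bore_retention %||% 0.5
  if (length(bore) > 0) {
    u_rel <- state$u[bore, , drop = FALSE]
    # captured positions must not jam the tissue near collapse: accept the
    # retained fraction only while the configuration keeps a healthy
    # Jacobian margin, otherwise fall back towards the released state
    # (tissue slips along the shaft instead of collapsing)
    jmin_rel <- cpp_internal_forces(state$u, ctx$csr0$ptr, ctx$csr0$idx,
                                    ctx$shape$ip$gx, ctx$shape$ip$gy,
                                    ctx$shape$ip$gz, ctx$domain$ip_weight,
                                    ctx$eff$mu, ctx$eff$kappa)$J_min
    j_ok <- max(0.1, 0.5 * jmin_rel)
    for (beta in c(beta0, beta0 / 2, 0)) {
      btar_m <- u_rel + beta * (u_driven[bore, , drop = FALSE] - u_rel)
      u_try <- state$u
      u_try[bore, ] <- btar_m
      chk <- cpp_internal_forces(u_try, ctx$csr0$ptr, ctx$csr0$idx,
                                 ctx$shape$ip$gx, ctx$shape$ip$gy,
                                 ctx$shape$ip$gz, ctx$domain$ip_weight,
                                 ctx$eff$mu, ctx$eff$kappa)
      if (chk$bad_ip == 0 && chk$J_min >= j_ok) break
    }
    state$u[bore, ] <- btar_m
    bdof <- node_dofs(bore, n)
    btar <- as.numeric(btar_m)
    keep <- !(state$prescribed_dof %in% bdof)
    state$prescribed_dof <- c(state$prescribed_dof[keep], bdof)
    state$prescribed_target <- c(state$prescribed_target[keep], btar)
  }
  report <- res$report
  report$iterations <- report$iterations + res2$report$iterations
  report$converged <- res2$report$converged
  report$final_incr <- res2$report$final_incr
  list(state = state, report = report)
}

#' Apply anchor-needle stiffening
#'
#' After both anchors are at full depth, surrounding-tissue integration
#' points distal to the anchors' tip plane (along the insertion axis) have
#' their stiffening scale raised to the configured factor. Prostate points
#' are never modified; composition is by maximum, so repeated application is
#' idempotent.
#'
#' @param field A `bs_material_field`.
#' @param anchors Needle-plan rows of type `"anchor"` (at final depth).
#' @param domain A `bs_domain`.
#' @param cfg An [insertion_config()].
#' @return The updated `bs_material_field`.
#' @export
apply_anchor_stiffening <- function(field, anchors, domain, cfg) {
  stopifnot(inherits(field, "bs_material_field"), nrow(anchors) >= 1)
  i <- axis_index(domain$insertion_axis)
  sgn <- sign(domain$insertion_axis[i])
  # tip coordinate along the travel direction; the plane of the deepest tip
  tips <- anchors[[c("entry_x", "entry_y", "entry_z")[i]]] +
    sgn * anchors$depth_mm
  plane <- if (sgn > 0) max(tips) else min(tips)
  ax <- domain$ip_coords[, i]
  distal <- if (sgn > 0) ax > plane else ax < plane
  sel <- distal & domain$ip_region == "surrounding"
  field$scale[sel] <- pmax(field$scale[sel], cfg$stiffening_factor)
  field
}

#' Apply placed-catheter stiffening
#'
#' Integration points within the catheter stiffening radius of a placed
#' catheter's full path get their scale raised to the configured factor
#' (max-composition: overlapping sleeves never compound).
#'
#' @param field A `bs_material_field`.
#' @param placed One needle-plan row (catheter at final depth).
#' @param cfg An [insertion_config()].
#' @param domain A `bs_domain`.
#' @return The updated `bs_material_field`.
#' @export
apply_catheter_stiffening <- function(field, placed, cfg, domain) {
  stopifnot(inherits(field, "bs_material_field"))
  r <- dist_to_segment(domain$ip_coords, needle_entry(placed),
                       needle_dir(placed), placed$depth_mm)
  sel <- r <= cfg$catheter_stiffening_radius
  field$scale[sel] <- pmax(field$scale[sel], cfg$stiffening_factor)
  field
}

#' Precompute the solver context for a domain
#'
#' Bundles the shape table, material field, lumped masses, stable time step
#' and relaxation controls used by [advance_needle()] and [run_procedure()].
#'
#' @param domain A `bs_domain`.
#' @param shape Optional precomputed [build_shape_table()].
#' @param field Optional [material_field()]; defaults to
#'   [default_materials()].
#' @param safety Time-step safety factor.
#' @param tol,window,max_iter Relaxation controls, see
#'   [relax_to_equilibrium()].
#' @param increment_max_iter Iteration budget for the relaxation after each
#'   individual advance increment (the needle advances at a finite rate);
#'   the state is fully relaxed to `tol` with budget `max_iter` once a
#'   needle reaches its final depth. Default 150.
#' @param mass_scaling Uniform mass scaling for quasi-static relaxation.
#: placeholder
#' @return Object of class `bs_solver_context`.
#' @export
solver_context <- function(domain, shape = NULL, field = NULL, safety = 0.5,
                           tol = 1e-3, window = 50, max_iter = 5000,
                           increment_max_iter = 150,
                           mass_scaling = 1, damping = NULL) {
  if (is.null(shape)) shape <- build_shape_table(domain)
  if (is.null(field)) field <- material_field(domain)
  base_masses <- lumped_mass(domain, shape, field)
  csr0 <- list(ptr = shape$ip$ptr - 1L, idx = shape$ip$idx - 1L)
  ctx <- structure(list(domain = domain, shape = shape, field = field,
                        csr0 = csr0,
                        base_masses = base_masses, masses = base_masses,
                        dt = NA_real_, damping = damping,
                        safety = safety, tol = tol, window = window,
                        max_iter = max_iter,
                        increment_max_iter = increment_max_iter,
                        mass_scaling = mass_scaling),
                   class = "bs_solver_context")
  refresh_context(ctx, field)
}

# Refresh effective masses and dt after a stiffening change. Stiffened
# regions get their nodal masses scaled by the local stiffening factor
# (selective mass scaling, quasi-static only): the local wave speed is then
# unchanged and the stable time step stays at its unstiffened value instead
# of shrinking by sqrt(stiffening_factor).
refresh_context <- function(ctx, field) {
  ctx$field <- field
  node_scale <- rep(1, length(ctx$base_masses))
  if (any(field$scale > 1)) {
    ip <- ctx$shape$ip
    ent <- rep(seq_len(length(ip$ptr) - 1L), diff(ip$ptr))
    agg <- tapply(field$scale[ent], ip$idx, max)
    node_scale[as.integer(names(agg))] <- pmax(
      node_scale[as.integer(names(agg))], agg)
  }
  ctx$node_scale <- node_scale
  # narrow stiffness flag for the kinematic drive: a node counts as part of
  # a stiffened region only if a stiffened integration point lies within
  # its own lattice cell neighbourhood (the mass-scaling map above uses the
  # full support adjacency, which is deliberately broad for stability)
  node_stiff <- rep(FALSE, length(ctx$base_masses))
  stiff_ips <- which(field$scale > 1)
  if (length(stiff_ips) > 0) {
    near <- cpp_radius_neighbors(
      ctx$domain$ip_coords[stiff_ips, , drop = FALSE],
      ctx$domain$nodes, rep(0.9 * ctx$domain$spacing,
                            nrow(ctx$domain$nodes)))
    node_stiff <- diff(near$ptr) > 0
  }
  ctx$node_stiff <- node_stiff
  ctx$masses <- ctx$base_masses * node_scale
  ctx$eff <- effective_moduli(field)
  # dt from the unstiffened moduli: mass scaling keeps the local wave speed
  # of stiffened regions at its base value
  base_field <- field
  base_field$scale <- rep(1, length(field$scale))
  ctx$dt <- stable_timestep(ctx$domain, base_field, safety = ctx$safety) *
    sqrt(ctx$mass_scaling)
  ctx
}

# fast relaxation path for the insertion driver: reuses the context's
# cached 0-based CSR, effective moduli and masses instead of rebuilding
# them on every increment
relax_core <- function(state, ctx, extra_dof, extra_target, max_iter,
                       warn = FALSE, ramp = 0) {
  dt <- ctx$dt
  adaptive <- is.null(ctx$damping)
  alpha0 <- if (!adaptive) ctx$damping
            else if (!is.null(ctx$alpha_state)) ctx$alpha_state
            else 0.05 / dt
  con <- state_constraints(state, extra_dof, extra_target)
  res <- cpp_relax(state$u, ctx$csr0$ptr, ctx$csr0$idx,
                   ctx$shape$ip$gx, ctx$shape$ip$gy, ctx$shape$ip$gz,
                   ctx$domain$ip_weight, ctx$eff$mu, ctx$eff$kappa,
                   ctx$masses * ctx$mass_scaling, dt, alpha0,
                   con$dof, con$target, ctx$tol, as.integer(ctx$window),
                   as.integer(max_iter), adaptive, as.integer(ramp))
  if (res$bad_ip > 0) {
    stop("inverted element (det F <= 0) at integration point ", res$bad_ip,
         " during relaxation", call. = FALSE)
  }
  if (res$diverged) {
    stop("divergence error: non-finite displacements during relaxation",
         call. = FALSE)
  }
  if (!res$converged && warn) {
    warning("relaxation did not converge within ", max_iter, " iterations",
            call. = FALSE)
  }
  state$u <- res$u
  state$v <- res$v
  state$time <- state$time + res$iterations * dt
  list(state = state,
       report = tibble::tibble(iterations = res$iterations,
                               converged = res$converged,
                               final_incr = res$final_incr,
                               kinetic_energy = res$kinetic_energy,
                               alpha_final = res$alpha_final))
}

#' Run the full sequential insertion procedure
#'
#' Needles are processed in `order_index` order. Each needle advances in
#' increments of `cfg$increment` with a dynamic relaxation to quasi-static
#' equilibrium after every increment. After the last anchor reaches full
#' depth the anchor stiffening is applied (unless disabled); after each
#' catheter reaches full depth the placed-catheter stiffening is applied. A
#' displacement snapshot is stored after every completed needle, plus the
#' initial state.
#'
#' @param domain A `bs_domain`.
#' @param plan A [generate_needle_plan()] tibble.
#' @param cfg An [insertion_config()].
#' @param materials Named material list for [material_field()].
#' @param anchor_stiffening Logical; `FALSE` reproduces the
#'   anchors-disabled comparison run.
#' @param ctx Optional prebuilt [solver_context()] (its field is reset to a
#'   fresh material field).
#' @param quiet Suppress per-event progress messages.
#' @return Object of class `bs_procedure_result`: `snapshots` (named list of
#'   n x 3 displacement matrices, `"initial"` plus one per needle), `events`
#'   (tibble of per-event relaxation statistics), the final `field`,
#'   `domain`, `plan`, `cfg` and flags.
#' @export
run_procedure <- function(domain, plan, cfg = insertion_config(),
                          materials = default_materials(),
                          anchor_stiffening = TRUE, ctx = NULL,
                          quiet = TRUE) {
  stopifnot(inherits(plan, "bs_needle_plan") || is.data.frame(plan))
  if (nrow(plan) > 0 && cfg$influence_radius <= max(plan$radius_mm)) {
    stop("influence_radius must exceed every needle radius", call. = FALSE)
  }
  field <- material_field(domain, materials)
  if (is.null(ctx)) {
    ctx <- solver_context(domain, field = field)
  } else {
    ctx <- refresh_context(ctx, field)
  }
  state <- sim_state(domain)
  plan <- plan[order(plan$order_index), ]
  snapshots <- list(initial = state$u)
  events <- list()
  anchors_done <- FALSE
  n_anchor <- sum(plan$type == "anchor")
  failed <- character(0)
  for (k in seq_len(nrow(plan))) {
    needle <- plan[k, ]
    if (!quiet) message("inserting ", needle$needle_id, " (", needle$type,
                        ", depth ", round(needle$depth_mm, 1), " mm)")
    iter_total <- 0L
    conv_all <- TRUE
    last <- NULL
    ok <- TRUE
    while (ok && (is.na(d <- state$tip_depth[needle$needle_id]) ||
                  d < needle$depth_mm - 1e-9 || is.null(last))) {
      res <- NULL
      for (dd in cfg$increment / c(1, 2, 4, 8)) {
        res <- tryCatch(advance_needle(state, needle, dd, cfg, ctx),
                        error = function(e) e)
        if (!inherits(res, "error")) break
      }
      if (inherits(res, "error")) {
        warning("event ", needle$needle_id, " failed: ",
                conditionMessage(res), call. = FALSE)
        failed <- c(failed, needle$needle_id)
        ok <- FALSE
        break
      }
      state <- res$state
      if (!is.null(res$report$alpha_final) &&
          is.finite(res$report$alpha_final)) {
        ctx$alpha_state <- res$report$alpha_final
      }
      iter_total <- iter_total + res$report$iterations
      conv_all <- conv_all && res$report$converged
      last <- res$report
      if (is.null(names(state$tip_depth)) ||
          !(needle$needle_id %in% names(state$tip_depth))) break
    }
    # full equilibration at final depth (increments advance at a bounded
    # per-increment effort)
    if (ok) {
      fin <- tryCatch(
        relax_core(state, ctx, integer(0), numeric(0), ctx$max_iter,
                   warn = TRUE),
        error = function(e) e)
      if (inherits(fin, "error")) {
        warning("final relaxation for ", needle$needle_id, " failed: ",
                conditionMessage(fin), call. = FALSE)
        failed <- c(failed, needle$needle_id)
        ok <- FALSE
      } else {
        state <- fin$state
        iter_total <- iter_total + fin$report$iterations
        conv_all <- fin$report$converged
        last <- fin$report
        if (is.finite(fin$report$alpha_final)) {
          ctx$alpha_state <- fin$report$alpha_final
        }
      }
    }
    snapshots[[needle$needle_id]] <- state$u
    umag <- sqrt(rowSums(state$u^2))
    events[[k]] <- tibble::tibble(
      event = needle$needle_id, type = needle$type,
      order_index = needle$order_index,
      tip_depth = if (needle$needle_id %in% names(state$tip_depth))
        state$tip_depth[[needle$needle_id]] else 0,
      iterations = iter_total, converged = conv_all,
      final_incr = if (!is.null(last)) last$final_incr else NA_real_,
      max_displacement = max(umag), failed = !ok)
    # stiffening events
    if (!anchors_done && needle$type == "anchor" &&
        sum(plan$type[seq_len(k)] == "anchor") == n_anchor) {
      anchors_done <- TRUE
      if (anchor_stiffening && n_anchor > 0) {
        field <- apply_anchor_stiffening(field,
                                         plan[plan$type == "anchor", ],
                                         domain, cfg)
        ctx <- refresh_context(ctx, field)
      }
    }
    if (needle$type == "catheter" && ok) {
      field <- apply_catheter_stiffening(field, needle, cfg, domain)
      ctx <- refresh_context(ctx, field)
    }
  }
  structure(list(snapshots = snapshots,
                 events = if (length(events) > 0) dplyr::bind_rows(events)
                          else tibble::tibble(),
                 state = state, field = field, domain = domain, plan = plan,
                 cfg = cfg, anchor_stiffening = anchor_stiffening,
                 failed_events = failed),
            class = "bs_procedure_result")
}

#' @export
print.bs_procedure_result <- function(x, ...) {
  cat("<bs_procedure_result> ", nrow(x$plan), " insertion events, ",
      length(x$snapshots), " snapshots\n", sep = "")
  if (nrow(x$events) > 0) {
    cat(sprintf("  max displacement %.2f mm; %d/%d events converged; anchor stiffening %s\n",
                max(x$events$max_displacement), sum(x$events$converged),
                nrow(x$events),
                if (x$anchor_stiffening) "on" else "off"))
  }
  if (length(x$failed_events) > 0) {
    cat("  FAILED events:", paste(x$failed_events, collapse = ", "), "\n")
  }
  invisible(x)
}
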