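# Explicit-dynamics solver: assembly, lumping, time step, stepping,
# relaxation.

test_that("internal forces vanish for rigid translations and match virtual work", {
  fx <- fix_phantom()
  dom <- fx$domain
  shp <- fx$shape
  fld <- material_field(dom)
  n <- nrow(dom$nodes)
  f0 <- internal_forces(matrix(0, n, 3), shp, fld, dom)
  expect_identical(max(abs(f0)), 0)
  ft <- internal_forces(matrix(1.7, n, 3), shp, fld, dom)
  expect_lt(max(abs(ft)), 1e-10)
  # virtual-work oracle: f . du equals the directional derivative of the
  # total strain energy
  set.seed(9)
  u <- matrix(rnorm(3 * n, sd = 0.3), n, 3)
  du <- matrix(rnorm(3 * n), n, 3)
  du <- du / sqrt(sum(du^2))
  f <- internal_forces(u, shp, fld, dom)
  eps <- 1e-4
  fd <- (total_strain_energy(u + eps * du, shp, fld, dom) -
           total_strain_energy(u - eps * du, shp, fld, dom)) / (2 * eps)
  expect_lt(abs(sum(f * du) - fd) / abs(fd), 1e-5)
  # inverted element names the integration point
  ubad <- matrix(0, n, 3)
  ubad[, 3] <- -1.1 * dom$nodes[, 3]
  expect_error(internal_forces(ubad, shp, fld, dom), "integration point")
})

test_that("lumped masses conserve mass, scale with density, match the lattice cell", {
  bar <- fix_bar()
  mm <- bar$masses
  expect_true(all(mm > 0))
  v_tot <- sum(bar$domain$ip_weight)
  expect_equal(sum(mm), v_tot * 1000 * 1e-9, tolerance = 1e-10)
  # doubling the density doubles every mass
  fld2 <- material_field(bar$domain,
                         list(surrounding = material(E = 25, nu = 0.49,
                                                     rho = 2000)))
  mm2 <- lumped_mass(bar$domain, bar$shape, fld2)
  expect_equal(mm2, 2 * mm, tolerance = 1e-12)
  # deep-interior nodes carry exactly rho h^3 (symmetric neighbourhood)
  h <- bar$domain$spacing
  ext <- bar$domain$block_dims
  depth <- pmin(bar$domain$nodes[, 1], ext[1] - bar$domain$nodes[, 1],
                bar$domain$nodes[, 2], ext[2] - bar$domain$nodes[, 2],
                bar$domain$nodes[, 3], ext[3] - bar$domain$nodes[, 3])
  deep <- depth >= 4 * h - 1e-9
  expect_gt(sum(deep), 5)
  expect_lt(max(abs(mm[deep] / (1000 * 1e-9 * h^3) - 1)), 0.01)
})

test_that("stable time step follows the CFL bound", {
  fx <- fix_phantom()
  dom <- fx$domain
  fld <- material_field(dom)
  dt0 <- stable_timestep(dom, fld)
  # formula recomputation oracle
  effc <- max(1e3 * sqrt(1e3 * (fld$kappa0 + 4 * fld$mu0 / 3) / fld$rho))
  expect_equal(dt0, 0.5 * dom$spacing / effc)
  expect_gt(dt0, 1e-5)
  expect_lt(dt0, 1e-3)
  # stiffening part of a homogeneous domain by 30 shrinks dt by sqrt(30)
  bar <- fix_bar()
  dtb <- stable_timestep(bar$domain, bar$field)
  fld30 <- bar$field
  fld30$scale[seq_len(100)] <- 30
  expect_lte(stable_timestep(bar$domain, fld30), dtb / sqrt(30) + 1e-15)
  # halving the spacing halves dt
  dom2 <- dom
  dom2$spacing <- dom$spacing / 2
  expect_equal(stable_timestep(dom2, fld), dt0 / 2)
})

test_that("damped central-difference step honours its contracts", {
  fx <- fix_phantom()
  dom <- fx$domain
  st <- sim_state(dom)
  n <- nrow(dom$nodes)
  msk <- rep(1e-5, n)
  # zero forces, zero velocity: state unchanged
  st2 <- step_state(st, matrix(0, n, 3), msk, 1e-4, damping = 100)
  expect_identical(st2$u, st$u)
  # prescribed (free) node snapped to target regardless of forces
  free <- setdiff(seq_len(n), dom$boundary$fixed_external)[1]
  st$prescribed_dof <- node_dofs(free, n)
  st$prescribed_target <- c(0.3, -0.2, 0.1)
  f <- matrix(rnorm(3 * n), n, 3)
  st3 <- step_state(st, f, msk, 1e-4, damping = 0)
  expect_equal(st3$u[free, ], c(0.3, -0.2, 0.1))
  expect_true(all(st3$u[dom$boundary$fixed_external, ] == 0))
})

test_that("a single-mass oscillator reproduces the analytic period", {
  # one free node driven by a linear spring force through step_state
  m <- 0.002  # kg
  k <- 5      # mN/mm
  st <- structure(list(u = matrix(c(1, 0, 0), 1, 3),
                       v = matrix(0, 1, 3), time = 0,
                       fixed_dof = integer(0), prescribed_dof = integer(0),
                       prescribed_target = numeric(0),
                       tip_depth = numeric(0), n_nodes = 1L),
                  class = "bs_sim_state")
  omega <- sqrt(k / m)
  t_exact <- 2 * pi / omega
  dt <- t_exact / 200
  pos <- numeric(2000)
  for (i in seq_along(pos)) {
    f <- matrix(c(k * st$u[1, 1], 0, 0), 1, 3)
    st <- step_state(st, f, m, dt, damping = 0)
    pos[i] <- st$u[1, 1]
  }
  zc <- which(diff(sign(pos)) != 0)
  t_num <- 2 * mean(diff(zc)) * dt
  # leapfrog period error is O(dt^2): (omega dt)^2 / 24 relative
  expect_lt(abs(t_num - t_exact) / t_exact, 4 * (omega * dt)^2 / 24 + 1e-4)
})

test_that("energy decays monotonically under damping with no load", {
  bar <- fix_bar()
  st <- sim_state(bar$domain)
  # smooth displacement modes (kinetic energy is stored at half steps, so
  # a rough white-noise field would show transient exchange artifacts)
  zz <- bar$domain$nodes[, 3] / max(bar$domain$nodes[, 3])
  st$u <- cbind(0.2 * sin(pi * zz) * sin(pi * bar$domain$nodes[, 1] / 20),
                0.1 * sin(pi * zz), 0.2 * sin(2 * pi * zz))
  st$u[bar$domain$boundary$fixed_external, ] <- 0
  dt <- stable_timestep(bar$domain, bar$field, safety = 0.3)
  etot <- numeric(60)
  for (i in seq_along(etot)) {
    f <- internal_forces(st$u, bar$shape, bar$field, bar$domain)
    ke <- 0.5 * sum(bar$masses * rowSums(st$v^2))
    etot[i] <- attr(f, "energy") + ke
    st <- step_state(st, f, bar$masses, dt, damping = 0.05 / dt)
  }
  expect_true(all(diff(etot) <= 1e-10 * etot[1]))
  expect_lt(etot[60], 0.2 * etot[1])
})

test_that("relaxation converges immediately for an unloaded state", {
  fx <- fix_phantom()
  dom <- fx$domain
  fld <- material_field(dom)
  mm <- lumped_mass(dom, fx$shape, fld)
  res <- relax_to_equilibrium(sim_state(dom), fx$shape, fld, dom, mm)
  expect_true(res$report$converged)
  expect_lte(res$report$iterations, 50)
  expect_lt(max(abs(res$state$u)), 1e-12)
})

test_that("fixed inputs give bit-identical relaxation trajectories", {
  bar <- fix_bar()
  n <- nrow(bar$domain$nodes)
  z <- bar$domain$nodes[, 3]
  top <- which(z > max(z) - 1e-9)
  ed <- node_dofs(top, n, comps = 3)
  run_once <- function() {
    relax_to_equilibrium(sim_state(bar$domain, fix = NULL), bar$shape,
                         bar$field, bar$domain, bar$masses, tol = 1e-4,
                         max_iter = 600, extra_dof = ed,
                         extra_target = rep(-0.1, length(top)),
                         warn = FALSE)
  }
  r1 <- run_once()
  r2 <- run_once()
  expect_identical(r1$state$u, r2$state$u)
  expect_identical(r1$report, r2$report)
})
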