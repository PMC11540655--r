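# Shared fixtures, built lazily and cached for the whole test session.
# Everything is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, builder(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

# coarse study phantom: 40x30x30 mm prostate in a 60 mm block, 5 mm lattice
fix_phantom <- function() {
  fixture("phantom", function() {
    dom <- generate_phantom(phantom_spec(prostate_semi_axes = c(20, 15, 15),
                                         block_dims = c(60, 60, 60),
                                         nodal_spacing = 5))
    list(domain = dom, shape = build_shape_table(dom))
  })
}

# finer phantom used where geometric accuracy matters (no shape table)
fix_phantom_fine <- function() {
  fixture("phantom_fine", function() {
    generate_phantom(phantom_spec(prostate_semi_axes = c(20, 15, 15),
                                  block_dims = c(60, 60, 60),
                                  nodal_spacing = 2))
  })
}

# homogeneous bar for the uniaxial verification problems (~1400 nodes)
fix_bar <- function() {
  fixture("bar", function() {
    bar <- block_domain(c(20, 20, 40), 2.5)
    shape <- build_shape_table(bar)
    field <- material_field(bar,
                            list(surrounding = material(E = 25, nu = 0.49)))
    list(domain = bar, shape = shape, field = field,
         masses = lumped_mass(bar, shape, field))
  })
}

# jittered random node cloud with a regular backbone (always resolvable
# supports), used for the shape-function property sweeps
random_cloud <- function(n = 500, seed = 1, jitter = 0.35) {
  set.seed(seed)
  side <- ceiling(n^(1 / 3))
  g <- as.matrix(expand.grid(seq_len(side), seq_len(side), seq_len(side)))
  g <- g[seq_len(n), , drop = FALSE]
  g + matrix(runif(3 * n, -jitter, jitter), n, 3)
}

# random deformation gradient with controlled determinant
random_F <- function(det_range = c(0.5, 2)) {
  repeat {
    F <- diag(3) + matrix(runif(9, -0.4, 0.4), 3, 3)
    if (det(F) >= det_range[1] && det(F) <= det_range[2]) return(F)
  }
}

random_rotation <- function() {
  qr.Q(qr(matrix(rnorm(9), 3, 3)))
}

# one-needle mini procedure on a small phantom (fast, reused by tidier and
# I/O tests)
fix_mini_procedure <- function() {
  fixture("mini_procedure", function() {
    dom <- generate_phantom(phantom_spec(prostate_semi_axes = c(16, 14, 12),
                                         block_dims = c(45, 45, 45),
                                         nodal_spacing = 4))
    plan <- generate_needle_plan(dom, n_anchor = 1, n_catheter = 1,
                                 template_pitch = 4)
    run_procedure(dom, plan)
  })
}
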