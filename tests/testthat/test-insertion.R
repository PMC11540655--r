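# Kinematic insertion rules and stiffening events.

test_that("tip influence weight follows the radial decay contract", {
  cfg <- insertion_config(influence_radius = 3, decay = "linear")
  needle <- tibble::tibble(needle_id = "N", type = "catheter",
                           entry_x = 0, entry_y = 0, entry_z = 0,
                           dir_x = 0, dir_y = 0, dir_z = 1,
                           depth_mm = 30, radius_mm = 0.75, order_index = 1)
  a <- 0.75; R <- 3
  # on the axis within the penetrated segment: w = 1
  expect_equal(tip_influence(c(0, 0, 10), needle, 20, cfg), 1)
  # inside the bore radius: w = 1
  expect_equal(tip_influence(c(0.5, 0, 10), needle, 20, cfg), 1)
  # beyond the influence radius: w = 0
  expect_equal(tip_influence(c(4, 0, 10), needle, 20, cfg), 0)
  # distal to the tip plane by more than the influence radius: w = 0
  expect_equal(tip_influence(c(0, 0, 24), needle, 20, cfg), 0)
  # linear decay formula at 20 sampled radii, non-increasing
  r <- seq(a + 0.05, R - 0.05, length.out = 20)
  pts <- cbind(r, 0, 10)
  w <- tip_influence(pts, needle, 20, cfg)
  expect_equal(w, (R - r) / (R - a), tolerance = 1e-12)
  expect_true(all(diff(w) < 0))
  # exponential decay: also monotone, 1 at the bore, ~0 at R
  cfge <- insertion_config(influence_radius = 3, decay = "exponential")
  we <- tip_influence(pts, needle, 20, cfge)
  expect_true(all(diff(we) < 0))
  expect_true(all(we <= 1 & we >= 0))
  # zero depth: no influence anywhere
  expect_identical(tip_influence(pts, needle, 0, cfg), rep(0, 20))
})

test_that("insertion config validates its parameters", {
  expect_error(insertion_config(increment = 0))
  expect_error(insertion_config(stiffening_factor = 0.5))
  cfg <- insertion_config()
  expect_equal(cfg$stiffening_factor, 30)
  expect_equal(cfg$influence_radius, 3)
})

test_that("advancing by zero leaves the state untouched", {
  fx <- fix_phantom()
  plan <- generate_needle_plan(fx$domain)
  ctx <- solver_context(fx$domain, shape = fx$shape)
  st <- sim_state(fx$domain)
  res <- advance_needle(st, plan[1, ], 0, insertion_config(), ctx)
  expect_identical(res$state$u, st$u)
  expect_true(res$report$converged)
  expect_identical(res$report$iterations, 0L)
})

test_that("anchor stiffening affects only surrounding tissue behind the tip plane", {
  fx <- fix_phantom()
  dom <- fx$domain
  cfg <- insertion_config()
  plan <- generate_needle_plan(dom)
  anchors <- plan[plan$type == "anchor", ]
  fld <- apply_anchor_stiffening(material_field(dom), anchors, dom, cfg)
  tip_z <- max(anchors$entry_z + anchors$depth_mm)
  distal <- dom$ip_coords[, 3] > tip_z
  surr <- dom$ip_region == "surrounding"
  expect_true(all(fld$scale[distal & surr] == 30))
  # prostate points never modified, proximal points never modified
  expect_true(all(fld$scale[!surr] == 1))
  expect_true(all(fld$scale[!distal] == 1))
  # effective shear modulus exactly 30x base in the stiffened region
  k <- which(distal & surr)[1]
  expect_equal(effective_material(fld, k)$mu, 30 * fld$mu0[k])
  # idempotent
  expect_identical(apply_anchor_stiffening(fld, anchors, dom, cfg)$scale,
                   fld$scale)
})

test_that("catheter stiffening is local, monotone and max-composed", {
  fx <- fix_phantom()
  dom <- fx$domain
  cfg <- insertion_config()
  plan <- generate_needle_plan(dom)
  cats <- plan[plan$type == "catheter", ]
  fld <- material_field(dom)
  n_stiff <- integer(0)
  for (k in seq_len(5)) {
    fld <- apply_catheter_stiffening(fld, cats[k, ], cfg, dom)
    n_stiff <- c(n_stiff, sum(fld$scale > 1))
    # points beyond the stiffening radius of all placed paths unchanged
    r <- sapply(seq_len(k), function(j) {
      brachysim:::dist_to_segment(dom$ip_coords,
                                  brachysim:::needle_entry(cats[j, ]),
                                  brachysim:::needle_dir(cats[j, ]),
                                  cats$depth_mm[j])
    })
    far <- apply(r, 1, min) > cfg$catheter_stiffening_radius
    expect_true(all(fld$scale[far] == 1))
    expect_true(all(fld$scale %in% c(1, 30)))  # max composition, never 900
  }
  # the stiffened set grows monotonically with each placed catheter
  expect_true(all(diff(n_stiff) >= 0))
  expect_gt(n_stiff[1], 0)
})

test_that("an empty plan yields one snapshot and zero displacement", {
  fx <- fix_phantom()
  plan <- generate_needle_plan(fx$domain, n_anchor = 0, n_catheter = 0)
  ctx <- solver_context(fx$domain, shape = fx$shape)
  res <- run_procedure(fx$domain, plan, ctx = ctx)
  expect_length(res$snapshots, 1)
  expect_identical(max(abs(res$snapshots$initial)), 0)
  expect_equal(nrow(res$events), 0)
})

test_that("a mini procedure produces ordered snapshots and converged events", {
  res <- fix_mini_procedure()
  expect_s3_class(res, "bs_procedure_result")
  # snapshot count = events + 1, in plan order
  expect_length(res$snapshots, nrow(res$plan) + 1)
  expect_identical(names(res$snapshots),
                   c("initial", res$plan$needle_id[order(res$plan$order_index)]))
  expect_true(all(res$events$converged))
  expect_length(res$failed_events, 0)
  # needles reached their planned depths
  expect_equal(res$events$tip_depth, res$plan$depth_mm, tolerance = 1e-9)
  # displacement grows as needles go in, and the bore keeps the final
  # state away from the reference
  expect_gt(max(abs(res$state$u)), 0.1)
  # displacement decays with distance from the needle paths
  dom <- res$domain
  umag <- sqrt(rowSums(res$state$u^2))
  r <- sapply(seq_len(nrow(res$plan)), function(j) {
    brachysim:::dist_to_segment(dom$nodes,
                                brachysim:::needle_entry(res$plan[j, ]),
                                brachysim:::needle_dir(res$plan[j, ]),
                                res$plan$depth_mm[j])
  })
  rmin <- apply(r, 1, min)
  near <- rmin < 5
  far <- rmin > 15
  expect_gt(mean(umag[near]), mean(umag[far]))
})
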