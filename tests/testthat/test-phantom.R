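# Phantom generation, needle plans and mask-derived domains.

test_that("phantom lattice geometry and labels are internally consistent", {
  spec <- phantom_spec(prostate_semi_axes = c(20, 15, 15),
                       block_dims = c(60, 60, 60), nodal_spacing = 5)
  dom <- fix_phantom()$domain
  # node count = prod(floor(L/h) + 1)
  expect_equal(nrow(dom$nodes), prod(floor(c(60, 60, 60) / 5) + 1))
  # every prostate-labelled node satisfies the ellipsoid inequality
  ctr <- dom$prostate$centre
  ax <- dom$prostate$semi_axes
  q <- ((dom$nodes[, 1] - ctr[1]) / ax[1])^2 +
    ((dom$nodes[, 2] - ctr[2]) / ax[2])^2 +
    ((dom$nodes[, 3] - ctr[3]) / ax[3])^2
  expect_true(all(q[dom$node_region == "prostate"] <= 1 + 1e-12))
  expect_true(all(q[dom$node_region == "surrounding"] > 1))
  # integration weights positive, total equals block volume
  expect_true(all(dom$ip_weight > 0))
  expect_equal(sum(dom$ip_weight), prod(dom$block_dims))
  # every integration point inside the block
  expect_true(all(dom$ip_coords > 0 & dom$ip_coords <
                    matrix(dom$block_dims, nrow(dom$ip_coords), 3,
                           byrow = TRUE)))
  # boundary sets disjoint and non-empty
  expect_length(intersect(dom$boundary$fixed_external,
                          dom$boundary$insertion_face), 0)
  expect_gt(length(dom$boundary$fixed_external), 0)
  expect_gt(length(dom$boundary$insertion_face), 0)
  # insertion face nodes lie on the z = 0 plane
  expect_true(all(dom$nodes[dom$boundary$insertion_face, 3] == 0))
})

test_that("prostate quadrature volume matches the analytic ellipsoid", {
  v_exact <- 4 / 3 * pi * 20 * 15 * 15
  # spec example: semi-axes (20,15,15), h = 2 mm -> within 5%
  dom2 <- fix_phantom_fine()
  v2 <- region_volumes(dom2)[["prostate"]]
  expect_lt(abs(v2 - v_exact) / v_exact, 0.05)
  # volume error decreases as the lattice is refined
  dom5 <- fix_phantom()$domain
  v5 <- region_volumes(dom5)[["prostate"]]
  expect_lt(abs(v2 - v_exact), abs(v5 - v_exact))
  expect_lt(abs(v5 - v_exact) / v_exact, 0.05)
})

test_that("phantom generation is deterministic and validates its inputs", {
  spec <- phantom_spec(nodal_spacing = 5, block_dims = c(50, 50, 50))
  expect_identical(generate_phantom(spec), generate_phantom(spec))
  expect_error(phantom_spec(prostate_semi_axes = c(30, 15, 15),
                            block_dims = c(50, 50, 50)), "geometry")
  expect_error(phantom_spec(nodal_spacing = 9), "resolution")
  expect_error(phantom_spec(insertion_axis = c(0, 0, 2)), "unit norm")
  expect_error(phantom_spec(insertion_axis = c(0, 0.6, 0.8)), "aligned")
})

test_that("needle plans carry the procedure geometry", {
  dom <- fix_phantom()$domain
  plan <- generate_needle_plan(dom)
  # 2 anchors + 17 catheters, in order, anchors first
  expect_equal(nrow(plan), 19)
  expect_equal(sum(plan$type == "anchor"), 2)
  expect_equal(sum(plan$type == "catheter"), 17)
  expect_equal(plan$order_index, 1:19)
  expect_equal(plan$type[1:2], c("anchor", "anchor"))
  # diameters: 1 mm anchors, 1.5 mm catheters
  expect_equal(unique(plan$radius_mm[plan$type == "anchor"]), 0.5)
  expect_equal(unique(plan$radius_mm[plan$type == "catheter"]), 0.75)
  # entry points on the insertion face, depths within the block
  expect_true(all(plan$entry_z == 0))
  expect_true(all(plan$depth_mm <= dom$block_dims[3]))
  # catheters travel deeper than anchors
  expect_gt(min(plan$depth_mm[plan$type == "catheter"]),
            max(plan$depth_mm[plan$type == "anchor"]))
  # no two needles closer than the template pitch
  xy <- as.matrix(plan[, c("entry_x", "entry_y")])
  dmin <- min(dist(xy))
  expect_gte(dmin, 5 - 1e-9)
})

test_that("ordering rules permute the same needle set", {
  dom <- fix_phantom()$domain
  p1 <- generate_needle_plan(dom, sequence = "alternate_lb_rt")
  p2 <- generate_needle_plan(dom, sequence = "alternate_rb_lb")
  key <- function(p) {
    k <- paste(p$entry_x, p$entry_y, p$type)
    sort(k)
  }
  expect_identical(key(p1), key(p2))
  ord1 <- paste(p1$entry_x, p1$entry_y)
  ord2 <- paste(p2$entry_x, p2$entry_y)
  expect_false(identical(ord1, ord2))
  # the first catheter of the original sequence starts on the left-bottom
  c1 <- p1[p1$type == "catheter", ][1, ]
  ctr <- dom$prostate$centre[1:2]
  expect_true(c1$entry_x <= ctr[1] && c1$entry_y <= ctr[2])
  # the alternate sequence starts bottom-right
  c2 <- p2[p2$type == "catheter", ][1, ]
  expect_true(c2$entry_x >= ctr[1] && c2$entry_y <= ctr[2])
})

test_that("needle plan edge cases", {
  dom <- fix_phantom()$domain
  only_anchors <- generate_needle_plan(dom, n_catheter = 0)
  expect_equal(nrow(only_anchors), 2)
  expect_true(all(only_anchors$type == "anchor"))
  expect_error(generate_needle_plan(dom, n_catheter = 500), "capacity")
})

test_that("domains can be built from binary masks", {
  # voxelised ellipsoid at 1 mm -> round-trip volume within 5%
  ax <- c(16, 13, 12)
  dm <- c(41, 35, 33)
  ctr <- (dm - 1) / 2
  g <- expand.grid(i = 0:(dm[1] - 1), j = 0:(dm[2] - 1), k = 0:(dm[3] - 1))
  inside <- ((g$i - ctr[1]) / ax[1])^2 + ((g$j - ctr[2]) / ax[2])^2 +
    ((g$k - ctr[3]) / ax[3])^2 <= 1
  mask <- voxel_mask(array(inside, dm), origin = c(0, 0, 0), voxel = 1)
  dom <- domain_from_mask(mask, spacing = 4, margin = 12)
  v <- region_volumes(dom)[["prostate"]]
  v_exact <- 4 / 3 * pi * prod(ax)
  expect_lt(abs(v - v_exact) / v_exact, 0.05)
  expect_setequal(unique(dom$node_region), c("prostate", "surrounding"))
  expect_gt(length(dom$boundary$fixed_external), 0)
  # degenerate inputs: empty mask errors, single voxel never silently works
  empty <- voxel_mask(array(FALSE, c(5, 5, 5)), c(0, 0, 0), 1)
  expect_error(domain_from_mask(empty, spacing = 2), "empty")
  single <- voxel_mask(array(c(rep(FALSE, 62), TRUE, rep(FALSE, 62)),
                             c(5, 5, 5)), c(0, 0, 0), 1)
  res <- tryCatch(domain_from_mask(single, spacing = 2, margin = 4),
                  error = function(e) e)
  if (inherits(res, "error")) {
    expect_match(conditionMessage(res), "resolution|spacing")
  } else {
    expect_gte(sum(res$node_region == "prostate"), 1)
  }
})
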