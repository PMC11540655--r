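# Supports and MMLS shape functions.

# independent dense penalised weighted-least-squares oracle: solve the
# normal equations of min sum_j w_j (p(xi_j)'a - e_j)^2 + mu_p |Q a|^2 for
# each cardinal function and evaluate at the origin
mmls_oracle <- function(eval_point, nodes, h, pen = 1e-6, eps = 1e-8) {
  k <- nrow(nodes)
  xi <- sweep(nodes, 2, eval_point) / h
  P <- cbind(1, xi[, 1], xi[, 2], xi[, 3], xi[, 1]^2, xi[, 2]^2, xi[, 3]^2,
             xi[, 1] * xi[, 2], xi[, 2] * xi[, 3], xi[, 3] * xi[, 1])
  w <- 1 / (rowSums(xi^2) + eps)
  A <- t(P) %*% (w * P)
  mu_p <- pen * sum(diag(A)) / 10
  A <- A + diag(c(rep(0, 4), rep(mu_p, 6)))
  # fitted value at the evaluation point (xi = 0) for nodal data e_j:
  # phi_j = [A^{-1} P' W]_{1j}
  sol <- solve(A, t(P) %*% diag(w))
  sol[1, ]
}

test_that("single-point MMLS matches an independent normal-equations solve", {
  set.seed(11)
  cloud <- random_cloud(120, seed = 11)
  x <- colMeans(cloud) + runif(3, -0.2, 0.2)
  d <- sqrt(rowSums(sweep(cloud, 2, x)^2))
  sup <- cloud[d <= 2.2, , drop = FALSE]
  expect_gte(nrow(sup), 11)
  res <- mmls_shape(x, sup, h = 2.2)
  expect_equal(res$values, mmls_oracle(x, sup, 2.2), tolerance = 1e-10)
  expect_equal(sum(res$values), 1, tolerance = 1e-10)
})

test_that("shape functions satisfy their algebraic invariants on random clouds", {
  for (seed in c(1, 2, 3)) {
    cloud <- random_cloud(500, seed = seed)
    # evaluate at 40 random interior points
    set.seed(seed + 100)
    lo <- apply(cloud, 2, quantile, 0.25)
    hi <- apply(cloud, 2, quantile, 0.75)
    pts <- cbind(runif(40, lo[1], hi[1]), runif(40, lo[2], hi[2]),
                 runif(40, lo[3], hi[3]))
    for (i in seq_len(nrow(pts))) {
      x <- pts[i, ]
      d <- sqrt(rowSums(sweep(cloud, 2, x)^2))
      h <- 2.0
      while (sum(d <= h) < 11) h <- h * 1.25
      supn <- cloud[d <= h, , drop = FALSE]
      res <- mmls_shape(x, supn, h)
      # partition of unity
      expect_lt(abs(sum(res$values) - 1), 1e-8)
      # linear reproduction of coordinates and affine fields
      expect_lt(max(abs(colSums(res$values * supn) - x)), 1e-8 * h)
      # gradient null-sum
      expect_lt(max(abs(colSums(res$gradients))), 1e-8 / h)
      # gradient of an affine field u = A X + b equals A
      A <- matrix(c(1.5, 0.2, -0.3, 0.1, -2, 0.4, 0.7, 0, 1), 3, 3)
      gA <- t(res$gradients) %*% (supn %*% t(A))
      expect_lt(max(abs(t(gA) - A)), 1e-8)
    }
  }
})

test_that("shape table on the phantom is interpolating and consistent", {
  fx <- fix_phantom()
  dom <- fx$domain
  shp <- fx$shape
  ip <- shp$ip
  m <- length(ip$ptr) - 1
  ent <- rep(seq_len(m), diff(ip$ptr))
  # partition of unity and linear reproduction at all integration points
  expect_lt(max(abs(rowsum(ip$phi, ent) - 1)), 1e-8)
  for (d in 1:3) {
    rec <- rowsum(ip$phi * dom$nodes[ip$idx, d], ent)
    expect_lt(max(abs(rec - dom$ip_coords[, d])), 1e-8 * 10)
  }
  # gradient null-sum
  expect_lt(max(abs(rowsum(ip$gx, ent))), 1e-8)
  expect_lt(max(abs(rowsum(ip$gy, ent))), 1e-8)
  expect_lt(max(abs(rowsum(ip$gz, ent))), 1e-8)
  # delta property at the nodes
  nd <- shp$node
  nent <- rep(seq_len(length(nd$ptr) - 1), diff(nd$ptr))
  delta <- ifelse(nd$idx == nent, nd$phi - 1, nd$phi)
  expect_lt(max(abs(delta)), 1e-6)
  # constant nodal field reproduced with zero gradient
  cst <- rep(4.2, nrow(dom$nodes))
  expect_lt(max(abs(interpolate_field(shp, cst) - 4.2)), 1e-8)
  g <- interpolate_field(shp, cst, what = "gradients")
  expect_lt(max(abs(g)), 1e-8)
  # quadratic nodal field reproduced in the well-supported interior
  f <- function(p) 2 * p[, 1]^2 - p[, 2]^2 + 0.5 * p[, 3]^2 +
    p[, 1] * p[, 2] - p[, 2] * p[, 3] + 3
  rec <- as.vector(rowsum(ip$phi * f(dom$nodes)[ip$idx], ent))
  tru <- f(dom$ip_coords)
  interior <- rowSums(
    abs(sweep(dom$ip_coords, 2, dom$block_dims / 2)) <
      matrix(dom$block_dims / 2 - 12, m, 3, byrow = TRUE)) == 3
  expect_gt(sum(interior), 50)
  expect_lt(max(abs(rec - tru)[interior]) / max(abs(tru)), 1e-6)
})

test_that("gradients agree with central finite differences", {
  set.seed(3)
  fx <- fix_phantom()
  dom <- fx$domain
  sup <- build_supports(dom)
  ids <- sample(nrow(dom$ip_coords), 20)
  worst <- 0
  for (e in ids) {
    rng <- sup$ptr[e]:(sup$ptr[e + 1] - 1)
    nd <- dom$nodes[sup$idx[rng], , drop = FALSE]
    h <- sup$radius[e]
    x <- dom$ip_coords[e, ]
    res <- mmls_shape(x, nd, h)
    d <- 1e-5
    for (k in 1:3) {
      xp <- x; xp[k] <- xp[k] + d
      xm <- x; xm[k] <- xm[k] - d
      fd <- (mmls_shape(xp, nd, h)$values -
               mmls_shape(xm, nd, h)$values) / (2 * d)
      worst <- max(worst, max(abs(fd - res$gradients[, k])) /
                     max(abs(res$gradients[, k])))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("support construction enforces its preconditions and minimum size", {
  fx <- fix_phantom()
  dom <- fx$domain
  expect_error(build_supports(dom, dilation = 1.0), "dilation")
  sup <- build_supports(dom, dilation = 2)
  counts <- diff(sup$ptr)
  # interior integration points see at least 27 nodes on a regular lattice
  expect_gte(max(counts), 27)
  expect_true(all(counts >= 11))
  # brute-force all-pairs oracle on a jittered cloud
  cloud <- random_cloud(200, seed = 7)
  domc <- structure(list(nodes = cloud, spacing = 1,
                         ip_coords = cloud + 0.4,
                         ip_weight = rep(1, 200),
                         node_region = rep("prostate", 200),
                         ip_region = rep("prostate", 200),
                         boundary = list(), block_dims = c(9, 9, 9),
                         insertion_axis = c(0, 0, 1)),
                    class = "bs_domain")
  supc <- build_supports(domc, dilation = 2)
  for (e in c(1, 57, 200)) {
    rng <- supc$ptr[e]:(supc$ptr[e + 1] - 1)
    d <- sqrt(rowSums(sweep(cloud, 2, domc$ip_coords[e, ])^2))
    expect_setequal(supc$idx[rng], which(d <= supc$radius[e]))
    expect_gte(length(rng), 11)
  }
  expect_true(all(diff(supc$ptr) >= 11))
})
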