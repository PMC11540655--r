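# Neighbour supports and MMLS interpolating shape functions.

BASIS_SIZE <- 10L   # quadratic basis in 3D
N_MIN <- 11L        # minimum support size: basis size + 1
MMLS_PENALTY <- 1e-6  # penalty factor on quadratic coefficients (x tr(A)/10)
MMLS_EPS <- 1e-8      # regularisation of the singular weight kernel

#' Build nodal support lists for integration points or nodes
#'
#' Radius search with support radius `h = dilation * nodal_spacing`. Supports
#' with fewer than the minimum node count (11, the quadratic basis size plus
#' one) are enlarged locally by factors of 1.25, at most five times.
#'
#' @param domain A `bs_domain`.
#' @param dilation Support dilation relative to the nodal spacing; must be
#'   at least 1.5. Default 2.
#' @param at Evaluate supports at `"integration_points"` (default) or at
#'   `"nodes"` (used for the interpolation/delta check).
#' @return An object of class `bs_supports`: CSR fields `ptr` (length m+1,
#'   1-based offsets), `idx` (supporting node indices), and `radius` per
#'   evaluation point.
#' @export
build_supports <- function(domain, dilation = 2,
                           at = c("integration_points", "nodes")) {
  stopifnot(inherits(domain, "bs_domain"))
  at <- match.arg(at)
  if (dilation < 1.5) {
    stop("dilation must be >= 1.5 (support too small for a quadratic basis)",
         call. = FALSE)
  }
  query <- if (at == "integration_points") domain$ip_coords else domain$nodes
  m <- nrow(query)
  radius <- rep(dilation * domain$spacing, m)
  res <- cpp_radius_neighbors(domain$nodes, query, radius)
  counts <- diff(res$ptr)
  tries <- 0
  while (any(counts < N_MIN) && tries < 5) {
    deficient <- which(counts < N_MIN)
    radius[deficient] <- radius[deficient] * 1.25
    res <- cpp_radius_neighbors(domain$nodes, query, radius)
    counts <- diff(res$ptr)
    tries <- tries + 1
  }
  if (any(counts < N_MIN)) {
    bad <- which(counts < N_MIN)[1]
    stop("discretisation error: evaluation point ", bad, " at (",
         paste(round(query[bad, ], 3), collapse = ", "), ") has only ",
         counts[bad], " supporting nodes after 5 enlargements", call. = FALSE)
  }
  structure(list(ptr = res$ptr + 1L, idx = res$idx + 1L, radius = radius,
                 at = at, n_min = N_MIN, dilation = dilation),
            class = "bs_supports")
}

#' @export
print.bs_supports <- function(x, ...) {
  counts <- diff(x$ptr)
  cat("<bs_supports> ", length(counts), " evaluation points (", x$at, ")\n",
      sep = "")
  cat("  support size: min ", min(counts), ", median ",
      stats::median(counts), ", max ", max(counts), "\n", sep = "")
  invisible(x)
}

#' MMLS shape functions at a single evaluation point
#'
#' Weighted least-squares fit with the quadratic basis
#' `[1, x, y, z, x^2, y^2, z^2, xy, yz, zx]` (shifted to the evaluation
#' point and scaled by `h`), a diagonal penalty on the six quadratic
#' coefficients so the moment matrix stays invertible when only linear
#' reproduction is supported, and a regularised-singular weight
#' `w(r) = 1/((r/h)^2 + eps)` that makes the approximation interpolating at
#' the nodes to within about `eps`. Spatial gradients are exact derivatives
#' of this evaluation, computed by complex-step differentiation.
#'
#' @param eval_point Numeric length 3 (mm).
#' @param support_nodes k x 3 matrix of supporting node coordinates (mm);
#'   at least 11 nodes.
#' @param h Support radius (mm).
#' @param penalty Penalty factor on the quadratic block, as a fraction of
#'   `tr(A)/10`.
#' @param eps Weight-kernel regularisation.
#' @return List with `values` (length k, sums to 1) and `gradients`
#'   (k x 3, 1/mm).
#' @export
mmls_shape <- function(eval_point, support_nodes, h,
                       penalty = MMLS_PENALTY, eps = MMLS_EPS) {
  support_nodes <- as.matrix(support_nodes)
  stopifnot(length(eval_point) == 3, ncol(support_nodes) == 3, h > 0)
  k <- nrow(support_nodes)
  if (k < N_MIN) {
    stop("support has ", k, " nodes; at least ", N_MIN,
         " are required for the quadratic basis", call. = FALSE)
  }
  res <- cpp_mmls_batch(support_nodes, matrix(eval_point, 1, 3),
                        c(0L, k), 0:(k - 1), h, penalty, eps, TRUE)
  check_mmls_condition(res)
  list(values = res$phi, gradients = cbind(res$gx, res$gy, res$gz))
}

check_mmls_condition <- function(res) {
  if (res$rcond_min < 1e-13) {
    stop("numerical error: singular moment matrix despite penalty at ",
         "evaluation point ", res$worst_eval,
         " (reciprocal condition number ",
         format(res$rcond_min, digits = 3), ")", call. = FALSE)
  }
  invisible(res)
}

#' Build the shape table for a domain
#'
#' Evaluates MMLS shape values and reference-configuration gradients at all
#' integration points, and shape values at all nodes (where the interpolating
#' property makes them near-delta). Stored sparsely in CSR form.
#'
#' @param domain A `bs_domain`.
#' @param supports Optional precomputed [build_supports()] result for the
#'   integration points.
#' @param dilation Support dilation used when `supports` is `NULL`.
#' @param penalty,eps See [mmls_shape()].
#' @param cache_file Optional path; when given, the shape table is read from
#'   this file if it exists and written to it after construction (keyed by a
#'   content hash of the domain geometry).
#' @return Object of class `bs_shape_table` with components `ip`
#'   (`ptr`, `idx`, `phi`, `gx`, `gy`, `gz`) and `node` (`ptr`, `idx`,
#'   `phi`).
#' @export
build_shape_table <- function(domain, supports = NULL, dilation = 2,
                              penalty = MMLS_PENALTY, eps = MMLS_EPS,
                              cache_file = NULL) {
  stopifnot(inherits(domain, "bs_domain"))
  key <- NULL
  if (!is.null(cache_file)) {
    key <- domain_hash(domain, dilation, penalty, eps)
    if (file.exists(cache_file)) {
      cached <- readRDS(cache_file)
      if (identical(cached$key, key)) return(cached$table)
    }
  }
  if (is.null(supports)) supports <- build_supports(domain, dilation)
  stopifnot(supports$at == "integration_points")
  ipres <- cpp_mmls_batch(domain$nodes, domain$ip_coords,
                          supports$ptr - 1L, supports$idx - 1L,
                          supports$radius, penalty, eps, TRUE)
  check_mmls_condition(ipres)
  nsup <- build_supports(domain, dilation, at = "nodes")
  nres <- cpp_mmls_batch(domain$nodes, domain$nodes,
                         nsup$ptr - 1L, nsup$idx - 1L,
                         nsup$radius, penalty, eps, FALSE)
  check_mmls_condition(nres)
  tab <- structure(list(
    ip = list(ptr = supports$ptr, idx = supports$idx, phi = ipres$phi,
              gx = ipres$gx, gy = ipres$gy, gz = ipres$gz,
              radius = supports$radius),
    node = list(ptr = nsup$ptr, idx = nsup$idx, phi = nres$phi),
    penalty = penalty, eps = eps, dilation = dilation,
    n_nodes = nrow(domain$nodes), n_ip = nrow(domain$ip_coords)),
    class = "bs_shape_table")
  if (!is.null(cache_file)) {
    saveRDS(list(key = key, table = tab), cache_file)
  }
  tab
}

domain_hash <- function(domain, dilation, penalty, eps) {
  # cheap content key: geometry summaries, not a cryptographic hash
  c(n = nrow(domain$nodes), m = nrow(domain$ip_coords),
    s = domain$spacing, d = dilation, p = penalty, e = eps,
    cs = sum(domain$nodes), cs2 = sum(domain$nodes^2),
    pr = sum(domain$node_region == "prostate"))
}

#' @export
print.bs_shape_table <- function(x, ...) {
  cat("<bs_shape_table> ", x$n_ip, " integration points, ", x$n_nodes,
      " nodes, ", length(x$ip$phi), " ip entries\n", sep = "")
  invisible(x)
}

#' Interpolate a nodal field at the integration points
#'
#' @param shape A `bs_shape_table`.
#' @param nodal_values Numeric vector (length n nodes) or matrix (n x q).
#' @param what `"values"` or `"gradients"` (gradients only for vector input).
#' @return Interpolated values (m or m x q), or an m x 3 gradient matrix.
#' @export
interpolate_field <- function(shape, nodal_values, what = c("values",
                                                            "gradients")) {
  what <- match.arg(what)
  ip <- shape$ip
  m <- length(ip$ptr) - 1L
  ent <- rep(seq_len(m), diff(ip$ptr))
  if (what == "values") {
    v <- as.matrix(nodal_values)
    out <- sapply(seq_len(ncol(v)), function(q) {
      as.vector(rowsum_full(ip$phi * v[ip$idx, q], ent, m))
    })
    if (is.vector(nodal_values)) out <- drop(out)
    out
  } else {
    v <- as.numeric(nodal_values)
    cbind(rowsum_full(ip$gx * v[ip$idx], ent, m),
          rowsum_full(ip$gy * v[ip$idx], ent, m),
          rowsum_full(ip$gz * v[ip$idx], ent, m))
  }
}

# rowsum over groups 1..m including empty groups
rowsum_full <- function(x, g, m) {
  out <- numeric(m)
  rs <- rowsum(x, g)
  out[as.integer(rownames(rs))] <- rs
  out
}
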