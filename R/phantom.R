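# Synthetic phantom domains, block domains and needle plans.

#' Specify a synthetic prostate phantom
#'
#' Describes an ellipsoidal prostate embedded in a softer cuboidal block of
#' surrounding tissue, discretised on a regular node lattice. The defaults
#' emulate a typical gland of roughly 40 mm span with a transperineal
#' insertion face at the proximal end of the insertion axis.
#'
#' @param prostate_semi_axes Numeric length 3, ellipsoid semi-axes (a, b, c)
#'   in mm. Default `c(20, 15, 15)`.
#' @param block_dims Numeric length 3, block edge lengths (Lx, Ly, Lz) in mm.
#'   The ellipsoid must fit strictly inside. Default `c(80, 80, 80)`.
#' @param nodal_spacing Lattice spacing in mm; must be positive and at most
#'   one third of the smallest semi-axis. Default 2.5.
#' @param insertion_axis Unit vector along which needles travel; must be
#'   aligned with a coordinate axis. Default `c(0, 0, 1)`.
#' @param rng_seed Integer seed recorded with the phantom description so any
#'   stochastic downstream choice is reproducible. The lattice itself is
#'   deterministic.
#'
#' @return An object of class `bs_phantom_spec`.
#' @seealso [generate_phantom()]
#' @export
phantom_spec <- function(prostate_semi_axes = c(20, 15, 15),
                         block_dims = c(80, 80, 80),
                         nodal_spacing = 2.5,
                         insertion_axis = c(0, 0, 1),
                         rng_seed = 1L) {
  stopifnot(length(prostate_semi_axes) == 3, length(block_dims) == 3,
            length(insertion_axis) == 3, length(nodal_spacing) == 1)
  if (any(prostate_semi_axes <= 0)) {
    stop("prostate semi-axes must be positive", call. = FALSE)
  }
  if (any(block_dims <= 0)) stop("block dimensions must be positive", call. = FALSE)
  if (nodal_spacing <= 0) stop("nodal_spacing must be positive", call. = FALSE)
  if (nodal_spacing > min(prostate_semi_axes) / 3) {
    stop("resolution error: nodal_spacing exceeds min(semi-axis)/3; ",
         "the prostate would be under-resolved", call. = FALSE)
  }
  if (abs(sqrt(sum(insertion_axis^2)) - 1) > 1e-10) {
    stop("insertion_axis must have unit norm", call. = FALSE)
  }
  ax <- axis_index(insertion_axis)
  # ellipsoid centred at the block centre must fit strictly inside
  if (any(2 * prostate_semi_axes >= block_dims)) {
    stop("geometry error: ellipsoid does not fit strictly inside the block",
         call. = FALSE)
  }
  structure(list(prostate_semi_axes = as.numeric(prostate_semi_axes),
                 block_dims = as.numeric(block_dims),
                 nodal_spacing = as.numeric(nodal_spacing),
                 insertion_axis = as.numeric(insertion_axis),
                 axis_index = ax,
                 rng_seed = as.integer(rng_seed)),
            class = "bs_phantom_spec")
}

# dominant coordinate axis of a unit vector; errors if not axis-aligned
axis_index <- function(v) {
  i <- which.max(abs(v))
  e <- numeric(3); e[i] <- sign(v[i])
  if (max(abs(v - e)) > 1e-10) {
    stop("insertion_axis must be aligned with a coordinate axis", call. = FALSE)
  }
  i
}

#' @export
print.bs_phantom_spec <- function(x, ...) {
  cat("<bs_phantom_spec>\n")
  cat("  prostate semi-axes:", paste(x$prostate_semi_axes, collapse = " x "),
      "mm\n")
  cat("  block:", paste(x$block_dims, collapse = " x "), "mm, spacing",
      x$nodal_spacing, "mm\n")
  cat("  insertion axis:", paste(x$insertion_axis, collapse = ", "), "\n")
  invisible(x)
}

# Shared lattice construction for phantom and block domains.
# Nodes sit at i*h, i = 0..floor(L/h). Integration points per background
# cell: quadrature = 1 puts one point at the cell centre (weight h^3);
# quadrature = 4 (default) a degree-2-exact tetrahedral 4-point rule at
# centre + (+-h/4, +-h/4, +-h/4) with alternating signs (weight h^3/4);
# quadrature = 8 a full 2x2x2 subdivision (weight h^3/8). The multi-point
# rules suppress the spurious near-zero-energy modes that single-point cell
# quadrature leaves in the Galerkin stiffness (they stall dynamic
# relaxation).
build_lattice <- function(block_dims, h, quadrature = 4L) {
  stopifnot(quadrature %in% c(1L, 4L, 8L))
  ncell <- floor(block_dims / h + 1e-9)
  if (any(ncell < 2)) stop("resolution error: fewer than two cells per axis",
                           call. = FALSE)
  axes <- lapply(1:3, function(i) (0:ncell[i]) * h)
  nodes <- as.matrix(expand.grid(x = axes[[1]], y = axes[[2]], z = axes[[3]],
                                 KEEP.OUT.ATTRS = FALSE))
  dimnames(nodes) <- NULL
  ctr_axes <- lapply(1:3, function(i) ((1:ncell[i]) - 0.5) * h)
  ctrs <- as.matrix(expand.grid(x = ctr_axes[[1]], y = ctr_axes[[2]],
                                z = ctr_axes[[3]], KEEP.OUT.ATTRS = FALSE))
  dimnames(ctrs) <- NULL
  if (quadrature == 1L) {
    ips <- ctrs
    wq <- h^3
  } else if (quadrature == 4L) {
    # the 4-point tetrahedral rule is chiral; alternating the tetrahedron
    # orientation in a checkerboard pattern keeps the integration-point
    # cloud mirror-symmetric (for even cell counts) and cancels the
    # leading odd-order quadrature error between neighbouring cells
    idx <- as.matrix(expand.grid(i = 1:ncell[1], j = 1:ncell[2],
                                 k = 1:ncell[3]))
    sgn <- ifelse((rowSums(idx) %% 2) == 0, 1, -1)
    offs <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1),
                  c(-1, -1, 1)) * h / 4
    ips <- do.call(rbind, lapply(1:4, function(k) {
      ctrs + sgn * matrix(offs[k, ], nrow(ctrs), 3, byrow = TRUE)
    }))
    wq <- h^3 / 4
  } else {
    offs <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))) * h / 4
    ips <- do.call(rbind, lapply(1:8, function(k) {
      sweep(ctrs, 2, offs[k, ], "+")
    }))
    wq <- h^3 / 8
  }
  list(nodes = nodes, ips = ips, extent = ncell * h, ncell = ncell,
       ip_weight = wq)
}

# boundary node sets for a cuboid lattice: every external face is fixed
# except the face pierced by the insertion axis on the proximal side, which
# is the traction-free insertion face. Shared edge/corner nodes go to the
# fixed set so the two sets stay disjoint.
boundary_sets <- function(nodes, extent, axis_index, axis_sign) {
  eps <- 1e-9
  on_face <- vapply(1:3, function(i) {
    cbind(nodes[, i] < eps, nodes[, i] > extent[i] - eps)
  }, matrix(logical(1), nrow(nodes), 2))
  dim(on_face) <- c(nrow(nodes), 6)
  # insertion face: proximal face along the axis (minimal coordinate when the
  # axis points in +direction, maximal otherwise)
  ins_col <- (axis_index - 1) * 2 + if (axis_sign > 0) 1 else 2
  ins <- on_face[, ins_col]
  other <- rowSums(on_face[, -ins_col, drop = FALSE]) > 0
  list(fixed_external = which(other),
       insertion_face = which(ins & !other))
}

#' Generate a synthetic prostate phantom domain
#'
#' Builds a regular node lattice filling the block, labels nodes and
#' integration points inside the centred ellipsoid as prostate, places
#' integration points at the centres of the (subdivided) background lattice
#' cells with weight equal to the sub-cell volume, and populates the
#' boundary node sets: all block faces are fixed except the proximal face
#' along the insertion axis, which is the traction-free insertion face.
#'
#' @param spec A [phantom_spec()].
#' @param quadrature Integration points per background cell: 1 (cell
#'   centre), 4 (tetrahedral rule, default) or 8 (2x2x2 subdivision).
#' @return An object of class `bs_domain` with fields `nodes` (n x 3 matrix,
#'   mm), `ip_coords`, `ip_weight` (mm^3), `node_region` and `ip_region`
#'   (character, `"prostate"` or `"surrounding"`), `boundary`
#'   (`fixed_external`, `insertion_face` node indices), `spacing`,
#'   `insertion_axis` and the prostate ellipsoid geometry.
#' @examples
#' dom <- generate_phantom(phantom_spec(nodal_spacing = 5))
#' dom
#' @export
generate_phantom <- function(spec, quadrature = 4L) {
  stopifnot(inherits(spec, "bs_phantom_spec"))
  h <- spec$nodal_spacing
  lat <- build_lattice(spec$block_dims, h, quadrature)
  centre <- lat$extent / 2
  ax <- spec$prostate_semi_axes
  if (any(centre - ax <= 0) || any(centre + ax >= lat$extent)) {
    stop("geometry error: ellipsoid does not fit strictly inside the block",
         call. = FALSE)
  }
  in_ell <- function(p) {
    ((p[, 1] - centre[1]) / ax[1])^2 + ((p[, 2] - centre[2]) / ax[2])^2 +
      ((p[, 3] - centre[3]) / ax[3])^2 <= 1
  }
  node_region <- ifelse(in_ell(lat$nodes), "prostate", "surrounding")
  ip_region <- ifelse(in_ell(lat$ips), "prostate", "surrounding")
  i <- spec$axis_index
  bnd <- boundary_sets(lat$nodes, lat$extent, i, sign(spec$insertion_axis[i]))
  structure(list(nodes = lat$nodes,
                 ip_coords = lat$ips,
                 ip_weight = rep(lat$ip_weight, nrow(lat$ips)),
                 node_region = node_region,
                 ip_region = ip_region,
                 boundary = bnd,
                 spacing = h,
                 block_dims = lat$extent,
                 insertion_axis = spec$insertion_axis,
                 prostate = list(semi_axes = ax, centre = centre),
                 spec = spec),
            class = "bs_domain")
}

#' Build a homogeneous block domain
#'
#' A cuboidal lattice domain with a single region label, used for solver
#' verification problems (patch tests, uniaxial bars).
#'
#' @param dims Block edge lengths (mm), length 3.
#' @param spacing Lattice spacing (mm).
#' @param region Region label applied everywhere.
#' @param insertion_axis Axis used to orient the traction-free face.
#' @param quadrature Integration points per cell: 1, 4 (default) or 8.
#' @return A `bs_domain`.
#' @export
block_domain <- function(dims, spacing, region = "surrounding",
                         insertion_axis = c(0, 0, 1), quadrature = 4L) {
  stopifnot(length(dims) == 3, spacing > 0)
  lat <- build_lattice(dims, spacing, quadrature)
  i <- axis_index(insertion_axis)
  bnd <- boundary_sets(lat$nodes, lat$extent, i, sign(insertion_axis[i]))
  structure(list(nodes = lat$nodes,
                 ip_coords = lat$ips,
                 ip_weight = rep(lat$ip_weight, nrow(lat$ips)),
                 node_region = rep(region, nrow(lat$nodes)),
                 ip_region = rep(region, nrow(lat$ips)),
                 boundary = bnd,
                 spacing = spacing,
                 block_dims = lat$extent,
                 insertion_axis = as.numeric(insertion_axis),
                 prostate = NULL,
                 spec = NULL),
            class = "bs_domain")
}

#' @export
print.bs_domain <- function(x, ...) {
  cat("<bs_domain> ", nrow(x$nodes), " nodes, ", nrow(x$ip_coords),
      " integration points\n", sep = "")
  cat("  block: ", paste(round(x$block_dims, 3), collapse = " x "),
      " mm, spacing ", x$spacing, " mm\n", sep = "")
  tab <- table(x$node_region)
  cat("  node regions:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  boundary: fixed_external=", length(x$boundary$fixed_external),
      ", insertion_face=", length(x$boundary$insertion_face), "\n", sep = "")
  invisible(x)
}

#' Summed quadrature volume per region
#'
#' @param domain A `bs_domain`.
#' @return Named numeric vector of summed integration weights (mm^3).
#' @export
region_volumes <- function(domain) {
  tapply(domain$ip_weight, domain$ip_region, sum)
}

# prostate extent along the insertion axis (world coordinates), from the
# analytic ellipsoid when available, otherwise from labelled nodes
prostate_axis_extent <- function(domain) {
  i <- axis_index(domain$insertion_axis)
  if (!is.null(domain$prostate)) {
    c(domain$prostate$centre[i] - domain$prostate$semi_axes[i],
      domain$prostate$centre[i] + domain$prostate$semi_axes[i])
  } else {
    pr <- domain$node_region == "prostate"
    if (!any(pr)) stop("domain has no prostate nodes", call. = FALSE)
    range(domain$nodes[pr, i])
  }
}

# projected prostate silhouette centre on the insertion face, snapped to the
# node lattice so that template holes coincide with node columns whenever the
# template pitch is a multiple of the nodal spacing
silhouette_centre <- function(domain) {
  i <- axis_index(domain$insertion_axis)
  tang <- setdiff(1:3, i)
  ctr <- if (!is.null(domain$prostate)) {
    domain$prostate$centre[tang]
  } else {
    colMeans(domain$nodes[domain$node_region == "prostate", tang, drop = FALSE])
  }
  round(ctr / domain$spacing) * domain$spacing
}

#' Generate a needle plan on a template grid
#'
#' Places `n_anchor` anchor needles adjacent to the prostate midline and
#' `n_catheter` catheter-needles on square template-grid holes covering the
#' prostate silhouette on the insertion face. Anchors are inserted first.
#' Two built-in catheter orderings are provided: `"alternate_lb_rt"` starts
#' at the left-bottom hole, jumps to the right-top hole and alternates
#' inward; `"alternate_rb_lb"` starts bottom-right, jumps bottom-left and
#' alternates similarly.
#'
#' Anchor needles default to 0.5 mm radius (1 mm diameter) and stop at two
#' thirds of the prostate extent along the insertion axis; catheter-needles
#' default to 0.75 mm radius (1.5 mm diameter) and traverse to 2 mm beyond
#' the distal prostate boundary.
#'
#' @param domain A `bs_domain`.
#' @param n_anchor,n_catheter Needle counts (defaults 2 and 17).
#' @param template_pitch Template hole spacing in mm (default 5).
#' @param sequence Ordering rule id, `"alternate_lb_rt"` (default) or
#'   `"alternate_rb_lb"`.
#' @param anchor_radius,catheter_radius Needle radii in mm.
#' @param silhouette_shrink Fraction of the silhouette ellipse within which
#'   template holes are accepted (default 0.85).
#' @return A tibble of class `bs_needle_plan`, one row per insertion event in
#'   `order_index` order, with entry point, unit direction, depth, radius and
#'   type.
#' @export
generate_needle_plan <- function(domain, n_anchor = 2, n_catheter = 17,
                                 template_pitch = 5,
                                 sequence = c("alternate_lb_rt",
                                              "alternate_rb_lb"),
                                 anchor_radius = 0.5, catheter_radius = 0.75,
                                 silhouette_shrink = 0.85) {
  stopifnot(inherits(domain, "bs_domain"), n_anchor >= 0, n_catheter >= 0,
            template_pitch > 0, anchor_radius > 0, catheter_radius > 0)
  sequence <- match.arg(sequence)
  i <- axis_index(domain$insertion_axis)
  sgn <- sign(domain$insertion_axis[i])
  tang <- setdiff(1:3, i)
  ctr2 <- silhouette_centre(domain)
  # silhouette semi-axes in the face plane
  if (!is.null(domain$prostate)) {
    sil <- domain$prostate$semi_axes[tang]
  } else {
    pr <- domain$nodes[domain$node_region == "prostate", tang, drop = FALSE]
    sil <- apply(sweep(pr, 2, ctr2), 2, function(v) max(abs(v)))
  }
  # face coordinate along the axis (entry plane)
  face_coord <- if (sgn > 0) 0 else domain$block_dims[i]
  # template holes over the (shrunk) silhouette ellipse
  K <- ceiling(max(sil) / template_pitch) + 1
  g <- expand.grid(a = -K:K, b = -K:K)
  hx <- ctr2[1] + g$a * template_pitch
  hy <- ctr2[2] + g$b * template_pitch
  keep <- ((hx - ctr2[1]) / (silhouette_shrink * sil[1]))^2 +
    ((hy - ctr2[2]) / (silhouette_shrink * sil[2]))^2 <= 1
  holes <- cbind(hx[keep], hy[keep])
  if (nrow(holes) == 0) {
    stop("capacity error: template grid has no holes over the prostate ",
         "silhouette", call. = FALSE)
  }
  # anchors: the two template holes nearest the silhouette centre, one per
  # side of the midline
  anchors <- matrix(numeric(0), 0, 2)
  if (n_anchor > 0) {
    side <- rep_len(c(-1, 1), n_anchor)
    row_off <- rep(seq(0, by = 1, length.out = ceiling(n_anchor / 2)),
                   each = 2)[seq_len(n_anchor)]
    anchors <- cbind(ctr2[1] + side * template_pitch,
                     ctr2[2] - row_off * template_pitch)
  }
  # catheter holes: remaining template holes
  taken <- apply(holes, 1, function(p) {
    any(abs(p[1] - anchors[, 1]) < 1e-9 & abs(p[2] - anchors[, 2]) < 1e-9)
  })
  cat_holes <- holes[!taken, , drop = FALSE]
  if (nrow(cat_holes) < n_catheter) {
    stop("capacity error: ", n_catheter, " catheters requested but only ",
         nrow(cat_holes), " template holes cover the prostate silhouette",
         call. = FALSE)
  }
  # catheter set: the n_catheter holes nearest the silhouette centre
  # (sequence-independent), then ordered by the chosen sequence rule
  rad <- ((cat_holes[, 1] - ctr2[1]) / sil[1])^2 +
    ((cat_holes[, 2] - ctr2[2]) / sil[2])^2
  keep_idx <- order(rad, cat_holes[, 1], cat_holes[, 2])[seq_len(n_catheter)]
  cat_set <- cat_holes[keep_idx, , drop = FALSE]
  cath <- cat_set[order_catheter_holes(cat_set, ctr2, sequence), ,
                  drop = FALSE]

  ext <- prostate_axis_extent(domain)
  # depth measured from the entry face along the direction of travel
  depth_anchor <- if (sgn > 0) ext[1] + (2 / 3) * diff(ext) else
    (domain$block_dims[i] - ext[2]) + (2 / 3) * diff(ext)
  # each catheter stops 2 mm past the distal prostate boundary along its
  # own path (the gland is shallower off-centre)
  cath_depth_at <- function(h2) {
    if (!is.null(domain$prostate)) {
      ax3 <- domain$prostate$semi_axes
      ctr3 <- domain$prostate$centre
      q <- 1 - ((h2[, 1] - ctr2[1]) / sil[1])^2 -
        ((h2[, 2] - ctr2[2]) / sil[2])^2
      q <- pmax(q, 0)
      zb <- ctr3[i] + ax3[i] * sqrt(q)
      d <- if (sgn > 0) zb + 2 else (domain$block_dims[i] - zb) + 2
    } else {
      d <- rep(if (sgn > 0) ext[2] + 2 else
        (domain$block_dims[i] - ext[1]) + 2, nrow(h2))
    }
    pmin(d, domain$block_dims[i])
  }

  mk <- function(h2, type, radius, depth, ids) {
    n <- nrow(h2)
    if (n == 0) return(NULL)
    entry <- matrix(0, n, 3)
    entry[, tang[1]] <- h2[, 1]
    entry[, tang[2]] <- h2[, 2]
    entry[, i] <- face_coord
    tibble::tibble(needle_id = ids, type = type,
                   entry_x = entry[, 1], entry_y = entry[, 2],
                   entry_z = entry[, 3],
                   dir_x = domain$insertion_axis[1],
                   dir_y = domain$insertion_axis[2],
                   dir_z = domain$insertion_axis[3],
                   depth_mm = depth, radius_mm = radius)
  }
  plan <- dplyr::bind_rows(
    mk(anchors, "anchor", anchor_radius, depth_anchor,
       if (n_anchor > 0) paste0("A", seq_len(n_anchor)) else character(0)),
    mk(cath, "catheter", catheter_radius, cath_depth_at(cath),
       if (n_catheter > 0) paste0("C", seq_len(n_catheter)) else character(0)))
  if (is.null(plan) || ncol(plan) == 0) {
    plan <- tibble::tibble(needle_id = character(0), type = character(0),
                           entry_x = numeric(0), entry_y = numeric(0),
                           entry_z = numeric(0), dir_x = numeric(0),
                           dir_y = numeric(0), dir_z = numeric(0),
                           depth_mm = numeric(0), radius_mm = numeric(0))
  }
  plan$order_index <- seq_len(nrow(plan))
  # entry points must lie on the insertion face plane and inside the block
  stopifnot(all(plan$depth_mm <= domain$block_dims[i] + 1e-9))
  class(plan) <- c("bs_needle_plan", class(plan))
  attr(plan, "sequence") <- sequence
  attr(plan, "template_pitch") <- template_pitch
  plan
}

# indices 1..n alternating between the two ends of a list, moving inward
alternate_ends <- function(n, start_front = TRUE) {
  if (n == 0) return(integer(0))
  lo <- 1L; hi <- as.integer(n); from_lo <- start_front
  out <- integer(n)
  for (k in seq_len(n)) {
    if (from_lo) { out[k] <- lo; lo <- lo + 1L }
    else { out[k] <- hi; hi <- hi - 1L }
    from_lo <- !from_lo
  }
  out
}

# Built-in catheter insertion orderings (permutations of the hole rows).
# alternate_lb_rt: global alternation along the left-bottom/right-top
# diagonal, moving inward; alternate_rb_lb: row by row from the bottom,
# alternating right and left ends within each row.
order_catheter_holes <- function(holes, ctr2, sequence) {
  n <- nrow(holes)
  if (n == 0) return(integer(0))
  if (sequence == "alternate_lb_rt") {
    s <- (holes[, 1] - ctr2[1]) + (holes[, 2] - ctr2[2])
    ord <- order(s, holes[, 1], holes[, 2])
    ord[alternate_ends(n, start_front = TRUE)]
  } else {
    out <- integer(0)
    for (y in sort(unique(holes[, 2]))) {
      row <- which(abs(holes[, 2] - y) < 1e-9)
      row <- row[order(-holes[row, 1])]  # rightmost first
      out <- c(out, row[alternate_ends(length(row), start_front = TRUE)])
    }
    out
  }
}

#' Build a domain from a binary segmentation mask
#'
#' Entry point for real prostate segmentations: nodes are placed on a regular
#' lattice covering the mask bounding box plus a surrounding margin shell;
#' nodes (and cell-centre integration points) whose nearest voxel is
#' non-zero are labelled prostate, the shell is labelled surrounding.
#'
#' @param mask A [voxel_mask()] (or path readable by [read_mask()]).
#' @param spacing Nodal spacing in mm.
#' @param margin Thickness of the surrounding-tissue shell in mm (default 20).
#' @param insertion_axis Axis along which needles travel (default +z).
#' @param quadrature Integration points per cell: 1, 4 (default) or 8.
#' @return A `bs_domain`.
#' @export
domain_from_mask <- function(mask, spacing, margin = 20,
                             insertion_axis = c(0, 0, 1), quadrature = 4L) {
  if (is.character(mask)) mask <- read_mask(mask)
  stopifnot(inherits(mask, "bs_voxel_mask"), spacing > 0, margin >= 0)
  occ <- which(mask$data, arr.ind = TRUE)
  if (nrow(occ) == 0) stop("input error: mask is empty", call. = FALSE)
  # world coordinates of occupied voxel centres
  wc <- sweep((occ - 1) * mask$voxel, 2, mask$origin, "+")
  lo <- apply(wc, 2, min) - margin
  hi <- apply(wc, 2, max) + margin
  dims <- hi - lo
  lat <- build_lattice(dims, spacing, quadrature)
  nodes <- sweep(lat$nodes, 2, lo, "+")
  ips <- sweep(lat$ips, 2, lo, "+")
  lookup <- function(p) {
    idx <- sweep(p, 2, mask$origin) / mask$voxel
    idx <- round(idx) + 1
    ok <- idx[, 1] >= 1 & idx[, 1] <= dim(mask$data)[1] &
      idx[, 2] >= 1 & idx[, 2] <= dim(mask$data)[2] &
      idx[, 3] >= 1 & idx[, 3] <= dim(mask$data)[3]
    val <- logical(nrow(p))
    if (any(ok)) {
      val[ok] <- mask$data[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
    }
    val
  }
  node_region <- ifelse(lookup(nodes), "prostate", "surrounding")
  ip_region <- ifelse(lookup(ips), "prostate", "surrounding")
  if (!any(node_region == "prostate")) {
    stop("resolution error: no lattice node falls inside the mask; ",
         "decrease the spacing", call. = FALSE)
  }
  i <- axis_index(insertion_axis)
  bnd <- boundary_sets(lat$nodes, lat$extent, i, sign(insertion_axis[i]))
  structure(list(nodes = nodes,
                 ip_coords = ips,
                 ip_weight = rep(lat$ip_weight, nrow(ips)),
                 node_region = node_region,
                 ip_region = ip_region,
                 boundary = bnd,
                 spacing = spacing,
                 block_dims = lat$extent,
                 insertion_axis = as.numeric(insertion_axis),
                 prostate = NULL,
                 spec = NULL),
            class = "bs_domain")
}
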