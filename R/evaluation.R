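# Voxelisation, Dice similarity and displacement statistics.

#' Construct a voxel mask
#'
#' Binary occupancy grid on an axis-aligned domain with isotropic voxels.
#' `origin` is the world coordinate of the centre of voxel `[1, 1, 1]`.
#'
#' @param data Logical (or coercible) 3-D array.
#' @param origin Numeric length 3, mm.
#' @param voxel Isotropic voxel edge length, mm.
#' @return Object of class `bs_voxel_mask`.
#' @export
voxel_mask <- function(data, origin, voxel) {
  data <- array(as.logical(data), dim = dim(data))
  stopifnot(length(dim(data)) == 3, length(origin) == 3, voxel > 0,
            all(dim(data) >= 1))
  structure(list(data = data, origin = as.numeric(origin),
                 voxel = as.numeric(voxel)),
            class = "bs_voxel_mask")
}

#' @export
print.bs_voxel_mask <- function(x, ...) {
  cat("<bs_voxel_mask> ", paste(dim(x$data), collapse = " x "), " voxels @ ",
      x$voxel, " mm, ", sum(x$data), " occupied (",
      format(mask_volume(x), digits = 6), " mm^3)\n", sep = "")
  invisible(x)
}

#' Mask volume
#' @param mask A `bs_voxel_mask`.
#' @return Occupied volume in mm^3.
#' @export
mask_volume <- function(mask) {
  sum(mask$data) * mask$voxel^3
}

# quasi-uniform unit directions (Fibonacci sphere)
fibonacci_directions <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- pi * (1 + sqrt(5)) * i
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Voxelise a deformed region of the domain
#'
#' The deformed positions of the region's nodes define a convex envelope
#' (supporting-halfspace approximation of the convex hull over a
#' quasi-uniform direction set), expanded outward by `offset` to compensate
#' for the support deficit of lattice sampling: along any direction the
#' outermost node lies inside the true surface by about
#' `h^1.5 / sqrt(2 R)` for nodal spacing `h` and surface curvature radius
#' `R` (the tangency cap of width `sqrt(2 R t)` must be wide enough to
#' contain a lattice point). The default offset evaluates this with `R`
#' taken as the equivalent-sphere radius of the region. Voxels whose
#' centres fall inside the envelope are set; the grid spans the
#' axis-aligned bounding cube padded by two voxels.
#'
#' The prostate is nearly convex, so the convex envelope is an adequate
#' surface reconstruction at the accuracy of the nodal sampling.
#'
#' @param domain A `bs_domain`.
#' @param state A `bs_sim_state`, an n x 3 displacement matrix, or `NULL`
#'   for the reference configuration.
#' @param region Region label to voxelise. Default `"prostate"`.
#' @param voxel Voxel size, mm. Default 1.
#' @param offset Outward surface offset, mm; default
#'   `h^1.5 / sqrt(2 R_equiv)` as described above.
#' @param n_dirs Number of support directions. Default 4000.
#' @return A [voxel_mask()].
#' @export
voxelize_region <- function(domain, state = NULL, region = "prostate",
                            voxel = 1, offset = NULL, n_dirs = 4000) {
  stopifnot(inherits(domain, "bs_domain"), voxel > 0)
  sel <- domain$node_region == region
  if (!any(sel)) stop("no nodes labelled '", region, "'", call. = FALSE)
  if (is.null(offset)) {
    h <- domain$spacing
    r_equiv <- (3 * sum(sel) * h^3 / (4 * pi))^(1 / 3)
    offset <- h^1.5 / sqrt(2 * r_equiv)
  }
  pts <- domain$nodes[sel, , drop = FALSE]
  if (!is.null(state)) {
    u <- if (inherits(state, "bs_sim_state")) state$u else as.matrix(state)
    pts <- pts + u[sel, , drop = FALSE]
  }
  if (any(!is.finite(pts))) {
    stop("non-finite deformed coordinates", call. = FALSE)
  }
  # degenerate (coplanar or thinner) point sets cannot bound a volume
  sv <- svd(sweep(pts, 2, colMeans(pts)), nu = 0, nv = 0)$d
  if (length(sv) < 3 || sv[3] / sqrt(nrow(pts)) < 1e-6) {
    stop("geometry error: degenerate (coplanar) point set", call. = FALSE)
  }
  lo <- apply(pts, 2, min) - offset
  hi <- apply(pts, 2, max) + offset
  side <- max(hi - lo) + 4 * voxel  # bounding cube, padded by 2 voxels
  ctr <- (lo + hi) / 2
  nvox <- ceiling(side / voxel)
  origin <- ctr - (nvox - 1) / 2 * voxel
  dirs <- fibonacci_directions(n_dirs)
  occ <- cpp_support_occupancy(pts, dirs, origin, voxel,
                               rep(as.integer(nvox), 3), offset)
  voxel_mask(array(occ, dim = rep(nvox, 3)), origin, voxel)
}

# nearest-neighbour resample of a mask onto a target grid
resample_mask <- function(mask, origin, voxel, nvox) {
  ax <- lapply(1:3, function(i) origin[i] + (0:(nvox - 1)) * voxel)
  idx <- lapply(1:3, function(i) {
    round((ax[[i]] - mask$origin[i]) / mask$voxel) + 1
  })
  dm <- dim(mask$data)
  ok <- lapply(1:3, function(i) idx[[i]] >= 1 & idx[[i]] <= dm[i])
  out <- array(FALSE, dim = rep(nvox, 3))
  ii <- which(ok[[1]]); jj <- which(ok[[2]]); kk <- which(ok[[3]])
  if (length(ii) && length(jj) && length(kk)) {
    out[ii, jj, kk] <- mask$data[idx[[1]][ii], idx[[2]][jj], idx[[3]][kk],
                                 drop = FALSE]
  }
  out
}

#' Dice similarity coefficient between two masks
#'
#' The operands are resampled (nearest neighbour) onto a common cubic
#' domain — the bounding cube of both grids at the finest of the two voxel
#' sizes — and `D = 2|A & B| / (|A| + |B|)` is evaluated by voxel counting.
#' Two empty masks compare as 1 with a warning.
#'
#' @param a,b [voxel_mask()] objects.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stopifnot(inherits(a, "bs_voxel_mask"), inherits(b, "bs_voxel_mask"))
  ref <- if (b$voxel < a$voxel) b else a
  voxel <- ref$voxel
  corner <- function(m) {
    list(lo = m$origin - m$voxel / 2,
         hi = m$origin + (dim(m$data) - 0.5) * m$voxel)
  }
  ca <- corner(a); cb <- corner(b)
  lo <- pmin(ca$lo, cb$lo)
  hi <- pmax(ca$hi, cb$hi)
  # common cubic grid aligned with the finer operand's voxel centres, so
  # that resampling is exact whenever the operands share a grid
  i_lo <- floor((lo - ref$origin) / voxel + 0.5)
  i_hi <- ceiling((hi - ref$origin) / voxel - 0.5)
  nvox <- max(i_hi - i_lo + 1)
  origin <- ref$origin + i_lo * voxel
  A <- resample_mask(a, origin, voxel, nvox)
  B <- resample_mask(b, origin, voxel, nvox)
  na <- sum(A); nb <- sum(B)
  if (na + nb == 0) {
    warning("both masks are empty; Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(A & B) / (na + nb)
}

#' In-plane displacement statistics
#'
#' Projects prostate-node displacements onto the plane orthogonal to
#' `plane_normal` (by default the insertion axis, the short-axis imaging
#' analogue) and summarises the projected magnitudes.
#'
#' @param state A `bs_sim_state` or displacement matrix.
#' @param domain A `bs_domain`.
#' @param plane_normal Unit normal of the projection plane; defaults to the
#'   domain's insertion axis.
#' @param region Node region to summarise. Default `"prostate"`.
#' @return One-row tibble: `mean_mm`, `sd_mm`, `max_mm`, `n_nodes`, and the
#'   plane normal components.
#' @export
inplane_displacement_stats <- function(state, domain,
                                       plane_normal = NULL,
                                       region = "prostate") {
  if (is.null(plane_normal)) plane_normal <- domain$insertion_axis
  stopifnot(abs(sqrt(sum(plane_normal^2)) - 1) < 1e-8)
  u <- if (inherits(state, "bs_sim_state")) state$u else as.matrix(state)
  sel <- domain$node_region == region
  up <- u[sel, , drop = FALSE]
  axial <- as.vector(up %*% plane_normal)
  uin <- up - outer(axial, plane_normal)
  mag <- sqrt(rowSums(uin^2))
  tibble::tibble(mean_mm = mean(mag), sd_mm = stats::sd(mag),
                 max_mm = max(mag), n_nodes = sum(sel),
                 normal_x = plane_normal[1], normal_y = plane_normal[2],
                 normal_z = plane_normal[3])
}

#' Centroid displacement of a region
#'
#' @param state A `bs_sim_state` or displacement matrix.
#' @param domain A `bs_domain`.
#' @param region Region label. Default `"prostate"`.
#' @return Length-3 displacement of the region centroid (mm).
#' @export
centroid_displacement <- function(state, domain, region = "prostate") {
  u <- if (inherits(state, "bs_sim_state")) state$u else as.matrix(state)
  sel <- domain$node_region == region
  colMeans(u[sel, , drop = FALSE])
}

#' Dice between two procedure snapshots
#'
#' Voxelises the prostate at two stored snapshots of a procedure and
#' returns their mutual Dice coefficient.
#'
#' @param result A [run_procedure()] result.
#' @param events Character length 2, snapshot names (e.g. `"initial"`,
#'   `"C17"`).
#' @param voxel Voxel size, mm.
#' @return Dice coefficient.
#' @export
compare_snapshots <- function(result, events, voxel = 1) {
  stopifnot(inherits(result, "bs_procedure_result"), length(events) == 2)
  missing_ev <- setdiff(events, names(result$snapshots))
  if (length(missing_ev) > 0) {
    stop("lookup error: no snapshot named ",
         paste(missing_ev, collapse = ", "), call. = FALSE)
  }
  m1 <- voxelize_region(result$domain, result$snapshots[[events[1]]],
                        voxel = voxel)
  m2 <- voxelize_region(result$domain, result$snapshots[[events[2]]],
                        voxel = voxel)
  dice(m1, m2)
}
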