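# Mask input (NIfTI / MetaImage), VTK export, YAML run configs and JSON
# metric reports.

#' Read a binary segmentation mask
#'
#' NIfTI (`.nii`, `.nii.gz`) is read through RNifti; MetaImage (`.mha`,
#' uncompressed or gzip-compressed, local data) through a minimal built-in
#' parser. Any non-zero voxel of any integer dtype counts as prostate.
#' Anisotropic voxels are accepted only when (near-)isotropic, since the
#' evaluation grid is isotropic.
#'
#' @param path File path.
#' @return A [voxel_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    vox <- RNifti::pixdim(img)
    data <- array(as.array(img) != 0, dim = dim(img))
    if (max(vox) - min(vox) > 1e-6 * max(vox)) {
      stop("anisotropic voxels (", paste(signif(vox, 4), collapse = " x "),
           " mm) are not supported", call. = FALSE)
    }
    # voxel [1,1,1] centre at the NIfTI offset (qform translation)
    xf <- RNifti::xform(img)
    origin <- xf[1:3, 4]
    return(voxel_mask(data, origin, vox[1]))
  }
  if (grepl("\\.mha$", path, ignore.case = TRUE)) {
    return(read_mha(path))
  }
  stop("unsupported mask format: ", path,
       " (expected .nii, .nii.gz or .mha)", call. = FALSE)
}

# Minimal MetaImage reader: ASCII header then raw (optionally gzip) voxels.
read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (length(line) == 0) stop("malformed MetaImage header", call. = FALSE)
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed MetaImage header line: ", line,
                              call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    hdr[[key]] <- val
    if (key == "ElementDataFile") break
  }
  if (!identical(hdr[["ElementDataFile"]], "LOCAL")) {
    stop("only MetaImage files with local data are supported", call. = FALSE)
  }
  ndims <- as.integer(hdr[["NDims"]])
  if (!identical(ndims, 3L)) stop("expected a 3-D MetaImage", call. = FALSE)
  dims <- as.integer(strsplit(hdr[["DimSize"]], "\\s+")[[1]])
  spacing <- as.numeric(strsplit(hdr[["ElementSpacing"]] %||% "1 1 1",
                                 "\\s+")[[1]])
  origin <- as.numeric(strsplit(hdr[["Offset"]] %||% "0 0 0", "\\s+")[[1]])
  type <- hdr[["ElementType"]] %||% "MET_UCHAR"
  sizes <- c(MET_CHAR = 1, MET_UCHAR = 1, MET_SHORT = 2, MET_USHORT = 2,
             MET_INT = 4, MET_UINT = 4, MET_FLOAT = 4, MET_DOUBLE = 8)
  if (!type %in% names(sizes)) stop("unsupported ElementType ", type,
                                    call. = FALSE)
  nbytes <- prod(dims) * sizes[[type]]
  raw <- readBin(con, "raw", n = nbytes + 64)
  if (identical(tolower(hdr[["CompressedData"]] %||% "false"), "true")) {
    raw <- memDecompress(raw, type = "gzip")
  }
  what <- if (type %in% c("MET_FLOAT", "MET_DOUBLE")) "numeric" else "integer"
  vals <- readBin(raw, what, n = prod(dims), size = sizes[[type]],
                  signed = !(type %in% c("MET_UCHAR", "MET_USHORT")))
  if (max(spacing) - min(spacing) > 1e-6 * max(spacing)) {
    stop("anisotropic voxels are not supported", call. = FALSE)
  }
  voxel_mask(array(vals != 0, dim = dims), origin, spacing[1])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a mask as an uncompressed MetaImage file
#'
#' @param mask A [voxel_mask()].
#' @param path Output path (`.mha`).
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "bs_voxel_mask"))
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image", "NDims = 3", "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste("DimSize =", paste(dim(mask$data), collapse = " ")),
           paste("ElementSpacing =", paste(rep(mask$voxel, 3),
                                           collapse = " ")),
           paste("Offset =", paste(mask$origin, collapse = " ")),
           "ElementType = MET_UCHAR", "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  writeBin(as.raw(as.integer(mask$data)), con)
  invisible(path)
}

#' Export a domain state as a VTK unstructured grid (.vtu)
#'
#' Nodes are written as vertex cells with region labels, displacement and
#' any extra point data, in ASCII XML — loadable in ParaView.
#'
#' @param domain A `bs_domain`.
#' @param path Output path.
#' @param state Optional `bs_sim_state` or displacement matrix; written as
#'   the `displacement` point-data array (and added to the points when
#'   `deformed = TRUE`).
#' @param point_data Named list of additional per-node numeric vectors.
#' @param deformed Write deformed node positions. Default `FALSE`.
#' @return `path`, invisibly.
#' @export
write_vtu <- function(domain, path, state = NULL, point_data = list(),
                      deformed = FALSE) {
  n <- nrow(domain$nodes)
  u <- matrix(0, n, 3)
  if (!is.null(state)) {
    u <- if (inherits(state, "bs_sim_state")) state$u else as.matrix(state)
  }
  pts <- if (deformed) domain$nodes + u else domain$nodes
  num <- function(x) paste(format(x, trim = TRUE, digits = 9),
                           collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w('<?xml version="1.0"?>')
  w('<VTKFile type="UnstructuredGrid" version="0.1" byte_order="LittleEndian">')
  w('<UnstructuredGrid><Piece NumberOfPoints="', n, '" NumberOfCells="', n,
    '">')
  w('<Points><DataArray type="Float64" NumberOfComponents="3" format="ascii">')
  w(num(t(pts)))
  w('</DataArray></Points>')
  w('<Cells>')
  w('<DataArray type="Int64" Name="connectivity" format="ascii">')
  w(paste(0:(n - 1), collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Int64" Name="offsets" format="ascii">')
  w(paste(1:n, collapse = " "))
  w('</DataArray>')
  w('<DataArray type="UInt8" Name="types" format="ascii">')
  w(paste(rep(1, n), collapse = " "))  # VTK_VERTEX
  w('</DataArray>')
  w('</Cells>')
  w('<PointData>')
  w('<DataArray type="Int32" Name="region" format="ascii">')
  w(paste(as.integer(domain$node_region == "prostate"), collapse = " "))
  w('</DataArray>')
  w('<DataArray type="Float64" Name="displacement" NumberOfComponents="3" format="ascii">')
  w(num(t(u)))
  w('</DataArray>')
  for (nm in names(point_data)) {
    w('<DataArray type="Float64" Name="', nm, '" format="ascii">')
    w(num(point_data[[nm]]))
    w('</DataArray>')
  }
  w('</PointData>')
  w('</Piece></UnstructuredGrid></VTKFile>')
  invisible(path)
}

#' Write a ParaView time-series collection (.pvd)
#'
#' @param files Character vector of `.vtu` paths (relative to the `.pvd`).
#' @param path Output `.pvd` path.
#' @param times Numeric time stamps; defaults to the event index.
#' @return `path`, invisibly.
#' @export
write_pvd <- function(files, path, times = seq_along(files) - 1) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines('<?xml version="1.0"?>', con)
  writeLines('<VTKFile type="Collection" version="0.1"><Collection>', con)
  for (i in seq_along(files)) {
    writeLines(sprintf('<DataSet timestep="%g" file="%s"/>', times[i],
                       files[i]), con)
  }
  writeLines('</Collection></VTKFile>', con)
  invisible(path)
}

#' Export a procedure result as a VTK time series
#'
#' One `.vtu` per snapshot (with region, displacement and stiffening scale
#' interpolated per node) plus a `.pvd` collection.
#'
#' @param result A [run_procedure()] result.
#' @param dir Output directory (created if missing).
#' @param basename File stem. Default `"state"`.
#' @return Path of the `.pvd` file, invisibly.
#' @export
write_procedure_vtk <- function(result, dir, basename = "state") {
  stopifnot(inherits(result, "bs_procedure_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nms <- names(result$snapshots)
  files <- character(length(nms))
  for (i in seq_along(nms)) {
    files[i] <- sprintf("%s_%03d.vtu", basename, i - 1)
    write_vtu(result$domain, file.path(dir, files[i]),
              state = result$snapshots[[i]])
  }
  pvd <- file.path(dir, paste0(basename, ".pvd"))
  write_pvd(files, pvd)
  invisible(pvd)
}

#' Read a run configuration (YAML)
#'
#' Schema (all blocks optional, defaults apply): `phantom` (arguments of
#' [phantom_spec()]), `plan` (arguments of [generate_needle_plan()]),
#' `materials` (per-region `E`, `nu`, `rho` or `mu`, `kappa`), `insertion`
#' (arguments of [insertion_config()]), `solver` (`safety`, `tol`,
#' `window`, `max_iter`, `mass_scaling`), and `run`
#' (`anchor_stiffening`, `voxel`).
#'
#' @param path YAML file path.
#' @return Nested list of class `bs_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  structure(cfg, class = "bs_run_config")
}

config_materials <- function(cfg) {
  if (is.null(cfg$materials)) return(default_materials())
  lapply(cfg$materials, function(m) do.call(material, m))
}

#' Run a full procedure from a configuration
#'
#' Convenience wrapper used by the command-line interface: builds the
#' phantom, the needle plan and the insertion configuration from a
#' [read_run_config()] list, runs the procedure and returns the result with
#' summary metrics attached.
#'
#' @param cfg A `bs_run_config` (or path to one).
#' @param quiet Suppress progress output.
#' @return A [run_procedure()] result; attribute `metrics` holds a named
#'   list of summary values.
#' @export
run_from_config <- function(cfg, quiet = TRUE) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  spec <- do.call(phantom_spec, cfg$phantom %||% list())
  domain <- generate_phantom(spec)
  plan <- do.call(generate_needle_plan,
                  c(list(domain = domain), cfg$plan %||% list()))
  icfg <- do.call(insertion_config, cfg$insertion %||% list())
  run_opts <- cfg$run %||% list()
  ctx <- do.call(solver_context,
                 c(list(domain = domain,
                        field = material_field(domain,
                                               config_materials(cfg))),
                   cfg$solver %||% list()))
  res <- run_procedure(domain, plan, icfg,
                       materials = config_materials(cfg),
                       anchor_stiffening = run_opts$anchor_stiffening %||%
                         TRUE,
                       ctx = ctx, quiet = quiet)
  voxel <- run_opts$voxel %||% 1
  stats <- inplane_displacement_stats(res$state, domain)
  final <- utils::tail(names(res$snapshots), 1)
  metrics <- list(
    mean_inplane_mm = stats$mean_mm, sd_inplane_mm = stats$sd_mm,
    max_inplane_mm = stats$max_mm,
    dice_initial_vs_final = compare_snapshots(res, c("initial", final),
                                              voxel = voxel),
    n_snapshots = length(res$snapshots))
  attr(res, "metrics") <- metrics
  res
}

#' Write a metrics list as JSON
#'
#' @param metrics Named list of scalar metrics.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(metrics, path) {
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
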