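# Near-incompressible Neo-Hookean hyperelasticity and the spatial material
# field with multiplicative stiffening.

#' Define a material
#'
#' Near-incompressible Neo-Hookean material, specified either by shear and
#' bulk moduli or by Young's modulus and Poisson ratio. Near-incompressibility
#' requires a bulk-to-shear ratio of at least 10.
#'
#' @param E Young's modulus, kPa.
#' @param nu Poisson ratio.
#' @param mu Shear modulus, kPa (alternative to `E`/`nu`).
#' @param kappa Bulk modulus, kPa (alternative to `E`/`nu`).
#' @param rho Density, kg/m^3. Default 1000.
#' @return Object of class `bs_material` with fields `mu`, `kappa`, `rho`
#'   (and `E`, `nu` when derivable).
#' @examples
#' material(E = 25, nu = 0.49)
#' @export
material <- function(E = NULL, nu = NULL, mu = NULL, kappa = NULL,
                     rho = 1000) {
  if (!is.null(E) && !is.null(nu)) {
    if (E <= 0 || nu <= 0 || nu >= 0.5) {
      stop("require E > 0 and 0 < nu < 0.5", call. = FALSE)
    }
    mu <- E / (2 * (1 + nu))
    kappa <- E / (3 * (1 - 2 * nu))
  } else if (is.null(mu) || is.null(kappa)) {
    stop("specify either (E, nu) or (mu, kappa)", call. = FALSE)
  } else {
    nu <- (3 * kappa - 2 * mu) / (2 * (3 * kappa + mu))
    E <- 2 * mu * (1 + nu)
  }
  if (mu <= 0 || kappa <= 0) stop("moduli must be positive", call. = FALSE)
  if (kappa / mu < 10) {
    stop("near-incompressibility requires kappa/mu >= 10 (got ",
         round(kappa / mu, 2), ")", call. = FALSE)
  }
  if (rho <= 0) stop("density must be positive", call. = FALSE)
  structure(list(mu = mu, kappa = kappa, rho = rho, E = E, nu = nu),
            class = "bs_material")
}

#' @export
print.bs_material <- function(x, ...) {
  cat(sprintf("<bs_material> mu=%.3f kPa, kappa=%.3f kPa (E=%.2f kPa, nu=%.4f), rho=%g kg/m^3\n",
              x$mu, x$kappa, x$E, x$nu, x$rho))
  invisible(x)
}

#' Default tissue materials
#'
#' Mid-range elastography values: prostate E = 25 kPa, surrounding tissue
#' E = 10 kPa, both with nu = 0.49 and density 1000 kg/m^3.
#' @return Named list of [material()] objects by region label.
#' @export
default_materials <- function() {
  list(prostate = material(E = 25, nu = 0.49, rho = 1000),
       surrounding = material(E = 10, nu = 0.49, rho = 1000))
}

#' Per-integration-point material field with stiffening scale
#'
#' Assigns a base material to every integration point by region label and
#' initialises the multiplicative stiffening scale to 1 everywhere. Anchor
#' and catheter events raise the scale via max-composition (scales never
#' compound).
#'
#' @param domain A `bs_domain`.
#' @param materials Named list of [material()] objects keyed by region label.
#' @return Object of class `bs_material_field` with per-point vectors `mu0`,
#'   `kappa0`, `rho` and `scale`.
#' @export
material_field <- function(domain, materials = default_materials()) {
  stopifnot(inherits(domain, "bs_domain"))
  regions <- unique(domain$ip_region)
  missing_m <- setdiff(regions, names(materials))
  if (length(missing_m) > 0) {
    stop("no material given for region(s): ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  mu0 <- kappa0 <- rho <- numeric(length(domain$ip_region))
  for (r in regions) {
    sel <- domain$ip_region == r
    mu0[sel] <- materials[[r]]$mu
    kappa0[sel] <- materials[[r]]$kappa
    rho[sel] <- materials[[r]]$rho
  }
  structure(list(mu0 = mu0, kappa0 = kappa0, rho = rho,
                 scale = rep(1, length(mu0)), materials = materials),
            class = "bs_material_field")
}

#' @export
print.bs_material_field <- function(x, ...) {
  cat("<bs_material_field> ", length(x$mu0), " integration points; ",
      sum(x$scale > 1), " stiffened (max scale ", max(x$scale), ")\n",
      sep = "")
  invisible(x)
}

#' Effective material at one integration point
#'
#' Base moduli multiplied by the point's stiffening scale; density is never
#' scaled.
#'
#' @param field A `bs_material_field`.
#' @param ip Integration-point index.
#' @return A `bs_material`.
#' @export
effective_material <- function(field, ip) {
  stopifnot(inherits(field, "bs_material_field"),
            ip >= 1, ip <= length(field$mu0))
  s <- field$scale[ip]
  structure(list(mu = field$mu0[ip] * s, kappa = field$kappa0[ip] * s,
                 rho = field$rho[ip],
                 E = NA_real_, nu = NA_real_),
            class = "bs_material")
}

# effective per-point modulus vectors, used by the solver
effective_moduli <- function(field) {
  list(mu = field$mu0 * field$scale, kappa = field$kappa0 * field$scale)
}

#' Neo-Hookean strain-energy density
#'
#' Decoupled (J-split) form
#' `W = mu/2 (J^{-2/3} tr(F'F) - 3) + kappa/2 (J - 1)^2` with `J = det F`.
#' Zero exactly at any rotation.
#'
#' @param F 3 x 3 deformation gradient (det F > 0).
#' @param m A [material()].
#' @return Energy density in kPa (equivalently mJ/cm^3).
#' @export
strain_energy <- function(F, m) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)), inherits(m, "bs_material"))
  J <- det(F)
  if (J <= 0) stop("inverted-element error: det F = ", format(J), " <= 0",
                   call. = FALSE)
  I1 <- sum(F^2)
  0.5 * m$mu * (J^(-2 / 3) * I1 - 3) + 0.5 * m$kappa * (J - 1)^2
}

#' First Piola-Kirchhoff stress
#'
#' Analytic derivative of [strain_energy()] with respect to the deformation
#' gradient:
#' `P = mu J^{-2/3} (F - I1/3 F^{-T}) + kappa (J - 1) J F^{-T}`.
#'
#' @inheritParams strain_energy
#' @return 3 x 3 stress matrix, kPa.
#' @export
pk1_stress <- function(F, m) {
  F <- as.matrix(F)
  stopifnot(all(dim(F) == c(3, 3)), inherits(m, "bs_material"))
  J <- det(F)
  if (J <= 0) stop("inverted-element error: det F = ", format(J), " <= 0",
                   call. = FALSE)
  I1 <- sum(F^2)
  FinvT <- t(solve(F))
  m$mu * J^(-2 / 3) * (F - (I1 / 3) * FinvT) + m$kappa * (J - 1) * J * FinvT
}
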