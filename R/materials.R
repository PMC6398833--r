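#' Hyperelastic tissue materials
#'
#' Two constitutive families describe the venous tissues, both functions of
#' the first stretch invariant I1 (the fiber-direction terms in the full
#' transversely isotropic forms drop out in the transverse plane, alpha = 1):
#'
#' * wall / sinus (polynomial): `W = c1(a-1) + c2(a-1)^3 + c3(I1-3)
#'   + c4(I1-3)(a-1) + c5(I1-3)^2`
#' * valve (exponential): `W = c0(exp(c1 (I1-3)^2 + c2 (a-1)^4) - 1)
#'   + mu_baseline/2 (I1-3)`
#'
#' The exponential valve law has zero tangent modulus at the reference state,
#' so a neo-Hookean baseline term with shear modulus `mu_baseline` supplies
#' the small-strain stiffness; its default 200/3 kPa makes the small-strain
#' Young modulus of the healthy valve about 200 kPa under near
#' incompressibility. Lesion cases scale `c0` and `mu_baseline` together.
#'
#' Energies are stated in kPa (= 10 J/m^3 per unit volume); the solver
#' converts to CGS internally.
#'
#' @param c1,c2,c3,c4,c5 wall polynomial coefficients (kPa); the alpha terms
#'   `c1`, `c2`, `c4` default to 0 (inert for alpha = 1). The default `c3`,
#'   `c5` are the characteristic coefficient pair (2.0, 187.5) scaled by a
#'   common factor 125 so that the small-strain Young modulus (about `6 c3`
#'   under near incompressibility) matches the wall's stated initial elastic
#'   modulus of 1.5 MPa; the sinus takes a quarter of the wall stiffness.
#' @param rho_s tissue density (g/cm^3).
#' @return material list of class `wall_material` / `valve_material`.
#' @name tissue_materials
NULL

#' @rdname tissue_materials
#' @export
wall_material <- function(c3 = 250, c5 = 23437.5, c1 = 0, c2 = 0, c4 = 0,
                          rho_s = 1.10) {
  stopifnot(c3 > 0, c5 >= 0, rho_s > 0)
  structure(list(type = "poly", c1 = c1, c2 = c2, c3 = c3, c4 = c4, c5 = c5,
                 rho_s = rho_s),
            class = c("wall_material", "tissue_material"))
}

#' @rdname tissue_materials
#' @export
sinus_material <- function(c3 = 62.5, c5 = 5859.375, rho_s = 1.10) {
  m <- wall_material(c3 = c3, c5 = c5, rho_s = rho_s)
  m
}

#' @rdname tissue_materials
#' @param c0 exponential prefactor (kPa).
#' @param c1_exp,c2_exp dimensionless exponential coefficients.
#' @param mu_baseline baseline shear modulus (kPa).
#' @export
valve_material <- function(c0 = 417, c1_exp = 0.06, c2_exp = 0,
                           mu_baseline = 200 / 3, rho_s = 1.10) {
  stopifnot(c0 > 0, c1_exp >= 0, mu_baseline >= 0, rho_s > 0)
  structure(list(type = "exp", c0 = c0, c1_exp = c1_exp, c2_exp = c2_exp,
                 mu_baseline = mu_baseline, rho_s = rho_s),
            class = c("valve_material", "tissue_material"))
}

#' Strain energy density of the wall material
#'
#' @param I1 first stretch invariant (3 at the reference state).
#' @param alpha fiber-direction stretch (1 in the transverse plane).
#' @param mat a [wall_material()].
#' @return energy density in kPa.
#' @export
strain_energy_wall <- function(I1, alpha = 1, mat = wall_material()) {
  stopifnot(all(I1 >= 2), all(alpha > 0))
  mat$c1 * (alpha - 1) + mat$c2 * (alpha - 1)^3 + mat$c3 * (I1 - 3) +
    mat$c4 * (I1 - 3) * (alpha - 1) + mat$c5 * (I1 - 3)^2
}

#' Strain energy density of the valve material
#'
#' The exponent is clamped at 700 to guard overflow; energies above
#' `1e4 * c0` trigger a divergence warning.
#'
#' @inheritParams strain_energy_wall
#' @param mat a [valve_material()].
#' @return energy density in kPa.
#' @export
strain_energy_valve <- function(I1, alpha = 1, mat = valve_material()) {
  stopifnot(all(I1 >= 2), all(alpha > 0))
  ex <- pmin(mat$c1_exp * (I1 - 3)^2 + mat$c2_exp * (alpha - 1)^4, 700)
  W <- mat$c0 * (exp(ex) - 1) + mat$mu_baseline / 2 * (I1 - 3)
  if (any(W > 1e4 * mat$c0))
    warning("valve strain energy exceeds 1e4 * c0: likely divergence")
  W
}

# dW/dI1 in kPa (alpha = 1); vectorized
dW_dI1 <- function(I1, mat) {
  if (mat$type == "poly") {
    mat$c3 + 2 * mat$c5 * (I1 - 3)
  } else {
    ex <- pmin(mat$c1_exp * (I1 - 3)^2, 400)
    mat$c0 * exp(ex) * 2 * mat$c1_exp * (I1 - 3) + mat$mu_baseline / 2
  }
}

# d2W/dI1^2 in kPa
d2W_dI12 <- function(I1, mat) {
  if (mat$type == "poly") {
    rep(2 * mat$c5, length(I1))
  } else {
    ex <- pmin(mat$c1_exp * (I1 - 3)^2, 400)
    mat$c0 * exp(ex) * (2 * mat$c1_exp + (2 * mat$c1_exp * (I1 - 3))^2)
  }
}

# reference shear modulus 2 dW/dI1 at I1 = 3, in kPa
reference_shear_modulus <- function(mat) 2 * dW_dI1(3, mat)

#' Deformation kinematics
#'
#' Builds the kinematic quantities from a 2x2 deformation gradient under the
#' plane-strain convention (out-of-plane stretch 1): `B = F F^T`,
#' `I1 = tr(B) + 1`, fiber stretch `alpha = |F N|`.
#'
#' @param F 2x2 deformation gradient.
#' @param N reference fiber axis unit vector (default e1).
#' @return list of class `kinematics` with `F`, `B`, `I1`, `alpha`, `J`.
#' @export
kinematics <- function(F, N = c(1, 0)) {
  F <- matrix(F, 2, 2)
  B <- F %*% t(F)
  J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  if (J <= 0) stop("element failure: non-positive Jacobian")
  n <- N / sqrt(sum(N^2))
  structure(list(F = F, B = B, I1 = sum(diag(B)) + 1,
                 alpha = sqrt(sum((F %*% n)^2)), N = n, J = J),
            class = "kinematics")
}

#' Cauchy stress of a tissue material
#'
#' With the default `p_s = NULL` the nearly incompressible plane-strain form
#' is used: the energy is evaluated at the isochoric invariant
#' `I1_bar = tr(B)/J + 1` and a volumetric penalty `kappa (J - 1)` supplies
#' the pressure, so the reference state is exactly stress free:
#' `sigma = (2 W'(I1_bar) / J^2)(B - tr(B)/2 I) + kappa (J - 1) I`.
#' Supplying `p_s` instead evaluates the Lagrange-multiplier form
#' `sigma = -p_s I + 2 W'(I1) B` directly.
#'
#' @param kin a [kinematics()] object.
#' @param mat a tissue material.
#' @param p_s optional pressure (kPa).
#' @param kappa_factor penalty stiffness as a multiple of the reference shear
#'   modulus.
#' @return 2x2 symmetric Cauchy stress in dyn/cm^2.
#' @export
cauchy_stress <- function(kin, mat, p_s = NULL, kappa_factor = 100) {
  B <- kin$B; J <- kin$J
  if (is.null(p_s)) {
    I1b <- sum(diag(B)) / J + 1
    Wp <- kpa_to_cgs(dW_dI1(I1b, mat))
    kap <- kappa_factor * kpa_to_cgs(reference_shear_modulus(mat))
    s <- (2 * Wp / J^2) * (B - sum(diag(B)) / 2 * diag(2)) +
      kap * (J - 1) * diag(2)
  } else {
    Wp <- kpa_to_cgs(dW_dI1(kin$I1, mat))
    s <- -kpa_to_cgs(p_s) * diag(2) + 2 * Wp * B
  }
  if (any(!is.finite(s))) stop("element failure: non-finite stress")
  (s + t(s)) / 2
}

#' Total strain energy density used by the solid solver
#'
#' `Psi(F) = W(I1_bar) + kappa/2 (J-1)^2` in CGS (dyn/cm^2); the potential
#' whose Piola stress the assembler integrates.
#'
#' @param F 2x2 deformation gradient.
#' @param mat tissue material.
#' @param kappa_factor penalty multiple.
#' @return scalar energy density (dyn/cm^2 = erg/cm^3).
#' @export
solid_energy_density <- function(F, mat, kappa_factor = 100) {
  F <- matrix(F, 2, 2)
  J <- F[1, 1] * F[2, 2] - F[1, 2] * F[2, 1]
  T <- sum(F^2)
  I1b <- T / J + 1
  W <- if (mat$type == "poly") strain_energy_wall(I1b, 1, mat)
       else strain_energy_valve(I1b, 1, mat)
  kap <- kappa_factor * reference_shear_modulus(mat)
  kpa_to_cgs(W + kap / 2 * (J - 1)^2)
}
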