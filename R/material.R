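# Constitutive laws: Mooney-Rivlin ground matrix with logarithmic volumetric
# term, and the transversely isotropic muscle fibre law (exponential passive
# branch turning linear at the maximum stretch, parabolic active
# force-length curve).  Stresses in kPa at this interface.

#' Default passive tissue material parameters
#'
#' Mooney-Rivlin coefficients C10 = 2.5 kPa, C20 = 1.175 kPa, logarithmic
#' volumetric stiffness kappa = 25 kPa, soft-incompressibility bulk modulus
#' 25 kPa, tissue density 1040 kg/m^3, gravity 9.8 m/s^2 downward.
#'
#' @param ... overrides for individual fields.
#' @return list of material parameters.
#' @export
material_params <- function(...) {
  p <- list(c10_kpa = 2.5, c20_kpa = 1.175, kappa_kpa = 25,
            bulk_kpa = 25, density_kg_m3 = 1040, gravity_m_s2 = 9.8)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) {
    stop_lipmaps(sprintf("unknown material parameter(s): %s",
                         paste(bad, collapse = ", ")), "lipmaps_config_error")
  }
  p[names(over)] <- over
  if (p$c10_kpa <= 0 || p$c20_kpa <= 0 || p$kappa_kpa <= 0 ||
      p$density_kg_m3 <= 0) {
    stop_lipmaps("stiffnesses and density must be positive",
                 "lipmaps_config_error")
  }
  p
}

#' Mooney-Rivlin strain energy and Cauchy stress
#'
#' Energy density
#' `W = C10 (I1~ - 3) + C20 (I1~ - 3)^2 + kappa/2 (ln J)^2`
#' with `I1~ = trace(B~)`, `B~ = F~ F~'`, `F~ = J^{-1/3} F` the distortional
#' part of the deformation gradient.  The Cauchy stress is the
#' energy-consistent derivative,
#' `sigma = (2/J)(C10 + 2 C20 (I1~ - 3)) dev(B~) + (kappa ln J / J) I`.
#'
#' @param f 3x3 deformation gradient with positive determinant.
#' @param mat material parameters from [material_params()].
#' @return list: `W` (kPa), `cauchy` (3x3, kPa), `pk1` (3x3 first
#'   Piola-Kirchhoff stress, kPa), `J`, `I1_bar`.
#' @export
mooney_rivlin <- function(f, mat = material_params()) {
  f <- as.matrix(f)
  stopifnot(all(dim(f) == c(3, 3)))
  j <- det(f)
  if (j <= 0) {
    stop_lipmaps(sprintf("inverted configuration: det F = %g <= 0", j),
                 "lipmaps_inverted_element")
  }
  i1 <- sum(f * f)
  i1b <- j^(-2 / 3) * i1
  dev_term <- mat$c10_kpa + 2 * mat$c20_kpa * (i1b - 3)
  b_bar <- j^(-2 / 3) * tcrossprod(f)
  dev_b <- b_bar - diag(sum(diag(b_bar)) / 3, 3)
  cauchy <- (2 / j) * dev_term * dev_b + diag(mat$kappa_kpa * log(j) / j, 3)
  w <- mat$c10_kpa * (i1b - 3) + mat$c20_kpa * (i1b - 3)^2 +
    mat$kappa_kpa / 2 * log(j)^2
  f_inv_t <- t(solve(f))
  pk1 <- dev_term * 2 * j^(-2 / 3) * (f - (i1 / 3) * f_inv_t) +
    mat$kappa_kpa * log(j) * f_inv_t
  list(W = w, cauchy = cauchy, pk1 = pk1, J = j, I1_bar = i1b)
}

#' Muscle definition
#'
#' @param name model muscle channel name, e.g. "ZYG_L".
#' @param polyline numeric matrix (>= 2 x 3) of fibre path points (mm),
#'   ordered origin to insertion.
#' @param lambda_star stretch where the passive law turns linear (default 1.4).
#' @param p1 exponential stress coefficient (default 0.05).
#' @param p2 uncrimping factor (default 6.6).
#' @param lambda_ofl optimal fibre stretch (default 1: reference length).
#' @param elements optional explicit element id override for muscle-element
#'   assignment (bypasses the distance rule).
#' @return object of class `muscle_def`.
#' @export
muscle_def <- function(name, polyline, lambda_star = 1.4, p1 = 0.05,
                       p2 = 6.6, lambda_ofl = 1.0, elements = NULL) {
  polyline <- as.matrix(polyline)
  stopifnot(nrow(polyline) >= 2, ncol(polyline) == 3,
            lambda_star > 1, p1 > 0, p2 > 0, lambda_ofl > 0)
  structure(list(name = name, polyline = polyline, lambda_star = lambda_star,
                 p1 = p1, p2 = p2, lambda_ofl = lambda_ofl,
                 elements = elements),
            class = "muscle_def")
}

# normalised passive force-stretch: 0 at or below rest length, exponential
# up to lambda_star, then linear with matched value and slope (C1)
f_passive <- function(lb, p1, p2, lambda_star) {
  out <- numeric(length(lb))
  mid <- lb > 1 & lb < lambda_star
  out[mid] <- p1 * (exp(p2 * (lb[mid] - 1)) - 1)
  hi <- lb >= lambda_star
  f_star <- p1 * (exp(p2 * (lambda_star - 1)) - 1)
  slope <- p1 * p2 * exp(p2 * (lambda_star - 1))
  out[hi] <- f_star + slope * (lb[hi] - lambda_star)
  out
}

# normalised active force-length: parabola peaking at optimal stretch,
# zero outside [0.5, 1.5]
f_active <- function(lb) {
  pmax(0, 1 - 4 * (lb - 1)^2)
}

#' Along-fibre muscle Cauchy stress
#'
#' `sigma = sigma_max (f_passive(lambda/lambda_ofl) +
#'          a f_active(lambda/lambda_ofl))`, in kPa, applied along the fibre
#' direction.  At optimal stretch with full activation the stress equals
#' `sigma_max` exactly (the active curve is normalised to 1 at its peak).
#'
#' @param lambda fibre stretch (> 0).
#' @param a activation in `[0, 1]`.
#' @param m a [muscle_def()] (supplies lambda_star, p1, p2, lambda_ofl).
#' @param sigma_max_kpa maximum isometric stress (kPa).
#' @return along-fibre Cauchy stress (kPa).
#' @export
muscle_fibre_stress <- function(lambda, a, m = muscle_def("generic",
                                  rbind(c(0, 0, 0), c(1, 0, 0))),
                                sigma_max_kpa = 300) {
  stopifnot(all(lambda > 0))
  if (any(a < 0 | a > 1)) {
    stop_lipmaps("activation must lie in [0, 1]", "lipmaps_config_error")
  }
  lb <- lambda / m$lambda_ofl
  sigma_max_kpa * (f_passive(lb, m$p1, m$p2, m$lambda_star) + a * f_active(lb))
}
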