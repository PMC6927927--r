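.MMHG <- 133.322e-6  # MPa per mmHg

#' Hyperelastic artery tube
#'
#' Homogeneous, isotropic, phenomenological artery model with a 6th-order
#' reduced polynomial strain energy,
#' \deqn{U = \sum_{i=1}^{6} c_i (\bar I_1 - 3)^i + (1/D_1)(J^{el}-1)^2,}
#' nearly incompressible (only the first volumetric term is present). The
#' default coefficients fit elderly-male aortic pressure-radius data.
#' The tube response is evaluated semi-analytically: incompressible
#' plane-strain thick-wall inflation integrated through the wall.
#'
#' @param coefs six deviatoric coefficients c1..c6 (MPa)
#' @param D1 first volumetric coefficient (1/MPa)
#' @param thickness wall thickness (mm)
#' @param R_ref unloaded inner radius (mm)
#' @param seg_length segment length (mm)
#' @param density informational (tonne/mm^3)
#' @return object of class \code{vesselTube}
#' @export
vesselTube <- function(coefs = c(0.0048, 0.0911, -1.0600, 9.5292,
                                 -31.7421, 46.3921),
                       D1 = 0.004593, thickness = 2, R_ref = 10,
                       seg_length = NULL, density = 1.16e-9) {
  stopifnot(length(coefs) == 6, D1 > 0, thickness > 0, R_ref > 0)
  tube <- list(c = coefs, D1 = D1, thickness = thickness, R_ref = R_ref,
               length = if (is.null(seg_length)) 4 * R_ref else seg_length,
               density = density)
  class(tube) <- "vesselTube"
  tube
}

#' @export
print.vesselTube <- function(x, ...) {
  cat(sprintf("vesselTube: R_ref %.3f mm, wall %.1f mm, length %.1f mm\n",
              x$R_ref, x$thickness, x$length))
  cat("  c (MPa):", paste(format(x$c, digits = 4), collapse = " "), "\n")
  invisible(x)
}

#' Strain energy density of the vessel material
#'
#' @param tube \code{\link{vesselTube}}
#' @param I1_bar first distortional strain invariant (>= 3)
#' @param J_el elastic volume ratio (> 0)
#' @return energy density (MPa)
#' @export
strainEnergy <- function(tube, I1_bar, J_el = 1) {
  if (any(I1_bar < 3 - 1e-12)) stop("I1_bar must be >= 3")
  if (any(J_el <= 0)) stop("J_el must be positive")
  x <- I1_bar - 3
  dev <- rowSums(outer(x, seq_len(6), function(a, i) a^i) *
                   matrix(tube$c, length(x), 6, byrow = TRUE))
  dev + (1 / tube$D1) * (J_el - 1)^2
}

# dW/dI1 at I1
.dWdI1 <- function(tube, I1) {
  x <- I1 - 3
  rowSums(outer(x, 0:5, function(a, i) a^i) *
            matrix(tube$c * seq_len(6), length(x), 6, byrow = TRUE))
}

# luminal pressure (MPa) needed to hold inner radius ri (incompressible
# plane-strain thick-wall inflation, Gauss-Legendre through the wall)
.tubePressureAt <- function(tube, ri, ngauss = 32) {
  Ri <- tube$R_ref; Ro <- Ri + tube$thickness
  gl <- .gaussLegendre(ngauss, Ri, Ro)
  R <- gl$x
  r2 <- ri^2 + R^2 - Ri^2
  lam2 <- r2 / R^2
  I1 <- lam2 + 1 / lam2 + 1
  integrand <- 2 * (lam2 - 1 / lam2) * .dWdI1(tube, I1) * R / r2
  sum(gl$w * integrand)
}

.gaussLegendre <- function(n, a, b) {
  # Golub-Welsch via symmetric tridiagonal eigen
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- diag(0, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

#' Inner radius of the pressurized vessel
#'
#' Solves the closed-tube incompressible axisymmetric inflation of the
#' reduced-polynomial wall (plane strain axially, thick-wall integration)
#' for the inner radius at a given luminal pressure.
#'
#' @param tube \code{\link{vesselTube}}
#' @param P luminal pressure (mmHg, 0..200)
#' @param extra_MPa additional luminal pressure in MPa (e.g. an equivalent
#'   ring contact pressure)
#' @return inner radius (mm), root-found to 1e-6 mm
#' @export
pressureRadius <- function(tube, P, extra_MPa = 0) {
  stopifnot(P >= 0, P <= 200)
  Pm <- P * .MMHG + extra_MPa
  if (Pm == 0) return(tube$R_ref)
  f <- function(ri) .tubePressureAt(tube, ri) - Pm
  lo <- tube$R_ref * (if (Pm > 0) 1 else 0.5)
  hi <- tube$R_ref * 3
  if (f(hi) < 0) stop("no inflation root in bracket; pressure outside model range")
  stats::uniroot(f, c(if (Pm > 0) lo else 0.2 * lo, hi), tol = 1e-8)$root
}

#' Time-weighted mean arterial pressure
#'
#' \code{P_m = P_d + (P_s - P_d)/3}.
#'
#' @param P_d diastolic pressure (mmHg)
#' @param P_s systolic pressure (mmHg)
#' @return mean pressure (mmHg)
#' @export
meanPressure <- function(P_d = 80, P_s = 120) P_d + (P_s - P_d) / 3

#' Size a vessel for a target ring oversize
#'
#' Chooses the unloaded inner radius so that the vessel pressurized to
#' \code{P_m} leaves the ring with the requested oversize,
#' \code{R_vessel = R_ring / (1 + oversize/100)}; wall thickness 2 mm and
#' segment length twice the ring diameter.
#'
#' @param config \code{\link{ringConfig}}
#' @param oversize_pct ring oversize at \code{P_m} (percent, > 0)
#' @param P_m sizing pressure (mmHg); default the time-weighted mean of
#'   80/120
#' @param ... further arguments to \code{\link{vesselTube}} (coefficients)
#' @return \code{vesselTube} with calibrated \code{R_ref}
#' @export
sizeVessel <- function(config, oversize_pct = 10, P_m = meanPressure(), ...) {
  if (oversize_pct <= 0) stop("oversize must be positive")
  R_target <- (config$D_ring / 2) / (1 + oversize_pct / 100)
  f <- function(Rr) {
    tb <- vesselTube(R_ref = Rr, seg_length = 2 * config$D_ring, ...)
    pressureRadius(tb, P_m) - R_target
  }
  Rr <- stats::uniroot(f, c(0.5 * R_target, 1.05 * R_target), tol = 1e-9)$root
  vesselTube(R_ref = Rr, seg_length = 2 * config$D_ring, ...)
}

#' Vessel radius under combined blood pressure and ring load
#'
#' Effective-radial-stiffness coupling of the ring to the tube: the total
#' radial contact force is spread over an axial footprint \code{L_eff} as an
#' equivalent extra luminal pressure, and the inflation problem is re-solved.
#' \code{L_eff} defaults to \code{1.5 * sqrt(R t)}, the bending decay length
#' scale of a pressurized cylindrical shell under a ring line load.
#'
#' @param tube \code{\link{vesselTube}}
#' @param P blood pressure (mmHg)
#' @param F_radial total outward radial force of the ring on the wall (N)
#' @param L_eff axial footprint (mm); NULL for the default
#' @return inner radius (mm)
#' @export
vesselRadiusUnderLoad <- function(tube, P, F_radial, L_eff = NULL) {
  if (is.null(L_eff))
    L_eff <- 1.5 * sqrt((tube$R_ref + tube$thickness / 2) * tube$thickness)
  if (F_radial <= 0) return(pressureRadius(tube, P))
  f <- function(ri) .tubePressureAt(tube, ri) -
    (P * .MMHG + F_radial / (2 * pi * ri * L_eff))
  stats::uniroot(f, c(tube$R_ref * 0.99, tube$R_ref * 3), tol = 1e-8)$root
}
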