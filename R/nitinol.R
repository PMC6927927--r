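#' Superelastic Nitinol material parameters
#'
#' Parameter set for the one-dimensional superelastic constitutive model used
#' at every fiber (cross-section integration point) of the beam elements.
#' The model idealizes the stress-induced austenite/martensite transformation
#' at body temperature (37 C) with linear transformation kinetics: the
#' martensite volume fraction evolves linearly with stress between the start
#' and end stresses of the active transformation surface, the elastic modulus
#' is the compliance (Reuss) mixture of the two phases, and the loading
#' surfaces in compression are the tension surfaces scaled by
#' \code{sigma_CS / sigma_LS} (tension-compression asymmetry).
#'
#' @param E_A austenite Young's modulus (MPa)
#' @param nu_A austenite Poisson ratio (dimensionless)
#' @param E_M martensite Young's modulus (MPa)
#' @param nu_M martensite Poisson ratio (dimensionless)
#' @param eps_L transformation strain magnitude (dimensionless)
#' @param sigma_LS start of forward transformation, tension loading (MPa)
#' @param sigma_LE end of forward transformation, tension loading (MPa)
#' @param sigma_US start of reverse transformation, unloading (MPa)
#' @param sigma_UE end of reverse transformation, unloading (MPa)
#' @param sigma_CS start of forward transformation in compression,
#'   magnitude (MPa)
#' @param density mass density (g/cm^3, informational; the solver is
#'   quasi-static)
#' @param compression_scale ratio applied to all tension surfaces to obtain
#'   the compression branch. Defaults to \code{sigma_CS / sigma_LS}; the
#'   unloading surfaces in compression are not separately parameterized and
#'   reuse this scale.
#' @return object of class \code{nitinolParams}
#' @export
nitinolParams <- function(E_A = 59000, nu_A = 0.33, E_M = 26500, nu_M = 0.33,
                          eps_L = 0.05,
                          sigma_LS = 636, sigma_LE = 740,
                          sigma_US = 430, sigma_UE = 302,
                          sigma_CS = 965, density = 6.45,
                          compression_scale = NULL) {
  stopifnot(is.finite(E_A), is.finite(E_M), E_A > E_M, E_M > 0)
  stopifnot(eps_L > 0, eps_L < 1)
  if (!(sigma_LS < sigma_LE)) stop("sigma_LS must be < sigma_LE")
  if (!(sigma_US > sigma_UE)) stop("sigma_US must be > sigma_UE")
  if (!(sigma_UE < sigma_LS)) stop("open hysteresis loop requires sigma_UE < sigma_LS")
  if (!(sigma_CS > sigma_LS)) stop("compression onset must exceed tension onset")
  if (is.null(compression_scale)) compression_scale <- sigma_CS / sigma_LS
  p <- list(E_A = E_A, nu_A = nu_A, E_M = E_M, nu_M = nu_M, eps_L = eps_L,
            sigma_LS = sigma_LS, sigma_LE = sigma_LE,
            sigma_US = sigma_US, sigma_UE = sigma_UE,
            sigma_CS = sigma_CS, density = density,
            compression_scale = compression_scale)
  class(p) <- "nitinolParams"
  p
}

#' @export
print.nitinolParams <- function(x, ...) {
  cat("Superelastic Nitinol parameters (1-D, 37 C)\n")
  cat(sprintf("  E_A = %g MPa, E_M = %g MPa, eps_L = %g\n", x$E_A, x$E_M, x$eps_L))
  cat(sprintf("  tension loading  : %g -> %g MPa\n", x$sigma_LS, x$sigma_LE))
  cat(sprintf("  tension unloading: %g -> %g MPa\n", x$sigma_US, x$sigma_UE))
  cat(sprintf("  compression onset: %g MPa (scale %.4f)\n",
              x$sigma_CS, x$compression_scale))
  invisible(x)
}

#' Material state of a single Nitinol fiber
#'
#' Load-history dependent state: two states with equal total strain may carry
#' different stress depending on the transformation history.
#'
#' @param xi martensite volume fraction in [0, 1]
#' @param eps_tr signed transformation strain; |eps_tr| <= xi * eps_L
#' @param eps_total total strain
#' @param sigma stress (MPa)
#' @return object of class \code{materialState}
#' @export
materialState <- function(xi = 0, eps_tr = 0, eps_total = 0, sigma = 0) {
  stopifnot(xi >= -1e-12, xi <= 1 + 1e-12)
  s <- list(xi = min(max(xi, 0), 1), eps_tr = eps_tr,
            eps_total = eps_total, sigma = sigma)
  class(s) <- "materialState"
  s
}

#' @export
print.materialState <- function(x, ...) {
  cat(sprintf("Nitinol state: xi = %.4f, eps_tr = %.5f, eps = %.5f, sigma = %.2f MPa\n",
              x$xi, x$eps_tr, x$eps_total, x$sigma))
  invisible(x)
}

# mixture compliance modulus
.nitE <- function(par, xi) 1 / ((1 - xi) / par$E_A + xi / par$E_M)

# Solve s*E(xi)*(eps - s*xi*eps_L) = b*(sig0 + xi*dsig) for xi.
# With 1/E = a0 + a1*xi this is a quadratic in xi; the physical root is
# returned (exact return mapping, no iteration needed).
.nitSolveXi <- function(par, eps, s, b, sig0, dsig) {
  a0 <- 1 / par$E_A
  a1 <- 1 / par$E_M - 1 / par$E_A
  A <- b * dsig * a1
  B <- b * (sig0 * a1 + dsig * a0) + par$eps_L
  C <- b * sig0 * a0 - s * eps
  disc <- pmax(B * B - 4 * A * C, 0)
  # A, B > 0 so the negative-branch root is always < 0; the + branch is physical
  (-B + sqrt(disc)) / (2 * A)
}

# Vectorized core update. xi, eptr, eps are equal-length vectors of committed
# martensite fraction, signed transformation strain and NEW total strain.
# Returns list(sigma, xi, eptr, Et) with Et the consistent tangent.
.nitUpdate <- function(par, xi, eptr, eps) {
  if (any(!is.finite(eps))) stop("non-finite strain passed to Nitinol update")
  epsL <- par$eps_L
  dLo <- par$sigma_LE - par$sigma_LS
  dUn <- par$sigma_US - par$sigma_UE
  n <- length(eps)
  d <- ifelse(xi > 1e-14, sign(eptr), 0)
  # fibers that fully transformed in pure tension/compression keep direction
  d[xi > 1e-14 & d == 0] <- 1
  a1 <- 1 / par$E_M - 1 / par$E_A
  Et <- numeric(n)
  sig <- numeric(n)
  active <- rep(TRUE, n)  # fibers whose regime is not yet settled
  for (pass in 1:4) {
    if (!any(active)) break
    rerun <- rep(FALSE, n)

    # --- reverse transformation (martensite -> austenite) ---
    E <- .nitE(par, xi)
    strial <- E * (eps - eptr)
    bR <- ifelse(d < 0, par$compression_scale, 1)
    revSurf <- bR * (par$sigma_UE + xi * dUn)
    rev <- active & xi > 1e-14 & (d * strial < revSurf - 1e-12)
    if (any(rev)) {
      i <- which(rev)
      xin <- .nitSolveXi(par, eps[i], d[i], bR[i], par$sigma_UE, dUn)
      full <- xin < 0
      xi[i] <- ifelse(full, 0, pmin(xin, xi[i]))  # reverse cannot increase xi
      eptr[i] <- d[i] * xi[i] * epsL
      Ei <- .nitE(par, xi[i])
      sig[i] <- Ei * (eps[i] - eptr[i])
      denom <- d[i] * bR[i] * dUn / Ei + sig[i] * a1 + d[i] * epsL
      Et[i] <- ifelse(full, Ei, d[i] * bR[i] * dUn / denom)
      d[i][xi[i] <= 1e-14] <- 0
      # fully reverted fibers may immediately load forward (sign flip): re-run
      rerun[i[full]] <- TRUE
      active[i[!full]] <- FALSE
    }

    # --- forward transformation (austenite -> martensite) ---
    E <- .nitE(par, xi)
    strial <- E * (eps - eptr)
    s <- sign(strial)
    bF <- ifelse(s < 0, par$compression_scale, 1)
    okdir <- (xi <= 1e-14) | (s == d)
    fwdSurf <- bF * (par$sigma_LS + xi * dLo)
    fwd <- active & okdir & xi < 1 - 1e-14 &
      (abs(strial) > fwdSurf + 1e-12) & s != 0
    if (any(fwd)) {
      i <- which(fwd)
      xin <- .nitSolveXi(par, eps[i], s[i], bF[i], par$sigma_LS, dLo)
      sat <- xin > 1
      xi[i] <- pmin(pmax(xin, xi[i]), 1)  # forward cannot decrease xi
      d[i] <- s[i]
      eptr[i] <- d[i] * xi[i] * epsL
      Ei <- .nitE(par, xi[i])
      sig[i] <- Ei * (eps[i] - eptr[i])
      denom <- s[i] * bF[i] * dLo / Ei + sig[i] * a1 + s[i] * epsL
      Et[i] <- ifelse(sat, Ei, s[i] * bF[i] * dLo / denom)
      active[i] <- FALSE
    }

    # --- elastic (inside the hysteresis loop or pure phase) ---
    el <- active & !rerun
    if (any(el)) {
      i <- which(el)
      Ei <- .nitE(par, xi[i])
      sig[i] <- Ei * (eps[i] - eptr[i])
      Et[i] <- Ei
      active[i] <- FALSE
    }
    active <- active & rerun
  }
  list(sigma = sig, xi = xi, eptr = eptr, Et = Et)
}

#' Update the state of a Nitinol fiber to a new total strain
#'
#' Strain-driven update of the superelastic flow rule: linear-elastic response
#' with the mixture modulus below the active transformation surface, forward
#' transformation between \code{sigma_LS} and \code{sigma_LE} (tension;
#' compression-scaled surfaces in compression), reverse transformation between
#' \code{sigma_US} and \code{sigma_UE}, linear evolution of the martensite
#' fraction with the driving stress between surface start/end values, and
#' elastic unloading/reloading inside the loop. The return mapping is solved
#' in closed form (the kinetics are linear in the martensite fraction).
#'
#' @param params \code{\link{nitinolParams}}
#' @param state \code{\link{materialState}} (committed state)
#' @param eps_new new total strain (dimensionless)
#' @return updated \code{materialState}
#' @export
updateState <- function(params, state, eps_new) {
  stopifnot(inherits(params, "nitinolParams"), inherits(state, "materialState"))
  if (!is.finite(eps_new)) stop("non-finite strain rejected")
  r <- .nitUpdate(params, state$xi, state$eps_tr, eps_new)
  materialState(xi = r$xi, eps_tr = r$eptr, eps_total = eps_new, sigma = r$sigma)
}

#' Drive a Nitinol fiber through a strain path
#'
#' Applies \code{\link{updateState}} sequentially from the virgin state and
#' returns the full trajectory.
#'
#' @param params \code{\link{nitinolParams}}
#' @param eps_path numeric vector of total strains (finite)
#' @return data.frame with columns \code{eps}, \code{sigma}, \code{xi},
#'   \code{eps_tr}
#' @export
driveCycle <- function(params, eps_path) {
  stopifnot(all(is.finite(eps_path)))
  st <- materialState()
  out <- matrix(0, length(eps_path), 4)
  for (k in seq_along(eps_path)) {
    st <- updateState(params, st, eps_path[k])
    out[k, ] <- c(st$eps_total, st$sigma, st$xi, st$eps_tr)
  }
  data.frame(eps = out[, 1], sigma = out[, 2], xi = out[, 3], eps_tr = out[, 4])
}

#' Algorithmically consistent tangent modulus
#'
#' Tangent of \code{\link{updateState}} at a state, for an infinitesimal
#' strain step in the loading (strain-increasing along the current stress
#' sign) or unloading direction. Equals \code{E_A} at the virgin state,
#' \code{E_M} when fully martensitic, and the plateau slope during active
#' transformation.
#'
#' @param params \code{\link{nitinolParams}}
#' @param state \code{\link{materialState}}
#' @param direction \code{"loading"} or \code{"unloading"}
#' @return tangent modulus (MPa)
#' @export
tangentModulus <- function(params, state, direction = c("loading", "unloading")) {
  direction <- match.arg(direction)
  s <- if (state$sigma != 0) sign(state$sigma) else 1
  h <- 1e-9 * s * if (direction == "loading") 1 else -1
  r <- .nitUpdate(params, state$xi, state$eps_tr, state$eps_total + h)
  r$Et
}

#' Strain at which the austenite branch ends in monotonic tension
#'
#' The total strain at first activation of the forward transformation
#' surface, \code{sigma_LS / E_A} (about 1.08\% for the default 37 C
#' parameter set).
#'
#' @param params \code{\link{nitinolParams}}
#' @return strain (dimensionless)
#' @export
austeniteStrainLimit <- function(params) params$sigma_LS / params$E_A
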