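#' Ring bundle configuration
#'
#' Geometric definition of a ring-stent wire bundle: wire diameter, ring mean
#' diameter, number of wire turns, and whether the manufacturing pre-strain
#' (bending the straight wire stock into the circle) is simulated.
#'
#' @param d_wire wire diameter (mm)
#' @param D_ring ring mean (centerline) diameter (mm)
#' @param n_turns number of wire turns (>= 1)
#' @param include_prestrain simulate the wire-to-ring forming step (default
#'   TRUE); if FALSE the ring is created directly as a circle with virgin
#'   material
#' @return object of class \code{ringConfig}
#' @export
ringConfig <- function(d_wire, D_ring, n_turns = 1, include_prestrain = TRUE) {
  stopifnot(d_wire > 0, n_turns >= 1, n_turns == round(n_turns))
  if (D_ring <= 0) stop("ring diameter must be positive")
  if (D_ring / d_wire < 20)
    warning("ring is not slender (D_ring/d_wire < 20); beam idealization is questionable")
  cfg <- list(d_wire = d_wire, D_ring = D_ring, n_turns = as.integer(n_turns),
              include_prestrain = isTRUE(include_prestrain))
  class(cfg) <- "ringConfig"
  cfg
}

#' @export
print.ringConfig <- function(x, ...) {
  cat(sprintf("ringConfig: wire %.3f mm, ring %.2f mm, %d turns, prestrain %s\n",
              x$d_wire, x$D_ring, x$n_turns,
              if (x$include_prestrain) "yes" else "no"))
  invisible(x)
}

#' Analytical manufacturing strain
#'
#' Peak strain at the outer surface of a round wire bent to the ring mean
#' radius: \code{R_wire / R_ring}.
#'
#' @param config \code{\link{ringConfig}}
#' @return strain (dimensionless)
#' @export
analyticFormingStrain <- function(config) {
  (config$d_wire / 2) / (config$D_ring / 2)
}

#' Form a straight wire into a closed pre-strained ring
#'
#' Manufacturing step of the simulation. A straight wire of length
#' \code{pi * D_ring} is wrapped into a circle by a ramped guided-kinematics
#' program (all nodes follow the wrap of a regular polygon whose side length
#' preserves the wire arc length and whose per-node triad turning ramps to
#' \code{2 pi / n_elem}), so every fiber accumulates a monotonic bending
#' strain history up to \code{+/- R_wire/R_ring}. The ends are then welded
#' and the ring is released and equilibrated; a ring formed this way carries
#' a uniform internal bending moment and is self-equilibrated.
#'
#' With \code{include_prestrain = FALSE} the ring is created directly as a
#' circle with all fibers virgin.
#'
#' @param config \code{\link{ringConfig}}
#' @param n_elem elements around the circumference (multiple of 4;
#'   default 64)
#' @param n_incr wrap increments (default 12; the wrap is kinematic, the
#'   increments only refine the strain history)
#' @param matpar \code{\link{nitinolParams}}
#' @param opts \code{\link{solverOptions}}
#' @return object of class \code{formedRing}: list(model, config, eps_fe,
#'   eps_analytic, report)
#' @export
formRing <- function(config, n_elem = 64, n_incr = 12,
                     matpar = nitinolParams(), opts = solverOptions()) {
  stopifnot(inherits(config, "ringConfig"))
  if (n_elem %% 4 != 0) stop("n_elem must be a multiple of 4")
  r_wire <- config$d_wire / 2
  R_ring <- config$D_ring / 2
  r_bundle <- bwRatio(config$n_turns) * r_wire

  if (!config$include_prestrain) {
    m <- circleRingModel(R_ring, n_elem, matpar, r_wire,
                         nmult = config$n_turns, r_bundle = r_bundle)
    m$meta <- list(config = config, R_ring = R_ring)
    out <- list(model = m, config = config, eps_fe = 0,
                eps_analytic = analyticFormingStrain(config), report = NULL)
    class(out) <- "formedRing"
    return(out)
  }

  L <- 2 * pi * R_ring
  m <- straightWireModel(L, n_elem, matpar, r_wire,
                         nmult = config$n_turns, r_bundle = r_bundle)
  l0 <- L / n_elem
  # ramped kinematic wrap: per-node triad turning grows to 2*pi/n_elem
  for (t in seq_len(n_incr)) {
    dth <- (t / n_incr) * 2 * pi / n_elem
    k <- seq_len(n_elem)
    m$x <- cbind(c(0, 0, 0),
                 rbind(cumsum(l0 * cos((k - 0.5) * dth)),
                       cumsum(l0 * sin((k - 0.5) * dth)),
                       0))
    ang <- (0:n_elem) * dth
    m$q <- rbind(cos(ang / 2), 0, 0, sin(ang / 2))
    asm <- .assemble(m, needK = FALSE)
    m <- .commit(m, asm)
  }
  # weld the coincident ends and release
  m <- weldClose(m, 1L, as.integer(n_elem + 1), tol = 1e-6)
  # clamp one node against rigid-body motion; the formed ring is
  # self-equilibrated so the clamp carries (numerically) no reaction
  m <- fixDof(m, 1L, 1:6)
  sol <- solveProgram(m, list(list(name = "release", nincr = 1)), opts)
  m <- sol$model
  m$fixed <- integer(0)

  # recentre: ring centroid to origin, node 1 to angle 0
  ctr <- rowMeans(m$x[, seq_len(n_elem), drop = FALSE])
  m$x <- m$x - ctr
  phi1 <- atan2(m$x[2, 1], m$x[1, 1])
  Rz <- .rotZ(-phi1)
  m$x <- Rz %*% m$x
  qz <- .matToQuat(Rz)
  m$q <- .quatNormalize(.quatMul(matrix(qz, 4, m$nn), m$q))
  m$X0 <- m$x; m$q0 <- m$q

  ss <- surfaceStrains(m)
  out <- list(model = m, config = config,
              eps_fe = max(ss$eps_absmax),
              eps_analytic = analyticFormingStrain(config),
              report = sol$report)
  class(out) <- "formedRing"
  out
}

#' @export
print.formedRing <- function(x, ...) {
  cat("formedRing\n")
  print(x$config)
  cat(sprintf("  FE peak forming strain  : %.5g\n", x$eps_fe))
  cat(sprintf("  analytic R_wire/R_ring  : %.5g\n", x$eps_analytic))
  if (x$eps_analytic > 0)
    cat(sprintf("  relative deviation      : %.3g%%\n",
                100 * abs(x$eps_fe - x$eps_analytic) / x$eps_analytic))
  invisible(x)
}

#' Quarter-point node ids of a formed ring
#'
#' Nodes at circumferential angles 0, 90, 180, 270 degrees (labels B, A, D,
#' C follow the deployment convention: peaks A, C on the y axis, valleys B,
#' D on the x axis).
#'
#' @param m ring \code{beamModel} with \code{n_elem} circumferential nodes
#' @return named integer vector (B, A, D, C)
#' @export
quarterNodes <- function(m) {
  ne <- length(m$el$n1)
  n4 <- ne / 4
  c(B = 1L, A = as.integer(1 + n4), D = as.integer(1 + 2 * n4),
    C = as.integer(1 + 3 * n4))
}
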