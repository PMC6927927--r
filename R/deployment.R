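#' Deployment scenario configuration
#'
#' Compaction of the formed ring into its delivery catheter by a shrinking
#' cylindrical sheath (with a rigid inner tube), release into the sized
#' vessel, and pulsation between diastolic and systolic pressure.
#'
#' @param catheter_diameter sheath inner diameter at full compaction (mm);
#'   default 6.9 (approx. 20.7 Fr delivery profile)
#' @param inner_tube_diameter rigid core diameter (mm)
#' @param oversize_pct ring oversize in the vessel at mean pressure
#' @param P_d,P_s diastolic / systolic pressure (mmHg)
#' @param mu_vessel ring-vessel friction coefficient
#' @param mu_sheath ring-sheath friction coefficient (0: frictionless
#'   catheter)
#' @param kpen contact penalty stiffness (N/mm per node). The default is
#'   the local indentation stiffness of the wall under a wire segment
#'   (tangent modulus of the pressurized aortic media, about 0.3-1 MPa,
#'   acting over a one-element footprint on a 2 mm wall), so wire-scale
#'   indentation of the tissue is represented by the penalty
#' @param perturb symmetry-breaking jitter amplitude as a fraction of the
#'   ring diameter (applied to the guided fold arc positions)
#' @param kpen_sheath penalty stiffness of the rigid delivery-system
#'   surfaces (sheath, inner tube; N/mm per node)
#' @param seed seed for the jitter pattern (deterministic runs)
#' @param n_pulse_cycles pressure cycles after deployment
#' @param L_eff axial footprint for the ring-load/vessel coupling (mm); NULL
#'   for the shell bending-length default
#' @return object of class \code{deploymentConfig}
#' @export
deploymentConfig <- function(catheter_diameter = 6.9, inner_tube_diameter = 2,
                             oversize_pct = 10, P_d = 80, P_s = 120,
                             mu_vessel = 0.05, mu_sheath = 0, kpen = 2,
                             kpen_sheath = 50, perturb = 1e-4, seed = 1,
                             n_pulse_cycles = 2, L_eff = NULL) {
  stopifnot(P_d < P_s, catheter_diameter > inner_tube_diameter,
            mu_vessel >= 0, mu_sheath >= 0, oversize_pct > 0)
  cfg <- list(catheter_diameter = catheter_diameter,
              inner_tube_diameter = inner_tube_diameter,
              oversize_pct = oversize_pct, P_d = P_d, P_s = P_s,
              mu_vessel = mu_vessel, mu_sheath = mu_sheath, kpen = kpen,
              kpen_sheath = kpen_sheath, perturb = perturb, seed = seed,
              n_pulse_cycles = n_pulse_cycles, L_eff = L_eff)
  class(cfg) <- "deploymentConfig"
  cfg
}

# Stability restraints for compaction/deployment:
# peaks A, C on the y axis, valleys B, D on the x axis.
.deployBCs <- function(m, qn) {
  m <- fixDof(m, c(qn["B"], qn["D"]), 4)          # Rotation_x = 0 at B, D
  m <- fixDof(m, c(qn["A"], qn["C"]), 5)          # Rotation_y = 0 at A, C
  m <- fixDof(m, c(qn["A"], qn["B"], qn["C"], qn["D"]), 6)  # Rotation_z = 0
  m <- fixDof(m, c(qn["A"], qn["C"]), 1)          # Disp_x = 0 at A, C
  m <- fixDof(m, c(qn["B"], qn["D"]), 2)          # Disp_y = 0 at B, D
  m <- fixDof(m, c(qn["B"], qn["D"]), 3)          # Disp_z = 0 at B, D
  # anti-roll: a circular isotropic section gives the closed ring a
  # zero-energy mode (uniform spin of all sections about the wire tangent);
  # the tangential restraint at one valley suppresses it
  m <- fixDof(m, qn["B"], 5)                      # Rotation_y = 0 at B
  m
}

# Fold family of the compacted ring on a cylinder of radius a:
#   z(phi) = (h/2) (1 - tanh(w cos 2 phi)/tanh(w)),
# valleys at phi = 0, pi (z = 0), peaks at phi = pi/2, 3 pi/2 (z = h).
# w -> 0 is the shallow sinusoidal saddle; large w gives hairpin legs with
# rounded turns. For each a, the amplitude h follows from arc-length
# conservation and the sharpness w minimizes the peak curvature.
# place(a, sjit) returns node positions and tangents at CHORD spacing l0
# (arc spacing would compress high-curvature elements axially).
.foldFamily <- function(R_ring, nb, l0, ngrid = 2048) {
  phg <- (seq_len(ngrid) - 0.5) * 2 * pi / ngrid
  dphg <- 2 * pi / ngrid
  zShape <- function(w) (1 - tanh(w * cos(2 * phg)) / tanh(w)) / 2
  zSlope <- function(w) (w * sin(2 * phg) / tanh(w)) / cosh(w * cos(2 * phg))^2
  hOfAW <- function(a, w, Ltarget = 2 * pi * R_ring) {
    zp <- zSlope(w)
    len <- function(h) mean(sqrt(a^2 + h^2 * zp^2)) * 2 * pi
    if (len(0) >= Ltarget) return(0)
    stats::uniroot(function(h) len(h) - Ltarget,
                   c(0, 16 * R_ring), tol = 1e-9)$root
  }
  d1 <- function(v) (c(v[-1], v[1]) - c(v[length(v)], v[-length(v)])) /
    (2 * dphg)
  curvGrid <- function(a, h, w) {
    x <- a * cos(phg); y <- a * sin(phg); z <- h * zShape(w)
    xp <- d1(x); yp <- d1(y); zp <- d1(z)
    xpp <- d1(xp); ypp <- d1(yp); zpp <- d1(zp)
    cr <- sqrt((yp * zpp - zp * ypp)^2 + (zp * xpp - xp * zpp)^2 +
                 (xp * ypp - yp * xpp)^2)
    cr / (xp^2 + yp^2 + zp^2)^1.5
  }
  wOfA <- function(a) {
    if (a >= R_ring) return(0.1)
    stats::optimize(function(w) max(curvGrid(a, hOfAW(a, w), w)),
                    c(0.05, 8))$minimum
  }
  place <- function(a, sjit) {
    if (a >= R_ring) {
      phik <- 2 * pi * (seq_len(nb) - 1) / nb
      return(list(x = rbind(a * cos(phik), a * sin(phik), 0),
                  t = rbind(-sin(phik), cos(phik), 0), h = 0, w = 0.1))
    }
    w <- wOfA(a)
    Ltarget <- 2 * pi * R_ring
    for (pass in 1:3) {
      h <- hOfAW(a, w, Ltarget)
      zg <- h * zShape(w)
      zpg <- h * zSlope(w)
      g <- sqrt(a^2 + zpg^2)
      sgrid <- cumsum(g) * dphg
      S <- sgrid[length(sgrid)]
      crv <- curvGrid(a, h, w)
      kap <- stats::approxfun(c(0, sgrid), c(crv[1], crv), rule = 2)
      ds <- function(s) {
        k <- kap(s)
        if (!is.finite(k) || k < 1e-9) return(l0)
        r <- 1 / k
        if (l0 >= 2 * r) 1.3 * l0 else 2 * r * asin(l0 / (2 * r))
      }
      s <- 0
      for (k in seq_len(nb)) s <- s + ds(s %% S)
      if (abs(s - S) < 1e-6 * S) break
      Ltarget <- Ltarget + (s - S)
    }
    sk <- numeric(nb)
    s <- 0
    for (k in seq_len(nb)) {
      sk[k] <- (s + sjit[k]) %% S
      s <- s + ds(s %% S)
    }
    phik <- stats::approx(c(0, sgrid), c(0, phg + dphg / 2), xout = sk,
                          ties = "ordered")$y
    zk <- stats::approx(c(0, phg + dphg / 2), c(0, zg), xout = phik,
                        ties = "ordered")$y
    dzk <- stats::approx(c(0, phg + dphg / 2), c(0, zpg), xout = phik,
                         ties = "ordered")$y
    tg <- rbind(-a * sin(phik), a * cos(phik), dzk)
    list(x = rbind(a * cos(phik), a * sin(phik), zk),
         t = sweep(tg, 2, sqrt(colSums(tg^2)), "/"),
         h = h, w = w)
  }
  list(place = place, hOfAW = hOfAW, wOfA = wOfA)
}

# apply one guided increment: move nodes to the family position at radius a,
# rotate triads by the minimal (torsion-free) rotation carrying the old
# tangents to the new ones, and commit the fiber states
.applyFoldState <- function(m, fam, a, sjit, tOld) {
  nb <- length(m$el$n1)  # distinct circumferential nodes (weld slave follows)
  pl <- fam$place(a, sjit)
  tNew <- pl$t
  ax <- rbind(tOld[2, ] * tNew[3, ] - tOld[3, ] * tNew[2, ],
              tOld[3, ] * tNew[1, ] - tOld[1, ] * tNew[3, ],
              tOld[1, ] * tNew[2, ] - tOld[2, ] * tNew[1, ])
  sa <- sqrt(colSums(ax * ax))
  ca <- colSums(tOld * tNew)
  ang <- atan2(sa, ca)
  axn <- sweep(ax, 2, pmax(sa, 1e-14), "/")
  dq <- .quatFromRotvec(sweep(axn, 2, ang, "*"))
  m$q[, 1:nb] <- .quatNormalize(.quatMul(dq, m$q[, 1:nb, drop = FALSE]))
  m$x[, 1:nb] <- pl$x
  if (m$nbeam > nb) {
    m$x[, nb + 1] <- m$x[, 1]
    m$q[, nb + 1] <- m$q[, 1]
  }
  asm <- .assemble(m, needK = FALSE)
  m <- .commit(m, asm)
  list(model = m, tNew = tNew, h = pl$h, asm = asm)
}

#' Compact a formed ring into its delivery catheter
#'
#' Shrinks the delivery sheath from just outside the free ring down to the
#' catheter bore. The axisymmetric squeeze keeps the flat ring an exact but
#' unstable equilibrium at every radius, and the equilibrium fold passes
#' through snap-through bifurcations, so the shrink is applied as a
#' displacement-guided kinematic program along the inextensible fold family
#' (see the methods vignette), committing the fiber state at every increment
#' so the full monotonic bending history of the wire is retained.
#' Compaction is the severest load the wire sees; equilibrium is recovered
#' by the solver during deployment, once curvatures return to the range the
#' mesh resolves.
#'
#' @param formed \code{formedRing} (pre-strained)
#' @param config \code{\link{deploymentConfig}}
#' @param nincr shrink increments
#' @param opts \code{\link{solverOptions}}
#' @param target_radius stop the shrink at this sheath radius instead of the
#'   catheter radius (used for the no-compaction variant)
#' @return object of class \code{compactedRing}
#' @export
compact <- function(formed, config = deploymentConfig(), nincr = 60,
                    opts = solverOptions(), target_radius = NULL) {
  stopifnot(inherits(formed, "formedRing"))
  m <- formed$model
  qn <- quarterNodes(m)
  D_ring <- formed$config$D_ring
  R_ring <- D_ring / 2
  rb <- m$r_bundle
  nb <- length(m$el$n1)
  Rsheath <- if (is.null(target_radius)) config$catheter_diameter / 2
             else target_radius
  aEnd <- Rsheath - rb
  if (aEnd <= config$inner_tube_diameter / 2 + rb)
    stop("catheter bore too small for the bundle envelope and inner tube")
  # seeded symmetry-breaking jitter of the guided arc positions; smooth
  # low-harmonic form so adjacent chords stay equal (independent per-node
  # jitter would strain the nearly inextensible wire axially)
  set.seed(config$seed)
  psi <- stats::runif(2, 0, 2 * pi)
  kk <- 2 * pi * (seq_len(nb) - 1) / nb
  sjit <- config$perturb * D_ring *
    (sin(3 * kk + psi[1]) + 0.5 * sin(5 * kk + psi[2]))
  l0 <- 2 * pi * R_ring / nb
  fam <- .foldFamily(R_ring, nb, l0)
  Rc <- max(sqrt(colSums(m$x[1:2, 1:nb, drop = FALSE]^2)))
  tOld <- rbind(-m$x[2, 1:nb], m$x[1, 1:nb], 0)
  tOld <- sweep(tOld, 2, sqrt(colSums(tOld^2)), "/")
  hist <- list()
  for (tt in seq_len(nincr)) {
    a <- Rc + (tt / nincr) * (aEnd - Rc)
    st <- .applyFoldState(m, fam, a, sjit, tOld)
    m <- st$model; tOld <- st$tNew
    ss <- abs(st$asm$fr$eps_c) +
      m$sec$r_wire * sqrt(st$asm$fr$k2^2 + st$asm$fr$k3^2)
    hist[[tt]] <- c(a = a, h = st$h, eps_max = max(ss), xi_max = max(m$xi))
  }
  m <- .deployBCs(m, qn)
  m <- addContact(m, "sheath", "outer", Rsheath,
                  mu = config$mu_sheath, kpen = config$kpen_sheath)
  m <- addContact(m, "innertube", "inner", config$inner_tube_diameter / 2,
                  mu = 0, kpen = config$kpen_sheath)
  out <- list(model = m, history = as.data.frame(do.call(rbind, hist)),
              config = config, formed_config = formed$config,
              guide = list(sjit = sjit, tOld = tOld, a = aEnd, Rc = Rc,
                           l0 = l0, nb = nb, R_ring = R_ring),
              converged = TRUE)
  class(out) <- "compactedRing"
  out
}

#' @export
print.compactedRing <- function(x, ...) {
  ss <- surfaceStrains(x$model)
  cat(sprintf("compactedRing: sheath r %.2f mm, fold height %.1f mm, peak strain %.2f%%\n",
              x$model$contacts$sheath$R, max(x$model$x[3, ]),
              100 * max(ss$eps_absmax)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vessel-coupled equilibrium at blood pressure P (mmHg): the rigid contact
# cylinder radius follows the tube inflation response under blood pressure
# plus the equivalent ring contact pressure
.equilibrateAtPressure <- function(m, tube, P, config, opts, nincr = 2) {
  F <- sum((.assemble(m, needK = FALSE)$contacts$vessel$N) %||% 0)
  Rv <- vesselRadiusUnderLoad(tube, P, F, config$L_eff)
  Gprev <- NULL; Rprev <- NULL
  for (k in 1:10) {
    sol <- solveProgram(m, list(list(name = sprintf("P%.1f", P),
                                     nincr = nincr,
                                     contactR = c(vessel = Rv))), opts)
    m <- sol$model
    F <- sum((.assemble(m, needK = FALSE)$contacts$vessel$N) %||% 0)
    Rnew <- vesselRadiusUnderLoad(tube, P, F, config$L_eff)
    G <- Rnew - Rv
    if (abs(G) < 1e-3)
      return(list(model = m, R_v = Rnew, F_radial = F,
                  converged = sol$converged))
    # secant update on the scalar coupling G(Rv) = 0
    if (!is.null(Gprev) && abs(G - Gprev) > 1e-12) {
      step <- -G * (Rv - Rprev) / (G - Gprev)
      step <- sign(step) * min(abs(step), 0.5)
      Rnext <- Rv + step
    } else Rnext <- Rv + 0.7 * G
    Rprev <- Rv; Gprev <- G
    Rv <- Rnext
    nincr <- 1
  }
  warning("vessel radius coupling did not settle to 1e-3 mm")
  list(model = m, R_v = Rv, F_radial = F, converged = FALSE)
}

#' Deploy a compacted ring into the vessel and pulsate
#'
#' Re-inflates the sheath so the ring unfolds (guided back along the fold
#' family through the curvature range the mesh cannot equilibrate), releases
#' it onto the pressurized vessel wall via a pinned-relaxation equilibrium
#' solve, and cycles the vessel between diastolic and systolic pressure.
#' The vessel remains a cylinder whose radius follows its thick-wall
#' inflation response under blood pressure plus the equivalent ring contact
#' pressure. Chronic outward force is reported at the mean pressure, fiber
#' strain extrema at diastole and systole.
#'
#' @param compacted \code{compactedRing}
#' @param tube \code{vesselTube} sized via \code{\link{sizeVessel}}
#' @param opts \code{\link{solverOptions}}
#' @param nincr_deploy sheath inflation increments
#' @return object of class \code{deploymentResult} with fields \code{COF}
#'   (N, at mean pressure), \code{COF_diast}, \code{COF_syst},
#'   \code{eps_diast}, \code{eps_syst}, \code{M_eps}, strain location
#'   angles, per-phase vessel radii, histories and the final model
#' @export
deployAndPulse <- function(compacted, tube, opts = solverOptions(),
                           nincr_deploy = 30) {
  stopifnot(inherits(compacted, "compactedRing"))
  config <- compacted$config
  m <- compacted$model
  qn <- quarterNodes(m)
  gd <- compacted$guide
  nb <- gd$nb
  P_m <- meanPressure(config$P_d, config$P_s)
  Rv0 <- pressureRadius(tube, P_m)
  fam <- .foldFamily(gd$R_ring, nb, gd$l0)
  # guided unfolding from the catheter back to just inside the vessel
  aLand <- min(Rv0 - m$r_bundle - 0.02, gd$Rc)
  tOld <- gd$tOld
  if (aLand > gd$a) {
    for (tt in seq_len(nincr_deploy)) {
      a <- gd$a + (tt / nincr_deploy) * (aLand - gd$a)
      st <- .applyFoldState(m, fam, a, gd$sjit, tOld)
      m <- st$model; tOld <- st$tNew
    }
  }
  # delivery system removed; ring released onto the vessel wall
  m$contacts$sheath$active <- FALSE
  m$contacts$innertube$active <- FALSE
  m <- addContact(m, "vessel", "outer", Rv0, mu = config$mu_vessel,
                  kpen = config$kpen)
  k0 <- 20
  m$pins <- list(k = k0, xref = m$x[, seq_len(m$nbeam), drop = FALSE])
  relax <- function(mm, frac) {
    mm$pins$k <- k0 * (1 - frac)^3
    mm
  }
  sol <- solveProgram(m, list(list(name = "land", nincr = 12,
                                   hook = relax)), opts)
  m <- sol$model
  m$pins <- NULL
  reports <- list(sol$report)
  eqm <- .equilibrateAtPressure(m, tube, P_m, config, opts, nincr = 2)
  m <- eqm$model

  strains <- function(mm) {
    ss <- surfaceStrains(mm)
    k <- which.max(ss$eps_absmax)
    nd <- mm$el$n1[k]
    c(eps = max(ss$eps_absmax),
      angle = atan2(mm$x[2, nd], mm$x[1, nd]) * 180 / pi)
  }

  phases <- list()
  hist <- list()
  epsD <- epsS <- NULL
  for (cy in seq_len(config$n_pulse_cycles)) {
    eqd <- .equilibrateAtPressure(m, tube, config$P_d, config, opts)
    m <- eqd$model
    sd <- strains(m)
    epsD <- surfaceStrains(m)$eps_absmax
    hist[[length(hist) + 1]] <- c(cycle = cy, phase = 1, eps = sd[["eps"]],
                                  COF = eqd$F_radial, R_v = eqd$R_v)
    eqs <- .equilibrateAtPressure(m, tube, config$P_s, config, opts)
    m <- eqs$model
    ss2 <- strains(m)
    epsS <- surfaceStrains(m)$eps_absmax
    hist[[length(hist) + 1]] <- c(cycle = cy, phase = 2, eps = ss2[["eps"]],
                                  COF = eqs$F_radial, R_v = eqs$R_v)
    phases[[cy]] <- list(diast = list(eps = sd, cof = eqd$F_radial,
                                      R_v = eqd$R_v),
                         syst = list(eps = ss2, cof = eqs$F_radial,
                                     R_v = eqs$R_v))
  }
  eqm2 <- .equilibrateAtPressure(m, tube, P_m, config, opts)
  m <- eqm2$model
  last <- phases[[length(phases)]]
  res <- list(
    COF = eqm2$F_radial,
    COF_diast = last$diast$cof, COF_syst = last$syst$cof,
    eps_diast = last$diast$eps[["eps"]], eps_syst = last$syst$eps[["eps"]],
    M_eps = max((epsD + epsS) / 2),
    angle_diast = last$diast$eps[["angle"]],
    angle_syst = last$syst$eps[["angle"]],
    R_v = c(diast = last$diast$R_v, syst = last$syst$R_v, mean = eqm2$R_v),
    history = as.data.frame(do.call(rbind, hist)),
    model = m, reports = reports,
    config = config)
  class(res) <- "deploymentResult"
  res
}

#' @export
print.deploymentResult <- function(x, ...) {
  cat("Deployment result\n")
  cat(sprintf("  COF at P_m : %.3f N (diast %.3f, syst %.3f)\n",
              x$COF, x$COF_diast, x$COF_syst))
  cat(sprintf("  eps_Diast  : %.3f%%  at %.0f deg\n",
              100 * x$eps_diast, x$angle_diast))
  cat(sprintf("  eps_Syst   : %.3f%%  at %.0f deg\n",
              100 * x$eps_syst, x$angle_syst))
  cat(sprintf("  M_eps      : %.3f%%\n", 100 * x$M_eps))
  invisible(x)
}

#' Chronic outward force
#'
#' Sum of the radial components of the nodal contact forces the ring exerts
#' on the vessel surface at the current state.
#'
#' @param m \code{beamModel} in contact equilibrium
#' @param cylinder_id contact name (default "vessel")
#' @return force (N)
#' @export
chronicOutwardForce <- function(m, cylinder_id = "vessel") {
  sum(contactForces(m, cylinder_id)$N)
}

#' Run the full deployment scenario for a ring configuration
#'
#' Convenience wrapper: form, compact, size the vessel, deploy and pulsate.
#'
#' @param ring \code{\link{ringConfig}}
#' @param config \code{\link{deploymentConfig}}
#' @param n_elem mesh density (multiple of 4)
#' @param nincr_compact compaction increments
#' @param opts \code{\link{solverOptions}}
#' @param skip_compaction deploy without the deep compaction step (the ring
#'   is only brought to the vessel radius); used to quantify the effect of
#'   the load history, not a physical delivery sequence
#' @return \code{deploymentResult}
#' @export
runDeployment <- function(ring, config = deploymentConfig(), n_elem = 96,
                          nincr_compact = 60,
                          opts = solverOptions(tolF = 0.01, tolM = 1, maxit = 80,
                                               dulim = 5),
                          skip_compaction = FALSE) {
  fr <- formRing(ring, n_elem = n_elem, opts = opts)
  tube <- sizeVessel(ring, config$oversize_pct,
                     P_m = meanPressure(config$P_d, config$P_s))
  if (skip_compaction) {
    Rv0 <- pressureRadius(tube, meanPressure(config$P_d, config$P_s))
    cp <- compact(fr, config, nincr = max(10, nincr_compact %/% 4),
                  opts = opts,
                  target_radius = Rv0 - 0.02)
  } else {
    cp <- compact(fr, config, nincr = nincr_compact, opts = opts)
  }
  deployAndPulse(cp, tube, opts = opts)
}
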