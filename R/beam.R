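#' Beam models of ring-stent wire bundles
#'
#' A \code{beamModel} carries the current kinematic state (node positions and
#' orientation quaternions), the element table of a corotational Timoshenko
#' beam discretization with fiber-integrated circular cross sections, the
#' committed Nitinol state of every fiber, and the constraint/connector/
#' contact definitions of a scenario. All \code{n} wire turns of a bundle are
#' superimposed: a single wire mesh carries a section-force multiplier
#' \code{n} (\code{nmult}), which is mathematically identical to \code{n}
#' coincident welded wires sharing the same kinematics.
#'
#' Units are mm, N, MPa throughout.
#'
#' @name beamModel
NULL

.GSHEAR_K <- 0.9  # shear correction factor, circular section

# internal constructor
.newBeamModel <- function(X0, Q0, n1, n2, section, matpar, nmult, r_bundle) {
  nn <- ncol(X0)
  ne <- length(n1)
  nf <- length(section$y)
  G <- matpar$E_A / (2 * (1 + matpar$nu_A))
  m <- list(
    nn = nn, nbeam = nn, x = X0, q = Q0, X0 = X0, q0 = Q0,
    el = list(n1 = n1, n2 = n2,
              l0 = sqrt(colSums((X0[, n2, drop = FALSE] -
                                 X0[, n1, drop = FALSE])^2)),
              qCa = .quatIdentity(ne), qCb = .quatIdentity(ne)),
    sec = section, matpar = matpar, nmult = nmult,
    r_bundle = r_bundle,
    GJ = G * section$J, GAs = .GSHEAR_K * G * section$A,
    xi = matrix(0, nf, ne), eptr = matrix(0, nf, ne),
    fixed = integer(0), welds = matrix(integer(0), 0, 2),
    connectors = list(), contacts = list(),
    Fext = matrix(0, 6, nn),
    lastFib = matrix(0, nf, ne), lastStrains = NULL
  )
  class(m) <- "beamModel"
  m
}

#' @export
print.beamModel <- function(x, ...) {
  cat(sprintf("beamModel: %d nodes, %d elements, %d fibers/section, nmult = %d\n",
              x$nn, length(x$el$n1), length(x$sec$y), x$nmult))
  cat(sprintf("  wire r = %g mm, bundle envelope r = %g mm\n",
              x$sec$r_wire, x$r_bundle))
  cat(sprintf("  %d fixed dofs, %d welds, %d connectors, %d contacts\n",
              length(x$fixed), nrow(x$welds), length(x$connectors),
              length(x$contacts)))
  cat(sprintf("  max |fiber strain| committed: %.4g\n", max(abs(x$lastFib))))
  invisible(x)
}

# compute per-element node->element-frame quaternion offsets so that local
# rotations are zero in the as-built configuration
.initElementOffsets <- function(m) {
  fr <- .elemFrames(m)
  ne <- length(m$el$n1)
  for (e in seq_len(ne)) {
    Re <- cbind(fr$e1[, e], fr$e2[, e], fr$e3[, e])
    Ta <- matrix(.quatToMat(m$q[, m$el$n1[e], drop = FALSE]), 3, 3)
    Tb <- matrix(.quatToMat(m$q[, m$el$n2[e], drop = FALSE]), 3, 3)
    m$el$qCa[, e] <- .matToQuat(t(Ta) %*% Re)
    m$el$qCb[, e] <- .matToQuat(t(Tb) %*% Re)
  }
  m
}

#' Straight wire model
#'
#' Open straight wire along the global x axis, the raw stock from which a
#' ring is formed.
#'
#' @param length wire length (mm)
#' @param n_elem number of beam elements
#' @param matpar \code{\link{nitinolParams}}
#' @param r_wire wire radius (mm)
#' @param nmult turn multiplier (number of superimposed turns)
#' @param r_bundle bundle envelope radius for contact offset (mm); default
#'   from \code{\link{bwRatio}}
#' @param n_theta,n_rad fiber grid resolution
#' @return \code{beamModel}
#' @export
straightWireModel <- function(length, n_elem, matpar, r_wire, nmult = 1,
                              r_bundle = NULL, n_theta = 8, n_rad = 3) {
  nn <- n_elem + 1
  X0 <- rbind(seq(0, length, length.out = nn), 0, 0)
  Q0 <- .quatIdentity(nn)
  if (is.null(r_bundle)) r_bundle <- bwRatio(nmult) * r_wire
  sec <- fiberSection(r_wire, n_theta, n_rad)
  .newBeamModel(X0, Q0, seq_len(n_elem), seq_len(n_elem) + 1L,
                sec, matpar, nmult, r_bundle)
}

#' Closed circular ring model (no manufacturing pre-strain)
#'
#' Ring built directly as a regular polygon of \code{n_elem} elements with
#' side length \code{2 pi R_ring / n_elem}; all fibers virgin. Used for the
#' no-pre-strain variant. Node 1 sits at angle \code{phi0}; node triads are
#' (tangent, outward radial, -z).
#'
#' @param R_ring ring mean (centerline) radius (mm)
#' @inheritParams straightWireModel
#' @param phi0 angular position of node 1 (rad)
#' @return \code{beamModel} (closed: last element connects node n to node 1)
#' @export
circleRingModel <- function(R_ring, n_elem, matpar, r_wire, nmult = 1,
                            r_bundle = NULL, n_theta = 8, n_rad = 3,
                            phi0 = 0) {
  l0 <- 2 * pi * R_ring / n_elem
  # polygon circumradius so that side length equals the arc share
  Rc <- l0 / (2 * sin(pi / n_elem))
  phi <- phi0 + 2 * pi * (seq_len(n_elem) - 1) / n_elem
  X0 <- rbind(Rc * cos(phi), Rc * sin(phi), 0)
  Q0 <- sapply(phi, function(p) {
    t1 <- c(-sin(p), cos(p), 0); t2 <- c(cos(p), sin(p), 0)
    .matToQuat(cbind(t1, t2, c(0, 0, -1)))
  })
  if (is.null(r_bundle)) r_bundle <- bwRatio(nmult) * r_wire
  sec <- fiberSection(r_wire, n_theta, n_rad)
  m <- .newBeamModel(X0, Q0, seq_len(n_elem),
                     c(seq_len(n_elem - 1) + 1L, 1L),
                     sec, matpar, nmult, r_bundle)
  .initElementOffsets(m)
}

#' Add an auxiliary node (reference point)
#'
#' Reference points serve as string anchors / crossheads. Their rotational
#' dofs are fixed (they carry no rotational stiffness).
#'
#' @param m \code{beamModel}
#' @param pos 3-vector position (mm)
#' @return list(model, node id)
#' @export
addRefNode <- function(m, pos) {
  m$x <- cbind(m$x, pos); m$X0 <- cbind(m$X0, pos)
  m$q <- cbind(m$q, c(1, 0, 0, 0)); m$q0 <- cbind(m$q0, c(1, 0, 0, 0))
  m$Fext <- cbind(m$Fext, 0)
  m$nn <- m$nn + 1L
  m$fixed <- union(m$fixed, (m$nn - 1L) * 6L + 4:6)
  list(model = m, node = m$nn)
}

#' Weld two coincident nodes
#'
#' Six-dof tie (translations and rotations) between the two wire ends,
#' idealizing the crimp that closes the manufactured ring. Implemented as
#' exact dof identification, so the joint can never open.
#'
#' @param m \code{beamModel}
#' @param node_a,node_b node ids; must be geometrically coincident
#' @param tol coincidence tolerance (mm)
#' @return updated model
#' @export
weldClose <- function(m, node_a, node_b, tol = 1e-6) {
  d <- sqrt(sum((m$x[, node_a] - m$x[, node_b])^2))
  if (d > tol)
    stop(sprintf("weld rejected: nodes %d and %d are %.3g mm apart (tol %.3g)",
                 node_a, node_b, d, tol))
  m$welds <- rbind(m$welds, c(node_b, node_a))  # (slave, master)
  m
}

#' Attach an axial spring connector
#'
#' Pin-ended axial spring between two nodes (the polyethylene strings of the
#' saddle rig). Force is stiffness times elongation; a slack connector
#' carries no compressive force.
#'
#' @param m \code{beamModel}
#' @param na,nb node ids
#' @param k stiffness (N/mm)
#' @param L0 rest length (mm); default current distance
#' @param slack drop compressive force (string behavior)
#' @return updated model
#' @export
addConnector <- function(m, na, nb, k, L0 = NULL, slack = TRUE) {
  if (is.null(L0)) L0 <- sqrt(sum((m$x[, na] - m$x[, nb])^2))
  stopifnot(k > 0)
  m$connectors[[length(m$connectors) + 1]] <-
    list(na = na, nb = nb, k = k, L0 = L0, slack = slack)
  m
}

#' Add a rigid cylindrical contact surface
#'
#' Penalty contact of beam nodes (evaluated at centerline offset by the
#' bundle envelope radius) against a rigid cylinder coaxial with z.
#' \code{type = "outer"} confines the ring from outside (sheath, vessel);
#' \code{type = "inner"} is the delivery-system inner tube.
#'
#' @param m \code{beamModel}
#' @param name contact id used in radius schedules
#' @param type "outer" or "inner"
#' @param radius cylinder radius (mm)
#' @param mu Coulomb friction coefficient
#' @param kpen penalty stiffness per node (N/mm)
#' @param roff contact offset from the centerline; defaults to the bundle
#'   envelope radius
#' @return updated model
#' @export
addContact <- function(m, name, type = c("outer", "inner"), radius,
                       mu = 0, kpen = 50, roff = NULL) {
  type <- match.arg(type)
  if (is.null(roff)) roff <- m$r_bundle
  cn <- setdiff(seq_len(m$nbeam), m$welds[, 1])  # weld slaves are coincident
  m$contacts[[name]] <- list(name = name, type = type, R = radius, mu = mu,
                             kpen = kpen, roff = roff, active = TRUE,
                             cnodes = cn,
                             anchors = m$x[, cn, drop = FALSE])
  m
}

#' Fix nodal degrees of freedom
#'
#' @param m \code{beamModel}
#' @param node node id (scalar or vector)
#' @param comps dof components (1:3 translations x,y,z; 4:6 rotations)
#' @return updated model
#' @export
fixDof <- function(m, node, comps) {
  ids <- as.integer(outer(comps, (node - 1L) * 6L, "+"))
  m$fixed <- union(m$fixed, ids)
  m
}

# global dof id helper
.dofId <- function(node, comp) (node - 1L) * 6L + comp
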