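# Corotational kinematics and assembly of residual / tangent.
#
# Local deformational dofs per element: p = (u, Theta_a, Theta_b) with
# u the axial elongation and Theta_i the small local rotation vectors of the
# node triads relative to the corotated element frame. Strain measures:
#   eps_c = u/l0, tau = (Tb1-Ta1)/l0, k2 = (Tb2-Ta2)/l0, k3 = (Tb3-Ta3)/l0,
#   g2 = -(Ta3+Tb3)/2, g3 = (Ta2+Tb2)/2  (Timoshenko mean shear)
# Fiber axial strain: eps = eps_c + z*k2 - y*k3.
#
# The element tangent is the directional finite difference of the element
# force over its own 12 dofs (vectorized across elements), i.e. the
# algorithmically consistent tangent including all corotational geometric
# terms and the active material branch.

# frames/strains from explicit element-local nodal arrays
.elemFramesLocal <- function(m, xa, xb, qa, qb) {
  d <- xb - xa
  ln <- sqrt(colSums(d * d))
  e1 <- sweep(d, 2, ln, "/")
  qGa <- .quatMul(qa, m$el$qCa)
  qGb <- .quatMul(qb, m$el$qCb)
  sgn <- sign(colSums(qGa * qGb)); sgn[sgn == 0] <- 1
  qGb <- sweep(qGb, 2, sgn, "*")
  qm <- .quatNormalize(qGa + qGb)
  Rm <- .quatToMat(qm)
  gm2 <- Rm[4:6, , drop = FALSE]
  proj <- colSums(gm2 * e1)
  e2 <- gm2 - sweep(e1, 2, proj, "*")
  e2 <- sweep(e2, 2, sqrt(colSums(e2 * e2)), "/")
  e3 <- rbind(e1[2, ] * e2[3, ] - e1[3, ] * e2[2, ],
              e1[3, ] * e2[1, ] - e1[1, ] * e2[3, ],
              e1[1, ] * e2[2, ] - e1[2, ] * e2[1, ])
  Ga <- .quatToMat(qGa); Gb <- .quatToMat(qGb)
  locrot <- function(G) {
    L <- rbind(colSums(e1 * G[1:3, , drop = FALSE]),
               colSums(e2 * G[1:3, , drop = FALSE]),
               colSums(e3 * G[1:3, , drop = FALSE]),
               colSums(e1 * G[4:6, , drop = FALSE]),
               colSums(e2 * G[4:6, , drop = FALSE]),
               colSums(e3 * G[4:6, , drop = FALSE]),
               colSums(e1 * G[7:9, , drop = FALSE]),
               colSums(e2 * G[7:9, , drop = FALSE]),
               colSums(e3 * G[7:9, , drop = FALSE]))
    .rotvecFromMat(L)
  }
  Ta <- locrot(Ga); Tb <- locrot(Gb)
  l0 <- m$el$l0
  list(e1 = e1, e2 = e2, e3 = e3, ln = ln, Ta = Ta, Tb = Tb,
       eps_c = (ln - l0) / l0,
       tau = (Tb[1, ] - Ta[1, ]) / l0,
       k2 = (Tb[2, ] - Ta[2, ]) / l0,
       k3 = (Tb[3, ] - Ta[3, ]) / l0,
       g2 = -(Ta[3, ] + Tb[3, ]) / 2,
       g3 = (Ta[2, ] + Tb[2, ]) / 2)
}

.elemFrames <- function(m) {
  n1 <- m$el$n1; n2 <- m$el$n2
  .elemFramesLocal(m, m$x[, n1, drop = FALSE], m$x[, n2, drop = FALSE],
                   m$q[, n1, drop = FALSE], m$q[, n2, drop = FALSE])
}

.fiberStrains <- function(m, fr) {
  outer(rep(1, length(m$sec$y)), fr$eps_c) +
    outer(m$sec$z, fr$k2) - outer(m$sec$y, fr$k3)
}

# element nodal force blocks (12 x Ne, global frame) from local nodal arrays.
# light = TRUE returns only the force matrix.
.elemForces <- function(m, xa, xb, qa, qb, light = FALSE) {
  fr <- .elemFramesLocal(m, xa, xb, qa, qb)
  feps <- .fiberStrains(m, fr)
  upd <- .nitUpdate(m$matpar, as.numeric(m$xi), as.numeric(m$eptr),
                    as.numeric(feps))
  nf <- length(m$sec$y); ne <- length(m$el$n1)
  sig <- matrix(upd$sigma, nf, ne)
  w <- m$sec$w; y <- m$sec$y; z <- m$sec$z
  nm <- m$nmult
  N <- nm * colSums(w * sig)
  M2 <- nm * colSums((w * z) * sig)
  M3 <- -nm * colSums((w * y) * sig)
  Tq <- nm * m$GJ * fr$tau
  V2 <- nm * m$GAs * fr$g2
  V3 <- nm * m$GAs * fr$g3
  l0 <- m$el$l0
  fu <- N
  ma1 <- -Tq; ma2 <- -M2 + l0 * V3 / 2; ma3 <- -M3 - l0 * V2 / 2
  mb1 <- Tq;  mb2 <- M2 + l0 * V3 / 2;  mb3 <- M3 - l0 * V2 / 2
  e1 <- fr$e1; e2 <- fr$e2; e3 <- fr$e3; ln <- fr$ln
  Ma <- sweep(e1, 2, ma1, "*") + sweep(e2, 2, ma2, "*") + sweep(e3, 2, ma3, "*")
  Mb <- sweep(e1, 2, mb1, "*") + sweep(e2, 2, mb2, "*") + sweep(e3, 2, mb3, "*")
  Msum <- Ma + Mb
  d2 <- colSums(e2 * Msum); d3 <- colSums(e3 * Msum); d1 <- colSums(e1 * Msum)
  StM <- sweep(e2, 2, d3 / ln, "*") - sweep(e3, 2, d2 / ln, "*")
  gAt <- -sweep(e1, 2, fu, "*") + StM
  half <- sweep(e1, 2, d1 / 2, "*")
  Fel <- rbind(gAt, Ma - half, -gAt, Mb - half)
  if (light) return(Fel)
  list(Fel = Fel, fr = fr, feps = feps, sig = sig,
       trial = list(xi = matrix(upd$xi, nf, ne),
                    eptr = matrix(upd$eptr, nf, ne)))
}

# Full assembly. contactR: named numeric vector overriding contact radii.
.assemble <- function(m, contactR = NULL, needK = TRUE) {
  ne <- length(m$el$n1); nn <- m$nn
  ndof <- 6L * nn
  n1 <- m$el$n1; n2 <- m$el$n2
  xa <- m$x[, n1, drop = FALSE]; xb <- m$x[, n2, drop = FALSE]
  qa <- m$q[, n1, drop = FALSE]; qb <- m$q[, n2, drop = FALSE]
  ef <- .elemForces(m, xa, xb, qa, qb)

  g <- numeric(ndof)
  eldofs <- rbind(
    outer(1:3, (n1 - 1L) * 6L, "+"),
    outer(4:6, (n1 - 1L) * 6L, "+"),
    outer(1:3, (n2 - 1L) * 6L, "+"),
    outer(4:6, (n2 - 1L) * 6L, "+"))        # 12 x Ne global dof ids
  acc <- rowsum(as.numeric(ef$Fel), as.integer(eldofs))
  g[as.integer(rownames(acc))] <- acc[, 1]

  # ---- connectors ----
  connForce <- numeric(length(m$connectors))
  for (ci in seq_along(m$connectors)) {
    cn <- m$connectors[[ci]]
    dv <- m$x[, cn$nb] - m$x[, cn$na]
    L <- sqrt(sum(dv * dv)); u <- dv / L
    eL <- L - cn$L0
    f <- cn$k * eL
    if (cn$slack && f < 0) f <- 0
    connForce[ci] <- f
    fa <- f * u
    ia <- .dofId(cn$na, 1:3); ib <- .dofId(cn$nb, 1:3)
    g[ia] <- g[ia] - fa
    g[ib] <- g[ib] + fa
  }

  # ---- contacts ----
  contactTab <- list()
  for (ct in m$contacts) {
    if (!ct$active) next
    R <- if (!is.null(contactR) && ct$name %in% names(contactR))
      contactR[[ct$name]] else ct$R
    cn <- ct$cnodes
    xy <- m$x[1:2, cn, drop = FALSE]
    rho <- pmax(sqrt(colSums(xy * xy)), 1e-9)
    rh <- sweep(xy, 2, rho, "/")
    pen <- if (ct$type == "outer") rho + ct$roff - R else (R + ct$roff) - rho
    act <- pen > 0
    # C1-smoothed penalty: N = k pen^2 / (pen + d0); removes the stiffness
    # jump at grazing contact that makes the active set chatter
    d0 <- 0.02
    Ncf <- ifelse(act, ct$kpen * pen^2 / (pen + d0), 0)
    dirn <- if (ct$type == "outer") -1 else 1
    Fx <- dirn * Ncf * rh[1, ]; Fy <- dirn * Ncf * rh[2, ]
    Ft <- matrix(0, 3, length(cn))
    if (ct$mu > 0 && any(act)) {
      slip <- m$x[, cn, drop = FALSE] - ct$anchors
      srad <- colSums(slip[1:2, , drop = FALSE] * rh)
      st <- slip
      st[1:2, ] <- st[1:2, ] - sweep(rh, 2, srad, "*")
      ftr <- -ct$kpen * st
      fmag <- sqrt(colSums(ftr * ftr))
      cap <- ct$mu * Ncf
      # smooth Coulomb regularization: |Ft| = cap * tanh(k|s|/cap)
      scl <- ifelse(cap > 0 & fmag > 1e-14,
                    cap * tanh(fmag / cap) / fmag, 0)
      Ft <- sweep(ftr, 2, ifelse(act, scl, 0), "*")
    }
    kk <- which(act | colSums(abs(Ft)) > 0)
    for (k in kk) {
      ii <- .dofId(cn[k], 1:3)
      g[ii] <- g[ii] - c(Fx[k], Fy[k], 0) - Ft[, k]
    }
    contactTab[[ct$name]] <- list(nodes = cn, pen = pen, N = Ncf,
                                  Fx = Fx, Fy = Fy, Ft = Ft, R = R,
                                  radial = Ncf, act = act)
  }

  # ---- pin springs (continuation aid: ramped to zero by the caller) ----
  if (!is.null(m$pins) && m$pins$k > 0) {
    pn <- seq_len(m$nbeam)
    dx <- m$x[, pn, drop = FALSE] - m$pins$xref
    ids <- as.integer(outer(1:3, (pn - 1L) * 6L, "+"))
    g[ids] <- g[ids] + m$pins$k * as.numeric(dx)
  }

  # ---- external loads ----
  g <- g - as.numeric(m$Fext)

  K <- NULL
  if (needK) {
    # FD step: small enough that the tangent accuracy does not limit the
    # attainable residual of the elastic oracle problems
    h <- 1e-7
    F0 <- ef$Fel
    nt <- 144L * ne
    tx <- numeric(nt)
    base <- (seq_len(ne) - 1L) * 144L
    # batch all 12 dof perturbations into one vectorized force evaluation
    XA <- matrix(xa, 3, 12L * ne); XB <- matrix(xb, 3, 12L * ne)
    QA <- matrix(qa, 4, 12L * ne); QB <- matrix(qb, 4, 12L * ne)
    for (j in 1:3) {
      cols <- (j - 1L) * ne + seq_len(ne)
      XA[j, cols] <- XA[j, cols] + h
      cols <- (j + 5L) * ne + seq_len(ne)
      XB[j, cols] <- XB[j, cols] + h
    }
    for (j in 1:3) {
      dw <- matrix(0, 3, ne); dw[j, ] <- h
      dq <- .quatFromRotvec(dw)
      cols <- (j + 2L) * ne + seq_len(ne)
      QA[, cols] <- .quatNormalize(.quatMul(dq, qa))
      cols <- (j + 8L) * ne + seq_len(ne)
      QB[, cols] <- .quatNormalize(.quatMul(dq, qb))
    }
    mb <- m
    rep12 <- rep(seq_len(ne), times = 12)
    mb$el <- list(n1 = rep(m$el$n1, 12), n2 = rep(m$el$n2, 12),
                  l0 = m$el$l0[rep12],
                  qCa = m$el$qCa[, rep12, drop = FALSE],
                  qCb = m$el$qCb[, rep12, drop = FALSE])
    mb$xi <- m$xi[, rep12, drop = FALSE]
    mb$eptr <- m$eptr[, rep12, drop = FALSE]
    FB <- .elemForces(mb, XA, XB, QA, QB, light = TRUE)  # 12 x (12 Ne)
    for (j in 1:12) {
      Fj <- FB[, (j - 1L) * ne + seq_len(ne), drop = FALSE]
      Kcol <- (Fj - F0) / h                       # 12 x Ne
      tx[rep(base, each = 12L) + (j - 1L) * 12L + seq_len(12L)] <-
        as.numeric(Kcol)
    }
    ti <- integer(nt); tj <- integer(nt)
    for (j in 1:12) {
      pos <- rep(base, each = 12L) + (j - 1L) * 12L + seq_len(12L)
      ti[pos] <- as.integer(eldofs)
      tj[pos] <- as.integer(eldofs[rep(j, 12), , drop = FALSE])
    }
    trip_i <- ti; trip_j <- tj; trip_x <- tx
    # connector stiffness
    for (cn in m$connectors) {
      dv <- m$x[, cn$nb] - m$x[, cn$na]
      L <- sqrt(sum(dv * dv)); u <- dv / L
      eL <- L - cn$L0
      slackNow <- cn$slack && (cn$k * eL < 0)
      kmat <- if (slackNow) 1e-9 * diag(3) else
        cn$k * tcrossprod(u) + (cn$k * eL / L) * (diag(3) - tcrossprod(u))
      da <- .dofId(cn$na, 1:3); db <- .dofId(cn$nb, 1:3)
      dd <- c(da, db)
      Kc <- rbind(cbind(kmat, -kmat), cbind(-kmat, kmat))
      trip_i <- c(trip_i, rep(dd, times = 6))
      trip_j <- c(trip_j, rep(dd, each = 6))
      trip_x <- c(trip_x, as.numeric(Kc))
    }
    # contact stiffness
    for (nm2 in names(contactTab)) {
      ct <- m$contacts[[nm2]]
      tab <- contactTab[[nm2]]
      for (k in which(tab$act)) {
        nd <- tab$nodes[k]
        xy <- m$x[1:2, nd]
        rho <- max(sqrt(sum(xy^2)), 1e-9)
        rh <- c(xy / rho, 0)
        hoop <- c(-rh[2], rh[1], 0)
        d0 <- 0.02
        pk <- tab$pen[k]
        dN <- ct$kpen * pk * (pk + 2 * d0) / (pk + d0)^2
        Kc3 <- dN * tcrossprod(rh) + (tab$N[k] / rho) * tcrossprod(hoop)
        if (ct$mu > 0) {
          # tangent of the smooth Coulomb law: k sech^2(k|s|/cap), fading
          # from the stick stiffness to zero as the node slips
          cap <- ct$mu * tab$N[k]
          sA <- m$x[, nd] - ct$anchors[, which(ct$cnodes == nd)]
          fmag <- ct$kpen * sqrt(sum(sA^2))
          ktf <- if (cap > 0) ct$kpen / cosh(min(fmag / cap, 20))^2 else 0
          Kc3 <- Kc3 + ktf * (tcrossprod(hoop) + diag(c(0, 0, 1)))
        }
        dd <- .dofId(nd, 1:3)
        trip_i <- c(trip_i, rep(dd, times = 3))
        trip_j <- c(trip_j, rep(dd, each = 3))
        trip_x <- c(trip_x, as.numeric(Kc3))
      }
    }
    if (!is.null(m$pins) && m$pins$k > 0) {
      ids <- as.integer(outer(1:3, (seq_len(m$nbeam) - 1L) * 6L, "+"))
      trip_i <- c(trip_i, ids)
      trip_j <- c(trip_j, ids)
      trip_x <- c(trip_x, rep(m$pins$k, length(ids)))
    }
    K <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                              dims = c(ndof, ndof))
  }
  list(g = g, K = K, fr = ef$fr, feps = ef$feps, sig = ef$sig,
       trial = ef$trial, contacts = contactTab, connForce = connForce)
}

# commit trial state after a converged increment
.commit <- function(m, asm) {
  m$xi <- asm$trial$xi
  m$eptr <- asm$trial$eptr
  m$lastFib <- asm$feps
  m$lastStrains <- asm$fr
  for (nm2 in names(m$contacts)) {
    ct <- m$contacts[[nm2]]
    if (!nm2 %in% names(asm$contacts)) next
    if (ct$mu > 0) {
      tab <- asm$contacts[[nm2]]
      x <- m$x[, ct$cnodes, drop = FALSE]
      anch <- ct$anchors
      for (k in which(tab$act)) {
        s <- x[, k] - anch[, k]
        cap <- ct$mu * tab$N[k]
        sm <- sqrt(sum(s^2))
        slim <- 2 * cap / ct$kpen   # tanh(2) = 0.96: re-anchoring at this
        if (cap > 0 && sm > slim)   # slip leaves the force nearly unchanged
          anch[, k] <- x[, k] - s * (slim / sm)
      }
      anch[, !tab$act] <- x[, !tab$act]
      m$contacts[[nm2]]$anchors <- anch
    } else {
      m$contacts[[nm2]]$anchors <- m$x[, ct$cnodes, drop = FALSE]
    }
  }
  m
}
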