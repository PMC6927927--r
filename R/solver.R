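# Incremental-iterative quasi-static solution.

#' Solver options
#'
#' @param tolF force residual tolerance (N)
#' @param tolM moment residual tolerance (N mm)
#' @param maxit Newton iterations per increment
#' @param maxBisect maximum increment bisection levels
#' @param verbose print per-increment summaries
#' @return list of options
#' @export
solverOptions <- function(tolF = 1e-7, tolM = 1e-5, maxit = 30,
                          maxBisect = 8, dulim = NULL, verbose = FALSE) {
  list(tolF = tolF, tolM = tolM, maxit = maxit, maxBisect = maxBisect,
       dulim = dulim, verbose = verbose)
}

# equation map: every dof -> reduced equation id (0 = eliminated).
# Welded slaves share the master's equations; fixed dofs are eliminated.
.eqMap <- function(m) {
  ndof <- 6L * m$nn
  owner <- seq_len(ndof)
  if (nrow(m$welds) > 0) {
    for (r in seq_len(nrow(m$welds))) {
      sl <- m$welds[r, 1]; ma <- m$welds[r, 2]
      owner[.dofId(sl, 1:6)] <- .dofId(ma, 1:6)
    }
  }
  # a slave whose master is fixed is fixed too (owner indirection handles it)
  isFree <- rep(TRUE, ndof)
  isFree[m$fixed] <- FALSE
  isFree <- isFree[owner]          # slave inherits master's status
  isFree[m$fixed] <- FALSE
  keep <- sort(unique(owner[isFree]))
  eq <- integer(ndof)
  eq[keep] <- seq_along(keep)
  eq <- eq[owner]
  eq[!isFree] <- 0L
  list(eq = eq, neq = length(keep))
}

# apply a reduced-solution increment to the model state
.applyDelta <- function(m, eq, du, scale = 1) {
  ndof <- 6L * m$nn
  full <- numeric(ndof)
  sel <- eq$eq > 0L
  full[sel] <- du[eq$eq[sel]] * scale
  dU <- matrix(full, 6, m$nn)
  m$x <- m$x + dU[1:3, , drop = FALSE]
  rot <- which(colSums(abs(dU[4:6, , drop = FALSE])) > 0)
  if (length(rot)) {
    dq <- .quatFromRotvec(dU[4:6, rot, drop = FALSE])
    m$q[, rot] <- .quatNormalize(.quatMul(dq, m$q[, rot, drop = FALSE]))
  }
  m
}

.resNorms <- function(g, eq, nn) {
  sel <- which(eq$eq > 0L)
  comp <- ((sel - 1L) %% 6L) + 1L
  gred <- rowsum(g[sel], eq$eq[sel])  # welded dofs: sum of partner residuals
  compOfEq <- integer(eq$neq)
  compOfEq[eq$eq[sel]] <- comp       # merged dofs share the same component
  isF <- compOfEq[as.integer(rownames(gred))] <= 3
  c(F = if (any(isF)) max(abs(gred[isF])) else 0,
    M = if (any(!isF)) max(abs(gred[!isF])) else 0)
}

# One load increment: Newton with adaptive Levenberg damping.
# prescribe: data.frame(dof, value) of absolute dof positions (translations).
.newtonIncrement <- function(m, eq, contactR, opts) {
  lam <- 0
  bestG <- Inf
  noImp <- 0
  damp <- 1
  best <- NULL
  # Plain full-step Newton handles the smooth beam problems (including the
  # legitimate residual spikes of slender-beam force steps); the trust
  # region + adaptive damping mode is for contact/plateau-dominated
  # scenarios and is engaged by setting dulim in the solver options.
  plain <- is.null(opts$dulim)
  dulim <- if (plain) Inf else opts$dulim
  sel <- which(eq$eq > 0L)
  redNorm2 <- function(g) {
    acc <- rowsum(g[sel], eq$eq[sel])
    sum(acc^2)
  }
  for (it in seq_len(opts$maxit)) {
    asm <- .assemble(m, contactR, needK = TRUE)
    nr <- .resNorms(asm$g, eq, m$nn)
    if (nr["F"] < opts$tolF && nr["M"] < opts$tolM)
      return(list(model = m, asm = asm, iters = it, res = nr, ok = TRUE))
    if (!plain && it == 1 && nr["F"] < 5 * opts$tolF && nr["M"] < 5 * opts$tolM)
      damp <- 0.5  # polish a nearly converged state gently
    if (is.null(best) || max(nr["F"] / opts$tolF, nr["M"] / opts$tolM) <
          max(best$res["F"] / opts$tolF, best$res["M"] / opts$tolM))
      best <- list(model = m, asm = asm, res = nr)
    gred <- numeric(eq$neq)
    acc <- rowsum(asm$g[sel], eq$eq[sel])
    gred[as.integer(rownames(acc))] <- acc[, 1]
    Pm <- Matrix::sparseMatrix(i = eq$eq[sel], j = sel, x = 1,
                               dims = c(eq$neq, length(eq$eq)))
    Kred <- Pm %*% asm$K %*% Matrix::t(Pm)
    if (lam > 0)
      Kred <- Kred + lam * Matrix::Diagonal(eq$neq, x = pmax(Matrix::diag(Kred), 1))
    du <- tryCatch(as.numeric(Matrix::solve(Kred, -gred)),
                   error = function(e) NULL)
    if (is.null(du)) {
      if (lam == 0) { lam <- 1e-6; next }
      return(list(model = m, asm = asm, iters = it, res = nr, ok = FALSE,
                  why = "singular stiffness (rigid-body mode?)"))
    }
    gn <- sum(gred^2)
    if (!is.finite(gn))
      return(list(model = m, asm = asm, iters = it, res = nr, ok = FALSE,
                  why = "non-finite residual"))
    if (gn < bestG) { bestG <- gn; noImp <- 0 } else noImp <- noImp + 1
    if (noImp > 20) {
      if (!is.null(best) && best$res["F"] < opts$tolF &&
            best$res["M"] < opts$tolM)
        return(list(model = best$model, asm = best$asm, iters = it,
                    res = best$res, ok = TRUE))
      return(list(model = best$model %||% m, asm = best$asm %||% asm,
                  iters = it, res = (best %||% list(res = nr))$res,
                  ok = FALSE, why = "stagnation"))
    }
    # displacement trust region: a Newton step far beyond the element
    # length scale is outside the corotational linearization radius.
    # The adaptive damping settles semismooth oscillation across material
    # branch and contact state switches.
    sc0 <- min(1, dulim / max(abs(du))) * damp
    # backtracking line search: with the consistent tangent, small scaled
    # steps are always descent steps; if no scale reduces the residual
    # (the legitimate residual spike of a slender-beam force step), the
    # full trust-region step is taken non-monotonically.
    # Non-monotone acceptance: bending-dominated force steps legitimately
    # spike the residual by orders of magnitude before Newton contracts,
    # so a step is accepted if it stays within a growth cap of the current
    # residual OR below an absolute force scale; otherwise smaller scales
    # are tried and, failing that, the increment is left to bisection.
    cap <- 1e4 * max(gn, 1e-12)
    if (plain) {
      # non-monotone full-step Newton: accept any step within the growth
      # cap (bending force steps legitimately spike the residual); when
      # even scaled steps exceed it, Levenberg-damp the tangent and retry
      mt <- .applyDelta(m, eq, du, sc0)
      at <- .assemble(mt, contactR, needK = FALSE)
      gt <- redNorm2(at$g)
      if (!is.finite(gt) || gt > cap) {
        ok2 <- FALSE
        for (sc in sc0 * c(0.5, 0.25, 0.1, 0.03)) {
          mt2 <- .applyDelta(m, eq, du, sc)
          at2 <- .assemble(mt2, contactR, needK = FALSE)
          gt2 <- redNorm2(at2$g)
          if (is.finite(gt2) && gt2 <= cap) {
            mt <- mt2; gt <- gt2; ok2 <- TRUE
            break
          }
        }
        if (!ok2) {
          lam <- max(lam * 10, 1e-5)
          next
        }
      } else if (lam > 0) {
        lam <- lam / 5
        if (lam < 1e-9) lam <- 0
      }
      m <- mt
    } else {
      # contact/plateau mode: prefer descent; accept the best bounded
      # non-monotone step otherwise, with adaptive step damping
      pick <- NULL
      for (sc in sc0 * c(1, 0.5, 0.25, 0.1, 0.03)) {
        mt2 <- .applyDelta(m, eq, du, sc)
        at2 <- .assemble(mt2, contactR, needK = FALSE)
        gt2 <- redNorm2(at2$g)
        if (!is.finite(gt2)) next
        if (gt2 < gn || gt2 <= cap) { pick <- list(m = mt2, gt = gt2); break }
        if (is.null(pick) || gt2 < pick$gt) pick <- list(m = mt2, gt = gt2)
      }
      if (is.null(pick)) {
        lam <- max(lam * 10, 1e-5)
        next
      }
      gt <- pick$gt
      if (gt < gn) {
        if (lam > 0) { lam <- lam / 5; if (lam < 1e-9) lam <- 0 }
      } else if (gt > cap) {
        lam <- max(lam * 3, 1e-6)
      }
      damp <- if (gt > gn) max(damp / 2, 0.03) else min(1, damp * 1.6)
      m <- pick$m
    }
  }
  asm <- .assemble(m, contactR, needK = FALSE)
  nr <- .resNorms(asm$g, eq, m$nn)
  if (!is.null(best) && max(best$res["F"] / opts$tolF,
                            best$res["M"] / opts$tolM) <
        max(nr["F"] / opts$tolF, nr["M"] / opts$tolM)) {
    m <- best$model; asm <- best$asm; nr <- best$res
  }
  ok <- nr["F"] < opts$tolF && nr["M"] < opts$tolM
  list(model = m, asm = asm, iters = opts$maxit, res = nr, ok = ok,
       why = if (!ok) "no convergence in maxit")
}

#' Run a program of quasi-static load steps
#'
#' Incremental-iterative Newton solution of a \code{\link{beamModel}} under
#' an ordered list of steps. Each step ramps prescribed nodal displacements,
#' contact radius schedules and external loads linearly over its increments;
#' non-converged increments are bisected automatically. Fiber material states
#' are committed at every converged increment, preserving load-history
#' dependence across steps.
#'
#' @param m \code{beamModel}
#' @param steps list of steps; each a list with optional fields:
#'   \code{name}; \code{nincr} (number of increments, default 10);
#'   \code{prescribe} data.frame(node, comp, target) of absolute target
#'   positions for translational dofs (held fixed after reaching target);
#'   \code{contactR} named vector of contact radii at step end;
#'   \code{Fext} 6 x nn external load matrix at step end;
#'   \code{record} function(model, asm) -> named numeric, evaluated at each
#'   converged increment;
#'   \code{hook} function(model, frac) -> model, called before each increment
#' @param opts \code{\link{solverOptions}}
#' @return list(model, report, history) where report is a data.frame of
#'   per-increment convergence data and history collects \code{record} rows
#' @export
solveProgram <- function(m, steps, opts = solverOptions()) {
  report <- list()
  history <- list()
  for (si in seq_along(steps)) {
    st <- steps[[si]]
    nm0 <- if (!is.null(st$name)) st$name else paste0("step", si)
    nincr <- if (!is.null(st$nincr)) st$nincr else 10
    presc <- st$prescribe
    F0 <- m$Fext
    F1 <- if (!is.null(st$Fext)) st$Fext else F0
    cR0 <- vapply(m$contacts, function(ct) ct$R, numeric(1))
    cR1 <- cR0
    if (!is.null(st$contactR)) cR1[names(st$contactR)] <- st$contactR
    x0p <- NULL
    if (!is.null(presc)) {
      ids <- .dofId(presc$node, 1)  # start positions of the prescribed comps
      x0p <- vapply(seq_len(nrow(presc)),
                    function(r) m$x[presc$comp[r], presc$node[r]], numeric(1))
      for (r in seq_len(nrow(presc)))
        m <- fixDof(m, presc$node[r], presc$comp[r])
    }
    eq <- .eqMap(m)
    frac <- 0
    dfrac <- 1 / nincr
    lvl <- 0
    while (frac < 1 - 1e-12) {
      target <- min(frac + dfrac, 1)
      mtry <- m
      if (!is.null(st$hook)) mtry <- st$hook(mtry, target)
      if (!is.null(presc)) {
        for (r in seq_len(nrow(presc))) {
          mtry$x[presc$comp[r], presc$node[r]] <-
            x0p[r] + target * (presc$target[r] - x0p[r])
        }
      }
      mtry$Fext <- F0 + target * (F1 - F0)
      cRt <- cR0 + target * (cR1 - cR0)
      res <- .newtonIncrement(mtry, eq, cRt, opts)
      if (res$ok) {
        m <- .commit(res$model, res$asm)
        m$Fext <- mtry$Fext
        for (nmc in names(cRt)) m$contacts[[nmc]]$R <- cRt[[nmc]]
        report[[length(report) + 1]] <-
          data.frame(step = nm0, frac = target, iters = res$iters,
                     resF = res$res["F"], resM = res$res["M"],
                     converged = TRUE)
        if (!is.null(st$record))
          history[[length(history) + 1]] <-
            c(step = si, frac = target, st$record(m, res$asm))
        frac <- target
        if (lvl > 0) { lvl <- lvl - 1; dfrac <- dfrac * 2 }
      } else {
        lvl <- lvl + 1
        dfrac <- dfrac / 2
        if (lvl > opts$maxBisect) {
          report[[length(report) + 1]] <-
            data.frame(step = nm0, frac = target, iters = res$iters,
                       resF = res$res["F"], resM = res$res["M"],
                       converged = FALSE)
          warning(sprintf("step '%s' failed at fraction %.4f (residual F=%.3g)",
                          nm0, target, res$res["F"]))
          return(list(model = m, report = do.call(rbind, report),
                      history = .bindHistory(history), converged = FALSE))
        }
      }
      if (opts$verbose)
        cat(sprintf("[%s] frac %.3f it %d resF %.2e\n", nm0, frac,
                    res$iters, res$res["F"]))
    }
  }
  list(model = m, report = do.call(rbind, report),
       history = .bindHistory(history), converged = TRUE)
}

.bindHistory <- function(h) {
  if (!length(h)) return(NULL)
  as.data.frame(do.call(rbind, h))
}

#' Nodal contact forces against a cylindrical surface
#'
#' Penalty-regularized normal and Coulomb-capped tangential nodal forces for
#' the named contact at the current state.
#'
#' @param m converged \code{beamModel}
#' @param cylinder_id contact name
#' @return data.frame(node, Fx, Fy, Fz, N, radial); \code{radial} is the
#'   radial component of the force the RING exerts on the surface (positive
#'   outward for an outer surface)
#' @export
contactForces <- function(m, cylinder_id) {
  if (!cylinder_id %in% names(m$contacts)) stop("unknown contact: ", cylinder_id)
  asm <- .assemble(m, needK = FALSE)
  tab <- asm$contacts[[cylinder_id]]
  if (is.null(tab))
    return(data.frame(node = integer(0), Fx = numeric(0), Fy = numeric(0),
                      Fz = numeric(0), N = numeric(0), radial = numeric(0)))
  data.frame(node = tab$nodes, Fx = tab$Fx + tab$Ft[1, ],
             Fy = tab$Fy + tab$Ft[2, ], Fz = tab$Ft[3, ],
             N = tab$N, radial = tab$radial)
}

#' Maximum strain at the wire surface
#'
#' Per-element extreme of the axial strain over the circular section
#' boundary, \code{eps_c +/- r * sqrt(k2^2 + k3^2)}; exact for the beam
#' kinematics regardless of the fiber grid. Based on the last committed
#' state.
#'
#' @param m \code{beamModel}
#' @return data.frame(element, eps_max, eps_min, eps_absmax) per element
#' @export
surfaceStrains <- function(m) {
  fr <- if (!is.null(m$lastStrains)) m$lastStrains else .elemFrames(m)
  r <- m$sec$r_wire
  bend <- r * sqrt(fr$k2^2 + fr$k3^2)
  data.frame(element = seq_along(fr$eps_c),
             eps_max = fr$eps_c + bend,
             eps_min = fr$eps_c - bend,
             eps_absmax = abs(fr$eps_c) + bend)
}

#' Global equilibrium check
#'
#' Sum of all forces on the free system (internal, external, contact,
#' connector); near zero at a converged state.
#'
#' @param m \code{beamModel}
#' @return max abs residual over free translational dofs (N)
#' @export
equilibriumResidual <- function(m) {
  eq <- .eqMap(m)
  asm <- .assemble(m, needK = FALSE)
  unname(.resNorms(asm$g, eq, m$nn)["F"])
}
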