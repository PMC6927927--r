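# Optimal ratios R_enclosing / r_circle for packing n equal circles in the
# smallest enclosing circle (circle-packing literature), n = 1..14, printed
# to 3 decimals. n = 2..4 and 7 have closed forms (2, 1 + 2/sqrt(3),
# 1 + sqrt(2), 3); the numerical cross-check below recovers n <= 8.
.bwTable <- c(1.000, 2.000, 2.154, 2.414, 2.701, 3.000, 3.000,
              3.304, 3.613, 3.813, 3.923, 4.029, 4.236, 4.328)

#' Bundle-to-wire radius ratio from circle packing
#'
#' Ratio of the radius of the smallest circle that can enclose \code{n} equal
#' wire cross sections to the wire radius. Used to size the bundle envelope
#' of an \code{n}-turn ring bundle.
#'
#' @param n number of wire turns (integer >= 1). Values above 14 fall back to
#'   the asymptotic hexagonal-packing estimate \code{sqrt(n / 0.9069)} with a
#'   warning.
#' @return dimensionless ratio
#' @export
bwRatio <- function(n) {
  if (length(n) != 1 || !is.finite(n) || n < 1 || n != round(n))
    stop("n must be a single integer >= 1")
  if (n <= 14) return(.bwTable[n])
  warning("packing ratio tabulated only for n <= 14; using hexagonal estimate")
  sqrt(n / 0.9069)
}

#' Bundle envelope diameter
#'
#' Diameter of the smallest circle enclosing \code{n} wire turns of radius
#' \code{r_wire}: \code{2 * bwRatio(n) * r_wire}.
#'
#' @param r_wire wire radius (mm), positive
#' @param n number of wire turns
#' @return bundle diameter (mm)
#' @export
bundleDiameter <- function(r_wire, n) {
  if (!is.finite(r_wire) || r_wire <= 0) stop("r_wire must be positive")
  2 * bwRatio(n) * r_wire
}

#' Bundle cross-section geometry
#'
#' @param r_wire wire radius (mm)
#' @param n_turns number of wire turns
#' @return object of class \code{bundleGeometry} with fields \code{n_turns},
#'   \code{r_wire}, \code{BW} and the envelope radius \code{r_bundle}
#' @export
bundleGeometry <- function(r_wire, n_turns) {
  bw <- bwRatio(n_turns)
  g <- list(n_turns = n_turns, r_wire = r_wire, BW = bw,
            r_bundle = bw * r_wire)
  class(g) <- "bundleGeometry"
  g
}

#' @export
print.bundleGeometry <- function(x, ...) {
  cat(sprintf("Bundle: %d turns of r = %g mm wire, BW = %.3f, envelope r = %.4f mm\n",
              x$n_turns, x$r_wire, x$BW, x$r_bundle))
  invisible(x)
}

# Contraction/separation polish: radially contract the layout by a decaying
# step, then resolve pairwise overlaps; keeps the best feasible enclosing
# radius seen. Exact (non-smoothed) geometry, so it closes the residual gap
# the penalty formulation leaves.
.packPolish <- function(cx, steps = 1500) {
  n <- nrow(cx)
  bestFeasible <- function(cx) {
    dmat <- as.matrix(stats::dist(cx))
    if (n > 1 && min(dmat[upper.tri(dmat)]) < 2 - 1e-9) return(Inf)
    max(sqrt(rowSums(cx^2))) + 1
  }
  separate <- function(cx) {
    for (sweep in 1:30) {
      dmat <- as.matrix(stats::dist(cx))
      worst <- 2 - min(dmat[upper.tri(dmat)])
      if (worst < 1e-12) break
      for (i in seq_len(n - 1)) for (j in (i + 1):n) {
        d <- dmat[i, j]
        if (d < 2 - 1e-12) {
          dir <- if (d > 1e-9) (cx[j, ] - cx[i, ]) / d else stats::rnorm(2)
          push <- (2 - d) / 2 + 1e-12
          cx[i, ] <- cx[i, ] - dir * push
          cx[j, ] <- cx[j, ] + dir * push
          dmat <- as.matrix(stats::dist(cx))
        }
      }
    }
    cx
  }
  cx <- separate(cx)
  best <- bestFeasible(cx)
  bx <- cx
  step <- 1e-2
  fails <- 0
  for (it in seq_len(steps)) {
    rad <- sqrt(rowSums(cx^2))
    shrink <- pmin(step, rad) / pmax(rad, 1e-12)
    jit <- matrix(stats::rnorm(2 * n, sd = 0.5 * step), n, 2)
    trial <- separate(cx * (1 - shrink) + jit)
    v <- bestFeasible(trial)
    if (v < best - 1e-12) {
      best <- v
      bx <- trial
      cx <- trial
      fails <- 0
    } else {
      cx <- bx
      fails <- fails + 1
      if (fails >= 8) {
        step <- step * 0.6
        fails <- 0
        if (step < 1e-7) break
      }
    }
  }
  best
}

#' Numerically verify a packing ratio
#'
#' Independent cross-check of the embedded packing table: finds the smallest
#' enclosing circle for \code{n} unit circles by multi-start quasi-Newton
#' minimization of the enclosing radius with quadratic penalties on pairwise
#' overlap. Intended for \code{n <= 8}; optimal packings for larger \code{n}
#' are hard targets for a generic optimizer and the table is authoritative.
#'
#' @param n number of circles (2..8)
#' @param tol acceptance tolerance on the ratio (reporting only)
#' @param starts number of random restarts
#' @return best ratio found (attribute \code{converged} reports whether it is
#'   within \code{tol} above the tabulated optimum)
#' @export
verifyPacking <- function(n, tol = 1e-3, starts = 40) {
  if (n < 1 || n > 8) stop("numerical packing verification supports n in 1..8")
  if (n == 1) return(structure(1, converged = TRUE))
  obj <- function(x, w, rho) {
    cx <- matrix(x, ncol = 2)
    rad <- sqrt(rowSums(cx^2))
    dmat <- as.matrix(stats::dist(cx))
    ov <- pmax(0, 2 - dmat[upper.tri(dmat)])
    # soft-max of center radii + overlap penalty
    smax <- log(sum(exp(rho * (rad - max(rad))))) / rho + max(rad)
    smax + w * sum(ov^2)
  }
  best <- Inf
  for (s in seq_len(starts)) {
    # structured starts: k circles on a regular polygon (+ optional center)
    if (s <= 3 && n >= 3) {
      k <- n - (s - 1) %% 2
      th <- 2 * pi * seq_len(k) / k
      r0 <- 1 / sin(pi / k)
      x0 <- rbind(cbind(r0 * cos(th), r0 * sin(th)),
                  matrix(0, n - k, 2))
    } else {
      x0 <- matrix(stats::rnorm(2 * n, sd = 0.8 * n^0.5), ncol = 2)
    }
    x <- as.numeric(x0) + stats::rnorm(2 * n, sd = 0.02)
    sched <- cbind(w = c(50, 5e3), rho = c(60, 300))
    for (k in seq_len(nrow(sched))) {
      op <- stats::optim(x, obj, w = sched[k, 1], rho = sched[k, 2],
                         method = "BFGS",
                         control = list(maxit = 300, reltol = 1e-12))
      x <- op$par
    }
    val <- .packPolish(matrix(x, ncol = 2), steps = 400)
    if (val < best) best <- val
    if (best <= .bwTable[n] + tol) break  # optimum certified by the table
  }
  if (!is.finite(best)) stop("packing optimizer failed to find a feasible layout")
  conv <- best >= .bwTable[n] - tol && best <= .bwTable[n] + tol
  if (!conv) warning(sprintf("best packing ratio %.5f differs from table %.3f",
                             best, .bwTable[n]))
  structure(best, converged = conv)
}
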