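#' Fiber discretization of a circular wire cross section
#'
#' Builds the grid of section integration points ("fibers") used for the
#' elasto-transformational part of the beam response. Points lie on
#' \code{n_rad} concentric rings (the outermost exactly on the wire surface,
#' so peak surface strain is sampled directly) with \code{n_theta} equally
#' spaced angular stations. Ring weights are moment-matched so that the
#' quadrature integrates area, second moment and fourth moment of the section
#' exactly; bending stiffness of a uniform section is therefore exact.
#'
#' @param r_wire wire radius (mm)
#' @param n_theta angular stations (default 8)
#' @param n_rad radial rings (default 3; positions r * c(0.35, 0.75, 1))
#' @return list with fiber offsets \code{y}, \code{z} (mm), weights \code{w}
#'   (mm^2), \code{r_wire}, and section constants \code{A}, \code{I},
#'   \code{J}
#' @export
fiberSection <- function(r_wire, n_theta = 8, n_rad = 3) {
  stopifnot(r_wire > 0, n_theta >= 4, n_rad >= 2)
  rho <- r_wire * switch(as.character(n_rad),
                         "2" = c(0.55, 1),
                         "3" = c(0.35, 0.75, 1),
                         seq(0.3, 1, length.out = n_rad))
  # ring weights W_i with sum_i W_i rho_i^(2j-2) = 2 pi r^(2j) / (2j):
  # exact area, second and fourth section moments
  V <- t(vapply(seq_len(n_rad), function(j) rho^(2 * j - 2), numeric(n_rad)))
  m <- vapply(seq_len(n_rad), function(j) r_wire^(2 * j) / (2 * j), numeric(1))
  Wring <- solve(V, m) * 2 * pi
  if (any(Wring <= 0)) stop("fiber ring weights must be positive; adjust radii")
  th <- 2 * pi * (seq_len(n_theta) - 1) / n_theta  # includes principal axes
  y <- as.numeric(outer(sin(th), rho))
  z <- as.numeric(outer(cos(th), rho))
  w <- rep(Wring / n_theta, each = n_theta)
  list(y = y, z = z, w = w, r_wire = r_wire,
       A = pi * r_wire^2, I = pi * r_wire^4 / 4, J = pi * r_wire^4 / 2)
}
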