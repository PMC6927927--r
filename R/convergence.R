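#' Mesh convergence check for the saddle pull test
#'
#' Runs the pull phase of the saddle test at a series of mesh densities and
#' reports the peak machine force and its relative change between
#' consecutive meshes. Used to confirm independence of the results from the
#' element size.
#'
#' @param config \code{\link{ringConfig}}
#' @param n_elems vector of element counts (multiples of 4)
#' @param saddle \code{\link{saddleConfig}}
#' @param opts \code{\link{solverOptions}}
#' @return data.frame(n_elem, peak_force_N, rel_change)
#' @export
meshConvergence <- function(config, n_elems = c(48, 96),
                            saddle = saddleConfig(n_cycles = 1),
                            opts = solverOptions(tolF = 1e-6, tolM = 1e-4,
                                                 maxit = 60, dulim = 3)) {
  stopifnot(length(n_elems) >= 2)
  peak <- vapply(n_elems, function(ne) {
    fr <- formRing(config, n_elem = ne, opts = opts)
    sr <- runSaddle(fr, saddle, nincr_pull = 16, nincr_cycle = 6,
                    opts = opts)
    max(sr$curve$force_N)
  }, numeric(1))
  data.frame(n_elem = n_elems, peak_force_N = peak,
             rel_change = c(NA, abs(diff(peak)) / peak[-length(peak)]))
}
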