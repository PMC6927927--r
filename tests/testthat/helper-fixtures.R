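# Shared fixtures, built once per test run and cached. Expensive scenario
# runs (deployments, saddle pulls) are reused across test files.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, expr) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, expr, envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

fixtureRings <- function() {
  list(ring1 = ringConfig(0.180, 27.02, 10),
       ring2 = ringConfig(0.160, 33.16, 8),
       ring3 = ringConfig(0.220, 39.25, 14),
       ring4 = ringConfig(0.200, 48.09, 9))
}

# test-scale solver settings; scenOpts engages the damped trust-region
# mode used for contact/plateau-dominated runs
testOpts <- function() solverOptions(tolF = 1e-6, tolM = 1e-4, maxit = 60)
scenOpts <- function() solverOptions(tolF = 1e-6, tolM = 1e-4, maxit = 60,
                                     dulim = 3)

# formed rings at the test mesh
formedRingFx <- function(name, n_elem = 48) {
  cachedFixture(paste0("formed_", name, "_", n_elem),
                formRing(fixtureRings()[[name]], n_elem = n_elem,
                         opts = testOpts()))
}

# full deployment at reduced scale (64 elements, 40 shrink increments);
# used by the deployment properties and the acceptance strain checks
deployedFx <- function(name, n_elem = 64, nincr = 40, cycles = 2) {
  cachedFixture(
    paste0("deploy_", name, "_", n_elem, "_", cycles),
    runDeployment(fixtureRings()[[name]],
                  config = deploymentConfig(n_pulse_cycles = cycles),
                  n_elem = n_elem, nincr_compact = nincr))
}

# saddle pull (pull phase + cycles) at reduced scale
saddleFx <- function(name, prestrain = TRUE, n_elem = 32, cycles = 1) {
  key <- paste0("saddle_", name, "_", prestrain, "_", n_elem, "_", cycles)
  cachedFixture(key, {
    cfg <- fixtureRings()[[name]]
    cfg$include_prestrain <- prestrain
    fr <- formRing(cfg, n_elem = n_elem, opts = scenOpts())
    runSaddle(fr, saddleConfig(n_cycles = cycles),
              nincr_pull = 14, nincr_cycle = 6, opts = scenOpts())
  })
}
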