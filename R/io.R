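# Configuration, fixtures, result serialization.

# Fixture presets: the four ring bundle configurations, the 37 C Nitinol
# parameter set, and the elderly-male aortic wall coefficients.
.presets <- list(
  ring1 = list(d_wire = 0.180, D_ring = 27.02, n_turns = 10),
  ring2 = list(d_wire = 0.160, D_ring = 33.16, n_turns = 8),
  ring3 = list(d_wire = 0.220, D_ring = 39.25, n_turns = 14),
  ring4 = list(d_wire = 0.200, D_ring = 48.09, n_turns = 9),
  nitinol_37C = list(E_A = 59000, nu_A = 0.33, E_M = 26500, nu_M = 0.33,
                     eps_L = 0.05, sigma_LS = 636, sigma_LE = 740,
                     sigma_US = 430, sigma_UE = 302, sigma_CS = 965,
                     density = 6.45),
  aorta_labrosse_67_77 = list(c1 = 0.0048, c2 = 0.0911, c3 = -1.0600,
                              c4 = 9.5292, c5 = -31.7421, c6 = 46.3921,
                              D1 = 0.004593, thickness = 2,
                              density = 1.16e-9)
)

#' Named fixture preset
#'
#' Resolve one of the built-in presets: \code{ring1}..\code{ring4} (the four
#' bundle configurations), \code{nitinol_37C} (wire material at body
#' temperature) or \code{aorta_labrosse_67_77} (vessel wall coefficients).
#'
#' @param name preset name
#' @return named list of parameters
#' @export
presetConfig <- function(name) {
  if (!name %in% names(.presets))
    stop("unknown preset '", name, "'; available: ",
         paste(names(.presets), collapse = ", "))
  .presets[[name]]
}

.allowedKeys <- list(
  ring = c("preset", "d_wire", "D_ring", "n_turns", "include_prestrain"),
  nitinol = c("preset", "E_A", "nu_A", "E_M", "nu_M", "eps_L", "sigma_LS",
              "sigma_LE", "sigma_US", "sigma_UE", "sigma_CS", "density",
              "compression_scale"),
  vessel = c("preset", "c1", "c2", "c3", "c4", "c5", "c6", "D1", "thickness",
             "length_factor", "density"),
  saddle = c("string_stiffness_ref", "crosshead_height", "oversize_high",
             "oversize_low", "overshoot", "n_cycles"),
  deploy = c("catheter_diameter", "inner_tube_diameter", "oversize_pct",
             "P_d", "P_s", "mu_vessel", "mu_sheath", "kpen", "perturb",
             "seed", "n_pulse_cycles", "L_eff"),
  units = c("length", "force", "stress", "stiffness", "pressure")
)
.expectedUnits <- c(length = "mm", force = "N", stress = "MPa",
                    stiffness = "N/mm", pressure = "mmHg")

#' Load and validate a scenario configuration
#'
#' Reads a YAML (or JSON) configuration with blocks \code{ring},
#' \code{nitinol}, \code{vessel}, \code{saddle}, \code{deploy} and an
#' optional \code{units} declaration. Unknown keys are rejected with the
#' offending name; unit declarations that deviate from the fixed mm/N/MPa/
#' mmHg convention are rejected naming the expected unit. Preset names
#' (\code{ring1}..\code{ring4}, \code{nitinol_37C},
#' \code{aorta_labrosse_67_77}) are resolvable in the respective blocks.
#'
#' @param path configuration file
#' @return list with resolved \code{ring} (\code{ringConfig}),
#'   \code{nitinol} (\code{nitinolParams}), \code{vessel} (coefficients
#'   list), \code{saddle} (\code{saddleConfig}), \code{deploy}
#'   (\code{deploymentConfig}) and the raw echo
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
         else yaml::read_yaml(path)
  for (blk in names(raw)) {
    if (!blk %in% names(.allowedKeys))
      stop("unknown configuration block '", blk, "'")
    extra <- setdiff(names(raw[[blk]]), .allowedKeys[[blk]])
    if (length(extra))
      stop("unknown key '", extra[1], "' in block '", blk, "'")
  }
  if (!is.null(raw$units)) {
    for (u in names(raw$units)) {
      if (!identical(raw$units[[u]], .expectedUnits[[u]]))
        stop(sprintf("unit error: '%s' must be %s (got %s)",
                     u, .expectedUnits[[u]], raw$units[[u]]))
    }
  }
  out <- list(echo = raw)
  resolve <- function(blk) {
    b <- raw[[blk]]
    if (!is.null(b$preset)) {
      p <- presetConfig(b$preset)
      b$preset <- NULL
      b <- utils::modifyList(p, b)
    }
    b
  }
  if (!is.null(raw$ring)) {
    b <- resolve("ring")
    out$ring <- do.call(ringConfig, b)
  }
  if (!is.null(raw$nitinol)) {
    b <- resolve("nitinol")
    out$nitinol <- do.call(nitinolParams, b)
  } else {
    out$nitinol <- do.call(nitinolParams, .presets$nitinol_37C)
  }
  if (!is.null(raw$vessel)) {
    b <- resolve("vessel")
    out$vessel <- b
  }
  if (!is.null(raw$saddle)) out$saddle <- do.call(saddleConfig, raw$saddle)
  if (!is.null(raw$deploy)) out$deploy <- do.call(deploymentConfig, raw$deploy)
  out
}

#' Run manifest
#'
#' Records the fully resolved parameters of a run (including every default
#' that filled a gap in the published inputs: catheter and inner-tube bore,
#' penalty stiffness, perturbation seed, vessel-coupling footprint), the
#' package version, the units convention and per-step solver reports.
#'
#' @param config resolved configuration (list)
#' @param seed seed used for the perturbation pattern
#' @param reports solver report data.frame(s)
#' @return list of class \code{runManifest}
#' @export
runManifest <- function(config, seed = NULL, reports = NULL) {
  man <- list(
    package = "ringmech",
    version = as.character(utils::packageVersion("ringmech")),
    units = as.list(.expectedUnits),
    seed = seed,
    config = config,
    reports = reports)
  class(man) <- "runManifest"
  man
}

#' Write scenario results to disk
#'
#' Emits the scalar results and manifest as JSON, curve tables as CSV and
#' (optionally) the deformed geometry as a legacy ASCII VTK polyline.
#' Output is byte-stable for identical configuration and package version.
#'
#' @param result list of scalar results (e.g. a \code{deploymentResult}
#'   stripped of its model) or a \code{saddleResult}
#' @param dir output directory (created if missing)
#' @param name file stem
#' @param manifest optional \code{\link{runManifest}}
#' @param model optional \code{beamModel} for geometry export
#' @return invisibly, the paths written
#' @export
writeResults <- function(result, dir, name = "run", manifest = NULL,
                         model = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  scal <- result
  curves <- list()
  if (inherits(result, "saddleResult")) {
    curves$fd_curve <- result$curve
    scal <- list(peak_force_N = max(result$curve$force_N),
                 bounds_mm = as.list(result$bounds),
                 converged = result$converged)
  } else if (inherits(result, "deploymentResult")) {
    curves$pulse_history <- result$history
    scal <- list(COF_N = result$COF, COF_diast_N = result$COF_diast,
                 COF_syst_N = result$COF_syst,
                 eps_diast = result$eps_diast, eps_syst = result$eps_syst,
                 M_eps = result$M_eps,
                 R_v_mm = as.list(result$R_v))
  }
  jp <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(scal, jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, jp)
  for (cn in names(curves)) {
    cp <- file.path(dir, paste0(name, "_", cn, ".csv"))
    utils::write.csv(curves[[cn]], cp, row.names = FALSE)
    paths <- c(paths, cp)
  }
  if (!is.null(manifest)) {
    mp <- file.path(dir, paste0(name, "_manifest.json"))
    man <- manifest
    man$reports <- NULL  # keep the manifest compact; reports go to CSV
    jsonlite::write_json(man, mp, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE)
    paths <- c(paths, mp)
  }
  if (!is.null(model)) {
    vp <- file.path(dir, paste0(name, ".vtk"))
    writeVTKPolyline(model, vp)
    paths <- c(paths, vp)
  }
  invisible(paths)
}

#' Write a beam model as a legacy ASCII VTK polyline
#'
#' Node positions as points, elements as a polyline cell set, with the
#' per-element surface strain extreme attached as cell data.
#'
#' @param m \code{beamModel}
#' @param path output file (.vtk)
#' @return invisibly, \code{path}
#' @export
writeVTKPolyline <- function(m, path) {
  nb <- m$nbeam
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "ringmech beam geometry", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d double", nb)), con)
  writeLines(apply(m$x[, seq_len(nb), drop = FALSE], 2,
                   function(p) paste(format(p, digits = 10), collapse = " ")),
             con)
  ne <- length(m$el$n1)
  writeLines(sprintf("LINES %d %d", ne, 3 * ne), con)
  writeLines(sprintf("2 %d %d", pmin(m$el$n1, nb) - 1L,
                     pmin(m$el$n2, nb) - 1L), con)
  ss <- surfaceStrains(m)
  writeLines(c(sprintf("CELL_DATA %d", ne),
               "SCALARS surface_strain double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(ss$eps_absmax, digits = 8), con)
  invisible(path)
}
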