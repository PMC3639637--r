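#' Default run configuration
#'
#' A run configuration is a plain nested list (serialised as YAML) with
#' blocks `scenario` (fluid and inflow parametrization), `geometry` (vessel,
#' aneurysm stage, stent), `solver` (type and stopping rule), `analysis`
#' (cutline sampling), `output` and `seed`. All physical quantities carry
#' explicit unit suffixes in their key names. Runs are fully deterministic:
#' two runs from the same configuration produce identical outputs (`seed` is
#' reserved for optional randomized initial perturbations, none by default).
#'
#' @return A named list with all configuration keys at their defaults:
#'   blood at 1060 kg/m^3 and 0.004 Pa.s in a 3 mm vessel with a 50 mm/s
#'   peak parabolic inflow, 30 lattice cells across the width, and a medium
#'   aneurysm without stent.
#' @export
default_config <- function() {
  list(
    scenario = list(
      density_kg_m3 = 1060,
      viscosity_pa_s = 0.004,
      channel_width_mm = 3,
      u_max_mm_s = 50,
      cells_across_width = 30L,
      u_lattice_max = 0.05
    ),
    geometry = list(
      dimensionality = 2L,
      vessel_length_mm = 15,
      stage = "medium",
      stent = FALSE,
      n_struts = 5L,
      strut_diameter_mm = 0.2
    ),
    solver = list(
      type = "lbm",
      tolerance = 1e-6,
      check_interval = 200L,
      max_steps = 200000L
    ),
    analysis = list(n_samples = 101L),
    output = list(dir = NULL),
    seed = NULL
  )
}

#' Scenario presets
#'
#' Named, fully specified configurations: `poiseuille-2d` (straight channel,
#' the analytic validation case), `medium-2d`, `larger-2d`,
#' `larger-2d-stented` (the aneurysm comparison cases) and `medium-3d-small`
#' (a reduced-resolution 3D tube run at the same Reynolds number, sized for
#' a single CPU core).
#'
#' @param name Preset name.
#' @return A run configuration list.
#' @export
preset_config <- function(name = c("poiseuille-2d", "medium-2d", "larger-2d",
                                   "larger-2d-stented", "medium-3d-small")) {
  name <- match.arg(name)
  cfg <- default_config()
  switch(name,
    "poiseuille-2d" = {
      cfg$geometry$stage <- "none"
      cfg$geometry$vessel_length_mm <- 12
    },
    "medium-2d" = {
      cfg$geometry$stage <- "medium"
    },
    "larger-2d" = {
      cfg$geometry$stage <- "larger"
    },
    "larger-2d-stented" = {
      cfg$geometry$stage <- "larger"
      cfg$geometry$stent <- TRUE
    },
    "medium-3d-small" = {
      cfg$geometry$dimensionality <- 3L
      cfg$geometry$stage <- "medium"
      cfg$scenario$cells_across_width <- 16L
      cfg$solver$max_steps <- 60000L
    }
  )
  cfg
}

# Allowed configuration keys per block.
config_schema <- function() {
  lapply(default_config()[c("scenario", "geometry", "solver", "analysis",
                            "output")], names)
}

#' Validate, read and write run configurations
#'
#' `validate_config()` checks block and key names against the schema and
#' basic value sanity, returning the completed configuration (missing keys
#' filled with defaults); unknown keys raise a descriptive error before any
#' computation. `read_run_config()`/`write_run_config()` round-trip the
#' configuration through a YAML file.
#'
#' @param config A configuration list.
#' @param path File path.
#' @return The validated configuration (or the path, invisibly, for the
#'   writer).
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  schema <- config_schema()
  unknown_blocks <- setdiff(names(config), c(names(schema), "seed"))
  if (length(unknown_blocks) > 0) {
    stop("unknown config block(s): ", paste(unknown_blocks, collapse = ", "),
         call. = FALSE)
  }
  full <- default_config()
  for (blk in names(schema)) {
    if (is.null(config[[blk]])) next
    unknown <- setdiff(names(config[[blk]]), schema[[blk]])
    if (length(unknown) > 0) {
      stop(sprintf("unknown key(s) in block '%s': %s", blk,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    full[[blk]][names(config[[blk]])] <- config[[blk]]
  }
  full$seed <- config$seed
  if (!full$solver$type %in% c("lbm", "ns", "both")) {
    stop("solver type must be one of lbm, ns, both", call. = FALSE)
  }
  if (!full$geometry$stage %in% c("none", "medium", "larger")) {
    stop("geometry stage must be one of none, medium, larger", call. = FALSE)
  }
  if (isTRUE(full$geometry$stent) && full$geometry$stage == "none") {
    stop("a stent requires an aneurysm stage", call. = FALSE)
  }
  full
}

#' @rdname validate_config
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

#' @rdname validate_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

# Build the domain objects implied by a validated configuration.
config_objects <- function(config) {
  sc <- config$scenario
  geo <- config$geometry
  fluid <- fluid_properties(sc$density_kg_m3, sc$viscosity_pa_s)
  scenario <- flow_scenario(sc$channel_width_mm * 1e-3, sc$u_max_mm_s * 1e-3,
                            fluid, geo$dimensionality)
  units <- build_unit_system(scenario, sc$cells_across_width, sc$u_lattice_max)
  vessel <- vessel_spec(scenario$D, geo$vessel_length_mm * 1e-3,
                        geo$dimensionality)
  aneurysm <- aneurysm_spec(geo$stage)
  stent <- if (isTRUE(geo$stent)) {
    stent_spec(geo$n_struts, geo$strut_diameter_mm * 1e-3)
  }
  mask <- build_domain(vessel, aneurysm, stent, sc$cells_across_width)
  list(scenario = scenario, units = units, vessel = vessel,
       aneurysm = aneurysm, stent = stent, mask = mask)
}

#' Run a configured scenario
#'
#' Builds the unit system and domain from a configuration, runs the selected
#' solver(s) to steady state, post-processes cutline profiles and the flow
#' summary (or, for the straight-channel case, the analytic Poiseuille
#' error), and optionally writes artifacts: velocity and vorticity fields as
#' legacy VTK, cutline profiles as CSV, the summary as JSON, and the
#' convergence log.
#'
#' @param config A run configuration (see [default_config()],
#'   [preset_config()], [read_run_config()]).
#' @param out_dir Output directory (created if needed); `NULL` (default:
#'   `config$output$dir`) writes nothing.
#' @return An object of class `run_result`: list with `config`, `mask`,
#'   `units`, `fields` (named by solver), `profiles` (per solver, per
#'   cutline), `summaries` (per solver; `flow_summary` for aneurysm domains,
#'   a list with `poiseuille_rel_l2` for the straight channel), `cutlines`.
#' @export
run_scenario <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  if (is.null(out_dir)) out_dir <- config$output$dir
  if (!is.null(config$seed)) set.seed(config$seed)
  obj <- config_objects(config)
  check_watertight(obj$mask)
  solvers <- if (config$solver$type == "both") c("lbm", "ns") else config$solver$type
  if ("ns" %in% solvers && obj$vessel$dimensionality == 3L) {
    stop("unsupported combination: the Navier-Stokes reference solver is 2D-only",
         call. = FALSE)
  }
  crit_lbm <- steady_state_criterion(config$solver$tolerance,
                                     config$solver$check_interval,
                                     config$solver$max_steps)
  fields <- list()
  for (sv in solvers) {
    fields[[sv]] <- if (sv == "lbm") {
      st <- lbm_init(obj$mask, obj$units)
      velocity_field(run_to_steady(st, crit_lbm))
    } else {
      solve_ns(obj$mask, obj$scenario,
               criterion = steady_state_criterion(config$solver$tolerance,
                                                  100L,
                                                  config$solver$max_steps))
    }
  }

  has_sac <- obj$aneurysm$stage != "none"
  cutlines <- if (has_sac) {
    make_cutlines(obj$aneurysm, obj$vessel, config$analysis$n_samples)
  }
  profiles <- list()
  summaries <- list()
  for (sv in solvers) {
    if (has_sac) {
      profiles[[sv]] <- lapply(cutlines, function(cl) {
        sample_cutline(fields[[sv]], cl)
      })
      summaries[[sv]] <- flow_summary(fields[[sv]], cutlines)
    } else {
      summaries[[sv]] <- list(
        poiseuille_rel_l2 = channel_poiseuille_error(fields[[sv]],
                                                     obj$scenario$u_max),
        converged = isTRUE(fields[[sv]]$convergence$converged),
        steps = fields[[sv]]$convergence$steps
      )
    }
  }
  res <- structure(
    list(config = config, mask = obj$mask, units = obj$units, fields = fields,
         profiles = profiles, summaries = summaries, cutlines = cutlines),
    class = "run_result"
  )
  if (!is.null(out_dir)) write_run_artifacts(res, out_dir)
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat(sprintf("<run_result: stage %s%s, solver(s) %s>\n",
              x$config$geometry$stage,
              if (isTRUE(x$config$geometry$stent)) " (stented)" else "",
              paste(names(x$fields), collapse = ", ")))
  for (sv in names(x$summaries)) {
    s <- x$summaries[[sv]]
    if (inherits(s, "flow_summary")) {
      print(s)
    } else {
      cat(sprintf("  [%s] Poiseuille relative L2 error: %.4f (steps %d)\n",
                  sv, s$poiseuille_rel_l2, s$steps))
    }
  }
  invisible(x)
}

#' Analytic Poiseuille validation error of a channel field
#'
#' Relative L2 error of the velocity magnitude against the analytic
#' parabolic profile with the scenario's peak velocity, over the fluid nodes
#' of the column nearest the channel midpoint.
#'
#' @param field A `flow_field` on a straight-channel domain.
#' @param u_max_m_s Peak analytic velocity; default 0.05.
#' @return Relative L2 error (dimensionless).
#' @export
channel_poiseuille_error <- function(field, u_max_m_s = 0.05) {
  stopifnot(inherits(field, "flow_field"))
  mask <- field$mask
  g <- field$grid
  i <- as.integer(round(g$dims[1] / 2))
  fl <- which(mask$class[i, ] != CLS_SOLID)
  y <- g$origin[2] + (fl - 0.5) * g$dx
  ana <- u_max_m_s * pmax(1 - (2 * y / mask$vessel$D - 1)^2, 0)
  num <- velocity_magnitude(field)[cbind(i, fl)]
  sqrt(sum((num - ana)^2) / sum(ana^2))
}

#' Run both solvers and compare cutline profiles
#'
#' Executes the scenario with `solver: both` and reports, per cutline, the
#' relative L2 and maximum pointwise difference between the lattice
#' Boltzmann and Navier-Stokes velocity profiles, alongside both summaries.
#'
#' @param config A run configuration; its solver type is overridden to
#'   `both`.
#' @param out_dir Optional output directory.
#' @return List with `comparison` (per-cutline metric list), `result` (the
#'   underlying `run_result`).
#' @export
run_comparison <- function(config, out_dir = NULL) {
  config <- validate_config(config)
  config$solver$type <- "both"
  res <- run_scenario(config, out_dir)
  comparison <- NULL
  if (length(res$profiles) == 2L) {
    comparison <- lapply(names(res$cutlines), function(nm) {
      compare_profiles(res$profiles$lbm[[nm]], res$profiles$ns[[nm]])
    })
    names(comparison) <- names(res$cutlines)
  }
  list(comparison = comparison, result = res)
}

# ---- artifact writers ------------------------------------------------------

#' Export run artifacts
#'
#' `write_profiles_csv()` writes cutline profiles in long form (columns
#' `position_mm`, `velocity_mm_s`, `solver`, `cutline`; comma separated,
#' header row, '.' decimal). `write_summary_json()` writes the summaries;
#' `write_vtk_field()` writes velocity (vectors), speed and, in 2D,
#' vorticity as legacy ASCII VTK structured points. `write_run_artifacts()`
#' writes all of them plus the configuration and convergence log into a
#' directory.
#'
#' @param profiles List of `cutline_profile`s.
#' @param path,dir Output file / directory.
#' @param summaries Named list of summaries.
#' @param field A `flow_field`.
#' @param result A `run_result`.
#' @return The written path, invisibly.
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, as.data.frame))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
write_summary_json <- function(summaries, path) {
  jsonlite::write_json(lapply(summaries, unclass), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
write_vtk_field <- function(field, path) {
  stopifnot(inherits(field, "flow_field"))
  g <- field$grid
  d <- length(g$dims)
  dims3 <- c(g$dims, rep(1L, 3 - d))
  org3 <- c(g$origin + g$dx / 2, rep(0, 3 - d))
  n <- prod(dims3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("aneuflow %s velocity field", field$solver),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", dims3[1], dims3[2], dims3[3]),
               sprintf("ORIGIN %g %g %g", org3[1], org3[2], org3[3]),
               sprintf("SPACING %g %g %g", g$dx, g$dx, g$dx),
               sprintf("POINT_DATA %d", n),
               "VECTORS velocity double"), con)
  comp <- vapply(seq_len(d), function(k) c(slice_component(field$u, k, d)),
                 numeric(n))
  vec <- cbind(comp, matrix(0, n, 3 - d))
  writeLines(sprintf("%g %g %g", vec[, 1], vec[, 2], vec[, 3]), con)
  writeLines(c("SCALARS speed double 1", "LOOKUP_TABLE default"), con)
  writeLines(sprintf("%g", c(velocity_magnitude(field))), con)
  if (d == 2L) {
    writeLines(c("SCALARS vorticity double 1", "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%g", c(vorticity_2d(field))), con)
  }
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
write_run_artifacts <- function(result, dir) {
  stopifnot(inherits(result, "run_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_run_config(result$config, file.path(dir, "config.yaml"))
  for (sv in names(result$fields)) {
    write_vtk_field(result$fields[[sv]], file.path(dir, paste0("field_", sv, ".vtk")))
    conv <- result$fields[[sv]]$convergence
    if (!is.null(conv)) {
      utils::write.csv(conv$history,
                       file.path(dir, paste0("convergence_", sv, ".csv")),
                       row.names = FALSE, quote = FALSE)
    }
  }
  if (length(result$profiles) > 0) {
    all_profiles <- unlist(result$profiles, recursive = FALSE)
    write_profiles_csv(all_profiles, file.path(dir, "profiles.csv"))
  }
  write_summary_json(result$summaries, file.path(dir, "summary.json"))
  invisible(dir)
}
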