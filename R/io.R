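# File formats: legacy ASCII VTK for meshes and per-cell fields, CSV for
# maps, trajectories and metrics, JSON run manifests.  All cell indices in
# files are 0-based.

#' Export a surface mesh to legacy VTK
#'
#' Writes the quadrilateral domains as VTK POLYDATA with optional per-domain
#' CELL_DATA scalar fields (the region label is always included as an
#' integer code).
#'
#' @param mesh A `surface_mesh`.
#' @param path Output `.vtk` path.
#' @param cell_data Optional named list of per-domain numeric vectors.
#' @return `path`, invisibly.
#' @export
write_mesh_vtk <- function(mesh, path, cell_data = NULL) {
  v <- mesh$vertices
  d <- mesh$domains
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "bifurcation surface mesh", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(v))), con)
  writeLines(sprintf("%.9g %.9g %.9g", v$x, v$y, v$z), con)
  writeLines(sprintf("POLYGONS %d %d", nrow(d), 5 * nrow(d)), con)
  writeLines(sprintf("4 %d %d %d %d", d$v00 - 1L, d$v10 - 1L,
                     d$v11 - 1L, d$v01 - 1L), con)
  region_code <- match(d$region, c("uniform", "apex", "lateral_seam",
                                   "outer_wall", "inner_wall")) - 1L
  fields <- c(list(region = region_code), cell_data)
  writeLines(sprintf("CELL_DATA %d", nrow(d)), con)
  for (nm in names(fields)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(sprintf("%.9g", fields[[nm]]), con)
  }
  invisible(path)
}

#' Export per-cell values to legacy VTK points
#'
#' Writes the cell centers of a lattice as VTK points with per-point scalar
#' fields, e.g. an ATP map or a time-averaged calcium field.
#'
#' @param lattice A `cell_lattice`.
#' @param path Output `.vtk` path.
#' @param values Named list of per-cell vectors (over all cells, ECs first).
#' @param type Optional filter: `"ec"` or `"smc"`.
#' @return `path`, invisibly.
#' @export
write_cells_vtk <- function(lattice, path, values = list(), type = NULL) {
  cells <- lattice$cells
  keep <- if (is.null(type)) rep(TRUE, nrow(cells)) else cells$cell_type == type
  cc <- cells[keep, ]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "cell lattice", "ASCII",
               "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(cc))), con)
  writeLines(sprintf("%.9g %.9g %.9g", cc$x, cc$y, cc$z), con)
  writeLines(sprintf("VERTICES %d %d", nrow(cc), 2 * nrow(cc)), con)
  writeLines(sprintf("1 %d", seq_len(nrow(cc)) - 1L), con)
  if (length(values)) {
    writeLines(sprintf("POINT_DATA %d", nrow(cc)), con)
    for (nm in names(values)) {
      val <- values[[nm]][keep]
      writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
      writeLines(sprintf("%.9g", val), con)
    }
  }
  invisible(path)
}

#' Write the unwrapped 2D cell map to CSV
#'
#' Columns: `cell_id` (0-based), `type`, `u`, `v`, `region`.
#'
#' @param lattice A `cell_lattice`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_unwrapped_csv <- function(lattice, path) {
  m <- unwrap_mesh(lattice)
  out <- tibble(cell_id = m$cell_id - 1L, type = m$type,
                u = m$u, v = m$v, region = m$region)
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a recorded trajectory to CSV (long format)
#'
#' One row per (time, cell, species).  A JSON manifest with the
#' configuration, network hash and cell metadata is written alongside as
#' `<path>.manifest.json`.
#'
#' @param record A `sim_record`.
#' @param path Output CSV path.
#' @param species Species to write (default all recorded fields).
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path,
                             species = NULL) {
  long <- tidy(record, species = species)
  readr::write_csv(long, path)
  manifest <- list(
    config = unclass(record$config),
    network_hash = record$network_hash,
    n_ec = record$n_ec, n_smc = record$n_smc,
    species = unique(long$species),
    cells = list(cell_id = record$cells$cell_id - 1L,
                 cell_type = record$cells$cell_type,
                 type_index = record$cells$type_index,
                 region = record$cells$region,
                 u = record$cells$u, v = record$cells$v))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a recorded trajectory written by [write_record_csv()]
#'
#' @param path CSV path (its `.manifest.json` sidecar must exist).
#' @return A `sim_record` containing the stored species.
#' @export
read_record_csv <- function(path) {
  man_path <- paste0(path, ".manifest.json")
  if (!file.exists(path)) abort(sprintf("record file not found: %s", path))
  if (!file.exists(man_path)) abort(sprintf("manifest not found: %s", man_path))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  long <- readr::read_csv(path, show_col_types = FALSE)
  times <- sort(unique(long$time))
  blocks <- function(tp, n) {
    sub <- long[long$type == tp, ]
    sp <- unique(sub$species)
    setNames(lapply(sp, function(s) {
      ss <- sub[sub$species == s, ]
      m <- matrix(NA_real_, nrow = length(times), ncol = n)
      m[cbind(match(ss$time, times), ss$index)] <- ss$value
      m
    }), sp)
  }
  cells <- as_tibble(man$cells)
  cells$cell_id <- cells$cell_id + 1L
  cfg <- man$config
  config <- simulation_config(
    duration = cfg$duration, record_interval = cfg$record_interval,
    exchange_interval = cfg$exchange_interval, rtol = cfg$rtol,
    atol = cfg$atol, seed = cfg$seed, perturbation = cfg$perturbation,
    mode = cfg$mode)
  structure(
    list(times = times,
         ec = blocks("ec", man$n_ec), smc = blocks("smc", man$n_smc),
         n_ec = man$n_ec, n_smc = man$n_smc,
         cells = cells, config = config,
         network_hash = man$network_hash, final_state = NULL),
    class = "sim_record")
}

#' Load the packaged reference parameter set
#'
#' Reads the versioned YAML parameter file shipped with the package and
#' returns the four constructed parameter objects.  Any overrides must name
#' existing keys; unknown keys are errors.
#'
#' @param path YAML file; defaults to the packaged reference set.
#' @return List with `ip3`, `ec`, `smc`, `coupling`, `phospho` parameter
#'   objects and the file's `version`.
#' @export
reference_params <- function(path = system.file("extdata",
                                                "reference_params.yaml",
                                                package = "bifwave")) {
  if (!file.exists(path)) abort(sprintf("parameter file not found: %s", path))
  y <- yaml::read_yaml(path)
  need <- c("version", "ip3", "ec", "smc", "coupling", "phospho")
  miss <- setdiff(need, names(y))
  if (length(miss)) abort(paste("parameter file lacks sections:",
                                paste(miss, collapse = ", ")))
  check_keys <- function(vals, ref, section) {
    bad <- setdiff(names(vals), names(ref))
    if (length(bad)) {
      abort(sprintf("unknown %s parameter(s): %s", section,
                    paste(bad, collapse = ", ")))
    }
  }
  check_keys(y$ip3, formals(ip3_params), "ip3")
  check_keys(y$phospho, formals(phospho_params), "phospho")
  check_keys(y$coupling, formals(coupling_params), "coupling")
  check_keys(y$ec, ec_params(), "ec")
  check_keys(y$smc, smc_params(), "smc")
  list(version = y$version,
       ip3 = do.call(ip3_params, y$ip3),
       ec = do.call(ec_params, y$ec),
       smc = do.call(smc_params, y$smc),
       coupling = do.call(coupling_params, y$coupling),
       phospho = do.call(phospho_params, y$phospho))
}

#' Read a run configuration file
#'
#' YAML key/value configuration with explicit unit suffixes
#' (`duration_s`, `record_interval_s`, `exchange_interval_s`, `rtol`,
#' `atol`, `seed`, `perturbation`, `mode`).  Unknown keys are errors, so
#' typos cannot silently corrupt a physiology run.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  known <- c(duration_s = "duration", record_interval_s = "record_interval",
             exchange_interval_s = "exchange_interval", rtol = "rtol",
             atol = "atol", seed = "seed", perturbation = "perturbation",
             mode = "mode")
  bad <- setdiff(names(y), names(known))
  if (length(bad)) {
    abort(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")))
  }
  args <- setNames(y, known[names(y)])
  do.call(simulation_config, args)
}
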