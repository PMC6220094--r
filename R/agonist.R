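# Luminal ATP concentration maps over the EC layer: a parametric surrogate
# for advection-dominated transport over a bifurcation (high at the apex, low
# over the lateral seams, near-uniform elsewhere) or an imported per-cell
# field.

#' Parameters of the parametric ATP surrogate
#'
#' The surrogate field is `background + apex bump - seam wells`, built from
#' Gaussian kernels around the flow divider and the two lateral seams, then
#' clipped to `[seam, apex]`.  The seam well width shrinks with the
#' bifurcation angle, so the low-concentration seam area is strictly
#' decreasing in angle.
#'
#' @param apex Peak concentration at the bifurcation apex (uM).
#' @param seam Floor concentration at the lateral seams (uM).
#' @param background Concentration far from the junction (uM).
#' @param apex_sigma Gaussian width of the apex bump (mm).
#' @param seam_sigma Gaussian width of the seam wells at the reference
#'   angle (mm).
#' @param angle_ref Reference angle (degrees) at which `seam_sigma` applies;
#'   the effective width is `seam_sigma * angle_ref / angle`.
#' @return A list of class `agonist_params`.
#' @export
agonist_params <- function(apex = 1.0, seam = 0.2, background = 0.5,
                           apex_sigma = 1.2, seam_sigma = 1.8,
                           angle_ref = 50) {
  vals <- c(apex = apex, seam = seam, background = background)
  if (any(!is.finite(vals)) || any(vals < 0.2 - 1e-12) || any(vals > 1.0 + 1e-12)) {
    abort("ATP levels must lie within the physiological range [0.2, 1.0] uM")
  }
  if (seam > background || background > apex) {
    abort("require seam <= background <= apex")
  }
  if (apex_sigma <= 0 || seam_sigma <= 0) abort("kernel widths must be positive")
  structure(list(apex = apex, seam = seam, background = background,
                 apex_sigma = apex_sigma, seam_sigma = seam_sigma,
                 angle_ref = angle_ref),
            class = "agonist_params")
}

#' Synthesize a per-EC ATP concentration map
#'
#' Evaluates the parametric surrogate on every EC of a lattice.  The apex
#' bump is centred on the flow divider (the mean position of apex-labelled
#' domains) and the seam wells on the two lateral seam bands; distances are
#' Euclidean in 3D.  On meshes without apex/seam regions (plain tubes) the
#' field is the uniform background.
#'
#' @param lattice A [build_cell_lattice()] result.
#' @param params An [agonist_params()] list.
#' @param angle_deg Bifurcation angle used for the seam-width scaling;
#'   defaults to the mesh's own angle.
#' @return A tibble of class `agonist_map` with `cell_id`, `type_index` and
#'   `atp` (uM) for every EC.
#' @export
synthesize_atp_map <- function(lattice, params = agonist_params(),
                               angle_deg = NULL) {
  if (!inherits(lattice, "cell_lattice")) abort("`lattice` must be a cell_lattice")
  if (!inherits(params, "agonist_params")) abort("`params` must be agonist_params")
  if (is.null(angle_deg)) angle_deg <- lattice$mesh$spec$angle_deg
  ec <- lattice$cells[lattice$cells$cell_type == "ec", ]
  doms <- lattice$mesh$domains
  atp <- rep(params$background, nrow(ec))

  anchor <- function(region) {
    d <- doms[doms$region == region, c("cx", "cy", "cz")]
    if (nrow(d) == 0) return(NULL)
    d
  }
  gauss_min_dist <- function(pts, anchors) {
    # distance from each point to the nearest anchor center
    d2 <- outer(pts$x, anchors$cx, "-")^2 +
      outer(pts$y, anchors$cy, "-")^2 +
      outer(pts$z, anchors$cz, "-")^2
    sqrt(apply(d2, 1, min))
  }
  apex_a <- anchor("apex"); seam_a <- anchor("lateral_seam")
  if (!is.null(apex_a) && !is.null(seam_a) && !is.na(angle_deg)) {
    s_seam <- params$seam_sigma * params$angle_ref / angle_deg
    d_apex <- gauss_min_dist(ec, apex_a)
    d_seam <- gauss_min_dist(ec, seam_a)
    atp <- params$background +
      (params$apex - params$background) * exp(-d_apex^2 / (2 * params$apex_sigma^2)) -
      (params$background - params$seam) * exp(-d_seam^2 / (2 * s_seam^2))
    atp <- pmin(pmax(atp, params$seam), params$apex)
  }
  out <- tibble(cell_id = ec$cell_id, type_index = ec$type_index, atp = atp)
  structure(out, class = c("agonist_map", class(out)),
            source = "parametric", params = params)
}

#' Uniform ATP map
#'
#' Convenience constructor for a spatially constant agonist field, used for
#' the apex-regime and seam-regime patch experiments.
#'
#' @param lattice A `cell_lattice`.
#' @param level ATP concentration (uM) applied to every EC.
#' @return An `agonist_map` tibble.
#' @export
uniform_atp_map <- function(lattice, level) {
  if (!is.finite(level) || level < 0) abort("`level` must be finite and >= 0")
  ec <- lattice$cells[lattice$cells$cell_type == "ec", ]
  out <- tibble(cell_id = ec$cell_id, type_index = ec$type_index,
                atp = rep(level, nrow(ec)))
  structure(out, class = c("agonist_map", class(out)),
            source = "parametric", params = NULL)
}

#' Read an ATP map from a per-cell CSV file
#'
#' The file must have columns `cell_id` and `atp_uM`, one row per EC of the
#' lattice (0-based cell ids as written by [write_atp_map()]).
#'
#' @param path CSV file path.
#' @param lattice The `cell_lattice` the map belongs to.
#' @return An `agonist_map` tibble.
#' @export
load_atp_map <- function(path, lattice) {
  if (!file.exists(path)) abort(sprintf("ATP map file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("cell_id", "atp_uM") %in% names(df))) {
    abort("ATP map must have columns `cell_id` and `atp_uM`")
  }
  ec <- lattice$cells[lattice$cells$cell_type == "ec", ]
  if (nrow(df) != nrow(ec)) {
    abort(sprintf("ATP map has %d rows but the lattice has %d ECs",
                  nrow(df), nrow(ec)))
  }
  df <- df[order(df$cell_id), ]
  bad <- which(!is.finite(df$atp_uM) | df$atp_uM < 0)
  if (length(bad) > 0) {
    abort(sprintf("non-finite or negative ATP at cell_id %s",
                  paste(df$cell_id[head(bad, 5)], collapse = ", ")))
  }
  out <- tibble(cell_id = ec$cell_id, type_index = ec$type_index,
                atp = df$atp_uM)
  structure(out, class = c("agonist_map", class(out)),
            source = "imported", params = NULL)
}

#' Write an ATP map to CSV
#'
#' @param map An `agonist_map`.
#' @param path Output CSV path.  Cell ids are written 0-based.
#' @return `path`, invisibly.
#' @export
write_atp_map <- function(map, path) {
  readr::write_csv(tibble(cell_id = map$cell_id - 1L, atp_uM = map$atp), path)
  invisible(path)
}
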