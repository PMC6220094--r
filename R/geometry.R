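# Parametric bifurcating arterial surface meshes, quadrilateral domain grids,
# and the EC/SMC cell lattices that live on them.

# Cells per quadrilateral domain.  ECs are axially elongated (13 rows of 16
# around the circumference), SMCs circumferentially elongated (4 rows of 20),
# so one domain always carries 208 + 80 = 288 cells.
EC_GRID  <- c(axial = 13L, circ = 16L)
SMC_GRID <- c(axial = 4L,  circ = 20L)

#' Parent radius from Murray's law
#'
#' At an arterial bifurcation the parent and daughter radii satisfy
#' \eqn{r_p^3 = r_{d1}^3 + r_{d2}^3}.  Given the daughter radii this returns
#' the parent radius.
#'
#' @param r_d1,r_d2 Daughter branch radii (mm).  Non-negative, not both zero.
#' @return Parent radius (mm).
#' @examples
#' murray_parent_radius(1, 1)   # 2^(1/3)
#' @export
murray_parent_radius <- function(r_d1, r_d2) {
  if (any(r_d1 < 0) || any(r_d2 < 0)) {
    abort("daughter radii must be non-negative")
  }
  if (any(r_d1 == 0 & r_d2 == 0)) {
    abort("at least one daughter radius must be positive")
  }
  (r_d1^3 + r_d2^3)^(1 / 3)
}

#' Specify a bifurcation geometry
#'
#' Describes a three-segment bifurcating arterial surface: a parent tube that
#' splits into two daughter tubes separated by `angle_deg`, with radii tied by
#' Murray's law.  By default the daughters are symmetric and the parent
#' diameter is 2.5 mm with a total model length of 18 mm (6 mm per segment).
#'
#' @param angle_deg Angle between the daughter branch axes, in degrees
#'   (exclusive range 0--180).  Physiological reference values are 50, 80
#'   and 110 degrees.
#' @param diameter Parent vessel diameter (mm).
#' @param segment_length Length of each of the three tubular segments (mm).
#' @param daughter_ratio Ratio `r_d2 / r_d1`; 1 gives symmetric daughters.
#' @param curvature Out-of-plane bend of the centerlines (1/mm); 0 gives a
#'   planar bifurcation.
#' @return An object of class `bifurcation_spec`.
#' @export
bifurcation_spec <- function(angle_deg, diameter = 2.5, segment_length = 6,
                             daughter_ratio = 1, curvature = 0) {
  if (!is.numeric(angle_deg) || angle_deg <= 0 || angle_deg >= 180) {
    abort("`angle_deg` must lie strictly between 0 and 180 degrees")
  }
  if (diameter <= 0 || segment_length <= 0 || daughter_ratio <= 0) {
    abort("`diameter`, `segment_length` and `daughter_ratio` must be positive")
  }
  r_parent <- diameter / 2
  # invert Murray's law for the daughters at the requested asymmetry
  r_d1 <- r_parent / (1 + daughter_ratio^3)^(1 / 3)
  r_d2 <- r_d1 * daughter_ratio
  spec <- structure(
    list(angle_deg = angle_deg, r_parent = r_parent, r_d1 = r_d1, r_d2 = r_d2,
         segment_length = segment_length, total_length = 3 * segment_length,
         diameter = diameter, curvature = curvature),
    class = "bifurcation_spec")
  stopifnot(abs(r_parent^3 - r_d1^3 - r_d2^3) / r_parent^3 < 1e-9)
  spec
}

#' @export
print.bifurcation_spec <- function(x, ...) {
  cat(sprintf(
    "<bifurcation_spec> angle %g deg, r_p %.4g mm, r_d %.4g/%.4g mm, %g mm/segment%s\n",
    x$angle_deg, x$r_parent, x$r_d1, x$r_d2, x$segment_length,
    if (x$curvature > 0) sprintf(", curvature %g/mm", x$curvature) else ""))
  invisible(x)
}

# ring basis vectors for a daughter branch blending away from the parent axis.
# h in [0,1] is the blend fraction; d is the daughter axis direction.
.blend_normal <- function(h, d) {
  n <- cbind((1 - h) * 0 + h * d[1], 0, (1 - h) * 1 + h * d[3])
  n / sqrt(rowSums(n^2))
}

.segment_vertices <- function(segment, spec, n_ax, n_circ, blend_frac = 0.35) {
  L <- spec$segment_length
  phi <- 2 * pi * (seq_len(n_circ) - 1) / n_circ
  rings <- 0:n_ax
  if (segment == "parent") {
    s <- L * rings / n_ax
    ctr <- cbind(0, 0, s - L)
    r <- rep(spec$r_parent, length(s))
    e1 <- matrix(rep(c(1, 0, 0), length(s)), ncol = 3, byrow = TRUE)
    n <- matrix(rep(c(0, 0, 1), length(s)), ncol = 3, byrow = TRUE)
    path <- s
  } else {
    sgn <- if (segment == "daughter1") 1 else -1
    r_d <- if (segment == "daughter1") spec$r_d1 else spec$r_d2
    half <- spec$angle_deg / 2 * pi / 180
    d <- c(sgn * sin(half), 0, cos(half))
    s <- L * rings / n_ax
    u <- pmin(s / (blend_frac * L), 1)
    h <- u^2 * (3 - 2 * u)                       # smoothstep blend
    r <- spec$r_parent + (r_d - spec$r_parent) * h
    n <- .blend_normal(h, d)
    e1 <- cbind(n[, 3], 0, -n[, 1])              # e_y x n, unit as n is unit in xz
    ctr <- cbind(s * d[1], s * d[2], s * d[3])
    path <- spec$segment_length + s
  }
  # expand rings x circumferential positions
  ring_id <- rep(rings, each = n_circ)
  pos_id <- rep(seq_len(n_circ) - 1L, times = length(rings))
  cphi <- cos(rep(phi, times = length(rings)))
  sphi <- sin(rep(phi, times = length(rings)))
  ri <- rep(r, each = n_circ)
  x <- rep(ctr[, 1], each = n_circ) + ri * (cphi * rep(e1[, 1], each = n_circ))
  y <- rep(ctr[, 2], each = n_circ) + ri * sphi   # e2 = e_y everywhere
  z <- rep(ctr[, 3], each = n_circ) + ri * (cphi * rep(e1[, 3], each = n_circ))
  tibble(segment = segment, ring = ring_id, pos = pos_id,
         x = x, y = y, z = z, path = rep(path, each = n_circ))
}

.quad_area <- function(p1, p2, p3, p4) {
  # area of quad split into two triangles (vertices as nx3 matrices)
  tri <- function(a, b, c) {
    u <- b - a; v <- c - a
    cx <- u[, 2] * v[, 3] - u[, 3] * v[, 2]
    cy <- u[, 3] * v[, 1] - u[, 1] * v[, 3]
    cz <- u[, 1] * v[, 2] - u[, 2] * v[, 1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  tri(p1, p2, p3) + tri(p1, p3, p4)
}

.ang_dist <- function(a, b) {
  d <- abs((a - b) %% (2 * pi))
  pmin(d, 2 * pi - d)
}

#' Build a bifurcating arterial surface mesh
#'
#' Constructs the three tubular quadrilateral-domain surface grids (parent and
#' two daughters) for a [bifurcation_spec()].  The daughters emanate from the
#' parent's distal ring, whose vertices they share exactly, and their cross
#' sections blend from the parent radius to the Murray-law daughter radius.
#' Each segment's domain grid is periodic in the circumferential direction.
#' Domains are labelled by region: `apex` (around the flow divider),
#' `lateral_seam` (bands flanking the bifurcation plane near the junction),
#' `outer_wall`, `inner_wall` and `uniform`.
#'
#' @param spec A [bifurcation_spec()].
#' @param domains_axial,domains_circ Domain grid resolution per segment
#'   (axial count per segment, circumferential count).  Minimum 2 x 4.
#' @param apex_extent Axial extent of the apex band from the junction (mm).
#' @param apex_halfwidth_deg Circumferential half-width of the apex band
#'   around the inner (divider-facing) direction, degrees.
#' @param seam_extent Axial extent of the lateral-seam bands from the
#'   junction (mm).
#' @param seam_halfwidth_deg Circumferential half-width of the seam bands
#'   around the out-of-plane directions, degrees.
#' @return An object of class `surface_mesh` with `vertices` and `domains`
#'   tibbles.
#' @export
build_bifurcation_mesh <- function(spec, domains_axial = 4, domains_circ = 8,
                                   apex_extent = 1.5, apex_halfwidth_deg = 60,
                                   seam_extent = 2.5, seam_halfwidth_deg = 40) {
  if (!inherits(spec, "bifurcation_spec")) abort("`spec` must be a bifurcation_spec")
  if (domains_axial < 2 || domains_circ < 4) {
    abort("resolution too coarse: need at least 2 axial x 4 circumferential domains per segment")
  }
  segs <- c("parent", "daughter1", "daughter2")
  verts <- dplyr::bind_rows(lapply(
    segs, .segment_vertices, spec = spec,
    n_ax = domains_axial, n_circ = domains_circ))
  # out-of-plane bend: rigid per-ring translation in y along the path coordinate
  if (spec$curvature > 0) {
    k <- spec$curvature
    verts$y <- verts$y + (1 - cos(k * verts$path)) / k
  }
  verts$vertex_id <- seq_len(nrow(verts))

  # domain table: for segment seg, domain (a, c) has corners rings (a-1, a),
  # positions (c-1, c mod n_circ)
  nC <- domains_circ
  dom <- tidyr::expand_grid(segment = segs,
                            ax = seq_len(domains_axial),
                            circ = seq_len(nC))
  vid <- function(seg, ring, pos) {
    off <- (match(seg, segs) - 1) * (domains_axial + 1) * nC
    off + ring * nC + (pos %% nC) + 1L
  }
  dom$v00 <- vid(dom$segment, dom$ax - 1L, dom$circ - 1L)
  dom$v10 <- vid(dom$segment, dom$ax,      dom$circ - 1L)
  dom$v11 <- vid(dom$segment, dom$ax,      dom$circ)
  dom$v01 <- vid(dom$segment, dom$ax - 1L, dom$circ)
  vm <- as.matrix(verts[, c("x", "y", "z")])
  dom$area <- .quad_area(vm[dom$v00, , drop = FALSE], vm[dom$v10, , drop = FALSE],
                         vm[dom$v11, , drop = FALSE], vm[dom$v01, , drop = FALSE])
  ctr <- (vm[dom$v00, , drop = FALSE] + vm[dom$v10, , drop = FALSE] +
          vm[dom$v11, , drop = FALSE] + vm[dom$v01, , drop = FALSE]) / 4
  dom$cx <- ctr[, 1]; dom$cy <- ctr[, 2]; dom$cz <- ctr[, 3]

  # region labels from the unbent parametric coordinates
  L <- spec$segment_length
  phi_c <- 2 * pi * (dom$circ - 0.5) / nC
  s_c <- L * (dom$ax - 0.5) / domains_axial          # axial center within segment
  dist_junction <- ifelse(dom$segment == "parent", L - s_c, s_c)
  phi_inner <- ifelse(dom$segment == "daughter1", pi, 0)   # side facing the divider
  aw <- apex_halfwidth_deg * pi / 180
  sw <- seam_halfwidth_deg * pi / 180
  is_daughter <- dom$segment != "parent"
  region <- rep("uniform", nrow(dom))
  d_seam <- pmin(.ang_dist(phi_c, pi / 2), .ang_dist(phi_c, 3 * pi / 2))
  region[dist_junction <= seam_extent & d_seam <= sw] <- "lateral_seam"
  region[is_daughter & dist_junction <= seam_extent &
           .ang_dist(phi_c, ifelse(dom$segment == "daughter1", 0, pi)) <= pi / 4 &
           region == "uniform"] <- "outer_wall"
  region[is_daughter & s_c > apex_extent & .ang_dist(phi_c, phi_inner) <= pi / 4 &
           region == "uniform"] <- "inner_wall"
  region[is_daughter & s_c <= apex_extent & .ang_dist(phi_c, phi_inner) <= aw] <- "apex"
  dom$region <- region

  # unwrapped planar coordinates of domain centers: u along the nominal
  # circumference of the segment, v along the centerline path
  r_nom <- c(parent = spec$r_parent, daughter1 = spec$r_d1, daughter2 = spec$r_d2)
  dom$u <- phi_c * r_nom[dom$segment]
  dom$v <- ifelse(dom$segment == "parent", s_c, L + s_c)
  dom$domain_id <- seq_len(nrow(dom))

  structure(
    list(spec = spec, vertices = verts,
         domains = as_tibble(dom),
         domain_grid_shape = c(axial = as.integer(domains_axial),
                               circ = as.integer(domains_circ)),
         segments = segs),
    class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d segments, %d domains (%d x %d per segment), %d vertices\n",
              length(x$segments), nrow(x$domains),
              x$domain_grid_shape[["axial"]], x$domain_grid_shape[["circ"]],
              nrow(x$vertices)))
  print(table(x$domains$region))
  invisible(x)
}

# single straight tube mesh (one segment); used by fixtures and small patches
build_tube_mesh <- function(radius = 1.25, length = 6,
                            domains_axial = 1, domains_circ = 1) {
  spec <- structure(
    list(angle_deg = NA_real_, r_parent = radius, r_d1 = NA_real_,
         r_d2 = NA_real_, segment_length = length, total_length = length,
         diameter = 2 * radius, curvature = 0),
    class = "bifurcation_spec")
  n_circ <- max(domains_circ, 1L)
  verts <- .segment_vertices("parent", spec, domains_axial, max(n_circ, 4L))
  # with fewer than 4 circumferential domains we still mesh vertices at 4+
  nC <- max(n_circ, 4L)
  verts$vertex_id <- seq_len(nrow(verts))
  dom <- tidyr::expand_grid(segment = "parent",
                            ax = seq_len(domains_axial), circ = seq_len(n_circ))
  step <- nC / n_circ
  vid <- function(ring, pos) ring * nC + ((pos * step) %% nC) + 1L
  dom$v00 <- vid(dom$ax - 1L, dom$circ - 1L)
  dom$v10 <- vid(dom$ax,      dom$circ - 1L)
  dom$v11 <- vid(dom$ax,      dom$circ)
  dom$v01 <- vid(dom$ax - 1L, dom$circ)
  vm <- as.matrix(verts[, c("x", "y", "z")])
  dom$area <- .quad_area(vm[dom$v00, , drop = FALSE], vm[dom$v10, , drop = FALSE],
                         vm[dom$v11, , drop = FALSE], vm[dom$v01, , drop = FALSE]) *
    (nC / n_circ)  # each logical domain spans nC/n_circ meshed quads
  ctr <- (vm[dom$v00, , drop = FALSE] + vm[dom$v10, , drop = FALSE] +
          vm[dom$v11, , drop = FALSE] + vm[dom$v01, , drop = FALSE]) / 4
  dom$cx <- ctr[, 1]; dom$cy <- ctr[, 2]; dom$cz <- ctr[, 3]
  dom$region <- "uniform"
  phi_c <- 2 * pi * (dom$circ - 0.5) / n_circ
  dom$u <- phi_c * radius
  dom$v <- length * (dom$ax - 0.5) / domains_axial
  dom$domain_id <- seq_len(nrow(dom))
  structure(
    list(spec = spec, vertices = verts, domains = as_tibble(dom),
         domain_grid_shape = c(axial = as.integer(domains_axial),
                               circ = as.integer(n_circ)),
         segments = "parent"),
    class = "surface_mesh")
}

# index matrix for a segment's cell grid: rows = axial, cols = circumferential
.grid_index <- function(offset, n_row, n_col) {
  matrix(offset + seq_len(n_row * n_col), nrow = n_row, ncol = n_col, byrow = TRUE)
}

# 4-neighborhood with circumferential wrap; axial boundaries get NA
.grid_neighbors <- function(idx) {
  n_row <- nrow(idx); n_col <- ncol(idx)
  down  <- rbind(matrix(NA_integer_, 1, n_col), idx[-n_row, , drop = FALSE])
  up    <- rbind(idx[-1, , drop = FALSE], matrix(NA_integer_, 1, n_col))
  left  <- idx[, c(n_col, seq_len(n_col - 1)), drop = FALSE]
  right <- idx[, c(seq_len(n_col)[-1], 1), drop = FALSE]
  if (n_col == 1) { left[] <- NA_integer_; right[] <- NA_integer_ }
  cbind(as.vector(t(down)), as.vector(t(up)), as.vector(t(left)), as.vector(t(right)))
}

# per-domain EC<->SMC overlap weights on the unit square, normalized per EC.
# Returns triplets (ec_local, smc_local, w) for one 208 x 80 domain.
.hetero_pattern <- function() {
  ov <- function(n1, n2) {
    # overlap lengths between n1 and n2 equal subdivisions of [0,1]
    a0 <- (seq_len(n1) - 1) / n1; a1 <- seq_len(n1) / n1
    b0 <- (seq_len(n2) - 1) / n2; b1 <- seq_len(n2) / n2
    m <- outer(a1, b1, pmin) - outer(a0, b0, pmax)
    m[m < 0] <- 0
    m
  }
  ax <- ov(EC_GRID[["axial"]], SMC_GRID[["axial"]])     # 13 x 4
  ci <- ov(EC_GRID[["circ"]], SMC_GRID[["circ"]])       # 16 x 20
  out <- list()
  k <- 1L
  for (ia in seq_len(nrow(ax))) for (ka in seq_len(ncol(ax))) {
    if (ax[ia, ka] <= 0) next
    jc <- which(ci > 0, arr.ind = TRUE)
    w <- ax[ia, ka] * ci[jc]
    # EC local index (row-major: axial row ia, circ col j)
    ecl <- (ia - 1L) * EC_GRID[["circ"]] + jc[, 1]
    sml <- (ka - 1L) * SMC_GRID[["circ"]] + jc[, 2]
    out[[k]] <- cbind(ecl, sml, w)
    k <- k + 1L
  }
  trip <- do.call(rbind, out)
  # normalize so weights over each EC sum to 1
  tot <- tapply(trip[, 3], trip[, 1], sum)
  trip[, 3] <- trip[, 3] / tot[as.character(trip[, 1])]
  trip
}

#' Build the EC/SMC cell lattice of a surface mesh
#'
#' Places 208 axially aligned endothelial cells (13 x 16) and 80
#' circumferentially aligned smooth muscle cells (4 x 20) on every
#' quadrilateral domain, for 288 cells per domain.  Homocellular adjacency is
#' a 4-neighborhood that is periodic circumferentially and crosses domain
#' boundaries; at the parent/daughter junction each parent-edge cell connects
#' to the geometrically nearest daughter.  Heterocellular (myoendothelial)
#' links are assigned by geometric overlap of the two grids within each
#' domain, with weights normalized to sum to one over each EC.
#'
#' @param mesh A `surface_mesh`.
#' @return An object of class `cell_lattice` with a `cells` tibble,
#'   homocellular neighbor index matrices and a sparse heterocellular weight
#'   matrix.
#' @export
build_cell_lattice <- function(mesh) {
  if (!inherits(mesh, "surface_mesh")) abort("`mesh` must be a surface_mesh")
  nA <- mesh$domain_grid_shape[["axial"]]
  nC <- mesh$domain_grid_shape[["circ"]]
  segs <- mesh$segments
  doms <- mesh$domains

  build_type <- function(grid) {
    rows_per <- grid[["axial"]]; cols_per <- grid[["circ"]]
    n_row <- nA * rows_per; n_col <- nC * cols_per
    per_seg <- n_row * n_col
    idx <- list(); nb <- list(); cells <- list()
    for (si in seq_along(segs)) {
      off <- (si - 1L) * per_seg
      m <- .grid_index(off, n_row, n_col)
      nbm <- .grid_neighbors(m)
      row <- rep(seq_len(n_row), each = n_col)
      col <- rep(seq_len(n_col), times = n_row)
      dom_ax <- (row - 1L) %/% rows_per + 1L
      dom_ci <- (col - 1L) %/% cols_per + 1L
      dd <- doms[doms$segment == segs[si], ]
      key <- (dom_ax - 1L) * nC + dom_ci
      dmap <- dd[order((dd$ax - 1L) * nC + dd$circ), ]
      cells[[si]] <- tibble(
        segment = segs[si], row = row, col = col,
        domain_id = dmap$domain_id[key], region = dmap$region[key],
        frac_ax = (row - 0.5) / n_row, frac_ci = (col - 0.5) / n_col)
      idx[[si]] <- m
      nb[[si]] <- nbm
    }
    nb <- do.call(rbind, nb)
    # junction wiring: parent's last axial row -> nearest daughter's first row
    if (length(segs) == 3L) {
      par_top <- idx[[1]][n_row, ]
      for (j in seq_len(n_col)) {
        phi <- 2 * pi * (j - 0.5) / n_col
        di <- if (cos(phi) >= 0) 2L else 3L     # daughter1 occupies +x
        tgt <- idx[[di]][1, j]
        nb[par_top[j], 2] <- tgt     # "up" neighbor of parent edge cell
        nb[tgt, 1] <- par_top[j]     # "down" neighbor of daughter edge cell
      }
    }
    list(cells = dplyr::bind_rows(cells), nb = nb)
  }

  ec <- build_type(EC_GRID)
  smc <- build_type(SMC_GRID)
  n_ec <- nrow(ec$cells); n_smc <- nrow(smc$cells)

  # cell center positions: bilinear interpolation on the domain corners
  locate <- function(cells, grid) {
    dd <- doms[match(cells$domain_id, doms$domain_id), ]
    vm <- as.matrix(mesh$vertices[, c("x", "y", "z")])
    rows_per <- grid[["axial"]]; cols_per <- grid[["circ"]]
    fa <- ((cells$row - 1L) %% rows_per + 0.5) / rows_per
    fc <- ((cells$col - 1L) %% cols_per + 0.5) / cols_per
    p <- (1 - fa) * (1 - fc) * vm[dd$v00, , drop = FALSE] +
      fa * (1 - fc) * vm[dd$v10, , drop = FALSE] +
      fa * fc * vm[dd$v11, , drop = FALSE] +
      (1 - fa) * fc * vm[dd$v01, , drop = FALSE]
    r_nom <- c(parent = mesh$spec$r_parent, daughter1 = mesh$spec$r_d1,
               daughter2 = mesh$spec$r_d2)
    seg_len <- mesh$spec$segment_length
    u <- 2 * pi * cells$frac_ci * r_nom[cells$segment]
    u[is.na(u)] <- 2 * pi * cells$frac_ci[is.na(u)] * mesh$spec$r_parent
    v <- cells$frac_ax * seg_len + ifelse(cells$segment == "parent", 0, seg_len)
    cells$x <- p[, 1]; cells$y <- p[, 2]; cells$z <- p[, 3]
    cells$u <- u; cells$v <- v
    cells
  }
  ec$cells <- locate(ec$cells, EC_GRID)
  smc$cells <- locate(smc$cells, SMC_GRID)

  ec$cells$cell_type <- "ec"; smc$cells$cell_type <- "smc"
  ec$cells$type_index <- seq_len(n_ec)
  smc$cells$type_index <- seq_len(n_smc)
  cells <- dplyr::bind_rows(ec$cells, smc$cells)
  cells$cell_id <- seq_len(nrow(cells))

  # heterocellular links, replicated per domain from the unit-square pattern
  pat <- .hetero_pattern()
  ec_by_dom <- split(ec$cells$type_index,
                     paste(ec$cells$segment, ec$cells$domain_id))
  smc_by_dom <- split(smc$cells$type_index,
                      paste(smc$cells$segment, smc$cells$domain_id))
  # within a domain, local index is row-major over (axial row, circ col)
  local_order <- function(cells_t, grid, ids) {
    cc <- cells_t[ids, ]
    lr <- (cc$row - 1L) %% grid[["axial"]]
    lc <- (cc$col - 1L) %% grid[["circ"]]
    ids[order(lr * grid[["circ"]] + lc)]
  }
  keys <- names(ec_by_dom)
  tri <- lapply(keys, function(key) {
    eids <- local_order(ec$cells, EC_GRID, ec_by_dom[[key]])
    sids <- local_order(smc$cells, SMC_GRID, smc_by_dom[[key]])
    list(i = eids[pat[, 1]], j = sids[pat[, 2]])
  })
  hetero <- Matrix::sparseMatrix(
    i = unlist(lapply(tri, `[[`, "i")),
    j = unlist(lapply(tri, `[[`, "j")),
    x = rep(pat[, 3], length(keys)),
    dims = c(n_ec, n_smc))

  structure(
    list(mesh = mesh, cells = as_tibble(cells),
         n_ec = n_ec, n_smc = n_smc,
         ec_nb = ec$nb, smc_nb = smc$nb, hetero = hetero,
         cells_per_domain = c(ec = unname(prod(EC_GRID)),
                              smc = unname(prod(SMC_GRID)))),
    class = "cell_lattice")
}

#' @export
print.cell_lattice <- function(x, ...) {
  cat(sprintf("<cell_lattice> %d ECs + %d SMCs = %d cells on %d domains\n",
              x$n_ec, x$n_smc, x$n_ec + x$n_smc,
              length(unique(x$cells$domain_id))))
  invisible(x)
}

#' Unwrap a mesh or lattice to flat 2D coordinates
#'
#' Maps every cell (or domain) to planar coordinates: `u` runs along the
#' circumference (periodic, scaled by the segment's nominal radius) and `v`
#' along the centerline path from the parent inlet.  The map is a bijection
#' on cell indices; circumferential edges are periodic with period
#' `2 * pi * r` for each segment.
#'
#' @param x A `cell_lattice` (per-cell map) or `surface_mesh` (per-domain map).
#' @return A tibble with `cell_id` (or `domain_id`), `type`, `u`, `v`,
#'   `region`, carrying a `circumference` attribute per segment.
#' @export
unwrap_mesh <- function(x) {
  if (inherits(x, "cell_lattice")) {
    out <- x$cells[, c("cell_id", "cell_type", "segment", "u", "v", "region")]
    names(out)[2] <- "type"
    spec <- x$mesh$spec
  } else if (inherits(x, "surface_mesh")) {
    out <- x$domains[, c("domain_id", "segment", "u", "v", "region")]
    spec <- x$spec
  } else {
    abort("`x` must be a cell_lattice or surface_mesh")
  }
  circumf <- 2 * pi * c(parent = spec$r_parent, daughter1 = spec$r_d1,
                        daughter2 = spec$r_d2)
  attr(out, "circumference") <- circumf
  class(out) <- c("unwrapped_map", class(out))
  out
}
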