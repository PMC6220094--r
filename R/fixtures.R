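# Self-contained desk-scale fixtures: an EC/SMC pair, a chain of coupled
# SMC units, or a patch of full 288-cell quadrilateral domains.

# reference domain footprint (mm): 40 circumferential x 34 axial domains per
# 6 mm segment tile the nominal 18 mm x pi*2.5 mm bifurcation surface with
# 4080 domains in three segments.
DOMAIN_W <- pi * 2.5 / 40      # circumferential extent of one domain
DOMAIN_L <- 6 / 34             # axial extent

# In a full domain every SMC is contacted by 208/80 = 2.6 ECs on average
# (EC-side weights are normalized to 1).  Pair and chain fixtures carry one
# EC per SMC, so their single myoendothelial link uses this multiplicity to
# reproduce the per-SMC drive of the reference lattice.
MYOEND_MULT <- 208 / 80

.minimal_cells <- function(n_ec, n_smc, spacing = DOMAIN_L / 4,
                           domain_per_unit = FALSE) {
  dom_e <- if (domain_per_unit) seq_len(n_ec) else rep(1L, n_ec)
  dom_s <- if (domain_per_unit) seq_len(n_smc) else rep(1L, n_smc)
  dplyr::bind_rows(
    tibble(cell_type = "ec", type_index = seq_len(n_ec),
           segment = "parent", row = seq_len(n_ec), col = 1L,
           domain_id = dom_e, region = "uniform",
           u = 0, v = (seq_len(n_ec) - 0.5) * spacing,
           x = 0, y = 0, z = (seq_len(n_ec) - 0.5) * spacing),
    tibble(cell_type = "smc", type_index = seq_len(n_smc),
           segment = "parent", row = seq_len(n_smc), col = 1L,
           domain_id = dom_s, region = "uniform",
           u = 0, v = (seq_len(n_smc) - 0.5) * spacing,
           x = 0, y = 0.01, z = (seq_len(n_smc) - 0.5) * spacing)) |>
    dplyr::mutate(cell_id = dplyr::row_number())
}

#' Generate a desk-scale test fixture
#'
#' * `pair`: one EC heterocellularly linked to one SMC.
#' * `chain`: `size` EC/SMC units in a line; the SMCs are homocellularly
#'   coupled to their chain neighbors (the classic synchronization
#'   scenario), each driven by its own EC through a myoendothelial link.
#' * `patch`: `size` full 288-cell quadrilateral domains stacked axially on
#'   a periodic tube, with homocellular, heterocellular and cross-domain
#'   adjacency, ready for [assemble_network()].
#'
#' @param kind Fixture kind: `"pair"`, `"chain"` or `"patch"`.
#' @param size Number of chain units or patch domains (patches are limited
#'   to 16 domains).
#' @param seed Seed recorded for downstream use.
#' @param atp ATP level(s) (uM) for the fixture's agonist map: a scalar, a
#'   per-EC vector, or `"gradient"` (patch only) for an axial ramp from the
#'   apex peak to the seam floor of [agonist_params()].
#' @return List with `lattice`, `atp` (an `agonist_map`) and `seed`.
#' @export
generate_fixture <- function(kind = c("pair", "chain", "patch"), size = 1,
                             seed = 1, atp = 1.0) {
  kind <- match.arg(kind)
  if (kind == "patch" && size > 16) {
    abort("patch fixtures are limited to 16 domains")
  }
  if (kind == "pair") size <- 1
  lattice <- switch(
    kind,
    pair = {
      cells <- .minimal_cells(1, 1)
      structure(list(
        mesh = NULL, cells = cells, n_ec = 1L, n_smc = 1L,
        ec_nb = matrix(NA_integer_, 1, 4), smc_nb = matrix(NA_integer_, 1, 4),
        hetero = Matrix::sparseMatrix(i = 1, j = 1, x = MYOEND_MULT,
                                      dims = c(1, 1)),
        cells_per_domain = c(ec = 1, smc = 1)), class = "cell_lattice")
    },
    chain = {
      cells <- .minimal_cells(size, size, domain_per_unit = TRUE)
      smc_nb <- cbind(c(NA, seq_len(size - 1)), c(seq_len(size - 1) + 1, NA),
                      NA_integer_, NA_integer_)
      structure(list(
        mesh = NULL, cells = cells, n_ec = size, n_smc = size,
        ec_nb = matrix(NA_integer_, size, 4), smc_nb = smc_nb,
        hetero = Matrix::sparseMatrix(i = seq_len(size), j = seq_len(size),
                                      x = MYOEND_MULT, dims = c(size, size)),
        cells_per_domain = c(ec = size, smc = size)), class = "cell_lattice")
    },
    patch = {
      mesh <- build_tube_mesh(radius = DOMAIN_W / (2 * pi),
                              length = DOMAIN_L * size,
                              domains_axial = size, domains_circ = 1)
      build_cell_lattice(mesh)
    })
  n_ec <- lattice$n_ec
  map <- if (identical(atp, "gradient")) {
    if (kind != "patch") abort("`gradient` maps require a patch fixture")
    ap <- agonist_params()
    ec <- lattice$cells[lattice$cells$cell_type == "ec", ]
    f <- (ec$v - min(ec$v)) / max(diff(range(ec$v)), 1e-12)
    m <- uniform_atp_map(lattice, 0)
    m$atp <- ap$seam + (ap$apex - ap$seam) * f
    m
  } else if (length(atp) == 1) {
    uniform_atp_map(lattice, atp)
  } else {
    if (length(atp) != n_ec) abort("per-EC ATP vector has the wrong length")
    m <- uniform_atp_map(lattice, 0)
    m$atp <- as.numeric(atp)
    m
  }
  list(lattice = lattice, atp = map, seed = seed, kind = kind, size = size)
}
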