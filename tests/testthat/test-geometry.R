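test_that("Murray's law radius relation holds for degenerate, symmetric and asymmetric daughters", {
  expect_equal(murray_parent_radius(1, 0), 1)
  expect_equal(murray_parent_radius(1, 1), 2^(1 / 3), tolerance = 1e-12)
  expect_equal(murray_parent_radius(1, 0.5), 1.125^(1 / 3), tolerance = 1e-12)
  expect_equal(murray_parent_radius(1, 0.5), 1.040042, tolerance = 1e-6)
  expect_error(murray_parent_radius(-1, 1), "non-negative")
  expect_error(murray_parent_radius(0, 0), "positive")
})

test_that("bifurcation specs enforce Murray's law and reject bad angles", {
  for (ang in c(50, 80, 110)) {
    for (ratio in c(1, 0.8)) {
      s <- bifurcation_spec(ang, daughter_ratio = ratio)
      expect_lt(abs(s$r_parent^3 - s$r_d1^3 - s$r_d2^3) / s$r_parent^3, 1e-9)
      expect_equal(s$r_d2 / s$r_d1, ratio, tolerance = 1e-12)
    }
  }
  s <- bifurcation_spec(110)
  expect_equal(s$diameter, 2.5)
  expect_equal(s$total_length, 18)
  expect_error(bifurcation_spec(0), "between 0 and 180")
  expect_error(bifurcation_spec(180), "between 0 and 180")
  expect_error(bifurcation_spec(90, diameter = -1), "positive")
})

test_that("the three segments share the junction ring exactly and the grid is circumferentially periodic", {
  mesh <- build_bifurcation_mesh(bifurcation_spec(110), 4, 8)
  v <- mesh$vertices
  ring_of <- function(seg, ring) {
    r <- v[v$segment == seg & v$ring == ring, ]
    as.matrix(r[order(r$pos), c("x", "y", "z")])
  }
  par_end <- ring_of("parent", 4)
  expect_lt(max(abs(par_end - ring_of("daughter1", 0))), 1e-9)
  expect_lt(max(abs(par_end - ring_of("daughter2", 0))), 1e-9)
  # each domain has 4 domain-neighbors under the periodic circumferential
  # boundary: column index arithmetic must wrap
  d <- mesh$domains
  for (seg in mesh$segments) {
    dd <- d[d$segment == seg, ]
    expect_setequal(dd$circ, 1:8)
    expect_equal(nrow(dd), 4 * 8)
  }
  expect_error(build_bifurcation_mesh(bifurcation_spec(110), 1, 8), "coarse")
})

test_that("symmetric-daughter meshes are mirror symmetric about the bifurcation plane", {
  mesh <- build_bifurcation_mesh(bifurcation_spec(90), 4, 8)
  v1 <- mesh$vertices[mesh$vertices$segment == "daughter1", c("x", "y", "z")]
  v2 <- mesh$vertices[mesh$vertices$segment == "daughter2", c("x", "y", "z")]
  refl <- v2; refl$x <- -refl$x
  # reflected daughter2 vertex set must coincide with daughter1's
  d <- as.matrix(v1)
  r <- as.matrix(refl)
  nn <- apply(r, 1, function(p) min(colSums((t(d) - p)^2)))
  expect_lt(max(sqrt(nn)), 1e-9)
})

test_that("doubling the circumferential resolution changes total area by under 2 percent", {
  a1 <- sum(build_bifurcation_mesh(bifurcation_spec(110), 4, 8)$domains$area)
  a2 <- sum(build_bifurcation_mesh(bifurcation_spec(110), 4, 16)$domains$area)
  expect_lt(abs(a2 - a1) / a1, 0.02)
})

test_that("curvature bends the mesh out of plane and zero curvature is planar", {
  flat <- build_bifurcation_mesh(bifurcation_spec(80), 4, 8)
  bent <- build_bifurcation_mesh(bifurcation_spec(80, curvature = 0.05), 4, 8)
  expect_lt(diff(range(flat$vertices$y)), 2 * 1.25 + 1e-9)  # tube width only
  expect_gt(max(bent$vertices$y), max(flat$vertices$y) + 0.1)
  # mirror symmetry in x is preserved under the bend
  expect_equal(sort(bent$vertices$x), sort(-bent$vertices$x), tolerance = 1e-9)
})

test_that("cell lattices carry 208 ECs + 80 SMCs per domain with symmetric 4-neighbor adjacency", {
  lat <- build_cell_lattice(build_bifurcation_mesh(bifurcation_spec(110), 2, 4))
  n_dom <- nrow(lat$mesh$domains)
  expect_equal(lat$n_ec, 208 * n_dom)
  expect_equal(lat$n_smc, 80 * n_dom)
  expect_equal(nrow(lat$cells), 288 * n_dom)
  per_dom <- dplyr::count(lat$cells, .data$domain_id)
  expect_true(all(per_dom$n == 288))
  # adjacency symmetry: a in N(b) <=> b in N(a)
  check_sym <- function(nb, rows = seq_len(nrow(nb))) {
    ok <- vapply(rows, function(i) {
      js <- nb[i, ][!is.na(nb[i, ])]
      all(vapply(js, function(j) i %in% nb[j, ], logical(1)))
    }, logical(1))
    expect_true(all(ok))
  }
  check_sym(lat$smc_nb)
  check_sym(lat$ec_nb, rows = seq(1, nrow(lat$ec_nb), by = 7))
  # interior cells have exactly 4 homocellular neighbors
  expect_true(mean(rowSums(!is.na(lat$ec_nb)) == 4) > 0.9)
  expect_true(all(rowSums(!is.na(lat$ec_nb)) >= 3))
})

test_that("heterocellular weights sum to one over each EC and every cell is linked", {
  lat <- build_cell_lattice(build_bifurcation_mesh(bifurcation_spec(50), 2, 4))
  expect_equal(range(Matrix::rowSums(lat$hetero)), c(1, 1), tolerance = 1e-12)
  expect_true(all(Matrix::colSums(lat$hetero) > 0))   # every SMC linked
  expect_true(all(Matrix::rowSums(lat$hetero != 0) >= 1))
})

test_that("unwrapping is a bijection that preserves periodicity and area", {
  lat <- build_cell_lattice(build_bifurcation_mesh(bifurcation_spec(110), 3, 6))
  m <- unwrap_mesh(lat)
  expect_equal(sort(m$cell_id), seq_len(nrow(lat$cells)))   # bijection
  expect_equal(nrow(m), lat$n_ec + lat$n_smc)
  # circumferentially adjacent cells across the cut are adjacent modulo the
  # periodic circumference
  circ <- attr(m, "circumference")[["parent"]]
  ec <- lat$cells[lat$cells$cell_type == "ec" & lat$cells$segment == "parent", ]
  row1 <- ec[ec$row == 1, ]
  first <- row1[which.min(row1$col), ]; last <- row1[which.max(row1$col), ]
  gap <- unname((first$u - last$u) %% circ)
  expect_equal(gap, unname(circ / nrow(row1)), tolerance = 1e-9)
  # planar area matches 3D area within 5 percent in total
  mesh <- lat$mesh
  planar <- sum((2 * pi * c(parent = mesh$spec$r_parent,
                            daughter1 = mesh$spec$r_d1,
                            daughter2 = mesh$spec$r_d2)[mesh$domains$segment] /
                   mesh$domain_grid_shape[["circ"]]) *
                  (mesh$spec$segment_length / mesh$domain_grid_shape[["axial"]]))
  expect_lt(abs(planar - sum(mesh$domains$area)) / sum(mesh$domains$area), 0.05)
})

test_that("region labels include an apex band and two lateral seams near the junction", {
  mesh <- build_bifurcation_mesh(bifurcation_spec(110), 6, 12)
  tab <- table(mesh$domains$region)
  expect_true(all(c("apex", "lateral_seam", "uniform") %in% names(tab)))
  apex <- mesh$domains[mesh$domains$region == "apex", ]
  expect_true(all(apex$segment != "parent"))
  # apex domains sit close to the flow divider (the junction origin)
  expect_lt(max(sqrt(apex$cx^2 + apex$cy^2 + apex$cz^2)), 3)
})
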