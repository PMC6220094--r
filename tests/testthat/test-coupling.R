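cp <- coupling_params()

test_that("the electro-diffusive current vanishes without gradients, negates under exchange, and is Fickian for IP3", {
  expect_equal(electro_diffusive_current(0.5, 0.5, -40, -40, "ca", cp), 0)
  a <- electro_diffusive_current(0.3, 0.9, -50, -30, "ca", cp)
  b <- electro_diffusive_current(0.9, 0.3, -30, -50, "ca", cp)
  expect_equal(a, -b, tolerance = 1e-12)
  # valence zero removes the drift term entirely
  i1 <- electro_diffusive_current(0.3, 0.9, -50, -30, "ip3", cp)
  i2 <- electro_diffusive_current(0.3, 0.9, 0, 0, "ip3", cp)
  expect_equal(i1, i2, tolerance = 1e-12)
  fick <- cp$P_x * cp$sigma * cp$A_segment * 96485.33212 * (0.9 - 0.3) / cp$dx
  expect_equal(i1, fick, tolerance = 1e-9)
  expect_error(electro_diffusive_current(-0.1, 0.5, 0, 0, "ca", cp), ">= 0")
  expect_error(electro_diffusive_current(0.1, 0.5, 0, 0, "na", cp), "arg")
})

test_that("electrical coupling coefficients follow g = G/Cm and resistance conversions", {
  expect_equal(conductance_to_coefficient(30, 30), 1000)
  expect_equal(resistance_to_conductance(3), 1000 / 3, tolerance = 1e-12)
  # myoendothelial junction: 900 MOhm, ~20 pF net -> order 50 per second
  g_het <- conductance_to_coefficient(resistance_to_conductance(900), 20)
  expect_equal(g_het, 55.6, tolerance = 0.01)
  expect_equal(membrane_potential_coupling(-40, -40, 50), 0)
  expect_equal(membrane_potential_coupling(-50, -30, 1000), 20000)
  expect_error(membrane_potential_coupling(0, 0, -1), "non-negative")
})

test_that("uniform lattice states produce zero coupling flux everywhere", {
  fx <- generate_fixture("patch", size = 1)
  lat <- fx$lattice
  st <- list(
    ec = list(ca_cyt = rep(0.4, lat$n_ec), ca_store = rep(1, lat$n_ec),
              v_m = rep(-50, lat$n_ec), ip3 = rep(0.7, lat$n_ec),
              g_prot = rep(100, lat$n_ec)),
    smc = list(ca_cyt = rep(0.4, lat$n_smc), ca_store = rep(1, lat$n_smc),
               v_m = rep(-50, lat$n_smc), w_k = rep(0.2, lat$n_smc),
               ip3 = rep(0.7, lat$n_smc)))
  fl <- coupling_terms(lat, st, cp)
  expect_lt(max(abs(unlist(fl))), 1e-9)
})

test_that("coupling fluxes conserve each species globally (pairwise antisymmetry)", {
  fx <- generate_fixture("patch", size = 2)
  lat <- fx$lattice
  for (seed in c(1, 7, 23)) {
    st <- random_states(lat, seed)
    fl <- coupling_terms(lat, st, cp)
    rel_sum <- function(a, b) {
      abs(sum(a) + sum(b)) / max(sum(abs(a)) + sum(abs(b)), 1e-12)
    }
    expect_lt(rel_sum(fl$ec$ca, fl$smc$ca), 1e-10)
    expect_lt(rel_sum(fl$ec$ip3, fl$smc$ip3), 1e-10)
    expect_lt(rel_sum(fl$ec$vm, fl$smc$vm), 1e-10)
  }
})

test_that("a closed two-cell system conserves total calcium under store and gap-junction fluxes only", {
  # two SMCs with membrane fluxes disabled, coupled by calcium diffusion
  p <- smc_params(D = 0, G_Ca = 0, G_NaCa = 0)
  pc <- 0.05
  f <- function(t, y, parms) {
    s1 <- list(ca_cyt = y[1], ca_store = y[2], v_m = y[3], w_k = y[4], ip3 = y[5])
    s2 <- list(ca_cyt = y[6], ca_store = y[7], v_m = y[8], w_k = y[9], ip3 = y[10])
    J12 <- pc * (y[6] - y[1])
    d1 <- smc_rhs(s1, coupling = list(ca = J12, ip3 = 0, vm = 0), params = p)
    d2 <- smc_rhs(s2, coupling = list(ca = -J12, ip3 = 0, vm = 0), params = p)
    list(c(unlist(d1, use.names = FALSE), unlist(d2, use.names = FALSE)))
  }
  y0 <- c(0.9, 1.0, -45, 0.2, 0, 0.2, 1.5, -55, 0.1, 0)
  tr <- deSolve::ode(y0, seq(0, 60, 0.5), f, NULL, method = "lsoda",
                     rtol = 1e-10, atol = 1e-12)
  total <- tr[, 2] + tr[, 3] + tr[, 7] + tr[, 8]
  expect_lt(max(abs(total - total[1])), 1e-6)
})

test_that("zeroing all coupling coefficients reproduces the concatenated single-cell derivatives bitwise", {
  fx <- generate_fixture("patch", size = 1)
  net <- assemble_network(fx$lattice, fx$atp,
                          coupling = coupling_params(
                            g_homo_ec = 0, g_homo_smc = 0, g_hetero = 0,
                            p_ca_homo_ec = 0, p_ca_homo_smc = 0,
                            p_ca_hetero = 0, p_ip3_homo = 0, p_ip3_hetero = 0))
  st <- random_states(fx$lattice, 5)
  y <- c(unlist(st$ec, use.names = FALSE), unlist(st$smc, use.names = FALSE))
  d_net <- network_rhs(0, y, net)
  d_ec <- ec_rhs(st$ec, net$atp, params = net$ec_params,
                 ip3_pars = net$ip3_params)
  d_smc <- smc_rhs(st$smc, params = net$smc_params)
  expect_identical(d_net,
                   c(d_ec$ca_cyt, d_ec$ca_store, d_ec$v_m, d_ec$ip3,
                     d_ec$g_prot, d_smc$ca_cyt, d_smc$ca_store, d_smc$v_m,
                     d_smc$w_k, d_smc$ip3))
})

test_that("five homocellularly coupled SMCs synchronize their oscillations", {
  on <- sync_experiment(TRUE)
  off <- sync_experiment(FALSE)
  # coupled phase spread collapses; uncoupled phase offsets persist
  expect_lt(on[["late"]], 0.6 * off[["late"]])
  expect_lt(on[["late"]], 0.6 * on[["early"]])
  expect_gt(off[["late"]], 0.8 * off[["early"]])
})

test_that("a perturbation on a chain spreads outward without remote excitation", {
  fx <- generate_fixture("chain", size = 9, atp = 1.0)
  net <- assemble_network(fx$lattice, fx$atp)
  cfg <- simulation_config(duration = 30, record_interval = 0.5,
                           seed = 1, perturbation = 0)
  y0 <- initial_state(net, cfg)
  ref <- run_simulation(net, cfg, y0 = y0)       # undisturbed reference
  y0[net$layout$smc$ca_cyt[5]] <- 1.2            # kick the center SMC
  rec <- run_simulation(net, cfg, y0 = y0)
  dev <- abs(rec$smc$ca_cyt - ref$smc$ca_cyt)
  first_influence <- apply(dev > 0.02, 2, function(z) {
    i <- which(z); if (length(i)) rec$times[i[1]] else Inf
  })
  d <- abs(seq_len(9) - 5)
  # influence arrival is non-decreasing in distance from the kicked cell
  for (k in 1:3) {
    expect_lte(max(first_influence[d == k]), min(first_influence[d == k + 1]))
  }
})
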