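# Build a minimal sim_record from synthetic trace matrices, for analysis
# tests that need known ground truth.
make_record <- function(times, smc_ca, ec_ca = NULL) {
  n_s <- ncol(smc_ca)
  n_e <- if (is.null(ec_ca)) 1 else ncol(ec_ca)
  if (is.null(ec_ca)) ec_ca <- matrix(0.1, nrow = length(times), ncol = 1)
  cells <- dplyr::bind_rows(
    tibble::tibble(cell_type = "ec", type_index = seq_len(n_e),
                   segment = "parent", row = seq_len(n_e), col = 1L,
                   domain_id = 1L, region = "uniform",
                   u = 0, v = (seq_len(n_e) - 0.5) * 0.05,
                   x = 0, y = 0, z = 0),
    tibble::tibble(cell_type = "smc", type_index = seq_len(n_s),
                   segment = "parent", row = seq_len(n_s), col = 1L,
                   domain_id = 1L, region = "uniform",
                   u = 0, v = (seq_len(n_s) - 0.5) * 0.05,
                   x = 0, y = 0, z = 0))
  cells$cell_id <- seq_len(nrow(cells))
  structure(
    list(times = times,
         ec = list(ca_cyt = ec_ca),
         smc = list(ca_cyt = smc_ca),
         n_ec = n_e, n_smc = n_s, cells = cells,
         config = simulation_config(duration = max(times),
                                    record_interval = diff(times)[1]),
         network_hash = "synthetic", final_state = NULL),
    class = "sim_record")
}

# random cell states for coupling/property tests
random_states <- function(lattice, seed = 42) {
  set.seed(seed)
  nE <- lattice$n_ec; nS <- lattice$n_smc
  list(
    ec = list(ca_cyt = runif(nE, 0.05, 1.5), ca_store = runif(nE, 0.5, 2),
              v_m = runif(nE, -80, -20), ip3 = runif(nE, 0, 2),
              g_prot = runif(nE, 0, 1e4)),
    smc = list(ca_cyt = runif(nS, 0.05, 1.5), ca_store = runif(nS, 0.5, 2),
               v_m = runif(nS, -80, -20), w_k = runif(nS, 0, 1),
               ip3 = runif(nS, 0, 2)))
}
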