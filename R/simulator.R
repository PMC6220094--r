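# Assemble the coupled ODE system over a cell lattice and integrate it.

#' Simulation configuration
#'
#' @param duration Physiological seconds to simulate (default 500).
#' @param record_interval Recording cadence in seconds (default 1: state
#'   snapshots after every elapsed physiological second).
#' @param exchange_interval Boundary-state refresh cadence (s) for the
#'   block-wise (`mode = "exchange"`) evaluation structure (default 0.01).
#' @param rtol,atol Solver tolerances.
#' @param seed RNG seed for the initial-condition perturbations.
#' @param perturbation Relative amplitude of the seeded multiplicative
#'   perturbation applied to the rest state per cell (default 0.01).
#' @param mode `"continuous"` integrates the full coupled system with one
#'   adaptive stiff solve; `"exchange"` mirrors a domain-decomposed run,
#'   integrating each quadrilateral domain separately and refreshing
#'   cross-domain boundary states every `exchange_interval`.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(duration = 500, record_interval = 1,
                              exchange_interval = 0.01,
                              rtol = 1e-6, atol = 1e-9, seed = 1,
                              perturbation = 0.01,
                              mode = c("continuous", "exchange")) {
  if (duration < 0) abort("`duration` must be non-negative")
  if (record_interval <= 0 || (duration > 0 && record_interval > duration)) {
    abort("require 0 < record_interval <= duration")
  }
  if (exchange_interval > record_interval) {
    abort("require exchange_interval <= record_interval")
  }
  structure(list(duration = duration, record_interval = record_interval,
                 exchange_interval = exchange_interval, rtol = rtol,
                 atol = atol, seed = seed, perturbation = perturbation,
                 mode = match.arg(mode)),
            class = "simulation_config")
}

EC_FIELDS <- c("ca_cyt", "ca_store", "v_m", "ip3", "g_prot")
SMC_FIELDS <- c("ca_cyt", "ca_store", "v_m", "w_k", "ip3")

#' Assemble the coupled cell network
#'
#' Combines a cell lattice, a per-EC agonist map and the model and coupling
#' parameter sets into a single ODE system over all cells.  The state vector
#' stacks the EC fields (cytosolic and store calcium, membrane potential,
#' IP3, activated G-protein) followed by the SMC fields (calcium, store,
#' potential, K-channel open fraction, IP3), each field contiguous across
#' cells.
#'
#' @param lattice A `cell_lattice`.
#' @param atp An `agonist_map` (or numeric vector with one ATP value per EC,
#'   uM).
#' @param ec,smc,ip3,coupling Parameter sets; defaults are the reference
#'   parameter values.
#' @return An object of class `cell_network`.
#' @export
assemble_network <- function(lattice, atp, ec = ec_params(),
                             smc = smc_params(), ip3 = ip3_params(),
                             coupling = coupling_params()) {
  if (!inherits(lattice, "cell_lattice")) abort("`lattice` must be a cell_lattice")
  atp_vec <- if (inherits(atp, "agonist_map")) {
    atp$atp[order(atp$type_index)]
  } else {
    as.numeric(atp)
  }
  if (length(atp_vec) != lattice$n_ec) {
    abort(sprintf("agonist map has %d values for %d ECs",
                  length(atp_vec), lattice$n_ec))
  }
  if (any(!is.finite(atp_vec)) || any(atp_vec < 0)) {
    abort("ATP values must be finite and non-negative")
  }
  nE <- lattice$n_ec; nS <- lattice$n_smc
  layout <- list(
    ec = setNames(lapply(seq_along(EC_FIELDS),
                         function(k) (k - 1) * nE + seq_len(nE)), EC_FIELDS),
    smc = setNames(lapply(seq_along(SMC_FIELDS),
                          function(k) 5 * nE + (k - 1) * nS + seq_len(nS)),
                   SMC_FIELDS))
  net <- structure(
    list(lattice = lattice, atp = atp_vec,
         ec_params = ec, smc_params = smc, ip3_params = ip3,
         coupling_params = coupling,
         n_ec = nE, n_smc = nS, n_state = 5 * (nE + nS), layout = layout),
    class = "cell_network")
  net$hash <- network_hash(net)
  net
}

network_hash <- function(net) {
  rlang::hash(list(net$n_ec, net$n_smc, net$lattice$ec_nb, net$lattice$smc_nb,
                   Matrix::which(net$lattice$hetero != 0), net$atp,
                   unclass(net$ec_params), unclass(net$smc_params),
                   unclass(net$ip3_params), unclass(net$coupling_params)))
}

#' @export
print.cell_network <- function(x, ...) {
  cat(sprintf("<cell_network> %d ECs + %d SMCs, %d states, ATP %.3g-%.3g uM\n",
              x$n_ec, x$n_smc, x$n_state, min(x$atp), max(x$atp)))
  invisible(x)
}

.unpack <- function(y, net) {
  lay <- net$layout
  list(
    ec = lapply(lay$ec, function(ix) y[ix]),
    smc = lapply(lay$smc, function(ix) y[ix]))
}

#' Network right-hand side
#'
#' Time derivative of the full stacked state: per-cell single-cell dynamics
#' plus gap-junctional coupling.  With all coupling coefficients zero this
#' reduces exactly (bitwise) to the concatenation of the independent
#' single-cell derivatives.
#'
#' @param t Time (s; the dynamics are autonomous).
#' @param y Stacked state vector.
#' @param net A `cell_network`.
#' @return Derivative vector.
#' @export
network_rhs <- function(t, y, net) {
  st <- .unpack(y, net)
  cpl <- coupling_terms(net$lattice, st, net$coupling_params)
  d_ec <- ec_rhs(st$ec, net$atp, cpl$ec, net$ec_params, net$ip3_params)
  d_smc <- smc_rhs(st$smc, cpl$smc, net$smc_params)
  c(d_ec$ca_cyt, d_ec$ca_store, d_ec$v_m, d_ec$ip3, d_ec$g_prot,
    d_smc$ca_cyt, d_smc$ca_store, d_smc$v_m, d_smc$w_k, d_smc$ip3)
}

#' Rest-state initial conditions with seeded perturbations
#'
#' The zero-agonist rest state of each cell type (obtained by settling the
#' single-cell dynamics) replicated over the lattice, with a per-cell
#' multiplicative perturbation `1 + perturbation * U(-1, 1)` drawn from the
#' seeded RNG so that spatial symmetry can break.
#'
#' @param net A `cell_network`.
#' @param config A [simulation_config()].
#' @return Stacked state vector.
#' @export
initial_state <- function(net, config = simulation_config()) {
  rest <- coupled_unit_rest(atp = 0, ec_pars = net$ec_params,
                            smc_pars = net$smc_params,
                            ip3_pars = net$ip3_params,
                            cpl = net$coupling_params)
  rest_ec <- rest$ec
  rest_smc <- rest$smc
  yE <- as.vector(vapply(EC_FIELDS, function(f) rep(rest_ec[[f]], net$n_ec),
                         numeric(net$n_ec)))
  yS <- as.vector(vapply(SMC_FIELDS, function(f) rep(rest_smc[[f]], net$n_smc),
                         numeric(net$n_smc)))
  y <- c(yE, yS)
  if (config$perturbation > 0) {
    set.seed(config$seed)
    y <- y * (1 + config$perturbation * runif(length(y), -1, 1))
  }
  y
}

#' Run a coupled-cells simulation
#'
#' Integrates the assembled network over `[0, duration]` with an adaptive
#' stiff solver (sparse-Jacobian BDF), recording full state snapshots at
#' the configured cadence.
#'
#' @param net A `cell_network`.
#' @param config A [simulation_config()].
#' @param y0 Optional explicit initial state (overrides the rest-state
#'   policy).
#' @return An object of class `sim_record`.
#' @export
run_simulation <- function(net, config = simulation_config(), y0 = NULL) {
  if (!inherits(net, "cell_network")) abort("`net` must be a cell_network")
  y0 <- y0 %||% initial_state(net, config)
  if (length(y0) != net$n_state) abort("initial state has the wrong length")
  times <- seq(0, config$duration, by = config$record_interval)
  out <- if (config$mode == "continuous") {
    .integrate_window(net, y0, times, config)
  } else {
    .integrate_exchange(net, y0, times, config)
  }
  build_record(net, out, config)
}

.integrate_window <- function(net, y0, times, config) {
  sol <- deSolve::lsodes(
    y = y0, times = times,
    func = function(t, y, parms) list(network_rhs(t, y, parms)),
    parms = net, rtol = config$rtol, atol = config$atol,
    sparsetype = "sparseint", maxsteps = 1e6)
  if (attr(sol, "istate")[1] < 0) {
    abort(sprintf("stiff solver failed near t = %.3f s", max(sol[, 1])))
  }
  sol
}

# block-wise evaluation: every exchange window, each quadrilateral domain is
# integrated on its own with cross-domain neighbor state frozen at the
# window start (ghost-cell semantics of a domain-decomposed run).
.integrate_exchange <- function(net, y0, times, config) {
  cells <- net$lattice$cells
  dom_of_ec <- cells$domain_id[cells$cell_type == "ec"]
  dom_of_smc <- cells$domain_id[cells$cell_type == "smc"]
  doms <- sort(unique(c(dom_of_ec, dom_of_smc)))
  lay <- net$layout
  # state indices per domain
  dom_ix <- lapply(doms, function(d) {
    e <- which(dom_of_ec == d); s <- which(dom_of_smc == d)
    c(unlist(lapply(lay$ec, function(ix) ix[e]), use.names = FALSE),
      unlist(lapply(lay$smc, function(ix) ix[s]), use.names = FALSE))
  })
  y <- y0
  out <- matrix(NA_real_, nrow = length(times), ncol = length(y0) + 1)
  out[1, ] <- c(times[1], y)
  rec_i <- 2L
  t_now <- times[1]
  t_end <- times[length(times)]
  h <- config$exchange_interval
  n_win <- round((t_end - t_now) / h)
  for (w in seq_len(n_win)) {
    t_next <- t_now + h
    frozen <- y
    for (k in seq_along(doms)) {
      ix <- dom_ix[[k]]
      f_sub <- function(t, ysub, parms) {
        yfull <- frozen
        yfull[ix] <- ysub
        list(network_rhs(t, yfull, net)[ix])
      }
      sol <- deSolve::lsoda(y[ix], c(t_now, t_next), f_sub, NULL,
                            rtol = config$rtol, atol = config$atol)
      y[ix] <- as.numeric(sol[nrow(sol), -1])
    }
    t_now <- t_next
    while (rec_i <= length(times) && times[rec_i] <= t_now + 1e-9) {
      out[rec_i, ] <- c(times[rec_i], y)
      rec_i <- rec_i + 1L
    }
  }
  out
}

build_record <- function(net, sol, config, meta = NULL) {
  times <- sol[, 1]
  lay <- net$layout
  take <- function(ix_list) {
    lapply(ix_list, function(ix) {
      m <- sol[, ix + 1, drop = FALSE]
      dimnames(m) <- NULL
      m
    })
  }
  rec <- structure(
    list(times = times,
         ec = take(lay$ec), smc = take(lay$smc),
         n_ec = net$n_ec, n_smc = net$n_smc,
         cells = net$lattice$cells,
         config = config, network_hash = net$hash,
         final_state = as.numeric(sol[nrow(sol), -1])),
    class = "sim_record")
  caps <- c(rec$ec$ca_cyt, rec$smc$ca_cyt)
  if (any(!is.finite(caps)) || any(caps < -1e-6) || any(caps > 10)) {
    warn("recorded calcium outside the physically sane range [0, 10] uM")
  }
  rec
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> %d snapshots over %.6g s, %d ECs + %d SMCs\n",
              length(x$times), max(x$times), x$n_ec, x$n_smc))
  invisible(x)
}

#' Continue a simulation from its recorded end state
#'
#' Restarts the integration from the final snapshot of `record` and returns
#' the concatenated trajectory.  The network must match the one that
#' produced the record (checked by hash).
#'
#' @param net The `cell_network` that produced `record`.
#' @param record A `sim_record`.
#' @param config Configuration for the continuation; `duration` is the
#'   additional time to simulate.
#' @return A `sim_record` covering the full concatenated time span.
#' @export
continue_from_checkpoint <- function(net, record, config = simulation_config()) {
  if (!identical(record$network_hash, net$hash)) {
    abort("checkpoint does not match this network (hash mismatch)")
  }
  if (config$duration == 0) return(record)
  t0 <- max(record$times)
  times <- seq(0, config$duration, by = config$record_interval)
  sol <- .integrate_window(net, record$final_state, times, config)
  sol[, 1] <- sol[, 1] + t0
  cont <- build_record(net, sol, config)
  glue <- function(a, b) {
    lapply(seq_along(a), function(k) rbind(a[[k]], b[[k]][-1, , drop = FALSE]))
  }
  rec <- record
  rec$times <- c(record$times, cont$times[-1])
  rec$ec <- setNames(glue(record$ec, cont$ec), names(record$ec))
  rec$smc <- setNames(glue(record$smc, cont$smc), names(record$smc))
  rec$final_state <- cont$final_state
  rec
}

#' Extract a single-cell trace from a record
#'
#' @param record A `sim_record`.
#' @param type `"ec"` or `"smc"`.
#' @param index Type-local cell index.
#' @param species State field name (e.g. `"ca_cyt"`).
#' @return Tibble with `time` and `value`.
#' @export
cell_trace <- function(record, type = c("smc", "ec"), index = 1,
                       species = "ca_cyt") {
  type <- match.arg(type)
  block <- record[[type]]
  if (!species %in% names(block)) abort(sprintf("unknown species `%s`", species))
  tibble(time = record$times, value = block[[species]][, index])
}
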