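# Single-cell dynamics.
#
# EC state: ca_cyt (uM), ca_store (uM), v_m (mV), ip3 (uM), g_prot
#   (molecules of activated G-protein).
# SMC state: ca_cyt, ca_store, v_m, w_k (K-channel open fraction), ip3.
#
# The calcium/membrane machinery follows the minimal EC/SMC formulations of
# the Koenigsberger model family (CICR, SERCA uptake, store leak, extrusion,
# nonselective cation influx and Ca-gated K currents in the EC; VOCC,
# Na+/Ca2+ exchange, Cl- and Ca-gated K currents in the SMC).  IP3 production
# in the EC follows the receptor-level agonist pathway: ATP binds P2Y
# receptors, activates G-protein, which with cytosolic calcium activates PLC
# to hydrolyse PIP2 into IP3.  SMC IP3 has no intrinsic production; it
# arrives only through myoendothelial gap junctions and decays first-order.

#' IP3-pathway parameters (agonist to IP3 production)
#'
#' @param alpha Effective PLC signal gain (1/s per activated G-protein
#'   molecule).  This gain is not separately measurable; the default is
#'   calibrated so that apex-level ATP (1 uM) drives the coupled SMC into
#'   its oscillatory window while seam-level ATP (0.2 uM) leaves it just
#'   below threshold (see the methods vignette).
#' @param K_Ca Dissociation constant for calcium binding to PLC (uM).
#' @param k_a,k_d G-protein activation and deactivation rates (1/s).
#' @param delta Intrinsic (agonist-independent) G-protein activity.
#' @param G_prot_tot Total G-protein molecules per EC.
#' @param K_ATP Michaelis constant for ATP binding to P2Y receptors (uM).
#' @param PIP2_tot Total PIP2 molecules, treated as constant.
#' @param u_c Unit conversion (uM per mol/L, i.e. 1e6).
#' @param N_a Avogadro's number (1/mol).
#' @param V_EC EC cytosolic volume (L).
#' @param k_deg First-order IP3 degradation rate in the EC (1/s).
#' @return List of class `ip3_params`; includes the derived
#'   `eps = u_c / (N_a * V_EC)` (uM per molecule).
#' @export
ip3_params <- function(alpha = 3.1e-6, K_Ca = 0.4, k_a = 0.017, k_d = 0.15,
                       delta = 1.235e-3, G_prot_tot = 1e5, K_ATP = 0.1,
                       PIP2_tot = 5.0e7, u_c = 1e6, N_a = 6.02214076e23,
                       V_EC = 1e-12, k_deg = 1.25) {
  p <- as.list(environment())
  if (any(unlist(p[c("alpha", "K_Ca", "k_a", "k_d", "G_prot_tot", "K_ATP",
                     "PIP2_tot", "u_c", "N_a", "V_EC", "k_deg")]) <= 0) ||
      delta < 0) {
    abort("ip3_params: rates and constants must be positive (delta >= 0)")
  }
  p$eps <- u_c / (N_a * V_EC)
  structure(p, class = "ip3_params")
}

#' EC model parameters
#'
#' Flux constants of the endothelial cell: IP3-gated store release, SERCA
#' uptake, CICR, extrusion, store leak, nonselective cation influx, a
#' constant background calcium influx, BK/SK calcium-gated potassium
#' currents, a residual current, and the membrane capacitance.
#' Conductances in nS, capacitance in pF, concentrations in uM,
#' potentials in mV, time in s.
#'
#' @param ... Override any default constant by name.
#' @return List of class `ec_params`.
#' @export
ec_params <- function(...) {
  p <- list(
    F_ip3 = 0.23, K_r = 1,            # IP3-gated store release (uM/s, uM)
    B = 0.5, c_b = 1,                 # SERCA uptake
    C_cicr = 5, s_c = 2, c_c = 0.9,   # CICR
    D = 0.24,                         # extrusion (1/s)
    L = 0.025,                        # store leak (1/s)
    G_cat = 6.6e-4, E_Ca = 50,        # nonselective cation channel
    m3cat = -0.18, m4cat = 0.37,      # (log10 uM gating)
    J0 = 0.029,                       # background Ca influx (uM/s)
    G_tot = 6.927, v_K = -80,         # total K conductance (nS), K reversal
    a1 = 53.3, a2 = 53.3, b_bk = -80.8, c_bk = -0.4,
    m3b = 1.32e-3, m4b = 0.3,         # BK gating surface
    m3s = -0.28, m4s = 0.389,         # SK gating
    G_R = 0.955, v_rest = -31.1,      # residual current (nS, mV)
    C_m = 30)                         # membrane capacitance (pF)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) abort(paste("unknown ec_params:", paste(bad, collapse = ", ")))
  p[names(over)] <- over
  structure(p, class = "ec_params")
}

#' SMC model parameters
#'
#' Flux constants of the smooth muscle cell: IP3-gated store release, SERCA
#' uptake, CICR, voltage-dependent extrusion, store leak, voltage-operated
#' calcium channels (VOCC), Na+/Ca2+ exchange, Na+/K+ pump, Cl- and
#' Ca-gated K+ currents, the K-channel activation kinetics and the
#' flux-to-voltage scaling `gamma`.  Units as in [ec_params()]; channel
#' "conductances" are expressed as calcium flux coefficients
#' (uM mV^-1 s^-1).
#'
#' @param ... Override any default constant by name.
#' @return List of class `smc_params`.
#' @export
smc_params <- function(...) {
  p <- list(
    F_ip3 = 0.23, K_r = 1,
    B = 2.025, c_b = 1,
    C_cicr = 55, s_c = 2, c_c = 0.9,
    D = 0.24, v_d = -100, R_d = 250,
    L = 0.025,
    G_Ca = 1.29e-3, v_Ca1 = 100, v_Ca2 = -24, R_Ca = 8.5,
    G_NaCa = 3.16e-3, c_NaCa = 0.5, v_NaCa = -30,
    F_NaK = 0.0432,
    G_Cl = 1.34e-3, v_Cl = -25,
    G_K = 4.46e-3, v_K = -94,
    lambda_w = 45, c_w = 0, beta = 0.13, v_Ca3 = -27, R_K = 12,
    gamma = 1970,                      # mV/uM flux-to-voltage scaling
    k_deg = 0.1,                       # SMC IP3 degradation (1/s)
    C_m = 10)                          # pF (recorded; gamma already scales v)
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) abort(paste("unknown smc_params:", paste(bad, collapse = ", ")))
  p[names(over)] <- over
  structure(p, class = "smc_params")
}

#' Fraction of agonist-bound P2Y receptors
#'
#' Fast-kinetics receptor occupancy: `atp / (K_ATP + atp)`.
#'
#' @param atp Luminal ATP concentration (uM), non-negative.
#' @param K_ATP Michaelis constant (uM), positive.
#' @return Bound fraction in `[0, 1)`.
#' @export
rho_p2y <- function(atp, K_ATP) {
  if (any(atp < 0)) abort("`atp` must be non-negative")
  if (any(K_ATP <= 0)) abort("`K_ATP` must be positive")
  atp / (K_ATP + atp)
}

#' Activated G-protein kinetics
#'
#' `dG/dt = k_a (delta + rho) (G_tot - G) - k_d G`.  The interval
#' `[0, G_tot]` is invariant for any non-negative receptor occupancy.
#'
#' @param g_prot Activated G-protein (molecules).
#' @param rho Bound P2Y receptor fraction.
#' @param params An [ip3_params()] list.
#' @return Time derivative (molecules/s).
#' @export
g_protein_rate <- function(g_prot, rho, params) {
  params$k_a * (params$delta + rho) * (params$G_prot_tot - g_prot) -
    params$k_d * g_prot
}

#' PIP2 hydrolysis rate by activated PLC
#'
#' `r_h = alpha * ca / (ca + K_Ca) * g_prot` (1/s): linear in activated
#' G-protein, Michaelis--Menten in cytosolic calcium.
#'
#' @param ca_cyt EC cytosolic calcium (uM).
#' @param g_prot Activated G-protein (molecules).
#' @param params An [ip3_params()] list.
#' @return Hydrolysis rate (1/s).
#' @export
plc_hydrolysis_rate <- function(ca_cyt, g_prot, params) {
  params$alpha * (ca_cyt / (ca_cyt + params$K_Ca)) * g_prot
}

#' EC IP3 balance
#'
#' `dI/dt = eps * r_h * PIP2_tot - k_deg * I + coupling`.
#'
#' @param ip3 EC IP3 concentration (uM).
#' @param rh PIP2 hydrolysis rate (1/s), from [plc_hydrolysis_rate()].
#' @param coupling Net gap-junctional IP3 flux into the cell (uM/s).
#' @param params An [ip3_params()] list.
#' @return dI/dt (uM/s).
#' @export
ec_ip3_rate <- function(ip3, rh, coupling, params) {
  params$eps * rh * params$PIP2_tot - params$k_deg * ip3 + coupling
}

.check_state <- function(state, who) {
  bad <- !vapply(state, function(v) all(is.finite(v)), logical(1))
  if (any(bad)) {
    idx <- which(!is.finite(state[[which(bad)[1]]]))[1]
    abort(sprintf("non-finite %s state in species `%s` at cell %d",
                  who, names(state)[which(bad)[1]], idx))
  }
}

#' EC right-hand side
#'
#' Complete time derivative of the EC state.  `state` is a list (or
#' one-row tibble) of equal-length numeric vectors `ca_cyt`, `ca_store`,
#' `v_m`, `ip3`, `g_prot`; the function is vectorized over cells.
#'
#' @param state Named list of EC state vectors.
#' @param atp Luminal ATP (uM), scalar or per cell.
#' @param coupling Named list of gap-junctional fluxes into each cell:
#'   `ca` (uM/s), `ip3` (uM/s), `vm` (mV/s).  Defaults to zero.
#' @param params [ec_params()].
#' @param ip3_pars [ip3_params()].
#' @return Named list of derivatives of each state field.
#' @export
ec_rhs <- function(state, atp, coupling = list(ca = 0, ip3 = 0, vm = 0),
                   params = ec_params(), ip3_pars = ip3_params()) {
  .check_state(state, "EC")
  c_ <- state$ca_cyt; s_ <- state$ca_store; v <- state$v_m
  I <- state$ip3; G <- state$g_prot
  p <- params
  lc <- log10(pmax(c_, 1e-8))
  f_ip3 <- p$F_ip3 * I^2 / (p$K_r^2 + I^2)
  f_up <- p$B * c_^2 / (p$c_b^2 + c_^2)
  f_cicr <- p$C_cicr * (s_^2 / (p$s_c^2 + s_^2)) * (c_^4 / (p$c_c^4 + c_^4))
  f_ext <- p$D * c_
  f_leak <- p$L * s_
  f_cat <- p$G_cat * (p$E_Ca - v) * 0.5 * (1 + tanh((lc - p$m3cat) / p$m4cat))
  k_bk <- 0.2 * (1 + tanh(((lc - p$c_bk) * (v - p$b_bk) - p$a1) /
                            (p$m3b * (v + p$a2 * (lc - p$c_bk) - p$b_bk)^2 + p$m4b))) +
    0.3 * (1 + tanh((lc - p$m3s) / p$m4s))
  I_K <- p$G_tot * k_bk * (v - p$v_K)      # pA (nS * mV)
  I_R <- p$G_R * (v - p$v_rest)
  rho <- rho_p2y(atp, ip3_pars$K_ATP)
  rh <- plc_hydrolysis_rate(c_, G, ip3_pars)
  list(
    ca_cyt = f_ip3 - f_up + f_cicr - f_ext + f_leak + f_cat + p$J0 + coupling$ca,
    ca_store = f_up - f_cicr - f_leak,
    v_m = -1000 * (I_K + I_R) / p$C_m + coupling$vm,   # pA/pF -> mV/s
    ip3 = ec_ip3_rate(I, rh, coupling$ip3, ip3_pars),
    g_prot = g_protein_rate(G, rho, ip3_pars))
}

#' SMC right-hand side
#'
#' Complete time derivative of the SMC state (vectorized over cells).  SMC
#' IP3 has no intrinsic production: it is sourced from coupled ECs and
#' degrades first-order.
#'
#' @param state Named list of SMC state vectors `ca_cyt`, `ca_store`, `v_m`,
#'   `w_k`, `ip3`.
#' @param coupling Named list of fluxes into each cell (`ca`, `ip3`, `vm`).
#' @param params [smc_params()].
#' @return Named list of derivatives.
#' @export
smc_rhs <- function(state, coupling = list(ca = 0, ip3 = 0, vm = 0),
                    params = smc_params()) {
  .check_state(state, "SMC")
  c_ <- state$ca_cyt; s_ <- state$ca_store; v <- state$v_m
  w <- state$w_k; I <- state$ip3
  p <- params
  f_ip3 <- p$F_ip3 * I^2 / (p$K_r^2 + I^2)
  f_up <- p$B * c_^2 / (p$c_b^2 + c_^2)
  f_cicr <- p$C_cicr * (s_^2 / (p$s_c^2 + s_^2)) * (c_^4 / (p$c_c^4 + c_^4))
  f_ext <- p$D * c_ * (1 + (v - p$v_d) / p$R_d)
  f_leak <- p$L * s_
  f_vocc <- p$G_Ca * (v - p$v_Ca1) / (1 + exp(-(v - p$v_Ca2) / p$R_Ca))
  f_naca <- p$G_NaCa * (c_ / (c_ + p$c_NaCa)) * (v - p$v_NaCa)
  f_cl <- p$G_Cl * (v - p$v_Cl)
  f_k <- p$G_K * w * (v - p$v_K)
  k_act <- (c_ + p$c_w)^2 / ((c_ + p$c_w)^2 + p$beta * exp(-(v - p$v_Ca3) / p$R_K))
  list(
    ca_cyt = f_ip3 - f_up + f_cicr - f_ext + f_leak - f_vocc + f_naca + coupling$ca,
    ca_store = f_up - f_cicr - f_leak,
    v_m = p$gamma * (-p$F_NaK - f_cl - 2 * f_vocc - f_naca - f_k) + coupling$vm,
    w_k = p$lambda_w * (k_act - w),
    ip3 = -p$k_deg * I + coupling$ip3)
}

# integrate a single cell of either type to (near) steady state at the given
# agonist level; used to construct rest-state initial conditions.
single_cell_rest <- function(type = c("ec", "smc"), atp = 0,
                             params = NULL, ip3_pars = ip3_params(),
                             t_settle = 2000) {
  type <- match.arg(type)
  if (type == "ec") {
    params <- params %||% ec_params()
    y0 <- c(ca_cyt = 0.1, ca_store = 1, v_m = -40, ip3 = 0, g_prot = 0)
    f <- function(t, y, parms) {
      st <- as.list(y)
      list(unlist(ec_rhs(st, atp = atp, params = params, ip3_pars = ip3_pars),
                  use.names = FALSE))
    }
  } else {
    params <- params %||% smc_params()
    y0 <- c(ca_cyt = 0.2, ca_store = 1, v_m = -40, w_k = 0.1, ip3 = 0)
    f <- function(t, y, parms) {
      st <- as.list(y)
      list(unlist(smc_rhs(st, params = params), use.names = FALSE))
    }
  }
  out <- deSolve::ode(y0, c(0, t_settle / 2, t_settle), f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  setNames(as.numeric(out[nrow(out), -1]), names(y0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# rest state of one coupled EC/SMC unit (myoendothelial weight w_het) at the
# given agonist level: the lattice rest state is this unit replicated, since
# every SMC carries exactly 208/80 EC-link weight.
coupled_unit_rest <- function(atp = 0, ec_pars = ec_params(),
                              smc_pars = smc_params(),
                              ip3_pars = ip3_params(),
                              cpl = coupling_params(),
                              w_het = 208 / 80, t_settle = 3000) {
  f <- function(t, y, parms) {
    ec <- list(ca_cyt = y[1], ca_store = y[2], v_m = y[3], ip3 = y[4],
               g_prot = y[5])
    smc <- list(ca_cyt = y[6], ca_store = y[7], v_m = y[8], w_k = y[9],
                ip3 = y[10])
    zf <- cpl$zF_RT_ca
    J_ca <- cpl$p_ca_hetero * ((smc$ca_cyt - ec$ca_cyt) +
                                 zf * (smc$ca_cyt + ec$ca_cyt) / 2 *
                                   (smc$v_m - ec$v_m))
    J_ip <- cpl$p_ip3_hetero * (smc$ip3 - ec$ip3)
    J_vm <- cpl$g_hetero * (smc$v_m - ec$v_m)
    # each EC carries unit link weight; each SMC aggregates w_het of them
    d_ec <- ec_rhs(ec, atp, list(ca = J_ca, ip3 = J_ip, vm = J_vm),
                   ec_pars, ip3_pars)
    d_smc <- smc_rhs(smc, list(ca = -w_het * J_ca, ip3 = -w_het * J_ip,
                               vm = -w_het * J_vm), smc_pars)
    list(c(unlist(d_ec, use.names = FALSE), unlist(d_smc, use.names = FALSE)))
  }
  y0 <- c(0.1, 1, -40, 0, 0, 0.2, 1, -40, 0.1, 0)
  out <- deSolve::ode(y0, c(0, t_settle / 2, t_settle), f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  y <- as.numeric(out[nrow(out), -1])
  list(ec = setNames(y[1:5], EC_FIELDS), smc = setNames(y[6:10], SMC_FIELDS))
}
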