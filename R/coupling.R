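# Gap-junctional exchange between neighboring cells: electro-diffusive
# currents for calcium (concentration gradient + membrane-potential drift),
# Fickian diffusion for IP3 (zero valence), and ohmic membrane-potential
# coupling, at homocellular and myoendothelial (heterocellular) junctions.

FARADAY <- 96485.33212      # C/mol
GAS_R <- 8.314462618        # J/(mol K)

#' Gap-junction coupling parameters
#'
#' Rate coefficients (1/s) convert neighbor differences directly into state
#' rates: electrical coefficients are `g = G / C_m` (1000 1/s homocellular
#' for both layers from a 30 nS mean junctional conductance and 30 pF EC /
#' 10 pF SMC capacitances of matching order; 50 1/s heterocellular from a
#' 900 MOhm myoendothelial resistance and ~20 pF net capacitance), and the
#' species coefficients absorb `P_x sigma A_segment / (dx V_cell)`.
#' The raw electro-diffusive current of [electro_diffusive_current()] uses
#' the physical constants directly.
#'
#' @param g_homo_ec,g_homo_smc Homocellular electrical coefficients (1/s).
#' @param g_hetero Heterocellular electrical coefficient (1/s).
#' @param p_ca_homo_ec,p_ca_homo_smc Homocellular calcium coefficients (1/s).
#' @param p_ca_hetero Heterocellular calcium coefficient (1/s).
#' @param p_ip3_homo,p_ip3_hetero IP3 (Fickian) coefficients (1/s).
#' @param P_x Gap-junction permeability to calcium (um/s), for the raw
#'   current form.
#' @param sigma Dimensionless gap-junction scaling factor.
#' @param A_segment Neighbor interface area (um^2).
#' @param dx Intercellular distance (um).
#' @param T Absolute temperature (K).
#' @return List of class `coupling_params`.
#' @export
coupling_params <- function(g_homo_ec = 1000, g_homo_smc = 1000,
                            g_hetero = 50,
                            p_ca_homo_ec = 0.05, p_ca_homo_smc = 0.05,
                            p_ca_hetero = 0.05,
                            p_ip3_homo = 0.05, p_ip3_hetero = 0.05,
                            P_x = 0.05, sigma = 1, A_segment = 25,
                            dx = 25, T = 310) {
  p <- as.list(environment())
  if (any(unlist(p) < 0)) abort("coupling coefficients must be non-negative")
  if (T <= 0) abort("temperature must be positive")
  # drift factor z F / (R T) per mV, for z = +2 (calcium)
  p$zF_RT_ca <- 2 * FARADAY / (GAS_R * T) / 1000
  structure(p, class = "coupling_params")
}

#' Electro-diffusive gap-junction current
#'
#' The junctional current for an ion of valence `z` between cells `a` and
#' `b` combines the Fickian concentration-gradient term with a drift term
#' proportional to the membrane-potential gradient:
#' `I = P_x sigma A F [ grad(phi) + (zF/RT) mean(phi) grad(Vm) ]`,
#' where gradients are neighbor differences over the intercellular distance
#' and `mean(phi)` is the arithmetic mean concentration.  The sign
#' convention is flux from `b` into `a`; swapping the cells negates the
#' current.  For IP3 (`z = 0`) the drift term vanishes and the current is
#' purely Fickian.
#'
#' @param conc_a,conc_b Species concentrations in the two cells (uM).
#' @param vm_a,vm_b Membrane potentials (mV).
#' @param ion `"ca"` (z = +2) or `"ip3"` (z = 0).
#' @param params [coupling_params()].
#' @return Current (aC/s = 1e-18 A per unit sigma), positive into cell `a`.
#' @export
electro_diffusive_current <- function(conc_a, conc_b, vm_a, vm_b,
                                      ion = c("ca", "ip3"),
                                      params = coupling_params()) {
  ion <- match.arg(ion)
  if (any(conc_a < 0) || any(conc_b < 0)) abort("concentrations must be >= 0")
  z <- switch(ion, ca = 2, ip3 = 0)
  grad_c <- (conc_b - conc_a) / params$dx
  grad_v <- (vm_b - vm_a) / params$dx
  cbar <- (conc_a + conc_b) / 2
  drift <- z * FARADAY / (GAS_R * params$T * 1000) * cbar * grad_v
  params$P_x * params$sigma * params$A_segment * FARADAY * (grad_c + drift)
}

#' Ohmic membrane-potential coupling
#'
#' Rate of change of cell `a`'s membrane potential due to a gap junction to
#' cell `b`: `coefficient * (vm_b - vm_a)` with `coefficient = G / C_m`.
#'
#' @param vm_a,vm_b Membrane potentials (mV).
#' @param coefficient Coupling coefficient `g` (1/s), non-negative.
#' @return mV/s into cell `a`.
#' @export
membrane_potential_coupling <- function(vm_a, vm_b, coefficient) {
  if (any(coefficient < 0)) abort("coupling coefficient must be non-negative")
  coefficient * (vm_b - vm_a)
}

#' Electrical coupling coefficient from conductance and capacitance
#'
#' `g = G / C_m`; with `G` in nS and `C_m` in pF the result is in 1/s.
#'
#' @param G_nS Junctional conductance (nS).
#' @param C_pF Membrane capacitance (pF).
#' @return Coefficient (1/s).
#' @export
conductance_to_coefficient <- function(G_nS, C_pF) 1000 * G_nS / C_pF

#' Conductance from junctional resistance
#'
#' @param R_MOhm Resistance in megaohms.
#' @return Conductance in nS (`1e3 / R_MOhm`).
#' @export
resistance_to_conductance <- function(R_MOhm) 1000 / R_MOhm

# --- lattice-level coupling -------------------------------------------------

# neighbor index matrices padded with self-indices produce zero flux at
# missing links without branching.
.pad_self <- function(nb) {
  self <- matrix(rep(seq_len(nrow(nb)), 4), ncol = 4)
  nb[is.na(nb)] <- self[is.na(nb)]
  nb
}

.homo_sum <- function(x, nb) {
  # sum over the 4 neighbor slots of (x[neighbor] - x)
  (x[nb[, 1]] + x[nb[, 2]] + x[nb[, 3]] + x[nb[, 4]]) - 4 * x
}

.homo_electro_ca <- function(c_, v, nb, p_ca, zf) {
  s <- 0
  for (k in 1:4) {
    cn <- c_[nb[, k]]; vn <- v[nb[, k]]
    s <- s + (cn - c_) + zf * (c_ + cn) / 2 * (vn - v)
  }
  p_ca * s
}

#' Gap-junction coupling fluxes over a lattice
#'
#' Evaluates, for every EC and SMC, the net gap-junctional rates for
#' calcium (electro-diffusive), IP3 (Fickian) and membrane potential,
#' summing homocellular 4-neighborhoods and weighted myoendothelial links.
#' Pairwise antisymmetry makes each species' fluxes sum to zero over the
#' whole lattice (membrane potential sums to zero when the two sides use
#' equal coefficients, as in the defaults).
#'
#' @param lattice A `cell_lattice` (or the internal padded form).
#' @param states Named list with elements `ec` and `smc`, each a named list
#'   of state vectors as in [ec_rhs()] / [smc_rhs()].
#' @param params [coupling_params()].
#' @return List with elements `ec` and `smc`, each a list of per-cell rates
#'   `ca` (uM/s), `ip3` (uM/s), `vm` (mV/s).
#' @export
coupling_terms <- function(lattice, states, params = coupling_params()) {
  ec <- states$ec; smc <- states$smc
  nbE <- .pad_self(lattice$ec_nb)
  nbS <- .pad_self(lattice$smc_nb)
  if (max(nbE) > length(ec$ca_cyt) || max(nbS) > length(smc$ca_cyt)) {
    abort("dangling neighbor index: lattice and state sizes disagree")
  }
  W <- lattice$hetero                 # nE x nS, rows sum to 1
  zf <- params$zF_RT_ca
  # homocellular
  ec_ca <- .homo_electro_ca(ec$ca_cyt, ec$v_m, nbE, params$p_ca_homo_ec, zf)
  ec_ip <- params$p_ip3_homo * .homo_sum(ec$ip3, nbE)
  ec_vm <- params$g_homo_ec * .homo_sum(ec$v_m, nbE)
  smc_ca <- .homo_electro_ca(smc$ca_cyt, smc$v_m, nbS, params$p_ca_homo_smc, zf)
  smc_ip <- params$p_ip3_homo * .homo_sum(smc$ip3, nbS)
  smc_vm <- params$g_homo_smc * .homo_sum(smc$v_m, nbS)
  # heterocellular: pairwise flux into the EC; exact negation into the SMC
  wsumE <- Matrix::rowSums(W)         # 1 by construction (0 for unlinked)
  wS <- Matrix::colSums(W)
  Wc <- as.numeric(W %*% smc$ca_cyt); Wv <- as.numeric(W %*% smc$v_m)
  Wi <- as.numeric(W %*% smc$ip3)
  tWc <- as.numeric(Matrix::crossprod(W, ec$ca_cyt))
  tWv <- as.numeric(Matrix::crossprod(W, ec$v_m))
  tWi <- as.numeric(Matrix::crossprod(W, ec$ip3))
  Wcv <- as.numeric(W %*% (smc$ca_cyt * smc$v_m))
  tWcv <- as.numeric(Matrix::crossprod(W, ec$ca_cyt * ec$v_m))
  # drift term: sum_j w_ij (c_i + c_j)/2 (v_j - v_i)
  #   = 0.5 [ c_i Wv - c_i w_i v_i + W(cv) - v_i Wc ]
  drift_ec <- 0.5 * (ec$ca_cyt * Wv - ec$ca_cyt * wsumE * ec$v_m +
                       Wcv - ec$v_m * Wc)
  h_ec_ca <- params$p_ca_hetero * ((Wc - wsumE * ec$ca_cyt) + zf * drift_ec)
  h_ec_ip <- params$p_ip3_hetero * (Wi - wsumE * ec$ip3)
  h_ec_vm <- params$g_hetero * (Wv - wsumE * ec$v_m)
  # SMC side: negate each pairwise flux and re-aggregate over columns
  drift_smc <- 0.5 * (smc$ca_cyt * tWv - smc$ca_cyt * wS * smc$v_m +
                        tWcv - smc$v_m * tWc)
  h_smc_ca <- params$p_ca_hetero * ((tWc - wS * smc$ca_cyt) + zf * drift_smc)
  h_smc_ip <- params$p_ip3_hetero * (tWi - wS * smc$ip3)
  h_smc_vm <- params$g_hetero * (tWv - wS * smc$v_m)
  list(
    ec = list(ca = ec_ca + h_ec_ca, ip3 = ec_ip + h_ec_ip, vm = ec_vm + h_ec_vm),
    smc = list(ca = smc_ca + h_smc_ca, ip3 = smc_ip + h_smc_ip,
               vm = smc_vm + h_smc_vm))
}
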