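# Reference parameter set (versioned).  Units follow the package convention:
# concentrations uM, potentials mV, time s, conductances nS, capacitance pF,
# G-protein and PIP2 pools in molecules.
version: 1
ip3:
  alpha: 3.1e-6        # PLC signal gain, 1/s per activated G-protein molecule
  K_Ca: 0.4            # Ca-PLC dissociation constant, uM
  k_a: 0.017           # G-protein activation rate, 1/s
  k_d: 0.15            # G-protein deactivation rate, 1/s
  delta: 1.235e-3      # intrinsic G-protein activity, dimensionless
  G_prot_tot: 1.0e+5    # total G-protein molecules per EC
  K_ATP: 0.1           # ATP-P2Y Michaelis constant, uM
  PIP2_tot: 5.0e+7      # total PIP2 molecules
  u_c: 1.0e+6           # uM per mol/L
  N_a: 6.02214076e+23   # Avogadro, 1/mol
  V_EC: 1.0e-12        # EC cytosolic volume, L
  k_deg: 1.25          # EC IP3 degradation, 1/s
ec:
  F_ip3: 0.23
  K_r: 1
  B: 0.5
  c_b: 1
  C_cicr: 5
  s_c: 2
  c_c: 0.9
  D: 0.24
  L: 0.025
  G_cat: 6.6e-4
  E_Ca: 50
  m3cat: -0.18
  m4cat: 0.37
  J0: 0.029
  G_tot: 6.927
  v_K: -80
  a1: 53.3
  a2: 53.3
  b_bk: -80.8
  c_bk: -0.4
  m3b: 1.32e-3
  m4b: 0.3
  m3s: -0.28
  m4s: 0.389
  G_R: 0.955
  v_rest: -31.1
  C_m: 30              # EC membrane capacitance, pF
smc:
  F_ip3: 0.23
  K_r: 1
  B: 2.025
  c_b: 1
  C_cicr: 55
  s_c: 2
  c_c: 0.9
  D: 0.24
  v_d: -100
  R_d: 250
  L: 0.025
  G_Ca: 1.29e-3
  v_Ca1: 100
  v_Ca2: -24
  R_Ca: 8.5
  G_NaCa: 3.16e-3
  c_NaCa: 0.5
  v_NaCa: -30
  F_NaK: 0.0432
  G_Cl: 1.34e-3
  v_Cl: -25
  G_K: 4.46e-3
  v_K: -94
  lambda_w: 45
  c_w: 0
  beta: 0.13
  v_Ca3: -27
  R_K: 12
  gamma: 1970
  k_deg: 0.1
  C_m: 10              # SMC membrane capacitance, pF
coupling:
  g_homo_ec: 1000      # 1/s
  g_homo_smc: 1000
  g_hetero: 50
  p_ca_homo_ec: 0.05
  p_ca_homo_smc: 0.05
  p_ca_hetero: 0.05
  p_ip3_homo: 0.05
  p_ip3_hetero: 0.05
  P_x: 0.05            # um/s
  sigma: 1
  A_segment: 25        # um^2
  dx: 25               # um
  T: 310               # K
phospho:
  v_p: 2               # max phosphatase rate, 1/s
  W_T: 1
  K_1: 0.01
  K_2: 0.01
  V_MK: 4              # max kinase rate, 1/s
  K_a: 0.45            # kinase Ca half-activation, uM
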