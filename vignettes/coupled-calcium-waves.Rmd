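---
title: "Coupled EC/SMC calcium dynamics on bifurcating arterial surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled EC/SMC calcium dynamics on bifurcating arterial surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bifwave)
```

## The problem

Atherosclerotic plaques form preferentially near arterial bifurcations,
where disturbed flow produces spatially varying agonist concentrations at
the endothelial surface.  `bifwave` simulates how a steady luminal ATP
field, high at the bifurcation apex and low over the lateral seams, drives
calcium signalling in the two coupled cell layers of the arterial wall:
endothelial cells (ECs) facing the lumen and smooth muscle cells (SMCs)
beneath them.  The package builds the geometry (parametric, non-planar
bifurcation surfaces obeying Murray's law $r_p^3 = r_{d1}^3 + r_{d2}^3$),
the agonist field, the coupled ordinary-differential-equation network over
the cell lattice, and the post-processing that summarizes the resulting
calcium waves and their frequency-encoded effect on protein
phosphorylation.

## Cell lattice

Each quadrilateral surface domain carries 208 axially elongated ECs
(13 axial x 16 circumferential) and 80 circumferentially elongated SMCs
(4 x 20), 288 cells in total; a reference surface of 4080 domains holds
1,175,040 cells.  Only the totals and orientations are constrained by the
biology, so the factorizations are a package choice: they respect the
orthogonal alignment of the two layers and tile the same unit square.
Homocellular gap junctions form a 4-neighborhood, periodic around the
circumference; myoendothelial (EC-SMC) junctions are assigned by geometric
overlap of the two grids, with weights proportional to overlap area and
normalized to sum to one over each EC.  A consequence worth remembering is
that every SMC then aggregates exactly $208/80 = 2.6$ units of EC link
weight; the pair and chain fixtures reproduce this multiplicity so that a
single EC/SMC unit behaves like one column of the full lattice.

## Single-cell models

The single-cell dynamics follow the minimal EC/SMC formulations of the
Koenigsberger model family.  The SMC state is (cytosolic Ca$^{2+}$ $c$,
store Ca$^{2+}$ $s$, membrane potential $v$, K$^+$-channel open fraction
$w$, IP$_3$ $I$), with IP$_3$-gated store release, calcium-induced calcium
release (CICR), SERCA uptake, store leak, voltage-dependent extrusion,
voltage-operated calcium channels (VOCC), Na$^+$/Ca$^{2+}$ exchange, and
Cl$^-$/K$^+$ currents; the flux-to-voltage factor $\gamma = 1970$ mV/uM
converts the net ionic calcium-equivalent flux into membrane-potential
change.  The EC carries (c, s, v, I) plus activated G-protein, with a
nonselective cation influx, a constant background influx, and BK/SK
calcium-gated potassium currents whose activation surface depends on both
calcium and voltage.  All constants are recorded in the versioned
parameter file `inst/extdata/reference_params.yaml` and as the defaults of
`ec_params()`, `smc_params()`, `ip3_params()`.

IP$_3$ production in the EC is receptor-resolved rather than a lumped
ATP-to-IP$_3$ gain: ATP occupies P2Y receptors with fast kinetics
($\rho = [ATP]/(K_{ATP} + [ATP])$), occupancy activates G-protein
($dG/dt = k_a(\delta+\rho)(G_{tot}-G) - k_d G$, which keeps $G$ in
$[0, G_{tot}]$ for any non-negative input), and activated G-protein with
cytosolic calcium activates PLC to hydrolyse a constant PIP$_2$ pool:
$r_h = \alpha\, c/(c+K_{Ca})\, G$ and
$dI/dt = \epsilon\, r_h\, \mathrm{PIP2}_{tot} - k_{deg} I + \mathrm{coupling}$,
with $\epsilon = u_c/(N_A V_{EC})$ converting molecules to uM.  SMC IP$_3$
has no intrinsic production: it arrives only through myoendothelial
junctions and decays first order.

### Calibration of the receptor gain

Two pathway constants are not independently measurable and were identified
once, before the acceptance machinery was written, against the qualitative
regime structure the model must reproduce: at apex-level ATP (1 uM) the
coupled SMC must sit just inside its oscillatory window (slow, large
relaxation oscillations), while at seam-level ATP (0.2 uM) it must sit just
below threshold with elevated EC calcium.  This fixes the PLC signal gain
$\alpha = 3.1\times10^{-6}$ s$^{-1}$ per molecule and
$K_{ATP} = 0.1$ uM (within the reported sub-micromolar potency range of
ATP at endothelial P2Y receptors).  With these values the apex regime
oscillates with a period near 17 s and ~0.66 uM peaks, and the seam regime
rests at ~0.21 uM SMC calcium with the EC near 0.6 uM.  Two quantitative
features of the reference phenomenology are *not* reproduced and are
deliberately left so rather than distorting published flux constants: the
SMC spike ceiling of this model family is ~0.7 uM rather than ~1 uM, and a
spatially uniform seam-level patch produces no sporadic spikes (in the
full spatially graded system those spikes are wave invasions from
higher-ATP neighborhoods, which a uniform patch cannot supply).

## Gap-junction coupling

Charged species couple electro-diffusively: the junctional current
combines the Fickian concentration-gradient term with a drift term,
$I_{gap} = P_x \sigma A F\,[\nabla c + (zF/RT)\,\bar c\,\nabla V_m]$, with
$\bar c$ the arithmetic mean of the two cells.  In the network the current
is expressed directly as a state rate with coefficients that absorb
$P_x \sigma A/(\delta x\, V_{cell})$: calcium 0.05 s$^{-1}$ (homocellular
and myoendothelial), IP$_3$ 0.05 s$^{-1}$ (purely Fickian, valence 0), and
membrane potential $g = G/C_m$ = 1000 s$^{-1}$ homocellular (30 nS mean
junctional conductance) and 50 s$^{-1}$ myoendothelial (900 MOhm junction,
~20 pF net capacitance).  Whether the myoendothelial calcium coefficient
equals the IP$_3$ value is not settled; the package defaults to 0.05 and
exposes it in `coupling_params()`.  Every pairwise flux is antisymmetric,
so each species' coupling contributions sum to zero over the lattice at
every evaluation; with the defaults this also holds for the
membrane-potential terms because both sides use equal coefficients.

## Network integration

The full system stacks all EC fields then all SMC fields, each field
contiguous across cells (a 288-cell domain is a 1440-dimensional state).
Integration uses an adaptive stiff sparse-Jacobian BDF solver
(`deSolve::lsodes`) with defaults rtol $10^{-6}$, atol $10^{-9}$; the
electrical coupling at 1000 s$^{-1}$ and the millisecond-scale EC membrane
time constant make the system genuinely stiff.  Initial conditions are the
rest state of the *coupled* EC/SMC unit at zero ATP (the two layers pull
each other's membrane potentials, so isolated single-cell rest states are
not stationary for the network), plus seeded multiplicative perturbations
of 1% per cell so that spatial symmetry can break; perturbation amplitude
and seed live in `simulation_config()`.  Snapshots of the full state are
recorded every physiological second for 500 s by default.

An optional block-wise evaluation mode (`mode = "exchange"`) mirrors a
domain-decomposed run: each quadrilateral domain is integrated separately
while cross-domain neighbor state is frozen at the start of each 0.01 s
exchange window (ghost-cell semantics).  It reproduces the continuous
solution to within a few percent of a calcium spike on the chain fixtures
and exists to make the communication-interval semantics testable, not for
speed.

## Fixtures and what they do (and do not) emulate

`generate_fixture()` provides the desk-scale study systems: `pair` (one
EC/SMC unit), `chain` (units in a line, SMCs coupled homocellularly; the
classic five-cell synchronization scenario), and `patch` (full 288-cell
domains on a periodic tube).  The reference experiments are patches of
1-16 domains, 288-4608 cells, chosen so that a 500 s trajectory integrates
in seconds-to-minutes on one CPU while preserving the per-domain lattice
structure exactly.  Uniform-ATP patches isolate the apex and seam regimes;
a `gradient` map produces propagating waves.  What the fixtures do not
emulate: the full bifurcation's spatially curved ATP field (and therefore
wave invasion of the seams from surrounding tissue), inter-segment
junction topology at scale, and any flow-mediated heterogeneity in
coupling.  Conclusions about real vessels should lean on the full mesh
plus `synthesize_atp_map()`, not on uniform patches.

The parametric agonist surrogate is `background + apex bump − seam wells`
built from Gaussian kernels around the flow divider and the two lateral
seam bands, clipped to the physiological 0.2-1.0 uM range; the seam well
width scales inversely with the bifurcation angle, so the low-ATP seam
area shrinks as the angle widens.  The anchor levels (apex 1.0, seam 0.2,
background 0.5 uM) are configuration values chosen inside the reported
physiological range, not measured quantities.

## Analysis

Per-cell temporal averages are normalized by the sample count (inclusive
endpoints) rather than by $t_f - t_i$, so the mean always lies between the
trace minimum and maximum; the default window 300-500 s excludes the
initial transient.  Oscillation metrics use prominence-based peak
detection (default 0.05 uM prominence, enough to separate spikes from
baseline jitter) with the dominant period estimated as the median
inter-peak interval and an autocorrelation fallback for sparse spiking.
Wave-front speed comes from a linear fit of threshold-crossing arrival
times against distance along a cell path, which tolerates moderate noise;
paths whose cells cross within a recording interval of each other are
flagged as having no resolvable front.

The phosphorylation module implements the zero-order ultrasensitive
kinase/phosphatase cycle: $dW^*/dt = v_p W_T [ (v_k/v_p)(1-W^*)/(K_1+1-W^*)
- W^*/(K_2+W^*) ]$ with the calcium-activated kinase rate
$v_k = V_{MK}\, \mathrm{Ca}/(K_a + \mathrm{Ca})$.  With $K_1 = K_2 = 0.01$
the steady-state $W^*$ is a sharp switch crossing $1/2$ exactly at
$v_k = v_p$; the kinase half-activation $K_a = 0.45$ uM places that
threshold between the SMC baseline and spike levels, and
$v_p W_T = 2$ s$^{-1}$ makes the cycle fast relative to the ~20 s calcium
period, so $W^*(t)$ tracks the spikes.  $W^*$ is treated as a
dimensionless fraction in $[0,1]$ throughout.  The time-averaged fraction
$\bar W^*$ (trapezoidal mean, default window the whole trace) increases
with calcium spike frequency, which is the property that makes the cycle a
frequency decoder.

## Numerical choices and degenerate inputs

Tolerances: solver rtol $10^{-6}$/atol $10^{-9}$ (halving them changes
recorded traces by well under 1% RMS on the pair fixture); rest states are
settled to rtol $10^{-10}$.  Calcium is floored at $10^{-8}$ uM inside
logarithmic channel gatings.  Non-finite states abort with the offending
cell and species named.  Degenerate agonist parameters (apex = seam =
background) produce an exactly constant field; a curvature of zero gives a
planar bifurcation; a zero-length continuation returns its checkpoint
unchanged.  Checkpoints are validated by a hash over the lattice topology,
agonist field and all parameters.

## A worked patch

```{r patch, eval = FALSE}
fx  <- generate_fixture("patch", size = 1, atp = 1.0)
net <- assemble_network(fx$lattice, fx$atp)
rec <- run_simulation(net, simulation_config(duration = 500, seed = 1))
oscillation_metrics(rec, "smc", window = c(300, 500)) |> glance()
temporal_average(rec) |> autoplot()
```

## Known limitations

* The single-cell flux constants are transcriptions of the published
  family values; the two gain constants above are calibrated, and the
  quantitative spike amplitude inherits the family's ~0.7 uM ceiling.
* Each cell has exactly four homocellular neighbors; real ECs and SMCs
  contact up to six, and EC alignment with local shear is not modeled.
* Agonist maps are steady; nitric oxide, EDH/EET pathways and
  stretch-activated channels are out of scope, as are pathological
  coupling cases.
* The parent/daughter junction shares a full ring between both daughters,
  which is a parametric surrogate for a true flow divider; domains close
  to the junction should be interpreted qualitatively.
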