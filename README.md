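# respcpg

Simulation and dynamical-systems analysis of a reduced respiratory
central pattern generator (CPG) network in R.

## The scientific problem

Some excitatory neurons of the pre-Bötzinger complex (preBötC), the
inspiratory kernel of the mammalian brainstem, are *conditional
pacemakers*: depending on their tonic drive they are quiescent,
intrinsically oscillatory (via slow inactivation of the persistent
sodium current I_NaP), or tonically active. A long-standing question
is what this intrinsic bursting capability contributes once those
neurons are embedded in the full respiratory circuit, where they
receive strong phasic inhibition from post-inspiratory (post-I) and
augmenting-expiratory (aug-E) populations of the adjacent Bötzinger
complex (BötC). This package implements a reduced activity-based
network model built to answer that question, together with the full
analysis pipeline: rhythm metrics, isolated-unit bifurcation
structure, phase-plane escape geometry, and the parameter-sweep and
inhibition-block experiments that demonstrate *masking* — the network
rhythm's mechanism and parameter dependence are essentially invariant
to whether the preBötC unit is tuned to be an oscillator or not.

## The model

Units (1 pre-I, 2 early-I, 3 post-I, 4 aug-E, optionally 5 PiCo) are
non-spiking population units,

    C dV_i/dt = -I_NaP,i - I_K,i - I_L,i - I_synI,i - I_synE,i
      dh_i/dt = (h_inf(V_i) - h_i) / tau_h(V_i)
      dp_i/dt = (d_i f_out(V_i) - p_i) / tau_p,i     (inhibitory units)

with I_NaP = g_NaP m_inf(V) h (V − E_Na) for every unit, a weak
instantaneous delayed rectifier for excitatory units, a strong
adaptation current gated by p for inhibitory units, and instantaneous
sigmoidal synaptic coupling with weights `a_ji` (excitatory), `b_ji`
(inhibitory) and tonic drives `c_1i + c_2i`. The dimensionless
weighted inhibition sum `Σ_j b_ji f_out(V_j)` is the "inhibition
level" used in all phase-plane analyses. The right-hand side is
compiled (C, via deSolve), so full attractor runs take ~0.1 s and
parameter grids run in minutes. See the methods vignette
(`vignettes/respcpg-methods.Rmd`) for assumptions, defaults and design
choices.

## Worked example

```r
library(respcpg)

cfg <- preset("oscillatory")     # baseline 4-unit net, c11 = -0.03
cfg
#> <cpg_config> 4 units (pre-I, early-I, post-I, aug-E), h_mode = dynamic, 11 state variables

tr <- find_attractor(cfg)        # integrate past the transient
tr
#> <cpg_trace> 40001 samples over 40 s, units: pre-I, early-I, post-I, aug-E, attractor: periodic

compute_metrics(tr)
#> <cpg_metrics> regime: rhythmic; T = 5.281 s (T_I = 1.161, T_E = 4.121), amplitude = 0.830, 6 cycles

validate_three_phase(tr)$valid   # pre-I/early-I -> post-I -> aug-E order
#> [1] TRUE

max(tr$inh_sum[, "pre-I"])       # peak inhibition received by pre-I
#> [1] 0.09761701

oscillation_boundaries(preset("baseline4")$units[[1]])
#> [1] -0.05957031 -0.01167969
```

The metrics line reads: the network produces a three-phase rhythm of
period 5.28 s, of which 1.16 s is inspiration (pre-I voltage above
−35 mV) and 4.12 s expiration; the pre-I output sweeps 83% of its
range. The last call shows the isolated pre-I unit is intrinsically
oscillatory only for drive c11 in roughly (−0.060, −0.012) — the
embedded network above is rhythmic far outside that interval, which is
the masking phenomenon the experiments quantify
(`compare_isolated_embedded()`, `grid_sweep()`, `drive_sweep()`,
`inhibition_block()`, `pico_suite()`).

A thin command-line wrapper for config export, simulation and
phase-plane tables is installed at `inst/cli/respcpg.R`.

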