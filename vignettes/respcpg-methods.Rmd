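---
title: "Model and methods: a reduced respiratory CPG network"
author: "respcpg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: a reduced respiratory CPG network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(respcpg)
```

## The model

`respcpg` implements a reduced (activity-based, non-spiking) model of
the mammalian respiratory central pattern generator. Each neuronal
population is a single unit whose voltage represents the population
average; populations are assumed to activate and inactivate in
synchrony without spike-level synchrony, so spiking currents are
omitted. The core network has four units — an excitatory pre-I unit
(the conditional pacemaker kernel of the pre-Bötzinger complex) and
three inhibitory units, early-I, post-I and aug-E (the latter two
representing Bötzinger-complex populations) — mutually coupled by
instantaneous sigmoidal synapses and driven by tonic excitation. An
optional fifth, excitatory PiCo (post-inspiratory complex) unit can be
included.

Unit `i` obeys

$$C \dot V_i = -I_{NaP,i} - I_{K,i} - I_{L,i} - I_{synI,i} - I_{synE,i},
\qquad \dot h_i = \frac{h_\infty(V_i) - h_i}{\tau_h(V_i)},$$

with the persistent sodium current
$I_{NaP} = g_{NaP}\, m_\infty(V)\, h\, (V - E_{Na})$ common to all
units. For excitatory units the potassium current is a weak
instantaneous delayed rectifier, $g_K n_\infty^4(V)(V - E_K)$; for
inhibitory units it is a much stronger adaptation current
$g_K\, p\, (V - E_K)$ with its own slow gating state
$\dot p_i = (d_i f_{out}(V_i) - p_i)/\tau_{p,i}$. Synaptic currents
are driven by the dimensionless weighted sums

$$\mathrm{inh}_i = \sum_j b_{ji} f_{out}(V_j), \qquad
\mathrm{exc}_i = \sum_j a_{ji} f_{out}(V_j) + c_{1i} + c_{2i},$$

multiplied by conductance scale and driving force
($I_{synI,i} = g_{synI}(V_i - E_{synI})\,\mathrm{inh}_i$, analogously
for excitation). The "level of inhibition" quantity used throughout
the phase-plane analysis is the weighted sum itself, not the current
in pA: the package's baseline peak values (≈ 0.098 for pre-I, ≈ 0.56
for post-I) are commensurate with the weight budgets
($b_{31}+b_{41}=0.14$, $b_{23}+b_{43}=0.65$), which only works under
this reading.

Units are mV, ms, nS, pF and pA throughout (nS·mV = pA, pA/pF =
mV/ms). The slow variable is the persistent-sodium inactivation `h`
with time-constant scale $\epsilon = 4000$ ms against a membrane time
of a few ms, which makes every unit a relaxation oscillator candidate.
All baseline parameter values are frozen in `preset()` and in the
packaged `inst/extdata/baseline*.cfg` files, which round-trip
bit-exactly through `read_cpg_config()`.

### Two deliberate modeling choices

**Inhibitory-unit h is integrated by default** (`h_mode = "dynamic"`).
The model equations give every unit an `h` equation, and with it the
4-unit network has 11 state variables; slaving the inhibitory `h` to
$h_\infty(V)$ yields the often-quoted 8-dimensional reduction, which
is retained as `h_mode = "quasi-steady"`. Since
$g_{NaP,inh} = 0.25$ nS is small the two modes agree closely (the test
suite pins the baseline period agreement to 5%; observed ≈ 0.3%), but
the integrated mode reproduces the reference phase-plane landmark
values slightly better, so it is the default and the mode in which the
acceptance quantities are evaluated.

**The adaptation drive coefficient is $d_i = 1$** for all inhibitory
units. No value is quoted for it in the baseline lists; with $d = 1$
the adaptation gate saturates exactly at the output range and the
baseline network reproduces the independent printed observables (peak
inhibition landmarks, the period range of 3–7 s, the inhibition-block
boundaries), so the default was fixed once at 1 and exposed in
`unit_params()`.

## Simulation and rhythm metrics

Integration uses `deSolve::lsoda` on a C implementation of the vector
field (`rel_tol` $10^{-8}$, `abs_tol` $10^{-10}$, maximum step 10 ms —
chosen for the stiff fast–slow structure; halving the tolerances moves
the network period by less than 0.1%). `find_attractor()` discards a
60 s transient (15 multiples of the slowest time constant) and then
requires either a periodic certificate — at least 4 complete cycles
with cycle-to-cycle period CV below 0.1% — or a steady one (max
$|\dot V| < 10^{-5}$ mV/ms over the final 5 s, i.e. a drift of
0.01 mV/s, far below any resolvable dynamics). Traces that meet
neither criterion within the extension cap are labeled
`undetermined`, never silently classified. Multistability was not
assumed: seeded random initial states reproduce the baseline attractor
metrics to 0.5% (tested).

Periodicity detection uses up-crossings of the pre-I voltage through
the midpoint of its recorded excursion, because small-amplitude
oscillations (near the soft upper Hopf point, or at low $g_{NaP}$)
never reach any fixed voltage landmark. The reported metrics keep the
conventional definitions: the period `T` is the mean interval between
up-crossings of $V_1$ through −35 mV, the inspiratory duration `T_I`
the mean up-to-down interval through the same threshold,
`T_E = T − T_I`, and the amplitude is max − min of the pre-I output
$f(V_1)$ over the analyzed cycles (≥ 4, with the count reported).
When the oscillation stays below −35 mV, `T` falls back to mid-range
crossings and `T_I` is flagged `NA` rather than invented.

Crossing times are refined by monotone (Fritsch–Carlson) cubic
interpolation on the bracketing samples of the 1 ms recording grid,
giving sub-sample accuracy without event-based solving.

### Regime classification

A trace is *rhythmic* if it is on a periodic attractor and the output
excursion exceeds 0.05 (sub-threshold ripple near a Hopf point does
not count). A steady trace is *tonic* when its voltage settles above
$\theta_h = -48$ mV — equivalently $h_\infty(V_{ss}) < 0.5$, i.e.
drive keeps the unit depolarized enough that persistent-sodium
deinactivation is limited — and *quiescent* otherwise. An
output-based split (e.g. steady $f_{out} > 0.5$) would misclassify
the depolarized state: the tonic fixed point of the isolated pre-I
unit sits near −38 mV where $f_{out} \approx 0.3$. The $\theta_h$
split matches the mechanism and is insensitive to wide variation of
the excursion cutoff (tested at ±50%).

### Three-phase validation

A functional eupneic rhythm requires, per cycle: pre-I onset before or
together with early-I (50 ms slack), then post-I, then aug-E, and
aug-E output exceeding post-I output at the last sample before the
next inspiratory onset. Onsets are each unit's up-crossing of the
midpoint of its own cycle range, since only pre-I has a conventional
voltage threshold. When a unit crosses its onset level more than once
per cycle, the crossing followed by the longest continuous
time-above-level wins; this rejects the brief aug-E transient spike at
the inspiratory-to-expiratory transition (post-I and aug-E compete and
post-I wins) in favor of the sustained late-expiratory surge.

## Isolated-unit analysis

With synaptic input frozen, an excitatory unit is a planar $(V, h)$
system. `find_fixed_points()` locates equilibria by a 2000-point sign
scan over $V \in [-100, 20]$ mV with root refinement (the nullcline
intersection count is at most 3, so the dense scan is cheap and
robust), and classifies stability from the analytic 2×2 Jacobian.
`hopf_point()` refines trace$(J) = 0$ with det$(J) > 0$;
`oscillation_boundaries()` bisects the simulated large-amplitude
oscillation boundary to $10^{-4}$ in the tunable drive. Both boundary
notions are reported because the canard explosion makes them nearly
coincide (within $2\times10^{-4}$ at baseline; the suite requires
0.002): at the lower boundary orbits appear at essentially full
amplitude, while the upper transition is a soft supercritical Hopf
where the 0.05 excursion cutoff biases the simulated boundary left by
a few $10^{-4}$.

`continue_transition_curve()` follows the oscillatory-to-tonic
boundary through $(g_{NaP}, c_{11})$ by warm-started re-solving at
each conductance on the grid, with a cold rescan fallback. The curve
genuinely terminates near $g_{NaP} \approx 3.9$ nS at baseline, where
the oscillatory interval closes; the truncation point is recorded
rather than extrapolated.

## Phase-plane geometry

Because `h` enters $\dot V$ linearly, the V-nullcline under frozen
input has the closed form $h(V) = -\,(I_K + I_L + I_{synI} +
I_{synE})/(g_{NaP} m_\infty(V)(V - E_{Na}))$; its folds (knees) are
roots of the analytic derivative $dh/dV$. For inhibitory units the
adaptation gate is taken at quasi-steady value in this projection.
`knee_curve()` tracks the left knee against the inhibition level and
bisects the termination level where the nullcline turns monotone (for
the intrinsically tonic tuning this happens near inhibition 0.007; for
the oscillatory tuning the nullcline is cubic down to zero
inhibition). "Escape" — the release of inspiration — is
operationalized as the first crossing per cycle of the trajectory's
$(\mathrm{inh}, h)$ projection through the left-knee curve, detected
by sign change of $h(t) - h_{LK}(\mathrm{inh}(t))$ with linear
interpolation of the knee curve and sub-sample refinement.

A caution for users comparing published landmark values: at frozen
inhibition 0.09 on the oscillatory tuning the left knee lies at
$h \approx 5.4$, far outside the invariant range $h \le 1$, so no
trajectory can cross the knee curve at that level; escape values
computed here for the two standard tunings are ≈ 0.010 and ≈ 0.015.
The companion aug-E landmarks (inhibition to aug-E ≈ 0.05 at its
minimum, ≈ 0.28 at the pre-I peak, ≈ 0.35 at the post-I peak) are
reproduced to a few percent.

## Experiments

All sweeps warm-start each point from the previous point's final state
to stay on the attractor branch — essential at low $g_{NaP}$, where
the rhythmic branch coexists with a steady state and a cold start
would drop off it. Grid and sweep resolutions are package defaults
(e.g. the riluzole-analogue box $c_{11} \in [-0.006, 0.004]$ step
0.002, $g_{NaP} \in [1.7, 4.1]$ nS step 0.1), chosen to bracket the
referenced features while keeping the full analysis suite in the
minutes range on one CPU; all are overridable arguments.

Inhibition block emulates postsynaptic antagonism: a common factor
$\kappa$ scales all inhibitory weights onto the target group — pre-I
and early-I for the preBötC protocol ($b_{31}, b_{41}, b_{32},
b_{42}$), post-I and aug-E for the BötC protocol ($b_{23}, b_{43},
b_{24}, b_{34}$); tonic drives are never scaled, and $\kappa = 1$ is
bit-identical to baseline (tested). The loss-of-rhythm boundary is
bisected to 0.5% in $\kappa$ and means literal loss of the
oscillation; the three-phase flag is reported alongside, because under
the oscillatory tuning the preBötC-block rhythm never literally dies
(an uninhibited intrinsically oscillatory pre-I keeps cycling) while
its eupneic order degrades — for that protocol the boundary metrics
are evaluated at the smallest probed $\kappa$.

## What the presets do and do not emulate

The presets are complete, self-contained model configurations — there
is no external data in this problem. They emulate the study
conditions: baseline connectivity, the two standard pre-I tunings
($c_{11} = -0.03$ oscillatory, $0.01$ tonic), modified post-I→pre-I
inhibition, and the PiCo extension. They do not represent biological
heterogeneity within populations, spiking dynamics, synaptic kinetics
beyond instantaneous sigmoids, conductance noise, or other burst
mechanisms (e.g. CAN-current variants); conclusions from passing
tests are claims about this reduced model class, not about tissue.

## Known limitations

- The adaptation coefficient $d_i$ and the inhibitory-h mode are
  resolved choices of this package (documented above); other values
  would shift quantitative landmarks.
- Phase durations tied to the −35 mV convention are undefined for
  rhythms that stay below it; `T_I` is then `NA` by design.
- The PiCo rescue question (whether an oscillatory PiCo can restore
  rhythmicity to a non-rhythmic network) is represented only by the
  package's sweep tools, not by an exhaustive search.
- Near-boundary periods diverge steeply; sweep maxima (e.g. the > 7 s
  period at the low-drive edge) require the refinement steps the
  analysis functions provide, not just a coarse grid.
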