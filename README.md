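# trnreduce

Neurons of the thalamic reticular nucleus (TRN) — the inhibitory shell
that gates information flow between thalamus and cortex — switch between
two signature firing modes: **rebound bursting** (a barrage of fast
spikes on a low-threshold Ca²⁺ potential, fired on release from
hyperpolarization) and **tonic spiking** under sustained depolarization.
`trnreduce` is an R package for dissecting the dynamics behind this
switch. It is written for computational neuroscientists who want a
conductance-based TRN model they can simulate *and* analyse: the package
pairs a full six-variable Hodgkin–Huxley-type model with a principled
three-variable reduction on which phase-plane and bifurcation analysis
becomes tractable.

## The model and its reduction

The full model is a single-compartment membrane equation

C dV/dt = −(I_Na + I_K + I_T + I_L + I_KL) + 10⁻³ I_syn(t)/A

with I_Na = g_Na m³h (V−E_Na), I_K = g_K n⁴ (V−E_K), a
Huguenard–Prince-type low-threshold calcium current
I_T = g_T p²q (V−E_T), two leaks, and first-order gate kinetics
dθ/dt = φ_θ [θ∞(V) − θ]/τ_θ(V) for θ ∈ {m, h, n, p, q}.

The reduction follows the equivalent-potential method of Kepler, Abbott
and Marder: every gate is mapped to the voltage v_θ = θ∞⁻¹(θ) that would
produce it at steady state, and variables sharing a time scale are
collapsed into weighted averages

x = ρ_V V + ρ_m v_m,  y = ρ_h v_h + ρ_n v_n + ρ_p v_p,  z = v_q,

where the weights minimize the first-order discrepancy between reduced
and full voltage dynamics and are recomputed from closed-form
expressions at every state (ρ_p = k = 0.01; ρ_h : ρ_n = ∂F/∂v_h :
∂F/∂v_n; ρ_V a quadratic root balancing ∂F/∂V, ∂F/∂v_m and C φ_m/τ_m).
In the resulting three-variable model, x acts as the membrane potential,
y as the collapsed recovery variable and z as the slow T-current
de-inactivation level; treating z as a frozen parameter of the fast
(x, y) subsystem exposes the bifurcation skeleton: rebound bursting is
of the fold/homoclinic type (rest lost through a saddle-node, spiking
terminated through a saddle-homoclinic orbit), and the tonic branch
terminates where the spiking manifold folds.

The toolkit locates all of these events numerically: `findFold()`,
`findHomoclinic()`, `findFoldCycle()` on the fast subsystem;
`findHopf()`, `findFoldCycleIsyn()`, `findFoldEquilibria()` and
`oneParameterDiagram()` on the full three-variable system in the
injected current; `detectSpikes()`/`burstStatistics()` for firing-pattern
metrics; and `runExperiment()`/`presetConfig()` for the ready-made
simulation protocols.

## A worked example

Release from a 200 ms inhibitory pulse triggers a rebound burst in the
reduced model, and the fast-subsystem detectors bound the bistable
interval of the slow variable:

```r
library(trnreduce)

p <- trnParams(gKL = 0.0152)                       # comparison parameter set
tr <- simulateReduced(p, stepProtocol(-0.05, 0, 200, 1000))
sp <- detectSpikes(tr)
sp
#> Spike train: 12 spike(s) over [230.128, 268.826] ms
burstStatistics(sp)
#> 1 burst(s); spikes per burst: 12

params <- trnParams()                              # analysis parameter set
findFold(0, params)
#> fold bifurcation at z = -66.5642 (bracket [-66.5645, -66.5639], tol 0.001)
findHomoclinic(0, params)
#> saddle-homoclinic bifurcation at z = -65.2964 (bracket [-65.2998, -65.293], tol 0.01)
findHopf(c(-0.08, 0.01), params)[[1]]
#> hopf bifurcation at Isyn = -0.0519688 (bracket [-0.052, -0.0519375], tol 0.0001)
```

The rebound burst arrives ~30 ms after release (all 12 spikes within one
39 ms burst, i.e. a single burst by the 30 ms gap criterion). The fold at
z ≈ −66.56 mV and the saddle-homoclinic orbit at z ≈ −65.30 mV bound the
fast subsystem's bistable window: inside it a stable rest state and the
spiking limit cycle coexist, which is what lets the slow variable sweep
the neuron through a burst. The Hopf point at I_syn ≈ −0.052 marks where
sustained inhibition turns the resting state into a periodic burster.

The ready-made protocol presets (`presetNames()`) reproduce the standard
demonstrations, e.g.
`runExperiment(presetConfig("fig2-compare"))` for the full-vs-reduced
firing-pattern comparison. A thin command-line wrapper over the same
functions is installed at `inst/scripts/trn-workbench.R`.

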