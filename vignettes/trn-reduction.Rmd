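---
title: "Reducing and dissecting the TRN neuron model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reducing and dissecting the TRN neuron model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trnreduce)
```

## The model

Neurons of the thalamic reticular nucleus (TRN) fire in two characteristic
modes: rebound bursts of fast spikes riding on a low-threshold calcium
potential when released from hyperpolarization, and regular tonic spiking
under sustained depolarization. `trnreduce` implements a single-compartment
conductance-based model of this cell — a Hodgkin-Huxley scheme with fast
sodium ($g_{Na} m^3 h$), delayed-rectifier potassium ($g_K n^4$), a
low-threshold T-type calcium current ($g_T p^2 q$) of the
Huguenard-Prince type, and ohmic plus potassium leaks:

$$C \frac{dV}{dt} = -\big(I_{Na} + I_K + I_T + I_L + I_{KL}\big) +
  \frac{10^{-3}}{A} I_{syn}(t),$$

with every gate relaxing as
$d\theta/dt = \phi_\theta\,[\theta_\infty(V) - \theta]/\tau_\theta(V)$.
The gate kinetics are the classic Traub-style rate functions for
$m, h, n$ (shifted by the spike-adjusting threshold
$V^{th}_{Na} = V^{th}_K = -55$ mV) and the nucleus-reticularis T-current
steady states and time constants for $p, q$ (shifted by
$V^{th}_T = -3$ mV), with rate scales $\phi_p = 6.9$, $\phi_q = 3.7$.
`trnParams()` carries all of this; its defaults are the analysis set used
throughout this vignette ($g_T = 2.25$, $g_{KL} = 0.0065$ mS/cm²,
$E_L = -70$ mV).

A note on stimulus units: the voltage equation normalizes the synaptic
current $I_{syn}$ (nA) by the membrane area $A = 1.43\times10^{-4}$ cm²
with a $10^{-3}$ factor. All protocol amplitudes in this package are
quoted on that $I_{syn}$ scale, so the values used in the worked examples
(−0.03, 0.2, …) can be passed straight to `stepProtocol()` /
`constantProtocol()`; `synCurrentDensity()` exposes the conversion to
µA/cm². One nominal µA/cm² of $I_{syn}$ therefore corresponds to
$10^{-3}/A \approx 6.99$ µA/cm² of membrane current density — the reading
under which the model's bifurcation structure is internally consistent
(see *Known limitations*).

## The reduction

Six coupled variables make phase-plane reasoning impossible, so the
package implements the equivalent-potential reduction of Kepler, Abbott
and Marder. Each gating fraction is mapped to the voltage that would
produce it at steady state, $v_\theta = \theta_\infty^{-1}(\theta)$
(`inverseSteadyState()`, `equivalentPotentials()`), making all state
variables commensurate in mV. Simulated trajectories then separate into
three time-scale groups — $\{V, v_m\}$ fast, $\{v_h, v_n, v_p\}$
intermediate, $\{v_q\}$ slow — and each group is collapsed into a single
weighted average:

$$x = \rho_V V + \rho_m v_m, \qquad
  y = \rho_h v_h + \rho_n v_n + \rho_p v_p, \qquad z = v_q,$$

with non-negative weights normalized within each group. Minimizing the
first-order discrepancy between the reduced and full voltage dynamics
fixes the weights in closed form (`computeWeights()`): $\rho_p$ is pinned
to a small constant $k$ (default 0.01 — large enough to keep the
T-channel's activation represented in $y$, small enough not to distort
the $h$/$n$ balance); $\rho_h$ and $\rho_n$ split $1-k$ in proportion to
$\partial F/\partial v_h$ and $\partial F/\partial v_n$; and $\rho_V$
solves a quadratic balancing $\partial F/\partial V$,
$\partial F/\partial v_m$ and the $m$-gate rate $C\phi_m/\tau_m$. Here
$F$ is the total ionic current expressed through equivalent potentials
(`fTotal()`, `partialsOfF()`). Because the partials depend on the state,
the weights are recomputed at every evaluation of the reduced vector
field, with $v_m$ identified with $x$ and $v_h, v_n, v_p$ with $y$.

The reduced system (`reducedRHS()`, `simulateReduced()`) is

$$C\rho_V \frac{dx}{dt} = -g_{Na} m_\infty^3(x)\, h_\infty(y)\,(x-E_{Na})
 - g_K n_\infty^4(y)\,(x-E_K) - g_T p_\infty^2(y)\, q_\infty(z)\,(x-E_T)
 - I_L - I_{KL} + \tfrac{10^{-3}}{A} I_{syn},$$

with $y$ and $z$ relaxing towards $x$ through weighted
equivalent-potential dynamics. Both the $y$- and $z$-nullclines are
exactly the diagonal ($dy/dt = 0$ at $y = x$, $dz/dt = 0$ at $z = x$) —
a property the test suite asserts on a grid. The per-channel currents
are recoverable from $(x, y, z)$ at any time
(`recoverChannelCurrents()`), so the reduction preserves the biophysical
interpretation of the original model.

### The closure choice in the y equation

One genuine design freedom deserves a frank account. The collapsed
intermediate variable obeys

$$\frac{dy}{dt} = \sum_{\theta \in \{h,n,p\}} \rho_\theta\, \phi_\theta\,
  \frac{\theta_\infty(x) - \theta_\infty(y)}{\tau_\theta(x)\,
  \theta_\infty'(\,\cdot\,)},$$

and the argument of the steady-state slope $\theta_\infty'$ is not fixed
by the first-order construction: evaluating it at the relaxing variable
$y$ (the exact equivalent-potential chain rule) or at the instantaneous
membrane potential $x$ agrees to first order near the diagonal $y = x$,
which is all the derivation controls. The two closures nevertheless give
quantitatively different global dynamics. `trnParams(steepness =)`
selects between them:

* `"local"` (default) — the slope at $y$, i.e. the chain rule applied
  verbatim. This closure preserves the model's three-dimensional
  structure best: a clean periodic-bursting rhythm under weak
  inhibition, a bistable window between rest and tonic spiking under
  weak depolarization, and full-vs-reduced spike counts that agree well
  under the comparison protocols.
* `"driving"` — the slope at $x$. This closure yields more physiological
  spike amplitudes in the fast subsystem and pushes the
  saddle-homoclinic values about 2 mV higher, but it degrades the
  three-dimensional behaviour badly (the tonic window disappears and
  burst rhythms become irregular), so it is not the default.

The slow equation always uses $q_\infty'(z)$: $z = v_q$ is an exact
identity, not an approximation, and evaluating its slope at $x$ makes
the denominator underflow at spike voltages where $q_\infty$ saturates.

## Fast-slow dissection

With $z$ (the T-current's de-inactivation state, time constant 85–600 ms)
frozen as a parameter, the fast $(x, y)$ subsystem explains both firing
modes. Its equilibria are the roots of the current-voltage relation
$I(V, z)$ obtained by setting $y = V$ (`ivRelation()`,
`findEquilibriaFast()`); at the default parameters and $z = -65$ mV there
are three: a stable low-voltage rest state, a saddle, and an unstable
high-voltage point surrounded by the spiking limit cycle.

The toolkit locates the organizing bifurcations by bisection on three
different predicates, each with an explicit bracket whose endpoints must
genuinely differ (asserted, never assumed):

* **Fold of equilibria** (`findFold()`): bisection on the root count of
  $I(V, z)$, to 10⁻³ mV; the result carries a tangency residual
  ($\min_V \max(|I|, |\partial I/\partial V|) < 10^{-3}$ at the located
  value, the defining property of a saddle-node).
* **Saddle-homoclinic orbit** (`findHomoclinic()`): bisection on the
  existence of the spiking limit cycle, to 10⁻² mV. Cycle existence is
  decided by simulation (`limitCycleProbe()`): a standardized
  superthreshold start, a 200 ms transient, then upward threshold
  crossings that must persist to the end of the observation window. Each
  bisection probe is seeded from the cycle state found at the nearest
  $z$ where the cycle exists — plain restarts under-estimate the
  boundary when the cycle's basin shrinks near the saddle connection.
  The detector verifies the saddle persists across the boundary and
  records the period-growth signature (the period 0.05 mV below the
  boundary exceeds the one 0.5 mV below by well over 1.5×, the
  logarithmic divergence expected of a homoclinic).
* **Fold of limit cycles** (`findFoldCycle()`): the same cycle-existence
  bisection, with the opposite post-check — the period must stay finite
  at the boundary. When the period *does* diverge and the boundary
  coincides with an equilibrium fold, the event is a saddle-node on an
  invariant circle rather than a genuine cycle fold, and the detector
  says so rather than keeping the requested label. This is exactly what
  happens at $I_{syn} = 0.1$: the tonic branch terminates at
  $z \approx -56.28$ mV, within 0.003 mV of the equilibrium fold, with
  an edge period near one second. Probe windows extend adaptively
  (500 → 1500 → 4500 ms) to outlast the saddle-node ghost passages near
  that boundary.

For the full three-variable system, global equilibria lie on the diagonal
$x = y = z$ (`globalEquilibria()`) and are classified by the eigenvalues
of the 3×3 Jacobian (finite differences at step 10⁻⁶; classification
rules in `classifyStability()`, with real parts within 10⁻⁹ of zero
flagged marginal rather than forced into a class). Andronov-Hopf points
(`findHopf()`) are sign changes of the real part of the lowest
equilibrium's complex pair, tracked on an $I_{syn}$ grid of 0.002 and
bisected to 10⁻⁴; a real-eigenvalue crossing is rejected as not-Hopf. The
onset of sustained tonic spiking (`findFoldCycleIsyn()`) is bisected on
long-run simulations (6 s horizon, final 1.5 s analysed) from a
spike-like initial condition, and the closing of the bistable window
(`findFoldEquilibria()`) on the diagonal root count.
`oneParameterDiagram()` assembles equilibria, dual-initial-condition
regimes and all four bifurcation annotations over an $I_{syn}$ range.

## Numerical choices

* **Integration**: all vector fields are evaluated in compiled code for
  deSolve's `lsoda` (the equivalent-potential dynamics are stiff
  wherever a gate saturates: the $1/\theta_\infty'$ factors become very
  large). Default tolerances are rtol 10⁻⁸ / atol 10⁻¹⁰ for
  simulations, relaxed to 10⁻⁶ / 10⁻⁸ inside cycle probes and long-run
  regime scans, where only topological outcomes matter; the homoclinic
  boundary moves by less than its 10⁻² mV tolerance between the two
  settings. A fixed-step `rk4` mode (dt = 0.01 ms) exists for
  convergence-order checks. `fullRHS()` and `reducedRHS()` are the
  reference R implementations of the same fields; the tests hold the
  two routes together to ~10⁻⁵ relative.
* **Resting states**: `init = "steady"` locates the lowest root of the
  steady-state current balance and relaxes it for a settling period
  (default 2000 ms) rather than integrating from an arbitrary state.
  Regime scans settle the rest state *under the applied current* and
  then kick $x$ by 0.5 mV — small enough to stay in a stable rest's
  basin, large enough to expose an unstable focus within the horizon.
* **Spikes and bursts**: spikes are upward crossings of 0 mV separated
  by more than 2 ms, linearly interpolated in time; bursts split where
  the inter-spike interval exceeds 30 ms. Regime labels additionally
  require burst interval patterns to be heterogeneous (max/min ISI
  > 2), because a uniform tonic train can be slower than the burst gap.
* **Removable singularities**: the $u/(e^{u/c}-1)$ rate terms switch to
  their analytic limit when $|u/c| < 10^{-7}$ (value) or $10^{-5}$
  (derivative); steepness derivatives are analytic throughout.
* **$\rho_V$ root selection**: of the two quadratic roots the one in
  [0, 1] is taken (the principal root in practice along every
  trajectory we probed); if neither qualifies the linearized solution
  $a/(a+\partial F/\partial V)$ is clamped into [0, 1] with a warning,
  and $\rho_V$ is floored at 10⁻⁶ before dividing.
* **Problem sizes**: voltage scans use a 0.01 mV grid on [−100, 20];
  z-bisections start from brackets a few mV wide; Hopf tracking uses 46
  grid points on [−0.08, 0.01]; long-run regime probes simulate 5–6 s.
  These sizes resolve every reported quantity to well inside its stated
  tolerance while keeping the full analysis suite to a few minutes.

## What the stimulus protocols do and do not emulate

The package generates its own inputs: piecewise-constant current steps
(`stepProtocol()`, `constantProtocol()`), which realize the standard
current-clamp protocols — hyperpolarize-and-release for rebound bursts,
sustained injection for tonic spiking, and constant bias levels for the
one-parameter analysis. They do not emulate synaptic conductance
transients, noise, or network feedback; a real TRN neuron receives
fluctuating GABAergic and glutamatergic bombardment. Passing behavioural
checks under these protocols therefore validates the deterministic
skeleton of the dynamics — the bifurcation structure — not the model's
response to in-vivo-like input statistics.

## Known limitations

* The model is a point neuron: no dendritic T-current gradients, no
  synaptic receptor kinetics, no temperature scaling beyond the fixed
  $\phi$ factors, and no network interactions.
* The reduction collapses $v_h, v_n, v_p$ into one variable by
  construction; manipulations that decouple those gates (e.g.
  channel-specific pharmacology) have no reduced counterpart.
* The closure ambiguity described above is real: published analyses of
  this model family report saddle-homoclinic boundaries up to ~2 mV
  above what the verbatim chain-rule closure yields (with matching
  knock-on differences: three rather than two spikes per burst under
  −0.03 inhibition, and a tonic-spiking onset nearer 0.059 than 0.037),
  while the fold, fold-cycle/SNIC, first Hopf and equilibrium-fold
  values agree to printed precision. The package ships both closures and
  the test suite pins down which quantities are closure-sensitive; the
  two-spike/three-spike discrepancy disappears in the full six-variable
  model, which produces three spikes per burst under the same protocol.
* Stability classification near a bifurcation is ill-conditioned by
  nature; rely on the `marginal` flag and the bracketed bifurcation
  values, not on point classifications taken exactly at a boundary.

## A worked example

```{r example, eval = FALSE}
params <- trnParams()

# rebound burst of the reduced model after release from inhibition
trace <- simulateReduced(params, stepProtocol(-0.05, 0, 200, 1000))
burstStatistics(detectSpikes(trace))

# the bistable z-interval of the fast subsystem at zero stimulus
findFold(0, params)          # lower boundary: fold of equilibria
findHomoclinic(0, params)    # upper boundary: saddle-homoclinic orbit

# the one-parameter structure in the injected current
findHopf(c(-0.08, 0.01), params)
findFoldEquilibria(params)
```
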