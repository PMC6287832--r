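---
title: "Receptor kinetics for odorant mixtures: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Receptor kinetics for odorant mixtures: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olfmix)
```

## The receptor model

Odor transduction is modelled as a two-stage process on a population of
identical receptors. A free receptor (fraction $r_0$) binds odorant at rate
$(k_1 c)^n$, where $c$ is the dimensionless odorant concentration and $n$ the
Hill coefficient of transduction; a bound receptor (fraction $r$) unbinds at
$k_{-1}$ or activates at $k_2$; an activated receptor ($r^*$) deactivates at
$k_{-2}$. All rates are in ms$^{-1}$, all receptors start unbound at stimulus
onset, and spontaneous activation is not modelled. The activated fraction
$r^*$ is what drives the olfactory receptor neuron (ORN).

For a mixture, all components compete for the same free receptors. The
package's mixture dynamics let the *total* binding rate depend on the linear
sum of the components, $(\sum_j k_{1j} c_j)^n$, while each component receives
its share in proportion to its single-odorant rate. That requires the factor

$$w(n) = \frac{(\sum_j k_{1j} c_j)^n}{\sum_j (k_{1j} c_j)^n},$$

which multiplies every per-component binding term. $w$ is exactly 1 for a
single component or for $n = 1$, and equals $N^{n-1}$ for $N$ identical
components. Its role is *consistency*: a pure odorant arbitrarily split into
identical "components" behaves exactly like the unsplit odorant
(`integrate_kinetics()` and `steady_state_mixture()` agree to integrator
precision, and the test suite checks this to $10^{-10}$). The biophysical
interpretation of $w(n)$ is left open deliberately; the package treats it as
a defined algebraic factor. The earlier model variant without $w$ (and with
free-receptor depletion $\sum_j (k_{1j} c_j)^n$) is retained behind
`legacy = TRUE` / `model = "legacy"` everywhere, because the qualitative
mixture effects are expected to survive in it — the tests confirm they do —
while it demonstrably fails the self-mixture consistency check.

### Steady states

The closed-form steady state for one odorant is
$r^* = 1/(1/K_2' + 1/(K_\mathrm{eff}\, c^n))$ with $K_1 = k_1^n/k_{-1}$,
$K_2 = k_2/k_{-2}$, plateau $K_2' = K_2/(1+K_2)$ and low-concentration gain
$K_\mathrm{eff} = K_1 K_2$. A mixture takes the same form with
$K_\mathrm{eff}^{mix}\, c_\mathrm{eff} = w \sum_i K_{\mathrm{eff},i} c_i^n$
and plateau $K_2^{mix\prime} = 1/\sum_i p_i / K_{2i}'$, the weighted harmonic
mean of the component plateaus with weights
$p_i = K_{\mathrm{eff},i} c_i^n / \sum_j K_{\mathrm{eff},j} c_j^n$. The
weights use the capital-K effective gains $K_\mathrm{eff} = K_1 K_2$: that is
what the steady-state derivation of the mixture dynamics forces, and it is
the quantity that is "proportional to the activation gain at low
concentrations". Unequal component concentrations simply carry their
$c_i^n$ factors into the sums; `steady_state_mixture()` implements the
general expression directly and the closed form is recovered exactly for
equal concentrations.

Two consequences drive everything else in the package:

* **Low concentration.** The response is $\approx w \sum_i K_{\mathrm{eff},i}
  c_i^n$; the factor $w$ makes mixture interactions synergistic for $n > 1$,
  strictly additive for $n = 1$, and hypoadditive for $n < 1$ (below the sum
  of the components, above the weakest component — not necessarily above the
  *strongest*, since $w < 1$ can pull a mixture below a dominant component).
  `classify_interaction()` encodes this trichotomy.
* **High concentration.** All receptors are bound and the mixture plateau is
  the weighted harmonic mean above — strictly between the component plateaus,
  i.e. always hypoadditive, for any $n$. Crucially, the weights $p_i$ depend
  on the binding gains, so for mixtures the high-concentration pattern
  retains information about the low-concentration pattern. For single
  odorants $K_2'$ is independent of $K_1$, and no such coupling exists. This
  asymmetry is the mechanism behind the pattern-stability results.

`reduce_mixture()` expresses an $N$-component mixture as nested binary
mixtures. The inner pseudo-odorant carries its pooled gain and harmonic-mean
plateau plus *two* binding sums ($\sum k_1$ and $\sum k_1^n$): the outer
binary $w$ must see the inner mixture's linear sum in its numerator but the
power sum in its denominator, otherwise the recursion does not reproduce the
direct formula. With that bookkeeping the recursion is exact (tested to
$10^{-10}$), which is what makes component-count monotonicity arguments
inductive.

### Short-time behaviour

Immediately after onset, activation grows quadratically,
$r^*(t) \approx k_\mathrm{eff} c^n t^2/2$ with
$k_\mathrm{eff} = k_1^n k_2$, and for mixtures the pooled slope constant is
$w(n) \sum_i k_{\mathrm{eff},i} c_i^n$. At matched molecule count ($N$
components at $c$ versus one odorant at $Nc$) the mixture ramp is faster for
$n \le 1$ because $w \ge N^{n-1}$ (power-mean inequality). This is the origin
of the shorter first-spike latencies.

## Parameter ensembles and the correlation study

`run_table1()` asks: is the correlation between a stimulus's response
pattern at low and at high concentration larger for binary mixtures than for
single odorants? Per trial it samples a population of odor–receptor
combinations with independent $k_1^n$, $k_{-1}$ and $K_2$ draws
(`ensemble_spec_table1()` ships the uniform, log-scale-uniform and normal
parameter sets), pairs two draws per receptor into a binary mixture, and
compares Pearson correlations at two levels:

* `"constants"` — the asymptotic determinants themselves:
  $\mathrm{cor}(K_\mathrm{eff}^{mix}, K_2^{mix\prime})$ across mixtures
  minus $\mathrm{cor}(K_\mathrm{eff}, K_2')$ across singles.
* `"orn_rate"` — steady-state activation at $c = 10^{-4}$ and $10^{-1}$
  mapped through the conductance-based LIF rate (`orn_rate_map()`), then the
  cross-concentration correlation difference.

Correlations are plain Pearson on the raw values. We verified that log-scale
or rank correlations destroy the effect entirely, so the raw-value reading
is the meaningful one even though it is heavy-tail sensitive.

Choices a reader should know about, all fixed before the package's own
studies were finalized:

* **Population size.** The per-trial population is 160 receptors (matching
  the antennal lobe model's glomerulus count), i.e. 320 single combinations
  and 160 mixtures; it is configurable via `pop_size`. The per-trial noise of
  a Pearson correlation over 160–320 points means a small percentage of
  trials can show a (slightly) lower mixture correlation even though the
  population effect is robust; with the heavy-tailed normal ensemble this
  discordant fraction does not vanish even for much larger populations.
* **Rate map.** `orn_rate_map()` uses the published ORN LIF parameters with
  $g_e = g_\mathrm{ORN} \sum_i r_i^*$, $g_i = 0$ and adaptation amplitude
  $I^{base}_{adapt} \sum_i r_i^*$, but **no background conductances**. The
  background terms model spontaneous antennal-lobe input; in the abstract
  ensemble study they pin every unit a fraction of a millivolt below
  threshold, so that every combination fires at every concentration and the
  threshold nonlinearity — which differentiates weak from silent units and
  is what the rate level adds over the constants level — is erased. Omitting
  them leaves the threshold at $\sum r_i^* = 0.1$ and roughly triples the
  measured correlation difference. Even so, the package's rate-level
  differences are smaller than the published ones (about 0.15 versus 0.24
  for the uniform ensemble); the exact rate-mapping constants behind those
  reference values are not fully determined by the published parameter set, and we chose
  not to introduce free constants beyond the published table. The
  qualitative claims — zero discordance, amplification over the constants
  level, weakening under variable $n$ — all reproduce.
* **Variable Hill coefficients.** In `n_mode = "variable"` each receptor's
  log$_{10}$-axis slope $n'$ is drawn log-normally
  ($\log n' \sim N(0.44, 0.22)$) and converted by $n = n'/\ln 10$ (natural
  log; median $n \approx 0.67$, consistent with the fixed-$n$ value 0.65 and
  with most receptors having $n < 1$; a base-10 reading would give median
  $n \approx 1.2$ and contradict both).
* **"Exp(uniform)" and "Log(uniform)"** are read as: uniform on the log
  scale between the printed endpoints, and the log of a uniform variable,
  respectively — in both cases the printed ranges are the endpoints of the
  resulting values.

## The antennal lobe model

The synthetic activation-pattern generator
(`generate_activation_matrix()`) emulates the summary statistics of honey
bee glomerular imaging responses: per-receptor mean and variance of the
saturating response $g_{max}$ across a 16-odor panel, the distribution of
pairwise odor–odor pattern correlations, and the matrix of normalized
Euclidean distances between odor patterns. The shipped default targets are
*synthetic* reference statistics (a latent-factor construction with three
odor classes), not measured data; any of them can be replaced by the user.
Patterns start as correlated Gaussian columns, rows are rescaled to the
target moments, and the distance matrix is matched by damped gradient
descent with the moments re-imposed each sweep (moments within 5%,
correlation KS distance < 0.1, distance RMS within 5%, all seeded and
reproducible). What passing these tolerances does *not* show: real
glomerular data have temporal structure, trial-to-trial noise and
concentration-dependent pattern reshaping that the generator does not
emulate; it provides realistic *statistics* for population-level studies,
not surrogate recordings.

Each combination's Hill descriptors ($C_{1/2} \sim N(-3, 1)$ truncated to
$(-4.4, -0.4)$; $n'$ log-normal truncated to $(0.7, 3.5)$, shared per
receptor) are inverted to kinetic constants by `calibrate_from_hill()`:
$K_2 = g_{max}/(1-g_{max})$, $k_{-2} = k_2/K_2$ with
$k_2 \sim N(0.1, 0.01)$, and $k_1$ solved in closed form so half-activation
falls exactly at $c = 10^{C_{1/2}}$, then clamped to the hard interval
$(0.1, 5000)$. On the log-concentration axis the resulting dose–response
curve *is* the logistic with slope $n \ln 10$ — the package implements the
rising orientation, since responses must grow with concentration. Clamping
can leave a small fraction of combinations hypersensitive or desensitized
relative to their nominal $C_{1/2}$; tests therefore bound population
averages rather than every unit.

`build_network()` wires 160 glomeruli: uniform jittered ORN→PN and ORN→LN
inputs, and LN→PN / LN→LN lateral inhibition whose weight grows with the
Pearson correlation $\rho_{ij}$ between the glomeruli's odor tuning at high
concentration ($c = 0.3$): $(1-\delta_{ij})\,s_{ij}\,[w_0 +
H(\rho_{ij})\rho_{ij} w_{corr}]$. The published table lists both the
$w_0/w_{corr}$ constants and separate LN→PN / LN→LN strengths; no reading
reconciles all magnitudes, so the per-type strengths are treated as synaptic
gains $s_{ij}$ multiplying the correlation-dependent structure. All normal
draws are truncated at mean ± 2 sd.

`simulate_network()` runs quasi-stationary rate dynamics: each unit's rate
is the LIF first-crossing rate of its instantaneous input, conductances are
(weight × presynaptic rate in Hz) plus background, and PN/LN rates are
iterated synchronously with damping 0.5 to the fixed point (ORN rates need
no iteration). Adaptation amplitudes follow the published rule — the driving
$\sum r^*$ for ORNs, the unit's previous rate for PNs and LNs — with the
presynaptic rate in spikes/ms for the latter: in Hz the printed amplitude
constants would inject tens of millivolts and silence the network,
contradicting its own spontaneous-rate calibration. With the published
background conductances PNs sit ~0.2 mV above threshold, so the 5–20 Hz
spontaneous regime holds for the population mean while individual jittered
PNs scatter over 0–30 Hz. PN-level outputs are treated as qualitative
throughout (orderings and inequalities, not rate values).

## First-spike latency

`first_spike_latency()` co-integrates the receptor ODE and the membrane
equation (with $g_e(t) = g_\mathrm{ORN} \sum_i r^*_i(t)$ plus background,
$I_{adapt} = 0$ before the first spike, $V(0)$ at the background resting
potential) with fixed-step RK4 at 0.01 ms — dense output makes first-crossing
detection trivial, which is why an adaptive scheme is not used — and
interpolates the crossing linearly. One millisecond is added for odorant
diffusion in the sensillum, and latencies are capped at 100 ms *before*
averaging (`average_latency()` follows the cap-then-average rule).
Molecule-matched comparisons put $N$ components at $c_0$ against a single
odorant at $N c_0$.

## Numerical choices

* Receptor ODE: `deSolve::lsoda` (stiff-capable; sampled rate constants span
  four orders of magnitude) at rtol $10^{-8}$ / atol $10^{-10}$; tests that
  assert $10^{-10}$ agreement tighten to rtol $10^{-11}$.
* Steady-state detection: integrate until the activated-fraction derivative
  falls below $10^{-10}$ ms$^{-1}$, default horizon $10^4$ ms. Near
  saturation the redistribution of bound receptors between components has
  timescale $\sim 1/(k_{-1} r_0)$ and can exceed that horizon; the function
  flags non-convergence and accepts a larger `t_max`.
* LIF first crossing: closed form when there is no adaptation; otherwise a
  forward scan from the no-adaptation crossing time (a strict lower bound,
  since the adaptation transient only lowers $V$) in 0.05 ms steps, then
  bisection to $10^{-9}$ ms. Agreement with a 0.01 ms scan is part of the
  test suite.
* Fixed-point network iteration: synchronous update with damping 0.5,
  tolerance 0.01 Hz, warning on non-convergence.
* All Monte-Carlo entry points take explicit seeds and are bit-reproducible.

## Problem sizes used by the shipped tests

The package's own test suite runs the constants-level correlation studies at
the full published size (1000 trials × 160 receptors; they are vectorized
and fast), the rate-level studies at 300 trials, the network tests on 24–36
glomeruli with 6–8 odors, and the latency experiments on 30–60 receptor
ensembles — sizes chosen so the whole suite stays interactive while the
Monte-Carlo standard errors remain far below the tolerances being asserted.
The acceptance script (`scripts/acceptance.R`) always runs the full 1000
trials.

## Known limitations

* The exact constants that map steady-state activation to the reference ORN
  firing-rate results are not fully determined by the published parameter
  set; the package's
  documented convention reproduces the direction and structure of the
  rate-level results but underestimates their printed magnitudes (see the
  discussion above).
* Inhibitory mixture interactions (masking) and $n \le 0$ regimes are out of
  scope by design; the model cannot produce a mixture response below the
  weakest component.
* Ephaptic interactions between neighbouring ORNs, spike-time-resolved
  dynamics and mushroom-body readout are not modelled; the rate model's
  $\nu$ carries no spike-timing information beyond the first-spike latency,
  which is computed by direct integration.
* The activation-pattern generator reproduces target statistics, not
  individual glomeruli: a generated glomerulus does not correspond to any
  particular biological one.
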