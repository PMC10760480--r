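---
title: "Single-channel gating kinetics from filtered current fluctuations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel gating kinetics from filtered current fluctuations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flickerfit)
```

## The problem

Single ion-channel recordings are low-pass filtered (typically a few kHz)
before digitization, so gating transitions faster than the filter rise time
are not resolved as discrete events. They appear instead as excess
open-channel noise, incomplete closures ("flicker"), and asymmetric tails in
the all-points amplitude histogram. Threshold-based idealization quantifies
the slow gating; the fast gating must be inferred from the *shape* of the
amplitude distribution — the (extended) beta-distribution approach. This
package implements both halves of that workflow, together with the
synthetic-data machinery needed to validate every stage against a known
ground truth, and the macroscopic conductance–voltage analysis that connects
microscopic rate constants to whole-patch behavior. The motivating system is
a TRPV1-like nonselective cation channel whose flicker kinetics depend on
the permeant ion, but nothing in the code is specific to that channel.

## The gating model

Gating is modelled as a continuous-time Markov chain on a small set of open
and closed states (`gating_scheme()`). Each allowed transition carries a
single-exponential voltage-dependent rate

$$k(V) = k(0)\, e^{z V e_0 / k_B T},$$

with $k(0)$ the rate at 0 mV and $z$ the apparent partial charge
(`rate_law()`, `rate_at_voltage()`). The temperature is fixed at 296 K, so
$k_B T / e_0 \approx 25.51$ mV. Charges may be negative; closing rates of
depolarization-activated channels usually are.

The central topology is the star scheme (`scheme1_params()`): one open state
O connected to three closed states by slow ($\alpha$), medium ($\beta$) and
fast ($\gamma$) transition pairs. At steady state each closed/open occupancy
ratio is the inverse equilibrium constant $K_i = k_{i,o}/k_{i,c}$, giving
the closed form

$$P_O = \left[1 + 1/K_s + 1/K_m + 1/K_f\right]^{-1},$$

which the test suite verifies to $10^{-10}$ relative error against an
independent null-space solution of the four-state generator
(`steady_state_occupancy()`). Because the three closed pathways enter
symmetrically, fitted pairs are only identified up to permutation; the
package reports them in canonical slow/medium/fast order by closing rate
(`canonicalize_star_rates()`), the convention used when classifying
transitions by magnitude at 0 mV.

## Synthetic recordings

`simulate_state_path()` draws dwell sequences by the standard Monte Carlo
rule: a sojourn in state $i$ lasts $d = -\ln(R)/\sum_j k_{ij}$ with $R$
uniform, and the successor is drawn from the branching probabilities
$p_{ij} = k_{ij}/\sum_j k_{ij}$. `render_trace()` converts a path into a
realistic recording in three steps:

1. the infinite-bandwidth current (0 pA closed, $i_{open}$ pA open) is
   point-sampled at the sampling rate $f_s$ (sample midpoints);
2. white Gaussian baseline noise is added;
3. the series is convolved with the impulse response of a Gaussian filter,
   $H(t) \propto \exp(-t^2/2\sigma_g^2)$ with
   $\sigma_g = \sqrt{\ln 2}/(2\pi f_c) \approx 26.5\ \mu s$ at
   $f_c = 5$ kHz, discretized at $f_s$, truncated at $\pm 5 \sigma_g$ and
   renormalized to unit sum.

Noise is added *before* filtering, and the requested `noise_sigma` is the
post-filter closed-level SD: the pre-filter white SD is scaled up by the
filter's noise-bandwidth gain $1/\sqrt{\sum h_k^2}$ so the rendered baseline
SD matches the request. Convolution is circular, which makes the filter's
unit DC gain exact (the trace mean is preserved to machine precision); for
records hundreds of thousands of samples long the wrap-around affects a
dozen samples at each end. The default condition throughout is
$f_s = 50$ kHz, $f_c = 5$ kHz, matching high-resolution patch-clamp
practice, with reference star-scheme rates
$\alpha_o = 1500$, $\alpha_c = 27$, $\beta_o = 22{,}500$, $\beta_c = 600$,
$\gamma_o = 127{,}500$, $\gamma_c = 30{,}000\ s^{-1}$ — a strongly flickery
burst regime with $P_O \approx 0.781$.

`simulate_resolvable_path()` is a truncated variant (every dwell is the
state's exponential shifted by `t_min`) used to build ground truths whose
events are all long enough to idealize; for schemes with comparable open and
closed mean dwells the open-time fraction deviates from the untruncated
steady state by well under 1%.

What the generator deliberately does *not* emulate: baseline drift, 1/f and
capacitive noise, analog Bessel-filter phase response (the Gaussian filter
is the specified model), multi-channel patches, and ligand-gating
nonstationarity. Tests passing on these synthetics therefore validate the
estimators under the model's own assumptions, not against every artifact of
real recordings.

## Idealization and dwell statistics

`idealize_half_amplitude()` implements half-amplitude threshold crossing:
the trace is cubic-spline interpolated (10-fold oversampling, locating
crossings to $1/(10 f_s)$; finer grids cost memory without changing the
detected events) and
crossings of the 50% level between baseline and open amplitude become event
boundaries. A sample exactly at threshold keeps the preceding state. Events
shorter than the filter dead time $T_d = 0.179/f_c$ (35.8 µs at 5 kHz,
printed as 36 µs) cannot be genuine and are censored by
`apply_dead_time()`: each sub-dead-time event is removed and its flanking
same-class neighbours merged, absorbing the removed duration, so total
record time is conserved and alternation preserved. Removal proceeds
shortest-event-first, which makes censoring deterministic, order-independent
and idempotent. The alternative reading of "discarding" short events —
deleting them and leaving a gap — would break both alternation and time
conservation, so concatenation was chosen.

Dwell distributions are displayed as log-binned histograms
(`log_binned_histogram()`) and fitted by maximum likelihood with mixtures of
left-truncated exponentials (`fit_dwell_mixture()`, EM algorithm; truncation
at $T_d$ accounts for the censored short events, and each component is a
shifted exponential by memorylessness, so the one-component fit reduces
exactly to `mean(d - T_d)`). Histograms serve display and initialization;
the likelihood uses the raw durations.

Bursts are runs of openings separated by closed gaps shorter than the
critical time $t_c$, the root of

$$a_f e^{-t_c/\tau_f} = a_s\,(1 - e^{-t_c/\tau_s}),$$

which balances the two misclassification counts between the adjacent fast
and slow closed-time components (`critical_time()`). When a closed-time
mixture has more than two components, the pair spanning the largest
time-constant ratio defines $t_c$ (`critical_time_from_mixture()`) — the
natural burst/gap boundary; which components the original analysis used per
condition is not reported, so this rule is the package's own deterministic
choice.

## Amplitude histograms and the extended beta fit

`all_points_histogram()` accumulates every sample of the selected segments
into uniform bins (default width `noise_sigma/5`) and normalizes to unit
probability mass. For recordings with an unknown baseline offset the
histogram can be re-anchored to the closed-state mode; at high open
probability the closed level may be only a shoulder under the flicker tail,
in which case no shift is applied (with a warning) — synthetic traces are
generated at a known zero baseline and use `align = FALSE`.

Because no analytic amplitude distribution exists for filtered gating with
more than two states, the model histogram is *simulated*:
`simulate_histogram()` runs the full synthetic pipeline at the candidate
rates with the data's $f_s$, $f_c$ and noise, and bins the result on the
experimental binning. `histogram_distance()` is the summed squared
difference of normalized densities ($\chi^2$). `fit_extended_beta()` wraps
this in the zero-order stochastic search: 100 iterations by default; each
iteration perturbs one randomly chosen rate multiplicatively — a small step
(factor $U(1, 1.1)^{\pm 1}$) or a large step (factor $U(2, 3)^{\pm 1}$) with
equal probability — and accepts the proposal only if the *average* of 10
freshly simulated $\chi^2$ values beats the best average so far. Averaging
is essential: a single simulated record can score well by chance. The
accepted-merit sequence is non-increasing by construction, and the entire
fit is reproducible from its configuration seed. Each merit evaluation
simulates 10 s of gating by default; this sets the $\chi^2$ noise floor and
is exposed in `beta_fit_config()`.

Two practical points matter for honest use:

* **The open amplitude is not free.** `measured_open_amplitude()` estimates
  $i_{open}$ from the data. With heavy flicker the open peak's apex is
  pulled below the true level (most filter windows contain a closure), so
  the estimator regresses a fixed-width Gaussian on the peak's right flank
  — the side least affected by flicker. It still under-estimates a strongly
  flickery level by roughly 2%; the residual propagates into mild rate
  biases that the recovery tests absorb within their tolerances.
* **Initialization.** A hundred single-coordinate iterations refine rather
  than explore, and the merit surface contains a nearly flat valley: because
  the histogram mean fixes only the *sum* of the closed/open occupancy
  ratios, extra medium closing rate can be traded against fast flicker with
  almost no change in the plain least-squares merit. Starting values must
  therefore already resolve that trade-off. `initial_rates_from_trace()`
  estimates the slow pair from the slow component of a closed-dwell mixture
  fit and the medium pair from full-amplitude closures in the duration band
  $[2.8, 8.4]\,T_d$ (below the band, apparent durations are dominated by
  partially resolved flicker dips; the amplitude filter of
  `annotate_amplitudes()` rejects merged flicker runs that fail to reach
  the baseline). `refine_initial_rates()` then (i) calibrates the medium
  pair by indirect inference — the band's event rate and apparent time
  constant are matched between the data and idealized *simulations* at the
  candidate rates, which absorbs detection artifacts such as
  flicker-extension of medium closures; (ii) calibrates the slow pair the
  same way, matching the apparent two-component mixture estimates (their
  contamination bias cancels because the simulation suffers it equally);
  (iii) pins the fast-pair ratio with the measured mean current; and
  (iv) scans the fast-pair magnitude (ratio-preserving) against a
  short-record histogram merit, on a finer grid at higher precision in the
  final cycle. Three such cycles converge; more only add random-walk
  noise. The zero-order search then polishes all six rates.

Model comparison mirrors standard practice: the same histogram is fitted
with one-, two- and three-closed-state star topologies, and the best
achieved $\chi^2$ values are compared — data generated with three closed
states are fit an order of magnitude better by the three-state scheme.

## Macroscopic conductance–voltage analysis

`generate_macroscopic()` emulates a voltage-step family (default 20-mV
steps, −130 to +130 mV, 150 ms): each step's steady-state current is
$N P_O(V) g (V - V_{rev})/1000$ pA plus white noise, with $P_O$ from either
a Boltzmann description or star-scheme rate laws. `measure_steady_state()`
averages the last 20% of each step; `conductance_from_iv()` applies Ohm's
law (the point at $V_{rev}$ is excluded); `fit_boltzmann()` fits

$$G(V) = G_{max}\left[1 + e^{-z (V - V_{1/2}) e_0/k_B T}\right]^{-1}$$

by Levenberg–Marquardt. The sign convention makes $z$ positive for
conductance that rises with depolarization. Activation energies are
$\Delta G = z V_{1/2}$ (e0·mV, with kJ/mol via the Faraday constant) and
$\Delta\Delta G$ is taken relative to a declared reference condition
(`activation_energies()`). `fit_rate_voltage()` recovers $(k(0), z)$ of a
rate law by log-linear least squares, and `predict_gv_from_scheme()` turns
a set of fitted rate laws into a normalized open-probability curve for
comparison with measured G–V relations. Reversal potentials are
interpolated from the I–V zero crossing.

## Numerical choices and problem sizes

* Thermal voltage from CODATA constants at 296 K (25.507 mV); all
  voltage-dependence formulas share it.
* The steady-state solver uses a least-squares solve of the transposed
  generator with the normalization row appended; schemes must be strongly
  connected.
* EM for dwell mixtures stops when the log-likelihood changes by less than
  $10^{-8}$ (relative) or after 500 iterations; non-convergence is flagged
  on the returned object, never an error. Components are reported in
  ascending $\tau$.
* `critical_time()` brackets its root inside $(\tau_f, \tau_s)$ and widens
  the bracket when extreme amplitude ratios push the root outside.
* Proposals in the beta fit that would make a rate non-positive are
  rejected, not clamped (multiplicative steps cannot produce them, but the
  contract is explicit).
* The test suite and the acceptance script size their simulations to run
  on a single CPU in minutes: 10-s records for histogram fits (the
  package's default evaluation length), 25–60 s of gating for dwell/burst
  statistics, and a 30-s record for idealization fidelity. These lengths
  were chosen as the smallest that leave comfortable statistical margins
  for the properties being checked, and they are stated in the tests
  themselves.

## Known limitations

* Sub-conductance levels are not modelled: closed means 0 pA, open means
  one amplitude.
* The half-amplitude idealizer assumes a stable baseline; no drift
  correction is provided.
* The extended-beta fit explores a fixed topology; it compares topologies
  by $\chi^2$ but does not penalize parameter count.
* The zero-order optimizer is a refinement procedure. Its step schedule
  (small steps $\times$ occasional large escapes) assumes a sensible start;
  global search is out of scope.
* With very fast flicker the measured open amplitude is biased low by a few
  percent (see above); where the true single-channel amplitude is known
  independently (e.g., from slow-gating I–V measurements), passing it as
  `i_open` is preferable.
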