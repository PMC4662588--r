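---
title: "The vibrating reed bank: model, measurements, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The vibrating reed bank: model, measurements, numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frahm)
```

## The model

`frahm` simulates a vibrating-reed (Frahm) frequency meter: a bank of $n$
passive, damped harmonic oscillators, graded in natural frequency, coupled to
their nearest neighbours by an elastic band, and driven *in parallel* by a
common sinusoidal force.  The system is the classic mechanical analogue of
the cochlea: the reeds stand for the tonotopically tuned resonant elements
and the parallel forcing for sound reaching every hair cell almost
simultaneously through the fluid, while the elastic coupling carries the
serial energy path along the partition.  Reed $j$ obeys

$$
x_j'' + \gamma\,\omega_j\,x_j' + \omega_j^2\,x_j
  = f_0\,m_j\,\sin\omega t
  + \kappa_{j-1,j}\,(x_{j-1}-x_j) + \kappa_{j,j+1}\,(x_{j+1}-x_j),
$$

with natural angular frequency $\omega_j = 2\pi f_j$, dimensionless damping
$\gamma$ (quality factor $Q = 1/\gamma$), per-reed forcing mask $m_j \in
[0,1]$, and per-link elastic coupling $\kappa$.  Links that do not exist (at
the two free ends) contribute nothing; for uniform coupling this is exactly
the classic end prescription $\kappa(x_2 - x_1)$ and $\kappa(x_{n-1} -
x_n)$.  Everything is linear and passive: $f_0$ only sets an overall scale,
there are no active (negative-damping) elements, and the coupling is real
(purely elastic).

Coupling is stored **per link** ($n-1$ values) rather than per reed.  The
historical description of the boundary-taper experiment ("coupling increased
progressively over 10 reeds") is ambiguous between the two conventions; the
per-link reading with a linear ramp over 10 links at each end
(`tapered_coupling_profile()`) was adopted because it keeps the uniform case
as an exact special instance and makes each link a single physical rubber
band segment.

## Two solution engines

* **Time domain** (`simulate_forced()`, `simulate_impulse()`): the
  $2n$-dimensional first-order system is integrated with `deSolve` (`lsoda`,
  `rtol = 1e-8`, `atol = 1e-10`) through a compiled C right-hand side.
  Output is sampled at 40 points per cycle of the highest natural frequency,
  dense enough for peak picking on every reed.  Runs are deterministic bit
  for bit given the solver settings.
* **Frequency domain** (`solve_phasors()`): at steady state, substituting
  $x_j = \mathrm{Im}(X_j e^{i\omega t})$ turns the system into a complex
  tridiagonal solve $A X = f_0 m$ with
  $A_{jj} = \omega_j^2 - \omega^2 + i\gamma\omega_j\omega + \kappa_\text{left}
  + \kappa_\text{right}$ and $A_{j,j\pm1} = -\kappa$.  With the $\sin$
  forcing convention the phasor of the force is real, $|X_j|$ is the
  steady-state amplitude and $-\arg X_j$ the phase lag behind the force.
  The solver uses the Thomas algorithm (a dense path is retained as a
  cross-check) and underpins the dense response maps and single-reed-forcing
  experiments.

The two engines are verified against each other continuously: the test suite
requires last-three-cycle amplitudes within 1% and phases within 0.005
cycles across dozens of randomly generated banks, and the compiled right-hand
side is additionally checked against a literal R transcription of the
uniform-coupling equations.  The transient allowed before that comparison is
scaled to the damping, $t \approx 2\ln(400)/(\gamma\,\omega_{\min})$, because
the switch-on transient of reed $j$ decays at rate $\gamma\omega_j/2$: a
fixed number of drive periods would leave percent-level residuals at the
weakest damping.

## Parameters and their defaults

| Parameter | Default | Meaning |
|---|---|---|
| $f_j$ | bank builder | natural frequencies in Hz |
| $\gamma$ | 0.014 (Wilson), 0.025 (kHz banks) | damping ratio, $Q = 1/\gamma$ |
| $\kappa$ | user | per-link coupling, $(\mathrm{rad/s})^2$ internally |
| $f_0$ | 1000 | forcing amplitude (arbitrary units) |
| `samples_per_cycle` | 40 | output sampling of the fastest reed |
| `rtol`, `atol` | $10^{-8}$, $10^{-10}$ | integrator tolerances |

Three bank builders cover the canonical configurations.
`build_wilson_bank()` is the analogue instrument: 21 reeds from 55 Hz (reed
1) down to 45 Hz in 0.5 Hz steps, with `gamma = "auto"` applying the
rubber-band calibration $\gamma = 3.37\times10^{-6}\kappa + 0.00553$ (a
rubber band supplies damping along with elasticity, so the two move
together).  `build_greenwood_bank()` places 201 oscillators on the standard
human Greenwood place-frequency map $F = 165.4\,(10^{0.06x} - 0.88)$ over
16.5--18.5 mm from the apex in 0.01 mm steps (one hair-cell width), giving
roughly 1.47--1.99 kHz in nearly 2.5 Hz steps; the map constants are
overridable because sources differ slightly.  `build_linear_bank()` spaces
frequencies exactly evenly (used for the 1--2 kHz clustering experiments).
The kilohertz banks default to $\gamma = 0.025$: the only constraint stated
for them is $Q \approx 40$.

### Coupling units

A subtlety worth spelling out: the coupling constants conventionally quoted
for the kilohertz banks ($\kappa$ of a few hundred) cannot be in
$(\mathrm{rad/s})^2$.  Against $\omega_j^2 \approx 1.2\times10^8$ a coupling
of 200 $(\mathrm{rad/s})^2$ is six orders of magnitude too small to matter
— the chain would be indistinguishable from uncoupled (we measure about 84
dB of attenuation per reed under single-reed forcing in that reading),
which contradicts every published kilohertz-bank phenomenon.  Those runs
are naturally read in millisecond time units, where the same numbers are
$(\mathrm{rad/ms})^2 = 10^6\,(\mathrm{rad/s})^2$.  With that conversion a
single factor reproduces, simultaneously, the secondary-peak ratio, the
ripple ratios, both attenuation slopes, the impulse-spectrum peak spacing
and the plateau ratios at their standard $\kappa$ values.  The builders for
kilohertz banks therefore take `kappa_unit = "rad2_per_ms2"` by default and
convert internally; the Wilson bank (solved in seconds) keeps its constants
in $(\mathrm{rad/s})^2$ unchanged.

## The measurement toolkit

* `steady_state_profile()` measures amplitude as the peak $|x_j|$ over the
  final three drive cycles (matching the classic protocol; not RMS) and
  phase as the single-frequency Fourier component over the same window,
  obtained by least squares against $\sin\omega t$ and $\cos\omega t$ so
  that non-integer samples per cycle introduce no bias.
* **Phase unwrapping** runs along the array in the direction of accumulating
  lag (toward lower natural frequency) with the branch window
  $[-\pi/2, 3\pi/2)$.  A conventional symmetric $(-\pi,\pi]$ unwrap fails on
  the 21-reed bank at strong coupling: at amplitude minima the lag jumps by
  *more* than $\pi$ between adjacent reeds, and the symmetric rule silently
  drops whole turns (reporting 0.52 cycles of total lag where the true
  accumulation is 2.5).  The asymmetric window admits those rapid forward
  transitions while tolerating small backward wiggles.
* `find_peaks()` detects local maxima of $20\log_{10}$ magnitude with a
  topographic-prominence threshold (default 1 dB — the ripples are tiny on a
  linear scale but regular in dB) and refines locations by a three-point
  quadratic fit in the dB domain.
* `attenuation_slopes()` fits $20\log_{10}$ amplitude against $\log_2$
  natural frequency over the region 3--23 dB below the single-driven reed's
  peak, stopping at the first reed below the lower bound so the ripple train
  cannot re-enter the fit.  The window is a fixed design choice; note that on
  the high-frequency side the local slope keeps steepening with distance
  (from roughly 400 dB/oct one reed out to 700+ dB/oct at the window's far
  edge), so the fitted value sits below the far-field asymptote that a
  by-eye line through the tail would give.
* `phase_band_period()` measures the spatial periodicity of the
  amplitude/phase bands as the spacing between amplitude minima (minima and
  rapid phase transitions coincide; the minima are numerically the more
  robust marker).  Because the band spacing shrinks roughly geometrically
  away from the main peak (successive ripple ratios near 1.03), a mean over
  *every* minimum depends on how far the array happens to extend; the
  default therefore reports the spacing of the fully developed band adjacent
  to the main peak (`n_bands = 1`), which is extent-independent, with
  `n_bands = Inf` available for the whole-array mean.
* `impulse_spectrum()` transforms the full (transient-complete) impulse
  records without a taper window, zero-padded eightfold so that quadratic
  interpolation can resolve peak spacings at ratios near 1.05 from 50 ms
  records whose native resolution is 20 Hz.
* `plateau_ratios()` collapses runs of oscillators sharing a dominant
  frequency.  Two neighbours belong to one plateau when their dominant
  frequencies differ by less than half the *local tonotopic step*: cluster
  members are nearly synchronised (differences far below the gradient),
  while an unclustered map steps by exactly the gradient and never merges.
  Tying the tolerance to the FFT grid instead turns out to be fragile — the
  padded grid is finer than the slow drift of the interpolated peak across
  one cluster, and the native grid can exceed the tonotopic step.
  `min_run = 3` keeps single oscillators from counting as plateaus.
* `settling_time()` declares a reed settled at the earliest cycle boundary
  after which every cycle's peak stays within 2% of the final steady-state
  amplitude.  This is stricter than it sounds: reeds sitting at a spatial
  amplitude minimum have small steady amplitudes but receive
  normally-sized transients through their neighbours, so their *relative*
  residual crosses 2% last — at (κ, γ) = (2500, 0.014) and 50 Hz a few reeds
  settle only around 2.3--2.6 s even though the pattern looks steady on a
  plot well before 2 s.

## Scenario runner and fixtures

`run_scenario()` reproduces each canonical experiment (switch-on transients,
waterfalls, the 51-combination coupling sweep, response maps, boundary-taper
comparison, single-reed forcing, phase bands, impulse spectra, plateau
clustering) and writes a deterministic bundle: config echo, per-stage CSVs,
derived statistics as JSON, and a log (the only file with timestamps).  The
default durations follow the original protocols — 5 s for the 21-reed forced
runs, 100 ms for the 201-reed forced runs, 50 ms for impulses — and a
`scale` factor shrinks durations and grid resolutions proportionally for
quick runs.  A thin command-line wrapper is installed under
`inst/cli/frahm`.

`generate_fixture_bank()` draws small random banks (by default 3--12 reeds,
40--60 Hz monotone profiles, $\kappa \le 5000$, $\gamma \in [0.005, 0.05]$)
for property-style tests.  These fixtures exercise the mathematics — the
engines, reciprocity, superposition, power balance — not the biology: they
make no attempt to emulate measured cochlear maps, noise, or nonlinearity,
so green property tests certify the solver and the measurement chain, not
agreement with real ears.  Agreement with the study's published numbers is
checked separately in the acceptance suite at the study's own
configurations.

## Degenerate inputs and edge cases

Banks validate on construction ($n \ge 2$, positive frequencies,
non-negative damping and coupling, mask in $[0,1]$, exactly $n-1$ links).
$\kappa = 0$ reduces every operation to the closed-form single oscillator,
which the tests exploit as an oracle.  An undamped bank driven exactly at a
resonance of the coupled system would make the phasor matrix singular; this
is detected and reported rather than returned as infinities.  All-zero
series produce empty peak sets; profiles with fewer than two minima, fit
windows with fewer than three reeds, and flat spectra raise informative
errors instead of fabricating statistics.

## Known limitations

* Entirely passive and linear: no van der Pol (active) elements, no
  compressive nonlinearity, no complex (dissipative) coupling — so no
  spontaneous emissions or level-dependent tuning.
* Strictly nearest-neighbour coupling; no fluid (long-range) coupling and no
  transmission-line equivalent.
* The millisecond/SI coupling convention above is an inference from
  published behaviour, made explicit and overridable rather than hidden.
* The time-domain engine caps at 1000 reeds (fixed parameter block in the
  compiled code); the phasor engine has no such limit.
* Measurement defaults (1 dB prominence, 3--23 dB slope window, three-cycle
  amplitude window) are fixed, documented choices; results quoted from the
  package should state them when they matter.

## Problem sizes used by the tests

The test and acceptance suites run the full study-scale configurations —
201-oscillator banks, 5 s Wilson runs, 100 ms forced and 50 ms impulse
kilohertz runs, a 601-point response map — plus 50 randomly generated small
banks for the cross-engine equivalence property.  The whole suite completes
in about two minutes on a single CPU.
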