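---
title: "Oscillatory-interference grid cell simulation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oscillatory-interference grid cell simulation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(oscgrid)
```

## The model

`oscgrid` simulates a single medial entorhinal grid cell as a leaky
integrate-and-fire (LIF) neuron driven by six populations of
head-direction-selective "band cells" acting as velocity-controlled
oscillators (VCOs). The membrane potential follows the explicit Euler
update

$$V_m(t+\mathrm{d}t) = V_m(t) + \left[I(t) -
  \tfrac{1}{\tau_{GL}}\bigl(V_m(t) - E_L\bigr)\right]\mathrm{d}t,$$

with no spike reset and no refractory period: every sample with
$V_m > V_t$ is a spike sample, so several spike samples can occur within
one theta cycle. Defaults are $\tau_{GL} = 0.1$ s, $E_L = -67$ mV,
$V_t = -56$ mV, $\mathrm{d}t = 0.002$ s.

Each band-cell population $n$ receives a common 6 Hz baseline
oscillation with its own phase offset $\varphi_n$ and accumulates a VCO
phase $\theta_n$ at the instantaneous angular frequency

$$\omega_n(t) = \omega_b + g\,\beta\, s(t)
  \cos\bigl(\Phi(t) - \Phi_n\bigr),$$

where $s$ is running speed, $\Phi$ the heading, $\Phi_n$ the preferred
heading ($0°, 60°, \dots, 300°$) and $\omega_b = 2\pi\cdot 6$ rad/s.
The population output is the sigmoid-rectified interference of baseline
and VCO, gated to zero whenever the heading is more than 90° from the
preferred heading:

$$HD_n(t) = S\bigl(\cos(\omega_b t + \varphi_n) +
  \cos\theta_n(t)\bigr)\cdot H\bigl(|\Phi - \Phi_n|\bigr),
  \qquad S(x) = \frac{1}{1+e^{-a(x-T)}} - \frac{1}{1+e^{aT}}.$$

The grid cell input is $I(t) = \sum_n G_I\, HD_n(t)$ with $G_I = 100$,
$a = 4$, $T = 1$. Because the population's accumulated phase, relative
to its baseline, equals $g\beta$ times the displacement projected onto
its preferred direction, each population fires in parallel spatial
bands of wavelength $2\pi/(g\beta)$ cm; summing six populations 60°
apart produces firing at the vertices of a triangular lattice, and
half-wave rectification gives the summed input a positive, non-linear
mean that the long membrane time constant integrates into an in-field
DC depolarization ("ramp").

Three numerical points deserve mention:

* **The phase gain `g`.** The published VCO update mixes a phase-valued
  and a rate-valued term, and taken verbatim produces no spatial
  banding; the unit convention behind $\beta$ is not recoverable. We
  therefore integrate an instantaneous frequency (above) and introduce
  one dimensionless calibration gain, fixed once (g = 30) so that the
  wide-spacing configuration $\beta = 0.00385$ yields exactly two
  discrete firing fields across a 200 cm straight transect. Any
  $g \in (16.3,\,32.6)$ satisfies that constraint; 30 is the round
  default. With the standard $\beta = 0.002$ this puts the lattice
  constant at $\approx 121$ cm: a central vertex plus a hexagonal ring
  inside the 200 × 200 cm arena. See "Known limitations" for what this
  choice implies.
* **Rectification.** $S(x)$ as printed has a small negative tail
  ($S(-2) \approx -0.018$). `sigmoidActivation()` implements the
  equation; `bandActivity()` clips population output at zero, since the
  output models a firing rate and the summed input must be
  non-negative. All tabulated values ($S(0)=0$, $S(1)$, $S(2)$) are
  unaffected.
* **Phase initialization.** $\theta_n(0) = \varphi_n$, so every VCO
  starts aligned with its own baseline and the trajectory origin is a
  constructive-interference point (a lattice vertex sits at the start
  position).

## Trajectories

`randomWalk()` implements a momentum random walk,
$\Delta x(t) = s(1-m)p + m\,\Delta x(t-1)$ with $p \sim N(0,1)$ per
axis and step, $s = 1.7$, $m = 0.999$, $\mathrm{d}t = 2$ ms, initial
step $(0.35, 0.35)$, in a 200 × 200 cm arena starting at the center.
A step that would exit the arena is reflected as $-R\,\Delta x$
($R = 0.6$) in the offending dimension only; in the rare case the
reflected step still exits, the position is clamped to the wall. The
stationary per-axis step s.d. is $s\sqrt{(1-m)/(1+m)}$, which gives a
mean speed of $\approx 23$ cm/s, matching the reference value of
22.74 cm/s within a few percent.

`straightLineTrajectory()` produces constant-velocity runs (default
5 cm/s), and `readTrajectory()` ingests recorded `(t, x, y)` tables
sampled at 0.02 s and up-samples them to 2 ms by linear interpolation.
Headings over zero-speed samples carry the previous moving heading
forward to avoid an undefined `atan2(0, 0)`.

## Analysis pipeline

**Field classification.** The arena is divided into 5 cm bins. The
spike series is circularly rotated 1000 times by offsets uniform on
$[0.05N, 0.95N]$; each bin's empirical percentile $1-P$ is the fraction
of shuffles whose rate falls strictly below the observed rate.
In-field bins are members of a 3 × 3 block entirely at or above the
85th percentile, extended one bin outward (8-neighborhood, single
pass) where the 70th percentile is reached; out-of-field bins are
members of a 2 × 2 block at or below the 5th percentile. Ties count
into $P$: with 1–2 s of occupancy per bin the shuffled count is zero
in a quarter to three quarters of shuffles, and counting ties the
other way would make the out-of-field class unreachable for any bin.
Bins visited for fewer than 2 samples are excluded from rate maps
rather than zero-filled.

**Amplitude series.** The membrane trace (mean removed) is band-pass
filtered at 0.1–3 Hz (DC-shift component) and 5–10 Hz (theta
component) with a 2nd-order Butterworth applied forwards and
backwards; the series is mirror-extended over three filter time
constants at each end before filtering and the first/last 2 s are
excluded from class means. The theta envelope is the modulus of the
FFT-based analytic signal (internally mirror-padded to a highly
composite length so the transform stays fast for any series length).
For in/out-of-field comparisons the out-of-field mean is subtracted
from the DC series, making $\Delta\mathrm{amp}_{DC}$ simply the
in-field mean.

**Spike subsampling.** For precession and rate-correlation analyses at
most one spike is kept per membrane theta cycle: cycles are delimited
by troughs of the 5–10 Hz component, and the above-threshold sample
nearest each cycle's peak is retained. Rate maps and field
classification use the raw spike samples.

**Precession.** The field-index map is a 1 cm occupancy-normalized
rate map smoothed with a 5-bin-SD Gaussian and min–max normalized; the
pass index is the analytic phase of the mean-centered field-index
series (mean-centering is needed because the analytic phase of a
positive-mean series is dominated by the mean). Spike phases are
measured against the 0°-population baseline. The circular–linear
correlation fits the slope maximizing the resultant of
$\phi - 2\pi a x$, then correlates the phases with $2\pi|a|x$; using
$|a|$ in the circular transform lets the sign of $\rho$ carry the
direction of the relation (negative = precession).

**Rate correlations and information.** Three protocols: (i) per-ISI —
rate $= 1/\mathrm{ISI}$ paired with interval means of each amplitude
series, pooled over 10 × 1 min simulations, correlated unbinned and
after averaging within 8 equal-width amplitude bins (empty bins
dropped, sparse bins kept); (ii) sliding window — 1 s windows stepped
by $\mathrm{d}t$ over 20 × 10 min simulations, window spike count
normalized by each simulation's mean rate; (iii) mutual information —
a plug-in estimator on an 8 × 8 equal-width joint histogram between
each amplitude series and the field-index series, reported as the
DC : theta MI ratio per simulation. Differences between the two
dependent correlations are tested with Steiger's $Z_H$ (Fisher
transforms with the Dunn–Clark covariance at the average correlation);
its null calibration is verified by Monte-Carlo in the test suite.
The time-constant sweep co-adapts the threshold by +1 mV per +10 ms of
$\tau_{GL}$ (`thresholdForTau()`), interpolating linearly between the
listed pairs, with thresholds stored as physiological negative mV.

## What the generator emulates — and what it does not

The synthetic trajectories reproduce the speed statistics and wall
avoidance of a foraging rodent but not behavioral structure such as
thigmotaxis bouts, rests, or home-base returns; heading diffuses with a
~2 s correlation time, so it fluctuates a few degrees per theta cycle,
which real tracking data smoothed to 0.02 s does not show. The model
itself is noiseless: all variability in the statistics comes from the
trajectory. Passing tests therefore demonstrate internal consistency
of the model and pipeline, not fidelity to in vivo recordings.

## Problem sizes

The bundled test suite uses 300 s simulations with 200 shuffles for
unit-level checks, and for the study-level checks: 5 × 2000 s runs for
the amplitude differences, 10 × 1 min for the per-ISI and MI
protocols, 20 × 2 min for the sliding-window protocol (the acceptance
script runs the full 20 × 10 min), 600 s × 3 repetitions per
time-constant for the sweep, and 2000 s maps for gridness. These sizes
keep every statistic's sampling error well inside the tolerances being
asserted.

## Known limitations

* **One gain cannot reconcile all reference figures.** Calibrating `g`
  to the two-field straight-line transect fixes the default lattice
  constant at ~121 cm, a sparse-field regime. The reference random-walk
  figures imply a considerably denser grid (a full triangular lattice
  in the same arena, and an in-field spike density unreachable at
  121 cm spacing). In the sparse regime the pooled per-ISI records
  separate into an in-field and an out-of-field cluster that *both*
  amplitude series discriminate, which drives the theta-envelope/rate
  correlations up toward the DC ones; at a dense-regime gain (~60) the
  binned correlations and MI ratio land on the reference values but
  the two-field transect breaks. The package keeps the two-field
  calibration and reports what follows from it.
* **2D pass-index precession is weak under spread baseline offsets.**
  Each population's activity bumps sit at baseline phase
  $-\varphi_n - \delta_n/2$ relative to the 0° reference; as heading
  rotates, the dominant population changes and spike phases jump
  between offset-separated clusters, swamping the ~0.3–0.5 rad
  within-pass sweep. Setting all $\varphi_n = 0$ recovers strong
  pooled precession ($\rho \approx -0.8$), and straight-line runs
  always precess cleanly ($\rho \approx -0.9$); with the spread
  offsets that generate robust DC shifts, pooled random-walk $\rho$
  hovers near zero. This is a structural property of the offset
  architecture, not of the analysis.
* **Gridness does not collapse under a fixed threshold here.** With
  $V_t$ fixed at $-65$ mV and $\tau_{GL} = 100$ ms the cell fires on
  >90% of samples, yet the correlation-based gridness stays high
  because the deep voids between the widely spaced fields still
  modulate the map; truly constant firing (and hence gridness loss)
  requires the dense-field regime.
* The gridness annulus radii (first zero crossing of the central peak;
  1.25 × the median distance to the six nearest ring peaks, with
  fixed-fraction fallbacks) are one reasonable reading of the
  rotational-symmetry score; absolute scores depend on these choices,
  so only ordinal comparisons are asserted.
* Classification extension bins are applied in a single pass, not
  iteratively; percentile ties are resolved as described above.
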