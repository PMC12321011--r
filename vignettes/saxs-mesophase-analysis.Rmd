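---
title: "Mesophase identification and photoswitching kinetics from 1D SAXS curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesophase identification and photoswitching kinetics from 1D SAXS curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(saxsmeso)
```

## The problem

Lyotropic liquid crystals of phospholipids (DPPC, DLPC) mixed with
photoswitchable azobenzene amphiphiles form ordered mesophases — lamellar
bilayer stacks, bicontinuous cubic phases of space group Pn3m or Im3m,
and occasionally 2D hexagonal arrangements. Reduced 1D small-angle X-ray
scattering (SAXS) curves of such systems show sharp Bragg peaks whose
positions obey

$$ q_m = \frac{2\pi\, m}{a}, $$

where $a$ is the lattice parameter (the repeat distance $d$ for a
lamellar stack) and $m$ is the dimensionless spacing ratio of the
reflection: $m = n$ for lamellar order $n$, $m = \sqrt{h^2+k^2+l^2}$ for
cubic $hkl$, and $m = \sqrt{h^2+hk+k^2}$ (normalized to the first
reflection) for hexagonal. Which reflections are *allowed* follows from
the space-group reflection conditions; the package derives the tables by
brute-force enumeration rather than storing literals:

* lamellar — every order: $m = 1, 2, 3, \dots$
* Pn3m — $h00$ with $h$ even, $hk0$ with $h+k$ even:
  $m = \sqrt2, \sqrt3, \sqrt4, \sqrt6, \sqrt8, \sqrt9, \dots$
  (so $m^2 = 1, 5, 7$ are extinct)
* Im3m — body centring, $h+k+l$ even:
  $m = \sqrt2, \sqrt4, \sqrt6, \sqrt8, \sqrt{10}, \sqrt{12}, \dots$
* hexagonal — $m = 1, \sqrt3, \sqrt4, \sqrt7, \dots$

The analysis pipeline answers three questions: *which phases coexist in
a sample* (and at what lattice parameters, with what uncertainty), *does
illumination change the structure* (mesophase transition vs. d-spacing
shift vs. nothing), and *on what timescale* does a light-induced
transition proceed.

## The two-step fitting approach

Structure determination runs in two steps.

**Step 1 — peak fitting.** Candidate peaks are local maxima of a lightly
smoothed curve (5-point moving average) whose prominence above a local
linear baseline exceeds `min_prominence_snr` (default 3) times a robust
noise estimate — the median absolute deviation of the detrended curve,
which is insensitive to the peaks themselves. Candidates closer than
`min_separation` (default $3\sigma_q$) merge, keeping the higher apex.
Each candidate is then fitted as a Gaussian plus a local linear
background over a window of $\pm 5$ initial width guesses; candidates
with overlapping windows are fitted jointly as a sum of Gaussians
sharing one background. Two background starting points (detrended chord
and flat-at-minimum) guard against local minima in the larger joint
windows. Parameter uncertainties come from the local fit covariance
scaled by the reduced chi-square.

**Step 2 — lattice regression.** Assigned peak positions are regressed
through the origin, $q_i = (2\pi/a)\, m_i$, weighted by
$1/\sigma_{q,i}^2$ when position uncertainties are available. The
uncertainty of $a$ comes from the residual scatter of the positions
about the fitted lattice — the deviations of the peak positions are the
error estimate — with two guards: a single assigned peak propagates its
own position uncertainty instead, and when position uncertainties are
supplied the reported variance is never smaller than what they propagate
to (residual scatter estimated from one degree of freedom badly
under-covers).

## Phase identification by combination search

Observed peaks are explained by checking combinations of candidate
phases. For every subset of candidates (up to `max_phases`, default 3)
and every ordering of the subset, phases are seeded one at a time: the
lowest-q peak not yet claimed is tried as each low-order reflection of
the phase, peaks within `tol` (relative q, default 0.01) of the implied
positions are claimed greedily (one peak per reflection, nearest first),
and claim/refine iterates to a fixed point.

Assignments are ranked lexicographically:

1. fewest unexplained peaks — a peak may stay unexplained rather than
   force a bad match;
2. fewest phases whose *first* allowed reflection lies inside the
   measured window yet matches no peak. In lyotropic systems the
   lowest-order reflection is the strongest; an indexing that requires
   it to be invisible is almost surely a ratio artifact. This is what
   breaks the exact degeneracy between, e.g., Pn3m at $a$ claiming
   $(\sqrt2,\sqrt4,\sqrt6)$ and Pn3m at $a\sqrt{3/2}$ claiming
   $(\sqrt3,\sqrt6,\sqrt9)$ of the same three peaks;
3. fewest internal gaps — predicted reflections inside the window,
   below the highest claimed order, that match no peak. Orders beyond
   the last observed one may simply be weak; a skipped low order is
   damning;
4. fewest phases (parsimony), then lowest relative position RMS, then a
   fixed phase-name order so the ranking is deterministic.

All assignments within a reporting margin of the best are returned, so
near-degenerate alternatives stay visible instead of being silently
resolved. Phases supported by a single peak are flagged
`underdetermined`. The hexagonal candidate is opt-in
(`default_candidates(include_hexagonal = TRUE)`): its low-order ratios
$1 : \sqrt3 : \sqrt4$ coincide exactly with the ratios of Im3m's first
three observable reflections, so as a default candidate it would shadow
every Im3m assignment whenever the discriminating higher orders are weak
or merged.

Comparing two states (`compare_states`) classifies the outcome as a
mesophase transition (phases appear/disappear), a d-spacing shift, or no
change. A shift counts as significant when the two $a \pm \sigma$ error
bars do not overlap ($|\Delta a| > \sigma_1 + \sigma_2$) — the way such
tabulated values are read in practice, and the reading under which a
$6.51 \pm 0.01 \to 6.47 \pm 0.02$ nm change is a real 0.04 nm decrease.
A $z\sqrt{\sigma_1^2+\sigma_2^2}$ rule with $z = 2$ would call that same
change insignificant, which contradicts how the structural tables it is
meant to reproduce are interpreted.

## Time-resolved analysis

Time-resolved runs are fitted the way static runs fix them: the
structural parameters (positions from the seed lattices, a common width)
are held constant across the series and only amplitudes vary. Each frame
is then one *linear* weighted least-squares solve over a basis of
Gaussians at every known reflection position plus a smooth background
$c_0 + c_1 q + c_2 q^{-2}$. Linearity buys three things that per-peak
window fits could not deliver: the per-frame solution is unique (no
local minima, no component swapping between reflections 1.4 widths
apart, such as lamellar 100 and Pn3m 111), overlapping reflections are
handled by the normal equations rather than ad hoc windows, and honest
amplitude standard errors come straight from the weighted design matrix.

Tracked amplitudes are divided by the fitted amplitude of a spectator
reference reflection (Im3m 211 by default), cancelling per-frame scale
factors; the reference trace is identically 1. A fitted amplitude below
3 times the frame noise, or within 2 standard errors of zero, is
recorded as 0 with the local noise level as its uncertainty — vanished
peaks keep their time points.

Onset detection: the first frame deviating from the baseline mean by
more than `threshold` (default 3) baseline standard deviations, with the
next frame also deviating (debounce, so a single noisy frame never
triggers). The baseline window should cover the pre-change frames; for a
flat trace that is naturally a generous window. When per-frame
uncertainties are available the baseline scatter is floored at their
median — an empirical standard deviation from a handful of frames
fluctuates far too much to control a 3-sigma rate. Completion: the first
frame at or after onset from which every later value stays within
`tolerance` (default 5% of the total change, floored at 3 times the
per-frame uncertainty) of the final plateau; a trace still moving in its
last frames reports "not reached". Lamellar $d(t)$ tracking refits the
lamellar orders per frame (positions free within a 2% drift cap, all
visible orders modelled so unmodelled ones cannot inflate the residual
scale) and regresses $d$ per frame with its uncertainty.

## The synthetic generator

`generate_pattern()` builds $I(q) = A q^{-p} + C + \sum \mathrm{amp}\,
e^{-(q-q_m)^2/2\sigma_q^2}$ plus noise; `generate_kinetic_series()`
interpolates phase amplitudes between an initial and a final composition
(decay onset, delayed growth onset, common completion time,
piecewise-linear or endpoint-exact logistic shape), holds spectator
phases constant, and can drift a persisting phase's lattice between two
values. Defaults encode the studied conditions: q window 0.5–4.5 nm⁻¹
(512 points), Gaussian peaks of width 0.02 nm⁻¹, geometric intensity
decay 0.5 per order, lamellar decay starting 30 s after illumination,
Pn3m growth delayed to 50 s, completion at 120 s, frames every 10 s, and
either 2% fractional Gaussian noise or Poisson counting noise. An
intensity-transfer mode rescales growing amplitudes so total Bragg area
is conserved.

What the generator does *not* emulate — instrument smearing, structure
factors (relative intensities are free parameters), form-factor
scattering between peaks, detector artifacts, radiation damage — bounds
what passing tests show: they validate the inference machinery under the
model's own assumptions (Gaussian peaks on smooth background, counting
or fractional noise), not robustness to every feature of real beamline
data. Deposited measurements can be analyzed by pointing `run_analyze`
or `run_kinetics` at a manifest of 3-column ASCII curves.

## Numerical choices and problem sizes

* Peak width default $\sigma_q = 0.02$ nm⁻¹, a sharp powder ring at
  typical beamline resolution; the fitters treat it as an initial guess
  (static) or basis width (kinetics), configurable everywhere.
* Background default $A q^{-2} + C$: a generic diffuse-bilayer shape.
* Reflection lists truncate at 6 allowed reflections per phase;
  the 0.5–4.5 nm⁻¹ window and 6–13 nm lattices admit few more.
* Indexing tolerance is relative q (not absolute) because lattice
  parameters span 6–13 nm; the default 0.01 suits well-fitted positions,
  and should be ~3 times the expected relative position scatter.
* Degenerate inputs error early: non-increasing q grids, mismatched
  background grids (no silent regridding — regrid explicitly), empty
  peak lists, missing reference peaks (the offending frame is named).
* Test and acceptance problem sizes: 50 lattices per phase for round
  trips, 100 random mixtures for recovery, 10–20 noise seeds for
  Monte-Carlo calibrations, 19-frame kinetic series — enough replicates
  to pin the Monte-Carlo rates the properties assert.

## Known limitations

* Scoring uses peak positions only; relative intensities never enter
  the ranking (they are not structure-factor predictions), so
  ratio-coincident candidates at similar gap counts can tie — ties are
  reported, not resolved.
* The kinetics decomposition assumes constant peak positions and widths
  across the series; systems whose cubic lattices swell during the
  transition would need the d-tracking path per phase instead.
* Cubic lattice parameters are reported as the unit-cell edge $a$; for
  lamellar (and the hexagonal option) the reported value is the repeat
  distance of the first reflection.
* The NeXus-style result container is a hierarchical JSON document with
  NXcanSAS-inspired group names, validated against the package's own
  reader only.
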