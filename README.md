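# saxsmeso

Mesophase identification and photoswitching kinetics from 1D SAXS curves
of lyotropic liquid crystals.

Lipid–water systems (e.g. DPPC or DLPC mixed with photoswitchable
azobenzene amphiphiles) form lamellar, bicontinuous cubic (Pn3m, Im3m)
and hexagonal mesophases. Their reduced small-angle X-ray scattering
curves show Bragg peaks at

    q_m = 2π·m / a

where `a` is the lattice parameter (the repeat distance `d` for a
lamellar stack) and `m` is the spacing ratio of an allowed reflection:
`m = n` for lamellar order `n`, `m = √(h²+k²+l²)` for cubic `hkl`.
Space-group extinction rules fix the allowed sequences —
lamellar `1, 2, 3, …`; Pn3m `√2, √3, √4, √6, √8, √9, …`;
Im3m `√2, √4, √6, √8, √10, √12, …` — and those ratio fingerprints are
what lets a peak list be decomposed into coexisting phases.

The package provides, as composable R functions:

* **Peak fitting** — robust detection plus joint Gaussian/local-background
  fits with parameter uncertainties (`detect_peaks`, `fit_peaks`);
* **Phase indexing** — combination search over candidate phases, ranked
  by unexplained peaks, missing allowed reflections, parsimony and
  position RMS, with lattice parameters from weighted through-origin
  regression and errors from the position residuals (`index_phases`,
  `lattice_from_assignments`, `compare_states`);
* **Kinetics** — per-frame linear decomposition of time-resolved series
  with fixed structural parameters, reference-peak normalization,
  onset/completion detection and lamellar d(t) tracking (`track_series`,
  `detect_onset`, `detect_completion`, `track_d_spacing`);
* **Synthetic data** — a generator for static patterns and kinetic frame
  series with known ground truth (`generate_pattern`,
  `generate_kinetic_series`), so the whole chain is testable without
  beamline data;
* **I/O and pipeline** — 3-column ASCII curves, series manifests, a
  NeXus-style JSON result container, and `run_simulate` / `run_analyze` /
  `run_kinetics` orchestration (also exposed as the `inst/exec/saxsmeso`
  command-line wrapper).

## Worked example

A three-phase coexistence — lamellar at 6.9 nm, Pn3m at 11.6 nm, Im3m at
12.7 nm — simulated with Poisson counting noise and recovered blind:

```r
library(saxsmeso)

pat <- generate_pattern(
  list(phase_spec("lamellar", 6.9, 3000),
       phase_spec("Pn3m",    11.6, 1500),
       phase_spec("Im3m",    12.7, 1000)),
  noise_spec(noise = "poisson", seed = 1))

peaks   <- fit_peaks(pat, detect_peaks(pat))
ranking <- index_phases(peaks, q_window = c(0.5, 4.5))
ranking[[1]]
#> <phase_assignment> Im3m + Pn3m + lamellar
#>   Im3m       a = 12.706 +/- 0.022 nm (4 peaks)
#>   Pn3m       a = 11.607 +/- 0.016 nm (3 peaks)
#>   lamellar   a = 6.900 +/- 0.003 nm (4 peaks)
#>   unexplained 0, missing 2, rel. RMS 2.41e-03
```

Every observed peak is assigned to a (phase, reflection) pair; the three
lattice parameters come back within their quoted uncertainties, and the
ranking keeps any near-degenerate alternative visible.

A light-induced lamellar→Pn3m transition (lamellar decay starting 30 s
after illumination, delayed Pn3m growth at 50 s, completion at 120 s,
constant Im3m spectator, 2% noise):

```r
spec <- kinetic_spec(
  initial = list(phase_spec("lamellar", 6.9, 3000),
                 phase_spec("Im3m", 12.7, 1000)),
  final   = list(phase_spec("Pn3m", 11.6, 1500),
                 phase_spec("Im3m", 12.7, 1000)),
  t_on_decay = 30, t_on_growth = 50, t_end = 120)
frames <- generate_kinetic_series(spec,
  noise_spec(noise = "gaussian-fractional", level = 0.02, seed = 1))

tr <- track_series(frames,
  data.frame(phase = c("lamellar", "lamellar", "Pn3m"),
             reflection = c("100", "200", "110")),
  seed = c(lamellar = 6.9, Pn3m = 11.6, Im3m = 12.7),
  reference = c("Im3m", "211"))
kinetics_summary(tr)
#>      phase reflection t_onset t_complete
#> 1 lamellar        100      40        120
#> 2 lamellar        200      40        120
#> 3     Pn3m        110      60        120
#> 4     Im3m        211      NA         NA
```

Intensities are normalized to the Im3m 211 spectator (its trace is
identically 1, hence no onset). The lamellar peaks first deviate at the
frame after the 30 s onset, the Pn3m 110 peak follows at its delayed
onset, and all traces plateau at 120 s.

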