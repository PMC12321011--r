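# Shared builders for synthetic inputs used across the test files.

quiet_noise <- function() noise_spec(A = 0, C = 0, noise = "none")

# The three-phase trans-state mixture used repeatedly: lamellar 6.9 nm +
# Pn3m 11.6 nm + Im3m 12.7 nm.
threephase_specs <- function(amp = c(3000, 1500, 1000)) {
  list(phase_spec("lamellar", 6.9, amp[1]),
       phase_spec("Pn3m", 11.6, amp[2]),
       phase_spec("Im3m", 12.7, amp[3]))
}

# Lamellar-to-Pn3m photoswitching series with an Im3m spectator.
switching_spec <- function(t_on_decay = 30, t_on_growth = 50, t_end = 120,
                           frame_times = seq(0, 180, by = 10),
                           shape = "piecewise-linear") {
  kinetic_spec(
    initial = list(phase_spec("lamellar", 6.9, 3000),
                   phase_spec("Im3m", 12.7, 1000)),
    final = list(phase_spec("Pn3m", 11.6, 1500),
                 phase_spec("Im3m", 12.7, 1000)),
    t_on_decay = t_on_decay, t_on_growth = t_on_growth, t_end = t_end,
    frame_times = frame_times, shape = shape)
}

default_tracked <- function() {
  data.frame(phase = c("lamellar", "lamellar", "Pn3m"),
             reflection = c("100", "200", "110"))
}

seed_lat <- c(lamellar = 6.9, Pn3m = 11.6, Im3m = 12.7)
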