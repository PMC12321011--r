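#' Specify one phase of a synthetic pattern
#'
#' Describes the Bragg contribution of a single mesophase: Gaussian peaks
#' at the phase's allowed reflection positions with a configurable
#' amplitude pattern. Relative reflection intensities are free parameters
#' (default geometric decay with ratio 0.5), not structure-factor
#' calculations: the downstream analysis uses only positions and per-peak
#' intensities.
#'
#' @param phase mesophase name passed to [mesophase_model()].
#' @param a lattice parameter in nm (> 0).
#' @param amplitude apex amplitude of the strongest reflection (counts).
#' @param sigma_q common Gaussian peak width in nm^-1 (default 0.02,
#'   a sharp powder ring at typical beamline resolution).
#' @param rel_intensities optional vector of per-reflection relative
#'   intensities; recycled/truncated to the model's reflection count.
#' @param n_reflections reflections to simulate (default 6).
#' @return object of class `phase_spec`.
#' @export
phase_spec <- function(phase, a, amplitude = 1000, sigma_q = 0.02,
                       rel_intensities = NULL, n_reflections = 6L) {
  stopifnot(a > 0, amplitude >= 0, sigma_q > 0)
  model <- mesophase_model(phase, n_reflections)
  n <- nrow(model$reflections)
  if (is.null(rel_intensities)) rel_intensities <- 0.5^(seq_len(n) - 1L)
  rel_intensities <- rep_len(rel_intensities, n)
  if (any(rel_intensities < 0)) stop("relative intensities must be >= 0")
  structure(list(model = model, phase = model$name, a = a,
                 amplitude = amplitude, sigma_q = sigma_q,
                 rel_intensities = rel_intensities),
            class = "phase_spec")
}

#' Specify background and noise of a synthetic pattern
#'
#' The background is \eqn{A q^{-p} + C}, a generic diffuse-scattering
#' shape. Noise models: `"none"`, `"gaussian-fractional"` (sd = level x
#' model intensity) or `"poisson"` (counting statistics; intensities are
#' treated as counts). A fixed seed makes output bit-reproducible.
#'
#' @param A power-law amplitude (counts), default 50.
#' @param p power-law exponent, default 2.
#' @param C constant background (counts), default 10.
#' @param noise one of "none", "gaussian-fractional", "poisson".
#' @param level fractional noise level for gaussian-fractional (default 0.02).
#' @param seed optional integer RNG seed.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(A = 50, p = 2, C = 10,
                       noise = c("none", "gaussian-fractional", "poisson"),
                       level = 0.02, seed = NULL) {
  noise <- match.arg(noise)
  stopifnot(A >= 0, C >= 0, level >= 0)
  structure(list(A = A, p = p, C = C, noise = noise, level = level,
                 seed = seed), class = "noise_spec")
}

# Run code under a local RNG stream (restores .Random.seed afterwards).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Noise-free model intensity of a phase mixture on a q grid.
model_intensity <- function(phases, noise, q) {
  I <- noise$A * q^(-noise$p) + noise$C
  for (ph in phases) {
    pos <- reflection_positions(ph$model, ph$a, range(q))
    if (nrow(pos) == 0L) next
    amps <- ph$amplitude * ph$rel_intensities[seq_len(nrow(pos))]
    for (j in seq_len(nrow(pos))) {
      I <- I + amps[j] * exp(-(q - pos$q[j])^2 / (2 * ph$sigma_q^2))
    }
  }
  I
}

#' Generate one synthetic SAXS pattern
#'
#' \eqn{I(q) = A q^{-p} + C + \sum \mathrm{amp}\,e^{-(q-q_m)^2/2\sigma_q^2}}
#' plus noise per the noise model. The uncertainty column matches the noise
#' model (fractional: level x model; Poisson: sqrt(model); none: absent).
#' The generating truth (phases, lattices, amplitudes) is attached as
#' attribute `ground_truth`.
#'
#' @param phases list of [phase_spec()] (a single spec is accepted).
#' @param noise a [noise_spec()].
#' @param q_grid strictly increasing positive grid (default 512 points over
#'   0.5-4.5 nm^-1, the analysis window).
#' @param metadata metadata list for the pattern.
#' @return a [saxs_pattern()] with attribute `ground_truth`.
#' @export
generate_pattern <- function(phases, noise = noise_spec(),
                             q_grid = default_q_grid(),
                             metadata = list()) {
  if (inherits(phases, "phase_spec")) phases <- list(phases)
  stopifnot(all(vapply(phases, inherits, logical(1), "phase_spec")))
  if (any(q_grid <= 0)) stop("q grid must be positive")
  if (any(diff(q_grid) <= 0)) stop("q grid must be strictly increasing (no duplicates)")
  I_model <- model_intensity(phases, noise, q_grid)
  res <- with_seed(noise$seed, apply_noise(I_model, noise))
  gt <- list(
    phases = lapply(phases, function(ph) list(
      phase = ph$phase, a = ph$a, amplitude = ph$amplitude,
      sigma_q = ph$sigma_q, rel_intensities = ph$rel_intensities)),
    background = list(A = noise$A, p = noise$p, C = noise$C),
    noise = noise$noise)
  pat <- saxs_pattern(q_grid, res$I, res$sigma, metadata)
  attr(pat, "ground_truth") <- gt
  pat
}

apply_noise <- function(I_model, noise) {
  switch(noise$noise,
    none = list(I = I_model, sigma = NULL),
    "gaussian-fractional" = {
      sigma <- noise$level * I_model
      list(I = I_model + stats::rnorm(length(I_model), 0, sigma), sigma = sigma)
    },
    poisson = list(I = as.numeric(stats::rpois(length(I_model), I_model)),
                   sigma = sqrt(I_model)))
}

#' @rdname generate_pattern
#' @export
default_q_grid <- function() seq(0.5, 4.5, length.out = 512L)

#' Specify a kinetic frame series
#'
#' Describes a light-induced transition between an initial and a final
#' phase composition. Phases present only initially decay between
#' `t_on_decay` and `t_end`; phases present only finally grow between
#' `t_on_growth` and `t_end`; phases in both compositions are spectators
#' whose amplitudes stay constant. The transition shape is piecewise
#' linear or a logistic rescaled to reach exactly 0/1 at the endpoints.
#'
#' Defaults mirror the observed lamellar-to-Pn3m photoswitching
#' phenomenology: lamellar decay begins 30 s after illumination starts,
#' Pn3m growth is delayed to 50 s, and all intensities plateau by 120 s.
#'
#' @param initial,final lists of [phase_spec()].
#' @param t_on_decay,t_on_growth,t_end onset and completion times (s).
#' @param frame_times strictly increasing frame times (s).
#' @param shape "piecewise-linear" or "logistic".
#' @param intensity_transfer if TRUE, growing amplitudes follow the
#'   complement of the decay ramp so total Bragg area is conserved.
#' @return object of class `kinetic_spec`.
#' @export
kinetic_spec <- function(initial, final,
                         t_on_decay = 30, t_on_growth = 50, t_end = 120,
                         frame_times = seq(0, 180, by = 10),
                         shape = c("piecewise-linear", "logistic"),
                         intensity_transfer = FALSE) {
  shape <- match.arg(shape)
  if (inherits(initial, "phase_spec")) initial <- list(initial)
  if (inherits(final, "phase_spec")) final <- list(final)
  stopifnot(t_on_decay >= 0, t_on_growth >= 0,
            t_end >= t_on_decay, t_end >= t_on_growth)
  if (any(diff(frame_times) <= 0)) stop("frame times must be strictly increasing")
  if (t_on_growth < t_on_decay) {
    warning("growth onset precedes decay onset (reverse transition)")
  }
  structure(list(initial = initial, final = final,
                 t_on_decay = t_on_decay, t_on_growth = t_on_growth,
                 t_end = t_end, frame_times = frame_times, shape = shape,
                 intensity_transfer = intensity_transfer),
            class = "kinetic_spec")
}

# Transition progress in [0, 1]: 0 before t_on, 1 after t_end.
ramp <- function(t, t_on, t_end, shape) {
  if (t_end <= t_on) return(as.numeric(t >= t_end))
  u <- pmin(1, pmax(0, (t - t_on) / (t_end - t_on)))
  if (shape == "piecewise-linear") return(u)
  k <- 10
  g <- function(x) 1 / (1 + exp(-k * (x - 0.5)))
  (g(u) - g(0)) / (g(1) - g(0))
}

#' Generate a kinetic series of synthetic patterns
#'
#' @param spec a [kinetic_spec()].
#' @param noise a [noise_spec()]; per-frame noise draws derive from its
#'   seed deterministically.
#' @param q_grid q grid shared by all frames.
#' @return list of [saxs_pattern()] (one per frame, each with `time_s`
#'   metadata), with attribute `ground_truth` recording onsets, completion
#'   and per-frame amplitude scale factors.
#' @export
generate_kinetic_series <- function(spec, noise = noise_spec(),
                                    q_grid = default_q_grid()) {
  stopifnot(inherits(spec, "kinetic_spec"))
  init_names <- vapply(spec$initial, `[[`, character(1), "phase")
  fin_names <- vapply(spec$final, `[[`, character(1), "phase")
  decaying <- spec$initial[!(init_names %in% fin_names)]
  growing <- spec$final[!(fin_names %in% init_names)]
  # phases present in both compositions persist; their lattice parameter
  # interpolates between the two specs (a d-spacing drift when they differ)
  spectators <- spec$initial[init_names %in% fin_names]
  spectator_a_final <- vapply(spectators, function(ph) {
    spec$final[[which(fin_names == ph$phase)[1]]]$a
  }, numeric(1))

  f_dec <- ramp(spec$frame_times, spec$t_on_decay, spec$t_end, spec$shape)
  f_gro <- if (spec$intensity_transfer) f_dec else
    ramp(spec$frame_times, spec$t_on_growth, spec$t_end, spec$shape)

  # intensity transfer: growth mirrors decay and the growing amplitudes are
  # rescaled so the Bragg area gained equals the area lost per frame
  if (spec$intensity_transfer && length(growing)) {
    qr <- range(q_grid)
    area_of <- function(ph) {
      pos <- reflection_positions(ph$model, ph$a, qr)
      sum(ph$amplitude * ph$rel_intensities[seq_len(nrow(pos))] *
            ph$sigma_q * sqrt(2 * pi))
    }
    lost <- sum(vapply(decaying, area_of, numeric(1)))
    gain <- sum(vapply(growing, area_of, numeric(1)))
    if (gain > 0) {
      growing <- lapply(growing, function(ph) {
        ph$amplitude <- ph$amplitude * lost / gain
        ph
      })
    }
  }

  scale_phase <- function(ph, s) {
    ph$amplitude <- ph$amplitude * s
    ph
  }
  frames <- vector("list", length(spec$frame_times))
  for (i in seq_along(spec$frame_times)) {
    spectators_i <- spectators
    for (j in seq_along(spectators_i)) {
      spectators_i[[j]]$a <- spectators_i[[j]]$a +
        f_dec[i] * (spectator_a_final[j] - spectators_i[[j]]$a)
    }
    phases_i <- c(lapply(decaying, scale_phase, s = 1 - f_dec[i]),
                  lapply(growing, scale_phase, s = f_gro[i]),
                  spectators_i)
    seed_i <- if (is.null(noise$seed)) NULL else noise$seed + i - 1L
    noise_i <- noise
    noise_i$seed <- seed_i
    state <- if (f_dec[i] <= 0) "trans" else if (f_dec[i] >= 1) "cis" else
      "transitioning"
    frames[[i]] <- generate_pattern(
      phases_i, noise_i, q_grid,
      metadata = list(time_s = spec$frame_times[i], state = state))
  }
  attr(frames, "ground_truth") <- list(
    t_on_decay = spec$t_on_decay, t_on_growth = spec$t_on_growth,
    t_end = spec$t_end, shape = spec$shape,
    frame_times = spec$frame_times,
    decay_fraction = f_dec, growth_fraction = f_gro,
    decaying = vapply(decaying, `[[`, character(1), "phase"),
    growing = vapply(growing, `[[`, character(1), "phase"),
    spectators = vapply(spectators, `[[`, character(1), "phase"))
  frames
}

#' Write a fixture set to disk
#'
#' Writes each frame as 3-column ASCII, a manifest CSV (`filename`,
#' `time_s`, `illumination_nm`, `state`) and a ground-truth JSON sidecar.
#'
#' @param frames list of patterns (e.g. from [generate_kinetic_series()]);
#'   a single pattern is accepted.
#' @param dir output directory (created if missing).
#' @param prefix filename prefix.
#' @param illumination_nm illumination wavelength recorded in the manifest.
#' @return the manifest path, invisibly.
#' @export
write_fixture_set <- function(frames, dir, prefix = "frame",
                              illumination_nm = 365) {
  if (inherits(frames, "saxs_pattern")) frames <- list(frames)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- vector("list", length(frames))
  for (i in seq_along(frames)) {
    fn <- sprintf("%s_%03d.dat", prefix, i)
    write_dat(frames[[i]], file.path(dir, fn))
    md <- frames[[i]]$metadata
    rows[[i]] <- data.frame(filename = fn,
                            time_s = md$time_s %||% (i - 1),
                            illumination_nm = illumination_nm,
                            state = md$state %||% "trans")
  }
  man <- do.call(rbind, rows)
  man_path <- file.path(dir, "manifest.csv")
  utils::write.csv(man, man_path, row.names = FALSE)
  gt <- attr(frames, "ground_truth") %||%
    lapply(frames, function(f) attr(f, "ground_truth"))
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(man_path)
}
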