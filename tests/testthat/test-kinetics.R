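test_that("noiseless series: spectator trace is 1, lamellar follows ramp", {
  frames <- generate_kinetic_series(switching_spec(), quiet_noise())
  tr <- track_series(frames, default_tracked(), seed = seed_lat,
                     reference = c("Im3m", "211"))
  im <- get_trace(tr, "Im3m", "211")
  expect_equal(im$norm_intensity, rep(1, 19), tolerance = 1e-12)

  lam <- get_trace(tr, "lamellar", "100")
  t <- lam$time_s
  ramp <- pmin(1, pmax(0, (t - 30) / 90))
  scale <- lam$norm_intensity[1]
  # tracked amplitudes reproduce the generator ramp until the peak falls
  # under the significance floor near full decay
  big <- ramp < 0.9
  expect_equal(lam$norm_intensity[big] / scale, (1 - ramp)[big],
               tolerance = 0.02)
  pn <- get_trace(tr, "Pn3m", "110")
  gramp <- pmin(1, pmax(0, (t - 50) / 70))
  expect_equal(pn$norm_intensity[gramp > 0.1] / pn$norm_intensity[19],
               gramp[gramp > 0.1], tolerance = 0.02)
})

test_that("a series of identical frames gives constant traces", {
  pat <- function(t) {
    p <- generate_pattern(threephase_specs(), quiet_noise(),
                          metadata = list(time_s = t))
    p
  }
  frames <- lapply(seq(0, 50, by = 10), pat)
  tr <- track_series(frames, default_tracked(), seed = seed_lat,
                     reference = c("Im3m", "211"))
  for (k in seq_len(nrow(default_tracked()))) {
    g <- get_trace(tr, default_tracked()$phase[k],
                   default_tracked()$reflection[k])
    # frames 2..n share the drift-updated window exactly; frame 1 differs
    # only through the window seeded from the nominal lattice
    expect_equal(g$norm_intensity[-1], rep(g$norm_intensity[2], 5),
                 tolerance = 1e-6)
    expect_equal(g$norm_intensity[1], g$norm_intensity[2], tolerance = 0.01)
  }
  s <- kinetics_summary(tr)
  expect_true(all(is.na(s$t_onset)))
})

test_that("reverse-direction series mirrors the forward run", {
  fwd <- switching_spec()
  rev <- kinetic_spec(
    initial = list(phase_spec("Pn3m", 11.6, 1500),
                   phase_spec("Im3m", 12.7, 1000)),
    final = list(phase_spec("lamellar", 6.9, 3000),
                 phase_spec("Im3m", 12.7, 1000)),
    t_on_decay = 30, t_on_growth = 30, t_end = 120)
  frames <- generate_kinetic_series(rev, quiet_noise())
  tr <- track_series(frames, default_tracked(), seed = seed_lat,
                     reference = c("Im3m", "211"))
  lam <- get_trace(tr, "lamellar", "100")$norm_intensity
  pn <- get_trace(tr, "Pn3m", "110")$norm_intensity
  expect_gt(lam[19], lam[1])   # lamellar rises
  expect_gt(pn[1], pn[19])     # Pn3m falls
})

test_that("normalization is invariant under per-frame scale factors", {
  frames <- generate_kinetic_series(
    switching_spec(),
    noise_spec(noise = "gaussian-fractional", level = 0.02, seed = 31))
  tr1 <- track_series(frames, default_tracked(), seed = seed_lat,
                      reference = c("Im3m", "211"))
  set.seed(99)
  scaled <- lapply(frames, function(p) {
    f <- runif(1, 0.5, 2)
    saxs_pattern(p$q, p$I * f, p$sigma * f, p$metadata)
  })
  tr2 <- track_series(scaled, default_tracked(), seed = seed_lat,
                      reference = c("Im3m", "211"))
  expect_equal(tr2$traces$norm_intensity, tr1$traces$norm_intensity,
               tolerance = 1e-5)
})

test_that("missing reference peak names the offending frame", {
  frames <- generate_kinetic_series(switching_spec(), quiet_noise())
  # remove the Im3m 211 Gaussian from the frame at t = 50 s
  q211 <- 2 * pi * sqrt(6) / 12.7
  p <- frames[[6]]
  p$I <- p$I - 250 * exp(-(p$q - q211)^2 / (2 * 0.02^2))
  frames[[6]] <- p
  expect_error(
    track_series(frames, default_tracked(), seed = seed_lat,
                 reference = c("Im3m", "211")),
    "t = 50")
})

test_that("onset detector: exact step, debounce, and error cases", {
  t <- seq(0, 100, by = 10)
  v <- c(rep(1, 5), rep(2, 6))          # first deviating frame at t = 50
  expect_equal(detect_onset(v, t), 50)

  # single-frame glitch must not trigger (debounce)
  vg <- rep(1, 11); vg[6] <- 5
  expect_true(is.na(detect_onset(vg, t)))

  expect_true(is.na(detect_onset(rep(1, 11), t)))
  expect_error(detect_onset(1:3, c(0, 10, 20), baseline_n = 3), "baseline_n")
})

test_that("constant noisy traces rarely yield a false onset", {
  # for a flat trace every frame is pre-change, so the baseline window
  # covers half the trace (the detector's "k covering pre-change frames")
  none <- 0L
  for (s in 1:100) {
    set.seed(4000 + s)
    v <- rnorm(15, 1, 0.02)
    if (is.na(detect_onset(v, seq_along(v) * 10, baseline_n = 8L))) {
      none <- none + 1L
    }
  }
  expect_gte(none, 99L)
})

test_that("logistic growth onset is detected within one frame spacing", {
  hits <- 0L
  for (s in 1:10) {
    frames <- generate_kinetic_series(
      switching_spec(shape = "logistic"),
      noise_spec(noise = "gaussian-fractional", level = 0.02,
                 seed = 6000 + s))
    tr <- track_series(frames, data.frame(phase = "Pn3m",
                                          reflection = "110"),
                       seed = seed_lat, reference = c("Im3m", "211"))
    g <- get_trace(tr, "Pn3m", "110")
    on <- detect_onset(g$norm_intensity, g$time_s, sigma = g$sigma)
    if (!is.na(on) && abs(on - 50) <= 10) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("completion detector: plateau, step, and unfinished traces", {
  t <- seq(0, 180, by = 10)
  ramp <- pmin(1, pmax(0, (t - 30) / 90))       # ends at 120 s
  expect_equal(detect_completion(1 - ramp, t, onset = 40), 120)

  # constant after a step: completion at the first post-step frame
  v <- c(rep(0, 4), rep(1, 15))
  expect_equal(detect_completion(v, t, onset = 40), 40)

  # still rising at the last frame: not reached
  rising <- seq(0, 1, length.out = 19)^2
  cm <- detect_completion(rising, t, onset = 30)
  expect_true(is.na(cm))
  expect_equal(attr(cm, "status"), "not reached")
})

test_that("time-reversed series swaps onset and completion consistently", {
  t <- seq(0, 180, by = 10)
  ramp <- pmin(1, pmax(0, (t - 30) / 90))
  on_f <- detect_onset(1 - ramp, t)
  cm_f <- detect_completion(1 - ramp, t, on_f)
  rev_v <- rev(1 - ramp)
  on_r <- detect_onset(rev_v, t)
  cm_r <- detect_completion(rev_v, t, on_r)
  # forward transition spans [30,120]; reversed it spans [60,150]
  expect_equal(on_f, 40); expect_equal(cm_f, 120)
  expect_equal(on_r, 180 - cm_f + 10); expect_equal(cm_r, 180 - on_f + 10)
})

test_that("onset and completion are recovered across a parameter grid", {
  hits <- 0L; n <- 0L
  for (t_on in c(10, 30, 60)) {
    for (t_end in c(80, 120, 150)) {
      n <- n + 1L
      frames <- generate_kinetic_series(
        switching_spec(t_on_decay = t_on, t_on_growth = t_on,
                       t_end = t_end),
        noise_spec(noise = "gaussian-fractional", level = 0.02,
                   seed = 7000 + n))
      tr <- track_series(frames, data.frame(phase = "lamellar",
                                            reflection = "100"),
                         seed = seed_lat, reference = c("Im3m", "211"))
      g <- get_trace(tr, "lamellar", "100")
      k <- max(2L, sum(g$time_s < t_on))
      on <- detect_onset(g$norm_intensity, g$time_s, baseline_n = k,
                         sigma = g$sigma)
      cm <- detect_completion(g$norm_intensity, g$time_s, on,
                              sigma = g$sigma)
      if (!is.na(on) && abs(on - t_on) <= 10 &&
          !is.na(cm) && abs(cm - t_end) <= 10) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits, ceiling(0.9 * n))
})

test_that("lamellar d(t) drift 6.51 -> 6.47 nm is recovered", {
  spec <- kinetic_spec(
    initial = list(phase_spec("lamellar", 6.51, 3000)),
    final = list(phase_spec("lamellar", 6.47, 3000)),
    t_on_decay = 5, t_on_growth = 5, t_end = 50,
    frame_times = seq(0, 90, by = 10))
  frames <- generate_kinetic_series(
    spec, noise_spec(noise = "gaussian-fractional", level = 0.02, seed = 3))
  dt <- track_d_spacing(frames, 6.51)
  expect_true(all(dt$n_orders >= 1))
  expect_equal(dt$d_nm[1], 6.51, tolerance = 0.01)
  expect_equal(dt$d_nm[nrow(dt)], 6.47, tolerance = 0.01)
  expect_equal(dt$d_nm[nrow(dt)] - dt$d_nm[1], -0.04, tolerance = 0.02)

  # constant-d series: no onset in d(t)
  const <- generate_kinetic_series(
    kinetic_spec(initial = list(phase_spec("lamellar", 6.51, 3000)),
                 final = list(phase_spec("lamellar", 6.51, 3000)),
                 frame_times = seq(0, 90, by = 10)),
    quiet_noise())
  dtc <- track_d_spacing(const, 6.51)
  expect_true(is.na(detect_onset(dtc$d_nm, dtc$time_s)))
})

test_that("d(t) scatter is consistent with the reported sigma", {
  ds <- c(); sig <- c()
  for (s in 1:20) {
    frames <- generate_kinetic_series(
      kinetic_spec(initial = list(phase_spec("lamellar", 6.51, 3000)),
                   final = list(phase_spec("lamellar", 6.51, 3000)),
                   frame_times = c(0, 10, 20)),
      noise_spec(noise = "gaussian-fractional", level = 0.02,
                 seed = 8000 + s))
    dt <- track_d_spacing(frames, 6.51)
    ds <- c(ds, dt$d_nm)
    sig <- c(sig, dt$sigma_d)
  }
  emp <- sd(ds)
  expect_gt(mean(sig, na.rm = TRUE), emp / 2)
  expect_lt(mean(sig, na.rm = TRUE), emp * 2)
})
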