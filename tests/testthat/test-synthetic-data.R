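test_that("noiseless lamellar pattern peaks exactly at q = 1, 2, 3", {
  q <- seq(0.5, 3.5, length.out = 1501)  # grid hits integers exactly
  pat <- generate_pattern(phase_spec("lamellar", 2 * pi, 100), quiet_noise(),
                          q_grid = q)
  y <- pat$I
  locmax <- which(y[2:1500] > y[1:1499] & y[2:1500] > y[3:1501]) + 1L
  expect_equal(sort(q[locmax]), c(1, 2, 3), tolerance = 1e-9)
})

test_that("zero amplitudes reproduce the background formula pointwise", {
  ns <- noise_spec(A = 37, p = 2.5, C = 4, noise = "none")
  pat <- generate_pattern(phase_spec("lamellar", 6.9, amplitude = 0), ns)
  expect_equal(pat$I, 37 * pat$q^(-2.5) + 4, tolerance = 1e-12)
  expect_null(pat$sigma)
})

test_that("poisson noise has counting-statistics variance at a peak apex", {
  # 200 replicate draws of the apex intensity; relative sd should match
  # 1/sqrt(I) within 3x the sampling error of an sd estimate
  q <- seq(1.45, 1.55, length.out = 11)
  ph <- phase_spec("lamellar", 2 * pi / 1.5, amplitude = 1e4)
  apex <- vapply(1:200, function(i) {
    p <- generate_pattern(ph, noise_spec(A = 0, C = 0, noise = "poisson",
                                         seed = 5000 + i), q_grid = q)
    p$I[which.min(abs(p$q - 1.5))]
  }, numeric(1))
  rel <- sd(apex) / mean(apex)
  expected <- 1 / sqrt(1e4)
  sampling_err <- expected / sqrt(2 * (200 - 1))
  expect_lt(abs(rel - expected), 3 * sampling_err)
  # uncertainty column is sqrt(model)
  p <- generate_pattern(ph, noise_spec(A = 0, C = 0, noise = "poisson",
                                       seed = 1), q_grid = q)
  expect_equal(max(p$sigma), 100, tolerance = 1e-9)
})

test_that("identical spec and seed give bit-identical output", {
  ns <- noise_spec(noise = "gaussian-fractional", seed = 77)
  p1 <- generate_pattern(threephase_specs(), ns)
  p2 <- generate_pattern(threephase_specs(), ns)
  expect_identical(p1$I, p2$I)
  s1 <- generate_kinetic_series(switching_spec(), ns)
  s2 <- generate_kinetic_series(switching_spec(), ns)
  expect_identical(lapply(s1, `[[`, "I"), lapply(s2, `[[`, "I"))
})

test_that("duplicate q grid points are rejected", {
  expect_error(generate_pattern(phase_spec("lamellar", 6.9), quiet_noise(),
                                q_grid = c(1, 1, 2)), "strictly increasing")
})

test_that("kinetic series boundary frames are pure initial/final states", {
  spec <- switching_spec(frame_times = c(0, 200))
  frames <- generate_kinetic_series(spec, quiet_noise())
  gt <- attr(frames, "ground_truth")
  expect_equal(gt$growth_fraction, c(0, 1))
  expect_equal(gt$decay_fraction, c(0, 1))
  # first frame is exactly the initial composition, last exactly the final
  ref_init <- generate_pattern(list(phase_spec("lamellar", 6.9, 3000),
                                    phase_spec("Im3m", 12.7, 1000)),
                               quiet_noise())
  ref_final <- generate_pattern(list(phase_spec("Pn3m", 11.6, 1500),
                                     phase_spec("Im3m", 12.7, 1000)),
                                quiet_noise())
  expect_equal(frames[[1]]$I, ref_init$I, tolerance = 1e-12)
  expect_equal(frames[[2]]$I, ref_final$I, tolerance = 1e-12)
})

test_that("frame-wise decaying amplitudes equal the hand-computed ramp", {
  spec <- switching_spec(t_on_decay = 30, t_on_growth = 50, t_end = 120,
                         frame_times = seq(0, 150, by = 10))
  frames <- generate_kinetic_series(spec, quiet_noise())
  t <- seq(0, 150, by = 10)
  ramp_oracle <- pmin(1, pmax(0, (t - 30) / (120 - 30)))
  growth_oracle <- pmin(1, pmax(0, (t - 50) / (120 - 50)))
  gt <- attr(frames, "ground_truth")
  expect_equal(gt$decay_fraction, ramp_oracle, tolerance = 1e-12)
  expect_equal(gt$growth_fraction, growth_oracle, tolerance = 1e-12)
  # lamellar 200 apex (no neighbouring reflection within tail reach)
  q200 <- 2 * 2 * pi / 6.9
  apex <- vapply(frames, function(p) max(p$I[abs(p$q - q200) < 0.05]),
                 numeric(1))
  expect_equal(apex / 1500, 1 - ramp_oracle, tolerance = 0.01)
  # Pn3m 110 sampled at its apex grid point (its window overlaps the
  # Im3m 110 flank, so subtract the constant first-frame level)
  q110 <- 2 * pi * sqrt(2) / 11.6
  val <- vapply(frames, function(p) p$I[which.min(abs(p$q - q110))],
                numeric(1))
  expect_equal((val - val[1]) / 1500, growth_oracle, tolerance = 0.02)
})

test_that("Im3m spectator apex intensity is identical in every frame", {
  frames <- generate_kinetic_series(switching_spec(), quiet_noise())
  q211 <- 2 * pi * sqrt(6) / 12.7
  apex <- vapply(frames, function(p) max(p$I[abs(p$q - q211) < 0.04]),
                 numeric(1))
  expect_equal(apex, rep(apex[1], length(apex)), tolerance = 1e-6)
})

test_that("intensity-transfer mode conserves total Bragg area", {
  spec <- kinetic_spec(
    initial = list(phase_spec("lamellar", 6.9, 3000)),
    final = list(phase_spec("Pn3m", 11.6, 1500)),
    intensity_transfer = TRUE)
  frames <- generate_kinetic_series(spec, quiet_noise())
  # numeric Bragg area per frame: integrate intensity above background
  ns <- noise_spec()
  tot_area <- vapply(frames, function(p) {
    bragg <- p$I - (ns$A * p$q^(-ns$p) + ns$C)
    sum(diff(p$q) * (bragg[-1] + bragg[-length(bragg)]) / 2)
  }, numeric(1))
  expect_equal(tot_area, rep(tot_area[1], length(tot_area)),
               tolerance = 1e-5)
})

test_that("reverse transition (growth before decay) warns but proceeds", {
  expect_warning(
    kinetic_spec(initial = list(phase_spec("lamellar", 6.9)),
                 final = list(phase_spec("Pn3m", 11.6)),
                 t_on_decay = 50, t_on_growth = 30),
    "reverse")
})

test_that("fixture sets round-trip through manifest and sidecar", {
  dir <- withr::local_tempdir()
  frames <- generate_kinetic_series(
    switching_spec(frame_times = seq(0, 40, by = 20)),
    noise_spec(noise = "poisson", seed = 9))
  write_fixture_set(frames, dir, prefix = "kin")
  man <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(man), 3L)
  expect_equal(man$time_s, c(0, 20, 40))
  back <- read_series(file.path(dir, "manifest.csv"))
  expect_equal(back[[2]]$I, frames[[2]]$I, tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  expect_equal(gt$t_on_decay, 30)
  expect_equal(gt$t_end, 120)
})
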