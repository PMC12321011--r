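test_that("background-only pattern yields no candidates", {
  pat <- generate_pattern(phase_spec("lamellar", 6.9, amplitude = 0),
                          noise_spec(noise = "gaussian-fractional",
                                     level = 0.02, seed = 8))
  expect_length(detect_peaks(pat), 0L)
})

test_that("well-separated peaks are each found within one half-width", {
  truth <- c(1.0, 1.8, 3.1)
  specs <- lapply(truth, function(q0)
    phase_spec("lamellar", 2 * pi / q0, amplitude = 100, n_reflections = 1L))
  # SNR ~ 20: fractional noise on a flat background of comparable scale
  pat <- generate_pattern(specs,
                          noise_spec(A = 0, C = 50, noise = "gaussian-fractional",
                                     level = 0.1, seed = 21))
  cand <- detect_peaks(pat)
  expect_length(cand, 3L)
  for (q0 in truth) expect_lt(min(abs(cand - q0)), 0.01)  # half-width ~ sigma/2
})

test_that("an unresolved doublet merges into a single candidate", {
  # two Gaussians 1.5 sigma apart, default min_separation = 3 sigma
  q <- default_q_grid()
  y <- 100 * exp(-(q - 1.5)^2 / (2 * 0.02^2)) +
    80 * exp(-(q - 1.53)^2 / (2 * 0.02^2)) + 5
  pat <- saxs_pattern(q, y)
  cand <- detect_peaks(pat)
  expect_length(cand, 1L)
  expect_lt(abs(cand - 1.51), 0.05)
})

test_that("noiseless Gaussian is recovered to 1e-6 relative", {
  q <- default_q_grid()
  y <- 2 + 0.5 * q + 100 * exp(-(q - 1.5)^2 / (2 * 0.02^2))
  pat <- saxs_pattern(q, y)
  pk <- fit_peaks(pat, 1.49, snr_min = 0)
  expect_equal(pk$q0, 1.5, tolerance = 1e-6)
  expect_equal(pk$amplitude, 100, tolerance = 1e-6)
  expect_equal(pk$width, 0.02, tolerance = 1e-6)
  # internal consistency of the reported area
  expect_equal(pk$area, pk$amplitude * pk$width * sqrt(2 * pi),
               tolerance = 1e-12)
})

test_that("position estimates are invariant under added linear background", {
  q <- default_q_grid()
  y <- 50 + 200 * exp(-(q - 2.2)^2 / (2 * 0.02^2))
  p0 <- fit_peaks(saxs_pattern(q, y), 2.2, snr_min = 0)
  for (slope in c(-30, 15, 120)) {
    p1 <- fit_peaks(saxs_pattern(q, y + slope * q + 7), 2.2, snr_min = 0)
    expect_equal(p1$q0, p0$q0, tolerance = 1e-6)
    expect_equal(p1$amplitude, p0$amplitude, tolerance = 1e-4)
  }
})

test_that("overlapping candidates are fitted jointly and both recovered", {
  q <- default_q_grid()
  y <- 10 + 100 * exp(-(q - 1.50)^2 / (2 * 0.02^2)) +
    60 * exp(-(q - 1.62)^2 / (2 * 0.02^2))
  pk <- fit_peaks(saxs_pattern(q, y), c(1.50, 1.62), snr_min = 0)
  expect_equal(nrow(pk), 2L)
  expect_equal(pk$q0, c(1.50, 1.62), tolerance = 1e-5)
  expect_equal(pk$amplitude, c(100, 60), tolerance = 1e-3)
})

test_that("fitted positions are unbiased and sigma_q0 is calibrated", {
  q0_hat <- c(); sig_hat <- c()
  for (s in 1:20) {
    pat <- generate_pattern(
      phase_spec("lamellar", 2 * pi / 1.5, amplitude = 500,
                 n_reflections = 1L),
      noise_spec(A = 0, C = 20, noise = "gaussian-fractional",
                 level = 0.02, seed = 300 + s))
    pk <- fit_peaks(pat, 1.5, snr_min = 0)
    q0_hat <- c(q0_hat, pk$q0[1])
    sig_hat <- c(sig_hat, pk$sigma_q0[1])
  }
  se <- sd(q0_hat) / sqrt(20)
  expect_lt(abs(mean(q0_hat) - 1.5), 2 * se)
  # reported position uncertainty consistent with empirical scatter (x2)
  expect_gt(mean(sig_hat), sd(q0_hat) / 2)
  expect_lt(mean(sig_hat), sd(q0_hat) * 2)
})

test_that("peaks below the noise floor are excluded as non-significant", {
  pat <- generate_pattern(
    phase_spec("lamellar", 2 * pi / 1.5, amplitude = 1, n_reflections = 1L),
    noise_spec(A = 0, C = 100, noise = "gaussian-fractional",
               level = 0.05, seed = 77))
  # amplitude 1 on noise sd ~ 5: excluded at the default threshold
  pk <- tryCatch(fit_peaks(pat, 1.5), error = function(e) NULL)
  expect_true(is.null(pk) || nrow(pk) == 0L || all(!pk$significant))
})

test_that("end-to-end: fitted positions reproduce generator positions", {
  # noiseless flat-background mixture, fitter seeded with the generator's
  # reflection positions: the model class is exact, so every position must
  # come back to 1e-6 relative
  pat <- generate_pattern(threephase_specs(), quiet_noise())
  truth <- sort(unlist(lapply(
    list(c("lamellar", 6.9), c("Pn3m", 11.6), c("Im3m", 12.7)),
    function(x) reflection_positions(mesophase_model(x[1]),
                                     as.numeric(x[2]), c(0.5, 4.5))$q)))
  pk <- fit_peaks(pat, truth, snr_min = 0)
  expect_equal(nrow(pk), length(truth))
  expect_lt(max(abs(sort(pk$q0) - truth) / truth), 1e-6)

  # with automatic detection on a realistic power-law background: no
  # spurious peaks (every fitted candidate is near a generator position)
  # and all strong isolated reflections are found within half a width
  pat2 <- generate_pattern(threephase_specs(), noise_spec(noise = "none"))
  pk2 <- fit_peaks(pat2, detect_peaks(pat2), snr_min = 0)
  for (q0 in pk2$q0) {
    expect_lt(min(abs(truth - q0)), 0.03)
  }
  tt <- do.call(rbind, lapply(
    list(list("lamellar", 6.9, 3000), list("Pn3m", 11.6, 1500),
         list("Im3m", 12.7, 1000)),
    function(x) {
      pos <- reflection_positions(mesophase_model(x[[1]]), x[[2]],
                                  c(0.5, 4.5))
      k <- match(pos$label, mesophase_model(x[[1]])$reflections$label)
      data.frame(q = pos$q, amp = x[[3]] * 0.5^(k - 1))
    }))
  strong <- tt$q[vapply(seq_len(nrow(tt)), function(i)
    sum(abs(tt$q - tt$q[i]) < 0.06) == 1L && tt$amp[i] >= 100, logical(1))]
  for (t in strong) {
    expect_lt(min(abs(pk2$q0 - t)), 0.01)
  }
})
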