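#' Track reflection intensities through a time-resolved series
#'
#' Decomposes every frame over a basis of Gaussians at all reflection
#' positions implied by the seed lattices, plus a smooth background — the
#' structural parameters (positions, widths) determined from the static
#' assignment are held fixed across the run and only amplitudes vary, so
#' each frame is one weighted linear least-squares solve. Fitted apex
#' amplitudes are divided by the fitted amplitude of the reference
#' reflection when one is given (so arbitrary per-frame scale factors
#' cancel; the reference trace is identically 1), else by the frame's
#' total integrated intensity. Frames in which a tracked peak has
#' vanished (amplitude indistinguishable from zero) keep the time point
#' with amplitude 0 and an uncertainty equal to the local noise level, so
#' traces stay defined over the full series.
#'
#' @param frames list of [saxs_pattern()] in any order; sorted by their
#'   `time_s` metadata internally.
#' @param tracked data frame with columns `phase` and `reflection` (hkl
#'   label, e.g. "100"), or a list of `c(phase, reflection)` pairs.
#' @param seed named list/vector of lattice parameters (nm) per tracked
#'   phase, or a `phase_assignment` from [index_phases()]; if NULL, the
#'   first frame is indexed automatically.
#' @param reference optional `c(phase, reflection)` used for
#'   normalization (e.g. `c("Im3m", "211")`).
#' @param sigma_init Gaussian peak width used for the decomposition basis
#'   (nm^-1; default 0.02).
#' @return object of class `kinetics_trace`: list with `time_s`, `traces`
#'   (data frame: `time_s`, `phase`, `reflection`, `intensity`,
#'   `norm_intensity`, `sigma`, `q0`) and `reference`.
#' @export
track_series <- function(frames, tracked, seed = NULL, reference = NULL,
                         sigma_init = 0.02) {
  stopifnot(length(frames) >= 1L)
  times <- vapply(frames, function(f) f$metadata$time_s %||% NA_real_,
                  numeric(1))
  if (any(is.na(times))) stop("every frame needs `time_s` metadata")
  ord <- order(times)
  frames <- frames[ord]; times <- times[ord]
  tracked <- as_tracked(tracked)
  if (!is.null(reference)) {
    ref <- data.frame(phase = reference[[1]], reflection = reference[[2]])
    if (!any(tracked$phase == ref$phase &
             tracked$reflection == ref$reflection)) {
      tracked <- rbind(tracked, ref)
    }
  }

  lattices <- seed_lattices(seed, frames[[1]], tracked)
  expected <- mapply(function(ph, rf) {
    model <- mesophase_model(ph)
    m <- model$reflections$m[model$reflections$label == rf]
    if (length(m) != 1L) stop("unknown reflection ", rf, " for phase ", ph)
    2 * pi * m / lattices[[ph]]
  }, tracked$phase, tracked$reflection)

  # every reflection position implied by the seed lattices: each frame is
  # decomposed in one joint fit of all of them, mirroring how fixed
  # parameter sets are applied to every time-resolved scan
  all_pos <- sort(unique(unlist(lapply(names(lattices), function(ph) {
    reflection_positions(mesophase_model(ph), lattices[[ph]],
                         range(frames[[1]]$q))$q
  }))))
  tracked_idx <- vapply(expected, function(e)
    which.min(abs(all_pos - e)), integer(1))

  rows <- list()
  for (i in seq_along(frames)) {
    pat <- frames[[i]]
    noise <- stats::mad(pat$I - moving_average(pat$I, 5L))
    tab <- decompose_frame(pat, all_pos, sigma_init)
    for (j in seq_len(nrow(tracked))) {
      idx <- tracked_idx[j]
      obs <- component_obs(tab, idx, noise)
      if (!is.null(obs)) {
        amp <- obs$amplitude; sig <- obs$sigma_amplitude; q0 <- obs$q0
      } else {
        amp <- 0; sig <- noise; q0 <- NA_real_
      }
      rows[[length(rows) + 1L]] <- data.frame(
        time_s = times[i], phase = tracked$phase[j],
        reflection = tracked$reflection[j], intensity = amp,
        sigma = sig, q0 = q0)
    }
  }
  tr <- do.call(rbind, rows)

  if (!is.null(reference)) {
    is_ref <- tr$phase == ref$phase & tr$reflection == ref$reflection
    ref_rows <- match(tr$time_s, tr$time_s[is_ref])
    ref_amp <- tr$intensity[is_ref][ref_rows]
    ref_sig <- tr$sigma[is_ref][ref_rows]
    bad <- unique(tr$time_s[is_ref][tr$intensity[is_ref] <= 0])
    if (length(bad)) {
      stop("reference peak ", ref$phase, " ", ref$reflection,
           " absent in frame(s) at t = ", paste(bad, collapse = ", "), " s")
    }
    tr$norm_intensity <- tr$intensity / ref_amp
    # full ratio propagation: the reference's own uncertainty contributes
    tr$sigma <- sqrt((tr$sigma / ref_amp)^2 +
                       (tr$intensity * ref_sig / ref_amp^2)^2)
  } else {
    tot <- vapply(seq_along(frames), function(i) {
      p <- frames[[i]]
      sum(diff(p$q) * (p$I[-1] + p$I[-length(p$I)]) / 2)
    }, numeric(1))
    tot_per_row <- tot[match(tr$time_s, times)]
    tr$norm_intensity <- tr$intensity / tot_per_row
    tr$sigma <- tr$sigma / tot_per_row
  }
  structure(list(time_s = times, traces = tr,
                 reference = if (is.null(reference)) NULL else
                   paste(ref$phase, ref$reflection)),
            class = "kinetics_trace")
}

as_tracked <- function(tracked) {
  if (is.data.frame(tracked)) {
    stopifnot(all(c("phase", "reflection") %in% names(tracked)))
    return(tracked[, c("phase", "reflection")])
  }
  do.call(rbind, lapply(tracked, function(x)
    data.frame(phase = x[[1]], reflection = as.character(x[[2]]))))
}

seed_lattices <- function(seed, first_frame, tracked) {
  phases <- unique(tracked$phase)
  if (inherits(seed, "phase_assignment")) {
    lat <- lapply(seed$phases, `[[`, "a")
  } else if (!is.null(seed)) {
    lat <- as.list(seed)
  } else {
    cand <- detect_peaks(first_frame)
    if (length(cand) == 0L) stop("no peaks found in the first frame to seed tracking")
    pk <- fit_peaks(first_frame, cand)
    ranking <- index_phases(pk)
    if (length(ranking) == 0L) stop("could not index the first frame")
    lat <- lapply(ranking[[1]]$phases, `[[`, "a")
  }
  missing <- setdiff(phases, names(lat))
  if (length(missing)) {
    stop("no seed lattice for tracked phase(s): ",
         paste(missing, collapse = ", "))
  }
  lat
}

# Whole-pattern decomposition: one joint fit of Gaussians at every known
# reflection position plus a smooth global background
# c0 + c1 q + c2 q^-2, mirroring the fixed-parameter-set fits used on
# time-resolved scans. Positions are boxed to +/- mu_halfwidth of their
# seeds and widths to [sigma_init/4, 4 sigma_init]; a box no wider than
# half the distance to the nearest neighbour keeps components of
# overlapping reflections from swapping, and a vanished peak cannot
# migrate onto a neighbour. Returns one row per seed position, in input
# order.
fit_frame_peaks <- function(pattern, positions, sigma_init = 0.02,
                            mu_halfwidth = 3 * sigma_init) {
  k <- length(positions)
  q <- pattern$q
  y <- pattern$I
  bg_basis <- cbind(1, q, q^-2)

  # background start from points far from every seeded reflection
  far <- rep(TRUE, length(q))
  for (p0 in positions) far <- far & abs(q - p0) > 3 * sigma_init
  cfit <- if (sum(far) >= 6L) {
    stats::lm.fit(bg_basis[far, , drop = FALSE], y[far])$coefficients
  } else {
    c(min(y), 0, 0)
  }
  cfit[!is.finite(cfit)] <- 0
  bg0 <- as.numeric(bg_basis %*% cfit)
  amp0 <- vapply(positions, function(p0) {
    i <- which.min(abs(q - p0))
    max(y[i] - bg0[i], .Machine$double.eps)
  }, numeric(1))

  mu_halfwidth <- rep_len(mu_halfwidth, k)
  if (k > 1L) {
    # never let a position box cross half-way to the nearest neighbour
    gap <- vapply(seq_len(k), function(j)
      min(abs(positions[j] - positions[-j])), numeric(1))
    mu_halfwidth <- pmin(mu_halfwidth, gap / 2)
  }
  start <- c(rbind(amp0, positions, rep(sigma_init, k)))
  names(start) <- paste0(rep(c("A", "mu", "s"), k), rep(seq_len(k), each = 3))
  start <- c(start, c0 = unname(cfit[1]), c1 = unname(cfit[2]),
             c2 = unname(cfit[3]))
  lower <- c(rbind(0, positions - mu_halfwidth, rep(sigma_init / 4, k)),
             rep(-Inf, 3))
  upper <- c(rbind(Inf, positions + mu_halfwidth, rep(4 * sigma_init, k)),
             rep(Inf, 3))

  model <- function(p) {
    out <- p[["c0"]] + p[["c1"]] * q + p[["c2"]] * q^-2
    for (j in seq_len(k)) {
      out <- out + p[[paste0("A", j)]] *
        exp(-(q - p[[paste0("mu", j)]])^2 / (2 * p[[paste0("s", j)]]^2))
    }
    out
  }
  w <- if (!is.null(pattern$sigma) && all(pattern$sigma > 0)) {
    1 / pattern$sigma
  } else {
    rep(1, length(q))
  }
  jac <- function(p) {
    p <- as.list(p)
    J <- matrix(0, length(q), length(start))
    for (j in seq_len(k)) {
      A <- p[[paste0("A", j)]]
      mu <- p[[paste0("mu", j)]]
      s <- p[[paste0("s", j)]]
      g <- exp(-(q - mu)^2 / (2 * s^2))
      J[, 3 * j - 2] <- g
      J[, 3 * j - 1] <- A * g * (q - mu) / s^2
      J[, 3 * j] <- A * g * (q - mu)^2 / s^3
    }
    J[, 3 * k + 1] <- 1
    J[, 3 * k + 2] <- q
    J[, 3 * k + 3] <- q^-2
    -w * J
  }
  # numeric differencing: nls.lm's convergence tests misbehave when an
  # analytic jac is combined with box bounds; `jac` is kept for the
  # covariance fallback below
  fit <- tryCatch(
    suppressWarnings(
      minpack.lm::nls.lm(par = start, fn = function(p) w * (y - model(as.list(p))),
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500))),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(NULL)
  p <- fit$par
  dof <- length(q) - length(start)
  redchi <- sum(fit$fvec^2) / max(dof, 1)
  covm <- tryCatch(summary(fit)$cov.unscaled * redchi, error = function(e) {
    # singular when a vanished component pins its amplitude at zero;
    # fall back to the pseudo-inverse of J'J for the live parameters
    J <- jac(unlist(p))
    tryCatch(MASS::ginv(crossprod(J)) * redchi, error = function(e2) NULL)
  })
  se <- function(nm) {
    if (is.null(covm)) return(NA_real_)
    i <- match(nm, names(start))
    v <- covm[i, i]
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }
  do.call(rbind, lapply(seq_len(k), function(j) {
    A <- p[[paste0("A", j)]]
    s <- abs(p[[paste0("s", j)]])
    data.frame(q0 = p[[paste0("mu", j)]], sigma_q0 = se(paste0("mu", j)),
               amplitude = A, sigma_amplitude = se(paste0("A", j)),
               width = s, sigma_width = se(paste0("s", j)),
               area = A * s * sqrt(2 * pi), redchi = redchi)
  }))
}

# Linear decomposition of one frame: weighted least squares on a basis of
# Gaussians with FIXED positions and widths plus a smooth background
# (1, q, q^-2). Time-resolved scans are fitted with the structural
# parameters held at the values determined from the static assignment, so
# only the amplitudes (and the background) vary per frame; this makes the
# per-frame problem linear, hence unique and well-conditioned even for
# overlapping reflections. Returns one row per position with amplitude,
# its standard error, and the fitted apex position (the fixed input).
decompose_frame <- function(pattern, positions, widths) {
  k <- length(positions)
  q <- pattern$q
  y <- pattern$I
  widths <- rep_len(widths, k)
  X <- matrix(0, length(q), k + 3L)
  for (j in seq_len(k)) {
    X[, j] <- exp(-(q - positions[j])^2 / (2 * widths[j]^2))
  }
  X[, k + 1L] <- 1
  X[, k + 2L] <- q
  X[, k + 3L] <- q^-2
  w <- if (!is.null(pattern$sigma) && all(pattern$sigma > 0)) {
    1 / pattern$sigma^2
  } else {
    rep(1, length(q))
  }
  fit <- stats::lm.wfit(X, y, w)
  dof <- length(q) - fit$rank
  redchi <- sum(w * fit$residuals^2) / max(dof, 1)
  XtWX <- crossprod(X * sqrt(w))
  covm <- tryCatch(solve(XtWX) * redchi,
                   error = function(e) MASS::ginv(XtWX) * redchi)
  amps <- fit$coefficients[seq_len(k)]
  ses <- sqrt(pmax(diag(covm)[seq_len(k)], 0))
  data.frame(q0 = positions, sigma_q0 = NA_real_,
             amplitude = unname(amps), sigma_amplitude = unname(ses),
             width = widths, area = unname(amps) * widths * sqrt(2 * pi),
             redchi = redchi)
}

# Read one tracked component out of a frame decomposition, applying the
# significance gates; NULL means "peak absent in this frame".
component_obs <- function(tab, idx, noise) {
  if (is.null(tab)) return(NULL)
  obs <- tab[idx, ]
  if (obs$amplitude <= 3 * noise) return(NULL)
  if (is.finite(obs$sigma_amplitude) &&
      obs$amplitude <= 2 * obs$sigma_amplitude) {
    return(NULL)   # amplitude indistinguishable from zero
  }
  obs
}

#' Extract one reflection's trace
#'
#' @param trace a `kinetics_trace`.
#' @param phase,reflection identify the tracked reflection.
#' @return data frame with `time_s`, `norm_intensity`, `sigma`.
#' @export
get_trace <- function(trace, phase, reflection) {
  tr <- trace$traces
  out <- tr[tr$phase == phase & tr$reflection == as.character(reflection),
            c("time_s", "norm_intensity", "sigma", "q0", "intensity")]
  rownames(out) <- NULL
  out
}

#' Detect the onset of a change in a kinetic trace
#'
#' The baseline mean and scatter are taken from the first `baseline_n`
#' frames. The onset is the first later frame deviating from the baseline
#' mean by more than `threshold` baseline standard deviations, with the
#' following frame also deviating (debounce: a single noisy frame never
#' triggers). When per-frame uncertainties are supplied, the baseline
#' scatter is floored at their median: an empirical standard deviation
#' from a handful of frames fluctuates wildly, while the propagated
#' uncertainty is stable. Returns `NA` ("none") for flat traces.
#'
#' @param values trace values.
#' @param times frame times (s), same length.
#' @param baseline_n frames in the baseline window (default 3).
#' @param threshold deviation threshold in baseline standard deviations
#'   (default 3).
#' @param sigma optional per-frame uncertainties of `values`.
#' @return onset time (s) or `NA_real_`.
#' @export
detect_onset <- function(values, times, baseline_n = 3L, threshold = 3,
                         sigma = NULL) {
  stopifnot(length(values) == length(times))
  if (length(values) < baseline_n + 2L) {
    stop("need at least baseline_n + 2 frames")
  }
  base <- values[seq_len(baseline_n)]
  mu <- mean(base)
  s <- stats::sd(base)
  floor_s <- max(1e-12, 1e-9 * abs(mu))  # noiseless traces: any real step fires
  if (!is.null(sigma)) {
    floor_s <- max(floor_s, stats::median(sigma[seq_len(baseline_n)],
                                          na.rm = TRUE), na.rm = TRUE)
  }
  s <- max(s, floor_s)
  dev <- abs(values - mu) > threshold * s
  for (i in (baseline_n + 1L):(length(values) - 1L)) {
    if (dev[i] && dev[i + 1L]) return(times[i])
  }
  if (dev[length(values)] && length(values) > baseline_n + 1L &&
      dev[length(values) - 1L]) {
    return(times[length(values) - 1L])
  }
  NA_real_
}

#' Detect when a kinetic trace reaches its final plateau
#'
#' The plateau value is the mean of the last `run_length` frames. The
#' completion time is the first frame at or after the onset from which
#' every later value stays within `tolerance` of the total change of the
#' plateau value. When per-frame uncertainties are supplied the band is
#' floored at `threshold` times their median (a plateau cannot be held
#' tighter than the noise). If the last `run_length` frames still span
#' more than that band (the trace ends mid-transition), the result is
#' "not reached" (`NA`) with the last value attached.
#'
#' @param values trace values.
#' @param times frame times (s).
#' @param onset onset time from [detect_onset()]; `NA` returns `NA`.
#' @param tolerance plateau band as a fraction of the total change
#'   (default 0.05).
#' @param run_length frames defining the plateau (default 3).
#' @param sigma optional per-frame uncertainties of `values`.
#' @param threshold noise multiple flooring the band when `sigma` is given
#'   (default 3).
#' @return completion time (s), or `NA_real_` with attribute `last_value`
#'   when the plateau is not reached.
#' @export
detect_completion <- function(values, times, onset, tolerance = 0.05,
                              run_length = 3L, sigma = NULL, threshold = 3) {
  stopifnot(length(values) == length(times))
  if (is.na(onset)) return(NA_real_)
  n <- length(values)
  if (n < run_length + 1L) return(NA_real_)
  final <- mean(values[(n - run_length + 1L):n])
  base <- mean(values[times < onset])
  total <- abs(final - base)
  if (total == 0) total <- max(abs(values - final), .Machine$double.eps)
  band <- tolerance * total
  if (!is.null(sigma)) {
    band <- max(band, threshold * stats::median(sigma, na.rm = TRUE),
                na.rm = TRUE)
  }
  tail_vals <- values[(n - run_length + 1L):n]
  if (max(tail_vals) - min(tail_vals) > 2 * band) {
    return(structure(NA_real_, last_value = values[n],
                     status = "not reached"))
  }
  start <- which(times >= onset)[1]
  for (i in start:n) {
    if (all(abs(values[i:n] - final) <= band)) return(times[i])
  }
  structure(NA_real_, last_value = values[n], status = "not reached")
}

#' Track the lamellar d-spacing through a series
#'
#' Per frame, fits the lamellar orders in windows seeded from `d_seed` and
#' regresses the fitted positions through the origin
#' ([lattice_from_assignments()]) to get d(t) with an uncertainty from the
#' residual scatter (from the propagated position uncertainty when only
#' one order is found). Frames where no lamellar order can be fitted are
#' recorded as gaps (NA), not dropped.
#'
#' @param frames list of [saxs_pattern()] with `time_s` metadata.
#' @param d_seed starting lamellar repeat distance (nm).
#' @param orders diffraction orders to use (default 1:2).
#' @param sigma_init,max_drift as in [track_series()].
#' @return data frame of class `d_trace`: `time_s`, `d_nm`, `sigma_d`,
#'   `n_orders`.
#' @export
track_d_spacing <- function(frames, d_seed, orders = 1:2,
                            sigma_init = 0.02, max_drift = 0.02) {
  times <- vapply(frames, function(f) f$metadata$time_s %||% NA_real_,
                  numeric(1))
  if (any(is.na(times))) stop("every frame needs `time_s` metadata")
  ord <- order(times)
  frames <- frames[ord]; times <- times[ord]
  d_cur <- d_seed
  rows <- list()
  for (i in seq_along(frames)) {
    pat <- frames[[i]]
    noise <- stats::mad(pat$I - moving_average(pat$I, 5L))
    # model every order visible in the window (unmodelled higher orders
    # would inflate the residual scale and with it every uncertainty),
    # but regress the lattice only on the requested orders
    all_orders <- seq_len(max(1L, floor(max(pat$q) * d_cur / (2 * pi))))
    pos <- 2 * pi * all_orders / d_cur
    inside <- pos >= min(pat$q) & pos <= max(pat$q)
    tab <- fit_frame_peaks(pat, pos[inside], sigma_init,
                           mu_halfwidth = pmin(3 * sigma_init,
                                               max_drift * pos[inside]))
    qs <- c(); ms <- c(); ss <- c()
    for (jj in which(all_orders[inside] %in% orders)) {
      obs <- component_obs(tab, jj, noise)
      q_exp <- pos[inside][jj]
      if (is.null(obs) || abs(obs$q0 - q_exp) > max_drift * q_exp) next
      qs <- c(qs, obs$q0); ms <- c(ms, all_orders[inside][jj])
      ss <- c(ss, obs$sigma_q0)
    }
    if (length(qs) == 0L) {
      rows[[i]] <- data.frame(time_s = times[i], d_nm = NA_real_,
                              sigma_d = NA_real_, n_orders = 0L)
      next
    }
    est <- lattice_from_assignments(qs, ms,
                                    if (all(is.finite(ss)) && all(ss > 0)) ss)
    sigma_d <- est$sigma_a
    if (est$n_peaks == 1L && (!is.finite(sigma_d) || sigma_d == 0)) {
      sigma_d <- if (is.finite(ss[1])) est$a * ss[1] / qs[1] else NA_real_
    }
    d_cur <- est$a
    rows[[i]] <- data.frame(time_s = times[i], d_nm = est$a,
                            sigma_d = sigma_d, n_orders = est$n_peaks)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("d_trace", "data.frame")
  out
}

#' Summarize onsets and completions for all tracked reflections
#'
#' Applies [detect_onset()] and [detect_completion()] to every
#' (phase, reflection) trace in a `kinetics_trace`.
#'
#' @param trace a `kinetics_trace` from [track_series()].
#' @param baseline_n,threshold passed to [detect_onset()].
#' @param tolerance,run_length passed to [detect_completion()].
#' @return data frame: `phase`, `reflection`, `t_onset`, `t_complete`.
#' @export
kinetics_summary <- function(trace, baseline_n = 3L, threshold = 3,
                             tolerance = 0.05, run_length = 3L) {
  tr <- trace$traces
  keys <- unique(tr[, c("phase", "reflection")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- get_trace(trace, keys$phase[i], keys$reflection[i])
    on <- detect_onset(sub$norm_intensity, sub$time_s, baseline_n, threshold,
                       sigma = sub$sigma)
    cm <- detect_completion(sub$norm_intensity, sub$time_s, on,
                            tolerance, run_length, sigma = sub$sigma)
    data.frame(phase = keys$phase[i], reflection = keys$reflection[i],
               t_onset = as.numeric(on), t_complete = as.numeric(cm))
  })
  do.call(rbind, rows)
}

#' Export a kinetics trace as CSV
#'
#' @param trace a `kinetics_trace`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(trace$traces, path, row.names = FALSE)
  invisible(path)
}
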