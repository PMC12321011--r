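#' Detect candidate Bragg peaks
#'
#' Finds local maxima of a lightly smoothed curve (5-point moving average)
#' whose prominence above a local linear baseline exceeds
#' `min_prominence_snr` times a robust noise estimate. The noise level is
#' the median absolute deviation of the detrended curve (raw minus
#' smoothed), which is insensitive to the peaks themselves. Candidates
#' closer than `min_separation` are merged, keeping the higher apex, so an
#' unresolved doublet yields a single candidate. Deterministic for fixed
#' input.
#'
#' @param pattern a [saxs_pattern()] (background-corrected, or raw if the
#'   local-baseline model can absorb the background).
#' @param min_prominence_snr prominence threshold in units of the noise
#'   estimate (default 3).
#' @param min_separation minimum candidate spacing in nm^-1; default
#'   3 x `sigma_hint`.
#' @param sigma_hint prior guess of the Gaussian peak width (nm^-1),
#'   default 0.02.
#' @return numeric vector of candidate positions (possibly empty), sorted.
#' @export
detect_peaks <- function(pattern, min_prominence_snr = 3,
                         min_separation = NULL, sigma_hint = 0.02) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  if (is.null(min_separation)) min_separation <- 3 * sigma_hint
  q <- pattern$q
  y <- pattern$I
  n <- length(y)
  if (n < 7L) return(numeric(0))
  ys <- moving_average(y, 5L)
  noise <- stats::mad(y - ys)
  if (noise <= 0) noise <- .Machine$double.eps * max(abs(y), 1)

  # interior local maxima of the smoothed curve
  idx <- which(ys[2:(n - 1)] > ys[1:(n - 2)] & ys[2:(n - 1)] >= ys[3:n]) + 1L
  if (length(idx) == 0L) return(numeric(0))

  # prominence above the chord between the bracketing local minima
  prom <- vapply(idx, function(i) {
    lo <- i; while (lo > 1L && ys[lo - 1L] <= ys[lo]) lo <- lo - 1L
    hi <- i; while (hi < n && ys[hi + 1L] <= ys[hi]) hi <- hi + 1L
    base <- ys[lo] + (ys[hi] - ys[lo]) * (q[i] - q[lo]) / (q[hi] - q[lo])
    ys[i] - base
  }, numeric(1))
  keep <- idx[prom > min_prominence_snr * noise]
  if (length(keep) == 0L) return(numeric(0))

  # merge near-coincident candidates, keeping the higher apex
  ord <- keep[order(q[keep])]
  merged <- ord[1]
  for (i in ord[-1]) {
    last <- merged[length(merged)]
    if (q[i] - q[last] < min_separation) {
      if (ys[i] > ys[last]) merged[length(merged)] <- i
    } else {
      merged <- c(merged, i)
    }
  }
  q[merged]
}

moving_average <- function(y, k) {
  half <- (k - 1L) %/% 2L
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, rep(1 / k, k), sides = 2))[(half + 1L):(half + n)]
}

#' Fit Gaussian peaks with local linear backgrounds
#'
#' Each candidate is fitted as a Gaussian plus a local linear background
#' over a window of +/- `window_sigmas` initial width guesses around the
#' candidate; candidates whose windows overlap are fitted jointly as a sum
#' of Gaussians sharing one linear background. Parameter uncertainties come
#' from the local fit covariance. Non-converged fits are dropped with a
#' warning; fitted amplitudes below `snr_min` times the noise level are
#' flagged non-significant and excluded.
#'
#' @param pattern a [saxs_pattern()].
#' @param candidates candidate positions from [detect_peaks()] (or known
#'   expected positions).
#' @param sigma_init initial Gaussian width guess (nm^-1), default 0.02.
#' @param window_sigmas half-width of the fit window in units of
#'   `sigma_init` (default 5).
#' @param snr_min significance threshold on fitted amplitude over noise
#'   (default 3); set to 0 to keep everything.
#' @return data frame of class `peak_table`, one row per retained peak:
#'   `q0`, `sigma_q0`, `amplitude`, `sigma_amplitude`, `width`,
#'   `sigma_width`, `area`, `bg_intercept`, `bg_slope`, `redchi`,
#'   `converged`, `significant`.
#' @export
fit_peaks <- function(pattern, candidates, sigma_init = 0.02,
                      window_sigmas = 5, snr_min = 3) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  if (length(candidates) == 0L) stop("at least one candidate position is required")
  candidates <- sort(as.numeric(candidates))
  q <- pattern$q
  y <- pattern$I
  noise <- stats::mad(y - moving_average(y, 5L))
  if (noise <= 0) noise <- .Machine$double.eps * max(abs(y), 1)
  half <- window_sigmas * sigma_init

  # group candidates whose fit windows overlap
  groups <- list(1L)
  if (length(candidates) > 1L) {
    for (i in 2:length(candidates)) {
      g <- groups[[length(groups)]]
      if (candidates[i] - candidates[g[length(g)]] < 2 * half) {
        groups[[length(groups)]] <- c(g, i)
      } else {
        groups[[length(groups) + 1L]] <- i
      }
    }
  }

  rows <- list()
  n_failed <- 0L
  for (g in groups) {
    cand <- candidates[g]
    sel <- q >= min(cand) - half & q <= max(cand) + half
    if (sum(sel) < 3L * length(cand) + 2L) {
      n_failed <- n_failed + length(cand)
      next
    }
    fit <- fit_gaussian_group(q[sel], y[sel],
                              if (!is.null(pattern$sigma)) pattern$sigma[sel],
                              cand, sigma_init)
    if (is.null(fit)) {
      n_failed <- n_failed + length(cand)
      next
    }
    rows[[length(rows) + 1L]] <- fit
  }
  if (n_failed > 0L) {
    if (length(rows) == 0L) {
      stop("all peak fits failed to converge (", n_failed, " candidate(s)); ",
           "check the candidate positions and width guess")
    }
    warning(n_failed, " candidate(s) dropped: fit did not converge")
  }
  out <- do.call(rbind, rows)
  out$significant <- out$amplitude > snr_min * noise
  if (any(!out$significant)) {
    out <- out[out$significant | snr_min == 0, , drop = FALSE]
  }
  out <- out[order(out$q0), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peak_table", "data.frame")
  out
}

# Joint fit of k Gaussians + shared local background on one window.
# With constrain = TRUE each position is boxed to +/- 3 sigma_init of its
# candidate and widths to [sigma_init/4, 4 sigma_init] (used by tracking,
# where a component must not migrate onto a neighbouring peak).
# bg_degree 1 fits a linear background; 2 adds a quadratic term (tracking
# windows are widened to cover neighbours, where power-law curvature is no
# longer locally linear).
fit_gaussian_group <- function(q, y, sigma, cand, sigma_init,
                               constrain = FALSE, bg_degree = 1L) {
  k <- length(cand)
  n <- length(q)
  b1_0 <- (y[n] - y[1]) / (q[n] - q[1])
  b0_0 <- min(y - b1_0 * (q - mean(q)))
  amp0 <- vapply(cand, function(c0) {
    near <- abs(q - c0) <= 2 * sigma_init
    if (!any(near)) near <- which.min(abs(q - c0))
    max(y[near] - (b0_0 + b1_0 * (q[near] - mean(q))))
  }, numeric(1))
  amp0 <- pmax(amp0, .Machine$double.eps)
  # two background starts: detrended chord and flat-at-minimum; keep the
  # better optimum (large joint windows are prone to local minima)
  make_start <- function(b0, b1, amps) {
    s <- c(rbind(amps, cand, rep(sigma_init, k)))
    names(s) <- paste0(rep(c("A", "mu", "s"), k), rep(seq_len(k), each = 3))
    s <- c(s, b0 = b0, b1 = b1)
    if (bg_degree >= 2L) s <- c(s, b2 = 0)
    s
  }
  amp0_flat <- vapply(cand, function(c0) {
    near <- abs(q - c0) <= 2 * sigma_init
    if (!any(near)) near <- which.min(abs(q - c0))
    max(y[near]) - min(y)
  }, numeric(1))
  starts <- list(make_start(b0_0, b1_0, amp0),
                 make_start(min(y), 0, pmax(amp0_flat, .Machine$double.eps)))
  start <- starts[[1]]

  model <- function(par, q) {
    out <- par[["b0"]] + par[["b1"]] * (q - mean(q))
    if (bg_degree >= 2L) out <- out + par[["b2"]] * (q - mean(q))^2
    for (j in seq_len(k)) {
      out <- out + par[[paste0("A", j)]] *
        exp(-(q - par[[paste0("mu", j)]])^2 / (2 * par[[paste0("s", j)]]^2))
    }
    out
  }
  w <- if (!is.null(sigma) && all(sigma > 0)) 1 / sigma else rep(1, length(q))
  resid_fun <- function(p) {
    par <- as.list(p)
    w * (y - model(par, q))
  }
  n_bg <- length(start) - 3L * k
  if (constrain) {
    lower <- c(rbind(0, cand - 3 * sigma_init, rep(sigma_init / 4, k)),
               rep(-Inf, n_bg))
    upper <- c(rbind(Inf, cand + 3 * sigma_init, rep(4 * sigma_init, k)),
               rep(Inf, n_bg))
  } else {
    lower <- rep(-Inf, length(start))
    upper <- rep(Inf, length(start))
  }
  fit <- NULL
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = st, fn = resid_fun,
                         lower = lower, upper = upper,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(f) || !f$info %in% 1:4) next
    if (is.null(fit) || sum(f$fvec^2) < sum(fit$fvec^2)) fit <- f
  }
  if (is.null(fit)) return(NULL)
  p <- fit$par
  dof <- length(q) - length(start)
  redchi <- sum(fit$fvec^2) / max(dof, 1)
  covm <- tryCatch(summary(fit)$cov.unscaled * redchi, error = function(e) NULL)
  se <- function(nm) {
    if (is.null(covm)) return(NA_real_)
    i <- match(nm, names(start))
    v <- covm[i, i]
    if (is.finite(v) && v >= 0) sqrt(v) else NA_real_
  }
  rows <- lapply(seq_len(k), function(j) {
    A <- p[[paste0("A", j)]]
    mu <- p[[paste0("mu", j)]]
    s <- abs(p[[paste0("s", j)]])
    data.frame(q0 = mu, sigma_q0 = se(paste0("mu", j)),
               amplitude = A, sigma_amplitude = se(paste0("A", j)),
               width = s, sigma_width = se(paste0("s", j)),
               area = A * s * sqrt(2 * pi),
               bg_intercept = p[["b0"]], bg_slope = p[["b1"]],
               redchi = redchi, converged = TRUE)
  })
  out <- do.call(rbind, rows)
  # reject pathological solutions (position escaped the window, zero width)
  ok <- out$q0 >= min(q) & out$q0 <= max(q) & out$width > 0 &
    out$amplitude >= 0
  out[ok, , drop = FALSE]
}

#' Export a peak table as CSV
#'
#' @param peaks a `peak_table` from [fit_peaks()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_peak_table <- function(peaks, path) {
  utils::write.csv(as.data.frame(peaks), path, row.names = FALSE)
  invisible(path)
}
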