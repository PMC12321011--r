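#' Candidate mesophase models
#'
#' A mesophase model holds the ordered list of allowed reflections of one
#' lyotropic phase and the spacing-ratio sequence that fixes where its Bragg
#' peaks fall for a given lattice parameter. Peak positions follow
#' \eqn{q_m = 2\pi m / a}, where the dimensionless spacing ratio \eqn{m} is
#' \eqn{\sqrt{h^2+k^2+l^2}} for the cubic phases, the diffraction order
#' \eqn{n} for a lamellar stack, and \eqn{\sqrt{h^2+hk+k^2}} (relative to the
#' first reflection) for the 2D hexagonal phase.
#'
#' Allowed reflections are derived from the space-group reflection
#' conditions, not typed in as literals:
#' * lamellar: every order \eqn{n = 1, 2, 3, \dots} (encoded as (n,0,0));
#' * Pn3m (cubic aspect of the double-diamond phase): \eqn{h00} requires
#'   \eqn{h} even and \eqn{hk0}-type reflections require \eqn{h+k} even,
#'   giving the ratio sequence \eqn{\sqrt2, \sqrt3, \sqrt4, \sqrt6, \sqrt8,
#'   \sqrt9, \dots};
#' * Im3m (primitive bicontinuous phase, body-centred): \eqn{h+k+l} even,
#'   giving \eqn{\sqrt2, \sqrt4, \sqrt6, \sqrt8, \sqrt{10}, \sqrt{12}, \dots};
#' * hexagonal: ratios \eqn{1, \sqrt3, \sqrt4, \sqrt7, \dots}; its reported
#'   "lattice" parameter is the d-spacing of the (10) reflection.
#'
#' @param name one of `"lamellar"`, `"Pn3m"`, `"Im3m"`, `"hexagonal"`.
#' @param n_reflections number of allowed reflections to keep (default 6;
#'   the 0.5-4.5 nm^-1 window and 6-13 nm lattices admit few orders).
#' @return an object of class `mesophase_model` with fields `name`,
#'   `dimensionality`, and `reflections` (data frame with columns
#'   `h`, `k`, `l`, `m`, `label`).
#' @examples
#' mesophase_model("Pn3m")$reflections$m^2  # 2 3 4 6 8 9
#' @export
mesophase_model <- function(name = c("lamellar", "Pn3m", "Im3m", "hexagonal"),
                            n_reflections = 6L) {
  name <- match.arg(name)
  stopifnot(n_reflections >= 1L)
  refl <- switch(name,
    lamellar = {
      n <- seq_len(n_reflections)
      data.frame(h = n, k = 0L, l = 0L, m = as.numeric(n))
    },
    Pn3m = cubic_reflections(pn3m_allowed, n_reflections),
    Im3m = cubic_reflections(im3m_allowed, n_reflections),
    hexagonal = hexagonal_reflections(n_reflections)
  )
  refl$label <- paste0(refl$h, refl$k, refl$l)
  dim_tag <- switch(name, lamellar = "1D", hexagonal = "2D", "3D")
  structure(list(name = name, dimensionality = dim_tag, reflections = refl),
            class = "mesophase_model")
}

#' @export
print.mesophase_model <- function(x, ...) {
  cat(sprintf("<mesophase_model> %s (%s)\n", x$name, x$dimensionality))
  cat("  reflections:", paste(x$reflections$label, collapse = " "), "\n")
  cat("  m^2:", paste(signif(x$reflections$m^2, 6), collapse = " "), "\n")
  invisible(x)
}

#' Default candidate set used by the indexer
#'
#' Lamellar, Pn3m and Im3m by default. The 2D hexagonal phase is opt-in:
#' its low-order spacing ratios (1, sqrt(3), sqrt(4)) coincide exactly
#' with the ratios of Im3m's first three observable reflections, so with
#' sparse peak lists a hexagonal candidate shadows every Im3m assignment;
#' enable it when a hexagonal phase is genuinely plausible and inspect
#' the reported ranking for the resulting ambiguity.
#'
#' @param include_hexagonal include the hexagonal candidate (default FALSE).
#' @param n_reflections passed to [mesophase_model()].
#' @return named list of `mesophase_model` objects.
#' @export
default_candidates <- function(include_hexagonal = FALSE, n_reflections = 6L) {
  names <- c("lamellar", "Pn3m", "Im3m", if (include_hexagonal) "hexagonal")
  stats::setNames(lapply(names, mesophase_model, n_reflections = n_reflections),
                  names)
}

# Reflection condition for Im3m (body centring): h+k+l even.
im3m_allowed <- function(h, k, l) (h + k + l) %% 2L == 0L

# Reflection conditions for Pn3m, applied to the canonical representative
# with h >= k >= l >= 0: h00 needs h even; hk0 needs h+k even; general hkl
# unrestricted.
pn3m_allowed <- function(h, k, l) {
  if (k == 0L && l == 0L) return(h %% 2L == 0L)
  if (l == 0L) return((h + k) %% 2L == 0L)
  TRUE
}

# Enumerate cubic hkl (h >= k >= l >= 0), keep allowed ones, deduplicate by
# h^2+k^2+l^2 and keep the first n in increasing m.
cubic_reflections <- function(allowed, n) {
  hmax <- max(6L, ceiling(sqrt(4 * n)) + 2L)
  out <- list()
  for (h in 1:hmax) for (k in 0:h) for (l in 0:k) {
    if (allowed(h, k, l)) {
      out[[length(out) + 1L]] <- c(h, k, l, h^2 + k^2 + l^2)
    }
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab[, 4], tab[, 1], tab[, 2], tab[, 3]), , drop = FALSE]
  tab <- tab[!duplicated(tab[, 4]), , drop = FALSE]
  tab <- tab[seq_len(min(n, nrow(tab))), , drop = FALSE]
  data.frame(h = as.integer(tab[, 1]), k = as.integer(tab[, 2]),
             l = as.integer(tab[, 3]), m = sqrt(tab[, 4]))
}

# 2D hexagonal (hk0): m = sqrt(h^2 + hk + k^2), normalized so the first
# reflection has m = 1 (the reported parameter is d of the (10) reflection).
hexagonal_reflections <- function(n) {
  hmax <- max(4L, ceiling(sqrt(as.numeric(n) * 3)) + 2L)
  out <- list()
  for (h in 1:hmax) for (k in 0:h) {
    out[[length(out) + 1L]] <- c(h, k, h^2 + h * k + k^2)
  }
  tab <- do.call(rbind, out)
  tab <- tab[order(tab[, 3], tab[, 1]), , drop = FALSE]
  tab <- tab[!duplicated(tab[, 3]), , drop = FALSE]
  tab <- tab[seq_len(min(n, nrow(tab))), , drop = FALSE]
  data.frame(h = as.integer(tab[, 1]), k = as.integer(tab[, 2]), l = 0L,
             m = sqrt(tab[, 3]))
}

#' Bragg-peak positions of a mesophase in a q window
#'
#' Positions follow \eqn{q_m = 2\pi m / a}. Only reflections falling inside
#' `q_window` are returned, sorted by q.
#'
#' @param model a [mesophase_model()].
#' @param lattice lattice parameter a in nm (> 0); for lamellar this is the
#'   repeat distance d.
#' @param q_window numeric length-2 interval in nm^-1 (default the
#'   0.5-4.5 nm^-1 analysis window).
#' @return data frame with columns `h`, `k`, `l`, `m`, `label`, `q`.
#' @examples
#' reflection_positions(mesophase_model("lamellar"), 2 * pi, c(0.5, 3.5))$q
#' @export
reflection_positions <- function(model, lattice, q_window = c(0.5, 4.5)) {
  stopifnot(inherits(model, "mesophase_model"))
  if (!is.numeric(lattice) || length(lattice) != 1L || !is.finite(lattice) ||
      lattice <= 0) {
    stop("`lattice` must be a single positive number (nm)")
  }
  stopifnot(length(q_window) == 2L, q_window[1] < q_window[2])
  refl <- model$reflections
  refl$q <- 2 * pi * refl$m / lattice
  refl <- refl[refl$q >= q_window[1] & refl$q <= q_window[2], , drop = FALSE]
  refl[order(refl$q), c("h", "k", "l", "m", "label", "q")]
}

#' Lattice parameter from assigned peak positions
#'
#' Weighted least-squares fit of \eqn{q_i = (2\pi/a) m_i} through the
#' origin. Weights are \eqn{1/\sigma_{q,i}^2} when every assigned peak
#' carries a position uncertainty, otherwise uniform. With two or more
#' peaks the uncertainty of a comes from the residual scatter of the peak
#' positions about the fitted lattice; with a single peak it is propagated
#' first-order from that peak's position uncertainty.
#'
#' @param q peak positions (nm^-1), all > 0.
#' @param m spacing ratios of the assigned reflections, all > 0.
#' @param sigma_q optional position uncertainties (nm^-1).
#' @return object of class `lattice_estimate`: list with `a` (nm), `sigma_a`
#'   (nm), `rms_rel` (RMS of relative position residuals), `n_peaks`.
#' @examples
#' lattice_from_assignments(q = c(0.99, 2.01), m = c(1, 2))
#' @export
lattice_from_assignments <- function(q, m, sigma_q = NULL) {
  if (length(q) == 0L) stop("at least one assigned peak is required")
  if (length(q) != length(m)) stop("`q` and `m` must have equal length")
  if (any(!is.finite(q)) || any(q <= 0)) stop("peak positions must be > 0")
  if (any(!is.finite(m)) || any(m <= 0)) stop("spacing ratios must be > 0")
  n <- length(q)
  use_w <- !is.null(sigma_q) && all(is.finite(sigma_q)) && all(sigma_q > 0)
  w <- if (use_w) 1 / sigma_q^2 else rep(1, n)

  s <- sum(w * m * q) / sum(w * m^2)   # slope 2*pi/a
  a <- 2 * pi / s
  r <- q - s * m
  rms_rel <- sqrt(mean((r / (s * m))^2))

  if (n >= 2L) {
    var_s <- sum(w * r^2) / (n - 1) / sum(w * m^2)
    # with supplied position uncertainties, never report less than the
    # variance they propagate to (residual scatter is noisy at small n)
    if (use_w) var_s <- max(var_s, 1 / sum(w * m^2))
    sigma_s <- sqrt(var_s)
  } else {
    sq <- if (use_w) sigma_q[1] else 0
    sigma_s <- sq / m[1]
  }
  sigma_a <- a * sigma_s / s
  structure(list(a = a, sigma_a = sigma_a, rms_rel = rms_rel, n_peaks = n),
            class = "lattice_estimate")
}

#' @export
print.lattice_estimate <- function(x, ...) {
  cat(sprintf("<lattice_estimate> a = %.4f +/- %.4f nm (n = %d, rel. RMS %.2e)\n",
              x$a, x$sigma_a, x$n_peaks, x$rms_rel))
  invisible(x)
}
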