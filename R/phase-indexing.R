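#' Assign fitted peaks to coexisting mesophases
#'
#' Combination search over candidate phases, mirroring the manual practice
#' of checking phase combinations against the visible peaks. For every
#' subset of candidates up to `max_phases` (and every ordering of the
#' subset), phases are seeded one at a time: the lowest-q peak not yet
#' claimed is tried as each low-order reflection of the phase, peaks
#' within `tol` (relative q) of the implied positions are claimed
#' greedily, the lattice is refined by [lattice_from_assignments()], and
#' claim/refine iterates to a fixed point (at most 10 rounds).
#'
#' Assignments are ranked lexicographically by: fewest unexplained peaks;
#' fewest phases whose first allowed reflection falls inside the measured
#' window yet matches no peak (in lyotropic phases the lowest-order
#' reflection is the strongest, so an indexing that requires it to be
#' invisible is suspect — this breaks the ratio degeneracy between, e.g.,
#' a cubic lattice and the same lattice scaled by irrational factors);
#' fewest internal gaps (predicted reflections inside the window, below
#' the highest claimed order, that match no peak — trailing orders may
#' legitimately be too weak, but a skipped low order is damning); fewest
#' phases; and lowest relative position RMS. Remaining exact ties break
#' by a fixed phase-name order (lamellar, Pn3m, Im3m, hexagonal — the
#' order these mesophases are commonly encountered in lipid-water
#' systems), so the ranking is deterministic. A peak may stay unexplained
#' rather than force a bad match. Phases supported by a single peak are
#' flagged `underdetermined`: a lone first-order peak cannot discriminate
#' between candidate phases.
#'
#' @param peaks a `peak_table` from [fit_peaks()], or a numeric vector of
#'   peak positions (nm^-1).
#' @param candidates named list of [mesophase_model()] objects (default
#'   [default_candidates()]).
#' @param max_phases maximum number of coexisting phases (default 3).
#' @param tol relative q tolerance for claiming a peak (default 0.01).
#' @param margin report every assignment whose unexplained-peak count is
#'   within `margin` of the best (default 1), so near-degenerate
#'   alternatives stay visible.
#' @param lattice_range admissible lattice parameters in nm (default
#'   c(1, 50)); seeds outside it are discarded.
#' @param q_window measured q range in nm^-1; used to decide which
#'   predicted reflections count as missing (default: the span of the
#'   observed peaks).
#' @return list of `phase_assignment` objects, best first, with class
#'   `phase_ranking`. Each assignment has `phases` (named list of
#'   [lattice_from_assignments()] estimates), `peak_map` (data frame), a
#'   `score` list (`n_unexplained`, `n_missing`, `n_phases`, `rms_rel`),
#'   and `underdetermined` (character vector of phase names).
#' @export
index_phases <- function(peaks, candidates = default_candidates(),
                         max_phases = 3L, tol = 0.01, margin = 1L,
                         lattice_range = c(1, 50), q_window = NULL) {
  pk <- as_peak_input(peaks)
  if (nrow(pk) == 0L) stop("at least one peak is required")
  stopifnot(max_phases >= 1L, tol > 0)
  if (is.null(q_window)) {
    q_window <- c(min(pk$q0) * (1 - tol), max(pk$q0) * (1 + tol))
  }
  cand_names <- names(candidates)
  if (is.null(cand_names)) {
    cand_names <- vapply(candidates, `[[`, character(1), "name")
    names(candidates) <- cand_names
  }

  found <- list()
  for (size in seq_len(min(max_phases, length(candidates)))) {
    for (subset in combn_list(cand_names, size)) {
      for (ord in permutations(subset)) {
        asg <- assign_sequential(pk, candidates[ord], tol, lattice_range,
                                 q_window)
        if (is.null(asg)) next
        key <- assignment_key(asg)
        if (is.null(found[[key]])) found[[key]] <- asg
      }
    }
  }
  if (length(found) == 0L) {
    out <- structure(list(), class = "phase_ranking",
                     diagnostic = "no candidate phase explains any peak")
    return(out)
  }
  scores <- lapply(found, `[[`, "score")
  canon <- vapply(found, function(a)
    paste(sprintf("%02d", sort(phase_rank(names(a$phases)))), collapse = ""),
    character(1))
  ord <- order(vapply(scores, `[[`, numeric(1), "n_unexplained"),
               vapply(scores, `[[`, numeric(1), "first_missing"),
               vapply(scores, `[[`, numeric(1), "n_missing"),
               vapply(scores, `[[`, numeric(1), "n_phases"),
               vapply(scores, `[[`, numeric(1), "rms_rel"),
               canon, names(found))
  ranked <- unname(found[ord])
  best_unexp <- ranked[[1]]$score$n_unexplained
  keep <- vapply(ranked, function(a)
    a$score$n_unexplained <= best_unexp + margin, logical(1))
  structure(ranked[keep], class = "phase_ranking")
}

as_peak_input <- function(peaks) {
  if (is.numeric(peaks)) {
    pk <- data.frame(q0 = as.numeric(peaks),
                     sigma_q0 = rep(NA_real_, length(peaks)),
                     amplitude = rep(NA_real_, length(peaks)))
  } else {
    pk <- as.data.frame(peaks)
    if (!"q0" %in% names(pk)) stop("peak table must have a `q0` column")
    if (!"sigma_q0" %in% names(pk)) pk$sigma_q0 <- NA_real_
    if (!"amplitude" %in% names(pk)) pk$amplitude <- NA_real_
  }
  pk <- pk[order(pk$q0), , drop = FALSE]
  rownames(pk) <- NULL
  pk
}

# fixed tie-break order over the built-in candidates; unknown phases last
phase_rank <- function(names) {
  r <- match(names, c("lamellar", "Pn3m", "Im3m", "hexagonal"))
  r[is.na(r)] <- 90L
  r
}

combn_list <- function(x, m) {
  if (m > length(x)) return(list())
  asplit(utils::combn(x, m), 2L)
}

permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

# Sequentially seed and refine each phase in `models` (an ordered named
# list) against the peak table. Returns a phase_assignment or NULL if some
# phase in the subset claims nothing.
assign_sequential <- function(pk, models, tol, lattice_range, q_window) {
  n <- nrow(pk)
  claimed_by <- rep(NA_character_, n)   # phase name per peak
  claimed_refl <- rep(NA_character_, n)
  claimed_m <- rep(NA_real_, n)
  estimates <- list()

  for (nm in names(models)) {
    model <- models[[nm]]
    free <- which(is.na(claimed_by))
    if (length(free) == 0L) return(NULL)
    anchor_q <- pk$q0[free[1]]
    best <- NULL
    for (j in seq_len(nrow(model$reflections))) {
      a0 <- 2 * pi * model$reflections$m[j] / anchor_q
      if (a0 < lattice_range[1] || a0 > lattice_range[2]) next
      res <- claim_refine(pk, free, model, a0, tol, q_window)
      if (is.null(res)) next
      # same criteria as the global ranking: most claims, then no missing
      # first reflection, then fewest missing reflections, then RMS
      better <- is.null(best) ||
        length(res$peaks) > length(best$peaks) ||
        (length(res$peaks) == length(best$peaks) &&
           (res$first_missing < best$first_missing ||
              (res$first_missing == best$first_missing &&
                 (res$n_missing < best$n_missing ||
                    (res$n_missing == best$n_missing && res$rms < best$rms)))))
      if (better) best <- res
    }
    if (is.null(best) || !free[1] %in% best$peaks) {
      # the anchor peak itself must be explained by the phase seeded on it
      if (is.null(best)) return(NULL)
    }
    claimed_by[best$peaks] <- nm
    claimed_refl[best$peaks] <- best$labels
    claimed_m[best$peaks] <- best$m
    estimates[[nm]] <- best$estimate
  }

  finalize_assignment(pk, models, estimates, claimed_by, claimed_refl,
                      claimed_m, tol, q_window)
}

# Greedy claim of free peaks for one phase at trial lattice a0, then
# refine a and re-claim until the claimed set is stable (<= 10 rounds).
claim_refine <- function(pk, free, model, a0, tol, q_window) {
  a <- a0
  prev <- NULL
  for (iter in 1:10) {
    pred_q <- 2 * pi * model$reflections$m / a
    match <- greedy_match(pk$q0[free], pred_q, tol)
    if (length(match$peak) == 0L) return(NULL)
    sel <- free[match$peak]
    est <- lattice_from_assignments(pk$q0[sel], model$reflections$m[match$refl],
                                    pk$sigma_q0[sel])
    a <- est$a
    if (!is.null(prev) && identical(prev, sel)) break
    prev <- sel
  }
  used <- seq_len(nrow(model$reflections)) %in% match$refl
  gaps <- reflection_gaps(model, a, used, q_window)
  list(peaks = sel, refl = match$refl,
       labels = model$reflections$label[match$refl],
       m = model$reflections$m[match$refl],
       estimate = est, rms = est$rms_rel,
       n_missing = gaps$internal, first_missing = gaps$first)
}

# For one phase at lattice a: how many predicted reflections inside the
# measured window and below the highest claimed order match no peak
# ("internal gaps"), and is the first allowed reflection among them?
reflection_gaps <- function(model, a, used, q_window) {
  pred <- 2 * pi * model$reflections$m / a
  inside <- pred >= q_window[1] & pred <= q_window[2]
  top <- if (any(used)) max(which(used)) else 0L
  below_top <- seq_along(pred) <= top
  list(internal = sum(inside & !used & below_top),
       first = as.integer(inside[1] && !used[1]))
}

# One-to-one matching of observed to predicted positions by ascending
# relative deviation, capped at tol.
greedy_match <- function(q_obs, q_pred, tol) {
  dev <- abs(outer(q_obs, q_pred, "-")) /
    matrix(q_pred, length(q_obs), length(q_pred), byrow = TRUE)
  ord <- order(dev)
  used_p <- logical(length(q_obs))
  used_r <- logical(length(q_pred))
  peak <- integer(0); refl <- integer(0)
  for (k in ord) {
    if (dev[k] > tol) break
    i <- (k - 1L) %% length(q_obs) + 1L
    j <- (k - 1L) %/% length(q_obs) + 1L
    if (used_p[i] || used_r[j]) next
    used_p[i] <- TRUE; used_r[j] <- TRUE
    peak <- c(peak, i); refl <- c(refl, j)
  }
  list(peak = peak, refl = refl)
}

finalize_assignment <- function(pk, models, estimates, claimed_by,
                                claimed_refl, claimed_m, tol, q_window) {
  if (all(is.na(claimed_by))) return(NULL)
  q_pred <- rep(NA_real_, nrow(pk))
  for (i in which(!is.na(claimed_by))) {
    q_pred[i] <- 2 * pi * claimed_m[i] / estimates[[claimed_by[i]]]$a
  }
  rel_dev <- (pk$q0 - q_pred) / q_pred
  peak_map <- data.frame(q0 = pk$q0, sigma_q0 = pk$sigma_q0,
                         amplitude = pk$amplitude,
                         phase = ifelse(is.na(claimed_by), "unexplained",
                                        claimed_by),
                         reflection = claimed_refl, m = claimed_m,
                         q_pred = q_pred, rel_dev = rel_dev)

  # internal gaps: predicted reflections inside the measured window, below
  # the highest claimed order, matching no peak; a phase whose FIRST
  # allowed reflection (normally the strongest) is in the window but
  # unobserved is counted separately and penalized harder
  n_missing <- 0L
  first_missing <- 0L
  for (nm in names(estimates)) {
    used <- models[[nm]]$reflections$label %in%
      claimed_refl[which(claimed_by == nm)]
    gaps <- reflection_gaps(models[[nm]], estimates[[nm]]$a, used, q_window)
    n_missing <- n_missing + gaps$internal
    first_missing <- first_missing + gaps$first
  }

  mapped <- !is.na(claimed_by)
  score <- list(
    n_unexplained = sum(!mapped),
    first_missing = first_missing,
    n_missing = n_missing,
    n_phases = length(estimates),
    rms_rel = sqrt(mean(rel_dev[mapped]^2)))
  under <- names(estimates)[vapply(estimates, function(e) e$n_peaks, 0L) < 2L]
  structure(list(phases = estimates, peak_map = peak_map, score = score,
                 underdetermined = under),
            class = "phase_assignment")
}

assignment_key <- function(asg) {
  paste(paste(sort(names(asg$phases)), collapse = "+"),
        paste(asg$peak_map$phase, asg$peak_map$reflection,
              sep = ":", collapse = ","),
        sep = "|")
}

#' @export
print.phase_assignment <- function(x, ...) {
  cat("<phase_assignment>", paste(names(x$phases), collapse = " + "), "\n")
  for (nm in names(x$phases)) {
    e <- x$phases[[nm]]
    cat(sprintf("  %-10s a = %.3f +/- %.3f nm (%d peaks)%s\n", nm, e$a,
                e$sigma_a, e$n_peaks,
                if (nm %in% x$underdetermined) "  [underdetermined]" else ""))
  }
  cat(sprintf("  unexplained %d, missing %d, rel. RMS %.2e\n",
              x$score$n_unexplained, x$score$n_missing, x$score$rms_rel))
  invisible(x)
}

#' @export
print.phase_ranking <- function(x, ...) {
  if (length(x) == 0L) {
    cat("<phase_ranking> empty:", attr(x, "diagnostic"), "\n")
    return(invisible(x))
  }
  cat("<phase_ranking>", length(x), "assignment(s); best first\n")
  for (i in seq_along(x)) {
    cat(sprintf("[%d] ", i)); print(x[[i]])
  }
  invisible(x)
}

# Plain-list view of an assignment for JSON reports.
assignment_report <- function(asg) {
  if (inherits(asg, "phase_ranking")) {
    return(lapply(unclass(asg), assignment_report))
  }
  list(
    phases = lapply(asg$phases, function(e)
      list(a_nm = e$a, sigma_a_nm = e$sigma_a, rms_rel = e$rms_rel,
           n_peaks = e$n_peaks)),
    peak_map = asg$peak_map,
    score = asg$score,
    underdetermined = asg$underdetermined)
}

#' Compare phase assignments of two illumination states
#'
#' Reports phases that appear, disappear or persist between two states
#' (e.g. trans vs cis) and, for persisting phases, the lattice change
#' \eqn{\Delta a \pm \sigma} with \eqn{\sigma = \sqrt{\sigma_1^2+\sigma_2^2}}.
#' The outcome is classified as a mesophase transition (any phase appears
#' or disappears), a d-spacing shift (some persisting phase moves
#' significantly), or no change. A shift counts as significant when the
#' two \eqn{a \pm \sigma} error bars do not overlap
#' (\eqn{|\Delta a| > \sigma_1 + \sigma_2}), the way such tabulated values
#' are read in practice.
#'
#' @param before,after `phase_assignment` objects (e.g. trans and cis).
#' @return list of class `transition_report` with `appearing`,
#'   `disappearing`, `persisting` (data frame with `phase`, `a_before`,
#'   `a_after`, `delta_a`, `sigma_delta`, `significant`), and `outcome`.
#' @export
compare_states <- function(before, after) {
  stopifnot(inherits(before, "phase_assignment"),
            inherits(after, "phase_assignment"))
  pb <- names(before$phases); pa <- names(after$phases)
  persisting <- intersect(pb, pa)
  per <- if (length(persisting)) {
    do.call(rbind, lapply(persisting, function(nm) {
      e1 <- before$phases[[nm]]; e2 <- after$phases[[nm]]
      d <- e2$a - e1$a
      s <- sqrt(e1$sigma_a^2 + e2$sigma_a^2)
      data.frame(phase = nm, a_before = e1$a, a_after = e2$a,
                 delta_a = d, sigma_delta = s,
                 significant = abs(d) > e1$sigma_a + e2$sigma_a)
    }))
  } else {
    data.frame(phase = character(0), a_before = numeric(0),
               a_after = numeric(0), delta_a = numeric(0),
               sigma_delta = numeric(0), significant = logical(0))
  }
  appearing <- setdiff(pa, pb)
  disappearing <- setdiff(pb, pa)
  outcome <- if (length(appearing) || length(disappearing)) {
    "mesophase transition"
  } else if (any(per$significant)) {
    "d-spacing shift"
  } else {
    "no change"
  }
  structure(list(appearing = appearing, disappearing = disappearing,
                 persisting = per, outcome = outcome),
            class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat("<transition_report>", x$outcome, "\n")
  if (length(x$disappearing)) cat("  disappearing:",
                                  paste(x$disappearing, collapse = ", "), "\n")
  if (length(x$appearing)) cat("  appearing:",
                               paste(x$appearing, collapse = ", "), "\n")
  if (nrow(x$persisting)) {
    for (i in seq_len(nrow(x$persisting))) {
      p <- x$persisting[i, ]
      cat(sprintf("  %-10s delta a = %+.3f +/- %.3f nm%s\n", p$phase,
                  p$delta_a, p$sigma_delta,
                  if (p$significant) " (significant)" else ""))
    }
  }
  invisible(x)
}
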