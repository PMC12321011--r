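#' Construct a 1D SAXS pattern
#'
#' Container for one reduced scattering curve: scattering vector q (nm^-1),
#' intensity I (counts, arbitrary units), optional per-point uncertainty,
#' plus sample metadata.
#'
#' @param q strictly increasing positive numeric vector (nm^-1).
#' @param I intensity vector, same length as `q`.
#' @param sigma optional uncertainty vector (>= 0), same length.
#' @param metadata named list; recognized entries include `sample`,
#'   `composition`, `state` (one of "trans", "cis", "transitioning"),
#'   `time_s`, `illumination_nm`, `temperature_C`.
#' @return object of class `saxs_pattern`.
#' @export
saxs_pattern <- function(q, I, sigma = NULL, metadata = list()) {
  q <- as.numeric(q); I <- as.numeric(I)
  if (length(q) != length(I)) stop("`q` and `I` must have equal length")
  if (any(!is.finite(q))) stop("`q` must be finite")
  if (any(diff(q) <= 0)) stop("`q` must be strictly increasing")
  if (!is.null(sigma)) {
    sigma <- as.numeric(sigma)
    if (length(sigma) != length(q)) stop("`sigma` must match `q` in length")
    if (any(sigma < 0, na.rm = TRUE)) stop("`sigma` must be >= 0")
  }
  if (!is.null(metadata$state) &&
      !metadata$state %in% c("trans", "cis", "transitioning")) {
    stop("metadata$state must be 'trans', 'cis' or 'transitioning'")
  }
  structure(list(q = q, I = I, sigma = sigma, metadata = metadata),
            class = "saxs_pattern")
}

#' @export
print.saxs_pattern <- function(x, ...) {
  cat(sprintf("<saxs_pattern> %d points, q in [%.3g, %.3g] nm^-1%s\n",
              length(x$q), min(x$q), max(x$q),
              if (is.null(x$sigma)) "" else ", with uncertainties"))
  if (length(x$metadata)) {
    keep <- vapply(x$metadata, function(v) is.atomic(v) && length(v) == 1L,
                   logical(1))
    md <- x$metadata[keep]
    if (length(md))
      cat("  ", paste(names(md), unlist(md), sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a 3-column ASCII SAXS curve
#'
#' Parses whitespace- or comma-delimited columns q, I and (optionally)
#' sigma. Lines starting with `#` are treated as comments; if any comment
#' line declares inverse-Angstrom units (e.g. `q(A^-1)`, `1/A`,
#' `Angstrom^-1`), q is converted to nm^-1 by multiplying by 10.
#'
#' @param path file path.
#' @param metadata metadata list attached to the returned pattern.
#' @return a [saxs_pattern()].
#' @export
read_dat <- function(path, metadata = list()) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  comments <- lines[startsWith(trimws(lines), "#")]
  body <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (length(body) == 0L) stop("no data rows in ", path)
  rows <- lapply(strsplit(trimws(body), "[,[:space:]]+"), as.numeric)
  ncol <- unique(lengths(rows))
  if (length(ncol) != 1L) stop("inconsistent column counts in ", path)
  if (ncol < 2L) stop("need at least 2 numeric columns (q, I) in ", path)
  tab <- do.call(rbind, rows)
  if (any(!is.finite(tab[, 1:2]))) stop("non-numeric q or I values in ", path)
  q <- tab[, 1]
  angstrom <- any(grepl("(A|Å|Angstrom)\\s*(\\^-1|\\⁻¹|-1)|1\\s*/\\s*(A|Å)",
                        comments, ignore.case = TRUE))
  if (angstrom) q <- q * 10
  if (any(diff(q) <= 0)) stop("q column is not strictly increasing in ", path)
  sigma <- if (ncol >= 3L) tab[, 3] else NULL
  saxs_pattern(q, tab[, 2], sigma, metadata)
}

#' Write a SAXS pattern as 3-column ASCII
#'
#' Writes `# q(nm^-1) I sigma` columns at full double precision so that a
#' read/write round trip reproduces the arrays.
#'
#' @param pattern a [saxs_pattern()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_dat <- function(pattern, path) {
  stopifnot(inherits(pattern, "saxs_pattern"))
  has_sigma <- !is.null(pattern$sigma)
  header <- if (has_sigma) "# q(nm^-1) I sigma" else "# q(nm^-1) I"
  cols <- if (has_sigma) {
    cbind(pattern$q, pattern$I, pattern$sigma)
  } else {
    cbind(pattern$q, pattern$I)
  }
  body <- apply(cols, 1L, function(r)
    paste(formatC(r, format = "g", digits = 17), collapse = " "))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Subtract a scaled buffer measurement
#'
#' \eqn{I_{corr} = I_{sample} - s\,I_{buffer}} on a shared q grid. The two
#' grids must agree point-by-point; no implicit regridding is performed,
#' because background subtraction on silently interpolated grids corrupts
#' peak shapes. Uncertainties combine in quadrature,
#' \eqn{\sigma_{corr} = \sqrt{\sigma_s^2 + s^2 \sigma_b^2}}, when both
#' patterns carry them. The scale and buffer identity are recorded in the
#' result's metadata as provenance.
#'
#' @param sample,buffer [saxs_pattern()] objects on identical q grids.
#' @param scale dimensionless buffer scale factor (default 1).
#' @return corrected [saxs_pattern()].
#' @export
subtract_background <- function(sample, buffer, scale = 1) {
  stopifnot(inherits(sample, "saxs_pattern"), inherits(buffer, "saxs_pattern"))
  if (length(sample$q) != length(buffer$q) ||
      max(abs(sample$q - buffer$q)) > 1e-9 * max(abs(sample$q))) {
    stop("sample and buffer q grids differ; regrid the buffer explicitly ",
         "before subtracting (no implicit interpolation is performed)")
  }
  I_corr <- sample$I - scale * buffer$I
  sigma <- NULL
  if (!is.null(sample$sigma) && !is.null(buffer$sigma)) {
    sigma <- sqrt(sample$sigma^2 + scale^2 * buffer$sigma^2)
  } else if (!is.null(sample$sigma)) {
    sigma <- sample$sigma
  }
  md <- sample$metadata
  md$background_subtracted <- TRUE
  md$background_scale <- scale
  md$background_id <- buffer$metadata$sample %||% "buffer"
  saxs_pattern(sample$q, I_corr, sigma, md)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a hierarchical analysis-result container
#'
#' Serializes raw pattern, corrected pattern, reduction provenance, peak
#' fits and phase assignments into one self-describing hierarchical JSON
#' container whose group layout follows NXcanSAS naming where it is
#' obvious (`entry/data/...`). Numeric arrays are written at full
#' precision; the writer is idempotent (no timestamps), so writing the
#' same objects twice yields byte-identical files.
#'
#' @param path output path (conventionally `.json`).
#' @param raw raw [saxs_pattern()].
#' @param corrected optional corrected [saxs_pattern()].
#' @param peaks optional peak table (data frame from [fit_peaks()]).
#' @param assignment optional `phase_assignment` from [index_phases()].
#' @return the path, invisibly.
#' @export
write_result_container <- function(path, raw, corrected = NULL, peaks = NULL,
                                   assignment = NULL) {
  stopifnot(inherits(raw, "saxs_pattern"))
  pat_group <- function(p) {
    g <- list(q = p$q, I = p$I, q_units = "nm^-1")
    if (!is.null(p$sigma)) g$Idev <- p$sigma else g$uncertainty_missing <- TRUE
    g$metadata <- p$metadata
    g
  }
  entry <- list(definition = "NXcanSAS-inspired",
                data = list(raw = pat_group(raw)))
  if (!is.null(corrected)) {
    entry$data$corrected <- pat_group(corrected)
    entry$reduction <- list(
      scale = corrected$metadata$background_scale,
      background_id = corrected$metadata$background_id)
  }
  if (!is.null(peaks)) entry$peaks <- peaks
  if (!is.null(assignment)) entry$assignment <- assignment_report(assignment)
  jsonlite::write_json(list(entry = entry), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' Read back a result container written by [write_result_container()]
#'
#' @param path container path.
#' @return nested list mirroring the container groups; the raw and
#'   corrected groups are re-materialized as [saxs_pattern()] objects under
#'   `$patterns`.
#' @export
read_result_container <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- obj$entry
  out$patterns <- list()
  for (nm in intersect(c("raw", "corrected"), names(out$data))) {
    g <- out$data[[nm]]
    out$patterns[[nm]] <- saxs_pattern(g$q, g$I, g$Idev,
                                       as.list(g$metadata))
  }
  out
}

#' Read a frame-series manifest
#'
#' Manifest CSV with columns `filename`, `time_s`, `illumination_nm`,
#' `state`; frames are returned sorted by time.
#'
#' @param path manifest CSV path.
#' @return data frame sorted by `time_s`.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("filename", "time_s")
  if (!all(need %in% names(man))) {
    stop("manifest must contain columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(man$time_s))) stop("manifest frame times must be numeric")
  man[order(man$time_s), , drop = FALSE]
}

#' Load the frames listed in a manifest
#'
#' @param path manifest CSV path; frame files are resolved relative to the
#'   manifest's directory.
#' @return list of [saxs_pattern()] in time order, each carrying `time_s`,
#'   `illumination_nm` and `state` metadata.
#' @export
read_series <- function(path) {
  man <- read_manifest(path)
  dir <- dirname(path)
  lapply(seq_len(nrow(man)), function(i) {
    read_dat(file.path(dir, man$filename[i]),
             metadata = list(time_s = man$time_s[i],
                             illumination_nm = man$illumination_nm[i],
                             state = man$state[i]))
  })
}
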