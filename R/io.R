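# Plain-text readers/writers: 2-column TSV with '#'-prefixed metadata
# headers. No vendor binary formats.

parse_meta <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  kv <- regmatches(meta_lines, regexec("^#\\s*([^:]+):\\s*(.*)$", meta_lines))
  out <- list()
  for (m in kv) {
    if (length(m) == 3) out[[trimws(m[2])]] <- trimws(m[3])
  }
  out
}

read_two_col <- function(path, col_names) {
  lines <- readLines(path)
  body <- which(!grepl("^#", lines) & nzchar(trimws(lines)))
  if (length(body) == 0) abort(sprintf("%s: no data rows.", path))
  fields <- strsplit(trimws(lines[body]), "[\t ]+")
  bad <- which(vapply(fields, length, integer(1)) != 2)
  if (length(bad))
    abort(sprintf("%s: line %d is not a 2-column row.", path, body[bad[1]]))
  x <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1)))
  y <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2)))
  nonnum <- which(is.na(x) | is.na(y))
  if (length(nonnum))
    abort(sprintf("%s: line %d contains a non-numeric value.", path,
                  body[nonnum[1]]))
  out <- tibble::tibble(!!col_names[1] := x, !!col_names[2] := y)
  attr(out, "meta") <- parse_meta(lines)
  attr(out, "lines") <- body
  out
}

#' Read a TCSPC decay histogram from TSV
#'
#' Expects two whitespace-separated columns (time in ns, counts), with
#' optional `# key: value` metadata headers. Bins must be uniformly spaced
#' and counts non-negative; violations are reported with the offending line
#' number.
#'
#' @param path Input file.
#' @return A `decay_histogram` tibble (`time`, `counts`) with parsed
#'   metadata in the `meta` attribute.
#' @export
read_decay <- function(path) {
  out <- read_two_col(path, c("time", "counts"))
  body <- attr(out, "lines")
  neg <- which(out$counts < 0)
  if (length(neg))
    abort(sprintf("%s: negative count on line %d.", path, body[neg[1]]))
  if (nrow(out) > 2) {
    db <- diff(out$time)
    irregular <- which(abs(db - db[1]) > 1e-6 * max(abs(db[1]), 1e-12))
    if (length(irregular))
      abort(sprintf("%s: non-uniform bin width at line %d.", path,
                    body[irregular[1] + 1]))
  }
  attr(out, "lines") <- NULL
  structure(out, class = c("decay_histogram", class(out)),
            dt = if (nrow(out) > 1) out$time[2] - out$time[1] else NA_real_)
}

#' Write a decay histogram (or survival curve) as TSV
#'
#' @param decay A `decay_histogram` or `survival_curve` tibble.
#' @param path Output file.
#' @param meta Named list written as `# key: value` headers.
#' @return `path`, invisibly.
#' @export
write_decay <- function(decay, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15),
                                            collapse = ",")), con)
  value_col <- if ("counts" %in% names(decay)) "counts" else "g"
  writeLines(sprintf("%.10g\t%.10g", decay$time, decay[[value_col]]), con)
  invisible(path)
}

#' Read an FCS autocorrelation curve from TSV
#'
#' Two columns (lag in s, G value) with optional `# key: value` headers;
#' lags must be strictly increasing.
#'
#' @param path Input file.
#' @return A tibble (`lag`, `g`) with metadata (including any `z_nm`) in
#'   attributes.
#' @export
read_fcs <- function(path) {
  out <- read_two_col(path, c("lag", "g"))
  body <- attr(out, "lines")
  if (is.unsorted(out$lag, strictly = TRUE)) {
    i <- which(diff(out$lag) <= 0)[1]
    abort(sprintf("%s: lag times not strictly increasing at line %d.", path,
                  body[i + 1]))
  }
  attr(out, "lines") <- NULL
  meta <- attr(out, "meta")
  if (!is.null(meta$z_nm))
    attr(out, "z_nm") <- as.numeric(meta$z_nm)
  out
}

#' Write an FCS autocorrelation curve as TSV
#' @param curve A tibble with `lag` and `g`.
#' @param path Output file.
#' @param meta Named list of `# key: value` headers (e.g. `z_nm`).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(curve, path, meta = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(meta))
    writeLines(sprintf("# %s: %s", k, paste(format(meta[[k]], digits = 15),
                                            collapse = ",")), con)
  writeLines(sprintf("%.10g\t%.10g", curve$lag, curve$g), con)
  invisible(path)
}

#' Build a z-scan dwell-time series from autocorrelation files
#'
#' Reads every per-z autocorrelation TSV, fits the 2D diffusion model with
#' [fit_acf()], and assembles the `(z, tau, n_particles)` series consumed by
#' [zscan_diffusion_fit()]. Dwell times are converted to ms.
#'
#' @param paths Character vector of FCS TSV files carrying `z_nm` metadata.
#' @return A tibble with one row per file: `z`, `tau` (ms), `n_particles`,
#'   `converged`.
#' @export
zscan_series_from_files <- function(paths) {
  purrr::map_dfr(paths, function(p) {
    curve <- read_fcs(p)
    z <- attr(curve, "z_nm")
    if (is.null(z)) abort(sprintf("%s: missing 'z_nm' metadata header.", p))
    fit <- fit_acf(curve)
    tibble::tibble(z = z, tau = fit$tau_diff * 1e3,
                   n_particles = fit$n_particles, converged = fit$converged)
  })
}
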