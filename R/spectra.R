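#' Construct an MS/MS spectrum
#'
#' A precursor plus a centroided peak list. Peaks are stored sorted by
#' ascending m/z with non-negative intensities.
#'
#' @param id Spectrum identifier (TITLE in MGF).
#' @param precursor_mz Precursor m/z.
#' @param precursor_charge Precursor charge state (>= 1).
#' @param peaks A data frame with numeric columns `mz` and `intensity`
#'   (may have zero rows).
#' @return A `spectrum` object.
#' @export
spectrum <- function(id, precursor_mz, precursor_charge, peaks) {
  peaks <- tibble::as_tibble(peaks)
  stopifnot(all(c("mz", "intensity") %in% names(peaks)),
            is.numeric(precursor_mz), precursor_mz > 0,
            precursor_charge >= 1)
  if (nrow(peaks)) {
    stopifnot(!anyNA(peaks$mz), !anyNA(peaks$intensity),
              all(peaks$intensity >= 0))
    peaks <- dplyr::arrange(peaks[c("mz", "intensity")], .data$mz)
  } else {
    peaks <- tibble::tibble(mz = numeric(), intensity = numeric())
  }
  structure(
    list(id = as.character(id), precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge), peaks = peaks),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s: precursor %.4f m/z (%d+), %d peaks\n",
              x$id, x$precursor_mz, x$precursor_charge, nrow(x$peaks)))
  invisible(x)
}

#' Read spectra from a Mascot generic format (MGF) file
#'
#' Parses BEGIN IONS/END IONS blocks with PEPMASS, CHARGE and TITLE
#' headers into [spectrum()] objects. CHARGE values like "2+" are read
#' as 2.
#'
#' @param path Path to an MGF file.
#' @return A list of `spectrum` objects.
#' @export
read_mgf <- function(path) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  spectra <- list()
  in_block <- FALSE
  title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
  mzs <- ints <- numeric()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (line == "BEGIN IONS") {
      if (in_block) stop("MGF parse error at line ", ln,
                         ": nested BEGIN IONS", call. = FALSE)
      in_block <- TRUE
      title <- NA_character_; pepmass <- NA_real_; charge <- NA_integer_
      mzs <- ints <- numeric()
    } else if (line == "END IONS") {
      if (!in_block) stop("MGF parse error at line ", ln,
                          ": END IONS without BEGIN IONS", call. = FALSE)
      if (is.na(pepmass)) stop("MGF parse error at line ", ln,
                               ": block without PEPMASS", call. = FALSE)
      if (is.na(charge)) charge <- 1L
      if (is.na(title)) title <- paste0("spectrum_", length(spectra) + 1L)
      spectra[[length(spectra) + 1L]] <- spectrum(
        id = title, precursor_mz = pepmass, precursor_charge = charge,
        peaks = tibble::tibble(mz = mzs, intensity = ints)
      )
      in_block <- FALSE
    } else if (in_block && grepl("=", line, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", line))
      value <- sub("^[^=]*=", "", line)
      if (key == "TITLE") title <- value
      if (key == "PEPMASS") {
        pepmass <- suppressWarnings(as.numeric(strsplit(value, "[ \t]")[[1]][1]))
        if (is.na(pepmass)) stop("MGF parse error at line ", ln,
                                 ": bad PEPMASS", call. = FALSE)
      }
      if (key == "CHARGE") {
        charge <- suppressWarnings(as.integer(sub("\\+$", "", value)))
        if (is.na(charge)) stop("MGF parse error at line ", ln,
                                ": bad CHARGE", call. = FALSE)
      }
    } else if (in_block) {
      fields <- suppressWarnings(as.numeric(strsplit(line, "[ \t]+")[[1]]))
      if (length(fields) < 2L || anyNA(fields[1:2])) {
        stop("MGF parse error at line ", ln, ": bad peak line", call. = FALSE)
      }
      mzs <- c(mzs, fields[1]); ints <- c(ints, fields[2])
    } else {
      stop("MGF parse error at line ", ln,
           ": content outside BEGIN IONS/END IONS", call. = FALSE)
    }
  }
  if (in_block) stop("MGF parse error: unterminated BEGIN IONS", call. = FALSE)
  spectra
}

#' Write spectra to an MGF file
#'
#' Round-trips with [read_mgf()]; m/z and intensities are written with
#' six decimals.
#'
#' @param spectra A list of [spectrum()] objects (or a single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  out <- character()
  for (sp in spectra) {
    stopifnot(inherits(sp, "spectrum"))
    out <- c(out,
             "BEGIN IONS",
             paste0("TITLE=", sp$id),
             sprintf("PEPMASS=%.6f", sp$precursor_mz),
             sprintf("CHARGE=%d+", sp$precursor_charge),
             sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity),
             "END IONS", "")
  }
  writeLines(out, path)
  invisible(path)
}

# Maximum bipartite matching (Kuhn's augmenting paths) between
# theoretical ions and observed peaks, edges = pairs within tolerance.
# Seeded in order of increasing |error| (ties: higher intensity) so the
# returned matching is both count-maximal and error-greedy.
.match_assign <- function(ion_mz, peak_mz, peak_int, tol) {
  n_ion <- length(ion_mz); n_peak <- length(peak_mz)
  cand <- vector("list", n_ion)
  for (i in seq_len(n_ion)) {
    within <- which(abs(peak_mz - ion_mz[i]) <= tol)
    err <- abs(peak_mz[within] - ion_mz[i])
    cand[[i]] <- within[order(err, -peak_int[within])]
  }
  peak_owner <- integer(n_peak)  # 0 = free
  ion_of <- integer(n_ion)       # 0 = unmatched
  augment <- function(i, env) {
    for (p in cand[[i]]) {
      if (env$visited[p]) next
      env$visited[p] <- TRUE
      if (peak_owner[p] == 0L || augment(peak_owner[p], env)) {
        peak_owner[p] <<- i
        ion_of[i] <<- p
        return(TRUE)
      }
    }
    FALSE
  }
  # process ions whose best candidate error is smallest first
  best_err <- vapply(seq_len(n_ion), function(i) {
    if (length(cand[[i]])) abs(peak_mz[cand[[i]][1]] - ion_mz[i]) else Inf
  }, numeric(1))
  for (i in order(best_err)) {
    if (length(cand[[i]])) {
      env <- new.env()
      env$visited <- logical(n_peak)
      augment(i, env)
    }
  }
  ion_of
}

#' Match theoretical ions to observed peaks
#'
#' Assigns theoretical fragment ions to spectrum peaks within an
#' absolute fragment tolerance (Da), each peak and each ion used at
#' most once. The assignment maximizes the number of matches and,
#' among count-maximal assignments, prefers smaller |error| then
#' higher intensity. Precursor agreement is evaluated separately on
#' the relative (ppm) scale.
#'
#' @param spec A [spectrum()].
#' @param ions A fragment-ion tibble ([fragment_series()] /
#'   [neutral_loss_ions()]).
#' @param fragment_tol Fragment tolerance, Da (> 0; default 0.5).
#' @param precursor_ppm Precursor tolerance, ppm (> 0; default 10).
#' @param expected_precursor_mz Theoretical precursor m/z for the ppm
#'   check (optional; NA skips the check).
#' @return A `match_result` object: tibble `matches` (ion columns plus
#'   `peak_mz`, `intensity`, `error`), counts `n_matched`,
#'   `n_theoretical`, and `precursor_error_ppm` /
#'   `precursor_within_tol`.
#' @export
match_peaks <- function(spec, ions, fragment_tol = 0.5, precursor_ppm = 10,
                        expected_precursor_mz = NA_real_) {
  stopifnot(inherits(spec, "spectrum"), fragment_tol > 0, precursor_ppm > 0)
  ions <- tibble::as_tibble(ions)
  assignment <- .match_assign(ions$mz, spec$peaks$mz, spec$peaks$intensity,
                              fragment_tol)
  hit <- assignment > 0L
  matches <- ions[hit, , drop = FALSE]
  matches$peak_mz <- spec$peaks$mz[assignment[hit]]
  matches$intensity <- spec$peaks$intensity[assignment[hit]]
  matches$error <- matches$peak_mz - matches$mz
  prec_err <- if (is.na(expected_precursor_mz)) NA_real_ else {
    (spec$precursor_mz - expected_precursor_mz) / expected_precursor_mz * 1e6
  }
  structure(
    list(matches = matches,
         n_matched = sum(hit),
         n_theoretical = nrow(ions),
         precursor_error_ppm = prec_err,
         precursor_within_tol = if (is.na(prec_err)) NA else
           abs(prec_err) <= precursor_ppm),
    class = "match_result"
  )
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result> %d/%d theoretical ions matched", x$n_matched,
              x$n_theoretical))
  if (!is.na(x$precursor_error_ppm)) {
    cat(sprintf("; precursor %+.2f ppm (%s)", x$precursor_error_ppm,
                if (isTRUE(x$precursor_within_tol)) "within" else "outside"))
  }
  cat("\n")
  invisible(x)
}
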