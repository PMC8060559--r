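#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a site assignment into its candidate table
#'
#' @param x A [localize()] result.
#' @param ... Unused.
#' @return A tibble with one row per candidate placement: `positions`,
#'   `residues`, `score`, `is_best`.
#' @method tidy site_assignment
#' @export
tidy.site_assignment <- function(x, ...) {
  out <- x$candidates
  out$is_best <- out$positions == paste(x$positions, collapse = ",")
  dplyr::arrange(out, dplyr::desc(.data$score))
}

#' One-row summary of a site assignment
#'
#' @param x A [localize()] result.
#' @param ... Unused.
#' @return A one-row tibble: `sequence`, `positions`, `residues`,
#'   `score`, `runner_up_delta`, `neutral_loss_found`, `status`.
#' @method glance site_assignment
#' @export
glance.site_assignment <- function(x, ...) {
  tibble::tibble(
    sequence = x$sequence,
    positions = paste(x$positions, collapse = ","),
    residues = paste(x$residues, collapse = ","),
    score = x$score,
    runner_up_delta = x$runner_up_delta,
    neutral_loss_found = x$neutral_loss_found,
    status = x$status
  )
}

#' Tidy a sequence logo into long form
#'
#' @param x A [build_logo()] result.
#' @param ... Unused.
#' @return A tibble with `offset`, `residue`, `frequency`,
#'   `information` (bits, per offset), `n_obs`.
#' @method tidy cit_logo
#' @export
tidy.cit_logo <- function(x, ...) {
  long <- tibble::as_tibble(as.table(x$freq), .name_repair = "minimal")
  names(long) <- c("offset", "residue", "frequency")
  long$offset <- as.integer(as.character(long$offset))
  long$information <- x$information[as.character(long$offset)]
  long$n_obs <- x$n_obs[as.character(long$offset)]
  dplyr::arrange(long, .data$offset, .data$residue)
}

#' One-row summary of a sequence logo
#'
#' @param x A [build_logo()] result.
#' @param ... Unused.
#' @return A one-row tibble: `n_sites`, `half_width`, `max_information`,
#'   `total_information`.
#' @method glance cit_logo
#' @export
glance.cit_logo <- function(x, ...) {
  tibble::tibble(
    n_sites = x$n_sites,
    half_width = x$half_width,
    max_information = max(x$information, na.rm = TRUE),
    total_information = sum(x$information, na.rm = TRUE)
  )
}

#' Tidy a match result
#'
#' @param x A [match_peaks()] result.
#' @param ... Unused.
#' @return The matches tibble (`series`, `index`, `charge`, `mz`,
#'   `peak_mz`, `intensity`, `error`, ...).
#' @method tidy match_result
#' @export
tidy.match_result <- function(x, ...) {
  x$matches
}

#' One-row summary of a match result
#'
#' @param x A [match_peaks()] result.
#' @param ... Unused.
#' @return A one-row tibble with the match counts and precursor check.
#' @method glance match_result
#' @export
glance.match_result <- function(x, ...) {
  tibble::tibble(
    n_matched = x$n_matched,
    n_theoretical = x$n_theoretical,
    fraction_matched = x$n_matched / max(1L, x$n_theoretical),
    precursor_error_ppm = x$precursor_error_ppm,
    precursor_within_tol = x$precursor_within_tol
  )
}

#' Tidy a change summary
#'
#' @param x A [summarize_changes()] result.
#' @param ... Unused.
#' @return The per-record class tibble.
#' @method tidy cit_summary
#' @export
tidy.cit_summary <- function(x, ...) {
  x$classes
}

#' One-row summary of a change summary
#'
#' @param x A [summarize_changes()] result.
#' @param ... Unused.
#' @return A one-row tibble of class counts.
#' @method glance cit_summary
#' @export
glance.cit_summary <- function(x, ...) {
  tibble::as_tibble(as.list(x$counts))
}
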