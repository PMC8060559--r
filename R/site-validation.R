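#' Score thresholds for peptide and protein acceptance
#'
#' Lower bounds on the -10*log10 ion score: 30 for a citrullinated
#' peptide, 32 for a protein identification.
#'
#' @param peptide_min Minimum peptide ion score (default 30).
#' @param protein_min Minimum protein score (default 32).
#' @return A `score_thresholds` list.
#' @export
score_thresholds <- function(peptide_min = 30, protein_min = 32) {
  stopifnot(peptide_min > 0, protein_min > 0)
  structure(list(peptide_min = peptide_min, protein_min = protein_min),
            class = "score_thresholds")
}

#' Enumerate candidate placements of +0.984 Da deltas
#'
#' Every way of placing `n_deltas` +0.984016 Da shifts on the
#' peptide's R (citrullination) and N/Q (deamidation) residues -- the
#' two chemically distinct but isobaric explanations that must be
#' weighed against each other. Candidates are ordered
#' lexicographically by their position sets; a configurable cap guards
#' combinatorial blow-up on arginine-rich peptides.
#'
#' @param sequence Peptide sequence.
#' @param n_deltas Number of deltas to place (>= 1).
#' @param max_candidates Cap on the number of candidates (default
#'   200); truncation is signalled with a warning.
#' @return A list of [modified_peptide()]s (empty when fewer eligible
#'   residues than deltas).
#' @examples
#' length(candidate_placements("ETYMLSSLARVKTR", 2))  # 1: cit at 10 and 14
#' @export
candidate_placements <- function(sequence, n_deltas = 1L,
                                 max_candidates = 200L) {
  stopifnot(n_deltas >= 1L)
  sequence <- toupper(sequence)
  residues <- strsplit(sequence, "")[[1]]
  eligible <- which(residues %in% c("R", "N", "Q"))
  if (length(eligible) < n_deltas) return(list())
  combos <- utils::combn(eligible, n_deltas, simplify = FALSE)
  if (length(combos) > max_candidates) {
    warning("candidate placements truncated to ", max_candidates, " of ",
            length(combos), call. = FALSE)
    combos <- combos[seq_len(max_candidates)]
  }
  lapply(combos, function(pos) {
    mods <- lapply(residues[pos], function(r) {
      if (r == "R") mod_citrullination() else mod_deamidation()
    })
    modified_peptide(sequence, mods = mods, positions = pos)
  })
}

#' Binomial ion score of a peptide-spectrum match
#'
#' A chance-corrected match score on the familiar -10*log10 scale:
#' with n theoretical 1+ b/y ions, k of them matched, and a per-ion
#' chance-match probability p = (number of observed peaks * 2 *
#' fragment tolerance) / observed m/z span (clamped into (0, 1)), the
#' score is -10*log10 P(X >= k) for X ~ Binomial(n, p). Larger is
#' better; an empty match scores 0.
#'
#' @param spec A [spectrum()] (non-empty peak list).
#' @param mp A [modified_peptide()] candidate.
#' @param fragment_tol Fragment tolerance, Da (default 0.5).
#' @param precursor_ppm Precursor tolerance, ppm (default 10).
#' @return A single non-negative score.
#' @export
ion_score <- function(spec, mp, fragment_tol = 0.5, precursor_ppm = 10) {
  stopifnot(inherits(spec, "spectrum"), nrow(spec$peaks) > 0L)
  ions <- fragment_series(mp, max_charge = 1L)
  res <- match_peaks(spec, ions, fragment_tol = fragment_tol,
                     precursor_ppm = precursor_ppm,
                     expected_precursor_mz =
                       mz(peptide_mass(mp), spec$precursor_charge))
  .binomial_score(res$n_matched, res$n_theoretical,
                  .chance_p(spec, fragment_tol))
}

.chance_p <- function(spec, fragment_tol) {
  span <- diff(range(spec$peaks$mz))
  p <- nrow(spec$peaks) * 2 * fragment_tol / max(span, .Machine$double.eps)
  min(max(p, 1e-9), 1 - 1e-9)
}

.binomial_score <- function(k, n, p) {
  if (k <= 0L) return(0)
  tail <- stats::pbinom(k - 1L, n, p, lower.tail = FALSE)
  max(0, -10 * log10(max(tail, .Machine$double.xmin)))
}

#' Neutral-loss diagnostic for a citrullination assignment
#'
#' Checks the spectrum for the isocyanic-acid loss that distinguishes
#' citrulline from isobaric deamidation: a peak within the fragment
#' tolerance of precursor - 43.005814/z, or of any cit-containing
#' fragment minus the loss, with relative intensity at least
#' `intensity_floor` of the base peak. A placement without citrulline
#' generates no loss companions, so the diagnostic is FALSE for purely
#' deamidated candidates on clean spectra.
#'
#' @param spec A [spectrum()].
#' @param mp The candidate [modified_peptide()].
#' @param fragment_tol Fragment tolerance, Da (default 0.5).
#' @param intensity_floor Minimum relative intensity (default 0.01).
#' @return A list: `found` (logical), `on_precursor`, `on_fragment`
#'   (which companion fired).
#' @export
neutral_loss_diagnostic <- function(spec, mp, fragment_tol = 0.5,
                                    intensity_floor = 0.01) {
  stopifnot(inherits(spec, "spectrum"), inherits(mp, "modified_peptide"))
  if (nrow(spec$peaks) == 0L) {
    return(list(found = FALSE, on_precursor = FALSE, on_fragment = FALSE))
  }
  ions <- fragment_series(mp, max_charge = 1L)
  aug <- neutral_loss_ions(ions, mp,
                           precursor_charge = spec$precursor_charge)
  losses <- dplyr::filter(aug, .data$ion_type == "loss")
  if (nrow(losses) == 0L) {
    return(list(found = FALSE, on_precursor = FALSE, on_fragment = FALSE))
  }
  floor_abs <- intensity_floor * max(spec$peaks$intensity)
  strong <- spec$peaks[spec$peaks$intensity >= floor_abs, , drop = FALSE]
  seen <- vapply(losses$mz, function(m) {
    any(abs(strong$mz - m) <= fragment_tol)
  }, logical(1))
  list(
    found = any(seen),
    on_precursor = any(seen & losses$series == "precursor"),
    on_fragment = any(seen & losses$series != "precursor")
  )
}

#' Verify a citrullinated peptide against its unmodified counterpart
#'
#' TRUE iff the sequences are identical and every assigned
#' modification site is an arginine in the unmodified peptide -- the
#' manual check that each citrullinated residue corresponds to an R in
#' the counterpart identification.
#'
#' @param mp The modified [modified_peptide()].
#' @param unmodified The unmodified peptide sequence.
#' @return Logical.
#' @export
verify_counterpart <- function(mp, unmodified) {
  stopifnot(inherits(mp, "modified_peptide"),
            is.character(unmodified), length(unmodified) == 1L)
  unmodified <- toupper(unmodified)
  if (mp$sequence != unmodified) return(FALSE)
  pos <- mp$positions
  all(substring(unmodified, pos, pos) == "R")
}

#' Localize +0.984 Da deltas on a peptide from a spectrum
#'
#' Scores every candidate placement ([candidate_placements()]) with
#' [ion_score()] and returns the winner with its validation context:
#' runner-up score margin, neutral-loss diagnostic, and an overall
#' status. `accepted` requires a clear margin, an all-arginine
#' (citrullination) placement, and a score at or above the peptide
#' threshold; `ambiguous` flags a thin margin or a best placement
#' involving deamidation; `rejected` marks scores below threshold.
#'
#' @param spec A [spectrum()].
#' @param sequence Peptide sequence.
#' @param n_deltas Number of +0.984016 Da deltas to place.
#' @param fragment_tol,precursor_ppm Matching tolerances.
#' @param thresholds A [score_thresholds()].
#' @param margin Ambiguity margin in score units (default 5).
#' @param intensity_floor Neutral-loss relative intensity floor.
#' @return A `site_assignment` object.
#' @export
localize <- function(spec, sequence, n_deltas = 1L, fragment_tol = 0.5,
                     precursor_ppm = 10, thresholds = score_thresholds(),
                     margin = 5, intensity_floor = 0.01) {
  candidates <- candidate_placements(sequence, n_deltas)
  if (length(candidates) == 0L) {
    stop("no R/N/Q residue can carry the observed mass delta in '",
         sequence, "'", call. = FALSE)
  }
  scores <- vapply(candidates, function(cand) {
    ion_score(spec, cand, fragment_tol = fragment_tol,
              precursor_ppm = precursor_ppm)
  }, numeric(1))
  ord <- order(scores, decreasing = TRUE)
  best <- candidates[[ord[1]]]
  runner_up_delta <- if (length(scores) > 1L) {
    scores[ord[1]] - scores[ord[2]]
  } else Inf
  residues <- strsplit(best$sequence, "")[[1]][best$positions]
  loss <- neutral_loss_diagnostic(spec, best, fragment_tol = fragment_tol,
                                  intensity_floor = intensity_floor)
  status <- if (scores[ord[1]] < thresholds$peptide_min) {
    "rejected"
  } else if (any(residues != "R") || runner_up_delta < margin) {
    "ambiguous"
  } else {
    "accepted"
  }
  structure(
    list(peptide = best, sequence = toupper(sequence),
         positions = best$positions, residues = residues,
         score = scores[ord[1]], runner_up_delta = runner_up_delta,
         neutral_loss_found = loss$found, neutral_loss = loss,
         counterpart_verified = NA, status = status,
         candidates = tibble::tibble(
           positions = vapply(candidates, function(cand) {
             paste(cand$positions, collapse = ",")
           }, character(1)),
           residues = vapply(candidates, function(cand) {
             paste(strsplit(cand$sequence, "")[[1]][cand$positions],
                   collapse = ",")
           }, character(1)),
           score = scores
         )),
    class = "site_assignment"
  )
}

#' @export
print.site_assignment <- function(x, ...) {
  cat(sprintf("<site_assignment> %s: delta on %s (%s), score %.1f (margin %.1f), loss %s -> %s\n",
              x$sequence,
              paste(x$positions, collapse = ","),
              paste(x$residues, collapse = ","),
              x$score, x$runner_up_delta,
              if (isTRUE(x$neutral_loss_found)) "found" else "absent",
              x$status))
  invisible(x)
}

#' Final acceptance decision for a site assignment
#'
#' Accepted iff the score clears the peptide threshold, the best
#' placement is all-arginine, and -- when required -- the neutral-loss
#' diagnostic fired and the unmodified counterpart was verified.
#'
#' @param assignment A [localize()] result.
#' @param thresholds A [score_thresholds()].
#' @param require_loss Demand the 43 Da neutral loss?
#' @param require_counterpart Demand counterpart verification?
#' @return One of "accepted", "ambiguous", "rejected".
#' @export
accept <- function(assignment, thresholds = score_thresholds(),
                   require_loss = FALSE, require_counterpart = FALSE) {
  stopifnot(inherits(assignment, "site_assignment"))
  if (assignment$score < thresholds$peptide_min) return("rejected")
  if (any(assignment$residues != "R")) return("ambiguous")
  if (require_loss && !isTRUE(assignment$neutral_loss_found)) {
    return("ambiguous")
  }
  if (require_counterpart && !isTRUE(assignment$counterpart_verified)) {
    return("ambiguous")
  }
  if (assignment$status == "ambiguous") return("ambiguous")
  "accepted"
}
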