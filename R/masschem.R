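#' Neutral monoisotopic mass of a modified peptide
#'
#' Sum of residue masses plus one water (termini) plus all modification
#' deltas.
#'
#' @param mp A [modified_peptide()].
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass(modified_peptide("G"))  # 75.032028
#' @export
peptide_mass <- function(mp) {
  stopifnot(inherits(mp, "modified_peptide"))
  residues <- strsplit(mp$sequence, "")[[1]]
  deltas <- vapply(mp$mods, `[[`, numeric(1), "delta")
  sum(.mass$residues[residues]) + .mass$water + sum(deltas)
}

#' m/z of a neutral mass at a given charge
#'
#' @param mass Neutral monoisotopic mass (Da).
#' @param charge Positive integer charge state.
#' @return m/z value.
#' @examples
#' mz(75.032028, 2)
#' @export
mz <- function(mass, charge) {
  stopifnot(all(charge >= 1))
  (mass + charge * .mass$proton) / charge
}

#' Theoretical b/y fragment ions of a modified peptide
#'
#' Enumerates the N-terminal (b) and C-terminal (y) backbone fragment
#' series produced by collision-induced dissociation, at charge states
#' 1..`max_charge`. For a peptide of length n each series has ions of
#' index 1..n-1. `contains_cit` flags fragments that span at least one
#' citrullination site: only these (and the precursor) can shed the
#' HNCO neutral loss.
#'
#' @param mp A [modified_peptide()].
#' @param series Which series to generate, a subset of c("b", "y").
#' @param max_charge Highest fragment charge state (default 1).
#' @return A tibble with columns `series`, `index`, `charge`, `mz`,
#'   `contains_cit`, `ion_type` ("primary").
#' @examples
#' mp <- modified_peptide("GG")
#' fragment_series(mp)
#' @export
fragment_series <- function(mp, series = c("b", "y"), max_charge = 1L) {
  stopifnot(inherits(mp, "modified_peptide"), max_charge >= 1L)
  series <- match.arg(series, c("b", "y"), several.ok = TRUE)
  residues <- strsplit(mp$sequence, "")[[1]]
  n <- length(residues)
  stopifnot(n >= 2L)

  site_mass <- .mass$residues[residues]
  deltas <- numeric(n)
  deltas[mp$positions] <- vapply(mp$mods, `[[`, numeric(1), "delta")
  site_mass <- unname(site_mass) + deltas
  cit_at <- logical(n)
  cit_at[cit_positions(mp)] <- TRUE

  idx <- seq_len(n - 1L)
  rows <- list()
  if ("b" %in% series) {
    b_neutral <- cumsum(site_mass)[idx]  # residue sums; proton added by mz()
    rows$b <- tibble::tibble(
      series = "b", index = idx,
      neutral = b_neutral,
      contains_cit = cumsum(cit_at)[idx] > 0L
    )
  }
  if ("y" %in% series) {
    y_neutral <- rev(cumsum(rev(site_mass)))[n - idx + 1L] + .mass$water
    rows$y <- tibble::tibble(
      series = "y", index = idx,
      neutral = y_neutral,
      contains_cit = rev(cumsum(rev(cit_at)))[n - idx + 1L] > 0L
    )
  }
  out <- dplyr::bind_rows(rows)
  out <- tidyr::crossing(out, charge = seq_len(max_charge))
  out$mz <- mz(out$neutral, out$charge)
  out$ion_type <- "primary"
  dplyr::select(out, "series", "index", "charge", "mz", "contains_cit",
                "ion_type")
}

#' Add HNCO neutral-loss companion ions
#'
#' For every ion that contains a citrullination site, and for the
#' precursor of a citrullinated peptide, appends a companion ion at
#' m/z - 43.005814/charge. The loss of isocyanic acid from the
#' citrulline ureido group is the diagnostic that separates
#' citrullination from isobaric deamidation, which cannot shed it.
#'
#' @param ions A fragment-ion tibble from [fragment_series()].
#' @param mp The [modified_peptide()] the ions belong to.
#' @param precursor_charge Charge for the precursor companion; defaults
#'   to the peptide's charge hint, else 1.
#' @return The ion tibble with rows of `ion_type` "loss" appended
#'   (including a `series` "precursor" row when the peptide is
#'   citrullinated); unchanged if nothing contains citrulline.
#' @export
neutral_loss_ions <- function(ions, mp, precursor_charge = NULL) {
  stopifnot(inherits(mp, "modified_peptide"))
  if (is.null(precursor_charge)) {
    precursor_charge <- if (is.null(mp$charge)) 1L else mp$charge
  }
  companions <- dplyr::filter(ions, .data$contains_cit,
                              .data$ion_type == "primary")
  if (length(cit_positions(mp)) == 0L && nrow(companions) == 0L) {
    return(ions)
  }
  companions$mz <- companions$mz - .mass$hnco_loss / companions$charge
  companions$ion_type <- "loss"
  if (length(cit_positions(mp)) > 0L) {
    prec <- tibble::tibble(
      series = "precursor", index = NA_integer_,
      charge = as.integer(precursor_charge),
      mz = mz(peptide_mass(mp), precursor_charge) -
        .mass$hnco_loss / precursor_charge,
      contains_cit = TRUE, ion_type = "loss"
    )
    companions <- dplyr::bind_rows(companions, prec)
  }
  dplyr::bind_rows(ions, companions)
}
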