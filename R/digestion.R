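#' Tryptic cleavage sites
#'
#' Positions after which trypsin cuts: every K or R not followed by
#' proline, excluding the C-terminal residue. Citrullinated arginines
#' lose the positive charge trypsin recognizes and are therefore not
#' cleaved; pass their positions in `blocked` to suppress them.
#'
#' @param sequence Protein or peptide sequence (uppercase string).
#' @param blocked Integer positions at which cleavage is blocked
#'   (e.g. citrullination sites).
#' @return Increasing integer vector of cut positions (cut is after
#'   position i).
#' @examples
#' cleavage_sites("AKERAVEALRAG")  # 2 4 10
#' @export
cleavage_sites <- function(sequence, blocked = integer()) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  residues <- strsplit(toupper(sequence), "")[[1]]
  n <- length(residues)
  if (n < 2L) return(integer())
  i <- seq_len(n - 1L)
  sites <- i[residues[i] %in% c("K", "R") & residues[i + 1L] != "P"]
  setdiff(sites, as.integer(blocked))
}

#' In-silico tryptic digestion
#'
#' Enumerates all peptide spans between consecutive cleavage boundaries
#' with at most `max_missed` internal (missed) cleavage sites,
#' including the protein N- and C-terminal spans. Annotated
#' citrullination sites block cleavage at their arginine and do not
#' count as missed cleavages unless `cleave_cit = TRUE` restores naive
#' behaviour.
#'
#' @param sequence Protein sequence, or a one-row protein tibble from
#'   [read_fasta()].
#' @param max_missed Maximum missed cleavages (>= 0); the search that
#'   motivated this package allowed one.
#' @param accession Accession label for the output (taken from the
#'   tibble when one is given).
#' @param cit_sites Integer protein positions of citrullinated
#'   arginines.
#' @param cleave_cit If TRUE, ignore `cit_sites` when placing cuts.
#' @param min_length,max_length Optional length filter on the reported
#'   spans.
#' @return A tibble of peptide spans sorted by (start, end):
#'   `accession`, `start`, `end`, `sequence`, `missed_cleavages`,
#'   `prev_residue`, `next_residue` ('-' at protein termini).
#' @examples
#' digest("AKERAVEALRAG", max_missed = 1)
#' @export
digest <- function(sequence, max_missed = 1L, accession = NA_character_,
                   cit_sites = integer(), cleave_cit = FALSE,
                   min_length = 1L, max_length = Inf) {
  if (is.data.frame(sequence)) {
    stopifnot(nrow(sequence) == 1L)
    accession <- sequence$accession
    sequence <- sequence$sequence
  }
  stopifnot(is.character(sequence), length(sequence) == 1L,
            max_missed >= 0L)
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  blocked <- if (cleave_cit) integer() else as.integer(cit_sites)
  sites <- cleavage_sites(sequence, blocked = blocked)
  bounds <- c(0L, sites, n)  # span k runs (bounds[k]+1)..bounds[k+1]
  nb <- length(bounds)
  spans <- list()
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + max_missed)) {
      spans[[length(spans) + 1L]] <-
        c(start = bounds[i] + 1L, end = bounds[j], missed = j - i - 1L)
    }
  }
  span_tab <- tibble::as_tibble(do.call(rbind, spans))
  prev_res <- ifelse(span_tab$start == 1L, "-",
                     substring(sequence, span_tab$start - 1L,
                               span_tab$start - 1L))
  next_res <- ifelse(span_tab$end == n, "-",
                     substring(sequence, span_tab$end + 1L,
                               span_tab$end + 1L))
  out <- tibble::tibble(
    accession = accession,
    start = span_tab$start, end = span_tab$end,
    sequence = substring(sequence, span_tab$start, span_tab$end),
    missed_cleavages = span_tab$missed,
    prev_residue = prev_res,
    next_residue = next_res
  )
  out <- dplyr::filter(out, nchar(.data$sequence) >= min_length,
                       nchar(.data$sequence) <= max_length)
  dplyr::arrange(out, .data$start, .data$end)
}

#' Flanked-peptide notation
#'
#' Renders peptide spans in the conventional "X.PEPTIDE.Y" notation,
#' with the preceding and following protein residues around the dots
#' and '-' at protein termini.
#'
#' @param spans A span tibble from [digest()].
#' @return Character vector, one entry per span.
#' @examples
#' flanked_notation(digest("AKERAVEALRAG", 1)[3, ])
#' @export
flanked_notation <- function(spans) {
  stopifnot(is.data.frame(spans))
  paste0(spans$prev_residue, ".", spans$sequence, ".", spans$next_residue)
}

#' Parse flanked-peptide notation
#'
#' Inverse of [flanked_notation()] for a single "X.PEPTIDE.Y" string.
#' Lowercase letters in the body (used in some published tables to
#' annotate residues) are recorded and upper-cased; a missing leading
#' flank (".PEPTIDE.Y") is read as a protein N-terminus.
#'
#' @param text A flanked peptide string.
#' @return A list with `sequence`, `prev_residue`, `next_residue`,
#'   `lowercase_positions` (1-based positions printed in lowercase).
#' @export
parse_flanked <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([A-Za-z-]?)\\.([A-Za-z]+)\\.([A-Za-z-]?)$",
                                text))[[1]]
  if (length(m) == 0L) {
    stop("not a flanked peptide: '", text, "'", call. = FALSE)
  }
  body <- m[3]
  chars <- strsplit(body, "")[[1]]
  list(
    sequence = toupper(body),
    prev_residue = if (nzchar(m[2])) toupper(m[2]) else "-",
    next_residue = if (nzchar(m[4])) toupper(m[4]) else "-",
    lowercase_positions = which(chars %in% letters)
  )
}
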