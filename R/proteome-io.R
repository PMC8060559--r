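#' Normalize a TAIR-style accession
#'
#' Case-folds a locus identifier such as "At5g08170" to "AT5G08170" and
#' splits a trailing ".n" isoform suffix. Anything after the first
#' whitespace or '|' is ignored. Unparseable inputs are returned as an
#' opaque upper-cased locus with a warning, never an error.
#'
#' @param text Character vector of raw accession strings.
#' @return A tibble with columns `locus` (character) and `isoform`
#'   (integer, NA when absent).
#' @examples
#' normalize_accession("At2g21450.1 | chromatin remodeling 34")
#' @export
normalize_accession <- function(text) {
  stopifnot(is.character(text), all(nzchar(text)))
  head_part <- toupper(sub("[[:space:]|].*$", "", text))
  locus <- head_part
  isoform <- rep(NA_integer_, length(text))
  has_iso <- grepl("\\.[0-9]+$", head_part)
  isoform[has_iso] <-
    as.integer(sub("^.*\\.([0-9]+)$", "\\1", head_part[has_iso]))
  locus[has_iso] <- sub("\\.[0-9]+$", "", head_part[has_iso])
  tair <- grepl("^AT(?:[1-5CM])G[0-9]{5}$", locus)
  if (any(!tair)) {
    warning("accession(s) not in TAIR form, kept verbatim: ",
            paste(unique(locus[!tair]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(locus = locus, isoform = isoform)
}

# letters accepted in input sequences: the 20 standard plus ambiguity
# codes X/B/Z and selenocysteine U
.allowed_letters <- c(names(residue_formulas), "X", "B", "Z", "U")

#' Read a protein FASTA file
#'
#' Parses a multi-record amino-acid FASTA (via Biostrings) into a
#' protein table with TAIR accessions normalized: one row per record,
#' in file order. Duplicated accessions are retained with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `accession` (normalized locus),
#'   `isoform` (integer or NA), `description`, `sequence`.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    stop("no FASTA records in '", path, "'", call. = FALSE)
  }
  headers <- names(aa)
  seqs <- toupper(as.character(aa))
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", paste(.allowed_letters, collapse = "")),
                   seqs[i])
    if (bad > 0L) {
      stop("record '", headers[i], "': letter '",
           substr(seqs[i], bad, bad), "' at position ", bad,
           " outside the amino-acid alphabet", call. = FALSE)
    }
    if (!nzchar(seqs[i])) {
      stop("record '", headers[i], "' has an empty sequence", call. = FALSE)
    }
  }
  acc <- normalize_accession(headers)
  desc <- sub("^[^[:space:]|]+[[:space:]|]*", "", headers)
  desc <- sub("^\\|?[[:space:]]*", "", desc)
  out <- tibble::tibble(
    accession = acc$locus, isoform = acc$isoform,
    description = desc, sequence = unname(seqs)
  )
  key <- paste(out$accession, out$isoform)
  if (anyDuplicated(key)) {
    dup <- unique(out$accession[duplicated(key)])
    warning("duplicate accession(s) retained: ",
            paste(dup, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a protein table to FASTA
#'
#' Inverse of [read_fasta()]: headers are `accession[.isoform]
#' description`, sequences wrapped at `width` residues per line.
#'
#' @param records A protein tibble (columns `accession`, `isoform`,
#'   `description`, `sequence`).
#' @param path Output path.
#' @param width Residues per sequence line (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), width >= 1L)
  if (nrow(records) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  name <- records$accession
  if ("isoform" %in% names(records)) {
    has <- !is.na(records$isoform)
    name[has] <- paste0(name[has], ".", records$isoform[has])
  }
  if ("description" %in% names(records)) {
    has <- !is.na(records$description) & nzchar(records$description)
    name[has] <- paste(name[has], records$description[has])
  }
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- name
  Biostrings::writeXStringSet(aa, path, width = as.integer(width))
  invisible(path)
}

#' Record and residue counts of a protein FASTA
#'
#' @param path Path to a FASTA file.
#' @return A tibble with `n_records`, `n_loci`, `n_residues`.
#' @export
fasta_stats <- function(path) {
  prot <- read_fasta(path)
  tibble::tibble(
    n_records = nrow(prot),
    n_loci = dplyr::n_distinct(prot$accession),
    n_residues = sum(nchar(prot$sequence))
  )
}
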