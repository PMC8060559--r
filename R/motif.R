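#' Parse a PROSITE-style motif pattern
#'
#' Accepts two dialects and compiles both to the same token list:
#' \describe{
#'   \item{compact}{`"[RS]xRx{4}RL"` -- residue classes in brackets,
#'     `x` wildcards, `x{n}` / `x{a,b}` bounded gaps.}
#'   \item{dashed}{`"W-X-R-D-[TS]-G-X(100,140)-H-[VIL]-D"` -- tokens
#'     separated by dashes, `X(n)` / `X(a,b)` bounded gaps.}
#' }
#' Residues are case-insensitive. A gap of (n,n) is equivalent to n
#' consecutive wildcards.
#'
#' @param text Pattern text.
#' @return A `motif_pattern`: list of tokens, each of kind "class"
#'   (with `letters`), "wildcard", or "gap" (with `min`, `max`), plus
#'   the source text.
#' @examples
#' parse_pattern("[RS]xRx{4}RL")
#' @export
parse_pattern <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, nzchar(text))
  dashed <- grepl("-", gsub("\\[[^]]*\\]", "", text), fixed = TRUE)
  tokens <- if (dashed) .parse_dashed(text) else .parse_compact(text)
  structure(list(tokens = tokens, source = text), class = "motif_pattern")
}

.pattern_error <- function(text, offset, what) {
  stop("pattern parse error at offset ", offset, " in '", text, "': ",
       what, call. = FALSE)
}

.class_token <- function(inner, text, offset) {
  letters20 <- names(residue_formulas)
  members <- unique(strsplit(toupper(inner), "")[[1]])
  if (length(members) == 0L) .pattern_error(text, offset, "empty class")
  if (!all(members %in% letters20)) {
    .pattern_error(text, offset, "class with non-standard residue")
  }
  list(kind = "class", letters = members)
}

.gap_token <- function(spec, text, offset) {
  parts <- strsplit(spec, ",", fixed = TRUE)[[1]]
  bounds <- suppressWarnings(as.integer(parts))
  if (anyNA(bounds) || length(bounds) < 1L || length(bounds) > 2L) {
    .pattern_error(text, offset, "bad gap bounds")
  }
  if (length(bounds) == 1L) bounds <- c(bounds, bounds)
  if (bounds[1] > bounds[2] || bounds[1] < 0L) {
    .pattern_error(text, offset, "gap min exceeds max")
  }
  list(kind = "gap", min = bounds[1], max = bounds[2])
}

.parse_compact <- function(text) {
  chars <- strsplit(text, "")[[1]]
  tokens <- list()
  i <- 1L
  n <- length(chars)
  letters20 <- names(residue_formulas)
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      close <- regexpr("]", substring(text, i), fixed = TRUE)
      if (close < 0L) .pattern_error(text, i, "unbalanced '['")
      tokens[[length(tokens) + 1L]] <-
        .class_token(substring(text, i + 1L, i + close - 2L), text, i)
      i <- i + close
    } else if (ch %in% c("x", "X")) {
      if (i < n && chars[i + 1L] == "{") {
        close <- regexpr("}", substring(text, i), fixed = TRUE)
        if (close < 0L) .pattern_error(text, i, "unbalanced '{'")
        tokens[[length(tokens) + 1L]] <-
          .gap_token(substring(text, i + 2L, i + close - 2L), text, i)
        i <- i + close
      } else {
        tokens[[length(tokens) + 1L]] <- list(kind = "wildcard")
        i <- i + 1L
      }
    } else if (toupper(ch) %in% letters20) {
      tokens[[length(tokens) + 1L]] <-
        list(kind = "class", letters = toupper(ch))
      i <- i + 1L
    } else {
      .pattern_error(text, i, paste0("unexpected character '", ch, "'"))
    }
  }
  if (length(tokens) == 0L) .pattern_error(text, 1L, "empty pattern")
  tokens
}

.parse_dashed <- function(text) {
  parts <- strsplit(text, "-", fixed = TRUE)[[1]]
  tokens <- list()
  offset <- 1L
  letters20 <- names(residue_formulas)
  for (part in parts) {
    part <- trimws(part)
    if (!nzchar(part)) .pattern_error(text, offset, "empty token")
    if (grepl("^\\[.*\\]$", part)) {
      tokens[[length(tokens) + 1L]] <-
        .class_token(substring(part, 2L, nchar(part) - 1L), text, offset)
    } else if (grepl("^[xX]\\(([0-9]+(,[0-9]+)?)\\)$", part)) {
      tokens[[length(tokens) + 1L]] <-
        .gap_token(sub("^[xX]\\(([^)]*)\\)$", "\\1", part), text, offset)
    } else if (part %in% c("x", "X")) {
      tokens[[length(tokens) + 1L]] <- list(kind = "wildcard")
    } else if (nchar(part) == 1L && toupper(part) %in% letters20) {
      tokens[[length(tokens) + 1L]] <-
        list(kind = "class", letters = toupper(part))
    } else {
      .pattern_error(text, offset, paste0("unexpected token '", part, "'"))
    }
    offset <- offset + nchar(part) + 1L
  }
  tokens
}

#' Canonical compact rendering of a motif pattern
#'
#' @param x A `motif_pattern`.
#' @param ... Unused.
#' @return Pattern text in the compact dialect: single-letter classes
#'   bare, multi-letter classes bracketed and sorted, wildcards `x`,
#'   gaps `x{n}` / `x{a,b}`.
#' @export
format.motif_pattern <- function(x, ...) {
  paste(vapply(x$tokens, function(tok) {
    switch(tok$kind,
      class = if (length(tok$letters) == 1L) tok$letters else
        paste0("[", paste(sort(tok$letters), collapse = ""), "]"),
      wildcard = "x",
      gap = if (tok$min == tok$max) sprintf("x{%d}", tok$min) else
        sprintf("x{%d,%d}", tok$min, tok$max)
    )
  }, character(1)), collapse = "")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat("<motif_pattern>", format(x), "\n")
  invisible(x)
}

# enumerate the per-token length choices of a pattern as regexes of
# fixed length; returns tibble(regex, length)
.pattern_regexes <- function(pattern) {
  pieces <- lapply(pattern$tokens, function(tok) {
    switch(tok$kind,
      class = tibble::tibble(
        re = if (length(tok$letters) == 1L) tok$letters else
          paste0("[", paste(tok$letters, collapse = ""), "]"),
        len = 1L),
      wildcard = tibble::tibble(re = ".", len = 1L),
      gap = tibble::tibble(re = sprintf(".{%d}", tok$min:tok$max),
                           len = tok$min:tok$max)
    )
  })
  combos <- Reduce(function(a, b) {
    tidyr::crossing(a = seq_len(nrow(a)), b = seq_len(nrow(b))) |>
      (\(ix) tibble::tibble(re = paste0(a$re[ix$a], b$re[ix$b]),
                            len = a$len[ix$a] + b$len[ix$b]))()
  }, pieces)
  combos
}

#' Scan a sequence for motif matches
#'
#' Reports every distinct (start, end) occurrence of the pattern,
#' enumerating each admissible gap length; overlapping matches are
#' allowed. Ambiguity letters X/B/Z/U in the sequence satisfy only
#' wildcard and gap tokens, never residue classes.
#'
#' @param pattern A pattern string or [parse_pattern()] result.
#' @param sequence A sequence string, or a protein tibble (scanned
#'   row-wise).
#' @return A tibble with columns `accession` (NA for a bare string),
#'   `start`, `end` (1-based inclusive), ordered by accession, start,
#'   end.
#' @examples
#' scan_motif("[RS]xRx{4}RL", "SARGGGGRL")
#' @export
scan_motif <- function(pattern, sequence) {
  if (!inherits(pattern, "motif_pattern")) pattern <- parse_pattern(pattern)
  if (is.data.frame(sequence)) {
    hits <- purrr::map2_dfr(sequence$accession, sequence$sequence,
                            function(acc, s) {
                              h <- .scan_one(pattern, s)
                              h$accession <- acc
                              h
                            })
    if (nrow(hits) == 0L) {
      return(tibble::tibble(accession = character(), start = integer(),
                            end = integer()))
    }
    return(dplyr::arrange(hits[c("accession", "start", "end")],
                          .data$accession, .data$start, .data$end))
  }
  stopifnot(is.character(sequence), length(sequence) == 1L)
  out <- .scan_one(pattern, sequence)
  out$accession <- NA_character_
  out[c("accession", "start", "end")]
}

.scan_one <- function(pattern, sequence) {
  sequence <- toupper(sequence)
  regexes <- .pattern_regexes(pattern)
  hits <- list()
  for (i in seq_len(nrow(regexes))) {
    m <- gregexpr(paste0("(?=", regexes$re[i], ")"), sequence,
                  perl = TRUE)[[1]]
    starts <- as.integer(m[m > 0L])
    if (length(starts)) {
      hits[[length(hits) + 1L]] <-
        tibble::tibble(start = starts, end = starts + regexes$len[i] - 1L)
    }
  }
  out <- dplyr::bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  dplyr::arrange(dplyr::distinct(out), .data$start, .data$end)
}

#' Count proteins (loci) matched by a pattern
#'
#' Number of distinct loci with at least one motif occurrence;
#' isoforms of one locus count once.
#'
#' @param pattern A pattern string or [parse_pattern()] result.
#' @param proteome A protein tibble ([read_fasta()]).
#' @return Integer count.
#' @export
count_matching_proteins <- function(pattern, proteome) {
  stopifnot(is.data.frame(proteome))
  if (nrow(proteome) == 0L) return(0L)
  hits <- scan_motif(pattern, proteome)
  dplyr::n_distinct(hits$accession)
}
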