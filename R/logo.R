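#' Build a sequence-context logo around citrullination sites
#'
#' Aligns the ±`half_width` windows around a set of citrullinated
#' arginines and tabulates per-offset residue frequencies and
#' information content (log2 20 minus the Shannon entropy of the
#' frequency column, in bits). Windows are not padded at protein
#' termini: an offset outside a protein contributes nothing there, and
#' frequencies normalize over the observations actually present.
#'
#' @param sites A tibble with columns `accession` and `position`
#'   (1-based protein coordinate of a citrullinated R).
#' @param proteome A protein tibble ([read_fasta()]); every site must
#'   point at an R.
#' @param half_width Window half-width w (default 7; offsets -w..+w,
#'   the citrullinated R at 0).
#' @return A `cit_logo` object: `freq` (matrix offsets x 20 residues),
#'   `information` (named numeric, bits), `n_obs` (observations per
#'   offset), `n_sites`.
#' @export
build_logo <- function(sites, proteome, half_width = 7L) {
  stopifnot(is.data.frame(sites), is.data.frame(proteome),
            all(c("accession", "position") %in% names(sites)),
            half_width >= 1L, nrow(sites) >= 1L)
  seq_of <- stats::setNames(proteome$sequence, proteome$accession)
  offsets <- seq(-half_width, half_width)
  letters20 <- names(residue_formulas)
  counts <- matrix(0L, nrow = length(offsets), ncol = 20,
                   dimnames = list(as.character(offsets), letters20))
  for (i in seq_len(nrow(sites))) {
    acc <- sites$accession[i]
    pos <- sites$position[i]
    s <- seq_of[[acc]]
    if (is.null(s)) stop("site ", i, ": accession '", acc,
                         "' not in proteome", call. = FALSE)
    if (pos < 1L || pos > nchar(s) || substr(s, pos, pos) != "R") {
      stop("site ", i, " (", acc, " position ", pos,
           "): residue is not an arginine", call. = FALSE)
    }
    for (k in seq_along(offsets)) {
      p <- pos + offsets[k]
      if (p < 1L || p > nchar(s)) next
      res <- substr(s, p, p)
      if (res %in% letters20) counts[k, res] <- counts[k, res] + 1L
    }
  }
  n_obs <- rowSums(counts)
  freq <- counts / ifelse(n_obs == 0, 1, n_obs)
  information <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    if (!length(f)) return(NA_real_)
    log2(20) - (-sum(f * log2(f)))
  })
  structure(
    list(freq = freq, information = information, n_obs = n_obs,
         n_sites = nrow(sites), half_width = as.integer(half_width)),
    class = "cit_logo"
  )
}

#' @export
print.cit_logo <- function(x, ...) {
  cat(sprintf("<cit_logo> %d sites, offsets %+d..%+d\n", x$n_sites,
              -x$half_width, x$half_width))
  top <- apply(x$freq, 1, function(f) names(which.max(f)))
  cat("  top residues:", paste(top, collapse = ""), "\n")
  invisible(x)
}

#' Translate a logo into a search pattern
#'
#' Renders each offset whose top residue frequency reaches `threshold`
#' as a residue class, the citrullination target at offset 0 always as
#' R, and sub-threshold offsets as wildcards; runs of two or more
#' wildcards collapse to a bounded gap `x{n}` and uninformative
#' leading/trailing wildcards are trimmed. Within a specified offset
#' the class contains every residue whose frequency is clearly above
#' the uniform background of 1/20 (`min_class_freq`, default 0.2 =
#' four times background), so an evenly split two-residue preference
#' is kept intact rather than collapsed to its sampling-majority
#' member.
#'
#' @param logo A [build_logo()] result.
#' @param threshold Frequency threshold in (0, 1] an offset's top
#'   residue must reach for the offset to be specified (default 0.5).
#' @param min_class_freq Minimum frequency for class membership at a
#'   specified offset (default 0.2).
#' @return Pattern text in the compact dialect.
#' @export
consensus_pattern <- function(logo, threshold = 0.5, min_class_freq = 0.2) {
  stopifnot(inherits(logo, "cit_logo"), threshold > 0, threshold <= 1,
            min_class_freq > 0, min_class_freq <= 1)
  offsets <- as.integer(rownames(logo$freq))
  tokens <- character(length(offsets))
  for (k in seq_along(offsets)) {
    if (offsets[k] == 0L) {
      tokens[k] <- "R"
      next
    }
    f <- logo$freq[k, ]
    if (logo$n_obs[k] == 0L || max(f) < threshold) {
      tokens[k] <- "x"
      next
    }
    members <- sort(names(f)[f >= min_class_freq])
    tokens[k] <- if (length(members) == 1L) members else
      paste0("[", paste(members, collapse = ""), "]")
  }
  # trim uninformative flanks, collapse internal wildcard runs
  keep <- which(tokens != "x")
  if (length(keep) == 0L) return("x")
  tokens <- tokens[min(keep):max(keep)]
  out <- character()
  run <- 0L
  for (tok in tokens) {
    if (tok == "x") {
      run <- run + 1L
    } else {
      if (run == 1L) out <- c(out, "x")
      if (run >= 2L) out <- c(out, sprintf("x{%d}", run))
      run <- 0L
      out <- c(out, tok)
    }
  }
  paste(out, collapse = "")
}
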