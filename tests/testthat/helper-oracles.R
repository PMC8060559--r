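# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# residue monoisotopic masses as tabulated in standard references
# (independent of the package's elemental-composition route)
oracle_residue_masses <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931
)

oracle_peptide_mass <- function(sequence) {
  sum(oracle_residue_masses[strsplit(sequence, "")[[1]]]) + 18.010565
}

# digestion oracle: enumerate all substrings, keep those bounded by cut
# sites or termini with <= max_missed internal sites
oracle_digest <- function(sequence, max_missed) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  is_site <- function(i) {
    i >= 1 && i < n && chars[i] %in% c("K", "R") && chars[i + 1] != "P"
  }
  spans <- list()
  for (start in 1:n) {
    for (end in start:n) {
      left_ok <- start == 1 || is_site(start - 1)
      right_ok <- end == n || is_site(end)
      if (!left_ok || !right_ok) next
      internal <- if (end > start) {
        sum(vapply(start:(end - 1), is_site, logical(1)))
      } else 0
      if (internal <= max_missed) {
        spans[[length(spans) + 1]] <- c(start = start, end = end,
                                        missed = internal)
      }
    }
  }
  out <- do.call(rbind, spans)
  out[order(out[, "start"], out[, "end"]), , drop = FALSE]
}

# recursive position-by-position motif matcher
oracle_scan <- function(tokens, sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  match_from <- function(pos, t) {
    if (t > length(tokens)) {
      # end position (inclusive); invalid if we consumed past the end
      return(if (pos - 1L <= n) pos - 1L else integer())
    }
    if (pos > n) return(integer())
    tok <- tokens[[t]]
    if (tok$kind == "class") {
      if (chars[pos] %in% tok$letters) match_from(pos + 1L, t + 1L)
      else integer()
    } else if (tok$kind == "wildcard") {
      match_from(pos + 1L, t + 1L)
    } else {
      ends <- integer()
      for (len in tok$min:tok$max) {
        if (pos + len - 1L > n && len > 0L) break
        ends <- c(ends, match_from(pos + len, t + 1L))
      }
      unique(ends)
    }
  }
  hits <- list()
  for (start in seq_len(n)) {
    for (end in match_from(start, 1L)) {
      hits[[length(hits) + 1L]] <- c(start = start, end = end)
    }
  }
  if (!length(hits)) {
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  out <- unique(do.call(rbind, hits))
  out[order(out[, "start"], out[, "end"]), , drop = FALSE]
}

# binomial upper-tail by exhaustive enumeration of outcomes (n <= 12)
oracle_binom_tail <- function(k, n, p) {
  total <- 0
  for (x in k:n) {
    total <- total + choose(n, x) * p^x * (1 - p)^(n - x)
  }
  total
}

# maximum number of ion-peak matches within tolerance, by exhaustive
# assignment (each ion and peak used at most once)
oracle_max_matches <- function(ion_mz, peak_mz, tol) {
  best <- 0L
  recurse <- function(i, used) {
    if (i > length(ion_mz)) {
      best <<- max(best, sum(used > 0L))
      return(invisible())
    }
    cand <- which(abs(peak_mz - ion_mz[i]) <= tol & !seq_along(peak_mz) %in% used)
    recurse(i + 1L, used)  # leave ion i unmatched
    for (p in cand) recurse(i + 1L, c(used, p))
  }
  recurse(1L, integer())
  best
}

# a small citrullinated test peptide shared by several files
fixture_cit_peptide <- function() {
  modified_peptide("LNGRK", mods = list(mod_citrullination()),
                   positions = 4L)
}
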